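#!/usr/bin/env Rscript

# Stage 1: simulate the study inputs.
#
# Builds a two-chromosome F2 mapping population segregating Class I
# (interfering, gamma-renewal) and Class II (non-interfering, Poisson)
# crossovers on a sinusoidal SNP-density landscape, then derives the three
# kinds of raw data the downstream stages consume: a GBS-style marker
# table, seed fluorescence class counts, and eight-class pollen counts.

suppressPackageStartupMessages(library(meiomap))

seed <- 20260929
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(seed)

sinusoid_density <- function(length_bp, step = 5e5, cycles = 3) {
  start <- seq(0, length_bp - 1, by = step)
  end <- pmin(start + step, length_bp)
  mid <- (start + end) / 2
  data.frame(start = start, end = end,
             snps_per_kb = pmax(6 + 6 * sin(2 * pi * cycles * mid / length_bp), 0))
}

gm <- genome_model(
  data.frame(name = c("chr1", "chr2"), length = c(2e7, 1.5e7)),
  centromeres = c(chr1 = 1e7, chr2 = 7.5e6),
  snp_density = list(chr1 = sinusoid_density(2e7),
                     chr2 = sinusoid_density(1.5e7)))

shared_classI <- function(d, bd) 0.5 + 0.15 * d

pp_wt <- pathway_params(classI_base_cM_per_Mb = 3, classI_nu = 5,
                        classI_poly_response = shared_classI,
                        classII_base_cM_per_Mb = 2)
pp_mut <- pathway_params(classI_base_cM_per_Mb = 3, classI_nu = 5,
                         classI_poly_response = shared_classI,
                         classII_base_cM_per_Mb = 2,
                         classII_poly_response = density_suppression_response(0.5))

n_f2 <- 300
pop_wt <- simulate_f2_population(gm, pp_wt, n_f2)
pop_mut <- simulate_f2_population(gm, pp_mut, n_f2)

tab <- simulate_gbs(pop_wt, gm, mean_coverage = 5, error_rate = 0.002,
                    sites_per_Mb = 80)
write_marker_table(tab, file.path(out, "markers_wt.tsv"), seed = seed)

truth_wt <- crossovers_truth(pop_wt)
truth_mut <- crossovers_truth(pop_mut)
utils::write.table(truth_wt, file.path(out, "truth_wt.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(truth_mut, file.path(out, "truth_mut.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# fluorescence data implied by a 20-cM seed interval and a pollen
# three-marker system with moderate interference
seeds <- simulate_seed_counts(r = 0.2, n_total = 2500)
utils::write.table(
  data.frame(green_only = seeds$green_only, red_only = seeds$red_only,
             both = seeds$both, neither = seeds$neither),
  file.path(out, "seed_counts.csv"), sep = ",", quote = FALSE,
  row.names = FALSE)

pollen <- simulate_pollen_counts(d_b = 12, d_c = 15, coc = 0.35,
                                 n_total = 30000)
utils::write.table(as.data.frame(unlist(pollen)),
                   file.path(out, "pollen_counts.csv"), sep = ",",
                   quote = FALSE, col.names = FALSE)

cat("Simulated", n_f2, "wild-type and", n_f2, "mutant F2 individuals\n")
cat("  true crossovers (wt):", nrow(truth_wt),
    sprintf("(%.2f per F2)\n", nrow(truth_wt) / n_f2))
cat("  true crossovers (mut):", nrow(truth_mut),
    sprintf("(%.2f per F2)\n", nrow(truth_mut) / n_f2))
cat("  marker rows:", nrow(tab), "\n")
cat("Outputs in", out, "\n")
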