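#!/usr/bin/env Rscript

# Stage 3: recombination-landscape analysis.
#
# Bins wild-type and mutant crossovers into fixed windows, compares the
# two genome-wide profiles by rank correlation, ranks 100-kb windows by
# SNP density into groups of 12, and contrasts per-group crossover
# frequency (delta cM, mutant minus wild type) against SNP density with a
# loess trend — the windowed differential analysis of a polymorphism-
# responsive crossover landscape.

suppressPackageStartupMessages(library(meiomap))

out <- "results/analysis"
seed <- 20260929
set.seed(seed + 3)

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

truth_wt <- utils::read.table(file.path(out, "truth_wt.tsv"), header = TRUE,
                              sep = "\t")
truth_mut <- utils::read.table(file.path(out, "truth_mut.tsv"), header = TRUE,
                               sep = "\t")
n_f2 <- length(unique(truth_wt$individual))

# 0.3 Mb profile correlation between the two populations
w_wt3 <- bin_crossovers(truth_wt, gm, 3e5, n_f2)
w_mut3 <- bin_crossovers(truth_mut, gm, 3e5, n_f2)
cm <- profile_correlation(list(wt = w_wt3, mut = w_mut3))
utils::write.table(round(cm, 4), file.path(out, "profile_correlation.tsv"),
                   sep = "\t", quote = FALSE)
cat(sprintf("Spearman rho between wt and mutant 0.3-Mb profiles: %.3f\n",
            cm["wt", "mut"]))

# telomere-to-centromere scaled profile of the wild type
prof <- scaled_arm_profile(truth_wt, gm, n_bins = 20, n_individuals = n_f2)
utils::write.table(prof, file.path(out, "scaled_arm_profile_wt.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# SNP-density grouping at 100 kb and the differential (delta cM) curve
w_wt1 <- bin_crossovers(truth_wt, gm, 1e5, n_f2)
w_mut1 <- bin_crossovers(truth_mut, gm, 1e5, n_f2)
dens <- unlist(lapply(c("chr1", "chr2"), function(nm) {
  tr <- gm$snp_density[[nm]]
  mid <- (w_wt1$start + w_wt1$end)[w_wt1$chrom == nm] / 2
  tr$snps_per_kb[findInterval(mid, tr$start)]
}))
w_wt1$snps_per_kb <- dens
w_mut1$snps_per_kb <- dens

grouping <- snp_density_grouping(w_wt1, k = 12)
cat(sprintf("Ranked %d windows into %d density groups of %d (%d excluded)\n",
            nrow(grouping$windows), nrow(grouping$groups), grouping$k,
            nrow(grouping$excluded)))

g_wt <- group_recombination(grouping, w_wt1)
g_mut <- group_recombination(grouping, w_mut1)
d <- delta_cm(g_mut, g_wt)
trend <- loess_trend(d$mean_snps_per_kb, d$delta_cM, span = 0.75)
d$loess <- trend$fitted
utils::write.table(
  cbind(d, cM_wt = g_wt$cM_per_window, cM_mut = g_mut$cM_per_window),
  file.path(out, "delta_cm_groups.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)

rho <- correlate_delta_density(d$mean_snps_per_kb, d$delta_cM)
cat(sprintf("delta cM vs SNP density: rho = %.3f, P = %.3g (n = %d groups)\n",
            rho$rho, rho$p_value, rho$n))
hi <- d$mean_snps_per_kb > 6
cat(sprintf("  delta cM < 0 in %.0f%% of the %d groups above 6 SNPs/kb\n",
            100 * mean(d$delta_cM[hi] < 0), sum(hi)))
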