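# meiomap

Measurement and landscape analysis of meiotic crossovers in F2 plant
populations, with a fully synthetic meiosis generator so every analysis
is runnable — and checkable against known ground truth — without any
sequencing data.

The package is for geneticists working with two kinds of recombination
read-outs:

* **Fluorescent-tagged lines (FTLs)**, where genetic distance is scored
  from seed or pollen fluorescence classes. For seeds of a selfed
  coupling-phase hemizygous F1, with single-colour fraction
  f = (N_G + N_R)/N_T,

  cM = 100 · (1 − √(1 − 2f)),

  the exact inverse of the selfing gamete algebra. For three-fluorophore
  pollen, interval distances d_b and d_c are recombinant-gamete fractions
  × 100, the expected double-crossover count under independence is
  (d_b/100)(d_c/100)·N, and crossover interference is reported as
  1 − CoC with CoC = observed DCO / expected DCO.

* **Genotyping-by-sequencing (GBS) of F2 individuals**, where crossovers
  are called as genotype switches along chromosomes from sparse, noisy
  allele-count tables (quality > 100, depth > 2.5×, libraries under
  100,000 reads discarded; allele-fraction genotype bands; sliding-window
  majority-vote smoothing) and assigned to the midpoint between flanking
  informative markers. Windowed summaries, telomere–centromere scaled
  profiles, SNP-density percentile groups (ranked 100-kb windows in runs
  of 12) and differential Δ cM curves with loess trends quantify how the
  landscape shifts between genotypes.

The simulator generates all of these inputs from a configurable genome
model: Class I (interfering) crossovers as a stationary gamma-renewal
process with shape ν on the bivalent genetic scale, Class II
(non-interfering) crossovers as a superposed Poisson process, both
thinned by 1/2 per chromatid, with local rates responding to SNP density
and heterozygosity-block boundaries. See `vignettes/meiomap-methods.Rmd`
for the models and all numerical choices.

## Worked example

```r
library(meiomap)
set.seed(42)

# seed-based genetic distance at a true 20-cM interval
counts <- simulate_seed_counts(r = 0.2, n_total = 2500)
counts
#> seed_counts: G 214 | R 239 | both 1669 | neither 378 (n = 2500)
seed_cm(counts)
#>         cM standard_error n_total
#> 1 20.15014      0.9647701    2500

# two-interval pollen interference (truth: d_b 12, d_c 15, CoC 0.35)
i3bc_interference(simulate_pollen_counts(12, 15, coc = 0.35, n_total = 30000))
#>     d_b      d_c observed_dco expected_dco       coc interference ...
#> 1 12.02 14.86667          183      536.092 0.3413593    0.6586407

# simulate an F2 population and call crossovers from GBS-like markers
gm <- genome_model(data.frame(name = c("chr1", "chr2"),
                              length = c(2e7, 1.5e7)),
                   centromeres = c(chr1 = 1e7, chr2 = 7.5e6))
pop <- simulate_f2_population(gm, pathway_params(), n = 100)
tab <- simulate_gbs(pop, gm, mean_coverage = 30, error_rate = 0,
                    sites_per_Mb = 100, anchor_ends = TRUE)
calls <- call_crossovers_from_markers(tab, k = 3, min_support = 1)
nrow(calls); nrow(crossovers_truth(pop))
#> [1] 247
#> [1] 247
head(calls, 3)
#>   individual chrom left_marker_pos right_marker_pos midpoint transition
#> 1    F2_0001  chr1         1644749          1671087  1657918     AB->BB
#> 2    F2_0001  chr2        11230170         11236113 11233141     AB->AA
#> 3    F2_0002  chr2         3502022          3508376  3505199     BB->AB
```

The seed estimate recovers the 20-cM truth within its binomial standard
error; the pollen statistics recover the injected interference of 0.65;
and at noise-free depth the caller's 247 calls match the 247 simulated
crossovers, each inside its true flanking-marker interval.

## Analysis workflow

The `analysis/` scripts chain the full study on simulated data and write
their tables under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R        # populations, markers, seed/pollen counts
Rscript analysis/02_call_crossovers.R # filters, genotype switches, counts
Rscript analysis/03_landscape.R       # windows, density groups, delta cM, loess
Rscript analysis/04_ftl_estimates.R   # seed/pollen estimators, Welch comparison
```

A YAML-configured end-to-end run (`validate_config()` + `run_pipeline()`)
produces the same stages with a provenance manifest; marker tables can
also be ingested from TSV or converted from a VCF with per-sample `AD`
fields (`convert_vcf_to_marker_table()`).

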