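# Shared fixtures: small genome models and simulation settings used across
# the suite. All data are generated in code at test time.

two_chrom_model <- function(het_blocks = NULL, snp_density = NULL) {
  genome_model(
    data.frame(name = c("chr1", "chr2"), length = c(2e7, 1.5e7)),
    centromeres = c(chr1 = 1e7, chr2 = 7.5e6),
    snp_density = snp_density, het_blocks = het_blocks)
}

# piecewise-constant sinusoidal SNP-density track covering 0..12 SNPs/kb,
# in steps of `step` bp, used for landscape experiments
sinusoid_density <- function(length_bp, step = 5e5, cycles = 3) {
  start <- seq(0, length_bp - 1, by = step)
  end <- pmin(start + step, length_bp)
  mid <- (start + end) / 2
  d <- 6 + 6 * sin(2 * pi * cycles * mid / length_bp)
  data.frame(start = start, end = end, snps_per_kb = pmax(d, 0))
}

landscape_model <- function() {
  two_chrom_model(snp_density = list(
    chr1 = sinusoid_density(2e7),
    chr2 = sinusoid_density(1.5e7)))
}

# per-individual true crossover counts aligned to a count table
truth_counts <- function(truth, ids) {
  tt <- table(truth$individual)
  vapply(ids, function(i) if (i %in% names(tt)) tt[[i]] else 0, numeric(1))
}

# fraction of calls whose flanking-marker interval contains a true event
containment_fraction <- function(calls, truth) {
  if (!nrow(calls)) return(NA_real_)
  ok <- mapply(function(ind, l, r, ch) {
    any(truth$individual == ind & truth$chrom == ch &
          truth$pos >= l & truth$pos <= r)
  }, calls$individual, calls$left_marker_pos, calls$right_marker_pos,
  calls$chrom)
  mean(ok)
}

# gamete-level coefficient of coincidence over two physical intervals
coc_from_gametes <- function(gametes, b = c(0, 1e7), c_int = c(1e7, 2e7)) {
  in_b <- vapply(gametes, function(g) any(g$pos >= b[1] & g$pos < b[2]),
                 logical(1))
  in_c <- vapply(gametes, function(g) any(g$pos >= c_int[1] & g$pos < c_int[2]),
                 logical(1))
  n <- length(gametes)
  p_b <- mean(in_b)
  p_c <- mean(in_c)
  p_bc <- mean(in_b & in_c)
  list(coc = p_bc / (p_b * p_c), n_b = sum(in_b), n_c = sum(in_c),
       n_bc = sum(in_b & in_c), n = n)
}
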