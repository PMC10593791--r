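test_that("neutral responses give constant intensity tracks at base rates", {
  gm <- two_chrom_model()
  pp <- pathway_params(classI_base_cM_per_Mb = 3, classII_base_cM_per_Mb = 1)
  tr <- build_intensity_profiles(gm, pp)
  for (nm in names(tr)) {
    expect_true(all(tr[[nm]]$classI_cM_per_Mb == 3))
    expect_true(all(tr[[nm]]$classII_cM_per_Mb == 1))
  }
  expect_equal(unname(track_map_length(tr$chr1)), c(60, 20))
})

test_that("density-suppression response scales Class II directly", {
  # response 1/(1+d) evaluated at d = 4 SNPs/kb must give 0.2 x base
  gm <- two_chrom_model(snp_density = list(
    chr1 = data.frame(start = 0, end = 2e7, snps_per_kb = 4),
    chr2 = data.frame(start = 0, end = 1.5e7, snps_per_kb = 4)))
  pp <- pathway_params(classII_base_cM_per_Mb = 1,
                       classII_poly_response = function(d) 1 / (1 + d))
  tr <- build_intensity_profiles(gm, pp)
  expect_true(all(abs(tr$chr1$classII_cM_per_Mb - 0.2) < 1e-12))
})

test_that("boundary stimulation peaks near a HET/HOM junction", {
  # step density and a het/hom junction at 10 Mb; oracle = direct pointwise
  # evaluation of the response spec
  gm <- two_chrom_model(
    snp_density = list(
      chr1 = data.frame(start = c(0, 1e7), end = c(1e7, 2e7),
                        snps_per_kb = c(0, 8)),
      chr2 = data.frame(start = 0, end = 1.5e7, snps_per_kb = 4)),
    het_blocks = list(chr1 = data.frame(start = 1e7, end = 2e7),
                      chr2 = data.frame(start = 0, end = 1.5e7)))
  A <- 2; L <- 5e5
  pp <- pathway_params(classI_base_cM_per_Mb = 3,
                       classI_poly_response = boundary_stimulation_response(A, L))
  tr <- build_intensity_profiles(gm, pp, grid_bp = 5e4)
  t1 <- tr$chr1
  het <- t1$start >= 1e7
  # oracle: base * (1 + A exp(-dist/L)) at segment midpoints
  mid <- (t1$start + t1$end) / 2
  oracle <- 3 * (1 + A * exp(-abs(mid - 1e7) / L))
  expect_equal(t1$classI_cM_per_Mb, oracle, tolerance = 1e-10)
  # local maximum sits within the boundary window on the het side
  peak <- t1$start[het][which.max(t1$classI_cM_per_Mb[het])]
  expect_lt(peak - 1e7, 2 * L)
})

test_that("zero intensity yields no crossovers; Poisson limit has Poisson moments", {
  gm <- two_chrom_model()
  pp0 <- pathway_params(classI_base_cM_per_Mb = 0, classII_base_cM_per_Mb = 0)
  tr0 <- build_intensity_profiles(gm, pp0)
  set.seed(42)
  for (i in 1:20) expect_equal(nrow(simulate_gamete(tr0$chr1, nu = 1)), 0)

  # nu = 1, 50 cM total -> gamete count ~ Poisson(0.5)
  pp <- pathway_params(classI_base_cM_per_Mb = 2.5, classII_base_cM_per_Mb = 0,
                       classI_nu = 1)
  tr <- build_intensity_profiles(gm, pp)
  set.seed(202)
  n_draw <- 10000
  counts <- vapply(seq_len(n_draw),
                   function(i) nrow(simulate_gamete(tr$chr1, nu = 1)),
                   numeric(1))
  lambda <- 0.5
  se_mean <- sqrt(lambda / n_draw)
  expect_lt(abs(mean(counts) - lambda), 3 * se_mean)
  # index of dispersion within its chi-square null band
  disp <- (n_draw - 1) * var(counts) / mean(counts)
  band <- qchisq(c(0.0005, 0.9995), df = n_draw - 1)
  expect_gt(disp, band[1])
  expect_lt(disp, band[2])
})

test_that("non-integer interference shape draws a stationary renewal process", {
  gm <- two_chrom_model()
  pp <- pathway_params(classI_base_cM_per_Mb = 2.5, classII_base_cM_per_Mb = 0,
                       classI_nu = 2.5)
  tr <- build_intensity_profiles(gm, pp)
  set.seed(99)
  counts <- vapply(seq_len(4000),
                   function(i) nrow(simulate_gamete(tr$chr1, nu = 2.5)),
                   numeric(1))
  # stationarity preserves the mean count (map length / 100)
  expect_lt(abs(mean(counts) - 0.5), 3 * sd(counts) / sqrt(4000))
})

test_that("interference is absent at nu = 1 and present at nu = 10", {
  # two adjacent 10-cM intervals on one chromosome
  gm <- genome_model(data.frame(name = "chr1", length = 2e7),
                     c(chr1 = 1e7))
  pp1 <- pathway_params(classI_base_cM_per_Mb = 1, classII_base_cM_per_Mb = 0,
                        classI_nu = 1)
  tr <- build_intensity_profiles(gm, pp1)
  set.seed(7)
  g1 <- lapply(seq_len(30000), function(i) simulate_gamete(tr$chr1, nu = 1))
  est1 <- coc_from_gametes(g1)
  se <- est1$coc * sqrt(1 / est1$n_bc + 1 / est1$n_b + 1 / est1$n_c)
  expect_lt(abs(est1$coc - 1), 3 * se)

  g10 <- lapply(seq_len(30000), function(i) simulate_gamete(tr$chr1, nu = 10))
  est10 <- coc_from_gametes(g10)
  expect_lt(est10$coc, 1)
})

test_that("F2 individuals conserve crossovers and match the expected map", {
  gm <- two_chrom_model()
  pp0 <- pathway_params(classI_base_cM_per_Mb = 0, classII_base_cM_per_Mb = 0)
  set.seed(3)
  pop0 <- simulate_f2_population(gm, pp0, 1)
  seg <- pop0$individuals[[1]]$chromosomes$chr1$segments
  expect_equal(nrow(seg), 1)
  expect_true(seg$genotype %in% c("AA", "AB", "BB"))

  # total map 200 cM per gamete -> mean 4 crossovers per F2
  ppm <- pathway_params(classI_base_cM_per_Mb = 200 / 35 * 0.8,
                        classII_base_cM_per_Mb = 200 / 35 * 0.2,
                        classI_nu = 1)
  set.seed(11)
  pop <- simulate_f2_population(gm, ppm, 500)
  truth <- crossovers_truth(pop)
  ids <- vapply(pop$individuals, `[[`, character(1), "id")
  counts <- truth_counts(truth, ids)
  expect_lt(abs(mean(counts) - 4), 3 * sd(counts) / sqrt(500))

  # conservation: segment boundaries equal crossover count per individual
  for (ind in pop$individuals[1:20]) {
    nb <- sum(vapply(ind$chromosomes, function(ch) {
      nrow(ch$segments) - 1L
    }, integer(1)))
    nx <- sum(vapply(ind$chromosomes, function(ch) {
      nrow(ch$gametes[[1]]$xo) + nrow(ch$gametes[[2]]$xo)
    }, integer(1)))
    expect_equal(nb, nx)
  }

  # segments tile each chromosome exactly
  seg1 <- pop$individuals[[1]]$chromosomes$chr1$segments
  expect_equal(seg1$start[1], 0)
  expect_equal(seg1$end[nrow(seg1)], 2e7)
  if (nrow(seg1) > 1) {
    expect_equal(seg1$start[-1], seg1$end[-nrow(seg1)])
  }
})

test_that("GBS tables have Poisson depth, clean homozygote counts and no HOM-block sites", {
  gm <- two_chrom_model(het_blocks = list(
    chr1 = data.frame(start = c(0, 1.2e7), end = c(8e6, 2e7)),
    chr2 = data.frame(start = 0, end = 1.5e7)))
  pp <- pathway_params(classI_nu = 1)
  set.seed(5)
  pop <- simulate_f2_population(gm, pp, 10)
  tab <- simulate_gbs(pop, gm, mean_coverage = 3, error_rate = 0,
                      sites_per_Mb = 40)
  # no marker inside the homozygous block (8 - 12 Mb on chr1)
  expect_equal(sum(tab$chrom == "chr1" & tab$pos > 8e6 & tab$pos <= 1.2e7), 0)
  # mean depth within 3 standard errors of the Poisson mean
  depth <- tab$ref_count + tab$alt_count
  expect_lt(abs(mean(depth) - 3), 3 * sqrt(3 / length(depth)))
  # at zero error, a fully parental AA individual never reports alt reads
  pp0 <- pathway_params(classI_base_cM_per_Mb = 0, classII_base_cM_per_Mb = 0)
  pop0 <- simulate_f2_population(gm, pp0, 30)
  tab0 <- simulate_gbs(pop0, gm, mean_coverage = 4, error_rate = 0,
                       sites_per_Mb = 20)
  aa_chr1 <- vapply(pop0$individuals, function(ind) {
    all(ind$chromosomes$chr1$segments$genotype == "AA")
  }, logical(1))
  expect_true(any(aa_chr1))  # deterministic under the fixed seed
  id <- pop0$individuals[[which(aa_chr1)[1]]]$id
  expect_true(all(tab0$alt_count[tab0$individual == id &
                                   tab0$chrom == "chr1"] == 0))
  expect_true(all(tab$ref_count >= 0 & tab$alt_count >= 0))
  expect_true(!is.unsorted(tab$pos[tab$individual == tab$individual[1] &
                                     tab$chrom == "chr1"]))
})

test_that("seeded simulation runs are bit-reproducible", {
  gm <- two_chrom_model()
  pp <- pathway_params()
  run <- function() {
    set.seed(123)
    pop <- simulate_f2_population(gm, pp, 5)
    simulate_gbs(pop, gm, mean_coverage = 3, error_rate = 0.01,
                 sites_per_Mb = 20)
  }
  expect_identical(run(), run())
})

test_that("seed class probabilities are a valid distribution inverted by the estimator", {
  for (r in seq(0, 1, by = 0.05)) {
    p <- seed_class_probs(r)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  expect_equal(unname(seed_class_probs(0)), c(0, 0, 3 / 4, 1 / 4))
  expect_equal(unname(seed_class_probs(1)), c(1 / 4, 1 / 4, 1 / 2, 0))

  # independent oracle: enumerate the 4x4 gamete-pair table at r = 0.2
  r <- 0.2
  gam <- c(GR = (1 - r) / 2, G = r / 2, R = r / 2, none = (1 - r) / 2)
  cls <- matrix(0, 1, 4, dimnames = list(NULL, c("green_only", "red_only",
                                                 "both", "neither")))
  for (a in names(gam)) for (b in names(gam)) {
    g <- grepl("G", a) || grepl("G", b)
    rr <- grepl("R", a) || grepl("R", b)
    key <- if (g && rr) "both" else if (g) "green_only" else
      if (rr) "red_only" else "neither"
    cls[1, key] <- cls[1, key] + gam[[a]] * gam[[b]]
  }
  expect_equal(seed_class_probs(0.2), cls[1, c("green_only", "red_only",
                                               "both", "neither")],
               tolerance = 1e-12)
  expect_equal(unname(seed_class_probs(0.2)),
               c(0.09, 0.09, 0.66, 0.16), tolerance = 1e-12)
})

test_that("pollen class model is feasible, normalised and exact at the expectation", {
  p <- pollen_class_probs(10, 10, 1)
  expect_equal(sum(p), 1)
  # d = 10 cM each, coc = 1, n = 10000: DCO classes total 100, each
  # single-interval recombinant class pair totals 900
  ec <- expected_pollen_counts(10, 10, 1, 10000)
  expect_equal(ec$m1m3 + ec$m2, 100)
  expect_equal(ec$m1 + ec$m2m3, 900)
  expect_equal(ec$m1m2 + ec$m3, 900)
  # no recombination: only parental classes populated
  p0 <- pollen_class_probs(0, 0, 1)
  expect_equal(unname(p0[c("m1m2m3", "none")]), c(0.5, 0.5))
  expect_equal(sum(p0) - p0[["m1m2m3"]] - p0[["none"]], 0)
  # infeasible coincidence rejected
  expect_error(pollen_class_probs(1, 50, 10), "infeasible")
  # multinomial draws sum to n_total
  set.seed(8)
  pc <- simulate_pollen_counts(12, 15, 0.35, 30000)
  expect_equal(attr(pc, "n_total"), 30000)
})
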