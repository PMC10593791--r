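test_that("window binning uses half-open windows and conserves totals", {
  gm <- two_chrom_model()
  calls <- data.frame(chrom = "chr1", midpoint = 150000)
  w <- bin_crossovers(calls, gm, window_bp = 3e5, n_individuals = 1)
  expect_equal(w$xo_per_f2[w$chrom == "chr1" & w$start == 0], 1)

  # a call exactly at a window start belongs to the right-hand window
  calls2 <- data.frame(chrom = "chr1", midpoint = 3e5)
  w2 <- bin_crossovers(calls2, gm, window_bp = 3e5, n_individuals = 1)
  expect_equal(w2$n_crossovers[w2$chrom == "chr1" & w2$start == 3e5], 1)
  expect_equal(w2$n_crossovers[w2$chrom == "chr1" & w2$start == 0], 0)

  # conservation over random calls
  set.seed(101)
  calls3 <- data.frame(
    chrom = sample(c("chr1", "chr2"), 500, replace = TRUE),
    midpoint = NA_real_)
  calls3$midpoint <- ifelse(calls3$chrom == "chr1",
                            runif(500, 0, 2e7), runif(500, 0, 1.5e7))
  w3 <- bin_crossovers(calls3, gm, window_bp = 3e5, n_individuals = 10)
  expect_equal(sum(w3$n_crossovers), 500)
  expect_equal(sum(w3$xo_per_f2), 50)

  expect_error(bin_crossovers(data.frame(chrom = "chr1", midpoint = 3e7),
                              gm, 3e5, 1), "beyond")
})

test_that("scaled arm profile maps telomere to 0 and centromere to 1", {
  gm <- two_chrom_model()
  # a call at the very start of chr1 (left-arm telomere) lands in bin 1
  p1 <- scaled_arm_profile(data.frame(chrom = "chr1", midpoint = 1),
                           gm, n_bins = 10)
  expect_equal(p1$n_crossovers[1], 1)
  # mirror symmetry: equal fractional positions on the two arms share a bin
  cen <- 1e7; len <- 2e7
  f <- 0.37
  both <- data.frame(chrom = "chr1",
                     midpoint = c(f * cen, len - f * (len - cen)))
  p2 <- scaled_arm_profile(both, gm, n_bins = 10)
  expect_equal(sum(p2$n_crossovers > 0), 1)
  expect_equal(max(p2$n_crossovers), 2)

  # uniform intensity gives a flat profile (chi-square GOF not rejected)
  ppu <- pathway_params(classI_base_cM_per_Mb = 5, classI_nu = 1,
                        classII_base_cM_per_Mb = 0)
  set.seed(111)
  pop <- simulate_f2_population(two_chrom_model(), ppu, 700)
  truth <- crossovers_truth(pop)
  prof <- scaled_arm_profile(truth, gm, n_bins = 10, n_individuals = 700)
  gof <- chisq.test(prof$n_crossovers)
  expect_gt(gof$p.value, 0.01)
})

test_that("profile correlation is rank-invariant and detects a shared landscape", {
  gm <- landscape_model()
  pp <- pathway_params(
    classI_base_cM_per_Mb = 3,
    classI_poly_response = function(d, bd) 0.5 + 0.15 * d,
    classII_base_cM_per_Mb = 2,
    classII_poly_response = density_suppression_response(0.4))
  set.seed(121)
  pop1 <- simulate_f2_population(gm, pp, 300)
  pop2 <- simulate_f2_population(gm, pp, 300)
  w1 <- bin_crossovers(crossovers_truth(pop1), gm, 3e5, 300)
  w2 <- bin_crossovers(crossovers_truth(pop2), gm, 3e5, 300)
  cm <- profile_correlation(list(a = w1, b = w2))
  expect_equal(diag(cm), c(a = 1, b = 1))
  expect_gt(cm["a", "b"], 0)
  # significance of the shared landscape
  ct <- cor.test(w1$xo_per_f2, w2$xo_per_f2, method = "spearman",
                 exact = FALSE)
  expect_lt(ct$p.value, 0.01)

  # rank invariance: monotone transform leaves rho = 1
  w1t <- w1
  w1t$xo_per_f2 <- exp(w1$xo_per_f2)
  expect_equal(profile_correlation(list(x = w1, y = w1t))["x", "y"], 1)

  # mismatched grids are an error
  w300 <- bin_crossovers(crossovers_truth(pop1), gm, 3e5, 300)
  w100 <- bin_crossovers(crossovers_truth(pop1), gm, 1e5, 300)
  expect_error(profile_correlation(list(w300, w100)), "grids")
})

test_that("density grouping forms deterministic complete runs of k", {
  # 1191 ranked windows in groups of 12: 99 groups, 3 excluded
  set.seed(131)
  w <- data.frame(chrom = "chr1", start = (0:1190) * 1e5,
                  end = (1:1191) * 1e5,
                  n_crossovers = rpois(1191, 2),
                  snps_per_kb = runif(1191, 0, 14))
  class(w) <- c("window_track", "data.frame")
  attr(w, "n_individuals") <- 100
  g <- snp_density_grouping(w, k = 12)
  expect_equal(nrow(g$groups), 99)
  expect_equal(nrow(g$excluded), 3)
  expect_true(all(table(g$windows$group) == 12))
  # the excluded remainder is the high-density tail
  expect_true(min(g$excluded$snps_per_kb) >=
                max(g$windows$snps_per_kb[!is.na(g$windows$group)]))
  # group means are non-decreasing along the ranked list
  expect_true(all(diff(g$groups$mean_snps_per_kb) >= 0))

  # n = 24, k = 12: two complete groups, none excluded
  g2 <- snp_density_grouping(w[1:24, ], k = 12)
  expect_equal(nrow(g2$groups), 2)
  expect_equal(nrow(g2$excluded), 0)

  expect_error(snp_density_grouping(w[1:5, ], k = 12), "fewer windows")

  # determinism under permuted row order, including density ties
  w$snps_per_kb[5] <- w$snps_per_kb[17]  # inject a tie
  g_a <- snp_density_grouping(w, k = 12)
  perm <- w[sample(nrow(w)), ]
  g_b <- snp_density_grouping(perm, k = 12)
  key <- function(g) paste(g$windows$chrom, g$windows$start, g$windows$group)
  expect_setequal(key(g_a), key(g_b))
})

test_that("group recombination aggregates and conserves normalised crossovers", {
  set.seed(141)
  w <- data.frame(chrom = "chr1", start = (0:119) * 1e5, end = (1:120) * 1e5,
                  n_crossovers = rpois(120, 3),
                  snps_per_kb = runif(120, 0, 10))
  class(w) <- c("window_track", "data.frame")
  attr(w, "n_individuals") <- 50
  g <- snp_density_grouping(w, k = 12)
  gr <- group_recombination(g, w)
  expect_equal(nrow(gr), 10)
  # conservation: group totals + excluded = all crossovers
  expect_equal(sum(gr$n_crossovers) + sum(g$excluded$n_crossovers),
               sum(w$n_crossovers))
  # zero calls -> all groups zero
  w0 <- w
  w0$n_crossovers <- 0
  expect_true(all(group_recombination(g, w0)$cM_per_window == 0))
})

test_that("delta cM is an antisymmetric elementwise difference", {
  a <- data.frame(group = 1:5, mean_snps_per_kb = 1:5,
                  n_crossovers = c(5, 7, 2, 8, 1),
                  cM_per_window = c(0.5, 0.7, 0.2, 0.8, 0.1))
  b <- a
  b$cM_per_window <- c(0.4, 0.9, 0.2, 0.2, 0.3)
  expect_true(all(delta_cm(a, a)$delta_cM == 0))
  expect_equal(delta_cm(a, b)$delta_cM, -delta_cm(b, a)$delta_cM)
  bad <- b
  bad$group <- 2:6
  expect_error(delta_cm(a, bad), "match")
})

test_that("loess trend reproduces constants and low-order polynomials", {
  x <- seq(1, 10, length.out = 30)
  cfit <- loess_trend(x, rep(4, 30), span = 0.75)
  expect_equal(cfit$fitted, rep(4, 30), tolerance = 1e-8)
  lfit <- loess_trend(x, 2 * x, span = 1, degree = 1)
  expect_equal(lfit$fitted, 2 * x, tolerance = 1e-6)
  # smoothing reduces noise around a quadratic signal
  set.seed(151)
  y <- (x - 5)^2 + rnorm(30, sd = 2)
  sfit <- loess_trend(x, y, span = 0.5)
  expect_lt(sqrt(mean((sfit$fitted - (x - 5)^2)^2)),
            sqrt(mean((y - (x - 5)^2)^2)))
  expect_error(loess_trend(x[1:5], x[1:5]), "at least 10")
  expect_error(loess_trend(x, x, span = 0.01), "span")
})

test_that("rank correlation handles ties and respects the null", {
  x <- 1:20
  expect_equal(correlate_delta_density(x, -x)$rho, -1)
  y <- x
  y[3] <- y[4]  # tie pair
  expect_gt(correlate_delta_density(x, y)$rho, 0.99)
  expect_error(correlate_delta_density(x, rep(1, 20)), "constant")
  # independent vectors rarely show |rho| > 0.3 at n = 99
  set.seed(161)
  hits <- vapply(seq_len(400), function(i) {
    abs(correlate_delta_density(rnorm(99), rnorm(99))$rho) < 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("injected Class II density suppression shows up in the delta cM curve", {
  gm <- landscape_model()
  shared_classI <- function(d, bd) 0.5 + 0.15 * d
  pp_wt <- pathway_params(classI_base_cM_per_Mb = 3,
                          classI_poly_response = shared_classI,
                          classII_base_cM_per_Mb = 2)
  pp_mut <- pathway_params(classI_base_cM_per_Mb = 3,
                           classI_poly_response = shared_classI,
                           classII_base_cM_per_Mb = 2,
                           classII_poly_response =
                             density_suppression_response(0.5))
  set.seed(171)
  pop_wt <- simulate_f2_population(gm, pp_wt, 400)
  pop_mut <- simulate_f2_population(gm, pp_mut, 400)
  w_wt <- bin_crossovers(crossovers_truth(pop_wt), gm, 1e5, 400)
  w_mut <- bin_crossovers(crossovers_truth(pop_mut), gm, 1e5, 400)
  # density per window from the model track (deterministic)
  dens <- unlist(lapply(c(chr1 = "chr1", chr2 = "chr2"), function(nm) {
    tr <- gm$snp_density[[nm]]
    mid <- (w_wt$start + w_wt$end)[w_wt$chrom == nm] / 2
    tr$snps_per_kb[findInterval(mid, tr$start)]
  }))
  w_wt$snps_per_kb <- dens
  w_mut$snps_per_kb <- dens
  grouping <- snp_density_grouping(w_wt, k = 12)
  d <- delta_cm(group_recombination(grouping, w_mut),
                group_recombination(grouping, w_wt))
  hi <- d$mean_snps_per_kb > 6
  expect_gt(sum(hi), 5)
  expect_gte(mean(d$delta_cM[hi] < 0), 0.9)
})
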