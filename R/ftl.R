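#' Seed fluorescence class counts
#'
#' Container for the four seed classes of a two-colour fluorescent-tagged
#' line: green-only, red-only, both colours, neither.
#'
#' @param green_only,red_only,both,neither class counts (>= 0; may be
#'   non-integer for expectation counts).
#' @return An object of class `seed_counts`.
#' @export
seed_counts <- function(green_only, red_only, both, neither) {
  x <- c(green_only = green_only, red_only = red_only,
         both = both, neither = neither)
  if (any(x < 0) || any(!is.finite(x))) stop("seed counts must be finite and >= 0")
  structure(list(green_only = green_only, red_only = red_only,
                 both = both, neither = neither,
                 n_total = sum(x)),
            class = "seed_counts")
}

#' @export
print.seed_counts <- function(x, ...) {
  cat(sprintf("seed_counts: G %s | R %s | both %s | neither %s (n = %s)\n",
              format(x$green_only), format(x$red_only), format(x$both),
              format(x$neither), format(x$n_total)))
  invisible(x)
}

#' Pollen fluorescence class counts
#'
#' Either four classes (`R`, `Y`, `RY`, `N`) from a two-colour interval, or
#' eight classes keyed by the subset of three fluorophores present
#' (`m1m2m3`, `m1m2`, `m2m3`, `m1m3`, `m1`, `m2`, `m3`, `none`), ordered by
#' genomic position m1 < m2 < m3.
#'
#' @param counts named numeric vector with exactly the 4-class or 8-class
#'   keys; all >= 0.
#' @return An object of class `pollen_counts` with attribute
#'   `n_classes` (4 or 8).
#' @export
pollen_counts <- function(counts) {
  keys8 <- c("m1m2m3", "m1m2", "m2m3", "m1m3", "m1", "m2", "m3", "none")
  keys4 <- c("R", "Y", "RY", "N")
  nm <- names(counts)
  if (setequal(nm, keys8)) {
    counts <- counts[keys8]
    k <- 8L
  } else if (setequal(nm, keys4)) {
    counts <- counts[keys4]
    k <- 4L
  } else {
    stop("counts must be named with the 4-class (R, Y, RY, N) or 8-class keys")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("pollen counts must be finite and >= 0")
  }
  structure(as.list(counts),
            n_total = sum(counts), n_classes = k, class = "pollen_counts")
}

#' @export
print.pollen_counts <- function(x, ...) {
  cat(sprintf("pollen_counts (%d classes, n = %s):\n",
              attr(x, "n_classes"), format(attr(x, "n_total"))))
  print(unlist(x))
  invisible(x)
}

#' Classify seeds from two-channel fluorescence intensities
#'
#' Applies fixed user-supplied channel thresholds (the conventional manual
#' thresholding from fluorescence histograms): a seed is scored positive
#' for a colour when its intensity strictly exceeds that channel's
#' threshold.
#'
#' @param table data.frame with columns `seed_id` (optional),
#'   `red_intensity`, `green_intensity`; intensities >= 0.
#' @param red_threshold,green_threshold channel thresholds (> 0).
#' @return A [seed_counts] object.
#' @export
classify_seeds <- function(table, red_threshold, green_threshold) {
  stopifnot(is.data.frame(table),
            all(c("red_intensity", "green_intensity") %in% names(table)))
  if (!nrow(table)) stop("empty seed intensity table")
  if (red_threshold <= 0 || green_threshold <= 0) stop("thresholds must be > 0")
  g <- table$green_intensity > green_threshold
  r <- table$red_intensity > red_threshold
  seed_counts(green_only = sum(g & !r), red_only = sum(r & !g),
              both = sum(g & r), neither = sum(!g & !r))
}

#' Histogram-valley threshold helper
#'
#' Optional helper for choosing a channel threshold as the deepest valley
#' of a kernel density estimate of log-intensities between the two modes.
#' Never the default — [classify_seeds] requires explicit thresholds.
#'
#' @param intensities positive channel intensities.
#' @param bw density bandwidth passed to [stats::density].
#' @return Suggested threshold on the original intensity scale.
#' @export
suggest_threshold <- function(intensities, bw = "nrd0") {
  x <- log(intensities[intensities > 0])
  d <- stats::density(x, bw = bw)
  y <- d$y
  # interior local minima of the density
  locmin <- which(diff(sign(diff(y))) == 2) + 1
  if (!length(locmin)) stop("no valley found in intensity histogram")
  exp(d$x[locmin[which.min(y[locmin])]])
}

#' Genetic distance from seed fluorescence classes
#'
#' For NG green-only seeds, NR red-only seeds and NT total seeds from a
#' selfed coupling-phase hemizygous F1, the single-colour fraction
#' f = (NG + NR)/NT equals (1 - q^2)/2 with q = 1 - r, so the map distance
#' is cM = 100 * (1 - sqrt(1 - 2 f)) — the exact inverse of the selfing
#' class-probability algebra. The standard error is delta-method
#' propagation of the binomial variance of f:
#' SE = 100 / sqrt(1 - 2 f) * sqrt(f (1 - f) / NT).
#'
#' @param counts a [seed_counts] object.
#' @return data.frame (`cM`, `standard_error`, `n_total`) of class
#'   `interval_estimate`.
#' @export
seed_cm <- function(counts) {
  stopifnot(inherits(counts, "seed_counts"))
  NT <- counts$n_total
  if (NT <= 0) stop("n_total must be > 0")
  f <- (counts$green_only + counts$red_only) / NT
  if (f > 0.5) {
    stop(sprintf(
      "infeasible counts: single-colour fraction %.4f exceeds 0.5; ", f),
      "the seed estimator is undefined (not clamped)")
  }
  cm <- 100 * (1 - sqrt(1 - 2 * f))
  se <- if (f < 0.5) 100 / sqrt(1 - 2 * f) * sqrt(f * (1 - f) / NT) else Inf
  structure(data.frame(cM = cm, standard_error = se, n_total = NT),
            class = c("interval_estimate", "data.frame"))
}

#' Genetic distance from four-class pollen counts
#'
#' For a two-colour pollen interval scored as red (R), yellow (Y),
#' double-colour (RY) and non-colour (N), the map distance within the
#' tester-selected gamete pool is cM = 100 * Y / (Y + RY). The standard
#' error is binomial: 100 * sqrt(p (1 - p) / (Y + RY)) with p = Y/(Y+RY).
#'
#' @param counts a [pollen_counts] object with 4 classes.
#' @return An `interval_estimate` data.frame.
#' @export
pollen_cm_two_color <- function(counts) {
  stopifnot(inherits(counts, "pollen_counts"))
  if (attr(counts, "n_classes") != 4L) stop("4-class pollen counts required")
  denom <- counts$Y + counts$RY
  if (denom <= 0) stop("undefined estimate: Y + RY = 0")
  p <- counts$Y / denom
  structure(data.frame(cM = 100 * p,
                       standard_error = 100 * sqrt(p * (1 - p) / denom),
                       n_total = attr(counts, "n_total")),
            class = c("interval_estimate", "data.frame"))
}

#' Two-interval interference from eight-class pollen counts
#'
#' Computes the I3bc-style statistics: interval distances d_b and d_c as
#' 100 times the recombinant-gamete fraction in each interval, the expected
#' double-crossover (DCO) count under independence
#' (d_b/100) * (d_c/100) * n_total, the coefficient of coincidence
#' CoC = observed DCO / expected DCO, and interference = 1 - CoC. The
#' observed DCO classes are {m1,m3} and {m2}.
#'
#' @param counts a [pollen_counts] object with 8 classes.
#' @return data.frame (`d_b`, `d_c`, `observed_dco`, `expected_dco`, `coc`,
#'   `interference`, `n_total`) of class `interference_estimate`; when the
#'   expected DCO is zero, `coc` and `interference` are `NA` and the
#'   `undefined` column is `TRUE`.
#' @export
i3bc_interference <- function(counts) {
  stopifnot(inherits(counts, "pollen_counts"))
  if (attr(counts, "n_classes") != 8L) stop("8-class pollen counts required")
  n <- attr(counts, "n_total")
  if (n <= 0) stop("n_total must be > 0")
  dco <- counts$m1m3 + counts$m2
  rec_b <- counts$m1 + counts$m2m3 + dco
  rec_c <- counts$m1m2 + counts$m3 + dco
  d_b <- 100 * rec_b / n
  d_c <- 100 * rec_c / n
  exp_dco <- (d_b / 100) * (d_c / 100) * n
  undefined <- exp_dco <= 0
  coc <- if (undefined) NA_real_ else dco / exp_dco
  structure(data.frame(d_b = d_b, d_c = d_c, observed_dco = dco,
                       expected_dco = exp_dco, coc = coc,
                       interference = if (undefined) NA_real_ else 1 - coc,
                       undefined = undefined, n_total = n),
            class = c("interference_estimate", "data.frame"))
}

#' Compare genetic-distance estimates between groups
#'
#' Delegates to the standard tests used for fluorescence-based estimates:
#' Welch's two-sample t test (two groups), one-way ANOVA with Tukey HSD, or
#' Kruskal-Wallis followed by pairwise Mann-Whitney U tests with Bonferroni
#' correction. All P values are two-sided.
#'
#' @param values numeric vector of per-replicate estimates (e.g. cM).
#' @param group factor or character vector of group labels, same length.
#' @param method one of `"welch"`, `"anova_tukey"`, `"kruskal_mw"`.
#' @return A list of class `group_comparison` with elements `method`,
#'   `statistic`, `p_value`, and for the post-hoc variants a `pairwise`
#'   data.frame with the correction recorded.
#' @export
compare_groups <- function(values, group,
                           method = c("welch", "anova_tukey", "kruskal_mw")) {
  method <- match.arg(method)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  tab <- table(group)
  if (length(tab) < 2) stop("at least two groups required")
  if (any(tab < 2)) stop("each group needs >= 2 replicates")
  if (method == "welch") {
    if (length(tab) != 2) stop("Welch's t test requires exactly two groups")
    ht <- stats::t.test(values ~ group, var.equal = FALSE)
    out <- list(method = "Welch two-sample t test",
                statistic = unname(ht$statistic), p_value = ht$p.value,
                correction = "none")
  } else if (method == "anova_tukey") {
    fit <- stats::aov(values ~ group)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    out <- list(method = "One-way ANOVA with Tukey HSD",
                statistic = summary(fit)[[1]][["F value"]][1], p_value = p,
                pairwise = data.frame(pair = rownames(tk),
                                      diff = tk[, "diff"],
                                      p_adj = tk[, "p adj"],
                                      row.names = NULL),
                correction = "Tukey HSD")
  } else {
    kw <- stats::kruskal.test(values, group)
    levs <- levels(group)
    pairs <- utils::combn(levs, 2)
    m <- ncol(pairs)
    pw <- data.frame(pair = apply(pairs, 2, paste, collapse = "-"),
                     p_raw = apply(pairs, 2, function(pr) {
                       stats::wilcox.test(values[group == pr[1]],
                                          values[group == pr[2]],
                                          exact = FALSE)$p.value
                     }))
    pw$p_adj <- stats::p.adjust(pw$p_raw, method = "bonferroni")
    out <- list(method = "Kruskal-Wallis with pairwise Mann-Whitney U",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = pw, correction = "bonferroni",
                adjusted_alpha = 0.05 / m)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, P = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("pairwise (", x$correction, "):\n", sep = "")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
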