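#' Bin crossover calls into fixed-width genomic windows
#'
#' Tiles each chromosome with half-open windows `[start, start + w)` from
#' position 0 and assigns each call to the window containing its midpoint.
#' The last, partial window is retained by default (its own true length is
#' used for any per-kb normalisation); set `drop_partial` to discard it.
#' When SNP positions are supplied the per-window SNP density (SNPs/kb) is
#' computed alongside.
#'
#' @param calls data.frame with `chrom` and `midpoint` (or `pos`) columns.
#' @param model a [genome_model] supplying chromosome lengths.
#' @param window_bp window width in bp (> 0); 300000 for the usual
#'   0.3 Mb profiles, 100000 for SNP-density grouping.
#' @param n_individuals population-size normaliser for crossovers per F2.
#' @param snp_positions optional data.frame (`chrom`, `pos`) of polymorphic
#'   sites for the density track.
#' @param drop_partial drop the trailing partial window instead of keeping
#'   it at its true length.
#' @return data.frame (`chrom`, `start`, `end`, `n_crossovers`,
#'   `xo_per_f2`, and with SNPs: `n_snps`, `snps_per_kb`) of class
#'   `window_track`, with `n_individuals` as an attribute.
#' @export
bin_crossovers <- function(calls, model, window_bp = 3e5, n_individuals,
                           snp_positions = NULL, drop_partial = FALSE) {
  stopifnot(window_bp > 0, n_individuals > 0)
  pos_col <- if ("midpoint" %in% names(calls)) "midpoint" else "pos"
  stopifnot(pos_col %in% names(calls), "chrom" %in% names(calls))
  chrs <- model$chromosomes$name
  lens <- stats::setNames(model$chromosomes$length, chrs)
  bad <- !calls$chrom %in% chrs
  if (any(bad)) stop("calls on unknown chromosome: ", calls$chrom[bad][1])
  if (any(calls[[pos_col]] > lens[calls$chrom])) {
    stop("call midpoint beyond chromosome length (corrupt input)")
  }
  out <- lapply(chrs, function(nm) {
    L <- lens[[nm]]
    start <- seq(0, L - 1e-9, by = window_bp)
    end <- pmin(start + window_bp, L)
    if (drop_partial && end[length(end)] - start[length(start)] < window_bp) {
      start <- start[-length(start)]
      end <- end[-length(end)]
    }
    p <- calls[[pos_col]][calls$chrom == nm]
    idx <- findInterval(p, start)  # half-open: pos == start goes right
    idx <- idx[idx >= 1 & p < end[pmin(idx, length(end))]]
    cnt <- tabulate(idx, nbins = length(start))
    w <- data.frame(chrom = nm, start = start, end = end,
                    n_crossovers = cnt, xo_per_f2 = cnt / n_individuals)
    if (!is.null(snp_positions)) {
      sp <- snp_positions$pos[snp_positions$chrom == nm]
      sidx <- findInterval(sp, start)
      sidx <- sidx[sidx >= 1 & sp < end[pmin(sidx, length(end))]]
      w$n_snps <- tabulate(sidx, nbins = length(start))
      w$snps_per_kb <- w$n_snps / ((w$end - w$start) / 1000)
    }
    w
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "n_individuals") <- n_individuals
  class(out) <- c("window_track", "data.frame")
  out
}

#' Telomere-to-centromere scaled crossover profile
#'
#' Maps every chromosome arm onto the unit interval (0 = telomere,
#' 1 = centromere), bins crossover positions by fractional arm position,
#' and aggregates over arms, normalising per F2 individual.
#'
#' @param calls data.frame with `chrom` and `midpoint` (or `pos`).
#' @param model a [genome_model] with centromere positions.
#' @param n_bins number of proportional bins (default 20).
#' @param n_individuals population-size normaliser.
#' @return data.frame (`bin`, `frac_lo`, `frac_hi`, `n_crossovers`,
#'   `xo_per_f2`).
#' @export
scaled_arm_profile <- function(calls, model, n_bins = 20, n_individuals = 1) {
  pos_col <- if ("midpoint" %in% names(calls)) "midpoint" else "pos"
  cen <- model$centromeres
  lens <- stats::setNames(model$chromosomes$length, model$chromosomes$name)
  p <- calls[[pos_col]]
  chrom <- calls$chrom
  left <- p < cen[chrom]
  frac <- ifelse(left, p / cen[chrom],
                 (lens[chrom] - p) / (lens[chrom] - cen[chrom]))
  bin <- pmin(floor(frac * n_bins) + 1, n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  data.frame(bin = seq_len(n_bins),
             frac_lo = (seq_len(n_bins) - 1) / n_bins,
             frac_hi = seq_len(n_bins) / n_bins,
             n_crossovers = cnt, xo_per_f2 = cnt / n_individuals)
}

#' Pairwise correlation of windowed crossover profiles
#'
#' Spearman (default) correlation matrix of per-window crossover
#' frequencies between populations computed on identical window grids.
#'
#' @param tracks named list of `window_track` objects on the same grid.
#' @param method correlation method passed to [stats::cor].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(tracks, method = "spearman") {
  stopifnot(length(tracks) >= 2)
  ref <- tracks[[1]]
  for (tr in tracks[-1]) {
    if (nrow(tr) != nrow(ref) || any(tr$chrom != ref$chrom) ||
        any(tr$start != ref$start)) {
      stop("window grids do not match across tracks")
    }
  }
  m <- sapply(tracks, function(tr) tr$xo_per_f2)
  stats::cor(m, method = method)
}

#' Group ranked windows by SNP density
#'
#' Sorts windows ascending by SNPs/kb (ties broken by chromosome then
#' start, so grouping is deterministic under permuted input) and forms
#' consecutive runs of exactly `k` windows. The trailing remainder — the
#' `n %% k` highest-density windows — is excluded and reported.
#'
#' @param windows a `window_track` with a `snps_per_kb` column
#'   (conventionally 100-kb windows).
#' @param k windows per group (default 12).
#' @return A list of class `snp_density_groups`: `windows` (input rows
#'   with a `group` column, `NA` for excluded), `groups` (per-group
#'   `n_windows` and `mean_snps_per_kb`), `excluded` (the dropped rows),
#'   `k`.
#' @export
snp_density_grouping <- function(windows, k = 12) {
  stopifnot(k >= 1, "snps_per_kb" %in% names(windows))
  n <- nrow(windows)
  if (n < k) stop("fewer windows (", n, ") than group size k = ", k)
  o <- order(windows$snps_per_kb, windows$chrom, windows$start)
  w <- windows[o, , drop = FALSE]
  G <- n %/% k
  grp <- rep(NA_integer_, n)
  grp[seq_len(G * k)] <- rep(seq_len(G), each = k)
  w$group <- grp
  groups <- data.frame(
    group = seq_len(G),
    n_windows = k,
    mean_snps_per_kb = vapply(seq_len(G), function(g) {
      mean(w$snps_per_kb[which(w$group == g)])
    }, numeric(1)))
  structure(list(windows = w, groups = groups,
                 excluded = w[is.na(w$group), , drop = FALSE], k = k),
            class = "snp_density_groups")
}

#' @export
print.snp_density_groups <- function(x, ...) {
  cat(sprintf("snp_density_groups: %d groups of %d windows (%d excluded)\n",
              nrow(x$groups), x$k, nrow(x$excluded)))
  invisible(x)
}

#' Per-group normalised crossover frequency
#'
#' For each SNP-density group, sums the member windows' crossover counts
#' from a population's window track (same grid), normalises by sample size
#' and gamete number, and expresses the result as cM per window:
#' `100 * count / (2 * n_individuals * k)`.
#'
#' @param grouping a [snp_density_grouping] result.
#' @param track the population's `window_track` on the identical grid.
#' @return data.frame (`group`, `mean_snps_per_kb`, `n_crossovers`,
#'   `cM_per_window`).
#' @export
group_recombination <- function(grouping, track) {
  stopifnot(inherits(grouping, "snp_density_groups"))
  w <- grouping$windows
  key_g <- paste(w$chrom, w$start)
  key_t <- paste(track$chrom, track$start)
  idx <- match(key_g, key_t)
  if (any(is.na(idx))) stop("track windows do not match the grouping grid")
  n_ind <- attr(track, "n_individuals")
  cnt <- track$n_crossovers[idx]
  out <- grouping$groups
  out$n_crossovers <- vapply(out$group, function(g) {
    sum(cnt[which(w$group == g)])
  }, numeric(1))
  out$cM_per_window <- 100 * out$n_crossovers / (2 * n_ind * grouping$k)
  out[, c("group", "mean_snps_per_kb", "n_crossovers", "cM_per_window")]
}

#' Differential crossover frequency between two populations
#'
#' Elementwise difference of per-group crossover frequencies
#' (population a minus population b, e.g. mutant minus wild type) over
#' identical SNP-density groups.
#'
#' @param a,b [group_recombination] tables with identical `group` and
#'   density columns.
#' @return data.frame (`group`, `mean_snps_per_kb`, `delta_cM`).
#' @export
delta_cm <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$group != b$group) ||
      any(abs(a$mean_snps_per_kb - b$mean_snps_per_kb) > 1e-9)) {
    stop("group definitions do not match")
  }
  data.frame(group = a$group, mean_snps_per_kb = a$mean_snps_per_kb,
             delta_cM = a$cM_per_window - b$cM_per_window)
}

#' Loess trend of a delta-cM curve
#'
#' Local polynomial regression (degree 2, tricube weights — the standard
#' loess) of `y ~ x`, evaluated at the input x values.
#'
#' @param x group mean densities (SNPs/kb).
#' @param y per-group delta cM (or cM) values.
#' @param span loess span in (0, 1].
#' @param degree local polynomial degree (default 2).
#' @return data.frame (`x`, `y`, `fitted`).
#' @export
loess_trend <- function(x, y, span = 0.75, degree = 2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("need at least 10 points for a loess trend")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(x) < degree + 1) {
    stop("span too small for the neighbourhood size")
  }
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  data.frame(x = x, y = y, fitted = stats::predict(fit, newdata = x))
}

#' Rank correlation between SNP density and crossover-frequency change
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided P
#' value, delegated to [stats::cor.test].
#'
#' @param x group mean densities.
#' @param y per-group delta cM values.
#' @return list (`rho`, `p_value`, `n`).
#' @export
correlate_delta_density <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
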