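#' Marker-table filter configuration
#'
#' Thresholds follow the conventional GBS pre-filtering semantics:
#' site mapping quality must strictly exceed `min_site_quality`
#' (default > 100); the read depth covering a site in an individual's
#' library must strictly exceed `min_mean_coverage` (default > 2.5x, i.e.
#' at least 3 reads); libraries with total reads strictly below
#' `min_library_reads` (default 100,000) are discarded entirely.
#'
#' @param min_site_quality strict lower bound on site quality.
#' @param min_mean_coverage strict lower bound on per-site read depth.
#' @param min_library_reads libraries strictly below this total are dropped.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_site_quality = 100, min_mean_coverage = 2.5,
                          min_library_reads = 1e5) {
  stopifnot(min_site_quality >= 0, min_mean_coverage >= 0,
            min_library_reads >= 0)
  structure(list(min_site_quality = min_site_quality,
                 min_mean_coverage = min_mean_coverage,
                 min_library_reads = min_library_reads),
            class = "filter_config")
}

#' Filter a marker table
#'
#' Applies the three independent rules of [filter_config] as row/library
#' predicates on the input table, so the rules commute: site-quality and
#' coverage filters act per row, the library filter drops whole
#' individuals. Library sizes come from the table's `library_sizes`
#' attribute when present, otherwise from summed allele counts.
#'
#' @param table a marker table (`individual`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `quality`).
#' @param cfg a [filter_config].
#' @param apply_library,apply_site enable/disable rule families
#'   (both `TRUE` by default; useful for auditing order-independence).
#' @return The filtered marker table, with attribute `filter_report`
#'   (counts removed per rule) and `library_sizes` restricted to retained
#'   individuals. If nothing survives, the empty table carries
#'   `empty_after_filtering = TRUE` in its report and a warning is issued.
#' @export
filter_markers <- function(table, cfg = filter_config(),
                           apply_library = TRUE, apply_site = TRUE) {
  stopifnot(inherits(cfg, "filter_config"))
  lib <- attr(table, "library_sizes")
  if (is.null(lib)) {
    lib <- tapply(table$ref_count + table$alt_count, table$individual, sum)
    lib <- stats::setNames(as.numeric(lib), names(lib))
  }
  keep <- rep(TRUE, nrow(table))
  report <- list(individuals_removed = character(0),
                 rows_removed_library = 0L,
                 rows_removed_quality = 0L,
                 rows_removed_coverage = 0L)
  if (apply_library) {
    bad_ind <- names(lib)[lib < cfg$min_library_reads]
    drop <- table$individual %in% bad_ind
    report$individuals_removed <- bad_ind
    report$rows_removed_library <- sum(drop & keep)
    keep <- keep & !drop
  }
  if (apply_site) {
    qbad <- !(table$quality > cfg$min_site_quality)
    report$rows_removed_quality <- sum(qbad & keep)
    keep <- keep & !qbad
    depth <- table$ref_count + table$alt_count
    cbad <- !(depth > cfg$min_mean_coverage)
    report$rows_removed_coverage <- sum(cbad & keep)
    keep <- keep & !cbad
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  report$rows_retained <- nrow(out)
  report$empty_after_filtering <- nrow(out) == 0
  if (report$empty_after_filtering) {
    warning("marker table is empty after filtering")
  }
  attr(out, "library_sizes") <- lib[setdiff(names(lib),
                                            report$individuals_removed)]
  attr(out, "filter_report") <- report
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Call per-site genotypes from allele counts
#'
#' Rule-based genotyping of a filtered marker table: with alt-allele
#' fraction `a` at a site of nonzero depth, the call is `AA` if
#' `a <= e`, `BB` if `a >= 1 - e`, `AB` if `h_lo <= a <= h_hi`, otherwise
#' `missing`; zero-depth sites are `missing`. The score is the binomial
#' log-likelihood ratio of the best versus second-best state using
#' emission probabilities `(e, 0.5, 1 - e)`.
#'
#' @param table filtered marker table.
#' @param e homozygote band half-width (default 0.1).
#' @param h_lo,h_hi heterozygote band (defaults 0.3, 0.7).
#' @return data.frame (`individual`, `chrom`, `pos`, `call`, `score`) of
#'   class `genotype_track`, sorted by (individual, chrom, pos).
#' @export
call_genotypes <- function(table, e = 0.1, h_lo = 0.3, h_hi = 0.7) {
  stopifnot(e >= 0, e < h_lo, h_lo < h_hi, h_hi < 1)
  depth <- table$ref_count + table$alt_count
  a <- ifelse(depth > 0, table$alt_count / depth, NA_real_)
  call <- rep("missing", nrow(table))
  call[!is.na(a) & a <= e] <- "AA"
  call[!is.na(a) & a >= 1 - e] <- "BB"
  call[!is.na(a) & a >= h_lo & a <= h_hi] <- "AB"
  p_em <- c(max(e, 0.01), 0.5, 1 - max(e, 0.01))
  ll <- vapply(p_em, function(p) {
    stats::dbinom(table$alt_count, depth, p, log = TRUE)
  }, numeric(nrow(table)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(table))
  best <- pmax(ll[, 1], ll[, 2], ll[, 3])
  worst <- pmin(ll[, 1], ll[, 2], ll[, 3])
  second <- ll[, 1] + ll[, 2] + ll[, 3] - best - worst
  score <- ifelse(depth > 0, best - second, 0)
  out <- data.frame(individual = table$individual, chrom = table$chrom,
                    pos = table$pos, call = call, score = score)
  out <- out[order(out$individual, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genotype_track", "data.frame")
  out
}

# majority vote of 3-state calls in a centred window of k sites, truncated
# at chromosome ends; ties keep the site's own call when it is among the
# tied states, otherwise the first state in (AA, AB, BB) order
.majority_vote <- function(calls, k) {
  states <- c("AA", "AB", "BB")
  n <- length(calls)
  h <- (k - 1) %/% 2
  counts <- sapply(states, function(s) cumsum(calls == s))
  counts <- rbind(0, counts)
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  win <- counts[hi + 1, , drop = FALSE] - counts[lo, , drop = FALSE]
  mx <- pmax(win[, 1], win[, 2], win[, 3])
  out <- states[max.col(win, ties.method = "first")]
  own <- match(calls, states)
  own_tied <- !is.na(own) & win[cbind(seq_len(n), own)] == mx
  out[own_tied] <- calls[own_tied]
  out
}

# merge runs shorter than m into the larger flanking run (ties -> left)
.merge_short_runs <- function(states, m) {
  repeat {
    r <- rle(states)
    if (length(r$lengths) <= 1 || all(r$lengths >= m)) break
    i <- which(r$lengths < m)[which.min(r$lengths[r$lengths < m])]
    if (i == 1) {
      r$values[1] <- r$values[2]
    } else if (i == length(r$values)) {
      r$values[i] <- r$values[i - 1]
    } else {
      left_len <- r$lengths[i - 1]
      right_len <- r$lengths[i + 1]
      r$values[i] <- if (right_len > left_len) r$values[i + 1] else r$values[i - 1]
    }
    states <- inverse.rle(r)
  }
  states
}

#' Segment a genotype track into genotype runs
#'
#' Denoises per-site calls with a k-site sliding-window majority vote
#' (missing calls excluded), merges runs shorter than `min_support` sites
#' into their flanking state, and returns the maximal-run segmentation.
#' Robust to isolated miscalls by construction.
#'
#' @param track a `genotype_track`.
#' @param k odd window size in sites (default 5).
#' @param min_support minimum run length in sites (default 3).
#' @return data.frame (`individual`, `chrom`, `state`, `first_pos`,
#'   `last_pos`, `n_sites`) of class `genotype_segments`. Chromosomes with
#'   fewer than `min_support` informative sites yield no segments and are
#'   listed in the `skipped` attribute.
#' @export
segment_track <- function(track, k = 5, min_support = 3) {
  stopifnot(k %% 2 == 1, min_support >= 1)
  inf <- track[track$call != "missing", , drop = FALSE]
  segs <- list()
  skipped <- character(0)
  key_all <- paste(inf$individual, inf$chrom, sep = "\r")
  idx_by_key <- split(seq_len(nrow(inf)), key_all)
  for (key in names(idx_by_key)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- inf[idx_by_key[[key]], , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    if (nrow(sub) < min_support) {
      skipped <- c(skipped, paste(parts[1], parts[2], sep = ":"))
      next
    }
    sm <- .majority_vote(sub$call, k)
    sm <- .merge_short_runs(sm, min_support)
    r <- rle(sm)
    ends <- cumsum(r$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    segs[[length(segs) + 1]] <- data.frame(
      individual = parts[1], chrom = parts[2], state = r$values,
      first_pos = sub$pos[starts], last_pos = sub$pos[ends],
      n_sites = r$lengths)
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(individual = character(0), chrom = character(0),
               state = character(0), first_pos = numeric(0),
               last_pos = numeric(0), n_sites = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("genotype_segments", "data.frame")
  out
}

#' Call crossovers at genotype switches
#'
#' Emits one crossover per adjacent segment pair of a segmented genotype
#' track. The flanking markers are the last informative site of the left
#' segment and the first of the right; the call is assigned to the
#' midpoint `floor((left + right) / 2)` (clamped into the open interval
#' for adjacent-bp markers). Direct `AA <-> BB` transitions — a double
#' crossover between adjacent markers, or an artefact — are kept but
#' flagged `suspect`.
#'
#' @param segments a `genotype_segments` data.frame.
#' @return data.frame (`individual`, `chrom`, `left_marker_pos`,
#'   `right_marker_pos`, `midpoint`, `transition`, `suspect`) of class
#'   `crossover_calls`.
#' @export
call_crossovers <- function(segments) {
  calls <- list()
  key_all <- paste(segments$individual, segments$chrom, sep = "\r")
  idx_by_key <- split(seq_len(nrow(segments)), key_all)
  for (key in names(idx_by_key)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- segments[idx_by_key[[key]], , drop = FALSE]
    if (nrow(sub) < 2) next
    l <- sub$last_pos[-nrow(sub)]
    r <- sub$first_pos[-1]
    mid <- pmax(floor((l + r) / 2), l + 1)
    from <- sub$state[-nrow(sub)]
    to <- sub$state[-1]
    calls[[length(calls) + 1]] <- data.frame(
      individual = parts[1], chrom = parts[2],
      left_marker_pos = l, right_marker_pos = r, midpoint = mid,
      transition = paste0(from, "->", to),
      suspect = (from == "AA" & to == "BB") | (from == "BB" & to == "AA"))
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(individual = character(0), chrom = character(0),
               left_marker_pos = numeric(0), right_marker_pos = numeric(0),
               midpoint = numeric(0), transition = character(0),
               suspect = logical(0))
  rownames(out) <- NULL
  class(out) <- c("crossover_calls", "data.frame")
  out
}

#' Crossover counts per individual
#'
#' @param calls a `crossover_calls` data.frame.
#' @param individuals optional character vector of all individuals in the
#'   population; those with zero calls appear with count 0.
#' @return data.frame (`individual`, `n_crossovers`).
#' @export
count_per_individual <- function(calls, individuals = NULL) {
  ids <- unique(c(individuals, calls$individual))
  n <- vapply(ids, function(id) sum(calls$individual == id), numeric(1))
  out <- data.frame(individual = ids, n_crossovers = as.integer(n))
  rownames(out) <- NULL
  out[order(out$individual), , drop = FALSE]
}

#' Run the full caller on a marker table
#'
#' Convenience chain: [filter_markers] -> [call_genotypes] ->
#' [segment_track] -> [call_crossovers].
#'
#' @param table a marker table.
#' @param cfg a [filter_config].
#' @param k,min_support passed to [segment_track].
#' @param e,h_lo,h_hi passed to [call_genotypes].
#' @return A `crossover_calls` data.frame with the filter report attached
#'   as attribute `filter_report`.
#' @export
call_crossovers_from_markers <- function(table, cfg = filter_config(),
                                         k = 5, min_support = 3,
                                         e = 0.1, h_lo = 0.3, h_hi = 0.7) {
  filtered <- filter_markers(table, cfg)
  track <- call_genotypes(filtered, e = e, h_lo = h_lo, h_hi = h_hi)
  segs <- segment_track(track, k = k, min_support = min_support)
  calls <- call_crossovers(segs)
  attr(calls, "filter_report") <- attr(filtered, "filter_report")
  calls
}
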