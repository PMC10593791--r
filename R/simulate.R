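#' Build per-chromosome crossover intensity tracks
#'
#' Evaluates the two pathway intensities along each chromosome as
#' piecewise-constant tracks in cM/Mb (gamete map scale). Class I intensity
#' is `classI_base * classI_poly_response(density, boundary_dist)`; Class II
#' is `classII_base * classII_poly_response(density)`. The interhomolog SNP
#' density seen by the responses is the model's density track inside
#' heterozygous blocks and 0 inside homozygous blocks (no polymorphism
#' between homologues there); intensity itself is defined genome-wide, so
#' true crossovers also occur where no marker can detect them. With
#' `msh2_active = FALSE` both responses are neutral except the residual
#' MSH2-independent Class II inhibition.
#'
#' Because the boundary-distance argument varies continuously, segments are
#' subdivided on a grid of `grid_bp` before evaluating the responses at
#' segment midpoints.
#'
#' @param model a [genome_model].
#' @param params a [pathway_params].
#' @param grid_bp discretisation step (bp) for response evaluation.
#' @return A named list (one per chromosome) of data.frames with columns
#'   `start`, `end`, `classI_cM_per_Mb`, `classII_cM_per_Mb`; class
#'   `intensity_tracks`.
#' @export
build_intensity_profiles <- function(model, params, grid_bp = 50000) {
  stopifnot(inherits(model, "genome_model"), inherits(params, "pathway_params"))
  chrs <- model$chromosomes$name
  tracks <- lapply(chrs, function(nm) {
    L <- model$chromosomes$length[model$chromosomes$name == nm]
    dens <- model$snp_density[[nm]]
    het <- model$het_blocks[[nm]]
    # breakpoints: density track, het edges, and a regular grid
    bp <- sort(unique(c(0, L, dens$start, dens$end, het$start, het$end,
                        seq(0, L, by = grid_bp))))
    bp <- bp[bp >= 0 & bp <= L]
    start <- bp[-length(bp)]
    end <- bp[-1]
    mid <- (start + end) / 2

    in_het <- .in_intervals(mid, het)
    d_track <- dens$snps_per_kb[findInterval(mid, dens$start)]
    d_eff <- ifelse(in_het, d_track, 0)

    # distance to the nearest internal HET/HOM junction (chromosome ends
    # are not junctions); Inf when the chromosome has none
    edges <- sort(unique(c(het$start, het$end)))
    edges <- edges[edges > 0 & edges < L]
    if (length(edges)) {
      bdist <- vapply(mid, function(x) min(abs(x - edges)), numeric(1))
    } else {
      bdist <- rep(Inf, length(mid))
    }

    m1 <- if (params$msh2_active) {
      mapply(params$classI_poly_response, d_eff, bdist)
    } else rep(1, length(mid))
    m2 <- if (params$msh2_active) {
      vapply(d_eff, params$classII_poly_response, numeric(1))
    } else rep(1, length(mid))
    m2 <- m2 * vapply(d_eff, params$classII_residual_response, numeric(1))
    if (any(!is.finite(m1)) || any(!is.finite(m2)) ||
        any(m1 < 0) || any(m2 < 0)) {
      stop("polymorphism response returned a non-finite or negative multiplier")
    }

    data.frame(start = start, end = end,
               classI_cM_per_Mb = params$classI_base_cM_per_Mb * m1,
               classII_cM_per_Mb = params$classII_base_cM_per_Mb * m2)
  })
  names(tracks) <- chrs
  structure(tracks, class = "intensity_tracks",
            nu = params$classI_nu, obligate_CO = params$obligate_CO)
}

.in_intervals <- function(x, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(x)))
  vapply(x, function(p) any(p >= iv$start & p < iv$end), logical(1))
}

#' Total gamete map length of an intensity track
#'
#' @param track one chromosome's intensity data.frame.
#' @return Named vector `c(classI =, classII =)` in cM.
#' @export
track_map_length <- function(track) {
  mb <- (track$end - track$start) / 1e6
  c(classI = sum(mb * track$classI_cM_per_Mb),
    classII = sum(mb * track$classII_cM_per_Mb))
}

# Stationary first-arrival (forward recurrence) time of a gamma(nu, nu)
# renewal process: Fe(t) = t * (1 - F(t)) + F_{nu+1, nu}(t). Inverted
# numerically for non-integer nu.
.equilibrium_gamma_draw <- function(nu) {
  u <- stats::runif(1)
  Fe <- function(t) {
    t * stats::pgamma(t, shape = nu, rate = nu, lower.tail = FALSE) +
      stats::pgamma(t, shape = nu + 1, rate = nu)
  }
  hi <- 1
  while (Fe(hi) < u) hi <- hi * 2
  stats::uniroot(function(t) Fe(t) - u, c(0, hi), tol = 1e-10)$root
}

# Event positions (on a unit-rate genetic scale of total length len) of a
# stationary gamma-renewal process with shape nu and mean interval 1.
.gamma_renewal_events <- function(len, nu) {
  if (len <= 0) return(numeric(0))
  if (abs(nu - round(nu)) < 1e-9) {
    # chi-square (counting) construction: rate-nu Poisson process, keep
    # every nu-th point with a uniformly random phase -- exactly stationary
    nu <- as.integer(round(nu))
    n <- stats::rpois(1, nu * len)
    if (n == 0) return(numeric(0))
    pts <- sort(stats::runif(n, 0, len))
    phase <- sample.int(nu, 1)
    if (phase > n) return(numeric(0))
    pts[seq.int(phase, n, by = nu)]
  } else {
    t <- .equilibrium_gamma_draw(nu)
    out <- numeric(0)
    while (t <= len) {
      out <- c(out, t)
      t <- t + stats::rgamma(1, shape = nu, rate = nu)
    }
    out
  }
}

# Map positions on the cumulative gamete-cM scale of one pathway back to bp
# (linear interpolation within piecewise-constant segments).
.genetic_to_bp <- function(g_cM, track, rate_col) {
  mb <- (track$end - track$start) / 1e6
  seg_cM <- mb * track[[rate_col]]
  cum <- c(0, cumsum(seg_cM))
  idx <- findInterval(g_cM, cum, rightmost.closed = TRUE)
  idx[idx > nrow(track)] <- nrow(track)
  frac <- (g_cM - cum[idx]) / seg_cM[idx]
  track$start[idx] + frac * (track$end[idx] - track$start[idx])
}

#' Simulate one gamete's crossover positions on one chromosome
#'
#' Class I crossovers are drawn as a stationary gamma-renewal process with
#' shape `nu` on the cumulative genetic scale of the bivalent (twice the
#' gamete map length, in Morgans) and each event is retained with
#' probability 1/2 (chromatid thinning). Class II crossovers are an
#' independent inhomogeneous Poisson process, thinned likewise. With
#' `obligate_CO`, bivalents with no event are redrawn.
#'
#' @param track one chromosome's intensity data.frame (from
#'   [build_intensity_profiles]).
#' @param nu gamma-renewal shape (>= 1); `nu = 1` is the no-interference
#'   Poisson limit.
#' @param obligate_CO redraw event-free bivalents.
#' @return data.frame with columns `pos` (bp, sorted) and `pathway`
#'   (`"classI"`/`"classII"`).
#' @export
simulate_gamete <- function(track, nu = 1, obligate_CO = FALSE) {
  if (nu < 1) stop("nu must be >= 1")
  if (any(track$classI_cM_per_Mb < 0) || any(track$classII_cM_per_Mb < 0)) {
    stop("negative intensity")
  }
  len <- track_map_length(track)
  biv1 <- 2 * len[["classI"]] / 100   # bivalent Morgans, Class I
  biv2 <- 2 * len[["classII"]] / 100
  repeat {
    ev1 <- .gamma_renewal_events(biv1, nu)
    n2 <- if (biv2 > 0) stats::rpois(1, biv2) else 0L
    ev2 <- if (n2 > 0) sort(stats::runif(n2, 0, biv2)) else numeric(0)
    if (!obligate_CO || length(ev1) + length(ev2) > 0) break
  }
  # chromatid thinning: each bivalent CO lands on a given chromatid w.p. 1/2
  ev1 <- ev1[stats::runif(length(ev1)) < 0.5]
  ev2 <- ev2[stats::runif(length(ev2)) < 0.5]
  pos1 <- .genetic_to_bp(ev1 * 100 / 2, track, "classI_cM_per_Mb")
  pos2 <- .genetic_to_bp(ev2 * 100 / 2, track, "classII_cM_per_Mb")
  out <- data.frame(pos = c(pos1, pos2),
                    pathway = rep(c("classI", "classII"),
                                  c(length(pos1), length(pos2))))
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate an F2 population
#'
#' Each F2 individual unites two independent meiotic products (gametes) of
#' the selfed F1. Per chromosome, each gamete carries a random starting
#' parental phase and a set of crossover positions; genotype segments
#' (`AA`/`AB`/`BB`) are derived by overlaying the two gamete mosaics.
#' Ground-truth crossover positions and pathway labels are retained.
#'
#' @param model a [genome_model].
#' @param params a [pathway_params].
#' @param n number of F2 individuals (> 0).
#' @param grid_bp passed to [build_intensity_profiles].
#' @return An object of class `f2_population`: a list of individuals, each
#'   with `id`, per-chromosome `gametes` (crossover tables plus `phase0`)
#'   and derived `segments`.
#' @export
simulate_f2_population <- function(model, params, n, grid_bp = 50000) {
  stopifnot(n > 0)
  tracks <- build_intensity_profiles(model, params, grid_bp = grid_bp)
  chrs <- model$chromosomes$name
  lens <- stats::setNames(model$chromosomes$length, chrs)
  inds <- lapply(seq_len(n), function(i) {
    per_chr <- lapply(chrs, function(nm) {
      g1 <- simulate_gamete(tracks[[nm]], params$classI_nu, params$obligate_CO)
      g2 <- simulate_gamete(tracks[[nm]], params$classI_nu, params$obligate_CO)
      p1 <- sample(0:1, 1)
      p2 <- sample(0:1, 1)
      seg <- .overlay_gametes(g1$pos, p1, g2$pos, p2, lens[[nm]])
      list(gametes = list(list(xo = g1, phase0 = p1),
                          list(xo = g2, phase0 = p2)),
           segments = seg)
    })
    names(per_chr) <- chrs
    list(id = sprintf("F2_%04d", i), chromosomes = per_chr)
  })
  structure(list(individuals = inds, model = model, params = params),
            class = "f2_population")
}

# Overlay two gamete phase mosaics into AA/AB/BB segments tiling [0, len).
.overlay_gametes <- function(xo1, p1, xo2, p2, len) {
  bnd <- sort(unique(c(xo1, xo2)))
  start <- c(0, bnd)
  end <- c(bnd, len)
  mid <- (start + end) / 2
  ph1 <- (p1 + findInterval(mid, sort(xo1))) %% 2
  ph2 <- (p2 + findInterval(mid, sort(xo2))) %% 2
  dose <- ph1 + ph2  # copies of parent B allele
  geno <- c("AA", "AB", "BB")[dose + 1]
  data.frame(start = start, end = end, genotype = geno)
}

#' @export
print.f2_population <- function(x, ...) {
  n <- length(x$individuals)
  nxo <- vapply(x$individuals, function(ind) {
    sum(vapply(ind$chromosomes,
               function(ch) nrow(ch$gametes[[1]]$xo) + nrow(ch$gametes[[2]]$xo),
               numeric(1)))
  }, numeric(1))
  cat(sprintf("f2_population: %d individuals, mean %.2f crossovers per F2\n",
              n, mean(nxo)))
  invisible(x)
}

#' Ground-truth crossover table of a simulated population
#'
#' @param population an [simulate_f2_population] result.
#' @return data.frame with columns `individual`, `chrom`, `pos`, `pathway`,
#'   `gamete` (1 or 2).
#' @export
crossovers_truth <- function(population) {
  stopifnot(inherits(population, "f2_population"))
  rows <- list()
  for (ind in population$individuals) {
    for (nm in names(ind$chromosomes)) {
      for (g in 1:2) {
        xo <- ind$chromosomes[[nm]]$gametes[[g]]$xo
        if (nrow(xo)) {
          rows[[length(rows) + 1]] <- data.frame(
            individual = ind$id, chrom = nm, pos = xo$pos,
            pathway = xo$pathway, gamete = g)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(individual = character(0), chrom = character(0),
                      pos = numeric(0), pathway = character(0),
                      gamete = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a GBS-style marker table for an F2 population
#'
#' Marker positions are shared across individuals (one SNP list for the
#' cross), placed proportionally to the model's SNP-density track and only
#' inside heterozygous blocks — the cross is uninformative elsewhere.
#' Per-site sequencing depth is Poisson(`mean_coverage`); allele counts are
#' binomial with success probability 0 / 0.5 / 1 by true genotype,
#' perturbed by `error_rate`. Site quality is drawn from a two-component
#' mixture (arbitrary scale) so that roughly `quality_fail_frac` of sites
#' fall at or below the conventional quality-100 cutoff. Each individual's
#' total library read count is the summed on-marker depth times
#' `library_size_factor` (GBS reads are mostly off-marker), stored in the
#' `library_sizes` attribute.
#'
#' @param population an `f2_population`.
#' @param model the [genome_model] used to simulate it.
#' @param mean_coverage mean reads per marker site (> 0).
#' @param error_rate per-read allele error probability in `[0, 0.5)`.
#' @param sites_per_Mb expected marker density over the whole chromosome.
#' @param quality_fail_frac fraction of sites drawn from the low-quality
#'   component.
#' @param library_size_factor multiplier from on-marker depth to total
#'   library reads.
#' @param anchor_ends also place one marker at the first and last bp of
#'   every heterozygous block, so the informative-marker span covers the
#'   block; without it, crossovers distal to the outermost random marker
#'   are invisible to any caller. Useful for caller-oracle comparisons.
#' @return data.frame (`individual`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `quality`) with attribute `library_sizes`; class
#'   `marker_table`.
#' @export
simulate_gbs <- function(population, model, mean_coverage = 3,
                         error_rate = 0.005, sites_per_Mb = 50,
                         quality_fail_frac = 0.05,
                         library_size_factor = 50,
                         anchor_ends = FALSE) {
  stopifnot(inherits(population, "f2_population"),
            mean_coverage > 0, error_rate >= 0, error_rate < 0.5)
  chrs <- model$chromosomes$name
  sites <- lapply(chrs, function(nm) {
    L <- model$chromosomes$length[model$chromosomes$name == nm]
    dens <- model$snp_density[[nm]]
    het <- model$het_blocks[[nm]]
    n_exp <- sites_per_Mb * L / 1e6
    n <- stats::rpois(1, n_exp)
    if (n == 0) return(data.frame(chrom = character(0), pos = numeric(0),
                                  quality = numeric(0)))
    # weight density segments by overlap with het blocks
    w <- numeric(nrow(dens))
    for (i in seq_len(nrow(dens))) {
      if (nrow(het)) {
        ov <- pmin(dens$end[i], het$end) - pmax(dens$start[i], het$start)
        w[i] <- sum(pmax(ov, 0)) * dens$snps_per_kb[i]
      }
    }
    if (sum(w) == 0) return(data.frame(chrom = character(0), pos = numeric(0),
                                       quality = numeric(0)))
    seg <- sample.int(nrow(dens), n, replace = TRUE, prob = w)
    pos <- vapply(seg, function(i) {
      # rejection into het sub-intervals of the chosen segment
      repeat {
        p <- stats::runif(1, dens$start[i], dens$end[i])
        if (.in_intervals(p, het)) return(p)
      }
    }, numeric(1))
    pos <- floor(pos) + 1  # 1-based integer bp
    if (anchor_ends && nrow(het)) {
      pos <- c(pos, het$start + 1, het$end)
    }
    pos <- sort(unique(pos))
    qual <- ifelse(stats::runif(length(pos)) < quality_fail_frac,
                   stats::runif(length(pos), 20, 100),
                   101 + stats::rexp(length(pos), rate = 1 / 150))
    data.frame(chrom = nm, pos = pos, quality = round(qual, 1))
  })
  sites <- do.call(rbind, sites)

  rows <- vector("list", length(population$individuals))
  lib <- numeric(length(population$individuals))
  for (k in seq_along(population$individuals)) {
    ind <- population$individuals[[k]]
    geno <- character(nrow(sites))
    for (nm in unique(sites$chrom)) {
      sel <- sites$chrom == nm
      seg <- ind$chromosomes[[nm]]$segments
      idx <- findInterval(sites$pos[sel] - 0.5, seg$start)
      geno[sel] <- seg$genotype[idx]
    }
    depth <- stats::rpois(nrow(sites), mean_coverage)
    p_alt <- c(AA = error_rate, AB = 0.5, BB = 1 - error_rate)[geno]
    alt <- stats::rbinom(nrow(sites), depth, p_alt)
    rows[[k]] <- data.frame(individual = ind$id, chrom = sites$chrom,
                            pos = sites$pos, ref_count = depth - alt,
                            alt_count = alt, quality = sites$quality)
    lib[k] <- round(sum(depth) * library_size_factor)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(lib) <- vapply(population$individuals, `[[`, character(1), "id")
  attr(out, "library_sizes") <- lib
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Seed fluorescence class probabilities for a given recombination fraction
#'
#' For a coupling-phase F1 hemizygous for two linked fluorescent reporters
#' (green and red) separated by recombination fraction `r`, selfing yields
#' seed classes with probabilities (q = 1 - r): green-only = red-only =
#' (1 - q^2)/4, both = (2 + q^2)/4, neither = q^2/4.
#'
#' @param r recombination fraction in `[0, 1]`.
#' @return Named numeric vector over `green_only`, `red_only`, `both`,
#'   `neither`; sums to 1.
#' @export
seed_class_probs <- function(r) {
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  q <- 1 - r
  c(green_only = (1 - q^2) / 4, red_only = (1 - q^2) / 4,
    both = (2 + q^2) / 4, neither = q^2 / 4)
}

#' Simulate seed fluorescence class counts
#'
#' Multinomial draw from [seed_class_probs].
#'
#' @param r true recombination fraction in `[0, 1]`.
#' @param n_total number of seeds.
#' @return A `seed_counts` object (see [seed_counts]).
#' @export
simulate_seed_counts <- function(r, n_total) {
  p <- seed_class_probs(r)
  x <- stats::rmultinom(1, n_total, p)[, 1]
  seed_counts(x[["green_only"]], x[["red_only"]], x[["both"]], x[["neither"]])
}

#' Expected seed class counts (no sampling noise)
#' @inheritParams simulate_seed_counts
#' @return A `seed_counts` object with (generally non-integer) expectation
#'   counts.
#' @export
expected_seed_counts <- function(r, n_total) {
  p <- seed_class_probs(r) * n_total
  seed_counts(p[["green_only"]], p[["red_only"]], p[["both"]], p[["neither"]])
}

#' Eight-class pollen probabilities for two intervals and a coincidence
#'
#' Three linked fluorophores at positions m1, m2, m3 define intervals
#' b = (m1, m2) and c = (m2, m3). With map fractions `r_b = d_b/100`,
#' `r_c = d_c/100` and coefficient of coincidence `coc`, double-crossover
#' gametes ({m1,m3} and {m2}) have total probability `coc * r_b * r_c`;
#' single-b gametes ({m1} and {m2,m3}) total `r_b - coc*r_b*r_c`; single-c
#' ({m1,m2} and {m3}) analogous; parental gametes ({m1,m2,m3} and {}) take
#' the remainder. Each pair is split equally.
#'
#' @param d_b,d_c interval genetic distances in cM.
#' @param coc coefficient of coincidence (>= 0).
#' @return Named probability vector over the 8 fluorophore subsets.
#' @export
pollen_class_probs <- function(d_b, d_c, coc) {
  r_b <- d_b / 100
  r_c <- d_c / 100
  p_dco <- coc * r_b * r_c
  if (p_dco > min(r_b, r_c) + 1e-12) {
    stop("infeasible parameters: coc * r_b * r_c exceeds min(r_b, r_c)")
  }
  p_sb <- r_b - p_dco
  p_sc <- r_c - p_dco
  p_par <- 1 - p_sb - p_sc - p_dco
  if (p_par < -1e-12) stop("infeasible parameters: class probabilities < 0")
  p <- c(m1m2m3 = p_par / 2, none = p_par / 2,
         m1 = p_sb / 2, m2m3 = p_sb / 2,
         m1m2 = p_sc / 2, m3 = p_sc / 2,
         m1m3 = p_dco / 2, m2 = p_dco / 2)
  pmax(p, 0)
}

#' Simulate eight-class pollen counts
#'
#' Multinomial draw from [pollen_class_probs].
#'
#' @inheritParams pollen_class_probs
#' @param n_total number of pollen grains.
#' @return A `pollen_counts` object with 8 classes.
#' @export
simulate_pollen_counts <- function(d_b, d_c, coc, n_total) {
  p <- pollen_class_probs(d_b, d_c, coc)
  x <- stats::rmultinom(1, n_total, p)[, 1]
  pollen_counts(stats::setNames(as.numeric(x), names(p)))
}

#' Expected eight-class pollen counts (no sampling noise)
#' @inheritParams simulate_pollen_counts
#' @return A `pollen_counts` object with expectation counts.
#' @export
expected_pollen_counts <- function(d_b, d_c, coc, n_total) {
  pollen_counts(pollen_class_probs(d_b, d_c, coc) * n_total)
}
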