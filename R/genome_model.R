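#' Construct a genome model for meiosis simulation
#'
#' A genome model describes the simulator's world: chromosome lengths,
#' centromere positions, a piecewise-constant SNP-density track (SNPs/kb)
#' and the heterozygosity-block layout of the F1 whose meioses are
#' simulated. Regions outside `het_blocks` are homozygous in the cross and
#' therefore carry no informative markers, although crossovers still occur
#' there.
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (bp, > 0).
#' @param centromeres named numeric vector of centromere positions (bp),
#'   one per chromosome, each strictly inside its chromosome.
#' @param snp_density per-chromosome piecewise-constant density track:
#'   a named list of data.frames with columns `start`, `end` (half-open bp
#'   intervals tiling `[0, length)`) and `snps_per_kb` (>= 0). If `NULL`, a
#'   uniform track of `default_snps_per_kb` is built.
#' @param het_blocks per-chromosome list of data.frames with columns
#'   `start`, `end`: sorted, non-overlapping half-open heterozygous
#'   intervals. If `NULL`, each whole chromosome is heterozygous (the
#'   standard two-accession F1 hybrid).
#' @param default_snps_per_kb uniform SNP density used when `snp_density`
#'   is `NULL`.
#'
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, centromeres, snp_density = NULL,
                         het_blocks = NULL, default_snps_per_kb = 4) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be > 0")
  }
  if (anyDuplicated(chromosomes$name)) {
    stop("duplicate chromosome names")
  }
  chr_len <- stats::setNames(chromosomes$length, chromosomes$name)

  centromeres <- centromeres[chromosomes$name]
  if (any(is.na(centromeres))) {
    stop("centromere position missing for some chromosome")
  }
  if (any(centromeres <= 0 | centromeres >= chr_len)) {
    stop("centromeres must lie strictly inside their chromosome")
  }

  if (is.null(snp_density)) {
    snp_density <- lapply(chr_len, function(L) {
      data.frame(start = 0, end = L, snps_per_kb = default_snps_per_kb)
    })
  }
  snp_density <- snp_density[chromosomes$name]
  for (nm in chromosomes$name) {
    tr <- snp_density[[nm]]
    if (is.null(tr)) stop("snp_density track missing for chromosome ", nm)
    .check_tiling(tr, chr_len[[nm]], paste0("snp_density[", nm, "]"))
    if (any(tr$snps_per_kb < 0)) stop("snp_density must be >= 0 everywhere")
  }

  if (is.null(het_blocks)) {
    het_blocks <- lapply(chr_len, function(L) data.frame(start = 0, end = L))
  }
  het_blocks <- het_blocks[chromosomes$name]
  for (nm in chromosomes$name) {
    hb <- het_blocks[[nm]]
    if (is.null(hb)) {
      het_blocks[[nm]] <- data.frame(start = numeric(0), end = numeric(0))
      next
    }
    if (nrow(hb)) {
      if (any(hb$end <= hb$start)) stop("empty or inverted het block on ", nm)
      if (is.unsorted(hb$start, strictly = TRUE) && nrow(hb) > 1) {
        stop("het_blocks must be sorted by start on ", nm)
      }
      if (nrow(hb) > 1 && any(hb$start[-1] < hb$end[-nrow(hb)])) {
        stop("het_blocks overlap on ", nm)
      }
      if (any(hb$start < 0) || any(hb$end > chr_len[[nm]])) {
        stop("het_blocks outside chromosome ", nm)
      }
    }
  }

  structure(list(chromosomes = chromosomes,
                 centromeres = centromeres,
                 snp_density = snp_density,
                 het_blocks = het_blocks),
            class = "genome_model")
}

.check_tiling <- function(tr, len, what) {
  stopifnot(all(c("start", "end") %in% names(tr)))
  o <- order(tr$start)
  tr <- tr[o, ]
  if (tr$start[1] != 0 || tr$end[nrow(tr)] != len ||
      (nrow(tr) > 1 && any(tr$start[-1] != tr$end[-nrow(tr)]))) {
    stop(what, " must tile [0, chromosome length) exactly")
  }
  invisible(tr)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      sprintf("%.1f Mb total\n", sum(x$chromosomes$length) / 1e6))
  for (i in seq_len(nrow(x$chromosomes))) {
    nm <- x$chromosomes$name[i]
    het <- x$het_blocks[[nm]]
    cat(sprintf("  %s: %.1f Mb, cen %.1f Mb, %d het block(s)\n",
                nm, x$chromosomes$length[i] / 1e6,
                x$centromeres[[nm]] / 1e6, nrow(het)))
  }
  invisible(x)
}

#' Crossover-pathway parameters
#'
#' Parameterises the two crossover pathways of the simulator: Class I
#' (interference-sensitive, ZMM-type) as a gamma-renewal process with
#' shape `classI_nu`, and Class II (interference-insensitive, MUS81-type)
#' as an independent Poisson process. Local rates are modulated by
#' polymorphism-response functions emulating the mismatch-recognition
#' (MSH2-dependent) stimulation of Class I near heterozygosity-block
#' boundaries and the suppression of Class II at high SNP density.
#'
#' @param classI_base_cM_per_Mb baseline Class I map-rate (cM/Mb, gamete
#'   scale).
#' @param classI_nu gamma-renewal interference shape; `1` reduces Class I
#'   to a Poisson process (no interference); larger values give stronger
#'   interference.
#' @param classII_base_cM_per_Mb baseline Class II map-rate (cM/Mb).
#' @param classI_poly_response function of `(snps_per_kb, boundary_dist_bp)`
#'   returning a multiplier >= 0 applied to the Class I rate; default is
#'   neutral (always 1).
#' @param classII_poly_response function of `snps_per_kb` returning a
#'   multiplier in `[0, 1]` for the Class II rate; default neutral.
#' @param msh2_active if `FALSE` (an msh2 mutant), both polymorphism
#'   responses are replaced by neutral multipliers except a residual
#'   MSH2-independent Class II inhibition `classII_residual_response`.
#' @param classII_residual_response function of `snps_per_kb`, the
#'   MSH2-independent part of Class II inhibition; default neutral.
#' @param obligate_CO if `TRUE`, bivalents with no crossover are redrawn
#'   (slightly distorts the map; off by default).
#'
#' @return An object of class `pathway_params`.
#' @export
pathway_params <- function(classI_base_cM_per_Mb = 3,
                           classI_nu = 5,
                           classII_base_cM_per_Mb = 0.5,
                           classI_poly_response = NULL,
                           classII_poly_response = NULL,
                           msh2_active = TRUE,
                           classII_residual_response = NULL,
                           obligate_CO = FALSE) {
  if (classI_nu < 1) stop("classI_nu must be >= 1")
  if (classI_base_cM_per_Mb < 0 || classII_base_cM_per_Mb < 0) {
    stop("base rates must be >= 0")
  }
  neutral2 <- function(snps_per_kb, boundary_dist_bp) 1
  neutral1 <- function(snps_per_kb) 1
  if (is.null(classI_poly_response)) classI_poly_response <- neutral2
  if (is.null(classII_poly_response)) classII_poly_response <- neutral1
  if (is.null(classII_residual_response)) classII_residual_response <- neutral1
  stopifnot(is.function(classI_poly_response),
            is.function(classII_poly_response),
            is.function(classII_residual_response))
  structure(list(classI_base_cM_per_Mb = classI_base_cM_per_Mb,
                 classI_nu = classI_nu,
                 classII_base_cM_per_Mb = classII_base_cM_per_Mb,
                 classI_poly_response = classI_poly_response,
                 classII_poly_response = classII_poly_response,
                 classII_residual_response = classII_residual_response,
                 msh2_active = msh2_active,
                 obligate_CO = obligate_CO),
            class = "pathway_params")
}

#' Boundary-stimulation response for Class I crossovers
#'
#' Convenience constructor for the heterozygosity-juxtaposition response:
#' inside heterozygous blocks the Class I rate is multiplied by
#' `1 + A * exp(-boundary_dist / L)`, a minimal emulation of the elevated
#' Class I activity observed next to HET/HOM block boundaries. Illustrative
#' parameterisation, not fitted to data.
#'
#' @param A amplitude of the boundary stimulation (>= 0).
#' @param L decay length in bp (> 0).
#' @return A function usable as `classI_poly_response`.
#' @export
boundary_stimulation_response <- function(A = 1, L = 5e5) {
  stopifnot(A >= 0, L > 0)
  function(snps_per_kb, boundary_dist_bp) {
    1 + A * exp(-boundary_dist_bp / L)
  }
}

#' Density-suppression response for Class II crossovers
#'
#' Multiplier `1 / (1 + gamma * snps_per_kb)`, emulating mismatch-dependent
#' inhibition of the Class II pathway at polymorphic sites.
#'
#' @param gamma suppression strength per SNPs/kb (>= 0).
#' @return A function usable as `classII_poly_response`.
#' @export
density_suppression_response <- function(gamma = 0.25) {
  stopifnot(gamma >= 0)
  function(snps_per_kb) 1 / (1 + gamma * snps_per_kb)
}
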