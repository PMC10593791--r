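.meiomap_version <- function() {
  as.character(utils::packageVersion("meiomap"))
}

.file_header <- function(config_hash = "none", seed = NA) {
  sprintf("# meiomap %s; config_hash=%s; seed=%s",
          .meiomap_version(), config_hash, seed)
}

# md5 of an arbitrary R object via a canonical temp-file serialisation
.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

#' Write / read a marker table as tab-separated text
#'
#' The TSV carries comment lines (`#`) with the tool version and, when
#' known, per-individual library sizes, then a header row
#' `individual  chrom  pos  ref_count  alt_count  quality`.
#'
#' @param table a marker table.
#' @param path output path.
#' @param config_hash,seed provenance recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(table, path, config_hash = "none", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(config_hash, seed), con)
  lib <- attr(table, "library_sizes")
  if (!is.null(lib)) {
    writeLines(paste0("# library_sizes: ",
                      paste(names(lib), lib, sep = "=", collapse = ",")), con)
  }
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  lines <- readLines(path)
  cm <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  libline <- grep("^# library_sizes:", cm, value = TRUE)
  if (length(libline)) {
    kv <- strsplit(strsplit(sub("^# library_sizes: *", "", libline[1]),
                            ",")[[1]], "=")
    attr(tab, "library_sizes") <- stats::setNames(
      as.numeric(vapply(kv, `[`, character(1), 2)),
      vapply(kv, `[`, character(1), 1))
  }
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' Write crossover calls as BED and as a full TSV
#'
#' The BED6-like output has one row per call: `chrom`, `midpoint - 1`,
#' `midpoint` (0-based half-open around the 1-based midpoint),
#' `individual`, score 0, `transition`. The TSV keeps the flanking-marker
#' interval and the `suspect` flag.
#'
#' @param calls a `crossover_calls` data.frame.
#' @param path output path.
#' @param config_hash,seed provenance for the header comment.
#' @return `path`, invisibly.
#' @export
write_crossover_bed <- function(calls, path, config_hash = "none", seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(config_hash, seed), con)
  bed <- data.frame(chrom = calls$chrom,
                    start = calls$midpoint - 1,
                    end = calls$midpoint,
                    name = calls$individual,
                    score = 0,
                    transition = calls$transition)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_crossover_bed
#' @export
write_crossover_table <- function(calls, path, config_hash = "none",
                                  seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(config_hash, seed), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.config_defaults <- list(
  seed = 1L,
  out_dir = "results/pipeline",
  genome = list(chromosomes = list(list(name = "chr1", length = 2e7),
                                   list(name = "chr2", length = 15e6)),
                centromeres = list(chr1 = 1e7, chr2 = 7.5e6),
                default_snps_per_kb = 4),
  pathways = list(classI_base_cM_per_Mb = 3, classI_nu = 5,
                  classII_base_cM_per_Mb = 0.5, msh2_active = TRUE,
                  obligate_CO = FALSE),
  simulator = list(n_individuals = 200, mean_coverage = 5,
                   error_rate = 0, sites_per_Mb = 50,
                   quality_fail_frac = 0.05, library_size_factor = 50),
  caller = list(min_site_quality = 100, min_mean_coverage = 2.5,
                min_library_reads = 1e5, window_k = 5, min_support = 3),
  landscape = list(window_bp = 3e5, group_window_bp = 1e5, group_size = 12)
)

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys (naming the offender),
#' fills documented defaults and checks value ranges. The returned object
#' echoes every effective value, so a run is fully described by it.
#'
#' @param path path to a YAML config file.
#' @return A `run_config` list with elements `seed`, `out_dir`, `genome`,
#'   `pathways`, `simulator`, `caller`, `landscape`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(.config_defaults))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  cfg <- .config_defaults
  for (blk in names(raw)) {
    if (is.list(.config_defaults[[blk]]) && !is.null(names(.config_defaults[[blk]]))) {
      bad <- setdiff(names(raw[[blk]]), names(.config_defaults[[blk]]))
      if (length(bad)) stop("unknown config key: ", blk, ".", bad[1])
      cfg[[blk]][names(raw[[blk]])] <- raw[[blk]]
    } else {
      cfg[[blk]] <- raw[[blk]]
    }
  }
  for (key in c("min_site_quality", "min_mean_coverage", "min_library_reads")) {
    if (cfg$caller[[key]] < 0) stop("invalid value for ", key, ": must be >= 0")
  }
  if (cfg$simulator$mean_coverage <= 0) {
    stop("invalid value for mean_coverage: must be > 0")
  }
  if (cfg$simulator$error_rate < 0 || cfg$simulator$error_rate >= 0.5) {
    stop("invalid value for error_rate: must be in [0, 0.5)")
  }
  if (cfg$pathways$classI_nu < 1) {
    stop("invalid value for classI_nu: must be >= 1")
  }
  structure(cfg, class = "run_config")
}

.model_from_config <- function(cfg) {
  chromosomes <- do.call(rbind, lapply(cfg$genome$chromosomes, function(ch) {
    data.frame(name = ch$name, length = ch$length)
  }))
  genome_model(chromosomes,
               centromeres = unlist(cfg$genome$centromeres),
               default_snps_per_kb = cfg$genome$default_snps_per_kb)
}

.params_from_config <- function(cfg) {
  pathway_params(classI_base_cM_per_Mb = cfg$pathways$classI_base_cM_per_Mb,
                 classI_nu = cfg$pathways$classI_nu,
                 classII_base_cM_per_Mb = cfg$pathways$classII_base_cM_per_Mb,
                 msh2_active = cfg$pathways$msh2_active,
                 obligate_CO = cfg$pathways$obligate_CO)
}

#' Run the simulate -> filter -> call -> landscape pipeline
#'
#' Executes the full workflow described by a validated configuration:
#' simulate an F2 population and its GBS marker table (or ingest an
#' existing marker TSV via `markers`), filter, call genotypes and
#' crossovers, and produce windowed landscape summaries. Each stage's
#' outputs are written under `out_dir` with provenance headers; the
#' manifest records row counts, filter tallies and output checksums.
#' Reruns with identical config and seed reproduce identical output
#' checksums.
#'
#' @param cfg a `run_config` from [validate_config] (or a config path).
#' @param markers optional path to a marker-table TSV to ingest instead of
#'   simulating.
#' @return A `run_manifest` list (version, config hash, seed, per-stage
#'   summaries, output checksums), also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg, markers = NULL) {
  if (is.character(cfg)) cfg <- validate_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  hash <- .object_hash(unclass(cfg))
  seed <- cfg$seed
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  set.seed(seed)
  model <- .model_from_config(cfg)

  if (is.null(markers)) {
    pop <- stage("simulate", {
      simulate_f2_population(model, .params_from_config(cfg),
                             n = cfg$simulator$n_individuals)
    })
    tab <- stage("simulate_gbs", {
      simulate_gbs(pop, model,
                   mean_coverage = cfg$simulator$mean_coverage,
                   error_rate = cfg$simulator$error_rate,
                   sites_per_Mb = cfg$simulator$sites_per_Mb,
                   quality_fail_frac = cfg$simulator$quality_fail_frac,
                   library_size_factor = cfg$simulator$library_size_factor)
    })
    truth <- crossovers_truth(pop)
    utils::write.table(truth, file.path(cfg$out_dir, "crossovers_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_marker_table(tab, file.path(cfg$out_dir, "markers.tsv"), hash, seed)
    stages$simulate <- list(n_individuals = cfg$simulator$n_individuals,
                            n_true_crossovers = nrow(truth),
                            n_marker_rows = nrow(tab))
    n_ind <- cfg$simulator$n_individuals
  } else {
    tab <- stage("ingest", read_marker_table(markers))
    stages$ingest <- list(path = markers, n_marker_rows = nrow(tab))
    n_ind <- length(unique(tab$individual))
  }

  calls <- stage("call", {
    call_crossovers_from_markers(
      tab,
      filter_config(cfg$caller$min_site_quality,
                    cfg$caller$min_mean_coverage,
                    cfg$caller$min_library_reads),
      k = cfg$caller$window_k, min_support = cfg$caller$min_support)
  })
  write_crossover_bed(calls, file.path(cfg$out_dir, "crossovers.bed"),
                      hash, seed)
  write_crossover_table(calls, file.path(cfg$out_dir, "crossovers.tsv"),
                        hash, seed)
  counts <- count_per_individual(calls, unique(tab$individual))
  utils::write.table(counts, file.path(cfg$out_dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$call <- list(n_calls = nrow(calls),
                      filter_report = attr(calls, "filter_report"))

  track <- stage("landscape", {
    snps <- unique(tab[, c("chrom", "pos")])
    bin_crossovers(calls, model, window_bp = cfg$landscape$window_bp,
                   n_individuals = n_ind, snp_positions = snps)
  })
  utils::write.table(track, file.path(cfg$out_dir, "windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$landscape <- list(n_windows = nrow(track))

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(tool = "meiomap", version = .meiomap_version(),
                   config_hash = hash, seed = seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = stages,
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, class = "run_manifest")
}

#' Convert a VCF with per-sample allelic depths to a marker table
#'
#' Reads a VCF (requires the `vcfR` package), keeps biallelic SNP records,
#' and emits one marker-table row per (sample, site) from the `AD` format
#' field, with the record's `QUAL` as site quality. Multiallelic records
#' are skipped and counted in the `n_multiallelic_skipped` attribute.
#'
#' @param vcf_path path to a VCF file.
#' @param sample_map optional named character vector renaming VCF samples
#'   (`new_name = vcf_name`).
#' @return A `marker_table` data.frame.
#' @export
convert_vcf_to_marker_table <- function(vcf_path, sample_map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the vcfR package is required for VCF ingestion")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  n_multi <- sum(multi)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) stop("missing AD depth field in VCF"))
  if (all(is.na(ad))) stop("missing AD depth field in VCF")
  samples <- colnames(ad)
  rows <- list()
  for (s in samples) {
    vals <- ad[!multi, s]
    if (all(is.na(vals))) stop("missing AD depth field for sample ", s)
    parts <- strsplit(vals, ",", fixed = TRUE)
    ref <- as.numeric(vapply(parts, function(p) p[1] %||% NA_character_,
                             character(1)))
    alt <- as.numeric(vapply(parts, function(p) p[2] %||% NA_character_,
                             character(1)))
    out_name <- s
    if (!is.null(sample_map)) {
      hit <- names(sample_map)[sample_map == s]
      if (length(hit)) out_name <- hit[1]
    }
    rows[[s]] <- data.frame(
      individual = out_name,
      chrom = fix[!multi, "CHROM"],
      pos = as.numeric(fix[!multi, "POS"]),
      ref_count = ref, alt_count = alt,
      quality = as.numeric(fix[!multi, "QUAL"]))
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$ref_count) & !is.na(out$alt_count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_multiallelic_skipped") <- n_multi
  class(out) <- c("marker_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
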