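PIPELINE_STAGES <- c("quality", "abundance", "variants", "regions", "dgr")

#' Load and validate a sample manifest
#'
#' The manifest is a TSV with one row per sample: `sample_id`, `site`,
#' `vegetation`, `library_reads`, and the paths (relative to the manifest
#' file) of that sample's pileup and coverage tables. The derived group
#' label is `site` pasted to `vegetation` (e.g. ALJR, MASA).
#'
#' @param path Manifest TSV path.
#' @return A tibble with a `group` column and absolute `pileup`/`coverage`
#'   paths.
#' @export
load_manifest <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (nrow(df) == 0) abort("no samples in manifest")
  check_cols(df, c("sample_id", "site", "vegetation", "library_reads",
                   "pileup", "coverage"), sprintf("manifest '%s'", path))
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample_id in manifest: %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  df$pileup <- file.path(base, df$pileup)
  df$coverage <- file.path(base, df$coverage)
  for (i in seq_len(nrow(df))) {
    for (col in c("pileup", "coverage")) {
      if (!file.exists(df[[col]][i])) {
        abort(sprintf("sample %s: %s file not found: %s",
                      df$sample_id[i], col, df[[col]][i]))
      }
    }
  }
  mutate(df, group = paste0(.data$site, .data$vegetation))
}

#' Assemble and validate a pipeline configuration
#'
#' Collects the input paths and every stage threshold into one validated
#' object. All thresholds are checked against their operations'
#' preconditions here, before any stage runs.
#'
#' @param manifest Path to the sample manifest TSV ([load_manifest()]).
#' @param mags Path to the MAG manifest TSV.
#' @param gene_presence Path to the gene-presence TSV.
#' @param annotation Optional gene annotation path.
#' @param annotation_dialect `"gff3"` or `"bed"`.
#' @param contigs,rt_loci Optional contig FASTA and RT-locus TSV
#'   (`contig_id`, `start`, `end`) enabling the DGR stage.
#' @param gcpm_threshold Detection threshold in GCPM (default 2).
#' @param min_depth,min_maf SNV caller thresholds (defaults 10, 0.1).
#' @param window,breadth_present,breadth_absent,min_region Differential
#'   region parameters (defaults 1000, 0.5, 0.1, 5000).
#' @param dgr_window,dgr_min_len,dgr_min_identity,dgr_k,min_mismatches,min_polarity
#'   DGR detector parameters (defaults 20000, 50, 0.8, 12, 4, 0.75).
#' @param skip Character vector of stage names to skip.
#' @param seed Seed echoed into the report (no pipeline stage is
#'   stochastic, but the value is recorded for provenance).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, mags, gene_presence,
                            annotation = NULL, annotation_dialect = "gff3",
                            contigs = NULL, rt_loci = NULL,
                            gcpm_threshold = 2,
                            min_depth = 10, min_maf = 0.1,
                            window = 1000, breadth_present = 0.5,
                            breadth_absent = 0.1, min_region = 5000,
                            dgr_window = 20000, dgr_min_len = 50,
                            dgr_min_identity = 0.8, dgr_k = 12,
                            min_mismatches = 4, min_polarity = 0.75,
                            skip = character(), seed = 1) {
  if (!is.numeric(gcpm_threshold) || gcpm_threshold < 0) {
    abort("`gcpm_threshold` must be >= 0")
  }
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  check_fraction(min_maf, "min_maf", lo = 0, hi = 0.5, lo_open = TRUE)
  if (window <= 0) abort("`window` must be > 0")
  check_fraction(breadth_present, "breadth_present")
  check_fraction(breadth_absent, "breadth_absent")
  if (breadth_absent >= breadth_present) {
    abort("`breadth_absent` must be < `breadth_present`")
  }
  check_fraction(dgr_min_identity, "dgr_min_identity", lo = 0, lo_open = TRUE)
  check_fraction(min_polarity, "min_polarity")
  if (min_mismatches < 1) abort("`min_mismatches` must be >= 1")
  bad <- setdiff(skip, PIPELINE_STAGES)
  if (length(bad) > 0) {
    abort(sprintf("unknown stage(s) in `skip`: %s", paste(bad, collapse = ", ")))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages quality -> abundance -> variants -> regions -> dgr
#' in order, writing each stage's TSV outputs before the next starts and
#' a consolidated `report.json` at the end. A stage error aborts the
#' remaining stages; partial outputs are retained and the failure is
#' flagged in the report. Re-running with identical inputs and config
#' reproduces the outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly (a list; also written as
#'   `report.json`). Element `ok` is `FALSE` if any stage errored.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  thresholds <- config[c("gcpm_threshold", "min_depth", "min_maf", "window",
                         "breadth_present", "breadth_absent", "min_region",
                         "dgr_window", "dgr_min_len", "dgr_min_identity",
                         "dgr_k", "min_mismatches", "min_polarity")]
  report <- list(schema_version = "1.0", seed = config$seed,
                 thresholds = thresholds, stages = list())
  state <- new.env()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "not_run")
      return(invisible())
    }
    if (name %in% config$skip) {
      log_msg(name, "skipped")
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    log_msg(name, "starting")
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    if (res$ok) {
      report$stages[[name]] <<- c(list(status = "ok"), res$value)
      log_msg(name, "done")
    } else {
      report$stages[[name]] <<- list(status = "failed", error = res$msg)
      log_msg(name, "FAILED: %s", res$msg)
      failed <<- TRUE
    }
  }

  manifest <- load_manifest(config$manifest)
  state$manifest <- manifest
  state$mags <- read_mag_manifest(config$mags)
  state$annotation <- if (!is.null(config$annotation)) {
    read_annotation(config$annotation, config$annotation_dialect)
  }

  run_stage("quality", function() {
    q <- mag_quality(state$mags)
    guild <- classify_sulfur_guild(read_gene_presence(config$gene_presence))
    out <- left_join(q, mutate(guild,
                               missing_srb = vapply(.data$missing_srb, paste,
                                                    character(1), collapse = ","),
                               missing_sox = vapply(.data$missing_sox, paste,
                                                    character(1), collapse = ",")),
                     by = "mag_id")
    out$guild[is.na(out$guild)] <- "none"
    readr::write_tsv(out, p("quality.tsv"))
    state$quality <- out
    list(n_mags = nrow(out), n_pass = sum(out$passes),
         guilds = as.list(table(out$guild)))
  })

  run_stage("abundance", function() {
    cov <- bind_rows(lapply(unique(manifest$coverage), read_coverage))
    ab <- build_abundance_matrix(
      cov, state$mags,
      manifest[, c("sample_id", "site", "vegetation", "library_reads")],
      threshold = config$gcpm_threshold)
    wide <- abundance_wide(ab)
    readr::write_tsv(as_tibble(wide, rownames = "mag_id"), p("abundance.tsv"))
    bc <- bray_curtis(ab)
    readr::write_tsv(as_tibble(bc, rownames = "sample_id"), p("bray_curtis.tsv"))
    state$coverage <- cov
    list(n_mags = nrow(wide), n_samples = ncol(wide),
         n_detected = sum(ab$detected))
  })

  run_stage("variants", function() {
    pile <- bind_rows(lapply(manifest$pileup, read_pileup))
    snvs <- call_snvs(pile, min_depth = config$min_depth,
                      min_maf = config$min_maf)
    readr::write_tsv(snvs, p("snvs.tsv"))
    gv <- NULL
    if (!is.null(state$annotation)) {
      gv <- purrr::map_dfr(unique(pile$sample_id), function(sid) {
        mutate(summarize_gene_variability(
          snvs[snvs$sample_id == sid, ], pile[pile$sample_id == sid, ],
          state$annotation, min_depth = config$min_depth),
          sample_id = sid, .before = 1)
      })
      readr::write_tsv(gv, p("gene_variability.tsv"))
      mean_gv <- summarise(group_by(gv, .data$gene_id),
                           snv_per_kbp = mean(.data$snv_per_kbp),
                           .groups = "drop")
      if (nrow(mean_gv) >= 4) {
        readr::write_tsv(flag_hotspot_genes(mean_gv), p("hotspots.tsv"))
      }
    }
    mapped <- summarise(group_by(state$coverage %||%
                                   bind_rows(lapply(unique(manifest$coverage),
                                                    read_coverage)),
                                 .data$sample_id),
                        mapped_reads = sum(.data$mapped_reads),
                        .groups = "drop")
    sv <- sample_variability(snvs, mapped)
    readr::write_tsv(sv, p("sample_variability.tsv"))
    state$pileups <- pile
    list(n_snvs = nrow(snvs), n_genes = if (is.null(gv)) 0L else
      length(unique(gv$gene_id)))
  })

  run_stage("regions", function() {
    depths <- pileup_depth(state$pileups)
    lens <- setNames(state$mags$length, state$mags$contig_id)
    regions <- detect_differential_regions(
      depths, manifest[, c("sample_id", "group")], lens,
      annotation = state$annotation,
      window = config$window, breadth_present = config$breadth_present,
      breadth_absent = config$breadth_absent, min_region = config$min_region)
    readr::write_tsv(regions, p("regions.tsv"))
    list(n_regions = nrow(regions))
  })

  run_stage("dgr", function() {
    if (is.null(config$contigs) || is.null(config$rt_loci)) {
      return(list(note = "no contigs/rt_loci configured; nothing to do",
                  n_cassettes = 0L))
    }
    seqs <- read_fasta(config$contigs)
    rt <- readr::read_tsv(config$rt_loci, show_col_types = FALSE)
    check_cols(rt, c("contig_id", "start", "end"), "`rt_loci`")
    rows <- list()
    for (ctg in unique(rt$contig_id)) {
      if (!ctg %in% names(seqs)) abort(sprintf("RT contig not in FASTA: %s", ctg))
      orfs <- state$annotation[state$annotation$contig_id == ctg, ]
      scr <- detect_dgr(seqs[[ctg]], rt[rt$contig_id == ctg, ], orfs,
                        window = config$dgr_window,
                        min_len = config$dgr_min_len,
                        min_identity = config$dgr_min_identity,
                        k = config$dgr_k,
                        min_mismatches = config$min_mismatches,
                        min_polarity = config$min_polarity,
                        contig_id = ctg)
      rows[[ctg]] <- tidy(scr)
    }
    cassettes <- bind_rows(rows)
    readr::write_tsv(cassettes, p("dgr_cassettes.tsv"))
    list(n_cassettes = nrow(cassettes))
  })

  report$ok <- !failed
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(report)
}
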