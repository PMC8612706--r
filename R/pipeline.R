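# End-to-end orchestration: configuration, the full ingest -> features ->
# mitotypes -> statistics -> dynamics -> platelet analysis pipeline, and a
# reproducible report bundle with a run manifest.

.pipeline_keys <- c("simulate", "n_participants", "seed", "inputs", "registry",
                    "qc_cv_threshold", "sd_type", "mhi_stratum", "top_n_subtypes",
                    "n_weeks", "n_depletion_subjects", "depletion_efficiency",
                    "out_dir")

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Unknown keys are rejected. The configuration (and the seed) is echoed
#' verbatim into the run manifest of every report bundle.
#'
#' @param path Optional JSON file to read the configuration from.
#' @param ... Configuration values overriding the file/defaults: `simulate`
#'   (default TRUE), `n_participants`, `seed`, `inputs` (list of CSV paths:
#'   `plate`, `ct`, `weekly`, `triplets`), `registry` (path or "default"),
#'   `qc_cv_threshold`, `sd_type`, `mhi_stratum`, `top_n_subtypes`,
#'   `n_weeks`, `n_depletion_subjects`, `depletion_efficiency`, `out_dir`.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(simulate = TRUE, n_participants = 21, seed = 1L,
              inputs = list(), registry = "default",
              qc_cv_threshold = 0.15, sd_type = "sample",
              mhi_stratum = "subtype", top_n_subtypes = 6,
              n_weeks = 9, n_depletion_subjects = 9,
              depletion_efficiency = 1, out_dir = tempfile("immunomito_run_"))
  if (!is.null(path)) {
    file_cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  unknown <- setdiff(names(cfg), .pipeline_keys)
  assert_that(length(unknown) == 0,
              paste("unknown configuration keys:", paste(unknown, collapse = ", ")))
  assert_that(cfg$sd_type %in% c("sample", "population"), "sd_type must be sample/population")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest -> feature assembly (+ MHI) -> mitotypes ->
#' cross-sectional statistics (sex and age effect ranking, category
#' enrichment, co-regulation) -> weekly dynamics -> platelet depletion
#' analysis, as inputs are available, and writes tidy CSV/JSON outputs plus a
#' run manifest into `config$out_dir`. Identical config + seed reproduce
#' byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param write Write the report bundle to disk (default TRUE).
#' @return Invisibly, a list with all in-memory result tables and
#'   `qc_failures` (count of replicate-CV QC flags).
#' @export
run_pipeline <- function(config = pipeline_config(), write = TRUE) {
  assert_that(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  res <- list()
  if (isTRUE(config$simulate)) {
    scfg <- synthetic_config(n_participants = config$n_participants,
                             seed = config$seed)
    cohort <- generate_cohort(scfg)
    raw <- generate_raw_tables(cohort, well_cv = 0.03, drift_per_position = 0.002,
                               ct_sd = 0.05)
    plate <- raw$plate; ct <- raw$ct
    participants <- cohort$participants
    weekly <- generate_repeat_series(scfg, n_weeks = config$n_weeks)
    triplets <- generate_depletion_triplets(
      scfg, n_subjects = config$n_depletion_subjects,
      depletion_efficiency = config$depletion_efficiency)
  } else {
    req <- function(key) {
      p <- config$inputs[[key]]
      assert_that(!is.null(p), paste0("missing required input: '", key, "'"))
      assert_that(file.exists(p), paste0("input file not found: ", p))
      .read_csv_checked(p, key)
    }
    plate <- req("plate"); ct <- req("ct")
    participants <- req("participants")
    weekly <- if (!is.null(config$inputs$weekly)) req("weekly") else NULL
    triplets <- if (!is.null(config$inputs$triplets)) req("triplets") else NULL
  }
  features <- ingest_features(plate, ct)
  cv_cols <- grep("^cv_", names(features))
  res$qc_failures <- sum(unlist(features[cv_cols]) > config$qc_cv_threshold,
                         na.rm = TRUE)
  meta <- participants[, c("participant", "sex", "age")]
  features <- merge(features, meta, by = "participant", sort = TRUE)
  features <- features[order(features$participant, features$subtype), ]
  ref <- compute_reference_stats(features, stratum = config$mhi_stratum)
  features <- add_mhi(features, ref)
  res$features <- features
  registry <- read_registry(config$registry)
  mito <- compute_mitotypes(features, registry)
  res$mitotypes <- mito
  res$celltype_summary <- suppressWarnings(celltype_summary(mito))
  purified <- mito[mito$subtype != "PBMC", ]
  attr(purified, "registry") <- registry
  res$sex_ranking <- suppressWarnings(effect_ranking(purified, "sex"))
  res$sex_enrichment <- category_enrichment(res$sex_ranking)
  res$age_ranking <- suppressWarnings(effect_ranking(purified, "age"))
  res$age_enrichment <- category_enrichment(res$age_ranking)
  res$coregulation <- lapply(stats::setNames(nm = c(.feature_names, "MHI")), function(f)
    suppressWarnings(coregulation(features[features$subtype != "PBMC", ], f)))
  if (!is.null(weekly)) {
    res$weekly_metrics <- suppressWarnings(weekly_metrics(weekly))
    res$within_person <- lapply(stats::setNames(nm = intersect(.feature_names,
                                                               unique(weekly$feature))),
                                function(f) suppressWarnings(
                                  within_person_coregulation(weekly, f)))
  }
  if (!is.null(triplets)) {
    res$depletion <- depletion_analysis(triplets)
    # a zero-share feature (CIV) yields negative raw shares under noise; the
    # clip warning is expected there
    res$platelet_share <- suppressWarnings(platelet_share_estimate(
      triplets, efficiency = config$depletion_efficiency))
  }
  if (write) .write_bundle(res, config)
  invisible(res)
}

.read_csv_checked <- function(path, what) {
  out <- tryCatch(utils::read.csv(path),
                  error = function(e) stop("failed to parse ", what, " (", path, "): ",
                                           conditionMessage(e), call. = FALSE))
  bad <- which(!stats::complete.cases(out))
  if (length(bad)) stop("schema violation in ", path, ": incomplete rows at lines ",
                        paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
  out
}

.write_bundle <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(df, file.path(config$out_dir, name),
                                            row.names = FALSE)
  wr(res$features, "features.csv")
  wr(res$mitotypes, "mitotypes.csv")
  wr(res$celltype_summary, "celltype_summary.csv")
  wr(res$sex_ranking, "sex_ranking.csv")
  wr(res$sex_enrichment, "sex_enrichment.csv")
  wr(res$age_ranking, "age_ranking.csv")
  wr(res$age_enrichment, "age_enrichment.csv")
  if (!is.null(res$weekly_metrics)) wr(res$weekly_metrics, "weekly_metrics.csv")
  if (!is.null(res$depletion)) {
    wr(res$depletion$per_feature, "depletion_analysis.csv")
    wr(res$platelet_share, "platelet_share.csv")
  }
  coreg <- lapply(res$coregulation, function(z)
    list(average_rz = z$average_rz, n_pairs = z$n_pairs))
  jsonlite::write_json(coreg, file.path(config$out_dir, "coregulation.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "immunomito",
                   version = as.character(utils::packageVersion("immunomito")),
                   config = unclass(config), seed = config$seed,
                   qc_failures = res$qc_failures,
                   created = "run manifest; timestamps omitted for reproducibility")
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  manifest$config_hash <- unname(tools::md5sum(mpath))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(mpath)
}
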