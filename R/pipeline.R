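#' Pipeline configuration
#'
#' Builds/validates the configuration for [run_pipeline()]. Accepts a YAML
#' file path or a named list; missing entries take the defaults below.
#'
#' @param config path to a YAML file or a named list.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    n = 300, seed = 0, k = 3, nor_limits = c(20, 10, 10),
    bootstrap_B = 0, n_init = 10, standardize = FALSE,
    input_dir = NULL, participants_csv = NULL, out_dir = NULL,
    qc = list(),
    indicators = c("adl_compromised", "cognition_impaired", "fried_positive",
                   "slow_gait", "balance_impaired", "recent_fall"),
    models = c("unadjusted", "age_sex", "full"),
    recordings = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (cfg$k < 2)
    stop("configuration error: k must be at least 2 (silhouette and morphology ",
         "diagnostics are undefined for k = 1)")
  class(cfg) <- "pipeline_config"
  cfg
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL  # output location does not affect the analysis
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], file = tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full morphology analysis pipeline
#'
#' Executes prep (read or simulate recordings, quality screen) -> feature
#' extraction -> k-means++ clustering with morphology labels -> NOR
#' reassignment -> frailty association analysis, optionally writing
#' `features.csv`, `clusters.json`, `groups.csv` and `assoc.csv` to
#' `out_dir` (atomically, via write-then-rename). With no `input_dir`, a
#' synthetic cohort of size `n` is simulated.
#'
#' @param config see [pipeline_config()].
#' @return object of class `bp_report`: `features`, `fit`
#'   (the [bp_morphology]), `groups`, `reassignment`, `associations`,
#'   `qc` (per-participant quality reports, if recordings were processed)
#'   and `meta` (seed, config hash, package version, stage counts).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  counts <- c()
  qc_reports <- NULL

  if (!is.null(cfg$input_dir)) {
    files <- list.files(cfg$input_dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
    files <- files[basename(files) != "participants.csv"]
    if (!length(files)) stop("prep: no recording files in ", cfg$input_dir)
    recs <- lapply(files, read_bp_recording)
    participants <- if (!is.null(cfg$participants_csv))
      utils::read.csv(cfg$participants_csv, stringsAsFactors = FALSE) else NULL
  } else {
    sim <- simulate_cohort(n = cfg$n, seed = cfg$seed, recordings = cfg$recordings)
    recs <- sim$recordings
    participants <- sim$participants
  }

  if (!is.null(recs)) {
    counts["recorded"] <- length(recs)
    qc <- do.call(qc_config, cfg$qc)
    qc_reports <- lapply(recs, screen_quality, cfg = qc)
    keep <- vapply(qc_reports, `[[`, logical(1), "passed")
    for (r in qc_reports[!keep])
      message(sprintf("pipeline: excluding %s (%s)", r$participant_id,
                      paste(r$flags, collapse = ", ")))
    recs <- recs[keep]
    counts["passed_qc"] <- length(recs)
    if (!length(recs)) stop("prep: no recording passed quality screening")
    features <- extract_features_cohort(recs)
  } else {
    features <- participants[, c("participant_id", "baseline", "early_pct",
                                 "stab_pct", "late_pct", "early_mmhg",
                                 "stab_mmhg", "late_mmhg")]
  }
  counts["features"] <- nrow(features)

  fit <- bp_morphology(features, k = cfg$k, nor_limits = cfg$nor_limits,
                       standardize = cfg$standardize, n_init = cfg$n_init,
                       seed = cfg$seed, bootstrap_B = cfg$bootstrap_B)

  associations <- NULL
  if (!is.null(participants)) {
    merged <- merge(fit$groups, participants, by = "participant_id")
    inds <- intersect(cfg$indicators, names(merged))
    if (length(inds))
      associations <- cluster_associations(merged, inds, models = cfg$models)
  }

  meta <- list(seed = cfg$seed, config_hash = config_hash(cfg),
               version = as.character(utils::packageVersion("orthomorph")),
               counts = counts)

  report <- structure(list(features = features, fit = fit, groups = fit$groups,
                           reassignment = fit$reassignment,
                           associations = associations, qc = qc_reports,
                           meta = meta),
                      class = "bp_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_atomic(function(p) utils::write.csv(features, p, row.names = FALSE),
                 file.path(cfg$out_dir, "features.csv"))
    write_atomic(function(p) utils::write.csv(fit$groups, p, row.names = FALSE),
                 file.path(cfg$out_dir, "groups.csv"))
    cl <- list(k = fit$kmeans$k,
               centroids = unname(apply(fit$centers, 1, as.numeric, simplify = FALSE)),
               morphology = fit$morphology,
               labels = fit$groups$original_cluster,
               inertia = fit$kmeans$inertia, i_conv = fit$kmeans$i_conv,
               quality = list(d_c = fit$quality$d_c,
                              diameter = fit$quality$diameter,
                              d_cc = fit$quality$d_cc[lower.tri(fit$quality$d_cc)],
                              silhouette = fit$quality$silhouette,
                              jaccard = fit$quality$jaccard),
               meta = meta)
    write_atomic(function(p) jsonlite::write_json(cl, p, auto_unbox = TRUE,
                                                  digits = NA, pretty = TRUE),
                 file.path(cfg$out_dir, "clusters.json"))
    if (!is.null(associations))
      write_atomic(function(p) utils::write.csv(associations, p, row.names = FALSE),
                   file.path(cfg$out_dir, "assoc.csv"))
  }
  report
}

#' @export
print.bp_report <- function(x, ...) {
  cat("Active-stand morphology analysis report\n")
  cat(sprintf("seed %s, config %s, orthomorph %s\n", x$meta$seed,
              x$meta$config_hash, x$meta$version))
  if (length(x$meta$counts))
    cat("stage counts:", paste(names(x$meta$counts), x$meta$counts,
                               sep = "=", collapse = ", "), "\n")
  print(x$fit)
  if (!is.null(x$associations)) {
    cat("\nassociations vs NOR (first rows):\n")
    print(utils::head(x$associations), row.names = FALSE)
  }
  invisible(x)
}
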