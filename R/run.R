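#' Pipeline configuration defaults
#'
#' The standard study conditions: 8 phase lags `k * pi / 4`, 24 time steps
#' per cycle, 2 mA current amplitude (4 mA peak-to-peak) at 20 Hz, the
#' 99.9th-percentile / 2% threshold pair, timewise RDM, and 10000
#' permutations.
#'
#' @param ... overrides for any default field.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "synthetic",          # "synthetic" or "files"
    out_dir = NULL,
    phase_lags = default_phase_lags(),
    n_time_steps = 24,
    io = 2, f = 20,
    pct = 99.9, floor_frac = 0.02,
    rdm_mode = "timewise",
    area_frac = 0.5,
    n_permutations = 10000,
    alpha = 0.05,
    seed = 1,
    # synthetic mode
    n_individuals = 6, subdivisions = 3, radius = 80,
    overlap = 0.3, field_mode = "overlapping",
    site_jitter_sd = 0.04, amp_sdlog = 0.2,
    montage_ids = NULL,
    # files mode: mesh path, labels path, named field paths per montage
    mesh = NULL, labels = NULL, fields = NULL,
    region_labels = list(M1_right = 1L, M1_left = 2L, surrounding = 3L),
    # individualization objectives
    objectives = c("delta_dotp", "rdm"),
    test_metrics = c("peak_magnitude", "peak_normal", "rdm",
                     "delta_dotp", "effective_area")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, over)
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: obtain inputs (generate a synthetic cohort, or read
#' mesh / labels / per-montage field files), compute the metric table,
#' run the phase-lag modulation tests with Holm correction, select
#' individualized montages for each objective, and write everything to
#' `out_dir`: `metrics.tsv`, `tests.tsv`, `selection_<objective>.tsv`,
#' `individualization.json` and a `manifest.json` with the configuration
#' hash, package version and seed. Deterministic given (inputs, config,
#' seed).
#'
#' @param config list from [pipeline_config()], or a path to a JSON file
#'   of overrides.
#' @return list with `metrics`, `tests`, `cv`, `individualization` and
#'   the output paths, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    config <- do.call(pipeline_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  if (!config$rdm_mode %in% c("timewise", "envelope")) {
    stop("configuration error: rdm_mode must be \"timewise\" or ",
         "\"envelope\", got '", config$rdm_mode, "'")
  }
  if (is.null(config$out_dir)) stop("configuration error: out_dir not set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    montages <- default_montages()
    if (!is.null(config$montage_ids)) {
      montages <- montages[montages$montage_id %in% config$montage_ids, ]
      if (nrow(montages) == 0L) stop("no known montage ids selected")
    }
    spec <- synthetic_montage_spec(overlap = config$overlap,
                                   mode = config$field_mode)
    cohort <- make_cohort(spec, n_individuals = config$n_individuals,
                          seed = config$seed,
                          site_jitter_sd = config$site_jitter_sd,
                          amp_sdlog = config$amp_sdlog,
                          montages = montages,
                          radius = config$radius,
                          subdivisions = config$subdivisions,
                          io = config$io, f = config$f)
  } else if (config$mode == "files") {
    if (is.null(config$mesh) || is.null(config$fields)) {
      stop("configuration error: files mode needs `mesh` and `fields`")
    }
    mesh <- read_mesh(config$mesh)
    labels <- if (is.null(config$labels)) NULL else
      read_labels_tsv(config$labels)
    sheet <- cortical_sheet(mesh$nodes, mesh$triangles, labels,
                            region_sets = config$region_labels)
    basis <- lapply(config$fields, read_fields_tsv)
    if (is.null(names(basis))) {
      names(basis) <- vapply(basis, function(b) b$montage_id, "")
    }
    cohort <- list(list(individual_id = basis[[1]]$individual_id,
                        sheet = sheet, basis = basis))
  } else {
    stop("configuration error: mode must be \"synthetic\" or \"files\"")
  }

  message("computing metrics for ", length(cohort), " individual(s) x ",
          length(cohort[[1]]$basis), " montage(s)")
  metrics <- cohort_metrics(
    cohort, phase_lags = config$phase_lags,
    n_steps = config$n_time_steps, rdm_mode = config$rdm_mode,
    pct = config$pct, floor_frac = config$floor_frac,
    area_frac = config$area_frac
  )
  metrics_path <- file.path(config$out_dir, "metrics.tsv")
  utils::write.table(metrics, metrics_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  tests <- NULL
  tests_path <- NULL
  if (length(cohort) >= 2L) {
    tests <- test_phase_modulation(
      dplyr::filter(metrics, .data$metric %in% config$test_metrics),
      n_perm = config$n_permutations, seed = config$seed,
      alpha = config$alpha
    )
    tests_path <- file.path(config$out_dir, "tests.tsv")
    utils::write.table(tidy(tests), tests_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  cv <- metric_cv(metrics)
  utils::write.table(cv, file.path(config$out_dir, "cv.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  indiv <- NULL
  if (length(cohort) >= 2L && length(cohort[[1]]$basis) >= 2L) {
    indiv <- lapply(config$objectives, function(obj) {
      s <- individualized_summary(metrics, obj)
      utils::write.table(
        tibble::as_tibble(s$selection)[c("individual_id", "montage_id")],
        file.path(config$out_dir, paste0("selection_", obj, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
      s
    })
    names(indiv) <- config$objectives
    jsonlite::write_json(
      lapply(indiv, function(s) {
        list(metric = s$metric, fixed_best_montage = s$fixed_best_montage,
             mean_fixed_best = s$mean_fixed_best,
             mean_individualized = s$mean_individualized,
             cv_fixed_best = s$cv_fixed_best,
             cv_individualized = s$cv_individualized)
      }),
      file.path(config$out_dir, "individualization.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  cfg_ser <- config
  cfg_ser$phase_lags <- as.numeric(cfg_ser$phase_lags)
  jsonlite::write_json(
    list(package = "dstacs",
         version = as.character(utils::packageVersion("dstacs")),
         r_version = as.character(getRversion()),
         seed = config$seed,
         config_hash = rlang::hash(cfg_ser),
         n_individuals = length(cohort),
         n_montages = length(cohort[[1]]$basis),
         n_metric_rows = nrow(metrics)),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(metrics = metrics, tests = tests, cv = cv,
                 individualization = indiv,
                 paths = list(metrics = metrics_path, tests = tests_path,
                              out_dir = config$out_dir)))
}
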