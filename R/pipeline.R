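#' Per-dyad summary metrics
#'
#' Runs the full per-dyad analysis on an energy pair: whole-recording
#' cross-correlation (synchrony `c0` and entrainment centre of mass
#' `com_s`), jitter band power of each person's energy spectrum, and the
#' windowed dominance analysis (dominance ratio). The dominance ratio is
#' `NA` when one side never leads; the entrainment is `NA` when no
#' centre-of-mass weight survives rectification.
#'
#' @param energy a [dyad_energy()] tibble.
#' @param max_lag whole-recording maximum lag T (s).
#' @param window_len,hop,window_max_lag moving-window settings (s), see
#'   [windowed_entrainment()].
#' @param jitter_band jitter band (Hz), see [band_power()].
#' @param normalize_jitter report jitter as a fraction of non-DC power.
#' @param weights centre-of-mass weight mode, see [center_of_mass()].
#' @param fps frame-rate override (Hz).
#' @return A one-row tibble: `c0`, `com_s`, `jitter_subject`,
#'   `jitter_actor`, `dominance_ratio`, `n_bouts_subject`,
#'   `n_bouts_actor`, `duration_s`, `fps`.
#' @export
dyad_metrics <- function(energy, max_lag = 15, window_len = 20, hop = 1,
                         window_max_lag = 5, jitter_band = c(1.5, 5),
                         normalize_jitter = FALSE,
                         weights = c("threshold", "clip", "raw"), fps = NULL) {
  weights <- match.arg(weights)
  fps <- energy_fps(energy, fps)
  cc <- cross_correlation(energy, max_lag = max_lag, fps = fps)
  c0 <- synchrony_score(cc)
  com <- tryCatch(center_of_mass(cc, weights = weights),
                  dyadsync_degenerate_error = function(e) NA_real_)
  jit <- function(x) {
    band_power(power_spectrum(x, fps), jitter_band[1], jitter_band[2],
               normalize = normalize_jitter)
  }
  prof <- windowed_entrainment(energy, window_len, hop, window_max_lag,
                               weights = weights, fps = fps)
  bouts <- dominance_bouts(prof)
  ratio <- tryCatch(dominance_ratio(bouts),
                    dyadsync_undefined_ratio = function(e) NA_real_)
  tibble(
    c0 = c0,
    com_s = com,
    jitter_subject = jit(energy$subject),
    jitter_actor = jit(energy$actor),
    dominance_ratio = ratio,
    n_bouts_subject = sum(bouts$leader == "subject"),
    n_bouts_actor = sum(bouts$leader == "actor"),
    duration_s = nrow(energy) / fps,
    fps = fps
  )
}

#' Metrics table for a whole cohort
#'
#' @param cohort a tibble with columns `dyad_id`, `label` and `energy`
#'   (list of [dyad_energy()]), as produced by [gen_cohort()].
#' @param ... passed to [dyad_metrics()].
#' @return A tibble with one row per dyad: identifiers, label and all
#'   [dyad_metrics()] columns.
#' @export
cohort_metrics <- function(cohort, ...) {
  stopifnot(all(c("dyad_id", "label", "energy") %in% names(cohort)))
  res <- purrr::map_dfr(cohort$energy, dyad_metrics, ...)
  dplyr::bind_cols(cohort[c("dyad_id", "label")], res)
}

#' Group comparison and classifier report for a cohort
#'
#' For each per-dyad metric, compares scenario groups A and B with a
#' Mann-Whitney test and rank-biserial effect size, then fits and
#' bootstraps the two-feature logistic classifier on (x = `c0`,
#' y = `com_s`).
#'
#' @param metrics a [cohort_metrics()] table (columns `label`, `c0`,
#'   `com_s`, `jitter_subject`, `jitter_actor`, `dominance_ratio`).
#' @param n_boot bootstrap replicates for the classifier.
#' @param seed integer seed for the bootstrap.
#' @param oob evaluate classifier accuracy out-of-bag.
#' @return A list of class `cohort_report`: `tests` (tibble of
#'   Mann-Whitney results per metric), `classifier` (a `dyad_classifier`),
#'   `group_means`, `seed`, `n_boot`.
#' @export
cohort_report <- function(metrics, n_boot = 1000L, seed = 1L, oob = TRUE) {
  if (!"label" %in% names(metrics)) stop_config("metrics table lacks a `label` column")
  labs <- unique(metrics$label)
  if (length(labs) < 2L) stop_config("metrics table has a single label; need two groups")
  if (min(table(metrics$label)) < 2L) stop_domain("need >= 2 dyads per label")
  vars <- intersect(
    c("c0", "com_s", "jitter_subject", "jitter_actor", "dominance_ratio"),
    names(metrics)
  )
  tests <- purrr::map_dfr(vars, function(v) {
    dplyr::bind_cols(
      tibble(metric = v),
      mann_whitney(metrics[[v]][metrics$label == "A"],
                   metrics[[v]][metrics$label == "B"])
    )
  })
  group_means <- metrics |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                   ~ mean(.x, na.rm = TRUE)),
                     n = dplyr::n(), .groups = "drop")
  clf_data <- tibble(x = metrics$c0, y = metrics$com_s, label = metrics$label)
  classifier <- bootstrap_classifier(clf_data, positive = "B",
                                     n_boot = n_boot, seed = seed, oob = oob)
  structure(
    list(tests = tests, classifier = classifier, group_means = group_means,
         seed = seed, n_boot = n_boot),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n\nGroup means:\n")
  print(x$group_means)
  cat("\nMann-Whitney tests (A vs B):\n")
  print(x$tests)
  cat("\n")
  print(x$classifier)
  invisible(x)
}

report_as_list <- function(report) {
  clf <- report$classifier
  td <- tidy(clf)
  list(
    tests = report$tests,
    group_means = report$group_means,
    classifier = list(
      a = clf$a, b = clf$b, c = clf$c,
      boot_mean = as.list(setNames(td$boot.mean, td$term)),
      boot_sd = as.list(setNames(td$std.error, td$term)),
      accuracy_mean = mean(clf$boot$accuracy),
      accuracy_sd = sd(clf$boot$accuracy),
      oob = clf$oob, n_boot = clf$n_boot
    ),
    seed = report$seed
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input(sprintf("config file '%s' not found", config))
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or a YAML/JSON path")
  config
}

run_log <- function(out_dir, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...))
  message(line)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

#' Analyze recordings end-to-end
#'
#' For each input (an image-sequence directory or a precomputed energy
#' CSV), computes the energy series, cross-correlation, spectra and
#' per-dyad metrics, and writes them as CSV/JSON under `out_dir`. Every
#' output records the seed and a hash of the configuration. Per-input
#' failures are logged and skipped; the run fails only if every input
#' fails.
#'
#' @param config a list (or YAML/JSON path) with elements: `inputs`
#'   (character vector), `out_dir`, and optionally `fps`, `boundary_col`,
#'   `subject_side`, `start`, `end`, `flow` (list for [flow_params()]),
#'   `analysis` (list of [dyad_metrics()] settings), `seed`.
#' @return Invisibly, the per-dyad metrics tibble.
#' @export
run_analyze <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$inputs) || !length(cfg$inputs)) stop_config("config needs a non-empty `inputs`")
  if (is.null(cfg$out_dir)) stop_config("config needs `out_dir`")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- rlang::hash(cfg)
  seed <- cfg$seed %||% 1L
  an <- cfg$analysis %||% list()
  run_log(cfg$out_dir, "analyze: %d input(s), config %s, seed %d, dyadsync %s",
          length(cfg$inputs), cfg_hash, seed,
          as.character(utils::packageVersion("dyadsync")))
  results <- list()
  for (inp in cfg$inputs) {
    stem <- tools::file_path_sans_ext(basename(inp))
    res <- tryCatch({
      de <- if (dir.exists(inp)) {
        fs <- read_frames(inp, fps = cfg$fps)
        split <- split_regions(ncol(fs$frames[[1]]), cfg$boundary_col,
                               cfg$subject_side %||% "left")
        energy_series(fs, split, do.call(flow_params, cfg$flow %||% list()))
      } else {
        read_energy_csv(inp, fps = cfg$fps)
      }
      if (!is.null(cfg$start) || !is.null(cfg$end)) {
        de <- trim_energy(de, cfg$start, cfg$end)
      }
      fps <- energy_fps(de)
      cc <- cross_correlation(de, max_lag = an$max_lag %||% 15)
      spec <- power_spectrum(de)
      met <- do.call(dyad_metrics, c(list(energy = de), an))
      meta <- list(source = inp, config_hash = cfg_hash, seed = seed)
      write_energy_csv(de, file.path(cfg$out_dir, paste0(stem, "_energy.csv")), meta)
      utils::write.csv(as.data.frame(cc),
                       file.path(cfg$out_dir, paste0(stem, "_crosscorr.csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(spec),
                       file.path(cfg$out_dir, paste0(stem, "_spectrum.csv")),
                       row.names = FALSE)
      jsonlite::write_json(c(as.list(met), meta),
                           file.path(cfg$out_dir, paste0(stem, "_metrics.json")),
                           auto_unbox = TRUE, digits = NA)
      run_log(cfg$out_dir, "analyzed %s: %d samples at %g fps", inp, nrow(de), fps)
      dplyr::bind_cols(tibble(dyad_id = stem), met)
    }, error = function(e) {
      run_log(cfg$out_dir, "FAILED %s: %s", inp, conditionMessage(e))
      NULL
    })
    results[[stem]] <- res
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop_input("all inputs failed to analyze")
  invisible(dplyr::bind_rows(results[ok]))
}

#' Group-level cohort analysis from a metrics table
#'
#' Reads a cohort metrics CSV (columns `dyad_id`, `x` or `c0`, `y` or
#' `com_s`, `jitter_subject`, `jitter_actor`, `dominance_ratio`, `label`),
#' runs the Mann-Whitney comparisons and the bootstrap classifier, and
#' writes a JSON report.
#'
#' @param metrics_path CSV path (or a data frame).
#' @param out_path output JSON path (`NULL` = no file).
#' @param n_boot,seed,oob passed to [cohort_report()].
#' @return The [cohort_report()] object, invisibly.
#' @export
run_cohort <- function(metrics_path, out_path = NULL, n_boot = 1000L,
                       seed = 1L, oob = TRUE) {
  metrics <- if (is.data.frame(metrics_path)) metrics_path
  else {
    if (!file.exists(metrics_path)) stop_input(sprintf("'%s' not found", metrics_path))
    utils::read.csv(metrics_path)
  }
  nm <- names(metrics)
  if ("x" %in% nm && !"c0" %in% nm) names(metrics)[nm == "x"] <- "c0"
  nm <- names(metrics)
  if ("y" %in% nm && !"com_s" %in% nm) names(metrics)[nm == "y"] <- "com_s"
  if (!"label" %in% names(metrics)) stop_config("metrics table lacks a `label` column")
  report <- cohort_report(as_tibble(metrics), n_boot = n_boot, seed = seed, oob = oob)
  if (!is.null(out_path)) {
    jsonlite::write_json(report_as_list(report), out_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(report)
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` dyads from a scenario preset and writes each as an energy
#' CSV with the generating ground truth in its JSON sidecar.
#'
#' @param out_dir output directory.
#' @param preset `"A"` or `"B"`, or a [dyad_sim_params()] record.
#' @param n number of dyads.
#' @param seed integer seed.
#' @param ... preset overrides passed to [scenario_preset()].
#' @return Invisibly, the written CSV paths.
#' @export
run_simulate <- function(out_dir, preset = "B", n = 5L, seed = 1L, ...) {
  if (is.character(preset)) {
    if (!preset %in% c("A", "B")) stop_config(sprintf("unknown preset '%s'", preset))
    preset <- scenario_preset(preset, ...)
  }
  if (!inherits(preset, "dyad_sim_params")) stop_config("invalid preset")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dyad_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  paths <- character(n)
  for (i in seq_len(n)) {
    p <- unclass(preset)
    p$seed <- dyad_seeds[i]
    de <- gen_energy_dyad(do.call(dyad_sim_params, p))
    paths[i] <- file.path(out_dir, sprintf("dyad_%03d.csv", i))
    write_energy_csv(de, paths[i],
                     meta = list(ground_truth = attr(de, "ground_truth"),
                                 master_seed = seed))
  }
  run_log(out_dir, "simulate: wrote %d dyads (seed %d)", n, seed)
  invisible(paths)
}
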