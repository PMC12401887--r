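#' Pipeline configuration
#'
#' All tunable analysis parameters in one flat list: the analysis window,
#' treatment trim thresholds, coupling-slope windowing, the poikilothermy
#' band, the thermal-time-constant parameters and the bootstrap settings.
#'
#' @param window_start,window_end Analysis window (clock times).
#' @param trim_benign_c,trim_high_c Trim thresholds, deg C.
#' @param beta_window_minutes,beta_min_points,beta_min_air_range_c Coupling
#'   window width, minimum points and minimum air range per window.
#' @param beta_epsilon Poikilothermy band half-width around beta = 1.
#' @param tau A [tau_params()] object.
#' @param n_boot,ci_level Bootstrap resamples and confidence level.
#' @param pca_scale Standardize traits before PCA.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_start = "12:30", window_end = "15:00",
                            trim_benign_c = 16, trim_high_c = 31,
                            beta_window_minutes = 30, beta_min_points = 10,
                            beta_min_air_range_c = 0.2, beta_epsilon = 0.1,
                            tau = tau_params(), n_boot = 1000,
                            ci_level = 0.95, pca_scale = TRUE) {
  structure(list(
    window_start = window_start, window_end = window_end,
    thresholds = c(benign = trim_benign_c, high = trim_high_c),
    beta_window_minutes = beta_window_minutes,
    beta_min_points = beta_min_points,
    beta_min_air_range_c = beta_min_air_range_c,
    beta_epsilon = beta_epsilon,
    tau = tau, n_boot = n_boot, ci_level = ci_level, pca_scale = pca_scale
  ), class = "pipeline_config")
}

#' Read a written experiment back from disk
#'
#' Counterpart of [write_experiment()]: reads `metadata.csv`, `traits.csv`
#' and every logger CSV under `dir/logs/`.
#'
#' @param dir Directory written by [write_experiment()].
#' @return A list with `series`, `meta`, `traits` (same shapes as the
#'   corresponding [generate_experiment()] fields).
#' @export
read_experiment <- function(dir) {
  tabs <- read_tables(file.path(dir, "metadata.csv"),
    file.path(dir, "traits.csv"))
  files <- sort(list.files(file.path(dir, "logs"), pattern = "\\.csv$",
    full.names = TRUE))
  if (length(files) == 0L) stop("no logger CSVs under ", dir, call. = FALSE)
  series <- lapply(files, read_logger_csv)
  names(series) <- sub("\\.csv$", "", basename(files))
  list(series = series, meta = tabs$meta, traits = tabs$traits)
}

#' Run the full thermoregulation analysis pipeline
#'
#' Sequences every stage on one experiment: per-series preprocessing (window
#' clipping and cooler-trim), per-plant coupling metrics (delta-T, windowed
#' slopes, beta, thermoregulatory class), derived leaf traits and thermal
#' time constants, biome x treatment bootstrap summaries, fixed-effects
#' Type III ANOVA and Tukey-Kramer contrasts for delta-T and beta, and the
#' six-trait PCA. Deterministic given `seed`.
#'
#' @param experiment A [generate_experiment()] result, a [read_experiment()]
#'   result, or `NULL` to simulate with `sim_config`.
#' @param sim_config [synthetic_config()] used when `experiment` is `NULL`.
#' @param config A [pipeline_config()].
#' @param seed Integer seed used for simulation (when applicable) and for the
#'   bootstrap resampling.
#' @return A list of class `thermoreg_run` with tibbles `metrics`,
#'   `trim_reports`, `traits`, `summary_delta_t`, `summary_beta`,
#'   `anova_delta_t`, `anova_beta`, `contrasts_delta_t`, `contrasts_beta`,
#'   the `pca` ([pca_traits()] object) and a `manifest` list.
#' @export
run_pipeline <- function(experiment = NULL, sim_config = synthetic_config(),
                         config = pipeline_config(), seed = 1) {
  simulated <- is.null(experiment)
  if (simulated) experiment <- generate_experiment(sim_config, seed)

  metrics_rows <- vector("list", length(experiment$series))
  trim_rows <- vector("list", length(experiment$series))
  for (i in seq_along(experiment$series)) {
    s <- experiment$series[[i]]
    pre <- tryCatch(
      preprocess_series(s, config$window_start, config$window_end,
        config$thresholds),
      warning = function(w) stop("preprocess stage failed for plant ",
        attr(s, "plant_id"), " (", attr(s, "treatment"), "): ",
        conditionMessage(w), call. = FALSE)
    )
    metrics_rows[[i]] <- tryCatch(
      coupling_metrics(pre$series,
        window_minutes = config$beta_window_minutes,
        min_points = config$beta_min_points,
        min_air_range = config$beta_min_air_range_c,
        anchor = config$window_start,
        epsilon = config$beta_epsilon),
      error = function(e) stop("coupling stage failed for plant ",
        attr(s, "plant_id"), " (", attr(s, "treatment"), "): ",
        conditionMessage(e), call. = FALSE)
    )
    trim_rows[[i]] <- pre$report
  }
  # canonical row order so results do not depend on series input order
  metrics <- dplyr::bind_rows(metrics_rows)
  metrics <- metrics[order(metrics$plant_id, metrics$treatment), ]
  trim_reports <- dplyr::bind_rows(trim_rows)
  trim_reports <- trim_reports[order(trim_reports$plant_id, trim_reports$treatment), ]
  metrics <- dplyr::left_join(metrics,
    experiment$meta[, c("plant_id", "species", "biome")], by = "plant_id")

  traits <- derive_traits(experiment$traits)
  traits <- dplyr::left_join(traits,
    experiment$meta[, c("plant_id", "species", "biome")], by = "plant_id")
  traits$tau_s <- thermal_time_constant(
    lma = traits$lma_kg_m2, ldmc = traits$ldmc,
    width_m = traits$width_mm / 1000, params = config$tau
  )

  summary_delta_t <- group_summaries(metrics, "delta_t_mean",
    c("biome", "treatment"), config$n_boot, config$ci_level, seed = seed + 101)
  summary_beta <- group_summaries(metrics, "beta",
    c("biome", "treatment"), config$n_boot, config$ci_level, seed = seed + 211)

  anova_delta_t <- two_way_anova(metrics$delta_t_mean, metrics$treatment,
    metrics$biome)
  anova_beta <- two_way_anova(metrics$beta, metrics$treatment, metrics$biome)
  cell <- paste(metrics$biome, metrics$treatment, sep = ".")
  contrasts_delta_t <- pairwise_contrasts(metrics$delta_t_mean, cell)
  contrasts_beta <- pairwise_contrasts(metrics$beta, cell)

  pca <- pca_traits(traits, scale = config$pca_scale)

  manifest <- list(
    package_version = as.character(utils::packageVersion("thermoreg")),
    seed = seed,
    simulated = simulated,
    n_plants = nrow(experiment$meta),
    n_series = length(experiment$series),
    config = unclass(config)[setdiff(names(config), "tau")],
    tau_params = unclass(config$tau)
  )

  structure(list(
    metrics = metrics, trim_reports = trim_reports, traits = traits,
    summary_delta_t = summary_delta_t, summary_beta = summary_beta,
    anova_delta_t = anova_delta_t, anova_beta = anova_beta,
    contrasts_delta_t = contrasts_delta_t, contrasts_beta = contrasts_beta,
    pca = pca, manifest = manifest,
    coupling_truth = experiment$coupling_truth
  ), class = "thermoreg_run")
}

#' @export
print.thermoreg_run <- function(x, ...) {
  cat(sprintf("<thermoreg_run> %d plant x treatment metric rows\n",
    nrow(x$metrics)))
  cat("biome x treatment mean thermal offsets (degC):\n")
  print(as.data.frame(x$summary_delta_t), digits = 3)
  invisible(x)
}

#' Write a pipeline run to tidy CSVs plus a JSON manifest
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "thermoreg_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  wr(run$metrics, "metrics.csv")
  wr(run$trim_reports, "trim_reports.csv")
  wr(run$traits, "traits.csv")
  wr(run$summary_delta_t, "group_summaries_delta_t.csv")
  wr(run$summary_beta, "group_summaries_beta.csv")
  wr(run$anova_delta_t, "anova_delta_t.csv")
  wr(run$anova_beta, "anova_beta.csv")
  wr(run$contrasts_delta_t, "contrasts_delta_t.csv")
  wr(run$contrasts_beta, "contrasts_beta.csv")
  wr(as.data.frame(run$pca$loadings), "pca_loadings.csv")
  wr(run$pca$scores, "pca_scores.csv")
  wr(data.frame(component = seq_along(run$pca$variance_explained),
    variance_explained = run$pca$variance_explained), "pca_variance.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
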