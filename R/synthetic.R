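#' Climate presets for the three biomes of origin
#'
#' Long-term climate normals of the three seed-source biomes: mean annual
#' temperature (MAT), mean minimum temperature of the coldest month (MinT),
#' mean maximum temperature of the warmest month (MaxT), the printed annual
#' temperature range, and mean annual precipitation (MAP).
#'
#' @return A tibble with one row per biome: `biome`, `mat_c`, `min_t_c`,
#'   `max_t_c`, `t_range_printed_c`, `map_mm`.
#' @seealso [validate_t_range()]
#' @export
climate_presets <- function() {
  tibble::tibble(
    biome = c("alpine", "temperate", "desert"),
    mat_c = c(4.5, 16.5, 20.2),
    min_t_c = c(-5.2, 7.4, 4.5),
    max_t_c = c(16.5, 24.6, 36.0),
    t_range_printed_c = c(22.7, 17.2, 31.5),
    map_mm = c(1764, 1285, 332)
  )
}

#' Check internal consistency of the climate presets
#'
#' Recomputes the annual temperature range as MaxT - MinT and compares it to
#' the preset's printed range. The alpine preset carries a 1.0 deg C
#' discrepancy (printed 22.7 vs recomputed 21.7); the validator reports it and
#' deliberately does not resolve it.
#'
#' @param presets Output of [climate_presets()] (or a compatible tibble).
#' @param tol Absolute agreement tolerance in deg C.
#' @return The presets with `t_range_computed_c`, `discrepancy_c` and logical
#'   `consistent` columns added.
#' @export
validate_t_range <- function(presets = climate_presets(), tol = 1e-9) {
  presets$t_range_computed_c <- presets$max_t_c - presets$min_t_c
  presets$discrepancy_c <- presets$t_range_printed_c - presets$t_range_computed_c
  presets$consistent <- abs(presets$discrepancy_c) <= tol
  presets
}

#' Default configuration of the synthetic glasshouse experiment
#'
#' Bundles every generating parameter of the simulated experiment: the design
#' (5 species per biome, 5 replicate plants per species, two sequential
#' temperature treatments), the glasshouse air-profile model, the per-plant
#' leaf-air coupling presets (biome x treatment offset and slope
#' distributions), and the biome-clustered trait distributions.
#'
#' Air profiles fluctuate (AR(1)) around canopy means of 23.2 deg C (benign,
#' setpoint 25) and 35.7 deg C (high, setpoint 38); stochastic
#' evaporative-cooler dips are calibrated so that about 10 % of minutes fall
#' below the treatment's trim threshold (16 / 31 deg C). Offset presets
#' (mean, between-plant sd, deg C): temperate 1.99 (1.30) benign and
#' 0.60 (0.91) high; alpine 0.63 (1.01) and -1.25 (0.77); desert 0.50 (1.05)
#' and -1.66 (0.92). Slope presets are qualitative: all biomes couple at 0.85
#' under benign conditions; under high temperature, temperate 1.1 and
#' alpine/desert 1.0.
#'
#' @param n_species_per_biome,n_reps Design counts.
#' @param minutes Logged minutes per series (default 181 = 12:00-15:00).
#' @param start_clock First logged minute.
#' @param noise_sd Per-minute leaf-temperature noise sd, deg C.
#' @param slope_sd Between-plant sd of the coupling slope.
#' @param n_gsw_missing Number of plants whose stomatal conductance could not
#'   be measured (small leaves); their `gsw` field is missing, not zero.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species_per_biome = 5, n_reps = 5,
                             minutes = 181, start_clock = "12:00",
                             noise_sd = 0.3, slope_sd = 0.05,
                             n_gsw_missing = 18) {
  cfg <- list(
    design = list(
      biomes = .biomes, treatments = .treatments,
      n_species_per_biome = n_species_per_biome, n_reps = n_reps
    ),
    air = list(
      benign = list(canopy_mean = 23.2, setpoint = 25, ar_coef = 0.9,
        innovation_sd = 0.3, dip_rate = 0.02, dip_duration = 5, dip_depth = 9,
        dip_depth_sd = 0.5),
      high = list(canopy_mean = 35.7, setpoint = 38, ar_coef = 0.9,
        innovation_sd = 0.3, dip_rate = 0.02, dip_duration = 5, dip_depth = 6,
        dip_depth_sd = 0.5)
    ),
    minutes = minutes,
    start_clock = start_clock,
    coupling = tibble::tibble(
      biome = rep(.biomes, each = 2),
      treatment = rep(.treatments, 3),
      offset_mean = c(0.63, -1.25, 1.99, 0.60, 0.50, -1.66),
      offset_sd = c(1.01, 0.77, 1.30, 0.91, 1.05, 0.92),
      slope_mean = c(0.85, 1.0, 0.85, 1.1, 0.85, 1.0),
      slope_sd = slope_sd
    ),
    noise_sd = noise_sd,
    traits = list(
      # lognormal meanlog/sdlog for sizes and density, normal for LWC;
      # alpine: thick, water-rich, high-gsw leaves; temperate: thin, dense,
      # wide leaf-area range; desert: small, narrow leaves
      alpine = list(area = c(log(8), 0.4), width = c(log(15), 0.3),
        thickness = c(log(0.6), 0.25), lwc = c(0.75, 0.05),
        ld = c(log(0.25), 0.2), gsw = c(log(0.40), 0.3)),
      temperate = list(area = c(log(20), 0.7), width = c(log(25), 0.4),
        thickness = c(log(0.25), 0.2), lwc = c(0.55, 0.06),
        ld = c(log(0.45), 0.2), gsw = c(log(0.15), 0.35)),
      desert = list(area = c(log(3), 0.5), width = c(log(6), 0.35),
        thickness = c(log(0.4), 0.25), lwc = c(0.62, 0.05),
        ld = c(log(0.35), 0.2), gsw = c(log(0.30), 0.35))
    ),
    n_gsw_missing = n_gsw_missing
  )
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate a glasshouse air-temperature profile
#'
#' One treatment's canopy air record: a mean-reverting AR(1) fluctuation
#' around the canopy mean, plus stochastic evaporative-cooler dips (random
#' onsets, fixed duration, depth large enough to cross the treatment's trim
#' threshold). Under the default configuration about 10 % of minutes fall
#' below the threshold.
#'
#' @param treatment `"benign"` or `"high"`.
#' @param minutes Number of 1-min steps.
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of air temperatures, deg C.
#' @export
generate_air_profile <- function(treatment, minutes = 181,
                                 config = synthetic_config(), seed = NULL) {
  treatment <- match.arg(treatment, .treatments)
  if (!is.null(seed)) set.seed(seed)
  p <- config$air[[treatment]]
  # stationary AR(1) fluctuation
  sd_stat <- p$innovation_sd / sqrt(1 - p$ar_coef^2)
  x <- numeric(minutes)
  x[1] <- rnorm(1, 0, sd_stat)
  innov <- rnorm(minutes, 0, p$innovation_sd)
  for (t in seq_len(minutes)[-1]) x[t] <- p$ar_coef * x[t - 1] + innov[t]
  t_air <- p$canopy_mean + x
  # cooler dips: Bernoulli onsets, fixed duration, near-constant depth
  onsets <- which(runif(minutes) < p$dip_rate)
  for (o in onsets) {
    span <- o:min(minutes, o + p$dip_duration - 1)
    t_air[span] <- t_air[span] - rnorm(1, p$dip_depth, p$dip_depth_sd)
  }
  t_air
}

#' Simulate a leaf-temperature channel from an air profile
#'
#' Linear coupling model: `t_leaf = anchor + offset + slope * (t_air - anchor)
#' + noise`, with iid Gaussian per-minute noise. With the default anchor (the
#' series mean of `t_air`), the generating thermal offset is exactly `offset`
#' and the generating coupling slope exactly `slope`.
#'
#' @param t_air Numeric air-temperature series, deg C.
#' @param offset Generating thermal offset delta-T, deg C.
#' @param slope Generating coupling slope.
#' @param noise_sd Per-minute noise sd, deg C.
#' @param seed Optional integer seed.
#' @param anchor Temperature about which the coupling line pivots; the
#'   default is `mean(t_air)`. Passing the treatment's canopy operating mean
#'   instead defines the offset at operating temperature, independent of any
#'   cooler-dip minutes present in `t_air`.
#' @return Numeric leaf-temperature series.
#' @export
generate_leaf_series <- function(t_air, offset, slope, noise_sd = 0,
                                 seed = NULL, anchor = mean(t_air)) {
  stopifnot(all(is.finite(c(t_air, offset, slope, noise_sd, anchor))))
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) rnorm(length(t_air), 0, noise_sd) else 0
  anchor + offset + slope * (t_air - anchor) + eps
}

#' Simulate a complete glasshouse experiment
#'
#' Generates the full study: 15 species (5 per biome) x 5 replicate plants,
#' each logged under both the benign and the high-temperature treatment
#' (default 150 paired series of 181 minutes), a plant metadata table, and a
#' raw leaf-measurement table drawn from biome-clustered distributions, with
#' a subset of plants lacking stomatal conductance. Per-plant coupling
#' parameters are drawn from the biome x treatment presets in the
#' configuration: offset ~ Normal(offset_mean, offset_sd), slope ~
#' Normal(slope_mean, slope_sd). Leaf channels are anchored at the
#' treatment's canopy mean, so a plant's generating offset is its expected
#' delta-T at operating temperature.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the same seed reproduces the experiment exactly.
#' @return A list of class `synthetic_experiment`: `series` (named list of
#'   [paired_series], names `<plant_id>_<treatment>`), `meta`, `traits`,
#'   `coupling_truth` (the per-plant generating offset/slope, for parameter
#'   -recovery checks), `config`, `seed`.
#' @export
generate_experiment <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  d <- config$design
  start_min <- parse_clock_time(config$start_clock)
  times <- start_min + seq_len(config$minutes) - 1

  growth_forms <- c("shrub", "herb", "tree", "grass", "subshrub")
  meta_rows <- list()
  for (bi in seq_along(d$biomes)) {
    biome <- d$biomes[bi]
    for (sp in seq_len(d$n_species_per_biome)) {
      species <- sprintf("%s_sp%02d", biome, sp)
      for (rep in seq_len(d$n_reps)) {
        meta_rows[[length(meta_rows) + 1L]] <- tibble::tibble(
          plant_id = sprintf("%s_r%d", species, rep),
          species = species,
          biome = biome,
          family = sprintf("synthfam_%s%d", substr(biome, 1, 3), ((sp - 1) %% 3) + 1),
          growth_form = growth_forms[((sp - 1) %% length(growth_forms)) + 1]
        )
      }
    }
  }
  meta <- dplyr::bind_rows(meta_rows)

  # paired series and generating coupling parameters
  series <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(meta))) {
    for (tr in d$treatments) {
      preset <- config$coupling[config$coupling$biome == meta$biome[i] &
        config$coupling$treatment == tr, ]
      delta <- rnorm(1, preset$offset_mean, preset$offset_sd)
      slope <- rnorm(1, preset$slope_mean, preset$slope_sd)
      t_air <- generate_air_profile(tr, config$minutes, config)
      t_leaf <- generate_leaf_series(t_air, delta, slope, config$noise_sd,
        anchor = config$air[[tr]]$canopy_mean)
      key <- paste(meta$plant_id[i], tr, sep = "_")
      series[[key]] <- paired_series(meta$plant_id[i], tr, times, t_leaf, t_air)
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        plant_id = meta$plant_id[i], biome = meta$biome[i], treatment = tr,
        offset_true = delta, slope_true = slope
      )
    }
  }

  # biome-clustered raw leaf traits: draw area/width/thickness/LWC/LD/gsw,
  # back out wet and dry mass so the raw table satisfies its invariants
  traits_rows <- lapply(seq_len(nrow(meta)), function(i) {
    p <- config$traits[[meta$biome[i]]]
    area <- stats::rlnorm(1, p$area[1], p$area[2])
    width <- stats::rlnorm(1, p$width[1], p$width[2])
    thickness <- stats::rlnorm(1, p$thickness[1], p$thickness[2])
    lwc <- min(max(rnorm(1, p$lwc[1], p$lwc[2]), 0.05), 0.95)
    ld <- stats::rlnorm(1, p$ld[1], p$ld[2])
    gsw <- stats::rlnorm(1, p$gsw[1], p$gsw[2])
    dry_mg <- ld * area * (thickness / 10) * 1000 # g cm-3 * cm3 -> g -> mg
    tibble::tibble(
      plant_id = meta$plant_id[i],
      wet_mass_mg = dry_mg / (1 - lwc),
      dry_mass_mg = dry_mg,
      area_cm2 = area,
      thickness_mm = thickness,
      width_mm = width,
      gsw_mol_m2_s = gsw
    )
  })
  traits <- dplyr::bind_rows(traits_rows)
  if (config$n_gsw_missing > 0) {
    miss <- sample(traits$plant_id, config$n_gsw_missing)
    traits$gsw_mol_m2_s[traits$plant_id %in% miss] <- NA_real_
  }

  structure(
    list(series = series, meta = meta, traits = traits,
      coupling_truth = dplyr::bind_rows(truth_rows),
      config = config, seed = seed),
    class = "synthetic_experiment"
  )
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment> %d plants, %d paired series of %d min (seed %d)\n",
    nrow(x$meta), length(x$series), x$config$minutes, x$seed
  ))
  invisible(x)
}

#' Write a synthetic experiment to the three-table CSV layout
#'
#' Writes one logger CSV per plant x treatment (`<plant_id>_<treatment>.csv`
#' under `dir/logs/`) plus `metadata.csv` and `traits.csv`, the layout read
#' back by [read_logger_csv()] and [read_tables()].
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  logdir <- file.path(dir, "logs")
  dir.create(logdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(experiment$series)) {
    write_logger_csv(experiment$series[[key]],
      file.path(logdir, paste0(key, ".csv")))
  }
  write_tables(experiment$meta, experiment$traits,
    file.path(dir, "metadata.csv"), file.path(dir, "traits.csv"))
  invisible(dir)
}
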