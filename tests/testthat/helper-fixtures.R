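# Shared fixtures, built in code.

# A small valid paired series inside the default analysis window.
make_series <- function(plant_id = "p1", treatment = "benign",
                        time_min = 750:760,
                        t_air = seq(22, 24, length.out = length(time_min)),
                        t_leaf = t_air + 1) {
  paired_series(plant_id, treatment, time_min, t_leaf, t_air)
}

# A full-window series (12:30-15:00) with an exact linear leaf-air relation
# t_leaf = a + b * t_air, safely above both trim thresholds.
make_linear_series <- function(plant_id, treatment, a, b) {
  tm <- 750:900
  t_air <- 32 + 1.5 * sin(seq(0, 3 * pi, length.out = length(tm)))
  paired_series(plant_id, treatment, tm, a + b * t_air, t_air)
}

# A tiny hand-built experiment: 2 biomes x 2 plants x 2 treatments with
# exactly collinear series and simple trait values.
make_hand_experiment <- function() {
  plants <- tibble::tibble(
    plant_id = c("alp_a", "alp_b", "des_a", "des_b"),
    species = c("alpine_sp01", "alpine_sp01", "desert_sp01", "desert_sp01"),
    biome = c("alpine", "alpine", "desert", "desert"),
    family = "synthfam_x",
    growth_form = "shrub"
  )
  # per plant x treatment: intercept a and slope b of t_leaf = a + b * t_air
  pars <- expand.grid(plant_id = plants$plant_id, treatment = c("benign", "high"),
    stringsAsFactors = FALSE)
  pars$a <- c(2, 1, -3, -2, 4, 3, -6, -5)
  pars$b <- c(0.9, 0.95, 1.0, 1.05, 1.1, 1.0, 0.9, 1.0)
  series <- list()
  for (i in seq_len(nrow(pars))) {
    key <- paste(pars$plant_id[i], pars$treatment[i], sep = "_")
    series[[key]] <- make_linear_series(pars$plant_id[i], pars$treatment[i],
      pars$a[i], pars$b[i])
  }
  traits <- tibble::tibble(
    plant_id = plants$plant_id,
    wet_mass_mg = c(200, 240, 90, 110),
    dry_mass_mg = c(80, 100, 50, 60),
    area_cm2 = c(10, 12, 3, 4),
    thickness_mm = c(0.5, 0.6, 0.35, 0.4),
    width_mm = c(14, 16, 5, 6),
    gsw_mol_m2_s = c(0.4, 0.45, 0.25, 0.3)
  )
  list(series = series, meta = plants, traits = traits, pars = pars)
}
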