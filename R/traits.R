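#' Derive structural leaf traits from raw measurements
#'
#' Fills in the four derived structural traits from a raw leaf-measurement
#' table:
#' * leaf water content, `lwc = (wet - dry) / wet` (dimensionless fraction),
#' * leaf dry matter content, `ldmc = dry / wet` (kg kg-1, so `lwc + ldmc = 1`),
#' * leaf mass per area, `lma = dry / area` (kg m-2),
#' * leaf tissue density, `ld = dry / (area x thickness)` (g cm-3).
#'
#' Masses are measured in mg, area in cm2 and thickness in mm; unit
#' conversions to the trait units above are applied internally.
#'
#' @param traits Tibble with columns `plant_id`, `wet_mass_mg`, `dry_mass_mg`,
#'   `area_cm2`, `thickness_mm`, `width_mm` and optionally `gsw_mol_m2_s`.
#' @return The input with columns `lwc`, `ldmc`, `lma_kg_m2`, `ld_g_cm3` added.
#' @examples
#' derive_traits(tibble::tibble(plant_id = "p1", wet_mass_mg = 200,
#'   dry_mass_mg = 100, area_cm2 = 10, thickness_mm = 0.5, width_mm = 12))
#' @export
derive_traits <- function(traits) {
  need <- c("wet_mass_mg", "dry_mass_mg", "area_cm2", "thickness_mm", "width_mm")
  stopifnot(all(need %in% names(traits)))
  with_vals <- traits[, need]
  if (any(!is.na(with_vals) & with_vals <= 0)) {
    stop("raw leaf measurements must all be positive", call. = FALSE)
  }
  bad <- !is.na(traits$dry_mass_mg) & !is.na(traits$wet_mass_mg) &
    traits$dry_mass_mg > traits$wet_mass_mg
  if (any(bad)) {
    stop("dry mass exceeds wet mass for plant(s): ",
      paste(traits$plant_id[bad], collapse = ", "), call. = FALSE)
  }
  traits$lwc <- (traits$wet_mass_mg - traits$dry_mass_mg) / traits$wet_mass_mg
  traits$ldmc <- traits$dry_mass_mg / traits$wet_mass_mg
  # mg/cm2 -> kg/m2: (mg/1e6) / (cm2/1e4) = mg / (100 * cm2)
  traits$lma_kg_m2 <- traits$dry_mass_mg / (100 * traits$area_cm2)
  # (mg/1000 g) / (cm2 * mm/10 cm) = mg / (100 * cm2 * mm)
  traits$ld_g_cm3 <- traits$dry_mass_mg /
    (100 * traits$area_cm2 * traits$thickness_mm)
  traits
}

#' Principal components analysis of the six leaf traits
#'
#' Summarises covariation among the five passive traits (leaf area, width,
#' thickness, water content, density) and the active trait (stomatal
#' conductance, `gsw`). Plants with any missing trait (typically `gsw` on
#' small-leaved species) are excluded first. Traits are z-score standardized
#' by default (they mix cm2, mm and mol m-2 s-1), i.e. the decomposition is of
#' the trait correlation matrix. Each loading vector is oriented so its
#' largest-magnitude element is positive, a deterministic sign convention.
#'
#' @param data Tibble containing the columns named in `trait_cols`.
#' @param trait_cols Character vector of trait columns to decompose.
#' @param scale Standardize traits before decomposition (default `TRUE`).
#' @return An object of class `trait_pca`: a list with `loadings` (traits x
#'   components, unit-norm columns), `variance_explained` (% per component,
#'   summing to 100), `contributions` (% per trait per component, each column
#'   summing to 100), `scores` (plants x components, with `plant_id` if
#'   present), `n` and `trait_cols`.
#' @export
pca_traits <- function(data,
                       trait_cols = c("area_cm2", "width_mm", "thickness_mm",
                                      "lwc", "ld_g_cm3", "gsw_mol_m2_s"),
                       scale = TRUE) {
  stopifnot(all(trait_cols %in% names(data)))
  x <- as.data.frame(data[, trait_cols])
  complete <- complete.cases(x)
  if (sum(!complete) > 0L) {
    message(sprintf("pca_traits: excluding %d plant(s) with incomplete traits",
      sum(!complete)))
  }
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3L) {
    stop("need at least 3 complete records for a trait PCA", call. = FALSE)
  }
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0)) {
    stop("zero-variance trait(s): ",
      paste(trait_cols[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- prcomp(x, center = TRUE, scale. = scale)
  load <- fit$rotation
  scores <- fit$x
  # orient each component so its largest-magnitude loading is positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varexp <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  contrib <- sweep(load^2, 2, colSums(load^2), "/") * 100
  scores_tbl <- tibble::as_tibble(as.data.frame(scores))
  if ("plant_id" %in% names(data)) {
    scores_tbl <- dplyr::bind_cols(
      tibble::tibble(plant_id = data$plant_id[complete]), scores_tbl
    )
  }
  structure(
    list(loadings = load, variance_explained = varexp,
      contributions = contrib, scores = scores_tbl,
      n = nrow(x), trait_cols = trait_cols, scaled = scale),
    class = "trait_pca"
  )
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("<trait_pca> %d plants, %d traits\n", x$n, length(x$trait_cols)))
  ve <- x$variance_explained
  cat(sprintf("PC1 %.1f%%, PC2 %.1f%% (first two axes: %.1f%%)\n",
    ve[1], ve[2], ve[1] + ve[2]))
  invisible(x)
}
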