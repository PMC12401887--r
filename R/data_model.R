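#' Construct a paired leaf/air temperature series
#'
#' A `paired_series` holds one plant's 1-min paired thermocouple record for one
#' temperature treatment: clock times plus leaf (`t_leaf`) and canopy air
#' (`t_air`) temperature in degrees Celsius. It is the unit of input to the
#' preprocessing and coupling stages.
#'
#' @param plant_id Single character plant identifier.
#' @param treatment `"benign"` or `"high"`.
#' @param time_min Numeric minutes since midnight (e.g. `12:30` is 750).
#'   Must be strictly increasing.
#' @param t_leaf,t_air Numeric temperatures in deg C, same length as
#'   `time_min`, finite and within the sanity bounds \[-20, 70\] deg C.
#'
#' @return A tibble of class `paired_series` with columns `time_min`,
#'   `t_leaf`, `t_air` and attributes `plant_id`, `treatment`.
#' @examples
#' ps <- paired_series("p1", "benign", 750:752, c(24, 24.5, 25), c(23, 23.5, 24))
#' ps
#' @export
paired_series <- function(plant_id, treatment, time_min, t_leaf, t_air) {
  stopifnot(is.character(plant_id), length(plant_id) == 1L)
  treatment <- match.arg(treatment, .treatments)
  time_min <- as.numeric(time_min)
  t_leaf <- as.numeric(t_leaf)
  t_air <- as.numeric(t_air)
  n <- length(time_min)
  if (length(t_leaf) != n || length(t_air) != n) {
    stop("t_leaf and t_air must have the same length as time_min", call. = FALSE)
  }
  if (n > 1L && any(diff(time_min) <= 0)) {
    stop("timestamps must be strictly increasing for plant ", plant_id, call. = FALSE)
  }
  temps <- c(t_leaf, t_air)
  if (n > 0L && (any(!is.finite(temps)) || any(temps < -20) || any(temps > 70))) {
    stop("temperatures must be finite and within [-20, 70] degC for plant ",
      plant_id, call. = FALSE)
  }
  out <- tibble::tibble(time_min = time_min, t_leaf = t_leaf, t_air = t_air)
  attr(out, "plant_id") <- plant_id
  attr(out, "treatment") <- treatment
  class(out) <- c("paired_series", class(out))
  out
}

# Rebuild a paired_series from a filtered tibble, keeping identity attributes.
# Used by row-filter operations (window clipping, threshold trimming) so that
# an empty result is representable without re-triggering validation errors.
ps_rebuild <- function(template, rows) {
  out <- tibble::tibble(
    time_min = rows$time_min, t_leaf = rows$t_leaf, t_air = rows$t_air
  )
  attr(out, "plant_id") <- attr(template, "plant_id")
  attr(out, "treatment") <- attr(template, "treatment")
  class(out) <- c("paired_series", class(out))
  out
}

#' @export
print.paired_series <- function(x, ...) {
  cat(sprintf(
    "<paired_series> plant %s, %s treatment, %d minutes\n",
    attr(x, "plant_id"), attr(x, "treatment"), nrow(x)
  ))
  NextMethod()
}

#' Parse clock timestamps
#'
#' Accepts `HH:MM`, `HH:MM:SS`, or ISO-8601 date-times (`YYYY-MM-DDTHH:MM[:SS]`,
#' with `T` or a space); the date part, when present, is ignored — analysis
#' windows are clock-time based. Unparseable entries return `NA`.
#'
#' @param x Character vector of timestamps.
#' @return Numeric minutes since midnight (fractional for seconds).
#' @examples
#' parse_clock_time(c("12:30", "2022-01-15T14:05:30", "bad"))
#' @export
parse_clock_time <- function(x) {
  x <- as.character(x)
  # strip ISO date prefix
  tm <- sub("^\\d{4}-\\d{2}-\\d{2}[T ]", "", x)
  ok <- grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", tm)
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    parts <- strsplit(tm[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      v <- as.numeric(p)
      if (v[1] > 23 || v[2] > 59) return(NA_real_)
      v[1] * 60 + v[2] + if (length(v) == 3) v[3] / 60 else 0
    }, numeric(1))
  }
  out
}

format_clock_time <- function(time_min) {
  h <- time_min %/% 60
  m <- floor(time_min %% 60)
  s <- round((time_min - floor(time_min)) * 60)
  ifelse(s > 0,
    sprintf("%02d:%02d:%02d", h, m, s),
    sprintf("%02d:%02d", h, m)
  )
}

#' Read a logger CSV into a paired series
#'
#' Reads a thermocouple-logger export with columns `timestamp`, `t_leaf_c`,
#' `t_air_c`. Rows with unparseable timestamps or non-numeric/missing
#' temperatures are dropped with a message reporting the count; they are never
#' silently discarded.
#'
#' @param path Path to the CSV file.
#' @param plant_id,treatment Series identity. When `NULL`, both are taken from
#'   a file name of the form `<plant_id>_<treatment>.csv`.
#' @return A [paired_series].
#' @seealso [write_logger_csv()]
#' @export
read_logger_csv <- function(path, plant_id = NULL, treatment = NULL) {
  if (!file.exists(path)) stop("logger file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("logger file is empty: ", path, call. = FALSE)
  need <- c("timestamp", "t_leaf_c", "t_air_c")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("logger file ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(plant_id) || is.null(treatment)) {
    stem <- sub("\\.csv$", "", basename(path))
    m <- regmatches(stem, regexec("^(.*)_(benign|high)$", stem))[[1]]
    if (length(m) != 3L) {
      stop("cannot infer plant_id/treatment from file name '", basename(path),
        "'; pass them explicitly", call. = FALSE)
    }
    if (is.null(plant_id)) plant_id <- m[2]
    if (is.null(treatment)) treatment <- m[3]
  }
  tmin <- parse_clock_time(df$timestamp)
  tl <- suppressWarnings(as.numeric(df$t_leaf_c))
  ta <- suppressWarnings(as.numeric(df$t_air_c))
  keep <- !is.na(tmin) & !is.na(tl) & !is.na(ta)
  n_bad <- sum(!keep)
  if (n_bad > 0L) {
    message(sprintf("read_logger_csv: dropped %d malformed row(s) from %s",
      n_bad, basename(path)))
  }
  paired_series(plant_id, treatment, tmin[keep], tl[keep], ta[keep])
}

#' Write a paired series to a logger CSV
#'
#' @param series A [paired_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  stopifnot(inherits(series, "paired_series"))
  df <- data.frame(
    timestamp = format_clock_time(series$time_min),
    t_leaf_c = fmt_num(series$t_leaf),
    t_air_c = fmt_num(series$t_air)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision numeric formatting so write/read round trips are exact
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Read and join the plant metadata and raw leaf trait tables
#'
#' Metadata CSV columns: `plant_id,species,biome,family,growth_form`. Trait CSV
#' columns: `plant_id,wet_mass_mg,dry_mass_mg,area_cm2,thickness_mm,width_mm,
#' gsw_mol_m2_s` (empty `gsw` field means stomatal conductance could not be
#' measured; such plants are retained and flagged, never imputed).
#'
#' @param meta_path,traits_path Paths to the two CSVs.
#' @return A list with tibbles `meta`, `traits`, and `plants` (the left join of
#'   meta onto traits, with a logical `gsw_missing` flag).
#' @export
read_tables <- function(meta_path, traits_path) {
  meta <- tibble::as_tibble(read.csv(meta_path, stringsAsFactors = FALSE))
  traits <- tibble::as_tibble(read.csv(traits_path, stringsAsFactors = FALSE))
  need_meta <- c("plant_id", "species", "biome", "family", "growth_form")
  need_traits <- c("plant_id", "wet_mass_mg", "dry_mass_mg", "area_cm2",
    "thickness_mm", "width_mm", "gsw_mol_m2_s")
  if (!all(need_meta %in% names(meta))) {
    stop("metadata table lacks column(s): ",
      paste(setdiff(need_meta, names(meta)), collapse = ", "), call. = FALSE)
  }
  if (!all(need_traits %in% names(traits))) {
    stop("trait table lacks column(s): ",
      paste(setdiff(need_traits, names(traits)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(meta$plant_id)) {
    stop("duplicate plant_id in metadata: ",
      paste(unique(meta$plant_id[duplicated(meta$plant_id)]), collapse = ", "),
      call. = FALSE)
  }
  if (anyDuplicated(traits$plant_id)) {
    stop("duplicate plant_id in trait table", call. = FALSE)
  }
  bad_biome <- setdiff(unique(meta$biome), .biomes)
  if (length(bad_biome) > 0L) {
    stop("unknown biome label(s): ", paste(bad_biome, collapse = ", "),
      call. = FALSE)
  }
  orphans <- setdiff(meta$plant_id, traits$plant_id)
  if (length(orphans) > 0L) {
    warning("plant(s) in metadata without trait measurements: ",
      paste(orphans, collapse = ", "), call. = FALSE)
  }
  plants <- dplyr::left_join(meta, traits, by = "plant_id")
  plants$gsw_missing <- is.na(plants$gsw_mol_m2_s)
  list(meta = meta, traits = traits, plants = plants)
}

#' Write the metadata and trait tables
#'
#' Counterparts of [read_tables()]; missing `gsw` is written as an empty field.
#'
#' @param meta,traits Tibbles with the documented columns.
#' @param meta_path,traits_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_tables <- function(meta, traits, meta_path, traits_path) {
  traits <- as.data.frame(traits)
  for (j in seq_along(traits)) {
    if (is.numeric(traits[[j]])) traits[[j]] <- fmt_num(traits[[j]])
  }
  write.csv(meta, meta_path, row.names = FALSE, quote = FALSE, na = "")
  write.csv(traits, traits_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(meta_path, traits_path))
}
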