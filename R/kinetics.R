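#' @keywords internal
#' @noRd
obs_columns <- c("individual_id", "species", "setting", "time_days",
                 "kind", "value", "replicate")

#' Validate a table of wound observations
#'
#' Checks the longitudinal observation schema: one row per reading of one
#' wound at one time point, either a width (mm) or an area (mm²), with a
#' replicate index for duplicate measurements of the same photograph.
#'
#' @param observations Data frame with columns `individual_id`, `species`,
#'   `setting` (`"experimental"` or `"natural"`), `time_days`, `kind`
#'   (`"width"` or `"area"`), `value`, `replicate`, and optionally `unit`
#'   (`"mm"`, `"cm"`, `"mm2"`, `"cm2"`; defaults to mm / mm² by kind).
#' @return A tibble in canonical units (mm, mm²) with a `unit` column.
#' @export
validate_observations <- function(observations) {
  obs <- as_tibble(observations)
  missing_cols <- setdiff(obs_columns, names(obs))
  if (length(missing_cols)) {
    stop_user("observations are missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  }
  if (nrow(obs) == 0) {
    stop_user("observations table is empty")
  }
  if (!all(obs$kind %in% c("width", "area"))) {
    bad <- which(!obs$kind %in% c("width", "area"))
    stop_user("unknown measurement kind in row(s) %s (must be 'width' or 'area')",
              paste(head(bad, 5), collapse = ", "))
  }
  if (!is.numeric(obs$value) || any(!is.finite(obs$value)) || any(obs$value < 0)) {
    stop_user("measurement values must be finite and >= 0")
  }
  if (!is.numeric(obs$time_days) || any(!is.finite(obs$time_days)) || any(obs$time_days < 0)) {
    stop_user("time_days must be finite and >= 0")
  }
  if (any(obs$replicate < 1) || any(obs$replicate != round(obs$replicate))) {
    stop_user("replicate must be a positive integer index")
  }
  if (!"unit" %in% names(obs)) {
    obs$unit <- NA_character_
  }
  # rows without an explicit unit are taken to be in canonical units already
  obs$unit <- dplyr::coalesce(obs$unit, ifelse(obs$kind == "width", "mm", "mm2"))
  convert_units(obs)
}

# Explicit unit conversion to internal mm / mm^2; never silent.
convert_units <- function(obs) {
  known <- c("mm", "cm", "mm2", "cm2")
  if (!all(obs$unit %in% known)) {
    stop_user("unknown unit(s): %s", paste(setdiff(unique(obs$unit), known), collapse = ", "))
  }
  width_units <- c("mm", "cm")
  mismatch <- (obs$kind == "width" & !obs$unit %in% width_units) |
    (obs$kind == "area" & obs$unit %in% width_units)
  if (any(mismatch)) {
    stop_user("unit does not match measurement kind in row(s) %s",
              paste(head(which(mismatch), 5), collapse = ", "))
  }
  factor <- c(mm = 1, cm = 10, mm2 = 1, cm2 = 100)[obs$unit]
  obs$value <- obs$value * unname(factor)
  obs$unit <- ifelse(obs$kind == "width", "mm", "mm2")
  obs
}

#' Reference size of a wound trajectory
#'
#' The reference is the size at the first observation (`t = 0`) when that is
#' the largest size seen; when an early inflammatory response enlarges the
#' wound after `t = 0`, the maximum observed size is used instead. Both
#' branches reduce to the trajectory maximum.
#'
#' @param sizes Numeric vector of wound sizes (mm) for one wound, one
#'   replicate, in time order.
#' @return Reference size in mm.
#' @export
#' @examples
#' reference_size(c(40, 36, 30, 22))  # 40, the t = 0 size
#' reference_size(c(40, 42, 38))      # 42, the inflammation-phase maximum
reference_size <- function(sizes) {
  if (length(sizes) == 0) {
    stop_user("cannot take the reference size of an empty trajectory")
  }
  if (!is.numeric(sizes) || any(!is.finite(sizes))) {
    stop_user("trajectory sizes must be finite numeric")
  }
  max(sizes)
}

#' Convert natural (area-recorded) wounds to width trajectories
#'
#' Applies the positive-root quadratic inversion [width_from_area()] pointwise
#' to every `area` observation, and re-indexes each such trajectory so that
#' its first photographed day becomes `t = 0` (natural wounds are first seen
#' some time after injury; the calendar day of injury is not needed).
#' Width observations pass through unchanged.
#'
#' @param observations Observation table (see [validate_observations()]).
#' @param relation An [ellipse_relation()].
#' @param quadratic Root form passed to [width_from_area()].
#' @return Observation tibble in which every row is a width in mm.
#' @export
natural_wound_to_widths <- function(observations, relation,
                                    quadratic = c("derived", "printed")) {
  quadratic <- match.arg(quadratic)
  obs <- validate_observations(observations)
  is_area <- obs$kind == "area"
  if (!any(is_area)) {
    return(obs)
  }
  area_ids <- unique(obs$individual_id[is_area])
  mixed <- obs$individual_id %in% area_ids & !is_area
  if (any(mixed)) {
    stop_user("individual(s) %s mix width and area records; convert or split them first",
              paste(unique(obs$individual_id[mixed]), collapse = ", "))
  }
  converted <- obs |>
    dplyr::filter(is_area) |>
    dplyr::group_by(.data$individual_id, .data$replicate) |>
    dplyr::mutate(time_days = .data$time_days - min(.data$time_days)) |>
    dplyr::ungroup() |>
    dplyr::mutate(value = width_from_area(.data$value, relation, quadratic = quadratic),
                  kind = "width", unit = "mm")
  dplyr::bind_rows(obs[!is_area, , drop = FALSE], converted) |>
    dplyr::arrange(.data$individual_id, .data$replicate, .data$time_days)
}

#' Healing distances from wound observations
#'
#' The mixed model's response. For each wound and replicate, the healing
#' distance at time `t` is the reference size minus the observed size, so it
#' runs from 0 at baseline to the reference size at complete closure. When an
#' early inflammatory enlargement makes the maximum occur after `t = 0`, the
#' maximum is the reference and the `t = 0` distance is positive; distances
#' are clipped below at 0 either way.
#'
#' @param observations Observation table. Area records are converted through
#'   `relation` first (an error if areas are present and `relation` is NULL).
#' @param relation Optional [ellipse_relation()] for area records.
#' @param replicates `"keep"` (default; duplicate measurements enter the model
#'   as repeated measures) or `"average"`.
#' @param clip Clip distances below at 0 (default TRUE). With the
#'   maximum-size reference rule no negative distance can arise, so this is
#'   exposed only for verification.
#' @param quadratic Root form passed to [width_from_area()] for area records.
#' @return Tibble of healing records: `individual_id`, `species`, `setting`,
#'   `time_days`, `healing_distance_mm`, `replicate`.
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   individual_id = "b1", species = "baboon", setting = "experimental",
#'   time_days = c(0, 3, 6, 9), kind = "width", value = c(40, 36, 30, 22),
#'   replicate = 1
#' )
#' healing_distances(obs)
healing_distances <- function(observations, relation = NULL,
                              replicates = c("keep", "average"), clip = TRUE,
                              quadratic = c("derived", "printed")) {
  replicates <- match.arg(replicates)
  quadratic <- match.arg(quadratic)
  obs <- validate_observations(observations)
  if (any(obs$kind == "area")) {
    if (is.null(relation)) {
      stop_user("area records present; supply `relation` so widths can be recovered first")
    }
    obs <- natural_wound_to_widths(obs, relation, quadratic = quadratic)
  }
  records <- obs |>
    dplyr::group_by(.data$individual_id, .data$species, .data$setting, .data$replicate) |>
    dplyr::mutate(healing_distance_mm = reference_size(.data$value) - .data$value) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(c("individual_id", "species", "setting",
                                  "time_days", "healing_distance_mm", "replicate"))) |>
    dplyr::arrange(.data$individual_id, .data$replicate, .data$time_days)
  if (clip) {
    records$healing_distance_mm <- pmax(records$healing_distance_mm, 0)
  }
  merge_replicates(records, mode = replicates)
}

#' Merge duplicate measurements
#'
#' Each wound photograph is typically measured twice, independently. By
#' default both readings are kept and absorbed by the model as repeated
#' residual draws; `mode = "average"` collapses them to their mean per
#' (individual, time) for sensitivity checks.
#'
#' @param records Healing-record tibble (see [healing_distances()]).
#' @param mode `"keep"` or `"average"`.
#' @return Healing-record tibble.
#' @export
merge_replicates <- function(records, mode = c("keep", "average")) {
  mode <- match.arg(mode)
  if (mode == "keep") {
    return(as_tibble(records))
  }
  records |>
    dplyr::group_by(.data$individual_id, .data$species, .data$setting, .data$time_days) |>
    dplyr::summarise(healing_distance_mm = mean(.data$healing_distance_mm),
                     .groups = "drop") |>
    dplyr::mutate(replicate = 1L) |>
    dplyr::select(dplyr::all_of(c("individual_id", "species", "setting",
                                  "time_days", "healing_distance_mm", "replicate"))) |>
    dplyr::arrange(.data$individual_id, .data$time_days)
}

#' Read / write observation and healing-record CSV files
#'
#' `read_observations()` reads the `observations.csv` schema
#' (`individual_id, species, setting, time_days, kind, value, unit,
#' replicate`), converting any cm / cm² values to mm / mm².
#' `write_healing_records()` and `read_healing_records()` round-trip the
#' `healing_records.csv` schema (`individual_id, species, setting, time_days,
#' healing_distance_mm, replicate`) losslessly.
#'
#' @param path CSV file path.
#' @return A tibble (readers); `path`, invisibly (writers).
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    stop_user("input file does not exist: %s", path)
  }
  obs <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           individual_id = readr::col_character(),
                           species = readr::col_character(),
                           setting = readr::col_character(),
                           time_days = readr::col_double(),
                           kind = readr::col_character(),
                           value = readr::col_double(),
                           replicate = readr::col_integer(),
                           .default = readr::col_character()
                         ))
  validate_observations(obs)
}

#' @rdname read_observations
#' @param observations Observation tibble.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(as_tibble(observations), path)
  invisible(path)
}

#' @rdname read_observations
#' @param records Healing-record tibble.
#' @export
write_healing_records <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' @rdname read_observations
#' @export
read_healing_records <- function(path) {
  if (!file.exists(path)) {
    stop_user("input file does not exist: %s", path)
  }
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    individual_id = readr::col_character(),
                    species = readr::col_character(),
                    setting = readr::col_character(),
                    time_days = readr::col_double(),
                    healing_distance_mm = readr::col_double(),
                    replicate = readr::col_integer()
                  ))
}

#' Plot healing records
#'
#' Healing distance against time, one line per individual and replicate,
#' coloured by species.
#'
#' @param records Healing-record tibble.
#' @return A ggplot object.
#' @export
plot_healing_records <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$time_days, y = .data$healing_distance_mm,
                               colour = .data$species,
                               group = interaction(.data$individual_id, .data$replicate))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "time (days)", y = "healing distance (mm)", colour = "species") +
    ggplot2::theme_minimal()
}
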