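# Delimited-text table readers and writers. Files are comma-separated UTF-8
# with "." decimals; measurement columns carry explicit unit columns
# (volume_unit, weight_unit, area_unit, length_unit) and are converted to SI
# at this boundary. All in-memory tables are SI.

UNIT_FACTORS <- list(
  volume = c(m3 = 1, cm3 = 1e-6, mm3 = 1e-9, L = 1e-3),
  weight = c(kg = 1, g = 1e-3, mg = 1e-6),
  area = c(m2 = 1, cm2 = 1e-4, mm2 = 1e-6),
  length = c(m = 1, cm = 1e-2, mm = 1e-3)
)

convert_unit <- function(x, unit, kind, default) {
  unit <- ifelse(is.na(unit) | unit == "", default, unit)
  fac <- UNIT_FACTORS[[kind]][unit]
  if (anyNA(fac)) {
    abort_validity(sprintf(
      "unknown %s unit(s): %s", kind,
      paste(unique(unit[is.na(fac)]), collapse = ", ")
    ))
  }
  x * unname(fac)
}

# character -> numeric with row-level error collection
parse_numeric_cols <- function(data, cols) {
  problems <- character(0)
  for (col in intersect(cols, names(data))) {
    raw <- data[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "column %s: non-numeric value(s) in data row(s) %s",
        col, paste(bad, collapse = ", ")
      ))
    }
    val[!is.na(raw) & raw == ""] <- NA_real_
    data[[col]] <- val
  }
  if (length(problems) > 0) {
    abort_validity(paste(problems, collapse = "; "))
  }
  data
}

#' Read a particle trait table
#'
#' Reads a delimited trait file, converts measurement columns to SI using the
#' explicit unit columns (defaulting to SI when absent) and validates the
#' schema. Derived columns (`rho`, `d_n`, `s_f`, `route`, `buoyant`) are
#' passed through when present; otherwise call [derive_traits()] next.
#'
#' @param path File path. Required columns: `specimen_id`, `morphology`,
#'   `volume`, `wet_weight`; route columns (`projection_area`,
#'   `branch_width`, `axis_a/b/c`) as the morphologies demand; optional unit
#'   columns `volume_unit` (m3/cm3/mm3/L), `weight_unit` (kg/g/mg),
#'   `area_unit` (m2/cm2/mm2), `length_unit` (m/cm/mm).
#' @return An SI trait tibble.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) abort_validity(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(data) == 0) abort_validity(sprintf("empty table: %s", path))
  required <- c("specimen_id", "morphology", "volume", "wet_weight")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0(
      "trait table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  num_cols <- c("volume", "wet_weight", "projection_area", "branch_width",
                "axis_a", "axis_b", "axis_c", "rho", "d_n", "s_f")
  data <- parse_numeric_cols(data, num_cols)

  unit_of <- function(col) if (col %in% names(data)) data[[col]] else NA
  data$volume <- convert_unit(data$volume, unit_of("volume_unit"),
                              "volume", "m3")
  data$wet_weight <- convert_unit(data$wet_weight, unit_of("weight_unit"),
                                  "weight", "kg")
  if ("projection_area" %in% names(data)) {
    data$projection_area <- convert_unit(
      data$projection_area, unit_of("area_unit"), "area", "m2")
  }
  for (col in intersect(c("branch_width", "axis_a", "axis_b", "axis_c"),
                        names(data))) {
    data[[col]] <- convert_unit(data[[col]], unit_of("length_unit"),
                                "length", "m")
  }
  data |>
    select(-dplyr::any_of(c("volume_unit", "weight_unit", "area_unit",
                            "length_unit"))) |>
    as_tibble()
}

#' Write a particle trait table
#'
#' Writes SI values with explicit SI unit columns, including any derived
#' columns present.
#'
#' @param data Trait tibble (SI).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(data, path) {
  data <- as_tibble(data)
  data$volume_unit <- "m3"
  data$weight_unit <- "kg"
  if ("projection_area" %in% names(data)) data$area_unit <- "m2"
  if (any(c("branch_width", "axis_a") %in% names(data))) {
    data$length_unit <- "m"
  }
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a settling-observation table
#'
#' One row per replicate velocity measurement. The medium may differ between
#' replicates (temperature and salinity drifted from day to day in the study),
#' so each row either carries `temperature`/`salinity` (converted through
#' [water_properties()]) or explicit `rho_sw`/`nu` (and optionally `g`)
#' columns.
#'
#' @param path File path with columns `specimen_id`, `replicate`, `omega`
#'   (m s^-1) and medium columns as above.
#' @return An observation tibble with `rho_sw`, `nu`, `g` populated per row.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) abort_validity(sprintf("file not found: %s", path))
  data <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (nrow(data) == 0) abort_validity(sprintf("empty table: %s", path))
  required <- c("specimen_id", "omega")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0(
      "observation table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- parse_numeric_cols(
    data, c("replicate", "omega", "temperature", "salinity",
            "rho_sw", "nu", "g")
  )
  has_ts <- all(c("temperature", "salinity") %in% names(data))
  has_direct <- all(c("rho_sw", "nu") %in% names(data))
  if (!has_ts && !has_direct) {
    abort_validity(
      "observation table needs temperature+salinity or rho_sw+nu columns"
    )
  }
  if (!"g" %in% names(data)) data$g <- 9.81
  data$g[is.na(data$g)] <- 9.81
  if (has_ts && (!has_direct || anyNA(data$rho_sw) || anyNA(data$nu))) {
    fill <- if (has_direct) is.na(data$rho_sw) | is.na(data$nu)
            else rep(TRUE, nrow(data))
    med <- water_properties(data$temperature[fill], data$salinity[fill])
    if (!has_direct) {
      data$rho_sw <- NA_real_
      data$nu <- NA_real_
    }
    data$rho_sw[fill] <- med$rho_sw
    data$nu[fill] <- med$nu
  }
  as_tibble(data)
}

#' Write a settling-observation table
#'
#' @param data Observation tibble (SI).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(data, path) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}
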