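# Particle trait descriptors: nominal diameter, mass density and the Corey
# shape factor, with the two indirect axis-derivation routes used for
# macrophytes (flattened thalli and three-dimensionally branched thalli).

#' Nominal diameter of a particle
#'
#' Diameter of the sphere with the same volume as the particle:
#' `d_n = 2 * (3 V / (4 pi))^(1/3)`.
#'
#' @param volume Particle volume, m^3 (> 0). Vectorised.
#' @return Nominal diameter(s), m.
#' @examples
#' nominal_diameter(1e-7) * 100 # the study's smallest specimen, in cm
#' @export
nominal_diameter <- function(volume) {
  check_positive(volume, "volume")
  2 * (3 * volume / (4 * pi))^(1 / 3)
}

#' Corey shape factor from three perpendicular axes
#'
#' `S_f = c / sqrt(a b)` over the longest (`a`), intermediate (`b`) and
#' shortest (`c`) mutually perpendicular particle axes. 1 for a sphere,
#' much smaller than 1 for blades and filaments. Unsorted axes are reordered
#' with a warning.
#'
#' @param a,b,c Axis lengths, m (> 0). Vectorised; recycled to a common
#'   length.
#' @return Shape factor(s) in (0, 1].
#' @examples
#' corey_shape_factor(1, 1, 1)
#' corey_shape_factor(4, 1, 1)
#' @export
corey_shape_factor <- function(a, b, c) {
  check_positive(a, "a"); check_positive(b, "b"); check_positive(c, "c")
  ax <- cbind(a, b, c)
  sorted <- t(apply(ax, 1, sort, decreasing = TRUE))
  if (any(abs(ax - sorted) > 0)) {
    warning("axes not in descending order; reordering as a >= b >= c",
            call. = FALSE)
  }
  unname(sorted[, 3] / sqrt(sorted[, 1] * sorted[, 2]))
}

#' Shape factor via the flattened-thallus route
#'
#' For leaf-like morphologies the scanned projection area is the product of
#' the two longest axes, `P = a b`, and the thickness follows from the volume
#' as `c = V / P`, so `S_f = V * P^(-3/2)`.
#'
#' @param projection_area Scanned projection area `P = a b`, m^2 (> 0).
#' @param volume Particle volume, m^3 (> 0).
#' @return A tibble with columns `c` (derived thickness, m) and `s_f`.
#'   Errors when the derived `S_f` exceeds 1 (the shape is not flattened).
#' @examples
#' shape_factor_flattened(1e-2, 1e-7) # P = 100 cm^2, V = 0.1 cm^3
#' @export
shape_factor_flattened <- function(projection_area, volume) {
  check_positive(projection_area, "projection_area")
  check_positive(volume, "volume")
  cc <- volume / projection_area
  s_f <- volume * projection_area^(-1.5)
  if (any(s_f > 1)) {
    abort_validity(
      "derived S_f > 1: thickness exceeds sqrt(projection area); shape is not flattened"
    )
  }
  tibble::tibble(c = cc, s_f = s_f)
}

#' Shape factor via the branched-thallus route
#'
#' For three-dimensionally branched morphologies the shortest axis `c` is
#' measured directly (mean width of the youngest branches) and the product of
#' the two longer axes follows from the volume, `a b = V / c`, so
#' `S_f = c^(3/2) / sqrt(V)`.
#'
#' @param branch_width Representative shortest axis `c`, m (> 0).
#' @param volume Particle volume, m^3 (> 0).
#' @return A tibble with columns `ab` (derived axis product, m^2) and `s_f`.
#'   Errors when the derived `S_f` exceeds 1.
#' @examples
#' shape_factor_branched(4e-4, 4e-6) # c = 0.04 cm, V = 4 cm^3
#' @export
shape_factor_branched <- function(branch_width, volume) {
  check_positive(branch_width, "branch_width")
  check_positive(volume, "volume")
  ab <- volume / branch_width
  s_f <- branch_width^1.5 / sqrt(volume)
  if (any(s_f > 1)) {
    abort_validity(
      "derived S_f > 1: branch width exceeds sqrt(V/c); shape is not branched/cylindrical"
    )
  }
  tibble::tibble(ab = ab, s_f = s_f)
}

#' Particle mass density from blotting weight and volume
#'
#' @param wet_weight Blotted wet weight, kg (> 0).
#' @param volume Volume, m^3 (> 0).
#' @return Density, kg m^-3.
#' @examples
#' mass_density(1.10444e-3, 1e-6) # the study's median particle density
#' @export
mass_density <- function(wet_weight, volume) {
  check_positive(wet_weight, "wet_weight")
  check_positive(volume, "volume")
  wet_weight / volume
}

#' Classify buoyancy against a medium
#'
#' A particle sinks iff its density exceeds the water density. Exact ties are
#' classified floating and flagged.
#'
#' @param rho Particle density, kg m^-3.
#' @param medium A `medium_properties` object.
#' @return A tibble with columns `buoyancy` ("sinking"/"floating") and `tie`.
#' @examples
#' classify_buoyancy(1104.44, medium_override(1009.45, 1.0915e-6))
#' @export
classify_buoyancy <- function(rho, medium) {
  check_positive(rho, "rho")
  check_medium(medium)
  tie <- rho == medium$rho_sw
  tibble::tibble(
    buoyancy = ifelse(rho > medium$rho_sw, "sinking", "floating"),
    tie = tie
  )
}

#' Derive model-ready descriptors for a trait table
#'
#' Takes one row per specimen with raw measurements in SI units and computes
#' the derived columns the velocity models need: `rho`, `d_n`, `s_f`, the
#' derivation `route` and the buoyancy class. The route follows the
#' `morphology` column:
#'
#' * `"flattened"` — needs `projection_area`; thickness is derived from the
#'   volume (also used for unbranched cylinders scanned lengthwise).
#' * `"cylindrical_or_branched"` — needs `branch_width` (the measured shortest
#'   axis); the axis product is derived from the volume.
#' * `"direct_axes"` — needs `axis_a`, `axis_b`, `axis_c` (plastics and other
#'   objects whose perpendicular axes are directly measurable).
#'
#' @param data Data frame with columns `specimen_id`, `morphology`, `volume`
#'   (m^3), `wet_weight` (kg) and the route-specific columns above.
#' @param medium Optional `medium_properties` used for the buoyancy class;
#'   defaults to the study's median medium.
#' @return The input as a tibble with added columns `rho`, `d_n`, `s_f`,
#'   `route` and `buoyant`.
#' @examples
#' tibble::tibble(
#'   specimen_id = "sp1", morphology = "flattened",
#'   volume = 1e-6, wet_weight = 1.2e-3, projection_area = 1e-2
#' ) |> derive_traits()
#' @export
derive_traits <- function(data, medium = median_study_medium()) {
  data <- as_tibble(data)
  check_medium(medium)
  required <- c("specimen_id", "morphology", "volume", "wet_weight")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0(
      "trait table is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  known <- c("flattened", "cylindrical_or_branched", "direct_axes")
  if (!all(data$morphology %in% known)) {
    abort_validity(paste0(
      "unknown morphology value(s): ",
      paste(unique(setdiff(data$morphology, known)), collapse = ", ")
    ))
  }
  check_positive(data$volume, "volume")
  check_positive(data$wet_weight, "wet_weight")

  col_or_na <- function(col, i) {
    if (col %in% names(data)) data[[col]][i] else NA_real_
  }
  s_f <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    s_f[i] <- switch(data$morphology[i],
      flattened = {
        p <- col_or_na("projection_area", i)
        if (is.na(p)) {
          abort_validity(sprintf(
            "row %d (flattened): `projection_area` is required", i
          ))
        }
        shape_factor_flattened(p, data$volume[i])$s_f
      },
      cylindrical_or_branched = {
        w <- col_or_na("branch_width", i)
        if (is.na(w)) {
          abort_validity(sprintf(
            "row %d (cylindrical_or_branched): `branch_width` is required", i
          ))
        }
        shape_factor_branched(w, data$volume[i])$s_f
      },
      direct_axes = {
        ax <- c(col_or_na("axis_a", i), col_or_na("axis_b", i),
                col_or_na("axis_c", i))
        if (anyNA(ax)) {
          abort_validity(sprintf(
            "row %d (direct_axes): `axis_a`, `axis_b`, `axis_c` are required", i
          ))
        }
        corey_shape_factor(ax[1], ax[2], ax[3])
      }
    )
  }

  rho <- mass_density(data$wet_weight, data$volume)
  data |>
    mutate(
      rho = rho,
      d_n = nominal_diameter(.data$volume),
      s_f = s_f,
      route = .data$morphology,
      buoyant = classify_buoyancy(rho, medium)$buoyancy == "floating"
    )
}
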