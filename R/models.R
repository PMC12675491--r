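# The drag-based sedimentation-velocity models. All constants are SI-bound:
# Model A's drag term nu/(d_n g) is not dimensionless, so evaluating in
# anything but m/kg/s gives answers wrong by large factors. Every function
# here therefore requires SI inputs.

MODEL_C_NAMES <- c(
  "k_lam0", "k_lam1", "k_turb0", "k_turb1",
  "p_turb1", "k_turb2", "p_turb2", "p_outer"
)

model_presets <- function() {
  list(
    A = c(k = 4567661),
    B = c(k = 4146.337),
    C = setNames(
      c(198.3826, 34121.98, 0.8906959, 9939.812,
        2.972455, 87764.06, 52.04557, 5.566767),
      MODEL_C_NAMES
    )
  )
}

#' Specify a sedimentation-velocity model
#'
#' The three empirical model structures, with the study's fitted constants as
#' presets:
#'
#' * **A** — no shape dependence; drag `C_D = k nu / (d_n g)` (one constant).
#' * **B** — shape enters the numerator as `S_f^(2/3)` (ellipsoid treatment);
#'   drag `C_D = k nu / (d_n^1.5 g^0.5)` (one constant).
#' * **C** — shape also enters the drag:
#'   `C_D = ((k_lam0 + k_lam1 S_f) nu / (d_n^1.5 g^0.5) + k_turb0
#'   - k_turb1 S_f^p_turb1 - k_turb2 S_f^p_turb2)^p_outer` (eight constants).
#'
#' @param structure `"A"`, `"B"` or `"C"`.
#' @param constants Optional named numeric vector replacing the preset
#'   constants; names and length must match the structure.
#' @return A `model_spec` object (list with `structure` and `constants`).
#' @examples
#' model_spec("C")
#' model_spec("B", c(k = 5000))
#' @export
model_spec <- function(structure = c("A", "B", "C"), constants = NULL) {
  structure <- match.arg(structure)
  preset <- model_presets()[[structure]]
  if (is.null(constants)) {
    constants <- preset
  } else {
    if (length(constants) != length(preset)) {
      abort_validity(sprintf(
        "structure %s takes %d constant(s), got %d",
        structure, length(preset), length(constants)
      ))
    }
    if (is.null(names(constants)) || all(names(constants) == "")) {
      names(constants) <- names(preset)
    }
    if (!identical(sort(names(constants)), sort(names(preset)))) {
      abort_validity(sprintf(
        "constants for structure %s must be named %s",
        structure, paste(names(preset), collapse = ", ")
      ))
    }
    constants <- constants[names(preset)]
  }
  structure(
    list(structure = structure, constants = constants),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> structure", x$structure, "\n")
  print(x$constants)
  invisible(x)
}

is_model_spec <- function(x) inherits(x, "model_spec")

#' Terminal settling velocity from the general force balance
#'
#' Equates effective weight with drag for a particle of diameter `d`:
#' `omega = sqrt((4/3) (rho/rho_sw - 1) g d / C_D)`.
#'
#' @param rho Particle density, kg m^-3 (must be >= the water density).
#' @param medium A `medium_properties` object.
#' @param d Particle diameter, m.
#' @param c_d Drag coefficient (> 0).
#' @return Settling velocity, m s^-1 (0 at neutral buoyancy). Vectorised over
#'   `rho`, `d` and `c_d`.
#' @export
general_velocity <- function(rho, medium, d, c_d) {
  check_positive(rho, "rho")
  check_medium(medium)
  check_positive(d, "d")
  if (any(c_d <= 0)) abort_domain("`c_d` must be positive")
  if (any(rho < medium$rho_sw)) {
    abort_buoyancy("particle density below water density: particle floats")
  }
  sqrt((4 / 3) * (rho / medium$rho_sw - 1) * medium$g * d / c_d)
}

#' Settling velocity with the ellipsoid shape correction
#'
#' The general balance with `S_f^(2/3)` in the numerator, treating the
#' particle as an ellipsoid of nominal diameter `d_n`:
#' `omega = sqrt((4/3) (rho/rho_sw - 1) g d_n S_f^(2/3) / C_D)`.
#'
#' @param rho Particle density, kg m^-3.
#' @param medium A `medium_properties` object.
#' @param d_n Nominal diameter, m.
#' @param s_f Corey shape factor in (0, 1].
#' @param c_d Drag coefficient (> 0).
#' @return Settling velocity, m s^-1.
#' @export
riazi_velocity <- function(rho, medium, d_n, s_f, c_d) {
  check_positive(s_f, "s_f")
  if (any(s_f > 1)) abort_validity("`s_f` must be <= 1")
  general_velocity(rho, medium, d_n * s_f^(2 / 3), c_d)
}

#' Shape-dependent drag coefficient
#'
#' `C_D = (X2 nu / (d_n^1.5 g^0.5) + X3)^X1`, the dimensionless drag form in
#' which `X2` (laminar) and `X3` (turbulent) may themselves depend on the
#' shape factor. Note `nu / (d_n^1.5 g^0.5)` is dimensionless.
#'
#' @param d_n Nominal diameter, m.
#' @param medium A `medium_properties` object.
#' @param x1,x2,x3 Constants (outer exponent, laminar and turbulent terms).
#' @return Drag coefficient. Errors (class `sinkvel_error_domain`) when the
#'   base `x2 nu / (d_n^1.5 g^0.5) + x3` is not positive.
#' @export
drag_riazi <- function(d_n, medium, x1, x2, x3) {
  check_positive(d_n, "d_n")
  check_medium(medium)
  base <- x2 * medium$nu / (d_n^1.5 * medium$g^0.5) + x3
  if (any(base <= 0)) {
    abort_domain(
      sprintf("drag base is non-positive (min %.6g); outside model domain",
              min(base))
    )
  }
  exp(x1 * log(base))
}

# s_f^p via exp(p log s_f); underflow to 0 is intended for the huge exponents
pow_sf <- function(s_f, p) exp(p * log(s_f))

# Vectorised core evaluation shared by predict_velocity(), the surface and the
# GA objective. rho/d_n/s_f/rho_sw/nu/g are plain vectors (recycled); returns
# omega, c_d, in_domain and a reason string. Out-of-domain and buoyant cases
# give NA omega here; the user-facing wrappers decide whether to flag or abort.
eval_model <- function(structure, constants, rho, d_n, s_f, rho_sw, nu, g) {
  n <- max(length(rho), length(d_n), length(s_f), length(rho_sw), length(nu),
           length(g))
  rho <- rep_len(rho, n); d_n <- rep_len(d_n, n); s_f <- rep_len(s_f, n)
  rho_sw <- rep_len(rho_sw, n); nu <- rep_len(nu, n); g <- rep_len(g, n)

  buoyant <- rho < rho_sw
  if (structure == "A") {
    c_d <- constants[["k"]] * nu / (d_n * g)
    num <- (4 / 3) * (rho / rho_sw - 1) * g * d_n
    base <- c_d
  } else {
    num <- (4 / 3) * (rho / rho_sw - 1) * g * d_n * s_f^(2 / 3)
    if (structure == "B") {
      c_d <- constants[["k"]] * nu / (d_n^1.5 * g^0.5)
      base <- c_d
    } else {
      k <- constants
      base <- (k[["k_lam0"]] + k[["k_lam1"]] * s_f) * nu / (d_n^1.5 * g^0.5) +
        k[["k_turb0"]] -
        k[["k_turb1"]] * pow_sf(s_f, k[["p_turb1"]]) -
        k[["k_turb2"]] * pow_sf(s_f, k[["p_turb2"]])
      c_d <- ifelse(base > 0, exp(k[["p_outer"]] * log(pmax(base, 1e-300))),
                    NA_real_)
    }
  }
  in_domain <- !buoyant & is.finite(base) & base > 0
  omega <- ifelse(in_domain, sqrt(pmax(num, 0) / c_d), NA_real_)
  reason <- rep("ok", n)
  reason[buoyant] <- "buoyant: rho < rho_sw"
  reason[!buoyant & !(is.finite(base) & base > 0)] <-
    sprintf("drag base non-positive (%.4g)",
            base[!buoyant & !(is.finite(base) & base > 0)])
  list(omega = omega, c_d = c_d, in_domain = in_domain, reason = reason,
       base = base)
}

#' Predict settling velocities for a trait table
#'
#' Evaluates one of the velocity models for every specimen. Inputs must be in
#' SI units (use [read_trait_table()] or [derive_traits()] to get there).
#'
#' @param data Data frame with columns `specimen_id`, `rho`, `d_n` and (for
#'   structures B and C) `s_f`, e.g. from [derive_traits()].
#' @param medium A `medium_properties` object, or `NULL` if the table itself
#'   carries `rho_sw`, `nu` and `g` columns (per-specimen media).
#' @param model A [model_spec()]; defaults to the preset Model C.
#' @param on_invalid `"flag"` (default) marks buoyant or out-of-domain rows
#'   with `in_domain = FALSE` and `NA` velocity; `"error"` aborts with a
#'   buoyancy or domain error instead.
#' @return A tibble with columns `specimen_id`, `omega_pred` (m s^-1), `c_d`,
#'   `in_domain`, `diagnostics` and `model`.
#' @examples
#' traits <- tibble::tibble(specimen_id = "x", rho = 1104.44,
#'                          d_n = 0.02, s_f = 0.01)
#' predict_velocity(traits, median_study_medium(), model_spec("C"))
#' @export
predict_velocity <- function(data, medium = median_study_medium(),
                             model = model_spec("C"),
                             on_invalid = c("flag", "error")) {
  data <- as_tibble(data)
  on_invalid <- match.arg(on_invalid)
  if (!is_model_spec(model)) abort_validity("`model` must be a model_spec")
  need <- c("specimen_id", "rho", "d_n")
  if (model$structure != "A") need <- c(need, "s_f")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0("missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
  }
  if (is.null(medium)) {
    if (!all(c("rho_sw", "nu", "g") %in% names(data))) {
      abort_validity(
        "without `medium`, the table must carry rho_sw, nu and g columns"
      )
    }
    rho_sw <- data$rho_sw; nu <- data$nu; g <- data$g
  } else {
    check_medium(medium)
    rho_sw <- medium$rho_sw; nu <- medium$nu; g <- medium$g
  }
  s_f <- if ("s_f" %in% names(data)) data$s_f else rep(1, nrow(data))
  if (model$structure != "A") {
    check_positive(s_f, "s_f")
    if (any(s_f > 1)) abort_validity("`s_f` must be <= 1")
  }
  check_positive(data$rho, "rho")
  check_positive(data$d_n, "d_n")

  ev <- eval_model(model$structure, model$constants,
                   data$rho, data$d_n, s_f, rho_sw, nu, g)
  if (on_invalid == "error" && !all(ev$in_domain)) {
    bad <- which(!ev$in_domain)[1]
    if (grepl("buoyant", ev$reason[bad])) {
      abort_buoyancy(sprintf("specimen %s: %s",
                             data$specimen_id[bad], ev$reason[bad]))
    }
    abort_domain(sprintf("specimen %s: %s",
                         data$specimen_id[bad], ev$reason[bad]))
  }
  tibble::tibble(
    specimen_id = data$specimen_id,
    omega_pred = ev$omega,
    c_d = ev$c_d,
    in_domain = ev$in_domain,
    diagnostics = ev$reason,
    model = model$structure
  )
}

#' Velocity surface over a shape-factor / diameter grid
#'
#' Evaluates a model on the full `d_n` x `s_f` grid at fixed particle density
#' and medium, masking (not erroring) cells outside the model's validity
#' domain. Reproduces the study's prediction-surface view of how size and
#' shape interact.
#'
#' @param model A [model_spec()].
#' @param medium A `medium_properties` object.
#' @param rho Particle density, kg m^-3.
#' @param d_n Vector of nominal diameters, m.
#' @param s_f Vector of shape factors in (0, 1].
#' @return A tibble of class `sinkvel_surface` with columns `d_n`, `s_f`,
#'   `omega` (`NA` when masked), `c_d` and `in_domain`.
#' @examples
#' prediction_surface(model_spec("C"), median_study_medium(), 1104.44,
#'                    d_n = c(0.01, 0.02), s_f = c(0.001, 0.01))
#' @export
prediction_surface <- function(model, medium, rho, d_n, s_f) {
  if (!is_model_spec(model)) abort_validity("`model` must be a model_spec")
  check_medium(medium)
  check_positive(rho, "rho")
  check_positive(d_n, "d_n")
  check_positive(s_f, "s_f")
  if (any(s_f > 1)) abort_validity("`s_f` must be <= 1")
  grid <- tidyr::expand_grid(d_n = sort(d_n), s_f = sort(s_f))
  ev <- eval_model(model$structure, model$constants, rho, grid$d_n, grid$s_f,
                   medium$rho_sw, medium$nu, medium$g)
  out <- grid |>
    mutate(omega = ev$omega, c_d = ev$c_d, in_domain = ev$in_domain)
  class(out) <- c("sinkvel_surface", class(out))
  attr(out, "model") <- model$structure
  out
}

#' Plot a prediction surface
#'
#' Heatmap of settling velocity over the shape-factor / diameter grid;
#' out-of-domain cells are blank.
#'
#' @param object A `sinkvel_surface` from [prediction_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sinkvel_surface <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$s_f, y = .data$d_n * 100, fill = .data$omega)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90",
                                  name = expression(omega ~ (m ~ s^-1))) +
    ggplot2::labs(
      x = expression("Corey shape factor" ~ S[f]),
      y = expression("nominal diameter" ~ d[n] ~ (cm)),
      title = paste("Predicted settling velocity, model",
                    attr(object, "model"))
    )
}
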