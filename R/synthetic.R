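# Synthetic particle traits and settling observations with the statistical
# structure of the study: nominal diameters and shape factors log-uniform over
# the observed spans, densities lognormal around the observed median, and
# replicate velocities with multiplicative lognormal noise.

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study conditions: nominal diameters spanning
#' 0.576–4.844 cm, macrophyte shape factors spanning 0.00029–0.0689 (plastic
#' mode extends to sphere-like values near 1), particle densities lognormal
#' around the median 1104.44 kg m^-3, the median experimental medium, and
#' five replicate velocity measurements per specimen with a multiplicative
#' noise coefficient of variation of 0.1.
#'
#' @param n_specimens Number of specimens to generate.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param d_n_range Nominal-diameter span, m (log-uniform draw).
#' @param s_f_range Shape-factor span (log-uniform draw).
#' @param rho_median Median particle density, kg m^-3.
#' @param rho_sdlog Lognormal sdlog of the density distribution.
#' @param medium `medium_properties` the observations are measured in.
#' @param generating_model [model_spec()] that produces the true velocities.
#' @param noise_cv Coefficient of variation of the multiplicative velocity
#'   noise; 0 gives noiseless observations.
#' @param replicates Replicate velocity measurements per specimen (the study
#'   used 5, or 7 for one batch).
#' @param plastic_mode If `TRUE`, specimens get directly measured axes
#'   (`direct_axes` route), `s_f_range` may extend to 1, and the
#'   buoyancy-shape coupling below is disabled (dense plastics sink at any
#'   shape factor).
#' @param s_f_sink_max In macrophyte mode, draws with a shape factor above
#'   this value are emitted as floating specimens (density drawn just below
#'   the water density), reproducing the study's observation that no
#'   negatively buoyant seaweed exceeded a shape factor of 0.0278 while
#'   compact, vesicle-bearing (high shape factor) thalli floated. Settling
#'   observations therefore only arise from the shape range the study
#'   measured them in.
#' @param max_resample Redraw cap per specimen when the generating model is
#'   out of domain for a draw.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_specimens, seed = NULL,
                             d_n_range = c(0.00576, 0.04844),
                             s_f_range = c(0.00029, 0.0689),
                             rho_median = 1104.44, rho_sdlog = 0.04,
                             medium = median_study_medium(),
                             generating_model = model_spec("C"),
                             noise_cv = 0.1, replicates = 5,
                             plastic_mode = FALSE, s_f_sink_max = 0.0278,
                             max_resample = 100) {
  check_positive(n_specimens, "n_specimens")
  check_positive(d_n_range, "d_n_range")
  check_positive(s_f_range, "s_f_range")
  if (is.unsorted(d_n_range) || length(d_n_range) != 2) {
    abort_validity("`d_n_range` must be an increasing length-2 vector")
  }
  if (is.unsorted(s_f_range) || length(s_f_range) != 2 ||
      s_f_range[2] > 1) {
    abort_validity("`s_f_range` must be increasing with upper bound <= 1")
  }
  if (noise_cv < 0) abort_validity("`noise_cv` must be >= 0")
  check_positive(replicates, "replicates")
  check_medium(medium)
  if (!is_model_spec(generating_model)) {
    abort_validity("`generating_model` must be a model_spec")
  }
  structure(
    list(
      n_specimens = as.integer(n_specimens), seed = seed,
      d_n_range = d_n_range, s_f_range = s_f_range,
      rho_median = rho_median, rho_sdlog = rho_sdlog, medium = medium,
      generating_model = generating_model, noise_cv = noise_cv,
      replicates = as.integer(replicates), plastic_mode = plastic_mode,
      s_f_sink_max = s_f_sink_max,
      max_resample = as.integer(max_resample)
    ),
    class = "synthetic_config"
  )
}

draw_specimens <- function(config, n, id_offset = 0) {
  d_n <- exp(runif(n, log(config$d_n_range[1]), log(config$d_n_range[2])))
  s_f <- exp(runif(n, log(config$s_f_range[1]), log(config$s_f_range[2])))
  rho <- rlnorm(n, log(config$rho_median), config$rho_sdlog)
  if (!config$plastic_mode) {
    # buoyancy-shape coupling seen in the study: compact (high shape factor)
    # thalli floated; settling specimens all had s_f <= s_f_sink_max
    floats <- s_f > config$s_f_sink_max
    rho[floats] <- config$medium$rho_sw * runif(sum(floats), 0.97, 0.999)
  }
  volume <- (pi / 6) * d_n^3 # inverse of the nominal-diameter relation
  tibble::tibble(
    specimen_id = sprintf("syn%03d", id_offset + seq_len(n)),
    d_n = d_n, s_f = s_f, rho = rho, volume = volume,
    wet_weight = rho * volume
  )
}

# attach morphology-route measurement columns consistent with (V, s_f)
attach_route <- function(draws, plastic_mode) {
  n <- nrow(draws)
  out <- draws |>
    mutate(
      morphology = NA_character_, projection_area = NA_real_,
      branch_width = NA_real_, axis_a = NA_real_, axis_b = NA_real_,
      axis_c = NA_real_
    )
  if (plastic_mode) {
    # prolate-box construction with a = b: V = a^2 c, s_f = c / a
    a <- (out$volume / out$s_f)^(1 / 3)
    out$morphology <- "direct_axes"
    out$axis_a <- a; out$axis_b <- a; out$axis_c <- out$s_f * a
  } else {
    flat <- out$s_f < 0.01
    out$morphology <- ifelse(flat, "flattened", "cylindrical_or_branched")
    # flattened: s_f = V P^(-3/2) -> P = (V / s_f)^(2/3)
    out$projection_area[flat] <-
      (out$volume[flat] / out$s_f[flat])^(2 / 3)
    # branched: s_f = c^(3/2) V^(-1/2) -> c = (s_f^2 V)^(1/3)
    out$branch_width[!flat] <-
      (out$s_f[!flat]^2 * out$volume[!flat])^(1 / 3)
  }
  out
}

#' Generate a synthetic specimen trait table
#'
#' Draws specimen traits per the configuration and emits the same schema the
#' real-data readers produce, including the morphology-route measurement
#' columns (projection area, branch width or direct axes) that reproduce the
#' drawn shape factor exactly. Draws for which the generating model is out of
#' domain are redrawn (up to `max_resample` per specimen, then an error), so
#' downstream observation generation always succeeds.
#'
#' @param config A [synthetic_config()].
#' @return A trait tibble with columns `specimen_id`, `morphology`, `volume`,
#'   `wet_weight`, route columns, `rho`, `d_n`, `s_f`, `route`, `buoyant`, and
#'   an attribute `resampled` counting redraws.
#' @export
generate_specimens <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validity("`config` must come from synthetic_config()")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  draws <- draw_specimens(config, config$n_specimens)
  m <- config$medium
  resampled <- 0L
  for (attempt in seq_len(config$max_resample)) {
    ev <- eval_model(config$generating_model$structure,
                     config$generating_model$constants,
                     draws$rho, draws$d_n, draws$s_f, m$rho_sw, m$nu, m$g)
    # buoyant draws are legitimate specimens (flagged later); only redraw
    # draws the generating model refuses for domain reasons
    bad <- !ev$in_domain & !(draws$rho < m$rho_sw)
    if (!any(bad)) break
    resampled <- resampled + sum(bad)
    draws[bad, ] <- draw_specimens(config, sum(bad),
                                   id_offset = config$n_specimens + resampled
    ) |> mutate(specimen_id = draws$specimen_id[bad])
    if (attempt == config$max_resample) {
      abort_domain(sprintf(
        "%d specimen draw(s) still out of the generating model's domain after %d redraws",
        sum(bad), config$max_resample
      ))
    }
  }
  out <- attach_route(draws, config$plastic_mode) |>
    mutate(
      route = .data$morphology,
      buoyant = .data$rho <= m$rho_sw
    ) |>
    select(all_of(c(
      "specimen_id", "morphology", "volume", "wet_weight",
      "projection_area", "branch_width", "axis_a", "axis_b", "axis_c",
      "rho", "d_n", "s_f", "route", "buoyant"
    )))
  attr(out, "resampled") <- resampled
  out
}

#' Generate synthetic settling observations
#'
#' Evaluates the generating model for each sinking specimen and emits
#' `replicates` velocity measurements with multiplicative lognormal noise of
#' the configured coefficient of variation (noise factor has mean exactly 1).
#' Floating specimens (density at or below the water density) are emitted with
#' a single flagged row and no velocity.
#'
#' @param traits A trait table from [generate_specimens()] (or any table with
#'   `specimen_id`, `rho`, `d_n`, `s_f`).
#' @param config The [synthetic_config()] used for the traits.
#' @return An observation tibble: `specimen_id`, `replicate`, `omega`
#'   (m s^-1, `NA` for floating specimens), `buoyant`, `rho_sw`, `nu`, `g`.
#' @export
generate_observations <- function(traits, config) {
  if (!inherits(config, "synthetic_config")) {
    abort_validity("`config` must come from synthetic_config()")
  }
  traits <- as_tibble(traits)
  m <- config$medium
  ev <- eval_model(config$generating_model$structure,
                   config$generating_model$constants,
                   traits$rho, traits$d_n, traits$s_f, m$rho_sw, m$nu, m$g)
  floating <- traits$rho <= m$rho_sw
  if (any(!ev$in_domain & !floating)) {
    abort_domain(
      "generating model is out of domain for some sinking specimens; regenerate traits"
    )
  }
  sink_idx <- which(!floating)
  r <- config$replicates
  sigma <- sqrt(log(1 + config$noise_cv^2))
  obs_sink <- tibble::tibble(
    specimen_id = rep(traits$specimen_id[sink_idx], each = r),
    replicate = rep(seq_len(r), length(sink_idx)),
    omega = rep(ev$omega[sink_idx], each = r) *
      (if (config$noise_cv > 0) {
        rlnorm(length(sink_idx) * r, -sigma^2 / 2, sigma)
      } else 1),
    buoyant = FALSE
  )
  obs_float <- tibble::tibble(
    specimen_id = traits$specimen_id[floating],
    replicate = NA_integer_, omega = NA_real_, buoyant = TRUE
  )
  bind_rows(obs_sink, obs_float) |>
    mutate(rho_sw = m$rho_sw, nu = m$nu, g = m$g) |>
    arrange(.data$specimen_id, .data$replicate)
}
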