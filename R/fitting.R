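# Refitting the model constants to settling observations with a real-coded
# genetic algorithm (tournament selection, BLX-alpha crossover, Gaussian
# mutation, elitism, stall-window stopping), minimising the mean squared
# error of predicted vs observed velocity. Multiplicative constants are
# searched on a log10 scale (the fitted constants span 0.89 to 4.6e6, so a
# linear encoding cannot move); exponents are searched linearly.

#' Genetic-algorithm configuration
#'
#' Defaults are the study's optimiser settings: population 5000, crossover
#' probability 0.8, mutation probability 0.1, elitism 250, at most 500 000
#' generations, stopping when the best mean squared error has not improved
#' over 5000 generations. Reduced settings (e.g. `population_size = 200`,
#' `stall_window = 200`) are appropriate for quick refits and tests.
#'
#' @param population_size Individuals per generation.
#' @param crossover_prob Probability a selected parent pair is recombined.
#' @param mutation_prob Per-gene probability of Gaussian mutation.
#' @param elitism Number of best individuals copied unchanged.
#' @param max_generations Hard generation cap.
#' @param stall_window Generations without improvement before stopping.
#' @param seed Integer seed; all GA randomness flows from it.
#' @param bounds Optional named list `lower`/`upper` of per-constant bounds on
#'   the natural scale, overriding the defaults (multiplicative constants:
#'   three decades either side of the preset; exponents: 0 to 100).
#' @param local_polish Run a bounded quasi-Newton refinement (L-BFGS-B) from
#'   the best individuals after the GA stops. On by default; recovers the
#'   precision the full-scale GA buys with generations.
#' @param tournament_size Selection tournament size.
#' @param blx_alpha Blend-crossover expansion factor.
#' @param mutation_sd_frac Mutation standard deviation as a fraction of each
#'   gene's bound width.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 5000, crossover_prob = 0.8,
                      mutation_prob = 0.1, elitism = 250,
                      max_generations = 500000, stall_window = 5000,
                      seed = NULL, bounds = NULL, local_polish = TRUE,
                      tournament_size = 3, blx_alpha = 0.5,
                      mutation_sd_frac = 0.1) {
  check_range(crossover_prob, "crossover_prob", 0, 1)
  check_range(mutation_prob, "mutation_prob", 0, 1)
  check_positive(population_size, "population_size")
  if (elitism >= population_size) {
    abort_validity("`elitism` must be smaller than `population_size`")
  }
  if (stall_window > max_generations) {
    abort_validity("`stall_window` must not exceed `max_generations`")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      crossover_prob = crossover_prob, mutation_prob = mutation_prob,
      elitism = as.integer(elitism),
      max_generations = as.integer(max_generations),
      stall_window = as.integer(stall_window), seed = seed, bounds = bounds,
      local_polish = isTRUE(local_polish),
      tournament_size = as.integer(tournament_size), blx_alpha = blx_alpha,
      mutation_sd_frac = mutation_sd_frac
    ),
    class = "ga_config"
  )
}

# gene encoding: log10 for multiplicative constants, identity for exponents
encoding_for <- function(structure, bounds = NULL) {
  preset <- model_presets()[[structure]]
  nm <- names(preset)
  log_scale <- !grepl("^p_", nm)
  lower <- ifelse(log_scale, preset / 1000, 0)
  upper <- ifelse(log_scale, preset * 1000, 100)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  glo <- ifelse(log_scale, log10(lower), lower)
  gup <- ifelse(log_scale, log10(upper), upper)
  list(names = nm, log_scale = log_scale, glo = glo, gup = gup)
}

decode_genes <- function(genes, enc) {
  # genes: matrix pop x G
  out <- genes
  out[, enc$log_scale] <- 10^out[, enc$log_scale, drop = FALSE]
  colnames(out) <- enc$names
  out
}

# population-level objective: MSE per candidate, with infeasible candidates
# (any observation out of the model's domain) receiving a large finite
# penalty plus the domain-violation magnitude, so selection still ranks them
make_objective <- function(structure, obs) {
  n <- nrow(obs)
  g <- obs$g
  lam <- obs$nu / (obs$d_n^1.5 * sqrt(g)) # dimensionless laminar group
  if (structure == "A") {
    num <- (4 / 3) * (obs$rho / obs$rho_sw - 1) * g * obs$d_n
    drag_pre <- obs$nu / (obs$d_n * g)
  } else {
    num <- (4 / 3) * (obs$rho / obs$rho_sw - 1) * g * obs$d_n * obs$s_f^(2 / 3)
  }
  omega_obs <- obs$omega
  log_sf <- if (structure == "C") log(obs$s_f) else NULL

  function(const) {
    # const: matrix pop x n_constants on the natural scale
    p <- nrow(const)
    if (structure %in% c("A", "B")) {
      pre <- if (structure == "A") drag_pre else lam
      c_d <- outer(const[, "k"], pre) # p x n, always positive
      omega <- sqrt(matrix(num, p, n, byrow = TRUE) / c_d)
      mse <- rowMeans((omega - matrix(omega_obs, p, n, byrow = TRUE))^2)
      return(list(mse = mse, feasible = rep(TRUE, p),
                  violation = numeric(p)))
    }
    base <- outer(const[, "k_lam0"], lam) +
      outer(const[, "k_lam1"], obs$s_f * lam) +
      const[, "k_turb0"] -
      const[, "k_turb1"] * exp(outer(const[, "p_turb1"], log_sf)) -
      const[, "k_turb2"] * exp(outer(const[, "p_turb2"], log_sf))
    feasible_cell <- is.finite(base) & base > 0
    feasible <- rowSums(feasible_cell) == n
    violation <- rowSums(pmax(-base, 0, na.rm = TRUE))
    c_d <- exp(const[, "p_outer"] * log(pmax(base, 1e-300)))
    omega <- sqrt(matrix(num, p, n, byrow = TRUE) / c_d)
    sqerr <- (omega - matrix(omega_obs, p, n, byrow = TRUE))^2
    mse <- rowMeans(sqerr)
    mse[!feasible] <- NA_real_
    list(mse = mse, feasible = feasible, violation = violation)
  }
}

penalised_fitness <- function(objective, genes, enc) {
  res <- objective(decode_genes(genes, enc))
  fit <- res$mse
  if (any(!res$feasible)) {
    worst <- if (any(res$feasible)) max(res$mse[res$feasible]) else 1e-3
    fit[!res$feasible] <- 1e3 * worst * (1 + res$violation[!res$feasible])
  }
  list(fitness = fit, feasible = res$feasible)
}

#' Refit model constants by genetic algorithm
#'
#' Minimises the mean squared error between predicted and observed settling
#' velocities over the free constants of one model structure. Candidate
#' constant vectors that put any observation outside the model's validity
#' domain receive a large finite penalty (counted in the result) rather than
#' an error, so the search can recover.
#'
#' @param data Per-specimen observations: a data frame with columns `omega`
#'   (observed settling velocity, m s^-1, e.g. the replicate mean from
#'   [aggregate_replicates()]), `rho`, `d_n`, `s_f` (structures B/C) and
#'   either `rho_sw`, `nu`, `g` columns or a `medium` argument.
#' @param structure `"A"`, `"B"` or `"C"`.
#' @param config A [ga_config()].
#' @param medium Optional `medium_properties` applied to all observations.
#' @return A `sinkvel_fit` object: fitted [model_spec()], `objective` (MSE,
#'   m^2 s^-2), per-generation best-objective `history`, `converged` flag,
#'   `n_obs` and `penalty_hits`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_specimens = 10, seed = 1, noise_cv = 0,
#'                         generating_model = model_spec("B"))
#' traits <- generate_specimens(cfg)
#' obs <- generate_observations(traits, cfg) |> aggregate_replicates()
#' fit <- prepare_fit_data(traits, obs, cfg$medium) |>
#'   fit_model("B", ga_config(population_size = 60, elitism = 5,
#'                            max_generations = 200, stall_window = 50,
#'                            seed = 1))
#' glance(fit)
#' }
#' @export
fit_model <- function(data, structure = c("A", "B", "C"),
                      config = ga_config(), medium = NULL) {
  structure <- match.arg(structure)
  data <- as_tibble(data)
  if (!inherits(config, "ga_config")) {
    abort_validity("`config` must come from ga_config()")
  }
  if (!is.null(medium)) {
    check_medium(medium)
    data$rho_sw <- medium$rho_sw; data$nu <- medium$nu; data$g <- medium$g
  }
  need <- c("omega", "rho", "d_n", "rho_sw", "nu", "g")
  if (structure != "A") need <- c(need, "s_f")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_validity(paste0("observations are missing column(s): ",
                          paste(missing_cols, collapse = ", ")))
  }
  if (nrow(data) == 0) abort_validity("no observations supplied")
  n_const <- length(model_presets()[[structure]])
  if (nrow(data) < n_const) {
    abort_validity(sprintf(
      "structure %s has %d free constants but only %d observations",
      structure, n_const, nrow(data)
    ))
  }
  if (any(data$rho < data$rho_sw)) {
    abort_buoyancy("observations include floating specimens (rho < rho_sw)")
  }
  check_positive(data$omega, "omega")

  enc <- encoding_for(structure, config$bounds)
  objective <- make_objective(structure, data)
  ng <- length(enc$names)
  pop_n <- config$population_size
  width <- enc$gup - enc$glo
  mut_sd <- config$mutation_sd_frac * width

  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
  }

  pop <- matrix(runif(pop_n * ng, rep(enc$glo, each = pop_n),
                      rep(enc$gup, each = pop_n)), pop_n, ng)
  evald <- penalised_fitness(objective, pop, enc)
  fitness <- evald$fitness
  penalty_hits <- sum(!evald$feasible)

  history <- numeric(0)
  best <- Inf
  last_improve <- 0L
  gen <- 0L
  converged <- FALSE
  n_child <- pop_n - config$elitism

  while (gen < config$max_generations) {
    gen <- gen + 1L
    ord <- order(fitness)
    pop <- pop[ord, , drop = FALSE]
    fitness <- fitness[ord]
    if (fitness[1] < best) {
      best <- fitness[1]
      last_improve <- gen
    }
    history <- c(history, best)
    if (gen - last_improve >= config$stall_window && gen > 1L) {
      converged <- TRUE
      break
    }

    # tournament selection of parents for the non-elite slots
    tmat <- matrix(sample.int(pop_n, 2L * n_child * config$tournament_size,
                              replace = TRUE),
                   ncol = config$tournament_size)
    parents <- tmat[cbind(seq_len(nrow(tmat)), max.col(-matrix(
      fitness[tmat], nrow(tmat), config$tournament_size)))]
    p1 <- pop[parents[seq_len(n_child)], , drop = FALSE]
    p2 <- pop[parents[n_child + seq_len(n_child)], , drop = FALSE]

    # BLX-alpha blend crossover on recombined pairs
    do_cx <- runif(n_child) < config$crossover_prob
    child <- p1
    if (any(do_cx)) {
      lo <- pmin(p1[do_cx, , drop = FALSE], p2[do_cx, , drop = FALSE])
      hi <- pmax(p1[do_cx, , drop = FALSE], p2[do_cx, , drop = FALSE])
      span <- hi - lo
      child[do_cx, ] <- lo - config$blx_alpha * span +
        matrix(runif(sum(do_cx) * ng), sum(do_cx), ng) *
          (1 + 2 * config$blx_alpha) * span
    }

    # Gaussian mutation, clamped to the gene box
    mut <- matrix(runif(n_child * ng) < config$mutation_prob, n_child, ng)
    if (any(mut)) {
      noise <- matrix(stats::rnorm(n_child * ng, 0,
                                   rep(mut_sd, each = n_child)), n_child, ng)
      child[mut] <- child[mut] + noise[mut]
    }
    child <- pmin(pmax(child, rep(enc$glo, each = n_child)),
                  rep(enc$gup, each = n_child))

    evald <- penalised_fitness(objective, child, enc)
    penalty_hits <- penalty_hits + sum(!evald$feasible)
    pop <- rbind(pop[seq_len(config$elitism), , drop = FALSE], child)
    fitness <- c(fitness[seq_len(config$elitism)], evald$fitness)
  }
  ord <- order(fitness)
  pop <- pop[ord, , drop = FALSE]
  fitness <- fitness[ord]
  if (fitness[1] < best) best <- fitness[1]
  history <- c(history, best)

  best_genes <- pop[1, ]
  if (config$local_polish) {
    scalar_obj <- function(x) {
      penalised_fitness(objective, matrix(x, 1), enc)$fitness
    }
    clamped_obj <- function(x) {
      scalar_obj(pmin(pmax(x, enc$glo), enc$gup))
    }
    starts <- unique(round(pop[seq_len(min(10L, pop_n)), , drop = FALSE], 10))
    for (i in seq_len(nrow(starts))) {
      par <- starts[i, ]
      if (ng > 1) {
        nm <- tryCatch(
          optim(par, clamped_obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12)),
          error = function(e) NULL
        )
        if (!is.null(nm) && is.finite(nm$value)) {
          par <- pmin(pmax(nm$par, enc$glo), enc$gup)
          if (nm$value < best) {
            best <- nm$value
            best_genes <- par
          }
        }
      }
      res <- tryCatch(
        optim(par, scalar_obj, method = "L-BFGS-B",
              lower = enc$glo, upper = enc$gup,
              control = list(maxit = 500, factr = 1e4)),
        error = function(e) NULL
      )
      if (!is.null(res) && is.finite(res$value) && res$value < best) {
        best <- res$value
        best_genes <- res$par
      }
    }
    history <- c(history, best)
  }

  constants <- drop(decode_genes(matrix(best_genes, 1), enc))
  names(constants) <- enc$names
  final <- objective(matrix(constants, 1, dimnames = list(NULL, enc$names)))
  structure(
    list(
      model = model_spec(structure, constants),
      objective = best,
      feasible = isTRUE(final$feasible),
      history = history,
      converged = converged,
      generations = gen,
      n_obs = nrow(data),
      penalty_hits = penalty_hits,
      config = config
    ),
    class = "sinkvel_fit"
  )
}

#' @export
print.sinkvel_fit <- function(x, ...) {
  cat("<sinkvel_fit> structure", x$model$structure,
      sprintf("| MSE %.4g m^2 s^-2 | %d generations%s | n = %d\n",
              x$objective, x$generations,
              if (x$converged) " (converged)" else "", x$n_obs))
  print(x$model$constants)
  invisible(x)
}

#' @rdname fit_model
#' @param x,object A `sinkvel_fit`.
#' @param ... Unused.
#' @export
tidy.sinkvel_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$model$constants),
    estimate = unname(x$model$constants)
  )
}

#' @rdname fit_model
#' @export
glance.sinkvel_fit <- function(x, ...) {
  tibble::tibble(
    structure = x$model$structure,
    mse = x$objective,
    converged = x$converged,
    generations = x$generations,
    n_obs = x$n_obs,
    penalty_hits = x$penalty_hits
  )
}

#' @rdname fit_model
#' @export
autoplot.sinkvel_fit <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$history),
                       best_mse = object$history)
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$best_mse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "best MSE (m² s⁻²)",
                  title = paste("GA objective trajectory, structure",
                                object$model$structure))
}

#' Split observations into modeling and testing groups
#'
#' Partitions per-specimen records by a label column or a named label vector,
#' mirroring the study's 20-specimen modeling / 29-specimen testing design.
#'
#' @param data Data frame with a `specimen_id` column.
#' @param assignment Either the name of a column of `data` holding the labels,
#'   or a character vector of labels named by specimen id. Labels must be
#'   `"modeling"` or `"testing"` and cover every specimen exactly once.
#' @return A list with tibbles `modeling` and `testing` and a `counts` vector.
#' @export
split_modeling_testing <- function(data, assignment = "group") {
  data <- as_tibble(data)
  if (!"specimen_id" %in% names(data)) {
    abort_validity("`data` must have a specimen_id column")
  }
  if (is.character(assignment) && length(assignment) == 1 &&
      assignment %in% names(data)) {
    labels <- setNames(data[[assignment]], data$specimen_id)
  } else {
    if (is.null(names(assignment))) {
      abort_validity("`assignment` must be a label column name or a named vector")
    }
    if (!all(data$specimen_id %in% names(assignment))) {
      abort_validity("assignment does not cover all specimens")
    }
    labels <- assignment[as.character(data$specimen_id)]
  }
  bad <- setdiff(unique(labels), c("modeling", "testing"))
  if (length(bad) > 0) {
    abort_validity(paste0("unknown split label(s): ",
                          paste(bad, collapse = ", ")))
  }
  per_spec <- tapply(labels, names(labels) %||% data$specimen_id,
                     function(x) length(unique(x)))
  if (any(per_spec > 1)) {
    abort_validity("specimen assigned to both modeling and testing")
  }
  modeling <- data[labels == "modeling", , drop = FALSE]
  testing <- data[labels == "testing", , drop = FALSE]
  if (nrow(testing) == 0) {
    warning("testing set is empty", call. = FALSE)
  }
  if (nrow(modeling) == 0) {
    warning("modeling set is empty", call. = FALSE)
  }
  list(
    modeling = modeling, testing = testing,
    counts = c(modeling = nrow(modeling), testing = nrow(testing))
  )
}

#' Join traits and aggregated observations into fit-ready records
#'
#' Convenience assembler: merges a trait table (from [derive_traits()] or
#' [generate_specimens()]) with per-specimen observed velocities and a medium
#' into the flat table [fit_model()] and [evaluate_predictions()] consume.
#'
#' @param traits Trait table with `specimen_id`, `rho`, `d_n`, `s_f`.
#' @param observations Per-specimen velocities with `specimen_id` and `omega`
#'   (e.g. from [aggregate_replicates()]); may carry its own `rho_sw`, `nu`,
#'   `g` columns.
#' @param medium Optional `medium_properties` filling `rho_sw`, `nu`, `g`.
#' @return A tibble with one row per observed specimen.
#' @export
prepare_fit_data <- function(traits, observations, medium = NULL) {
  traits <- as_tibble(traits)
  observations <- as_tibble(observations)
  out <- observations |>
    left_join(
      traits |> select(all_of(c("specimen_id", "rho", "d_n", "s_f"))),
      by = "specimen_id"
    )
  if (!is.null(medium)) {
    check_medium(medium)
    out$rho_sw <- medium$rho_sw; out$nu <- medium$nu; out$g <- medium$g
  }
  if (anyNA(out$rho)) {
    abort_validity("some observations have no matching specimen in `traits`")
  }
  out
}
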