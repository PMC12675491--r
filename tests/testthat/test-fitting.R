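# reduced GA settings keep unit tests fast; the optimiser defaults mirror the
# full-scale study configuration
quick_ga <- function(seed, pop = 80, stall = 60) {
  ga_config(population_size = pop, elitism = max(2, round(pop * 0.05)),
            max_generations = 1000, stall_window = stall, seed = seed)
}

make_b_data <- function(n = 20, seed = 1, noise_cv = 0) {
  cfg <- synthetic_config(n_specimens = n, seed = seed, noise_cv = noise_cv,
                          generating_model = model_spec("B"))
  tr <- generate_specimens(cfg)
  tr <- tr[!tr$buoyant, ]
  obs <- aggregate_replicates(generate_observations(tr, cfg))
  prepare_fit_data(tr, obs, cfg$medium)
}

test_that("ga_config validates its hyperparameters", {
  expect_error(ga_config(population_size = 10, elitism = 10),
               class = "sinkvel_error_validity")
  expect_error(ga_config(crossover_prob = 1.2),
               class = "sinkvel_error_validity")
  expect_error(ga_config(max_generations = 10, stall_window = 100),
               class = "sinkvel_error_validity")
  cfg <- ga_config()
  expect_equal(cfg$population_size, 5000L)
  expect_equal(cfg$crossover_prob, 0.8)
  expect_equal(cfg$mutation_prob, 0.1)
  expect_equal(cfg$elitism, 250L)
  expect_equal(cfg$max_generations, 500000L)
  expect_equal(cfg$stall_window, 5000L)
})

test_that("identical seed, config and data give identical fits", {
  d <- make_b_data(12, seed = 4, noise_cv = 0.1)
  f1 <- fit_model(d, "B", quick_ga(123))
  f2 <- fit_model(d, "B", quick_ga(123))
  expect_identical(f1$model$constants, f2$model$constants)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$objective, f2$objective)
})

test_that("elitism keeps the best objective non-increasing", {
  d <- make_b_data(12, seed = 6, noise_cv = 0.1)
  f <- fit_model(d, "B", quick_ga(7))
  expect_true(all(diff(f$history) <= 0))
  expect_gte(f$objective, 0)
  expect_equal(f$n_obs, nrow(d))
})

test_that("noiseless synthetic data recover the generating constants", {
  d <- make_b_data(20, seed = 1)
  fit_b <- fit_model(d, "B", quick_ga(2))
  expect_lt(abs(fit_b$model$constants[["k"]] / 4146.337 - 1), 0.01)
  expect_lt(fit_b$objective, 1e-12)

  cfg_a <- synthetic_config(n_specimens = 20, seed = 2, noise_cv = 0,
                            generating_model = model_spec("A"))
  tr <- generate_specimens(cfg_a)
  tr <- tr[!tr$buoyant, ]
  obs <- aggregate_replicates(generate_observations(tr, cfg_a))
  fit_a <- fit_model(prepare_fit_data(tr, obs, cfg_a$medium), "A",
                     quick_ga(2))
  expect_lt(abs(fit_a$model$constants[["k"]] / 4567661 - 1), 0.01)
})

test_that("fits refuse underdetermined or invalid observation sets", {
  d <- make_b_data(12, seed = 5)
  expect_error(fit_model(d[1:3, ], "C", quick_ga(1)),
               class = "sinkvel_error_validity")
  expect_error(fit_model(d[0, ], "B", quick_ga(1)),
               class = "sinkvel_error_validity")
  bad <- d; bad$rho[1] <- bad$rho_sw[1] - 50
  expect_error(fit_model(bad, "B", quick_ga(1)),
               class = "sinkvel_error_buoyancy")
})

test_that("fitted model B constant is unbiased under replicate noise", {
  # stochastic check: relative bias of the refit constant over seeded repeats
  ks <- vapply(1:20, function(i) {
    d <- make_b_data(12, seed = 100 + i, noise_cv = 0.1)
    fit_model(d, "B", quick_ga(i, pop = 40, stall = 30))$model$constants[["k"]]
  }, 0)
  expect_lt(abs(mean(ks) / 4146.337 - 1), 0.05)
})

test_that("fit results expose tidy, glance and autoplot methods", {
  d <- make_b_data(12, seed = 8, noise_cv = 0.1)
  f <- fit_model(d, "B", quick_ga(3))
  td <- tidy(f)
  expect_equal(td$term, "k")
  expect_equal(td$estimate, unname(f$model$constants))
  gl <- glance(f)
  expect_equal(gl$structure, "B")
  expect_equal(gl$mse, f$objective)
  expect_s3_class(autoplot(f), "ggplot")
  expect_output(print(f), "sinkvel_fit")
})

test_that("modeling/testing split partitions specimens exactly", {
  d <- tibble::tibble(specimen_id = sprintf("s%02d", 1:49),
                      group = rep(c("modeling", "testing"), c(20, 29)))
  sp <- split_modeling_testing(d, "group")
  expect_equal(unname(sp$counts), c(20L, 29L))
  expect_equal(nrow(sp$modeling), 20)
  expect_true(length(intersect(sp$modeling$specimen_id,
                               sp$testing$specimen_id)) == 0)

  labels <- setNames(d$group, d$specimen_id)
  sp2 <- split_modeling_testing(d, labels)
  expect_identical(sp2$counts, sp$counts)

  all_model <- d |> dplyr::mutate(group = "modeling")
  expect_warning(split_modeling_testing(all_model, "group"), "testing")

  dup <- dplyr::bind_rows(d, tibble::tibble(specimen_id = "s01",
                                            group = "testing"))
  expect_error(split_modeling_testing(dup, "group"),
               class = "sinkvel_error_validity")
  bad <- d; bad$group[1] <- "validation"
  expect_error(split_modeling_testing(bad, "group"),
               class = "sinkvel_error_validity")
})

test_that("generate-fit-evaluate closes on noiseless model B data", {
  # the package's primary integration loop: the generator is the oracle
  cfg <- synthetic_config(n_specimens = 20, seed = 10, noise_cv = 0,
                          generating_model = model_spec("B"))
  tr <- generate_specimens(cfg)
  tr <- tr[!tr$buoyant, ]
  obs <- aggregate_replicates(generate_observations(tr, cfg))
  d <- prepare_fit_data(tr, obs, cfg$medium)
  fit <- fit_model(d, "B", quick_ga(11))
  pred <- predict_velocity(d, cfg$medium, fit$model)
  report <- evaluate_predictions(
    dplyr::left_join(d, pred[, c("specimen_id", "omega_pred")],
                     by = "specimen_id")
  )
  expect_lt(report$msd, 1e-12)
  expect_lt(abs(fit$model$constants[["k"]] / 4146.337 - 1), 0.01)
})
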