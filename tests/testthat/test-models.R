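test_that("model presets carry the published constants", {
  expect_equal(unname(model_spec("A")$constants), 4567661)
  expect_equal(unname(model_spec("B")$constants), 4146.337)
  expect_equal(
    unname(model_spec("C")$constants),
    c(198.3826, 34121.98, 0.8906959, 9939.812, 2.972455, 87764.06,
      52.04557, 5.566767)
  )
  expect_error(model_spec("C", c(k = 1)), class = "sinkvel_error_validity")
})

test_that("general velocity follows the force balance", {
  m <- study_medium()
  expect_equal(general_velocity(m$rho_sw, m, 0.02, 1), 0)
  # engineered inputs: (rho/rho_sw - 1) g d = 1, C_D = 4/3 -> omega = 1
  rho <- m$rho_sw * (1 + 1 / (m$g * 0.02))
  expect_equal(general_velocity(rho, m, 0.02, 4 / 3), 1)
  expect_error(general_velocity(1000, m, 0.02, 1),
               class = "sinkvel_error_buoyancy")
  expect_error(general_velocity(1100, m, 0.02, -1),
               class = "sinkvel_error_domain")
})

test_that("ellipsoid correction scales velocity as the cube root of s_f", {
  m <- study_medium()
  w1 <- riazi_velocity(1104.44, m, 0.02, 1, 0.5)
  expect_equal(w1, general_velocity(1104.44, m, 0.02, 0.5))
  w2 <- riazi_velocity(1104.44, m, 0.02, 0.001, 0.5)
  expect_equal(w2 / w1, 0.001^(1 / 3))
})

test_that("drag form is dimensionless and handles limiting cases", {
  m <- study_medium()
  expect_equal(drag_riazi(0.02, m, x1 = 3, x2 = 0, x3 = 1), 1)
  expect_equal(drag_riazi(0.02, m, x1 = 1, x2 = 7, x3 = 0),
               7 * m$nu / (0.02^1.5 * m$g^0.5))
  # dimensional invariance: (nu, d_n) -> (k nu, k^(2/3) d_n) leaves C_D fixed
  set.seed(3)
  for (k in exp(runif(10, log(0.2), log(5)))) {
    m2 <- medium_override(m$rho_sw, k * m$nu, m$g)
    expect_equal(
      drag_riazi(0.02, m, 2.5, 1234, 0.7),
      drag_riazi(k^(2 / 3) * 0.02, m2, 2.5, 1234, 0.7),
      tolerance = 1e-12
    )
  }
  expect_error(drag_riazi(0.02, m, 5.57, 1, -10),
               class = "sinkvel_error_domain")
})

test_that("all three models match the independent log-domain oracle", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = "t", rho = 1104.44, d_n = 0.02,
                       s_f = 0.01)
  # frozen values computed with the oracle evaluators
  a <- predict_velocity(tr, m, model_spec("A"))$omega_pred
  expect_equal(a, 0.0311247668480366, tolerance = 1e-10)
  b <- predict_velocity(tr, m, model_spec("B"))$omega_pred
  expect_equal(b, 0.0472927230488912, tolerance = 1e-10)
  cc <- predict_velocity(tr, m, model_spec("C"))$omega_pred
  expect_equal(cc, 0.0394626240139682, tolerance = 1e-10)

  inputs <- random_model_inputs(300, seed = 99)
  tab <- inputs |> dplyr::mutate(specimen_id = as.character(dplyr::row_number()))
  pa <- predict_velocity(tab, NULL, model_spec("A"))$omega_pred
  pb <- predict_velocity(tab, NULL, model_spec("B"))$omega_pred
  pc <- predict_velocity(tab, NULL, model_spec("C"))$omega_pred
  with(inputs, {
    expect_lt(max(abs(pa / oracle_model_a(rho, rho_sw, nu, g, d_n) - 1)), 1e-10)
    expect_lt(max(abs(pb / oracle_model_b(rho, rho_sw, nu, g, d_n, s_f) - 1)),
              1e-10)
    expect_lt(max(abs(pc / oracle_model_c(rho, rho_sw, nu, g, d_n, s_f) - 1)),
              1e-10)
  })
})

test_that("models return zero velocity at neutral buoyancy", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = "t", rho = m$rho_sw, d_n = 0.02,
                       s_f = 0.01)
  for (s in c("A", "B", "C")) {
    expect_equal(predict_velocity(tr, m, model_spec(s))$omega_pred, 0)
  }
})

test_that("model A velocity is proportional to nominal diameter", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = c("s", "l"), rho = 1104.44,
                       d_n = c(0.01, 0.02), s_f = 1)
  w <- predict_velocity(tr, m, model_spec("A"))$omega_pred
  expect_equal(w[2] / w[1], 2, tolerance = 1e-12)
})

test_that("model B velocity scales as the cube root of the shape factor", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = c("a", "b"), rho = 1104.44, d_n = 0.02,
                       s_f = c(0.02, 0.01))
  w <- predict_velocity(tr, m, model_spec("B"))$omega_pred
  expect_equal(w[2] / w[1], 0.5^(1 / 3), tolerance = 1e-12)
})

test_that("the huge shape exponent vanishes at macrophyte shape factors", {
  # s_f^52.04557, evaluated in log space, must be below 1e-15 throughout
  # s_f <= 0.5 (underflowing to 0 at small s_f) and must never be NaN
  for (sf in c(0.00029, 0.0278, 0.0689, 0.5)) {
    p <- sinkvel:::pow_sf(sf, 52.04557)
    expect_false(is.nan(p))
    expect_lt(p, 1e-15)
  }
  # hard underflow to exact zero at the smallest study shape factors is fine
  expect_identical(sinkvel:::pow_sf(1e-7, 52.04557), 0)
})

test_that("model C refuses sphere-like particles; model B does not", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = "ball", rho = 1104.44, d_n = 0.04,
                       s_f = 1)
  expect_error(predict_velocity(tr, m, model_spec("C"), on_invalid = "error"),
               class = "sinkvel_error_domain")
  flagged <- predict_velocity(tr, m, model_spec("C"))
  expect_false(flagged$in_domain)
  expect_true(is.na(flagged$omega_pred))
  expect_match(flagged$diagnostics, "base")
  b <- predict_velocity(tr, m, model_spec("B"))
  expect_true(b$in_domain && is.finite(b$omega_pred))
})

test_that("buoyant rows are flagged or raise a buoyancy error", {
  m <- study_medium()
  tr <- tibble::tibble(specimen_id = c("f", "s"), rho = c(1000, 1104.44),
                       d_n = 0.02, s_f = 0.01)
  out <- predict_velocity(tr, m, model_spec("C"))
  expect_equal(out$in_domain, c(FALSE, TRUE))
  expect_match(out$diagnostics[1], "buoyant")
  expect_error(predict_velocity(tr, m, model_spec("C"), on_invalid = "error"),
               class = "sinkvel_error_buoyancy")
})

test_that("model B rescales as the drag invariance predicts", {
  # under (nu, d_n) -> (k nu, k^(2/3) d_n), C_D is unchanged so omega scales
  # as sqrt(d_n), i.e. by k^(1/3)
  m <- study_medium()
  k <- 3.7
  m2 <- medium_override(m$rho_sw, k * m$nu, m$g)
  tr1 <- tibble::tibble(specimen_id = "x", rho = 1104.44, d_n = 0.02,
                        s_f = 0.01)
  tr2 <- tr1 |> dplyr::mutate(d_n = k^(2 / 3) * d_n)
  w1 <- predict_velocity(tr1, m, model_spec("B"))$omega_pred
  w2 <- predict_velocity(tr2, m2, model_spec("B"))$omega_pred
  expect_equal(w2 / w1, k^(1 / 3), tolerance = 1e-12)
})

test_that("prediction surface masks invalid cells instead of erroring", {
  m <- study_medium()
  g1 <- prediction_surface(model_spec("C"), m, 1104.44, 0.02, 0.01)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$omega,
               predict_velocity(
                 tibble::tibble(specimen_id = "x", rho = 1104.44,
                                d_n = 0.02, s_f = 0.01),
                 m, model_spec("C"))$omega_pred)
  grid <- prediction_surface(model_spec("C"), m, 1104.44,
                             d_n = c(0.01, 0.04844),
                             s_f = c(0.001, 0.0689, 1))
  expect_true(any(!grid$in_domain))
  expect_true(all(is.na(grid$omega[!grid$in_domain])))
  expect_true(all(is.finite(grid$omega[grid$in_domain])))
  expect_s3_class(autoplot(grid), "ggplot")
})

test_that("surface velocity is non-decreasing in diameter at fixed shape", {
  m <- study_medium()
  grid <- prediction_surface(
    model_spec("C"), m, 1104.44,
    d_n = exp(seq(log(0.00576), log(0.04844), length.out = 30)),
    s_f = exp(seq(log(0.00029), log(0.0689), length.out = 30))
  )
  by_sf <- split(grid, grid$s_f)
  for (piece in by_sf) {
    w <- piece$omega[order(piece$d_n)]
    w <- w[!is.na(w)]
    if (length(w) > 1) expect_true(all(diff(w) >= 0))
  }
})
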