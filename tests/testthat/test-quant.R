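test_that("the synthetic input function is a gamma variate", {
  a <- synth_aif(times = seq(0, 120, 0.5), A = 2, t0 = 10, gamma = 3, tau = 8)
  expect_true(all(a$kbq_ml[a$time_s <= 10] == 0))
  expect_true(all(a$kbq_ml >= 0))
  expect_equal(a$time_s[which.max(a$kbq_ml)], 10 + 3 * 8, tolerance = 0.6)
})

test_that("the water model reaches its partition-coefficient steady state", {
  const <- quant_constants()
  flat <- tac(c(0, 10000), c(5, 5))
  # A(T) - A(T - dT) ~ C(T) * dT with C at equilibrium p * rho * Ca
  A1 <- h2o_tissue_counts(50, flat, const, T = 4000)
  A2 <- h2o_tissue_counts(50, flat, const, T = 4100)
  c_eq <- (A2 - A1) / 100
  expect_lt(abs(c_eq - const$p * const$rho * 5) / (const$p * const$rho * 5), 0.01)
  expect_equal(h2o_tissue_counts(0, flat, const, T = 100), 0)
  expect_error(h2o_tissue_counts(-5, flat, const), "negative")
})

test_that("accumulated water counts increase monotonically with flow", {
  aif <- synth_aif()
  A <- h2o_tissue_counts(seq(10, 120, by = 10), aif, T = 180)
  expect_true(all(diff(A) > 0))
})

test_that("autoradiographic CBF inverts its forward model", {
  aif <- synth_aif(A = 0.02)
  const <- quant_constants()
  for (f in c(20, 50, 90)) {
    A <- h2o_tissue_counts(f, aif, const, T = 180)
    f_hat <- cbf_autoradiographic(A, aif, const, T = 180)
    expect_lt(abs(as.numeric(f_hat) - f) / f, 1e-3)
  }
  expect_equal(as.numeric(cbf_autoradiographic(0, aif, const)), 0)
  # above-table input is clamped and flagged
  big <- h2o_tissue_counts(150, aif, const, T = 180) * 2
  f_big <- cbf_autoradiographic(big, aif, const, T = 180)
  expect_true(attr(f_big, "clamped")[1])
  expect_equal(as.numeric(f_big), 150)
})

test_that("CBF estimation stays unbiased under measurement noise", {
  aif <- synth_aif(A = 0.02)
  const <- quant_constants()
  A50 <- h2o_tissue_counts(50, aif, const, T = 180)
  set.seed(31)
  noisy <- A50 * (1 + 0.05 * rnorm(100))
  f_hat <- cbf_autoradiographic(noisy, aif, const, T = 180)
  expect_lt(abs(mean(f_hat) - 50) / 50, 0.02)
})

test_that("CBV follows the intravascular ratio formula", {
  const <- quant_constants()
  expect_equal(cbv_from_co(3.536, 100, const), 4, tolerance = 1e-6)
  expect_equal(cbv_from_co(0, 100, const), 0)
  expect_equal(cbv_from_co(7.072, 200, const), cbv_from_co(3.536, 100, const))
  expect_error(cbv_from_co(1, 0, const), "positive")
})

test_that("OEF and CMRO2 invert the simplified oxygen model", {
  aif <- synth_aif(A = 0.015, t0 = 10, gamma = 2.5, tau = 10)
  const <- quant_constants()
  oefs <- c(0.25, 0.4, 0.6)
  fs <- c(30, 50, 70)
  cbvs <- c(3, 4, 5)
  A <- o2_tissue_counts(oefs, fs, cbvs, aif, const, T = 180)
  est <- oef_cmro2(A, fs, cbvs, aif, const, T = 180)
  expect_lt(max(abs(as.numeric(est$oef) - oefs) / oefs), 0.005)
  expect_equal(
    as.numeric(est$cmro2),
    as.numeric(est$oef) * fs * const$CaO2
  )
  # worked number: OEF 0.4 at f 50 with CaO2 0.19 -> 3.8 ml O2/100 g/min
  expect_equal(0.4 * 50 * 0.19, 3.8)
  # zero extraction: only the intravascular term remains
  A0 <- o2_tissue_counts(0, 50, 4, aif, const, T = 180)
  est0 <- oef_cmro2(A0, 50, 4, aif, const, T = 180)
  expect_lt(abs(as.numeric(est0$oef)), 1e-9)
  # zero flow is flagged, not an error
  estf <- oef_cmro2(A0, 0, 4, aif, const, T = 180)
  expect_true(attr(estf$oef, "flagged")[1])
})

test_that("quantification round-trips hold across a physiological grid", {
  aif <- synth_aif(A = 0.02)
  aif_o2 <- synth_aif(A = 0.015, t0 = 10, gamma = 2.5, tau = 10)
  const <- quant_constants()
  grid <- expand.grid(f = c(20, 40, 60, 90), oef = c(0.3, 0.5), cbv = c(2, 5))
  A_h2o <- h2o_tissue_counts(grid$f, aif, const, T = 180)
  f_hat <- as.numeric(cbf_autoradiographic(A_h2o, aif, const, T = 180))
  expect_lt(max(abs(f_hat - grid$f) / grid$f), 0.005)
  cbv_hat <- cbv_from_co(grid$cbv / 100 * const$rho * const$R_sl * 100, 100, const)
  expect_lt(max(abs(cbv_hat - grid$cbv) / grid$cbv), 1e-9)
  A_o2 <- o2_tissue_counts(grid$oef, grid$f, grid$cbv, aif_o2, const, T = 180)
  oef_hat <- as.numeric(oef_cmro2(A_o2, f_hat, cbv_hat, aif_o2, const, T = 180)$oef)
  expect_lt(max(abs(oef_hat - grid$oef) / grid$oef), 0.005)
})
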