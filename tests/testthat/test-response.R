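test_that("HRE occupancy fractions follow the fast-binding expressions", {
  expect_equal(hre_occupancy(0, 0, 0, 0.3), list(cad = 0, cadoh = 0))
  occ <- hre_occupancy(1, 0, 1, 0.3)
  expect_equal(occ$cad, 1 / 1.3)
  expect_equal(occ$cadoh, 0)
  occ2 <- hre_occupancy(0.5, 0.5, 1, 0.3)
  expect_equal(occ2$cad, occ2$cadoh)
  expect_equal(occ2$cad, 0.5 / 1.3)
  expect_error(hre_occupancy(0.5, 0.2, 1, 0.3), "inconsistent")
})

test_that("scanned curves keep fractions in range and sum below one", {
  rc <- response_scan("full", full_params(), oxygen_grid(1e-4, 1, 20))
  expect_true(all(rc$HRE_CAD >= 0 & rc$HRE_CAD <= 1))
  expect_true(all(rc$HRE_CADOH >= 0 & rc$HRE_CADOH <= 1))
  expect_true(all(rc$HRE_total <= 1 + 1e-12))
  expect_true(all(rc$F_free >= 0 & rc$F_free <= 1))
})

test_that("total HIF-alpha declines monotonically without repeats", {
  p <- full_params(A_tot = 0, gamma = 0)
  expect_equal(steady_state("full", p, 0)[["H_tot"]], 1, tolerance = 1e-9)
  rc <- response_scan("full", p, oxygen_grid(1e-4, 1, 30))
  expect_equal(rc$H_tot[1], 1, tolerance = 1e-2)   # residual PHD activity
  expect_true(all(diff(rc$H_tot) < 0))
})

test_that("SKM2 scan endpoints match the closed-form steady states", {
  rc <- response_scan("skm2", skm2_params(10, 50), oxygen_grid(1e-4, 10, 30))
  expect_equal(rc$F_free[1], 1 / (1 + 10 * skm2_root(10, 50, 1e-4)),
               tolerance = 1e-6)
  expect_equal(rc$F_free[30], 1 / (1 + 10 * skm2_root(10, 50, 10)),
               tolerance = 1e-6)
  expect_gt(rc$F_free[30], 0.9)
  expect_lt(rc$F_free[1], 0.12)
})

test_that("gene regimes order none -> NAD -> NAD+CAD as oxygen decreases", {
  rc <- response_scan("skm1", skm1_regime_params(), oxygen_grid(1e-4, 1, 80))
  gr <- gene_regimes(rc)
  runs <- rle(as.character(gr$regime))$values
  expect_equal(runs, c("NAD+CAD", "NAD", "none"))   # grid is low -> high O2
  expect_error(gene_regimes(rc, threshold = 1), "threshold")
  # an impossible threshold puts every point in 'none'
  gr99 <- gene_regimes(rc, threshold = 0.99)
  expect_true(all(gr99$regime == "none"))
  # no CAD-hydroxylated HIF-alpha, no CADOH regime
  rc0 <- rc
  rc0$HRE_CADOH <- 0
  expect_true(all(!gene_regimes(rc0)$cadoh))
})

test_that("threshold finding recovers closed-form half-response points", {
  o <- oxygen_grid(1e-2, 1e2, 300)
  expect_equal(find_threshold(o, o^2 / (0.25 + o^2)), 0.5, tolerance = 1e-3)
  # decreasing observables are handled symmetrically
  expect_equal(find_threshold(o, 1 / (1 + o)), 1, tolerance = 1e-3)
  expect_error(find_threshold(o, rep(1, length(o))), "constant")
  expect_error(find_threshold(o, o, level = 0), "level")
})

test_that("apparent Hill exponents recover classical identities", {
  o <- oxygen_grid(1e-3, 1e3, 400)
  expect_equal(hill_coefficient(o, o / (1 + o)), 1, tolerance = 0.01)
  expect_equal(hill_coefficient(o, o^2 / (1 + o^2)), 2, tolerance = 0.01)
})

test_that("threshold and Hill metrics are stable under grid refinement", {
  p <- full_params(A_tot = 100, gamma = 0.02, epsilon = 5)
  r1 <- response_scan("full", p, oxygen_grid(1e-4, 1, 60))
  r2 <- response_scan("full", p, oxygen_grid(1e-4, 1, 120))
  t1 <- find_threshold(r1$oxygen, r1$F_free)
  t2 <- find_threshold(r2$oxygen, r2$F_free)
  expect_equal(t1, t2, tolerance = 0.01)
  h1 <- hill_coefficient(r1$oxygen, r1$H)
  h2 <- hill_coefficient(r2$oxygen, r2$H)
  expect_equal(h1, h2, tolerance = 0.01)
})

test_that("peak location is refined by local quadratic interpolation", {
  o <- seq(0.5, 1.5, by = 0.01)
  pk <- find_peak(o, 1 - (o - 1)^2)
  expect_true(pk$interior)
  expect_equal(pk$oxygen, 1, tolerance = 1e-3)
  expect_equal(pk$value, 1, tolerance = 1e-4)
  expect_error(find_peak(o, rep(0, length(o))), "zero")
  # monotone observable: argmax sits at the boundary, flagged non-interior
  expect_false(find_peak(o, o)$interior)
})

test_that("CAD-hydroxylated HIF-alpha peaks at intermediate oxygen (SKM1)", {
  rc <- response_scan("skm1", skm1_regime_params(), oxygen_grid(1e-4, 3, 80))
  pk <- find_peak(rc$oxygen, rc$H_OH)
  expect_true(pk$interior)
  expect_lt(rc$H_OH[1], 0.2 * pk$value)
  expect_lt(rc$H_OH[nrow(rc)], 0.2 * pk$value)
})

test_that("interior CADOH peak persists across skeleton parameter draws", {
  # FIH activity at least as effective as PHD activity, the stated
  # condition for significant CAD-hydroxylation
  set.seed(42)
  for (i in 1:6) {
    act_P <- runif(1, 30, 300)
    mult <- runif(1, 1, 5)
    p <- full_params(P_tot = 1, KD_P = runif(1, 0.3, 3), kcat_P = act_P,
                     F_tot = 1, KD_FH = runif(1, 0.3, 3),
                     kcat_FH = act_P * mult, alpha = runif(1, 0.2, 1),
                     A_tot = 0, gamma = 0, epsilon = 1)
    rc <- response_scan("skm1", p, oxygen_grid(1e-4, 5, 50))
    expect_true(find_peak(rc$oxygen, rc$H_OH)$interior,
                label = sprintf("draw %d", i))
  }
})

test_that("reoxygenation delay measures the half-response time", {
  q <- skm2_params(30, 100)
  tr <- equilibrate_then_step("skm2", q, 0.01, 0.5, duration = 4,
                              step = 0.005)
  d <- reoxygenation_delay(tr, "F_free")
  expect_gt(d, 0)
  f0 <- tr$F_free[1]; ff <- tr$F_free[nrow(tr)]
  at_d <- approx(tr$time, tr$F_free, d)$y
  expect_equal(at_d, f0 + 0.5 * (ff - f0), tolerance = 1e-3)
  # an observable already at its final value has zero delay
  flat <- tr; flat$F_free <- 1
  expect_equal(reoxygenation_delay(flat, "F_free"), 0)
  expect_error(reoxygenation_delay(tr, "nope"), "column")
})

test_that("memory map delays grow with hypoxia severity and duration", {
  p <- full_params(A_tot = 100, gamma = 0.02, epsilon = 5)
  mm <- memory_map("full", p, severities = c(0.001, 0.01),
                   durations = c(2, 10, 40), post_cap = 80, step = 0.05)
  expect_true(all(mm >= 0))
  # nondecreasing along the duration axis at fixed severity
  expect_true(all(apply(mm, 1, function(r) all(diff(r) >= -1e-6))))
  # more severe hypoxia leaves a longer post-reoxygenation delay
  expect_true(all(mm["0.001", ] >= mm["0.01", ]))
  # very short episodes leave almost no delay compared to long ones
  expect_lt(mm["0.001", "2"], mm["0.001", "40"])
  expect_error(memory_map("full", p, severities = 0.6, durations = 1),
               "below the normoxic")
})
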