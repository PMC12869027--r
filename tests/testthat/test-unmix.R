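test_that("linear unmixing recovers constructed spectra exactly", {
  eox <- get_extinction("HbO2", wl11, tab)
  ede <- get_extinction("Hb", wl11, tab)
  r <- lu_unmix(2 * eox, wl11, tab)
  expect_equal(r$c_ox, 2, tolerance = 1e-10)
  expect_equal(r$c_de, 0, tolerance = 1e-10)
  expect_equal(r$so2_pct, 100, tolerance = 1e-10)
  r2 <- lu_unmix(eox + ede, wl11, tab)
  expect_equal(r2$so2_pct, 50, tolerance = 1e-8)
  expect_equal(r2$thb_rel, 2, tolerance = 1e-8)
  r3 <- lu_unmix(rep(0, 11), wl11, tab)
  expect_true(is.na(r3$so2_pct))
  expect_equal(r3$thb_rel, 0)
  expect_error(lu_unmix(c(1, 2), c(750, 800), tab),
               class = "qpat_domain_error")
})

test_that("a fluence decreasing in wavelength biases LU downward", {
  mu <- 0.8 * get_extinction("HbO2", wl11, tab) +
    0.2 * get_extinction("Hb", wl11, tab)
  phi <- exp(-0.002 * (wl11 - 730))  # decreasing over 730-830
  p <- phi * mu
  r <- lu_unmix(p, wl11, tab)
  expect_lt(r$so2_pct, 80)
  # grid-search oracle agrees with the active-set solution
  E <- cbind(get_extinction("HbO2", wl11, tab),
             get_extinction("Hb", wl11, tab))
  cg <- grid_nnls2(E, p)
  expect_equal(r$so2_pct, so2_from_conc(cg[1], cg[2]), tolerance = 0.5)
})

test_that("LU underestimates high saturations under declining fluence", {
  phi <- exp(-0.0015 * (wl11 - 730))
  for (s in c(50, 60, 75, 90, 100)) {
    mu <- sat_absorption_for_test(s, wl11)
    r <- lu_unmix(phi * mu, wl11, tab)
    expect_lte(r$so2_pct, s + 1e-8)
  }
})

test_that("compensated unmixing inverts a known coloring exactly", {
  phi <- exp(-0.003 * (wl11 - 780))
  mu60 <- sat_absorption_for_test(60, wl11)
  r <- clu_unmix(phi * mu60, wl11, phi, tab)
  expect_equal(r$so2_pct, 60, tolerance = 1e-8)
  expect_equal(r$method, "CLU")
  # identity compensation reproduces LU exactly
  p <- phi * mu60
  a <- clu_unmix(p, wl11, rep(1, 11), tab)
  b <- lu_unmix(p, wl11, tab)
  expect_identical(a$c_ox, b$c_ox)
  expect_identical(a$c_de, b$c_de)
  expect_error(clu_unmix(p, wl11, c(rep(1, 10), 0), tab),
               class = "qpat_compensation_error")
})

test_that("CLU with phi_ave beats LU on average over member colorings", {
  set.seed(5)
  members <- sapply(seq(-0.004, 0.004, length.out = 6), function(a)
    exp(a * (wl11 - 800)) * (1 + 0.02 * sin(wl11 / 17)))
  eig <- synthetic_eigenspectra(members, wl11)
  errs <- sapply(seq_len(ncol(members)), function(j) {
    p <- eig$spectra[, j] * sat_absorption_for_test(80, wl11)
    c(clu = abs(clu_unmix(p, wl11, eig$phi_ave, tab)$so2_pct - 80),
      lu = abs(lu_unmix(p, wl11, tab)$so2_pct - 80))
  })
  expect_lt(mean(errs["clu", ]), mean(errs["lu", ]))
})

test_that("batch two-species NNLS matches the active-set solver", {
  E <- cbind(get_extinction("NiSO4", wl11, tab),
             get_extinction("CuSO4", wl11, tab))
  set.seed(8)
  P <- sapply(1:200, function(i) {
    p <- E %*% runif(2, -0.5, 2) + rnorm(11, 0, 0.1)
    as.numeric(p)
  })
  got <- qpat:::nnls2_batch(E, P)
  for (i in seq_len(ncol(P))) {
    ref <- pracma::lsqnonneg(E, P[, i])$x
    expect_equal(unname(got[1:2, i]), ref, tolerance = 1e-7)
  }
})

test_that("saturation is invariant to overall pressure scale", {
  set.seed(21)
  members <- sapply(c(-0.002, 0, 0.002), function(a) exp(a * (wl11 - 800)))
  eig <- synthetic_eigenspectra(members, wl11)
  for (i in 1:5) {
    p <- abs(rnorm(11, 1, 0.3)) * sat_absorption_for_test(runif(1, 5, 95),
                                                          wl11)
    k <- runif(1, 0.01, 50)
    expect_equal(lu_unmix(k * p, wl11, tab)$so2_pct,
                 lu_unmix(p, wl11, tab)$so2_pct, tolerance = 1e-8)
    expect_equal(clu_unmix(k * p, wl11, eig$phi_ave, tab)$so2_pct,
                 clu_unmix(p, wl11, eig$phi_ave, tab)$so2_pct,
                 tolerance = 1e-8)
    expect_equal(cc_estimate(k * p, wl11, eig, tab,
                             so2_grid = seq(0, 100, 5))$so2_pct,
                 cc_estimate(p, wl11, eig, tab,
                             so2_grid = seq(0, 100, 5))$so2_pct,
                 tolerance = 1e-8)
  }
})

test_that("convex-cone estimation is exact for in-cone constructions", {
  members <- sapply(c(-0.003, -0.001, 0.002), function(a)
    exp(a * (wl11 - 800)))
  eig <- synthetic_eigenspectra(members, wl11)
  p1 <- eig$spectra[, 1] * sat_absorption_for_test(80, wl11)
  r1 <- cc_estimate(p1, wl11, eig, tab)
  expect_equal(r1$so2_pct, 80)
  expect_lt(r1$residual, 1e-9)
  p2 <- (0.5 * eig$spectra[, 1] + 0.5 * eig$spectra[, 2]) *
    sat_absorption_for_test(40, wl11)
  r2 <- cc_estimate(p2, wl11, eig, tab)
  expect_equal(r2$so2_pct, 40)
  expect_lt(r2$residual, 1e-8)
  # zero-norm input is flagged, not an error
  r0 <- cc_estimate(rep(0, 11), wl11, eig, tab)
  expect_true(is.na(r0$so2_pct))
})

test_that("convex-cone estimator matches the exhaustive-enumeration oracle", {
  wl6 <- seq(730, 830, 20)
  set.seed(99)
  members <- sapply(c(-0.004, -0.001, 0.001, 0.003), function(a)
    exp(a * (wl6 - 800)) * (1 + 0.03 * cos(wl6 / 23)))
  eig <- synthetic_eigenspectra(members, wl6, ref = 810)
  grid <- seq(0, 100, 1)
  for (i in 1:100) {
    w <- -log(runif(4)); w <- w / sum(w)
    s_true <- sample(grid, 1)
    p <- as.numeric(eig$spectra %*% w) *
      sat_absorption_for_test(s_true, wl6) + abs(rnorm(6, 0, 1e-4))
    mine <- cc_estimate(p, wl6, eig, tab, so2_grid = grid)
    ref <- oracle_cc(p, eig, tab, c("HbO2", "Hb"), 1, grid)
    expect_lte(abs(mine$so2_pct - ref$s), 1)
    expect_lt(abs(mine$residual - ref$angle), 1e-6)
  }
})

test_that("saturation and total formulas are exact and guarded", {
  expect_equal(so2_from_conc(1, 0), 100)
  expect_equal(so2_from_conc(1, 1), 50)
  expect_equal(so2_from_conc(3, 1), 75)
  expect_equal(thb_from_conc(3, 1), 4)
  expect_true(is.na(so2_from_conc(0, 0)))
  expect_error(so2_from_conc(-1, 1), class = "qpat_domain_error")
  expect_error(thb_from_conc(1, -1), class = "qpat_domain_error")
})
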