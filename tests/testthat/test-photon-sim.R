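test_that("non-scattering absorber follows the Beer-Lambert law", {
  ph <- uniform_phantom(mu_a = 2, mu_s = 0)
  fl <- simulate_fluence(ph, pa_source("pencil", x_mm = 15),
                         n_photons = 2e4, seed = 1)
  prof <- rowSums(fl$values[, , 1])
  z <- fluence_depths(fl)
  sel <- z <= 2
  fit <- lm(log(prof[sel]) ~ z[sel])
  expect_equal(unname(-coef(fit)[2]), 2, tolerance = 0.02)
})

test_that("transport is deterministic given seed and conserves weight", {
  ph <- uniform_phantom(mu_a = 0.05, mu_s = 20, g = 0.9, nz = 40, nx = 40,
                        wavelengths = c(760, 800))
  f1 <- simulate_fluence(ph, pa_source(), n_photons = 5e3, seed = 42)
  f2 <- simulate_fluence(ph, pa_source(), n_photons = 5e3, seed = 42)
  expect_identical(f1$values, f2$values)
  f3 <- simulate_fluence(ph, pa_source(), n_photons = 5e3, seed = 43)
  expect_false(identical(f1$values, f3$values))
  bal <- with(f1$conservation, absorbed + escaped + roulette_net)
  expect_equal(bal, rep(1, 2), tolerance = 1e-9)
  expect_true(all(f1$values >= 0))
})

test_that("degenerate media and tiny photon budgets are rejected", {
  ph <- uniform_phantom(mu_a = 0, mu_s = 0)
  expect_error(simulate_fluence(ph, pa_source(), n_photons = 1e4, seed = 1),
               class = "qpat_degenerate_error")
  ph2 <- uniform_phantom(mu_a = 0.1, mu_s = 10)
  expect_error(simulate_fluence(ph2, pa_source(), n_photons = 10, seed = 1),
               class = "qpat_config_error")
})

test_that("lateral-average fluence decays monotonically past one transport mfp", {
  ph <- uniform_phantom(mu_a = 0.1, mu_s = 10, g = 0, nz = 80, nx = 120)
  fl <- simulate_fluence(ph, pa_source("bracket", gap_mm = 0, width_mm = 40),
                         n_photons = 1e5, seed = 9)
  z <- fluence_depths(fl)
  prof <- rowMeans(fl$values[, , 1])
  # beyond one transport mean free path (1/mu_s' = 0.1 cm): smooth to tame
  # counting noise, then require a decreasing trend
  sm <- stats::filter(prof, rep(1 / 5, 5), sides = 2)
  sel <- which(z > 0.2 & z < 3 & !is.na(sm))
  expect_true(all(diff(sm[sel]) < 0))
})

test_that("depth-attenuation fit recovers planted exponentials", {
  z <- (0:99) * 0.05
  vals <- array(rep(exp(-2 * z), 20), c(100, 20, 1))
  fl <- synthetic_fluence(vals, 800)
  dm <- fit_depth_attenuation(fl, 800, c(0.5, 3), mu_b = 0)
  expect_equal(dm$mu_f, 2, tolerance = 1e-6)
  expect_equal(dm$fit_r2, 1, tolerance = 1e-9)
  flat <- synthetic_fluence(array(1, c(100, 20, 1)), 800)
  expect_equal(fit_depth_attenuation(flat, 800, c(0.5, 3))$mu_f, 0,
               tolerance = 1e-12)
  neg <- synthetic_fluence(array(c(rep(1, 50), rep(0, 50)), c(100, 20, 1)),
                           800)
  expect_error(fit_depth_attenuation(neg, 800, c(0.5, 3)),
               class = "qpat_log_domain_error")
  expect_error(fit_depth_attenuation(fl, 800, c(0.5, 0.55)),
               class = "qpat_config_error")
})

test_that("eigenspectra extraction honors separable and clustered fields", {
  wl <- wl4
  f_shape <- c(1.4, 1.2, 1.0, 0.9)
  a <- matrix(runif(400, 0.5, 2), 20, 20)
  vals <- array(0, c(20, 20, 4))
  for (k in 1:4) vals[, , k] <- a * f_shape[k]
  fl <- synthetic_fluence(vals, wl)
  mask <- matrix(TRUE, 20, 20)
  eig <- extract_eigenspectra(fl, mask, 800, n_keep = 3)
  for (j in seq_len(ncol(eig$spectra)))
    expect_equal(unname(eig$spectra[, j]), f_shape / f_shape[3],
                 tolerance = 1e-12)
  expect_equal(unname(eig$phi_ave), f_shape / f_shape[3], tolerance = 1e-12)

  # identity reduction: n_keep = number of sampled voxels
  mask2 <- matrix(FALSE, 20, 20); mask2[1, 1:5] <- TRUE
  eig2 <- extract_eigenspectra(fl, mask2, 800, n_keep = 5)
  expect_equal(ncol(eig2$spectra), 5)

  # two-cluster field: medoids are the two generating shapes
  f1 <- c(2.0, 1.5, 1.0, 0.8); f2 <- c(0.9, 0.95, 1.0, 1.3)
  vals2 <- array(0, c(10, 10, 4))
  for (k in 1:4) {
    m <- matrix(f2[k], 10, 10); m[, 1:5] <- f1[k]
    vals2[, , k] <- m
  }
  fl2 <- synthetic_fluence(vals2, wl)
  eig3 <- extract_eigenspectra(fl2, matrix(TRUE, 10, 10), 800, n_keep = 2)
  got <- apply(eig3$spectra, 2, function(s) paste(round(s, 9), collapse = ","))
  want <- c(paste(round(f1 / f1[3], 9), collapse = ","),
            paste(round(f2 / f2[3], 9), collapse = ","))
  expect_setequal(got, want)
  expect_equal(unname(eig3$phi_ave), (f1 / f1[3] + f2 / f2[3]) / 2,
               tolerance = 1e-12)

  # zero fluence under the mask is degenerate
  vals3 <- vals; vals3[1, 1, 2] <- 0
  expect_error(extract_eigenspectra(synthetic_fluence(vals3, wl),
                                    mask, 800, 3),
               class = "qpat_degenerate_error")
})

test_that("member spectra and phi_ave are unit-normalized at the reference", {
  ph <- build_phantom(tube_phantom_spec(sni = 80), tab, wl4)
  fl <- simulate_fluence(ph$phantom, pa_source(), n_photons = 5e3, seed = 3)
  eig <- extract_eigenspectra(fl, absorber_mask(ph$phantom), 800, n_keep = 4)
  iref <- match(800, wl4)
  expect_equal(unname(eig$spectra[iref, ]), rep(1, 4), tolerance = 1e-9)
  expect_equal(eig$phi_ave[iref], 1, tolerance = 1e-9)
  expect_true(all(eig$spectra > 0))
})
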