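# shared fixtures: all built in code, no stored data beyond the bundled
# extinction/tissue tables

tab <- extinction_table()
wl11 <- seq(730, 830, by = 10)
wl4 <- c(750, 780, 800, 830)

# uniform single-wavelength phantom for transport checks
uniform_phantom <- function(mu_a, mu_s, g = 0, nz = 100, nx = 60,
                            voxel_mm = 0.5, wavelengths = 800) {
  nl <- length(wavelengths)
  digital_phantom(array(mu_a, c(nz, nx, nl)), array(mu_s, c(nz, nx, nl)),
                  matrix(g, nz, nx), matrix(1L, nz, nx),
                  c("1" = "background"), voxel_mm, wavelengths)
}

# hand-made fluence container with prescribed values (bypasses the engine)
synthetic_fluence <- function(values, wavelengths, voxel_mm = 0.5) {
  structure(list(values = values, wavelengths = wavelengths,
                 voxel_size_mm = voxel_mm, n_photons = NA, seed = NA,
                 conservation = data.frame(wavelength_nm = wavelengths,
                                           absorbed = NA, escaped = NA,
                                           roulette_net = NA)),
            class = "pa_fluence")
}

# hand-made eigenspectra set from given member spectra (columns)
synthetic_eigenspectra <- function(members, wavelengths, ref = 800) {
  iref <- which.min(abs(wavelengths - ref))
  members <- sweep(members, 2, members[iref, ], "/")
  colnames(members) <- paste0("phi_", seq_len(ncol(members)))
  phi_ave <- rowMeans(members)
  structure(list(spectra = members, phi_ave = phi_ave / phi_ave[iref],
                 samples = members,
                 sample_weights = rep(1 / ncol(members), ncol(members)),
                 wavelengths = wavelengths,
                 reference_wavelength = wavelengths[iref],
                 provenance = "synthetic fixture"),
            class = "pa_eigenspectra")
}

# hemoglobin absorption spectrum at saturation s (unit total concentration)
sat_absorption_for_test <- function(s, wavelengths, table = tab) {
  (s / 100) * get_extinction("HbO2", wavelengths, table) +
    (1 - s / 100) * get_extinction("Hb", wavelengths, table)
}

# brute-force non-negative least squares by dense grid + refinement;
# independent of the active-set solvers used in the package
grid_nnls2 <- function(E, p, hi = NULL, steps = 60, rounds = 3) {
  if (is.null(hi)) hi <- rep(2 * max(abs(p)) / apply(abs(E), 2, max), 2)
  lo <- c(0, 0)
  best <- c(0, 0)
  for (r in seq_len(rounds)) {
    g1 <- seq(lo[1], hi[1], length.out = steps)
    g2 <- seq(lo[2], hi[2], length.out = steps)
    rss <- outer(g1, g2, Vectorize(function(a, b)
      sum((p - E[, 1] * a - E[, 2] * b)^2)))
    i <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    best <- c(g1[i[1]], g2[i[2]])
    w1 <- (hi[1] - lo[1]) / steps; w2 <- (hi[2] - lo[2]) / steps
    lo <- pmax(0, best - 2 * c(w1, w2)); hi <- best + 2 * c(w1, w2)
  }
  best
}

# exact cone projection by enumerating active sets (small generator counts);
# independent oracle for the convex-cone estimator
enum_cone_angle <- function(G, p) {
  n <- ncol(G)
  best <- Inf
  for (m in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) == 0) next
    Gs <- G[, sel, drop = FALSE]
    a <- tryCatch(solve(crossprod(Gs), crossprod(Gs, p)),
                  error = function(e) NULL)
    if (is.null(a) || any(a < -1e-12)) next
    proj <- Gs %*% pmax(a, 0)
    cs <- sum(p * proj) / sqrt(sum(p^2) * sum(proj^2))
    ang <- acos(min(1, max(-1, cs)))
    if (ang < best) best <- ang
  }
  if (!is.finite(best)) best <- pi / 2
  best
}

oracle_cc <- function(p, eig, table, species, ox_scale, so2_grid) {
  angles <- vapply(so2_grid, function(s) {
    mu <- (s / 100) * ox_scale * get_extinction(species[1], eig$wavelengths,
                                                table) +
      (1 - s / 100) * get_extinction(species[2], eig$wavelengths, table)
    enum_cone_angle(eig$spectra * mu, p)
  }, numeric(1))
  list(s = so2_grid[which.min(angles)], angle = min(angles))
}
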