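#' Spectral unmixing of photoacoustic pressure spectra
#'
#' The three estimators mapping a per-pixel (or per-cluster) pressure
#' spectrum to chromophore concentrations, saturation and relative total
#' concentration:
#'
#' * `lu_unmix()` — conventional linear unmixing (LU): non-negative
#'   least-squares fit of the pressure spectrum against the two extinction
#'   spectra, treating pressure as directly proportional to absorption
#'   (flat-fluence assumption).
#' * `clu_unmix()` — compensated linear unmixing (CLU): LU applied to the
#'   spectrum divided by a single compensating fluence spectrum `phi_ave`.
#' * `cc_estimate()` — convex-cone estimation: for each candidate
#'   saturation, the measured spectrum is projected (non-negatively) onto
#'   the cone spanned by the fluence eigenspectra times the candidate
#'   absorption spectrum; the estimate is the candidate minimizing the
#'   angle between the spectrum and its projection.
#'
#' Saturation is scale-invariant for all three methods: the unknown
#' Grueneisen factor and laser energy cancel in the concentration ratio.
#' Totals (`thb_rel`) are therefore reported in relative units.
#'
#' For the sulfate phantom pair set `species = c("NiSO4", "CuSO4")` and
#' `ox_scale = 14.28`: saturation then equals the nickel saturation
#' definition (oxidized-analog concentration divided by 14.28) and
#' `thb_rel` equals the total-sulfate analog.
#'
#' @param p Numeric pressure spectrum (arbitrary units), one value per
#'   wavelength; at least 3 wavelengths.
#' @param wavelengths Wavelengths (nm) of `p`.
#' @param table An [extinction_table()].
#' @param species Character pair `c(ox_name, de_name)`.
#' @param ox_scale Concentration-scaling factor of the saturation
#'   definition: 1 for HbO2/Hb, 14.28 for NiSO4/CuSO4.
#' @return An object of class `pa_unmix` with fields `c_ox`, `c_de`,
#'   `so2_pct` (NA when total concentration is zero), `thb_rel`, `method`,
#'   `residual` (RMS fit residual for LU/CLU, minimal angle in radians for
#'   CC).
#' @examples
#' tab <- extinction_table()
#' wl <- seq(730, 830, 20)
#' p <- build_absorption(c(HbO2 = 2e-3, Hb = 2e-3), wl, tab)
#' lu_unmix(p, wl, tab)
#' @name unmix
NULL

unmix_result <- function(c_ox, c_de, method, residual, ox_scale,
                         species = c("HbO2", "Hb")) {
  total <- c_ox / ox_scale + c_de
  structure(list(c_ox = c_ox, c_de = c_de,
                 so2_pct = if (total > 0) 100 * (c_ox / ox_scale) / total
                           else NA_real_,
                 thb_rel = total, method = method, residual = residual,
                 ox_scale = ox_scale, species = species),
            class = "pa_unmix")
}

#' @export
print.pa_unmix <- function(x, ...) {
  cat(sprintf("%s unmixing [%s/%s]\n", x$method, x$species[1], x$species[2]))
  cat(sprintf("  saturation: %s %%   total (relative): %s\n",
              if (is.na(x$so2_pct)) "undefined" else fmt_num(x$so2_pct),
              fmt_num(x$thb_rel)))
  cat(sprintf("  c_ox = %s, c_de = %s, residual = %s\n",
              fmt_num(x$c_ox), fmt_num(x$c_de), fmt_num(x$residual)))
  invisible(x)
}

#' @export
coef.pa_unmix <- function(object, ...) {
  c(c_ox = object$c_ox, c_de = object$c_de, so2_pct = object$so2_pct,
    thb_rel = object$thb_rel)
}

check_unmix_input <- function(p, wavelengths) {
  if (length(p) != length(wavelengths))
    stop_qpat("pressure spectrum and wavelengths differ in length",
              class = "qpat_domain_error")
  if (length(p) < 3)
    stop_qpat("unmixing needs at least 3 wavelengths",
              class = "qpat_domain_error")
  if (any(!is.finite(p)))
    stop_qpat("pressure spectrum must be finite", class = "qpat_domain_error")
}

#' @rdname unmix
#' @export
lu_unmix <- function(p, wavelengths, table = extinction_table(),
                     species = c("HbO2", "Hb"), ox_scale = 1) {
  check_unmix_input(p, wavelengths)
  E <- cbind(get_extinction(species[1], wavelengths, table),
             get_extinction(species[2], wavelengths, table))
  if (all(p == 0))
    return(unmix_result(0, 0, "LU", 0, ox_scale, species))
  fit <- pracma::lsqnonneg(E, as.numeric(p))
  unmix_result(fit$x[1], fit$x[2], "LU",
               sqrt(sum((p - E %*% fit$x)^2) / length(p)), ox_scale, species)
}

#' @rdname unmix
#' @param phi_ave Compensating fluence spectrum on `wavelengths`
#'   (strictly positive), or a `pa_eigenspectra` object whose `phi_ave` is
#'   used.
#' @export
clu_unmix <- function(p, wavelengths, phi_ave, table = extinction_table(),
                      species = c("HbO2", "Hb"), ox_scale = 1) {
  check_unmix_input(p, wavelengths)
  if (inherits(phi_ave, "pa_eigenspectra")) {
    stopifnot(isTRUE(all.equal(as.numeric(phi_ave$wavelengths),
                               as.numeric(wavelengths))))
    phi_ave <- phi_ave$phi_ave
  }
  if (length(phi_ave) == 1) phi_ave <- rep(phi_ave, length(p))
  if (length(phi_ave) != length(p) || any(!is.finite(phi_ave)) ||
      any(phi_ave <= 0))
    stop_qpat("phi_ave must be strictly positive on the grid",
              class = "qpat_compensation_error")
  out <- lu_unmix(as.numeric(p) / phi_ave, wavelengths, table, species,
                  ox_scale)
  out$method <- "CLU"
  out
}

#' @rdname unmix
#' @param eig A `pa_eigenspectra` set (members span the fluence cone).
#' @param so2_grid Candidate saturations (percent), default 0--100 in 0.5
#'   steps; ties resolve to the smallest candidate.
#' @export
cc_estimate <- function(p, wavelengths, eig, table = extinction_table(),
                        species = c("HbO2", "Hb"), ox_scale = 1,
                        so2_grid = seq(0, 100, by = 0.5)) {
  check_unmix_input(p, wavelengths)
  stopifnot(inherits(eig, "pa_eigenspectra"))
  if (length(so2_grid) < 1 || any(so2_grid < 0 | so2_grid > 100))
    stop_qpat("so2_grid must be non-empty with values in [0, 100]",
              class = "qpat_config_error")
  if (length(p) < 4)
    warning("convex-cone estimation below 4 wavelengths may be unstable")
  p <- as.numeric(p)
  if (sqrt(sum(p^2)) <= 0)
    return(unmix_result(0, 0, "CC", NA_real_, ox_scale, species))
  so2_grid <- sort(so2_grid)
  Phi <- eig$spectra
  best <- list(angle = Inf, s = NA_real_, alpha = NULL)
  for (s in so2_grid) {
    mu <- sat_absorption(s, wavelengths, table, species, ox_scale)
    G <- Phi * mu  # columns: phi_i(lambda) * mu_a(lambda; s)
    fit <- pracma::lsqnonneg(G, p)
    proj <- as.numeric(G %*% fit$x)
    # atan2 form of the angle between p and its cone projection: exact for
    # tiny angles where acos(cos_sim) loses all precision
    np <- sqrt(sum(proj^2))
    ang <- if (np == 0) pi / 2 else atan2(sqrt(sum((p - proj)^2)), np)
    if (ang < best$angle - 1e-15) best <- list(angle = ang, s = s,
                                               alpha = fit$x)
  }
  total <- sum(best$alpha)  # generators carry unit total concentration
  unmix_result(c_ox = ox_scale * (best$s / 100) * total,
               c_de = (1 - best$s / 100) * total,
               "CC", best$angle, ox_scale, species)
}

#' Saturation and total concentration from fitted concentrations
#'
#' Exact closed forms: saturation is the oxidized fraction (after dividing
#' the oxidized-analog concentration by `ox_scale`) in percent, total is
#' the scaled sum. With `ox_scale = 1` these are the oxygen-saturation and
#' total-hemoglobin definitions; with `ox_scale = 14.28` and sulfate
#' concentrations they are the nickel-saturation and total-sulfate analogs.
#'
#' @param c_ox,c_de Non-negative concentrations (vectorized).
#' @param ox_scale Concentration-scaling factor (see [unmix]).
#' @return Percentage in \[0, 100\] (`NA` where both concentrations are
#'   zero), or the relative total.
#' @examples
#' so2_from_conc(3, 1)      # 75
#' thb_from_conc(3, 1)      # 4
#' so2_from_conc(14.28, 1, ox_scale = 14.28)  # 50: nickel saturation
#' @export
so2_from_conc <- function(c_ox, c_de, ox_scale = 1) {
  if (any(c_ox < 0, na.rm = TRUE) || any(c_de < 0, na.rm = TRUE))
    stop_qpat("concentrations must be non-negative",
              class = "qpat_domain_error")
  total <- c_ox / ox_scale + c_de
  ifelse(total > 0, 100 * (c_ox / ox_scale) / total, NA_real_)
}

#' @rdname so2_from_conc
#' @export
thb_from_conc <- function(c_ox, c_de, ox_scale = 1) {
  if (any(c_ox < 0, na.rm = TRUE) || any(c_de < 0, na.rm = TRUE))
    stop_qpat("concentrations must be non-negative",
              class = "qpat_domain_error")
  c_ox / ox_scale + c_de
}

# Exact non-negative least squares for a two-column design, vectorized over
# many right-hand sides. Solves min ||p - E c||^2, c >= 0 for each column of
# P by comparing the unconstrained solution with the two single-column
# boundary solutions (exact for 2 variables).
nnls2_batch <- function(E, P) {
  g11 <- sum(E[, 1]^2); g22 <- sum(E[, 2]^2); g12 <- sum(E[, 1] * E[, 2])
  det <- g11 * g22 - g12^2
  b1 <- crossprod(E[, 1], P)[1, ]; b2 <- crossprod(E[, 2], P)[1, ]
  # unconstrained
  c1 <- (g22 * b1 - g12 * b2) / det
  c2 <- (g11 * b2 - g12 * b1) / det
  ok <- c1 >= 0 & c2 >= 0
  # boundary candidates
  a1 <- pmax(0, b1 / g11)   # c2 = 0
  a2 <- pmax(0, b2 / g22)   # c1 = 0
  pn <- colSums(P^2)
  r1 <- pn - 2 * a1 * b1 + a1^2 * g11
  r2 <- pn - 2 * a2 * b2 + a2^2 * g22
  use1 <- r1 <= r2
  out1 <- ifelse(ok, c1, ifelse(use1, a1, 0))
  out2 <- ifelse(ok, c2, ifelse(use1, 0, a2))
  res <- ifelse(ok, pmax(0, pn - c1 * b1 - c2 * b2), pmin(r1, r2))
  rbind(c_ox = out1, c_de = out2, rss = pmax(0, res))
}
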