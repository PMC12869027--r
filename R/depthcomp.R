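#' Multispectral beamformed pressure map
#'
#' Container for per-wavelength 2-D beamformed pressure images. Rows index
#' depth (shallowest first), columns lateral position. The depth of row `i`
#' (1-based) is `z0_cm + (i - 1) * pixel_size_mm / 10` cm from the
#' transducer face.
#'
#' @param images Numeric array `nz x nx x n_wavelengths`.
#' @param wavelengths Wavelengths (nm) of the third dimension.
#' @param pixel_size_mm Pixel edge length (mm), > 0.
#' @param z0_cm Depth of the first row (cm), >= 0.
#' @param mask Optional logical region-of-interest image (`nz x nx`).
#' @return An object of class `pa_pressure_map`.
#' @export
pressure_map <- function(images, wavelengths, pixel_size_mm, z0_cm = 0,
                         mask = NULL) {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(dim(images)) == 3,
            dim(images)[3] == length(wavelengths))
  if (pixel_size_mm <= 0 || z0_cm < 0)
    stop_qpat("pixel_size_mm must be > 0 and z0_cm >= 0",
              class = "qpat_domain_error")
  if (!is.null(mask))
    stopifnot(is.logical(mask), all(dim(mask) == dim(images)[1:2]))
  structure(list(images = images, wavelengths = wavelengths,
                 pixel_size_mm = pixel_size_mm, z0_cm = z0_cm, mask = mask),
            class = "pa_pressure_map")
}

#' @export
print.pa_pressure_map <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Pressure map: %d x %d pixels (%.2f mm), %d wavelengths (%g-%g nm), z0 = %g cm\n",
              d[1], d[2], x$pixel_size_mm, d[3], min(x$wavelengths),
              max(x$wavelengths), x$z0_cm))
  invisible(x)
}

#' Depth coordinates of a pressure map
#'
#' @param m A [pressure_map()].
#' @return Depth (cm) of each pixel row.
#' @export
map_depths <- function(m) {
  m$z0_cm + (seq_len(dim(m$images)[1]) - 1) * m$pixel_size_mm / 10
}

#' Depth-wise compensation of a pressure map
#'
#' Multiplies each pixel at depth `z` (cm) by `exp((mu_f + mu_b) * z)`,
#' identically at every wavelength, undoing the modeled exponential decay
#' of optical fluence (`mu_f`) and acoustic attenuation (`mu_b`). The
#' factor is >= 1 and non-decreasing in depth for non-negative
#' coefficients; because it is wavelength-independent it leaves saturation
#' estimates unchanged and only rescales totals.
#'
#' @param m A [pressure_map()].
#' @param model A [depth_model()].
#' @return A compensated [pressure_map()] of the same shape.
#' @export
compensate_depth <- function(m, model) {
  stopifnot(inherits(m, "pa_pressure_map"), inherits(model, "pa_depth_model"))
  fac <- exp((model$mu_f + model$mu_b) * map_depths(m))
  out <- m
  out$images <- m$images * array(fac, dim(m$images))
  out
}

#' Quantitative saturation / total-concentration maps
#'
#' @param m A [pressure_map()].
#' @param table,species,ox_scale See [unmix].
#' @param phi_ave Compensating spectrum (or `pa_eigenspectra`) for the
#'   CLU-based pipelines.
#' @param model A [depth_model()] for the depth-compensation stage.
#' @param floor_frac Amplitude floor: pixels whose maximum cross-wavelength
#'   amplitude is below `floor_frac` times the 99th-percentile amplitude
#'   are flagged undefined (saturation `NA`, total 0).
#' @return An object of class `pa_quant_maps`: `so2_map` (percent, `NA`
#'   where undefined), `thb_map` (relative units), `method`, `depth_model`.
#'
#' @details
#' `lu_maps()` applies plain linear unmixing per pixel.
#' `clu_maps()` applies spectrally compensated unmixing per pixel.
#' `isdc_maps()` is the integrated spectral and depth compensation
#' pipeline: saturation from CLU (depth compensation cancels there) and
#' total concentration from CLU applied to the depth-compensated map.
#' @export
lu_maps <- function(m, table = extinction_table(),
                    species = c("HbO2", "Hb"), ox_scale = 1,
                    floor_frac = 0.05) {
  batch_maps(m, NULL, table, species, ox_scale, floor_frac, "LU", NULL)
}

#' @rdname lu_maps
#' @export
clu_maps <- function(m, phi_ave, table = extinction_table(),
                     species = c("HbO2", "Hb"), ox_scale = 1,
                     floor_frac = 0.05) {
  batch_maps(m, phi_ave, table, species, ox_scale, floor_frac, "CLU", NULL)
}

#' @rdname lu_maps
#' @export
isdc_maps <- function(m, phi_ave, model, table = extinction_table(),
                      species = c("HbO2", "Hb"), ox_scale = 1,
                      floor_frac = 0.05) {
  stopifnot(inherits(model, "pa_depth_model"))
  mc <- compensate_depth(m, model)
  # the amplitude floor is judged on the raw map: compensation amplifies
  # deep noise and would otherwise unflag it
  flag <- amplitude_floor(m, floor_frac)
  out <- batch_maps(mc, phi_ave, table, species, ox_scale, floor_frac,
                    "ISDC", flag)
  out$depth_model <- model
  out
}

amplitude_floor <- function(m, floor_frac) {
  amp <- apply(abs(m$images), c(1, 2), max)
  low <- amp < floor_frac * quantile(amp, 0.99)
  if (!is.null(m$mask)) low <- low | !m$mask
  low
}

batch_maps <- function(m, phi_ave, table, species, ox_scale, floor_frac,
                       method, flag) {
  stopifnot(inherits(m, "pa_pressure_map"))
  d <- dim(m$images)
  wl <- m$wavelengths
  if (length(wl) < 3)
    stop_qpat("unmixing needs at least 3 wavelengths",
              class = "qpat_domain_error")
  if (is.null(flag)) flag <- amplitude_floor(m, floor_frac)
  P <- t(matrix(m$images, d[1] * d[2], d[3]))  # wavelengths x pixels
  if (!is.null(phi_ave)) {
    if (inherits(phi_ave, "pa_eigenspectra")) phi_ave <- phi_ave$phi_ave
    if (length(phi_ave) != length(wl) || any(phi_ave <= 0) ||
        any(!is.finite(phi_ave)))
      stop_qpat("phi_ave must be strictly positive on the grid",
                class = "qpat_compensation_error")
    P <- P / phi_ave
  }
  E <- cbind(get_extinction(species[1], wl, table),
             get_extinction(species[2], wl, table))
  fit <- nnls2_batch(E, P)
  so2 <- matrix(so2_from_conc(fit["c_ox", ], fit["c_de", ], ox_scale),
                d[1], d[2])
  thb <- matrix(thb_from_conc(fit["c_ox", ], fit["c_de", ], ox_scale),
                d[1], d[2])
  so2[flag] <- NA_real_
  thb[flag] <- 0
  structure(list(so2_map = so2, thb_map = thb, method = method,
                 depth_model = NULL, wavelengths = wl,
                 pixel_size_mm = m$pixel_size_mm, z0_cm = m$z0_cm),
            class = "pa_quant_maps")
}

#' @export
print.pa_quant_maps <- function(x, ...) {
  cat(sprintf("%s quantitative maps: %d x %d pixels\n", x$method,
              nrow(x$so2_map), ncol(x$so2_map)))
  ok <- !is.na(x$so2_map)
  cat(sprintf("  defined pixels: %d (%.1f%%), saturation %s-%s %%, median total %s\n",
              sum(ok), 100 * mean(ok),
              fmt_num(suppressWarnings(min(x$so2_map, na.rm = TRUE))),
              fmt_num(suppressWarnings(max(x$so2_map, na.rm = TRUE))),
              fmt_num(stats::median(x$thb_map[ok]))))
  invisible(x)
}

#' @export
plot.pa_quant_maps <- function(x, which = c("so2", "thb"), ...) {
  which <- match.arg(which)
  img <- if (which == "so2") x$so2_map else x$thb_map
  z <- x$z0_cm + (seq_len(nrow(img)) - 1) * x$pixel_size_mm / 10
  xx <- (seq_len(ncol(img)) - 1) * x$pixel_size_mm / 10
  image(xx, z, t(img)[, rev(seq_len(nrow(img)))],
        col = hcl.colors(64, if (which == "so2") "RdYlBu" else "Inferno"),
        xlab = "lateral x (cm)", ylab = "depth z (cm)",
        main = sprintf("%s %s map", x$method,
                       if (which == "so2") "saturation (%)" else "relative total"),
        ...)
  invisible(x)
}
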