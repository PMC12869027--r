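#' Nickel saturation and total sulfate from sulfate concentrations
#'
#' The phantom analogs of oxygen saturation and total hemoglobin for
#' NiSO4/CuSO4 solutions. The factor 14.28 rescales the NiSO4
#' concentration to account for the higher absorption of CuSO4:
#' `sni = (c_ni/14.28) / (c_ni/14.28 + c_cu) * 100` and
#' `tsf = c_ni/14.28 + c_cu`.
#'
#' @param c_ni,c_cu Non-negative NiSO4 / CuSO4 concentrations (vectorized).
#' @return Percentage in \[0, 100\] (`NA` when both are zero), or the total
#'   sulfate in relative units.
#' @examples
#' sni_from_concentrations(14.28, 0)  # 100
#' sni_from_concentrations(14.28, 1)  # 50
#' tsf_from_concentrations(14.28, 1)  # 2
#' @export
sni_from_concentrations <- function(c_ni, c_cu) {
  so2_from_conc(c_ni, c_cu, ox_scale = 14.28)
}

#' @rdname sni_from_concentrations
#' @export
tsf_from_concentrations <- function(c_ni, c_cu) {
  thb_from_conc(c_ni, c_cu, ox_scale = 14.28)
}

#' Sulfate concentrations realizing a target nickel saturation
#'
#' Algebraic inverse of the saturation/total definitions: returns the
#' `(c_ni, c_cu)` pair with the requested nickel saturation and total
#' sulfate.
#'
#' @param target_sni Target saturation in percent, \[0, 100\].
#' @param tsf Target total sulfate (> 0, relative units).
#' @return Named numeric vector `c(NiSO4 = ..., CuSO4 = ...)`.
#' @examples
#' concentrations_for_sni(100, 1)  # c(NiSO4 = 14.28, CuSO4 = 0)
#' @export
concentrations_for_sni <- function(target_sni, tsf) {
  if (target_sni < 0 || target_sni > 100)
    stop_qpat("target_sni must lie in [0, 100]", class = "qpat_domain_error")
  if (tsf <= 0)
    stop_qpat("tsf must be positive", class = "qpat_domain_error")
  c(NiSO4 = 14.28 * tsf * target_sni / 100,
    CuSO4 = tsf * (1 - target_sni / 100))
}

#' Phantom specifications
#'
#' Geometry and composition descriptions consumed by [build_phantom()].
#' Three kinds emulate the package's validation phantoms:
#'
#' * `tube_phantom_spec()` — a depth-varying tube phantom: sulfate-filled
#'   tube cross-sections (filled disks in the imaging plane, ~15 per
#'   B-scan) at several depths in an Intralipid-like scattering background.
#' * `sphere_phantom_spec()` — an ovary-mimicking sphere (~2 cm) with four
#'   tubes inside (two at 40% and two at 75% nickel saturation) and two
#'   outside (one at each level).
#' * `clinical_phantom_spec()` — a layered medium (muscle, peritoneal
#'   fluid, ovary) with embedded hemoglobin-filled vessels.
#'
#' All geometry defaults are configurable; tissue optical properties come
#' from the bundled background table.
#'
#' @param sni Nickel saturation(s) in percent; recycled over tubes.
#' @param tsf Total sulfate (relative units; equals the tube absorption
#'   coefficient at 800 nm in cm^-1 with the bundled tables).
#' @param tube_depths_mm,tube_x_mm Depth and lateral tube-center
#'   coordinates; their outer product gives the cross-section layout.
#' @param stagger_mm Lateral shift added per depth level so that deeper
#'   tubes are not vertically aligned with shallower ones (as when a
#'   single tube is threaded through a staggered hole grid); avoids
#'   composition-dependent self-shadowing dominating the fluence.
#' @param tube_diameter_mm Tube diameter (mm).
#' @param width_mm,depth_mm,voxel_size_mm Domain size and voxel pitch.
#' @param g Scattering anisotropy for all tissues.
#' @param bg_mu_sp_800 Background reduced scattering coefficient at 800 nm
#'   (cm^-1); the bundled Intralipid-like dispersion curve is rescaled to
#'   this value. The default is the ~1 cm^-1 Intralipid condition rescaled
#'   so the imaged depth range spans the same number of transport mean
#'   free paths in 2-D transport as in the bench experiment it emulates.
#' @param noise_snr_db Forward-model signal-to-noise target (dB).
#' @return A list of class `pa_phantom_spec`.
#' @export
tube_phantom_spec <- function(sni = c(20, 60, 80, 100), tsf = 1.0,
                              tube_depths_mm = c(5, 9, 13, 17, 21),
                              tube_x_mm = c(15, 20, 25),
                              stagger_mm = 2,
                              tube_diameter_mm = 1.2,
                              width_mm = 40, depth_mm = 30,
                              voxel_size_mm = 0.25, g = 0.9,
                              bg_mu_sp_800 = 2, noise_snr_db = 30) {
  structure(list(kind = "tube", sni = sni, tsf = tsf,
                 tube_depths_mm = tube_depths_mm, tube_x_mm = tube_x_mm,
                 stagger_mm = stagger_mm,
                 tube_diameter_mm = tube_diameter_mm, width_mm = width_mm,
                 depth_mm = depth_mm, voxel_size_mm = voxel_size_mm, g = g,
                 bg_mu_sp_800 = bg_mu_sp_800, noise_snr_db = noise_snr_db),
            class = "pa_phantom_spec")
}

#' @rdname tube_phantom_spec
#' @param sphere_diameter_mm Sphere diameter (mm).
#' @param sphere_center_mm Sphere center `c(x, z)` (mm).
#' @export
sphere_phantom_spec <- function(sni = c(40, 75), tsf = 1.0,
                                sphere_diameter_mm = 20,
                                sphere_center_mm = c(20, 18),
                                tube_diameter_mm = 1.2,
                                width_mm = 40, depth_mm = 35,
                                voxel_size_mm = 0.25, g = 0.9,
                                bg_mu_sp_800 = 2, noise_snr_db = 30) {
  structure(list(kind = "sphere", sni = sni, tsf = tsf,
                 sphere_diameter_mm = sphere_diameter_mm,
                 sphere_center_mm = sphere_center_mm,
                 tube_diameter_mm = tube_diameter_mm, width_mm = width_mm,
                 depth_mm = depth_mm, voxel_size_mm = voxel_size_mm, g = g,
                 bg_mu_sp_800 = bg_mu_sp_800, noise_snr_db = noise_snr_db),
            class = "pa_phantom_spec")
}

#' @rdname tube_phantom_spec
#' @param muscle_mm,fluid_mm Layer thicknesses (mm).
#' @param ovary_diameter_mm Ovary diameter (mm).
#' @param vessels Data frame with columns `x_mm, z_mm, diameter_mm,
#'   so2_pct, c_total` (hemoglobin molar concentration); may have zero
#'   rows.
#' @export
clinical_phantom_spec <- function(muscle_mm = 5, fluid_mm = 10,
                                  ovary_diameter_mm = 20,
                                  vessels = data.frame(
                                    x_mm = c(16, 24, 20),
                                    z_mm = c(22, 26, 30),
                                    diameter_mm = c(2, 2, 1.5),
                                    so2_pct = c(85, 75, 80),
                                    c_total = 5e-3),
                                  width_mm = 40, depth_mm = 40,
                                  voxel_size_mm = 0.25, g = 0.9,
                                  noise_snr_db = 30) {
  structure(list(kind = "clinical", muscle_mm = muscle_mm,
                 fluid_mm = fluid_mm, ovary_diameter_mm = ovary_diameter_mm,
                 vessels = vessels, width_mm = width_mm, depth_mm = depth_mm,
                 voxel_size_mm = voxel_size_mm, g = g,
                 noise_snr_db = noise_snr_db),
            class = "pa_phantom_spec")
}

# interpolate a tissue property from the bundled background table
tissue_property <- function(tissue, what, wavelengths,
                            tissues = read_tissue_table()) {
  d <- tissues[tissues$tissue == tissue, ]
  if (nrow(d) == 0)
    stop_qpat("unknown tissue '", tissue, "'", class = "qpat_lookup_error")
  approx(d$wavelength_nm, d[[what]], xout = wavelengths)$y
}

read_tissue_table <- function(path = system.file("extdata", "tissues.csv",
                                                 package = "qpat")) {
  read.csv(path, comment.char = "#")
}

#' Voxelize a phantom specification
#'
#' Builds the per-voxel optical-property fields: the background scattering
#' medium gets `mu_s = mu_s' / (1 - g)` from the bundled tissue table, and
#' each absorber structure gets `mu_a` assembled from its chromophore
#' concentrations via [build_absorption()]. Labels distinguish every
#' structure; the returned ground truth records each structure's true
#' saturation and total concentration.
#'
#' @param spec A `pa_phantom_spec`.
#' @param table An [extinction_table()].
#' @param wavelengths Simulation wavelengths (nm).
#' @return List with elements `phantom` (a [digital_phantom()]) and
#'   `truth` (data frame: `structure_id, label, true_sni_pct, true_tsf`).
#' @export
build_phantom <- function(spec, table = extinction_table(),
                          wavelengths = seq(730, 830, by = 10)) {
  stopifnot(inherits(spec, "pa_phantom_spec"))
  wavelengths <- as.numeric(wavelengths)
  dx <- spec$voxel_size_mm
  nz <- round(spec$depth_mm / dx); nx <- round(spec$width_mm / dx)
  nl <- length(wavelengths)
  zc <- (seq_len(nz) - 0.5) * dx   # voxel centers, mm
  xc <- (seq_len(nx) - 0.5) * dx
  Z <- matrix(zc, nz, nx); X <- matrix(xc, nz, nx, byrow = TRUE)

  mu_a <- array(0, c(nz, nx, nl)); mu_s <- array(0, c(nz, nx, nl))
  bg_a <- tissue_property("intralipid", "mu_a", wavelengths)
  bg_sp <- tissue_property("intralipid", "mu_sp", wavelengths)
  if (!is.null(spec$bg_mu_sp_800)) {
    at800 <- tissue_property("intralipid", "mu_sp", 800)
    bg_sp <- bg_sp * spec$bg_mu_sp_800 / at800
  }
  bg_s <- bg_sp / (1 - spec$g)
  for (k in seq_len(nl)) { mu_a[, , k] <- bg_a[k]; mu_s[, , k] <- bg_s[k] }
  labels <- matrix(1L, nz, nx)
  label_names <- c("1" = "background")
  truth <- data.frame(structure_id = integer(), label = character(),
                      true_sni_pct = numeric(), true_tsf = numeric())

  put_disk <- function(x0, z0, diam) {
    (X - x0)^2 + (Z - z0)^2 <= (diam / 2)^2
  }
  add_structure <- function(mask, name, mua_spec, sni = NA, tsf = NA) {
    if (!any(mask))
      stop_qpat("structure '", name, "' lies outside the voxel grid",
                class = "qpat_construction_error")
    id <- max(labels) + 1L
    labels[mask] <<- id
    for (k in seq_len(nl)) {
      m <- mu_a[, , k]; m[mask] <- mua_spec[k]; mu_a[, , k] <<- m
    }
    label_names[as.character(id)] <<- name
    truth <<- rbind(truth, data.frame(structure_id = id, label = name,
                                      true_sni_pct = sni, true_tsf = tsf))
  }
  set_tissue <- function(mask, name, tissue) {
    id <- max(labels) + 1L
    labels[mask] <<- id
    ta <- tissue_property(tissue, "mu_a", wavelengths)
    ts <- tissue_property(tissue, "mu_sp", wavelengths) / (1 - spec$g)
    for (k in seq_len(nl)) {
      m <- mu_a[, , k]; m[mask] <- ta[k]; mu_a[, , k] <<- m
      m <- mu_s[, , k]; m[mask] <- ts[k]; mu_s[, , k] <<- m
    }
    label_names[as.character(id)] <<- name
  }

  if (spec$kind == "tube") {
    layout <- expand.grid(z = spec$tube_depths_mm, x = spec$tube_x_mm)
    di <- match(layout$z, spec$tube_depths_mm)
    nlev <- length(spec$tube_depths_mm)
    layout$x <- layout$x + (di - (nlev + 1) / 2) * (spec$stagger_mm %||% 0)
    sni <- rep(spec$sni, length.out = nrow(layout))
    for (i in seq_len(nrow(layout))) {
      conc <- concentrations_for_sni(sni[i], spec$tsf)
      mua <- build_absorption(conc, wavelengths, table)
      add_structure(put_disk(layout$x[i], layout$z[i], spec$tube_diameter_mm),
                    sprintf("tube_%02d", i), mua, sni[i], spec$tsf)
    }
  } else if (spec$kind == "sphere") {
    ctr <- spec$sphere_center_mm; r <- spec$sphere_diameter_mm / 2
    set_tissue(put_disk(ctr[1], ctr[2], spec$sphere_diameter_mm),
               "ovary_sphere", "ovary")
    # four tubes inside (two per saturation level), two outside
    inside <- rbind(c(ctr[1] - r / 2, ctr[2] - r / 2),
                    c(ctr[1] + r / 2, ctr[2] - r / 2),
                    c(ctr[1] - r / 2, ctr[2] + r / 2),
                    c(ctr[1] + r / 2, ctr[2] + r / 2))
    outside <- rbind(c(ctr[1] - r - 6, ctr[2]), c(ctr[1] + r + 6, ctr[2]))
    pos <- rbind(inside, outside)
    sni <- c(spec$sni[1], spec$sni[2], spec$sni[1], spec$sni[2],
             spec$sni[1], spec$sni[2])
    where <- c(rep("in", 4), rep("out", 2))
    for (i in seq_len(nrow(pos))) {
      conc <- concentrations_for_sni(sni[i], spec$tsf)
      mua <- build_absorption(conc, wavelengths, table)
      add_structure(put_disk(pos[i, 1], pos[i, 2], spec$tube_diameter_mm),
                    sprintf("tube_%s_%02d", where[i], i), mua, sni[i],
                    spec$tsf)
    }
  } else if (spec$kind == "clinical") {
    set_tissue(Z <= spec$muscle_mm, "muscle", "muscle")
    set_tissue(Z > spec$muscle_mm & Z <= spec$muscle_mm + spec$fluid_mm,
               "peritoneal_fluid", "peritoneal_fluid")
    ctr <- c(spec$width_mm / 2,
             spec$muscle_mm + spec$fluid_mm + spec$ovary_diameter_mm / 2)
    set_tissue(put_disk(ctr[1], ctr[2], spec$ovary_diameter_mm),
               "ovary", "ovary")
    v <- spec$vessels
    if (nrow(v) > 0) {
      for (i in seq_len(nrow(v))) {
        conc <- c(HbO2 = v$c_total[i] * v$so2_pct[i] / 100,
                  Hb = v$c_total[i] * (1 - v$so2_pct[i] / 100))
        mua <- build_absorption(conc, wavelengths, table)
        add_structure(put_disk(v$x_mm[i], v$z_mm[i], v$diameter_mm[i]),
                      sprintf("vessel_%02d", i), mua, v$so2_pct[i],
                      v$c_total[i])
      }
    }
  } else stop_qpat("unknown phantom kind", class = "qpat_construction_error")

  ph <- digital_phantom(mu_a, mu_s, matrix(spec$g, nz, nx), labels,
                        label_names, dx, wavelengths)
  list(phantom = ph, truth = truth)
}

#' Forward photoacoustic pressure model
#'
#' Generates a multispectral beamformed pressure map from a phantom and its
#' simulated fluence: `p = Gamma * phi * mu_a` voxelwise, optionally decayed
#' by an acoustic attenuation factor `exp(-mu_b z)` (so the depth
#' compensation stage has a measurement effect to undo), plus seeded
#' additive white Gaussian noise scaled to `noise_snr_db` relative to the
#' RMS of the absorber-voxel signal.
#'
#' @param phantom A [digital_phantom()].
#' @param fluence The matching [simulate_fluence()] result.
#' @param gamma Grueneisen scale: scalar or `nz x nx` matrix.
#' @param noise_snr_db Signal-to-noise target in dB (`Inf` disables noise).
#' @param mu_b Acoustic attenuation coefficient (cm^-1) applied to emulate
#'   the measurement.
#' @param seed Seed for the noise draw (required if noise is finite).
#' @return A [pressure_map()].
#' @export
forward_pressure <- function(phantom, fluence, gamma = 1,
                             noise_snr_db = Inf, mu_b = 0, seed = NULL) {
  stopifnot(inherits(phantom, "pa_phantom"), inherits(fluence, "pa_fluence"))
  d <- dim(phantom$mu_a)
  if (!all(dim(fluence$values) == d))
    stop_qpat("fluence and phantom shapes differ",
              class = "qpat_construction_error")
  if (is.matrix(gamma)) stopifnot(all(dim(gamma) == d[1:2]))
  img <- array(0, d)
  z <- (seq_len(d[1]) - 1) * phantom$voxel_size_mm / 10
  dec <- exp(-mu_b * z)
  for (k in seq_len(d[3]))
    img[, , k] <- gamma * fluence$values[, , k] * phantom$mu_a[, , k] * dec
  if (is.finite(noise_snr_db)) {
    if (is.null(seed))
      stop_qpat("seed is required when noise is enabled",
                class = "qpat_config_error")
    ab <- phantom$labels != 1L
    sig <- sqrt(mean(img[array(ab, d)]^2))
    sigma <- sig / 10^(noise_snr_db / 20)
    img <- img + with_seed(seed, array(rnorm(length(img), 0, sigma), d))
  }
  pressure_map(img, phantom$wavelengths, phantom$voxel_size_mm, z0_cm = 0)
}
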