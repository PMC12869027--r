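#' Construct a digital phantom
#'
#' A 2-D voxel description of optical properties used by the Monte-Carlo
#' transport engine: per-voxel, per-wavelength absorption and scattering,
#' per-voxel anisotropy, and an integer label image identifying tissues and
#' absorbers. Rows index depth (z, downward from the transducer face),
#' columns lateral position (x).
#'
#' @param mu_a,mu_s Numeric arrays `nz x nx x n_wavelengths` (cm^-1),
#'   non-negative.
#' @param g Numeric matrix `nz x nx`, anisotropy in \[-1, 1\].
#' @param labels Integer matrix `nz x nx`, tissue/absorber IDs.
#' @param label_names Named character/integer mapping: names are labels as
#'   character IDs, values the structure names.
#' @param voxel_size_mm Voxel edge length in mm.
#' @param wavelengths Wavelengths (nm) of the third array dimension.
#' @return An object of class `pa_phantom`.
#' @export
digital_phantom <- function(mu_a, mu_s, g, labels, label_names,
                            voxel_size_mm, wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  stopifnot(length(dim(mu_a)) == 3, all(dim(mu_a) == dim(mu_s)),
            dim(mu_a)[3] == length(wavelengths),
            all(dim(g) == dim(mu_a)[1:2]), all(dim(labels) == dim(g)),
            voxel_size_mm > 0)
  if (any(mu_a < 0) || any(mu_s < 0))
    stop_qpat("mu_a and mu_s must be non-negative",
              class = "qpat_domain_error")
  if (any(abs(g) > 1))
    stop_qpat("anisotropy g must lie in [-1, 1]", class = "qpat_domain_error")
  ids <- sort(unique(as.integer(labels)))
  if (!all(as.character(ids) %in% names(label_names)))
    stop_qpat("all label IDs must appear in label_names",
              class = "qpat_domain_error")
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, labels = labels,
                 label_names = label_names, voxel_size_mm = voxel_size_mm,
                 wavelengths = wavelengths),
            class = "pa_phantom")
}

#' @export
print.pa_phantom <- function(x, ...) {
  d <- dim(x$mu_a)
  cat(sprintf("Digital phantom: %d x %d voxels (%.2f mm), %d wavelengths (%g-%g nm)\n",
              d[1], d[2], x$voxel_size_mm, d[3], min(x$wavelengths),
              max(x$wavelengths)))
  cat("Structures:", paste(unique(x$label_names), collapse = ", "), "\n")
  invisible(x)
}

#' Illumination source description
#'
#' Defines where photons enter the top surface of the phantom. The
#' `"bracket"` geometry idealizes side-fiber illumination: two surface
#' line segments flanking a central detector gap, each emitting into a
#' half-angle around the downward normal. The default (`gap_mm = 0` with
#' wide segments) emulates the diffuse reflective sheath of the probe,
#' which spreads the four-fiber output into near-uniform surface
#' illumination; set a positive gap for bare side-fire fibers. A
#' `"pencil"` source (a normal zero-width beam at `x_mm`) is provided for
#' analytic checks.
#'
#' @param type `"bracket"` or `"pencil"`.
#' @param x_mm Pencil-beam lateral position (mm), pencil type only.
#' @param gap_mm Width of the central detector gap (mm), bracket type.
#' @param width_mm Width of each flanking emitting segment (mm).
#' @param half_angle_deg Emission half-angle around the downward normal.
#' @return An object of class `pa_source`.
#' @export
pa_source <- function(type = c("bracket", "pencil"), x_mm = NULL,
                      gap_mm = 0, width_mm = 20, half_angle_deg = 20) {
  type <- match.arg(type)
  structure(list(type = type, x_mm = x_mm, gap_mm = gap_mm,
                 width_mm = width_mm, half_angle_deg = half_angle_deg),
            class = "pa_source")
}

# source -> matrix of [x_start, x_end] segments in cm, clipped to the surface
source_segments <- function(source, width_cm) {
  if (source$type == "pencil") {
    x <- if (is.null(source$x_mm)) width_cm / 2 else source$x_mm / 10
    seg <- matrix(c(x, x + 1e-6), nrow = 1)
  } else {
    c0 <- width_cm / 2
    gap <- source$gap_mm / 20  # half-gap in cm
    w <- source$width_mm / 10
    seg <- rbind(c(c0 - gap - w, c0 - gap), c(c0 + gap, c0 + gap + w))
  }
  seg[] <- pmin(pmax(seg, 0), width_cm - 1e-9)
  seg
}

#' Simulate wavelength-resolved optical fluence by Monte-Carlo transport
#'
#' Runs the 2-D voxel Monte-Carlo engine (Henyey-Greenstein scattering,
#' implicit-capture weighting, Russian roulette with survival threshold
#' 1e-4 and survival chance 0.1) for each wavelength of the phantom and
#' returns the fluence per launched photon, estimated from absorbed weight
#' per voxel divided by `mu_a` times voxel area. Each wavelength uses its
#' own seeded pseudo-random stream (`seed + wavelength index - 1`), so a
#' given `(seed, n_photons)` pair is exactly reproducible.
#'
#' @param phantom A [digital_phantom()].
#' @param source A [pa_source()]; must lie on the phantom's top surface.
#' @param n_photons Photons launched per wavelength (>= 1000).
#' @param seed Integer seed (required; no hidden global state).
#' @return An object of class `pa_fluence`: list with `values`
#'   (`nz x nx x n_wavelengths` array), `wavelengths`, `voxel_size_mm`,
#'   `n_photons`, `seed`, and a `conservation` data frame with per-wavelength
#'   absorbed/escaped/roulette weight totals (per launched photon).
#' @export
simulate_fluence <- function(phantom, source = pa_source(),
                             n_photons = 1e5, seed) {
  stopifnot(inherits(phantom, "pa_phantom"))
  if (missing(seed)) stop_qpat("seed is required", class = "qpat_config_error")
  if (n_photons < 1e3)
    stop_qpat("n_photons must be at least 1000", class = "qpat_config_error")
  if (all(phantom$mu_a == 0) && all(phantom$mu_s == 0))
    stop_qpat("degenerate medium: zero scattering and zero absorption",
              class = "qpat_degenerate_error")
  d <- dim(phantom$mu_a)
  dx <- phantom$voxel_size_mm / 10
  seg <- source_segments(source, d[2] * dx)
  ha <- source$half_angle_deg * pi / 180
  vals <- array(0, d)
  cons <- data.frame(wavelength_nm = phantom$wavelengths, absorbed = NA_real_,
                     escaped = NA_real_, roulette_net = NA_real_)
  for (k in seq_len(d[3])) {
    res <- with_seed(seed + k - 1,
      .mc_fluence_cpp(phantom$mu_a[, , k], phantom$mu_s[, , k], phantom$g,
                      dx, seg, ha, as.integer(n_photons)))
    vals[, , k] <- res$fluence
    cons$absorbed[k] <- res$absorbed
    cons$escaped[k] <- res$escaped
    cons$roulette_net[k] <- res$roulette_net
  }
  structure(list(values = vals, wavelengths = phantom$wavelengths,
                 voxel_size_mm = phantom$voxel_size_mm,
                 n_photons = n_photons, seed = seed, conservation = cons),
            class = "pa_fluence")
}

#' @export
print.pa_fluence <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Fluence volume: %d x %d voxels, %d wavelengths, %g photons/wavelength (seed %d)\n",
              d[1], d[2], d[3], x$n_photons, x$seed))
  bal <- with(x$conservation, absorbed + escaped + roulette_net)
  cat(sprintf("Weight balance (absorbed+escaped+roulette)/launched: %.8f-%.8f\n",
              min(bal), max(bal)))
  invisible(x)
}

# depth coordinate (cm) of each voxel row
fluence_depths <- function(fluence) {
  (seq_len(dim(fluence$values)[1]) - 1) * fluence$voxel_size_mm / 10
}

#' Extract fluence eigenspectra and their ensemble mean
#'
#' Samples per-voxel fluence spectra under `mask`, normalizes each to 1 at
#' the reference wavelength, and reduces them to `n_keep` representative
#' spectra by k-medoids clustering under cosine distance (medoids are
#' actual sampled spectra, so non-negative combinations of them remain
#' realizable fluence spectra). The ensemble mean `phi_ave` is the
#' elementwise mean of the sampled normalized spectra, renormalized to 1
#' at the reference wavelength. By default the mean weights each depth
#' stratum equally and, within a stratum, weights voxels by their fluence
#' amplitude at the reference wavelength: measured pressure spectra are
#' amplitude-weighted averages over an absorber's bright voxels, so an
#' amplitude-weighted ensemble mean represents the fluence as it actually
#' contributes to detectable signal (dim, strongly self-filtered absorber
#' interiors contribute little). Set `weighting = "uniform"` for the plain
#' unweighted mean.
#'
#' @param fluence A [simulate_fluence()] result.
#' @param mask Logical matrix selecting sample voxels (e.g.
#'   [absorber_mask()]); all selected voxels must have strictly positive
#'   fluence at every wavelength.
#' @param reference_wavelength Normalization wavelength (nm); if absent from
#'   the grid the nearest grid wavelength is used and recorded.
#' @param n_keep Number of spectra to retain; defaults to the number of
#'   wavelengths.
#' @param max_sample Cap on sampled voxels (deterministic, depth-stratified
#'   thinning).
#' @param weighting `"amplitude"` (default) or `"uniform"` ensemble-mean
#'   weighting for `phi_ave` (members are always unweighted medoids).
#' @return An object of class `pa_eigenspectra`: `spectra` (matrix,
#'   wavelengths x n_keep), `phi_ave`, `wavelengths`,
#'   `reference_wavelength`, `provenance`, and `samples` (the normalized
#'   sampled voxel spectra the reduction was computed from).
#' @export
extract_eigenspectra <- function(fluence, mask, reference_wavelength = 800,
                                 n_keep = length(fluence$wavelengths),
                                 max_sample = 500,
                                 weighting = c("amplitude", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(fluence, "pa_fluence"), is.logical(mask),
            all(dim(mask) == dim(fluence$values)[1:2]))
  idx <- which(mask)
  if (length(idx) < n_keep)
    stop_qpat("mask selects fewer voxels (", length(idx),
              ") than n_keep (", n_keep, ")", class = "qpat_config_error")
  nl <- dim(fluence$values)[3]
  S <- sapply(seq_len(nl), function(k) fluence$values[, , k][idx])
  S <- t(S)  # wavelengths x voxels
  if (any(S <= 0))
    stop_qpat("mask selects voxels with non-positive fluence at some wavelength",
              class = "qpat_degenerate_error")
  iref <- which.min(abs(fluence$wavelengths - reference_wavelength))
  ref_used <- fluence$wavelengths[iref]
  rows <- (idx - 1) %% dim(mask)[1] + 1
  # deterministic depth-stratified thinning: order by depth, take evenly
  # spaced voxels so every depth decile stays represented
  if (ncol(S) > max_sample) {
    o <- order(rows)
    keep <- o[round(seq(1, length(o), length.out = max_sample))]
    S <- S[, keep, drop = FALSE]
    rows <- rows[keep]
  }
  Sn <- sweep(S, 2, S[iref, ], "/")
  m <- ncol(Sn)
  if (n_keep >= m) {
    med <- Sn
  } else {
    # k-medoids under cosine distance on the normalized spectra
    nrm <- sqrt(colSums(Sn^2))
    cs <- crossprod(sweep(Sn, 2, nrm, "/"))
    dmat <- 1 - pmin(pmax(cs, -1), 1)
    fit <- cluster::pam(stats::as.dist(dmat), k = n_keep, diss = TRUE)
    med <- Sn[, fit$id.med, drop = FALSE]
  }
  colnames(med) <- paste0("phi_", seq_len(ncol(med)))
  if (weighting == "amplitude") {
    # equal weight per depth stratum; amplitude-weighted within stratum
    strat <- cut(rank(rows, ties.method = "first"), breaks = 10,
                 labels = FALSE)
    w <- S[iref, ]
    for (d in unique(strat)) {
      sel <- strat == d
      w[sel] <- w[sel] / sum(w[sel])
    }
    phi_ave <- as.numeric(Sn %*% w) / sum(w)
  } else {
    phi_ave <- rowMeans(Sn)
  }
  phi_ave <- phi_ave / phi_ave[iref]
  structure(list(spectra = med, phi_ave = phi_ave,
                 samples = Sn, sample_weights = if (weighting == "amplitude")
                   w / sum(w) else rep(1 / ncol(Sn), ncol(Sn)),
                 wavelengths = fluence$wavelengths,
                 reference_wavelength = ref_used,
                 provenance = sprintf(
                   "k-medoids (cosine) of %d depth-stratified voxel spectra, seed %s",
                   m, fluence$seed %||% "NA")),
            class = "pa_eigenspectra")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw random in-cone trial fluence spectra
#'
#' Generates trial fluence spectra for the compensator-ranking experiment
#' as random convex combinations of spectra from the realizable fluence
#' set: by default mixtures of the sampled voxel spectra (drawn with their
#' sampling weights, so the trial distribution matches the simulated
#' fluence data), or of the medoid members when `from = "members"`.
#'
#' @param eig A `pa_eigenspectra` object.
#' @param n Number of trial spectra.
#' @param k Spectra mixed per trial (flat Dirichlet weights).
#' @param from `"samples"` or `"members"`.
#' @param seed Integer seed.
#' @return Matrix, wavelengths x `n`.
#' @export
sample_cone_fluences <- function(eig, n, k = 3,
                                 from = c("samples", "members"), seed) {
  from <- match.arg(from)
  if (missing(seed)) stop_qpat("seed is required", class = "qpat_config_error")
  pool <- if (from == "samples" && !is.null(eig$samples)) eig$samples
          else eig$spectra
  pw <- if (from == "samples" && !is.null(eig$sample_weights))
    eig$sample_weights else rep(1 / ncol(pool), ncol(pool))
  with_seed(seed, {
    out <- matrix(0, nrow(pool), n)
    for (i in seq_len(n)) {
      j <- sample.int(ncol(pool), k, replace = TRUE, prob = pw)
      w <- -log(runif(k)); w <- w / sum(w)
      out[, i] <- pool[, j, drop = FALSE] %*% w
    }
    out
  })
}

#' @export
print.pa_eigenspectra <- function(x, ...) {
  cat(sprintf("Fluence eigenspectra: %d members + phi_ave on %d wavelengths (ref %g nm)\n",
              ncol(x$spectra), length(x$wavelengths), x$reference_wavelength))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Mask of absorber-labelled voxels
#'
#' Default sampling region for [extract_eigenspectra()]: all voxels whose
#' label names contain "tube" or "vessel" (the embedded absorbers).
#'
#' @param phantom A [digital_phantom()].
#' @param pattern Regular expression matched against label names.
#' @return Logical matrix.
#' @export
absorber_mask <- function(phantom, pattern = "tube|vessel") {
  ids <- as.integer(names(phantom$label_names)[grepl(pattern,
                                                     phantom$label_names)])
  matrix(phantom$labels %in% ids, nrow(phantom$labels), ncol(phantom$labels))
}

#' Depth-attenuation model
#'
#' Holds the exponential decay coefficients used for depth compensation:
#' `mu_f` for optical fluence (from simulation) and `mu_b` for acoustic
#' attenuation (from co-registered ultrasound; an input here).
#'
#' @param mu_f,mu_b Non-negative decay coefficients (cm^-1).
#' @param fit_range Depth interval (cm) used for the `mu_f` fit, if any.
#' @param fit_r2 Goodness of the log-linear fit.
#' @return An object of class `pa_depth_model`.
#' @export
depth_model <- function(mu_f, mu_b = 0.5, fit_range = NULL, fit_r2 = NA_real_) {
  if (mu_f < 0 || mu_b < 0)
    stop_qpat("attenuation coefficients must be non-negative",
              class = "qpat_domain_error")
  structure(list(mu_f = mu_f, mu_b = mu_b, fit_range = fit_range,
                 fit_r2 = fit_r2), class = "pa_depth_model")
}

#' @export
print.pa_depth_model <- function(x, ...) {
  cat(sprintf("Depth model: mu_f = %.4g cm^-1, mu_b = %.4g cm^-1", x$mu_f, x$mu_b))
  if (!is.null(x$fit_range))
    cat(sprintf(" (fit over %g-%g cm, R^2 = %.4f)", x$fit_range[1],
                x$fit_range[2], x$fit_r2))
  cat("\n")
  invisible(x)
}

#' Fit the fluence depth-attenuation coefficient
#'
#' Least-squares fit of a line to the log of the laterally averaged fluence
#' versus depth over `fit_range`; `mu_f` is the negative slope. The fit is
#' done at a single wavelength (default: the grid wavelength nearest
#' 800 nm).
#'
#' @param fluence A [simulate_fluence()] result.
#' @param wavelength Wavelength (nm) at which to fit.
#' @param fit_range Depth interval `c(zmin, zmax)` in cm; must span at
#'   least 5 depth samples with strictly positive lateral-mean fluence.
#' @param mu_b Acoustic attenuation coefficient to store in the returned
#'   model (cm^-1).
#' @param lateral_frac Central fraction of lateral columns averaged for
#'   the depth profile; the default 0.5 excludes edge columns whose
#'   faster, escape-dominated decay is unrepresentative of the imaged
#'   center.
#' @return A [depth_model()] with the fitted `mu_f`.
#' @export
fit_depth_attenuation <- function(fluence, wavelength = 800, fit_range,
                                  mu_b = 0.5, lateral_frac = 0.5) {
  stopifnot(inherits(fluence, "pa_fluence"), length(fit_range) == 2,
            lateral_frac > 0, lateral_frac <= 1)
  k <- which.min(abs(fluence$wavelengths - wavelength))
  z <- fluence_depths(fluence)
  nx <- dim(fluence$values)[2]
  half <- max(1, round(nx * lateral_frac / 2))
  cols <- max(1, round(nx / 2) - half):min(nx, round(nx / 2) + half)
  prof <- rowMeans(fluence$values[, cols, k, drop = FALSE])
  sel <- z >= fit_range[1] & z <= fit_range[2]
  if (sum(sel) < 5)
    stop_qpat("fit_range must span at least 5 depth samples",
              class = "qpat_config_error")
  if (any(prof[sel] <= 0))
    stop_qpat("laterally averaged fluence must be strictly positive over fit_range",
              class = "qpat_log_domain_error")
  fit <- lm(log(prof[sel]) ~ z[sel])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  depth_model(mu_f = max(0, -unname(coef(fit)[2])), mu_b = mu_b,
              fit_range = fit_range, fit_r2 = r2)
}
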