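#' Plain-text container I/O
#'
#' Every multi-array object (pressure maps, fluence volumes, digital
#' phantoms, quantitative maps) is serialized to a directory containing a
#' `meta.json` file (metadata, dimensions, wavelengths, seeds) and one
#' long-format CSV per array (`wavelength_nm, row, col, value` for
#' wavelength-resolved arrays; `row, col, value` for images). Values are
#' written with 17 significant digits so write -> read is an identity on
#' the in-memory types (up to floating-point text round-trip). Undefined
#' saturation pixels are encoded as `NA`.
#'
#' @param x Object to write.
#' @param path Target directory (created if needed).
#' @return `write_*` return `path` invisibly; `read_*` return the
#'   reconstructed object.
#' @name container_io
NULL

write_array_csv <- function(a, file, wavelengths = NULL) {
  if (length(dim(a)) == 3) {
    d <- dim(a)
    df <- data.frame(
      wavelength_nm = rep(wavelengths, each = d[1] * d[2]),
      row = rep(rep(seq_len(d[1]), d[2]), d[3]),
      col = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
      value = sprintf("%.17g", as.vector(a)))
  } else {
    df <- data.frame(row = rep(seq_len(nrow(a)), ncol(a)),
                     col = rep(seq_len(ncol(a)), each = nrow(a)),
                     value = sprintf("%.17g", as.vector(a)))
  }
  write.csv(df, file, row.names = FALSE, quote = FALSE)
}

read_array_csv <- function(file, dims) {
  df <- read.csv(file)
  array(as.numeric(df$value), dims)
}

#' @rdname container_io
#' @export
write_pressure_map <- function(x, path) {
  stopifnot(inherits(x, "pa_pressure_map"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(type = "pressure_map", dims = dim(x$images),
               wavelengths_nm = x$wavelengths,
               pixel_size_mm = x$pixel_size_mm, z0_cm = x$z0_cm,
               has_mask = !is.null(x$mask))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(x$images, file.path(path, "pressure.csv"), x$wavelengths)
  if (!is.null(x$mask))
    write_array_csv(x$mask * 1, file.path(path, "mask.csv"))
  invisible(path)
}

#' @rdname container_io
#' @export
read_pressure_map <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(meta$type == "pressure_map")
  img <- read_array_csv(file.path(path, "pressure.csv"), meta$dims)
  mask <- if (isTRUE(meta$has_mask))
    read_array_csv(file.path(path, "mask.csv"), meta$dims[1:2]) > 0
  pressure_map(img, meta$wavelengths_nm, meta$pixel_size_mm, meta$z0_cm,
               mask)
}

#' @rdname container_io
#' @export
write_fluence <- function(x, path) {
  stopifnot(inherits(x, "pa_fluence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(type = "fluence", dims = dim(x$values),
               wavelengths_nm = x$wavelengths,
               voxel_size_mm = x$voxel_size_mm, n_photons = x$n_photons,
               seed = x$seed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(x$values, file.path(path, "fluence.csv"), x$wavelengths)
  write.csv(x$conservation, file.path(path, "conservation.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname container_io
#' @export
read_fluence <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(meta$type == "fluence")
  structure(list(values = read_array_csv(file.path(path, "fluence.csv"),
                                         meta$dims),
                 wavelengths = meta$wavelengths_nm,
                 voxel_size_mm = meta$voxel_size_mm,
                 n_photons = meta$n_photons, seed = meta$seed,
                 conservation = read.csv(file.path(path,
                                                   "conservation.csv"))),
            class = "pa_fluence")
}

#' @rdname container_io
#' @export
write_phantom <- function(x, path) {
  stopifnot(inherits(x, "pa_phantom"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(type = "phantom", dims = dim(x$mu_a),
               wavelengths_nm = x$wavelengths,
               voxel_size_mm = x$voxel_size_mm,
               label_names = as.list(x$label_names))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(x$mu_a, file.path(path, "mu_a.csv"), x$wavelengths)
  write_array_csv(x$mu_s, file.path(path, "mu_s.csv"), x$wavelengths)
  write_array_csv(x$g, file.path(path, "g.csv"))
  write_array_csv(x$labels, file.path(path, "labels.csv"))
  invisible(path)
}

#' @rdname container_io
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(meta$type == "phantom")
  d <- meta$dims
  lab <- read_array_csv(file.path(path, "labels.csv"), d[1:2])
  digital_phantom(read_array_csv(file.path(path, "mu_a.csv"), d),
                  read_array_csv(file.path(path, "mu_s.csv"), d),
                  read_array_csv(file.path(path, "g.csv"), d[1:2]),
                  matrix(as.integer(lab), d[1], d[2]),
                  unlist(meta$label_names), meta$voxel_size_mm,
                  meta$wavelengths_nm)
}

#' @rdname container_io
#' @export
write_quant_maps <- function(x, path) {
  stopifnot(inherits(x, "pa_quant_maps"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(type = "quant_maps", dims = dim(x$so2_map),
               wavelengths_nm = x$wavelengths, method = x$method,
               pixel_size_mm = x$pixel_size_mm, z0_cm = x$z0_cm,
               mu_f = x$depth_model$mu_f, mu_b = x$depth_model$mu_b)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write_array_csv(x$so2_map, file.path(path, "so2.csv"))
  write_array_csv(x$thb_map, file.path(path, "thb.csv"))
  invisible(path)
}

#' @rdname container_io
#' @export
read_quant_maps <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(meta$type == "quant_maps")
  d <- meta$dims
  dm <- if (!is.null(meta$mu_f)) depth_model(meta$mu_f, meta$mu_b)
  structure(list(so2_map = read_array_csv(file.path(path, "so2.csv"), d),
                 thb_map = read_array_csv(file.path(path, "thb.csv"), d),
                 method = meta$method, depth_model = dm,
                 wavelengths = meta$wavelengths_nm,
                 pixel_size_mm = meta$pixel_size_mm, z0_cm = meta$z0_cm),
            class = "pa_quant_maps")
}

#' Eigenspectra CSV round trip
#'
#' CSV layout: first column `wavelength_nm`, one column per member
#' spectrum (`phi_1` ...), final column `phi_ave`.
#'
#' @param x A `pa_eigenspectra` object.
#' @param file CSV path.
#' @export
write_eigenspectra <- function(x, file) {
  stopifnot(inherits(x, "pa_eigenspectra"))
  df <- data.frame(wavelength_nm = x$wavelengths)
  for (j in seq_len(ncol(x$spectra)))
    df[[colnames(x$spectra)[j]]] <- sprintf("%.17g", x$spectra[, j])
  df$phi_ave <- sprintf("%.17g", x$phi_ave)
  con <- file(file, "w")
  writeLines(sprintf("# fluence eigenspectra; reference wavelength %g nm; %s",
                     x$reference_wavelength, x$provenance), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_eigenspectra
#' @export
read_eigenspectra <- function(file) {
  hdr <- readLines(file, n = 1)
  ref <- as.numeric(sub("^# fluence eigenspectra; reference wavelength ([0-9.]+) nm.*",
                        "\\1", hdr))
  df <- read.csv(file, comment.char = "#")
  members <- setdiff(names(df), c("wavelength_nm", "phi_ave"))
  structure(list(spectra = as.matrix(df[members]),
                 phi_ave = df$phi_ave,
                 wavelengths = df$wavelength_nm,
                 reference_wavelength = ref,
                 provenance = sub("^#\\s*", "", hdr)),
            class = "pa_eigenspectra")
}

#' Ground-truth table round trip
#'
#' @param truth Ground-truth data frame from [build_phantom()].
#' @param file CSV path.
#' @export
write_ground_truth <- function(truth, file) {
  write.csv(truth, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) read.csv(file)

#' Write a machine-readable run manifest
#'
#' Records the configuration, seeds, package version and output files of a
#' pipeline run as JSON; written before outputs with `status = "running"`
#' and finalized to `"ok"`/`"failed"` so partial outputs are always
#' identifiable.
#'
#' @param path Manifest path (JSON).
#' @param config Named list echoed verbatim.
#' @param outputs Character vector of declared output paths.
#' @param status Run status string.
#' @export
write_manifest <- function(path, config, outputs = character(),
                           status = "ok") {
  jsonlite::write_json(
    list(package = "qpat",
         version = as.character(utils::packageVersion("qpat")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         status = status, config = config, outputs = outputs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
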