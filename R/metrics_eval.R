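#' Cluster tube cross-sections in a pressure map
#'
#' Groups supra-threshold pixels into connected components
#' (8-connectivity) and returns, for each component of at least
#' `min_pixels` pixels, its pixel coordinates, mean depth and mean pressure
#' spectrum. Per-cluster mean spectra are much more robust inputs for
#' unmixing than single pixels.
#'
#' @param m A [pressure_map()].
#' @param amplitude_threshold_quantile Quantile of the maximum
#'   cross-wavelength amplitude image used as threshold.
#' @param min_pixels Minimum component size.
#' @return An object of class `pa_clusters`: list with `clusters` (a list
#'   of `list(pixels, mean_depth_cm, mean_spectrum)`), `wavelengths`, and a
#'   `summary` data frame. An empty mask yields zero clusters, not an
#'   error.
#' @export
cluster_cross_sections <- function(m, amplitude_threshold_quantile = 0.90,
                                   min_pixels = 5) {
  stopifnot(inherits(m, "pa_pressure_map"))
  amp <- apply(abs(m$images), c(1, 2), max)
  thr <- quantile(amp, amplitude_threshold_quantile)
  mask <- amp > thr
  lab <- .label_components_cpp(mask)
  z <- map_depths(m)
  d <- dim(m$images)
  clusters <- list()
  for (id in setdiff(sort(unique(as.integer(lab))), 0L)) {
    idx <- which(lab == id)
    if (length(idx) < min_pixels) next
    rows <- (idx - 1) %% d[1] + 1
    spec <- vapply(seq_len(d[3]),
                   function(k) mean(m$images[, , k][idx]), numeric(1))
    clusters[[length(clusters) + 1]] <-
      list(pixels = idx, mean_depth_cm = mean(z[rows]), mean_spectrum = spec)
  }
  o <- order(vapply(clusters, `[[`, numeric(1), "mean_depth_cm"))
  clusters <- clusters[o]
  summ <- data.frame(
    cluster = seq_along(clusters),
    n_pixels = vapply(clusters, function(cl) length(cl$pixels), numeric(1)),
    mean_depth_cm = vapply(clusters, `[[`, numeric(1), "mean_depth_cm"))
  structure(list(clusters = clusters, wavelengths = m$wavelengths,
                 summary = summ), class = "pa_clusters")
}

#' @export
print.pa_clusters <- function(x, ...) {
  cat(sprintf("%d clusters", length(x$clusters)))
  if (length(x$clusters))
    cat(sprintf(" at depths %.2f-%.2f cm",
                min(x$summary$mean_depth_cm), max(x$summary$mean_depth_cm)))
  cat("\n")
  invisible(x)
}

#' Recompute cluster mean spectra from another map
#'
#' Keeps the cluster pixel memberships (detected, e.g., on the raw map,
#' where the noise floor is uniform) but recomputes each cluster's mean
#' pressure spectrum from `m` — typically the depth-compensated map, so
#' that detection happens before compensation amplifies deep noise while
#' quantification uses the compensated amplitudes.
#'
#' @param cl A [cluster_cross_sections()] result.
#' @param m A [pressure_map()] with the same geometry as the clustered map.
#' @return `cl` with updated mean spectra.
#' @export
cluster_mean_spectra <- function(cl, m) {
  stopifnot(inherits(cl, "pa_clusters"), inherits(m, "pa_pressure_map"))
  d <- dim(m$images)
  cl$clusters <- lapply(cl$clusters, function(x) {
    x$mean_spectrum <- vapply(seq_len(d[3]),
                              function(k) mean(m$images[, , k][x$pixels]),
                              numeric(1))
    x
  })
  cl$wavelengths <- m$wavelengths
  cl
}

#' Unmix every cluster of a cluster set
#'
#' Convenience wrapper applying an unmixing method to each cluster's mean
#' spectrum.
#'
#' @param cl A [cluster_cross_sections()] result.
#' @param method `"lu"`, `"clu"` or `"cc"`.
#' @param ... Passed to the corresponding estimator ([unmix]).
#' @return Data frame: cluster, mean depth, saturation, total.
#' @export
unmix_clusters <- function(cl, method = c("lu", "clu", "cc"), ...) {
  method <- match.arg(method)
  fn <- switch(method, lu = lu_unmix, clu = clu_unmix, cc = cc_estimate)
  res <- lapply(cl$clusters, function(x)
    fn(x$mean_spectrum, cl$wavelengths, ...))
  data.frame(cluster = seq_along(res),
             mean_depth_cm = cl$summary$mean_depth_cm,
             so2_pct = vapply(res, `[[`, numeric(1), "so2_pct"),
             thb_rel = vapply(res, `[[`, numeric(1), "thb_rel"))
}

#' Uniformity standard deviation
#'
#' Population standard deviation (divisor `n`, as used for the per-B-scan
#' total-sulfate uniformity measure): the square root of the mean squared
#' deviation from the mean.
#'
#' @param values Numeric vector, length >= 2.
#' @return Spread in the units of `values`.
#' @examples
#' uniformity_std(c(1, 3))        # 1
#' uniformity_std(c(2, 4, 6, 8))  # sqrt(5)
#' @export
uniformity_std <- function(values) {
  if (length(values) < 2)
    stop_qpat("uniformity_std needs at least 2 values",
              class = "qpat_domain_error")
  sqrt(mean((values - mean(values))^2))
}

#' Malignant-to-benign total-hemoglobin ratio
#'
#' Ratio of the group means of per-lesion total-hemoglobin values.
#'
#' @param malignant_means,benign_means Non-empty numeric vectors of
#'   per-lesion mean THb.
#' @return The ratio of group means.
#' @export
thb_ratio <- function(malignant_means, benign_means) {
  if (length(malignant_means) == 0 || length(benign_means) == 0)
    stop_qpat("both groups must be non-empty", class = "qpat_domain_error")
  mb <- mean(benign_means)
  if (mb <= 0)
    stop_qpat("benign group mean must be positive",
              class = "qpat_domain_error")
  mean(malignant_means) / mb
}

#' Rank candidate compensating spectra for CLU
#'
#' The numerical experiment comparing CLU compensated by each individual
#' fluence eigenspectrum against CLU compensated by their ensemble mean.
#' For every candidate compensator and every trial (a true saturation and a
#' true fluence spectrum), the trial spectrum `p = fluence * mu_a(truth)`
#' is unmixed with the candidate as compensating spectrum, and the
#' saturation error in percentage points is recorded. Per-candidate
#' aggregates:
#'
#' * MAE, RMSE (percentage points),
#' * robustness: fraction of trials with |error| <= `tolerance_pp`,
#' * consistency: standard deviation of the error,
#' * composite score: mean of the four per-metric ranks (rank 1 = best;
#'   robustness ranked descending), ties broken by MAE rank.
#'
#' @param eig A `pa_eigenspectra` set; candidates are its members plus
#'   `phi_ave`.
#' @param table,species,ox_scale See [unmix].
#' @param so2_truths True saturations (percent), at least 2.
#' @param trial_fluences Matrix (wavelengths x trials) of true fluence
#'   spectra; trials are the cross product of truths and fluences.
#' @param tolerance_pp Robustness tolerance in percentage points.
#' @return An object of class `pa_compensator_report`: data frame with one
#'   row per candidate (metrics, per-metric ranks, composite score and
#'   overall rank), plus attributes `errors` (candidate x trial matrix).
#' @export
rank_compensators <- function(eig, table = extinction_table(),
                              species = c("HbO2", "Hb"), ox_scale = 1,
                              so2_truths, trial_fluences, tolerance_pp = 5) {
  stopifnot(inherits(eig, "pa_eigenspectra"))
  trial_fluences <- as.matrix(trial_fluences)
  if (length(so2_truths) < 2 || ncol(trial_fluences) < 1 ||
      length(so2_truths) * ncol(trial_fluences) < 2)
    stop_qpat("need at least 2 trial conditions",
              class = "qpat_config_error")
  wl <- eig$wavelengths
  stopifnot(nrow(trial_fluences) == length(wl))
  cand <- cbind(eig$spectra, phi_ave = eig$phi_ave)
  if (ncol(cand) < 2)
    stop_qpat("need at least 2 candidate spectra",
              class = "qpat_config_error")
  E <- cbind(get_extinction(species[1], wl, table),
             get_extinction(species[2], wl, table))
  # trial spectra, one column per (truth, fluence) pair
  trials <- do.call(cbind, lapply(so2_truths, function(s)
    trial_fluences * sat_absorption(s, wl, table, species, ox_scale)))
  truth <- rep(so2_truths, each = ncol(trial_fluences))
  err <- matrix(NA_real_, ncol(cand), length(truth),
                dimnames = list(colnames(cand), NULL))
  for (ci in seq_len(ncol(cand))) {
    fit <- nnls2_batch(E, trials / cand[, ci])
    est <- so2_from_conc(fit["c_ox", ], fit["c_de", ], ox_scale)
    err[ci, ] <- est - truth
  }
  mae <- rowMeans(abs(err))
  rmse <- sqrt(rowMeans(err^2))
  robust <- rowMeans(abs(err) <= tolerance_pp)
  consist <- apply(err, 1, sd)
  r_mae <- rank(mae, ties.method = "min")
  r_rmse <- rank(rmse, ties.method = "min")
  r_rob <- rank(-robust, ties.method = "min")
  r_con <- rank(consist, ties.method = "min")
  composite <- (r_mae + r_rmse + r_rob + r_con) / 4
  overall <- rank(composite + 1e-9 * r_mae, ties.method = "min")
  rep_df <- data.frame(candidate = colnames(cand), mae = mae, rmse = rmse,
                       robustness = robust, consistency = consist,
                       rank_mae = r_mae, rank_rmse = r_rmse,
                       rank_robustness = r_rob, rank_consistency = r_con,
                       composite = composite, rank_overall = overall,
                       row.names = NULL)
  structure(rep_df, errors = err, tolerance_pp = tolerance_pp,
            class = c("pa_compensator_report", "data.frame"))
}

#' @export
`[.pa_compensator_report` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.pa_compensator_report <- function(x, ...) {
  cat("Compensator ranking (", nrow(x), "candidates,",
      ncol(attr(x, "errors")), "trials )\n")
  df <- as.data.frame(x)
  df[2:5] <- lapply(df[2:5], function(v) signif(v, 4))
  print.data.frame(df[order(df$rank_overall), ], row.names = FALSE)
  invisible(x)
}

#' Simulate a synthetic lesion cohort
#'
#' Draws per-lesion mean saturation and relative total-hemoglobin features
#' for a two-class (benign / malignant) cohort from bivariate Gaussian
#' group distributions. The defaults qualitatively emulate the clinical
#' pattern (malignant: lower saturation, higher THb) at two compensation
#' quality levels: `"LU"`-style features carry a smaller group separation
#' (THb ratio ~1.4) and `"ISDC"`-style features a larger one (THb ratio
#' ~1.9, saturation shifted up ~5 points in both groups). All effect sizes
#' are synthetic design choices, not measured values.
#'
#' @param n_malignant,n_benign Group sizes.
#' @param method `"ISDC"` or `"LU"` feature style.
#' @param seed Integer seed.
#' @param params Optional full override: list with `so2_mean`, `so2_sd`,
#'   `thb_mean`, `thb_sd`, each `c(benign, malignant)`.
#' @return Data frame of class `pa_lesion_features`: `lesion_id`,
#'   `mean_so2_pct`, `mean_thb_rel`, `class_label`.
#' @export
simulate_lesion_cohort <- function(n_malignant = 15, n_benign = 67,
                                   method = c("ISDC", "LU"), seed,
                                   params = NULL) {
  method <- match.arg(method)
  if (missing(seed)) stop_qpat("seed is required", class = "qpat_config_error")
  if (is.null(params))
    params <- if (method == "LU")
      list(so2_mean = c(68, 61), so2_sd = c(9, 9),
           thb_mean = c(1.00, 1.40), thb_sd = c(0.35, 0.50))
    else
      list(so2_mean = c(73, 65), so2_sd = c(9, 9),
           thb_mean = c(1.05, 2.00), thb_sd = c(0.35, 0.60))
  with_seed(seed, {
    n <- c(n_benign, n_malignant)
    lab <- rep(c("benign", "malignant"), n)
    g <- rep(1:2, n)
    so2 <- pmin(100, pmax(0, rnorm(sum(n), params$so2_mean[g],
                                   params$so2_sd[g])))
    thb <- pmax(0.01, rnorm(sum(n), params$thb_mean[g], params$thb_sd[g]))
    structure(data.frame(lesion_id = seq_len(sum(n)), mean_so2_pct = so2,
                         mean_thb_rel = thb, class_label = lab),
              class = c("pa_lesion_features", "data.frame"))
  })
}

#' Lesion classification by logistic regression with ROC analysis
#'
#' Fits an unregularized maximum-likelihood logistic regression on
#' standardized features (saturation, total hemoglobin, or both) and
#' computes the in-sample ROC curve and AUC of the fitted scores.
#'
#' @param features Data frame with columns `mean_so2_pct`, `mean_thb_rel`,
#'   `class_label` (`"benign"` / `"malignant"`); both classes present,
#'   n >= 10.
#' @param feature_subset `"both"`, `"so2"` or `"thb"`.
#' @return List: `auc`, `roc_points` (data frame `fpr, tpr, threshold`,
#'   a non-decreasing staircase from (0,0) to (1,1)), `coefficients`, and
#'   the fitted `model`.
#' @export
classify_lesions <- function(features, feature_subset = c("both", "so2",
                                                          "thb")) {
  feature_subset <- match.arg(feature_subset)
  stopifnot(all(c("mean_so2_pct", "mean_thb_rel", "class_label") %in%
                names(features)))
  y <- features$class_label == "malignant"
  if (length(unique(y)) < 2)
    stop_qpat("both classes must be present", class = "qpat_domain_error")
  if (nrow(features) < 10)
    stop_qpat("need at least 10 lesions", class = "qpat_domain_error")
  X <- switch(feature_subset,
              both = features[c("mean_so2_pct", "mean_thb_rel")],
              so2 = features["mean_so2_pct"],
              thb = features["mean_thb_rel"])
  X <- as.data.frame(lapply(X, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  # perfectly separated synthetic cohorts are legitimate inputs here, so
  # the usual fitted-probabilities-0/1 warning is expected and silenced
  fit <- suppressWarnings(glm(y ~ ., data = cbind(y = y, X),
                              family = binomial()))
  score <- predict(fit, type = "link")
  r <- pROC::roc(response = y, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(FALSE, TRUE))
  pts <- data.frame(fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities),
                    threshold = rev(r$thresholds))
  list(auc = as.numeric(r$auc), roc_points = pts,
       coefficients = coef(fit), model = fit)
}
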