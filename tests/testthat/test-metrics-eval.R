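disk_map <- function(centers, radius_px = 3, n = 40, amp = 1, wl = wl4) {
  img <- array(0, c(n, n, length(wl)))
  for (k in seq_along(wl)) {
    m <- matrix(0, n, n)
    for (i in seq_len(nrow(centers))) {
      rr <- outer(seq_len(n) - centers[i, 1], seq_len(n) - centers[i, 2],
                  function(a, b) a^2 + b^2)
      m[rr <= radius_px^2] <- amp
    }
    img[, , k] <- m
  }
  pressure_map(img, wl, 0.5)
}

test_that("connected-component clustering finds constructed cross-sections", {
  m <- disk_map(rbind(c(10, 10), c(30, 30)))
  cl <- cluster_cross_sections(m, 0.9, 5)
  expect_equal(length(cl$clusters), 2)
  # threshold above the global maximum: no clusters, no error
  cl0 <- cluster_cross_sections(m, 1, 5)
  expect_equal(length(cl0$clusters), 0)
  # 15 rendered cross-sections are recovered as 15 clusters
  ctr <- as.matrix(expand.grid(seq(6, 34, 7), seq(6, 34, 7)))[1:15, ]
  m15 <- disk_map(ctr, radius_px = 2)
  cl15 <- cluster_cross_sections(m15, 0.80, 4)
  expect_equal(length(cl15$clusters), 15)
  # diagonal-touching pixels join one component (8-connectivity)
  img <- array(0, c(4, 4, 4)); img[1, 1, ] <- 1; img[2, 2, ] <- 1
  cl8 <- cluster_cross_sections(pressure_map(img, wl4, 1), 0.5, 1)
  expect_equal(length(cl8$clusters), 1)
})

test_that("cluster mean spectra and depths are correct", {
  wl <- wl4
  img <- array(0, c(10, 10, 4))
  spec <- c(4, 3, 2, 1)
  for (k in 1:4) img[6:7, 3:4, k] <- spec[k]
  m <- pressure_map(img, wl, 1)  # 1 mm pixels
  cl <- cluster_cross_sections(m, 0.9, 2)
  expect_equal(length(cl$clusters), 1)
  expect_equal(cl$clusters[[1]]$mean_spectrum, spec)
  expect_equal(cl$clusters[[1]]$mean_depth_cm, mean(c(5, 6) * 0.1))
  # spectra recomputed from a rescaled map keep memberships
  m2 <- m; m2$images <- m$images * 2
  cl2 <- cluster_mean_spectra(cl, m2)
  expect_equal(cl2$clusters[[1]]$mean_spectrum, 2 * spec)
})

test_that("uniformity standard deviation uses the population divisor", {
  expect_equal(uniformity_std(c(5, 5, 5)), 0)
  expect_equal(uniformity_std(c(1, 3)), 1)
  expect_equal(uniformity_std(c(2, 4, 6, 8)), sqrt(5))
  set.seed(1)
  x <- rnorm(20)
  expect_equal(uniformity_std(x + 17), uniformity_std(x), tolerance = 1e-12)
  expect_equal(uniformity_std(3 * x), 3 * uniformity_std(x),
               tolerance = 1e-12)
  expect_error(uniformity_std(5), class = "qpat_domain_error")
})

test_that("total-hemoglobin ratio matches designed group contrasts", {
  expect_equal(thb_ratio(2, 2), 1)
  expect_equal(thb_ratio(c(4, 2), c(2, 1)), 2)
  expect_error(thb_ratio(numeric(), 1), class = "qpat_domain_error")
  expect_error(thb_ratio(1, c(0, 0)), class = "qpat_domain_error")
  # cohort simulator round trip: designed malignant/benign contrast ~1.9
  ratios <- vapply(1:20, function(i) {
    co <- simulate_lesion_cohort(15, 67, "ISDC", seed = 1000 + i)
    thb_ratio(co$mean_thb_rel[co$class_label == "malignant"],
              co$mean_thb_rel[co$class_label == "benign"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) / 1.9 - 1), 0.1)
})

test_that("compensator ranking rewards the perfect compensator", {
  wl <- wl11
  members <- sapply(c(-0.003, 0.002), function(a) exp(a * (wl - 800)))
  truth_f <- members[, 1]
  eig <- synthetic_eigenspectra(cbind(truth_f, members[, 2]), wl)
  rep <- rank_compensators(eig, tab, so2_truths = c(30, 70),
                           trial_fluences = cbind(truth_f, truth_f))
  i <- which(rep$candidate == "phi_1")
  expect_equal(rep$mae[i], 0, tolerance = 1e-6)
  expect_equal(rep$rank_mae[i], 1)
  expect_equal(rep$rank_overall[i], 1)
  # dominance: candidate further from truth ranks behind on every metric
  expect_true(all(rep$rank_mae[rep$candidate == "phi_2"] >
                  rep$rank_mae[i]))
  expect_error(rank_compensators(eig, tab, so2_truths = 50,
                                 trial_fluences = truth_f),
               class = "qpat_config_error")
})

test_that("ranking is equivariant under candidate relabeling", {
  wl <- wl11
  set.seed(31)
  members <- sapply(c(-0.004, -0.001, 0.001, 0.003), function(a)
    exp(a * (wl - 800)))
  eig <- synthetic_eigenspectra(members, wl)
  trials <- sample_cone_fluences(eig, 40, k = 4, seed = 32)
  r1 <- rank_compensators(eig, tab, so2_truths = c(25, 50, 75),
                          trial_fluences = trials)
  perm <- c(3, 1, 4, 2)
  eig2 <- eig
  eig2$spectra <- eig$spectra[, perm]
  colnames(eig2$spectra) <- paste0("phi_", 1:4)
  r2 <- rank_compensators(eig2, tab, so2_truths = c(25, 50, 75),
                          trial_fluences = trials)
  m1 <- r1$rank_overall[match(paste0("phi_", perm), r1$candidate)]
  expect_equal(r2$rank_overall[1:4], m1)
  expect_setequal(r1$rank_mae, seq_len(5))
})

test_that("lesion classification reproduces textbook ROC behavior", {
  co <- simulate_lesion_cohort(15, 67, "ISDC", seed = 5)
  # perfectly separated synthetic feature
  sep <- co
  sep$mean_thb_rel <- ifelse(sep$class_label == "malignant", 10, 1)
  sep$mean_so2_pct <- 50
  expect_equal(classify_lesions(sep, "thb")$auc, 1)
  # uninformative constant feature
  flat <- co
  flat$mean_thb_rel <- 1
  expect_equal(classify_lesions(flat, "thb")$auc, 0.5)
  # ROC curve is a staircase from (0,0) to (1,1)
  r <- classify_lesions(co, "both")
  pts <- r$roc_points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  # AUC equals the rank (Mann-Whitney) statistic of the fitted scores
  sc <- predict(r$model, type = "link")
  y <- co$class_label == "malignant"
  u <- wilcox.test(sc[y], sc[!y], exact = FALSE)$statistic
  expect_equal(r$auc, unname(u) / (sum(y) * sum(!y)), tolerance = 1e-9)
  # AUC invariant under monotone transform of a single feature
  co2 <- co
  co2$mean_thb_rel <- exp(co$mean_thb_rel)
  a1 <- classify_lesions(co, "thb")$auc
  a2 <- classify_lesions(co2, "thb")$auc
  expect_equal(a1, a2, tolerance = 1e-9)
  # guards
  one <- co[co$class_label == "benign", ]
  expect_error(classify_lesions(one, "both"), class = "qpat_domain_error")
  expect_error(classify_lesions(co[1:5, ], "both"),
               class = "qpat_domain_error")
})

test_that("cohort simulator is seeded and respects bounds and sizes", {
  a <- simulate_lesion_cohort(15, 67, "LU", seed = 9)
  b <- simulate_lesion_cohort(15, 67, "LU", seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$class_label == "malignant"), 15)
  expect_equal(sum(a$class_label == "benign"), 67)
  expect_true(all(a$mean_so2_pct >= 0 & a$mean_so2_pct <= 100))
  expect_true(all(a$mean_thb_rel > 0))
})
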