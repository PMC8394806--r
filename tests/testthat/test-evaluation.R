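make_pair <- function(err_by_kp = c(Ba = 0, Ar = 0, Aprime = 0, PNS = 0)) {
  gt <- landmark_set(Ba = c(50, 80), Ar = c(50, 20), Aprime = c(80, 50),
                     PNS = c(90, 75))
  m <- unclass(gt)
  pred <- landmark_set(m["Ba", ] + c(err_by_kp["Ba"], 0),
                       m["Ar", ] + c(err_by_kp["Ar"], 0),
                       m["Aprime", ] + c(err_by_kp["Aprime"], 0),
                       m["PNS", ] + c(err_by_kp["PNS"], 0))
  list(pred = pred, gt = gt)
}

test_that("localization errors are per-keypoint means with an average row", {
  pr <- make_pair()
  tab <- localization_errors(list(pr$gt), list(pr$gt))
  expect_equal(tab$error_px, rep(0, 5))

  gt <- pr$gt
  m <- unclass(gt)
  pred <- landmark_set(m["Ba", ] + c(3, 4), m["Ar", ], m["Aprime", ],
                       m["PNS", ])
  tab <- localization_errors(list(pred), list(gt))
  expect_equal(tab$error_px[tab$keypoint == "Ba"], 5)
  expect_equal(tab$error_px[tab$keypoint == "average"], 1.25)

  # permutation invariance
  set.seed(3)
  preds <- replicate(6, rand_landmarks(), simplify = FALSE)
  gts <- replicate(6, rand_landmarks(), simplify = FALSE)
  t1 <- localization_errors(preds, gts)
  perm <- c(4, 2, 6, 1, 3, 5)
  t2 <- localization_errors(preds[perm], gts[perm])
  expect_equal(t1$error_px, t2$error_px)
})

test_that("AP/AR follow the distance-threshold definition", {
  pr <- make_pair()
  exact <- keypoint_ap_ar(list(pr$gt), list(pr$gt))
  expect_equal(exact$ap, 1)
  expect_equal(exact$ar, 1)

  far <- make_pair(c(Ba = 30, Ar = 40, Aprime = 50, PNS = 60))
  expect_equal(keypoint_ap_ar(list(far$pred), list(far$gt))$ap, 0)

  # errors {0.5, 2.5, 5.5, 20}: hand-enumerated over thresholds 1..10
  # (correct counts per threshold: 1,1,2,2,2,3,3,3,3,3 of 4)
  mixed <- make_pair(c(Ba = 0.5, Ar = 2.5, Aprime = 5.5, PNS = 20))
  res <- keypoint_ap_ar(list(mixed$pred), list(mixed$gt))
  expect_equal(res$ap, mean(c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3) / 4))
  expect_equal(res$ap, 0.575)

  # moving one prediction closer never decreases AP
  closer <- make_pair(c(Ba = 0.5, Ar = 2.5, Aprime = 4.5, PNS = 20))
  expect_gte(keypoint_ap_ar(list(closer$pred), list(closer$gt))$ap, res$ap)

  expect_error(keypoint_ap_ar(list(pr$gt), list(pr$gt), thresholds = c()),
               class = "cephan_error_config")
})

test_that("A/N ratio error is the mean absolute ratio difference", {
  set.seed(4)
  gts <- replicate(5, rand_landmarks(), simplify = FALSE)
  expect_equal(an_ratio_error(gts, gts)$mae, 0)

  # invariance under a joint rigid transform of both sides
  preds <- replicate(5, rand_landmarks(), simplify = FALSE)
  e0 <- an_ratio_error(preds, gts)$mae
  pt <- lapply(preds, transform_lm, angle = 33, shift = c(40, -17))
  gtt <- lapply(gts, transform_lm, angle = 33, shift = c(40, -17))
  expect_equal(an_ratio_error(pt, gtt)$mae, e0, tolerance = 1e-9)
})

test_that("the worked confusion matrix yields the expected marginal rates", {
  gt <- c(rep("hypertrophic", 32), rep("normal", 128))
  pred <- c(rep("hypertrophic", 29), rep("normal", 3),       # TP=29 FN=3
            rep("hypertrophic", 8), rep("normal", 120))      # FP=8 TN=120
  rep_ <- diagnostic_metrics(pred, gt)
  expect_equal(unname(rep_$counts), c(29, 8, 120, 3))
  est <- function(nm) rep_$metrics$estimate[rep_$metrics$metric == nm]
  expect_equal(est("sensitivity"), 0.90625)
  expect_equal(est("specificity"), 0.9375)
  expect_equal(est("accuracy"), 0.93125)
  expect_equal(est("LR_positive"), 0.90625 / (1 - 0.9375), tolerance = 1e-9)
  expect_equal(est("LR_negative"), (1 - 0.90625) / 0.9375, tolerance = 1e-9)

  # perfect prediction
  perf <- diagnostic_metrics(gt, gt)
  expect_equal(perf$metrics$estimate[perf$metrics$metric == "sensitivity"], 1)
  expect_equal(perf$metrics$estimate[perf$metrics$metric == "LR_negative"], 0)

  # all-negative prediction
  none <- diagnostic_metrics(rep("normal", 160), gt)
  expect_equal(none$metrics$estimate[none$metrics$metric == "sensitivity"], 0)
  expect_equal(none$metrics$estimate[none$metrics$metric == "specificity"], 1)

  expect_error(diagnostic_metrics(gt, rep("normal", 160)),
               class = "cephan_error_undefined_metric")
})

test_that("Wilson intervals contain the estimate and tighten with n", {
  for (k in c(1, 5, 9)) {
    ci <- cephan:::wilson_ci(k, 10)
    expect_lte(ci[1], k / 10)
    expect_gte(ci[2], k / 10)
  }
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    diff(cephan:::wilson_ci(round(0.9 * n), n))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("AUC equals the all-pairs Mann-Whitney statistic", {
  r <- roc_auc(c(0.7, 0.65, 0.5, 0.4),
               c("hypertrophic", "normal", "hypertrophic", "normal"),
               n_boot = 10)
  expect_equal(r$auc, 0.75)

  # perfectly separated / all-tied degenerate cases
  lab <- c(rep("hypertrophic", 5), rep("normal", 5))
  expect_equal(roc_auc(c(6:10, 1:5) / 10, lab, n_boot = 10)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), lab, n_boot = 10)$auc, 0.5)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    lab <- sample(c("hypertrophic", "normal"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    sc <- round(stats::runif(n), 2)     # rounding forces ties
    pos <- sc[lab == "hypertrophic"]; neg <- sc[lab != "hypertrophic"]
    wins <- 0
    for (p in pos) for (q in neg) {
      wins <- wins + (p > q) + 0.5 * (p == q)
    }
    expect_equal(roc_auc(sc, lab, n_boot = 10)$auc,
                 wins / (length(pos) * length(neg)), tolerance = 1e-9)
  }
  expect_error(roc_auc(1:4 / 10, rep("normal", 4)),
               class = "cephan_error_undefined_metric")
})

test_that("the ROC curve is monotone and the CI brackets the AUC", {
  set.seed(7)
  lab <- sample(c("hypertrophic", "normal"), 60, replace = TRUE)
  sc <- stats::runif(60) + 0.3 * (lab == "hypertrophic")
  r <- roc_auc(sc, lab, n_boot = 200, seed = 5)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_lte(r$ci_low, r$auc)
  expect_gte(r$ci_high, r$auc)
  expect_true(r$auc >= 0 && r$auc <= 1)
})

test_that("thresholding ground-truth ratios reproduces classify_ah labels", {
  set.seed(8)
  ratios <- stats::runif(200)
  labels <- ifelse(ratios > 0.6, "hypertrophic", "normal")
  rep_ <- diagnostic_metrics(classify_ah(ratios), labels)
  expect_equal(
    rep_$metrics$estimate[rep_$metrics$metric == "accuracy"], 1)
})

test_that("evaluate_predictions assembles the full report", {
  samples <- tiny_samples(30, size = 32, seed = 44)
  gt_df <- cephan:::samples_to_manifest(samples)
  pred_df <- an_ratio(gt_df[, setdiff(names(gt_df),
                                      c("true_ratio", "true_label"))])
  rep_ <- evaluate_predictions(pred_df, gt_df, n_boot = 50)
  expect_s3_class(rep_, "metrics_report")
  expect_equal(rep_$ap, 1)
  expect_lt(rep_$an_error$mae, 0.011)
  g <- glance(rep_)
  expect_true(all(c("ap", "f1", "an_ratio_mae", "sensitivity",
                    "specificity", "accuracy", "auc") %in% names(g)))
  expect_equal(g$auc, 1)  # true ratios separate the classes perfectly
})
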