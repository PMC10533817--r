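test_that("rank AUC handles separation, ties, and matches the all-pairs oracle", {
  expect_equal(auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1)), 1)

  set.seed(71)
  for (r in 1:5) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(1:8, n, replace = TRUE)   # many ties
    pairs <- 0; wins <- 0
    for (i in which(y == 1)) for (j in which(y == 0)) {
      pairs <- pairs + 1
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    expect_equal(auc(s, y), wins / pairs)
  }

  # label-independent scores: AUC near 1/2 at n = 500
  set.seed(72)
  y <- rbinom(500, 1, 0.5); s <- rnorm(500)
  expect_gt(auc(s, y), 0.45); expect_lt(auc(s, y), 0.55)
})

test_that("stratified bootstrap CI brackets the point AUC and matches pROC", {
  set.seed(73)
  y <- rep(0:1, each = 40)
  s <- y + rnorm(80, 0, 0.8)
  ci <- auc_with_ci(s, y, n_boot = 500, seed = 2)
  expect_lte(ci$ci_low, ci$auc); expect_gte(ci$ci_high, ci$auc)
  # independent oracle for the point estimate
  expect_equal(ci$auc, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("Wilson intervals match the printed example and the score-test oracle", {
  w <- wilson_ci(197, 238)
  expect_equal(round(100 * w$estimate), 83)
  expect_equal(round(100 * w$lower), 77)
  expect_equal(round(100 * w$upper), 87)

  expect_equal(wilson_ci(0, 20)$lower, 0)

  # oracle: prop.test without continuity correction computes the same interval
  set.seed(74)
  for (r in 1:10) {
    n <- sample(10:300, 1); k <- sample(0:n, 1)
    w2 <- wilson_ci(k, n, z = qnorm(0.975))
    pt <- prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(w2$lower, pt[1], tolerance = 1e-9)
    expect_equal(w2$upper, pt[2], tolerance = 1e-9)
  }
})

test_that("the specificity threshold is the smallest achieving the target", {
  set.seed(75)
  y <- rep(c(0, 1), c(200, 100))
  s <- c(runif(200), runif(100, 0.5, 1.5))
  res <- sensitivity_at_specificity(s, y, specificity = 0.95)
  healthy <- s[y == 0]
  expect_gte(mean(healthy < res$threshold), 0.95)
  # the next-lower healthy score fails the target
  lower <- max(healthy[healthy < res$threshold])
  expect_lt(mean(healthy < lower), 0.95)
  # sensitivity consistent with its Wilson interval
  w <- wilson_ci(res$n_detected, res$n_cancer)
  expect_equal(res$ci_low, w$lower)
  # ties at the threshold count as positive calls
  expect_equal(res$sensitivity, mean(s[y == 1] >= res$threshold))
})

test_that("clinical LOD recovers a planted 50% crossing and scales with VAF", {
  set.seed(76)
  tf <- runif(200, 0.0005, 0.05)
  vt <- simulate_vaf_table(tf, midpoint = 1e-3, seed = 7)
  fit <- clod(vt$detected, vt$mean_vaf)
  expect_gt(fit$lod, 1e-3 / 1.5); expect_lt(fit$lod, 1e-3 * 1.5)
  expect_lt(fit$ci_low, fit$lod); expect_gt(fit$ci_high, fit$lod)

  # doubling every VAF doubles the LOD
  fit2 <- clod(vt$detected, 2 * vt$mean_vaf)
  expect_equal(fit2$lod, 2 * fit$lod, tolerance = 1e-9)

  expect_error(clod(rep(1, 50), runif(50, 1e-4, 1e-2)), "both detection outcomes")
})

test_that("screening projection reproduces the worked example and conserves people", {
  pr <- screening_projection(0.83, 0.99, 0.015, 100000)
  expect_equal(pr$tp, 1245)
  expect_equal(pr$fp, 985)
  expect_equal(round(100 * pr$ppv), 56)

  perfect <- screening_projection(1, 1, 0.015, 100000)
  expect_equal(perfect$fp, 0)
  expect_equal(perfect$ppv, 1)

  set.seed(77)
  for (r in 1:5) {
    se <- runif(1); sp <- runif(1); inc <- runif(1, 0, 0.1); pop <- 1e5
    pr2 <- screening_projection(se, sp, inc, pop)
    expect_equal(pr2$tp, pop * inc * se)
    expect_equal(pr2$fp, pop * (1 - inc) * (1 - sp))
    expect_equal(pr2$tp + pr2$fn + pr2$fp + pr2$tn, pop)
  }
})

test_that("association profiles count commonly altered windows and correlations", {
  z0 <- matrix(0, 10, 50)
  jitter_m <- function() matrix(rnorm(500, 0, 1e-6), 10)
  out <- association_profiles(z0 + jitter_m(), z0 + jitter_m(), z0 + jitter_m())
  expect_equal(unname(out$commonly_altered), c(0, 0, 0))

  # planted: 30% of windows shifted 3 SD in every sample of one feature
  set.seed(78)
  n_w <- 300
  mk <- function() matrix(rnorm(20 * n_w), 20)
  fsi <- mk(); mfr <- mk(); cna <- mk()
  fsi[, 1:(0.3 * n_w)] <- fsi[, 1:(0.3 * n_w)] + 3
  out2 <- association_profiles(fsi, mfr, cna)
  expect_equal(unname(out2$commonly_altered["fsi"]), 0.30, tolerance = 0.067)

  # per-sample correlations equal the covariance formula
  i <- 3
  expect_equal(unname(out2$correlations[i, "mfr_cna"]),
               cov(mfr[i, ], cna[i, ]) / (sd(mfr[i, ]) * sd(cna[i, ])))
})

test_that("split harnesses enumerate combinations and reproduce under a seed", {
  strata <- rep(c("healthy", "cancer"), each = 20)
  groups <- rep(rep(c("site1", "site2"), each = 10), 2)
  res <- grouped_split_harness(strata, groups, function(tr, te) length(te))
  expect_equal(nrow(res), 4)  # 2 strata x 2 groups
  expect_true(all(res$metric == 20))

  # product rule with unequal group counts
  strata2 <- rep(c("a", "b"), c(30, 20))
  groups2 <- c(rep(c("g1", "g2", "g3"), each = 10), rep(c("h1", "h2"), each = 10))
  res2 <- grouped_split_harness(strata2, groups2, function(tr, te) 1)
  expect_equal(nrow(res2), 3 * 2)

  labels <- rep(0:1, each = 30)
  m1 <- repeated_split_harness(labels, function(tr, te) mean(labels[te]),
                               n_repeats = 5, seed = 9)
  m2 <- repeated_split_harness(labels, function(tr, te) mean(labels[te]),
                               n_repeats = 5, seed = 9)
  expect_identical(m1, m2)
  expect_length(repeated_split_harness(labels, function(tr, te) 1,
                                       n_repeats = 1, seed = 1), 1)
})
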