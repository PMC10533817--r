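test_that("peak methylation is the methylated fraction of CpG observations", {
  peaks <- data.frame(chrom = "chrA", start = c(1000, 5000), end = c(1500, 5500))
  fr <- sample_fragments(do.call(rbind, list(
    frag_df(start = 1100, length = 160, cpg_total = 6, cpg_methylated = 2),
    frag_df(start = 1200, length = 160, cpg_total = 4, cpg_methylated = 2))))
  pm <- peak_methylation(fr, peaks)
  expect_equal(pm[1], 0.4)           # 4 methylated of 10 observations
  expect_true(is.na(pm[2]))          # no fragments

  # 50 simulated peaks vs a per-observation counting oracle
  set.seed(61)
  pk50 <- data.frame(chrom = "chrA", start = seq(0, by = 2000, length.out = 50),
                     end = seq(0, by = 2000, length.out = 50) + 500)
  fr2 <- random_fragments(800, c(chrA = 1.1e5), seed = 62)
  got <- peak_methylation(fr2, pk50)
  meth <- tot <- numeric(50)
  for (i in seq_len(nrow(fr2))) {
    mid <- floor((fr2$start[i] + fr2$end[i]) / 2)
    j <- which(pk50$start <= mid & mid < pk50$end)
    if (!length(j)) next
    meth[j] <- meth[j] + fr2$cpg_methylated[i]
    tot[j] <- tot[j] + fr2$cpg_total[i]
  }
  expect_equal(got, ifelse(tot > 0, meth / tot, NA_real_))
})

test_that("hypomethylated-peak selection controls the null and finds planted peaks", {
  set.seed(63)
  # null: retained fraction below 2 x alpha over 1000 peaks
  cancer <- matrix(runif(10 * 1000), 10)
  healthy <- matrix(runif(10 * 1000), 10)
  kept <- select_hypomethylated_peaks(cancer, healthy, alpha = 0.05)
  expect_lt(mean(kept), 0.10)

  # maximal separation: everything retained
  all0 <- matrix(0, 10, 20); all1 <- matrix(1, 10, 20)
  expect_true(all(select_hypomethylated_peaks(all0, all1)))

  # planted: 80% of peaks hypomethylated by 0.3 at n = 50/50
  n_pk <- 200
  healthy2 <- matrix(runif(50 * n_pk, 0.4, 0.9), 50)
  cancer2 <- matrix(runif(50 * n_pk, 0.4, 0.9), 50)
  planted <- seq_len(0.8 * n_pk)
  cancer2[, planted] <- pmax(cancer2[, planted] - 0.3, 0)
  kept2 <- select_hypomethylated_peaks(cancer2, healthy2)
  expect_gt(mean(kept2[planted]), 0.95)

  expect_error(select_hypomethylated_peaks(cancer[1, , drop = FALSE], healthy),
               "2 samples")
})

test_that("per-sample min-max scaling maps z-vectors into [0,1]", {
  z <- seq(-2, 2, length.out = 18)
  s <- themis:::scale01(z)
  expect_equal(s, seq(0, 1, length.out = 18))
  # affine invariance
  expect_equal(themis:::scale01(3 * z + 7), s)
  # degenerate constant vector
  expect_equal(themis:::scale01(rep(1.3, 18)), rep(0.5, 18))
})

test_that("cluster features highlight a planted hypomethylated cluster", {
  cfg <- simulation_config(seed = 64, n_healthy = 8, n_cancer = 1,
                           cancer_types = "COREADish",
                           cluster_effects = list(COREADish = 2L),
                           fragments_per_sample = 20000, signal = "strong",
                           n_clusters = 6, peaks_per_cluster = 40)
  sim <- simulate_cohort(cfg)
  peaks <- sim$genome$peaks
  retained <- rep(TRUE, nrow(peaks))
  baseline <- build_cso_baseline(sim$samples[1:8], peaks, retained)
  feats <- cluster_features(sim$samples[["C001"]], peaks, retained, baseline)
  m <- feats[startsWith(names(feats), "m_")]
  expect_equal(names(which.min(m)), "m_c02")
  expect_true(all(feats >= 0 & feats <= 1))
})

test_that("the signal-origin forest separates planted classes and not shuffled ones", {
  set.seed(65)
  classes <- c("BRCA", "NSCLC", "ESCA", "STAD", "COREAD", "LIHC", "PACA")
  n_per <- 20
  y <- factor(rep(classes, each = n_per), levels = classes)
  x <- matrix(runif(length(y) * 54, 0.3, 0.7), length(y), 54,
              dimnames = list(NULL, paste0("f", 1:54)))
  for (k in seq_along(classes)) {       # strong class-specific depression
    rows <- which(y == classes[k])
    x[rows, (k - 1) * 3 + 1:3] <- x[rows, (k - 1) * 3 + 1:3] - 0.45
  }
  fit <- cso_fit(x, y, ntree = 300, seed = 6)
  expect_gt(mean(fit$loo_predictions == y), 0.9)

  y_shuf <- sample(y)
  fit0 <- cso_fit(x, y_shuf, ntree = 300, seed = 6)
  acc0 <- mean(fit0$loo_predictions == y_shuf)
  expect_lt(abs(acc0 - 1 / 7), 0.1)

  # determinism under a fixed seed
  fit2 <- cso_fit(x, y, ntree = 300, seed = 6)
  expect_identical(fit$loo_predictions, fit2$loo_predictions)
  expect_identical(predict(fit, x[1:5, ]), predict(fit2, x[1:5, ]))

  expect_error(cso_fit(x[1:21, ], factor(c(rep("A", 20), "B")), ntree = 10),
               "at least 2")
})

test_that("merged-group accuracy counts within-group confusions as correct", {
  classes <- c("BRCA", "NSCLC", "ESCA", "STAD", "COREAD", "LIHC", "PACA")
  ident <- diag(7) * 10
  dimnames(ident) <- list(classes, classes)
  acc <- merged_accuracy(ident)
  expect_equal(acc$raw_accuracy, 1)
  expect_equal(acc$merged_accuracy, 1)

  # all STAD predicted COREAD: raw 0, merged 1 (same digestive group)
  m <- matrix(0, 7, 7, dimnames = list(classes, classes))
  m["STAD", "COREAD"] <- 10
  acc2 <- merged_accuracy(m)
  expect_equal(acc2$raw_accuracy, 0)
  expect_equal(acc2$merged_accuracy, 1)

  # random matrices: double-loop oracle and merged >= raw
  set.seed(66)
  groups <- cso_merge_groups()
  group_of <- stats::setNames(classes, classes)
  for (g in names(groups)) group_of[classes %in% groups[[g]]] <- g
  for (r in 1:10) {
    cm <- matrix(rpois(49, 3), 7, 7, dimnames = list(classes, classes))
    acc3 <- merged_accuracy(cm)
    correct <- 0
    for (i in 1:7) for (j in 1:7)
      if (group_of[classes[i]] == group_of[classes[j]]) correct <- correct + cm[i, j]
    expect_equal(acc3$merged_accuracy, correct / sum(cm))
    expect_gte(acc3$merged_accuracy, acc3$raw_accuracy)
  }
})
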