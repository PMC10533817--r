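#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney statistic; ties count one half).
#'
#' @param scores numeric classifier scores
#' @param labels binary labels (cancer = 1)
#' @return AUC in \[0,1\]
#' @export
auc <- function(scores, labels) {
  y <- binarize_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a stratified-bootstrap confidence interval
#'
#' Percentile 95% CI from `n_boot` bootstrap replicates resampled within
#' each class (2000 replicates by default).
#'
#' @inheritParams auc
#' @param n_boot bootstrap replicates (default 2000)
#' @param seed integer seed
#' @param conf confidence level (default 0.95)
#' @return list with `auc`, `ci_low`, `ci_high`
#' @export
auc_with_ci <- function(scores, labels, n_boot = 2000, seed = 1, conf = 0.95) {
  y <- binarize_labels(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  point <- auc(scores, y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    ii <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    auc(scores[ii], y[ii])
  }, numeric(1))
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(auc = point, ci_low = q[1], ci_high = q[2])
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes
#' @param n trials
#' @param z normal quantile (default 1.959964, the two-sided 95% level)
#' @return list with `estimate`, `lower`, `upper`
#' @export
wilson_ci <- function(k, n, z = 1.959964) {
  stopifnot(n > 0, k >= 0, k <= n)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Sensitivity at a fixed specificity
#'
#' The decision threshold is the smallest score cut achieving at least the
#' target specificity on the healthy samples (a call is positive when
#' score >= threshold, so ties at the threshold count as positive calls);
#' sensitivity is then computed on the cancer samples with a 95% Wilson
#' interval.
#'
#' @inheritParams auc
#' @param specificity target specificity (default 0.99)
#' @return list with `threshold`, `sensitivity`, `ci_low`, `ci_high`,
#'   `specificity_achieved`
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.99) {
  y <- binarize_labels(labels)
  healthy <- sort(scores[y == 0])
  cancer <- scores[y == 1]
  # candidate cuts at every observed score, plus Inf for the no-call limit
  candidates <- c(sort(unique(scores)), Inf)
  spec_at <- vapply(candidates, function(t) mean(healthy < t), numeric(1))
  ok <- which(spec_at >= specificity)
  thr <- candidates[ok[1]]
  k <- sum(cancer >= thr)
  ci <- wilson_ci(k, length(cancer))
  list(threshold = thr, sensitivity = ci$estimate,
       ci_low = ci$lower, ci_high = ci$upper,
       specificity_achieved = mean(healthy < thr),
       n_detected = k, n_cancer = length(cancer))
}

#' Clinical limit of detection
#'
#' Fits a logistic regression of binary detection outcomes on log10(mean
#' variant allele fraction); the clinical LOD is the mean VAF at which the
#' detection probability crosses 50%, with a 95% CI from a Gaussian (delta
#' method) approximation of the crossing point's standard error on the log10
#' scale.
#'
#' @param detected binary detection outcomes
#' @param mean_vaf positive per-sample mean variant allele fractions
#' @return list with `lod`, `ci_low`, `ci_high`, and the fitted `model`
#' @export
clod <- function(detected, mean_vaf) {
  detected <- binarize_labels(detected)
  stopifnot(all(mean_vaf > 0))
  if (length(unique(detected)) < 2)
    stop("both detection outcomes required; no 50% crossing exists")
  lv <- log10(mean_vaf)
  fit <- suppressWarnings(stats::glm(detected ~ lv, family = stats::binomial()))
  if (!fit$converged || max(abs(stats::coef(fit))) > 50)
    warning("near-perfect separation; boundary estimate reported")
  a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
  x50 <- -a / b
  V <- stats::vcov(fit)
  grad <- c(-1 / b, a / b^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- 1.959964
  list(lod = 10^x50, ci_low = 10^(x50 - z * se), ci_high = 10^(x50 + z * se),
       model = fit)
}

#' Population screening projection
#'
#' Projects a test's yield onto a screening population: expected true and
#' false positives per `population` screened at the given annual cancer
#' incidence, and the implied positive predictive value.
#'
#' @param sensitivity,specificity test operating point in \[0,1\]
#' @param incidence cancer incidence (fraction of the population)
#' @param population number screened
#' @return list with `tp`, `fp`, `fn`, `tn`, `ppv`
#' @export
screening_projection <- function(sensitivity, specificity, incidence, population) {
  tp <- population * incidence * sensitivity
  fn <- population * incidence * (1 - sensitivity)
  fp <- population * (1 - incidence) * (1 - specificity)
  tn <- population * (1 - incidence) * specificity
  list(tp = tp, fp = fp, fn = fn, tn = tn, ppv = tp / (tp + fp))
}

#' Cross-modality association profiles
#'
#' For aligned per-window z-score matrices (samples x windows) of the size
#' index, methylated fragment ratio and copy number: per-sample pairwise
#' Pearson correlations among the three window profiles, and per feature the
#' fraction of windows altered (|z| > `z_cut`) in at least half of the
#' samples ("commonly altered windows").
#'
#' @param fsi_z,mfr_z,cna_z matrices (samples x windows), aligned
#' @param z_cut alteration threshold (default 2)
#' @return list with `correlations` (samples x 3: fsi_mfr, fsi_cna, mfr_cna)
#'   and `commonly_altered` (fractions per feature)
#' @export
association_profiles <- function(fsi_z, mfr_z, cna_z, z_cut = 2) {
  stopifnot(all(dim(fsi_z) == dim(mfr_z)), all(dim(fsi_z) == dim(cna_z)))
  cors <- t(vapply(seq_len(nrow(fsi_z)), function(i) {
    c(fsi_mfr = stats::cor(fsi_z[i, ], mfr_z[i, ], use = "complete.obs"),
      fsi_cna = stats::cor(fsi_z[i, ], cna_z[i, ], use = "complete.obs"),
      mfr_cna = stats::cor(mfr_z[i, ], cna_z[i, ], use = "complete.obs"))
  }, numeric(3)))
  common <- function(zm) {
    frac_altered <- colMeans(abs(zm) > z_cut, na.rm = TRUE)
    mean(frac_altered >= 0.5)
  }
  list(correlations = cors,
       commonly_altered = c(fsi = common(fsi_z), mfr = common(mfr_z),
                            cna = common(cna_z)))
}

#' Hold-one-group-out evaluation harness
#'
#' Enumerates the cartesian product of one held-out group per cohort stratum
#' (e.g. one hospital's healthy samples and one hospital's cancer samples)
#' and calls `eval_fun(train_idx, test_idx)` for each combination.
#'
#' @param strata factor assigning each sample to a stratum (e.g. label)
#' @param groups factor assigning each sample to a group (e.g. site)
#' @param eval_fun function of (train indices, test indices) returning a
#'   single numeric metric
#' @return data.frame with one row per combination and its metric
#' @export
grouped_split_harness <- function(strata, groups, eval_fun) {
  strata <- as.factor(strata); groups <- as.factor(groups)
  per_stratum <- lapply(levels(strata), function(s)
    unique(as.character(groups[strata == s])))
  names(per_stratum) <- levels(strata)
  combos <- expand.grid(per_stratum, stringsAsFactors = FALSE)
  res <- vapply(seq_len(nrow(combos)), function(i) {
    test <- rep(FALSE, length(strata))
    for (s in levels(strata))
      test <- test | (strata == s & as.character(groups) == combos[i, s])
    eval_fun(which(!test), which(test))
  }, numeric(1))
  cbind(combos, metric = res)
}

#' Repeated stratified-split evaluation harness
#'
#' Performs `n_repeats` stratified random splits of the cohort at the given
#' training ratio and evaluates each split.
#'
#' @param labels stratification labels
#' @param eval_fun function of (train indices, test indices) returning a
#'   single numeric metric
#' @param ratio training fraction (default 0.7)
#' @param n_repeats number of splits (default 100)
#' @param seed integer seed
#' @return numeric vector of metrics, one per split
#' @export
repeated_split_harness <- function(labels, eval_fun, ratio = 0.7,
                                   n_repeats = 100, seed = 1) {
  labels <- as.factor(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(n_repeats), function(r) {
    tr <- unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, max(1, round(ratio * length(idx))))
    }), use.names = FALSE)
    eval_fun(tr, setdiff(seq_along(labels), tr))
  }, numeric(1))
}
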