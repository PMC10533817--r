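#' Per-modality base classifier (PCA + bootstrap sub-models)
#'
#' Trains the published base-model recipe for one feature modality: 10
#' bootstraps of the training cohort each take a stratified 70% for model
#' fitting and hold out 30% for validation. Within each bootstrap the
#' features are reduced by PCA to the smallest number of leading components
#' explaining at least `variance_threshold` of the training-fold variance
#' (95% for the methylated fragment ratio and end motifs, 90% for the size
#' index), and a classifier is fitted on the components: a support vector
#' machine with 10-fold cross-validated cost/kernel selection for MFR and
#' FSI, a logistic regression for FEM. The prediction score of a sample is
#' the mean probability over the 10 sub-models.
#'
#' Missing feature values (e.g. windows with no qualifying fragments) are
#' imputed with the training-fold column mean.
#'
#' @param features numeric matrix, samples x features
#' @param labels binary vector (logical, 0/1, or 2-level factor); the second
#'   level / `TRUE` / `1` is the cancer class
#' @param modality one of `"MFR"`, `"FSI"`, `"FEM"` (sets defaults)
#' @param variance_threshold PCA explained-variance threshold; default by
#'   modality
#' @param model_family `"svm"` or `"logistic"`; default by modality
#' @param n_boot number of bootstraps (default 10)
#' @param seed integer seed controlling all bootstrap randomness
#' @param cost_grid SVM cost grid (default 0.1, 1, 10, 100)
#' @param kernels SVM kernels tried (default linear and radial)
#' @return an object of class `themis_base`
#' @export
train_base_model <- function(features, labels,
                             modality = c("MFR", "FSI", "FEM"),
                             variance_threshold = NULL, model_family = NULL,
                             n_boot = 10, seed = 1,
                             cost_grid = c(0.1, 1, 10, 100),
                             kernels = c("linear", "radial")) {
  modality <- match.arg(modality)
  if (is.null(variance_threshold))
    variance_threshold <- c(MFR = 0.95, FSI = 0.90, FEM = 0.95)[[modality]]
  if (is.null(model_family))
    model_family <- c(MFR = "svm", FSI = "svm", FEM = "logistic")[[modality]]
  features <- as.matrix(features)
  if (ncol(features) < 2) stop("need at least 2 features")
  y <- binarize_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(y) < 20) stop("need at least 20 samples")
  n <- length(y)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boot_seeds <- sample.int(1e6, n_boot)
  sub_models <- vector("list", n_boot)
  oof_sum <- numeric(n); oof_n <- numeric(n)
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    tr <- stratified_sample(y, 0.7)
    va <- setdiff(seq_len(n), tr)
    sm <- fit_sub_model(features[tr, , drop = FALSE], y[tr],
                        variance_threshold, model_family, cost_grid, kernels)
    sm$train_idx <- tr
    sub_models[[b]] <- sm
    p <- predict_sub_model(sm, features[va, , drop = FALSE])
    oof_sum[va] <- oof_sum[va] + p
    oof_n[va] <- oof_n[va] + 1
  }
  obj <- structure(
    list(modality = modality, variance_threshold = variance_threshold,
         model_family = model_family, sub_models = sub_models,
         labels = y, seed = seed),
    class = "themis_base")
  full <- predict(obj, features)
  oof <- ifelse(oof_n > 0, oof_sum / pmax(oof_n, 1), full)
  obj$oof_scores <- oof
  obj
}

binarize_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly 2 levels")
    as.integer(labels) - 1L
  } else if (is.logical(labels)) as.integer(labels)
  else {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(labels)
  }
}

stratified_sample <- function(y, frac) {
  unlist(lapply(unique(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1, round(frac * length(idx))))
  }), use.names = FALSE)
}

fit_sub_model <- function(x, y, variance_threshold, model_family,
                          cost_grid, kernels) {
  col_mean <- colMeans(x, na.rm = TRUE)
  col_mean[is.na(col_mean)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- col_mean[j]
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  k <- which(cumsum(ev) >= variance_threshold)[1]
  if (is.na(k)) k <- length(ev)
  k <- max(k, 2L)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  yf <- factor(y, levels = c(0, 1))
  if (model_family == "svm") {
    cross <- min(10, length(y))
    tuned <- e1071::tune(e1071::svm, train.x = scores, train.y = yf,
                         ranges = list(cost = cost_grid, kernel = kernels),
                         probability = TRUE,
                         tunecontrol = e1071::tune.control(cross = cross))
    fit <- tuned$best.model
  } else {
    dat <- data.frame(y = yf, scores)
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  }
  list(center = pca$center, rotation = pca$rotation[, seq_len(k), drop = FALSE],
       impute = col_mean, k = k, fit = fit, family = model_family)
}

predict_sub_model <- function(sm, x) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- sm$impute[j]
  scores <- sweep(x, 2, sm$center) %*% sm$rotation
  if (sm$family == "svm") {
    pr <- stats::predict(sm$fit, scores, probability = TRUE)
    probs <- attr(pr, "probabilities")
    unname(probs[, "1"])
  } else {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    dat <- as.data.frame(scores)
    unname(stats::predict(sm$fit, newdata = dat, type = "response"))
  }
}

#' @export
predict.themis_base <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p <- vapply(object$sub_models, predict_sub_model, numeric(nrow(newdata)),
              x = newdata)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  rowMeans(p)
}

#' @export
print.themis_base <- function(x, ...) {
  cat(sprintf("<themis_base> %s: %d sub-models (%s), variance threshold %.0f%%\n",
              x$modality, length(x$sub_models), x$model_family,
              100 * x$variance_threshold))
  invisible(x)
}

#' Elastic-net logistic ensemble over the four modality scores
#'
#' Fits a logistic generalized linear model with elastic-net penalization on
#' the three base-model scores plus the log10 plasma-aneuploidy score; the
#' penalty mixing parameter and strength are chosen by 20-fold
#' cross-validated deviance.
#'
#' @param base_scores matrix (samples x 3) with columns `mfr`, `fsi`, `fem`
#' @param caff_log10 per-sample log10(PA + 1) vector
#' @param labels binary labels (cancer = 1)
#' @param seed integer seed (fold assignment)
#' @param nfolds cross-validation folds (default 20; reduced with a warning
#'   when the cohort is smaller)
#' @param alphas elastic-net mixing grid (default 0, 0.25, 0.5, 0.75, 1)
#' @return an object of class `themis_ensemble` with `intercept` and
#'   `coefficients` (mfr, fsi, caff, fem)
#' @export
train_ensemble <- function(base_scores, caff_log10, labels, seed = 1,
                           nfolds = 20, alphas = c(0, 0.25, 0.5, 0.75, 1)) {
  y <- binarize_labels(labels)
  x <- cbind(mfr = base_scores[, 1], fsi = base_scores[, 2],
             caff = caff_log10, fem = base_scores[, 3])
  stopifnot(nrow(x) == length(y))
  if (length(y) < 3 * nfolds) {
    nfolds <- max(3, floor(length(y) / 3))
    warning(sprintf("cohort too small for the requested folds; reducing to %d",
                    nfolds))
  }
  if (all(apply(x, 2, stats::sd) == 0)) {
    # no informative predictor: intercept-only logistic limit
    return(structure(list(intercept = stats::qlogis(mean(y)),
                          coefficients = stats::setNames(rep(0, 4), colnames(x)),
                          alpha = NA_real_, lambda = NA_real_,
                          cv_deviance = NA_real_),
                     class = "themis_ensemble"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- stratified_folds(y, nfolds)
  best <- NULL
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = a,
                            foldid = foldid, type.measure = "deviance")
    cvm <- min(cv$cvm)
    if (is.null(best) || cvm < best$cvm)
      best <- list(cv = cv, alpha = a, cvm = cvm)
  }
  cf <- as.numeric(stats::coef(best$cv, s = "lambda.min"))
  structure(list(intercept = cf[1],
                 coefficients = stats::setNames(cf[-1], colnames(x)),
                 alpha = best$alpha, lambda = best$cv$lambda.min,
                 cv_deviance = best$cvm),
            class = "themis_ensemble")
}

stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' The THEMIS score
#'
#' Evaluates the logistic ensemble: Pr(cancer) = exp(Z)/(1 + exp(Z)) with
#' Z = intercept + b_mfr * MFR + b_fsi * FSI + b_caff * CAFF + b_fem * FEM,
#' where MFR/FSI/FEM are the base-model probability scores and CAFF the
#' log10-transformed plasma aneuploidy score.
#'
#' @param model a `themis_ensemble` (e.g. [themis_reference_model])
#' @param mfr_score,fsi_score,caff_log10,fem_score numeric inputs (vectors
#'   recycle as usual)
#' @return probability in (0, 1)
#' @export
themis_score <- function(model, mfr_score, fsi_score, caff_log10, fem_score) {
  cf <- model$coefficients
  z <- model$intercept + cf[["mfr"]] * mfr_score + cf[["fsi"]] * fsi_score +
    cf[["caff"]] * caff_log10 + cf[["fem"]] * fem_score
  stats::plogis(z)
}

#' Reference coefficients of the original THEMIS ensemble
#'
#' The published ensemble evaluates
#' Z = 0.57 + 0.33 * MFR + 0.34 * FSI + 0.06 * CAFF + 0.58 * FEM and
#' Pr(cancer) = exp(Z)/(1 + exp(Z)). Shipped as a ready-made
#' `themis_ensemble` so scores can be computed without retraining.
#' @export
themis_reference_model <- structure(
  list(intercept = 0.57,
       coefficients = c(mfr = 0.33, fsi = 0.34, caff = 0.06, fem = 0.58),
       alpha = NA_real_, lambda = NA_real_, cv_deviance = NA_real_),
  class = "themis_ensemble")

#' @export
print.themis_ensemble <- function(x, ...) {
  cat("<themis_ensemble> Z =", format(x$intercept, digits = 3))
  for (nm in names(x$coefficients))
    cat(sprintf(" + %s*%s", format(x$coefficients[[nm]], digits = 3), toupper(nm)))
  cat("\n")
  invisible(x)
}

#' @export
coef.themis_ensemble <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Fit the full multimodal cancer-detection model
#'
#' The main fitting entry point: trains the three per-modality base models
#' (MFR and FSI support vector machines, FEM logistic regression, each a
#' 10-bootstrap PCA ensemble) and integrates their out-of-fold training
#' scores with the log10 plasma-aneuploidy score in an elastic-net logistic
#' ensemble. Out-of-fold base scores are used for ensemble training to limit
#' information leakage from the base models.
#'
#' @param mfr,fsi,fem per-sample feature matrices (samples x windows/motifs)
#' @param caff_log10 per-sample log10(PA + 1) vector
#' @param labels binary labels (cancer = 1)
#' @param seed integer seed for all training randomness
#' @param ... passed through to [train_base_model()]
#' @return an object of class `themis_fit` with `print`, `summary`, `coef`
#'   and `predict` methods
#' @export
themis_fit <- function(mfr, fsi, fem, caff_log10, labels, seed = 1, ...) {
  y <- binarize_labels(labels)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seeds <- sample.int(1e6, 4)
  base <- list(
    mfr = train_base_model(mfr, y, "MFR", seed = seeds[1], ...),
    fsi = train_base_model(fsi, y, "FSI", seed = seeds[2], ...),
    fem = train_base_model(fem, y, "FEM", seed = seeds[3], ...))
  oof <- cbind(mfr = base$mfr$oof_scores, fsi = base$fsi$oof_scores,
               fem = base$fem$oof_scores)
  ensemble <- train_ensemble(oof, caff_log10, y, seed = seeds[4])
  train_scores <- themis_score(ensemble, oof[, "mfr"], oof[, "fsi"],
                               caff_log10, oof[, "fem"])
  structure(list(base = base, ensemble = ensemble, labels = y,
                 train_scores = train_scores, seed = seed,
                 n = length(y)),
            class = "themis_fit")
}

#' @export
#' @rdname themis_fit
#' @param object a `themis_fit`
#' @param newdata list with elements `mfr`, `fsi`, `fem` (feature matrices)
#'   and `caff_log10` (vector) for the samples to score
predict.themis_fit <- function(object, newdata, ...) {
  p_mfr <- predict(object$base$mfr, newdata$mfr)
  p_fsi <- predict(object$base$fsi, newdata$fsi)
  p_fem <- predict(object$base$fem, newdata$fem)
  themis_score(object$ensemble, p_mfr, p_fsi, newdata$caff_log10, p_fem)
}

#' @export
print.themis_fit <- function(x, ...) {
  cat(sprintf("<themis_fit> trained on %d samples (%d cancer, %d healthy)\n",
              x$n, sum(x$labels == 1), sum(x$labels == 0)))
  print(x$ensemble)
  invisible(x)
}

#' @export
coef.themis_fit <- function(object, ...) coef(object$ensemble)

#' @export
summary.themis_fit <- function(object, ...) {
  a <- auc(object$train_scores, object$labels)
  out <- list(n = object$n, n_cancer = sum(object$labels == 1),
              ensemble = coef(object$ensemble),
              alpha = object$ensemble$alpha, lambda = object$ensemble$lambda,
              train_auc = a)
  class(out) <- "summary.themis_fit"
  out
}

#' @export
print.summary.themis_fit <- function(x, ...) {
  cat(sprintf("Multimodal cfDNA cancer-detection fit\n  samples: %d (%d cancer)\n",
              x$n, x$n_cancer))
  cat(sprintf("  elastic net: alpha = %.2f, lambda = %.4g\n", x$alpha, x$lambda))
  cat("  ensemble coefficients:\n")
  print(round(x$ensemble, 4))
  cat(sprintf("  apparent (out-of-fold base score) training AUC: %.3f\n", x$train_auc))
  invisible(x)
}
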