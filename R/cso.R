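#' Per-peak methylation level
#'
#' The methylation level of an open-chromatin peak is the fraction of
#' methylated CpG observations among fragments assigned to the peak (by
#' fragment midpoint, the same convention as genomic binning). Peaks with no
#' CpG observations are `NA`.
#'
#' @param sample a `sample_fragments` data.frame
#' @param peaks data.frame with `chrom`, `start`, `end` (one row per peak)
#' @return numeric vector of per-peak methylated fractions
#' @export
peak_methylation <- function(sample, peaks) {
  n <- nrow(peaks)
  meth <- tot <- numeric(n)
  if (nrow(sample)) {
    mid <- floor((sample$start + sample$end) / 2)
    for (ch in unique(peaks$chrom)) {
      p <- which(peaks$chrom == ch)
      f <- which(sample$chrom == ch)
      if (!length(f)) next
      o <- order(peaks$start[p])
      ps <- peaks$start[p][o]; pe <- peaks$end[p][o]
      slot <- findInterval(mid[f], ps)
      ok <- slot >= 1
      ok[ok] <- mid[f][ok] < pe[slot[ok]]
      if (!any(ok)) next
      tgt <- p[o][slot[ok]]
      src <- f[ok]
      meth_add <- tapply(sample$cpg_methylated[src], tgt, sum)
      tot_add <- tapply(sample$cpg_total[src], tgt, sum)
      ii <- as.integer(names(meth_add))
      meth[ii] <- meth[ii] + meth_add
      tot[ii] <- tot[ii] + tot_add
    }
  }
  ifelse(tot > 0, meth / tot, NA_real_)
}

#' Select peaks hypomethylated in cancer
#'
#' Per peak, a one-sided Wilcoxon rank-sum test of cancer methylation below
#' healthy methylation; peaks with p < `alpha` are retained. On real
#' whole-methylome cohorts this keeps roughly 90% of open-chromatin peaks,
#' reflecting the broad hypomethylation of accessible chromatin in tumors.
#'
#' @param cancer_peak_meth,healthy_peak_meth matrices (samples x peaks)
#' @param alpha significance level (default 0.05)
#' @return logical vector of retained peaks
#' @export
select_hypomethylated_peaks <- function(cancer_peak_meth, healthy_peak_meth,
                                        alpha = 0.05) {
  stopifnot(ncol(cancer_peak_meth) == ncol(healthy_peak_meth))
  if (nrow(cancer_peak_meth) < 2 || nrow(healthy_peak_meth) < 2)
    stop("need at least 2 samples per group")
  vapply(seq_len(ncol(cancer_peak_meth)), function(j) {
    x <- cancer_peak_meth[, j]; y <- healthy_peak_meth[, j]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) return(FALSE)
    if (stats::sd(c(x, y)) == 0) return(FALSE)
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less")$p.value)
    p < alpha
  }, logical(1))
}

# Min-max scale a z-vector to [0,1] per sample; a constant (degenerate)
# vector maps to all 0.5.
scale01 <- function(z) {
  rng <- range(z, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] == 0) return(rep(0.5, length(z)))
  out <- (z - rng[1]) / (rng[2] - rng[1])
  out[is.na(out)] <- 0.5
  out
}

#' Per-cluster methylation and fragmentation features
#'
#' For each of the peak clusters: the mean methylation over retained
#' (cancer-hypomethylated) peaks is z-scored against the healthy baseline of
#' that cluster and the z-vector min-max scaled to \[0,1\] within the sample;
#' identically for the aggregate short-fragment (100-166 bp) and
#' long-fragment (169-240 bp) counts over the cluster's peaks (normalised to
#' per-sample proportions before z-scoring so depth cancels). Clusters with
#' no retained peaks are imputed at 0.5 with a warning.
#'
#' @param sample a `sample_fragments` data.frame
#' @param peaks peak table from [load_peak_clusters()]
#' @param retained logical vector over peaks from
#'   [select_hypomethylated_peaks()]
#' @param baseline per-cluster healthy baseline from [build_cso_baseline()]
#' @param gates size gates
#' @return named numeric vector of 3 x n_cluster features
#'   (`m_<cluster>`, `s_<cluster>`, `l_<cluster>`)
#' @export
cluster_features <- function(sample, peaks, retained, baseline,
                             gates = size_gates()) {
  raw <- cluster_raw_features(sample, peaks, retained, gates)
  feats <- lapply(c("meth", "short", "long"), function(what) {
    z <- (raw[[what]] - baseline[[what]]$mean) / baseline[[what]]$sd
    z[baseline[[what]]$sd == 0] <- NA_real_
    if (anyNA(z))
      warning("clusters without usable features imputed at 0.5: ",
              paste(names(z)[is.na(z)], collapse = ", "))
    scale01(z)
  })
  clusters <- names(raw$meth)
  stats::setNames(unlist(feats),
                  c(paste0("m_", clusters), paste0("s_", clusters),
                    paste0("l_", clusters)))
}

# Raw per-cluster quantities shared between samples and the baseline:
# mean retained-peak methylation, and short/long fragment counts over the
# cluster's peaks as proportions of the sample's genome-wide gated totals.
cluster_raw_features <- function(sample, peaks, retained, gates = size_gates()) {
  clusters <- sort(unique(peaks$cluster))
  pm <- peak_methylation(sample, peaks)
  mid <- floor((sample$start + sample$end) / 2)
  short_gate <- sample$length >= gates$short_range[1] & sample$length <= gates$short_range[2]
  long_gate <- sample$length >= gates$long_range[1] & sample$length <= gates$long_range[2]
  in_peak_cluster <- rep(NA_character_, nrow(sample))
  for (ch in unique(peaks$chrom)) {
    p <- which(peaks$chrom == ch)
    f <- which(sample$chrom == ch)
    if (!length(f)) next
    o <- order(peaks$start[p])
    slot <- findInterval(mid[f], peaks$start[p][o])
    ok <- slot >= 1
    ok[ok] <- mid[f][ok] < peaks$end[p][o][slot[ok]]
    in_peak_cluster[f[ok]] <- peaks$cluster[p[o][slot[ok]]]
  }
  n_short <- max(sum(short_gate), 1)
  n_long <- max(sum(long_gate), 1)
  meth <- short <- long <- stats::setNames(numeric(length(clusters)), clusters)
  for (cl in clusters) {
    keep <- retained & peaks$cluster == cl
    v <- pm[keep]
    meth[cl] <- if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
    inc <- !is.na(in_peak_cluster) & in_peak_cluster == cl
    short[cl] <- sum(inc & short_gate) / n_short
    long[cl] <- sum(inc & long_gate) / n_long
  }
  list(meth = meth, short = short, long = long)
}

#' Healthy per-cluster baseline for signal-origin features
#'
#' @param healthy_samples list of `sample_fragments`
#' @param peaks peak table
#' @param retained retained-peak mask (the same subset used for cancer
#'   samples)
#' @param gates size gates
#' @return list of per-cluster `mean`/`sd` for methylation, short and long
#'   coverage
#' @export
build_cso_baseline <- function(healthy_samples, peaks, retained,
                               gates = size_gates()) {
  raw <- lapply(healthy_samples, cluster_raw_features, peaks = peaks,
                retained = retained, gates = gates)
  per <- function(what) {
    m <- do.call(rbind, lapply(raw, `[[`, what))
    list(mean = colMeans(m, na.rm = TRUE),
         sd = apply(m, 2, stats::sd, na.rm = TRUE))
  }
  list(meth = per("meth"), short = per("short"), long = per("long"))
}

#' Fit the cancer-signal-origin random forest
#'
#' Trains a random forest (2000 trees by default) on the per-cluster
#' methylation/short/long features and records leave-one-out
#' cross-validation predictions for reporting.
#'
#' @param features matrix (samples x features) from [cluster_features()]
#' @param labels factor of cancer types
#' @param ntree number of trees (default 2000)
#' @param seed integer seed
#' @param loo record leave-one-out predictions (default TRUE)
#' @return an object of class `cso_fit`
#' @export
cso_fit <- function(features, labels, ntree = 2000, seed = 1, loo = TRUE) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  tab <- table(labels)
  if (any(tab < 2))
    stop("every class needs at least 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  forest <- randomForest::randomForest(x = features, y = labels, ntree = ntree)
  loo_pred <- NULL
  if (loo) {
    loo_pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
    for (i in seq_along(labels)) {
      set.seed(seed + i)
      f <- randomForest::randomForest(x = features[-i, , drop = FALSE],
                                      y = labels[-i], ntree = ntree)
      loo_pred[i] <- stats::predict(f, features[i, , drop = FALSE])
    }
  }
  structure(list(forest = forest, labels = labels, loo_predictions = loo_pred,
                 ntree = ntree, seed = seed),
            class = "cso_fit")
}

#' @export
predict.cso_fit <- function(object, newdata, ...) {
  stats::predict(object$forest, as.matrix(newdata), ...)
}

#' @export
print.cso_fit <- function(x, ...) {
  cat(sprintf("<cso_fit> %d classes, %d samples, %d trees\n",
              nlevels(x$labels), length(x$labels), x$ntree))
  if (!is.null(x$loo_predictions)) {
    acc <- mean(x$loo_predictions == x$labels)
    cat(sprintf("  leave-one-out accuracy: %.3f\n", acc))
  }
  invisible(x)
}

#' Default merged cancer-type groups
#'
#' Digestive-tract cancers (esophageal, gastric, colorectal) and
#' hepatopancreatic cancers (liver, pancreatic) are each evaluated as one
#' group when computing merged signal-origin accuracy.
#' @export
cso_merge_groups <- function() {
  list(digestive = c("ESCA", "STAD", "COREAD"),
       hepatopancreatic = c("LIHC", "PACA"))
}

#' Raw and merged-group accuracy from a confusion matrix
#'
#' A prediction counts as merged-correct when the true and predicted labels
#' fall in the same merged group (singleton classes are their own group).
#'
#' @param confusion square count matrix, rows = true, columns = predicted
#' @param merge_groups named list of label groups (default
#'   [cso_merge_groups()])
#' @return list with `raw_accuracy` and `merged_accuracy`
#' @export
merged_accuracy <- function(confusion, merge_groups = cso_merge_groups()) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  labs <- rownames(confusion)
  if (is.null(labs)) labs <- colnames(confusion)
  if (is.null(labs)) stop("confusion matrix must have dimnames")
  group_of <- stats::setNames(labs, labs)
  for (g in names(merge_groups))
    group_of[labs %in% merge_groups[[g]]] <- g
  total <- sum(confusion)
  raw <- sum(diag(confusion)) / total
  merged <- 0
  for (i in seq_along(labs)) for (j in seq_along(labs))
    if (group_of[labs[i]] == group_of[labs[j]]) merged <- merged + confusion[i, j]
  list(raw_accuracy = raw, merged_accuracy = merged / total)
}
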