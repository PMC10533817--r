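#' Per-window fragment coverage
#'
#' Assigns each fragment to the window containing its midpoint (fragments are
#' never split across windows, so counts are conserved) and returns the
#' per-window count. An optional size gate restricts which fragments count,
#' e.g. the aneuploidy gate keeping only fragments shorter than 151 bp or
#' longer than 220 bp.
#'
#' @param sample a `sample_fragments` data.frame
#' @param bins a `window_set` (non-overlapping)
#' @param size_gate optional predicate over fragment lengths, e.g.
#'   `function(len) len < 151 | len > 220`
#' @return numeric vector of counts aligned to `bins$index`
#' @export
bin_coverage <- function(sample, bins, size_gate = NULL) {
  frag <- sample
  if (!is.null(size_gate)) frag <- frag[size_gate(frag$length), , drop = FALSE]
  counts <- numeric(nrow(bins))
  if (nrow(frag) == 0) return(counts)
  mid <- floor((frag$start + frag$end) / 2)
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    m <- mid[frag$chrom == ch]
    if (!length(m)) next
    slot <- findInterval(m, b$start)
    ok <- slot >= 1 & slot <= nrow(b)
    ok[ok] <- m[ok] < b$end[slot[ok]]
    tab <- tabulate(slot[ok], nbins = nrow(b))
    counts[b$index] <- counts[b$index] + tab
  }
  counts
}

#' LOESS GC-content correction of a per-window profile
#'
#' Fits a locally weighted regression of the profile on per-window GC
#' fraction and removes the fitted trend while preserving the unmasked mean
#' exactly: corrected = raw - fitted + mean(fitted). Masked entries (NA in
#' `values` or in `gc`) are excluded from the fit and returned as NA.
#'
#' @param values numeric per-window profile
#' @param gc per-window GC fractions, aligned with `values`
#' @param span LOESS span (default 0.75), degree 2
#' @return corrected numeric vector of the same length
#' @export
loess_gc_correct <- function(values, gc, span = 0.75) {
  stopifnot(length(values) == length(gc))
  ok <- !is.na(values) & !is.na(gc)
  if (sum(ok) == 0) stop("all windows are masked; nothing to correct")
  if (sum(ok) < 10) stop("need at least 10 unmasked windows for the GC fit")
  fit <- suppressWarnings(stats::loess(values[ok] ~ gc[ok], span = span,
                                       degree = 2, family = "gaussian"))
  fitted <- rep(NA_real_, length(values))
  fitted[ok] <- stats::predict(fit, newdata = gc[ok])
  out <- values - fitted + mean(fitted[ok])
  out[!ok] <- NA_real_
  out
}

#' Filter unstable windows against a healthy baseline
#'
#' Windows are z-scored across baseline (healthy training) samples; a window
#' is dropped when its |z| exceeds `z_soft` in more than `soft_count` samples
#' or exceeds `z_hard` in any sample. With the published cohort the soft count
#' was 60 of 352 baselines; by default it generalises to `round(0.17 * n)`.
#' Windows with zero baseline variance are dropped as degenerate.
#'
#' @param baseline_profiles numeric matrix, samples x windows
#' @param z_soft,z_hard z-score thresholds (defaults 2 and 4)
#' @param soft_count absolute override for the soft-threshold sample count
#' @return logical vector, `TRUE` for retained windows
#' @export
baseline_bin_filter <- function(baseline_profiles, z_soft = 2, z_hard = 4,
                                soft_count = NULL) {
  stopifnot(is.matrix(baseline_profiles), nrow(baseline_profiles) >= 2)
  n <- nrow(baseline_profiles)
  if (is.null(soft_count)) soft_count <- round(0.17 * n)
  mu <- colMeans(baseline_profiles)
  sdv <- apply(baseline_profiles, 2, stats::sd)
  keep <- rep(TRUE, ncol(baseline_profiles))
  degenerate <- sdv == 0 | is.na(sdv)
  keep[degenerate] <- FALSE
  for (j in which(!degenerate)) {
    z <- abs((baseline_profiles[, j] - mu[j]) / sdv[j])
    if (sum(z > z_soft) > soft_count || any(z > z_hard)) keep[j] <- FALSE
  }
  keep
}

#' Drop windows zeroed out by GC correction
#'
#' Windows with raw coverage above `raw_min` whose corrected coverage is zero
#' or negative indicate a pathological fit and are excluded.
#'
#' @param raw,corrected aligned numeric vectors
#' @param raw_min raw-coverage threshold (default 100)
#' @return logical vector, `TRUE` for retained windows
#' @export
filter_zero_after_correction <- function(raw, corrected, raw_min = 100) {
  stopifnot(length(raw) == length(corrected))
  !(!is.na(raw) & !is.na(corrected) & raw > raw_min & corrected <= 0)
}

#' Summarise baseline samples per window
#'
#' @param baseline_profiles numeric matrix, samples x windows
#' @param bin_mask optional logical retained-window mask
#' @return list with `mean`, `sd`, `n_baseline`, `bin_mask`
#' @export
baseline_stats <- function(baseline_profiles, bin_mask = NULL) {
  if (is.null(bin_mask)) bin_mask <- rep(TRUE, ncol(baseline_profiles))
  list(mean = colMeans(baseline_profiles),
       sd = apply(baseline_profiles, 2, stats::sd),
       n_baseline = nrow(baseline_profiles),
       bin_mask = bin_mask)
}

#' Per-window z-score against the healthy baseline
#'
#' @param values per-window profile
#' @param baseline a [baseline_stats()] object
#' @return z-score vector; masked or zero-variance windows are `NA`
#' @export
zscore_vs_baseline <- function(values, baseline) {
  stopifnot(length(values) == length(baseline$mean))
  z <- (values - baseline$mean) / baseline$sd
  z[!baseline$bin_mask | baseline$sd == 0] <- NA_real_
  z
}

#' Quantile-normalize a sample against a healthy reference distribution
#'
#' Each sample value is replaced by the reference quantile at its own
#' fractional rank (average ranks for ties, linear interpolation between
#' reference order statistics). A constant sample maps to the reference
#' median.
#'
#' @param sample_values numeric vector
#' @param reference_values pooled healthy reference vector
#' @return normalized vector aligned with `sample_values`
#' @export
quantile_normalize_to_reference <- function(sample_values, reference_values) {
  stopifnot(length(sample_values) > 0, length(reference_values) > 0)
  ok <- !is.na(sample_values)
  x <- sample_values[ok]
  n <- length(x)
  p <- if (n == 1) 0.5 else (rank(x, ties.method = "average") - 1) / (n - 1)
  out <- rep(NA_real_, length(sample_values))
  out[ok] <- unname(stats::quantile(reference_values, probs = p, type = 7,
                                    na.rm = TRUE))
  out
}
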