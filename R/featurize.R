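#' Fragment-size gates for the four modalities
#'
#' Inclusive bounds follow "between"/"within" wording of the underlying size
#' criteria; strict bounds follow "shorter/longer than":
#' short fragments 100-166 bp and long fragments 169-240 bp (inclusive) for
#' the size index; the aneuploidy gate keeps fragments < 151 bp or > 220 bp
#' (strict); end-motif profiling keeps fragments < 171 bp (strict); the
#' methylated fragment ratio keeps 80-250 bp (inclusive).
#'
#' @return list of gate bounds used throughout the package
#' @export
size_gates <- function() {
  list(short_range = c(100L, 166L), long_range = c(169L, 240L),
       caff_short_max = 150L, caff_long_min = 221L,
       fem_max = 170L, mfr_range = c(80L, 250L))
}

#' Differentially represented fragment sizes
#'
#' For every fragment size, a one-sided Wilcoxon rank-sum test compares the
#' per-sample frequency of that size between cancer and healthy training
#' samples; both directions are tested and the smaller p (with its direction)
#' is reported. Sizes significant at `alpha` are returned. With the published
#' training cohort this selects essentially all of 50-300 bp except 167-168 bp
#' and 241-259 bp, motivating the short/long gate bounds.
#'
#' @param cancer_size_freqs,healthy_size_freqs matrices (samples x sizes) of
#'   per-sample size frequencies, columns named by size in bp
#' @param alpha significance level (default 0.01)
#' @return list with `sizes` (selected sizes) and `table`
#'   (size, direction, p-value)
#' @export
size_frequency_test <- function(cancer_size_freqs, healthy_size_freqs,
                                alpha = 0.01) {
  stopifnot(ncol(cancer_size_freqs) == ncol(healthy_size_freqs),
            nrow(cancer_size_freqs) >= 3, nrow(healthy_size_freqs) >= 3)
  sizes <- as.integer(colnames(cancer_size_freqs))
  if (any(is.na(sizes))) stop("columns must be named by fragment size")
  res <- lapply(seq_along(sizes), function(j) {
    x <- cancer_size_freqs[, j]; y <- healthy_size_freqs[, j]
    if (stats::sd(c(x, y)) == 0)
      return(data.frame(size = sizes[j], direction = "none", p = 1))
    pg <- suppressWarnings(stats::wilcox.test(x, y, alternative = "greater")$p.value)
    pl <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less")$p.value)
    if (pg <= pl) data.frame(size = sizes[j], direction = "greater", p = pg)
    else data.frame(size = sizes[j], direction = "less", p = pl)
  })
  tab <- do.call(rbind, res)
  list(sizes = tab$size[tab$p < alpha], table = tab)
}

# Fragments eligible for methylation featurization: >= 3 CpGs observed,
# length within the cfDNA size band, and non-CpG conversion above 95%
# (fragments with no non-CpG cytosine observations pass: nothing to flag).
mfr_qualifying <- function(sample, gates = size_gates()) {
  conv_ok <- sample$noncpg_c_total == 0 |
    (sample$noncpg_c_converted / pmax(sample$noncpg_c_total, 1)) > 0.95
  sample$cpg_total >= 3 &
    sample$length >= gates$mfr_range[1] & sample$length <= gates$mfr_range[2] &
    conv_ok
}

#' Methylated fragment ratio per window
#'
#' Keeps fragments covering at least 3 CpGs, 80-250 bp long, with non-CpG
#' conversion above 95%, then computes per window the fraction of qualifying
#' fragments whose observed CpGs are all methylated. Windows with no
#' qualifying fragment are `NA`.
#'
#' @param sample a `sample_fragments` data.frame
#' @param windows a `window_set` (typically 1-Mb)
#' @param gates size gates (see [size_gates()])
#' @return numeric vector in \[0,1\] aligned to `windows$index`
#' @export
compute_mfr <- function(sample, windows, gates = size_gates()) {
  q <- sample[mfr_qualifying(sample, gates), , drop = FALSE]
  total <- bin_coverage(q, windows)
  fully <- q[q$cpg_methylated == q$cpg_total, , drop = FALSE]
  meth <- bin_coverage(fully, windows)
  out <- ifelse(total > 0, meth / total, NA_real_)
  out
}

#' Fragment size index over merged windows
#'
#' Per 100-kb bin, the ratio of short (100-166 bp) to long (169-240 bp)
#' fragment counts with a +1 pseudocount on both; ratios are LOESS-corrected
#' against GC, averaged over the member bins of each merged (5-Mb) window,
#' and the resulting vector is z-scored across the genome (mean 0, sd 1).
#'
#' @param sample a `sample_fragments` data.frame
#' @param bins the 100-kb `window_set`, with `gc` filled in
#' @param merge_map bin-to-window mapping from [merge_bins_to_windows()]
#' @param n_windows number of merged windows
#' @param gates size gates
#' @param span LOESS span for the GC correction
#' @return z-scored FSI vector over merged windows
#' @export
compute_fsi <- function(sample, bins, merge_map, n_windows,
                        gates = size_gates(), span = 0.75) {
  if (n_windows < 2) stop("need at least 2 merged windows")
  short <- bin_coverage(sample, bins, function(l)
    l >= gates$short_range[1] & l <= gates$short_range[2])
  long <- bin_coverage(sample, bins, function(l)
    l >= gates$long_range[1] & l <= gates$long_range[2])
  ratio <- (short + 1) / (long + 1)
  corrected <- loess_gc_correct(ratio, bins$gc, span = span)
  win <- vapply(seq_len(n_windows), function(w) {
    v <- corrected[!is.na(merge_map) & merge_map == w]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  s <- stats::sd(win, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(0, n_windows))  # flat profile: no signal
  (win - mean(win, na.rm = TRUE)) / s
}

#' Reference FSI profile from healthy controls
#'
#' @param healthy_fsi matrix (samples x windows) of healthy FSI vectors
#' @return per-window median vector
#' @export
reference_fsi_profile <- function(healthy_fsi) {
  stopifnot(nrow(healthy_fsi) >= 1)
  apply(healthy_fsi, 2, stats::median, na.rm = TRUE)
}

#' Similarity of an FSI profile to the healthy reference
#'
#' @param sample_fsi,reference aligned FSI vectors
#' @return Pearson correlation over jointly non-missing windows
#' @export
fsi_similarity <- function(sample_fsi, reference) {
  ok <- !is.na(sample_fsi) & !is.na(reference)
  stats::cor(sample_fsi[ok], reference[ok])
}

#' Plasma aneuploidy score
#'
#' The PA score sums |z| over the `k` chromosome arms with the most extreme
#' copy-number z-scores (default 5); ties are broken by arm label so the
#' score is deterministic.
#'
#' @param arm_z named numeric vector of per-arm z-scores
#' @param k number of arms to sum (default 5)
#' @return non-negative scalar
#' @export
pa_score <- function(arm_z, k = 5) {
  arm_z <- arm_z[!is.na(arm_z)]
  if (length(arm_z) < k)
    stop(sprintf("need at least %d arms with z-scores, have %d", k, length(arm_z)))
  ord <- order(-abs(arm_z), names(arm_z))
  sum(abs(arm_z[ord[seq_len(k)]]))
}

#' Arm-level aneuploidy of size-selected fragments
#'
#' Follows copy-number profiling on fragments passing the aneuploidy size
#' gate (< 151 bp or > 220 bp): size-gated 100-kb coverage, LOESS GC
#' correction, baseline bin mask, arm totals (sum of retained member-bin
#' coverage, normalised to genome-wide proportions so the score is
#' depth-invariant), per-arm z against the healthy baseline arm
#' distribution, and finally the PA score over the five most altered arms.
#'
#' @param sample a `sample_fragments` data.frame
#' @param bins 100-kb `window_set` with `gc`
#' @param arms arm table from [build_arms()]
#' @param baseline baseline from [build_caff_baseline()]
#' @param gates size gates
#' @param k arms summed into the PA score
#' @return list with `pa_score`, `caff_log10` (= log10(PA + 1)), and `arm_z`
#' @export
compute_caff <- function(sample, bins, arms, baseline, gates = size_gates(),
                         k = 5) {
  props <- caff_arm_proportions(sample, bins, arms, baseline$bin_mask, gates)
  z <- (props - baseline$arm_mean) / baseline$arm_sd
  z[baseline$arm_sd == 0] <- NA_real_
  pa <- pa_score(z, k = k)
  list(pa_score = pa, caff_log10 = log10(pa + 1), arm_z = z)
}

# Shared path for samples and baselines: gated, GC-corrected, masked bin
# coverage summed per arm and normalised to proportions.
caff_arm_proportions <- function(sample, bins, arms, bin_mask,
                                 gates = size_gates(), span = 0.75) {
  gate <- function(l) l < (gates$caff_short_max + 1) | l > (gates$caff_long_min - 1)
  cov <- bin_coverage(sample, bins, gate)
  if (sum(cov) == 0) stop("no fragments pass the aneuploidy size gate")
  corrected <- loess_gc_correct(cov, bins$gc, span = span)
  corrected[!bin_mask] <- NA_real_
  arm_of <- assign_bins_to_arms(bins, arms)
  totals <- vapply(arms$arm, function(a) {
    v <- corrected[!is.na(arm_of) & arm_of == a]
    if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(totals))
    warning("arms with no retained bins skipped: ",
            paste(arms$arm[is.na(totals)], collapse = ", "))
  totals / sum(totals, na.rm = TRUE)
}

# Label each bin with the arm containing its midpoint (NA outside all arms,
# e.g. centromeric bins).
assign_bins_to_arms <- function(bins, arms) {
  mid <- (bins$start + bins$end) / 2
  out <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(arms))) {
    hit <- bins$chrom == arms$chrom[i] & mid >= arms$start[i] & mid < arms$end[i]
    out[hit] <- arms$arm[i]
  }
  out
}

#' Build the aneuploidy baseline from healthy samples
#'
#' Computes size-gated, GC-corrected 100-kb coverage for each healthy sample,
#' derives the unstable-bin mask (baseline z filtering plus the
#' zero-after-correction rule), and records the mean and sd of the arm-level
#' coverage proportions.
#'
#' @param healthy_samples list of `sample_fragments`
#' @param bins 100-kb `window_set` with `gc`
#' @param arms arm table
#' @param gates size gates
#' @param span LOESS span
#' @inheritParams baseline_bin_filter
#' @return list with `arm_mean`, `arm_sd`, `bin_mask`, `n_baseline`
#' @export
build_caff_baseline <- function(healthy_samples, bins, arms,
                                gates = size_gates(), span = 0.75,
                                z_soft = 2, z_hard = 4, soft_count = NULL) {
  gate <- function(l) l < (gates$caff_short_max + 1) | l > (gates$caff_long_min - 1)
  raw <- t(vapply(healthy_samples, function(s) bin_coverage(s, bins, gate),
                  numeric(nrow(bins))))
  corrected <- t(apply(raw, 1, function(v) loess_gc_correct(v, bins$gc, span = span)))
  mask <- baseline_bin_filter(corrected, z_soft = z_soft, z_hard = z_hard,
                              soft_count = soft_count)
  zero_mask <- apply(raw > 100 & corrected <= 0, 2, any)
  mask <- mask & !zero_mask
  props <- t(vapply(seq_along(healthy_samples), function(i)
    caff_arm_proportions(healthy_samples[[i]], bins, arms, mask, gates, span),
    numeric(nrow(arms))))
  list(arm_mean = colMeans(props), arm_sd = apply(props, 2, stats::sd),
       bin_mask = mask, n_baseline = length(healthy_samples))
}

#' The 256 fragment 5' end motifs
#' @return character vector of all 4-mers over ACGT, sorted
#' @export
fem_vocabulary <- function() {
  b <- c("A", "C", "G", "T")
  sort(apply(expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1], 1, paste,
             collapse = ""))
}

#' Fragment end-motif frequency vector
#'
#' Frequencies of the 256 4-mers at the Crick-strand 5' end among fragments
#' shorter than 171 bp that carry a motif. Returns the all-zero vector when
#' no fragment qualifies; otherwise the vector sums to 1.
#'
#' @param sample a `sample_fragments` data.frame
#' @param gates size gates
#' @return named numeric 256-vector (motifs AAAA..TTTT)
#' @export
compute_fem <- function(sample, gates = size_gates()) {
  vocab <- fem_vocabulary()
  q <- sample[sample$length < (gates$fem_max + 1) & !is.na(sample$motif_crick), ,
              drop = FALSE]
  q <- q[q$motif_crick %in% vocab, , drop = FALSE]
  counts <- table(factor(q$motif_crick, levels = vocab))
  out <- as.numeric(counts)
  names(out) <- vocab
  if (sum(out) > 0) out <- out / sum(out)
  out
}
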