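#' Synthetic cfDNA cohort configuration
#'
#' Describes the generative model for fragment-level synthetic cohorts on a
#' toy genome. Healthy plasma contributes fragments with a 167-bp modal
#' (discretised lognormal) size distribution, high CpG methylation, GC-biased
#' coverage, and a fixed 4-mer end-motif spectrum. Cancer samples mix in
#' tumor-derived fragments at the sample's tumor fraction: arm-weighted
#' positions under the configured copy-number spec, a shorter size mode,
#' globally hypomethylated CpGs, a distorted end-motif spectrum, and reduced
#' methylation with elevated accessibility in the affected open-chromatin
#' peak clusters.
#'
#' Tumor fractions are drawn per clinical stage from the bands
#' I: 0.1-1%, II: 0.5-2%, III: 2-8%, IV: 5-20%. The `signal` presets switch
#' the whole configuration between those faint stage-graded conditions
#' (`"staged"`), a strong-signal regime used for end-to-end checks
#' (`"strong"`: tumor fraction 10-30% at every stage), and a null regime
#' (`"null"`: tumor fraction 0, i.e. "cancer" samples are generatively
#' healthy).
#'
#' @param seed integer seed; the whole cohort is reproducible from it
#' @param n_healthy number of healthy samples
#' @param n_cancer number of cancer samples, split evenly over
#'   `cancer_types`
#' @param cancer_types character vector of pseudo-type labels
#' @param fragments_per_sample fragments simulated per sample
#' @param signal one of `"staged"`, `"strong"`, `"null"`
#' @param chrom_sizes named lengths of the toy chromosomes
#' @param centromeres data.frame (`chrom`, `start`, `end`)
#' @param cpg_spacing uniform CpG grid spacing in bp
#' @param cna_spec named copy ratios per arm label (e.g. `c(chr1q = 1.5)`)
#' @param hypomethylation_factor multiplier on the per-CpG methylation
#'   probability of tumor fragments
#' @param healthy_meth_prob per-CpG methylation probability in healthy
#'   fragments
#' @param size_mode healthy modal fragment length (bp)
#' @param size_shift tumor modal length reduction (bp)
#' @param size_sigma lognormal shape of the size distribution
#' @param motif_distortion probability that a tumor fragment draws its end
#'   motif from the distorted spectrum
#' @param conversion_error non-CpG cytosine conversion failure rate
#' @param n_clusters,peaks_per_cluster,peak_width open-chromatin peak layout
#' @param frac_in_peaks fraction of fragments placed inside peaks (peaks
#'   cover a far larger share of a real genome than of the toy genome; this
#'   keeps per-peak depth comparable)
#' @param cluster_effects named list: for each cancer type, the cluster ids
#'   with tumor-specific hypomethylation and elevated accessibility
#' @param cluster_meth_factor extra methylation multiplier for tumor
#'   fragments in affected-cluster peaks
#' @param cluster_access_boost placement weight multiplier for
#'   affected-cluster peaks in tumor fragments
#' @param gc_coverage_coef,gc_short_coef GC coverage-bias strengths (log
#'   scale per GC unit); the short-fragment term gives the size-index ratio
#'   a GC trend for the LOESS correction to remove
#' @return a `sim_config` list
#' @export
simulation_config <- function(seed = 1, n_healthy = 60, n_cancer = 60,
                              cancer_types = "CANCER",
                              fragments_per_sample = 20000,
                              signal = c("staged", "strong", "null"),
                              chrom_sizes = stats::setNames(rep(30e6, 4),
                                                            paste0("chr", 1:4)),
                              centromeres = NULL,
                              cpg_spacing = 80,
                              cna_spec = c(chr1q = 1.5, chr3p = 0.5),
                              hypomethylation_factor = 0.75,
                              healthy_meth_prob = 0.85,
                              size_mode = 167, size_shift = 20,
                              size_sigma = 0.18,
                              motif_distortion = 0.5,
                              conversion_error = 0.006,
                              n_clusters = 18, peaks_per_cluster = 60,
                              peak_width = 500, frac_in_peaks = 0.2,
                              cluster_effects = NULL,
                              cluster_meth_factor = 0.4,
                              cluster_access_boost = 2,
                              gc_coverage_coef = 2.5,
                              gc_short_coef = 1.5) {
  signal <- match.arg(signal)
  if (is.null(centromeres))
    centromeres <- data.frame(chrom = names(chrom_sizes),
                              start = unname(chrom_sizes) / 2 - 0.5e6,
                              end = unname(chrom_sizes) / 2 + 0.5e6,
                              stringsAsFactors = FALSE)
  tf_bands <- switch(signal,
    staged = list(I = c(0.001, 0.01), II = c(0.005, 0.02),
                  III = c(0.02, 0.08), IV = c(0.05, 0.20)),
    strong = list(I = c(0.10, 0.30), II = c(0.10, 0.30),
                  III = c(0.10, 0.30), IV = c(0.10, 0.30)),
    null = list(I = c(0, 0), II = c(0, 0), III = c(0, 0), IV = c(0, 0)))
  if (is.null(cluster_effects) && length(cancer_types))
    cluster_effects <- stats::setNames(
      lapply(seq_along(cancer_types), function(i)
        ((i - 1) %% n_clusters) + 1L), cancer_types)
  cfg <- list(seed = seed, n_healthy = n_healthy, n_cancer = n_cancer,
              cancer_types = cancer_types,
              fragments_per_sample = fragments_per_sample, signal = signal,
              chrom_sizes = chrom_sizes, centromeres = centromeres,
              cpg_spacing = cpg_spacing, cna_spec = cna_spec,
              hypomethylation_factor = hypomethylation_factor,
              healthy_meth_prob = healthy_meth_prob,
              size_mode = size_mode, size_shift = size_shift,
              size_sigma = size_sigma, motif_distortion = motif_distortion,
              conversion_error = conversion_error,
              n_clusters = n_clusters, peaks_per_cluster = peaks_per_cluster,
              peak_width = peak_width, frac_in_peaks = frac_in_peaks,
              tumor_fraction_by_stage = tf_bands,
              cluster_effects = cluster_effects,
              cluster_meth_factor = cluster_meth_factor,
              cluster_access_boost = cluster_access_boost,
              gc_coverage_coef = gc_coverage_coef,
              gc_short_coef = gc_short_coef)
  class(cfg) <- "sim_config"
  cfg
}

# Position-weight end-motif spectra: product distributions over the 256
# 4-mers. The healthy spectrum is C-rich at the 5' end, as plasma cfDNA ends
# are; the distorted (tumor) spectrum flattens that preference.
motif_spectrum <- function(kind = c("healthy", "distorted")) {
  kind <- match.arg(kind)
  w <- if (kind == "healthy")
    list(c(A = .15, C = .40, G = .25, T = .20),
         c(A = .20, C = .30, G = .25, T = .25),
         c(A = .25, C = .25, G = .25, T = .25),
         c(A = .25, C = .25, G = .25, T = .25))
  else
    list(c(A = .30, C = .20, G = .20, T = .30),
         c(A = .25, C = .25, G = .25, T = .25),
         c(A = .20, C = .30, G = .30, T = .20),
         c(A = .25, C = .25, G = .25, T = .25))
  vocab <- fem_vocabulary()
  p <- vapply(vocab, function(m) {
    ch <- strsplit(m, "")[[1]]
    prod(vapply(1:4, function(i) w[[i]][[ch[i]]], numeric(1)))
  }, numeric(1))
  p / sum(p)
}

# Fixed genome annotation derived from the config (seeded independently of
# per-sample draws): 100-kb bins with a smooth GC track, chromosome arms,
# and the clustered open-chromatin peaks.
sim_genome <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  bins <- tile_autosomes(config$chrom_sizes, 1e5)
  i <- seq_len(nrow(bins))
  bins$gc <- pmin(0.65, pmax(0.30,
    0.45 + 0.08 * sin(2 * pi * i / 40) + stats::rnorm(nrow(bins), 0, 0.01)))
  arms <- build_arms(config$centromeres, config$chrom_sizes)
  bins$arm <- assign_bins_to_arms(bins, arms)
  # peaks: uniform over non-centromeric positions, clusters round-robin
  n_peaks <- config$n_clusters * config$peaks_per_cluster
  pk_chrom <- sample(names(config$chrom_sizes), n_peaks, replace = TRUE)
  pk_start <- floor(stats::runif(n_peaks) *
                      (config$chrom_sizes[pk_chrom] - config$peak_width))
  peaks <- data.frame(chrom = pk_chrom, start = pk_start,
                      end = pk_start + config$peak_width,
                      cluster = sprintf("c%02d",
                                        rep_len(seq_len(config$n_clusters), n_peaks)),
                      stringsAsFactors = FALSE)
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  list(bins = bins, arms = arms, peaks = peaks,
       chrom_sizes = config$chrom_sizes, centromeres = config$centromeres)
}

# CpG count on the uniform grid within [start, end): sites at multiples of
# `spacing`, a site counted when both its bases lie inside the fragment.
grid_cpg_count <- function(start, end, spacing) {
  pmax(0, floor((end - 2) / spacing) - ceiling(start / spacing) + 1)
}

# Draw one sample's fragments. `tumor_fraction` = 0 gives the healthy model.
sim_sample_fragments <- function(config, genome, tumor_fraction,
                                 affected_clusters, sample_seed, sample_id) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(sample_seed)
  n <- config$fragments_per_sample
  bins <- genome$bins
  n_bins <- nrow(bins)
  is_tumor <- stats::runif(n) < tumor_fraction

  # fragment lengths: discretised lognormal with the given mode
  draw_len <- function(k, mode) {
    mu <- log(mode) + config$size_sigma^2
    len <- round(exp(stats::rnorm(k, mu, config$size_sigma)))
    pmin(pmax(len, 60), 400)
  }
  len <- numeric(n)
  len[!is_tumor] <- draw_len(sum(!is_tumor), config$size_mode)
  len[is_tumor] <- draw_len(sum(is_tumor), config$size_mode - config$size_shift)

  # placement: inside a peak with prob frac_in_peaks, else genomic with
  # GC-biased (and, for tumor fragments, copy-ratio-weighted) bin intensity
  in_peak <- stats::runif(n) < config$frac_in_peaks
  gcw <- exp(config$gc_coverage_coef * (bins$gc - 0.45))
  shortw <- exp(config$gc_short_coef * (bins$gc - 0.45))
  cna_w <- rep(1, n_bins)
  for (a in names(config$cna_spec))
    cna_w[!is.na(bins$arm) & bins$arm == a] <- config$cna_spec[[a]]

  short_frag <- len <= 166
  bin_idx <- integer(n)
  for (grp in list(
    list(sel = !in_peak & !is_tumor & !short_frag, w = gcw),
    list(sel = !in_peak & !is_tumor & short_frag, w = gcw * shortw),
    list(sel = !in_peak & is_tumor & !short_frag, w = gcw * cna_w),
    list(sel = !in_peak & is_tumor & short_frag, w = gcw * shortw * cna_w))) {
    k <- sum(grp$sel)
    if (k) bin_idx[grp$sel] <- sample.int(n_bins, k, replace = TRUE, prob = grp$w)
  }
  mid <- numeric(n)
  gsel <- !in_peak
  mid[gsel] <- bins$start[bin_idx[gsel]] +
    floor(stats::runif(sum(gsel)) * (bins$end[bin_idx[gsel]] - bins$start[bin_idx[gsel]]))
  chrom <- character(n)
  chrom[gsel] <- bins$chrom[bin_idx[gsel]]

  # peak placement; tumor fragments prefer affected clusters
  pks <- genome$peaks
  if (any(in_peak)) {
    pw_h <- rep(1, nrow(pks))
    pw_t <- pw_h
    if (length(affected_clusters)) {
      aff <- pks$cluster %in% sprintf("c%02d", affected_clusters)
      pw_t[aff] <- config$cluster_access_boost
    }
    hsel <- in_peak & !is_tumor
    tsel <- in_peak & is_tumor
    pick <- integer(n)
    if (any(hsel)) pick[hsel] <- sample.int(nrow(pks), sum(hsel), TRUE, prob = pw_h)
    if (any(tsel)) pick[tsel] <- sample.int(nrow(pks), sum(tsel), TRUE, prob = pw_t)
    psel <- in_peak
    mid[psel] <- pks$start[pick[psel]] +
      floor(stats::runif(sum(psel)) * (pks$end[pick[psel]] - pks$start[pick[psel]]))
    chrom[psel] <- pks$chrom[pick[psel]]
    in_affected <- psel & is_tumor & length(affected_clusters) > 0 &
      pks$cluster[pmax(pick, 1)] %in% sprintf("c%02d", affected_clusters)
  } else in_affected <- rep(FALSE, n)

  start <- pmax(0, mid - floor(len / 2))
  maxlen <- config$chrom_sizes[chrom]
  end <- pmin(start + len, maxlen)
  start <- pmax(0, end - len)
  len <- end - start

  cpg_total <- grid_cpg_count(start, end, config$cpg_spacing)
  p_meth <- ifelse(is_tumor, config$healthy_meth_prob * config$hypomethylation_factor,
                   config$healthy_meth_prob)
  p_meth[in_affected] <- p_meth[in_affected] * config$cluster_meth_factor
  cpg_methylated <- stats::rbinom(n, cpg_total, p_meth)

  noncpg_total <- stats::rbinom(n, pmax(len - 2 * cpg_total, 0), 0.2)
  noncpg_conv <- stats::rbinom(n, noncpg_total, 1 - config$conversion_error)

  vocab <- fem_vocabulary()
  p_healthy <- motif_spectrum("healthy")
  p_dist <- motif_spectrum("distorted")
  use_dist <- is_tumor & stats::runif(n) < config$motif_distortion
  motif <- character(n)
  if (any(!use_dist))
    motif[!use_dist] <- sample(vocab, sum(!use_dist), TRUE, prob = p_healthy)
  if (any(use_dist))
    motif[use_dist] <- sample(vocab, sum(use_dist), TRUE, prob = p_dist)

  sample_fragments(data.frame(
    chrom = chrom, start = start, end = end, length = len, mapq = 60,
    cpg_total = cpg_total, cpg_methylated = cpg_methylated,
    noncpg_c_total = noncpg_total, noncpg_c_converted = noncpg_conv,
    motif_crick = motif, stringsAsFactors = FALSE), sample_id)
}

#' Simulate a fragment-level cohort
#'
#' Generates healthy and cancer samples under [simulation_config()], fully
#' reproducible from the config seed (per-sample seeds are derived
#' deterministically, so any subset of samples is reproducible in
#' isolation).
#'
#' @param config a `sim_config`
#' @param write_dir optional directory; when given, fragment TSVs, the truth
#'   table and a peak BED are written there
#' @return list with `samples` (named list of `sample_fragments`), `truth`
#'   (sample metadata with true tumor fractions), and `genome` (bins with GC
#'   track, arms, peaks, chromosome sizes)
#' @export
simulate_cohort <- function(config, write_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  stages <- names(config$tumor_fraction_by_stage)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n_can <- config$n_cancer
  types <- rep_len(config$cancer_types, n_can)
  truth <- data.frame(
    sample_id = c(sprintf("H%03d", seq_len(config$n_healthy)),
                  sprintf("C%03d", seq_len(n_can))),
    label = c(rep("healthy", config$n_healthy), types),
    stage = c(rep(NA_character_, config$n_healthy),
              sample(stages, n_can, replace = TRUE)),
    stringsAsFactors = FALSE)
  tf <- numeric(nrow(truth))
  for (i in which(truth$label != "healthy")) {
    band <- config$tumor_fraction_by_stage[[truth$stage[i]]]
    tf[i] <- stats::runif(1, band[1], band[2])
  }
  truth$tumor_fraction <- tf
  truth$affected_clusters <- vapply(truth$label, function(l) {
    if (l == "healthy" || is.null(config$cluster_effects[[l]])) ""
    else paste(config$cluster_effects[[l]], collapse = ",")
  }, character(1))
  sample_seeds <- config$seed + 7919L * seq_len(nrow(truth))
  samples <- lapply(seq_len(nrow(truth)), function(i) {
    aff <- if (nzchar(truth$affected_clusters[i]))
      as.integer(strsplit(truth$affected_clusters[i], ",")[[1]]) else integer()
    sim_sample_fragments(config, genome, truth$tumor_fraction[i], aff,
                         sample_seeds[i], truth$sample_id[i])
  })
  names(samples) <- truth$sample_id
  out <- list(samples = samples, truth = truth, genome = genome)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(samples))
      write_fragment_table(samples[[id]], file.path(write_dir, paste0(id, ".frags.tsv")))
    utils::write.table(truth, file.path(write_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pk <- genome$peaks
    utils::write.table(
      data.frame(pk$chrom, format(pk$start, scientific = FALSE, trim = TRUE),
                 format(pk$end, scientific = FALSE, trim = TRUE), pk$cluster),
      file.path(write_dir, "peaks.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  out
}

#' Simulate a mean-VAF table with detection outcomes
#'
#' Mean variant allele fraction is proportional to tumor fraction with
#' lognormal noise; detection is drawn from a logistic in log10(VAF) with
#' the given slope and 50% midpoint. Supports limit-of-detection recovery
#' checks.
#'
#' @param tumor_fractions positive per-sample tumor fractions
#' @param midpoint mean VAF at 50% detection probability
#' @param slope logistic slope per log10 unit
#' @param vaf_scale VAF per unit tumor fraction
#' @param noise_sd lognormal noise sd (log scale)
#' @param seed integer seed
#' @return data.frame with `mean_vaf` and `detected`
#' @export
simulate_vaf_table <- function(tumor_fractions, midpoint = 1.5e-3, slope = 6,
                               vaf_scale = 0.5, noise_sd = 0.3, seed = 1) {
  stopifnot(all(tumor_fractions > 0))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(tumor_fractions)
  vaf <- vaf_scale * tumor_fractions * exp(stats::rnorm(n, 0, noise_sd))
  p <- stats::plogis(slope * (log10(vaf) - log10(midpoint)))
  data.frame(mean_vaf = vaf, detected = as.integer(stats::runif(n) < p))
}

#' Toy reference sequence for alignment-reader tests
#'
#' @param chrom_sizes named lengths (keep small; sequences are materialised)
#' @param seed integer seed
#' @return a [Biostrings::DNAStringSet]
#' @export
simulate_toy_reference <- function(chrom_sizes, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  seqs <- vapply(chrom_sizes, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(chrom_sizes)))
}

#' Write a toy paired-end SAM file with methylation call strings
#'
#' Emits one proper pair per row of `pairs`: read 1 on the Watson strand at
#' the fragment start, read 2 (reverse) ending at the fragment end, with the
#' supplied XM-dialect call strings. Sequences are taken from the reference.
#'
#' @param pairs data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open fragment span), `mapq`, `read_len`, `xm1`, `xm2` (call
#'   strings of length `read_len`)
#' @param reference a [Biostrings::DNAStringSet]
#' @param path output SAM path
#' @export
write_toy_sam <- function(pairs, reference, path) {
  nm <- sub("\\s.*", "", names(reference))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", nm, Biostrings::width(reference)))
  recs <- character(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    stopifnot(nchar(p$xm1) == p$read_len, nchar(p$xm2) == p$read_len)
    pos1 <- p$start + 1
    pos2 <- p$end - p$read_len + 1
    tlen <- p$end - p$start
    seqref <- reference[[match(p$chrom, nm)]]
    s1 <- as.character(Biostrings::subseq(seqref, pos1, pos1 + p$read_len - 1))
    s2 <- as.character(Biostrings::subseq(seqref, pos2, pos2 + p$read_len - 1))
    q <- strrep("I", p$read_len)
    cig <- sprintf("%dM", p$read_len)
    qn <- sprintf("frag%05d", i)
    recs <- c(recs,
      paste(qn, 99, p$chrom, pos1, p$mapq, cig, "=", pos2, tlen, s1, q,
            paste0("XM:Z:", p$xm1), sep = "\t"),
      paste(qn, 147, p$chrom, pos2, p$mapq, cig, "=", pos1, -tlen, s2, q,
            paste0("XM:Z:", p$xm2), sep = "\t"))
  }
  ord <- order(rep(pairs$chrom, each = 2),
               as.integer(vapply(strsplit(recs, "\t"), `[`, "", 4)))
  writeLines(c(hdr, recs[ord]), path)
  invisible(path)
}
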