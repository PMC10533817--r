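#' Build the window scaffolding for a simulated (or real) genome
#'
#' From 100-kb bins with a GC track: 1-Mb windows for the methylated
#' fragment ratio (GC aggregated from member bins), merged 5-Mb windows for
#' the size index, and the chromosome arms.
#'
#' @param genome list with `bins` (100-kb `window_set` with `gc`), `arms`,
#'   `chrom_sizes` (as returned in `simulate_cohort()$genome`)
#' @return list with `bins`, `windows_1mb`, `merge` (5-Mb windows + map),
#'   `arms`
#' @export
build_scaffold <- function(genome) {
  bins <- genome$bins
  w1 <- tile_autosomes(genome$chrom_sizes, 1e6)
  mid <- (bins$start + bins$end) / 2
  w1$gc <- vapply(seq_len(nrow(w1)), function(i) {
    m <- bins$chrom == w1$chrom[i] & mid >= w1$start[i] & mid < w1$end[i]
    mean(bins$gc[m], na.rm = TRUE)
  }, numeric(1))
  merge <- merge_bins_to_windows(bins, 5e6)
  list(bins = bins, windows_1mb = w1, merge = merge, arms = genome$arms)
}

#' Featurize a set of samples into the four modalities
#'
#' @param samples named list of `sample_fragments`
#' @param scaffold from [build_scaffold()]
#' @param caff_baseline from [build_caff_baseline()]
#' @param gates size gates
#' @return list of matrices `mfr`, `fsi`, `fem` (samples x features) and
#'   vectors `caff_log10`, `pa_score`
#' @export
featurize_cohort <- function(samples, scaffold, caff_baseline,
                             gates = size_gates()) {
  n5 <- nrow(scaffold$merge$windows)
  mfr <- t(vapply(samples, compute_mfr, numeric(nrow(scaffold$windows_1mb)),
                  windows = scaffold$windows_1mb, gates = gates))
  fsi <- t(vapply(samples, compute_fsi, numeric(n5), bins = scaffold$bins,
                  merge_map = scaffold$merge$map, n_windows = n5, gates = gates))
  fem <- t(vapply(samples, compute_fem, numeric(256), gates = gates))
  caff <- lapply(samples, compute_caff, bins = scaffold$bins,
                 arms = scaffold$arms, baseline = caff_baseline, gates = gates)
  list(mfr = mfr, fsi = fsi, fem = fem,
       caff_log10 = vapply(caff, `[[`, numeric(1), "caff_log10"),
       pa_score = vapply(caff, `[[`, numeric(1), "pa_score"),
       arm_z = t(vapply(caff, `[[`, numeric(nrow(scaffold$arms)), "arm_z")))
}

#' Run the full detection pipeline on a simulated cohort
#'
#' simulate -> scaffold -> baseline -> featurize -> fit -> score -> evaluate.
#' The cohort is split (stratified by label) into training and test at
#' `train_fraction`; healthy training samples form the aneuploidy baseline.
#' A sample can never appear in both baseline/training and test.
#'
#' @param config a [simulation_config()]
#' @param train_fraction training fraction (default 0.7)
#' @param specificity operating specificity for sensitivity reporting
#' @param ... passed to [themis_fit()]
#' @return list with the fitted model, per-sample scores and roles, feature
#'   matrices, and summary metrics (train/test AUC, sensitivity at the
#'   target specificity), plus a reproducibility manifest
#' @export
run_pipeline <- function(config, train_fraction = 0.7, specificity = 0.99,
                         ...) {
  sim <- simulate_cohort(config)
  scaffold <- build_scaffold(sim$genome)
  y <- as.integer(sim$truth$label != "healthy")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  tr <- stratified_sample(y, train_fraction)
  te <- setdiff(seq_along(y), tr)
  if (length(intersect(tr, te)))
    stop("leakage guard: a sample appears in both training and test")
  baseline_ids <- which(y == 0 & seq_along(y) %in% tr)
  caff_base <- build_caff_baseline(sim$samples[baseline_ids], scaffold$bins,
                                   scaffold$arms)
  feats <- featurize_cohort(sim$samples, scaffold, caff_base)
  fit <- themis_fit(feats$mfr[tr, ], feats$fsi[tr, ], feats$fem[tr, ],
                    feats$caff_log10[tr], y[tr], seed = config$seed, ...)
  test_scores <- predict(fit, list(mfr = feats$mfr[te, , drop = FALSE],
                                   fsi = feats$fsi[te, , drop = FALSE],
                                   fem = feats$fem[te, , drop = FALSE],
                                   caff_log10 = feats$caff_log10[te]))
  train_auc <- auc(fit$train_scores, y[tr])
  test_auc <- auc(test_scores, y[te])
  sens <- sensitivity_at_specificity(test_scores, y[te], specificity)
  manifest <- list(
    package_version = as.character(utils::packageVersion("themis")),
    seed = config$seed, n_samples = length(y),
    n_train = length(tr), n_test = length(te),
    config_hash = config_hash(config))
  list(fit = fit, truth = sim$truth, features = feats,
       train_idx = tr, test_idx = te,
       test_scores = test_scores, labels = y,
       metrics = list(train_auc = train_auc, test_auc = test_auc,
                      sensitivity = sens),
       scaffold = scaffold, caff_baseline = caff_base,
       samples = sim$samples, genome = sim$genome,
       manifest = manifest)
}

# md5 of the serialized config, for run manifests
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}
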