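test_that("differential fragment-size selection finds planted shifts only", {
  set.seed(12)
  sizes <- 100:260
  base <- matrix(rep(1 / length(sizes), 20 * length(sizes)), 20,
                 dimnames = list(NULL, sizes))
  noise <- function() matrix(abs(rnorm(20 * length(sizes), 0, 1e-4)),
                             20, length(sizes))
  healthy <- base + noise()
  cancer <- base + noise()
  expect_lt(length(size_frequency_test(cancer, healthy, alpha = 0.01)$sizes),
            0.05 * length(sizes))

  planted <- cancer
  planted[, as.character(120:140)] <- planted[, as.character(120:140)] + 0.01
  sel <- size_frequency_test(planted, healthy, alpha = 0.01)
  expect_true(all(120:140 %in% sel$sizes))
  # unplanted sizes appear only at the false-positive rate
  expect_lt(sum(!(sel$sizes %in% 120:140)), 0.05 * length(sizes))
  expect_equal(sel$table$direction[sel$table$size == 130], "greater")

  expect_length(size_frequency_test(planted, healthy, alpha = 0)$sizes, 0)
})

test_that("MFR keeps qualifying fragments and counts fully methylated ones", {
  w <- tile_autosomes(c(chrA = 1e6), 1e6)
  fr <- sample_fragments(do.call(rbind, list(
    frag_df(start = 1000, cpg_total = 3, cpg_methylated = 3),
    frag_df(start = 2000, cpg_total = 3, cpg_methylated = 2),
    frag_df(start = 3000, cpg_total = 4, cpg_methylated = 4),
    frag_df(start = 4000, cpg_total = 5, cpg_methylated = 0))))
  expect_equal(compute_mfr(fr, w), 0.5)

  # fewer than 3 CpGs, out-of-band lengths, poor conversion: all excluded
  excl <- sample_fragments(do.call(rbind, list(
    frag_df(start = 1000, cpg_total = 2, cpg_methylated = 2),
    frag_df(start = 2000, length = 79, cpg_total = 3, cpg_methylated = 3),
    frag_df(start = 3000, length = 251, cpg_total = 3, cpg_methylated = 3),
    frag_df(start = 4000, noncpg_c_total = 100, noncpg_c_converted = 90))))
  expect_true(is.na(compute_mfr(excl, w)))

  # boundary lengths 80 and 250 are inside the band
  bound <- sample_fragments(rbind(frag_df(start = 1000, length = 80),
                                  frag_df(start = 2000, length = 250)))
  expect_equal(compute_mfr(bound, w), 1)
})

test_that("MFR equals a per-fragment filtering + counting oracle", {
  w <- tile_autosomes(toy_sizes, 1e6)
  fr <- random_fragments(1000, toy_sizes, seed = 23)
  got <- compute_mfr(fr, w)
  num <- den <- numeric(nrow(w))
  for (i in seq_len(nrow(fr))) {
    ok <- fr$cpg_total[i] >= 3 && fr$length[i] >= 80 && fr$length[i] <= 250 &&
      (fr$noncpg_c_total[i] == 0 ||
         fr$noncpg_c_converted[i] / fr$noncpg_c_total[i] > 0.95)
    if (!ok) next
    mid <- floor((fr$start[i] + fr$end[i]) / 2)
    j <- which(w$chrom == fr$chrom[i] & w$start <= mid & mid < w$end)
    den[j] <- den[j] + 1
    if (fr$cpg_methylated[i] == fr$cpg_total[i]) num[j] <- num[j] + 1
  }
  expect_equal(got, ifelse(den > 0, num / den, NA_real_))
  expect_true(all(got >= 0 & got <= 1, na.rm = TRUE))

  # invariant to fragment order
  perm <- sample(nrow(fr))
  expect_equal(compute_mfr(sample_fragments(as.data.frame(fr)[perm, ]), w), got)
})

test_that("FSI is z-scored, gates sizes strictly, and matches a pipeline oracle", {
  cfg <- simulation_config(seed = 31, n_healthy = 1, n_cancer = 0,
                           fragments_per_sample = 30000)
  sim <- simulate_cohort(cfg)
  sc <- build_scaffold(sim$genome)
  s <- sim$samples[[1]]
  n5 <- nrow(sc$merge$windows)
  got <- compute_fsi(s, sc$bins, sc$merge$map, n5)
  expect_equal(mean(got), 0, tolerance = 1e-6)
  expect_equal(sd(got), 1, tolerance = 1e-6)

  # independent straight-line oracle
  mid <- floor((s$start + s$end) / 2)
  short <- long <- numeric(nrow(sc$bins))
  for (i in seq_len(nrow(s))) {
    j <- which(sc$bins$chrom == s$chrom[i] & sc$bins$start <= mid[i] &
                 mid[i] < sc$bins$end)
    j <- j[1]
    if (is.na(j)) next
    if (s$length[i] >= 100 && s$length[i] <= 166) short[j] <- short[j] + 1
    if (s$length[i] >= 169 && s$length[i] <= 240) long[j] <- long[j] + 1
  }
  ratio <- (short + 1) / (long + 1)
  corr <- loess_gc_correct(ratio, sc$bins$gc)
  wmean <- vapply(seq_len(n5), function(wdx)
    mean(corr[which(!is.na(sc$merge$map) & sc$merge$map == wdx)]), numeric(1))
  oracle <- (wmean - mean(wmean)) / sd(wmean)
  expect_equal(got, oracle, tolerance = 1e-9)

  # a 167-bp fragment counts in neither gate; 166 and 169 are inclusive
  w2 <- tile_autosomes(c(chrA = 2e5), 1e5)
  attr(w2, "bin_size") <- 1e5
  fr <- sample_fragments(rbind(
    frag_df(start = 10000, length = 167), frag_df(start = 1.1e5, length = 167)))
  gates <- size_gates()
  s_cnt <- bin_coverage(fr, w2, function(l) l >= gates$short_range[1] &
                          l <= gates$short_range[2])
  l_cnt <- bin_coverage(fr, w2, function(l) l >= gates$long_range[1] &
                          l <= gates$long_range[2])
  expect_equal(sum(s_cnt) + sum(l_cnt), 0)
})

test_that("reference FSI profile and similarity behave as medians/correlations", {
  m <- matrix(c(1, 2, 9, 4, 5, 6), 3, 2)
  expect_equal(reference_fsi_profile(m), c(2, 5))
  one <- matrix(rnorm(10), 1)
  expect_equal(reference_fsi_profile(one), as.numeric(one))
  set.seed(14)
  big <- matrix(rnorm(25 * 40), 25)
  expect_equal(reference_fsi_profile(big), apply(big, 2, function(v) sort(v)[13]))

  v <- rnorm(40)
  expect_equal(fsi_similarity(v, v), 1)
  expect_equal(fsi_similarity(v, -v), -1)
  u <- rnorm(40)
  expect_equal(fsi_similarity(v, u),
               mean((v - mean(v)) * (u - mean(u))) / (sd(v) * sd(u)) * 40 / 39,
               tolerance = 1e-12)
})

test_that("PA score sums the five most extreme arm z-scores", {
  z0 <- stats::setNames(rep(0, 8), paste0("a", 1:8))
  expect_equal(pa_score(z0), 0)

  z <- stats::setNames(c(5, -4, 3, -2, 1, 0, 0, 0), paste0("a", 1:8))
  expect_equal(pa_score(z), 15)

  # exhaustive 5-subset oracle on 39 random arms
  set.seed(15)
  z39 <- stats::setNames(rnorm(39), paste0("arm", 1:39))
  best <- max(combn(39, 5, function(ii) sum(abs(z39[ii]))))
  expect_equal(pa_score(z39), best)

  # monotone in any single |z|
  z2 <- z39; z2[7] <- z2[7] + 5
  expect_gte(pa_score(z2), pa_score(z39))

  expect_error(pa_score(stats::setNames(rnorm(3), letters[1:3])), "at least 5")
})

test_that("CAFF flags a planted arm-level gain and rejects fully gated samples", {
  cfg <- simulation_config(seed = 41, n_healthy = 10, n_cancer = 1,
                           fragments_per_sample = 15000, signal = "strong",
                           cna_spec = c(chr2q = 1.8), frac_in_peaks = 0)
  sim <- simulate_cohort(cfg)
  sc <- build_scaffold(sim$genome)
  base <- build_caff_baseline(sim$samples[1:8], sc$bins, sc$arms)
  # held-out healthy sample: PA below the strong planted signal
  healthy_caff <- compute_caff(sim$samples[[9]], sc$bins, sc$arms, base)
  cancer_caff <- compute_caff(sim$samples[["C001"]], sc$bins, sc$arms, base)
  expect_equal(names(which.max(abs(cancer_caff$arm_z))), "chr2q")
  expect_gt(cancer_caff$pa_score, healthy_caff$pa_score)
  expect_equal(cancer_caff$caff_log10, log10(cancer_caff$pa_score + 1))

  # all fragments inside the 151-220 bp gate -> nothing to analyse
  gated <- sample_fragments(frag_df(start = 1000, length = 180))
  expect_error(compute_caff(gated, sc$bins, sc$arms, base), "size gate")
})

test_that("end-motif vector spans 256 4-mers, sums to one, matches a tally oracle", {
  vocab <- fem_vocabulary()
  expect_length(vocab, 256)
  expect_false(any(duplicated(vocab)))
  expect_true(all(nchar(vocab) == 4))

  one <- sample_fragments(frag_df(length = 120, motif_crick = "CCCA"))
  fem1 <- compute_fem(one)
  expect_equal(unname(fem1["CCCA"]), 1)
  expect_equal(sum(fem1), 1)

  fr <- random_fragments(200, seed = 25)
  got <- compute_fem(fr)
  keep <- fr$length < 171 & !is.na(fr$motif_crick)
  oracle <- table(factor(fr$motif_crick[keep], levels = vocab))
  expect_equal(unname(got), as.numeric(oracle) / sum(oracle))
  expect_equal(sum(got), 1, tolerance = 1e-9)

  # 171-bp fragments are out; duplication of the sample leaves frequencies fixed
  out171 <- sample_fragments(frag_df(length = 171))
  expect_equal(sum(compute_fem(out171)), 0)
  dup <- sample_fragments(rbind(as.data.frame(fr), as.data.frame(fr)))
  expect_equal(compute_fem(dup), got)
})
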