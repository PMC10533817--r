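# Shared fixture builders. Everything is generated in code at test time.

# Minimal fragment table; defaults give a valid mid-size cfDNA molecule.
frag_df <- function(chrom = "chrA", start = 1000, end = start + length,
                    length = 167, mapq = 60, cpg_total = 3,
                    cpg_methylated = 3, noncpg_c_total = 20,
                    noncpg_c_converted = 20, motif_crick = "CCCA") {
  data.frame(chrom = chrom, start = start, end = end, length = end - start,
             mapq = mapq, cpg_total = cpg_total,
             cpg_methylated = cpg_methylated, noncpg_c_total = noncpg_c_total,
             noncpg_c_converted = noncpg_c_converted,
             motif_crick = motif_crick, stringsAsFactors = FALSE)
}

# Random valid fragments spread over a toy genome.
random_fragments <- function(n, chrom_sizes = c(chrA = 1e6, chrB = 1e6),
                             seed = 1) {
  set.seed(seed)
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  len <- sample(60:350, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_sizes[chrom] - len))
  cpg <- rpois(n, 3)
  meth <- rbinom(n, cpg, 0.8)
  nct <- rpois(n, 20)
  ncc <- rbinom(n, nct, 0.99)
  vocab <- fem_vocabulary()
  sample_fragments(data.frame(
    chrom = chrom, start = start, end = start + len, length = len,
    mapq = 60, cpg_total = cpg, cpg_methylated = meth,
    noncpg_c_total = nct, noncpg_c_converted = ncc,
    motif_crick = sample(vocab, n, replace = TRUE),
    stringsAsFactors = FALSE), "random")
}

# Two 10-Mb toy chromosomes.
toy_sizes <- c(chrA = 1e7, chrB = 1e7)
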