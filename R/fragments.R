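#' Fragment tables
#'
#' A fragment is one sequenced cfDNA molecule. Fragments are stored as a
#' `data.frame` (class `sample_fragments`) with columns:
#' `chrom`, `start`, `end` (0-based half-open outer span of the read pair),
#' `length` (= end - start, the template length), `mapq` (minimum over mates),
#' `cpg_total` / `cpg_methylated` (CpG observations on the molecule),
#' `noncpg_c_total` / `noncpg_c_converted` (non-CpG cytosine observations used
#' for the conversion-rate filter), and `motif_crick` (the 4-mer at the 5' end
#' of the Crick-strand mate, i.e. the reverse complement of reference bases
#' `[end-4, end)`, or `NA`).
#'
#' @param df data.frame with the columns above
#' @param sample_id sample identifier attached as an attribute
#' @return validated `sample_fragments` data.frame
#' @export
sample_fragments <- function(df, sample_id = "sample") {
  req <- c("chrom", "start", "end", "length", "mapq", "cpg_total",
           "cpg_methylated", "noncpg_c_total", "noncpg_c_converted", "motif_crick")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing fragment columns: ", paste(miss, collapse = ", "))
  bad <- which(df$end - df$start <= 0 | df$length != df$end - df$start |
                 df$cpg_methylated > df$cpg_total |
                 df$noncpg_c_converted > df$noncpg_c_total |
                 df$cpg_total < 0 | df$cpg_methylated < 0 |
                 df$noncpg_c_total < 0 | df$noncpg_c_converted < 0)
  if (length(bad))
    stop(sprintf("fragment invariant violated at row %d", bad[1]))
  mot <- df$motif_crick
  bad_mot <- which(!is.na(mot) & (nchar(mot) != 4 | grepl("[^ACGT]", mot)))
  if (length(bad_mot))
    stop(sprintf("fragment invariant violated at row %d: bad motif", bad_mot[1]))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("sample_fragments", "data.frame")
  df
}

#' Read a fragment table (TSV)
#'
#' The TSV dialect has a header line with the `sample_fragments` columns;
#' `motif_crick` uses `.` for an absent motif. Gzip-compressed files are
#' handled transparently.
#'
#' @param tsv_path path to the table
#' @param sample_id sample identifier (defaults to the file name)
#' @return a `sample_fragments` data.frame
#' @export
read_fragment_table <- function(tsv_path, sample_id = basename(tsv_path)) {
  df <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", motif_crick = "character"))
  df$motif_crick[df$motif_crick == "."] <- NA_character_
  sample_fragments(df, sample_id)
}

#' @rdname read_fragment_table
#' @param fragments a `sample_fragments` data.frame
#' @export
write_fragment_table <- function(fragments, tsv_path) {
  out <- as.data.frame(fragments)
  out$motif_crick[is.na(out$motif_crick)] <- "."
  con <- if (grepl("\\.gz$", tsv_path)) gzfile(tsv_path, "w") else file(tsv_path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

# Tally a methylation call string (bisulfite-aligner tag dialect):
# Z/z methylated/unmethylated CpG; X/x, H/h, U/u non-CpG contexts where the
# lower-case letter indicates a converted (read-as-T) cytosine.
tally_calls <- function(xm) {
  ch <- strsplit(xm, "", fixed = TRUE)[[1]]
  c(cpg_total = sum(ch %in% c("Z", "z")),
    cpg_methylated = sum(ch == "Z"),
    noncpg_c_total = sum(ch %in% c("X", "x", "H", "h", "U", "u")),
    noncpg_c_converted = sum(ch %in% c("x", "h", "u")))
}

#' Read aligned methylation-sequencing fragments
#'
#' Merges coordinate-sorted, deduplicated proper pairs into fragments:
#' start = leftmost mate start, end = rightmost mate end (outer/template
#' span), mapq = min over mates. Methylation call strings (XM-tag dialect)
#' are tallied per molecule; where mates overlap, the overlapping prefix of
#' the rightmost mate is clipped so every base is counted once. Pairs with
#' minimum mapping quality below `min_mapq` are dropped; secondary,
#' supplementary and duplicate-flagged records are ignored. Only
#' match/mismatch CIGARs (optionally soft-clipped) are supported.
#'
#' @param alignment_source path to a BAM file, or a SAM file (converted on
#'   the fly)
#' @param min_mapq minimum of the two mate mapping qualities (default 20)
#' @param reference optional [Biostrings::DNAStringSet] (or FASTA path) used
#'   to compute the Crick-strand 5' end motif from the reference sequence
#' @param sample_id sample identifier
#' @return a `sample_fragments` data.frame; counters for skipped records are
#'   attached as attribute `qc`
#' @export
read_fragments <- function(alignment_source, min_mapq = 20, reference = NULL,
                           sample_id = basename(alignment_source)) {
  bam <- alignment_source
  if (grepl("\\.sam$", alignment_source, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment_source,
                            destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "cigar", "mapq", "flag"),
    tag = "XM")
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  qc <- c(unpaired = 0L, missing_tag = 0L, bad_cigar = 0L, low_mapq = 0L)
  if (n == 0) {
    empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        length = numeric(), mapq = numeric(), cpg_total = numeric(),
                        cpg_methylated = numeric(), noncpg_c_total = numeric(),
                        noncpg_c_converted = numeric(), motif_crick = character(),
                        stringsAsFactors = FALSE)
    out <- sample_fragments(empty, sample_id)
    attr(out, "qc") <- qc
    return(out)
  }
  ref_width <- function(cig) {
    # reference-consumed width for M/=/X/D/N ops
    ops <- gregexpr("\\d+[MIDNSHP=X]", cig)[[1]]
    toks <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    sum(vapply(toks, function(t) {
      op <- substr(t, nchar(t), nchar(t))
      len <- as.integer(substr(t, 1, nchar(t) - 1))
      if (op %in% c("M", "=", "X", "D", "N")) len else 0L
    }, integer(1)))
  }
  xm <- rec$tag$XM
  if (is.null(xm)) xm <- rep(NA_character_, n)
  keep_simple <- grepl("^(\\d+S)?\\d+M(\\d+S)?$", rec$cigar)
  qc["bad_cigar"] <- sum(!keep_simple)
  by_q <- split(which(keep_simple), rec$qname[keep_simple])
  by_q <- by_q[lengths(by_q) == 2]
  qc["unpaired"] <- sum(keep_simple) - 2L * length(by_q)
  if (!is.null(reference) && is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  ref_names <- if (!is.null(reference)) sub("\\s.*", "", names(reference)) else NULL

  rows <- lapply(by_q, function(ii) {
    pos <- rec$pos[ii]
    w <- vapply(rec$cigar[ii], ref_width, integer(1))
    o <- order(pos)
    ii <- ii[o]; pos <- pos[o]; w <- w[o]
    start0 <- pos[1] - 1
    end0 <- max(pos + w - 1)
    mq <- min(rec$mapq[ii])
    if (mq < min_mapq) return(NULL)
    x1 <- xm[ii[1]]; x2 <- xm[ii[2]]
    missing_tag <- is.na(x1) && is.na(x2)
    # clip rightmost mate's prefix overlapping the leftmost mate
    ov <- (pos[1] + w[1]) - pos[2]
    if (!is.na(x2) && ov > 0) x2 <- substr(x2, min(ov, nchar(x2)) + 1, nchar(x2))
    t1 <- if (!is.na(x1)) tally_calls(x1) else rep(0, 4)
    t2 <- if (!is.na(x2)) tally_calls(x2) else rep(0, 4)
    tt <- t1 + t2
    motif <- NA_character_
    chrom <- as.character(rec$rname[ii[1]])
    if (!is.null(reference) && chrom %in% ref_names && end0 >= 4) {
      s <- Biostrings::subseq(reference[[match(chrom, ref_names)]],
                              start = end0 - 3, end = end0)
      m <- as.character(Biostrings::reverseComplement(s))
      if (!grepl("[^ACGT]", m)) motif <- m
    }
    data.frame(chrom = chrom, start = start0, end = end0, length = end0 - start0,
               mapq = mq, cpg_total = tt[1], cpg_methylated = tt[2],
               noncpg_c_total = tt[3], noncpg_c_converted = tt[4],
               motif_crick = motif, missing_tag = missing_tag,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(df)) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     length = numeric(), mapq = numeric(), cpg_total = numeric(),
                     cpg_methylated = numeric(), noncpg_c_total = numeric(),
                     noncpg_c_converted = numeric(), motif_crick = character(),
                     missing_tag = logical(), stringsAsFactors = FALSE)
  }
  qc["low_mapq"] <- length(by_q) - nrow(df)
  qc["missing_tag"] <- sum(df$missing_tag)
  df$missing_tag <- NULL
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  out <- sample_fragments(df, sample_id)
  attr(out, "qc") <- qc
  out
}

#' Estimate enzymatic conversion rate from an unmethylated spike-in
#'
#' On an unmethylated control (e.g. lambda DNA) every cytosine is unmodified,
#' so the conversion rate pools CpG and non-CpG contexts:
#' converted / observed cytosines over all fragments. With zero observations
#' the rate is undefined and `NA` is returned.
#'
#' @param spikein_fragments `sample_fragments` aligned to the spike-in
#' @return conversion rate in \[0, 1\], or `NA_real_`
#' @export
estimate_conversion <- function(spikein_fragments) {
  total <- sum(spikein_fragments$cpg_total) + sum(spikein_fragments$noncpg_c_total)
  if (total == 0) return(NA_real_)
  converted <- sum(spikein_fragments$cpg_total - spikein_fragments$cpg_methylated) +
    sum(spikein_fragments$noncpg_c_converted)
  converted / total
}

#' Downsample fragments without replacement
#'
#' @param sample a `sample_fragments` data.frame
#' @param n number of fragments to keep
#' @param seed integer seed; identical (input, n, seed) gives identical output
#' @export
downsample_fragments <- function(sample, n, seed) {
  if (n > nrow(sample))
    stop(sprintf("n = %d exceeds the %d available fragments; keep all instead",
                 n, nrow(sample)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(sample.int(nrow(sample), n))
  out <- sample[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(sample, "sample_id")
  class(out) <- c("sample_fragments", "data.frame")
  out
}

# Save/restore the RNG state so seeded utilities do not disturb the caller's
# random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
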