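#' Genomic window scaffolding
#'
#' All feature modalities are computed over fixed, non-overlapping tilings of
#' the autosomes: 100-kb bins for copy-number work, 1-Mb windows for the
#' methylated fragment ratio, and 5-Mb windows (merged from 100-kb bins) for
#' the fragment size index. A window set is an ordinary `data.frame` with
#' columns `chrom`, `start`, `end` (0-based, half-open), `index` (contiguous
#' 1-based ordinal), and optional annotation columns `gc` and `arm`, carrying
#' the nominal bin size and a provenance string as attributes.
#'
#' @param chrom character chromosome names
#' @param start,end integer-valued 0-based half-open coordinates
#' @param bin_size nominal window width in bp
#' @param provenance free-text description of how the set was derived
#' @return a `window_set` data.frame
#' @export
window_set <- function(chrom, start, end, bin_size, provenance = "") {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (length(start) && any(start < 0 | end <= start))
    stop("window coordinates must satisfy 0 <= start < end")
  ws <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    index = seq_along(start),
    gc = rep(NA_real_, length(start)),
    arm = rep(NA_character_, length(start)),
    stringsAsFactors = FALSE
  )
  ord <- order(ws$chrom, ws$start)
  if (any(ord != seq_along(ord))) ws <- ws[ord, , drop = FALSE]
  ws$index <- seq_len(nrow(ws))
  rownames(ws) <- NULL
  attr(ws, "bin_size") <- bin_size
  attr(ws, "provenance") <- provenance
  class(ws) <- c("window_set", "data.frame")
  ws
}

#' @keywords internal
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Tile autosomes into fixed-width windows
#'
#' Tiles each chromosome from position 0 into adjacent windows of `bin_size`
#' bp. Chromosome-terminal partial tiles are dropped, as is any tile
#' overlapping an exclusion interval (blacklist, assembly gap) by one or more
#' bases. Retained tiles are re-indexed contiguously.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp); the
#'   caller restricts this to autosomes
#' @param bin_size window width in bp
#' @param exclusions optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions whose overlapping tiles are removed
#' @return a `window_set`
#' @export
tile_autosomes <- function(chrom_sizes, bin_size, exclusions = NULL) {
  if (length(chrom_sizes) == 0) stop("chrom_sizes is empty")
  stopifnot(bin_size > 0)
  chroms <- names(chrom_sizes)
  if (is.null(chroms)) stop("chrom_sizes must be named by chromosome")
  tiles <- lapply(chroms, function(ch) {
    n <- floor(chrom_sizes[[ch]] / bin_size)
    if (n == 0) return(NULL)
    s <- (seq_len(n) - 1) * bin_size
    data.frame(chrom = ch, start = s, end = s + bin_size,
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, tiles)
  if (is.null(tiles) || nrow(tiles) == 0) {
    warning("bin_size exceeds every chromosome length; empty window set")
    return(window_set(character(), numeric(), numeric(), bin_size))
  }
  prov <- sprintf("tiled %d chromosomes at %d bp", length(chroms), bin_size)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(tiles), as_granges(exclusions),
                                        minoverlap = 1L)
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) tiles <- tiles[-drop, , drop = FALSE]
    prov <- paste0(prov, sprintf("; %d tiles removed by exclusion tracks", length(drop)))
  }
  window_set(tiles$chrom, tiles$start, tiles$end, bin_size, prov)
}

#' Annotate windows with reference GC content
#'
#' GC fraction is (#G + #C) / (#A + #C + #G + #T) within each window;
#' ambiguous bases count in neither numerator nor denominator. Windows with
#' more than 50% ambiguous bases are dropped and the remainder re-indexed.
#'
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file
#' @param windows a `window_set`
#' @param max_n_fraction windows with a higher fraction of ambiguous bases are
#'   dropped (default 0.5)
#' @return the `window_set` with `gc` filled in
#' @export
compute_gc <- function(reference, windows, max_n_fraction = 0.5) {
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  nm <- sub("\\s.*", "", names(reference))
  seqlen <- stats::setNames(Biostrings::width(reference), nm)
  bad <- !(windows$chrom %in% nm) |
    windows$end > seqlen[windows$chrom]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("window %d (%s:%d-%d) lies beyond the reference sequence",
                 windows$index[i], windows$chrom[i], windows$start[i], windows$end[i]))
  }
  counts <- t(vapply(seq_len(nrow(windows)), function(i) {
    s <- Biostrings::subseq(reference[[match(windows$chrom[i], nm)]],
                            start = windows$start[i] + 1L, end = windows$end[i])
    Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  }, numeric(4)))
  acgt <- rowSums(counts)
  width <- windows$end - windows$start
  keep <- (width - acgt) / width <= max_n_fraction & acgt > 0
  gc <- ifelse(acgt > 0, (counts[, 2] + counts[, 3]) / acgt, NA_real_)
  out <- windows[keep, , drop = FALSE]
  out$gc <- gc[keep]
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "bin_size") <- attr(windows, "bin_size")
  attr(out, "provenance") <- paste0(attr(windows, "provenance"),
                                    "; GC annotated, high-N windows dropped")
  class(out) <- c("window_set", "data.frame")
  out
}

#' Build chromosome arms from centromere intervals
#'
#' The p-arm spans from 0 to the centromere start and the q-arm from the
#' centromere end to the chromosome end. Acrocentric p-arms (on hg19:
#' 13p, 14p, 15p, 21p, 22p) are excluded, which yields the standard 39
#' autosomal arms used for arm-level aneuploidy scoring.
#'
#' @param centromeres data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), one row per autosome
#' @param chrom_sizes named numeric vector of chromosome lengths
#' @param acrocentric character vector of arm labels (e.g. `"chr13p"`) to drop
#' @return data.frame with columns `arm`, `chrom`, `start`, `end`
#' @export
build_arms <- function(centromeres, chrom_sizes,
                       acrocentric = character()) {
  stopifnot(all(centromeres$chrom %in% names(chrom_sizes)))
  len <- chrom_sizes[centromeres$chrom]
  if (any(centromeres$start < 0 | centromeres$end > len))
    stop("centromere interval outside its chromosome")
  arms <- rbind(
    data.frame(arm = paste0(centromeres$chrom, "p"), chrom = centromeres$chrom,
               start = 0, end = centromeres$start, stringsAsFactors = FALSE),
    data.frame(arm = paste0(centromeres$chrom, "q"), chrom = centromeres$chrom,
               start = centromeres$end, end = as.numeric(len),
               stringsAsFactors = FALSE)
  )
  arms <- arms[arms$end > arms$start & !(arms$arm %in% acrocentric), , drop = FALSE]
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  rownames(arms) <- NULL
  arms
}

#' hg19 acrocentric p-arm labels
#' @export
ACROCENTRIC_P_ARMS <- c("chr13p", "chr14p", "chr15p", "chr21p", "chr22p")

#' Merge small bins into larger windows
#'
#' Groups consecutive retained bins on the same chromosome into blocks of
#' `target_size / bin_size` bins (50 for 100-kb bins and 5-Mb windows). A
#' chromosome-terminal block is kept only if it contains at least half of the
#' full bin complement; smaller remainders are dropped. The returned mapping
#' assigns each input bin its merged-window index (`NA` for dropped bins).
#'
#' @param bins a `window_set` of small bins (sorted)
#' @param target_size merged window width, an integer multiple of the bin size
#' @return list with elements `windows` (a `window_set`) and `map` (integer
#'   vector over input bins)
#' @export
merge_bins_to_windows <- function(bins, target_size) {
  bin_size <- attr(bins, "bin_size")
  stopifnot(!is.null(bin_size), target_size %% bin_size == 0)
  if (is.unsorted(order(bins$chrom, bins$start)))
    stop("bins must be sorted by (chrom, start)")
  per <- target_size / bin_size
  map <- rep(NA_integer_, nrow(bins))
  wins <- list()
  next_id <- 0L
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    grp <- (seq_along(idx) - 1) %/% per
    for (g in unique(grp)) {
      members <- idx[grp == g]
      if (length(members) < per / 2) next   # terminal remainder too small
      next_id <- next_id + 1L
      map[members] <- next_id
      wins[[next_id]] <- data.frame(
        chrom = ch, start = min(bins$start[members]), end = max(bins$end[members]),
        stringsAsFactors = FALSE)
    }
  }
  wdf <- if (length(wins)) do.call(rbind, wins) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  ws <- window_set(wdf$chrom, wdf$start, wdf$end, target_size,
                   sprintf("merged from %d-bp bins, %d per window", bin_size, per))
  # window_set() may reorder; remap ids to the sorted order
  if (nrow(wdf)) {
    ord <- order(wdf$chrom, wdf$start)
    remap <- integer(nrow(wdf)); remap[ord] <- seq_len(nrow(wdf))
    map <- ifelse(is.na(map), NA_integer_, remap[map])
  }
  list(windows = ws, map = map)
}

#' Load tissue-specific open-chromatin peak clusters
#'
#' Reads a BED4+ file whose fourth column labels each 500-bp ATAC-seq peak
#' with its tissue-specificity cluster. A full peak set has 18 clusters; toy
#' fixtures may use fewer (a warning, not an error).
#'
#' @param bed_path path to the peak BED file
#' @return data.frame with columns `chrom`, `start`, `end`, `cluster`
#' @export
load_peak_clusters <- function(bed_path) {
  lines <- readLines(bed_path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 4))
    stop(sprintf("malformed BED line %d: fewer than 4 fields", which(n < 4)[1]))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  cluster <- vapply(fields, `[`, "", 4L)
  bad <- is.na(start) | is.na(end) | end <= start | start < 0
  if (any(bad))
    stop(sprintf("malformed BED line %d: invalid interval", which(bad)[1]))
  peaks <- data.frame(chrom = chrom, start = start, end = end,
                      cluster = cluster, stringsAsFactors = FALSE)
  n_cl <- length(unique(peaks$cluster))
  if (n_cl != 18)
    warning(sprintf("peak file has %d clusters (a full set has 18)", n_cl))
  peaks
}

#' Persist / restore a window set as BED4 plus an annotation sidecar
#'
#' @param windows a `window_set`
#' @param bed_path output BED path; the sidecar is written next to it with
#'   suffix `.annot.tsv`
#' @export
write_window_set <- function(windows, bed_path) {
  bed <- data.frame(windows$chrom, format(windows$start, scientific = FALSE, trim = TRUE),
                    format(windows$end, scientific = FALSE, trim = TRUE), windows$index)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  annot <- data.frame(index = windows$index, gc = windows$gc, arm = windows$arm)
  utils::write.table(annot, paste0(bed_path, ".annot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}

#' @rdname write_window_set
#' @param bin_size nominal width recorded on the restored set
#' @export
read_window_set <- function(bed_path, bin_size) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE)
  ws <- window_set(bed[[1]], bed[[2]], bed[[3]], bin_size,
                   sprintf("restored from %s", basename(bed_path)))
  sidecar <- paste0(bed_path, ".annot.tsv")
  if (file.exists(sidecar)) {
    annot <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    ws$gc <- annot$gc[match(ws$index, annot$index)]
    ws$arm <- as.character(annot$arm[match(ws$index, annot$index)])
  }
  ws
}
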