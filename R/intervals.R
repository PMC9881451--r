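#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, the convention used for
#' every region resource in the package; positions are converted to VCF's
#' 1-based coordinates only at VCF read/write boundaries.
#'
#' @param chrom character chromosome names.
#' @param start 0-based inclusive starts (bp).
#' @param end 0-based exclusive ends (bp).
#' @param ... further equal-length vectors stored as extra columns
#'   (e.g. `name`, `value`).
#' @return a data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  n <- max(length(chrom), length(start), length(end))
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (length(chrom) > 0) {
    stopifnot(all(nzchar(chrom)), all(start >= 0), all(end > start))
  }
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Build an interval index supporting overlap queries
#'
#' Thin wrapper around a [GenomicRanges::GRanges] object (interval trees via
#' IRanges) storing 0-based half-open intervals. Point and window queries go
#' through [query_overlaps()].
#'
#' @param intervals a `genomic_intervals` data.frame (or any data.frame with
#'   `chrom`, `start`, `end` and optional extra columns).
#' @return an object of class `interval_index`.
#' @export
build_interval_index <- function(intervals) {
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0) {
    gr <- GenomicRanges::GRanges()
  } else {
    # GRanges is 1-based closed: [start, end) becomes [start + 1, end]
    gr <- GenomicRanges::GRanges(
      seqnames = intervals$chrom,
      ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
    )
  }
  structure(list(gr = gr, table = intervals), class = "interval_index")
}

#' @export
print.interval_index <- function(x, ...) {
  cat("<interval_index> of", nrow(x$table), "intervals on",
      length(unique(x$table$chrom)), "chromosomes\n")
  invisible(x)
}

#' Query an interval index with half-open windows
#'
#' Returns, for each query window, the indexed intervals overlapping it.
#' Overlap is strict half-open: a window `[20, 30)` does not touch an
#' interval `[10, 20)`.
#'
#' @param index an `interval_index`.
#' @param chrom,start,end equal-length vectors of query windows, 0-based
#'   half-open.
#' @return a data.frame with columns `query` (index into the query vectors)
#'   and `hit` (row index into the indexed interval table).
#' @export
query_overlaps <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "interval_index"))
  n <- length(chrom)
  if (n == 0 || length(index$gr) == 0) {
    return(data.frame(query = integer(0), hit = integer(0)))
  }
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = pmax(end, start + 1))
  )
  # end <= start would be an empty window; IRanges needs width >= 1, so empty
  # windows are dropped explicitly
  keep <- end > start
  # a query chromosome absent from the index is an ordinary zero-hit case,
  # not a condition worth a seqlevel warning
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, index$gr))
  out <- data.frame(query = S4Vectors::queryHits(ov),
                    hit = S4Vectors::subjectHits(ov))
  out[keep[out$query], , drop = FALSE]
}

#' Count indexed intervals overlapping each query window
#'
#' @inheritParams query_overlaps
#' @return integer vector of counts, one per query window.
#' @export
count_overlaps_in <- function(index, chrom, start, end) {
  n <- length(chrom)
  hits <- query_overlaps(index, chrom, start, end)
  counts <- integer(n)
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$query, levels = seq_len(n)))
    counts <- as.integer(tab)
  }
  counts
}

#' Test whether each query window overlaps any indexed interval
#'
#' @inheritParams query_overlaps
#' @return logical vector, one per query window.
#' @export
overlaps_any <- function(index, chrom, start, end) {
  count_overlaps_in(index, chrom, start, end) > 0
}

#' Read intervals from a BED file
#'
#' BED is 0-based half-open already; the `name` column (4th), when present,
#' is kept (used for region classes and gene identifiers).
#'
#' @param path BED file (3+ columns, tab separated).
#' @return a `genomic_intervals` data.frame.
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(genomic_intervals(character(0), numeric(0), numeric(0),
                             name = character(0)))
  }
  nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    name = nm
  )
}

#' Write intervals to a BED file
#'
#' @param intervals a `genomic_intervals` data.frame; a `name` column, when
#'   present, is written as the 4th BED column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)
  cols <- data.frame(chrom = df$chrom,
                     start = format(df$start, scientific = FALSE, trim = TRUE),
                     end = format(df$end, scientific = FALSE, trim = TRUE),
                     stringsAsFactors = FALSE)
  if (!is.null(df$name)) cols$name <- df$name
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
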