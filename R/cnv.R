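# Tumor-only copy-number post-processing and the matched-vs-tumor-only
# concordance benchmark. Segments arrive from an upstream allele-specific
# copy-number caller as per-sample tables of (total, major, minor) copy
# number; post-processing removes segments in curated artifact regions near
# telomeres/centromeres, rounds slightly negative estimates (in (-0.5, 0))
# to 0 and drops largely negative ones (< -0.5) as unreliable.

#' Construct a per-sample copy-number callset
#'
#' @param sample sample identifier.
#' @param purity tumor purity in (0, 1].
#' @param ploidy mean tumor copy number (> 0).
#' @param segments data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `total_cn`, `major_cn`, `minor_cn` (real-valued).
#' @param check validate invariants (non-overlap within chromosome,
#'   major >= minor, major + minor == total within 1e-6).
#' @return object of class `cn_callset`.
#' @export
cn_callset <- function(sample, purity, ploidy, segments, check = TRUE) {
  stopifnot(purity > 0, purity <= 1, ploidy > 0)
  segments <- as.data.frame(segments)
  if (check && nrow(segments) > 0) {
    stopifnot(all(segments$end > segments$start),
              all(segments$major_cn >= segments$minor_cn - 1e-9))
    both <- is.finite(segments$major_cn) & is.finite(segments$minor_cn)
    stopifnot(all(abs(segments$major_cn[both] + segments$minor_cn[both] -
                        segments$total_cn[both]) < 1e-6))
    o <- order(chrom_rank(segments$chrom), segments$start)
    segments <- segments[o, , drop = FALSE]
    ov <- segments$chrom[-1] == segments$chrom[-nrow(segments)] &
      segments$start[-1] < segments$end[-nrow(segments)]
    if (length(ov) > 0 && any(ov)) stop("overlapping segments within a chromosome")
    rownames(segments) <- NULL
  }
  structure(list(sample = sample, purity = purity, ploidy = ploidy,
                 segments = segments), class = "cn_callset")
}

#' @export
print.cn_callset <- function(x, ...) {
  cat(sprintf("<cn_callset> %s: purity %.3f, ploidy %.3f, %d segments\n",
              x$sample, x$purity, x$ploidy, nrow(x$segments)))
  invisible(x)
}

#' Write a copy-number callset as a segment table
#'
#' Tab-separated with a per-sample header line
#' `##sample=<id>\tpurity=<p>\tploidy=<pl>` followed by the segment columns.
#'
#' @param cs a `cn_callset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cn_callset <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("##sample=%s\tpurity=%.6f\tploidy=%.6f",
                     cs$sample, cs$purity, cs$ploidy), con)
  seg <- cs$segments
  out <- data.frame(
    sample = rep(cs$sample, nrow(seg)),
    chrom = seg$chrom,
    start = format(seg$start, scientific = FALSE, trim = TRUE),
    end = format(seg$end, scientific = FALSE, trim = TRUE),
    # write total as the sum of the rounded alleles so the allele-sum
    # invariant survives the 6-decimal serialization exactly
    copyNumber = sprintf("%.6f", round(seg$major_cn, 6) + round(seg$minor_cn, 6)),
    majorAlleleCopyNumber = sprintf("%.6f", seg$major_cn),
    minorAlleleCopyNumber = sprintf("%.6f", seg$minor_cn),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' @param path file written by [write_cn_callset()].
#' @param check validate invariants.
#' @return a `cn_callset`.
#' @export
read_cn_callset <- function(path, check = TRUE) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "##sample=")) stop("missing per-sample header in ", path)
  kv <- strsplit(strsplit(sub("^##", "", header), "\t")[[1]], "=", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                           stringsAsFactors = FALSE)
  cn_callset(
    sample = vals[["sample"]],
    purity = as.numeric(vals[["purity"]]),
    ploidy = as.numeric(vals[["ploidy"]]),
    segments = data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
                          total_cn = tab$copyNumber,
                          major_cn = tab$majorAlleleCopyNumber,
                          minor_cn = tab$minorAlleleCopyNumber,
                          stringsAsFactors = FALSE),
    check = check
  )
}

#' Curated artifact regions for the synthetic genome
#'
#' Telomeric and centromeric flanks of the miniature genome where focal
#' artifact peaks concentrate in tumor-only copy-number calls. Shipped as a
#' plain BED asset (synthetic; users substitute their own curated list for
#' real genomes).
#'
#' @return a `genomic_intervals` data.frame.
#' @export
cn_exclusion_regions <- function() {
  path <- system.file("extdata", "cn_exclusion_synthetic.bed",
                      package = "tosomatic", mustWork = TRUE)
  read_bed_intervals(path)
}

#' Post-process a tumor-only copy-number callset
#'
#' Applies, in order: (1) removal of every segment overlapping (by any base
#' pair) an artifact exclusion interval; (2) rounding of slightly negative
#' copy-number values (in (-0.5, 0)) to 0; (3) removal of segments carrying
#' any value below -0.5 (high read-depth noise, unreliable). A removal log
#' records each dropped segment with its reason and length.
#'
#' @param cs a `cn_callset`.
#' @param excl exclusion intervals (default the shipped synthetic asset).
#' @return list with `callset` (cleaned `cn_callset`), `log` (data.frame of
#'   removed segments with `reason` and `bp`), and `excluded_fraction`
#'   (removed bp / input bp).
#' @export
postprocess_tumor_only <- function(cs, excl = cn_exclusion_regions()) {
  seg <- cs$segments
  n <- nrow(seg)
  idx <- build_interval_index(excl)
  in_excl <- if (n > 0) overlaps_any(idx, seg$chrom, seg$start, seg$end) else logical(0)

  keep <- seg[!in_excl, , drop = FALSE]
  cols <- c("total_cn", "major_cn", "minor_cn")
  for (cl in cols) {
    slight <- keep[[cl]] > -0.5 & keep[[cl]] < 0
    keep[[cl]][slight] <- 0
  }
  large_neg <- rowSums(sapply(cols, function(cl) keep[[cl]] < -0.5)) > 0
  if (nrow(keep) == 0) large_neg <- logical(0)

  log <- rbind(
    data.frame(seg[in_excl, c("chrom", "start", "end"), drop = FALSE],
               reason = rep("artifact_region", sum(in_excl)),
               bp = seg$end[in_excl] - seg$start[in_excl]),
    data.frame(keep[large_neg, c("chrom", "start", "end"), drop = FALSE],
               reason = rep("largely_negative", sum(large_neg)),
               bp = keep$end[large_neg] - keep$start[large_neg])
  )
  rownames(log) <- NULL
  out_seg <- keep[!large_neg, , drop = FALSE]
  rownames(out_seg) <- NULL
  total_bp <- sum(seg$end - seg$start)
  list(
    callset = cn_callset(cs$sample, cs$purity, cs$ploidy, out_seg, check = FALSE),
    log = log,
    excluded_fraction = if (total_bp > 0) sum(log$bp) / total_bp else 0
  )
}

#' Length-weighted genome state fractions
#'
#' Assigns each segment a state from its rounded total copy number
#' (round < 2 deleted, = 2 diploid, > 2 amplified; "diploid" is the absolute
#' two-copy state, not relative to sample ploidy) and returns fractions
#' weighted by segment length over the total covered length.
#'
#' @param cs a post-processed `cn_callset`.
#' @return named numeric vector `c(deleted, diploid, amplified)`, summing
#'   to 1.
#' @export
genome_state_fractions <- function(cs) {
  seg <- cs$segments
  total <- sum(seg$end - seg$start)
  if (total <= 0) stop("zero total segment length")
  r <- round(seg$total_cn)
  len <- seg$end - seg$start
  c(deleted = sum(len[r < 2]) / total,
    diploid = sum(len[r == 2]) / total,
    amplified = sum(len[r > 2]) / total)
}

#' Per-gene major/minor copy number
#'
#' Each gene takes the major/minor copy number of the overlapping segment
#' with the largest overlap length (ties towards the lower total copy
#' number); genes overlapping no segment are reported absent (NA).
#'
#' @param cs a `cn_callset`.
#' @param genes `genomic_intervals` with a `name` column of gene ids.
#' @return data.frame (gene, major_cn, minor_cn) with NA for absent genes.
#' @export
gene_level_cn <- function(cs, genes) {
  seg <- cs$segments
  out <- data.frame(gene = genes$name,
                    major_cn = NA_real_, minor_cn = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(seg) == 0 || nrow(genes) == 0) return(out)
  idx <- build_interval_index(seg)
  hits <- query_overlaps(idx, genes$chrom, genes$start, genes$end)
  if (nrow(hits) == 0) return(out)
  ov_len <- pmin(genes$end[hits$query], seg$end[hits$hit]) -
    pmax(genes$start[hits$query], seg$start[hits$hit])
  for (g in unique(hits$query)) {
    ii <- which(hits$query == g)
    best <- ii[order(-ov_len[ii], seg$total_cn[hits$hit[ii]])][1]
    out$major_cn[g] <- seg$major_cn[hits$hit[best]]
    out$minor_cn[g] <- seg$minor_cn[hits$hit[best]]
  }
  out
}

#' Matched-vs-tumor-only concordance benchmark
#'
#' For each sample present in both lists, computes the six sample-level
#' metrics (purity, ploidy, segment count, diploid/amplified/deleted
#' fraction) from each callset and reports the paired vectors with their
#' Pearson correlation; gene-level major and minor copy numbers are pooled
#' over all (gene, sample) pairs present in both callsets.
#'
#' @param tumor_only list of `cn_callset` (tumor-only calls).
#' @param matched list of `cn_callset` (matched tumor/normal calls).
#' @param genes gene spans for the gene-level comparison (NULL to skip).
#' @return list of class `concordance_report`: `metrics` (named list of
#'   data.frames with columns `sample`, `tumor_only`, `matched`),
#'   `gene_level` (data.frames for major/minor), and `r` (named vector of
#'   Pearson correlations).
#' @export
compare_callsets <- function(tumor_only, matched, genes = NULL) {
  ids_t <- vapply(tumor_only, `[[`, "", "sample")
  ids_m <- vapply(matched, `[[`, "", "sample")
  unpaired <- c(setdiff(ids_t, ids_m), setdiff(ids_m, ids_t))
  if (length(unpaired) > 0) stop("unpaired sample: ", unpaired[1])
  names(tumor_only) <- ids_t
  names(matched) <- ids_m
  ids <- sort(ids_t)

  metric_fns <- list(
    purity = function(cs) cs$purity,
    ploidy = function(cs) cs$ploidy,
    n_segments = function(cs) nrow(cs$segments),
    diploid_fraction = function(cs) genome_state_fractions(cs)[["diploid"]],
    amplified_fraction = function(cs) genome_state_fractions(cs)[["amplified"]],
    deleted_fraction = function(cs) genome_state_fractions(cs)[["deleted"]]
  )
  metrics <- lapply(metric_fns, function(f) {
    data.frame(sample = ids,
               tumor_only = vapply(tumor_only[ids], f, numeric(1)),
               matched = vapply(matched[ids], f, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  # identical paired vectors are perfect concordance even when degenerate
  # (e.g. every sample at ploidy 2); otherwise a zero-variance vector has no
  # defined correlation and is reported NA
  safe_r <- function(x, y) {
    if (isTRUE(all.equal(x, y))) return(1)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    pearson_correlation(x, y)
  }
  r <- vapply(metrics, function(df) safe_r(df$tumor_only, df$matched),
              numeric(1))

  gene_level <- NULL
  if (!is.null(genes)) {
    maj <- min <- list()
    for (id in ids) {
      gt <- gene_level_cn(tumor_only[[id]], genes)
      gm <- gene_level_cn(matched[[id]], genes)
      ok <- !is.na(gt$major_cn) & !is.na(gm$major_cn)
      maj[[id]] <- data.frame(sample = id, gene = gt$gene[ok],
                              tumor_only = gt$major_cn[ok], matched = gm$major_cn[ok])
      min[[id]] <- data.frame(sample = id, gene = gt$gene[ok],
                              tumor_only = gt$minor_cn[ok], matched = gm$minor_cn[ok])
    }
    gene_level <- list(major_cn = do.call(rbind, maj), minor_cn = do.call(rbind, min))
    r <- c(r,
           gene_major_cn = safe_r(gene_level$major_cn$tumor_only,
                                  gene_level$major_cn$matched),
           gene_minor_cn = safe_r(gene_level$minor_cn$tumor_only,
                                  gene_level$minor_cn$matched))
  }
  structure(list(metrics = metrics, gene_level = gene_level, r = r),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> Pearson r:\n")
  for (nm in names(x$r)) cat(sprintf("  %-20s %.4f\n", nm, x$r[nm]))
  invisible(x)
}
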