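# The small-variant feature space: 20 features in three blocks ---
# external databases (4), genomic location/impact/signature context (6),
# and caller-derived metrics (10). The indel model drops the is_snv
# indicator and uses the remaining 19.

#' Feature names for the SNV classification model
#' @return character vector of the 20 SNV model features, in block order.
#' @export
snv_feature_names <- function() {
  c("popdb_present", "popdb_af", "cancerdb_present", "cancerdb_count",
    "region_class", "impact_class", "trinucleotide_context", "repeat_flag",
    "conserved_flag", "homopolymer_run",
    "allele_fraction", "total_depth", "alt_count", "median_base_quality",
    "median_mapping_quality", "strand_balance", "caller_confidence",
    "filter_pass", "multiallelic", "is_snv")
}

#' Feature names for the indel classification model (SNV indicator removed)
#' @return character vector of 19 features.
#' @export
indel_feature_names <- function() setdiff(snv_feature_names(), "is_snv")

#' Single-base-substitution channel index (96 channels)
#'
#' Maps a substitution and its reference trinucleotide context onto the
#' standard 96-channel mutational-signature grid: substitutions are
#' normalized to the pyrimidine strand (C>A, C>G, C>T, T>A, T>C, T>G, in
#' that order), each combined with the 16 flanking-base contexts. The index
#' is `substitution * 16 + left_base * 4 + right_base` with bases ordered
#' A, C, G, T, giving values 0-95.
#'
#' @param ref,alt single-base alleles (vectors).
#' @param context reference trinucleotide centred on the site (vector);
#'   `NA` or malformed contexts give sentinel -1.
#' @return integer vector in 0..95, or -1 where undefined (non-SNV rows,
#'   missing context).
#' @export
trinucleotide_index <- function(ref, alt, context) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  n <- length(ref)
  out <- rep(-1L, n)
  ok <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    !is.na(context) & nchar(context) == 3 &
    ref %in% bases & alt %in% bases
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- toupper(context[ok])
  left <- substr(ctx, 1, 1); right <- substr(ctx, 3, 3)
  purine <- r %in% c("A", "G")
  # pyrimidine-strand normalization: reverse-complement purine-reference rows
  r2 <- ifelse(purine, comp[r], r)
  a2 <- ifelse(purine, comp[a], a)
  l2 <- ifelse(purine, comp[right], left)
  rt2 <- ifelse(purine, comp[left], right)
  s_idx <- match(paste0(r2, ">", a2), subs) - 1L
  l_idx <- match(l2, bases) - 1L
  r_idx <- match(rt2, bases) - 1L
  valid <- !is.na(s_idx) & !is.na(l_idx) & !is.na(r_idx)
  res <- rep(-1L, sum(ok))
  res[valid] <- s_idx[valid] * 16L + l_idx[valid] * 4L + r_idx[valid]
  out[ok] <- res
  out
}

region_class_at <- function(rs, chrom, start, end) {
  # ordinal region class: CDS=3, UTR=2, intron=1, intergenic=0; a window
  # hitting several features takes the highest class
  cls_rank <- c(CDS = 3, UTR = 2, intron = 1)
  hits <- query_overlaps(rs$gene_features, chrom, start, end)
  out <- rep(0, length(chrom))
  if (nrow(hits) > 0) {
    v <- cls_rank[rs$gene_features$table$name[hits$hit]]
    v[is.na(v)] <- 0
    agg <- tapply(v, hits$query, max)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Label tumor-only calls against matched-normal somatic ground truth
#'
#' A tumor-only record is labeled somatic iff an exact (chrom, pos, ref, alt)
#' match exists in the somatic calls from the matched tumor/normal analysis
#' of the same sample; everything else is labeled germline. Matched somatic
#' calls absent from the tumor-only set are returned separately as recall
#' misses.
#'
#' @param tumor_only small-variant data.frame from tumor-only calling.
#' @param matched_somatic small-variant data.frame of matched somatic calls.
#' @return list with `labeled` (tumor-only records, `truth_label` filled) and
#'   `misses` (matched somatic records not seen in the tumor-only set).
#' @export
label_against_ground_truth <- function(tumor_only, matched_somatic) {
  tk <- site_key(tumor_only$chrom, tumor_only$pos, tumor_only$ref, tumor_only$alt)
  mk <- site_key(matched_somatic$chrom, matched_somatic$pos,
                 matched_somatic$ref, matched_somatic$alt)
  labeled <- tumor_only
  labeled$truth_label <- ifelse(tk %in% mk, "somatic", "germline")
  misses <- matched_somatic[!(mk %in% tk), , drop = FALSE]
  rownames(misses) <- NULL
  list(labeled = labeled, misses = misses)
}

#' Extract the small-variant feature matrix
#'
#' Builds the 20-feature vectors feeding the random forest: database block
#' by exact lookup against the population database and cancer catalogue;
#' location/impact/context block by interval queries at the variant position
#' and the 96-channel substitution context; caller block copied from the
#' caller-reported metrics (missing values stay at their -1 sentinel, which
#' tree models split on directly). Works on whole tables; a single variant
#' is a one-row table.
#'
#' @param variants small-variant data.frame (as returned by
#'   [read_small_variants()], optionally labeled).
#' @param rs a `resource_set`.
#' @return data.frame with the 20 feature columns plus `label`
#'   (`truth_label` carried through).
#' @export
extract_snv_features <- function(variants, rs) {
  v <- variants
  n <- nrow(v)
  qs <- v$pos - 1  # 1-based site -> 0-based half-open [pos-1, pos)
  qe <- v$pos
  af <- popdb_lookup(rs, v$chrom, v$pos, v$ref, v$alt)
  cnt <- cancerdb_lookup(rs, v$chrom, v$pos, v$ref, v$alt)
  region <- region_class_at(rs, v$chrom, qs, qe)
  is_snv <- as.numeric(v$vclass == "SNV")
  tri <- trinucleotide_index(v$ref, v$alt, v$context)
  tri[v$vclass != "SNV"] <- -1L
  n_missing_ctx <- sum(is_snv == 1 & tri == -1)
  if (n_missing_ctx > 0) {
    message(sprintf("trinucleotide context unavailable for %d SNV record(s); sentinel -1",
                    n_missing_ctx))
  }
  # impact proxy from region + variant class only (no external effect
  # predictor): frameshift-like indel in CDS > coding SNV > UTR > intron
  impact <- ifelse(region == 3 & is_snv == 0, 4,
                   ifelse(region == 3, 3, region))
  out <- data.frame(
    popdb_present = as.numeric(af >= 0),
    popdb_af = af,
    cancerdb_present = as.numeric(cnt > 0),
    cancerdb_count = cnt,
    region_class = region,
    impact_class = impact,
    trinucleotide_context = as.numeric(tri),
    repeat_flag = as.numeric(overlaps_any(rs$repeats, v$chrom, qs, qe)),
    conserved_flag = as.numeric(overlaps_any(rs$conserved, v$chrom, qs, qe)),
    homopolymer_run = v$homopolymer_run,
    allele_fraction = v$allele_fraction,
    total_depth = v$total_depth,
    alt_count = v$alt_count,
    median_base_quality = v$median_base_quality,
    median_mapping_quality = v$median_mapping_quality,
    strand_balance = v$strand_balance,
    caller_confidence = v$caller_confidence,
    filter_pass = as.numeric(v$filter_pass),
    multiallelic = as.numeric(v$multiallelic),
    is_snv = is_snv,
    stringsAsFactors = FALSE
  )
  out$label <- if (!is.null(v$truth_label)) v$truth_label else "unknown"
  stopifnot(identical(setdiff(names(out), "label"), snv_feature_names()))
  out
}
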