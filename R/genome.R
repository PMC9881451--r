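#' Miniature genome model used by the synthetic cohort
#'
#' A desk-scale genome (three 50 Mbp autosomes, a 30 Mbp X and a 10 Mbp Y)
#' small enough that brute-force oracles over every base pair or every pair
#' of records run in seconds, while keeping the chromosome structure
#' (autosomes vs. sex chromosomes, telomeric/centromeric ends) that the
#' copy-number and sex-validation logic depends on.
#'
#' @return A data.frame with columns `chrom` and `length` (bp).
#' @export
synthetic_genome <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
    length = c(50e6, 50e6, 50e6, 30e6, 10e6),
    stringsAsFactors = FALSE
  )
}

#' Canonical chromosome ordering
#'
#' Natural order chr1..chr22, chrX, chrY; unknown contigs after, in
#' lexicographic order. Used to normalize breakpoint pairs so that a
#' structural variant is always stored with its lower breakpoint first,
#' giving deterministic pair orientation regardless of caller conventions.
#'
#' @param chrom character vector of chromosome names.
#' @return integer rank vector (lower = earlier).
#' @export
chrom_rank <- function(chrom) {
  canonical <- c(paste0("chr", 1:22), "chrX", "chrY")
  r <- match(chrom, canonical)
  unknown <- is.na(r)
  if (any(unknown)) {
    extra <- sort(unique(chrom[unknown]))
    r[unknown] <- length(canonical) + match(chrom[unknown], extra)
  }
  r
}

#' Compare two genomic positions under the canonical chromosome order
#'
#' @param chrom1,pos1,chrom2,pos2 vectors describing two positions.
#' @return logical: TRUE where (chrom1, pos1) <= (chrom2, pos2).
#' @keywords internal
position_leq <- function(chrom1, pos1, chrom2, pos2) {
  r1 <- chrom_rank(chrom1)
  r2 <- chrom_rank(chrom2)
  r1 < r2 | (r1 == r2 & pos1 <= pos2)
}
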