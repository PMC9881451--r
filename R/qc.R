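# Cross-omic cohort validation: sex prediction from genome coverage,
# expression sums and methylation intensity, reconciled against clinical
# annotation (with somatic Y-loss detection), and purity-estimate
# concordance across pathologic, genomic and transcriptomic sources.

#' Pearson product-moment correlation
#'
#' Shared by the copy-number benchmark and the purity concordance analysis.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in correlation input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Sex from methylation array intensity
#'
#' Calls female iff the difference of log2 median total intensities
#' (Y minus X) falls below the cutoff (default -2); the boundary value
#' itself is classed male (strict inequality).
#'
#' @param meth_x_median,meth_y_median log2 median total intensity on X / Y.
#' @param cutoff difference threshold (default -2).
#' @return character vector in {M, F, ambiguous} (ambiguous where a median
#'   is missing).
#' @export
sex_from_methylation <- function(meth_x_median, meth_y_median, cutoff = -2) {
  d <- meth_y_median - meth_x_median
  ifelse(is.na(d), "ambiguous", ifelse(d < cutoff, "F", "M"))
}

#' Sex from normalized sex-chromosome coverage
#'
#' Coverage is the mean depth on each sex chromosome divided by the mean
#' autosomal depth, making the call invariant to sequencing depth. XY
#' samples sit near 0.5 normalized Y coverage, XX near 0; the band between
#' the thresholds (default 0.10-0.25) is called ambiguous and flags a
#' somatic Y-loss candidate.
#'
#' @param x_coverage,y_coverage normalized mean coverages.
#' @param male_min Y coverage at or above which the call is M.
#' @param female_max Y coverage below which the call is F.
#' @return character vector in {M, F, ambiguous}.
#' @export
sex_from_coverage <- function(x_coverage, y_coverage,
                              male_min = 0.25, female_max = 0.10) {
  ifelse(is.na(y_coverage), "ambiguous",
         ifelse(y_coverage >= male_min, "M",
                ifelse(y_coverage < female_max, "F", "ambiguous")))
}

#' Sex from Y-chromosome expression sums
#'
#' One-dimensional two-class split of the per-sample sums of
#' variance-stabilized counts over Y-chromosome genes: a deterministic
#' two-means step (centers initialized at the data extremes) yields class
#' means whose midpoint is the decision boundary. With fewer than two
#' distinct values no split exists and all calls are ambiguous.
#'
#' @param y_expression numeric vector over the cohort.
#' @param min_separation minimal distance between the two class means (vst
#'   units) for the split to be trusted; below it (e.g. a single-sex cohort)
#'   every call is ambiguous.
#' @return character vector in {M, F, ambiguous}, aligned with the input.
#' @export
sex_from_expression <- function(y_expression, min_separation = 3) {
  ok <- !is.na(y_expression)
  out <- rep("ambiguous", length(y_expression))
  v <- y_expression[ok]
  if (length(unique(v)) < 2) return(out)
  km <- stats::kmeans(v, centers = matrix(range(v), ncol = 1))
  if (abs(diff(as.numeric(km$centers))) < min_separation) return(out)
  midpoint <- mean(km$centers)
  out[ok] <- ifelse(v > midpoint, "M", "F")
  out
}

#' Reconcile per-modality sex calls into a consensus
#'
#' Consensus is the majority over the available modality calls (ambiguous
#' calls excluded); the discordance flag compares consensus against the
#' clinical annotation when known. A coverage call in the ambiguous Y-loss
#' band combined with male evidence from the other modalities (or male
#' clinical sex) marks the sample as a suspected somatic Y-loss tumor.
#'
#' @param evidence data.frame with one row per sample and columns `sample`,
#'   `clinical_sex` ({M, F, unknown}), `x_coverage`, `y_coverage`,
#'   `x_expression`, `y_expression`, `meth_x_median`, `meth_y_median`
#'   (modalities may be NA).
#' @return data.frame with per-modality calls, `consensus`,
#'   `discordance_flag` (NA when clinical sex unknown) and
#'   `y_loss_suspected`.
#' @export
reconcile_sex <- function(evidence) {
  cov_call <- sex_from_coverage(evidence$x_coverage, evidence$y_coverage)
  expr_call <- sex_from_expression(evidence$y_expression)
  meth_call <- sex_from_methylation(evidence$meth_x_median, evidence$meth_y_median)
  calls <- cbind(cov_call, expr_call, meth_call)
  consensus <- apply(calls, 1, function(row) {
    row <- row[row != "ambiguous"]
    if (length(row) == 0) return("ambiguous")
    n_m <- sum(row == "M")
    if (n_m * 2 == length(row)) return("ambiguous")
    if (n_m * 2 > length(row)) "M" else "F"
  })
  clinical <- evidence$clinical_sex
  known <- !is.na(clinical) & clinical %in% c("M", "F")
  discordance <- ifelse(known & consensus != "ambiguous",
                        consensus != clinical, NA)
  other_male <- (expr_call == "M") | (meth_call == "M") |
    (known & clinical == "M")
  y_loss <- cov_call == "ambiguous" & !is.na(evidence$y_coverage) & other_male
  data.frame(sample = evidence$sample,
             coverage_call = cov_call, expression_call = expr_call,
             methylation_call = meth_call, consensus = consensus,
             clinical_sex = clinical, discordance_flag = discordance,
             y_loss_suspected = y_loss,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concordance of purity estimates across three sources
#'
#' Pairwise Pearson correlations between pathologic, genomic and
#' transcriptomic purity estimates with two-sided tests and
#' Benjamini-Hochberg adjustment over the three comparisons. Samples
#' missing one of a pair's estimates (e.g. no genomic estimate because no
#' somatic copy-number variants were found) are excluded pairwise.
#'
#' @param pathologic,genomic,transcriptomic equal-length per-sample purity
#'   vectors (NA = missing).
#' @return data.frame with one row per pair: `pair`, `n`, `r`, `p`, `q`.
#' @export
purity_concordance <- function(pathologic, genomic, transcriptomic) {
  stopifnot(length(pathologic) == length(genomic),
            length(genomic) == length(transcriptomic))
  pairs <- list(
    pathologic_vs_genomic = list(pathologic, genomic),
    pathologic_vs_transcriptomic = list(pathologic, transcriptomic),
    genomic_vs_transcriptomic = list(genomic, transcriptomic)
  )
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]][[1]]; b <- pairs[[nm]][[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ", nm)
    ct <- stats::cor.test(a[ok], b[ok], method = "pearson",
                          alternative = "two.sided")
    data.frame(pair = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
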