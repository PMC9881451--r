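#' @importFrom stats rbeta rbinom rnorm rpois runif setNames complete.cases
NULL

# Extract a scalar INFO key from vectorized INFO strings; NA where absent.
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
}

info_flag <- function(info, key) {
  grepl(paste0("(?:^|;)", key, "(?:;|$)"), info)
}

# Numeric with sentinel -1 for absent values; warns once with a count.
info_numeric_sentinel <- function(info, key, what = key) {
  raw <- info_field(info, key)
  out <- suppressWarnings(as.numeric(raw))
  n_missing <- sum(is.na(out))
  if (n_missing > 0) {
    warning(sprintf("%d record(s) missing %s; sentinel -1 recorded", n_missing, what),
            call. = FALSE)
    out[is.na(out)] <- -1
  }
  out
}

variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

empty_small_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), vclass = character(0),
             allele_fraction = numeric(0), total_depth = numeric(0),
             alt_count = numeric(0), median_base_quality = numeric(0),
             median_mapping_quality = numeric(0), strand_balance = numeric(0),
             caller_confidence = numeric(0), filter_pass = logical(0),
             multiallelic = logical(0), context = character(0),
             homopolymer_run = numeric(0), truth_label = character(0),
             stringsAsFactors = FALSE)
}

vcf_body_count <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    lines <- readLines(con, n = 10000L)
    if (length(lines) == 0) break
    n <- n + sum(!startsWith(lines, "#"))
  }
  n
}

#' Read small-variant calls from a VCF file
#'
#' Understands the annotation layout emitted by tumor-only point-mutation
#' callers of the Mutect2 family (FORMAT `AF`/`AD`/`DP`; INFO `TLOD`, `MBQ`,
#' `MMQ` and, when present, the package's own `SB`, `TNC`, `HRUN` keys).
#' Multi-allelic rows are split into one record per alternate allele and
#' flagged `multiallelic`. Records come back sorted by (chromosome, position)
#' under the canonical chromosome order.
#'
#' A missing annotation key yields a per-file warning and sentinel value -1
#' in the affected records (imputation is the classifier's job); a malformed
#' mandatory field aborts with the offending row number.
#'
#' @param path VCF 4.2 file.
#' @param dialect caller dialect; `"mutect2"` (default) and the synonymous
#'   `"generic"` are supported.
#' @return data.frame of small-variant records (one row per variant/allele).
#' @export
read_small_variants <- function(path, dialect = c("mutect2", "generic")) {
  dialect <- match.arg(dialect)
  if (vcf_body_count(path) == 0) return(empty_small_variants())
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | is.na(fix$REF) | is.na(fix$ALT) | fix$ALT == "")
  if (length(bad) > 0) {
    stop(sprintf("malformed VCF record at data row %d of %s", bad[1], path))
  }

  gt <- vcf@gt
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  smp <- strsplit(gt[, 2], ":", fixed = TRUE)
  fmt_get <- function(key) {
    mapply(function(f, s) {
      j <- match(key, f)
      if (is.na(j) || j > length(s)) NA_character_ else s[j]
    }, fmt, smp, USE.NAMES = FALSE)
  }

  n <- nrow(fix)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_of <- rep(seq_len(n), n_alt)        # expansion index: one row per allele

  info <- fix$INFO
  mbq <- info_numeric_sentinel(info, "MBQ", "median base quality (MBQ)")
  mmq <- info_numeric_sentinel(info, "MMQ", "median mapping quality (MMQ)")
  sb <- info_numeric_sentinel(info, "SB", "strand balance (SB)")
  tnc <- info_field(info, "TNC")
  hrun <- suppressWarnings(as.numeric(info_field(info, "HRUN")))
  hrun[is.na(hrun)] <- -1

  # per-allele numeric lists: pad/NA-fill to n_alt slots, then unlist
  per_allele <- function(raw) {
    parts <- strsplit(ifelse(is.na(raw), "", raw), ",", fixed = TRUE)
    vals <- lapply(seq_len(n), function(i) {
      v <- suppressWarnings(as.numeric(parts[[i]]))
      if (length(v) == 0) v <- NA_real_
      rep_len(v, n_alt[i])
    })
    unlist(vals)
  }
  warn_sentinel <- function(x, key) {
    miss <- is.na(x)
    if (any(miss)) {
      warning(sprintf("%d record(s) missing %s; sentinel -1 recorded",
                      sum(miss), key), call. = FALSE)
      x[miss] <- -1
    }
    x
  }

  dp <- suppressWarnings(as.numeric(fmt_get("DP")))
  dp <- warn_sentinel(dp, "DP")
  ad_raw <- fmt_get("AD")
  ad_parts <- strsplit(ifelse(is.na(ad_raw), "", ad_raw), ",", fixed = TRUE)
  alt_count <- unlist(lapply(seq_len(n), function(i) {
    v <- suppressWarnings(as.numeric(ad_parts[[i]]))
    if (length(v) >= n_alt[i] + 1) v[1 + seq_len(n_alt[i])] else rep(NA_real_, n_alt[i])
  }))
  alt_count <- warn_sentinel(alt_count, "AD")
  afv <- per_allele(fmt_get("AF"))
  derivable <- is.na(afv) & alt_count >= 0 & dp[row_of] > 0
  afv[derivable] <- alt_count[derivable] / dp[row_of][derivable]
  afv <- warn_sentinel(afv, "AF")
  tlod <- warn_sentinel(per_allele(info_field(info, "TLOD")), "TLOD")

  out <- data.frame(
    chrom = fix$CHROM[row_of], pos = pos[row_of], ref = fix$REF[row_of],
    alt = unlist(alts),
    allele_fraction = afv, total_depth = dp[row_of], alt_count = alt_count,
    median_base_quality = mbq[row_of], median_mapping_quality = mmq[row_of],
    strand_balance = sb[row_of], caller_confidence = tlod,
    filter_pass = (fix$FILTER == "PASS")[row_of],
    multiallelic = (n_alt > 1)[row_of],
    context = ifelse(is.na(tnc), NA_character_, tnc)[row_of],
    homopolymer_run = hrun[row_of],
    stringsAsFactors = FALSE
  )
  out$vclass <- variant_class(out$ref, out$alt)
  out$truth_label <- "unknown"
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out[, names(empty_small_variants())]
}

small_variant_header <- function(genome, extra_info = character(0)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
    "##INFO=<ID=TLOD,Number=A,Type=Float,Description=\"Log odds of variant existing\">",
    "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Median base quality\">",
    "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Median mapping quality\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand balance of alt reads\">",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Reference trinucleotide context\">",
    "##INFO=<ID=HRUN,Number=1,Type=Integer,Description=\"Homopolymer run length at site\">",
    extra_info,
    "##FILTER=<ID=germline,Description=\"Classified germline\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR")
}

fmt_num <- function(x, digits = 6) {
  out <- formatC(x, format = "fg", digits = digits, flag = "#")
  out <- sub("\\.$", "", sub("0+$", "", out))
  out[x == round(x)] <- format(round(x[x == round(x)]), scientific = FALSE, trim = TRUE)
  out
}

# Assemble VCF body lines from a small-variant table; rows sharing
# (chrom, pos, ref) collapse into one multi-allelic row. Single-allele rows
# (the vast majority) are formatted vectorized.
small_variant_body <- function(v, extra_info_fun = NULL, filter_fun = NULL) {
  if (nrow(v) == 0) return(character(0))
  v <- v[order(chrom_rank(v$chrom), v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  key <- paste(v$chrom, v$pos, v$ref, sep = "\r")
  grp <- match(key, unique(key))
  gsize <- tabulate(grp)[grp]

  line_for <- function(ii) {
    first <- ii[1]
    k <- length(ii)
    dp <- as.integer(round(v$total_depth[first]))
    ad <- c(max(dp - as.integer(round(sum(v$alt_count[ii]))), 0),
            as.integer(round(v$alt_count[ii])))
    af <- paste(sprintf("%.6f", v$allele_fraction[ii]), collapse = ",")
    gt <- if (k > 1) "1/2" else if (v$allele_fraction[first] > 0.9) "1/1" else "0/1"
    info <- sprintf("TLOD=%s;MBQ=%s;MMQ=%s;SB=%s;TNC=%s;HRUN=%d",
                    paste(sprintf("%.3f", v$caller_confidence[ii]), collapse = ","),
                    sprintf("%.2f", v$median_base_quality[first]),
                    sprintf("%.2f", v$median_mapping_quality[first]),
                    sprintf("%.4f", v$strand_balance[first]),
                    if (is.na(v$context[first])) "." else v$context[first],
                    as.integer(round(v$homopolymer_run[first])))
    if (!is.null(extra_info_fun)) info <- paste0(info, ";", extra_info_fun(ii))
    filt <- if (!is.null(filter_fun)) filter_fun(ii) else {
      if (v$filter_pass[first]) "PASS" else "weak_evidence"
    }
    paste(v$chrom[first], v$pos[first], ".", v$ref[first],
          paste(v$alt[ii], collapse = ","), ".", filt, info,
          "GT:AD:DP:AF", paste(gt, paste(ad, collapse = ","), dp, af, sep = ":"),
          sep = "\t")
  }

  lines <- character(max(grp))
  single <- gsize == 1
  if (any(single)) {
    s <- which(single)
    dp <- as.integer(round(v$total_depth[s]))
    ac <- as.integer(round(v$alt_count[s]))
    info <- sprintf("TLOD=%s;MBQ=%s;MMQ=%s;SB=%s;TNC=%s;HRUN=%d",
                    sprintf("%.3f", v$caller_confidence[s]),
                    sprintf("%.2f", v$median_base_quality[s]),
                    sprintf("%.2f", v$median_mapping_quality[s]),
                    sprintf("%.4f", v$strand_balance[s]),
                    ifelse(is.na(v$context[s]), ".", v$context[s]),
                    as.integer(round(v$homopolymer_run[s])))
    if (!is.null(extra_info_fun)) {
      info <- paste0(info, ";",
                     vapply(s, function(i) extra_info_fun(i), character(1)))
    }
    filt <- if (!is.null(filter_fun)) {
      vapply(s, function(i) filter_fun(i), character(1))
    } else ifelse(v$filter_pass[s], "PASS", "weak_evidence")
    gt <- ifelse(v$allele_fraction[s] > 0.9, "1/1", "0/1")
    lines[grp[s]] <- paste(v$chrom[s], v$pos[s], ".", v$ref[s], v$alt[s], ".",
                           filt, info, "GT:AD:DP:AF",
                           paste(gt, paste(pmax(dp - ac, 0), ac, sep = ","),
                                 dp, sprintf("%.6f", v$allele_fraction[s]),
                                 sep = ":"),
                           sep = "\t")
  }
  if (any(!single)) {
    for (ii in split(which(!single), grp[!single])) {
      lines[grp[ii[1]]] <- line_for(ii)
    }
  }
  lines
}

#' Write small-variant records to a VCF file
#'
#' Inverse of [read_small_variants()]: rows sharing (chrom, pos, ref) are
#' collapsed back into multi-allelic VCF rows. Used by the synthetic cohort
#' generator and by round-trip tests.
#'
#' @param variants small-variant data.frame.
#' @param path output path.
#' @param genome genome table for the contig header lines.
#' @return `path`, invisibly.
#' @export
write_small_variants <- function(variants, path, genome = synthetic_genome()) {
  lines <- c(small_variant_header(genome), small_variant_body(variants))
  writeLines(lines, path)
  invisible(path)
}

#' Write classified variants with somatic probabilities to VCF
#'
#' Adds INFO keys `SOMATIC_PROB` (random-forest somatic probability, 6
#' decimals) and `RF_CLASS` (`somatic`/`germline` at threshold 0.5), and sets
#' FILTER to `PASS` for the somatic class (`germline` otherwise).
#'
#' @param variants small-variant data.frame.
#' @param probabilities numeric vector of somatic probabilities, one per row.
#' @param path output path.
#' @param threshold probability cutoff for the somatic call.
#' @param genome genome table for contig header lines.
#' @return `path`, invisibly.
#' @export
write_classified_variants <- function(variants, probabilities, path,
                                      threshold = 0.5,
                                      genome = synthetic_genome()) {
  stopifnot(nrow(variants) == length(probabilities))
  extra <- c(
    "##INFO=<ID=SOMATIC_PROB,Number=A,Type=Float,Description=\"RF somatic probability\">",
    "##INFO=<ID=RF_CLASS,Number=A,Type=String,Description=\"RF class at threshold 0.5\">")
  v <- variants
  v$.prob <- probabilities
  # pre-sort with the body writer's ordering so closure indices line up
  v <- v[order(chrom_rank(v$chrom), v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  body <- small_variant_body(
    v,
    extra_info_fun = function(ii) {
      sprintf("SOMATIC_PROB=%s;RF_CLASS=%s",
              paste(sprintf("%.6f", v$.prob[ii]), collapse = ","),
              paste(ifelse(v$.prob[ii] >= threshold, "somatic", "germline"),
                    collapse = ","))
    },
    filter_fun = function(ii) {
      if (any(v$.prob[ii] >= threshold)) "PASS" else "germline"
    })
  writeLines(c(small_variant_header(genome, extra), body), path)
  invisible(path)
}

#' Read back a classified VCF, including probabilities
#'
#' @param path VCF written by [write_classified_variants()].
#' @return small-variant data.frame with extra columns `somatic_prob` and
#'   `rf_class`.
#' @export
read_classified_variants <- function(path) {
  out <- read_small_variants(path)
  if (nrow(out) == 0) {
    out$somatic_prob <- numeric(0)
    out$rf_class <- character(0)
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  probs <- strsplit(info_field(fix$INFO, "SOMATIC_PROB"), ",", fixed = TRUE)
  cls <- strsplit(info_field(fix$INFO, "RF_CLASS"), ",", fixed = TRUE)
  long <- data.frame(
    chrom = rep(fix$CHROM, lengths(alts)),
    pos = rep(as.integer(fix$POS), lengths(alts)),
    ref = rep(fix$REF, lengths(alts)),
    alt = unlist(alts),
    somatic_prob = as.numeric(unlist(probs)),
    rf_class = unlist(cls),
    stringsAsFactors = FALSE
  )
  m <- match(paste(out$chrom, out$pos, out$ref, out$alt),
             paste(long$chrom, long$pos, long$ref, long$alt))
  out$somatic_prob <- long$somatic_prob[m]
  out$rf_class <- long$rf_class[m]
  out
}
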