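# Structural variants are represented as oriented breakpoint pairs:
# orient "+" means the retained segment extends to the left of the breakpoint
# (the junction uses the 3' side), "-" that it extends to the right (5' side).
# Canonical intra-chromosomal orientation pairs: DEL (+,-), DUP (-,+),
# INV (+,+)/(-,-); translocations (TRA) take any combination.

empty_sv_calls <- function() {
  data.frame(chrom1 = character(0), pos1 = integer(0), orient1 = character(0),
             chrom2 = character(0), pos2 = integer(0), orient2 = character(0),
             svtype = character(0), length = numeric(0),
             allele_fraction = numeric(0), read_depth = numeric(0),
             split_reads = numeric(0), discordant_pairs = numeric(0),
             caller_quality = numeric(0), imprecise = logical(0),
             caller_id = character(0), truth_label = character(0),
             stringsAsFactors = FALSE)
}

#' Normalize breakpoint pairs to the canonical ordering
#'
#' Ensures (chrom1, pos1) <= (chrom2, pos2) under the canonical chromosome
#' order, swapping ends (and their orientations) where needed, and recomputes
#' `length` (= pos2 - pos1 within a chromosome, sentinel -1 across
#' chromosomes; insertions keep their inserted-sequence length).
#'
#' @param svs SV breakpoint-pair data.frame.
#' @return the normalized data.frame.
#' @export
normalize_breakpoints <- function(svs) {
  if (nrow(svs) == 0) return(svs)
  swap <- !position_leq(svs$chrom1, svs$pos1, svs$chrom2, svs$pos2)
  if (any(swap)) {
    tmp <- svs[swap, c("chrom1", "pos1", "orient1")]
    svs[swap, c("chrom1", "pos1", "orient1")] <-
      svs[swap, c("chrom2", "pos2", "orient2")]
    svs[swap, c("chrom2", "pos2", "orient2")] <- tmp
  }
  intra <- svs$chrom1 == svs$chrom2
  keep_len <- svs$svtype == "INS"   # inserted-sequence length, not a span
  svs$length[intra & !keep_len] <- svs$pos2[intra & !keep_len] - svs$pos1[intra & !keep_len]
  svs$length[!intra] <- -1
  svs$svtype[!intra] <- "TRA"
  svs
}

orient_pair_to_type <- function(o1, o2) {
  ifelse(o1 == "+" & o2 == "-", "DEL",
         ifelse(o1 == "-" & o2 == "+", "DUP", "INV"))
}

type_to_orients <- function(svtype) {
  o1 <- ifelse(svtype == "DUP", "-", "+")
  o2 <- ifelse(svtype == "DUP" | svtype == "INV", "+", "-")
  cbind(o1, o2)
}

bnd_alt <- function(ref, o_self, mate_chrom, mate_pos, o_mate) {
  b <- ifelse(o_mate == "-", "[", "]")
  m <- paste0(b, mate_chrom, ":", mate_pos, b)
  ifelse(o_self == "+", paste0(ref, m), paste0(m, ref))
}

parse_bnd_alt <- function(alt) {
  fwd_pat <- "^([A-Za-z]+)([\\[\\]])([^:\\[\\]]+):([0-9]+)[\\[\\]]$"
  rev_pat <- "^([\\[\\]])([^:\\[\\]]+):([0-9]+)[\\[\\]]([A-Za-z]+)$"
  out <- data.frame(o_self = rep(NA_character_, length(alt)),
                    o_mate = NA_character_,
                    mate_chrom = NA_character_, mate_pos = NA_integer_,
                    stringsAsFactors = FALSE)
  fwd <- regmatches(alt, regexec(fwd_pat, alt, perl = TRUE))
  rev <- regmatches(alt, regexec(rev_pat, alt, perl = TRUE))
  for (i in seq_along(alt)) {
    mf <- fwd[[i]]
    if (length(mf) == 5) {
      out$o_self[i] <- "+"
      out$o_mate[i] <- if (mf[3] == "[") "-" else "+"
      out$mate_chrom[i] <- mf[4]
      out$mate_pos[i] <- as.integer(mf[5])
      next
    }
    mr <- rev[[i]]
    if (length(mr) == 5) {
      out$o_self[i] <- "-"
      out$o_mate[i] <- if (mr[2] == "]") "+" else "-"
      out$mate_chrom[i] <- mr[3]
      out$mate_pos[i] <- as.integer(mr[4])
    }
  }
  out
}

sv_header <- function(genome, caller_id) {
  c("##fileformat=VCFv4.2",
    sprintf("##source=%s", caller_id),
    sprintf("##contig=<ID=%s,length=%d>", genome$chrom, as.integer(genome$length)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Second chromosome\">",
    "##INFO=<ID=CT,Number=1,Type=String,Description=\"Connection type\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Supporting read depth\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Discordant pairs\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

sv_metric_info <- function(svs, i) {
  paste0(sprintf("AF=%.4f;DP=%d;SR=%d;PE=%d",
                 svs$allele_fraction[i], as.integer(round(svs$read_depth[i])),
                 as.integer(round(svs$split_reads[i])),
                 as.integer(round(svs$discordant_pairs[i]))),
         ifelse(svs$imprecise[i], ";IMPRECISE", ""))
}

#' Write SV calls in one of the supported caller dialects
#'
#' Three dialects mirror the encodings seen across SV callers:
#' `"bnd_pairs"` writes every event as two mated BND records with bracket
#' notation; `"symbolic_end"` uses symbolic ALT alleles (`<DEL>`, ...) with
#' INFO `END`/`SVLEN` and falls back to BND mates for translocations;
#' `"symbolic_chr2"` uses symbolic ALTs (including `<TRA>`) with INFO
#' `CHR2`/`END` and a `CT` connection-type key encoding orientations
#' (`+` = 3', `-` = 5', e.g. `3to5`).
#'
#' @param svs SV breakpoint-pair data.frame.
#' @param path output path.
#' @param dialect one of `"bnd_pairs"`, `"symbolic_end"`, `"symbolic_chr2"`.
#' @param genome genome table for contig header lines.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(svs, path,
                           dialect = c("bnd_pairs", "symbolic_end", "symbolic_chr2"),
                           genome = synthetic_genome()) {
  dialect <- match.arg(dialect)
  caller <- if (nrow(svs) > 0 && !is.null(svs$caller_id)) svs$caller_id[1] else dialect
  lines <- sv_header(genome, caller)
  if (nrow(svs) > 0) {
    svs <- normalize_breakpoints(svs)
    body <- character(0)
    for (i in seq_len(nrow(svs))) {
      id <- sprintf("sv%05d", i)
      qual <- sprintf("%.1f", svs$caller_quality[i])
      metr <- sv_metric_info(svs, i)
      as_bnd <- dialect == "bnd_pairs" ||
        (dialect == "symbolic_end" && svs$svtype[i] == "TRA")
      if (as_bnd) {
        a1 <- bnd_alt("N", svs$orient1[i], svs$chrom2[i], svs$pos2[i], svs$orient2[i])
        a2 <- bnd_alt("N", svs$orient2[i], svs$chrom1[i], svs$pos1[i], svs$orient1[i])
        body <- c(body,
          paste(svs$chrom1[i], svs$pos1[i], paste0(id, "_1"), "N", a1, qual, "PASS",
                sprintf("SVTYPE=BND;MATEID=%s_2;%s", id, metr), sep = "\t"),
          paste(svs$chrom2[i], svs$pos2[i], paste0(id, "_2"), "N", a2, qual, "PASS",
                sprintf("SVTYPE=BND;MATEID=%s_1;%s", id, metr), sep = "\t"))
      } else if (dialect == "symbolic_end") {
        svlen <- if (svs$svtype[i] == "DEL") -svs$length[i] else svs$length[i]
        body <- c(body,
          paste(svs$chrom1[i], svs$pos1[i], id, "N",
                paste0("<", svs$svtype[i], ">"), qual, "PASS",
                sprintf("SVTYPE=%s;END=%d;SVLEN=%d;%s", svs$svtype[i],
                        as.integer(svs$pos2[i]), as.integer(svlen), metr),
                sep = "\t"))
      } else {
        ct <- paste0(ifelse(svs$orient1[i] == "+", "3", "5"), "to",
                     ifelse(svs$orient2[i] == "+", "3", "5"))
        body <- c(body,
          paste(svs$chrom1[i], svs$pos1[i], id, "N",
                paste0("<", svs$svtype[i], ">"), qual, "PASS",
                sprintf("SVTYPE=%s;CHR2=%s;END=%d;CT=%s;%s", svs$svtype[i],
                        svs$chrom2[i], as.integer(svs$pos2[i]), ct, metr),
                sep = "\t"))
      }
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SV calls from a caller VCF, joining BND mates into breakpoint pairs
#'
#' BND mate records are joined via `MATEID` into one oriented breakpoint
#' pair (orientations from bracket notation); symbolic records are expanded
#' from `END`/`CHR2`. Breakpoints are normalized to the canonical ordering.
#' Unpaired BND mates are dropped with a warning; the count of drops is
#' attached as attribute `n_dropped`.
#'
#' @inheritParams write_sv_calls
#' @param path caller VCF.
#' @param caller_id label stored in the `caller_id` column.
#' @return SV breakpoint-pair data.frame (attribute `n_dropped`).
#' @export
read_sv_calls <- function(path,
                          dialect = c("bnd_pairs", "symbolic_end", "symbolic_chr2"),
                          caller_id = "callerA") {
  dialect <- match.arg(dialect)
  if (vcf_body_count(path) == 0) {
    out <- empty_sv_calls()
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  info <- fix$INFO
  base <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), id = fix$ID, alt = fix$ALT,
    svtype = info_field(info, "SVTYPE"),
    mateid = info_field(info, "MATEID"),
    end = suppressWarnings(as.integer(info_field(info, "END"))),
    chr2 = info_field(info, "CHR2"),
    ct = info_field(info, "CT"),
    svlen = suppressWarnings(as.numeric(info_field(info, "SVLEN"))),
    allele_fraction = suppressWarnings(as.numeric(info_field(info, "AF"))),
    read_depth = suppressWarnings(as.numeric(info_field(info, "DP"))),
    split_reads = suppressWarnings(as.numeric(info_field(info, "SR"))),
    discordant_pairs = suppressWarnings(as.numeric(info_field(info, "PE"))),
    caller_quality = suppressWarnings(as.numeric(fix$QUAL)),
    imprecise = info_flag(info, "IMPRECISE"),
    stringsAsFactors = FALSE
  )

  is_bnd <- !is.na(base$svtype) & base$svtype == "BND"
  out <- list()
  n_dropped <- 0L

  if (any(is_bnd)) {
    b <- base[is_bnd, , drop = FALSE]
    parsed <- parse_bnd_alt(b$alt)
    mate_row <- match(b$mateid, b$id)
    unpaired <- is.na(mate_row)
    if (any(unpaired)) {
      n_dropped <- n_dropped + sum(unpaired)
      warning(sprintf("%d unpaired BND mate record(s) dropped in %s",
                      sum(unpaired), path), call. = FALSE)
    }
    keep <- which(!unpaired)
    # keep each mate pair once: the record whose id sorts first
    keep <- keep[b$id[keep] < b$id[mate_row[keep]]]
    if (length(keep) > 0) {
      j <- mate_row[keep]
      pairs <- data.frame(
        chrom1 = b$chrom[keep], pos1 = b$pos[keep], orient1 = parsed$o_self[keep],
        chrom2 = b$chrom[j], pos2 = b$pos[j], orient2 = parsed$o_self[j],
        svtype = NA_character_, length = NA_real_,
        allele_fraction = b$allele_fraction[keep], read_depth = b$read_depth[keep],
        split_reads = b$split_reads[keep], discordant_pairs = b$discordant_pairs[keep],
        caller_quality = b$caller_quality[keep], imprecise = b$imprecise[keep],
        stringsAsFactors = FALSE
      )
      intra <- pairs$chrom1 == pairs$chrom2
      pairs$svtype[!intra] <- "TRA"
      pairs$svtype[intra] <- orient_pair_to_type(pairs$orient1[intra], pairs$orient2[intra])
      out <- c(out, list(pairs))
    }
  }

  if (any(!is_bnd)) {
    s <- base[!is_bnd, , drop = FALSE]
    chrom2 <- ifelse(!is.na(s$chr2), s$chr2, s$chrom)
    pos2 <- s$end
    o <- type_to_orients(s$svtype)
    orient1 <- o[, 1]; orient2 <- o[, 2]
    if (dialect == "symbolic_chr2" && any(!is.na(s$ct))) {
      has_ct <- !is.na(s$ct)
      parts <- strsplit(s$ct[has_ct], "to", fixed = TRUE)
      orient1[has_ct] <- ifelse(vapply(parts, `[`, "", 1) == "3", "+", "-")
      orient2[has_ct] <- ifelse(vapply(parts, `[`, "", 2) == "3", "+", "-")
    }
    len <- ifelse(s$svtype == "INS" & !is.na(s$svlen), abs(s$svlen),
                  ifelse(s$chrom == chrom2, pos2 - s$pos, -1))
    sym <- data.frame(
      chrom1 = s$chrom, pos1 = s$pos, orient1 = orient1,
      chrom2 = chrom2, pos2 = pos2, orient2 = orient2,
      svtype = s$svtype, length = len,
      allele_fraction = s$allele_fraction, read_depth = s$read_depth,
      split_reads = s$split_reads, discordant_pairs = s$discordant_pairs,
      caller_quality = s$caller_quality, imprecise = s$imprecise,
      stringsAsFactors = FALSE
    )
    out <- c(out, list(sym))
  }

  out <- if (length(out) > 0) do.call(rbind, out) else empty_sv_calls()[, 1:14]
  out$caller_id <- rep(caller_id, nrow(out))
  out$truth_label <- rep("unknown", nrow(out))
  out <- normalize_breakpoints(out)
  out <- out[order(chrom_rank(out$chrom1), out$pos1, chrom_rank(out$chrom2), out$pos2), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
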