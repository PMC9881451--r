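# Annotation resources: exact-match small-variant databases (population
# allele frequencies, cancer mutation catalogue) and interval indexes
# (panel-of-normals SV breakpoints, known-SV database, gene features,
# conserved elements, cancer genes, repeats). Lookups always return an
# explicit "absent" value, never fail.

site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = "\r")

#' Assemble a resource set from in-memory tables
#'
#' @param popdb data.frame (chrom, pos, ref, alt, af): population database.
#' @param cancerdb data.frame (chrom, pos, ref, alt, count): cancer mutation
#'   catalogue.
#' @param pon_sv intervals of panel-of-normals SV breakpoints.
#' @param sv_db intervals of known SV breakpoints (population + pan-cancer)
#'   with columns `af` and `pancancer` (0/1).
#' @param gene_features intervals with `name` in CDS/UTR/intron.
#' @param conserved intervals of conserved elements.
#' @param cancer_genes intervals with `name` = gene symbol.
#' @param repeats repeat intervals.
#' @param genes whole-gene spans with `name` = gene id (used for gene-level
#'   copy-number summaries).
#' @return object of class `resource_set`.
#' @export
resource_set <- function(popdb, cancerdb, pon_sv, sv_db, gene_features,
                         conserved, cancer_genes, repeats,
                         genes = NULL) {
  structure(list(
    popdb = popdb, popdb_keys = site_key(popdb$chrom, popdb$pos, popdb$ref, popdb$alt),
    cancerdb = cancerdb,
    cancerdb_keys = site_key(cancerdb$chrom, cancerdb$pos, cancerdb$ref, cancerdb$alt),
    pon_sv = build_interval_index(pon_sv),
    sv_db = build_interval_index(sv_db),
    gene_features = build_interval_index(gene_features),
    conserved = build_interval_index(conserved),
    cancer_genes = build_interval_index(cancer_genes),
    repeats = build_interval_index(repeats),
    genes = if (is.null(genes)) NULL else genes
  ), class = "resource_set")
}

#' @export
print.resource_set <- function(x, ...) {
  cat("<resource_set>\n",
      " popdb:", nrow(x$popdb), "sites; cancerdb:", nrow(x$cancerdb), "sites\n",
      " pon_sv:", nrow(x$pon_sv$table), "breakpoints; sv_db:", nrow(x$sv_db$table),
      "entries\n",
      " gene_features:", nrow(x$gene_features$table), "; conserved:",
      nrow(x$conserved$table), "; cancer_genes:", nrow(x$cancer_genes$table),
      "; repeats:", nrow(x$repeats$table), "\n")
  invisible(x)
}

#' Population-database allele-frequency lookup (exact match)
#'
#' Literal match on (chrom, pos, ref, alt); no indel realignment.
#'
#' @param rs a `resource_set`.
#' @param chrom,pos,ref,alt vectors identifying variants.
#' @return numeric vector of population allele frequencies; -1 where absent.
#' @export
popdb_lookup <- function(rs, chrom, pos, ref, alt) {
  m <- match(site_key(chrom, pos, ref, alt), rs$popdb_keys)
  ifelse(is.na(m), -1, rs$popdb$af[m])
}

#' Cancer-catalogue occurrence-count lookup (exact match)
#'
#' @inheritParams popdb_lookup
#' @return integer vector of occurrence counts; 0 where absent.
#' @export
cancerdb_lookup <- function(rs, chrom, pos, ref, alt) {
  m <- match(site_key(chrom, pos, ref, alt), rs$cancerdb_keys)
  ifelse(is.na(m), 0, rs$cancerdb$count[m])
}

# --- site-database VCF serialization (popdb / cancerdb) ---------------------

write_site_db <- function(db, path, value_key, genome = synthetic_genome()) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                      as.integer(genome$length)),
              sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"site annotation\">",
                      value_key),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(db) > 0) {
    db <- db[order(chrom_rank(db$chrom), db$pos), , drop = FALSE]
    val <- db[[setdiff(names(db), c("chrom", "pos", "ref", "alt"))[1]]]
    body <- paste(db$chrom, db$pos, ".", db$ref, db$alt, ".", ".",
                  sprintf("%s=%s", value_key, fmt_num(val)), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

read_site_db <- function(path, value_key, value_name) {
  if (vcf_body_count(path) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    out[[value_name]] <- numeric(0)
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf, getINFO = TRUE), stringsAsFactors = FALSE)
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  out[[value_name]] <- suppressWarnings(as.numeric(info_field(fix$INFO, value_key)))
  out
}

#' Load a resource set from a directory of standard-format files
#'
#' Expects the layout written by [simulate_resources()]: `popdb.vcf`
#' (INFO `AF`), `cancerdb.vcf` (INFO `CNT`), `pon_sv.bed`, `sv_db.bed`
#' (name column `af|pancancer`), `gene_features.bed` (name = region class),
#' `conserved.bed`, `cancer_genes.bed`, `repeats.bed`, `genes.bed`.
#'
#' @param dir resource directory.
#' @return a `resource_set`.
#' @export
load_resources <- function(dir) {
  svdb <- read_bed_intervals(file.path(dir, "sv_db.bed"))
  if (nrow(svdb) > 0) {
    parts <- strsplit(svdb$name, "|", fixed = TRUE)
    svdb$af <- as.numeric(vapply(parts, `[`, "", 1))
    svdb$pancancer <- as.numeric(vapply(parts, `[`, "", 2))
  } else {
    svdb$af <- numeric(0); svdb$pancancer <- numeric(0)
  }
  resource_set(
    popdb = read_site_db(file.path(dir, "popdb.vcf"), "AF", "af"),
    cancerdb = read_site_db(file.path(dir, "cancerdb.vcf"), "CNT", "count"),
    pon_sv = read_bed_intervals(file.path(dir, "pon_sv.bed")),
    sv_db = svdb,
    gene_features = read_bed_intervals(file.path(dir, "gene_features.bed")),
    conserved = read_bed_intervals(file.path(dir, "conserved.bed")),
    cancer_genes = read_bed_intervals(file.path(dir, "cancer_genes.bed")),
    repeats = read_bed_intervals(file.path(dir, "repeats.bed")),
    genes = read_bed_intervals(file.path(dir, "genes.bed"))
  )
}

#' Write a resource set to a directory
#'
#' @param rs a `resource_set` (with raw tables attached, as built by the
#'   simulator).
#' @param dir output directory (created if needed).
#' @param genome genome table for VCF contig headers.
#' @return `dir`, invisibly.
#' @export
write_resources <- function(rs, dir, genome = synthetic_genome()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_site_db(rs$popdb, file.path(dir, "popdb.vcf"), "AF", genome)
  write_site_db(rs$cancerdb, file.path(dir, "cancerdb.vcf"), "CNT", genome)
  write_bed_intervals(rs$pon_sv$table, file.path(dir, "pon_sv.bed"))
  svdb <- rs$sv_db$table
  if (nrow(svdb) > 0) {
    svdb$name <- paste(fmt_num(svdb$af), fmt_num(svdb$pancancer), sep = "|")
  }
  write_bed_intervals(svdb, file.path(dir, "sv_db.bed"))
  write_bed_intervals(rs$gene_features$table, file.path(dir, "gene_features.bed"))
  write_bed_intervals(rs$conserved$table, file.path(dir, "conserved.bed"))
  write_bed_intervals(rs$cancer_genes$table, file.path(dir, "cancer_genes.bed"))
  write_bed_intervals(rs$repeats$table, file.path(dir, "repeats.bed"))
  if (!is.null(rs$genes)) write_bed_intervals(rs$genes, file.path(dir, "genes.bed"))
  invisible(dir)
}
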