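# Multi-caller SV consensus: breakpoint-proximity merging in the style of
# SURVIVOR (both breakpoints within a maximum distance, optional type and
# strand matching, transitive closure), per-caller random-forest
# classification over 19 features, and vote-based integration into the
# final somatic SV set.

#' Merge parameters for SV consensus clustering
#'
#' @param max_breakpoint_distance maximum distance (bp) between both
#'   breakpoints of two calls for them to co-cluster (default 1000, the
#'   common convention for consensus merging).
#' @param require_type_match only cluster calls of the same SV type.
#' @param require_strand_match only cluster calls with identical breakpoint
#'   orientations.
#' @return list of class `merge_params`.
#' @export
merge_params <- function(max_breakpoint_distance = 1000,
                         require_type_match = TRUE,
                         require_strand_match = TRUE) {
  stopifnot(max_breakpoint_distance >= 0)
  structure(list(max_breakpoint_distance = max_breakpoint_distance,
                 require_type_match = require_type_match,
                 require_strand_match = require_strand_match),
            class = "merge_params")
}

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Merge SV callsets from several callers into consensus events
#'
#' Two calls co-cluster iff |pos1 - pos1'| and |pos2 - pos2'| are both within
#' `max_breakpoint_distance` on the same chromosome pair (plus type/strand
#' matching when required); events are the transitive closure of this
#' pairwise relation. Each event's representative is the member with the
#' highest caller quality (ties by lexicographic caller id, then position).
#' The result is invariant under permutation of caller order, and merging
#' the representatives of a merged set again changes nothing.
#'
#' @param callsets a list of SV breakpoint-pair data.frames (one per caller,
#'   `caller_id` column set), or a single combined data.frame.
#' @param p a `merge_params`.
#' @return list with `events` (one row per consensus event, representative
#'   fields plus `support_count` = number of distinct callers and
#'   `n_members`) and `members` (all input calls with their `event_id`).
#' @export
merge_callsets <- function(callsets, p = merge_params()) {
  calls <- if (is.data.frame(callsets)) callsets else do.call(rbind, callsets)
  if (is.null(calls) || nrow(calls) == 0) {
    return(list(events = cbind(empty_sv_calls()[, 1:14],
                               data.frame(event_id = integer(0),
                                          support_count = integer(0),
                                          n_members = integer(0))),
                members = cbind(empty_sv_calls(),
                                data.frame(event_id = integer(0)))))
  }
  calls <- normalize_breakpoints(calls)
  # canonical input order makes the clustering caller-order invariant
  ord <- order(chrom_rank(calls$chrom1), calls$pos1,
               chrom_rank(calls$chrom2), calls$pos2,
               calls$svtype, calls$orient1, calls$orient2,
               calls$caller_id, calls$caller_quality)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)

  key <- paste(calls$chrom1, calls$chrom2,
               if (p$require_type_match) calls$svtype else "",
               if (p$require_strand_match) paste(calls$orient1, calls$orient2) else "")
  parent <- uf_new(n)
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2) next
    g <- grp[order(calls$pos1[grp])]
    for (a in seq_along(g)) {
      i <- g[a]
      b <- a + 1
      while (b <= length(g) && calls$pos1[g[b]] - calls$pos1[i] <= p$max_breakpoint_distance) {
        j <- g[b]
        if (abs(calls$pos2[j] - calls$pos2[i]) <= p$max_breakpoint_distance) {
          ri <- uf_find(parent, i); rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        b <- b + 1
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  event_id <- match(root, sort(unique(root)))

  members <- calls
  members$event_id <- event_id

  rep_idx <- vapply(split(seq_len(n), event_id), function(ii) {
    ii[order(-calls$caller_quality[ii], calls$caller_id[ii], calls$pos1[ii])][1]
  }, integer(1))
  events <- calls[rep_idx, , drop = FALSE]
  events$event_id <- as.integer(names(rep_idx))
  events$support_count <- vapply(split(calls$caller_id, event_id),
                                 function(x) length(unique(x)), integer(1))
  events$n_members <- as.integer(table(event_id))
  events <- events[order(events$event_id), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events, members = members)
}

#' Count panel-of-normals breakpoints near both breakpoints of each SV
#'
#' Counts PON breakpoints within a half-open window of width `2 * window`
#' centered on each breakpoint (`[pos - window, pos + window)`).
#'
#' @param svs SV breakpoint-pair data.frame.
#' @param pon_index an `interval_index` over PON breakpoint positions.
#' @param window half-width of the window in bp (default 200).
#' @return data.frame with columns `pon_count_bp1`, `pon_count_bp2`.
#' @export
count_pon_near_breakpoints <- function(svs, pon_index, window = 200) {
  data.frame(
    pon_count_bp1 = count_overlaps_in(pon_index, svs$chrom1,
                                      svs$pos1 - window, svs$pos1 + window),
    pon_count_bp2 = count_overlaps_in(pon_index, svs$chrom2,
                                      svs$pos2 - window, svs$pos2 + window)
  )
}

nearest_db_distance <- function(index, chrom, pos, cap = 1e6) {
  n <- length(chrom)
  out <- rep(cap, n)
  if (n == 0 || length(index$gr) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos))
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(q, index$gr))
  out[S4Vectors::queryHits(hits)] <-
    pmin(as.numeric(S4Vectors::mcols(hits)$distance), cap)
  out
}

#' Feature names for the SV classification models
#' @return character vector of the 19 SV model features, in block order.
#' @export
sv_feature_names <- function() {
  c("svdb_overlap", "svdb_af_max", "svdb_nearest_distance", "pancancer_overlap",
    "pon_count_bp1", "pon_count_bp2",
    "cancer_gene_flag", "gene_class_bp1", "gene_class_bp2",
    "conserved_bp1", "conserved_bp2",
    "svtype_ord", "log_length", "allele_fraction", "read_depth",
    "split_reads", "discordant_pairs", "caller_quality", "imprecise_flag")
}

#' Extract the 19-feature matrix for SV classification
#'
#' Database block from overlap/nearest queries against the known-SV database
#' (an entry within `merge_distance` of both breakpoints counts as overlap);
#' PON block from breakpoint-window counts; region block from interval
#' queries at both breakpoints; caller block from the caller metrics.
#' `log_length` is ln(1 + length), 0 for translocations.
#'
#' @param svs SV breakpoint-pair data.frame (optionally labeled).
#' @param rs a `resource_set`.
#' @param pon_window PON window half-width (bp).
#' @param merge_distance proximity used for database overlap (bp).
#' @return data.frame with the 19 feature columns plus `label`.
#' @export
extract_sv_features <- function(svs, rs, pon_window = 200, merge_distance = 1000) {
  n <- nrow(svs)
  near1 <- count_overlaps_in(rs$sv_db, svs$chrom1,
                             svs$pos1 - merge_distance, svs$pos1 + merge_distance)
  near2 <- count_overlaps_in(rs$sv_db, svs$chrom2,
                             svs$pos2 - merge_distance, svs$pos2 + merge_distance)
  hits1 <- query_overlaps(rs$sv_db, svs$chrom1,
                          svs$pos1 - merge_distance, svs$pos1 + merge_distance)
  hits2 <- query_overlaps(rs$sv_db, svs$chrom2,
                          svs$pos2 - merge_distance, svs$pos2 + merge_distance)
  hits <- rbind(hits1, hits2)
  af_max <- rep(0, n)
  pancancer <- rep(0, n)
  if (nrow(hits) > 0) {
    af_agg <- tapply(rs$sv_db$table$af[hits$hit], hits$query, max)
    af_max[as.integer(names(af_agg))] <- as.numeric(af_agg)
    pc_agg <- tapply(rs$sv_db$table$pancancer[hits$hit], hits$query, max)
    pancancer[as.integer(names(pc_agg))] <- as.numeric(pc_agg)
  }
  pon <- count_pon_near_breakpoints(svs, rs$pon_sv, pon_window)
  w1s <- svs$pos1 - 1; w1e <- svs$pos1
  w2s <- svs$pos2 - 1; w2e <- svs$pos2
  type_ord <- c(DEL = 1, DUP = 2, INV = 3, INS = 4, TRA = 5)
  loglen <- ifelse(svs$length < 0, 0, log1p(svs$length))
  out <- data.frame(
    svdb_overlap = as.numeric(near1 > 0 & near2 > 0),
    svdb_af_max = af_max,
    svdb_nearest_distance = pmin(nearest_db_distance(rs$sv_db, svs$chrom1, svs$pos1),
                                 nearest_db_distance(rs$sv_db, svs$chrom2, svs$pos2)),
    pancancer_overlap = pancancer,
    pon_count_bp1 = pon$pon_count_bp1,
    pon_count_bp2 = pon$pon_count_bp2,
    cancer_gene_flag = as.numeric(overlaps_any(rs$cancer_genes, svs$chrom1, w1s, w1e) |
                                    overlaps_any(rs$cancer_genes, svs$chrom2, w2s, w2e)),
    gene_class_bp1 = region_class_at(rs, svs$chrom1, w1s, w1e),
    gene_class_bp2 = region_class_at(rs, svs$chrom2, w2s, w2e),
    conserved_bp1 = as.numeric(overlaps_any(rs$conserved, svs$chrom1, w1s, w1e)),
    conserved_bp2 = as.numeric(overlaps_any(rs$conserved, svs$chrom2, w2s, w2e)),
    svtype_ord = as.numeric(type_ord[svs$svtype]),
    log_length = loglen,
    allele_fraction = svs$allele_fraction,
    read_depth = svs$read_depth,
    split_reads = svs$split_reads,
    discordant_pairs = svs$discordant_pairs,
    caller_quality = svs$caller_quality,
    imprecise_flag = as.numeric(svs$imprecise),
    stringsAsFactors = FALSE
  )
  out$label <- if (!is.null(svs$truth_label)) svs$truth_label else "unknown"
  stopifnot(identical(setdiff(names(out), "label"), sv_feature_names()))
  out
}

#' Train one somatic-vs-germline random forest per SV caller
#'
#' Each caller's labeled feature table is balanced to 1:1 class proportions,
#' split 75/25 stratified, trained with the stock random-forest settings
#' (mtry 4, 400 trees, node size 1) and evaluated on its held-out quarter;
#' the balancing/splitting/training/evaluation machinery is shared with the
#' small-variant classifier.
#'
#' @param per_caller_features named list of labeled SV feature data.frames.
#' @param hp `rf_hyperparams` shared by the three models.
#' @param train_fraction stratified training fraction.
#' @param seed seed for balancing and splitting.
#' @return named list (per caller) of lists with `model`, `report`,
#'   `importance`.
#' @export
train_sv_models <- function(per_caller_features, hp = sv_default_hyperparams(),
                            train_fraction = 0.75, seed = 42) {
  lapply(per_caller_features, function(tab) {
    bal <- balance_one_to_one(tab, seed = seed)
    sp <- split_train_test(bal, train_fraction = train_fraction, seed = seed)
    model <- train_rf(sp$train, sv_feature_names(), hp)
    list(model = model, report = evaluate_model(model, sp$test),
         importance = model$importance)
  })
}

#' Integrate per-caller somatic classifications into the consensus SV set
#'
#' For each consensus event, `somatic_votes` counts the distinct callers
#' whose member call was classified somatic. The event is retained as
#' somatic iff the somatic callers are unanimous among its supporters
#' (`somatic_votes == support_count`, covering single- and double-caller
#' events) or at least two callers vote somatic. Every retained event keeps
#' its `support_count` for downstream filtering.
#'
#' @param merged result of [merge_callsets()].
#' @param member_somatic logical vector, one per row of `merged$members`:
#'   was that member call classified somatic?
#' @return the `events` data.frame with added `somatic_votes` and
#'   `final_class` columns.
#' @export
integrate_somatic_svs <- function(merged, member_somatic) {
  members <- merged$members
  stopifnot(length(member_somatic) == nrow(members))
  if (any(is.na(member_somatic))) stop("unclassified member call")
  votes <- vapply(split(seq_len(nrow(members)), members$event_id), function(ii) {
    length(unique(members$caller_id[ii][member_somatic[ii]]))
  }, integer(1))
  events <- merged$events
  events$somatic_votes <- votes[match(events$event_id, as.integer(names(votes)))]
  events$final_class <- ifelse(
    events$somatic_votes >= 1 &
      (events$somatic_votes == events$support_count | events$somatic_votes >= 2),
    "somatic", "germline")
  events
}
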