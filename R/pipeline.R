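# End-to-end wrappers: tumor-only small-variant classification, SV
# consensus + classification, copy-number benchmarking and cohort QC, each
# runnable on a synthetic cohort object or its on-disk representation.

#' Load a simulated cohort back from its on-disk representation
#'
#' Reconstructs a cohort object from a directory written by
#' [simulate_cohort()]/[write_cohort()]: per-sample VCFs (small variants and
#' the three SV caller dialects), copy-number segment tables, evidence
#' tables, truth tables and annotation resources. Truth labels on the
#' re-read call sets are restored from the truth tables where available.
#'
#' @param dir cohort directory.
#' @return a `synthetic_cohort` object.
#' @export
read_cohort <- function(dir) {
  params <- yaml::read_yaml(file.path(dir, "params.yaml"))
  meta <- utils::read.table(file.path(dir, "truth", "samples.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  dialects <- c(callerA = "bnd_pairs", callerB = "symbolic_end",
                callerC = "symbolic_chr2")
  samples <- lapply(stats::setNames(meta$sample, meta$sample), function(id) {
    sd <- file.path(dir, "samples", id)
    sv_calls <- lapply(names(dialects), function(caller) {
      read_sv_calls(file.path(sd, paste0(caller, ".vcf")),
                    dialects[[caller]], caller)
    })
    names(sv_calls) <- names(dialects)
    list(tumor_only = read_small_variants(file.path(sd, "tumor_only.vcf")),
         matched_somatic = read_small_variants(file.path(sd, "matched_somatic.vcf")),
         sv_calls = sv_calls,
         cn_matched = read_cn_callset(file.path(sd, "cn_matched.tsv"), check = FALSE),
         cn_tumor_only = read_cn_callset(file.path(sd, "cn_tumor_only.tsv"),
                                         check = FALSE))
  })
  truth <- list(
    small_variants = utils::read.table(file.path(dir, "truth", "small_variants.tsv"),
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  svp <- file.path(dir, "truth", "svs.tsv")
  if (file.exists(svp)) {
    truth$svs <- utils::read.table(svp, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  }
  cnp <- file.path(dir, "truth", "cn_injected.tsv")
  if (file.exists(cnp)) {
    truth$cn_injected <- utils::read.table(cnp, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
  }
  evidence <- list(
    sex = utils::read.table(file.path(dir, "evidence", "sex_evidence.tsv"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    purity = utils::read.table(file.path(dir, "evidence", "purity_estimates.tsv"),
                               header = TRUE, sep = "\t", stringsAsFactors = FALSE))
  structure(list(params = params, meta = meta, samples = samples,
                 truth = truth, evidence = evidence,
                 resources = load_resources(file.path(dir, "resources")),
                 dir = dir),
            class = "synthetic_cohort")
}

cohort_small_calls <- function(cohort, use_files) {
  ids <- names(cohort$samples)
  lapply(stats::setNames(ids, ids), function(id) {
    if (use_files) {
      sd <- file.path(cohort$dir, "samples", id)
      list(tumor_only = read_small_variants(file.path(sd, "tumor_only.vcf")),
           matched_somatic = read_small_variants(file.path(sd, "matched_somatic.vcf")))
    } else {
      cohort$samples[[id]][c("tumor_only", "matched_somatic")]
    }
  })
}

#' Run the tumor-only small-variant classification pipeline
#'
#' Labels each sample's tumor-only calls against its matched somatic ground
#' truth, extracts the 20-feature matrix, balances classes 1:1, splits
#' 75/25 stratified, trains the SNV model (20 features, SNV records) and
#' the indel model (19 features, all records, SNV indicator removed) and
#' evaluates both on their held-out quarters.
#'
#' @param cohort a `synthetic_cohort`.
#' @param hp `rf_hyperparams` (defaults to the small-variant optimum
#'   8/1000/5).
#' @param train_fraction stratified training fraction.
#' @param seed seed for balancing/splitting.
#' @param use_files read call sets back from `cohort$dir` rather than using
#'   the in-memory tables (exercises the VCF round trip).
#' @return list with `models` (snv, indel), `reports` (held-out
#'   `evaluation_report`s), `importances`, `features` (labeled feature
#'   table) and `label_counts`.
#' @export
run_snv_pipeline <- function(cohort, hp = snv_default_hyperparams(),
                             train_fraction = 0.75, seed = 42,
                             use_files = !is.null(cohort$dir)) {
  calls <- cohort_small_calls(cohort, use_files)
  labeled <- do.call(rbind, lapply(names(calls), function(id) {
    lab <- label_against_ground_truth(calls[[id]]$tumor_only,
                                      calls[[id]]$matched_somatic)$labeled
    lab$sample <- id
    lab
  }))
  rs <- cohort$resources
  feats <- extract_snv_features(labeled, rs)

  fit_one <- function(tab, features) {
    bal <- balance_one_to_one(tab, seed = seed)
    sp <- split_train_test(bal, train_fraction = train_fraction, seed = seed)
    model <- train_rf(sp$train, features, hp)
    list(model = model, report = evaluate_model(model, sp$test))
  }
  snv_fit <- fit_one(feats[feats$is_snv == 1, , drop = FALSE], snv_feature_names())
  indel_fit <- fit_one(feats, indel_feature_names())

  list(models = list(snv = snv_fit$model, indel = indel_fit$model),
       reports = list(snv = snv_fit$report, indel = indel_fit$report),
       importances = list(snv = snv_fit$model$importance,
                          indel = indel_fit$model$importance),
       features = feats,
       label_counts = table(labeled$truth_label))
}

#' Run the SV consensus + classification pipeline
#'
#' Pools each caller's calls across the cohort, extracts the 19-feature
#' matrix, trains one random forest per caller (1:1 balanced, 75/25 split,
#' stock settings 4/400/1), then per sample merges the three callsets into
#' consensus events, classifies every member call with its caller's model
#' and integrates the votes into the final somatic SV set.
#'
#' @param cohort a `synthetic_cohort`.
#' @param hp `rf_hyperparams` for the per-caller models.
#' @param p `merge_params` for consensus merging.
#' @param pon_window PON breakpoint window half-width (bp).
#' @param seed seed for balancing/splitting.
#' @return list with `models` (per caller: model, report, importance),
#'   `events` (per-sample integrated event tables) and `summary`
#'   (per-sample counts of consensus and somatic SVs with purity).
#' @export
run_sv_pipeline <- function(cohort, hp = sv_default_hyperparams(),
                            p = merge_params(), pon_window = 200, seed = 42) {
  rs <- cohort$resources
  callers <- names(cohort$samples[[1]]$sv_calls)
  pooled <- lapply(stats::setNames(callers, callers), function(caller) {
    do.call(rbind, lapply(cohort$samples, function(s) s$sv_calls[[caller]]))
  })
  feats <- lapply(pooled, function(calls) {
    extract_sv_features(calls, rs, pon_window = pon_window,
                        merge_distance = p$max_breakpoint_distance)
  })
  models <- train_sv_models(feats, hp = hp, seed = seed)

  events <- list()
  rows <- list()
  for (id in names(cohort$samples)) {
    calls <- cohort$samples[[id]]$sv_calls
    merged <- merge_callsets(calls, p)
    mf <- extract_sv_features(merged$members, rs, pon_window = pon_window,
                              merge_distance = p$max_breakpoint_distance)
    prob <- numeric(nrow(mf))
    for (caller in callers) {
      ii <- merged$members$caller_id == caller
      if (any(ii)) {
        prob[ii] <- predict_somatic_prob(models[[caller]]$model,
                                         mf[ii, , drop = FALSE])
      }
    }
    ev <- integrate_somatic_svs(merged, prob >= 0.5)
    events[[id]] <- ev
    rows[[id]] <- data.frame(
      sample = id,
      purity = cohort$meta$purity[cohort$meta$sample == id],
      n_events = nrow(ev),
      n_somatic = sum(ev$final_class == "somatic"),
      stringsAsFactors = FALSE
    )
  }
  list(models = models, events = events, summary = do.call(rbind, rows))
}

#' Run the tumor-only copy-number post-processing and benchmark
#'
#' Post-processes every tumor-only callset (exclusion regions, negative
#' values) and compares the cleaned callsets against their matched
#' counterparts across the six sample-level metrics and the gene-level
#' major/minor copy numbers.
#'
#' @param cohort a `synthetic_cohort`.
#' @param excl exclusion intervals.
#' @return list with `report` (`concordance_report`), `excluded_fraction`
#'   (cohort-wide removed/input segment length) and `logs` (per-sample
#'   removal logs).
#' @export
run_cn_benchmark <- function(cohort, excl = cn_exclusion_regions()) {
  post <- lapply(cohort$samples, function(s) {
    postprocess_tumor_only(s$cn_tumor_only, excl)
  })
  tumor_only <- lapply(post, `[[`, "callset")
  matched <- lapply(cohort$samples, `[[`, "cn_matched")
  report <- compare_callsets(unname(tumor_only), unname(matched),
                             genes = cohort$resources$genes)
  total_in <- sum(vapply(cohort$samples, function(s) {
    sum(s$cn_tumor_only$segments$end - s$cn_tumor_only$segments$start)
  }, numeric(1)))
  removed <- sum(vapply(post, function(x) sum(x$log$bp), numeric(1)))
  list(report = report,
       excluded_fraction = removed / total_in,
       logs = lapply(post, `[[`, "log"))
}

#' Run cohort-level quality control (sex and purity concordance)
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `sex` (per-sample reconciliation from
#'   [reconcile_sex()]) and `purity` (pairwise [purity_concordance()]
#'   results).
#' @export
run_cohort_qc <- function(cohort) {
  sex <- reconcile_sex(cohort$evidence$sex)
  pe <- cohort$evidence$purity
  purity <- purity_concordance(pe$pathologic, pe$genomic, pe$transcriptomic)
  list(sex = sex, purity = purity)
}
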