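#' Subtype an independent cohort by a PD/Control-derived threshold
#'
#' Splits independent-cohort subjects into subgroup 1 (PD-like,
#' `score >= threshold`) and subgroup 2 (control-like).  The threshold
#' must come from the Control/PD ROC analysis only, so no information
#' about the independent cohort enters its own subtyping.  A subject
#' exactly at the threshold is assigned to subgroup 1: someone at a
#' screening cut-off should be flagged.
#'
#' @param scores Data frame with `subject_id` and `score` columns (e.g.
#'   from [ensemble_predict()]).
#' @param threshold Decision threshold in \[0, 1\] from
#'   [optimal_threshold()] on the Control/PD curve.
#' @return A `subtype_assignment` data frame: `subject_id`, `score`,
#'   `subgroup` (1 or 2); attribute `threshold`.
#' @export
subtype <- function(scores, threshold) {
  stopifnot(is.data.frame(scores),
            all(c("subject_id", "score") %in% names(scores)))
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  out <- data.frame(subject_id = scores$subject_id,
                    score = scores$score,
                    subgroup = ifelse(scores$score >= threshold, 1L, 2L),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

#' Clinical trajectory summaries per subgroup
#'
#' Summarizes each clinical scale per (subgroup, visit): n, mean, SD and
#' interquartile range.  No significance testing is performed - with
#' subgroups this small, p-values would be misleading; the summaries
#' support a descriptive trajectory plot (group mean with IQR band).
#' Missing visit values reduce the cell's n; nothing is imputed.
#' Single-observation cells report `sd = NA`.
#'
#' @param clinical A [simulate_clinical()]-style long table
#'   (`subject_id`, `visit`, scale columns).
#' @param assignment A [subtype()] result.
#' @return Data frame: `subgroup`, `scale`, `visit`, `n`, `mean`, `sd`,
#'   `q25`, `q75`.
#' @export
trajectory_summary <- function(clinical, assignment) {
  stopifnot(inherits(assignment, "subtype_assignment"))
  scales <- intersect(c("updrs3", "hy", "moca", "sdm"), names(clinical))
  if (!length(scales)) stop("no clinical scale columns found")
  cl <- merge(clinical, assignment[, c("subject_id", "subgroup")],
              by = "subject_id")
  if (!nrow(cl)) stop("no clinical data for assigned subjects")
  visits <- sort(unique(cl$visit))
  rows <- list()
  for (sg in sort(unique(cl$subgroup))) {
    for (sc in scales) {
      for (v in visits) {
        x <- cl[cl$subgroup == sg & cl$visit == v, sc]
        x <- x[!is.na(x)]
        rows[[length(rows) + 1L]] <- data.frame(
          subgroup = sg, scale = sc, visit = v, n = length(x),
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
          q25 = if (length(x)) unname(stats::quantile(x, 0.25)) else
            NA_real_,
          q75 = if (length(x)) unname(stats::quantile(x, 0.75)) else
            NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full longitudinal-connectome analysis
#'
#' End-to-end driver: simulate (or accept) a cohort, train the
#' progression classifier on Control+PD under stratified k-fold
#' cross-validation, model-average scores for the independent PROD
#' cohort, estimate permutation-null feature relevance, produce
#' evaluation reports for Control-vs-PD and Control-vs-PROD, subtype the
#' PROD group by the Control/PD-derived threshold and summarize its
#' clinical trajectories.  PROD subjects never enter any training fold,
#' any null permutation, or the threshold choice.  The run is fully
#' reproducible from `config$seed`.
#'
#' @param config A [simulation_config()]; its seed drives every stage.
#' @param cohort Optionally a pre-built `cohort` (e.g. from
#'   [read_cohort()]); when `NULL` one is simulated from `config`.
#' @param spec Classifier specification (default L1 logistic
#'   regression).
#' @param k Folds; default = number of PD subjects (the maximum
#'   stratified fold count the positive class admits).
#' @param n_perm Permutations per fold for the relevance null.
#' @param n_boot Bootstrap repetitions for CIs.
#' @param relevance Set `FALSE` to skip the (slow) permutation
#'   relevance stage.
#' @param out_dir Optional directory; when given, score tables,
#'   relevance table and reports are written as TSV/JSON with a
#'   provenance block.
#' @return A `longconn_analysis` list: `cohort`, `clinical`,
#'   `cv` (scores + ensemble), `prod_scores`, `report_pd`,
#'   `report_prod`, `relevance`, `prominent`, `subtypes`,
#'   `trajectories`, `provenance`.
#' @export
run_full_analysis <- function(config, cohort = NULL,
                              spec = model_spec("logreg_l1"),
                              k = NULL, n_perm = 1000L, n_boot = 1000L,
                              relevance = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  clinical <- simulate_clinical(config, cohort)
  man <- cohort$manifest
  seed <- config$seed

  train_idx <- man$group %in% c("CNT", "PD")
  prod_idx <- man$group == "PROD"
  x_train <- cohort$features[train_idx, , drop = FALSE]
  y_train <- man$group[train_idx]
  if (is.null(k)) k <- sum(y_train == "PD")

  cv <- cross_validated_scores(x_train, y_train, spec, k = k, seed = seed)

  report_pd <- evaluate_scores(cv$scores$score, y_train,
                               age = man$age[train_idx],
                               gender = man$gender[train_idx],
                               n_boot = n_boot, seed = seed)
  threshold <- report_pd$chosen_threshold

  prod_scores <- NULL; report_prod <- NULL; subtypes <- NULL
  trajectories <- NULL
  if (any(prod_idx)) {
    prod_scores <- ensemble_predict(
      cv$ensemble, cohort$features[prod_idx, , drop = FALSE])
    cnt_idx <- man$group == "CNT"
    sc_cnt <- cv$scores$score[y_train == "CNT"]
    labels_cp <- c(rep("CNT", sum(cnt_idx)), rep("PROD", sum(prod_idx)))
    report_prod <- evaluate_scores(
      c(sc_cnt, prod_scores$score),
      as_binary(labels_cp, positive = "PROD"),
      age = c(man$age[cnt_idx], man$age[prod_idx]),
      gender = c(man$gender[cnt_idx], man$gender[prod_idx]),
      n_boot = n_boot, seed = seed + 1L)
    subtypes <- subtype(prod_scores, threshold)
    trajectories <- trajectory_summary(clinical, subtypes)
  } else {
    warning("no PROD subjects: subtyping stage skipped")
  }

  rel <- NULL; prom <- NULL
  if (relevance && !is.null(cv$ensemble$fold_models[[1]]$weights)) {
    zmat <- fold_relevance(x_train, y_train, cv$ensemble,
                           n_perm = n_perm, seed = seed)
    rel <- aggregate_relevance(zmat)
    prom <- prominent_connections(rel, threshold = 5)
  }

  provenance <- list(package = "longconn",
                     version = as.character(utils::packageVersion("longconn")),
                     seed = seed, k = k, family = spec$family,
                     scaling = spec$scaling, n_perm = n_perm,
                     n_boot = n_boot,
                     config = unclass(config)[setdiff(names(unclass(config)),
                                                      "affected_edges")])
  res <- structure(
    list(cohort = cohort, clinical = clinical, cv = cv,
         prod_scores = prod_scores, report_pd = report_pd,
         report_prod = report_prod, relevance = rel, prominent = prom,
         subtypes = subtypes, trajectories = trajectories,
         provenance = provenance),
    class = "longconn_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.longconn_analysis <- function(x, ...) {
  cat("<longconn_analysis>\n")
  cat("Control vs PD (out-of-fold):\n"); print(x$report_pd)
  if (!is.null(x$report_prod)) {
    cat("Control vs PROD (model-averaged):\n"); print(x$report_prod)
  }
  if (!is.null(x$prominent))
    cat(nrow(x$prominent), "prominent connections at z >= 5\n")
  if (!is.null(x$subtypes))
    cat(sprintf("PROD subtypes: %d PD-like / %d control-like (threshold %.3f)\n",
                sum(x$subtypes$subgroup == 1L),
                sum(x$subtypes$subgroup == 2L),
                attr(x$subtypes, "threshold")))
  invisible(x)
}

report_to_list <- function(r) {
  if (is.null(r)) return(NULL)
  list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
       chosen_threshold = r$chosen_threshold,
       metrics_optimal = r$metrics_optimal[
         c("sensitivity", "specificity", "balanced_accuracy", "kappa")],
       metrics_05 = r$metrics_05[
         c("sensitivity", "specificity", "balanced_accuracy", "kappa")],
       adjusted_p = r$adjusted_p, n_pos = r$n_pos, n_neg = r$n_neg,
       settings = r$settings)
}

#' Write the artifacts of a full analysis to a directory
#'
#' Emits deterministic, full-precision text outputs: out-of-fold and
#' model-averaged score tables (TSV), the relevance table (TSV), both
#' evaluation reports plus subtyping and provenance (JSON), and the
#' trajectory summary (TSV).  Identical config + seed produce
#' byte-identical files.
#'
#' @param res A [run_full_analysis()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(res, out_dir) {
  stopifnot(inherits(res, "longconn_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file, digits_cols = NULL) {
    for (cn in names(df)) if (is.numeric(df[[cn]]) &&
                                !is.integer(df[[cn]]))
      df[[cn]] <- fmt_full(df[[cn]])
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$cv$scores, "scores_oof.tsv")
  if (!is.null(res$prod_scores)) wt(res$prod_scores, "scores_prod.tsv")
  if (!is.null(res$relevance)) {
    rel <- res$relevance
    rel$prominent <- !is.na(rel$z) & rel$z >= 5
    wt(as.data.frame(rel), "relevance.tsv")
  }
  if (!is.null(res$subtypes)) wt(as.data.frame(res$subtypes),
                                 "subtypes.tsv")
  if (!is.null(res$trajectories)) wt(res$trajectories,
                                     "trajectories.tsv")
  jsonlite::write_json(
    list(control_vs_pd = report_to_list(res$report_pd),
         control_vs_prod = report_to_list(res$report_prod),
         subtype_threshold = if (!is.null(res$subtypes))
           attr(res$subtypes, "threshold") else NULL,
         provenance = res$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
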