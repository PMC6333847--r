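# Full-precision text round trip for doubles: %.17g preserves every
# IEEE-754 double exactly through write/read.
fmt_full <- function(x) sprintf("%.17g", x)

write_connectome_csv <- function(mat, path) {
  lines <- apply(mat, 1, function(r) paste(fmt_full(r), collapse = ","))
  writeLines(lines, path)
}

read_connectome_csv <- function(path) {
  if (!file.exists(path)) stop("connectome file not found: ", path)
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  if (length(rows) != 16L || any(lengths(rows) != 16L))
    stop("malformed connectome file (need 16x16): ", path)
  matrix(as.numeric(unlist(rows)), 16, 16, byrow = TRUE)
}

#' Write a cohort to a directory of plain-text files
#'
#' Lays a cohort out as one CSV per (subject, timepoint, metric)
#' connectome (16 rows x 16 columns, no header), a TSV manifest with the
#' subject table and the six file paths per subject, a features TSV (one
#' row per subject, 360 named columns), a truth JSON (synthetic ground
#' truth) and a provenance JSON (config and seed).  All numeric output is
#' written at full precision so the round trip through [read_cohort()] is
#' exact.
#'
#' @param cohort A [simulate_cohort()] result (or a cohort read back from
#'   disk).
#' @param directory Output directory, created if needed.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  conn_dir <- file.path(directory, "connectomes")
  dir.create(conn_dir, showWarnings = FALSE)
  man <- cohort$manifest
  shorts <- vapply(connectome_metrics(), metric_short, character(1))
  path_cols <- as.vector(outer(c("baseline", "followup"), shorts,
                               function(tp, m) paste("path", tp, m,
                                                     sep = "_")))
  for (pc in path_cols) man[[pc]] <- NA_character_
  for (s in seq_len(nrow(man))) {
    sid <- man$subject_id[s]
    for (tp in c("baseline", "followup")) {
      for (metric in connectome_metrics()) {
        fn <- sprintf("%s_%s_%s.csv", sid, tp, metric_short(metric))
        write_connectome_csv(
          cohort$connectomes[[sid]][[paste0(tp, ".", metric)]],
          file.path(conn_dir, fn))
        man[s, paste("path", tp, metric_short(metric), sep = "_")] <-
          file.path("connectomes", fn)
      }
    }
  }
  utils::write.table(man, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_features_tsv(cohort$features, file.path(directory, "features.tsv"))
  truth <- cohort$truth
  truth$latent_class <- as.list(truth$latent_class)
  jsonlite::write_json(truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(directory, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(directory)
}

#' Write a feature matrix as TSV
#'
#' One row per subject; first column `subject_id`, then the 360 feature
#' columns named by [edge_feature_map()]. Values at full precision.
#'
#' @param features Numeric matrix with subject-id rownames.
#' @param path Output file.
#' @export
write_features_tsv <- function(features, path) {
  df <- data.frame(subject_id = rownames(features),
                   stringsAsFactors = FALSE)
  vals <- apply(features, 2, fmt_full)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- colnames(features)
  utils::write.table(cbind(df, vals), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV back into a matrix
#' @param path File written by [write_features_tsv()].
#' @return Numeric matrix with subject-id rownames.
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE,
                          colClasses = c(subject_id = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  m
}

#' Read a cohort from a directory
#'
#' Inverse of [write_cohort()]: reads the manifest, validates and loads
#' every connectome file, recomputes the longitudinal feature matrix from
#' the connectomes, and restores truth and provenance when present (they
#' are absent for user-supplied, non-synthetic cohorts).  A manifest row
#' pointing at a missing file raises an error naming the subject.
#'
#' @param directory Directory written by [write_cohort()] (or laid out in
#'   the same schema by other tools).
#' @return A `cohort` object.
#' @export
read_cohort <- function(directory) {
  man_path <- file.path(directory, "manifest.tsv")
  if (!file.exists(man_path)) stop("manifest not found: ", man_path)
  man <- utils::read.table(man_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character"))
  shorts <- vapply(connectome_metrics(), metric_short, character(1))
  n <- nrow(man)
  map <- edge_feature_map()
  features <- matrix(0, n, 360L,
                     dimnames = list(man$subject_id, map$name))
  connectomes <- vector("list", n)
  names(connectomes) <- man$subject_id
  for (s in seq_len(n)) {
    sid <- man$subject_id[s]
    conns <- list()
    objs <- list()
    for (tp in c("baseline", "followup")) {
      for (metric in connectome_metrics()) {
        pc <- paste("path", tp, metric_short(metric), sep = "_")
        path <- file.path(directory, man[[pc]][s])
        if (!file.exists(path))
          stop("subject ", sid, ": missing connectome file ", man[[pc]][s])
        mat <- read_connectome_csv(path)
        conns[[paste0(tp, ".", metric)]] <- mat
        objs[[paste0(tp, ".", metric)]] <-
          validate_connectome(mat, metric, subject_id = sid,
                              timepoint = tp)
      }
    }
    features[s, ] <- build_feature_vector(objs)
    connectomes[[s]] <- conns
  }
  truth <- NULL
  tp <- file.path(directory, "truth.json")
  if (file.exists(tp)) {
    truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
    truth$latent_class <- unlist(truth$latent_class)
  }
  config <- NULL
  pp <- file.path(directory, "provenance.json")
  if (file.exists(pp)) config <- jsonlite::read_json(pp,
                                                     simplifyVector = TRUE)
  core <- c("subject_id", "group", "age", "gender", "days_between_scans")
  structure(
    list(features = features,
         manifest = man[, intersect(core, names(man)), drop = FALSE],
         truth = truth,
         connectomes = connectomes,
         config = config),
    class = "cohort"
  )
}
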