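#' Validate and construct a connectome
#'
#' Checks a raw 16x16 matrix against the invariants of its connectivity
#' metric and returns a `connectome` object.  The matrix must be symmetric
#' within `tol` (connectivity metrics are symmetric by construction);
#' small asymmetries below the tolerance are removed by averaging with the
#' transpose.  Metric-specific range constraints: streamline counts are
#' non-negative, mean FA lies in \[0, 1\], mean MD is non-negative
#' (zero is allowed for unconnected pairs).
#'
#' @param raw_matrix Numeric 16x16 matrix.
#' @param metric One of [connectome_metrics()].
#' @param subject_id Subject identifier (string).
#' @param timepoint `"baseline"` or `"followup"`.
#' @param tol Maximum tolerated absolute asymmetry (default `1e-9`,
#'   intended to absorb file round-trip noise only).
#' @return An object of class `connectome`: a list with elements
#'   `matrix`, `metric`, `subject_id`, `timepoint`.
#' @examples
#' m <- matrix(0, 16, 16); m[1, 2] <- m[2, 1] <- 5
#' validate_connectome(m, "streamline_count", "s01", "baseline")
#' @export
validate_connectome <- function(raw_matrix, metric,
                                subject_id = "unknown",
                                timepoint = c("baseline", "followup"),
                                tol = 1e-9) {
  metric <- match.arg(metric, connectome_metrics())
  timepoint <- match.arg(timepoint)
  if (!is.matrix(raw_matrix) || !is.numeric(raw_matrix))
    stop("`raw_matrix` must be a numeric matrix")
  if (!all(dim(raw_matrix) == c(16L, 16L)))
    stop("connectome matrix must be 16x16, got ",
         paste(dim(raw_matrix), collapse = "x"))
  if (any(!is.finite(raw_matrix)))
    stop("connectome matrix contains non-finite values")
  asym <- max(abs(raw_matrix - t(raw_matrix)))
  if (asym > tol)
    stop(sprintf("connectome matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, tol))
  mat <- (raw_matrix + t(raw_matrix)) / 2
  off <- mat[upper.tri(mat)]
  if (any(off < 0))
    stop("negative ", metric, " values are not allowed")
  if (metric == "mean_fa" && any(off > 1))
    stop("mean FA values must lie in [0, 1]; max observed ",
         format(max(off)))
  structure(
    list(matrix = mat, metric = metric, subject_id = subject_id,
         timepoint = timepoint),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s, %s, %s; %d/120 nonzero edges\n",
              x$subject_id, x$timepoint, x$metric,
              sum(x$matrix[upper.tri(x$matrix)] != 0)))
  invisible(x)
}

#' Vectorize the strict upper triangle of a connectome
#'
#' Converts a symmetric connectome matrix into its canonical edge vector:
#' the 120 strictly-upper-triangle cells (i < j, diagonal excluded) in the
#' row-major order of [edge_pairs()].  The same enumeration is used for
#' every subject, timepoint and metric so that feature positions are
#' comparable across vectors.
#'
#' @param c A `connectome` object (or a bare symmetric 16x16 matrix, which
#'   is validated first with `metric`).
#' @param metric Required if `c` is a bare matrix.
#' @return A numeric vector of length 120 with attribute `metric`.
#' @export
vectorize_upper_triangle <- function(c, metric = NULL) {
  if (!inherits(c, "connectome")) {
    if (is.null(metric))
      stop("`metric` must be given when vectorizing a bare matrix")
    c <- validate_connectome(c, metric)
  }
  m <- c$matrix
  # row-major upper triangle: transpose, then lower.tri in column order
  v <- t(m)[lower.tri(m)]
  structure(as.numeric(v), metric = c$metric)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper_triangle()] on the off-diagonal cells; the
#' diagonal is set to zero.
#'
#' @param values Numeric vector of length 120 in canonical edge order.
#' @return A symmetric 16x16 matrix with zero diagonal.
#' @export
edge_vector_to_matrix <- function(values) {
  if (length(values) != 120L)
    stop("edge vector must have length 120, got ", length(values))
  m <- matrix(0, 16, 16)
  m[lower.tri(m)] <- values   # fills column-major lower = row-major upper
  m <- t(m)
  m + t(m)
}

#' Longitudinal distance between two edge vectors
#'
#' Element-wise L1 distance between the follow-up and baseline edge
#' vectors: `|x_fu - x_b|`.  The sign is discarded so that entries
#' represent magnitudes of connectivity change rather than directed
#' increases or decreases.
#'
#' @param x_b,x_fu Numeric edge vectors of equal length (as produced by
#'   [vectorize_upper_triangle()]); if both carry a `metric` attribute it
#'   must agree.
#' @return Non-negative numeric vector of the same length.
#' @export
longitudinal_distance <- function(x_b, x_fu) {
  if (length(x_b) != length(x_fu))
    stop("edge vectors differ in length: ", length(x_b), " vs ",
         length(x_fu))
  mb <- attr(x_b, "metric"); mf <- attr(x_fu, "metric")
  if (!is.null(mb) && !is.null(mf) && !identical(mb, mf))
    stop("metric mismatch: ", mb, " vs ", mf)
  structure(abs(as.numeric(x_fu) - as.numeric(x_b)), metric = mb)
}

#' Build one subject's longitudinal feature vector
#'
#' Concatenates the per-metric longitudinal distance vectors into the
#' 360-element feature vector: positions 1-120 hold the streamline-count
#' block, 121-240 mean FA, 241-360 mean MD.  No feature selection is
#' applied.
#'
#' @param connectomes A list of six `connectome` objects covering both
#'   timepoints for all three metrics of a single subject.
#' @return Numeric vector of length 360, named by
#'   [edge_feature_map()]`$name`, with attribute `subject_id`.
#' @export
build_feature_vector <- function(connectomes) {
  if (!is.list(connectomes) ||
      !all(vapply(connectomes, inherits, logical(1), "connectome")))
    stop("`connectomes` must be a list of connectome objects")
  ids <- unique(vapply(connectomes, `[[`, character(1), "subject_id"))
  if (length(ids) != 1L)
    stop("connectomes belong to different subjects: ",
         paste(ids, collapse = ", "))
  key <- vapply(connectomes, function(c)
    paste(c$timepoint, c$metric, sep = "."), character(1))
  blocks <- lapply(connectome_metrics(), function(metric) {
    b <- connectomes[key == paste0("baseline.", metric)]
    f <- connectomes[key == paste0("followup.", metric)]
    if (length(b) != 1L || length(f) != 1L)
      stop("need exactly one baseline and one followup connectome for ",
           metric, " (subject ", ids, ")")
    longitudinal_distance(vectorize_upper_triangle(b[[1]]),
                          vectorize_upper_triangle(f[[1]]))
  })
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- edge_feature_map()$name
  attr(out, "subject_id") <- ids
  out
}
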