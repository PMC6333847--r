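#' The 16-region subcortical parcellation
#'
#' The analysis operates on a fixed parcellation of 16 subcortical areas
#' relevant to Parkinson's disease: the left and right red nucleus (RN),
#' substantia nigra (SN), subthalamic nucleus (STN), caudate (CAUD),
#' putamen (PUT), globus pallidus externa (GPe), globus pallidus interna
#' (GPi) and thalamus (THAL).  The node order is fixed (left before right
#' within each structure, structures in the order above) so that edge and
#' feature indexing is reproducible across runs and machines.
#'
#' @return A data frame with columns `index` (1-16), `label`
#'   (e.g. `"L-RN"`), `hemisphere` and `structure`.
#' @examples
#' atlas_nodes()
#' @export
atlas_nodes <- function() {
  structures <- c("RN", "SN", "STN", "CAUD", "PUT", "GPe", "GPi", "THAL")
  labels <- as.vector(t(outer(structures, c("L", "R"),
                              function(s, h) paste(h, s, sep = "-"))))
  data.frame(
    index = seq_len(16L),
    label = labels,
    hemisphere = rep(c("L", "R"), times = 8),
    structure = rep(structures, each = 2),
    stringsAsFactors = FALSE
  )
}

#' Connectivity metrics handled by the pipeline
#'
#' Three symmetric connectivity metrics are computed per area pair:
#' streamline count (`"streamline_count"`), streamline-averaged fractional
#' anisotropy (`"mean_fa"`, values in \[0, 1\]) and streamline-averaged mean
#' diffusivity (`"mean_md"`, positive values in mm^2/s).  The short codes
#' `count`, `fa`, `md` are used in file names and feature labels.
#'
#' @return Character vector of the three metric identifiers, in the fixed
#'   concatenation order used by [build_feature_vector()].
#' @export
connectome_metrics <- function() {
  c("streamline_count", "mean_fa", "mean_md")
}

metric_short <- function(metric) {
  c(streamline_count = "count", mean_fa = "fa", mean_md = "md")[[metric]]
}

#' Canonical enumeration of node pairs
#'
#' Enumerates the C(16, 2) = 120 unordered node pairs in row-major
#' strict-upper-triangle order: (1,2), (1,3), ..., (1,16), (2,3), ...,
#' (15,16).  Self-connections are excluded: a streamline from an area to
#' itself is not a connection between areas, and averaged FA/MD along such
#' a loop is ill-defined.
#'
#' @return A data frame with columns `edge` (1-120), `i`, `j` (node
#'   indices, `i < j`), `node_a`, `node_b` (labels).
#' @export
edge_pairs <- function() {
  idx <- which(upper.tri(matrix(0, 16, 16)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  labels <- atlas_nodes()$label
  data.frame(
    edge = seq_len(nrow(idx)),
    i = unname(idx[, "row"]),
    j = unname(idx[, "col"]),
    node_a = labels[idx[, "row"]],
    node_b = labels[idx[, "col"]],
    stringsAsFactors = FALSE
  )
}

#' Map feature indices to (node pair, metric) triples
#'
#' The longitudinal feature vector has 360 entries: 120 node pairs for
#' each of the three metrics, concatenated in the order streamline count,
#' mean FA, mean MD.  This map is the bijection between feature index and
#' (unordered pair, metric), used to label model weights and relevance
#' tables.
#'
#' @return A data frame with 360 rows and columns `feature` (1-360),
#'   `edge` (1-120), `node_a`, `node_b`, `metric`, and `name`, a stable
#'   feature label such as `"L-RN__R-RN__count"`.
#' @examples
#' head(edge_feature_map())
#' @export
edge_feature_map <- function() {
  pairs <- edge_pairs()
  metrics <- connectome_metrics()
  out <- do.call(rbind, lapply(seq_along(metrics), function(m) {
    data.frame(
      feature = (m - 1L) * 120L + pairs$edge,
      edge = pairs$edge,
      node_a = pairs$node_a,
      node_b = pairs$node_b,
      metric = metrics[m],
      stringsAsFactors = FALSE
    )
  }))
  out$name <- paste(out$node_a, out$node_b,
                    vapply(out$metric, metric_short, character(1)),
                    sep = "__")
  rownames(out) <- NULL
  out
}
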