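#' Weighted structural connectome
#'
#' Construct a validated weighted connectome: a labelled, symmetric,
#' nonnegative matrix of streamline counts between grey-matter regions, with
#' an optional parallel matrix of mean fractional anisotropy (FA) per edge.
#' Nothing is symmetrized or repaired silently; invalid input is rejected
#' with the offending location.
#'
#' @param weights Square numeric matrix of streamline counts. Row and column
#'   names, if present, must agree; otherwise `node_labels` supplies them.
#' @param fa Optional square numeric matrix of per-edge mean FA in `[0, 1]`,
#'   sharing the sparsity pattern of `weights`.
#' @param node_labels Optional character vector of region labels (used when
#'   `weights` carries no dimnames).
#' @param subject_id Identifier attached to the connectome.
#' @return An object of class `weighted_connectome`: a list with elements
#'   `weights`, `fa`, `labels`, `subject_id`.
#' @examples
#' w <- matrix(c(0, 5, 3, 5, 0, 0, 3, 0, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' wc <- weighted_connectome(w)
#' node_labels(wc)
#' @export
weighted_connectome <- function(weights, fa = NULL, node_labels = NULL,
                                subject_id = NA_character_) {
  if (!is_square_matrix(weights)) {
    stop("`weights` must be a square matrix, got ", nrow(weights), " x ",
         ncol(weights), call. = FALSE)
  }
  labels <- rownames(weights) %||% node_labels
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(weights)))
  if (anyDuplicated(labels)) {
    stop("node labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(labels) != nrow(weights)) {
    stop("`node_labels` length (", length(labels),
         ") does not match matrix order (", nrow(weights), ")", call. = FALSE)
  }
  if (!is.null(colnames(weights)) && !identical(colnames(weights), labels)) {
    stop("row and column labels of `weights` disagree", call. = FALSE)
  }
  storage.mode(weights) <- "double"
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative weight at cell (", neg[1, 1], ",", neg[1, 2], ")",
         call. = FALSE)
  }
  asym <- which(abs(weights - t(weights)) > 1e-8 * (1 + abs(weights)),
                arr.ind = TRUE)
  if (nrow(asym) > 0) {
    bad <- asym[asym[, 1] > asym[, 2], , drop = FALSE]
    if (nrow(bad) == 0) bad <- asym
    stop("`weights` is not symmetric: cell (", bad[1, 1], ",", bad[1, 2],
         ") = ", weights[bad[1, 1], bad[1, 2]], " but cell (", bad[1, 2],
         ",", bad[1, 1], ") = ", weights[bad[1, 2], bad[1, 1]], call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    stop("diagonal of `weights` must be zero (no self-connections)",
         call. = FALSE)
  }
  dimnames(weights) <- list(labels, labels)
  if (!is.null(fa)) {
    if (!is_square_matrix(fa) || nrow(fa) != nrow(weights)) {
      stop("`fa` must be a square matrix of the same order as `weights`",
           call. = FALSE)
    }
    if (!is.null(rownames(fa)) && !identical(rownames(fa), labels)) {
      stop("label mismatch between `weights` and `fa`: fa rows start ",
           rownames(fa)[1], call. = FALSE)
    }
    storage.mode(fa) <- "double"
    if (any(fa < 0 | fa > 1)) {
      bad <- which(fa < 0 | fa > 1, arr.ind = TRUE)
      stop("FA out of [0, 1] at cell (", bad[1, 1], ",", bad[1, 2], ")",
           call. = FALSE)
    }
    off <- weights == 0 & fa != 0
    if (any(off)) {
      bad <- which(off, arr.ind = TRUE)
      stop("FA present on absent edge at cell (", bad[1, 1], ",", bad[1, 2],
           ")", call. = FALSE)
    }
    dimnames(fa) <- list(labels, labels)
  }
  structure(
    list(weights = weights, fa = fa, labels = labels,
         subject_id = subject_id),
    class = "weighted_connectome"
  )
}

#' @export
print.weighted_connectome <- function(x, ...) {
  n_edge <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("<weighted_connectome> ", length(x$labels), " nodes, ", n_edge,
      " edges", if (!is.null(x$fa)) ", with FA" else "",
      if (!is.na(x$subject_id)) paste0(" [", x$subject_id, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' @rdname weighted_connectome
#' @param x A `weighted_connectome`.
#' @export
node_labels <- function(x) {
  stopifnot(inherits(x, "weighted_connectome"))
  x$labels
}

#' @rdname weighted_connectome
#' @export
n_nodes <- function(x) length(node_labels(x))

#' Read and write connectome matrices
#'
#' Connectomes are stored as tab-separated square matrices whose first row
#' and first column hold the region labels. An FA matrix of identical shape
#' may accompany the weights. [read_edge_list()] reads the alternative
#' 3-column format (`label_i`, `label_j`, `weight`) against an explicit label
#' ordering.
#'
#' @param path,fa_path Paths to the weight (and optional FA) TSV files.
#' @param subject_id Identifier attached to the connectome.
#' @return A [weighted_connectome()].
#' @export
read_connectome <- function(path, fa_path = NULL, subject_id = NA_character_) {
  read_square <- function(p) {
    df <- utils::read.delim(p, check.names = FALSE, row.names = 1)
    m <- as.matrix(df)
    if (!is_square_matrix(m)) {
      stop("file ", p, " is not a labelled square matrix (", nrow(m), " x ",
           ncol(m), ")", call. = FALSE)
    }
    m
  }
  w <- read_square(path)
  fa <- if (!is.null(fa_path)) read_square(fa_path) else NULL
  weighted_connectome(w, fa = fa, subject_id = subject_id)
}

#' @rdname read_connectome
#' @param x A `weighted_connectome` to write.
#' @export
write_connectome <- function(x, path, fa_path = NULL) {
  stopifnot(inherits(x, "weighted_connectome"))
  utils::write.table(x$weights, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(fa_path)) {
    if (is.null(x$fa)) stop("connectome has no FA matrix to write")
    utils::write.table(x$fa, fa_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}

#' @rdname read_connectome
#' @param labels Character vector giving the node ordering for the edge list.
#' @export
read_edge_list <- function(path, labels, subject_id = NA_character_) {
  el <- utils::read.delim(path, header = TRUE)
  if (ncol(el) < 3) stop("edge list needs 3 columns: label_i, label_j, weight")
  miss <- setdiff(unique(c(el[[1]], el[[2]])), labels)
  if (length(miss) > 0) {
    stop("edge-list labels absent from label file: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  w <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_len(nrow(el))) {
    i <- el[[1]][k]; j <- el[[2]][k]
    w[i, j] <- el[[3]][k]
    w[j, i] <- el[[3]][k]
  }
  weighted_connectome(w, subject_id = subject_id)
}

#' Remove low-count edges
#'
#' Edges carrying fewer streamlines than `min_streamlines` are removed
#' (set absent in both the weight and FA matrices). Streamline-count
#' thresholding suppresses false-positive tracts and yields the sparse
#' matrix the downstream graph measures assume. The operation is idempotent.
#'
#' @param x A [weighted_connectome()].
#' @param min_streamlines Minimum surviving edge weight (default 3: edges
#'   with fewer than three streamlines are removed).
#' @return A thresholded `weighted_connectome`.
#' @export
threshold_edges <- function(x, min_streamlines = 3) {
  stopifnot(inherits(x, "weighted_connectome"), min_streamlines >= 1)
  drop <- x$weights < min_streamlines
  w <- x$weights
  w[drop] <- 0
  fa <- x$fa
  if (!is.null(fa)) fa[drop] <- 0
  weighted_connectome(w, fa = fa, subject_id = x$subject_id)
}

#' Identify hub nodes by degree
#'
#' A node is a hub when its degree (number of directly connected other
#' nodes) is strictly greater than `degree_threshold`. Hubs are computed on
#' each subject's own (thresholded) connectome unless a fixed group-level
#' set is supplied downstream.
#'
#' @param x A thresholded [weighted_connectome()].
#' @param degree_threshold Strict lower bound on degree (default 20).
#' @return Character vector of hub node labels.
#' @export
identify_hubs <- function(x, degree_threshold = 20) {
  stopifnot(inherits(x, "weighted_connectome"))
  deg <- rowSums(x$weights > 0)
  names(deg)[deg > degree_threshold]
}

#' Define the pivot-centred subnetwork
#'
#' Bundles the reading-network node list, the hub set, and the pivot node
#' (by default the left thalamus, `THA.L`). The analysis subnetwork is the
#' union of hubs and reading-network nodes.
#'
#' @param reading_nodes Character vector of reading-network region labels;
#'   must contain the pivot.
#' @param hub_nodes Character vector of hub labels (possibly empty).
#' @param pivot_node Label of the pivot region.
#' @return An object of class `network_definition`.
#' @export
network_definition <- function(reading_nodes,
                               hub_nodes = character(),
                               pivot_node = "THA.L") {
  if (!pivot_node %in% reading_nodes) {
    stop("pivot node ", pivot_node, " must be in `reading_nodes`",
         call. = FALSE)
  }
  structure(
    list(reading_nodes = unique(reading_nodes),
         hub_nodes = unique(hub_nodes),
         pivot_node = pivot_node,
         subnetwork_nodes = union(unique(hub_nodes), unique(reading_nodes))),
    class = "network_definition"
  )
}

#' @export
print.network_definition <- function(x, ...) {
  cat("<network_definition> pivot ", x$pivot_node, "; ",
      length(x$reading_nodes), " reading nodes, ", length(x$hub_nodes),
      " hubs, ", length(x$subnetwork_nodes), " subnetwork nodes\n", sep = "")
  invisible(x)
}

#' Packaged region label sets
#'
#' `aal90_labels()` returns the 90-region AAL cortical/subcortical labels in
#' template order. `reading_network_labels()` returns the 13 left-hemisphere
#' reading-network regions (pars triangularis and opercularis of IFG,
#' insula, fusiform, supramarginal and angular gyri, Heschl's gyrus, STG,
#' MTG, ITG, superior temporal pole, Rolandic operculum and the thalamus).
#'
#' @return Character vector of labels.
#' @export
aal90_labels <- function() {
  readLines(system.file("extdata", "aal90_labels.txt",
                        package = "thalroute"))
}

#' @rdname aal90_labels
#' @export
reading_network_labels <- function() {
  readLines(system.file("extdata", "reading_regions_left.txt",
                        package = "thalroute"))
}

#' Hub-attached subnetwork
#'
#' Induced subgraph over the union of hub nodes and reading-network nodes.
#' Weights (and FA) are restricted to those rows and columns with no
#' re-thresholding: every subnetwork edge equals the corresponding entry of
#' the full matrix.
#'
#' @param x A [weighted_connectome()].
#' @param nd A [network_definition()]; all its nodes must exist in `x`.
#' @return A `weighted_connectome` over `nd$subnetwork_nodes`, in the order
#'   they appear in `x`.
#' @export
hub_attached_subnetwork <- function(x, nd) {
  stopifnot(inherits(x, "weighted_connectome"),
            inherits(nd, "network_definition"))
  if (!nd$pivot_node %in% x$labels) {
    stop("pivot node ", nd$pivot_node, " absent from connectome",
         call. = FALSE)
  }
  miss <- setdiff(nd$subnetwork_nodes, x$labels)
  if (length(miss) > 0) {
    stop("subnetwork nodes absent from connectome: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  keep <- x$labels[x$labels %in% nd$subnetwork_nodes]
  weighted_connectome(x$weights[keep, keep, drop = FALSE],
                      fa = if (!is.null(x$fa)) x$fa[keep, keep, drop = FALSE],
                      subject_id = x$subject_id)
}

#' Mean edge FA
#'
#' Arithmetic mean of per-edge FA over existing (nonzero-weight) edges, each
#' undirected edge counted once. With `scope = "subnetwork"` all edges of
#' the supplied network are used (pass the hub-attached subnetwork to get
#' the correlation covariate); with `scope = "pivot-incident"` only edges
#' touching the pivot node (the thalamocortical-connection covariate).
#'
#' @param x A [weighted_connectome()] with FA.
#' @param scope `"subnetwork"` or `"pivot-incident"`.
#' @param pivot Pivot label, required for `"pivot-incident"`.
#' @return Scalar mean FA.
#' @export
mean_edge_fa <- function(x, scope = c("subnetwork", "pivot-incident"),
                         pivot = NULL) {
  stopifnot(inherits(x, "weighted_connectome"))
  scope <- match.arg(scope)
  if (is.null(x$fa)) stop("connectome carries no FA matrix", call. = FALSE)
  present <- x$weights > 0
  if (scope == "pivot-incident") {
    if (is.null(pivot) || !pivot %in% x$labels) {
      stop("`pivot` must name a node for scope = \"pivot-incident\"",
           call. = FALSE)
    }
    mask <- matrix(FALSE, n_nodes(x), n_nodes(x))
    i <- match(pivot, x$labels)
    mask[i, ] <- TRUE
    mask[, i] <- TRUE
    present <- present & mask
  }
  sel <- present & upper.tri(present)
  if (!any(sel)) stop("no edges in requested scope", call. = FALSE)
  mean(x$fa[sel])
}

#' Normalized probabilistic connectivity index
#'
#' For probabilistic tractography from a seed region with `v_seed` voxels
#' and 5000 streamlines launched per voxel, the index
#' `I = log(waytotal) / log(5000 * v_seed)` normalizes the surviving
#' streamline count by seed size; it is 1 when every launched streamline
#' reaches the target and 0 when exactly one does. The value does not depend
#' on the logarithm base.
#'
#' @param waytotal Positive integer count of surviving streamlines.
#' @param v_seed Positive integer voxel count of the seed region.
#' @return The index (vectorized over inputs).
#' @export
normalized_connectivity_index <- function(waytotal, v_seed) {
  if (any(waytotal < 1)) {
    stop("`waytotal` must be >= 1 (0 means no connection; handle upstream)",
         call. = FALSE)
  }
  if (any(v_seed < 1)) stop("`v_seed` must be >= 1", call. = FALSE)
  log(waytotal) / log(5000 * v_seed)
}

#' Tracking success rate
#'
#' Percentage of subjects with at least one surviving (post-threshold)
#' connection from a seed to any reading-network region. Input is a long
#' table of candidate connections; the streamline threshold is applied
#' before counting, mirroring how deterministic-tractography success rates
#' are tabulated.
#'
#' @param connections Data frame with columns `subject_id` and
#'   `n_streamlines` (one row per candidate connection; subjects with no
#'   rows count as failures when `denominator` covers them).
#' @param min_streamlines Streamline threshold applied first (default 3).
#' @param denominator Number of subjects to divide by; defaults to the
#'   number of distinct subjects in `connections`. An explicit value covers
#'   cohorts where failed subjects contribute no rows.
#' @return Percentage in `[0, 100]`.
#' @export
tracking_success_rate <- function(connections, min_streamlines = 3,
                                  denominator = NULL) {
  stopifnot(is.data.frame(connections),
            all(c("subject_id", "n_streamlines") %in% names(connections)))
  if (nrow(connections) == 0 && is.null(denominator)) {
    stop("need at least one subject or an explicit `denominator`",
         call. = FALSE)
  }
  ok <- connections |>
    dplyr::filter(.data$n_streamlines >= min_streamlines) |>
    dplyr::distinct(.data$subject_id) |>
    nrow()
  denom <- denominator %||% dplyr::n_distinct(connections$subject_id)
  100 * ok / denom
}
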