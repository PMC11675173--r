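# Nodal efficiency measures, weight-to-length conversion and geodesics.
#
# CC and LE are implemented directly (they are the quantities under test and
# need both binary and Onnela-weighted variants with a common normalization);
# shortest paths go through igraph's Dijkstra.

normalized_weights <- function(x) {
  w <- x$weights
  mx <- max(w)
  if (mx > 0) w / mx else w
}

#' Clustering coefficient
#'
#' Fraction of closed triangles around a node. In `"binary"` mode this is
#' `2 T_i / (k_i (k_i - 1))` with `T_i` the number of triangles through node
#' `i` and `k_i` its degree. In `"weighted"` mode the Onnela form is used:
#' triangle intensity is the geometric mean of the three max-normalized edge
#' weights, so uniform weights reduce exactly to the binary value. Nodes of
#' degree below 2 score 0.
#'
#' @param x A thresholded [weighted_connectome()].
#' @param nodes Node labels (default all nodes).
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return Named numeric vector of coefficients.
#' @export
clustering_coefficient <- function(x, nodes = NULL,
                                   mode = c("weighted", "binary")) {
  stopifnot(inherits(x, "weighted_connectome"))
  mode <- match.arg(mode)
  nodes <- nodes %||% x$labels
  miss <- setdiff(nodes, x$labels)
  if (length(miss) > 0) {
    stop("unknown node(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- (x$weights > 0) * 1
  wh <- if (mode == "weighted") normalized_weights(x)^(1 / 3) else a
  k <- rowSums(a)
  # diag of wh^3 path products counts (ordered) triangles through each node
  tri <- diag(wh %*% wh %*% wh)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  names(cc) <- x$labels
  cc[nodes]
}

#' Local efficiency
#'
#' Mean inverse shortest-path length between a node's neighbours, with
#' paths computed inside the subgraph induced by the neighbours (the node
#' itself excluded, so trivial two-step detours through the centre do not
#' count). Degree below 2 scores 0. In `"weighted"` mode lengths come from
#' the reciprocal of max-normalized weights; `"binary"` uses unit lengths.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of efficiencies.
#' @export
local_efficiency <- function(x, nodes = NULL,
                             mode = c("weighted", "binary")) {
  stopifnot(inherits(x, "weighted_connectome"))
  mode <- match.arg(mode)
  nodes <- nodes %||% x$labels
  miss <- setdiff(nodes, x$labels)
  if (length(miss) > 0) {
    stop("unknown node(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  a <- x$weights > 0
  wn <- if (mode == "weighted") normalized_weights(x) else a * 1
  le <- vapply(nodes, function(v) {
    nb <- x$labels[a[v, ]]
    k <- length(nb)
    if (k < 2) return(0)
    sub <- wn[nb, nb, drop = FALSE]
    len <- ifelse(sub > 0, 1 / sub, Inf)
    g <- igraph::graph_from_adjacency_matrix(
      ifelse(is.finite(len), len, 0), mode = "undirected", weighted = TRUE
    )
    dmat <- igraph::distances(g, algorithm = "dijkstra")
    inv <- 1 / dmat[upper.tri(dmat)]
    inv[!is.finite(inv)] <- 0
    sum(inv) * 2 / (k * (k - 1))
  }, numeric(1))
  names(le) <- nodes
  le
}

#' Per-node metric table
#'
#' Tidy table of degree, strength, clustering coefficient and local
#' efficiency for every node of a connectome, ready to join with phenotype
#' tables.
#'
#' @inheritParams clustering_coefficient
#' @param network Label recorded in the `network` column (e.g.
#'   `"whole-brain"` or `"hub-attached"`).
#' @return A tibble with columns `subject_id`, `network`, `node`, `degree`,
#'   `strength`, `cc`, `le`, `mode`.
#' @export
node_metrics <- function(x, mode = c("weighted", "binary"),
                         network = "whole-brain") {
  stopifnot(inherits(x, "weighted_connectome"))
  mode <- match.arg(mode)
  tibble::tibble(
    subject_id = x$subject_id,
    network = network,
    node = x$labels,
    degree = unname(as.integer(rowSums(x$weights > 0))),
    strength = unname(rowSums(x$weights)),
    cc = unname(clustering_coefficient(x, mode = mode)),
    le = unname(local_efficiency(x, mode = mode)),
    mode = mode
  )
}

#' Convert streamline weights to edge lengths
#'
#' Routing and shortest-path computations need a length (cost) per edge
#' that decreases with connection strength. `"reciprocal"` uses
#' `d = 1 / w`; `"neglog"` uses `d = -log(w / max(w)) + epsilon`. Off-edge
#' entries are infinite.
#'
#' @param x A thresholded [weighted_connectome()].
#' @param transform `"reciprocal"` (default) or `"neglog"`.
#' @param epsilon Positive offset for `"neglog"` so the strongest edge keeps
#'   a positive length.
#' @return An object of class `length_matrix`: list with `lengths` (square
#'   matrix, `Inf` off edges) and `transform`.
#' @export
weight_to_length <- function(x, transform = c("reciprocal", "neglog"),
                             epsilon = 1e-6) {
  stopifnot(inherits(x, "weighted_connectome"))
  transform <- match.arg(transform)
  w <- x$weights
  on_edge <- w > 0
  if (any(w[on_edge] <= 0)) stop("nonpositive weight on an existing edge")
  d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
  if (any(on_edge)) {
    if (transform == "reciprocal") {
      d[on_edge] <- 1 / w[on_edge]
    } else {
      stopifnot(epsilon > 0)
      d[on_edge] <- -log(w[on_edge] / max(w)) + epsilon
    }
  }
  diag(d) <- Inf  # no self-loops: a walker must leave its node
  structure(list(lengths = d, transform = transform,
                 labels = rownames(w)),
            class = "length_matrix")
}

#' @export
print.length_matrix <- function(x, ...) {
  cat("<length_matrix> ", length(x$labels), " nodes, transform ",
      x$transform, "\n", sep = "")
  invisible(x)
}

#' Geodesic (shortest-path) distance matrix
#'
#' All-pairs shortest-path lengths over a [weight_to_length()] matrix,
#' computed with Dijkstra's algorithm. Unreachable pairs are `Inf`; the
#' diagonal is 0.
#'
#' @param d A `length_matrix`.
#' @return Square numeric matrix of geodesic distances.
#' @export
geodesic_matrix <- function(d) {
  stopifnot(inherits(d, "length_matrix"))
  len <- d$lengths
  if (any(len[is.finite(len)] < 0)) stop("negative edge length")
  adj <- ifelse(is.finite(len), len, 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  gm <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(gm) <- dimnames(len)
  gm
}
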