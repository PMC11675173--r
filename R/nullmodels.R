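# Randomized reference networks and cost normalization.
#
# Topology is rewired with degree-preserving double-edge swaps (igraph);
# the original weight multiset is then reassigned onto the new topology by
# rank-matching edge weights to the product of the original endpoint
# strengths, so degrees and the weight distribution are preserved exactly
# and strengths approximately.

#' Degree-, strength- and weight-preserving randomization
#'
#' Produces a randomized counterpart of a connectome that preserves the
#' node degree sequence and the edge-weight multiset exactly, and node
#' strengths approximately (weights are reassigned to the rewired topology
#' by iterative rank-matching against residual expected strengths).
#'
#' @param x A thresholded [weighted_connectome()].
#' @param n_swap_per_edge Double-edge swap attempts per edge (default 10).
#' @param seed Integer seed; same seed gives the same member.
#' @return A randomized `weighted_connectome` (FA is dropped).
#' @export
randomize_network <- function(x, n_swap_per_edge = 10, seed) {
  stopifnot(inherits(x, "weighted_connectome"))
  a <- x$weights > 0
  n_edges <- sum(a[upper.tri(a)])
  if (n_edges < 2) {
    warning("graph too small to swap; returning a copy", call. = FALSE)
    return(x)
  }
  with_seed(seed, {
    g <- igraph::graph_from_adjacency_matrix(a * 1, mode = "undirected")
    g <- igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE,
                                niter = n_swap_per_edge * n_edges))
    el <- igraph::as_edgelist(g, names = FALSE)
    s <- rowSums(x$weights)                       # original strengths
    wts <- sort(x$weights[upper.tri(x$weights) & x$weights > 0],
                decreasing = TRUE)
    m <- nrow(el)
    assigned <- numeric(m)
    resid <- s                                    # residual strength budget
    remaining <- seq_len(m)
    # heaviest weight goes to the edge whose endpoints have the largest
    # residual strength product; budgets shrink as weights are placed
    for (k in seq_len(m)) {
      sc <- resid[el[remaining, 1]] * resid[el[remaining, 2]]
      pick <- remaining[which.max(sc)]
      assigned[pick] <- wts[k]
      resid[el[pick, 1]] <- max(resid[el[pick, 1]] - wts[k], 0)
      resid[el[pick, 2]] <- max(resid[el[pick, 2]] - wts[k], 0)
      remaining <- remaining[remaining != pick]
    }
    w <- matrix(0, n_nodes(x), n_nodes(x),
                dimnames = dimnames(x$weights))
    w[el] <- assigned
    w[el[, c(2, 1), drop = FALSE]] <- assigned
    weighted_connectome(w, subject_id = x$subject_id)
  })
}

#' Ensemble of randomized networks
#'
#' @param x A thresholded [weighted_connectome()].
#' @param n_members Ensemble size (500 for analyses; smaller for tests).
#' @param n_swap_per_edge Swap attempts per edge for each member.
#' @param seed Integer seed; member `i` uses a sub-seed derived from it.
#' @return Object of class `null_ensemble`: list with `members` (list of
#'   connectomes), `parent_subject`, `seed`, `n_swap_per_edge`.
#' @export
null_ensemble <- function(x, n_members = 500, n_swap_per_edge = 10, seed) {
  stopifnot(inherits(x, "weighted_connectome"), n_members >= 1)
  members <- purrr::map(seq_len(n_members), function(i) {
    randomize_network(x, n_swap_per_edge,
                      seed = derive_seed(seed, paste0("null-", i)))
  })
  structure(list(members = members, parent_subject = x$subject_id,
                 seed = seed, n_swap_per_edge = n_swap_per_edge),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("<null_ensemble> ", length(x$members), " members (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Normalized cost curves against a null ensemble
#'
#' Divides the empirical pair-averaged cost curves by the ensemble mean of
#' the same curves computed on each randomized member, per `ln(lambda)`.
#' Ratios below 1 mark the lambda range where the empirical network routes
#' more cheaply than its randomized counterparts. Grid points where the
#' ensemble mean is zero or nonfinite are excluded with a message.
#'
#' @param x The empirical [weighted_connectome()].
#' @param ensemble A [null_ensemble()] of `x`.
#' @param pairs,grid,transform,null Passed to [cost_spectrum()] for both
#'   empirical and member curves.
#' @param member_stat `"mean"` (default) or `"median"` ensemble aggregation.
#' @return Tibble of class `normalized_cost_spectrum` with columns
#'   `ln_lambda`, `ratio_trans`, `ratio_info`, plus the per-member curves in
#'   attribute `member_curves`.
#' @export
normalized_cost_curves <- function(x, ensemble, pairs = NULL,
                                   grid = lambda_grid(),
                                   transform = "reciprocal",
                                   null = "lambda0",
                                   member_stat = c("mean", "median")) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  member_stat <- match.arg(member_stat)
  emp <- average_cost_curves(
    suppressMessages(cost_spectrum(x, pairs, grid, transform, null)))
  mem <- purrr::imap_dfr(ensemble$members, function(m, i) {
    suppressMessages(cost_spectrum(m, pairs, grid, transform, null)) |>
      average_cost_curves() |>
      dplyr::mutate(member = i)
  })
  stat <- if (member_stat == "mean") mean else stats::median
  denom <- mem |>
    dplyr::group_by(.data$ln_lambda) |>
    dplyr::summarise(rand_trans = stat(.data$c_trans),
                     rand_info = stat(.data$c_info), .groups = "drop")
  out <- dplyr::left_join(emp, denom, by = "ln_lambda") |>
    dplyr::mutate(ratio_trans = .data$c_trans / .data$rand_trans,
                  ratio_info = .data$c_info / .data$rand_info)
  bad <- !is.finite(out$ratio_trans) | !is.finite(out$ratio_info) |
    out$rand_trans <= 0 | out$rand_info <= 0
  if (any(bad)) {
    message(sum(bad), " grid point(s) excluded: degenerate ensemble cost")
    out <- out[!bad, ]
  }
  out <- dplyr::select(out, "ln_lambda", "ratio_trans", "ratio_info",
                       "c_trans", "c_info", "rand_trans", "rand_info")
  attr(out, "member_curves") <- mem
  attr(out, "n_members") <- length(ensemble$members)
  class(out) <- c("normalized_cost_spectrum", class(out))
  out
}

#' Efficient lambda window
#'
#' Grid points of a normalized cost spectrum where the ratio is strictly
#' below 1 — the lambda range in which the empirical network communicates
#' more cheaply than its randomized counterparts.
#'
#' @param ncs A [normalized_cost_curves()] result.
#' @param kind `"trans"` or `"info"`.
#' @return Sorted numeric vector of `ln_lambda` grid points (possibly
#'   empty, with a warning).
#' @export
efficient_lambda_window <- function(ncs, kind = c("trans", "info")) {
  kind <- match.arg(kind)
  ratio <- ncs[[paste0("ratio_", kind)]]
  win <- sort(ncs$ln_lambda[ratio < 1])
  if (length(win) == 0) {
    warning("no grid point with ", kind, " ratio < 1; empty window",
            call. = FALSE)
  }
  win
}

#' Window-averaged cost
#'
#' Arithmetic mean of a per-lambda cost over the grid points falling inside
#' a window. The window may be a closed `ln(lambda)` interval
#' (`c(lo, hi)`, e.g. the transmission window `c(-5.1, 0.15)` or the
#' information window `c(-0.14, 2.76)`) or an explicit set of grid points
#' from [efficient_lambda_window()].
#'
#' @param curve Data frame with `ln_lambda` and the cost column.
#' @param window Length-2 closed interval, or a vector of grid points.
#' @param value Name of the cost column to average (e.g. `"total"`,
#'   `"c_trans"`).
#' @return Scalar mean cost.
#' @export
window_average_cost <- function(curve, window, value) {
  stopifnot(is.data.frame(curve), value %in% names(curve),
            "ln_lambda" %in% names(curve))
  if (length(window) == 0) {
    stop("empty window: supply a nonempty interval or grid-point set",
         call. = FALSE)
  }
  inside <- if (length(window) == 2 && window[2] >= window[1]) {
    curve$ln_lambda >= window[1] & curve$ln_lambda <= window[2]
  } else {
    curve$ln_lambda %in% window
  }
  if (!any(inside)) {
    stop("no grid points inside the window", call. = FALSE)
  }
  mean(curve[[value]][inside])
}
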