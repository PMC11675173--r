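# The lambda-tuned stochastic routing model.
#
# For a signal at node i heading for target t, the probability of stepping
# to neighbour j is
#
#   P_lambda(Y = j | X = i, T = t)  proportional to  exp(-(lambda (d_ij + g_jt) + d_ij))
#
# where d_ij is the edge length (local topology) and g_jt the geodesic
# distance from j to the target (global topology). lambda = 0 gives an
# unbiased locally weight-driven walk; lambda -> Inf concentrates all mass
# on the neighbour minimizing d_ij + g_jt, i.e. the shortest-path next hop.
# Transmission cost is the expected walked distance of the absorbing walk;
# informational cost is the expected KL divergence (bits) from the null
# (lambda = 0) walk, accumulated over expected node visits. Both are exact,
# via direct solves against the transient block of the absorbing chain.

#' Grid of ln(lambda) values for cost spectra
#'
#' @param preset `"consistent"` (default): 30 equally spaced points on
#'   `ln(lambda)` in `[-5.1, 2.76]`, chosen so both cost-averaging windows
#'   (`[-5.1, 0.15]` for transmission, `[-0.14, 2.76]` for information) lie
#'   inside the grid. `"printed"`: the narrower `[-2.2, 1.45]` spectrum
#'   preset.
#' @param ln_min,ln_max,n Explicit bounds and step count, overriding the
#'   preset.
#' @return Strictly increasing numeric vector of `ln(lambda)` values.
#' @export
lambda_grid <- function(preset = c("consistent", "printed"),
                        ln_min = NULL, ln_max = NULL, n = 30) {
  preset <- match.arg(preset)
  if (is.null(ln_min) || is.null(ln_max)) {
    bounds <- switch(preset,
                     consistent = c(-5.1, 2.76),
                     printed = c(-2.2, 1.45))
    ln_min <- ln_min %||% bounds[1]
    ln_max <- ln_max %||% bounds[2]
  }
  stopifnot(ln_max > ln_min, n >= 2)
  seq(ln_min, ln_max, length.out = n)
}

# geodesic distances to one target (column of the geodesic matrix)
target_geodesics <- function(g, target) {
  if (!target %in% colnames(g)) stop("unknown target node ", target)
  g[, target]
}

#' Per-target transition model
#'
#' Builds the row-stochastic transition matrix of the routing walk towards
#' one target at one value of `ln(lambda)`. Nodes with no finite geodesic
#' route to the target are excluded from the transient set and listed in
#' the `dropped` field. The target row is absorbing. Numerical underflow at
#' large lambda is avoided by shifting each row's exponents by their
#' minimum before exponentiation, which leaves the normalized probabilities
#' unchanged.
#'
#' @param d A [weight_to_length()] `length_matrix`.
#' @param g A [geodesic_matrix()] over `d`.
#' @param ln_lambda Log of the tuning parameter; `-Inf` gives the
#'   `lambda = 0` unbiased walk.
#' @param target Target node label.
#' @param null Use `"lambda0"` for the routing model itself; `"uniform"`
#'   replaces the kernel with equal probability over neighbours (an
#'   alternative null).
#' @return Object of class `transition_model`: list with `P` (matrix over
#'   retained nodes, target row absorbing), `nodes`, `target`, `ln_lambda`,
#'   `dropped`.
#' @export
transition_model <- function(d, g, ln_lambda, target,
                             null = c("lambda0", "uniform")) {
  stopifnot(inherits(d, "length_matrix"))
  null <- match.arg(null)
  len <- d$lengths
  labels <- d$labels
  if (!target %in% labels) stop("unknown target node ", target)
  gt <- target_geodesics(g, target)
  keep <- is.finite(gt)
  dropped <- labels[!keep]
  nodes <- labels[keep]
  if (length(dropped) > 0) {
    message(length(dropped), " node(s) have no route to ", target,
            " and were dropped: ", paste(dropped, collapse = ", "))
  }
  lam <- if (identical(ln_lambda, -Inf)) 0 else exp(ln_lambda)
  m <- length(nodes)
  P <- matrix(0, m, m, dimnames = list(nodes, nodes))
  lsub <- len[nodes, nodes, drop = FALSE]
  gsub <- gt[nodes]
  for (i in seq_len(m)) {
    if (nodes[i] == target) next
    nb <- which(is.finite(lsub[i, ]))
    if (length(nb) == 0) next  # isolated within the retained set
    if (null == "uniform") {
      P[i, nb] <- 1 / length(nb)
    } else {
      expo <- lam * (lsub[i, nb] + gsub[nb]) + lsub[i, nb]
      expo <- expo - min(expo)  # row shift: cancels in the normalizer Z_it
      z <- exp(-expo)
      P[i, nb] <- z / sum(z)
    }
  }
  P[target, target] <- 1
  structure(list(P = P, nodes = nodes, target = target,
                 ln_lambda = ln_lambda, null = null, dropped = dropped),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model> target ", x$target, ", ln(lambda) = ",
      format(x$ln_lambda), ", ", length(x$nodes), " nodes\n", sep = "")
  invisible(x)
}

transient_block <- function(tm) {
  tr <- setdiff(tm$nodes, tm$target)
  list(tr = tr, Q = tm$P[tr, tr, drop = FALSE])
}

solve_fundamental <- function(Q, b) {
  A <- diag(nrow(Q)) - Q
  out <- tryCatch(solve(A, b, tol = 1e-12),
                  error = function(e) {
                    stop("transient system is numerically non-absorbing: ",
                         conditionMessage(e), call. = FALSE)
                  })
  out
}

#' Transmission cost of the routing walk
#'
#' Expected total edge length walked from each source to the target, under
#' the transition model. Computed exactly from the absorbing chain: with
#' `Q` the transient block and `r_i` the expected length of one step from
#' node `i` (including the absorbing step into the target), the cost vector
#' solves `(I - Q) c = r`.
#'
#' @param tm A [transition_model()].
#' @param d The `length_matrix` the model was built from.
#' @param source Optional source label(s); default all transient nodes.
#' @return Named numeric vector of costs (0 for the target itself).
#' @export
transmission_cost <- function(tm, d, source = NULL) {
  stopifnot(inherits(tm, "transition_model"), inherits(d, "length_matrix"))
  tb <- transient_block(tm)
  len <- d$lengths[tm$nodes, tm$nodes, drop = FALSE]
  step_len <- len
  step_len[!is.finite(step_len)] <- 0
  r_full <- rowSums(tm$P * step_len)
  cost <- stats::setNames(numeric(length(tm$nodes)), tm$nodes)
  if (length(tb$tr) > 0) {
    cost[tb$tr] <- as.numeric(solve_fundamental(tb$Q, r_full[tb$tr]))
  }
  if (is.null(source)) return(cost)
  miss <- setdiff(source, tm$nodes)
  if (length(miss) > 0) {
    stop("source node(s) not in transient set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cost[source]
}

#' Informational cost of the routing walk
#'
#' Expected number of bits needed to encode the routing strategy relative
#' to the null walk: the KL divergence (base 2) between the model's and the
#' null's transition distributions at each node, accumulated over the
#' expected visits of the absorbing walk. Solves `(I - Q) c = k` with
#' `k_i = KL(P_i || P0_i)`.
#'
#' @param tm A [transition_model()].
#' @param null_tm The null [transition_model()] for the same graph and
#'   target (typically `ln_lambda = -Inf`, the unbiased walk).
#' @param source Optional source label(s); default all transient nodes.
#' @return Named numeric vector of costs in bits.
#' @export
informational_cost <- function(tm, null_tm, source = NULL) {
  stopifnot(inherits(tm, "transition_model"),
            inherits(null_tm, "transition_model"))
  if (!identical(tm$target, null_tm$target) ||
      !identical(tm$nodes, null_tm$nodes)) {
    stop("null model must share the graph and target", call. = FALSE)
  }
  P <- tm$P
  P0 <- null_tm$P
  if (any(P > 0 & P0 == 0)) {
    bad <- which(P > 0 & P0 == 0, arr.ind = TRUE)[1, ]
    stop("null support violation at row ", tm$nodes[bad[1]], " -> ",
         tm$nodes[bad[2]], call. = FALSE)
  }
  ratio <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  pos <- P > 0
  ratio[pos] <- P[pos] * log2(P[pos] / P0[pos])
  k_full <- rowSums(ratio)
  tb <- transient_block(tm)
  cost <- stats::setNames(numeric(length(tm$nodes)), tm$nodes)
  if (length(tb$tr) > 0) {
    cost[tb$tr] <- as.numeric(solve_fundamental(tb$Q, k_full[tb$tr]))
  }
  if (is.null(source)) return(cost)
  miss <- setdiff(source, tm$nodes)
  if (length(miss) > 0) {
    stop("source node(s) not in transient set: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cost[source]
}

#' Expected node visits of the absorbing walk
#'
#' Row of the fundamental matrix for one source: expected number of times
#' each transient node is visited before absorption (the source counts its
#' own starting visit, so its entry is at least 1).
#'
#' @inheritParams transmission_cost
#' @param source Source node label.
#' @return Named numeric vector over transient nodes.
#' @export
expected_visits <- function(tm, source) {
  stopifnot(inherits(tm, "transition_model"))
  tb <- transient_block(tm)
  if (!source %in% tb$tr) stop("source not in transient set", call. = FALSE)
  e <- stats::setNames(numeric(length(tb$tr)), tb$tr)
  e[source] <- 1
  v <- solve_fundamental(t(tb$Q), e)
  stats::setNames(as.numeric(v), tb$tr)
}

# costs from all sources to one target across a grid: one transition model
# and one 2-RHS solve per (target, lambda)
costs_to_target <- function(d, g, target, grid,
                            null = c("lambda0", "uniform")) {
  null <- match.arg(null)
  null_tm <- if (null == "uniform") {
    transition_model(d, g, -Inf, target, null = "uniform")
  } else {
    suppressMessages(transition_model(d, g, -Inf, target))
  }
  purrr::map_dfr(grid, function(ll) {
    tm <- suppressMessages(transition_model(d, g, ll, target))
    ct <- transmission_cost(tm, d)
    ci <- informational_cost(tm, null_tm)
    tibble::tibble(source = tm$nodes, target = target, ln_lambda = ll,
                   c_trans = unname(ct), c_info = unname(ci))
  })
}

#' Cost spectrum over a lambda grid
#'
#' Computes transmission and informational costs for the requested
#' source-target pairs at every grid value of `ln(lambda)`. Pairs whose
#' source cannot reach the target are recorded with infinite cost and
#' excluded from averages (a message reports their count).
#'
#' @param x A thresholded [weighted_connectome()].
#' @param pairs Data frame with columns `source` and `target` (labels), or
#'   `NULL` for all ordered pairs of distinct nodes.
#' @param grid Numeric vector from [lambda_grid()].
#' @param transform Weight-to-length transform, see [weight_to_length()].
#' @param null Null-model choice for the informational cost.
#' @return A tibble of class `cost_spectrum` with columns `subject_id`,
#'   `source`, `target`, `ln_lambda`, `c_trans`, `c_info`, carrying the
#'   geodesic matrix in attribute `geodesics`.
#' @export
cost_spectrum <- function(x, pairs = NULL, grid = lambda_grid(),
                          transform = c("reciprocal", "neglog"),
                          null = c("lambda0", "uniform")) {
  stopifnot(inherits(x, "weighted_connectome"))
  transform <- match.arg(transform)
  null <- match.arg(null)
  d <- weight_to_length(x, transform)
  g <- geodesic_matrix(d)
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(source = x$labels, target = x$labels) |>
      dplyr::filter(.data$source != .data$target)
  }
  stopifnot(all(c("source", "target") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$source, pairs$target)), x$labels)
  if (length(miss) > 0) {
    stop("pair nodes absent from connectome: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  res <- purrr::map_dfr(unique(pairs$target), function(t) {
    all_costs <- costs_to_target(d, g, t, grid, null = null)
    want <- pairs$source[pairs$target == t]
    full <- tidyr::expand_grid(source = want, ln_lambda = grid) |>
      dplyr::mutate(target = t)
    dplyr::left_join(full, all_costs, by = c("source", "target", "ln_lambda")) |>
      dplyr::mutate(c_trans = ifelse(is.na(.data$c_trans), Inf, .data$c_trans),
                    c_info = ifelse(is.na(.data$c_info), Inf, .data$c_info)) |>
      dplyr::select("source", "target", "ln_lambda", "c_trans", "c_info")
  })
  n_unreach <- res |>
    dplyr::filter(!is.finite(.data$c_trans)) |>
    dplyr::distinct(.data$source, .data$target) |>
    nrow()
  if (n_unreach > 0) {
    message(n_unreach, " unreachable pair(s) recorded with infinite cost")
  }
  out <- tibble::as_tibble(res) |>
    dplyr::mutate(subject_id = x$subject_id, .before = 1)
  attr(out, "geodesics") <- g
  attr(out, "transform") <- transform
  attr(out, "null") <- null
  class(out) <- c("cost_spectrum", class(out))
  out
}

#' Pair-averaged cost curves
#'
#' Averages a [cost_spectrum()] over its finite pairs at each grid point,
#' giving the mean transmission and informational cost as a function of
#' `ln(lambda)`.
#'
#' @param spec A `cost_spectrum`.
#' @return Tibble with `ln_lambda`, `c_trans`, `c_info`, `n_pairs`.
#' @export
average_cost_curves <- function(spec) {
  spec |>
    dplyr::filter(is.finite(.data$c_trans), is.finite(.data$c_info)) |>
    dplyr::group_by(.data$ln_lambda) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     c_trans = mean(.data$c_trans),
                     c_info = mean(.data$c_info), .groups = "drop")
}

#' Source-target pairs through the pivot
#'
#' All (region, pivot) and (pivot, region) ordered pairs for the
#' reading-network regions of a [network_definition()], pivot excluded from
#' the region list.
#'
#' @param nd A `network_definition`.
#' @return Tibble with columns `source`, `target`.
#' @export
pivot_pairs <- function(nd) {
  stopifnot(inherits(nd, "network_definition"))
  regions <- setdiff(nd$reading_nodes, nd$pivot_node)
  dplyr::bind_rows(
    tibble::tibble(source = regions, target = nd$pivot_node),
    tibble::tibble(source = nd$pivot_node, target = regions)
  )
}

#' Pivot-aggregated communication cost
#'
#' Treats the pivot (left thalamus) as a temporary target and source node:
#' per `ln(lambda)` and per cost kind, sums the cost from every
#' reading-network region into the pivot and from the pivot out to every
#' region, and their total. Direction asymmetry is expected and preserved.
#'
#' @param spec A [cost_spectrum()] containing every pivot pair.
#' @param nd A [network_definition()].
#' @param aggregate `"sum"` (as defined) or `"mean"` over regions.
#' @return Tibble of class `thalamic_cost` with columns `subject_id`,
#'   `ln_lambda`, `cost` (`"trans"`/`"info"`), `to_pivot`, `from_pivot`,
#'   `total`.
#' @export
thalamic_cost <- function(spec, nd, aggregate = c("sum", "mean")) {
  stopifnot(inherits(nd, "network_definition"))
  aggregate <- match.arg(aggregate)
  want <- pivot_pairs(nd)
  have <- dplyr::distinct(spec, .data$source, .data$target)
  missing <- dplyr::anti_join(want, have, by = c("source", "target"))
  if (nrow(missing) > 0) {
    stop("spectrum is missing pivot pair(s): ",
         paste(missing$source, "->", missing$target, collapse = ", "),
         call. = FALSE)
  }
  agg <- if (aggregate == "sum") sum else mean
  long <- spec |>
    dplyr::semi_join(want, by = c("source", "target")) |>
    tidyr::pivot_longer(c("c_trans", "c_info"), names_to = "cost",
                        names_prefix = "c_", values_to = "value") |>
    dplyr::mutate(direction = ifelse(.data$target == nd$pivot_node,
                                     "to_pivot", "from_pivot"))
  out <- long |>
    dplyr::group_by(.data$subject_id, .data$ln_lambda, .data$cost,
                    .data$direction) |>
    dplyr::summarise(value = agg(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "value") |>
    dplyr::mutate(total = .data$to_pivot + .data$from_pivot)
  class(out) <- c("thalamic_cost", class(out))
  attr(out, "pivot") <- nd$pivot_node
  attr(out, "aggregate") <- aggregate
  out
}

#' Monte-Carlo walk simulation
#'
#' Simulates independent absorbing walks under a transition model and
#' reports the empirical mean walked distance and, when a null model is
#' given, the mean accumulated `log2` probability ratio versus the null —
#' the stochastic counterparts of [transmission_cost()] and
#' [informational_cost()] used as an oracle in tests.
#'
#' @param tm A [transition_model()].
#' @param d The matching `length_matrix`.
#' @param source Source node label.
#' @param n_walks Number of independent walks.
#' @param seed Integer seed (same seed, same output).
#' @param max_steps Cap on walk length; capped walks are counted in
#'   `n_capped` and excluded from the means with a warning.
#' @param null_tm Optional null [transition_model()].
#' @return List with `mean_distance`, `mean_log2_ratio` (NA without
#'   `null_tm`), `n_walks`, `n_capped`, `se_distance`.
#' @export
simulate_walks <- function(tm, d, source, n_walks, seed,
                           max_steps = 10000L, null_tm = NULL) {
  stopifnot(inherits(tm, "transition_model"), n_walks >= 1)
  nodes <- tm$nodes
  m <- length(nodes)
  src <- match(source, nodes)
  tgt <- match(tm$target, nodes)
  if (is.na(src)) stop("source not in transient set", call. = FALSE)
  len <- d$lengths[nodes, nodes, drop = FALSE]
  P <- tm$P
  logratio <- !is.null(null_tm)
  if (logratio) {
    P0 <- null_tm$P
    LR <- matrix(0, m, m)
    pos <- P > 0
    LR[pos] <- log2(P[pos] / P0[pos])
  }
  with_seed(seed, {
    cur <- rep.int(src, n_walks)
    dist_acc <- numeric(n_walks)
    lr_acc <- numeric(n_walks)
    active <- cur != tgt
    steps <- 0L
    while (any(active) && steps < max_steps) {
      idx <- which(active)
      for (node in unique(cur[idx])) {
        at <- idx[cur[idx] == node]
        nxt <- sample.int(m, length(at), replace = TRUE, prob = P[node, ])
        dist_acc[at] <- dist_acc[at] + len[node, nxt]
        if (logratio) lr_acc[at] <- lr_acc[at] + LR[node, nxt]
        cur[at] <- nxt
      }
      active <- cur != tgt
      steps <- steps + 1L
    }
    n_capped <- sum(active)
    if (n_capped > 0) {
      warning(n_capped, " walk(s) hit max_steps = ", max_steps,
              " without absorbing", call. = FALSE)
    }
    done <- !active
    list(
      mean_distance = mean(dist_acc[done]),
      mean_log2_ratio = if (logratio) mean(lr_acc[done]) else NA_real_,
      n_walks = n_walks,
      n_capped = n_capped,
      se_distance = stats::sd(dist_acc[done]) / sqrt(sum(done))
    )
  })
}
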