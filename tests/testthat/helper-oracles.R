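# Independent brute-force oracles, deliberately implemented with naive
# loops so they share no code path with the package.

# random symmetric integer-weight connectome (ER topology); an explicit
# weight set (e.g. the dyadic c(3, 6, 12, 24), which quantizes path
# lengths so suboptimal-route gaps are bounded away from zero) may replace
# the uniform integer draw
random_connectome <- function(n, p = 0.5, wmax = 9L, seed = 1,
                              weights_from = NULL) {
  withr::with_seed(seed, {
    w <- matrix(0L, n, n)
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (stats::runif(1) < p) {
        w[i, j] <- w[j, i] <- if (is.null(weights_from)) {
          sample.int(wmax, 1) + 2L  # weights >= 3
        } else {
          sample(weights_from, 1)
        }
      }
    }
    dimnames(w) <- list(paste0("n", 1:n), paste0("n", 1:n))
    weighted_connectome(w)
  })
}

# clustering coefficient by exhaustive triangle enumeration (binary)
bf_cc <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  tri <- 0
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
  }
  2 * tri / (k * (k - 1))
}

# all-pairs shortest paths by Floyd-Warshall on a length matrix
bf_floyd <- function(len) {
  n <- nrow(len)
  g <- len
  diag(g) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (g[i, k] + g[k, j] < g[i, j]) g[i, j] <- g[i, k] + g[k, j]
  }
  g
}

# local efficiency via Floyd-Warshall on the neighbour-induced subgraph
bf_le <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  sub <- ifelse(adj[nb, nb, drop = FALSE] > 0, 1, Inf)
  g <- bf_floyd(sub)
  tot <- 0
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    if (is.finite(g[a, b])) tot <- tot + 1 / g[a, b]
  }
  2 * tot / (k * (k - 1))
}

# value-iteration oracle: solves c = k + Q c by fixed-point iteration, a
# different algorithm from the package's direct linear solve
bf_value_iteration <- function(Q, k, tol = 1e-14, max_iter = 100000) {
  c_old <- numeric(length(k))
  for (it in seq_len(max_iter)) {
    c_new <- k + as.numeric(Q %*% c_old)
    if (max(abs(c_new - c_old)) < tol) return(unname(c_new))
    c_old <- c_new
  }
  stop("value iteration did not converge")
}

# exhaustive absorbing-walk enumeration with probability pruning: expected
# walked distance and expected log2 probability ratio from `source`.
# Only tractable on very small, sparse graphs (branching factor <= 2).
bf_walk_costs <- function(P, P0, len, nodes, source, target,
                          prune = 1e-13, max_depth = 400) {
  ed <- 0; elr <- 0; mass <- 0
  recurse <- function(cur, prob, dist, lr, depth) {
    if (cur == target) {
      ed <<- ed + prob * dist
      elr <<- elr + prob * lr
      mass <<- mass + prob
      return(invisible())
    }
    if (prob < prune || depth == 0) return(invisible())
    for (j in nodes) {
      pj <- P[cur, j]
      if (pj > 0) {
        recurse(j, prob * pj, dist + len[cur, j],
                lr + log2(pj / P0[cur, j]), depth - 1)
      }
    }
  }
  recurse(source, 1, 0, 0, max_depth)
  list(c_trans = ed, c_info = elr, mass = mass)
}

# Dijkstra next hop: the neighbour j of i minimizing d_ij + g_jt
bf_next_hop <- function(len, g, i, target) {
  nb <- which(is.finite(len[i, ]))
  nb[which.min(len[i, nb] + g[nb, target])]
}
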