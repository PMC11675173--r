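routing_setup <- function(x) {
  d <- weight_to_length(x)
  list(d = d, g = geodesic_matrix(d))
}

test_that("lambda grids are equally spaced with the documented bounds", {
  g <- lambda_grid()
  expect_length(g, 30)
  expect_equal(range(g), c(-5.1, 2.76))
  expect_true(all(abs(diff(diff(g))) < 1e-12))
  gp <- lambda_grid("printed")
  expect_equal(range(gp), c(-2.2, 1.45))
})

test_that("forced moves get probability one and symmetric ties split evenly", {
  p3 <- toy_fixture("path3")$connectome
  rs <- routing_setup(p3)
  for (ll in c(-3, 0, 2)) {
    tm <- transition_model(rs$d, rs$g, ll, "C")
    expect_equal(tm$P["A", "B"], 1)  # A's only neighbour
  }
  # equal-length neighbours with equal geodesics to the target
  w <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  w["A", "B"] <- w["B", "A"] <- 5
  w["A", "C"] <- w["C", "A"] <- 5
  w["B", "D"] <- w["D", "B"] <- 5
  w["C", "D"] <- w["D", "C"] <- 5
  sq <- weighted_connectome(w)
  rs2 <- routing_setup(sq)
  for (ll in c(-2, 0.5, 3)) {
    tm <- transition_model(rs2$d, rs2$g, ll, "D")
    expect_equal(tm$P["A", "B"], 0.5)
    expect_equal(tm$P["A", "C"], 0.5)
  }
})

test_that("rows are stochastic over neighbours and the target absorbs", {
  x <- random_connectome(10, p = 0.5, seed = 21)
  rs <- routing_setup(x)
  tm <- transition_model(rs$d, rs$g, 0.7, "n3")
  expect_equal(unname(rowSums(tm$P)), rep(1, 10))
  expect_equal(tm$P["n3", "n3"], 1)
  off_support <- tm$P > 0 & !is.finite(rs$d$lengths[tm$nodes, tm$nodes]) &
    row(tm$P) != match("n3", tm$nodes)
  expect_false(any(off_support))
})

test_that("at large lambda the modal next hop is the Dijkstra successor", {
  for (s in 1:50) {
    x <- random_connectome(10, p = 0.45, seed = 300 + s)
    rs <- routing_setup(x)
    tgt <- "n1"
    if (any(!is.finite(rs$g[, tgt]))) next
    tm <- transition_model(rs$d, rs$g, 8, tgt)
    len <- rs$d$lengths
    for (i in setdiff(tm$nodes, tgt)) {
      hop <- names(which.max(tm$P[i, ]))
      # the modal hop attains the minimal one-step-plus-geodesic cost
      # (ties between equally good successors are allowed)
      nb <- which(is.finite(len[i, ]))
      best <- min(len[i, nb] + rs$g[nb, tgt])
      expect_equal(len[i, hop] + rs$g[hop, tgt], best, tolerance = 1e-12)
    }
  }
})

test_that("single-edge costs are flat: distance d and zero bits at every lambda", {
  se <- toy_fixture("single_edge")
  rs <- routing_setup(se$connectome)
  null_tm <- transition_model(rs$d, rs$g, -Inf, "B")
  for (ll in lambda_grid()) {
    tm <- transition_model(rs$d, rs$g, ll, "B")
    expect_equal(unname(transmission_cost(tm, rs$d, "A")), se$expected$c_trans)
    expect_equal(unname(informational_cost(tm, null_tm, "A")),
                 se$expected$c_info)
  }
})

test_that("forced routes cost their path length and zero bits", {
  # star with the centre as target: every leaf has a single neighbour, so
  # every transient row is forced and the strategy equals the null walk
  star <- toy_fixture("star5")$connectome
  rs <- routing_setup(star)
  null_tm <- transition_model(rs$d, rs$g, -Inf, "A")
  for (ll in c(-2, 0, 3)) {
    tm <- transition_model(rs$d, rs$g, ll, "A")
    expect_equal(unname(transmission_cost(tm, rs$d, "B")),
                 rs$d$lengths["B", "A"])
    expect_equal(unname(informational_cost(tm, null_tm, "B")), 0)
  }
  # an undirected chain only approaches its path length as lambda grows
  # (at finite lambda the walker can step backwards)
  p3 <- toy_fixture("path3")$connectome
  rs3 <- routing_setup(p3)
  tm10 <- transition_model(rs3$d, rs3$g, 10, "C")
  expect_equal(unname(transmission_cost(tm10, rs3$d, "B")),
               rs3$d$lengths["B", "C"], tolerance = 1e-6)
  expect_gt(unname(transmission_cost(transition_model(rs3$d, rs3$g, 0, "C"),
                                     rs3$d, "B")),
            rs3$d$lengths["B", "C"])
  # a model compared against itself is free
  tm <- transition_model(rs3$d, rs3$g, 1.3, "C")
  expect_equal(unname(informational_cost(tm, tm, "A")), 0)
})

test_that("analytic costs equal exhaustive walk enumeration on a tiny graph", {
  # 3-node triangle with unequal weights: branching factor 2, enumerable
  w <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  w["A", "B"] <- w["B", "A"] <- 4
  w["B", "C"] <- w["C", "B"] <- 8
  w["A", "C"] <- w["C", "A"] <- 3
  rs <- routing_setup(weighted_connectome(w))
  null_tm <- transition_model(rs$d, rs$g, -Inf, "C")
  for (ll in c(-1, 0.5, 2)) {
    tm <- transition_model(rs$d, rs$g, ll, "C")
    bf <- bf_walk_costs(tm$P, null_tm$P, rs$d$lengths, tm$nodes, "A", "C")
    expect_gt(bf$mass, 1 - 1e-9)
    expect_equal(unname(transmission_cost(tm, rs$d, "A")), bf$c_trans,
                 tolerance = 1e-8)
    expect_equal(unname(informational_cost(tm, null_tm, "A")), bf$c_info,
                 tolerance = 1e-7)
  }
})

test_that("direct solves agree with a value-iteration oracle on random graphs", {
  for (s in 1:10) {
    x <- random_connectome(9, p = 0.5, seed = 40 + s)
    rs <- routing_setup(x)
    tgt <- "n1"
    null_tm <- transition_model(rs$d, rs$g, -Inf, tgt)
    for (ll in c(-1, 0.5, 2)) {
      tm <- transition_model(rs$d, rs$g, ll, tgt)
      tr <- setdiff(tm$nodes, tgt)
      Q <- tm$P[tr, tr]
      len <- rs$d$lengths[tm$nodes, tm$nodes]
      step_len <- ifelse(is.finite(len), len, 0)
      r <- rowSums(tm$P * step_len)[tr]
      expect_equal(unname(transmission_cost(tm, rs$d)[tr]),
                   bf_value_iteration(Q, r), tolerance = 1e-10)
      kl <- rowSums(ifelse(tm$P > 0,
                           tm$P * log2(tm$P / pmax(null_tm$P, 1e-300)),
                           0))[tr]
      expect_equal(unname(informational_cost(tm, null_tm)[tr]),
                   bf_value_iteration(Q, kl), tolerance = 1e-10)
    }
  }
})

test_that("transmission cost dominates the geodesic and approaches it", {
  x <- random_connectome(9, p = 0.5, seed = 77)
  rs <- routing_setup(x)
  tgt <- "n2"
  null_tm <- transition_model(rs$d, rs$g, -Inf, tgt)
  prev <- NULL
  for (ll in c(-4, -2, 0, 2, 4, 8)) {
    tm <- transition_model(rs$d, rs$g, ll, tgt)
    ct <- transmission_cost(tm, rs$d)
    others <- setdiff(tm$nodes, tgt)
    expect_true(all(ct[others] >= rs$g[others, tgt] - 1e-10))
    if (!is.null(prev)) expect_true(all(ct[others] <= prev[others] + 1e-8))
    prev <- ct
  }
  tm8 <- transition_model(rs$d, rs$g, 8, tgt)
  ct8 <- transmission_cost(tm8, rs$d)
  others <- setdiff(tm8$nodes, tgt)
  expect_lt(max(abs(ct8[others] - rs$g[others, tgt]) / rs$g[others, tgt]),
            1e-4)
})

test_that("informational cost vanishes at the null and grows with lambda", {
  x <- random_connectome(9, p = 0.5, seed = 78)
  rs <- routing_setup(x)
  tgt <- "n5"
  null_tm <- transition_model(rs$d, rs$g, -Inf, tgt)
  expect_equal(max(abs(informational_cost(null_tm, null_tm))), 0)
  prev <- NULL
  for (ll in lambda_grid()) {
    tm <- transition_model(rs$d, rs$g, ll, tgt)
    ci <- informational_cost(tm, null_tm)
    expect_true(all(ci >= -1e-12))
    if (!is.null(prev)) expect_true(all(ci >= prev - 1e-8))
    prev <- ci
  }
})

test_that("transition rows are equivariant under node relabelling", {
  x <- random_connectome(8, p = 0.5, seed = 90)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  w2 <- x$weights[perm, perm]
  y <- weighted_connectome(w2)
  rsx <- routing_setup(x); rsy <- routing_setup(y)
  tmx <- transition_model(rsx$d, rsx$g, 0.8, "n2")
  tmy <- transition_model(rsy$d, rsy$g, 0.8, "n2")
  expect_equal(tmy$P[tmx$nodes, tmx$nodes], tmx$P)
})

test_that("expected visits start at one and funnel through cut vertices", {
  x <- random_connectome(8, p = 0.6, seed = 91)
  rs <- routing_setup(x)
  tm <- transition_model(rs$d, rs$g, 0.3, "n1")
  v <- expected_visits(tm, "n6")
  expect_gte(v["n6"], 1)

  bridge <- toy_fixture("two_module_bridge")
  rsb <- routing_setup(bridge$connectome)
  tmb <- transition_model(rsb$d, rsb$g, 0.5, "D")  # target in module b
  for (src in bridge$expected$module_a) {
    vb <- expected_visits(tmb, src)
    expect_gte(vb[bridge$expected$bridge], 1)
  }
})

test_that("expected visits agree with simulated visit counts", {
  x <- random_connectome(7, p = 0.6, seed = 92)
  rs <- routing_setup(x)
  tm <- transition_model(rs$d, rs$g, 0.5, "n1")
  v <- expected_visits(tm, "n5")
  # simulate visits by hand with the package's walk engine probabilities
  n_sim <- 5000
  counts <- withr::with_seed(17, {
    out <- numeric(length(tm$nodes)); names(out) <- tm$nodes
    for (k in seq_len(n_sim)) {
      cur <- "n5"
      while (cur != "n1") {
        out[cur] <- out[cur] + 1
        cur <- sample(tm$nodes, 1, prob = tm$P[cur, ])
      }
    }
    out / n_sim
  })
  for (nd in names(v)) {
    se <- sqrt(max(counts[nd], 1 / n_sim) / n_sim) * 3 + 0.01
    expect_lt(abs(v[nd] - counts[nd]), 3 * se + 0.05 * v[nd])
  }
})

test_that("walk simulation is seed-deterministic and matches forced routes", {
  star <- toy_fixture("star5")$connectome
  rs <- routing_setup(star)
  tm <- transition_model(rs$d, rs$g, 1, "A")
  s1 <- simulate_walks(tm, rs$d, "C", 500, seed = 5)
  s2 <- simulate_walks(tm, rs$d, "C", 500, seed = 5)
  expect_identical(s1, s2)
  expect_equal(unname(s1$mean_distance), unname(rs$d$lengths["C", "A"]))
  expect_equal(s1$se_distance, 0)
})

test_that("walk estimates converge on the analytic transmission cost", {
  x <- random_connectome(8, p = 0.5, seed = 93)
  rs <- routing_setup(x)
  tm <- transition_model(rs$d, rs$g, 1, "n1")
  ct <- unname(transmission_cost(tm, rs$d, "n4"))
  small <- simulate_walks(tm, rs$d, "n4", 500, seed = 6)
  large <- simulate_walks(tm, rs$d, "n4", 20000, seed = 6)
  expect_lt(large$se_distance, small$se_distance / 4)
  expect_lt(abs(large$mean_distance - ct), 4 * large$se_distance)
})

test_that("cost spectra carry every pair at every grid point", {
  x <- random_connectome(8, p = 0.6, seed = 94)
  pairs <- tibble::tibble(source = c("n2", "n3"), target = c("n1", "n1"))
  spec <- cost_spectrum(x, pairs, grid = lambda_grid(n = 5))
  expect_equal(nrow(spec), 2 * 5)
  expect_true(all(is.finite(spec$c_trans)))
  curves <- average_cost_curves(spec)
  expect_equal(nrow(curves), 5)
})

test_that("unreachable pairs are recorded as infinite and excluded from curves", {
  w <- matrix(0, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
  w["A", "B"] <- w["B", "A"] <- 4
  w["C", "D"] <- w["D", "C"] <- 4
  x <- weighted_connectome(w)
  pairs <- tibble::tibble(source = c("A", "C"), target = c("B", "B"))
  expect_message(spec <- cost_spectrum(x, pairs, lambda_grid(n = 4)),
                 "unreachable")
  expect_true(all(is.infinite(spec$c_trans[spec$source == "C"])))
  expect_equal(unique(average_cost_curves(spec)$n_pairs), 1L)
})

test_that("thalamic cost sums both directions through the pivot", {
  x <- threshold_edges(generate_connectome(n_nodes = 20, density = 0.3,
                                           n_hubs = 2, degree_threshold = 12,
                                           seed = 8))
  labels <- node_labels(x)
  nd <- network_definition(reading_nodes = c(labels[1:4], labels[20]),
                           hub_nodes = character(), pivot_node = labels[20])
  grid <- lambda_grid(n = 6)
  spec <- suppressMessages(cost_spectrum(x, pivot_pairs(nd), grid))
  tc <- thalamic_cost(spec, nd)
  expect_equal(tc$total, tc$to_pivot + tc$from_pivot)
  # independent enumeration over the explicit pair list
  for (ll in grid) {
    for (kind in c("trans", "info")) {
      col <- paste0("c_", kind)
      to_p <- sum(spec[[col]][spec$target == labels[20] &
                              spec$ln_lambda == ll])
      from_p <- sum(spec[[col]][spec$source == labels[20] &
                                spec$ln_lambda == ll])
      row <- tc[tc$ln_lambda == ll & tc$cost == kind, ]
      expect_equal(row$to_pivot, to_p)
      expect_equal(row$from_pivot, from_p)
    }
  }
  # single-region definition reduces to a two-term sum
  nd1 <- network_definition(c(labels[3], labels[20]), character(), labels[20])
  tc1 <- thalamic_cost(spec, nd1)
  one <- tc1[tc1$ln_lambda == grid[1] & tc1$cost == "trans", ]
  expect_equal(one$total,
               spec$c_trans[spec$source == labels[3] &
                            spec$target == labels[20] &
                            spec$ln_lambda == grid[1]] +
               spec$c_trans[spec$source == labels[20] &
                            spec$target == labels[3] &
                            spec$ln_lambda == grid[1]])
  # missing pairs are reported by name
  nd_bad <- network_definition(c(labels[1:6], labels[20]), character(),
                               labels[20])
  expect_error(thalamic_cost(dplyr::filter(spec, .data$source != labels[1]),
                             nd_bad), "missing")
})

test_that("costs are not invariant to global weight rescaling", {
  # under the reciprocal transform, rescaling all weights rescales lengths
  # and geodesics but lambda is not rescaled with them, so the routing
  # strategy (and both costs) genuinely change; this guards against silent
  # normalization being introduced
  x <- random_connectome(9, p = 0.5, seed = 96)
  y <- weighted_connectome(x$weights * 3)
  rsx <- routing_setup(x); rsy <- routing_setup(y)
  tmx <- transition_model(rsx$d, rsx$g, 0.5, "n1")
  tmy <- transition_model(rsy$d, rsy$g, 0.5, "n1")
  nx <- transition_model(rsx$d, rsx$g, -Inf, "n1")
  ny <- transition_model(rsy$d, rsy$g, -Inf, "n1")
  ctx <- unname(transmission_cost(tmx, rsx$d, "n5"))
  cty <- unname(transmission_cost(tmy, rsy$d, "n5"))
  expect_false(isTRUE(all.equal(ctx, cty * 3, tolerance = 1e-8)))
  cix <- unname(informational_cost(tmx, nx, "n5"))
  ciy <- unname(informational_cost(tmy, ny, "n5"))
  expect_false(isTRUE(all.equal(cix, ciy, tolerance = 1e-8)))
})

test_that("direction asymmetry is preserved, not averaged away", {
  x <- random_connectome(9, p = 0.5, seed = 95)
  rs <- routing_setup(x)
  tm_to1 <- transition_model(rs$d, rs$g, 0.6, "n1")
  tm_to5 <- transition_model(rs$d, rs$g, 0.6, "n5")
  c_51 <- unname(transmission_cost(tm_to1, rs$d, "n5"))
  c_15 <- unname(transmission_cost(tm_to5, rs$d, "n1"))
  expect_false(isTRUE(all.equal(c_51, c_15, tolerance = 1e-6)))
})
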