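# Synthetic connectome cohorts and closed-form toy graphs.
#
# The generator emulates the statistical structure the analysis needs —
# hub-like high-degree nodes, modular periphery, integer streamline
# weights, per-subject jitter, covariates, and reading scores with a
# planted linear association to a pipeline-computed network metric. It
# makes no attempt at geometric realism.

#' Generate a synthetic connectome
#'
#' Builds a symmetric integer-weight connectome with a planted set of hub
#' nodes (degree strictly above `degree_threshold`) over a modular
#' periphery whose node degrees stay at or below the threshold, connected
#' after streamline thresholding. Generation is seed-deterministic.
#'
#' @param n_nodes Number of nodes (default 90; the AAL labels are used at
#'   that size).
#' @param density Target edge density of the periphery, in (0, 1).
#' @param n_hubs Number of planted hubs.
#' @param degree_threshold Hub degree cut-off the planting respects.
#' @param weight_range Integer range of edge weights (min at least the
#'   streamline threshold keeps the graph intact after thresholding).
#' @param labels Optional node labels.
#' @param hub_labels Optional labels forced into the planted hub set (e.g.
#'   the pivot region: the thalamus is itself a connectome hub); the
#'   remaining hubs are sampled.
#' @param seed Integer seed.
#' @param subject_id Identifier for the resulting connectome.
#' @return A [weighted_connectome()] with attribute `planted_hubs`.
#' @export
generate_connectome <- function(n_nodes = 90, density = 0.15, n_hubs = 6,
                                degree_threshold = 20,
                                weight_range = c(6L, 60L),
                                labels = NULL, hub_labels = NULL, seed,
                                subject_id = NA_character_) {
  if (density <= 0 || density >= 1) {
    stop("`density` must be in (0, 1)", call. = FALSE)
  }
  if (n_hubs >= n_nodes) stop("`n_hubs` must be < `n_nodes`", call. = FALSE)
  if (n_hubs > 0 && n_nodes <= degree_threshold + 1) {
    stop("cannot plant hubs of degree > ", degree_threshold, " with only ",
         n_nodes, " nodes", call. = FALSE)
  }
  if (density * (n_nodes - 1) > degree_threshold) {
    stop("`density` too high: expected peripheral degree exceeds the hub ",
         "threshold, planted hub set would not be recoverable",
         call. = FALSE)
  }
  labels <- labels %||% if (n_nodes == 90) aal90_labels() else
    paste0("R", seq_len(n_nodes))
  stopifnot(length(labels) == n_nodes)
  forced <- match(hub_labels, labels)
  if (any(is.na(forced))) {
    stop("`hub_labels` not among node labels: ",
         paste(hub_labels[is.na(forced)], collapse = ", "), call. = FALSE)
  }
  if (length(forced) > n_hubs) stop("more `hub_labels` than `n_hubs`")
  with_seed(seed, {
    hubs <- if (n_hubs > 0) {
      sort(c(forced, sample(setdiff(seq_len(n_nodes), forced),
                            n_hubs - length(forced))))
    } else integer()
    periph <- setdiff(seq_len(n_nodes), hubs)
    adj <- matrix(FALSE, n_nodes, n_nodes)
    deg <- integer(n_nodes)
    add_edge <- function(i, j) {
      adj[i, j] <<- TRUE; adj[j, i] <<- TRUE
      deg[i] <<- deg[i] + 1L; deg[j] <<- deg[j] + 1L
    }
    # hubs form a clique and reach past the degree threshold via random
    # peripheral partners whose own degree budget is reserved
    if (n_hubs >= 2) {
      for (a in seq_len(n_hubs - 1)) for (b in seq((a + 1), n_hubs)) {
        add_edge(hubs[a], hubs[b])
      }
    }
    for (h in hubs) {
      want <- degree_threshold + 1L + sample.int(4, 1) - deg[h]
      partners <- sample(setdiff(periph, which(adj[h, ])))
      for (p in partners) {
        if (want <= 0) break
        if (deg[p] < degree_threshold - 1L) {
          add_edge(h, p); want <- want - 1L
        }
      }
      if (deg[h] <= degree_threshold) {
        stop("infeasible parameters: could not raise hub degree above ",
             degree_threshold, call. = FALSE)
      }
    }
    # modular periphery, degree-capped
    n_modules <- max(2L, round(length(periph) / 15))
    module <- sample(rep_len(seq_len(n_modules), length(periph)))
    n_target <- round(density * length(periph) * (length(periph) - 1) / 2)
    tries <- 0L
    placed <- 0L
    while (placed < n_target && tries < 50 * n_target) {
      tries <- tries + 1L
      same <- stats::runif(1) < 0.8
      if (same) {
        mod <- sample.int(n_modules, 1)
        cand <- periph[module == mod]
        if (length(cand) < 2) next
        ij <- sample(cand, 2)
      } else {
        ij <- sample(periph, 2)
      }
      i <- ij[1]; j <- ij[2]
      if (adj[i, j]) next
      if (deg[i] >= degree_threshold - 1L || deg[j] >= degree_threshold - 1L) next
      add_edge(i, j)
      placed <- placed + 1L
    }
    # stitch disconnected components onto the largest one (via a hub when
    # available) without creating spurious hubs
    repeat {
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      comp <- igraph::components(g)
      if (comp$no == 1) break
      main <- which.max(comp$csize)
      other <- which(comp$membership != main)
      cand <- other[which.min(deg[other])]
      anchor_pool <- if (n_hubs > 0) hubs else {
        inmain <- which(comp$membership == main)
        inmain[deg[inmain] < degree_threshold - 1L]
      }
      if (length(anchor_pool) == 0 || deg[cand] >= degree_threshold) {
        stop("infeasible parameters: cannot connect components within the ",
             "degree budget", call. = FALSE)
      }
      add_edge(sample(anchor_pool, 1), cand)
    }
    w <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
    ut <- which(adj & upper.tri(adj), arr.ind = TRUE)
    vals <- sample(seq(weight_range[1], weight_range[2]), nrow(ut),
                   replace = TRUE)
    w[ut] <- vals
    w[ut[, c(2, 1), drop = FALSE]] <- vals
    out <- weighted_connectome(w, subject_id = subject_id)
    attr(out, "planted_hubs") <- labels[hubs]
    out
  })
}

#' Cohort simulation specification
#'
#' @param n_subjects Cohort size (default 64).
#' @param n_nodes Nodes per connectome (default 90).
#' @param planted_rho Correlation planted between the target metric and the
#'   target score, in (-1, 1).
#' @param target_metric One of `"cc_pivot"`, `"le_pivot"`, `"degree_pivot"`,
#'   `"strength_pivot"`, `"c_thal_trans"`, `"c_thal_info"`.
#' @param score_name Score column receiving the planted association.
#' @param score_mean,score_sd Standard-score scale of the planted score.
#' @param jitter_sd Log-normal SD of the per-subject multiplicative weight
#'   jitter.
#' @param density,n_hubs,weight_range,degree_threshold Template parameters,
#'   see [generate_connectome()]; the threshold also drives per-subject hub
#'   identification.
#' @param covariate_effects Optional named numeric vector of linear
#'   covariate slopes added to the planted score (names among
#'   `age_years`, `sex`, `handedness`, `mean_fa`).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 64, n_nodes = 90, planted_rho = 0.4,
                        target_metric = "cc_pivot", score_name = "pde_std",
                        score_mean = 100, score_sd = 15, jitter_sd = 0.15,
                        density = 0.15, n_hubs = 6,
                        weight_range = c(6L, 60L), degree_threshold = 20,
                        covariate_effects = NULL, seed = 1L) {
  stopifnot(abs(planted_rho) < 1, n_subjects >= 8)
  target_metric <- match.arg(target_metric,
                             c("cc_pivot", "le_pivot", "degree_pivot",
                               "strength_pivot", "c_thal_trans",
                               "c_thal_info"))
  structure(list(n_subjects = n_subjects, n_nodes = n_nodes,
                 planted_rho = planted_rho, target_metric = target_metric,
                 score_name = score_name, score_mean = score_mean,
                 score_sd = score_sd, jitter_sd = jitter_sd,
                 density = density, n_hubs = n_hubs,
                 weight_range = weight_range,
                 degree_threshold = degree_threshold,
                 covariate_effects = covariate_effects, seed = seed),
            class = "cohort_spec")
}

default_network_definition <- function(x, per_subject_hubs = TRUE,
                                       degree_threshold = 20) {
  labels <- node_labels(x)
  if (all(reading_network_labels() %in% labels)) {
    reading <- reading_network_labels()
    pivot <- "THA.L"
  } else {
    pivot <- labels[length(labels)]
    reading <- unique(c(labels[seq_len(min(6, length(labels) - 1))], pivot))
  }
  hubs <- if (per_subject_hubs) identify_hubs(x, degree_threshold) else
    character()
  network_definition(reading, hubs, pivot)
}

subject_metric <- function(x, spec_metric, nd,
                           window = c(-5.1, 0.15), grid = lambda_grid()) {
  pivot <- nd$pivot_node
  sub <- hub_attached_subnetwork(x, nd)
  switch(spec_metric,
    cc_pivot = unname(clustering_coefficient(sub, pivot)),
    le_pivot = unname(local_efficiency(sub, pivot)),
    degree_pivot = sum(sub$weights[pivot, ] > 0),
    strength_pivot = sum(sub$weights[pivot, ]),
    c_thal_trans = {
      spec <- suppressMessages(cost_spectrum(sub, pivot_pairs(nd), grid))
      tc <- thalamic_cost(spec, nd)
      window_average_cost(dplyr::filter(tc, .data$cost == "trans"),
                          window, "total")
    },
    c_thal_info = {
      spec <- suppressMessages(cost_spectrum(sub, pivot_pairs(nd), grid))
      tc <- thalamic_cost(spec, nd)
      window_average_cost(dplyr::filter(tc, .data$cost == "info"),
                          c(-0.14, 2.76), "total")
    },
    stop("unknown target metric: ", spec_metric)
  )
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

score_defaults <- function() {
  tibble::tribble(
    ~score, ~mean, ~sd,
    "swe_std", 93.0, 21.4,
    "pde_std", 92.7, 19.8,
    "pc_std", 90.0, 13.3,
    "ran_items_per_sec", 1.87, 0.48
  )
}

#' Generate a synthetic cohort
#'
#' Jitters a template connectome per subject (integer-preserving
#' multiplicative noise on edge weights, plus per-edge FA values), computes
#' the target network metric through the real analysis pipeline, and draws
#' the planted score as
#' `score = mean + sd * (rho * z_metric + sqrt(1 - rho^2) * eps)` with
#' `z_metric` the standardized metric and `eps` standard normal. The other
#' reading scores and the covariates (age uniform on 9-14 years, sex
#' Bernoulli 0.5, handedness Bernoulli 0.95 right, mean FA from the
#' generated edge FA) are drawn independently.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `connectomes`
#'   (named list of [weighted_connectome()]s with FA), `phenotypes`
#'   (tibble; scores, covariates, and the target-metric column), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- if (spec$n_nodes == 90) aal90_labels() else
    paste0("R", seq_len(spec$n_nodes))
  pivot <- if ("THA.L" %in% labels) "THA.L" else labels[length(labels)]
  template <- generate_connectome(
    n_nodes = spec$n_nodes, density = spec$density, n_hubs = spec$n_hubs,
    degree_threshold = spec$degree_threshold,
    weight_range = spec$weight_range, labels = labels, hub_labels = pivot,
    seed = derive_seed(spec$seed, "template"))
  subjects <- sprintf("sub-%03d", seq_len(spec$n_subjects))
  w0 <- template$weights
  ut <- upper.tri(w0) & w0 > 0
  connectomes <- purrr::map(seq_len(spec$n_subjects), function(i) {
    with_seed(derive_seed(spec$seed, paste0("subject-", i)), {
      w <- w0
      jit <- round(w0[ut] * exp(stats::rnorm(sum(ut), 0, spec$jitter_sd)))
      w[ut] <- pmax(jit, 0)
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      fa <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
      shift <- stats::rnorm(1, 0, 0.03)
      fav <- round(rtruncnorm1(sum(ut), 0.45 + shift, 0.05, 0.30, 0.60), 4)
      fa[ut] <- fav
      fa[lower.tri(fa)] <- t(fa)[lower.tri(fa)]
      fa[w == 0] <- 0
      weighted_connectome(w, fa = fa, subject_id = subjects[i])
    })
  })
  names(connectomes) <- subjects
  metric <- vapply(connectomes, function(x) {
    xt <- threshold_edges(x)
    nd <- default_network_definition(
      xt, degree_threshold = spec$degree_threshold)
    subject_metric(xt, spec$target_metric, nd)
  }, numeric(1))
  if (stats::sd(metric) < 1e-12) {
    stop("target metric is constant across subjects; increase `jitter_sd`",
         call. = FALSE)
  }
  mean_fa <- vapply(connectomes, function(x) {
    xt <- threshold_edges(x)
    nd <- default_network_definition(
      xt, degree_threshold = spec$degree_threshold)
    mean_edge_fa(hub_attached_subnetwork(xt, nd))
  }, numeric(1))
  pheno <- with_seed(derive_seed(spec$seed, "phenotypes"), {
    n <- spec$n_subjects
    z <- as.numeric(scale(metric))
    eps <- stats::rnorm(n)
    planted <- spec$score_mean + spec$score_sd *
      (spec$planted_rho * z + sqrt(1 - spec$planted_rho^2) * eps)
    out <- tibble::tibble(
      subject_id = subjects,
      age_years = stats::runif(n, 9, 14),
      sex = stats::rbinom(n, 1, 0.5),
      handedness = stats::rbinom(n, 1, 0.95),
      mean_fa = mean_fa
    )
    for (sc in score_defaults()$score) {
      if (sc == spec$score_name) next
      row <- score_defaults()[score_defaults()$score == sc, ]
      out[[sc]] <- stats::rnorm(n, row$mean, row$sd)
    }
    out[[spec$score_name]] <- planted
    if (!is.null(spec$covariate_effects)) {
      for (cv in names(spec$covariate_effects)) {
        out[[spec$score_name]] <- out[[spec$score_name]] +
          spec$covariate_effects[[cv]] * out[[cv]]
      }
    }
    out[[spec$target_metric]] <- metric
    out
  })
  structure(list(connectomes = connectomes, phenotypes = pheno,
                 spec = spec, template = template),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$connectomes), " subjects, ",
      x$spec$n_nodes, " nodes; planted rho = ", x$spec$planted_rho,
      " on ", x$spec$target_metric, " vs ", x$spec$score_name, "\n",
      sep = "")
  invisible(x)
}

#' Write and read a cohort in the package file formats
#'
#' Emits one weight TSV and one FA TSV per subject plus a phenotype CSV and
#' a JSON manifest recording the spec and seed, into `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$connectomes)) {
    write_connectome(cohort$connectomes[[id]],
                     file.path(dir, paste0(id, "_connectome.tsv")),
                     file.path(dir, paste0(id, "_fa.tsv")))
  }
  readr::write_csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  manifest <- cohort$spec
  manifest$weight_range <- as.numeric(manifest$weight_range)
  jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pheno <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                           show_col_types = FALSE)
  connectomes <- purrr::map(pheno$subject_id, function(id) {
    read_connectome(file.path(dir, paste0(id, "_connectome.tsv")),
                    file.path(dir, paste0(id, "_fa.tsv")),
                    subject_id = id)
  })
  names(connectomes) <- pheno$subject_id
  list(connectomes = connectomes, phenotypes = pheno)
}

#' Closed-form toy graphs
#'
#' Small named fixtures with hand-computable metric and cost values, used
#' throughout the test suite.
#'
#' @param name One of `"triangle"`, `"star5"`, `"path3"`, `"complete4"`,
#'   `"two_module_bridge"`, `"single_edge"`.
#' @return List with `connectome` and `expected` (named list of closed-form
#'   values).
#' @export
toy_fixture <- function(name) {
  mk <- function(edges, n, labels = LETTERS[seq_len(n)]) {
    w <- matrix(0, n, n, dimnames = list(labels, labels))
    for (e in edges) {
      w[e[[1]], e[[2]]] <- e[[3]]
      w[e[[2]], e[[1]]] <- e[[3]]
    }
    weighted_connectome(w, subject_id = name)
  }
  switch(name,
    triangle = list(
      connectome = mk(list(list(1, 2, 3), list(2, 3, 3), list(1, 3, 3)), 3),
      expected = list(cc = 1, le = 1)
    ),
    star5 = list(
      connectome = mk(purrr::map(2:6, function(i) list(1, i, 3)), 6),
      expected = list(cc_center = 0, le_center = 0, degree_center = 5)
    ),
    path3 = list(
      # weights 3 and 6: reciprocal lengths 1/3 and 1/6, so g(A,C) = 1/2
      connectome = mk(list(list(1, 2, 3), list(2, 3, 6)), 3),
      expected = list(g_AC = 1 / 3 + 1 / 6)
    ),
    complete4 = list(
      connectome = mk({
        p <- utils::combn(4, 2)
        purrr::map(seq_len(ncol(p)), function(k) list(p[1, k], p[2, k], 3))
      }, 4),
      expected = list(cc = 1, le = 1)
    ),
    two_module_bridge = list(
      # two triangles joined through a single cut vertex E: every
      # cross-module route passes E
      connectome = mk(list(
        list(1, 2, 3), list(2, 3, 3), list(1, 3, 3),
        list(4, 5, 3), list(5, 6, 3), list(4, 6, 3),
        list(3, 7, 3), list(4, 7, 3)
      ), 7, labels = c("A", "B", "C", "D", "E2", "F", "E")),
      expected = list(bridge = "E", module_a = c("A", "B", "C"),
                      module_b = c("D", "E2", "F"))
    ),
    single_edge = list(
      connectome = mk(list(list(1, 2, 4)), 2),
      expected = list(d = 0.25, c_trans = 0.25, c_info = 0)
    ),
    stop("unknown fixture: ", name, call. = FALSE)
  )
}
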