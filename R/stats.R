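# Brain-behaviour statistics: partial correlations with permutation-based
# family-wise error correction, and hierarchical regression ladders.
# Model fits go through lm / least squares; the permutation scheme is
# Freedman-Lane on outcome residuals with a family-wise max-|r| statistic.

residualize <- function(v, Z) {
  X <- cbind(`(Intercept)` = 1, Z)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_cols <- colnames(X)[qr_x$pivot[seq(qr_x$rank + 1, ncol(X))]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  qr.resid(qr_x, v)
}

#' Partial correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares projection on an intercept plus the covariates, with a
#' two-sided p-value from the t distribution on `n - k - 2` degrees of
#' freedom (`k` covariates).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariates;
#'   `NULL` reduces to the plain Pearson correlation.
#' @return Tibble with columns `estimate`, `p.value`, `n`, `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  Z <- if (is.null(covariates)) {
    matrix(numeric(0), n, 0)
  } else {
    as.matrix(covariates)
  }
  k <- ncol(Z)
  if (n <= k + 2) {
    stop("need n > number of covariates + 2 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  rx <- residualize(x, Z)
  ry <- residualize(y, Z)
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  tibble::tibble(estimate = r, p.value = p, n = n, df = df)
}

#' Covariate set for a reading score
#'
#' Standard scores (SWE, PDE, passage comprehension) are age-normed, so
#' their partial correlations control for sex, mean FA within the
#' hub-attached reading network and handedness. RAN (items per second) is
#' not age-normed, so age joins the set. Covariates that are constant in
#' the supplied cohort (e.g. handedness in an all-right-handed sample) are
#' dropped with a warning.
#'
#' @param score One of `"swe_std"`, `"pde_std"`, `"pc_std"`,
#'   `"ran_items_per_sec"`.
#' @param cohort Optional cohort data frame used to drop constant columns.
#' @param ran_covariates For RAN, `"full"` (default: age, sex, mean FA,
#'   handedness) or `"age_only"`.
#' @return Character vector of covariate column names.
#' @export
covariate_set <- function(score, cohort = NULL,
                          ran_covariates = c("full", "age_only")) {
  ran_covariates <- match.arg(ran_covariates)
  std_scores <- c("swe_std", "pde_std", "pc_std")
  covs <- if (score %in% std_scores) {
    c("sex", "mean_fa", "handedness")
  } else if (score == "ran_items_per_sec") {
    if (ran_covariates == "full") {
      c("age_years", "sex", "mean_fa", "handedness")
    } else {
      "age_years"
    }
  } else {
    stop("unknown score: ", score, call. = FALSE)
  }
  if (!is.null(cohort)) {
    const <- covs[vapply(covs, function(v) {
      length(unique(cohort[[v]])) < 2
    }, logical(1))]
    if (length(const) > 0) {
      warning("dropping constant covariate(s): ",
              paste(const, collapse = ", "), call. = FALSE)
      covs <- setdiff(covs, const)
    }
  }
  covs
}

#' Permutation-corrected partial correlations
#'
#' Tests a family of (network metric, reading score) pairs by partial
#' correlation and corrects for the family-wise error rate with a
#' max-statistic Monte-Carlo permutation scheme: in each permutation the
#' outcome residuals (after covariate projection, Freedman-Lane) are
#' shuffled with a common permutation across tests, the partial
#' correlations are recomputed, and the family-wise maximum `|r|` forms the
#' null. Corrected p-values use the add-one convention
#' `(1 + #[max |r*| >= |r|]) / (1 + n_perm)`.
#'
#' @param cohort Data frame with one row per subject holding the metric,
#'   score and covariate columns.
#' @param metrics Character vector of metric column names.
#' @param scores Character vector of score column names.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; same seed gives identical output.
#' @param ran_covariates Passed to [covariate_set()].
#' @return Tibble of class `stat_report`: one row per test with `metric`,
#'   `score`, `estimate`, `p.value` (parametric, uncorrected), `p.fwe`,
#'   `n`, `covariates`.
#' @export
permutation_fwe <- function(cohort, metrics, scores, n_perm = 10000, seed,
                            ran_covariates = "full") {
  stopifnot(is.data.frame(cohort), length(metrics) >= 1,
            length(scores) >= 1, n_perm >= 100)
  tests <- tidyr::expand_grid(metric = metrics, score = scores)
  n <- nrow(cohort)
  prep <- purrr::pmap(tests, function(metric, score) {
    covs <- suppressWarnings(
      covariate_set(score, cohort, ran_covariates = ran_covariates))
    Z <- as.matrix(cohort[covs])
    rx <- residualize(cohort[[metric]], Z)
    if (stats::sd(rx) < 1e-12) {
      stop("metric ", metric, " has no variance after covariate ",
           "adjustment; exclude it from the family", call. = FALSE)
    }
    ry <- residualize(cohort[[score]], Z)
    list(rx = rx / sqrt(sum(rx^2)), ry = ry, Z = Z, covs = covs)
  })
  observed <- purrr::map2_dfr(
    seq_len(nrow(tests)), prep,
    function(i, pr) {
      pc <- partial_correlation(cohort[[tests$metric[i]]],
                                cohort[[tests$score[i]]],
                                cohort[pr$covs])
      dplyr::mutate(pc, metric = tests$metric[i], score = tests$score[i],
                    covariates = paste(pr$covs, collapse = "+"))
    })
  # Freedman-Lane: y* = Z beta + pi(e); residualizing y* on Z leaves the
  # projected permuted residuals, so r* = cor(rx, M_Z pi(e)).
  perms <- with_seed(seed, {
    replicate(n_perm, sample.int(n), simplify = FALSE)
  })
  r_null <- matrix(NA_real_, n_perm, nrow(tests))
  for (j in seq_len(nrow(tests))) {
    pr <- prep[[j]]
    E <- vapply(perms, function(p) pr$ry[p], numeric(n))
    E <- E - cbind(1, pr$Z) %*%
      qr.coef(qr(cbind(1, pr$Z)), E)            # M_Z applied columnwise
    E <- sweep(E, 2, sqrt(colSums(E^2)), "/")
    r_null[, j] <- abs(as.numeric(crossprod(pr$rx, E)))
  }
  max_null <- apply(r_null, 1, max)
  out <- observed |>
    dplyr::mutate(
      p.fwe = purrr::map_dbl(.data$estimate, function(r) {
        (1 + sum(max_null >= abs(r))) / (1 + n_perm)
      })
    ) |>
    dplyr::select("metric", "score", "estimate", "p.value", "p.fwe",
                  "n", "df", "covariates")
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "max_null") <- max_null
  attr(out, "coding") <- "sex: 0 = male, 1 = female; handedness: 0 = left, 1 = right"
  class(out) <- c("stat_report", class(out))
  out
}

#' Hierarchical (nested) regression ladder
#'
#' Fits a sequence of nested ordinary-least-squares models, each adding one
#' block of predictors, and tests the increment: `R^2`, the change
#' `Delta R^2` over the previous model, and the F test of the change,
#' `F = (Delta R^2 / q) / ((1 - R^2_current) / (n - p_current - 1))` with
#' `q` the block size.
#'
#' @param data Data frame of subjects.
#' @param response Name of the outcome column.
#' @param blocks Named list of character vectors; block `i` enters at model
#'   `i`. Blocks must not overlap.
#' @return Tibble of class `regression_ladder`: one row per model with
#'   `model`, `predictors`, `r.squared`, `delta.r.squared`, `f.change`,
#'   `p.change`, `df1`, `df2`, `n`.
#' @export
hierarchical_regression <- function(data, response, blocks) {
  stopifnot(is.data.frame(data), response %in% names(data),
            length(blocks) >= 1)
  all_pred <- unlist(blocks)
  if (anyDuplicated(all_pred)) {
    stop("blocks overlap: ", paste(unique(all_pred[duplicated(all_pred)]),
                                   collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  if (n - 2 <= length(all_pred)) {
    stop("too many cumulative predictors (", length(all_pred),
         ") for n = ", n, call. = FALSE)
  }
  if (is.null(names(blocks))) {
    names(blocks) <- paste0("Model ", seq_along(blocks))
  }
  y <- data[[response]]
  r2_prev <- 0
  rows <- purrr::imap(blocks, function(block, label) {
    idx <- seq_len(which(names(blocks) == label))
    preds <- unlist(blocks[idx])
    X <- as.matrix(data[preds])
    qr_x <- qr(cbind(1, X))
    if (qr_x$rank < ncol(X) + 1) {
      stop("collinearity in cumulative design at ", label, call. = FALSE)
    }
    res <- qr.resid(qr_x, y)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    q <- length(block)
    p_full <- length(preds)
    df2 <- n - p_full - 1
    dr2 <- r2 - r2_prev
    f <- (dr2 / q) / ((1 - r2) / df2)
    p <- stats::pf(f, q, df2, lower.tail = FALSE)
    r2_prev <<- r2
    tibble::tibble(model = label,
                   predictors = paste(block, collapse = "+"),
                   r.squared = r2, delta.r.squared = dr2,
                   f.change = f, p.change = p,
                   df1 = q, df2 = df2, n = n)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "response") <- response
  class(out) <- c("regression_ladder", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stat report or regression ladder
#'
#' @param x A `stat_report` or `regression_ladder`.
#' @param ... Unused.
#' @return A plain tibble of the per-test / per-model rows.
#' @export
tidy.stat_report <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.stat_report
#' @export
tidy.regression_ladder <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.stat_report
#' @export
glance.stat_report <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x), n_perm = attr(x, "n_perm"),
                 seed = attr(x, "seed"),
                 n_significant_fwe = sum(x$p.fwe < 0.05))
}

#' @rdname tidy.stat_report
#' @export
glance.regression_ladder <- function(x, ...) {
  tibble::tibble(response = attr(x, "response"), n_models = nrow(x),
                 r.squared.final = x$r.squared[nrow(x)], n = x$n[1])
}

#' @export
print.stat_report <- function(x, ...) {
  cat("<stat_report> ", nrow(x), " tests, ", attr(x, "n_perm"),
      " permutations\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
print.regression_ladder <- function(x, ...) {
  cat("<regression_ladder> response: ", attr(x, "response"), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}
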