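test_that("partial correlation reduces to Pearson without covariates", {
  withr::with_seed(1, {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  })
  pc <- partial_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(pc$estimate, unname(ct$estimate))
  expect_equal(pc$p.value, ct$p.value, tolerance = 1e-12)
  expect_equal(partial_correlation(x, x)$estimate, 1)
})

test_that("partial correlation matches the residualize-then-correlate oracle", {
  # fixed 10-subject table, two covariates
  tab <- data.frame(
    x = c(3.1, 2.7, 5.5, 4.2, 6.0, 1.9, 3.3, 4.8, 5.1, 2.2),
    y = c(101, 95, 118, 104, 120, 88, 97, 111, 116, 90),
    z1 = c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1),
    z2 = c(10.2, 11.5, 9.8, 12.0, 10.7, 9.1, 10.9, 11.2, 9.5, 12.4))
  pc <- partial_correlation(tab$x, tab$y, tab[c("z1", "z2")])
  rx <- stats::residuals(stats::lm(x ~ z1 + z2, tab))
  ry <- stats::residuals(stats::lm(y ~ z1 + z2, tab))
  expect_equal(pc$estimate, stats::cor(rx, ry), tolerance = 1e-12)
  expect_equal(pc$df, 10 - 2 - 2)
  # p from the t distribution on n - k - 2 df
  tval <- pc$estimate * sqrt(pc$df / (1 - pc$estimate^2))
  expect_equal(pc$p.value, 2 * stats::pt(-abs(tval), pc$df))
})

test_that("partial correlation is affine-invariant", {
  withr::with_seed(2, {
    x <- rnorm(40); y <- rnorm(40); z <- matrix(rnorm(80), 40)
  })
  a <- partial_correlation(x, y, z)
  b <- partial_correlation(3 * x - 7, -2 * y + 1, 10 * z + 5)
  expect_equal(abs(a$estimate), abs(b$estimate), tolerance = 1e-12)
})

test_that("rank-deficient covariates are refused with the column named", {
  withr::with_seed(3, {
    x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  })
  Z <- cbind(a = z, b = 2 * z)
  expect_error(partial_correlation(x, y, Z), "collinear")
  expect_error(partial_correlation(x[1:3], y[1:3], Z[1:3, ]), "n >")
})

test_that("covariate sets follow the age-norming of each score", {
  expect_setequal(covariate_set("ran_items_per_sec"),
                  c("age_years", "sex", "mean_fa", "handedness"))
  expect_setequal(covariate_set("pde_std"), c("sex", "mean_fa", "handedness"))
  expect_setequal(covariate_set("ran_items_per_sec",
                                ran_covariates = "age_only"), "age_years")
  expect_error(covariate_set("iq"), "unknown score")
  # all-right-handed cohorts drop the constant covariate
  cohort <- tibble::tibble(sex = c(0, 1, 0), mean_fa = c(.4, .5, .45),
                           handedness = c(1, 1, 1))
  expect_warning(cs <- covariate_set("swe_std", cohort), "handedness")
  expect_setequal(cs, c("sex", "mean_fa"))
})

make_cohort <- function(n = 40, rho = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- rnorm(n)
    tibble::tibble(
      subject_id = sprintf("s%03d", 1:n),
      metric_a = m,
      metric_b = 0.7 * m + 0.3 * rnorm(n),
      age_years = runif(n, 9, 14),
      sex = rbinom(n, 1, 0.5),
      handedness = rbinom(n, 1, 0.9),
      mean_fa = runif(n, 0.35, 0.55),
      pde_std = 100 + 15 * (rho * m + sqrt(1 - rho^2) * rnorm(n)),
      swe_std = rnorm(n, 100, 15))
  })
}

test_that("permutation FWE is seed-reproducible and orders corrected p by |r|", {
  cohort <- make_cohort(40, rho = 0.5, seed = 4)
  a <- permutation_fwe(cohort, c("metric_a", "metric_b"),
                       c("pde_std", "swe_std"), n_perm = 300, seed = 9)
  b <- permutation_fwe(cohort, c("metric_a", "metric_b"),
                       c("pde_std", "swe_std"), n_perm = 300, seed = 9)
  expect_identical(tidy(a), tidy(b))
  expect_true(all(a$p.fwe >= a$p.value - 1 / 301))
  ord <- order(abs(a$estimate), decreasing = TRUE)
  expect_true(all(diff(a$p.fwe[ord]) >= 0))
  expect_true(all(a$p.fwe > 0 & a$p.fwe <= 1))
})

test_that("a singleton family corrects to about the uncorrected p", {
  cohort <- make_cohort(50, rho = 0.35, seed = 5)
  rep1 <- permutation_fwe(cohort, "metric_a", "pde_std",
                          n_perm = 2000, seed = 10)
  expect_lt(abs(rep1$p.fwe - rep1$p.value), 0.03)
})

test_that("degenerate metrics are refused with advice", {
  cohort <- make_cohort(30, seed = 6)
  cohort$flat <- 1
  expect_error(permutation_fwe(cohort, "flat", "pde_std", 200, seed = 1),
               "no variance")
})

test_that("regression ladder matches a from-scratch normal-equations oracle", {
  # small fixed dataset, 8 points
  dat <- data.frame(
    y = c(12.1, 9.8, 14.3, 11.0, 15.2, 8.7, 13.5, 10.4),
    a = c(1.2, 0.8, 1.9, 1.1, 2.2, 0.5, 1.7, 0.9),
    b = c(3.0, 2.1, 4.2, 2.8, 4.8, 1.9, 3.9, 2.5),
    c = c(0, 1, 0, 1, 0, 1, 0, 1))
  ladder <- hierarchical_regression(dat, "y", list(m1 = "a", m2 = c("b", "c")))
  oracle_r2 <- function(X, y) {
    X1 <- cbind(1, X)
    beta <- solve(t(X1) %*% X1, t(X1) %*% y)
    res <- y - X1 %*% beta
    1 - sum(res^2) / sum((y - mean(y))^2)
  }
  r2_1 <- oracle_r2(as.matrix(dat["a"]), dat$y)
  r2_2 <- oracle_r2(as.matrix(dat[c("a", "b", "c")]), dat$y)
  expect_equal(ladder$r.squared, c(r2_1, r2_2), tolerance = 1e-10)
  expect_equal(ladder$delta.r.squared, c(r2_1, r2_2 - r2_1),
               tolerance = 1e-10)
  f2 <- ((r2_2 - r2_1) / 2) / ((1 - r2_2) / (8 - 3 - 1))
  expect_equal(ladder$f.change[2], f2, tolerance = 1e-10)
  expect_equal(ladder$p.change[2],
               stats::pf(f2, 2, 4, lower.tail = FALSE), tolerance = 1e-10)
  # cross-check the change test against anova() on nested lm fits
  m1 <- stats::lm(y ~ a, dat); m2 <- stats::lm(y ~ a + b + c, dat)
  an <- stats::anova(m1, m2)
  expect_equal(ladder$f.change[2], an$F[2], tolerance = 1e-10)
  expect_equal(ladder$p.change[2], an$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("orthogonal blocks decompose R squared additively", {
  withr::with_seed(7, {
    X <- qr.Q(qr(matrix(rnorm(40 * 3), 40)))  # orthonormal columns
    y <- X %*% c(2, -1, 0.5) + rnorm(40, sd = 0.5)
    dat <- data.frame(y = y, p1 = X[, 1], p2 = X[, 2], p3 = X[, 3])
  })
  ladder <- hierarchical_regression(dat, "y",
                                    list(b1 = "p1", b2 = c("p2", "p3")))
  full <- summary(stats::lm(y ~ p1 + p2 + p3, dat))$r.squared
  expect_equal(sum(ladder$delta.r.squared), full, tolerance = 1e-10)

  # a block orthogonal to y and the earlier block adds nothing
  withr::with_seed(8, {
    y2 <- rnorm(40)
    p <- rnorm(40)
  })
  resid_p <- stats::residuals(stats::lm(p ~ y2))
  dat2 <- data.frame(y = y2, p1 = resid_p)
  lad2 <- hierarchical_regression(dat2, "y", list(b1 = "p1"))
  expect_lt(lad2$delta.r.squared[1], 0.03)
})

test_that("R squared never decreases along the ladder", {
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      dat <- as.data.frame(matrix(rnorm(35 * 5), 35))
      names(dat) <- c("y", "a", "b", "c", "d")
    })
    lad <- hierarchical_regression(dat, "y",
                                   list(m1 = c("a", "b"), m2 = "c", m3 = "d"))
    expect_true(all(diff(lad$r.squared) >= -1e-12))
    expect_true(all(lad$delta.r.squared >= -1e-12))
  }
})

test_that("overlapping or collinear blocks are refused", {
  dat <- data.frame(y = rnorm(20), a = rnorm(20))
  dat$b <- dat$a * 2
  expect_error(hierarchical_regression(dat, "y", list("a", c("a", "b"))),
               "overlap")
  expect_error(hierarchical_regression(dat, "y", list(m1 = "a", m2 = "b")),
               "collinear")
})

test_that("tidiers return plain tibbles with the reported columns", {
  cohort <- make_cohort(30, rho = 0.4, seed = 9)
  rep1 <- permutation_fwe(cohort, "metric_a", c("pde_std", "swe_std"),
                          n_perm = 200, seed = 2)
  td <- tidy(rep1)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "stat_report"))
  expect_named(td, c("metric", "score", "estimate", "p.value", "p.fwe",
                     "n", "df", "covariates"))
  gl <- glance(rep1)
  expect_equal(gl$n_tests, 2)
  lad <- hierarchical_regression(as.data.frame(cohort), "pde_std",
                                 list(m1 = c("sex", "mean_fa"),
                                      m2 = "metric_a"))
  expect_named(glance(lad), c("response", "n_models", "r.squared.final", "n"))
})
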