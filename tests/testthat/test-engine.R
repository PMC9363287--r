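# --- implied covariance ----------------------------------------------------

test_that("implied covariance reproduces hand computations", {
  m <- parse_model("factor F: y1 y2")
  ps <- param_template(m)
  ps$lambda[, "F"] <- c(1, 0.5)
  ps$psi["F", "F"] <- 1
  ps$theta[] <- 1
  Sig <- implied_covariance(ps)
  expect_equal(Sig$values,
               matrix(c(2, 0.5, 0.5, 1.25), 2,
                      dimnames = list(c("y1", "y2"), c("y1", "y2"))))
  # all loadings zero -> diagonal theta
  ps$lambda[, "F"] <- 0
  expect_equal(implied_covariance(ps)$values, diag(c(1, 1)),
               ignore_attr = TRUE)
})

test_that("implied covariance is symmetric for random admissible draws", {
  for (seed in 1:20) {
    ps <- random_params(toy_two_factor_path(), seed)
    expect_symmetric(implied_covariance(ps)$values)
  }
})

test_that("implied covariance matches a large simulation", {
  ps <- random_params(toy_two_factor_path(), 99)
  Sig <- implied_covariance(ps)$values
  Y <- simulate_from_params(ps, 4e5, 100)
  expect_lt(max(abs(cov(as.matrix(Y)) - Sig)), 0.03)
})

test_that("singular (I - B) raises a model-structure error", {
  m <- toy_two_factor_path()
  ps <- param_template(m)
  ps$beta["B", "A"] <- 1
  ps$beta["A", "B"] <- 1   # bypasses parser; engine must still catch it
  expect_error(implied_covariance(ps), "singular")
})

# --- ML discrepancy --------------------------------------------------------

test_that("ml_discrepancy: identity, scalar closed form, eigen agreement", {
  labs <- c("a", "b")
  S <- cov_matrix(matrix(c(2, 0.3, 0.3, 1), 2), labels = labs, n = 50)
  expect_equal(ml_discrepancy(S, cov_matrix(S$values, labels = labs)), 0,
               tolerance = 1e-12)
  S1 <- cov_matrix(matrix(2, 1, 1), labels = "x", n = 10)
  G1 <- cov_matrix(matrix(1, 1, 1), labels = "x")
  expect_equal(ml_discrepancy(S1, G1), 2 - log(2) - 1, tolerance = 1e-12)
  # second route: log-dets via eigenvalues
  for (seed in 1:10) {
    set.seed(seed)
    A <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    B <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    labs3 <- c("x", "y", "z")
    f1 <- ml_discrepancy(cov_matrix(A, labs3, 10), cov_matrix(B, labs3))
    f2 <- sum(log(eigen(B, symmetric = TRUE, only.values = TRUE)$values)) +
      sum(diag(solve(B) %*% A)) -
      sum(log(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) - 3
    expect_equal(f1, f2, tolerance = 1e-10)
    expect_gte(f1, 0)
  }
})

test_that("ml_discrepancy rejects a non-positive-definite implied matrix", {
  labs <- c("a", "b")
  S <- cov_matrix(diag(2), labels = labs, n = 10)
  bad <- cov_matrix(matrix(c(1, 2, 2, 1), 2), labels = labs)
  expect_error(ml_discrepancy(S, bad), "not positive definite")
})

# --- analytic gradient -----------------------------------------------------

test_that("analytic gradient matches central finite differences", {
  m <- toy_two_factor_path()
  ps <- param_template(m)
  info <- cohortsem:::param_index(ps)
  truth <- random_params(m, 7)
  S <- implied_covariance(truth)
  set.seed(8)
  Sv <- S$values + crossprod(matrix(rnorm(36, sd = 0.1), 6)) # off-model S
  dimnames(Sv) <- dimnames(S$values)
  attr(Sv, "logdet") <- as.numeric(determinant(Sv, TRUE)$modulus)
  for (seed in 1:5) {
    x <- param_pack(random_params(m, seed + 20))
    an <- cohortsem:::fml_value_grad(unname(x), ps, info, Sv)$grad
    fd <- vapply(seq_along(x), function(k) {
      h <- 1e-6 * max(1, abs(x[k]))
      e <- numeric(length(x)); e[k] <- h
      (cohortsem:::fml_value_grad(unname(x + e), ps, info, Sv, FALSE)$value -
       cohortsem:::fml_value_grad(unname(x - e), ps, info, Sv, FALSE)$value) / (2 * h)
    }, numeric(1))
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

# --- fitting ---------------------------------------------------------------

test_that("saturated model gives T = 0, df = 0", {
  txt <- paste("observed_exogenous", c("a", "b", "c"), collapse = "\n")
  m <- parse_model(txt)
  set.seed(3)
  X <- as.data.frame(matrix(rnorm(300), 100))
  names(X) <- c("a", "b", "c")
  fit <- sem_fit(m, X, se = FALSE, starts = 1)
  expect_equal(fit$df, 0)
  expect_equal(fit$T, 0, tolerance = 1e-6)
  expect_equal(fit$rmsea, 0)
})

test_that("fit recovers the generating parameters from an exact covariance", {
  m <- toy_two_factor_path()
  truth <- random_params(m, 11)
  Sig <- implied_covariance(truth)
  S <- cov_matrix(Sig$values, labels = Sig$labels, n = 20000)
  fit <- sem_fit(m, S, se = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$T, 0, tolerance = 1e-4)
  expect_equal(unname(param_pack(fit$estimates)),
               unname(param_pack(truth)), tolerance = 1e-4)
})

test_that("Heywood case is clamped, flagged, and its SE withheld", {
  labs <- c("y1", "y2", "y3")
  S <- cov_matrix(matrix(c(1, .8, .8, .8, 1, .5, .8, .5, 1), 3),
                  labels = labs, n = 200)
  m <- toy_one_factor(3)
  expect_warning(fit <- sem_fit(m, S, starts = 2), "Heywood")
  expect_true(length(fit$heywood) >= 1)
  expect_true(grepl("y1~~y1", fit$heywood[1]))
  expect_true(is.na(fit$std_errors[["y1~~y1"]]))
})

# --- fit statistics --------------------------------------------------------

test_that("fit_statistics closed forms and truncation", {
  fs <- fit_statistics(114, 57, 443, 600, 78)
  expect_equal(fs$rmsea, sqrt(57 / (57 * 442)), tolerance = 1e-12)
  fs2 <- fit_statistics(120, 57, 443, 600, 78)
  expect_equal(fs2$cfi, 1 - 63 / 522, tolerance = 1e-12)
  # boundary truncation: T <= df gives rmsea exactly 0 and cfi 1
  fs3 <- fit_statistics(56.43, 57, 443, 600, 78)
  expect_identical(fs3$rmsea, 0)
  expect_identical(fs3$cfi, 1)
  expect_equal(fs3$p_value, pchisq(56.43, 57, lower.tail = FALSE))
  expect_error(fit_statistics(10, 0, 100, 20, 5), "df <= 0")
})

test_that("rmsea truncation holds over random T <= df", {
  set.seed(12)
  for (i in 1:50) {
    df <- sample(5:80, 1)
    T <- runif(1, 0, df)
    expect_identical(fit_statistics(T, df, 300, 5 * df, df + 10)$rmsea, 0)
  }
})

# --- standard errors -------------------------------------------------------

test_that("SE of a single free variance matches the closed form", {
  m <- parse_model("observed_exogenous x")
  set.seed(21)
  d <- data.frame(x = rnorm(500, sd = 2))
  fit <- sem_fit(m, d, starts = 1)
  s2 <- fit$estimates$psi["x", "x"]
  expect_equal(unname(fit$std_errors[["x~~x"]]),
               s2 * sqrt(2 / (nrow(d) - 1)), tolerance = 0.01)
})

test_that("SEs shrink like 1/sqrt(n)", {
  m <- toy_one_factor(3)
  truth <- random_params(m, 31)
  Sig <- implied_covariance(truth)
  ses <- sapply(c(500, 2000, 8000), function(n) {
    f <- sem_fit(m, cov_matrix(Sig$values, Sig$labels, n = n), starts = 1)
    f$std_errors[["F~~F"]]
  })
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.05)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.05)
})

# --- standardization -------------------------------------------------------

test_that("standardization is idempotent and marker-choice invariant", {
  m <- toy_two_factor_path()
  truth <- random_params(m, 41)
  std <- standardize_params(truth)
  std2 <- standardize_params(std)
  expect_equal(param_pack(std2), param_pack(std), tolerance = 1e-10)
  # implied covariance of a standardized set is a correlation matrix
  expect_equal(unname(diag(implied_covariance(std)$values)), rep(1, 6),
               tolerance = 1e-10)

  # marker vs unit-variance identification: same standardized solution
  Sig <- implied_covariance(truth)
  S <- cov_matrix(Sig$values, Sig$labels, n = 5000)
  f_marker <- sem_fit(toy_two_factor_path(), S, se = FALSE)
  m_unit <- parse_model("
    factor A: y1 y2 y3
    factor B: y4 y5 y6
    path A -> B
  ", identification = "unit")
  f_unit <- sem_fit(m_unit, S, se = FALSE)
  expect_equal(f_marker$standardized$lambda, f_unit$standardized$lambda,
               tolerance = 1e-6)
  expect_equal(f_marker$standardized$beta, f_unit$standardized$beta,
               tolerance = 1e-6)
})
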