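#' Labeled covariance matrices
#'
#' Light container used for both the sample covariance matrix S and the
#' model-implied matrix Sigma: an ordered label vector, a symmetric matrix
#' with strictly positive diagonal, and the number of observations it
#' summarizes (NA for implied matrices).
#'
#' @param values symmetric numeric matrix.
#' @param labels variable names (default: colnames of `values`).
#' @param n number of observations summarized.
#' @return object of class `cov_matrix`.
#' @export
cov_matrix <- function(values, labels = colnames(values), n = NA_integer_) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("cov_matrix needs variable labels", call. = FALSE)
  if (nrow(values) != ncol(values)) stop("matrix not square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("matrix not symmetric", call. = FALSE)
  values <- (values + t(values)) / 2
  if (any(diag(values) <= 0))
    stop("covariance matrix has non-positive diagonal", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, n = n),
            class = "cov_matrix")
}

#' Sample covariance of a data table
#'
#' Convenience wrapper building a [cov_matrix] from complete-case rows of
#' the named columns (denominator n - 1).
#'
#' @param data data.frame.
#' @param vars columns to use (default all numeric columns).
#' @return `cov_matrix` with `n` = number of complete rows.
#' @export
sample_cov <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop(sprintf("columns not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  x <- as.matrix(data[, vars, drop = FALSE])
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  cov_matrix(stats::cov(x), labels = vars, n = nrow(x))
}

#' @export
print.cov_matrix <- function(x, ...) {
  cat("cov_matrix:", length(x$labels), "variables, n =", x$n, "\n")
  print(round(x$values, 4))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Implied covariance and the ML discrepancy

#' Model-implied covariance matrix
#'
#' Computes \eqn{\Sigma(\theta) = \Lambda (I - B)^{-1} \Psi
#' (I - B)^{-\top} \Lambda^\top + \Theta} for a parameter set.
#'
#' @param model a [sem_model][parse_model] (taken from `params` if omitted).
#' @param params a `sem_params`.
#' @return [cov_matrix] over the model's manifest variables.
#' @export
implied_covariance <- function(params, model = params$model) {
  m <- length(model$latents)
  IB <- diag(m) - params$beta
  M <- tryCatch(solve(IB), error = function(e)
    stop("singular (I - B): model structure error", call. = FALSE))
  G <- M %*% params$psi %*% t(M)            # latent covariance matrix
  S <- params$lambda %*% G %*% t(params$lambda)
  diag(S) <- diag(S) + params$theta
  cov_matrix((S + t(S)) / 2, labels = model$manifest)
}

# latent covariance matrix (I-B)^-1 Psi (I-B)^-T
latent_cov <- function(params) {
  m <- nrow(params$beta)
  M <- solve(diag(m) - params$beta)
  G <- M %*% params$psi %*% t(M)
  dimnames(G) <- dimnames(params$beta)
  G
}

#' Maximum-likelihood discrepancy function
#'
#' \eqn{F_{ML} = \log|\Sigma| + tr(S \Sigma^{-1}) - \log|S| - p}, the
#' normal-theory discrepancy whose minimum over the model parameters, times
#' (n - 1), is the chi-square test statistic. Non-negative, zero iff
#' S = Sigma.
#'
#' @param S sample [cov_matrix].
#' @param Sigma implied [cov_matrix] (must be positive definite).
#' @return non-negative scalar.
#' @export
ml_discrepancy <- function(S, Sigma) {
  if (!identical(S$labels, Sigma$labels))
    stop("covariance matrices have different variable labels", call. = FALSE)
  p <- length(S$labels)
  R <- tryCatch(chol(Sigma$values), error = function(e)
    stop("implied covariance matrix is not positive definite", call. = FALSE))
  ldSig <- 2 * sum(log(diag(R)))
  ldS <- determinant(S$values, logarithm = TRUE)
  if (ldS$sign <= 0)
    stop("sample covariance matrix is singular", call. = FALSE)
  tr <- sum(diag(chol2inv(R) %*% S$values))
  ldSig + tr - as.numeric(ldS$modulus) - p
}

# F_ML and its analytic gradient w.r.t. the free parameter vector.
# dF = tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma], with
#   dF/dLambda = 2 E Lambda G,   dF/dTheta_jj = E_jj,
#   dF/dPsi    = A' E A (off-diagonals doubled),  A = Lambda M,
#   dF/dB      = 2 M' Lambda' E Lambda M Psi M',  M = (I-B)^-1.
fml_value_grad <- function(x, params, info, Sv, want_grad = TRUE) {
  params <- param_unpack(params, x)
  m <- nrow(params$beta)
  IB <- diag(m) - params$beta
  M <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(M)) return(list(value = 1e10, grad = NULL))
  G <- M %*% params$psi %*% t(M)
  Sig <- params$lambda %*% G %*% t(params$lambda)
  diag(Sig) <- diag(Sig) + params$theta
  Sig <- (Sig + t(Sig)) / 2
  R <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(R)) return(list(value = 1e10, grad = NULL))
  Siginv <- chol2inv(R)
  p <- nrow(Sv)
  ldS <- attr(Sv, "logdet")
  val <- 2 * sum(log(diag(R))) + sum(Siginv * Sv) - ldS - p
  if (!want_grad) return(list(value = val, grad = NULL))

  E <- Siginv - Siginv %*% Sv %*% Siginv
  A <- params$lambda %*% M
  dLam <- 2 * (E %*% params$lambda %*% G)
  dPsi <- t(A) %*% E %*% A
  LtEL <- t(params$lambda) %*% E %*% params$lambda
  dB <- 2 * (t(M) %*% LtEL %*% M %*% params$psi %*% t(M))
  g <- numeric(nrow(info))
  for (k in seq_len(nrow(info))) {
    i <- info$i[k]; j <- info$j[k]
    g[k] <- switch(info$mat[k],
                   lambda = dLam[i, j],
                   beta = dB[i, j],
                   psi = if (i == j) dPsi[i, i] else 2 * dPsi[i, j],
                   theta = E[i, i])
  }
  list(value = val, grad = g)
}

# ---------------------------------------------------------------------------
# Fitting

#' Fit a covariance-structure model by maximum likelihood
#'
#' Minimizes the ML discrepancy over the free parameters with a
#' quasi-Newton method (box constraints keep variances non-negative),
#' from a small number of jittered starts. Convergence is declared from
#' the analytic-gradient max-norm at the optimum; variances that end on
#' their lower bound (Heywood cases) are flagged and retained at the
#' bound with a warning.
#'
#' @param model a [sem_model][parse_model].
#' @param S sample [cov_matrix] (or a data.frame, from which the sample
#'   covariance of the model's manifest columns is taken).
#' @param n sample size; defaults to `S$n`.
#' @param starts number of jittered starts (first start is unjittered).
#' @param se compute standard errors from the inverse observed information
#'   (numerical Hessian of (n-1)/2 F_ML over the analytic gradient).
#' @param grad_tol gradient max-norm for the converged flag.
#' @return object of class `sem_fit`: list with `estimates` (sem_params),
#'   `standardized` (sem_params on the fully standardized scale),
#'   `std_errors` (named vector, NA where withheld), `param_table`
#'   (data.frame: label, estimate, se, z, p, std), `T` (chi-square
#'   statistic), `df`, `p_value`, `rmsea`, `cfi`, `F_min`, `converged`,
#'   `n`, `heywood` (labels of clamped variances),
#'   `construct_reliabilities`, `S`.
#' @examples
#' m <- parse_model("factor F: y1 y2 y3")
#' set.seed(1)
#' f <- rnorm(200)
#' d <- data.frame(y1 = f + rnorm(200), y2 = 0.8 * f + rnorm(200),
#'                 y3 = 0.6 * f + rnorm(200))
#' fit <- sem_fit(m, d, se = FALSE)
#' fit$rmsea
#' @export
sem_fit <- function(model, S, n = NULL, starts = 5, se = TRUE,
                    grad_tol = 1e-8) {
  if (is.data.frame(S)) S <- sample_cov(S, vars = model$manifest)
  if (!identical(S$labels, model$manifest)) {
    missing <- setdiff(model$manifest, S$labels)
    if (length(missing))
      stop(sprintf("sample covariance lacks variables: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    S <- cov_matrix(S$values[model$manifest, model$manifest],
                    labels = model$manifest, n = S$n)
  }
  if (is.null(n)) n <- S$n
  p <- length(model$manifest)
  if (is.na(n) || n <= p)
    stop("need sample size n > number of manifest variables", call. = FALSE)

  params <- param_template(model)
  params <- start_values(params, S)
  info <- param_index(params)
  x0 <- param_pack(params)
  lower <- info$lower

  Sv <- S$values
  attr(Sv, "logdet") <- as.numeric(determinant(Sv, TRUE)$modulus)

  objfun <- function(x) fml_value_grad(x, params, info, Sv, want_grad = FALSE)$value
  gradfun <- function(x) {
    g <- fml_value_grad(x, params, info, Sv)$grad
    if (is.null(g)) rep(0, length(x)) else g
  }

  jitters <- start_jitter(length(x0), starts)
  best <- NULL
  for (s in seq_len(starts)) {
    xs <- x0 * jitters[[s]]
    xs <- pmax(xs, lower)
    opt <- tryCatch(
      stats::nlminb(xs, objfun, gradient = gradfun, lower = lower,
                    control = list(iter.max = 2000, eval.max = 4000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective - 1e-12) best <- opt
  }
  if (is.null(best))
    stop("optimization failed from every start", call. = FALSE)

  # Newton polish: nlminb stops on relative progress around |g| ~ 1e-6;
  # a few damped Newton steps on the analytic gradient reach the
  # gradient-norm criterion proper
  xhat <- pmax(best$par, lower)
  f_cur <- objfun(xhat)
  for (it in 1:20) {
    g <- gradfun(xhat)
    free_dir <- !(is.finite(lower) & xhat <= lower + 1e-9 & g > 0)
    if (max(abs(g[free_dir]), 0) < grad_tol) break
    H <- grad_hessian(gradfun, xhat)
    step <- rep(0, length(xhat))
    sol <- tryCatch(solve(H[free_dir, free_dir, drop = FALSE], g[free_dir]),
                    error = function(e) NULL)
    if (is.null(sol)) break
    step[free_dir] <- sol
    accepted <- FALSE
    for (damp in 2^-(0:8)) {
      xn <- pmax(xhat - damp * step, lower)
      fn <- objfun(xn)
      if (is.finite(fn) && fn <= f_cur + 1e-12) {
        xhat <- xn; f_cur <- fn; accepted <- TRUE; break
      }
    }
    if (!accepted) break
  }
  est <- param_unpack(params, xhat)
  F_min <- objfun(xhat)
  at_bound <- is.finite(lower) & (xhat <= lower + 1e-9)
  heywood <- info$label[at_bound]
  if (length(heywood))
    warning(sprintf("Heywood case: variance(s) clamped at bound: %s",
                    paste(heywood, collapse = ", ")), call. = FALSE)

  # converged: interior gradient components near zero; at active bounds the
  # projected gradient must be non-negative (pushing into the bound)
  g <- gradfun(xhat)
  gn <- max(abs(g[!at_bound]), 0)
  converged <- is.finite(F_min) && gn < grad_tol && all(g[at_bound] > -grad_tol)

  df <- p * (p + 1) / 2 - nrow(info)
  T_stat <- max(0, (n - 1) * F_min)
  base <- baseline_model(S, n)
  fitidx <- if (df > 0) {
    fit_statistics(T_stat, df, n, base$T, base$df)
  } else list(p_value = NA_real_, rmsea = 0, cfi = 1)

  std <- standardize_params(est)
  crs <- reliabilities_from_std(std)

  ses <- rep(NA_real_, nrow(info))
  if (se && converged) {
    H <- grad_hessian(gradfun, xhat) * (n - 1) / 2
    ok <- !at_bound
    Hi <- tryCatch(solve(H[ok, ok, drop = FALSE]), error = function(e) NULL)
    if (!is.null(Hi)) {
      d <- diag(Hi)
      d[d < 0] <- NA_real_
      ses[ok] <- sqrt(d)
    }
  }
  zs <- param_pack(est) / ses
  pt <- data.frame(label = info$label,
                   matrix = info$mat,
                   estimate = unname(param_pack(est)),
                   se = ses,
                   z = unname(zs),
                   p = 2 * stats::pnorm(-abs(unname(zs))),
                   std = unname(param_pack(std)),
                   stringsAsFactors = FALSE)

  structure(list(model = model, estimates = est, standardized = std,
                 std_errors = stats::setNames(ses, info$label),
                 param_table = pt,
                 T = T_stat, df = df, p_value = fitidx$p_value,
                 rmsea = fitidx$rmsea, cfi = fitidx$cfi,
                 F_min = F_min, converged = converged, n = n,
                 heywood = heywood,
                 construct_reliabilities = crs, S = S),
            class = "sem_fit")
}

# documented multi-start scheme: start 1 is the plain default, later starts
# jitter multiplicatively; the sequence is deterministic and independent of
# the caller's RNG state.
start_jitter <- function(k, starts) {
  out <- vector("list", starts)
  out[[1]] <- rep(1, k)
  if (starts > 1) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(830217L)
    for (s in 2:starts) out[[s]] <- exp(stats::runif(k, -0.3, 0.3))
  }
  out
}

# loadings 0.7 on the marker-indicator scale, paths 0, variances from the
# sample diagonal
start_values <- function(params, S) {
  model <- params$model
  d <- diag(S$values)
  for (f in names(model$factors)) {
    inds <- model$factors[[f]]
    marker_var <- d[inds[1]]
    params$psi[f, f] <- if (params$free_psi[f, f]) 0.5 * marker_var else params$psi[f, f]
    sc <- max(sqrt(marker_var), 1e-8)
    for (ii in inds)
      if (params$free_lambda[ii, f])
        params$lambda[ii, f] <- 0.7 * sqrt(d[ii]) / sc
  }
  for (v in model$observed_exogenous)
    if (params$free_psi[v, v]) params$psi[v, v] <- d[v]
  if (!is.null(model$second_order)) {
    so <- model$second_order$name
    if (params$free_psi[so, so])
      params$psi[so, so] <- 0.5 * params$psi[model$second_order$governs[1],
                                             model$second_order$governs[1]]
  }
  for (i in seq_along(model$manifest))
    if (params$free_theta[i]) params$theta[i] <- 0.5 * d[i]
  params
}

# independence baseline: free variances, all covariances zero
baseline_model <- function(S, n) {
  p <- length(S$labels)
  Sig0 <- cov_matrix(diag(diag(S$values), p), labels = S$labels)
  F0 <- ml_discrepancy(S, Sig0)
  list(T = (n - 1) * F0, df = p * (p - 1) / 2)
}

# symmetric numerical Hessian from central differences of the gradient
grad_hessian <- function(gradfun, x, h = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * max(1, abs(x[j]))
    e <- numeric(k); e[j] <- hj
    H[, j] <- (gradfun(x + e) - gradfun(x - e)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Chi-square based fit statistics
#'
#' @param T chi-square test statistic (n - 1 times the minimized
#'   discrepancy).
#' @param df model degrees of freedom (> 0).
#' @param n sample size.
#' @param T_baseline,df_baseline statistic and df of the independence
#'   baseline model (free variances, zero covariances).
#' @return list with `p_value` (upper-tail chi-square), `rmsea` =
#'   sqrt(max(0, (T - df) / (df (n - 1)))) — exactly 0 when T <= df — and
#'   `cfi` = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0), clipped to
#'   \[0, 1\].
#' @export
fit_statistics <- function(T, df, n, T_baseline, df_baseline) {
  if (df <= 0) stop("fit indices undefined for df <= 0", call. = FALSE)
  if (df_baseline < df)
    stop("baseline model cannot have fewer df than the target model",
         call. = FALSE)
  p_value <- stats::pchisq(T, df, lower.tail = FALSE)
  rmsea <- sqrt(max(0, (T - df) / (df * (n - 1))))
  den <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - max(T - df, 0) / den
  cfi <- min(max(cfi, 0), 1)
  list(p_value = p_value, rmsea = rmsea, cfi = cfi)
}

#' Standardize a fitted or raw parameter set
#'
#' Rescales every latent and manifest variable to unit variance: loadings
#' become correlations-scale weights, structural coefficients become the
#' beta weights reported in path diagrams, error variances become residual
#' variance proportions. Invariant to the identification rule used to fit.
#'
#' @param x a `sem_fit` or `sem_params`.
#' @return a `sem_params` on the standardized scale.
#' @export
standardize_params <- function(x) {
  params <- if (inherits(x, "sem_fit")) x$estimates else x
  G <- latent_cov(params)
  Dl <- sqrt(diag(G))
  if (any(Dl <= 0)) stop("zero-variance latent: cannot standardize", call. = FALSE)
  Sig <- implied_covariance(params)$values
  Dm <- sqrt(diag(Sig))
  out <- params
  Dmi <- diag(1 / Dm, length(Dm))
  Dli <- diag(1 / Dl, length(Dl))
  Dld <- diag(Dl, length(Dl))
  out$lambda <- Dmi %*% params$lambda %*% Dld
  dimnames(out$lambda) <- dimnames(params$lambda)
  out$beta <- Dli %*% params$beta %*% Dld
  dimnames(out$beta) <- dimnames(params$beta)
  out$psi <- Dli %*% params$psi %*% Dli
  dimnames(out$psi) <- dimnames(params$psi)
  out$theta <- params$theta / Dm^2
  out
}

# composite reliability of each multi-indicator factor from the
# standardized solution
reliabilities_from_std <- function(std) {
  model <- std$model
  out <- numeric(0)
  for (f in names(model$factors)) {
    inds <- model$factors[[f]]
    if (length(inds) < 2) next
    out[f] <- construct_reliability(std$lambda[inds, f], std$theta[inds])
  }
  out
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat(sprintf("sem_fit: chi-square = %.2f, df = %d, p = %.3f\n",
              x$T, x$df, x$p_value))
  cat(sprintf("  RMSEA = %.3f, CFI = %.3f, n = %d, converged: %s\n",
              x$rmsea, x$cfi, x$n, x$converged))
  if (length(x$heywood))
    cat("  Heywood:", paste(x$heywood, collapse = ", "), "\n")
  if (length(x$construct_reliabilities)) {
    cat("  construct reliabilities:\n")
    print(round(x$construct_reliabilities, digits))
  }
  cat("  parameters:\n")
  pt <- x$param_table
  pt[] <- lapply(pt, function(c) if (is.numeric(c)) round(c, digits) else c)
  print(pt, row.names = FALSE)
  invisible(x)
}
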