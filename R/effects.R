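#' Composite (construct) reliability
#'
#' The proportion of a unit-weight composite's variance attributable to
#' its factor: \eqn{CR = (\sum \lambda)^2 / ((\sum \lambda)^2 + \sum
#' \theta)}, computed from the standardized loadings and error variances
#' of one factor's indicators. Values above 0.60 are conventionally read
#' as high reliability.
#'
#' @param loadings standardized loadings of the factor's indicators.
#' @param errors standardized error variances (defaults to
#'   `1 - loadings^2`, the no-cross-loading case).
#' @return scalar in (0, 1\]; equals 1 when all errors are 0.
#' @examples
#' construct_reliability(rep(0.5464, 4)) # ~0.63
#' @export
construct_reliability <- function(loadings, errors = 1 - loadings^2) {
  if (!length(loadings)) stop("empty indicator list", call. = FALSE)
  if (length(errors) != length(loadings))
    stop("loadings and errors differ in length", call. = FALSE)
  if (any(errors < 0)) stop("negative error variance", call. = FALSE)
  sl2 <- sum(loadings)^2
  sl2 / (sl2 + sum(errors))
}

#' Indirect (mediated) effects along directed chains
#'
#' Enumerates every directed chain from `source` to `target` through the
#' latent graph (structural paths and second-order loadings) and returns
#' the product of standardized coefficients along each chain plus their
#' sum — the classic product-of-coefficients mediation measure.
#'
#' @param fit a `sem_fit` (or a `sem_params` already on the scale of
#'   interest).
#' @param source,target latent names; `source` must precede `target` in
#'   the acyclic graph.
#' @return list with `chains` (list of character vectors of node names),
#'   `effects` (per-chain products), `total` (their sum) and `note`
#'   ("no path" when no chain exists, in which case `total` is 0).
#' @examples
#' # two-segment chain: -0.29 * 0.74 = -0.2146
#' @export
indirect_effects <- function(fit, source, target) {
  params <- if (inherits(fit, "sem_fit")) fit$standardized else fit
  model <- params$model
  if (!source %in% model$latents || !target %in% model$latents)
    stop("source/target must be latent names", call. = FALSE)
  B <- params$beta
  chains <- list()
  effects <- numeric(0)
  walk <- function(node, path, prod) {
    succ <- rownames(B)[params$free_beta[, node] | B[, node] != 0]
    for (s in succ) {
      coeff <- B[s, node]
      if (s == target) {
        chains[[length(chains) + 1L]] <<- c(path, s)
        effects[length(effects) + 1L] <<- prod * coeff
      } else {
        walk(s, c(path, s), prod * coeff)
      }
    }
  }
  walk(source, source, 1)
  note <- if (!length(chains)) "no path" else NA_character_
  list(chains = chains, effects = effects,
       total = if (length(effects)) sum(effects) else 0, note = note)
}

#' Regression-method (Thomson) factor scores
#'
#' Subject-level latent estimates \eqn{\hat\eta = \mathrm{Cov}(\eta, y)
#' S^{-1} (y - \bar y)}: the model-implied latent-by-manifest covariance
#' applied to the inverse sample covariance of the centered observed
#' variables. Scores are 0 for a subject exactly at the variable means.
#'
#' @param fit converged `sem_fit`.
#' @param data data.frame holding (at least) the model's manifest columns;
#'   complete cases only.
#' @param latents which latent scores to return (default all).
#' @param center named vector of variable means used for centering
#'   (default: the column means of `data`). Pass the baseline means when
#'   scoring a follow-up occasion against a baseline-fitted model, so
#'   that score changes measure absolute shifts.
#' @param indicators `"all"` (default) uses every manifest variable per
#'   score — the efficient estimator, but with correlated factors each
#'   score borrows from neighbouring blocks; `"own"` restricts each
#'   first-order factor's score to its own indicators, so the score
#'   reflects only that construct (used by the arm-change tests).
#' @return matrix (subjects x latents) of factor scores.
#' @export
factor_scores <- function(fit, data, latents = fit$model$latents,
                          center = NULL, indicators = c("all", "own")) {
  indicators <- match.arg(indicators)
  model <- fit$model
  missing <- setdiff(model$manifest, names(data))
  if (length(missing))
    stop(sprintf("data lacks manifest columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  Y <- as.matrix(data[, model$manifest, drop = FALSE])
  if (any(!stats::complete.cases(Y)))
    stop("factor_scores requires complete cases", call. = FALSE)
  params <- fit$estimates
  G <- latent_cov(params)
  # Cov(eta, y) = G Lambda' (measurement errors independent of latents)
  C <- G %*% t(params$lambda)
  Sinv <- tryCatch(solve(fit$S$values), error = function(e)
    stop("singular sample covariance: cannot compute factor scores",
         call. = FALSE))
  if (is.null(center)) center <- colMeans(Y)
  if (is.null(names(center)) && length(center) == ncol(Y))
    names(center) <- colnames(Y)
  Yc <- sweep(Y, 2, center[colnames(Y)])
  scores <- Yc %*% Sinv %*% t(C)
  colnames(scores) <- model$latents
  if (indicators == "own") {
    for (f in intersect(latents, names(model$factors))) {
      inds <- model$factors[[f]]
      Sb <- fit$S$values[inds, inds, drop = FALSE]
      wb <- solve(Sb, C[f, inds])
      scores[, f] <- Yc[, inds, drop = FALSE] %*% wb
    }
  }
  scores[, latents, drop = FALSE]
}
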