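#' Parameter sets for covariance-structure models
#'
#' A `sem_params` object holds every model matrix of the LISREL-type
#' composition
#' \deqn{\Sigma = \Lambda (I - B)^{-1} \Psi (I - B)^{-\top} \Lambda^\top + \Theta}
#' together with free/fixed masks:
#' \describe{
#'   \item{lambda}{p x m loadings of manifest variables on latents
#'     (first-order loadings; observed-exogenous variables load 1 on their
#'     own latent).}
#'   \item{beta}{m x m regression matrix over latents; row i, column j is
#'     the coefficient of latent j in the equation of latent i. Second-order
#'     loadings live here as edges second-order factor -> governed factor.}
#'   \item{psi}{m x m symmetric covariance matrix of exogenous latents and
#'     disturbances of endogenous latents; off-diagonals are free only
#'     among exogenous latents.}
#'   \item{theta}{length-p vector of measurement-error variances.}
#' }
#'
#' @param model a [sem_model][parse_model].
#' @return `param_template()` returns a `sem_params` with identification
#'   constraints applied and neutral starting values (free loadings 0.7,
#'   paths 0, variances 1).
#' @export
param_template <- function(model) {
  p <- length(model$manifest)
  m <- length(model$latents)
  lam <- matrix(0, p, m, dimnames = list(model$manifest, model$latents))
  fl <- matrix(FALSE, p, m, dimnames = dimnames(lam))
  B <- matrix(0, m, m, dimnames = list(model$latents, model$latents))
  fB <- matrix(FALSE, m, m, dimnames = dimnames(B))
  Psi <- diag(1, m)
  dimnames(Psi) <- dimnames(B)
  fPsi <- matrix(FALSE, m, m, dimnames = dimnames(B))
  th <- stats::setNames(rep(1, p), model$manifest)
  fth <- stats::setNames(rep(TRUE, p), model$manifest)

  marker <- identical(model$identification, "marker")

  for (f in names(model$factors)) {
    inds <- model$factors[[f]]
    lam[inds, f] <- 0.7
    fl[inds, f] <- TRUE
    if (marker || length(inds) == 1) {
      lam[inds[1], f] <- 1
      fl[inds[1], f] <- FALSE
    }
    if (f %in% names(model$fixed_error)) {
      th[inds] <- model$fixed_error[[f]]
      fth[inds] <- FALSE
    }
  }
  for (v in model$observed_exogenous) {
    lam[v, v] <- 1
    th[v] <- 0
    fth[v] <- FALSE
  }
  if (!is.null(model$second_order)) {
    so <- model$second_order
    B[so$governs, so$name] <- 0.7
    fB[so$governs, so$name] <- TRUE
    if (marker) {
      B[so$governs[1], so$name] <- 1
      fB[so$governs[1], so$name] <- FALSE
    }
  }
  if (nrow(model$paths)) {
    for (i in seq_len(nrow(model$paths))) {
      B[model$paths[i, "to"], model$paths[i, "from"]] <- 0
      fB[model$paths[i, "to"], model$paths[i, "from"]] <- TRUE
    }
  }

  exo <- exogenous_latents(model)
  diag(fPsi) <- TRUE
  if (!marker) {
    # unit-latent-variance rule: fix exogenous variances and endogenous
    # disturbances at 1, free every loading instead
    diag(fPsi) <- FALSE
    diag(Psi) <- 1
  }
  if (length(exo) > 1) {
    for (a in seq_along(exo)) for (b in seq_along(exo)) {
      if (a < b) {
        fPsi[exo[a], exo[b]] <- TRUE
        Psi[exo[a], exo[b]] <- Psi[exo[b], exo[a]] <- 0
      }
    }
  }

  ps <- structure(list(model = model, lambda = lam, beta = B, psi = Psi,
                       theta = th, free_lambda = fl, free_beta = fB,
                       free_psi = fPsi, free_theta = fth),
                  class = "sem_params")
  ps
}

#' Flat-vector view of the free parameters
#'
#' `param_pack()` extracts the free parameters as a named numeric vector in
#' a canonical order (loadings, structural/second-order coefficients,
#' latent (co)variances, error variances); `param_unpack()` writes such a
#' vector back. The round-trip is the identity, and fixed entries are never
#' touched.
#'
#' @param params a `sem_params`.
#' @param x numeric vector as produced by `param_pack`.
#' @return `param_pack`: named numeric vector. `param_unpack`: `sem_params`.
#' @export
param_pack <- function(params) {
  info <- param_index(params)
  v <- numeric(nrow(info))
  for (k in seq_len(nrow(info))) {
    v[k] <- switch(info$mat[k],
                   lambda = params$lambda[info$i[k], info$j[k]],
                   beta = params$beta[info$i[k], info$j[k]],
                   psi = params$psi[info$i[k], info$j[k]],
                   theta = params$theta[info$i[k]])
  }
  stats::setNames(v, info$label)
}

#' @rdname param_pack
#' @export
param_unpack <- function(params, x) {
  info <- param_index(params)
  if (length(x) != nrow(info))
    stop(sprintf("expected %d free parameters, got %d", nrow(info), length(x)),
         call. = FALSE)
  for (k in seq_len(nrow(info))) {
    i <- info$i[k]; j <- info$j[k]
    switch(info$mat[k],
           lambda = params$lambda[i, j] <- x[k],
           beta = params$beta[i, j] <- x[k],
           psi = {
             params$psi[i, j] <- x[k]
             params$psi[j, i] <- x[k]
           },
           theta = params$theta[i] <- x[k])
  }
  params
}

# Bookkeeping table of the free parameters: matrix name, indices, label,
# and the optimizer's lower bound (variances bounded below at ~0).
param_index <- function(params) {
  mv <- params$model$manifest
  lv <- params$model$latents
  rows <- list()
  add <- function(mat, i, j, label, lower) {
    rows[[length(rows) + 1L]] <<- data.frame(mat = mat, i = i, j = j,
                                             label = label, lower = lower,
                                             stringsAsFactors = FALSE)
  }
  for (j in seq_along(lv)) for (i in seq_along(mv))
    if (params$free_lambda[i, j])
      add("lambda", i, j, sprintf("%s=~%s", lv[j], mv[i]), -Inf)
  for (j in seq_along(lv)) for (i in seq_along(lv))
    if (params$free_beta[i, j])
      add("beta", i, j, sprintf("%s~%s", lv[i], lv[j]), -Inf)
  for (i in seq_along(lv))
    if (params$free_psi[i, i])
      add("psi", i, i, sprintf("%s~~%s", lv[i], lv[i]), 1e-10)
  for (i in seq_along(lv)) for (j in seq_along(lv))
    if (i < j && params$free_psi[i, j])
      add("psi", i, j, sprintf("%s~~%s", lv[i], lv[j]), -Inf)
  for (i in seq_along(mv))
    if (params$free_theta[i])
      add("theta", i, NA_integer_, sprintf("%s~~%s", mv[i], mv[i]), 1e-10)
  do.call(rbind, rows)
}

#' @export
print.sem_params <- function(x, ...) {
  n_free <- sum(x$free_lambda) + sum(x$free_beta) +
    sum(x$free_psi[upper.tri(x$free_psi, diag = TRUE)]) + sum(x$free_theta)
  cat("sem_params:", length(x$model$manifest), "manifest,",
      length(x$model$latents), "latents,", n_free, "free parameters\n")
  invisible(x)
}

n_free_params <- function(params) nrow(param_index(params))
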