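# shared fixtures: tiny models and random admissible parameter draws

toy_one_factor <- function(k = 3) {
  parse_model(paste("factor F:", paste0("y", seq_len(k), collapse = " ")))
}

toy_two_factor_path <- function() {
  parse_model("
    factor A: y1 y2 y3
    factor B: y4 y5 y6
    path A -> B
  ")
}

# random admissible parameter set for a given model (standardized-ish
# scales, comfortably positive variances)
random_params <- function(model, seed) {
  set.seed(seed)
  ps <- param_template(model)
  ps$lambda[ps$free_lambda] <- runif(sum(ps$free_lambda), 0.4, 1.2)
  ps$beta[ps$free_beta] <- runif(sum(ps$free_beta), -0.6, 0.6)
  dg <- which(diag(ps$free_psi))
  diag(ps$psi)[dg] <- runif(length(dg), 0.5, 1.5)
  off <- which(ps$free_psi & upper.tri(ps$free_psi), arr.ind = TRUE)
  if (nrow(off)) for (r in seq_len(nrow(off))) {
    i <- off[r, 1]; j <- off[r, 2]
    v <- runif(1, -0.3, 0.3) * sqrt(ps$psi[i, i] * ps$psi[j, j])
    ps$psi[i, j] <- ps$psi[j, i] <- v
  }
  ps$theta[ps$free_theta] <- runif(sum(ps$free_theta), 0.3, 1.0)
  ps
}

# draw n observations from the linear latent system of a parameter set
simulate_from_params <- function(ps, n, seed) {
  set.seed(seed)
  m <- nrow(ps$beta)
  L <- chol(ps$psi + diag(1e-12, m))
  zeta <- matrix(rnorm(n * m), n, m) %*% L
  eta <- t(solve(diag(m) - ps$beta, t(zeta)))
  eps <- sweep(matrix(rnorm(n * length(ps$theta)), n), 2, sqrt(ps$theta), `*`)
  Y <- eta %*% t(ps$lambda) + eps
  colnames(Y) <- ps$model$manifest
  as.data.frame(Y)
}

expect_symmetric <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol)
}
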