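# --- construct reliability -------------------------------------------------

test_that("construct reliability: closed forms and limits", {
  expect_equal(construct_reliability(c(1, 1), c(0, 0)), 1)
  expect_equal(construct_reliability(rep(0.5464, 4)), 0.63, tolerance = 1e-3)
  expect_equal(construct_reliability(rep(0.7338, 2)), 0.70, tolerance = 1e-3)
  expect_error(construct_reliability(numeric(0)), "empty")
  expect_error(construct_reliability(c(0.5, 0.5), c(-0.1, 0.2)), "negative")
})

# --- indirect effects ------------------------------------------------------

test_that("indirect effects are products of chain coefficients", {
  m <- parse_model("
    factor F1: a1 a2
    factor F2: b1 b2
    factor F3: c1 c2
    path F1 -> F2
    path F2 -> F3
  ")
  ps <- param_template(m)
  ps$beta["F2", "F1"] <- -0.29
  ps$beta["F3", "F2"] <- 0.74
  eff <- indirect_effects(ps, "F1", "F3")
  expect_equal(eff$total, -0.29 * 0.74)
  expect_equal(round(eff$total, 2), -0.21)
  ps$beta["F3", "F2"] <- 0.65
  expect_equal(round(indirect_effects(ps, "F1", "F3")$total, 2), -0.19)
  # zero coefficient on the chain
  ps$beta["F2", "F1"] <- 0
  expect_equal(indirect_effects(ps, "F1", "F3")$total, 0)
  # no path at all
  none <- indirect_effects(ps, "F3", "F1")
  expect_equal(none$total, 0)
  expect_identical(none$note, "no path")
})

test_that("indirect effects equal brute-force path-tracing on random DAGs", {
  # independent oracle: enumerate all simple chains by recursive expansion
  # over the adjacency list, multiply edge weights, sum
  oracle <- function(adj, W, from, to) {
    total <- 0
    expand <- function(node, prod) {
      for (nxt in adj[[node]]) {
        w <- prod * W[nxt, node]
        if (nxt == to) total <<- total + w else expand(nxt, w)
      }
    }
    expand(from, 1)
    total
  }
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    lat <- paste0("L", 1:k)
    # random DAG on the ordered latents (edges only forward)
    stmts <- c(sapply(lat, function(f)
      sprintf("factor %s: %s_i1 %s_i2", f, f, f)))
    edges <- list()
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (runif(1) < 0.5) edges[[length(edges) + 1]] <- c(lat[i], lat[j])
    if (!length(edges)) edges[[1]] <- c(lat[1], lat[2])
    stmts <- c(stmts, sapply(edges, function(e)
      sprintf("path %s -> %s", e[1], e[2])))
    m <- parse_model(paste(stmts, collapse = "\n"))
    ps <- param_template(m)
    W <- matrix(0, k, k, dimnames = list(lat, lat))
    adj <- setNames(vector("list", k), lat)
    for (e in edges) {
      w <- round(runif(1, -1, 1), 3)
      ps$beta[e[2], e[1]] <- w
      W[e[2], e[1]] <- w
      adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    }
    expect_equal(indirect_effects(ps, lat[1], lat[k])$total,
                 oracle(adj, W, lat[1], lat[k]), tolerance = 1e-12)
  }
})

test_that("panel mediation chains go through the second-order factor", {
  gp <- build_generating_parameters(generator_config())
  eff <- indirect_effects(gp$params, "sel_age", "Fibrosis")
  expect_length(eff$chains, 1)
  expect_identical(eff$chains[[1]], c("sel_age", "InflOxStress", "Fibrosis"))
  expect_equal(eff$total, -0.29 * 0.74)
  effI <- indirect_effects(gp$params, "sel_age", "Inflammation")
  expect_equal(effI$total, -0.29 * 0.80)
})

# --- factor scores ---------------------------------------------------------

test_that("factor scores vanish at the variable means and match hand algebra", {
  m <- parse_model("factor F: y1 y2")
  truth <- param_template(m)
  truth$lambda[, "F"] <- c(1, 0.8)
  truth$psi["F", "F"] <- 1
  truth$theta[] <- c(0.5, 0.7)
  set.seed(5)
  d <- simulate_from_params(truth, 400, 5)
  fit <- sem_fit(m, d, se = FALSE, starts = 1)
  sc <- factor_scores(fit, d)
  # subject exactly at the means scores zero
  d0 <- as.data.frame(t(colMeans(d)))
  expect_equal(unname(factor_scores(fit, rbind(d, d0))[401, "F"]), 0,
               tolerance = 1e-10)
  # hand linear algebra: Cov(eta, y) S^-1 (y - ybar)
  lam <- fit$estimates$lambda[, "F"]
  phi <- fit$estimates$psi["F", "F"]
  w <- solve(fit$S$values, phi * lam)
  hand <- sweep(as.matrix(d), 2, colMeans(d)) %*% w
  expect_equal(unname(sc[, "F"]), unname(hand[, 1]), tolerance = 1e-8)
})

test_that("scores track the true simulated latents", {
  cfg <- generator_config()
  base <- simulate_baseline(cfg, n = 5000, seed = 55)
  tab <- sel_age_quotient(preprocess(base))$table
  fit <- run_cfa_stage(tab, se = FALSE, starts = 2)
  sc <- factor_scores(fit, tab)
  lat <- attr(base, "latents")
  for (f in c("Inflammation", "OxStress", "Fibrosis"))
    expect_gt(cor(sc[, f], lat[[f]]), 0.6)
  # block-restricted scores also track, slightly less efficiently
  sco <- factor_scores(fit, tab, indicators = "own")
  for (f in c("Inflammation", "OxStress", "Fibrosis"))
    expect_gt(cor(sco[, f], lat[[f]]), 0.6)
})

test_that("factor scores demand complete matching columns", {
  m <- parse_model("factor F: y1 y2")
  truth <- random_params(m, 6)
  d <- simulate_from_params(truth, 100, 6)
  fit <- sem_fit(m, d, se = FALSE, starts = 1)
  expect_error(factor_scores(fit, d[, "y1", drop = FALSE]), "lacks manifest")
  d$y1[3] <- NA
  expect_error(factor_scores(fit, d), "complete cases")
})
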