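#' Preprocess a cohort for covariance modelling
#'
#' Natural-log transforms the 13 biomarker concentrations (columns keep
#' their names) and adds `log_selenium`; raw `selenium_ugL` and
#' `age_years` are retained for the quotient and the age checks.
#' Incomplete rows (any missing biomarker, selenium or age) are dropped
#' and counted; a non-positive concentration is an error naming the row.
#'
#' @param cohort a `cohort_table` (or data.frame with canonical columns).
#' @return an analysis table (data.frame) with attributes `n_dropped` and
#'   `stage_report`.
#' @export
preprocess <- function(cohort) {
  tab <- as.data.frame(cohort)
  missing <- setdiff(cohort_columns(), names(tab))
  if (length(missing))
    stop(sprintf("canonical column(s) absent: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  vars <- c(panel_markers(), "selenium_ugL", "age_years")
  for (v in c(panel_markers(), "selenium_ugL")) {
    bad <- which(!is.na(tab[[v]]) & tab[[v]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive concentration in column '%s', row %d",
                   v, bad[1]), call. = FALSE)
  }
  keep <- stats::complete.cases(tab[, vars])
  dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  for (v in panel_markers()) tab[[v]] <- log(tab[[v]])
  tab$log_selenium <- log(tab$selenium_ugL)
  attr(tab, "n_dropped") <- dropped
  attr(tab, "stage_report") <- stage_report("preprocess", tab,
                                            list(rows_dropped = dropped))
  tab
}

stage_report <- function(stage, data, stats, warnings = character(0)) {
  structure(list(stage = stage,
                 n = nrow(data),
                 seed = attr(data, "seed", exact = TRUE),
                 config_hash = attr(data, "config_hash", exact = TRUE),
                 statistics = stats,
                 warnings = warnings),
            class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat(sprintf("[%s] n = %d\n", x$stage, x$n))
  utils::str(x$statistics, max.level = 2, give.attr = FALSE)
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' First-order partial correlation
#'
#' Closed form \eqn{r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#' \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations.
#' @return the partial correlation of x and y given z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (any(den <= 0)) stop("degenerate correlation with the covariate",
                          call. = FALSE)
  (r_xy - r_xz * r_yz) / den
}

#' Age-adjustment screen of the biomarker correlation matrix
#'
#' Computes the raw pairwise correlation matrix of the 13 log biomarkers
#' plus log selenium, partials age out of every pair, and reports the
#' percentage of pairs whose sign and two-sided significance status
#' (alpha = 0.05) are identical before and after adjustment — the
#' criterion for "the variable relations remained the same".
#'
#' @param tab analysis table from [preprocess()] (baseline rows are used).
#' @param alpha significance level for the status comparison.
#' @return list with `raw` and `partial` correlation matrices,
#'   `percent_unchanged` (0-100), `n` and a `stage_report`.
#' @export
age_partial_adjustment <- function(tab, alpha = 0.05) {
  tab <- baseline_rows(tab)
  vars <- c(panel_markers(), "log_selenium")
  if (!all(vars %in% names(tab)))
    stop("run preprocess() first (log_selenium missing)", call. = FALSE)
  n <- nrow(tab)
  if (n <= 3) stop("need n > 3 for partial correlations", call. = FALSE)
  if (any(vapply(tab[vars], stats::sd, numeric(1)) == 0) ||
      stats::sd(tab$age_years) == 0)
    stop("constant column", call. = FALSE)
  R <- stats::cor(tab[, vars])
  ra <- stats::cor(tab[, vars], tab$age_years)[, 1]
  P <- R
  for (i in seq_along(vars)) for (j in seq_along(vars))
    if (i != j) P[i, j] <- partial_correlation(R[i, j], ra[i], ra[j])

  crit <- function(r, df) abs(r) * sqrt(df / (1 - r^2)) >
    stats::qt(1 - alpha / 2, df)
  same <- 0L; total <- 0L
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i < j) {
      total <- total + 1L
      s_raw <- crit(R[i, j], n - 2)
      s_par <- crit(P[i, j], n - 3)
      if (s_raw == s_par && sign(R[i, j]) == sign(P[i, j]))
        same <- same + 1L
    }
  }
  pct <- 100 * same / total
  list(raw = R, partial = P, percent_unchanged = pct, n = n,
       age_correlations = ra,
       stage_report = stage_report("age_partial_adjustment", tab,
                                   list(percent_unchanged = pct)))
}

#' Selenium/age quotient
#'
#' Adds the exogenous selenium-status variable `sel_age` =
#' selenium (ug/L) / age (years), raw scales, and reports its Pearson
#' correlations with selenium and age.
#'
#' @param tab analysis table (any occasion; the column is added row-wise).
#' @return list with `table` (tab + `sel_age` column), `cor_selenium`,
#'   `cor_age`, `stage_report`.
#' @export
sel_age_quotient <- function(tab) {
  if (any(tab$age_years <= 0)) stop("age must be positive", call. = FALSE)
  tab$sel_age <- tab$selenium_ugL / tab$age_years
  b <- baseline_rows(tab)
  safe_cor <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  cs <- safe_cor(b$sel_age, b$selenium_ugL)
  ca <- safe_cor(b$sel_age, b$age_years)
  list(table = tab, cor_selenium = cs, cor_age = ca,
       stage_report = stage_report("sel_age_quotient", tab,
                                   list(cor_selenium = cs, cor_age = ca)))
}

baseline_rows <- function(tab) {
  if ("occasion_months" %in% names(tab))
    tab[tab$occasion_months == 0, , drop = FALSE]
  else tab
}

#' Three-factor CFA of the biomarker panel
#'
#' Fits the measurement model (inflammation 4, oxidative stress 2,
#' fibrosis 6 indicators; freely correlated factors) to the baseline
#' occasion by maximum likelihood and attaches construct reliabilities.
#'
#' @param tab analysis table from [preprocess()].
#' @param ... passed to [sem_fit()].
#' @return a `sem_fit`.
#' @export
run_cfa_stage <- function(tab, ...) {
  sem_fit(panel_cfa_model(), baseline_rows(tab), ...)
}

#' Full second-order structural model
#'
#' Fits the complete model: three biomarker factors plus single-indicator
#' myocardium (NT-proBNP), the second-order inflammation/oxidative-stress
#' factor, and the exogenous selenium/age quotient with paths to the
#' second-order factor and from it to fibrosis and myocardium. Refuses a
#' table lacking the `sel_age` column (stage order).
#'
#' @param tab analysis table with the `sel_age` column (see
#'   [sel_age_quotient()]).
#' @param ... passed to [sem_fit()].
#' @return a `sem_fit` with an extra `indirect` element: the mediated
#'   selenium effects on each downstream factor (standardized products).
#' @export
run_sem_stage <- function(tab, ...) {
  if (!"sel_age" %in% names(tab))
    stop("sel_age column missing: run sel_age_quotient() before the SEM stage",
         call. = FALSE)
  fit <- sem_fit(panel_sem_model(), baseline_rows(tab), ...)
  fit$indirect <- lapply(
    c(Inflammation = "Inflammation", OxStress = "OxStress",
      Fibrosis = "Fibrosis", Myocardium = "Myocardium"),
    function(tg) indirect_effects(fit, "sel_age", tg))
  fit
}

#' Paired t statistic
#'
#' Differences are taken as first minus second occasion, so an increase
#' over time yields a negative t (the study's printed sign convention).
#'
#' @param x1,x2 paired measurements (baseline, follow-up).
#' @return list `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(x1, x2) {
  d <- x1 - x2
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1,
       p = 2 * stats::pt(-abs(t), n - 1),
       mean_diff = mean(d), n = n)
}

#' Arm-wise factor-score change tests
#'
#' Scores every subject on the fitted factors at both occasions (scores
#' from the baseline-fitted model applied to both occasions' data) and
#' runs a paired t test of baseline minus 48 months per factor and arm.
#'
#' @param tab analysis table containing both occasions (preprocessed; with
#'   `sel_age` if the fitted model needs it).
#' @param fit the baseline `sem_fit` whose factors are scored (typically
#'   the CFA stage fit).
#' @param factors latents to test (default: the fit's multi-indicator
#'   factors plus any single-indicator factors).
#' @return data.frame with columns `factor, arm, n, t, df, p, mean_diff`,
#'   plus a `stage_report` attribute. Subjects missing an occasion are
#'   excluded with a warning.
#' @export
arm_change_tests <- function(tab, fit,
                             factors = names(fit$model$factors)) {
  b <- tab[tab$occasion_months == 0, , drop = FALSE]
  f <- tab[tab$occasion_months == 48, , drop = FALSE]
  common <- intersect(b$subject_id, f$subject_id)
  n_un <- (nrow(b) - length(common)) + (nrow(f) - length(common))
  warn <- character(0)
  if (n_un > 0) {
    warn <- sprintf("%d unmatched occasion rows excluded", n_un)
    warning(warn, call. = FALSE)
  }
  b <- b[match(common, b$subject_id), , drop = FALSE]
  f <- f[match(common, f$subject_id), , drop = FALSE]
  # both occasions centered at the baseline means: score differences then
  # measure absolute 48-month shifts, not deviations from the occasion mean
  # block-restricted scores: with correlated factors a full regression
  # score borrows from neighbouring blocks and a shift in one construct
  # would bleed into every other factor's change test
  ctr <- colMeans(as.matrix(b[, fit$model$manifest, drop = FALSE]))
  s1 <- factor_scores(fit, b, latents = factors, center = ctr,
                      indicators = "own")
  s2 <- factor_scores(fit, f, latents = factors, center = ctr,
                      indicators = "own")
  rows <- list()
  for (fac in factors) for (a in unique(b$arm)) {
    sel <- b$arm == a
    tt <- paired_t(s1[sel, fac], s2[sel, fac])
    rows[[length(rows) + 1L]] <-
      data.frame(factor = fac, arm = a, n = tt$n, t = tt$t, df = tt$df,
                 p = tt$p, mean_diff = tt$mean_diff,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "stage_report") <- stage_report("arm_change_tests", b,
                                            list(tests = out), warn)
  out
}

#' Cardiovascular-age regression
#'
#' Ordinary least squares of chronological age on selenium and NT-proBNP
#' (log scale by default), the basis of the "CV age" predictor: an
#' algorithm estimating the functional age of the heart from the two
#' markers. Returns the fitted coefficients with t statistics, the
#' overall ANOVA block, the correlation of observed age with the fitted
#' CV age, and a pure predictor function that can also be run with
#' user-supplied (e.g. published) coefficients.
#'
#' @param tab analysis table (baseline rows used).
#' @param scale `"log"` (default; natural logs of both markers), `"raw"`,
#'   or `"zlog"` (z-scored logs).
#' @return list with `coefficients` (data.frame: term, estimate, se, t,
#'   p), `anova` (`mean_square`, `f_ratio`, `p`; `perfect_fit` flag when
#'   the residual variance is 0), `cor_age_cvage`, `predictor`
#'   (`function(selenium, ntprobnp, coef = fitted)`), `scale`,
#'   `stage_report`.
#' @export
cv_age_regression <- function(tab, scale = c("log", "raw", "zlog")) {
  scale <- match.arg(scale)
  b <- baseline_rows(tab)
  # the analysis table carries log(ntprobnp) in the marker column;
  # build the design on the chosen scale from raw quantities
  sel_raw <- b$selenium_ugL
  ntp_log <- b$ntprobnp                    # natural log after preprocess()
  X <- switch(scale,
              raw = data.frame(selenium = sel_raw, ntprobnp = exp(ntp_log)),
              log = data.frame(selenium = log(sel_raw), ntprobnp = ntp_log),
              zlog = data.frame(selenium = as.numeric(scale(log(sel_raw))),
                                ntprobnp = as.numeric(scale(ntp_log))))
  dat <- cbind(age = b$age_years, X)
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < 3) stop("rank-deficient design", call. = FALSE)
  m <- stats::lm(age ~ selenium + ntprobnp, data = dat)
  sm <- summary(m)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  an <- stats::anova(m)
  perfect <- sm$sigma < 1e-10
  anova_block <- if (perfect) {
    list(mean_square = NA_real_, f_ratio = Inf, p = 0, perfect_fit = TRUE)
  } else {
    ms_model <- sum(an[1:2, "Sum Sq"]) / sum(an[1:2, "Df"])
    f <- ms_model / an["Residuals", "Mean Sq"]
    list(mean_square = ms_model, f_ratio = f,
         p = stats::pf(f, 2, an["Residuals", "Df"], lower.tail = FALSE),
         perfect_fit = FALSE)
  }
  beta <- stats::coef(m)
  mu_sel <- mean(X$selenium); sd_sel <- stats::sd(X$selenium)
  mu_ntp <- mean(X$ntprobnp); sd_ntp <- stats::sd(X$ntprobnp)
  predictor <- function(selenium, ntprobnp, coef = beta) {
    v <- switch(scale,
                raw = cbind(selenium, ntprobnp),
                log = cbind(log(selenium), log(ntprobnp)),
                zlog = cbind((log(selenium) - mu_sel) / sd_sel,
                             (log(ntprobnp) - mu_ntp) / sd_ntp))
    as.numeric(coef[1] + v %*% coef[2:3])
  }
  cv <- stats::fitted(m)
  list(coefficients = co, anova = anova_block,
       cor_age_cvage = stats::cor(b$age_years, cv),
       predictor = predictor, scale = scale,
       stage_report = stage_report("cv_age_regression", b,
                                   list(coefficients = co,
                                        anova = anova_block)))
}

#' Pearson chi-square for a 2x2 table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} over the four cells, no continuity
#' correction, 1 degree of freedom.
#'
#' @param counts 2x2 matrix (or 4 counts, row-wise) of non-negative
#'   integers.
#' @return list `chi_square`, `df`, `p_value`, `table` (with margins
#'   preserved as attributes).
#' @examples
#' chisq_2x2(matrix(c(29, 78, 16, 95), 2, byrow = TRUE)) # ~5.35
#' @export
chisq_2x2 <- function(counts) {
  O <- if (is.matrix(counts)) matrix(as.numeric(counts), 2, 2)
       else matrix(as.numeric(counts), 2, 2, byrow = TRUE)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0) || N == 0)
    stop("degenerate 2x2 table (empty margin)", call. = FALSE)
  E <- outer(rs, cs) / N
  x2 <- sum((O - E)^2 / E)
  list(chi_square = x2, df = 1L,
       p_value = stats::pchisq(x2, 1, lower.tail = FALSE),
       table = O, expected = E)
}

#' Selenium-quartile mortality test
#'
#' Splits subjects into serum-selenium quartiles (stable tie-breaking),
#' tabulates 5-year cardiovascular deaths in the lowest vs highest
#' quartile, and tests homogeneity with the Pearson chi-square (1 df, no
#' continuity correction).
#'
#' @param cohort a cohort or analysis table with `selenium_ugL` and
#'   `cv_death_5y` (baseline rows used).
#' @return list `table` (2x2: quartile x death), `chi_square`, `df`,
#'   `p_value`, `rates` (death fraction per extreme quartile),
#'   `stage_report`.
#' @export
quartile_mortality_test <- function(cohort) {
  b <- baseline_rows(as.data.frame(cohort))
  b <- b[!is.na(b$cv_death_5y), , drop = FALSE]
  if (nrow(b) < 8) stop("need at least 8 subjects", call. = FALSE)
  qi <- selenium_quartile(b$selenium_ugL)
  lo <- b$cv_death_5y[qi == 1]
  hi <- b$cv_death_5y[qi == 4]
  if (!length(lo) || !length(hi)) stop("empty quartile", call. = FALSE)
  O <- matrix(c(sum(lo), length(lo) - sum(lo),
                sum(hi), length(hi) - sum(hi)),
              2, 2, byrow = TRUE,
              dimnames = list(c("lowest_quartile", "highest_quartile"),
                              c("dead", "alive")))
  ch <- chisq_2x2(O)
  res <- list(table = O, chi_square = ch$chi_square, df = ch$df,
              p_value = ch$p_value,
              rates = c(lowest = mean(lo), highest = mean(hi)))
  res$stage_report <- stage_report("quartile_mortality_test", b,
                                   res[c("chi_square", "p_value", "rates")])
  res
}

#' Run the complete study pipeline
#'
#' Simulate (or accept) a cohort, then execute the analysis stages in
#' order: preprocess, age partial-correlation screen, selenium/age
#' quotient, three-factor CFA, full structural model with mediated
#' effects, arm-wise factor change tests (rct mode), cardiovascular-age
#' regression, and the selenium-quartile mortality test. Any stage error
#' halts the pipeline with the stage named.
#'
#' @param config a [generator_config].
#' @param seed RNG seed (default `config$seed`).
#' @param cohort optionally, an existing `cohort_table` to analyse
#'   instead of simulating.
#' @param n optional subject-count override for simulation.
#' @return object of class `pipeline_report`: named list of stage results
#'   (`simulate`, `preprocess`, `age_check`, `quotient`, `cfa`, `sem`,
#'   `arm_changes`, `cv_age`, `mortality`) plus `seed` and `config`.
#' @export
run_full_pipeline <- function(config = generator_config(),
                              seed = config$seed, cohort = NULL, n = NULL) {
  stage <- "simulate"
  res <- list(seed = seed, config = config)
  tryCatch({
    if (is.null(cohort)) cohort <- simulate_cohort(config, n = n, seed = seed)
    res$simulate <- list(n_rows = nrow(cohort),
                         n_subjects = length(unique(cohort$subject_id)))
    stage <- "preprocess"
    tab <- preprocess(cohort)
    res$preprocess <- attr(tab, "stage_report")
    stage <- "age_check"
    res$age_check <- age_partial_adjustment(tab)
    stage <- "quotient"
    qt <- sel_age_quotient(tab)
    res$quotient <- qt[c("cor_selenium", "cor_age")]
    tab <- qt$table
    stage <- "cfa"
    res$cfa <- run_cfa_stage(tab)
    stage <- "sem"
    res$sem <- run_sem_stage(tab)
    if (config$mode == "rct") {
      stage <- "arm_changes"
      res$arm_changes <- arm_change_tests(tab, res$cfa)
    }
    stage <- "cv_age"
    res$cv_age <- cv_age_regression(tab)
    stage <- "mortality"
    res$mortality <- quartile_mortality_test(cohort)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  structure(res, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("cohortsem pipeline report (seed =", x$seed, ", mode =",
      x$config$mode, ")\n")
  cat(sprintf("  cohort: %d rows, %d subjects\n",
              x$simulate$n_rows, x$simulate$n_subjects))
  cat(sprintf("  age screen: %.1f%% of variable relations unchanged\n",
              x$age_check$percent_unchanged))
  cat(sprintf("  sel/age quotient: r(selenium) = %.2f, r(age) = %.2f\n",
              x$quotient$cor_selenium, x$quotient$cor_age))
  cat(sprintf("  CFA: RMSEA = %.3f, CFI = %.3f; CR = %s\n",
              x$cfa$rmsea, x$cfa$cfi,
              paste(sprintf("%.2f", x$cfa$construct_reliabilities),
                    collapse = "/")))
  sb <- x$sem$standardized$beta
  cat(sprintf("  SEM: sel->IO %.2f, IO->Fib %.2f, IO->Myo %.2f, SO %.2f/%.2f\n",
              sb["InflOxStress", "sel_age"], sb["Fibrosis", "InflOxStress"],
              sb["Myocardium", "InflOxStress"],
              sb["Inflammation", "InflOxStress"],
              sb["OxStress", "InflOxStress"]))
  if (!is.null(x$arm_changes)) {
    cat("  arm changes (t, baseline - 48 mo):\n")
    ac <- x$arm_changes
    for (i in seq_len(nrow(ac)))
      cat(sprintf("    %-12s %-8s t = %6.2f  p = %.3g\n",
                  ac$factor[i], ac$arm[i], ac$t[i], ac$p[i]))
  }
  cat(sprintf("  CV-age: %s\n",
              paste(sprintf("%s %.3f", x$cv_age$coefficients$term,
                            x$cv_age$coefficients$estimate), collapse = ", ")))
  cat(sprintf("  quartile mortality: chi2 = %.2f, p = %.3g (rates %.3f vs %.3f)\n",
              x$mortality$chi_square, x$mortality$p_value,
              x$mortality$rates["lowest"], x$mortality$rates["highest"]))
  invisible(x)
}
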