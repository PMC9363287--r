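#' Declarative covariance-structure model specifications
#'
#' A `sem_model` describes the measurement and structural parts of a
#' covariance-structure model: manifest (observed) variables, first-order
#' latent factors with their indicators, an optional second-order factor
#' governing a subset of the first-order factors, directed structural paths
#' among latents, and the identification rule used to give every latent a
#' scale.
#'
#' The plain-text grammar accepted by [parse_model()] has one statement per
#' line (`#` starts a comment):
#'
#' \preformatted{
#' factor <Name>: <ind1> <ind2> ...
#' factor <Name>: <ind> fix_error=<value>
#' second_order <Name>: <F1> <F2> ...
#' observed_exogenous <Name>
#' path <A> -> <B>
#' }
#'
#' `observed_exogenous` declares a manifest variable that enters the latent
#' system directly (loading fixed to 1, measurement error fixed to 0).
#' Single-indicator factors must carry an explicit `fix_error=` value.
#'
#' @param text Character scalar (or vector of lines) with the model
#'   description.
#' @param identification Scale-setting rule: `"marker"` fixes the first
#'   loading of every latent to 1; `"unit"` fixes every latent
#'   (co)variance/disturbance to 1 and frees all loadings. Both yield the
#'   same standardized solution.
#' @return An object of class `sem_model`: a list with elements
#'   `manifest` (ordered manifest names), `latents` (ordered latent names:
#'   first-order factors, then second-order, then observed-exogenous),
#'   `factors` (named list of indicator vectors), `second_order`,
#'   `observed_exogenous`, `paths` (two-column matrix `from`/`to`),
#'   `fixed_error` (named numeric), `identification`.
#' @examples
#' m <- parse_model("
#'   factor F1: y1 y2 y3
#'   factor F2: y4 y5
#'   path F1 -> F2
#' ")
#' m$latents
#' @export
parse_model <- function(text, identification = c("marker", "unit")) {
  identification <- match.arg(identification)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty model specification", call. = FALSE)

  factors <- list()
  fixed_error <- numeric(0)
  second_order <- NULL
  obs_exo <- character(0)
  paths <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))

  perr <- function(line, msg) {
    stop(sprintf("model spec error in line '%s': %s", line, msg), call. = FALSE)
  }

  for (ln in lines) {
    toks <- strsplit(ln, "\\s+")[[1]]
    head <- toks[1]
    if (head == "factor") {
      body <- sub("^factor\\s+", "", ln)
      if (!grepl(":", body)) perr(ln, "expected 'factor <Name>: <indicators>'")
      nm <- trimws(sub(":.*$", "", body))
      rest <- strsplit(trimws(sub("^[^:]*:", "", body)), "\\s+")[[1]]
      fe <- grepl("^fix_error=", rest)
      inds <- rest[!fe]
      if (nm %in% names(factors)) perr(ln, sprintf("factor '%s' declared twice", nm))
      if (!length(inds)) perr(ln, "factor with no indicators")
      if (any(fe)) {
        val <- as.numeric(sub("^fix_error=", "", rest[fe][1]))
        if (is.na(val) || val < 0) perr(ln, "fix_error must be a non-negative number")
        fixed_error[nm] <- val
      }
      if (length(inds) == 1 && !nm %in% names(fixed_error))
        perr(ln, "single-indicator factor needs an explicit fix_error=")
      factors[[nm]] <- inds
    } else if (head == "second_order") {
      if (!is.null(second_order)) perr(ln, "only one second_order statement supported")
      body <- sub("^second_order\\s+", "", ln)
      nm <- trimws(sub(":.*$", "", body))
      governed <- strsplit(trimws(sub("^[^:]*:", "", body)), "\\s+")[[1]]
      if (length(governed) < 2) perr(ln, "second-order factor needs >= 2 first-order factors")
      second_order <- list(name = nm, governs = governed)
    } else if (head == "observed_exogenous") {
      if (length(toks) != 2) perr(ln, "expected 'observed_exogenous <Name>'")
      obs_exo <- c(obs_exo, toks[2])
    } else if (head == "path") {
      if (length(toks) != 4 || toks[3] != "->")
        perr(ln, "expected 'path <A> -> <B>'")
      paths <- rbind(paths, c(toks[2], toks[4]))
    } else {
      perr(ln, sprintf("unknown statement '%s'", head))
    }
  }

  inds_all <- unlist(factors, use.names = FALSE)
  dup <- unique(inds_all[duplicated(inds_all)])
  if (length(dup))
    stop(sprintf("indicator(s) assigned to more than one factor: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  if (any(obs_exo %in% inds_all))
    stop("observed_exogenous variable cannot also be a factor indicator",
         call. = FALSE)

  manifest <- c(inds_all, obs_exo)
  latents <- c(names(factors),
               if (!is.null(second_order)) second_order$name,
               obs_exo)
  if (anyDuplicated(latents))
    stop("duplicated latent names", call. = FALSE)

  if (!is.null(second_order)) {
    bad <- setdiff(second_order$governs, names(factors))
    if (length(bad))
      stop(sprintf("second_order governs unknown factor(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nrow(paths)) {
    bad <- setdiff(c(paths), latents)
    if (length(bad))
      stop(sprintf("path references unknown latent(s): %s",
                   paste(unique(bad), collapse = ", ")), call. = FALSE)
  }

  m <- structure(list(manifest = manifest,
                      latents = latents,
                      factors = factors,
                      second_order = second_order,
                      observed_exogenous = obs_exo,
                      paths = paths,
                      fixed_error = fixed_error,
                      identification = identification),
                 class = "sem_model")
  edges <- latent_edges(m)
  if (has_cycle(edges, m$latents))
    stop("directed path graph is cyclic", call. = FALSE)
  m
}

# All directed latent-level edges: structural paths plus second-order
# loadings (second-order factor -> governed first-order factor).
latent_edges <- function(model) {
  e <- model$paths
  if (!is.null(model$second_order)) {
    so <- model$second_order
    e <- rbind(e, cbind(rep(so$name, length(so$governs)), so$governs))
  }
  colnames(e) <- c("from", "to")
  e
}

has_cycle <- function(edges, nodes) {
  if (!nrow(edges)) return(FALSE)
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  adj <- split(edges[, "to"], factor(edges[, "from"], levels = nodes))
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (visit(v)) return(TRUE)
  FALSE
}

# Latents with no incoming edge in the latent graph (exogenous): these get
# free variances and, by default, free covariances among themselves.
exogenous_latents <- function(model) {
  e <- latent_edges(model)
  setdiff(model$latents, unique(e[, "to"]))
}

#' @export
print.sem_model <- function(x, ...) {
  cat("sem_model:", length(x$manifest), "manifest variables,",
      length(x$latents), "latents\n")
  for (f in names(x$factors))
    cat("  factor", f, ":", paste(x$factors[[f]], collapse = " "), "\n")
  if (!is.null(x$second_order))
    cat("  second_order", x$second_order$name, ":",
        paste(x$second_order$governs, collapse = " "), "\n")
  for (v in x$observed_exogenous) cat("  observed_exogenous", v, "\n")
  if (nrow(x$paths))
    for (i in seq_len(nrow(x$paths)))
      cat("  path", x$paths[i, 1], "->", x$paths[i, 2], "\n")
  cat("  identification:", x$identification, "\n")
  invisible(x)
}

#' Built-in model descriptions for the 13-biomarker panel
#'
#' `panel_cfa_model()` is the three-factor measurement model
#' (inflammation: TNFr1, TNFr2, osteoprotegerin, osteopontin; oxidative
#' stress: copeptin, MR-proADM; fibrosis: endostatin, galectin-3, TIMP-1,
#' cathepsin S, GDF-15, MMP-1) with freely correlated factors.
#' `panel_sem_model()` adds the single-indicator myocardium factor
#' (NT-proBNP), the second-order inflammation/oxidative-stress factor and
#' the exogenous selenium/age quotient with its three structural paths.
#'
#' @param identification passed to [parse_model()].
#' @return A `sem_model`.
#' @export
panel_cfa_model <- function(identification = "marker") {
  parse_model(panel_cfa_text(), identification = identification)
}

#' @rdname panel_cfa_model
#' @export
panel_sem_model <- function(identification = "marker") {
  parse_model(panel_sem_text(), identification = identification)
}

panel_cfa_text <- function() {
  paste(
    "factor Inflammation: tnfr1 tnfr2 opg opn",
    "factor OxStress: copeptin mrproadm",
    "factor Fibrosis: endostatin galectin3 timp1 cathepsin_s gdf15 mmp1",
    sep = "\n")
}

panel_sem_text <- function() {
  paste(
    panel_cfa_text(),
    "factor Myocardium: ntprobnp fix_error=0",
    "second_order InflOxStress: Inflammation OxStress",
    "observed_exogenous sel_age",
    "path sel_age -> InflOxStress",
    "path InflOxStress -> Fibrosis",
    "path InflOxStress -> Myocardium",
    sep = "\n")
}
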