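# Sequential path models and bias-corrected bootstrap mediation ----------
#
# The path model is an ordered DAG of standardized linear regressions:
# each node is regressed on its declared parents plus the covariates, all
# continuous variables standardized (binary covariates centred only).
# Indirect effects are products of path coefficients along directed
# chains; inference uses bias-corrected (BC) bootstrap percentile
# intervals over participant resamples.

#' Construct a path-model specification
#'
#' @param ordered_nodes node names in causal order; these must be columns
#'   of the cohort table when fitting.
#' @param edges data frame with columns `from`, `to`; every edge must go
#'   forward in node order.
#' @param covariates covariate column names entered into every node
#'   regression (default age, sex, APOE4, ICV).
#' @param n_boot bootstrap iterations (default 10000).
#' @param alpha CI level complement (default 0.05 for 95% intervals).
#' @param seed integer seed for the bootstrap.
#' @return A `path_model_spec`.
#' @export
path_model_spec <- function(ordered_nodes, edges,
                            covariates = c("age", "sex", "apoe4", "icv"),
                            n_boot = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  pos <- stats::setNames(seq_along(ordered_nodes), ordered_nodes)
  if (!all(edges$from %in% ordered_nodes) || !all(edges$to %in% ordered_nodes))
    stop("edge endpoints must be declared nodes")
  if (any(pos[edges$from] >= pos[edges$to]))
    stop("edges must respect node order (acyclic)")
  if (n_boot < 100L) stop("n_boot must be >= 100")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  structure(list(ordered_nodes = ordered_nodes, edges = edges,
                 covariates = covariates, n_boot = as.integer(n_boot),
                 alpha = alpha, seed = as.integer(seed)),
            class = "path_model_spec")
}

#' Published path-model topologies
#'
#' Two sequential topologies over the extracted biomarkers. `"amyloid"`:
#' choroid plexus volume and ventricular radioactivity act on neocortical
#' amyloid with ventricular volume as the mediator (vr_amyloid -> vv,
#' cpv -> vv, vv -> abeta, plus the direct cpv/vr -> abeta edges).
#' `"tau"`: extends the chain to temporal tau with neocortical amyloid as
#' the downstream mediator.
#'
#' @param which "amyloid" or "tau".
#' @param ... passed to [path_model_spec()] (n_boot, alpha, seed,
#'   covariates).
#' @return A `path_model_spec` over columns `cpv_resid`, `vr_amyloid`,
#'   `vv_resid`, `abeta_neocortex` (and `tau_metaroi` for "tau").
#' @export
path_preset <- function(which = c("amyloid", "tau"), ...) {
  which <- match.arg(which)
  if (which == "amyloid") {
    nodes <- c("cpv_resid", "vr_amyloid", "vv_resid", "abeta_neocortex")
    edges <- data.frame(
      from = c("cpv_resid", "cpv_resid", "vr_amyloid", "cpv_resid", "vr_amyloid", "vv_resid"),
      to   = c("vr_amyloid", "vv_resid", "vv_resid", "abeta_neocortex", "abeta_neocortex", "abeta_neocortex"),
      stringsAsFactors = FALSE)
  } else {
    nodes <- c("cpv_resid", "vr_amyloid", "vv_resid", "abeta_neocortex", "tau_metaroi")
    edges <- data.frame(
      from = c("cpv_resid", "cpv_resid", "vr_amyloid", "cpv_resid", "vr_amyloid", "vv_resid",
               "vv_resid", "abeta_neocortex"),
      to   = c("vr_amyloid", "vv_resid", "vv_resid", "abeta_neocortex", "abeta_neocortex", "abeta_neocortex",
               "tau_metaroi", "tau_metaroi"),
      stringsAsFactors = FALSE)
  }
  path_model_spec(nodes, edges, ...)
}

# internal: fit all node regressions on a numeric matrix; returns named
# edge coefficients ("from->to")
fit_paths_matrix <- function(M, spec) {
  cols <- colnames(M)
  out <- numeric(nrow(spec$edges))
  names(out) <- paste0(spec$edges$from, "->", spec$edges$to)
  for (node in unique(spec$edges$to)) {
    parents <- spec$edges$from[spec$edges$to == node]
    X <- cbind(1, M[, c(parents, spec$covariates), drop = FALSE])
    fit <- stats::.lm.fit(X, M[, node])
    if (any(abs(diag(fit$qr)[seq_len(ncol(X))]) < 1e-10))
      stop("collinearity in node regression for ", node)
    cf <- fit$coefficients[1 + seq_along(parents)]
    out[paste0(parents, "->", node)] <- cf
  }
  out
}

standardize_matrix <- function(data, vars) {
  M <- vapply(vars, function(v) standardize_column(data[[v]]),
              numeric(nrow(data)))
  colnames(M) <- vars
  M
}

#' Fit a sequential path model
#'
#' Each node, in causal order, is regressed (standardized) on its declared
#' parents plus the covariates; coefficients are standardized partial
#' effects.
#'
#' @param cohort data frame with node and covariate columns.
#' @param spec a [path_model_spec()].
#' @return A `path_model` object with `coefficients` (named edge
#'   coefficients), `spec`, `n`.
#' @export
fit_path_model <- function(cohort, spec) {
  vars <- c(spec$ordered_nodes, spec$covariates)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols))
    stop("schema error, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- cohort[stats::complete.cases(cohort[vars]), vars, drop = FALSE]
  n_par <- nrow(spec$edges) + length(spec$covariates)
  if (nrow(d) <= n_par + 5L) stop("too few complete cases")
  M <- standardize_matrix(d, vars)
  structure(list(coefficients = fit_paths_matrix(M, spec),
                 spec = spec, n = nrow(d)),
            class = "path_model")
}

#' @export
coef.path_model <- function(object, ...) object$coefficients

#' @export
print.path_model <- function(x, ...) {
  cat(sprintf("Sequential path model (n = %d)\n", x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

# enumerate all directed paths of length >= 2 ending at the terminal node
enumerate_paths <- function(spec) {
  terminal <- spec$ordered_nodes[length(spec$ordered_nodes)]
  adj <- split(spec$edges$to, spec$edges$from)
  paths <- list()
  walk <- function(chain) {
    last <- chain[length(chain)]
    if (last == terminal && length(chain) >= 3L) {
      paths[[length(paths) + 1L]] <<- chain
    }
    for (nxt in adj[[last]]) walk(c(chain, nxt))
  }
  for (start in setdiff(spec$ordered_nodes, terminal)) walk(start)
  paths
}

#' Indirect effects as path products
#'
#' Enumerates every directed path of length >= 2 from each upstream node
#' to the terminal outcome and multiplies the constituent edge
#' coefficients.
#'
#' @param model a fitted `path_model` (or a named coefficient vector with
#'   names "from->to").
#' @param spec the `path_model_spec`; taken from the model when omitted.
#' @return Data frame with `path` (node sequence, "a>b>c") and `estimate`.
#' @export
indirect_effects <- function(model, spec = NULL) {
  if (inherits(model, "path_model")) {
    if (is.null(spec)) spec <- model$spec
    coefs <- model$coefficients
  } else coefs <- model
  paths <- enumerate_paths(spec)
  est <- vapply(paths, function(p) {
    prod(coefs[paste0(p[-length(p)], "->", p[-1])])
  }, numeric(1))
  data.frame(path = vapply(paths, paste, "", collapse = ">"),
             estimate = est, stringsAsFactors = FALSE)
}

#' Bias-corrected bootstrap mediation analysis
#'
#' Resamples participants with replacement, refits the full path model per
#' resample, and forms bias-corrected (BC) percentile intervals for every
#' indirect effect: z0 is the normal quantile of the proportion of
#' bootstrap estimates below the point estimate, and the interval
#' endpoints are the bootstrap quantiles at Phi(2*z0 -+ z_(1-alpha/2)).
#' An effect is flagged significant when its CI excludes zero. Resamples
#' with a rank-deficient node regression are rejected and redrawn.
#'
#' @param cohort data frame with node and covariate columns.
#' @param spec a [path_model_spec()]; `n_boot`, `alpha` and `seed` are
#'   taken from it.
#' @return A `mediation_result`: `path_coefficients`, `indirect` (path,
#'   estimate, ci_lo, ci_hi, significant), `direct` (per-edge estimate and
#'   BC CI), `n_boot_used`, `n_rejected`.
#' @export
bootstrap_ci <- function(cohort, spec) {
  point <- fit_path_model(cohort, spec)
  vars <- c(spec$ordered_nodes, spec$covariates)
  d <- cohort[stats::complete.cases(cohort[vars]), vars, drop = FALSE]
  n <- nrow(d)
  ind_point <- indirect_effects(point)

  set.seed(spec$seed)
  B <- spec$n_boot
  boot_edges <- matrix(NA_real_, B, nrow(spec$edges))
  boot_ind <- matrix(NA_real_, B, nrow(ind_point))
  rejected <- 0L
  b <- 1L
  while (b <= B) {
    rows <- sample.int(n, n, replace = TRUE)
    cf <- tryCatch(fit_paths_matrix(standardize_matrix(d[rows, ], vars), spec),
                   error = function(e) NULL)
    if (is.null(cf)) { rejected <- rejected + 1L; next }
    boot_edges[b, ] <- cf
    boot_ind[b, ] <- indirect_effects(cf, spec)$estimate
    b <- b + 1L
  }
  if (rejected > 0.05 * B)
    warning(rejected, " bootstrap resamples rejected for rank deficiency")

  bc_ci <- function(draws, est, alpha) {
    prop <- mean(draws < est)
    prop <- min(max(prop, 1 / (length(draws) + 1)),
                1 - 1 / (length(draws) + 1))
    z0 <- stats::qnorm(prop)
    za <- stats::qnorm(1 - alpha / 2)
    qs <- stats::pnorm(c(2 * z0 - za, 2 * z0 + za))
    stats::quantile(draws, qs, names = FALSE, type = 7)
  }

  ind <- ind_point
  cis <- t(vapply(seq_len(nrow(ind)), function(i)
    bc_ci(boot_ind[, i], ind$estimate[i], spec$alpha), numeric(2)))
  ind$ci_lo <- cis[, 1]; ind$ci_hi <- cis[, 2]
  ind$significant <- ind$ci_lo > 0 | ind$ci_hi < 0

  dir <- data.frame(edge = names(point$coefficients),
                    estimate = unname(point$coefficients),
                    stringsAsFactors = FALSE)
  dcis <- t(vapply(seq_len(nrow(dir)), function(i)
    bc_ci(boot_edges[, i], dir$estimate[i], spec$alpha), numeric(2)))
  dir$ci_lo <- dcis[, 1]; dir$ci_hi <- dcis[, 2]
  dir$significant <- dir$ci_lo > 0 | dir$ci_hi < 0

  structure(list(path_coefficients = point$coefficients,
                 indirect = ind, direct = dir,
                 n = n, n_boot_used = B, n_rejected = rejected,
                 alpha = spec$alpha, spec = spec),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation analysis: n = %d, %d BC bootstrap iterations (%d rejected)\n",
              x$n, x$n_boot_used, x$n_rejected))
  cat("Indirect effects (", 100 * (1 - x$alpha), "% BC CIs):\n", sep = "")
  print(format(x$indirect, digits = 3), row.names = FALSE)
  cat("Direct (edge) effects:\n")
  print(format(x$direct, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mediation_result <- function(object, ...) {
  object
}
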