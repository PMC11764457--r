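#' Linear opinion pool of per-expert fitted distributions
#'
#' Combines fitted distributions for one node into a finite mixture
#' with density `f(x) = sum_i w_i f_i(x)`. Expert opinions are equally
#' weighted by default, regardless of seniority or confidence; unequal
#' weights are supported but must be passed explicitly.
#'
#' @param fits List of `fitted_dist` objects (or bare `family_params`)
#'   for the same node; at least two for a genuine pool.
#' @param weights Optional non-negative weights, normalized to sum to 1.
#'   Default: equal weights `1/n`.
#' @return An object of class `linear_pool`.
#' @export
linear_pool <- function(fits, weights = NULL) {
  if (length(fits) < 1L) stop("empty pool", call. = FALSE)
  comps <- lapply(fits, function(f) {
    if (inherits(f, "fitted_dist")) f$params else .check_family(f)
  })
  node_ids <- unique(unlist(lapply(fits, function(f) {
    if (inherits(f, "fitted_dist")) f$node_id else NULL
  })))
  if (length(node_ids) > 1L) {
    stop("fits belong to different nodes: ",
         paste(node_ids, collapse = ", "), call. = FALSE)
  }
  expert_ids <- unlist(lapply(fits, function(f) {
    if (inherits(f, "fitted_dist")) f$expert_id else NA_character_
  }))
  n <- length(comps)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) {
    stop("need one weight per component", call. = FALSE)
  }
  if (any(weights < 0)) stop("negative weight in pool", call. = FALSE)
  if (sum(weights) <= 0) stop("weights sum to zero", call. = FALSE)
  weights <- weights / sum(weights)
  structure(list(node_id = if (length(node_ids)) node_ids else NA_character_,
                 components = comps, expert_ids = expert_ids,
                 families = vapply(comps, `[[`, character(1), "family"),
                 weights = weights),
            class = "linear_pool")
}

#' Density, CDF, quantile and random generation for a linear pool
#'
#' `dpool`/`ppool` are the weighted component sums; `qpool` inverts the
#' mixture CDF numerically (bisection bracketed on the union of the
#' component 1e-6 / 1-1e-6 quantiles, tolerance 1e-8); `rpool` draws the
#' component index and then from the component.
#'
#' @param pool A [linear_pool()].
#' @param x Evaluation points.
#' @return Numeric vector.
#' @export
dpool <- function(pool, x) {
  .check_pool(pool)
  mat <- vapply(pool$components, function(cp) dfamily(cp, x),
                numeric(length(x)))
  as.numeric(matrix(mat, nrow = length(x)) %*% pool$weights)
}

#' @rdname dpool
#' @export
ppool <- function(pool, x) {
  .check_pool(pool)
  mat <- vapply(pool$components, function(cp) pfamily(cp, x),
                numeric(length(x)))
  as.numeric(matrix(mat, nrow = length(x)) %*% pool$weights)
}

#' @rdname dpool
#' @param p Probabilities strictly inside (0, 1).
#' @export
qpool <- function(pool, p) {
  .check_pool(pool)
  if (any(p <= 0 | p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  lo <- min(vapply(pool$components, qfamily, numeric(1), p = 1e-6))
  hi <- max(vapply(pool$components, qfamily, numeric(1), p = 1 - 1e-6))
  vapply(p, function(pi) {
    stats::uniroot(function(x) ppool(pool, x) - pi, lower = lo, upper = hi,
                   extendInt = "upX", tol = 1e-8)$root
  }, numeric(1))
}

#' @rdname dpool
#' @param n Number of draws.
#' @export
rpool <- function(pool, n) {
  .check_pool(pool)
  idx <- sample.int(length(pool$components), n, replace = TRUE,
                    prob = pool$weights)
  out <- numeric(n)
  for (k in unique(idx)) {
    sel <- idx == k
    out[sel] <- rfamily(pool$components[[k]], sum(sel))
  }
  out
}

.check_pool <- function(pool) {
  if (!inherits(pool, "linear_pool")) {
    stop("expected a 'linear_pool'", call. = FALSE)
  }
  pool
}

#' Closed-form moments of a linear pool
#'
#' `mean = sum w_i m_i`; `var = sum w_i (v_i + m_i^2) - mean^2`.
#' Components without finite moments (log-T types, T with df <= 2)
#' contribute truncated numeric moments when `allow_truncated = TRUE`
#' (the default for pooling, so admissible heavy-tailed fits do not
#' crash the pipeline); the result is then flagged
#' `method = "truncated"`.
#'
#' @param pool A [linear_pool()].
#' @param allow_truncated Substitute truncated moments for undefined
#'   component moments.
#' @return List with `mean`, `sd`, `method`.
#' @export
pool_moments <- function(pool, allow_truncated = TRUE) {
  .check_pool(pool)
  ms <- lapply(pool$components, fam_moments,
               allow_truncated = allow_truncated)
  m <- vapply(ms, `[[`, numeric(1), "mean")
  s <- vapply(ms, `[[`, numeric(1), "sd")
  w <- pool$weights
  mu <- sum(w * m)
  v <- sum(w * (s^2 + m^2)) - mu^2
  list(mean = mu, sd = sqrt(max(v, 0)),
       method = if (any(vapply(ms, `[[`, character(1), "method") ==
                         "truncated")) "truncated" else "closed")
}

#' Family concordance of a fitted panel
#'
#' Counts each expert's best-fit family and reports the prevalent
#' (modal) one as `count` out of `total`, the census printed as e.g.
#' `"T (6/8)"`. Ties are broken by the fixed family precedence order.
#'
#' @param fits List of `fitted_dist` objects (each typically from
#'   [fit_best()]).
#' @return An object of class `concordance_summary` with fields
#'   `node_id`, `prevalent_family`, `count`, `total`.
#' @export
concordance <- function(fits) {
  if (length(fits) < 1L) stop("no fits to summarize", call. = FALSE)
  fams <- vapply(fits, function(f) f$params$family, character(1))
  node_id <- unique(vapply(fits, `[[`, character(1), "node_id"))
  if (length(node_id) > 1L) {
    stop("fits belong to different nodes", call. = FALSE)
  }
  tab <- table(factor(fams, levels = family_names()))
  prevalent <- names(tab)[which.max(tab)]  # which.max keeps first = precedence
  structure(list(node_id = node_id, prevalent_family = prevalent,
                 count = as.integer(max(tab)),
                 total = length(fams)),
            class = "concordance_summary")
}

#' Format a concordance summary as printed in elicitation reports
#'
#' @param x A `concordance_summary`.
#' @return String like `"MirrorlogT (8/8)"`.
#' @export
format_concordance <- function(x) {
  sprintf("%s (%d/%d)", .family_labels[[x$prevalent_family]],
          x$count, x$total)
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance> node %s: %s\n", x$node_id,
              format_concordance(x)))
  invisible(x)
}

#' @export
print.linear_pool <- function(x, ...) {
  cat(sprintf("<linear pool> node %s: %d components (%s)\n",
              x$node_id, length(x$components),
              paste(x$families, collapse = ", ")))
  invisible(x)
}
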