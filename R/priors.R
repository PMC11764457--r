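#' Beta feasibility of a (mean, sd) pair
#'
#' A beta distribution with mean `m` in (0, 1) exists for standard
#' deviation `s` only when `s^2 < m (1 - m)`.
#'
#' @param mean,sd Pooled moments.
#' @return Logical.
#' @export
beta_feasible <- function(mean, sd) {
  is.finite(mean) && is.finite(sd) && mean > 0 && mean < 1 && sd > 0 &&
    sd^2 < mean * (1 - mean)
}

#' Beta prior by moment matching
#'
#' Transforms the pooled mean and standard deviation of a proportion
#' node into beta shape (`alpha`) and scale (`beta`) parameters: with
#' `c = mean (1 - mean) / sd^2 - 1`, `alpha = mean * c` and
#' `beta = (1 - mean) * c`. The round trip beta -> moments -> beta is
#' the identity on the feasible region.
#'
#' @param mean Pooled mean in (0, 1).
#' @param sd Pooled standard deviation; must satisfy
#'   `sd^2 < mean * (1 - mean)`.
#' @return An object of class `beta_prior` with fields `alpha`, `beta`,
#'   `source = "moment_match"`.
#' @examples
#' beta_from_moments(0.56, 0.13)  # alpha ~ 7.60, beta ~ 5.97
#' @export
beta_from_moments <- function(mean, sd) {
  if (!(is.finite(mean) && mean > 0 && mean < 1)) {
    stop("mean must lie in (0, 1)", call. = FALSE)
  }
  if (!beta_feasible(mean, sd)) {
    stop(sprintf(
      "beta-infeasible moments: sd^2 = %.4g must be < mean*(1-mean) = %.4g",
      sd^2, mean * (1 - mean)), call. = FALSE)
  }
  cc <- mean * (1 - mean) / sd^2 - 1
  structure(list(alpha = mean * cc, beta = (1 - mean) * cc,
                 source = "moment_match"),
            class = "beta_prior")
}

#' Moments implied by a beta prior
#'
#' @param prior A `beta_prior` (or anything with `alpha`/`beta` fields).
#' @return List with `mean` and `sd`.
#' @export
beta_moments <- function(prior) {
  a <- prior$alpha; b <- prior$beta
  list(mean = a / (a + b),
       sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

#' Beta prior by quantile interpolation of a pool
#'
#' Least-squares fit of a beta quantile function to the pooled
#' quantiles on a probability grid (default
#' `{0.01, 0.25, 0.5, 0.75, 0.99}`), for proportion nodes whose pooled
#' shape a single moment-matched beta represents poorly.
#'
#' @param pool A [linear_pool()] supported on \[0, 1\].
#' @param probs Probability grid.
#' @return A `beta_prior` with `source = "quantile_interpolation"` and
#'   an `sse` field (squared quantile error attained).
#' @export
beta_from_quantiles <- function(pool, probs = c(0.01, 0.25, 0.5, 0.75,
                                                0.99)) {
  .check_pool(pool)
  sup <- range(vapply(pool$components, function(cp) {
    c(cp$support_lower, cp$support_upper)
  }, numeric(2)))
  if (sup[1] < -1e-9 || sup[2] > 1 + 1e-9) {
    stop("beta_from_quantiles requires node support within [0, 1]",
         call. = FALSE)
  }
  target <- qpool(pool, probs)
  pm <- pool_moments(pool)
  start <- if (beta_feasible(pm$mean, pm$sd)) {
    b0 <- beta_from_moments(pm$mean, pm$sd)
    log(c(b0$alpha, b0$beta))
  } else log(c(2, 2))
  obj <- function(par) {
    ab <- exp(pmin(pmax(par, -30), 30))
    sum((target - stats::qbeta(probs, ab[1], ab[2]))^2)
  }
  o <- stats::optim(start, obj, method = "Nelder-Mead",
                    control = list(maxit = 2000L, reltol = 1e-12))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 2000L, reltol = 1e-12))
  ab <- exp(o$par)
  structure(list(alpha = ab[1], beta = ab[2],
                 source = "quantile_interpolation", sse = o$value),
            class = "beta_prior")
}

#' Pooled Student-T prior for a continuous node
#'
#' Location-scale Student-T prior with location and scale taken from
#' the pooled moments and degrees of freedom set to the number of
#' complete-case experts for the node minus one.
#'
#' @param pooled_mean,pooled_sd Moments of the linear pool.
#' @param n_experts Number of complete-case judgments pooled
#'   (integer >= 2).
#' @return An object of class `student_t_prior` with `location`,
#'   `scale`, `df = n_experts - 1`.
#' @examples
#' t_prior_from_pool(130.29, 207.84, 8)  # df = 7
#' @export
t_prior_from_pool <- function(pooled_mean, pooled_sd, n_experts) {
  n_experts <- as.integer(n_experts)
  if (is.na(n_experts) || n_experts < 2L) {
    stop("insufficient panel: need at least 2 complete-case experts",
         call. = FALSE)
  }
  if (!is.finite(pooled_sd) || pooled_sd <= 0) {
    stop("pooled_sd must be positive", call. = FALSE)
  }
  structure(list(location = pooled_mean, scale = pooled_sd,
                 df = n_experts - 1L),
            class = "student_t_prior")
}

#' Build a node's informative prior from its pool
#'
#' Dispatches on strategy: `"beta_moment"` (moment matching, the default
#' route for proportion nodes) or `"beta_quantile"` (quantile
#' interpolation) for proportions; `"pooled_moment_t"` (location-scale T
#' on the pooled moments with df = n - 1) or `"refit_best_family"`
#' (re-run the best-fit search on the pooled quantile grid, which is how
#' mirror-log-T pooled priors arise for left-skewed continuous nodes)
#' for continuous nodes.
#'
#' @param node One-row [node_catalog()] entry (or a list with `node_id`,
#'   `kind`, `support_lower`, `support_upper`).
#' @param pool The node's [linear_pool()].
#' @param strategy One of `"pooled_moment_t"`, `"refit_best_family"`,
#'   `"beta_moment"`, `"beta_quantile"`.
#' @param probs Quantile grid for the refit / interpolation strategies.
#' @return An object of class `prior_spec`: `node_id`, `kind`
#'   (`"beta"`, `"student_t"` or `"refit_family"`), `parameters`,
#'   pooled moments, `n_experts` and a formatted `label`.
#' @export
make_prior <- function(node, pool,
                       strategy = c("pooled_moment_t", "refit_best_family",
                                    "beta_moment", "beta_quantile"),
                       probs = c(0.01, 0.25, 0.5, 0.75, 0.99)) {
  strategy <- match.arg(strategy)
  node <- as.list(node)
  .check_pool(pool)
  n <- length(pool$components)
  pm <- pool_moments(pool)
  ok <- switch(node$kind,
    proportion = strategy %in% c("beta_moment", "beta_quantile"),
    continuous = strategy %in% c("pooled_moment_t", "refit_best_family"),
    FALSE)
  if (!ok) {
    stop("strategy '", strategy, "' is not admissible for a ",
         node$kind, " node", call. = FALSE)
  }
  out <- switch(strategy,
    beta_moment = list(kind = "beta",
                       parameters = beta_from_moments(pm$mean, pm$sd)),
    beta_quantile = list(kind = "beta",
                         parameters = beta_from_quantiles(pool, probs)),
    pooled_moment_t = list(
      kind = "student_t",
      parameters = t_prior_from_pool(pm$mean, pm$sd, n)),
    refit_best_family = {
      a <- probability_assessment("pool", node$node_id, probs,
                                  qpool(pool, probs),
                                  support_lower = node$support_lower,
                                  support_upper = node$support_upper)
      f <- fit_best(a, df_fixed = max(n - 1L, 1L))
      list(kind = "refit_family", parameters = f$params)
    })
  spec <- structure(c(list(node_id = node$node_id, node_kind = node$kind),
                      out,
                      list(pooled_mean = pm$mean, pooled_sd = pm$sd,
                           moment_method = pm$method, n_experts = n)),
                    class = "prior_spec")
  spec$label <- format_prior(spec)
  spec
}

#' Format a prior as printed in elicitation reports
#'
#' Beta priors print as `"Beta (7.62, 5.76)"`; pooled Student-T priors
#' as `"T (130.29, 207.84, df = 7)"`; refitted pooled families print
#' their family label with the pooled mean, pooled SD and
#' df = n - 1, e.g. `"MirrorlogT (23.74, 11.45, df = 7)"`.
#'
#' @param x A `prior_spec`, `beta_prior` or `student_t_prior`.
#' @return A string.
#' @export
format_prior <- function(x) {
  if (inherits(x, "beta_prior")) {
    return(sprintf("Beta (%.2f, %.2f)", x$alpha, x$beta))
  }
  if (inherits(x, "student_t_prior")) {
    return(sprintf("T (%.2f, %.2f, df = %d)", x$location, x$scale, x$df))
  }
  if (inherits(x, "prior_spec")) {
    return(switch(x$kind,
      beta = format_prior(x$parameters),
      student_t = format_prior(x$parameters),
      refit_family = sprintf("%s (%.2f, %.2f, df = %d)",
                             .family_labels[[x$parameters$family]],
                             x$pooled_mean, x$pooled_sd,
                             x$n_experts - 1L)))
  }
  stop("cannot format object of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

#' Parse a printed prior string
#'
#' Inverse of [format_prior()] for report round-trips:
#' `"Beta (7.62, 5.76)"` yields a beta prior; `"T (m, s, df = k)"` a
#' Student-T prior; any other family label with `df` yields a
#' refit-family record holding the pooled mean/SD and df.
#'
#' @param s String to parse.
#' @return A `beta_prior`, `student_t_prior`, or a list for refit
#'   families.
#' @export
parse_prior_string <- function(s) {
  m <- regmatches(s, regexec(
    "^\\s*([A-Za-z]+)\\s*\\(\\s*([-0-9.eE]+)\\s*,\\s*([-0-9.eE]+)\\s*(?:,\\s*df\\s*=\\s*([0-9]+)\\s*)?\\)\\s*$",
    s))[[1]]
  if (length(m) == 0L) stop("unparseable prior string: ", s, call. = FALSE)
  label <- m[2]
  a <- as.numeric(m[3]); b <- as.numeric(m[4])
  df <- if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  fam <- names(.family_labels)[match(label, .family_labels)]
  if (is.na(fam)) stop("unknown family label: ", label, call. = FALSE)
  if (fam == "shifted_scaled_beta") {
    structure(list(alpha = a, beta = b, source = "parsed"),
              class = "beta_prior")
  } else if (fam == "student_t" && !is.na(df)) {
    structure(list(location = a, scale = b, df = df),
              class = "student_t_prior")
  } else {
    list(kind = "refit_family", family = fam, pooled_mean = a,
         pooled_sd = b, df = df)
  }
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior> node %s (%s): %s [n = %d experts]\n", x$node_id,
              x$node_kind, x$label, x$n_experts))
  invisible(x)
}

#' @export
print.beta_prior <- function(x, ...) {
  cat(format_prior(x), sprintf("[%s]\n", x$source))
  invisible(x)
}

#' @export
print.student_t_prior <- function(x, ...) {
  cat(format_prior(x), "\n")
  invisible(x)
}

#' Screen a table of pooled moments for beta feasibility
#'
#' Flags proportion rows whose printed pooled moments are
#' beta-infeasible (`sd^2 >= mean (1 - mean)`) instead of silently
#' repairing them; such rows cannot yield a moment-matched beta prior
#' and typically indicate a transcription problem upstream.
#'
#' @param table Data frame with columns `node_id`, `mean`, `sd`.
#' @return The table with added logical `feasible` and character `note`
#'   columns.
#' @export
check_beta_feasibility <- function(table) {
  table$feasible <- mapply(beta_feasible, table$mean, table$sd)
  table$note <- ifelse(table$feasible, "",
    sprintf("infeasible: sd^2 = %.4g >= mean*(1-mean) = %.4g",
            table$sd^2, table$mean * (1 - table$mean)))
  table
}
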