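# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# effective shift / reflection bounds for a family given an assessment:
# the catalog support where finite, else (for mirror families, by
# default) the elicited upper plausible limit
.effective_bounds <- function(family, assessment,
                              mirror_bound = c("elicited", "support")) {
  mirror_bound <- match.arg(mirror_bound)
  L <- assessment$support_lower
  U <- assessment$support_upper
  if (family %in% c("mirror_gamma", "mirror_log_t",
                    "shifted_scaled_beta") && !is.finite(U) &&
      mirror_bound == "elicited") {
    U <- max(assessment$values)
  }
  if (family %in% c("shifted_gamma", "lognormal", "log_t",
                    "shifted_scaled_beta") && !is.finite(L)) {
    # shifted/log families reflect positive-support shapes; an unstated
    # lower bound is taken as 0 when the data allow it
    if (min(assessment$values) >= 0) L <- 0
  }
  list(L = L, U = U)
}

#' Which candidate families can be fitted to an assessment
#'
#' Mirror families need a finite reflection bound: the catalog's upper
#' support bound when finite or, under the default
#' `mirror_bound = "elicited"`, the expert's upper plausible limit.
#' Shifted and log families need a finite lower bound (the catalog's,
#' or 0 for non-negative data). The shifted-scaled beta needs both.
#'
#' @param assessment A [probability_assessment()].
#' @param families Candidate subset of [family_names()].
#' @param mirror_bound `"elicited"` (default) or `"support"`.
#' @return Character vector of admissible families, in precedence order.
#' @export
admissible_families <- function(assessment, families = family_names(),
                                mirror_bound = c("elicited", "support")) {
  mirror_bound <- match.arg(mirror_bound)
  families <- family_names()[family_names() %in% families]
  ok <- vapply(families, function(f) {
    b <- .effective_bounds(f, assessment, mirror_bound)
    switch(f,
      normal = , student_t = TRUE,
      shifted_gamma = , lognormal = , log_t = is.finite(b$L) &&
        stats::median(assessment$values) > b$L,
      mirror_gamma = , mirror_log_t = is.finite(b$U) &&
        stats::median(assessment$values) < b$U,
      shifted_scaled_beta = is.finite(b$L) && is.finite(b$U) &&
        b$L < b$U)
  }, logical(1))
  families[ok]
}

# moment-flavoured starting values on the transformed (unconstrained)
# scale; qq = quartile triple interpolated from the assessment
.start_values <- function(family, qq, L, U, df_fixed) {
  eps <- 1e-8
  m0 <- qq[2]
  iqr <- max(qq[3] - qq[1], eps * max(abs(qq), 1), eps)
  s0 <- iqr / 1.349
  switch(family,
    normal = c(m0, log(s0)),
    student_t = c(m0, log(iqr / (2 * stats::qt(0.75, df_fixed)))),
    shifted_gamma = {
      mu <- max(m0 - L, eps)
      c(log(max((mu / s0)^2, eps)), log(max(mu / s0^2, eps)))
    },
    mirror_gamma = {
      mu <- max(U - m0, eps)
      c(log(max((mu / s0)^2, eps)), log(max(mu / s0^2, eps)))
    },
    lognormal = {
      y <- pmax(qq - L, eps)
      c(log(y[2]), log(max((log(y[3]) - log(y[1])) / 1.349, eps)))
    },
    log_t = {
      y <- pmax(qq - L, eps)
      c(log(y[2]),
        log(max((log(y[3]) - log(y[1])) /
                  (2 * stats::qt(0.75, df_fixed)), eps)))
    },
    mirror_log_t = {
      y <- pmax(U - rev(qq), eps)  # increasing in the reflected variable
      c(log(y[2]),
        log(max((log(y[3]) - log(y[1])) /
                  (2 * stats::qt(0.75, df_fixed)), eps)))
    },
    shifted_scaled_beta = {
      z <- pmin(pmax((qq - L) / (U - L), eps), 1 - eps)
      m <- z[2]
      s <- max((z[3] - z[1]) / 1.349, eps)
      if (s^2 < m * (1 - m)) {
        cc <- m * (1 - m) / s^2 - 1
        c(log(max(m * cc, eps)), log(max((1 - m) * cc, eps)))
      } else c(log(2), log(2))
    })
}

.theta_from_par <- function(family, par, df_fixed) {
  par <- pmin(pmax(par, -40), 40)  # guard exp overflow
  switch(family,
    normal = c(mean = par[1], sd = exp(par[2])),
    student_t = c(location = par[1], scale = exp(par[2]), df = df_fixed),
    shifted_gamma = ,
    mirror_gamma = c(shape = exp(par[1]), rate = exp(par[2])),
    lognormal = c(meanlog = par[1], sdlog = exp(par[2])),
    log_t = ,
    mirror_log_t = c(location = par[1], scale = exp(par[2]),
                     df = df_fixed),
    shifted_scaled_beta = c(alpha = exp(par[1]), beta = exp(par[2])))
}

#' Fit one candidate family to an assessment by least squares
#'
#' Minimizes the sum of squared deviations between the elicited
#' quantiles and the family's quantile function at the same
#' probabilities, `sum_j (q_j - Q(p_j; theta))^2`, by Nelder-Mead from
#' moment-matched starting values with seeded jittered restarts; the
#' best restart is polished once more. T-type families have their
#' degrees of freedom fixed at `df_fixed` (a conventional heavy-tail
#' default of 3 for per-expert fits).
#'
#' @param assessment A [probability_assessment()].
#' @param family One of [family_names()].
#' @param df_fixed Fixed df for T-type families.
#' @param n_restarts Number of jittered restarts beyond the moment start.
#' @param seed Seed controlling the restart jitter (deterministic fits).
#' @param mirror_bound See [admissible_families()].
#' @return An object of class `fitted_dist`: `expert_id`, `node_id`,
#'   `params` (a `family_params`), `sse`, `convergence`.
#' @export
fit_family <- function(assessment, family, df_fixed = 3,
                       n_restarts = 5, seed = 1,
                       mirror_bound = c("elicited", "support")) {
  mirror_bound <- match.arg(mirror_bound)
  if (!inherits(assessment, "probability_assessment")) {
    stop("expected a 'probability_assessment'", call. = FALSE)
  }
  if (!family %in% admissible_families(assessment, family, mirror_bound)) {
    stop("family '", family, "' is not admissible for this assessment's ",
         "support", call. = FALSE)
  }
  b <- .effective_bounds(family, assessment, mirror_bound)
  probs <- assessment$probs
  values <- assessment$values
  qq <- stats::approx(probs, values, xout = c(0.25, 0.5, 0.75),
                      rule = 2, ties = "ordered")$y

  obj <- function(par) {
    th <- .theta_from_par(family, par, df_fixed)
    fp <- tryCatch(make_family(family, th, b$L, b$U),
                   error = function(e) NULL)
    if (is.null(fp)) return(1e10)
    qs <- tryCatch(qfamily(fp, probs), error = function(e) NULL)
    if (is.null(qs) || any(!is.finite(qs))) return(1e10)
    sum((values - qs)^2)
  }

  start0 <- .start_values(family, qq, b$L, b$U, df_fixed)
  starts <- .with_seed(seed, {
    c(list(start0),
      lapply(seq_len(n_restarts), function(i) {
        start0 + stats::rnorm(length(start0), 0, 0.25)
      }))
  })
  ctl <- list(maxit = 2000L, reltol = 1e-12)
  runs <- lapply(starts, function(st) {
    tryCatch(stats::optim(st, obj, method = "Nelder-Mead", control = ctl),
             error = function(e) list(par = st, value = obj(st),
                                      convergence = 99L))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  polish <- tryCatch(
    stats::optim(best$par, obj, method = "Nelder-Mead", control = ctl),
    error = function(e) best)
  if (polish$value <= best$value) best <- polish
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("least-squares fit of family '", family,
         "' failed to converge", call. = FALSE)
  }
  params <- make_family(family, .theta_from_par(family, best$par, df_fixed),
                        b$L, b$U)
  structure(list(expert_id = assessment$expert_id,
                 node_id = assessment$node_id,
                 params = params, sse = best$value,
                 convergence = best$convergence),
            class = "fitted_dist")
}

#' Fit all admissible families and keep the best
#'
#' Selects the admissible fit with the lowest sum of squared quantile
#' deviations. Near-ties (within a 1e-10 relative tolerance) are broken
#' by the fixed family precedence order of [family_names()].
#'
#' @inheritParams fit_family
#' @param families Candidate families to try.
#' @return The best `fitted_dist`, with attributes `sse_by_family`
#'   (named vector over fitted families) and `skipped` (inadmissible
#'   families with reasons).
#' @export
fit_best <- function(assessment, families = family_names(), df_fixed = 3,
                     n_restarts = 5, seed = 1,
                     mirror_bound = c("elicited", "support")) {
  mirror_bound <- match.arg(mirror_bound)
  adm <- admissible_families(assessment, families, mirror_bound)
  skipped <- setdiff(family_names()[family_names() %in% families], adm)
  if (length(adm) == 0L) {
    stop("no admissible family for expert '", assessment$expert_id,
         "', node '", assessment$node_id, "'", call. = FALSE)
  }
  fits <- lapply(adm, function(f) {
    tryCatch(fit_family(assessment, f, df_fixed = df_fixed,
                        n_restarts = n_restarts, seed = seed,
                        mirror_bound = mirror_bound),
             error = function(e) NULL)
  })
  names(fits) <- adm
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    stop("all candidate fits failed for expert '", assessment$expert_id,
         "', node '", assessment$node_id, "'", call. = FALSE)
  }
  best <- fits[[1]]
  for (f in fits[-1]) {
    if (f$sse < best$sse - 1e-10 * (1 + best$sse)) best <- f
  }
  attr(best, "sse_by_family") <-
    vapply(fits, `[[`, numeric(1), "sse")
  attr(best, "skipped") <- if (length(skipped)) {
    stats::setNames(rep("inadmissible for node support", length(skipped)),
                    skipped)
  } else NULL
  best
}

#' @export
print.fitted_dist <- function(x, ...) {
  cat(sprintf("<fit> expert %s, node %s: %s, sse = %.3g\n",
              x$expert_id, x$node_id, x$params$family, x$sse))
  invisible(x)
}

#' Tabulate a list of fits for serialization
#'
#' One row per fit: expert, node, family, JSON-encoded parameters, sse.
#' This is the per-node CSV from which the family census (prevalent
#' distribution counts) is built.
#'
#' @param fits List of `fitted_dist` objects.
#' @return A data frame.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(expert_id = f$expert_id, node_id = f$node_id,
               family = f$params$family,
               params = as.character(family_to_json(f$params)),
               sse = f$sse, stringsAsFactors = FALSE)
  }))
}
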