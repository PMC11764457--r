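#' The eight candidate elicitation families
#'
#' The quartile-elicitation workflow fits each expert's judgment over a
#' fixed menu of eight parametric families: normal, location-scale
#' Student-T, shifted gamma, mirror (reflected) gamma, (shifted)
#' lognormal, (shifted) log-T, mirror log-T, and shifted-scaled beta.
#' Mirror families reflect a positive-support family about a finite
#' upper bound and therefore produce left-skewed shapes on bounded
#' support; shifted families translate a positive-support family to a
#' finite lower bound.
#'
#' @return Character vector of the eight admissible family names, in the
#'   fixed precedence order used for tie-breaking.
#' @export
family_names <- function() {
  c("normal", "student_t", "shifted_gamma", "mirror_gamma",
    "lognormal", "log_t", "mirror_log_t", "shifted_scaled_beta")
}

.family_labels <- c(
  normal = "Normal", student_t = "T", shifted_gamma = "ShiftedGamma",
  mirror_gamma = "MirrorGamma", lognormal = "LogNormal", log_t = "LogT",
  mirror_log_t = "MirrorlogT", shifted_scaled_beta = "Beta")

.family_theta_names <- list(
  normal = c("mean", "sd"),
  student_t = c("location", "scale", "df"),
  shifted_gamma = c("shape", "rate"),
  mirror_gamma = c("shape", "rate"),
  lognormal = c("meanlog", "sdlog"),
  log_t = c("location", "scale", "df"),
  mirror_log_t = c("location", "scale", "df"),
  shifted_scaled_beta = c("alpha", "beta"))

# shift used by lognormal / log_t: the finite lower support bound, or 0
.shift0 <- function(L) if (is.finite(L)) L else 0

#' Construct a parameterized distribution family
#'
#' Parameters are passed by name to avoid convention drift: `(mean, sd)`
#' for normal; `(location, scale, df)` for the T types; `(shape, rate)`
#' for the gamma types; `(meanlog, sdlog)` for lognormal; `(alpha, beta)`
#' for the shifted-scaled beta. Support bounds carry the shift / mirror
#' construction: shifted gamma lives on `[support_lower, Inf)`, mirror
#' families on `(-Inf, support_upper]` reflected about the upper bound,
#' and the shifted-scaled beta on `[support_lower, support_upper]`.
#' Lognormal and log-T act on `log(x - support_lower)` when the lower
#' bound is finite and on `log(x)` otherwise.
#'
#' @param family One of [family_names()].
#' @param theta Named numeric vector of parameters (see Details).
#' @param support_lower,support_upper Support bounds; may be infinite
#'   where the family permits.
#' @return An object of class `family_params`.
#' @examples
#' fp <- make_family("normal", c(mean = 0, sd = 1))
#' qfamily(fp, 0.25)
#' @export
make_family <- function(family, theta, support_lower = -Inf,
                        support_upper = Inf) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% family_names()) {
    stop("unknown family: ", paste(family, collapse = ", "),
         " (admissible: ", paste(family_names(), collapse = ", "), ")",
         call. = FALSE)
  }
  want <- .family_theta_names[[family]]
  theta <- unlist(theta)
  if (!all(want %in% names(theta))) {
    stop(family, " requires parameters named ",
         paste(want, collapse = ", "), call. = FALSE)
  }
  theta <- theta[want]
  if (any(!is.finite(theta))) {
    stop("non-finite parameter value for ", family, call. = FALSE)
  }
  pos <- intersect(c("sd", "scale", "shape", "rate", "sdlog",
                     "alpha", "beta"), want)
  if (any(theta[pos] <= 0)) {
    stop("scale and shape parameters must be strictly positive (",
         family, ")", call. = FALSE)
  }
  if ("df" %in% want && theta[["df"]] < 1) {
    stop("df must be >= 1", call. = FALSE)
  }
  if (family %in% c("mirror_gamma", "mirror_log_t") &&
      !is.finite(support_upper)) {
    stop(family, " requires a finite upper support bound", call. = FALSE)
  }
  if (family == "shifted_gamma" && !is.finite(support_lower)) {
    stop("shifted_gamma requires a finite lower support bound",
         call. = FALSE)
  }
  if (family == "shifted_scaled_beta" &&
      (!is.finite(support_lower) || !is.finite(support_upper) ||
       support_lower >= support_upper)) {
    stop("shifted_scaled_beta requires finite bounds with lower < upper",
         call. = FALSE)
  }
  structure(list(family = family, theta = theta,
                 support_lower = support_lower,
                 support_upper = support_upper),
            class = "family_params")
}

.check_family <- function(params) {
  if (!inherits(params, "family_params")) {
    stop("expected a 'family_params' object", call. = FALSE)
  }
  params
}

#' Quantile function of an elicitation family
#'
#' Strictly increasing in `p` and confined to the declared support.
#' Mirror families satisfy the reflection identity
#' `Q_mirror(p) = U - Q_base(1 - p)`.
#'
#' @param params A `family_params` object.
#' @param p Probabilities strictly inside (0, 1).
#' @return Numeric vector of quantiles.
#' @export
qfamily <- function(params, p) {
  .check_family(params)
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  th <- params$theta
  L <- params$support_lower
  U <- params$support_upper
  switch(params$family,
    normal = stats::qnorm(p, th[["mean"]], th[["sd"]]),
    student_t = th[["location"]] + th[["scale"]] * stats::qt(p, th[["df"]]),
    shifted_gamma = L + stats::qgamma(p, th[["shape"]], rate = th[["rate"]]),
    mirror_gamma = U - stats::qgamma(1 - p, th[["shape"]],
                                     rate = th[["rate"]]),
    lognormal = .shift0(L) + stats::qlnorm(p, th[["meanlog"]], th[["sdlog"]]),
    log_t = .shift0(L) +
      exp(th[["location"]] + th[["scale"]] * stats::qt(p, th[["df"]])),
    mirror_log_t = U -
      exp(th[["location"]] + th[["scale"]] * stats::qt(1 - p, th[["df"]])),
    shifted_scaled_beta = L +
      (U - L) * stats::qbeta(p, th[["alpha"]], th[["beta"]]))
}

#' Cumulative distribution function of an elicitation family
#'
#' @inheritParams qfamily
#' @param x Numeric vector of evaluation points.
#' @return Probabilities in \[0, 1\]; 0 below the support and 1 above it.
#' @export
pfamily <- function(params, x) {
  .check_family(params)
  th <- params$theta
  L <- params$support_lower
  U <- params$support_upper
  out <- switch(params$family,
    normal = stats::pnorm(x, th[["mean"]], th[["sd"]]),
    student_t = stats::pt((x - th[["location"]]) / th[["scale"]],
                          th[["df"]]),
    shifted_gamma = stats::pgamma(x - L, th[["shape"]], rate = th[["rate"]]),
    mirror_gamma = 1 - stats::pgamma(U - x, th[["shape"]],
                                     rate = th[["rate"]]),
    lognormal = stats::plnorm(x - .shift0(L), th[["meanlog"]], th[["sdlog"]]),
    log_t = ifelse(x <= .shift0(L), 0,
      stats::pt((log(pmax(x - .shift0(L), .Machine$double.xmin)) -
                   th[["location"]]) / th[["scale"]], th[["df"]])),
    mirror_log_t = ifelse(x >= U, 1,
      1 - stats::pt((log(pmax(U - x, .Machine$double.xmin)) -
                       th[["location"]]) / th[["scale"]], th[["df"]])),
    shifted_scaled_beta = stats::pbeta((x - L) / (U - L), th[["alpha"]],
                                       th[["beta"]]))
  pmin(pmax(out, 0), 1)
}

#' Density of an elicitation family
#'
#' Zero outside the declared support; integrates to one over it
#' (mirror and shifted densities arise from a unit-Jacobian reflection
#' or translation; log types carry the usual `1/(scale * y)` factor).
#'
#' @inheritParams pfamily
#' @return Non-negative density values.
#' @export
dfamily <- function(params, x) {
  .check_family(params)
  th <- params$theta
  L <- params$support_lower
  U <- params$support_upper
  out <- switch(params$family,
    normal = stats::dnorm(x, th[["mean"]], th[["sd"]]),
    student_t = stats::dt((x - th[["location"]]) / th[["scale"]],
                          th[["df"]]) / th[["scale"]],
    shifted_gamma = stats::dgamma(x - L, th[["shape"]], rate = th[["rate"]]),
    mirror_gamma = stats::dgamma(U - x, th[["shape"]], rate = th[["rate"]]),
    lognormal = stats::dlnorm(x - .shift0(L), th[["meanlog"]], th[["sdlog"]]),
    log_t = {
      y <- x - .shift0(L)
      ifelse(y <= 0, 0,
        stats::dt((log(pmax(y, .Machine$double.xmin)) - th[["location"]]) /
                    th[["scale"]], th[["df"]]) /
          (th[["scale"]] * pmax(y, .Machine$double.xmin)))
    },
    mirror_log_t = {
      y <- U - x
      ifelse(y <= 0, 0,
        stats::dt((log(pmax(y, .Machine$double.xmin)) - th[["location"]]) /
                    th[["scale"]], th[["df"]]) /
          (th[["scale"]] * pmax(y, .Machine$double.xmin)))
    },
    shifted_scaled_beta = stats::dbeta((x - L) / (U - L), th[["alpha"]],
                                       th[["beta"]]) / (U - L))
  ifelse(is.finite(out), pmax(out, 0), 0)
}

#' Draw random variates from an elicitation family
#'
#' Inverse-CDF sampling, so a fixed RNG state gives reproducible draws
#' for every family through the same path.
#'
#' @inheritParams qfamily
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
rfamily <- function(params, n) {
  qfamily(params, stats::runif(n))
}

# conditional moments on the central 0.001--0.999 quantile range; used
# when the full-support moments do not exist (log-T types; T with df <= 2)
.truncated_moments <- function(params, lo_p = 0.001, hi_p = 0.999) {
  lo <- qfamily(params, lo_p)
  hi <- qfamily(params, hi_p)
  mass <- hi_p - lo_p
  m1 <- stats::integrate(function(x) x * dfamily(params, x), lo, hi,
                         rel.tol = 1e-8, subdivisions = 500L)$value / mass
  m2 <- stats::integrate(function(x) x^2 * dfamily(params, x), lo, hi,
                         rel.tol = 1e-8, subdivisions = 500L)$value / mass
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)), method = "truncated")
}

#' Mean and standard deviation of an elicitation family
#'
#' Closed forms are used wherever they exist. The log-T types have no
#' finite moments at any df, and the T types have infinite variance at
#' df <= 2; for those, `allow_truncated = TRUE` substitutes conditional
#' moments on the central 0.001--0.999 quantile range and marks the
#' result with `method = "truncated"`. With the default
#' `allow_truncated = FALSE` such requests raise an undefined-moment
#' error.
#'
#' @inheritParams qfamily
#' @param allow_truncated Fall back to truncated numeric moments when
#'   full-support moments are undefined.
#' @return List with elements `mean`, `sd` and `method`
#'   (`"closed"` or `"truncated"`).
#' @export
fam_moments <- function(params, allow_truncated = FALSE) {
  .check_family(params)
  th <- params$theta
  L <- params$support_lower
  U <- params$support_upper
  undefined <- function(what) {
    if (allow_truncated) return(.truncated_moments(params))
    stop("undefined moment for ", params$family, ": ", what, call. = FALSE)
  }
  res <- switch(params$family,
    normal = list(mean = th[["mean"]], sd = th[["sd"]]),
    student_t = {
      if (th[["df"]] <= 2) undefined("variance requires df > 2") else {
        list(mean = th[["location"]],
             sd = th[["scale"]] * sqrt(th[["df"]] / (th[["df"]] - 2)))
      }
    },
    shifted_gamma = list(mean = L + th[["shape"]] / th[["rate"]],
                         sd = sqrt(th[["shape"]]) / th[["rate"]]),
    mirror_gamma = list(mean = U - th[["shape"]] / th[["rate"]],
                        sd = sqrt(th[["shape"]]) / th[["rate"]]),
    lognormal = {
      m <- exp(th[["meanlog"]] + th[["sdlog"]]^2 / 2)
      list(mean = .shift0(L) + m,
           sd = m * sqrt(exp(th[["sdlog"]]^2) - 1))
    },
    log_t = undefined("exp of a Student-T has no finite moments"),
    mirror_log_t = undefined("exp of a Student-T has no finite moments"),
    shifted_scaled_beta = {
      a <- th[["alpha"]]; b <- th[["beta"]]
      list(mean = L + (U - L) * a / (a + b),
           sd = (U - L) * sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    })
  if (is.null(res$method)) res$method <- "closed"
  res
}

#' @export
print.family_params <- function(x, ...) {
  cat(sprintf("<%s> %s\n  support: [%g, %g]\n", x$family,
              paste(sprintf("%s = %.6g", names(x$theta), x$theta),
                    collapse = ", "),
              x$support_lower, x$support_upper))
  invisible(x)
}

#' Serialize family parameters to and from plain lists / JSON
#'
#' Parameters are serialized by name, so files remain readable and
#' immune to positional-convention drift.
#'
#' @param params A `family_params` object.
#' @return `family_to_list()`: a plain list; `family_to_json()`: a JSON
#'   string; the `from` counterparts invert them.
#' @export
family_to_list <- function(params) {
  .check_family(params)
  list(family = params$family, theta = as.list(params$theta),
       support_lower = params$support_lower,
       support_upper = params$support_upper)
}

#' @rdname family_to_list
#' @param x A list (or JSON string) produced by the `to` counterpart.
#' @export
family_from_list <- function(x) {
  make_family(x$family, unlist(x$theta),
              support_lower = if (is.null(x$support_lower)) -Inf else
                as.numeric(x$support_lower),
              support_upper = if (is.null(x$support_upper)) Inf else
                as.numeric(x$support_upper))
}

#' @rdname family_to_list
#' @export
family_to_json <- function(params) {
  jsonlite::toJSON(family_to_list(params), auto_unbox = TRUE, digits = NA)
}

#' @rdname family_to_list
#' @export
family_from_json <- function(x) {
  family_from_list(jsonlite::fromJSON(x, simplifyVector = TRUE))
}
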