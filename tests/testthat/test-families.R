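test_that("quantile functions reproduce known constants", {
  std <- make_family("normal", c(mean = 0, sd = 1))
  expect_equal(qfamily(std, 0.25), qnorm(0.25), tolerance = 1e-10)
  expect_equal(dfamily(std, 0), dnorm(0), tolerance = 1e-10)
  unif <- make_family("shifted_scaled_beta", c(alpha = 1, beta = 1), 0, 1)
  expect_equal(qfamily(unif, 0.37), 0.37, tolerance = 1e-12)
  b22 <- make_family("shifted_scaled_beta", c(alpha = 2, beta = 2), 0, 1)
  expect_equal(dfamily(b22, 0.5), 1.5, tolerance = 1e-12)
})

test_that("mirror families satisfy the reflection identities", {
  mg <- make_family("mirror_gamma", c(shape = 3, rate = 0.5),
                    support_upper = 10)
  p <- c(0.1, 0.5, 0.9)
  expect_equal(qfamily(mg, p), 10 - qgamma(1 - p, 3, 0.5),
               tolerance = 1e-12)
  # mirror log-t density equals the log-t density of the reflected
  # variable (unit-Jacobian change of variables), on a grid
  mlt <- make_family("mirror_log_t", c(location = 1, scale = 0.4, df = 3),
                     support_upper = 20)
  lt <- make_family("log_t", c(location = 1, scale = 0.4, df = 3),
                    support_lower = 0)
  x <- seq(0.5, 19.5, length.out = 101)
  expect_equal(dfamily(mlt, x), dfamily(lt, 20 - x), tolerance = 1e-12)
  expect_equal(pfamily(mlt, x), 1 - pfamily(lt, 20 - x),
               tolerance = 1e-12)
})

test_that("mirroring twice reproduces the original quantiles", {
  # X = U - G  =>  U - X = G: reflect the mirror about the same bound
  p <- seq(0.05, 0.95, by = 0.05)
  g <- make_family("shifted_gamma", c(shape = 2.5, rate = 0.8),
                   support_lower = 0)
  mg <- make_family("mirror_gamma", c(shape = 2.5, rate = 0.8),
                    support_upper = 7)
  expect_equal(7 - qfamily(mg, 1 - p), qfamily(g, p), tolerance = 1e-12)
})

test_that("quantile and numerically inverted CDF agree for all families", {
  grid <- seq(0.02, 0.98, by = 0.08)
  for (fp in reference_families()) {
    q <- qfamily(fp, grid)
    expect_equal(pfamily(fp, q), grid, tolerance = 1e-6,
                 info = fp$family)
    expect_true(all(diff(q) > 0), info = fp$family)
  }
})

test_that("densities carry the mass their CDF claims", {
  # integrate over the central 0.001--0.999 quantile range: the log-T
  # types have tails far too heavy for full-support quadrature
  for (fp in reference_families()) {
    lo <- qfamily(fp, 0.001)
    hi <- qfamily(fp, 0.999)
    mass <- integrate(function(x) dfamily(fp, x), lo, hi,
                      rel.tol = 1e-8, subdivisions = 500L)$value
    expect_equal(mass, 0.998, tolerance = 1e-5, info = fp$family)
  }
})

test_that("closed-form moments match seeded Monte-Carlo moments", {
  finite_var <- c("normal", "student_t", "shifted_gamma", "mirror_gamma",
                  "lognormal", "shifted_scaled_beta")
  fams <- reference_families()
  # df = 3 t has infinite kurtosis; use df = 5 so the MC check is stable
  fams$student_t <- make_family("student_t",
                                c(location = 5, scale = 1.5, df = 5))
  set.seed(42)
  for (nm in finite_var) {
    fp <- fams[[nm]]
    m <- fam_moments(fp)
    x <- rfamily(fp, 1e6)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - m$mean), 3 * se + 1e-9)
    expect_equal(sd(x), m$sd, tolerance = 0.02, info = nm)
    expect_identical(m$method, "closed")
  }
})

test_that("undefined moments error unless the truncated fallback is on", {
  heavy <- make_family("log_t", c(location = 1, scale = 0.3, df = 2),
                       support_lower = 0)
  expect_error(fam_moments(heavy), "undefined moment")
  tr <- fam_moments(heavy, allow_truncated = TRUE)
  expect_identical(tr$method, "truncated")
  expect_true(is.finite(tr$mean) && is.finite(tr$sd))
  t2 <- make_family("student_t", c(location = 0, scale = 1, df = 2))
  expect_error(fam_moments(t2), "undefined moment")
})

test_that("invalid parameters and probabilities are rejected", {
  expect_error(make_family("cauchy", c(location = 0, scale = 1)),
               "unknown family")
  expect_error(make_family("normal", c(mean = 0, sd = -1)),
               "strictly positive")
  expect_error(make_family("student_t",
                           c(location = 0, scale = 1, df = 0.5)),
               "df must be")
  expect_error(make_family("mirror_gamma", c(shape = 1, rate = 1)),
               "finite upper")
  expect_error(make_family("shifted_scaled_beta",
                           c(alpha = 1, beta = 1), 1, 0),
               "lower < upper")
  std <- make_family("normal", c(mean = 0, sd = 1))
  expect_error(qfamily(std, 0), "inside \\(0, 1\\)")
  expect_error(qfamily(std, 1.2), "inside \\(0, 1\\)")
})

test_that("family parameters survive JSON round-trips by name", {
  for (fp in reference_families()) {
    back <- family_from_json(family_to_json(fp))
    expect_identical(back$family, fp$family)
    expect_equal(back$theta, fp$theta, tolerance = 1e-12)
    expect_equal(back$support_lower, fp$support_lower)
    expect_equal(back$support_upper, fp$support_upper)
  }
})
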