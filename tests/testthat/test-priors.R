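test_that("beta moment matching reproduces hand-derived cases", {
  u <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(u$alpha, 1, tolerance = 1e-10)
  expect_equal(u$beta, 1, tolerance = 1e-10)
  g <- beta_from_moments(0.56, 0.13)  # direct evaluation: c = 13.580
  expect_equal(g$alpha, 0.56 * (0.56 * 0.44 / 0.13^2 - 1),
               tolerance = 1e-12)
  expect_equal(g$alpha, 7.6047, tolerance = 1e-4)
})

test_that("infeasible pooled moments raise a feasibility error", {
  expect_error(beta_from_moments(0.65, 0.65), "beta-infeasible")
  expect_false(beta_feasible(0.65, 0.65))
  tab <- check_beta_feasibility(data.frame(
    node_id = c("gender", "year_of_diagnosis"),
    mean = c(0.56, 0.65), sd = c(0.13, 0.65)))
  expect_identical(tab$feasible, c(TRUE, FALSE))
  expect_match(tab$note[2], "infeasible")
})

test_that("beta round-trip is the identity over randomized shapes", {
  set.seed(123)
  for (i in 1:50) {
    ab <- runif(2, 0.1, 50)
    m <- beta_moments(list(alpha = ab[1], beta = ab[2]))
    back <- beta_from_moments(m$mean, m$sd)
    expect_equal(back$alpha, ab[1], tolerance = 1e-10)
    expect_equal(back$beta, ab[2], tolerance = 1e-10)
  }
})

test_that("quantile interpolation recovers betas and beats components", {
  b22 <- make_family("shifted_scaled_beta", c(alpha = 2, beta = 2), 0, 1)
  pl <- linear_pool(list(b22, b22))
  fit <- beta_from_quantiles(pl)
  expect_equal(fit$alpha, 2, tolerance = 0.01)
  expect_equal(fit$beta, 2, tolerance = 0.01)
  unif <- make_family("shifted_scaled_beta", c(alpha = 1, beta = 1), 0, 1)
  fitu <- beta_from_quantiles(linear_pool(list(unif, unif)))
  expect_equal(fitu$alpha, 1, tolerance = 0.01)
  expect_equal(fitu$beta, 1, tolerance = 0.01)
  # bimodal-ish mixture: the interpolated beta fits the pooled
  # quantiles at least as well as either single component (brute force)
  b25 <- make_family("shifted_scaled_beta", c(alpha = 2, beta = 5), 0, 1)
  b52 <- make_family("shifted_scaled_beta", c(alpha = 5, beta = 2), 0, 1)
  pl2 <- linear_pool(list(b25, b52))
  probs <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  target <- qpool(pl2, probs)
  fit2 <- beta_from_quantiles(pl2)
  sse_components <- vapply(list(c(2, 5), c(5, 2)), function(ab) {
    sum((target - qbeta(probs, ab[1], ab[2]))^2)
  }, numeric(1))
  expect_lt(fit2$sse, min(sse_components))
  expect_error(beta_from_quantiles(linear_pool(list(
    make_family("normal", c(mean = 10, sd = 2))))), "within \\[0, 1\\]")
})

test_that("the pooled T prior applies the df = n - 1 rule", {
  pr <- t_prior_from_pool(130.29, 207.84, 8)
  expect_identical(pr$df, 7L)
  expect_equal(pr$location, 130.29)
  expect_equal(pr$scale, 207.84)
  expect_identical(format_prior(pr), "T (130.29, 207.84, df = 7)")
  expect_identical(t_prior_from_pool(0, 1, 2)$df, 1L)
  expect_error(t_prior_from_pool(0, 1, 1), "insufficient panel")
})

test_that("make_prior dispatches by node kind and strategy", {
  node_p <- node_catalog("sym", "proportion")
  node_c <- node_catalog("marker", "continuous")
  b1 <- make_family("shifted_scaled_beta", c(alpha = 3, beta = 2), 0, 1)
  b2 <- make_family("shifted_scaled_beta", c(alpha = 4, beta = 2.5), 0, 1)
  pool_p <- linear_pool(list(b1, b2))
  pr <- make_prior(node_p, pool_p, "beta_moment")
  expect_identical(pr$kind, "beta")
  pm <- pool_moments(pool_p)
  byhand <- beta_from_moments(pm$mean, pm$sd)
  expect_equal(pr$parameters$alpha, byhand$alpha, tolerance = 1e-12)
  comps <- lapply(1:8, function(i) {
    make_family("lognormal", c(meanlog = 4 + 0.02 * i, sdlog = 1),
                support_lower = 0)
  })
  pool_c <- linear_pool(comps)
  prc <- make_prior(node_c, pool_c, "pooled_moment_t")
  expect_identical(prc$parameters$df, 7L)
  expect_match(prc$label, "df = 7")
  expect_error(make_prior(node_c, pool_c, "beta_moment"),
               "not admissible")
  expect_error(make_prior(node_p, pool_p, "pooled_moment_t"),
               "not admissible")
})

test_that("refitting the pooled quantiles finds the generating family", {
  comps <- lapply(c(0.95, 1, 1.05), function(s) {
    make_family("mirror_log_t",
                c(location = 2, scale = 0.4 * s, df = 3),
                support_upper = 100)
  })
  pool <- linear_pool(comps)
  node <- node_catalog("age", "continuous", support_upper = 100)
  pr <- make_prior(node, pool, "refit_best_family")
  expect_identical(pr$kind, "refit_family")
  expect_identical(pr$parameters$family, "mirror_log_t")
  expect_match(pr$label, "^MirrorlogT \\(.*df = 2\\)$")
})

test_that("published-style prior strings parse and format consistently", {
  b <- parse_prior_string("Beta (7.62, 5.76)")
  expect_s3_class(b, "beta_prior")
  expect_equal(b$alpha, 7.62)
  t <- parse_prior_string("T (130.29, 207.84, df = 7)")
  expect_s3_class(t, "student_t_prior")
  expect_identical(format_prior(t), "T (130.29, 207.84, df = 7)")
  m <- parse_prior_string("MirrorlogT (23.74, 11.45, df = 7)")
  expect_identical(m$family, "mirror_log_t")
  expect_error(parse_prior_string("Weibull (1, 2)"), "unknown family")
})
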