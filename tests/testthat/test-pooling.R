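mix_pool <- function() {
  linear_pool(list(make_family("normal", c(mean = 0, sd = 1)),
                   make_family("normal", c(mean = 2, sd = 1))))
}

test_that("symmetric mixtures and degenerate pools behave exactly", {
  pl <- mix_pool()
  expect_equal(ppool(pl, 1), 0.5, tolerance = 1e-12)
  expect_equal(qpool(pl, 0.5), 1, tolerance = 1e-7)
  # single component at weight one is the component
  one <- linear_pool(list(make_family("normal", c(mean = 3, sd = 2))))
  p <- c(0.1, 0.5, 0.9)
  expect_equal(qpool(one, p), qnorm(p, 3, 2), tolerance = 1e-6)
  # weight (1, 0) degenerates to the first component
  w10 <- linear_pool(list(make_family("normal", c(mean = 0, sd = 1)),
                          make_family("normal", c(mean = 50, sd = 1))),
                     weights = c(1, 0))
  expect_equal(qpool(w10, p), qnorm(p), tolerance = 1e-6)
})

test_that("pooled moments match the closed-form mixture formulas", {
  pm <- pool_moments(mix_pool())
  expect_equal(pm$mean, 1, tolerance = 1e-12)
  expect_equal(pm$sd, sqrt(2), tolerance = 1e-12)
  # identical components pool to the component moments
  same <- linear_pool(list(make_family("normal", c(mean = 5, sd = 2)),
                           make_family("normal", c(mean = 5, sd = 2))))
  pm2 <- pool_moments(same)
  expect_equal(pm2$mean, 5); expect_equal(pm2$sd, 2)
  # pooled sd is never below the smallest component sd
  het <- linear_pool(list(make_family("normal", c(mean = 0, sd = 0.5)),
                          make_family("normal", c(mean = 4, sd = 2))))
  expect_gte(pool_moments(het)$sd, 0.5)
})

test_that("pooled quantiles and variance match a seeded sampling oracle", {
  pl <- linear_pool(list(
    make_family("shifted_gamma", c(shape = 3, rate = 0.5),
                support_lower = 0),
    make_family("lognormal", c(meanlog = 1, sdlog = 0.4),
                support_lower = 0)))
  set.seed(7)
  x <- rpool(pl, 1e6)
  for (p in c(0.25, 0.5, 0.9)) {
    q <- qpool(pl, p)
    se <- sqrt(p * (1 - p) / length(x)) / dpool(pl, q)
    expect_lt(abs(q - quantile(x, p, names = FALSE)), 3 * se + 1e-6)
  }
  pm <- pool_moments(pl)
  expect_equal(pm$mean, mean(x), tolerance = 0.01)
  expect_equal(pm$sd, sd(x), tolerance = 0.01)
})

test_that("pooled moments equal numeric integration of the mixture", {
  pl <- mix_pool()
  m1 <- integrate(function(x) x * dpool(pl, x), -10, 12,
                  rel.tol = 1e-10)$value
  m2 <- integrate(function(x) x^2 * dpool(pl, x), -10, 12,
                  rel.tol = 1e-10)$value
  pm <- pool_moments(pl)
  expect_equal(pm$mean, m1, tolerance = 1e-6)
  expect_equal(pm$sd, sqrt(m2 - m1^2), tolerance = 1e-6)
})

test_that("pooling is invariant to component order", {
  comps <- list(make_family("normal", c(mean = 0, sd = 1)),
                make_family("shifted_gamma", c(shape = 2, rate = 1),
                            support_lower = 0),
                make_family("lognormal", c(meanlog = 0.2, sdlog = 0.3),
                            support_lower = 0))
  p1 <- linear_pool(comps)
  p2 <- linear_pool(rev(comps))
  x <- seq(-2, 8, by = 0.5)
  expect_equal(dpool(p1, x), dpool(p2, x), tolerance = 1e-12)
  expect_equal(pool_moments(p1)$sd, pool_moments(p2)$sd,
               tolerance = 1e-12)
})

test_that("pool input validation catches mismatches", {
  f1 <- structure(list(expert_id = "E1", node_id = "a",
                       params = make_family("normal", c(mean = 0, sd = 1)),
                       sse = 0), class = "fitted_dist")
  f2 <- structure(list(expert_id = "E2", node_id = "b",
                       params = make_family("normal", c(mean = 1, sd = 1)),
                       sse = 0), class = "fitted_dist")
  expect_error(linear_pool(list(f1, f2)), "different nodes")
  expect_error(linear_pool(list(f1), weights = c(-1)), "negative weight")
})

test_that("concordance census counts the prevalent best-fit family", {
  mk <- function(fam, fp) {
    structure(list(expert_id = "E", node_id = "n", params = fp, sse = 0),
              class = "fitted_dist")
  }
  tfit <- mk("t", make_family("student_t",
                              c(location = 0, scale = 1, df = 3)))
  nfit <- mk("n", make_family("normal", c(mean = 0, sd = 1)))
  gfit <- mk("g", make_family("shifted_gamma", c(shape = 1, rate = 1),
                              support_lower = 0))
  cs <- concordance(c(rep(list(tfit), 6), list(nfit), list(gfit)))
  expect_identical(cs$prevalent_family, "student_t")
  expect_identical(cs$count, 6L)
  expect_identical(cs$total, 8L)
  expect_identical(format_concordance(cs), "T (6/8)")
  # unanimity formats like the absolute-concordance rows
  mlt <- mk("m", make_family("mirror_log_t",
                             c(location = 1, scale = 0.3, df = 3),
                             support_upper = 10))
  cs2 <- concordance(rep(list(mlt), 8))
  expect_identical(format_concordance(cs2), "MirrorlogT (8/8)")
  # 4-4 tie goes to the earlier family in precedence order
  cs3 <- concordance(c(rep(list(nfit), 4), rep(list(tfit), 4)))
  expect_identical(cs3$prevalent_family, "normal")
})
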