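test_that("network construction validates structure", {
  bn <- two_node_bn()
  expect_identical(unname(bn$edges[, "parent"]), "A")
  expect_identical(bn$order, c("A", "B"))
  # chain from parent lists
  n1 <- bn_node("A", "continuous",
                prior = make_family("normal", c(mean = 0, sd = 1)))
  n2 <- bn_node("B", "continuous", parents = "A",
                model = list(class = "linear", intercept = 0,
                             coef = list(A = 1), sigma = 1))
  n3 <- bn_node("C", "continuous", parents = "B",
                model = list(class = "linear", intercept = 0,
                             coef = list(B = 1), sigma = 1))
  ch <- build_network(list(n1, n2, n3))
  expect_equal(nrow(ch$edges), 2L)
  expect_identical(ch$order, c("A", "B", "C"))
  # cycle error
  c1 <- bn_node("A", "continuous", parents = "B",
                model = list(class = "linear", coef = list(B = 1),
                             sigma = 1))
  c2 <- bn_node("B", "continuous", parents = "A",
                model = list(class = "linear", coef = list(A = 1),
                             sigma = 1))
  expect_error(build_network(list(c1, c2)), "cycle")
  # dangling parent
  expect_error(build_network(list(n2)), "dangling")
  # root without prior
  expect_error(bn_node("A", "continuous"), "must carry a prior")
})

test_that("the shipped replica config builds an edgeless 12-node net", {
  bn <- read_network_config(replica_config_path())
  expect_length(bn$nodes, 12L)
  expect_identical(nrow(bn$edges), 0L)
  expect_setequal(names(bn$nodes),
                  c("ca19_9", "age", "tumor_size", "gender", "bmi",
                    "year_of_diagnosis", "tumor_location", "diabetes",
                    "symptoms", "asa_score", "resectability",
                    "neoadjuvant"))
  smp <- forward_sample(bn, 500, seed = 1)
  expect_identical(ncol(smp), 12L)
  expect_true(all(smp$ca19_9 >= 0))
  expect_true(all(smp$age <= 110))
})

test_that("forward-sampled root marginals follow their priors", {
  # fixed proportion 0.5
  nd <- bn_node("coin", "categorical", categories = c("h", "t"),
                prior = list(kind = "fixed", probs = c(h = 0.5, t = 0.5)))
  bn <- build_network(list(nd))
  x <- forward_sample(bn, 1e5, seed = 2)$coin
  expect_lt(abs(mean(x == "h") - 0.5), 0.005)
  # beta prior-predictive male frequency approaches the beta mean
  g <- bn_node("gender", "categorical", categories = c("male", "female"),
               prior = list(kind = "beta", alpha = 7.62, beta = 5.76))
  bng <- build_network(list(g))
  xm <- forward_sample(bng, 1e5, seed = 3)$gender
  expect_lt(abs(mean(xm == "male") - 7.62 / (7.62 + 5.76)), 0.005)
  # fixed mode removes the prior-predictive overdispersion source
  xf <- forward_sample(bng, 1e5, seed = 4,
                       proportion_mode = "fixed")$gender
  expect_lt(abs(mean(xf == "male") - 7.62 / (7.62 + 5.76)), 0.005)
  # continuous T root: KS distance against the truncated prior CDF
  ct <- bn_node("m", "continuous", support = c(0, Inf),
                prior = list(kind = "student_t", location = 130.29,
                             scale = 207.84, df = 7))
  bnc <- build_network(list(ct))
  x <- forward_sample(bnc, 1e4, seed = 5)$m
  fp <- make_family("student_t",
                    c(location = 130.29, scale = 207.84, df = 7))
  p0 <- pfamily(fp, 0)
  cdf <- function(q) (pfamily(fp, q) - p0) / (1 - p0)
  ks <- suppressWarnings(ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("likelihood weighting matches the exact two-node posterior", {
  bn <- two_node_bn(0.6, 0.9, 0.2)
  post <- condition_network(bn, list(B = "b1"), n = 1e5, seed = 11)
  p_hat <- posterior_summary(post)$A[["a1"]]
  exact <- 0.54 / 0.62
  se <- sqrt(exact * (1 - exact) / post$ess)
  expect_lt(abs(p_hat - exact), 3 * se)
})

test_that("likelihood weighting matches enumeration on a 4-node net", {
  bn <- four_node_bn()
  cases <- list(list(q = "A", ev = list(D = "1")),
                list(q = "B", ev = list(C = "1", D = "0")),
                list(q = "C", ev = list(A = "0", D = "1")))
  for (cs in cases) {
    exact <- enumerate_binary_posterior(bn, cs$q, cs$ev)
    post <- condition_network(bn, cs$ev, n = 1e5, seed = 17)
    p_hat <- posterior_summary(post)[[cs$q]][["1"]]
    se <- sqrt(exact * (1 - exact) / post$ess)
    expect_lt(abs(p_hat - exact), 3 * se + 1e-4)
  }
})

test_that("conditioning edge cases behave as specified", {
  bn <- two_node_bn()
  # empty evidence reproduces forward sampling with unit weights
  post <- condition_network(bn, list(), n = 1000, seed = 21)
  expect_true(all(post$weights == 1))
  expect_equal(post$samples, forward_sample(bn, 1000, seed = 21))
  # evidence on a root is a point mass there
  postA <- condition_network(bn, list(A = "a0"), n = 500, seed = 22)
  expect_true(all(postA$samples$A == "a0"))
  # invalid category is rejected before sampling
  expect_error(condition_network(bn, list(A = "unknown"), 100),
               "not a category")
  # structurally impossible evidence gives zero total weight
  bn0 <- two_node_bn(pa = 0.6, pb_given_a1 = 0, pb_given_a0 = 0)
  expect_error(condition_network(bn0, list(B = "b1"), 1000, seed = 1),
               "degenerate evidence")
  # continuous evidence outside support is rejected
  ct <- bn_node("m", "continuous", support = c(0, Inf),
                prior = list(kind = "student_t", location = 10,
                             scale = 2, df = 5))
  bnc <- build_network(list(ct))
  expect_error(condition_network(bnc, list(m = -3), 100),
               "outside the support")
})

test_that("regression-type child models sample and weight correctly", {
  g <- bn_node("x", "continuous",
               prior = make_family("normal", c(mean = 0, sd = 1)))
  y <- bn_node("y", "continuous", parents = "x",
               model = list(class = "linear", intercept = 1,
                            coef = list(x = 2), sigma = 0.5))
  z <- bn_node("z", "categorical", categories = c("no", "yes"),
               parents = "x",
               model = list(class = "logistic", intercept = 0,
                            coef = list(x = 1.5)))
  bn <- build_network(list(g, y, z))
  smp <- forward_sample(bn, 2e4, seed = 31)
  fit <- lm(y ~ x, data = smp)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 0.02)
  expect_equal(sd(residuals(fit)), 0.5, tolerance = 0.02)
  gl <- glm(I(z == "yes") ~ x, family = binomial, data = smp)
  expect_equal(unname(coef(gl)), c(0, 1.5), tolerance = 0.1)
  # conditioning on continuous evidence shifts the parent posterior:
  # x | y = 3 has analytic posterior mean = 2*(3-1)/ (2^2 + 0.25) * 1
  post <- condition_network(bn, list(y = 3), n = 5e4, seed = 32)
  mu_exact <- 2 * (3 - 1) / (2^2 + 0.5^2)
  mu_hat <- posterior_summary(post)$x[["mean"]]
  expect_lt(abs(mu_hat - mu_exact), 0.03)
})

test_that("informative and flat regimes diverge, then reconcile", {
  g <- bn_node("p", "categorical", categories = c("a", "b"),
               prior = list(kind = "beta", alpha = 8, beta = 2))
  bn_inf <- build_network(list(g))
  # identical regimes show ~0 divergence
  cmp0 <- compare_prior_regimes(bn_inf, bn_inf, n = 2e4, seed = 41)
  expect_lt(cmp0$divergence$divergence[1], 0.01)
  # flat vs informative priors differ without evidence...
  bn_flat <- noninformative_network(bn_inf)
  expect_equal(bn_flat$nodes$p$prior$alpha, 1)
  cmp1 <- compare_prior_regimes(bn_inf, bn_flat, n = 2e4, seed = 42)
  expect_lt(abs(cmp1$divergence$divergence[1] - abs(0.8 - 0.5)), 0.03)
  # ...and evidence clamping a node reconciles its posterior exactly
  cmp2 <- compare_prior_regimes(bn_inf, bn_flat,
                                evidence = list(p = "a"),
                                n = 2e4, seed = 43)
  expect_lt(cmp2$divergence$divergence[1], 1e-12)
  # structure mismatch is refused
  other <- build_network(list(bn_node("q", "categorical",
                                      categories = c("a", "b"),
                                      prior = list(kind = "beta",
                                                   alpha = 1, beta = 1))))
  expect_error(compare_prior_regimes(bn_inf, other, n = 100),
               "structure")
})

test_that("DOT export lists nodes and edges deterministically", {
  e2 <- build_network(list(
    bn_node("a", "continuous",
            prior = make_family("normal", c(mean = 0, sd = 1))),
    bn_node("b", "continuous",
            prior = make_family("normal", c(mean = 0, sd = 1)))))
  dot <- to_dot(e2)
  expect_identical(length(gregexpr("shape=", dot)[[1]]), 2L)
  expect_false(grepl("->", dot))
  bn <- two_node_bn()
  expect_match(to_dot(bn), "\"A\" -> \"B\"", fixed = TRUE)
  expect_identical(to_dot(bn), to_dot(bn))
  replica <- read_network_config(replica_config_path())
  expect_identical(length(gregexpr("shape=", to_dot(replica))[[1]]), 12L)
})
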