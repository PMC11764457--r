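# Shared fixtures: assessments generated exactly from a known family,
# tiny catalogs/panels, and small discrete networks with enumerable
# posteriors.

five_probs <- c(0.01, 0.25, 0.5, 0.75, 0.99)

# an assessment whose points are the exact quantiles of `truth`
exact_assessment <- function(truth, probs = five_probs,
                             expert_id = "E1", node_id = "x",
                             support_lower = truth$support_lower,
                             support_upper = truth$support_upper) {
  probability_assessment(expert_id, node_id, probs,
                         qfamily(truth, probs),
                         support_lower = support_lower,
                         support_upper = support_upper)
}

# one representative parameterization per family, on desk scales
reference_families <- function() {
  list(
    normal = make_family("normal", c(mean = 10, sd = 2)),
    student_t = make_family("student_t",
                            c(location = 5, scale = 1.5, df = 3)),
    shifted_gamma = make_family("shifted_gamma",
                                c(shape = 3, rate = 0.5),
                                support_lower = 2),
    mirror_gamma = make_family("mirror_gamma", c(shape = 3, rate = 0.5),
                               support_upper = 20),
    lognormal = make_family("lognormal", c(meanlog = 1, sdlog = 0.5),
                            support_lower = 0),
    log_t = make_family("log_t", c(location = 1, scale = 0.3, df = 3),
                        support_lower = 0),
    mirror_log_t = make_family("mirror_log_t",
                               c(location = 1, scale = 0.3, df = 3),
                               support_upper = 15),
    shifted_scaled_beta = make_family("shifted_scaled_beta",
                                      c(alpha = 2, beta = 5),
                                      support_lower = 0,
                                      support_upper = 1))
}

demo_catalog <- function() {
  node_catalog(c("gender", "age", "ca19_9"),
               c("proportion", "continuous", "continuous"))
}

demo_panel_df <- function() {
  data.frame(
    expert_id = c("E1", "E2", "E3"),
    node_id = "gender",
    lower = c(0.30, 0.35, 0.25),
    q1 = c(0.50, 0.48, 0.45),
    median = c(0.56, 0.55, 0.52),
    q3 = c(0.62, 0.60, 0.58),
    upper = c(0.80, 0.75, 0.70),
    stringsAsFactors = FALSE)
}

# two-node binary network: A ~ fixed(pa), B | A from a cpt
two_node_bn <- function(pa = 0.6, pb_given_a1 = 0.9, pb_given_a0 = 0.2) {
  nA <- bn_node("A", "categorical", categories = c("a1", "a0"),
                prior = list(kind = "fixed",
                             probs = c(a1 = pa, a0 = 1 - pa)))
  nB <- bn_node("B", "categorical", categories = c("b1", "b0"),
                parents = "A",
                model = list(class = "cpt", table = data.frame(
                  A = c("a1", "a0"),
                  b1 = c(pb_given_a1, pb_given_a0),
                  b0 = c(1 - pb_given_a1, 1 - pb_given_a0))))
  build_network(list(nA, nB))
}

# a 4-node binary chain/collider net with all-cpt models, enumerable
four_node_bn <- function() {
  nA <- bn_node("A", "categorical", categories = c("1", "0"),
                prior = list(kind = "fixed", probs = c(`1` = 0.3,
                                                       `0` = 0.7)))
  nB <- bn_node("B", "categorical", categories = c("1", "0"),
                prior = list(kind = "fixed", probs = c(`1` = 0.6,
                                                       `0` = 0.4)))
  nC <- bn_node("C", "categorical", categories = c("1", "0"),
                parents = c("A", "B"),
                model = list(class = "cpt", table = data.frame(
                  A = c("1", "1", "0", "0"), B = c("1", "0", "1", "0"),
                  `1` = c(0.9, 0.5, 0.4, 0.1),
                  `0` = c(0.1, 0.5, 0.6, 0.9), check.names = FALSE)))
  nD <- bn_node("D", "categorical", categories = c("1", "0"),
                parents = "C",
                model = list(class = "cpt", table = data.frame(
                  C = c("1", "0"), `1` = c(0.8, 0.25),
                  `0` = c(0.2, 0.75), check.names = FALSE)))
  build_network(list(nA, nB, nC, nD))
}

# exact enumeration of P(query = "1" | evidence) on an all-binary
# all-cpt/fixed network -- the brute-force oracle for likelihood
# weighting
enumerate_binary_posterior <- function(bn, query, evidence) {
  ids <- names(bn$nodes)
  grid <- expand.grid(lapply(bn$nodes, function(nd) nd$categories),
                      stringsAsFactors = FALSE)
  names(grid) <- ids
  joint <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (id in ids) {
      nd <- bn$nodes[[id]]
      v <- grid[i, id]
      p <- p * if (length(nd$parents) == 0L) {
        nd$prior$probs[[v]]
      } else {
        tab <- nd$model$table
        sel <- rep(TRUE, nrow(tab))
        for (pp in nd$parents) sel <- sel & tab[[pp]] == grid[i, pp]
        tab[sel, v][[1]]
      }
    }
    p
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (id in names(evidence)) keep <- keep & grid[[id]] == evidence[[id]]
  sum(joint[keep & grid[[query]] == bn$nodes[[query]]$categories[1]]) /
    sum(joint[keep])
}

replica_config_path <- function() {
  path <- system.file("extdata", "paper_replica.yaml", package = "elicitbn")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata",
                                       "paper_replica.yaml")
  path
}
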