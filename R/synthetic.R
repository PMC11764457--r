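#' Configure a synthetic expert panel with known ground truth
#'
#' Emulates a quartile-elicitation panel: each expert reports the true
#' distribution's (tail, 0.25, 0.5, 0.75, 1 - tail) quantiles perturbed
#' by seeded multiplicative Gaussian noise (relative, so nodes whose
#' scales differ by orders of magnitude — proportions vs CA 19-9 UI/mL —
#' are perturbed comparably), truncated at the support bounds and
#' re-sorted to restore monotonicity. Designated experts per node emit
#' incomplete judgments (a missing lower limit), reproducing the
#' complete-case bookkeeping of real panels.
#'
#' @param n_experts Panel size.
#' @param nodes Named list: `node_id = list(kind =, truth =)` where
#'   `truth` is a [make_family()] object (node support is taken from the
#'   catalog defaults for the kind unless `support` is given).
#' @param judgment_noise_sd Relative standard deviation of the
#'   multiplicative noise (0 = noiseless).
#' @param missingness Named list `node_id = k`: number of experts with
#'   an incomplete judgment for that node (`k < n_experts`).
#' @param seed Single seed; all panel randomness flows from it.
#' @param tail_probability Probability attached to the plausible limits.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_experts, nodes, judgment_noise_sd = 0,
                         missingness = list(), seed = 1,
                         tail_probability = 0.01) {
  stopifnot(n_experts >= 2, judgment_noise_sd >= 0)
  for (id in names(missingness)) {
    if (!id %in% names(nodes)) {
      stop("missingness names an unknown node: ", id, call. = FALSE)
    }
    if (missingness[[id]] >= n_experts) {
      stop("missingness for '", id, "' must be < n_experts", call. = FALSE)
    }
  }
  for (id in names(nodes)) {
    nd <- nodes[[id]]
    if (is.null(nd$kind) || !nd$kind %in% c("proportion", "continuous")) {
      stop("node '", id, "' needs kind 'proportion' or 'continuous'",
           call. = FALSE)
    }
    if (!inherits(nd$truth, "family_params")) {
      stop("node '", id, "' needs a family_params truth", call. = FALSE)
    }
  }
  structure(list(n_experts = n_experts, nodes = nodes,
                 judgment_noise_sd = judgment_noise_sd,
                 missingness = missingness, seed = seed,
                 tail_probability = tail_probability),
            class = "panel_config")
}

#' Node catalog implied by a panel configuration
#'
#' @param config A [panel_config()].
#' @return A [node_catalog()].
#' @export
panel_catalog <- function(config) {
  ids <- names(config$nodes)
  kinds <- vapply(config$nodes, `[[`, character(1), "kind")
  lo <- vapply(ids, function(id) {
    s <- config$nodes[[id]]$support
    if (!is.null(s)) s[1] else if (kinds[[id]] == "proportion") 0 else 0
  }, numeric(1))
  hi <- vapply(ids, function(id) {
    s <- config$nodes[[id]]$support
    if (!is.null(s)) s[2] else if (kinds[[id]] == "proportion") 1 else Inf
  }, numeric(1))
  node_catalog(ids, kinds, support_lower = lo, support_upper = hi)
}

#' Simulate a panel of quartile judgments
#'
#' Deterministic given the config seed: the same configuration always
#' yields byte-identical panels.
#'
#' @param config A [panel_config()].
#' @return A `quartile_panel` data frame.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  probs <- c(config$tail_probability, 0.25, 0.5, 0.75,
             1 - config$tail_probability)
  catalog <- panel_catalog(config)
  .with_seed(config$seed, {
    rows <- list()
    for (id in names(config$nodes)) {
      nd <- config$nodes[[id]]
      cat_row <- catalog[catalog$node_id == id, ]
      q_true <- qfamily(nd$truth, probs)
      miss_k <- config$missingness[[id]] %||% 0
      miss_experts <- if (miss_k > 0) {
        sample.int(config$n_experts, miss_k)
      } else integer(0)
      for (e in seq_len(config$n_experts)) {
        q <- q_true
        if (config$judgment_noise_sd > 0) {
          q <- q * (1 + stats::rnorm(5, 0, config$judgment_noise_sd))
          q <- pmin(pmax(q, cat_row$support_lower), cat_row$support_upper)
          q <- sort(q)
        }
        if (e %in% miss_experts) q[1] <- NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          expert_id = sprintf("E%d", e), node_id = id,
          lower = q[1], q1 = q[2], median = q[3], q3 = q[4], upper = q[5],
          stringsAsFactors = FALSE)
      }
    }
    read_judgments(do.call(rbind, rows), catalog)
  })
}

#' Run the whole pipeline on a synthetic panel and score recovery
#'
#' Fits every complete judgment over the candidate families, pools per
#' node, builds the prior appropriate for the node kind, and reports the
#' bias of the pooled moments against the generating truth together
#' with the proportion of experts whose best-fit family equals the
#' generating family (a synthetic family-concordance census).
#'
#' @param config A [panel_config()].
#' @param families Candidate families for the per-expert fits.
#' @param df_fixed,seed Passed to [fit_best()].
#' @return An object of class `recovery_report`: data frame `per_node`
#'   (truth vs pooled moments, biases, family recovery, prior label) and
#'   lists `fits`, `pools`, `priors` keyed by node.
#' @export
recovery_experiment <- function(config, families = family_names(),
                                df_fixed = 3, seed = 1) {
  panel <- simulate_panel(config)
  catalog <- panel_catalog(config)
  fits <- list(); pools <- list(); priors <- list(); rows <- list()
  for (id in names(config$nodes)) {
    nd <- config$nodes[[id]]
    assessments <- node_assessments(panel, catalog, id,
                                    config$tail_probability)
    nf <- lapply(assessments, fit_best, families = families,
                 df_fixed = df_fixed, seed = seed)
    pool <- linear_pool(nf)
    pm <- pool_moments(pool)
    tm <- fam_moments(nd$truth, allow_truncated = TRUE)
    strategy <- if (nd$kind == "proportion") "beta_moment" else
      "pooled_moment_t"
    prior <- make_prior(catalog[catalog$node_id == id, ], pool, strategy)
    cs <- concordance(nf)
    fits[[id]] <- nf; pools[[id]] <- pool; priors[[id]] <- prior
    rows[[id]] <- data.frame(
      node_id = id, true_family = nd$truth$family,
      true_mean = tm$mean, true_sd = tm$sd,
      pooled_mean = pm$mean, pooled_sd = pm$sd,
      bias_mean = pm$mean - tm$mean, bias_sd = pm$sd - tm$sd,
      n_experts = length(nf),
      family_recovery = mean(vapply(nf, function(f) f$params$family,
                                    character(1)) == nd$truth$family),
      concordance = format_concordance(cs),
      prior = prior$label, stringsAsFactors = FALSE)
  }
  structure(list(per_node = do.call(rbind, c(rows,
                                             make.row.names = FALSE)),
                 fits = fits, pools = pools, priors = priors,
                 config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery report>\n")
  print(x$per_node[, c("node_id", "true_family", "bias_mean", "bias_sd",
                       "family_recovery", "prior")])
  invisible(x)
}

#' A panel preset emulating the pancreatic-cancer elicitation study
#'
#' Nine experts and twelve clinical nodes: ten proportions (gender,
#' BMI class, year of diagnosis, tumor location, diabetes, symptoms,
#' ASA class, resectability, neoadjuvant treatment) and three positive
#' continuous quantities (CA 19-9 in UI/mL, age in years, tumor size in
#' mm), with incomplete responses for age (2 experts), tumor size (1)
#' and CA 19-9 (1). True distributions are chosen so the pooled moments
#' approximate the published pooled summaries; the preset is an
#' end-to-end smoke-test surface, not ground truth for the study.
#'
#' @param seed Panel seed.
#' @param judgment_noise_sd Relative noise between experts.
#' @return A [panel_config()].
#' @export
paper_like_config <- function(seed = 1, judgment_noise_sd = 0.05) {
  bt <- function(a, b) {
    make_family("shifted_scaled_beta", c(alpha = a, beta = b), 0, 1)
  }
  prop <- function(a, b) list(kind = "proportion", truth = bt(a, b))
  nodes <- list(
    # lognormal matched to pooled mean 130.29, SD 207.84
    ca19_9 = list(kind = "continuous",
                  truth = make_family("lognormal",
                                      c(meanlog = 4.2372, sdlog = 1.1250),
                                      support_lower = 0)),
    # left-skewed ages, reflected about a 100-year bound
    age = list(kind = "continuous", support = c(0, 100),
               truth = make_family("mirror_gamma",
                                   c(shape = 3.781, rate = 0.1239),
                                   support_upper = 100)),
    tumor_size = list(kind = "continuous",
                      truth = make_family("shifted_gamma",
                                          c(shape = 4.365, rate = 0.1830),
                                          support_lower = 0)),
    gender = prop(7.62, 5.76),
    bmi = prop(10.07, 6.69),
    year_of_diagnosis = prop(3.85, 2.08),
    tumor_location = prop(4.26, 3.63),
    diabetes = prop(12.52, 10.00),
    symptoms = prop(3.46, 2.15),
    asa_score = prop(4.75, 2.94),
    resectability = prop(3.83, 2.13),
    neoadjuvant = prop(3.46, 2.22))
  panel_config(9, nodes, judgment_noise_sd = judgment_noise_sd,
               missingness = list(age = 2, tumor_size = 1, ca19_9 = 1),
               seed = seed)
}
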