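#' Write a reproducibility manifest next to a command's outputs
#'
#' Every artifact-producing pipeline command records what ran: the
#' command name, the MD5 of its input file(s), the seed, the package
#' version and a timestamp.
#'
#' @param command Command name.
#' @param inputs Character vector of input file paths (hashed if they
#'   exist).
#' @param seed Seed used, or `NA`.
#' @param path Output path for the JSON manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, inputs, seed, path) {
  hashes <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(command = command,
                   inputs = as.list(stats::setNames(hashes, inputs)),
                   seed = if (is.null(seed)) NA else seed,
                   package = "elicitbn",
                   version = as.character(utils::packageVersion("elicitbn")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Fit all experts' judgments (pipeline stage 1)
#'
#' Reads a judgment file and node catalog, applies the per-node
#' complete-case filter, standardizes the five-point summaries, and
#' writes one best-fit row per retained (expert, node) pair as CSV and
#' JSON, plus a run manifest.
#'
#' @param judgments_path CSV/JSON judgments (see [read_judgments()]).
#' @param catalog_path JSON/YAML node catalog.
#' @param out_dir Output directory (created if needed).
#' @param tail_probability,families,df_fixed,seed Fitting options.
#' @return Invisibly, the list of `fitted_dist` objects per node.
#' @export
run_fit <- function(judgments_path, catalog_path, out_dir,
                    tail_probability = 0.01, families = family_names(),
                    df_fixed = 3, seed = 1) {
  catalog <- read_node_catalog(catalog_path)
  panel <- read_judgments(judgments_path, catalog)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  for (id in unique(panel$node_id)) {
    assessments <- node_assessments(panel, catalog, id, tail_probability)
    fits[[id]] <- lapply(assessments, fit_best, families = families,
                         df_fixed = df_fixed, seed = seed)
  }
  tab <- do.call(rbind, lapply(fits, fits_table))
  rownames(tab) <- NULL
  utils::write.csv(tab, file.path(out_dir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(tab, file.path(out_dir, "fits.json"),
                       dataframe = "rows", digits = NA)
  write_manifest("fit", c(judgments_path, catalog_path), seed,
                 file.path(out_dir, "fit_manifest.json"))
  invisible(fits)
}

#' Load a fit table back into fitted_dist objects
#'
#' @param path `fits.csv` or `fits.json` written by [run_fit()].
#' @return Named list (by node) of lists of `fitted_dist` objects.
#' @export
read_fits <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(tab))) {
    f <- structure(list(expert_id = as.character(tab$expert_id[i]),
                        node_id = as.character(tab$node_id[i]),
                        params = family_from_json(tab$params[i]),
                        sse = tab$sse[i], convergence = 0L),
                   class = "fitted_dist")
    out[[f$node_id]] <- c(out[[f$node_id]], list(f))
  }
  out
}

#' Pool fits and build priors (pipeline stage 2)
#'
#' Per node: equally weighted linear pool, pooled moments, the prior
#' appropriate for the node kind, and the family-concordance census.
#' Writes a pooled-summary CSV (node, pooled mean, pooled SD, prior
#' string, note) and a concordance CSV (node, prevalent family as
#' `"Family (k/n)"`). Proportion nodes whose pooled moments are
#' beta-infeasible are flagged with a WARN note — the run continues and
#' no beta prior is emitted for them.
#'
#' @param fits Named list per node of `fitted_dist` lists (from
#'   [run_fit()] or [read_fits()]), or a path to a fit table.
#' @param catalog A [node_catalog()] or a path to one.
#' @param out_dir Output directory.
#' @param proportion_strategy `"beta_moment"` or `"beta_quantile"`.
#' @param continuous_strategy `"pooled_moment_t"` or
#'   `"refit_best_family"`.
#' @return Invisibly, list with `pool_table`, `concordance_table`,
#'   `priors`.
#' @export
run_pool_priors <- function(fits, catalog, out_dir,
                            proportion_strategy = "beta_moment",
                            continuous_strategy = "pooled_moment_t") {
  if (is.character(fits)) fits <- read_fits(fits)
  if (is.character(catalog)) catalog <- read_node_catalog(catalog)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pool_rows <- list(); conc_rows <- list(); priors <- list()
  for (id in names(fits)) {
    node <- catalog[catalog$node_id == id, , drop = FALSE]
    if (nrow(node) != 1L) {
      stop("fitted node '", id, "' not in catalog", call. = FALSE)
    }
    nf <- fits[[id]]
    cs <- concordance(nf)
    conc_rows[[id]] <- data.frame(node_id = id,
                                  prevalent = format_concordance(cs),
                                  stringsAsFactors = FALSE)
    if (length(nf) < 2L) {
      pool_rows[[id]] <- data.frame(node_id = id, pooled_mean = NA,
                                    pooled_sd = NA, prior = NA,
                                    note = "WARN: fewer than 2 experts",
                                    stringsAsFactors = FALSE)
      next
    }
    pool <- linear_pool(nf)
    pm <- pool_moments(pool)
    strategy <- if (node$kind == "proportion") proportion_strategy else
      continuous_strategy
    note <- ""
    prior_label <- NA_character_
    if (node$kind == "proportion" && strategy == "beta_moment" &&
        !beta_feasible(pm$mean, pm$sd)) {
      note <- sprintf(
        "WARN: beta-infeasible pooled moments (sd^2 = %.4g >= %.4g)",
        pm$sd^2, pm$mean * (1 - pm$mean))
    } else {
      pr <- make_prior(node, pool, strategy)
      priors[[id]] <- pr
      prior_label <- pr$label
      if (pm$method == "truncated") note <- "truncated pooled moments"
    }
    pool_rows[[id]] <- data.frame(node_id = id, pooled_mean = pm$mean,
                                  pooled_sd = pm$sd, prior = prior_label,
                                  note = note, stringsAsFactors = FALSE)
  }
  pool_table <- do.call(rbind, c(pool_rows, make.row.names = FALSE))
  conc_table <- do.call(rbind, c(conc_rows, make.row.names = FALSE))
  utils::write.csv(pool_table, file.path(out_dir, "pooled_priors.csv"),
                   row.names = FALSE)
  utils::write.csv(conc_table, file.path(out_dir, "concordance.csv"),
                   row.names = FALSE)
  write_manifest("pool_priors", character(0), NA,
                 file.path(out_dir, "pool_manifest.json"))
  invisible(list(pool_table = pool_table, concordance_table = conc_table,
                 priors = priors))
}

#' Sample (optionally conditioned) from a configured network
#' (pipeline stage 3)
#'
#' Builds the network from a config file, validates any evidence before
#' sampling, and writes the (weighted, if conditioned) sample table as
#' CSV with one column per node, plus a manifest. Identical seeds give
#' identical outputs.
#'
#' @param config_path Network YAML/JSON.
#' @param n Number of replicates.
#' @param seed Seed.
#' @param evidence Optional named list of evidence.
#' @param out_path Output CSV path.
#' @return Invisibly, the sample data frame (with a `.weight` column
#'   when evidence was given).
#' @export
run_sample <- function(config_path, n, seed, evidence = NULL,
                       out_path = "samples.csv") {
  bn <- read_network_config(config_path)
  if (is.null(evidence) || length(evidence) == 0L) {
    smp <- forward_sample(bn, n, seed)
  } else {
    post <- condition_network(bn, evidence, n, seed)
    smp <- post$samples
    smp$.weight <- post$weights
  }
  dir.create(dirname(out_path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(smp, out_path, row.names = FALSE)
  write_manifest("sample", config_path, seed,
                 sub("\\.csv$", "_manifest.json", out_path))
  invisible(smp)
}
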