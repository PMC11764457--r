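#' Describe the quantities of interest (network nodes)
#'
#' A node catalog records, for each quantity of interest elicited from
#' the panel, its identifier, kind and support. Proportion nodes (the
#' elicited probability of the first-listed category of a categorical
#' variable) default to support \[0, 1\]; continuous clinical nodes
#' (e.g. CA 19-9 in UI/mL, tumor size in mm, age in years) default to
#' \[0, Inf).
#'
#' @param node_id Character vector of unique node identifiers.
#' @param kind `"proportion"` or `"continuous"`, recycled.
#' @param units Optional units string per node.
#' @param support_lower,support_upper Optional support bounds; defaults
#'   depend on `kind`.
#' @return A data frame of class `node_catalog`.
#' @export
node_catalog <- function(node_id, kind, units = NA_character_,
                         support_lower = NULL, support_upper = NULL) {
  kind <- match.arg(kind, c("proportion", "continuous"),
                    several.ok = TRUE)
  n <- length(node_id)
  kind <- rep_len(kind, n)
  if (anyDuplicated(node_id)) {
    stop("duplicate node_id in catalog", call. = FALSE)
  }
  if (is.null(support_lower)) {
    support_lower <- ifelse(kind == "proportion", 0, 0)
  }
  if (is.null(support_upper)) {
    support_upper <- ifelse(kind == "proportion", 1, Inf)
  }
  out <- data.frame(node_id = as.character(node_id), kind = kind,
                    units = rep_len(units, n),
                    support_lower = rep_len(support_lower, n),
                    support_upper = rep_len(support_upper, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("node_catalog", "data.frame")
  out
}

#' Read a node catalog from JSON or YAML
#'
#' The file holds a list of objects with fields `node_id`, `kind` and
#' optionally `units`, `support_lower`, `support_upper` (or a
#' two-element `support`).
#'
#' @param path File path; format chosen by extension
#'   (`.json` vs `.yaml`/`.yml`).
#' @return A `node_catalog`.
#' @export
read_node_catalog <- function(path) {
  recs <- .read_config_file(path)
  if (!is.null(recs$nodes)) recs <- recs$nodes
  one <- function(r) {
    sup <- r$support
    lo <- if (!is.null(r$support_lower)) r$support_lower else
      if (!is.null(sup)) sup[[1]] else NULL
    hi <- if (!is.null(r$support_upper)) r$support_upper else
      if (!is.null(sup)) sup[[2]] else NULL
    node_catalog(r$node_id, r$kind,
                 units = if (is.null(r$units)) NA_character_ else r$units,
                 support_lower = if (is.null(lo)) NULL else as.numeric(lo),
                 support_upper = if (is.null(hi)) NULL else as.numeric(hi))
  }
  out <- do.call(rbind, lapply(recs, one))
  class(out) <- c("node_catalog", "data.frame")
  out
}

.read_config_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
}

.judgment_cols <- c("lower", "q1", "median", "q3", "upper")

# complete iff all five summaries are present and not identical-null
.is_complete <- function(v) {
  v <- as.numeric(v)
  if (anyNA(v)) return(FALSE)
  if (length(unique(v)) == 1L) return(FALSE)
  TRUE
}

#' Read and validate expert quartile judgments
#'
#' Each row is one expert's five-point summary for one node: plausible
#' lower limit, lower quartile, median, upper quartile, plausible upper
#' limit. Rows with missing cells, or whose five values are all
#' identical (a null response), are retained but flagged
#' `complete = FALSE`; complete rows must be monotone
#' (`lower <= q1 <= median <= q3 <= upper`) and, for proportion nodes,
#' lie in \[0, 1\].
#'
#' @param source A data frame, or a path to a CSV file (columns
#'   `expert_id,node_id,lower,q1,median,q3,upper`) or a JSON file (an
#'   array of objects with those fields).
#' @param catalog A [node_catalog()] naming the admissible nodes.
#' @return A data frame of class `quartile_panel` with an added logical
#'   `complete` column.
#' @export
read_judgments <- function(source, catalog) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
    df <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::fromJSON(source, simplifyVector = TRUE)
    } else {
      utils::read.csv(source, stringsAsFactors = FALSE)
    }
  } else {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
  }
  need <- c("expert_id", "node_id", .judgment_cols)
  if (nrow(df) == 0L) stop("judgment source contains no rows", call. = FALSE)
  if (!all(need %in% names(df))) {
    stop("judgment source must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  df$expert_id <- as.character(df$expert_id)
  df$node_id <- as.character(df$node_id)
  for (cl in .judgment_cols) df[[cl]] <- as.numeric(df[[cl]])

  unknown <- setdiff(df$node_id, catalog$node_id)
  if (length(unknown) > 0L) {
    stop("unknown node_id not in catalog: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df[, c("expert_id", "node_id")])) {
    stop("duplicate (expert_id, node_id) rows in judgments", call. = FALSE)
  }
  df$complete <- vapply(seq_len(nrow(df)), function(i) {
    .is_complete(df[i, .judgment_cols])
  }, logical(1))

  for (i in seq_len(nrow(df))) {
    v <- as.numeric(df[i, .judgment_cols])
    if (df$complete[i] && is.unsorted(v, strictly = FALSE)) {
      stop(sprintf(
        "non-monotone quartile judgment for expert '%s', node '%s'",
        df$expert_id[i], df$node_id[i]), call. = FALSE)
    }
    kind <- catalog$kind[match(df$node_id[i], catalog$node_id)]
    if (kind == "proportion" && any(!is.na(v) & (v < 0 | v > 1))) {
      stop(sprintf(
        "proportion judgment outside [0, 1] for expert '%s', node '%s'",
        df$expert_id[i], df$node_id[i]), call. = FALSE)
    }
  }
  class(df) <- c("quartile_panel", "data.frame")
  df
}

#' Write a panel of judgments to CSV or JSON
#'
#' Inverse of [read_judgments()] (round-trips valid panels exactly up to
#' numeric formatting). The derived `complete` flag is not written; it
#' is recomputed on read.
#'
#' @param panel A `quartile_panel`.
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_judgments <- function(panel, path) {
  cols <- c("expert_id", "node_id", .judgment_cols)
  df <- as.data.frame(panel)[, cols]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Per-node complete-case filter
#'
#' Retains only the experts who gave a complete five-point judgment for
#' the node; the retained count `n` feeds the pooled-prior degrees of
#' freedom rule `df = n - 1`. Idempotent and never increases the panel.
#'
#' @param panel A `quartile_panel`.
#' @param node_id Node to filter on.
#' @return The complete rows for `node_id`, as a `quartile_panel`.
#' @export
complete_case_filter <- function(panel, node_id) {
  out <- panel[panel$node_id == node_id & panel$complete, , drop = FALSE]
  if (nrow(out) < 2L) {
    stop(sprintf(
      "insufficient panel: node '%s' has %d complete judgment(s); need >= 2",
      node_id, nrow(out)), call. = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("quartile_panel", "data.frame")
  out
}

#' A (probability, quantile) assessment for one expert and node
#'
#' @param expert_id,node_id Identifiers.
#' @param probs Strictly increasing probabilities in (0, 1).
#' @param values Non-decreasing quantile values, one per probability.
#' @param support_lower,support_upper Support bounds for the node.
#' @return An object of class `probability_assessment`.
#' @export
probability_assessment <- function(expert_id, node_id, probs, values,
                                   support_lower = -Inf,
                                   support_upper = Inf) {
  probs <- as.numeric(probs); values <- as.numeric(values)
  if (length(probs) != length(values) || length(probs) < 3L) {
    stop("an assessment needs at least 3 (probability, quantile) points",
         call. = FALSE)
  }
  if (any(probs <= 0 | probs >= 1) || is.unsorted(probs, strictly = TRUE)) {
    stop("probabilities must be strictly increasing within (0, 1)",
         call. = FALSE)
  }
  if (is.unsorted(values, strictly = FALSE)) {
    stop("quantile values must be non-decreasing", call. = FALSE)
  }
  structure(list(expert_id = as.character(expert_id),
                 node_id = as.character(node_id),
                 probs = probs, values = values,
                 support_lower = support_lower,
                 support_upper = support_upper),
            class = "probability_assessment")
}

#' Standardize a quartile judgment into a probability assessment
#'
#' Attaches probabilities to the five elicited summaries: the plausible
#' limits become the `tail_probability` and `1 - tail_probability`
#' quantiles (limits are treated as near-certain bounds, the overconfidence
#' standardization step), and the quartiles keep 0.25 / 0.5 / 0.75. The
#' quantile values themselves are preserved exactly.
#'
#' @param judgment A single-row `quartile_panel` (or a list with the
#'   judgment fields).
#' @param tail_probability Probability mass assigned outside each
#'   plausible limit; must be < 0.25. Default 0.01.
#' @param support_lower,support_upper Node support from the catalog.
#' @return A [probability_assessment()].
#' @export
standardize_intervals <- function(judgment, tail_probability = 0.01,
                                  support_lower = -Inf,
                                  support_upper = Inf) {
  if (!(tail_probability > 0 && tail_probability < 0.25)) {
    stop("tail_probability must lie in (0, 0.25): quartile probabilities ",
         "would collide", call. = FALSE)
  }
  j <- as.list(judgment)
  v <- as.numeric(c(j$lower, j$q1, j$median, j$q3, j$upper))
  if (anyNA(v)) {
    stop(sprintf("incomplete judgment for expert '%s', node '%s' cannot be ",
                 j$expert_id, j$node_id),
         "standardized; apply complete_case_filter() first", call. = FALSE)
  }
  probability_assessment(j$expert_id, j$node_id,
                         probs = c(tail_probability, 0.25, 0.5, 0.75,
                                   1 - tail_probability),
                         values = v,
                         support_lower = support_lower,
                         support_upper = support_upper)
}

#' Standardize all complete judgments of one node
#'
#' Convenience wrapper: complete-case filter, then
#' [standardize_intervals()] per retained expert, with support taken
#' from the catalog.
#'
#' @param panel A `quartile_panel`.
#' @param catalog A [node_catalog()].
#' @param node_id Node to process.
#' @param tail_probability See [standardize_intervals()].
#' @param fit_quartiles_only If `TRUE`, drop the tail points and keep
#'   only the three quartiles (the plausible limits then only constrain
#'   support, they do not enter the least-squares fit).
#' @return List of `probability_assessment` objects.
#' @export
node_assessments <- function(panel, catalog, node_id,
                             tail_probability = 0.01,
                             fit_quartiles_only = FALSE) {
  row <- catalog[catalog$node_id == node_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("node '", node_id, "' not in catalog",
                            call. = FALSE)
  kept <- complete_case_filter(panel, node_id)
  lapply(seq_len(nrow(kept)), function(i) {
    a <- standardize_intervals(kept[i, ], tail_probability,
                               support_lower = row$support_lower,
                               support_upper = row$support_upper)
    if (fit_quartiles_only) {
      probability_assessment(a$expert_id, a$node_id, a$probs[2:4],
                             a$values[2:4], a$support_lower,
                             a$support_upper)
    } else a
  })
}

#' @export
print.probability_assessment <- function(x, ...) {
  cat(sprintf("<assessment> expert %s, node %s\n", x$expert_id, x$node_id))
  print(stats::setNames(x$values, format(x$probs)))
  invisible(x)
}
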