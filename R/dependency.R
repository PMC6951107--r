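## The retrieval-dependency statistic: proportion of joint retrieval in the
## data versus under an independence model built from the participant's
## marginal accuracies, averaged over six 2x2 contingency tables.

#' Cross-classify two retrieval directions into a 2x2 contingency table
#'
#' For one of the six table specifications (see [table_specs()]), counts the
#' events where both, one, or neither of the two directions sharing a common
#' element were retrieved correctly. Events that do not administer both
#' directions (open-loops with a different common element) are excluded, so
#' closed-loop events contribute to all six tables and open-loop events to
#' exactly the two tables matching their common element.
#'
#' @param x A [response_matrix()].
#' @param spec One row of [table_specs()].
#' @return A list of class `"contingency_table"` with counts `n11`, `n10`,
#'   `n01`, `n00`, total `n`, the two per-direction marginal accuracies
#'   `p1`, `p2` (computed over the contributing events), and the spec.
#'   `n == 0` flags an empty table.
#' @export
contingency_table <- function(x, spec) {
  a <- x$resp[spec$dir1, ]
  b <- x$resp[spec$dir2, ]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  structure(list(
    n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
    n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0),
    n = length(a),
    p1 = if (length(a)) mean(a) else NA_real_,
    p2 = if (length(b)) mean(b) else NA_real_,
    spec = spec
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table (%s, common = %s), %d events\n",
              x$spec$orientation, x$spec$common, x$n))
  m <- matrix(c(x$n11, x$n01, x$n10, x$n00), 2,
              dimnames = list(c("dir1 correct", "dir1 incorrect"),
                              c("dir2 correct", "dir2 incorrect")))
  print(m)
  invisible(x)
}

#' Proportion of joint retrieval of a contingency table
#'
#' Leading-diagonal proportion: the fraction of events where the two
#' directions were both correct or both incorrect.
#'
#' @param table A [contingency_table()].
#' @return `(n11 + n00) / n`.
#' @export
joint_retrieval <- function(table) {
  if (table$n < 1L) stop("empty contingency table")
  (table$n11 + table$n00) / table$n
}

#' Joint proportion under independence
#'
#' Expected proportion of joint (in)correct retrieval for two directions with
#' marginal accuracies `p1` and `p2` retrieved independently:
#' `p1 * p2 + (1 - p1) * (1 - p2)`. The statistic scales with accuracy (it is
#' minimized at marginals of .5), which is why only the difference between
#' data and model is interpretable.
#'
#' @param p1,p2 Marginal accuracies in `[0, 1]` (vectorized).
#' @return Proportion(s) in `[0, 1]`.
#' @examples
#' independent_joint(0.7, 0.6)  # 0.54
#' @export
independent_joint <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("marginal accuracies must lie in [0, 1]")
  p1 * p2 + (1 - p1) * (1 - p2)
}

#' Dependency for one participant-session response matrix
#'
#' Builds the six contingency tables, computes the proportion of joint
#' retrieval in the data and under the independence model for each, and
#' averages over the non-empty tables. The independence model uses the
#' marginal accuracies of each table's contributing events, so data and
#' model are always compared on identical event sets. Dependency is the
#' data-minus-model difference; values above zero indicate that retrievals
#' of associations from the same event succeed and fail together.
#'
#' @param x A [response_matrix()] (missing responses must already be coded
#'   incorrect upstream; see [read_trials()]).
#' @return A list of class `"dependency_result"`: `p_joint_data`,
#'   `p_joint_model`, `dependency`, `n_tables` (non-empty tables used) and
#'   `tables`, the per-table breakdown.
#' @export
dependency_for_participant <- function(x) {
  specs <- table_specs()
  i1 <- match(specs$dir1, DIRECTIONS$id)
  i2 <- match(specs$dir2, DIRECTIONS$id)
  n <- n11 <- n10 <- n01 <- n00 <- p1 <- p2 <- numeric(6)
  for (k in 1:6) {
    a <- x$resp[i1[k], ]
    b <- x$resp[i2[k], ]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    n[k] <- length(a)
    n11[k] <- sum(a & b); n00[k] <- sum(!a & !b)
    n10[k] <- sum(a) - n11[k]; n01[k] <- sum(b) - n11[k]
    p1[k] <- if (n[k]) mean(a) else NA_real_
    p2[k] <- if (n[k]) mean(b) else NA_real_
  }
  breakdown <- data.frame(
    orientation = specs$orientation, common = specs$common,
    n = n, n11 = n11, n10 = n10, n01 = n01, n00 = n00, p1 = p1, p2 = p2,
    joint_data = ifelse(n > 0, (n11 + n00) / n, NA_real_),
    joint_model = independent_joint(p1, p2),
    stringsAsFactors = FALSE)
  used <- breakdown$n > 0L
  if (!any(used)) stop("all six contingency tables are empty")
  res <- list(p_joint_data = mean(breakdown$joint_data[used]),
              p_joint_model = mean(breakdown$joint_model[used]),
              n_tables = sum(used),
              tables = breakdown)
  res$dependency <- res$p_joint_data - res$p_joint_model
  class(res) <- "dependency_result"
  res
}

#' @export
print.dependency_result <- function(x, digits = 3, ...) {
  cat(sprintf("Joint retrieval: data %.*f, independent model %.*f  (over %d tables)\n",
              digits, x$p_joint_data, digits, x$p_joint_model, x$n_tables))
  cat(sprintf("Dependency: %.*f\n", digits, x$dependency))
  invisible(x)
}

#' Group summary of dependency results
#'
#' Per-group mean and standard deviation of the proportion of joint retrieval
#' in the data and independence model, and of their difference - the shape in
#' which such results are conventionally tabulated.
#'
#' @param results data.frame of per-participant results (e.g.
#'   `fit$results` from [retdep()]) with columns `p_joint_data`,
#'   `p_joint_model`, `dependency`.
#' @param by Character vector of grouping columns (default session and loop
#'   type). Empty groups are dropped with a warning.
#' @return data.frame with one row per group: `n`, mean and sd of the three
#'   quantities.
#' @export
group_summary <- function(results, by = c("session", "loop_type")) {
  if (!nrow(results)) stop("no results to summarize")
  missing_by <- setdiff(by, names(results))
  if (length(missing_by)) stop("unknown grouping columns: ",
                               paste(missing_by, collapse = ", "))
  g <- interaction(results[by], drop = FALSE, sep = ".")
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty)) warning("omitting empty groups: ", paste(empty, collapse = ", "))
  g <- droplevels(g)
  agg <- function(v, f) as.numeric(tapply(results[[v]], g, f))
  keys <- do.call(rbind, strsplit(levels(g), ".", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- by
  out$n <- as.integer(tapply(seq_along(g), g, length))
  for (v in c("p_joint_data", "p_joint_model", "dependency")) {
    out[[paste0(v, "_mean")]] <- agg(v, mean)
    out[[paste0(v, "_sd")]] <- agg(v, stats::sd)
  }
  rownames(out) <- NULL
  out
}
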