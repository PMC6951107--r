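#' Fit the retrieval-dependency model to trial-level data
#'
#' The main entry point of the package. For every participant x session x
#' loop-type cell, the fit builds the 6 x N response matrix, constructs the
#' six 2x2 contingency tables, and compares the observed proportion of joint
#' retrieval against the independence model derived from the participant's
#' own marginal accuracies. A positive dependency means associations from
#' the same event are retrieved (or lost) together - the signature of
#' holistic event representations.
#'
#' By convention the delayed-session analysis only uses events that were not
#' already tested at the immediate session, so retrieval-practice effects do
#' not contaminate the forgetting contrast; disable with
#' `t2_untested_only = FALSE`. Inference trials (never-encoded open-loop
#' associations) never enter the fit.
#'
#' @param data A `cohort` from [simulate_cohort()], or a trial-level
#'   data.frame in the schema of [read_trials()].
#' @param t2_untested_only Drop T2 events flagged `tested_at_T1` whenever the
#'   participant also has T1 trials (default `TRUE`).
#' @return An object of class `"retdep"`: list with `results` (one row per
#'   participant x session x loop type: `n_events`, `accuracy`,
#'   `p_joint_data`, `p_joint_model`, `dependency`), `details` (per-cell
#'   [dependency_for_participant()] breakdowns), `matrices` (the per-cell
#'   response matrices) and `call`.
#' @seealso [summary.retdep()], [simulate.retdep()] for the
#'   independent-forgetting model, [group_summary()].
#' @examples
#' co <- simulate_cohort(gen_params(n_participants = 4, seed = 1),
#'                       experiment_config(2, "closed"))
#' fit <- retdep(co)
#' summary(fit)
#' @export
retdep <- function(data, t2_untested_only = TRUE) {
  cl <- match.call()
  trials <- if (inherits(data, "cohort")) data$trials else as.data.frame(data)
  needed <- c("participant", "session", "triplet_id", "loop_type",
              "common_category", "trial_kind", "cue_role", "target_role",
              "tested_at_T1", "response")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trial data lack columns: ", paste(missing_cols, collapse = ", "))
  trials <- trials[trials$trial_kind == "direct", , drop = FALSE]
  if (t2_untested_only) {
    has_t1 <- unique(trials$participant[trials$session == "T1"])
    drop <- trials$session == "T2" & trials$tested_at_T1 &
      trials$participant %in% has_t1
    trials <- trials[!drop, , drop = FALSE]
  }
  mats <- trials_to_matrices(trials)
  rows <- list(); details <- list(); cell_mats <- list()
  for (nm in names(mats)) {
    m <- mats[[nm]]
    for (lt in intersect(c("closed", "open"), unique(m$events$loop_type))) {
      sub <- subset_loop(m, lt)
      dep <- dependency_for_participant(sub)
      key <- paste(m$participant, m$session, lt, sep = ".")
      cell_mats[[key]] <- sub
      details[[key]] <- dep
      rows[[key]] <- data.frame(
        participant = m$participant, session = m$session, loop_type = lt,
        n_events = ncol(sub$resp), accuracy = accuracy(sub),
        p_joint_data = dep$p_joint_data, p_joint_model = dep$p_joint_model,
        dependency = dep$dependency, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  results <- results[order(results$participant, results$session,
                           results$loop_type), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, details = details,
                 matrices = cell_mats, call = cl),
            class = "retdep")
}

#' @export
print.retdep <- function(x, ...) {
  cat("Retrieval-dependency fit:",
      length(unique(x$results$participant)), "participants,",
      nrow(x$results), "participant x session x loop cells\n")
  cat("Mean dependency by cell:\n")
  s <- group_summary(x$results)
  print(data.frame(s[c("session", "loop_type", "n")],
                   dependency = round(s$dependency_mean, 3)))
  cat("Use summary() for the full data-vs-model comparison.\n")
  invisible(x)
}

#' Summarize a retrieval-dependency fit
#'
#' Group means and standard deviations of the proportion of joint retrieval
#' (data and independence model) and dependency, by session and loop type,
#' with a one-sample t test of dependency against zero per cell.
#'
#' @param object A [retdep()] fit.
#' @param by Grouping columns of `object$results`.
#' @param ... Unused.
#' @return data.frame of class `"summary.retdep"`.
#' @export
summary.retdep <- function(object, by = c("session", "loop_type"), ...) {
  s <- group_summary(object$results, by = by)
  g <- interaction(object$results[by], drop = TRUE, sep = ".")
  key <- do.call(paste, c(s[by], sep = "."))
  tt <- lapply(key, function(k) {
    v <- object$results$dependency[as.character(g) == k]
    if (length(v) >= 2 && stats::sd(v) > 0) one_sample_t(v)
    else list(t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_)
  })
  s$t <- vapply(tt, `[[`, numeric(1), "t")
  s$df <- vapply(tt, `[[`, numeric(1), "df")
  s$p <- vapply(tt, `[[`, numeric(1), "p")
  class(s) <- c("summary.retdep", "data.frame")
  s
}

#' @export
print.summary.retdep <- function(x, digits = 3, ...) {
  cat("Proportion of joint retrieval (data vs. independence model)\n")
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.retdep <- function(object, ...) {
  stats::setNames(object$results$dependency,
                  paste(object$results$participant, object$results$session,
                        object$results$loop_type, sep = "."))
}

#' @export
fitted.retdep <- function(object, ...) {
  stats::setNames(object$results$p_joint_model,
                  paste(object$results$participant, object$results$session,
                        object$results$loop_type, sep = "."))
}

#' Residuals of a retrieval-dependency fit
#'
#' The data-minus-model differences, i.e. the per-cell dependency scores:
#' what remains after the independence model has accounted for marginal
#' accuracy.
#'
#' @param object A [retdep()] fit.
#' @param ... Unused.
#' @export
residuals.retdep <- function(object, ...) coef.retdep(object)

#' Plot dependency by session and loop type
#'
#' Bar plot of mean dependency with +/- 1 standard-error bars.
#'
#' @param x A [retdep()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.retdep <- function(x, ...) {
  s <- group_summary(x$results)
  se <- s$dependency_sd / sqrt(s$n)
  lab <- paste(s$loop_type, s$session)
  ylim <- range(0, s$dependency_mean + 1.5 * se, s$dependency_mean - 1.5 * se)
  mid <- graphics::barplot(s$dependency_mean, names.arg = lab,
                           ylab = "Dependency (data - independent model)",
                           ylim = ylim, ...)
  graphics::arrows(mid, s$dependency_mean - se, mid, s$dependency_mean + se,
                   angle = 90, code = 3, length = 0.05)
  graphics::abline(h = 0)
  invisible(s)
}

#' Simulate delayed-session dependency under independent forgetting
#'
#' For every participant with both an immediate (T1) and a delayed (T2)
#' closed-loop cell, runs the independent-forgetting model: the T1 response
#' matrix is degraded by random correct-to-incorrect conversions until its
#' accuracy matches the participant's observed T2 accuracy, and dependency
#' is recomputed on each simulated matrix (`nsim` per participant). This is
#' the model-based prediction of what delayed dependency should look like if
#' associations were forgotten independently; comparing it with the observed
#' T2 dependency is the package's core dissociation.
#'
#' @param object A [retdep()] fit.
#' @param nsim Simulated data sets per participant (default 100).
#' @param seed Integer master seed.
#' @param ... Unused.
#' @return data.frame of class `"retdep_sim"`, one row per participant:
#'   observed T1/T2 dependency, mean simulated T2 dependency and joint
#'   proportions, and the per-simulation flip count.
#' @export
simulate.retdep <- function(object, nsim = 100, seed = NULL, ...) {
  res <- object$results
  ok <- res$loop_type == "closed"
  parts <- intersect(res$participant[ok & res$session == "T1"],
                     res$participant[ok & res$session == "T2"])
  if (!length(parts))
    stop("independent-forgetting simulation needs closed-loop cells at both T1 and T2")
  master <- if (is.null(seed)) stats::runif(1, 1, 2^30) else seed
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[i]
    m1 <- object$matrices[[paste(p, "T1", "closed", sep = ".")]]
    target <- res$accuracy[res$participant == p & res$session == "T2" &
                             res$loop_type == "closed"]
    sim <- forgetting_model_dependency(m1, target, n_sims = nsim,
                                       seed = derive_seed(master, i))
    data.frame(participant = p,
               dependency_T1 = res$dependency[res$participant == p &
                                                res$session == "T1" & ok],
               dependency_T2 = res$dependency[res$participant == p &
                                                res$session == "T2" & ok],
               simulated_T2 = sim$mean_dependency,
               simulated_joint_data = mean(sim$sims$p_joint_data),
               simulated_joint_model = mean(sim$sims$p_joint_model),
               flips = sim$flips, target_accuracy = sim$target_accuracy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("retdep_sim", "data.frame")
  out
}
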