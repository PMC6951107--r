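## Synthetic behavioral cohorts. The generator makes the contrast between the
## two theoretical panels of the forgetting question explicit: events encoded
## holistically (one storage draw per closed-loop) versus as independent
## pairwise associations, and forgotten all-or-none (one survival draw per
## stored event) versus association-by-association.

#' Generative parameters for a synthetic cohort
#'
#' One parameter set per cohort. Defaults emulate the closed-loop accuracies
#' of the one-week-delay designs (about .74 correct immediately and .46 after
#' a week): a trace is stored with `p_store`, a stored trace yields a correct
#' response with `1 - lapse`, an absent trace is guessed at `p_guess` (1/6,
#' the six-alternative forced-choice floor), and a stored trace survives to
#' the delayed session with `survival_T2`.
#'
#' @param p_store Probability an event (holistic mode, closed-loops) or a
#'   pairwise association (independent mode, and open-loops always) is stored
#'   at encoding.
#' @param lapse Probability a stored trace still yields an incorrect response
#'   on a given retrieval trial.
#' @param p_guess Probability of a correct response without a trace.
#' @param survival_T2 Probability a stored trace survives to the delayed
#'   session.
#' @param encoding_mode `"holistic"`: one storage draw per closed-loop event,
#'   shared by its three associations. `"independent_associations"`: one draw
#'   per encoded pair. Open-loops always store per pair - they are not bound
#'   into a single representation.
#' @param forgetting_mode `"all_or_none"`: one survival draw per stored
#'   closed-loop event. `"association_independent"`: one draw per stored
#'   pair (fragmentation). Open-loop pairs always survive independently.
#' @param tested_boost Multiplier on `survival_T2` for triplets tested at T1
#'   (default 1: testing effect off). `survival_T2 * tested_boost` must not
#'   exceed 1.
#' @param n_participants Cohort size.
#' @param seed Master seed; per-participant streams are derived from it so
#'   any participant is reproducible in isolation.
#' @return A list of class `"gen_params"`.
#' @examples
#' gen_params(p_store = 0.72, survival_T2 = 0.5, n_participants = 26, seed = 1)
#' @export
gen_params <- function(p_store = 0.72, lapse = 0.03, p_guess = 1 / 6,
                       survival_T2 = 0.5,
                       encoding_mode = c("holistic", "independent_associations"),
                       forgetting_mode = c("all_or_none", "association_independent"),
                       tested_boost = 1, n_participants = 26L, seed = NULL) {
  encoding_mode <- match.arg(encoding_mode)
  forgetting_mode <- match.arg(forgetting_mode)
  probs <- c(p_store = p_store, lapse = lapse, p_guess = p_guess,
             survival_T2 = survival_T2)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (survival_T2 * tested_boost > 1)
    stop("survival_T2 * tested_boost must not exceed 1")
  if (n_participants < 1L) stop("n_participants must be >= 1")
  structure(list(p_store = p_store, lapse = lapse, p_guess = p_guess,
                 survival_T2 = survival_T2, encoding_mode = encoding_mode,
                 forgetting_mode = forgetting_mode, tested_boost = tested_boost,
                 n_participants = as.integer(n_participants), seed = seed),
            class = "gen_params")
}

#' @export
print.gen_params <- function(x, ...) {
  cat("Generative parameters:", x$encoding_mode, "encoding,",
      x$forgetting_mode, "forgetting\n",
      sprintf(" p_store = %.3f, lapse = %.3f, p_guess = %.3f, survival_T2 = %.3f, tested_boost = %.2f\n",
              x$p_store, x$lapse, x$p_guess, x$survival_T2, x$tested_boost),
      sprintf(" n_participants = %d, seed = %s\n", x$n_participants,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

## latent traces per (triplet, pair): storage at encoding and survival to T2
draw_traces <- function(params, triplets) {
  rows <- lapply(seq_len(nrow(triplets)), function(i) {
    t <- triplets[i, ]
    pairs <- if (t$loop_type == "closed") PAIRS else pairs_with_role(t$common_category)
    surv_p <- min(1, params$survival_T2 *
                    if (isTRUE(t$tested_at_T1)) params$tested_boost else 1)
    holistic_event <- t$loop_type == "closed" &&
      params$encoding_mode == "holistic"
    stored <- if (holistic_event) {
      rep(stats::runif(1) < params$p_store, length(pairs))
    } else {
      stats::runif(length(pairs)) < params$p_store
    }
    ## one survival draw for the whole event only where a unitary engram
    ## exists: a holistically stored closed-loop; independently stored pairs
    ## have nothing to lose all-or-none
    unit_survival <- holistic_event && params$forgetting_mode == "all_or_none"
    survives <- if (unit_survival) {
      rep(stats::runif(1) < surv_p, length(pairs)) & stored
    } else {
      (stats::runif(length(pairs)) < surv_p) & stored
    }
    data.frame(triplet_id = t$triplet_id, pair = pairs,
               stored = stored, survives = survives,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate one participant's retrieval outcomes
#'
#' Draws latent memory traces per event/association under the configured
#' encoding and forgetting regimes, then fills the given test schedules with
#' binary outcomes: a trial backed by a (surviving) trace is correct with
#' probability `1 - lapse`, otherwise correct with probability `p_guess`.
#' Both retrieval directions of a pair share its trace; guessing is
#' independent across trials. Inference trials (never-encoded pairs) have no
#' trace and respond at the guessing rate.
#'
#' @param params A [gen_params()] object.
#' @param triplets Output of [generate_triplets()].
#' @param schedules Named list of test schedules (`T1` optional, `T2`
#'   required), from [build_test_schedule()].
#' @param seed Integer seed for this participant.
#' @param participant Participant identifier carried into the output.
#' @return A list with `trials` (the schedules stacked, plus a `response`
#'   column) and `matrices` (a [response_matrix()] per session, direct
#'   trials only).
#' @export
simulate_participant <- function(params, triplets, schedules, seed = NULL,
                                 participant = "P001") {
  stopifnot(inherits(params, "gen_params"), "T2" %in% names(schedules))
  with_seed(seed, {
    traces <- draw_traces(params, triplets)
    key <- function(id, pair) paste(id, pair, sep = "|")
    stored <- survives <- logical(0)
    stored[key(traces$triplet_id, traces$pair)] <- traces$stored
    survives[key(traces$triplet_id, traces$pair)] <- traces$survives
    fill <- function(sch, session) {
      pair <- DIRECTIONS$pair[match(direction_id(sch$cue_role, sch$target_role),
                                    DIRECTIONS$id)]
      k <- key(sch$triplet_id, pair)
      trace <- if (session == "T1") stored[k] else survives[k]
      trace[is.na(trace) | sch$trial_kind == "inference"] <- FALSE
      p_correct <- ifelse(trace, 1 - params$lapse, params$p_guess)
      sch$response <- ifelse(stats::runif(nrow(sch)) < p_correct,
                             "correct", "incorrect")
      sch
    }
    sessions <- intersect(c("T1", "T2"), names(schedules))
    trials <- do.call(rbind, lapply(sessions, function(s) fill(schedules[[s]], s)))
    rownames(trials) <- NULL
    trials$participant <- participant
    mats <- trials_to_matrices(trials)
    names(mats) <- sub(paste0("^", participant, "\\."), "", names(mats))
    list(trials = trials, matrices = mats)
  })
}

#' Simulate a whole cohort
#'
#' Independent participants, each with their own randomized triplets and
#' schedules; per-participant seed streams are derived from the master seed
#' in [gen_params()], so any participant can be regenerated in isolation.
#'
#' @param params A [gen_params()] object (holds `n_participants` and `seed`).
#' @param config An [experiment_config()].
#' @return An object of class `"cohort"`: list with `params`, `config` and
#'   `trials`, a trial-level data.frame over all participants and sessions
#'   with columns `experiment, participant, session, block, trial_index,
#'   triplet_id, loop_type, common_category, trial_kind, cue_role,
#'   target_role, tested_at_T1, response`.
#' @examples
#' p <- gen_params(n_participants = 2, seed = 7)
#' co <- simulate_cohort(p, experiment_config(2, "closed"))
#' head(co$trials)
#' @export
simulate_cohort <- function(params, config) {
  stopifnot(inherits(params, "gen_params"), inherits(config, "experiment_config"))
  master <- if (is.null(params$seed)) stats::runif(1, 1, 2^30) else params$seed
  all_tr <- lapply(seq_len(params$n_participants), function(i) {
    s_design <- derive_seed(master, 4L * i)
    loop_design <- if (config$loop_design == "between") config$loop else "within"
    triplets <- generate_triplets(config$n_triplets, loop_design,
                                  seed = s_design,
                                  tested_fraction = if (config$t1_test) 0.5 else 0)
    schedules <- list()
    if (config$t1_test)
      schedules$T1 <- build_test_schedule(triplets, "T1", config,
                                          seed = derive_seed(master, 4L * i + 1L))
    schedules$T2 <- build_test_schedule(triplets, "T2", config,
                                        seed = derive_seed(master, 4L * i + 2L))
    sim <- simulate_participant(params, triplets, schedules,
                                seed = derive_seed(master, 4L * i + 3L),
                                participant = sprintf("P%03d", i))
    tt <- sim$trials
    tt$experiment <- config$experiment
    tt
  })
  trials <- do.call(rbind, all_tr)
  cols <- c("experiment", "participant", "session", "block", "trial_index",
            "triplet_id", "loop_type", "common_category", "trial_kind",
            "cue_role", "target_role", "tested_at_T1", "response")
  structure(list(params = params, config = config, trials = trials[, cols]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$params$n_participants, "participants,",
      "experiment", x$config$experiment, "design,",
      x$params$encoding_mode, "encoding /", x$params$forgetting_mode,
      "forgetting\n ", nrow(x$trials), "trials; accuracy by session:\n")
  acc <- tapply(x$trials$response == "correct", x$trials$session, mean)
  print(round(acc, 3))
  invisible(x)
}
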