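## The independent-forgetting model: degrade an immediate-test response
## matrix to the observed delayed accuracy by random correct->incorrect
## conversions, and ask what dependency survives. If associations from one
## event are forgotten independently, dependency should dilute; if events
## are lost all-or-none, it should not.

#' Simulate one delayed-session matrix under independent forgetting
#'
#' Converts correct entries of a closed-loop 6 x N response matrix to
#' incorrect, drawn uniformly without replacement, until the matrix-wide
#' accuracy is equated to `target_accuracy`. The default scheme flips an
#' exact count `k = round((acc_T1 - target_accuracy) * 6N)` (clamped to the
#' number of correct cells), so every correct cell is equally likely to be
#' forgotten; `method = "bernoulli"` instead flips each correct cell
#' independently with probability `(acc_T1 - target) / acc_T1`. Incorrect
#' cells are never flipped back - the model cannot create memories, so a
#' target above the observed T1 accuracy yields zero flips with a warning.
#'
#' @param x A closed-loop [response_matrix()] (all six directions
#'   administered for every event).
#' @param target_accuracy Observed delayed-session accuracy to match.
#' @param seed Integer seed.
#' @param method `"exact"` (default) or `"bernoulli"` (see above).
#' @return A `response_matrix` with the flips applied; attribute `"flips"`
#'   records the number of conversions.
#' @export
simulate_t2_matrix <- function(x, target_accuracy, seed = NULL,
                               method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "response_matrix"))
  if (any(x$events$loop_type != "closed") || anyNA(x$resp))
    stop("the independent-forgetting model applies to closed-loop matrices only")
  if (target_accuracy < 0 || target_accuracy > 1)
    stop("target_accuracy must lie in [0, 1]")
  acc <- accuracy(x)
  cells <- length(x$resp)
  correct <- which(x$resp == 1L)
  if (target_accuracy > acc) {
    warning("target accuracy exceeds T1 accuracy; no trials flipped ",
            "(the model only removes memories)")
    k <- 0L
  } else {
    k <- as.integer(round((acc - target_accuracy) * cells))
    k <- max(0L, min(k, length(correct)))
  }
  with_seed(seed, {
    resp <- x$resp
    if (method == "exact") {
      if (k > 0L) resp[sample(correct, k)] <- 0L
    } else {
      p_flip <- if (acc > 0) max(0, min(1, (acc - target_accuracy) / acc)) else 0
      flip <- correct[stats::runif(length(correct)) < p_flip]
      resp[flip] <- 0L
      k <- length(flip)
    }
    ## already validated: same events, entries only flipped 1 -> 0
    out <- structure(list(resp = resp, events = x$events,
                          participant = x$participant, session = "T2sim"),
                     class = "response_matrix")
    attr(out, "flips") <- k
    out
  })
}

#' Predicted delayed dependency under independent forgetting
#'
#' Runs [simulate_t2_matrix()] `n_sims` times and applies
#' [dependency_for_participant()] to every simulated matrix, recomputing the
#' independence model from each simulated matrix's own marginals. The mean
#' over simulations is the model's prediction of the participant's delayed
#' dependency if pairwise associations were forgotten independently of one
#' another.
#'
#' @inheritParams simulate_t2_matrix
#' @param n_sims Number of simulated data sets (100 in the standard
#'   analysis).
#' @return A list of class `"forgetting_sim"`: `sims` (per-simulation
#'   `dependency`, `p_joint_data`, `p_joint_model`, `accuracy`),
#'   `mean_dependency`, `flips`, `acc_T1` and `target_accuracy`.
#' @examples
#' co <- simulate_cohort(gen_params(n_participants = 1, seed = 3),
#'                       experiment_config(2, "closed"))
#' fit <- retdep(co)
#' m1 <- fit$matrices[["P001.T1.closed"]]
#' forgetting_model_dependency(m1, target_accuracy = 0.5, n_sims = 20, seed = 4)
#' @export
forgetting_model_dependency <- function(x, target_accuracy, n_sims = 100,
                                        seed = NULL,
                                        method = c("exact", "bernoulli")) {
  method <- match.arg(method)
  if (n_sims < 1L) stop("n_sims must be >= 1")
  master <- if (is.null(seed)) stats::runif(1, 1, 2^30) else seed
  dependency <- p_joint_data <- p_joint_model <- acc <- flips <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    m2 <- simulate_t2_matrix(x, target_accuracy,
                             seed = derive_seed(master, s), method = method)
    dep <- dependency_for_participant(m2)
    dependency[s] <- dep$dependency
    p_joint_data[s] <- dep$p_joint_data
    p_joint_model[s] <- dep$p_joint_model
    acc[s] <- accuracy(m2)
    flips[s] <- attr(m2, "flips")
  }
  sims <- data.frame(dependency = dependency, p_joint_data = p_joint_data,
                     p_joint_model = p_joint_model, accuracy = acc,
                     flips = flips)
  structure(list(sims = sims, n_sims = n_sims,
                 mean_dependency = mean(sims$dependency),
                 flips = sims$flips[1], acc_T1 = accuracy(x),
                 target_accuracy = target_accuracy),
            class = "forgetting_sim")
}

#' @export
print.forgetting_sim <- function(x, ...) {
  cat(sprintf(paste0("Independent-forgetting model: %d simulations, ",
                     "%d flips (accuracy %.3f -> target %.3f)\n"),
              x$n_sims, x$flips, x$acc_T1, x$target_accuracy))
  cat(sprintf("Mean simulated dependency: %.3f (sd %.3f)\n",
              x$mean_dependency, stats::sd(x$sims$dependency)))
  invisible(x)
}
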