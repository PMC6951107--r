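## Experimental design: triplet generation and the encoding/test trial
## schedules of the four cued-recognition experiments.

## pair presentation orders rotated across encoding blocks; for open-loops
## the order is forced by the common element (the two encoded pairs are the
## ones containing it, studied in the quoted order)
CLOSED_ROTATIONS <- list(
  c("location-person", "location-object", "person-object"),
  c("location-object", "person-object", "location-person"),
  c("person-object", "location-person", "location-object")
)
OPEN_ROTATIONS <- list(
  location = c("location-person", "location-object"),
  object   = c("location-object", "person-object"),
  person   = c("person-object", "location-person")
)

#' Generate location-person-object triplets
#'
#' Builds the per-participant stimulus structures: each triplet is one
#' location, one person and one object, assigned to the closed-loop condition
#' (all three pairwise associations encoded) or the open-loop condition (only
#' the two associations containing a designated common element encoded).
#' Element labels are synthetic (`location_01`, ...); no element is shared
#' between triplets.
#'
#' @param n Number of triplets (60 in the standard designs).
#' @param loop_design `"closed"` or `"open"` for a between-subjects cohort in
#'   which every triplet has that loop type; `"within"` for an equal split.
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @param pool_size Number of elements available per category (default `n`).
#' @param tested_fraction Fraction of triplets (stratified by loop type)
#'   flagged for testing at the immediate session T1. The standard designs
#'   test half immediately and reserve half for the delayed session only.
#' @return A data.frame with one row per triplet: `triplet_id`, `location`,
#'   `person`, `object`, `loop_type`, `common_category` (`NA` for
#'   closed-loops), `tested_at_T1`.
#' @examples
#' tr <- generate_triplets(60, "open", seed = 1)
#' table(tr$common_category)  # 20 per common element
#' @export
generate_triplets <- function(n, loop_design = c("closed", "open", "within"),
                              seed = NULL, pool_size = n,
                              tested_fraction = 0.5) {
  loop_design <- match.arg(loop_design)
  if (n < 1) stop("n must be >= 1")
  if (pool_size < n) stop("element pool exhausted: pool_size < n")
  if (loop_design == "within" && n %% 2L != 0L)
    stop("within designs need an even number of triplets")
  with_seed(seed, {
    pools <- lapply(ROLES, function(r)
      sample(sprintf("%s_%02d", r, seq_len(pool_size)), n))
    names(pools) <- ROLES
    tr <- data.frame(triplet_id = seq_len(n),
                     location = pools$location,
                     person = pools$person,
                     object = pools$object,
                     stringsAsFactors = FALSE)
    tr$loop_type <- switch(loop_design,
      closed = rep("closed", n),
      open   = rep("open", n),
      within = sample(rep(c("closed", "open"), each = n %/% 2L))
    )
    tr$common_category <- NA_character_
    open_idx <- which(tr$loop_type == "open")
    if (length(open_idx)) {
      ## balanced over the three possible common elements (round-robin over a
      ## shuffled role order when not divisible by 3)
      cats <- rep_len(sample(ROLES), length(open_idx))
      tr$common_category[sample(open_idx)] <- cats
    }
    tr$tested_at_T1 <- FALSE
    for (lt in unique(tr$loop_type)) {
      idx <- which(tr$loop_type == lt)
      k <- round(tested_fraction * length(idx))
      if (k > 0) tr$tested_at_T1[sample(idx, k)] <- TRUE
    }
    tr
  })
}

#' Configuration of one experimental design
#'
#' Fixed design parameters of the four experiments: loop manipulation
#' (between- or within-subject), number of triplets, whether an immediate
#' test (T1) is run, whether the open-loop cohort performs the delayed
#' inference test, and break spacing.
#'
#' @param experiment Integer 1-4.
#' @param loop For the between-subjects designs (Experiments 1 and 2), which
#'   cohort: `"closed"` or `"open"`. Ignored for within-subject designs.
#' @return A list of class `"experiment_config"`.
#' @examples
#' experiment_config(3)
#' @export
experiment_config <- function(experiment, loop = c("closed", "open")) {
  if (!experiment %in% 1:4) stop("unknown experiment id: ", experiment)
  loop <- match.arg(loop)
  between <- experiment %in% 1:2
  cfg <- list(
    experiment = as.integer(experiment),
    loop_design = if (between) "between" else "within",
    loop = if (between) loop else NA_character_,
    n_triplets = 60L,
    t1_test = experiment != 3L,
    inference_at_t2 = experiment == 1L && between && loop == "open",
    ## breaks every 30 trials, except every 25 at the Experiment-4 immediate test
    break_every = c(T1 = if (experiment == 4L) 25L else 30L, T2 = 30L),
    delay = if (experiment == 1L) "12h" else "1week"
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment", x$experiment, "design:",
      if (x$loop_design == "between") paste0("between-subjects (", x$loop, " cohort)")
      else "within-subject (30 closed + 30 open)",
      "\n  triplets:", x$n_triplets,
      "| T1 test:", x$t1_test,
      "| inference at T2:", x$inference_at_t2,
      "| delay:", x$delay, "\n")
  invisible(x)
}

## triplets consistent with a config?
check_triplets <- function(triplets, config) {
  if (config$loop_design == "between") {
    if (!all(triplets$loop_type == config$loop))
      stop("between-subjects config expects all triplets of loop type ", config$loop)
  }
  invisible(TRUE)
}

#' Build an encoding schedule
#'
#' Lays out the study phase: one pairwise association per trial, one pair from
#' each triplet per block, pair order rotated across blocks. Closed-loops
#' contribute three trials over three blocks, open-loops two trials over two
#' blocks (their non-encoded pair never appears). In the within-subject
#' designs (Experiments 3 and 4) the phase is three blocks of 30, 60 and 60
#' trials with the first block holding closed-loop associations only.
#' Within each block, presentation order is randomized.
#'
#' @param triplets Output of [generate_triplets()].
#' @param config An [experiment_config()].
#' @param seed Integer seed for rotation assignment and block shuffles.
#' @return A data.frame of encoding trials: `triplet_id`, `pair`, `block`,
#'   `position_in_block`, `trial_index`, `loop_type`, `common_category`.
#' @examples
#' tr <- generate_triplets(60, "closed", seed = 1)
#' nrow(build_encoding_schedule(tr, experiment_config(1), seed = 2))  # 180
#' @export
build_encoding_schedule <- function(triplets, config, seed = NULL) {
  check_triplets(triplets, config)
  with_seed(seed, {
    closed <- triplets[triplets$loop_type == "closed", , drop = FALSE]
    open <- triplets[triplets$loop_type == "open", , drop = FALSE]
    ## round-robin rotation assignment to shuffled closed triplets
    rot_of_closed <- integer(0)
    if (nrow(closed)) {
      ord <- sample(nrow(closed))
      rot_of_closed[ord] <- rep_len(1:3, nrow(closed))
    }
    pair_in_block <- function(i_closed, b) CLOSED_ROTATIONS[[rot_of_closed[i_closed]]][b]
    blocks <- list()
    if (config$loop_design == "between" || config$experiment %in% 1:2) {
      n_blocks <- if (config$loop == "closed") 3L else 2L
      for (b in seq_len(n_blocks)) {
        rows <- if (config$loop == "closed") {
          data.frame(triplet_id = closed$triplet_id,
                     pair = vapply(seq_len(nrow(closed)), pair_in_block, character(1), b = b),
                     stringsAsFactors = FALSE)
        } else {
          data.frame(triplet_id = open$triplet_id,
                     pair = vapply(open$common_category,
                                   function(cc) OPEN_ROTATIONS[[cc]][b], character(1)),
                     stringsAsFactors = FALSE)
        }
        blocks[[b]] <- rows
      }
    } else {
      ## Experiments 3/4: blocks of 30/60/60; block 1 closed-loops only, so the
      ## time between last exposure and the delayed test matches across loops
      open_pair <- function(b) vapply(open$common_category,
                                      function(cc) OPEN_ROTATIONS[[cc]][b], character(1))
      closed_pair <- function(b) vapply(seq_len(nrow(closed)), pair_in_block, character(1), b = b)
      blocks[[1]] <- data.frame(triplet_id = closed$triplet_id, pair = closed_pair(1),
                                stringsAsFactors = FALSE)
      for (b in 2:3) {
        blocks[[b]] <- rbind(
          data.frame(triplet_id = closed$triplet_id, pair = closed_pair(b),
                     stringsAsFactors = FALSE),
          data.frame(triplet_id = open$triplet_id, pair = open_pair(b - 1L),
                     stringsAsFactors = FALSE))
      }
    }
    out <- do.call(rbind, lapply(seq_along(blocks), function(b) {
      rows <- blocks[[b]][sample(nrow(blocks[[b]])), , drop = FALSE]
      rows$block <- b
      rows$position_in_block <- seq_len(nrow(rows))
      rows
    }))
    out$trial_index <- seq_len(nrow(out))
    m <- match(out$triplet_id, triplets$triplet_id)
    out$loop_type <- triplets$loop_type[m]
    out$common_category <- triplets$common_category[m]
    rownames(out) <- NULL
    out
  })
}

#' Build a test schedule
#'
#' Lays out one cued-recognition session: every encoded pairwise association
#' of every eligible triplet is tested in both directions exactly once.
#' T1 tests only triplets flagged `tested_at_T1`; T2 tests all triplets.
#' Closed-loops spread their six directions one per block over six blocks;
#' open-loops spread their four directions over four blocks (a random four
#' of the six in within-subject designs, so block sizes vary). For the
#' Experiment-1 open-loop cohort at T2, the inference test is appended: the
#' never-encoded association of each open-loop, in both directions, over two
#' further blocks (`trial_kind == "inference"`).
#'
#' @inheritParams build_encoding_schedule
#' @param session `"T1"` or `"T2"`.
#' @return A data.frame of test trials: `session`, `block`, `trial_index`,
#'   `position_in_block`, `triplet_id`, `loop_type`, `common_category`,
#'   `trial_kind`, `cue_role`, `target_role`, `tested_at_T1`.
#' @examples
#' tr <- generate_triplets(60, "within", seed = 1)
#' nrow(build_test_schedule(tr, "T2", experiment_config(3), seed = 2))  # 300
#' @export
build_test_schedule <- function(triplets, session = c("T1", "T2"), config,
                                seed = NULL) {
  session <- match.arg(session)
  check_triplets(triplets, config)
  if (session == "T1" && !config$t1_test)
    stop("experiment ", config$experiment, " has no immediate test session")
  with_seed(seed, {
    eligible <- if (session == "T1") triplets[triplets$tested_at_T1, , drop = FALSE]
                else triplets
    ## open-loop cohorts in the between designs use four test blocks
    pure_open <- config$loop_design == "between" && config$loop == "open"
    n_blocks <- if (pure_open) 4L else 6L
    rows <- lapply(seq_len(nrow(eligible)), function(i) {
      t <- eligible[i, ]
      pairs <- if (t$loop_type == "closed") PAIRS else pairs_with_role(t$common_category)
      dirs <- do.call(rbind, lapply(pairs, function(p) {
        r <- pair_roles(p)
        data.frame(cue_role = c(r[1], r[2]), target_role = c(r[2], r[1]),
                   stringsAsFactors = FALSE)
      }))
      ## one direction per block; open-loops draw 4 of the available blocks
      dirs$block <- if (nrow(dirs) == 6L) sample(n_blocks)
                    else sample(n_blocks, 4L)
      dirs$triplet_id <- t$triplet_id
      dirs
    })
    out <- do.call(rbind, rows)
    out$trial_kind <- "direct"
    if (session == "T2" && config$inference_at_t2) {
      inf <- build_inference_trials(eligible, n_blocks)
      out <- rbind(out, inf)
    }
    ## randomize within blocks, then index sequentially
    out <- out[order(out$block, sample(nrow(out))), , drop = FALSE]
    out$position_in_block <- stats::ave(seq_len(nrow(out)), out$block, FUN = seq_along)
    out$trial_index <- seq_len(nrow(out))
    m <- match(out$triplet_id, triplets$triplet_id)
    out$loop_type <- triplets$loop_type[m]
    out$common_category <- triplets$common_category[m]
    out$tested_at_T1 <- triplets$tested_at_T1[m]
    out$session <- session
    rownames(out) <- NULL
    out[, c("session", "block", "trial_index", "position_in_block",
            "triplet_id", "loop_type", "common_category", "trial_kind",
            "cue_role", "target_role", "tested_at_T1")]
  })
}

## both directions of the never-encoded pair, over two blocks appended after
## the main task
build_inference_trials <- function(triplets, first_block) {
  if (any(triplets$loop_type == "closed"))
    stop("inference trials are only defined for open-loops")
  rows <- lapply(seq_len(nrow(triplets)), function(i) {
    t <- triplets[i, ]
    r <- pair_roles(pair_without_role(t$common_category))
    b <- sample(2L)
    data.frame(cue_role = c(r[1], r[2]), target_role = c(r[2], r[1]),
               block = first_block + b, triplet_id = t$triplet_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$trial_kind <- "inference"
  out[, c("cue_role", "target_role", "block", "triplet_id", "trial_kind")]
}

#' Response options for one six-alternative forced-choice trial
#'
#' One correct target plus five foils drawn from other triplets' elements of
#' the same category, with the target's slot uniform over the six positions.
#'
#' @param trial A single test-trial row (needs `triplet_id` and `target_role`).
#' @param triplets The triplet table the trial was built from.
#' @param seed Integer seed.
#' @return A list with `options` (character vector of 6), `target`, and
#'   `target_position`.
#' @examples
#' tr <- generate_triplets(60, "closed", seed = 1)
#' sch <- build_test_schedule(tr, "T2", experiment_config(1), seed = 2)
#' foil_set(sch[1, ], tr, seed = 3)
#' @export
foil_set <- function(trial, triplets, seed = NULL) {
  role <- trial$target_role
  target <- triplets[[role]][triplets$triplet_id == trial$triplet_id]
  pool <- triplets[[role]][triplets$triplet_id != trial$triplet_id]
  if (length(pool) < 5L) stop("fewer than 5 eligible foils in category ", role)
  with_seed(seed, {
    foils <- sample(pool, 5L)
    pos <- sample(6L, 1L)
    options <- append(foils, target, after = pos - 1L)
    list(options = options, target = target, target_position = pos)
  })
}
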