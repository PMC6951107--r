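## The 6 x N response matrix: rows are the six cue->target directions,
## columns are events; entries 1 (correct), 0 (incorrect), NA (direction not
## administered, e.g. the two directions of an open-loop's never-encoded pair).

#' Construct a response matrix
#'
#' The per-participant, per-session container for binary retrieval outcomes:
#' a 6 x N matrix with one row per retrieval direction (`location>person`,
#' `location>object`, `person>location`, `person>object`, `object>location`,
#' `object>person`) and one column per event, plus event metadata. Closed-loop
#' events carry all six entries; open-loop events carry exactly the four
#' directions involving their common element.
#'
#' @param resp 6 x N matrix of 1/0/NA, rows in the canonical direction order.
#' @param events data.frame with one row per column of `resp`: `triplet_id`,
#'   `loop_type`, `common_category`, `tested_at_T1`.
#' @param participant Participant identifier.
#' @param session `"T1"` or `"T2"`.
#' @return An object of class `"response_matrix"`.
#' @export
response_matrix <- function(resp, events, participant = NA, session = NA) {
  stopifnot(is.matrix(resp), nrow(resp) == 6L, ncol(resp) == nrow(events))
  rownames(resp) <- DIRECTIONS$id
  for (j in seq_len(ncol(resp))) {
    adm <- unname(which(!is.na(resp[, j])))
    if (events$loop_type[j] == "closed") {
      if (length(adm) != 6L)
        stop("closed-loop event ", events$triplet_id[j],
             " must administer all 6 directions")
    } else {
      want <- which(DIRECTIONS$cue == events$common_category[j] |
                    DIRECTIONS$target == events$common_category[j])
      if (!identical(sort(adm), sort(want)))
        stop("open-loop event ", events$triplet_id[j],
             " must administer exactly the 4 directions involving its common element")
    }
  }
  structure(list(resp = resp, events = events,
                 participant = participant, session = session),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: participant", x$participant, "session", x$session,
      "-", ncol(x$resp), "events (",
      sum(x$events$loop_type == "closed"), "closed /",
      sum(x$events$loop_type == "open"), "open ), accuracy",
      sprintf("%.3f", accuracy(x)), "\n")
  invisible(x)
}

#' Mean accuracy of a response matrix
#'
#' Proportion correct over all administered entries.
#'
#' @param x A [response_matrix()].
#' @return A proportion in `[0, 1]`.
#' @export
accuracy <- function(x) mean(x$resp, na.rm = TRUE)

#' Marginal accuracies of the six retrieval directions
#'
#' For each direction, the proportion correct over the events administering
#' it: the quantities the independence model is built from.
#'
#' @param x A [response_matrix()].
#' @return Named numeric vector of length 6 (NaN for directions never
#'   administered).
#' @export
marginal_accuracies <- function(x) {
  p <- rowMeans(x$resp, na.rm = TRUE)
  names(p) <- DIRECTIONS$id
  p
}

#' Build response matrices from trial-level records
#'
#' Collapses trial records (one row per retrieval trial, see [read_trials()]
#' for the schema) into one [response_matrix()] per participant x session.
#' Only direct retrieval trials enter (`trial_kind == "inference"` rows are
#' dropped: never-encoded associations have no place in the dependency
#' analysis).
#'
#' @param trials Trial-level data.frame with a `response` column coded
#'   `"correct"`/`"incorrect"` (or 1/0).
#' @return A list of `response_matrix` objects named `<participant>.<session>`.
#' @export
trials_to_matrices <- function(trials) {
  trials <- trials[trials$trial_kind == "direct", , drop = FALSE]
  if (!nrow(trials)) stop("no direct retrieval trials")
  correct <- if (is.numeric(trials$response)) trials$response
             else as.integer(trials$response == "correct")
  trials$..correct <- correct
  keys <- interaction(trials$participant, trials$session, drop = TRUE, sep = ".")
  out <- lapply(split(trials, keys), function(tt) {
    ids <- sort(unique(tt$triplet_id))
    resp <- matrix(NA_integer_, 6L, length(ids), dimnames = list(DIRECTIONS$id, NULL))
    j <- match(tt$triplet_id, ids)
    i <- match(direction_id(tt$cue_role, tt$target_role), DIRECTIONS$id)
    if (anyNA(i)) stop("invalid cue/target role combination in trials")
    if (anyDuplicated(cbind(i, j)))
      stop("duplicate (event, direction) trials within one session")
    resp[cbind(i, j)] <- tt$..correct
    first <- !duplicated(tt$triplet_id)
    ev <- data.frame(triplet_id = tt$triplet_id[first],
                     loop_type = tt$loop_type[first],
                     common_category = tt$common_category[first],
                     tested_at_T1 = tt$tested_at_T1[first],
                     stringsAsFactors = FALSE)
    ev <- ev[match(ids, ev$triplet_id), , drop = FALSE]
    rownames(ev) <- NULL
    response_matrix(resp, ev, participant = tt$participant[1], session = tt$session[1])
  })
  out
}

## subset a response matrix to events of one loop type
subset_loop <- function(x, loop_type) {
  keep <- x$events$loop_type == loop_type
  if (!any(keep)) return(NULL)
  response_matrix(x$resp[, keep, drop = FALSE],
                  x$events[keep, , drop = FALSE],
                  participant = x$participant, session = x$session)
}
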