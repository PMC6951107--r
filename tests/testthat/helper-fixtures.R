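# Fixture builders used across test files; everything is generated in code.

# a closed-loop response matrix from explicit 6 x N entries
make_closed_matrix <- function(resp, participant = "P001", session = "T1") {
  n <- ncol(resp)
  events <- data.frame(triplet_id = seq_len(n),
                       loop_type = "closed",
                       common_category = NA_character_,
                       tested_at_T1 = FALSE,
                       stringsAsFactors = FALSE)
  response_matrix(resp, events, participant = participant, session = session)
}

# a matrix whose events are all-correct, all-incorrect, or a fixed mixed
# pattern discordant on every one of the six table specs
make_ternary_matrix <- function(n_allcorrect, n_allwrong, n_mixed) {
  mixed <- c(1L, 0L, 0L, 1L, 1L, 0L)
  resp <- cbind(
    matrix(1L, 6, n_allcorrect),
    matrix(0L, 6, n_allwrong),
    matrix(rep(mixed, n_mixed), 6)
  )
  make_closed_matrix(resp)
}

# one open-loop event with a given common element
make_open_matrix <- function(common = "location", values = c(1L, 1L, 1L, 1L)) {
  dirs <- loopdep::table_specs()
  adm <- which(DIRECTIONS_ids_cue() == common | DIRECTIONS_ids_target() == common)
  resp <- matrix(NA_integer_, 6, 1)
  resp[adm, 1] <- values
  events <- data.frame(triplet_id = 1L, loop_type = "open",
                       common_category = common, tested_at_T1 = FALSE,
                       stringsAsFactors = FALSE)
  response_matrix(resp, events)
}

DIRECTIONS_ids_cue <- function() {
  c("location", "location", "person", "person", "object", "object")
}
DIRECTIONS_ids_target <- function() {
  c("person", "object", "location", "object", "location", "person")
}

small_cohort <- function(n = 6, seed = 11, experiment = 2, loop = "closed", ...) {
  simulate_cohort(gen_params(n_participants = n, seed = seed, ...),
                  experiment_config(experiment, loop))
}
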