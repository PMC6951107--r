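#' @keywords internal
"_PACKAGE"

## Element categories, undirected pairs and the six ordered retrieval
## directions used throughout. Order is fixed so that response matrices are
## always 6 x N with the same row layout.

ROLES <- c("location", "person", "object")

## undirected encoded pairs, canonical role order
PAIRS <- c("location-person", "location-object", "person-object")

## the six cue -> target directions (rows of a response matrix)
DIRECTIONS <- data.frame(
  cue    = c("location", "location", "person", "person", "object", "object"),
  target = c("person", "object", "location", "object", "location", "person"),
  stringsAsFactors = FALSE
)
DIRECTIONS$id   <- paste0(DIRECTIONS$cue, ">", DIRECTIONS$target)
DIRECTIONS$pair <- vapply(seq_len(6), function(i) {
  r <- sort(match(c(DIRECTIONS$cue[i], DIRECTIONS$target[i]), ROLES))
  paste(ROLES[r], collapse = "-")
}, character(1))

direction_id <- function(cue, target) paste0(cue, ">", target)

## roles making up an undirected pair
pair_roles <- function(pair) strsplit(pair, "-", fixed = TRUE)[[1]]

## the two pairs of an open-loop with a given common element
pairs_with_role <- function(role) PAIRS[vapply(PAIRS, function(p) role %in% pair_roles(p), logical(1))]

## the pair not containing the common element (the never-encoded association)
pair_without_role <- function(role) PAIRS[!PAIRS %in% pairs_with_role(role)]

#' The six contingency-table specifications
#'
#' Dependency is assessed over six 2x2 contingency tables per participant:
#' for each element category X, one table cross-classifies the two retrievals
#' *cued by* X (cue-common) and one the two retrievals *of* X when cued by
#' the other two elements (target-common).
#'
#' @return A data.frame with one row per specification and columns
#'   `common` (the shared element category), `orientation`
#'   (`"cue_common"` or `"target_common"`), and `dir1`/`dir2`, the ids of the
#'   two retrieval directions the table cross-classifies.
#' @examples
#' table_specs()
#' @export
table_specs <- function() .TABLE_SPECS

build_table_specs <- function() {
  out <- do.call(rbind, lapply(ROLES, function(x) {
    others <- setdiff(ROLES, x)
    rbind(
      data.frame(common = x, orientation = "cue_common",
                 dir1 = direction_id(x, others[1]),
                 dir2 = direction_id(x, others[2]),
                 stringsAsFactors = FALSE),
      data.frame(common = x, orientation = "target_common",
                 dir1 = direction_id(others[1], x),
                 dir2 = direction_id(others[2], x),
                 stringsAsFactors = FALSE)
    )
  }))
  rownames(out) <- paste(out$orientation, out$common, sep = ".")
  out
}

.TABLE_SPECS <- build_table_specs()

## run code under a temporary RNG state seeded with `seed`; restores the
## caller's RNG afterwards so schedules are reproducible in isolation
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

## derive a per-unit seed from a master seed; keeps results < 2^31 and
## reproducible for any unit in isolation
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + 7919 * as.double(index)) %% 2147483647)
}
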