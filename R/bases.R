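#' @keywords internal
"_PACKAGE"

## Channel/base convention used throughout: index 1..4 = A, C, G, T.
## Trellis states are ordered base pairs (first, second) enumerated
## AA, AC, AG, AT, CA, ..., TT, i.e. state = 4 * (first - 1) + second.

BASES <- c("A", "C", "G", "T")

#' Base letters in channel order
#'
#' The four nucleotides in the fixed channel order A, C, G, T used by every
#' intensity matrix, crosstalk matrix and posterior table in the package.
#'
#' @return Character vector `c("A","C","G","T")`.
#' @export
base_letters <- function() BASES

#' Trellis state index for an ordered base pair
#'
#' States of the decoding trellis are ordered pairs of bases: the state at
#' stage `i` holds the template bases at positions `i` and `i + 1`. The 16
#' states are enumerated AA, AC, AG, AT, CA, ..., TT.
#'
#' @param first,second Integer base indices in 1..4 (A, C, G, T), vectorized.
#' @return Integer state indices in 1..16.
#' @seealso [state_first()], [state_second()], [state_labels()]
#' @export
#' @examples
#' state_index(1, 2)          # AC
#' state_labels()[state_index(4, 4)]  # "TT"
state_index <- function(first, second) {
  stopifnot(all(first %in% 1:4), all(second %in% 1:4))
  4L * (as.integer(first) - 1L) + as.integer(second)
}

#' First base of a trellis state
#' @param state Integer state indices in 1..16.
#' @return Integer base indices in 1..4.
#' @export
state_first <- function(state) (as.integer(state) - 1L) %/% 4L + 1L

#' Second base of a trellis state
#' @param state Integer state indices in 1..16.
#' @return Integer base indices in 1..4.
#' @export
state_second <- function(state) (as.integer(state) - 1L) %% 4L + 1L

#' Labels of the 16 trellis states
#' @return Character vector "AA", "AC", ..., "TT".
#' @export
state_labels <- function() {
  paste0(BASES[state_first(1:16)], BASES[state_second(1:16)])
}

#' Valid-transition mask of the trellis
#'
#' A transition from state `s` at stage `i` to state `t` at stage `i + 1` is
#' valid iff the second base of `s` equals the first base of `t` (the two
#' states overlap in the shared template position). Every state has exactly
#' four valid successors and four valid predecessors.
#'
#' @return 16 x 16 logical matrix; entry `[s, t]` is `TRUE` for valid `s -> t`.
#' @export
transition_mask <- function() {
  outer(state_second(1:16), state_first(1:16), `==`)
}

## map a base-index vector (a template) to the stage state path along it
seq_to_states <- function(base_idx) {
  n <- length(base_idx)
  stopifnot(n >= 2)
  state_index(base_idx[-n], base_idx[-1])
}

## string <-> integer codes
dna_to_idx <- function(s) {
  idx <- match(strsplit(toupper(s), "")[[1]], BASES)
  if (anyNA(idx)) stop("sequence contains letters outside A/C/G/T")
  idx
}

idx_to_dna <- function(idx) paste(BASES[idx], collapse = "")
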