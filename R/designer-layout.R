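#' Reverse complement of DNA sequences
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

domainPattern <- function(bp_per_turn) {
  # one domain = half a helical turn; four consecutive domains span two
  # full turns, so their lengths must sum to 2 * bp_per_turn nucleotides
  switch(sprintf("%.1f", bp_per_turn),
         "10.0" = c(5L, 5L, 5L, 5L),
         "10.5" = c(5L, 5L, 5L, 6L),
         "11.0" = c(5L, 6L, 5L, 6L),
         "11.5" = c(5L, 6L, 6L, 6L),
         "12.0" = c(6L, 6L, 6L, 6L),
         NULL)
}

#' Generate a half-turn domain layout
#'
#' Deterministic layout of 2n domain lengths (5 or 6 nt) such that every
#' window of four consecutive domains sums to \code{2 * bp_per_turn}
#' nucleotides: 21 nt at 10.5 bp/turn (repeating 5,5,5,6), 22 nt at
#' 11.0 bp/turn (alternating 5,6).  \code{phase} rotates the repeating
#' pattern, which changes the ribbon's mechanics but not the window sums.
#'
#' @param n half coordination number (the slat carries 2n domains).
#' @param bp_per_turn base pairs per helical turn; must admit an integer
#'   two-turn sum with 5/6-nt domains (10, 10.5, 11, 11.5 or 12).
#' @param phase integer rotation of the domain pattern (default 0,
#'   canonical).
#' @return a [DomainLayout-class].
#' @examples
#' domainLayout(6, 10.5)   # v6: 12 domains, 63 nt core
#' domainLayout(8, 11.0)   # v8 underwound variant: 16 domains, 88 nt
#' @export
domainLayout <- function(n, bp_per_turn = 10.5, phase = 0L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  pat <- domainPattern(bp_per_turn)
  if (is.null(pat))
    stop(sprintf(
      "bp_per_turn %.2f is unattainable with 5/6-nt half-turn domains",
      bp_per_turn))
  pat <- pat[((seq_along(pat) - 1L + as.integer(phase)) %% 4L) + 1L]
  lengths <- rep_len(pat, 2L * n)
  new("DomainLayout", n = n, bpPerTurn = bp_per_turn, lengths = lengths,
      phase = as.integer(phase) %% 4L)
}

#' Twist summary of a layout
#'
#' Reports winding relative to the relaxed 10.5 bp/turn and the qualitative
#' coil class of the resulting ribbon: the canonical 10.5 layout gives flat
#' ribbons, a phase-shifted 10.5 pattern gives loosely coiled ribbons, and
#' underwinding to 11.0 bp/turn gives tightly coiled ribbons (which close
#' into constant-diameter tubes when sticky ends are added).
#'
#' @param layout a [DomainLayout-class].
#' @return list with \code{bp_per_turn}, \code{winding} ("relaxed",
#'   "underwound", "overwound"), \code{delta_bp_per_turn} and
#'   \code{coil_class} ("flat", "loose-coil", "tight-coil").
#' @export
twistReport <- function(layout) {
  stopifnot(is(layout, "DomainLayout"))
  d <- layout@bpPerTurn - 10.5
  winding <- if (d == 0) "relaxed" else if (d > 0) "underwound" else "overwound"
  coil <- if (layout@bpPerTurn > 10.5) "tight-coil"
          else if (layout@bpPerTurn < 10.5) "tight-coil"
          else if (layout@phase != 0L) "loose-coil"
          else "flat"
  list(bp_per_turn = layout@bpPerTurn, winding = winding,
       delta_bp_per_turn = d, coil_class = coil)
}
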