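#' Build a slat blueprint (crossing map, sequences unassigned)
#'
#' Constructs the full slat set for a crisscross ribbon: 2n nucleating
#' y-slats plus the periodic repeat of x- and y-slat roles.  The slat at
#' position i of the x layer crosses the 2n y-slats at positions
#' \code{i .. i + 2n - 1}; at the crossing, domain \code{d = j - i} of the
#' x-slat pairs with domain \code{2n - 1 - d} of the y-slat, so each binding
#' domain has exactly one conjugate (the crossing map is a bijection).
#' Sequence identity is periodic with the repeat-unit size set by the
#' symmetry mode: \code{"full"} uses 2n distinct x and 2n distinct y roles,
#' \code{"n_pairs"} n of each, \code{"half_n_pairs"} n/2 (even n only).
#'
#' Nucleating y-slats are chimeras: their ribbon-proximal half carries the
#' same domains as the corresponding periodic y role (so the first x-slats
#' bind them seamlessly) while the other half presents unique seed-handle
#' domains, the sites through which a DNA-origami (or folded ssDNA-genome)
#' seed pre-pays the nucleation barrier.
#'
#' @param layout a [DomainLayout-class].
#' @param symmetry_mode repeat symmetry, see Details.
#' @return a [SlatBlueprint-class] without sequences.
#' @examples
#' bp <- buildBlueprint(domainLayout(6, 10.5), "full")
#' length(nucYSlats(bp))  # 12
#' @export
buildBlueprint <- function(layout,
                           symmetry_mode = c("full", "n_pairs",
                                             "half_n_pairs")) {
  symmetry_mode <- match.arg(symmetry_mode)
  n <- layout@n
  w <- 2L * n
  u <- switch(symmetry_mode,
              full = w, n_pairs = n,
              half_n_pairs = {
                if (n %% 2L != 0L)
                  stop("half_n_pairs symmetry requires an even n")
                n %/% 2L
              })
  lenX <- layout@lengths              # x-slat domain lengths, 5' -> 3'
  lenY <- rev(layout@lengths)         # y layout is the reverse

  roleName <- function(class, r) sprintf("%s%02d", class, r)
  slats <- rbind(
    data.frame(name = vapply(0:(w - 1L), roleName, "", class = "nucY"),
               class = "nuc_y", role = 0:(w - 1L),
               threading = "crossover-every-half-turn",
               stringsAsFactors = FALSE),
    data.frame(name = vapply(0:(u - 1L), roleName, "", class = "x"),
               class = "x", role = 0:(u - 1L),
               threading = "no-crossover",
               stringsAsFactors = FALSE),
    data.frame(name = vapply(0:(u - 1L), roleName, "", class = "y"),
               class = "y", role = 0:(u - 1L),
               threading = "crossover-every-half-turn",
               stringsAsFactors = FALSE))

  rows <- list()
  for (a in 0:(u - 1L)) {             # x roles
    d <- 0:(w - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      slat = roleName("x", a), class = "x", role = a, domain = d,
      length = lenX[d + 1L],
      partner_class = "y", partner_role = (a + d) %% u,
      partner_domain = w - 1L - d, stringsAsFactors = FALSE)
  }
  for (b in 0:(u - 1L)) {             # y roles
    k <- 0:(w - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      slat = roleName("y", b), class = "y", role = b, domain = k,
      length = lenY[k + 1L],
      partner_class = "x", partner_role = (b - (w - 1L - k)) %% u,
      partner_domain = w - 1L - k, stringsAsFactors = FALSE)
  }
  for (j in 0:(w - 1L)) {             # nucleating y-slats
    k <- 0:(w - 1L)
    seedHalf <- k < n
    rows[[length(rows) + 1L]] <- data.frame(
      slat = roleName("nucY", j), class = "nuc_y", role = j, domain = k,
      length = lenY[k + 1L],
      partner_class = ifelse(seedHalf, "seed", "x"),
      partner_role = ifelse(seedHalf, NA_integer_,
                            (j - (w - 1L - k)) %% u),
      partner_domain = ifelse(seedHalf, NA_integer_, w - 1L - k),
      stringsAsFactors = FALSE)
  }
  domains <- do.call(rbind, rows)
  new("SlatBlueprint", layout = layout, symmetryMode = symmetry_mode,
      period = u, slats = slats, domains = domains,
      sequences = character(), decorations = list())
}

## orthogonal domain pools -----------------------------------------------
##
## Binding domains are drawn from a GF(4) single-parity-check code (all
## words whose base values A=0, C=1, G=2, T=3 sum to a fixed residue mod
## 4): any two distinct codewords differ at >= 2 positions, so the
## Hamming-distance floor of 2 holds by construction.  Seed-handle domains
## use a different residue class (a coset), orthogonal among themselves.

parityPool <- function(len, residue = 0L, gc_window = c(0.3, 0.7),
                       max_homopolymer = 4L) {
  b <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(b), len), stringsAsFactors = FALSE))
  seqs <- do.call(paste0, grid)
  val <- rowSums(vapply(grid, function(col) match(col, b) - 1L,
                        integer(length(seqs))))
  gc <- rowSums(vapply(grid, function(col) col %in% c("G", "C"),
                       logical(length(seqs))))
  lo <- ceiling(gc_window[1] * len)
  hi <- floor(gc_window[2] * len)
  k <- max_homopolymer + 1L
  pat <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", k, k, k, k)
  keep <- (val %% 4L == residue) & gc >= lo & gc <= hi & !grepl(pat, seqs)
  seqs[keep]
}

greedyPool <- function(len, size, min_hamming, gc_window, max_homopolymer,
                       max_tries = 20000L) {
  b <- c("A", "C", "G", "T")
  k <- max_homopolymer + 1L
  pat <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", k, k, k, k)
  lo <- ceiling(gc_window[1] * len); hi <- floor(gc_window[2] * len)
  pool <- character(); mat <- NULL
  for (i in seq_len(max_tries)) {
    cand <- sample(b, len, replace = TRUE)
    s <- paste0(cand, collapse = "")
    gc <- sum(cand %in% c("G", "C"))
    if (gc < lo || gc > hi || grepl(pat, s)) next
    if (!is.null(mat) &&
        any(colSums(mat != cand) < min_hamming)) next
    pool <- c(pool, s)
    mat <- cbind(mat, cand)
    if (length(pool) >= size) return(pool)
  }
  stop(sprintf(
    "could not assemble %d orthogonal %d-mers at Hamming >= %d ",
    size, len, min_hamming),
    sprintf("(got %d after %d tries); relax the constraints",
            length(pool), max_tries))
}
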