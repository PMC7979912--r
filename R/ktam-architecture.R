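#' Build a monomer architecture
#'
#' Constructs the bond-topology model used by the kTAM landscape machinery.
#' Square tiles (\code{"ST"}) and hexagonal tiles (\code{"HT"}) live on
#' periodic square / triangular lattices wrapped into a tube of the given
#' circumference; crisscross slats (\code{"CS"}) form a non-periodic ribbon
#' in which the slat at position \code{i} of one layer crosses the 2n slats
#' at positions \code{i .. i + 2n - 1} of the perpendicular layer.
#'
#' @param kind \code{"ST"}, \code{"HT"} or \code{"CS"}.
#' @param n half coordination number (required for CS; implied for tiles:
#'   2 for ST, 3 for HT).
#' @param circumference tube circumference in tiles (ST/HT only).  A
#'   circumference of 1 is the degenerate single-helix chain and is accepted
#'   with a warning.
#' @return an [Architecture-class] object.
#' @examples
#' architecture("CS", n = 6)             # slat with 12 binding sites
#' architecture("ST", circumference = 8)
#' @export
architecture <- function(kind = c("CS", "ST", "HT"), n = NULL,
                         circumference = NULL) {
  kind <- match.arg(kind)
  if (kind == "ST") n <- 2L
  if (kind == "HT") n <- 3L
  if (is.null(n)) stop("CS architectures need a half coordination number n")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (kind %in% c("ST", "HT")) {
    if (is.null(circumference))
      stop(kind, " architectures need a tube circumference")
    circumference <- as.integer(circumference)
    if (is.na(circumference) || circumference < 1L)
      stop("circumference must be a positive integer")
    if (circumference == 1L)
      warning("circumference 1 is a degenerate single-wide chain")
    new("Architecture", kind = kind, n = n, circumference = circumference,
        width = 2L * n)
  } else {
    if (!is.null(circumference))
      stop("CS ribbons are non-periodic in width; do not give a circumference")
    new("Architecture", kind = "CS", n = n, circumference = NA_integer_,
        width = 2L * n)
  }
}

## ---- assembly states --------------------------------------------------
##
## CS state: list(y = sorted integer positions, x = sorted integer positions)
## Tile state: integer matrix with columns (u, v); u wraps modulo the
## circumference.  Placements: list(axis = "y"/"x", pos = j) for CS,
## c(u, v) for tiles.

#' Empty assembly for an architecture
#' @param arch an [Architecture-class].
#' @return an empty assembly state.
#' @export
newAssembly <- function(arch) {
  if (arch@kind == "CS") list(y = integer(), x = integer())
  else matrix(integer(), ncol = 2, dimnames = list(NULL, c("u", "v")))
}

#' @rdname newAssembly
#' @param assembly an assembly state.
#' @export
assemblySize <- function(assembly) {
  if (is.list(assembly)) length(assembly$y) + length(assembly$x)
  else nrow(assembly)
}

tileOffsets <- function(kind) {
  if (kind == "ST")
    cbind(u = c(1L, -1L, 0L, 0L), v = c(0L, 0L, 1L, -1L))
  else  # triangular lattice, axial coordinates
    cbind(u = c(1L, -1L, 0L, 0L, 1L, -1L), v = c(0L, 0L, 1L, -1L, -1L, 1L))
}

tileKey <- function(cells) paste(cells[, 1], cells[, 2], sep = ",")

# Tile bond counting must keep multi-edges on narrow tubes
# (circumference 2: both lateral neighbours are the same cell => 2 bonds).
attachmentBondsTile <- function(arch, assembly, placement) {
  m <- arch@circumference
  off <- tileOffsets(arch@kind)
  nb <- cbind((placement[1] + off[, 1]) %% m, placement[2] + off[, 2])
  self <- nb[, 1] == placement[1] %% m & nb[, 2] == placement[2]
  nb <- nb[!self, , drop = FALSE]
  if (!nrow(assembly)) return(0L)
  occ <- tileKey(assembly)
  sum(paste(nb[, 1], nb[, 2], sep = ",") %in% occ)
}

#' Total bond count of an assembly
#'
#' Recomputed from scratch by enumerating all satisfied binding-site pairs;
#' the incremental bookkeeping of the landscape search is tested against
#' this.  A complete CS n-by-n junction has exactly n^2 bonds.
#'
#' @inheritParams attachmentBonds
#' @return integer total bond count B.
#' @export
assemblyBonds <- function(arch, assembly) {
  if (arch@kind == "CS") {
    w <- arch@width
    if (!length(assembly$y) || !length(assembly$x)) return(0L)
    d <- outer(assembly$y, assembly$x, "-")
    sum(d >= 0L & d < w)
  } else {
    if (nrow(assembly) < 2L) return(0L)
    b <- 0L
    for (i in seq_len(nrow(assembly))) {
      others <- assembly[-seq_len(i), , drop = FALSE]
      if (nrow(others))
        b <- b + attachmentBondsTile(arch, others,
                                     c(assembly[i, 1], assembly[i, 2]))
    }
    b
  }
}

#' @rdname attachmentBonds
#' @export
placeMonomer <- function(arch, assembly, placement) {
  if (arch@kind == "CS") {
    if (placement$axis == "y")
      assembly$y <- sort(c(assembly$y, placement$pos))
    else
      assembly$x <- sort(c(assembly$x, placement$pos))
    assembly
  } else {
    rbind(assembly,
          c(placement[1] %% arch@circumference, placement[2]))
  }
}

#' Candidate attachment placements
#'
#' All unoccupied placements adjacent-by-bond to the assembly (for an empty
#' assembly, the canonical first placements).
#'
#' @inheritParams attachmentBonds
#' @return list of placements.
#' @export
candidatePlacements <- function(arch, assembly) {
  if (arch@kind == "CS") {
    w <- arch@width
    if (!assemblySize(assembly))
      return(list(list(axis = "y", pos = 0L)))
    ycand <- setdiff(unique(unlist(lapply(assembly$x,
                                          function(i) i:(i + w - 1L)))),
                     assembly$y)
    xcand <- setdiff(unique(unlist(lapply(assembly$y,
                                          function(j) (j - w + 1L):j))),
                     assembly$x)
    c(lapply(ycand, function(p) list(axis = "y", pos = p)),
      lapply(xcand, function(p) list(axis = "x", pos = p)))
  } else {
    m <- arch@circumference
    if (!nrow(assembly)) return(list(c(0L, 0L)))
    off <- tileOffsets(arch@kind)
    nb <- do.call(rbind, lapply(seq_len(nrow(assembly)), function(i)
      cbind((assembly[i, 1] + off[, 1]) %% m, assembly[i, 2] + off[, 2])))
    nb <- unique(nb)
    occ <- tileKey(assembly)
    keep <- !(paste(nb[, 1], nb[, 2], sep = ",") %in% occ)
    nb <- nb[keep, , drop = FALSE]
    lapply(seq_len(nrow(nb)), function(i) c(nb[i, 1], nb[i, 2]))
  }
}

#' Canonical key of an assembly state
#'
#' Translation-invariant (and, for tubes, rotation-invariant) string label
#' used to deduplicate states during landscape searches.
#'
#' @inheritParams attachmentBonds
#' @return character scalar.
#' @export
canonicalKey <- function(arch, assembly) {
  if (arch@kind == "CS") {
    t0 <- min(c(assembly$y, assembly$x, 0L))
    if (assemblySize(assembly))
      t0 <- min(c(assembly$y, assembly$x))
    paste0("y", paste(assembly$y - t0, collapse = ","),
           "|x", paste(assembly$x - t0, collapse = ","))
  } else {
    if (!nrow(assembly)) return("empty")
    m <- arch@circumference
    v <- assembly[, 2] - min(assembly[, 2])
    best <- NULL
    for (r in 0L:(m - 1L)) {
      u <- (assembly[, 1] + r) %% m
      o <- order(u, v)
      key <- paste(u[o], v[o], sep = ",", collapse = ";")
      if (is.null(best) || key < best) best <- key
    }
    best
  }
}

#' Bonds gained by attaching a monomer
#'
#' Number of bonds an incoming monomer forms when placed at \code{placement}
#' on \code{assembly}.  The first monomer on an empty assembly makes 0 bonds;
#' a CS slat landing at a complete ribbon end with full flanking context
#' makes n bonds (securing n consecutive cross-binding interactions).
#'
#' @param arch an [Architecture-class].
#' @param assembly an assembly state (see [newAssembly()]).
#' @param placement for CS, \code{list(axis = "y" or "x", pos = integer)};
#'   for tiles, an integer pair \code{c(u, v)}.
#' @return integer bond count.
#' @export
attachmentBonds <- function(arch, assembly, placement) {
  if (arch@kind == "CS") {
    w <- arch@width
    if (placement$axis == "y") {
      if (placement$pos %in% assembly$y) stop("placement already occupied")
      d <- placement$pos - assembly$x
      as.integer(sum(d >= 0L & d < w))
    } else {
      if (placement$pos %in% assembly$x) stop("placement already occupied")
      d <- assembly$y - placement$pos
      as.integer(sum(d >= 0L & d < w))
    }
  } else {
    m <- arch@circumference
    pu <- placement[1] %% m
    if (nrow(assembly) &&
        any(assembly[, 1] == pu & assembly[, 2] == placement[2]))
      stop("placement already occupied")
    as.integer(attachmentBondsTile(arch, assembly, placement))
  }
}
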