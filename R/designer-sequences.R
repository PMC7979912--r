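#' Assign orthogonal sequences to a blueprint
#'
#' Draws binding-domain sequences from orthogonal pools (a GF(4)
#' parity-check code filtered by the GC window and homopolymer rule, so any
#' two same-length domains within a pool differ at >= \code{min_hamming}
#' positions for the default floor of 2), derives every x-slat domain as
#' the exact reverse complement of its conjugate y-domain, fills
#' seed-handle domains from a disjoint coset pool, and screens assembled
#' slats for homopolymer runs, self-structure and (optionally) the
#' y-over-x base-stacking polarity, regenerating until all screens pass.
#' Identical \code{(blueprint, rng_seed, constraints)} give identical
#' sequences.
#'
#' @param blueprint a [SlatBlueprint-class] from [buildBlueprint()].
#' @param rng_seed integer seed.
#' @param constraints list: \code{max_homopolymer} (default 4),
#'   \code{gc} window (default c(0.3, 0.7)), \code{min_hamming} (default 2),
#'   \code{max_self_structure} (longest tolerated self-complementary stem
#'   in an assembled slat, default 7: stems of 8 nt or more are rejected,
#'   well below stability at the 46-56 C growth temperatures),
#'   \code{stacking_polarity} (require stronger y than x stacking,
#'   default TRUE), \code{max_tries} (default 50).
#' @return the blueprint with sequences assigned; the constraint report is
#'   attached as the \code{"constraint_report"} attribute.
#' @export
assignSequences <- function(blueprint, rng_seed = 42L, constraints = list()) {
  con <- utils::modifyList(
    list(max_homopolymer = 4L, gc = c(0.3, 0.7), min_hamming = 2L,
         max_self_structure = 7L, stacking_polarity = TRUE,
         max_tries = 50L),
    constraints)
  n <- blueprint@layout@n
  w <- 2L * n
  u <- blueprint@period
  dom <- blueprint@domains
  set.seed(rng_seed)

  lens <- sort(unique(dom$length))
  mainPools <- lapply(lens, function(len) {
    p <- parityPool(len, 0L, con$gc, con$max_homopolymer)
    if (con$min_hamming > 2L)
      p <- greedyPool(len, length(p), con$min_hamming, con$gc,
                      con$max_homopolymer)
    p
  })
  names(mainPools) <- lens
  seedPools <- lapply(lens, function(len)
    parityPool(len, 1L, con$gc, con$max_homopolymer))
  names(seedPools) <- lens

  yNeed <- dom[dom$class == "y", ]
  seedNeed <- dom[dom$class == "nuc_y" & dom$partner_class == "seed", ]
  for (len in lens) {
    need <- sum(yNeed$length == len)
    if (need > length(mainPools[[as.character(len)]]))
      stop(sprintf(
        "infeasible constraints: %d orthogonal %d-nt domains required but only %d satisfy the GC/homopolymer/Hamming rules",
        need, len, length(mainPools[[as.character(len)]])))
    needS <- sum(seedNeed$length == len)
    if (needS > length(seedPools[[as.character(len)]]))
      stop(sprintf(
        "infeasible constraints: %d orthogonal %d-nt seed handles required but only %d available",
        needS, len, length(seedPools[[as.character(len)]])))
  }

  assembleOnce <- function() {
    main <- lapply(mainPools, sample)   # shuffled copies to draw from
    seedp <- lapply(seedPools, sample)
    take <- function(pools, len) {
      key <- as.character(len)
      s <- pools[[key]][1]
      pools[[key]] <<- pools[[key]][-1]
      s
    }
    # y-role domain sequences
    ydom <- matrix(NA_character_, nrow = u, ncol = w)
    for (b in 0:(u - 1L)) for (k in 0:(w - 1L)) {
      len <- rev(blueprint@layout@lengths)[k + 1L]
      s <- main[[as.character(len)]][1]
      main[[as.character(len)]] <- main[[as.character(len)]][-1]
      ydom[b + 1L, k + 1L] <- s
    }
    # x-role domains are reverse complements of their conjugates
    xdom <- matrix(NA_character_, nrow = u, ncol = w)
    for (a in 0:(u - 1L)) for (d in 0:(w - 1L))
      xdom[a + 1L, d + 1L] <- revcomp(ydom[(a + d) %% u + 1L, w - d])
    # nucleating y-slats: seed half fresh, ribbon half copies the y role
    nucdom <- matrix(NA_character_, nrow = w, ncol = w)
    for (j in 0:(w - 1L)) for (k in 0:(w - 1L)) {
      if (k < n) {
        len <- rev(blueprint@layout@lengths)[k + 1L]
        s <- seedp[[as.character(len)]][1]
        seedp[[as.character(len)]] <- seedp[[as.character(len)]][-1]
        nucdom[j + 1L, k + 1L] <- s
      } else {
        nucdom[j + 1L, k + 1L] <- ydom[j %% u + 1L, k + 1L]
      }
    }
    list(y = ydom, x = xdom, nuc = nucdom)
  }

  ok <- FALSE
  for (try in seq_len(con$max_tries)) {
    dm <- assembleOnce()
    seqs <- c(
      stats::setNames(apply(dm$nuc, 1, paste0, collapse = ""),
                      sprintf("nucY%02d", 0:(w - 1L))),
      stats::setNames(apply(dm$x, 1, paste0, collapse = ""),
                      sprintf("x%02d", 0:(u - 1L))),
      stats::setNames(apply(dm$y, 1, paste0, collapse = ""),
                      sprintf("y%02d", 0:(u - 1L))))
    k <- con$max_homopolymer + 1L
    pat <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", k, k, k, k)
    if (any(grepl(pat, seqs))) next
    ss <- vapply(seqs, scoreSelfStructure, numeric(1))
    if (any(ss > con$max_self_structure)) next
    bpTry <- blueprint
    bpTry@sequences <- seqs
    if (isTRUE(con$stacking_polarity)) {
      pol <- stackingPolarity(bpTry)
      if (!pol$polarity_ok) next
    }
    ok <- TRUE
    break
  }
  if (!ok)
    stop("could not satisfy the sequence constraints after ", con$max_tries,
         " attempts; constraint set may be infeasible (self-structure cap ",
         con$max_self_structure, ", homopolymer cap ", con$max_homopolymer,
         ")")
  report <- constraintReport(bpTry, con)
  attr(bpTry, "constraint_report") <- report
  bpTry
}

domainSequence <- function(blueprint, slat, domain) {
  dom <- blueprint@domains
  row <- dom[dom$slat == slat & dom$domain == domain, ]
  seqs <- blueprint@sequences
  start <- sum(dom$length[dom$slat == slat & dom$domain < domain])
  substr(seqs[[slat]], start + 1L, start + row$length)
}

#' Constraint report for an assigned blueprint
#'
#' Verifies every crossing for base-by-base complementarity and computes
#' GC content, homopolymer runs, self-structure scores and the realized
#' minimum pairwise Hamming distances per domain length within the
#' y-binding and seed-handle pools.
#'
#' @param blueprint an assigned [SlatBlueprint-class].
#' @param constraints the constraint list the design was built under.
#' @return list of check results.
#' @export
constraintReport <- function(blueprint, constraints = list()) {
  dom <- blueprint@domains
  seqs <- blueprint@sequences
  if (!length(seqs)) stop("sequences have not been assigned")
  cross <- dom[dom$partner_class %in% c("x", "y"), ]
  okComp <- logical(nrow(cross))
  for (i in seq_len(nrow(cross))) {
    r <- cross[i, ]
    partner <- sprintf("%s%02d", r$partner_class, r$partner_role)
    a <- domainSequence(blueprint, r$slat, r$domain)
    b <- domainSequence(blueprint, partner, r$partner_domain)
    okComp[i] <- identical(a, revcomp(b))
  }
  ydom <- dom[dom$class == "y", ]
  yseqs <- vapply(seq_len(nrow(ydom)), function(i)
    domainSequence(blueprint, ydom$slat[i], ydom$domain[i]), "")
  hamMin <- function(v) {
    if (length(v) < 2L) return(NA_integer_)
    m <- do.call(rbind, strsplit(v, ""))
    best <- ncol(m)
    for (i in seq_len(nrow(m) - 1L)) {
      d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                     matrix(m[i, ], nrow = nrow(m) - i, ncol = ncol(m),
                            byrow = TRUE))
      best <- min(best, d)
    }
    as.integer(best)
  }
  byLen <- split(yseqs, nchar(yseqs))
  gc <- vapply(seqs, function(s) {
    v <- strsplit(s, "")[[1]]
    mean(v %in% c("G", "C"))
  }, numeric(1))
  list(all_crossings_complementary = all(okComp),
       n_crossings = nrow(cross),
       min_hamming_by_length = vapply(byLen, hamMin, integer(1)),
       gc_range = range(gc),
       max_self_structure = max(vapply(seqs, scoreSelfStructure,
                                       numeric(1))),
       constraints = constraints)
}

#' Self-structure score of a sequence
#'
#' Hairpin proxy: length of the longest contiguous stem formed by two
#' non-overlapping subsequences that are exact reverse complements of each
#' other.  0 means no self-complementary match of length >= 1; a perfect
#' 2k-nt palindrome scores k.
#'
#' @param sequence a DNA sequence over ACGT.
#' @return integer stem length.
#' @examples
#' scoreSelfStructure("AAAAAAAA")      # 0
#' scoreSelfStructure("ACGTACGTACGT")  # >= 5 impossible here; try it
#' @export
scoreSelfStructure <- function(sequence) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  s <- strsplit(toupper(sequence), "")[[1]]
  if (!all(s %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T")
  L <- length(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pairs <- function(a, b) comp[[a]] == b
  best <- 0L
  # M[i, j]: length of contiguous complementary run extending inward from
  # (i, j); the usable stem is capped so the two arms do not overlap.
  M <- matrix(0L, L, L)
  for (span in seq_len(L - 1L)) {
    for (i in seq_len(L - span)) {
      j <- i + span
      if (pairs(s[i], s[j])) {
        inner <- if (j - i >= 2L) M[i + 1L, j - 1L] else 0L
        M[i, j] <- 1L + inner
        stem <- min(M[i, j], (j - i + 1L) %/% 2L)
        if (stem > best) best <- stem
      }
    }
  }
  as.integer(best)
}

#' Nearest-neighbour base-stacking free energies
#'
#' Dinucleotide stack free energies (kcal/mol) measured from nicked-duplex
#' electrophoresis (Protozanova et al., J Mol Biol 2004), the standard set
#' for ranking coaxial-stacking strength at nicks and junctions.
#'
#' @return named numeric vector over the 16 dinucleotide steps.
#' @export
stackingTable <- function() {
  c(AA = -1.11, AC = -1.81, AG = -1.26, AT = -1.34,
    CA = -0.55, CC = -1.44, CG = -0.91, CT = -1.26,
    GA = -1.43, GC = -2.17, GG = -1.44, GT = -1.81,
    TA = -0.19, TC = -1.43, TG = -0.55, TT = -1.11)
}

stackSteps <- function(blueprint, class) {
  # junction dinucleotides: for y-slats the crossover steps between
  # consecutive domains (stacking propagating across the ribbon, y axis);
  # for x-slats the end-to-end abutment of successive slats along a helix
  # (x axis).
  dom <- blueprint@domains
  seqs <- blueprint@sequences
  out <- character()
  if (class == "y") {
    for (slat in unique(dom$slat[dom$class == "y"])) {
      s <- seqs[[slat]]
      lens <- dom$length[dom$slat == slat][order(dom$domain[dom$slat == slat])]
      ends <- cumsum(lens)
      for (e in ends[-length(ends)])
        out <- c(out, substr(s, e, e + 1L))
    }
  } else {
    for (slat in unique(dom$slat[dom$class == "x"])) {
      s <- seqs[[slat]]
      out <- c(out, paste0(substr(s, nchar(s), nchar(s)), substr(s, 1L, 1L)))
    }
  }
  out
}

#' Base-stacking polarity of a design
#'
#' Sums (and averages) junction stacking energies propagating along the x
#' versus y directions of the ribbon and flags designs that violate the
#' intended polarity of stronger stacking along y than along x (mean
#' junction stack more stabilizing in y).
#'
#' @param blueprint an assigned [SlatBlueprint-class].
#' @param stacking_table named dinucleotide energies, kcal/mol
#'   (default [stackingTable()]).
#' @return list with per-direction totals, means, junction counts and
#'   \code{polarity_ok}.
#' @export
stackingPolarity <- function(blueprint, stacking_table = stackingTable()) {
  need <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
            "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  if (!all(need %in% names(stacking_table)))
    stop("incomplete stacking table: missing ",
         paste(setdiff(need, names(stacking_table)), collapse = ", "))
  ySteps <- stackSteps(blueprint, "y")
  xSteps <- stackSteps(blueprint, "x")
  yE <- unname(stacking_table[ySteps])
  xE <- unname(stacking_table[xSteps])
  res <- list(y_total = sum(yE), x_total = sum(xE),
              y_mean = mean(yE), x_mean = mean(xE),
              n_y = length(yE), n_x = length(xE))
  res$polarity_difference <- res$y_mean - res$x_mean
  res$polarity_ok <- res$y_mean < res$x_mean  # more negative = stronger
  res
}
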