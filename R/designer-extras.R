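#' Decorate a blueprint with brushes, sticky ends and blockers
#'
#' Appends non-binding poly-T brushes to slat ends (passivating ribbon
#' edges against blunt-end stacking aggregation), adds short sticky ends
#' with self-consistent pairing across the ribbon edge (3-4 nt overhangs
#' drive closure of coiled ribbons into tubes), and generates blocking
#' strands, full reverse complements of selected nucleating y-slats whose
#' sequestration terminates seeded assembly.
#'
#' @param blueprint an assigned [SlatBlueprint-class].
#' @param brush_length poly-T brush length in nt (0 for none).
#' @param brush_end \code{"3p"}, \code{"5p"} or \code{"both"}.
#' @param sticky_end_length 0 (none), 3 or 4 nt.
#' @param blockers integer indices (0-based) of nucleating y-slats to
#'   generate blocking strands for.
#' @param sticky_seq sticky-end sequence; default deterministic per length.
#' @return the decorated blueprint; decorations are annotated in
#'   \code{@decorations} and blocker records appended to the slat table.
#' @export
decorateBlueprint <- function(blueprint, brush_length = 0L,
                              brush_end = c("3p", "5p", "both"),
                              sticky_end_length = 0L, blockers = integer(),
                              sticky_seq = NULL) {
  brush_end <- match.arg(brush_end)
  if (!length(blueprint@sequences))
    stop("assign sequences before decorating")
  if (!sticky_end_length %in% c(0L, 3L, 4L))
    stop("sticky ends are 3 or 4 nt (or 0 for none)")
  bp <- blueprint
  dec <- bp@decorations

  if (brush_length > 0L) {
    brush <- strrep("T", brush_length)
    targets <- bp@slats$name[bp@slats$class %in% c("x", "y", "nuc_y")]
    for (nm in targets) {
      s <- bp@sequences[[nm]]
      if (brush_end %in% c("5p", "both")) s <- paste0(brush, s)
      if (brush_end %in% c("3p", "both")) s <- paste0(s, brush)
      bp@sequences[[nm]] <- s
    }
    dec[[length(dec) + 1L]] <- list(type = "brush", length = brush_length,
                                    end = brush_end, binding = FALSE,
                                    slats = targets)
  } else {
    dec[[length(dec) + 1L]] <- list(type = "brush", length = 0L,
                                    binding = FALSE, slats = character())
  }

  if (sticky_end_length > 0L) {
    xs <- bp@slats$name[bp@slats$class == "x"]
    if (!length(xs))
      stop("sticky ends require slats with edge domains (no x-slats found)")
    s <- if (is.null(sticky_seq)) {
      if (sticky_end_length == 3L) "TGC" else "ATGC"
    } else sticky_seq
    if (nchar(s) != sticky_end_length)
      stop("sticky_seq length disagrees with sticky_end_length")
    # one ribbon edge presents s, the opposite edge its reverse complement,
    # so a coiled sheet can seal on itself
    for (nm in xs) {
      bp@sequences[[nm]] <- paste0(s, bp@sequences[[nm]], revcomp(s))
    }
    tw <- twistReport(bp@layout)
    closure <- if (tw$coil_class == "tight-coil")
      "closed-tube-constant-diameter"
    else if (tw$coil_class == "loose-coil")
      "closed-tube-varying-diameter"
    else "edge-sealed-ribbon"
    dec[[length(dec) + 1L]] <- list(type = "sticky_end",
                                    length = sticky_end_length,
                                    sequence = s, annotation = closure,
                                    slats = xs)
  }

  if (length(blockers)) {
    w <- 2L * bp@layout@n
    if (any(blockers < 0L | blockers >= w))
      stop("blocker indices must address nucleating y-slats 0..", w - 1L)
    for (j in blockers) {
      nm <- sprintf("nucY%02d", j)
      bnm <- sprintf("blocker%02d", j)
      bp@sequences[[bnm]] <- revcomp(blueprint@sequences[[nm]])
      bp@slats <- rbind(bp@slats,
                        data.frame(name = bnm, class = "blocker",
                                   role = j, threading = "none",
                                   stringsAsFactors = FALSE))
    }
    dec[[length(dec) + 1L]] <- list(type = "blocker", targets = blockers)
  }
  bp@decorations <- dec
  bp
}

#' Design genome-folding nucleators
#'
#' Builds the set of six nuc-x-slats that folds a 190-nt segment of an
#' arbitrary single-stranded DNA genome (e.g. M13) into a nucleus for
#' periodic v6 ribbon assembly: the genome-binding domains of the six slats
#' are reverse complements tiling the window without gaps or overlaps (in
#' near-equal consecutive blocks), and the remaining domains present v6
#' y-slat handles taken from the blueprint's x roles.
#'
#' @param genome_sequence genome as a character string,
#'   \code{Biostrings::DNAString}, or path to a FASTA file.
#' @param window_start 0-based start of the 190-nt window (half-open
#'   coordinates).
#' @param blueprint an assigned v6 [SlatBlueprint-class] supplying the
#'   y-slat handle domains; default builds one with seed 1.
#' @param window_nt window width, 190 nt.
#' @return \code{Biostrings::DNAStringSet} of six nuc-x-slats; the tiling
#'   table (block coordinates and sequences) is attached as the
#'   \code{"tiling"} attribute (metadata columns).
#' @export
designGenomeNucleators <- function(genome_sequence, window_start,
                                   blueprint = NULL, window_nt = 190L) {
  if (is.character(genome_sequence) && length(genome_sequence) == 1L &&
      file.exists(genome_sequence)) {
    genome_sequence <- as.character(
      Biostrings::readDNAStringSet(genome_sequence)[[1]])
  }
  genome <- toupper(as.character(genome_sequence))
  if (window_start < 0L || window_start + window_nt > nchar(genome))
    stop("window [", window_start, ", ", window_start + window_nt,
         ") is out of range for a genome of ", nchar(genome), " nt")
  window <- substr(genome, window_start + 1L, window_start + window_nt)
  if (grepl("[^ACGT]", window))
    stop("genome window contains ambiguous bases")
  if (is.null(blueprint)) {
    blueprint <- assignSequences(buildBlueprint(domainLayout(6L, 10.5),
                                                "full"), rng_seed = 1L)
  }
  if (!length(blueprint@sequences))
    stop("blueprint must have assigned sequences")
  n_slats <- 6L
  base <- window_nt %/% n_slats
  extra <- window_nt %% n_slats
  sizes <- c(rep(base + 1L, extra), rep(base, n_slats - extra))
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-n_slats])
  n <- blueprint@layout@n
  handleFor <- function(i) {
    # first n domains of x role (i mod period): the half that recruits
    # periodic y-slats
    nm <- sprintf("x%02d", i %% blueprint@period)
    lens <- blueprint@domains$length[blueprint@domains$slat == nm]
    substr(blueprint@sequences[[nm]], 1L, sum(lens[seq_len(n)]))
  }
  slats <- character(n_slats)
  tiling <- data.frame(name = sprintf("genomeNucX%02d", 0:(n_slats - 1L)),
                       genome_start = window_start + starts,
                       genome_end = window_start + ends,
                       block = substring(window, starts + 1L, ends),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_slats)) {
    genomeDomain <- revcomp(tiling$block[i])
    slats[i] <- paste0(genomeDomain, handleFor(i - 1L))
  }
  out <- Biostrings::DNAStringSet(stats::setNames(slats, tiling$name))
  attr(out, "tiling") <- tiling
  out
}

#' Export slat sequences as FASTA and plate layout
#'
#' Writes one FASTA record per slat (annotated headers, deterministic
#' ordering: nucleating y-slats, then the requested number of repeat units
#' of x- and y-slats, then blockers) and a 96-well plate-layout CSV with
#' column-major well assignment (A1, B1, ..., H1, A2, ...), overflowing
#' onto further plates as needed.
#'
#' @param blueprint an assigned [SlatBlueprint-class].
#' @param dir output directory.
#' @param basename file stem for the outputs.
#' @param repeats number of repeat units exported (each contributes one
#'   copy of every x and y role).
#' @return invisibly, a list with the FASTA and CSV paths and the record
#'   table.
#' @export
exportSequences <- function(blueprint, dir = ".", basename = "slats",
                            repeats = 1L) {
  if (!length(blueprint@sequences))
    stop("sequences have not been assigned; run assignSequences() first")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sl <- blueprint@slats
  nucs <- sl$name[sl$class == "nuc_y"]
  xs <- sl$name[sl$class == "x"]
  ys <- sl$name[sl$class == "y"]
  blk <- sl$name[sl$class == "blocker"]
  records <- c(
    stats::setNames(blueprint@sequences[nucs],
                    sprintf("%s|nuc-y|role=%s", nucs, sub("nucY", "", nucs))),
    unlist(lapply(seq_len(repeats), function(r)
      c(stats::setNames(blueprint@sequences[xs],
                        sprintf("%s_u%02d|x|unit=%d", xs, r, r)),
        stats::setNames(blueprint@sequences[ys],
                        sprintf("%s_u%02d|y|unit=%d", ys, r, r))))),
    stats::setNames(blueprint@sequences[blk],
                    if (length(blk)) sprintf("%s|blocker", blk)
                    else character()))
  fasta <- file.path(dir, paste0(basename, ".fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(records), fasta,
                              width = 80L)
  idx <- seq_along(records) - 1L
  plate <- idx %/% 96L + 1L
  within <- idx %% 96L
  well <- paste0(LETTERS[within %% 8L + 1L], within %/% 8L + 1L)
  tab <- data.frame(plate = plate, well = well, name = names(records),
                    sequence = unname(records), stringsAsFactors = FALSE)
  csv <- file.path(dir, paste0(basename, "_plates.csv"))
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(list(fasta = fasta, plate_csv = csv, records = tab))
}
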