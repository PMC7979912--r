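#' @import methods
NULL

#' Monomer architecture for nucleation-barrier analysis
#'
#' Describes the bond topology of a self-assembling monomer system: square
#' tiles (\code{"ST"}, half coordination n = 2) and hexagonal tiles
#' (\code{"HT"}, n = 3) polymerizing into nanotubes of a given circumference,
#' or crisscross slats (\code{"CS"}) with arbitrary half coordination n
#' polymerizing into ribbons.  A slat carries a linear array of 2n weak
#' binding sites, each specific to exactly one conjugate site on one of 2n
#' distinct perpendicular slats; the full coordination number is 2n for every
#' kind.
#'
#' @slot kind one of \code{"ST"}, \code{"HT"}, \code{"CS"}.
#' @slot n half coordination number (bonds a monomer must make to be stably
#'   attached under near-reversible conditions).
#' @slot circumference tube circumference in tiles (ST/HT only).
#' @slot width number of binding sites per slat, \code{2 * n} (CS only).
#'
#' @seealso [architecture()]
#' @export
setClass("Architecture",
  representation(kind = "character", n = "integer",
                 circumference = "integer", width = "integer"))

setValidity("Architecture", function(object) {
  msg <- character()
  if (!object@kind %in% c("ST", "HT", "CS"))
    msg <- c(msg, "kind must be one of 'ST', 'HT', 'CS'")
  if (length(object@n) != 1L || is.na(object@n) || object@n < 1L)
    msg <- c(msg, "n must be a positive integer")
  if (object@kind == "ST" && object@n != 2L)
    msg <- c(msg, "ST has half coordination n = 2")
  if (object@kind == "HT" && object@n != 3L)
    msg <- c(msg, "HT has half coordination n = 3")
  if (object@kind %in% c("ST", "HT")) {
    if (length(object@circumference) != 1L || is.na(object@circumference) ||
        object@circumference < 1L)
      msg <- c(msg, "tile architectures need a positive circumference")
  } else {
    if (object@width != 2L * object@n)
      msg <- c(msg, "a CS slat carries exactly 2n binding sites")
  }
  if (length(msg)) msg else TRUE
})

#' kTAM energy parameterization
#'
#' Free energies in "decades" (log10 units), so that barrier differences
#' translate directly into orders of magnitude of relative nucleation rate.
#' \code{gMC} is the per-monomer entropic cost set by concentration,
#' \code{gMC = log10(c0 / c)} with standard state \code{c0 = 20} M;
#' \code{gSE} is the per-bond energy; \code{epsilon = n * gSE - gMC} measures
#' irreversibility (log10 of the attachment:detachment rate ratio for an
#' n-bond attachment; \code{epsilon = 2} means 100:1 growth:shrinkage).
#'
#' @slot gMC monomer cost in decades.
#' @slot gSE per-bond energy in decades.
#' @slot epsilon irreversibility in decades (\code{n * gSE - gMC}).
#' @slot concentration monomer concentration in mol/L.
#' @slot n half coordination number the parameterization refers to.
#'
#' @seealso [ktamParams()]
#' @export
setClass("KtamParams",
  representation(gMC = "numeric", gSE = "numeric", epsilon = "numeric",
                 concentration = "numeric", n = "integer"))

setValidity("KtamParams", function(object) {
  msg <- character()
  if (object@gMC <= 0) msg <- c(msg, "gMC must be positive")
  if (object@gSE <= 0) msg <- c(msg, "gSE must be positive")
  if (abs(object@epsilon - (object@n * object@gSE - object@gMC)) > 1e-8)
    msg <- c(msg, "epsilon must equal n * gSE - gMC")
  if (length(msg)) msg else TRUE
})

#' Free-energy landscape of a nucleation pathway
#'
#' The minimal-barrier attachment ordering for an architecture under a given
#' kTAM parameterization.  \code{Gprofile[i]} is the assembly free energy
#' after \code{i - 1} attachments (so the first element is the empty assembly
#' at G = 0).  The barrier is the profile maximum and the critical size the
#' monomer count at which it is attained (ties at a near-reversible plateau
#' are reported as the completed junction).
#'
#' @slot pathway data.frame with one row per attachment (N, placement label,
#'   bonds formed, dG, cumulative G).
#' @slot Gprofile numeric vector of free energies, starting at 0.
#' @slot barrier profile maximum, decades.
#' @slot criticalSize monomer count at the barrier.
#' @slot bondsAtCritical bond count at the barrier.
#' @slot method search method used ("exact", "staircase", "seeded").
#' @slot arch the [Architecture-class] searched.
#' @slot params the [KtamParams-class] used.
#' @export
setClass("NucleationLandscape",
  representation(pathway = "data.frame", Gprofile = "numeric",
                 barrier = "numeric", criticalSize = "integer",
                 bondsAtCritical = "numeric", method = "character",
                 arch = "Architecture", params = "KtamParams"))

#' Kinetic parameters of the seeded ribbon-growth model
#'
#' Continuous-time Markov model of ribbon elongation: a ribbon end switches
#' between growing and stalled states (rates \code{kStall}, \code{kResume}),
#' elongates at velocity \code{v} while growing, and is absorbed
#' (terminated) at rate \code{kTerm}.  The effective velocity is
#' \code{vEff = v * kResume / (kResume + kStall)}.  \code{J} is the
#' spontaneous (seed-independent) nucleation rate.
#'
#' @slot v intrinsic growth velocity, nm/s.
#' @slot kStall,kResume stall / resume rates, 1/s.
#' @slot kTerm absorbing termination rate, 1/s.
#' @slot J spontaneous nucleation rate, mol/L/s.
#' @slot seedConc seed concentration, mol/L.
#' @slot slatConc per-slat monomer concentration, mol/L.
#' @slot delta ribbon extension per added slat, nm (default 1.5).
#' @seealso [growthParams()]
#' @export
setClass("GrowthParams",
  representation(v = "numeric", kStall = "numeric", kResume = "numeric",
                 kTerm = "numeric", J = "numeric", seedConc = "numeric",
                 slatConc = "numeric", delta = "numeric"))

setValidity("GrowthParams", function(object) {
  msg <- character()
  for (s in c("v", "kStall", "kResume", "kTerm", "J", "seedConc", "slatConc"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be non-negative"))
  if (object@delta <= 0) msg <- c(msg, "delta must be positive")
  if (length(msg)) msg else TRUE
})

#' Fitted growth model
#'
#' Result of [fitGrowthModel()]: weighted least-squares estimates of the
#' effective growth velocity and termination rate, with bootstrap confidence
#' intervals.
#'
#' @slot estimates named numeric (vEff nm/s, kTerm 1/s).
#' @slot ci 2-column matrix of bootstrap percentile confidence limits.
#' @slot level confidence level.
#' @slot boot matrix of bootstrap replicate estimates.
#' @slot data per-timepoint summary used in the fit.
#' @slot fitted fitted mean lengths at the observed times.
#' @export
setClass("GrowthFit",
  representation(estimates = "numeric", ci = "matrix", level = "numeric",
                 boot = "matrix", data = "data.frame", fitted = "numeric"))

#' Half-turn domain layout of a slat
#'
#' A slat core is a linear array of 2n binding domains, each spanning half a
#' helical turn of DNA (5 or 6 nt).  Every window of four consecutive domains
#' spans two full turns and must sum to \code{2 * bpPerTurn} nucleotides:
#' 21 nt at 10.5 bp/turn, 22 nt at 11.0 bp/turn.  \code{phase} rotates the
#' repeating 5/6 pattern; a shifted 10.5 phase yields loosely coiled ribbons
#' and 11.0 bp/turn tightly coiled ones (see [twistReport()]).
#'
#' @slot n half coordination number.
#' @slot bpPerTurn base pairs per helical turn.
#' @slot lengths integer vector of 2n domain lengths (5 or 6).
#' @slot phase integer rotation of the domain pattern.
#' @seealso [domainLayout()]
#' @export
setClass("DomainLayout",
  representation(n = "integer", bpPerTurn = "numeric", lengths = "integer",
                 phase = "integer"))

setValidity("DomainLayout", function(object) {
  msg <- character()
  if (length(object@lengths) != 2L * object@n)
    msg <- c(msg, "layout must have 2n domains")
  if (!all(object@lengths %in% c(5L, 6L)))
    msg <- c(msg, "domains must be 5 or 6 nt")
  target <- 2 * object@bpPerTurn
  if (length(object@lengths) >= 4L) {
    sums <- vapply(seq_len(length(object@lengths) - 3L),
                   function(i) sum(object@lengths[i:(i + 3L)]), numeric(1))
    if (any(sums != target))
      msg <- c(msg, sprintf("every 4-domain window must sum to %g nt", target))
  }
  if (length(msg)) msg else TRUE
})

#' Complete crisscross slat set
#'
#' The full design of a crisscross ribbon: nucleating y-slats (captured by
#' the seed), x-slats and y-slats of the periodic repeat, the crossing map
#' pairing every binding domain with its unique conjugate, assigned
#' sequences, and decorations (poly-T brushes, sticky ends, blockers).
#' x-slats never cross over between helices; y-slats cross over every half
#' turn (recorded in the threading annotation).
#'
#' @slot layout the [DomainLayout-class].
#' @slot symmetryMode "full" (period 2n), "n_pairs" (period n) or
#'   "half_n_pairs" (period n/2).
#' @slot period repeat-unit size implied by the symmetry mode.
#' @slot slats data.frame of slat records (name, class, role, threading).
#' @slot domains data.frame crossing map: one row per (slat, domain) with its
#'   partner slat/domain or seed-handle annotation.
#' @slot sequences named character vector of slat core sequences (5'->3'),
#'   empty until [assignSequences()] is run.
#' @slot decorations list of decoration records.
#' @seealso [buildBlueprint()]
#' @export
setClass("SlatBlueprint",
  representation(layout = "DomainLayout", symmetryMode = "character",
                 period = "integer", slats = "data.frame",
                 domains = "data.frame", sequences = "character",
                 decorations = "list"))

#' Ground-truth-labelled synthetic dataset bundle
#'
#' @slot trueParams the [GrowthParams-class] used to generate the data.
#' @slot lengthSamples data.frame of TEM-style ribbon lengths
#'   (condition, time_h, length_nm).
#' @slot gelLanes data.frame of gel lanes (see [gelLanes()]).
#' @slot rngSeed integer seed the bundle was generated with.
#' @slot noiseModel list describing the noise applied.
#' @export
setClass("SyntheticBundle",
  representation(trueParams = "GrowthParams", lengthSamples = "data.frame",
                 gelLanes = "data.frame", rngSeed = "integer",
                 noiseModel = "list"))
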