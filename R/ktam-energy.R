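#' kTAM energy parameters
#'
#' Builds the energy parameterization for an architecture.  The per-monomer
#' cost is set by concentration against the kTAM standard state
#' \code{c0 = 20} M: \code{gMC = log10(c0 / c)} (7.301 decades at 1 uM).
#' Given an irreversibility \code{epsilon}, the per-bond energy follows as
#' \code{gSE = (gMC + epsilon) / n}; alternatively \code{gSE} may be given
#' directly and \code{epsilon = n * gSE - gMC} is derived.
#'
#' @param arch an [Architecture-class], or a half coordination number n.
#' @param epsilon irreversibility in decades (log10 attachment:detachment
#'   ratio of an n-bond attachment; 2 means 100:1).
#' @param concentration monomer concentration, mol/L.
#' @param gSE per-bond energy in decades; overrides \code{epsilon} if given.
#' @param gMC per-monomer cost in decades; overrides \code{concentration}
#'   if given.
#' @param referenceConc standard-state concentration c0, mol/L.
#' @return a [KtamParams-class] object.
#' @examples
#' ktamParams(architecture("CS", n = 6), epsilon = 2, concentration = 1e-6)
#' @export
ktamParams <- function(arch, epsilon = 2, concentration = 1e-6, gSE = NULL,
                       gMC = NULL, referenceConc = 20) {
  n <- if (is(arch, "Architecture")) arch@n else as.integer(arch)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (is.null(gMC)) {
    if (concentration <= 0 || concentration >= referenceConc)
      stop("concentration must be positive and below the standard state")
    gMC <- log10(referenceConc / concentration)
  } else {
    concentration <- referenceConc * 10^(-gMC)
  }
  if (is.null(gSE)) {
    gSE <- gseFromEpsilon(epsilon, n, gMC)
  } else {
    epsilon <- n * gSE - gMC
  }
  new("KtamParams", gMC = gMC, gSE = gSE, epsilon = epsilon,
      concentration = concentration, n = n)
}

#' Per-bond energy from irreversibility
#'
#' \code{gSE = (gMC + epsilon) / n}: a monomer attaching by n bonds then has
#' an attachment:detachment rate ratio of \code{10^epsilon}.  At
#' \code{epsilon = 0} (reversible limit) this recovers \code{gSE = gMC / n}.
#'
#' @param epsilon irreversibility, decades.
#' @param n half coordination number.
#' @param g_mc monomer cost, decades.
#' @return per-bond energy in decades.
#' @examples
#' gseFromEpsilon(0, 6, 6)  # 1.0
#' @export
gseFromEpsilon <- function(epsilon, n, g_mc) {
  if (any(n == 0)) stop("n must be at least 1")
  if (any(g_mc <= 0)) stop("g_mc must be positive")
  (g_mc + epsilon) / n
}

#' @rdname gseFromEpsilon
#' @param g_se per-bond energy, decades.
#' @export
epsilonFromGse <- function(g_se, n, g_mc) n * g_se - g_mc

#' Assembly free energy
#'
#' \code{G(A) = N * gMC - B * gSE} in decades; the empty assembly has G = 0
#' and an attachment making b bonds changes G by \code{gMC - b * gSE}.
#'
#' @param params a [KtamParams-class].
#' @param N monomer count (or counts).
#' @param B bond count (or counts).
#' @return free energy in decades.
#' @export
freeEnergy <- function(params, N, B) N * params@gMC - B * params@gSE

#' @rdname freeEnergy
#' @param arch an [Architecture-class].
#' @param assembly an assembly state.
#' @export
assemblyFreeEnergy <- function(arch, assembly, params) {
  freeEnergy(params, assemblySize(assembly), assemblyBonds(arch, assembly))
}

#' Relative spontaneous nucleation rate
#'
#' Barrier difference in decades: the expected number of orders of magnitude
#' by which nucleation with barrier \code{barrier_a} is slower than with
#' \code{barrier_b} (rate ratio \code{10^-(barrier_a - barrier_b)}).
#'
#' @param barrier_a,barrier_b barriers in decades.
#' @return decades by which a is slower than b.
#' @examples
#' relativeNucleationRate(34.4, 10.8)  # 23.6
#' @export
relativeNucleationRate <- function(barrier_a, barrier_b) barrier_a - barrier_b
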