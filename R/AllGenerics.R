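#' @rdname NucleationLandscape-class
#' @param object,x an object.
#' @export
setGeneric("barrier", function(x) standardGeneric("barrier"))

#' @rdname NucleationLandscape-class
#' @export
setGeneric("criticalSize", function(x) standardGeneric("criticalSize"))

#' @rdname NucleationLandscape-class
#' @export
setGeneric("gProfile", function(x) standardGeneric("gProfile"))

#' @rdname Architecture-class
#' @export
setGeneric("kind", function(x) standardGeneric("kind"))

#' @rdname Architecture-class
#' @export
setGeneric("halfCoordination", function(x) standardGeneric("halfCoordination"))

#' @rdname KtamParams-class
#' @export
setGeneric("gMC", function(x) standardGeneric("gMC"))

#' @rdname KtamParams-class
#' @export
setGeneric("gSE", function(x) standardGeneric("gSE"))

#' @rdname KtamParams-class
#' @export
setGeneric("epsilon", function(x) standardGeneric("epsilon"))

#' @rdname GrowthParams-class
#' @export
setGeneric("effectiveVelocity", function(x) standardGeneric("effectiveVelocity"))

#' @rdname SlatBlueprint-class
#' @export
setGeneric("slatSequences", function(x) standardGeneric("slatSequences"))

#' @rdname SlatBlueprint-class
#' @export
setGeneric("nucYSlats", function(x) standardGeneric("nucYSlats"))

setMethod("barrier", "NucleationLandscape", function(x) x@barrier)
setMethod("criticalSize", "NucleationLandscape", function(x) x@criticalSize)
setMethod("gProfile", "NucleationLandscape", function(x) x@Gprofile)
setMethod("kind", "Architecture", function(x) x@kind)
setMethod("halfCoordination", "Architecture", function(x) x@n)
setMethod("gMC", "KtamParams", function(x) x@gMC)
setMethod("gSE", "KtamParams", function(x) x@gSE)
setMethod("epsilon", "KtamParams", function(x) x@epsilon)

setMethod("effectiveVelocity", "GrowthParams", function(x) {
  if (x@kStall == 0) return(x@v)
  x@v * x@kResume / (x@kResume + x@kStall)
})

#' @describeIn SlatBlueprint-class sequences of all slats (named, 5'->3').
setMethod("slatSequences", "SlatBlueprint", function(x) {
  if (!length(x@sequences))
    stop("sequences have not been assigned; run assignSequences() first")
  Biostrings::DNAStringSet(x@sequences)
})

#' @describeIn SlatBlueprint-class names of the nucleating y-slats (2n of them).
setMethod("nucYSlats", "SlatBlueprint", function(x) {
  x@slats$name[x@slats$class == "nuc_y"]
})

setMethod("show", "Architecture", function(object) {
  cat(sprintf("%s architecture: half coordination n = %d", object@kind,
              object@n))
  if (object@kind %in% c("ST", "HT"))
    cat(sprintf(", tube circumference %d", object@circumference))
  else
    cat(sprintf(", %d binding sites per slat", object@width))
  cat("\n")
})

setMethod("show", "KtamParams", function(object) {
  cat(sprintf(
    "kTAM parameters (decades): gMC = %.4f, gSE = %.4f, epsilon = %.4f\n",
    object@gMC, object@gSE, object@epsilon))
  cat(sprintf("  monomer concentration %.3g M, half coordination n = %d\n",
              object@concentration, object@n))
})

setMethod("show", "NucleationLandscape", function(object) {
  cat(sprintf("Nucleation landscape (%s, %s search)\n", object@arch@kind,
              object@method))
  cat(sprintf("  barrier %.3f decades at N = %d monomers (B = %g bonds)\n",
              object@barrier, object@criticalSize, object@bondsAtCritical))
  cat(sprintf("  profile over %d attachments\n", length(object@Gprofile) - 1L))
})

setMethod("show", "GrowthParams", function(object) {
  cat(sprintf(
    "Growth model: v = %.3g nm/s (vEff = %.3g), kStall = %.3g/s, kResume = %.3g/s, kTerm = %.3g/s\n",
    object@v, effectiveVelocity(object), object@kStall, object@kResume,
    object@kTerm))
  cat(sprintf("  J = %.3g M/s, seed %.3g M, slats %.3g M, delta = %.3g nm/slat\n",
              object@J, object@seedConc, object@slatConc, object@delta))
})

setMethod("show", "GrowthFit", function(object) {
  cat("Fitted seeded-growth model\n")
  ci <- object@ci
  cat(sprintf("  vEff  = %.4g nm/s  [%.4g, %.4g]\n", object@estimates["vEff"],
              ci["vEff", 1], ci["vEff", 2]))
  cat(sprintf("  kTerm = %.4g /s    [%.4g, %.4g]\n", object@estimates["kTerm"],
              ci["kTerm", 1], ci["kTerm", 2]))
  cat(sprintf("  %d timepoints, %d bootstrap resamples, %.0f%% intervals\n",
              nrow(object@data), nrow(object@boot), 100 * object@level))
})

setMethod("show", "DomainLayout", function(object) {
  cat(sprintf("Domain layout: n = %d, %.1f bp/turn, phase %d\n", object@n,
              object@bpPerTurn, object@phase))
  cat(sprintf("  domains [%s], core %d nt\n",
              paste(object@lengths, collapse = ","), sum(object@lengths)))
})

setMethod("show", "SlatBlueprint", function(object) {
  tab <- table(object@slats$class)
  cat(sprintf("Slat blueprint (n = %d, %s symmetry, period %d)\n",
              object@layout@n, object@symmetryMode, object@period))
  cat(sprintf("  slats: %s\n",
              paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  sequences %s; %d decoration(s)\n",
              if (length(object@sequences)) "assigned" else "unassigned",
              length(object@decorations)))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf("Synthetic bundle (seed %d): %d length measurements, %d gel lanes\n",
              object@rngSeed, nrow(object@lengthSamples),
              nrow(object@gelLanes)))
})
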