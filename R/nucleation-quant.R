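AVOGADRO <- 6.02214076e23

#' Slats per ribbon
#'
#' A ribbon of contour length L at \code{delta} nm extension per slat
#' contains \code{L / delta} slats: a 5 um ribbon at 1.5 nm/slat carries
#' ~3300 slats.
#'
#' @param length_nm ribbon contour length, nm.
#' @param delta extension per slat, nm.
#' @param signif_digits significant figures used for reporting; the exact
#'   value is kept in the \code{"exact"} attribute.
#' @return slat count, rounded for reporting.
#' @examples
#' slatsPerRibbon(5000)  # ~3300
#' @export
slatsPerRibbon <- function(length_nm, delta = 1.5, signif_digits = 2) {
  if (any(length_nm <= 0) || delta <= 0) stop("inputs must be positive")
  exact <- length_nm / delta
  structure(signif(exact, signif_digits), exact = exact)
}

#' Ribbon count to molar concentration
#'
#' \code{count / (N_A * volume)}: half a million ribbons in a 4 uL reaction
#' is about 200 fM.
#'
#' @param count number of ribbons.
#' @param volume_uL reaction volume, microliters.
#' @return concentration, mol/L.
#' @examples
#' ribbonsToMolar(5e5, 4)  # ~2.1e-13 M
#' @export
ribbonsToMolar <- function(count, volume_uL) {
  if (any(volume_uL <= 0)) stop("volume must be positive")
  count / (AVOGADRO * volume_uL * 1e-6)
}

#' @rdname ribbonsToMolar
#' @param conc concentration, mol/L.
#' @export
molarToRibbons <- function(conc, volume_uL) {
  if (any(volume_uL <= 0)) stop("volume must be positive")
  conc * AVOGADRO * volume_uL * 1e-6
}

#' Ribbon specification for mass conversion
#'
#' @param length_nm ribbon contour length, nm.
#' @param delta nm per slat.
#' @param slat_nt mean nucleotides per slat (v6 core is 63 nt plus brush).
#' @param nt_mass average ssDNA nucleotide mass, g/mol.
#' @return list used by [ribbonMass()].
#' @export
ribbonSpec <- function(length_nm = 5000, delta = 1.5, slat_nt = 66,
                       nt_mass = 330) {
  if (length_nm <= 0 || delta <= 0 || slat_nt <= 0 || nt_mass <= 0)
    stop("all ribbon spec fields must be positive")
  list(length_nm = length_nm, delta = delta, slat_nt = slat_nt,
       nt_mass = nt_mass)
}

#' Total DNA mass of a ribbon population
#'
#' \code{count * slats_per_ribbon * slat_nt * nt_mass / N_A} grams; half a
#' million 5 um ribbons of 66-nt slats weigh ~60 pg, consistent with the
#' ~65 pg agarose detection floor.
#'
#' @param spec a [ribbonSpec()].
#' @param count number of ribbons.
#' @return mass in grams.
#' @export
ribbonMass <- function(spec, count) {
  slats <- spec$length_nm / spec$delta
  count * slats * spec$slat_nt * spec$nt_mass / AVOGADRO
}

#' Endpoint spontaneous nucleation rate
#'
#' Ribbon concentration accumulated over a nucleation phase of
#' \code{duration_h} hours corresponds to a mean rate
#' \code{conc / (duration_h * 3600)}: 200 fM over 100 h is ~0.6 aM/s.
#'
#' @param ribbon_conc ribbon concentration, mol/L.
#' @param duration_h nucleation-phase duration, hours.
#' @return nucleation rate, mol/L/s.
#' @export
nucleationRateEndpoint <- function(ribbon_conc, duration_h) {
  if (any(duration_h <= 0)) stop("duration must be positive")
  ribbon_conc / (duration_h * 3600)
}

#' Gel lane table
#'
#' Assembles (and validates) a lane table for [unseededRateFromGel()]:
#' background-subtracted band intensities with loading metadata.
#'
#' @param role lane roles: \code{"unseeded"}, \code{"seeded_control"} or
#'   \code{"ladder"}.
#' @param intensity background-subtracted intensity, arbitrary units.
#' @param loaded_volume_uL volume loaded on the gel, uL.
#' @param reaction_volume_uL reaction volume, uL.
#' @param duration_h nucleation-phase duration, hours.
#' @param seed_conc seed concentration of control lanes, mol/L (NA
#'   elsewhere).
#' @return validated data.frame of lanes.
#' @export
gelLanes <- function(role, intensity, loaded_volume_uL = 4,
                     reaction_volume_uL = 4, duration_h = 16,
                     seed_conc = NA_real_) {
  if (!length(role))
    return(data.frame(role = character(), intensity = numeric(),
                      loaded_volume_uL = numeric(),
                      reaction_volume_uL = numeric(),
                      duration_h = numeric(), seed_conc = numeric(),
                      stringsAsFactors = FALSE))
  lanes <- data.frame(role = role, intensity = intensity,
                      loaded_volume_uL = loaded_volume_uL,
                      reaction_volume_uL = reaction_volume_uL,
                      duration_h = duration_h, seed_conc = seed_conc,
                      stringsAsFactors = FALSE)
  if (!all(lanes$role %in% c("unseeded", "seeded_control", "ladder")))
    stop("unknown lane role")
  if (any(lanes$intensity < 0)) stop("intensities must be non-negative")
  if (any(lanes$loaded_volume_uL <= 0) || any(lanes$reaction_volume_uL <= 0))
    stop("volumes must be positive")
  lanes
}

#' Spontaneous nucleation rate from gel densitometry
#'
#' Two-step protocol quantification: ribbon concentration in each unseeded
#' lane is the intensity ratio to a seeded control lane of known seed
#' concentration (intensities normalized per loaded volume; seed-to-ribbon
#' conversion assumed complete by default), converted to a nucleation rate
#' over the nucleation-phase duration.  Lanes whose implied concentration
#' falls below the detection floor never yield a point estimate: they are
#' censored and reported as an upper bound at the floor.
#'
#' @param lanes a [gelLanes()] table with exactly one
#'   \code{"seeded_control"} lane (known \code{seed_conc}) and at least one
#'   \code{"unseeded"} lane.
#' @param nucleation_h nucleation-phase duration used for the rate; defaults
#'   to each lane's \code{duration_h}.
#' @param conversion_fraction seed-to-ribbon conversion of the control.
#' @param floor_conc detection floor as ribbon concentration, mol/L
#'   (~200 fM for a typical agarose lane).
#' @return data.frame per unseeded lane: \code{ribbon_conc},
#'   \code{rate} (mol/L/s), \code{censored}, and for censored lanes the
#'   floor-level \code{upper_bound} on the rate.
#' @export
unseededRateFromGel <- function(lanes, nucleation_h = NULL,
                                conversion_fraction = 1,
                                floor_conc = 200e-15) {
  ctrl <- lanes[lanes$role == "seeded_control", , drop = FALSE]
  uns <- lanes[lanes$role == "unseeded", , drop = FALSE]
  if (nrow(ctrl) != 1L)
    stop("exactly one seeded_control lane is required")
  if (!nrow(uns)) stop("at least one unseeded lane is required")
  if (is.na(ctrl$seed_conc)) stop("the control lane needs a known seed_conc")
  if (ctrl$intensity <= 0) stop("control intensity must be positive")
  ctrlConc <- ribbonCountFromSeeds(ctrl$seed_conc, conversion_fraction)
  # intensity per loaded volume is proportional to ribbon concentration
  scale <- ctrl$intensity / ctrl$loaded_volume_uL / ctrlConc
  conc <- uns$intensity / uns$loaded_volume_uL / scale
  dur <- if (is.null(nucleation_h)) uns$duration_h else nucleation_h
  censored <- conc < floor_conc
  rate <- ifelse(censored, NA_real_, nucleationRateEndpoint(conc, dur))
  bound <- ifelse(censored, nucleationRateEndpoint(floor_conc, dur), NA_real_)
  data.frame(lane = rownames(uns), ribbon_conc = ifelse(censored, NA, conc),
             duration_h = dur, rate = rate, censored = censored,
             upper_bound = bound, floor_conc = floor_conc,
             stringsAsFactors = FALSE)
}
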