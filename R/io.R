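#' Read and write length-sample tables
#'
#' CSV schema: columns \code{condition}, \code{time_h}, \code{length_nm}.
#'
#' @param path CSV file path.
#' @return data.frame of length samples.
#' @export
readLengthSamples <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_h", "length_nm")
  if (!all(need %in% names(df)))
    stop("length-sample CSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$length_nm < 0)) stop("lengths must be non-negative")
  df
}

#' @rdname readLengthSamples
#' @param samples data.frame of length samples.
#' @export
writeLengthSamples <- function(samples, path) {
  utils::write.csv(samples[, c("condition", "time_h", "length_nm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read and write gel-lane tables
#'
#' CSV schema: \code{role}, \code{intensity}, \code{loaded_volume_uL},
#' \code{reaction_volume_uL}, \code{duration_h}, \code{seed_conc}.
#'
#' @param path CSV file path.
#' @return validated lane data.frame (see [gelLanes()]).
#' @export
readGelLanes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  gelLanes(role = df$role, intensity = df$intensity,
           loaded_volume_uL = df$loaded_volume_uL,
           reaction_volume_uL = df$reaction_volume_uL,
           duration_h = df$duration_h, seed_conc = df$seed_conc)
}

#' @rdname readGelLanes
#' @param lanes lane data.frame.
#' @export
writeGelLanes <- function(lanes, path) {
  utils::write.csv(lanes, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a landscape to JSON
#'
#' @param landscape a [NucleationLandscape-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLandscape <- function(landscape, path) {
  arch <- landscape@arch
  p <- landscape@params
  rec <- list(
    architecture = list(kind = arch@kind, n = arch@n,
                        circumference = if (is.na(arch@circumference)) NULL
                                        else arch@circumference),
    params = list(gMC = p@gMC, gSE = p@gSE, epsilon = p@epsilon,
                  concentration = p@concentration),
    eps = p@epsilon,
    barrier = landscape@barrier,
    critical_size = landscape@criticalSize,
    bonds_at_critical = landscape@bondsAtCritical,
    method = landscape@method,
    G_profile = landscape@Gprofile)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a barrier-versus-epsilon curve as CSV
#'
#' @param curve data.frame from [barrierVsEpsilon()].
#' @param path output path.
#' @export
writeBarrierCurve <- function(curve, path) {
  utils::write.csv(curve[, c("epsilon", "barrier", "critical_size")], path,
                   row.names = FALSE)
  invisible(path)
}
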