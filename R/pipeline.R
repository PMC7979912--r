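configDefaults <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    verbose = FALSE,
    stages = list("ktam"),
    ktam = list(kind = "CS", n = 6L, epsilon = 2, concentration = 1e-6,
                circumference = NULL, curve = FALSE, eps_max = 3,
                eps_steps = 61L),
    growth = list(v = 0.25, k_stall = 0, k_resume = 1e-3,
                  k_term = 1 / (12 * 3600), times_h = c(1, 2, 4, 8),
                  n_ribbons = 150L, input = NULL, fit = TRUE),
    quantify = list(input = NULL, nucleation_h = 12, floor_conc = 200e-15,
                    conversion = 1, true_J = 6e-19),
    design = list(n = 6L, bp_per_turn = 10.5, phase = 0L,
                  symmetry = "full", repeats = 1L, brush_length = 0L,
                  sticky_end_length = 0L),
    synth = list(preset = "optimal_fast"))
}

validateConfig <- function(cfg) {
  defaults <- configDefaults()
  problems <- character()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    problems <- c(problems,
                  paste0("unknown top-level key(s): ",
                         paste(unknown, collapse = ", ")))
  for (block in intersect(names(cfg), c("ktam", "growth", "quantify",
                                        "design", "synth"))) {
    bad <- setdiff(names(cfg[[block]]), names(defaults[[block]]))
    if (length(bad))
      problems <- c(problems,
                    paste0("unknown key(s) in '", block, "': ",
                           paste(bad, collapse = ", ")))
  }
  merged <- utils::modifyList(defaults, cfg)
  if (!is.null(cfg$stages)) {
    merged$stages <- as.list(unlist(cfg$stages))  # unnamed list: replace
    st <- unlist(cfg$stages)
    bad <- setdiff(st, c("ktam", "growth", "quantify", "design", "synth"))
    if (length(bad))
      problems <- c(problems, paste0("unknown stage(s): ",
                                     paste(bad, collapse = ", ")))
  }
  if (!is.null(merged$design$bp_per_turn) &&
      is.null(domainPattern(merged$design$bp_per_turn)))
    problems <- c(problems,
                  sprintf("design: bp_per_turn %.2f is unattainable with 5/6-nt half-turn domains",
                          merged$design$bp_per_turn))
  if (!is.null(merged$design$symmetry) &&
      !merged$design$symmetry %in% c("full", "n_pairs", "half_n_pairs"))
    problems <- c(problems, "design: unknown symmetry mode")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  merged
}

#' Load a pipeline run configuration
#'
#' YAML configuration with one block per stage; an empty file yields all
#' defaults.  Validation reports every problem (unknown keys, invalid
#' stage names, designer parameter violations), not just the first.
#'
#' @param path YAML file path.
#' @return validated configuration list with defaults applied.
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validateConfig(cfg)
}

#' @rdname loadRunConfig
#' @param config configuration list.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run pipeline stages
#'
#' Executes the requested stages with the given configuration, writing all
#' artifacts plus a manifest (configuration, package version, seeds; no
#' timestamps) into the output directory.  A run is idempotent: the same
#' configuration produces byte-identical manifests and artifacts.
#'
#' @param config configuration list (see [loadRunConfig()]); missing
#'   entries take defaults.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  artifacts <- character()
  addArtifact <- function(p) artifacts <<- c(artifacts, basename(p))

  for (stage in unlist(cfg$stages)) {
    say("running stage: ", stage)
    if (stage == "ktam") {
      k <- cfg$ktam
      arch <- if (k$kind == "CS") architecture("CS", n = k$n)
              else architecture(k$kind, circumference = k$circumference)
      p <- ktamParams(arch, epsilon = k$epsilon,
                      concentration = k$concentration)
      ls <- criticalNucleus(arch, p, max_size = 4L * arch@n + 4L)
      f <- file.path(cfg$out_dir, "ktam_landscape.json")
      writeLandscape(ls, f); addArtifact(f)
      if (isTRUE(k$curve)) {
        cur <- barrierVsEpsilon(arch, p,
                                seq(0, k$eps_max, length.out = k$eps_steps))
        f <- file.path(cfg$out_dir, "ktam_barrier_curve.csv")
        writeBarrierCurve(cur, f); addArtifact(f)
      }
    } else if (stage == "growth") {
      g <- cfg$growth
      if (is.null(g$input)) {
        p <- growthParams(v = g$v, k_stall = g$k_stall,
                          k_resume = g$k_resume, k_term = g$k_term)
        samples <- simulateRibbons(p, unlist(g$times_h),
                                   n_ribbons = g$n_ribbons,
                                   rng_seed = cfg$seed)
        f <- file.path(cfg$out_dir, "growth_lengths.csv")
        writeLengthSamples(samples, f); addArtifact(f)
      } else {
        samples <- readLengthSamples(g$input)
      }
      if (isTRUE(g$fit)) {
        fit <- fitGrowthModel(samples, rng_seed = cfg$seed)
        f <- file.path(cfg$out_dir, "growth_fit.json")
        jsonlite::write_json(
          list(estimates = as.list(fit@estimates),
               ci = list(vEff = as.numeric(fit@ci["vEff", ]),
                         kTerm = as.numeric(fit@ci["kTerm", ])),
               level = fit@level),
          f, auto_unbox = TRUE, digits = NA)
        addArtifact(f)
      }
    } else if (stage == "quantify") {
      q <- cfg$quantify
      lanes <- if (is.null(q$input))
        synthGelDataset(q$true_J, nucleation_h = q$nucleation_h,
                        rng_seed = cfg$seed)
      else readGelLanes(q$input)
      res <- unseededRateFromGel(lanes, nucleation_h = q$nucleation_h,
                                 conversion_fraction = q$conversion,
                                 floor_conc = q$floor_conc)
      f <- file.path(cfg$out_dir, "nucleation_rates.json")
      jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA,
                           na = "null")
      addArtifact(f)
    } else if (stage == "design") {
      d <- cfg$design
      bp <- buildBlueprint(domainLayout(d$n, d$bp_per_turn, d$phase),
                           d$symmetry)
      bp <- assignSequences(bp, rng_seed = cfg$seed)
      if (d$brush_length > 0L || d$sticky_end_length > 0L)
        bp <- decorateBlueprint(bp, brush_length = d$brush_length,
                                sticky_end_length = d$sticky_end_length)
      ex <- exportSequences(bp, cfg$out_dir, "slats", repeats = d$repeats)
      addArtifact(ex$fasta); addArtifact(ex$plate_csv)
    } else if (stage == "synth") {
      b <- scenarioPresets(cfg$synth$preset, rng_seed = cfg$seed)
      if (nrow(b@lengthSamples)) {
        f <- file.path(cfg$out_dir, "synth_lengths.csv")
        writeLengthSamples(b@lengthSamples, f); addArtifact(f)
      }
      if (nrow(b@gelLanes)) {
        f <- file.path(cfg$out_dir, "synth_gel_lanes.csv")
        writeGelLanes(b@gelLanes, f); addArtifact(f)
      }
      f <- file.path(cfg$out_dir, "synth_manifest.json")
      jsonlite::write_json(
        list(preset = cfg$synth$preset, seed = cfg$seed,
             true_params = list(v = b@trueParams@v,
                                k_stall = b@trueParams@kStall,
                                k_resume = b@trueParams@kResume,
                                k_term = b@trueParams@kTerm,
                                J = b@trueParams@J),
             noise_model = b@noiseModel),
        f, auto_unbox = TRUE, digits = NA)
      addArtifact(f)
    }
  }
  manifest <- list(package = "crisscross",
                   version = as.character(utils::packageVersion("crisscross")),
                   seed = cfg$seed,
                   config = cfg,
                   artifacts = sort(unique(artifacts)))
  mf <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
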