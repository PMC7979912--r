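#' Seeded growth-model parameters
#'
#' @param v intrinsic growth velocity, nm/s.
#' @param k_stall,k_resume stall/resume rates, 1/s.
#' @param k_term absorbing termination rate, 1/s.
#' @param J spontaneous nucleation rate, mol/L/s.
#' @param seed_conc seed concentration, mol/L.
#' @param slat_conc per-slat monomer concentration, mol/L.
#' @param delta extension per added slat, nm.
#' @return a [GrowthParams-class].
#' @examples
#' growthParams(v = 0.25, k_term = 1 / (12 * 3600))
#' @export
growthParams <- function(v = 0.25, k_stall = 0, k_resume = 1e-3, k_term = 0,
                         J = 0, seed_conc = 2e-9, slat_conc = 1e-6,
                         delta = 1.5) {
  new("GrowthParams", v = v, kStall = k_stall, kResume = k_resume,
      kTerm = k_term, J = J, seedConc = seed_conc, slatConc = slat_conc,
      delta = delta)
}

# growing-time of one ribbon over [0, tmax], evaluated at sorted times;
# start state drawn from the stationary growing/stalled mixture so the
# analytic mean is exact at all t.
simulateOneRibbon <- function(params, times_s) {
  v <- params@v; ks <- params@kStall; kr <- params@kResume
  tmax <- times_s[length(times_s)]
  tterm <- if (params@kTerm > 0) stats::rexp(1, params@kTerm) else Inf
  horizon <- min(tmax, tterm)
  if (ks == 0) return(v * pmin(times_s, horizon))
  growing <- stats::runif(1) < kr / (kr + ks)
  t <- 0; gtime <- 0
  gAt <- numeric(length(times_s)); nextIdx <- 1L
  while (t < horizon) {
    rate <- if (growing) ks else kr
    dt <- stats::rexp(1, rate)
    tEnd <- min(t + dt, horizon)
    while (nextIdx <= length(times_s) && times_s[nextIdx] <= tEnd) {
      gAt[nextIdx] <- gtime + if (growing) times_s[nextIdx] - t else 0
      nextIdx <- nextIdx + 1L
    }
    if (growing) gtime <- gtime + (tEnd - t)
    t <- tEnd
    growing <- !growing
  }
  while (nextIdx <= length(times_s)) {   # terminated before these times
    gAt[nextIdx] <- gtime
    nextIdx <- nextIdx + 1L
  }
  v * gAt
}

#' Simulate seeded ribbon growth
#'
#' Continuous-time Markov simulation of ribbon elongation: each ribbon end
#' switches between growing and stalled states (rates \code{kStall},
#' \code{kResume}), elongates at \code{v} nm/s while growing, and stops
#' permanently on termination (rate \code{kTerm}).  One cohort of ribbons is
#' followed and its lengths recorded at each requested time, mimicking
#' repeated TEM sampling of one reaction.  With
#' \code{nucleation = "poisson"} ribbon starts are staggered uniformly over
#' the observation window (spontaneous nucleation at a constant rate)
#' instead of synchronized at t = 0 (seeded growth).
#'
#' @param params a [GrowthParams-class].
#' @param times_h observation times, hours (increasing).
#' @param n_ribbons cohort size.
#' @param rng_seed integer seed; identical seeds give identical samples.
#' @param nucleation \code{"seeded"} or \code{"poisson"}.
#' @param condition label attached to the output.
#' @return data.frame (condition, time_h, length_nm).
#' @examples
#' p <- growthParams(v = 0.25, k_term = 1 / (12 * 3600))
#' head(simulateRibbons(p, c(1, 2, 4, 8), n_ribbons = 10, rng_seed = 1))
#' @export
simulateRibbons <- function(params, times_h, n_ribbons = 150L, rng_seed = 1L,
                            nucleation = c("seeded", "poisson"),
                            condition = "sim") {
  nucleation <- match.arg(nucleation)
  if (n_ribbons < 1L) stop("n_ribbons must be at least 1")
  if (is.unsorted(times_h, strictly = TRUE))
    stop("times must be strictly increasing")
  times_s <- times_h * 3600
  set.seed(rng_seed)
  L <- matrix(0, nrow = n_ribbons, ncol = length(times_s))
  for (i in seq_len(n_ribbons)) {
    if (nucleation == "seeded") {
      L[i, ] <- simulateOneRibbon(params, times_s)
    } else {
      # staggered start: conditional on being present at each time, a
      # spontaneously nucleated ribbon started uniformly in [0, t]
      t0 <- stats::runif(1) * times_s[length(times_s)]
      age <- pmax(times_s - t0, 0)
      pos <- age > 0
      if (any(pos))
        L[i, pos] <- simulateOneRibbon(params, age[pos])
    }
  }
  data.frame(condition = condition,
             time_h = rep(times_h, each = n_ribbons),
             length_nm = as.vector(L))
}

#' Analytic mean and spread of seeded ribbon length
#'
#' Closed-form solution of the growth model:
#' \code{mean(t) = (vEff / kTerm) (1 - exp(-kTerm t))}, reducing to
#' \code{vEff t} as \code{kTerm -> 0}; the effective velocity is
#' \code{vEff = v kResume / (kResume + kStall)}.  The standard deviation is
#' from the termination-dominated reduced model
#' (\code{L = vEff min(t, T)}, T exponential), the dominant spread for
#' seeded growth.
#'
#' @param params a [GrowthParams-class].
#' @param t_h times in hours.
#' @return data.frame (time_h, mean_nm, sd_nm).
#' @export
analyticMeanLength <- function(params, t_h) {
  if (any(t_h < 0)) stop("t must be non-negative")
  t <- t_h * 3600
  veff <- effectiveVelocity(params)
  k <- params@kTerm
  if (k == 0) {
    mean_nm <- veff * t
    sd_nm <- rep(0, length(t))
  } else {
    mean_nm <- veff / k * (1 - exp(-k * t))
    m2 <- veff^2 * (2 / k^2 - exp(-k * t) * (2 * t / k + 2 / k^2))
    sd_nm <- sqrt(pmax(m2 - mean_nm^2, 0))
  }
  data.frame(time_h = t_h, mean_nm = mean_nm, sd_nm = sd_nm)
}

meanCurve <- function(t_s, veff, kterm) {
  ifelse(kterm * t_s < 1e-12, veff * t_s,
         veff / kterm * (1 - exp(-kterm * t_s)))
}

fitMeans <- function(tab) {
  # weighted least squares on per-timepoint means, log-parameterized
  t_s <- tab$time_h * 3600
  w <- 1 / pmax(tab$se, 1e-6 * max(tab$mean))^2
  v0 <- max(tab$mean[1] / t_s[1], 1e-9)
  k0 <- 1 / max(t_s)
  fit <- minpack.lm::nlsLM(
    mean ~ meanCurve(t_s, exp(lv), exp(lk)),
    data = list(mean = tab$mean, t_s = t_s),
    start = list(lv = log(v0), lk = log(k0)),
    weights = w,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  c(vEff = unname(exp(cf["lv"])), kTerm = unname(exp(cf["lk"])))
}

#' Fit the growth model to length-versus-time data
#'
#' Weighted least squares of the analytic mean-length solution to
#' per-timepoint mean lengths (weights = inverse squared standard error of
#' the mean), estimating the effective growth velocity \code{vEff} (nm/s)
#' and termination rate \code{kTerm} (1/s), with bootstrap percentile
#' confidence intervals (lengths resampled within each timepoint).
#'
#' @param samples data.frame (condition, time_h, length_nm) with at least
#'   3 distinct timepoints.
#' @param n_boot bootstrap resamples for the confidence intervals.
#' @param level confidence level.
#' @param ci_type \code{"normal"} (estimate +/- z times the bootstrap
#'   standard error; default, well-calibrated for these near-symmetric
#'   estimators) or \code{"percentile"}.
#' @param rng_seed seed for the bootstrap.
#' @return a [GrowthFit-class].
#' @export
fitGrowthModel <- function(samples, n_boot = 200L, level = 0.95,
                           ci_type = c("normal", "percentile"),
                           rng_seed = 1729L) {
  ci_type <- match.arg(ci_type)
  if (!all(c("time_h", "length_nm") %in% names(samples)))
    stop("samples must have columns time_h and length_nm")
  if (length(unique(samples$time_h)) < 3L)
    stop("at least 3 distinct timepoints are required")
  if (all(samples$length_nm == 0))
    stop("degenerate input: all lengths are zero")
  sp <- split(samples$length_nm, samples$time_h)
  tab <- data.frame(time_h = as.numeric(names(sp)),
                    n = vapply(sp, length, integer(1)),
                    mean = vapply(sp, mean, numeric(1)),
                    se = vapply(sp, function(x)
                      stats::sd(x) / sqrt(length(x)), numeric(1)))
  tab$se[!is.finite(tab$se) | tab$se == 0] <- 1e-6 * max(tab$mean)
  est <- fitMeans(tab)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("vEff", "kTerm")))
  if (n_boot > 0) {
    set.seed(rng_seed)
    for (b in seq_len(n_boot)) {
      rtab <- tab
      for (i in seq_along(sp)) {
        x <- sample(sp[[i]], replace = TRUE)
        rtab$mean[i] <- mean(x)
        rtab$se[i] <- stats::sd(x) / sqrt(length(x))
      }
      rtab$se[!is.finite(rtab$se) | rtab$se == 0] <- 1e-6 * max(rtab$mean)
      boot[b, ] <- tryCatch(fitMeans(rtab), error = function(e) c(NA, NA))
    }
  }
  a <- (1 - level) / 2
  if (ci_type == "percentile") {
    ci <- t(apply(boot, 2, stats::quantile, probs = c(a, 1 - a),
                  na.rm = TRUE))
  } else {
    z <- stats::qnorm(1 - a)
    bs <- apply(boot, 2, stats::sd, na.rm = TRUE)
    ci <- cbind(est - z * bs, est + z * bs)
  }
  dimnames(ci) <- list(c("vEff", "kTerm"), c("lower", "upper"))
  new("GrowthFit", estimates = est, ci = ci, level = level, boot = boot,
      data = tab,
      fitted = meanCurve(tab$time_h * 3600, est["vEff"], est["kTerm"]))
}

#' Polydispersity index
#'
#' Weight-average over number-average length:
#' \code{PDI = mean(L^2) / mean(L)^2}, 1 for a monodisperse population and
#' 2 in expectation for exponentially distributed lengths.
#'
#' @param lengths non-negative lengths with at least one positive value.
#' @return PDI (>= 1 in expectation for any distribution).
#' @examples
#' polydispersityIndex(rep(5, 10))  # 1
#' @export
polydispersityIndex <- function(lengths) {
  if (!length(lengths) || any(lengths < 0))
    stop("lengths must be non-empty and non-negative")
  if (all(lengths == 0)) stop("all lengths are zero")
  mean(lengths^2) / mean(lengths)^2
}

#' Second-order rate constant from growth velocity
#'
#' \code{k_on = vEff / (delta * slat_conc)}: each slat addition extends the
#' ribbon by \code{delta} nm, so a velocity of 0.75 nm/s at 1 uM slats and
#' 1.5 nm/slat corresponds to 0.5e6 per molar per second.
#'
#' @param v_eff effective velocity, nm/s.
#' @param slat_conc per-slat concentration, mol/L.
#' @param delta nm per slat.
#' @return on-rate in 1/(M s).
#' @export
rateConstantFromVelocity <- function(v_eff, slat_conc, delta = 1.5) {
  if (slat_conc <= 0) stop("slat_conc must be positive")
  if (delta <= 0) stop("delta must be positive")
  v_eff / (delta * slat_conc)
}

#' @rdname rateConstantFromVelocity
#' @param k_on second-order rate constant, 1/(M s).
#' @export
velocityFromRateConstant <- function(k_on, slat_conc, delta = 1.5) {
  if (slat_conc <= 0) stop("slat_conc must be positive")
  k_on * delta * slat_conc
}

#' Ribbon concentration from seeds
#'
#' Under near-complete seed conversion the ribbon copy number is controlled
#' precisely by the number of starting seeds:
#' \code{ribbons = seed_conc * conversion_fraction}.
#'
#' @param seed_conc seed concentration, mol/L.
#' @param conversion_fraction fraction of seeds converted to ribbons.
#' @return ribbon concentration, mol/L.
#' @export
ribbonCountFromSeeds <- function(seed_conc, conversion_fraction = 1) {
  if (any(conversion_fraction < 0 | conversion_fraction > 1))
    stop("conversion_fraction must be in [0, 1]")
  seed_conc * conversion_fraction
}
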