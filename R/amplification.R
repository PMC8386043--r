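#' Amplification curve analysis
#'
#' @section Amplification curve analysis:
#' The analysis of one run proceeds in five steps: (1) per-reaction baseline
#' estimation by iterative slope bisection on the exponential phase, (2)
#' identification of the exponential phase (continuous fluorescence increase
#' up to the second-derivative maximum), (3) per-assay PCR efficiency from a
#' window-of-linearity placed to minimize the coefficient of variation of the
#' individual efficiencies, with optional outlier screening, (4) common
#' quantification threshold and Cq calling on an idealized curve built from
#' the assay efficiency, and (5) the efficiency-corrected target quantity
#' N0 = Nq / E^Cq.
#' @name amplification
#' @keywords internal
NULL

# ---- low-level numeric helpers ------------------------------------------

# Least-squares slope/intercept of y on x without lm() overhead.
ls_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  slope <- sum(dx * (y - my)) / sum(dx * dx)
  c(slope = slope, intercept = my - slope * mx)
}

# Three-point moving mean, endpoints copied.
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  s <- x
  s[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  s
}

# Cycle index of the maximum central second difference of the smoothed
# series; ties broken to the earlier cycle. NA when n < 3.
second_derivative_max <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_integer_)
  s <- smooth3(x)
  d2 <- s[3:n] - 2 * s[2:(n - 1)] + s[1:(n - 2)]
  as.integer(which.max(d2) + 1L)
}

# First index of the maximal strictly-increasing run that ends at `end`.
run_start_before <- function(x, end) {
  start <- end
  while (start > 1 && x[start] > x[start - 1L]) start <- start - 1L
  as.integer(start)
}

geometric_mean <- function(x) exp(mean(log(x)))

# ---- detection ----------------------------------------------------------

#' Classify a raw curve as amplified, not amplified, or lacking a plateau
#'
#' A reaction is called non-amplifying when the total fluorescence rise above
#' the early-cycle level stays below a noise-scaled multiple (ground-phase
#' noise is the standard deviation of the first-six-cycle differences). A
#' rising curve whose last cycles still climb steeply (mean slope of the last
#' five cycles above a quarter of the maximum per-cycle slope) lacks a
#' plateau. Both cut-offs are configurable; see [amp_config()].
#'
#' @param fluor Raw fluorescence series (one value per cycle).
#' @param config An [amp_config()].
#' @return One of `"amplified"`, `"not_amplified"`, `"no_plateau"`.
#' @export
#' @examples
#' detect_amplification(rep(50, 40))                    # flat: not amplified
detect_amplification <- function(fluor, config = amp_config()) {
  n <- length(fluor)
  if (n < 10) stop("insufficient data: at least 10 cycles required, got ", n)
  noise <- sd(diff(fluor[1:6]))
  noise <- max(noise, 1e-9 * max(abs(fluor), 1))
  rise <- max(fluor) - median(fluor[1:5])
  if (rise < config$no_amp_factor * noise) return("not_amplified")
  slopes <- diff(fluor)
  if (mean(tail(slopes, 5)) > config$plateau_slope_frac * max(slopes))
    return("no_plateau")
  "amplified"
}

# ---- baseline -----------------------------------------------------------

# Exponential-phase window used for the baseline half-slope comparison.
# Ground-phase cycles are excluded via the continuous-increase start; the
# top of the phase is capped two doublings below the SDM level because the
# efficiency already declines as the curve approaches the second-derivative
# maximum and the half-slope comparison must act on the log-linear segment.
baseline_window <- function(corrected, min_pts) {
  sdm <- second_derivative_max(corrected)
  if (is.na(sdm)) return(NULL)
  start <- run_start_before(corrected, sdm)
  w <- seq.int(start, sdm)
  w <- w[corrected[w] > 0]
  if (length(w) < min_pts) return(NULL)
  for (cap_frac in c(0.25, 0.5, 1)) {
    wc <- w[corrected[w] <= corrected[sdm] * cap_frac]
    if (length(wc) >= min_pts) return(wc)
  }
  w
}

# Difference (lower-half slope - upper-half slope) of log10 fluorescence vs
# cycle for a candidate baseline; NULL when no usable window exists. Both
# half fits use the multiplicative noise-model weights so that cycles close
# to the ground level, whose log values are noise-dominated and skewed, do
# not steer the comparison.
baseline_half_slopes <- function(fluor, b, min_pts) {
  corrected <- fluor - b
  w <- baseline_window(corrected, min_pts)
  if (is.null(w)) return(NULL)
  nlow <- ceiling(length(w) / 2)      # odd counts: middle cycle to lower half
  low <- w[seq_len(nlow)]
  up <- w[(nlow + 1L):length(w)]
  if (length(up) < 2 || length(low) < 2) return(NULL)
  wt <- noise_model_weights(corrected, max(b, 0))
  s_low <- wls_fit(low, log10(corrected[low]), wt[low])[["slope"]]
  s_up <- wls_fit(up, log10(corrected[up]), wt[up])[["slope"]]
  list(diff = s_low - s_up, s_low = s_low, s_up = s_up)
}

#' Estimate the baseline fluorescence of one reaction
#'
#' Iterative bisection on the slopes of the exponential phase: starting from
#' a deliberately high candidate, the baseline is lowered step-wise until the
#' slope of the upper half of the log-linear exponential phase becomes
#' steeper than that of the lower half (the candidate has become too low),
#' then raised one step, the step halved, and so on until the two half-slopes
#' differ by less than `config$slope_diff_tol` (on log10 fluorescence per
#' cycle). Ground-phase cycles are never used in the fits. Failure to find a
#' baseline that straightens the exponential phase is reported as a baseline
#' error.
#'
#' @param fluor Raw fluorescence series.
#' @param config An [amp_config()].
#' @return A list of class `baseline_fit`: `baseline`, `status` (`"ok"`,
#'   `"baseline_error"` or `"no_amplification"`), `corrected` (raw minus
#'   baseline) and `iterations`.
#' @export
#' @examples
#' f <- pmin(50 + 0.01 * 1.9^(1:40), 50 + 5000)
#' estimate_baseline(f)$baseline   # close to 50
estimate_baseline <- function(fluor, config = amp_config()) {
  min_pts <- max(4L, config$min_window_cycles + 1L)
  fail <- function(b, it) structure(list(baseline = b, status = "baseline_error",
                                         corrected = fluor - b, iterations = it),
                                    class = "baseline_fit")
  # candidate exponential region on the raw curve seeds the search
  sdm0 <- second_derivative_max(fluor)
  if (is.na(sdm0)) return(fail(0, 0L))
  start0 <- run_start_before(fluor, sdm0)
  if (sdm0 - start0 + 1L < min_pts) return(fail(0, 0L))
  b <- 0.99 * min(fluor[start0:sdm0])
  step <- if (abs(b) > 0) abs(b) / 10 else diff(range(fluor)) / 100
  cap <- config$baseline_max_iter
  it <- 0L

  eval_b <- function(b) baseline_half_slopes(fluor, b, min_pts)

  # Bring the candidate into the "too high" regime (lower slope steeper).
  r <- eval_b(b)
  while ((is.null(r) || r$diff <= 0) && it < cap) {
    if (!is.null(r) && r$diff <= 0) b <- b + step else b <- b - step
    it <- it + 1L
    r <- eval_b(b)
  }
  if (is.null(r) || r$diff <= 0) return(fail(b, it))
  # Step-wise lowering until the upper half becomes steeper.
  while (!is.null(r) && r$diff > 0 && it < cap) {
    b <- b - step
    it <- it + 1L
    r <- eval_b(b)
  }
  if (it >= cap && (is.null(r) || r$diff > 0)) return(fail(b, it))
  # One step back up, halve the step, iterate to convergence. On noisy data
  # the slope difference is not a continuous function of the candidate (the
  # set of usable cycles changes with it), so the slope criterion may be
  # unattainable; the search is then accepted once the candidate interval
  # has collapsed, provided a sign change was bracketed.
  b <- b + step
  converged <- FALSE
  bracketed <- FALSE
  b_scale <- max(abs(b), 1)
  while (it < cap) {
    step <- step / 2
    r <- eval_b(b)
    it <- it + 1L
    if (!is.null(r) && abs(r$diff) < config$slope_diff_tol) {
      converged <- TRUE
      break
    }
    if (!is.null(r) && r$diff < 0) bracketed <- TRUE
    if (bracketed && step < 1e-9 * b_scale) {
      converged <- TRUE
      break
    }
    if (is.null(r) || r$diff > 0) b <- b - step else b <- b + step
  }
  r <- eval_b(b)
  ok <- converged && !is.null(r) && r$s_low > 0 && r$s_up > 0
  structure(list(baseline = b,
                 status = if (ok) "ok" else "baseline_error",
                 corrected = fluor - b,
                 iterations = it),
            class = "baseline_fit")
}

# ---- exponential phase --------------------------------------------------

#' Locate the exponential phase of a baseline-corrected curve
#'
#' The phase starts at the first cycle beginning the maximal run of strictly
#' increasing fluorescence that persists to the second-derivative maximum
#' (SDM), and ends at the SDM. The centre of the phase is the geometric mean
#' of the corrected fluorescence over the phase; the corresponding fractional
#' cycle is read off the log-linear fit through the phase.
#'
#' @param corrected Baseline-corrected fluorescence series.
#' @param config An [amp_config()].
#' @param status Upstream [detect_amplification()] verdict; for
#'   `"no_plateau"` curves the phase is extended to the last cycle.
#' @param baseline The subtracted baseline level; when given, the centre fit
#'   uses the multiplicative noise-model weights so that ground-level cycles
#'   (whose corrected values are dominated by residual baseline error) do
#'   not bend the log-linear anchor.
#' @return A list of class `exp_phase`: `start_cycle`, `sdm_cycle`,
#'   `centre_cycle`, `centre_fluor`, `range_lo`, `range_hi` and `status`
#'   (`"ok"` or `"no_amplification"` when the increasing run is shorter than
#'   `config$min_window_cycles`).
#' @export
find_exponential_phase <- function(corrected, config = amp_config(),
                                   status = "amplified", baseline = NULL) {
  n <- length(corrected)
  sdm <- second_derivative_max(corrected)
  if (identical(status, "no_plateau")) sdm <- n
  if (is.na(sdm))
    return(structure(list(status = "no_amplification"), class = "exp_phase"))
  start <- run_start_before(corrected, sdm)
  w <- seq.int(start, sdm)
  w <- w[corrected[w] > 0]
  if (length(w) < config$min_window_cycles)
    return(structure(list(status = "no_amplification"), class = "exp_phase"))
  # centre fit: stay below the transition (two doublings under the SDM
  # level) and weight out ground-level cycles
  wc <- w[corrected[w] <= corrected[sdm] * 0.25]
  if (length(wc) < config$min_window_cycles) wc <- w
  wt <- noise_model_weights(corrected[wc], baseline)
  centre_fluor <- exp(sum(wt * log(corrected[wc])) / sum(wt))
  fit <- wls_fit(wc, log10(corrected[wc]), wt)
  centre_cycle <- (log10(centre_fluor) - fit[["intercept"]]) / fit[["slope"]]
  structure(list(start_cycle = as.integer(min(w)),
                 sdm_cycle = as.integer(sdm),
                 centre_cycle = centre_cycle,
                 centre_fluor = centre_fluor,
                 range_lo = min(corrected[w]),
                 range_hi = max(corrected[w]),
                 status = "ok"),
            class = "exp_phase")
}

# ---- efficiency fitting -------------------------------------------------

#' Fit a log-linear model to a cycle window and derive the PCR efficiency
#'
#' Least squares of log10(corrected fluorescence) on cycle number; the
#' efficiency is `10^slope`. The window must span at least
#' `config$min_window_cycles` consecutive cycles of strictly positive
#' fluorescence. Without `weights` the fit is ordinary least squares; the
#' assay-level machinery supplies inverse-variance weights derived from the
#' multiplicative noise model (see [optimize_window_of_linearity()]).
#'
#' @param corrected Baseline-corrected fluorescence series.
#' @param window Integer vector of consecutive cycle indices.
#' @param config An [amp_config()].
#' @param weights Optional non-negative per-cycle weights (same length as
#'   `window`).
#' @return A list: `slope`, `intercept`, `efficiency`, `window`.
#' @export
#' @examples
#' f <- 0.02 * 1.9^(1:40)
#' fit_log_linear(f, 5:9)$efficiency   # exactly 1.9
fit_log_linear <- function(corrected, window, config = amp_config(),
                           weights = NULL) {
  if (length(window) < config$min_window_cycles)
    stop("window invalid: spans ", length(window), " cycles, need at least ",
         config$min_window_cycles)
  if (any(diff(window) != 1))
    stop("window invalid: cycles must be consecutive")
  y <- corrected[window]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("window invalid: non-positive fluorescence inside the window")
  if (is.null(weights)) {
    fit <- ls_fit(window, log10(y))
  } else {
    stopifnot(length(weights) == length(window), all(weights >= 0))
    fit <- wls_fit(window, log10(y), weights)
  }
  list(slope = fit[["slope"]], intercept = fit[["intercept"]],
       efficiency = 10^fit[["slope"]], window = window)
}

# Weighted least-squares slope/intercept.
wls_fit <- function(x, y, w) {
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  c(slope = slope, intercept = ym - slope * xm)
}

# Inverse-variance weights for log fluorescence under multiplicative noise
# of the raw signal: sd(log f) is proportional to (f + B) / f with baseline
# B, so cycles close to the ground-phase level carry almost no weight.
noise_model_weights <- function(f, baseline) {
  if (is.null(baseline) || !is.finite(baseline) || baseline <= 0)
    return(rep(1, length(f)))
  (f / (f + baseline))^2
}

# Longest consecutive run of cycles (up to the SDM) whose log10 corrected
# fluorescence lies inside [lo, up]; NULL when shorter than min_cycles.
band_window <- function(corrected, phase, lo, up, min_cycles) {
  idx <- seq_len(phase$sdm_cycle)
  l <- suppressWarnings(log10(corrected[idx]))
  inside <- which(is.finite(l) & l >= lo & l <= up)
  if (length(inside) < min_cycles) return(NULL)
  runs <- split(inside, cumsum(c(1L, diff(inside) != 1L)))
  best <- runs[[which.max(lengths(runs))]]
  if (length(best) < min_cycles) return(NULL)
  best
}

#' Position the window-of-linearity of one assay
#'
#' The window is a fixed-width band on the log10 fluorescence axis (default
#' six doublings tall). Starting from an initial high position — set a few
#' doublings below the highest exponential-phase top, since the cycles just
#' under the second-derivative maximum already sit in the transition phase —
#' the band is stepped downward; at every position each reaction's
#' efficiency is fitted from the consecutive cycles whose corrected
#' fluorescence falls inside the band, weighted by the multiplicative noise
#' model when the reaction's baseline is known (cycles near the ground-phase
#' level carry almost no slope information). The highest position whose
#' coefficient of variation (sd / mean) of the individual efficiencies is
#' not meaningfully above the minimum is kept.
#'
#' @param assay_curves A named list (one element per reaction) of lists with
#'   elements `corrected` (numeric series), `phase` (an `exp_phase`) and
#'   optionally `baseline` (for the noise-model weights).
#' @param config An [amp_config()].
#' @param target_id Assay label carried into the result.
#' @return A list of class `assay_result`: `target_id`, `window` (upper and
#'   lower fluorescence bounds), `efficiencies` (named), `included` (logical
#'   mask, all `TRUE` here), `e_tar`, `cv`, `flags`, and `windows` (the
#'   per-reaction cycle windows actually used).
#' @export
optimize_window_of_linearity <- function(assay_curves, config = amp_config(),
                                         target_id = "") {
  stopifnot(length(assay_curves) >= 1)
  W <- config$wol_band_width
  mc <- config$min_window_cycles
  wells <- names(assay_curves)
  if (is.null(wells)) wells <- as.character(seq_along(assay_curves))

  phase_log_range <- function(ac) {
    log10(c(ac$phase$range_lo, ac$phase$range_hi))
  }
  flags <- character(0)

  fit_band <- function(ac, up) {
    w <- band_window(ac$corrected, ac$phase, up - W, up, mc)
    if (is.null(w)) return(NULL)
    fit_log_linear(ac$corrected, w, config,
                   weights = noise_model_weights(ac$corrected[w], ac$baseline))
  }
  full_phase_fit <- function(ac) {
    w <- seq.int(ac$phase$start_cycle, ac$phase$sdm_cycle)
    w <- w[ac$corrected[w] > 0]
    fit_log_linear(ac$corrected, w, config,
                   weights = noise_model_weights(ac$corrected[w], ac$baseline))
  }

  if (length(assay_curves) == 1L) {
    ac <- assay_curves[[1]]
    up <- log10(ac$phase$range_hi) - config$wol_top_gap
    if (up <= log10(max(ac$phase$range_lo, 1e-300)))
      up <- log10(ac$phase$range_hi)
    fit <- fit_band(ac, up)
    if (is.null(fit)) fit <- full_phase_fit(ac)
    eff <- setNames(fit$efficiency, wells)
    return(structure(list(target_id = target_id,
                          window = c(upper_fluor = 10^up, lower_fluor = 10^(up - W)),
                          efficiencies = eff,
                          included = setNames(TRUE, wells),
                          e_tar = fit$efficiency, cv = NA_real_,
                          flags = "single_reaction",
                          windows = setNames(list(fit$window), wells)),
                     class = "assay_result"))
  }

  ranges <- vapply(assay_curves, phase_log_range, numeric(2))
  # The scan starts wol_top_gap below the highest phase top: the cycles just
  # under the second-derivative maximum are already in the transition phase
  # and would bias the fitted efficiencies downward.
  u0 <- max(ranges[2, ]) - config$wol_top_gap
  floor_u <- min(ranges[1, ]) + W
  if (u0 <= floor_u) u0 <- max(ranges[2, ])
  step <- W * config$wol_step_frac
  uppers <- if (u0 <= floor_u) u0 else seq(u0, floor_u, by = -step)

  n_rx <- length(assay_curves)
  eff_mat <- matrix(NA_real_, nrow = length(uppers), ncol = n_rx)
  win_list <- vector("list", length(uppers))
  for (i in seq_along(uppers)) {
    fits <- lapply(assay_curves, fit_band, up = uppers[i])
    eff_mat[i, ] <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$efficiency,
                           numeric(1))
    win_list[[i]] <- lapply(fits, function(f) if (is.null(f)) NULL else f$window)
  }
  n_ok <- rowSums(!is.na(eff_mat))
  pool <- which(n_ok == n_rx)
  if (!length(pool)) {
    pool <- which(n_ok >= 2)
    if (!length(pool))
      stop("assay-level error: no window-of-linearity position provides at ",
           "least ", mc, " cycles for two or more reactions",
           if (nzchar(target_id)) paste0(" (target ", target_id, ")"))
    flags <- c(flags, "partial_window")
  }
  cvs <- apply(eff_mat[pool, , drop = FALSE], 1, function(e) {
    e <- e[!is.na(e)]
    sd(e) / mean(e)
  })
  # highest band whose CV is not meaningfully worse than the minimum: the
  # downward shift stops once it no longer improves the CV
  ok_cv <- cvs <= (1 + config$wol_cv_tol) * min(cvs)
  best <- pool[which(ok_cv)[1]]
  up <- uppers[best]
  eff <- eff_mat[best, ]
  wins <- win_list[[best]]
  for (j in which(is.na(eff))) {        # fallback: reaction's own full phase
    f <- full_phase_fit(assay_curves[[j]])
    eff[j] <- f$efficiency
    wins[[j]] <- f$window
  }
  eff <- setNames(eff, wells)
  structure(list(target_id = target_id,
                 window = c(upper_fluor = 10^up, lower_fluor = 10^(up - W)),
                 efficiencies = eff,
                 included = setNames(rep(TRUE, n_rx), wells),
                 e_tar = mean(eff), cv = sd(eff) / mean(eff),
                 flags = flags,
                 windows = setNames(wins, wells)),
            class = "assay_result")
}

# ---- outlier screening --------------------------------------------------

# One-sided Grubbs critical value from the t distribution.
grubbs_critical <- function(n, alpha, two_sided = FALSE) {
  a <- if (two_sided) alpha / (2 * n) else alpha / n
  t2 <- qt(a, df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

# Adjusted Fisher-Pearson skewness coefficient.
sample_skewness <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Screen individual PCR efficiencies for outliers
#'
#' Two strategies. `"grubbs"`: the sample skewness directs a one-sided Grubbs
#' test at the extreme value on the skewed side (two-sided on the larger
#' deviation when the skewness is essentially zero); rejected values are
#' removed and the test repeated until no further rejection. `"fixed_band"`:
#' efficiencies outside median plus/minus `halfwidth` are excluded in one
#' pass. Fewer than three values, or an all-equal set, are always fully
#' included.
#'
#' @param efficiencies Numeric vector of individual PCR efficiencies.
#' @param mode `"grubbs"`, `"fixed_band"` or `"none"`.
#' @param alpha Significance level of the Grubbs test.
#' @param halfwidth Half-width of the fixed acceptance band.
#' @return Logical inclusion mask aligned with `efficiencies`.
#' @export
#' @examples
#' detect_efficiency_outliers(c(rep(1.80, 11), 1.95))
detect_efficiency_outliers <- function(efficiencies,
                                       mode = c("grubbs", "fixed_band", "none"),
                                       alpha = 0.05, halfwidth = 0.05) {
  mode <- match.arg(mode)
  n <- length(efficiencies)
  keep <- rep(TRUE, n)
  if (mode == "none" || n == 0) return(keep)
  if (mode == "fixed_band") {
    med <- median(efficiencies)
    return(abs(efficiencies - med) <= halfwidth)
  }
  repeat {
    idx <- which(keep)
    x <- efficiencies[idx]
    m <- length(x)
    if (m < 3) break
    s <- sd(x)
    if (s == 0) break
    skew <- sample_skewness(x)
    two_sided <- abs(skew) < 1e-8
    cand <- if (two_sided) {
      if (max(x) - mean(x) >= mean(x) - min(x)) which.max(x) else which.min(x)
    } else if (skew > 0) which.max(x) else which.min(x)
    g <- abs(x[cand] - mean(x)) / s
    if (g > grubbs_critical(m, alpha, two_sided)) {
      keep[idx[cand]] <- FALSE
    } else break
  }
  keep
}

#' Iterate window placement and outlier screening for one assay
#'
#' Alternates [optimize_window_of_linearity()] (on the included reactions)
#' with [detect_efficiency_outliers()] until the inclusion mask is stable.
#' Excluded reactions keep their individual efficiency, are flagged as
#' efficiency outliers, and still receive Cq and N0 downstream from the assay
#' mean efficiency. An oscillating mask is stopped after
#' `config$outlier_iter_cap` rounds, keeping the mask with the most
#' inclusions.
#'
#' @inheritParams optimize_window_of_linearity
#' @return An `assay_result` whose `included` mask marks the outliers and
#'   whose `e_tar`/`cv` are computed over the included reactions only.
#' @export
iterate_assay <- function(assay_curves, config = amp_config(), target_id = "") {
  wells <- names(assay_curves)
  if (is.null(wells)) {
    wells <- as.character(seq_along(assay_curves))
    names(assay_curves) <- wells
  }
  keep <- setNames(rep(TRUE, length(assay_curves)), wells)
  seen <- list()
  res <- NULL
  warned <- FALSE
  for (round in seq_len(config$outlier_iter_cap)) {
    res <- optimize_window_of_linearity(assay_curves[keep], config, target_id)
    eff_in <- res$efficiencies
    mask_in <- detect_efficiency_outliers(eff_in, config$outlier_mode,
                                          config$grubbs_alpha,
                                          config$fixed_band_halfwidth)
    new_keep <- keep
    new_keep[names(eff_in)[!mask_in]] <- FALSE
    if (identical(new_keep, keep)) break
    key <- paste(new_keep, collapse = "")
    if (key %in% seen) {            # oscillation: keep the largest mask
      warning("assay ", target_id, ": oscillating outlier mask; keeping the ",
              "mask with most inclusions")
      warned <- TRUE
      masks <- c(seen, list(key))
      sizes <- vapply(masks, function(k) sum(strsplit(k, "")[[1]] == "TRUE"),
                      numeric(1))
      best <- strsplit(masks[[which.max(sizes)]], "")[[1]] == "TRUE"
      keep <- setNames(best, wells)
      res <- optimize_window_of_linearity(assay_curves[keep], config, target_id)
      break
    }
    seen <- c(seen, paste(keep, collapse = ""))
    keep <- new_keep
  }
  # Re-attach excluded reactions: efficiency from the chosen band when
  # possible, inclusion mask FALSE.
  all_eff <- setNames(rep(NA_real_, length(wells)), wells)
  all_win <- setNames(vector("list", length(wells)), wells)
  all_eff[names(res$efficiencies)] <- res$efficiencies
  all_win[names(res$windows)] <- res$windows
  up <- log10(res$window[["upper_fluor"]])
  for (w in wells[!keep]) {
    ac <- assay_curves[[w]]
    bw <- band_window(ac$corrected, ac$phase, up - config$wol_band_width, up,
                      config$min_window_cycles)
    f <- if (!is.null(bw))
           fit_log_linear(ac$corrected, bw, config,
                          weights = noise_model_weights(ac$corrected[bw],
                                                        ac$baseline))
         else {
           idx <- seq.int(ac$phase$start_cycle, ac$phase$sdm_cycle)
           idx <- idx[ac$corrected[idx] > 0]
           fit_log_linear(ac$corrected, idx, config,
                          weights = noise_model_weights(ac$corrected[idx],
                                                        ac$baseline))
         }
    all_eff[w] <- f$efficiency
    all_win[[w]] <- f$window
  }
  incl <- keep
  e_in <- all_eff[incl]
  structure(list(target_id = target_id,
                 window = res$window,
                 efficiencies = all_eff,
                 included = incl,
                 e_tar = mean(e_in),
                 cv = if (length(e_in) > 1) sd(e_in) / mean(e_in) else NA_real_,
                 flags = res$flags,
                 windows = all_win,
                 oscillated = warned),
            class = "assay_result")
}

# ---- threshold, Cq, N0 --------------------------------------------------

#' Set the common quantification threshold of a run
#'
#' The threshold Nq is shared by all assays of the run and placed in the
#' exponential phase of all reactions: the geometric mean of the bounds of
#' the intersection of the reactions' exponential-phase fluorescence ranges.
#' When the intersection is empty, the geometric mean of the phase centres is
#' used instead and every reaction whose phase excludes Nq is reported.
#'
#' @param phases List of `exp_phase` objects with status `"ok"`.
#' @return A list of class `run_threshold`: `nq`, `fallback` (logical) and
#'   `outside` (indices of reactions whose phase excludes `nq`).
#' @export
set_common_threshold <- function(phases) {
  ok <- vapply(phases, function(p) identical(p$status, "ok"), logical(1))
  if (!any(ok)) stop("run-level error: no reaction with a valid exponential phase")
  phases <- phases[ok]
  lo <- max(vapply(phases, `[[`, numeric(1), "range_lo"))
  hi <- min(vapply(phases, `[[`, numeric(1), "range_hi"))
  if (lo < hi) {
    nq <- sqrt(lo * hi)
    fallback <- FALSE
  } else {
    nq <- geometric_mean(vapply(phases, `[[`, numeric(1), "centre_fluor"))
    fallback <- TRUE
  }
  outside <- which(vapply(phases, function(p) nq < p$range_lo || nq > p$range_hi,
                          logical(1)))
  structure(list(nq = nq, fallback = fallback,
                 outside = which(ok)[outside]),
            class = "run_threshold")
}

#' Call the quantification cycle from the idealized curve
#'
#' An ideal amplification curve
#' \eqn{N(c) = F_{centre} \cdot E_{tar}^{(c - c_{centre})}} is anchored at
#' the centre of the reaction's exponential phase and built from the mean
#' assay efficiency, cancelling residual per-reaction efficiency noise. The
#' Cq is the fractional cycle where this curve reaches the common threshold:
#' \deqn{C_q = c_{centre} + \log(N_q / F_{centre}) / \log(E_{tar})}
#'
#' @param phase An `exp_phase` with status `"ok"`.
#' @param e_tar Mean assay efficiency (> 1).
#' @param nq Common quantification threshold (> 0).
#' @return The fractional Cq value.
#' @export
call_cq <- function(phase, e_tar, nq) {
  if (!identical(phase$status, "ok")) stop("phase is not valid")
  if (!is.finite(e_tar) || e_tar <= 1)
    stop("undefined efficiency: e_tar must exceed 1, got ", e_tar)
  stopifnot(nq > 0)
  phase$centre_cycle + log(nq / phase$centre_fluor) / log(e_tar)
}

#' Efficiency-corrected target quantity
#'
#' \deqn{N_0 = N_q / E_{tar}^{C_q}} in the fluorescence units of the
#' threshold.
#'
#' @param nq Common quantification threshold (> 0).
#' @param e_tar Assay efficiency (> 1).
#' @param cq Quantification cycle (>= 0).
#' @return N0 in threshold-fluorescence units.
#' @export
#' @examples
#' compute_n0(1, 2, 20)       # 2^-20
compute_n0 <- function(nq, e_tar, cq) {
  if (!is.finite(nq) || nq <= 0) stop("domain error: nq must be positive")
  if (!is.finite(e_tar) || e_tar <= 1) stop("domain error: e_tar must exceed 1")
  if (!is.finite(cq) || cq < 0) stop("domain error: cq must be non-negative")
  nq / e_tar^cq
}

# ---- classification -----------------------------------------------------

#' Classify a reaction's quality by sample type
#'
#' Errors: amplification in a negative control, no amplification in a
#' positive control, and baseline errors. Warnings: no amplification in an
#' unknown sample, no plateau, and a deviating (outlier) PCR efficiency.
#' Errors suppress the automatic N0; the Cq and individual efficiency stay
#' available so the user can compute N0 = Nq / E^Cq manually.
#'
#' @param status [detect_amplification()] verdict (possibly amended by the
#'   baseline step to `"baseline_error"`).
#' @param sample_type `"unknown"`, `"positive_control"` or
#'   `"negative_control"`.
#' @param efficiency_outlier Whether the reaction was excluded as an
#'   efficiency outlier.
#' @return A list: `flags` (character vector), `messages`, and `severity`
#'   (`"ok"`, `"warning"` or `"error"`).
#' @export
classify_reaction <- function(status, sample_type,
                              efficiency_outlier = FALSE) {
  flags <- character(0)
  messages <- character(0)
  severity <- "ok"
  note <- function(fl, msg, sev) {
    flags <<- c(flags, fl)
    messages <<- c(messages, msg)
    severity <<- if (sev == "error" || severity == "error") "error"
                 else if (sev == "warning" || severity == "warning") "warning"
                 else "ok"
  }
  amplified <- status %in% c("amplified", "no_plateau")
  if (identical(status, "baseline_error"))
    note("baseline_error", "no baseline gives a straight exponential phase", "error")
  if (sample_type == "negative_control" && amplified)
    note("control_error", "amplification in negative control", "error")
  if (sample_type == "positive_control" && !amplified &&
      !identical(status, "baseline_error"))
    note("control_error", "no amplification in positive control", "error")
  if (identical(status, "not_amplified") && sample_type == "unknown")
    note("no_amplification", "no amplification", "warning")
  if (identical(status, "not_amplified") && sample_type == "negative_control") {
    # expected behaviour, no flag
  }
  if (identical(status, "no_plateau"))
    note("no_plateau", "reaction does not reach a plateau", "warning")
  if (isTRUE(efficiency_outlier))
    note("efficiency_outlier", "deviating PCR efficiency", "warning")
  list(flags = unique(flags), messages = messages, severity = severity)
}

# ---- orchestration ------------------------------------------------------

#' Analyze the amplification curves of a whole run
#'
#' Runs the full per-reaction pipeline (amplification detection, baseline
#' estimation, exponential-phase identification), the per-assay
#' window-of-linearity with outlier iteration, the run-wide common threshold,
#' and Cq/N0 calling with sample-type-aware classification. Results are
#' deterministic for fixed input and configuration.
#'
#' @param run A [run_data] object with amplification data.
#' @param config An [amp_config()].
#' @return A list of class `amp_analysis`: `reactions` (named list of
#'   per-reaction results), `assays` (named list of `assay_result`),
#'   `threshold` (a `run_threshold`) and `table` (the per-reaction result
#'   data frame, see [amp_result_table()]).
#' @export
#' @examples
#' sim <- generate_synthetic_run(default_plate_plan(n_targets = 1, n_unknown = 4,
#'                                                  melt = FALSE), seed = 3)
#' res <- analyze_amplification(sim$run)
#' res$assays[[1]]$e_tar
analyze_amplification <- function(run, config = amp_config()) {
  stopifnot(inherits(run, "run_data"))
  rx <- run$reactions
  has_adp <- vapply(rx, function(r) !is.null(r$adp), logical(1))
  if (!any(has_adp)) stop("run-level error: no reaction carries amplification data")

  results <- list()
  for (r in rx) {
    if (is.null(r$adp)) {
      results[[r$well]] <- list(well = r$well, sample_id = r$sample_id,
                                target_id = r$target_id,
                                sample_type = sample_type_of(run, r$sample_id),
                                status = "no_data", baseline = NULL, phase = NULL)
      next
    }
    fluor <- r$adp$fluor
    status <- tryCatch(detect_amplification(fluor, config),
                       error = function(e) "not_amplified")
    baseline <- NULL
    phase <- NULL
    if (status %in% c("amplified", "no_plateau")) {
      baseline <- estimate_baseline(fluor, config)
      if (baseline$status == "baseline_error") {
        status <- "baseline_error"
      } else {
        phase <- find_exponential_phase(baseline$corrected, config, status,
                                        baseline = baseline$baseline)
        if (!identical(phase$status, "ok")) {
          status <- "not_amplified"
          phase <- NULL
        }
      }
    }
    results[[r$well]] <- list(well = r$well, sample_id = r$sample_id,
                              target_id = r$target_id,
                              sample_type = sample_type_of(run, r$sample_id),
                              status = status, baseline = baseline,
                              phase = phase)
  }

  valid <- names(results)[vapply(results, function(x) !is.null(x$phase), logical(1))]
  if (!length(valid))
    stop("run-level error: no analyzable reaction in the run")

  # Window-of-linearity per assay on eligible reactions: valid phase, and not
  # a plateau-less curve unless configured otherwise.
  eligible <- valid[vapply(results[valid], function(x) {
    x$status == "amplified" || !config$exclude_no_plateau
  }, logical(1))]

  assays <- list()
  for (tg in unique(run$targets$target_id)) {
    in_assay <- eligible[vapply(results[eligible], function(x)
      identical(x$target_id, tg), logical(1))]
    if (!length(in_assay)) next
    curves <- lapply(results[in_assay], function(x)
      list(corrected = x$baseline$corrected, phase = x$phase,
           baseline = x$baseline$baseline))
    names(curves) <- in_assay
    assays[[tg]] <- iterate_assay(curves, config, target_id = tg)
  }

  threshold <- set_common_threshold(lapply(results[valid], `[[`, "phase"))
  nq <- threshold$nq

  table_rows <- list()
  for (w in names(results)) {
    x <- results[[w]]
    a <- assays[[x$target_id]]
    outlier <- !is.null(a) && w %in% names(a$included) && !a$included[[w]]
    cls <- classify_reaction(x$status, x$sample_type, outlier)
    e_tar <- if (!is.null(a)) a$e_tar else NA_real_
    indiv <- if (!is.null(a) && w %in% names(a$efficiencies))
      unname(a$efficiencies[[w]]) else NA_real_
    cq <- n0 <- NA_real_
    if (!is.null(x$phase) && is.finite(e_tar) && e_tar > 1) {
      cq <- call_cq(x$phase, e_tar, nq)
      if (cls$severity != "error" && cq >= 0) n0 <- compute_n0(nq, e_tar, cq)
    }
    if (w %in% names(results)[threshold$outside])
      cls$flags <- unique(c(cls$flags, "threshold_outside_phase"))
    x$e_tar <- e_tar; x$indiv_efficiency <- indiv
    x$cq <- cq; x$n0 <- n0
    x$flags <- cls$flags; x$messages <- cls$messages; x$severity <- cls$severity
    results[[w]] <- x
    table_rows[[w]] <- data.frame(
      well = w, sample = x$sample_id, sample_type = x$sample_type,
      target = x$target_id, e_tar = e_tar, indiv_E = indiv,
      cq = cq, n0 = n0,
      flags = paste(cls$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, table_rows)
  rownames(tab) <- NULL
  structure(list(reactions = results, assays = assays,
                 threshold = threshold, table = tab, config = config),
            class = "amp_analysis")
}

#' Per-reaction amplification result table
#'
#' @param x An `amp_analysis` object.
#' @return A data frame with one row per reaction: well, sample, sample type,
#'   target, assay efficiency, individual efficiency, Cq, N0 and flags.
#' @export
amp_result_table <- function(x) {
  stopifnot(inherits(x, "amp_analysis"))
  x$table
}

#' @export
print.amp_analysis <- function(x, ...) {
  cat("Amplification analysis: ", nrow(x$table), " reactions, ",
      length(x$assays), " assays, common threshold Nq = ",
      format(x$threshold$nq, digits = 4), "\n", sep = "")
  for (a in x$assays)
    cat("  ", a$target_id, ": E = ", format(a$e_tar, digits = 4),
        " (CV ", format(a$cv, digits = 3), ", ",
        sum(a$included), "/", length(a$included), " included)\n", sep = "")
  invisible(x)
}
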