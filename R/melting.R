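#' Melting curve analysis
#'
#' @section Melting curve analysis:
#' Raw melting data are smoothed with a simplified supersmoother (running
#' local-linear fits with a leave-one-out choice among a small span ladder),
#' normalized to remove the temperature-dependent but dissociation-independent
#' fluorescence loss, and differentiated. Peaks of -dF/dT are called, sized
#' by the flanking extrema of the second derivative, filtered on relative
#' height and width, compared with the expected product melting temperature,
#' and quantified as fractions of the total peak fluorescence loss; with a
#' saturating dye the expected-product fraction corrects Cq and N0 of
#' reactions that co-amplified artifacts.
#' @name melting
#' @keywords internal
NULL

# Running local-linear fit over a centered window of `k` points, returning
# fitted values and leave-one-out absolute residuals (via the hat diagonal).
local_linear_pass <- function(x, y, k) {
  n <- length(x)
  k <- max(3L, min(as.integer(k), n))
  half <- k %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, x * x)); cxy <- cumsum(c(0, x * y))
  m <- hi - lo + 1
  sx <- cx[hi + 1L] - cx[lo]
  sy <- cy[hi + 1L] - cy[lo]
  sxx <- cxx[hi + 1L] - cxx[lo]
  sxy <- cxy[hi + 1L] - cxy[lo]
  xbar <- sx / m
  ssxx <- sxx - sx * xbar
  slope <- ifelse(ssxx > 0, (sxy - sx * sy / m) / ssxx, 0)
  fit <- sy / m + slope * (x - xbar)
  lev <- 1 / m + ifelse(ssxx > 0, (x - xbar)^2 / ssxx, 0)
  loo <- abs(y - fit) / pmax(1 - lev, 1e-8)
  list(fit = fit, loo = loo)
}

running_mean <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(as.integer(k), n))
  half <- k %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cs <- cumsum(c(0, x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1)
}

#' Smooth a melting curve with a simplified supersmoother
#'
#' Running local-linear fits are computed for a small ladder of spans and
#' compared through locally averaged leave-one-out residuals. Per temperature
#' point the largest span whose residual stays within `bass_tol` of the
#' best one is selected — wide spans win on featureless stretches, narrow
#' spans around melting transitions — the span sequence is smoothed,
#' adjacent passes are blended, and, when the residual noise is
#' non-negligible, a final light local-linear pass removes span-transition
#' seams. Noise-free data pass through almost unchanged and peak positions
#' of -dF/dT are not displaced by more than about one temperature step.
#'
#' @param temperature Strictly increasing temperatures (degrees C).
#' @param fluor Fluorescence values.
#' @param spans Span ladder as fractions of the number of points; each span
#'   is floored at 3 points.
#' @param bass_tol Relative tolerance favouring wider spans.
#' @return Numeric vector of smoothed fluorescence values.
#' @export
smooth_melt <- function(temperature, fluor,
                        spans = c(0.01, 0.05, 0.2, 0.5),
                        bass_tol = 0.3) {
  n <- length(temperature)
  if (n < 20) stop("insufficient data: at least 20 melting points required, got ", n)
  stopifnot(length(fluor) == n, all(diff(temperature) > 0))
  ks <- sort(unique(pmax(3L, pmin(n, as.integer(round(spans * n))))))
  passes <- lapply(ks, function(k) local_linear_pass(temperature, fluor, k))
  # residuals averaged over a mid-size neighbourhood stabilise the choice
  resid_mat <- vapply(passes, function(p) running_mean(p$loo, round(0.2 * n)),
                      numeric(n))
  rmin <- do.call(pmin, as.data.frame(resid_mat))
  within <- resid_mat <= (1 + bass_tol) * rmin
  kbest <- ks[apply(within, 1, function(ok) max(which(ok)))]
  ksm <- running_mean(kbest, round(0.2 * n))
  fit_mat <- vapply(passes, `[[`, numeric(n), "fit")
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- findInterval(ksm[i], ks)
    if (j >= length(ks)) out[i] <- fit_mat[i, length(ks)]
    else if (j < 1) out[i] <- fit_mat[i, 1]
    else {
      w <- (ksm[i] - ks[j]) / (ks[j + 1] - ks[j])
      out[i] <- (1 - w) * fit_mat[i, j] + w * fit_mat[i, j + 1]
    }
  }
  noisy <- median(passes[[1]]$loo) > 1e-3 * diff(range(fluor))
  if (noisy) out <- local_linear_pass(temperature, out, ks[min(2, length(ks))])$fit
  out
}

# Least-squares line over an index window; returns c(intercept, slope).
anchor_line <- function(x, y) {
  f <- ls_fit(x, y)
  c(f[["intercept"]], f[["slope"]])
}

#' Normalize a melting curve
#'
#' Removes the temperature-dependent but dissociation-independent
#' fluorescence decrease. `"bilinear"` fits straight trend lines to the low-
#' and high-temperature anchor windows and rescales the curve to the height
#' above the lower trend as a proportion of the distance between the trends
#' (pre-melt plateau close to 1, post-melt close to 0). `"exponential"` fits
#' an exponential decay to the slopes of the curve at the start and end of
#' the temperature range, divides it out and rescales on the anchors.
#' `"combined"` runs the bilinear normalization after the exponential one.
#'
#' @param temperature Temperatures (degrees C).
#' @param smoothed Smoothed fluorescence values.
#' @param method `"bilinear"`, `"exponential"` or `"combined"`.
#' @param anchor_frac Fraction of the temperature range forming each anchor
#'   window.
#' @return Numeric vector of normalized fluorescence.
#' @export
normalize_melt <- function(temperature, smoothed,
                           method = c("combined", "bilinear", "exponential"),
                           anchor_frac = 0.1) {
  method <- match.arg(method)
  n <- length(temperature)
  stopifnot(length(smoothed) == n, n >= 10)
  tr <- range(temperature)
  low_idx <- which(temperature <= tr[1] + anchor_frac * diff(tr))
  high_idx <- which(temperature >= tr[2] - anchor_frac * diff(tr))
  if (length(low_idx) < 3 || length(high_idx) < 3)
    stop("normalization error: anchor windows hold fewer than 3 points")

  bilinear <- function(f) {
    upper <- anchor_line(temperature[low_idx], f[low_idx])
    lower <- anchor_line(temperature[high_idx], f[high_idx])
    ut <- upper[1] + upper[2] * temperature
    lt <- lower[1] + lower[2] * temperature
    if (any(ut <= lt))
      stop("normalization error: upper trend not above lower trend over the ",
           "whole temperature range")
    (f - lt) / (ut - lt)
  }
  exponential <- function(f) {
    s1 <- anchor_line(temperature[low_idx], f[low_idx])[2]
    s2 <- anchor_line(temperature[high_idx], f[high_idx])[2]
    t1 <- mean(temperature[low_idx]); t2 <- mean(temperature[high_idx])
    scale <- diff(range(f)) / diff(tr)
    k <- 0
    if (s1 < -1e-8 * scale && s2 < -1e-8 * scale) {
      ratio <- s1 / s2
      if (ratio > 0) k <- log(ratio) / (t2 - t1)
    } else if (s1 < -1e-8 * scale || s2 < -1e-8 * scale) {
      stop("normalization error: anchor slopes do not describe a common decay")
    }
    g <- f / exp(-k * (temperature - t1))
    # rescale on the anchor means so the result sits near [0, 1]
    g1 <- mean(g[low_idx]); g2 <- mean(g[high_idx])
    if (g1 <= g2)
      stop("normalization error: degenerate anchors after exponential removal")
    (g - g2) / (g1 - g2)
  }
  switch(method,
         bilinear = bilinear(smoothed),
         exponential = exponential(smoothed),
         combined = bilinear(exponential(smoothed)))
}

#' First and second derivatives of a melting curve
#'
#' Central differences on the temperature grid; one-sided differences at the
#' endpoints. Returns the negative first derivative (the familiar melt-peak
#' curve) and the second derivative.
#'
#' @param temperature Temperatures (degrees C).
#' @param values Normalized fluorescence.
#' @return A list with `d1neg` (-dF/dT) and `d2` (d2F/dT2).
#' @export
melt_derivatives <- function(temperature, values) {
  n <- length(temperature)
  stopifnot(length(values) == n, n >= 5)
  d1 <- numeric(n)
  d1[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) /
    (temperature[3:n] - temperature[1:(n - 2)])
  d1[1] <- (values[2] - values[1]) / (temperature[2] - temperature[1])
  d1[n] <- (values[n] - values[n - 1]) / (temperature[n] - temperature[n - 1])
  d2 <- numeric(n)
  d2[2:(n - 1)] <- (d1[3:n] - d1[1:(n - 2)]) /
    (temperature[3:n] - temperature[1:(n - 2)])
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  list(d1neg = -d1, d2 = d2)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

# Parabolic sub-grid refinement of an apex position.
refine_apex <- function(temperature, y, i) {
  n <- length(y)
  if (i <= 1 || i >= n) return(temperature[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(temperature[i])
  offset <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  temperature[i] + offset * (temperature[min(i + 1, n)] - temperature[i])
}

#' Call melting peaks from the derivative curves
#'
#' Candidate peaks are the local maxima of -dF/dT. Each candidate is sized by
#' its inflection points — the flanking extrema of the second derivative,
#' taken as the extreme-curvature points within the peak's support (from the
#' -dF/dT valley on each side; between adjacent candidates the boundary is
#' the -dF/dT valley between their apexes).
#' The delta peak height is the apex value minus the mean derivative value at
#' the inflection points, the width is the temperature span between them.
#' Candidates below `min_peak_height_frac` of the summed delta heights, or
#' wider than `max_peak_width`, are discarded.
#'
#' @param temperature Temperatures (degrees C).
#' @param d1neg Negative first derivative of the normalized curve.
#' @param d2 Second derivative of the normalized curve.
#' @param config A [melt_config()].
#' @return A data frame of retained peaks: `tm`, `delta_height`, `width`,
#'   `t_left`, `t_right`, `idx_left`, `idx_right`, `apex_idx`; the number of
#'   candidates is carried in attribute `n_candidates`.
#' @export
call_melt_peaks <- function(temperature, d1neg, d2, config = melt_config()) {
  apexes <- local_maxima(d1neg)
  apexes <- apexes[d1neg[apexes] > 0]
  empty <- data.frame(tm = numeric(0), delta_height = numeric(0),
                      width = numeric(0), t_left = numeric(0),
                      t_right = numeric(0), idx_left = integer(0),
                      idx_right = integer(0), apex_idx = integer(0))
  if (!length(apexes)) {
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }
  n <- length(temperature)
  valleys <- local_minima(d1neg)
  apexes <- sort(apexes)
  # merge candidates that are not separated by a real valley: two apexes
  # count as distinct products only when the -dF/dT minimum between them
  # drops below peak_valley_frac of the smaller apex
  repeat {
    if (length(apexes) < 2) break
    merged <- FALSE
    for (j in seq_len(length(apexes) - 1L)) {
      seg <- apexes[j]:apexes[j + 1L]
      v <- min(d1neg[seg])
      if (v > config$peak_valley_frac * min(d1neg[apexes[j]],
                                            d1neg[apexes[j + 1L]])) {
        drop <- if (d1neg[apexes[j]] < d1neg[apexes[j + 1L]]) j else j + 1L
        apexes <- apexes[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # peak support: from the valley (or boundary of the adjacent peak) on each
  # side; overlapping neighbours are split at the -dF/dT minimum between
  # their apexes
  lo_support <- hi_support <- integer(length(apexes))
  for (j in seq_along(apexes)) {
    a <- apexes[j]
    lo <- if (j > 1) {
      seg <- apexes[j - 1L]:a
      seg[which.min(d1neg[seg])]
    } else {
      v <- valleys[valleys < a]
      if (length(v)) max(v) else 1L
    }
    hi <- if (j < length(apexes)) {
      seg <- a:apexes[j + 1L]
      seg[which.min(d1neg[seg])]
    } else {
      v <- valleys[valleys > a]
      if (length(v)) min(v) else n
    }
    lo_support[j] <- lo
    hi_support[j] <- hi
  }
  # inflection points: the extreme second-derivative points inside the
  # support segments (robust against small curvature wiggles)
  left <- right <- integer(length(apexes))
  for (j in seq_along(apexes)) {
    a <- apexes[j]
    seg_l <- lo_support[j]:a
    seg_r <- a:hi_support[j]
    left[j] <- seg_l[which.min(d2[seg_l])]
    right[j] <- seg_r[which.max(d2[seg_r])]
  }
  delta <- d1neg[apexes] - (d1neg[left] + d1neg[right]) / 2
  delta <- pmax(delta, 0)
  width <- temperature[right] - temperature[left]
  tm <- vapply(apexes, function(a) refine_apex(temperature, d1neg, a), numeric(1))
  total <- sum(delta)
  retain <- delta >= config$min_peak_height_frac * total &
    width <= config$max_peak_width & width > 0
  out <- data.frame(tm = tm, delta_height = delta, width = width,
                    t_left = temperature[left], t_right = temperature[right],
                    idx_left = left, idx_right = right,
                    apex_idx = apexes)[retain, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- length(apexes)
  out
}

#' Compare called peaks with the expected product melting temperature
#'
#' A peak represents the intended product when its melting temperature lies
#' within `tol` degrees of the expected value; with several peaks inside the
#' window the closest one is taken and the others count as additional
#' products. Reactions lacking an expected-temperature peak are flagged, and
#' a note is raised when more than one product is detected.
#'
#' @param peaks Peak data frame from [call_melt_peaks()].
#' @param expected_tm Expected melting temperature (degrees C), or `NA`.
#' @param tol Acceptance window (degrees C).
#' @return The peak data frame with an `is_expected` column, and attribute
#'   `flags` (subset of `"no_peaks"`, `"no_expected_peak"`,
#'   `"multiple_products"`).
#' @export
match_expected_tm <- function(peaks, expected_tm, tol = 1.0) {
  flags <- character(0)
  peaks$is_expected <- logical(nrow(peaks))
  if (!nrow(peaks)) {
    attr(peaks, "flags") <- "no_peaks"
    return(peaks)
  }
  if (nrow(peaks) > 1) flags <- c(flags, "multiple_products")
  if (!is.na(expected_tm)) {
    dist <- abs(peaks$tm - expected_tm)
    inside <- which(dist <= tol)
    if (!length(inside)) {
      flags <- c(flags, "no_expected_peak")
    } else {
      peaks$is_expected[inside[which.min(dist[inside])]] <- TRUE
    }
  }
  attr(peaks, "flags") <- flags
  peaks
}

#' Fluorescence loss and fractional contribution per peak
#'
#' The fluorescence of a peak is the loss of the normalized melting curve
#' between its inflection-point temperatures; the fraction is its share of
#' the summed losses over all retained peaks (fractions sum to one).
#'
#' @param normalized Normalized fluorescence values.
#' @param peaks Peak data frame with `idx_left` / `idx_right` columns.
#' @return The peak data frame with `fluorescence` and `fraction` columns.
#' @export
peak_fluorescence_fractions <- function(normalized, peaks) {
  if (!nrow(peaks)) stop("quantification error: no retained peaks")
  fl <- normalized[peaks$idx_left] - normalized[peaks$idx_right]
  fl <- pmax(fl, 0)
  total <- sum(fl)
  if (total <= 0) stop("quantification error: zero total peak fluorescence")
  peaks$fluorescence <- fl
  peaks$fraction <- fl / total
  peaks
}

#' Correct Cq and N0 for artifact amplification
#'
#' When a saturating DNA-binding dye was used, the fraction of the total peak
#' fluorescence found in the correct-product peak rescales the target
#' quantity, `corrected_n0 = fraction * n0`, with the matching shift of the
#' quantification cycle, `corrected_cq = cq - log(fraction) / log(e_tar)`, so
#' that `corrected_n0 = nq / e_tar^corrected_cq` still holds. With a
#' non-saturating dye the correction is refused.
#'
#' @param cq,n0 Values from the amplification analysis.
#' @param fraction Correct-peak fluorescence fraction in (0, 1].
#' @param e_tar Assay efficiency (> 1).
#' @param dye_saturating Whether the dye permits partitioning fluorescence
#'   among products.
#' @return A list: `applicable`, `correction_factor`, `corrected_cq`,
#'   `corrected_n0`, `flag`.
#' @export
#' @examples
#' correct_quantification(20, 1e-5, 0.25, 2, TRUE)   # cq + 2, n0 / 4
correct_quantification <- function(cq, n0, fraction, e_tar, dye_saturating) {
  if (!isTRUE(dye_saturating))
    return(list(applicable = FALSE, correction_factor = NA_real_,
                corrected_cq = NA_real_, corrected_n0 = NA_real_,
                flag = "correction_requires_saturating_dye"))
  if (!is.finite(fraction) || fraction <= 0)
    return(list(applicable = FALSE, correction_factor = NA_real_,
                corrected_cq = NA_real_, corrected_n0 = NA_real_,
                flag = "zero_correct_peak_fraction"))
  stopifnot(fraction <= 1, e_tar > 1)
  list(applicable = TRUE, correction_factor = fraction,
       corrected_cq = cq - log(fraction) / log(e_tar),
       corrected_n0 = fraction * n0,
       flag = NA_character_)
}

#' Analyze the melting curves of a run
#'
#' Per reaction with melting data: smoothing, normalization, derivatives,
#' peak calling, expected-temperature matching, peak-fluorescence fractions
#' and — when a saturating dye is annotated and exactly one expected-product
#' peak was found — correction of the amplification Cq and N0 by the
#' correct-peak fraction. Reactions without melting data are skipped.
#'
#' @param run A [run_data] object with melting data.
#' @param amp_results An `amp_analysis` from [analyze_amplification()], or
#'   `NULL` for a melt-only analysis (no corrections possible).
#' @param config A [melt_config()].
#' @return A list of class `melt_analysis`: `reactions` (per-well lists with
#'   `peaks`, `flags`, `correction_factor`, `corrected_cq`, `corrected_n0`),
#'   `table` (one row per retained peak, see [melt_result_table()]) and
#'   `corrected_table` (the amplification result table with corrected Cq/N0
#'   substituted where a correction applied).
#' @export
analyze_melting <- function(run, amp_results = NULL, config = melt_config()) {
  stopifnot(inherits(run, "run_data"))
  out <- list()
  rows <- list()
  for (r in run$reactions) {
    if (is.null(r$mdp)) next
    tinfo <- target_info_of(run, r$target_id)
    dye_sat <- if (is.na(config$dye_saturating)) isTRUE(tinfo$dye_saturating)
               else isTRUE(config$dye_saturating)
    res <- list(well = r$well, flags = character(0),
                correction_factor = NA_real_,
                corrected_cq = NA_real_, corrected_n0 = NA_real_)
    peaks <- tryCatch({
      sm <- smooth_melt(r$mdp$temperature, r$mdp$fluor)
      norm <- normalize_melt(r$mdp$temperature, sm, config$normalization,
                             config$anchor_frac)
      dv <- melt_derivatives(r$mdp$temperature, norm)
      pk <- call_melt_peaks(r$mdp$temperature, dv$d1neg, dv$d2, config)
      pk <- match_expected_tm(pk, tinfo$expected_tm, config$tm_tolerance)
      res$flags <- attr(pk, "flags")
      if (nrow(pk)) pk <- peak_fluorescence_fractions(norm, pk)
      pk
    }, error = function(e) {
      res$flags <<- c(res$flags, "melt_analysis_failed")
      message("melting analysis skipped for well ", r$well, ": ",
              conditionMessage(e))
      NULL
    })
    res$peaks <- peaks
    amp_rx <- if (!is.null(amp_results)) amp_results$reactions[[r$well]] else NULL
    if (!is.null(peaks) && nrow(peaks) && sum(peaks$is_expected) == 1L &&
        peaks$fraction[peaks$is_expected] < 1 &&
        config$apply_correction && !is.null(amp_rx) &&
        is.finite(amp_rx$cq) && is.finite(amp_rx$n0) &&
        is.finite(amp_rx$e_tar) && amp_rx$e_tar > 1) {
      corr <- correct_quantification(amp_rx$cq, amp_rx$n0,
                                     peaks$fraction[peaks$is_expected],
                                     amp_rx$e_tar, dye_sat)
      if (corr$applicable) {
        res$correction_factor <- corr$correction_factor
        res$corrected_cq <- corr$corrected_cq
        res$corrected_n0 <- corr$corrected_n0
      } else if (!is.na(corr$flag)) {
        res$flags <- c(res$flags, corr$flag)
      }
    }
    out[[r$well]] <- res
    stype <- sample_type_of(run, r$sample_id)
    if (!is.null(peaks) && nrow(peaks)) {
      for (j in seq_len(nrow(peaks))) {
        rows[[length(rows) + 1L]] <- data.frame(
          well = r$well, sample = r$sample_id, sample_type = stype,
          target = r$target_id, peak = j,
          tm = peaks$tm[j], delta_height = peaks$delta_height[j],
          width = peaks$width[j], fluorescence = peaks$fluorescence[j],
          fraction = peaks$fraction[j], is_expected = peaks$is_expected[j],
          flags = paste(res$flags, collapse = ";"),
          correction_factor = res$correction_factor,
          corrected_cq = res$corrected_cq,
          corrected_n0 = res$corrected_n0,
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        well = r$well, sample = r$sample_id, sample_type = stype,
        target = r$target_id, peak = NA_integer_, tm = NA_real_,
        delta_height = NA_real_, width = NA_real_, fluorescence = NA_real_,
        fraction = NA_real_, is_expected = NA,
        flags = paste(res$flags, collapse = ";"),
        correction_factor = NA_real_, corrected_cq = NA_real_,
        corrected_n0 = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("run-level error: no reaction carries melting data")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  corrected <- NULL
  if (!is.null(amp_results)) {
    corrected <- amp_results$table
    for (w in names(out)) {
      i <- which(corrected$well == w)
      if (length(i) == 1L && is.finite(out[[w]]$corrected_cq)) {
        corrected$cq[i] <- out[[w]]$corrected_cq
        corrected$n0[i] <- out[[w]]$corrected_n0
      }
    }
  }
  structure(list(reactions = out, table = tab, corrected_table = corrected,
                 config = config),
            class = "melt_analysis")
}

#' Per-peak melting result table
#'
#' @param x A `melt_analysis` object.
#' @return A data frame with one row per retained peak (reactions without
#'   peaks contribute one all-`NA` row): well, sample, sample type, target,
#'   peak index, Tm, delta height, width, fluorescence, fraction,
#'   expected-product verdict, flags, correction factor and corrected Cq/N0.
#' @export
melt_result_table <- function(x) {
  stopifnot(inherits(x, "melt_analysis"))
  x$table
}

#' @export
print.melt_analysis <- function(x, ...) {
  npk <- sum(!is.na(x$table$peak))
  cat("Melting analysis: ", length(x$reactions), " reactions, ",
      npk, " retained peaks, ",
      sum(is.finite(vapply(x$reactions, `[[`, numeric(1), "correction_factor"))),
      " corrections applied\n", sep = "")
  invisible(x)
}
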