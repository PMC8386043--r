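#' Analysis settings for amplification curves
#'
#' Collects the tunable parameters of the amplification-curve pipeline.
#' Defaults follow common qPCR practice: the baseline bisection stops when the
#' two half-slopes of the log-linear exponential phase differ by less than
#' `slope_diff_tol` (on log10 fluorescence per cycle; at an efficiency of 1.8
#' a slope difference of 1e-4 corresponds to an efficiency difference of about
#' 4e-4), efficiencies are fitted from at least `min_window_cycles` consecutive
#' cycles, and individual efficiencies are screened with a skewness-directed
#' Grubbs test at `grubbs_alpha`.
#'
#' @param slope_diff_tol Convergence tolerance for the baseline bisection,
#'   as a difference between the log10-slopes of the lower and upper half of
#'   the exponential phase. Must be positive.
#' @param min_window_cycles Minimum number of consecutive cycles used in any
#'   efficiency fit (at least 3).
#' @param exclude_no_plateau Exclude reactions that never reach a plateau from
#'   the window-of-linearity search (default `TRUE`).
#' @param outlier_mode One of `"grubbs"` (skewness-directed Grubbs test),
#'   `"fixed_band"` (median +/- `fixed_band_halfwidth`) or `"none"`.
#' @param fixed_band_halfwidth Half-width of the fixed efficiency acceptance
#'   band around the per-assay median (efficiency units).
#' @param grubbs_alpha Significance level of the Grubbs test.
#' @param wol_band_width Width of the window-of-linearity band on the log10
#'   fluorescence axis. The default, `log10(64)` (six doublings), holds at
#'   least six cycles up to an efficiency of 2; the noise-model weighting
#'   keeps near-ground cycles from degrading the fit.
#' @param wol_top_gap Gap, on the log10 fluorescence axis, between the
#'   highest exponential-phase top and the start of the downward band scan
#'   (default `log10(16)`, four doublings below the second-derivative
#'   maximum, where amplification is still close to exponential).
#' @param wol_step_frac Step of the downward band scan, as a fraction of
#'   `wol_band_width`.
#' @param wol_cv_tol Relative tolerance on the efficiency CV when choosing
#'   the band position: the highest band whose CV lies within
#'   `(1 + wol_cv_tol)` of the minimum is selected, so the downward shift
#'   stops once it no longer improves the CV meaningfully.
#' @param baseline_max_iter Iteration cap of the baseline bisection.
#' @param no_amp_factor A reaction is called non-amplifying when its total
#'   fluorescence rise is below `no_amp_factor` times the ground-phase noise
#'   (standard deviation of the first-six-cycle differences).
#' @param plateau_slope_frac A reaction is called "no plateau" when the mean
#'   per-cycle slope over the last five cycles exceeds `plateau_slope_frac`
#'   times the maximum per-cycle slope.
#' @param outlier_iter_cap Cap on window/outlier alternation rounds per assay.
#'
#' @return An object of class `amp_config` (a named list).
#' @export
#' @examples
#' cfg <- amp_config(outlier_mode = "fixed_band")
#' cfg$fixed_band_halfwidth
amp_config <- function(slope_diff_tol = 1e-4,
                       min_window_cycles = 3L,
                       exclude_no_plateau = TRUE,
                       outlier_mode = c("grubbs", "fixed_band", "none"),
                       fixed_band_halfwidth = 0.05,
                       grubbs_alpha = 0.05,
                       wol_band_width = log10(64),
                       wol_top_gap = log10(16),
                       wol_step_frac = 0.1,
                       wol_cv_tol = 0.25,
                       baseline_max_iter = 100L,
                       no_amp_factor = 7,
                       plateau_slope_frac = 0.25,
                       outlier_iter_cap = 10L) {
  outlier_mode <- match.arg(outlier_mode)
  stopifnot(slope_diff_tol > 0,
            min_window_cycles >= 3,
            grubbs_alpha > 0, grubbs_alpha < 1,
            fixed_band_halfwidth > 0,
            wol_band_width > 0,
            wol_step_frac > 0, wol_step_frac <= 1,
            wol_cv_tol >= 0)
  structure(list(slope_diff_tol = slope_diff_tol,
                 min_window_cycles = as.integer(min_window_cycles),
                 exclude_no_plateau = isTRUE(exclude_no_plateau),
                 outlier_mode = outlier_mode,
                 fixed_band_halfwidth = fixed_band_halfwidth,
                 grubbs_alpha = grubbs_alpha,
                 wol_band_width = wol_band_width,
                 wol_top_gap = wol_top_gap,
                 wol_step_frac = wol_step_frac,
                 wol_cv_tol = wol_cv_tol,
                 baseline_max_iter = as.integer(baseline_max_iter),
                 no_amp_factor = no_amp_factor,
                 plateau_slope_frac = plateau_slope_frac,
                 outlier_iter_cap = as.integer(outlier_iter_cap)),
            class = "amp_config")
}

#' Analysis settings for melting curves
#'
#' @param normalization Background-removal strategy: `"combined"` (exponential
#'   followed by bilinear, the default), `"bilinear"` or `"exponential"`.
#' @param tm_tolerance Acceptance window around the expected melting
#'   temperature, in degrees Celsius (default 1.0).
#' @param min_peak_height_frac Minimum delta peak height, as a fraction of the
#'   sum of all candidate delta peak heights (default 0.05).
#' @param max_peak_width Maximum allowed peak width between the inflection
#'   points, in degrees Celsius (default 5.0); wider bumps are discarded.
#' @param dye_saturating Whether the run used a saturating DNA-binding dye;
#'   required for artifact correction of Cq and N0. When `NA` (default) the
#'   per-target annotation of the run is used.
#' @param anchor_frac Fraction of the temperature range used as low- and
#'   high-temperature anchor windows by the normalization fits.
#' @param peak_valley_frac Two adjacent -dF/dT maxima count as distinct
#'   peaks only when the valley between them drops below this fraction of
#'   the smaller apex; shallower dips are merged into one peak.
#' @param apply_correction Apply the melt-based artifact correction to Cq and
#'   N0 (set to `FALSE` to report melt results without touching the
#'   amplification results).
#'
#' @return An object of class `melt_config` (a named list).
#' @export
melt_config <- function(normalization = c("combined", "bilinear", "exponential"),
                        tm_tolerance = 1.0,
                        min_peak_height_frac = 0.05,
                        max_peak_width = 5.0,
                        dye_saturating = NA,
                        anchor_frac = 0.1,
                        peak_valley_frac = 0.8,
                        apply_correction = TRUE) {
  normalization <- match.arg(normalization)
  stopifnot(tm_tolerance > 0,
            min_peak_height_frac > 0, min_peak_height_frac < 1,
            max_peak_width > 0,
            anchor_frac > 0, anchor_frac < 0.5,
            peak_valley_frac > 0, peak_valley_frac < 1)
  structure(list(normalization = normalization,
                 tm_tolerance = tm_tolerance,
                 min_peak_height_frac = min_peak_height_frac,
                 max_peak_width = max_peak_width,
                 dye_saturating = dye_saturating,
                 anchor_frac = anchor_frac,
                 peak_valley_frac = peak_valley_frac,
                 apply_correction = isTRUE(apply_correction)),
            class = "melt_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Keys must match
#' fields of [amp_config()] or [melt_config()]; logical values are written
#' `true`/`false`. Unknown keys raise an error.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `amp` (an `amp_config`) and `melt`
#'   (a `melt_config`).
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    kv[[m[2]]] <- m[3]
  }
  amp_defaults <- amp_config()
  melt_defaults <- melt_config()
  amp_args <- list(); melt_args <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key %in% names(amp_defaults)) {
      amp_args[[key]] <- coerce_config_value(val, amp_defaults[[key]])
    } else if (key %in% names(melt_defaults)) {
      melt_args[[key]] <- coerce_config_value(val, melt_defaults[[key]])
    } else {
      stop("unknown configuration key: ", key)
    }
  }
  list(amp = do.call(amp_config, amp_args),
       melt = do.call(melt_config, melt_args))
}

coerce_config_value <- function(chr, template) {
  if (is.logical(template)) {
    tolower(chr) %in% c("true", "1", "yes")
  } else if (is.numeric(template)) {
    as.numeric(chr)
  } else {
    chr
  }
}
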