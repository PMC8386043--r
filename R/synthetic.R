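#' Synthetic amplification and melting data
#'
#' @section Simulator model:
#' Amplification is simulated with a resource-limited recurrence that produces
#' the four canonical phases of a qPCR curve (ground, exponential, transition,
#' plateau): starting from the true target quantity, each cycle multiplies the
#' amplicon amount by an efficiency that declines linearly as the signal
#' approaches the plateau. Observed fluorescence adds a constant baseline and
#' optional multiplicative noise. Melting curves are sums of logistic
#' dissociation transitions on a linearly decaying background.
#' @name synthetic
#' @keywords internal
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a single amplification curve with known ground truth
#'
#' The noiseless amplicon amount follows the recurrence
#' \deqn{N_1 = N_0^{true},\quad
#'       N_{c+1} = N_c \left(1 + (E - 1)\left(1 - N_c / P\right)\right)}
#' with efficiency \eqn{E} and plateau \eqn{P}; while \eqn{N_c \ll P} the
#' curve is purely exponential with per-cycle factor \eqn{E}. The observed
#' fluorescence is \eqn{F_c = (B + N_c)(1 + \epsilon_c)} with baseline
#' \eqn{B} and \eqn{\epsilon_c \sim N(0, \sigma)} multiplicative noise.
#'
#' @param n0_true Starting quantity in fluorescence units (0 allowed, e.g. for
#'   negative controls).
#' @param efficiency_true Per-cycle amplification factor in (1, 2].
#' @param baseline_true Amplification-independent fluorescence.
#' @param plateau Fluorescence cap of the reaction.
#' @param n_cycles Number of cycles.
#' @param noise_sd Relative standard deviation of the multiplicative noise.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG state.
#'
#' @return A list of class `sim_amp_curve` with elements `cycles`, `fluor`
#'   (observed), and `truth` (a list holding the parameters and the noiseless
#'   amplicon series `n_series`).
#' @seealso [true_cq()] for the exact quantification cycle of the noiseless
#'   curve at any threshold.
#' @export
#' @examples
#' sim <- simulate_amplification_curve(n0_true = 1e-4, efficiency_true = 1.9,
#'                                     baseline_true = 50, seed = 1)
#' true_cq(sim, nq = 10)
simulate_amplification_curve <- function(n0_true = 1e-4,
                                         efficiency_true = 1.9,
                                         baseline_true = 50,
                                         plateau = 5000,
                                         n_cycles = 45L,
                                         noise_sd = 0,
                                         seed = NULL) {
  stopifnot(efficiency_true > 1, efficiency_true <= 2,
            plateau > baseline_true, baseline_true >= 0,
            n0_true >= 0, n_cycles >= 2, noise_sd >= 0)
  n <- integer(0)
  n_series <- numeric(n_cycles)
  n_series[1] <- n0_true
  for (c in seq_len(n_cycles - 1L)) {
    nc <- n_series[c]
    n_series[c + 1L] <- nc * (1 + (efficiency_true - 1) * (1 - nc / plateau))
  }
  eps <- with_seed(seed, if (noise_sd > 0) stats::rnorm(n_cycles, 0, noise_sd) else numeric(n_cycles))
  fluor <- (baseline_true + n_series) * (1 + eps)
  structure(list(cycles = seq_len(n_cycles),
                 fluor = fluor,
                 truth = list(n0_true = n0_true,
                              efficiency_true = efficiency_true,
                              baseline_true = baseline_true,
                              plateau = plateau,
                              noise_sd = noise_sd,
                              n_series = n_series)),
            class = "sim_amp_curve")
}

#' Exact quantification cycle of a noiseless simulated curve
#'
#' Solves \eqn{N(C_q) = N_q} on the noiseless amplicon series of a simulated
#' curve by log-linear interpolation between the two bracketing cycles.
#'
#' @param sim A `sim_amp_curve` (or its `truth` list, or a bare numeric
#'   noiseless amplicon series indexed by cycle).
#' @param nq Threshold fluorescence (baseline-corrected units).
#' @return The fractional cycle at which the series crosses `nq`, or `NA` if
#'   it never does.
#' @export
true_cq <- function(sim, nq) {
  n_series <- if (inherits(sim, "sim_amp_curve")) sim$truth$n_series
              else if (is.list(sim)) sim$n_series
              else sim
  stopifnot(is.numeric(n_series), nq > 0)
  above <- which(n_series >= nq)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1L) return(1)
  l0 <- log10(n_series[i - 1L]); l1 <- log10(n_series[i])
  if (!is.finite(l0)) return(as.numeric(i))
  (i - 1L) + (log10(nq) - l0) / (l1 - l0)
}

#' Simulate a melting curve with known ground truth
#'
#' The fluorescence is a sum of logistic dissociation transitions on a linear
#' background:
#' \deqn{F(T) = a + bT + \sum_i \frac{A_i}{1 + e^{(T - T_{m,i})/s_i}}}
#' so each product appears in \eqn{-dF/dT} as a peak at its melting
#' temperature \eqn{T_{m,i}} with width controlled by the steepness
#' \eqn{s_i}. Optional multiplicative noise is applied to the whole signal.
#'
#' @param products Data frame with columns `tm` (degrees C), `steepness`
#'   (degrees C) and `amplitude` (fluorescence); zero rows give a pure
#'   background curve.
#' @param background Numeric length-2 vector `c(intercept, slope)` of the
#'   linear background (slope per degree C, typically negative).
#' @param t_range Numeric length-3 vector `c(start, stop, step)` in degrees C.
#' @param noise_sd Relative standard deviation of multiplicative noise.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#'
#' @return A list of class `sim_melt_curve` with elements `temperature`,
#'   `fluor` and `truth` (product table plus amplitude `share`s).
#' @export
#' @examples
#' two <- data.frame(tm = c(79, 85), steepness = 0.8, amplitude = c(0.75, 0.25))
#' sim <- simulate_melt_curve(products = two)
simulate_melt_curve <- function(products = data.frame(tm = 85, steepness = 0.8,
                                                      amplitude = 1),
                                background = c(2.5, -0.02),
                                t_range = c(65, 95, 0.1),
                                noise_sd = 0,
                                seed = NULL) {
  stopifnot(length(t_range) == 3, t_range[2] > t_range[1], t_range[3] > 0,
            length(background) == 2, noise_sd >= 0)
  if (nrow(products)) {
    stopifnot(all(products$amplitude > 0),
              all(products$tm >= t_range[1] & products$tm <= t_range[2]))
  }
  temperature <- seq(t_range[1], t_range[2], by = t_range[3])
  fluor <- background[1] + background[2] * temperature
  for (i in seq_len(nrow(products))) {
    fluor <- fluor + products$amplitude[i] /
      (1 + exp((temperature - products$tm[i]) / products$steepness[i]))
  }
  eps <- with_seed(seed, if (noise_sd > 0) stats::rnorm(length(fluor), 0, noise_sd)
                         else numeric(length(fluor)))
  fluor <- fluor * (1 + eps)
  share <- if (nrow(products)) products$amplitude / sum(products$amplitude) else numeric(0)
  structure(list(temperature = temperature,
                 fluor = fluor,
                 truth = list(products = products, share = share,
                              background = background, noise_sd = noise_sd)),
            class = "sim_melt_curve")
}

#' Default demonstration plate plan
#'
#' A plate plan describing, per well, the sample annotation and the simulation
#' parameters for [generate_synthetic_run()]. The default emulates a small
#' two-assay run: per target, `n_unknown` unknown samples whose starting
#' quantities are log-spaced over `decades` decades, one positive and one
#' negative control. Baseline fluorescence is set to about 1% of the plateau,
#' as seen in optimized DNA-dye assays, and measurement noise is 1%
#' (multiplicative).
#'
#' @param n_targets Number of targets (assays), at most 4.
#' @param n_unknown Unknown reactions per target.
#' @param efficiencies Per-target true efficiencies (recycled).
#' @param expected_tms Per-target product melting temperatures (degrees C).
#' @param decades Number of decades spanned by the unknown starting
#'   quantities.
#' @param noise_sd Relative noise of the amplification curves.
#' @param melt_noise_sd Relative noise of the melting curves (instruments
#'   average several acquisitions per temperature, so melting data are less
#'   noisy than cycle readings).
#' @param n_cycles Cycles of the amplification protocol.
#' @param melt Include melting curves.
#'
#' @return A list of class `plate_plan` with elements `run_id`, `targets`
#'   (data frame: `target_id`, `expected_tm`, `dye_saturating`) and `wells`
#'   (one row per reaction with all simulation parameters).
#' @export
default_plate_plan <- function(n_targets = 2L, n_unknown = 10L,
                               efficiencies = c(1.9, 1.85, 1.8, 1.95),
                               expected_tms = c(85, 80.5, 87.5, 82),
                               decades = 4, noise_sd = 0.01,
                               melt_noise_sd = 0.005,
                               n_cycles = 45L, melt = TRUE) {
  stopifnot(n_targets >= 1, n_targets <= 4, n_unknown >= 1)
  targets <- data.frame(target_id = paste0("tgt", seq_len(n_targets)),
                        expected_tm = expected_tms[seq_len(n_targets)],
                        dye_saturating = TRUE,
                        stringsAsFactors = FALSE)
  rows <- list()
  well_i <- 0L
  for (t in seq_len(n_targets)) {
    eff <- efficiencies[t]
    n0s <- 10^seq(-2, -2 - decades, length.out = n_unknown)
    types <- c(rep("unknown", n_unknown), "positive_control", "negative_control")
    n0 <- c(n0s, 1e-2, 0)
    for (k in seq_along(types)) {
      well_i <- well_i + 1L
      rows[[well_i]] <- data.frame(
        well = paste0(LETTERS[(well_i - 1L) %/% 12L + 1L], (well_i - 1L) %% 12L + 1L),
        sample_id = sprintf("s%02d", well_i),
        target_id = targets$target_id[t],
        sample_type = types[k],
        n0 = n0[k], efficiency = eff, baseline = 50, plateau = 5000,
        n_cycles = n_cycles, noise_sd = noise_sd,
        melt_noise_sd = melt_noise_sd,
        melt_products = if (melt && types[k] != "negative_control")
          sprintf("%g:0.8:1", targets$expected_tm[t]) else "",
        stringsAsFactors = FALSE)
    }
  }
  structure(list(run_id = "sim_run", targets = targets,
                 wells = do.call(rbind, rows)),
            class = "plate_plan")
}

parse_melt_products <- function(spec) {
  if (is.na(spec) || !nzchar(spec))
    return(data.frame(tm = numeric(0), steepness = numeric(0), amplitude = numeric(0)))
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 3 || anyNA(suppressWarnings(as.numeric(p))),
                logical(1))
  if (any(bad)) stop("malformed melt product spec: ", spec)
  out <- do.call(rbind, lapply(parts, as.numeric))
  data.frame(tm = out[, 1], steepness = out[, 2], amplitude = out[, 3])
}

format_melt_products <- function(df) {
  if (!nrow(df)) return("")
  paste(sprintf("%g:%g:%g", df$tm, df$steepness, df$amplitude), collapse = ";")
}

#' Generate a complete synthetic run with ground truth
#'
#' Simulates every well of a plate plan (negative controls as baseline plus
#' noise only) and assembles a [run_data] object accepted by the analysis and
#' I/O functions, together with a per-well truth table.
#'
#' @param plan A `plate_plan`, e.g. from [default_plate_plan()] or
#'   [read_plate_plan()].
#' @param seed Integer seed controlling all simulated noise.
#' @param t_range Melting protocol `c(start, stop, step)` in degrees C.
#' @param melt_background Linear melt background `c(intercept, slope)`.
#'
#' @return A list with elements `run` (a `run_data`) and `truth` (data frame:
#'   one row per well with the simulation parameters and amplitude shares).
#' @export
#' @examples
#' sim <- generate_synthetic_run(default_plate_plan(n_targets = 1, n_unknown = 3),
#'                               seed = 7)
#' nrow(sim$truth)
generate_synthetic_run <- function(plan, seed = 1L,
                                   t_range = c(65, 95, 0.1),
                                   melt_background = c(2.5, -0.02)) {
  stopifnot(inherits(plan, "plate_plan"))
  wells <- plan$wells
  if (anyDuplicated(wells$well))
    stop("plate plan error: duplicate well identifiers: ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  with_seed(seed, {
    reactions <- vector("list", nrow(wells))
    truth_rows <- vector("list", nrow(wells))
    for (i in seq_len(nrow(wells))) {
      w <- wells[i, ]
      is_nc <- identical(w$sample_type, "negative_control")
      amp <- simulate_amplification_curve(
        n0_true = if (is_nc) 0 else w$n0,
        efficiency_true = w$efficiency, baseline_true = w$baseline,
        plateau = w$plateau, n_cycles = w$n_cycles, noise_sd = w$noise_sd,
        seed = NULL)
      products <- parse_melt_products(w$melt_products)
      mdp <- NULL
      shares <- ""
      if (nrow(products) || nzchar(w$melt_products)) {
        m_noise <- if (!is.null(w$melt_noise_sd) && !is.na(w$melt_noise_sd))
          w$melt_noise_sd else w$noise_sd
        melt <- simulate_melt_curve(products = products,
                                    background = melt_background,
                                    t_range = t_range,
                                    noise_sd = m_noise, seed = NULL)
        mdp <- data.frame(temperature = melt$temperature, fluor = melt$fluor)
        shares <- paste(sprintf("%g", melt$truth$share), collapse = ";")
      }
      reactions[[i]] <- reaction_record(
        well = w$well, sample_id = w$sample_id, target_id = w$target_id,
        adp = data.frame(cycle = amp$cycles, fluor = amp$fluor),
        mdp = mdp)
      truth_rows[[i]] <- data.frame(
        well = w$well, sample_id = w$sample_id, target_id = w$target_id,
        sample_type = w$sample_type, efficiency = w$efficiency,
        n0 = if (is_nc) 0 else w$n0, baseline = w$baseline,
        plateau = w$plateau,
        tms = format_melt_products(products), shares = shares,
        stringsAsFactors = FALSE)
    }
    samples <- unique(wells[, c("sample_id", "sample_type")])
    run <- run_data(run_id = plan$run_id,
                    reactions = reactions,
                    targets = plan$targets,
                    samples = samples)
    list(run = run, truth = do.call(rbind, truth_rows))
  })
}

#' Write / read a plate plan as a flat text file
#'
#' The file holds three sections: a `[run]` key=value block, a `[targets]`
#' tab-separated table and a `[wells]` tab-separated table. Round-trips
#' exactly through [read_plate_plan()].
#'
#' @param plan A `plate_plan`.
#' @param path Destination file.
#' @return `write_plate_plan` returns `path` invisibly; `read_plate_plan`
#'   returns a `plate_plan`.
#' @export
write_plate_plan <- function(plan, path) {
  stopifnot(inherits(plan, "plate_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[run]", paste0("run_id = ", plan$run_id), "", "[targets]"), con)
  write.table(plan$targets, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("", "[wells]"), con)
  write.table(plan$wells, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_plan
#' @export
read_plate_plan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- cumsum(grepl("^\\[", lines))
  labs <- sub("^\\[(.*)\\]$", "\\1", lines[grepl("^\\[", lines)])
  get_section <- function(name) {
    idx <- which(labs == name)
    if (!length(idx)) stop("plate plan file lacks [", name, "] section")
    body <- lines[sec == idx]
    body[-1][nzchar(trimws(body[-1]))]
  }
  run_kv <- get_section("run")
  run_id <- trimws(sub("^run_id\\s*=", "", run_kv[grepl("^run_id", run_kv)]))
  read_tsv_block <- function(block) {
    read.table(text = paste(block, collapse = "\n"), sep = "\t", header = TRUE,
               stringsAsFactors = FALSE, colClasses = NA, na.strings = "NA_NONE_")
  }
  targets <- read_tsv_block(get_section("targets"))
  wells <- read_tsv_block(get_section("wells"))
  if (is.null(wells$melt_products)) wells$melt_products <- ""
  wells$melt_products[is.na(wells$melt_products)] <- ""
  wells$well <- as.character(wells$well)
  structure(list(run_id = run_id, targets = targets, wells = wells),
            class = "plate_plan")
}
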