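# Shared fixture builders. Everything is generated in code; no data files.

# A set of baseline-corrected curves + phases for one assay, as consumed by
# optimize_window_of_linearity() / iterate_assay().
make_assay_curves <- function(efficiencies, n0s, baseline = 50, plateau = 5000,
                              n_cycles = 55L, noise_sd = 0, seed = NULL,
                              config = amp_config()) {
  stopifnot(length(efficiencies) == length(n0s))
  with_seed_local(seed, {
    curves <- list()
    for (i in seq_along(efficiencies)) {
      s <- simulate_amplification_curve(n0s[i], efficiencies[i], baseline,
                                        plateau, n_cycles, noise_sd)
      bl <- estimate_baseline(s$fluor, config)
      stopifnot(bl$status == "ok")
      ph <- find_exponential_phase(bl$corrected, config,
                                   baseline = bl$baseline)
      curves[[paste0("w", i)]] <- list(corrected = bl$corrected, phase = ph,
                                       baseline = bl$baseline)
    }
    curves
  })
}

with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Independent baseline oracle: dense grid search over candidate baselines,
# maximizing the R^2 of the log10-linear fit over a fixed known-exponential
# cycle window.
oracle_baseline <- function(fluor, window, n_grid = 4000) {
  bs <- seq(0, min(fluor[window]) * 0.9999, length.out = n_grid)
  r2 <- vapply(bs, function(b) {
    y <- log10(fluor[window] - b)
    if (any(!is.finite(y))) return(-Inf)
    summary(lm(y ~ window))$r.squared
  }, numeric(1))
  bs[which.max(r2)]
}

# Small run with hand-picked sample types, built from simulated pieces.
make_classification_run <- function(seed = 401) {
  with_seed_local(seed, {
    mk <- function(n0) simulate_amplification_curve(n0, 1.9, 50, 5000, 45, 0.005)
    rx <- list(
      reaction_record("A1", "unk1", "t1",
                      adp = data.frame(cycle = 1:45, fluor = mk(1e-4)$fluor)),
      reaction_record("A2", "unk2", "t1",
                      adp = data.frame(cycle = 1:45, fluor = mk(1e-5)$fluor)),
      # amplified negative control (contamination)
      reaction_record("A3", "nc1", "t1",
                      adp = data.frame(cycle = 1:45, fluor = mk(1e-5)$fluor)),
      # silent positive control (failed reaction)
      reaction_record("A4", "pc1", "t1",
                      adp = data.frame(cycle = 1:45, fluor = mk(0)$fluor)),
      # silent unknown
      reaction_record("A5", "unk3", "t1",
                      adp = data.frame(cycle = 1:45, fluor = mk(0)$fluor)))
    run_data("class_run", rx,
             targets = data.frame(target_id = "t1", expected_tm = 85,
                                  dye_saturating = TRUE),
             samples = data.frame(
               sample_id = c("unk1", "unk2", "nc1", "pc1", "unk3"),
               sample_type = c("unknown", "unknown", "negative_control",
                               "positive_control", "unknown")))
  })
}

# Minimal annotated run for I/O tests.
make_tiny_run <- function(n_rx = 1, n_cycles = 40, melt = FALSE, seed = 51) {
  with_seed_local(seed, {
    rx <- lapply(seq_len(n_rx), function(i) {
      s <- simulate_amplification_curve(10^-(2 + i), 1.9, 50, 5000, n_cycles,
                                        0.005)
      mdp <- NULL
      if (melt) {
        m <- simulate_melt_curve(noise_sd = 0.002)
        mdp <- data.frame(temperature = m$temperature, fluor = m$fluor)
      }
      reaction_record(paste0("A", i), paste0("s", i), "t1",
                      adp = data.frame(cycle = seq_len(n_cycles),
                                       fluor = s$fluor),
                      mdp = mdp)
    })
    run_data("tiny", rx,
             targets = data.frame(target_id = "t1", expected_tm = 85,
                                  dye_saturating = TRUE),
             samples = data.frame(sample_id = paste0("s", seq_len(n_rx)),
                                  sample_type = "unknown"))
  })
}


# Field-by-field equality of two runs.
run_fields_equal <- function(a, b) {
  expect_identical(length(a$reactions), length(b$reactions))
  expect_identical(a$run_id, b$run_id)
  expect_equal(a$targets$target_id, b$targets$target_id)
  expect_equal(a$targets$expected_tm, b$targets$expected_tm)
  expect_equal(a$targets$dye_saturating, b$targets$dye_saturating)
  expect_equal(a$samples[order(a$samples$sample_id), ],
               b$samples[order(b$samples$sample_id), ],
               ignore_attr = TRUE)
  for (i in seq_along(a$reactions)) {
    ra <- a$reactions[[i]]; rb <- b$reactions[[i]]
    expect_identical(ra$well, rb$well)
    expect_identical(ra$sample_id, rb$sample_id)
    expect_identical(ra$target_id, rb$target_id)
    expect_identical(ra$adp$cycle, rb$adp$cycle)
    expect_identical(ra$adp$fluor, rb$adp$fluor)
    expect_identical(ra$mdp$temperature, rb$mdp$temperature)
    expect_identical(ra$mdp$fluor, rb$mdp$fluor)
  }
}

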