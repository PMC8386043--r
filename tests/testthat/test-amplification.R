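test_that("detect_amplification separates flat, sigmoid and truncated curves", {
  set.seed(21)
  flat <- 50 * (1 + rnorm(40, 0, 0.01))
  expect_identical(detect_amplification(flat), "not_amplified")
  full <- simulate_amplification_curve(1e-4, 1.9, 50, 5000, 45, 0)
  expect_identical(detect_amplification(full$fluor), "amplified")
  sdm <- which.max(diff(diff(full$truth$n_series))) + 1L
  expect_identical(detect_amplification(full$fluor[1:sdm]), "no_plateau")
  expect_error(detect_amplification(full$fluor[1:8]), "insufficient")
})

test_that("baseline bisection recovers a known baseline on a capped exponential", {
  f <- pmin(50 + 0.01 * 1.9^(1:40), 50 + 5000)
  fit <- estimate_baseline(f)
  expect_identical(fit$status, "ok")
  expect_lt(abs(fit$baseline - 50) / 50, 0.005)
  # agreement with the independent grid-search oracle
  b_star <- oracle_baseline(f, window = 8:20)
  expect_lt(abs(fit$baseline - b_star), 0.05)
})

test_that("baseline of a curve without added baseline is near zero", {
  f <- pmin(0.01 * 1.9^(1:40), 5000)
  fit <- estimate_baseline(f)
  expect_identical(fit$status, "ok")
  expect_lt(abs(fit$baseline), 0.05)
})

test_that("monotone linear drift yields a baseline error", {
  f <- 100 + 3 * (1:40)
  fit <- estimate_baseline(f)
  expect_identical(fit$status, "baseline_error")
})

test_that("baseline matches the grid-search oracle on simulated curves", {
  for (E in c(1.8, 1.95)) {
    s <- simulate_amplification_curve(1e-4, E, 60, 5000, 45, 0)
    fit <- estimate_baseline(s$fluor)
    expect_identical(fit$status, "ok")
    N <- s$truth$n_series
    window <- which(N > 1 & N < 5000 / 20)     # known log-linear segment
    b_star <- oracle_baseline(s$fluor, window)
    expect_lt(abs(fit$baseline - b_star), 0.6)
    expect_lt(abs(fit$baseline - 60) / 60, 0.005)
  }
})

test_that("exponential phase ends at the brute-force second-difference maximum", {
  s <- simulate_amplification_curve(1e-4, 1.9, 0, 5000, 45, 0)
  corrected <- s$fluor
  ph <- find_exponential_phase(corrected)
  # independent brute force on the 3-point-smoothed series
  sm <- stats::filter(corrected, rep(1 / 3, 3), sides = 2)
  d2 <- diff(diff(as.numeric(sm)))
  expect_identical(ph$sdm_cycle, as.integer(which.max(d2) + 1L))
  expect_lt(ph$start_cycle, ph$sdm_cycle)
  expect_gte(ph$centre_cycle, ph$start_cycle)
  expect_lte(ph$centre_cycle, ph$sdm_cycle)
})

test_that("without plateau exclusion the phase extends to the last cycle", {
  f <- 0.02 * 1.85^(1:30)               # strictly exponential, no plateau
  ph <- find_exponential_phase(f, status = "no_plateau")
  expect_identical(ph$sdm_cycle, 30L)
})

test_that("noise-only series gives no exponential phase", {
  set.seed(5)
  f <- rnorm(40, 0, 0.5)
  ph <- find_exponential_phase(f)
  expect_identical(ph$status, "no_amplification")
})

test_that("log-linear fit is exact on exact exponentials and rejects bad windows", {
  f <- 0.02 * 1.9^(1:40)
  for (w in list(3:5, 10:14, 20:25))
    expect_equal(fit_log_linear(f, w)$efficiency, 1.9, tolerance = 1e-12)
  expect_error(fit_log_linear(f, 5:6), "window invalid")
  f2 <- f; f2[12] <- 0
  expect_error(fit_log_linear(f2, 10:14), "window invalid")
})

test_that("window of linearity recovers a shared efficiency with tiny CV", {
  # exact shift replicates on ideal corrected curves: n0 values a whole
  # number of cycles apart, no baseline step involved
  E <- 1.85
  curves <- lapply(seq_len(8), function(i) {
    s <- simulate_amplification_curve(1e-3 * E^-(i * 3), E, 0, 5000, 55, 0)
    list(corrected = s$fluor,
         phase = find_exponential_phase(s$fluor))
  })
  names(curves) <- paste0("w", seq_len(8))
  res <- optimize_window_of_linearity(curves, target_id = "tgtA")
  expect_lt(res$cv, 1e-6)
  expect_equal(unname(res$e_tar), E, tolerance = 5e-3)
  expect_true(all(abs(res$efficiencies - E) < 5e-3))
  expect_gt(res$window[["upper_fluor"]], res$window[["lower_fluor"]])
})

test_that("a single-reaction assay is flagged and uses its own window", {
  curves <- make_assay_curves(1.9, 1e-4)
  res <- optimize_window_of_linearity(curves, target_id = "solo")
  expect_true("single_reaction" %in% res$flags)
  expect_equal(unname(res$e_tar), 1.9, tolerance = 0.01)
})

test_that("assays are processed independently of plate order", {
  curves <- make_assay_curves(rep(1.9, 4), 10^-(3:6), noise_sd = 0.01,
                              seed = 17)
  a <- iterate_assay(curves, target_id = "t")
  b <- iterate_assay(rev(curves), target_id = "t")
  expect_equal(sort(a$efficiencies), sort(b$efficiencies), tolerance = 1e-12)
  expect_equal(a$e_tar, b$e_tar, tolerance = 1e-12)
})

test_that("Grubbs screening matches the t-distribution formula", {
  # all equal: nothing excluded
  expect_true(all(detect_efficiency_outliers(rep(1.80, 12))))
  # planted high outlier among 11 replicates
  e <- c(rep(1.80, 11), 1.95)
  mask <- detect_efficiency_outliers(e, "grubbs", alpha = 0.05)
  # independent computation of the one-sided Grubbs decision
  g <- (max(e) - mean(e)) / sd(e)
  t2 <- qt(0.05 / 12, df = 10, lower.tail = FALSE)^2
  g_crit <- (11 / sqrt(12)) * sqrt(t2 / (10 + t2))
  expect_gt(g, g_crit)                 # the oracle agrees it is an outlier
  expect_identical(which(!mask), 12L)
  # below n = 3 the test is undefined: all included
  expect_true(all(detect_efficiency_outliers(c(1.7, 1.95), "grubbs")))
})

test_that("fixed-band screening excludes values outside median +/- halfwidth", {
  e <- c(1.70, 1.80, 1.82, 1.84, 1.95)
  mask <- detect_efficiency_outliers(e, "fixed_band", halfwidth = 0.05)
  expect_identical(mask, c(FALSE, TRUE, TRUE, TRUE, FALSE))
})

test_that("outlier mode none keeps everything", {
  e <- c(rep(1.8, 5), 1.2, 2.4)
  expect_true(all(detect_efficiency_outliers(e, "none")))
})

test_that("iterate_assay excludes a planted low-efficiency reaction", {
  curves <- make_assay_curves(c(rep(1.85, 7), 1.5),
                              c(10^-(2:8 * 6 / 8), 1e-4), noise_sd = 0)
  res <- iterate_assay(curves, target_id = "t")
  expect_false(res$included[["w8"]])
  expect_true(all(res$included[1:7]))
  expect_equal(unname(res$e_tar), 1.85, tolerance = 0.005)
  # the outlier still carries its own individual efficiency
  expect_equal(unname(res$efficiencies[["w8"]]), 1.5, tolerance = 0.02)
})

test_that("iterate_assay is a fixed point when no outliers are present", {
  curves <- make_assay_curves(rep(1.9, 5), 10^-(2:6), noise_sd = 0)
  res <- iterate_assay(curves, target_id = "t")
  expect_true(all(res$included))
})

test_that("common threshold lies inside every exponential phase", {
  ph1 <- structure(list(status = "ok", range_lo = 2, range_hi = 800,
                        centre_fluor = 40), class = "exp_phase")
  single <- set_common_threshold(list(ph1))
  expect_equal(single$nq, sqrt(2 * 800))
  expect_false(single$fallback)
  # idempotent on identical duplicates
  expect_equal(set_common_threshold(list(ph1, ph1))$nq, single$nq)
  # heterogeneous plate: threshold inside all ranges
  curves <- make_assay_curves(rep(1.9, 10), 10^-seq(2, 8, length.out = 10),
                              noise_sd = 0)
  thr <- set_common_threshold(lapply(curves, `[[`, "phase"))
  for (c in curves) {
    expect_gte(thr$nq, c$phase$range_lo)
    expect_lte(thr$nq, c$phase$range_hi)
  }
})

test_that("Cq calling follows the ideal-curve closed form", {
  ph <- structure(list(status = "ok", centre_cycle = 18.5, centre_fluor = 30),
                  class = "exp_phase")
  expect_equal(call_cq(ph, 1.9, 30), 18.5)
  expect_equal(call_cq(ph, 2.0, 120), 18.5 + 2)
  expect_error(call_cq(ph, 1.0, 30), "efficiency")
  # noiseless simulated reaction: called Cq within 0.05 cycles of the truth
  s <- simulate_amplification_curve(1e-5, 1.9, 50, 5000, 50, 0)
  bl <- estimate_baseline(s$fluor)
  phase <- find_exponential_phase(bl$corrected, baseline = bl$baseline)
  nq <- 20
  expect_lt(abs(call_cq(phase, 1.9, nq) - true_cq(s, nq)), 0.05)
})

test_that("N0 follows Nq / E^Cq with its algebraic identities", {
  expect_equal(compute_n0(1, 2, 20), 2^-20)
  expect_equal(compute_n0(12.5, 1.9, 0), 12.5)
  for (i in 1:20) {
    e <- runif(1, 1.5, 2); cq <- runif(1, 5, 35); d <- runif(1, 0, 5)
    expect_equal(compute_n0(1, e, cq) / compute_n0(1, e, cq + d), e^d,
                 tolerance = 1e-12)
  }
  expect_error(compute_n0(-1, 1.9, 20), "domain")
  expect_error(compute_n0(1, 0.9, 20), "domain")
})

test_that("classification implements the control logic by sample type", {
  amp_nc <- classify_reaction("amplified", "negative_control")
  expect_true("control_error" %in% amp_nc$flags)
  expect_identical(amp_nc$severity, "error")
  silent_pc <- classify_reaction("not_amplified", "positive_control")
  expect_true("control_error" %in% silent_pc$flags)
  expect_identical(silent_pc$severity, "error")
  silent_unk <- classify_reaction("not_amplified", "unknown")
  expect_true("no_amplification" %in% silent_unk$flags)
  expect_identical(silent_unk$severity, "warning")
  clean <- classify_reaction("amplified", "unknown")
  expect_length(clean$flags, 0)
  silent_nc <- classify_reaction("not_amplified", "negative_control")
  expect_length(silent_nc$flags, 0)
  outl <- classify_reaction("amplified", "unknown", efficiency_outlier = TRUE)
  expect_true("efficiency_outlier" %in% outl$flags)
})

test_that("whole-run analysis flags controls and suppresses N0 on errors", {
  run <- make_classification_run()
  res <- analyze_amplification(run)
  tab <- res$table
  expect_true(grepl("control_error", tab$flags[tab$well == "A3"]))
  expect_true(grepl("control_error", tab$flags[tab$well == "A4"]))
  expect_true(grepl("no_amplification", tab$flags[tab$well == "A5"]))
  # the amplified NC keeps its Cq for manual use but gets no automatic N0
  expect_true(is.finite(tab$cq[tab$well == "A3"]))
  expect_true(is.na(tab$n0[tab$well == "A3"]))
  expect_true(is.finite(tab$n0[tab$well == "A1"]))
})

test_that("shuffling plate order leaves per-well results unchanged", {
  plan <- default_plate_plan(n_targets = 2, n_unknown = 5, melt = FALSE)
  sim <- generate_synthetic_run(plan, seed = 9)
  res1 <- analyze_amplification(sim$run)
  run2 <- sim$run
  run2$reactions <- rev(run2$reactions)
  res2 <- analyze_amplification(run2)
  t1 <- res1$table[order(res1$table$well), ]
  t2 <- res2$table[order(res2$table$well), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("a plate of empty wells raises a run-level error", {
  set.seed(33)
  rx <- lapply(1:4, function(i)
    reaction_record(paste0("A", i), "s1", "t1",
                    adp = data.frame(cycle = 1:40,
                                     fluor = 50 * (1 + rnorm(40, 0, 0.01)))))
  run <- run_data("empty", rx,
                  targets = data.frame(target_id = "t1"),
                  samples = data.frame(sample_id = "s1",
                                       sample_type = "unknown"))
  expect_error(analyze_amplification(run), "run-level error")
})

test_that("slope tolerance translates to the documented efficiency difference", {
  s <- log10(1.8)
  delta_emp <- 10^(s + 1e-4) - 10^s
  delta_ana <- log(10) * 1.8 * 1e-4
  expect_equal(delta_emp, delta_ana, tolerance = 1e-3)
  expect_equal(signif(delta_ana, 1), 4e-4)
})
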