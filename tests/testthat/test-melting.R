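two_products <- data.frame(tm = c(79, 85), steepness = 0.8,
                           amplitude = c(0.75, 0.25))

# full derivative pipeline on a simulated curve
melt_pipeline <- function(sim, config = melt_config()) {
  sm <- smooth_melt(sim$temperature, sim$fluor)
  norm <- normalize_melt(sim$temperature, sm, config$normalization,
                         config$anchor_frac)
  dv <- melt_derivatives(sim$temperature, norm)
  peaks <- call_melt_peaks(sim$temperature, dv$d1neg, dv$d2, config)
  list(norm = norm, d1neg = dv$d1neg, d2 = dv$d2, peaks = peaks)
}

test_that("smoothing leaves noise-free curves essentially untouched", {
  sim <- simulate_melt_curve(products = two_products, noise_sd = 0)
  sm <- smooth_melt(sim$temperature, sim$fluor)
  expect_lt(max(abs(sm - sim$fluor)) / diff(range(sim$fluor)), 1e-3)
  # constant series stays constant
  temps <- seq(65, 95, 0.5)
  expect_equal(smooth_melt(temps, rep(2, length(temps))), rep(2, length(temps)),
               tolerance = 1e-9)
  expect_error(smooth_melt(1:10, rnorm(10)), "insufficient")
})

test_that("smoothing does not displace the main melt peak under noise", {
  sim0 <- simulate_melt_curve(products = two_products, noise_sd = 0)
  d0 <- melt_derivatives(sim0$temperature,
                         normalize_melt(sim0$temperature,
                                        smooth_melt(sim0$temperature, sim0$fluor)))
  ref <- sim0$temperature[which.max(d0$d1neg)]
  simn <- simulate_melt_curve(products = two_products, noise_sd = 0.005,
                              seed = 12)
  dn <- melt_derivatives(simn$temperature,
                         normalize_melt(simn$temperature,
                                        smooth_melt(simn$temperature, simn$fluor)))
  noisy <- simn$temperature[which.max(dn$d1neg)]
  expect_lte(abs(noisy - ref), 0.2)   # within two grid steps of 0.1 C
})

test_that("bilinear normalization maps pre-melt to 1 and post-melt to 0", {
  sim <- simulate_melt_curve(products = data.frame(tm = 82, steepness = 0.8,
                                                   amplitude = 1),
                             background = c(3, -0.02), noise_sd = 0)
  norm <- normalize_melt(sim$temperature, smooth_melt(sim$temperature, sim$fluor),
                         "bilinear")
  expect_lt(max(abs(norm[1:20] - 1)), 0.02)
  expect_lt(max(abs(tail(norm, 20))), 0.02)
})

test_that("with a flat background bilinear equals min-max rescaling", {
  sim <- simulate_melt_curve(products = data.frame(tm = 80, steepness = 0.6,
                                                   amplitude = 1),
                             background = c(0.5, 0), noise_sd = 0)
  norm <- normalize_melt(sim$temperature, sim$fluor, "bilinear")
  rescaled <- (sim$fluor - min(sim$fluor)) / diff(range(sim$fluor))
  expect_equal(norm, rescaled, tolerance = 1e-3)
})

test_that("combined normalization flattens an exponential background better", {
  temps <- seq(65, 95, 0.1)
  bg <- 2 * exp(-0.03 * (temps - 65))
  product <- 1 / (1 + exp((temps - 82) / 0.8))
  f <- bg + product
  bil <- normalize_melt(temps, f, "bilinear")
  comb <- normalize_melt(temps, f, "combined")
  pre <- which(temps <= 75)
  expect_lt(var(comb[pre]), var(bil[pre]))
})

test_that("normalizing an already-normalized curve is idempotent", {
  temps <- seq(65, 95, 0.1)
  f <- 1 / (1 + exp((temps - 80) / 0.6))
  once <- normalize_melt(temps, f, "bilinear")
  expect_lt(max(abs(once - f)), 1e-6)
})

test_that("derivatives recover analytic peak positions", {
  temps <- seq(70, 95, 0.1)
  f <- 1 / (1 + exp((temps - 85) / 0.8))
  dv <- melt_derivatives(temps, f)
  expect_lt(abs(temps[which.max(dv$d1neg)] - 85), 0.11)
  # linear curve: constant first derivative, zero second derivative
  lin <- 5 - 0.1 * temps
  dl <- melt_derivatives(temps, lin)
  expect_equal(dl$d1neg, rep(0.1, length(temps)), tolerance = 1e-9)
  expect_equal(max(abs(dl$d2)), 0, tolerance = 1e-9)
  # two separated products: two local maxima at the two Tm values
  f2 <- 0.6 / (1 + exp((temps - 78) / 0.7)) + 0.4 / (1 + exp((temps - 88) / 0.7))
  d1 <- melt_derivatives(temps, f2)$d1neg
  n <- length(d1)
  is_max <- which(d1[2:(n - 1)] > d1[1:(n - 2)] & d1[2:(n - 1)] >= d1[3:n]) + 1L
  maxima <- temps[is_max]
  expect_true(any(abs(maxima - 78) < 0.2))
  expect_true(any(abs(maxima - 88) < 0.2))
})

test_that("peak calling keeps both products of a 75/25 mixture", {
  sim <- simulate_melt_curve(products = two_products, noise_sd = 0)
  pl <- melt_pipeline(sim)
  expect_identical(nrow(pl$peaks), 2L)
  expect_lt(abs(pl$peaks$tm[1] - 79), 0.15)
  expect_lt(abs(pl$peaks$tm[2] - 85), 0.15)
  expect_true(all(pl$peaks$width > 0 & pl$peaks$width <= 5))
})

test_that("bumps below the relative height cut-off are excluded", {
  small <- data.frame(tm = c(79, 86), steepness = 0.8, amplitude = c(0.97, 0.03))
  sim <- simulate_melt_curve(products = small, noise_sd = 0)
  pl <- melt_pipeline(sim)
  expect_identical(nrow(pl$peaks), 1L)
  expect_lt(abs(pl$peaks$tm - 79), 0.15)
  expect_gt(attr(pl$peaks, "n_candidates"), 1L)
})

test_that("transitions wider than the width cut-off are excluded", {
  wide <- data.frame(tm = c(75, 86), steepness = c(2.8, 0.8), amplitude = c(1, 1))
  sim <- simulate_melt_curve(products = wide, t_range = c(60, 95, 0.1),
                             noise_sd = 0)
  pl <- melt_pipeline(sim)
  expect_identical(nrow(pl$peaks), 1L)
  expect_lt(abs(pl$peaks$tm - 86), 0.15)
})

test_that("expected-Tm matching labels peaks and raises the right flags", {
  pk <- data.frame(tm = c(85.4), delta_height = 1, width = 2,
                   t_left = 84, t_right = 86, idx_left = 1L, idx_right = 2L,
                   apex_idx = 1L)
  m <- match_expected_tm(pk, 85.0, tol = 1.0)
  expect_true(m$is_expected[1])
  expect_length(attr(m, "flags"), 0)
  m2 <- match_expected_tm(transform(pk, tm = 78), 85, tol = 1.0)
  expect_true("no_expected_peak" %in% attr(m2, "flags"))
  pk2 <- rbind(pk, transform(pk, tm = 79))
  m3 <- match_expected_tm(pk2, 85, tol = 1.0)
  expect_identical(m3$is_expected, c(TRUE, FALSE))
  expect_true("multiple_products" %in% attr(m3, "flags"))
  # two peaks inside the window: the closer one wins
  pk3 <- rbind(pk, transform(pk, tm = 85.9))
  m4 <- match_expected_tm(pk3, 85, tol = 1.0)
  expect_identical(m4$is_expected, c(TRUE, FALSE))
})

test_that("peak fractions recover amplitude shares and sum to one", {
  sim <- simulate_melt_curve(products = two_products, noise_sd = 0)
  pl <- melt_pipeline(sim)
  pk <- peak_fluorescence_fractions(pl$norm, pl$peaks)
  expect_equal(sum(pk$fraction), 1, tolerance = 1e-9)
  expect_equal(pk$fraction, c(0.75, 0.25), tolerance = 0.03)
  # single product: fraction 1
  one <- simulate_melt_curve(noise_sd = 0)
  p1 <- melt_pipeline(one)
  expect_equal(peak_fluorescence_fractions(p1$norm, p1$peaks)$fraction, 1)
  # invariance under uniform rescaling of the normalized curve
  pk2 <- peak_fluorescence_fractions(pl$norm * 3.7, pl$peaks)
  expect_equal(pk2$fraction, pk$fraction, tolerance = 1e-12)
})

test_that("fraction recovery holds across amplitude shares", {
  for (p in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    prods <- data.frame(tm = c(79, 85), steepness = 0.8, amplitude = c(1 - p, p))
    sim <- simulate_melt_curve(products = prods, noise_sd = 0)
    pl <- melt_pipeline(sim)
    pk <- peak_fluorescence_fractions(pl$norm, pl$peaks)
    got <- pk$fraction[which.min(abs(pk$tm - 85))]
    expect_lt(abs(got - p), 0.03)
  }
})

test_that("quantification correction preserves the threshold identity", {
  same <- correct_quantification(20, 1e-5, 1, 1.9, TRUE)
  expect_equal(same$corrected_cq, 20)
  expect_equal(same$corrected_n0, 1e-5)
  q <- correct_quantification(20, 1e-5, 0.25, 2, TRUE)
  expect_equal(q$corrected_cq, 22)
  expect_equal(q$corrected_n0, 2.5e-6)
  refused <- correct_quantification(20, 1e-5, 0.25, 2, FALSE)
  expect_false(refused$applicable)
  expect_match(refused$flag, "saturating")
  set.seed(8)
  for (i in 1:25) {
    nq <- runif(1, 1, 100); e <- runif(1, 1.5, 2)
    cq <- runif(1, 10, 35); fr <- runif(1, 0.05, 1)
    n0 <- nq / e^cq
    cr <- correct_quantification(cq, n0, fr, e, TRUE)
    expect_equal(cr$corrected_n0, nq / e^cr$corrected_cq, tolerance = 1e-12)
  }
})

test_that("melt analysis of a clean plate applies no corrections", {
  plan <- default_plate_plan(n_targets = 2, n_unknown = 3, noise_sd = 0,
                             melt_noise_sd = 0)
  sim <- generate_synthetic_run(plan, seed = 31)
  amp <- analyze_amplification(sim$run)
  mel <- analyze_melting(sim$run, amp)
  tab <- mel$table
  with_peaks <- tab[!is.na(tab$peak), ]
  expect_true(all(with_peaks$fraction == 1))
  expect_true(all(with_peaks$is_expected))
  expect_true(all(!nzchar(with_peaks$flags)))
  expect_true(all(is.na(tab$correction_factor)))
  expect_equal(mel$corrected_table$cq, amp$table$cq)
})

test_that("an artifact-dominated reaction is noted and corrected", {
  plan <- default_plate_plan(n_targets = 1, n_unknown = 3, noise_sd = 0,
                             melt_noise_sd = 0)
  # well 2 amplifies 75% artifact (Tm 79) and 25% correct product (Tm 85)
  plan$wells$melt_products[2] <- "79:0.8:0.75;85:0.8:0.25"
  sim <- generate_synthetic_run(plan, seed = 32)
  amp <- analyze_amplification(sim$run)
  mel <- analyze_melting(sim$run, amp)
  w <- plan$wells$well[2]
  res <- mel$reactions[[w]]
  expect_true("multiple_products" %in% res$flags)
  expect_equal(res$correction_factor, 0.25, tolerance = 0.03)
  amp_row <- amp$table[amp$table$well == w, ]
  expect_equal(res$corrected_n0, res$correction_factor * amp_row$n0,
               tolerance = 1e-12)
  # ignoring the melt correction leaves the amplification results untouched
  mel2 <- analyze_melting(sim$run, amp, melt_config(apply_correction = FALSE))
  expect_equal(mel2$corrected_table$cq, amp$table$cq)
  expect_equal(mel2$corrected_table$n0, amp$table$n0)
})
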