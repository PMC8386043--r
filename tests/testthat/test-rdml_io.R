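test_that("a minimal archive round-trips exactly", {
  run <- make_tiny_run(1)
  path <- withr::local_tempfile(fileext = ".rdml")
  write_rdml(run, path)
  back <- read_rdml(path)
  expect_length(back$reactions, 1)
  expect_identical(nrow(back$reactions[[1]]$adp), 40L)
  run_fields_equal(run, back)
})

test_that("a simulated plate round-trips field-by-field", {
  plan <- default_plate_plan(n_targets = 2, n_unknown = 6)
  sim <- generate_synthetic_run(plan, seed = 41)
  path <- withr::local_tempfile(fileext = ".rdml")
  write_rdml(sim$run, path)
  back <- read_rdml(path)
  run_fields_equal(sim$run, back)
})

test_that("RDML versions below 1.1 are rejected", {
  run <- make_tiny_run(1)
  path <- withr::local_tempfile(fileext = ".rdml")
  write_rdml(run, path)
  xml <- readLines(ampmelt:::zip_read_entry(path), warn = FALSE)
  xml <- sub('version="1.2"', 'version="1.0"', xml, fixed = TRUE)
  ampmelt:::zip_write_single(path, "rdml_data.xml", xml)
  expect_error(read_rdml(path), "version 1.1 or higher")
})

test_that("non-zip input raises a format error", {
  txt <- withr::local_tempfile(fileext = ".rdml")
  writeLines("this is not an archive", txt)
  expect_error(read_rdml(txt), "format error")
  expect_error(read_rdml(file.path(tempdir(), "does_not_exist.rdml")), "I/O")
})

test_that("stored analysis results survive the round trip", {
  run <- make_tiny_run(4, melt = TRUE)
  amp <- analyze_amplification(run)
  mel <- analyze_melting(run, amp)
  path <- withr::local_tempfile(fileext = ".rdml")
  write_rdml(run, path, amp_results = amp, melt_results = mel)
  back <- read_rdml(path)
  expect_false(is.null(back$results))
  m <- match(amp$table$well, back$results$well)
  expect_identical(back$results$cq[m], amp$table$cq)
  expect_identical(back$results$n0[m], amp$table$n0)
  expect_identical(back$results$amp_eff[m], amp$table$e_tar)
  expect_identical(unique(back$results$quant_fluor), amp$threshold$nq)
})

test_that("an invalid run is rejected before writing", {
  run <- make_tiny_run(2)
  run$reactions[[2]]$well <- run$reactions[[1]]$well
  expect_error(write_rdml(run, withr::local_tempfile(fileext = ".rdml")),
               "validation error")
})

test_that("long and wide tables import to identical runs", {
  set.seed(61)
  wells <- c("A1", "A2")
  curves <- lapply(1:2, function(i)
    simulate_amplification_curve(10^-(2 + i), 1.85, 40, 5000, 30, 0.01)$fluor)
  long <- do.call(rbind, lapply(1:2, function(i)
    data.frame(well = wells[i], cycle = 1:30, fluor = curves[[i]],
               sample = paste0("s", i), target = "t1",
               sample_type = "unknown")))
  wide <- data.frame(cycle = 1:30, A1 = curves[[1]], A2 = curves[[2]])
  ann <- data.frame(well = wells, sample = c("s1", "s2"), target = "t1",
                    sample_type = "unknown")
  r_long <- import_table(long, table_layout("long"))
  r_wide <- import_table(wide, table_layout("wide"), annotation = ann)
  run_fields_equal(r_long, r_wide)
})

test_that("small long tables import with the expected shape", {
  long <- data.frame(well = rep(c("A1", "B7"), each = 3),
                     cycle = rep(1:3, 2), fluor = c(1, 2, 4, 2, 4, 8))
  expect_warning(run <- import_table(long), "annotation")
  expect_length(run$reactions, 2)
  expect_identical(nrow(run$reactions[[1]]$adp), 3L)
  expect_identical(run$samples$sample_type, c("unknown", "unknown"))
})

test_that("defective tables raise named errors", {
  long <- data.frame(well = "A1", kykle = 1:3, fluor = c(1, 2, 4))
  expect_error(import_table(long), "column 'cycle' not found")
  bad <- data.frame(well = "A1", cycle = 1:3, fluor = c("1", "oops", "4"))
  expect_error(suppressWarnings(import_table(bad)), "row 2")
})

test_that("result CSVs are written, flagged and parse back exactly", {
  run <- make_classification_run()
  amp <- analyze_amplification(run)
  amp_csv <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(run, amp, amp_csv)
  parsed <- read.csv(amp_csv, stringsAsFactors = FALSE)
  expect_identical(nrow(parsed), nrow(amp$table))
  # non-amplifying reaction: empty Cq and N0, populated flag column
  a5 <- parsed[parsed$well == "A5", ]
  expect_true(is.na(a5$cq))
  expect_true(is.na(a5$n0))
  expect_match(a5$flags, "no_amplification")
  # numeric columns reproduce the results to full printed precision
  ok <- is.finite(amp$table$cq)
  expect_equal(parsed$cq[ok], amp$table$cq[ok], tolerance = 1e-14)
  expect_equal(parsed$n0[ok], amp$table$n0[ok], tolerance = 1e-14)
})

test_that("one-reaction export yields a header plus one row", {
  run <- make_tiny_run(1)
  amp <- analyze_amplification(run)
  path <- withr::local_tempfile(fileext = ".csv")
  export_results_csv(run, amp, path)
  expect_length(readLines(path), 2L)
})
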