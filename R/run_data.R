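#' Construct a reaction record
#'
#' One well of a run: annotation plus the raw amplification data points
#' (`adp`: cycle, fluorescence) and/or melting data points (`mdp`:
#' temperature, fluorescence). Raw series are stored untouched; no analysis
#' function ever modifies them.
#'
#' @param well Well identifier, e.g. `"D8"`.
#' @param sample_id,target_id Identifiers resolved against the run annotation.
#' @param adp Data frame with columns `cycle` (strictly increasing consecutive
#'   integers starting anywhere at or above 1) and `fluor`, or `NULL`.
#' @param mdp Data frame with columns `temperature` (strictly increasing,
#'   degrees C) and `fluor`, or `NULL`.
#' @return A list of class `reaction_record`.
#' @export
reaction_record <- function(well, sample_id, target_id, adp = NULL, mdp = NULL) {
  if (!is.null(adp) && nrow(adp)) {
    stopifnot(all(c("cycle", "fluor") %in% names(adp)))
    cyc <- adp$cycle
    if (cyc[1] < 1 || (length(cyc) > 1 && any(diff(cyc) != 1)))
      stop("reaction ", well, ": adp cycles must be consecutive integers >= 1")
  } else adp <- NULL
  if (!is.null(mdp) && nrow(mdp)) {
    stopifnot(all(c("temperature", "fluor") %in% names(mdp)))
    if (any(diff(mdp$temperature) <= 0))
      stop("reaction ", well, ": mdp temperatures must be strictly increasing")
  } else mdp <- NULL
  if (is.null(adp) && is.null(mdp))
    stop("reaction ", well, ": at least one of adp/mdp must be non-empty")
  structure(list(well = as.character(well),
                 sample_id = as.character(sample_id),
                 target_id = as.character(target_id),
                 adp = adp, mdp = mdp),
            class = "reaction_record")
}

#' Construct a run container
#'
#' Holds the reactions of one qPCR run together with its target and sample
#' annotation. Sample types drive the error/warning classification: positive
#' controls must amplify, negative controls must not.
#'
#' @param run_id Run identifier.
#' @param reactions List of [reaction_record()] objects.
#' @param targets Data frame with columns `target_id`, optional `expected_tm`
#'   (degrees C, must lie in \[40, 99\] when given) and optional
#'   `dye_saturating` (logical).
#' @param samples Data frame with columns `sample_id` and `sample_type`
#'   (one of `"unknown"`, `"positive_control"`, `"negative_control"`).
#' @param results Optional analysis results (attached by [write_rdml()] /
#'   [read_rdml()] round trips).
#' @return A list of class `run_data`.
#' @export
run_data <- function(run_id, reactions, targets, samples, results = NULL) {
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(targets$expected_tm)) targets$expected_tm <- NA_real_
  if (is.null(targets$dye_saturating)) targets$dye_saturating <- FALSE
  run <- structure(list(run_id = as.character(run_id),
                        reactions = reactions,
                        targets = targets,
                        samples = samples,
                        results = results),
                   class = "run_data")
  validate_run_data(run)
  run
}

#' Validate the structural invariants of a run
#'
#' Checks that wells are unique, every reaction references an annotated sample
#' and target, sample types take one of the three allowed values and expected
#' melting temperatures are plausible. Called by [run_data()] and before
#' [write_rdml()].
#'
#' @param run A `run_data` object.
#' @return `run`, invisibly; errors describe the first violated invariant.
#' @export
validate_run_data <- function(run) {
  stopifnot(inherits(run, "run_data"))
  wells <- vapply(run$reactions, `[[`, character(1), "well")
  if (anyDuplicated(wells))
    stop("validation error: duplicate wells: ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  ok_types <- c("unknown", "positive_control", "negative_control")
  bad <- setdiff(run$samples$sample_type, ok_types)
  if (length(bad))
    stop("validation error: invalid sample_type: ", paste(bad, collapse = ", "))
  for (r in run$reactions) {
    if (!r$sample_id %in% run$samples$sample_id)
      stop("validation error: reaction ", r$well,
           " references unknown sample_id '", r$sample_id, "'")
    if (!r$target_id %in% run$targets$target_id)
      stop("validation error: reaction ", r$well,
           " references unknown target_id '", r$target_id, "'")
  }
  tm <- run$targets$expected_tm
  if (any(!is.na(tm) & (tm < 40 | tm > 99)))
    stop("validation error: expected_tm outside [40, 99] degrees C")
  invisible(run)
}

#' @export
print.run_data <- function(x, ...) {
  cat("qPCR run '", x$run_id, "': ", length(x$reactions), " reactions, ",
      nrow(x$targets), " targets, ", nrow(x$samples), " samples\n", sep = "")
  n_adp <- sum(vapply(x$reactions, function(r) !is.null(r$adp), logical(1)))
  n_mdp <- sum(vapply(x$reactions, function(r) !is.null(r$mdp), logical(1)))
  cat("  amplification data: ", n_adp, " reactions; melting data: ",
      n_mdp, " reactions\n", sep = "")
  invisible(x)
}

sample_type_of <- function(run, sample_id) {
  i <- match(sample_id, run$samples$sample_id)
  if (is.na(i)) "unknown" else run$samples$sample_type[i]
}

target_info_of <- function(run, target_id) {
  i <- match(target_id, run$targets$target_id)
  if (is.na(i)) list(expected_tm = NA_real_, dye_saturating = FALSE)
  else as.list(run$targets[i, ])
}
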