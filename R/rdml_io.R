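#' RDML input and output
#'
#' @section RDML dialect:
#' RDML stores a qPCR run as a zip-compressed XML document. This package
#' writes a single practical dialect (v1.2 element names, file entry
#' `rdml_data.xml`) and reads v1.1-v1.3 files by tolerant, namespace-stripped
#' element lookup. Two conventions extend the pre-1.3 schema: the expected
#' product melting temperature is stored as a `meltingTemperature` child of
#' `target`, and the saturating-dye property as a `dyeSaturating` child.
#' Analysis results are stored per reaction inside `data`: `ampEff` (assay
#' efficiency), `quantFluor` (common threshold), `cq`, `N0`, `corrF`
#' (melting correction factor), `corrCq`, and `note` (flags).
#' @name rdml_io
#' @keywords internal
NULL

fmt_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x), "")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

sample_type_to_rdml <- c(unknown = "unkn", positive_control = "pos",
                         negative_control = "ntc")
sample_type_from_rdml <- c(unkn = "unknown", pos = "positive_control",
                           ntc = "negative_control", nac = "negative_control",
                           std = "unknown", opt = "unknown")

#' Write a run (and optionally its analysis results) to an RDML file
#'
#' Produces a zip archive holding one XML document (`rdml_data.xml`) in the
#' dialect described under [rdml_io]. When analysis results are supplied,
#' the per-target efficiency and common threshold, per-reaction Cq and N0,
#' and the melting correction factor are stored with the raw data.
#'
#' @param run A [run_data] object (validated before writing).
#' @param path Destination file path.
#' @param amp_results Optional `amp_analysis` from [analyze_amplification()].
#' @param melt_results Optional `melt_analysis` from [analyze_melting()].
#' @return `path`, invisibly.
#' @export
write_rdml <- function(run, path, amp_results = NULL, melt_results = NULL) {
  validate_run_data(run)
  out <- character(0)
  add <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<rdml version="1.2" xmlns="http://www.rdml.org">')
  for (i in seq_len(nrow(run$samples))) {
    s <- run$samples[i, ]
    add('  <sample id="', xml_escape(s$sample_id), '">',
        '<type>', sample_type_to_rdml[[s$sample_type]], '</type></sample>')
  }
  for (i in seq_len(nrow(run$targets))) {
    t <- run$targets[i, ]
    add('  <target id="', xml_escape(t$target_id), '"><type>toi</type>',
        if (!is.na(t$expected_tm))
          paste0('<meltingTemperature>', fmt_num(t$expected_tm),
                 '</meltingTemperature>') else "",
        if (isTRUE(t$dye_saturating)) '<dyeSaturating>true</dyeSaturating>'
        else "",
        '</target>')
  }
  add('  <experiment id="exp1">')
  add('    <run id="', xml_escape(run$run_id), '">')
  amp_tab <- if (!is.null(amp_results)) amp_results$table else NULL
  for (r in run$reactions) {
    add('      <react id="', xml_escape(r$well), '">')
    add('        <sample id="', xml_escape(r$sample_id), '"/>')
    add('        <data><tar id="', xml_escape(r$target_id), '"/>')
    if (!is.null(amp_tab)) {
      i <- match(r$well, amp_tab$well)
      if (!is.na(i)) {
        row <- amp_tab[i, ]
        if (is.finite(row$e_tar)) add('          <ampEff>', fmt_num(row$e_tar), '</ampEff>')
        if (!is.null(amp_results$threshold))
          add('          <quantFluor>', fmt_num(amp_results$threshold$nq), '</quantFluor>')
        if (is.finite(row$cq)) add('          <cq>', fmt_num(row$cq), '</cq>')
        if (is.finite(row$n0)) add('          <N0>', fmt_num(row$n0), '</N0>')
        if (nzchar(row$flags)) add('          <note>', xml_escape(row$flags), '</note>')
      }
    }
    if (!is.null(melt_results)) {
      mr <- melt_results$reactions[[r$well]]
      if (!is.null(mr) && is.finite(mr$correction_factor)) {
        add('          <corrF>', fmt_num(mr$correction_factor), '</corrF>')
        add('          <corrCq>', fmt_num(mr$corrected_cq), '</corrCq>')
      }
    }
    if (!is.null(r$adp)) {
      add(paste0('          <adp><cyc>', r$adp$cycle, '</cyc><fluor>',
                 fmt_num(r$adp$fluor), '</fluor></adp>', collapse = "\n"))
    }
    if (!is.null(r$mdp)) {
      add(paste0('          <mdp><tmp>', fmt_num(r$mdp$temperature),
                 '</tmp><fluor>', fmt_num(r$mdp$fluor), '</fluor></mdp>',
                 collapse = "\n"))
    }
    add('        </data>')
    add('      </react>')
  }
  add('    </run>')
  add('  </experiment>')
  add('</rdml>')
  zip_write_single(path, "rdml_data.xml", paste(out, collapse = "\n"))
  invisible(path)
}

num_or_na <- function(x) if (length(x)) as.numeric(x) else NA_real_

#' Read an RDML file
#'
#' Accepts RDML versions 1.1-1.3 by tolerant element lookup (namespaces are
#' stripped; the react `id` attribute is taken as the well label). Raw
#' amplification and melting series are returned exactly as stored — never
#' baseline-corrected. Analysis results stored in the file are exposed in
#' the `results` element of the returned run.
#'
#' @param path Path to a zip-compressed RDML file.
#' @return A [run_data] object.
#' @export
read_rdml <- function(path) {
  xml_path <- zip_read_entry(path)
  doc <- tryCatch(xml2::read_xml(xml_path),
                  error = function(e) stop("format error: invalid XML in '",
                                           path, "': ", conditionMessage(e)))
  # namespace-qualified lookup: stripping namespaces walks the whole
  # document and is prohibitively slow on plate-sized files
  nsmap <- xml2::xml_ns(doc)
  prefixed <- length(nsmap) > 0 && "d1" %in% names(nsmap)
  xp <- function(path) {
    if (prefixed) gsub("/(?=[A-Za-z])", "/d1:", path, perl = TRUE) else path
  }
  root <- xml2::xml_name(doc)
  if (!identical(root, "rdml"))
    stop("structural error: root element is '", root, "', expected 'rdml'")
  version <- suppressWarnings(as.numeric(xml2::xml_attr(doc, "version")))
  if (is.finite(version) && version < 1.1)
    stop("unsupported RDML version ", version,
         ": version 1.1 or higher is required")

  sample_nodes <- xml2::xml_find_all(doc, xp("./sample"))
  if (!length(sample_nodes)) stop("structural error: missing element 'sample'")
  samples <- data.frame(
    sample_id = xml2::xml_attr(sample_nodes, "id"),
    sample_type = vapply(sample_nodes, function(s) {
      ty <- xml2::xml_text(xml2::xml_find_first(s, xp("./type")))
      if (is.na(ty) || !ty %in% names(sample_type_from_rdml)) "unknown"
      else sample_type_from_rdml[[ty]]
    }, character(1)),
    stringsAsFactors = FALSE)

  target_nodes <- xml2::xml_find_all(doc, xp("./target"))
  if (!length(target_nodes)) stop("structural error: missing element 'target'")
  targets <- data.frame(
    target_id = xml2::xml_attr(target_nodes, "id"),
    expected_tm = vapply(target_nodes, function(t)
      num_or_na(xml2::xml_text(xml2::xml_find_all(t, xp("./meltingTemperature")))),
      numeric(1)),
    dye_saturating = vapply(target_nodes, function(t)
      identical(xml2::xml_text(xml2::xml_find_first(t, xp("./dyeSaturating"))), "true"),
      logical(1)),
    stringsAsFactors = FALSE)

  run_node <- xml2::xml_find_first(doc, xp("./experiment/run"))
  if (inherits(run_node, "xml_missing"))
    stop("structural error: missing element 'experiment/run'")
  run_id <- xml2::xml_attr(run_node, "id")
  if (is.na(run_id)) run_id <- "run1"

  react_nodes <- xml2::xml_find_all(run_node, xp("./react"))
  if (!length(react_nodes)) stop("structural error: missing element 'react'")
  n_rx <- length(react_nodes)
  wells <- xml2::xml_attr(react_nodes, "id")

  # vectorized extraction: per-node XPath queries are prohibitively slow on
  # plate-sized documents, so everything is pulled in a handful of global
  # queries and split by per-react element counts
  sample_ids <- xml2::xml_attr(xml2::xml_find_first(react_nodes, xp("./sample")), "id")
  if (anyNA(sample_ids))
    stop("structural error: react '", wells[which(is.na(sample_ids))[1]],
         "' lacks element 'sample'")
  data_nodes <- xml2::xml_find_first(react_nodes, xp("./data"))
  n_data <- xml2::xml_find_num(react_nodes, xp("count(./data)"))
  if (any(n_data < 1))
    stop("structural error: react '", wells[which(n_data < 1)[1]],
         "' lacks element 'data'")
  target_ids <- xml2::xml_attr(xml2::xml_find_first(data_nodes, xp("./tar")), "id")
  if (anyNA(target_ids))
    stop("structural error: react '", wells[which(is.na(target_ids))[1]],
         "' lacks element 'tar'")

  base_xp <- "./experiment/run/react/data"
  pull <- function(sub) as.numeric(xml2::xml_text(
    xml2::xml_find_all(doc, xp(paste0(base_xp, "/", sub)))))
  n_adp <- xml2::xml_find_num(react_nodes, xp("count(./data/adp)"))
  n_mdp <- xml2::xml_find_num(react_nodes, xp("count(./data/mdp)"))
  adp_cyc <- pull("adp/cyc"); adp_fl <- pull("adp/fluor")
  mdp_tmp <- pull("mdp/tmp"); mdp_fl <- pull("mdp/fluor")
  if (length(adp_cyc) != sum(n_adp) || length(mdp_tmp) != sum(n_mdp))
    stop("structural error: incomplete adp/mdp data points")
  adp_split <- split(seq_along(adp_cyc), rep(seq_len(n_rx), n_adp))
  mdp_split <- split(seq_along(mdp_tmp), rep(seq_len(n_rx), n_mdp))

  # string() + as.numeric: XPath number() does not parse to full precision
  res_field <- function(el) {
    txt <- xml2::xml_find_chr(data_nodes, xp(paste0("string(./", el, ")")))
    suppressWarnings(as.numeric(ifelse(nzchar(txt), txt, NA_character_)))
  }
  res_df <- data.frame(well = wells, target = target_ids,
                       cq = res_field("cq"), n0 = res_field("N0"),
                       amp_eff = res_field("ampEff"),
                       quant_fluor = res_field("quantFluor"),
                       corr_f = res_field("corrF"),
                       corr_cq = res_field("corrCq"),
                       note = xml2::xml_find_chr(data_nodes, xp("string(./note)")),
                       stringsAsFactors = FALSE)
  has_res <- rowSums(!is.na(res_df[, c("cq", "n0", "amp_eff", "quant_fluor",
                                       "corr_f", "corr_cq")])) > 0
  results <- if (any(has_res)) res_df[has_res, , drop = FALSE] else NULL

  reactions <- vector("list", n_rx)
  for (i in seq_len(n_rx)) {
    ai <- adp_split[[as.character(i)]]
    mi <- mdp_split[[as.character(i)]]
    adp <- if (length(ai)) data.frame(cycle = as.integer(adp_cyc[ai]),
                                      fluor = adp_fl[ai]) else NULL
    mdp <- if (length(mi)) data.frame(temperature = mdp_tmp[mi],
                                      fluor = mdp_fl[mi]) else NULL
    reactions[[i]] <- reaction_record(wells[i], sample_ids[i], target_ids[i],
                                      adp, mdp)
  }
  run_data(run_id = run_id, reactions = reactions, targets = targets,
           samples = samples, results = results)
}

# ---- flat instrument tables ---------------------------------------------

#' Describe the layout of a flat fluorescence table
#'
#' @param format `"long"` (columns well, cycle, fluorescence — one reading
#'   per row) or `"wide"` (one cycle column, one column per well).
#' @param well,cycle,fluor Column names of the respective quantities.
#' @param sample,target,sample_type Names of the optional annotation columns
#'   (long format) matched per well.
#' @param sep Field separator used when reading from a file path.
#' @return A list of class `table_layout`.
#' @export
table_layout <- function(format = c("long", "wide"),
                         well = "well", cycle = "cycle", fluor = "fluor",
                         sample = "sample", target = "target",
                         sample_type = "sample_type", sep = ",") {
  format <- match.arg(format)
  structure(list(format = format, well = well, cycle = cycle, fluor = fluor,
                 sample = sample, target = target, sample_type = sample_type,
                 sep = sep),
            class = "table_layout")
}

#' Import a flat instrument table as a run
#'
#' Converts a rectangular text table of raw fluorescence readings, as
#' exported by qPCR instruments, into a [run_data] object. Annotation
#' (sample, target, sample type) is taken from the table's own columns (long
#' format) or from a separate `annotation` data frame keyed by well; wells
#' without annotation default to an eponymous sample of type `"unknown"`
#' with a warning.
#'
#' @param x A data frame, or a path to a delimited text file.
#' @param layout A [table_layout()].
#' @param annotation Optional data frame with columns `well`, `sample`,
#'   `target`, `sample_type`.
#' @param run_id Identifier of the created run.
#' @return A [run_data] object.
#' @export
import_table <- function(x, layout = table_layout(), annotation = NULL,
                         run_id = "imported_run") {
  if (is.character(x) && length(x) == 1L) {
    x <- tryCatch(read.table(x, header = TRUE, sep = layout$sep,
                             stringsAsFactors = FALSE, check.names = FALSE),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)

  require_col <- function(col) {
    if (!col %in% names(x))
      stop("format error: required column '", col, "' not found")
  }
  check_numeric <- function(values, colname) {
    num <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(num) & !is.na(values) & nzchar(trimws(values)))
    if (length(bad))
      stop("parse error: non-numeric value '", values[bad[1]],
           "' in column '", colname, "', row ", bad[1])
    if (anyNA(num))
      stop("parse error: missing value in column '", colname, "', row ",
           which(is.na(num))[1])
    num
  }

  if (layout$format == "long") {
    require_col(layout$well); require_col(layout$cycle); require_col(layout$fluor)
    well <- as.character(x[[layout$well]])
    cycle <- check_numeric(x[[layout$cycle]], layout$cycle)
    fluor <- check_numeric(x[[layout$fluor]], layout$fluor)
    per_well <- split(seq_len(nrow(x)), well)
    ann_from_table <- NULL
    if (layout$sample %in% names(x) || layout$target %in% names(x)) {
      ann_from_table <- unique(data.frame(
        well = well,
        sample = if (layout$sample %in% names(x))
          as.character(x[[layout$sample]]) else well,
        target = if (layout$target %in% names(x))
          as.character(x[[layout$target]]) else "target1",
        sample_type = if (layout$sample_type %in% names(x))
          as.character(x[[layout$sample_type]]) else NA_character_,
        stringsAsFactors = FALSE))
    }
    if (is.null(annotation)) annotation <- ann_from_table
    series <- lapply(per_well, function(idx) {
      ord <- idx[order(cycle[idx])]
      data.frame(cycle = as.integer(cycle[ord]), fluor = fluor[ord])
    })
  } else {
    require_col(layout$cycle)
    cycle <- check_numeric(x[[layout$cycle]], layout$cycle)
    well_cols <- setdiff(names(x), layout$cycle)
    if (!length(well_cols))
      stop("format error: wide table holds no well columns")
    series <- lapply(well_cols, function(w) {
      data.frame(cycle = as.integer(cycle),
                 fluor = check_numeric(x[[w]], w))
    })
    names(series) <- well_cols
    series <- series[order(names(series))]
  }

  wells <- names(series)
  ann_of <- function(w) {
    if (!is.null(annotation)) {
      i <- match(w, annotation$well)
      if (!is.na(i)) {
        st <- annotation$sample_type[i]
        return(list(sample = as.character(annotation$sample[i]),
                    target = as.character(annotation$target[i]),
                    sample_type = if (is.na(st)) "unknown" else st,
                    annotated = !is.na(st)))
      }
    }
    list(sample = w, target = "target1", sample_type = "unknown",
         annotated = FALSE)
  }
  anns <- lapply(wells, ann_of)
  n_default <- sum(!vapply(anns, `[[`, logical(1), "annotated"))
  if (n_default > 0)
    warning(n_default, " reaction(s) without sample-type annotation default ",
            "to 'unknown'")
  reactions <- Map(function(w, a, s) reaction_record(w, a$sample, a$target, adp = s),
                   wells, anns, series)
  samples <- unique(data.frame(
    sample_id = vapply(anns, `[[`, character(1), "sample"),
    sample_type = vapply(anns, `[[`, character(1), "sample_type"),
    stringsAsFactors = FALSE))
  targets <- data.frame(target_id = unique(vapply(anns, `[[`, character(1), "target")),
                        stringsAsFactors = FALSE)
  run_data(run_id = run_id, reactions = unname(reactions),
           targets = targets, samples = samples)
}

#' Export annotated result tables as CSV
#'
#' Writes the amplification result table (one row per reaction) and, when
#' melting results are given, the melting result table (one row per peak).
#' Files are UTF-8, comma-delimited, `.` decimal separator; flags are
#' concatenated with `;`; unavailable values (e.g. Cq of a non-amplifying
#' reaction) are left empty.
#'
#' @param run A [run_data] object (for annotation completeness checks).
#' @param amp_results An `amp_analysis`.
#' @param amp_path Destination of the amplification table.
#' @param melt_results Optional `melt_analysis`.
#' @param melt_path Destination of the melting table (required with
#'   `melt_results`).
#' @return Invisibly, the written paths.
#' @export
export_results_csv <- function(run, amp_results, amp_path,
                               melt_results = NULL, melt_path = NULL) {
  stopifnot(inherits(amp_results, "amp_analysis"))
  write.table(amp_results$table, amp_path, sep = ",", dec = ".", na = "",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  paths <- amp_path
  if (!is.null(melt_results)) {
    if (is.null(melt_path)) stop("melt_path required when melt_results given")
    write.table(melt_results$table, melt_path, sep = ",", dec = ".", na = "",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, melt_path)
  }
  invisible(paths)
}
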