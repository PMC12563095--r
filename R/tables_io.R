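#' Built-in screening parameters and their vocabularies
#'
#' The qualitative ADMET parameters handled by the screen, with the
#' controlled vocabulary of each.  Clearance is parsed and reported but is
#' never scored (its predictions failed validation against experimental
#' data); blood-brain-barrier penetration is not modelled at all.
#'
#' @return named list mapping parameter name to its category vocabulary.
#' @examples
#' call_vocabulary()$herg
#' @export
call_vocabulary <- function() {
  list(
    caco2          = c("high", "moderate", "low"),
    hia            = c("high", "moderate", "low"),
    mdck           = c("high", "moderate", "low"),
    pgp_substrate  = c("yes", "no"),
    pgp_inhibitor  = c("yes", "no"),
    ppb            = c("high", "low"),
    clearance      = c("high", "moderate", "low"),
    ames           = c("positive", "negative"),
    carcinogenicity = c("positive", "negative"),
    herg           = c("active", "inactive"),
    hepatotoxicity = c("positive", "negative")
  )
}

# numeric descriptor parameters accepted in platform tables
descriptor_parameters <- function() {
  c("MW", "TPSA", "MR", "LogP", "nRB", "nHA", "nHD", "nRings",
    "nRigidB", "nAtoms", "nCarbon", "nHeteroatoms", "nAromaticRings")
}

#' Read a per-platform prediction table
#'
#' Reads a delimited table with one row per compound and one column per
#' (platform, parameter) pair, headed `platform.parameter` (for example
#' `SwissADME.MW` or `DeepPK.herg`).  A `compound_id` column is required; a
#' `smiles` column is optional.  Cells spelled "nd", "*" or left empty are
#' missing; numeric cells that fail to parse become missing with a warning.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, anything
#'   else comma-separated.
#' @param parameters character vector of known parameter names; defaults to
#'   the built-in descriptor and ADMET parameter sets.
#' @return list of `compound_record` objects, in file order.  Each record
#'   has `compound_id`, `structure` (SMILES or `NA`), `platform_values`
#'   (data frame platform/parameter/value) and `platform_calls` (data frame
#'   platform/parameter/call).
#' @export
read_platform_table <- function(path,
                                parameters = c(descriptor_parameters(),
                                               names(call_vocabulary()))) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character", strip.white = TRUE)
  if (nrow(raw) == 0L) return(list())
  if (!"compound_id" %in% names(raw))
    stop("platform table needs a 'compound_id' column")
  if (anyDuplicated(raw$compound_id))
    stop("duplicate compound_id: ",
         paste(unique(raw$compound_id[duplicated(raw$compound_id)]),
               collapse = ", "))

  cell_cols <- setdiff(names(raw), c("compound_id", "smiles"))
  split_hdr <- regmatches(cell_cols, regexpr("\\.", cell_cols), invert = TRUE)
  bad <- lengths(split_hdr) != 2L
  if (any(bad))
    stop("column header not of the form platform.parameter: ",
         paste(cell_cols[bad], collapse = ", "))
  platforms <- vapply(split_hdr, `[`, "", 1L)
  params <- vapply(split_hdr, `[`, "", 2L)
  unknown <- setdiff(params, parameters)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unique(unknown), collapse = ", "),
         "; known parameters: ", paste(parameters, collapse = ", "))

  is_num <- params %in% descriptor_parameters()
  lapply(seq_len(nrow(raw)), function(i) {
    vals <- calls <- NULL
    if (any(is_num)) {
      cells <- unlist(raw[i, cell_cols[is_num], drop = TRUE], use.names = FALSE)
      num <- parse_numeric_cells(cells)
      garbled <- !is.na(clean_cell(cells)) & is.na(num)
      if (any(garbled))
        warning("unparseable numeric cell(s) for ", raw$compound_id[i], ": ",
                paste(cells[garbled], collapse = ", "), " -> treated as missing")
      vals <- data.frame(platform = platforms[is_num],
                         parameter = params[is_num],
                         value = num, stringsAsFactors = FALSE)
    }
    if (any(!is_num)) {
      cells <- clean_cell(unlist(raw[i, cell_cols[!is_num], drop = TRUE],
                                 use.names = FALSE))
      calls <- data.frame(platform = platforms[!is_num],
                          parameter = params[!is_num],
                          call = tolower(cells), stringsAsFactors = FALSE)
      voc <- call_vocabulary()
      ok <- is.na(calls$call) |
        mapply(function(p, v) v %in% voc[[p]], calls$parameter, calls$call)
      if (!all(ok))
        stop("call outside vocabulary for ", raw$compound_id[i], ": ",
             paste(calls$parameter[!ok], "=", calls$call[!ok], collapse = ", "))
    }
    structure(list(compound_id = raw$compound_id[i],
                   structure = if ("smiles" %in% names(raw))
                     clean_cell(raw$smiles[i]) else NA_character_,
                   platform_values = vals,
                   platform_calls = calls),
              class = "compound_record")
  })
}

#' @export
print.compound_record <- function(x, ...) {
  cat("<compound_record> ", x$compound_id,
      if (!is.na(x$structure)) paste0(" (", x$structure, ")"), "\n", sep = "")
  if (!is.null(x$platform_values))
    cat("  ", sum(!is.na(x$platform_values$value)), "numeric platform values\n")
  if (!is.null(x$platform_calls))
    cat("  ", sum(!is.na(x$platform_calls$call)), "qualitative platform calls\n")
  invisible(x)
}

fixture_registry <- function() {
  c(table3_consensus_example = "table3_consensus_example.csv",
    table4_adme_calls        = "table4_adme_calls.csv",
    table5_tox_calls         = "table5_tox_calls.csv",
    table6_druglikeness      = "table6_druglikeness.csv",
    table7_medchem           = "table7_medchem.csv",
    table8_bioavailability   = "table8_bioavailability.csv",
    table9_distribution      = "table9_distribution.csv",
    table9_excretion         = "table9_excretion.csv",
    table10_toxicity         = "table10_toxicity.csv",
    table11_fda_descriptors  = "table11_fda_descriptors.csv",
    table12_regression       = "table12_regression.csv",
    table13_regression_logp  = "table13_regression_logp.csv",
    table14_admet_expvspred  = "table14_admet_expvspred.csv",
    table15_hits             = "table15_hits.csv",
    table16_selected         = "table16_selected.csv",
    table17_crossdocking     = "table17_crossdocking.csv")
}

#' List or load the packaged reference tables
#'
#' The validation study's printed tables ship with the package as plain CSV
#' transcriptions: rule statuses and category scores for 63 FDA-approved
#' tyrosine kinase inhibitors (tables 6-10), their consensus-predicted
#' versus reference physicochemical descriptors (table 11) and printed
#' regression summaries (tables 12-13), experimental-versus-predicted ADMET
#' calls (table 14), the per-criterion pass lists and final selection for
#' the 29 studied compounds (tables 15-16), and cross-docking scores with
#' pose RMSD values (table 17).  Values are stored exactly as printed;
#' missing markers ("nd", "*", "-") are preserved as `NA`.
#'
#' @param name fixture identifier, one of `list_fixtures()`.
#' @return `load_fixture()`: a data frame of class `fixture_table` with
#'   attribute `fixture` (the name).  Character columns keep their printed
#'   text; numeric columns are parsed.  `table11_fda_descriptors`
#'   additionally carries attribute `column_means`, the printed column
#'   averages.  `list_fixtures()`: character vector of identifiers.
#' @examples
#' nrow(load_fixture("table11_fda_descriptors"))
#' @export
load_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  path <- system.file("extdata", "tables", reg[[name]], package = "dadmet",
                      mustWork = TRUE)
  x <- read.csv(path, check.names = FALSE, colClasses = "character",
                strip.white = TRUE)
  for (j in seq_along(x)) {
    cleaned <- clean_cell(x[[j]])
    num <- suppressWarnings(as.numeric(cleaned))
    x[[j]] <- if (all(is.na(num) == is.na(cleaned))) num else cleaned
  }
  if (name == "table11_fda_descriptors") {
    m <- read.csv(system.file("extdata", "tables", "table11_column_means.csv",
                              package = "dadmet", mustWork = TRUE))
    attr(x, "column_means") <- unlist(m[1, ])
  }
  attr(x, "fixture") <- name
  class(x) <- c("fixture_table", "data.frame")
  x
}

#' @rdname load_fixture
#' @export
list_fixtures <- function() names(fixture_registry())

#' Write a result table or report to disk
#'
#' Serialises any of the package's report objects (or a plain data frame)
#' to CSV or JSON with deterministic column order.  CSV output renders
#' floating point columns with a fixed precision (3 decimals by default,
#' matching the printed tables); JSON output keeps full precision and
#' round-trips losslessly, with missing values written as `null`.
#'
#' @param result data frame or report object (anything `as.data.frame()`
#'   or `unclass()` can flatten).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param digits decimal places for CSV floats.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("csv", "json"), digits = 3) {
  format <- match.arg(format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  if (format == "json") {
    payload <- if (is.data.frame(result)) result else unclass(result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
    return(invisible(path))
  }
  df <- if (is.data.frame(result)) result else
    as.data.frame(lapply(unclass(result), function(v)
      if (length(v) == 1L) v else I(list(v))), check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]]) && any(df[[j]] %% 1 != 0, na.rm = TRUE))
      df[[j]] <- formatC(df[[j]], format = "f", digits = digits)
    df[[j]][is.na(df[[j]]) | df[[j]] %in% c("NA", "NaN")] <- ""
  }
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
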