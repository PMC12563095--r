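#' Missing-value markers
#'
#' Platform prediction tables mark values a platform does not compute with
#' "nd" (not determined), and reference tables mark absent experimental data
#' with "*" or an empty cell.  All accepted spellings map to a single
#' internal sentinel, `NA`, on input; on output missing cells are written as
#' empty strings in CSV and `null` in JSON.
#'
#' @param x character vector of raw cell values.
#' @return `is_missing_marker()`: logical vector; `clean_cell()`: character
#'   vector with missing spellings replaced by `NA`.
#' @examples
#' is_missing_marker(c("nd", "*", "", "3.4"))
#' @export
is_missing_marker <- function(x) {
  x <- trimws(as.character(x))
  is.na(x) | tolower(x) %in% c("nd", "nd *", "*", "", "-", "na")
}

#' @rdname is_missing_marker
#' @export
clean_cell <- function(x) {
  x <- trimws(as.character(x))
  x[is_missing_marker(x)] <- NA_character_
  x
}

# numeric parse that maps unparseable cells to NA (caller warns)
parse_numeric_cells <- function(x) {
  x <- clean_cell(x)
  suppressWarnings(as.numeric(x))
}

#' Canonicalise a compound identifier
#'
#' The printed tables spell some compound ids inconsistently across columns
#' (e.g. "DDK8" vs "DDK.8").  Comparisons of membership lists use a
#' canonical form: dots and whitespace stripped, upper-cased.
#'
#' @param x character vector of compound ids.
#' @return character vector of canonical ids.
#' @examples
#' normalize_compound_id(c("DDK8", "DDK.8", "tki.2a"))
#' @export
normalize_compound_id <- function(x) {
  toupper(gsub("[.\\s]+", "", as.character(x), perl = TRUE))
}

# round half up (printed tables round .5 away from zero for counts)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
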