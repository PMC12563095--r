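#' Load a structural-alert SMARTS catalog
#'
#' Catalog files carry one pattern per line: a SMARTS string, whitespace,
#' and a pattern id; `#` starts a comment.  The packaged defaults are
#' curated subsets of the published PAINS and Brenk catalogs (see the
#' files under `extdata/alerts/`); point `file` at a full catalog to
#' override them.
#'
#' @param catalog `"pains"` or `"brenk"` for the packaged subsets.
#' @param file optional path to a user catalog (overrides `catalog`).
#' @return data frame with columns `smarts` and `id`.
#' @export
load_alert_catalog <- function(catalog = c("pains", "brenk"), file = NULL) {
  if (is.null(file)) {
    catalog <- match.arg(catalog)
    file <- system.file("extdata", "alerts",
                        paste0(catalog, "_subset.smarts"),
                        package = "dadmet", mustWork = TRUE)
  }
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  bad <- lengths(parts) < 2L
  if (any(bad))
    stop("malformed catalog line(s): ", paste(lines[bad], collapse = "; "))
  data.frame(smarts = vapply(parts, `[`, "", 1L),
             id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Structural alert screening (PAINS / Brenk)
#'
#' Matches a molecule against a catalog of unwanted-substructure SMARTS
#' patterns.  A compound passes a catalog when no pattern matches.
#'
#' @param structure SMILES string, SDF path, or `ChemmineR::SDFset`.
#' @param catalog `"pains"` or `"brenk"` (packaged subsets), or a data
#'   frame from [load_alert_catalog()].
#' @return object of class `alert_result`: list with `catalog`,
#'   `n_matches` (number of catalog patterns matched),
#'   `matched_pattern_ids`, and `pass` (`TRUE` iff no matches).
#' @examples
#' \dontrun{alerts("c1ccccc1", "pains")$n_matches  # 0}
#' @export
alerts <- function(structure, catalog = c("pains", "brenk")) {
  if (is.data.frame(catalog)) {
    cat_name <- "user"
    patterns <- catalog
  } else {
    cat_name <- match.arg(catalog)
    patterns <- load_alert_catalog(cat_name)
  }
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("package ChemmineR is required for structure input")
  sdf <- as_sdfset(structure)
  hits <- vapply(seq_len(nrow(patterns)), function(i) {
    n <- tryCatch(
      ChemmineR::smartsSearchOB(sdf, patterns$smarts[i], uniqueMatches = TRUE),
      error = function(e) stop("unparseable SMARTS pattern '",
                               patterns$id[i], "': ", patterns$smarts[i]))
    unname(n) > 0
  }, logical(1))
  structure(list(catalog = cat_name,
                 n_matches = sum(hits),
                 matched_pattern_ids = patterns$id[hits],
                 pass = !any(hits)),
            class = "alert_result")
}

#' @export
print.alert_result <- function(x, ...) {
  cat("<alert_result> ", x$catalog, ": ",
      if (x$pass) "pass (0 matches)"
      else paste0(x$n_matches, " match(es): ",
                  paste(x$matched_pattern_ids, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
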