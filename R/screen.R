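#' Majority-vote consensus of qualitative platform calls
#'
#' The consensus ADMET call for a parameter is the category with a strict
#' plurality among the non-missing platform calls.  On a tie among the
#' top categories, the vote is repeated restricted to the tie-break
#' platforms (by default AdmetLab 3.0, Deep-PK and admetSAR 3.0, the
#' platforms with the most recently updated algorithms); if that vote is
#' still tied, the call of the first tie-break platform in configured
#' order wins and the result is flagged `tie_broken`.
#'
#' @param calls named character vector: platform -> category (`NA` =
#'   platform did not call this parameter).
#' @param parameter parameter name; fixes the category vocabulary (see
#'   [call_vocabulary()]).  `NULL` accepts any categories.
#' @param tiebreak_platforms ordered character vector of platform names
#'   used to resolve ties.
#' @return object of class `qual_call`: list with `parameter`, `calls`,
#'   `consensus`, `tie_broken`.
#' @examples
#' majority_vote(c(PreADMET = "high", SwissADME = "low", AdmetLab3 = "high",
#'                 pkSCM = "high", `Deep-PK` = "high", admetSAR3 = "high"),
#'               parameter = "hia")
#' @export
majority_vote <- function(calls, parameter = NULL,
                          tiebreak_platforms = c("AdmetLab3", "Deep-PK",
                                                 "admetSAR3")) {
  calls <- vapply(calls, as.character, "")
  known <- calls[!is.na(calls) & !is_missing_marker(calls)]
  if (length(known) == 0L) stop("all platform calls missing")
  if (!is.null(parameter)) {
    voc <- call_vocabulary()[[parameter]]
    if (is.null(voc)) stop("unknown parameter: ", parameter)
    bad <- setdiff(unique(known), voc)
    if (length(bad))
      stop("category outside vocabulary for ", parameter, ": ",
           paste(bad, collapse = ", "))
  }
  tally <- table(known)
  top <- names(tally)[tally == max(tally)]
  tie_broken <- FALSE
  if (length(top) > 1L) {
    tie_broken <- TRUE
    sub <- known[intersect(tiebreak_platforms, names(known))]
    sub <- sub[sub %in% top]
    if (length(sub)) {
      sub_tally <- table(sub)
      sub_top <- names(sub_tally)[sub_tally == max(sub_tally)]
      top <- if (length(sub_top) == 1L) sub_top else
        # still tied: first tie-break platform (configured order) wins
        sub[[intersect(tiebreak_platforms, names(sub))[1L]]]
    } else {
      # no tie-break platform voted among the tied categories
      top <- top[1L]
    }
  }
  structure(list(parameter = parameter, calls = calls,
                 consensus = unname(top[1L]), tie_broken = tie_broken),
            class = "qual_call")
}

#' @export
print.qual_call <- function(x, ...) {
  cat("<qual_call> ", if (!is.null(x$parameter)) paste0(x$parameter, ": "),
      x$consensus, if (x$tie_broken) " (tie broken)", "\n", sep = "")
  invisible(x)
}

#' Category score container
#'
#' One of the five scored screening criteria.  Maximum scores are 7
#' (druglikeness: six rule filters plus QED), 4 (medicinal chemistry), 5
#' (bioavailability), 1 (distribution) and 4 (toxicity); the minimum
#' acceptable scores are taken from [screen_thresholds()].
#'
#' @param category one of `"druglikeness"`, `"medchem"`,
#'   `"bioavailability"`, `"distribution"`, `"toxicity"`.
#' @param score numeric score.
#' @param thresholds named list of minimum acceptable scores.
#' @return object of class `category_score`: list with `category`,
#'   `score`, `max_score`, `passed`.
#' @export
category_score <- function(category, score, thresholds = screen_thresholds()) {
  category <- match.arg(category, c("druglikeness", "medchem",
                                    "bioavailability", "distribution",
                                    "toxicity"))
  max_score <- c(druglikeness = 7, medchem = 4, bioavailability = 5,
                 distribution = 1, toxicity = 4)[[category]]
  if (is.na(score) || score < 0 || score > max_score)
    stop(category, " score out of range [0, ", max_score, "]: ", score)
  structure(list(category = category, score = score, max_score = max_score,
                 passed = score >= thresholds[[category]]),
            class = "category_score")
}

#' @export
print.category_score <- function(x, ...) {
  cat("<category_score> ", x$category, ": ", x$score, "/", x$max_score,
      if (x$passed) " (pass)" else " (fail)", "\n", sep = "")
  invisible(x)
}

#' Minimum acceptable category scores
#'
#' The printed minimum acceptable scores: druglikeness 3.501, medicinal
#' chemistry 2, bioavailability 2.51, toxicity 2.01 (all compared with
#' `>=`), and distribution passing only on a `low` plasma-protein-binding
#' call.  These bracket "50% of the maximum" but are applied exactly as
#' printed (medicinal chemistry admits exactly 50%).
#'
#' @return named list of thresholds (distribution entry is the score a
#'   `low` PPB call receives, 1).
#' @export
screen_thresholds <- function() {
  list(druglikeness = 3.501, medchem = 2, bioavailability = 2.51,
       distribution = 1, toxicity = 2.01)
}

# printed-status -> points maps
.rule_points <- c(pass = 1, one_violation = 0.5, fail = 0, mid_structure = 0)
.level_points <- c(high = 1, moderate = 0.5, low = 0)

# accept rule_status objects, printed strings ("1 violation",
# "mid-structure") or canonical strings
as_status <- function(x) {
  if (inherits(x, "rule_status")) return(x$status)
  s <- gsub("[ -]", "_", tolower(trimws(as.character(x))))
  s <- c("1_violation" = "one_violation")[s] %c% s
  if (!s %in% names(.rule_points)) stop("unknown rule status: ", x)
  s
}
`%c%` <- function(a, b) if (is.na(a)) b else a

#' Druglikeness category score
#'
#' Sum of points over the six rule filters (pass = 1, one Lipinski
#' violation = 0.5, fail and mid-structure = 0) plus the QED value;
#' maximum 7.
#'
#' @param statuses list/vector of the six rule outcomes, in the order
#'   Lipinski, Ghose, Veber, Egan, Muegge, MDDR-like; each a
#'   [rule_status()] or a status string (printed spellings such as
#'   `"1 violation"` and `"mid-structure"` are accepted).
#' @param qed_value QED in \[0, 1\].
#' @return a [category_score()].
#' @examples
#' druglikeness_score(rep("pass", 6), 0.671)$score  # 6.671
#' @export
druglikeness_score <- function(statuses, qed_value) {
  if (length(statuses) != 6L) stop("need 6 rule statuses, got ", length(statuses))
  if (is.na(qed_value) || qed_value < 0 || qed_value > 1)
    stop("qed_value must be in [0, 1]")
  pts <- vapply(statuses, function(s) .rule_points[[as_status(s)]], numeric(1))
  category_score("druglikeness", sum(pts) + qed_value)
}

#' Medicinal-chemistry category score
#'
#' Number of passes over Leadlikeness, GSK, PAINS and Brenk (pass = 1,
#' fail = 0); maximum 4.
#'
#' @param statuses list/vector of the four outcomes (order Leadlikeness,
#'   GSK, PAINS, Brenk); [rule_status()], [alerts()] results or strings.
#' @return a [category_score()].
#' @export
medchem_score <- function(statuses) {
  if (length(statuses) != 4L) stop("need 4 statuses, got ", length(statuses))
  pts <- vapply(statuses, function(s) {
    if (inherits(s, "alert_result")) as.numeric(s$pass)
    else .rule_points[[as_status(s)]]
  }, numeric(1))
  category_score("medchem", sum(pts))
}

#' Bioavailability category score
#'
#' Caco-2, HIA and MDCK permeability calls score high = 1, moderate =
#' 0.5, low = 0.  The P-glycoprotein substrate/inhibitor pair scores as a
#' combination: no/no = 2 (best: neither substrate nor inhibitor), no/yes
#' = 1, yes/yes = 1, yes/no = 0 (worst: a substrate that is not an
#' inhibitor is efficiently effluxed).  Maximum 5.
#'
#' @param caco2,hia,mdck permeability calls: `"high"`, `"moderate"` or
#'   `"low"`.
#' @param pgp_substrate,pgp_inhibitor `"yes"` or `"no"`.
#' @return a [category_score()].
#' @examples
#' bioavailability_score("high", "high", "high", "no", "no")$score  # 5
#' @export
bioavailability_score <- function(caco2, hia, mdck, pgp_substrate,
                                  pgp_inhibitor) {
  lv <- function(x, what) {
    x <- tolower(trimws(as.character(x)))
    if (is.na(x) || !x %in% names(.level_points))
      stop("missing or invalid ", what, " call: ", x)
    .level_points[[x]]
  }
  yn <- function(x, what) {
    x <- tolower(trimws(as.character(x)))
    if (is.na(x) || !x %in% c("yes", "no"))
      stop("missing or invalid ", what, " call: ", x)
    x
  }
  combo <- c("no.no" = 2, "no.yes" = 1, "yes.yes" = 1, "yes.no" = 0)
  s <- lv(caco2, "caco2") + lv(hia, "hia") + lv(mdck, "mdck") +
    combo[[paste(yn(pgp_substrate, "pgp_substrate"),
                 yn(pgp_inhibitor, "pgp_inhibitor"), sep = ".")]]
  category_score("bioavailability", s)
}

#' Toxicity category score
#'
#' Count of favourable calls over the Ames test, rat carcinogenicity,
#' hERG blockade and hepatotoxicity (negative/inactive = 1,
#' positive/active = 0); maximum 4.
#'
#' @param ames,carcinogenicity,hepatotoxicity `"positive"` or
#'   `"negative"`.
#' @param herg `"active"` or `"inactive"` (`"positive"`/`"negative"` also
#'   accepted, as printed in the validation table).
#' @return a [category_score()].
#' @export
toxicity_score <- function(ames, carcinogenicity, herg, hepatotoxicity) {
  fav <- function(x, what) {
    x <- tolower(trimws(as.character(x)))
    if (is.na(x) || !x %in% c("positive", "negative", "active", "inactive"))
      stop("missing or invalid ", what, " call: ", x)
    as.numeric(x %in% c("negative", "inactive"))
  }
  category_score("toxicity",
                 fav(ames, "ames") + fav(carcinogenicity, "carcinogenicity") +
                   fav(herg, "herg") + fav(hepatotoxicity, "hepatotoxicity"))
}

#' Distribution criterion
#'
#' Only compounds predicted to have low plasma protein binding pass the
#' distribution criterion: the unbound fraction is the pharmacologically
#' active one.
#'
#' @param ppb `"high"` or `"low"`.
#' @return a [category_score()] with score 1 (low) or 0 (high).
#' @export
distribution_pass <- function(ppb) {
  ppb <- tolower(trimws(as.character(ppb)))
  if (is.na(ppb) || !ppb %in% c("high", "low"))
    stop("missing or invalid ppb call: ", ppb)
  category_score("distribution", as.numeric(ppb == "low"))
}

#' Multi-criteria selection
#'
#' Applies the five category thresholds and the hit rule: a compound is
#' selected when it passes at least 3 of the 5 criteria (60%).  The
#' selection threshold is `>= 3` because the printed selection includes
#' 3-hit (60%) compounds.
#'
#' @param scores data frame with columns `compound_id`, `druglikeness`,
#'   `medchem`, `bioavailability`, `distribution` (score 1/0 or call
#'   `"low"`/`"high"`), `toxicity`.
#' @param thresholds named list as [screen_thresholds()].
#' @return data frame of class `screen_result`: per-compound category
#'   scores, pass flags, `hits` (0-5) and `selected`, sorted by hits
#'   descending then compound id.
#' @export
select_compounds <- function(scores, thresholds = screen_thresholds()) {
  cats <- c("druglikeness", "medchem", "bioavailability", "distribution",
            "toxicity")
  missing_cols <- setdiff(c("compound_id", cats), names(scores))
  if (length(missing_cols))
    stop("scores table missing column(s): ", paste(missing_cols, collapse = ", "))
  dist <- scores$distribution
  if (is.character(dist)) dist <- as.numeric(tolower(dist) == "low")
  sc <- data.frame(compound_id = scores$compound_id,
                   druglikeness = as.numeric(scores$druglikeness),
                   medchem = as.numeric(scores$medchem),
                   bioavailability = as.numeric(scores$bioavailability),
                   distribution = dist,
                   toxicity = as.numeric(scores$toxicity),
                   stringsAsFactors = FALSE)
  for (cat in cats)
    if (anyNA(sc[[cat]]))
      stop("missing ", cat, " score for: ",
           paste(sc$compound_id[is.na(sc[[cat]])], collapse = ", "))
  pass <- vapply(cats, function(cat) sc[[cat]] >= thresholds[[cat]],
                 logical(nrow(sc)))
  if (!is.matrix(pass)) pass <- matrix(pass, nrow = 1L)
  colnames(pass) <- paste0(cats, "_pass")
  out <- cbind(sc, as.data.frame(pass))
  out$hits <- rowSums(pass)
  out$selected <- out$hits >= 3L
  out <- out[order(-out$hits, out$compound_id), ]
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Selection from per-criterion membership lists
#'
#' Counts, for each compound, how many of the five per-criterion pass
#' lists it appears on, and selects compounds on at least 3 lists.
#' Compound ids are canonicalised with [normalize_compound_id()] before
#' matching (the printed lists spell some ids inconsistently).
#'
#' @param memberships named list of up to five character vectors of
#'   compound ids (one per criterion).
#' @param all_ids optional character vector of the full compound set, so
#'   compounds on no list appear with 0 hits.
#' @return data frame with `compound_id` (first spelling seen), `hits`,
#'   `selected`, sorted by hits descending then id.
#' @examples
#' hit_selection(list(a = c("X", "Y"), b = c("X"), c = c("X", "Z")))
#' @export
hit_selection <- function(memberships, all_ids = NULL) {
  stopifnot(is.list(memberships), length(memberships) >= 1L)
  longs <- lapply(memberships, function(v) unique(normalize_compound_id(
    v[!is.na(v) & nzchar(trimws(v))])))
  raw <- unlist(lapply(memberships, function(v) v[!is.na(v) & nzchar(trimws(v))]),
                use.names = FALSE)
  if (!is.null(all_ids)) raw <- c(raw, all_ids)
  canon <- normalize_compound_id(raw)
  first_spelling <- raw[!duplicated(canon)]
  names(first_spelling) <- canon[!duplicated(canon)]
  hits <- vapply(names(first_spelling), function(id)
    sum(vapply(longs, function(v) id %in% v, logical(1))), integer(1))
  out <- data.frame(compound_id = unname(first_spelling),
                    hits = unname(hits),
                    selected = unname(hits) >= 3L,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$hits, out$compound_id), ]
  rownames(out) <- NULL
  out
}

#' Run the consensus screen over score tables
#'
#' The central entry point: assembles the five per-category tables into
#' one screening result.  Each table is matched on (canonicalised)
#' compound id; every compound must be scored in all five categories.
#'
#' @param druglikeness data frame with `id` and `score` (or the packaged
#'   `table6_druglikeness` fixture layout).
#' @param medchem data frame with `id` and `score`.
#' @param bioavailability data frame with `id` and `score`.
#' @param distribution data frame with `id` and `ppb`.
#' @param toxicity data frame with `id` and `score`.
#' @param thresholds named list as [screen_thresholds()].
#' @return object of class `admet_screen`: the [select_compounds()] table
#'   plus attributes `thresholds` and `n`.
#' @examples
#' scr <- admet_screen(load_fixture("table6_druglikeness"),
#'                     load_fixture("table7_medchem"),
#'                     load_fixture("table8_bioavailability"),
#'                     load_fixture("table9_distribution"),
#'                     load_fixture("table10_toxicity"))
#' sum(scr$selected)  # 39
#' @export
admet_screen <- function(druglikeness, medchem, bioavailability,
                         distribution, toxicity,
                         thresholds = screen_thresholds()) {
  pick <- function(df, value_col, what) {
    if (!all(c("id", value_col) %in% names(df)))
      stop(what, " table needs columns 'id' and '", value_col, "'")
    setNames(df[[value_col]], normalize_compound_id(df$id))
  }
  d <- pick(druglikeness, "score", "druglikeness")
  m <- pick(medchem, "score", "medchem")
  b <- pick(bioavailability, "score", "bioavailability")
  p <- pick(distribution, "ppb", "distribution")
  t <- pick(toxicity, "score", "toxicity")
  ids <- normalize_compound_id(druglikeness$id)
  for (s in list(m, b, p, t)) {
    absent <- setdiff(ids, names(s))
    if (length(absent))
      stop("compound(s) missing a category: ", paste(absent, collapse = ", "))
  }
  scores <- data.frame(compound_id = druglikeness$id,
                       druglikeness = unname(d[ids]),
                       medchem = unname(m[ids]),
                       bioavailability = unname(b[ids]),
                       distribution = unname(p[ids]),
                       toxicity = unname(t[ids]),
                       stringsAsFactors = FALSE)
  out <- select_compounds(scores, thresholds)
  attr(out, "thresholds") <- thresholds
  attr(out, "n") <- nrow(out)
  class(out) <- c("admet_screen", class(out))
  out
}

#' @export
print.screen_result <- function(x, ...) {
  sel <- sum(x$selected)
  cat("<screen_result> ", nrow(x), " compounds, ", sel, " selected (>= 3/5 hits)\n",
      sep = "")
  print.data.frame(head(as.data.frame(
    x[, c("compound_id", "hits", "selected")]), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
print.admet_screen <- function(x, ...) {
  cat("Consensus ADMET screen: ", attr(x, "n"), " compounds, ",
      sum(x$selected), " selected\n", sep = "")
  NextMethod()
}

#' @export
summary.admet_screen <- function(object, ...) {
  cats <- c("druglikeness", "medchem", "bioavailability", "distribution",
            "toxicity")
  passes <- vapply(paste0(cats, "_pass"), function(cn) sum(object[[cn]]),
                   numeric(1))
  names(passes) <- cats
  out <- list(n = attr(object, "n"), selected = sum(object$selected),
              category_passes = passes,
              hit_distribution = table(object$hits),
              thresholds = attr(object, "thresholds"))
  class(out) <- "summary.admet_screen"
  out
}

#' @export
print.summary.admet_screen <- function(x, ...) {
  cat("Consensus ADMET screen of", x$n, "compounds\n")
  cat("Passes per category:\n")
  print(x$category_passes)
  cat("Hit distribution (criteria passed):\n")
  print(x$hit_distribution)
  cat("Selected (>= 3/5):", x$selected, "\n")
  invisible(x)
}
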