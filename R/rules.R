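#' Rule status container
#'
#' @param rule rule name.
#' @param status one of `"pass"`, `"one_violation"` (Lipinski only),
#'   `"fail"`, `"mid_structure"` (MDDR-like only).
#' @param violated character vector of violated condition labels (empty
#'   iff status is `"pass"`).
#' @return object of class `rule_status`.
#' @export
rule_status <- function(rule, status, violated = character()) {
  status <- match.arg(status, c("pass", "one_violation", "fail", "mid_structure"))
  if ((status == "pass") != (length(violated) == 0L) && status != "mid_structure")
    stop("violated_conditions must be empty iff status is pass")
  structure(list(rule = rule, status = status, violated = violated),
            class = "rule_status")
}

#' @export
print.rule_status <- function(x, ...) {
  cat("<rule_status> ", x$rule, ": ", x$status,
      if (length(x$violated)) paste0(" (", paste(x$violated, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

# fetch descriptors from a profile/named list, erroring on absences
need <- function(profile, fields) {
  p <- unclass(profile)
  for (f in fields)
    if (is.null(p[[f]]) || is.na(p[[f]]))
      stop("missing descriptor: ", f)
  lapply(p[fields], as.numeric)
}

# evaluate a named list of conditions -> violated labels
check_conditions <- function(conds) names(conds)[!unlist(conds)]

#' Druglikeness and medicinal-chemistry rule filters
#'
#' Threshold filters over a [descriptor_profile()].  Boundary comparisons
#' are inclusive throughout.  The threshold sets follow the cited
#' originals as implemented by the SwissADME conventions:
#' \describe{
#'   \item{lipinski}{MW <= 500, LogP <= 5, nHD <= 5, nHA <= 10; a single
#'     failed condition yields status `one_violation`, two or more `fail`.}
#'   \item{ghose}{160 <= MW <= 480, -0.4 <= LogP <= 5.6, 40 <= MR <= 130,
#'     20 <= nAtoms <= 70.}
#'   \item{veber}{nRB <= 10, TPSA <= 140.}
#'   \item{egan}{LogP <= 5.88, TPSA <= 131.6.}
#'   \item{muegge}{200 <= MW <= 600, -2 <= LogP <= 5, TPSA <= 150,
#'     nRings <= 7, nCarbon > 4, nHeteroatoms > 1, nRB <= 15, nHA <= 10,
#'     nHD <= 5.}
#'   \item{leadlikeness}{250 <= MW <= 350, LogP <= 3.5, nRB <= 7.}
#'   \item{gsk}{MW <= 400, LogP <= 4.}
#'   \item{mddr_like}{drug-like (`pass`) iff nRings >= 3, nRigidB >= 18
#'     and nRB >= 6; nondrug-like (`fail`) iff nRings <= 2, nRigidB < 18
#'     and nRB < 6; anything in between is `mid_structure`.}
#' }
#'
#' @param profile a [descriptor_profile()] or named list with the needed
#'   descriptors (missing ones raise an error naming them).
#' @return a [rule_status()].
#' @examples
#' lipinski(list(mw = 329.28, logp = 3.03, n_hd = 2, n_ha = 6))
#' @export
lipinski <- function(profile) {
  p <- need(profile, c("mw", "logp", "n_hd", "n_ha"))
  v <- check_conditions(list(
    "MW <= 500" = p$mw <= 500, "LogP <= 5" = p$logp <= 5,
    "nHD <= 5" = p$n_hd <= 5, "nHA <= 10" = p$n_ha <= 10))
  rule_status("lipinski",
              if (length(v) == 0L) "pass"
              else if (length(v) == 1L) "one_violation" else "fail", v)
}

#' @rdname lipinski
#' @export
ghose <- function(profile) {
  p <- need(profile, c("mw", "logp", "mr", "n_atoms"))
  v <- check_conditions(list(
    "160 <= MW <= 480" = p$mw >= 160 && p$mw <= 480,
    "-0.4 <= LogP <= 5.6" = p$logp >= -0.4 && p$logp <= 5.6,
    "40 <= MR <= 130" = p$mr >= 40 && p$mr <= 130,
    "20 <= nAtoms <= 70" = p$n_atoms >= 20 && p$n_atoms <= 70))
  rule_status("ghose", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
veber <- function(profile) {
  p <- need(profile, c("n_rb", "tpsa"))
  v <- check_conditions(list("nRB <= 10" = p$n_rb <= 10,
                             "TPSA <= 140" = p$tpsa <= 140))
  rule_status("veber", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
egan <- function(profile) {
  p <- need(profile, c("logp", "tpsa"))
  v <- check_conditions(list("LogP <= 5.88" = p$logp <= 5.88,
                             "TPSA <= 131.6" = p$tpsa <= 131.6))
  rule_status("egan", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
muegge <- function(profile) {
  p <- need(profile, c("mw", "logp", "tpsa", "n_rings", "n_carbon",
                       "n_heteroatoms", "n_rb", "n_ha", "n_hd"))
  v <- check_conditions(list(
    "200 <= MW <= 600" = p$mw >= 200 && p$mw <= 600,
    "-2 <= LogP <= 5" = p$logp >= -2 && p$logp <= 5,
    "TPSA <= 150" = p$tpsa <= 150,
    "nRings <= 7" = p$n_rings <= 7,
    "nCarbon > 4" = p$n_carbon > 4,
    "nHeteroatoms > 1" = p$n_heteroatoms > 1,
    "nRB <= 15" = p$n_rb <= 15,
    "nHA <= 10" = p$n_ha <= 10,
    "nHD <= 5" = p$n_hd <= 5))
  rule_status("muegge", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
leadlikeness <- function(profile) {
  p <- need(profile, c("mw", "logp", "n_rb"))
  v <- check_conditions(list(
    "250 <= MW <= 350" = p$mw >= 250 && p$mw <= 350,
    "LogP <= 3.5" = p$logp <= 3.5,
    "nRB <= 7" = p$n_rb <= 7))
  rule_status("leadlikeness", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
gsk <- function(profile) {
  p <- need(profile, c("mw", "logp"))
  v <- check_conditions(list("MW <= 400" = p$mw <= 400,
                             "LogP <= 4" = p$logp <= 4))
  rule_status("gsk", if (length(v)) "fail" else "pass", v)
}

#' @rdname lipinski
#' @export
mddr_like <- function(profile) {
  p <- need(profile, c("n_rings", "n_rigidb", "n_rb"))
  druglike <- p$n_rings >= 3 && p$n_rigidb >= 18 && p$n_rb >= 6
  nondrug <- p$n_rings <= 2 && p$n_rigidb < 18 && p$n_rb < 6
  if (druglike) return(rule_status("mddr_like", "pass"))
  v <- check_conditions(list(
    "nRings >= 3" = p$n_rings >= 3, "nRigidB >= 18" = p$n_rigidb >= 18,
    "nRB >= 6" = p$n_rb >= 6))
  rule_status("mddr_like", if (nondrug) "fail" else "mid_structure", v)
}
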