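#' Screening configuration
#'
#' Assembles the tunable settings of the screen, optionally overridden
#' from a YAML file.  Keys:
#' \describe{
#'   \item{thresholds}{minimum acceptable category scores
#'     ([screen_thresholds()]).}
#'   \item{tiebreak_platforms}{ordered platforms used to break consensus
#'     ties (default AdmetLab3, Deep-PK, admetSAR3).}
#'   \item{logp_mode}{`"consensus"` (all-platform mean) or
#'     `"two_platform"` (Molinspiration-Molsoft mean, the variant that
#'     validated best against experimental LogP).}
#'   \item{natoms_convention}{`"all"` or `"heavy"` atom counting for the
#'     Ghose window.}
#'   \item{rmse_divisor}{`"n"` or `"n-1"` in the RMSE formulas.}
#'   \item{digits}{decimals for CSV report rendering.}
#'   \item{class_cutoffs}{optional per-platform numeric cutoffs mapping
#'     quantitative platform outputs to high/moderate/low classes (no
#'     published defaults exist; any mapping here is user-chosen).
#'     Entries are lists `platform -> parameter -> c(low_lt, high_ge)`.}
#'   \item{alert_catalogs}{optional named file paths overriding the
#'     packaged PAINS/Brenk subsets.}
#' }
#'
#' @param path optional YAML file whose top-level keys override the
#'   defaults.
#' @return named list of settings.
#' @export
dadmet_config <- function(path = NULL) {
  cfg <- list(thresholds = screen_thresholds(),
              tiebreak_platforms = c("AdmetLab3", "Deep-PK", "admetSAR3"),
              logp_mode = "consensus",
              natoms_convention = "all",
              rmse_divisor = "n",
              digits = 3,
              class_cutoffs = list(),
              alert_catalogs = list())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Map a quantitative platform output to a qualitative class
#'
#' Converts a numeric platform prediction to `"low"` / `"moderate"` /
#' `"high"` using a two-point cutoff: values below `cutoffs[1]` are low,
#' values at or above `cutoffs[2]` are high, anything between is
#' moderate.  Platform-specific cutoffs live in the config's
#' `class_cutoffs`; there are no published defaults, so cutoffs must be
#' supplied explicitly.
#'
#' @param x numeric value(s).
#' @param cutoffs numeric length-2 vector `c(low_below, high_at_least)`.
#' @return character vector of classes (`NA` for missing input).
#' @examples
#' classify_quantitative(c(-5.2, -4.9, -4.2), cutoffs = c(-5.15, -4.70))
#' @export
classify_quantitative <- function(x, cutoffs) {
  if (length(cutoffs) != 2L || cutoffs[1] > cutoffs[2])
    stop("cutoffs must be c(low_below, high_at_least) with low <= high")
  out <- ifelse(x < cutoffs[1], "low",
                ifelse(x >= cutoffs[2], "high", "moderate"))
  out[is.na(x)] <- NA_character_
  out
}
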