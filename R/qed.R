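# Published parameterisation of the QED desirability functions:
# asymmetric double sigmoid ADS(x) = a + b / (1 + exp(-(x-c+d/2)/e)) *
#   (1 - 1 / (1 + exp(-(x-c-d/2)/f))), normalised by its maximum.
.qed_params <- list(
  MW     = c(a = 2.817065973, b = 392.5754953, c = 290.7489764,
             d = 2.419764353, e = 49.22325677, f = 65.37051707,
             dmax = 104.9805561),
  ALOGP  = c(a = 3.172690585, b = 137.8624751, c = 2.534937431,
             d = 4.581497897, e = 0.822739154, f = 0.576295591,
             dmax = 131.3186604),
  HBA    = c(a = 2.948620388, b = 160.4605972, c = 3.615294657,
             d = 4.435986202, e = 0.290141953, f = 1.300669958,
             dmax = 148.7763046),
  HBD    = c(a = 1.618662227, b = 1010.051101, c = 0.985094388,
             d = 1e-09, e = 0.713820843, f = 0.920922555,
             dmax = 258.1632616),
  PSA    = c(a = 1.876861559, b = 125.2232657, c = 62.90773554,
             d = 87.83366614, e = 12.01999824, f = 28.51324732,
             dmax = 104.5686167),
  ROTB   = c(a = 0.01, b = 272.4121427, c = 2.55837997,
             d = 1.565547684, e = 1.271567166, f = 2.758063707,
             dmax = 105.4420403),
  AROM   = c(a = 3.21778897, b = 957.7374108, c = 2.274627939,
             d = 1e-09, e = 1.317690384, f = 0.375760881,
             dmax = 312.337261),
  ALERTS = c(a = 0.01, b = 1199.094025, c = -0.09002883,
             d = 1e-09, e = 0.185904477, f = 0.875193782,
             dmax = 417.725314))

#' QED desirability of a single property
#'
#' Evaluates the published asymmetric-double-sigmoid desirability function
#' for one of the eight QED properties.
#'
#' @param x property value.
#' @param property one of `"MW"`, `"ALOGP"`, `"HBA"`, `"HBD"`, `"PSA"`,
#'   `"ROTB"`, `"AROM"`, `"ALERTS"`.
#' @return desirability in (0, 1].
#' @export
qed_desirability <- function(x, property) {
  p <- .qed_params[[match.arg(property, names(.qed_params))]]
  ads <- p[["a"]] + p[["b"]] /
    (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
    (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
  pmax(ads / p[["dmax"]], 1e-10)
}

#' Default QED property weights
#'
#' The published weight set for the weighted-mean QED (`QED_w`).
#' @return named numeric vector of eight weights.
#' @export
qed_weights <- function() {
  c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
    PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)
}

#' Quantitative estimate of druglikeness (QED)
#'
#' Weighted geometric mean of the eight property desirabilities, in \[0,1\].
#' The weighted geometric mean normalises by the weight sum, so the value
#' is invariant to rescaling all weights by a constant.
#'
#' @param mw molecular weight (g/mol).
#' @param alogp octanol-water log partition estimate.
#' @param hba,hbd H-bond acceptor and donor counts.
#' @param psa topological polar surface area (Angstrom^2).
#' @param rotb rotatable bond count.
#' @param arom aromatic ring count.
#' @param alerts structural alert match count.
#' @param weights named weights over the eight properties; defaults to the
#'   published `QED_w` set.
#' @return QED value in \[0, 1\].
#' @examples
#' qed_score(mw = 300, alogp = 2.5, hba = 4, hbd = 1, psa = 70,
#'           rotb = 4, arom = 2, alerts = 0)
#' @export
qed_score <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts,
                      weights = qed_weights()) {
  x <- c(MW = mw, ALOGP = alogp, HBA = hba, HBD = hbd, PSA = psa,
         ROTB = rotb, AROM = arom, ALERTS = alerts)
  if (anyNA(x))
    stop("missing QED input(s): ", paste(names(x)[is.na(x)], collapse = ", "))
  w <- weights[names(x)]
  if (anyNA(w)) stop("weights must cover all eight QED properties")
  d <- vapply(names(x), function(k) qed_desirability(x[[k]], k), numeric(1))
  qed_combine(d, w)
}

# weighted geometric mean; equals 1 when every desirability is 1 and is
# invariant to rescaling the weights
qed_combine <- function(d, w) exp(sum(w * log(d)) / sum(w))

#' @describeIn qed_score QED from a [descriptor_profile()] plus an alert
#'   count; uses the profile's `logp`, aromatic ring count and the given
#'   number of structural alert matches.
#' @param profile a [descriptor_profile()].
#' @param n_alerts structural alert match count for the molecule.
#' @export
qed <- function(profile, n_alerts = 0) {
  p <- need(profile, c("mw", "logp", "n_ha", "n_hd", "tpsa", "n_rb",
                       "n_aromatic_rings"))
  qed_score(p$mw, p$logp, p$n_ha, p$n_hd, p$tpsa, p$n_rb,
            p$n_aromatic_rings, n_alerts)
}
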