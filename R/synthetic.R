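#' Simulation configuration
#'
#' Parameters of the seeded generators that emulate the pipeline's
#' inputs: per-platform descriptor tables (latent true value plus
#' platform noise plus missingness), qualitative call tables with
#' controllable inter-platform disagreement, and ranked actives/decoys
#' score lists with controllable separation.
#'
#' Descriptor truth ranges default to the confidence intervals estimated
#' for screen-passing approved kinase inhibitors (e.g. MW in
#' \[416.81, 461.47\] g/mol); per-platform noise standard deviations
#' default to magnitudes like the spread seen across real platforms
#' (tight for MW, loose for LogP, integer-valued counts left exact).
#'
#' @param n_compounds number of simulated compounds.
#' @param n_platforms number of simulated platforms (>= 1).
#' @param descriptor_truth_ranges named list of c(lower, upper) ranges
#'   the latent true values are drawn from, uniformly.
#' @param platform_noise_sd named numeric vector of per-descriptor noise
#'   standard deviations.
#' @param missing_rate probability a platform cell is masked missing;
#'   either a scalar or one rate per platform.
#' @param call_flip_rate probability a platform's qualitative call
#'   disagrees with the latent truth (flipped calls are uniform over the
#'   other categories).
#' @param n_actives,n_decoys docking-set composition (defaults 30/302,
#'   the 332-compound enrichment benchmark layout).
#' @param score_separation mean shift of active scores over decoys, in
#'   score standard deviations.
#' @param seed mandatory integer seed; every generator is deterministic
#'   given it.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_compounds = 500L, n_platforms = 8L,
                       descriptor_truth_ranges = list(
                         MW = c(416.81, 461.47), TPSA = c(83.48, 95.83),
                         MR = c(115.14, 128.65), LogP = c(2.62, 3.49),
                         nRB = c(5, 7), nHA = c(7, 8), nHD = c(2, 2),
                         nRings = c(4, 5), nRigidB = c(23, 26),
                         nAtoms = c(52, 58)),
                       platform_noise_sd = c(MW = 0.1, TPSA = 3, MR = 2,
                                             LogP = 0.5, nRB = 0, nHA = 0,
                                             nHD = 0, nRings = 0,
                                             nRigidB = 0, nAtoms = 0),
                       missing_rate = 0.1, call_flip_rate = 0.2,
                       n_actives = 30L, n_decoys = 302L,
                       score_separation = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_compounds >= 1, all(missing_rate >= 0), all(missing_rate <= 1),
            call_flip_rate >= 0, call_flip_rate <= 1)
  if (n_platforms < 1) stop("n_platforms must be >= 1")
  if (!length(missing_rate) %in% c(1L, n_platforms))
    stop("missing_rate must be scalar or one rate per platform")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_platforms = as.integer(n_platforms),
                 descriptor_truth_ranges = descriptor_truth_ranges,
                 platform_noise_sd = platform_noise_sd,
                 missing_rate = missing_rate,
                 call_flip_rate = call_flip_rate,
                 n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 score_separation = score_separation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-platform descriptor tables
#'
#' Draws a latent true value per compound and descriptor from the
#' configured ranges, then builds one noisy copy per platform
#' (truth + Gaussian noise, integer descriptors rounded) and masks cells
#' missing at the configured rate.
#'
#' @param config a [sim_config()].
#' @return list with `truth` (data frame compound x descriptor) and
#'   `platforms` (data frame compound_id, platform, descriptor, value
#'   with `NA` for masked cells).
#' @export
gen_descriptor_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ranges <- config$descriptor_truth_ranges
  descs <- names(ranges)
  n <- config$n_compounds
  ids <- sprintf("SIM.%0*d", nchar(n), seq_len(n))
  is_int <- startsWith(descs, "n")
  truth <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (k in seq_along(descs)) {
    v <- runif(n, ranges[[k]][1], ranges[[k]][2])
    truth[[descs[k]]] <- if (is_int[k]) round_half_up(v) else v
  }
  plat_names <- paste0("P", seq_len(config$n_platforms))
  rows <- expand.grid(compound_id = ids, platform = plat_names,
                      descriptor = descs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tr <- unlist(truth[descs], use.names = FALSE)[
    match(rows$compound_id, ids) +
      (match(rows$descriptor, descs) - 1L) * n]
  sdv <- config$platform_noise_sd[rows$descriptor]
  sdv[is.na(sdv)] <- 0
  val <- tr + rnorm(nrow(rows), 0, sdv)
  int_row <- startsWith(rows$descriptor, "n")
  val[int_row] <- round_half_up(val[int_row])
  mr <- rep(config$missing_rate, length.out = config$n_platforms)
  val[runif(nrow(rows)) < mr[match(rows$platform, plat_names)]] <- NA_real_
  rows$value <- val
  list(truth = truth, platforms = rows)
}

#' Simulate qualitative call tables
#'
#' Draws a latent true category per compound and parameter, then builds
#' per-platform calls that agree with the truth with probability
#' `1 - call_flip_rate` and otherwise take a uniformly random different
#' category from that parameter's vocabulary.
#'
#' @param config a [sim_config()].
#' @param parameters which qualitative parameters to simulate; defaults
#'   to all of [call_vocabulary()].
#' @return list with `truth` (data frame compound x parameter) and
#'   `platforms` (long data frame compound_id, platform, parameter,
#'   call).
#' @export
gen_qual_tables <- function(config, parameters = names(call_vocabulary())) {
  stopifnot(inherits(config, "sim_config"))
  voc <- call_vocabulary()[parameters]
  if (any(lengths(voc) == 0L) || length(voc) == 0L)
    stop("empty vocabulary for: ",
         paste(parameters[lengths(voc) == 0L], collapse = ", "))
  set.seed(config$seed + 1L)
  n <- config$n_compounds
  ids <- sprintf("SIM.%0*d", nchar(n), seq_len(n))
  truth <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (p in names(voc))
    truth[[p]] <- sample(voc[[p]], n, replace = TRUE)
  plat_names <- paste0("P", seq_len(config$n_platforms))
  rows <- expand.grid(compound_id = ids, platform = plat_names,
                      parameter = names(voc), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  true_call <- mapply(function(id, p) truth[[p]][match(id, ids)],
                      rows$compound_id, rows$parameter, USE.NAMES = FALSE)
  flip <- runif(nrow(rows)) < config$call_flip_rate
  call <- true_call
  if (any(flip)) {
    call[flip] <- mapply(function(p, cur) {
      others <- setdiff(call_vocabulary()[[p]], cur)
      if (length(others) == 1L) others else sample(others, 1L)
    }, rows$parameter[flip], true_call[flip], USE.NAMES = FALSE)
  }
  rows$call <- call
  list(truth = truth, platforms = rows)
}

#' Simulate a ranked actives/decoys docking set
#'
#' Active scores are drawn N(separation, 1) and decoy scores N(0, 1);
#' records come back ranked by score, best first, ready for
#' [enrichment_factor()] and [roc_auc()].  A negative separation is
#' allowed (adversarial ranking).
#'
#' @param config a [sim_config()].
#' @return data frame with `ligand_id`, `score`, `is_active`, ranked by
#'   descending score.
#' @export
gen_docking_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_actives < 1L || config$n_decoys < 1L)
    stop("need at least one active and one decoy")
  set.seed(config$seed + 2L)
  n <- config$n_actives + config$n_decoys
  is_active <- c(rep(TRUE, config$n_actives), rep(FALSE, config$n_decoys))
  score <- rnorm(n, mean = ifelse(is_active, config$score_separation, 0))
  out <- data.frame(ligand_id = sprintf("LIG.%03d", seq_len(n)),
                    score = score, is_active = is_active,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, seq_len(n)), ]
  rownames(out) <- NULL
  out
}
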