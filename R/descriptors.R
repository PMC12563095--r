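#' Consensus mean over platforms
#'
#' The consensus estimate of a molecular descriptor is the arithmetic mean
#' over the platforms that report it; platforms that do not compute the
#' descriptor simply drop out.  Count-valued descriptors are rounded half
#' up to the nearest integer, continuous descriptors are carried at full
#' precision (the printed tables round them to 2 decimals for display
#' only).
#'
#' @param values numeric vector of per-platform values, `NA` = not
#'   determined.
#' @param integer logical; round the mean half-up to an integer (use for
#'   count descriptors such as nRB, nHA, nHD, nRings).
#' @return the consensus value, or `NA` (with a warning) when every
#'   platform value is missing.
#' @examples
#' consensus_mean(c(329.33, 329.12, 329.33, 329.32, 329.12, 329.33,
#'                  329.33, 329.33))  # 329.27625, printed as 329.28
#' @export
consensus_mean <- function(values, integer = FALSE) {
  values <- as.numeric(values)
  if (all(is.na(values))) {
    warning("all platform values missing; compound flagged incomplete")
    return(NA_real_)
  }
  m <- mean(values, na.rm = TRUE)
  if (integer) round_half_up(m) else m
}

#' Two-platform LogP estimate
#'
#' Validation against experimental octanol-water partition coefficients
#' showed the all-platform consensus LogP correlating at r = 0.645, while
#' the mean of just the Molinspiration and Molsoft predictions reached
#' r = 0.750 with a smaller error.  This helper computes that two-platform
#' estimate; both platforms must be present.
#'
#' @param values named numeric vector or list with elements
#'   `Molinspiration` and `Molsoft` (case-insensitive).
#' @return mean of the two platform values.
#' @examples
#' logp_two_platform(c(Molinspiration = 3.73, Molsoft = 2.61))
#' @export
logp_two_platform <- function(values) {
  v <- unlist(values)
  names(v) <- tolower(names(v))
  for (p in c("molinspiration", "molsoft"))
    if (!p %in% names(v) || is.na(v[[p]]))
      stop("LogP value missing for platform: ", p)
  mean(c(v[["molinspiration"]], v[["molsoft"]]))
}

#' Descriptor profile container
#'
#' A named set of the molecular descriptors used by the druglikeness and
#' medicinal-chemistry rule filters.  Units: `mw` g/mol, `tpsa` Angstrom^2,
#' `mr` unitless molar refractivity, `logp` octanol-water log partition;
#' the remaining entries are non-negative counts.
#'
#' @param mw,tpsa,mr,logp continuous descriptors.
#' @param n_rb,n_ha,n_hd,n_rings,n_rigidb,n_atoms,n_carbon,n_heteroatoms,n_aromatic_rings
#'   count descriptors.
#' @return object of class `descriptor_profile` (a named list).
#' @export
descriptor_profile <- function(mw = NA, tpsa = NA, mr = NA, logp = NA,
                               n_rb = NA, n_ha = NA, n_hd = NA,
                               n_rings = NA, n_rigidb = NA, n_atoms = NA,
                               n_carbon = NA, n_heteroatoms = NA,
                               n_aromatic_rings = NA) {
  p <- list(mw = mw, tpsa = tpsa, mr = mr, logp = logp, n_rb = n_rb,
            n_ha = n_ha, n_hd = n_hd, n_rings = n_rings,
            n_rigidb = n_rigidb, n_atoms = n_atoms, n_carbon = n_carbon,
            n_heteroatoms = n_heteroatoms,
            n_aromatic_rings = n_aromatic_rings)
  p <- lapply(p, as.numeric)
  counts <- p[grep("^n_", names(p))]
  bad <- vapply(counts, function(v) !is.na(v) && (v < 0 || v %% 1 != 0),
                logical(1))
  if (any(bad))
    stop("count descriptors must be non-negative integers: ",
         paste(names(counts)[bad], collapse = ", "))
  if (!is.na(p$tpsa) && p$tpsa < 0) stop("TPSA must be >= 0")
  if (!is.na(p$mw) && p$mw <= 0) stop("MW must be > 0")
  structure(p, class = "descriptor_profile")
}

#' @export
print.descriptor_profile <- function(x, ...) {
  cat("<descriptor_profile>\n")
  v <- unlist(x)
  print(round(v[!is.na(v)], 3))
  invisible(x)
}

# parse an elemental formula string like "C7H7NO" into named counts
parse_formula <- function(f) {
  parts <- regmatches(f, gregexpr("[A-Z][a-z]?\\d*", f))[[1]]
  el <- sub("\\d+$", "", parts)
  n <- as.integer(sub("^[A-Za-z]+", "", parts))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' Compute molecular descriptors from a structure
#'
#' Native computation of the descriptor profile from a SMILES string or an
#' SDF record, via ChemmineR/ChemmineOB (OpenBabel).  TPSA follows the
#' Ertl fragment scheme; LogP is an atom-contribution (Crippen-type)
#' estimate and should be treated as one more "platform", not as a mimic
#' of any particular web server.  Counting conventions: `n_ha` counts N+O
#' acceptors, `n_hd` counts heteroatoms bearing at least one H, `n_rb`
#' counts single non-ring bonds between non-terminal heavy atoms,
#' `n_rigidb` is heavy-atom bonds minus `n_rb`, and `n_atoms` counts all
#' atoms including hydrogens by default (the Ghose 20-70 atom window is
#' defined on all atoms) or heavy atoms only with `natoms = "heavy"`.
#'
#' @param structure a SMILES string, a path to an SDF file (first record),
#'   or a `ChemmineR::SDFset`.
#' @param natoms `"all"` (default) or `"heavy"`; atom-count convention.
#' @return a [descriptor_profile()].
#' @export
compute_native_descriptors <- function(structure, natoms = c("all", "heavy")) {
  natoms <- match.arg(natoms)
  for (pkg in c("ChemmineR", "ChemmineOB"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("package ", pkg, " is required for structure input")
  sdf <- as_sdfset(structure)

  props <- ChemmineR::propOB(sdf)
  ring <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  if (!is.null(dim(ring))) ring <- setNames(as.numeric(ring[1, ]), colnames(ring))
  fcounts <- parse_formula(props$formula[1])
  n_h <- if ("H" %in% names(fcounts)) fcounts[["H"]] else 0L
  n_all <- sum(fcounts)
  n_heavy <- n_all - n_h
  n_carbon <- if ("C" %in% names(fcounts)) fcounts[["C"]] else 0L

  n_rb <- unname(ChemmineR::smartsSearchOB(
    sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]", uniqueMatches = TRUE))
  # heavy-atom bond count: bond rows whose endpoints are both non-H
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  sym <- gsub("_.*", "", rownames(ab))
  heavy_bond <- sum(sym[bb[, 1]] != "H" & sym[bb[, 2]] != "H")

  descriptor_profile(
    mw = props$MW[1], tpsa = props$TPSA[1], mr = props$MR[1],
    logp = props$logP[1],
    n_rb = n_rb, n_ha = props$HBA1[1], n_hd = props$HBD[1],
    n_rings = ring[["RINGS"]], n_rigidb = heavy_bond - n_rb,
    n_atoms = if (natoms == "all") n_all else n_heavy,
    n_carbon = n_carbon, n_heteroatoms = n_heavy - n_carbon,
    n_aromatic_rings = ring[["AROMATIC"]])
}

# coerce SMILES string / SDF path / SDFset to a one-molecule SDFset
as_sdfset <- function(structure) {
  if (inherits(structure, "SDFset")) return(structure[1])
  if (!is.character(structure) || length(structure) != 1L || is.na(structure))
    stop("structure must be a SMILES string, SDF path, or SDFset")
  if (file.exists(structure) && grepl("\\.sdf$", structure, ignore.case = TRUE))
    return(ChemmineR::read.SDFset(structure)[1])
  if (is.null(names(structure))) names(structure) <- "mol"  # title required
  sdf <- tryCatch(ChemmineR::smiles2sdf(structure),
                  error = function(e) stop("unparseable structure: ",
                                           structure, " (", conditionMessage(e), ")"))
  if (!ChemmineR::validSDF(sdf)) stop("unparseable structure: ", structure)
  sdf
}
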