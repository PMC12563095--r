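#' Virtual-screening enrichment factor
#'
#' The enrichment factor at fraction x compares the density of active
#' compounds in the top x% of a ranked list with their density overall:
#' \deqn{EF_{x\%} = \frac{actives_{x\%}/dataset_{x\%}}
#'                       {actives_{total}/dataset_{total}}}
#' with the top set of size `floor(x * N)`.  An EF above 1 means the
#' ranking concentrates actives better than random selection.
#'
#' @param is_active logical vector over the ranked dataset, best rank
#'   first (when `scores` is given, the input order is replaced by the
#'   score ranking, ties keeping input order).
#' @param x_fraction top fraction to evaluate, in (0, 1\]; default 0.10
#'   (at 1 the whole list is "top" and EF is exactly 1).
#' @param scores optional numeric scores used to rank.
#' @param higher_is_better ranking direction for `scores` (set `FALSE`
#'   for binding affinities, where more negative is better).
#' @return object of class `enrichment_report`: list with `x_fraction`,
#'   `n_top`, `actives_in_top`, `n_total`, `actives_total`, `ef`, and
#'   `auc` (ROC area, computed when `scores` is given, else `NA`).
#' @examples
#' # 332 compounds, 30 actives, 13 of them in the top 33
#' act <- c(rep(TRUE, 13), rep(FALSE, 20), rep(TRUE, 17), rep(FALSE, 282))
#' enrichment_factor(act, 0.10)$ef  # 4.36
#' @export
enrichment_factor <- function(is_active, x_fraction = 0.10, scores = NULL,
                              higher_is_better = TRUE) {
  is_active <- as.logical(is_active)
  if (anyNA(is_active)) stop("is_active must be known for every record")
  n_total <- length(is_active)
  actives_total <- sum(is_active)
  if (actives_total == 0L) stop("no active compounds in the dataset")
  if (!is.numeric(x_fraction) || x_fraction <= 0 || x_fraction > 1)
    stop("x_fraction must be in (0, 1]")
  auc <- NA_real_
  if (!is.null(scores)) {
    if (length(scores) != n_total)
      stop("scores and is_active must have equal length")
    auc <- roc_auc(scores, is_active, higher_is_better)
    key <- if (higher_is_better) -scores else scores
    ord <- order(key, seq_along(key))   # stable: ties keep input order
    is_active <- is_active[ord]
  }
  n_top <- floor(x_fraction * n_total)
  if (n_top == 0L) stop("top fraction selects zero records; increase x_fraction")
  actives_top <- sum(is_active[seq_len(n_top)])
  ef <- (actives_top / n_top) / (actives_total / n_total)
  structure(list(x_fraction = x_fraction, n_top = n_top,
                 actives_in_top = actives_top, n_total = n_total,
                 actives_total = actives_total, ef = ef, auc = auc),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report> EF(%g%%) = %.3f\n", 100 * x$x_fraction, x$ef))
  cat(sprintf("  %d of %d actives in the top %d of %d records\n",
              x$actives_in_top, x$actives_total, x$n_top, x$n_total))
  if (!is.na(x$auc)) cat(sprintf("  ROC-AUC %.3f\n", x$auc))
  invisible(x)
}

#' ROC area under the curve
#'
#' AUC computed as the Mann-Whitney probability that a randomly chosen
#' active outranks a randomly chosen decoy, with ties counted 1/2 -- so
#' it is invariant under any strictly monotone transform of the scores.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) active flags.
#' @param higher_is_better score direction.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(3, 2, 1), c(TRUE, FALSE, FALSE))  # 1
#' @export
roc_auc <- function(scores, labels, higher_is_better = TRUE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC")
  s <- if (higher_is_better) scores else -scores
  r <- rank(s, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Docking pose RMSD with symmetry-aware atom matching
#'
#' Heavy-atom root-mean-square deviation between a docked pose and its
#' reference coordinates, without superposition (in-place docking RMSD).
#' Topologically equivalent atoms (e.g. the two orientations of a phenyl
#' ring) are matched by minimising the RMSD over all graph isomorphisms
#' between the two element-labelled molecular graphs, so a benzene
#' rotated by 60 degrees scores 0 rather than ~1.4 A.
#'
#' Quality bands follow the usual docking-validation convention:
#' below 2.0 A the pose is consistent with the reference, between 2.0 and
#' 3.0 A it is shifted but keeps the orientation, above 3.0 A it is
#' inaccurate.
#'
#' @param reference,docked the same molecule as either a
#'   `ChemmineR::SDFset` (first record used) / SDF file path, or a list
#'   with elements `elements` (character), `coords` (n x 3 matrix) and
#'   `bonds` (2-column matrix of atom indices).
#' @return object of class `rmsd_result`: list with `rmsd`, `band`,
#'   `n_matched_atoms`, `n_mappings` (graph isomorphisms examined).
#' @export
pose_rmsd <- function(reference, docked) {
  ref <- as_molgraph(reference)
  doc <- as_molgraph(docked)
  if (length(ref$elements) != length(doc$elements))
    stop("atom count mismatch: ", length(ref$elements), " vs ",
         length(doc$elements))
  g1 <- molgraph_igraph(ref); g2 <- molgraph_igraph(doc)
  maps <- igraph::graph.get.isomorphisms.vf2(
    g1, g2, vertex.color1 = igraph::V(g1)$color,
    vertex.color2 = igraph::V(g2)$color)
  if (length(maps) == 0L)
    stop("molecular graphs are not isomorphic; cannot match atoms")
  best <- Inf
  for (m in maps) {
    # m lists reference vertices in docked-vertex order
    d <- ref$coords[as.integer(m), , drop = FALSE] - doc$coords
    r <- sqrt(mean(rowSums(d^2)))
    if (r < best) best <- r
  }
  structure(list(rmsd = best, band = rmsd_band(best),
                 n_matched_atoms = length(ref$elements),
                 n_mappings = length(maps)),
            class = "rmsd_result")
}

#' @rdname pose_rmsd
#' @param rmsd numeric RMSD value(s) in Angstrom.
#' @export
rmsd_band <- function(rmsd) {
  if (any(rmsd < 0, na.rm = TRUE)) stop("rmsd must be >= 0")
  cut(rmsd, breaks = c(-Inf, 2, 3, Inf),
      labels = c("consistent", "shifted", "inaccurate"),
      right = FALSE) -> b
  # boundary 3.0 belongs to "shifted" ("between 2.0 and 3.0")
  b[rmsd == 3] <- "shifted"
  as.character(b)
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<rmsd_result> %.3f A (%s), %d heavy atoms, %d mapping(s)\n",
              x$rmsd, x$band, x$n_matched_atoms, x$n_mappings))
  invisible(x)
}

# coerce SDFset / SDF path / plain list to heavy-atom graph + coordinates
as_molgraph <- function(x) {
  if (is.list(x) && !inherits(x, "SDFset") &&
      all(c("elements", "coords", "bonds") %in% names(x))) {
    el <- as.character(x$elements)
    xyz <- as.matrix(x$coords)
    bonds <- as.matrix(x$bonds)[, 1:2, drop = FALSE]
  } else {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("package ChemmineR is required for SDF input")
    sdf <- if (inherits(x, "SDFset")) x[[1]] else
      ChemmineR::read.SDFset(x)[[1]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    el <- gsub("_.*", "", rownames(ab))
    xyz <- ab[, 1:3, drop = FALSE]
    bonds <- bb[, 1:2, drop = FALSE]
  }
  stopifnot(ncol(xyz) >= 3L)
  heavy <- el != "H"
  idx <- cumsum(heavy)                 # old index -> heavy index
  keep_bond <- heavy[bonds[, 1]] & heavy[bonds[, 2]]
  list(elements = el[heavy],
       coords = matrix(as.numeric(xyz[heavy, 1:3]), ncol = 3),
       bonds = cbind(idx[bonds[keep_bond, 1]], idx[bonds[keep_bond, 2]]))
}

molgraph_igraph <- function(m) {
  g <- igraph::graph_from_edgelist(m$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(m$elements) - igraph::vcount(g)))
  igraph::V(g)$color <- as.integer(factor(m$elements,
                                          levels = sort(unique(m$elements))))
  g
}
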