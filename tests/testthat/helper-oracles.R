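# Brute-force oracles and small builders shared across the suite.

# O(n^2) pairwise AUC: P(active outranks decoy), ties 1/2
bf_auc <- function(scores, labels, higher_is_better = TRUE) {
  s <- if (higher_is_better) scores else -scores
  pos <- s[as.logical(labels)]
  neg <- s[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# exhaustive minimum RMSD over element- and adjacency-preserving
# permutations (usable up to ~8 heavy atoms)
bf_min_rmsd <- function(ref, doc) {
  n <- length(ref$elements)
  adj <- function(m) {
    a <- matrix(0L, n, n)
    a[m$bonds] <- 1L
    a[m$bonds[, 2:1, drop = FALSE]] <- 1L
    a
  }
  a1 <- adj(ref); a2 <- adj(doc)
  best <- Inf
  for (p in all_perms(n)) {
    p <- unlist(p)
    if (!all(ref$elements == doc$elements[p])) next
    if (!all(a1 == a2[p, p])) next
    d <- ref$coords - doc$coords[p, , drop = FALSE]
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

# regular hexagon "benzene" molgraph with ring bonds
hexagon_mol <- function(rot_deg = 0) {
  th <- (0:5) * pi / 3 + rot_deg * pi / 180
  list(elements = rep("C", 6),
       coords = cbind(1.39 * cos(th), 1.39 * sin(th), 0),
       bonds = cbind(1:6, c(2:6, 1)))
}

# tiny asymmetric molecule (C-C-O chain)
chain_mol <- function(shift = c(0, 0, 0)) {
  list(elements = c("C", "C", "O"),
       coords = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.1, 0)) +
         rep(shift, each = 3),
       bonds = cbind(1:2, 2:3))
}

# write a platform table CSV and return its path
write_platform_csv <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

expect_exact <- function(object, expected) expect_equal(object, expected,
                                                        tolerance = 1e-12)

# absolute-difference comparison against a printed value
expect_within <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
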