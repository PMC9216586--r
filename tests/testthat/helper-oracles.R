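# Independent reference implementations used to cross-check the package's
# geometry and sequence code.  These deliberately use different
# constructions from the package internals.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## Dihedral by projecting the outer bonds onto the plane normal to the
## axis and taking the signed angle between the projections.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  proj <- function(v) v - sum(v * b2) / sum(b2 * b2) * b2
  v1 <- proj(p1 - p2)
  v2 <- proj(p4 - p3)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(cross3(v1, v2) * b2) < 0) -ang else ang
}

## Identity by explicit character loop.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n_match <- 0
  for (k in seq_along(av)) if (av[k] == bv[k]) n_match <- n_match + 1
  100 * n_match / length(av)
}

## Pairwise loop relation by integer-interval set operations.
oracle_pair_relation <- function(p, q) {
  s1 <- seq(p[1], p[2])
  s2 <- seq(q[1], q[2])
  ov <- intersect(s1, s2)
  if (length(ov) == 0) "independent"
  else if (all(s2 %in% s1) || all(s1 %in% s2)) "nested"
  else "interlocked"
}

oracle_topology <- function(pairing) {
  pairing <- t(apply(pairing, 1, sort))
  nb <- nrow(pairing)
  if (nb == 1) return("independent")
  rel <- character(0)
  for (u in 1:(nb - 1)) for (v in (u + 1):nb)
    rel <- c(rel, oracle_pair_relation(pairing[u, ], pairing[v, ]))
  if (length(unique(rel)) == 1) rel[1] else "mixed"
}

## Plain argmin chi1-grid sulphur fixation (no tie logic), any grid step.
oracle_fix_dss <- function(s, i, j, step) {
  s <- ensure_cbeta(s)
  co <- s$coords
  grid <- seq(-180 + step, 180, by = step)
  sgi <- place_sgamma(co$N[i, ], co$CA[i, ], co$CB[i, ], grid)
  sgj <- place_sgamma(co$N[j, ], co$CA[j, ], co$CB[j, ], grid)
  d <- sqrt(pmax(outer(rowSums(sgi^2), rowSums(sgj^2), "+") -
                   2 * tcrossprod(sgi, sgj), 0))
  d[which.min(abs(d - 2.04))]
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  an <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(an) * K + (1 - cos(an)) * (K %*% K)
}

## A compact random-coil structure built from the package's own
## Ramachandran sampler (deterministic given the seed).
random_coil <- function(n, seed, sequence = NULL) {
  if (is.null(sequence)) sequence <- strrep("A", n)
  withr::with_seed(seed, {
    tor <- sample_torsions(sequence)
    build_backbone(sequence, tor$phi, tor$psi, tor$omega,
                   id = sprintf("coil%d_s%d", n, seed))
  })
}
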