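# Vector geometry primitives: distances, angles, dihedrals, Cbeta
# reconstruction, Sgamma placement and torsion-to-Cartesian chain building.

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-10) stop("degenerate (zero-length) vector")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## wrap an angle in degrees into (-180, 180]
.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Ideal peptide stereochemistry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used for building
#' backbones, reconstructing Cbeta atoms and placing Sgamma atoms.  Values
#' follow standard peptide stereochemistry; every constant can be overridden.
#'
#' @param ... named overrides for individual constants.
#' @return A named list of constants:
#'   \code{b_n_ca} 1.458, \code{b_ca_c} 1.525, \code{b_c_n} 1.329,
#'   \code{b_c_o} 1.231, \code{b_ca_cb} 1.521, \code{b_cb_sg} 1.808,
#'   \code{a_n_ca_c} 111.2, \code{a_ca_c_n} 116.2, \code{a_c_n_ca} 121.7,
#'   \code{a_ca_c_o} 120.8, \code{a_n_ca_cb} 110.5, \code{a_ca_cb_sg} 114.0,
#'   \code{ss_ideal} 2.04 (ideal S-S bond length),
#'   \code{a_cb_sg_sg} 104.2 (ideal CB-SG-SG' angle),
#'   \code{chiss_ideal} 90 (ideal |chi_ss|).
#' @export
#' @examples
#' geom <- ideal_geometry()
#' geom$ss_ideal
ideal_geometry <- function(...) {
  geom <- list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
    b_ca_cb = 1.521, b_cb_sg = 1.808,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.8, a_n_ca_cb = 110.5, a_ca_cb_sg = 114.0,
    ss_ideal = 2.04, a_cb_sg_sg = 104.2, chiss_ideal = 90)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(geom))
    if (length(bad)) stop("unknown geometry constant(s): ",
                          paste(bad, collapse = ", "))
    geom[names(ov)] <- ov
  }
  stopifnot(all(unlist(geom[grep("^b_|^ss_", names(geom))]) > 0))
  geom
}

#' Bond angle between three points
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is measured at \code{p2}.
#' @return Angle in degrees, in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- .unit(p1 - p2)
  v <- .unit(p3 - p2)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking along \code{p2 -> p3}, the angle is
#' positive for a clockwise rotation carrying \code{p1} onto \code{p4}.
#' Reversing the point order negates the angle.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return Dihedral angle in degrees, in (-180, 180].
#' @export
#' @examples
#' dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)) # trans: 180
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2 * b2)) < 1e-10) stop("degenerate dihedral axis")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < 1e-16 || sum(n2 * n2) < 1e-16)
    stop("degenerate dihedral: collinear points")
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2) / sqrt(sum(b2 * b2))
  .wrap180(.rad2deg(atan2(y, x)))
}

## Place atom D from reference atoms A-B-C with bond length |C-D|, bond
## angle at C (B-C-D, degrees) and torsion A-B-C-D (degrees).  The
## workhorse for internal-coordinate chain extension (NeRF-style).
.nerf <- function(a, b, c_, len, ang, tor) {
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  th <- .deg2rad(ang)
  ph <- .deg2rad(tor)
  d2 <- c(-len * cos(th), len * sin(th) * cos(ph), len * sin(th) * sin(ph))
  c_ + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Vectorised .nerf over a vector of torsions -> matrix (length(tor) x 3)
.nerf_multi <- function(a, b, c_, len, ang, tor) {
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  th <- .deg2rad(ang)
  ph <- .deg2rad(tor)
  x <- -len * cos(th)
  y <- len * sin(th) * cos(ph)
  z <- len * sin(th) * sin(ph)
  cbind(c_[1L] + x * bc[1L] + y * m[1L] + z * n[1L],
        c_[2L] + x * bc[2L] + y * m[2L] + z * n[2L],
        c_[3L] + x * bc[3L] + y * m[3L] + z * n[3L])
}

#' Reconstruct an ideal Cbeta position from backbone atoms
#'
#' Places Cbeta at the ideal tetrahedral position for an L-amino acid:
#' CA-CB bond length from \code{geom}, equal angles to N and C, and
#' L-chirality (the triple product (N-CA) x (C-CA) . (CB-CA) is positive;
#' equivalently the improper dihedral C-N-CA-CB is near -122.7 degrees).
#'
#' @param n,ca,c numeric 3-vectors: backbone N, CA and C positions.
#' @param geom geometry constants, see [ideal_geometry()].
#' @return Cbeta position as a numeric 3-vector.
#' @export
reconstruct_cbeta <- function(n, ca, c, geom = ideal_geometry()) {
  u1 <- .unit(n - ca)
  u2 <- .unit(c - ca)
  w <- .cross3(u1, u2)
  wn <- sqrt(sum(w * w))
  if (wn < 1e-8) stop("collinear N, CA, C: cannot reconstruct CB")
  w <- w / wn
  cosg <- sum(u1 * u2)
  ct <- cos(.deg2rad(geom$a_n_ca_cb))
  alpha <- ct / (1 + cosg)
  ip <- alpha^2 * 2 * (1 + cosg)     # |alpha (u1 + u2)|^2
  if (ip >= 1) stop("infeasible CB geometry for this backbone frame")
  beta <- sqrt(1 - ip)               # positive: L-chirality
  d <- alpha * (u1 + u2) + beta * w
  ca + geom$b_ca_cb * d
}

#' Place a cysteine Sgamma atom for a given chi1
#'
#' Fixes Sgamma off Cbeta with bond length CB-SG, bond angle CA-CB-SG and
#' side-chain torsion chi1 = dihedral N-CA-CB-SG.
#'
#' @param n,ca,cb numeric 3-vectors.
#' @param chi1 side-chain torsion in degrees; may be a vector, in which
#'   case a matrix with one row per chi1 value is returned.
#' @param geom geometry constants, see [ideal_geometry()].
#' @return Numeric 3-vector (or matrix for vector \code{chi1}).
#' @export
place_sgamma <- function(n, ca, cb, chi1, geom = ideal_geometry()) {
  if (length(chi1) == 1L)
    .nerf(n, ca, cb, geom$b_cb_sg, geom$a_ca_cb_sg, chi1)
  else
    .nerf_multi(n, ca, cb, geom$b_cb_sg, geom$a_ca_cb_sg, chi1)
}

#' Build backbone coordinates from torsion angles
#'
#' Realises a (phi, psi, omega) torsion assignment as Cartesian coordinates
#' by sequential internal-coordinate chain extension with ideal peptide
#' stereochemistry.  Each residue receives N, CA, C, O and (except glycine)
#' an ideal Cbeta.  \code{phi[1]} and \code{psi[n]} do not affect the chain
#' (there is no preceding/following peptide unit); \code{psi[n]} only
#' orients the terminal carbonyl oxygen.  \code{omega[i]} is the peptide
#' torsion CA(i)-C(i)-N(i+1)-CA(i+1) following residue i.
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param phi,psi,omega torsion angles in degrees; recycled to the sequence
#'   length.
#' @param chain chain identifier for the generated residues.
#' @param id structure identifier.
#' @param geom geometry constants, see [ideal_geometry()].
#' @return A \code{ssf_structure} (see [read_structure()] for the layout).
#' @export
#' @examples
#' helix <- build_backbone(strrep("A", 10), phi = -57, psi = -47)
#' measure_torsions(helix)
build_backbone <- function(sequence, phi, psi, omega = 180,
                           chain = "A", id = "built",
                           geom = ideal_geometry()) {
  aa <- .seq_to_vec(sequence)
  nres <- length(aa)
  if (nres < 1L) stop("empty sequence")
  phi <- rep_len(phi, nres)
  psi <- rep_len(psi, nres)
  omega <- rep_len(omega, nres)
  if (anyNA(phi[-1L]) || anyNA(psi[-nres]) || anyNA(omega[-nres]))
    stop("NA torsions are only allowed at the chain termini")
  if (is.na(psi[nres])) psi[nres] <- 180

  N <- CA <- C <- O <- CB <- matrix(NA_real_, nres, 3L)
  ## frame for residue 1: N at origin, CA on x, C in the xy-plane
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(geom$b_n_ca, 0, 0)
  th <- .deg2rad(geom$a_n_ca_c)
  C[1L, ] <- CA[1L, ] + geom$b_ca_c * c(-cos(th), sin(th), 0)
  if (nres > 1L) {
    for (i in seq_len(nres - 1L)) {
      N[i + 1L, ] <- .nerf(N[i, ], CA[i, ], C[i, ],
                           geom$b_c_n, geom$a_ca_c_n, psi[i])
      CA[i + 1L, ] <- .nerf(CA[i, ], C[i, ], N[i + 1L, ],
                            geom$b_n_ca, geom$a_c_n_ca, omega[i])
      C[i + 1L, ] <- .nerf(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                           geom$b_ca_c, geom$a_n_ca_c, phi[i + 1L])
      O[i, ] <- .nerf(N[i + 1L, ], CA[i, ], C[i, ],
                      geom$b_c_o, geom$a_ca_c_o, 180)
    }
  }
  ## terminal oxygen: anti to where the next N would sit
  O[nres, ] <- .nerf(N[nres, ], CA[nres, ], C[nres, ],
                     geom$b_c_o, geom$a_ca_c_o, .wrap180(psi[nres] + 180))
  for (i in seq_len(nres)) {
    if (aa[i] != "G")
      CB[i, ] <- reconstruct_cbeta(N[i, ], CA[i, ], C[i, ], geom)
  }
  residues <- data.frame(
    chain = rep(chain, nres), resno = seq_len(nres),
    icode = rep("", nres), idx = seq_len(nres), aa = aa,
    cb_source = ifelse(aa == "G", NA_character_, "reconstructed"),
    stringsAsFactors = FALSE)
  new_structure(id = id, residues = residues,
                coords = list(N = N, CA = CA, C = C, O = O, CB = CB,
                              SG = matrix(NA_real_, nres, 3L)),
                source = "build_backbone")
}

#' Measure backbone torsions of a structure
#'
#' Inverse of [build_backbone()]: recovers per-residue phi, psi and omega
#' from coordinates.  Undefined torsions at the termini are NA.
#'
#' @param structure a \code{ssf_structure}.
#' @param chain chain to measure; default the first chain.
#' @return data.frame with columns \code{idx}, \code{aa}, \code{phi},
#'   \code{psi}, \code{omega} (degrees).
#' @export
measure_torsions <- function(structure, chain = NULL) {
  res <- structure$residues
  if (is.null(chain)) chain <- res$chain[1L]
  sel <- which(res$chain == chain)
  if (!length(sel)) stop("no such chain: ", chain)
  N <- structure$coords$N[sel, , drop = FALSE]
  CA <- structure$coords$CA[sel, , drop = FALSE]
  C <- structure$coords$C[sel, , drop = FALSE]
  n <- length(sel)
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) phi[i] <- dihedral(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) {
      psi[i] <- dihedral(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- dihedral(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  data.frame(idx = res$idx[sel], aa = res$aa[sel],
             phi = phi, psi = psi, omega = omega)
}

.seq_to_vec <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  aa <- toupper(as.character(sequence))
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]))
    stop("sequence contains non-standard one-letter codes")
  aa
}
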