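# Deterministic synthetic structures with known disulphide geometry and
# planted connectivity, so the whole toolkit is testable without any
# structure downloads.

#' Ideal alpha-helical structure
#'
#' A poly-alanine helix built with phi = -57, psi = -47, omega = 180.
#'
#' @param n number of residues (>= 4).
#' @param seed kept for the fixture interface; the helix is fully
#'   deterministic.
#' @param sequence optional sequence (defaults to poly-Ala of length n).
#' @return A \code{ssf_structure}.
#' @export
make_ideal_helix <- function(n, seed = 1L, sequence = NULL) {
  if (n < 4L) stop("a helix fixture needs at least 4 residues")
  if (is.null(sequence)) sequence <- strrep("A", n)
  build_backbone(sequence, phi = -57, psi = -47, omega = 180,
                 id = sprintf("helix%d", n))
}

#' Extended-chain structure
#'
#' A beta-strand-like extended backbone (phi = -120, psi = 130).
#'
#' @param sequence one-letter sequence string.
#' @param id structure identifier.
#' @return A \code{ssf_structure}.
#' @export
make_extended_chain <- function(sequence, id = "extended") {
  build_backbone(sequence, phi = -120, psi = 130, omega = 180, id = id)
}

## Improper torsion CB-N-CA-C realised by ideal L-geometry; computed once
## from a reference residue so fixture construction is exactly consistent
## with reconstruct_cbeta().
.improper_cb_n_ca_c <- function(geom) {
  n0 <- c(0, 0, 0)
  ca0 <- c(geom$b_n_ca, 0, 0)
  th <- geom$a_n_ca_c * pi / 180
  c0 <- ca0 + geom$b_ca_c * c(-cos(th), sin(th), 0)
  cb0 <- reconstruct_cbeta(n0, ca0, c0, geom)
  dihedral(cb0, n0, ca0, c0)
}

## Build one Cys-centred segment outward from its already-placed side
## chain (SG, CB), then extend the backbone by `flank` residues on each
## side with the given torsions.
.segment_from_sidechain <- function(sg_self, sg_other, cb, chi1, chi2,
                                    flank, phi, psi, geom) {
  ca <- .nerf(sg_other, sg_self, cb, geom$b_ca_cb, geom$a_ca_cb_sg, chi2)
  n <- .nerf(sg_self, cb, ca, geom$b_n_ca, geom$a_n_ca_cb, chi1)
  c_ <- .nerf(cb, n, ca, geom$b_ca_c, geom$a_n_ca_c,
              .improper_cb_n_ca_c(geom))
  nres <- 2L * flank + 1L
  N <- CA <- C <- O <- CB <- matrix(NA_real_, nres, 3L)
  mid <- flank + 1L
  N[mid, ] <- n; CA[mid, ] <- ca; C[mid, ] <- c_; CB[mid, ] <- cb
  ## forward extension
  for (i in seq_len(flank)) {
    k <- mid + i - 1L
    N[k + 1L, ] <- .nerf(N[k, ], CA[k, ], C[k, ], geom$b_c_n,
                         geom$a_ca_c_n, psi)
    CA[k + 1L, ] <- .nerf(CA[k, ], C[k, ], N[k + 1L, ], geom$b_n_ca,
                          geom$a_c_n_ca, 180)
    C[k + 1L, ] <- .nerf(C[k, ], N[k + 1L, ], CA[k + 1L, ], geom$b_ca_c,
                         geom$a_n_ca_c, phi)
    O[k, ] <- .nerf(N[k + 1L, ], CA[k, ], C[k, ], geom$b_c_o,
                    geom$a_ca_c_o, 180)
  }
  ## backward extension
  for (i in seq_len(flank)) {
    k <- mid - i + 1L
    prevC <- .nerf(C[k, ], CA[k, ], N[k, ], geom$b_c_n, geom$a_c_n_ca, phi)
    prevCA <- .nerf(CA[k, ], N[k, ], prevC, geom$b_ca_c, geom$a_ca_c_n, 180)
    prevN <- .nerf(N[k, ], prevC, prevCA, geom$b_n_ca, geom$a_n_ca_c, psi)
    C[k - 1L, ] <- prevC; CA[k - 1L, ] <- prevCA; N[k - 1L, ] <- prevN
    O[k - 1L, ] <- .nerf(N[k, ], prevCA, prevC, geom$b_c_o,
                         geom$a_ca_c_o, 180)
  }
  ## oxygens and CBs not yet placed
  O[nres, ] <- .nerf(N[nres, ], CA[nres, ], C[nres, ], geom$b_c_o,
                     geom$a_ca_c_o, .wrap180(psi + 180))
  for (i in seq_len(nres))
    if (!all(is.finite(CB[i, ])))
      CB[i, ] <- reconstruct_cbeta(N[i, ], CA[i, ], C[i, ], geom)
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

#' Two-segment fixture with a planted disulphide bridge
#'
#' Builds a cystine core first -- both sulphurs at exactly the target S-S
#' distance and chi_ss -- and hangs a short backbone segment off each
#' side, so the planted geometry is exact by construction.  The two
#' segments are chains A and B with the cysteine in the middle; the
#' bridge is declared so SSBOND records are written on output.  The seed
#' randomises the side-chain torsions (chi1, chi2) and the rigid-body
#' pose of the whole fixture; the bridge geometry itself is unaffected.
#'
#' @param d_ss target S-S distance in Angstrom (default the ideal 2.04).
#' @param chi_ss target CB-SG-SG'-CB' torsion in degrees (default +90;
#'   sign is honoured).
#' @param seed integer seed for the pose randomisation.
#' @param flank residues on each side of the cysteine per segment
#'   (default 2, so each chain has 5 residues).
#' @param randomize_chi randomise chi1/chi2 (default TRUE); when FALSE
#'   chi1 = -60 and chi2 = -85 on both sides.
#' @param geom geometry constants.
#' @return A \code{ssf_structure} with chains A and B, SG coordinates for
#'   both cysteines and the bridge declared.
#' @export
#' @examples
#' fx <- make_disulphide_fixture(seed = 3)
#' nb <- native_disulphides(fx)
#' nb$d_ss  # 2.04 by construction
make_disulphide_fixture <- function(d_ss = 2.04, chi_ss = 90, seed = 1L,
                                    flank = 2L, randomize_chi = TRUE,
                                    geom = ideal_geometry()) {
  if (!is.finite(d_ss) || d_ss <= 0.5 || d_ss > 3.5)
    stop("target d_ss ", d_ss, " is not a reachable S-S separation")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  chi1 <- if (randomize_chi) stats::runif(2L, -180, 180) else c(-60, -60)
  chi2 <- if (randomize_chi) stats::runif(2L, -180, 180) else c(-85, -85)

  ## cystine core
  sg_i <- c(0, 0, 0)
  sg_j <- c(d_ss, 0, 0)
  th <- geom$a_cb_sg_sg * pi / 180
  cb_i <- sg_i + geom$b_cb_sg * c(cos(th), sin(th), 0)
  cb_j <- .nerf(cb_i, sg_i, sg_j, geom$b_cb_sg, geom$a_cb_sg_sg, chi_ss)

  seg_i <- .segment_from_sidechain(sg_i, sg_j, cb_i, chi1[1L], chi2[1L],
                                   flank, -120, 130, geom)
  seg_j <- .segment_from_sidechain(sg_j, sg_i, cb_j, chi1[2L], chi2[2L],
                                   flank, -120, 130, geom)
  nres <- 2L * flank + 1L
  mid <- flank + 1L
  aa <- rep("A", nres); aa[mid] <- "C"
  SGa <- matrix(NA_real_, nres, 3L); SGa[mid, ] <- sg_i
  SGb <- matrix(NA_real_, nres, 3L); SGb[mid, ] <- sg_j
  residues <- data.frame(
    chain = rep(c("A", "B"), each = nres),
    resno = rep(seq_len(nres), 2L), icode = "",
    idx = rep(seq_len(nres), 2L), aa = c(aa, aa),
    cb_source = "observed", stringsAsFactors = FALSE)
  coords <- list(N = rbind(seg_i$N, seg_j$N), CA = rbind(seg_i$CA, seg_j$CA),
                 C = rbind(seg_i$C, seg_j$C), O = rbind(seg_i$O, seg_j$O),
                 CB = rbind(seg_i$CB, seg_j$CB), SG = rbind(SGa, SGb))
  s <- new_structure(id = sprintf("bridge_fixture_s%d", seed),
                     residues = residues, coords = coords,
                     source = "make_disulphide_fixture")
  s <- declare_native(s, data.frame(i = mid, j = nres + mid))
  ## random rigid-body pose
  ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax^2))
  an <- stats::runif(1L, 0, 2 * pi)
  K <- matrix(c(0, ax[3L], -ax[2L], -ax[3L], 0, ax[1L],
                ax[2L], -ax[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(an) * K + (1 - cos(an)) * (K %*% K)
  transform_structure(s, R, stats::runif(3L, -20, 20))
}

## Random sequence with cysteines planted at given positions
.planted_sequence <- function(len, cys_at) {
  pool <- strsplit("ADEFIKLMNQRSTVWY", "")[[1L]]
  aa <- sample(pool, len, replace = TRUE)
  aa[cys_at] <- "C"
  paste(aa, collapse = "")
}

#' Toy loop database with planted connectivity patterns
#'
#' Six deterministic single-chain structures: three embed the canonical
#' test connectivities -- the interlocked two-bridge arrangement
#' (2,10)+(4,11), the nested arrangement (11,32)+(15,28) and the
#' three-bridge pattern with canonical offsets 0,5,10,15,17,22 planted at
#' positions (4,19),(9,21),(14,26) -- and three decoys carry perturbed
#' spacings of the same patterns.  Bridges are declared (SSBOND
#' semantics) on extended backbones.  The ground-truth table lists every
#' plantable hit.
#'
#' @param seed integer seed (controls the random non-cysteine sequence).
#' @return A list with \code{structures} (named list of
#'   \code{ssf_structure}) and \code{truth}, a data.frame with columns
#'   \code{pattern}, \code{source_id}, \code{anchor} (window start index
#'   of the planted hit).
#' @export
make_toy_database <- function(seed = 7L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  spec <- list(
    toy_interlocked = list(len = 12L, pairs = rbind(c(2L, 10L), c(4L, 11L))),
    toy_nested = list(len = 36L, pairs = rbind(c(11L, 32L), c(15L, 28L))),
    toy_threebridge = list(len = 30L,
                           pairs = rbind(c(4L, 19L), c(9L, 21L), c(14L, 26L))),
    decoy_interlocked = list(len = 12L, pairs = rbind(c(2L, 9L), c(4L, 11L))),
    decoy_nested = list(len = 36L, pairs = rbind(c(11L, 31L), c(15L, 28L))),
    decoy_threebridge = list(len = 30L,
                             pairs = rbind(c(4L, 19L), c(9L, 22L),
                                           c(14L, 26L))))
  structures <- lapply(names(spec), function(nm) {
    sp <- spec[[nm]]
    cys <- sort(as.vector(sp$pairs))
    s <- make_extended_chain(.planted_sequence(sp$len, cys), id = nm)
    declare_native(s, data.frame(i = sp$pairs[, 1L], j = sp$pairs[, 2L]))
  })
  names(structures) <- names(spec)
  truth <- data.frame(
    pattern = c("C2-C10, C4-C11", "C11-C32, C15-C28",
                "C4-C19, C9-C21, C14-C26"),
    source_id = c("toy_interlocked", "toy_nested", "toy_threebridge"),
    anchor = c(2L, 11L, 4L), stringsAsFactors = FALSE)
  list(structures = structures, truth = truth)
}
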