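# Random Ramachandran-allowed backbone conformation generation under
# disulphide-connectivity constraints, with optional secondary-structure
# clues.  Accepted models are reported in trial order; no ranking is
# performed -- choosing among them is left to the user.

#' Ramachandran sampling regions
#'
#' The (phi, psi) boxes sampled per residue class, with their selection
#' weights.  Non-glycine, non-proline residues are treated as alanine.
#' Glycine additionally samples left-handed-helical and mirrored-extended
#' regions; proline has a restricted phi near -63.  Boxes are uniform:
#' a region is chosen by its weight, then phi and psi are drawn uniformly
#' within the box.
#'
#' @return A list with one element per residue class (\code{general},
#'   \code{gly}, \code{pro}); each is a data.frame with columns
#'   \code{name}, \code{phi_lo}, \code{phi_hi}, \code{psi_lo},
#'   \code{psi_hi}, \code{weight} (weights sum to 1 per class), plus the
#'   clue boxes under \code{helix} and \code{strand}.
#' @export
ranmod_regions <- function() {
  box <- function(name, phi_lo, phi_hi, psi_lo, psi_hi, weight)
    data.frame(name = name, phi_lo = phi_lo, phi_hi = phi_hi,
               psi_lo = psi_lo, psi_hi = psi_hi, weight = weight,
               stringsAsFactors = FALSE)
  regions <- list(
    general = rbind(
      box("alphaR", -90, -40, -65, -10, 0.45),
      box("beta", -170, -60, 90, 175, 0.55)),
    gly = rbind(
      box("alphaR", -90, -40, -65, -10, 0.30),
      box("beta", -170, -60, 90, 175, 0.30),
      box("alphaL", 45, 90, 10, 60, 0.20),
      box("gly-extra", 60, 170, -175, -90, 0.20)),
    pro = rbind(
      box("pro-alpha", -78, -48, -50, -10, 0.40),
      box("pro-trans", -78, -48, 110, 160, 0.60)),
    helix = box("helix-clue", -67, -47, -57, -37, 1),
    strand = box("strand-clue", -140, -100, 110, 150, 1))
  for (cl in c("general", "gly", "pro"))
    stopifnot(abs(sum(regions[[cl]]$weight) - 1) < 1e-12)
  regions
}

#' Parse secondary-structure clues
#'
#' Clue syntax: comma-separated ranges prefixed by kind, e.g.
#' \code{"H:5-16,H:21-35"} (H = helix, E or S = strand).  A data.frame
#' with columns \code{start}, \code{end}, \code{kind} is accepted as-is
#' after validation.
#'
#' @param clues clue string or data.frame, or NULL.
#' @param n sequence length (for range validation).
#' @return data.frame with columns \code{start}, \code{end}, \code{kind}
#'   ("helix"/"strand"), possibly empty.
#' @export
parse_clues <- function(clues, n) {
  empty <- data.frame(start = integer(), end = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (is.null(clues)) return(empty)
  if (is.character(clues)) {
    parts <- trimws(strsplit(clues, ",")[[1L]])
    parts <- parts[nzchar(parts)]
    if (!length(parts)) return(empty)
    m <- regmatches(parts, regexec("^([HhEeSs]):([0-9]+)-([0-9]+)$", parts))
    if (any(lengths(m) != 4L)) stop("malformed clue specification: ", clues)
    clues <- data.frame(
      start = as.integer(vapply(m, `[`, "", 3L)),
      end = as.integer(vapply(m, `[`, "", 4L)),
      kind = ifelse(toupper(vapply(m, `[`, "", 2L)) == "H",
                    "helix", "strand"),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "kind") %in% names(clues)))
  if (!nrow(clues)) return(empty)
  if (any(clues$start < 1L) || any(clues$end > n) ||
      any(clues$start > clues$end))
    stop("clue range outside the sequence (length ", n, ")")
  if (!all(clues$kind %in% c("helix", "strand")))
    stop("clue kind must be helix or strand")
  ord <- order(clues$start)
  clues <- clues[ord, , drop = FALSE]
  if (nrow(clues) > 1L &&
      any(clues$start[-1L] <= clues$end[-nrow(clues)]))
    stop("clue ranges overlap")
  clues
}

#' Sample random allowed backbone torsions for a sequence
#'
#' Assigns random (phi, psi) values residue by residue: residues inside a
#' clue range draw uniformly from the clue box; otherwise a Ramachandran
#' region is chosen by residue-class weight (glycine and proline have
#' their own region sets; everything else, including cysteine, is treated
#' as alanine) and (phi, psi) drawn uniformly within it.  Omega is fixed
#' at 180 (trans).  Consumes the current R random number stream.
#'
#' @param sequence one-letter string or character vector.
#' @param clues clue specification (see [parse_clues()]) or NULL.
#' @param regions region set from [ranmod_regions()].
#' @return data.frame with per-residue \code{aa}, \code{phi}, \code{psi},
#'   \code{omega}, the \code{region} drawn from and its box bounds.
#' @export
sample_torsions <- function(sequence, clues = NULL,
                            regions = ranmod_regions()) {
  aa <- .seq_to_vec(sequence)
  plan <- .torsion_plan(aa, parse_clues(clues, length(aa)), regions)
  t <- .sample_torsions_core(plan)
  data.frame(aa = aa, phi = t$phi, psi = t$psi, omega = 180,
             region = plan$name[t$box], phi_lo = plan$phi_lo[t$box],
             phi_hi = plan$phi_hi[t$box], psi_lo = plan$psi_lo[t$box],
             psi_hi = plan$psi_hi[t$box], stringsAsFactors = FALSE)
}

## Pre-compile the per-residue sampling plan: a flat box table plus, for
## each residue, the rows it may draw from and their cumulative weights.
.torsion_plan <- function(aa, cl, regions) {
  n <- length(aa)
  clue_of <- rep(NA_character_, n)
  for (k in seq_len(nrow(cl)))
    clue_of[cl$start[k]:cl$end[k]] <- cl$kind[k]
  tabs <- list(general = regions$general, gly = regions$gly,
               pro = regions$pro, helix = regions$helix,
               strand = regions$strand)
  flat <- do.call(rbind, tabs)
  offs <- cumsum(c(0L, vapply(tabs, nrow, 1L)))
  names(offs) <- c(names(tabs), "end")
  cls <- ifelse(!is.na(clue_of), clue_of,
                ifelse(aa == "G", "gly", ifelse(aa == "P", "pro",
                                                "general")))
  rows <- lapply(names(tabs), function(nm)
    offs[[nm]] + seq_len(nrow(tabs[[nm]])))
  names(rows) <- names(tabs)
  cumw <- lapply(names(tabs), function(nm) cumsum(tabs[[nm]]$weight))
  names(cumw) <- names(tabs)
  list(n = n, cls = cls, rows = rows, cumw = cumw,
       name = flat$name, phi_lo = flat$phi_lo, phi_hi = flat$phi_hi,
       psi_lo = flat$psi_lo, psi_hi = flat$psi_hi)
}

## One draw per trial: consumes exactly 3n uniforms (region, phi, psi).
.sample_torsions_core <- function(plan) {
  n <- plan$n
  u_reg <- stats::runif(n)
  u_phi <- stats::runif(n)
  u_psi <- stats::runif(n)
  box <- integer(n)
  for (i in seq_len(n)) {
    cw <- plan$cumw[[plan$cls[i]]]
    k <- 1L
    while (k < length(cw) && u_reg[i] > cw[k]) k <- k + 1L
    box[i] <- plan$rows[[plan$cls[i]]][k]
  }
  phi <- plan$phi_lo[box] + u_phi * (plan$phi_hi[box] - plan$phi_lo[box])
  psi <- plan$psi_lo[box] + u_psi * (plan$psi_hi[box] - plan$psi_lo[box])
  list(phi = phi, psi = psi, box = box)
}

#' Steric clash filter on CA positions
#'
#' A conformation fails if any two CA atoms separated by at least three
#' positions in sequence are closer than \code{clash_min_ca}.
#'
#' @param x a \code{ssf_structure} or an n x 3 CA coordinate matrix.
#' @param clash_min_ca minimum allowed CA-CA distance in Angstrom
#'   (default 3.5).
#' @return TRUE (pass) or FALSE (fail).
#' @export
clash_filter <- function(x, clash_min_ca = 3.5) {
  ca <- if (inherits(x, "ssf_structure")) x$coords$CA else x
  n <- nrow(ca)
  if (n < 4L || clash_min_ca <= 0) return(TRUE)
  m2 <- clash_min_ca^2
  for (i in seq_len(n - 3L)) {
    for (j in (i + 3L):n) {
      if ((ca[i, 1L] - ca[j, 1L])^2 + (ca[i, 2L] - ca[j, 2L])^2 +
          (ca[i, 3L] - ca[j, 3L])^2 < m2) return(FALSE)
    }
  }
  TRUE
}

#' RANMOD configuration
#'
#' @param n_trials number of random conformations to examine (default
#'   200000).
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param accept_grades grades a bridge may have for the conformation to
#'   be accepted (default A, B and C; D -- sulphur unfixable -- always
#'   rejects).
#' @param clash_min_ca CA clash threshold, see [clash_filter()].
#' @param max_models maximum number of accepted models to keep in full
#'   (acceptance counting continues beyond it).
#' @param regions sampling regions, see [ranmod_regions()].
#' @param modip bridge-evaluation settings, see [modip_config()].
#' @return A list of class \code{ranmod_config}.
#' @export
ranmod_config <- function(n_trials = 200000L, seed = 1L,
                          accept_grades = c("A", "B", "C"),
                          clash_min_ca = 3.5, max_models = 10L,
                          regions = ranmod_regions(),
                          modip = modip_config()) {
  stopifnot(n_trials >= 1L, !"D" %in% accept_grades,
            all(accept_grades %in% c("A", "B", "C")))
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 accept_grades = accept_grades,
                 clash_min_ca = clash_min_ca,
                 max_models = as.integer(max_models),
                 regions = regions, modip = modip),
            class = "ranmod_config")
}

## Fast backbone build for the trial loop: N/CA/C matrices only, CB just
## where requested.  Mirrors build_backbone() with ideal geometry.
.build_bb_fast <- function(n, phi, psi, omega, cb_at, geom) {
  N <- CA <- C <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(geom$b_n_ca, 0, 0)
  th <- geom$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + geom$b_ca_c * c(-cos(th), sin(th), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1L, ] <- .nerf(N[i, ], CA[i, ], C[i, ],
                           geom$b_c_n, geom$a_ca_c_n, psi[i])
      CA[i + 1L, ] <- .nerf(CA[i, ], C[i, ], N[i + 1L, ],
                            geom$b_n_ca, geom$a_c_n_ca, omega[i])
      C[i + 1L, ] <- .nerf(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                           geom$b_ca_c, geom$a_n_ca_c, phi[i + 1L])
    }
  }
  CB <- matrix(NA_real_, n, 3L)
  for (i in cb_at) CB[i, ] <- reconstruct_cbeta(N[i, ], CA[i, ], C[i, ], geom)
  list(N = N, CA = CA, C = C, CB = CB)
}

.check_pairing <- function(sequence, pairing) {
  aa <- .seq_to_vec(sequence)
  if (is.null(pairing) || !length(pairing))
    return(matrix(integer(), 0L, 2L))
  pairing <- as.matrix(as.data.frame(pairing))[, 1:2, drop = FALSE]
  storage.mode(pairing) <- "integer"
  if (!any(aa == "C")) stop("pairing given but the sequence has no cysteine")
  if (any(pairing[, 1L] >= pairing[, 2L]))
    stop("each disulphide pair must be given as (i, j) with i < j")
  pos <- as.vector(pairing)
  if (any(pos < 1L | pos > length(aa)))
    stop("pairing position outside the sequence")
  bad <- pos[aa[pos] != "C"]
  if (length(bad))
    stop("pairing references non-cysteine position(s): ",
         paste(unique(bad), collapse = ", "))
  if (anyDuplicated(pos)) stop("a position appears in more than one pair")
  pairing
}

#' Evaluate a conformation against a disulphide connectivity
#'
#' For each queried pair the CA-CA and CB-CB distance thresholds are
#' checked first; if compatible, sulphurs are fixed by the chi1 grid
#' search and the bridge graded.  The conformation passes when every pair
#' is gradeable with a grade in \code{accept_grades}.
#'
#' @param structure a \code{ssf_structure} (single chain).
#' @param pairing matrix/data.frame of 1-based residue position pairs;
#'   all positions must be cysteine in the sequence.
#' @param config a [ranmod_config()].
#' @return list with \code{pass} (logical) and \code{bridges}, a
#'   data.frame with one row per pair (columns as in [modip()] reports;
#'   pairs failing the distance pre-check have NA geometry and grade).
#' @export
evaluate_connectivity <- function(structure, pairing,
                                  config = ranmod_config()) {
  pairing <- .check_pairing(structure_sequence(structure), pairing)
  structure <- ensure_cbeta(structure, config$modip$geom)
  co <- structure$coords
  res <- .eval_conn_core(co$N, co$CA, co$CB, pairing, config)
  list(pass = res$pass, bridges = .bridges_df(res, pairing))
}

## Allocation-light connectivity check used inside the trial loop.
## Returns pass, a per-pair failure tag ("distance"/"grade"/NA) and the
## fixed-bridge parameter lists for pairs that reached the grid search.
.eval_conn_core <- function(N, CA, CB, pairing, config) {
  mc <- config$modip
  np <- nrow(pairing)
  pass <- TRUE
  dist_fail <- FALSE
  fixed <- vector("list", np)
  d_ca_v <- d_cb_v <- rep(NA_real_, np)
  for (k in seq_len(np)) {
    i <- pairing[k, 1L]; j <- pairing[k, 2L]
    dca2 <- (CA[i, 1L] - CA[j, 1L])^2 + (CA[i, 2L] - CA[j, 2L])^2 +
      (CA[i, 3L] - CA[j, 3L])^2
    d_ca_v[k] <- sqrt(dca2)
    if (d_ca_v[k] > mc$ca_max) { pass <- FALSE; dist_fail <- TRUE; next }
    dcb2 <- (CB[i, 1L] - CB[j, 1L])^2 + (CB[i, 2L] - CB[j, 2L])^2 +
      (CB[i, 3L] - CB[j, 3L])^2
    d_cb_v[k] <- sqrt(dcb2)
    if (d_cb_v[k] > mc$cb_max) { pass <- FALSE; dist_fail <- TRUE; next }
    b <- .fix_sulphurs_core(N[i, ], CA[i, ], CB[i, ],
                            N[j, ], CA[j, ], CB[j, ], mc)
    fixed[[k]] <- b
    if (!b$grade %in% config$accept_grades) pass <- FALSE
  }
  list(pass = pass, dist_fail = dist_fail, fixed = fixed,
       d_ca = d_ca_v, d_cb = d_cb_v)
}

.bridges_df <- function(res, pairing) {
  np <- nrow(pairing)
  g <- function(fld) vapply(seq_len(np), function(k) {
    b <- res$fixed[[k]]
    if (is.null(b)) NA_real_ else b[[fld]]
  }, numeric(1L))
  data.frame(
    pos_i = pairing[, 1L], pos_j = pairing[, 2L],
    d_ca = res$d_ca, d_cb = res$d_cb, d_ss = g("d_ss"),
    chi1_i = g("chi1_i"), chi1_j = g("chi1_j"), chi_ss = g("chi_ss"),
    grade = vapply(seq_len(np), function(k) {
      b <- res$fixed[[k]]
      if (is.null(b)) NA_character_ else b$grade
    }, character(1L)),
    stringsAsFactors = FALSE)
}

#' Generate random conformations satisfying a disulphide connectivity
#'
#' The trial loop: sample torsions, build the backbone, apply the clash
#' filter, then evaluate the queried disulphide connectivity.  Models
#' whose bridges are all gradeable within \code{accept_grades} are
#' accepted.  Accepted models are returned in trial order (no ranking);
#' the whole run is reproducible from the seed.
#'
#' @param sequence one-letter peptide sequence.
#' @param pairing disulphide connectivity: matrix/data.frame of 1-based
#'   position pairs, or a pattern string accepted by
#'   [parse_connectivity()].
#' @param clues optional secondary-structure clues, see [parse_clues()].
#' @param config a [ranmod_config()].
#' @return A list of class \code{ssf_ranmod}:
#'   \describe{
#'     \item{models}{list of accepted models (up to \code{max_models}),
#'       each with \code{trial}, \code{torsions}, \code{structure} (with
#'       fixed SG coordinates and declared disulphides) and
#'       \code{bridges}}
#'     \item{summary}{trial and rejection counts, accepted trial indices,
#'       seed}
#'   }
#' @export
#' @examples
#' run <- run_ranmod("ACACAAAAACC", rbind(c(2, 10), c(4, 11)),
#'                   config = ranmod_config(n_trials = 200, seed = 7))
#' run$summary$n_accepted
run_ranmod <- function(sequence, pairing, clues = NULL,
                       config = ranmod_config()) {
  aa <- .seq_to_vec(sequence)
  n <- length(aa)
  if (is.character(pairing) && length(pairing) == 1L)
    pairing <- .pattern_pairing_matrix(parse_connectivity(pairing))
  pairing <- .check_pairing(aa, pairing)
  cl <- parse_clues(clues, n)
  geom <- config$modip$geom
  cb_at <- sort(unique(as.vector(pairing)))

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  plan <- .torsion_plan(aa, cl, config$regions)
  models <- list()
  accepted_trials <- integer()
  n_clash <- n_dist <- n_grade <- 0L
  for (trial in seq_len(config$n_trials)) {
    tor <- .sample_torsions_core(plan)
    omega <- rep(180, n)
    bb <- .build_bb_fast(n, tor$phi, tor$psi, omega, cb_at, geom)
    if (!clash_filter(bb$CA, config$clash_min_ca)) {
      n_clash <- n_clash + 1L
      next
    }
    ev <- .eval_conn_core(bb$N, bb$CA, bb$CB, pairing, config)
    if (!ev$pass) {
      if (ev$dist_fail) n_dist <- n_dist + 1L
      else n_grade <- n_grade + 1L
      next
    }
    accepted_trials <- c(accepted_trials, trial)
    if (length(models) < config$max_models) {
      s <- build_backbone(aa, tor$phi, tor$psi, omega,
                          id = sprintf("ranmod_%06d", trial), geom = geom)
      for (k in seq_len(nrow(pairing))) {
        b <- ev$fixed[[k]]
        s$coords$SG[pairing[k, 1L], ] <- b$sg_i
        s$coords$SG[pairing[k, 2L], ] <- b$sg_j
      }
      s <- declare_native(s, pairing)
      torsions <- data.frame(
        aa = aa, phi = tor$phi, psi = tor$psi, omega = omega,
        region = plan$name[tor$box],
        phi_lo = plan$phi_lo[tor$box], phi_hi = plan$phi_hi[tor$box],
        psi_lo = plan$psi_lo[tor$box], psi_hi = plan$psi_hi[tor$box],
        stringsAsFactors = FALSE)
      models[[length(models) + 1L]] <-
        list(trial = trial, seed = config$seed, torsions = torsions,
             structure = s, bridges = .bridges_df(ev, pairing))
    }
  }
  out <- list(
    models = models,
    summary = list(
      n_trials = config$n_trials, seed = config$seed,
      n_accepted = length(accepted_trials),
      accepted_trials = accepted_trials,
      n_rejected_clash = n_clash,
      n_rejected_distance = n_dist,
      n_rejected_grade = n_grade,
      accept_grades = config$accept_grades))
  class(out) <- "ssf_ranmod"
  out
}

#' @export
print.ssf_ranmod <- function(x, ...) {
  s <- x$summary
  cat("RANMOD run: ", s$n_trials, " trials, seed ", s$seed, "\n",
      "  accepted: ", s$n_accepted,
      "  (clash ", s$n_rejected_clash,
      ", distance ", s$n_rejected_distance,
      ", grade ", s$n_rejected_grade, " rejected)\n", sep = "")
  for (m in x$models) {
    cat(sprintf("  trial %d: %s\n", m$trial,
                paste(sprintf("%d-%d %s", m$bridges$pos_i, m$bridges$pos_j,
                              m$bridges$grade), collapse = ", ")))
  }
  invisible(x)
}
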