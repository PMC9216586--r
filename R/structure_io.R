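# PDB-format structure handling: reading (via bio3d), writing, segment
# extraction and native disulphide detection.

#' Construct a ssf_structure
#'
#' Internal constructor for the package's residue-level structure container.
#' A \code{ssf_structure} is a list with elements:
#' \describe{
#'   \item{id}{structure identifier}
#'   \item{residues}{data.frame with one row per residue: \code{chain},
#'     \code{resno} (author number), \code{icode}, \code{idx} (1-based
#'     index within its chain), \code{aa} (one-letter code),
#'     \code{cb_source} ("observed", "reconstructed" or NA)}
#'   \item{coords}{list of n x 3 matrices \code{N}, \code{CA}, \code{C},
#'     \code{O}, \code{CB}, \code{SG}; rows of NA where an atom is absent}
#'   \item{native}{data.frame of declared disulphides with global residue
#'     row indices \code{i}, \code{j}}
#'   \item{source}{file path or provenance tag}
#' }
#'
#' @param id structure identifier.
#' @param residues residue data.frame (see above).
#' @param coords list of coordinate matrices (see above).
#' @param native data.frame with columns \code{i}, \code{j}.
#' @param source provenance string.
#' @return An object of class \code{ssf_structure}.
#' @keywords internal
#' @export
new_structure <- function(id, residues, coords,
                          native = data.frame(i = integer(), j = integer()),
                          source = NA_character_) {
  atoms <- c("N", "CA", "C", "O", "CB", "SG")
  stopifnot(is.data.frame(residues),
            all(c("chain", "resno", "icode", "idx", "aa", "cb_source")
                %in% names(residues)),
            all(atoms %in% names(coords)))
  n <- nrow(residues)
  for (a in atoms) {
    stopifnot(is.matrix(coords[[a]]), nrow(coords[[a]]) == n,
              ncol(coords[[a]]) == 3L)
  }
  for (ch in unique(residues$chain)) {
    idx <- residues$idx[residues$chain == ch]
    if (any(diff(idx) <= 0L)) stop("idx not strictly increasing in chain ", ch)
  }
  structure(list(id = id, residues = residues, coords = coords,
                 native = native, source = source),
            class = "ssf_structure")
}

#' @export
print.ssf_structure <- function(x, ...) {
  ch <- table(x$residues$chain)
  cat("ssf_structure", sQuote(x$id), "-", nrow(x$residues), "residues in",
      length(ch), "chain(s)\n")
  for (nm in names(ch)) cat("  chain", nm, ":", ch[[nm]], "residues\n")
  if (nrow(x$native))
    cat("  declared disulphides:", nrow(x$native), "\n")
  invisible(x)
}

.std_aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- stats::setNames(names(.std_aa3), unname(.std_aa3))

#' Read a PDB-format structure
#'
#' Parses ATOM records with \pkg{bio3d}, resolves alternate locations to
#' the highest-occupancy conformer (ties broken alphabetically, so 'A'
#' wins), selects one model of a multi-model (NMR) file, skips hetero and
#' non-standard residues with a warning, and records SSBOND declarations.
#'
#' @param file path to a PDB file.
#' @param model model number to keep for multi-model files (default 1, the
#'   first model of the ensemble).
#' @param id structure identifier; defaults to the file base name.
#' @return A \code{ssf_structure}; see [new_structure()] for the layout.
#'   SSBOND declarations are kept in attribute element \code{$ssbond} and
#'   folded into \code{$native} by [native_disulphides()].
#' @export
read_structure <- function(file, model = 1L, id = NULL) {
  if (!file.exists(file)) stop("no such file: ", file)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  p <- tryCatch(
    suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", file, ": ",
                             conditionMessage(e)))
  at <- p$atom
  if (is.null(at) || !nrow(at)) stop("no ATOM records in ", file)
  nmod <- nrow(p$xyz)
  if (model > nmod) stop("model ", model, " requested but file has ",
                         nmod, " model(s)")
  xyz <- matrix(p$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]

  keep <- at$type == "ATOM" & at$resid %in% names(.std_aa3)
  nonstd <- unique(at$resid[at$type == "ATOM" & !at$resid %in% names(.std_aa3)])
  if (length(nonstd))
    warning("skipping non-standard residue type(s): ",
            paste(nonstd, collapse = ", "))
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no standard amino-acid ATOM records in ", file)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- " "

  ## resolve altlocs: keep highest occupancy per atom site, tie -> first
  ## alphabetically ('A')
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]

  ## residue table, ordered by chain (file order) then author number+icode
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  chains <- unique(at$chain)
  rtab <- unique(data.frame(chain = at$chain, resno = at$resno,
                            icode = at$insert, key = rkey,
                            resid = at$resid, stringsAsFactors = FALSE))
  rtab <- rtab[order(match(rtab$chain, chains), rtab$resno, rtab$icode), ,
               drop = FALSE]
  n <- nrow(rtab)
  idx <- stats::ave(seq_len(n), rtab$chain, FUN = seq_along)
  coords <- lapply(c(N = "N", CA = "CA", C = "C", O = "O",
                     CB = "CB", SG = "SG"),
                   function(a) {
                     m <- matrix(NA_real_, n, 3L)
                     sub <- at[at$elety == a, , drop = FALSE]
                     pos <- match(paste(sub$chain, sub$resno, sub$insert,
                                        sep = "\r"), rtab$key)
                     ok <- !is.na(pos)
                     m[pos[ok], ] <- as.matrix(sub[ok, c("x", "y", "z")])
                     m
                   })
  aa <- unname(.std_aa3[rtab$resid])
  cb_source <- ifelse(aa == "G", NA_character_,
                      ifelse(is.finite(coords$CB[, 1L]), "observed",
                             NA_character_))
  miss_bb <- !is.finite(coords$N[, 1L]) | !is.finite(coords$CA[, 1L]) |
    !is.finite(coords$C[, 1L])
  if (any(miss_bb))
    warning(sum(miss_bb), " residue(s) with incomplete backbone flagged")
  residues <- data.frame(chain = rtab$chain, resno = rtab$resno,
                         icode = rtab$icode, idx = idx, aa = aa,
                         cb_source = cb_source, stringsAsFactors = FALSE)
  s <- new_structure(id = id, residues = residues, coords = coords,
                     source = file)
  s$ssbond <- .parse_ssbond(readLines(file, warn = FALSE))
  s$incomplete_backbone <- which(miss_bb)
  s
}

.parse_ssbond <- function(lines) {
  ss <- lines[startsWith(lines, "SSBOND")]
  if (!length(ss))
    return(data.frame(chain1 = character(), resno1 = integer(),
                      icode1 = character(), chain2 = character(),
                      resno2 = integer(), icode2 = character(),
                      stringsAsFactors = FALSE))
  ss <- format(ss, width = 40)
  data.frame(
    chain1 = trimws(substr(ss, 16, 16)),
    resno1 = as.integer(substr(ss, 18, 21)),
    icode1 = trimws(substr(ss, 22, 22)),
    chain2 = trimws(substr(ss, 30, 30)),
    resno2 = as.integer(substr(ss, 32, 35)),
    icode2 = trimws(substr(ss, 36, 36)),
    stringsAsFactors = FALSE)
}

.match_residue <- function(structure, chain, resno, icode = "") {
  r <- structure$residues
  chain[chain == ""] <- " "
  which(r$chain == chain & r$resno == resno & r$icode == icode)[1L]
}

#' Detect native disulphide bonds
#'
#' Returns the union of (a) SSBOND-declared pairs and (b) cysteine pairs
#' whose Sgamma-Sgamma distance is at most \code{sg_cutoff}, deduplicated
#' and ordered.  SSBOND records naming a non-cysteine residue are dropped
#' with a warning.  The detected pairs are also stored in the returned
#' structure's \code{$native} when called via [declare_native()].
#'
#' @param structure a \code{ssf_structure}.
#' @param sg_cutoff Sgamma-Sgamma distance cutoff in Angstrom (default
#'   2.5: covalent S-S of about 2.04 plus coordinate-error margin).
#' @return data.frame with one row per bond: global residue row indices
#'   \code{i}, \code{j} (ordered by chain then index), chains, author
#'   numbers, \code{d_ss} (NA when no Sgamma coordinates) and
#'   \code{evidence} ("ssbond", "geometry" or "both").
#' @export
native_disulphides <- function(structure, sg_cutoff = 2.5) {
  r <- structure$residues
  pairs <- list()
  ev <- character()
  if (nrow(structure$native)) {
    for (k in seq_len(nrow(structure$native))) {
      pairs[[length(pairs) + 1L]] <- sort(c(structure$native$i[k],
                                            structure$native$j[k]))
      ev <- c(ev, "ssbond")
    }
  }
  ssb <- structure$ssbond
  if (!is.null(ssb) && nrow(ssb)) {
    for (k in seq_len(nrow(ssb))) {
      i <- .match_residue(structure, ssb$chain1[k], ssb$resno1[k], ssb$icode1[k])
      j <- .match_residue(structure, ssb$chain2[k], ssb$resno2[k], ssb$icode2[k])
      if (is.na(i) || is.na(j)) {
        warning("SSBOND names an unknown residue; record dropped")
        next
      }
      if (r$aa[i] != "C" || r$aa[j] != "C") {
        warning("SSBOND names a non-cysteine residue (",
                r$aa[i], r$resno[i], "-", r$aa[j], r$resno[j],
                "); record dropped")
        next
      }
      pairs[[length(pairs) + 1L]] <- sort(c(i, j))
      ev <- c(ev, "ssbond")
    }
  }
  cys <- which(r$aa == "C" & is.finite(structure$coords$SG[, 1L]))
  if (length(cys) > 1L) {
    sg <- structure$coords$SG[cys, , drop = FALSE]
    d <- as.matrix(stats::dist(sg))
    hit <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
    for (k in seq_len(nrow(hit))) {
      pairs[[length(pairs) + 1L]] <- sort(c(cys[hit[k, 1L]], cys[hit[k, 2L]]))
      ev <- c(ev, "geometry")
    }
  }
  if (!length(pairs))
    return(data.frame(i = integer(), j = integer(), chain_i = character(),
                      resno_i = integer(), chain_j = character(),
                      resno_j = integer(), d_ss = numeric(),
                      evidence = character(), stringsAsFactors = FALSE))
  m <- do.call(rbind, pairs)
  key <- paste(m[, 1L], m[, 2L])
  evidence <- vapply(split(ev, key)[unique(key)], function(e) {
    if (all(e == "ssbond")) "ssbond"
    else if (all(e == "geometry")) "geometry" else "both"
  }, character(1L))
  m <- m[!duplicated(key), , drop = FALSE]
  sgc <- structure$coords$SG
  d_ss <- vapply(seq_len(nrow(m)), function(k) {
    a <- sgc[m[k, 1L], ]; b <- sgc[m[k, 2L], ]
    if (all(is.finite(c(a, b)))) sqrt(sum((a - b)^2)) else NA_real_
  }, numeric(1L))
  out <- data.frame(i = m[, 1L], j = m[, 2L],
                    chain_i = r$chain[m[, 1L]], resno_i = r$resno[m[, 1L]],
                    chain_j = r$chain[m[, 2L]], resno_j = r$resno[m[, 2L]],
                    d_ss = d_ss, evidence = unname(evidence),
                    stringsAsFactors = FALSE)
  out[order(out$chain_i, out$i, out$chain_j, out$j), , drop = FALSE]
}

#' Declare disulphide bonds on a structure
#'
#' Stores residue pairs in \code{$native} so that [write_model()] emits
#' SSBOND records for them.  Both members must be cysteine.
#'
#' @param structure a \code{ssf_structure}.
#' @param pairs data.frame with columns \code{i}, \code{j} (global residue
#'   row indices) or a 2-column matrix.
#' @return The structure with \code{$native} set.
#' @export
declare_native <- function(structure, pairs) {
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("i", "j")
  aa <- structure$residues$aa
  if (nrow(pairs) && !all(aa[pairs$i] == "C" & aa[pairs$j] == "C"))
    stop("declared disulphide joins a non-cysteine residue")
  if (any(pairs$i == pairs$j)) stop("self-paired residue in disulphide list")
  structure$native <- pairs
  structure
}

.fmt_atom <- function(serial, name, resid3, chain, resno, icode, xyz,
                      occ = 1, b = 0) {
  elem <- substr(name, 1L, 1L)
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resid3, chain, resno, icode,
          xyz[1L], xyz[2L], xyz[3L], occ, b, elem)
}

#' Write a structure as PDB-format text
#'
#' Emits SSBOND records for declared disulphides followed by ATOM records
#' (N, CA, C, O, CB, and optionally SG) with 1-based serials, preserving
#' chain identifiers and author numbering, with TER after each chain.
#'
#' @param structure a \code{ssf_structure}.
#' @param file optional path; when given the text is also written there.
#' @param include_sg include SG atoms where present (default TRUE).
#' @return The PDB text as a character vector of lines, invisibly when
#'   \code{file} is given.
#' @export
write_model <- function(structure, file = NULL, include_sg = TRUE) {
  r <- structure$residues
  co <- structure$coords
  lines <- character()
  if (nrow(structure$native)) {
    for (k in seq_len(nrow(structure$native))) {
      i <- structure$native$i[k]; j <- structure$native$j[k]
      lines <- c(lines, sprintf(
        "SSBOND %3d CYS %1s %4d%1s   CYS %1s %4d%1s",
        k, r$chain[i], r$resno[i], ifelse(r$icode[i] == "", " ", r$icode[i]),
        r$chain[j], r$resno[j], ifelse(r$icode[j] == "", " ", r$icode[j])))
    }
  }
  serial <- 0L
  atoms <- c("N", "CA", "C", "O", "CB", if (include_sg) "SG")
  for (ch in unique(r$chain)) {
    for (i in which(r$chain == ch)) {
      resid3 <- .aa1to3[[r$aa[i]]]
      for (a in atoms) {
        xyz <- co[[a]][i, ]
        if (!all(is.finite(xyz))) next
        serial <- serial + 1L
        lines <- c(lines, .fmt_atom(serial, a, resid3, ch, r$resno[i],
                                    ifelse(r$icode[i] == "", " ", r$icode[i]),
                                    xyz))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Extract a contiguous residue segment
#'
#' Slices residues \code{start..end} (1-based chain indices, inclusive)
#' of one chain.  Declared disulphides fully inside the slice are kept;
#' bonds cut by the slice are dropped with a warning.
#'
#' @param structure a \code{ssf_structure}.
#' @param chain chain identifier.
#' @param start,end first and last chain index to keep (inclusive).
#' @return A \code{ssf_structure} for the segment.
#' @export
extract_segment <- function(structure, chain, start, end) {
  r <- structure$residues
  sel <- which(r$chain == chain)
  if (!length(sel)) stop("no such chain: ", chain)
  if (start > end) stop("start must be <= end")
  if (start < 1L || end > length(sel)) stop("segment out of range for chain ",
                                            chain, " (", length(sel),
                                            " residues)")
  keep <- sel[start:end]
  map <- match(seq_len(nrow(r)), keep)   # old global index -> new index
  nat <- structure$native
  if (nrow(nat)) {
    inside <- !is.na(map[nat$i]) & !is.na(map[nat$j])
    cut <- xor(!is.na(map[nat$i]), !is.na(map[nat$j]))
    if (any(cut)) warning(sum(cut), " disulphide(s) cut by the segment ",
                          "boundary dropped")
    nat <- data.frame(i = map[nat$i[inside]], j = map[nat$j[inside]])
  }
  res <- r[keep, , drop = FALSE]
  res$idx <- seq_len(nrow(res))
  rownames(res) <- NULL
  new_structure(id = paste0(structure$id, "_", chain, start, "-", end),
                residues = res,
                coords = lapply(structure$coords,
                                function(m) m[keep, , drop = FALSE]),
                native = nat, source = structure$source)
}

#' Amino-acid sequence of a chain
#'
#' @param structure a \code{ssf_structure}.
#' @param chain chain identifier; default the first chain.
#' @return One-letter sequence string.
#' @export
structure_sequence <- function(structure, chain = NULL) {
  r <- structure$residues
  if (is.null(chain)) chain <- r$chain[1L]
  paste(r$aa[r$chain == chain], collapse = "")
}

#' Fill in missing Cbeta atoms
#'
#' Reconstructs an ideal Cbeta (see [reconstruct_cbeta()]) for every
#' residue without an observed one (including glycine, which is treated
#' as a cysteine-mutation target), provided N, CA and C are present.
#'
#' @param structure a \code{ssf_structure}.
#' @param geom geometry constants.
#' @return The structure with \code{coords$CB} completed and
#'   \code{cb_source} updated.
#' @export
ensure_cbeta <- function(structure, geom = ideal_geometry()) {
  co <- structure$coords
  need <- which(!is.finite(co$CB[, 1L]))
  for (i in need) {
    n <- co$N[i, ]; ca <- co$CA[i, ]; c_ <- co$C[i, ]
    if (!all(is.finite(c(n, ca, c_)))) next
    structure$coords$CB[i, ] <- reconstruct_cbeta(n, ca, c_, geom)
    structure$residues$cb_source[i] <- "reconstructed"
  }
  structure
}

#' Apply a rigid-body transform to a structure
#'
#' @param structure a \code{ssf_structure}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation numeric 3-vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  structure$coords <- lapply(structure$coords, function(m) {
    out <- m %*% t(rotation)
    out[, 1L] <- out[, 1L] + translation[1L]
    out[, 2L] <- out[, 2L] + translation[2L]
    out[, 3L] <- out[, 3L] + translation[3L]
    out
  })
  structure
}

#' Read sequences from a FASTA file
#'
#' @param file path to a FASTA file.
#' @return Named character vector of one-letter sequences (gaps removed).
#' @export
read_fasta_sequences <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  ali <- bio3d::read.fasta(file)
  out <- apply(ali$ali, 1L, function(x) paste(x[x != "-"], collapse = ""))
  stats::setNames(toupper(out), ali$id)
}
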