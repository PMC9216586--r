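# Disulphide-loop database: connectivity-pattern parsing, loop topology
# classification, segment indexing and multi-disulphide pattern search
# with optional sequence-identity ranking.

#' Parse a disulphide connectivity pattern
#'
#' Accepts strings like \code{"C4-C19, C9-C21, C14-C26"} (case and space
#' tolerant; "Cys" is accepted as a synonym for "C").
#'
#' @param text pattern string.
#' @return A list of class \code{ssf_pattern}:
#'   \code{positions} (sorted cysteine positions, 1-based),
#'   \code{pairing} (matrix of position pairs, each row ordered),
#'   \code{offsets} (canonical offsets: positions minus the first),
#'   \code{topology} (see [classify_topology()]).
#' @export
#' @examples
#' p <- parse_connectivity("C4-C19, C9-C21, C14-C26")
#' p$offsets    # 0 5 10 15 17 22
#' p$topology
parse_connectivity <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  t <- gsub("[[:space:]]", "", text)
  t <- gsub("(?i)cys", "C", t, perl = TRUE)
  parts <- strsplit(t, "[,;]")[[1L]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty connectivity pattern")
  m <- regmatches(parts, regexec("^[Cc]([0-9]+)-[Cc]([0-9]+)$", parts))
  if (any(lengths(m) != 3L))
    stop("malformed connectivity pattern near: ",
         parts[which(lengths(m) != 3L)[1L]])
  a <- as.integer(vapply(m, `[`, "", 2L))
  b <- as.integer(vapply(m, `[`, "", 3L))
  if (any(a == b)) stop("self-paired cysteine (C", a[a == b][1L], "-C",
                        a[a == b][1L], ")")
  pairing <- cbind(pmin(a, b), pmax(a, b))
  pos <- as.vector(pairing)
  if (anyDuplicated(pos))
    stop("cysteine position ", pos[duplicated(pos)][1L],
         " appears in more than one pair")
  positions <- sort(pos)
  out <- list(positions = positions,
              pairing = pairing[order(pairing[, 1L]), , drop = FALSE],
              offsets = positions - positions[1L])
  out$topology <- classify_topology(out$pairing)
  class(out) <- "ssf_pattern"
  out
}

#' @export
print.ssf_pattern <- function(x, ...) {
  cat("ssf_pattern:",
      paste(sprintf("C%d-C%d", x$pairing[, 1L], x$pairing[, 2L]),
            collapse = ", "),
      sprintf("[%s]\n", x$topology))
  invisible(x)
}

.pattern_pairing_matrix <- function(pattern) pattern$pairing

#' Classify the loop topology of a disulphide pairing
#'
#' For every pair of bridges (a, b) and (c, d) with a < b, c < d, a < c
#' the loops are \emph{independent} if b < c (disjoint intervals),
#' \emph{nested} if d < b (one inside the other) and \emph{interlocked}
#' if c < b < d (intervals interleave -- the cystine-knot hallmark).
#' The overall label is the common relation if all bridge pairs agree,
#' otherwise \code{mixed}; a single bridge is \code{independent}.
#'
#' @param pairing 2-column matrix/data.frame of cysteine position pairs,
#'   or a \code{ssf_pattern}.
#' @return One of "nested", "interlocked", "independent", "mixed".
#' @export
#' @examples
#' classify_topology(rbind(c(11, 32), c(15, 28)))  # nested
#' classify_topology(rbind(c(2, 10), c(4, 11)))    # interlocked
classify_topology <- function(pairing) {
  if (inherits(pairing, "ssf_pattern")) pairing <- pairing$pairing
  pairing <- as.matrix(as.data.frame(pairing))[, 1:2, drop = FALSE]
  pairing <- t(apply(pairing, 1L, sort))
  nb <- nrow(pairing)
  if (nb < 1L) stop("at least one bridge is required")
  if (nb == 1L) return("independent")
  rel <- character()
  for (u in seq_len(nb - 1L)) {
    for (v in (u + 1L):nb) {
      p <- pairing[u, ]; q <- pairing[v, ]
      if (p[1L] > q[1L]) { tmp <- p; p <- q; q <- tmp }
      a <- p[1L]; b <- p[2L]; c_ <- q[1L]; d <- q[2L]
      rel <- c(rel, if (b < c_) "independent"
                    else if (d < b) "nested"
                    else "interlocked")
    }
  }
  if (length(unique(rel)) == 1L) rel[1L] else "mixed"
}

#' Build a searchable disulphide-loop database
#'
#' Indexes every disulphide-bonded segment of the input structures: native
#' bridges are always recorded; modelled bridges are found by running the
#' site-modelling scan ([modip()]) and kept when their grade is in
#' \code{grades}.  Each bridge yields one loop record spanning the two
#' cysteine positions inclusive.  Only intra-chain segments are indexed;
#' inter-chain bridges are recorded separately and are not searchable as
#' loops.
#'
#' @param structures list of \code{ssf_structure} objects.
#' @param grades grade filter for modelled bridges (default A, B, C).
#' @param run_modip also index modelled (engineerable) bridges
#'   (default TRUE).
#' @param config a [modip_config()].
#' @return A list of class \code{ssf_loopdb} with element \code{records},
#'   a data.frame: \code{source_id}, \code{chain}, \code{start_idx},
#'   \code{end_idx} (1-based chain indices), \code{start_resno},
#'   \code{end_resno}, \code{loop_size} (inclusive span), \code{sequence},
#'   \code{grade} (NA for ungradeable natives), \code{provenance}, and
#'   \code{interchain}, a data.frame of inter-chain bridges.
#' @export
build_loop_database <- function(structures, grades = c("A", "B", "C"),
                                run_modip = TRUE, config = modip_config()) {
  if (inherits(structures, "ssf_structure")) structures <- list(structures)
  if (!length(structures)) stop("at least one structure is required")
  recs <- list()
  inter <- list()
  for (s in structures) {
    ok <- tryCatch({
      tab <- if (run_modip) {
        rep <- modip(s, config)
        rbind(rep$native,
              rep$modelled[rep$modelled$grade %in% grades, , drop = FALSE])
      } else {
        .native_table(s, config)
      }
      r <- s$residues
      for (k in seq_len(nrow(tab))) {
        b <- tab[k, ]
        if (b$chain_i != b$chain_j) {
          inter[[length(inter) + 1L]] <-
            cbind(source_id = s$id, b, stringsAsFactors = FALSE)
          next
        }
        ii <- r$idx[b$i]; jj <- r$idx[b$j]
        seg <- r$aa[r$chain == b$chain_i][ii:jj]
        recs[[length(recs) + 1L]] <- data.frame(
          source_id = s$id, chain = b$chain_i,
          start_idx = ii, end_idx = jj,
          start_resno = b$resno_i, end_resno = b$resno_j,
          loop_size = jj - ii + 1L,
          sequence = paste(seg, collapse = ""),
          d_ss = b$d_ss, grade = b$grade, provenance = b$provenance,
          stringsAsFactors = FALSE)
      }
      TRUE
    }, error = function(e) {
      warning("skipping structure ", s$id, ": ", conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  empty <- data.frame(source_id = character(), chain = character(),
                      start_idx = integer(), end_idx = integer(),
                      start_resno = integer(), end_resno = integer(),
                      loop_size = integer(), sequence = character(),
                      d_ss = numeric(), grade = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  records <- if (length(recs)) do.call(rbind, recs) else empty
  records <- records[order(records$source_id, records$chain,
                           records$start_idx, records$end_idx), ,
                     drop = FALSE]
  rownames(records) <- NULL
  ## chain sequences, for window extraction at search time
  seqs <- list()
  for (s in structures)
    for (ch in unique(s$residues$chain))
      seqs[[paste(s$id, ch, sep = "\r")]] <- structure_sequence(s, ch)
  out <- list(records = records,
              interchain = if (length(inter)) do.call(rbind, inter)
                           else NULL,
              chain_seqs = seqs)
  class(out) <- "ssf_loopdb"
  out
}

#' @export
print.ssf_loopdb <- function(x, ...) {
  cat("ssf_loopdb:", nrow(x$records), "loop records from",
      length(unique(x$records$source_id)), "structure(s)\n")
  if (nrow(x$records)) {
    tb <- table(x$records$provenance)
    cat(" ", paste(names(tb), tb, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Persist / load a loop database as TSV
#'
#' Two tab-separated tables are written under \code{dir}:
#' \code{records.tsv} (the loop records) and \code{chains.tsv}
#' (per-chain sequences).
#'
#' @param db a \code{ssf_loopdb}.
#' @param dir directory to write to (created if needed).
#' @return \code{write_loop_database}: \code{dir}, invisibly.
#' @export
write_loop_database <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(db$records, file.path(dir, "records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ch <- do.call(rbind, lapply(names(db$chain_seqs), function(k) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(source_id = p[1L], chain = p[2L],
               sequence = db$chain_seqs[[k]], stringsAsFactors = FALSE)
  }))
  utils::write.table(ch, file.path(dir, "chains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_loop_database
#' @return \code{read_loop_database}: the reloaded \code{ssf_loopdb}.
#' @export
read_loop_database <- function(dir) {
  records <- utils::read.table(
    file.path(dir, "records.tsv"), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE,
    colClasses = c(source_id = "character", chain = "character",
                   start_idx = "integer", end_idx = "integer",
                   start_resno = "integer", end_resno = "integer",
                   loop_size = "integer", sequence = "character",
                   d_ss = "numeric", grade = "character",
                   provenance = "character"))
  ch <- utils::read.table(file.path(dir, "chains.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  seqs <- stats::setNames(as.list(ch$sequence),
                          paste(ch$source_id, ch$chain, sep = "\r"))
  out <- list(records = records, interchain = NULL, chain_seqs = seqs)
  class(out) <- "ssf_loopdb"
  out
}

#' Position-wise percent identity of two equal-length sequences
#'
#' @param a,b one-letter sequence strings of equal length.
#' @return 100 * matches / length.
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  if (!nchar(a)) stop("empty sequences")
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  100 * sum(av == bv) / length(av)
}

.grade_rank <- c(native = 0, A = 1, B = 2, C = 3, D = 4)

#' Search a loop database by connectivity pattern
#'
#' A window of a chain matches when, for every pair of the query pattern,
#' a recorded bridge (within the grade filter) sits at exactly the
#' corresponding offsets from the window origin (optional per-position
#' tolerance \code{tol} relaxes the spacing by up to that many residues).
#' When a query sequence is given, ungapped positional identity over the
#' matched window is reported.  Hits are ranked by best bridge grade
#' class (native < A < B < C < D), then identity (descending), then
#' source id.
#'
#' @param db a \code{ssf_loopdb}.
#' @param pattern a \code{ssf_pattern} from [parse_connectivity()] or a
#'   pattern string.
#' @param query_sequence optional full query sequence (1-based positions
#'   as in the pattern).  If its cysteine positions do not match the
#'   pattern, a warning is given and the pattern is taken as
#'   authoritative.
#' @param grades grade filter (default native plus A, B, C).
#' @param tol per-position spacing tolerance in residues (default 0:
#'   exact spacing).
#' @return data.frame of hits: \code{source_id}, \code{chain},
#'   \code{window_start_idx}, \code{window_end_idx},
#'   \code{window_start_resno}, \code{sequence} (the window),
#'   \code{grades} (per-bridge, comma-separated in query-pair order),
#'   \code{best_grade}, \code{identity_pct}; sorted by rank.
#' @export
search_loops <- function(db, pattern, query_sequence = NULL,
                         grades = c("native", "A", "B", "C"), tol = 0L) {
  if (is.character(pattern)) pattern <- parse_connectivity(pattern)
  stopifnot(inherits(pattern, "ssf_pattern"))
  qpos <- pattern$positions
  qwin_len <- qpos[length(qpos)] - qpos[1L] + 1L
  if (!is.null(query_sequence)) {
    qv <- .seq_to_vec(query_sequence)
    cys <- which(qv == "C")
    if (!identical(cys, as.integer(qpos)))
      warning("cysteine positions of the query sequence (",
              paste(cys, collapse = ","),
              ") do not match the pattern (",
              paste(qpos, collapse = ","),
              "); the pattern is taken as authoritative")
  }
  rec <- db$records
  gsel <- ifelse(rec$provenance == "native", "native", rec$grade)
  rec <- rec[gsel %in% grades & !is.na(gsel) |
               (rec$provenance == "native" & "native" %in% grades), ,
             drop = FALSE]
  hits <- list()
  poff <- pattern$pairing - qpos[1L]   # pair offsets relative to window start
  for (grp in split(rec, paste(rec$source_id, rec$chain, sep = "\r"))) {
    if (!nrow(grp)) next
    chain_seq <- db$chain_seqs[[paste(grp$source_id[1L], grp$chain[1L],
                                      sep = "\r")]]
    nch <- if (is.null(chain_seq)) max(grp$end_idx) else nchar(chain_seq)
    ## candidate anchors from bridges matching the first query pair
    anchors <- unique(unlist(lapply(seq_len(nrow(grp)), function(k) {
      s <- grp$start_idx[k] - poff[1L, 1L]
      d <- (s - tol):(s + tol)
      d
    })))
    anchors <- anchors[anchors >= 1L & anchors + qwin_len - 1L <= nch]
    for (s in sort(anchors)) {
      gr <- character(nrow(poff))
      ok <- TRUE
      for (k in seq_len(nrow(poff))) {
        a <- s + poff[k, 1L]; b <- s + poff[k, 2L]
        match_k <- which(abs(grp$start_idx - a) <= tol &
                           abs(grp$end_idx - b) <= tol)
        if (!length(match_k)) { ok <- FALSE; break }
        gk <- ifelse(grp$provenance[match_k] == "native", "native",
                     grp$grade[match_k])
        gr[k] <- gk[which.min(.grade_rank[gk])]
      }
      if (!ok) next
      win_seq <- if (!is.null(chain_seq))
        substr(chain_seq, s, s + qwin_len - 1L) else NA_character_
      idp <- NA_real_
      if (!is.null(query_sequence) && !is.na(win_seq)) {
        qs <- paste(.seq_to_vec(query_sequence), collapse = "")
        if (nchar(qs) >= qpos[1L] + qwin_len - 1L)
          idp <- percent_identity(
            substr(qs, qpos[1L], qpos[1L] + qwin_len - 1L), win_seq)
      }
      hits[[length(hits) + 1L]] <- data.frame(
        source_id = grp$source_id[1L], chain = grp$chain[1L],
        window_start_idx = s, window_end_idx = s + qwin_len - 1L,
        window_start_resno = grp$start_resno[
          which(grp$start_idx == s + poff[1L, 1L])[1L]],
        sequence = win_seq,
        grades = paste(gr, collapse = ","),
        best_grade = gr[which.min(.grade_rank[gr])],
        identity_pct = idp, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(source_id = character(), chain = character(),
                      window_start_idx = integer(),
                      window_end_idx = integer(),
                      window_start_resno = integer(),
                      sequence = character(), grades = character(),
                      best_grade = character(), identity_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[!duplicated(paste(out$source_id, out$chain,
                               out$window_start_idx)), , drop = FALSE]
  out <- out[order(.grade_rank[out$best_grade],
                   ifelse(is.na(out$identity_pct), 1,
                          -out$identity_pct),
                   out$source_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
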