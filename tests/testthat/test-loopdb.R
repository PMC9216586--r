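test_that("connectivity patterns parse with canonical offsets", {
  p <- parse_connectivity("C4-C19, C9-C21, C14-C26")
  expect_equal(p$offsets, c(0, 5, 10, 15, 17, 22))
  expect_equal(p$positions, c(4, 9, 14, 19, 21, 26))
  expect_equal(nrow(p$pairing), 3)
  p2 <- parse_connectivity("cys2-cys10,CYS4-CYS11")
  expect_equal(p2$offsets, c(0, 2, 8, 9))
  expect_equal(p2$pairing, rbind(c(2L, 10L), c(4L, 11L)), ignore_attr = TRUE)
  # pair order inside the string does not matter
  p3 <- parse_connectivity("C10-C2, C4-C11")
  expect_equal(p3$offsets, p2$offsets)
  expect_error(parse_connectivity("C1-C1"), "self-paired")
  expect_error(parse_connectivity("C2-C10, C10-C12"), "more than one pair")
  expect_error(parse_connectivity("C2-C10, C4"), "malformed")
  expect_error(parse_connectivity(""), "empty")
})

test_that("topology labels match the canonical arrangements", {
  expect_equal(classify_topology(rbind(c(11, 32), c(15, 28))), "nested")
  expect_equal(classify_topology(rbind(c(2, 10), c(4, 11))), "interlocked")
  expect_equal(classify_topology(rbind(c(2, 5), c(8, 12))), "independent")
  expect_equal(classify_topology(rbind(c(2, 5))), "independent")
  expect_equal(classify_topology(rbind(c(2, 20), c(4, 10), c(12, 18))),
               "mixed")    # nested twice + independent once
  # the three-bridge cyclotide-style pattern: uniform pairwise relation?
  p <- parse_connectivity("C4-C19, C9-C21, C14-C26")
  expect_equal(p$topology, oracle_topology(p$pairing))
  expect_equal(p$topology, "interlocked")
})

test_that("topology agrees with the interval-relation oracle", {
  # exhaustive over all two-bridge patterns on positions <= 16
  combs <- utils::combn(16L, 4L)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  mine <- character(0); ref <- character(0)
  for (k in seq_len(ncol(combs))) {
    pos <- combs[, k]
    for (pg in pairings) {
      pairing <- rbind(sort(pos[pg[1:2]]), sort(pos[pg[3:4]]))
      mine <- c(mine, classify_topology(pairing))
      ref <- c(ref, oracle_topology(pairing))
    }
  }
  expect_identical(mine, ref)
  expect_length(mine, 3 * choose(16, 4))
  expect_setequal(unique(mine), c("independent", "nested", "interlocked"))
  # randomised three- and four-bridge patterns over positions <= 30
  withr::with_seed(17, {
    res <- vapply(1:400, function(k) {
      nb <- sample(3:4, 1)
      pos <- sort(sample(30L, 2L * nb))
      perm <- matrix(sample(seq_along(pos)), ncol = 2)
      pairing <- t(apply(perm, 1, function(r) sort(pos[r])))
      identical(classify_topology(pairing), oracle_topology(pairing))
    }, logical(1))
    expect_true(all(res))
  })
})

test_that("percent identity matches brute-force counting", {
  expect_equal(percent_identity("ACDE", "ACDE"), 100)
  expect_equal(percent_identity("ACDE", "ACDF"), 75)
  expect_error(percent_identity("ACD", "AC"), "length")
  withr::with_seed(23, {
    alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (k in 1:1000) {
      n <- sample(5:40, 1)
      a <- paste(sample(alpha, n, replace = TRUE), collapse = "")
      b <- paste(sample(alpha, n, replace = TRUE), collapse = "")
      expect_equal(percent_identity(a, b), oracle_identity(a, b))
    }
  })
})

test_that("database build records one loop per bridge with inclusive size", {
  toy <- make_toy_database(7)
  db <- build_loop_database(toy$structures, run_modip = FALSE)
  # 2 + 2 + 3 + 2 + 2 + 3 planted bridges
  expect_equal(nrow(db$records), 14)
  expect_true(all(db$records$provenance == "native"))
  b <- db$records[db$records$source_id == "toy_nested" &
                    db$records$start_idx == 11, ]
  expect_equal(b$end_idx, 32)
  expect_equal(b$loop_size, 22)
  expect_equal(nchar(b$sequence), 22)
  expect_true(startsWith(b$sequence, "C") && endsWith(b$sequence, "C"))
  # grade-filter monotonicity on a structure with modelled sites
  s <- random_coil(30, seed = 5)
  dbA <- build_loop_database(list(s), grades = "A")
  dbAll <- build_loop_database(list(s), grades = c("A", "B", "C", "D"))
  expect_lte(nrow(dbA$records), nrow(dbAll$records))
  expect_true(all(dbAll$records$grade[dbAll$records$provenance ==
                                        "modelled"] %in%
                    c("A", "B", "C", "D")))
})

test_that("pattern search finds planted hits exactly", {
  toy <- make_toy_database(7)
  db <- build_loop_database(toy$structures, run_modip = FALSE)
  for (k in seq_len(nrow(toy$truth))) {
    hits <- search_loops(db, toy$truth$pattern[k])
    expect_equal(nrow(hits), 1)
    expect_equal(hits$source_id, toy$truth$source_id[k])
    expect_equal(hits$window_start_idx, toy$truth$anchor[k])
    # hit invariant: re-measured offsets equal the query offsets
    p <- parse_connectivity(toy$truth$pattern[k])
    seg <- hits$sequence
    expect_equal(which(strsplit(seg, "")[[1]] == "C") - 1,
                 p$offsets)
  }
  # spacing absent from the database (including decoys): no hits
  expect_equal(nrow(search_loops(db, "C2-C10, C5-C11")), 0)
  expect_equal(nrow(search_loops(db, "C11-C32, C15-C29")), 0)
  expect_equal(nrow(search_loops(db, "C4-C19, C9-C21, C14-C27")), 0)
})

test_that("search identity ranking and sequence handling work", {
  toy <- make_toy_database(7)
  db <- build_loop_database(toy$structures, run_modip = FALSE)
  qseq <- structure_sequence(toy$structures$toy_threebridge)
  hits <- search_loops(db, "C4-C19, C9-C21, C14-C26", query_sequence = qseq)
  expect_equal(hits$identity_pct, 100)
  # a query sequence with mismatched cysteines warns; pattern wins
  expect_warning(
    h2 <- search_loops(db, "C4-C19, C9-C21, C14-C26",
                       query_sequence = strrep("A", 30)),
    "authoritative")
  expect_equal(nrow(h2), 1)
  # search is invariant to record insertion order
  db_rev <- db
  db_rev$records <- db$records[rev(seq_len(nrow(db$records))), ]
  h3 <- search_loops(db_rev, "C2-C10, C4-C11")
  h4 <- search_loops(db, "C2-C10, C4-C11")
  expect_equal(h3, h4)
  # empty database
  empty_db <- db; empty_db$records <- db$records[0, ]
  expect_equal(nrow(search_loops(empty_db, "C2-C10, C4-C11")), 0)
})

test_that("database persists and reloads without changing search results", {
  toy <- make_toy_database(7)
  db <- build_loop_database(toy$structures, run_modip = FALSE)
  dir <- withr::local_tempdir()
  write_loop_database(db, dir)
  db2 <- read_loop_database(dir)
  expect_equal(db2$records, db$records)
  for (k in seq_len(nrow(toy$truth))) {
    expect_equal(search_loops(db2, toy$truth$pattern[k]),
                 search_loops(db, toy$truth$pattern[k]))
  }
})

test_that("search tolerance admits near-matching spacings", {
  toy <- make_toy_database(7)
  db <- build_loop_database(toy$structures, run_modip = FALSE)
  # decoy_nested carries (11,31),(15,28): one offset off the nested query
  h0 <- search_loops(db, "C11-C32, C15-C28", tol = 0)
  expect_equal(nrow(h0), 1)
  h1 <- search_loops(db, "C11-C32, C15-C28", tol = 1)
  expect_gte(nrow(h1), 2)
  expect_true("decoy_nested" %in% h1$source_id)
})
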