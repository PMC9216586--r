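write_tmp_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read/write round trip preserves residues and coordinates", {
  fx <- make_disulphide_fixture(seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(fx, f)
  s <- read_structure(f)
  expect_equal(nrow(s$residues), nrow(fx$residues))
  expect_equal(s$residues$aa, fx$residues$aa)
  expect_equal(s$residues$chain, fx$residues$chain)
  for (a in c("N", "CA", "C", "O", "CB", "SG"))
    expect_equal(s$coords[[a]], fx$coords[[a]], tolerance = 1e-3,
                 ignore_attr = TRUE)
  # SSBOND declared on write is recovered as a native bond on read
  nb <- native_disulphides(s)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$d_ss, 2.04, tolerance = 1e-3)
  # second round trip is exact (PDB precision already applied)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_model(s, f2)
  s2 <- read_structure(f2)
  expect_equal(s2$coords, s$coords)
})

test_that("multi-model files yield the selected model only", {
  res <- function(x) sprintf(
    "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    1:4, c("N", "CA", "C", "O"),
    rep(1, 4), x + c(0, 1.458, 2.009, 2.4), c(0, 0, 1.42, 2.4), rep(0, 4),
    c("N", "C", "C", "O"))
  f <- write_tmp_pdb(c("MODEL        1", res(0), "ENDMDL",
                       "MODEL        2", res(50), "ENDMDL", "END"))
  s1 <- read_structure(f)                 # default: first model
  expect_equal(nrow(s1$residues), 1)
  expect_equal(s1$coords$N[1, 1], 0)
  s2 <- read_structure(f, model = 2)
  expect_equal(s2$coords$N[1, 1], 50)
  expect_error(read_structure(f, model = 3), "2 model")
})

test_that("altlocs resolve to the highest occupancy, ties to A", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   9.000   9.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  s <- read_structure(write_tmp_pdb(lines))
  expect_equal(s$coords$CA[1, ], c(9, 9, 9))   # occupancy 0.6 wins
  lines[2] <- sub("0.40", "0.50", lines[2])
  lines[3] <- sub("0.60", "0.50", lines[3])
  s <- read_structure(write_tmp_pdb(lines))
  expect_equal(s$coords$CA[1, ], c(1.458, 0, 0))  # tie -> altloc A
})

test_that("parse failures and non-standard residues are handled", {
  expect_error(read_structure(write_tmp_pdb(c("REMARK nothing", "END"))))
  f <- write_tmp_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "HETATM    4 MG    MG A 201       5.000   5.000   5.000  1.00  0.00          MG",
    "ATOM      5  N   MSE A   2       3.300   2.000   0.000  1.00  0.00           N",
    "END"))
  expect_warning(s <- read_structure(f), "MSE")
  expect_equal(nrow(s$residues), 1)
})

test_that("native disulphide detection unions SSBOND and geometry", {
  fx <- make_disulphide_fixture(seed = 4)
  # geometric only: drop the declaration
  fx_geo <- fx; fx_geo$native <- data.frame(i = integer(), j = integer())
  nb <- native_disulphides(fx_geo)
  expect_equal(nrow(nb), 1)
  expect_equal(nb$evidence, "geometry")
  # declared + geometric -> single deduplicated pair
  nb2 <- native_disulphides(fx)
  expect_equal(nrow(nb2), 1)
  expect_equal(nb2$evidence, "both")
  expect_true(all(fx$residues$aa[c(nb2$i, nb2$j)] == "C"))
  # cutoff excludes long contacts
  expect_equal(nrow(native_disulphides(fx_geo, sg_cutoff = 1.0)), 0)
  # no cysteine -> empty
  expect_equal(nrow(native_disulphides(make_ideal_helix(8))), 0)
  # SSBOND naming a non-Cys residue is dropped with a warning
  f <- withr::local_tempfile(fileext = ".pdb")
  helix <- make_ideal_helix(6)
  txt <- write_model(helix)
  writeLines(c("SSBOND   1 CYS A    2    CYS A    5", txt), f)
  expect_warning(nb3 <- native_disulphides(read_structure(f)),
                 "non-cysteine")
  expect_equal(nrow(nb3), 0)
})

test_that("native detection is invariant to pair order in SSBOND", {
  fx <- make_disulphide_fixture(seed = 5)
  rev_native <- data.frame(i = fx$native$j, j = fx$native$i)
  fx_rev <- fx
  fx_rev$native <- data.frame(i = integer(), j = integer())
  fx_rev <- declare_native(fx_rev, rev_native)
  a <- native_disulphides(fx)[, c("i", "j")]
  b <- native_disulphides(fx_rev)[, c("i", "j")]
  expect_equal(a, b)
})

test_that("extract_segment slices inclusively and handles cut bridges", {
  s <- make_extended_chain(strrep("A", 30))
  seg <- extract_segment(s, "A", 4, 19)
  expect_equal(nrow(seg$residues), 16)
  expect_equal(seg$residues$resno, 4:19)
  expect_equal(seg$coords$CA, s$coords$CA[4:19, ], ignore_attr = TRUE)
  expect_error(extract_segment(s, "A", 10, 31), "out of range")
  expect_error(extract_segment(s, "B", 1, 5), "no such chain")
  # bridge inside the slice is kept, a cut bridge is dropped with warning
  toy <- make_toy_database(1)$structures$toy_interlocked    # bonds (2,10),(4,11)
  seg2 <- extract_segment(toy, "A", 1, 12)
  expect_equal(nrow(seg2$native), 2)
  expect_warning(seg3 <- extract_segment(toy, "A", 1, 10), "cut")
  expect_equal(nrow(seg3$native), 1)
})

test_that("write_model emits expected records", {
  s <- build_backbone("AGACA", -57, -47)
  expect_error(declare_native(s, data.frame(i = 2L, j = 4L)),
               "non-cysteine")   # position 2 is glycine
  s2 <- build_backbone("ACACA", -57, -47)
  s2$coords$SG[2, ] <- place_sgamma(s2$coords$N[2, ], s2$coords$CA[2, ],
                                    s2$coords$CB[2, ], -60)
  s2$coords$SG[4, ] <- place_sgamma(s2$coords$N[4, ], s2$coords$CA[4, ],
                                    s2$coords$CB[4, ], -60)
  s2 <- declare_native(s2, data.frame(i = 2L, j = 4L))
  txt <- write_model(s2)
  expect_equal(sum(startsWith(txt, "SSBOND")), 1)
  # 5 residues x (N, CA, C, O, CB) + 2 SG
  expect_equal(sum(startsWith(txt, "ATOM")), 27)
  txt_nosg <- write_model(s2, include_sg = FALSE)
  expect_equal(sum(startsWith(txt_nosg, "ATOM")), 25)
  # glycine gets no CB on output
  g <- build_backbone("AGA", -57, -47)
  expect_equal(sum(grepl(" CB ", write_model(g))), 2)
})
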