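# Two single-residue chains with controlled CA separation along the first
# residue's CA->CB direction.  The second residue is a rigid copy whose
# CB is flipped to point back along that axis; placing it on the +u side
# makes the CB vectors face each other (d_cb = ca_sep - 2 * 1.521),
# placing it on the -u side points them in opposite outward directions
# (d_cb = ca_sep + 2 * 1.521).
two_residue_structure <- function(ca_sep, face = c("toward", "apart")) {
  face <- match.arg(face)
  base <- build_backbone("A", -57, -47)
  co1 <- base$coords
  ca1 <- co1$CA[1, ]
  u <- (co1$CB[1, ] - ca1) / sqrt(sum((co1$CB[1, ] - ca1)^2))
  # 180-degree rotation about an axis perpendicular to u: flips CB
  ax <- c(-u[2], u[1], 0) / sqrt(u[1]^2 + u[2]^2)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
              3, 3)
  R <- diag(3) + 2 * (K %*% K)
  shift <- if (face == "toward") ca_sep * u else -ca_sep * u
  co2 <- lapply(co1, function(m) {
    out <- sweep(m, 2, ca1) %*% t(R)
    sweep(out, 2, ca1 + shift, "+")
  })
  residues <- data.frame(chain = c("A", "B"), resno = c(1L, 1L),
                         icode = "", idx = c(1L, 1L), aa = "A",
                         cb_source = "observed", stringsAsFactors = FALSE)
  co <- lapply(names(co1), function(a) rbind(co1[[a]], co2[[a]]))
  names(co) <- names(co1)
  new_structure("pairfx", residues, co)
}

test_that("candidate scan enforces both distance thresholds", {
  # CB vectors facing each other: d_cb < d_ca, so d_ca is the binding cut
  s_in <- two_residue_structure(6.4, "toward")
  cand <- scan_candidate_pairs(s_in)
  expect_equal(nrow(cand), 1)
  expect_lte(cand$d_ca, 6.5)
  expect_lte(cand$d_cb, 4.5)
  # same orientation but CA-CA over 6.5 -> excluded by the CA cutoff
  s_out <- two_residue_structure(6.6, "toward")
  d_cb_out <- sqrt(sum((s_out$coords$CB[1, ] - s_out$coords$CB[2, ])^2))
  expect_lt(d_cb_out, 4.5)   # CB criterion alone would admit it
  expect_equal(nrow(scan_candidate_pairs(s_out)), 0)
  # CA-CA inside but CB-CB outside -> excluded by the CB cutoff
  s_cb <- two_residue_structure(6.4, "apart")
  d_cb <- sqrt(sum((s_cb$coords$CB[1, ] - s_cb$coords$CB[2, ])^2))
  expect_gt(d_cb, 4.5)
  expect_equal(nrow(scan_candidate_pairs(s_cb)), 0)
})

test_that("scan applies the sequence-separation rule and excludes natives", {
  s <- random_coil(30, seed = 5)
  cand <- scan_candidate_pairs(s)
  expect_true(nrow(cand) > 0)
  # adjacent and near-adjacent pairs never appear
  expect_true(all(abs(cand$j - cand$i) >= 3))
  expect_true(all(cand$d_ca <= 6.5 & cand$d_cb <= 4.5))
  # an ideal helix has compatible CA but outward CB vectors: no sites
  expect_equal(nrow(scan_candidate_pairs(make_ideal_helix(12))), 0)
  # the bridged fixture pair is native, hence not in the modelled scan
  fx <- make_disulphide_fixture(seed = 6)
  nat <- native_disulphides(fx)
  cand_fx <- scan_candidate_pairs(fx)
  expect_false(any(cand_fx$i == nat$i[1] & cand_fx$j == nat$j[1]))
})

test_that("sulphur fixation recovers planted ideal bridges", {
  for (sd in c(1, 11, 23)) {
    fx <- make_disulphide_fixture(seed = sd)
    i <- fx$native$i[1]; j <- fx$native$j[1]
    fx$coords$SG[] <- NA   # strip side chains
    br <- fix_sulphurs(fx, i, j)
    expect_lt(abs(br$d_ss - 2.04), 0.05)
    expect_lt(abs(abs(br$chi_ss) - 90), 10)
    expect_equal(br$grade, "A")
    # construction constraints hold at the selected point
    expect_equal(sqrt(sum((br$sg_i - fx$coords$CB[i, ])^2)), 1.808,
                 tolerance = 1e-6)
  }
})

test_that("fixation is symmetric in pair order", {
  fx <- ensure_cbeta(make_disulphide_fixture(seed = 8))
  i <- fx$native$i[1]; j <- fx$native$j[1]
  fx$coords$SG[] <- NA
  a <- fix_sulphurs(fx, i, j)
  b <- fix_sulphurs(fx, j, i)
  expect_equal(a$d_ss, b$d_ss, tolerance = 1e-9)
  expect_equal(abs(a$chi_ss), abs(b$chi_ss), tolerance = 1e-6)
  expect_equal(a$grade, b$grade)
  expect_equal(a$chi1_i, b$chi1_j)
})

test_that("outward-pointing CB vectors yield unfixable sulphur (grade D)", {
  # CA/CB distances compatible (1.4 and ~4.44 A) but both CB vectors point
  # away from the partner, so no chi1 combination closes a covalent bond
  s <- two_residue_structure(1.4, "apart")
  cand <- scan_candidate_pairs(s)
  expect_equal(nrow(cand), 1)   # passes both thresholds
  br <- fix_sulphurs(s, 1, 2)
  expect_gt(br$d_ss_min, 2.6)
  expect_equal(br$grade, "D")
  # brute-force 1-degree sweep agrees that no grid point is covalent
  expect_gt(oracle_fix_dss(s, 1, 2, step = 1), 2.6)
})

test_that("grading partitions deterministically by the config windows", {
  cfg <- modip_config()
  g <- function(d_ss, chi_ss, dmin = d_ss, dmax = d_ss)
    grade_bridge(list(d_ss = d_ss, chi_ss = chi_ss, d_ss_min = dmin,
                      d_ss_max = dmax), cfg)
  expect_equal(g(2.04, 92), "A")
  expect_equal(g(2.5, 150), "B")
  expect_equal(g(2.5, 92), "B")     # distance outside the A window
  expect_equal(g(2.0, 150), "B")    # chi_ss outside the A window
  expect_equal(g(1.5, 90, dmin = 1.2, dmax = 1.55), "C")
  expect_equal(g(2.9, 90, dmin = 2.7, dmax = 4.0), "D")
  # every random fixture pair receives exactly one grade
  pairs <- scan_candidate_pairs(random_coil(40, seed = 3))
  s <- ensure_cbeta(random_coil(40, seed = 3))
  for (k in seq_len(min(nrow(pairs), 10))) {
    br <- fix_sulphurs(s, pairs$i[k], pairs$j[k])
    expect_true(br$grade %in% c("A", "B", "C", "D"))
  }
})

test_that("grades are invariant under rigid-body motion", {
  s <- random_coil(30, seed = 12)
  pairs <- scan_candidate_pairs(s)
  expect_gt(nrow(pairs), 0)
  s2 <- withr::with_seed(99, transform_structure(s, random_rotation(),
                                                 c(11, -6, 23)))
  for (k in seq_len(min(nrow(pairs), 8))) {
    a <- fix_sulphurs(s, pairs$i[k], pairs$j[k])
    b <- fix_sulphurs(s2, pairs$i[k], pairs$j[k])
    expect_equal(a$grade, b$grade)
    expect_equal(a$d_ss, b$d_ss, tolerance = 1e-6)
    expect_equal(a$chi_ss, b$chi_ss, tolerance = 1e-4)
  }
})

test_that("modip report separates native and modelled sections", {
  fx <- make_disulphide_fixture(seed = 3)
  rep <- modip(fx)
  expect_equal(nrow(rep$native), 1)
  expect_equal(rep$native$grade, "A")       # ideal planted geometry
  expect_equal(rep$native$provenance, "native")
  expect_true(all(rep$modelled$provenance == "modelled"))
  expect_true(all(rep$modelled$d_ca <= 6.5 & rep$modelled$d_cb <= 4.5))
  # empty structure -> empty report, no error
  rep0 <- modip(make_extended_chain("AAAAAAAA"))
  expect_equal(nrow(rep0$native), 0)
  expect_equal(nrow(rep0$modelled), 0)
  # TSV round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_modip_tsv(rep, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), nrow(rep$native) + nrow(rep$modelled))
})
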