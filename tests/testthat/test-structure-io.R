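test_that("PDB parsing represents all records with normalized fields", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy_pdb_lines(), f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(unique(m$atoms$chain), "A")
  expect_equal(m$atoms$elesy, c("N", "C", "C"))
  expect_equal(m$atoms$x, c(11.104, 11.639, 10.729))
  expect_false(any(m$atoms$is_het))
})

test_that("mmCIF and PDB serializations of the same atoms agree", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(toy_pdb_lines(), fp)
  writeLines(toy_cif_lines(), fc)
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  expect_equal(mc$atoms$x, mp$atoms$x)
  expect_equal(mc$atoms$y, mp$atoms$y)
  expect_equal(mc$atoms$z, mp$atoms$z)
  expect_equal(mc$atoms$resno, mp$atoms$resno)
  expect_equal(mc$atoms$elety, mp$atoms$elety)
})

test_that("unreadable input and unknown formats raise typed errors", {
  expect_error(read_structure("no/such/file.pdb"), class = "tcrpmhc_parse_error")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", f)
  expect_error(read_structure(f), class = "tcrpmhc_format_error")
})

test_that("altloc policy keeps highest occupancy, ties by letter", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CB BALA A   1       6.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  expect_message(m <- read_structure(f), "altloc")
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 0)       # occupancy 0.6 wins
  cb <- m$atoms[m$atoms$elety == "CB", ]
  expect_equal(cb$x, 1)       # tie: altloc A before B
})

test_that("write/read round trip reproduces coordinates at PDB precision", {
  cx <- default_toy()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(cx$structure$atoms))
  orig <- as.matrix(cx$structure$atoms[, c("x", "y", "z")])
  back <- as.matrix(m2$atoms[, c("x", "y", "z")])
  expect_lt(max(abs(orig - back)), 5.01e-4)
})

test_that("annotation validates roles and is idempotent", {
  cx <- default_toy()
  cfg <- list(roles = c(A = "mhc_heavy", B = "b2m", C = "peptide",
                        D = "tcr_alpha", E = "tcr_beta"))
  ann1 <- annotate_complex(cx$structure, cfg)
  ann2 <- annotate_complex(ann1, cfg)
  expect_equal(ann1$annotation$roles, ann2$annotation$roles)
  expect_equal(ann1$annotation$cdr_ranges, ann2$annotation$cdr_ranges)
  expect_equal(sort(unname(ann1$annotation$roles)),
               sort(c("mhc_heavy", "b2m", "peptide", "tcr_alpha", "tcr_beta")))
  ## unknown role and duplicated role are rejected
  expect_error(annotate_complex(cx$structure, list(roles = c(A = "spam"))),
               class = "tcrpmhc_annotation_error")
  expect_error(
    annotate_complex(cx$structure,
                     list(roles = c(A = "peptide", C = "peptide"))),
    class = "tcrpmhc_annotation_error")
  ## chain absent from the structure
  expect_error(annotate_complex(cx$structure, list(roles = c(Z = "peptide"))),
               class = "tcrpmhc_annotation_error")
})

test_that("peptide auto-detection finds the unique 8-13mer chain", {
  mk_chain <- function(chain, n) {
    atoms_at(cbind(seq_len(n) * 3.8, match(chain, LETTERS) * 50, 0),
             chain = chain, resno = seq_len(n))
  }
  m <- structure_model(rbind(mk_chain("A", 30), mk_chain("B", 9),
                             mk_chain("C", 20)))
  ac <- annotate_complex(m, list(roles = c(A = "mhc_heavy", C = "tcr_alpha"),
                                 peptide = "auto"))
  expect_equal(names(which(ac$annotation$roles == "peptide")), "B")
  ## two candidate chains of peptide length: ambiguous
  m2 <- structure_model(rbind(mk_chain("A", 30), mk_chain("B", 9),
                              mk_chain("C", 9)))
  expect_error(annotate_complex(m2, list(roles = c(A = "mhc_heavy"),
                                         peptide = "auto")),
               class = "tcrpmhc_annotation_error")
})

test_that("annotation config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("roles:", "  A: mhc_heavy", "  B: b2m", "  C: peptide",
               "  D: tcr_alpha", "  E: tcr_beta",
               "cys_pairs:", "  tcr_alpha: [23, 104]"), f)
  cfg <- read_annotation(f)
  cx <- annotate_complex(default_toy()$structure, cfg)
  expect_equal(unname(cx$annotation$roles["D"]), "tcr_alpha")
  expect_equal(cx$annotation$cys_pairs$tcr_alpha, c(23, 104))
})

test_that("conserved disulfide detection finds the unique close pair", {
  sg <- function(xyz, resno) atoms_at(xyz, elety = "SG", elesy = "S",
                                      resno = resno, resid = "CYS")
  ca <- function(xyz, resno) atoms_at(xyz, resno = resno, resid = "CYS")
  chain <- rbind(sg(c(0, 0, 0), 23), sg(c(2.05, 0, 0), 104),
                 ca(c(1, 1, 1), 23), ca(c(3, 1, 1), 104))
  det <- detect_conserved_cys(chain)
  expect_setequal(det$positions, c(23, 104))
  expect_false(any(det$ca_fallback))
  expect_equal(det$distance, 2.05)

  ## three Cys, exactly one pair within 2.5 A: enumerate pairs as oracle
  chain3 <- rbind(chain, sg(c(30, 0, 0), 55), ca(c(30, 1, 0), 55))
  sg3 <- chain3[chain3$elety == "SG", ]
  d <- as.matrix(dist(sg3[, c("x", "y", "z")]))
  qual <- which(upper.tri(d) & d <= 2.5, arr.ind = TRUE)
  expect_equal(nrow(qual), 1)   # the oracle confirms uniqueness
  det3 <- detect_conserved_cys(chain3)
  expect_setequal(det3$positions, sg3$resno[qual[1, ]])

  ## no qualifying pair
  far <- rbind(sg(c(0, 0, 0), 23), sg(c(10, 0, 0), 104))
  expect_error(detect_conserved_cys(far), class = "tcrpmhc_detection_error")
})

test_that("config override with missing SG falls back to CA and flags it", {
  sg <- atoms_at(c(0, 0, 0), elety = "SG", elesy = "S", resno = 23,
                 resid = "CYS")
  ca <- atoms_at(c(0, 4, 0), resno = 104, resid = "ALA")
  det <- detect_conserved_cys(rbind(sg, ca), override = c(23, 104))
  expect_equal(det$ca_fallback, c(FALSE, TRUE))
  expect_true(is.na(det$distance))
})

test_that("disulfide detection is invariant under rigid motion", {
  cx <- default_toy()
  chain <- cx$structure$atoms[cx$structure$atoms$chain == "D", ]
  det0 <- detect_conserved_cys(chain)
  set.seed(42)
  for (k in 1:3) {
    R <- random_rotation()
    moved <- chain
    xyz <- sweep(as.matrix(chain[, c("x", "y", "z")]) %*% t(R), 2,
                 rnorm(3, sd = 20), "+")
    moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
    det <- detect_conserved_cys(moved)
    expect_equal(sort(det$positions), sort(det0$positions))
    expect_equal(det$distance, det0$distance, tolerance = 1e-9)
  }
})
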