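test_that("isolated-atom SASA matches the closed-form sphere area", {
  at <- atoms_at(c(0, 0, 0), elety = "C", elesy = "C")
  s <- compute_sasa(at, radii = c(C = 1.88, default = 1.8))
  expect_equal(s$total, 4 * pi * 3.28^2, tolerance = 0.01)
  ## unknown element without fallback radius
  xe <- atoms_at(c(0, 0, 0), elety = "XX", elesy = "XX")
  expect_error(compute_sasa(xe, radii = c(C = 1.88)),
               class = "tcrpmhc_radii_error")
})

test_that("a fully caged atom has zero accessible surface", {
  center <- atoms_at(c(0, 0, 0), elety = "C", elesy = "C")
  cage <- atoms_at(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                         c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)),
                   elety = "C", elesy = "C", resno = 2:7)
  s <- compute_sasa(center, context = cage)
  expect_equal(s$per_atom[1], 0)
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  ## equal radii R = r + probe, centers d apart: each sphere loses a cap
  ## of area 2 pi R^2 (1 - d / (2R))
  r <- 1.88; probe <- 1.4; R <- r + probe; d <- 3
  at <- atoms_at(rbind(c(0, 0, 0), c(d, 0, 0)), elety = "C", elesy = "C",
                 resno = 1:2)
  s <- compute_sasa(at, radii = c(C = r, default = r))
  expected <- 4 * pi * R^2 - 2 * pi * R^2 * (1 - d / (2 * R))
  expect_equal(s$per_atom[1], expected, tolerance = 0.01)
  expect_equal(s$per_atom[2], expected, tolerance = 0.01)
  ## occlusion is monotone: each atom's SASA below its isolated value
  expect_true(all(s$per_atom < 4 * pi * R^2))
})

test_that("SASA is rotation and translation invariant", {
  set.seed(31)
  at <- atoms_at(matrix(rnorm(60, sd = 3), ncol = 3), elety = "C",
                 elesy = "C", resno = 1:20)
  s0 <- compute_sasa(at)
  R <- random_rotation()
  xyz <- sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(R), 2, c(5, -3, 8), "+")
  at2 <- at; at2$x <- xyz[, 1]; at2$y <- xyz[, 2]; at2$z <- xyz[, 3]
  s1 <- compute_sasa(at2)
  expect_equal(s1$total, s0$total, tolerance = 0.001)
  ## per-residue aggregates sum to per-atom values
  expect_equal(sum(s0$per_residue$sasa), sum(s0$per_atom))
})

test_that("complexation can only lose surface", {
  cx <- default_toy()
  at <- cx$structure$atoms
  whole <- compute_sasa(at)
  parts <- sum(vapply(unique(at$chain), function(ch) {
    compute_sasa(at[at$chain == ch, ])$total
  }, numeric(1)))
  expect_lte(whole$total, parts + 1e-6)
})

test_that("buried peptide fraction spans the burial limits", {
  ## peptide fully enveloped by a cage of TCR atoms -> fraction ~ 1
  pep <- atoms_at(c(0, 0, 0), chain = "C", resno = 1, resid = "ALA")
  pep <- rbind(pep, atoms_at(c(1.5, 0, 0), chain = "C", resno = 2),
               atoms_at(c(3, 0, 0), chain = "C", resno = 3))
  shell_pts <- sphere_points(80) * 4.5
  shell <- rbind(
    atoms_at(sweep(shell_pts, 2, c(0, 0, 0), "+"), chain = "D", resno = 1:80),
    atoms_at(sweep(shell_pts, 2, c(1.5, 0, 0), "+"), chain = "D", resno = 81:160),
    atoms_at(sweep(shell_pts, 2, c(3, 0, 0), "+"), chain = "E", resno = 1:80))
  mhc <- atoms_at(cbind(100 + 3.8 * (1:12), 0, 0), chain = "A", resno = 1:12)
  b2m <- atoms_at(cbind(100 + 3.8 * (1:5), 20, 0), chain = "B", resno = 1:5)
  m <- structure_model(rbind(pep, shell, mhc, b2m))
  cx <- annotate_complex(m, list(roles = c(A = "mhc_heavy", B = "b2m",
                                           C = "peptide", D = "tcr_alpha",
                                           E = "tcr_beta")))
  bf <- buried_peptide_fraction(cx, n_sphere_points = 240)
  expect_gt(bf$buried_fraction, 0.95)
  ## TCR displaced far away -> fraction 0
  far <- shift_chain(cx, c("D", "E"), c(0, 0, 500))
  bf0 <- buried_peptide_fraction(far, n_sphere_points = 240)
  expect_equal(bf0$buried_fraction, 0)
  expect_equal(bf0$buried_area, 0)
  ## missing role
  cx$annotation$roles <- cx$annotation$roles[-5]
  expect_error(buried_peptide_fraction(cx), class = "tcrpmhc_annotation_error")
})

test_that("planar dot fixtures reproduce the Gaussian Sc closed form", {
  for (d in c(0.5, 1.0)) {
    pr <- make_dot_surface_pair("plane", separation = d)
    r <- sc_from_dots(pr$a, pr$b)
    expect_equal(r$sc, exp(-0.5 * d^2), tolerance = 0.02)
    expect_equal(r$median_a_to_b, r$median_b_to_a, tolerance = 1e-9)
  }
  ## coincident surfaces approach the perfect score
  pr0 <- make_dot_surface_pair("plane", separation = 0)
  expect_equal(sc_from_dots(pr0$a, pr0$b)$sc, 1.0, tolerance = 1e-9)
  ## parallel normals give the negative score
  prp <- make_dot_surface_pair("plane", separation = 1, antiparallel = FALSE)
  expect_equal(sc_from_dots(prp$a, prp$b)$sc, -exp(-0.5), tolerance = 0.02)
  ## beyond the interface distance the statistic is undefined
  prf <- make_dot_surface_pair("plane", separation = 5)
  expect_error(sc_from_dots(prf$a, prf$b), class = "tcrpmhc_undefined_sc")
})

test_that("Sc is symmetric and converges with dot density", {
  pr <- make_dot_surface_pair("plane", separation = 1)
  r1 <- sc_from_dots(pr$a, pr$b)
  r2 <- sc_from_dots(pr$b, pr$a)
  expect_equal(r1$sc, r2$sc, tolerance = 1e-12)
  ## doubling the density moves Sc by < 0.02
  hi <- make_dot_surface_pair("plane", separation = 1, density = 30)
  expect_lt(abs(sc_from_dots(hi$a, hi$b)$sc - r1$sc), 0.02)
})

test_that("atomic shape complementarity behaves at the limits", {
  ## two flat sheets of atoms: high complementarity
  g <- as.matrix(expand.grid(x = seq(-8, 8, by = 2), y = seq(-8, 8, by = 2)))
  sheet_a <- atoms_at(cbind(g, 5.0), chain = "A", resno = seq_len(nrow(g)))
  sheet_b <- atoms_at(cbind(g, -1.5), chain = "B", resno = seq_len(nrow(g)))
  r <- shape_complementarity(sheet_a, sheet_b)
  expect_true(r$sc > 0.4 && r$sc <= 1)
  ## far-apart sides are rejected
  far_b <- atoms_at(cbind(g, -100), chain = "B", resno = seq_len(nrow(g)))
  expect_error(shape_complementarity(sheet_a, far_b),
               class = "tcrpmhc_undefined_sc")
})

test_that("dot surfaces honor density and outward normals", {
  at <- atoms_at(c(0, 0, 0), elety = "C", elesy = "C")
  ds <- dot_surface(at, density = 10)
  area <- 4 * pi * (1.87 + 1.4)^2
  expect_equal(nrow(ds$points), round(10 * area))
  expect_equal(rowSums(ds$normals^2), rep(1, nrow(ds$normals)),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## normals point away from the atom center
  expect_true(all(rowSums(ds$points * ds$normals) > 0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_surface(ds, f)
  expect_equal(nrow(read.delim(f)), nrow(ds$points))
})
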