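test_that("constructed groove gives the canonical frame", {
  pm <- make_toy_pmhc()
  f <- build_mhc_frame(pm)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(f$x_axis), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(abs(f$z_axis), c(0, 0, 1), tolerance = 1e-9)
  expect_equal(f$x_axis[1], 1, tolerance = 1e-9)   # oriented toward C-terminus
  expect_equal(f$z_axis[3], 1, tolerance = 1e-9)   # toward +z absent a TCR
  ## orthonormal right-handed
  A <- rbind(f$x_axis, f$y_axis, f$z_axis)
  expect_equal(A %*% t(A), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(A), 1, tolerance = 1e-9)
})

test_that("frame is equivariant under translation", {
  pm <- make_toy_pmhc()
  f0 <- build_mhc_frame(pm)
  f1 <- build_mhc_frame(shift_chain(pm, c("A", "B", "C"), c(5, 5, 5)))
  expect_equal(f1$origin, f0$origin + c(5, 5, 5), tolerance = 1e-9)
  expect_equal(f1$x_axis, f0$x_axis, tolerance = 1e-9)
  expect_equal(f1$z_axis, f0$z_axis, tolerance = 1e-9)
})

test_that("reversing the peptide flips the x axis toward the C-terminus", {
  pm <- make_toy_pmhc()
  at <- pm$structure$atoms
  pep <- at$chain == "C"
  at$resno[pep] <- max(at$resno[pep]) + 1 - at$resno[pep]  # renumber N<->C
  pm$structure$atoms <- at
  f <- build_mhc_frame(pm)
  expect_equal(f$x_axis, c(-1, 0, 0), tolerance = 1e-9)
})

test_that("degenerate helix geometry raises a frame error", {
  pm <- make_toy_pmhc()
  at <- pm$structure$atoms
  heavy <- at$chain == "A"
  at$y[heavy] <- 0; at$z[heavy] <- 0      # collapse helices onto the x axis
  pm$structure$atoms <- at
  expect_error(build_mhc_frame(pm), class = "tcrpmhc_frame_error")
})

test_that("domain center is the midpoint of the disulfide anchors", {
  sg <- function(xyz, resno) atoms_at(xyz, elety = "SG", elesy = "S",
                                      resno = resno, resid = "CYS")
  chain <- rbind(sg(c(0, 0, 0), 23), sg(c(2, 0, 0), 104))
  ctr <- domain_center(chain, cys_pair = c(23, 104))
  expect_equal(as.numeric(ctr), c(1, 0, 0))
  ## CA fallback at one position, with flag
  mixed <- rbind(sg(c(0, 0, 0), 23),
                 atoms_at(c(0, 4, 0), resno = 104, resid = "ALA"))
  ctr2 <- domain_center(mixed, cys_pair = c(23, 104))
  expect_equal(as.numeric(ctr2), c(0, 2, 0))
  expect_equal(attr(ctr2, "ca_fallback"), c(FALSE, TRUE))
  ## coincident anchors are degenerate
  same <- rbind(sg(c(0, 0, 0), 23), sg(c(0, 0, 0), 104))
  expect_error(domain_center(same, cys_pair = c(23, 104)),
               class = "tcrpmhc_geometry_error")
})

test_that("TCR center projection is frame arithmetic", {
  idf <- structure(list(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                        y_axis = c(0, 1, 0), z_axis = c(0, 0, 1)),
                   class = "reference_frame")
  p <- tcr_center_projection(c(10, 0, 8), c(14, 4, 12), idf)
  expect_equal(p$tcr_center, c(12, 2, 10))
  expect_equal(p$x_pos, 12)
  expect_equal(p$y_pos, 2)
  p0 <- tcr_center_projection(c(-3, -2, -1), c(3, 2, 1), idf)
  expect_equal(p0$tcr_center, c(0, 0, 0))
  expect_equal(c(p0$x_pos, p0$y_pos), c(0, 0))
  ## translating frame and centers together changes nothing
  t <- c(7, -4, 2)
  tf <- idf; tf$origin <- t
  pt <- tcr_center_projection(c(10, 0, 8) + t, c(14, 4, 12) + t, tf)
  expect_equal(c(pt$x_pos, pt$y_pos), c(p$x_pos, p$y_pos))
})

test_that("crossing and incident angles follow the frame conventions", {
  idf <- structure(list(origin = c(0, 0, 0), x_axis = c(1, 0, 0),
                        y_axis = c(0, 1, 0), z_axis = c(0, 0, 1)),
                   class = "reference_frame")
  expect_equal(crossing_angle(c(0, 0, 5), c(10, 0, 5), idf), 0)
  expect_equal(crossing_angle(c(0, 0, 5), c(0, 10, 5), idf), 90)
  expect_equal(incident_angle(c(0, 0, 5), c(10, 0, 5), idf), 0)
  expect_equal(incident_angle(c(0, 0, 0), c(0, 0, 10), idf), 90)
  ## vector perpendicular to the plane has no crossing angle
  expect_error(crossing_angle(c(0, 0, 0), c(0, 0, 10), idf),
               class = "tcrpmhc_geometry_error")
  expect_error(incident_angle(c(1, 1, 1), c(1, 1, 1), idf),
               class = "tcrpmhc_geometry_error")
  ## reflection across the x-z plane preserves the angle magnitude
  expect_equal(crossing_angle(c(0, 0, 5), c(7, 4, 5), idf),
               crossing_angle(c(0, 0, 5), c(7, -4, 5), idf))
  ## a custom incident-angle strategy is honored
  expect_equal(incident_angle(c(0, 0, 0), c(1, 0, 1), idf,
                              strategy = function(v) 12.5), 12.5)
})

test_that("docking descriptors are invariant under rigid motion", {
  cx <- default_toy()
  g0 <- docking_geometry(cx)
  set.seed(11)
  for (k in 1:5) {
    moved <- transform_complex(cx, random_rotation(), rnorm(3, sd = 30))
    g <- docking_geometry(moved)
    expect_equal(g$crossing_angle, g0$crossing_angle, tolerance = 1e-6)
    expect_equal(g$incident_angle, g0$incident_angle, tolerance = 1e-6)
    expect_equal(g$x_pos, g0$x_pos, tolerance = 1e-6)
    expect_equal(g$y_pos, g0$y_pos, tolerance = 1e-6)
  }
  ## repeated construction is deterministic
  g1 <- docking_geometry(cx)
  expect_identical(g0$crossing_angle, g1$crossing_angle)
  expect_true(g0$canonical_polarity)
})

test_that("rank and percentile reproduce the survey conventions", {
  ## 135 reference rows plus the query = 136 complexes total
  set.seed(1)
  base <- runif(135, 0, 15)
  ## rank 4: exactly three rows above the query
  vals <- base; vals[1:3] <- 30 + 1:3; vals[-(1:3)] <- runif(132, 0, 15)
  r4 <- rank_percentile(20, vals)
  expect_equal(r4$rank, 4L)
  expect_equal(r4$percentile, 97L)
  ## rank 14: thirteen rows above
  vals[1:13] <- 30 + 1:13
  r14 <- rank_percentile(20, vals)
  expect_equal(r14$rank, 14L)
  expect_equal(r14$percentile, 90L)
  ## query larger than every row
  expect_equal(rank_percentile(99, vals)$rank, 1L)
  expect_error(rank_percentile(1, numeric(0)), class = "tcrpmhc_ranking_error")
})

test_that("geometry reference tables round-trip as TSV", {
  tab <- data.frame(complex_id = c("x1", "x2"), crossing_angle = c(40, 60),
                    incident_angle = c(5, 12), x_pos = c(1, -2),
                    y_pos = c(0.5, 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_table(tab, f)
  back <- read_geometry_table(f)
  expect_equal(back, tab)
  tab$complex_id <- c("x1", "x1")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_table(tab, f2)
  expect_error(read_geometry_table(f2), class = "tcrpmhc_ranking_error")
})
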