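## Synthetic annotated TCR-pMHC complexes with prescribed docking
## geometry and contact layouts, plus geometric fixtures (ideal helices,
## dot-surface pairs).  Toy domains are geometric scaffolds, not folded
## immunoglobulin domains: the docking descriptors depend only on anchor
## atoms and the groove frame, so scaffolds suffice and are exact.

#' Specification of a toy TCR-pMHC complex
#'
#' @param crossing_angle Crossing angle, degrees in \[0, 180\].
#' @param incident_angle Incident (tilt) angle, degrees in \[0, 90\].
#' @param x_pos,y_pos TCR-center position in the groove frame, Angstrom.
#' @param peptide_length Peptide residues (>= 3, default 9).
#' @param helix_length Residues per groove helix (default 36 = ten full
#'   turns at 100 degrees/residue, which makes the constructed frame
#'   exactly canonical).
#' @param contact_layout Optional named integer vector of planted
#'   contact counts; names are `"<loop><chain>:<target>"`, e.g.
#'   `c("CDR3b:peptide" = 61, "CDR2a:mhc" = 39)` with loop in
#'   CDR1/CDR2/HV4/CDR3, chain `a`/`b`, target `peptide`/`mhc`.
#' @param seed Integer seed (generation is deterministic; the seed only
#'   matters when `jitter_sd > 0`).
#' @param jitter_sd Gaussian coordinate jitter, Angstrom (default 0).
#' @param z_height Height of the TCR center above the groove plane.
#' @param domain_sep Distance between the Valpha and Vbeta centers.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(crossing_angle = 45, incident_angle = 10,
                             x_pos = 2, y_pos = 0,
                             peptide_length = 9, helix_length = 36,
                             contact_layout = NULL, seed = 1L,
                             jitter_sd = 0, z_height = 25, domain_sep = 20) {
  if (crossing_angle < 0 || crossing_angle > 180) {
    stop_tcrpmhc("crossing_angle must be in [0, 180]", "tcrpmhc_generation_error")
  }
  if (incident_angle < 0 || incident_angle > 90) {
    stop_tcrpmhc("incident_angle must be in [0, 90]", "tcrpmhc_generation_error")
  }
  if (peptide_length < 3) {
    stop_tcrpmhc("peptide_length must be >= 3", "tcrpmhc_generation_error")
  }
  if (!is.null(contact_layout)) check_layout_names(contact_layout)
  structure(list(crossing_angle = crossing_angle,
                 incident_angle = incident_angle,
                 x_pos = x_pos, y_pos = y_pos,
                 peptide_length = peptide_length,
                 helix_length = helix_length,
                 contact_layout = contact_layout,
                 seed = as.integer(seed), jitter_sd = jitter_sd,
                 z_height = z_height, domain_sep = domain_sep),
            class = "toy_complex_spec")
}

check_layout_names <- function(layout) {
  ok <- grepl("^(CDR1|CDR2|HV4|CDR3)[ab]:(peptide|mhc)$", names(layout))
  if (!all(ok)) {
    stop_tcrpmhc(paste("bad contact_layout keys:",
                       paste(names(layout)[!ok], collapse = ", ")),
                 "tcrpmhc_generation_error")
  }
  if (any(layout < 0)) {
    stop_tcrpmhc("contact counts must be non-negative", "tcrpmhc_generation_error")
  }
}

#' Calpha trace of an ideal helix
#'
#' @param n_residues Number of residues (>= 2).
#' @param rise Rise per residue along the axis, Angstrom (default 1.5).
#' @param twist Twist per residue, degrees (default 100; period 3.6
#'   residues/turn).
#' @param radius Helix radius, Angstrom (default 2.3).
#' @param axis Unit axis direction (default +x).
#' @param origin Center of the helix (the trace is centered on it).
#' @param phase Phase offset, radians.
#' @return `n_residues` x 3 coordinate matrix.
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100,
                             radius = 2.3, axis = c(1, 0, 0),
                             origin = c(0, 0, 0), phase = 0) {
  if (n_residues < 2) stop_tcrpmhc("need >= 2 residues", "tcrpmhc_generation_error")
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- cross3(ref, axis); u <- u / sqrt(sum(u^2))
  v <- cross3(axis, u)
  i <- seq_len(n_residues) - 1
  t_ax <- (i - (n_residues - 1) / 2) * rise
  th <- phase + i * twist * pi / 180
  sweep(outer(t_ax, axis) + radius * (outer(cos(th), u) + outer(sin(th), v)),
        2, origin, "+")
}

ca_rows <- function(coords, chain, resno, resid = "GLY") {
  data.frame(type = "ATOM", eleno = NA_integer_, elety = "CA",
             alt = NA_character_, resid = resid, chain = chain,
             resno = resno, insert = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             o = 1, elesy = "C", is_het = FALSE, stringsAsFactors = FALSE)
}

atom_row <- function(xyz, chain, resno, elety, elesy, resid = "GLY") {
  data.frame(type = "ATOM", eleno = NA_integer_, elety = elety,
             alt = NA_character_, resid = resid, chain = chain,
             resno = resno, insert = "",
             x = xyz[1], y = xyz[2], z = xyz[3],
             o = 1, elesy = elesy, is_het = FALSE, stringsAsFactors = FALSE)
}

HELIX_Y <- 9      # half-distance between groove helix axes, Angstrom
PEPTIDE_Z <- 1    # height of the peptide Calpha trace above the plane
PEPTIDE_SPACING <- 3.3

#' Toy pMHC platform in the canonical groove frame
#'
#' Two antiparallel-phase ideal helices (the alpha1 helix at y = +9
#' numbered from 50, the alpha2 helix at y = -9 numbered from 138) whose
#' Calpha cloud has an exactly diagonal covariance, an extended peptide
#' Calpha trace along +x between them (N- to C-terminus toward +x), and
#' a short beta-2-microglobulin stub underneath.  [build_mhc_frame()] on
#' the output therefore returns the identity frame with origin at the
#' helix-Calpha mean.
#'
#' @param spec A `toy_complex_spec` (only the pMHC-related fields are
#'   used), or arguments via `...` passed to [toy_complex_spec()].
#' @param ... Used when `spec` is missing.
#' @return An `annotated_complex` with roles mhc_heavy (A), b2m (B),
#'   peptide (C).
#' @export
make_toy_pmhc <- function(spec = NULL, ...) {
  spec <- spec %||% toy_complex_spec(...)
  nh <- spec$helix_length
  h1 <- make_ideal_helix(nh, origin = c(0, HELIX_Y, 0))
  h2 <- make_ideal_helix(nh, origin = c(0, -HELIX_Y, 0), phase = pi)
  heavy <- rbind(ca_rows(h1, "A", 50:(50 + nh - 1)),
                 ca_rows(h2, "A", 138:(138 + nh - 1)))
  np <- spec$peptide_length
  px <- (seq_len(np) - (np + 1) / 2) * PEPTIDE_SPACING
  pep <- ca_rows(cbind(px, 0, PEPTIDE_Z), "C", seq_len(np), resid = "ALA")
  b2m <- ca_rows(cbind((0:4 - 2) * 3.8, 0, -20), "B", 1:5)
  atoms <- rbind(heavy, b2m, pep)
  model <- structure_model(atoms, id = "toy_pmhc")
  annotate_complex(model, list(roles = c(A = "mhc_heavy", B = "b2m",
                                         C = "peptide")))
}

#' Toy TCR-pMHC complex with prescribed docking geometry
#'
#' Places two pseudo-V domains, each carrying a synthetic conserved-Cys
#' Sgamma pair (residues 23 and 104), such that the measured crossing
#' angle, incident angle, x_pos and y_pos equal the specification to
#' numerical precision.  An optional `contact_layout` is realized by
#' planting carbon atoms at 3.5 Angstrom (strictly inside the 4.0
#' cutoff) from designated peptide or helix Calpha atoms, assigned to
#' residues inside the requested loop's range; the realized layout is
#' verified by exhaustive pair counting and any deviation raises a
#' generation error.
#'
#' @param spec A `toy_complex_spec`, or arguments via `...`.
#' @param ... Used when `spec` is missing.
#' @return An `annotated_complex` with all five roles (TCR alpha = D,
#'   beta = E).
#' @export
make_toy_tcr_pmhc <- function(spec = NULL, ...) {
  spec <- spec %||% toy_complex_spec(...)
  pmhc <- make_toy_pmhc(spec)
  chi <- spec$crossing_angle * pi / 180
  iota <- spec$incident_angle * pi / 180
  u <- c(cos(iota) * cos(chi), cos(iota) * sin(chi), sin(iota))
  center <- c(spec$x_pos, spec$y_pos, spec$z_height)
  va <- center - (spec$domain_sep / 2) * u
  vb <- center + (spec$domain_sep / 2) * u

  w <- cross3(u, c(0, 0, 1))
  if (sqrt(sum(w^2)) < 1e-6) w <- cross3(u, c(1, 0, 0))
  w <- w / sqrt(sum(w^2))

  domain <- function(chain, ctr) {
    sg1 <- ctr + 1.025 * w
    sg2 <- ctr - 1.025 * w
    ring <- seq_len(20)
    ang <- 2 * pi * (ring - 1) / 20
    v2 <- cross3(u, w)
    circ <- t(vapply(ang, function(a) ctr + 5 * (cos(a) * w + sin(a) * v2),
                     numeric(3)))
    rbind(
      ca_rows(circ, chain, ring),
      atom_row(sg1 + 1.8 * u, chain, 23, "CA", "C", "CYS"),
      atom_row(sg1, chain, 23, "SG", "S", "CYS"),
      atom_row(sg2 - 1.8 * u, chain, 104, "CA", "C", "CYS"),
      atom_row(sg2, chain, 104, "SG", "S", "CYS")
    )
  }
  tcr <- rbind(domain("D", va), domain("E", vb))

  planted <- plant_contacts(spec, pmhc)
  atoms <- rbind(pmhc$structure$atoms, tcr, planted)
  if (spec$jitter_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(atoms), sd = spec$jitter_sd), ncol = 3)
  }
  model <- structure_model(atoms, id = "toy_tcr_pmhc")
  cmplx <- annotate_complex(model, list(
    roles = c(A = "mhc_heavy", B = "b2m", C = "peptide",
              D = "tcr_alpha", E = "tcr_beta"),
    cys_pairs = list(tcr_alpha = c(23, 104), tcr_beta = c(23, 104))
  ))
  if (!is.null(spec$contact_layout) && spec$jitter_sd == 0) {
    verify_layout(cmplx, spec$contact_layout)
  }
  cmplx
}

## Realize the requested per-loop contact counts by planting carbon
## atoms 3.5 A from target Calpha atoms, tilted within safe cones so
## each planted atom contacts exactly its designated target.
plant_contacts <- function(spec, pmhc) {
  layout <- spec$contact_layout
  if (is.null(layout) || !length(layout)) return(NULL)
  heavy <- role_atoms(pmhc, "mhc_heavy")
  pep <- role_atoms(pmhc, "peptide")

  ## target lists with per-target tilt-slot capacity
  pep_targets <- lapply(seq_len(nrow(pep)), function(i) {
    list(pos = as.numeric(pep[i, c("x", "y", "z")]),
         dir0 = c(0, 0, 1), tilt = c(0, 1, 0), max_tilt = 45)
  })
  rad_y <- (heavy$y - ifelse(heavy$y > 0, HELIX_Y, -HELIX_Y)) / 2.3
  rad_z <- heavy$z / 2.3
  up <- which(rad_z >= 0.6)
  mhc_targets <- lapply(up, function(i) {
    list(pos = as.numeric(heavy[i, c("x", "y", "z")]),
         dir0 = c(0, rad_y[i], rad_z[i]), tilt = c(1, 0, 0), max_tilt = 18)
  })
  slots <- list(peptide = integer(length(pep_targets)),
                mhc = integer(length(mhc_targets)))
  targets <- list(peptide = pep_targets, mhc = mhc_targets)
  step <- 6   # degrees between tilt slots on one target

  cdr <- default_cdr_ranges()
  rows <- list()
  res_used <- integer(0)   # atoms planted so far per "chain:resno" key
  for (key in names(layout)) {
    n_req <- layout[[key]]
    if (n_req == 0) next
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    loop <- substr(parts[1], 1, nchar(parts[1]) - 1)
    chain <- if (substr(parts[1], nchar(parts[1]), nchar(parts[1])) == "a") "D" else "E"
    target <- parts[2]
    rng <- cdr[[loop]]
    res_pool <- rng[1]:rng[2]
    tg <- targets[[target]]
    for (k in seq_len(n_req)) {
      ## next free (target, tilt-slot) pair, round-robin over targets
      ti <- ((k - 1) %% length(tg)) + 1
      tries <- 0
      repeat {
        s <- slots[[target]][ti]
        cap <- 2 * floor(tg[[ti]]$max_tilt / step) + 1
        if (s < cap) break
        ti <- (ti %% length(tg)) + 1
        tries <- tries + 1
        if (tries > length(tg)) {
          stop_tcrpmhc(sprintf("contact_layout infeasible: no free slot for %s", key),
                       "tcrpmhc_generation_error")
        }
      }
      slots[[target]][ti] <- s + 1L
      phi <- (((s + 1) %/% 2) * step * if (s %% 2 == 1) 1 else -1) * pi / 180
      t0 <- tg[[ti]]
      dir <- cos(phi) * t0$dir0 + sin(phi) * t0$tilt
      pos <- t0$pos + 3.5 * dir
      ri <- ((k - 1) %% length(res_pool)) + 1
      rkey <- paste0(chain, ":", res_pool[ri])
      cnt <- if (rkey %in% names(res_used)) res_used[[rkey]] else 0L
      res_used[rkey] <- cnt + 1L
      name <- sprintf("C%d", cnt + 1L)
      rows[[length(rows) + 1L]] <-
        atom_row(pos, chain, res_pool[ri], name, "C", "ALA")
      if (cnt == 0L) {
        rows[[length(rows) + 1L]] <-
          atom_row(pos + c(0, 0, 1.5), chain, res_pool[ri], "CA", "C", "ALA")
      }
    }
  }
  do.call(rbind, rows)
}

## Exhaustive verification that the realized contact table equals the
## requested layout (and nothing else).
verify_layout <- function(cmplx, layout) {
  tab <- build_contact_table(cmplx, cutoff = 4.0)
  want <- tab$counts; want[] <- 0L
  for (key in names(layout)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    want[parts[2], parts[1]] <- layout[[key]]
  }
  if (!all(tab$counts == want) || tab$b2m_contacts > 0) {
    stop_tcrpmhc("contact_layout could not be realized without collisions",
                 "tcrpmhc_generation_error")
  }
  invisible(TRUE)
}

#' Congruent dot-surface pair for shape-complementarity fixtures
#'
#' Two congruent surfaces at a given separation with anti-parallel
#' (complementary) normals by default.  For `shape = "plane"` the
#' nearest partner of every dot lies directly across the gap, so
#' [sc_from_dots()] with weight w returns `exp(-w d^2)` exactly.
#'
#' @param shape `"plane"` or `"hemisphere"`.
#' @param separation Gap between the surfaces, Angstrom (>= 0).
#' @param density Dots per Angstrom^2 (default 15).
#' @param size Plane half-width or hemisphere radius, Angstrom.
#' @param antiparallel Complementary normals (default `TRUE`); `FALSE`
#'   gives parallel normals (anti-complementary, negative scores).
#' @return List with `a` and `b`, each a `dot_surface`.
#' @export
make_dot_surface_pair <- function(shape = c("plane", "hemisphere"),
                                  separation = 1, density = 15,
                                  size = 10, antiparallel = TRUE) {
  shape <- match.arg(shape)
  if (separation < 0) stop_tcrpmhc("separation must be >= 0",
                                   "tcrpmhc_generation_error")
  h <- 1 / sqrt(density)
  g <- seq(-size, size, by = h)
  if (shape == "plane") {
    grid <- as.matrix(expand.grid(x = g, y = g))
    pa <- cbind(grid, separation)
    pb <- cbind(grid, 0)
    na <- matrix(rep(c(0, 0, -1), each = nrow(pa)), ncol = 3)
    nb <- matrix(rep(c(0, 0, 1), each = nrow(pb)), ncol = 3)
  } else {
    grid <- as.matrix(expand.grid(x = g, y = g))
    r2 <- rowSums(grid^2)
    grid <- grid[r2 < size^2 * 0.99, , drop = FALSE]
    zcap <- sqrt(size^2 - rowSums(grid^2))
    pb <- cbind(grid, zcap - size)           # convex cap peaking at z = 0
    nb <- cbind(grid, zcap) / size           # outward (up) normals
    pa <- cbind(pb[, 1:2], pb[, 3] + separation)
    na <- -nb
  }
  if (!antiparallel) na <- -na
  mk <- function(p, n) structure(list(points = unname(p), normals = unname(n),
                                      atom = rep(NA_integer_, nrow(p))),
                                 class = "dot_surface")
  list(a = mk(pa, na), b = mk(pb, nb))
}
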