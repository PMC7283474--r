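## Solvent-accessible surface areas (Shrake-Rupley sphere sampling),
## buried peptide surface, and the Lawrence-Colman shape-complementarity
## statistic computed on solvent-accessible dot surfaces.

#' Deterministic unit-sphere point set (spherical Fibonacci lattice)
#'
#' @param n Number of points (>= 92 recommended for area work).
#' @return `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default van der Waals radii (Angstrom)
#'
#' Element-keyed united-atom-style radii in the NACCESS/Chothia
#' tradition; fully overridable through the `radii` argument of the
#' surface functions.  The `default` entry is the fallback for elements
#' not listed.
#'
#' @return Named numeric vector.
#' @export
default_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90, H = 1.00,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, default = 1.80)
}

atom_radii <- function(atoms, radii) {
  r <- radii[atoms$elesy]
  miss <- is.na(r)
  if (any(miss)) {
    if (is.na(radii["default"])) {
      stop_tcrpmhc(paste("no radius for element(s):",
                         paste(unique(atoms$elesy[miss]), collapse = ", ")),
                   "tcrpmhc_radii_error")
    }
    r[miss] <- radii["default"]
  }
  unname(r)
}

#' Solvent-accessible surface area by sphere-point sampling
#'
#' Shrake-Rupley: for each atom, points on the probe-expanded sphere
#' are tested against the probe-expanded spheres of its neighbors; the
#' accessible fraction times `4 pi (r + probe)^2` is the atom's SASA.
#' The point set is a fixed deterministic lattice, so areas are exactly
#' reproducible (and rotation-invariant to within sampling noise).
#'
#' Hydrogens are excluded from both the scored set and the occluders.
#'
#' @param atoms Atom table, `structure_model` or `annotated_complex`.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Sample points per atom (default 960; >= 92).
#' @param radii Named per-element radius vector, see [default_radii()].
#' @param context Optional atom table of additional occluding atoms that
#'   are not themselves scored (used for within-complex SASA).
#' @return A `sasa_result`: list with `per_atom` (Angstrom^2, one entry
#'   per scored atom), `atoms` (the scored table), `per_residue` and
#'   `per_chain` aggregate data frames, `total`, and the parameters.
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_sphere_points = 960,
                         radii = default_radii(), context = NULL) {
  atoms <- as_atom_table(atoms)
  if (probe_radius <= 0) stop_tcrpmhc("probe_radius must be > 0", "tcrpmhc_radii_error")
  if (n_sphere_points < 92) stop_tcrpmhc("need >= 92 sphere points", "tcrpmhc_radii_error")
  atoms <- atoms[!is_hydrogen(atoms), , drop = FALSE]
  if (!is.null(context)) {
    context <- as_atom_table(context)
    context <- context[!is_hydrogen(context), , drop = FALSE]
  }
  n <- nrow(atoms)
  if (n == 0) stop_tcrpmhc("no heavy atoms to score", "tcrpmhc_radii_error")

  occ <- if (is.null(context) || nrow(context) == 0) atoms else
    rbind(atoms[, c("x", "y", "z", "elesy")],
          context[, c("x", "y", "z", "elesy")])
  xyz <- atom_xyz(atoms)
  oxyz <- atom_xyz(occ)
  r_sc <- atom_radii(atoms, radii) + probe_radius
  r_oc <- atom_radii(occ, radii) + probe_radius
  pts <- sphere_points(n_sphere_points)

  per_atom <- numeric(n)
  max_reach <- max(r_oc)
  for (i in seq_len(n)) {
    ## neighbor occluders: centers within r_i + r_j
    d2 <- rowSums(sweep(oxyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r_sc[i] + r_oc)^2 & d2 > 1e-12)
    frac <- 1
    if (length(nb)) {
      nb <- nb[order(d2[nb])]
      p <- sweep(pts * r_sc[i], 2, xyz[i, ], "+")
      alive <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(alive)) break
        dj2 <- rowSums(sweep(p[alive, , drop = FALSE], 2, oxyz[j, ])^2)
        alive[alive] <- dj2 >= r_oc[j]^2
      }
      frac <- mean(alive)
    }
    per_atom[i] <- frac * 4 * pi * r_sc[i]^2
  }

  res_key <- paste(atoms$chain, atoms$resno, atoms$insert)
  per_res <- stats::aggregate(per_atom,
                              by = list(chain = atoms$chain, resno = atoms$resno,
                                        insert = atoms$insert, resid = atoms$resid),
                              FUN = sum)
  names(per_res)[names(per_res) == "x"] <- "sasa"
  per_res <- per_res[order(per_res$chain, per_res$resno, per_res$insert), ]
  rownames(per_res) <- NULL
  per_chain <- stats::aggregate(per_atom, by = list(chain = atoms$chain), FUN = sum)
  names(per_chain)[names(per_chain) == "x"] <- "sasa"

  out <- list(per_atom = per_atom, atoms = atoms,
              per_residue = per_res, per_chain = per_chain,
              total = sum(per_atom),
              probe_radius = probe_radius, n_sphere_points = n_sphere_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.1f A, %d points)\n",
              length(x$per_atom), x$total, x$probe_radius, x$n_sphere_points))
  invisible(x)
}

#' Buried peptide surface on TCR binding
#'
#' Buried area = SASA of the peptide within the pMHC alone (heavy chain
#' and beta-2-microglobulin as occluders) minus its SASA within the full
#' TCR-pMHC complex; the fraction is relative to the pMHC-alone value.
#'
#' @param complex An `annotated_complex` with peptide, MHC and TCR roles.
#' @inheritParams compute_sasa
#' @return List with `buried_area` (Angstrom^2), `buried_fraction`,
#'   `sasa_free` (peptide SASA in pMHC alone) and `sasa_complex`.
#' @export
buried_peptide_fraction <- function(complex, probe_radius = 1.4,
                                    n_sphere_points = 960,
                                    radii = default_radii()) {
  for (r in c("peptide", "mhc_heavy", "tcr_alpha", "tcr_beta")) {
    if (!has_role(complex, r)) {
      stop_tcrpmhc(sprintf("complex lacks role '%s'", r), "tcrpmhc_annotation_error")
    }
  }
  pep <- role_atoms(complex, "peptide")
  mhc <- role_atoms(complex, "mhc_heavy")
  if (has_role(complex, "b2m")) mhc <- rbind(mhc, role_atoms(complex, "b2m"))
  tcr <- rbind(role_atoms(complex, "tcr_alpha"), role_atoms(complex, "tcr_beta"))

  free <- compute_sasa(pep, probe_radius, n_sphere_points, radii, context = mhc)
  bound <- compute_sasa(pep, probe_radius, n_sphere_points, radii,
                        context = rbind(mhc, tcr))
  buried <- free$total - bound$total
  list(buried_area = buried,
       buried_fraction = if (free$total > 0) buried / free$total else NA_real_,
       sasa_free = free$total, sasa_complex = bound$total)
}

## ---------------------------------------------------------------------
## Dot surfaces and shape complementarity

#' Solvent-accessible dot surface of an atom group
#'
#' Dots on each atom's probe-expanded sphere that are not inside any
#' other probe-expanded sphere of the group, with outward radial
#' normals.  The dot count per atom is `density * 4 pi (r + probe)^2`.
#'
#' @param atoms Atom table (hydrogens ignored).
#' @param probe_radius Probe radius, Angstrom.
#' @param density Dots per Angstrom^2 (default 15).
#' @param radii Per-element radii, see [default_radii()].
#' @param context Optional additional occluding atoms of the same side
#'   that do not themselves carry dots.
#' @return A `dot_surface`: list with `points` (n x 3), `normals`
#'   (n x 3, unit, outward) and `atom` (index of the parent atom).
#' @export
dot_surface <- function(atoms, probe_radius = 1.4, density = 15,
                        radii = default_radii(), context = NULL) {
  atoms <- as_atom_table(atoms)
  atoms <- atoms[!is_hydrogen(atoms), , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0) stop_tcrpmhc("no heavy atoms", "tcrpmhc_radii_error")
  occ <- if (is.null(context) || nrow(context) == 0) atoms else {
    context <- as_atom_table(context)
    rbind(atoms[, c("x", "y", "z", "elesy")],
          context[!is_hydrogen(context), c("x", "y", "z", "elesy")])
  }
  xyz <- atom_xyz(atoms)
  oxyz <- atom_xyz(occ)
  r <- atom_radii(atoms, radii) + probe_radius
  r_oc <- atom_radii(occ, radii) + probe_radius
  pts <- list(); nrm <- list(); parent <- list()
  for (i in seq_len(n)) {
    np <- max(12L, round(density * 4 * pi * r[i]^2))
    s <- sphere_points(np)
    p <- sweep(s * r[i], 2, xyz[i, ], "+")
    alive <- rep(TRUE, np)
    d2 <- rowSums(sweep(oxyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r_oc)^2 & d2 > 1e-12)
    for (j in nb[order(d2[nb])]) {
      if (!any(alive)) break
      dj2 <- rowSums(sweep(p[alive, , drop = FALSE], 2, oxyz[j, ])^2)
      alive[alive] <- dj2 >= r_oc[j]^2 - 1e-9
    }
    if (any(alive)) {
      pts[[length(pts) + 1L]] <- p[alive, , drop = FALSE]
      nrm[[length(nrm) + 1L]] <- s[alive, , drop = FALSE]
      parent[[length(parent) + 1L]] <- rep(i, sum(alive))
    }
  }
  out <- list(points = do.call(rbind, pts), normals = do.call(rbind, nrm),
              atom = unlist(parent))
  class(out) <- "dot_surface"
  out
}

## Range-limited nearest neighbour via a cell list: for each row of X,
## the nearest row of Y within rmax (index NA / distance Inf when none).
## Only short-range distances matter for Sc, so the search radius is
## bounded and the cost stays linear in the number of dots.
nn_within <- function(X, Y, rmax) {
  nx <- nrow(X)
  idx <- rep(NA_integer_, nx); dist <- rep(Inf, nx)
  if (nx == 0 || nrow(Y) == 0) return(list(index = idx, distance = dist))
  h <- max(rmax, 1e-6)
  cy <- floor(Y / h)
  ymap <- split(seq_len(nrow(Y)), paste(cy[, 1], cy[, 2], cy[, 3]))
  cx <- floor(X / h)
  qkey <- paste(cx[, 1], cx[, 2], cx[, 3])
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (qc in unique(qkey)) {
    qi <- which(qkey == qc)
    base <- cx[qi[1], ]
    nkeys <- paste(base[1] + off[, 1], base[2] + off[, 2], base[3] + off[, 3])
    cand <- unlist(ymap[nkeys], use.names = FALSE)
    if (is.null(cand) || !length(cand)) next
    Yc <- Y[cand, , drop = FALSE]
    d2 <- outer(rowSums(X[qi, , drop = FALSE]^2), rowSums(Yc^2), "+") -
      2 * X[qi, , drop = FALSE] %*% t(Yc)
    j <- max.col(-d2, ties.method = "first")
    dd <- sqrt(pmax(0, d2[cbind(seq_along(qi), j)]))
    ok <- dd <= rmax
    idx[qi[ok]] <- cand[j[ok]]
    dist[qi[ok]] <- dd[ok]
  }
  list(index = idx, distance = dist)
}

#' Shape complementarity of two dot surfaces
#'
#' Core of the Lawrence-Colman statistic: for each interface dot on one
#' surface, the nearest dot on the partner surface contributes the score
#' `-(n . n') exp(-w d^2)` (so perfectly apposed anti-parallel surfaces
#' score +1).  Sc is the mean of the two directional medians.  Interface
#' dots are those within `interface_distance` of the partner surface;
#' dots within `border_trim` of the interface rim (the nearest
#' non-interface dot of the same surface) are excluded.
#'
#' @param dots_a,dots_b `dot_surface` objects.
#' @param weight_w Gaussian distance weight, Angstrom^-2 (default 0.5).
#' @param interface_distance Dot-to-partner-surface distance defining
#'   the interface, Angstrom (default 1.5).
#' @param border_trim Peripheral band width removed from the interface
#'   patch, Angstrom (default 1.5).
#' @return An `sc_result`: list with `sc`, `median_a_to_b`,
#'   `median_b_to_a`, `n_dots_a`, `n_dots_b`.
#' @export
sc_from_dots <- function(dots_a, dots_b, weight_w = 0.5,
                         interface_distance = 1.5, border_trim = 1.5) {
  if (weight_w <= 0 || interface_distance <= 0 || border_trim < 0) {
    stop_tcrpmhc("Sc parameters must be positive", "tcrpmhc_radii_error")
  }
  side <- function(A, B) {
    nnAB <- nn_within(A$points, B$points, interface_distance)
    inter <- is.finite(nnAB$distance)
    if (!any(inter)) {
      stop_tcrpmhc("no interface dots within interface_distance",
                   "tcrpmhc_undefined_sc")
    }
    keep <- inter
    if (any(!inter) && border_trim > 0) {
      rim <- nn_within(A$points[inter, , drop = FALSE],
                       A$points[!inter, , drop = FALSE], border_trim)
      keep_in <- !is.finite(rim$distance)
      if (!any(keep_in)) {
        stop_tcrpmhc("interface patch fully trimmed by border band",
                     "tcrpmhc_undefined_sc")
      }
      keep[inter] <- keep_in
    }
    nb <- nnAB$index[keep]
    d <- nnAB$distance[keep]
    s <- -rowSums(A$normals[keep, , drop = FALSE] *
                    B$normals[nb, , drop = FALSE]) * exp(-weight_w * d^2)
    list(median = median(s), n = sum(keep))
  }
  ab <- side(dots_a, dots_b)
  ba <- side(dots_b, dots_a)
  out <- list(sc = (ab$median + ba$median) / 2,
              median_a_to_b = ab$median, median_b_to_a = ba$median,
              n_dots_a = ab$n, n_dots_b = ba$n)
  class(out) <- "sc_result"
  out
}

#' @export
print.sc_result <- function(x, ...) {
  cat(sprintf("<sc_result> Sc = %.3f (medians %.3f / %.3f; %d / %d interface dots)\n",
              x$sc, x$median_a_to_b, x$median_b_to_a, x$n_dots_a, x$n_dots_b))
  invisible(x)
}

#' Shape complementarity of an atomic interface
#'
#' Builds solvent-accessible dot surfaces for both sides and evaluates
#' [sc_from_dots()].  For a TCR-pMHC interface the conventional sides
#' are the TCR chains versus peptide plus MHC heavy chain.
#'
#' @param side_a,side_b Atom tables for the two sides.
#' @param probe_radius,density,radii Dot-surface parameters, see
#'   [dot_surface()].
#' @inheritParams sc_from_dots
#' @return An `sc_result`.
#' @export
shape_complementarity <- function(side_a, side_b, probe_radius = 1.4,
                                  density = 15, radii = default_radii(),
                                  weight_w = 0.5, interface_distance = 1.5,
                                  border_trim = 1.5) {
  if (nrow(side_a) == 0 || nrow(side_b) == 0) {
    stop_tcrpmhc("empty interface side", "tcrpmhc_undefined_sc")
  }
  ## restrict dot generation to atoms near the interface: an atom can
  ## only carry interface dots if it lies within reach of the partner
  reach <- 2 * (max(default_radii()) + probe_radius) + interface_distance + 2
  near_mask <- function(A, B) {
    xb <- atom_xyz(B)
    vapply(seq_len(nrow(A)), function(i) {
      min(rowSums(sweep(xb, 2, as.numeric(A[i, c("x", "y", "z")]))^2)) <= reach^2
    }, logical(1))
  }
  ma <- near_mask(side_a, side_b)
  mb <- near_mask(side_b, side_a)
  if (!any(ma) || !any(mb)) {
    stop_tcrpmhc("sides are beyond interaction distance", "tcrpmhc_undefined_sc")
  }
  ## dots are generated only near the interface, but the whole side
  ## still occludes so the surface is not cut open at the selection edge
  da <- dot_surface(side_a[ma, , drop = FALSE], probe_radius, density, radii,
                    context = side_a[!ma, , drop = FALSE])
  db <- dot_surface(side_b[mb, , drop = FALSE], probe_radius, density, radii,
                    context = side_b[!mb, , drop = FALSE])
  sc_from_dots(da, db, weight_w = weight_w,
               interface_distance = interface_distance,
               border_trim = border_trim)
}

#' Write per-residue SASA or a dot surface as TSV
#'
#' @param x A `sasa_result` or `dot_surface`.
#' @param path Output path.
#' @export
write_surface <- function(x, path) {
  if (inherits(x, "sasa_result")) {
    write.table(x$per_residue, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "dot_surface")) {
    tab <- data.frame(x = x$points[, 1], y = x$points[, 2], z = x$points[, 3],
                      nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3],
                      atom = x$atom)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop_tcrpmhc("unsupported object", "tcrpmhc_parse_error")
  }
  invisible(path)
}
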