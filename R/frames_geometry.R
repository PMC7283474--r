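## pMHC reference frame and docking-geometry descriptors.
##
## The frame follows the groove convention: origin at the mean Calpha of
## the two groove-flanking helices, z normal to the helix plane pointing
## toward the TCR, x along the peptide groove with greater x toward the
## peptide C-terminus, y = z cross x (right-handed).

#' Build the pMHC groove reference frame
#'
#' Origin is the mean helix Calpha position.  The z axis is the
#' total-least-squares plane normal of the helix Calpha atoms (smallest
#' principal component), signed toward the mean TCR Calpha when TCR
#' chains are annotated, else toward input +z.  The x axis is the unit
#' projection onto that plane of the first principal axis of the peptide
#' Calpha atoms, oriented so the peptide C-terminal Calpha has the
#' greater x coordinate.  y = z cross x.
#'
#' @param complex An `annotated_complex` with `mhc_heavy` and `peptide`
#'   roles.
#' @return A `reference_frame`: list with `origin` and orthonormal unit
#'   vectors `x_axis`, `y_axis`, `z_axis` (right-handed).
#' @export
build_mhc_frame <- function(complex) {
  heavy <- role_atoms(complex, "mhc_heavy")
  hr <- complex$annotation$helix_ranges
  helix_ca <- heavy[heavy$elety == "CA" &
                      (in_range(heavy$resno, hr$alpha1) |
                         in_range(heavy$resno, hr$alpha2)), , drop = FALSE]
  n1 <- sum(in_range(helix_ca$resno, hr$alpha1))
  n2 <- sum(in_range(helix_ca$resno, hr$alpha2))
  if (n1 < 10 || n2 < 10) {
    stop_tcrpmhc(sprintf(
      "helix ranges resolve to too few Calpha atoms (alpha1: %d, alpha2: %d)",
      n1, n2), "tcrpmhc_frame_error")
  }
  pep <- role_atoms(complex, "peptide")
  pep_ca <- pep[pep$elety == "CA", , drop = FALSE]
  pep_ca <- pep_ca[order(pep_ca$resno, pep_ca$insert), , drop = FALSE]
  if (nrow(pep_ca) < 3) {
    stop_tcrpmhc("peptide has fewer than 3 Calpha atoms", "tcrpmhc_frame_error")
  }

  hx <- atom_xyz(helix_ca)
  origin <- colMeans(hx)
  pc <- prcomp(hx, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-6) {
    stop_tcrpmhc("helix Calpha atoms are collinear; frame undefined",
                 "tcrpmhc_frame_error")
  }
  z <- pc$rotation[, 3]
  ## sign: toward the TCR side
  tcr_roles <- intersect(c("tcr_alpha", "tcr_beta"),
                         unname(complex$annotation$roles))
  if (length(tcr_roles)) {
    tcr_ca <- do.call(rbind, lapply(tcr_roles, function(r) {
      a <- role_atoms(complex, r)
      atom_xyz(a[a$elety == "CA", , drop = FALSE])
    }))
    if (nrow(tcr_ca) && sum((colMeans(tcr_ca) - origin) * z) < 0) z <- -z
  } else if (z[3] < 0) {
    z <- -z
  }

  px <- atom_xyz(pep_ca)
  pep_pc <- prcomp(px, center = TRUE, scale. = FALSE)
  axis <- pep_pc$rotation[, 1]
  x <- axis - sum(axis * z) * z              # project into helix plane
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) {
    stop_tcrpmhc("peptide axis is perpendicular to the helix plane",
                 "tcrpmhc_frame_error")
  }
  x <- x / nx
  ## orient: C-terminal Calpha must have the greater x coordinate
  if (sum((px[nrow(px), ] - px[1, ]) * x) < 0) x <- -x
  y <- cross3(z, x)
  out <- list(origin = origin, x_axis = x, y_axis = y, z_axis = z)
  class(out) <- "reference_frame"
  out
}

in_range <- function(v, range) v >= range[1] & v <= range[2]

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame>\n")
  cat(sprintf("  origin: %8.3f %8.3f %8.3f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis")) {
    cat(sprintf("  %s: %8.4f %8.4f %8.4f\n", ax, x[[ax]][1], x[[ax]][2], x[[ax]][3]))
  }
  invisible(x)
}

## Express a point (or n x 3 matrix) in frame coordinates.
frame_coords <- function(frame, p) {
  R <- rbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (is.matrix(p)) t(R %*% (t(p) - frame$origin)) else
    as.numeric(R %*% (p - frame$origin))
}

#' V-domain center from the conserved disulfide anchors
#'
#' The domain center is the arithmetic mean of the two anchor atoms:
#' the Sgamma atoms of the conserved Cys pair, with Calpha substituting
#' at positions lacking Sgamma (flagged).
#'
#' @param complex An `annotated_complex` (or a chain atom table).
#' @param role `"tcr_alpha"` or `"tcr_beta"` (ignored for an atom table).
#' @param cys_pair Optional explicit residue-number pair; defaults to the
#'   annotation's `cys_pairs` entry or auto-detection.
#' @return Numeric 3-vector with attributes `ca_fallback` (logical
#'   2-vector) and `positions`.
#' @export
domain_center <- function(complex, role = NULL, cys_pair = NULL) {
  if (inherits(complex, "annotated_complex")) {
    stopifnot(!is.null(role))
    at <- role_atoms(complex, role)
    cys_pair <- cys_pair %||% complex$annotation$cys_pairs[[role]]
  } else {
    at <- complex
  }
  det <- detect_conserved_cys(at, override = cys_pair)
  anchors <- matrix(NA_real_, 2, 3)
  for (k in 1:2) {
    res <- at[at$resno == det$positions[k], , drop = FALSE]
    a <- res[res$elety == if (det$ca_fallback[k]) "CA" else "SG", , drop = FALSE]
    if (nrow(a) == 0) {
      stop_tcrpmhc(sprintf("anchor atom missing at residue %d", det$positions[k]),
                   "tcrpmhc_geometry_error")
    }
    anchors[k, ] <- atom_xyz(a)[1, ]
  }
  if (sum((anchors[1, ] - anchors[2, ])^2) < 1e-12) {
    stop_tcrpmhc("anchor positions coincide", "tcrpmhc_geometry_error")
  }
  structure(colMeans(anchors),
            ca_fallback = det$ca_fallback, positions = det$positions)
}

#' TCR center and its projection into the groove plane
#'
#' @param valpha_center,vbeta_center Numeric 3-vectors (input-frame
#'   coordinates of the Valpha and Vbeta disulfide centers).
#' @param frame A `reference_frame`.
#' @return List with `tcr_center` (midpoint, input coordinates),
#'   `valpha_center`, `vbeta_center` and `x_pos`, `y_pos` (frame
#'   coordinates of the midpoint, Angstrom).
#' @export
tcr_center_projection <- function(valpha_center, vbeta_center, frame) {
  center <- (as.numeric(valpha_center) + as.numeric(vbeta_center)) / 2
  fc <- frame_coords(frame, center)
  list(tcr_center = center,
       valpha_center = as.numeric(valpha_center),
       vbeta_center = as.numeric(vbeta_center),
       x_pos = fc[1], y_pos = fc[2])
}

#' Crossing (docking) angle of a TCR over the groove
#'
#' Angle in \[0, 180\] degrees between the groove-plane projection of the
#' Valpha-to-Vbeta vector and the +x axis (peptide N-to-C direction).
#'
#' @inheritParams tcr_center_projection
#' @return Angle in degrees.
#' @export
crossing_angle <- function(valpha_center, vbeta_center, frame) {
  v <- frame_coords(frame, as.numeric(vbeta_center)) -
    frame_coords(frame, as.numeric(valpha_center))
  proj <- v[1:2]
  np <- sqrt(sum(proj^2))
  if (np < 1e-9) {
    stop_tcrpmhc("inter-domain vector is perpendicular to the groove plane",
                 "tcrpmhc_geometry_error")
  }
  acos(max(-1, min(1, proj[1] / np))) * 180 / pi
}

#' Incident angle (tilt) of a TCR over the groove
#'
#' Default strategy `"elevation"`: the elevation angle in \[0, 90\]
#' degrees of the Valpha-to-Vbeta vector out of the groove plane
#' (arcsine of the absolute z component of the unit vector).  The
#' construction is pluggable via `strategy` because published tilt
#' definitions differ between surveys.
#'
#' @inheritParams tcr_center_projection
#' @param strategy Either `"elevation"` (default) or a function taking
#'   the frame-coordinate Valpha-to-Vbeta vector and returning degrees.
#' @return Angle in degrees.
#' @export
incident_angle <- function(valpha_center, vbeta_center, frame,
                           strategy = "elevation") {
  v <- frame_coords(frame, as.numeric(vbeta_center)) -
    frame_coords(frame, as.numeric(valpha_center))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) {
    stop_tcrpmhc("inter-domain vector has zero length", "tcrpmhc_geometry_error")
  }
  if (is.function(strategy)) return(strategy(v))
  asin(min(1, abs(v[3]) / nv)) * 180 / pi
}

#' Full docking geometry of an annotated complex
#'
#' Convenience wrapper: builds the groove frame, locates both V-domain
#' centers and reports all descriptors.
#'
#' @param complex An `annotated_complex` with all five roles.
#' @param frame Optional precomputed `reference_frame`.
#' @param strategy Incident-angle strategy, see [incident_angle()].
#' @return A `docking_geometry`: list with `crossing_angle`,
#'   `incident_angle` (degrees), `valpha_center`, `vbeta_center`,
#'   `tcr_center` (input coordinates), `x_pos`, `y_pos` (Angstrom),
#'   and `canonical_polarity` (`TRUE` when Valpha sits over the alpha2
#'   helix; a separate boolean diagnostic since the angles are reported
#'   as magnitudes).
#' @export
docking_geometry <- function(complex, frame = NULL, strategy = "elevation") {
  frame <- frame %||% build_mhc_frame(complex)
  va <- domain_center(complex, "tcr_alpha")
  vb <- domain_center(complex, "tcr_beta")
  proj <- tcr_center_projection(va, vb, frame)
  ## canonical polarity: Valpha sits over the alpha2 helix (same side of
  ## the groove, i.e. matching sign of the frame y coordinate)
  heavy <- role_atoms(complex, "mhc_heavy")
  hr <- complex$annotation$helix_ranges
  a2 <- heavy[heavy$elety == "CA" & in_range(heavy$resno, hr$alpha2), , drop = FALSE]
  a2_y <- mean(frame_coords(frame, atom_xyz(a2))[, 2])
  va_y <- frame_coords(frame, as.numeric(va))[2]
  out <- list(
    crossing_angle = crossing_angle(va, vb, frame),
    incident_angle = incident_angle(va, vb, frame, strategy = strategy),
    valpha_center = as.numeric(va), vbeta_center = as.numeric(vb),
    tcr_center = proj$tcr_center,
    x_pos = proj$x_pos, y_pos = proj$y_pos,
    canonical_polarity = sign(va_y) == sign(a2_y),
    ca_fallback = c(alpha = any(attr(va, "ca_fallback")),
                    beta = any(attr(vb, "ca_fallback")))
  )
  class(out) <- "docking_geometry"
  out
}

#' @export
print.docking_geometry <- function(x, ...) {
  cat(sprintf(
    "<docking_geometry> crossing %.1f deg, incident %.1f deg, x_pos %.1f A, y_pos %.1f A\n",
    x$crossing_angle, x$incident_angle, x$x_pos, x$y_pos))
  invisible(x)
}

## ---------------------------------------------------------------------
## Reference-table ranking

#' Rank a descriptor against a reference table
#'
#' Rank 1 is the highest value; the query is ranked against the table
#' rows and the percentile counts the query itself:
#' `percentile = round(100 * (1 - rank / (n_rows + 1)))`.
#'
#' @param value Descriptor value (degrees or Angstrom).
#' @param table Data frame with a column named as `column` (see
#'   [read_geometry_table()]), or a numeric vector of reference values.
#' @param column Column to rank against when `table` is a data frame.
#' @param direction Only `"highest_is_1"` is defined.
#' @return List with integer `rank` and `percentile`, and `n` (table
#'   rows plus the query).
#' @export
rank_percentile <- function(value, table, column = "incident_angle",
                            direction = "highest_is_1") {
  direction <- match.arg(direction, "highest_is_1")
  vals <- if (is.data.frame(table)) table[[column]] else as.numeric(table)
  if (length(vals) == 0) {
    stop_tcrpmhc("empty reference table", "tcrpmhc_ranking_error")
  }
  if (!is.finite(value) || anyNA(vals)) {
    stop_tcrpmhc("non-finite descriptor values", "tcrpmhc_ranking_error")
  }
  rank <- 1L + sum(vals > value)
  n <- length(vals) + 1L
  list(rank = rank, percentile = as.integer(round(100 * (1 - rank / n))), n = n)
}

#' Read or write a docking-geometry reference table
#'
#' Tab-separated with header columns `complex_id`, `crossing_angle`,
#' `incident_angle`, `x_pos`, `y_pos`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_geometry_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("complex_id", "crossing_angle", "incident_angle", "x_pos", "y_pos")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_tcrpmhc(paste("reference table lacks columns:",
                       paste(miss, collapse = ", ")), "tcrpmhc_ranking_error")
  }
  if (anyDuplicated(tab$complex_id)) {
    stop_tcrpmhc("duplicate complex ids in reference table",
                 "tcrpmhc_ranking_error")
  }
  num <- tab[, setdiff(need, "complex_id")]
  if (!all(vapply(num, function(v) all(is.finite(v)), logical(1)))) {
    stop_tcrpmhc("non-finite values in reference table", "tcrpmhc_ranking_error")
  }
  tab
}

#' @rdname read_geometry_table
#' @param table Data frame to write.
#' @export
write_geometry_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
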