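## Rigid-body superposition (Kabsch), fit-on/measure-on RMSDs and
## per-residue displacement profiles.

#' Optimal rigid superposition of matched coordinate sets (Kabsch)
#'
#' Returns the proper rotation `R` and translation `t` minimizing the
#' RMSD of `R %*% b + t` against `a` over given correspondences.
#' Reflection solutions are rejected (det(R) = +1).
#'
#' @param coords_a Reference coordinates, n x 3 matrix (n >= 3).
#' @param coords_b Moving coordinates, n x 3, row-matched to `coords_a`.
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (3-vector), `rmsd` (Angstrom, after transform) and `n_atoms_fit`.
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' s <- kabsch_superpose(a, a)
#' s$rmsd  # 0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) {
    stop_tcrpmhc(sprintf("coordinate counts differ (%d vs %d)", nrow(a), nrow(b)),
                 "tcrpmhc_pairing_error")
  }
  if (nrow(a) < 3) {
    stop_tcrpmhc("need at least 3 matched atoms", "tcrpmhc_pairing_error")
  }
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  H <- t(b0) %*% a0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (min(svd(a0)$d[2], svd(b0)$d[2]) < 1e-8) {
    warning("degenerate (collinear) coordinates; rotation about the axis is arbitrary")
  }
  tr <- ca - as.numeric(R %*% cb)
  fitted <- sweep(b %*% t(R), 2, tr, "+")
  out <- list(rotation = R, translation = tr,
              rmsd = sqrt(mean(rowSums((fitted - a)^2))),
              n_atoms_fit = nrow(a))
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d atoms\n",
              x$rmsd, x$n_atoms_fit))
  invisible(x)
}

#' Apply a superposition transform
#'
#' @param transform A `superposition`.
#' @param x Coordinates (n x 3), a `structure_model` or an
#'   `annotated_complex`.
#' @return The input with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  tx <- function(m) sweep(m %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (is.matrix(x)) return(tx(x))
  ac <- inherits(x, "annotated_complex")
  model <- if (ac) x$structure else x
  new <- tx(atom_xyz(model$atoms))
  model$atoms$x <- new[, 1]; model$atoms$y <- new[, 2]; model$atoms$z <- new[, 3]
  if (ac) { x$structure <- model; x } else model
}

## ---------------------------------------------------------------------
## Selections

#' Describe an atom selection on an annotated complex
#'
#' @param roles Character vector of chain roles to include.
#' @param resno Optional residue numbers (applied to every selected
#'   chain).
#' @param atoms One of `"ca"`, `"main_chain"` (N, CA, C, O),
#'   `"all_non_h"`, or a character vector of atom names (`"custom"`).
#' @param exclude Optional data frame with columns `resno` and
#'   optionally `atom` (atom-name prefix, e.g. side chains of one
#'   residue via its non-main-chain atoms) removed after selection; a
#'   row with `atom = "sidechain"` removes all non-main-chain atoms of
#'   that residue.
#' @return An `atom_selection` list.
#' @export
atom_selection <- function(roles, resno = NULL, atoms = "ca", exclude = NULL) {
  structure(list(roles = roles, resno = resno, atoms = atoms,
                 exclude = exclude),
            class = "atom_selection")
}

MAIN_CHAIN <- c("N", "CA", "C", "O")

## Resolve a selection to an atom table with a role column attached.
resolve_selection <- function(complex, selection) {
  parts <- lapply(selection$roles, function(r) {
    at <- role_atoms(complex, r)
    at$role <- r
    at
  })
  at <- do.call(rbind, parts)
  if (!is.null(selection$resno)) {
    at <- at[at$resno %in% selection$resno, , drop = FALSE]
  }
  sel_atoms <- selection$atoms
  if (identical(sel_atoms, "ca")) {
    at <- at[at$elety == "CA", , drop = FALSE]
  } else if (identical(sel_atoms, "main_chain")) {
    at <- at[at$elety %in% MAIN_CHAIN, , drop = FALSE]
  } else if (identical(sel_atoms, "all_non_h")) {
    ## role_atoms already removed hydrogens
  } else {
    at <- at[at$elety %in% sel_atoms, , drop = FALSE]
  }
  ex <- selection$exclude
  if (!is.null(ex)) {
    for (k in seq_len(nrow(ex))) {
      hit <- at$resno == ex$resno[k]
      if (!is.null(ex$atom) && !is.na(ex$atom[k])) {
        if (ex$atom[k] == "sidechain") {
          hit <- hit & !(at$elety %in% MAIN_CHAIN)
        } else {
          hit <- hit & at$elety == ex$atom[k]
        }
      }
      at <- at[!hit, , drop = FALSE]
    }
  }
  at
}

## Pair atoms of two resolved selections by (role, resno, insert, atom
## name).  Residues present in only one structure raise a pairing error
## naming them; atom-level mismatches within matched residues are
## dropped with a warning.
match_atoms <- function(ref_at, mov_at) {
  rkey <- function(at) paste(at$role, at$resno, at$insert, sep = "|")
  ref_res <- unique(rkey(ref_at)); mov_res <- unique(rkey(mov_at))
  only <- c(setdiff(ref_res, mov_res), setdiff(mov_res, ref_res))
  if (length(only)) {
    stop_tcrpmhc(paste("unmatched residues:",
                       paste(utils::head(only, 10), collapse = ", "),
                       if (length(only) > 10) "..." else ""),
                 "tcrpmhc_pairing_error")
  }
  akey <- function(at) paste(rkey(at), at$elety, sep = "|")
  ka <- akey(ref_at); kb <- akey(mov_at)
  common <- intersect(ka, kb)
  if (length(common) < length(ka) || length(common) < length(kb)) {
    warning(sprintf("%d unpaired atom(s) dropped from matched residues",
                    (length(ka) - length(common)) + (length(kb) - length(common))))
  }
  ref_at <- ref_at[match(common, ka), , drop = FALSE]
  mov_at <- mov_at[match(common, kb), , drop = FALSE]
  list(ref = ref_at, mov = mov_at)
}

#' Fit on one selection, measure RMSD on another
#'
#' The rigid transform is computed on `fit_selection` only; the RMSD is
#' then evaluated on `measure_selection` without refitting.  This is the
#' standard construction behind statements like "superposing the MHC
#' alpha1/alpha2 domains and measuring the peptide main-chain RMSD".
#'
#' @param ref,mov `annotated_complex` objects sharing author numbering
#'   within matched roles.
#' @param fit_selection,measure_selection [atom_selection()] objects.
#' @return List with `rmsd` (Angstrom, on the measure selection),
#'   `transform` (the `superposition` fitted on the fit selection),
#'   `n_fit`, `n_measure`, and `mov_aligned` (the whole moving complex
#'   after the transform, for downstream displacement profiles).
#' @export
fit_measure_rmsd <- function(ref, mov, fit_selection, measure_selection) {
  fit <- match_atoms(resolve_selection(ref, fit_selection),
                     resolve_selection(mov, fit_selection))
  sup <- kabsch_superpose(atom_xyz(fit$ref), atom_xyz(fit$mov))
  meas <- match_atoms(resolve_selection(ref, measure_selection),
                      resolve_selection(mov, measure_selection))
  moved <- apply_transform(sup, atom_xyz(meas$mov))
  rmsd <- sqrt(mean(rowSums((moved - atom_xyz(meas$ref))^2)))
  list(rmsd = rmsd, transform = sup,
       n_fit = sup$n_atoms_fit, n_measure = nrow(moved),
       mov_aligned = apply_transform(sup, mov))
}

#' Per-residue displacement profile of superposed structures
#'
#' Assumes `ref` and `mov` are already in a common frame (e.g. `mov` is
#' the `mov_aligned` element of [fit_measure_rmsd()]).  Reports the
#' same-atom distance per residue (default Calpha) and the residue of
#' maximal displacement, ties broken by lower residue number.
#'
#' @param ref,mov `annotated_complex` objects in a common frame.
#' @param selection An [atom_selection()]; its `atoms` field is
#'   overridden by `atom`.
#' @param atom Atom name whose displacement is tracked (default `"CA"`).
#' @return A `displacement_profile`: data frame with `role`, `resno`,
#'   `insert`, `resid`, `displacement` plus attributes `max_residue`
#'   (row of the maximum) and `rmsd` (over the profile).
#' @export
displacement_profile <- function(ref, mov, selection, atom = "CA") {
  selection$atoms <- atom
  ra <- resolve_selection(ref, selection)
  ma <- resolve_selection(mov, selection)
  ## residues lacking the tracked atom are skipped with a warning
  rk <- paste(ra$role, ra$resno, ra$insert)
  mk <- paste(ma$role, ma$resno, ma$insert)
  common <- intersect(rk, mk)
  if (length(common) < length(union(rk, mk))) {
    warning(sprintf("%d residue(s) lacking %s skipped",
                    length(union(rk, mk)) - length(common), atom))
  }
  ra <- ra[match(common, rk), , drop = FALSE]
  ma <- ma[match(common, mk), , drop = FALSE]
  d <- sqrt(rowSums((atom_xyz(ra) - atom_xyz(ma))^2))
  out <- data.frame(role = ra$role, resno = ra$resno, insert = ra$insert,
                    resid = ra$resid, displacement = d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$role, out$resno, out$insert), ]
  rownames(out) <- NULL
  attr(out, "max_residue") <- out[order(-out$displacement, out$resno)[1], ]
  attr(out, "rmsd") <- sqrt(mean(d^2))
  class(out) <- c("displacement_profile", "data.frame")
  out
}
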