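## Shared fixtures, all built in code.

## Minimal PDB text with three atoms in one chain.
toy_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.743  -4.123  1.00 10.00           C",
    "END")
}

## The same three atoms serialized as mmCIF.
toy_cif_lines <- function() {
  c("data_TOY",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 10.729 6.743 -4.123 1.00 10.00 ? 1 ALA A C 1")
}

## Bare atom table row(s) for geometric fixtures.
atoms_at <- function(xyz, elety = "CA", elesy = "C", chain = "A",
                     resno = NULL, resid = "GLY") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  data.frame(type = "ATOM", eleno = seq_len(n), elety = elety,
             alt = NA_character_, resid = resid, chain = chain,
             resno = resno %||% seq_len(n), insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1, elesy = elesy, is_het = FALSE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random proper rotation matrix.
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

## Apply a rigid transform to a whole annotated complex.
transform_complex <- function(cmplx, R = diag(3), t = c(0, 0, 0)) {
  at <- cmplx$structure$atoms
  new <- sweep(as.matrix(at[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  at$x <- new[, 1]; at$y <- new[, 2]; at$z <- new[, 3]
  cmplx$structure$atoms <- at
  cmplx
}

## Shift selected atoms of one chain (optionally one residue set).
shift_chain <- function(cmplx, chain, delta, resno = NULL) {
  at <- cmplx$structure$atoms
  sel <- at$chain %in% chain
  if (!is.null(resno)) sel <- sel & at$resno %in% resno
  at$x[sel] <- at$x[sel] + delta[1]
  at$y[sel] <- at$y[sel] + delta[2]
  at$z[sel] <- at$z[sel] + delta[3]
  cmplx$structure$atoms <- at
  cmplx
}

## Standard toy complex reused across tests (no contact layout).
default_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_toy_tcr_pmhc(toy_complex_spec(
        crossing_angle = 51, incident_angle = 20, x_pos = 3, y_pos = -1.5))
    }
    cache
  }
})
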