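## Structure reading, normalization and complex annotation.
##
## Structures are held as a `structure_model`: an atom table in bio3d-like
## column layout plus an identifier.  Author residue numbering (as
## deposited) is the canonical key throughout; the package never renumbers.

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF file into a normalized atom table.  All ATOM and
#' HETATM records are kept (waters are flagged as hetero and retained).
#' When a residue carries alternate locations, only the highest-occupancy
#' conformer of each atom is retained, with ties broken by altloc letter
#' order; the choice is reported via [message()].
#'
#' @param path Path to a structure file.
#' @param format One of `"auto"` (default; guessed from the file
#'   extension), `"pdb"` or `"cif"`.
#' @param id Identifier stored in the model; defaults to the file base
#'   name.
#' @return A `structure_model`: a list with elements `id` (character),
#'   `atoms` (data frame with columns `type`, `eleno`, `elety`, `alt`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `elesy`,
#'   `is_het`) and `resolution` (numeric or `NA`).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' m <- read_structure(pdb)
#' nrow(m$atoms)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif", "mmcif"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_tcrpmhc(sprintf("structure file not found: %s", path),
                 "tcrpmhc_parse_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "cif", mmcif = "cif",
      stop_tcrpmhc(
        sprintf("cannot guess format from extension '.%s'; pass format=", ext),
        "tcrpmhc_format_error"))
  }
  if (format == "mmcif") format <- "cif"
  ## rm.alt = FALSE: altloc resolution follows the package's own
  ## highest-occupancy policy below, not the reader's first-letter rule
  raw <- withCallingHandlers(
    tryCatch(
      if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
      error = function(e) {
        stop_tcrpmhc(sprintf("failed to parse %s as %s: %s",
                             path, format, conditionMessage(e)),
                     "tcrpmhc_parse_error")
      }),
    warning = function(w) {
      ## the reader's advisory notices (beta mmCIF support, unparsed
      ## secondary-structure records) are not about the atom records
      if (grepl("beta version|helix/sheet", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  at <- raw$atom
  atoms <- data.frame(
    type   = at$type,
    eleno  = at$eleno,
    elety  = at$elety,
    alt    = at$alt,
    resid  = at$resid,
    chain  = at$chain,
    resno  = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    elesy = guess_element(at$elesy, at$elety),
    stringsAsFactors = FALSE
  )
  atoms$is_het <- atoms$type == "HETATM"
  atoms <- resolve_altloc(atoms)
  structure_model(atoms, id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and the synthetic
#' structure generators.  Validates invariants: finite coordinates,
#' non-empty elements, occupancies in \[0, 1\], unique chain ids per
#' (chain, resno, insert, elety) key.
#'
#' @param atoms Atom data frame (see [read_structure()] for columns;
#'   missing bookkeeping columns are filled with defaults).
#' @param id Identifier string.
#' @param resolution Optional resolution in Angstrom.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, id = "model", resolution = NA_real_) {
  defaults <- list(type = "ATOM", eleno = NA_integer_, alt = NA_character_,
                   insert = "", o = 1, is_het = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (is.null(atoms$eleno) || anyNA(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(NULL, atoms$elety)
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop_tcrpmhc(paste("atom table lacks columns:", paste(miss, collapse = ", ")),
                 "tcrpmhc_parse_error")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_tcrpmhc("non-finite atom coordinates", "tcrpmhc_parse_error")
  }
  if (any(!nzchar(atoms$elesy) | is.na(atoms$elesy))) {
    stop_tcrpmhc("empty element symbol", "tcrpmhc_parse_error")
  }
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop_tcrpmhc("occupancy outside [0, 1]", "tcrpmhc_parse_error")
  }
  rownames(atoms) <- NULL
  out <- list(id = id, atoms = atoms, resolution = resolution)
  class(out) <- "structure_model"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat(sprintf("<structure_model> %s: %d atoms, %d chains (%s)\n",
              x$id, nrow(x$atoms), length(ch),
              paste(sprintf("%s:%d", names(ch), as.integer(ch)), collapse = " ")))
  invisible(x)
}

## Derive the chemical element from the PDB element column, falling back
## to the atom-name convention (leading digits stripped; one- or
## two-letter symbol).
guess_element <- function(elesy, elety) {
  if (is.null(elesy)) elesy <- rep(NA_character_, length(elety))
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy <- trimws(elesy)
  if (any(bad)) {
    nm <- gsub("[^A-Za-z]", "", elety[bad])
    two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "CA2", "SE")
    first <- toupper(substr(nm, 1, 1))
    ## distinguish e.g. "CA" (calcium het) is rare in ATOM records; for
    ## protein atom names the first letter is the element
    elesy[bad] <- ifelse(nzchar(first), first, "X")
    long <- toupper(nm) %in% two & nchar(nm) == 2
    elesy[bad][long] <- toupper(nm[long])
  }
  toupper(elesy)
}

is_hydrogen <- function(atoms) atoms$elesy %in% c("H", "D")

is_water <- function(atoms) atoms$resid %in% c("HOH", "WAT", "DOD")

## Altloc policy: within each (chain, resno, insert, elety) group keep the
## highest-occupancy record, ties broken by altloc letter order.
resolve_altloc <- function(atoms) {
  has_alt <- !is.na(atoms$alt) & nzchar(atoms$alt) & atoms$alt != " "
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(key, -atoms$o, ifelse(is.na(atoms$alt), "", atoms$alt))
  keep <- !duplicated(key[ord])
  sel <- sort(ord[keep])
  dropped <- nrow(atoms) - length(sel)
  if (dropped > 0) {
    message(sprintf(
      "altloc groups resolved: kept highest-occupancy conformer, dropped %d atom(s)",
      dropped))
  }
  out <- atoms[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals), so a
#' write/read round trip reproduces coordinates to 1e-3 Angstrom.
#'
#' @param model A `structure_model` or `annotated_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (inherits(model, "annotated_complex")) model <- model$structure
  at <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = at$type,
    resno = at$resno,
    resid = at$resid,
    eleno = at$eleno,
    elety = at$elety,
    chain = at$chain,
    insert = ifelse(nzchar(at$insert), at$insert, NA),
    o = at$o,
    b = rep(0, nrow(at)),
    elesy = at$elesy
  )
  invisible(path)
}

## Fill optional bookkeeping columns so bare coordinate tables can be
## fed straight into the atom-level functions.
as_atom_table <- function(atoms) {
  if (inherits(atoms, "annotated_complex")) atoms <- atoms$structure
  if (inherits(atoms, "structure_model")) atoms <- atoms$atoms
  defaults <- list(type = "ATOM", alt = NA_character_, insert = "",
                   resid = "UNK", o = 1, is_het = FALSE)
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(NULL, atoms$elety)
  atoms
}

atom_xyz <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

## ---------------------------------------------------------------------
## Annotation

#' Default CDR/HV4 loop ranges (IMGT-like numbering)
#'
#' Loop boundaries are data, not code: results are only reproducible
#' given the ranges actually used, so every range can be overridden per
#' structure through the annotation config.  Defaults follow the
#' IMGT-like convention CDR1 27-38, CDR2 56-65, HV4 81-86, CDR3 105-117.
#'
#' @return Named list with `CDR1`, `CDR2`, `HV4`, `CDR3` two-element
#'   integer vectors (first, last residue).
#' @export
default_cdr_ranges <- function() {
  list(CDR1 = c(27L, 38L), CDR2 = c(56L, 65L),
       HV4 = c(81L, 86L), CDR3 = c(105L, 117L))
}

#' Default MHC class I helix ranges
#'
#' The groove-flanking helices on the heavy chain: alpha1 = residues
#' 50-86, alpha2 = 138-176 (author numbering, overridable).
#'
#' @return Named list with `alpha1` and `alpha2` two-element vectors.
#' @export
default_helix_ranges <- function() {
  list(alpha1 = c(50L, 86L), alpha2 = c(138L, 176L))
}

#' Construct a complex annotation
#'
#' @param roles Named character vector mapping chain id to role; roles
#'   are `"mhc_heavy"`, `"b2m"`, `"peptide"`, `"tcr_alpha"`, `"tcr_beta"`.
#' @param cdr_ranges List with `tcr_alpha` and `tcr_beta` elements, each
#'   as [default_cdr_ranges()].  Missing chains get the defaults.
#' @param helix_ranges As [default_helix_ranges()].
#' @param cys_pairs Optional list with `tcr_alpha`/`tcr_beta` two-element
#'   residue-number vectors naming the conserved intrachain disulfide;
#'   `NULL` requests auto-detection.
#' @return A `complex_annotation`.
#' @export
complex_annotation <- function(roles,
                               cdr_ranges = NULL,
                               helix_ranges = NULL,
                               cys_pairs = NULL) {
  roles <- unlist(roles)
  bad <- setdiff(unname(roles), ROLES)
  if (length(bad)) {
    stop_tcrpmhc(paste("unknown roles:", paste(bad, collapse = ", ")),
                 "tcrpmhc_annotation_error")
  }
  dup <- names(which(table(roles) > 1))
  if (length(dup)) {
    stop_tcrpmhc(paste("role assigned to more than one chain:",
                       paste(dup, collapse = ", ")),
                 "tcrpmhc_annotation_error")
  }
  cdr_ranges <- cdr_ranges %||% list()
  for (tc in c("tcr_alpha", "tcr_beta")) {
    cdr_ranges[[tc]] <- fill_ranges(cdr_ranges[[tc]], default_cdr_ranges())
    check_ranges_disjoint(cdr_ranges[[tc]], tc)
  }
  helix_ranges <- fill_ranges(helix_ranges, default_helix_ranges())
  if (!is.null(cys_pairs)) {
    for (tc in names(cys_pairs)) {
      cp <- cys_pairs[[tc]]
      if (length(cp) != 2 || cp[1] == cp[2]) {
        stop_tcrpmhc(sprintf("cys pair for %s must be 2 distinct positions", tc),
                     "tcrpmhc_annotation_error")
      }
    }
  }
  out <- list(roles = roles, cdr_ranges = cdr_ranges,
              helix_ranges = helix_ranges, cys_pairs = cys_pairs)
  class(out) <- "complex_annotation"
  out
}

fill_ranges <- function(given, defaults) {
  out <- defaults
  for (nm in names(given)) out[[nm]] <- as.integer(given[[nm]])
  out
}

check_ranges_disjoint <- function(ranges, label) {
  ivs <- do.call(rbind, ranges)
  if (is.null(ivs) || nrow(ivs) < 2) return(invisible())
  ord <- order(ivs[, 1])
  ivs <- ivs[ord, , drop = FALSE]
  if (any(ivs[-1, 1] <= ivs[-nrow(ivs), 2])) {
    stop_tcrpmhc(sprintf("overlapping loop ranges for %s", label),
                 "tcrpmhc_annotation_error")
  }
  invisible()
}

#' Read an annotation config file
#'
#' The config is YAML with keys `roles` (chain id to role map; a chain
#' may be given as `auto` together with role `peptide` via
#' `peptide: auto`), `cdr_ranges`, `helix_ranges` and `cys_pairs`.
#'
#' @param path YAML file path.
#' @return A list suitable for [annotate_complex()]'s `config` argument.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) {
    stop_tcrpmhc(sprintf("annotation file not found: %s", path),
                 "tcrpmhc_annotation_error")
  }
  yaml::read_yaml(path)
}

#' Attach chain roles and loop ranges to a structure
#'
#' @param structure A `structure_model` (an already annotated complex is
#'   accepted; re-annotating with the same config is a no-op).
#' @param config List with elements `roles` (named chain-to-role map,
#'   where the value `"auto"` for key `peptide` — or a role map entry
#'   `peptide = "auto"` — requests peptide auto-detection: the unique
#'   protein chain of 8-13 residues), and optionally `cdr_ranges`,
#'   `helix_ranges`, `cys_pairs`.
#' @return An `annotated_complex`: list with `structure` and
#'   `annotation` elements.
#' @export
annotate_complex <- function(structure, config) {
  if (inherits(structure, "annotated_complex")) structure <- structure$structure
  stopifnot(inherits(structure, "structure_model"))
  roles <- unlist(config$roles)
  auto_pep <- FALSE
  if (!is.null(roles)) {
    ## allow either  roles = c(C = "peptide")  or  roles = c(peptide = "auto")
    auto_idx <- which(roles == "auto" | (names(roles) == "peptide" & roles == "auto"))
    if (length(auto_idx)) {
      auto_pep <- TRUE
      roles <- roles[-auto_idx]
    }
  }
  if (isTRUE(config$peptide == "auto")) auto_pep <- TRUE
  roles <- roles[!is.na(roles)]
  if (auto_pep) {
    pep_chain <- autodetect_peptide(structure, exclude = names(roles))
    roles <- c(roles, setNames("peptide", pep_chain))
  }
  present <- unique(structure$atoms$chain)
  missing_chain <- setdiff(names(roles), present)
  if (length(missing_chain)) {
    stop_tcrpmhc(paste("annotated chains absent from structure:",
                       paste(missing_chain, collapse = ", ")),
                 "tcrpmhc_annotation_error")
  }
  ann <- complex_annotation(roles,
                            cdr_ranges = config$cdr_ranges,
                            helix_ranges = config$helix_ranges,
                            cys_pairs = config$cys_pairs)
  out <- list(structure = structure, annotation = ann)
  class(out) <- "annotated_complex"
  out
}

#' @export
print.annotated_complex <- function(x, ...) {
  print(x$structure)
  r <- x$annotation$roles
  cat("  roles:", paste(sprintf("%s=%s", names(r), r), collapse = " "), "\n")
  invisible(x)
}

## The unique protein chain of length 8-13 residues is the peptide.
autodetect_peptide <- function(structure, exclude = character()) {
  at <- structure$atoms
  at <- at[!at$is_het & !is_water(at), , drop = FALSE]
  lens <- tapply(paste(at$resno, at$insert), at$chain,
                 function(k) length(unique(k)))
  lens <- lens[!(names(lens) %in% exclude)]
  cand <- names(lens)[lens >= 8 & lens <= 13]
  if (length(cand) != 1) {
    stop_tcrpmhc(sprintf(
      "peptide auto-detection: %d candidate chains of length 8-13 (%s)",
      length(cand), paste(cand, collapse = ", ")),
      "tcrpmhc_annotation_error")
  }
  cand
}

## ---------------------------------------------------------------------
## Chain/role accessors

role_chain <- function(complex, role) {
  r <- complex$annotation$roles
  ch <- names(r)[r == role]
  if (length(ch) != 1) {
    stop_tcrpmhc(sprintf("complex has %d chains with role '%s'",
                         length(ch), role), "tcrpmhc_annotation_error")
  }
  ch
}

has_role <- function(complex, role) any(complex$annotation$roles == role)

role_atoms <- function(complex, role, protein_only = TRUE, heavy_only = TRUE) {
  at <- complex$structure$atoms
  at <- at[at$chain == role_chain(complex, role), , drop = FALSE]
  if (protein_only) at <- at[!at$is_het & !is_water(at), , drop = FALSE]
  if (heavy_only) at <- at[!is_hydrogen(at), , drop = FALSE]
  at
}

chain_atoms <- function(structure, chain_id) {
  if (inherits(structure, "annotated_complex")) structure <- structure$structure
  structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
}

## ---------------------------------------------------------------------
## Conserved disulfide detection

#' Detect the conserved intrachain disulfide of a V domain
#'
#' Finds the unique Cys pair of a TCR chain whose Sgamma-Sgamma distance
#' is at most `max_dist` (default 2.5 Angstrom).  When a configured
#' position lacks an Sgamma atom, its Calpha substitutes for downstream
#' domain-center calculations and the fallback is flagged.
#'
#' @param chain_atoms Atom table of one TCR chain (or a
#'   `structure_model`/`annotated_complex` plus `chain_id`).
#' @param chain_id Chain to use when a full model is given.
#' @param override Optional two-element residue-number vector naming the
#'   pair explicitly (skips detection).
#' @param max_dist Sgamma-Sgamma distance cutoff in Angstrom.
#' @return List with `positions` (two residue numbers), `ca_fallback`
#'   (logical, per position) and `distance` (Angstrom, `NA` under
#'   Calpha fallback).
#' @export
detect_conserved_cys <- function(chain_atoms, chain_id = NULL,
                                 override = NULL, max_dist = 2.5) {
  if (inherits(chain_atoms, c("structure_model", "annotated_complex"))) {
    stopifnot(!is.null(chain_id))
    chain_atoms <- chain_atoms(chain_atoms, chain_id)
  }
  at <- chain_atoms
  if (length(unique(at$resno)) < 2) {
    stop_tcrpmhc("chain has fewer than 2 residues", "tcrpmhc_detection_error")
  }
  if (!is.null(override)) {
    if (length(override) != 2 || override[1] == override[2]) {
      stop_tcrpmhc("override must name 2 distinct positions",
                   "tcrpmhc_detection_error")
    }
    return(cys_pair_from_positions(at, override))
  }
  sg <- at[at$resid == "CYS" & at$elety == "SG", , drop = FALSE]
  if (nrow(sg) >= 2) {
    xyz <- atom_xyz(sg)
    d <- as.matrix(stats::dist(xyz))
    qual <- which(upper.tri(d) & d <= max_dist, arr.ind = TRUE)
    if (nrow(qual) == 1) {
      i <- qual[1, 1]; j <- qual[1, 2]
      return(list(positions = c(sg$resno[i], sg$resno[j]),
                  ca_fallback = c(FALSE, FALSE),
                  distance = d[i, j]))
    }
    if (nrow(qual) > 1) {
      stop_tcrpmhc(sprintf(
        "%d Cys pairs within %.1f A; specify cys_pairs in the annotation",
        nrow(qual), max_dist), "tcrpmhc_detection_error")
    }
  }
  stop_tcrpmhc(sprintf("no Cys pair with Sgamma atoms within %.1f A", max_dist),
               "tcrpmhc_detection_error")
}

cys_pair_from_positions <- function(at, positions) {
  fallback <- logical(2)
  anchors <- vector("list", 2)
  for (k in 1:2) {
    res <- at[at$resno == positions[k], , drop = FALSE]
    if (nrow(res) == 0) {
      stop_tcrpmhc(sprintf("residue %d not present in chain", positions[k]),
                   "tcrpmhc_detection_error")
    }
    sg <- res[res$elety == "SG", , drop = FALSE]
    if (nrow(sg) == 1) {
      anchors[[k]] <- atom_xyz(sg)[1, ]
    } else {
      ca <- res[res$elety == "CA", , drop = FALSE]
      if (nrow(ca) == 0) {
        stop_tcrpmhc(sprintf("residue %d has neither SG nor CA", positions[k]),
                     "tcrpmhc_detection_error")
      }
      anchors[[k]] <- atom_xyz(ca)[1, ]
      fallback[k] <- TRUE
    }
  }
  list(positions = positions, ca_fallback = fallback,
       distance = if (any(fallback)) NA_real_ else
         sqrt(sum((anchors[[1]] - anchors[[2]])^2)))
}
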