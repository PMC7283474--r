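## Interface contacts and per-CDR contact tables.
##
## A contact is a pair of non-hydrogen atoms from different role groups
## at 4.0 Angstrom or less (inclusive boundary).  Contact tables bucket
## TCR-side atoms into CDR1/CDR2/HV4/CDR3 per chain by residue range,
## with a visible framework bucket so nothing is silently dropped.

#' Atomic contacts between two atom groups
#'
#' Every pair of non-hydrogen atoms, one from each group, at distance
#' `cutoff` or less yields one record.  Symmetric in group order.
#'
#' @param group_a,group_b Atom tables (rows of a `structure_model`'s
#'   `atoms` data frame).
#' @param cutoff Distance cutoff in Angstrom, inclusive (default 4.0).
#' @param include_h Keep hydrogen/deuterium atoms (default `FALSE`).
#' @return A data frame of class `contact_records` with one row per
#'   contact: `chain_a`, `resno_a`, `insert_a`, `resid_a`, `atom_a`,
#'   `elesy_a`, the same `_b` columns, `distance` (Angstrom) and
#'   `category` (`"vdw"`; [detect_hbonds()] upgrades qualifying rows).
#' @export
atomic_contacts <- function(group_a, group_b, cutoff = 4.0,
                            include_h = FALSE) {
  if (cutoff <= 0) stop_tcrpmhc("cutoff must be positive", "tcrpmhc_parse_error")
  group_a <- as_atom_table(group_a)
  group_b <- as_atom_table(group_b)
  if (!include_h) {
    group_a <- group_a[!is_hydrogen(group_a), , drop = FALSE]
    group_b <- group_b[!is_hydrogen(group_b), , drop = FALSE]
  }
  empty <- data.frame(
    chain_a = character(), resno_a = integer(), insert_a = character(),
    resid_a = character(), atom_a = character(), elesy_a = character(),
    chain_b = character(), resno_b = integer(), insert_b = character(),
    resid_b = character(), atom_b = character(), elesy_b = character(),
    distance = numeric(), category = character(), stringsAsFactors = FALSE)
  class(empty) <- c("contact_records", "data.frame")
  if (nrow(group_a) == 0 || nrow(group_b) == 0) return(empty)

  xa <- atom_xyz(group_a)
  xb <- atom_xyz(group_b)
  ## chunked pair search keeps memory bounded for large groups
  chunk <- max(1L, floor(2e6 / max(1L, nrow(xb))))
  hits_i <- integer(0); hits_j <- integer(0); hits_d <- numeric(0)
  c2 <- cutoff^2
  for (start in seq(1L, nrow(xa), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(xa))
    d2 <- outer(rowSums(xa[idx, , drop = FALSE]^2), rowSums(xb^2), "+") -
      2 * xa[idx, , drop = FALSE] %*% t(xb)
    w <- which(d2 <= c2 + 1e-9, arr.ind = TRUE)
    if (nrow(w)) {
      hits_i <- c(hits_i, idx[w[, 1]])
      hits_j <- c(hits_j, w[, 2])
      hits_d <- c(hits_d, sqrt(pmax(0, d2[w])))
    }
  }
  if (!length(hits_i)) return(empty)
  out <- data.frame(
    chain_a = group_a$chain[hits_i], resno_a = group_a$resno[hits_i],
    insert_a = group_a$insert[hits_i], resid_a = group_a$resid[hits_i],
    atom_a = group_a$elety[hits_i], elesy_a = group_a$elesy[hits_i],
    chain_b = group_b$chain[hits_j], resno_b = group_b$resno[hits_j],
    insert_b = group_b$insert[hits_j], resid_b = group_b$resid[hits_j],
    atom_b = group_b$elety[hits_j], elesy_b = group_b$elesy[hits_j],
    distance = hits_d, category = "vdw", stringsAsFactors = FALSE)
  out <- out[out$distance > 0, , drop = FALSE]   # guard against self-pairs
  out <- out[order(out$resno_a, out$atom_a, out$resno_b, out$atom_b), ]
  rownames(out) <- NULL
  class(out) <- c("contact_records", "data.frame")
  out
}

#' Flag hydrogen bonds among contact records
#'
#' Distance-only default criterion: a contact is flagged `hbond` when
#' one heavy atom is donor-typed (N, O or S) and the other
#' acceptor-typed (N or O), at `max_dist` (3.5 Angstrom) or less.  No
#' angle term is applied (crystal structures rarely carry hydrogens).
#'
#' @param contacts A `contact_records` data frame.
#' @param max_dist Donor-acceptor heavy-atom distance limit, Angstrom.
#' @return The same data frame with qualifying rows re-categorised.
#' @export
detect_hbonds <- function(contacts, max_dist = 3.5) {
  donors <- c("N", "O", "S")
  acceptors <- c("N", "O")
  unknown <- !(contacts$elesy_a %in% c(donors, "C", "P", "H")) |
    !(contacts$elesy_b %in% c(donors, "C", "P", "H"))
  if (any(unknown)) {
    warning(sprintf("%d contact(s) with unrecognised atom typing left as vdw",
                    sum(unknown)))
  }
  da <- (contacts$elesy_a %in% donors & contacts$elesy_b %in% acceptors) |
    (contacts$elesy_b %in% donors & contacts$elesy_a %in% acceptors)
  contacts$category[da & contacts$distance <= max_dist & !unknown] <- "hbond"
  contacts
}

## Bucket a TCR residue number into a loop label ("CDR1".."CDR3") or "FR".
loop_of <- function(resno, ranges) {
  out <- rep("FR", length(resno))
  for (loop in names(ranges)) {
    out[in_range(resno, ranges[[loop]])] <- loop
  }
  out
}

#' Per-CDR contact table of a TCR-pMHC interface
#'
#' Counts atomic contacts between each TCR loop (CDR1, CDR2, HV4, CDR3
#' of either chain, plus framework) and the peptide and MHC heavy chain.
#' Waters are excluded; beta-2-microglobulin contacts are tallied
#' separately (the MHC column means the heavy chain only).
#'
#' @param complex An `annotated_complex` with complete roles and CDR
#'   ranges.
#' @param cutoff Contact cutoff in Angstrom, inclusive (default 4.0).
#' @return A `contact_table`: list with `counts` (2 x 10 integer matrix,
#'   rows `peptide`/`mhc`, columns `CDR1a..CDR3a`, `CDR1b..CDR3b`,
#'   `FRa`, `FRb`), `loop_total` (per-target sum over the 8 CDR loops),
#'   `grand_total` (including framework), `b2m_contacts` and
#'   `water_contacts` (counts), `contacts` (the raw records) and
#'   `cutoff`.
#' @export
build_contact_table <- function(complex, cutoff = 4.0) {
  for (r in c("peptide", "mhc_heavy", "tcr_alpha", "tcr_beta")) {
    if (!has_role(complex, r)) {
      stop_tcrpmhc(sprintf("complex lacks role '%s'", r),
                   "tcrpmhc_annotation_error")
    }
  }
  ann <- complex$annotation
  tcr <- rbind(role_atoms(complex, "tcr_alpha"),
               role_atoms(complex, "tcr_beta"))
  alpha_chain <- role_chain(complex, "tcr_alpha")
  targets <- list(peptide = role_atoms(complex, "peptide"),
                  mhc = role_atoms(complex, "mhc_heavy"))

  labels <- loop_labels()
  counts <- matrix(0L, nrow = 2, ncol = length(labels),
                   dimnames = list(c("peptide", "mhc"), labels))
  all_contacts <- list()
  for (tg in names(targets)) {
    cc <- atomic_contacts(tcr, targets[[tg]], cutoff = cutoff)
    if (nrow(cc)) {
      is_alpha <- cc$chain_a == alpha_chain
      ranges <- ifelse(is_alpha, "tcr_alpha", "tcr_beta")
      loops <- character(nrow(cc))
      for (tc in c("tcr_alpha", "tcr_beta")) {
        sel <- ranges == tc
        loops[sel] <- loop_of(cc$resno_a[sel], ann$cdr_ranges[[tc]])
      }
      lab <- paste0(loops, ifelse(is_alpha, "a", "b"))
      tab <- table(factor(lab, levels = labels))
      counts[tg, ] <- as.integer(tab)
      cc$loop <- lab
      cc$target <- tg
      all_contacts[[tg]] <- cc
    }
  }

  ## side tallies: beta-2-microglobulin and waters
  b2m_n <- 0L
  if (has_role(complex, "b2m")) {
    b2m_n <- nrow(atomic_contacts(tcr, role_atoms(complex, "b2m"),
                                  cutoff = cutoff))
  }
  at <- complex$structure$atoms
  wat <- at[is_water(at) & !is_hydrogen(at), , drop = FALSE]
  water_n <- if (nrow(wat)) nrow(atomic_contacts(tcr, wat, cutoff = cutoff)) else 0L

  cdr_cols <- setdiff(labels, c("FRa", "FRb"))
  out <- list(
    counts = counts,
    loop_total = rowSums(counts[, cdr_cols]),
    grand_total = rowSums(counts),
    b2m_contacts = b2m_n,
    water_contacts = water_n,
    contacts = if (length(all_contacts)) do.call(rbind, all_contacts) else NULL,
    cutoff = cutoff
  )
  class(out) <- "contact_table"
  out
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> cutoff %.1f A\n", x$cutoff))
  print(cbind(x$counts, total = x$grand_total))
  if (x$b2m_contacts) cat("  b2m contacts:", x$b2m_contacts, "\n")
  if (x$water_contacts) cat("  water contacts:", x$water_contacts, "\n")
  invisible(x)
}

#' Contact counts as percentages of each target total
#'
#' Each cell becomes `round(100 * count / target total)` (nearest
#' integer).  A target with zero contacts yields `NA` cells.
#'
#' @param table A `contact_table`, or a 2-row count matrix.
#' @param denominator `"grand"` (default; framework included in the
#'   total, matching the convention that totals reflect all TCR
#'   contacts) or `"loops"`.
#' @return Matrix of integer percentages with the shape of `counts`.
#' @export
contact_percentages <- function(table, denominator = c("grand", "loops")) {
  denominator <- match.arg(denominator)
  counts <- if (inherits(table, "contact_table")) table$counts else as.matrix(table)
  cdr_cols <- intersect(colnames(counts), setdiff(loop_labels(), c("FRa", "FRb")))
  totals <- if (denominator == "grand") rowSums(counts) else
    rowSums(counts[, cdr_cols, drop = FALSE])
  pct <- counts
  for (i in seq_len(nrow(counts))) {
    pct[i, ] <- if (totals[i] > 0)
      as.integer(round(100 * counts[i, ] / totals[i])) else NA_integer_
  }
  pct
}

#' Per-chain share of interface contacts
#'
#' Sums the four loops of one TCR chain plus its framework bucket and
#' reports the count and its rounded percentage of the target total.
#'
#' @param table A `contact_table`.
#' @param chain `"alpha"` or `"beta"`.
#' @param target `"mhc"` or `"peptide"`.
#' @return List with `count`, `percent` (integer, `NA` when the target
#'   total is zero) and `total`.
#' @export
chain_share <- function(table, chain = c("alpha", "beta"),
                        target = c("mhc", "peptide")) {
  chain <- match.arg(chain)
  target <- match.arg(target)
  suffix <- if (chain == "alpha") "a" else "b"
  cols <- paste0(c(LOOPS, "FR"), suffix)
  count <- sum(table$counts[target, cols])
  total <- table$grand_total[[target]]
  list(count = as.integer(count),
       percent = if (total > 0) as.integer(round(100 * count / total)) else NA_integer_,
       total = as.integer(total))
}

#' Write contact records or a contact table as TSV
#'
#' @param x `contact_records` or `contact_table`.
#' @param path Output path.
#' @export
write_contacts <- function(x, path) {
  if (inherits(x, "contact_table")) {
    tab <- data.frame(target = rownames(x$counts), x$counts,
                      loop_total = x$loop_total, grand_total = x$grand_total,
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
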