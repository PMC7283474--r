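## Orchestration: run every structural analysis on an annotated complex
## and collect the results in one machine-readable report.

#' Full structural analysis of a TCR-pMHC complex
#'
#' Runs the docking-geometry, interface-contact and surface analyses
#' and aggregates them into a single report.  With identical inputs and
#' parameters the report body is deterministic (only the provenance
#' timestamp varies between runs).
#'
#' @param complex An `annotated_complex` with all five chain roles, or a
#'   `structure_model` plus `config`.
#' @param config Annotation config (see [annotate_complex()]) when
#'   `complex` is not yet annotated.
#' @param cutoff Contact cutoff, Angstrom (default 4.0).
#' @param probe_radius SASA/dot probe radius, Angstrom (default 1.4).
#' @param n_sphere_points SASA sample points per atom.
#' @param sc Compute shape complementarity (default `TRUE`; the TCR
#'   chains versus peptide plus MHC heavy chain).
#' @param sc_density Dot density for Sc, dots per Angstrom^2.
#' @param reference_table Optional docking-geometry reference table
#'   (data frame or TSV path, see [read_geometry_table()]) for
#'   rank/percentile context.
#' @param input Optional input description recorded in provenance.
#' @return An `analysis_report`: list with sections `geometry`,
#'   `contacts` (counts, percentages, chain shares), `buried_surface`,
#'   `sc`, optional `ranking`, and `provenance`.
#' @export
analyze <- function(complex, config = NULL, cutoff = 4.0, probe_radius = 1.4,
                    n_sphere_points = 960, sc = TRUE, sc_density = 15,
                    reference_table = NULL, input = NULL) {
  if (!inherits(complex, "annotated_complex")) {
    if (is.null(config)) {
      stop_tcrpmhc("unannotated structure needs an annotation config",
                   "tcrpmhc_usage_error")
    }
    complex <- annotate_complex(complex, config)
  }
  geom <- docking_geometry(complex)
  tab <- build_contact_table(complex, cutoff = cutoff)
  pct <- contact_percentages(tab)
  shares <- list(
    alpha_mhc = chain_share(tab, "alpha", "mhc"),
    beta_mhc = chain_share(tab, "beta", "mhc"),
    alpha_peptide = chain_share(tab, "alpha", "peptide"),
    beta_peptide = chain_share(tab, "beta", "peptide")
  )
  buried <- buried_peptide_fraction(complex, probe_radius = probe_radius,
                                    n_sphere_points = n_sphere_points)
  sc_res <- NULL
  if (isTRUE(sc)) {
    tcr <- rbind(role_atoms(complex, "tcr_alpha"),
                 role_atoms(complex, "tcr_beta"))
    pmhc <- rbind(role_atoms(complex, "peptide"),
                  role_atoms(complex, "mhc_heavy"))
    sc_res <- tryCatch(
      shape_complementarity(tcr, pmhc, probe_radius = probe_radius,
                            density = sc_density),
      tcrpmhc_undefined_sc = function(e) NULL)
  }
  ranking <- NULL
  if (!is.null(reference_table)) {
    if (is.character(reference_table)) {
      reference_table <- read_geometry_table(reference_table)
    }
    ranking <- list(
      incident = rank_percentile(geom$incident_angle, reference_table,
                                 column = "incident_angle"),
      crossing = rank_percentile(geom$crossing_angle, reference_table,
                                 column = "crossing_angle"),
      x_pos = rank_percentile(geom$x_pos, reference_table, column = "x_pos")
    )
  }
  report <- list(
    complex_id = complex$structure$id,
    geometry = unclass(geom),
    contacts = list(counts = tab$counts,
                    loop_total = tab$loop_total,
                    grand_total = tab$grand_total,
                    b2m_contacts = tab$b2m_contacts,
                    water_contacts = tab$water_contacts,
                    percentages = pct,
                    chain_shares = shares,
                    cutoff = cutoff),
    buried_surface = buried,
    sc = if (!is.null(sc_res)) unclass(sc_res),
    ranking = ranking,
    provenance = list(
      input = input %||% complex$structure$id,
      parameters = list(cutoff = cutoff, probe_radius = probe_radius,
                        n_sphere_points = n_sphere_points,
                        sc_density = sc_density),
      tool = paste0("tcrpmhc ", as.character(packageVersion("tcrpmhc"))),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  class(report) <- "analysis_report"
  report
}

#' Superposition comparison of two complexes
#'
#' Fits `mov` onto `ref` on one selection, measures RMSD on another and
#' appends the per-residue displacement profile.
#'
#' @param ref,mov `annotated_complex` objects.
#' @param fit_selection,measure_selection [atom_selection()] objects.
#' @param profile_atom Atom name for the displacement profile.
#' @return List with `rmsd`, `n_fit`, `n_measure`, `fit_selection`,
#'   `measure_selection` (identities for provenance), `profile` (a
#'   `displacement_profile`) and `max_displacement`.
#' @export
compare <- function(ref, mov, fit_selection, measure_selection,
                    profile_atom = "CA") {
  fm <- fit_measure_rmsd(ref, mov, fit_selection, measure_selection)
  prof <- displacement_profile(ref, fm$mov_aligned, measure_selection,
                               atom = profile_atom)
  list(rmsd = fm$rmsd, n_fit = fm$n_fit, n_measure = fm$n_measure,
       fit_selection = unclass(fit_selection),
       measure_selection = unclass(measure_selection),
       profile = as.data.frame(prof),
       max_displacement = attr(prof, "max_residue"))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s\n", x$complex_id))
  g <- x$geometry
  cat(sprintf("  geometry: crossing %.1f deg, incident %.1f deg, x_pos %.1f, y_pos %.1f A\n",
              g$crossing_angle, g$incident_angle, g$x_pos, g$y_pos))
  cat(sprintf("  contacts: peptide %d, mhc %d (cutoff %.1f A)\n",
              x$contacts$grand_total[["peptide"]],
              x$contacts$grand_total[["mhc"]], x$contacts$cutoff))
  b <- x$buried_surface
  cat(sprintf("  buried peptide surface: %.0f A^2 (%.0f%%)\n",
              b$buried_area, 100 * b$buried_fraction))
  if (!is.null(x$sc)) cat(sprintf("  shape complementarity Sc: %.2f\n", x$sc$sc))
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' @param report An `analysis_report` (or any report list).
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Locate a locally stored deposited structure
#'
#' The package performs no downloads.  Coordinate files for deposited
#' accessions (e.g. the 6VR1/6VR5/6VRM/6VRN/6VQO/6VTH/6VTC series this
#' package's analyses were designed around) must be placed by the user
#' in `dir` as `<accession>.pdb` or `<accession>.cif` (case
#' insensitive).
#'
#' @param accession PDB accession, e.g. `"6VRM"`.
#' @param dir Directory searched; defaults to the option
#'   `tcrpmhc.structure_dir`, else the user data directory
#'   `tools::R_user_dir("tcrpmhc", "data")/structures`.
#' @return File path, or `NA_character_` when absent.
#' @export
deposited_structure_path <- function(accession,
                                     dir = getOption("tcrpmhc.structure_dir")) {
  dir <- dir %||% file.path(tools::R_user_dir("tcrpmhc", "data"), "structures")
  for (acc in c(accession, tolower(accession), toupper(accession))) {
    for (ext in c(".pdb", ".cif", ".ent")) {
      p <- file.path(dir, paste0(acc, ext))
      if (file.exists(p)) return(p)
    }
  }
  NA_character_
}
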