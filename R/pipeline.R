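#' Run the structural deviation pipeline
#'
#' End-to-end driver for the structural arm: parse the mutant and the two
#' wild-type reference structures, collapse alternate conformations,
#' compute the three averaged 25-alignment deviation profiles (M-Wt1,
#' M-Wt2, Wt2-Wt1), normalize against the wild-type control, and write the
#' per-residue profile table plus a human-readable flagged-residue
#' summary. Every stage logs its record counts, so each filter can be
#' audited.
#'
#' @param config Either a named list or a path to a YAML file with
#'   entries: `mutant`, `ref1`, `ref2` (paths to coordinate files or
#'   [pentamer()] objects when given as a list), optional `format`
#'   (`"auto"`/`"pdb"`/`"cif"`), `threshold` (default 5), `atom_set`
#'   (default `"calpha"`), `offset` (residue renumbering, default 0), and
#'   `out_dir`.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisibly, a list with `profile` (the combined per-residue
#'   table also written to `profile.csv`), `normalized`, `flagged`, and
#'   `files`.
#' @export
run_structure_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  for (role in c("mutant", "ref1", "ref2")) {
    if (is.null(cfg[[role]])) stop("config lacks entry '", role, "'")
    if (is.character(cfg[[role]]) && !file.exists(cfg[[role]])) {
      stop("structure stage: file for '", role, "' not found: ", cfg[[role]])
    }
  }
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  threshold <- cfg$threshold %||% 5
  atom_set <- cfg$atom_set %||% "calpha"
  offset <- cfg$offset %||% 0L
  fmt <- cfg$format %||% "auto"

  get_structure <- function(entry, id) {
    if (inherits(entry, "pentamer")) entry
    else read_pentamer(entry, format = fmt, offset = offset)
  }
  mutant <- resolve_altlocs(get_structure(cfg$mutant))
  ref1 <- resolve_altlocs(get_structure(cfg$ref1))
  ref2 <- resolve_altlocs(get_structure(cfg$ref2))
  message("parse: mutant ", nrow(mutant$atoms), " atoms; ref1 ",
          nrow(ref1$atoms), "; ref2 ", nrow(ref2$atoms))

  p1 <- average_profile(mutant, ref1, atom_set = atom_set)
  p2 <- average_profile(mutant, ref2, atom_set = atom_set)
  pc <- average_profile(ref2, ref1, atom_set = atom_set)
  message("profiles: ", nrow(p1), "/", nrow(p2), "/", nrow(pc),
          " positions (M-Wt1 / M-Wt2 / Wt2-Wt1)")

  norm <- normalize_profile(p1, p2, pc, threshold = threshold)
  flagged <- flagged_positions(norm)
  message("normalize: ", nrow(norm), " positions, ", length(flagged),
          " flagged at threshold ", threshold)

  combined <- dplyr::left_join(
    tibble::tibble(structure_id = mutant$structure_id,
                   res_seq = p1$res_seq,
                   v_rmsd = (p1$v_rmsd + p2$v_rmsd) / 2,
                   v_dca = (p1$v_dca + p2$v_dca) / 2,
                   n_samples = p1$n_samples + p2$n_samples),
    tibble::as_tibble(norm), by = "res_seq")
  combined$flagged[is.na(combined$flagged)] <- FALSE

  profile_file <- file.path(out_dir, "profile.csv")
  readr::write_csv(combined, profile_file)
  report_file <- file.path(out_dir, "flagged_residues.txt")
  writeLines(c(
    paste0("Structural deviation report for ", mutant$structure_id),
    paste0("references: ", ref1$structure_id, " (Wt1), ",
           ref2$structure_id, " (Wt2)"),
    paste0("threshold: ", threshold, "-fold over wild-type variability"),
    paste0("averaging: pooled samples over ", attr(p1, "n_tasks"),
           " alignment tasks"),
    paste0("positions evaluated: ", nrow(norm)),
    if (length(flagged) == 0) "flagged residues: none" else
      paste0("flagged residues: ", paste(flagged, collapse = ", "))
  ), report_file)

  invisible(list(profile = combined, normalized = norm, flagged = flagged,
                 files = c(profile = profile_file, report = report_file)))
}

#' Run the electrophysiology dose-response pipeline
#'
#' End-to-end driver for the functional arm: read the measurements table,
#' build per-oocyte recordings, fit every dose-response curve, apply the
#' QC filters (logging every exclusion with its reason), compute
#' batch-matched pH50 shifts, summarize and classify each construct, and
#' write the per-oocyte fit table, the per-mutant summary table, and a
#' plain-text classification report.
#'
#' @param config Named list or path to a YAML file with entries:
#'   `measurements` (path to a CSV with columns `oocyte_id`, `batch_id`,
#'   `construct`, `ph`, `peak1`/`peak1_uA`, `peak2`/`peak2_uA`, or a data
#'   frame when given as a list), optional `criteria` (named list of
#'   [qc_criteria()] overrides), `wt_construct` (default `"Wt"`), and
#'   `out_dir`.
#' @param out_dir Output directory (overrides the config entry).
#' @return Invisibly, a list with `fits`, `summary`, and `files`.
#' @export
run_ephys_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  if (is.null(cfg$measurements)) stop("config lacks entry 'measurements'")
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt_construct <- cfg$wt_construct %||% "Wt"
  criteria <- do.call(qc_criteria, as.list(cfg$criteria %||% list()))

  meas <- cfg$measurements
  if (is.character(meas)) {
    if (!file.exists(meas)) {
      stop("ephys stage: measurements file not found: ", meas)
    }
    meas <- readr::read_csv(meas, show_col_types = FALSE, progress = FALSE)
  }
  if (!wt_construct %in% meas$construct) {
    stop("ephys stage: no '", wt_construct,
         "' rows in measurements; a wild-type reference is required")
  }
  message("measurements: ", nrow(meas), " rows, ",
          dplyr::n_distinct(meas$oocyte_id), " oocytes, ",
          dplyr::n_distinct(meas$construct), " constructs")

  recordings <- build_recordings(meas)
  message("recordings: ", nrow(recordings), " oocytes")
  fits <- fit_recordings(recordings, criteria)
  excl <- dplyr::filter(fits, .data$qc_status != "pass")
  for (i in seq_len(nrow(excl))) {
    message("QC exclusion: oocyte ", excl$oocyte_id[i], " (",
            excl$construct[i], ", ", excl$batch_id[i], ") -> ",
            excl$qc_status[i])
  }
  message("fits: ", sum(fits$qc_status == "pass"), "/", nrow(fits),
          " pass QC")
  fits <- delta_ph50(fits, wt_construct)
  summary <- summarize_mutants(fits, criteria, wt_construct)

  fits_file <- file.path(out_dir, "oocyte_fits.csv")
  summary_file <- file.path(out_dir, "mutant_summary.csv")
  readr::write_csv(fits, fits_file)
  readr::write_csv(summary, summary_file)
  report_file <- file.path(out_dir, "classification.txt")
  lines <- c("Mutational scan classification",
             paste0("wild type: ", wt_construct, ", shift criterion: +/-",
                    criteria$significance_shift, " pH units"),
             sprintf("%-16s %7s %7s %10s %s", "construct", "n_pass",
                     "pH50", "dpH50", "classification"))
  for (i in seq_len(nrow(summary))) {
    lines <- c(lines, sprintf(
      "%-16s %7d %7.2f %10s %s", summary$construct[i], summary$n_pass[i],
      summary$mean_ph50[i],
      ifelse(is.na(summary$mean_dph50[i]), "-",
             sprintf("%+.2f", summary$mean_dph50[i])),
      summary$classification[i]))
  }
  writeLines(lines, report_file)

  invisible(list(fits = fits, summary = summary,
                 files = c(fits = fits_file, summary = summary_file,
                           report = report_file)))
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}
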