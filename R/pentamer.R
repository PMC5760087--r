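#' Construct a pentamer structure object
#'
#' A `pentamer` is a light container for a five-chain (A--E) atomic model:
#' a tibble of heavy-atom records plus a structure id and free-form metadata
#' (crystallization pH, mutation label, ...). All coordinates are in
#' Angstrom and residue numbers follow the numbering of the source file
#' (author numbering).
#'
#' @param structure_id Label for the structure (a PDB-style id or a
#'   synthetic tag).
#' @param atoms Tibble with columns `chain`, `res_seq`, `ins_code`,
#'   `res_name`, `atom_name`, `element`, `altloc`, `occupancy`, `x`, `y`,
#'   `z`. `ins_code` and `altloc` use `""` when absent.
#' @param metadata Named list of free-form metadata.
#'
#' @return An object of class `pentamer`.
#' @export
pentamer <- function(structure_id, atoms, metadata = list()) {
  atoms <- tibble::as_tibble(atoms)
  required <- c("chain", "res_seq", "ins_code", "res_name", "atom_name",
                "element", "altloc", "occupancy", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- atoms[, required]
  atoms$res_seq <- as.integer(atoms$res_seq)
  chains <- sort(unique(atoms$chain))
  missing_chains <- setdiff(LETTERS[1:5], chains)
  if (length(missing_chains) > 0) {
    stop("pentamer requires chains A-E; missing: ",
         paste(missing_chains, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  structure(
    list(structure_id = structure_id, atoms = atoms, metadata = metadata),
    class = "pentamer"
  )
}

#' @export
print.pentamer <- function(x, ...) {
  n_res <- dplyr::n_distinct(paste(x$atoms$chain, x$atoms$res_seq,
                                   x$atoms$ins_code))
  cat("<pentamer> ", x$structure_id, "\n", sep = "")
  cat("  ", nrow(x$atoms), " heavy atoms, ", n_res,
      " residues over chains A-E\n", sep = "")
  if (length(x$metadata) > 0) {
    cat("  metadata: ", paste(names(x$metadata), unlist(x$metadata),
                              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as_tibble.pentamer <- function(x, ...) x$atoms

#' Read a five-chain structure from a PDB or mmCIF file
#'
#' Parses a coordinate file through bio3d and keeps the protein heavy atoms
#' of chains A--E. Hydrogens (and deuteriums) and HETATM records (waters,
#' ligands) are dropped: deviation profiles are computed on protein heavy
#' atoms only. Extra chains beyond A--E are ignored with a warning; if any
#' of A--E is absent the parse fails naming the missing chains. Alternate
#' locations are retained as stored and can be collapsed afterwards with
#' [resolve_altlocs()].
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"cif"`.
#' @param structure_id Label for the structure; defaults to the file name
#'   without extension.
#' @param offset Integer added to all residue numbers on read, for
#'   reconciling structures deposited under numbering conventions shifted
#'   relative to each other. Default 0.
#' @param metadata Named list stored on the returned object.
#'
#' @return A [pentamer()] object.
#' @export
read_pentamer <- function(path, format = c("auto", "pdb", "cif"),
                          structure_id = NULL, offset = 0L,
                          metadata = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path)
  }
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- tibble::as_tibble(raw$atom)
  at <- dplyr::filter(at, .data$type == "ATOM")
  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  # fall back to the first letter of the atom name when the element field
  # is absent (minimal files)
  elem[elem == ""] <- substr(gsub("[0-9]", "", at$elety[elem == ""]), 1, 1)
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  elem <- elem[!(elem %in% c("H", "D"))]

  extra <- setdiff(unique(at$chain), LETTERS[1:5])
  if (length(extra) > 0) {
    warning("ignoring chains beyond A-E: ", paste(extra, collapse = ", "))
    keep <- at$chain %in% LETTERS[1:5]
    at <- at[keep, , drop = FALSE]
    elem <- elem[keep]
  }
  missing_chains <- setdiff(LETTERS[1:5], unique(at$chain))
  if (length(missing_chains) > 0) {
    stop("structure ", path, " lacks chains: ",
         paste(missing_chains, collapse = ", "))
  }
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  atoms <- tibble::tibble(
    chain = at$chain,
    res_seq = as.integer(at$resno) + as.integer(offset),
    ins_code = ifelse(is.na(at$insert), "", at$insert),
    res_name = at$resid,
    atom_name = at$elety,
    element = elem,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z
  )
  pentamer(structure_id, atoms, metadata)
}

#' Write a pentamer to a PDB or minimal mmCIF file
#'
#' The PDB writer delegates to [bio3d::write.pdb()]; the mmCIF writer emits
#' a minimal `atom_site` loop sufficient to round-trip the atom table.
#' Coordinates are written at the standard 3-decimal precision of the PDB
#' format in both dialects.
#'
#' @param x A [pentamer()] object.
#' @param path Output file path.
#' @param format `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_pentamer <- function(x, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  a <- x$atoms
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = rep("ATOM", nrow(a)),
      resno = a$res_seq,
      resid = a$res_name,
      eleno = seq_len(nrow(a)),
      elety = a$atom_name,
      chain = a$chain,
      insert = ifelse(a$ins_code == "", NA, a$ins_code),
      alt = ifelse(a$altloc == "", NA, a$altloc),
      o = a$occupancy,
      b = rep(0, nrow(a)),
      elesy = a$element
    )
  } else {
    header <- c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", x$structure_id)),
      "loop_",
      paste0("_atom_site.", c(
        "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
        "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
        "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
        "auth_atom_id", "pdbx_PDB_model_num"))
    )
    rows <- sprintf(
      "ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
      seq_len(nrow(a)), a$element, a$atom_name,
      ifelse(a$altloc == "", ".", a$altloc),
      a$res_name, a$chain, a$res_seq,
      ifelse(a$ins_code == "", "?", a$ins_code),
      a$x, a$y, a$z, a$occupancy,
      a$res_seq, a$res_name, a$chain, a$atom_name
    )
    writeLines(c(header, rows, "#"), path)
  }
  invisible(path)
}

#' Collapse alternate conformations to a single conformer
#'
#' Crystal structures may store several alternate locations (altlocs) for
#' one atom. For each atom-name group within a residue that carries more
#' than one location, exactly one atom is retained: a blank-altloc atom is
#' always preferred; otherwise the highest-occupancy location wins, with
#' ties broken by the lowest altloc character. The surviving atoms have
#' their altloc id cleared, so the result carries no altloc multiplicity.
#' The operation is idempotent.
#'
#' @param x A [pentamer()] object.
#' @return A [pentamer()] with one conformer per atom.
#' @export
resolve_altlocs <- function(x) {
  a <- dplyr::mutate(x$atoms, .row = dplyr::row_number())
  a <- dplyr::group_by(a, .data$chain, .data$res_seq, .data$ins_code,
                       .data$atom_name)
  a <- dplyr::arrange(a, .data$altloc != "", dplyr::desc(.data$occupancy),
                      .data$altloc, .by_group = TRUE)
  a <- dplyr::slice_head(a, n = 1)
  a <- dplyr::ungroup(a)
  a <- dplyr::arrange(a, .data$.row)
  a$altloc <- ""
  a$.row <- NULL
  out <- x
  out$atoms <- a
  out
}

#' Match residues between two structures
#'
#' Pairs residues of two structures chain-by-chain under an explicit chain
#' pairing, keyed by residue number and insertion code (no sequence
#' alignment). For each matched pair the common atom names (intersection)
#' are recorded; positions whose residue type differs are flagged
#' `mutated`, and residues present in only one structure are reported
#' unmatched.
#'
#' @param a,b [pentamer()] objects.
#' @param chain_map Named character vector mapping chains of `a` to chains
#'   of `b`, e.g. `c(A = "A", B = "B", ...)`. Defaults to the identity map
#'   over A--E.
#' @return A tibble with columns `chain_a`, `chain_b`, `res_seq`,
#'   `ins_code`, `res_name_a`, `res_name_b`, `status`
#'   (`matched`/`mutated`/`only_a`/`only_b`) and a list column
#'   `common_atoms`.
#' @export
match_residues <- function(a, b, chain_map = stats::setNames(LETTERS[1:5],
                                                             LETTERS[1:5])) {
  purrr::map2_dfr(names(chain_map), unname(chain_map), function(ca, cb) {
    ra <- residue_table(a, ca)
    rb <- residue_table(b, cb)
    j <- dplyr::full_join(ra, rb, by = c("res_seq", "ins_code"),
                          suffix = c("_a", "_b"))
    j <- dplyr::arrange(j, .data$res_seq, .data$ins_code)
    tibble::tibble(
      chain_a = ca,
      chain_b = cb,
      res_seq = j$res_seq,
      ins_code = j$ins_code,
      res_name_a = j$res_name_a,
      res_name_b = j$res_name_b,
      status = dplyr::case_when(
        is.na(j$res_name_b) ~ "only_a",
        is.na(j$res_name_a) ~ "only_b",
        j$res_name_a != j$res_name_b ~ "mutated",
        TRUE ~ "matched"
      ),
      common_atoms = purrr::map2(j$atoms_a, j$atoms_b, function(x, y) {
        if (is.null(x) || is.null(y)) character(0) else intersect(x, y)
      })
    )
  })
}

residue_table <- function(s, chain) {
  a <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  a <- dplyr::distinct(a, .data$res_seq, .data$ins_code, .data$res_name,
                       .data$atom_name)
  a <- dplyr::group_by(a, .data$res_seq, .data$ins_code)
  out <- dplyr::summarise(a,
    res_name = .data$res_name[1],
    atoms = list(unique(.data$atom_name)),
    .groups = "drop"
  )
  out
}

#' Positions whose residue identity differs between two structures
#'
#' Convenience wrapper over [match_residues()] returning the residue
#' numbers flagged as mutated under the identity chain map (a substituted
#' residue in a homopentamer appears in all five chains).
#'
#' @param a,b [pentamer()] objects.
#' @return Sorted integer vector of mutated residue numbers.
#' @export
mutated_positions <- function(a, b) {
  m <- match_residues(a, b)
  sort(unique(m$res_seq[m$status == "mutated"]))
}
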