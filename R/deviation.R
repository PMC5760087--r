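#' Per-residue deviation samples for one alignment task
#'
#' After mapping the mobile structure into the reference frame with the
#' task's fitted transform, every matched residue pair under the task's
#' chain correspondence yields (i) the RMSD over its common heavy atoms,
#' measured in the task's frame without per-residue re-fitting, and
#' (ii) the C-alpha to C-alpha Euclidean distance. Positions whose residue
#' type differs (mutated) contribute a C-alpha sample but no RMSD sample;
#' positions lacking a C-alpha in either structure are skipped with a
#' warning.
#'
#' @param mobile,reference [pentamer()] objects.
#' @param sup A `superposition` from [superpose()] for the task.
#' @param index Optional correspondence cache (internal use).
#' @return Tibble with one row per (residue, chain pair within the task):
#'   `res_seq`, `ins_code`, `chain_mobile`, `chain_ref`, `mutated`, `dca`,
#'   `rmsd` (`NA` at mutated positions).
#' @export
residue_deviations <- function(mobile, reference, sup, index = NULL) {
  if (is.null(index)) index <- correspondence_cache(mobile, reference)
  out <- vector("list", length(sup$chain_pairs))
  for (k in seq_along(sup$chain_pairs)) {
    mc <- sup$chain_pairs[[k]][1]
    rc <- sup$chain_pairs[[k]][2]
    cp <- chain_pair_index(index, mc, rc)
    xyz_t <- apply_transform(cp$xyz_m, sup)
    d2 <- rowSums((xyz_t - cp$xyz_r)^2)

    n_res <- length(cp$res_seq)
    ca_rows <- which(cp$atom_name == "CA")
    dca <- rep(NA_real_, n_res)
    dca[cp$res_idx[ca_rows]] <- sqrt(d2[ca_rows])
    if (anyNA(dca)) {
      warning("no C-alpha pair for residue(s) ",
              paste(cp$res_seq[is.na(dca)], collapse = ", "),
              " in chain pair ", mc, ">", rc, "; skipped")
    }
    ss <- rowsum(d2, cp$res_idx)
    nn <- rowsum(rep(1, length(d2)), cp$res_idx)
    rmsd <- rep(NA_real_, n_res)
    rmsd[as.integer(rownames(ss))] <- sqrt(ss[, 1] / nn[, 1])
    rmsd[cp$mutated] <- NA_real_

    keep <- !is.na(dca)
    out[[k]] <- tibble::tibble(
      res_seq = cp$res_seq[keep],
      ins_code = cp$ins_code[keep],
      chain_mobile = mc,
      chain_ref = rc,
      mutated = cp$mutated[keep],
      dca = dca[keep],
      rmsd = rmsd[keep]
    )
  }
  dplyr::bind_rows(out)
}

#' Average per-residue deviations over the 25-alignment scheme
#'
#' Runs every task of [alignment_scheme()], collects all per-residue
#' samples, and pools them across tasks and chain pairs with equal weight
#' (a position sampled in both chains of a pair task contributes two
#' samples from that task). Arithmetic means per position give the averaged
#' deviation profile: `v_rmsd` over common heavy atoms and `v_dca` for the
#' backbone C-alpha displacement.
#'
#' Alternate conformations are collapsed with [resolve_altlocs()] before
#' any distance is computed (the operation is idempotent, so pre-resolved
#' structures are unaffected).
#'
#' @param mobile,reference [pentamer()] objects (structure M and a
#'   wild-type reference).
#' @param atom_set Atom set driving each fit; see [superpose()].
#' @param scheme Task table, by default [alignment_scheme()].
#' @return A tibble of class `deviation_profile`: `res_seq`, `v_rmsd`,
#'   `v_dca`, `n_samples` (count of pooled C-alpha samples), with
#'   attributes `mobile_id`, `reference_id`, `mutated_positions`,
#'   `averaging = "pooled"` and `n_tasks`.
#' @export
average_profile <- function(mobile, reference, atom_set = "calpha",
                            scheme = alignment_scheme()) {
  mobile <- resolve_altlocs(mobile)
  reference <- resolve_altlocs(reference)
  index <- correspondence_cache(mobile, reference)
  samples <- vector("list", nrow(scheme))
  for (i in seq_len(nrow(scheme))) {
    task <- list(mobile = scheme$mobile[[i]], reference = scheme$reference[[i]])
    sup <- tryCatch(
      superpose(mobile, reference, task, atom_set = atom_set, index = index),
      error = function(e) {
        stop("alignment task ", scheme$task_id[i], " failed: ",
             conditionMessage(e), call. = FALSE)
      }
    )
    samples[[i]] <- residue_deviations(mobile, reference, sup, index = index)
  }
  pooled <- dplyr::bind_rows(samples)
  prof <- dplyr::summarise(
    dplyr::group_by(pooled, .data$res_seq),
    v_rmsd = if (all(is.na(.data$rmsd))) NA_real_ else
      mean(.data$rmsd, na.rm = TRUE),
    v_dca = mean(.data$dca),
    n_samples = dplyr::n(),
    .groups = "drop"
  )
  prof <- dplyr::arrange(prof, .data$res_seq)
  structure(
    prof,
    class = c("deviation_profile", class(prof)),
    mobile_id = mobile$structure_id,
    reference_id = reference$structure_id,
    mutated_positions = sort(unique(pooled$res_seq[pooled$mutated])),
    averaging = "pooled",
    n_tasks = nrow(scheme)
  )
}

#' Normalize a mutant deviation profile against wild-type variability
#'
#' A mutant M measured against two wild-type references Wt1 and Wt2 is
#' normalized by the intrinsic variability between the references
#' themselves, position by position:
#' \deqn{ratio = (V(M-Wt1) + V(M-Wt2)) / (2 V(Wt2-Wt1))}
#' applied identically to the heavy-atom RMSD and the C-alpha displacement.
#' Positions with a ratio of 1 move no more than the two wild-type
#' structures differ from each other; positions whose `dca_ratio` exceeds
#' the fold-change threshold (default 5) are flagged as significant local
#' changes. The mutated position itself is excluded from the output, and
#' positions where the control deviation is zero are omitted with a warning
#' (the ratio is undefined there).
#'
#' @param m_vs_wt1,m_vs_wt2 [average_profile()] results of the mutant
#'   against each reference.
#' @param wt2_vs_wt1 [average_profile()] of Wt2 against Wt1 (the control).
#' @param exclude Integer positions to omit (defaults to the mutated
#'   positions recorded on the mutant profiles).
#' @param threshold Fold-change flagging threshold on `dca_ratio`.
#' @return A tibble of class `normalized_profile`: `res_seq`,
#'   `rmsd_ratio`, `dca_ratio`, `flagged`, with attributes `mutant_id`,
#'   `threshold`, `excluded_positions`.
#' @export
normalize_profile <- function(m_vs_wt1, m_vs_wt2, wt2_vs_wt1,
                              exclude = NULL, threshold = 5) {
  if (is.null(exclude)) {
    exclude <- sort(unique(c(attr(m_vs_wt1, "mutated_positions"),
                             attr(m_vs_wt2, "mutated_positions"))))
  }
  j <- dplyr::inner_join(
    dplyr::inner_join(
      dplyr::select(tibble::as_tibble(m_vs_wt1), "res_seq",
                    v_rmsd_1 = "v_rmsd", v_dca_1 = "v_dca"),
      dplyr::select(tibble::as_tibble(m_vs_wt2), "res_seq",
                    v_rmsd_2 = "v_rmsd", v_dca_2 = "v_dca"),
      by = "res_seq"),
    dplyr::select(tibble::as_tibble(wt2_vs_wt1), "res_seq",
                  v_rmsd_c = "v_rmsd", v_dca_c = "v_dca"),
    by = "res_seq")
  j <- dplyr::filter(j, !(.data$res_seq %in% exclude))
  zero_ctrl <- j$v_dca_c == 0 | (!is.na(j$v_rmsd_c) & j$v_rmsd_c == 0)
  if (any(zero_ctrl)) {
    warning("control deviation is zero at position(s) ",
            paste(j$res_seq[zero_ctrl], collapse = ", "),
            "; ratio undefined, omitted")
    j <- j[!zero_ctrl, , drop = FALSE]
  }
  out <- tibble::tibble(
    res_seq = j$res_seq,
    rmsd_ratio = (j$v_rmsd_1 + j$v_rmsd_2) / (2 * j$v_rmsd_c),
    dca_ratio = (j$v_dca_1 + j$v_dca_2) / (2 * j$v_dca_c),
    flagged = (j$v_dca_1 + j$v_dca_2) / (2 * j$v_dca_c) > threshold
  )
  structure(
    out,
    class = c("normalized_profile", class(out)),
    mutant_id = attr(m_vs_wt1, "mobile_id"),
    threshold = threshold,
    excluded_positions = exclude
  )
}

#' Flagged positions of a normalized profile
#'
#' @param x A `normalized_profile`.
#' @return Integer vector of residue numbers whose `dca_ratio` exceeds the
#'   profile's threshold.
#' @export
flagged_positions <- function(x) {
  stopifnot(inherits(x, "normalized_profile"))
  x$res_seq[x$flagged]
}
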