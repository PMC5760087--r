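#' Enumerate the 25-alignment pairwise-chain superposition scheme
#'
#' The deviation analysis does not use a single global superposition.
#' Instead, a mutant pentamer M is aligned on a reference in 25 different
#' ways so that quaternary intersubunit-interface relations are sampled:
#' every adjacent subunit pair of M (`A+B`, `B+C`, `C+D`, `D+E`) is aligned
#' on every such pair of the reference (16 tasks); in place of a wrapped
#' `E+A` pair, chain E of M is aligned on each reference chain A--E
#' (5 tasks) and each chain of M is aligned on reference chain E (5 tasks),
#' with the duplicated E-on-E task counted once. Task order is fixed:
#' pair tasks in row-major (mobile pair, reference pair) order, then the
#' single-chain tasks.
#'
#' @return A tibble with columns `task_id`, `type` (`"pair"`/`"single"`),
#'   and list columns `mobile` and `reference` holding the ordered chain
#'   ids; the chain correspondence within a task is positionwise.
#' @export
alignment_scheme <- function() {
  pairs <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"))
  tasks <- list()
  for (mp in pairs) {
    for (rp in pairs) {
      tasks[[length(tasks) + 1]] <- list(mobile = mp, reference = rp,
                                         type = "pair")
    }
  }
  for (rc in LETTERS[1:5]) {
    tasks[[length(tasks) + 1]] <- list(mobile = "E", reference = rc,
                                       type = "single")
  }
  for (mc in LETTERS[1:4]) { # E-on-E already emitted above
    tasks[[length(tasks) + 1]] <- list(mobile = mc, reference = "E",
                                       type = "single")
  }
  tibble::tibble(
    task_id = vapply(tasks, function(t) {
      paste0(paste(t$mobile, collapse = ""), ">",
             paste(t$reference, collapse = ""))
    }, character(1)),
    type = vapply(tasks, `[[`, character(1), "type"),
    mobile = purrr::map(tasks, "mobile"),
    reference = purrr::map(tasks, "reference")
  )
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Closed-form solution for the proper rotation and translation minimizing
#' the sum of squared distances between paired coordinates, with a
#' reflection guard: when the optimal orthogonal transform is a reflection
#' the smallest singular direction is flipped so the returned rotation has
#' determinant +1. No outlier rejection is performed.
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates.
#' @return List with `rotation` (3 x 3), `translation` (length 3),
#'   `fit_rmsd`, `n_atoms`. The transform maps mobile coordinates into the
#'   reference frame as `x %*% t(rotation) + translation`.
#' @export
kabsch <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3, ncol(reference) == 3,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3) {
    stop("degenerate alignment: fewer than 3 atom pairs (", n, ")")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  sv_p <- svd(p)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    stop("degenerate alignment: fitting atoms are collinear")
  }
  h <- crossprod(p, q) # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cr - rot %*% cm)
  moved <- p %*% t(rot)
  fit_rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  list(rotation = rot, translation = trans, fit_rmsd = fit_rmsd, n_atoms = n)
}

#' Superpose a mobile pentamer on a reference for one alignment task
#'
#' Collects the fitting atoms implied by the task's positionwise chain
#' correspondence and solves the least-squares rigid transform with
#' [kabsch()]. By default only C-alpha atoms of matched (non-mutated,
#' non-missing) residues drive the fit, so substituted side chains cannot
#' bias the frame; `"backbone"` (N, CA, C, O) and `"all_common"` (all
#' common heavy atoms) are available alternatives.
#'
#' @param mobile,reference [pentamer()] objects (altlocs should be resolved
#'   first; see [resolve_altlocs()]).
#' @param task One row of [alignment_scheme()] (or any list with `mobile`
#'   and `reference` chain vectors of equal length 1 or 2).
#' @param atom_set `"calpha"`, `"backbone"`, or `"all_common"`.
#' @param index Optional precomputed correspondence cache (internal use).
#' @return An object of class `superposition`: list with `task_id`,
#'   `chain_pairs`, `rotation`, `translation`, `fit_rmsd`, `n_atoms_fit`.
#' @export
superpose <- function(mobile, reference, task,
                      atom_set = c("calpha", "backbone", "all_common"),
                      index = NULL) {
  atom_set <- match.arg(atom_set)
  task <- as_task(task)
  if (is.null(index)) index <- correspondence_cache(mobile, reference)
  coords <- fitting_coords(task, atom_set, index)
  fit <- kabsch(coords$m, coords$r)
  structure(
    list(
      task_id = paste0(paste(task$mobile, collapse = ""), ">",
                       paste(task$reference, collapse = "")),
      chain_pairs = Map(c, task$mobile, task$reference),
      rotation = fit$rotation,
      translation = fit$translation,
      fit_rmsd = fit$fit_rmsd,
      n_atoms_fit = fit$n_atoms
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> task ", x$task_id, ": fit RMSD ",
      format(x$fit_rmsd, digits = 4), " A over ", x$n_atoms_fit,
      " atoms\n", sep = "")
  invisible(x)
}

#' Tidy a superposition result
#'
#' @param x A `superposition` object.
#' @param ... Unused.
#' @return One-row tibble with the task id, fit RMSD, atom count, and the
#'   flattened 4 x 4 homogeneous transform columns `t11`..`t34`.
#' @export
tidy.superposition <- function(x, ...) {
  tf <- cbind(x$rotation, x$translation)
  vals <- as.list(as.numeric(t(tf)))
  names(vals) <- paste0("t", rep(1:3, each = 4), rep(1:4, 3))
  dplyr::bind_cols(
    tibble::tibble(task_id = x$task_id, fit_rmsd = x$fit_rmsd,
                   n_atoms_fit = x$n_atoms_fit),
    tibble::as_tibble(vals)
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param coords Numeric n x 3 matrix.
#' @param sup A `superposition` object (or list with `rotation` and
#'   `translation`).
#' @return Transformed n x 3 matrix in the reference frame.
#' @export
apply_transform <- function(coords, sup) {
  sweep(coords %*% t(sup$rotation), 2, sup$translation, `+`)
}

# --- internal correspondence machinery ------------------------------------

as_task <- function(task) {
  if (is.data.frame(task)) {
    stopifnot(nrow(task) == 1)
    task <- list(mobile = task$mobile[[1]], reference = task$reference[[1]])
  }
  stopifnot(length(task$mobile) == length(task$reference),
            length(task$mobile) %in% 1:2)
  task
}

# Per chain-pair atom correspondence, computed once per structure pair and
# memoised: the 25 tasks reuse the same 25 chain pairs.
correspondence_cache <- function(mobile, reference) {
  env <- new.env(parent = emptyenv())
  env$mobile <- mobile
  env$reference <- reference
  env
}

chain_pair_index <- function(index, mc, rc) {
  key <- paste0(mc, ":", rc)
  if (!is.null(index[[key]])) return(index[[key]])
  m <- index$mobile$atoms[index$mobile$atoms$chain == mc, , drop = FALSE]
  r <- index$reference$atoms[index$reference$atoms$chain == rc, , drop = FALSE]
  m <- dplyr::distinct(m, .data$res_seq, .data$ins_code, .data$atom_name,
                       .keep_all = TRUE)
  r <- dplyr::distinct(r, .data$res_seq, .data$ins_code, .data$atom_name,
                       .keep_all = TRUE)
  j <- dplyr::inner_join(m, r, by = c("res_seq", "ins_code", "atom_name"),
                         suffix = c("_m", "_r"))
  j <- dplyr::arrange(j, .data$res_seq, .data$ins_code, .data$atom_name)
  res_key <- paste(j$res_seq, j$ins_code)
  res_levels <- unique(res_key) # appearance order == sorted residue order
  res_idx <- match(res_key, res_levels)
  first <- !duplicated(res_key)
  out <- list(
    res_seq = j$res_seq[first],
    ins_code = j$ins_code[first],
    mutated = (j$res_name_m != j$res_name_r)[first],
    atom_name = j$atom_name,
    res_idx = res_idx,
    xyz_m = as.matrix(j[, c("x_m", "y_m", "z_m")]),
    xyz_r = as.matrix(j[, c("x_r", "y_r", "z_r")])
  )
  index[[key]] <- out
  out
}

fitting_coords <- function(task, atom_set, index) {
  ms <- list()
  rs <- list()
  for (k in seq_along(task$mobile)) {
    cp <- chain_pair_index(index, task$mobile[k], task$reference[k])
    keep_res <- !cp$mutated[cp$res_idx]
    keep <- switch(atom_set,
      calpha = keep_res & cp$atom_name == "CA",
      backbone = keep_res & cp$atom_name %in% c("N", "CA", "C", "O"),
      all_common = keep_res
    )
    ms[[k]] <- cp$xyz_m[keep, , drop = FALSE]
    rs[[k]] <- cp$xyz_r[keep, , drop = FALSE]
  }
  list(m = do.call(rbind, ms), r = do.call(rbind, rs))
}
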