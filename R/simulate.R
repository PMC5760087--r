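#' Configuration for synthetic pentamer generation
#'
#' Describes a toy homopentamer build: one procedurally built template
#' chain replicated five-fold around a central axis, replicate "wild-type"
#' structures that differ only by coordinate noise, and a mutant carrying
#' configurable per-residue displacements and residue substitutions. The
#' generator emulates the statistical structure the deviation analysis
#' assumes (near five-fold symmetry, duplicate references, local
#' perturbations); it makes no attempt at realistic protein energetics.
#'
#' @param n_residues_per_chain Residues per chain.
#' @param fold_template `"helix"`, `"extended"`, or `"mixed"` backbone
#'   geometry for the template chain.
#' @param control_noise_sd RMS atomic displacement magnitude (Angstrom) of
#'   the coordinate noise applied independently to every structure; the
#'   per-axis Gaussian sd is `control_noise_sd / sqrt(3)`.
#' @param perturbation Data frame with columns `res_seq`, `magnitude`
#'   (Angstrom), and `mode` (`"radial"` = away from the pentamer axis, or
#'   `"random"` = random direction per chain), applied to every chain of
#'   the mutant. `NULL` for none.
#' @param mutated_positions Named character vector mapping residue numbers
#'   to replacement residue codes (e.g. `c("30" = "ALA")`); substituted
#'   residues keep only the atoms of the replacement type.
#' @param altloc_fraction Fraction of residues given a second side-chain
#'   conformer (altloc A/B with occupancies 0.6/0.4).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Named list of class `structure_sim_config`.
#' @export
structure_sim_config <- function(n_residues_per_chain = 40,
                                 fold_template = c("helix", "extended",
                                                   "mixed"),
                                 control_noise_sd = 0.2,
                                 perturbation = NULL,
                                 mutated_positions = NULL,
                                 altloc_fraction = 0,
                                 seed = 1L) {
  fold_template <- match.arg(fold_template)
  stopifnot(control_noise_sd > 0, n_residues_per_chain >= 3,
            altloc_fraction >= 0, altloc_fraction <= 1)
  if (!is.null(perturbation)) {
    perturbation <- tibble::as_tibble(perturbation)
    stopifnot(all(c("res_seq", "magnitude", "mode") %in% names(perturbation)),
              all(perturbation$magnitude >= 0),
              all(perturbation$mode %in% c("radial", "random")))
  }
  structure(list(n_residues_per_chain = n_residues_per_chain,
                 fold_template = fold_template,
                 control_noise_sd = control_noise_sd,
                 perturbation = perturbation,
                 mutated_positions = mutated_positions,
                 altloc_fraction = altloc_fraction,
                 seed = as.integer(seed)),
            class = "structure_sim_config")
}

# Heavy-atom templates per residue type used by the toy builder. Offsets
# are in a local residue frame; they only need to be distinct and
# non-collinear, not stereochemically exact.
res_atom_offsets <- function(res_name) {
  base <- list(
    N = c(-1.20, 0.50, -0.90),
    CA = c(0, 0, 0),
    C = c(1.25, 0.45, 0.85),
    O = c(1.30, 1.65, 1.05),
    CB = c(0.55, -1.40, -0.35)
  )
  side <- list(
    CG = c(1.10, -2.55, -0.10),
    CD1 = c(0.90, -3.40, 1.10),
    CD2 = c(1.65, -3.30, -1.30)
  )
  if (res_name == "ALA") base else c(base, side)
}

build_template_chain <- function(n_res, fold) {
  geom <- function(kind, i) {
    if (kind == "helix") {
      ang <- i * 100 * pi / 180
      c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    } else {
      ang <- i * pi
      c(1.0 * cos(ang), 1.0 * sin(ang), 3.3 * i)
    }
  }
  kinds <- switch(fold,
    helix = rep("helix", n_res),
    extended = rep("extended", n_res),
    mixed = c(rep("helix", ceiling(n_res / 2)),
              rep("extended", floor(n_res / 2)))
  )
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    ca <- geom(kinds[i], i - 1)
    offs <- res_atom_offsets("LEU")
    rows[[i]] <- tibble::tibble(
      res_seq = i,
      res_name = "LEU",
      atom_name = names(offs),
      x = ca[1] + vapply(offs, `[`, numeric(1), 1),
      y = ca[2] + vapply(offs, `[`, numeric(1), 2),
      z = ca[3] + vapply(offs, `[`, numeric(1), 3)
    )
  }
  dplyr::bind_rows(rows)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# Assemble the ideal (noise-free) pentamer atom table from a template chain
# placed at radius 25 A from the z axis and rotated by 72 degrees per chain.
ideal_pentamer_atoms <- function(template) {
  placed <- dplyr::mutate(template, x = .data$x + 25)
  purrr::map_dfr(0:4, function(k) {
    r <- rot_z(k * 2 * pi / 5)
    xyz <- as.matrix(placed[, c("x", "y", "z")]) %*% t(r)
    tibble::tibble(
      chain = LETTERS[k + 1],
      res_seq = placed$res_seq,
      ins_code = "",
      res_name = placed$res_name,
      atom_name = placed$atom_name,
      element = substr(placed$atom_name, 1, 1),
      altloc = "",
      occupancy = 1,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
}

#' Generate a wild-type pair and a mutant pentamer
#'
#' Builds the ideal toy pentamer from the configured fold, then emits
#' three structures: `wt1` and `wt2` are independent noise realizations of
#' the ideal coordinates (emulating two independently solved wild-type
#' crystal structures), and `mutant` adds the configured per-residue
#' displacements (identically in all five chains), residue substitutions,
#' and optional alternate side-chain conformers on top of its own noise
#' realization. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [structure_sim_config()].
#' @return Named list of three [pentamer()] objects: `wt1`, `wt2`,
#'   `mutant`, each carrying the config seed in its metadata; the ground
#'   truth (perturbed and mutated positions) is attached as attribute
#'   `truth`.
#' @export
simulate_pentamer_set <- function(cfg) {
  stopifnot(inherits(cfg, "structure_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  ideal <- ideal_pentamer_atoms(
    build_template_chain(cfg$n_residues_per_chain, cfg$fold_template))
  axis_sd <- cfg$control_noise_sd / sqrt(3)
  noisy <- function(atoms) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, axis_sd)
    atoms$y <- atoms$y + stats::rnorm(n, 0, axis_sd)
    atoms$z <- atoms$z + stats::rnorm(n, 0, axis_sd)
    atoms
  }

  wt1 <- noisy(ideal)
  wt2 <- noisy(ideal)
  mut <- ideal

  if (!is.null(cfg$mutated_positions)) {
    for (k in seq_along(cfg$mutated_positions)) {
      pos <- as.integer(names(cfg$mutated_positions)[k])
      new_res <- cfg$mutated_positions[[k]]
      keep_atoms <- names(res_atom_offsets(new_res))
      drop <- mut$res_seq == pos & !(mut$atom_name %in% keep_atoms)
      mut <- mut[!drop, , drop = FALSE]
      mut$res_name[mut$res_seq == pos] <- new_res
    }
  }
  if (!is.null(cfg$perturbation)) {
    for (k in seq_len(nrow(cfg$perturbation))) {
      pos <- cfg$perturbation$res_seq[k]
      mag <- cfg$perturbation$magnitude[k]
      mode <- cfg$perturbation$mode[k]
      for (ch in LETTERS[1:5]) {
        sel <- mut$res_seq == pos & mut$chain == ch
        if (!any(sel)) next
        if (mode == "radial") {
          ca <- sel & mut$atom_name == "CA"
          dir <- c(mean(mut$x[ca]), mean(mut$y[ca]), 0)
          dir <- dir / sqrt(sum(dir^2))
        } else {
          v <- stats::rnorm(3)
          dir <- v / sqrt(sum(v^2))
        }
        mut$x[sel] <- mut$x[sel] + mag * dir[1]
        mut$y[sel] <- mut$y[sel] + mag * dir[2]
        mut$z[sel] <- mut$z[sel] + mag * dir[3]
      }
    }
  }
  mut <- noisy(mut)

  if (cfg$altloc_fraction > 0) {
    n_res <- cfg$n_residues_per_chain
    chosen <- sort(sample(seq_len(n_res),
                          size = round(cfg$altloc_fraction * n_res)))
    side <- mut$res_seq %in% chosen &
      !(mut$atom_name %in% c("N", "CA", "C", "O"))
    alt_b <- mut[side, , drop = FALSE]
    alt_b$altloc <- "B"
    alt_b$occupancy <- 0.4
    alt_b$x <- alt_b$x + stats::rnorm(nrow(alt_b), 0, 0.5)
    alt_b$y <- alt_b$y + stats::rnorm(nrow(alt_b), 0, 0.5)
    alt_b$z <- alt_b$z + stats::rnorm(nrow(alt_b), 0, 0.5)
    mut$altloc[side] <- "A"
    mut$occupancy[side] <- 0.6
    mut <- dplyr::bind_rows(mut, alt_b)
    mut <- dplyr::arrange(mut, .data$chain, .data$res_seq, .data$atom_name,
                          .data$altloc)
  }

  meta <- list(seed = cfg$seed, fold = cfg$fold_template,
               control_noise_sd = cfg$control_noise_sd)
  out <- list(
    wt1 = pentamer("SYN-WT1", wt1, c(meta, role = "reference1")),
    wt2 = pentamer("SYN-WT2", wt2, c(meta, role = "reference2")),
    mutant = pentamer("SYN-MUT", mut, c(meta, role = "mutant"))
  )
  attr(out, "truth") <- list(
    perturbed = if (is.null(cfg$perturbation)) integer(0) else
      sort(unique(cfg$perturbation$res_seq)),
    mutated = if (is.null(cfg$mutated_positions)) integer(0) else
      sort(as.integer(names(cfg$mutated_positions)))
  )
  out
}

#' Configuration for synthetic oocyte dose-response datasets
#'
#' Emulates a multi-batch two-electrode voltage clamp recording campaign:
#' every batch of oocytes carries its own wild-type pH50 offset, each
#' oocyte draws an individual Hill slope and a lognormal maximal current,
#' currents follow the Hill activation curve with multiplicative Gaussian
#' noise, each response is read out as two noisy peaks, and a configurable
#' fraction of recordings is deliberately corrupted (flat traces or
#' sub-threshold currents) to exercise the QC filters.
#'
#' @param n_batches Number of oocyte batches.
#' @param wt_ph50_mean Mean wild-type pH50.
#' @param wt_ph50_batch_sd Between-batch sd of the wild-type pH50.
#' @param hill_mean,hill_sd Per-oocyte Hill slope distribution.
#' @param imax_meanlog,imax_sdlog Lognormal parameters of the per-oocyte
#'   maximal current (uA).
#' @param current_noise_frac Multiplicative Gaussian noise fraction on each
#'   recorded peak.
#' @param construct_shifts Named numeric vector of true pH50 shifts per
#'   construct (`Wt` must be present, shift 0).
#' @param ph_grid Descending pH series; default 7.0 down to 4.0 in
#'   0.5-unit steps ending at 3.7, the standard protocol grid.
#' @param n_per_batch Oocytes per construct per batch.
#' @param corrupted_fraction Fraction of recordings replaced by a corrupted
#'   class (alternating flat-trace and low-current).
#' @param seed Integer seed.
#' @return Named list of class `ephys_sim_config`.
#' @export
ephys_sim_config <- function(n_batches = 3,
                             wt_ph50_mean = 5.0,
                             wt_ph50_batch_sd = 0.3,
                             hill_mean = 1.5, hill_sd = 0.2,
                             imax_meanlog = log(5), imax_sdlog = 0.4,
                             current_noise_frac = 0.05,
                             construct_shifts = c(Wt = 0),
                             ph_grid = c(7, 6.5, 6, 5.5, 5, 4.5, 4, 3.7),
                             n_per_batch = 2,
                             corrupted_fraction = 0,
                             seed = 1L) {
  stopifnot(all(diff(ph_grid) < 0), all(ph_grid >= 3.7), all(ph_grid <= 8),
            "Wt" %in% names(construct_shifts),
            corrupted_fraction >= 0, corrupted_fraction <= 1)
  structure(list(n_batches = n_batches, wt_ph50_mean = wt_ph50_mean,
                 wt_ph50_batch_sd = wt_ph50_batch_sd,
                 hill_mean = hill_mean, hill_sd = hill_sd,
                 imax_meanlog = imax_meanlog, imax_sdlog = imax_sdlog,
                 current_noise_frac = current_noise_frac,
                 construct_shifts = construct_shifts, ph_grid = ph_grid,
                 n_per_batch = n_per_batch,
                 corrupted_fraction = corrupted_fraction,
                 seed = as.integer(seed)),
            class = "ephys_sim_config")
}

#' Generate a synthetic oocyte measurements table
#'
#' @param cfg An [ephys_sim_config()].
#' @return Measurements tibble (`oocyte_id`, `batch_id`, `construct`,
#'   `ph`, `peak1`, `peak2`) suitable for [build_recordings()], with the
#'   per-oocyte ground truth attached as attribute `truth` (tibble with
#'   `oocyte_id`, `construct`, `batch_id`, `true_ph50`, `true_hill`,
#'   `true_imax`, `corrupted`).
#' @export
simulate_ephys_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ephys_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  rows <- list()
  truth <- list()
  oocyte_n <- 0L
  corrupt_kind <- 0L
  for (b in seq_len(cfg$n_batches)) {
    batch_id <- sprintf("batch%02d", b)
    batch_wt_ph50 <- cfg$wt_ph50_mean + stats::rnorm(1, 0,
                                                     cfg$wt_ph50_batch_sd)
    for (construct in names(cfg$construct_shifts)) {
      for (i in seq_len(cfg$n_per_batch)) {
        oocyte_n <- oocyte_n + 1L
        oocyte_id <- sprintf("oo%04d", oocyte_n)
        ph50 <- batch_wt_ph50 + cfg$construct_shifts[[construct]]
        hill <- max(0.2, stats::rnorm(1, cfg$hill_mean, cfg$hill_sd))
        imax <- stats::rlnorm(1, cfg$imax_meanlog, cfg$imax_sdlog)
        corrupted <- stats::runif(1) < cfg$corrupted_fraction
        kind <- NA_character_
        ideal <- hill_current(cfg$ph_grid, ph50, hill, imax)
        if (corrupted) {
          corrupt_kind <- corrupt_kind + 1L
          if (corrupt_kind %% 2L == 1L) {
            kind <- "flat"
            # featureless low-amplitude trace: nothing to fit
            ideal <- rep(0.3, length(cfg$ph_grid))
          } else {
            kind <- "low_imax"
            ideal <- ideal * (0.4 / imax)
            imax <- 0.4
          }
        }
        noise <- function(v) {
          pmax(0, v * (1 + stats::rnorm(length(v), 0,
                                        cfg$current_noise_frac)))
        }
        rows[[oocyte_n]] <- tibble::tibble(
          oocyte_id = oocyte_id, batch_id = batch_id, construct = construct,
          ph = cfg$ph_grid, peak1 = noise(ideal), peak2 = noise(ideal))
        truth[[oocyte_n]] <- tibble::tibble(
          oocyte_id = oocyte_id, construct = construct, batch_id = batch_id,
          true_ph50 = ph50, true_hill = hill, true_imax = imax,
          corrupted = corrupted, corruption = kind)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}
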