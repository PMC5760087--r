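# Fixtures are built in code: a tiny ideal pentamer, rigid-transform
# helpers, and an independent brute-force deviation oracle used to
# cross-check the package's superposition/averaging route.

ideal_pentamer <- function(n_res = 6, id = "IDEAL") {
  atoms <- pentascan:::ideal_pentamer_atoms(
    pentascan:::build_template_chain(n_res, "helix"))
  pentamer(id, atoms)
}

rot_z_deg <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply x -> x R^T + t to all atoms of a pentamer
transform_pentamer <- function(p, rot, trans) {
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rot), 2, trans, `+`)
  p$atoms$x <- xyz[, 1]
  p$atoms$y <- xyz[, 2]
  p$atoms$z <- xyz[, 3]
  p
}

# noise-free proton dose-response series
hill_series <- function(ph50, hill, imax,
                        ph = c(7, 6.5, 6, 5.5, 5, 4.5, 4, 3.7)) {
  tibble::tibble(ph = ph, current = imax / (1 + 10^(hill * (ph - ph50))))
}

# Independent brute-force oracle for the averaged C-alpha deviation
# profile: re-enumerates the alignment scheme with plain loops, fits each
# task with bio3d::fit.xyz, and averages pooled per-position distances.
oracle_dca_profile <- function(mobile, reference) {
  pairs <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"))
  tasks <- list()
  for (mp in pairs) for (rp in pairs) tasks <- c(tasks, list(list(m = mp, r = rp)))
  for (rc in LETTERS[1:5]) tasks <- c(tasks, list(list(m = "E", r = rc)))
  for (mc in LETTERS[1:4]) tasks <- c(tasks, list(list(m = mc, r = "E")))

  ca <- function(p, ch) {
    a <- p$atoms[p$atoms$chain == ch & p$atoms$atom_name == "CA", ]
    a[order(a$res_seq), ]
  }
  samples <- list()
  for (t in tasks) {
    mm <- do.call(rbind, lapply(t$m, ca, p = mobile))
    rr <- do.call(rbind, lapply(t$r, ca, p = reference))
    stopifnot(nrow(mm) == nrow(rr))
    fixed <- as.numeric(t(as.matrix(rr[, c("x", "y", "z")])))
    mob <- as.numeric(t(as.matrix(mm[, c("x", "y", "z")])))
    moved <- matrix(suppressWarnings(bio3d::fit.xyz(fixed, mob)),
                    ncol = 3, byrow = TRUE)
    d <- sqrt(rowSums((moved - as.matrix(rr[, c("x", "y", "z")]))^2))
    samples[[length(samples) + 1]] <-
      data.frame(res_seq = mm$res_seq, dca = d)
  }
  pooled <- do.call(rbind, samples)
  agg <- stats::aggregate(dca ~ res_seq, pooled, mean)
  agg[order(agg$res_seq), ]
}
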