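#' Plot a normalized per-residue deviation profile
#'
#' Draws the control-normalized C-alpha displacement ratio along the
#' sequence with the fold-change threshold as a dashed line and flagged
#' residues highlighted, mirroring the usual presentation of such
#' profiles.
#'
#' @param object A `normalized_profile` from [normalize_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  thr <- attr(object, "threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_seq, y = .data$dca_ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = df[df$flagged, , drop = FALSE],
                        colour = "firebrick", size = 2) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "residue number",
      y = expression(Delta * C * alpha / Delta * C * alpha["ctrl"]),
      title = attr(object, "mutant_id"),
      subtitle = paste0("flagging threshold: ", thr, "-fold")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an averaged deviation profile
#'
#' @param object A `deviation_profile` from [average_profile()].
#' @param ... Unused.
#' @return A ggplot object showing the per-residue C-alpha displacement
#'   and heavy-atom RMSD averaged over the alignment scheme.
#' @export
autoplot.deviation_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("v_rmsd", "v_dca"),
                            names_to = "measure", values_to = "value")
  df$measure <- dplyr::recode(df$measure, v_rmsd = "heavy-atom RMSD",
                              v_dca = "C-alpha displacement")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_seq, y = .data$value,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "residue number", y = "mean deviation (Å)",
      colour = NULL,
      title = paste0(attr(object, "mobile_id"), " vs ",
                     attr(object, "reference_id"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted dose-response curve
#'
#' Shows the recorded mean peak currents (normalized to the fitted maximal
#' current) against pH together with the fitted sigmoid and the pH50
#' midpoint.
#'
#' @param object A `dose_fit` from [fit_dose_response()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_fit <- function(object, ...) {
  s <- object$series
  if (!object$converged) {
    return(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$ph, y = .data$current)) +
        ggplot2::geom_point() +
        ggplot2::scale_x_reverse() +
        ggplot2::labs(x = "pH", y = "current (µA)",
                      title = "dose-response fit did not converge") +
        ggplot2::theme_minimal()
    )
  }
  grid <- tibble::tibble(ph = seq(max(s$ph), min(s$ph), length.out = 200))
  grid$i_norm <- hill_current(grid$ph, object$ph50, object$hill, 1)
  s$i_norm <- s$current / object$imax
  ggplot2::ggplot(s, ggplot2::aes(x = .data$ph, y = .data$i_norm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ph50, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "pH", y = expression(I / I[max]),
      title = sprintf("pH50 = %.2f, Hill = %.2f, Imax = %.2f µA [%s]",
                      object$ph50, object$hill, object$imax,
                      object$qc_status)
    ) +
    ggplot2::theme_minimal()
}
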