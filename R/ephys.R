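#' Quality-control criteria for dose-response fits and classification
#'
#' Bundles the thresholds used across the electrophysiology pipeline: a
#' per-oocyte fit is kept only when its coefficient of determination,
#' Hill slope, and maximal current pass the filters, and a mutant is called
#' a gain or loss of function only when both its mean batch-matched pH50
#' shift and its mean pH50 relative to wild type exceed the significance
#' shift (strict inequality).
#'
#' @param r2_min Minimum R-squared of a passing fit.
#' @param hill_min,hill_max Admissible Hill-slope range.
#' @param imax_min Minimum fitted maximal current, uA.
#' @param significance_shift Minimal |shift| in pH units for a gain/loss
#'   call.
#' @param t_alpha Reporting threshold for the Student t test p value
#'   (reported alongside; the shift criterion governs the label).
#' @param min_n Minimum number of QC-passing oocytes for a summary.
#' @return Named list of class `qc_criteria`.
#' @export
qc_criteria <- function(r2_min = 0.9, hill_min = 0.6, hill_max = 4,
                        imax_min = 0.9, significance_shift = 0.5,
                        t_alpha = 0.01, min_n = 2) {
  structure(list(r2_min = r2_min, hill_min = hill_min, hill_max = hill_max,
                 imax_min = imax_min,
                 significance_shift = significance_shift,
                 t_alpha = t_alpha, min_n = min_n),
            class = "qc_criteria")
}

#' Build per-oocyte recordings from a measurements table
#'
#' Each current response is recorded twice; the series value at a pH is the
#' mean of the two peak amplitudes. Rows sharing one oocyte and pH
#' (repeated applications) are averaged together with a message.
#'
#' @param measurements Data frame with columns `oocyte_id`, `batch_id`,
#'   `construct`, `ph`, and `peak1`/`peak2` (or `peak1_uA`/`peak2_uA`),
#'   peak current amplitudes in uA reported as positive magnitudes with the
#'   holding current subtracted.
#' @return Nested tibble, one row per oocyte: `oocyte_id`, `batch_id`,
#'   `construct`, `n_ph`, and list column `series` of tibbles
#'   (`ph`, `current`).
#' @export
build_recordings <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  nm <- names(m)
  names(m)[nm == "peak1_uA"] <- "peak1"
  names(m)[nm == "peak2_uA"] <- "peak2"
  required <- c("oocyte_id", "batch_id", "construct", "ph", "peak1", "peak2")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("measurements lack columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(m$peak1)) || any(!is.finite(m$peak2)) ||
      any(m$peak1 < 0) || any(m$peak2 < 0)) {
    stop("peak currents must be finite and >= 0 (magnitudes)")
  }
  if (any(m$ph < 3 | m$ph > 9)) {
    stop("pH values outside the plausible recording range [3, 9]")
  }
  m$current <- (m$peak1 + m$peak2) / 2
  dup <- dplyr::summarise(
    dplyr::group_by(m, .data$oocyte_id, .data$ph),
    n = dplyr::n(), .groups = "drop")
  if (any(dup$n > 1)) {
    message("averaging repeated pH applications for oocyte(s): ",
            paste(unique(dup$oocyte_id[dup$n > 1]), collapse = ", "))
  }
  grouped <- dplyr::summarise(
    dplyr::group_by(m, .data$oocyte_id, .data$batch_id, .data$construct,
                    .data$ph),
    current = mean(.data$current), .groups = "drop")
  out <- tidyr::nest(grouped, series = c("ph", "current"))
  out$series <- purrr::map(out$series, function(s) dplyr::arrange(s, -s$ph))
  out$n_ph <- purrr::map_int(out$series, nrow)
  out
}

# Hill-type proton activation curve: current grows as pH drops below pH50.
hill_current <- function(ph, ph50, hill, imax) {
  imax / (1 + 10^(hill * (ph - ph50)))
}

#' Fit a proton dose-response curve for one oocyte
#'
#' Least-squares fit of the sigmoidal activation model
#' \deqn{I(pH) = Imax / (1 + 10^{h (pH - pH50)})}
#' with the bottom fixed at zero and a positive Hill slope `h` (the sign
#' convention for a channel activated by protons: current rises as pH
#' drops). Optimization is bounded Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with pH50 in \[3, 8\], `h` in \[0.05, 10\], and
#' `Imax > 0`, started from the half-maximum pH by linear interpolation,
#' `h = 1.5`, and the maximal observed current, with a fixed deterministic
#' restart grid on failure. R-squared is `1 - SS_res/SS_tot` with `SS_tot`
#' about the mean of the series currents. The QC status applies the
#' exclusion filters in fixed precedence: convergence, then R-squared, then
#' Hill slope, then Imax; passing fits satisfy all filters.
#'
#' @param series Tibble/data frame with columns `ph` and `current` (uA), or
#'   one row of [build_recordings()] output.
#' @param criteria A [qc_criteria()] list.
#' @return Object of class `dose_fit`: list with `ph50`, `hill`, `imax`,
#'   `r2`, `qc_status` (`pass`, `fail_r2`, `fail_hill`, `fail_imax`,
#'   `fail_convergence`), `converged`, `n_ph`, and the input `series`.
#' @export
fit_dose_response <- function(series, criteria = qc_criteria()) {
  if (is.data.frame(series) && "series" %in% names(series)) {
    series <- series$series[[1]]
  }
  ph <- series$ph
  current <- series$current
  if (length(unique(ph)) < 3) {
    stop("insufficient data: need >= 3 distinct pH points")
  }
  if (max(current) <= 0) {
    stop("insufficient data: all currents are zero")
  }

  fit_one <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        current ~ imax / (1 + 10^(hill * (ph - ph50))),
        data = data.frame(ph = ph, current = current),
        start = start,
        lower = c(ph50 = 3, hill = 0.05, imax = 1e-6),
        upper = c(ph50 = 8, hill = 10, imax = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL,
      warning = function(w) NULL
    )
  }

  start0 <- list(ph50 = interp_half_max(ph, current), hill = 1.5,
                 imax = max(current))
  fit <- fit_one(start0)
  if (is.null(fit)) {
    grid <- expand.grid(ph50 = c(4, 5, 6, 7), hill = c(0.8, 1.5, 3))
    best_rss <- Inf
    for (g in seq_len(nrow(grid))) {
      f <- fit_one(list(ph50 = grid$ph50[g], hill = grid$hill[g],
                        imax = max(current)))
      if (!is.null(f)) {
        rss <- sum(stats::residuals(f)^2)
        if (rss < best_rss) {
          best_rss <- rss
          fit <- f
        }
      }
    }
  }

  if (is.null(fit)) {
    res <- list(ph50 = NA_real_, hill = NA_real_, imax = NA_real_,
                r2 = NA_real_, qc_status = "fail_convergence",
                converged = FALSE, n_ph = length(unique(ph)),
                series = tibble::tibble(ph = ph, current = current))
    return(structure(res, class = "dose_fit"))
  }

  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((current - mean(current))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  qc <- if (is.na(r2) || r2 < criteria$r2_min) {
    "fail_r2"
  } else if (cf[["hill"]] < criteria$hill_min ||
             cf[["hill"]] > criteria$hill_max) {
    "fail_hill"
  } else if (cf[["imax"]] < criteria$imax_min) {
    "fail_imax"
  } else {
    "pass"
  }
  structure(
    list(ph50 = cf[["ph50"]], hill = cf[["hill"]], imax = cf[["imax"]],
         r2 = r2, qc_status = qc, converged = TRUE,
         n_ph = length(unique(ph)),
         series = tibble::tibble(ph = ph, current = current)),
    class = "dose_fit"
  )
}

# pH at half-maximal current by linear interpolation on the sorted series;
# falls back to the median pH when the series does not bracket half-max.
interp_half_max <- function(ph, current) {
  o <- order(ph, decreasing = TRUE)
  ph <- ph[o]
  current <- current[o]
  half <- max(current) / 2
  above <- which(current >= half)[1]
  if (is.na(above) || above == 1) return(stats::median(ph))
  p1 <- ph[above - 1]; p2 <- ph[above]
  c1 <- current[above - 1]; c2 <- current[above]
  if (c2 == c1) return((p1 + p2) / 2)
  est <- p1 + (half - c1) * (p2 - p1) / (c2 - c1)
  min(max(est, 3), 8)
}

#' @export
print.dose_fit <- function(x, ...) {
  cat("<dose_fit> pH50 ", format(x$ph50, digits = 4), ", Hill ",
      format(x$hill, digits = 3), ", Imax ", format(x$imax, digits = 3),
      " uA, R2 ", format(x$r2, digits = 4), " [", x$qc_status, "]\n",
      sep = "")
  invisible(x)
}

#' @rdname fit_dose_response
#' @param x A `dose_fit` object.
#' @param ... Unused.
#' @export
tidy.dose_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ph50", "hill", "imax"),
    estimate = c(x$ph50, x$hill, x$imax)
  )
}

#' @rdname fit_dose_response
#' @export
glance.dose_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, qc_status = x$qc_status,
                 converged = x$converged, n_ph = x$n_ph)
}

#' Fit dose-response curves for every recording
#'
#' Maps [fit_dose_response()] over the recordings of [build_recordings()]
#' and returns one row per oocyte.
#'
#' @param recordings Output of [build_recordings()].
#' @param criteria A [qc_criteria()] list.
#' @return Tibble with `oocyte_id`, `batch_id`, `construct`, `ph50`,
#'   `hill`, `imax`, `r2`, `qc_status`, `n_ph`.
#' @export
fit_recordings <- function(recordings, criteria = qc_criteria()) {
  fits <- purrr::map(recordings$series, function(s) {
    tryCatch(fit_dose_response(s, criteria),
             error = function(e) {
               structure(list(ph50 = NA_real_, hill = NA_real_,
                              imax = NA_real_, r2 = NA_real_,
                              qc_status = "fail_convergence",
                              converged = FALSE,
                              n_ph = length(unique(s$ph)), series = s),
                         class = "dose_fit")
             })
  })
  tibble::tibble(
    oocyte_id = recordings$oocyte_id,
    batch_id = recordings$batch_id,
    construct = recordings$construct,
    ph50 = purrr::map_dbl(fits, "ph50"),
    hill = purrr::map_dbl(fits, "hill"),
    imax = purrr::map_dbl(fits, "imax"),
    r2 = purrr::map_dbl(fits, "r2"),
    qc_status = purrr::map_chr(fits, "qc_status"),
    n_ph = purrr::map_int(fits, "n_ph")
  )
}

#' Batch-matched pH50 shifts
#'
#' For every QC-passing mutant fit, the shift is its pH50 minus the mean
#' pH50 of the QC-passing wild-type oocytes recorded in the same batch;
#' referencing within a batch cancels the batch-to-batch variation of the
#' wild-type response exactly. Fits in batches without any QC-passing
#' wild-type oocyte get `NA` (they are excluded from shift aggregation but
#' still contribute to pH50 aggregation) with a warning naming the batches.
#'
#' @param fits Fit table from [fit_recordings()].
#' @param wt_construct Label of the wild-type construct.
#' @return `fits` with an added `dph50` column (`NA` for wild-type rows,
#'   non-passing fits, and unusable batches).
#' @export
delta_ph50 <- function(fits, wt_construct = "Wt") {
  wt <- dplyr::filter(fits, .data$construct == wt_construct,
                      .data$qc_status == "pass")
  if (nrow(wt) == 0) {
    stop("no QC-passing ", wt_construct, " fits in any batch")
  }
  wt_by_batch <- dplyr::summarise(
    dplyr::group_by(wt, .data$batch_id),
    wt_mean = mean(.data$ph50), .groups = "drop")
  out <- dplyr::left_join(fits, wt_by_batch, by = "batch_id")
  out$dph50 <- ifelse(
    out$construct != wt_construct & out$qc_status == "pass",
    out$ph50 - out$wt_mean, NA_real_)
  unusable <- unique(out$batch_id[
    out$construct != wt_construct & out$qc_status == "pass" &
      is.na(out$wt_mean)])
  if (length(unusable) > 0) {
    warning("no QC-passing ", wt_construct, " in batch(es) ",
            paste(unusable, collapse = ", "),
            "; shifts unavailable there")
  }
  out$wt_mean <- NULL
  out
}

#' Summarize and classify mutants
#'
#' Aggregates QC-passing fits per construct: mean and standard deviation of
#' pH50 and of the batch-matched shift, a two-sided two-sample Student
#' t test (equal variance) of the construct's pH50 values against wild
#' type, and a classification. A construct is a gain of function when both
#' its mean shift and its mean pH50 relative to the global wild-type mean
#' exceed `+significance_shift` (strictly), a loss of function when both
#' fall below `-significance_shift`, otherwise no effect;
#' `insufficient_data` when fewer than `min_n` fits pass QC or no shift
#' could be batch-referenced. The p value is reported alongside; the shift
#' criterion governs the label.
#'
#' @param fits Fit table from [fit_recordings()] (the shift column is added
#'   via [delta_ph50()] if absent).
#' @param criteria A [qc_criteria()] list.
#' @param wt_construct Label of the wild-type construct.
#' @return Tibble, one row per construct: `construct`, `n_pass`, `n_total`,
#'   `mean_ph50`, `sd_ph50`, `mean_dph50`, `sd_dph50`, `t_p_value`,
#'   `classification` (the wild-type row is labelled `reference`).
#' @export
summarize_mutants <- function(fits, criteria = qc_criteria(),
                              wt_construct = "Wt") {
  if (!"dph50" %in% names(fits)) {
    fits <- delta_ph50(fits, wt_construct)
  }
  wt_pass <- dplyr::filter(fits, .data$construct == wt_construct,
                           .data$qc_status == "pass")
  if (nrow(wt_pass) < 2) {
    stop("need >= 2 QC-passing ", wt_construct, " fits for a reference")
  }
  wt_mean <- mean(wt_pass$ph50)
  shift <- criteria$significance_shift

  per <- dplyr::group_by(fits, .data$construct)
  out <- dplyr::summarise(
    per,
    n_pass = sum(.data$qc_status == "pass"),
    n_total = dplyr::n(),
    mean_ph50 = mean(.data$ph50[.data$qc_status == "pass"]),
    sd_ph50 = stats::sd(.data$ph50[.data$qc_status == "pass"]),
    mean_dph50 = mean(.data$dph50[.data$qc_status == "pass"], na.rm = TRUE),
    sd_dph50 = stats::sd(.data$dph50[.data$qc_status == "pass"], na.rm = TRUE),
    n_dph50 = sum(!is.na(.data$dph50[.data$qc_status == "pass"])),
    t_p_value = tryCatch(
      stats::t.test(.data$ph50[.data$qc_status == "pass"], wt_pass$ph50,
                    var.equal = TRUE)$p.value,
      error = function(e) NA_real_),
    .groups = "drop"
  )
  out$mean_dph50[is.nan(out$mean_dph50)] <- NA_real_
  out$classification <- dplyr::case_when(
    out$construct == wt_construct ~ "reference",
    out$n_pass < criteria$min_n ~ "insufficient_data",
    out$n_dph50 == 0 ~ "insufficient_data",
    out$mean_dph50 > shift & (out$mean_ph50 - wt_mean) > shift ~ "gain",
    out$mean_dph50 < -shift & (out$mean_ph50 - wt_mean) < -shift ~ "loss",
    TRUE ~ "no_effect"
  )
  out$n_dph50 <- NULL
  dplyr::arrange(out, .data$construct != wt_construct, .data$construct)
}
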