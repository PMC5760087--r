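test_that("recordings average duplicate peaks and pH applications", {
  meas <- tibble::tibble(
    oocyte_id = c("o1", "o1", "o1", "o2", "o2", "o2"),
    batch_id = "b1",
    construct = "Wt",
    ph = c(5, 6, 7, 5, 6, 7),
    peak1 = c(2, 1, 0.5, 4, 2, 1),
    peak2 = c(4, 3, 0.7, 4, 2, 1))
  rec <- build_recordings(meas)
  expect_equal(nrow(rec), 2)
  s1 <- rec$series[[which(rec$oocyte_id == "o1")]]
  expect_equal(s1$current[s1$ph == 5], 3)

  # repeated application at one pH is averaged with a note
  meas2 <- dplyr::bind_rows(meas, tibble::tibble(
    oocyte_id = "o1", batch_id = "b1", construct = "Wt",
    ph = 5, peak1 = 5, peak2 = 5))
  expect_message(rec2 <- build_recordings(meas2), "o1")
  s2 <- rec2$series[[which(rec2$oocyte_id == "o1")]]
  expect_equal(s2$current[s2$ph == 5], 4) # mean of series means 3 and 5

  expect_error(build_recordings(dplyr::mutate(meas, peak1 = -peak1)),
               ">= 0")
  expect_error(build_recordings(dplyr::mutate(meas, ph = ph + 5)),
               "range")
})

test_that("noise-free curves are recovered exactly and pass QC", {
  f <- fit_dose_response(hill_series(5, 1.5, 4))
  expect_equal(f$ph50, 5, tolerance = 1e-6)
  expect_equal(f$hill, 1.5, tolerance = 1e-6)
  expect_equal(f$imax, 4, tolerance = 1e-6)
  expect_gt(f$r2, 1 - 1e-9)
  expect_equal(f$qc_status, "pass")
  # midpoint identity: I at the fitted pH50 is Imax / 2
  expect_equal(f$imax / (1 + 10^(f$hill * (f$ph50 - f$ph50))), f$imax / 2)
  expect_equal(tidy(f)$estimate, c(5, 1.5, 4), tolerance = 1e-6)
  expect_equal(glance(f)$qc_status, "pass")
})

test_that("each QC filter catches its engineered violation", {
  expect_equal(fit_dose_response(hill_series(5, 0.5, 4))$qc_status,
               "fail_hill")
  expect_equal(fit_dose_response(hill_series(5, 4.5, 4))$qc_status,
               "fail_hill")
  expect_equal(fit_dose_response(hill_series(5, 1.5, 0.5))$qc_status,
               "fail_imax")
  zig <- hill_series(5, 1.5, 4)
  zig$current <- zig$current * rep(c(1.6, 0.4), 4)
  expect_equal(fit_dose_response(zig)$qc_status, "fail_r2")
  # boundary values are inclusive for the Hill window
  expect_equal(fit_dose_response(hill_series(5, 0.6, 4))$qc_status, "pass")
  expect_equal(fit_dose_response(hill_series(5, 4, 4))$qc_status, "pass")
})

test_that("insufficient series are rejected", {
  expect_error(fit_dose_response(tibble::tibble(ph = c(5, 6),
                                                current = c(1, 2))),
               "3 distinct")
  expect_error(fit_dose_response(tibble::tibble(ph = c(5, 6, 7),
                                                current = c(0, 0, 0))),
               "zero")
})

test_that("current scaling shifts only Imax", {
  set.seed(5)
  s <- hill_series(5.2, 1.8, 3)
  s$current <- s$current * (1 + rnorm(nrow(s), 0, 0.05))
  a <- fit_dose_response(s)
  s2 <- s
  s2$current <- s2$current * 2.9
  b <- fit_dose_response(s2)
  expect_equal(b$ph50, a$ph50, tolerance = 1e-8)
  expect_equal(b$hill, a$hill, tolerance = 1e-8)
  expect_equal(b$imax, 2.9 * a$imax, tolerance = 1e-6)
})

test_that("batch-matched shifts use same-batch wild-type means", {
  fits <- tibble::tibble(
    oocyte_id = paste0("o", 1:4),
    batch_id = c("b1", "b1", "b1", "b2"),
    construct = c("Wt", "Wt", "mutA", "mutA"),
    ph50 = c(5.0, 5.2, 6.5, 6.0),
    hill = 1.5, imax = 4, r2 = 0.99,
    qc_status = "pass", n_ph = 8L)
  expect_warning(d <- delta_ph50(fits), "b2")
  expect_equal(d$dph50[d$oocyte_id == "o3"], 6.5 - 5.1)
  expect_true(is.na(d$dph50[d$oocyte_id == "o4"])) # no Wt in b2
  expect_true(all(is.na(d$dph50[d$construct == "Wt"])))

  # a mutant equal to the batch Wt mean shifts by zero
  fits0 <- dplyr::mutate(fits[1:3, ], ph50 = c(5, 5.2, 5.1))
  expect_equal(delta_ph50(fits0)$dph50[3], 0)

  # a qc-failing Wt does not anchor its batch
  fits_fail <- dplyr::mutate(fits[1:3, ],
                             qc_status = c("fail_r2", "fail_r2", "pass"))
  expect_error(delta_ph50(fits_fail), "no QC-passing")
})

test_that("adding a constant batch offset leaves every shift unchanged", {
  set.seed(8)
  cfg <- ephys_sim_config(construct_shifts = c(Wt = 0, mutA = 1),
                          n_batches = 2, n_per_batch = 3, seed = 8)
  fits <- fit_recordings(build_recordings(simulate_ephys_dataset(cfg)))
  d0 <- delta_ph50(fits)
  shifted <- dplyr::mutate(fits,
                           ph50 = ph50 + ifelse(batch_id == "batch01", 0.7, 0))
  d1 <- delta_ph50(shifted)
  expect_identical(d1$dph50, d0$dph50)
})

test_that("classification applies the strict 0.5-unit double criterion", {
  mk_fits <- function(shift) {
    wt <- tibble::tibble(
      oocyte_id = paste0("w", 1:6),
      batch_id = rep(c("b1", "b2", "b3"), each = 2),
      construct = "Wt",
      ph50 = rep(c(5.0, 5.1, 4.9), each = 2) + c(0, 0.02),
      hill = 1.5, imax = 4, r2 = 0.99, qc_status = "pass", n_ph = 8L)
    mu <- dplyr::mutate(wt, oocyte_id = paste0("m", 1:6),
                        construct = "mutA", ph50 = ph50 + shift)
    dplyr::bind_rows(wt, mu)
  }
  cls <- function(shift) {
    s <- summarize_mutants(mk_fits(shift))
    s$classification[s$construct == "mutA"]
  }
  expect_equal(cls(1.2), "gain")
  expect_equal(cls(-1.2), "loss")
  expect_equal(cls(0.4), "no_effect")
  expect_equal(cls(-0.4), "no_effect")
  # exactly +0.5 is not a gain: strict inequality
  expect_equal(cls(0.5), "no_effect")
  expect_equal(cls(-0.5), "no_effect")

  # insufficient data below the minimum passing count
  f <- mk_fits(1.2)
  f$qc_status[f$oocyte_id %in% paste0("m", 2:6)] <- "fail_r2"
  s <- summarize_mutants(f)
  expect_equal(s$classification[s$construct == "mutA"], "insufficient_data")
  expect_equal(s$n_pass[s$construct == "mutA"], 1L)

  # p values accompany the labels
  s2 <- summarize_mutants(mk_fits(1.2))
  expect_lt(s2$t_p_value[s2$construct == "mutA"], 0.01)
})

test_that("a small simulated scan recovers pH50s and labels", {
  cfg <- ephys_sim_config(
    construct_shifts = c(Wt = 0, gainer = 1.5, loser = -1.5, neutral = 0),
    n_batches = 3, n_per_batch = 2, seed = 19)
  meas <- simulate_ephys_dataset(cfg)
  truth <- attr(meas, "truth")
  fits <- fit_recordings(build_recordings(meas))
  merged <- dplyr::inner_join(fits, truth, by = c("oocyte_id", "construct",
                                                  "batch_id"))
  ok <- merged$qc_status == "pass"
  expect_lt(stats::median(abs(merged$ph50[ok] - merged$true_ph50[ok])), 0.05)
  s <- summarize_mutants(delta_ph50(fits))
  expect_equal(s$classification[match(c("gainer", "loser", "neutral"),
                                      s$construct)],
               c("gain", "loss", "no_effect"))
})
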