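test_that("viability normalization is treated over control times 100", {
  expect_equal(viability_percent(0.84, 0.84), 100)
  expect_equal(viability_percent(0, 0.84), 0)
  expect_equal(viability_percent(0.42, 0.84), 50)
  expect_error(viability_percent(0.1, 0), class = "phytonet_validation_error")
})

test_that("noiseless 4PL data are recovered to high relative accuracy", {
  truth <- list(top = 100, bottom = 0, hill = 1.5, ic50 = 18.09)
  dr <- gen_dose_response(truth$top, truth$bottom, truth$hill, truth$ic50,
    noise_sd = 0, reps = 1, seed = 1)
  fit <- fit_4pl(dr)
  expect_equal(fit$top, truth$top, tolerance = 1e-6)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-6)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-6)
  expect_equal(fit$ic50, truth$ic50, tolerance = 1e-6)
  # midpoint identity and analytic inverse
  expect_equal(predict(fit, fit$ic50), (fit$top + fit$bottom) / 2)
  expect_equal(icq(fit, 50), fit$ic50)
  expect_lt(icq(fit, 25), fit$ic50)
  expect_equal(predict(fit, icq(fit, 25)),
    fit$top - 0.25 * (fit$top - fit$bottom),
    tolerance = 1e-9)
})

test_that("rising curves (negative hill) are also recovered", {
  dr <- gen_dose_response(top = 95, bottom = 5, hill = -2, ic50 = 10,
    noise_sd = 0, reps = 1, seed = 2)
  fit <- fit_4pl(dr)
  expect_equal(fit$hill, -2, tolerance = 1e-5)
  expect_equal(fit$ic50, 10, tolerance = 1e-5)
})

test_that("noisy 4PL fits recover the midpoint within the calibrated error", {
  errs <- vapply(1:100, function(s) {
    dr <- gen_dose_response(100, 0, 1.5, 18.09, noise_sd = 3, reps = 3, seed = s)
    abs(fit_4pl(dr)$ic50 - 18.09) / 18.09
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("degenerate dose-response inputs are rejected with fit errors", {
  flat <- tibble::tibble(concentration = c(1, 2, 4, 8), viability = rep(80, 4))
  expect_error(fit_4pl(flat), class = "phytonet_fit_error")
  short <- tibble::tibble(concentration = c(1, 2, 4), viability = c(90, 50, 10))
  expect_error(fit_4pl(short), class = "phytonet_validation_error")
})

test_that("fourpl_fit tidiers expose parameters and the ic50 on both scales", {
  dr <- gen_dose_response(100, 0, 2, 20, noise_sd = 2, reps = 3, seed = 5)
  fit <- fit_4pl(dr)
  td <- tidy(fit)
  expect_setequal(td$term, c("top", "bottom", "hill", "lic50", "ic50"))
  expect_equal(td$estimate[td$term == "ic50"], 10^td$estimate[td$term == "lic50"])
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 27L)
  expect_gt(gl$sigma, 0)
})

test_that("selectivity indices and unit invariance", {
  expect_equal(round_half_up(selectivity_index(77.76, 18.09), 2), 4.30)
  expect_equal(round_half_up(selectivity_index(77.76, 27.74), 2), 2.80)
  expect_equal(selectivity_index(12, 12), 1)
  # rescaling both concentration axes leaves the fitted SI unchanged
  ic_data <- gen_dose_response(100, 0, 1.5, 18, noise_sd = 1, reps = 3, seed = 8)
  cc_data <- gen_dose_response(100, 5, 1.2, 78, noise_sd = 1, reps = 3, seed = 9)
  si1 <- selectivity_index(fit_4pl(cc_data)$ic50, fit_4pl(ic_data)$ic50)
  rescale <- function(d, f) dplyr::mutate(d, concentration = concentration * f)
  si2 <- selectivity_index(
    fit_4pl(rescale(cc_data, 1000))$ic50,
    fit_4pl(rescale(ic_data, 1000))$ic50
  )
  expect_equal(si1, si2, tolerance = 1e-6)
})

test_that("NCI classification applies inclusive activity and strict selectivity", {
  res <- nci_classify(c(18.09, 27.74, 66.04, 30), c(4.30, 2.80, 1.18, 3))
  expect_equal(res$active, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(res$selective, c(TRUE, FALSE, FALSE, FALSE))
  # monotone: lowering ic50 never unsets active; raising si never unsets selective
  base <- nci_classify(25, 3.5)
  expect_true(all(nci_classify(20, 3.5)$active >= base$active))
  expect_true(all(nci_classify(25, 5)$selective >= base$selective))
})

test_that("cytotoxicity profiles combine CC50, IC50, SI and flags", {
  data <- dplyr::filter(mq_cytotoxicity(), agent == "MQLEO")
  prof <- cytotoxicity_profile(data)
  expect_equal(prof$si_2dp[prof$cell_line == "A-549"], 4.30)
  expect_true(prof$active[prof$cell_line == "A-549"] &&
    prof$selective[prof$cell_line == "A-549"])
  expect_false(prof$active[prof$cell_line == "HepG-2"] ||
    prof$selective[prof$cell_line == "HepG-2"])
})

test_that("quadrant fractions partition events with gate-inclusive positives", {
  below <- tibble::tibble(annexin = runif(50, 0, 1), pi = runif(50, 0, 1))
  qf <- quadrant_fractions(below, 2, 2)
  expect_equal(unlist(qf[1, 1:4]),
    c(viable = 100, early_apoptotic = 0, late_apoptotic = 0, necrotic = 0))
  on_gate <- tibble::tibble(annexin = 2, pi = c(1, 2))
  qf2 <- quadrant_fractions(on_gate, 2, 2)
  expect_equal(qf2$early_apoptotic, 50)
  expect_equal(qf2$late_apoptotic, 50)
  for (s in 1:5) {
    set.seed(s)
    ev <- tibble::tibble(annexin = rnorm(200, 2, 1), pi = rnorm(200, 2, 1))
    tot <- rowSums(quadrant_fractions(ev, 2, 2)[, 1:4])
    expect_equal(unname(tot), 100, tolerance = 1e-9)
  }
})

test_that("simulated treated-cell profiles are recovered within a point", {
  # viable fraction is the complement of the published 27.61% total death
  w <- c(0.7239, 0.1502, 0.093, 0.0329)
  flow <- gen_flow_events(w, 50000, seed = 17)
  qf <- quadrant_fractions(flow$events, flow$annexin_gate, flow$pi_gate)
  expect_true(all(abs(unlist(qf[1, 1:4]) - 100 * w) <= 1))
})

test_that("death summary reproduces totals, apoptotic subtotal and fold", {
  out <- death_summary(c(15.02, 9.3, 3.29), c(0.52, 0.18, 1.91))
  expect_equal(out$total_treated, 27.61)
  expect_equal(out$total_control, 2.61)
  expect_equal(out$fold_1dp, 10.6)
  expect_equal(out$apoptotic_treated, 24.32)
  expect_equal(out$apoptotic_control, 0.70)
  same <- death_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$fold_1dp, 1.0)
  undef <- death_summary(c(1, 1, 1), c(0, 0, 0))
  expect_false(undef$fold_defined)
  expect_true(is.na(undef$fold))
})

test_that("cell-cycle gating normalizes over gated events, sub-G1 apart", {
  all_g1 <- cycle_fractions(runif(100, 1.0, 1.9), breaks = c(0.8, 2, 3))
  expect_equal(all_g1$g0g1, 100)
  expect_equal(all_g1$s + all_g1$g2m, 0)
  set.seed(31)
  n <- 50000
  phase <- sample(c("g1", "s", "g2"), n, replace = TRUE, prob = c(0.6, 0.25, 0.15))
  dna <- rnorm(n, mean = c(g1 = 1, s = 1.5, g2 = 2)[phase], sd = 0.08)
  cf <- cycle_fractions(dna, breaks = c(0.5, 1.25, 1.75))
  expect_true(all(abs(c(cf$g0g1, cf$s, cf$g2m) - c(60, 25, 15)) <= 1))
  expect_equal(cf$g0g1 + cf$s + cf$g2m, 100, tolerance = 1e-9)
  expect_error(cycle_fractions(dna, breaks = c(2, 1, 3)),
    class = "phytonet_validation_error")
})

test_that("wound metrics emit closure, relative closure and point reduction", {
  series <- tibble::tibble(
    time_h = c(0, 24, 0, 24),
    arm = c("treated", "treated", "control", "control"),
    area = c(100, 44.2, 100, 10)
  )
  wm <- wound_metrics(series)
  expect_equal(wm$closure_treated, 55.8)
  expect_equal(wm$closure_control, 90)
  expect_equal(round_half_up(wm$relative_closure_pct, 1), 62.0)
  expect_equal(wm$reduction_pp, 34.2)
  # boundary identities
  trivial <- tibble::tibble(
    time_h = c(0, 24, 0, 24),
    arm = c("treated", "treated", "control", "control"),
    area = c(50, 50, 50, 0)
  )
  wt <- wound_metrics(trivial)
  expect_equal(wt$closure_treated, 0)
  expect_equal(wt$closure_control, 100)
  grown <- dplyr::mutate(trivial, area = c(50, 60, 50, 25))
  expect_warning(wg <- wound_metrics(grown), "negative closure")
  expect_true(wg$flag_negative)
})

test_that("Welch test matches the textbook formulas and its conventions", {
  a <- c(1, 2, 3)
  b <- c(2, 3, 4)
  got <- two_group_test(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$statistic, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p_value, want$p)
  same <- two_group_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- two_group_test(c(0, 0, 0) + rnorm(3, 0, 1e-6), c(10, 10, 10) + rnorm(3, 0, 1e-6))
  expect_lt(sep$p_value, 0.001)
})
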