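test_that("ECAR to PER conversion is the documented product and is linear", {
  p <- per_params(2.6, 2.28, 1.6)
  expect_equal(ecar_to_per(0, p), 0)
  expect_equal(ecar_to_per(20, p), 189.696)
  ecar <- c(1, 5.5, -2, 40)
  expect_equal(ecar_to_per(2 * ecar, p), 2 * ecar_to_per(ecar, p))
  # linear in each conversion constant separately
  expect_equal(ecar_to_per(20, per_params(5.2, 2.28, 1.6)),
               2 * ecar_to_per(20, p))
  expect_equal(ecar_to_per(20, per_params(2.6, 4.56, 1.6)),
               2 * ecar_to_per(20, p))
  expect_equal(ecar_to_per(20, per_params(2.6, 2.28, 3.2)),
               2 * ecar_to_per(20, p))
  expect_error(per_params(-1, 2, 1), "positive")
})

test_that("basal glycolysis is the last pre-PMA measurement, not a mean", {
  p <- per_params()
  # drifting baseline: t = 1, 2, 3 min with ECAR 10, 11, 12; PMA at 3.5
  sched <- injection_schedule(c("PMA", "oligomycin", "2DG"),
                              c(3.5, 10, 20), assay = "glycolysis")
  fs <- flux_series("w1", c(1, 2, 3, 4, 5, 12, 25),
                    ecar = c(10, 11, 12, 30, 35, 34, 2), injections = sched)
  expect_equal(basal_glycolysis(fs, p), ecar_to_per(12, p))

  # PMA before all measurements is rejected at construction
  early <- injection_schedule(c("PMA", "oligomycin", "2DG"), c(0.5, 10, 20),
                              assay = "glycolysis")
  expect_error(flux_series("w2", c(1, 2, 3), ecar = c(1, 1, 1),
                           injections = early),
               "before PMA")
})

test_that("fold change uses the PMA-to-oligomycin window only", {
  p <- per_params()
  sched <- glyco_schedule(pma = 3.5, oligo = 10, dg = 20)
  # basal ECAR 10; window peak 38; a larger excursion after oligomycin
  # must be ignored
  fs <- flux_series("w1", c(1, 2, 3, 5, 7, 9, 12, 15, 25),
                    ecar = c(9, 10, 10, 30, 38, 35, 60, 55, 1),
                    injections = sched)
  expect_equal(fold_change_glycolysis(fs, p), 3.8)
  expect_equal(fold_change_glycolysis(fs, p, method = "mean"),
               mean(c(30, 38, 35)) / 10)

  # flat series: no response, fold exactly 1
  flat <- flux_series("w2", c(1, 2, 5, 7, 12, 25),
                      ecar = rep(10, 6), injections = sched)
  expect_equal(fold_change_glycolysis(flat, p), 1)

  # fold change invariant to a joint rescaling of the ECAR units
  fs2 <- flux_series("w3", fs$time_min, ecar = fs$ecar * 7.3,
                     injections = sched)
  expect_equal(fold_change_glycolysis(fs2, p), fold_change_glycolysis(fs, p))

  # zero basal is undefined, not infinite
  zb <- flux_series("w4", c(1, 2, 5, 12, 25), ecar = c(1, 0, 5, 4, 0),
                    injections = sched)
  expect_warning(f <- fold_change_glycolysis(zb, p), "basal")
  expect_true(is.na(f))
})

test_that("QC flags catch mitochondrial contribution and incomplete 2DG shutdown", {
  p <- per_params()
  sched <- glyco_schedule(pma = 3.5, oligo = 10, dg = 20)
  # post-oligomycin PER drops 40%: mitochondrial acidification was present
  mito <- flux_series("w1", c(1, 2, 5, 7, 12, 15, 25, 28),
                      ecar = c(10, 10, 30, 30, 18, 18, 0, 0),
                      injections = sched)
  qc <- qc_flags(mito, p, tol = 0.15)
  expect_true(qc$oligo_sensitive)
  expect_equal(qc$oligo_change, -0.4)
  expect_false(qc$incomplete_2dg_inhibition)

  # residual post-2DG activity above tol x basal
  resid <- flux_series("w2", c(1, 2, 5, 7, 12, 15, 25, 28),
                       ecar = c(10, 10, 30, 30, 30, 30, 5, 5),
                       injections = sched)
  qc2 <- qc_flags(resid, p, tol = 0.15)
  expect_true(qc2$incomplete_2dg_inhibition)
  expect_equal(qc2$residual_after_2dg, 0.5)

  # a clean simulated well raises no flags
  clean <- simulate_flux(noise_sd = 0, mito_fraction = 0, seed = 3)
  qc3 <- qc_flags(clean, p)
  expect_false(qc3$oligo_sensitive)
  expect_false(qc3$incomplete_2dg_inhibition)
  expect_false(qc3$negative_rates)

  neg <- flux_series("w3", c(1, 2, 5, 12, 25), ecar = c(10, 10, -3, 9, 0),
                     injections = sched)
  expect_true(qc_flags(neg, p)$negative_rates)
})

test_that("burst summary integrates the post-PMA OCR curve", {
  sched <- injection_schedule(c("RotAA", "PMA"), c(0, 10), assay = "burst")
  # constant OCR c over a post-PMA window of length T: area c*T
  tm <- c(2, 6, 10, 20, 30, 40, 50)
  const <- flux_series("w1", tm, ocr = c(1, 1, rep(8, 5)),
                       injections = sched)
  bs <- burst_summary(const)
  expect_equal(bs$total_o2, 8 * 40)
  expect_equal(bs$peak_ocr, 8)

  # still-rising curve: the apparent peak sits on the final timepoint, so
  # time_to_peak equals the window length and the peak is right-censored
  ramp <- flux_series("wr", tm, ocr = c(0, 0, 1, 2, 4, 7, 12),
                      injections = sched)
  bsr <- burst_summary(ramp)
  expect_equal(bsr$time_to_peak, 40)
  expect_true(bsr$peak_right_censored)

  # triangular pulse 0 -> P over a, back over b: area P(a+b)/2
  tt <- seq(10, 70, by = 0.25)
  pulse <- ifelse(tt <= 30, (tt - 10) / 20, pmax(0, 1 - (tt - 30) / 40)) * 150
  tri <- flux_series("w2", c(2, 6, tt), ocr = c(0, 0, pulse),
                     injections = sched)
  bs2 <- burst_summary(tri)
  expect_equal(bs2$total_o2, 150 * (20 + 40) / 2, tolerance = 1e-6)
  expect_equal(bs2$peak_ocr, 150)
  expect_equal(bs2$time_to_peak, 20)
  expect_false(bs2$peak_right_censored)
  expect_equal(burst_summary(tri, time_ref = "absolute")$time_to_peak, 30)

  expect_error(burst_summary(
    flux_series("w3", c(1, 5, 8), ocr = c(0, 0, 1),
                injections = injection_schedule("PMA", 7, assay = "burst"))),
    "fewer than 2 post-PMA")
})

test_that("trapezoidal area error decays at second order in the grid step", {
  sched <- injection_schedule(c("RotAA", "PMA"), c(0, 0.5), assay = "burst")
  area <- function(h) {
    tt <- seq(1, 11, by = h)
    fs <- flux_series("w", c(0.1, 0.3, tt), ocr = c(0, 0, (tt - 1)^2),
                      injections = sched)
    burst_summary(fs)$total_o2
  }
  exact <- 10^3 / 3
  err <- abs(c(area(1), area(0.5), area(0.25)) - exact)
  # halving h divides the error by ~4
  expect_equal(err[1] / err[2], 4, tolerance = 0.1)
  expect_equal(err[2] / err[3], 4, tolerance = 0.1)
})
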