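test_that("k-NN imputation reproduces the hand-computed weighting", {
  # observed days {1,4,6,10} = {50,60,60,50}, impute day 5 with k = 4:
  # (50/4 + 60/1 + 60/1 + 50/5) / (1/4 + 1 + 1 + 1/5) = 58.163
  out <- knn_impute_composition(c(1, 4, 5, 6, 10), c(50, 60, NA, 60, 50),
                                k = 4)
  expect_equal(out[3], 142.5 / 2.45, tolerance = 1e-12)
  expect_equal(round(out[3], 2), 58.16)
  # observed values unchanged
  expect_equal(out[-3], c(50, 60, 60, 50))
})

test_that("k-NN imputation limiting and degenerate cases", {
  # equal-valued neighbours on all sides -> that common value
  expect_equal(knn_impute_composition(1:5, c(7, 7, NA, 7, 7), k = 4)[3], 7)
  # k = 1 is nearest-value carry
  expect_equal(knn_impute_composition(c(1, 2, 10), c(3, NA, 9), k = 1)[2], 3)
  expect_error(knn_impute_composition(1:3, c(1, NA, 2), k = 4), "fewer")
  expect_error(knn_impute_composition(1:3, rep(NA_real_, 3), k = 1),
               "all-missing")
})

test_that("blank correction subtracts, scales, clips and averages", {
  days <- c(0, 5, 10)
  mk <- function(id, cond, ch4, bio) {
    data.frame(day = days, bottle_id = id, condition = cond,
               cum_biogas_ml = bio, cum_ch4_ml = ch4, ch4_frac = NA_real_)
  }
  bottles <- data.frame(
    bottle_id = c("a_1", "a_2", "bl_1"), condition = c("a", "a", "blank"),
    vs_feedstock = c(1, 1, 0), vs_inoculum = c(3, 3, 3),
    is_blank = c(FALSE, FALSE, TRUE))

  # replicates with net day-10 CH4 of 40 and 44 -> averaged 42
  ds <- bmp_dataset(rbind(mk("a_1", "a", c(0, 25, 50), c(0, 50, 100)),
                          mk("a_2", "a", c(0, 27, 54), c(0, 54, 108)),
                          mk("bl_1", "blank", c(0, 5, 10), c(0, 10, 20))),
                    bottles)
  net <- blank_correct(ds)
  expect_equal(net$net_ch4_ml[net$day == 10], (50 - 10 + 54 - 10) / 2)
  # bottle identical to the blank -> net curve identically zero
  ds0 <- bmp_dataset(rbind(mk("a_1", "a", c(0, 5, 10), c(0, 10, 20)),
                           mk("a_2", "a", c(0, 5, 10), c(0, 10, 20)),
                           mk("bl_1", "blank", c(0, 5, 10), c(0, 10, 20))),
                     bottles)
  expect_equal(blank_correct(ds0)$net_ch4_ml, rep(0, 3))
  # blank above the bottle -> clipped at zero with a message
  dsneg <- bmp_dataset(rbind(mk("a_1", "a", c(0, 2, 30), c(0, 4, 60)),
                             mk("a_2", "a", c(0, 2, 30), c(0, 4, 60)),
                             mk("bl_1", "blank", c(0, 5, 10), c(0, 10, 20))),
                       bottles)
  expect_message(netneg <- blank_correct(dsneg), "clipped")
  expect_equal(netneg$net_ch4_ml[netneg$day == 5], 0)
  expect_gt(attr(netneg, "clipped"), 0)
  # inoculum-mass scaling: blank per-g curve scaled by the bottle inoculum
  bottles2 <- bottles
  bottles2$vs_inoculum <- c(6, 6, 3)
  ds2 <- bmp_dataset(rbind(mk("a_1", "a", c(0, 25, 50), c(0, 50, 100)),
                           mk("a_2", "a", c(0, 25, 50), c(0, 50, 100)),
                           mk("bl_1", "blank", c(0, 5, 10), c(0, 10, 20))),
                     bottles2)
  net2 <- blank_correct(ds2)
  expect_equal(net2$net_ch4_ml[net2$day == 10], 50 - 10 / 3 * 6)
})

test_that("dataset validation enforces physical invariants", {
  days <- c(0, 5)
  bad <- data.frame(day = days, bottle_id = "a_1", condition = "a",
                    cum_biogas_ml = c(10, 5), cum_ch4_ml = c(5, 2),
                    ch4_frac = NA_real_)
  bottles <- data.frame(bottle_id = c("a_1", "bl_1"),
                        condition = c("a", "blank"),
                        vs_feedstock = c(1, 0), vs_inoculum = c(3, 3),
                        is_blank = c(FALSE, TRUE))
  expect_error(bmp_dataset(bad, bottles), "non-decreasing")
  expect_error(bmp_dataset(bad[0, ], bottles[!bottles$is_blank, ]), "blank")
})

test_that("kinetic curves satisfy their analytic identities", {
  expect_equal(first_order_curve(0, 0.204, 0.57), 0)
  expect_equal(first_order_curve(log(2) / 0.57, 0.204, 0.57), 0.204 / 2,
               tolerance = 1e-12)
  expect_equal(first_order_curve(25, 0.204, 0.57), 0.20399, tolerance = 1e-4)
  expect_error(first_order_curve(-1, 0.2, 0.5), "non-negative")

  # value at the lag point is b0 * exp(-e)
  expect_equal(gompertz_curve(2, 0.204, 76.12, lam = 2),
               0.204 * exp(-exp(1)), tolerance = 1e-12)
  expect_equal(gompertz_curve(0, 0.204, 76.12, lam = 0),
               0.204 * exp(-exp(1)), tolerance = 1e-12)
  # asymptote
  expect_equal(gompertz_curve(1e4, 0.204, 76.12, 0), 0.204,
               tolerance = 1e-9)
  expect_error(gompertz_curve(1, -0.2, 76, 0), "b0")
  # fitted/valid curves are non-decreasing in t
  tt <- seq(0, 25, by = 0.1)
  expect_false(is.unsorted(first_order_curve(tt, 0.204, 0.57)))
  expect_false(is.unsorted(gompertz_curve(tt, 0.204, 76.12, 1.5)))
})

test_that("noiseless fits recover the generating parameters", {
  t <- 0:25
  fo <- fit_model(t, first_order_curve(t, 0.204, 0.57), "first_order")
  expect_lt(abs(fo$k - 0.57), 1e-3)
  expect_lt(fo$rmse, 1e-9)
  expect_true(fo$converged)

  gz <- fit_model(t, gompertz_curve(t, 0.204, 76.12, 0), "gompertz")
  expect_lt(abs(gz$rm - 76.12), 0.1)
  expect_lt(abs(gz$b0 - 0.204), 1e-3)

  expect_error(fit_model(0:2, c(0, 1, 2), "first_order"), "4 points")
  expect_error(fit_model(0:4, rep(1, 5), "first_order"), "degenerate")
})

test_that("fitter reaches the grid-search oracle minimum", {
  set.seed(5)
  t <- 0:25
  b <- first_order_curve(t, 0.204, 0.57) + rnorm(26, sd = 0.004)
  fit <- fit_model(t, b, "first_order")
  oracle <- grid_fit_first_order(t, b,
                                 b0_grid = seq(0.15, 0.25, by = 5e-4),
                                 k_grid = seq(0.3, 0.9, by = 2e-3))
  expect_lte(fit$sse, oracle$sse + 1e-12)
  # argmin within grid resolution (two joint-grid steps) of the oracle's
  expect_lte(abs(fit$k - oracle$k), 2 * 2e-3)
  expect_lte(abs(fit$b0 - oracle$b0), 2 * 5e-4)
})

test_that("rate constant recovery is robust to 2% noise", {
  t <- 0:25
  clean <- first_order_curve(t, 0.204, 0.57)
  rel_err <- vapply(1:100, function(seed) {
    set.seed(seed)
    b <- pmax(clean + rnorm(length(t), sd = 0.02 * 0.204), 0)
    abs(fit_model(t, b, "first_order")$k - 0.57) / 0.57
  }, numeric(1))
  expect_lt(median(rel_err), 0.05)
})

test_that("first-order and Gompertz describe a no-lag curve comparably", {
  # with lam = 0 the sigmoid degenerates towards the exponential shape, so
  # both calibrated models should reach similar residuals
  t <- 0:25
  b <- first_order_curve(t, 0.133, 0.69)
  r_fo <- fit_model(t, b, "first_order")$rmse
  r_gz <- fit_model(t, b, "gompertz")$rmse
  expect_lt(r_gz, 0.05 * 0.133) # within 5% of the asymptote
  expect_lt(r_fo, 1e-9)
})

test_that("bmp_summary computes SMP, SGP, yield and max CH4 content", {
  net <- data.frame(condition = "c", day = c(0, 10, 25),
                    net_ch4_ml = c(0, 150, 204),
                    net_biogas_ml = c(0, 350, 540))
  sm <- bmp_summary(net, ch4_frac = c(0.4, 0.86, 0.6), vs_feedstock = 1)
  expect_equal(sm$smp, 0.204)
  expect_equal(sm$sgp, 0.540)
  expect_equal(sm$biogas_yield, 0.540 * 1.2)
  expect_equal(sm$max_ch4_content, 86)
  # zero methane -> zero SMP
  net0 <- transform(net, net_ch4_ml = 0)
  expect_equal(bmp_summary(net0, 0.5, 1)$smp, 0)
  expect_error(bmp_summary(net, 0.5, vs_feedstock = 0), "> 0")
})

test_that("generated dataset round-trips to the generator's B0 via SMP", {
  ds <- gen_bmp_dataset(fo_params(), bottle_spec("c", noise_sd = 2),
                        measurement_schedule(), seed = 4)
  net <- blank_correct(ds)
  b1 <- ds[ds$bottle_id == "c_1", ]
  frac <- knn_impute_composition(b1$day, b1$ch4_frac)
  sm <- bmp_summary(net, frac, attr(net, "vs_feedstock")[["c"]])
  # day-25 first-order value is within 0.1% of B0; noise adds a few mL
  expect_lt(abs(sm$smp - 0.204) / 0.204, 0.05)
  expect_true(all(frac >= 0 & frac <= 1))
})
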