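expect_balanced <- function(bal, tol = 1e-9) {
  expect_lt(abs(bal[["inflow"]] - bal[["outflow"]]) /
              max(bal[["inflow"]], 1), tol)
}

test_that("stream constructor enforces the composition invariants", {
  expect_error(stream(-1), "mass_flow")
  expect_error(stream(10, ts = 0.1, vs = 0.2), "vs")
  expect_error(stream(10, ts = 1.2), "ts")
  expect_error(stream(10, scod = 10, vfa = 20), "exceed")
  s <- stream(113788, ts = 0.041, vs = 0.031, temperature = 37)
  expect_s3_class(s, "stream")
})

test_that("screw press conserves mass and solids at any capture", {
  feed <- stream(105000, ts = 0.20, vs = 0.15)
  # full capture: reject carries no solids
  full <- screw_press(feed, dry_matter_out = 0.28, ts_capture = 1)
  expect_equal(full$reject$ts, 0)
  expect_balanced(full$balance)
  # design capture: 21,000 kg-TS/d -> 4678 kg-TS/d pressed
  pr <- screw_press(feed, 0.28, ts_capture = 4678 / 21000)
  expect_equal(pr$pressed$mass_flow * pr$pressed$ts, 4678, tolerance = 1e-9)
  expect_equal(pr$pressed$mass_flow, 4678 / 0.28, tolerance = 1e-9)
  expect_balanced(pr$balance)
  # TS conserved across the two outlets
  expect_equal(pr$pressed$mass_flow * pr$pressed$ts +
                 pr$reject$mass_flow * pr$reject$ts,
               feed$mass_flow * feed$ts, tolerance = 1e-9)
  expect_error(screw_press(feed, 0.28, 1.2), "ts_capture")
})

test_that("dilution to a target TS conserves solids", {
  pressed <- stream(16707, ts = 0.28, vs = 0.20)
  # no-op at the current TS
  expect_equal(dilute_to_ts(pressed, 0.28)$water_kg_day, 0)
  # 16,707 kg/d at 28% -> 6%: 77,967 kg/d total, 61,260 kg/d water
  dl <- dilute_to_ts(pressed, 0.06)
  expect_equal(dl$out$mass_flow, 16707 * 0.28 / 0.06, tolerance = 1e-9)
  expect_equal(dl$water_kg_day, dl$out$mass_flow - 16707, tolerance = 1e-9)
  expect_equal(dl$out$mass_flow * dl$out$ts, 16707 * 0.28,
               tolerance = 1e-9)
  expect_balanced(dl$balance)
  # temperature is the mass-weighted mix
  hot <- stream(1000, ts = 0.2, temperature = 60)
  mix <- dilute_to_ts(hot, 0.1, water_temperature = 15)
  expect_equal(mix$out$temperature, (1000 * 60 + 1000 * 15) / 2000)
  expect_error(dilute_to_ts(pressed, 0.5), "above")
})

test_that("pretreatment adds the dose and sets the hold temperature", {
  s <- stream(113688, ts = 0.041, vs = 0.031)
  expect_equal(pretreat_alkaline_thermal(s, 0)$out$mass_flow, 113688)
  pt <- pretreat_alkaline_thermal(s, 100, hold_temp = 60)
  expect_equal(pt$out$mass_flow, 113788)
  expect_equal(pt$out$temperature, 60)
  expect_balanced(pt$balance)
  expect_error(pretreat_alkaline_thermal(s, -5), "negative")
})

test_that("fermenter reproduces HRT, OLR and the VFA product flow", {
  feed <- stream(113788, ts = 4678 / 113788, vs = 0.031)
  spec <- reactor_spec(512, hrt_target = 4.5)
  conv <- conversion_spec(vfa_out_conc = 30.77, scod_out_conc = 34)
  fm <- acidogenic_fermenter(feed, spec, conv)
  expect_equal(round(fm$hrt, 1), 4.5)
  expect_equal(round(fm$olr, 2), 6.89)
  expect_equal(round(fm$vfa_product_kg_day), 3501)
  # zero gas: outlet mass equals inlet mass
  expect_equal(fm$out$mass_flow, feed$mass_flow)
  expect_balanced(fm$balance)
  # pass-through conversion leaves the stream unchanged
  passthrough <- acidogenic_fermenter(feed, spec, conversion_spec())
  expect_equal(passthrough$out$vfa, feed$vfa)
  # HRT/volume mismatch beyond 1% is rejected
  expect_error(
    acidogenic_fermenter(stream(200000, ts = 0.02, vs = 0.015), spec, conv),
    "HRT mismatch")
})

test_that("separator conserves mass and solids and hits the digester feed", {
  fout <- stream(113788, ts = 4678 / 113788, vs = 0.031, scod = 34,
                 vfa = 30.77, temperature = 37)
  sp <- separator(fout, solids_capture = 18180 * 0.18 / 4678,
                  cake_ts = 0.18, cake_vs_ts = 6.25 * 364 / (18180 * 0.18))
  expect_equal(sp$cake$mass_flow, 18180, tolerance = 1e-9)
  expect_equal(sp$cake$ts, 0.18)
  expect_balanced(sp$balance)
  expect_equal(sp$cake$mass_flow * sp$cake$ts +
                 sp$liquor$mass_flow * sp$liquor$ts,
               fout$mass_flow * fout$ts, tolerance = 1e-9)
  expect_error(separator(fout, 0.7, cake_ts = 0.02), "exceed")
  expect_error(separator(fout, 1.5, cake_ts = 0.2), "capture")
})

test_that("digester sizing matches both scenario design points", {
  # scenario 1: 364 m3 at 18,180 kg/d -> 20.0 d
  d1 <- anaerobic_digester(
    stream(18180, ts = 0.18, vs = 0.125, temperature = 37),
    reactor_spec(364, hrt_target = 20),
    conversion_spec(vs_destruction = 0.83, sgp = 0.56, ch4_frac = 0.35),
    biochar_dose = 0.12)
  expect_equal(round(d1$hrt, 1), 20.0)
  expect_balanced(d1$balance)
  # scenario 2: 2125 m3 at 85,012 kg/d -> 25.0 d
  d2 <- anaerobic_digester(
    stream(85012, ts = 0.055, vs = 0.0425, temperature = 37),
    reactor_spec(2125, hrt_target = 25),
    conversion_spec(vs_destruction = 0.80, sgp = 0.311 / 0.65,
                    ch4_frac = 0.65))
  expect_equal(round(d2$hrt, 1), 25.0)
  # biogas = SGP x VS fed; methane = biogas x CH4 fraction
  expect_equal(d2$biogas_nm3_day, 0.311 / 0.65 * 85012 * 0.0425,
               tolerance = 1e-9)
  expect_equal(d2$ch4_nm3_day / d2$biogas_nm3_day, 0.65, tolerance = 1e-12)
  # zero SGP: digestate equals the feed
  d0 <- anaerobic_digester(stream(18180, ts = 0.18, vs = 0.125,
                                  temperature = 37),
                           reactor_spec(364), conversion_spec())
  expect_equal(d0$digestate$mass_flow, 18180)
  expect_error(conversion_spec(vs_destruction = 1.2), "vs_destruction")
})

test_that("hrt and olr worked examples", {
  expect_equal(round(hrt(512, 113788), 1), 4.5)
  expect_equal(hrt(500, 500 * 1000), 1) # V over its own daily volume
  expect_equal(round(olr(113788, 0.031, 512), 2), 6.89)
  expect_equal(round(olr(85012, 0.0425, 2125), 2), 1.7)
  expect_error(hrt(0, 10), "> 0")
  expect_error(olr(10, 0.1, 0), "> 0")
})

test_that("scenario runs close every unit balance to 1e-6 relative", {
  for (sc in 1:2) {
    res <- run_scenario(scenario_config(sc))
    expect_true(all(res$balances$rel_err <= 1e-6))
    # global closure: inlet + water + additions = outlets + gas
    ins <- res$streams$inlet$mass_flow + res$water_kg_day +
      (if (sc == 1) res$config$pretreat$naoh_dose else 0) +
      res$config$digester$biochar_dose *
        res$streams$digester_feed$mass_flow *
        res$streams$digester_feed$vs
    outs <- res$streams$press_reject$mass_flow +
      res$streams$digestate$mass_flow +
      res$biogas_nm3_day * res$config$digester$gas_density +
      (if (sc == 1) res$streams$overflow$mass_flow else 0)
    expect_lt(abs(ins - outs) / ins, 1e-6)
  }
})

test_that("scenario 1 default run reproduces the printed stream table", {
  res <- run_scenario(scenario_config(1))
  expect_equal(res$streams$inlet$mass_flow * res$streams$inlet$ts, 21000)
  expect_equal(round(res$streams$fermenter_feed$mass_flow), 113788)
  expect_equal(round(res$streams$fermenter_feed$vs, 3), 0.031)
  expect_equal(round(res$streams$digester_feed$mass_flow), 18180)
  expect_equal(res$streams$digester_feed$ts, 0.18)
  expect_equal(round(res$vfa_product_kg_day), 3501)
  u <- res$units
  expect_equal(round(u$hrt[u$unit == "fermenter"], 1), 4.5)
  expect_equal(round(u$olr[u$unit == "fermenter"], 2), 6.89)
  expect_equal(round(u$hrt[u$unit == "digester"], 1), 20.0)
  expect_equal(round(u$olr[u$unit == "digester"], 2), 6.25)
})

test_that("scenario 2 default run reproduces the printed digester feed", {
  res <- run_scenario(scenario_config(2))
  expect_equal(round(res$streams$pressed$mass_flow *
                       res$streams$pressed$ts), 4678)
  expect_equal(res$streams$pressed$ts, 0.28)
  expect_equal(round(res$streams$digester_feed$mass_flow), 85012)
  u <- res$units
  expect_equal(round(u$hrt[u$unit == "digester"], 1), 25.0)
  expect_equal(round(u$olr[u$unit == "digester"], 2), 1.7)
})

test_that("streams scale linearly with population equivalents", {
  base <- run_scenario(scenario_config(1))
  double <- run_scenario(scenario_config(1, overrides = list(
    pe = 140000,
    pretreat = list(naoh_dose = 200),
    fermenter = list(volume = 1024, hrt_target = 4.5),
    digester = list(volume = 728, hrt_target = 20))))
  for (nm in names(base$streams)) {
    expect_equal(double$streams[[nm]]$mass_flow,
                 2 * base$streams[[nm]]$mass_flow, tolerance = 1e-9)
  }
  expect_equal(double$biogas_nm3_day, 2 * base$biogas_nm3_day,
               tolerance = 1e-9)
  # intensive quantities unchanged
  expect_equal(double$units$olr, base$units$olr, tolerance = 1e-9)
})

test_that("a zero-PE configuration yields all-zero streams without error", {
  res <- run_scenario(scenario_config(1, overrides = list(
    pe = 0, pretreat = list(naoh_dose = 0))))
  for (s in res$streams) expect_equal(s$mass_flow, 0)
  expect_equal(res$biogas_nm3_day, 0)
  expect_equal(res$vfa_product_kg_day, 0)
})
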