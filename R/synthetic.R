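#' Kinetic parameter set
#'
#' Container for the parameters of one cumulative-methane model, used both by
#' the synthetic generator and as a fit target.
#'
#' @param model `"first_order"` or `"gompertz"`.
#' @param b0 Ultimate specific methane yield, Nm3 CH4/kg-VS (`> 0`).
#' @param k First-order rate constant, 1/day (first-order only, `> 0`).
#' @param rm Maximum methane production rate, mL CH4/g-VS/day (Gompertz only).
#' @param lam Lag phase, days (Gompertz only, `>= 0`).
#' @return List of class `kinetic_params`.
#' @export
kinetic_params <- function(model = c("first_order", "gompertz"), b0,
                           k = NULL, rm = NULL, lam = NULL) {
  model <- match.arg(model)
  if (b0 <= 0) stop("'b0' must be > 0")
  if (model == "first_order") {
    if (is.null(k) || k <= 0) stop("first-order model needs k > 0")
    out <- list(model = model, b0 = b0, k = k)
  } else {
    if (is.null(rm) || rm <= 0) stop("gompertz model needs rm > 0")
    if (is.null(lam) || lam < 0) stop("gompertz model needs lam >= 0")
    out <- list(model = model, b0 = b0, rm = rm, lam = lam)
  }
  class(out) <- "kinetic_params"
  out
}

# Evaluate a kinetic_params curve at days t (Nm3/kg-VS).
eval_kinetics <- function(params, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$model == "first_order") {
    first_order_curve(t, params$b0, params$k)
  } else {
    gompertz_curve(t, params$b0, params$rm, params$lam)
  }
}

#' Bottle specification for a synthetic BMP condition
#'
#' @param condition Condition label (e.g. `"no_biochar"`, `"biochar_012"`).
#' @param n_replicates Number of replicate bottles (default 2, as in a
#'   duplicate-bottle BMP design).
#' @param vs_feedstock Feedstock VS per bottle, g (0 for a blank).
#' @param vs_inoculum Inoculum VS per bottle, g. The default pairs
#'   `vs_feedstock = 1` with an FS/IN VS ratio of 0.3.
#' @param noise_sd Gaussian noise SD added to cumulative volumes, mL.
#' @return List of class `bottle_spec`.
#' @export
bottle_spec <- function(condition, n_replicates = 2, vs_feedstock = 1,
                        vs_inoculum = vs_feedstock / 0.3, noise_sd = 0) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (vs_feedstock < 0) stop("'vs_feedstock' must be >= 0")
  if (noise_sd < 0) stop("negative 'noise_sd'")
  structure(list(condition = condition, n_replicates = n_replicates,
                 vs_feedstock = vs_feedstock, vs_inoculum = vs_inoculum,
                 noise_sd = noise_sd), class = "bottle_spec")
}

#' Measurement schedule of a BMP test
#'
#' Defaults mirror a 25-day test with daily volume readings and gas
#' chromatography on days 1, 4, 6, 10, 14, 16, 18, 21 and 25 only.
#'
#' @param gas_volume_days Days with cumulative volume readings.
#' @param composition_days Days with gas-composition measurements (must be a
#'   subset of `[0, horizon]`).
#' @param horizon Test duration, days.
#' @return List of class `measurement_schedule`.
#' @export
measurement_schedule <- function(gas_volume_days = 0:25,
                                 composition_days = c(1, 4, 6, 10, 14, 16,
                                                      18, 21, 25),
                                 horizon = 25) {
  if (length(gas_volume_days) == 0) stop("empty schedule")
  if (is.unsorted(gas_volume_days, strictly = TRUE) ||
      is.unsorted(composition_days, strictly = TRUE)) {
    stop("schedule days must be strictly increasing")
  }
  if (any(composition_days < 0) || any(composition_days > horizon)) {
    stop("composition days must lie within [0, horizon]")
  }
  structure(list(gas_volume_days = gas_volume_days,
                 composition_days = composition_days, horizon = horizon),
            class = "measurement_schedule")
}

# One bottle's noiseless cumulative CH4 curve (mL) = feedstock contribution
# plus endogenous inoculum contribution.
.bottle_ch4_ml <- function(t, params, spec, blank_params) {
  feed <- if (spec$vs_feedstock > 0) {
    eval_kinetics(params, t) * 1000 * spec$vs_feedstock # Nm3/kg == mL/g
  } else {
    rep(0, length(t))
  }
  endo <- if (!is.null(blank_params) && spec$vs_inoculum > 0) {
    eval_kinetics(blank_params, t) * 1000 * spec$vs_inoculum
  } else {
    rep(0, length(t))
  }
  feed + endo
}

#' Generate a synthetic BMP bottle dataset
#'
#' Simulates replicate BMP bottles for one feedstock condition plus
#' inoculum-only blanks. Each bottle's cumulative methane follows the chosen
#' kinetic curve scaled by its feedstock VS, plus an endogenous first-order
#' blank contribution scaled by its inoculum VS, plus Gaussian reading noise.
#' Noisy cumulative series are made non-decreasing with a running maximum
#' (cumulative readings cannot decrease) and clipped at zero. Biogas is
#' derived from methane through a methane content profile; the `ch4_frac`
#' column is populated only on composition (gas chromatography) days.
#'
#' @param params [kinetic_params()] of the feedstock condition.
#' @param spec [bottle_spec()] of the condition.
#' @param schedule [measurement_schedule()].
#' @param blank_params [kinetic_params()] of the endogenous inoculum
#'   production per g inoculum VS, or `NULL` for inert inoculum. The pilot
#'   data give no blank magnitude, so the default is a small, slow
#'   first-order curve.
#' @param n_blanks Number of blank bottles (default 2).
#' @param ch4_frac_fun Function of day returning the cumulative methane
#'   volume fraction of the condition's biogas (default: rises from 0.40
#'   towards 0.66).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A [bmp_dataset()].
#' @examples
#' ds <- gen_bmp_dataset(kinetic_params("first_order", b0 = 0.204, k = 0.57),
#'                       bottle_spec("no_biochar"), measurement_schedule(),
#'                       seed = 1)
#' head(ds)
#' @export
gen_bmp_dataset <- function(params, spec, schedule,
                            blank_params = kinetic_params("first_order",
                                                          b0 = 0.01,
                                                          k = 0.08),
                            n_blanks = 2,
                            ch4_frac_fun = function(d) {
                              0.66 - 0.26 * exp(-0.25 * d)
                            },
                            seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(spec, "bottle_spec"),
            inherits(schedule, "measurement_schedule"))
  set.seed(as.integer(seed))
  t <- schedule$gas_volume_days

  specs <- c(
    replicate(spec$n_replicates, spec, simplify = FALSE),
    replicate(n_blanks,
              bottle_spec("blank", 1, vs_feedstock = 0,
                          vs_inoculum = spec$vs_inoculum,
                          noise_sd = spec$noise_sd),
              simplify = FALSE)
  )
  rows <- vector("list", length(specs))
  bottles <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    id <- sprintf("%s_%d", sp$condition, sum(vapply(
      specs[seq_len(i)], function(x) x$condition == sp$condition, logical(1)
    )))
    ch4 <- .bottle_ch4_ml(t, params, sp, blank_params)
    # biogas accumulated increment-wise: each methane increment is divided
    # by the instantaneous methane fraction, so the cumulative biogas is
    # non-decreasing even while the methane content drifts
    frac <- pmin(pmax(ch4_frac_fun(t), 1e-6), 1)
    biogas <- cumsum(diff(c(0, ch4)) / frac)
    if (sp$noise_sd > 0) {
      ch4 <- cummax(pmax(ch4 + stats::rnorm(length(t), 0, sp$noise_sd), 0))
      biogas <- cummax(pmax(biogas + stats::rnorm(length(t), 0,
                                                  sp$noise_sd), 0))
      biogas <- pmax(biogas, ch4) # methane cannot exceed total biogas
    }
    obs_frac <- ifelse(t %in% schedule$composition_days & biogas > 0,
                       ch4 / biogas, NA_real_)
    rows[[i]] <- data.frame(day = t, bottle_id = id,
                            condition = sp$condition,
                            cum_biogas_ml = biogas, cum_ch4_ml = ch4,
                            ch4_frac = pmin(obs_frac, 1))
    bottles[[i]] <- data.frame(bottle_id = id, condition = sp$condition,
                               vs_feedstock = sp$vs_feedstock,
                               vs_inoculum = sp$vs_inoculum,
                               is_blank = sp$vs_feedstock == 0)
  }
  bmp_dataset(do.call(rbind, rows), do.call(rbind, bottles))
}

#' Generate a synthetic fermenter monitoring series
#'
#' Simulates daily effluent measurements of a mesophilic acidogenic
#' fermenter at pseudo-steady state: VFA drawn from a normal distribution
#' truncated at zero, SCOD tied to VFA through the VFA/SCOD ratio, and pH,
#' ammonium and phosphate as independent truncated-normal draws. Defaults
#' reflect the pilot fermenter at an HRT of 4.5 days (VFA 30.77, SD 2.82
#' g-SCOD/L).
#'
#' @param mean_vfa Mean VFA concentration, g-SCOD/L (`> 0`).
#' @param sd_vfa SD of daily VFA, g-SCOD/L (`>= 0`).
#' @param n_days Number of monitored days (`> 0`).
#' @param vfa_scod_ratio VFA/SCOD mass ratio in `(0, 1]` (default 0.892).
#' @param ph_mean,ph_sd Effluent pH distribution (defaults 6.56, 0.25).
#' @param nh4_mean,nh4_sd Ammonium, mg N-NH4+/L.
#' @param po4_mean,po4_sd Phosphate, mg P-PO43-/L.
#' @param seed Integer seed.
#' @return data.frame of class `fermenter_series` with columns `day`,
#'   `vfa_gscod_l`, `scod_g_l`, `ph`, `nh4_mg_l`, `po4_mg_l`.
#' @examples
#' gen_fermenter_series(30.77, 2.82, n_days = 9, seed = 1)
#' @export
gen_fermenter_series <- function(mean_vfa = 30.77, sd_vfa = 2.82, n_days = 9,
                                 vfa_scod_ratio = 0.892,
                                 ph_mean = 6.56, ph_sd = 0.25,
                                 nh4_mean = 528, nh4_sd = 60,
                                 po4_mean = 39, po4_sd = 16,
                                 seed = 1L) {
  if (mean_vfa <= 0) stop("'mean_vfa' must be > 0")
  if (sd_vfa < 0) stop("'sd_vfa' must be >= 0")
  if (n_days <= 0) stop("'n_days' must be positive")
  if (vfa_scod_ratio <= 0 || vfa_scod_ratio > 1) {
    stop("'vfa_scod_ratio' must be in (0, 1]")
  }
  set.seed(as.integer(seed))
  vfa <- pmax(stats::rnorm(n_days, mean_vfa, sd_vfa), 0)
  out <- data.frame(
    day = seq_len(n_days),
    vfa_gscod_l = vfa,
    scod_g_l = vfa / vfa_scod_ratio,
    ph = pmax(stats::rnorm(n_days, ph_mean, ph_sd), 0),
    nh4_mg_l = pmax(stats::rnorm(n_days, nh4_mean, nh4_sd), 0),
    po4_mg_l = pmax(stats::rnorm(n_days, po4_mean, po4_sd), 0)
  )
  class(out) <- c("fermenter_series", "data.frame")
  out
}
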