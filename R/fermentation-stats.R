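#' Feedstock characterization
#'
#' Physical-chemical characterization of the pretreated feedstock entering
#' acidogenic fermentation. Defaults are the measured means of the pilot
#' feedstock: TS 45 g/kg, VS 32 g/kg, TKN 12.9 g-N/kg-TS, P 4 g-P/kg-TS,
#' COD 565 g-COD/kg-TS, SCOD 25,814 mg/L, VFA 3500 mg-SCOD/L, ammonium
#' 325 mg/L, phosphate 14 mg/L.
#'
#' A density convention of 1 kg ~ 1 L links the per-kg solid measures with
#' per-litre concentrations (dilute aqueous stream).
#'
#' @param ts,vs Total / volatile solids, g/kg (`vs <= ts`).
#' @param scod_in Soluble COD, mg/L.
#' @param vfa_in VFA (as SCOD), mg/L.
#' @param tkn Total Kjeldahl nitrogen, g-N/kg-TS.
#' @param p Total phosphorus, g-P/kg-TS.
#' @param cod_ts Solid-phase COD, g-COD/kg-TS.
#' @param nh4_in Ammonium, mg N-NH4+/L.
#' @param po4_in Phosphate, mg P-PO43-/L.
#' @return List of class `feedstock`.
#' @export
feedstock_characterization <- function(ts = 45, vs = 32, scod_in = 25814,
                                       vfa_in = 3500, tkn = 12.9, p = 4,
                                       cod_ts = 565, nh4_in = 325,
                                       po4_in = 14) {
  vals <- c(ts, vs, scod_in, vfa_in, tkn, p, cod_ts, nh4_in, po4_in)
  if (any(vals < 0)) stop("feedstock values must be non-negative")
  if (vs > ts) stop("VS cannot exceed TS")
  structure(list(ts = ts, vs = vs, scod_in = scod_in, vfa_in = vfa_in,
                 tkn = tkn, p = p, cod_ts = cod_ts, nh4_in = nh4_in,
                 po4_in = po4_in), class = "feedstock")
}

.check_series <- function(series) {
  need <- c("day", "vfa_gscod_l", "scod_g_l")
  if (!all(need %in% names(series))) {
    stop("series must have columns: ", paste(need, collapse = ", "))
  }
  if (any(series$vfa_gscod_l > series$scod_g_l + 1e-9, na.rm = TRUE)) {
    stop("VFA (as SCOD) cannot exceed SCOD")
  }
  invisible(series)
}

#' COD solubilization of acidogenic fermentation
#'
#' Daily solubilization `(SCOD_out - SCOD_in) / VS0` in
#' delta-g-SCOD per g of feedstock VS, with SCOD in g/L and VS0 converted
#' from g/kg to g/L by the 1 kg ~ 1 L convention. Negative daily values
#' (effluent SCOD below the feed) are kept with a message, since the sign
#' carries information.
#'
#' @param series Fermenter series (see [gen_fermenter_series()]).
#' @param feed A [feedstock_characterization()].
#' @return List with `per_day`, `mean`, `sd`.
#' @export
cod_solubilization <- function(series, feed) {
  .check_series(series)
  if (feed$vs <= 0) stop("feed VS must be > 0")
  per_day <- (series$scod_g_l - feed$scod_in / 1000) / feed$vs
  if (any(per_day < 0)) {
    message("cod_solubilization: ", sum(per_day < 0),
            " day(s) with negative solubilization")
  }
  list(per_day = per_day, mean = mean(per_day), sd = stats::sd(per_day))
}

#' Default COD-to-mass conversion factors of the VFAs
#'
#' Theoretical oxygen demand per gram of acid (g-COD/g-acid), used to move a
#' VFA yield between the COD-equivalent basis the analytics report and an
#' acid-mass basis.
#'
#' @return Named numeric vector.
#' @export
vfa_cod_factors <- function() {
  c(acetic = 1.066, propionic = 1.512, isobutyric = 1.816, butyric = 1.816,
    isovaleric = 2.037, valeric = 2.037, caproic = 2.204)
}

#' VFA yield of acidogenic fermentation
#'
#' Daily yield `(VFA_out - VFA_in) / VS0` in delta-g-VFA per g of feedstock
#' VS. On the `"cod"` basis VFA stays in its measured COD-equivalent; on the
#' `"mass"` basis it is divided by the spectrum-weighted COD-to-mass factor
#' (g-COD/g-acid), which requires a [vfa_spectrum()].
#'
#' @param series Fermenter series.
#' @param feed A [feedstock_characterization()].
#' @param basis `"cod"` (default) or `"mass"`.
#' @param spectrum A [vfa_spectrum()] (mass basis only).
#' @param cod_to_mass Named per-acid factors, g-COD/g (default
#'   [vfa_cod_factors()]).
#' @return List with `per_day`, `mean`, `sd`, `basis` and, on the mass
#'   basis, the `cod_mass_factor` used.
#' @export
vfa_yield <- function(series, feed, basis = c("cod", "mass"),
                      spectrum = NULL, cod_to_mass = vfa_cod_factors()) {
  basis <- match.arg(basis)
  .check_series(series)
  if (feed$vs <= 0) stop("feed VS must be > 0")
  per_day <- (series$vfa_gscod_l - feed$vfa_in / 1000) / feed$vs
  factor <- 1
  if (basis == "mass") {
    if (is.null(spectrum)) stop("mass basis requires a VFA spectrum")
    acids <- names(spectrum)
    if (!all(acids %in% names(cod_to_mass))) {
      stop("missing COD factor for: ",
           paste(setdiff(acids, names(cod_to_mass)), collapse = ", "))
    }
    factor <- sum(unlist(spectrum) * cod_to_mass[acids])
    per_day <- per_day / factor
  }
  out <- list(per_day = per_day, mean = mean(per_day),
              sd = stats::sd(per_day), basis = basis)
  if (basis == "mass") out$cod_mass_factor <- factor
  out
}

#' Ammonia and phosphate release
#'
#' Percentage of the feed's nitrogen and phosphorus pools released to the
#' liquid phase: `100 * (NH4_out - NH4_in) / TKN_L` where the denominator is
#' the feed TKN expressed per litre (g-N/kg-TS x g-TS/kg = mg-N/L under the
#' 1 kg ~ 1 L convention); phosphate analogous with total P.
#'
#' @param series Fermenter series with columns `nh4_mg_l` and `po4_mg_l`.
#' @param feed A [feedstock_characterization()] with `tkn`, `p` `> 0`.
#' @return List with `ammonia` and `phosphate`, each holding `per_day`,
#'   `mean`, `sd` (percent).
#' @export
nutrient_release <- function(series, feed) {
  if (feed$tkn <= 0 || feed$p <= 0) stop("feed TKN and P must be > 0")
  if (!all(c("nh4_mg_l", "po4_mg_l") %in% names(series))) {
    stop("series must have nh4_mg_l and po4_mg_l columns")
  }
  tkn_l <- feed$tkn * feed$ts # mg-N/L
  p_l <- feed$p * feed$ts # mg-P/L
  amm <- 100 * (series$nh4_mg_l - feed$nh4_in) / tkn_l
  pho <- 100 * (series$po4_mg_l - feed$po4_in) / p_l
  if (any(amm > 100) || any(pho > 100)) {
    stop("release above 100% violates the nutrient balance")
  }
  list(
    ammonia = list(per_day = amm, mean = mean(amm), sd = stats::sd(amm)),
    phosphate = list(per_day = pho, mean = mean(pho), sd = stats::sd(pho))
  )
}

#' Daily VFA/SCOD ratio
#'
#' @param series Fermenter series with `scod_g_l > 0` on every day.
#' @return List with `per_day`, `mean`, `sd` (kg/kg).
#' @export
vfa_scod_ratio <- function(series) {
  .check_series(series)
  if (any(series$scod_g_l <= 0)) stop("SCOD must be > 0 on every day")
  r <- series$vfa_gscod_l / series$scod_g_l
  list(per_day = r, mean = mean(r), sd = stats::sd(r))
}

#' VFA weight-ratio spectrum
#'
#' Normalizes per-acid concentrations (any common weight unit) to weight
#' fractions of the total VFA pool.
#'
#' @param conc Named non-negative vector of per-acid concentrations; names
#'   must be among acetic, propionic, isobutyric, butyric, isovaleric,
#'   valeric, caproic.
#' @return Named vector of fractions summing to 1, class `vfa_spectrum`.
#' @examples
#' vfa_spectrum(c(acetic = 40, butyric = 24, caproic = 17, propionic = 10,
#'                valeric = 5, isovaleric = 4))
#' @export
vfa_spectrum <- function(conc) {
  acids <- names(vfa_cod_factors())
  if (is.null(names(conc)) || !all(names(conc) %in% acids)) {
    stop("concentrations must be named with acids among: ",
         paste(acids, collapse = ", "))
  }
  if (any(conc < 0)) stop("concentrations must be non-negative")
  tot <- sum(conc)
  if (tot <= 0) stop("all-zero VFA concentrations")
  structure(conc / tot, class = "vfa_spectrum")
}

#' Paired two-tailed t test
#'
#' Student's paired t test computed from the explicit formula
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` (the usual convention
#' of pairing by index, difference first-minus-second), `df = n - 1` and a
#' two-tailed p-value from the Student-t distribution. Implemented directly
#' so it can be cross-checked against an independent oracle.
#'
#' @param x,y Paired numeric vectors of equal length `n >= 2` (paired by
#'   day index).
#' @param ci_level Confidence level for the mean difference (default 0.95).
#' @return List of class `ttest_result`: `t_stat`, `df`, `p_value`,
#'   `ci_level`, `conf_int`, `mean_diff`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 3, 5)) # t = -4, df = 2
#' @export
paired_t_test <- function(x, y, ci_level = 0.95) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 2) stop("at least 2 pairs are required")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance of paired differences")
  se <- sd_d / sqrt(n)
  t_stat <- mean(d) / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(t_stat), df)
  q <- stats::qt(1 - (1 - ci_level) / 2, df)
  out <- list(t_stat = t_stat, df = df, p_value = p, ci_level = ci_level,
              conf_int = mean(d) + c(-1, 1) * q * se, mean_diff = mean(d))
  class(out) <- "ttest_result"
  out
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.3f, p = %.4g (CI %.0f%%: %.3f, %.3f)\n",
              x$df, x$t_stat, x$p_value, 100 * x$ci_level,
              x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Process stability summary
#'
#' Stability of a steady-state monitoring window judged by the coefficient of
#' variation of daily values: the process is called stable when the SD is
#' below `threshold` (default 10%) of the mean.
#'
#' @param values Numeric vector of daily values over the steady-state window.
#' @param threshold Relative-SD stability threshold (default 0.10).
#' @return List with `mean`, `sd`, `sd_over_mean`, `stable`.
#' @export
stability_summary <- function(values, threshold = 0.10) {
  if (length(values) == 0) stop("empty steady-state window")
  m <- mean(values)
  s <- if (length(values) > 1) stats::sd(values) else 0
  list(mean = m, sd = s, sd_over_mean = s / m,
       stable = (s / m) < threshold)
}

#' Steady-state window of a fermenter series
#'
#' Pseudo-steady state is assumed reached after about three hydraulic
#' retention times; the window keeps days `>= factor * hrt`.
#'
#' @param series Fermenter series.
#' @param hrt Hydraulic retention time, days.
#' @param factor Multiple of the HRT marking steady state (default 3).
#' @return The subset of `series` in the steady-state window.
#' @export
steady_state_window <- function(series, hrt, factor = 3) {
  out <- series[series$day >= factor * hrt, , drop = FALSE]
  if (nrow(out) == 0) stop("empty steady-state window")
  out
}
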