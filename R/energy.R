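#' Energy-balance boundary conditions
#'
#' Reference parameters for the energy flow analysis: biogas lower heating
#' value, CHP electrical and thermal yields, boundary temperatures and the
#' specific heat of the (water-like) process streams.
#'
#' The tabulated LHV of 23.012 MJ/Nm3 corresponds to a reference biogas
#' methane content (`ref_ch4_frac`, default 0.65); scenario gas with a
#' different methane fraction has its LHV scaled proportionally to the
#' methane content, since the methane carries the heating value.
#'
#' @param lhv_biogas Biogas lower heating value, MJ/Nm3 (default 23.012).
#' @param ref_ch4_frac Methane fraction the LHV refers to (default 0.65).
#' @param eta_el Electrical energy yield of the CHP (default 0.4).
#' @param eta_th Thermal energy yield of the CHP (default 0.5).
#' @param t_operative Reactor operating temperature, degC (default 37).
#' @param t_water Process water temperature, degC (default 15).
#' @param t_air Air temperature, degC (default 20).
#' @param t_ground Ground temperature, degC (default 25).
#' @param u_wall_outer,u_wall_inner,u_floor Heat transfer coefficients,
#'   W/(m2 degC): outer concrete wall 0.7, inner (buried) wall 1.2,
#'   floor 2.85.
#' @param cp_water Specific heat, kJ/(kg degC) (default 4.186).
#' @return List of class `energy_params`.
#' @export
energy_params <- function(lhv_biogas = 23.012, ref_ch4_frac = 0.65,
                          eta_el = 0.4, eta_th = 0.5, t_operative = 37,
                          t_water = 15, t_air = 20, t_ground = 25,
                          u_wall_outer = 0.7, u_wall_inner = 1.2,
                          u_floor = 2.85, cp_water = 4.186) {
  if (lhv_biogas <= 0) stop("'lhv_biogas' must be > 0")
  if (eta_el <= 0 || eta_el >= 1 || eta_th <= 0 || eta_th >= 1) {
    stop("CHP yields must be in (0, 1)")
  }
  structure(list(lhv_biogas = lhv_biogas, ref_ch4_frac = ref_ch4_frac,
                 eta_el = eta_el, eta_th = eta_th,
                 t_operative = t_operative, t_water = t_water,
                 t_air = t_air, t_ground = t_ground,
                 u_wall_outer = u_wall_outer, u_wall_inner = u_wall_inner,
                 u_floor = u_floor, cp_water = cp_water),
            class = "energy_params")
}

#' Sensible heating duty of a stream
#'
#' `Q = m cp (t_out - t_in) / 1000` in MJ/day. Negative temperature lifts
#' (stream already warmer than the target) clamp to zero with a message: the
#' plant does not book cooling credits.
#'
#' @param mass_flow Stream mass flow, kg/day.
#' @param t_in,t_out Inlet / target temperature, degC.
#' @param cp Specific heat, kJ/(kg degC) (default 4.186).
#' @return Heating duty, MJ/day.
#' @examples
#' stream_heating(113788, 15, 37) # about 10,478 MJ/d
#' @export
stream_heating <- function(mass_flow, t_in, t_out, cp = 4.186) {
  if (cp <= 0) stop("'cp' must be > 0")
  if (t_out <= t_in) {
    if (t_out < t_in) message("stream_heating: negative lift clamped to 0")
    return(0)
  }
  mass_flow * cp * (t_out - t_in) / 1000
}

#' Reactor wall heat loss
#'
#' Transmission losses `Q = sum(U A dT) * 86400 / 1e6` in MJ/day over the
#' reactor surfaces: above-grade wall and roof exchange with the air through
#' the outer-wall coefficient, the buried wall through the inner-wall
#' coefficient with the ground, and the floor through the floor coefficient
#' with the ground.
#'
#' @param spec A [reactor_spec()] (supplies areas and the operating
#'   temperature).
#' @param params An [energy_params()].
#' @return Heat loss, MJ/day.
#' @export
wall_loss <- function(spec, params = energy_params()) {
  stopifnot(inherits(spec, "reactor_spec"), inherits(params, "energy_params"))
  t_op <- spec$temperature
  dt_air <- t_op - params$t_air
  dt_ground <- t_op - params$t_ground
  w <- params$u_wall_outer * (spec$a_wall_above + spec$a_roof) * dt_air +
    params$u_wall_inner * spec$a_wall_buried * dt_ground +
    params$u_floor * spec$a_floor * dt_ground
  w * 86400 / 1e6
}

#' Combined heat and power conversion
#'
#' Converts a biogas flow into electricity and recoverable heat:
#' `E = V * LHV`, electricity `= eta_el * E`, heat `= eta_th * E`.
#'
#' @param biogas_nm3_day Biogas flow, Nm3/day (`>= 0`).
#' @param params An [energy_params()].
#' @param lhv Optional LHV override, MJ/Nm3 (e.g. scaled for the scenario's
#'   methane content); defaults to `params$lhv_biogas`.
#' @return List with `energy`, `electricity`, `heat` (MJ/day).
#' @examples
#' chp(1000) # 23,012 MJ/d fuel, 9205 MJ/d electricity
#' @export
chp <- function(biogas_nm3_day, params = energy_params(), lhv = NULL) {
  if (biogas_nm3_day < 0) stop("negative biogas volume")
  if (is.null(lhv)) lhv <- params$lhv_biogas
  e <- biogas_nm3_day * lhv
  list(energy = e, electricity = params$eta_el * e, heat = params$eta_th * e)
}

#' Energy balance of a scenario
#'
#' Sums the stream-heating duties recorded by [run_scenario()], the wall
#' losses of every reactor, and the CHP output of the produced biogas (LHV
#' scaled to the scenario's methane content), and reports the surplus
#' `thermal_recovered + electricity - heating_demand - wall_loss` (negative
#' when the plant is a net energy consumer).
#'
#' @param result A [run_scenario()] result.
#' @param params An [energy_params()].
#' @return List of class `energy_balance`: `heating_demand`, `wall_loss`,
#'   `thermal_recovered`, `electricity`, `surplus` (MJ/day) and the
#'   `lhv_used` (MJ/Nm3).
#' @export
scenario_energy <- function(result, params = energy_params()) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(params, "energy_params"))
  heating <- sum(vapply(result$heating_events, function(ev) {
    stream_heating(ev$mass, ev$t_in, ev$t_out, params$cp_water)
  }, numeric(1)))
  walls <- sum(vapply(result$reactors, wall_loss, numeric(1),
                      params = params))
  ch4_frac <- if (result$biogas_nm3_day > 0) {
    result$ch4_nm3_day / result$biogas_nm3_day
  } else {
    params$ref_ch4_frac
  }
  lhv <- params$lhv_biogas * ch4_frac / params$ref_ch4_frac
  conv <- chp(result$biogas_nm3_day, params, lhv = lhv)
  out <- list(heating_demand = heating, wall_loss = walls,
              thermal_recovered = conv$heat, electricity = conv$electricity,
              surplus = conv$heat + conv$electricity - heating - walls,
              lhv_used = lhv)
  class(out) <- "energy_balance"
  out
}

#' @export
print.energy_balance <- function(x, ...) {
  cat(sprintf(paste0("Energy balance (MJ/day): heating %.0f, wall loss",
                     " %.0f,\n  thermal %.0f, electricity %.0f,",
                     " surplus %.0f (LHV %.2f MJ/Nm3)\n"),
              x$heating_demand, x$wall_loss, x$thermal_recovered,
              x$electricity, x$surplus, x$lhv_used))
  invisible(x)
}
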