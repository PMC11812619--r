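#' Economic boundary conditions of a scenario
#'
#' Prices and cost conventions of the undiscounted payback analysis. Income
#' sources are the VFA product mass and the net electricity (electricity
#' remaining after the in-plant heat shortfall is covered); costs are a
#' fixed operating fraction of the capital cost, process water and disposal
#' of the residual dry solids.
#'
#' Capital cost defaults: 809,000 EUR for the multistep line (scenario 1)
#' and twice that for the single-step digestion (scenario 2), whose capital
#' cost is roughly double the line's. The VFA price has no measured
#' reference; the default 0.5 EUR/kg is a mid-range platform-chemical value
#' and [calibrate_vfa_price()] back-solves the price matching a target net
#' income.
#'
#' @param scenario 1 or 2 (selects the default capital cost).
#' @param capex Capital cost, EUR.
#' @param vfa_price VFA product price, EUR/kg-SCOD (default 0.5).
#' @param electricity_price EUR/MWh (default 130).
#' @param opex_frac Yearly operating cost as a fraction of capex
#'   (default 0.05).
#' @param water_price Process water price, EUR/m3 (default 1).
#' @param disposal_price Residual-solids disposal price, EUR/ton of dry
#'   solids (default 100, within the 75-125 EUR/ton range of Italian
#'   disposal costs).
#' @param net_electricity Use surplus (after in-plant demand) electricity
#'   for income (default `TRUE`); `FALSE` books the gross CHP electricity.
#' @return List of class `econ_params`.
#' @export
econ_params <- function(scenario = 1,
                        capex = if (scenario == 1) 809000 else 1618000,
                        vfa_price = 0.5, electricity_price = 130,
                        opex_frac = 0.05, water_price = 1,
                        disposal_price = 100, net_electricity = TRUE) {
  if (capex <= 0) stop("'capex' must be > 0")
  structure(list(capex = capex, vfa_price = vfa_price,
                 electricity_price = electricity_price,
                 opex_frac = opex_frac, water_price = water_price,
                 disposal_price = disposal_price,
                 net_electricity = net_electricity), class = "econ_params")
}

#' Payback economics of a product slate
#'
#' Undiscounted economics: yearly income
#' `365 * (vfa * vfa_price + max(electricity, 0) / 3600 * electricity_price)`
#' (MJ/day to MWh/day via 3600), yearly cost
#' `opex_frac * capex + 365 * (water * water_price + disposal *
#' disposal_price)`, and payback `capex / (income - cost)`. A non-positive
#' net income gives an infinite payback, flagged.
#'
#' @param capex Capital cost, EUR.
#' @param vfa_kg_day VFA product, kg/day.
#' @param electricity_mj_day Sellable electricity, MJ/day.
#' @param water_m3_day Process water, m3/day.
#' @param disposal_t_day Residual dry solids to dispose, t/day.
#' @param params An [econ_params()].
#' @return List of class `econ_summary`: `capex`, `annual_income`,
#'   `annual_cost`, `net_income` (EUR/yr), `payback` (years, `Inf` when net
#'   income is non-positive) and `profitable`.
#' @examples
#' economics(809000, vfa_kg_day = 3501, electricity_mj_day = 2850,
#'           water_m3_day = 97, disposal_t_day = 1.7)
#' @export
economics <- function(capex, vfa_kg_day, electricity_mj_day,
                      water_m3_day = 0, disposal_t_day = 0,
                      params = econ_params(capex = capex)) {
  stopifnot(inherits(params, "econ_params"))
  income <- 365 * (vfa_kg_day * params$vfa_price +
                     max(electricity_mj_day, 0) / 3600 *
                       params$electricity_price)
  cost <- params$opex_frac * capex +
    365 * (water_m3_day * params$water_price +
             disposal_t_day * params$disposal_price)
  net <- income - cost
  out <- list(capex = capex, annual_income = income, annual_cost = cost,
              net_income = net,
              payback = if (net > 0) capex / net else Inf,
              profitable = net > 0)
  class(out) <- "econ_summary"
  out
}

#' @export
print.econ_summary <- function(x, ...) {
  cat(sprintf(paste0("Economics: capex EUR %.0f, income EUR %.0f/yr,",
                     " cost EUR %.0f/yr,\n  net EUR %.0f/yr, payback %s\n"),
              x$capex, x$annual_income, x$annual_cost, x$net_income,
              if (is.finite(x$payback)) {
                sprintf("%.2f yr", x$payback)
              } else {
                "never (net income <= 0)"
              }))
  invisible(x)
}

# Sellable electricity of a scenario, MJ/day: either the gross CHP output
# or the output net of the in-plant heat shortfall (heat demand first met
# by recovered heat, the remainder by electricity).
.sellable_electricity <- function(energy, net = TRUE) {
  if (!net) return(energy$electricity)
  demand <- energy$heating_demand + energy$wall_loss
  shortfall <- max(demand - energy$thermal_recovered, 0)
  max(energy$electricity - shortfall, 0)
}

#' Economics of a scenario run
#'
#' Combines a mass-balance result and its energy balance into the payback
#' economics: the VFA product and the (net) electricity are the income, the
#' process water and residual dry solids the variable costs.
#'
#' @param result A [run_scenario()] result.
#' @param energy A [scenario_energy()] balance for the same run.
#' @param params An [econ_params()].
#' @return An `econ_summary` (see [economics()]).
#' @export
scenario_economics <- function(result, energy,
                               params = econ_params(result$scenario)) {
  stopifnot(inherits(result, "scenario_result"),
            inherits(energy, "energy_balance"))
  economics(params$capex,
            vfa_kg_day = result$vfa_product_kg_day,
            electricity_mj_day = .sellable_electricity(
              energy, params$net_electricity),
            water_m3_day = result$water_kg_day / 1000,
            disposal_t_day = result$residual_solids_kg_day / 1000,
            params = params)
}

#' Back-solve the VFA price matching a target net income
#'
#' The VFA market price is the least constrained economic input. This
#' utility inverts the linear income equation of [scenario_economics()] to
#' find the price at which the scenario's yearly net income equals a target,
#' for documentation of what the price would have to be; it is a
#' calibration aid, not a market value.
#'
#' @param result A scenario-1 style [run_scenario()] result with a VFA
#'   product.
#' @param energy Matching [scenario_energy()] balance.
#' @param target_net_income Target net income, EUR/yr.
#' @param params An [econ_params()].
#' @return Price, EUR/kg-SCOD.
#' @export
calibrate_vfa_price <- function(result, energy, target_net_income,
                                params = econ_params(result$scenario)) {
  if (result$vfa_product_kg_day <= 0) stop("scenario has no VFA product")
  elec <- .sellable_electricity(energy, params$net_electricity)
  cost <- params$opex_frac * params$capex +
    365 * (result$water_kg_day / 1000 * params$water_price +
             result$residual_solids_kg_day / 1000 * params$disposal_price)
  elec_income <- 365 * max(elec, 0) / 3600 * params$electricity_price
  (target_net_income + cost - elec_income) /
    (365 * result$vfa_product_kg_day)
}
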