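#' Process stream
#'
#' A steady-state mass flow with its composition, passed between unit
#' operations of the flowsheet. Aqueous streams are taken at a density of
#' 1000 kg/m3 (1 kg ~ 1 L), which links the kg/day mass flows to the
#' volumetric quantities (HRT, concentrations).
#'
#' @param mass_flow Mass flow, kg/day (`>= 0`).
#' @param ts Total solids fraction, kg-TS/kg in `[0, 1]`.
#' @param vs Volatile solids fraction, kg-VS/kg (`vs <= ts`).
#' @param scod Soluble COD concentration, g/L (default 0).
#' @param vfa VFA concentration, g-SCOD/L (`vfa <= scod`).
#' @param temperature Stream temperature, degC.
#' @return List of class `stream`.
#' @examples
#' stream(113788, ts = 0.0411, vs = 0.031, temperature = 37)
#' @export
stream <- function(mass_flow, ts = 0, vs = 0, scod = 0, vfa = 0,
                   temperature = 15) {
  if (mass_flow < 0) stop("'mass_flow' must be >= 0")
  if (ts < 0 || ts > 1) stop("'ts' must be in [0, 1]")
  if (vs < 0 || vs > ts + 1e-12) stop("'vs' must satisfy 0 <= vs <= ts")
  if (vfa > scod + 1e-9) stop("'vfa' cannot exceed 'scod'")
  structure(list(mass_flow = mass_flow, ts = ts, vs = vs, scod = scod,
                 vfa = vfa, temperature = temperature), class = "stream")
}

#' @export
print.stream <- function(x, ...) {
  cat(sprintf(paste0("Stream: %.0f kg/d, TS %.2f%%, VS %.2f%%, SCOD %.1f",
                     " g/L, VFA %.1f g/L, %.1f degC\n"),
              x$mass_flow, 100 * x$ts, 100 * x$vs, x$scod, x$vfa,
              x$temperature))
  invisible(x)
}

# Solid (TS) mass flow of a stream, kg/day.
ts_flow <- function(s) s$mass_flow * s$ts
vs_flow <- function(s) s$mass_flow * s$vs

#' Screw press
#'
#' Splits a feed into a pressed (dewatered) stream at a set dry-matter
#' content and a reject stream, conserving total mass and solids. The
#' fraction of the feed TS leaving in the pressed stream is a model
#' parameter (`ts_capture`); the VS/TS ratio of the feed is preserved in
#' both outputs.
#'
#' @param input A [stream()].
#' @param dry_matter_out TS fraction of the pressed stream, `(0, 1]`.
#' @param ts_capture Fraction of feed TS captured in the pressed stream.
#' @return List with `pressed`, `reject` (streams) and `balance`.
#' @export
screw_press <- function(input, dry_matter_out, ts_capture) {
  stopifnot(inherits(input, "stream"))
  if (dry_matter_out <= 0 || dry_matter_out > 1) {
    stop("'dry_matter_out' must be in (0, 1]")
  }
  if (ts_capture < 0 || ts_capture > 1) stop("'ts_capture' must be in [0, 1]")
  vs_ts <- if (input$ts > 0) input$vs / input$ts else 0
  ts_p <- ts_flow(input) * ts_capture
  m_p <- ts_p / dry_matter_out
  if (m_p > input$mass_flow) stop("pressed flow exceeds feed flow")
  m_r <- input$mass_flow - m_p
  ts_r <- ts_flow(input) - ts_p
  pressed <- stream(m_p, ts = dry_matter_out, vs = dry_matter_out * vs_ts,
                    scod = input$scod, vfa = input$vfa,
                    temperature = input$temperature)
  reject <- stream(m_r, ts = if (m_r > 0) ts_r / m_r else 0,
                   vs = if (m_r > 0) ts_r / m_r * vs_ts else 0,
                   scod = input$scod, vfa = input$vfa,
                   temperature = input$temperature)
  list(pressed = pressed, reject = reject,
       balance = c(inflow = input$mass_flow,
                   outflow = pressed$mass_flow + reject$mass_flow))
}

#' Dilute a stream with water to a target TS
#'
#' Adds water so that the solids fraction drops to `target_ts`; the TS mass
#' is conserved, soluble concentrations are diluted by the volume ratio, and
#' the outlet temperature is the mass-weighted mix of stream and water.
#'
#' @param s A [stream()].
#' @param target_ts Target TS fraction (`<= s$ts`).
#' @param water_temperature Dilution water temperature, degC (default 15).
#' @return List with `out` (stream), `water_kg_day` and `balance`.
#' @export
dilute_to_ts <- function(s, target_ts, water_temperature = 15) {
  stopifnot(inherits(s, "stream"))
  if (target_ts > s$ts + 1e-12) stop("target TS above the current TS")
  if (target_ts <= 0) stop("'target_ts' must be > 0")
  if (s$mass_flow == 0) {
    return(list(out = s, water_kg_day = 0,
                balance = c(inflow = 0, outflow = 0)))
  }
  water <- s$mass_flow * (s$ts / target_ts - 1)
  m_out <- s$mass_flow + water
  dil <- s$mass_flow / m_out # volume ratio under 1 kg ~ 1 L
  out <- stream(m_out, ts = target_ts,
                vs = target_ts * (if (s$ts > 0) s$vs / s$ts else 0),
                scod = s$scod * dil, vfa = s$vfa * dil,
                temperature = (s$mass_flow * s$temperature +
                                 water * water_temperature) / m_out)
  list(out = out, water_kg_day = water,
       balance = c(inflow = s$mass_flow + water, outflow = out$mass_flow))
}

#' Alkaline-thermal pretreatment
#'
#' Adds a sodium hydroxide solution (raising the pH to 9-10) and holds the
#' biomixture at the pretreatment temperature. Mass increases by the dose;
#' composition is otherwise passed through, since the solubilization effect
#' of the pretreatment enters downstream through the fermenter conversion
#' parameters. The NaOH solution is booked as a non-solids addition.
#'
#' @param s A [stream()].
#' @param naoh_dose NaOH solution dose, kg/day (`>= 0`).
#' @param hold_temp Pretreatment temperature, degC (default 60).
#' @return List with `out` (stream) and `balance`.
#' @export
pretreat_alkaline_thermal <- function(s, naoh_dose, hold_temp = 60) {
  stopifnot(inherits(s, "stream"))
  if (naoh_dose < 0) stop("negative NaOH dose")
  if (s$mass_flow == 0 && naoh_dose == 0) {
    return(list(out = s, balance = c(inflow = 0, outflow = 0)))
  }
  m_out <- s$mass_flow + naoh_dose
  out <- stream(m_out, ts = ts_flow(s) / m_out, vs = vs_flow(s) / m_out,
                scod = s$scod, vfa = s$vfa, temperature = hold_temp)
  list(out = out,
       balance = c(inflow = s$mass_flow + naoh_dose,
                   outflow = out$mass_flow))
}

#' Conversion specification of a biological reactor
#'
#' @param vs_destruction Fraction of fed VS destroyed (digester), `[0, 1]`.
#' @param sgp Specific gas production, Nm3 biogas/kg-VS fed (digester).
#' @param ch4_frac Methane volume fraction of the biogas, `[0, 1]`.
#' @param vfa_out_conc Effluent VFA concentration, g-SCOD/L (fermenter).
#' @param scod_out_conc Effluent SCOD concentration, g-SCOD/L (fermenter).
#' @return List of class `conversion_spec`.
#' @export
conversion_spec <- function(vs_destruction = 0, sgp = 0, ch4_frac = 0,
                            vfa_out_conc = NA_real_,
                            scod_out_conc = NA_real_) {
  if (vs_destruction < 0 || vs_destruction > 1) {
    stop("'vs_destruction' must be in [0, 1]")
  }
  if (ch4_frac < 0 || ch4_frac > 1) stop("'ch4_frac' must be in [0, 1]")
  if (sgp < 0) stop("'sgp' must be >= 0")
  structure(list(vs_destruction = vs_destruction, sgp = sgp,
                 ch4_frac = ch4_frac, vfa_out_conc = vfa_out_conc,
                 scod_out_conc = scod_out_conc), class = "conversion_spec")
}

#' Reactor specification
#'
#' Working volume, operating temperature, target HRT and the geometry used
#' for wall heat losses. The geometry defaults to a vertical cylinder with
#' height equal to diameter and a 20% buried fraction, dimensioned from the
#' working volume.
#'
#' @param working_volume Working volume, m3 (`> 0`).
#' @param temperature Operating temperature, degC (default 37, mesophilic).
#' @param hrt_target Design HRT, days.
#' @param height_diameter_ratio Cylinder height/diameter ratio (default 1).
#' @param buried_fraction Fraction of the wall below grade (default 0.2).
#' @return List of class `reactor_spec` with derived `diameter`, `height`
#'   and surface areas (`a_wall_above`, `a_wall_buried`, `a_floor`,
#'   `a_roof`, m2).
#' @export
reactor_spec <- function(working_volume, temperature = 37, hrt_target = NA,
                         height_diameter_ratio = 1, buried_fraction = 0.2) {
  if (working_volume <= 0) stop("'working_volume' must be > 0")
  if (buried_fraction < 0 || buried_fraction > 1) {
    stop("'buried_fraction' must be in [0, 1]")
  }
  d <- (4 * working_volume / (pi * height_diameter_ratio))^(1 / 3)
  h <- height_diameter_ratio * d
  lateral <- pi * d * h
  plan <- pi * d^2 / 4
  vol_check <- plan * h
  if (abs(vol_check - working_volume) / working_volume > 0.01) {
    stop("geometry inconsistent with working volume")
  }
  structure(list(working_volume = working_volume, temperature = temperature,
                 hrt_target = hrt_target, diameter = d, height = h,
                 buried_fraction = buried_fraction,
                 a_wall_above = lateral * (1 - buried_fraction),
                 a_wall_buried = lateral * buried_fraction,
                 a_floor = plan, a_roof = plan), class = "reactor_spec")
}

#' Hydraulic retention time
#'
#' `HRT = V / (Q / rho)`: working volume over volumetric throughput.
#'
#' @param volume_m3 Working volume, m3 (`> 0`).
#' @param flow_kg_day Mass throughput, kg/day (`> 0`).
#' @param density Stream density, kg/m3 (default 1000).
#' @return HRT in days.
#' @examples
#' hrt(512, 113788) # 4.5 days
#' @export
hrt <- function(volume_m3, flow_kg_day, density = 1000) {
  if (volume_m3 <= 0 || flow_kg_day <= 0) stop("volume and flow must be > 0")
  volume_m3 / (flow_kg_day / density)
}

#' Organic loading rate
#'
#' `OLR = Q * vs / V` in kg-VS per m3 of reactor per day.
#'
#' @param flow_kg_day Mass throughput, kg/day (`> 0`).
#' @param vs_fraction VS fraction of the feed, kg-VS/kg.
#' @param volume_m3 Working volume, m3 (`> 0`).
#' @return OLR, kg-VS/m3/day.
#' @examples
#' olr(113788, 0.031, 512) # 6.89
#' @export
olr <- function(flow_kg_day, vs_fraction, volume_m3) {
  if (volume_m3 <= 0 || flow_kg_day <= 0) stop("volume and flow must be > 0")
  flow_kg_day * vs_fraction / volume_m3
}

# Verify that the design HRT matches the actual throughput within tol.
.check_hrt <- function(spec, s, tol = 0.01, unit = "reactor") {
  if (is.na(spec$hrt_target) || s$mass_flow == 0) return(invisible(NULL))
  actual <- hrt(spec$working_volume, s$mass_flow)
  if (abs(actual / spec$hrt_target - 1) > tol) {
    stop(sprintf("%s HRT mismatch: actual %.2f d vs target %.2f d",
                 unit, actual, spec$hrt_target))
  }
  invisible(actual)
}

#' Mesophilic acidogenic fermenter
#'
#' Converts biosolids into VFAs and soluble COD at the effluent
#' concentrations of the conversion spec. The gaseous flow is taken as zero
#' (an HRT of a few days is too short for methanogen growth), so the outlet
#' mass equals the inlet mass. Solids fractions are passed through: the
#' solubilized organics remain part of the measured TS/VS pool in the
#' dissolved phase, so total solids and COD are conserved under this
#' convention.
#'
#' @param s Feed [stream()].
#' @param spec [reactor_spec()] (HRT consistency checked within 1%).
#' @param conv [conversion_spec()] with `vfa_out_conc`, `scod_out_conc`.
#' @return List with `out` (stream), `hrt`, `olr`, `vfa_product_kg_day` and
#'   `balance`.
#' @export
acidogenic_fermenter <- function(s, spec, conv) {
  stopifnot(inherits(s, "stream"), inherits(spec, "reactor_spec"),
            inherits(conv, "conversion_spec"))
  .check_hrt(spec, s, unit = "fermenter")
  vfa_out <- if (is.na(conv$vfa_out_conc)) s$vfa else conv$vfa_out_conc
  scod_out <- if (is.na(conv$scod_out_conc)) s$scod else conv$scod_out_conc
  out <- stream(s$mass_flow, ts = s$ts, vs = s$vs, scod = scod_out,
                vfa = vfa_out, temperature = spec$temperature)
  zero <- s$mass_flow == 0
  list(out = out,
       hrt = if (zero) NA_real_ else hrt(spec$working_volume, s$mass_flow),
       olr = if (zero) NA_real_ else olr(s$mass_flow, s$vs,
                                         spec$working_volume),
       vfa_product_kg_day = s$mass_flow * vfa_out / 1000, # L/d * g/L -> kg/d
       balance = c(inflow = s$mass_flow, outflow = out$mass_flow))
}

#' Solid-liquid separator
#'
#' Splits the fermenter effluent into a solid cake and an overflow liquor.
#' The cake takes `solids_capture` of the feed TS at a set cake TS; soluble
#' species keep the feed concentration in both outputs (the cake carries its
#' share of liquor). Mass and solids are conserved.
#'
#' @param s Feed [stream()].
#' @param solids_capture Fraction of feed TS sent to the cake, `(0, 1]`.
#' @param cake_ts Cake TS fraction (`> s$ts`).
#' @param cake_vs_ts Optional VS/TS ratio of the cake; defaults to the feed
#'   ratio. The separator can enrich the cake in inorganics, so the cake
#'   ratio may be below the feed value.
#' @return List with `cake`, `liquor` (streams) and `balance`.
#' @export
separator <- function(s, solids_capture, cake_ts, cake_vs_ts = NULL) {
  stopifnot(inherits(s, "stream"))
  if (solids_capture <= 0 || solids_capture > 1) {
    stop("'solids_capture' must be in (0, 1]")
  }
  if (s$mass_flow == 0) {
    return(list(cake = s, liquor = s, balance = c(inflow = 0, outflow = 0)))
  }
  if (cake_ts <= s$ts) stop("'cake_ts' must exceed the feed TS")
  ts_c <- ts_flow(s) * solids_capture
  m_c <- ts_c / cake_ts
  vs_ts <- if (is.null(cake_vs_ts)) {
    if (s$ts > 0) s$vs / s$ts else 0
  } else {
    cake_vs_ts
  }
  m_l <- s$mass_flow - m_c
  ts_l <- ts_flow(s) - ts_c
  vs_l <- vs_flow(s) - ts_c * vs_ts
  cake <- stream(m_c, ts = cake_ts, vs = cake_ts * vs_ts, scod = s$scod,
                 vfa = s$vfa, temperature = s$temperature)
  liquor <- stream(m_l, ts = ts_l / m_l, vs = max(vs_l, 0) / m_l,
                   scod = s$scod, vfa = s$vfa, temperature = s$temperature)
  list(cake = cake, liquor = liquor,
       balance = c(inflow = s$mass_flow,
                   outflow = cake$mass_flow + liquor$mass_flow))
}

#' Mesophilic anaerobic digester
#'
#' Produces biogas from the fed VS at the specified SGP and methane content.
#' Biochar (an inert solid amendment dosed per g of fed VS) enters the feed
#' mass balance; the digestate mass is the feed (plus biochar) minus the
#' biogas mass at a configurable gas density, and the digestate VS is the
#' fed VS reduced by the destruction fraction.
#'
#' @param s Feed [stream()].
#' @param spec [reactor_spec()] (HRT consistency checked on the liquid feed,
#'   before biochar addition).
#' @param conv [conversion_spec()] with `sgp`, `ch4_frac`, `vs_destruction`.
#' @param biochar_dose Biochar addition, g-biochar/g-VS fed (default 0).
#' @param gas_density Biogas density for the mass balance, kg/Nm3
#'   (default 1.2).
#' @return List with `digestate` (stream), `biogas_nm3_day`, `ch4_nm3_day`,
#'   `biochar_kg_day`, `hrt`, `olr` and `balance`.
#' @export
anaerobic_digester <- function(s, spec, conv, biochar_dose = 0,
                               gas_density = 1.2) {
  stopifnot(inherits(s, "stream"), inherits(spec, "reactor_spec"),
            inherits(conv, "conversion_spec"))
  .check_hrt(spec, s, unit = "digester")
  if (s$mass_flow == 0) {
    return(list(digestate = s, biogas_nm3_day = 0, ch4_nm3_day = 0,
                biochar_kg_day = 0, hrt = NA_real_, olr = NA_real_,
                balance = c(inflow = 0, outflow = 0)))
  }
  vs_fed <- vs_flow(s)
  biochar <- biochar_dose * vs_fed
  biogas <- conv$sgp * vs_fed
  ch4 <- biogas * conv$ch4_frac
  gas_mass <- biogas * gas_density
  m_in <- s$mass_flow + biochar
  m_dig <- m_in - gas_mass
  if (m_dig < 0) stop("biogas mass exceeds feed mass; check SGP/density")
  vs_dig <- vs_fed * (1 - conv$vs_destruction)
  ts_dig <- ts_flow(s) + biochar - vs_fed * conv$vs_destruction
  digestate <- stream(m_dig, ts = ts_dig / m_dig, vs = vs_dig / m_dig,
                      scod = s$scod, vfa = 0,
                      temperature = spec$temperature)
  list(digestate = digestate, biogas_nm3_day = biogas, ch4_nm3_day = ch4,
       biochar_kg_day = biochar,
       hrt = hrt(spec$working_volume, s$mass_flow),
       olr = olr(s$mass_flow, s$vs, spec$working_volume),
       balance = c(inflow = m_in,
                   outflow = digestate$mass_flow + gas_mass))
}
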