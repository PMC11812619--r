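#' Assemble a BMP dataset
#'
#' A BMP (biochemical methane potential) dataset is a tidy table of per-bottle
#' cumulative gas readings with a bottle metadata table attached as an
#' attribute. Readings for blank bottles (inoculum only, zero feedstock VS)
#' are used for endogenous-production correction.
#'
#' @param readings data.frame with columns `day`, `bottle_id`, `condition`,
#'   `cum_biogas_ml`, `cum_ch4_ml`, `ch4_frac` (`NA` outside gas
#'   chromatography days).
#' @param bottles data.frame with columns `bottle_id`, `condition`,
#'   `vs_feedstock` (g-VS, 0 for blanks), `vs_inoculum` (g-VS), `is_blank`.
#' @return The readings data.frame with class `bmp_dataset` and attribute
#'   `bottles`.
#' @export
bmp_dataset <- function(readings, bottles) {
  need <- c("day", "bottle_id", "condition", "cum_biogas_ml", "cum_ch4_ml",
            "ch4_frac")
  if (!all(need %in% names(readings))) {
    stop("readings must have columns: ", paste(need, collapse = ", "))
  }
  needb <- c("bottle_id", "condition", "vs_feedstock", "vs_inoculum",
             "is_blank")
  if (!all(needb %in% names(bottles))) {
    stop("bottles must have columns: ", paste(needb, collapse = ", "))
  }
  if (!any(bottles$is_blank)) stop("at least one blank bottle is required")
  if (any(bottles$vs_feedstock < 0) || any(bottles$vs_inoculum < 0)) {
    stop("VS masses must be non-negative")
  }
  for (id in unique(readings$bottle_id)) {
    cc <- readings[readings$bottle_id == id, ]
    cc <- cc[order(cc$day), ]
    if (is.unsorted(cc$cum_ch4_ml) || is.unsorted(cc$cum_biogas_ml)) {
      stop("cumulative volumes must be non-decreasing (bottle ", id, ")")
    }
  }
  fr <- readings$ch4_frac
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) stop("ch4_frac must be in [0, 1]")
  structure(readings, bottles = bottles, class = c("bmp_dataset",
                                                   "data.frame"))
}

#' k-nearest-neighbour imputation of a sparse time series
#'
#' Gas composition is only measured by gas chromatography on a handful of
#' days; remaining days are filled by k-NN on the time axis with
#' inverse-distance weights: each missing day takes the weighted mean of its
#' `k` nearest observed days, with weight `1/|day - observed day|`.
#' Observed values are never modified.
#'
#' @param days Numeric vector of days.
#' @param values Values at `days`, `NA` where unobserved.
#' @param k Number of neighbours (default 4, distance-weighted).
#' @return `values` with every `NA` imputed.
#' @examples
#' knn_impute_composition(c(1, 4, 5, 6, 10), c(50, 60, NA, 60, 50), k = 4)
#' @export
knn_impute_composition <- function(days, values, k = 4) {
  if (length(days) != length(values)) stop("length mismatch")
  if (k < 1) stop("'k' must be >= 1")
  obs <- which(!is.na(values))
  if (length(obs) == 0) stop("all-missing series cannot be imputed")
  if (length(obs) < k) {
    stop("fewer observed points (", length(obs), ") than neighbours k = ", k)
  }
  out <- values
  for (i in which(is.na(values))) {
    d <- abs(days[obs] - days[i])
    ord <- order(d, days[obs])
    sel <- ord[seq_len(k)]
    w <- 1 / d[sel]
    out[i] <- sum(w * values[obs][sel]) / sum(w)
  }
  out
}

#' Blank-correct and aggregate a BMP dataset
#'
#' Subtracts the endogenous (inoculum-only) gas production from each test
#' bottle, then averages the replicate bottles of each condition. The blank
#' curve is expressed per gram of inoculum VS and scaled by each bottle's own
#' inoculum VS, so bottles and blanks with different inoculum masses are
#' handled. Net volumes are clipped at zero (cumulative production cannot be
#' negative); the number of clipped readings is reported.
#'
#' @param ds A [bmp_dataset()].
#' @return data.frame with columns `condition`, `day`, `net_ch4_ml`,
#'   `net_biogas_ml` (replicate means of blank-corrected volumes), plus
#'   attributes `clipped` (count of readings clipped to zero) and
#'   `vs_feedstock` (named vector of mean feedstock VS per condition).
#' @export
blank_correct <- function(ds) {
  stopifnot(inherits(ds, "bmp_dataset"))
  bottles <- attr(ds, "bottles")
  blanks <- bottles$bottle_id[bottles$is_blank]
  if (length(blanks) == 0) stop("no blank bottles in dataset")

  bl <- ds[ds$bottle_id %in% blanks, ]
  bl <- merge(bl, bottles[, c("bottle_id", "vs_inoculum")], by = "bottle_id")
  # endogenous production per g inoculum VS, averaged across blank bottles
  blank_curve <- stats::aggregate(
    cbind(ch4 = bl$cum_ch4_ml / bl$vs_inoculum,
          biogas = bl$cum_biogas_ml / bl$vs_inoculum),
    by = list(day = bl$day), FUN = mean
  )

  test_ids <- bottles$bottle_id[!bottles$is_blank]
  clipped <- 0L
  rows <- list()
  for (id in test_ids) {
    bt <- ds[ds$bottle_id == id, ]
    meta <- bottles[bottles$bottle_id == id, ]
    m <- merge(bt, blank_curve, by = "day") # inner join on shared days
    if (nrow(m) < nrow(bt)) {
      message("blank_correct: dropped ", nrow(bt) - nrow(m),
              " day(s) of bottle ", id, " absent from the blank grid")
    }
    net_ch4 <- m$cum_ch4_ml - m$ch4 * meta$vs_inoculum
    net_bio <- m$cum_biogas_ml - m$biogas * meta$vs_inoculum
    clipped <- clipped + sum(net_ch4 < 0) + sum(net_bio < 0)
    rows[[id]] <- data.frame(condition = meta$condition, day = m$day,
                             bottle_id = id,
                             net_ch4_ml = pmax(net_ch4, 0),
                             net_biogas_ml = pmax(net_bio, 0))
  }
  if (clipped > 0) {
    message("blank_correct: clipped ", clipped, " negative net reading(s)")
  }
  per_bottle <- do.call(rbind, rows)
  out <- stats::aggregate(
    cbind(net_ch4_ml = per_bottle$net_ch4_ml,
          net_biogas_ml = per_bottle$net_biogas_ml),
    by = list(condition = per_bottle$condition, day = per_bottle$day),
    FUN = mean
  )
  out <- out[order(out$condition, out$day), ]
  rownames(out) <- NULL
  vsf <- tapply(bottles$vs_feedstock[!bottles$is_blank],
                bottles$condition[!bottles$is_blank], mean)
  structure(out, clipped = clipped, vs_feedstock = vsf)
}

#' Performance summary of one BMP condition
#'
#' Computes the specific methane production (SMP), specific gas production
#' (SGP), biogas yield and maximum methane content of a blank-corrected,
#' replicate-averaged condition. Volumes are assumed already normalized
#' (Nm3 reference 0 degC, 101.325 kPa); SMP/SGP are the final net cumulative
#' volumes per kg of feedstock VS, the biogas yield converts SGP to a mass
#' basis with a configurable biogas density, and the maximum methane content
#' is taken over the (imputed) composition series.
#'
#' @param net data.frame for a single condition with columns `day`,
#'   `net_ch4_ml`, `net_biogas_ml` (as returned by [blank_correct()]).
#' @param ch4_frac Methane volume fraction series on the full day grid
#'   (after [knn_impute_composition()]); values in `[0, 1]`.
#' @param vs_feedstock Feedstock VS in the bottle, g (`> 0`).
#' @param gas_density Biogas density, kg/Nm3 (default 1.2).
#' @return List of class `bmp_summary`: `smp` (Nm3 CH4/kg-VS), `sgp`
#'   (Nm3 biogas/kg-VS), `biogas_yield` (g-biogas/g-VS), `max_ch4_content`
#'   (% v/v).
#' @export
bmp_summary <- function(net, ch4_frac, vs_feedstock, gas_density = 1.2) {
  if (vs_feedstock <= 0) stop("'vs_feedstock' must be > 0")
  if (length(unique(net$condition)) > 1) {
    stop("'net' must contain a single condition")
  }
  net <- net[order(net$day), ]
  smp <- utils::tail(net$net_ch4_ml, 1) / 1000 / vs_feedstock # mL/g == L/kg
  sgp <- utils::tail(net$net_biogas_ml, 1) / 1000 / vs_feedstock
  out <- list(
    smp = smp,
    sgp = sgp,
    biogas_yield = sgp * gas_density, # Nm3/kg * kg/Nm3 = kg/kg = g/g
    max_ch4_content = max(ch4_frac, na.rm = TRUE) * 100
  )
  if (out$smp > out$sgp + 1e-9) {
    warning("SMP exceeds SGP; check methane/biogas volume consistency")
  }
  class(out) <- "bmp_summary"
  out
}

#' @export
print.bmp_summary <- function(x, ...) {
  cat(sprintf(paste0("BMP summary: SMP %.3f Nm3-CH4/kg-VS, SGP %.3f",
                     " Nm3/kg-VS,\n  biogas yield %.2f g/g-VS,",
                     " max CH4 content %.1f%% v/v\n"),
              x$smp, x$sgp, x$biogas_yield, x$max_ch4_content))
  invisible(x)
}
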