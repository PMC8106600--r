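#' Define a substance and its exposure-relevant parameters
#'
#' Bundles everything chemical-specific the simulator needs: per-capita
#' consumption, the fraction excreted unchanged, the fraction of total
#' emission occurring at the place of medical treatment (`f_site`, routed
#' through hospitals), removal efficiency per treatment category,
#' pseudo-first-order in-stream loss rates, and the regulatory thresholds
#' EQS and LOQ.
#'
#' Consumption and removal can optionally carry relative standard
#' deviations for Monte Carlo runs (`consumption_rsd`, `removal_rsd`);
#' zero (the default) means the parameter is treated as exact.
#'
#' @param name Substance name.
#' @param per_capita_consumption mg per inhabitant and day.
#' @param excretion_fraction Fraction excreted unchanged, in `[0,1]`.
#' @param f_site Fraction of total emission occurring at the treatment
#'   location (hospital sub-model), in `[0,1]`.  0 = pure household
#'   substance.
#' @param removal Named numeric vector or list, removal efficiency in
#'   `[0,1]` per treatment category (see [treatment_categories()]).
#' @param k_deg,k_sed,k_vol Pseudo-first-order loss rates for degradation,
#'   sedimentation and volatilisation, 1/h, `>= 0`.
#' @param eqs Environmental quality standard, ng/l (`NA` if none).
#' @param loq Limit of quantification, ng/l (`NA` if none).
#' @param consumption_rsd,removal_rsd Relative standard deviations for
#'   Monte Carlo sampling (lognormal for consumption, `[0,1]`-truncated
#'   normal for removal).
#' @return An object of class `substance`.
#' @export
substance <- function(name, per_capita_consumption, excretion_fraction,
                      f_site = 0, removal = c(activated_sludge = 0),
                      k_deg = 0, k_sed = 0, k_vol = 0,
                      eqs = NA_real_, loq = NA_real_,
                      consumption_rsd = 0, removal_rsd = 0) {
  stopifnot(is.character(name), length(name) == 1)
  .check_frac <- function(x, what) {
    if (!is.finite(x) || x < 0 || x > 1) stop(what, " must be in [0, 1]")
  }
  if (!is.finite(per_capita_consumption) || per_capita_consumption < 0)
    stop("per_capita_consumption must be >= 0")
  .check_frac(excretion_fraction, "excretion_fraction")
  .check_frac(f_site, "f_site")
  removal <- unlist(removal)
  if (is.null(names(removal)) || any(names(removal) == ""))
    stop("removal must be named by treatment category")
  bad <- setdiff(names(removal), treatment_categories())
  if (length(bad) > 0)
    stop("unknown treatment categories in removal: ", paste(bad, collapse = ", "))
  for (r in removal) .check_frac(r, "removal efficiency")
  for (k in c(k_deg, k_sed, k_vol))
    if (!is.finite(k) || k < 0) stop("loss rates must be >= 0")
  if (!is.na(eqs) && eqs <= 0) stop("eqs must be > 0 if set")
  structure(list(name = name,
                 per_capita_consumption = per_capita_consumption,
                 excretion_fraction = excretion_fraction,
                 f_site = f_site, removal = removal,
                 k_deg = k_deg, k_sed = k_sed, k_vol = k_vol,
                 eqs = eqs, loq = loq,
                 consumption_rsd = consumption_rsd,
                 removal_rsd = removal_rsd),
            class = "substance")
}

#' @export
print.substance <- function(x, ...) {
  cat(sprintf("<substance> %s: %.3g mg/(cap d), excretion %.2f, f_site %.3f, k_total %.3g 1/h\n",
              x$name, x$per_capita_consumption, x$excretion_fraction,
              x$f_site, k_total(x)))
  invisible(x)
}

#' Fraction of the administered dose emitted at the treatment site
#'
#' For hospital-administered substances (e.g. X-ray contrast agents) the
#' on-site fraction combines two paths: the dose given to stationary
#' inpatients is emitted at the hospital in full, and of the remainder
#' (out-patients) the part excreted before leaving is emitted there too:
#' `f_site = f_stationary + (1 - f_stationary) * f_excreted_window`.
#'
#' With 50% stationary administration and 75% of the dose excreted within
#' the first hours, 87.5% of the total dose is emitted at the treatment
#' site.
#'
#' @param f_stationary Fraction of doses administered to stationary
#'   inpatients, `[0,1]`.
#' @param f_excreted_window Fraction of the dose excreted before an
#'   out-patient leaves the site, `[0,1]`.
#' @return `f_site` in `[0,1]`.
#' @export
fraction_emitted_on_site <- function(f_stationary, f_excreted_window) {
  for (x in c(f_stationary, f_excreted_window))
    if (!is.finite(x) || x < 0 || x > 1)
      stop("arguments must be in [0, 1]")
  f_stationary + (1 - f_stationary) * f_excreted_window
}

#' Total basin-wide emission of a substance
#'
#' `L_total = (sum of connected inhabitants over all WWTPs) *
#' per_capita_consumption * excretion_fraction / 1000`, in g/day.
#'
#' @param sub A [substance()].
#' @param ct A [catchment()].
#' @return Mass flow in g/day.
#' @export
total_basin_emission <- function(sub, ct) {
  sum(ct$wwtps$population_connected) *
    sub$per_capita_consumption * sub$excretion_fraction / 1000
}

#' Allocate the hospital emission share across hospitals
#'
#' @param hospitals data.frame as in `ct$hospitals`.
#' @param mode `"by_patients"` (weights proportional to `patients_per_year`),
#'   `"by_beds"`, or `"custom"`.
#' @param weights For `mode = "custom"`: named numeric vector
#'   (hospital_id -> fraction), non-negative, summing to 1 within `1e-9`.
#' @return Named numeric vector of weights summing to 1.
#' @export
allocate_hospital_weights <- function(hospitals,
                                      mode = c("by_patients", "by_beds", "custom"),
                                      weights = NULL) {
  mode <- match.arg(mode)
  if (nrow(hospitals) == 0) stop("no hospitals to allocate to")
  ids <- hospitals$hospital_id
  if (mode == "custom") {
    if (is.null(weights) || is.null(names(weights)))
      stop("custom mode requires a named weights vector")
    if (!setequal(names(weights), ids))
      stop("custom weights must cover exactly the hospital ids")
    weights <- weights[ids]
    if (any(weights < 0)) stop("weights must be >= 0")
    if (abs(sum(weights) - 1) > 1e-9)
      stop("custom weights must sum to 1 (got ", sum(weights), ")")
    return(weights)
  }
  basis <- if (mode == "by_patients") hospitals$patients_per_year else hospitals$beds
  if (sum(basis) <= 0) stop("allocation basis sums to zero")
  stats::setNames(basis / sum(basis), ids)
}

#' Per-WWTP influent loads from household and hospital emissions
#'
#' The `(1 - f_site)` household share of the total emission is spread over
#' the resident population per plant (place-of-residence principle); the
#' `f_site` hospital share is split across hospitals by `weights` and
#' enters each hospital's receiving plant.  Hospital patients are not added
#' to the population term (no double counting).  The loads sum to
#' [total_basin_emission()] exactly.
#'
#' @param sub A [substance()].
#' @param ct A [catchment()].
#' @param weights Hospital weights from [allocate_hospital_weights()];
#'   required iff `sub$f_site > 0`.
#' @return Named numeric vector, wwtp_id -> influent mass flow in g/day.
#' @export
influent_loads <- function(sub, ct, weights = NULL) {
  w <- ct$wwtps
  L_total <- total_basin_emission(sub, ct)
  household <- (1 - sub$f_site) * sub$per_capita_consumption *
    sub$excretion_fraction * w$population_connected / 1000
  loads <- stats::setNames(household, w$wwtp_id)
  if (sub$f_site > 0) {
    if (is.null(weights))
      stop("f_site > 0 requires hospital allocation weights")
    hs <- ct$hospitals
    bad <- setdiff(hs$receiving_wwtp, w$wwtp_id)
    if (length(bad) > 0)
      stop("hospital references unknown WWTP: ", paste(bad, collapse = ", "))
    for (i in seq_len(nrow(hs))) {
      hid <- hs$hospital_id[i]
      loads[hs$receiving_wwtp[i]] <- loads[hs$receiving_wwtp[i]] +
        sub$f_site * L_total * weights[[hid]]
    }
  }
  loads
}

#' Effluent load after treatment
#'
#' `effluent = influent * (1 - removal[category])`, the simple
#' percentage-removal model of secondary treatment.
#'
#' @param influent Influent mass flow, g/day, `>= 0`.
#' @param treatment_category Category the plant belongs to.
#' @param sub A [substance()] whose `removal` covers the category.
#' @return Effluent mass flow, g/day.
#' @export
effluent_load <- function(influent, treatment_category, sub) {
  if (any(influent < 0)) stop("influent must be >= 0")
  if (!(treatment_category %in% names(sub$removal)))
    stop("substance has no removal efficiency for category '",
         treatment_category, "'")
  influent * (1 - sub$removal[[treatment_category]])
}

#' Effluent (hydraulic) flow of a plant
#'
#' Uses the plant's explicit `effluent_flow` when present, otherwise
#' `population_connected * q_ww` with the conventional design value
#' `q_ww = 0.2` m3 per inhabitant and day.
#'
#' @param wwtp One row of `ct$wwtps` (or a list with the same fields).
#' @param q_ww Per-capita wastewater volume, m3/(cap d).
#' @return Effluent flow in m3/day.
#' @export
effluent_flow <- function(wwtp, q_ww = 0.2) {
  if (!is.na(wwtp$effluent_flow)) return(wwtp$effluent_flow)
  wwtp$population_connected * q_ww
}

# vector over all plants, m3/d
.effluent_flows <- function(ct, q_ww = 0.2) {
  w <- ct$wwtps
  ef <- ifelse(is.na(w$effluent_flow),
               w$population_connected * q_ww, w$effluent_flow)
  stats::setNames(ef, w$wwtp_id)
}

# per-plant effluent loads honoring per-plant removal overrides (scenarios)
.effluent_loads <- function(sub, ct, weights = NULL) {
  infl <- influent_loads(sub, ct, weights)
  w <- ct$wwtps
  overrides <- attr(ct, "removal_override")
  out <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    cat_i <- w$treatment_category[i]
    r <- NULL
    if (!is.null(overrides)) {
      ov <- overrides[[w$wwtp_id[i]]]
      if (!is.null(ov) && cat_i %in% names(ov)) r <- ov[[cat_i]]
    }
    if (is.null(r)) {
      out[i] <- effluent_load(infl[[w$wwtp_id[i]]], cat_i, sub)
    } else {
      out[i] <- infl[[w$wwtp_id[i]]] * (1 - r)
    }
  }
  stats::setNames(out, w$wwtp_id)
}
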