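# The plant-side carbon and nutrient economy: seed reserves, emergence,
# photosynthesis, respiration, allocation and nutrient stress.

#' Create a plant carbon/nutrient budget
#'
#' Tracks the seed carbohydrate reserve, cumulative photosynthate and
#' respiration, structural carbon by tissue, plant nutrient pools and the
#' current stress factors. All carbon pools are in g C; the seed reserve is
#' carried in mg carbohydrate.
#'
#' @param phenotype a [plant_phenotype()].
#' @param control a [sim_control()] (supplies the carbohydrate-to-carbon
#'   yield).
#' @return Object of class `plant_budget`.
#' @export
plant_budget <- function(phenotype, control = sim_control()) {
  reserve <- seed_carbohydrate_reserve(phenotype$seed_mass,
                                       phenotype$carbohydrate_fraction)
  structure(list(
    seed_reserve_initial = reserve,
    seed_reserve_remaining = reserve,
    cumulative_photosynthate = 0,
    cumulative_respiration = 0,
    carbon_store = 0,
    structural_carbon = c(root = 0, stem = 0, leaf = 0),
    plant_n = phenotype$seed_nitrogen, plant_p = phenotype$seed_phosphorus,
    optimal_n = 0, optimal_p = 0,
    stress_n = 1, stress_p = 1,
    leaf_area = 0, mesocotyl_length = 0,
    emerged = FALSE, germination_failed = FALSE),
    class = "plant_budget")
}

#' Nominal emergence day from planting depth and mesocotyl growth
#'
#' The coleoptile reaches the surface (and photosynthesis can begin) when
#' the mesocotyl has elongated through the planting depth. In the coupled
#' simulation the mesocotyl is an explicit carbon sink and may stall if
#' reserves run out; this helper returns the unconstrained value
#' `depth / rate`.
#'
#' @param planting_depth cm (> 0).
#' @param mesocotyl_rate cm d^-1 (> 0).
#' @return Days after planting.
#' @export
emergence_day <- function(planting_depth, mesocotyl_rate) {
  stopifnot(planting_depth > 0)
  if (mesocotyl_rate <= 0)
    stop("zero mesocotyl growth rate: germination impossible")
  planting_depth / mesocotyl_rate
}

#' Draw carbon from the seed reserve
#'
#' Reserves are supplied on demand: the seedling receives
#' `min(demand, remaining reserve converted to carbon)`, and the reserve is
#' decremented by the carbohydrate equivalent of what was supplied.
#'
#' @param budget a [plant_budget()].
#' @param demand g C requested (>= 0).
#' @param yield g C per g carbohydrate (default from [sim_control()]).
#' @return `list(supplied = g C, budget = updated budget)`.
#' @export
draw_seed_reserves <- function(budget, demand, yield = 0.42) {
  stopifnot(demand >= 0)
  avail_c <- budget$seed_reserve_remaining / 1000 * yield
  supplied <- min(demand, avail_c)
  budget$seed_reserve_remaining <-
    max(0, budget$seed_reserve_remaining - supplied / yield * 1000)
  list(supplied = supplied, budget = budget)
}

#' Germination / emergence status check
#'
#' A seedling fails to germinate when its seed reserve is exhausted before
#' the coleoptile has reached the surface and no photosynthate has been
#' produced. Failed plants stop growing and keep a near-zero shoot dry
#' weight.
#'
#' @param budget a [plant_budget()].
#' @param day current day.
#' @param emergence_day nominal emergence day (see [emergence_day()]).
#' @return The budget with `emerged` / `germination_failed` updated.
#' @export
check_germination <- function(budget, day, emergence_day) {
  if (!budget$emerged && budget$mesocotyl_length <= 0 && day >= emergence_day)
    budget$emerged <- TRUE  # degenerate zero-depth case
  if (!budget$emerged && budget$seed_reserve_remaining <= 1e-12 &&
      budget$cumulative_photosynthate <= 0)
    budget$germination_failed <- TRUE
  budget
}

#' Daily photosynthesis from leaf area
#'
#' Light interception over the plant's ground area follows an exponential
#' (Beer's law) function of leaf area index, so carbon gain is linear in
#' leaf area for small plants and saturates at full interception:
#' `gain = lue * PAR_mol * ground_area * (1 - exp(-k * LAI))`.
#'
#' @param leaf_area cm^2.
#' @param par photosynthetically active radiation, umol m^-2 s^-1.
#' @param day_length photoperiod, h.
#' @param lue light-use efficiency, g C per mol intercepted photons.
#' @param ground_area_cm2 per-plant ground area, cm^2.
#' @param k canopy extinction coefficient.
#' @return Carbon gain, g C d^-1.
#' @export
photosynthesize <- function(leaf_area, par = 600, day_length = 14,
                            lue = 0.35, ground_area_cm2 = 1560, k = 0.6) {
  stopifnot(leaf_area >= 0, par >= 0, day_length >= 0, lue >= 0,
            ground_area_cm2 > 0)
  par_mol <- par * 1e-6 * day_length * 3600       # mol m^-2 d^-1
  ga_m2 <- ground_area_cm2 / 1e4
  lai <- leaf_area / ground_area_cm2
  lue * par_mol * ga_m2 * (1 - exp(-k * lai))
}

#' Root maintenance respiration summed over segments
#'
#' Each segment respires at its class rate times its dry mass. Rates are in
#' umol CO2 (g DW)^-1 s^-1 and are converted to g C d^-1
#' (1 umol CO2 = 12 ug C).
#'
#' @param segments data.frame with columns `class` and `mass` (g DW), as
#'   produced by [segment_table()], or any per-segment table.
#' @param class_rates named vector, umol CO2 g^-1 s^-1 per class.
#' @return Total respiration, g C d^-1.
#' @export
respire <- function(segments, class_rates) {
  if (any(class_rates < 0)) stop("respiration rates must be >= 0")
  if (NROW(segments) == 0) return(0)
  rates <- class_rates[segments$class]
  if (anyNA(rates)) stop("missing respiration rate for some class")
  sum(segments$mass * rates) * 12e-6 * 86400
}

#' Partition available carbon among sinks
#'
#' Carbon is offered to roots, stem and leaves in proportion to the
#' allocation coefficients; a sink never receives more than its demand, and
#' carbon declined by demand-capped sinks is re-offered to the unsatisfied
#' sinks in proportion to their coefficients until either the carbon or the
#' demand is exhausted.
#'
#' @param available g C (>= 0).
#' @param coefficients named fractions summing to 1.
#' @param demands named g C demands (same names).
#' @return Named allocation vector; `sum(out) <= available`,
#'   `out <= demands` elementwise.
#' @export
allocate_carbon <- function(available, coefficients, demands) {
  stopifnot(available >= 0, all(demands >= 0),
            abs(sum(coefficients) - 1) < 1e-9)
  demands <- demands[names(coefficients)]
  alloc <- stats::setNames(numeric(length(coefficients)), names(coefficients))
  remaining <- available
  for (i in 1:20) {
    open <- which(alloc < demands - 1e-15)
    if (!length(open) || remaining <= 1e-15) break
    w <- coefficients[open] / sum(coefficients[open])
    give <- pmin(w * remaining, demands[open] - alloc[open])
    alloc[open] <- alloc[open] + give
    remaining <- remaining - sum(give)
  }
  alloc
}

#' Optimal whole-plant nutrient content
#'
#' The dot product of tissue masses with the optimal tissue nutrient
#' concentrations, per nutrient.
#'
#' @param tissue_masses named g DW by tissue (e.g. `root`, `shoot`).
#' @param optimal_conc list per tissue of `c(n = , p = )` umol g^-1.
#' @return `c(n = umol, p = umol)`.
#' @export
optimal_nutrient_content <- function(tissue_masses, optimal_conc) {
  stopifnot(all(tissue_masses >= 0))
  out <- c(n = 0, p = 0)
  for (tis in names(tissue_masses)) {
    conc <- optimal_conc[[tis]]
    if (is.null(conc)) stop("no optimal concentrations for tissue ", tis)
    if (any(conc < 0)) stop("optimal concentrations must be >= 0")
    out <- out + tissue_masses[[tis]] * conc[c("n", "p")]
  }
  out
}

#' Nutrient stress factor
#'
#' The ratio of actual to optimal plant nutrient content, floored at a
#' configurable minimum and capped at 1. Applied multiplicatively to leaf
#' expansion, photosynthesis and root elongation.
#'
#' @param actual umol in the plant (>= 0).
#' @param optimal umol at optimum (>= 0).
#' @param floor minimum factor in `[0, 1]`.
#' @return Factor in `[floor, 1]`.
#' @export
stress_factor <- function(actual, optimal, floor = 0.1) {
  if (any(actual < 0) || any(optimal < 0)) stop("inputs must be >= 0")
  stopifnot(floor >= 0, floor <= 1)
  ifelse(optimal <= 0 | actual >= optimal, 1,
         pmax(floor, actual / optimal))
}
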