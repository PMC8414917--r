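# The coupled daily simulation loop: soil physics -> per-segment nutrient
# uptake -> carbon budget and stress -> photosynthesis / reserve draw ->
# allocation -> elongation and branching -> accounting.

# Internal: unconstrained carbon demand of elongation this step (mirrors the
# cost model in elongate() without advancing the RNG).
elongation_demand <- function(sys, day, dt, stress_factor) {
  cp <- sys$cp
  tip <- sys$tip
  act <- which(tip$born <= day - dt + 1e-9 & tip$cumlen < tip$maxlen - 1e-12)
  if (!length(act)) return(0)
  cls <- tip$class[act]
  rate <- pmax(0, cp$slope[cls] * day + cp$intercept[cls])
  dl <- pmin(rate * dt * stress_factor, tip$maxlen[act] - tip$cumlen[act])
  sum(dl * pi * cp$radius[cls]^2 * cp$density[cls]) *
    sys$control$carbon_fraction * sys$control$growth_overhead
}

#' Run one coupled seedling simulation
#'
#' Simulates one plant in one environment for `days` days at the control
#' time step. Each step runs the water balance, nitrate
#' convection-dispersion, mineralization, Michaelis-Menten nitrate uptake
#' and Barber-Cushman phosphorus uptake (one radial depletion state per
#' root class x soil layer x day-of-arrival cohort, apportioned by root
#' length), then updates the carbon budget (photosynthesis after
#' emergence, seed reserve draw on demand, maintenance respiration,
#' allocation to roots, stem/mesocotyl and leaves) and grows the root
#' system. A seedling whose reserve is exhausted before the mesocotyl
#' reaches the surface fails germination and stops growing; this is a
#' valid result with near-zero shoot mass, not an error.
#'
#' @param phenotype a [plant_phenotype()].
#' @param environment a [soil_environment()].
#' @param seed RNG seed; fixed seed gives a bit-identical result.
#' @param days simulated days after planting.
#' @param control a [sim_control()].
#' @param keep_geometry keep the full root system in the result.
#' @return Object of class `simulation_result`: per-day budget trajectory,
#'   cumulative uptake arrays (class x layer x day, umol), final shoot dry
#'   weight (g), mass-balance bookkeeping, and optionally the root system.
#' @export
run_simulation <- function(phenotype, environment, seed = 1, days = 25,
                           control = sim_control(), keep_geometry = TRUE) {
  stopifnot(inherits(phenotype, "plant_phenotype"),
            inherits(environment, "soil_environment"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  ctl <- control
  dt <- ctl$dt
  env <- environment
  soil <- soil_column(env)
  sys <- initiate_root_system(phenotype, env$prism, ctl)
  budget <- plant_budget(phenotype, ctl)
  cp <- sys$cp
  cfrac <- ctl$carbon_fraction
  over <- ctl$growth_overhead
  coefs <- phenotype$allocation_coefficients
  names(coefs) <- c("roots", "stem", "leaves")
  nl <- soil$n_layers
  area <- soil$area
  meso_area <- pi * (phenotype$mesocotyl_diameter / 2)^2
  meso_cost_cm <- meso_area * 0.08 * cfrac * over  # g C per cm mesocotyl
  resp_conv <- 12e-6 * 86400                       # umol/g/s -> gC/gDW/d

  n_steps <- round(days / dt)
  upt_n <- array(0, c(6, nl, days))
  upt_p <- array(0, c(6, nl, days))
  traj <- vector("list", days)
  # phosphorus depletion cohorts, per root class
  pstate <- lapply(1:6, function(k) list(
    grid = exp(seq(log(cp$radius[k]), log(ctl$p_rx), length.out = ctl$bc_nodes)),
    profiles = matrix(0, 0, ctl$bc_nodes), len = numeric(0),
    layer = integer(0)))
  LEN_prev <- sys$LEN
  failed_stop <- FALSE

  for (step in seq_len(n_steps)) {
    t_now <- step * dt
    day <- ceiling(t_now - 1e-9)
    # --- soil physics ---
    rain_mm <- env$rainfall[min(day, length(env$rainfall))] *
      env$rainfall_multiplier
    ws <- step_water(soil, rain_mm / 10 * dt, env$evaporation_rate / 10 * dt)
    soil <- ws$column
    tr <- transport_nitrate(soil, ws$fluxes)
    soil <- tr$column
    soil <- mineralize(soil, t_now, dt, ctl$mineralization_k0,
                       ctl$mineralization_s)$column
    if (!failed_stop) {
    # --- nutrient uptake ---
    tissue <- c(root = budget$structural_carbon[["root"]] / cfrac,
                shoot = (budget$structural_carbon[["stem"]] +
                           budget$structural_carbon[["leaf"]]) / cfrac)
    opt <- optimal_nutrient_content(tissue, phenotype$optimal_tissue_conc)
    budget$optimal_n <- opt[["n"]]; budget$optimal_p <- opt[["p"]]
    un <- uptake_nitrate(sys$SA, soil, c(ctl$n_imax, ctl$n_km),
                         demand_cap = max(0, opt[["n"]] - budget$plant_n),
                         dt = dt)
    soil <- un$column
    budget$plant_n <- budget$plant_n + sum(un$uptake)
    upt_n[, , day] <- upt_n[, , day] + un$uptake
    p_cap <- max(0, opt[["p"]] - budget$plant_p)
    conc_p <- p_solution_conc(soil)
    for (k in 1:6) {
      st <- pstate[[k]]
      if (!length(st$len)) next
      per_cm <- bc_step_cpp(st$profiles, st$grid, soil$texture$p_diffusion_coefficient,
                            soil$texture$p_buffer_power, ctl$p_imax, ctl$p_km,
                            ctl$p_cmin, ctl$p_v0, dt, ctl$bc_nsub)
      want <- per_cm * st$len
      by_layer <- tabulate_weighted(st$layer, want, nl)
      sc <- ifelse(by_layer > soil$p_labile & by_layer > 0,
                   soil$p_labile / by_layer, 1)
      got <- want * sc[st$layer]
      tot <- sum(got)
      if (tot > p_cap && tot > 0) { got <- got * p_cap / tot; tot <- p_cap }
      soil$p_labile <- pmax(0, soil$p_labile -
                              tabulate_weighted(st$layer, got, nl))
      budget$plant_p <- budget$plant_p + tot
      p_cap <- max(0, p_cap - tot)
      upt_p[k, , day] <- upt_p[k, , day] + tabulate_weighted(st$layer, got, nl)
    }
    # --- stress ---
    budget$stress_n <- stress_factor(budget$plant_n, opt[["n"]],
                                     ctl$stress_floor)
    budget$stress_p <- stress_factor(budget$plant_p, opt[["p"]],
                                     ctl$stress_floor)
    stress <- min(budget$stress_n, budget$stress_p)
    # --- carbon supply ---
    photos <- if (budget$emerged)
      photosynthesize(budget$leaf_area, ctl$par, ctl$photoperiod, ctl$lue,
                      area, ctl$k_light) * stress * dt else 0
    budget$cumulative_photosynthate <- budget$cumulative_photosynthate + photos
    maint <- sum(sys$mass_by_class * cp$resp) * resp_conv * dt +
      ctl$shoot_maintenance *
        (budget$structural_carbon[["stem"]] +
           budget$structural_carbon[["leaf"]]) * dt
    demand_root <- elongation_demand(sys, t_now, dt, stress)
    # leaves expand once the coleoptile has reached the surface
    dla_pot <- if (budget$emerged)
      eval_rate(phenotype$leaf_area_expansion_rate, t_now) * stress * dt
    else 0
    demand_leaf <- dla_pot / ctl$sla * cfrac * over
    if (!budget$emerged) {
      dmeso_pot <- min(phenotype$mesocotyl_rate * dt,
                       max(0, phenotype$planting_depth - budget$mesocotyl_length))
      demand_stem <- dmeso_pot * meso_cost_cm
    } else {
      demand_stem <- demand_leaf * coefs[["stem"]] / max(coefs[["leaves"]], 1e-9)
    }
    total_demand <- maint + demand_root + demand_leaf + demand_stem
    supply <- photos + budget$carbon_store
    if (supply < total_demand) {
      dr <- draw_seed_reserves(budget, total_demand - supply,
                               ctl$reserve_yield)
      budget <- dr$budget
      supply <- supply + dr$supplied
    }
    maint_paid <- min(maint, supply)
    budget$cumulative_respiration <- budget$cumulative_respiration + maint_paid
    avail_growth <- supply - maint_paid
    alloc <- allocate_carbon(avail_growth, coefs,
                             c(roots = demand_root, stem = demand_stem,
                               leaves = demand_leaf))
    # --- growth ---
    el <- elongate(sys, phenotype, t_now, dt, stress, alloc[["roots"]])
    budget$structural_carbon[["root"]] <-
      budget$structural_carbon[["root"]] + el$carbon_used / over
    branch_laterals(sys, phenotype, t_now)
    if (demand_leaf > 0 && alloc[["leaves"]] > 0) {
      budget$leaf_area <- budget$leaf_area +
        dla_pot * alloc[["leaves"]] / demand_leaf
      budget$structural_carbon[["leaf"]] <-
        budget$structural_carbon[["leaf"]] + alloc[["leaves"]] / over
    }
    if (alloc[["stem"]] > 0) {
      if (!budget$emerged && demand_stem > 0)
        budget$mesocotyl_length <- budget$mesocotyl_length +
          dmeso_pot * alloc[["stem"]] / demand_stem
      budget$structural_carbon[["stem"]] <-
        budget$structural_carbon[["stem"]] + alloc[["stem"]] / over
    }
    growth_c <- el$carbon_used + alloc[["leaves"]] + alloc[["stem"]]
    budget$cumulative_respiration <- budget$cumulative_respiration +
      growth_c * (1 - 1 / over)
    budget$carbon_store <- avail_growth - el$carbon_used -
      alloc[["leaves"]] - alloc[["stem"]]
    # --- emergence / germination ---
    if (!budget$emerged &&
        budget$mesocotyl_length >= phenotype$planting_depth - 1e-9)
      budget$emerged <- TRUE
    if (budget$seed_reserve_remaining <= 1e-9 &&
        budget$cumulative_photosynthate <= 0 &&
        budget$carbon_store <= 1e-12) {
      # all seed carbon spent before any photosynthate was produced: the
      # seedling never establishes
      budget$germination_failed <- TRUE
      failed_stop <- TRUE
    }
    # --- new root length joins the phosphorus cohorts at day boundaries
    # (one radial depletion state per class x layer x day of arrival) ---
    if (abs(t_now - day) < 1e-9) {
      dLEN <- sys$LEN - LEN_prev
      LEN_prev <- sys$LEN
      for (k in 1:6) {
        lay <- which(dLEN[k, ] > 1e-9)
        if (!length(lay)) next
        st <- pstate[[k]]
        st$profiles <- rbind(st$profiles,
                             matrix(conc_p[lay], length(lay), ctl$bc_nodes))
        st$len <- c(st$len, dLEN[k, lay])
        st$layer <- c(st$layer, lay)
        pstate[[k]] <- st
      }
    }
    }
    # --- daily trajectory ---
    if (abs(t_now - day) < 1e-9) {
      traj[[day]] <- data.frame(
        day = day,
        seed_reserve_remaining = budget$seed_reserve_remaining,
        cumulative_photosynthate = budget$cumulative_photosynthate,
        cumulative_respiration = budget$cumulative_respiration,
        root_c = budget$structural_carbon[["root"]],
        stem_c = budget$structural_carbon[["stem"]],
        leaf_c = budget$structural_carbon[["leaf"]],
        carbon_store = budget$carbon_store,
        leaf_area = budget$leaf_area,
        plant_n = budget$plant_n, plant_p = budget$plant_p,
        stress_n = budget$stress_n, stress_p = budget$stress_p,
        shoot_dry_weight = (budget$structural_carbon[["stem"]] +
                              budget$structural_carbon[["leaf"]]) / cfrac,
        root_length = sum(sys$LEN),
        emerged = budget$emerged,
        germination_failed = budget$germination_failed)
    }
  }
  # write out any buffered tip growth so the geometry is complete
  elongate(sys, phenotype, days, dt, 0, 0, flush = TRUE)
  traj <- do.call(rbind, traj[!vapply(traj, is.null, TRUE)])
  structure(list(
    phenotype_name = phenotype$name, seed = seed, days = days,
    trajectory = traj,
    uptake_n = upt_n, uptake_p = upt_p,
    # a seedling that never reached the surface has no shoot: its only
    # above-zero structural carbon is the buried mesocotyl
    shoot_dry_weight = if (budget$emerged)
      (budget$structural_carbon[["stem"]] +
         budget$structural_carbon[["leaf"]]) / cfrac else 0,
    plant_n = budget$plant_n, plant_p = budget$plant_p,
    seed_n = phenotype$seed_nitrogen, seed_p = phenotype$seed_phosphorus,
    budget = budget,
    root_system = if (keep_geometry) sys else NULL,
    max_rooting_depth = if (sys$nseg > 0)
      max(sys$seg[seq_len(sys$nseg), "z1"]) else 0,
    total_root_length = sum(sys$LEN),
    balance = list(
      n_initial = soil$initial_nitrate, n_mineralized = soil$mineralized_n,
      n_remaining = sum(soil$nitrate), n_leached = soil$leached_n,
      n_uptake = sum(upt_n),
      p_initial = soil$initial_p, p_remaining = sum(soil$p_labile),
      p_uptake = sum(upt_p)),
    fingerprint = sprintf("%s|%s|seed%d|days%d", phenotype$name,
                          env$texture$name, seed, days)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %s seed %d: shoot DW %.3f g, N %.0f umol, P %.1f umol, root %.0f cm%s\n",
    x$phenotype_name, x$seed, x$shoot_dry_weight, x$plant_n, x$plant_p,
    x$total_root_length,
    if (x$budget$germination_failed) " [germination failed]" else ""))
  invisible(x)
}

#' Cumulative root-class contributions to nutrient uptake
#'
#' Shares of cumulative nitrogen and phosphorus uptake by root class over
#' time. Laterals are their own stratum, so the seminal-root contribution
#' with and without its laterals can be separated.
#'
#' @param result a [run_simulation()] result.
#' @return `list(n, p)`: 6 x days matrices of cumulative shares (columns
#'   sum to 1 once uptake has occurred; all-`NA` columns flag zero total
#'   uptake), plus `seminal_share_n` / `seminal_share_p`, the day-`days`
#'   share of seminal roots plus their laterals.
#' @export
class_contribution <- function(result) {
  share_of <- function(arr) {
    cum <- apply(arr, c(1, 3), sum)           # class x day
    cum <- t(apply(cum, 1, cumsum))
    tot <- colSums(cum)
    sh <- sweep(cum, 2, tot, "/")
    sh[, tot <= 0] <- NA_real_
    rownames(sh) <- ROOT_CLASSES
    sh
  }
  n <- share_of(result$uptake_n)
  p <- share_of(result$uptake_p)
  last <- ncol(n)
  list(n = n, p = p,
       seminal_share_n = sum(n[c("seminal", "lateral_seminal"), last]),
       seminal_share_p = sum(p[c("seminal", "lateral_seminal"), last]))
}

#' Per-layer uptake by root class up to a given day
#'
#' @param result a [run_simulation()] result.
#' @param day day after planting (<= simulated days).
#' @param nutrient `"n"` or `"p"`.
#' @return 6 x layers matrix of cumulative uptake (umol), rows named by
#'   root class.
#' @export
by_depth_contribution <- function(result, day, nutrient = c("n", "p")) {
  nutrient <- match.arg(nutrient)
  arr <- if (nutrient == "n") result$uptake_n else result$uptake_p
  stopifnot(day >= 1, day <= dim(arr)[3])
  out <- apply(arr[, , 1:day, drop = FALSE], c(1, 2), sum)
  rownames(out) <- ROOT_CLASSES
  out
}
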