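# Experiment runners: seeded replicate sweeps over environments, planting
# densities, seminal root number, and the seminal-root x seed-reserve
# optimization.

# Replicate seeds: base + cell index * stride + replicate index, kept below
# 2^31 so they remain valid R integer seeds.
replicate_seed <- function(base_seed, cell, rep, stride = 1000L) {
  as.integer((as.numeric(base_seed) + as.numeric(cell) * stride + rep) %%
               2147483647)
}

run_reps <- function(phenotype, env, base_seed, cell, reps, days, control,
                     sim_fn, extract) {
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    s <- replicate_seed(base_seed, cell, r)
    res <- sim_fn(phenotype, env, seed = s, days = days, control = control)
    out[[r]] <- cbind(data.frame(replicate = r, rng_seed = s), extract(res))
  }
  do.call(rbind, out)
}

default_extract <- function(res) {
  data.frame(shoot_dry_weight = res$shoot_dry_weight,
             plant_n = res$plant_n, plant_p = res$plant_p,
             net_n_uptake = res$plant_n - res$seed_n,
             net_p_uptake = res$plant_p - res$seed_p,
             total_root_length = res$total_root_length,
             germination_failed = res$budget$germination_failed)
}

light_sim <- function(phenotype, env, seed, days, control) {
  run_simulation(phenotype, env, seed = seed, days = days, control = control,
                 keep_geometry = FALSE)
}

#' Factorial environment sweep
#'
#' Full factorial over nitrate multipliers, rainfall multipliers and soil
#' textures, with seeded replicates per cell. Reports day-`days` plant
#' nitrogen and shoot dry weight per replicate and cell means.
#'
#' @param phenotype a [plant_phenotype()].
#' @param base_env a [soil_environment()] (its texture is replaced per
#'   cell; profiles are kept).
#' @param n_multipliers,rain_multipliers numeric levels (>= 1 each).
#' @param textures character subset of `"silt_loam"`, `"sand"`.
#' @param reps replicates per cell (>= 6 in the study conditions).
#' @param base_seed integer.
#' @param days simulated days.
#' @param control a [sim_control()].
#' @return `list(cells, means)` data.frames; class `sweep_result`.
#' @export
run_env_grid <- function(phenotype, base_env, n_multipliers = 1,
                         rain_multipliers = 1, textures = "silt_loam",
                         reps = 6, base_seed = 1, days = 25,
                         control = sim_control()) {
  stopifnot(length(n_multipliers) >= 1, length(rain_multipliers) >= 1,
            length(textures) >= 1, reps >= 1)
  txs <- fixture_textures()
  grid <- expand.grid(n_multiplier = n_multipliers,
                      rain_multiplier = rain_multipliers,
                      texture = textures, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    env <- base_env
    env$texture <- txs[[grid$texture[i]]]
    env <- scale_environment_nutrients(env, factor_n = grid$n_multiplier[i])
    env <- scale_rainfall(env, grid$rain_multiplier[i])
    cell <- run_reps(phenotype, env, base_seed, i, reps, days, control,
                     light_sim, default_extract)
    rows[[i]] <- cbind(grid[rep(i, nrow(cell)), , drop = FALSE], cell,
                       row.names = NULL)
  }
  cells <- do.call(rbind, rows)
  means <- stats::aggregate(
    cbind(shoot_dry_weight, plant_n, net_n_uptake) ~
      n_multiplier + rain_multiplier + texture, cells, mean)
  structure(list(cells = cells, means = means, reps = reps),
            class = "sweep_result")
}

#' Planting-density sweep
#'
#' Row spacing is held at the commercial value and in-row spacing follows
#' from density; the per-plant soil prism and ground area shrink
#' accordingly. Also computes nearest-neighbour root distance CDFs with
#' and without seminal roots at a reference density, under nutrient
#' multipliers high enough that no nutrient stress occurs (so allometry
#' does not confound the geometry).
#'
#' @param phenotype a [plant_phenotype()].
#' @param env a [soil_environment()].
#' @param densities plants ha^-1.
#' @param reps replicates per density.
#' @param base_seed integer.
#' @param days simulated days.
#' @param control a [sim_control()].
#' @param cdf_density density for the neighbour-distance CDFs (default
#'   74100 plants ha^-1, near commercial).
#' @param cdf_samples segment midpoints sampled per CDF.
#' @return `list(cells, means, cdf_with, cdf_without)`; class
#'   `sweep_result`.
#' @export
run_density_sweep <- function(phenotype, env, densities, reps = 6,
                              base_seed = 1, days = 25,
                              control = sim_control(),
                              cdf_density = 74100, cdf_samples = 300) {
  stopifnot(all(densities > 0), reps >= 1)
  rows <- vector("list", length(densities))
  for (i in seq_along(densities)) {
    denv <- density_environment(env, densities[i])
    cell <- run_reps(phenotype, denv, base_seed, i, reps, days, control,
                     light_sim, default_extract)
    rows[[i]] <- cbind(data.frame(density = densities[i],
                                  in_row_spacing = denv$in_row_spacing),
                       cell, row.names = NULL)
  }
  cells <- do.call(rbind, rows)
  means <- stats::aggregate(
    cbind(shoot_dry_weight, plant_n, net_n_uptake) ~ density, cells, mean)
  # geometry-only neighbour CDFs at the reference density, unstressed
  spacing <- density_to_spacing(cdf_density, env$row_spacing)
  genv <- density_environment(env, cdf_density)
  genv <- scale_environment_nutrients(genv, 50, 50)
  offset <- c(0, spacing, 0)
  with_res <- run_simulation(phenotype, genv, seed = base_seed + 101,
                             days = days, control = control)
  without <- override_phenotype(phenotype, seminal_root_number = 0L)
  without_res <- run_simulation(without, genv, seed = base_seed + 101,
                                days = days, control = control)
  cdf_with <- nearest_neighbour_distances(with_res$root_system, offset,
                                          cdf_samples)
  cdf_without <- nearest_neighbour_distances(without_res$root_system, offset,
                                             cdf_samples)
  structure(list(cells = cells, means = means, cdf_with = cdf_with,
                 cdf_without = cdf_without, reps = reps),
            class = "sweep_result")
}

# Internal: shrink the per-plant prism to the in-row spacing of a density.
density_environment <- function(env, density) {
  spacing <- density_to_spacing(density, env$row_spacing)
  env$in_row_spacing <- spacing
  env$prism[["length"]] <- spacing
  env
}

#' Seminal-root-number sweep
#'
#' Clones the phenotype per level with the seminal root number overridden
#' and reports day-`days` nutrient uptake and shoot dry weight per cell.
#'
#' @param phenotype a [plant_phenotype()].
#' @param env a [soil_environment()].
#' @param srn_levels integer levels (>= 0).
#' @param reps replicates per level.
#' @param base_seed integer.
#' @param days simulated days.
#' @param control a [sim_control()].
#' @return `list(cells, means)`; class `sweep_result`.
#' @export
run_srn_sweep <- function(phenotype, env, srn_levels = 0:8, reps = 6,
                          base_seed = 1, days = 25,
                          control = sim_control()) {
  stopifnot(all(srn_levels >= 0), all(srn_levels == round(srn_levels)))
  rows <- vector("list", length(srn_levels))
  for (i in seq_along(srn_levels)) {
    ph <- override_phenotype(phenotype,
                             seminal_root_number = srn_levels[i])
    cell <- run_reps(ph, env, base_seed, i, reps, days, control,
                     light_sim, default_extract)
    rows[[i]] <- cbind(data.frame(seminal_root_number = srn_levels[i]),
                       cell, row.names = NULL)
  }
  cells <- do.call(rbind, rows)
  means <- stats::aggregate(
    cbind(shoot_dry_weight, plant_n, plant_p, net_n_uptake, net_p_uptake) ~
      seminal_root_number, cells, mean)
  structure(list(cells = cells, means = means, reps = reps),
            class = "sweep_result")
}

#' Pick the optimal seminal root number from cell means
#'
#' Cell-mean shoot dry weights are rounded to six decimal places (grams);
#' the smallest seminal root number attaining the rounded maximum wins, so
#' differences below a microgram-scale resolution never justify an extra
#' seminal root. Fully deterministic.
#'
#' @param cell_means named numeric vector: mean shoot dry weight (g) by
#'   seminal root number (names are the SRN levels).
#' @return The optimal seminal root number (integer).
#' @export
select_optimum <- function(cell_means) {
  if (!length(cell_means)) stop("empty cell-mean table")
  srn <- as.integer(names(cell_means))
  if (anyNA(srn)) stop("cell_means must be named by seminal root number")
  rounded <- round(as.numeric(cell_means), 6)
  best <- max(rounded)
  min(srn[rounded == best])
}

#' Optimize seminal root number against seed carbohydrate reserves
#'
#' Runs the full grid of seminal root number by seed mass, with the seed
#' carbohydrate fraction held at 0.7112 and seed nitrogen and phosphorus
#' fixed at the base phenotype's values, and selects the growth-maximizing
#' seminal root number per seed mass via [select_optimum()].
#'
#' @param phenotype base [plant_phenotype()] (the landrace).
#' @param env a [soil_environment()].
#' @param srn_range integer levels, default `0:8`.
#' @param seed_masses mg, default `seq(10, 150, by = 2.5)`.
#' @param reps replicates per cell, default 20.
#' @param base_seed integer.
#' @param days simulated days.
#' @param control a [sim_control()].
#' @param carbohydrate_fraction held constant across the grid.
#' @param sim_fn simulator to use (signature of [run_simulation()]);
#'   injectable so the selection pipeline can be validated against a stub
#'   response surface.
#' @return `list(grid, optimum)`: `grid` has one row per (seed mass, SRN)
#'   cell with the mean shoot dry weight; `optimum` has one row per seed
#'   mass with the optimal SRN and the corresponding carbohydrate reserve
#'   (mg).
#' @export
optimize_srn <- function(phenotype, env, srn_range = 0:8,
                         seed_masses = seq(10, 150, by = 2.5), reps = 20,
                         base_seed = 1, days = 25, control = sim_control(),
                         carbohydrate_fraction = 0.7112, sim_fn = NULL) {
  stopifnot(length(srn_range) >= 1, length(seed_masses) >= 1, reps >= 1)
  if (is.null(sim_fn)) sim_fn <- light_sim
  grid <- expand.grid(seed_mass = seed_masses, srn = as.integer(srn_range))
  mean_dw <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ph <- override_phenotype(phenotype,
                             seed_mass = grid$seed_mass[i],
                             carbohydrate_fraction = carbohydrate_fraction,
                             seminal_root_number = grid$srn[i])
    dws <- numeric(reps)
    for (r in seq_len(reps)) {
      s <- replicate_seed(base_seed, i, r)
      dws[r] <- sim_fn(ph, env, seed = s, days = days,
                       control = control)$shoot_dry_weight
    }
    mean_dw[i] <- mean(dws)
  }
  grid$mean_shoot_dry_weight <- mean_dw
  opt <- do.call(rbind, lapply(seed_masses, function(m) {
    sub <- grid[grid$seed_mass == m, ]
    cm <- stats::setNames(sub$mean_shoot_dry_weight, sub$srn)
    data.frame(seed_mass = m,
               carbohydrate_reserve =
                 seed_carbohydrate_reserve(m, carbohydrate_fraction),
               optimal_srn = select_optimum(cm))
  }))
  list(grid = grid, optimum = opt)
}

#' Smallest seed carbohydrate reserve that favours seminal roots
#'
#' From an [optimize_srn()] optimum table, the smallest carbohydrate
#' reserve (mg) at which the growth-maximizing seminal root number first
#' exceeds zero.
#'
#' @param optimum the `optimum` data.frame from [optimize_srn()].
#' @return Reserve in mg carbohydrate (`NA` if the optimum never leaves 0).
#' @export
reserve_threshold <- function(optimum) {
  pos <- optimum$carbohydrate_reserve[optimum$optimal_srn > 0]
  if (!length(pos)) return(NA_real_)
  min(pos)
}
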