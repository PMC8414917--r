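# Synthetic fixtures: every input the pipeline needs, generated in code.
#
# The printed contrasts between the maize landrace and the teosinte
# accession (seed mass ~280 vs ~30 mg, landrace carbohydrate fraction
# 0.7112, teosinte typically without seminal roots, nodal whorl emergence at
# 7 d) anchor the parameter sets; everything not printed is a documented
# literature default or free calibration value. Each numeric default
# carries exactly one provenance label in the fixture manifest.

#' Simulation control settings
#'
#' Numerical and physiological constants of the coupled simulation that are
#' not part of the heritable phenotype or the environment: time step, light
#' and carbon-conversion constants, stress-response shape, root trajectory
#' noise, uptake kinetics and solver resolution. Defaults are the
#' calibrated study conditions; each is documented in the fixture manifest.
#'
#' @param dt coupling time step, days.
#' @param carbon_fraction g C per g dry weight of structural tissue.
#' @param growth_overhead growth respiration factor on construction carbon.
#' @param reserve_yield g C available per g seed carbohydrate.
#' @param sla specific leaf area, cm^2 per g leaf DW.
#' @param par photosynthetically active radiation, umol m^-2 s^-1.
#' @param photoperiod h of light per day.
#' @param lue light-use efficiency, g C per mol intercepted photons.
#' @param k_light canopy extinction coefficient.
#' @param shoot_maintenance shoot maintenance respiration, g C (g shoot C)^-1 d^-1.
#' @param stress_floor minimum nutrient stress factor.
#' @param deflection_sd per-segment random heading deflection (component sd).
#' @param angle_jitter_deg sd of the insertion-angle jitter, degrees.
#' @param gravitropism per-class downward pull added to the heading
#'   (primary, seminal, nodal, and the three lateral classes).
#' @param emit_min segment emission resolution, cm: growth is buffered per
#'   tip and written out as segments of at least this length (and at most
#'   1 cm).
#' @param apical_zone apical non-branching zone, cm.
#' @param crown_depth depth of the nodal (crown) whorls, cm.
#' @param n_imax,n_km nitrate uptake kinetics, umol cm^-2 d^-1 and
#'   umol cm^-3.
#' @param p_imax,p_km,p_cmin phosphorus influx kinetics (same units).
#' @param p_rx outer no-flux radius of the depletion annulus, cm.
#' @param p_v0 inward water flux at the root surface, cm d^-1.
#' @param mineralization_k0,mineralization_s rate constant (d^-1) and aging
#'   exponent of organic-N mineralization.
#' @param bc_nodes,bc_nsub radial grid nodes and sub-steps of the
#'   phosphorus solver.
#' @return A list of class `sim_control`.
#' @export
sim_control <- function(dt = 0.25,
                        carbon_fraction = 0.45,
                        growth_overhead = 1.3,
                        reserve_yield = 0.42,
                        sla = 330,
                        par = 600,
                        photoperiod = 14,
                        lue = 0.5,
                        k_light = 0.6,
                        shoot_maintenance = 0.015,
                        stress_floor = 0.1,
                        deflection_sd = 0.09,
                        angle_jitter_deg = 5,
                        gravitropism = c(0.5, 0.08, 0.08, 0.02, 0.02, 0.02),
                        emit_min = 0.5,
                        apical_zone = 2,
                        crown_depth = 2,
                        n_imax = 12, n_km = 30,
                        p_imax = 2.2, p_km = 0.02, p_cmin = 1e-5,
                        p_rx = 0.6, p_v0 = 0.02,
                        mineralization_k0 = 0.012, mineralization_s = 0.5,
                        bc_nodes = 14, bc_nsub = 2) {
  ctl <- as.list(environment())
  stopifnot(ctl$dt > 0, ctl$carbon_fraction > 0, ctl$growth_overhead >= 1,
            ctl$reserve_yield > 0, length(ctl$gravitropism) == 6)
  class(ctl) <- "sim_control"
  ctl
}

fixture_entry <- function(field, value, provenance) {
  data.frame(field = field, value = as.character(value),
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Generate the phenotype fixture for the landrace or teosinte
#'
#' Builds the full [plant_phenotype()] for the Midwestern dent landrace or
#' the teosinte accession, together with a manifest labelling the
#' provenance of every numeric default: `printed-in-paper` (seed masses,
#' landrace carbohydrate fraction, whorl emergence at 7 d, teosinte without
#' seminal roots), `derived-from-paper` (teosinte carbohydrate fraction
#' 0.7112/1.34 = 0.531, from the landrace value and the reported 34 %
#' carbohydrate excess of landrace over teosinte kernels),
#' `literature-default`, or `free-calibration`.
#'
#' @param which `"landrace"` or `"teosinte"`.
#' @return `list(phenotype, manifest)`.
#' @export
make_phenotype_fixture <- function(which = c("landrace", "teosinte")) {
  which <- match.arg(which)
  man <- list()
  note <- function(field, value, prov)
    man[[length(man) + 1L]] <<- fixture_entry(field, value, prov)

  if (which == "landrace") {
    seed_mass <- 280; note("seed_mass", 280, "printed-in-paper")
    carb <- 0.7112; note("carbohydrate_fraction", 0.7112, "printed-in-paper")
    seed_n <- 190; note("seed_nitrogen", 190, "free-calibration")
    seed_p <- 11; note("seed_phosphorus", 11, "free-calibration")
    srn <- 4L; note("seminal_root_number", 4, "literature-default")
    whorls <- data.frame(emergence_day = c(7, 12), roots_per_whorl = c(5L, 6L))
    note("nodal_whorls.emergence_day[1]", 7, "printed-in-paper")
    note("nodal_whorls.emergence_day[2]", 12, "free-calibration")
    note("nodal_whorls.roots_per_whorl", "5,6", "free-calibration")
    meso_rate <- 1.5; meso_diam <- 0.15
    note("mesocotyl_rate", 1.5, "free-calibration")
    note("mesocotyl_diameter", 0.15, "literature-default")
    la_rate <- rate_function(1.7, 0)
    note("leaf_area_expansion_rate.slope", 1.7, "free-calibration")
    ax_rate <- c(primary = 3.0, seminal = 2.4, nodal = 3.4)
    lat_rate <- 0.6
    diam <- c(primary = 0.09, seminal = 0.06, nodal = 0.10,
              lateral_primary = 0.03, lateral_seminal = 0.025,
              lateral_nodal = 0.03)
    bfreq <- c(1.5, 2.5)
    angle <- c(primary = 0, seminal = 50, nodal = 40, lateral = 75)
    lat_max <- 4
  } else {
    seed_mass <- 30; note("seed_mass", 30, "printed-in-paper")
    carb <- 0.7112 / 1.34; note("carbohydrate_fraction", round(carb, 4),
                                "derived-from-paper")
    seed_n <- 35; note("seed_nitrogen", 35, "free-calibration")
    seed_p <- 1.5; note("seed_phosphorus", 1.5, "free-calibration")
    srn <- 0L; note("seminal_root_number", 0, "printed-in-paper")
    whorls <- data.frame(emergence_day = c(7, 12), roots_per_whorl = c(2L, 2L))
    note("nodal_whorls.emergence_day[1]", 7, "printed-in-paper")
    note("nodal_whorls.emergence_day[2]", 12, "free-calibration")
    note("nodal_whorls.roots_per_whorl", "2,2", "free-calibration")
    meso_rate <- 0.7; meso_diam <- 0.10
    note("mesocotyl_rate", 0.7, "free-calibration")
    note("mesocotyl_diameter", 0.10, "literature-default")
    la_rate <- rate_function(0.55, 0)
    note("leaf_area_expansion_rate.slope", 0.55, "free-calibration")
    ax_rate <- c(primary = 2.0, seminal = 2.4, nodal = 2.2)
    lat_rate <- 0.45
    # seminal class parameters mirror the landrace: seminal roots were too
    # rare in teosinte to parameterize, so the landrace values are reused
    # for what-if simulations.
    diam <- c(primary = 0.07, seminal = 0.06, nodal = 0.08,
              lateral_primary = 0.025, lateral_seminal = 0.025,
              lateral_nodal = 0.025)
    bfreq <- c(1.2, 2.2)
    angle <- c(primary = 0, seminal = 50, nodal = 40, lateral = 75)
    lat_max <- 3
  }
  note("axial_elongation_rates", paste(ax_rate, collapse = ","),
       "free-calibration")
  note("lateral_elongation_rate", lat_rate, "free-calibration")
  note("root_diameters", paste(diam, collapse = ","), "literature-default")
  note("branching_frequency_range", paste(bfreq, collapse = "-"),
       "literature-default")
  note("branch_angles", paste(angle, collapse = ","), "literature-default")
  note("lateral_max_length", lat_max, "free-calibration")
  note("tissue_density", 0.08, "literature-default")
  note("respiration_rate", 0.005, "literature-default")
  note("allocation_coefficients", "0.35,0.25,0.40", "literature-default")
  note("optimal_tissue_conc.root", "n=1200,p=45", "free-calibration")
  note("optimal_tissue_conc.shoot", "n=2000,p=55", "free-calibration")
  note("seminal_emergence_day", 1.5, "literature-default")

  rc <- function(cls, emerg, rate, ang, bf, d, maxlen = Inf)
    root_class_params(cls, emerg, rate_function(0, rate), ang, bf, d,
                      tissue_density = 0.08, respiration_rate = 0.005,
                      max_length = maxlen)
  classes <- list(
    primary = rc("primary", 0, ax_rate[["primary"]], angle[["primary"]],
                 bfreq, diam[["primary"]]),
    seminal = rc("seminal", 1.5, ax_rate[["seminal"]], angle[["seminal"]],
                 bfreq, diam[["seminal"]]),
    nodal = rc("nodal", 7, ax_rate[["nodal"]], angle[["nodal"]], bfreq,
               diam[["nodal"]]),
    lateral_primary = rc("lateral_primary", 0, lat_rate, angle[["lateral"]],
                         c(0, 0), diam[["lateral_primary"]], lat_max),
    lateral_seminal = rc("lateral_seminal", 0, lat_rate, angle[["lateral"]],
                         c(0, 0), diam[["lateral_seminal"]], lat_max),
    lateral_nodal = rc("lateral_nodal", 0, lat_rate, angle[["lateral"]],
                       c(0, 0), diam[["lateral_nodal"]], lat_max))
  phen <- plant_phenotype(
    name = which, seed_mass = seed_mass, carbohydrate_fraction = carb,
    seed_nitrogen = seed_n, seed_phosphorus = seed_p,
    seminal_root_number = srn, nodal_whorls = whorls,
    mesocotyl_rate = meso_rate, mesocotyl_diameter = meso_diam,
    planting_depth = 3,
    leaf_area_expansion_rate = la_rate,
    root_classes = classes,
    allocation_coefficients = c(roots = 0.35, stem = 0.25, leaves = 0.40),
    optimal_tissue_conc = list(root = c(n = 1200, p = 45),
                               shoot = c(n = 2000, p = 55)))
  list(phenotype = phen, manifest = do.call(rbind, man))
}

#' Generate a daily rainfall series
#'
#' A stand-in for a measured season. The default (`stochastic = FALSE`) is
#' a fixed "design season": wet days evenly spaced at frequency `wet_prob`
#' with depths taken from the quantiles of an exponential distribution with
#' mean `mean_depth`, rescaled so the season total equals its expectation
#' (`n_days * wet_prob * mean_depth`). Like the single measured record the
#' study environments share, this series is identical across model
#' replicates, so run-to-run stochasticity comes from the plant, not the
#' weather. `stochastic = TRUE` draws a random season from the same
#' marginal model (wet-day probability and exponential depths) using the
#' session RNG, for weather-variability studies.
#'
#' @param n_days length of the series.
#' @param wet_prob probability (or fixed frequency) of wet days.
#' @param mean_depth mean wet-day rainfall, mm (default 10).
#' @param stochastic draw a random season instead of the design season.
#' @return Numeric series, mm d^-1.
#' @export
make_rainfall_series <- function(n_days = 30, wet_prob = 0.3,
                                 mean_depth = 10, stochastic = FALSE) {
  if (stochastic) {
    wet <- stats::runif(n_days) < wet_prob
    depth <- stats::rexp(n_days, 1 / mean_depth)
    return(ifelse(wet, depth, 0))
  }
  n_wet <- max(1L, round(n_days * wet_prob))
  # wet days grouped into multi-day storms, as in frontal precipitation;
  # storm anchors are spread through the season
  n_storms <- max(1L, ceiling(n_wet / 2.5))
  anchors <- round(seq(3, n_days - 2, length.out = n_storms))
  days <- integer(0)
  i <- 0L
  while (length(days) < n_wet) {
    days <- unique(c(days, pmin(anchors + i %/% n_storms, n_days)))
    i <- i + n_storms
  }
  days <- sort(days[seq_len(n_wet)])
  q <- stats::qexp(seq(0.15, 0.92, length.out = n_wet), 1 / mean_depth)
  # largest depths on the storm anchor days, rescaled to the expected total
  depths <- numeric(n_wet)
  depths[order(!(days %in% anchors), days)] <- sort(q, decreasing = TRUE)
  depths <- depths * (n_days * wet_prob * mean_depth) / sum(depths)
  rain <- numeric(n_days)
  rain[days] <- depths
  rain
}

# The two textural parameterizations. Hydraulics are literature defaults
# for a silt loam and a sand; P sorption differs strongly between them.
fixture_textures <- function() {
  list(
    silt_loam = soil_texture("silt_loam", bulk_density = 1.3,
                             field_capacity = 0.33, wilting_point = 0.12,
                             saturated_conductivity = 50, dispersivity = 2,
                             p_buffer_power = 150,
                             p_diffusion_coefficient = 0.12),
    sand = soil_texture("sand", bulk_density = 1.55,
                        field_capacity = 0.12, wilting_point = 0.04,
                        saturated_conductivity = 200, dispersivity = 1,
                        p_buffer_power = 60,
                        p_diffusion_coefficient = 0.18))
}

# Unit bridges: 1 umol N cm^-2 of column = 1.4 kg N ha^-1;
# 1 umol P cm^-2 = 3.1 kg P ha^-1.
KG_HA_PER_UMOL_CM2_N <- 1.4
KG_HA_PER_UMOL_CM2_P <- 3.1

#' Generate an environment fixture
#'
#' Builds a [soil_environment()] with a surface-concentrated initial
#' nitrate profile (exponential with e-folding depth `z0_n`), an
#' organic-matter N pool concentrated in the topsoil, a top-concentrated
#' labile phosphorus profile, and a seeded stochastic rainfall series. The
#' nitrate profile is scaled so the 150-cm column integrates to `n_target`
#' kg N ha^-1 of available nitrate; phosphorus likewise to `p_target`
#' kg P ha^-1 of labile P.
#'
#' @param texture `"silt_loam"` or `"sand"`.
#' @param n_target available nitrate, kg N ha^-1.
#' @param p_target labile phosphorus, kg P ha^-1.
#' @param season_days length of the rainfall series.
#' @param depth column depth, cm (1-cm layers).
#' @param z0_n e-folding depth of the nitrate profile, cm.
#' @param om_target organic-matter N pool, kg N ha^-1 (defaults to
#'   `n_target`).
#' @return `list(environment, manifest)`.
#' @export
make_environment_fixture <- function(texture = c("silt_loam", "sand"),
                                     n_target = 50, p_target = 2,
                                     season_days = 30, depth = 150,
                                     z0_n = 20, om_target = n_target) {
  texture <- match.arg(texture)
  stopifnot(n_target >= 0, p_target >= 0, om_target >= 0)
  tx <- fixture_textures()[[texture]]
  z <- seq_len(depth) - 0.5
  shape_n <- exp(-z / z0_n)
  # nitrate: umol cm^-3 solution such that sum(conc * theta_fc * 1 cm)
  # equals the kg/ha target
  target_umol_cm2 <- n_target / KG_HA_PER_UMOL_CM2_N
  denom <- sum(shape_n * tx$field_capacity)
  conc_n <- if (target_umol_cm2 > 0) shape_n * target_umol_cm2 / denom
            else shape_n * 0
  # organic N: umol cm^-3 soil, concentrated in the top 30 cm
  shape_om <- exp(-z / 10) * (z < 30)
  om_umol_cm2 <- om_target / KG_HA_PER_UMOL_CM2_N
  om <- if (om_umol_cm2 > 0) shape_om * om_umol_cm2 / sum(shape_om)
        else shape_om * 0
  # labile P: solution umol cm^-3 such that sum(conc * b * 1 cm) hits the
  # kg/ha target; P is concentrated in the plough layer
  shape_p <- exp(-z / 15)
  p_umol_cm2 <- p_target / KG_HA_PER_UMOL_CM2_P
  conc_p <- if (p_umol_cm2 > 0) shape_p * p_umol_cm2 /
              sum(shape_p * tx$p_buffer_power)
            else shape_p * 0
  rain <- make_rainfall_series(season_days)
  env <- soil_environment(
    texture = tx, rainfall = rain,
    initial_nitrate_profile = conc_n,
    organic_matter_n_profile = om,
    initial_p_profile = conc_p,
    prism = c(width = 60, length = 26, depth = depth),
    row_spacing = 76.2, in_row_spacing = 26,
    evaporation_rate = 2)
  man <- rbind(
    fixture_entry("prism", "60x26x150", "printed-in-paper"),
    fixture_entry("n_target", n_target, "printed-in-paper"),
    fixture_entry("p_target", p_target, "printed-in-paper"),
    fixture_entry("z0_n", z0_n, "free-calibration"),
    fixture_entry("om_target", om_target, "free-calibration"),
    fixture_entry("rainfall_generator", "design season: wet_prob=0.3, mean=10mm, storm-clustered",
                  "free-calibration"),
    fixture_entry("texture_hydraulics", texture, "literature-default"),
    fixture_entry("row_spacing", 76.2, "printed-in-paper"),
    fixture_entry("evaporation_rate", 2, "literature-default"))
  list(environment = env, manifest = man)
}

#' Build the three composite phenotypes of the trait-swap experiment
#'
#' (1) the landrace given the teosinte root and shoot growth rates, (2)
#' teosinte given the landrace seed nitrogen and phosphorus, and (3)
#' teosinte given the landrace seed carbohydrate reserves (seed mass and
#' carbohydrate fraction). Built with [make_composite_phenotype()]; the
#' growth-rate swap replaces the leaf-area expansion rate and every root
#' class's elongation rate while keeping the landrace architecture,
#' diameters and seed.
#'
#' @param landrace,teosinte phenotypes from [make_phenotype_fixture()]
#'   (regenerated when omitted).
#' @return Named list of three [plant_phenotype()] objects.
#' @export
make_composite_fixtures <- function(landrace = NULL, teosinte = NULL) {
  if (is.null(landrace)) landrace <- make_phenotype_fixture("landrace")$phenotype
  if (is.null(teosinte)) teosinte <- make_phenotype_fixture("teosinte")$phenotype
  # 1: landrace with teosinte growth rates
  c1 <- make_composite_phenotype(landrace, teosinte,
                                 "leaf_area_expansion_rate")
  for (cl in names(c1$root_classes))
    c1$root_classes[[cl]]$elongation_rate <-
      teosinte$root_classes[[cl]]$elongation_rate
  c1$name <- "landrace_teosinte_rates"
  # 2: teosinte with landrace seed N and P
  c2 <- make_composite_phenotype(teosinte, landrace,
                                 c("seed_nitrogen", "seed_phosphorus"))
  c2$name <- "teosinte_landrace_seedNP"
  # 3: teosinte with landrace carbohydrate reserves
  c3 <- make_composite_phenotype(teosinte, landrace,
                                 c("seed_mass", "carbohydrate_fraction"))
  c3$name <- "teosinte_landrace_reserves"
  list(landrace_teosinte_rates = c1,
       teosinte_landrace_seedNP = c2,
       teosinte_landrace_reserves = c3)
}

#' Write all fixtures to a directory
#'
#' Emits the landrace and teosinte phenotype configs, both texture
#' environments, the rainfall CSV and the fixture manifests. Deterministic
#' under a fixed seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed RNG seed for the rainfall series.
#' @return `out_dir`, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  for (g in c("landrace", "teosinte")) {
    fx <- make_phenotype_fixture(g)
    write_phenotype_config(fx$phenotype,
                           file.path(out_dir, paste0(g, ".yml")))
    utils::write.csv(fx$manifest,
                     file.path(out_dir, paste0(g, "_manifest.csv")),
                     row.names = FALSE)
  }
  for (tx in c("silt_loam", "sand")) {
    fx <- make_environment_fixture(tx)
    write_environment_config(fx$environment,
                             file.path(out_dir, paste0("env_", tx, ".yml")))
    utils::write.csv(fx$manifest,
                     file.path(out_dir, paste0("env_", tx, "_manifest.csv")),
                     row.names = FALSE)
    write_rainfall_csv(fx$environment$rainfall,
                       file.path(out_dir, paste0("rain_", tx, ".csv")))
  }
  invisible(out_dir)
}
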