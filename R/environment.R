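#' Soil texture parameters
#'
#' Hydraulic and sorption parameters for one textural class. Two
#' parameterizations are used in the experiments: a silt loam and a sand,
#' which differ in bulk density, water retention and dispersivity.
#'
#' @param name label, e.g. `"silt_loam"` or `"sand"`.
#' @param bulk_density g cm^-3.
#' @param field_capacity,wilting_point volumetric water fractions,
#'   `0 < wilting_point < field_capacity < 1`.
#' @param saturated_conductivity cm d^-1 (caps the tipping-bucket drainage
#'   rate).
#' @param dispersivity cm; hydrodynamic dispersion is `dispersivity * |flux|`.
#' @param p_buffer_power dimensionless ratio of labile to solution-phase
#'   phosphorus.
#' @param p_diffusion_coefficient effective P diffusion coefficient,
#'   cm^2 d^-1.
#' @return Object of class `soil_texture`.
#' @export
soil_texture <- function(name, bulk_density, field_capacity, wilting_point,
                         saturated_conductivity, dispersivity,
                         p_buffer_power, p_diffusion_coefficient) {
  stopifnot(bulk_density > 0, saturated_conductivity > 0, dispersivity >= 0,
            p_buffer_power > 0, p_diffusion_coefficient > 0)
  if (!(wilting_point > 0 && wilting_point < field_capacity &&
        field_capacity < 1))
    stop("need 0 < wilting_point < field_capacity < 1")
  structure(list(name = name, bulk_density = bulk_density,
                 field_capacity = field_capacity,
                 wilting_point = wilting_point,
                 saturated_conductivity = saturated_conductivity,
                 dispersivity = dispersivity,
                 p_buffer_power = p_buffer_power,
                 p_diffusion_coefficient = p_diffusion_coefficient),
            class = "soil_texture")
}

#' A simulated growth environment
#'
#' One plant's resource environment: a rectangular soil prism (default
#' 60 x 26 x 150 cm) discretized into 1-cm layers, with initial nitrate,
#' organic-matter nitrogen and labile phosphorus profiles, a daily rainfall
#' series, and the planting geometry that sets the per-plant ground area.
#' Nutrient and rainfall multipliers implement the fertilization and
#' precipitation treatments.
#'
#' @param texture a [soil_texture()].
#' @param rainfall daily rainfall series, mm d^-1 (recycled to the run
#'   length if shorter).
#' @param initial_nitrate_profile per-layer nitrate concentration in soil
#'   solution, umol cm^-3.
#' @param organic_matter_n_profile per-layer mineralizable organic N,
#'   umol N cm^-3 soil.
#' @param initial_p_profile per-layer solution P concentration, umol cm^-3.
#' @param rainfall_multiplier,nutrient_multiplier_n,nutrient_multiplier_p
#'   non-negative treatment scalars.
#' @param prism named vector `c(width = , length = , depth = )`, cm; depth
#'   must equal the profile length (1-cm layers).
#' @param row_spacing,in_row_spacing planting geometry, cm.
#' @param evaporation_rate surface evaporation, mm d^-1.
#' @return Object of class `soil_environment`.
#' @export
soil_environment <- function(texture, rainfall, initial_nitrate_profile,
                             organic_matter_n_profile, initial_p_profile,
                             rainfall_multiplier = 1,
                             nutrient_multiplier_n = 1,
                             nutrient_multiplier_p = 1,
                             prism = c(width = 60, length = 26, depth = 150),
                             row_spacing = 76.2, in_row_spacing = 26,
                             evaporation_rate = 2) {
  stopifnot(inherits(texture, "soil_texture"),
            rainfall_multiplier >= 0, nutrient_multiplier_n >= 0,
            nutrient_multiplier_p >= 0, row_spacing > 0, in_row_spacing > 0,
            evaporation_rate >= 0)
  nl <- length(initial_nitrate_profile)
  if (length(organic_matter_n_profile) != nl ||
      length(initial_p_profile) != nl)
    stop("all profiles must have the same number of 1-cm layers")
  if (abs(prism[["depth"]] - nl) > 1e-9)
    stop("prism depth must equal number of layers x 1 cm")
  if (any(initial_nitrate_profile < 0) || any(organic_matter_n_profile < 0) ||
      any(initial_p_profile < 0) || any(rainfall < 0))
    stop("profiles and rainfall must be non-negative")
  structure(list(texture = texture, rainfall = as.numeric(rainfall),
                 rainfall_multiplier = rainfall_multiplier,
                 initial_nitrate_profile = as.numeric(initial_nitrate_profile),
                 organic_matter_n_profile = as.numeric(organic_matter_n_profile),
                 initial_p_profile = as.numeric(initial_p_profile),
                 nutrient_multiplier_n = nutrient_multiplier_n,
                 nutrient_multiplier_p = nutrient_multiplier_p,
                 prism = prism[c("width", "length", "depth")],
                 row_spacing = row_spacing, in_row_spacing = in_row_spacing,
                 evaporation_rate = evaporation_rate),
            class = "soil_environment")
}

#' @export
print.soil_environment <- function(x, ...) {
  cat(sprintf(
    "<soil_environment> %s, prism %g x %g x %g cm, multipliers N=%g P=%g rain=%g\n",
    x$texture$name, x$prism[["width"]], x$prism[["length"]],
    x$prism[["depth"]], x$nutrient_multiplier_n, x$nutrient_multiplier_p,
    x$rainfall_multiplier))
  invisible(x)
}

#' Scale the nutrient endowment of an environment
#'
#' Fertilization treatments multiply the initial nitrate and organic-matter
#' nitrogen profiles by `factor_n`, and the labile phosphorus profile by
#' `factor_p`, at every depth. Texture and rainfall are untouched.
#'
#' @param env a [soil_environment()].
#' @param factor_n,factor_p non-negative scalars.
#' @return A new environment with scaled profiles.
#' @export
scale_environment_nutrients <- function(env, factor_n = 1, factor_p = 1) {
  stopifnot(inherits(env, "soil_environment"))
  if (factor_n < 0 || factor_p < 0) stop("nutrient factors must be >= 0")
  env$initial_nitrate_profile <- env$initial_nitrate_profile * factor_n
  env$organic_matter_n_profile <- env$organic_matter_n_profile * factor_n
  env$initial_p_profile <- env$initial_p_profile * factor_p
  env
}

#' Scale the rainfall series of an environment
#'
#' Precipitation treatments multiply the measured daily rainfall by a
#' constant.
#'
#' @param env a [soil_environment()].
#' @param multiplier non-negative scalar.
#' @return A new environment with the scaled daily series.
#' @export
scale_rainfall <- function(env, multiplier) {
  stopifnot(inherits(env, "soil_environment"))
  if (multiplier < 0) stop("rainfall multiplier must be >= 0")
  env$rainfall <- env$rainfall * multiplier
  env
}

#' Convert planting density to in-row spacing
#'
#' Density treatments keep the commercial row spacing fixed and vary the
#' in-row spacing: `in_row = 1e8 / (row_spacing * density)` with density in
#' plants ha^-1 and spacings in cm (1 ha = 1e8 cm^2).
#'
#' @param density plants ha^-1 (> 0).
#' @param row_spacing cm (> 0), default the commercial 76.2 cm.
#' @return In-row spacing, cm.
#' @export
density_to_spacing <- function(density, row_spacing = 76.2) {
  if (any(density <= 0) || any(row_spacing <= 0))
    stop("density and row_spacing must be > 0")
  1e8 / (row_spacing * density)
}

#' @rdname density_to_spacing
#' @param in_row_spacing cm (> 0).
#' @export
spacing_to_density <- function(in_row_spacing, row_spacing = 76.2) {
  if (any(in_row_spacing <= 0) || any(row_spacing <= 0))
    stop("spacings must be > 0")
  1e8 / (row_spacing * in_row_spacing)
}

# Internal: per-plant ground area (cm^2) used to scope the soil column.
ground_area <- function(env) {
  unname(env$prism[["width"]] * env$prism[["length"]])
}
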