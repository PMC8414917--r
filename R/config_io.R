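# Structured-text configuration for phenotypes and environments.
#
# Numbers are serialized as "%.17g" strings so that a write/read round trip
# reproduces every double bit-identically (YAML's default float printing
# would truncate). A `units:` mapping in each file documents the units of
# every field.

num_out <- function(x) vapply(x, function(v) sprintf("%.17g", v), "")
num_in <- function(x) as.numeric(x)

rate_out <- function(r) list(kind = r$kind, slope = num_out(r$slope),
                             intercept = num_out(r$intercept))
rate_in <- function(l) rate_function(num_in(l$slope), num_in(l$intercept))

phenotype_units <- list(
  seed_mass = "mg", carbohydrate_fraction = "fraction of seed mass",
  seed_nitrogen = "umol N", seed_phosphorus = "umol P",
  mesocotyl_rate = "cm/d", mesocotyl_diameter = "cm", planting_depth = "cm",
  leaf_area_expansion_rate = "cm^2/d (linear in t)",
  elongation_rate = "cm/d (linear in t)", branch_angle = "degrees",
  branching_frequency_range = "branches/cm", diameter = "cm",
  tissue_density = "g/cm^3", respiration_rate = "umol CO2/g DW/s",
  max_length = "cm", optimal_tissue_conc = "umol/g DW")

#' Write / read a phenotype configuration file
#'
#' One YAML document per phenotype; numeric values round-trip
#' bit-identically.
#'
#' @param phenotype a [plant_phenotype()].
#' @param path file path.
#' @return `write_phenotype_config()` returns `path` invisibly;
#'   `read_phenotype_config()` returns the reconstructed
#'   [plant_phenotype()].
#' @export
write_phenotype_config <- function(phenotype, path) {
  stopifnot(inherits(phenotype, "plant_phenotype"))
  p <- phenotype
  doc <- list(
    type = "plant_phenotype",
    name = p$name,
    seed_mass = num_out(p$seed_mass),
    carbohydrate_fraction = num_out(p$carbohydrate_fraction),
    seed_nitrogen = num_out(p$seed_nitrogen),
    seed_phosphorus = num_out(p$seed_phosphorus),
    seminal_root_number = p$seminal_root_number,
    nodal_whorls = list(emergence_day = num_out(p$nodal_whorls$emergence_day),
                        roots_per_whorl = as.integer(p$nodal_whorls$roots_per_whorl)),
    mesocotyl_rate = num_out(p$mesocotyl_rate),
    mesocotyl_diameter = num_out(p$mesocotyl_diameter),
    planting_depth = num_out(p$planting_depth),
    leaf_area_expansion_rate = rate_out(p$leaf_area_expansion_rate),
    root_classes = lapply(p$root_classes, function(rc) list(
      class_id = rc$class_id,
      emergence_day = num_out(rc$emergence_day),
      elongation_rate = rate_out(rc$elongation_rate),
      branch_angle = num_out(rc$branch_angle),
      branching_frequency_range = num_out(rc$branching_frequency_range),
      diameter = num_out(rc$diameter),
      tissue_density = num_out(rc$tissue_density),
      respiration_rate = num_out(rc$respiration_rate),
      max_length = num_out(rc$max_length))),
    allocation_coefficients = as.list(num_out(p$allocation_coefficients)),
    optimal_tissue_conc = lapply(p$optimal_tissue_conc,
                                 function(v) as.list(num_out(v))),
    units = phenotype_units)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_phenotype_config
#' @export
read_phenotype_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$type, "plant_phenotype"))
    stop("not a plant_phenotype config: ", path)
  rcs <- lapply(doc$root_classes, function(rc) root_class_params(
    class_id = rc$class_id,
    emergence_day = num_in(rc$emergence_day),
    elongation_rate = rate_in(rc$elongation_rate),
    branch_angle = num_in(rc$branch_angle),
    branching_frequency_range = num_in(unlist(rc$branching_frequency_range)),
    diameter = num_in(rc$diameter),
    tissue_density = num_in(rc$tissue_density),
    respiration_rate = num_in(rc$respiration_rate),
    max_length = num_in(rc$max_length)))
  alloc <- vapply(doc$allocation_coefficients, num_in, 0)
  plant_phenotype(
    name = doc$name,
    seed_mass = num_in(doc$seed_mass),
    carbohydrate_fraction = num_in(doc$carbohydrate_fraction),
    seed_nitrogen = num_in(doc$seed_nitrogen),
    seed_phosphorus = num_in(doc$seed_phosphorus),
    seminal_root_number = doc$seminal_root_number,
    nodal_whorls = data.frame(
      emergence_day = num_in(unlist(doc$nodal_whorls$emergence_day)),
      roots_per_whorl = as.integer(unlist(doc$nodal_whorls$roots_per_whorl))),
    mesocotyl_rate = num_in(doc$mesocotyl_rate),
    mesocotyl_diameter = num_in(doc$mesocotyl_diameter),
    planting_depth = num_in(doc$planting_depth),
    leaf_area_expansion_rate = rate_in(doc$leaf_area_expansion_rate),
    root_classes = rcs,
    allocation_coefficients = alloc,
    optimal_tissue_conc = lapply(doc$optimal_tissue_conc,
                                 function(v) vapply(v, num_in, 0)))
}

environment_units <- list(
  rainfall = "mm/d", profiles = "umol/cm^3 (nitrate, P: solution; organic N: soil)",
  prism = "cm", row_spacing = "cm", in_row_spacing = "cm",
  evaporation_rate = "mm/d", bulk_density = "g/cm^3",
  saturated_conductivity = "cm/d", dispersivity = "cm",
  p_diffusion_coefficient = "cm^2/d")

#' Write / read an environment configuration file
#'
#' @param env a [soil_environment()].
#' @param path file path.
#' @return `write_environment_config()` returns `path` invisibly;
#'   `read_environment_config()` returns the reconstructed
#'   [soil_environment()].
#' @export
write_environment_config <- function(env, path) {
  stopifnot(inherits(env, "soil_environment"))
  tx <- env$texture
  doc <- list(
    type = "soil_environment",
    texture = list(name = tx$name,
                   bulk_density = num_out(tx$bulk_density),
                   field_capacity = num_out(tx$field_capacity),
                   wilting_point = num_out(tx$wilting_point),
                   saturated_conductivity = num_out(tx$saturated_conductivity),
                   dispersivity = num_out(tx$dispersivity),
                   p_buffer_power = num_out(tx$p_buffer_power),
                   p_diffusion_coefficient = num_out(tx$p_diffusion_coefficient)),
    rainfall = num_out(env$rainfall),
    rainfall_multiplier = num_out(env$rainfall_multiplier),
    initial_nitrate_profile = num_out(env$initial_nitrate_profile),
    organic_matter_n_profile = num_out(env$organic_matter_n_profile),
    initial_p_profile = num_out(env$initial_p_profile),
    nutrient_multiplier_n = num_out(env$nutrient_multiplier_n),
    nutrient_multiplier_p = num_out(env$nutrient_multiplier_p),
    prism = as.list(num_out(env$prism)),
    row_spacing = num_out(env$row_spacing),
    in_row_spacing = num_out(env$in_row_spacing),
    evaporation_rate = num_out(env$evaporation_rate),
    units = environment_units)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_environment_config
#' @export
read_environment_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$type, "soil_environment"))
    stop("not a soil_environment config: ", path)
  tx <- doc$texture
  texture <- soil_texture(
    name = tx$name, bulk_density = num_in(tx$bulk_density),
    field_capacity = num_in(tx$field_capacity),
    wilting_point = num_in(tx$wilting_point),
    saturated_conductivity = num_in(tx$saturated_conductivity),
    dispersivity = num_in(tx$dispersivity),
    p_buffer_power = num_in(tx$p_buffer_power),
    p_diffusion_coefficient = num_in(tx$p_diffusion_coefficient))
  prism <- vapply(doc$prism, num_in, 0)
  soil_environment(
    texture = texture,
    rainfall = num_in(unlist(doc$rainfall)),
    rainfall_multiplier = num_in(doc$rainfall_multiplier),
    initial_nitrate_profile = num_in(unlist(doc$initial_nitrate_profile)),
    organic_matter_n_profile = num_in(unlist(doc$organic_matter_n_profile)),
    initial_p_profile = num_in(unlist(doc$initial_p_profile)),
    nutrient_multiplier_n = num_in(doc$nutrient_multiplier_n),
    nutrient_multiplier_p = num_in(doc$nutrient_multiplier_p),
    prism = prism,
    row_spacing = num_in(doc$row_spacing),
    in_row_spacing = num_in(doc$in_row_spacing),
    evaporation_rate = num_in(doc$evaporation_rate))
}

#' Write / read a daily rainfall series as CSV
#'
#' Columns `day` (1-based) and `mm`.
#'
#' @param rainfall numeric vector, mm d^-1.
#' @param path file path.
#' @return `write_rainfall_csv()` returns `path` invisibly;
#'   `read_rainfall_csv()` returns the numeric series.
#' @export
write_rainfall_csv <- function(rainfall, path) {
  df <- data.frame(day = seq_along(rainfall), mm = num_out(rainfall))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rainfall_csv
#' @export
read_rainfall_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(day = "integer", mm = "character"))
  num_in(df$mm[order(df$day)])
}
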