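#' Per-class root parameters
#'
#' Each root class (primary, seminal, nodal whorls, and the lateral class
#' borne on each axial class) carries its own emergence time, elongation
#' rate, insertion angle, branching frequency range, diameter, tissue
#' density and respiration rate.
#'
#' @param class_id one of `"primary"`, `"seminal"`, `"nodal"`, or
#'   `"lateral_primary"`, `"lateral_seminal"`, `"lateral_nodal"`.
#' @param emergence_day days after planting the class starts elongating.
#' @param elongation_rate a [rate_function()], cm d^-1.
#' @param branch_angle mean insertion angle, degrees from vertical (axial
#'   classes) or from the parent axis (lateral classes).
#' @param branching_frequency_range uniform range, branches cm^-1 (axial
#'   classes; ignored for laterals).
#' @param diameter root diameter, cm.
#' @param tissue_density dry mass per unit root volume, g cm^-3.
#' @param respiration_rate maintenance respiration, umol CO2 (g root DW)^-1 s^-1.
#' @param max_length optional cap on axis length, cm (`Inf` = uncapped).
#' @return An object of class `root_class_params`.
#' @export
root_class_params <- function(class_id, emergence_day, elongation_rate,
                              branch_angle = 0,
                              branching_frequency_range = c(0, 0),
                              diameter, tissue_density = 0.08,
                              respiration_rate = 0.01,
                              max_length = Inf) {
  classes <- c("primary", "seminal", "nodal",
               "lateral_primary", "lateral_seminal", "lateral_nodal")
  if (!class_id %in% classes)
    stop("unknown class_id '", class_id, "'; valid: ",
         paste(classes, collapse = ", "))
  stopifnot(emergence_day >= 0, inherits(elongation_rate, "rate_function"),
            diameter > 0, tissue_density > 0, respiration_rate >= 0)
  if (length(branching_frequency_range) != 2L ||
      any(branching_frequency_range < 0) ||
      branching_frequency_range[1] > branching_frequency_range[2])
    stop("branching_frequency_range must be 0 <= low <= high")
  if (any(eval_rate(elongation_rate, seq(0, 25, by = 0.5)) < 0))
    stop("elongation rate must be non-negative over [0, 25] d")
  structure(list(
    class_id = class_id, emergence_day = emergence_day,
    elongation_rate = elongation_rate, branch_angle = branch_angle,
    branching_frequency_range = as.numeric(branching_frequency_range),
    diameter = diameter, tissue_density = tissue_density,
    respiration_rate = respiration_rate, max_length = max_length),
    class = "root_class_params")
}

#' A full heritable phenotype for one genotype
#'
#' Bundles everything the simulator needs to grow one seedling: seed
#' composition, embryonic and nodal root-system layout, mesocotyl traits,
#' shoot expansion, per-class root parameters, carbon allocation, and
#' optimal tissue nutrient concentrations. Composite phenotypes for
#' trait-swap experiments are built with [make_composite_phenotype()].
#'
#' @param name genotype label.
#' @param seed_mass seed (kernel) mass, mg.
#' @param carbohydrate_fraction seed carbohydrate content as a fraction of
#'   seed mass, in `[0, 1]`.
#' @param seed_nitrogen,seed_phosphorus seed nutrient reserves available to
#'   the seedling, umol.
#' @param seminal_root_number integer count of seminal axes.
#' @param nodal_whorls data.frame with columns `emergence_day`,
#'   `roots_per_whorl`.
#' @param mesocotyl_rate mesocotyl elongation rate, cm d^-1.
#' @param mesocotyl_diameter cm.
#' @param planting_depth cm.
#' @param leaf_area_expansion_rate a [rate_function()], cm^2 d^-1.
#' @param root_classes named list of [root_class_params()], one per class.
#' @param allocation_coefficients named fractions to `roots`, `stem`,
#'   `leaves`; must sum to 1.
#' @param optimal_tissue_conc list with elements `root` and `shoot`, each a
#'   named vector `c(n = , p = )` in umol (g DW)^-1.
#' @return An object of class `plant_phenotype`.
#' @export
plant_phenotype <- function(name, seed_mass, carbohydrate_fraction,
                            seed_nitrogen, seed_phosphorus,
                            seminal_root_number, nodal_whorls,
                            mesocotyl_rate, mesocotyl_diameter,
                            planting_depth, leaf_area_expansion_rate,
                            root_classes, allocation_coefficients,
                            optimal_tissue_conc) {
  stopifnot(seed_mass > 0, planting_depth > 0,
            carbohydrate_fraction >= 0, carbohydrate_fraction <= 1,
            seed_nitrogen >= 0, seed_phosphorus >= 0,
            mesocotyl_rate >= 0, mesocotyl_diameter > 0,
            inherits(leaf_area_expansion_rate, "rate_function"))
  if (seminal_root_number < 0 || seminal_root_number != round(seminal_root_number))
    stop("seminal_root_number must be a non-negative integer")
  stopifnot(is.data.frame(nodal_whorls),
            all(c("emergence_day", "roots_per_whorl") %in% names(nodal_whorls)))
  if (abs(sum(allocation_coefficients) - 1) > 1e-9)
    stop("allocation coefficients must sum to 1")
  stopifnot(all(c("roots", "stem", "leaves") %in% names(allocation_coefficients)))
  stopifnot(is.list(root_classes), all(vapply(root_classes, inherits,
                                              TRUE, "root_class_params")))
  stopifnot(all(c("root", "shoot") %in% names(optimal_tissue_conc)))
  structure(list(
    name = name, seed_mass = seed_mass,
    carbohydrate_fraction = carbohydrate_fraction,
    seed_nitrogen = seed_nitrogen, seed_phosphorus = seed_phosphorus,
    seminal_root_number = as.integer(seminal_root_number),
    nodal_whorls = nodal_whorls,
    mesocotyl_rate = mesocotyl_rate, mesocotyl_diameter = mesocotyl_diameter,
    planting_depth = planting_depth,
    leaf_area_expansion_rate = leaf_area_expansion_rate,
    root_classes = root_classes,
    allocation_coefficients = allocation_coefficients[c("roots", "stem", "leaves")],
    optimal_tissue_conc = optimal_tissue_conc),
    class = "plant_phenotype")
}

#' @export
print.plant_phenotype <- function(x, ...) {
  cat(sprintf("<plant_phenotype> %s: seed %g mg (%.1f%% carbohydrate), %d seminal roots\n",
              x$name, x$seed_mass, 100 * x$carbohydrate_fraction,
              x$seminal_root_number))
  invisible(x)
}

#' Seed carbohydrate reserve
#'
#' The carbohydrate reserve available to the heterotrophic seedling is the
#' seed mass times its carbohydrate fraction.
#'
#' @param seed_mass mg.
#' @param carbohydrate_fraction fraction of seed mass in `[0, 1]`.
#' @return Reserve in mg carbohydrate.
#' @export
seed_carbohydrate_reserve <- function(seed_mass, carbohydrate_fraction) {
  stopifnot(seed_mass >= 0)
  if (any(carbohydrate_fraction < 0 | carbohydrate_fraction > 1))
    stop("carbohydrate_fraction must lie in [0, 1]")
  seed_mass * carbohydrate_fraction
}

#' Combine components of two phenotypes
#'
#' Returns `base` with exactly the named fields replaced by the
#' corresponding values from `donor`. Used to build the composite
#' phenotypes of the trait-swap experiments (e.g. a landrace with teosinte
#' growth rates, or teosinte with landrace seed reserves). Inputs are never
#' modified.
#'
#' @param base,donor [plant_phenotype()] objects.
#' @param fields character vector of `plant_phenotype` field names to take
#'   from `donor`.
#' @return A new `plant_phenotype`.
#' @export
make_composite_phenotype <- function(base, donor, fields = character()) {
  stopifnot(inherits(base, "plant_phenotype"), inherits(donor, "plant_phenotype"))
  valid <- setdiff(names(base), NULL)
  bad <- setdiff(fields, valid)
  if (length(bad))
    stop("unknown phenotype field(s): ", paste(bad, collapse = ", "),
         "; valid fields: ", paste(valid, collapse = ", "))
  out <- base
  for (f in fields) out[[f]] <- donor[[f]]
  out
}

# Internal: clone a phenotype with some scalar overrides (used by sweeps).
override_phenotype <- function(phenotype, ...) {
  ov <- list(...)
  for (f in names(ov)) {
    if (!f %in% names(phenotype)) stop("unknown phenotype field: ", f)
    phenotype[[f]] <- ov[[f]]
  }
  if (!is.null(ov$seminal_root_number)) {
    if (ov$seminal_root_number < 0 ||
        ov$seminal_root_number != round(ov$seminal_root_number))
      stop("seminal_root_number must be a non-negative integer")
    phenotype$seminal_root_number <- as.integer(ov$seminal_root_number)
  }
  phenotype
}
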