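# The soil-side physics: a 1-D layered column per plant ground area with
# tipping-bucket water flow, conservative nitrate convection-dispersion,
# time-declining first-order mineralization, per-layer Michaelis-Menten
# nitrate uptake and Barber-Cushman radial phosphorus uptake.

#' Initialize the soil column of an environment
#'
#' Builds the 1-cm-layer state for one plant's ground area. Nitrate and
#' organic-N profiles are converted to per-layer amounts (umol per plant
#' column) after applying the environment's nitrogen multiplier; phosphorus
#' is carried as a per-layer labile pool (buffer power times solution
#' concentration) after the phosphorus multiplier. Water starts at field
#' capacity.
#'
#' @param env a [soil_environment()].
#' @return Object of class `soil_column` (a list of per-layer vectors).
#' @export
soil_column <- function(env) {
  stopifnot(inherits(env, "soil_environment"))
  tx <- env$texture
  nl <- length(env$initial_nitrate_profile)
  area <- ground_area(env)
  theta <- rep(tx$field_capacity, nl)
  conc_n <- env$initial_nitrate_profile * env$nutrient_multiplier_n
  conc_p <- env$initial_p_profile * env$nutrient_multiplier_p
  structure(list(
    n_layers = nl, area = area, texture = tx,
    water = theta,                                   # volumetric fraction
    nitrate = conc_n * theta * area,                 # umol per layer
    organic_n = env$organic_matter_n_profile * env$nutrient_multiplier_n * area,
    p_labile = conc_p * tx$p_buffer_power * area,    # umol per layer
    leached_n = 0, mineralized_n = 0,
    initial_nitrate = sum(conc_n * theta * area),
    initial_organic_n = sum(env$organic_matter_n_profile *
                              env$nutrient_multiplier_n * area),
    initial_p = sum(conc_p * tx$p_buffer_power * area)),
    class = "soil_column")
}

#' @export
print.soil_column <- function(x, ...) {
  cat(sprintf(
    "<soil_column> %d layers, %.0f cm^2; nitrate %.0f umol, labile P %.0f umol, leached %.1f umol\n",
    x$n_layers, x$area, sum(x$nitrate), sum(x$p_labile), x$leached_n))
  invisible(x)
}

# Solution-phase P concentration per layer (umol cm^-3).
p_solution_conc <- function(column) {
  column$p_labile / (column$texture$p_buffer_power * column$area)
}

#' Tipping-bucket water step
#'
#' Infiltrating water fills layers to field capacity from the top down;
#' excess cascades to the next layer and excess at the bottom leaves the
#' column as drainage. Evaporation then removes water from the top layers
#' down to wilting point. Exactly conservative:
#' `rain = d(storage) + drainage + evaporation`.
#'
#' @param column a [soil_column()].
#' @param rain_cm infiltrating water this step, cm.
#' @param evap_cm evaporative demand this step, cm.
#' @return `list(column, fluxes, drainage, evaporated)`; `fluxes[l]` is the
#'   downward water flux (cm) leaving layer `l`.
#' @export
step_water <- function(column, rain_cm, evap_cm = 0) {
  stopifnot(rain_cm >= 0, evap_cm >= 0)
  tx <- column$texture
  nl <- column$n_layers
  theta <- column$water
  fluxes <- numeric(nl)
  input <- rain_cm
  if (input > 0) {
    deficit <- pmax(0, tx$field_capacity - theta)
    absorbed <- pmin(cummax_input <- input - c(0, cumsum(deficit))[1:nl],
                     deficit)
    absorbed <- pmax(0, pmin(absorbed, deficit))
    theta <- theta + absorbed
    passed <- input - cumsum(absorbed)
    fluxes <- pmax(0, passed)
  }
  drainage <- fluxes[nl]
  evaporated <- 0
  if (evap_cm > 0) {
    demand <- evap_cm
    for (l in seq_len(nl)) {
      take <- min(demand, max(0, theta[l] - tx$wilting_point))
      theta[l] <- theta[l] - take
      demand <- demand - take
      evaporated <- evaporated + take
      if (demand <= 1e-15) break
    }
  }
  column$water <- theta
  list(column = column, fluxes = fluxes, drainage = drainage,
       evaporated = evaporated)
}

#' Convective-dispersive nitrate transport
#'
#' Explicit conservative finite-volume update on the layer stack:
#' convective transfer is `flux x upwind solution concentration`;
#' hydrodynamic dispersion is `dispersivity x |flux|` acting on the
#' concentration gradient. Outflow from a layer is limited to its content
#' (no negative pools), and the step is automatically sub-stepped when the
#' advective Courant number exceeds 0.5. Mass is conserved exactly:
#' nitrate before = nitrate after + leachate.
#'
#' @param column a [soil_column()] (water already stepped).
#' @param fluxes per-layer downward water fluxes, cm (from [step_water()]).
#' @return `list(column, leachate)`, leachate in umol.
#' @export
transport_nitrate <- function(column, fluxes) {
  nl <- column$n_layers
  theta <- pmax(column$water, 1e-6)
  if (all(fluxes <= 0))
    return(list(column = column, leachate = 0))
  courant <- max(fluxes / theta)
  ns <- max(1L, ceiling(courant / 0.5))
  f <- fluxes / ns
  disp <- column$texture$dispersivity
  leach <- 0
  nit <- column$nitrate
  for (s in seq_len(ns)) {
    conc <- nit / (theta * column$area)          # umol cm^-3 solution
    # downward convection, upwind (flow is downward only)
    conv <- f * conc * column$area               # umol crossing lower face
    # dispersive exchange across interior faces (can be upward)
    dq <- numeric(nl)
    if (disp > 0 && nl > 1) {
      fint <- f[-nl]
      dq[-nl] <- disp * fint * (conc[-nl] - conc[-1]) * column$area
    }
    out_down <- pmax(conv + pmin(dq, 0) * 0 + pmax(dq, 0), 0)  # leaving downward
    out_up <- c(0, pmax(-dq[-nl], 0))                          # leaving upward
    # limit total outflow to the layer content
    tot_out <- out_down + out_up
    scale <- ifelse(tot_out > nit & tot_out > 0, nit / tot_out, 1)
    out_down <- out_down * scale
    out_up <- out_up * scale
    gain <- c(0, out_down[-nl]) + c(out_up[-1], 0)
    nit <- nit - out_down - out_up + gain
    leach <- leach + out_down[nl]
  }
  column$nitrate <- pmax(nit, 0)
  column$leached_n <- column$leached_n + leach
  list(column = column, leachate = leach)
}

#' Organic-matter nitrogen mineralization
#'
#' First-order release with a time-declining rate constant,
#' `k(t) = k0 * (t + 1)^(-s)`, an aging form in which the remaining organic
#' matter becomes progressively more recalcitrant. Each layer releases
#' `organic_n * (1 - exp(-k dt))` into its nitrate pool.
#'
#' @param column a [soil_column()].
#' @param day current day.
#' @param dt step, days.
#' @param k0 initial rate constant, d^-1.
#' @param s aging exponent (>= 0); `s = 0` gives plain exponential decay.
#' @return `list(column, released)`, per-layer umol N released.
#' @export
mineralize <- function(column, day, dt, k0 = 0.01, s = 0.5) {
  stopifnot(k0 >= 0, s >= 0, dt > 0)
  k <- k0 * (day + 1)^(-s)
  released <- column$organic_n * (1 - exp(-k * dt))
  column$organic_n <- column$organic_n - released
  column$nitrate <- column$nitrate + released
  column$mineralized_n <- column$mineralized_n + sum(released)
  list(column = column, released = released)
}

#' Michaelis-Menten nitrate uptake by root surface area
#'
#' Potential uptake per class and layer is
#' `surface area x i_max x C / (C + k_m) x dt` at the layer solution
#' concentration. Realized uptake is rationed so that no layer gives up
#' more nitrate than it holds (proportional scaling among the classes in
#' the layer) and the plant total never exceeds `demand_cap`.
#'
#' @param surface_area matrix (class x layer) or vector (per layer) of root
#'   surface area, cm^2.
#' @param column a [soil_column()].
#' @param kinetics `c(i_max = umol cm^-2 d^-1, k_m = umol cm^-3)`.
#' @param demand_cap plant-level cap, umol.
#' @param dt step, days.
#' @return `list(column, uptake)`; `uptake` has the shape of
#'   `surface_area`.
#' @export
uptake_nitrate <- function(surface_area, column, kinetics, demand_cap = Inf,
                           dt = 1) {
  i_max <- kinetics[[1]]; k_m <- kinetics[[2]]
  stopifnot(i_max >= 0, k_m > 0, dt > 0, demand_cap >= 0)
  vec_in <- is.null(dim(surface_area))
  SA <- if (vec_in) matrix(surface_area, 1) else surface_area
  theta <- pmax(column$water, 1e-6)
  conc <- column$nitrate / (theta * column$area)
  mm <- conc / (conc + k_m)
  pot <- sweep(SA, 2, i_max * mm * dt, "*")
  layer_tot <- colSums(pot)
  layer_scale <- ifelse(layer_tot > column$nitrate & layer_tot > 0,
                        column$nitrate / layer_tot, 1)
  upt <- sweep(pot, 2, layer_scale, "*")
  tot <- sum(upt)
  if (tot > demand_cap && tot > 0) upt <- upt * (demand_cap / tot)
  column$nitrate <- pmax(0, column$nitrate - colSums(upt))
  list(column = column, uptake = if (vec_in) drop(upt) else upt)
}

#' Barber-Cushman parameter set
#'
#' Parameters of the radial convection-diffusion uptake model for
#' phosphorus: Michaelis-Menten influx kinetics at the root surface,
#' effective diffusion, buffer power, and the annulus geometry (root radius
#' to the half-distance between neighbouring roots).
#'
#' @param i_max maximal influx, umol cm^-2 root surface d^-1.
#' @param k_m Michaelis constant, umol cm^-3.
#' @param c_min concentration below which influx stops, umol cm^-3.
#' @param de effective diffusion coefficient, cm^2 d^-1.
#' @param b buffer power (dimensionless).
#' @param r0 root radius, cm.
#' @param rx outer (no-flux) radius, cm; half-distance between roots.
#' @param water_flux_at_root inward water flux at the root surface, cm d^-1.
#' @return Object of class `bc_params`.
#' @export
bc_params <- function(i_max, k_m, c_min = 0, de, b, r0, rx,
                      water_flux_at_root = 0) {
  stopifnot(i_max >= 0, k_m > 0, c_min >= 0, de > 0, b > 0, r0 > 0,
            water_flux_at_root >= 0)
  if (rx <= r0) stop("rx must exceed r0")
  structure(list(i_max = i_max, k_m = k_m, c_min = c_min, de = de, b = b,
                 r0 = r0, rx = rx, water_flux_at_root = water_flux_at_root),
            class = "bc_params")
}

bc_grid <- function(params, n_nodes = 16) {
  exp(seq(log(params$r0), log(params$rx), length.out = n_nodes))
}

#' Barber-Cushman radial phosphorus uptake
#'
#' Integrates the radial convection-diffusion equation around a root over
#' `dt` with Michaelis-Menten influx at the root surface and zero flux at
#' the half-distance boundary, per cm of root length, and returns the mass
#' taken up by `root_length` cm of root. The depletion profile persists in
#' `state` so depletion zones develop over consecutive calls.
#'
#' @param root_length cm of root sharing this depletion state.
#' @param params a [bc_params()].
#' @param c_initial initial solution concentration, umol cm^-3 (used when
#'   `state` is `NULL`).
#' @param dt step, days.
#' @param state previous return value's `state`, or `NULL` to start from an
#'   undepleted profile.
#' @param n_nodes radial grid nodes (log-spaced).
#' @param nsub sub-steps per call.
#' @return `list(uptake = umol, state = list(profile, grid))`.
#' @export
uptake_p_barber_cushman <- function(root_length, params, c_initial, dt,
                                    state = NULL, n_nodes = 16, nsub = 8) {
  stopifnot(inherits(params, "bc_params"), root_length >= 0, dt > 0,
            c_initial >= 0)
  if (is.null(state)) {
    grid <- bc_grid(params, n_nodes)
    profile <- matrix(c_initial, 1, n_nodes)
    state <- list(profile = profile, grid = grid)
  }
  upt_per_cm <- bc_step_cpp(state$profile, state$grid, params$de, params$b,
                            params$i_max, params$k_m, params$c_min,
                            params$water_flux_at_root, dt, as.integer(nsub))
  list(uptake = upt_per_cm[1] * root_length, state = state)
}
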