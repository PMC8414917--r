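# Segment-based 3-D root system architecture.
#
# A root system is a mutable environment (reference semantics, like a
# data.table) holding a growing segment buffer, the active tip states, and
# per-axis polylines. Coordinates are in cm with the origin at the corner of
# the soil prism; the plant sits at the prism centre in x/y; z is positive
# downward with 0 at the soil surface. Segments are never longer than 1 cm.

ROOT_CLASSES <- c("primary", "seminal", "nodal",
                  "lateral_primary", "lateral_seminal", "lateral_nodal")
AXIAL_CLASSES <- 1:3

class_index <- function(class_id) match(class_id, ROOT_CLASSES)

# Internal: flatten the per-class parameters into lookup vectors indexed by
# the integer class code.
class_param_table <- function(phenotype) {
  nm <- ROOT_CLASSES
  get <- function(field, default = NA_real_) {
    vapply(nm, function(cl) {
      rc <- phenotype$root_classes[[cl]]
      if (is.null(rc)) default else rc[[field]]
    }, 0)
  }
  rates <- lapply(nm, function(cl) {
    rc <- phenotype$root_classes[[cl]]
    if (is.null(rc)) rate_function(0, 0) else rc$elongation_rate
  })
  list(
    slope = vapply(rates, function(r) r$slope, 0),
    intercept = vapply(rates, function(r) r$intercept, 0),
    emergence = get("emergence_day", Inf),
    angle = get("branch_angle", 0),
    blo = vapply(nm, function(cl) {
      rc <- phenotype$root_classes[[cl]]
      if (is.null(rc)) 0 else rc$branching_frequency_range[1]
    }, 0),
    bhi = vapply(nm, function(cl) {
      rc <- phenotype$root_classes[[cl]]
      if (is.null(rc)) 0 else rc$branching_frequency_range[2]
    }, 0),
    radius = get("diameter", 0.02) / 2,
    density = get("tissue_density", 0.08),
    resp = get("respiration_rate", 0),
    maxlen = get("max_length", Inf))
}

#' Initiate a root system for one seedling
#'
#' Creates the embryonic and shoot-borne root tips: the primary root active
#' from its emergence day, the seminal roots scheduled after the primary,
#' and the nodal whorls per the phenotype's whorl schedule. The primary
#' heads straight down; seminal and nodal tips head at their class
#' insertion angle (with a small jitter) and a uniform random azimuth.
#' Uses the session RNG; seed it for reproducibility.
#'
#' @param phenotype a [plant_phenotype()].
#' @param prism named vector `c(width, length, depth)` in cm.
#' @param control a [sim_control()].
#' @return A `root_system` environment.
#' @export
initiate_root_system <- function(phenotype,
                                 prism = c(width = 60, length = 26, depth = 150),
                                 control = sim_control()) {
  sys <- new.env(parent = emptyenv())
  class(sys) <- "root_system"
  sys$prism <- prism
  sys$nlayer <- as.integer(round(prism[["depth"]]))
  cp <- class_param_table(phenotype)
  sys$cp <- cp
  sys$control <- control
  sys$nseg <- 0L
  sys$cap <- 2048L
  sys$seg <- matrix(0, 2048L, 12,
                    dimnames = list(NULL, c("x0", "y0", "z0", "x1", "y1", "z1",
                                            "len", "radius", "class", "birth",
                                            "axis", "parent")))
  sys$SA <- matrix(0, 6, sys$nlayer)    # root surface area, cm^2, class x layer
  sys$LEN <- matrix(0, 6, sys$nlayer)   # root length, cm, class x layer
  sys$mass_by_class <- numeric(6)       # g DW
  sys$axes <- list()
  sys$axis_class <- integer(0)
  sys$axis_parent <- integer(0)

  cx <- prism[["width"]] / 2
  cy <- prism[["length"]] / 2
  pd <- phenotype$planting_depth
  jit <- control$angle_jitter_deg * pi / 180

  tip <- list(x = numeric(0), y = numeric(0), z = numeric(0),
              hx = numeric(0), hy = numeric(0), hz = numeric(0),
              class = integer(0), axis = integer(0), born = numeric(0),
              cumlen = numeric(0), pending = numeric(0),
              next_branch = numeric(0),
              maxlen = numeric(0), last_seg = integer(0))

  add_tip <- function(x, y, z, h, cls, born) {
    aid <- length(sys$axes) + 1L
    tip$x <<- c(tip$x, x); tip$y <<- c(tip$y, y); tip$z <<- c(tip$z, z)
    tip$hx <<- c(tip$hx, h[1]); tip$hy <<- c(tip$hy, h[2]); tip$hz <<- c(tip$hz, h[3])
    tip$class <<- c(tip$class, cls)
    tip$axis <<- c(tip$axis, aid)
    tip$born <<- c(tip$born, born)
    tip$cumlen <<- c(tip$cumlen, 0)
    tip$pending <<- c(tip$pending, 0)
    freq <- sample_branching_frequency(c(cp$blo[cls], cp$bhi[cls]))
    tip$next_branch <<- c(tip$next_branch, if (freq > 0) 1 / freq else Inf)
    tip$maxlen <<- c(tip$maxlen, cp$maxlen[cls])
    tip$last_seg <<- c(tip$last_seg, 0L)
    sys$axes[[aid]] <- matrix(c(0, x, y, z, 0), 1, 5,
                              dimnames = list(NULL, c("s", "x", "y", "z", "seg")))
    sys$axis_class <- c(sys$axis_class, cls)
    sys$axis_parent <- c(sys$axis_parent, 0L)
    aid
  }

  angled_heading <- function(mean_angle_deg) {
    theta <- abs(mean_angle_deg * pi / 180 + stats::rnorm(1, 0, jit))
    phi <- stats::runif(1, 0, 2 * pi)
    c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }

  add_tip(cx, cy, pd, c(0, 0, 1), 1L, cp$emergence[1])
  if (phenotype$seminal_root_number > 0) {
    for (i in seq_len(phenotype$seminal_root_number))
      add_tip(cx, cy, pd, angled_heading(cp$angle[2]), 2L,
              cp$emergence[2])
  }
  crown_z <- min(pd, control$crown_depth)
  if (nrow(phenotype$nodal_whorls) > 0) {
    for (w in seq_len(nrow(phenotype$nodal_whorls))) {
      k <- phenotype$nodal_whorls$roots_per_whorl[w]
      if (k <= 0) next
      base_phi <- stats::runif(1, 0, 2 * pi)
      for (i in seq_len(k)) {
        theta <- abs(cp$angle[3] * pi / 180 + stats::rnorm(1, 0, jit))
        phi <- base_phi + 2 * pi * (i - 1) / k
        h <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
        add_tip(cx, cy, crown_z, h, 3L,
                phenotype$nodal_whorls$emergence_day[w])
      }
    }
  }
  sys$tip <- tip
  sys
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf("<root_system> %d segments, %d axes, %d tips, total length %.1f cm\n",
              x$nseg, length(x$axes), length(x$tip$x), sum(x$LEN)))
  invisible(x)
}

# Internal: grow the segment buffer.
ensure_capacity <- function(sys, n_extra) {
  need <- sys$nseg + n_extra
  if (need <= sys$cap) return(invisible())
  newcap <- max(need, 2L * sys$cap)
  m <- matrix(0, newcap, ncol(sys$seg), dimnames = dimnames(sys$seg))
  if (sys$nseg > 0) m[seq_len(sys$nseg), ] <- sys$seg[seq_len(sys$nseg), ]
  sys$seg <- m
  sys$cap <- newcap
  invisible()
}

# Internal: append segment rows (matrix with the seg columns) and update the
# per-layer length/surface-area accounting.
append_segments <- function(sys, rows) {
  n <- nrow(rows)
  if (n == 0) return(integer(0))
  ensure_capacity(sys, n)
  idx <- sys$nseg + seq_len(n)
  sys$seg[idx, ] <- rows
  sys$nseg <- sys$nseg + n
  cls <- as.integer(rows[, "class"])
  sa <- 2 * pi * rows[, "radius"] * rows[, "len"]
  mass <- pi * rows[, "radius"]^2 * rows[, "len"] * sys$cp$density[cls]
  sys$mass_by_class[1:6] <- sys$mass_by_class +
    vapply(1:6, function(k) sum(mass[cls == k]), 0)
  # apportion to 1-cm layers by z-extent (segments are <= 1 cm so they touch
  # at most two layers)
  zlo <- pmin(rows[, "z0"], rows[, "z1"])
  zhi <- pmax(rows[, "z0"], rows[, "z1"])
  l1 <- pmin(pmax(floor(zlo), 0), sys$nlayer - 1)
  l2 <- pmin(pmax(floor(zhi - 1e-12), 0), sys$nlayer - 1)
  span <- zhi - zlo
  f1 <- ifelse(l1 == l2, 1, pmin(1, (l1 + 1 - zlo) / pmax(span, 1e-12)))
  # single pass over a composite (class, layer) bin
  bin <- c((l1 + 1L - 1L) * 6L + cls, (l2 + 1L - 1L) * 6L + cls)
  wlen <- c(rows[, "len"] * f1, rows[, "len"] * (1 - f1))
  wsa <- c(sa * f1, sa * (1 - f1))
  keep <- c(rep(TRUE, n), (1 - f1) > 0)
  agg <- rowsum(cbind(wlen, wsa)[keep, , drop = FALSE], bin[keep])
  ib <- as.integer(rownames(agg))
  sys$LEN[ib] <- sys$LEN[ib] + agg[, 1]
  sys$SA[ib] <- sys$SA[ib] + agg[, 2]
  idx
}

tabulate_weighted <- function(bin, w, nbins) {
  if (!length(bin)) return(numeric(nbins))
  out <- numeric(nbins)
  agg <- rowsum(w, bin)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Reflect a growth step at the prism boundaries
#'
#' Propagates a straight growth step of given length from `start` along
#' `heading`, mirror-reflecting the corresponding heading component at the
#' vertical (x and y) walls. At the bottom the heading is deflected to
#' horizontal (growth is clamped at the prism depth); at the surface (z = 0)
#' the vertical component is reflected. Path length is preserved.
#'
#' @param start numeric xyz, inside the prism.
#' @param heading unit xyz vector.
#' @param length step length, cm.
#' @param prism `c(width, length, depth)`.
#' @return `list(points = polyline matrix, heading = final unit heading)`.
#' @export
reflect_at_boundaries <- function(start, heading, length, prism) {
  lim <- c(prism[["width"]], prism[["length"]], prism[["depth"]])
  pos <- as.numeric(start)
  h <- as.numeric(heading)
  h <- h / sqrt(sum(h^2))
  rem <- length
  pts <- matrix(pos, 1, 3)
  for (iter in 1:200) {
    t_hit <- rep(Inf, 3)
    for (d in 1:3) {
      if (h[d] > 1e-12) t_hit[d] <- (lim[d] - pos[d]) / h[d]
      else if (h[d] < -1e-12) t_hit[d] <- (0 - pos[d]) / h[d]
    }
    tmin <- min(t_hit)
    if (rem <= tmin + 1e-12) {
      pos <- pos + h * rem
      pts <- rbind(pts, pos)
      break
    }
    pos <- pos + h * tmin
    pts <- rbind(pts, pos)
    rem <- rem - tmin
    d <- which.min(t_hit)
    if (d == 3L && h[3] > 0) {
      # bottom: clamp vertical growth, continue horizontally
      hor <- sqrt(h[1]^2 + h[2]^2)
      if (hor < 1e-9) break
      h <- c(h[1] / hor, h[2] / hor, 0)
      pos[3] <- min(pos[3], lim[3] - 1e-9)
    } else {
      h[d] <- -h[d]
    }
    pos <- pmin(pmax(pos, 1e-12), lim - 1e-12)
  }
  list(points = unname(pts), heading = h)
}

#' Advance all active root tips
#'
#' Each tip whose class has emerged advances by `rate(class, day) * dt *
#' stress_factor`, split into segments of at most 1 cm, with a small random
#' deflection and a class-specific gravitropic pull applied per segment.
#' Construction carbon (volume x tissue density x carbon fraction x growth
#' overhead) is limited by `carbon_allowance`; when the allowance binds, all
#' tips are scaled down proportionally. Mutates `system` in place.
#'
#' @param system a `root_system`.
#' @param phenotype a [plant_phenotype()].
#' @param day current day (plant age the rate functions are evaluated at).
#' @param dt time step, days (> 0).
#' @param stress_factor multiplier in `[0, 1]` on elongation.
#' @param carbon_allowance g C available for construction.
#' @param flush emit all buffered growth as segments (done automatically at
#'   the end of a simulation). Growth shorter than the emission resolution
#'   (`control$emit_min`) is buffered per tip and emitted as one segment
#'   once accumulated, so segment counts stay proportional to root length
#'   rather than to the number of time steps.
#' @return `list(new_segments, carbon_used, length_added)`; `new_segments`
#'   is a matrix of the appended segment rows; `length_added` and
#'   `carbon_used` describe the realized growth (which may still be partly
#'   buffered).
#' @export
elongate <- function(system, phenotype, day, dt, stress_factor = 1,
                     carbon_allowance = Inf, flush = FALSE) {
  stopifnot(dt > 0, stress_factor >= 0, stress_factor <= 1)
  if (carbon_allowance < 0) stop("carbon allowance must be >= 0")
  sys <- system
  cp <- sys$cp
  ctl <- sys$control
  tip <- sys$tip
  cfrac <- ctl$carbon_fraction
  over <- ctl$growth_overhead
  act <- which(tip$born <= day - dt + 1e-9 & tip$cumlen < tip$maxlen - 1e-12)
  empty <- list(new_segments = sys$seg[0, , drop = FALSE], carbon_used = 0,
                length_added = 0)
  if (!length(act) && !flush) return(empty)
  carbon_used <- 0
  len_added <- 0
  if (length(act)) {
    cls <- tip$class[act]
    rate <- pmax(0, cp$slope[cls] * day + cp$intercept[cls])
    dl <- pmin(rate * dt * stress_factor, tip$maxlen[act] - tip$cumlen[act])
    ccost <- pi * cp$radius[cls]^2 * cp$density[cls] * cfrac * over
    demand <- sum(dl * ccost)
    if (demand > carbon_allowance) {
      if (demand <= 0) dl <- dl * 0 else dl <- dl * (carbon_allowance / demand)
    }
    keep <- dl > 1e-9
    act <- act[keep]; dl <- dl[keep]; ccost <- ccost[keep]
    carbon_used <- sum(dl * ccost)
    len_added <- sum(dl)
    tip$pending[act] <- tip$pending[act] + dl
    tip$cumlen[act] <- tip$cumlen[act] + dl
  }
  # emit buffered growth once it reaches the segment resolution (or the tip
  # is finished, or a flush is requested)
  emit_min <- if (is.null(ctl$emit_min)) 0.5 else ctl$emit_min
  emit <- which(tip$pending > 1e-9 &
                  (flush | tip$pending >= emit_min - 1e-9 |
                     tip$cumlen >= tip$maxlen - 1e-9))
  if (!length(emit)) {
    sys$tip <- tip
    return(list(new_segments = sys$seg[0, , drop = FALSE],
                carbon_used = carbon_used, length_added = len_added))
  }
  act <- emit
  dl <- tip$pending[act]
  tip$pending[act] <- 0
  lim <- c(sys$prism[["width"]], sys$prism[["length"]], sys$prism[["depth"]])
  first_new <- sys$nseg + 1L
  rem <- dl
  arc_base <- tip$cumlen[act] - dl   # emitted arclength before this call
  round_i <- 0L
  while (any(rem > 1e-9) && round_i < 50L) {
    round_i <- round_i + 1L
    sel <- which(rem > 1e-9)
    ids <- act[sel]
    piece <- pmin(rem[sel], 1)
    rem[sel] <- rem[sel] - piece
    n <- length(ids)
    # perturb headings: gaussian deflection + gravitropism, then normalize
    H <- cbind(tip$hx[ids], tip$hy[ids], tip$hz[ids])
    g <- ctl$gravitropism[tip$class[ids]]
    H <- H + matrix(stats::rnorm(3 * n, 0, ctl$deflection_sd), n, 3)
    H[, 3] <- H[, 3] + g
    H <- H / sqrt(rowSums(H^2))
    P0 <- cbind(tip$x[ids], tip$y[ids], tip$z[ids])
    P1 <- P0 + H * piece
    inside <- P1[, 1] > 0 & P1[, 1] < lim[1] &
      P1[, 2] > 0 & P1[, 2] < lim[2] &
      P1[, 3] > 0 & P1[, 3] < lim[3]
    rows_list <- vector("list", 2L)
    n_inside <- 0L
    if (any(inside)) {
      ii <- which(inside)
      n_inside <- length(ii)
      rows_list[[1]] <- cbind(P0[ii, 1], P0[ii, 2], P0[ii, 3],
                              P1[ii, 1], P1[ii, 2], P1[ii, 3],
                              piece[ii], cp$radius[tip$class[ids[ii]]],
                              tip$class[ids[ii]], day, tip$axis[ids[ii]],
                              tip$last_seg[ids[ii]])
      tip$x[ids[ii]] <- P1[ii, 1]; tip$y[ids[ii]] <- P1[ii, 2]
      tip$z[ids[ii]] <- P1[ii, 3]
      tip$hx[ids[ii]] <- H[ii, 1]; tip$hy[ids[ii]] <- H[ii, 2]
      tip$hz[ids[ii]] <- H[ii, 3]
    }
    refl_tip_rows <- integer(0)  # tip id per reflected segment row
    if (any(!inside)) {
      # wall-crossing tips: reflect within the step
      ref_rows <- list()
      for (j in which(!inside)) {
        id <- ids[j]
        rp <- reflect_at_boundaries(P0[j, ], H[j, ], piece[j], sys$prism)
        np <- nrow(rp$points)
        segs <- cbind(rp$points[-np, , drop = FALSE],
                      rp$points[-1, , drop = FALSE])
        slen <- sqrt(rowSums((segs[, 4:6, drop = FALSE] -
                                segs[, 1:3, drop = FALSE])^2))
        ok <- slen > 1e-12
        segs <- segs[ok, , drop = FALSE]; slen <- slen[ok]
        if (nrow(segs)) {
          ref_rows[[length(ref_rows) + 1L]] <-
            cbind(segs, slen, cp$radius[tip$class[id]], tip$class[id], day,
                  tip$axis[id], tip$last_seg[id])
          refl_tip_rows <- c(refl_tip_rows, rep(id, nrow(segs)))
        }
        tip$x[id] <- rp$points[np, 1]; tip$y[id] <- rp$points[np, 2]
        tip$z[id] <- rp$points[np, 3]
        tip$hx[id] <- rp$heading[1]; tip$hy[id] <- rp$heading[2]
        tip$hz[id] <- rp$heading[3]
      }
      if (length(ref_rows)) rows_list[[2]] <- do.call(rbind, ref_rows)
    }
    rows <- do.call(rbind, rows_list[!vapply(rows_list, is.null, TRUE)])
    if (!is.null(rows) && nrow(rows)) {
      colnames(rows) <- colnames(sys$seg)
      idx <- append_segments(sys, rows)
      # update last_seg: rows 1..n_inside are one-per-tip in ids[ii] order;
      # reflected rows follow, tagged in refl_tip_rows
      tip_of_row <- c(if (n_inside) ids[which(inside)], refl_tip_rows)
      if (n_inside) tip$last_seg[tip_of_row[seq_len(n_inside)]] <-
          idx[seq_len(n_inside)]
      if (length(refl_tip_rows)) {
        rr <- n_inside + seq_along(refl_tip_rows)
        # last row per reflected tip
        last_of <- tapply(idx[rr], refl_tip_rows, max)
        tip$last_seg[as.integer(names(last_of))] <- as.integer(last_of)
      }
      # extend axis polylines (axial classes only; laterals need no path)
      axial_rows <- which(rows[, "class"] <= 3)
      if (length(axial_rows)) {
        tor <- tip_of_row[axial_rows]
        for (id in unique(tor)) {
          srows <- axial_rows[tor == id]
          aid <- tip$axis[id]
          pathadd <- cbind(arc_base[match(id, act)] +
                             cumsum(rows[srows, "len"]),
                           rows[srows, "x1", drop = FALSE],
                           rows[srows, "y1", drop = FALSE],
                           rows[srows, "z1", drop = FALSE],
                           idx[srows])
          sys$axes[[aid]] <- rbind(sys$axes[[aid]], unname(pathadd))
        }
      }
    }
    arc_base[sel] <- arc_base[sel] + piece
  }
  sys$tip <- tip
  new_idx <- if (sys$nseg >= first_new) first_new:sys$nseg else integer(0)
  list(new_segments = sys$seg[new_idx, , drop = FALSE],
       carbon_used = carbon_used, length_added = len_added)
}

#' Insert lateral root tips along axial roots
#'
#' Walks each axial root: whenever the axis has extended one inter-branch
#' spacing (drawn from the class branching-frequency range) beyond the
#' apical non-branching zone, a first-order lateral tip is inserted at the
#' corresponding point of the axis, heading at the lateral class insertion
#' angle from the local axis direction with a uniform azimuth. Laterals
#' never branch (first order only). Mutates `system` in place.
#'
#' @param system a `root_system`.
#' @param phenotype a [plant_phenotype()].
#' @param day current day (birth day for new laterals).
#' @return Number of laterals created.
#' @export
branch_laterals <- function(system, phenotype, day = 0) {
  sys <- system
  cp <- sys$cp
  ctl <- sys$control
  tip <- sys$tip
  az <- ctl$apical_zone
  n_created <- 0L
  axial_tips <- which(tip$class %in% AXIAL_CLASSES)
  axial_tips <- axial_tips[tip$cumlen[axial_tips] - tip$pending[axial_tips] -
                             az >= tip$next_branch[axial_tips] - 1e-12]
  if (!length(axial_tips)) return(0L)
  new <- list(x = numeric(0), y = numeric(0), z = numeric(0),
              hx = numeric(0), hy = numeric(0), hz = numeric(0),
              class = integer(0), axis = integer(0), born = numeric(0),
              cumlen = numeric(0), pending = numeric(0),
              next_branch = numeric(0),
              maxlen = numeric(0), last_seg = integer(0))
  for (i in axial_tips) {
    avail <- tip$cumlen[i] - tip$pending[i] - az
    while (tip$next_branch[i] <= avail + 1e-12) {
      s <- tip$next_branch[i]
      path <- sys$axes[[tip$axis[i]]]
      row <- which.min(abs(path[, 1] - s))
      origin <- path[row, 2:4]
      segid <- path[row, 5]
      # local axis direction at the branch point
      r2 <- min(row + 1L, nrow(path))
      r1 <- max(row - 1L, 1L)
      d <- path[r2, 2:4] - path[r1, 2:4]
      nd <- sqrt(sum(d^2))
      d <- if (nd > 1e-12) d / nd else c(0, 0, 1)
      lcls <- tip$class[i] + 3L
      alpha <- cp$angle[lcls] * pi / 180
      # orthonormal basis perpendicular to d
      ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      u <- c(d[2] * ref[3] - d[3] * ref[2],
             d[3] * ref[1] - d[1] * ref[3],
             d[1] * ref[2] - d[2] * ref[1])
      u <- u / sqrt(sum(u^2))
      v <- c(d[2] * u[3] - d[3] * u[2],
             d[3] * u[1] - d[1] * u[3],
             d[1] * u[2] - d[2] * u[1])
      phi <- stats::runif(1, 0, 2 * pi)
      h <- cos(alpha) * d + sin(alpha) * (cos(phi) * u + sin(phi) * v)
      aid <- length(sys$axes) + length(new$x) + 1L
      new$x <- c(new$x, origin[1]); new$y <- c(new$y, origin[2])
      new$z <- c(new$z, origin[3])
      new$hx <- c(new$hx, h[1]); new$hy <- c(new$hy, h[2]); new$hz <- c(new$hz, h[3])
      new$class <- c(new$class, lcls)
      new$axis <- c(new$axis, aid)
      new$born <- c(new$born, day)
      new$cumlen <- c(new$cumlen, 0)
      new$pending <- c(new$pending, 0)
      new$next_branch <- c(new$next_branch, Inf)  # laterals never branch
      new$maxlen <- c(new$maxlen, cp$maxlen[lcls])
      new$last_seg <- c(new$last_seg, as.integer(segid))
      n_created <- n_created + 1L
      freq <- sample_branching_frequency(c(cp$blo[tip$class[i]],
                                           cp$bhi[tip$class[i]]))
      tip$next_branch[i] <- s + if (freq > 0) 1 / freq else Inf
    }
  }
  if (n_created > 0) {
    for (k in seq_len(n_created)) {
      sys$axes[[length(sys$axes) + 1L]] <-
        matrix(c(0, new$x[k], new$y[k], new$z[k], new$last_seg[k]), 1, 5)
    }
    sys$axis_class <- c(sys$axis_class, new$class)
    parent_axis <- integer(n_created)
    for (k in seq_len(n_created)) {
      ls <- new$last_seg[k]
      parent_axis[k] <- if (ls > 0) as.integer(sys$seg[ls, "axis"]) else 0L
    }
    sys$axis_parent <- c(sys$axis_parent, parent_axis)
    for (f in names(tip)) tip[[f]] <- c(tip[[f]], new[[f]])
  }
  sys$tip <- tip
  n_created
}

#' Apportion per-segment quantities to 1-cm depth layers
#'
#' Each segment's quantity is split across the layers it crosses in
#' proportion to the segment length inside each layer (for a straight
#' segment, proportional to its z-extent per layer). Totals are conserved.
#'
#' @param z0,z1 segment endpoint depths, cm.
#' @param values per-segment quantities.
#' @param n_layers number of 1-cm layers.
#' @param layer_height layer thickness, cm (default 1).
#' @return Numeric vector of per-layer totals (layer k covers
#'   `[(k-1), k) * layer_height`).
#' @export
bin_by_depth <- function(z0, z1, values, n_layers, layer_height = 1) {
  stopifnot(length(z0) == length(z1), length(values) == length(z0),
            layer_height > 0)
  out <- numeric(n_layers)
  if (!length(z0)) return(out)
  zlo <- pmin(z0, z1) / layer_height
  zhi <- pmax(z0, z1) / layer_height
  span <- zhi - zlo
  l_start <- pmin(pmax(floor(zlo), 0), n_layers - 1)
  maxspan <- max(ceiling(zhi) - floor(zlo))
  for (off in 0:max(0, maxspan - 1)) {
    l <- l_start + off
    active <- l < n_layers & l <= floor(zhi - 1e-12)
    if (!any(active)) break
    lo <- pmax(zlo, l)
    hi <- pmin(zhi, l + 1)
    frac <- ifelse(span > 1e-12, pmax(0, hi - lo) / span,
                   ifelse(off == 0, 1, 0))
    w <- values * frac * active
    out <- out + tabulate_weighted(as.integer(l) + 1L, w, n_layers)
  }
  out
}

#' Distances to the nearest root segment of a neighbouring plant
#'
#' Samples root segment midpoints of the plant and, for each, finds the
#' minimum Euclidean distance to any segment midpoint of the same root
#' system translated by the neighbour offset (the neighbouring plant in the
#' row). Returns the sorted sample and its empirical CDF.
#'
#' @param system a `root_system` (must contain segments).
#' @param neighbour_offset xyz translation to the neighbouring plant, cm
#'   (e.g. `c(0, in_row_spacing, 0)`).
#' @param n_samples number of sampled segments (>= 1).
#' @return `list(distances = sorted sample, cdf = ecdf function)`.
#' @export
nearest_neighbour_distances <- function(system, neighbour_offset,
                                        n_samples = 200) {
  stopifnot(n_samples >= 1)
  sys <- system
  if (sys$nseg == 0) stop("root system has no segments")
  S <- sys$seg[seq_len(sys$nseg), , drop = FALSE]
  M <- cbind((S[, "x0"] + S[, "x1"]) / 2,
             (S[, "y0"] + S[, "y1"]) / 2,
             (S[, "z0"] + S[, "z1"]) / 2)
  Nb <- sweep(M, 2, as.numeric(neighbour_offset), "+")
  idx <- sample.int(nrow(M), n_samples, replace = n_samples > nrow(M))
  d <- vapply(idx, function(i) {
    sqrt(min((Nb[, 1] - M[i, 1])^2 + (Nb[, 2] - M[i, 2])^2 +
               (Nb[, 3] - M[i, 3])^2))
  }, 0)
  d <- sort(d)
  list(distances = d, cdf = stats::ecdf(d))
}

#' Segment table of a root system
#'
#' @param system a `root_system`.
#' @return data.frame with id, parent, class, coordinates, radius, length,
#'   birth day, axis and dry mass (g) per segment.
#' @export
segment_table <- function(system) {
  sys <- system
  S <- sys$seg[seq_len(sys$nseg), , drop = FALSE]
  cls <- as.integer(S[, "class"])
  data.frame(
    id = seq_len(sys$nseg),
    parent = as.integer(S[, "parent"]),
    class = ROOT_CLASSES[cls],
    x0 = S[, "x0"], y0 = S[, "y0"], z0 = S[, "z0"],
    x1 = S[, "x1"], y1 = S[, "y1"], z1 = S[, "z1"],
    radius = S[, "radius"], length = S[, "len"],
    birth_day = S[, "birth"], axis = as.integer(S[, "axis"]),
    mass = pi * S[, "radius"]^2 * S[, "len"] * sys$cp$density[cls])
}
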