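# Root-system initiation, elongation, branching, boundary reflection,
# depth binning and neighbour distances.

test_that("initiation creates the scheduled embryonic and nodal tips", {
  set.seed(1)
  ph0 <- tiny_phenotype(srn = 0L)
  sys0 <- initiate_root_system(ph0, control = fast_control())
  expect_equal(sum(sys0$tip$class == 2L), 0)

  ph4 <- tiny_phenotype(srn = 4L)
  sys4 <- initiate_root_system(ph4, control = fast_control())
  expect_equal(sum(sys4$tip$class == 2L), 4)
  expect_equal(sum(sys4$tip$class == 1L), 1)

  # a whorl scheduled at day 7 never yields segments born earlier
  land <- make_phenotype_fixture("landrace")$phenotype
  env <- tiny_environment(n_layers = 50)
  res <- run_simulation(land, env, seed = 2, days = 10,
                        control = fast_control())
  seg <- segment_table(res$root_system)
  nodal <- seg[seg$class == "nodal", ]
  expect_gt(nrow(nodal), 0)
  expect_true(all(nodal$birth_day >= 7))
  # exactly 4 seminal axes exist for seminal_root_number = 4
  expect_equal(length(unique(seg$axis[seg$class == "seminal"])), 4)
})

test_that("elongation splits growth into <= 1 cm segments and respects the
          carbon allowance proportionally", {
  ph <- tiny_phenotype(primary_rate = 2)
  set.seed(5)
  sys <- initiate_root_system(ph, prism = c(width = 40, length = 40,
                                            depth = 60),
                              control = fast_control())
  # zero allowance: no growth at all
  out0 <- elongate(sys, ph, day = 1, dt = 1, carbon_allowance = 0)
  expect_equal(out0$carbon_used, 0)
  expect_equal(out0$length_added, 0)
  expect_equal(sys$nseg, 0)

  # a single vertical tip at 2 cm/d over one day: two 1-cm segments
  out <- elongate(sys, ph, day = 1, dt = 1)
  expect_equal(out$length_added, 2, tolerance = 1e-9)
  expect_equal(sys$nseg, 2)
  expect_true(all(sys$seg[1:2, "len"] <= 1 + 1e-9))

  # allowance at half the unconstrained demand halves the added length
  set.seed(5)
  sysA <- initiate_root_system(ph, control = fast_control())
  full <- elongate(sysA, ph, day = 1, dt = 1)
  set.seed(5)
  sysB <- initiate_root_system(ph, control = fast_control())
  half <- elongate(sysB, ph, day = 1, dt = 1,
                   carbon_allowance = full$carbon_used / 2)
  expect_equal(half$length_added, full$length_added / 2, tolerance = 1e-9)
  expect_equal(half$carbon_used, full$carbon_used / 2, tolerance = 1e-9)
})

test_that("total root length is non-increasing in stress and non-decreasing
          in time under a fixed seed", {
  ph <- tiny_phenotype(srn = 2L, laterals = TRUE)
  grow <- function(stress) {
    set.seed(42)
    sys <- initiate_root_system(ph, control = fast_control())
    lens <- numeric(8)
    for (d in 1:8) {
      elongate(sys, ph, day = d, dt = 1, stress_factor = stress)
      branch_laterals(sys, ph, day = d)
      lens[d] <- sum(sys$tip$cumlen)
    }
    lens
  }
  full <- grow(1)
  weak <- grow(0.5)
  expect_true(all(diff(full) >= -1e-9))
  expect_true(all(weak <= full + 1e-9))
})

test_that("lateral branching follows the drawn spacing outside the apical
          zone and laterals never branch", {
  ph <- tiny_phenotype(laterals = TRUE)  # frequency fixed at 1 cm^-1
  set.seed(8)
  sys <- initiate_root_system(ph, prism = c(width = 40, length = 40,
                                            depth = 60),
                              control = fast_control())
  for (d in 1:5) elongate(sys, ph, day = d, dt = 1)  # 10-cm axis
  n <- branch_laterals(sys, ph, day = 5)
  # 10-cm axis, 2-cm apical zone, 1 branch/cm -> 8 laterals
  expect_equal(n, 8)
  expect_equal(sum(sys$tip$class == 4L), 8)
  # laterals grow but never spawn second-order laterals
  for (d in 6:9) {
    elongate(sys, ph, day = d, dt = 1)
    branch_laterals(sys, ph, day = d)
  }
  expect_equal(sum(sys$tip$class > 3L), sum(sys$tip$class == 4L))
  expect_true(all(sys$axis_parent[sys$axis_class == 4L] == 1L))

  # zero branching frequency: no laterals ever
  ph0 <- tiny_phenotype(laterals = FALSE)
  set.seed(8)
  sys0 <- initiate_root_system(ph0, control = fast_control())
  for (d in 1:6) {
    elongate(sys0, ph0, day = d, dt = 1)
    expect_equal(branch_laterals(sys0, ph0, day = d), 0L)
  }
})

test_that("boundary reflection mirrors headings, preserves length and stays
          inside the prism", {
  prism <- c(width = 60, length = 26, depth = 150)
  # interior step: unchanged straight line
  r <- reflect_at_boundaries(c(30, 13, 5), c(0, 0, 1), 3, prism)
  expect_equal(nrow(r$points), 2)
  expect_equal(r$points[2, ], c(30, 13, 8))

  # crossing the x = 60 wall at 45 degrees: x-heading negated, length kept
  h <- c(sqrt(0.5), 0, sqrt(0.5))
  r2 <- reflect_at_boundaries(c(59, 13, 5), h, 4, prism)
  expect_equal(r2$heading, c(-sqrt(0.5), 0, sqrt(0.5)), tolerance = 1e-12)
  plen <- sum(sqrt(rowSums(diff(r2$points)^2)))
  expect_equal(plen, 4, tolerance = 1e-9)
  expect_true(all(r2$points[, 1] <= 60 + 1e-9))

  # corner crossings match the coordinate-folding oracle
  set.seed(21)
  for (i in 1:25) {
    start <- c(runif(1, 0, 60), runif(1, 0, 26), runif(1, 10, 80))
    hh <- rnorm(3)
    hh[3] <- abs(hh[3]) * 0.1  # avoid the z-clamp boundary
    hh <- hh / sqrt(sum(hh^2))
    len <- runif(1, 5, 80)
    got <- reflect_at_boundaries(start, hh, len, prism)
    want <- fold_oracle(start, hh, len, c(60, 26, 150))
    expect_equal(got$points[nrow(got$points), ], want, tolerance = 1e-6)
    plen <- sum(sqrt(rowSums(diff(got$points)^2)))
    expect_equal(plen, len, tolerance = 1e-9)
    expect_true(all(got$points[, 1] >= -1e-9 & got$points[, 1] <= 60 + 1e-9))
    expect_true(all(got$points[, 2] >= -1e-9 & got$points[, 2] <= 26 + 1e-9))
  }
})

test_that("depth binning apportions by in-layer length and conserves totals", {
  out <- bin_by_depth(0.5, 1.5, 1, n_layers = 5)
  expect_equal(out[1:2], c(0.5, 0.5))
  out2 <- bin_by_depth(10.2, 10.2, 7, n_layers = 20)
  expect_equal(out2[11], 7)
  set.seed(2)
  z0 <- runif(200, 0, 19)
  z1 <- pmin(z0 + runif(200, 0, 1), 20)
  v <- rexp(200)
  binned <- bin_by_depth(z0, z1, v, n_layers = 20)
  expect_equal(sum(binned), sum(v), tolerance = 1e-9)
})

test_that("nearest-neighbour distances match the brute-force oracle", {
  ph <- tiny_phenotype(srn = 2L, laterals = TRUE)
  set.seed(31)
  sys <- initiate_root_system(ph, control = fast_control())
  for (d in 1:6) {
    elongate(sys, ph, day = d, dt = 0.5)
    branch_laterals(sys, ph, day = d)
  }
  elongate(sys, ph, day = 7, dt = 0.5, stress_factor = 0, 0, flush = TRUE)
  expect_gt(sys$nseg, 20)

  # offset zero: every distance is zero
  set.seed(1)
  z <- nearest_neighbour_distances(sys, c(0, 0, 0), 40)
  expect_true(all(z$distances == 0))

  set.seed(1)
  got <- nearest_neighbour_distances(sys, c(0, 17.71, 0), 40)
  S <- segment_table(sys)
  M <- cbind((S$x0 + S$x1) / 2, (S$y0 + S$y1) / 2, (S$z0 + S$z1) / 2)
  Nb <- M
  Nb[, 2] <- Nb[, 2] + 17.71
  set.seed(1)
  idx <- sample.int(nrow(M), 40, replace = 40 > nrow(M))
  want <- sort(vapply(idx, function(i)
    sqrt(min(colSums((t(Nb) - M[i, ])^2))), 0))
  expect_equal(got$distances, want, tolerance = 1e-9)
  # CDF is a proper non-decreasing [0,1] step function
  expect_equal(got$cdf(max(want)), 1)
  expect_true(all(diff(got$cdf(sort(want))) >= 0))
})

test_that("segment geometry invariants hold after a coupled run", {
  land <- make_phenotype_fixture("landrace")$phenotype
  env <- tiny_environment(n_layers = 60)
  res <- run_simulation(land, env, seed = 4, days = 12,
                        control = fast_control())
  seg <- segment_table(res$root_system)
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 +
                (seg$z1 - seg$z0)^2)
  expect_true(all(len <= 1 + 1e-9))
  expect_equal(len, seg$length, tolerance = 1e-9)
  expect_true(all(seg$z0 >= -1e-9 & seg$z1 <= 60 + 1e-9))
  expect_true(all(seg$radius > 0))
  expect_equal(anyDuplicated(seg$id), 0)
  # parents exist and belong to a lower id (grown earlier)
  has_parent <- seg$parent > 0
  expect_true(all(seg$parent[has_parent] < seg$id[has_parent]))
  # one axis per embryonic tip plus nodal and laterals
  expect_equal(length(unique(seg$axis[seg$class == "primary"])), 1)
})

test_that("RSML, VTK and CSV exports produce parseable files", {
  ph <- tiny_phenotype(srn = 1L, laterals = TRUE)
  set.seed(12)
  sys <- initiate_root_system(ph, control = fast_control())
  for (d in 1:4) {
    elongate(sys, ph, day = d, dt = 1)
    branch_laterals(sys, ph, day = d)
  }
  f <- withr::local_tempfile(fileext = ".rsml")
  write_rsml(sys, f)
  doc <- xml2::read_xml(f)
  roots <- xml2::xml_find_all(doc, "//root")
  expect_gte(length(roots), 2)
  pts <- xml2::xml_find_all(doc, "//point")
  expect_gt(length(pts), 4)

  fv <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(sys, fv)
  head <- readLines(fv, n = 4)
  expect_equal(head[4], "DATASET POLYDATA")

  fc <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(sys, fc)
  tab <- utils::read.csv(fc)
  expect_equal(nrow(tab), sys$nseg)
})
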