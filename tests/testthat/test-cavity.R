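# GEPOL tessellation: sphere-area closure, the analytic two-sphere union
# oracle, rigid-motion invariance and deterministic rebuilds

analytic_union_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(4 * pi * max(r1, r2)^2)
  c1 <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  c2 <- (d^2 + r2^2 - r1^2) / (2 * d * r2)
  2 * pi * r1^2 * (1 + c1) + 2 * pi * r2^2 * (1 + c2)
}

two_spheres <- function(d_ang) {
  molecule(c("O", "O"), rbind(c(0, 0, 0), c(d_ang, 0, 0)), 0)
}

test_that("an isolated sphere closes to its exact area at every density", {
  m <- molecule("O", matrix(0, 1, 3), 0)
  for (np in c(60, 240, 960)) {
    cav <- tessellate_gepol(m, n_per_sphere = np)
    exact <- 4 * pi * cav$radii_bohr[1]^2
    expect_equal(cav$total_area, exact, tolerance = 1e-10,
                 label = paste("closure at", np))
    expect_identical(length(cav$area_bohr2), as.integer(np))
    expect_true(all(cav$area_bohr2 > 0))
  }
})

test_that("interlocked spheres reproduce the analytic union area", {
  errs960 <- errs60 <- c()
  for (d in c(0.6, 1.2, 1.8, 2.4, 3.0, 3.4)) {
    exact <- NULL
    for (np in c(60, 960)) {
      cav <- tessellate_gepol(two_spheres(d), n_per_sphere = np)
      rb <- cav$radii_bohr[1]
      exact <- analytic_union_area(rb, rb, d / 0.529167)
      rel <- abs(cav$total_area - exact) / exact
      if (np == 960) errs960 <- c(errs960, rel) else errs60 <- c(errs60, rel)
    }
  }
  expect_lt(max(errs960), 0.025)
  # refinement improves the closure on average
  expect_lt(mean(errs960), mean(errs60))
})

test_that("fully overlapping identical spheres collapse to one", {
  cav <- tessellate_gepol(two_spheres(1e-9), n_per_sphere = 960)
  single <- 4 * pi * cav$radii_bohr[1]^2
  expect_equal(cav$total_area, single, tolerance = 0.03)
})

test_that("retained representative points lie outside all other spheres", {
  cav <- tessellate_gepol(load_fixture("A5"), n_per_sphere = 240)
  for (s in seq_len(nrow(cav$spheres))) {
    d <- sqrt(colSums((t(cav$pos_bohr) - cav$centers_bohr[s, ])^2))
    other <- cav$sphere_row != s
    expect_true(all(d[other] >= cav$radii_bohr[s] - 1e-7))
  }
  # and they sit on their parent sphere with unit outward normals
  on_r <- sqrt(rowSums((cav$pos_bohr -
                          cav$centers_bohr[cav$sphere_row, ])^2))
  expect_equal(on_r, cav$radii_bohr[cav$sphere_row], tolerance = 1e-8)
  expect_equal(rowSums(cav$normal^2), rep(1, nrow(cav$normal)), tolerance = 1e-8)
})

test_that("the tessellation co-rotates with the molecule", {
  m <- load_fixture("A1")   # symmetric top: the hard case for the frame seed
  cav0 <- tessellate_gepol(m, 240)
  th <- 1.1; ax <- c(2, -1, 2) / 3
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  Rot <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  mr <- molecule(m$symbols, m$coords %*% t(Rot), m$charge)
  cavr <- tessellate_gepol(mr, 240)
  expect_equal(cavr$total_area / cav0$total_area, 1, tolerance = 1e-6)
  expect_identical(length(cavr$area_bohr2), length(cav0$area_bohr2))
  expect_equal(sort(cavr$area_bohr2), sort(cav0$area_bohr2), tolerance = 1e-6)
})

test_that("displacement rebuilds are deterministic and continuous", {
  m <- two_spheres(2.0)
  cav <- tessellate_gepol(m, 240)
  # zero displacement: bit-identical
  cav2 <- cavity_displacement_rebuild(cav, m)
  expect_identical(cav$pos_bohr, cav2$pos_bohr)
  expect_identical(cav$area_bohr2, cav2$area_bohr2)
  # rigid translation: positions shift, areas unchanged
  mt <- molecule(m$symbols, m$coords + rep(c(1, 2, -1), each = 2), m$charge)
  cavt <- cavity_displacement_rebuild(cav, mt)
  expect_equal(cavt$area_bohr2, cav$area_bohr2, tolerance = 1e-10)
  expect_equal(cavt$pos_bohr[1, ] - cav$pos_bohr[1, ],
               c(1, 2, -1) / 0.529167, tolerance = 1e-9)
  # a 1e-4 bohr displacement changes the total area continuously, bounded by
  # the analytic two-sphere union derivative (plus tessellation granularity)
  h <- 1e-4
  mp <- molecule(m$symbols, m$coords + rbind(c(0, 0, 0), c(h * 0.529167, 0, 0)), 0)
  cavp <- cavity_displacement_rebuild(cav, mp)
  dA <- abs(cavp$total_area - cav$total_area)
  rb <- cav$radii_bohr[1]; d0 <- 2 / 0.529167
  dA_exact <- abs(analytic_union_area(rb, rb, d0 + h) -
                    analytic_union_area(rb, rb, d0 - h)) / (2 * h)
  expect_lt(dA, 3 * dA_exact * h + 1e-3)
})

test_that("sphere assignment and its failure modes", {
  m <- load_fixture("A1")
  sph <- assign_radii(m)
  expect_identical(nrow(sph), 5L)
  expect_equal(max(sph$radius), 1.55 * 1.2)   # nitrogen sphere largest
  expect_equal(sph$radius[sph$element == "H"][1], 1.2 * 1.2)
  expect_error(assign_radii(m, scale = 0), "positive")
  expect_error(assign_radii(m, radii_table = c(C = 1.7)), "lacks element")
  expect_error(tessellate_gepol(m, n_per_sphere = 100), "60, 240, 960")
  # a sphere buried inside another yields no tesserae but no error
  big <- tessellate_gepol(
    molecule(c("O", "H"), rbind(c(0, 0, 0), c(0.1, 0, 0)), charge = 1),
    n_per_sphere = 60,
    radii_table = c(O = 3.0, H = 0.3))
  expect_true(all(big$sphere == 1))
})

test_that("cavity CSV dump has one row per tessera", {
  cav <- tessellate_gepol(load_fixture("A1"), 60)
  f <- tempfile(fileext = ".csv")
  write_cavity_csv(cav, f)
  df <- read.csv(f)
  expect_identical(nrow(df), length(cav$area_bohr2))
  expect_named(df, c("index", "sphere", "x", "y", "z", "area"))
})
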