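# Superposition, RMSD series, planarity, crossing angle, wrap coverage, FEL.

test_that("Kabsch superposition recovers planted transforms exactly", {
  set.seed(1)
  pts <- matrix(rnorm(30, 0, 5), ncol = 3)
  id <- superpose(pts, pts)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rotated <- pts %*% t(Rz90)
  fit <- superpose(pts, rotated)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, Rz90, tolerance = 1e-9)

  for (i in 1:10) {
    R <- random_rotation(); tr <- rnorm(3, 0, 10)
    moved <- sweep(pts %*% t(R), 2, tr, "+")
    f <- superpose(pts, moved)
    expect_equal(f$rotation, R, tolerance = 1e-9)
    expect_equal(f$translation, tr, tolerance = 1e-9)
    expect_lt(f$rmsd, 1e-9)
  }
  expect_error(superpose(pts[1:2, ], pts[1:2, ]), "3")
  collinear <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(collinear, collinear), "non-collinear")
})

test_that("jittered-copy superposition matches a brute-force numeric oracle", {
  set.seed(2)
  pts <- matrix(rnorm(15, 0, 4), ncol = 3)
  R <- random_rotation()
  moved <- sweep(pts %*% t(R), 2, c(1, -2, 3), "+") +
    matrix(rnorm(15, 0, 0.1), ncol = 3)
  fit <- superpose(pts, moved)
  # oracle: optimize over Euler angles + translation
  obj <- function(par) {
    cz <- cos(par[1]); sz <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cx <- cos(par[3]); sx <- sin(par[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    m <- sweep(pts %*% t(Rz %*% Ry %*% Rx), 2, par[4:6], "+")
    sqrt(mean(rowSums((m - moved)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- optim(c(runif(3, -pi, pi), rnorm(3)), obj,
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
  # independent library cross-check (bio3d reports at 3-decimal precision)
  expect_equal(round(fit$rmsd, 3),
               bio3d::rmsd(as.vector(t(pts)), as.vector(t(moved)),
                           fit = TRUE),
               tolerance = 1e-9)
  # symmetry of the minimized RMSD
  expect_equal(superpose(pts, moved)$rmsd, superpose(moved, pts)$rmsd,
               tolerance = 1e-9)
})

test_that("DNA-backbone RMSD series isolates DNA motion after protein fit", {
  toy <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 5, sigma = 0))
  top <- toy$trajectory$topology
  fit_on <- select_atoms(top, class = c("protein", "heavy"))
  measure_on <- union(select_atoms(top, class = "dna_phosphate"),
                      select_atoms(top, class = "dna_sugar"))
  # copies of the reference -> all zeros
  r0 <- dna_backbone_rmsd_series(toy$trajectory, fit_on, measure_on)
  expect_equal(r0, rep(0, 5), tolerance = 1e-9)
  # DNA rigidly translated by d with protein fixed -> series = d
  base <- frame_coords(toy$trajectory, 1)
  d <- 6
  shifted <- base
  shifted[toy$dna_atoms, 3] <- shifted[toy$dna_atoms, 3] + d
  tr2 <- wk_trajectory(top, array(c(base, shifted), c(nrow(base), 3, 2)))
  r2 <- dna_backbone_rmsd_series(tr2, fit_on, measure_on)
  expect_equal(r2, c(0, d), tolerance = 1e-9)
  expect_error(dna_backbone_rmsd_series(toy$trajectory, integer(0),
                                        measure_on), "empty")
})

test_that("Gaussian jitter RMSD matches its analytic expectation", {
  # jittering every atom with sd sigma gives RMSD ~ sigma * sqrt(3) once the
  # fitting selection is large enough for the fit to be stable
  toy <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 400,
                                  sigma = 0.5, seed = 31))
  top <- toy$trajectory$topology
  fit_on <- select_atoms(top, class = c("protein", "heavy"))
  measure_on <- union(select_atoms(top, class = "dna_phosphate"),
                      select_atoms(top, class = "dna_sugar"))
  # reference: the unjittered base coordinates are frame-mean-free, so use a
  # zero-jitter twin as reference coordinates
  ref_toy <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 1,
                                      sigma = 0, seed = 31))
  r <- dna_backbone_rmsd_series(toy$trajectory, fit_on, measure_on,
                                reference = frame_coords(ref_toy$trajectory,
                                                         1))
  expect_equal(mean(r), 0.5 * sqrt(3), tolerance = 0.05)
})

test_that("tetramer planarity dihedral is exact and rotation-invariant", {
  mk_top <- function(pts) {
    at <- do.call(rbind, lapply(1:4, function(i)
      data.frame(chain = LETTERS[i], resno = 1, insert = "",
                 resname = "GLY", elety = "CA", element = "C",
                 x = pts[i, 1], y = pts[i, 2], z = pts[i, 3], occ = 1)))
    wk_structure(at)
  }
  # trans-ordered coplanar centroids -> 180 degrees
  planar <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  tr <- wk_trajectory(mk_top(planar), coords(mk_top(planar)))
  expect_equal(abs(tetramer_planarity(tr, list(c("A", "B"), c("C", "D")))),
               180)
  expect_equal(tetramer_planarity(tr, list(c("A", "B"), c("C", "D")),
                                  convention = "zero"), 0)
  # lifting the last centroid by a known angle gives the analytic dihedral:
  # with the bond axis along x, rotating (p4 - p3) out of plane by
  # (180 - ang) makes the torsion equal ang
  for (ang in c(30, 60, 120)) {
    th <- ang * pi / 180
    lifted <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0),
                    c(1, 1 + cos(pi - th), sin(pi - th)))
    tr2 <- wk_trajectory(mk_top(lifted), coords(mk_top(lifted)))
    got <- tetramer_planarity(tr2, list(c("A", "B"), c("C", "D")))
    expect_equal(abs(got), ang, tolerance = 1e-9)
  }
  # rigid rotation leaves the dihedral unchanged
  set.seed(8)
  R <- random_rotation()
  rot <- sweep(planar %*% t(R), 2, c(5, -3, 2), "+")
  tr3 <- wk_trajectory(mk_top(rot), coords(mk_top(rot)))
  expect_equal(abs(tetramer_planarity(tr3, list(c("A", "B"), c("C", "D")))),
               180, tolerance = 1e-9)
  # collinear centroids -> NA
  line <- cbind(1:4, 0, 0)
  tr4 <- wk_trajectory(mk_top(line), coords(mk_top(line)))
  expect_true(is.na(tetramer_planarity(tr4, list(c("A", "B"),
                                                 c("C", "D")))))
})

test_that("helix crossing angle recovers constructed geometries", {
  h1 <- ideal_helix(12)
  for (ang in c(0, 20, 40, 75)) {
    th <- ang * pi / 180
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                3, 3, byrow = TRUE)
    h2 <- transform_structure(ideal_helix(12, chain = "B"), R, c(9, 0, 0))
    s <- wk_structure(rbind(h1$atoms, h2$atoms))
    got <- helix_crossing_angle(s, list(chain = "A", resno = 1:12),
                                list(chain = "B", resno = 1:12))
    expect_equal(got$angle, ang, tolerance = 0.1)
  }
  # antiparallel: second helix flipped by 180 about x
  Rflip <- diag(c(1, -1, -1))
  h3 <- transform_structure(ideal_helix(12, chain = "B"), Rflip, c(9, 0, 10))
  s3 <- wk_structure(rbind(h1$atoms, h3$atoms))
  got3 <- helix_crossing_angle(s3, list(chain = "A", resno = 1:12),
                               list(chain = "B", resno = 1:12))
  expect_equal(got3$angle, 0, tolerance = 0.1)
  expect_true(got3$antiparallel)
  expect_error(helix_crossing_angle(s3, list(chain = "A", resno = 1:4),
                                    list(chain = "B", resno = 1:12)),
               "at least 6")
})

test_that("wrap coverage counts base pairs within the contact cutoff", {
  toy <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 1, sigma = 0,
                                  seed = 2))
  wc <- wrap_coverage(toy$protein, toy$dna_segments[[1]])
  expect_equal(wc$bp_in_contact, 67)
  expect_equal(wc$longest_run, 67)
  expect_gt(wc$angular_coverage, 350)
  # DNA displaced far away -> nothing wrapped
  far <- set_coords(toy$dna_segments[[1]],
                    sweep(coords(toy$dna_segments[[1]]), 2, c(200, 0, 0),
                          "+"))
  attr(far, "bp_map") <- attr(toy$dna_segments[[1]], "bp_map")
  wc0 <- wrap_coverage(toy$protein, far)
  expect_equal(wc0$bp_in_contact, 0)
  # partial wrap: equals the generator's brute-force ground truth
  part <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 1,
                                   sigma = 0, wrapped_bp = 40, seed = 3))
  wp <- wrap_coverage(part$protein, part$dna_segments[[1]])
  expect_identical(wp$wrapped, part$ground_truth$wrapped_bp)
  expect_identical(wp$bp_in_contact, sum(part$ground_truth$wrapped_bp))
})

test_that("free-energy landscapes normalize, anchor at zero and rank basins", {
  # two occupied bins with P = 0.75/0.25 -> F = 0 at the mode and kT ln 3 at
  # the minor bin; the two unvisited bins stay undefined (NA, never Inf)
  kT <- 2.577
  f2 <- free_energy_landscape(c(rep(0, 75), rep(1, 25)),
                              c(rep(0, 75), rep(1, 25)), kT = kT, bins = 2)
  expect_equal(sum(f2$P), 1)
  vals <- sort(f2$F[!is.na(f2$F)])
  expect_equal(vals, c(0, kT * log(3)), tolerance = 1e-12)
  expect_equal(sum(is.na(f2$F)), 2)
  expect_false(any(is.infinite(f2$F)))
  # doubling all counts leaves F unchanged (normalization invariance)
  x <- rnorm(400); y <- rnorm(400)
  fa <- free_energy_landscape(x, y, bins = 10)
  fb <- free_energy_landscape(c(x, x), c(y, y), bins = 10)
  expect_equal(fa$F, fb$F, tolerance = 1e-9)
  # narrow ensemble has the smaller 1 kT basin than a wide one
  set.seed(12)
  narrow <- free_energy_landscape(rnorm(4000, 0, 0.5), rnorm(4000, 0, 0.5),
                                  bins = 40)
  wide <- free_energy_landscape(rnorm(4000, 0, 2), rnorm(4000, 0, 2),
                                bins = 40)
  expect_lt(narrow$basin$area, wide$basin$area)
  # analytic check: area within 1 kT of the minimum for a 2-D Gaussian is
  # pi * 2 * sigma^2 (since F = kT r^2 / (2 sigma^2))
  expect_equal(narrow$basin$area, 2 * pi * 0.5^2, tolerance = 0.35)
  expect_error(free_energy_landscape(c(1, 1), c(1, 2)), "distinct")
})

test_that("geometric measures are invariant under global rigid transforms", {
  toy <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 2,
                                  sigma = 0.2, seed = 13))
  top <- toy$trajectory$topology
  fit_on <- select_atoms(top, class = c("protein", "heavy"))
  measure_on <- select_atoms(top, class = "dna_phosphate")
  r_base <- dna_backbone_rmsd_series(toy$trajectory, fit_on, measure_on)
  set.seed(14)
  for (i in 1:3) {
    R <- random_rotation(); tr <- rnorm(3, 0, 20)
    xyz2 <- toy$trajectory$xyz
    for (f in 1:2) xyz2[, , f] <- sweep(xyz2[, , f] %*% t(R), 2, tr, "+")
    t2 <- wk_trajectory(top, xyz2)
    expect_equal(dna_backbone_rmsd_series(t2, fit_on, measure_on), r_base,
                 tolerance = 1e-9)
    wc2 <- wrap_coverage(
      transform_structure(toy$protein, R, tr),
      {s <- transform_structure(toy$dna_segments[[1]], R, tr)
       attr(s, "bp_map") <- attr(toy$dna_segments[[1]], "bp_map"); s})
    expect_equal(wc2$bp_in_contact,
                 wrap_coverage(toy$protein,
                               toy$dna_segments[[1]])$bp_in_contact)
  }
})
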