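# Contact counting, binding sites, fluctuation, smoothing, moieties, H-bonds.

test_that("contact counting respects the inclusive 4 A boundary", {
  xyz <- rbind(c(0, 0, 0), c(3.99, 0, 0), c(4.01, 0, 0))
  expect_equal(count_contacts(xyz, 1, 2)$count, 1)
  expect_equal(count_contacts(xyz, 1, 3)$count, 0)
  # complete bipartite: 3 A-atoms all within 4 A of 2 B-atoms
  xyz2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                c(0, 0, 3), c(1, 1, 2))
  expect_equal(count_contacts(xyz2, 1:3, 4:5)$count, 6)
  expect_error(count_contacts(xyz2, 1:3, 3:5), "overlap")
})

test_that("cell-list contact counts equal the all-pairs brute-force oracle", {
  set.seed(42)
  for (rep in 1:25) {
    n <- 500
    xyz <- matrix(runif(n * 3, 0, 25), ncol = 3)
    setA <- 1:200; setB <- 201:500
    cc <- count_contacts(xyz, setA, setB, method = "cell")
    expect_identical(cc$count, brute_contacts(xyz, setA, setB))
    dense <- count_contacts(xyz, setA, setB, method = "dense")$pairs
    expect_identical(dense[, c("i", "j")], cc$pairs[, c("i", "j")])
    expect_equal(dense$dist, cc$pairs$dist, tolerance = 1e-9)
    # pair list is sorted and distances are correct
    expect_false(is.unsorted(cc$pairs$i))
    if (nrow(cc$pairs))
      expect_equal(cc$pairs$dist,
                   sqrt(rowSums((xyz[cc$pairs$i, , drop = FALSE] -
                                   xyz[cc$pairs$j, , drop = FALSE])^2)))
  }
})

test_that("contact counts are invariant under rigid-body motion", {
  set.seed(7)
  xyz <- matrix(runif(300, 0, 15), ncol = 3)
  base <- count_contacts(xyz, 1:40, 41:100)
  for (i in 1:5) {
    R <- random_rotation()
    tr <- rnorm(3, 0, 30)
    moved <- sweep(xyz %*% t(R), 2, tr, "+")
    cc <- count_contacts(moved, 1:40, 41:100)
    expect_identical(cc$count, base$count)
    expect_identical(cc$pairs[, c("i", "j")], base$pairs[, c("i", "j")])
  }
})

test_that("binding fluctuation is the zero-mean deviation from the average", {
  expect_equal(binding_fluctuation(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(binding_fluctuation(c(1, 3)), c(-1, 1))
  set.seed(3)
  x <- rpois(500, 20)
  expect_lt(abs(sum(binding_fluctuation(x))), 1e-9)
  expect_error(binding_fluctuation(numeric(0)), "at least one")
})

test_that("centered moving-average smoothing matches direct re-computation", {
  expect_equal(smooth_series(rep(4, 20), 5), rep(4, 20))
  # impulse -> plateau of height 1/w
  x <- rep(0, 51); x[26] <- 1
  sm <- smooth_series(x, 7)
  expect_equal(sm[26], 1 / 7)
  expect_equal(sum(sm > 0), 7)
  # brute-force truncated-window oracle on a random series
  set.seed(9)
  y <- rnorm(200)
  w <- 11; half <- 5
  oracle <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - half):min(length(y), i + half)]), numeric(1))
  expect_equal(smooth_series(y, w), oracle, tolerance = 1e-12)
  # even windows are made odd; oversized windows error
  expect_equal(smooth_series(y, 10), smooth_series(y, 11))
  expect_error(smooth_series(y, 300), "exceeds")
})

test_that("canonical sites are four disjoint (chain, residue) sets", {
  toy <- gen_toy_complex(toy_spec(n_frames = 1, sigma = 0))
  top <- toy$trajectory$topology
  sites <- define_canonical_sites(top, chains = c("A", "B", "C", "D"))
  expect_named(sites, c("A-site 1", "A-site 2", "B-site 1", "B-site 2"))
  keys <- lapply(sites, function(s) paste(s$residues$chain, s$residues$resno))
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(keys[[i]], keys[[j]]), 0)
  # custom single-residue site is valid; absent residues error
  expect_s3_class(binding_site("custom", data.frame(chain = "A", resno = 13),
                               top), "binding_site")
  expect_error(binding_site("bad", data.frame(chain = "A", resno = 999), top),
               "absent")
})

test_that("contact series match the generator's planted engagement pattern", {
  wrap <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 40,
                                   sigma = 0.3, seed = 21))
  cs <- contact_series(wrap$trajectory, wrap$sites, wrap$dna_atoms)
  expect_true(all(cs$site_stats$mean > 0))
  expect_equal(classify_binding_mode(cs), "wrapping")
  expect_lt(abs(mean(cs$frame$fluctuation)), 1e-9)

  bridge <- gen_toy_complex(toy_spec(mode = "bridging", n_frames = 40,
                                     sigma = 0.3, seed = 22))
  cb <- contact_series(bridge$trajectory, bridge$sites, bridge$dna_atoms)
  st <- setNames(cb$site_stats$mean, cb$site_stats$site)
  expect_lt(st[["A-site 1"]], 0.5)
  expect_lt(st[["A-site 2"]], 0.5)
  expect_gt(st[["B-site 1"]], 5)
  expect_gt(st[["B-site 2"]], 5)
  expect_equal(classify_binding_mode(cb), "bridging")

  # single-frame series: length 1, SD 0
  one <- gen_toy_complex(toy_spec(mode = "wrapping", n_frames = 1, sigma = 0))
  c1 <- contact_series(one$trajectory, one$sites, one$dna_atoms)
  expect_equal(nrow(c1$frame), 1)
  expect_equal(c1$sd, 0)
  expect_true(all(c1$site_stats$sd == 0))
})

test_that("moiety classification is conserved and matches planted contacts", {
  d <- build_bdna("ACGT")
  prot <- data.frame(chain = "P", resno = 1, insert = "", resname = "LYS",
                     elety = "NZ", element = "N", x = 0, y = 0, z = 0,
                     occ = 1)
  s <- wk_structure(rbind(prot, d$atoms))
  # single P...NZ pair
  pidx <- which(s$atoms$elety == "P")[1]
  tab <- classify_contact_moieties(data.frame(i = 1, j = pidx, dist = 3), s)
  expect_equal(tab["phosphate", "sidechain"], 1)
  expect_equal(sum(tab), 1)
  # contacts placed only on sugar atoms -> sugar row carries the total
  sidx <- select_atoms(s, class = "dna_sugar")
  pairs <- data.frame(i = 1, j = sidx[1:5], dist = 3)
  tab2 <- classify_contact_moieties(pairs, s)
  expect_equal(sum(tab2["sugar", ]), 5)
  expect_equal(sum(tab2), 5)
  # marginals always sum to the pair count
  set.seed(5)
  dna_heavy <- select_atoms(s, class = "dna", element = c("C", "N", "O", "P"))
  pr <- data.frame(i = 1, j = sample(dna_heavy, 30, replace = TRUE), dist = 3)
  expect_equal(sum(classify_contact_moieties(pr, s)), 30)
})

test_that("hydrogen-bond and salt-bridge occupancy count satisfied frames", {
  at <- data.frame(chain = c("A", "A", "E"), resno = c(1, 1, 1),
                   resname = c("SER", "SER", "DA"),
                   elety = c("OG", "HG", "OP1"),
                   element = c("O", "H", "O"),
                   x = c(0, 0.6, 2.8), y = c(0, 0.7, 0.4), z = 0, occ = 1)
  top <- wk_structure(at)
  base <- coords(top)
  # all 10 frames satisfied
  xyz <- array(rep(base, 10), c(3, 3, 10))
  tr <- wk_trajectory(top, xyz)
  occ <- hbond_occupancy(tr, donors = 1, acceptors = 3)
  expect_equal(occ$occupancy, 1)
  expect_true(occ$persistent)
  # 4 of 10 frames satisfied -> not persistent at 0.5
  far <- base; far[3, 1] <- 8
  xyz2 <- array(c(rep(base, 4), rep(far, 6)), c(3, 3, 10))
  tr2 <- wk_trajectory(top, xyz2)
  occ2 <- hbond_occupancy(tr2, donors = 1, acceptors = 3)
  expect_equal(occ2$occupancy, 0.4)
  expect_false(occ2$persistent)
  # salt-bridge mode: charged-group distance only (<= 4 A)
  sb <- hbond_occupancy(tr2, donors = 1, acceptors = 3, mode = "saltbridge")
  expect_equal(sb$occupancy, 0.4)
  expect_warning(hbond_occupancy(tr, donors = integer(0), acceptors = 3),
                 "no donors")
})
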