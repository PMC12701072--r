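# Synthetic fixture generators with serialized ground truth ----------------------
#
# These generators emulate the statistical structure the analysis assumes --
# planted heavy-atom contacts at known sites, staircase unwrapping work,
# log-linear gel migration, logistic/isotherm titrations -- so every stage of
# the pipeline is testable without external data. They carry no force-field
# physics: pseudo-atoms use real atom names and elements so the production
# selection and contact code paths are exercised unchanged.

.site_contact_atom <- c(ALA = "CB", SER = "OG", LYS = "NZ", THR = "OG1",
                        ARG = "NH1", GLY = "CA", ASP = "OD1")
.site_resname <- c(`13` = "ALA", `14` = "SER", `15` = "LYS", `17` = "LYS",
                   `21` = "LYS", `27` = "THR", `29` = "GLY", `54` = "LYS",
                   `56` = "THR", `57` = "THR", `59` = "ARG")

#' Specification of a toy wrapping/bridging complex
#'
#' @param mode `"wrapping"` (one closed-circle duplex) or `"bridging"` (two
#'   straight duplexes).
#' @param n_bp duplex length: total (wrapping, default 67) or per segment
#'   (bridging, default 32).
#' @param engaged which canonical sites carry planted contacts. Defaults:
#'   all four (wrapping); B-sites only (bridging). Engaging an A-site in
#'   bridging mode is an impossible-geometry request and errors.
#' @param sigma per-atom Gaussian jitter SD per frame, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed; fixed seed gives bitwise-reproducible output.
#' @param wrapped_bp wrapping mode only: how many (contiguous) base pairs the
#'   protein surface ring tracks within contact distance (default all).
#' @param dna_wobble per-frame rigid random-direction DNA translation
#'   magnitude, Angstrom (default 0); sets the DNA-backbone RMSD scale.
#' @return validated `toy_spec` list.
#' @export
toy_spec <- function(mode = c("wrapping", "bridging"), n_bp = NULL,
                     engaged = NULL, sigma = 0.3, n_frames = 100, seed = 1,
                     wrapped_bp = NULL, dna_wobble = 0) {
  mode <- match.arg(mode)
  if (is.null(n_bp)) n_bp <- if (mode == "wrapping") 67 else 32
  all_sites <- c("A-site 1", "A-site 2", "B-site 1", "B-site 2")
  if (is.null(engaged))
    engaged <- if (mode == "wrapping") all_sites else
      c("B-site 1", "B-site 2")
  if (!all(engaged %in% all_sites))
    stop("unknown site(s): ", paste(setdiff(engaged, all_sites),
                                    collapse = ", "))
  if (mode == "bridging" && any(grepl("^A-site", engaged)))
    stop("impossible geometry: two separate straight segments cannot engage ",
         "the A-sites")
  if (sigma < 0) stop("sigma must be >= 0")
  if (is.null(wrapped_bp)) wrapped_bp <- n_bp
  if (wrapped_bp > n_bp) stop("wrapped_bp cannot exceed n_bp")
  structure(list(mode = mode, n_bp = n_bp, engaged = engaged, sigma = sigma,
                 n_frames = n_frames, seed = seed, wrapped_bp = wrapped_bp,
                 dna_wobble = dna_wobble), class = "toy_spec")
}

# place a point along direction v from anchor such that its minimum distance
# to the full coordinate set equals `target`
.plant_point <- function(anchor, v, dna_xyz, target) {
  f <- function(t) {
    p <- anchor + t * v
    min(sqrt(colSums((t(dna_xyz) - p)^2))) - target
  }
  t0 <- stats::uniroot(f, c(0, 4 * target), extendInt = "upX")$root
  anchor + t0 * v
}

#' Generate a toy wrapping/bridging complex trajectory with ground truth
#'
#' Builds a coarse tetramer (four pseudo-monomer chains carrying the
#' canonical site residues with real atom names) around idealized B-DNA --
#' a closed circle (wrapping) or two straight duplexes (bridging). Engaged
#' sites receive contact atoms planted at exactly 3.5 A from their nearest
#' DNA heavy atom; disengaged site atoms sit >= 6 A from all DNA. Frames add
#' Gaussian jitter (and optionally a rigid per-frame DNA displacement).
#'
#' @param spec a [toy_spec()].
#' @return `list(trajectory, sites, dna_atoms, ground_truth)`; `sites` are
#'   the four canonical `binding_site`s on the toy tetramer, `dna_atoms` the
#'   DNA atom indices, and `ground_truth` records the planted engagement
#'   pattern, contact pairs, per-bp wrapped flags (brute-force distances at
#'   zero jitter) and the generator parameters.
#' @export
gen_toy_complex <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  h <- 3.4
  site_az <- c(`B-site 1` = 90, `A-site 1` = 180, `B-site 2` = 270,
               `A-site 2` = 0)
  site_chains <- list(`A-site 1` = c("B", "C"), `A-site 2` = c("D", "A"),
                      `B-site 1` = c("A", "B"), `B-site 2` = c("C", "D"))
  a_res <- c(27, 29, 56, 57, 54, 59)
  b_res <- c(13, 14, 15, 17, 21)

  # --- DNA ---
  seq_n <- function(n) paste(rep_len(c("A", "C", "G", "T"), n), collapse = "")
  if (spec$mode == "wrapping") {
    kappa <- 2 * pi / (spec$n_bp * h)
    dna <- build_bdna(duplex_spec(seq_n(spec$n_bp), curvature = kappa),
                      chains = c("E", "F"))
    # center the circle on the origin (arc center is at (-R, 0, 0))
    xyz <- sweep(coords(dna), 2, c(-1 / kappa, 0, 0))
    dna <- set_coords(dna, xyz)
    segs <- list(dna)
  } else {
    d_off <- 24
    seg1 <- build_bdna(duplex_spec(seq_n(spec$n_bp)), chains = c("E", "F"))
    seg2 <- build_bdna(duplex_spec(seq_n(spec$n_bp)), chains = c("G", "H"))
    place <- function(s, ysign) {
      xyz <- coords(s)
      L <- (spec$n_bp - 1) * h
      # duplex axis along x at y = ysign * d_off
      M <- .rot_between(c(0, 0, 1), c(1, 0, 0))
      xyz <- xyz %*% t(M)
      xyz[, 1] <- xyz[, 1] - L / 2
      xyz[, 2] <- xyz[, 2] + ysign * d_off
      set_coords(s, xyz)
    }
    segs <- list(place(seg1, +1), place(seg2, -1))
    bm2 <- attr(seg2, "bp_map")
    segs[[1]] <- `attr<-`(segs[[1]], "bp_map", attr(seg1, "bp_map"))
    segs[[2]] <- `attr<-`(segs[[2]], "bp_map", bm2)
  }
  dna_atoms_df <- do.call(rbind, lapply(segs, function(s) s$atoms))
  dna_xyz <- as.matrix(dna_atoms_df[, c("x", "y", "z")])
  dna_heavy <- !(dna_atoms_df$element %in% c("H", "D"))

  # --- protein ---
  rows <- list()
  planted <- list()
  add_atom <- function(chain, resno, resname, elety, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resname = resname,
      elety = elety, element = infer_element(elety),
      x = p[1], y = p[2], z = p[3], occ = 1, stringsAsFactors = FALSE)
  }
  # monomer cores near the center so they stay far from the DNA
  for (m in 1:4) {
    ch <- LETTERS[m]
    th <- (45 + 90 * (m - 1)) * pi / 180
    cen <- 3 * c(cos(th), sin(th), 0)
    for (r in 1:3)
      add_atom(ch, r, "GLY", "CA", cen + c(cos(r), sin(r), r - 2))
  }
  for (sname in names(site_az)) {
    res <- if (grepl("^A-site", sname)) a_res else b_res
    chs <- site_chains[[sname]]
    eng <- sname %in% spec$engaged
    m <- length(res) * 2
    offs <- seq(-15, 15, length.out = m)
    k <- 0
    for (ci in 1:2) for (r in res) {
      k <- k + 1
      az <- (site_az[[sname]] + offs[k]) * pi / 180
      u <- c(cos(az), sin(az), 0)
      resname <- .site_resname[[as.character(r)]]
      atomname <- .site_contact_atom[[resname]]
      if (eng) {
        # anchor: DNA heavy atom nearest to this azimuth ray, inner side
        proj <- dna_xyz %*% u
        perp2 <- rowSums(dna_xyz^2) - proj^2
        cand <- which(dna_heavy & proj > 0)
        anchor_i <- cand[which.min(perp2[cand] + pmax(0, -proj[cand]))]
        anchor <- dna_xyz[anchor_i, ]
        v <- -anchor / sqrt(sum(anchor^2))
        p <- .plant_point(anchor, v, dna_xyz[dna_heavy, , drop = FALSE], 3.5)
        planted[[length(planted) + 1]] <- data.frame(
          site = sname, chain = chs[ci], resno = r, elety = atomname,
          dist = 3.5, stringsAsFactors = FALSE)
      } else {
        p <- 3.5 * u + c(0, 0, 0.3 * k)
      }
      add_atom(chs[ci], r, resname, atomname, p)
      if (atomname != "CA")
        add_atom(chs[ci], r, resname, "CA", p - 1.5 * (p / sqrt(sum(p^2))))
    }
  }
  # wrapping surface ring: one pseudo-CA per wrapped bp at 3.6 A
  wrapped_idx <- integer(0)
  if (spec$mode == "wrapping" && spec$wrapped_bp > 0) {
    wrapped_idx <- seq_len(spec$wrapped_bp)
    bm <- attr(segs[[1]], "bp_map")
    a <- segs[[1]]$atoms
    for (i in wrapped_idx) {
      j <- which((a$chain == bm$chain1[i] & a$resno == bm$resno1[i]) |
                   (a$chain == bm$chain2[i] & a$resno == bm$resno2[i]))
      j <- j[!(a$element[j] %in% c("H", "D"))]
      bxyz <- as.matrix(a[j, c("x", "y", "z")])
      rad <- sqrt(bxyz[, 1]^2 + bxyz[, 2]^2)
      anchor <- bxyz[which.min(rad), ]
      v <- -c(anchor[1], anchor[2], 0)
      v <- v / sqrt(sum(v^2))
      # plant inward of this base pair so it is wrapped by construction
      # (own-bp distance as close to 3.6 A as possible) while keeping a
      # >= 3.2 A clearance from every other DNA atom
      all_h <- dna_xyz[dna_heavy, , drop = FALSE]
      near <- colSums((t(all_h) - anchor)^2) < 14^2
      all_h <- all_h[near, , drop = FALSE]
      ts <- seq(0.8, 6, by = 0.1)
      own <- vapply(ts, function(t)
        min(sqrt(colSums((t(bxyz) - (anchor + t * v))^2))), numeric(1))
      glob <- vapply(ts, function(t)
        min(sqrt(colSums((t(all_h) - (anchor + t * v))^2))), numeric(1))
      feas <- own <= 3.9 & glob >= 3.2
      tsel <- if (any(feas)) ts[feas][which.min(abs(own[feas] - 3.6))] else
        ts[which.max(glob - 10 * pmax(0, own - 3.9))]
      p <- anchor + tsel * v
      add_atom(LETTERS[(i - 1) %% 4 + 1], 100 + i, "GLY", "CA", p)
    }
  }
  prot <- do.call(rbind, rows)
  topo_atoms <- rbind(prot, dna_atoms_df)
  rownames(topo_atoms) <- NULL
  topology <- wk_structure(topo_atoms)
  dna_idx <- seq(nrow(prot) + 1, nrow(topo_atoms))

  # brute-force per-bp wrapped flags at zero jitter (ground truth)
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  gt_wrapped <- NULL
  if (spec$mode == "wrapping") {
    bm <- attr(segs[[1]], "bp_map")
    a <- segs[[1]]$atoms
    gt_wrapped <- vapply(seq_len(nrow(bm)), function(i) {
      j <- which((a$chain == bm$chain1[i] & a$resno == bm$resno1[i]) |
                   (a$chain == bm$chain2[i] & a$resno == bm$resno2[i]))
      j <- j[!(a$element[j] %in% c("H", "D"))]
      b <- as.matrix(a[j, c("x", "y", "z")])
      d2 <- outer(rowSums(b^2), rowSums(prot_xyz^2), "+") -
        2 * b %*% t(prot_xyz)
      sqrt(max(min(d2), 0)) <= 4
    }, logical(1))
  }

  # frames
  base <- coords(topology)
  nf <- spec$n_frames
  xyz <- array(NA_real_, c(nrow(base), 3, nf))
  for (f in seq_len(nf)) {
    fr <- base + matrix(stats::rnorm(length(base), 0, spec$sigma),
                        ncol = 3)
    if (spec$dna_wobble > 0) {
      dvec <- stats::rnorm(3)
      dvec <- spec$dna_wobble * dvec / sqrt(sum(dvec^2))
      fr[dna_idx, ] <- sweep(fr[dna_idx, , drop = FALSE], 2, dvec, "+")
    }
    xyz[, , f] <- fr
  }
  traj <- wk_trajectory(topology, xyz, dt = 0.1)
  sites <- define_canonical_sites(topology, chains = c("A", "B", "C", "D"))
  gt <- list(mode = spec$mode, engaged = spec$engaged,
             planted_pairs = if (length(planted)) do.call(rbind, planted)
             else data.frame(),
             wrapped_bp = gt_wrapped, sigma = spec$sigma, seed = spec$seed,
             n_frames = nf, dna_wobble = spec$dna_wobble)
  list(trajectory = traj, sites = sites, dna_atoms = dna_idx,
       protein = wk_structure(prot), dna_segments = segs,
       bp_map = attr(segs[[1]], "bp_map"), ground_truth = gt)
}

#' Generate a synthetic steered-unwrapping pulling series
#'
#' The force profile is a sum of Gaussian bumps whose integrals equal the
#' planted barrier heights, so the cumulative work is an analytic staircase.
#' Site-contact series are co-generated: each barrier's site loses its
#' contacts sigmoidally at the barrier position.
#'
#' @param barriers data frame with columns `xi` (positions, Angstrom),
#'   `height` (kJ/mol) and `site` (labels). Default: the two-barrier
#'   staircase (500 kJ/mol at B-site 2, then 400 kJ/mol at A-site 2).
#' @param xi_max end of the pulling coordinate (default 45).
#' @param n samples (default 1501).
#' @param width Gaussian bump SD (default 1.2).
#' @param noise force noise SD, kJ/mol/A (default 0).
#' @param c0 initial per-site contact count (default 30).
#' @param seed RNG seed.
#' @return `list(series, site_contacts, ground_truth)`.
#' @export
gen_smd_series <- function(barriers = data.frame(
                             xi = c(12, 28), height = c(500, 400),
                             site = c("B-site 2", "A-site 2"),
                             stringsAsFactors = FALSE),
                           xi_max = 45, n = 1501, width = 1.2, noise = 0,
                           c0 = 30, seed = 1) {
  set.seed(seed)
  xi <- seq(0, xi_max, length.out = n)
  force <- rep(0, n)
  for (b in seq_len(nrow(barriers)))
    force <- force + barriers$height[b] *
      stats::dnorm(xi, barriers$xi[b], width)
  if (noise > 0) force <- force + stats::rnorm(n, 0, noise)
  ser <- pulling_series(xi, force, units = "A")
  sc <- data.frame(xi = xi)
  for (b in seq_len(nrow(barriers)))
    sc[[barriers$site[b]]] <- c0 * stats::pnorm(xi, barriers$xi[b], width,
                                                lower.tail = FALSE) +
      if (noise > 0) stats::rnorm(n, 0, noise / 10) else 0
  analytic_W <- function(x) {
    out <- 0
    for (b in seq_len(nrow(barriers)))
      out <- out + barriers$height[b] * stats::pnorm(x, barriers$xi[b], width)
    out
  }
  list(series = ser, site_contacts = sc,
       ground_truth = list(barriers = barriers, width = width, noise = noise,
                           seed = seed, analytic_W = analytic_W))
}

#' Generate a synthetic gel lane (and matching marker lane)
#'
#' Gaussian bands placed through a monotone log-linear migration model
#' `position = a - b * log10(size_bp)`, with additive Gaussian noise.
#'
#' @param sizes planted fragment sizes, bp (default the 35-72 bp
#'   protection-ladder range: 35, 46, 72).
#' @param marker_sizes marker fragment sizes (default: ultra-low-range
#'   ladder, 10-300 bp).
#' @param a,b migration model intercept/slope (profile units).
#' @param band_sd Gaussian band width (default 6).
#' @param amplitude band amplitude (default 100).
#' @param noise additive noise SD (default 0.5).
#' @param n_pos profile grid length (default 1000).
#' @param seed RNG seed.
#' @return `list(sample, marker, marker_sizes, ground_truth)`; lanes are
#'   [lane_profile()]s; ground truth has planted sizes, positions, model
#'   parameters, and an `unresolved` flag per planted band (bands closer
#'   than `2.5 * band_sd` merge).
#' @export
gen_gel_lane <- function(sizes = c(35, 46, 72),
                         marker_sizes = c(10, 15, 20, 25, 35, 50, 75, 100,
                                          150, 200, 300),
                         a = 1050, b = 400, band_sd = 6, amplitude = 100,
                         noise = 0.5, n_pos = 1000, seed = 1) {
  set.seed(seed)
  x <- seq_len(n_pos)
  migrate <- function(bp) a - b * log10(bp)
  mk <- function(bps) {
    y <- rep(0, n_pos)
    for (bp in bps) y <- y + amplitude * exp(-(x - migrate(bp))^2 /
                                               (2 * band_sd^2))
    if (noise > 0) y <- y + abs(stats::rnorm(n_pos, 0, noise))
    lane_profile(x, y)
  }
  pos <- migrate(sizes)
  unresolved <- vapply(seq_along(pos), function(i)
    any(abs(pos[-i] - pos[i]) < 2.5 * band_sd), logical(1))
  list(sample = mk(sizes), marker = mk(marker_sizes),
       marker_sizes = marker_sizes,
       ground_truth = list(sizes = sizes, positions = pos, a = a, b = b,
                           band_sd = band_sd, noise = noise, seed = seed,
                           unresolved = unresolved))
}

#' Generate a synthetic titration table
#'
#' @param model `"logistic"` (TPM-style RMS-vs-concentration decay) or
#'   `"isotherm"` (fraction bound vs concentration).
#' @param params logistic: `list(rms0, rms_min, c50, k)` (defaults 140 nm,
#'   80 nm, 1500 nM, 2); isotherm: `list(kd, bmax, n)` (defaults 2, 1, 1).
#' @param conc concentrations; defaults: 0 plus log-spaced 50-20000 nM
#'   (logistic) or log-spaced 0.02-200 (isotherm).
#' @param noise replicate noise SD in response units.
#' @param replicates technical replicates per concentration (default 3).
#' @param seed RNG seed.
#' @return `list(data, ground_truth)`; `data` has `conc`, `mean`, `sd` and
#'   the replicate matrix as attribute `replicates`.
#' @export
gen_titration <- function(model = c("logistic", "isotherm"), params = NULL,
                          conc = NULL, noise = 0, replicates = 3, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  if (model == "logistic") {
    params <- utils::modifyList(list(rms0 = 140, rms_min = 80, c50 = 1500,
                                     k = 2), params %||% list())
    if (is.null(conc))
      conc <- c(0, 10^seq(log10(50), log10(20000), length.out = 11))
    truth <- with(params, rms_min + (rms0 - rms_min) / (1 + (conc / c50)^k))
  } else {
    params <- utils::modifyList(list(kd = 2, bmax = 1, n = 1),
                                params %||% list())
    if (is.null(conc)) conc <- 10^seq(log10(0.02), log10(200),
                                      length.out = 12)
    truth <- with(params, bmax * conc^n / (kd^n + conc^n))
  }
  reps <- matrix(rep(truth, replicates), ncol = replicates)
  if (noise > 0) reps <- reps + matrix(stats::rnorm(length(reps), 0, noise),
                                       ncol = replicates)
  data <- data.frame(conc = conc, mean = rowMeans(reps),
                     sd = apply(reps, 1, stats::sd))
  attr(data, "replicates") <- reps
  list(data = data,
       ground_truth = c(params, list(model = model, noise = noise,
                                     seed = seed, truth = truth)))
}

#' Ideal alpha-helix CA trace as a structure
#'
#' @param n residues (default 12).
#' @param radius helix radius, A (default 2.3).
#' @param rise rise per residue, A (default 1.5).
#' @param twist twist per residue, degrees (default 100).
#' @param chain chain id.
#' @param start_resno first residue number.
#' @return `wk_structure` of ALA CA atoms winding about the z axis.
#' @export
ideal_helix <- function(n = 12, radius = 2.3, rise = 1.5, twist = 100,
                        chain = "A", start_resno = 1) {
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180
  atoms <- data.frame(chain = chain, resno = start_resno + i, insert = "",
                      resname = "ALA", elety = "CA", element = "C",
                      x = radius * cos(th), y = radius * sin(th),
                      z = i * rise, occ = 1, stringsAsFactors = FALSE)
  wk_structure(atoms)
}

#' Apply a rigid transform to a structure
#' @param s a `wk_structure`.
#' @param rotation 3x3 matrix (default identity).
#' @param translation length-3 vector (default 0).
#' @return transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  set_coords(s, sweep(coords(s) %*% t(rotation), 2, translation, "+"))
}

#' Serialize / restore generator ground truth
#'
#' Plain-text serialization (R `dput` with hex-exact numerics) so that ground
#' truth round-trips losslessly alongside a fixture. Closures (such as
#' analytic work functions) are dropped with a note.
#'
#' @param gt ground-truth list.
#' @param path output file.
#' @return `path` invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  gt <- gt[!vapply(gt, is.function, logical(1))]
  dput(gt, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) dget(path)
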