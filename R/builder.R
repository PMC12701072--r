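# Idealized B-DNA construction and model assembly -------------------------------

# Base heavy-atom coordinates in the standard base-pair reference frame
# (x toward the major groove, y toward strand I's backbone, z along the helix
# axis; base planes idealized as z = 0). Values follow the conventional
# reference-frame geometry to ~0.05 A, which is ample for heavy-atom contact
# and wrapping metrics.
.base_xy <- list(
  DA = rbind(N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897), N7 = c(0.877, 3.902),
             C5 = c(0.071, 2.771), C6 = c(0.369, 1.398), N6 = c(1.611, 0.909),
             N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023),
             N3 = c(-2.320, 2.290), C4 = c(-1.267, 3.124)),
  DG = rbind(N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
             C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
             N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
             N2 = c(-2.949, 0.139), N3 = c(-2.342, 2.364),
             C4 = c(-1.265, 3.177)),
  DC = rbind(N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158),
             O2 = c(-2.628, 2.709), N3 = c(-0.391, 2.344),
             C4 = c(0.837, 2.868), N4 = c(1.875, 2.027),
             C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068)),
  DT = rbind(N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135),
             O2 = c(-2.562, 2.608), N3 = c(-0.298, 2.407),
             C4 = c(0.994, 2.897), O4 = c(1.944, 2.119),
             C5 = c(1.106, 4.338), C7 = c(2.466, 4.961),
             C6 = c(-0.024, 5.057)))

# Sugar-phosphate template for a strand-I nucleotide in the same frame.
# Approximate fiber geometry: P sits one step below the base plane so that
# O3'(i) lands within bonding distance of P(i+1) under (+36 deg, +3.4 A).
.backbone_xyz <- rbind(
  P     = c(-3.15, 8.35, -2.10),
  OP1   = c(-4.45, 9.05, -2.35),
  OP2   = c(-2.05, 9.10, -2.65),
  `O5'` = c(-3.30, 8.05, -0.65),
  `C5'` = c(-3.95, 7.30,  0.25),
  `C4'` = c(-4.55, 6.55,  1.10),
  `O4'` = c(-3.70, 5.50,  0.90),
  `C3'` = c(-5.55, 6.35,  1.25),
  `C2'` = c(-3.40, 6.60,  0.95),
  `O3'` = c(-6.35, 5.95,  1.30),
  `C1'` = c(-2.48, 5.35,  0.00))

.complement <- c(A = "T", C = "G", G = "C", T = "A")

# full heavy-atom template of a strand-I nucleotide of the given base (x,y,z)
.nt_template <- function(base) {
  b <- .base_xy[[paste0("D", base)]]
  rbind(.backbone_xyz[rownames(.backbone_xyz) != "C1'", , drop = FALSE],
        `C1'` = .backbone_xyz["C1'", ],
        cbind(b, 0))
}

# rotation matrices
.rotz <- function(th) matrix(c(cos(th), sin(th), 0,
                               -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
.rotx180 <- diag(c(1, -1, -1))

#' Specify an idealized B-DNA duplex
#'
#' @param sequence 5'->3' sequence of strand I (A/C/G/T).
#' @param rise axial rise per base pair, Angstrom (default 3.4).
#' @param twist helical twist per base pair, degrees (default 36; use ~34.3
#'   for a 10.5 bp/turn dialect).
#' @param curvature global axis curvature in 1/Angstrom; 0 builds a straight
#'   axis, `k > 0` bends the axis onto a circular arc of radius `1/k`.
#' @return a `duplex_spec` list, validated.
#' @export
duplex_spec <- function(sequence, rise = 3.4, twist = 36, curvature = 0) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (grepl("[^ACGT]", sequence))
    stop("sequence contains non-ACGT symbol(s): ",
         paste(unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]]),
               collapse = ""))
  if (rise <= 0) stop("rise must be > 0")
  if (twist <= 0 || twist >= 60) stop("twist must lie in (0, 60) deg/bp")
  n <- nchar(sequence)
  if (curvature < 0) stop("curvature must be >= 0")
  if (curvature * (n - 1) * rise > 2 * pi + 1e-9)
    stop("curvature * contour length exceeds 2*pi (self-intersecting arc)")
  structure(list(sequence = sequence, rise = rise, twist = twist,
                 curvature = curvature), class = "duplex_spec")
}

# base-pair frame i (0-based): origin + 3x3 orientation (columns = local xyz)
.bp_frame <- function(i, rise, twist, curvature) {
  tw <- .rotz(i * twist * pi / 180)
  if (curvature == 0) {
    list(origin = c(0, 0, i * rise), M = tw)
  } else {
    R <- 1 / curvature
    al <- i * rise * curvature
    origin <- c(R * cos(al) - R, R * sin(al), 0)   # bp0 at the global origin
    # local helix axis = arc tangent; local x kept radial (toward arc center)
    zl <- c(-sin(al), cos(al), 0)
    xl <- -c(cos(al), sin(al), 0)
    yl <- c(zl[2] * xl[3] - zl[3] * xl[2],
            zl[3] * xl[1] - zl[1] * xl[3],
            zl[1] * xl[2] - zl[2] * xl[1])
    list(origin = origin, M = cbind(xl, yl, zl) %*% tw)
  }
}

#' Build an idealized B-DNA duplex
#'
#' Places rigid nucleotide templates on successive base-pair frames along a
#' straight or circular-arc axis. Strand I is chain `A` (residues 1..n,
#' 5'->3'); strand II is chain `B` (its own 5'->3' numbering, exact reverse
#' complement). 5'-terminal nucleotides carry no phosphate group. Atom names
#' follow the PDB nucleotide convention (`DA`, `DC`, `DG`, `DT`).
#'
#' @param spec a [duplex_spec()] (or a bare sequence string, which is wrapped
#'   with default parameters).
#' @param chains length-2 chain identifiers.
#' @param twist_phase initial helical phase in degrees (rotates every
#'   nucleotide about its local helix axis; used when reconnecting built DNA
#'   to crystal-derived fragments).
#' @return a [wk_structure()] with attributes `bp_map` (data frame pairing
#'   residues of both strands per base pair) and `spec`.
#' @export
build_bdna <- function(spec, chains = c("A", "B"), twist_phase = 0) {
  if (is.character(spec)) spec <- duplex_spec(spec)
  stopifnot(inherits(spec, "duplex_spec"))
  seq1 <- strsplit(spec$sequence, "")[[1]]
  n <- length(seq1)
  rows <- vector("list", 2 * n)
  for (i in seq_len(n)) {
    fr <- .bp_frame(i - 1, spec$rise, spec$twist, spec$curvature)
    if (twist_phase != 0) fr$M <- fr$M %*% .rotz(twist_phase * pi / 180)
    b1 <- seq1[i]
    b2 <- .complement[[b1]]
    t1 <- .nt_template(b1)
    t2 <- .nt_template(b2) %*% t(.rotx180)   # dyad partner, antiparallel
    rownames(t2) <- rownames(.nt_template(b2))
    g1 <- sweep(t1 %*% t(fr$M), 2, fr$origin, "+")
    g2 <- sweep(t2 %*% t(fr$M), 2, fr$origin, "+")
    mk <- function(g, base, chain, resno, drop_p) {
      nm <- rownames(g)
      if (drop_p) {
        keep <- !(nm %in% c("P", "OP1", "OP2"))
        g <- g[keep, , drop = FALSE]; nm <- nm[keep]
      }
      data.frame(chain = chain, resno = resno, insert = "",
                 resname = paste0("D", base), elety = nm,
                 element = substr(nm, 1, 1),
                 x = g[, 1], y = g[, 2], z = g[, 3], occ = 1,
                 stringsAsFactors = FALSE)
    }
    # strand II runs antiparallel: residue j of chain B pairs bp (n + 1 - j)
    rows[[i]] <- mk(g1, b1, chains[1], i, drop_p = (i == 1))
    rows[[n + i]] <- mk(g2, b2, chains[2], n + 1 - i, drop_p = (i == n))
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(match(atoms$chain, chains), atoms$resno), ]
  rownames(atoms) <- NULL
  s <- wk_structure(atoms)
  attr(s, "bp_map") <- data.frame(bp = seq_len(n),
                                  chain1 = chains[1], resno1 = seq_len(n),
                                  chain2 = chains[2], resno2 = n:1)
  attr(s, "spec") <- spec
  s
}

#' Recover per-step rise and twist from a built duplex
#'
#' Re-derives each base-pair frame by least-squares superposition of the ideal
#' base-pair template onto the observed atoms, then reports per-step rise
#' (origin displacement along the step rotation axis) and twist (rotation
#' angle between successive frames).
#'
#' @param s duplex from [build_bdna()] (requires its `bp_map`/`spec`
#'   attributes or an explicit `bp_map`).
#' @param bp_map optional base-pair mapping data frame.
#' @return data frame with one row per step: `rise`, `twist` (degrees).
#' @export
measure_duplex_params <- function(s, bp_map = attr(s, "bp_map")) {
  frames <- .duplex_frames(s, bp_map)
  n <- length(frames)
  steps <- data.frame(rise = numeric(n - 1), twist = numeric(n - 1))
  for (i in seq_len(n - 1)) {
    Rrel <- frames[[i + 1]]$M %*% t(frames[[i]]$M)
    ang <- acos(pmin(1, pmax(-1, (sum(diag(Rrel)) - 1) / 2)))
    # rotation axis of the step
    if (ang > 1e-9) {
      ax <- c(Rrel[3, 2] - Rrel[2, 3], Rrel[1, 3] - Rrel[3, 1],
              Rrel[2, 1] - Rrel[1, 2]) / (2 * sin(ang))
    } else ax <- frames[[i]]$M[, 3]
    d <- frames[[i + 1]]$o - frames[[i]]$o
    steps$rise[i] <- abs(sum(d * ax))
    steps$twist[i] <- ang * 180 / pi
  }
  steps
}

#' Base-pair frame origins of a duplex
#'
#' The helix-axis point of every base pair, recovered by superposing the
#' ideal base-pair template onto the observed atoms (so the result is
#' twist-phase independent, unlike raw C1' midpoints).
#'
#' @inheritParams measure_duplex_params
#' @return `n x 3` matrix of frame origins.
#' @export
duplex_bp_origins <- function(s, bp_map = attr(s, "bp_map")) {
  t(vapply(.duplex_frames(s, bp_map), function(f) f$o, numeric(3)))
}

.duplex_frames <- function(s, bp_map) {
  if (is.null(bp_map)) stop("no base-pair map available")
  n <- nrow(bp_map)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    a1 <- s$atoms[s$atoms$chain == bp_map$chain1[i] &
                    s$atoms$resno == bp_map$resno1[i], ]
    a2 <- s$atoms[s$atoms$chain == bp_map$chain2[i] &
                    s$atoms$resno == bp_map$resno2[i], ]
    b1 <- sub("^D", "", a1$resname[1]); b2 <- sub("^D", "", a2$resname[1])
    t1 <- .nt_template(b1); t2 <- .nt_template(b2) %*% t(.rotx180)
    rownames(t2) <- rownames(.nt_template(b2))
    ref <- rbind(t1[match(a1$elety, rownames(t1)), , drop = FALSE],
                 t2[match(a2$elety, rownames(t2)), , drop = FALSE])
    obs <- rbind(as.matrix(a1[, c("x", "y", "z")]),
                 as.matrix(a2[, c("x", "y", "z")]))
    fit <- superpose(ref, obs)     # transform ideal -> observed
    frames[[i]] <- list(M = fit$rotation,
                        o = as.numeric(fit$translation))
  }
  frames
}

# Complex models -----------------------------------------------------------------

#' Construct (and validate) a protein-DNA complex model
#'
#' @param protein tetramer `wk_structure`.
#' @param dna_segments list of DNA `wk_structure`s (1 for wrapping, 2 for
#'   bridging).
#' @param mode `"wrapping"` or `"bridging"`.
#' @param provenance character labels of the source interfaces.
#' @param clash_cutoff protein-DNA heavy-atom pairs closer than this (A) make
#'   the model invalid (default 2.0).
#' @return object of class `complex_model`.
#' @export
complex_model <- function(protein, dna_segments, mode = c("wrapping",
                                                          "bridging"),
                          provenance = character(0), clash_cutoff = 2.0) {
  mode <- match.arg(mode)
  n_seg <- length(dna_segments)
  if (mode == "wrapping" && n_seg != 1)
    stop("wrapping mode requires exactly 1 DNA segment, got ", n_seg)
  if (mode == "bridging" && n_seg != 2)
    stop("bridging mode requires exactly 2 DNA segments, got ", n_seg)
  ph <- coords(protein, select_atoms(protein, class = "heavy"))
  for (seg in dna_segments) {
    dh <- coords(seg, select_atoms(seg, class = "heavy"))
    d <- min_cross_dist(ph, dh)
    if (d < clash_cutoff)
      stop(sprintf("protein-DNA clash: minimum heavy-atom distance %.2f A < %.2f A",
                   d, clash_cutoff))
  }
  structure(list(protein = protein, dna_segments = dna_segments, mode = mode,
                 provenance = provenance), class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat("complex_model (", x$mode, "): tetramer of ",
      length(x$protein$chains), " chain(s) + ", length(x$dna_segments),
      " DNA segment(s)\n", sep = "")
  invisible(x)
}

# superpose template protein onto the tetramer via shared atoms and return the
# transform applied to arbitrary coordinates
.template_transform <- function(tetramer, template) {
  key <- function(a) paste(a$chain, a$resno, a$elety, sep = "\r")
  ta <- template$atoms; pa <- tetramer$atoms
  tp <- ta[ta$resname %in% .aa3, ]
  shared <- intersect(key(tp), key(pa))
  if (length(shared) < 3)
    stop("template shares fewer than 3 protein atoms with the tetramer")
  m_t <- coords(template)[match(shared, key(ta)), , drop = FALSE]
  m_p <- coords(tetramer)[match(shared, key(pa)), , drop = FALSE]
  fit <- superpose(m_t, m_p)
  function(xyz) sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

# base-pair centers of a template's DNA after transformation; pairs residue j
# of the first DNA chain with residue (n + 1 - j) of the second
.template_bp_centers <- function(template, transform) {
  bp_map <- attr(template, "bp_map")
  a <- template$atoms
  if (is.null(bp_map)) {
    dchains <- unique(a$chain[a$resname %in% .dna_res])
    if (length(dchains) != 2)
      stop("cannot infer base pairing: template DNA has ",
           length(dchains), " chain(s)")
    r1 <- sort(unique(a$resno[a$chain == dchains[1]]))
    r2 <- sort(unique(a$resno[a$chain == dchains[2]]))
    if (length(r1) != length(r2))
      stop("cannot infer base pairing: strand lengths differ")
    bp_map <- data.frame(bp = seq_along(r1), chain1 = dchains[1], resno1 = r1,
                         chain2 = dchains[2], resno2 = rev(r2))
  }
  centers <- t(vapply(seq_len(nrow(bp_map)), function(i) {
    c1 <- a$chain == bp_map$chain1[i] & a$resno == bp_map$resno1[i] &
      a$elety %in% c("C1'", "C1*")
    c2 <- a$chain == bp_map$chain2[i] & a$resno == bp_map$resno2[i] &
      a$elety %in% c("C1'", "C1*")
    colMeans(rbind(as.matrix(a[c1, c("x", "y", "z")]),
                   as.matrix(a[c2, c("x", "y", "z")])))
  }, numeric(3)))
  transform(centers)
}

#' Assemble a wrapping starting model
#'
#' Superposes each protein-DNA interface template onto the tetramer, derives
#' the wrapping path (plane, radius, phase) from the transformed template
#' base-pair centers, and lays a single idealized B-DNA arc of `n_bp` base
#' pairs through the interfaces. Overlapping template coverage is absorbed by
#' the common circle fit; gaps are bridged by the arc itself. The tetramer
#' coordinates are preserved bit-exactly. If the arc clashes with the protein
#' its radius is inflated in 0.25 A steps (up to 5 A).
#'
#' @param tetramer complete 4-chain `wk_structure`.
#' @param interface_templates list of `wk_structure`s carrying protein chains
#'   (shared atom names with the tetramer) plus a bound DNA duplex.
#' @param n_bp total DNA length (default 67).
#' @param sequence optional strand-I sequence (defaults to a repeating
#'   ACGT...); length must equal `n_bp`.
#' @param rise,twist B-DNA step parameters.
#' @return a [complex_model()] in wrapping mode.
#' @export
assemble_wrapping_model <- function(tetramer, interface_templates, n_bp = 67,
                                    sequence = NULL, rise = 3.4, twist = 36) {
  if (length(interface_templates) == 0)
    stop("at least one interface template is required")
  if (length(tetramer$chains) < 4)
    stop("tetramer must have 4 chains, got ", length(tetramer$chains))
  centers <- do.call(rbind, lapply(interface_templates, function(tpl) {
    tr <- .template_transform(tetramer, tpl)
    .template_bp_centers(tpl, tr)
  }))
  # wrapping plane from the template bp centers, then a least-squares circle
  # fit within that plane (center and radius)
  cmean <- colMeans(centers)
  pc <- prcomp(centers, center = TRUE)
  axis <- pc$rotation[, 3]
  e1 <- pc$rotation[, 1]; e2 <- pc$rotation[, 2]
  if (det(cbind(e1, e2, axis)) < 0) e2 <- -e2   # right-handed frame
  proj <- sweep(centers, 2, cmean)
  u <- c(proj %*% e1); v <- c(proj %*% e2); w <- c(proj %*% axis)
  cf <- stats::lm.fit(cbind(u, v, 1), -(u^2 + v^2))$coefficients
  uc <- -cf[1] / 2; vc <- -cf[2] / 2
  r <- sqrt(max(uc^2 + vc^2 - cf[3], 0))
  cen0 <- cmean + uc * e1 + vc * e2 + mean(w) * axis
  radii <- sqrt((u - uc)^2 + (v - vc)^2)
  if (length(radii) > 1 && stats::sd(radii) > 0.35 * mean(radii))
    stop(sprintf(paste0("template interfaces are not consistent with a single",
                        " wrapping path (radius %.1f +/- %.1f A): gap geometry",
                        " cannot be bridged without a >90 degree kink"),
                 mean(radii), stats::sd(radii)))
  span <- n_bp * rise / r
  if (span > 2 * pi) r <- n_bp * rise / (2 * pi)  # close the circle instead
  if (is.null(sequence))
    sequence <- paste(rep_len(c("A", "C", "G", "T"), n_bp), collapse = "")
  if (nchar(sequence) != n_bp) stop("sequence length must equal n_bp")
  # phase: start the arc at the first template's first bp center
  v0 <- centers[1, ] - cen0
  build_arc <- function(Rr, twist_phase, flip) {
    # the plane normal's sign is arbitrary; a flipped axis would turn the
    # right-handed duplex left-handed globally, so both orientations are
    # scanned and scored against the templates
    b2 <- if (flip) -e2 else e2
    ax <- if (flip) -axis else axis
    M <- cbind(e1, b2, ax)
    phase <- atan2(sum(v0 * b2), sum(v0 * e1))
    arc <- build_bdna(duplex_spec(sequence, rise = rise, twist = twist,
                                  curvature = 1 / Rr),
                      chains = c("X", "Y"), twist_phase = twist_phase)
    # built arc: bp0 at origin, arc center at (-R, 0, 0), plane z = 0
    xyz <- sweep(coords(arc), 2, c(-Rr, 0, 0))  # center arc on the origin
    xyz2 <- sweep((xyz %*% t(.rotz(phase))) %*% t(M), 2, cen0, "+")
    arc2 <- set_coords(arc, xyz2)
    attr(arc2, "bp_map") <- attr(arc, "bp_map")
    attr(arc2, "spec") <- attr(arc, "spec")
    arc2
  }
  # reconnection refinement: pick the helical phase that best matches the
  # transformed template C1' atoms
  tc1 <- do.call(rbind, lapply(seq_along(interface_templates), function(i) {
    tpl <- interface_templates[[i]]
    tr <- .template_transform(tetramer, tpl)
    a <- tpl$atoms
    sel <- a$resname %in% .dna_res & a$elety %in% c("C1'", "C1*")
    tr(as.matrix(a[sel, c("x", "y", "z")]))
  }))
  # fast scan: place only the C1' atoms analytically
  c1l <- rbind(.backbone_xyz["C1'", ], .backbone_xyz["C1'", ] %*% t(.rotx180))
  arc_c1 <- function(Rr, twist_phase, flip) {
    b2 <- if (flip) -e2 else e2
    ax <- if (flip) -axis else axis
    M <- cbind(e1, b2, ax)
    phase <- atan2(sum(v0 * b2), sum(v0 * e1))
    out <- matrix(NA_real_, 2 * n_bp, 3)
    for (i in seq_len(n_bp)) {
      fr <- .bp_frame(i - 1, rise, twist, 1 / Rr)
      Mi <- fr$M %*% .rotz(twist_phase * pi / 180)
      out[c(i, n_bp + i), ] <- sweep(c1l %*% t(Mi), 2, fr$origin, "+")
    }
    out <- sweep(out, 2, c(-Rr, 0, 0))
    sweep((out %*% t(.rotz(phase))) %*% t(M), 2, cen0, "+")
  }
  score <- function(ac1) {
    mean(vapply(seq_len(nrow(tc1)), function(k)
      min(colSums((t(ac1) - tc1[k, ])^2)), numeric(1)))
  }
  coarse <- expand.grid(p = seq(0, 350, by = 10), flip = c(FALSE, TRUE))
  sc <- vapply(seq_len(nrow(coarse)), function(k)
    score(arc_c1(r, coarse$p[k], coarse$flip[k])), numeric(1))
  bk <- which.min(sc)
  flip <- coarse$flip[bk]
  fine <- seq(coarse$p[bk] - 9, coarse$p[bk] + 9, by = 1)
  scf <- vapply(fine, function(p) score(arc_c1(r, p, flip)), numeric(1))
  best <- fine[which.min(scf)]
  for (try in 0:20) {
    arc2 <- build_arc(r + 0.25 * try, best, flip)
    ok <- tryCatch({
      model <- complex_model(tetramer, list(arc2), mode = "wrapping",
                             provenance = paste0("template_",
                                                 seq_along(interface_templates)))
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(model)
  }
  stop("could not place a clash-free wrapping arc within +5 A of the template radius")
}

#' Assemble a bridging starting model
#'
#' Each of the two opposing interface templates receives its own straight
#' `n_bp` duplex, extended along the template DNA's own axis. Segments must
#' stay clash-free against the protein and > 4 A apart from each other.
#'
#' @inheritParams assemble_wrapping_model
#' @param n_bp per-segment length (default 32).
#' @return a [complex_model()] in bridging mode.
#' @export
assemble_bridging_model <- function(tetramer, interface_templates, n_bp = 32,
                                    sequence = NULL, rise = 3.4, twist = 36) {
  if (length(interface_templates) != 2)
    stop("bridging assembly requires exactly 2 interface templates, got ",
         length(interface_templates))
  if (is.null(sequence))
    sequence <- paste(rep_len(c("A", "C", "G", "T"), n_bp), collapse = "")
  if (nchar(sequence) != n_bp) stop("sequence length must equal n_bp")
  segs <- lapply(seq_along(interface_templates), function(i) {
    tpl <- interface_templates[[i]]
    tr <- .template_transform(tetramer, tpl)
    centers <- .template_bp_centers(tpl, tr)
    cen <- colMeans(centers)
    dir <- prcomp(centers, center = TRUE)$rotation[, 1]
    if (nrow(centers) > 1 &&
        sum((centers[nrow(centers), ] - centers[1, ]) * dir) < 0)
      dir <- -dir
    dup <- build_bdna(duplex_spec(sequence, rise = rise, twist = twist),
                      chains = c(c("W", "X")[i], c("Y", "Z")[i]))
    xyz <- coords(dup)
    xyz[, 3] <- xyz[, 3] - (n_bp - 1) * rise / 2   # center on the axis midpoint
    # rotate z onto dir, keep template's radial orientation via its centroid
    M <- .rot_between(c(0, 0, 1), dir)
    xyz2 <- sweep(xyz %*% t(M), 2, cen, "+")
    dup2 <- set_coords(dup, xyz2)
    attr(dup2, "bp_map") <- attr(dup, "bp_map")
    attr(dup2, "spec") <- attr(dup, "spec")
    dup2
  })
  d12 <- min_cross_dist(coords(segs[[1]], select_atoms(segs[[1]], "heavy")),
                        coords(segs[[2]], select_atoms(segs[[2]], "heavy")))
  if (d12 <= 4)
    stop(sprintf("bridging segments contact each other (min distance %.2f A <= 4 A)",
                 d12))
  complex_model(tetramer, segs, mode = "bridging",
                provenance = c("template_1", "template_2"))
}

# minimal rotation taking unit vector a onto unit vector b
.rot_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite vectors: rotate 180 deg about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Reverse complement of a DNA sequence string
#' @param x character string (A/C/G/T).
#' @return reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  paste(rev(.complement[strsplit(toupper(x), "")[[1]]]), collapse = "")
}
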