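# Superposition, RMSD, angles, wrap coverage, free-energy landscapes -----------

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `mobile`
#' onto `reference` (correspondence by row order). The returned transform
#' satisfies `mobile %*% t(rotation) + translation ~ reference`.
#'
#' @param mobile,reference `n x 3` matrices, equal `n >= 3`.
#' @return `list(rotation, translation, rmsd)` with `det(rotation) = +1`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have equal atom counts")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(A)$d[2] < 1e-9 * max(svd(A)$d[1], 1))
    stop("need at least 3 non-collinear points")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- sweep(mobile %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#' @param a,b `n x 3` matrices.
#' @return RMSD in the coordinate units.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' DNA-backbone RMSD along a trajectory
#'
#' Each frame is first superposed onto the reference through the `fit_on`
#' atoms (typically protein heavy atoms), then the RMSD is measured over
#' `measure_on` (typically DNA phosphate + sugar heavy atoms).
#'
#' @param traj a `wk_trajectory`.
#' @param fit_on,measure_on integer atom index sets.
#' @param reference reference coordinates (`n_atoms x 3`) or a frame index
#'   into `traj` (default 1).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
dna_backbone_rmsd_series <- function(traj, fit_on, measure_on, reference = 1) {
  if (!length(fit_on) || !length(measure_on))
    stop("empty fit_on/measure_on selection")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  vapply(seq_len(n_frames(traj)), function(i) {
    f <- frame_coords(traj, i)
    fit <- superpose(f[fit_on, , drop = FALSE], ref[fit_on, , drop = FALSE])
    moved <- sweep(f %*% t(fit$rotation), 2, fit$translation, "+")
    rmsd(moved[measure_on, , drop = FALSE], ref[measure_on, , drop = FALSE])
  }, numeric(1))
}

# torsion angle (deg) of four ordered points, in (-180, 180]
.torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2); y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Tetramer planarity dihedral along a trajectory
#'
#' The four monomer centroids (heavy atoms per chain) are taken in the order
#' first dimer (monomer A, monomer B) then second dimer (monomer A, monomer
#' B), and their torsion angle is reported in degrees. For a planar tetramer
#' with trans-ordered centroids the dihedral is 180 degrees (set
#' `convention = "zero"` to report the deviation-from-plane convention where a
#' planar tetramer reads 0). Frames with collinear centroids yield `NA`.
#'
#' @param traj a `wk_trajectory`.
#' @param dimers list of two character vectors of chain ids, two chains each.
#' @param convention `"trans"` (planar = 180) or `"zero"` (planar = 0).
#' @return numeric vector of per-frame dihedrals (degrees, (-180, 180]).
#' @export
tetramer_planarity <- function(traj, dimers, convention = c("trans", "zero")) {
  convention <- match.arg(convention)
  chains <- unlist(dimers)
  if (length(chains) != 4) stop("dimers must partition 4 chains into 2 pairs")
  a <- traj$topology$atoms
  heavy <- !(a$element %in% c("H", "D"))
  idx <- lapply(chains, function(ch) which(a$chain == ch & heavy))
  if (any(!lengths(idx))) stop("chain(s) absent from topology: ",
                               paste(chains[!lengths(idx)], collapse = ", "))
  out <- vapply(seq_len(n_frames(traj)), function(i) {
    f <- frame_coords(traj, i)
    cent <- lapply(idx, function(j) colMeans(f[j, , drop = FALSE]))
    .torsion(cent[[1]], cent[[2]], cent[[3]], cent[[4]])
  }, numeric(1))
  if (convention == "zero") out <- 180 - abs(out)
  out
}

# Helix axis by the perpendicular-bisector construction: for an ideal helix
# the second-difference vectors at consecutive CA positions are both exactly
# perpendicular to the axis, so their cross product lies along it.
.helix_axis <- function(ca) {
  n <- nrow(ca)
  if (n < 6) stop("need at least 6 CA atoms per helix")
  d <- ca[seq_len(n - 2) , , drop = FALSE] +
    ca[seq(3, n), , drop = FALSE] - 2 * ca[seq(2, n - 1), , drop = FALSE]
  axes <- vapply(seq_len(nrow(d) - 1), function(i) {
    a <- d[i, ]; b <- d[i + 1, ]
    v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) rep(NA_real_, 3) else v / nv
  }, numeric(3))
  ax <- rowMeans(axes, na.rm = TRUE)
  ax <- ax / sqrt(sum(ax^2))
  # orient N -> C
  if (sum((ca[n, ] - ca[1, ]) * ax) < 0) ax <- -ax
  ax
}

#' Crossing angle between two helices
#'
#' Fits an axis to each helix from its CA atoms (least-squares
#' bisector construction, exact for ideal helices) and reports the crossing
#' angle folded to `[0, 90]` degrees, plus whether the axes run antiparallel
#' (N->C orientations opposed).
#'
#' @param s a `wk_structure`.
#' @param helixA,helixB selections: `list(chain =, resno =)` describing each
#'   helix's residues.
#' @return `list(angle, antiparallel, axisA, axisB)`.
#' @export
helix_crossing_angle <- function(s, helixA, helixB) {
  get_ca <- function(sel) {
    idx <- select_atoms(s, chain = sel$chain, resno = sel$resno, elety = "CA")
    ca <- coords(s, idx)
    ord <- order(s$atoms$resno[idx])
    ca[ord, , drop = FALSE]
  }
  a1 <- .helix_axis(get_ca(helixA))
  a2 <- .helix_axis(get_ca(helixB))
  cosang <- sum(a1 * a2)
  ang <- acos(pmin(1, abs(cosang))) * 180 / pi
  list(angle = ang, antiparallel = cosang < 0, axisA = a1, axisB = a2)
}

#' Base-pair wrap coverage of a protein by DNA
#'
#' A base pair counts as wrapped when at least one heavy atom of either of
#' its nucleotides lies within `cutoff` of any protein heavy atom. Angular
#' coverage is measured from the azimuths of wrapped base-pair centers about
#' the wrapping axis (normal of the best-fit plane through all base-pair
#' centers, through the protein centroid): it is 360 minus the largest
#' angular gap between consecutive wrapped base pairs.
#'
#' @param protein `wk_structure` (or a complex's protein component).
#' @param dna `wk_structure` with a `bp_map` attribute, or supply `bp_map`.
#' @param cutoff contact cutoff in Angstrom (default 4).
#' @param bp_map optional explicit base-pair map.
#' @return `list(bp_in_contact, longest_run, angular_coverage, wrapped)`.
#' @export
wrap_coverage <- function(protein, dna, cutoff = 4, bp_map = NULL) {
  if (is.null(bp_map)) bp_map <- attr(dna, "bp_map")
  a <- dna$atoms
  heavy_p <- coords(protein, select_atoms(protein, class = "heavy"))
  if (is.null(bp_map)) {
    warning("no base pairing available; falling back to per-nucleotide counts")
    key <- paste(a$chain, a$resno)
    bp_map <- data.frame(bp = seq_along(unique(key)))
    nts <- split(seq_len(nrow(a)), key)
  } else {
    nts <- lapply(seq_len(nrow(bp_map)), function(i)
      which((a$chain == bp_map$chain1[i] & a$resno == bp_map$resno1[i]) |
              (a$chain == bp_map$chain2[i] & a$resno == bp_map$resno2[i])))
  }
  heavy <- !(a$element %in% c("H", "D"))
  wrapped <- vapply(nts, function(j) {
    j <- j[heavy[j]]
    length(j) > 0 &&
      min_cross_dist(as.matrix(a[j, c("x", "y", "z")]), heavy_p) <= cutoff
  }, logical(1))
  runs <- rle(wrapped)
  longest <- if (any(wrapped)) max(runs$lengths[runs$values]) else 0L
  ang_cov <- 0
  if (sum(wrapped) >= 2) {
    centers <- t(vapply(nts, function(j)
      colMeans(as.matrix(a[j, c("x", "y", "z")])), numeric(3)))
    pc <- prcomp(centers, center = TRUE)
    origin <- colMeans(heavy_p)
    rel <- sweep(centers[wrapped, , drop = FALSE], 2, origin)
    e1 <- pc$rotation[, 1]; e2 <- pc$rotation[, 2]
    az <- sort(atan2(rel %*% e2, rel %*% e1) * 180 / pi)
    gaps <- diff(c(az, az[1] + 360))
    ang_cov <- 360 - max(gaps)
  }
  list(bp_in_contact = sum(wrapped), longest_run = as.integer(longest),
       angular_coverage = ang_cov, wrapped = wrapped)
}

#' Two-dimensional free-energy landscape
#'
#' Histograms two collective-variable series, converts probabilities to free
#' energies `F = -kT log(P / Pmax)` and characterizes the minimum basin.
#' Empty bins are `NA` (undefined), never infinite.
#'
#' @param cv1,cv2 equal-length numeric series.
#' @param kT thermal energy in kJ/mol (default 2.577, i.e. 310 K).
#' @param bins number of bins per axis (default 50).
#' @param basin_threshold basin boundary in kJ/mol above the minimum
#'   (default `kT`, i.e. the 1 kT isocontour).
#' @return object of class `wk_fel`: bin edges/midpoints, `P`, `F`, `kT`, and
#'   `basin` (`list(location, depth, area)`; area in CV-units squared at
#'   `F < basin_threshold`).
#' @export
free_energy_landscape <- function(cv1, cv2, kT = 2.577, bins = 50,
                                  basin_threshold = kT) {
  if (length(cv1) != length(cv2)) stop("cv series must have equal length")
  if (kT <= 0) stop("kT must be > 0")
  if (length(unique(cv1)) < 2 || length(unique(cv2)) < 2)
    stop("need at least 2 distinct samples on each axis")
  pad <- function(x) {
    r <- range(x); w <- diff(r)
    if (w == 0) w <- abs(r[1]) + 1
    seq(r[1] - 1e-9 * w, r[2] + 1e-9 * w, length.out = bins + 1)
  }
  ex <- pad(cv1); ey <- pad(cv2)
  ix <- findInterval(cv1, ex, rightmost.closed = TRUE)
  iy <- findInterval(cv2, ey, rightmost.closed = TRUE)
  counts <- matrix(0, bins, bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  P <- counts / sum(counts)
  FF <- matrix(NA_real_, bins, bins)
  nz <- P > 0
  FF[nz] <- -kT * log(P[nz] / max(P))
  mx <- (ex[-1] + ex[-length(ex)]) / 2
  my <- (ey[-1] + ey[-length(ey)]) / 2
  imin <- which(FF == 0, arr.ind = TRUE)[1, ]
  cellarea <- diff(ex)[1] * diff(ey)[1]
  basin <- list(location = c(mx[imin[1]], my[imin[2]]),
                depth = max(FF, na.rm = TRUE),
                area = sum(FF < basin_threshold, na.rm = TRUE) * cellarea)
  structure(list(x = mx, y = my, x_edges = ex, y_edges = ey, P = P, F = FF,
                 kT = kT, basin = basin), class = "wk_fel")
}

#' @export
print.wk_fel <- function(x, ...) {
  cat("wk_fel:", length(x$x), "x", length(x$y), "bins; kT =", x$kT,
      "kJ/mol; basin area", signif(x$basin$area, 4), "at",
      sprintf("(%.3g, %.3g)\n", x$basin$location[1], x$basin$location[2]))
  invisible(x)
}
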