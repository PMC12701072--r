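# Heavy-atom contact analytics (binding sites, fluctuation, moieties, H-bonds) --

#' Contact-counting parameters
#' @param cutoff distance cutoff in Angstrom; contacts are pairs at distance
#'   `<= cutoff` (inclusive). Default 4.0.
#' @param heavy_only restrict both sets to heavy atoms (default TRUE).
#' @return validated `contact_params` list.
#' @export
contact_params <- function(cutoff = 4.0, heavy_only = TRUE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, heavy_only = heavy_only),
            class = "contact_params")
}

#' Define the four canonical HLp DNA-binding sites
#'
#' Maps the tetramer's binding motifs onto (chain, residue) sets: the two
#' A-sites each comprise two beta-bridge motifs (T27, G29 in loop l1; T56,
#' T57 in loop l2) plus their flanking l2 DNA-binding residues (K54, R59) at
#' a tetramerization interface, and the two B-sites are each centered on a
#' paired-end-of-helices motif (A13, S14, K15) plus the adjacent alpha1
#' residues (K17, K21) across a dimer. With chains ordered
#' `(dimer1 = c1, c2; dimer2 = c3, c4)`: B-site 1 spans (c1, c2), B-site 2
#' spans (c3, c4), A-site 1 spans (c2, c3), A-site 2 spans (c4, c1). The four
#' sites are pairwise disjoint.
#'
#' @param tetramer a `wk_structure` with >= 4 chains.
#' @param chains the four chain ids in dimer order (default: first four).
#' @param residue_lists optional override,
#'   `list(a_site = resnos, b_site = resnos)`.
#' @return named list of four `binding_site` objects.
#' @export
define_canonical_sites <- function(tetramer, chains = tetramer$chains[1:4],
                                   residue_lists = NULL) {
  if (length(chains) != 4 || anyNA(chains))
    stop("need four chains to define the canonical sites")
  a_res <- residue_lists$a_site %||% c(27, 29, 56, 57, 54, 59)
  b_res <- residue_lists$b_site %||% c(13, 14, 15, 17, 21)
  if (length(intersect(a_res, b_res)))
    stop("A-site and B-site residue lists must be disjoint")
  mk <- function(name, chs, res)
    binding_site(name, data.frame(chain = rep(chs, each = length(res)),
                                  resno = rep(res, 2)), tetramer)
  list(`A-site 1` = mk("A-site 1", chains[c(2, 3)], a_res),
       `A-site 2` = mk("A-site 2", chains[c(4, 1)], a_res),
       `B-site 1` = mk("B-site 1", chains[c(1, 2)], b_res),
       `B-site 2` = mk("B-site 2", chains[c(3, 4)], b_res))
}

#' Construct a binding site
#' @param name site label.
#' @param residues data frame with columns `chain`, `resno`.
#' @param validate_in optional `wk_structure`; every residue must exist in it.
#' @return `binding_site` object.
#' @export
binding_site <- function(name, residues, validate_in = NULL) {
  stopifnot(is.data.frame(residues), nrow(residues) > 0,
            all(c("chain", "resno") %in% names(residues)))
  if (!is.null(validate_in)) {
    a <- validate_in$atoms
    present <- paste(a$chain, a$resno)
    want <- paste(residues$chain, residues$resno)
    miss <- setdiff(want, present)
    if (length(miss))
      stop("site '", name, "': residue(s) absent from structure: ",
           paste(miss, collapse = ", "))
  }
  structure(list(name = name, residues = residues), class = "binding_site")
}

# atom indices of a site within a structure (optionally heavy only)
site_atoms <- function(s, site, heavy_only = TRUE) {
  a <- s$atoms
  key <- paste(a$chain, a$resno)
  idx <- which(key %in% paste(site$residues$chain, site$residues$resno))
  if (heavy_only) idx <- idx[!(a$element[idx] %in% c("H", "D"))]
  idx
}

#' Count heavy-atom contacts between two disjoint atom sets
#'
#' A contact is an unordered pair (a in A, b in B) with distance `<= cutoff`.
#' Uses a cell-list (spatial hashing) neighbor search; the pair list is
#' returned in sorted order for reproducibility.
#'
#' @param xyz `n x 3` coordinate matrix for the whole system.
#' @param setA,setB disjoint integer atom index sets.
#' @param params a [contact_params()].
#' @param heavy optional logical vector marking heavy atoms (required if
#'   `params$heavy_only` and `xyz` carries no such information).
#' @param method `"auto"` picks the dense all-pairs path for small systems
#'   and the cell list for large ones; `"cell"`/`"dense"` force one.
#' @return `list(count, pairs)` where `pairs` is a data frame
#'   (`i`, `j`, `dist`) sorted by (`i`, `j`).
#' @export
count_contacts <- function(xyz, setA, setB, params = contact_params(),
                           heavy = NULL, method = c("auto", "cell",
                                                    "dense")) {
  method <- match.arg(method)
  if (length(intersect(setA, setB)))
    stop("setA and setB overlap; self-contacts are undefined")
  if (params$heavy_only && !is.null(heavy)) {
    setA <- setA[heavy[setA]]
    setB <- setB[heavy[setB]]
  }
  if (!length(setA) || !length(setB))
    return(list(count = 0L,
                pairs = data.frame(i = integer(0), j = integer(0),
                                   dist = numeric(0))))
  A <- xyz[setA, , drop = FALSE]
  B <- xyz[setB, , drop = FALSE]
  cutoff <- params$cutoff
  if (method == "auto")
    method <- if (length(setA) * length(setB) <= 4e6) "dense" else "cell"
  if (method == "dense") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
    ord <- order(setA[hit[, 1]], setB[hit[, 2]])
    pairs <- data.frame(i = setA[hit[ord, 1]], j = setB[hit[ord, 2]],
                        dist = sqrt(pmax(d2[hit[ord, , drop = FALSE]], 0)))
    return(list(count = nrow(pairs), pairs = pairs))
  }
  # cell list over B
  lo <- pmin(apply(A, 2, min), apply(B, 2, min))
  keyB <- .cell_key(B, lo, cutoff)
  bmap <- split(seq_len(nrow(B)), keyB)
  cellsA <- .cell_idx(A, lo, cutoff)
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ia in seq_len(nrow(A))) {
    neigh <- integer(0)
    base <- cellsA[ia, ]
    for (o in seq_len(nrow(offs))) {
      k <- paste(base + offs[o, ], collapse = ",")
      nb <- bmap[[k]]
      if (!is.null(nb)) neigh <- c(neigh, nb)
    }
    if (!length(neigh)) next
    d2 <- colSums((t(B[neigh, , drop = FALSE]) - A[ia, ])^2)
    hit <- d2 <= cutoff^2 + 1e-12
    if (any(hit)) {
      res_i <- c(res_i, rep(setA[ia], sum(hit)))
      res_j <- c(res_j, setB[neigh[hit]])
      res_d <- c(res_d, sqrt(d2[hit]))
    }
  }
  ord <- order(res_i, res_j)
  pairs <- data.frame(i = res_i[ord], j = res_j[ord], dist = res_d[ord])
  list(count = nrow(pairs), pairs = pairs)
}

.cell_idx <- function(m, lo, h) {
  cbind(floor((m[, 1] - lo[1]) / h), floor((m[, 2] - lo[2]) / h),
        floor((m[, 3] - lo[3]) / h))
}
.cell_key <- function(m, lo, h) {
  ci <- .cell_idx(m, lo, h)
  paste(ci[, 1], ci[, 2], ci[, 3], sep = ",")
}

#' Per-frame contact series over a trajectory
#'
#' Counts protein-DNA heavy-atom contacts per frame: total, per binding site
#' and per protein residue, plus the binding fluctuation (deviation of each
#' frame's total from the trajectory mean).
#'
#' @param traj a `wk_trajectory`.
#' @param sites named list of `binding_site`s (may be empty).
#' @param dna integer atom indices of the DNA partner.
#' @param params a [contact_params()].
#' @param protein optional protein atom indices (default: all protein atoms).
#' @return object of class `contact_series`: `frame` data frame (`time`,
#'   `total`, one column per site, `fluctuation`), `residue_mean` (mean
#'   contacts per protein residue), `mean`, `sd`, `site_stats`.
#' @export
contact_series <- function(traj, sites = list(), dna,
                           params = contact_params(), protein = NULL) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  top <- traj$topology
  heavy <- !(top$atoms$element %in% c("H", "D"))
  if (is.null(protein)) protein <- select_atoms(top, class = "protein")
  if (!length(protein) || !length(dna)) stop("empty protein/dna selection")
  site_idx <- lapply(sites, function(st) site_atoms(top, st,
                                                    params$heavy_only))
  nf <- n_frames(traj)
  total <- numeric(nf)
  per_site <- matrix(0, nf, length(sites),
                     dimnames = list(NULL, names(sites)))
  res_tab <- NULL
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    cc <- count_contacts(xyz, protein, dna, params, heavy = heavy)
    total[f] <- cc$count
    if (nrow(cc$pairs)) {
      rk <- paste(top$atoms$chain[cc$pairs$i], top$atoms$resno[cc$pairs$i])
      tb <- table(rk)
      if (is.null(res_tab)) res_tab <- numeric(0)
      for (nm in names(tb))
        res_tab[nm] <- (if (is.na(res_tab[nm])) 0 else res_tab[nm]) + tb[[nm]]
    }
    for (k in seq_along(site_idx)) {
      si <- setdiff(site_idx[[k]], dna)
      per_site[f, k] <- count_contacts(xyz, si, dna, params,
                                       heavy = heavy)$count
    }
  }
  res_mean <- if (is.null(res_tab)) numeric(0) else res_tab / nf
  fr <- data.frame(time = traj$times, total = total)
  if (length(sites)) fr <- cbind(fr, as.data.frame(per_site,
                                                   check.names = FALSE))
  fr$fluctuation <- binding_fluctuation(total)
  site_stats <- if (length(sites)) {
    data.frame(site = colnames(per_site), mean = colMeans(per_site),
               sd = apply(per_site, 2, stats::sd), row.names = NULL)
  } else data.frame(site = character(0), mean = numeric(0), sd = numeric(0))
  if (nf == 1) site_stats$sd <- 0
  structure(list(frame = fr, residue_mean = res_mean,
                 mean = mean(total),
                 sd = if (nf > 1) stats::sd(total) else 0,
                 site_stats = site_stats, params = params),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("contact_series:", nrow(x$frame), "frames; total contacts",
      sprintf("%.1f +/- %.1f", x$mean, x$sd), "\n")
  if (nrow(x$site_stats)) print(x$site_stats)
  invisible(x)
}

#' Binding fluctuation of a contact-count series
#'
#' The deviation of each frame's contact number from the average across all
#' frames; sums to zero by construction.
#'
#' @param counts numeric per-frame contact counts (>= 1 frame).
#' @return numeric vector `counts - mean(counts)`.
#' @export
binding_fluctuation <- function(counts) {
  if (!length(counts)) stop("need at least one frame")
  counts - mean(counts)
}

#' Centered moving-average smoothing
#'
#' Truncated windows at the edges; output length equals input length. Even
#' window sizes are bumped to the next odd integer so the window centers.
#'
#' @param x numeric series.
#' @param window window size in frames (default 100).
#' @return smoothed numeric vector.
#' @export
smooth_series <- function(x, window = 100) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(x)) stop("window (", window, ") exceeds series length (",
                               length(x), ")")
  if (window %% 2 == 0) window <- window + 1
  half <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Classify contact pairs by DNA moiety and protein side
#'
#' @param pairs data frame from [count_contacts()] (`i` = protein atom index,
#'   `j` = DNA atom index).
#' @param s the topology `wk_structure`.
#' @return 3 x 2 contingency matrix (phosphate/sugar/base x
#'   backbone/sidechain); marginals sum to the pair count.
#' @export
classify_contact_moieties <- function(pairs, s) {
  out <- matrix(0L, 3, 2, dimnames = list(c("phosphate", "sugar", "base"),
                                          c("backbone", "sidechain")))
  if (!nrow(pairs)) return(out)
  a <- s$atoms
  dna_cls <- function(j) {
    if (.class_mask(a, "dna_phosphate")[j]) "phosphate"
    else if (.class_mask(a, "dna_sugar")[j]) "sugar"
    else if (.class_mask(a, "dna_base")[j]) "base"
    else stop("atom ", j, " (", a$elety[j], " ", a$resname[j],
              ") is not a classifiable DNA heavy atom")
  }
  prot_cls <- function(i) {
    if (.class_mask(a, "protein_backbone")[i]) "backbone"
    else if (.class_mask(a, "protein_sidechain")[i]) "sidechain"
    else stop("atom ", i, " (", a$elety[i], " ", a$resname[i],
              ") is not a protein atom")
  }
  for (k in seq_len(nrow(pairs))) {
    r <- dna_cls(pairs$j[k]); cc <- prot_cls(pairs$i[k])
    out[r, cc] <- out[r, cc] + 1L
  }
  out
}

#' Hydrogen-bond / salt-bridge criteria
#' @param d_da donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle minimum D-H...A angle in degrees (default 120).
#' @param salt_cutoff charged-group N/O distance for salt bridges (default 4).
#' @param persistence occupancy fraction above which a pair is persistent
#'   (default 0.5).
#' @return `hbond_criteria` list.
#' @export
hbond_criteria <- function(d_da = 3.5, angle = 120, salt_cutoff = 4.0,
                           persistence = 0.5) {
  if (d_da <= 0) stop("d_da must be > 0")
  if (angle <= 0 || angle >= 180) stop("angle must lie in (0, 180)")
  structure(list(d_da = d_da, angle = angle, salt_cutoff = salt_cutoff,
                 persistence = persistence), class = "hbond_criteria")
}

#' Hydrogen-bond / salt-bridge occupancy over a trajectory
#'
#' For every donor-acceptor pair, the fraction of frames satisfying the
#' geometric criteria. When hydrogens are present, the D-H...A angle test
#' uses the hydrogen bonded to the donor (within 1.3 A in frame 1); without
#' hydrogens (or in `mode = "saltbridge"`) a distance-only test is applied.
#'
#' @param traj a `wk_trajectory`.
#' @param donors,acceptors integer atom index sets.
#' @param criteria a [hbond_criteria()].
#' @param mode `"hbond"` or `"saltbridge"` (charged-group distance only).
#' @return data frame (`donor`, `acceptor`, `occupancy`, `persistent`).
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            criteria = hbond_criteria(),
                            mode = c("hbond", "saltbridge")) {
  mode <- match.arg(mode)
  if (!length(donors) || !length(acceptors)) {
    warning("no donors/acceptors in selection")
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      occupancy = numeric(0), persistent = logical(0)))
  }
  top <- traj$topology
  cutoff <- if (mode == "saltbridge") criteria$salt_cutoff else criteria$d_da
  # hydrogens bonded to each donor (frame 1 topology distances)
  h_of <- NULL
  use_angle <- FALSE
  if (mode == "hbond") {
    h_idx <- which(top$atoms$element %in% c("H", "D"))
    if (length(h_idx)) {
      f1 <- frame_coords(traj, 1)
      h_of <- lapply(donors, function(d) {
        d2 <- colSums((t(f1[h_idx, , drop = FALSE]) - f1[d, ])^2)
        h_idx[d2 <= 1.3^2]
      })
      use_angle <- any(lengths(h_of) > 0)
    }
  }
  nf <- n_frames(traj)
  grid <- expand.grid(di = seq_along(donors), ai = seq_along(acceptors))
  hits <- numeric(nrow(grid))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    D <- xyz[donors, , drop = FALSE]
    A <- xyz[acceptors, , drop = FALSE]
    d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)
    ok <- d2 <= cutoff^2 + 1e-12
    if (use_angle) {
      for (p in which(ok[cbind(grid$di, grid$ai)])) {
        di <- grid$di[p]; ai <- grid$ai[p]
        hs <- h_of[[di]]
        if (!length(hs)) next
        good <- FALSE
        for (h in hs) {
          v1 <- xyz[donors[di], ] - xyz[h, ]
          v2 <- xyz[acceptors[ai], ] - xyz[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= criteria$angle) { good <- TRUE; break }
        }
        ok[di, ai] <- good
      }
    }
    hits <- hits + as.numeric(ok[cbind(grid$di, grid$ai)])
  }
  occ <- hits / nf
  data.frame(donor = donors[grid$di], acceptor = acceptors[grid$ai],
             occupancy = occ, persistent = occ >= criteria$persistence)
}

#' Classify a trajectory's binding mode from site engagement
#'
#' Wrapping: all four canonical sites engaged (mean contacts above
#' `threshold`); bridging: both B-sites engaged, both A-sites not.
#'
#' @param cs a `contact_series` computed with the four canonical sites.
#' @param threshold mean-contact engagement threshold (default 1).
#' @return `"wrapping"`, `"bridging"` or `"other"`.
#' @export
classify_binding_mode <- function(cs, threshold = 1) {
  st <- cs$site_stats
  eng <- setNames(st$mean > threshold, st$site)
  a <- eng[grep("^A-site", names(eng))]
  b <- eng[grep("^B-site", names(eng))]
  if (all(a) && all(b)) "wrapping"
  else if (all(b) && !any(a)) "bridging"
  else "other"
}
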