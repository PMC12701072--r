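# Steered-unwrapping post-processing ---------------------------------------------

#' Construct a pulling series
#'
#' @param xi pulling coordinate (monotone non-decreasing after optional
#'   smoothing), in `units`.
#' @param force applied force, kJ/mol per `units`.
#' @param time optional times (ns).
#' @param units `"A"` or `"nm"`; declared once, carried through.
#' @return `pulling_series` object.
#' @export
pulling_series <- function(xi, force, time = NULL, units = c("A", "nm")) {
  units <- match.arg(units)
  if (length(xi) != length(force)) stop("xi and force must align")
  if (length(xi) < 2) stop("need at least 2 samples")
  if (any(diff(xi) < 0)) {
    sm <- smooth_series(xi, min(51, length(xi)))
    if (any(diff(sm) < 0))
      stop("pulling coordinate is not monotone non-decreasing")
    xi <- sm
  }
  structure(list(xi = xi, force = force, time = time, units = units),
            class = "pulling_series")
}

#' Read pull data from two-/three-column whitespace or XVG text
#'
#' Lines starting with `#`, `@` or `&` are ignored (XVG dialect). With two
#' columns they are taken as (xi, force); with three, (time, xi, force).
#'
#' @param path file path.
#' @param units coordinate units, `"A"` or `"nm"`.
#' @return a [pulling_series()].
#' @export
read_pull_data <- function(path, units = c("A", "nm")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^[#@&]", trimws(lines)) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  if (ncol(m) == 2) pulling_series(m[, 1], m[, 2], units = units)
  else if (ncol(m) >= 3) pulling_series(m[, 2], m[, 3], time = m[, 1],
                                        units = units)
  else stop("parse error in ", path, ": need 2 or 3 numeric columns")
}

#' Cumulative work profile of a pulling series
#'
#' Trapezoidal integration of force over the pulling coordinate;
#' `W(xi[1]) = 0`.
#'
#' @param p a [pulling_series()].
#' @return object of class `work_profile`: `xi`, `W` (kJ/mol), `units`,
#'   `barriers` (empty until [detect_barriers()]).
#' @export
work_profile <- function(p) {
  stopifnot(inherits(p, "pulling_series"))
  W <- pracma::cumtrapz(p$xi, p$force)[, 1]
  structure(list(xi = p$xi, W = W, units = p$units,
                 barriers = data.frame()), class = "work_profile")
}

#' @export
print.work_profile <- function(x, ...) {
  cat("work_profile:", length(x$xi), "points; total W =",
      sprintf("%.1f kJ/mol", x$W[length(x$W)]), "\n")
  if (nrow(x$barriers)) print(x$barriers)
  invisible(x)
}

#' Detect work barriers and attribute them to binding sites
#'
#' Segments the profile by the sign structure of the smoothed slope dW/dxi:
#' maximal stretches where the slope exceeds `slope_frac` of its maximum are
#' rising segments; each is anchored at the midpoints of its flanking flat
#' stretches, and the rise of W between anchors is a barrier when it exceeds
#' `min_height`. A monotone profile yields a single barrier equal to its
#' total rise (or none, if below `min_height`). When per-site contact series
#' over the same coordinate are supplied, each barrier is attributed to the
#' site whose contact count drops most across its interval.
#'
#' @param wp a [work_profile()].
#' @param min_height minimum barrier height, kJ/mol.
#' @param site_contacts optional data frame: column `xi` plus one numeric
#'   column per site.
#' @param smooth_window smoothing window for the slope (default 100, capped
#'   at the series length).
#' @param slope_frac flat/rising threshold as a fraction of the maximum
#'   smoothed slope (default 0.1).
#' @return the `work_profile` with a populated `barriers` data frame
#'   (`xi_start`, `xi_peak`, `height`, `site`).
#' @export
detect_barriers <- function(wp, min_height, site_contacts = NULL,
                            smooth_window = 100, slope_frac = 0.1) {
  stopifnot(inherits(wp, "work_profile"))
  n <- length(wp$xi)
  slope <- c(diff(wp$W) / diff(wp$xi), 0)
  slope <- smooth_series(slope, min(smooth_window, n))
  thresh <- slope_frac * max(slope, 0)
  rising <- slope > thresh & slope > 0
  runs <- rle(rising)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seg <- which(runs$values)
  bars <- list()
  for (k in seg) {
    # anchor at midpoints of the flanking flat runs (or the series ends)
    i0 <- if (k == 1) 1L else floor((starts[k - 1] + ends[k - 1]) / 2)
    i1 <- if (k == length(runs$values)) n else
      floor((starts[k + 1] + ends[k + 1]) / 2)
    rise <- wp$W[i1] - wp$W[i0]
    if (rise >= min_height) {
      site <- NA_character_
      if (!is.null(site_contacts)) {
        sc <- site_contacts
        cols <- setdiff(names(sc), "xi")
        inwin <- sc$xi >= wp$xi[i0] & sc$xi <= wp$xi[i1]
        if (sum(inwin) >= 2) {
          drops <- vapply(cols, function(cl) {
            v <- sc[[cl]][inwin]
            v[1] - v[length(v)]
          }, numeric(1))
          if (any(drops > 0)) site <- cols[which.max(drops)]
        }
      }
      bars[[length(bars) + 1]] <- data.frame(
        xi_start = wp$xi[i0], xi_peak = wp$xi[i1], height = rise,
        site = site, stringsAsFactors = FALSE)
    }
  }
  wp$barriers <- if (length(bars)) do.call(rbind, bars) else
    data.frame(xi_start = numeric(0), xi_peak = numeric(0),
               height = numeric(0), site = character(0))
  wp
}

#' Site release order along a pulling coordinate
#'
#' A site is released at the first coordinate where its smoothed contact
#' count falls below `threshold` times its initial mean and stays below for
#' `dwell` consecutive samples. Sites that never engage (initial mean below
#' `engaged_min`) are excluded with a note.
#'
#' @param site_contacts data frame: column `xi` plus one column per site.
#' @param threshold release threshold fraction (default 0.5).
#' @param dwell dwell window in samples (default 20).
#' @param smooth_window smoothing window (default 51).
#' @param init_frac fraction of the series used for the initial mean
#'   (default 0.1).
#' @param engaged_min minimum initial mean to count as engaged (default 0.5).
#' @return data frame (`site`, `xi_release`) ordered by release coordinate;
#'   excluded sites are reported in the `"excluded"` attribute.
#' @export
release_order <- function(site_contacts, threshold = 0.5, dwell = 20,
                          smooth_window = 51, init_frac = 0.1,
                          engaged_min = 0.5) {
  cols <- setdiff(names(site_contacts), "xi")
  if (!length(cols)) stop("need at least one site series")
  xi <- site_contacts$xi
  n <- length(xi)
  n0 <- max(2, ceiling(init_frac * n))
  out <- list(); excluded <- character(0)
  for (cl in cols) {
    v <- smooth_series(site_contacts[[cl]], min(smooth_window, n))
    v0 <- mean(v[seq_len(n0)])
    if (v0 < engaged_min) { excluded <- c(excluded, cl); next }
    below <- v < threshold * v0
    rel <- NA_real_
    for (i in seq_len(n)) {
      if (below[i] && all(below[i:min(i + dwell - 1L, n)])) {
        rel <- xi[i]
        break
      }
    }
    if (!is.na(rel)) out[[cl]] <- data.frame(site = cl, xi_release = rel,
                                             stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(site = character(0), xi_release = numeric(0))
  res <- res[order(res$xi_release), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

# Coulomb constant in kJ mol^-1 A e^-2
.coulomb_k <- 1389.35458

#' Per-residue protein-DNA interaction energy decomposition
#'
#' For each protein residue, the mean over frames of the cutoff-truncated
#' nonbonded energy (Coulomb with relative dielectric `eps_r`, plus
#' Lennard-Jones when parameters are supplied) between the residue's atoms
#' and all DNA atoms within `cutoff`. Fractions are reported on the
#' magnitude of the attractive (negative-energy) residues.
#'
#' @param traj a `wk_trajectory`.
#' @param charges per-atom partial charges (e), length = atom count.
#' @param protein,dna atom index sets.
#' @param lj optional `list(eps =, sigma =)` per-atom Lennard-Jones
#'   parameters (kJ/mol, Angstrom).
#' @param cutoff interaction cutoff, Angstrom (default 12).
#' @param eps_r relative dielectric (default 1).
#' @return object of class `residue_energy_table`: data frame (`chain`,
#'   `resno`, `energy`, `fraction`) plus `total` (one-pass total energy).
#' @export
residue_energy_decomposition <- function(traj, charges, protein, dna,
                                         lj = NULL, cutoff = 12, eps_r = 1) {
  top <- traj$topology
  if (length(charges) != nrow(top$atoms))
    stop("charges must cover all ", nrow(top$atoms), " atoms; missing for ",
         nrow(top$atoms) - length(charges), " atom(s)")
  if (anyNA(charges[c(protein, dna)])) {
    bad <- c(protein, dna)[is.na(charges[c(protein, dna)])]
    stop("missing charge parameters for atom(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  res_key <- paste(top$atoms$chain, top$atoms$resno)
  groups <- split(protein, res_key[protein])
  nf <- n_frames(traj)
  e_res <- setNames(numeric(length(groups)), names(groups))
  total <- 0
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    Dn <- xyz[dna, , drop = FALSE]
    for (g in seq_along(groups)) {
      gi <- groups[[g]]
      P <- xyz[gi, , drop = FALSE]
      d2 <- outer(rowSums(P^2), rowSums(Dn^2), "+") - 2 * P %*% t(Dn)
      d2[d2 < 1e-12] <- 1e-12
      r <- sqrt(d2)
      within <- r <= cutoff
      if (!any(within)) next
      qq <- outer(charges[gi], charges[dna])
      e <- .coulomb_k * qq / (eps_r * r)
      if (!is.null(lj)) {
        sig <- outer(lj$sigma[gi], lj$sigma[dna], "+") / 2
        eps <- sqrt(outer(lj$eps[gi], lj$eps[dna]))
        sr6 <- (sig / r)^6
        e <- e + 4 * eps * (sr6^2 - sr6)
      }
      e[!within] <- 0
      e_res[g] <- e_res[g] + sum(e)
    }
  }
  e_res <- e_res / nf
  total <- sum(e_res)
  attractive <- e_res < 0
  frac <- rep(NA_real_, length(e_res))
  if (any(attractive))
    frac[attractive] <- abs(e_res[attractive]) / sum(abs(e_res[attractive]))
  parts <- strsplit(names(groups), " ")
  tab <- data.frame(chain = vapply(parts, `[`, "", 1),
                    resno = as.integer(vapply(parts, `[`, "", 2)),
                    energy = unname(e_res), fraction = frac,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$energy), ]
  rownames(tab) <- NULL
  structure(list(table = tab, total = total), class = "residue_energy_table")
}

#' @export
print.residue_energy_table <- function(x, ...) {
  cat("residue_energy_table: total", sprintf("%.2f kJ/mol;", x$total),
      "top contributors:\n")
  print(utils::head(x$table, 5))
  invisible(x)
}
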