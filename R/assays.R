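# Assay quantitation: masses, SD scan, ladder sizing, TPM and isotherm fits -----

# Average residue masses (Da): amino-acid residues (monomer - water) and
# water, standard IUPAC average atomic weights.
.aa_residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mass <- 18.0153
# deoxynucleoside-5'-monophosphate free-acid average masses (Da)
.dnmp_mass <- c(A = 331.2218, C = 307.1971, G = 347.2212, T = 322.2085)
.hpo3_mass <- 79.9799

#' Average molecular mass of a protein sequence
#'
#' Peptide mass = sum of residue masses + one water (N- and C-terminal H/OH).
#'
#' @param seq a protein `wk_seqrec` or a 1-letter sequence string.
#' @param remove_met drop the initiator methionine before computing.
#' @return object of class `mass_result`: `mass` (Da), `kda` (1-decimal kDa),
#'   `composition` (residue counts).
#' @export
protein_mass <- function(seq, remove_met = FALSE) {
  s <- if (inherits(seq, "wk_seqrec")) seq$residues else
    toupper(gsub("\\s", "", seq))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s))
    stop("non-standard amino-acid letter(s): ",
         paste(unique(strsplit(gsub("[ACDEFGHIKLMNPQRSTVWY]", "", s),
                               "")[[1]]), collapse = ""))
  if (remove_met && startsWith(s, "M")) s <- substring(s, 2)
  res <- strsplit(s, "")[[1]]
  mass <- sum(.aa_residue_mass[res]) + .water_mass
  mass_result(mass, composition = table(res))
}

#' Average molecular mass of a DNA sequence
#'
#' @param seq a dna `wk_seqrec` or sequence string (one strand, 5'->3').
#' @param strands 1 (single strand) or 2 (duplex: the strand plus its exact
#'   reverse complement).
#' @param five_prime terminal chemistry: `"OH"` (synthesized oligos, default)
#'   or `"phosphate"` (5'-monophosphate).
#' @return a `mass_result`.
#' @export
nucleic_mass <- function(seq, strands = 2, five_prime = c("OH", "phosphate")) {
  five_prime <- match.arg(five_prime)
  s <- if (inherits(seq, "wk_seqrec")) seq$residues else
    toupper(gsub("\\s", "", seq))
  if (grepl("[^ACGT]", s)) stop("non-ACGT symbol in DNA sequence")
  # 5'-OH (synthesized oligos): the chain simply lacks the terminal HPO3
  one <- function(x) {
    nt <- strsplit(x, "")[[1]]
    m <- sum(.dnmp_mass[nt]) - (length(nt) - 1) * .water_mass
    if (five_prime == "OH") m <- m - .hpo3_mass
    m
  }
  mass <- if (strands == 2) one(s) + one(reverse_complement(s)) else one(s)
  mass_result(mass, composition = table(strsplit(s, "")[[1]]))
}

#' Mass of a stoichiometric complex
#'
#' @param parts list of `mass_result`s or bare masses (Da).
#' @param stoichiometry integer counts, one per part.
#' @param measured optional measured mass (Da) for a percent-deviation report.
#' @return a `mass_result`; with `measured`, carries `deviation_pct`.
#' @export
complex_mass <- function(parts, stoichiometry, measured = NULL) {
  if (!length(parts) || !length(stoichiometry)) {
    warning("empty stoichiometry; mass is 0")
    return(mass_result(0))
  }
  if (length(parts) != length(stoichiometry))
    stop("parts and stoichiometry lengths differ")
  masses <- vapply(parts, function(p)
    if (inherits(p, "mass_result")) p$mass else as.numeric(p), numeric(1))
  out <- mass_result(sum(masses * stoichiometry))
  if (!is.null(measured))
    out$deviation_pct <- 100 * (measured - out$mass) / out$mass
  out
}

mass_result <- function(mass, composition = NULL) {
  structure(list(mass = mass, kda = round(mass / 1000, 1),
                 composition = composition), class = "mass_result")
}

#' @export
print.mass_result <- function(x, ...) {
  cat(sprintf("mass_result: %.2f Da (%.1f kDa)\n", x$mass, x$kda))
  invisible(x)
}

#' Shine-Dalgarno scan upstream of candidate start codons
#'
#' Slides the SD core (complement of the anti-SD, default `AGGAGG`) over a
#' 4-14 nt spacing window upstream of each candidate start and scores the
#' best placement by its longest contiguous match.
#'
#' @param context a dna `wk_seqrec` or string (genomic context, 5'->3').
#' @param starts 1-based positions of candidate start codons within
#'   `context`; each needs >= 20 nt upstream.
#' @param sd_core SD consensus to match (default "AGGAGG").
#' @param spacing integer range of allowed spacer lengths (nt between the SD
#'   core's 3' end and the start codon), default 4:14.
#' @return data frame (`start`, `codon`, `score`, `spacing`, `strong`),
#'   ranked by score; non-ATG/GTG/TTG codons warned about but still scored.
#' @export
sd_scan <- function(context, starts, sd_core = "AGGAGG", spacing = 4:14) {
  s <- if (inherits(context, "wk_seqrec")) context$residues else
    toupper(gsub("\\s", "", context))
  k <- nchar(sd_core)
  core <- strsplit(sd_core, "")[[1]]
  rows <- lapply(starts, function(st) {
    if (st - max(spacing) - k < 1 || st - 20 < 1)
      stop("start at ", st, " lacks 20 nt of upstream context")
    codon <- substr(s, st, st + 2)
    if (!codon %in% c("ATG", "GTG", "TTG"))
      warning("start at ", st, " is not ATG/GTG/TTG (", codon,
              "); scored anyway")
    best <- 0L; best_sp <- NA_integer_
    for (sp in spacing) {
      frag <- strsplit(substr(s, st - sp - k, st - sp - 1), "")[[1]]
      match_run <- rle(frag == core)
      run <- if (any(match_run$values)) max(match_run$lengths[match_run$values])
      else 0L
      if (run > best) { best <- run; best_sp <- sp }
    }
    data.frame(start = st, codon = codon, score = best, spacing = best_sp,
               strong = best >= 5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

#' Construct a gel lane profile
#' @param position migration positions (pixels or mm), increasing.
#' @param intensity non-negative intensities, same length.
#' @return `lane_profile` object.
#' @export
lane_profile <- function(position, intensity) {
  stopifnot(length(position) == length(intensity))
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  structure(list(position = position, intensity = intensity),
            class = "lane_profile")
}

#' Detect peaks in a lane profile
#'
#' Local maxima above the noise floor (median + 3 MAD of the profile).
#'
#' @param lane a [lane_profile()].
#' @param min_separation minimum peak separation in position units.
#' @param min_frac additional threshold as a fraction of the profile maximum
#'   (default 0.05), guarding against baseline noise spikes on lanes whose
#'   background dominates the median/MAD floor.
#' @return numeric vector of peak positions (may be empty).
#' @export
find_lane_peaks <- function(lane, min_separation = 5, min_frac = 0.05) {
  y <- lane$intensity; x <- lane$position
  floor_ <- max(stats::median(y) + 3 * stats::mad(y), min_frac * max(y))
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE) & y > floor_
  px <- x[is_peak]; py <- y[is_peak]
  if (!length(px)) return(numeric(0))
  # merge peaks closer than min_separation, keeping the taller
  keep <- rep(TRUE, length(px))
  ord <- order(-py)
  for (i in ord) {
    if (!keep[i]) next
    close <- which(abs(px - px[i]) < min_separation & seq_along(px) != i)
    keep[close] <- FALSE
  }
  sort(px[keep])
}

#' Size DNA fragments from a densitometric gel ladder
#'
#' Calibrates migration against a marker lane (monotone `log10(bp)` vs
#' position, least squares) and interpolates sample peak positions.
#'
#' @param sample a [lane_profile()] of the digested sample.
#' @param marker a [lane_profile()] of the size marker.
#' @param marker_sizes marker fragment sizes in bp (descending migration
#'   order is resolved automatically); >= 3 bands required.
#' @param min_separation peak-merge distance (see [find_lane_peaks()]).
#' @return data frame (`position`, `size_bp`, `uncertainty_bp`,
#'   `extrapolated`); empty for a flat lane.
#' @export
ladder_sizing <- function(sample, marker, marker_sizes, min_separation = 5) {
  mpk <- find_lane_peaks(marker, min_separation)
  if (length(mpk) < 3)
    stop("need >= 3 detected marker bands, found ", length(mpk))
  sizes <- sort(marker_sizes, decreasing = TRUE)
  if (length(mpk) != length(sizes))
    stop("marker lane has ", length(mpk), " detected bands but ",
         length(sizes), " sizes were given")
  # larger fragments migrate less: ascending position = descending size
  fit <- stats::lm(log10(sizes) ~ mpk)
  if (coef(fit)[2] >= 0)
    stop("marker calibration is not monotone decreasing in position")
  sig <- stats::sd(stats::residuals(fit))
  spk <- find_lane_peaks(sample, min_separation)
  if (!length(spk))
    return(data.frame(position = numeric(0), size_bp = numeric(0),
                      uncertainty_bp = numeric(0), extrapolated = logical(0)))
  lg <- stats::predict(fit, newdata = data.frame(mpk = spk))
  size <- 10^lg
  unc <- size * log(10) * sig
  extra <- spk < min(mpk) | spk > max(mpk)
  if (any(extra))
    warning(sum(extra), " sample peak(s) outside the marker range; ",
            "sizes are extrapolated")
  data.frame(position = spk, size_bp = unname(size),
             uncertainty_bp = unname(unc), extrapolated = extra)
}

#' Fit a tethered-particle-motion titration to a logistic curve
#'
#' `RMS(c) = RMSmin + (RMS0 - RMSmin) / (1 + (c / c50)^k)`, least squares
#' (optionally weighted by replicate SDs). The saturation concentration is
#' where 95% of the total RMS drop is reached.
#'
#' @param conc concentrations (nM), >= 4 values including 0 or near-0.
#' @param rms mean RMS excursions (nm).
#' @param sd optional replicate standard deviations (weights `1/sd^2`).
#' @return object of class `tpm_fit`: `rms0`, `rms_min`, `c50`, `k`,
#'   `saturation` (nM), `fitted`, `converged`, `degenerate`.
#' @export
tpm_logistic_fit <- function(conc, rms, sd = NULL) {
  if (length(conc) < 4) stop("need >= 4 concentrations")
  if (min(conc) > 0.05 * max(conc))
    stop("need a zero or near-zero concentration anchor")
  if (stats::sd(rms) < 1e-9 * max(abs(rms), 1))
    return(structure(list(rms0 = mean(rms), rms_min = mean(rms), c50 = NA,
                          k = NA, saturation = NA, fitted = rms,
                          converged = FALSE, degenerate = TRUE),
                     class = "tpm_fit"))
  w <- if (is.null(sd)) rep(1, length(conc)) else 1 / pmax(sd, 1e-6)^2
  df <- data.frame(conc = conc, rms = rms)
  start <- list(rms0 = max(rms), rms_min = min(rms),
                c50 = stats::median(conc[conc > 0]), k = 1.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(rms ~ rms_min + (rms0 - rms_min) / (1 + (conc / c50)^k),
                      data = df, start = start, weights = w,
                      lower = c(rms0 = 0, rms_min = 0, c50 = 1e-9, k = 0.05),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(rms0 = NA, rms_min = NA, c50 = NA, k = NA,
                          saturation = NA, fitted = rep(NA_real_,
                                                        length(conc)),
                          converged = FALSE, degenerate = FALSE),
                     class = "tpm_fit"))
  p <- as.list(coef(fit))
  structure(list(rms0 = p$rms0, rms_min = p$rms_min, c50 = p$c50, k = p$k,
                 saturation = p$c50 * 19^(1 / p$k),
                 fitted = stats::fitted(fit),
                 converged = fit$convInfo$isConv %||% TRUE,
                 degenerate = FALSE),
            class = "tpm_fit")
}

#' @export
print.tpm_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("tpm_fit: degenerate (constant RMS)\n")
  else cat(sprintf(
    "tpm_fit: RMS %.1f -> %.1f nm, c50 = %.0f nM, k = %.2f, saturation ~ %.0f nM\n",
    x$rms0, x$rms_min, x$c50, x$k, x$saturation))
  invisible(x)
}

#' Fit a binding isotherm
#'
#' Fits both a 1:1 model (ligand-depletion-aware quadratic when the probe
#' concentration is given, simple hyperbola otherwise) and a Hill variant,
#' and reports both with an AIC-based model selection.
#'
#' @param conc titrant concentrations, spanning >= 2 decades over >= 5 points.
#' @param response fraction bound (or any saturating response).
#' @param probe fixed probe/target concentration, same units as `conc`
#'   (default 0: no depletion).
#' @return object of class `isotherm_fit`: `kd`, `hill` (n, Kd), `model`
#'   (selected), `no_binding`, `narrow_span`, per-model AIC.
#' @export
isotherm_fit <- function(conc, response, probe = 0) {
  if (length(conc) < 5) stop("need >= 5 concentrations")
  pos <- conc[conc > 0]
  narrow <- diff(log10(range(pos))) < 2
  if (stats::sd(response) < 1e-6 * max(abs(response), 1))
    return(structure(list(kd = NA, hill = NULL, model = "none",
                          no_binding = TRUE, narrow_span = narrow),
                     class = "isotherm_fit"))
  df <- data.frame(conc = conc, y = response)
  bound11 <- function(conc, kd, bmax) {
    if (probe > 0) {
      s <- conc + probe + kd
      bmax * (s - sqrt(s^2 - 4 * conc * probe)) / (2 * probe)
    } else bmax * conc / (kd + conc)
  }
  f1 <- tryCatch(minpack.lm::nlsLM(
    y ~ bound11(conc, kd, bmax), data = df,
    start = list(kd = stats::median(pos), bmax = max(response)),
    lower = c(kd = 1e-12, bmax = 1e-12)), error = function(e) NULL)
  fh <- tryCatch(minpack.lm::nlsLM(
    y ~ bmax * conc^n / (kd^n + conc^n), data = df,
    start = list(kd = stats::median(pos), bmax = max(response), n = 1.5),
    lower = c(kd = 1e-12, bmax = 1e-12, n = 0.1)), error = function(e) NULL)
  aic1 <- if (!is.null(f1)) stats::AIC(f1) else Inf
  aich <- if (!is.null(fh)) stats::AIC(fh) else Inf
  model <- if (aic1 <= aich) "1:1" else "hill"
  kd <- if (!is.null(f1)) coef(f1)[["kd"]] else NA
  hill <- if (!is.null(fh)) list(kd = coef(fh)[["kd"]], n = coef(fh)[["n"]],
                                 aic = aich) else NULL
  structure(list(kd = kd, aic = aic1, hill = hill, model = model,
                 no_binding = FALSE, narrow_span = narrow,
                 fit_11 = f1, fit_hill = fh),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  if (isTRUE(x$no_binding)) cat("isotherm_fit: no binding detected\n")
  else cat(sprintf("isotherm_fit: Kd (1:1) = %.3g; selected model: %s%s\n",
                   x$kd, x$model,
                   if (isTRUE(x$narrow_span)) " [narrow span: bound only]"
                   else ""))
  invisible(x)
}
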