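# Trajectory container and I/O --------------------------------------------------

#' Construct a trajectory
#'
#' @param topology a `wk_structure` (defines the atom order of every frame).
#' @param xyz numeric array `n_atoms x 3 x n_frames`, or a list of `n x 3`
#'   matrices, or a single matrix (one frame).
#' @param times frame times in ns; strictly increasing. Default `0, dt, ...`.
#' @param dt stride used when `times` is not given.
#' @return object of class `wk_trajectory`.
#' @export
wk_trajectory <- function(topology, xyz, times = NULL, dt = 0.1) {
  stopifnot(inherits(topology, "wk_structure"))
  if (is.list(xyz)) {
    xyz <- simplify2array(xyz)            # n x 3 x F
  }
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  n <- nrow(topology$atoms)
  if (dim(xyz)[1] != n || dim(xyz)[2] != 3)
    stop("frame atom count (", dim(xyz)[1],
         ") does not match topology atom count (", n, ")")
  nf <- dim(xyz)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame_times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times)),
            class = "wk_trajectory")
}

#' @export
print.wk_trajectory <- function(x, ...) {
  cat("wk_trajectory:", n_frames(x), "frames x", dim(x$xyz)[1], "atoms;",
      "t =", x$times[1], "..", x$times[n_frames(x)], "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `wk_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Coordinates of one frame
#' @param traj a `wk_trajectory`.
#' @param i frame index.
#' @param idx optional atom indices.
#' @return `n x 3` matrix.
#' @export
frame_coords <- function(traj, i, idx = NULL) {
  m <- traj$xyz[, , i]
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Read a trajectory
#'
#' Supports the package's plain-text frame format (see
#' [write_trajectory()]) and binary DCD (via bio3d). The text format is:
#' a header line `# wrapkit-traj natoms=N nframes=F`, then for every frame a
#' line `# frame I time_ns=T` followed by N whitespace-delimited `x y z`
#' rows.
#'
#' @param topology a `wk_structure`; frame atom counts must match.
#' @param frames_path path to `.traj`/text file or `.dcd`.
#' @param dt stride (ns) used to synthesize times for formats without them.
#' @return a [wk_trajectory()].
#' @export
read_trajectory <- function(topology, frames_path, dt = 0.1) {
  if (grepl("\\.dcd$", frames_path, ignore.case = TRUE)) {
    m <- bio3d::read.dcd(frames_path, verbose = FALSE)
    nat <- ncol(m) / 3
    if (nat != nrow(topology$atoms))
      stop("atom-count mismatch: frames have ", nat, ", topology has ",
           nrow(topology$atoms))
    xyz <- array(NA_real_, c(nat, 3, nrow(m)))
    for (i in seq_len(nrow(m)))
      xyz[, , i] <- matrix(m[i, ], ncol = 3, byrow = TRUE)
    return(wk_trajectory(topology, xyz, dt = dt))
  }
  lines <- readLines(frames_path, warn = FALSE)
  hd <- lines[1]
  n <- as.integer(sub(".*natoms=([0-9]+).*", "\\1", hd))
  if (is.na(n)) stop("parse error in ", frames_path,
                     ": missing 'natoms=' header record")
  if (n != nrow(topology$atoms))
    stop("atom-count mismatch: frames have ", n, ", topology has ",
         nrow(topology$atoms))
  fr <- grep("^# frame", lines)
  if (!length(fr)) stop("parse error in ", frames_path, ": no frame records")
  times <- as.numeric(sub(".*time_ns=([-0-9.eE+]+).*", "\\1", lines[fr]))
  if (anyNA(times)) times <- (seq_along(fr) - 1) * dt
  xyz <- array(NA_real_, c(n, 3, length(fr)))
  for (i in seq_along(fr)) {
    block <- lines[(fr[i] + 1):(fr[i] + n)]
    m <- matrix(scan(text = block, quiet = TRUE), ncol = 3, byrow = TRUE)
    if (nrow(m) != n) stop("parse error in ", frames_path, ": frame ", i,
                           " has ", nrow(m), " atoms, expected ", n)
    xyz[, , i] <- m
  }
  wk_trajectory(topology, xyz, times = times)
}

#' Write a trajectory in the plain-text frame format
#'
#' Coordinates are printed with 17 significant digits so that a
#' write-then-read round trip reproduces them bit-exactly.
#'
#' @param traj a `wk_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nf <- n_frames(traj)
  n <- dim(traj$xyz)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wrapkit-traj natoms=%d nframes=%d", n, nf), con)
  for (i in seq_len(nf)) {
    writeLines(sprintf("# frame %d time_ns=%.17g", i, traj$times[i]), con)
    m <- traj$xyz[, , i]
    writeLines(sprintf("%.17g %.17g %.17g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}
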