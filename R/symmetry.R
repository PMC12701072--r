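# Crystallographic symmetry expansion ------------------------------------------

#' Parse a symmetry operator in "x,y,z" algebra
#'
#' Accepts mmCIF/International Tables operator strings such as
#' `"-X,Y+1/2,-Z"` and returns the rotation matrix and translation vector in
#' fractional coordinates.
#'
#' @param op operator string, three comma-separated components.
#' @return `list(R = 3x3 matrix, t = length-3 vector)`.
#' @export
parse_symop <- function(op) {
  parts <- strsplit(gsub("\\s", "", tolower(op)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", op)
  R <- matrix(0, 3, 3); tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "\\+")[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sgn <- 1
      if (startsWith(tm, "-")) { sgn <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        f <- as.numeric(strsplit(tm, "/")[[1]])
        tr[i] <- tr[i] + sgn * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        tr[i] <- tr[i] + sgn * as.numeric(tm)
      } else if (grepl("^[0-9]+/[0-9]+[xyz]$|^[0-9.]*[xyz]$", tm)) {
        ax <- substring(tm, nchar(tm))
        co <- substr(tm, 1, nchar(tm) - 1)
        val <- if (grepl("/", co)) {
          f <- as.numeric(strsplit(co, "/")[[1]]); f[1] / f[2]
        } else if (nzchar(co)) as.numeric(co) else 1
        R[i, match(ax, c("x", "y", "z"))] <- sgn * val
      } else stop("cannot parse operator term '", tm, "' in ", op)
    }
  }
  list(R = R, t = tr)
}

# Built-in operator tables for common Sohncke space groups (compact symbol,
# spaces stripped). Files carrying their own operator loop override these.
.sg_ops <- list(
  "P1"       = c("x,y,z"),
  "P21"      = c("x,y,z", "-x,y+1/2,-z"),
  "P1211"    = c("x,y,z", "-x,y+1/2,-z"),
  "C2"       = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "C121"     = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P21212"   = c("x,y,z", "-x,-y,z", "-x+1/2,y+1/2,-z", "x+1/2,-y+1/2,-z"),
  "P212121"  = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                 "x+1/2,-y+1/2,-z"),
  "C2221"    = c("x,y,z", "-x,-y,z+1/2", "-x,y,-z+1/2", "x,-y,-z",
                 "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2",
                 "-x+1/2,y+1/2,-z+1/2", "x+1/2,-y+1/2,-z"),
  "P41212"   = c("x,y,z", "-x,-y,z+1/2", "-y+1/2,x+1/2,z+1/4",
                 "y+1/2,-x+1/2,z+3/4", "-x+1/2,y+1/2,-z+1/4",
                 "x+1/2,-y+1/2,-z+3/4", "y,x,-z", "-y,-x,-z+1/2"),
  "P43212"   = c("x,y,z", "-x,-y,z+1/2", "-y+1/2,x+1/2,z+3/4",
                 "y+1/2,-x+1/2,z+1/4", "-x+1/2,y+1/2,-z+3/4",
                 "x+1/2,-y+1/2,-z+1/4", "y,x,-z", "-y,-x,-z+1/2"),
  "P3121"    = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3", "y,x,-z",
                 "x-y,-y,-z+2/3", "-x,-x+y,-z+1/3"),
  "P3221"    = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3", "y,x,-z",
                 "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3"),
  "P61"      = c("x,y,z", "x-y,x,z+1/6", "-y,x-y,z+1/3", "-x,-y,z+1/2",
                 "-x+y,-x,z+2/3", "y,-x+y,z+5/6"),
  "P65"      = c("x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2",
                 "-x+y,-x,z+1/3", "y,-x+y,z+1/6"))

#' Look up space-group symmetry operators
#' @param sgroup Hermann-Mauguin symbol (spacing-insensitive, e.g. `"P 21"`,
#'   `"P 1 21 1"`).
#' @return character vector of operator strings.
#' @export
sg_operators <- function(sgroup) {
  key <- toupper(gsub("\\s", "", sgroup))
  ops <- .sg_ops[[key]]
  if (is.null(ops))
    stop("no built-in operators for space group '", sgroup,
         "'; pass operators explicitly or use a pre-expanded assembly")
  ops
}

# orthogonalization matrix (fractional -> cartesian), standard PDB convention
.frac2cart <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)), 3, 3, byrow = TRUE)
}

#' Expand crystallographic symmetry around a seed selection
#'
#' Applies all space-group operators plus lattice translations and keeps every
#' generated copy having at least one atom within `radius` (atom-to-atom) of
#' the seed selection. The identity copy is always retained first; generated
#' copies receive fresh unique chain identifiers (original chains recorded in
#' the `source_chain` column).
#'
#' @param s a `wk_structure` with cell and space group (or `ops`).
#' @param radius Angstrom; default 20 (symmetry mates within 20 A).
#' @param seed_selection integer atom indices; default all atoms.
#' @param ops optional character vector of operator strings, overriding the
#'   file/space-group table.
#' @param max_shift lattice translation search range per axis.
#' @return a `wk_structure` containing the retained copies.
#' @export
expand_symmetry <- function(s, radius = 20, seed_selection = NULL, ops = NULL,
                            max_shift = 2) {
  if (radius <= 0) stop("radius must be > 0")
  if (is.null(ops)) ops <- s$symops
  if (is.null(ops)) {
    if (is.null(s$cell) || is.null(s$sgroup))
      stop("missing symmetry metadata (cell/space group); ",
           "use a pre-expanded biological assembly instead")
    ops <- sg_operators(s$sgroup)
  }
  if (is.null(s$cell))
    stop("missing unit cell; use a pre-expanded biological assembly instead")
  M <- .frac2cart(s$cell)
  Minv <- solve(M)
  xyz <- coords(s)
  frac <- xyz %*% t(Minv)
  seed_xyz <- if (is.null(seed_selection)) xyz else
    xyz[seed_selection, , drop = FALSE]
  seed_c <- colMeans(seed_xyz)
  seed_r <- sqrt(max(rowSums(sweep(seed_xyz, 2, seed_c)^2)))

  shifts <- as.matrix(expand.grid(-max_shift:max_shift, -max_shift:max_shift,
                                  -max_shift:max_shift))
  parsed <- lapply(ops, parse_symop)
  pool <- c(LETTERS, letters, as.character(0:9))
  used <- unique(s$atoms$chain)
  next_chain <- function(orig) {
    cand <- setdiff(pool, used)
    id <- if (length(cand)) cand[1] else paste0(orig, length(used))
    used <<- c(used, id)
    id
  }
  out <- list()
  copy_id <- 0L
  for (k in seq_along(parsed)) {
    op <- parsed[[k]]
    f1 <- frac %*% t(op$R)
    for (si in seq_len(nrow(shifts))) {
      tvec <- op$t + as.numeric(shifts[si, ])
      identity_copy <- k == 1 && all(op$t == 0) &&
        all(shifts[si, ] == 0) && all(op$R == diag(3))
      f2 <- sweep(f1, 2, tvec, "+")
      cart <- f2 %*% t(M)
      if (!identity_copy) {
        cc <- colMeans(cart)
        rr <- sqrt(max(rowSums(sweep(cart, 2, cc)^2)))
        if (sqrt(sum((cc - seed_c)^2)) - rr - seed_r > radius) next
        dmin <- min_cross_dist(cart, seed_xyz)
        if (dmin > radius) next
        if (dmin < 1e-6) next  # coincides with identity copy
      }
      copy_id <- copy_id + 1L
      a <- s$atoms
      a$x <- cart[, 1]; a$y <- cart[, 2]; a$z <- cart[, 3]
      a$source_chain <- a$chain
      if (!identity_copy) {
        map <- vapply(unique(a$chain), next_chain, character(1))
        a$chain <- unname(map[a$chain])
      }
      a$symop <- sprintf("%s | %+d%+d%+d", ops[k], shifts[si, 1],
                         shifts[si, 2], shifts[si, 3])
      out[[length(out) + 1L]] <- if (identity_copy) c(list(1), list(a)) else
        c(list(2), list(a))
    }
  }
  ord <- order(vapply(out, function(x) x[[1]], numeric(1)))
  atoms <- do.call(rbind, lapply(out[ord], function(x) x[[2]]))
  wk_structure(atoms, cell = s$cell, sgroup = s$sgroup, symops = s$symops)
}

# minimum cross distance between two coordinate sets (blocked to bound memory)
min_cross_dist <- function(a, b, block = 2000L) {
  best <- Inf
  for (i in seq(1, nrow(a), by = block)) {
    ii <- i:min(i + block - 1L, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
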