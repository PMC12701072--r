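# Structure container and atom selection -------------------------------------

# Residue-name vocabularies used by the selection classes.
.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL","MSE")
.dna_res <- c(t(outer(c("DA","DC","DG","DT","DU","DI","A","C","G","T","U"),
                      c("", "3", "5"), paste0)))
.phosphate_names <- c("P","OP1","OP2","OP3","O1P","O2P","O3P",
                      "O5'","O3'","O5*","O3*")
.sugar_names <- c("C1'","C2'","C3'","C4'","C5'","O4'","O2'",
                  "C1*","C2*","C3*","C4*","C5*","O4*","O2*")
.bb_names <- c("N","CA","C","O","OXT")

#' Construct a molecular structure object
#'
#' A `wk_structure` holds one model's atoms plus, when known, the crystal
#' cell and space group. Atoms live in a data frame with one row per atom:
#' `chain`, `resno` (author numbering, as deposited), `insert`, `resname`,
#' `elety` (PDB atom name), `element`, `x`, `y`, `z`, `occ`.
#'
#' @param atoms data frame with at least `chain`, `resno`, `resname`,
#'   `elety`, `x`, `y`, `z`; `element`, `insert`, `occ` are filled in when
#'   missing (elements inferred from atom names, with a warning).
#' @param cell numeric length-6 unit cell (a, b, c in Angstrom; alpha, beta,
#'   gamma in degrees) or `NULL` when absent.
#' @param sgroup Hermann-Mauguin space-group symbol or `NULL`.
#' @param symops optional character vector of symmetry operators in
#'   "x,y,z"-algebra (as found in mmCIF); used by [expand_symmetry()].
#' @return An object of class `wk_structure`.
#' @export
wk_structure <- function(atoms, cell = NULL, sgroup = NULL, symops = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resname", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element) || anyNA(atoms$element) ||
      any(!nzchar(atoms$element))) {
    bad <- if (is.null(atoms$element)) rep(TRUE, nrow(atoms)) else
      (is.na(atoms$element) | !nzchar(atoms$element))
    if (is.null(atoms$element)) atoms$element <- NA_character_
    atoms$element[bad] <- infer_element(atoms$elety[bad])
    if (any(bad))
      warning(sum(bad), " atom(s) had no element; inferred from atom names")
  }
  atoms$element <- toupper(trimws(atoms$element))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    if (length(cell) != 6 || !all(is.finite(cell)) || any(cell[1:3] <= 0))
      stop("cell must be 6 finite numbers (a, b, c > 0; alpha, beta, gamma)")
  }
  structure(list(atoms = atoms, cell = cell, sgroup = sgroup,
                 symops = symops, chains = unique(atoms$chain)),
            class = "wk_structure")
}

#' @export
print.wk_structure <- function(x, ...) {
  cat("wk_structure:", nrow(x$atoms), "atoms,",
      length(x$chains), "chain(s) [", paste(x$chains, collapse = " "), "]\n")
  if (!is.null(x$cell))
    cat("  cell:", paste(signif(x$cell, 6), collapse = " "),
        " space group:", x$sgroup %||% "?", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the coordinate matrix of a structure
#'
#' @param s a `wk_structure`.
#' @param idx optional integer atom indices.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  if (!is.null(idx)) m <- m[idx, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#' @param s a `wk_structure`.
#' @param xyz numeric n x 3 matrix.
#' @return the modified structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# Element inference from PDB atom names: strip digits/primes, map leading-H
# variants ("1HB", "HG21") to H, recognise common two-letter elements.
infer_element <- function(elety) {
  vapply(elety, function(a) {
    a0 <- toupper(trimws(a))
    if (a0 %in% c("FE","ZN","MG","MN","CL","BR","CU","NI","CO","SE","CD"))
      return(a0)
    a1 <- gsub("[0-9'*\"]", "", a0)
    if (!nzchar(a1)) return("X")
    if (grepl("^[0-9]*H", a0)) return("H")
    substr(a1, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Select atoms of a structure
#'
#' Deterministic, order-preserving selection. Criteria are combined by
#' intersection; build unions with `union()` over several calls. Named atom
#' classes: `"protein"`, `"dna"`, `"heavy"` (element not H/D),
#' `"dna_phosphate"` (P, OP1, OP2, O5', O3'), `"dna_sugar"` (C1'-C5', O4'),
#' `"dna_base"` (remaining heavy DNA atoms), `"protein_backbone"`
#' (N, CA, C, O, OXT) and `"protein_sidechain"`. 5'-terminal nucleotides that
#' lack a phosphate simply contribute fewer phosphate atoms; this is not an
#' error, and an empty selection returns `integer(0)`.
#'
#' @param s a `wk_structure`.
#' @param class character vector of class names (intersected).
#' @param chain,resno,resname,elety,element optional vectors restricting the
#'   selection to matching atoms.
#' @return integer vector of atom row indices (increasing).
#' @export
select_atoms <- function(s, class = NULL, chain = NULL, resno = NULL,
                         resname = NULL, elety = NULL, element = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(class)) {
    known <- c("protein", "dna", "heavy", "dna_phosphate", "dna_sugar",
               "dna_base", "protein_backbone", "protein_sidechain")
    bad <- setdiff(class, known)
    if (length(bad))
      stop("unknown selection class(es): ", paste(bad, collapse = ", "))
    for (cl in class) keep <- keep & .class_mask(a, cl)
  }
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(elety))   keep <- keep & a$elety %in% elety
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  which(keep)
}

.class_mask <- function(a, cl) {
  heavy <- !(a$element %in% c("H", "D"))
  is_dna <- a$resname %in% .dna_res
  is_prot <- a$resname %in% .aa3
  switch(cl,
    heavy = heavy,
    protein = is_prot,
    dna = is_dna,
    dna_phosphate = is_dna & heavy & a$elety %in% .phosphate_names,
    dna_sugar = is_dna & heavy & a$elety %in% .sugar_names,
    dna_base = is_dna & heavy & !(a$elety %in% c(.phosphate_names,
                                                 .sugar_names)),
    protein_backbone = is_prot & a$elety %in% .bb_names,
    protein_sidechain = is_prot & !(a$elety %in% .bb_names))
}

# Structure file input ---------------------------------------------------------

#' Read a structure from PDB or mmCIF
#'
#' Returns the first model's atoms. Alternate locations keep the
#' highest-occupancy conformer (ties: first in file). Cell and space group are
#' populated when the file carries them (`CRYST1` / `_cell`,`_symmetry`),
#' otherwise left `NULL`; mmCIF symmetry operator lists
#' (`_space_group_symop`) are retained for [expand_symmetry()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [wk_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") .read_pdb_file(path) else .read_cif_file(path)
}

.read_pdb_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("parse error in ", path, ": no ATOM/HETATM records found")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  at <- pdb$atom
  # first model only
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
    at$x <- xyz1[, 1]; at$y <- xyz1[, 2]; at$z <- xyz1[, 3]
  }
  at <- .resolve_altloc(at)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = at$resid, elety = at$elety,
                      element = ifelse(is.na(at$elesy), "", at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  cry <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; sg <- NULL
  if (length(cry)) {
    cry <- cry[1]
    cell <- suppressWarnings(as.numeric(c(
      substr(cry, 7, 15), substr(cry, 16, 24), substr(cry, 25, 33),
      substr(cry, 34, 40), substr(cry, 41, 47), substr(cry, 48, 54))))
    sg <- trimws(substr(cry, 56, 66))
    if (anyNA(cell) || all(cell[1:3] == 1)) { cell <- NULL; sg <- NULL }
    if (!is.null(sg) && !nzchar(sg)) sg <- NULL
  }
  wk_structure(atoms, cell = cell, sgroup = sg)
}

# keep highest-occupancy altloc per (chain, resno, insert, elety); ties ->
# first occurrence in file order
.resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt))) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  keep <- !duplicated(key[ord])
  at[sort(ord[keep]), , drop = FALSE]
}

.read_cif_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cif <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  at <- .resolve_altloc(cif$atom)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = at$resid, elety = at$elety,
                      element = ifelse(is.na(at$elesy), "", at$elesy),
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA)
    val <- trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- suppressWarnings(as.numeric(c(
    grab("_cell.length_a"), grab("_cell.length_b"), grab("_cell.length_c"),
    grab("_cell.angle_alpha"), grab("_cell.angle_beta"),
    grab("_cell.angle_gamma"))))
  if (anyNA(cell)) cell <- NULL
  sg <- grab("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group.name_H-M_alt")
  if (is.na(sg)) sg <- NULL
  symops <- .cif_symops(lines)
  wk_structure(atoms, cell = cell, sgroup = sg, symops = symops)
}

# pull operator strings out of a _space_group_symop/_symmetry_equiv loop
.cif_symops <- function(lines) {
  i <- grep("_space_group_symop\\.operation_xyz|_symmetry_equiv(_pos)?\\.pos_as_xyz|_symmetry_equiv_pos_as_xyz",
            lines)
  if (!length(i)) return(NULL)
  ops <- character(0)
  for (j in seq(i[1] + 1, length(lines))) {
    ln <- trimws(lines[j])
    if (!nzchar(ln) || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "#")) break
    m <- regmatches(ln, regexpr("'[^']+'|\"[^\"]+\"|[-+0-9/xyzXYZ,]+$", ln))
    if (length(m)) ops <- c(ops, gsub("^['\"]|['\"]$", "", m))
  }
  if (length(ops)) ops else NULL
}

#' Write a structure to a PDB file
#'
#' Writes `CRYST1` (when cell/space group are present) and fixed-width ATOM
#' records; coordinates are printed at the format's 3-decimal precision.
#'
#' @param s a `wk_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  out <- character(0)
  if (!is.null(s$cell)) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                   s$cell[1], s$cell[2], s$cell[3],
                   s$cell[4], s$cell[5], s$cell[6], s$sgroup %||% "P 1")
  }
  nm <- vapply(seq_len(nrow(a)), function(i) {
    e <- a$elety[i]
    if (nchar(e) >= 4) e
    else if (nchar(a$element[i]) == 2) sprintf("%-4s", e)
    else sprintf(" %-3s", e)
  }, character(1))
  rec <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(a)) %% 100000, nm, a$resname,
                 substr(a$chain, 1, 1), a$resno %% 10000,
                 substr(paste0(a$insert, " "), 1, 1),
                 a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(out, rec, "END"), path)
  invisible(path)
}

# Sequences --------------------------------------------------------------------

#' Read sequence records from a FASTA file
#'
#' @param path FASTA file.
#' @param kind `"auto"` guesses protein vs dna from the alphabet.
#' @return list of records, each `list(id, kind, residues)` with `residues`
#'   a 1-letter string (1-based positions).
#' @export
read_sequences <- function(path, kind = c("auto", "protein", "dna")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  hd <- grep("^>", lines)
  if (!length(hd)) stop("parse error in ", path, ": no FASTA headers")
  ends <- c(hd[-1] - 1, length(lines))
  lapply(seq_along(hd), function(i) {
    id <- sub("^>\\s*", "", lines[hd[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    seqs <- paste(lines[seq(hd[i] + 1, ends[i])], collapse = "")
    seqs <- toupper(gsub("[^A-Za-z*]", "", seqs))
    k <- kind
    if (k == "auto")
      k <- if (grepl("^[ACGTUN]+$", seqs)) "dna" else "protein"
    sequence_record(id, k, seqs)
  })
}

#' Construct a sequence record
#' @param id accession or name.
#' @param kind `"protein"` or `"dna"`.
#' @param residues 1-letter residue string.
#' @return `wk_seqrec` object.
#' @export
sequence_record <- function(id, kind = c("protein", "dna"), residues) {
  kind <- match.arg(kind)
  residues <- toupper(gsub("\\s", "", residues))
  if (kind == "dna" && !grepl("^[ACGTUN]*$", residues))
    stop("dna record contains non-nucleotide letters")
  if (kind == "protein" && !grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", residues))
    stop("protein record contains non-standard letters")
  structure(list(id = id, kind = kind, residues = residues),
            class = "wk_seqrec")
}
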