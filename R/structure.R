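#' Bundled van der Waals radii
#'
#' Element radii in Angstrom used for occupancy tests: C 1.70, N 1.55,
#' O 1.52, S 1.80, P 1.80, H 1.20.  Unknown elements default to 1.7 with
#' a warning at structure construction.
#'
#' @return named numeric vector of radii (Angstrom).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

.element_from_name <- function(name) {
  # strip digits/primes, take the leading element letter(s)
  el <- gsub("[^A-Za-z]", "", name)
  # two-letter elements we care about would come through elesy; atom names
  # in proteins start with the element letter
  toupper(substr(el, 1, 1))
}

#' Construct a structure from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (residue name), `resno`, `chain`, `insert`, `x`, `y`, `z`
#'   (Angstrom) and optionally `occ`.  Missing `element` entries are
#'   derived from the atom name.
#' @param xyz optional n_models x 3n coordinate matrix for multi-model
#'   structures (defaults to a single model from the atom table).
#' @param radii named radius table (defaults to [vdw_radii()]).
#' @return object of class `calyx_structure`.
#' @export
new_structure <- function(atoms, xyz = NULL, radii = vdw_radii()) {
  need <- c("serial", "name", "resid", "resno", "chain", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(atoms$element)) atoms$element <- NA_character_
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  miss <- is.na(atoms$element) | !nzchar(trimws(atoms$element))
  atoms$element[miss] <- .element_from_name(atoms$name[miss])
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  unknown <- !(atoms$element %in% names(radii))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(atoms$element[unknown]),
                                         collapse = ", "),
            ": using default radius 1.7 A")
  }
  atoms$radius <- ifelse(unknown, 1.7, radii[atoms$element])
  if (is.null(xyz)) {
    xyz <- matrix(rbind(atoms$x, atoms$y, atoms$z), nrow = 1)
  }
  stopifnot(ncol(xyz) == 3 * nrow(atoms))
  structure(list(atoms = atoms, xyz = xyz, n_models = nrow(xyz)),
            class = "calyx_structure")
}

#' Coordinates of one model as an n x 3 matrix
#'
#' @param structure a `calyx_structure`.
#' @param model model (frame) index.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
structure_coords <- function(structure, model = 1) {
  stopifnot(inherits(structure, "calyx_structure"),
            model >= 1, model <= structure$n_models)
  matrix(structure$xyz[model, ], ncol = 3, byrow = TRUE)
}

# pre-scan for unparseable coordinate fields so errors can name the line
.scan_pdb_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz))) {
      stop("unparseable coordinate field in ", basename(path), " line ", i)
    }
  }
  invisible(NULL)
}

#' Read a PDB structure (single- or multi-model)
#'
#' Parses ATOM/HETATM records (via bio3d), resolving alternate locations
#' to the highest-occupancy copy and preserving insertion codes.
#' Multi-model files become trajectory frames.
#'
#' @param path path to a PDB file.
#' @param radii named radius table (defaults to [vdw_radii()]).
#' @return a `calyx_structure`.
#' @export
read_structure <- function(path, radii = vdw_radii()) {
  .scan_pdb_coords(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  # resolve altlocs: among records carrying an altloc code, keep the
  # highest-occupancy copy of each atom identity
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  has_alt <- nzchar(at$alt)
  for (k in unique(key[has_alt][duplicated(key[has_alt])])) {
    idx <- which(key == k & has_alt)
    best <- idx[which.max(at$o[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  if (is.null(dim(pdb$xyz))) pdb$xyz <- matrix(pdb$xyz, nrow = 1)
  xyz <- pdb$xyz[, as.numeric(t(outer(which(keep), 1:3,
                                      function(i, j) 3 * (i - 1) + j))),
                 drop = FALSE]
  atoms <- data.frame(serial = at$eleno, name = at$elety,
                      element = at$elesy, resid = at$resid,
                      resno = at$resno, chain = at$chain,
                      insert = at$insert,
                      x = xyz[1, c(TRUE, FALSE, FALSE)],
                      y = xyz[1, c(FALSE, TRUE, FALSE)],
                      z = xyz[1, c(FALSE, FALSE, TRUE)],
                      occ = at$o, stringsAsFactors = FALSE)
  new_structure(atoms, xyz = unclass(xyz), radii = radii)
}

#' Write a structure as PDB
#'
#' Writes fixed-width ATOM records; multi-model structures are wrapped in
#' MODEL/ENDMDL blocks.  Coordinates are written at PDB precision
#' (0.001 Angstrom).
#'
#' @param structure a `calyx_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "calyx_structure"))
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- structure$n_models > 1
  for (m in seq_len(structure$n_models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    co <- structure_coords(structure, m)
    name4 <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                    sprintf("%-4s", a$name))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000, name4, substr(a$resid, 1, 3),
      ifelse(is.na(a$chain) | !nzchar(a$chain), "A", substr(a$chain, 1, 1)),
      a$resno %% 10000, substr(paste0(a$insert, " "), 1, 1),
      co[, 1], co[, 2], co[, 3], a$occ, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @export
print.calyx_structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d model(s), %d residue(s)\n",
              nrow(x$atoms), x$n_models,
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}
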