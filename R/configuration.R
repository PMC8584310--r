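#' Boxed nanotube + ligand configuration
#'
#' Holds one coordinate snapshot: nanotube (carrier) atoms and a list of
#' ligand molecules inside an orthorhombic box, all in nanometres. Analyses
#' treat the nanotube as a single rigid entity and each ligand molecule as a
#' group of atoms with masses (unit masses by default, appropriate for
#' coarse-grained beads).
#'
#' @param box Numeric triple of box edge lengths (nm).
#' @param cnt Matrix (n x 3) of nanotube atom coordinates (nm); may have zero
#'   rows for a configuration without a carrier.
#' @param molecules List of coordinate matrices (atoms x 3), one per ligand
#'   molecule; each must be non-empty.
#' @param masses Optional list of per-atom mass vectors matching `molecules`;
#'   defaults to unit masses.
#' @param periodic Apply periodic boundary conditions (minimum-image
#'   distances)?
#' @return An object of class `configuration`.
#' @export
configuration <- function(box, cnt = matrix(numeric(), 0, 3), molecules = list(),
                          masses = NULL, periodic = TRUE) {
  box <- as.numeric(box)
  stopifnot(length(box) == 3L, all(box > 0))
  cnt <- as_coord_matrix(cnt)
  molecules <- lapply(molecules, as_coord_matrix)
  if (any(vapply(molecules, nrow, integer(1)) == 0L)) {
    stop("every molecule must contain at least one atom", call. = FALSE)
  }
  if (is.null(masses)) {
    masses <- lapply(molecules, function(m) rep(1, nrow(m)))
  }
  stopifnot(length(masses) == length(molecules))
  ok <- mapply(function(m, w) length(w) == nrow(m) && all(w > 0),
               molecules, masses)
  if (length(ok) && !all(ok)) stop("masses must match molecule atoms", call. = FALSE)
  structure(
    list(box = box, cnt = cnt, molecules = molecules, masses = masses,
         periodic = isTRUE(periodic)),
    class = "configuration"
  )
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("Configuration: box %g x %g x %g nm, %d nanotube atoms, %d molecules (%s)\n",
              x$box[1], x$box[2], x$box[3], nrow(x$cnt), length(x$molecules),
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

n_molecules <- function(config) length(config$molecules)

# Displacements under the minimum-image convention for an orthorhombic box.
# d is a matrix of raw displacements (rows = vectors, cols = x,y,z).
min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# All pairwise distances between two coordinate sets (optionally periodic).
pair_dists <- function(a, b, box, periodic) {
  na <- nrow(a); nb <- nrow(b)
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (periodic) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Mass-weighted centre of mass of one coordinate matrix.
centre_of_mass <- function(coords, masses = rep(1, nrow(coords))) {
  colSums(coords * masses) / sum(masses)
}

molecule_coms <- function(config) {
  if (n_molecules(config) == 0L) return(matrix(numeric(), 0, 3))
  t(mapply(centre_of_mass, config$molecules, config$masses))
}

# ---------------------------------------------------------------------------
# XYZ reader/writer. Extended XYZ: comment line may carry `box=Lx,Ly,Lz nm`.
# Molecule grouping comes from a sidecar CSV (columns atom, molecule; the
# value "CNT" marks nanotube atoms) or from an explicit molecule_map vector.

#' Read an XYZ configuration
#'
#' Reads a (single-frame) XYZ file. The comment line may contain a
#' `box=Lx,Ly,Lz` tag (nm); otherwise `box` must be supplied. Molecule
#' grouping comes from `molecule_map`: a vector with one entry per atom,
#' `"CNT"` for nanotube atoms and a molecule identifier otherwise, or the
#' path of a sidecar CSV with columns `atom`, `molecule`.
#'
#' @param path XYZ file path.
#' @param molecule_map Character/numeric vector (one entry per atom) or path
#'   to a sidecar CSV.
#' @param box Box lengths (nm) if not encoded in the comment line.
#' @param unit `"nm"` (default) or `"angstrom"` (divided by 10 on read).
#' @param periodic Passed to [configuration()].
#' @return A [configuration()].
#' @export
read_xyz <- function(path, molecule_map, box = NULL, unit = c("nm", "angstrom"),
                     periodic = TRUE) {
  unit <- match.arg(unit)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed XYZ: fewer than 2 lines", call. = FALSE)
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop("malformed XYZ at line 1: atom count expected", call. = FALSE)
  if (length(lines) < 2L + nat) {
    stop(sprintf("malformed XYZ: expected %d atom lines, file ends at line %d",
                 nat, length(lines)), call. = FALSE)
  }
  comment <- lines[2]
  m <- regmatches(comment,
                  regexec("box=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                          comment))[[1]]
  if (length(m) == 4L) box <- as.numeric(m[2:4])
  if (is.null(box)) stop("no box= tag in XYZ comment and no box supplied",
                         call. = FALSE)
  coords <- matrix(NA_real_, nat, 3)
  for (i in seq_len(nat)) {
    tok <- strsplit(trimws(lines[2L + i]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L) {
      stop(sprintf("malformed XYZ at line %d: element x y z expected", 2L + i),
           call. = FALSE)
    }
    coords[i, ] <- as.numeric(tok[2:4])
  }
  if (anyNA(coords)) stop("malformed XYZ: non-numeric coordinates", call. = FALSE)
  if (unit == "angstrom") coords <- coords / 10
  if (length(molecule_map) == 1L && is.character(molecule_map) &&
      file.exists(molecule_map)) {
    map_df <- utils::read.csv(molecule_map)
    molecule_map <- map_df$molecule[order(map_df$atom)]
  }
  if (length(molecule_map) != nat) {
    stop("molecule_map must have one entry per atom", call. = FALSE)
  }
  build_configuration(coords, molecule_map, box, periodic)
}

build_configuration <- function(coords, molecule_map, box, periodic) {
  molecule_map <- as.character(molecule_map)
  is_cnt <- molecule_map == "CNT"
  cnt <- coords[is_cnt, , drop = FALSE]
  ids <- unique(molecule_map[!is_cnt])
  mols <- lapply(ids, function(id)
    coords[molecule_map == id, , drop = FALSE])
  configuration(box, cnt, mols, periodic = periodic)
}

#' Write an XYZ configuration (plus molecule-map sidecar)
#'
#' @param config A [configuration()].
#' @param path Output XYZ path; the sidecar CSV is written to
#'   `paste0(path, ".molecules.csv")` unless `map_path` is given.
#' @param map_path Optional sidecar CSV path.
#' @return Invisibly, the XYZ path.
#' @export
write_xyz <- function(config, path, map_path = paste0(path, ".molecules.csv")) {
  stopifnot(inherits(config, "configuration"))
  coords <- rbind(config$cnt, do.call(rbind, c(config$molecules,
                                               list(matrix(numeric(), 0, 3)))))
  map <- c(rep("CNT", nrow(config$cnt)),
           rep(sprintf("M%d", seq_along(config$molecules)),
               vapply(config$molecules, nrow, integer(1))))
  elem <- ifelse(map == "CNT", "C", "X")
  lines <- c(
    as.character(nrow(coords)),
    sprintf("box=%.6f,%.6f,%.6f nm", config$box[1], config$box[2], config$box[3]),
    sprintf("%s %.6f %.6f %.6f", elem, coords[, 1], coords[, 2], coords[, 3])
  )
  writeLines(lines, path)
  utils::write.csv(data.frame(atom = seq_along(map), molecule = map),
                   map_path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GRO reader/writer (standard fixed-column format, coordinates in nm).
# Molecule grouping comes from residue ids; nanotube atoms are the residues
# named `cnt_resname`.

#' Read a GRO configuration
#'
#' Standard fixed-column GROMACS coordinate file (nm). Atoms of residues
#' named `cnt_resname` become the nanotube; every other residue id becomes
#' one ligand molecule.
#'
#' @param path GRO file path.
#' @param cnt_resname Residue name marking nanotube atoms (default `"CNT"`).
#' @param periodic Passed to [configuration()].
#' @return A [configuration()].
#' @export
read_gro <- function(path, cnt_resname = "CNT", periodic = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO: fewer than 3 lines", call. = FALSE)
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop("malformed GRO at line 2: atom count expected", call. = FALSE)
  if (length(lines) < 3L + nat) {
    stop("malformed GRO: truncated atom records", call. = FALSE)
  }
  atom_lines <- lines[3:(2L + nat)]
  resid <- as.integer(substr(atom_lines, 1, 5))
  resname <- trimws(substr(atom_lines, 6, 10))
  x <- as.numeric(substr(atom_lines, 21, 28))
  y <- as.numeric(substr(atom_lines, 29, 36))
  z <- as.numeric(substr(atom_lines, 37, 44))
  if (anyNA(x) || anyNA(y) || anyNA(z)) {
    stop("malformed GRO: non-numeric coordinates", call. = FALSE)
  }
  box <- as.numeric(strsplit(trimws(lines[3L + nat]), "[[:space:]]+")[[1]])[1:3]
  if (anyNA(box)) stop("malformed GRO: bad box line", call. = FALSE)
  map <- ifelse(resname == cnt_resname, "CNT", sprintf("R%d", resid))
  build_configuration(cbind(x, y, z), map, box, periodic)
}

#' Write a GRO configuration
#'
#' @param config A [configuration()].
#' @param path Output path.
#' @param cnt_resname Residue name used for nanotube atoms.
#' @return Invisibly, the path.
#' @export
write_gro <- function(config, path, cnt_resname = "CNT") {
  stopifnot(inherits(config, "configuration"))
  fmt <- function(resid, resname, atomname, idx, xyz) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid %% 100000L, resname,
            atomname, idx %% 100000L, xyz[1], xyz[2], xyz[3])
  }
  lines <- c("configuration written by cntrelease", "")
  idx <- 0L
  recs <- character(0)
  for (i in seq_len(nrow(config$cnt))) {
    idx <- idx + 1L
    recs <- c(recs, fmt(1L, cnt_resname, "C", idx, config$cnt[i, ]))
  }
  for (j in seq_along(config$molecules)) {
    mol <- config$molecules[[j]]
    for (i in seq_len(nrow(mol))) {
      idx <- idx + 1L
      recs <- c(recs, fmt(j + 1L, "LIG", "X", idx, mol[i, ]))
    }
  }
  lines[2] <- as.character(idx)
  lines <- c(lines, recs,
             sprintf("%10.5f%10.5f%10.5f", config$box[1], config$box[2],
                     config$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration in either supported format
#'
#' @param path Coordinate file path.
#' @param format `"xyz"` or `"gro"`; default guessed from the extension.
#' @param ... Passed to [read_xyz()] or [read_gro()].
#' @return A [configuration()].
#' @export
read_configuration <- function(path, format = c("auto", "xyz", "gro"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "xyz"
  }
  switch(format, xyz = read_xyz(path, ...), gro = read_gro(path, ...))
}
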