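# Fixed-width PDB (v3) input/output for single structures and multi-MODEL
# conformational ensembles.
#
# A structure is a data frame of atom records plus a title; an ensemble keeps
# one shared atom roster and a frames-by-coordinates matrix (frame i stores
# x1,y1,z1,x2,... in row i), which is the natural layout for superposition and
# fluctuation work.

.ATOM_COLS <- c("type", "serial", "name", "alt", "resname", "chain",
                "resno", "icode", "x", "y", "z", "occ", "b", "element")

new_structure <- function(atoms, title = "") {
  stopifnot(is.data.frame(atoms), all(.ATOM_COLS %in% names(atoms)))
  structure(list(atoms = atoms[, .ATOM_COLS], title = title),
            class = "pdb_structure")
}

new_ensemble <- function(roster, xyz, times = NULL, label = "") {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L * nrow(roster))
  if (!is.null(times)) {
    stopifnot(length(times) == nrow(xyz))
    if (any(diff(times) <= 0)) .stopf("frame times must be strictly increasing")
  }
  structure(list(atoms = roster, xyz = xyz, times = times, label = label),
            class = "pdb_ensemble")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms, chains: %s%s\n", nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ""),
              if (nzchar(x$title)) paste0(" | ", x$title) else ""))
  invisible(x)
}

#' @export
print.pdb_ensemble <- function(x, ...) {
  cat(sprintf("<pdb_ensemble> %d frames x %d atoms%s\n", nrow(x$xyz),
              nrow(x$atoms),
              if (nzchar(x$label)) paste0(" | ", x$label) else ""))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param x A `pdb_structure`.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "pdb_structure"))
  cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z)
}

#' @rdname coords
#' @param value Replacement coordinate matrix (atoms by 3).
#' @export
`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "pdb_structure"), nrow(value) == nrow(x$atoms))
  x$atoms$x <- value[, 1]
  x$atoms$y <- value[, 2]
  x$atoms$z <- value[, 3]
  x
}

#' Number of frames in an ensemble
#' @param ensemble A `pdb_ensemble`.
#' @export
n_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  nrow(ensemble$xyz)
}

#' Extract one frame of an ensemble as a structure
#' @param ensemble A `pdb_ensemble`.
#' @param i Frame index.
#' @export
ens_frame <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  if (!.is_count(i) || i < 1 || i > nrow(ensemble$xyz)) .stopf("bad frame index")
  m <- matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
  atoms <- ensemble$atoms
  atoms$x <- m[, 1]
  atoms$y <- m[, 2]
  atoms$z <- m[, 3]
  new_structure(atoms, title = sprintf("%s frame %d", ensemble$label, i))
}

#' Assemble an ensemble from structures with identical atom rosters
#' @param frames List of `pdb_structure` objects.
#' @param times Optional strictly increasing frame times (ns).
#' @param label Free-text label.
#' @export
ensemble_from_frames <- function(frames, times = NULL, label = "") {
  stopifnot(length(frames) >= 1L)
  ros <- frames[[1]]$atoms
  key <- function(a) paste(a$chain, a$resno, a$icode, a$name, sep = "|")
  k1 <- key(ros)
  for (f in frames[-1]) {
    if (nrow(f$atoms) != nrow(ros) || !identical(key(f$atoms), k1)) {
      .stopf("inconsistent atom rosters across frames",
             class = "phosready_ensemble_error")
    }
  }
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(coords(f)))))
  new_ensemble(ros, xyz, times = times, label = label)
}

.parse_atom_lines <- function(lines, lineno) {
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  lines <- vapply(lines, pad, character(1), n = 80, USE.NAMES = FALSE)
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(lines, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0) {
      .stopf("malformed %s field in PDB line %d", what, lineno[bad[1]],
             class = "phosready_parse_error")
    }
    v
  }
  elem <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  guess <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
  elem <- ifelse(nzchar(elem), elem, guess)
  data.frame(
    type = trimws(substr(lines, 1, 6)),
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    alt = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resno = as.integer(num(23, 26, "residue number")),
    icode = substr(lines, 27, 27),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = num(55, 60, "occupancy"), b = num(61, 66, "B-factor"),
    element = elem,
    stringsAsFactors = FALSE
  )
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records per the PDB v3 fixed-width layout. Files with a
#' single coordinate set give a `pdb_structure`; multi-MODEL files give a
#' `pdb_ensemble` after verifying that every MODEL carries the same atom
#' roster. Alternate locations other than blank or `'A'` are dropped.
#'
#' @param path Path to a PDB file.
#' @return A `pdb_structure` or `pdb_ensemble`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) .stopf("PDB file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  title <- paste(trimws(substr(lines[rec == "TITLE "], 11, 80)), collapse = " ")
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) <= 1L) {
    idx <- which(is_atom)
    if (length(idx) == 0L) .stopf("no ATOM/HETATM records in %s", path,
                                  class = "phosready_parse_error")
    atoms <- .parse_atom_lines(lines[idx], idx)
    atoms <- atoms[atoms$alt %in% c(" ", "A"), , drop = FALSE]
    rownames(atoms) <- NULL
    return(new_structure(atoms, title = title))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts)) {
    .stopf("unbalanced MODEL/ENDMDL records in %s", path,
           class = "phosready_parse_error")
  }
  frames <- lapply(seq_along(model_starts), function(i) {
    idx <- which(is_atom & seq_along(lines) > model_starts[i] &
                   seq_along(lines) < model_ends[i])
    atoms <- .parse_atom_lines(lines[idx], idx)
    atoms <- atoms[atoms$alt %in% c(" ", "A"), , drop = FALSE]
    rownames(atoms) <- NULL
    new_structure(atoms, title = title)
  })
  ens <- tryCatch(ensemble_from_frames(frames, label = title),
                  phosready_ensemble_error = function(e) {
                    .stopf("inconsistent atom rosters across MODELs in %s", path,
                           class = "phosready_ensemble_error")
                  })
  ens
}

.format_atom_lines <- function(atoms) {
  if (any(abs(c(atoms$x, atoms$y, atoms$z)) >= 10000)) {
    .stopf("coordinate magnitude >= 10000 Angstrom does not fit the fixed-width format",
           class = "phosready_format_error")
  }
  name4 <- ifelse(nchar(atoms$name) >= 4L | nchar(atoms$element) >= 2L,
                  sprintf("%-4s", atoms$name), sprintf(" %-3s", atoms$name))
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$type, atoms$serial, name4, atoms$alt, atoms$resname,
          atoms$chain, atoms$resno, atoms$icode,
          atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
          formatC(atoms$element, width = 2))
}

#' Write a structure or ensemble to a PDB file
#'
#' Fixed-width PDB v3 output; coordinates are rounded to 3 decimals and
#' B-factors to 2. Ensembles are wrapped in MODEL/ENDMDL records.
#'
#' @param x A `pdb_structure` or `pdb_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  out <- character(0)
  if (inherits(x, "pdb_structure")) {
    if (nzchar(x$title)) out <- sprintf("TITLE     %s", x$title)
    out <- c(out, .format_atom_lines(x$atoms), "END")
  } else if (inherits(x, "pdb_ensemble")) {
    if (nzchar(x$label)) out <- sprintf("TITLE     %s", x$label)
    for (i in seq_len(nrow(x$xyz))) {
      fr <- ens_frame(x, i)
      out <- c(out, sprintf("MODEL     %4d", i),
               .format_atom_lines(fr$atoms), "ENDMDL")
    }
    out <- c(out, "END")
  } else {
    .stopf("x must be a pdb_structure or pdb_ensemble")
  }
  writeLines(out, path)
  invisible(path)
}

#' Select atoms of a structure or roster
#'
#' @param x A `pdb_structure`, `pdb_ensemble` or atom data frame.
#' @param what One of `"all"`, `"backbone"` (N, CA, C, O of ATOM records),
#'   `"calpha"`, `"sidechain"` (ATOM records beyond the backbone) or
#'   `"heavy"`.
#' @param chain,resno,name,resname Optional additional filters.
#' @return Integer vector of atom indices.
#' @export
atom_select <- function(x, what = c("all", "backbone", "calpha", "sidechain",
                                    "heavy"),
                        chain = NULL, resno = NULL, name = NULL,
                        resname = NULL) {
  what <- match.arg(what)
  atoms <- if (is.data.frame(x)) x else x$atoms
  keep <- switch(what,
    all = rep(TRUE, nrow(atoms)),
    backbone = atoms$type == "ATOM" & atoms$name %in% .BACKBONE,
    calpha = atoms$type == "ATOM" & atoms$name == "CA",
    sidechain = atoms$type == "ATOM" & !(atoms$name %in% .BACKBONE),
    heavy = atoms$element != "H"
  )
  keep <- keep & atoms$element != "H"   # hydrogens never enter selections
  if (!is.null(chain)) keep <- keep & atoms$chain %in% chain
  if (!is.null(resno)) keep <- keep & atoms$resno %in% resno
  if (!is.null(name)) keep <- keep & atoms$name %in% name
  if (!is.null(resname)) keep <- keep & atoms$resname %in% resname
  which(keep)
}
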