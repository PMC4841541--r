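# Internal constants and small geometry helpers shared across modules.

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA1_FROM_3 <- stats::setNames(names(.AA3), unname(.AA3))

# conventional backbone heavy-atom set
.BACKBONE <- c("N", "CA", "C", "O")

# Debye-Waller conversion constant: B = (8 * pi^2 / 3) * <dr^2>
.B_CONST <- 8 * pi^2 / 3

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

.stopf <- function(fmt, ..., class = "phosready_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

.check_residue_letters <- function(residues, what = "sequence") {
  letters1 <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters1), .AA1)
  if (length(bad) > 0) {
    .stopf("%s contains non-standard residue letters: %s", what,
           paste(bad, collapse = ", "), class = "phosready_input_error")
  }
  letters1
}

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) .stopf("cannot normalise a zero-length vector")
  v / n
}

# Place atom D given atoms a-b-c, the c-D bond length, the D-c-b angle and
# the D-c-b-a dihedral (degrees). Natural-extension reference frame.
.place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .unit(c - b)
  n <- .unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.dist3 <- function(p, q) sqrt(sum((p - q)^2))

# pairwise distance matrix between two coordinate matrices (rows = atoms)
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
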