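# Independent oracles and shared fixtures for the test suite. The oracles
# deliberately use naive position-by-position / all-pairs loops so they share
# no code with the implementation they check.

# the RS-domain-bearing fragment used throughout (author numbering 72-87)
lbr_region <- function() rs_region("PSRRSRSRSRSRSPGR", start = 72, name = "LBR")

# brute-force minimal-consensus scanner: loop over every position
oracle_akt_scan <- function(residues, start) {
  aa <- strsplit(residues, "")[[1]]
  hits <- integer(0)
  for (i in seq_along(aa)) {
    if (!(aa[i] %in% c("S", "T"))) next
    if (i - 5 < 1) next
    if (aa[i - 3] == "R" && aa[i - 5] == "R") hits <- c(hits, i + start - 1L)
  }
  hits
}

# brute-force RS/SR dipeptide scanner: check both neighbours of every S
oracle_srpk_scan <- function(residues, start) {
  aa <- strsplit(residues, "")[[1]]
  hits <- integer(0)
  for (i in seq_along(aa)) {
    if (aa[i] != "S") next
    left <- i > 1 && aa[i - 1] == "R"
    right <- i < length(aa) && aa[i + 1] == "R"
    if (left || right) hits <- c(hits, i + start - 1L)
  }
  hits
}

# brute-force candidate filter: Ser/Thr, -3 Arg, full -6..+3 window
oracle_candidate_sites <- function(residues, start) {
  aa <- strsplit(residues, "")[[1]]
  hits <- integer(0)
  for (i in seq_along(aa)) {
    if (!(aa[i] %in% c("S", "T"))) next
    if (i - 6 < 1 || i + 3 > length(aa)) next
    if (aa[i - 3] == "R") hits <- c(hits, i + start - 1L)
  }
  hits
}

# canonical heavy-atom counts of side chains (CB onwards), written out by hand
SIDECHAIN_HEAVY <- c(ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5,
                     GLU = 5, GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5,
                     MET = 4, PHE = 7, PRO = 3, SER = 2, THR = 3, TRP = 10,
                     TYR = 8, VAL = 3)

# naive all-pairs minimum distance between two atom tables
oracle_min_distance <- function(atoms_a, atoms_b) {
  best <- Inf
  for (i in seq_len(nrow(atoms_a))) {
    for (j in seq_len(nrow(atoms_b))) {
      d <- sqrt((atoms_a$x[i] - atoms_b$x[j])^2 +
                  (atoms_a$y[i] - atoms_b$y[j])^2 +
                  (atoms_a$z[i] - atoms_b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# textbook Pearson formula, written independently of stats::cor
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# a small complex keeping atom counts down for ensemble-heavy tests
small_complex <- function(seq = "RRSRSRSRSR", distance = 3.5,
                          mode = "ternary", seed = 1) {
  make_toy_complex(seq, catalytic_distance = distance, mode = mode,
                   n_kinase_residues = 4L, seed = seed, name = "small")
}

# random amino-acid string over a restricted alphabet
random_seq <- function(n, alphabet = c("A", "R", "S", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# deform the peptide of a structure with an internal hinge rotation (survives
# rigid superposition, unlike a whole-body displacement)
hinge_deform <- function(structure, chain = "B", angle_deg = 60) {
  idx <- atom_select(structure, chain = chain)
  resnos <- sort(unique(structure$atoms$resno[idx]))
  moving <- idx[structure$atoms$resno[idx] %in% resnos[6:length(resnos)]]
  th <- angle_deg * pi / 180
  rot <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
                byrow = TRUE)
  xyz <- coords(structure)
  pivot <- xyz[moving[1], ]
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, pivot) %*% rot,
                         2, pivot, "+")
  coords(structure) <- xyz
  structure
}
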