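# Synthetic fixtures standing in for molecular-dynamics output: toy
# kinase/peptide/cofactor complexes with prescribed catalytic geometry, and
# Gaussian conformational ensembles with prescribed per-residue fluctuation
# amplitudes. These generators are statistical stand-ins, not physics: frames
# are i.i.d. isotropic Gaussian displacements with no temporal
# autocorrelation, which is sufficient for estimators that are functions of
# the marginal fluctuation (RMSF, B-factors, cluster memberships).

.BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 n_ca_c = 111.0, ca_c_n = 116.2, c_n_ca = 121.7,
                 ca_c_o = 120.8)

# backbone of a chain with fixed (phi, psi); returns list of 4x3 matrices
.build_backbone <- function(n_res, phi, psi) {
  g <- .BB_GEOM
  out <- vector("list", n_res)
  n <- c(0, 0, 0)
  ca <- c(g$n_ca, 0, 0)
  ang <- g$n_ca_c * pi / 180
  c_at <- ca + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      n_next <- .place_atom(n, ca, c_at, g$c_n, g$ca_c_n, psi)
      o <- .place_atom(n_next, ca, c_at, g$c_o, g$ca_c_o, 180)
      ca_next <- .place_atom(ca, c_at, n_next, g$n_ca, g$c_n_ca, 180)
      c_next <- .place_atom(c_at, n_next, ca_next, g$ca_c, g$n_ca_c, phi)
    } else {
      o <- .place_atom(n, ca, c_at, g$c_o, g$ca_c_o, psi + 180)
    }
    out[[i]] <- rbind(N = n, CA = ca, C = c_at, O = o)
    if (i < n_res) {
      n <- n_next
      ca <- ca_next
      c_at <- c_next
    }
  }
  out
}

# one peptide chain as a structure: fixed backbone conformation, side chains
# from ideal residue geometry fitted to the backbone
.build_chain <- function(seq1, chain, resno_start, phi = -139, psi = 135,
                         b = 20, offset = c(0, 0, 0), type = "ATOM") {
  letters1 <- .check_residue_letters(toupper(seq1), "chain sequence")
  bb <- .build_backbone(length(letters1), phi, psi)
  rows <- lapply(seq_along(letters1), function(i) {
    res3 <- unname(.AA3[letters1[i]])
    anchors <- bb[[i]][c("N", "CA", "C"), , drop = FALSE]
    fit <- .fit_residue_template(res3, anchors)
    keep <- !(fit$names %in% .BACKBONE)
    xyz <- rbind(bb[[i]], fit$coords[keep, , drop = FALSE])
    nm <- c(.BACKBONE, fit$names[keep])
    el <- c("N", "C", "C", "O", fit$elements[keep])
    data.frame(type = type, serial = 0L, name = nm, alt = " ",
               resname = res3, chain = chain,
               resno = resno_start + i - 1L, icode = " ",
               x = xyz[, 1] + offset[1], y = xyz[, 2] + offset[2],
               z = xyz[, 3] + offset[3],
               occ = 1, b = b, element = el, stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_structure(atoms)
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
.rotation_between <- function(a, b) {
  a <- .unit(a)
  b <- .unit(b)
  v <- pracma_cross(a, b)
  s <- .vnorm(v)
  cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(pracma_cross(a, p))
    return(2 * outer(axis, axis) - diag(3))
  }
  k <- v / s
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + s * kx + (1 - cth) * (kx %*% kx)
}

# place an isolated, ideal-geometry kinase residue so that its side-chain tip
# sits `gap` Angstrom beyond the tip of the paired peptide side chain, pointing
# back at it
.place_contact_residue <- function(resname, resno, chain, pep_atoms,
                                   pep_resno, gap, b = 15) {
  pr <- pep_atoms[pep_atoms$resno == pep_resno, , drop = FALSE]
  p_ca <- unlist(pr[pr$name == "CA", c("x", "y", "z")])
  sc <- pr[!(pr$name %in% .BACKBONE), , drop = FALSE]
  if (nrow(sc) == 0L) {
    p_tip <- p_ca
    u <- c(0, 0, 1)
  } else {
    d <- apply(as.matrix(sc[, c("x", "y", "z")]), 1L,
               function(p) .dist3(p, p_ca))
    p_tip <- unlist(sc[which.max(d), c("x", "y", "z")])
    u <- .unit(p_tip - p_ca)
  }
  tpl <- .residue_template(resname)
  txyz <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(txyz) <- tpl$name
  t_ca <- txyz["CA", ]
  tsc <- txyz[!(tpl$name %in% .BACKBONE), , drop = FALSE]
  d <- apply(tsc, 1L, function(p) .dist3(p, t_ca))
  t_tip <- tsc[which.max(d), ]
  rot <- .rotation_between(.unit(t_ca - t_tip), u)
  placed <- sweep(sweep(txyz, 2L, t_tip) %*% t(rot), 2L,
                  p_tip + gap * u, "+")
  data.frame(type = "ATOM", serial = 0L, name = tpl$name, alt = " ",
             resname = resname, chain = chain, resno = resno, icode = " ",
             x = placed[, 1], y = placed[, 2], z = placed[, 3],
             occ = 1, b = b, element = tpl$element, stringsAsFactors = FALSE)
}

.het_atoms <- function(names, elements, xyz, resname, chain, resno, b = 20) {
  data.frame(type = "HETATM", serial = 0L, name = names, alt = " ",
             resname = resname, chain = chain, resno = resno, icode = " ",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occ = 1, b = b,
             element = elements, stringsAsFactors = FALSE)
}

#' Build a toy kinase/peptide/cofactor complex
#'
#' A geometrically plausible placeholder complex for testing and synthetic
#' studies: the 10-mer substrate peptide in an extended conformation, a
#' compact dummy helical kinase scaffold, single kinase residues from the
#' contact checklist ([default_contact_checklist()]) placed against their
#' peptide partners, and (in ternary mode) a nucleotide whose
#' gamma-phosphorus is placed so that the p0 hydroxyl-oxygen distance equals
#' `catalytic_distance` exactly, two metal ions, three metal-coordinated
#' waters and two distant waters. Deterministic given `seed`.
#'
#' @param peptide_seq 10-residue one-letter sequence, Ser/Thr at position 7.
#' @param catalytic_distance Prescribed Ser-O-gamma to P-gamma distance
#'   (Angstrom).
#' @param mode `"ternary"` (with cofactor/metals/waters) or `"binary"`.
#' @param cofactor_name `"ATP"` or `"ANP"` (sets the beta-gamma bridge atom to
#'   O3B or N3B accordingly).
#' @param metal_name `"MG"` or `"MN"`.
#' @param n_kinase_residues Length of the dummy scaffold helix.
#' @param peptide_start_resno Author numbering of the peptide's first residue
#'   (the phosphosite is then `peptide_start_resno + 6`).
#' @param og_bfactor B-factor stamped on the p0 hydroxyl oxygen.
#' @param include_tail Add a 14-residue hydrophobic-motif tail (residues
#'   466-479 of the kinase chain, Asp at 474).
#' @param seed Integer seed (scaffold sequence sampling).
#' @param name System label.
#' @return A `complex_model`.
#' @export
make_toy_complex <- function(peptide_seq, catalytic_distance = 3.5,
                             mode = c("ternary", "binary"),
                             cofactor_name = "ATP", metal_name = "MG",
                             n_kinase_residues = 30L,
                             peptide_start_resno = 1L, og_bfactor = 20,
                             include_tail = FALSE, seed = 1L, name = "toy") {
  mode <- match.arg(mode)
  peptide_seq <- toupper(peptide_seq)
  if (nchar(peptide_seq) != 10L) {
    .stopf("peptide_seq must have exactly 10 residues",
           class = "phosready_input_error")
  }
  letters1 <- .check_residue_letters(peptide_seq, "peptide_seq")
  if (!(letters1[7] %in% c("S", "T"))) {
    .stopf("peptide position 7 must be Ser/Thr",
           class = "phosready_input_error")
  }
  if (catalytic_distance < 0) .stopf("catalytic_distance must be >= 0")
  set.seed(seed)

  peptide <- .build_chain(peptide_seq, "B", peptide_start_resno, b = 20)
  p0_resno <- peptide_start_resno + 6L
  is_og <- peptide$atoms$resno == p0_resno &
    peptide$atoms$name %in% c("OG", "OG1")
  peptide$atoms$b[is_og] <- og_bfactor

  scaffold_seq <- paste(sample(c("A", "L", "S", "V", "G", "E", "K"),
                               n_kinase_residues, replace = TRUE),
                        collapse = "")
  kin <- .build_chain(scaffold_seq, "A", 150L, phi = -57, psi = -47,
                      b = 15, offset = c(-5, 12, 8))$atoms
  ck <- default_contact_checklist()
  gaps <- ifelse(ck$kind %in% c("salt_bridge", "h_bond"), 2.8, 3.8)
  for (i in seq_len(nrow(ck))) {
    kin <- rbind(kin, .place_contact_residue(
      ck$kinase_resname[i], ck$kinase_resno[i], "A", peptide$atoms,
      p0_resno + ck$register[i], gaps[i]))
  }
  kin <- kin[order(kin$resno), , drop = FALSE]
  kin$serial <- seq_len(nrow(kin))
  rownames(kin) <- NULL
  kinase <- new_structure(kin)

  tail <- if (include_tail) {
    .build_chain("QRTHFPQFDYSASI", "A", 466L, phi = -57, psi = -47,
                 b = 25, offset = c(10, -16, 6))
  } else .empty_slice()

  if (mode == "binary") {
    model <- new_complex_model(kinase, peptide, tail, .empty_slice(),
                               .empty_slice(), .empty_slice(),
                               mode = "binary", site = p0_resno, label = name)
    model$meta$seed <- seed
    return(model)
  }

  og <- unlist(peptide$atoms[is_og, c("x", "y", "z")][1, ])
  cb <- unlist(peptide$atoms[peptide$atoms$resno == p0_resno &
                               peptide$atoms$name == "CB",
                             c("x", "y", "z")][1, ])
  v <- .unit(og - cb)
  w1 <- .unit(pracma_cross(v, if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  w2 <- pracma_cross(v, w1)
  pg <- og + catalytic_distance * v
  bridge <- if (cofactor_name == "ANP") c("N3B", "N") else c("O3B", "O")
  cof_names <- c("PG", "O1G", "O2G", "O3G", bridge[1], "PB", "O1B", "O2B",
                 "O3A", "PA", "O1A", "O2A", "O5'", "C5'")
  cof_elem <- c("P", "O", "O", "O", bridge[2], "P", "O", "O",
                "O", "P", "O", "O", "O", "C")
  along <- c(0, 0.5, 0.5, 0.5, 1.6, 3.2, 3.7, 3.7, 4.8, 6.4, 6.9, 6.9, 8.0, 9.4)
  side1 <- c(0, 1.5, -0.75, -0.75, 0, 0, 1.5, -0.75, 0, 0, 1.5, -0.75, 0, 0)
  side2 <- c(0, 0, 1.3, -1.3, 0, 0, 0, 1.3, 0, 0, 0, 1.3, 0, 0.8)
  cof_xyz <- t(vapply(seq_along(cof_names), function(i) {
    pg + along[i] * v + side1[i] * w1 + side2[i] * w2
  }, numeric(3)))
  cofactor <- new_structure({
    a <- .het_atoms(cof_names, cof_elem, cof_xyz, cofactor_name, "C", 500L)
    a$serial <- seq_len(nrow(a))
    a
  })

  o1g <- cof_xyz[2, ]
  o1b <- cof_xyz[7, ]
  m_xyz <- rbind(o1g + 2.1 * w1, o1b + 2.1 * w1)
  metals <- new_structure({
    a <- .het_atoms(c(metal_name, metal_name), c(metal_name, metal_name),
                    m_xyz, metal_name, "C", c(601L, 602L))
    a$serial <- seq_len(nrow(a))
    a
  })

  w_xyz <- rbind(m_xyz[1, ] + 2.15 * w2,
                 m_xyz[1, ] - 2.15 * w2,
                 m_xyz[2, ] + 2.15 * w2,
                 m_xyz[1, ] + 9.0 * w2,
                 m_xyz[2, ] - 9.0 * w2)
  waters <- new_structure({
    a <- .het_atoms(rep("O", 5), rep("O", 5), w_xyz, "HOH", "W",
                    701:705, b = 30)
    a$serial <- seq_len(nrow(a))
    a
  })

  model <- new_complex_model(kinase, peptide, tail, cofactor, metals, waters,
                             mode = "ternary", site = p0_resno, label = name)
  model$meta$seed <- seed
  model
}

#' Synthetic stand-in for the kinase/GSK3-peptide template crystal structure
#'
#' Builds a complete synthetic template complex laid out like the deposited
#' Akt2 kinase domain in complex with its GSK3-beta 10-mer substrate peptide
#' (sequence GRPRTTSFAE), AMP-PNP (ANP) and two Mn ions (PDB entry 1O6K):
#' kinase and hydrophobic-motif tail (residues 466-479, Asp474) on chain A,
#' peptide on chain B, cofactor, metals and coordinated waters as
#' heteroatoms. The catalytic geometry is calibrated to the published values
#' for that entry (Ser-O-gamma to P-gamma distance 3.57 Angstrom;
#' crystallographic O-gamma B-factor 14.8 Angstrom^2) so the stand-in
#' exercises the same measurement paths as the real file. Users holding the
#' actual crystal structure should read it with [read_pdb()] and pass it to
#' [extract_template()] instead; this object is synthetic and carries no
#' experimental coordinates.
#'
#' @param path Optional path; when given the structure is also written as a
#'   PDB file.
#' @return A `pdb_structure` of the assembled synthetic template.
#' @export
synthetic_template <- function(path = NULL) {
  model <- make_toy_complex("GRPRTTSFAE", catalytic_distance = 3.57,
                            mode = "ternary", cofactor_name = "ANP",
                            metal_name = "MN", n_kinase_residues = 40L,
                            peptide_start_resno = 1L, og_bfactor = 14.8,
                            include_tail = TRUE, seed = 106L,
                            name = "SYNTHETIC Akt2-like template complex (stand-in, not experimental coordinates)")
  s <- as_structure(model)
  s$title <- model$label
  if (!is.null(path)) write_pdb(s, path)
  s
}

#' Per-register fluctuation specification
#'
#' Prescribes the per-coordinate Gaussian displacement scale (sigma,
#' Angstrom) for each consensus register position of the bound peptide, plus
#' a common scale for all non-peptide atoms. The built-in profiles emulate
#' the two qualitative behaviours of bound substrate peptides: `optimal_like`
#' peptides are held rigidly over the consensus span (-5..+1) and fray only
#' at the termini, while `weak_like` peptides stay mobile throughout,
#' including around the phosphosite.
#'
#' @param profile_label `"optimal_like"`, `"weak_like"` or `"custom"`.
#' @param sigma For `"custom"`: named numeric vector over registers
#'   `-6..3` (names `"-6"` ... `"3"`).
#' @param kinase_sigma Scale for all non-peptide atoms (Angstrom).
#' @return An object of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(profile_label = c("optimal_like", "weak_like",
                                               "custom"),
                             sigma = NULL, kinase_sigma = 0.1) {
  profile_label <- match.arg(profile_label)
  regs <- as.character(-6:3)
  if (profile_label == "optimal_like") {
    sigma <- stats::setNames(rep(1.0, 10), regs)
    sigma[as.character(-5:1)] <- 0.65
  } else if (profile_label == "weak_like") {
    sigma <- stats::setNames(rep(0.95, 10), regs)
  } else {
    if (is.null(sigma) || !all(regs %in% names(sigma))) {
      .stopf("custom profile needs sigma named over registers -6..3")
    }
    sigma <- sigma[regs]
  }
  if (any(sigma < 0) || kinase_sigma < 0) .stopf("sigma must be >= 0")
  structure(list(sigma = sigma, kinase_sigma = kinase_sigma,
                 profile_label = profile_label),
            class = "fluctuation_spec")
}

.atom_sigmas <- function(model, spec) {
  s <- as_structure(model)
  pep_chain <- model$peptide$atoms$chain[1]
  pep_resnos <- unique(model$peptide$atoms$resno)
  sig <- rep(spec$kinase_sigma, nrow(s$atoms))
  in_pep <- s$atoms$chain == pep_chain & s$atoms$resno %in% pep_resnos &
    s$atoms$type == "ATOM"
  reg <- s$atoms$resno[in_pep] - model$site
  sig[in_pep] <- unname(spec$sigma[as.character(reg)])
  list(structure = s, sigma = sig)
}

#' Gaussian conformational ensemble around a model
#'
#' Each frame displaces every atom of the base structure by independent
#' isotropic Gaussian noise with the atom's per-coordinate sigma. With a
#' [fluctuation_spec()], peptide atoms take the sigma of their register
#' position and all other atoms the kinase sigma. The analytic expectations
#' `RMSF = sigma * sqrt(3)` and `B = 8 pi^2 sigma^2` make these ensembles
#' exact calibration targets for the fluctuation estimators.
#'
#' @param x A `complex_model` (with a `fluctuation_spec`) or `pdb_structure`
#'   (with scalar or per-atom numeric `sigma`).
#' @param sigma A `fluctuation_spec`, a scalar, or a per-atom numeric vector.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed; output is bit-reproducible given (x, sigma,
#'   seed).
#' @return A `pdb_ensemble`.
#' @export
gaussian_ensemble <- function(x, sigma, n_frames = 200L, seed = 1L) {
  if (n_frames < 2L) .stopf("n_frames must be >= 2")
  if (inherits(sigma, "fluctuation_spec")) {
    stopifnot(inherits(x, "complex_model"))
    as <- .atom_sigmas(x, sigma)
    s <- as$structure
    sig <- as$sigma
  } else {
    s <- if (inherits(x, "complex_model")) as_structure(x) else x
    stopifnot(inherits(s, "pdb_structure"))
    sig <- if (length(sigma) == 1L) rep(sigma, nrow(s$atoms)) else sigma
    stopifnot(length(sig) == nrow(s$atoms))
  }
  if (any(sig < 0)) .stopf("sigma must be >= 0")
  base <- as.vector(t(coords(s)))
  sd_vec <- rep(sig, each = 3L)
  set.seed(seed)
  noise <- matrix(stats::rnorm(n_frames * length(base)), nrow = n_frames)
  noise <- sweep(noise, 2L, sd_vec, "*")
  xyz <- sweep(noise, 2L, base, "+")
  new_ensemble(s$atoms, xyz,
               label = sprintf("%s | gaussian ensemble (seed %d)",
                               s$title, seed))
}

#' Two-conformer trajectory with known cluster labels
#'
#' Frames are drawn from two conformers (with mixture weights) plus small
#' Gaussian jitter; the true conformer label of every frame is returned so
#' clustering can be validated against ground truth.
#'
#' @param model_a,model_b Structures (or complex models) with one shared
#'   roster.
#' @param weights Length-2 mixture weights summing to 1.
#' @param n_frames Number of frames.
#' @param jitter Per-coordinate Gaussian jitter sigma (Angstrom), small
#'   against the conformer separation.
#' @param seed Integer seed.
#' @return List with `ensemble` (a `pdb_ensemble`) and `labels` (1/2 per
#'   frame).
#' @export
two_state_trajectory <- function(model_a, model_b, weights = c(0.5, 0.5),
                                 n_frames = 100L, jitter = 0.2, seed = 1L) {
  a <- if (inherits(model_a, "complex_model")) as_structure(model_a) else model_a
  b <- if (inherits(model_b, "complex_model")) as_structure(model_b) else model_b
  stopifnot(inherits(a, "pdb_structure"), inherits(b, "pdb_structure"))
  if (abs(sum(weights) - 1) > 1e-9 || length(weights) != 2L) {
    .stopf("weights must be two values summing to 1",
           class = "phosready_input_error")
  }
  if (nrow(a$atoms) != nrow(b$atoms)) .stopf("conformer rosters differ")
  set.seed(seed)
  labels <- sample(1:2, n_frames, replace = TRUE, prob = weights)
  base_a <- as.vector(t(coords(a)))
  base_b <- as.vector(t(coords(b)))
  noise <- matrix(stats::rnorm(n_frames * length(base_a), sd = jitter),
                  nrow = n_frames)
  xyz <- noise + rbind(base_a, base_b)[labels, , drop = FALSE]
  list(ensemble = new_ensemble(a$atoms, xyz,
                               label = sprintf("two-state (seed %d)", seed)),
       labels = labels)
}

.DEFAULT_CLASS_DISTANCE <- c(optimal = 3.5, weak = 3.65, impaired = 6.6,
                             non_site = 8.0)

.sanitize_label <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

#' Specification of a synthetic replica study
#'
#' Describes a full multi-system, multi-replica synthetic study emulating the
#' replica design of an MD campaign: every candidate is simulated in binary
#' and ternary mode with several independent replicas. Sites classified
#' `optimal` get the `optimal_like` fluctuation profile, all others
#' `weak_like`. Ternary systems carry prescribed catalytic distances; by
#' default these follow the site's rule-based class (optimal 3.5, weak 3.65,
#' impaired 6.6, non-site 8.0 Angstrom).
#'
#' @param candidates List of [extract_candidate_window()] results.
#' @param modes Character subset of `c("binary", "ternary")`.
#' @param replicas Replicas per system (>= 1).
#' @param frames Frames per replica.
#' @param seed Integer master seed; all generation derives from it.
#' @param distances Optional named numeric vector of catalytic distances by
#'   site.
#' @param efficiencies Optional named numeric vector of phosphorylation
#'   efficiencies (percent) by site, carried into the ground truth.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(candidates, modes = c("binary", "ternary"),
                                 replicas = 3L, frames = 200L, seed = 1L,
                                 distances = NULL, efficiencies = NULL) {
  stopifnot(length(candidates) >= 1L, replicas >= 1L, frames >= 2L)
  modes <- match.arg(modes, c("binary", "ternary"), several.ok = TRUE)
  structure(list(candidates = candidates, modes = modes,
                 replicas = as.integer(replicas), frames = as.integer(frames),
                 seed = as.integer(seed), distances = distances,
                 efficiencies = efficiencies),
            class = "synthetic_study_spec")
}

#' Generate a synthetic replica study on disk
#'
#' Writes, for every candidate-by-mode system, `replicas` multi-model PDB
#' ensembles plus the underlying model PDB, together with a
#' `ground_truth.yaml` manifest recording the generating parameters (sigma
#' profiles, prescribed distances, expected O-gamma B-factors and competence
#' classes, seeds and file names). Re-running with the same spec reproduces
#' the files bit for bit.
#'
#' @param spec A [synthetic_study_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the ground-truth manifest as a list.
#' @export
synthesize_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  systems <- list()
  for (cand in spec$candidates) {
    cls <- classify_akt_site(cand)
    prof_label <- if (cls$class == "optimal") "optimal_like" else "weak_like"
    fspec <- fluctuation_spec(prof_label)
    dist <- if (!is.null(spec$distances) &&
                as.character(cand$site) %in% names(spec$distances)) {
      unname(spec$distances[as.character(cand$site)])
    } else unname(.DEFAULT_CLASS_DISTANCE[cls$class])
    sigma0 <- unname(fspec$sigma[["0"]])
    expected_b <- 8 * pi^2 * sigma0^2
    for (mode in spec$modes) {
      label <- .sanitize_label(sprintf("%s_%s", cand$name, mode))
      model <- make_toy_complex(
        cand$sequence, catalytic_distance = dist, mode = mode,
        peptide_start_resno = cand$span[1],
        seed = spec$seed + cand$site,
        name = sprintf("%s (%s)", cand$name, mode))
      model_file <- file.path(dir, sprintf("model_%s.pdb", label))
      write_pdb(as_structure(model), model_file)
      files <- character(spec$replicas)
      for (r in seq_len(spec$replicas)) {
        seed_r <- spec$seed + cand$site * 1000L + r +
          if (mode == "ternary") 500L else 0L
        ens <- gaussian_ensemble(model, fspec, n_frames = spec$frames,
                                 seed = seed_r)
        files[r] <- file.path(dir, sprintf("%s_rep%d.pdb", label, r))
        write_pdb(ens, files[r])
      }
      systems[[label]] <- list(
        label = label, site = cand$site, mode = mode,
        sequence = cand$sequence, class = cls$class,
        profile = prof_label, sigma = as.list(fspec$sigma),
        kinase_sigma = fspec$kinase_sigma,
        catalytic_distance = if (mode == "ternary") dist else NA,
        expected_og_b = if (mode == "ternary") expected_b else NA,
        expected_competence = if (mode == "ternary") {
          unname(classify_competence(dist, expected_b))
        } else NA,
        efficiency = if (!is.null(spec$efficiencies) &&
                         as.character(cand$site) %in% names(spec$efficiencies)) {
          unname(spec$efficiencies[as.character(cand$site)])
        } else NA,
        replicas = spec$replicas, frames = spec$frames,
        model_file = basename(model_file), files = basename(files),
        extraction = list(kinase_chain = "A", peptide_chain = "B",
                          cofactor_name = if (mode == "ternary") "ATP" else NA,
                          metal_name = "MG")
      )
    }
  }
  manifest <- list(seed = spec$seed, n_systems = length(systems),
                   systems = systems)
  yaml::write_yaml(manifest, file.path(dir, "ground_truth.yaml"))
  invisible(manifest)
}
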