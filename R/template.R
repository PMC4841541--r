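# Partitioning a kinase/peptide/cofactor complex into labelled components.
#
# The reference layout mirrors the Akt2/GSK3-peptide template complex: the
# kinase domain and its C-terminal hydrophobic-motif tail on one chain, the
# bound 10-mer substrate peptide on another, the nucleotide cofactor
# (AMP-PNP, "ANP", or ATP) plus two divalent metals and their coordinated
# water oxygens as heteroatoms.

new_complex_model <- function(kinase, peptide, tail, cofactor, metals, waters,
                              mode, site = NA_integer_, label = "",
                              meta = list()) {
  mode <- match.arg(mode, c("binary", "ternary"))
  pep_res <- unique(peptide$atoms[, c("chain", "resno", "icode")])
  if (nrow(pep_res) != 10L) {
    .stopf("substrate peptide must have exactly 10 residues, found %d",
           nrow(pep_res), class = "phosready_extraction_error")
  }
  p0 <- peptide$atoms$resname[peptide$atoms$resno == pep_res$resno[7]][1]
  if (!(p0 %in% c("SER", "THR"))) {
    .stopf("peptide position 7 is %s, not Ser/Thr", p0,
           class = "phosready_extraction_error")
  }
  if (mode == "ternary") {
    if (nrow(cofactor$atoms) == 0L || !("PG" %in% cofactor$atoms$name)) {
      .stopf("ternary model requires a cofactor with a gamma-phosphorus (PG) atom",
             class = "phosready_extraction_error")
    }
    if (nrow(metals$atoms) != 2L) {
      .stopf("ternary model requires exactly 2 metal ions, found %d",
             nrow(metals$atoms), class = "phosready_extraction_error")
    }
  }
  structure(list(kinase = kinase, peptide = peptide, tail = tail,
                 cofactor = cofactor, metals = metals, waters = waters,
                 mode = mode, site = site, label = label, meta = meta),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf(
    "<complex_model> %s [%s]: kinase %d atoms, peptide %d, tail %d, cofactor %d, metals %d, waters %d\n",
    x$label, x$mode, nrow(x$kinase$atoms), nrow(x$peptide$atoms),
    nrow(x$tail$atoms), nrow(x$cofactor$atoms), nrow(x$metals$atoms),
    nrow(x$waters$atoms)))
  invisible(x)
}

.empty_slice <- function() {
  new_structure(data.frame(type = character(0), serial = integer(0),
                           name = character(0), alt = character(0),
                           resname = character(0), chain = character(0),
                           resno = integer(0), icode = character(0),
                           x = numeric(0), y = numeric(0), z = numeric(0),
                           occ = numeric(0), b = numeric(0),
                           element = character(0)))
}

.slice <- function(structure, idx) {
  atoms <- structure$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  new_structure(atoms, title = structure$title)
}

#' Partition a complex structure into kinase, peptide, cofactor and solvent
#'
#' Splits a single-structure complex into its named components. Waters are
#' retained only when their oxygen lies within `water_cutoff` of either metal
#' ion (the metal first-coordination-shell waters); the hydrophobic-motif
#' tail peptide is cut from the kinase chain by residue span.
#'
#' @param structure A `pdb_structure` holding the whole complex.
#' @param kinase_chain Chain identifier of the kinase domain.
#' @param peptide_chain Chain identifier of the bound 10-mer substrate peptide.
#' @param tail_span Inclusive residue-number range of the tail peptide on the
#'   kinase chain (`c(466, 479)` in the Akt2 template), or `NULL` for none.
#' @param cofactor_name Heteroatom residue name of the nucleotide (`"ANP"` or
#'   `"ATP"`); `NULL` extracts a binary (no-cofactor) model.
#' @param metal_name Residue name of the metal ions (`"MN"` or `"MG"`).
#' @param water_cutoff Metal-to-water-oxygen coordination cutoff in Angstrom.
#' @param site Author-numbered phosphosite carried as metadata.
#' @param label Free-text system label.
#' @return A `complex_model`.
#' @export
extract_template <- function(structure, kinase_chain = "A", peptide_chain = "B",
                             tail_span = c(466, 479), cofactor_name = "ANP",
                             metal_name = "MN", water_cutoff = 3.0,
                             site = NA_integer_, label = "") {
  stopifnot(inherits(structure, "pdb_structure"))
  atoms <- structure$atoms
  used <- rep(FALSE, nrow(atoms))

  take <- function(idx, component) {
    if (length(idx) == 0L) {
      .stopf("component not found in structure: %s", component,
             class = "phosready_extraction_error")
    }
    if (any(used[idx])) .stopf("internal error: overlapping component %s", component)
    used[idx] <<- TRUE
    .slice(structure, idx)
  }

  pep_idx <- which(atoms$type == "ATOM" & atoms$chain == peptide_chain)
  peptide <- take(pep_idx, sprintf("substrate peptide (chain %s)", peptide_chain))

  kin_all <- which(atoms$type == "ATOM" & atoms$chain == kinase_chain)
  if (!is.null(tail_span)) {
    tail_idx <- kin_all[atoms$resno[kin_all] >= tail_span[1] &
                          atoms$resno[kin_all] <= tail_span[2]]
    tail <- take(tail_idx, sprintf("tail peptide (%s %d-%d)", kinase_chain,
                                   tail_span[1], tail_span[2]))
    kin_idx <- setdiff(kin_all, tail_idx)
  } else {
    tail <- .empty_slice()
    kin_idx <- kin_all
  }
  kinase <- take(kin_idx, sprintf("kinase (chain %s)", kinase_chain))

  if (!is.null(cofactor_name)) {
    cof_idx <- which(atoms$type == "HETATM" & atoms$resname == cofactor_name)
    cofactor <- take(cof_idx, sprintf("cofactor %s", cofactor_name))
    met_idx <- which(atoms$type == "HETATM" & atoms$resname == metal_name)
    metals <- take(met_idx, sprintf("metal ions %s", metal_name))
    wat_idx <- which(atoms$type == "HETATM" & atoms$resname == "HOH" &
                       atoms$element == "O")
    if (length(wat_idx) > 0 && water_cutoff > 0) {
      d <- .cross_dist(as.matrix(atoms[wat_idx, c("x", "y", "z")]),
                       as.matrix(metals$atoms[, c("x", "y", "z")]))
      wat_idx <- wat_idx[apply(d, 1L, min) <= water_cutoff]
    } else {
      wat_idx <- integer(0)
    }
    waters <- if (length(wat_idx) > 0) {
      used[wat_idx] <- TRUE
      .slice(structure, wat_idx)
    } else .empty_slice()
    mode <- "ternary"
  } else {
    cofactor <- .empty_slice()
    metals <- .empty_slice()
    waters <- .empty_slice()
    mode <- "binary"
  }

  model <- new_complex_model(kinase, peptide, tail, cofactor, metals, waters,
                             mode = mode, site = site, label = label)
  model$meta$discarded_atoms <- sum(!used)
  model$meta$source_title <- structure$title
  model
}

#' Assemble a complex model back into one structure
#'
#' Concatenates the component slices (kinase, tail, peptide, cofactor, metals,
#' waters) and renumbers atom serials.
#'
#' @param model A `complex_model`.
#' @return A `pdb_structure`.
#' @export
as_structure <- function(model) {
  stopifnot(inherits(model, "complex_model"))
  parts <- list(model$kinase, model$tail, model$peptide, model$cofactor,
                model$metals, model$waters)
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new_structure(atoms, title = model$label)
}

#' Relabel an ANP/Mn template cofactor as ATP/Mg
#'
#' Models the ATP-bound ternary system from an AMP-PNP (ANP) template by
#' renaming records only: the cofactor residue becomes ATP, the bridging N3B
#' nitrogen becomes the O3B oxygen, and the two Mn ions become Mg. No
#' coordinate changes are made and the atom count is preserved.
#'
#' @param model A ternary `complex_model` carrying ANP and Mn.
#' @return The relabelled `complex_model`.
#' @export
relabel_cofactor <- function(model) {
  stopifnot(inherits(model, "complex_model"))
  if (model$mode != "ternary") .stopf("relabel_cofactor needs a ternary model")
  if (all(model$cofactor$atoms$resname == "ATP")) {
    warning("cofactor is already ATP; nothing to relabel")
    return(model)
  }
  cof <- model$cofactor$atoms
  cof$resname[cof$resname == "ANP"] <- "ATP"
  swap <- cof$name == "N3B"
  cof$name[swap] <- "O3B"
  cof$element[swap] <- "O"
  model$cofactor$atoms <- cof
  met <- model$metals$atoms
  is_mn <- met$resname == "MN"
  met$resname[is_mn] <- "MG"
  met$name[met$name == "MN"] <- "MG"
  met$element[met$element == "MN"] <- "MG"
  model$metals$atoms <- met
  model$meta$cofactor_relabelled <- TRUE
  model
}
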