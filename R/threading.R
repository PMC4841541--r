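# Template-based threading: a candidate 10-mer is built in the kinase active
# site by copying the bound template peptide's backbone coordinates verbatim
# and rebuilding side chains from ideal residue geometry.

.residue_template <- function(resname) {
  tpl <- .residue_templates[.residue_templates$resname == resname, , drop = FALSE]
  if (nrow(tpl) == 0L) .stopf("no ideal template for residue %s", resname)
  tpl
}

# Rigidly fit the ideal residue template onto anchor atoms (named coordinate
# rows shared between the ideal fragment and the target) and return the
# transformed ideal coordinates for all template atoms.
.fit_residue_template <- function(resname, anchors) {
  tpl <- .residue_template(resname)
  tc <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(tc) <- tpl$name
  shared <- intersect(rownames(anchors), tpl$name)
  if (length(shared) < 3L) .stopf("need >= 3 anchor atoms to fit %s", resname)
  fit <- kabsch_superpose(tc[shared, , drop = FALSE],
                          anchors[shared, , drop = FALSE])
  out <- apply_transform(tc, fit)
  rownames(out) <- tpl$name
  list(coords = out, names = tpl$name, elements = tpl$element)
}

# split a peptide slice into per-residue atom data frames, roster order
.residue_list <- function(peptide) {
  atoms <- peptide$atoms
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  split(atoms, factor(key, levels = unique(key)))
}

#' Check a candidate against the template substrate-peptide register
#'
#' Confirms the template peptide has 10 residues with its phosphoacceptor
#' (Ser/Thr) at position 7, so that the candidate's p0 maps onto it, and
#' reports the per-position residue pairing over the -6..+3 register.
#'
#' @param candidate A [extract_candidate_window()] result.
#' @param template_peptide A `pdb_structure` slice of the bound 10-mer.
#' @return A list with `ok = TRUE` and a `pairs` data frame
#'   (register, template residue, target residue).
#' @export
validate_register <- function(candidate, template_peptide) {
  stopifnot(inherits(candidate, "peptide_candidate"),
            inherits(template_peptide, "pdb_structure"))
  res <- .residue_list(template_peptide)
  if (length(res) != 10L) {
    .stopf("template peptide has %d residues, expected 10", length(res),
           class = "phosready_template_error")
  }
  tnames <- vapply(res, function(r) r$resname[1], character(1))
  if (!(tnames[7] %in% c("SER", "THR"))) {
    .stopf("template phosphoacceptor at position 7 is %s, not Ser/Thr",
           tnames[7], class = "phosready_template_error")
  }
  pairs <- data.frame(
    register = -6:3,
    template = unname(.AA1_FROM_3[tnames]),
    target = unname(candidate$register)
  )
  list(ok = TRUE, pairs = pairs)
}

#' Thread a candidate peptide onto the template backbone
#'
#' For each of the 10 positions the backbone atoms (N, CA, C, O) are copied
#' bit-exactly from the template peptide. When target and template residue
#' types are identical the whole residue is copied; otherwise CB is copied
#' when both residue types carry one, and all further side-chain atoms are
#' rebuilt from ideal residue geometry (standard bond lengths and angles in a
#' fixed canonical conformer) rigidly fitted onto the threaded backbone.
#' No clash relief is performed, and the kinase, tail, cofactor, metals and
#' waters are copied unchanged: downstream ensemble statistics, not a
#' minimised initial geometry, carry the analysis.
#'
#' @param template A `complex_model` (the extracted template complex).
#' @param candidate A [extract_candidate_window()] result.
#' @return An object of class `threading_result`: list with `model` (the new
#'   `complex_model`), `backbone_rmsd_to_template` (exactly 0 by construction)
#'   and `rebuilt` (register positions whose side chain was rebuilt).
#' @export
thread_peptide <- function(template, candidate) {
  stopifnot(inherits(template, "complex_model"))
  validate_register(candidate, template$peptide)
  res <- .residue_list(template$peptide)
  chain <- template$peptide$atoms$chain[1]
  target1 <- unname(candidate$register)
  rebuilt <- integer(0)

  rows <- vector("list", 10L)
  for (k in 1:10) {
    tres <- res[[k]]
    rownames(tres) <- tres$name
    tgt3 <- unname(.AA3[target1[k]])
    same <- identical(tres$resname[1], tgt3)
    miss_bb <- setdiff(.BACKBONE, tres$name)
    if (length(miss_bb) > 0) {
      .stopf("template residue %d lacks backbone atom(s): %s", k,
             paste(miss_bb, collapse = ", "),
             class = "phosready_template_error")
    }
    if (same) {
      new <- tres
    } else {
      rebuilt <- c(rebuilt, k - 7L)
      tpl <- .residue_template(tgt3)
      anchors <- as.matrix(tres[.BACKBONE, c("x", "y", "z")])
      copy_cb <- "CB" %in% tres$name && "CB" %in% tpl$name
      if (copy_cb) anchors <- rbind(anchors, CB = unlist(tres["CB", c("x", "y", "z")]))
      fit <- .fit_residue_template(tgt3, anchors)
      copied <- c(.BACKBONE, if (copy_cb) "CB")
      xyz <- fit$coords
      xyz[copied, ] <- anchors[copied, , drop = FALSE]
      b_fill <- tres["CA", "b"]
      new <- data.frame(
        type = "ATOM", serial = 0L, name = fit$names, alt = " ",
        resname = tgt3, chain = chain, resno = 0L, icode = " ",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        occ = 1, b = b_fill, element = fit$elements,
        stringsAsFactors = FALSE
      )
      rownames(new) <- new$name
      new[copied, "b"] <- tres[copied, "b"]
      new[copied, "occ"] <- tres[copied, "occ"]
    }
    new$resno <- candidate$span[1] + k - 1L
    rownames(new) <- NULL
    rows[[k]] <- new
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  peptide <- new_structure(atoms, title = candidate$name)

  model <- new_complex_model(template$kinase, peptide, template$tail,
                             template$cofactor, template$metals,
                             template$waters, mode = template$mode,
                             site = candidate$site, label = candidate$name,
                             meta = template$meta)
  bb_new <- atom_select(peptide, "backbone")
  bb_old <- atom_select(template$peptide, "backbone")
  rmsd0 <- sqrt(mean(rowSums((coords(peptide)[bb_new, , drop = FALSE] -
                                coords(template$peptide)[bb_old, , drop = FALSE])^2)))
  structure(list(model = model, backbone_rmsd_to_template = rmsd0,
                 rebuilt = rebuilt),
            class = "threading_result")
}

#' @export
print.threading_result <- function(x, ...) {
  cat(sprintf("<threading_result> %s: backbone RMSD to template %.3g A, rebuilt registers: %s\n",
              x$model$label, x$backbone_rmsd_to_template,
              if (length(x$rebuilt)) paste(x$rebuilt, collapse = ", ") else "none"))
  invisible(x)
}

#' Build the binary/ternary study manifest
#'
#' One system per candidate-by-mode combination, deterministically ordered by
#' site ascending with binary before ternary (the four candidate peptides in
#' two modes give the eight-system study design). Ternary entries model the
#' ATP/Mg cofactor via [relabel_cofactor()] of the ANP/Mn template; the
#' handling of the activation-loop phospho-threonine is recorded as metadata
#' only (the template kinase residues are taken as given).
#'
#' @param candidates List of [extract_candidate_window()] results.
#' @param modes Character subset of `c("binary", "ternary")`.
#' @param template_source Free-text provenance of the threading template.
#' @return A data frame of system specifications.
#' @export
build_manifest <- function(candidates, modes = c("binary", "ternary"),
                           template_source = "Akt2/GSK3-peptide template") {
  stopifnot(length(candidates) >= 1L)
  modes <- match.arg(modes, c("binary", "ternary"), several.ok = TRUE)
  df <- expand.grid(
    site = vapply(candidates, `[[`, integer(1), "site"),
    mode = factor(modes, levels = c("binary", "ternary")),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  seqs <- stats::setNames(vapply(candidates, `[[`, character(1), "sequence"),
                          vapply(candidates, `[[`, integer(1), "site"))
  names_by_site <- stats::setNames(vapply(candidates, `[[`, character(1), "name"),
                                   names(seqs))
  df$sequence <- unname(seqs[as.character(df$site)])
  df$label <- sprintf("%s%s", names_by_site[as.character(df$site)],
                      ifelse(df$mode == "ternary", ".ATP/MG", ""))
  df$cofactor <- ifelse(df$mode == "ternary", "ATP+2MG (relabelled from ANP/MN)", "none")
  df$activation_loop <- ifelse(df$mode == "ternary",
                               "pThr309 modelled as Glu (metadata only)",
                               "pThr309 modelled as Thr (metadata only)")
  df$template <- template_source
  df <- df[order(df$site, df$mode), , drop = FALSE]
  df$mode <- as.character(df$mode)
  rownames(df) <- NULL
  df
}
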