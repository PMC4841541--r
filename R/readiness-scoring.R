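# Catalytic-geometry and interaction analysis: is each candidate phosphosite
# positioned and stable enough for phosphoryl transfer?

#' Catalytic Ser-O-gamma to ATP P-gamma distance
#'
#' Euclidean distance between the hydroxyl oxygen (OG/OG1) of the p0 residue
#' of the bound peptide and the gamma-phosphorus of the nucleotide cofactor.
#' Distances below about 4 Angstrom indicate a positioning adequate for
#' phosphoryl transfer.
#'
#' @param model A ternary `complex_model` (or the crystal-like template with
#'   ANP bound).
#' @return Distance in Angstrom.
#' @export
catalytic_distance <- function(model) {
  stopifnot(inherits(model, "complex_model"))
  if (model$mode != "ternary") {
    .stopf("catalytic distance needs a ternary (cofactor-bound) model",
           class = "phosready_geometry_error")
  }
  pep <- model$peptide$atoms
  resnos <- unique(pep$resno)
  p0 <- resnos[7]
  og <- pep[pep$resno == p0 & pep$name %in% c("OG", "OG1"), , drop = FALSE]
  if (nrow(og) == 0L) {
    .stopf("p0 residue %d has no hydroxyl oxygen (OG/OG1)", p0,
           class = "phosready_geometry_error")
  }
  pg <- model$cofactor$atoms[model$cofactor$atoms$name == "PG", , drop = FALSE]
  if (nrow(pg) == 0L) {
    .stopf("cofactor has no gamma-phosphorus (PG) atom",
           class = "phosready_geometry_error")
  }
  .dist3(unlist(og[1, c("x", "y", "z")]), unlist(pg[1, c("x", "y", "z")]))
}

#' Classify phospho-readiness from distance and mobility
#'
#' A site is `competent` when the catalytic distance is below the distance
#' cutoff and the hydroxyl-oxygen B-factor is low; `transient` when the
#' distance is adequate but the oxygen is highly mobile (the near-attack
#' geometry is only transiently visited); `displaced` when the distance
#' exceeds the cutoff. The published mobility values split cleanly: efficient
#' sites carry O-gamma B-factors of roughly 14-45 Angstrom^2 and poor sites
#' above 65, so the default `b_high` of 60 separates the two groups; both
#' thresholds are configurable. The reported distance boundary is a single
#' cutoff at 4 Angstrom (adequate below 4, clearly displaced above 6; the
#' 4-6 gap is unobserved and is folded into the displaced class).
#'
#' @param distance Catalytic distance in Angstrom.
#' @param og_bfactor B-factor of the p0 hydroxyl oxygen in Angstrom^2.
#' @param distance_cutoff Competence distance boundary (Angstrom).
#' @param b_high Mobility boundary (Angstrom^2).
#' @return One of `"competent"`, `"transient"`, `"displaced"` (vectorised).
#' @examples
#' classify_competence(3.44, 36.5)  # competent
#' classify_competence(3.65, 65.8)  # transient
#' classify_competence(6.63, 67.9)  # displaced
#' @export
classify_competence <- function(distance, og_bfactor, distance_cutoff = 4.0,
                                b_high = 60) {
  if (any(!is.finite(distance)) || any(!is.finite(og_bfactor)) ||
      any(distance < 0) || any(og_bfactor < 0)) {
    .stopf("distance and og_bfactor must be finite and non-negative",
           class = "phosready_input_error")
  }
  ifelse(distance >= distance_cutoff, "displaced",
         ifelse(og_bfactor >= b_high, "transient", "competent"))
}

#' Default kinase-substrate contact checklist
#'
#' The interaction inventory of the Akt2 substrate groove: the compulsory -3
#' arginine salt bridge to Glu236; the -5 arginine salt bridge to Glu279; the
#' -4 position hydrogen bond to Glu315 (the route by which a site lacking the
#' -5 arginine can still be held); the -6/-7 arginine reinforcement by
#' Asp440; and the +1 residue packing against the hydrophobic +1 pocket
#' (Phe310, Phe359, Leu317, Pro314).
#'
#' @return Data frame with columns `kinase_resno`, `kinase_resname`,
#'   `register`, `kind`.
#' @export
default_contact_checklist <- function() {
  data.frame(
    kinase_resno = c(236L, 279L, 315L, 440L, 310L, 359L, 317L, 314L),
    kinase_resname = c("GLU", "GLU", "GLU", "ASP", "PHE", "PHE", "LEU", "PRO"),
    register = c(-3L, -5L, -4L, -6L, 1L, 1L, 1L, 1L),
    kind = c("salt_bridge", "salt_bridge", "h_bond", "h_bond",
             "hydrophobic_contact", "hydrophobic_contact",
             "hydrophobic_contact", "hydrophobic_contact"),
    stringsAsFactors = FALSE
  )
}

.CONTACT_CUTOFFS <- c(salt_bridge = 4.0, h_bond = 3.5,
                      hydrophobic_contact = 4.5, stacking_proxy = 4.5)

# side-chain heavy atoms of one residue (CB onwards; CA for Gly)
.sidechain_xyz <- function(atoms, resno, polar_only = FALSE) {
  r <- atoms[atoms$resno == resno & atoms$element != "H" &
               !(atoms$name %in% .BACKBONE), , drop = FALSE]
  if (nrow(r) == 0L) r <- atoms[atoms$resno == resno & atoms$name == "CA", ,
                                drop = FALSE]
  if (polar_only) {
    p <- r[r$element %in% c("N", "O"), , drop = FALSE]
    if (nrow(p) > 0L) r <- p
  }
  as.matrix(r[, c("x", "y", "z")])
}

#' Kinase-peptide contact report
#'
#' For every checklist entry, the minimal heavy-atom side-chain distance
#' between the named kinase residue and the peptide residue at the given
#' consensus register is measured and compared against a kind-specific
#' cutoff: salt bridges between charged-group N/O atoms at 4.0 Angstrom,
#' hydrogen bonds between N/O heavy atoms at 3.5, and hydrophobic packing or
#' stacking proxies between any side-chain heavy atoms at 4.5. Checklist
#' residues absent from the kinase are reported as not evaluable rather than
#' silently dropped. Ring-geometry criteria for stacking and cation-pi
#' contacts are deliberately not applied; proximity is the only proxy.
#'
#' @param model A `complex_model`.
#' @param checklist A data frame like [default_contact_checklist()].
#' @return Data frame of class `contact_table`: one row per checklist entry
#'   with the peptide pairing, minimal distance and presence call.
#' @export
contact_report <- function(model, checklist = default_contact_checklist()) {
  stopifnot(inherits(model, "complex_model"))
  kin <- rbind(model$kinase$atoms, model$tail$atoms)
  pep <- model$peptide$atoms
  resnos <- unique(pep$resno)
  rows <- lapply(seq_len(nrow(checklist)), function(i) {
    ck <- checklist[i, ]
    pep_resno <- resnos[7L + ck$register]
    pep_res <- pep$resname[pep$resno == pep_resno][1]
    krows <- kin[kin$resno == ck$kinase_resno &
                   kin$resname == ck$kinase_resname, , drop = FALSE]
    polar <- ck$kind %in% c("salt_bridge", "h_bond")
    if (nrow(krows) == 0L) {
      return(data.frame(peptide_position = ck$register,
                        peptide_residue = pep_res,
                        kinase_residue = sprintf("%s%d", ck$kinase_resname,
                                                 ck$kinase_resno),
                        kind = ck$kind, min_distance = NA_real_,
                        present = NA, evaluable = FALSE))
    }
    kxyz <- .sidechain_xyz(krows, ck$kinase_resno, polar_only = polar)
    pxyz <- .sidechain_xyz(pep, pep_resno, polar_only = polar)
    dmin <- min(.cross_dist(kxyz, pxyz))
    data.frame(peptide_position = ck$register, peptide_residue = pep_res,
               kinase_residue = sprintf("%s%d", ck$kinase_resname,
                                        ck$kinase_resno),
               kind = ck$kind, min_distance = dmin,
               present = dmin <= .CONTACT_CUTOFFS[[ck$kind]],
               evaluable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_table", class(out))
  out
}

#' Pearson correlation between phosphorylation efficiency and mobility
#'
#' The product-moment correlation between measured phosphorylation
#' efficiencies (percent, user-supplied, e.g. from densitometry of mutant
#' phosphorylation assays) and the B-factors of the corresponding p0 hydroxyl
#' oxygens. A strong negative value indicates that mobile hydroxyl oxygens
#' are phosphorylated poorly.
#'
#' @param efficiency Numeric vector of efficiencies (percent).
#' @param og_bfactor Numeric vector of matching O-gamma B-factors
#'   (Angstrom^2).
#' @return Pearson r in `[-1, 1]`.
#' @export
efficiency_mobility_correlation <- function(efficiency, og_bfactor) {
  if (length(efficiency) != length(og_bfactor) || length(efficiency) < 3L) {
    .stopf("need >= 3 matched (efficiency, B-factor) pairs",
           class = "phosready_input_error")
  }
  if (stats::sd(efficiency) == 0 || stats::sd(og_bfactor) == 0) {
    .stopf("correlation undefined: zero variance in one variable",
           class = "phosready_input_error")
  }
  stats::cor(efficiency, og_bfactor, method = "pearson")
}

# O-gamma B-factor of the model's p0 residue, looked up in a profile whose
# roster covers the assembled complex
.og_bfactor <- function(model, profile) {
  pep_chain <- model$peptide$atoms$chain[1]
  p0 <- unique(model$peptide$atoms$resno)[7]
  idx <- which(profile$atoms$chain == pep_chain & profile$atoms$resno == p0 &
                 profile$atoms$name %in% c("OG", "OG1"))
  if (length(idx) == 0L) {
    .stopf("profile has no O-gamma entry for peptide residue %d", p0,
           class = "phosready_geometry_error")
  }
  profile$b[idx[1]]
}

#' Assemble the per-site readiness report
#'
#' One row per candidate site combining the catalytic distance (ternary
#' models), the p0 hydroxyl-oxygen B-factor from the fluctuation profile, the
#' competence class and a contact summary, ordered by site. When efficiencies
#' are supplied, the efficiency-mobility Pearson correlation is attached as
#' the `"correlation"` attribute.
#'
#' @param models List of `complex_model` objects (one per site).
#' @param fluctuations List of matching `fluctuation_profile` objects whose
#'   rosters cover the assembled complexes.
#' @param efficiencies Optional data frame with columns `site` and
#'   `efficiency` (percent). Efficiencies are always user-supplied input;
#'   the pipeline never fabricates them.
#' @param distance_cutoff,b_high Passed to [classify_competence()].
#' @return Data frame of class `readiness_report`.
#' @export
build_report <- function(models, fluctuations, efficiencies = NULL,
                         distance_cutoff = 4.0, b_high = 60) {
  if (length(models) == 0L) {
    out <- data.frame(site = integer(0), label = character(0),
                      mode = character(0), distance_A = numeric(0),
                      og_b_A2 = numeric(0), competence = character(0),
                      contacts = character(0))
    class(out) <- c("readiness_report", class(out))
    return(out)
  }
  if (length(models) != length(fluctuations)) {
    .stopf("models and fluctuations differ in length",
           class = "phosready_input_error")
  }
  rows <- lapply(seq_along(models), function(i) {
    m <- models[[i]]
    d <- if (m$mode == "ternary") catalytic_distance(m) else NA_real_
    b <- .og_bfactor(m, fluctuations[[i]])
    cont <- contact_report(m)
    data.frame(site = m$site, label = m$label, mode = m$mode,
               distance_A = d, og_b_A2 = b,
               competence = if (is.na(d)) NA_character_ else
                 classify_competence(d, b, distance_cutoff, b_high),
               contacts = sprintf("%d/%d",
                                  sum(cont$present, na.rm = TRUE),
                                  sum(cont$evaluable)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$mode), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(efficiencies)) {
    stopifnot(all(c("site", "efficiency") %in% names(efficiencies)))
    merged <- merge(out[!is.na(out$og_b_A2) & out$mode == "ternary",
                        c("site", "og_b_A2")],
                    efficiencies, by = "site")
    out$efficiency <- efficiencies$efficiency[match(out$site, efficiencies$site)]
    if (nrow(merged) >= 3L) {
      attr(out, "correlation") <-
        efficiency_mobility_correlation(merged$efficiency, merged$og_b_A2)
    }
  }
  class(out) <- c("readiness_report", class(out))
  out
}

#' @export
print.readiness_report <- function(x, ...) {
  cat("Phospho-readiness report\n")
  cat(sprintf("%-28s %10s %12s %-10s %s\n", "system", "dist (A)", "OG B (A2)",
              "class", "contacts"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-28s %10s %12s %-10s %s\n", x$label[i],
                ifelse(is.na(x$distance_A[i]), "-",
                       sprintf("%.2f", x$distance_A[i])),
                sprintf("%.1f", x$og_b_A2[i]),
                ifelse(is.na(x$competence[i]), "-", x$competence[i]),
                x$contacts[i]))
  }
  r <- attr(x, "correlation")
  if (!is.null(r)) cat(sprintf("efficiency-mobility Pearson r = %.2f\n", r))
  invisible(x)
}

#' Write a readiness report as TSV
#' @param report A [build_report()] result.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
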