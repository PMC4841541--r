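# Consensus-site scanning and rule-based classification of phosphosites.
#
# Two kinase specificities are covered:
#  * Akt (PKB): minimal consensus R(-5)-x-R(-3)-x-x-[S/T](0), usually followed
#    by a large hydrophobic residue at +1;
#  * SRPK-type: serines inside Arg-Ser or Ser-Arg dipeptides.

#' Scan a region for minimal Akt consensus sites
#'
#' Reports every Ser/Thr whose positions -3 and -5 are both arginine
#' (the minimal Akt consensus R-X-R-X-X-S/T). Sites whose -5 position falls
#' before the start of the region are not reported, because the determinant
#' cannot be verified.
#'
#' @param region An [rs_region()].
#' @return Integer vector of author-numbered site positions, ascending.
#' @examples
#' scan_akt_sites(rs_region("PSRRSRSRSRSRSPGR", start = 72))  # 80 82 84
#' @export
scan_akt_sites <- function(region) {
  stopifnot(inherits(region, "rs_region"))
  aa <- .check_residue_letters(region$residues, "region")
  n <- length(aa)
  if (n == 0L) return(integer(0))
  idx <- which(aa %in% c("S", "T"))
  idx <- idx[idx >= 6L]                       # -5 must exist inside the region
  hit <- idx[aa[idx - 3L] == "R" & aa[idx - 5L] == "R"]
  sort(hit + region$start - 1L)
}

#' Scan a region for SRPK-type RS/SR sites
#'
#' Reports every serine immediately preceded or followed by an arginine
#' (Arg-Ser or Ser-Arg dipeptide), the strict SRPK1 specificity.
#'
#' @param region An [rs_region()].
#' @return Integer vector of author-numbered site positions, ascending.
#' @examples
#' scan_srpk_sites(rs_region("RSRSRSRSRS", start = 75))  # 76 78 80 82 84
#' @export
scan_srpk_sites <- function(region) {
  stopifnot(inherits(region, "rs_region"))
  aa <- .check_residue_letters(region$residues, "region")
  n <- length(aa)
  if (n == 0L) return(integer(0))
  idx <- which(aa == "S")
  prev_r <- idx > 1L & aa[pmax(idx - 1L, 1L)] == "R"
  next_r <- idx < n & aa[pmin(idx + 1L, n)] == "R"
  sort(idx[prev_r | next_r] + region$start - 1L)
}

#' Extract the 10-mer candidate window around a phosphosite
#'
#' Candidate substrate peptides are 10 residues long with the phosphoacceptor
#' at the 7th position, i.e. spanning consensus register positions -6 to +3
#' (the register used for kinase-bound substrate peptides, where the
#' phosphoacceptor is position 0).
#'
#' @param region An [rs_region()].
#' @param site Author-numbered Ser/Thr position.
#' @return An object of class `peptide_candidate` with elements `sequence`
#'   (10-mer), `site`, `span` (inclusive author-numbered first/last residue),
#'   `register` (named residue vector for positions -6..+3) and `upstream`
#'   (residue at site-7 when the region provides it, else `NA`; used only for
#'   the optional -7 arginine reinforcement flag).
#' @examples
#' lbr <- rs_region("PSRRSRSRSRSRSPGR", start = 72)
#' extract_candidate_window(lbr, 80)  # RRSRSRSRSR, span 74-83
#' @export
extract_candidate_window <- function(region, site) {
  stopifnot(inherits(region, "rs_region"))
  if (!.is_count(site)) .stopf("site must be a single integer")
  site <- as.integer(site)
  last <- region$start + nchar(region$residues) - 1L
  if (site - 6L < region$start || site + 3L > last) {
    .stopf("window %d-%d exceeds region bounds %d-%d", site - 6L, site + 3L,
           region$start, last, class = "phosready_bounds_error")
  }
  p0 <- .region_residue(region, site)
  if (!(p0 %in% c("S", "T"))) {
    .stopf("residue at site %d is %s, not Ser/Thr", site, p0,
           class = "phosready_input_error")
  }
  i <- site - region$start + 1L
  seq10 <- substring(region$residues, i - 6L, i + 3L)
  reg <- strsplit(seq10, "")[[1]]
  names(reg) <- as.character(-6:3)
  structure(list(sequence = seq10,
                 site = as.integer(site),
                 span = c(site - 6L, site + 3L),
                 register = reg,
                 upstream = .region_residue(region, site - 7L),
                 name = sprintf("%s-S%d", region$name, site)),
            class = "peptide_candidate")
}

#' @export
print.peptide_candidate <- function(x, ...) {
  cat(sprintf("<peptide_candidate> %s: %s (span %d-%d, p0 = %s%d)\n",
              x$name, x$sequence, x$span[1], x$span[2],
              x$register[["0"]], x$site))
  invisible(x)
}

#' Enumerate candidate substrate peptides of a region
#'
#' A position qualifies as a candidate when it is Ser/Thr, carries the
#' mandatory -3 arginine, and its full -6..+3 window lies inside the region.
#' The -5 arginine is deliberately *not* required here: sites lacking it are
#' retained so they can later be classified as weak rather than dropped.
#'
#' @param region An [rs_region()].
#' @return List of [extract_candidate_window()] results, sites ascending.
#' @examples
#' length(enumerate_candidates(rs_region("PSRRSRSRSRSRSPGR", 72)))  # 4
#' @export
enumerate_candidates <- function(region) {
  stopifnot(inherits(region, "rs_region"))
  aa <- .check_residue_letters(region$residues, "region")
  n <- length(aa)
  if (n < 10L) return(list())
  idx <- which(aa %in% c("S", "T"))
  idx <- idx[idx >= 7L & idx + 3L <= n]        # full -6..+3 window
  idx <- idx[aa[idx - 3L] == "R"]              # mandatory -3 Arg
  lapply(idx + region$start - 1L, function(s) extract_candidate_window(region, s))
}

#' Rule-based Akt classification of a candidate peptide
#'
#' Classification hierarchy (first matching rule wins):
#' \describe{
#'   \item{non_site}{no arginine at -3 (the compulsory Akt determinant);}
#'   \item{impaired}{proline at +1, which blocks phosphorylation by Akt;}
#'   \item{weak}{no arginine at -5 (recognition survives, weakened);}
#'   \item{optimal}{full consensus.}
#' }
#' Determinant flags additionally record -6/-7 arginine reinforcement and
#' whether the +1 residue is compatible with the hydrophobic +1 pocket
#' (large hydrophobics F, L, I, M, V, W, Y, plus Arg, whose guanidinium group
#' can be accommodated through cation-pi packing against the pocket
#' aromatics).
#'
#' @param candidate A [extract_candidate_window()] result.
#' @return An object of class `site_classification` with elements `site`,
#'   `kinase` (`"akt"`), `class` and `flags`.
#' @export
classify_akt_site <- function(candidate) {
  stopifnot(inherits(candidate, "peptide_candidate"))
  reg <- candidate$register
  pocket_ok <- reg[["1"]] %in% c("F", "L", "I", "M", "V", "W", "Y", "R")
  flags <- c(
    if (reg[["-3"]] == "R") "minus3_arg",
    if (reg[["-5"]] == "R") "minus5_arg",
    if (reg[["-6"]] == "R") "minus6_arg",
    if (!is.na(candidate$upstream) && candidate$upstream == "R") "minus7_arg",
    if (reg[["1"]] == "P") "plus1_proline" else if (pocket_ok) "plus1_pocket_compatible"
  )
  klass <- if (reg[["-3"]] != "R") "non_site"
  else if (reg[["1"]] == "P") "impaired"
  else if (reg[["-5"]] != "R") "weak"
  else "optimal"
  structure(list(site = candidate$site, kinase = "akt",
                 class = klass, flags = flags %||% character(0)),
            class = "site_classification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf("<site_classification> site %d [%s]: %s (%s)\n",
              x$site, x$kinase, x$class, paste(x$flags, collapse = ", ")))
  invisible(x)
}

#' Tabulate and export site classifications
#'
#' @param region An [rs_region()].
#' @param path Optional path; when given the table is written as TSV with
#'   columns `site`, `kinase`, `class`, `flags`.
#' @return A data frame with one row per scanned site: all SRPK sites and all
#'   Akt candidate sites with their rule-based classes.
#' @export
site_report <- function(region, path = NULL) {
  srpk <- scan_srpk_sites(region)
  cands <- enumerate_candidates(region)
  akt <- lapply(cands, classify_akt_site)
  df <- rbind(
    if (length(srpk)) data.frame(site = srpk, kinase = "srpk", class = "site",
                                 flags = "rs_dipeptide"),
    if (length(akt)) data.frame(
      site = vapply(akt, `[[`, integer(1), "site"),
      kinase = "akt",
      class = vapply(akt, `[[`, character(1), "class"),
      flags = vapply(akt, function(a) paste(a$flags, collapse = ","), character(1))
    )
  )
  if (is.null(df)) {
    df <- data.frame(site = integer(0), kinase = character(0),
                     class = character(0), flags = character(0))
  }
  df <- df[order(df$kinase, df$site), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
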