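# Conformational-ensemble analytics: optimal superposition, convergence
# assessment, RMSD-cutoff neighbour clustering, structure averaging and
# fluctuation (RMSF / Debye-Waller B-factor) estimation.
#
# All selections weigh atoms equally (no mass weighting).

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares fit of `mobile` onto `reference` via the closed-form SVD
#' solution, constrained to a proper rotation (det = +1).
#'
#' @param mobile,reference Coordinate matrices (n atoms by 3), equal sizes,
#'   n >= 3 and non-collinear.
#' @return A list with `rotation` (3x3, row-vector convention), `translation`
#'   (length 3) and `rmsd` (post-fit, Angstrom). The fitted coordinates are
#'   `mobile %*% rotation + translation` (see [apply_transform()]).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    .stopf("mobile and reference must be equal-sized n-by-3 matrices",
           class = "phosready_superposition_error")
  }
  n <- nrow(mobile)
  if (n < 3L) .stopf("superposition needs >= 3 atoms",
                     class = "phosready_superposition_error")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  mc <- sweep(mobile, 2L, cm)
  rc <- sweep(reference, 2L, cr)
  if (svd(rc)$d[2] < 1e-8 || svd(mc)$d[2] < 1e-8) {
    .stopf("degenerate (collinear) coordinates; superposition is ill-defined",
           class = "phosready_superposition_error")
  }
  a <- crossprod(mc, rc)                  # 3x3 covariance
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- mc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - rc)^2)))
  list(rotation = rot, translation = cr - as.vector(cm %*% rot), rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param xyz Coordinate matrix (n by 3).
#' @param fit A [kabsch_superpose()] result.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2L, fit$translation, "+")
}

# frame i of an ensemble as an n x 3 matrix
.frame_xyz <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE)
}

.rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# fit every frame onto ref_xyz using the atoms in fit_idx; returns a list of
# n x 3 matrices
.fit_frames <- function(ensemble, ref_xyz, fit_idx) {
  lapply(seq_len(nrow(ensemble$xyz)), function(i) {
    fr <- .frame_xyz(ensemble, i)
    fit <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                            ref_xyz[fit_idx, , drop = FALSE])
    apply_transform(fr, fit)
  })
}

.resolve_selection <- function(ensemble, selection) {
  if (is.null(selection)) selection <- atom_select(ensemble$atoms, "all")
  if (is.character(selection) && length(selection) == 1L) {
    selection <- atom_select(ensemble$atoms, selection)
  }
  selection <- as.integer(selection)
  if (length(selection) == 0L) .stopf("empty atom selection",
                                      class = "phosready_selection_error")
  selection
}

#' Per-frame RMSD series over an ensemble
#'
#' Each frame is optimally superposed onto the reference on the selection and
#' the post-fit RMSD over that selection is reported, the standard monitor of
#' simulation convergence.
#'
#' @param ensemble A `pdb_ensemble`.
#' @param reference `"initial"` (frame 1), `"average"` (iterative mean
#'   structure), a frame index, or an n-by-3 coordinate matrix.
#' @param selection Atom indices or an [atom_select()] keyword
#'   (default `"backbone"`).
#' @return An object of class `rmsd_series`: list with `values` (Angstrom per
#'   frame), `reference` and `selection`.
#' @export
rmsd_series <- function(ensemble, reference = "initial",
                        selection = "backbone") {
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  sel <- .resolve_selection(ensemble, selection)
  ref_label <- "custom"
  if (is.character(reference) && length(reference) == 1L) {
    ref_label <- reference
    ref_xyz <- switch(reference,
      initial = .frame_xyz(ensemble, 1L),
      average = coords(average_structure(ensemble, fit_selection = sel)),
      .stopf("unknown reference '%s'", reference))
  } else if (is.numeric(reference) && length(reference) == 1L) {
    ref_label <- sprintf("frame %d", reference)
    ref_xyz <- .frame_xyz(ensemble, as.integer(reference))
  } else {
    ref_xyz <- as.matrix(reference)
  }
  vals <- vapply(seq_len(nrow(ensemble$xyz)), function(i) {
    fr <- .frame_xyz(ensemble, i)
    kabsch_superpose(fr[sel, , drop = FALSE],
                     ref_xyz[sel, , drop = FALSE])$rmsd
  }, numeric(1))
  structure(list(values = vals, reference = ref_label, selection = sel),
            class = "rmsd_series")
}

#' Assess equilibration of an RMSD series
#'
#' A trajectory is taken as converged when every RMSD value in the trailing
#' analysis window stays at or below the threshold. The defaults mirror the
#' usual protocol of requiring backbone RMSD <= 2 Angstrom over the final
#' fifth of the run (the last 10 ns of a 50 ns trajectory), which is then the
#' window used for all downstream ensemble statistics.
#'
#' @param series An [rmsd_series()] result (>= 10 frames).
#' @param threshold RMSD threshold in Angstrom.
#' @param window_fraction Trailing fraction of frames forming the window.
#' @return List with `converged` (logical) and `window` (first/last frame
#'   index of the analysis window).
#' @export
assess_convergence <- function(series, threshold = 2.0, window_fraction = 0.2) {
  stopifnot(inherits(series, "rmsd_series"))
  n <- length(series$values)
  if (n < 10L) .stopf("need >= 10 frames to assess convergence")
  w <- as.integer(ceiling(window_fraction * n))
  if (w < 1L) .stopf("empty analysis window", class = "phosready_window_error")
  from <- n - w + 1L
  list(converged = all(series$values[from:n] <= threshold),
       window = c(from, n))
}

#' RMSD-cutoff neighbour clustering of an ensemble
#'
#' Iterative neighbour-count clustering: all pairwise post-superposition RMSD
#' values on the selection are computed; the frame with the most neighbours
#' within the cutoff founds a cluster together with its neighbours; the
#' cluster is removed and the procedure repeats. Ties in neighbour count are
#' broken towards the lowest frame index, which makes the result
#' deterministic. For each cluster both the *center* (the founding frame with
#' maximal neighbour count) and the *representative* (the member with the
#' smallest average RMSD to its co-members) are recorded.
#'
#' @param ensemble A `pdb_ensemble`.
#' @param cutoff Neighbour RMSD cutoff in Angstrom (default 1.0).
#' @param selection Atom indices or keyword (default `"backbone"`).
#' @return An object of class `cluster_result`: `cutoff`, `clusters` (list of
#'   lists with `members`, `center`, `representative`), and `assignment`
#'   (cluster id per frame).
#' @export
cluster_gromos <- function(ensemble, cutoff = 1.0, selection = "backbone") {
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  sel <- .resolve_selection(ensemble, selection)
  n <- nrow(ensemble$xyz)
  sel_xyz <- lapply(seq_len(n), function(i) .frame_xyz(ensemble, i)[sel, , drop = FALSE])
  dm <- matrix(0, n, n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        dm[i, j] <- dm[j, i] <- kabsch_superpose(sel_xyz[[j]], sel_xyz[[i]])$rmsd
      }
    }
  }
  remaining <- seq_len(n)
  assignment <- integer(n)
  clusters <- list()
  cid <- 0L
  while (length(remaining) > 0L) {
    cid <- cid + 1L
    nb_counts <- vapply(remaining, function(i) {
      sum(dm[i, remaining] <= cutoff) - 1L
    }, integer(1))
    center <- remaining[which.max(nb_counts)]   # which.max takes lowest index on ties
    members <- remaining[dm[center, remaining] <= cutoff]
    avg <- vapply(members, function(i) {
      if (length(members) == 1L) 0 else mean(dm[i, setdiff(members, i)])
    }, numeric(1))
    representative <- members[which.min(avg)]
    assignment[members] <- cid
    clusters[[cid]] <- list(members = members, center = center,
                            representative = representative)
    remaining <- setdiff(remaining, members)
  }
  structure(list(cutoff = cutoff, clusters = clusters,
                 assignment = assignment),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("<cluster_result> cutoff %.2f A: %d cluster(s), sizes %s\n",
              x$cutoff, length(sizes), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Average structure of an ensemble
#'
#' Every frame is superposed onto the first (on `fit_selection`) and the
#' arithmetic per-atom mean of the fitted coordinates is returned. No
#' geometry regularisation is applied, so averages of very mobile regions can
#' be unphysical; they serve as superposition references, not as models.
#'
#' @param ensemble A `pdb_ensemble` (or list of `pdb_structure` frames).
#' @param fit_selection Atom indices or keyword used for the fit.
#' @return A `pdb_structure` with the mean coordinates.
#' @export
average_structure <- function(ensemble, fit_selection = NULL) {
  if (is.list(ensemble) && !inherits(ensemble, "pdb_ensemble")) {
    ensemble <- ensemble_from_frames(ensemble)
  }
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  sel <- .resolve_selection(ensemble, fit_selection)
  ref <- .frame_xyz(ensemble, 1L)
  fitted <- .fit_frames(ensemble, ref, sel)
  avg <- Reduce(`+`, fitted) / length(fitted)
  out <- ens_frame(ensemble, 1L)
  coords(out) <- avg
  out$title <- sprintf("average of %d frames", length(fitted))
  out
}

#' RMSF and B-factor profile of an ensemble window
#'
#' Frames in the analysis window are superposed onto their own average
#' structure, computed iteratively (superpose onto the running average,
#' re-average; `passes` rounds). The per-atom root-mean-square fluctuation is
#' \deqn{RMSF_i = \sqrt{\langle |r_i - \bar r_i|^2 \rangle}}{RMSF_i = sqrt(<|r_i - mean_i|^2>)}
#' and the Debye-Waller temperature factor follows as
#' \eqn{B_i = (8\pi^2/3)\, RMSF_i^2}.
#'
#' @param ensemble A `pdb_ensemble`.
#' @param window Frame range `c(from, to)` (default: all frames), normally
#'   the converged window from [assess_convergence()].
#' @param fit_selection Atoms used for the superposition fit (default: all
#'   atoms; commonly the kinase backbone so that peptide fluctuation is
#'   measured in the kinase frame).
#' @param passes Average/re-superpose iterations (2 is ample at these
#'   amplitudes).
#' @return An object of class `fluctuation_profile`: `atoms` (roster),
#'   `rmsf` (Angstrom), `b` (Angstrom^2), `aggregation`, `replica_sd` (NULL
#'   for a single window).
#' @export
rmsf_profile <- function(ensemble, window = NULL, fit_selection = NULL,
                         passes = 2L) {
  stopifnot(inherits(ensemble, "pdb_ensemble"))
  n <- nrow(ensemble$xyz)
  if (is.null(window)) window <- c(1L, n)
  window <- as.integer(window)
  if (window[2] - window[1] + 1L < 2L) {
    .stopf("analysis window must contain >= 2 frames",
           class = "phosready_window_error")
  }
  sel <- .resolve_selection(ensemble, fit_selection)
  sub <- new_ensemble(ensemble$atoms,
                      ensemble$xyz[window[1]:window[2], , drop = FALSE],
                      label = ensemble$label)
  ref <- .frame_xyz(sub, 1L)
  fitted <- NULL
  for (p in seq_len(passes)) {
    fitted <- .fit_frames(sub, ref, sel)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  dev2 <- lapply(fitted, function(m) rowSums((m - ref)^2))
  msf <- Reduce(`+`, dev2) / length(dev2)
  rmsf <- sqrt(msf)
  structure(list(atoms = ensemble$atoms, rmsf = rmsf, b = .B_CONST * msf,
                 aggregation = "single_window", replica_sd = NULL,
                 window = window),
            class = "fluctuation_profile")
}

#' Aggregate fluctuation profiles across replicas
#'
#' Per-atom mean and standard deviation (sample convention, n-1; replica
#' counts are small) of the RMSF across independent replicas; B-factors are
#' recomputed from the mean RMSF.
#'
#' @param profiles List of [rmsf_profile()] results with matching rosters.
#' @return A `fluctuation_profile` with `aggregation = "replica_mean_sd"`.
#' @export
replica_aggregate <- function(profiles) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "fluctuation_profile")))
  n_atoms <- nrow(profiles[[1]]$atoms)
  key <- paste(profiles[[1]]$atoms$chain, profiles[[1]]$atoms$resno,
               profiles[[1]]$atoms$name)
  for (p in profiles[-1]) {
    if (nrow(p$atoms) != n_atoms ||
        !identical(paste(p$atoms$chain, p$atoms$resno, p$atoms$name), key)) {
      .stopf("replica profiles have mismatching atom rosters",
             class = "phosready_ensemble_error")
    }
  }
  m <- do.call(cbind, lapply(profiles, `[[`, "rmsf"))
  mean_rmsf <- rowMeans(m)
  sd_rmsf <- if (ncol(m) > 1L) apply(m, 1L, stats::sd) else rep(0, n_atoms)
  structure(list(atoms = profiles[[1]]$atoms, rmsf = mean_rmsf,
                 b = .B_CONST * mean_rmsf^2, aggregation = "replica_mean_sd",
                 replica_sd = sd_rmsf, n_replicas = length(profiles)),
            class = "fluctuation_profile")
}

#' Estimate B-factors from a set of models
#'
#' Treats a small set of structures (e.g. the cluster representatives of
#' independent simulations) as an ensemble, superposes them onto their
#' average, and converts the per-atom mean-square fluctuation to a
#' Debye-Waller B-factor.
#'
#' @param models List of >= 2 `pdb_structure` objects with one shared roster.
#' @param fit_selection Atoms used for the superposition fit.
#' @return A `fluctuation_profile` with `aggregation = "model_set"`.
#' @export
bfactor_from_models <- function(models, fit_selection = NULL) {
  if (length(models) < 2L) .stopf("need >= 2 models")
  ens <- ensemble_from_frames(models, label = "model set")
  prof <- rmsf_profile(ens, fit_selection = fit_selection)
  prof$aggregation <- "model_set"
  prof
}

#' Write a fluctuation profile as TSV
#' @param profile A `fluctuation_profile`.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- data.frame(chain = profile$atoms$chain, resno = profile$atoms$resno,
                   resname = profile$atoms$resname, atom = profile$atoms$name,
                   rmsf_A = profile$rmsf, b_A2 = profile$b)
  if (!is.null(profile$replica_sd)) df$rmsf_sd_A <- profile$replica_sd
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stamp estimated B-factors into a structure
#'
#' Writes the profile's B-factors into the structure's B-factor column so the
#' mobility can be visualised with standard B-factor colouring.
#'
#' @param structure A `pdb_structure` whose roster matches the profile.
#' @param profile A `fluctuation_profile`.
#' @export
stamp_bfactors <- function(structure, profile) {
  stopifnot(inherits(structure, "pdb_structure"),
            nrow(structure$atoms) == nrow(profile$atoms))
  structure$atoms$b <- round(profile$b, 2)
  structure
}
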