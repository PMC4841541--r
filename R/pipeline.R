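# End-to-end orchestration: scan -> candidates -> synthetic ensembles (or
# user-supplied multi-model PDBs) -> convergence/clustering/fluctuation ->
# readiness report.

#' Protocol manifest for a replica study
#'
#' Carries the study bookkeeping: systems, replicas per system, trajectory
#' length, analysis window and analysis thresholds. The defaults mirror the
#' usual campaign shape: 50 ns trajectories analysed over their last 10 ns,
#' convergence called at backbone RMSD 2 Angstrom, clustering at a 1 Angstrom
#' neighbour cutoff.
#'
#' @param systems Data frame with at least `site`, `mode`, `label` (e.g. a
#'   [build_manifest()] result).
#' @param replicas Integer vector of replicas per system (recycled).
#' @param trajectory_ns,analysis_window_ns Simulated length and trailing
#'   analysis window (ns).
#' @param rmsd_convergence_threshold,cluster_cutoff Thresholds (Angstrom).
#' @return An object of class `protocol_manifest`.
#' @export
protocol_manifest <- function(systems, replicas = 4L, trajectory_ns = 50,
                              analysis_window_ns = 10,
                              rmsd_convergence_threshold = 2,
                              cluster_cutoff = 1) {
  stopifnot(is.data.frame(systems),
            all(c("site", "mode", "label") %in% names(systems)))
  replicas <- rep_len(as.integer(replicas), nrow(systems))
  structure(list(systems = systems, replicas = replicas,
                 trajectory_ns = trajectory_ns,
                 analysis_window_ns = analysis_window_ns,
                 rmsd_convergence_threshold = rmsd_convergence_threshold,
                 cluster_cutoff = cluster_cutoff),
            class = "protocol_manifest")
}

#' Validate a protocol manifest
#'
#' Checks the manifest invariants (analysis window inside the trajectory,
#' positive thresholds, replicas >= 1) and tallies the study size. Violations
#' are returned, not thrown.
#'
#' @param manifest A [protocol_manifest()].
#' @return List with `ok`, `violations` (character), `n_systems` and
#'   `total_trajectories`.
#' @export
validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "protocol_manifest"))
  v <- character(0)
  if (manifest$analysis_window_ns > manifest$trajectory_ns) {
    v <- c(v, "analysis window exceeds trajectory length")
  }
  if (manifest$rmsd_convergence_threshold <= 0) {
    v <- c(v, "rmsd_convergence_threshold must be > 0")
  }
  if (manifest$cluster_cutoff <= 0) v <- c(v, "cluster_cutoff must be > 0")
  if (any(manifest$replicas < 1L)) v <- c(v, "replicas must be >= 1")
  list(ok = length(v) == 0L, violations = v,
       n_systems = nrow(manifest$systems),
       total_trajectories = sum(manifest$replicas))
}

.default_config <- function() {
  list(
    region = list(residues = NULL, start = 1L, name = "region"),
    modes = c("binary", "ternary"),
    replicas = 3L,
    frames = 120L,
    seed = 1L,
    window_fraction = 0.2,
    convergence_threshold = 2.0,
    cluster_cutoff = 1.0,
    distance_cutoff = 4.0,
    b_high = 60,
    distances = NULL,
    efficiencies = NULL,
    study_dir = NULL,
    output_dir = NULL
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config file not found: %s", config,
                                     class = "phosready_config_error")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stopf("config must be a list or a YAML path",
                               class = "phosready_config_error")
  cfg <- utils::modifyList(.default_config(), config)
  unknown <- setdiff(names(config), names(.default_config()))
  if (length(unknown) > 0) {
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "),
           class = "phosready_config_error")
  }
  if (is.null(cfg$region$residues)) {
    .stopf("config$region$residues is required",
           class = "phosready_config_error")
  }
  if (is.null(cfg$output_dir)) .stopf("config$output_dir is required",
                                      class = "phosready_config_error")
  if (!all(cfg$modes %in% c("binary", "ternary"))) {
    .stopf("modes must be a subset of binary/ternary",
           class = "phosready_config_error")
  }
  for (k in c("replicas", "frames", "seed")) {
    if (!.is_count(cfg[[k]])) .stopf("config$%s must be a single integer", k,
                                     class = "phosready_config_error")
  }
  cfg
}

.log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  writeLines(msg, con)
}

#' Run the full scan-thread-simulate-analyze-score pipeline
#'
#' Executes the whole analysis on one region: consensus scan and candidate
#' enumeration, study manifest, synthetic replica ensembles (or a
#' pre-generated study directory with a `ground_truth.yaml`, e.g. holding
#' converted MD output), per-replica convergence assessment and clustering,
#' replica-averaged fluctuation profiles, and the readiness report. All
#' randomness derives from `config$seed`; re-running an identical config
#' reproduces the report files exactly (timestamps are confined to the log).
#'
#' @param config A list or YAML file path. Required keys: `region` (with
#'   `residues`, optional `start`, `name`) and `output_dir`. Optional keys
#'   and defaults: `modes` (binary+ternary), `replicas` (3), `frames` (120),
#'   `seed` (1), `window_fraction` (0.2), `convergence_threshold` (2),
#'   `cluster_cutoff` (1), `distance_cutoff` (4), `b_high` (60), `distances`
#'   (named by site), `efficiencies` (named by site, percent), `study_dir`
#'   (pre-generated study to analyse instead of simulating).
#' @return Invisibly, a list with the report, per-system analysis summaries
#'   and the run directory.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(cfg$output_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  .log_line(log_con, "pipeline start (seed %d)", cfg$seed)

  region <- rs_region(cfg$region$residues,
                      start = cfg$region$start %||% 1L,
                      name = cfg$region$name %||% "region")
  candidates <- enumerate_candidates(region)
  .log_line(log_con, "scan: %d Akt candidate site(s), %d SRPK site(s)",
            length(candidates), length(scan_srpk_sites(region)))
  utils::write.table(site_report(region),
                     file.path(cfg$output_dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (length(candidates) == 0L) {
    report <- build_report(list(), list())
    write_report_tsv(report, file.path(cfg$output_dir, "report.tsv"))
    .log_line(log_con, "no candidates; empty report written")
    return(invisible(list(report = report, systems = list(),
                          run_dir = cfg$output_dir)))
  }

  manifest_df <- build_manifest(candidates, cfg$modes)
  proto <- protocol_manifest(manifest_df, replicas = cfg$replicas)
  yaml::write_yaml(c(list(seed = cfg$seed), validate_manifest(proto),
                     list(systems = manifest_df$label)),
                   file.path(cfg$output_dir, "manifest.yaml"))

  study_dir <- cfg$study_dir
  if (is.null(study_dir)) {
    study_dir <- file.path(cfg$output_dir, "study")
    spec <- synthetic_study_spec(
      candidates, modes = cfg$modes, replicas = cfg$replicas,
      frames = cfg$frames, seed = cfg$seed,
      distances = if (!is.null(cfg$distances)) unlist(cfg$distances),
      efficiencies = if (!is.null(cfg$efficiencies)) unlist(cfg$efficiencies))
    synthesize_study(spec, study_dir)
    .log_line(log_con, "synthetic study generated under %s", study_dir)
  }
  truth <- yaml::read_yaml(file.path(study_dir, "ground_truth.yaml"))

  systems <- list()
  models <- list()
  profiles <- list()
  for (sys in truth$systems) {
    model <- extract_template(
      read_pdb(file.path(study_dir, sys$model_file)),
      kinase_chain = sys$extraction$kinase_chain,
      peptide_chain = sys$extraction$peptide_chain,
      tail_span = NULL,
      cofactor_name = if (sys$mode == "ternary") sys$extraction$cofactor_name,
      metal_name = sys$extraction$metal_name,
      site = sys$site, label = sys$label)
    asm <- as_structure(model)
    # whole-complex backbone for convergence/clustering (dominated by the
    # kinase, as in the standard protocol); kinase backbone as the fit frame
    # for fluctuation so peptide mobility is measured relative to the kinase
    bb_all <- atom_select(asm, "backbone")
    kin_bb <- setdiff(bb_all, atom_select(asm, "backbone",
                                          chain = model$peptide$atoms$chain[1]))
    rep_profiles <- list()
    conv <- logical(0)
    n_clusters <- integer(0)
    for (f in sys$files) {
      ens <- read_pdb(file.path(study_dir, f))
      series <- rmsd_series(ens, reference = "initial", selection = bb_all)
      cv <- assess_convergence(series, threshold = cfg$convergence_threshold,
                               window_fraction = cfg$window_fraction)
      conv <- c(conv, cv$converged)
      win <- new_ensemble(ens$atoms,
                         ens$xyz[cv$window[1]:cv$window[2], , drop = FALSE])
      cl <- cluster_gromos(win, cutoff = cfg$cluster_cutoff,
                           selection = bb_all)
      n_clusters <- c(n_clusters, length(cl$clusters))
      rep_profiles[[f]] <- rmsf_profile(ens, window = cv$window,
                                        fit_selection = kin_bb)
    }
    prof <- replica_aggregate(rep_profiles)
    systems[[sys$label]] <- list(label = sys$label, site = sys$site,
                                 mode = sys$mode, converged = conv,
                                 n_clusters = n_clusters)
    write_profile_tsv(prof, file.path(cfg$output_dir,
                                      sprintf("rmsf_%s.tsv", sys$label)))
    .log_line(log_con, "system %s: %d/%d replicas converged, clusters: %s",
              sys$label, sum(conv), length(conv),
              paste(n_clusters, collapse = ","))
    if (sys$mode == "ternary") {
      models[[sys$label]] <- model
      profiles[[sys$label]] <- prof
    }
  }

  eff_df <- NULL
  if (!is.null(cfg$efficiencies)) {
    eff <- unlist(cfg$efficiencies)
    eff_df <- data.frame(site = as.integer(names(eff)), efficiency = eff)
  }
  report <- build_report(models, profiles, efficiencies = eff_df,
                         distance_cutoff = cfg$distance_cutoff,
                         b_high = cfg$b_high)
  write_report_tsv(report, file.path(cfg$output_dir, "report.tsv"))
  r <- attr(report, "correlation")
  if (!is.null(r)) .log_line(log_con, "efficiency-mobility r = %.3f", r)
  .log_line(log_con, "pipeline done; report at %s",
            file.path(cfg$output_dir, "report.tsv"))
  invisible(list(report = report, systems = systems,
                 run_dir = cfg$output_dir))
}
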