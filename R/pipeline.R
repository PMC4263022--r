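# End-to-end orchestration: fit -> score -> calibrate -> networks ->
# metrics, with every stochastic step seeded from the run configuration
# and every artifact written as TSV through the data_io layer.

#' Run the full co-occurrence analysis pipeline
#'
#' Takes either file paths to the three input tables or a
#' [synthetic_spec()], and emits, in order: the fitted null model, the
#' calibrated taxa-axis (and optionally sample-axis) score tables, the
#' FPR/PPV calibration curve, the observed association network at the
#' configured thresholds or target PPV, a count-matched control network,
#' and the downstream metric tables.  All outputs are pure functions of
#' (inputs, config): rerunning with the same config reproduces them
#' bit-identically.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `matrix_path`/`env_path`/`taxonomy_path` *or* `synthetic` (arguments
#'   for [synthetic_spec()]); `level` (default `"subtype"`); `R`
#'   (calibration replicates, default 100); `T_agg`, `T_seg` *or*
#'   `target_ppv`; `sample_axis` (default `FALSE`); `S0` (default 4.92);
#'   `control_R` (default equal to `R`); `seed`; `outdir` (optional: when
#'   set, all tables are written there).
#' @return A run manifest (class `coocnet_manifest`): list with the
#'   fitted objects, the summary statistics, the seeds used, and the
#'   paths of any files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    level = "subtype", R = 100L, sample_axis = FALSE,
    T_agg = NULL, T_seg = NULL, target_ppv = NULL,
    S0 = 4.92, control_R = NULL, seed = 1L, outdir = NULL), config)
  if (is.null(cfg$control_R)) cfg$control_R <- cfg$R
  seed <- as.integer(cfg$seed)
  seeds <- list(calibrate_taxa = seed + 1L, calibrate_samples = seed + 2L,
                control = seed + 3L)
  paths <- list()

  # ---- inputs -------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    sp_args <- cfg$synthetic
    if (is.null(sp_args$seed)) sp_args$seed <- seed
    if (!is.null(sp_args$planted_pairs))
      sp_args$planted_pairs <- as.data.frame(sp_args$planted_pairs)
    spec <- do.call(synthetic_spec, sp_args)
    ds <- generate_dataset(spec)
  } else {
    ds <- read_dataset(cfg$matrix_path, cfg$env_path, cfg$taxonomy_path,
                       drop_unlabelled = isTRUE(cfg$drop_unlabelled))
    ds$truth <- NULL
  }
  X <- ds$presence; env <- ds$env

  # ---- null model ---------------------------------------------------
  model <- fit_null_model(X, env, level = cfg$level)

  # ---- scores and calibration --------------------------------------
  scores <- calibrate_scores(X, env, model, R = cfg$R,
                             seed = seeds$calibrate_taxa, axis = "taxa")
  sample_scores <- NULL
  if (isTRUE(cfg$sample_axis))
    sample_scores <- calibrate_scores(X, env, model, R = cfg$R,
                                      seed = seeds$calibrate_samples,
                                      axis = "samples")

  # ---- thresholds ---------------------------------------------------
  curve <- estimate_fpr_ppv(scores)
  if (!is.null(cfg$target_ppv)) {
    T_agg <- threshold_at_ppv(curve, cfg$target_ppv, "aggregation")
    T_seg <- threshold_at_ppv(curve, cfg$target_ppv, "segregation")
  } else {
    if (is.null(cfg$T_agg) || is.null(cfg$T_seg))
      stop("config needs either target_ppv or both T_agg and T_seg")
    T_agg <- cfg$T_agg; T_seg <- cfg$T_seg
  }

  # ---- networks -----------------------------------------------------
  network <- build_network(scores, T_agg, T_seg)
  n_agg <- sum(network$edges$type == "aggregation")
  n_seg <- sum(network$edges$type == "segregation")
  control <- build_control_network(model, env, n_agg, n_seg,
                                   seed = seeds$control, R = cfg$control_R)

  # ---- metrics ------------------------------------------------------
  triangles <- triangle_propensities(network, scores)
  triangles_control <- triangle_propensities(control, attr(control, "scores"))
  env_cosmo <- environmental_cosmopolitanism(X, env)
  comm_cosmo <- if (!is.null(sample_scores))
    community_cosmopolitanism(X, sample_scores, S0 = cfg$S0) else NULL
  deg_agg <- table(factor(
    c(network$edges$taxon_i[network$edges$type == "aggregation"],
      network$edges$taxon_j[network$edges$type == "aggregation"]),
    levels = X$taxa))
  cosmo_table <- data.frame(
    taxon = X$taxa, prevalence = X$prevalence,
    env_cosmopolitanism = as.integer(env_cosmo[X$taxa]),
    comm_cosmopolitanism = if (is.null(comm_cosmo)) NA_real_
      else comm_cosmo[X$taxa],
    n_aggregations = as.integer(deg_agg[X$taxa]),
    stringsAsFactors = FALSE)
  cosmo_table$agg_per_prevalence <-
    ifelse(cosmo_table$prevalence > 0,
           cosmo_table$n_aggregations / cosmo_table$prevalence, NA_real_)

  summary <- list(
    n_taxa = length(X$taxa), n_samples = length(X$samples),
    n_pairs = nrow(scores), loglik = sum(model$fit$loglik),
    thresholds = c(aggregation = T_agg, segregation = T_seg),
    n_aggregations = n_agg, n_segregations = n_seg,
    fpr_at_thresholds = c(
      aggregation = curve_value(curve, "aggregation", T_agg, "FPR"),
      segregation = curve_value(curve, "segregation", T_seg, "FPR")),
    ppv_at_thresholds = c(
      aggregation = curve_value(curve, "aggregation", T_agg, "PPV"),
      segregation = curve_value(curve, "segregation", T_seg, "PPV")))
  if (!is.null(ds$truth))
    summary$recovery_auc <- recovery_auc(scores, ds$truth)

  # ---- outputs ------------------------------------------------------
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    op <- function(f) file.path(cfg$outdir, f)
    write_dataset(ds, op("matrix.tsv"), op("env.tsv"), op("taxonomy.tsv"))
    write.table(data.frame(stratum = colnames(model$p), t(model$p)),
                op("model_p.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = names(model$q), q = model$q),
                op("model_q.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(model$fit, op("fit_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(scores), op("scores_taxa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(sample_scores))
      write.table(as.data.frame(sample_scores), op("scores_samples.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(curve), op("calibration_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_associations(network, scores, op("network_observed.tsv"))
    write_associations(control, attr(control, "scores"),
                       op("network_control.tsv"))
    write.table(triangles, op("triangle_propensities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(cosmo_table, op("cosmopolitanism.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- list(
      matrix = op("matrix.tsv"), env = op("env.tsv"),
      taxonomy = op("taxonomy.tsv"), model_p = op("model_p.tsv"),
      model_q = op("model_q.tsv"), fit_report = op("fit_report.tsv"),
      scores_taxa = op("scores_taxa.tsv"),
      curve = op("calibration_curve.tsv"),
      network_observed = op("network_observed.tsv"),
      network_control = op("network_control.tsv"),
      triangles = op("triangle_propensities.tsv"),
      cosmopolitanism = op("cosmopolitanism.tsv"))
  }

  structure(list(config = cfg, seeds = seeds, paths = paths,
                 dataset = ds, model = model, scores = scores,
                 sample_scores = sample_scores, curve = curve,
                 network = network, control = control,
                 triangles = triangles,
                 triangles_control = triangles_control,
                 cosmopolitanism = cosmo_table,
                 summary = summary),
            class = "coocnet_manifest")
}

curve_value <- function(curve, type, threshold, what) {
  cv <- curve[curve$type == type, , drop = FALSE]
  i <- which.min(abs(cv$threshold - threshold))
  cv[[what]][i]
}

#' @export
print.coocnet_manifest <- function(x, ...) {
  s <- x$summary
  cat(sprintf("coocnet run: %d taxa x %d samples (%d pairs)\n",
              s$n_taxa, s$n_samples, s$n_pairs))
  cat(sprintf("  network: %d aggregations, %d segregations at Z >= (%.2f, %.2f)\n",
              s$n_aggregations, s$n_segregations,
              s$thresholds[["aggregation"]], s$thresholds[["segregation"]]))
  if (!is.null(s$recovery_auc))
    cat(sprintf("  planted-pair recovery AUC: %.3f\n", s$recovery_auc))
  if (length(x$paths) > 0)
    cat("  outputs in:", dirname(x$paths[[1]]), "\n")
  invisible(x)
}
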