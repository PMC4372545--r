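#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end pipeline needs. Can be
#' built programmatically or loaded from YAML ([read_config()]).
#'
#' @param n_subjects Number of synthetic participants.
#' @param spec [acq_spec()] or a list of its arguments.
#' @param truth [ground_truth()] or a list of its arguments.
#' @param hrf [hrf_params()] or a list of its arguments.
#' @param model Encoding model used for the analysis design.
#' @param compare_models Models entered in the posterior predictive
#'   comparison (empty to skip).
#' @param alpha Uncorrected two-tailed voxel threshold.
#' @param fwe_level Corrected family-wise level.
#' @param n_perm Number of permutations (0 skips corrected inference).
#' @param perm_scheme `"global"` or `"within_subject"`.
#' @param roi_radius Sphere radius (mm) for the model check.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param n_ppc Posterior predictive replicates.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 4, spec = acq_spec(),
                            truth = ground_truth(), hrf = hrf_params(),
                            model = "decay",
                            compare_models = c("sample_only",
                                               "sample_plus_delay", "decay"),
                            alpha = 0.01, fwe_level = 0.05, n_perm = 199,
                            perm_scheme = "global", roi_radius = 5,
                            connectivity = 26, n_ppc = 20, seed = 1,
                            out_dir = tempfile("delaymem_out")) {
  if (is.list(spec) && !inherits(spec, "acq_spec"))
    spec <- do.call(acq_spec, spec)
  if (is.list(truth) && !inherits(truth, "ground_truth"))
    truth <- do.call(ground_truth, truth)
  if (is.list(hrf) && !inherits(hrf, "hrf_params"))
    hrf <- do.call(hrf_params, hrf)
  stopifnot(n_subjects >= 2,
            model %in% .ENCODING_MODELS,
            all(compare_models %in% .ENCODING_MODELS),
            alpha > 0, alpha < 1, fwe_level > 0, fwe_level < 1,
            n_perm >= 0, perm_scheme %in% c("global", "within_subject"),
            roi_radius > 0, connectivity %in% c(6, 18, 26), n_ppc >= 2)
  structure(list(n_subjects = as.integer(n_subjects), spec = spec,
                 truth = truth, hrf = hrf, model = model,
                 compare_models = compare_models, alpha = alpha,
                 fwe_level = fwe_level, n_perm = as.integer(n_perm),
                 perm_scheme = perm_scheme, roi_radius = roi_radius,
                 connectivity = as.integer(connectivity),
                 n_ppc = as.integer(n_ppc), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; `spec`, `truth` and `hrf` may be nested maps
#' of the corresponding constructor arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$truth$effect_mask))
    stop("effect_mask cannot be set from YAML; pass it programmatically")
  do.call(pipeline_config, raw)
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> design -> first level -> group WLS -> thresholding,
#' clustering and (optionally) permutation FWE -> posterior predictive
#' model comparison -> behavioral scoring, writing all tables, maps, and a
#' markdown report under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a `pipeline_result` list with every stage's objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec; truth <- config$truth
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  participants <- .stage("simulate", lapply(seq_len(config$n_subjects),
    function(i) simulate_participant(spec, truth,
                                     seed = config$seed + 37L * i)))

  coefs <- .stage("first level", lapply(participants, function(p) {
    design <- build_design(p$schedule, p$behavior, p$motion,
                           model = config$model, hrf = config$hrf,
                           spec = spec)
    encoding_coefficients(fit_voxelwise(p$bold, design))
  }))

  gd <- .stage("group model", stack_group_data(coefs))
  gfit <- fit_wls(gd)

  thr <- .stage("thresholding", {
    t_map <- array(gfit$t, dim = spec$grid_shape)
    threshold_map(t_map, df = gfit$df, alpha = config$alpha)
  })
  clusters <- label_clusters(thr$map, config$connectivity,
                             t_map = array(gfit$t, dim = spec$grid_shape),
                             affine = participants[[1]]$affine)
  write_tsv(clusters, out("clusters.tsv"))

  perm <- NULL
  if (config$n_perm > 0) {
    perm <- .stage("permutation FWE",
                   permutation_fwe(gd, B = config$n_perm,
                                   scheme = config$perm_scheme,
                                   seed = config$seed + 7L,
                                   store_t = length(gd$voxels) *
                                     config$n_perm <= 5e6))
  } else {
    warning("n_perm = 0: corrected inference skipped")
  }

  comparison <- NULL
  if (length(config$compare_models) > 0) {
    comparison <- .stage("model check",
                         compare_models(participants[[1]],
                                        models = config$compare_models,
                                        radius = config$roi_radius,
                                        n_sim = config$n_ppc,
                                        seed = config$seed + 11L))
    write_tsv(as.data.frame(comparison), out("model_comparison.tsv"))
  }

  behav <- .stage("behavior", behavior_summary(participants))
  write_tsv(behav, out("behavior_summary.tsv"))

  write_nifti(array(gfit$t, dim = spec$grid_shape), out("group_t.nii"),
              voxel_size = spec$voxel_size)
  write_nifti(array(gfit$slope, dim = spec$grid_shape),
              out("group_slope.nii"), voxel_size = spec$voxel_size)
  if (!is.null(perm))
    write_nifti(array(perm$p_corrected, dim = spec$grid_shape),
                out("p_fwe.nii"), voxel_size = spec$voxel_size)

  .write_report(config, gfit, thr, clusters, perm, comparison, behav,
                out("report.md"))
  res <- structure(list(config = config, participants = participants,
                        group_data = gd, group_fit = gfit, threshold = thr,
                        clusters = clusters, permutation = perm,
                        comparison = comparison, behavior = behav),
                   class = "pipeline_result")
  invisible(res)
}

.write_report <- function(config, gfit, thr, clusters, perm, comparison,
                          behav, path) {
  lines <- c(
    "# Delayed match-to-sample subsequent-memory pipeline report", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- subjects: %d, grid: %s, analysis model: %s",
            config$n_subjects, paste(config$spec$grid_shape, collapse = "x"),
            config$model),
    sprintf("- group df: %d over %d stacked points", gfit$df,
            gfit$n_points), "",
    sprintf("## Uncorrected threshold (two-tailed alpha = %g)",
            config$alpha),
    sprintf("- critical |t| = %.3f; %d positive, %d negative voxel(s)",
            thr$critical, thr$n_positive, thr$n_negative), "",
    "## Clusters", "",
    paste(utils::capture.output(print(clusters)), collapse = "\n"), "")
  if (!is.null(perm)) {
    lines <- c(lines,
      sprintf("## Permutation FWE (B = %d, %s shuffle)", perm$B,
              perm$scheme),
      sprintf("- voxels at corrected p <= %g: %d", config$fwe_level,
              sum(perm$p_corrected <= config$fwe_level)), "")
  }
  if (!is.null(comparison)) {
    lines <- c(lines, "## Posterior predictive model comparison", "",
               paste(utils::capture.output(
                 print(as.data.frame(comparison))), collapse = "\n"), "")
  }
  lines <- c(lines, "## Behavior", "",
             paste(utils::capture.output(print(behav)), collapse = "\n"))
  writeLines(lines, path)
  invisible(path)
}
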