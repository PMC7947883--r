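#' Pipeline configuration
#'
#' Bundles every stage's settings into one serializable object: cohort
#' composition, phantom overrides, perturbation distributions, delineation
#' thresholds/rules, statistics options, and the global seed. Defaults are
#' the study conditions (72 patients, 32/24/16 across upper/middle/distal).
#'
#' @param n_a,n_b,n_c group sizes.
#' @param seed global seed; expands into per-patient substreams.
#' @param out_dir default output directory for [run_all()].
#' @param delineation_mode "image" derives GTV_3D from the CT wall rule and
#'   GTV_PET-reg from the SUV auto-contour (heart-repaired) on the rendered
#'   volumes; "analytic" takes all three variants from the recorded
#'   ground-truth perturbations.
#' @param write_volumes write the full CT/PET volumes per patient (large and
#'   slow at cohort scale; masks, manifest and metrics are always written).
#' @param phantom named list of [phantom_spec()] overrides.
#' @param distributions named list of [cohort_distributions()] overrides.
#' @param threshold named list of [threshold_spec()] overrides
#'   (`absolute_suv`, `fraction_of_max`, `roi_margin`).
#' @param ct_rule named list of [ct_rule_spec()] overrides.
#' @param stats named list: `holm`.
#' @export
pipeline_config <- function(n_a = 32, n_b = 24, n_c = 16, seed = 1L,
                            out_dir = NULL,
                            delineation_mode = c("image", "analytic"),
                            write_volumes = FALSE,
                            phantom = list(), distributions = list(),
                            threshold = list(), ct_rule = list(),
                            stats = list(holm = FALSE)) {
  delineation_mode <- match.arg(delineation_mode)
  structure(list(n_a = n_a, n_b = n_b, n_c = n_c, seed = as.integer(seed),
                 out_dir = out_dir, delineation_mode = delineation_mode,
                 write_volumes = write_volumes, phantom = phantom,
                 distributions = distributions, threshold = threshold,
                 ct_rule = ct_rule, stats = stats),
            class = "pipeline_config")
}

cfg_phantom_spec <- function(config) {
  do.call(phantom_spec, config$phantom)
}

cfg_distributions <- function(config) {
  do.call(cohort_distributions, config$distributions)
}

# image-based delineation of one simulated patient -> list of three masks
delineate_patient <- function(patient, config) {
  spec <- patient$meta$spec
  ctr <- patient$meta$tumor_center
  thr <- config$threshold
  roi_margin <- if (!is.null(thr$roi_margin)) thr$roi_margin else 15
  ts <- threshold_spec(
    absolute_suv = if (!is.null(thr$absolute_suv)) thr$absolute_suv else 2.5,
    fraction_of_max = if (!is.null(thr$fraction_of_max))
      thr$fraction_of_max else 0.20,
    roi_center = ctr,
    roi_radius = max(spec$tumor_length / 2, spec$tumor_radius) + roi_margin)
  pet_mask <- suv_threshold(patient$pet_suv, ts)
  gtv_reg <- exclude_heart(pet_mask, patient$heart_mask, patient$planning_ct)
  ext <- spec$grid_shape * spec$spacing
  axis <- cbind(ctr[1], ctr[2], c(0.5 * spec$spacing[3],
                                  ext[3] - 0.5 * spec$spacing[3]))
  cr <- do.call(ct_rule_spec, config$ct_rule)
  gtv_3d <- ct_wall_rule(patient$planning_ct, axis, cr)
  list(gtv_3d = gtv_3d,
       gtv_pet_ref = patient$gtv_set$gtv_pet_ref,
       gtv_pet_reg = gtv_reg,
       threshold = attr(pet_mask, "threshold"),
       suvmax = attr(pet_mask, "suvmax"))
}

flatten_pert <- function(p, tag) {
  out <- c(p$com_shift, p$length_delta, p$radius_delta,
           p$deformation_amplitude)
  names(out) <- paste0(tag, "_", c("shift_lr", "shift_ap", "shift_cc",
                                   "length_delta", "radius_delta",
                                   "deformation"))
  as.list(out)
}

#' Run the full pipeline: simulate, delineate, compare, report
#'
#' Streams patient by patient (one patient's volumes in memory at a time):
#' simulates the phantom, derives/delineates the three GTVs, computes the
#' pairwise metric record, then drops the volumes. Writes, under `out_dir`:
#' per-patient masks (`masks/`), the cohort manifest (`cohort.csv`, with
#' applied perturbations, SUVmax, effective thresholds and voxel counts),
#' per-patient metrics (`metrics.csv`), one CSV per report table
#' (`tables/t2.csv` .. `t6.csv` and `*_tests.csv`), all test results as JSON,
#' the resolved configuration (`config.yaml`), and a log carrying the config
#' hash. Identical config + seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress per-patient progress messages.
#' @return a `cohort_result` (invisibly) with the per-patient metrics
#'   attached as attribute `metrics`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = config$out_dir,
                    quiet = FALSE) {
  if (is.null(out_dir)) stop("an output directory is required")
  stage <- "setup"
  tryCatch({
    dir.create(file.path(out_dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)
    if (config$write_volumes)
      dir.create(file.path(out_dir, "volumes"), showWarnings = FALSE)
    base_spec <- cfg_phantom_spec(config)
    dist <- cfg_distributions(config)
    ids <- c(if (config$n_a) sprintf("A%03d", seq_len(config$n_a)),
             if (config$n_b) sprintf("B%03d", seq_len(config$n_b)),
             if (config$n_c) sprintf("C%03d", seq_len(config$n_c)))
    locs <- c(rep("upper", config$n_a), rep("middle", config$n_b),
              rep("distal", config$n_c))
    hash <- config_hash(config)
    logf <- file.path(out_dir, "run.log")
    cat(sprintf("gtvconc run, config hash %s, seed %d, %d patients\n",
                hash, config$seed, length(ids)), file = logf)
    metrics_rows <- manifest_rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      stage <- paste0("simulate[", ids[i], "]")
      pat <- simulate_patient(ids[i], locs[i], dist, config$seed, base_spec,
                              keep_volumes = TRUE)
      stage <- paste0("delineate[", ids[i], "]")
      if (config$delineation_mode == "image") {
        dl <- delineate_patient(pat, config)
        gtvs <- dl[c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg")]
        thr_used <- dl$threshold; suvmax_obs <- dl$suvmax
      } else {
        gtvs <- pat$gtv_set[c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg")]
        thr_used <- NA_real_
        suvmax_obs <- max(pat$pet_suv$data[pat$truth_mask$data])
      }
      stage <- paste0("compare[", ids[i], "]")
      rec <- compare_gtv_set(gtvs)
      row <- as.data.frame(rec)
      row <- cbind(data.frame(id = pat$id, group = pat$group,
                              stringsAsFactors = FALSE), row)
      metrics_rows[[i]] <- row
      spec <- pat$meta$spec
      manifest_rows[[i]] <- cbind(
        data.frame(id = pat$id, group = pat$group,
                   tumor_location = spec$tumor_location,
                   tumor_length = spec$tumor_length,
                   tumor_radius = spec$tumor_radius,
                   tumor_suvmax = spec$tumor_suvmax,
                   suvmax_observed = suvmax_obs,
                   effective_threshold = thr_used,
                   truth_voxels = n_voxels(pat$truth_mask),
                   gtv_3d_voxels = n_voxels(gtvs$gtv_3d),
                   gtv_pet_ref_voxels = n_voxels(gtvs$gtv_pet_ref),
                   gtv_pet_reg_voxels = n_voxels(gtvs$gtv_pet_reg),
                   stringsAsFactors = FALSE),
        as.data.frame(c(flatten_pert(pat$gtv_set$applied$gtv_3d, "gtv_3d"),
                        flatten_pert(pat$gtv_set$applied$gtv_pet_ref, "ref"),
                        flatten_pert(pat$gtv_set$applied$gtv_pet_reg, "reg"))))
      stage <- paste0("write[", ids[i], "]")
      for (v in c("gtv_3d", "gtv_pet_ref", "gtv_pet_reg"))
        write_mask(gtvs[[v]],
                   file.path(out_dir, "masks",
                             sprintf("%s_%s.nii.gz", pat$id, v)))
      write_mask(pat$truth_mask,
                 file.path(out_dir, "masks",
                           sprintf("%s_truth.nii.gz", pat$id)))
      if (config$write_volumes) {
        write_volume(pat$planning_ct,
                     file.path(out_dir, "volumes",
                               sprintf("%s_ct.nii.gz", pat$id)))
        write_volume(pat$pet_suv,
                     file.path(out_dir, "volumes",
                               sprintf("%s_pet.nii.gz", pat$id)))
      }
      if (!quiet)
        cat(sprintf("[%s] %s group %s: SUVmax %.2f, threshold %.2f, GTV voxels %d/%d/%d\n",
                    hash, pat$id, pat$group, suvmax_obs,
                    if (is.na(thr_used)) -1 else thr_used,
                    n_voxels(gtvs$gtv_3d), n_voxels(gtvs$gtv_pet_ref),
                    n_voxels(gtvs$gtv_pet_reg)),
            file = logf, append = TRUE)
      rm(pat, gtvs)
    }
    stage <- "stats"
    metrics <- do.call(rbind, metrics_rows)
    manifest <- do.call(rbind, manifest_rows)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    holm <- isTRUE(config$stats$holm)
    result <- build_tables(metrics, holm = holm)
    for (tn in names(result$tables))
      utils::write.csv(result$tables[[tn]],
                       file.path(out_dir, "tables", paste0(tn, ".csv")),
                       row.names = FALSE)
    for (tn in names(result$tests))
      utils::write.csv(result$tests[[tn]],
                       file.path(out_dir, "tables", paste0(tn, "_tests.csv")),
                       row.names = FALSE)
    jsonlite::write_json(result$tests,
                         file.path(out_dir, "tables", "tests.json"),
                         dataframe = "rows", digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
    attr(result, "metrics") <- metrics
    invisible(result)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage %s: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
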