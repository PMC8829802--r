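# quantify one subject's maps for the requested modalities; returns a
# named list of absolute cbf_maps plus the subject's PC whole-brain CBF
quantify_subject <- function(phantom, cfg, schedule, aif, params, scheme,
                             seed) {
  grid <- phantom$grid
  target_fwb <- mean(phantom$true_cbf[phantom$brain_mask])
  pc <- simulate_pc(phantom, target_fwb, seed = seed)
  f_wb <- pc_whole_brain_cbf(pc)
  maps <- list()
  for (mod in cfg$modalities) {
    if (mod == "pet") {
      dyn <- simulate_pet_dynamic(phantom, aif, schedule,
                                  noise_sd = cfg$pet$noise_sd, seed = seed,
                                  lambda = cfg$constants$lambda_partition)
      tac <- frame_midpoint_tac(dyn, phantom$brain_mask)
      map <- pmrflow_cbf(dyn, tac, f_wb,
                         lambda = cfg$constants$lambda_partition,
                         integration_time = cfg$pet$integration_time,
                         mask = phantom$brain_mask)
      map <- smooth_gaussian(map, cfg$pet$fwhm)
    } else if (mod == "asl_sd") {
      acq <- simulate_asl_sd(phantom, params, n_pairs = cfg$asl$n_pairs,
                             noise_sd = cfg$asl$noise_sd, seed = seed + 1L)
      map <- quantify_sd_cbf(pairwise_subtract(acq), phantom$m0, params)
      map$valid <- map$valid & phantom$brain_mask
      map <- smooth_gaussian(map, cfg$asl$fwhm)
    } else if (mod == "asl_te") {
      acq <- simulate_asl_te(phantom, scheme, params,
                             noise_sd = cfg$asl$noise_sd, seed = seed + 2L)
      fit <- fit_te_cbf_att(hadamard_decode(acq), phantom$m0, params,
                            mask = phantom$brain_mask)
      map <- fit$cbf
      map <- smooth_gaussian(map, cfg$asl$fwhm)
    } else stop(sprintf("unknown modality '%s'", mod))
    maps[[mod]] <- normalize_to_wb(map, f_wb, phantom$brain_mask)
  }
  list(maps = maps, f_wb = f_wb)
}

#' Run the full simulation-to-concordance pipeline
#'
#' Sequences the whole analysis on synthetic data: build a control cohort
#' (between-subject variability as a global CBF scale factor) and a
#' patient set with known lesion geometry; simulate and quantify each
#' requested modality; smooth and intensity-normalize the maps; derive
#' per-patient hypoperfusion masks against the control cohort with the
#' Crawford-Howell test (absolute and relative CBF); and compute the
#' mask- and ROI-level concordance of each ASL modality against PET.
#'
#' @param config A [default_config()]-style `run_config`.
#' @param out_dir Optional directory; when given, concordance and
#'   ROI-agreement CSVs and a provenance JSON (full config and seed) are
#'   written there.
#' @param scales Which CBF scales to analyse (`"absolute"`,
#'   `"relative"`).
#' @return List with `concordance` (one row per patient x ASL modality x
#'   scale), `roi_agreement` (regression and Bland-Altman of ASL vs PET
#'   ROI means), `masks` (per patient, modality and scale), `atlas`, and
#'   `f_wb` per subject.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         scales = c("absolute", "relative")) {
  cfg <- validate_config(config)
  grid <- voxel_grid(cfg$grid$shape, cfg$grid$voxel_size)
  kc <- do.call(kinetic_constants, cfg$constants)
  params <- asl_params(cfg$asl$label_duration, cfg$asl$post_label_delay,
                       kc, cfg$background_suppression_factor)
  scheme <- hadamard_scheme(cfg$te$n_encode, cfg$te$sub_bolus_durations,
                            cfg$te$final_pld)
  schedule <- frame_schedule()
  aif <- gamma_variate_aif(cfg$aif$peak_time, cfg$aif$peak_value,
                           cfg$aif$shape,
                           times = seq(0, max(schedule$end), by = 0.25))
  base_seed <- as.integer(cfg$seed)

  set.seed(base_seed)
  ctl_scale <- pmax(0.5, stats::rnorm(cfg$n_controls, 1, cfg$subject_cbf_cv))

  subjects <- list()
  for (i in seq_len(cfg$n_controls)) {
    ph <- build_phantom(grid, gm_cbf = cfg$gm_cbf, wm_cbf = cfg$wm_cbf,
                        att_range = cfg$att_range, seed = base_seed,
                        cbf_scale = ctl_scale[i])
    subjects[[paste0("control", sprintf("%02d", i))]] <-
      c(quantify_subject(ph, cfg, schedule, aif, params, scheme,
                         seed = base_seed + 10L * i),
        list(role = "control", phantom = ph))
  }
  for (j in seq_along(cfg$patients)) {
    pdef <- cfg$patients[[j]]
    ph <- build_phantom(grid, lesion_spec = pdef$lesions,
                        gm_cbf = cfg$gm_cbf, wm_cbf = cfg$wm_cbf,
                        att_range = cfg$att_range, seed = base_seed)
    subjects[[pdef$id]] <-
      c(quantify_subject(ph, cfg, schedule, aif, params, scheme,
                         seed = base_seed + 10000L + 10L * j),
        list(role = "patient", phantom = ph))
  }

  roles <- vapply(subjects, `[[`, character(1), "role")
  controls <- subjects[roles == "control"]
  patients <- subjects[roles == "patient"]
  brain <- subjects[[1]]$phantom$brain_mask
  atlas <- phantom_atlas(patients[[1]]$phantom)
  min_vox <- min_cluster_extent(cfg$sphere_diameter_mm,
                                grid$voxel_size[1])
  t_crit <- critical_t(cfg$n_controls, cfg$alpha)

  get_map <- function(subj, mod, scale) {
    m <- subj$maps[[mod]]
    if (scale == "relative") m <- relative_cbf(m, brain)
    m
  }

  conc <- list(); masks <- list()
  for (scale in scales) {
    stats_by_mod <- lapply(stats::setNames(cfg$modalities, cfg$modalities),
                           function(mod)
      control_group_stats(lapply(controls, get_map, mod, scale)))
    for (pid in names(patients)) {
      pmask <- list()
      for (mod in cfg$modalities) {
        tmap <- crawford_howell_t(get_map(patients[[pid]], mod, scale),
                                  stats_by_mod[[mod]])
        pmask[[mod]] <- hypoperfusion_mask(tmap, t_crit)
        masks[[paste(pid, mod, scale, sep = ".")]] <- pmask[[mod]]
      }
      for (mod in setdiff(cfg$modalities, "pet")) {
        if (!"pet" %in% cfg$modalities) next
        row <- concordance_summary(pmask[[mod]], pmask[["pet"]], atlas,
                                   min_vox, cfg$connectivity)
        conc[[length(conc) + 1L]] <-
          cbind(data.frame(patient = pid, modality = mod, scale = scale),
                row)
      }
    }
  }
  concordance <- if (length(conc)) do.call(rbind, conc) else NULL

  # ROI-level agreement of absolute ASL vs PET means, pooled over subjects
  roi_agreement <- NULL
  if ("pet" %in% cfg$modalities && length(setdiff(cfg$modalities, "pet"))) {
    rows <- list()
    for (mod in setdiff(cfg$modalities, "pet")) {
      x <- unlist(lapply(subjects, function(s)
        roi_mean_cbf(s$maps[["pet"]], atlas)))
      y <- unlist(lapply(subjects, function(s)
        roi_mean_cbf(s$maps[[mod]], atlas)))
      reg <- regress_rois(x, y)
      ba <- bland_altman(x, y)
      rows[[mod]] <- data.frame(modality = mod, intercept = reg$intercept,
                                slope = reg$slope, r = reg$r,
                                bias = ba$bias, loa_lower = ba$lower,
                                loa_upper = ba$upper)
    }
    roi_agreement <- do.call(rbind, rows)
  }

  out <- list(concordance = concordance, roi_agreement = roi_agreement,
              masks = masks, atlas = atlas,
              f_wb = vapply(subjects, `[[`, numeric(1), "f_wb"),
              min_cluster_voxels = min_vox, t_crit = t_crit,
              config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(concordance))
      utils::write.csv(concordance, file.path(out_dir, "concordance.csv"),
                       row.names = FALSE)
    if (!is.null(roi_agreement))
      utils::write.csv(roi_agreement,
                       file.path(out_dir, "roi_agreement.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(config = unclass(cfg),
                              package_version =
                                as.character(utils::packageVersion("perfcon"))),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
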