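#' Read a NIfTI-1 volume and its grid
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param expect_grid Optional [voxel_grid()]; a mismatch raises an error
#'   naming both grids.
#' @return List with `data` (array, 3D or 4D) and `grid`.
#' @export
read_volume <- function(path, expect_grid = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim(img))
  pd <- RNifti::pixdim(img)[1:3]
  grid <- voxel_grid(dim(data)[1:3], pd)
  if (!is.null(expect_grid)) stop_if_grid_mismatch(expect_grid, grid, path)
  list(data = data, grid = grid)
}

#' Write a volume as NIfTI-1
#'
#' Integer volumes round-trip bit-exactly; doubles within float
#' precision (NIfTI stores what it is given; RNifti writes doubles as
#' float64 here).
#'
#' @param data 3D or 4D array.
#' @param path Output path (.nii or .nii.gz).
#' @param grid A [voxel_grid()] supplying voxel sizes.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop(sprintf("volume dims %s do not match grid %s",
                 paste(dim(data), collapse = "x"), format(grid)))
  img <- RNifti::asNifti(
    data, reference = list(pixdim = c(-1, grid$voxel_size,
                                      rep(1, 8 - 3 - 1))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Published per-patient overlap metrics (FTD PET/pCASL concordance)
#'
#' Per-patient overlap partition percentages and Jaccard indices of
#' hypoperfusion detected by two pCASL variants (single-delay and
#' Hadamard time-encoded "free lunch") against oxygen-15 water PET, for
#' nine patients across FTD subtypes and PSP, under absolute and
#' relative CBF. Useful as a worked example for [summarize_columns()]
#' and as a realistic reference for the ranges these metrics take in
#' patient data.
#'
#' @return data.frame with columns `patient`, `modality` (`flte`/`sd`),
#'   `scale` (`absolute`/`relative`), `overlap`, `adjacent`, `isolated`
#'   (percent) and `jaccard`.
#' @export
ftd_overlap_metrics <- function() {
  path <- system.file("extdata", "ftd_overlap_metrics.csv",
                      package = "perfcon", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort manifest
#'
#' A manifest lists one subject per row with columns `subject_id`,
#' `role` (`control` or `patient`), optional `subtype`, and file paths
#' per modality. Any case-control run needs at least two controls and
#' unique subject ids.
#'
#' @param path CSV path.
#' @return data.frame of class `cohort_manifest`.
#' @export
read_cohort_manifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "role")
  if (!all(req %in% colnames(mf)))
    stop("manifest needs columns subject_id and role")
  if (anyDuplicated(mf$subject_id)) stop("subject_id values must be unique")
  if (!all(mf$role %in% c("control", "patient")))
    stop("role must be 'control' or 'patient'")
  if (sum(mf$role == "control") < 2L)
    stop("need at least 2 controls")
  class(mf) <- c("cohort_manifest", class(mf))
  mf
}

#' Default run configuration for the simulation pipeline
#'
#' Returns the configuration [run_pipeline()] consumes, with the study
#' conditions as defaults: a 2 mm isotropic 64 x 64 x 48 grid, the
#' 37-frame PET schedule, single-delay pCASL at LD 1800 / PLD 2000 ms,
#' the N = 8 free-lunch Hadamard scheme (2000 ms + 6 x 250 ms sub-boli,
#' final PLD 200 ms), GM/WM CBF 60/20 ml/100 g/min, ATT 700-1700 ms, a
#' 10% between-subject SD on global CBF, alpha 0.05, a 10 mm
#' sphere-equivalent cluster extent and 26-connectivity. Override any
#' element by passing replacements in `...`.
#'
#' @param ... Named overrides of top-level elements.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(shape = c(64L, 64L, 48L), voxel_size = c(2, 2, 2)),
    gm_cbf = 60, wm_cbf = 20,
    att_range = c(700, 1700),
    subject_cbf_cv = 0.10,
    n_controls = 5,
    patients = list(
      list(id = "patient01",
           lesions = list(list(center = c(40, 90, 48), radius = 12,
                               cbf_reduction = 0.5)))),
    aif = list(peak_time = 30, peak_value = 30, shape = 3),
    pet = list(noise_sd = 0, fwhm = 6, integration_time = 300),
    asl = list(label_duration = 1800, post_label_delay = 2000,
               n_pairs = 16, noise_sd = 0, fwhm = 8),
    te = list(n_encode = 8L,
              sub_bolus_durations = c(2000, rep(250, 6)),
              final_pld = 200),
    constants = list(lambda_partition = 0.9, t1_blood = 1650,
                     labeling_efficiency = 0.85, brain_density = 1.05),
    background_suppression_factor = 0.83,
    alpha = 0.05, sphere_diameter_mm = 10, connectivity = 26,
    modalities = c("pet", "asl_sd"),
    seed = 1)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$grid$shape) == 3L)
  if (cfg$pet$integration_time <= 0)
    stop("integration_time must be > 0")
  n <- cfg$te$n_encode
  if (bitwAnd(as.integer(n), as.integer(n) - 1L) != 0L)
    stop("te$n_encode must be a power of 2")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$n_controls < 2) stop("need at least 2 controls")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in .json, .yaml or .yml.
#' @return A validated `run_config` (unspecified fields take the
#'   [default_config()] values).
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else stop("config must be .json, .yaml or .yml")
  do.call(default_config, raw)
}
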