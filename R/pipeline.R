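# Pipeline wiring: named resolution profiles, YAML run configs, staged
# artifact directories with reproducibility manifests, and a single
# dispatch function the command-line wrapper calls.

#' Resolution profiles
#'
#' Named working grids: `"full"` is the clinical working resolution
#' (112 x 112 x 40), `"reduced"` a half-scale profile (56 x 56 x 16) for
#' fast experimentation, and `"mini"` a small grid (32 x 32 x 8) for
#' smoke tests. Every profile is divisible by 8 along each axis, as the
#' three pooling stages require.
#'
#' @param profile profile name or an explicit integer vector of 3.
#' @return integer vector of 3.
#' @export
resolve_grid <- function(profile = "full") {
  if (is.numeric(profile)) {
    gs <- as.integer(profile)
    if (length(gs) != 3L) stop("explicit grid must have 3 dimensions")
    return(gs)
  }
  switch(match.arg(profile, c("full", "reduced", "mini")),
         full = c(112L, 112L, 40L),
         reduced = c(56L, 56L, 16L),
         mini = c(32L, 32L, 8L))
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("`config` must be a named list or a YAML file path")
}

write_manifest <- function(dir, command, config) {
  cfg_yaml <- yaml::as.yaml(config)
  manifest <- list(command = command,
                   config = config,
                   config_md5 = {
                     tf <- tempfile(fileext = ".yaml")
                     writeLines(cfg_yaml, tf)
                     on.exit(unlink(tf))
                     unname(tools::md5sum(tf))
                   },
                   package_version =
                     as.character(utils::packageVersion("cranionet")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_keys <- function(config, keys, command) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    stop(sprintf("invalid config for `%s`: missing keys %s", command,
                 paste(missing, collapse = ", ")))
}

load_pair_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^intact_.*\\.nii", full.names = TRUE))
  if (!length(files)) stop("no training pairs found in ", dir)
  meta_path <- file.path(dir, "defects.csv")
  meta <- if (file.exists(meta_path)) utils::read.csv(meta_path) else NULL
  lapply(seq_along(files), function(i) {
    f <- files[i]
    idx <- sub("^intact_", "", basename(f))
    intact <- read_volume(f)
    mask_vol <- read_volume(file.path(dir, paste0("mask_", idx)))
    pair <- apply_defect(intact, mask_vol)
    if (!is.null(meta) && i <= nrow(meta)) {
      gs <- dim(as_values(mask_vol))
      mid <- (gs[1] - 1) / 2
      occ_x <- which(apply(as_values(mask_vol), 1, sum) > 0) - 1
      pair$mask <- structure(list(values = mask_vol,
                                  family = meta$family[i], params = NULL,
                                  seed = NA_integer_,
                                  crosses_midline =
                                    any(occ_x <= mid) && any(occ_x >= mid)),
                             class = "defect_mask")
    }
    pair
  })
}

#' Run one pipeline stage
#'
#' Thin dispatcher over the package's functions; each stage reads and
#' writes NIfTI/CSV/RDS artifacts in a directory together with a
#' `manifest.json` (command, config, config hash, versions) sufficient to
#' regenerate it deterministically.
#'
#' Commands and their config keys:
#' \describe{
#'   \item{simulate}{`n`, `seed`, `out`; optional `profile`.}
#'   \item{preprocess}{`input` (NIfTI of HU intensities), `out`; optional
#'     `lo`, `hi`, `shape`.}
#'   \item{make_defects}{`cohort` (simulate output dir), `seed`, `out`;
#'     optional `fraction_lo`, `fraction_hi`, `families`.}
#'   \item{train}{`pairs` (make_defects output dir), `out` (checkpoint
#'     path); optional `epochs`, `batch_size`, `validation_split`,
#'     `seed`.}
#'   \item{complete}{`input` (defective NIfTI), `checkpoint` or
#'     `oracle` (+ `intact` for the identity oracle), `out`; optional
#'     `threshold`, `stl`.}
#'   \item{evaluate}{`pairs`, `checkpoint` or `oracle`, `out`; optional
#'     `threshold`.}
#'   \item{capability}{`cohort`, `checkpoint` or `oracle`, `seed`, `out`.}
#' }
#'
#' @param command one of `simulate`, `preprocess`, `make_defects`,
#'   `train`, `complete`, `evaluate`, `capability`.
#' @param config named list or YAML file path.
#' @return invisibly, a list of produced artifact paths.
#' @export
run_stage <- function(command, config) {
  command <- match.arg(command,
                       c("simulate", "preprocess", "make_defects", "train",
                         "complete", "evaluate", "capability"))
  cfg <- read_config(config)
  out <- switch(command,
    simulate = stage_simulate(cfg),
    preprocess = stage_preprocess(cfg),
    make_defects = stage_make_defects(cfg),
    train = stage_train(cfg),
    complete = stage_complete(cfg),
    evaluate = stage_evaluate(cfg),
    capability = stage_capability(cfg))
  invisible(out)
}

stage_simulate <- function(cfg) {
  require_keys(cfg, c("n", "seed", "out"), "simulate")
  gs <- resolve_grid(cfg$profile %||% "full")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg$n, seed = cfg$seed, grid_shape = gs)
  paths <- vapply(seq_along(cohort), function(i) {
    p <- file.path(cfg$out, sprintf("phantom_%04d.nii.gz", i))
    write_volume(cohort[[i]], p)
    p
  }, character(1))
  write_manifest(cfg$out, "simulate", cfg)
  list(dir = cfg$out, volumes = paths)
}

stage_preprocess <- function(cfg) {
  require_keys(cfg, c("input", "out"), "preprocess")
  hu <- read_volume_raw(cfg$input)
  bone <- threshold_hu(hu, cfg$lo %||% 1200, cfg$hi %||% 1817)
  shape <- as.integer(cfg$shape %||% c(112, 112, 40))
  model <- crop_and_downsample(bone, shape)
  dir.create(dirname(cfg$out), recursive = TRUE, showWarnings = FALSE)
  write_volume(model, cfg$out)
  list(out = cfg$out)
}

# intensity volumes bypass the [0,1] occupancy validation
read_volume_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
  hu_volume(array(as.numeric(img), dim(img)[1:3]), sp)
}

stage_make_defects <- function(cfg) {
  require_keys(cfg, c("cohort", "seed", "out"), "make_defects")
  files <- sort(list.files(cfg$cohort, pattern = "^phantom_.*\\.nii",
                           full.names = TRUE))
  if (!length(files)) stop("no phantoms found in ", cfg$cohort)
  cohort <- lapply(files, read_volume)
  rng <- c(cfg$fraction_lo %||% 0.05, cfg$fraction_hi %||% 0.35)
  fams <- cfg$families %||% defect_families()
  pairs <- make_training_pairs(cohort, cfg$seed, rng, fams)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(case = seq_along(pairs),
                     family = vapply(pairs, function(p) p$mask$family,
                                     character(1)),
                     defect_fraction = vapply(pairs, defect_fraction,
                                              numeric(1)))
  for (i in seq_along(pairs)) {
    write_volume(pairs[[i]]$intact,
                 file.path(cfg$out, sprintf("intact_%04d.nii.gz", i)))
    write_volume(pairs[[i]]$mask$values,
                 file.path(cfg$out, sprintf("mask_%04d.nii.gz", i)))
  }
  write.csv(meta, file.path(cfg$out, "defects.csv"), row.names = FALSE)
  write_manifest(cfg$out, "make_defects", cfg)
  list(dir = cfg$out, n = length(pairs))
}

stage_train <- function(cfg) {
  require_keys(cfg, c("pairs", "out"), "train")
  pairs <- load_pair_dir(cfg$pairs)
  ctrl <- cranionet_control(
    epochs = cfg$epochs %||% 60L,
    batch_size = cfg$batch_size %||% 10L,
    validation_split = cfg$validation_split %||% 0.1,
    seed = cfg$seed %||% 1L,
    verbose = isTRUE(cfg$verbose))
  net <- cranionet(pairs, control = ctrl)
  dir.create(dirname(cfg$out), recursive = TRUE, showWarnings = FALSE)
  save_network(net, cfg$out)
  write.csv(net$history,
            paste0(sub("\\.rds$", "", cfg$out), "_history.csv"),
            row.names = FALSE)
  list(checkpoint = cfg$out)
}

resolve_stage_predictor <- function(cfg) {
  if (!is.null(cfg$checkpoint)) load_network(cfg$checkpoint)
  else if (!is.null(cfg$oracle)) cfg$oracle
  else stop("config needs either `checkpoint` or `oracle`")
}

stage_complete <- function(cfg) {
  require_keys(cfg, c("input", "out"), "complete")
  defective <- read_volume(cfg$input)
  pred <- resolve_stage_predictor(cfg)
  completed <- if (inherits(pred, "cranionet")) {
    binarize(forward(pred, defective), cfg$threshold %||% 0.5)
  } else if (identical(pred, "identity")) {
    if (is.null(cfg$intact))
      stop("the identity oracle needs `intact` in the config")
    read_volume(cfg$intact)
  } else defective
  implant <- extract_implant(completed, defective,
                             provenance = list(checkpoint = cfg$checkpoint,
                                               threshold = cfg$threshold %||% 0.5))
  dir.create(dirname(cfg$out), recursive = TRUE, showWarnings = FALSE)
  write_volume(implant$volume, cfg$out)
  if (!is.null(cfg$stl) && voxel_count(implant$volume) > 0)
    export_mesh(implant, cfg$stl)
  list(implant = cfg$out)
}

stage_evaluate <- function(cfg) {
  require_keys(cfg, c("pairs", "out"), "evaluate")
  pred <- resolve_stage_predictor(cfg)
  pairs <- load_pair_dir(cfg$pairs)
  ev <- evaluate_pairs(pred, pairs, cfg$threshold %||% 0.5)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(ev$reports, file.path(cfg$out, "report.csv"),
            row.names = FALSE)
  jsonlite::write_json(ev$summary[c("mean_r", "max_r", "n")],
                       file.path(cfg$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg$out, "evaluate", cfg)
  list(report = file.path(cfg$out, "report.csv"), mean_r = ev$summary$mean_r)
}

stage_capability <- function(cfg) {
  require_keys(cfg, c("cohort", "seed", "out"), "capability")
  pred <- resolve_stage_predictor(cfg)
  files <- sort(list.files(cfg$cohort, pattern = "^phantom_.*\\.nii",
                           full.names = TRUE))
  phantoms <- lapply(files, read_volume)
  cc <- capability_curve(pred, phantoms, seed = cfg$seed)
  dir.create(dirname(cfg$out), recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(cc), cfg$out, row.names = FALSE)
  list(curve = cfg$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
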