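#' Run the full anti-aliasing workflow from one configuration
#'
#' Executes the requested stages in order — \code{simulate} (phantom),
#' \code{wrap} (venc reduction with ground truth), \code{conventional}
#' (baseline detection/correction), \code{cnn} (train on auxiliary
#' phantoms, then predict and correct), \code{evaluate} (Dice, Hausdorff,
#' in-vessel counts), \code{flow} (plane flow + Bland-Altman against the
#' true field) — writing every intermediate with an MD5 content digest and
#' the resolved configuration. All randomness flows from the single
#' \code{seed}, so identical configurations reproduce identical reports.
#'
#' @param config nested list (or path to a YAML file with the same
#'   structure): \code{seed}, \code{out_dir}, \code{stages} (character
#'   vector), \code{phantom} (arguments of [phantom_spec()]),
#'   \code{wrap} (\code{venc_fraction}, plus \code{allow_out_of_range} to
#'   permit fractions outside the 0.40-0.70 training range),
#'   \code{conventional} (arguments of [jump_params()]), \code{cnn}
#'   (arguments of [cnn_config()] plus \code{n_training_phantoms}).
#' @return A report list (also written as \code{report.json} in
#'   \code{out_dir}) with per-stage results and file digests.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  report <- list(config = cfg, stages = list(), digests = list())
  ok_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  spec <- do.call(phantom_spec, c(cfg$phantom, list(seed = cfg$seed)))
  phantom <- ok_stage("simulate", generate_phantom(spec))
  if ("simulate" %in% stages) {
    write_field(phantom$field, file.path(cfg$out_dir, "phantom"))
    write_mask(phantom$vessel, file.path(cfg$out_dir, "vessel.nii.gz"))
    report$stages$simulate <- list(
      n_vessel_voxels = sum(phantom$vessel),
      peak_speed_cms = max(abs(phantom$truth$values)))
  }

  wrapped <- NULL
  if (any(c("wrap", "conventional", "cnn", "evaluate", "flow") %in% stages)) {
    ws <- wrap_spec(venc_fraction = cfg$wrap$venc_fraction,
                    venc = phantom$field$venc)
    wrapped <- ok_stage("wrap", wrap_velocity(phantom$field, ws))
    write_field(wrapped$aliased, file.path(cfg$out_dir, "aliased"))
    write_mask(wrapped$truth, file.path(cfg$out_dir, "truth.nii.gz"))
    report$stages$wrap <- list(venc_sim_cms = ws$venc_sim,
                               fraction = ws$fraction,
                               n_aliased = sum(wrapped$truth),
                               n_aliased_in_vessel =
                                 count_aliased(wrapped$truth, phantom$vessel))
  }

  detections <- list()
  if ("conventional" %in% stages) {
    jp <- do.call(jump_params, cfg$conventional)
    conv <- ok_stage("conventional", conventional_unwrap(wrapped$aliased, jp))
    write_field(conv$corrected, file.path(cfg$out_dir, "conventional_corrected"))
    write_mask(conv$detected, file.path(cfg$out_dir, "conventional_mask.nii.gz"))
    detections$conventional <- conv$detected
    report$stages$conventional <- list(
      converged = conv$converged, iterations = conv$iterations,
      n_detected = sum(conv$detected))
  }

  if ("cnn" %in% stages) {
    ccfg <- do.call(cnn_config, c(
      cfg$cnn[setdiff(names(cfg$cnn), "n_training_phantoms")],
      list(seed = cfg$seed)))
    n_train <- cfg$cnn$n_training_phantoms %||% 3L
    train_specs <- lapply(seq_len(n_train), function(i) {
      s <- spec; s$seed <- spec$seed + i; s
    })
    model <- ok_stage("cnn", {
      m <- build_unet(ccfg)
      train_unet(m, lapply(train_specs, generate_phantom), ccfg)
    })
    save_checkpoint(model, file.path(cfg$out_dir, "weights.rds"))
    pred <- predict_unet(model, wrapped$aliased)
    write_mask(pred, file.path(cfg$out_dir, "cnn_mask.nii.gz"))
    corrected <- unwrap_with_mask(wrapped$aliased, pred)
    write_field(corrected, file.path(cfg$out_dir, "cnn_corrected"))
    detections$cnn <- pred
    report$stages$cnn <- list(
      n_detected = sum(pred),
      final_train_dice = utils::tail(model$record$train_dice, 1))
  }

  if ("mask_oracle" %in% stages) detections$mask_oracle <- wrapped$truth

  if ("evaluate" %in% stages) {
    if (length(detections) == 0L)
      stop("pipeline stage `evaluate` failed: no detection stage was run")
    report$stages$evaluate <- lapply(detections, function(mask) {
      hd <- tryCatch(
        hausdorff_mm(mask, wrapped$truth, phantom$field$voxel_spacing,
                     restrict = phantom$vessel),
        error = function(e) list(max_mm = NA_real_))
      list(dice = dice_score(mask, wrapped$truth, phantom$vessel),
           hausdorff_mm = hd$max_mm,
           n_in_vessel = count_aliased(mask, phantom$vessel))
    })
  }

  if ("flow" %in% stages) {
    planes <- phantom_planes(phantom)
    corr_fields <- lapply(detections, function(mask)
      unwrap_with_mask(wrapped$aliased, mask))
    flow_one <- function(field) lapply(planes, function(pl)
      plane_flow(field, pl, phantom$vessel))
    truth_flow <- flow_one(phantom$truth)
    report$stages$flow <- c(
      list(truth = lapply(truth_flow, unclass)),
      lapply(corr_fields, function(f) {
        fr <- flow_one(f)
        ref <- vapply(truth_flow, function(r) r$net_flow_ml, numeric(1))
        tst <- vapply(fr, function(r) r$net_flow_ml, numeric(1))
        agree <- if (length(ref) >= 2) unclass(bland_altman(ref, tst)) else NULL
        list(planes = lapply(fr, unclass), net_flow_agreement = agree)
      }))
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("report\\.json$", files)]
  report$digests <- as.list(tools::md5sum(files))
  names(report$digests) <- basename(files)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  cfg <- list(
    version = config$version %||% 1L,
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir %||% stop("config needs `out_dir`"),
    stages = config$stages %||%
      c("simulate", "wrap", "conventional", "evaluate", "flow"),
    phantom = config$phantom %||% list(),
    wrap = config$wrap %||% list(venc_fraction = 0.5),
    conventional = config$conventional %||% list(),
    cnn = config$cnn %||% list())
  if (cfg$version != 1L) stop("unsupported config schema version: ", cfg$version)
  known <- c("simulate", "wrap", "conventional", "cnn", "mask_oracle",
             "evaluate", "flow")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  fr <- cfg$wrap$venc_fraction %||% 0.5
  if ((fr < 0.40 || fr > 0.70) && !isTRUE(cfg$wrap$allow_out_of_range))
    stop("venc_fraction ", fr, " lies outside the [0.40, 0.70] training ",
         "range; set wrap$allow_out_of_range: true to override")
  cfg$wrap$venc_fraction <- fr
  cfg
}
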