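#' Configure the dense-block U-Net
#'
#' The published training recipe: learning rate 1e-4, dropout 0.1, batch
#' size 1, center crop to \code{[128, 96, Z]}, venc reduced to a uniform
#' random fraction in \code{[0.40, 0.70]} with each dataset wrapped four
#' times per epoch, 400 epochs at full scale. Dense-block internals
#' (encoder depth, layers per block, growth rate) are architecture choices
#' exposed here with moderate defaults; [cnn_tiny_config()] is a small
#' preset for desk-scale experiments on phantoms.
#'
#' @param crop_xy in-plane center-crop target (2 integers); must be
#'   divisible by \code{2^(levels-1)}.
#' @param levels encoder depth (number of resolutions).
#' @param dense_layers_per_block convolutions per dense block.
#' @param growth_rate channels added by each dense-block convolution.
#' @param channels base channel width carried between blocks.
#' @param dropout dropout rate on dense-layer outputs during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size optimizer batch size (1, as published; kept explicit).
#' @param epochs training epochs.
#' @param wraps_per_dataset_per_epoch simulated-aliasing draws per training
#'   field per epoch.
#' @param venc_fraction_range sampling range of the venc reduction.
#' @param seed RNG seed controlling initialization, dropout, and the wrap
#'   draws.
#' @return A \code{cnn_config}.
#' @export
cnn_config <- function(crop_xy = c(128, 96),
                       levels = 4,
                       dense_layers_per_block = 4,
                       growth_rate = 12,
                       channels = 12,
                       dropout = 0.1,
                       learning_rate = 1e-4,
                       batch_size = 1,
                       epochs = 30,
                       wraps_per_dataset_per_epoch = 4,
                       venc_fraction_range = c(0.40, 0.70),
                       seed = 1L) {
  crop_xy <- as.integer(crop_xy)
  stopifnot(length(crop_xy) == 2L, all(crop_xy >= 4L))
  if (any(crop_xy %% 2^(levels - 1) != 0))
    stop("`crop_xy` dims must be divisible by 2^(levels-1)")
  if (!(dropout >= 0 && dropout < 1)) stop("`dropout` must lie in [0, 1)")
  stopifnot(levels >= 1, dense_layers_per_block >= 1, growth_rate >= 1,
            channels >= 1, learning_rate > 0, batch_size >= 1, epochs >= 1,
            wraps_per_dataset_per_epoch >= 1)
  stopifnot(length(venc_fraction_range) == 2L,
            venc_fraction_range[1] > 0, venc_fraction_range[2] < 1)
  structure(list(crop_xy = crop_xy, levels = as.integer(levels),
                 dense_layers_per_block = as.integer(dense_layers_per_block),
                 growth_rate = as.integer(growth_rate),
                 channels = as.integer(channels),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 wraps_per_dataset_per_epoch =
                   as.integer(wraps_per_dataset_per_epoch),
                 venc_fraction_range = as.numeric(venc_fraction_range),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' @rdname cnn_config
#' @param ... overrides passed to [cnn_config()].
#' @export
cnn_tiny_config <- function(...) {
  defaults <- list(crop_xy = c(48, 32), levels = 2,
                   dense_layers_per_block = 1, growth_rate = 4,
                   channels = 4, learning_rate = 1e-3, epochs = 30)
  do.call(cnn_config, modifyList(defaults, list(...)))
}

#' Center-crop (or pad) an in-plane volume
#'
#' Crops a 3-D volume symmetrically about the array center to the target
#' in-plane dims, putting the extra voxel of an odd margin on the low side;
#' volumes smaller than the target are zero-padded symmetrically (extra pad
#' voxel on the low side). The returned offsets and padding allow exact
#' re-embedding with [embed_crop()].
#'
#' @param volume 3-D numeric array.
#' @param crop_xy 2 integers, in-plane target dims.
#' @return List with \code{volume}, \code{offset} (voxels removed on the
#'   low side per in-plane axis), and \code{pad} (low/high padding per
#'   in-plane axis, a 2x2 matrix).
#' @examples
#' center_crop(array(0, c(160, 120, 30)), c(128, 96))$offset
#' @export
center_crop <- function(volume, crop_xy) {
  stopifnot(length(dim(volume)) == 3L, length(crop_xy) == 2L)
  d <- dim(volume)
  offset <- c(0L, 0L)
  pad <- matrix(0L, 2, 2, dimnames = list(c("x", "y"), c("low", "high")))
  out <- volume
  for (ax in 1:2) {
    n <- dim(out)[ax]; target <- crop_xy[ax]
    if (n > target) {
      lo <- as.integer(ceiling((n - target) / 2))
      idx <- seq.int(lo + 1L, lo + target)
      out <- if (ax == 1) out[idx, , , drop = FALSE] else out[, idx, , drop = FALSE]
      offset[ax] <- lo
    } else if (n < target) {
      lo <- as.integer(ceiling((target - n) / 2)); hi <- target - n - lo
      d2 <- dim(out); d2[ax] <- target
      padded <- array(0, d2)
      idx <- seq.int(lo + 1L, lo + n)
      if (ax == 1) padded[idx, , ] <- out else padded[, idx, ] <- out
      out <- padded
      pad[ax, ] <- c(lo, hi)
    }
  }
  list(volume = out, offset = offset, pad = pad)
}

#' @rdname center_crop
#' @param cropped a cropped/padded volume (e.g. a predicted mask volume).
#' @param original_dim the 3-D dims to re-embed into.
#' @param crop_info the list returned by [center_crop()].
#' @details [embed_crop()] inverts the geometry: padded regions are
#'   discarded and cropped-away regions are filled with \code{fill}.
#' @param fill value for voxels outside the crop.
#' @export
embed_crop <- function(cropped, original_dim, crop_info, fill = 0) {
  out <- array(fill, original_dim)
  d <- dim(cropped)
  src <- cropped
  # strip padding first
  for (ax in 1:2) {
    lo <- crop_info$pad[ax, 1]; hi <- crop_info$pad[ax, 2]
    if (lo + hi > 0) {
      idx <- seq.int(lo + 1L, dim(src)[ax] - hi)
      src <- if (ax == 1) src[idx, , , drop = FALSE] else src[, idx, , drop = FALSE]
    }
  }
  ox <- crop_info$offset[1]; oy <- crop_info$offset[2]
  out[ox + seq_len(dim(src)[1]), oy + seq_len(dim(src)[2]), ] <- src
  out
}

#' Build a dense-block U-Net model
#'
#' A 3-D encoder-decoder: each resolution level is a dense block (small
#' convolutions whose outputs are concatenated onto their inputs) followed
#' by a 1x1x1 compression convolution; levels are linked by 2x2 in-plane
#' max pooling and nearest-neighbor upsampling with skip concatenation; a
#' two-channel voxelwise softmax head scores background vs aliased. The
#' untrained head is biased toward background, so a fresh model predicts an
#' empty mask. Identical seeds give identical initial weights.
#'
#' @param config a [cnn_config()].
#' @return An object of class \code{unet_model}.
#' @export
build_unet <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  ptr <- .unet_create(config$levels, config$dense_layers_per_block,
                      config$growth_rate, config$channels, config$dropout,
                      config$seed)
  structure(list(ptr = ptr, config = config, trained = FALSE,
                 record = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> levels:", x$config$levels,
      "| dense layers/block:", x$config$dense_layers_per_block,
      "| growth:", x$config$growth_rate,
      "| parameters:", format(n_params(x), big.mark = ","),
      if (x$trained) "| trained" else "| untrained", "\n")
  invisible(x)
}

#' @rdname build_unet
#' @param model a \code{unet_model}.
#' @export
n_params <- function(model) .unet_n_params(model$ptr)

#' Composite training loss
#'
#' Softmax cross-entropy plus a soft-Dice loss
#' \code{1 - (2 sum(p t) + 1e-5) / (sum(p) + sum(t) + 1e-5)}, the same
#' epsilon convention as the evaluation Dice so empty-truth volumes are
#' well defined.
#'
#' @param prob_fg array/vector of foreground (aliased) probabilities.
#' @param truth congruent binary truth.
#' @return List with \code{ce}, \code{dice_loss}, and \code{loss} (the sum).
#' @export
composite_loss <- function(prob_fg, truth) {
  p <- as.vector(prob_fg); t <- as.numeric(as.logical(truth))
  stopifnot(length(p) == length(t))
  eps <- 1e-5
  ce <- -mean(ifelse(t == 1, log(pmax(p, 1e-12)), log(pmax(1 - p, 1e-12))))
  dice_loss <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  list(ce = ce, dice_loss = dice_loss, loss = ce + dice_loss)
}

# Normalized, cropped per-(frame, direction) sample volumes of a field.
# Normalization by the field's venc maps values into [-1, 1), so one model
# serves all vencs.
field_samples <- function(field, crop_xy) {
  dims <- dim(field$values)
  out <- list()
  for (d in seq_len(dims[5])) for (t in seq_len(dims[4])) {
    vol <- field$values[, , , t, d] / field$venc
    cc <- center_crop(vol, crop_xy)
    out[[length(out) + 1L]] <- list(volume = cc$volume, crop = cc,
                                    frame = t, direction = d)
  }
  out
}

#' Train the U-Net on phantoms with simulated aliasing
#'
#' Per epoch, every training field is wrapped
#' \code{wraps_per_dataset_per_epoch} times at independently drawn uniform
#' venc fractions; every (frame, direction) volume of each wrapped field is
#' one training sample, normalized by its venc and center-cropped. The
#' optimizer takes one Adam step per sample (batch size 1) on the composite
#' loss. All randomness flows from \code{config$seed}.
#'
#' @param model a [build_unet()] model.
#' @param phantoms list of \code{flow_phantom} objects or
#'   [velocity_field()]s with no aliasing (the ground-truth scans).
#' @param config training configuration; defaults to the model's.
#' @param validation optional held-out \code{flow_phantom}/field; when
#'   given, a per-epoch validation Dice at venc fraction 0.5 is recorded.
#' @param verbose print a line per epoch.
#' @return The model (invisibly modified in place via its external
#'   pointer), with \code{$record}: a data frame with one row per epoch
#'   (mean cross-entropy, mean Dice loss, mean training Dice, optional
#'   validation Dice, elapsed seconds).
#' @export
train_unet <- function(model, phantoms, config = model$config,
                       validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  fields <- lapply(phantoms, as_training_field)
  if (length(fields) == 0L) stop("empty training set")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  val_truth <- NULL
  if (!is.null(validation)) {
    vf <- as_training_field(validation)
    vw <- wrap_velocity(vf, wrap_spec(venc_fraction = 0.5, venc = vf$venc))
    val_aliased <- vw$aliased; val_truth <- vw$truth
  }

  rec <- data.frame(epoch = seq_len(config$epochs), ce = NA_real_,
                    dice_loss = NA_real_, train_dice = NA_real_,
                    val_dice = NA_real_, seconds = NA_real_)
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    samples <- list()
    for (f in fields) {
      for (w in seq_len(config$wraps_per_dataset_per_epoch)) {
        frac <- sample_venc_fraction(1, config$venc_fraction_range)
        wr <- wrap_velocity(f, wrap_spec(venc_fraction = frac, venc = f$venc))
        svols <- field_samples(wr$aliased, config$crop_xy)
        for (s in svols) {
          tvol <- center_crop(
            array(wr$truth[, , , s$frame, s$direction] * 1L,
                  dim(wr$truth)[1:3]), config$crop_xy)$volume
          samples[[length(samples) + 1L]] <-
            list(v = s$volume, t = as.integer(tvol != 0))
        }
      }
    }
    ord <- sample.int(length(samples))
    ce_sum <- dl_sum <- dice_sum <- 0
    for (i in ord) {
      s <- samples[[i]]
      st <- .unet_train_step(model$ptr, as.numeric(s$v), s$t,
                             dim(s$v), config$learning_rate)
      ce_sum <- ce_sum + st$ce
      dl_sum <- dl_sum + st$dice_loss
      dice_sum <- dice_sum + st$hard_dice
    }
    n <- length(samples)
    rec$ce[epoch] <- ce_sum / n
    rec$dice_loss[epoch] <- dl_sum / n
    rec$train_dice[epoch] <- dice_sum / n
    if (!is.null(val_truth)) {
      pm <- predict_unet(model, val_aliased)
      rec$val_dice[epoch] <- dice_score(pm, val_truth)
    }
    rec$seconds[epoch] <- proc.time()[["elapsed"]] - t0
    if (verbose)
      message(sprintf(
        "epoch %3d | CE %.4f | dice loss %.4f | train dice %.3f%s | %.1fs",
        epoch, rec$ce[epoch], rec$dice_loss[epoch], rec$train_dice[epoch],
        if (is.na(rec$val_dice[epoch])) ""
        else sprintf(" | val dice %.3f", rec$val_dice[epoch]),
        rec$seconds[epoch]))
  }
  model$trained <- TRUE
  model$record <- rec
  model
}

as_training_field <- function(x) {
  if (inherits(x, "flow_phantom")) return(x$field)
  if (is_velocity_field(x)) return(x)
  stop("training inputs must be flow_phantom or velocity_field objects")
}

#' Predict the aliased-voxel mask for a field
#'
#' Runs the network on every (frame, direction) volume with the same
#' normalization and center crop as training, takes the voxelwise channel
#' argmax, and re-embeds the crops into the full field geometry (regions
#' outside the crop are reported non-aliased).
#'
#' @param model a trained [build_unet()] model.
#' @param field a [velocity_field()]; its venc metadata drives the input
#'   normalization.
#' @return Logical 5-D mask congruent with the field.
#' @export
predict_unet <- function(model, field) {
  stopifnot(inherits(model, "unet_model"))
  if (!is_velocity_field(field) || is.null(field$venc))
    stop("`field` must be a velocity_field with venc metadata")
  dims <- dim(field$values)
  mask <- array(FALSE, dims)
  for (d in seq_len(dims[5])) for (t in seq_len(dims[4])) {
    vol <- field$values[, , , t, d] / field$venc
    cc <- center_crop(vol, model$config$crop_xy)
    out <- .unet_forward(model$ptr, as.numeric(cc$volume), dim(cc$volume))
    pred <- array(out$mask, dim(cc$volume))
    mask[, , , t, d] <- embed_crop(pred, dims[1:3], cc, fill = 0) != 0
  }
  mask
}

#' Save / load a model checkpoint
#'
#' The checkpoint carries the full configuration and all weights, so a
#' loaded model reproduces predictions exactly. Optimizer state is not
#' preserved.
#'
#' @param model a \code{unet_model}.
#' @param path file path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(config = model$config, weights = .unet_get_weights(model$ptr),
               trained = model$trained, record = model$record), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_unet(ck$config)
  .unet_set_weights(model$ptr, ck$weights)
  model$trained <- isTRUE(ck$trained)
  model$record <- ck$record
  model
}
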