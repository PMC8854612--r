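# The 12-layer skip-connected 3D autoencoder with a dilated bottleneck.
#
# Encoder: two plain conv layers with 2x max-pooling after each, then two
# plain conv layers at quarter resolution. Bottleneck: four dilated conv
# layers (rates 2, 4, 8, 16) followed by the third pooling. Decoder: three
# "deconvolution" layers (plain 3x3x3 convs, stride 1) interleaved with
# parameter-free nearest-neighbour 2x up-sampling, and a final sigmoid
# output conv. All convolutions use zero "same" padding, so the channel
# sequence (8,8,4,4, 4,4,4,4, 4,8,8, 1) with biases gives exactly
# 27*C_in*C_out + C_out parameters per layer, 8,269 in total — attainable
# only because the 8 skip connections are additive and add no channels.
#
# Tensors are named "input", "conv1".."conv12", "pool1".."pool3",
# "up1".."up3". A skip edge (src, dst) adds the finished tensor `src`
# element-wise into the tensor `dst` right after `dst` is produced.

default_skips <- function() {
  list(c("pool1", "conv11"), c("pool2", "conv10"), c("conv3", "up1"),
       c("conv3", "conv4"), c("conv4", "conv5"), c("conv5", "conv6"),
       c("conv6", "conv7"), c("conv7", "conv8"))
}

#' Network architecture specification
#'
#' Describes the 12-conv-layer skip-connected dilated autoencoder. The
#' defaults realize the reference architecture: channel sequence
#' `(8,8,4,4, 4,4,4,4, 4,8,8, 1)`, dilation sequence
#' `(1,1,1,1, 2,4,8,16, 1,1,1, 1)`, 3x3x3 kernels, stride 1, ReLU
#' activations except a final sigmoid, three max-pooling and three
#' up-sampling positions, and eight additive skip connections.
#'
#' @param channels integer vector of 12 output-channel counts.
#' @param dilations integer vector of 12 dilation rates.
#' @param pool_after layer indices after which 2x max-pooling occurs
#'   (exactly 3).
#' @param upsample_after layer indices after which 2x nearest-neighbour
#'   up-sampling occurs (exactly 3).
#' @param skips list of exactly 8 `c(source, destination)` tensor-name
#'   pairs, combined additively.
#' @param in_channels input channel count (1 for binary occupancy).
#' @return an object of class `cranionet_spec`.
#' @export
cranionet_spec <- function(channels = c(8, 8, 4, 4, 4, 4, 4, 4, 4, 8, 8, 1),
                           dilations = c(1, 1, 1, 1, 2, 4, 8, 16, 1, 1, 1, 1),
                           pool_after = c(1, 2, 8),
                           upsample_after = c(9, 10, 11),
                           skips = default_skips(),
                           in_channels = 1L) {
  n <- length(channels)
  if (length(dilations) != n)
    stop("`channels` and `dilations` must have equal length")
  if (any(channels < 1) || any(dilations < 1))
    stop("channel counts and dilations must be positive")
  if (length(pool_after) != 3L || length(upsample_after) != 3L)
    stop("the network has exactly 3 pooling and 3 up-sampling positions")
  if (length(skips) != 8L)
    stop("the network has exactly 8 skip connections, got ", length(skips))
  kinds <- rep("conv3d", n)
  kinds[dilations > 1] <- "dilated_conv3d"
  dec <- setdiff(seq_len(n), seq_len(max(pool_after)))
  kinds[utils::head(dec, -1)] <- "deconv3d"
  kinds[n] <- "output_conv3d"
  spec <- structure(list(
    channels = as.integer(channels), dilations = as.integer(dilations),
    pool_after = as.integer(sort(pool_after)),
    upsample_after = as.integer(sort(upsample_after)),
    skips = skips, in_channels = as.integer(in_channels),
    kinds = kinds,
    activations = c(rep("relu", n - 1), "sigmoid")), class = "cranionet_spec")
  plan_steps(spec)  # validates skip-edge shape compatibility
  spec
}

#' @export
print.cranionet_spec <- function(x, ...) {
  df <- data.frame(type = x$kinds, kernel = "3x3x3", dilation = x$dilations,
                   stride = "1x1x1", channels = x$channels,
                   activation = x$activations)
  cat(sprintf("<cranionet_spec: %d conv layers, %d pool, %d upsample, %d skips>\n",
              length(x$channels), length(x$pool_after),
              length(x$upsample_after), length(x$skips)))
  print(df)
  invisible(x)
}

# Turn a spec into an ordered step plan and per-tensor (level, channels)
# bookkeeping; errors on any skip edge joining incompatible tensors.
plan_steps <- function(spec) {
  nlayer <- length(spec$channels)
  steps <- list()
  info <- list(input = c(level = 0L, channels = spec$in_channels))
  level <- 0L
  prev <- "input"
  npool <- 0L
  nup <- 0L
  for (i in seq_len(nlayer)) {
    nm <- paste0("conv", i)
    steps[[length(steps) + 1L]] <- list(type = "conv", layer = i, name = nm,
                                        input = prev)
    info[[nm]] <- c(level = level, channels = spec$channels[i])
    prev <- nm
    if (i %in% spec$pool_after) {
      npool <- npool + 1L
      level <- level + 1L
      nm <- paste0("pool", npool)
      steps[[length(steps) + 1L]] <- list(type = "pool", name = nm,
                                          input = prev)
      info[[nm]] <- c(level = level, channels = spec$channels[i])
      prev <- nm
    }
    if (i %in% spec$upsample_after) {
      nup <- nup + 1L
      level <- level - 1L
      nm <- paste0("up", nup)
      steps[[length(steps) + 1L]] <- list(type = "up", name = nm,
                                          input = prev)
      info[[nm]] <- c(level = level, channels = spec$channels[i])
      prev <- nm
    }
  }
  for (e in spec$skips) {
    if (!all(e %in% names(info)))
      stop("skip edge references unknown tensor: ",
           paste(e, collapse = " -> "))
    a <- info[[e[1]]]; b <- info[[e[2]]]
    if (a["level"] != b["level"] || a["channels"] != b["channels"])
      stop(sprintf(
        "skip edge %s -> %s joins incompatible tensors (level %d/%d, channels %d/%d)",
        e[1], e[2], a["level"], b["level"], a["channels"], b["channels"]))
  }
  add_into <- lapply(steps, function(s)
    vapply(Filter(function(e) e[2] == s$name, spec$skips),
           function(e) e[1], character(1)))
  # integer encoding of the same plan for the fused C++ training pass:
  # tensor 1 is the input, step i writes tensor i + 1
  tensor_id <- stats::setNames(seq_len(length(steps) + 1L),
                               c("input", vapply(steps, `[[`, "", "name")))
  cplan <- list(
    step_type = vapply(steps, function(s)
      switch(s$type, conv = 0L, pool = 1L, up = 2L), integer(1)),
    step_layer = vapply(steps, function(s)
      if (is.null(s$layer)) 0L else as.integer(s$layer), integer(1)),
    step_input = unname(tensor_id[vapply(steps, `[[`, "", "input")]),
    adds = lapply(add_into, function(a) as.integer(unname(tensor_id[a]))))
  list(steps = steps, info = info, add_into = add_into, cplan = cplan,
       max_level = max(vapply(info, function(x) x["level"], integer(1))))
}

#' Build a network from a specification
#'
#' Realizes the layer list with seeded Glorot-uniform weight
#' initialization and zero biases. Construction fails with an explicit
#' message if any skip edge joins tensors of different resolution level or
#' channel count, or if the skip/pool/up-sample counts deviate from the
#' architecture's 8/3/3.
#'
#' @param spec a [cranionet_spec()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `cranionet` (untrained).
#' @export
build_network <- function(spec = cranionet_spec(), seed = 1L) {
  if (!inherits(spec, "cranionet_spec")) stop("`spec` must be a cranionet_spec")
  plan <- plan_steps(spec)
  cin <- c(spec$in_channels, utils::head(spec$channels, -1))
  weights <- with_seed(seed, lapply(seq_along(spec$channels), function(i) {
    fan_in <- 27 * cin[i]
    fan_out <- 27 * spec$channels[i]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = matrix(stats::runif(fan_in * spec$channels[i], -lim, lim),
                    nrow = fan_in, ncol = spec$channels[i]),
         b = rep(0, spec$channels[i]))
  }))
  structure(list(spec = spec, weights = weights, seed = as.integer(seed),
                 plan = plan, trained = FALSE, history = NULL,
                 control = NULL),
            class = "cranionet")
}

#' Count trainable parameters
#'
#' @param net a `cranionet`.
#' @return total number of trainable scalars (weights plus biases).
#' @export
count_parameters <- function(net) {
  sum(layer_parameter_counts(net))
}

#' @rdname count_parameters
#' @return `layer_parameter_counts` returns the per-layer counts, each
#'   equal to `27 * C_in * C_out + C_out`.
#' @export
layer_parameter_counts <- function(net) {
  vapply(net$weights, function(w) length(w$W) + length(w$b), numeric(1))
}

#' Effective receptive field of a dilated kernel
#'
#' A kernel of odd size k with dilation rate d spans
#' `d * (k - 1) + 1` voxels per axis while keeping k^3 weights; e.g. a
#' 3x3x3 kernel at dilation 2 has the field of view of a 5x5x5 kernel
#' with only 27 parameters.
#'
#' @param kernel odd kernel size per axis.
#' @param dilation positive dilation rate.
#' @return the effective field width per axis (odd integer).
#' @export
effective_receptive_field <- function(kernel, dilation) {
  if (kernel < 1 || kernel %% 2 != 1) stop("`kernel` must be odd and >= 1")
  if (dilation < 1) stop("`dilation` must be >= 1")
  as.integer(dilation * (kernel - 1) + 1)
}

check_input_shape <- function(net, d) {
  div <- 2^net$plan$max_level
  if (any(d %% div != 0))
    stop(sprintf(
      "input shape %s must be divisible by %d along every axis (%d pooling levels)",
      paste(d, collapse = "x"), div, net$plan$max_level))
}

activate <- function(z, act) {
  if (act == "relu") {
    z[z < 0] <- 0
    z
  } else 1 / (1 + exp(-z))
}

# Full forward pass; returns an environment with every named tensor, its
# dims, pooling argmax indices and pre-skip activations (for backprop).
cn_forward_cache <- function(net, x, final_linear = FALSE) {
  d <- dim(x)
  check_input_shape(net, d)
  spec <- net$spec
  cache <- new.env(parent = emptyenv())
  cache$tensors <- list(input = as.numeric(x))
  cache$dims <- list(input = c(d, spec$in_channels))
  cache$acts <- list()
  cache$argmax <- list()
  nlayer <- length(spec$channels)
  plan <- net$plan
  for (si in seq_along(plan$steps)) {
    s <- plan$steps[[si]]
    xin <- cache$tensors[[s$input]]
    din <- cache$dims[[s$input]]
    if (s$type == "conv") {
      i <- s$layer
      z <- .cn_conv3d_fwd(xin, as.integer(din), net$weights[[i]]$W,
                          net$weights[[i]]$b, spec$dilations[i])
      a <- if (i == nlayer && final_linear) z
           else activate(z, spec$activations[i])
      cache$acts[[s$name]] <- a
      out <- a
      dout <- c(din[1:3], spec$channels[i])
    } else if (s$type == "pool") {
      mp <- .cn_maxpool_fwd(xin, as.integer(din))
      out <- mp$y
      cache$argmax[[s$name]] <- mp$argmax
      dout <- c(din[1:3] %/% 2L, din[4])
    } else {
      out <- .cn_upsample_fwd(xin, as.integer(din))
      dout <- c(din[1:3] * 2L, din[4])
    }
    for (src in plan$add_into[[si]]) out <- out + cache$tensors[[src]]
    cache$tensors[[s$name]] <- out
    cache$dims[[s$name]] <- dout
  }
  cache$output_name <- plan$steps[[length(plan$steps)]]$name
  cache
}

# Backward pass from a gradient seeded at the final layer's
# pre-activation (delta = dLoss/dz12); returns per-layer gW, gb.
cn_backward <- function(net, cache, delta_out) {
  spec <- net$spec
  plan <- net$plan
  nlayer <- length(spec$channels)
  grads <- list()
  grads[[cache$output_name]] <- delta_out
  gW <- vector("list", nlayer)
  gb <- vector("list", nlayer)
  for (si in rev(seq_along(plan$steps))) {
    s <- plan$steps[[si]]
    g <- grads[[s$name]]
    if (is.null(g)) next
    for (src in plan$add_into[[si]])
      grads[[src]] <- if (is.null(grads[[src]])) g else grads[[src]] + g
    din <- cache$dims[[s$input]]
    if (s$type == "conv") {
      i <- s$layer
      gz <- if (i == nlayer) g else {
        act <- spec$activations[i]
        a <- cache$acts[[s$name]]
        if (act == "relu") g * (a > 0) else g * a * (1 - a)
      }
      want_gx <- s$input != "input"
      bw <- .cn_conv3d_bwd(cache$tensors[[s$input]], as.integer(din),
                           net$weights[[i]]$W, gz, spec$dilations[i],
                           want_gx)
      gW[[i]] <- bw$gW
      gb[[i]] <- as.numeric(bw$gb)
      if (want_gx)
        grads[[s$input]] <- if (is.null(grads[[s$input]])) bw$gx
                            else grads[[s$input]] + bw$gx
    } else if (s$type == "pool") {
      gx <- .cn_maxpool_bwd(g, cache$argmax[[s$name]], prod(din))
      grads[[s$input]] <- if (is.null(grads[[s$input]])) gx
                          else grads[[s$input]] + gx
    } else {
      gx <- .cn_upsample_bwd(g, as.integer(cache$dims[[s$name]]))
      grads[[s$input]] <- if (is.null(grads[[s$input]])) gx
                          else grads[[s$input]] + gx
    }
    grads[[s$name]] <- NULL
  }
  list(gW = gW, gb = gb)
}

#' Run the network on a defective volume
#'
#' Forward pass: input values in \[0, 1\], shape divisible by 8 along
#' every axis (three 2x poolings); output a probabilistic volume of the
#' same shape with values in \[0, 1\] (sigmoid final activation). The
#' pass is deterministic — there is no dropout or batch normalization.
#'
#' @param net a `cranionet`.
#' @param defective a `voxel_volume` (or 3D array) with values in \[0, 1\].
#' @return a probabilistic `voxel_volume` of the same shape.
#' @export
forward <- function(net, defective) {
  x <- as_values(defective)
  cache <- cn_forward_cache(net, x)
  out <- cache$tensors[[cache$output_name]]
  voxel_volume(array(out, dim(x)), vox_spacing(defective))
}

#' Inspect intermediate feature maps
#'
#' Returns the named intermediate activations of a forward pass. Stage
#' `"pre_dilation"` is the tensor entering the dilated bottleneck (4 maps
#' at quarter resolution, e.g. 28 x 28 x 10 for a 112 x 112 x 40 input);
#' `"post_dilation_pooled"` is the tensor entering the decoder (4 maps at
#' eighth resolution, e.g. 14 x 14 x 5). Any tensor name
#' (`"conv1"`..`"conv12"`, `"pool1"`..`"pool3"`, `"up1"`..`"up3"`) is also
#' accepted.
#'
#' @param net a `cranionet`.
#' @param input a `voxel_volume` or 3D array.
#' @param stage stage name (see details).
#' @return a list of 3D arrays, one per channel.
#' @export
feature_maps <- function(net, input, stage = "pre_dilation") {
  x <- as_values(input)
  cache <- cn_forward_cache(net, x)
  first_dil <- which(net$spec$dilations > 1)[1]
  np <- sum(net$spec$pool_after < first_dil)
  aliases <- c(pre_dilation = net$plan$steps[[
    which(vapply(net$plan$steps, function(s)
      s$type == "conv" && identical(s$layer, first_dil), logical(1)))]]$input,
    post_dilation_pooled = paste0("pool", length(net$spec$pool_after)))
  nm <- if (stage %in% names(aliases)) aliases[[stage]] else stage
  if (!nm %in% names(cache$tensors))
    stop("unknown stage '", stage, "'; available: ",
         paste(c(names(aliases), setdiff(names(cache$tensors), "input")),
               collapse = ", "))
  v <- cache$tensors[[nm]]
  dm <- cache$dims[[nm]]
  lapply(seq_len(dm[4]), function(c)
    array(v[((c - 1) * prod(dm[1:3]) + 1):(c * prod(dm[1:3]))], dm[1:3]))
}

#' @export
print.cranionet <- function(x, ...) {
  cat(sprintf("<cranionet: 12-layer skip-connected dilated 3D autoencoder, %d parameters%s>\n",
              count_parameters(x),
              if (x$trained) sprintf(", trained (%d epochs)",
                                     nrow(x$history)) else ", untrained"))
  invisible(x)
}

#' @export
summary.cranionet <- function(object, ...) {
  cat("Skip-connected dilated 3D autoencoder\n")
  cin <- c(object$spec$in_channels, utils::head(object$spec$channels, -1))
  df <- data.frame(layer = seq_along(object$spec$channels),
                   type = object$spec$kinds,
                   dilation = object$spec$dilations,
                   c_in = cin, c_out = object$spec$channels,
                   params = layer_parameter_counts(object))
  print(df, row.names = FALSE)
  cat(sprintf("Total trainable parameters: %d\n", count_parameters(object)))
  cat(sprintf("Skip connections (additive): %s\n",
              paste(vapply(object$spec$skips,
                           function(e) paste(e, collapse = "->"),
                           character(1)), collapse = ", ")))
  if (object$trained) {
    cat("\nTraining history (last epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.cranionet <- function(object, ...) {
  out <- unlist(lapply(seq_along(object$weights), function(i)
    c(stats::setNames(as.numeric(object$weights[[i]]$W),
                      sprintf("conv%d.W%d", i,
                              seq_along(object$weights[[i]]$W))),
      stats::setNames(object$weights[[i]]$b,
                      sprintf("conv%d.b%d", i,
                              seq_along(object$weights[[i]]$b))))))
  out
}

#' Predict a completed cranium
#'
#' @param object a `cranionet`.
#' @param newdata a `voxel_volume`, `training_pair` (its defective member
#'   is used), or a list of either.
#' @param type `"prob"` for the sigmoid output, `"binary"` for a
#'   thresholded volume.
#' @param threshold binarization threshold for `type = "binary"`.
#' @param ... unused.
#' @return a `voxel_volume`, or a list of them if `newdata` is a list.
#' @export
predict.cranionet <- function(object, newdata, type = c("prob", "binary"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(nd) {
    vol <- if (inherits(nd, "training_pair")) nd$defective else nd
    p <- forward(object, vol)
    if (type == "binary") binarize(p, threshold) else p
  }
  if (is.list(newdata) && !inherits(newdata, c("voxel_volume", "training_pair")))
    lapply(newdata, one)
  else one(newdata)
}

#' Serialize an architecture specification
#'
#' Round-trips a [cranionet_spec()] through a plain JSON or YAML config
#' file (chosen by the file extension), so architectures can be stored,
#' edited and rebuilt outside R.
#'
#' @param spec a `cranionet_spec`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_spec` returns a validated `cranionet_spec`.
#' @export
write_spec <- function(spec, path) {
  if (!inherits(spec, "cranionet_spec")) stop("`spec` must be a cranionet_spec")
  payload <- list(channels = spec$channels, dilations = spec$dilations,
                  pool_after = spec$pool_after,
                  upsample_after = spec$upsample_after,
                  skips = lapply(spec$skips, as.character),
                  in_channels = spec$in_channels)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(payload, path)
  else jsonlite::write_json(payload, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyMatrix = FALSE)
  cranionet_spec(channels = unlist(payload$channels),
                 dilations = unlist(payload$dilations),
                 pool_after = unlist(payload$pool_after),
                 upsample_after = unlist(payload$upsample_after),
                 skips = lapply(payload$skips, unlist),
                 in_channels = unlist(payload$in_channels))
}

#' Save / load a trained network checkpoint
#'
#' Single-file checkpoint embedding the architecture spec, weights,
#' training history and seeds; round-trips to bitwise-identical forward
#' outputs.
#'
#' @param net a `cranionet`.
#' @param path file path (`.rds`).
#' @return `load_network` returns the `cranionet`.
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "cranionet")) stop("not a cranionet checkpoint: ", path)
  net
}
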