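# Supervised training: voxelwise binary cross entropy, Adadelta updates,
# mini-batches of defective -> intact pairs, seeded shuffling and a
# random validation split.

#' Split a dataset into training and validation parts
#'
#' Disjoint and exhaustive random split; the validation part holds
#' `round(split * n)` elements. With `groups` supplied (e.g. the source
#' model of each augmented variant), whole groups are assigned to the
#' validation side, preventing leakage of near-duplicate variants across
#' the split.
#'
#' @param pairs a list (or vector) of cases.
#' @param split validation fraction in (0, 1).
#' @param seed integer seed.
#' @param groups optional vector of group ids, one per case.
#' @return list with elements `train` and `validation` (same container
#'   type as `pairs`), plus an attribute `"indices"`.
#' @export
split_dataset <- function(pairs, split = 0.1, seed = 1L, groups = NULL) {
  n <- length(pairs)
  if (n < 2L) stop("need at least 2 cases to split")
  if (split <= 0 || split >= 1) stop("`split` must lie in (0, 1)")
  nval <- round(split * n)
  if (nval < 1L || nval >= n)
    stop("split yields an empty partition for n = ", n)
  val_idx <- with_seed(seed, {
    if (is.null(groups)) {
      sort(sample.int(n, nval))
    } else {
      if (length(groups) != n) stop("`groups` must have one id per case")
      gs <- sample(unique(groups))
      sizes <- cumsum(table(groups)[as.character(gs)])
      k <- which.min(abs(sizes - nval))
      sort(which(groups %in% gs[seq_len(k)]))
    }
  })
  out <- list(train = pairs[-val_idx], validation = pairs[val_idx])
  attr(out, "indices") <- val_idx
  out
}

#' Voxelwise binary cross entropy
#'
#' Mean over voxels of `-(t log p + (1 - t) log(1 - p))`, with
#' probabilities clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param pred probabilistic `voxel_volume` or array in \[0, 1\].
#' @param target binary `voxel_volume` or array of the same shape.
#' @param eps clamping epsilon.
#' @return a nonnegative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  p <- as_values(pred)
  t <- as_values(target)
  if (!identical(dim(p), dim(t))) stop("shapes must match")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param batch_size mini-batch size (default 10).
#' @param validation_split fraction held out for validation (default 0.1);
#'   0 disables validation (e.g. single-pair overfitting checks).
#' @param seed integer seed for the split, the shuffling and (through
#'   [build_network()]) weight initialization.
#' @param rho Adadelta decay rate.
#' @param epsilon Adadelta conditioning constant.
#' @param patience early-stopping patience in epochs on the validation
#'   loss (`Inf` disables early stopping).
#' @param min_delta minimum validation-loss improvement that resets
#'   patience.
#' @param calibrate_bias initialize the output layer's bias to the
#'   empirical log-odds of voxel occupancy in the training targets (a
#'   standard calibration for imbalanced voxel grids; applied only to a
#'   freshly built, untrained network).
#' @param checkpoint_path optional path; the current best network is
#'   saved there every `checkpoint_cadence` epochs.
#' @param checkpoint_cadence epochs between checkpoints (0 = only at the
#'   end, if a path is given).
#' @param groups optional group ids for a leakage-free split (see
#'   [split_dataset()]).
#' @param verbose print per-epoch losses.
#' @return a list of class `cranionet_control`.
#' @export
cranionet_control <- function(epochs = 60L, batch_size = 10L,
                              validation_split = 0.1, seed = 1L,
                              rho = 0.95, epsilon = 1e-6,
                              patience = Inf, min_delta = 0,
                              calibrate_bias = TRUE,
                              checkpoint_path = NULL,
                              checkpoint_cadence = 0L,
                              groups = NULL, verbose = FALSE) {
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (validation_split < 0 || validation_split >= 1)
    stop("`validation_split` must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split,
                 seed = as.integer(seed), rho = rho, epsilon = epsilon,
                 patience = patience, min_delta = min_delta,
                 calibrate_bias = isTRUE(calibrate_bias),
                 checkpoint_path = checkpoint_path,
                 checkpoint_cadence = as.integer(checkpoint_cadence),
                 groups = groups, verbose = isTRUE(verbose)),
            class = "cranionet_control")
}

# one forward/backward pass (fused C++ path); returns loss, per-layer grads
grad_one <- function(net, pair) {
  x <- as_values(pair$defective)
  check_input_shape(net, dim(x))
  cp <- net$plan$cplan
  out <- .cn_train_pass(lapply(net$weights, `[[`, "W"),
                        lapply(net$weights, `[[`, "b"),
                        net$spec$dilations, cp$step_type, cp$step_layer,
                        cp$step_input, cp$adds,
                        as.numeric(x),
                        as.integer(c(dim(x), net$spec$in_channels)),
                        as.numeric(as_values(pair$intact)))
  out$gb <- lapply(out$gb, as.numeric)
  out
}

# reference implementation through the R-level engine; used to cross-check
# the fused pass in the test suite
grad_one_ref <- function(net, pair, eps = 1e-7) {
  x <- as_values(pair$defective)
  t <- as_values(pair$intact)
  cache <- cn_forward_cache(net, x, final_linear = TRUE)
  z <- cache$tensors[[cache$output_name]]
  p <- 1 / (1 + exp(-z))
  n <- length(p)
  pc <- pmin(pmax(p, eps), 1 - eps)
  loss <- -mean(as.numeric(t) * log(pc) + (1 - as.numeric(t)) * log(1 - pc))
  delta <- (p - as.numeric(t)) / n
  g <- cn_backward(net, cache, delta)
  list(loss = loss, gW = g$gW, gb = g$gb)
}

eval_loss <- function(net, pairs) {
  mean(vapply(pairs, function(pr)
    bce_loss(forward(net, pr$defective), pr$intact), numeric(1)))
}

#' Fit the cranial completion network
#'
#' Trains the 12-layer skip-connected dilated 3D autoencoder on
#' defective -> intact pairs with voxelwise binary cross entropy and the
#' Adadelta optimizer (decay rate 0.95, epsilon 1e-6 by default; Adadelta
#' adapts its own step sizes, so no learning rate is set). Shuffling, the
#' validation split and weight initialization are all derived from the
#' control seed, so a run is a pure function of (pairs, spec, control).
#' When a validation set exists, the returned network carries the weights
#' of the best validation epoch.
#'
#' @param pairs list of `training_pair`s, all on the same grid.
#' @param spec a [cranionet_spec()]; ignored when `net` is supplied.
#' @param control a [cranionet_control()].
#' @param net optionally, an existing `cranionet` to continue training
#'   (e.g. loaded from a checkpoint).
#' @return a trained `cranionet`; component `history` is a data frame of
#'   per-epoch training and validation loss and wall-clock seconds.
#' @export
cranionet <- function(pairs, spec = cranionet_spec(),
                      control = cranionet_control(), net = NULL) {
  if (!length(pairs)) stop("`pairs` must be non-empty")
  stopifnot(inherits(control, "cranionet_control"))
  if (is.null(net)) {
    net <- build_network(spec, seed = control$seed)
    if (isTRUE(control$calibrate_bias)) {
      occ <- mean(vapply(pairs, function(p) mean(as_values(p$intact)),
                         numeric(1)))
      occ <- min(max(occ, 1e-4), 1 - 1e-4)
      nl <- length(net$weights)
      net$weights[[nl]]$b <- rep(log(occ / (1 - occ)),
                                 length(net$weights[[nl]]$b))
    }
  }
  d <- dim(as_values(pairs[[1]]$defective))
  check_input_shape(net, d)

  if (control$validation_split > 0 && length(pairs) >= 2L) {
    parts <- split_dataset(pairs, control$validation_split, control$seed,
                           groups = control$groups)
    train_pairs <- parts$train
    val_pairs <- parts$validation
  } else {
    train_pairs <- pairs
    val_pairs <- list()
  }
  if (!length(train_pairs)) stop("training partition is empty")

  # accumulator state survives checkpoint/resume so continued training
  # picks up Adadelta's adapted step sizes
  state <- if (!is.null(net$optim)) net$optim
  else lapply(net$weights, function(w)
    list(EgW = 0 * w$W, EdW = 0 * w$W, Egb = 0 * w$b, Edb = 0 * w$b))
  rho <- control$rho
  eps <- control$epsilon
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), seconds = numeric(0))
  best_val <- Inf
  best_weights <- net$weights
  wait <- 0L

  run_epochs <- with_seed(control$seed + 1L, {
    for (ep in seq_len(control$epochs)) {
      t0 <- proc.time()[3]
      ord <- sample.int(length(train_pairs))
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1, length(ord), by = control$batch_size)) {
        idx <- ord[b0:min(length(ord), b0 + control$batch_size - 1L)]
        accW <- NULL
        accB <- NULL
        bl <- 0
        for (ii in idx) {
          g <- grad_one(net, train_pairs[[ii]])
          bl <- bl + g$loss
          if (is.null(accW)) {
            accW <- g$gW
            accB <- g$gb
          } else {
            for (l in seq_along(accW)) {
              accW[[l]] <- accW[[l]] + g$gW[[l]]
              accB[[l]] <- accB[[l]] + g$gb[[l]]
            }
          }
        }
        bl <- bl / length(idx)
        if (!is.finite(bl))
          stop(sprintf("non-finite loss at epoch %d, batch %d: %g",
                       ep, nb + 1L, bl))
        for (l in seq_along(net$weights)) {
          gW <- accW[[l]] / length(idx)
          gb <- accB[[l]] / length(idx)
          st <- state[[l]]
          st$EgW <- rho * st$EgW + (1 - rho) * gW^2
          dW <- -sqrt(st$EdW + eps) / sqrt(st$EgW + eps) * gW
          st$EdW <- rho * st$EdW + (1 - rho) * dW^2
          st$Egb <- rho * st$Egb + (1 - rho) * gb^2
          db <- -sqrt(st$Edb + eps) / sqrt(st$Egb + eps) * gb
          st$Edb <- rho * st$Edb + (1 - rho) * db^2
          net$weights[[l]]$W <- net$weights[[l]]$W + dW
          net$weights[[l]]$b <- net$weights[[l]]$b + db
          state[[l]] <- st
        }
        ep_loss <- ep_loss + bl
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      vl <- if (length(val_pairs)) eval_loss(net, val_pairs) else NA_real_
      hist[nrow(hist) + 1L, ] <- list(ep, ep_loss, vl, proc.time()[3] - t0)
      if (control$verbose)
        message(sprintf("epoch %3d  loss %.5f  val %.5f", ep, ep_loss, vl))
      if (length(val_pairs)) {
        if (vl < best_val - control$min_delta) {
          best_val <- vl
          best_weights <- net$weights
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= control$patience) break
        }
      }
      if (!is.null(control$checkpoint_path) &&
          control$checkpoint_cadence > 0L &&
          ep %% control$checkpoint_cadence == 0L)
        save_network(net, control$checkpoint_path)
    }
    NULL
  })

  if (length(val_pairs)) net$weights <- best_weights
  net$optim <- state
  if (nrow(hist))
    hist$epoch <- hist$epoch +
      (if (is.null(net$history)) 0L else nrow(net$history))
  net$history <- rbind(net$history, hist)
  net$trained <- !is.null(net$history) && nrow(net$history) > 0
  net$control <- control
  if (!is.null(control$checkpoint_path))
    save_network(net, control$checkpoint_path)
  net
}

#' Training-history plot
#'
#' @param x a trained `cranionet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cranionet <- function(x, ...) {
  if (is.null(x$history) || !nrow(x$history))
    stop("network has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "binary cross entropy", ...)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Per-case volumetric residuals
#'
#' For each pair: forward pass, 0.5 binarization, Boolean implant
#' extraction, and the volumetric error rate against the pair's ideal
#' implant.
#'
#' @param object a trained `cranionet`.
#' @param pairs list of `training_pair`s.
#' @param threshold binarization threshold.
#' @param ... unused.
#' @return numeric vector of error rates (percent).
#' @export
residuals.cranionet <- function(object, pairs, threshold = 0.5, ...) {
  vapply(pairs, function(pr) {
    completed <- binarize(forward(object, pr$defective), threshold)
    implant <- extract_implant(completed, pr$defective)
    volumetric_error_rate(pr$ideal_implant, implant$volume)
  }, numeric(1))
}
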