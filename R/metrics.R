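# Volumetric error rate and the evaluation harness.
#
# The error rate between the ideal implant P and a generated implant P*
# is r = 100 * ||P - P*||_1 / ||P||_1. On binary volumes the 1-norm of
# the voxelwise difference is the symmetric-difference count, so both
# missing (false-negative) and spurious (false-positive) voxels are
# penalized, and r can exceed 100%.

#' Volumetric error rate
#'
#' `r = 100 * ||P - P_star||_1 / ||P||_1` between the ideal implant `P`
#' and the generated implant `P_star`, where the difference is taken
#' voxelwise and the 1-norm sums absolute values. `r = 0` iff the two
#' binary volumes are identical.
#'
#' @param P binary `voxel_volume`, the ideal (ground-truth) implant;
#'   must be nonempty.
#' @param P_star binary `voxel_volume` of the same shape, the generated
#'   implant.
#' @return the error rate as a percentage (>= 0; can exceed 100).
#' @export
volumetric_error_rate <- function(P, P_star) {
  p <- as_values(P)
  q <- as_values(P_star)
  if (!identical(dim(p), dim(q))) stop("shapes must match")
  np <- sum(p)
  if (np == 0) stop("ideal implant P is empty; the error rate is undefined")
  100 * sum(abs(p - q)) / np
}

resolve_predictor <- function(object) {
  if (inherits(object, "cranionet"))
    return(function(pair) as_values(forward(object, pair$defective)))
  if (is.character(object)) {
    return(switch(match.arg(object, c("identity", "null")),
                  identity = function(pair) as_values(pair$intact),
                  null = function(pair) as_values(pair$defective)))
  }
  if (is.function(object)) return(object)
  stop("`object` must be a cranionet, 'identity', 'null', or a function")
}

#' Evaluate completion performance on a test set
#'
#' For every pair: forward pass (or oracle), binarization at `threshold`,
#' Boolean implant extraction against the pair's defective model, and the
#' volumetric error rate against the pair's ideal implant. In place of a
#' trained network, the string `"identity"` (completed := intact; the
#' pipeline-correctness oracle, r = 0 throughout) or `"null"`
#' (completed := defective; empty implant, r = 100%) substitutes a test
#' double for the network.
#'
#' @param object a trained `cranionet`, `"identity"`, `"null"`, or a
#'   function `pair -> completed values`.
#' @param pairs non-empty list of `training_pair`s.
#' @param threshold binarization threshold.
#' @return an object of class `cranionet_eval`: a list with `reports`
#'   (per-case data frame) and `summary` (mean and max error rate, and a
#'   per-family breakdown).
#' @export
evaluate_pairs <- function(object, pairs, threshold = 0.5) {
  if (!length(pairs)) stop("`pairs` must be non-empty")
  pred <- resolve_predictor(object)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    if (voxel_count(pr$ideal_implant) == 0) {
      warning("case ", i, " has an empty ideal implant; skipped")
      return(NULL)
    }
    completed <- binarize(voxel_volume(array(pred(pr),
                                             dim(as_values(pr$defective)))),
                          threshold)
    implant <- extract_implant(completed, pr$defective)
    pv <- as_values(pr$ideal_implant)
    qv <- as_values(implant$volume)
    data.frame(case = i,
               family = if (!is.null(pr$mask)) pr$mask$family else "unknown",
               defect_fraction = defect_fraction(pr),
               crosses_midline = if (!is.null(pr$mask))
                 pr$mask$crosses_midline else NA,
               volume_P = sum(pv),
               mismatch = sum(abs(pv - qv)),
               r = volumetric_error_rate(pr$ideal_implant, implant$volume))
  })
  reports <- do.call(rbind, rows)
  if (is.null(reports)) stop("no evaluable case (all ideal implants empty)")
  by_family <- stats::aggregate(r ~ family, reports, mean)
  structure(list(reports = reports,
                 summary = list(mean_r = mean(reports$r),
                                max_r = max(reports$r),
                                n = nrow(reports),
                                by_family = by_family)),
            class = "cranionet_eval")
}

#' @export
print.cranionet_eval <- function(x, ...) {
  cat(sprintf("Volumetric error rate over %d cases: mean %.2f%%, max %.2f%%\n",
              x$summary$n, x$summary$mean_r, x$summary$max_r))
  print(x$summary$by_family, row.names = FALSE)
  invisible(x)
}

#' Capability curve: error rate versus defect volume fraction
#'
#' Probes the repair capability over increasing defect sizes: for each
#' fraction bin, defects targeted at that bin are sampled on each phantom
#' of a held-out cohort, evaluated, and the mean error rate tabulated.
#' Since "satisfactory" repair is an application judgement, the curve is
#' annotated with an explicit surrogate criterion
#' (`r <= satisfactory_r`), reported per bin.
#'
#' @param object a trained `cranionet` or an oracle string (see
#'   [evaluate_pairs()]).
#' @param phantoms list of intact binary `voxel_volume`s, disjoint from
#'   the training sources.
#' @param breaks increasing fraction breakpoints spanning (0, 0.5\];
#'   consecutive values delimit the bins.
#' @param seed integer seed for the defect sampling.
#' @param threshold binarization threshold.
#' @param satisfactory_r surrogate threshold (percent) a bin must meet to
#'   be flagged satisfactory.
#' @return a data frame of class `capability_curve` with one row per bin:
#'   `fraction_lo`, `fraction_hi`, `n`, `mean_r`, `max_r`, `satisfactory`.
#' @export
capability_curve <- function(object, phantoms,
                             breaks = seq(0.05, 0.5, by = 0.05),
                             seed = 1L, threshold = 0.5,
                             satisfactory_r = 15) {
  if (length(breaks) < 2L || any(diff(breaks) <= 0))
    stop("`breaks` must be increasing with at least two values")
  seeds <- derive_seeds(seed, (length(breaks) - 1L) * length(phantoms))
  rows <- lapply(seq_len(length(breaks) - 1L), function(bi) {
    rng <- c(breaks[bi], breaks[bi + 1L])
    pairs <- list()
    for (pi in seq_along(phantoms)) {
      pr <- tryCatch(
        sample_training_pair(phantoms[[pi]],
                             seeds[(bi - 1L) * length(phantoms) + pi],
                             fraction_range = rng),
        error = function(e) NULL)
      if (!is.null(pr)) pairs[[length(pairs) + 1L]] <- pr
    }
    if (!length(pairs))
      return(data.frame(fraction_lo = rng[1], fraction_hi = rng[2],
                        n = 0L, mean_r = NA_real_, max_r = NA_real_,
                        satisfactory = NA))
    ev <- evaluate_pairs(object, pairs, threshold)
    data.frame(fraction_lo = rng[1], fraction_hi = rng[2],
               n = ev$summary$n, mean_r = ev$summary$mean_r,
               max_r = ev$summary$max_r,
               satisfactory = ev$summary$mean_r <= satisfactory_r)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$mean_r)
  attr(out, "monotone_trend") <-
    if (sum(ok) >= 2L && stats::sd(out$mean_r[ok]) > 0)
      stats::cor(out$fraction_lo[ok], out$mean_r[ok], method = "spearman")
    else NA_real_
  attr(out, "satisfactory_r") <- satisfactory_r
  class(out) <- c("capability_curve", "data.frame")
  out
}

#' @export
print.capability_curve <- function(x, ...) {
  cat(sprintf("Capability curve (surrogate satisfactory threshold: r <= %g%%)\n",
              attr(x, "satisfactory_r")))
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("Spearman trend of mean_r vs fraction: %.3f\n",
              attr(x, "monotone_trend")))
  invisible(x)
}

#' Storage accounting for a volume cohort
#'
#' Bytes needed to hold `n` dense volumes of a given shape at a given
#' bytes-per-voxel width (default 4, single precision); e.g. one
#' 112 x 112 x 40 volume is 2,007,040 bytes (about 2 MB) and 7,150 of
#' them total 14,350,336,000 bytes (14.35 GB decimal). Computed
#' analytically — nothing is allocated.
#'
#' @param grid_shape integer vector of 3.
#' @param n number of volumes.
#' @param bytes_per_voxel storage width per voxel.
#' @return total size in bytes.
#' @export
volume_storage_bytes <- function(grid_shape, n = 1,
                                 bytes_per_voxel = 4) {
  prod(as.numeric(grid_shape)) * bytes_per_voxel * n
}
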