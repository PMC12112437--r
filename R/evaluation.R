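#' Pooled control-point tracking RMSE
#'
#' Root-mean-square Euclidean distance between predicted and ground-truth
#' control-point positions, pooled over all frames and points of one image
#' space. This is the registration-error summary reported per scenario and
#' frame type (IR or VIS).
#'
#' @param predicted data.frame (\code{frame}, \code{point_id}, \code{x},
#'   \code{y}) of predicted positions.
#' @param ground_truth matching data.frame of reference positions, with
#'   identical frame indices and point ids.
#' @return single non-negative RMSE in pixels.
#' @export
cp_rmse <- function(predicted, ground_truth) {
  check_cp_table(predicted, "predicted")
  check_cp_table(ground_truth, "ground_truth")
  kp <- paste(predicted$frame, predicted$point_id, sep = "\r")
  kt <- paste(ground_truth$frame, ground_truth$point_id, sep = "\r")
  if (nrow(predicted) != nrow(ground_truth) || !setequal(kp, kt) ||
        anyDuplicated(kp) || anyDuplicated(kt)) {
    stopf("predicted and ground_truth must cover identical (frame, point_id) pairs")
  }
  idx <- match(kp, kt)
  d2 <- (predicted$x - ground_truth$x[idx])^2 +
    (predicted$y - ground_truth$y[idx])^2
  sqrt(mean(d2))
}

#' Fiducial registration error for one frame
#'
#' Eight (or more) control points are identified in both the fixed (VIS)
#' and moving (IR) frames. The transform is estimated from the three
#' designated pairs only; the remaining pairs are pushed through it and the
#' mean Euclidean distance between the transformed moving points and their
#' fixed counterparts is the frame's FRE.
#'
#' @param fixed_points data.frame (\code{point_id}, \code{x}, \code{y}) in
#'   the fixed space.
#' @param moving_points matching data.frame in the moving space.
#' @param transform_ids character vector of the 3 point ids defining the
#'   transform.
#' @return FRE in pixels (mean over held-out points).
#' @export
fre_frame <- function(fixed_points, moving_points, transform_ids) {
  check_cp_table(fixed_points, "fixed_points", require_frame = FALSE)
  check_cp_table(moving_points, "moving_points", require_frame = FALSE)
  ids_f <- as.character(fixed_points$point_id)
  ids_m <- as.character(moving_points$point_id)
  if (!setequal(ids_f, ids_m) || anyDuplicated(ids_f) || anyDuplicated(ids_m)) {
    stopf("fixed and moving point ids must match exactly")
  }
  if (length(transform_ids) != 3L) stopf("transform_ids must name exactly 3 points")
  if (!all(transform_ids %in% ids_f)) {
    stopf("transform id(s) absent: %s",
          paste(setdiff(transform_ids, ids_f), collapse = ", "))
  }
  held_out <- setdiff(ids_f, transform_ids)
  if (length(held_out) < 1L) {
    stopf("need at least 4 point pairs so at least one is held out")
  }
  fit <- estimate_affine(
    source = cbind(moving_points$x, moving_points$y)[match(transform_ids, ids_m), , drop = FALSE],
    target = cbind(fixed_points$x, fixed_points$y)[match(transform_ids, ids_f), , drop = FALSE])
  mv <- cbind(moving_points$x, moving_points$y)[match(held_out, ids_m), , drop = FALSE]
  fx <- cbind(fixed_points$x, fixed_points$y)[match(held_out, ids_f), , drop = FALSE]
  mean(point_distances(apply_affine(fit, mv), fx))
}

#' Mean fiducial registration error over a sequence
#'
#' Applies \code{\link{fre_frame}} to every frame of a tracked control-point
#' sequence and summarises with the arithmetic mean and the sample (n - 1)
#' standard deviation.
#'
#' @param fixed_tracks data.frame (\code{frame}, \code{point_id}, \code{x},
#'   \code{y}) in the fixed (VIS) space, all frames.
#' @param moving_tracks matching data.frame in the moving (IR) space.
#' @param transform_ids the 3 point ids defining the per-frame transform.
#' @return list with \code{mean}, \code{sd} and \code{per_frame} (named by
#'   frame index) FRE values in pixels.
#' @export
mean_fre <- function(fixed_tracks, moving_tracks, transform_ids) {
  check_cp_table(fixed_tracks, "fixed_tracks")
  check_cp_table(moving_tracks, "moving_tracks")
  frames <- sort(unique(fixed_tracks$frame))
  if (length(frames) < 1L) stopf("need at least one frame")
  if (!setequal(frames, unique(moving_tracks$frame))) {
    stopf("fixed and moving tracks must cover the same frames")
  }
  per_frame <- vapply(frames, function(f) {
    fre_frame(fixed_tracks[fixed_tracks$frame == f, ],
              moving_tracks[moving_tracks$frame == f, ],
              transform_ids)
  }, numeric(1))
  names(per_frame) <- frames
  list(mean = mean(per_frame),
       sd = if (length(per_frame) > 1L) stats::sd(per_frame) else NA_real_,
       per_frame = per_frame)
}
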