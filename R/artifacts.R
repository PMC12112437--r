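#' Two-sided sigma outlier bounds for an ROI temperature sample
#'
#' Eyelashes are markedly cooler than the ocular surface, so within a
#' cornea or sclera ROI they appear as temperature outliers. Assuming an
#' approximately normal temperature distribution across the ROI, pixels
#' outside \eqn{[\mu - k\sigma, \mu + k\sigma]} are flagged, with
#' \eqn{\mu} the ROI mean, \eqn{\sigma} the ROI population standard
#' deviation and \eqn{k = 2} by default.
#'
#' @param roi_temps numeric vector of ROI pixel temperatures in degrees C
#'   (at least 2 values).
#' @param k sigma multiplier (default 2).
#' @return object of class \code{outlier_bounds}: list with \code{mu},
#'   \code{sigma}, \code{lower}, \code{upper}, \code{k}.
#' @examples
#' outlier_bounds(c(33, 35))   # mu 34, sigma 1, bounds [32, 36]
#' @export
outlier_bounds <- function(roi_temps, k = 2.0) {
  roi_temps <- as.numeric(roi_temps)
  if (length(roi_temps) < 2L) {
    stopf("ROI must contain at least 2 pixels to define a standard deviation (got %d)",
          length(roi_temps))
  }
  if (!all(is.finite(roi_temps))) stopf("ROI temperatures must be finite")
  mu <- mean(roi_temps)
  sigma <- pop_sd(roi_temps)
  structure(list(mu = mu, sigma = sigma,
                 lower = mu - k * sigma, upper = mu + k * sigma, k = k),
            class = "outlier_bounds")
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat(sprintf("<outlier_bounds> mu %.4f sigma %.4f -> [%.4f, %.4f] (k = %g)\n",
              x$mu, x$sigma, x$lower, x$upper, x$k))
  invisible(x)
}

#' Remove eyelash artifacts from thermal ROIs
#'
#' Bounds are computed separately for each ROI label (cornea and sclera)
#' from that label's own pixels in a single pass over the original ROI; a
#' pixel is retained iff \code{lower <= T <= upper} (pixels exactly at a
#' bound are kept). The input frame is never mutated; removals are
#' recorded as coordinates.
#'
#' @param frame numeric temperature matrix (degrees C).
#' @param mask integer label matrix aligned to \code{frame} (0 background,
#'   1 cornea, 2 sclera).
#' @param k sigma multiplier passed to \code{\link{outlier_bounds}}.
#' @return named list (\code{cornea}, \code{sclera}; labels with fewer than
#'   2 pixels are skipped with a warning) of \code{cleaned_roi} objects:
#'   \code{label}, \code{retained} and \code{removed} (n x 2 matrices of
#'   1-based \code{row}, \code{col}), \code{removed_temps}, \code{bounds}.
#' @export
remove_eyelashes <- function(frame, mask, k = 2.0) {
  frame <- as.matrix(frame)
  mask <- as.matrix(mask)
  if (!identical(dim(frame), dim(mask))) {
    stopf("frame (%s) and mask (%s) shapes differ",
          paste(dim(frame), collapse = "x"), paste(dim(mask), collapse = "x"))
  }
  if (!any(mask > 0)) stopf("mask contains no labelled pixels")
  out <- list()
  for (lab in c(cornea = 1L, sclera = 2L)) {
    idx <- which(mask == lab, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    lab_name <- names(which(c(cornea = 1L, sclera = 2L) == lab))
    if (nrow(idx) < 2L) {
      warnf("label '%s' has fewer than 2 pixels; skipped", lab_name)
      next
    }
    temps <- frame[idx]
    b <- outlier_bounds(temps, k = k)
    keep <- temps >= b$lower & temps <= b$upper
    out[[lab_name]] <- structure(
      list(label = lab_name,
           retained = idx[keep, , drop = FALSE],
           removed = idx[!keep, , drop = FALSE],
           removed_temps = temps[!keep],
           bounds = b),
      class = "cleaned_roi")
  }
  out
}

#' Eye Aspect Ratio
#'
#' The EAR summarises eyelid openness from six eye landmarks P1..P6 (P1/P4
#' the horizontal eye corners, P2/P3 on the upper lid, P6/P5 their lower-lid
#' counterparts):
#' \deqn{EAR = \frac{\|P_2 - P_6\| + \|P_3 - P_5\|}{2\,\|P_1 - P_4\|}.}
#' It is invariant under similarity transforms of the landmark set and
#' drops towards 0 as the lid closes.
#'
#' @param landmarks data.frame with columns \code{point} (containing
#'   \code{"P1"}..\code{"P6"}), \code{x}, \code{y}.
#' @return non-negative dimensionless ratio.
#' @examples
#' lm <- data.frame(point = paste0("P", 1:6),
#'                  x = c(0, 1, 3, 4, 3, 1), y = c(0, 1, 1, 0, -1, -1))
#' ear(lm)   # 0.5
#' @export
ear <- function(landmarks) {
  if (!is.data.frame(landmarks) ||
        !all(c("point", "x", "y") %in% names(landmarks))) {
    stopf("landmarks must be a data.frame with columns point, x, y")
  }
  need <- paste0("P", 1:6)
  if (!all(need %in% landmarks$point)) {
    stopf("landmarks must contain points %s", paste(need, collapse = ", "))
  }
  p <- lapply(need, function(id) {
    r <- landmarks[landmarks$point == id, ][1, ]
    c(r$x, r$y)
  })
  names(p) <- need
  horiz <- sqrt(sum((p$P1 - p$P4)^2))
  if (horiz <= 0) stopf("P1 and P4 coincide: EAR undefined (zero horizontal extent)")
  v1 <- sqrt(sum((p$P2 - p$P6)^2))
  v2 <- sqrt(sum((p$P3 - p$P5)^2))
  (v1 + v2) / (2 * horiz)
}

#' Detect blink frames from eye landmarks
#'
#' Frames whose EAR falls strictly below the threshold (default 0.3) are
#' flagged as blinks and excluded from temperature analysis; a frame with
#' EAR exactly at the threshold is kept. When per-frame cornea masks are
#' supplied, frames with an empty cornea label are additionally excluded
#' with reason \code{"no_cornea"} (the EAR rule takes precedence when both
#' fire). Frames with degenerate landmarks (coincident eye corners) are
#' excluded with reason \code{"no_cornea"} and a warning.
#'
#' @param landmark_sequence data.frame (\code{frame}, \code{point},
#'   \code{x}, \code{y}) covering every frame.
#' @param cornea_masks optional list of label matrices indexed by
#'   \code{frame + 1}.
#' @param threshold EAR blink threshold (default 0.3).
#' @return data.frame with columns \code{frame}, \code{ear},
#'   \code{is_blink}, \code{reason} (\code{"ear_below_threshold"},
#'   \code{"no_cornea"} or \code{"none"}).
#' @export
detect_blinks <- function(landmark_sequence, cornea_masks = NULL,
                          threshold = 0.3) {
  if (!is.data.frame(landmark_sequence) ||
        !all(c("frame", "point", "x", "y") %in% names(landmark_sequence))) {
    stopf("landmark_sequence must have columns frame, point, x, y")
  }
  if (threshold <= 0) stopf("threshold must be positive")
  frames <- sort(unique(landmark_sequence$frame))
  recs <- lapply(frames, function(f) {
    lm <- landmark_sequence[landmark_sequence$frame == f, ]
    e <- tryCatch(ear(lm), error = function(err) NA_real_)
    if (is.na(e)) {
      warnf("frame %d: degenerate landmarks; frame excluded", f)
      return(data.frame(frame = f, ear = NA_real_, is_blink = TRUE,
                        reason = "no_cornea", stringsAsFactors = FALSE))
    }
    if (e < threshold) {
      return(data.frame(frame = f, ear = e, is_blink = TRUE,
                        reason = "ear_below_threshold", stringsAsFactors = FALSE))
    }
    if (!is.null(cornea_masks)) {
      m <- cornea_masks[[f + 1L]]
      if (!is.null(m) && !any(m == 1L)) {
        return(data.frame(frame = f, ear = e, is_blink = TRUE,
                          reason = "no_cornea", stringsAsFactors = FALSE))
      }
    }
    data.frame(frame = f, ear = e, is_blink = FALSE, reason = "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
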