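#' Follow control points through an image sequence
#'
#' Two strategies for carrying the frame-0 control points through a
#' sequence:
#' \describe{
#'   \item{\code{"static"}}{every frame's set equals the frame-0 set; robust
#'     when subject motion is small, immune to tracking drift.}
#'   \item{\code{"flow"}}{each point is updated frame-to-frame by a local
#'     translational patch tracker: the patch around the point in the
#'     reference frame is matched in the current frame by maximising
#'     normalized cross-correlation over integer offsets, then refined to
#'     sub-pixel precision by a quadratic fit of the correlation peak.}
#' }
#' Points listed in \code{anchored_ids} (fiducial-marker analogues) are
#' pinned at their frame-0 coordinates in every frame. Points whose
#' reference patch leaves the image, or whose best match presses against
#' an image-clipped edge of the search window (the point is exiting the
#' frame), are frozen at their last in-bounds location and flagged in the
#' \code{frozen} column.
#'
#' Frames listed in \code{hold_frames} (typically blink frames, whose
#' appearance change would corrupt patch matching) do not update any
#' point: positions are carried over, and the next update matches against
#' the last non-held frame.
#'
#' @param frames list of numeric image matrices (one per frame, same size).
#' @param initial_cps data.frame (\code{point_id}, \code{x}, \code{y}) of
#'   frame-0 control points (0-based pixel coordinates).
#' @param mode \code{"static"} or \code{"flow"}.
#' @param anchored_ids character vector of point ids held at their frame-0
#'   position.
#' @param hold_frames integer vector of 0-based frame indices skipped by
#'   the tracker.
#' @param patch_size odd integer patch edge length in pixels.
#' @param search_radius integer search radius in pixels.
#' @return data.frame with columns \code{frame}, \code{point_id}, \code{x},
#'   \code{y}, \code{frozen}, covering every frame.
#' @export
follow_cps <- function(frames, initial_cps, mode = c("static", "flow"),
                       anchored_ids = character(), hold_frames = integer(),
                       patch_size = 21L, search_radius = 10L) {
  mode <- match.arg(mode)
  if (!is.data.frame(initial_cps) || nrow(initial_cps) == 0L) {
    stopf("initial control-point set is empty")
  }
  check_cp_table(initial_cps, "initial_cps", require_frame = FALSE)
  if (!is.list(frames) || length(frames) == 0L) {
    stopf("frames must be a non-empty list of image matrices")
  }
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2L == 0L) stopf("patch_size must be odd")
  n_frames <- length(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  if (any(initial_cps$x < -1 | initial_cps$x > w | initial_cps$y < -1 |
            initial_cps$y > h)) {
    stopf("initial control points lie outside frame 0 bounds")
  }

  ids <- as.character(initial_cps$point_id)
  if (anyDuplicated(ids)) stopf("duplicate point ids in initial_cps")

  if (mode == "static") {
    out <- do.call(rbind, lapply(seq_len(n_frames) - 1L, function(f) {
      data.frame(frame = f, point_id = ids, x = initial_cps$x,
                 y = initial_cps$y, frozen = FALSE,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }

  half <- patch_size %/% 2L
  pos <- cbind(x = initial_cps$x, y = initial_cps$y)
  frozen <- rep(FALSE, nrow(pos))
  anchored <- ids %in% anchored_ids

  rows <- vector("list", n_frames)
  rows[[1]] <- data.frame(frame = 0L, point_id = ids, x = pos[, 1],
                          y = pos[, 2], frozen = FALSE,
                          stringsAsFactors = FALSE)
  ref_idx <- 1L   # last frame the tracker matched against
  for (f in seq_len(n_frames - 1L)) {
    if (!(f %in% hold_frames)) {
      cur <- frames[[f + 1L]]
      ref <- frames[[ref_idx]]
      for (i in seq_along(ids)) {
        if (anchored[i] || frozen[i]) next
        step <- track_patch(ref, cur, pos[i, 1], pos[i, 2],
                            half = half, radius = search_radius)
        if (is.null(step)) {
          frozen[i] <- TRUE
        } else {
          pos[i, ] <- pos[i, ] + step
        }
      }
      ref_idx <- f + 1L
    }
    rows[[f + 1L]] <- data.frame(frame = f, point_id = ids, x = pos[, 1],
                                 y = pos[, 2], frozen = frozen & !anchored,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# One tracking step for a single point: returns c(dx, dy), or NULL when
# the point cannot be tracked further (reference patch out of the image,
# or the best match pressed against an image-clipped search boundary).
track_patch <- function(prev, cur, x, y, half, radius) {
  # Patch is anchored at the rounded position; the fractional part of the
  # position is preserved by applying the measured displacement to the
  # floating-point coordinates.
  cx <- round_half_up(x) + 1L   # 1-based matrix column
  cy <- round_half_up(y) + 1L
  h <- nrow(prev); w <- ncol(prev)
  if (cx - half < 1L || cx + half > w || cy - half < 1L || cy + half > h) {
    return(NULL)
  }
  a <- prev[(cy - half):(cy + half), (cx - half):(cx + half)]
  av <- as.vector(a) - mean(a)
  an <- sqrt(sum(av^2))
  if (an < 1e-12) return(c(0, 0))    # featureless patch: assume no motion

  offs <- (-radius):radius
  score <- matrix(-Inf, nrow = length(offs), ncol = length(offs))
  clipped <- matrix(FALSE, nrow = length(offs), ncol = length(offs))
  for (iy in seq_along(offs)) {
    ry <- cy + offs[iy]
    if (ry - half < 1L || ry + half > h) {
      clipped[iy, ] <- TRUE
      next
    }
    for (ix in seq_along(offs)) {
      rx <- cx + offs[ix]
      if (rx - half < 1L || rx + half > w) {
        clipped[iy, ix] <- TRUE
        next
      }
      b <- cur[(ry - half):(ry + half), (rx - half):(rx + half)]
      bv <- as.vector(b) - mean(b)
      bn <- sqrt(sum(bv^2))
      if (bn < 1e-12) next
      score[iy, ix] <- sum(av * bv) / (an * bn)
    }
  }
  if (!any(is.finite(score))) return(NULL)
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  # Best match adjacent to an image-clipped offset: the point is exiting
  # the frame and its true displacement is unobservable.
  for (nb in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ny <- best[1] + nb[1]; nx <- best[2] + nb[2]
    if (ny >= 1L && ny <= length(offs) && nx >= 1L && nx <= length(offs) &&
          clipped[ny, nx]) {
      return(NULL)
    }
  }
  dy <- offs[best[1]]; dx <- offs[best[2]]
  # Quadratic sub-pixel refinement along each axis through the peak. A
  # (numerically) perfect correlation peak is an exact integer-offset
  # match; refining it would only import asymmetry of the neighbouring
  # scores, so it is left untouched.
  sub <- c(0, 0)
  if (score[best[1], best[2]] >= 1 - 1e-9) return(c(dx, dy))
  if (best[2] > 1L && best[2] < length(offs)) {
    sub[1] <- quad_peak(score[best[1], best[2] - 1L], score[best[1], best[2]],
                        score[best[1], best[2] + 1L])
  }
  if (best[1] > 1L && best[1] < length(offs)) {
    sub[2] <- quad_peak(score[best[1] - 1L, best[2]], score[best[1], best[2]],
                        score[best[1] + 1L, best[2]])
  }
  c(dx + sub[1], dy + sub[2])
}

# Offset of the vertex of the parabola through (-1, cm), (0, c0), (1, cp),
# clamped to half a pixel.
quad_peak <- function(cm, c0, cp) {
  if (!is.finite(cm) || !is.finite(cp)) return(0)
  denom <- cm - 2 * c0 + cp
  if (abs(denom) < 1e-12) return(0)
  max(-0.5, min(0.5, (cm - cp) / (2 * denom)))
}
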