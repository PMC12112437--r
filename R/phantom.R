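#' Configuration for the synthetic eye phantom
#'
#' The phantom emulates the statistical structure of a synchronized IR/VIS
#' ocular recording: a warm elliptical eye surface (cornea inside a scleral
#' annulus) with per-pixel temperatures in \code{base_temp_range} plus
#' Gaussian noise, a known VIS-to-IR affine relationship, fixed
#' high-contrast marker blobs (fiducial-tag analogues near the canthi),
#' injected cold eyelash pixels, and scripted blink intervals rendered by
#' eyelid closure and collapsing vertical landmarks.
#'
#' Artifact pixels are set to the contaminated label's clean mean plus
#' \code{eyelash_temp_offset}, which places them strictly below the
#' lower 2-sigma bound of their ROI whenever
#' \code{eyelash_fraction < 0.2} and
#' \code{abs(eyelash_temp_offset) >= 4 * noise_sd + 2}; both conditions are
#' enforced here.
#'
#' @param n_frames number of frames.
#' @param image_size \code{c(height, width)} in pixels, at least 32 x 32.
#'   The height must be at least 0.6 x width so that the open-eye aspect
#'   ratio keeps the EAR at or above the blink threshold.
#' @param base_temp_range \code{c(low, high)} surface temperature range in
#'   degrees C; the ocular surface typically sits between 32 and 36.
#' @param true_transform \code{\link{affine_transform}} mapping VIS to IR
#'   pixel coordinates.
#' @param eyelash_fraction fraction of each ROI label's pixels replaced by
#'   cold artifacts, in [0, 0.2); values above 0.2 are rejected because the
#'   artifacts would no longer be outliers of their ROI.
#' @param eyelash_temp_offset degrees C added to artifact pixels (negative;
#'   magnitude at least \code{4 * noise_sd + 2}).
#' @param noise_sd standard deviation (degrees C) of i.i.d. Gaussian surface
#'   noise.
#' @param blink_frames integer vector of 0-based frame indices with a
#'   (partially) closed eye.
#' @param drift_sd default per-frame control-point jitter (pixels) used by
#'   drift simulations.
#' @param marker_points optional n x 2 matrix of fixed marker coordinates in
#'   VIS space (at least 2 rows); defaults to two points just beyond the
#'   inner and outer canthus.
#' @param closure_fraction eyelid closure on blink frames, in (0, 1];
#'   vertical landmark distances scale by \code{1 - closure_fraction}.
#' @param seed integer RNG seed; all stochastic draws flow from it.
#' @return object of class \code{phantom_config} (a validated list).
#' @export
phantom_config <- function(n_frames = 50L,
                           image_size = c(64L, 64L),
                           base_temp_range = c(32, 36),
                           true_transform = affine_transform(
                             rbind(c(0.97, 0.03, 1.5), c(-0.02, 0.97, -2.0))),
                           eyelash_fraction = 0.05,
                           eyelash_temp_offset = -10,
                           noise_sd = 0.2,
                           blink_frames = integer(),
                           drift_sd = 1.0,
                           marker_points = NULL,
                           closure_fraction = 0.85,
                           seed = 1L) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stopf("n_frames must be positive")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 32L)) {
    stopf("image_size must be at least 32 x 32 pixels")
  }
  if (length(base_temp_range) != 2L ||
        base_temp_range[1] >= base_temp_range[2] ||
        base_temp_range[1] < 25 || base_temp_range[2] > 45) {
    stopf("base_temp_range must be (low, high) with low < high, within [25, 45] degC")
  }
  stopifnot(inherits(true_transform, "affine_transform"))
  if (eyelash_fraction < 0 || eyelash_fraction > 0.2) {
    stopf("eyelash_fraction must lie in [0, 0.2]: beyond 0.2 the injected pixels are no longer ROI outliers")
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (eyelash_fraction > 0) {
    if (eyelash_temp_offset >= 0) stopf("eyelash_temp_offset must be negative")
    if (abs(eyelash_temp_offset) < 4 * noise_sd + 2) {
      stopf("abs(eyelash_temp_offset) must be at least 4 * noise_sd + 2 degC for artifacts to be separable")
    }
  }
  blink_frames <- sort(unique(as.integer(blink_frames)))
  if (length(blink_frames) > 0 &&
        (min(blink_frames) < 0L || max(blink_frames) >= n_frames)) {
    stopf("blink_frames must lie in [0, n_frames)")
  }
  if (drift_sd < 0) stopf("drift_sd must be non-negative")
  if (closure_fraction <= 0 || closure_fraction > 1) {
    stopf("closure_fraction must lie in (0, 1]")
  }
  geom <- eye_geometry(image_size)
  open_ear <- geom$b / geom$a
  if (open_ear < 0.3) {
    stopf("image aspect ratio gives open-eye EAR %.3f < 0.3; use height >= 0.6 * width",
          open_ear)
  }
  if (open_ear * (1 - closure_fraction) >= 0.3) {
    stopf("closure_fraction %.2f leaves blink EAR >= 0.3; increase closure",
          closure_fraction)
  }
  if (is.null(marker_points)) {
    marker_points <- rbind(
      c(geom$cx - geom$a - 0.05 * image_size[2], geom$cy),
      c(geom$cx + geom$a + 0.05 * image_size[2], geom$cy))
  }
  marker_points <- as.matrix(marker_points)
  if (nrow(marker_points) < 2L || ncol(marker_points) != 2L) {
    stopf("marker_points must be an n x 2 matrix with n >= 2")
  }
  structure(list(n_frames = n_frames, image_size = image_size,
                 base_temp_range = base_temp_range,
                 true_transform = true_transform,
                 eyelash_fraction = eyelash_fraction,
                 eyelash_temp_offset = eyelash_temp_offset,
                 noise_sd = noise_sd, blink_frames = blink_frames,
                 drift_sd = drift_sd, marker_points = marker_points,
                 closure_fraction = closure_fraction,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Concentric-ellipse eye geometry in VIS space (0-based coordinates).
eye_geometry <- function(image_size) {
  h <- image_size[1]; w <- image_size[2]
  list(cx = (w - 1) / 2, cy = (h - 1) / 2,
       a = 0.40 * w, b = 0.20 * h,          # scleral outer semi-axes
       ac = 0.18 * w, bc = 0.15 * h)        # corneal semi-axes
}

# Label lookup for vectors of VIS-space coordinates: 0 background,
# 1 cornea, 2 sclera; on blink frames rows above cut_y are lid-covered.
eye_labels <- function(x, y, geom, cut_y = -Inf) {
  rc2 <- ((x - geom$cx) / geom$ac)^2 + ((y - geom$cy) / geom$bc)^2
  rs2 <- ((x - geom$cx) / geom$a)^2 + ((y - geom$cy) / geom$b)^2
  lab <- ifelse(rc2 <= 1, 1L, ifelse(rs2 <= 1, 2L, 0L))
  lab[y < cut_y] <- 0L
  lab
}

# Clean (noise-free) surface temperature at VIS-space coordinates:
# smooth radial gradient from the corneal centre, warmer cornea over a
# cooler sclera, lid/background at skin temperature.
surface_temp <- function(x, y, lab, geom, temp_range) {
  lo <- temp_range[1]; hi <- temp_range[2]; span <- hi - lo
  rc2 <- pmin(1, ((x - geom$cx) / geom$ac)^2 + ((y - geom$cy) / geom$bc)^2)
  rs2 <- pmin(1, ((x - geom$cx) / geom$a)^2 + ((y - geom$cy) / geom$b)^2)
  t <- rep(lo - 2, length(x))                       # skin background
  t[lab == 1L] <- lo + 0.70 * span + 0.3 * (1 - rc2[lab == 1L])
  t[lab == 2L] <- lo + 0.25 * span + 0.3 * (1 - rs2[lab == 2L])
  t
}

# Canonical control points: markers M1.. plus free feature points F1..
# on the mid-annulus ellipse, 8 points in total by default.
phantom_cp_positions <- function(config) {
  geom <- eye_geometry(config$image_size)
  mk <- config$marker_points
  n_free <- max(0L, 8L - nrow(mk))
  ang <- seq(0, 2 * pi, length.out = n_free + 1L)[-1] + pi / 7
  free <- cbind(geom$cx + 0.70 * geom$a * cos(ang),
                geom$cy + 0.70 * geom$b * sin(ang))
  pts <- rbind(mk, free)
  ids <- c(paste0("M", seq_len(nrow(mk))),
           if (n_free > 0) paste0("F", seq_len(n_free)))
  data.frame(point_id = ids, x = pts[, 1], y = pts[, 2],
             stringsAsFactors = FALSE)
}

phantom_landmarks <- function(config, frame) {
  geom <- eye_geometry(config$image_size)
  v <- if (frame %in% config$blink_frames) {
    geom$b * (1 - config$closure_fraction)
  } else geom$b
  data.frame(
    frame = frame,
    point = paste0("P", 1:6),
    x = c(geom$cx - geom$a, geom$cx - geom$a / 3, geom$cx + geom$a / 3,
          geom$cx + geom$a, geom$cx + geom$a / 3, geom$cx - geom$a / 3),
    y = c(geom$cy, geom$cy - v, geom$cy - v,
          geom$cy, geom$cy + v, geom$cy + v),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic IR/VIS eye sequence with ground truth
#'
#' Renders the phantom configured by \code{\link{phantom_config}}. The eye
#' geometry is defined in VIS space; IR frames are produced by pulling each
#' IR pixel centre back through the inverse of the true VIS-to-IR transform,
#' so the VIS frames are the IR geometry warped by that inverse. Cold
#' eyelash pixels are injected per ROI label at recorded coordinates, and
#' blink frames are rendered by covering the eye top-down by
#' \code{closure_fraction} and collapsing the vertical landmarks. Output is
#' deterministic for a fixed seed.
#'
#' @param config \code{phantom_config}.
#' @return list with elements \code{ir} (list of temperature matrices,
#'   degrees C, rounded to 4 decimals), \code{vis} (list of 8-bit grayscale
#'   matrices), \code{masks} (list of VIS-space label matrices),
#'   \code{landmarks} (long data.frame), \code{cps} (frame-0 control points,
#'   both spaces) and \code{truth}: \code{true_transform},
#'   \code{eyelash_pixels} (per-frame n x 3 matrices of 1-based row, col and
#'   label), \code{blink_frames}, \code{true_cp_tracks} (all frames, both
#'   spaces), \code{landmarks}, \code{masks_ir} (IR-space label matrices)
#'   and \code{clean_cornea_mean} (per-frame mean of the artifact-free
#'   cornea surface, NA when no cornea is visible).
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  geom <- eye_geometry(config$image_size)
  inv <- invert_affine(config$true_transform)

  # VIS pixel-centre grid (0-based), column-major like R matrices.
  xs_v <- rep(seq_len(w) - 1, each = h)
  ys_v <- rep(seq_len(h) - 1, times = w)
  # IR pixel centres pulled back into VIS coordinates.
  back <- apply_affine(inv, cbind(xs_v, ys_v))

  cp0 <- phantom_cp_positions(config)
  cp_ir <- apply_affine(config$true_transform, cbind(cp0$x, cp0$y))

  ir <- vector("list", config$n_frames)
  vis <- vector("list", config$n_frames)
  masks <- vector("list", config$n_frames)
  masks_ir <- vector("list", config$n_frames)
  eyelash_pixels <- vector("list", config$n_frames)
  landmarks <- vector("list", config$n_frames)
  clean_mean <- rep(NA_real_, config$n_frames)

  with_seed(config$seed, {
    # Static VIS texture, drawn once so non-blink frames are identical.
    tex <- matrix(stats::rnorm(h * w, 0, 4), h, w) +
      outer(4 * sin(seq_len(h) / 3), cos(seq_len(w) / 4))

    for (f in seq_len(config$n_frames) - 1L) {
      blink <- f %in% config$blink_frames
      cut_y <- if (blink) {
        geom$cy + geom$b * (2 * config$closure_fraction - 1)
      } else -Inf

      # --- VIS frame, mask, landmarks -----------------------------------
      lab_v <- eye_labels(xs_v, ys_v, geom, cut_y)
      masks[[f + 1L]] <- matrix(lab_v, h, w)
      inten <- rep(60, h * w)
      inten[lab_v == 1L] <- 110
      inten[lab_v == 2L] <- 190
      if (blink) {
        open_lab <- eye_labels(xs_v, ys_v, geom)
        inten[open_lab > 0L & ys_v < cut_y] <- 140   # eyelid
      }
      img <- matrix(inten, h, w) + tex
      for (mi in seq_len(nrow(config$marker_points))) {
        mx <- config$marker_points[mi, 1]; my <- config$marker_points[mi, 2]
        d2 <- (xs_v - mx)^2 + (ys_v - my)^2
        img[d2 <= 6.25] <- 255
        img[d2 > 6.25 & d2 <= 16] <- 20
      }
      vis[[f + 1L]] <- matrix(pmin(255, pmax(0, round(img))), h, w)
      landmarks[[f + 1L]] <- phantom_landmarks(config, f)

      # --- IR frame ------------------------------------------------------
      lab_i <- eye_labels(back[, 1], back[, 2], geom, cut_y)
      masks_ir[[f + 1L]] <- matrix(lab_i, h, w)
      base <- surface_temp(back[, 1], back[, 2], lab_i, geom,
                           config$base_temp_range)
      temps <- base + stats::rnorm(h * w, 0, config$noise_sd)
      if (any(lab_i == 1L)) clean_mean[f + 1L] <- mean(temps[lab_i == 1L])

      inj <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("row", "col", "label")))
      if (config$eyelash_fraction > 0) {
        for (lab in c(1L, 2L)) {
          pool <- which(lab_i == lab)
          n_inj <- floor(config$eyelash_fraction * length(pool))
          if (n_inj < 1L) next
          pick <- sample(pool, n_inj)
          temps[pick] <- mean(temps[pool]) + config$eyelash_temp_offset
          inj <- rbind(inj, cbind(row = (pick - 1L) %% h + 1L,
                                  col = (pick - 1L) %/% h + 1L,
                                  label = lab))
        }
      }
      eyelash_pixels[[f + 1L]] <- inj
      ir[[f + 1L]] <- matrix(round(temps, 4), h, w)
    }
  })

  cps <- rbind(
    data.frame(frame = 0L, point_id = cp0$point_id, space = "VIS",
               x = cp0$x, y = cp0$y, stringsAsFactors = FALSE),
    data.frame(frame = 0L, point_id = cp0$point_id, space = "IR",
               x = cp_ir[, 1], y = cp_ir[, 2],
               stringsAsFactors = FALSE))

  frames <- seq_len(config$n_frames) - 1L
  tracks <- do.call(rbind, lapply(frames, function(f) {
    d <- cps; d$frame <- f; d
  }))
  rownames(tracks) <- NULL

  list(ir = ir, vis = vis, masks = masks,
       landmarks = do.call(rbind, landmarks),
       cps = cps,
       truth = list(true_transform = config$true_transform,
                    eyelash_pixels = eyelash_pixels,
                    blink_frames = config$blink_frames,
                    true_cp_tracks = tracks,
                    landmarks = do.call(rbind, landmarks),
                    masks_ir = masks_ir,
                    clean_cornea_mean = clean_mean))
}

#' Simulate control-point tracking drift
#'
#' Optical-flow trackers accumulate small frame-to-frame localisation
#' errors ("tracking drift"). This models the drift of each non-anchored
#' point as a 2-D Gaussian random walk with per-frame increments of
#' standard deviation \code{drift_sd}; anchored points (fiducial-marker
#' analogues) and frame 0 are returned unperturbed.
#'
#' @param true_tracks data.frame (\code{frame}, \code{point_id}, optionally
#'   \code{space}, \code{x}, \code{y}) covering frames 0..T-1. When a
#'   \code{space} column is present, drift is drawn independently per
#'   space (the two cameras are tracked independently).
#' @param drift_sd per-frame increment standard deviation in pixels.
#' @param anchored_ids point ids exempt from drift.
#' @param seed integer RNG seed.
#' @return data.frame of the same shape with perturbed coordinates.
#' @export
simulate_cp_drift <- function(true_tracks, drift_sd, anchored_ids = character(),
                              seed = 1L) {
  check_cp_table(true_tracks, "true_tracks")
  if (drift_sd < 0) stopf("drift_sd must be non-negative")
  out <- true_tracks
  if (drift_sd == 0) return(out)
  frames <- sort(unique(out$frame))
  n_steps <- length(frames) - 1L
  if (n_steps < 1L) return(out)
  space <- if ("space" %in% names(out)) out$space else ""
  keys <- unique(data.frame(space = space, point_id = out$point_id,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$space, keys$point_id), , drop = FALSE]
  with_seed(seed, {
    for (ki in seq_len(nrow(keys))) {
      if (keys$point_id[ki] %in% anchored_ids) next
      walk_x <- cumsum(stats::rnorm(n_steps, 0, drift_sd))
      walk_y <- cumsum(stats::rnorm(n_steps, 0, drift_sd))
      sel <- out$point_id == keys$point_id[ki] & space == keys$space[ki]
      rows <- which(sel)
      rows <- rows[order(out$frame[rows])]
      moving <- rows[match(frames[-1], out$frame[rows])]
      out$x[moving] <- out$x[moving] + walk_x
      out$y[moving] <- out$y[moving] + walk_y
    }
  })
  out
}
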