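#' Temperature statistics for one cleaned ROI
#'
#' Summarises the retained (post eyelash-removal) pixels of one ROI in one
#' frame: pixel count, mean, population standard deviation, minimum and
#' maximum, in degrees C. An empty retained set yields an excluded record
#' with reason \code{"no_cornea"}.
#'
#' @param frame numeric temperature matrix.
#' @param cleaned a \code{cleaned_roi} from \code{\link{remove_eyelashes}}.
#' @param frame_index 0-based frame index recorded in the output row.
#' @return one-row data.frame in the profile schema.
#' @export
roi_statistics <- function(frame, cleaned, frame_index = 0L) {
  stopifnot(inherits(cleaned, "cleaned_roi"))
  ret <- cleaned$retained
  if (nrow(ret) > 0L &&
        (max(ret[, 1]) > nrow(frame) || max(ret[, 2]) > ncol(frame) ||
           min(ret) < 1L)) {
    stopf("retained pixel coordinates out of frame bounds")
  }
  if (nrow(ret) == 0L) {
    return(data.frame(frame = as.integer(frame_index), roi = cleaned$label,
                      n_pixels = NA_integer_, mean_c = NA_real_,
                      sd_c = NA_real_, min_c = NA_real_, max_c = NA_real_,
                      excluded = 1L, exclusion_reason = "no_cornea",
                      stringsAsFactors = FALSE))
  }
  temps <- frame[ret]
  data.frame(frame = as.integer(frame_index), roi = cleaned$label,
             n_pixels = nrow(ret), mean_c = mean(temps),
             sd_c = pop_sd(temps), min_c = min(temps), max_c = max(temps),
             excluded = 0L, exclusion_reason = "",
             stringsAsFactors = FALSE)
}

excluded_record <- function(frame_index, roi, reason) {
  data.frame(frame = as.integer(frame_index), roi = roi,
             n_pixels = NA_integer_, mean_c = NA_real_, sd_c = NA_real_,
             min_c = NA_real_, max_c = NA_real_, excluded = 1L,
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Flat configuration for \code{\link{run_pipeline}}. Every field has a
#' documented default; \code{\link{read_pipeline_config}} parses the same
#' fields from a \code{key = value} file and rejects unknown keys.
#'
#' @param input_dir sequence directory (layout of
#'   \code{\link{write_sequence}}).
#' @param output_dir directory for pipeline outputs.
#' @param mode control-point following mode, \code{"static"} or
#'   \code{"flow"}.
#' @param anchored_ids point ids pinned at their frame-0 position in flow
#'   mode (fiducial markers).
#' @param transform_ids the 3 point ids defining the per-frame transform;
#'   default: the first 3 ids in file order.
#' @param sigma_k sigma multiplier for eyelash outlier bounds.
#' @param ear_threshold EAR blink threshold.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            mode = c("static", "flow"),
                            anchored_ids = character(),
                            transform_ids = NULL,
                            sigma_k = 2.0, ear_threshold = 0.3) {
  mode <- match.arg(mode)
  if (sigma_k <= 0) stopf("sigma_k must be positive")
  if (ear_threshold <= 0) stopf("ear_threshold must be positive")
  if (!is.null(transform_ids) && length(transform_ids) != 3L) {
    stopf("transform_ids must name exactly 3 points")
  }
  structure(list(input_dir = input_dir, output_dir = output_dir, mode = mode,
                 anchored_ids = anchored_ids, transform_ids = transform_ids,
                 sigma_k = sigma_k, ear_threshold = ear_threshold),
            class = "pipeline_config")
}

#' Read a flat key-value pipeline configuration file
#'
#' Lines of the form \code{key = value} (\code{#} comments and blank lines
#' ignored). Recognised keys: \code{input_dir}, \code{output_dir},
#' \code{mode}, \code{anchored_ids}, \code{transform_ids} (comma-separated),
#' \code{sigma_k}, \code{ear_threshold}. Unknown keys are rejected.
#'
#' @param path config file path.
#' @param overrides named list of values taking precedence over the file.
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stopf("malformed config line: '%s'", ln)
    kv[[trimws(parts[1])]] <- trimws(parts[2])
  }
  known <- c("input_dir", "output_dir", "mode", "anchored_ids",
             "transform_ids", "sigma_k", "ear_threshold")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0L) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  kv[names(overrides)] <- overrides
  split_ids <- function(v) {
    if (is.null(v) || !nzchar(v)) character() else trimws(strsplit(v, ",")[[1]])
  }
  pipeline_config(
    input_dir = kv$input_dir %||% stopf("config must set input_dir"),
    output_dir = kv$output_dir %||% stopf("config must set output_dir"),
    mode = kv$mode %||% "static",
    anchored_ids = split_ids(kv$anchored_ids),
    transform_ids = if (is.null(kv$transform_ids)) NULL else split_ids(kv$transform_ids),
    sigma_k = as.numeric(kv$sigma_k %||% 2.0),
    ear_threshold = as.numeric(kv$ear_threshold %||% 0.3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full temperature-extraction pipeline
#'
#' Stages, in order: control-point following, per-frame VIS-to-IR affine
#' estimation, mask mapping into the IR frame, blink detection (blink
#' frames skip all temperature stages and are emitted as excluded
#' records), eyelash outlier removal, ROI statistics, profile output. In
#' static mode every per-frame output is a pure deterministic function of
#' that frame's inputs plus the frame-0 control points.
#'
#' Outputs written to \code{output_dir}: \code{profile.csv},
#' \code{transforms.csv} (frame + 6 row-major coefficients),
#' \code{tracked_cps.csv}, \code{blinks.csv}
#' (\code{frame,ear,is_blink,reason}) and \code{removed/frame_00000.csv}
#' (\code{row,col,label,temp_c}, 0-based coordinates) for non-excluded
#' frames. On a hard error, partial outputs are removed and the error
#' names the stage and frame.
#'
#' @param config \code{pipeline_config}.
#' @return the temperature profile data.frame, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_files <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(out_files, recursive = TRUE), add = TRUE)

  stage <- "read"
  result <- tryCatch({
    seq <- read_sequence(config$input_dir)
    for (need in c("masks", "landmarks", "cps")) {
      if (is.null(seq[[need]])) stopf("pipeline requires the %s component", need)
    }
    if (config$mode == "flow" && is.null(seq$vis)) {
      stopf("flow mode requires the vis component")
    }
    n <- seq$n_frames
    cps0 <- seq$cps[seq$cps$frame == 0L, ]
    vis0 <- cps0[cps0$space == "VIS", ]
    ir0 <- cps0[cps0$space == "IR", ]
    if (nrow(vis0) < 3L || !setequal(vis0$point_id, ir0$point_id)) {
      stopf("frame-0 control points must cover >= 3 shared ids in both spaces")
    }
    transform_ids <- config$transform_ids %||% vis0$point_id[1:3]

    stage <- "cp_following"
    log_stage(stage, 0L, n)
    # Landmark-only blink screen up front: the tracker must not update
    # through frames whose appearance is dominated by the closed lid.
    pre_blinks <- detect_blinks(seq$landmarks, cornea_masks = NULL,
                                threshold = config$ear_threshold)
    hold <- pre_blinks$frame[pre_blinks$is_blink]
    if (config$mode == "static") {
      vis_frames <- seq$vis %||% seq$ir
      vis_tracks <- follow_cps(vis_frames, vis0, mode = "static")
      ir_tracks <- follow_cps(seq$ir, ir0, mode = "static")
    } else {
      vis_tracks <- follow_cps(seq$vis, vis0, mode = "flow",
                               anchored_ids = config$anchored_ids,
                               hold_frames = hold)
      ir_gray <- lapply(seq$ir, function(m) {
        rng <- range(m); if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng) * 255
      })
      ir_tracks <- follow_cps(ir_gray, ir0, mode = "flow",
                              anchored_ids = config$anchored_ids,
                              hold_frames = hold)
    }

    stage <- "registration"
    transforms <- vector("list", n)
    mapped <- vector("list", n)
    for (f in seq_len(n) - 1L) {
      if (f %% 100L == 0L) log_stage(stage, f, n)
      tr <- register_frame(ir_tracks[ir_tracks$frame == f, ],
                           vis_tracks[vis_tracks$frame == f, ],
                           transform_ids)
      transforms[[f + 1L]] <- tr
      mapped[[f + 1L]] <- map_mask(seq$masks[[f + 1L]], tr,
                                   dim(seq$ir[[f + 1L]]))
    }

    stage <- "blink_detection"
    log_stage(stage, 0L, n)
    blinks <- detect_blinks(seq$landmarks, cornea_masks = mapped,
                            threshold = config$ear_threshold)

    stage <- "eyelash_removal"
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    removed_dir <- file.path(config$output_dir, "removed")
    dir.create(removed_dir, showWarnings = FALSE)
    out_files <- c(out_files, removed_dir)
    profile_rows <- list()
    for (f in seq_len(n) - 1L) {
      if (f %% 100L == 0L) log_stage(stage, f, n)
      brec <- blinks[blinks$frame == f, ]
      if (nrow(brec) == 1L && brec$is_blink) {
        reason <- if (brec$reason == "ear_below_threshold") "blink_ear" else "no_cornea"
        profile_rows[[length(profile_rows) + 1L]] <-
          rbind(excluded_record(f, "cornea", reason),
                excluded_record(f, "sclera", reason))
        next
      }
      msk <- mapped[[f + 1L]]
      if (!any(msk == 1L)) {
        profile_rows[[length(profile_rows) + 1L]] <-
          rbind(excluded_record(f, "cornea", "no_cornea"),
                excluded_record(f, "sclera", "no_cornea"))
        next
      }
      cleaned <- remove_eyelashes(seq$ir[[f + 1L]], msk, k = config$sigma_k)
      rows <- lapply(c("cornea", "sclera"), function(roi) {
        if (is.null(cleaned[[roi]])) return(excluded_record(f, roi, "no_cornea"))
        roi_statistics(seq$ir[[f + 1L]], cleaned[[roi]], f)
      })
      profile_rows[[length(profile_rows) + 1L]] <- do.call(rbind, rows)
      rem <- do.call(rbind, lapply(cleaned, function(cl) {
        if (nrow(cl$removed) == 0L) return(NULL)
        data.frame(row = cl$removed[, 1] - 1L, col = cl$removed[, 2] - 1L,
                   label = if (cl$label == "cornea") 1L else 2L,
                   temp_c = sprintf("%.4f", cl$removed_temps),
                   stringsAsFactors = FALSE)
      }))
      if (is.null(rem)) {
        rem <- data.frame(row = integer(0), col = integer(0),
                          label = integer(0), temp_c = character(0))
      }
      utils::write.csv(rem, file.path(removed_dir, sprintf("frame_%05d.csv", f)),
                       row.names = FALSE, quote = FALSE)
    }

    stage <- "profile_output"
    log_stage(stage, n, n)
    profile <- do.call(rbind, profile_rows)
    profile <- profile[order(profile$frame, profile$roi), ]
    rownames(profile) <- NULL

    paths <- file.path(config$output_dir,
                       c("profile.csv", "transforms.csv", "tracked_cps.csv",
                         "blinks.csv"))
    out_files <- c(out_files, paths)
    write_profile(profile, paths[1])
    tdf <- data.frame(frame = seq_len(n) - 1L,
                      do.call(rbind, lapply(transforms, function(m) {
                        v <- as.vector(t(unclass(m)))
                        stats::setNames(as.data.frame(t(v)),
                                        c("a11", "a12", "a13", "a21", "a22", "a23"))
                      })))
    utils::write.csv(tdf, paths[2], row.names = FALSE, quote = FALSE)
    tracked <- rbind(cbind(vis_tracks[, c("frame", "point_id")], space = "VIS",
                           vis_tracks[, c("x", "y")]),
                     cbind(ir_tracks[, c("frame", "point_id")], space = "IR",
                           ir_tracks[, c("x", "y")]))
    utils::write.csv(tracked, paths[3], row.names = FALSE, quote = FALSE)
    utils::write.csv(blinks, paths[4], row.names = FALSE, quote = FALSE)
    profile
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  ok <- TRUE
  invisible(result)
}

log_stage <- function(stage, frame, n_frames) {
  message(sprintf("[%s] frame %d/%d", stage, frame, n_frames))
}
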