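#' Write a phantom or imported sequence to a directory
#'
#' Layout: \code{ir/frame_00000.csv} (comma-separated temperature matrices,
#' degrees C, 4 decimals, row-major), \code{vis/frame_00000.png} (8-bit
#' grayscale), \code{masks/frame_00000.png} (8-bit with values 0/1/2),
#' \code{landmarks.csv} (\code{frame,point,x,y}), \code{cps.csv} (frame-0
#' annotations, \code{frame,point_id,space,x,y}). When ground truth is
#' present: \code{true_cps.csv} (all frames, both spaces) and
#' \code{ground_truth.json} (transform as 6 row-major numbers, blink frame
#' list, per-frame artifact pixel lists with 0-based row/col, and the
#' clean cornea surface means). All coordinates are 0-based with x = column
#' and y = row, pixel centres at integer coordinates.
#'
#' @param seq list as returned by \code{\link{generate_sequence}} (the
#'   \code{truth} element is optional).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(file.path(dir, "ir"), recursive = TRUE, showWarnings = FALSE)
  n <- length(seq$ir)
  for (f in seq_len(n) - 1L) {
    write_thermal_csv(seq$ir[[f + 1L]],
                      file.path(dir, "ir", sprintf("frame_%05d.csv", f)))
  }
  if (!is.null(seq$vis)) {
    dir.create(file.path(dir, "vis"), showWarnings = FALSE)
    for (f in seq_len(n) - 1L) {
      png::writePNG(seq$vis[[f + 1L]] / 255,
                    file.path(dir, "vis", sprintf("frame_%05d.png", f)))
    }
  }
  if (!is.null(seq$masks)) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (f in seq_len(n) - 1L) {
      png::writePNG(seq$masks[[f + 1L]] / 255,
                    file.path(dir, "masks", sprintf("frame_%05d.png", f)))
    }
  }
  if (!is.null(seq$landmarks)) {
    utils::write.csv(seq$landmarks, file.path(dir, "landmarks.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(seq$cps)) {
    utils::write.csv(seq$cps, file.path(dir, "cps.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(seq$truth)) {
    tr <- seq$truth
    utils::write.csv(tr$true_cp_tracks, file.path(dir, "true_cps.csv"),
                     row.names = FALSE, quote = FALSE)
    gt <- list(
      transform = as.vector(t(unclass(tr$true_transform))),
      blink_frames = as.integer(tr$blink_frames),
      eyelash_pixels = lapply(tr$eyelash_pixels, function(m) {
        if (nrow(m) == 0L) return(list())
        # serialized 0-based per the directory convention
        lapply(seq_len(nrow(m)), function(i) {
          list(row = unname(m[i, "row"]) - 1L, col = unname(m[i, "col"]) - 1L,
               label = unname(m[i, "label"]))
        })
      }),
      clean_cornea_mean_c = tr$clean_cornea_mean)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  }
  invisible(dir)
}

write_thermal_csv <- function(mat, path) {
  lines <- apply(mat, 1, function(r) paste(sprintf("%.4f", r), collapse = ","))
  writeLines(lines, path)
}

read_thermal_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  w <- length(rows[[1]])
  if (any(lengths(rows) != w)) stopf("%s: ragged rows", path)
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  mat <- matrix(vals, nrow = length(rows), ncol = w, byrow = TRUE)
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("%s: non-finite temperature at row %d, col %d (1-based)",
          path, bad[1, 1], bad[1, 2])
  }
  if (any(mat < 15 | mat > 45)) {
    warnf("%s: temperatures outside the plausible 15-45 degC band", path)
  }
  mat
}

check_frame_files <- function(dir, pattern, what) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stopf("no %s frames found in %s", what, dir)
  idx <- as.integer(sub(".*frame_(\\d+)\\..*", "\\1", basename(files)))
  expected <- seq_along(files) - 1L
  if (!identical(idx, expected)) {
    gap <- setdiff(expected, idx)[1]
    stopf("%s frame numbering is not contiguous from 0 (missing frame %d)",
          what, if (is.na(gap)) idx[which(idx != expected)[1]] else gap)
  }
  files
}

read_gray_png <- function(path, scale = 255) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * scale)
}

#' Read a sequence directory
#'
#' Reads the layout written by \code{\link{write_sequence}}. Only the
#' \code{ir/} component is mandatory; missing optional components are
#' returned as \code{NULL}, never defaulted. Malformed content (gaps in
#' frame numbering, IR/VIS frame-count mismatch, non-finite temperature
#' cells) is a hard error naming the offender.
#'
#' @param dir sequence directory.
#' @return list with \code{ir}, \code{vis}, \code{masks} (lists of
#'   matrices or NULL), \code{landmarks}, \code{cps} (data.frames or NULL),
#'   \code{n_frames}.
#' @export
read_sequence <- function(dir) {
  if (!dir.exists(file.path(dir, "ir"))) {
    stopf("sequence directory %s has no ir/ component", dir)
  }
  ir_files <- check_frame_files(file.path(dir, "ir"), "^frame_\\d+\\.csv$", "IR")
  ir <- lapply(ir_files, read_thermal_csv)
  n <- length(ir)

  vis <- masks <- landmarks <- cps <- NULL
  if (dir.exists(file.path(dir, "vis"))) {
    vf <- check_frame_files(file.path(dir, "vis"), "^frame_\\d+\\.png$", "VIS")
    if (length(vf) != n) {
      stopf("IR/VIS frame-count mismatch: %d IR vs %d VIS", n, length(vf))
    }
    vis <- lapply(vf, read_gray_png)
  }
  if (dir.exists(file.path(dir, "masks"))) {
    mf <- check_frame_files(file.path(dir, "masks"), "^frame_\\d+\\.png$", "mask")
    if (length(mf) != n) {
      stopf("IR/mask frame-count mismatch: %d IR vs %d masks", n, length(mf))
    }
    masks <- lapply(mf, function(p) {
      m <- read_gray_png(p)
      if (!all(m %in% c(0, 1, 2))) stopf("%s: mask labels outside {0, 1, 2}", p)
      matrix(as.integer(m), nrow = nrow(m))
    })
  }
  lm_path <- file.path(dir, "landmarks.csv")
  if (file.exists(lm_path)) {
    landmarks <- utils::read.csv(lm_path, stringsAsFactors = FALSE)
    if (!all(c("frame", "point", "x", "y") %in% names(landmarks))) {
      stopf("%s: expected columns frame,point,x,y", lm_path)
    }
  }
  cp_path <- file.path(dir, "cps.csv")
  if (file.exists(cp_path)) {
    cps <- utils::read.csv(cp_path, stringsAsFactors = FALSE)
    check_cp_table(cps, "cps.csv", require_space = TRUE)
  }
  list(ir = ir, vis = vis, masks = masks, landmarks = landmarks, cps = cps,
       n_frames = n)
}

#' Read a phantom ground-truth file
#'
#' Parses \code{ground_truth.json} back into the in-memory convention
#' (1-based artifact row/col).
#'
#' @param path path to \code{ground_truth.json}.
#' @return list with \code{true_transform}, \code{blink_frames},
#'   \code{eyelash_pixels}, \code{clean_cornea_mean}.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(
    true_transform = affine_transform(matrix(unlist(gt$transform), nrow = 2,
                                             byrow = TRUE)),
    blink_frames = as.integer(unlist(gt$blink_frames)),
    eyelash_pixels = lapply(gt$eyelash_pixels, function(px) {
      if (length(px) == 0L) {
        return(matrix(integer(0), ncol = 3,
                      dimnames = list(NULL, c("row", "col", "label"))))
      }
      do.call(rbind, lapply(px, function(p) {
        cbind(row = p$row + 1L, col = p$col + 1L, label = p$label)
      }))
    }),
    clean_cornea_mean = vapply(gt$clean_cornea_mean_c,
                               function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                               numeric(1)))
}

profile_columns <- c("frame", "roi", "n_pixels", "mean_c", "sd_c", "min_c",
                     "max_c", "excluded", "exclusion_reason")

#' Write a temperature profile CSV
#'
#' Schema: \code{frame,roi,n_pixels,mean_c,sd_c,min_c,max_c,excluded,}
#' \code{exclusion_reason}; floats carry 4 decimal places; excluded rows
#' (blink or empty-cornea frames) have empty statistics fields, with
#' \code{excluded} 1 and a reason of \code{"blink_ear"} or
#' \code{"no_cornea"}.
#'
#' @param profile data.frame with the columns above (statistics numeric,
#'   NA on excluded rows), sorted by frame then ROI.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profile <- function(profile, path) {
  if (!all(profile_columns %in% names(profile))) {
    stopf("profile is missing column(s): %s",
          paste(setdiff(profile_columns, names(profile)), collapse = ", "))
  }
  if (nrow(profile) > 0L) {
    key <- paste(profile$frame, profile$roi)
    if (anyDuplicated(key)) stopf("duplicate (frame, roi) rows in profile")
    if (!identical(order(profile$frame, profile$roi), seq_len(nrow(profile)))) {
      stopf("profile rows must be sorted by frame, then roi")
    }
  }
  header <- paste(profile_columns, collapse = ",")
  body <- if (nrow(profile) == 0L) character(0) else {
    paste(profile$frame,
          profile$roi,
          ifelse(is.na(profile$n_pixels), "", profile$n_pixels),
          fmt_num(profile$mean_c), fmt_num(profile$sd_c),
          fmt_num(profile$min_c), fmt_num(profile$max_c),
          profile$excluded,
          profile$exclusion_reason,
          sep = ",")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a temperature profile CSV
#'
#' @param path path written by \code{\link{write_profile}}.
#' @return data.frame in the in-memory profile representation (empty
#'   statistics fields become NA).
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), profile_columns)) {
    stopf("%s: unexpected profile header", path)
  }
  to_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  data.frame(frame = as.integer(df$frame), roi = df$roi,
             n_pixels = as.integer(to_num(df$n_pixels)),
             mean_c = to_num(df$mean_c), sd_c = to_num(df$sd_c),
             min_c = to_num(df$min_c), max_c = to_num(df$max_c),
             excluded = as.integer(df$excluded),
             exclusion_reason = ifelse(is.na(df$exclusion_reason), "",
                                       df$exclusion_reason),
             stringsAsFactors = FALSE)
}
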