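test_that("roi_statistics summarises retained pixels with the population SD", {
  frame <- matrix(34, 6, 6)
  cleaned <- structure(list(label = "cornea",
                            retained = which(frame == 34, arr.ind = TRUE),
                            removed = matrix(integer(0), ncol = 2),
                            removed_temps = numeric(0)),
                       class = "cleaned_roi")
  rec <- roi_statistics(frame, cleaned, 0L)
  expect_equal(rec$mean_c, 34); expect_equal(rec$sd_c, 0)
  expect_equal(rec$min_c, 34); expect_equal(rec$max_c, 34)
  expect_equal(rec$n_pixels, 36L)

  # two-point hand computation: mean 34, population sd 2
  frame2 <- matrix(c(32, 36), 1, 2)
  cleaned2 <- structure(list(label = "cornea",
                             retained = cbind(row = c(1L, 1L), col = c(1L, 2L)),
                             removed = matrix(integer(0), ncol = 2),
                             removed_temps = numeric(0)),
                        class = "cleaned_roi")
  rec2 <- roi_statistics(frame2, cleaned2, 3L)
  expect_equal(c(rec2$mean_c, rec2$sd_c, rec2$min_c, rec2$max_c),
               c(34, 2, 32, 36))

  # empty retained set -> excluded record
  cleaned3 <- cleaned2
  cleaned3$retained <- cleaned3$retained[0, , drop = FALSE]
  rec3 <- roi_statistics(frame2, cleaned3, 1L)
  expect_equal(rec3$excluded, 1L)
  expect_identical(rec3$exclusion_reason, "no_cornea")
  expect_true(is.na(rec3$mean_c))

  cleaned4 <- cleaned2
  cleaned4$retained <- cbind(5L, 9L)
  expect_error(roi_statistics(frame2, cleaned4, 0L), "bounds")
})

test_that("with nothing to remove the pipeline reduces to the plain ROI mean", {
  cfg <- phantom_config(n_frames = 3L, image_size = c(48L, 48L),
                        eyelash_fraction = 0, noise_sd = 0,
                        true_transform = affine_transform(
                          rbind(c(1, 0, 0), c(0, 1, 0))),
                        seed = 5L)
  s <- generate_sequence(cfg)
  d <- withr::local_tempdir()
  write_sequence(s, d)
  prof <- suppressMessages(run_pipeline(pipeline_config(d, file.path(d, "out"))))
  for (f in 0:2) {
    direct <- mean(s$ir[[f + 1]][s$truth$masks_ir[[f + 1]] == 1L])
    expect_equal(prof$mean_c[prof$frame == f & prof$roi == "cornea"], direct,
                 tolerance = 1e-9)
  }
})

test_that("blink frames are emitted as excluded rows, and cleaning never lowers the cornea mean", {
  cfg <- phantom_config(n_frames = 6L, image_size = c(48L, 48L),
                        blink_frames = 5L, seed = 9L)
  s <- generate_sequence(cfg)
  d <- withr::local_tempdir()
  write_sequence(s, d)
  prof <- suppressMessages(run_pipeline(pipeline_config(d, file.path(d, "out"))))

  blink_rows <- prof[prof$frame == 5L, ]
  expect_true(all(blink_rows$excluded == 1L))
  expect_true(all(blink_rows$exclusion_reason == "blink_ear"))
  expect_true(all(is.na(blink_rows$mean_c)))
  expect_true(all(prof$excluded[prof$frame != 5L] == 0L))

  # cold-only artifacts: removing outliers can only raise the cornea mean
  tr <- read.csv(file.path(d, "out", "transforms.csv"))
  for (f in 0:4) {
    m <- map_mask(s$masks[[f + 1]],
                  affine_transform(matrix(as.numeric(tr[tr$frame == f, -1]),
                                          2, 3, byrow = TRUE)),
                  dim(s$ir[[f + 1]]))
    raw_mean <- mean(s$ir[[f + 1]][m == 1L])
    expect_gte(prof$mean_c[prof$frame == f & prof$roi == "cornea"],
               raw_mean - 1e-12)
  }

  # static mode is end-to-end deterministic, byte for byte
  prof2 <- suppressMessages(run_pipeline(pipeline_config(d, file.path(d, "out2"))))
  expect_identical(readLines(file.path(d, "out", "profile.csv")),
                   readLines(file.path(d, "out2", "profile.csv")))
})

test_that("the full pipeline recovers the clean cornea surface temperature", {
  cfg <- phantom_config(n_frames = 8L, blink_frames = c(2L, 6L), seed = 21L)
  s <- generate_sequence(cfg)
  d <- withr::local_tempdir()
  write_sequence(s, d)
  prof <- suppressMessages(run_pipeline(pipeline_config(d, file.path(d, "out"))))
  inc <- prof$roi == "cornea" & prof$excluded == 0L
  expect_identical(sort(prof$frame[prof$roi == "cornea" & prof$excluded == 1L]),
                   c(2L, 6L))
  err <- abs(prof$mean_c[inc] - s$truth$clean_cornea_mean[prof$frame[inc] + 1L])
  expect_lt(max(err), 0.1)
})

test_that("flow-mode tracking holds through blink frames and keeps registration exact", {
  # noise- and artifact-free phantom: the visible content is static except
  # for the scripted blink, so a tracker that updates through the closed
  # lid would be pulled away while a held one must stay exact
  cfg <- phantom_config(n_frames = 6L, blink_frames = 2L,
                        eyelash_fraction = 0, noise_sd = 0, seed = 13L)
  s <- generate_sequence(cfg)
  d <- withr::local_tempdir()
  write_sequence(s, d)
  prof <- suppressMessages(run_pipeline(pipeline_config(
    d, file.path(d, "out"), mode = "flow", anchored_ids = c("M1", "M2"))))
  expect_identical(prof$exclusion_reason[prof$frame == 2L],
                   c("blink_ear", "blink_ear"))
  # the per-frame transform must be recovered exactly on every frame,
  # including the ones after the blink
  tdf <- read.csv(file.path(d, "out", "transforms.csv"))
  for (i in seq_len(nrow(tdf))) {
    expect_equal(as.numeric(tdf[i, -1]),
                 as.vector(t(unclass(s$truth$true_transform))),
                 tolerance = 1e-9)
  }
  inc <- prof$roi == "cornea" & prof$excluded == 0L
  # residual difference is ellipse-boundary discretisation only
  err <- abs(prof$mean_c[inc] - s$truth$clean_cornea_mean[prof$frame[inc] + 1L])
  expect_lt(max(err), 0.05)
  tracked <- read.csv(file.path(d, "out", "tracked_cps.csv"))
  vis <- tracked[tracked$space == "VIS", ]
  truth <- s$truth$true_cp_tracks
  tv <- truth[truth$space == "VIS", ]
  expect_lt(cp_rmse(vis[, c("frame", "point_id", "x", "y")],
                    tv[, c("frame", "point_id", "x", "y")]), 1e-6)
})

test_that("pipeline configuration files parse, validate and override", {
  d <- withr::local_tempdir()
  cfg_path <- file.path(d, "run.cfg")
  writeLines(c("# comment", "input_dir = in", "output_dir = out",
               "mode = flow", "anchored_ids = M1,M2", "sigma_k = 2.5"),
             cfg_path)
  cfg <- read_pipeline_config(cfg_path)
  expect_identical(cfg$mode, "flow")
  expect_identical(cfg$anchored_ids, c("M1", "M2"))
  expect_equal(cfg$sigma_k, 2.5)
  expect_equal(cfg$ear_threshold, 0.3)

  cfg2 <- read_pipeline_config(cfg_path, overrides = list(mode = "static"))
  expect_identical(cfg2$mode, "static")

  writeLines(c("input_dir = in", "output_dir = out", "wibble = 3"), cfg_path)
  expect_error(read_pipeline_config(cfg_path), "unknown config key")
  expect_error(pipeline_config("a", "b", sigma_k = -1), "sigma_k")
})
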