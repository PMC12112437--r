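test_that("estimate_affine interpolates three pairs exactly and validates input", {
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  id <- estimate_affine(tri, tri)
  expect_equal(unclass(id), rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-12,
               ignore_attr = TRUE)

  true_m <- rbind(c(2, 0, 5), c(0, 2, 7))
  src <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tgt <- apply_affine(affine_transform(true_m), src)
  fit <- estimate_affine(src, tgt)
  expect_equal(unclass(fit), true_m, tolerance = 1e-9, ignore_attr = TRUE)
  # exact interpolation of its own defining pairs
  expect_lt(max(abs(apply_affine(fit, src) - tgt)), 1e-9)

  expect_error(estimate_affine(rbind(c(0, 0), c(1, 1), c(2, 2)), tri),
               "collinear.*\\(1, 1\\)")
  expect_error(estimate_affine(tri, tri[1:2, ]), "mismatch")
  expect_error(estimate_affine(tri[1:2, ], tri[1:2, ]), "at least 3")
})

test_that("least-squares fits agree with the normal equations and are unbiased", {
  true_m <- rbind(c(1.2, 0.1, -3), c(-0.2, 0.9, 4))
  true_t <- affine_transform(true_m)
  src <- cbind(c(0, 10, 0, 10, 5, 2, 8, 5), c(0, 0, 10, 10, 5, 7, 3, 1))
  clean <- apply_affine(true_t, src)

  # independent oracle: 6-parameter normal equations solved explicitly
  normal_eq_fit <- function(src, tgt) {
    a <- cbind(src, 1)
    ata <- t(a) %*% a
    rbind(t(solve(ata, t(a) %*% tgt[, 1])), t(solve(ata, t(a) %*% tgt[, 2])))
  }

  withr::with_seed(42, {
    sums <- matrix(0, 2, 3)
    for (r in 1:1000) {
      tgt <- clean + matrix(rnorm(16, 0, 0.5), ncol = 2)
      fit <- estimate_affine(src, tgt)
      expect_equal(unclass(fit), normal_eq_fit(src, tgt), tolerance = 1e-9,
                   ignore_attr = TRUE)
      sums <- sums + unclass(fit)
    }
    # Monte-Carlo unbiasedness: each mean coefficient within ~4 standard
    # errors of the truth (se of the offset coefficients is the largest,
    # about 0.5/sqrt(1000) scaled by the design)
    expect_lt(max(abs(sums / 1000 - true_m)), 0.05)
  })
})

test_that("translation equivariance only shifts the offset column", {
  src <- cbind(c(0, 4, 1, 7), c(0, 1, 5, 6))
  tgt <- cbind(c(2, 9, 3, 15), c(1, 2, 11, 13))
  v <- c(13, -7)
  f1 <- estimate_affine(src, tgt)
  f2 <- estimate_affine(sweep(src, 2, -v), sweep(tgt, 2, -v))
  expect_equal(unclass(f1)[, 1:2], unclass(f2)[, 1:2], tolerance = 1e-9)
})

test_that("register_frame recovers the phantom transform from designated pairs", {
  s <- generate_sequence(small_config())
  cps <- s$cps
  ir <- cps[cps$space == "IR", c("point_id", "x", "y")]
  vis <- cps[cps$space == "VIS", c("point_id", "x", "y")]
  fit <- register_frame(ir, vis, c("M1", "M2", "F1"))
  expect_equal(unclass(fit), unclass(s$truth$true_transform),
               tolerance = 1e-6, ignore_attr = TRUE)

  # identical point sets give the identity
  idt <- register_frame(vis, vis, c("M1", "M2", "F1"))
  expect_equal(unclass(idt), rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # collinear designated triple and absent ids are errors
  col_vis <- data.frame(point_id = c("a", "b", "c", "d"),
                        x = c(0, 1, 2, 5), y = c(0, 1, 2, 9))
  expect_error(register_frame(col_vis, col_vis, c("a", "b", "c")), "collinear")
  expect_error(register_frame(ir, vis, c("M1", "M2", "nope")), "absent")
})

test_that("map_mask is the identity under the identity transform and preserves translated blocks", {
  mask <- matrix(0L, 40, 40)
  mask[10:20, 8:18] <- 1L
  mask[25:30, 20:30] <- 2L
  idt <- affine_transform(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_identical(map_mask(mask, idt, c(40, 40)), mask)

  shift <- affine_transform(rbind(c(1, 0, 5), c(0, 1, 3)))
  shifted <- map_mask(mask, shift, c(40, 40))
  expect_identical(sum(shifted == 1L), sum(mask == 1L))
  expect_identical(shifted[(10 + 3):(20 + 3), (8 + 5):(18 + 5)],
                   mask[10:20, 8:18])
})

test_that("mapped label area scales with the linear-block determinant", {
  h <- 220; w <- 220
  ys <- rep(seq_len(h) - 1, times = w); xs <- rep(seq_len(w) - 1, each = h)
  ell <- ((xs - 80) / 60)^2 + ((ys - 90) / 45)^2 <= 1
  mask <- matrix(as.integer(ell), h, w)
  tr <- affine_transform(rbind(c(1.3, 0, 4), c(0, 1.1, 6)))
  d <- 1.3 * 1.1
  mapped <- map_mask(mask, tr, c(h, w))
  ratio <- sum(mapped == 1L) / sum(mask == 1L)
  expect_equal(ratio, d, tolerance = 0.02)

  expect_error(map_mask(mask + 3L, tr, c(h, w)), "labels")
})

test_that("noiseless registration overlaps the ground-truth cornea mask almost perfectly", {
  cfg <- phantom_config(n_frames = 1L, image_size = c(256L, 256L),
                        eyelash_fraction = 0, noise_sd = 0, seed = 2L)
  s <- generate_sequence(cfg)
  fit <- register_frame(s$cps[s$cps$space == "IR", ],
                        s$cps[s$cps$space == "VIS", ],
                        c("M1", "M2", "F1"))
  mapped <- map_mask(s$masks[[1]], fit, dim(s$ir[[1]]))
  a <- mapped == 1L; b <- s$truth$masks_ir[[1]] == 1L
  jaccard <- sum(a & b) / sum(a | b)
  expect_gte(jaccard, 0.98)   # residual is boundary discretisation only
})

test_that("static CP following returns the frame-0 set for every frame", {
  s <- generate_sequence(small_config())
  init <- s$cps[s$cps$space == "VIS", c("point_id", "x", "y")]
  tracks <- follow_cps(s$vis, init, mode = "static")
  for (f in 0:3) {
    tf <- tracks[tracks$frame == f, ]
    expect_equal(tf$x, init$x)
    expect_equal(tf$y, init$y)
  }
  expect_error(follow_cps(s$vis, init[0, ], mode = "static"), "empty")
})

test_that("patch tracking follows pure translation and is stable on motionless input", {
  withr::with_seed(5, {
    base <- matrix(rnorm(120 * 220), 120, 220)
  })
  # content shifts left by 2 px per frame: a feature at column c appears
  # at c - 2t in frame t
  frames <- lapply(0:19, function(t) base[, (1 + 2 * t):(120 + 2 * t)])
  init <- data.frame(point_id = c("a", "b"), x = c(70, 60), y = c(60, 40))
  tracks <- follow_cps(frames, init, mode = "flow")
  last <- tracks[tracks$frame == 19, ]
  expect_lt(max(abs(last$x - (init$x - 38))), 0.5)
  expect_lt(max(abs(last$y - init$y)), 0.5)

  # motionless textured sequence: points stay put
  still <- lapply(1:10, function(i) base[, 1:120])
  tr2 <- follow_cps(still, init, mode = "flow")
  expect_lt(max(abs(tr2$x - rep(init$x, 10))), 0.1)
  expect_lt(max(abs(tr2$y - rep(init$y, 10))), 0.1)

  # anchored ids are pinned even under motion
  tr3 <- follow_cps(frames, init, mode = "flow", anchored_ids = "a")
  a_rows <- tr3[tr3$point_id == "a", ]
  expect_true(all(a_rows$x == 70 & a_rows$y == 60))

  # a point whose patch leaves the image freezes and is flagged
  init_edge <- data.frame(point_id = "e", x = 14, y = 60)
  tre <- follow_cps(frames, init_edge, mode = "flow")
  expect_true(any(tre$frozen))
  frozen_x <- tre$x[tre$frame == 19]
  expect_gte(frozen_x, 9)   # froze at its last in-bounds location
})
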