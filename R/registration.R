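#' Affine transform between image spaces
#'
#' A 2x3 coefficient matrix mapping source pixel coordinates \code{(x, y)}
#' to target coordinates \code{(x', y')} via
#' \deqn{x' = a_{11} x + a_{12} y + a_{13}, \quad
#'       y' = a_{21} x + a_{22} y + a_{23}.}
#' Coordinates follow the package-wide convention: 0-based, \code{x} = column
#' increasing rightward, \code{y} = row increasing downward, pixel centres at
#' integer coordinates.
#'
#' @param coefficients numeric 2x3 matrix (row-major \code{a11..a23}).
#' @return an object of class \code{affine_transform} (a 2x3 matrix).
#' @examples
#' identity_t <- affine_transform(rbind(c(1, 0, 0), c(0, 1, 0)))
#' apply_affine(identity_t, cbind(3, 4))
#' @export
affine_transform <- function(coefficients) {
  m <- as.matrix(coefficients)
  if (!identical(dim(m), c(2L, 3L))) {
    stopf("affine coefficients must form a 2x3 matrix, got %s",
          paste(dim(m), collapse = "x"))
  }
  if (!all(is.finite(m))) stopf("affine coefficients must be finite")
  d <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(d) < 1e-12) {
    stopf("affine transform is not invertible (linear-block determinant %g)", d)
  }
  structure(m, class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> (x, y) -> (x', y')\n")
  print(unclass(x))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform \code{affine_transform}.
#' @param xy n x 2 matrix (or length-2 vector) of \code{(x, y)} coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_affine <- function(transform, xy) {
  stopifnot(inherits(transform, "affine_transform"))
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stopf("xy must have two columns (x, y)")
  m <- unclass(transform)
  out <- xy %*% t(m[, 1:2, drop = FALSE])
  out[, 1] <- out[, 1] + m[1, 3]
  out[, 2] <- out[, 2] + m[2, 3]
  colnames(out) <- c("x", "y")
  out
}

#' Invert an affine transform
#'
#' @param transform \code{affine_transform}.
#' @return the inverse \code{affine_transform}.
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  m <- unclass(transform)
  a <- m[, 1:2, drop = FALSE]
  ainv <- solve(a)
  off <- -ainv %*% m[, 3]
  affine_transform(cbind(ainv, off))
}

# Signed doubled triangle area; used for collinearity checks.
triangle_area2 <- function(p) {
  (p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
    (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])
}

#' Estimate an affine transform from point correspondences
#'
#' With exactly three pairs the transform interpolates them exactly; with
#' more, the least-squares fit minimising the summed squared target-space
#' residuals is returned (solved by QR on the design matrix
#' \code{[x y 1]}).
#'
#' @param source n x 2 matrix of source-space points, n >= 3.
#' @param target n x 2 matrix of corresponding target-space points.
#' @return \code{affine_transform} mapping source to target.
#' @export
estimate_affine <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target)) {
    stopf("point count mismatch: %d source vs %d target points",
          nrow(source), nrow(target))
  }
  n <- nrow(source)
  if (n < 3L) stopf("need at least 3 point pairs, got %d", n)
  if (n == 3L) {
    if (abs(triangle_area2(source)) / 2 <= 1e-6) {
      stopf(paste0(
        "source points are collinear (degenerate triple: ",
        "(%g, %g), (%g, %g), (%g, %g))"),
        source[1, 1], source[1, 2], source[2, 1], source[2, 2],
        source[3, 1], source[3, 2])
    }
  } else {
    centred <- sweep(source, 2, colMeans(source))
    if (qr(centred)$rank < 2L) stopf("source points are collinear")
  }
  design <- cbind(source, 1)
  coef <- qr.solve(design, target)   # 3 x 2
  affine_transform(t(coef))
}

#' Per-frame VIS-to-IR registration from designated control-point pairs
#'
#' Estimates the transform from exactly the three designated point pairs,
#' leaving the remaining pairs untouched for later error assessment (the
#' fiducial-registration-error protocol).
#'
#' @param ir_cps data.frame (\code{point_id}, \code{x}, \code{y}) for one
#'   frame in IR space.
#' @param vis_cps matching data.frame in VIS space (same point ids).
#' @param transform_point_ids character vector of exactly 3 point ids.
#' @return \code{affine_transform} mapping VIS to IR.
#' @export
register_frame <- function(ir_cps, vis_cps, transform_point_ids) {
  check_cp_table(ir_cps, "ir_cps", require_frame = FALSE)
  check_cp_table(vis_cps, "vis_cps", require_frame = FALSE)
  if (length(transform_point_ids) != 3L) {
    stopf("transform_point_ids must name exactly 3 points")
  }
  miss <- setdiff(transform_point_ids, intersect(ir_cps$point_id, vis_cps$point_id))
  if (length(miss) > 0L) {
    stopf("transform point id(s) absent from control points: %s",
          paste(miss, collapse = ", "))
  }
  iv <- ir_cps[match(transform_point_ids, ir_cps$point_id), ]
  vv <- vis_cps[match(transform_point_ids, vis_cps$point_id), ]
  estimate_affine(cbind(vv$x, vv$y), cbind(iv$x, iv$y))
}

#' Map a VIS-space label mask into the IR frame
#'
#' Each IR pixel centre is pulled back through the inverse transform and
#' assigned the VIS label of the nearest pixel centre. Labels are
#' categorical, so no interpolation of label values is performed; pixels
#' that pull back outside the VIS mask get label 0.
#'
#' @param mask integer label matrix in VIS space (0 background, 1 cornea,
#'   2 sclera).
#' @param transform \code{affine_transform} mapping VIS to IR.
#' @param ir_shape integer vector \code{c(height, width)} of the IR frame.
#' @return label matrix of dimension \code{ir_shape} in IR space.
#' @export
map_mask <- function(mask, transform, ir_shape) {
  stopifnot(inherits(transform, "affine_transform"))
  mask <- as.matrix(mask)
  if (!all(as.vector(mask) %in% c(0, 1, 2))) {
    stopf("mask labels must be in {0, 1, 2}")
  }
  h <- as.integer(ir_shape[1]); w <- as.integer(ir_shape[2])
  inv <- invert_affine(transform)
  # All IR pixel centres, 0-based (x = col - 1, y = row - 1).
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  back <- apply_affine(inv, cbind(xs, ys))
  col <- round_half_up(back[, 1]) + 1L
  row <- round_half_up(back[, 2]) + 1L
  ok <- col >= 1L & col <= ncol(mask) & row >= 1L & row <= nrow(mask)
  lab <- integer(h * w)
  lab[ok] <- mask[cbind(row[ok], col[ok])]
  matrix(lab, nrow = h, ncol = w)
}
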