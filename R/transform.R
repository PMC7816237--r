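#' Construct a rigid in-plane transform
#'
#' @param txPx,tyPx translation in pixels (x rightward along columns,
#'   y downward along rows).
#' @param thetaDeg rotation about the image center in degrees.
#' @param converged optimizer convergence flag.
#' @param metricValue final metric value.
#' @return a [RigidTransform-class] object.
#' @export
RigidTransform <- function(txPx = 0, tyPx = 0, thetaDeg = 0,
                           converged = TRUE, metricValue = NA_real_) {
  new("RigidTransform", txPx = txPx, tyPx = tyPx, thetaDeg = thetaDeg,
      converged = converged, metricValue = metricValue)
}

isIdentityTransform <- function(tf, tol = 1e-12) {
  abs(tf@txPx) < tol && abs(tf@tyPx) < tol && abs(tf@thetaDeg) < tol
}

#' Apply a rigid transform to an image
#'
#' Moves the image content: each point `p` (pixel units, about the image
#' center) maps to `R(theta) (p - c) + c + t`. The output is produced by
#' inverse mapping with bilinear interpolation; output pixels whose
#' source location falls outside the input grid get `fill`.
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param tf a [RigidTransform-class].
#' @param fill value for out-of-bounds pixels (default `NA`).
#' @return transformed matrix of the same dimensions. The attribute
#'   `"inBounds"` carries the logical matrix of pixels whose source lay
#'   inside the input grid.
#' @export
applyTransform <- function(img, tf, fill = NA_real_) {
  stopifnot(is.matrix(img), is(tf, "RigidTransform"))
  if (isIdentityTransform(tf)) {
    out <- img
    attr(out, "inBounds") <- matrix(TRUE, nrow(img), ncol(img))
    return(out)
  }
  ny <- nrow(img); nx <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- tf@thetaDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  # inverse map: source = R(-theta) (dest - c - t) + c
  dx <- rep(seq_len(nx), each = ny) - cx - tf@txPx
  dy <- rep(seq_len(ny), times = nx) - cy - tf@tyPx
  sx <- ct * dx + st * dy + cx
  sy <- -st * dx + ct * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  v <- rep(fill, nx * ny)
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k - 1) * ny + y0k
    v[ok] <- (1 - fxk) * ((1 - fyk) * img[i00] + fyk * img[i00 + 1]) +
      fxk * ((1 - fyk) * img[i00 + ny] + fyk * img[i00 + ny + 1])
  }
  out <- matrix(v, ny, nx)
  attr(out, "inBounds") <- matrix(ok, ny, nx)
  out
}

#' Compose and invert rigid transforms
#'
#' `composeTransforms(t2, t1)` returns the transform equivalent to
#' applying `t1` first and then `t2`; `invertTransform(t)` returns the
#' transform undoing `t`.
#'
#' @param t1,t2,tf [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(t2, t1) {
  th2 <- t2@thetaDeg * pi / 180
  ct <- cos(th2); st <- sin(th2)
  tx <- ct * t1@txPx - st * t1@tyPx + t2@txPx
  ty <- st * t1@txPx + ct * t1@tyPx + t2@tyPx
  RigidTransform(tx, ty, t1@thetaDeg + t2@thetaDeg,
                 converged = t1@converged && t2@converged)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(tf) {
  th <- tf@thetaDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  RigidTransform(-(ct * tf@txPx + st * tf@tyPx),
                 -(-st * tf@txPx + ct * tf@tyPx),
                 -tf@thetaDeg, converged = tf@converged)
}

# Transform a logical mask (nearest-equivalent: bilinear then threshold).
transformMask <- function(mask, tf) {
  m <- applyTransform(mask * 1, tf, fill = 0)
  out <- m > 0.5
  attributes(out) <- list(dim = dim(m))
  out
}

# 2x2 mean pooling for multi-resolution registration; trims odd edges.
downsample2 <- function(img) {
  ny <- nrow(img) %/% 2 * 2; nx <- ncol(img) %/% 2 * 2
  img <- img[seq_len(ny), seq_len(nx), drop = FALSE]
  0.25 * (img[seq(1, ny, 2), seq(1, nx, 2)] + img[seq(2, ny, 2), seq(1, nx, 2)] +
          img[seq(1, ny, 2), seq(2, nx, 2)] + img[seq(2, ny, 2), seq(2, nx, 2)])
}
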