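#' Rigid-body transform
#'
#' Translation plus rotation about the image centre, the transform family used
#' to align serial periapical radiographs taken with the paralleling
#' technique. Applying the transform maps a point `u = (x, y)` (0-based pixel
#' coordinates, x right, y down) to `R(theta) (u - c) + c + (dx, dy)`, where
#' `c` is the image centre.
#'
#' @param dx,dy Translation in pixels (x right, y down).
#' @param theta Rotation in degrees, counter-clockwise in the (x, y) frame.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta))
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf(
    "<rigid_transform> dx=%.4f px, dy=%.4f px, theta=%.4f deg\n",
    x$dx, x$dy, x$theta
  ))
  obj <- attr(x, "objective")
  if (!is.null(obj)) cat(sprintf("  objective (MSE): %.4f\n", obj))
  invisible(x)
}

rot2 <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Invert a rigid transform
#'
#' Composing a transform with its inverse yields the identity to within
#' numerical precision.
#'
#' @param tf A [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  Rinv <- rot2(-tf$theta)
  d <- -Rinv %*% c(tf$dx, tf$dy)
  rigid_transform(d[1], d[2], -tf$theta)
}

#' Compose two rigid transforms
#'
#' @param t2,t1 [rigid_transform()]s; the result applies `t1` first, then `t2`.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  R2 <- rot2(t2$theta)
  d <- R2 %*% c(t1$dx, t1$dy) + c(t2$dx, t2$dy)
  rigid_transform(d[1], d[2], t1$theta + t2$theta)
}

# Bilinear sample of `mat` at 0-based coordinates (X, Y); returns list of
# values (0 outside support) and a validity flag per sample.
bilinear_sample <- function(mat, X, Y) {
  h <- nrow(mat)
  w <- ncol(mat)
  valid <- X >= 0 & X <= (w - 1) & Y >= 0 & Y <= (h - 1)
  x0 <- floor(X)
  y0 <- floor(Y)
  # clamp so the 4 corner indices stay in range; weights of clamped-away
  # corners are zero for in-support samples
  x0 <- pmin(pmax(x0, 0), w - 2)
  y0 <- pmin(pmax(y0, 0), h - 2)
  fx <- X - x0
  fy <- Y - y0
  i00 <- y0 + 1 + x0 * h
  v <- (1 - fx) * (1 - fy) * mat[i00] +
    fx * (1 - fy) * mat[i00 + h] +
    (1 - fx) * fy * mat[i00 + 1] +
    fx * fy * mat[i00 + h + 1]
  v[!valid] <- 0
  list(values = v, valid = valid)
}

# Apply a rigid transform to a plain numeric matrix (full precision, no
# quantization). out(u) = img(T^{-1}(u)).
warp_matrix <- function(mat, tf) {
  h <- nrow(mat)
  w <- ncol(mat)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  Rinv <- rot2(-tf$theta)
  X <- matrix(rep(0:(w - 1), each = h), h, w) - cx - tf$dx
  Y <- matrix(rep(0:(h - 1), times = w), h, w) - cy - tf$dy
  Xs <- Rinv[1, 1] * X + Rinv[1, 2] * Y + cx
  Ys <- Rinv[2, 1] * X + Rinv[2, 2] * Y + cy
  s <- bilinear_sample(mat, Xs, Ys)
  list(
    values = matrix(s$values, h, w),
    valid = matrix(s$valid, h, w)
  )
}

#' Resample a radiograph under a rigid transform
#'
#' Bilinear interpolation; pixels whose source location falls outside the
#' moving image are filled with 0 and flagged `FALSE` in the validity mask
#' attached as attribute `"valid"`. Metadata is preserved.
#'
#' @param moving A [radiograph()].
#' @param tf A [rigid_transform()].
#' @return A [radiograph()] with attribute `"valid"` (logical matrix).
#' @export
resample <- function(moving, tf) {
  stopifnot(inherits(moving, "radiograph"), inherits(tf, "rigid_transform"))
  if (tf$dx == 0 && tf$dy == 0 && tf$theta == 0) {
    attr(moving, "valid") <- matrix(TRUE, nrow(moving), ncol(moving))
    return(moving)
  }
  wp <- warp_matrix(unclass(moving), tf)
  out <- radiograph(clip255(wp$values),
    dpi = attr(moving, "dpi"),
    patient_id = attr(moving, "patient_id"),
    timepoint = attr(moving, "timepoint"),
    jaw = attr(moving, "jaw"), sex = attr(moving, "sex"),
    age = attr(moving, "age")
  )
  attr(out, "valid") <- wp$valid
  attr(out, "implant") <- attr(moving, "implant")
  out
}

# Mean 2x2 pooling (dimensions cropped to even).
downsample2 <- function(mat) {
  h <- 2 * floor(nrow(mat) / 2)
  w <- 2 * floor(ncol(mat) / 2)
  m <- mat[seq_len(h), seq_len(w)]
  (m[seq(1, h, 2), seq(1, w, 2)] + m[seq(2, h, 2), seq(1, w, 2)] +
    m[seq(1, h, 2), seq(2, w, 2)] + m[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# Valid-overlap mean squared difference between warped moving and fixed.
rigid_mse <- function(par, moving, fixed) {
  wp <- warp_matrix(moving, rigid_transform(par[1], par[2], par[3]))
  n <- sum(wp$valid)
  if (n < 0.25 * length(fixed)) {
    return(1e12)
  }
  mean((wp$values[wp$valid] - fixed[wp$valid])^2)
}

#' Rigid registration of a follow-up radiograph to its baseline
#'
#' Estimates the rigid-body transform (translation + rotation about the image
#' centre) that maps `moving` onto `fixed` by minimizing the mean squared
#' intensity difference over the region where the two images overlap, using a
#' coarse-to-fine image pyramid (mean 2x2 pooling; at least 3 levels, coarsest
#' level at least 32 px on its short side) with Nelder-Mead refinement at each
#' level.
#'
#' At the coarsest level the translation plane (and then the rotation axis) is
#' scanned exhaustively on an integer grid before local refinement, so the
#' optimizer cannot stall in the flat centre of the similarity landscape; the
#' capture range is `max_shift` pixels and `max_angle` degrees.
#'
#' @param moving,fixed [radiograph()]s of identical dimensions; neither may be
#'   constant.
#' @param max_iter Nelder-Mead iteration cap per pyramid level.
#' @param max_shift Largest translation searched, pixels (full resolution).
#' @param max_angle Largest rotation searched, degrees.
#' @return A [rigid_transform()] mapping `moving` onto `fixed`
#'   (`resample(moving, tf)` is aligned with `fixed`), with attributes
#'   `"objective"` (MSE at the optimum), `"objective_identity"` (MSE before
#'   alignment) and `"pyramid_levels"`.
#' @export
register_rigid <- function(moving, fixed, max_iter = 400, max_shift = 15,
                           max_angle = 6) {
  stopifnot(inherits(moving, "radiograph"), inherits(fixed, "radiograph"))
  if (!all(dim(moving) == dim(fixed))) {
    stop("`moving` and `fixed` must have identical dimensions", call. = FALSE)
  }
  mv <- unclass(moving)
  fx <- unclass(fixed)
  if (stats::sd(mv) == 0 || stats::sd(fx) == 0) {
    stop("registration is undefined for constant images", call. = FALSE)
  }
  # pyramid: keep halving while the short side stays >= 32 px, min 3 levels
  pyr <- list(list(m = mv, f = fx))
  while (min(dim(pyr[[length(pyr)]]$m)) / 2 >= 32 || length(pyr) < 3) {
    last <- pyr[[length(pyr)]]
    if (min(dim(last$m)) < 8) break
    pyr[[length(pyr) + 1]] <- list(m = downsample2(last$m), f = downsample2(last$f))
  }
  # exhaustive initialization at the coarsest level: integer shift grid,
  # then an angle sweep at the best shift
  coarse <- pyr[[length(pyr)]]
  r <- ceiling(max_shift / 2^(length(pyr) - 1)) + 1
  shift_grid <- expand.grid(dx = -r:r, dy = -r:r)
  vals <- vapply(
    seq_len(nrow(shift_grid)),
    function(i) rigid_mse(c(shift_grid$dx[i], shift_grid$dy[i], 0), coarse$m, coarse$f),
    numeric(1)
  )
  best <- shift_grid[which.min(vals), ]
  angles <- seq(-max_angle, max_angle, by = 1)
  avals <- vapply(
    angles,
    function(a) rigid_mse(c(best$dx, best$dy, a), coarse$m, coarse$f),
    numeric(1)
  )
  par <- c(best$dx, best$dy, angles[which.min(avals)])
  for (lev in rev(seq_along(pyr))) {
    opt <- stats::optim(
      par, rigid_mse,
      moving = pyr[[lev]]$m, fixed = pyr[[lev]]$f,
      method = "Nelder-Mead",
      control = list(maxit = max_iter, reltol = 1e-10)
    )
    # polish with quasi-Newton descent on numeric gradients
    opt2 <- tryCatch(
      stats::optim(
        opt$par, rigid_mse,
        moving = pyr[[lev]]$m, fixed = pyr[[lev]]$f,
        method = "BFGS",
        control = list(maxit = 50, reltol = 1e-12, ndeps = rep(1e-3, 3))
      ),
      error = function(e) opt
    )
    par <- if (opt2$value <= opt$value) opt2$par else opt$par
    if (lev > 1) par[1:2] <- par[1:2] * 2
  }
  tf <- rigid_transform(par[1], par[2], par[3])
  attr(tf, "objective") <- rigid_mse(par, mv, fx)
  attr(tf, "objective_identity") <- mean((mv - fx)^2)
  attr(tf, "pyramid_levels") <- length(pyr)
  tf
}
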