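#' 2D affine / similarity transform
#'
#' Planar coordinate mapping `y = A x + b` used to correlate light-microscope
#' pixel coordinates, low-magnification EM pixel coordinates, and EM stage
#' (mechanical) coordinates. Pixel coordinates are 0-based, x right, y down;
#' stage coordinates are in micrometres.
#'
#' @param linear 2x2 matrix (non-singular).
#' @param translation length-2 numeric.
#' @param model_kind "affine" or "similarity".
#' @param fit_rmse root-mean-square residual of the fit that produced the
#'   transform (same units as the target frame), or `NA` for a constructed
#'   transform.
#' @return object of class `"affine2d"`.
#' @export
affine2d <- function(linear, translation = c(0, 0),
                     model_kind = c("affine", "similarity"),
                     fit_rmse = NA_real_) {
  model_kind <- match.arg(model_kind)
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < .Machine$double.eps * 100)
    stop("linear part is singular")
  structure(list(linear = linear, translation = as.numeric(translation),
                 model_kind = model_kind, fit_rmse = fit_rmse),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("affine2d (%s)\n", x$model_kind))
  cat(sprintf("  [%9.5f %9.5f]   [%10.4f]\n  [%9.5f %9.5f] + [%10.4f]\n",
              x$linear[1, 1], x$linear[1, 2], x$translation[1],
              x$linear[2, 1], x$linear[2, 2], x$translation[2]))
  if (is.finite(x$fit_rmse)) cat(sprintf("  fit RMSE: %.4g\n", x$fit_rmse))
  invisible(x)
}

as_point_matrix <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("points must be an n x 2 matrix (x, y)")
  storage.mode(p) <- "double"
  p
}

#' Estimate a planar transform from paired landmarks
#'
#' Least-squares estimate of the mapping from `source` to `target` that
#' minimizes the mean squared target residual. The full affine model has 6
#' parameters; the similarity model (rotation + isotropic scale +
#' translation, 4 parameters) is a linear least-squares problem in
#' `(a, b, tx, ty)` with linear part `[[a, -b], [b, a]]`.
#'
#' @param source,target n x 2 matrices (or data frames) of paired points.
#' @param model_kind "affine" (default; needs >= 3 non-collinear pairs) or
#'   "similarity" (needs >= 2 distinct pairs).
#' @return An [affine2d()] with `fit_rmse` set to the RMS residual over the
#'   landmarks, and attribute `"residuals"` holding the per-point residual
#'   vector lengths (useful for curating bad picks).
#' @export
estimate_transform <- function(source, target,
                               model_kind = c("affine", "similarity")) {
  model_kind <- match.arg(model_kind)
  s <- as_point_matrix(source); t <- as_point_matrix(target)
  if (nrow(s) != nrow(t)) stop("source and target must pair up 1:1")
  n <- nrow(s)
  if (model_kind == "affine") {
    if (n < 3L) stop("affine estimation needs at least 3 landmark pairs")
    X <- cbind(1, s)
    if (qr(X)$rank < 3L)
      stop("degenerate landmark configuration: source points are collinear ",
           "or coincident")
    beta <- qr.solve(X, t)            # 3 x 2: intercepts then linear rows
    linear <- t(beta[2:3, , drop = FALSE])
    trans <- beta[1, ]
  } else {
    if (n < 2L) stop("similarity estimation needs at least 2 landmark pairs")
    if (all(abs(sweep(s, 2, s[1, ])) < 1e-12))
      stop("degenerate landmark configuration: source points are coincident")
    # target_x = a*sx - b*sy + tx ; target_y = b*sx + a*sy + ty
    X <- rbind(cbind(s[, 1], -s[, 2], 1, 0),
               cbind(s[, 2],  s[, 1], 0, 1))
    y <- c(t[, 1], t[, 2])
    beta <- qr.solve(X, y)
    linear <- matrix(c(beta[1], beta[2], -beta[2], beta[1]), 2, 2)
    trans <- beta[3:4]
  }
  tr <- affine2d(linear, trans, model_kind)
  fitted <- map_points(tr, s)
  res <- sqrt(rowSums((t - fitted)^2))
  tr$fit_rmse <- sqrt(mean(rowSums((t - fitted)^2)))
  attr(tr, "residuals") <- res
  tr
}

#' Apply a planar transform to points
#'
#' @param t an [affine2d()].
#' @param points n x 2 matrix or data frame.
#' @return n x 2 matrix of mapped points.
#' @export
map_points <- function(t, points) {
  stopifnot(inherits(t, "affine2d"))
  p <- as_point_matrix(points)
  sweep(p %*% t(t$linear), 2, t$translation, "+")
}

#' Compose two planar transforms
#'
#' `compose_transforms(t2, t1)` returns the transform equivalent to applying
#' `t1` first, then `t2`.
#' @param t2,t1 [affine2d()] objects.
#' @return an [affine2d()] (model_kind "similarity" only if both are).
#' @export
compose_transforms <- function(t2, t1) {
  kind <- if (t1$model_kind == "similarity" && t2$model_kind == "similarity")
    "similarity" else "affine"
  affine2d(t2$linear %*% t1$linear,
           as.vector(t2$linear %*% t1$translation) + t2$translation,
           model_kind = kind)
}

#' Invert a planar transform
#' @param t an [affine2d()].
#' @return the inverse [affine2d()].
#' @export
invert_transform <- function(t) {
  Ainv <- solve(t$linear)
  affine2d(Ainv, -as.vector(Ainv %*% t$translation),
           model_kind = t$model_kind)
}

#' Convert pixel positions to EM stage coordinates
#'
#' Fits an affine map from calibration pairs of (pixel position, mechanical
#' stage coordinate) — in practice around 15 holes in the carbon film picked
#' in both frames — and applies it to query pixel positions.
#'
#' @param pixel_points n x 2 query pixel positions.
#' @param calibration_pixels,calibration_stage m x 2 paired calibration
#'   coordinates (m >= 3, non-collinear pixels).
#' @param model_kind passed to [estimate_transform()].
#' @return list with `stage` (n x 2 predicted stage coordinates, um),
#'   `transform` (the fitted [affine2d()]), `rmse` (calibration residual
#'   RMSE, um) and `residuals` (per calibration point, um).
#' @export
pixel_to_stage <- function(pixel_points, calibration_pixels,
                           calibration_stage, model_kind = "affine") {
  cp <- as_point_matrix(calibration_pixels)
  if (nrow(cp) < 3L) stop("need at least 3 calibration pairs")
  tr <- estimate_transform(cp, calibration_stage, model_kind = model_kind)
  list(stage = map_points(tr, pixel_points),
       transform = tr,
       rmse = tr$fit_rmse,
       residuals = attr(tr, "residuals"))
}

#' Write / read a transform as JSON
#' @param t an [affine2d()].
#' @param path file path.
#' @return `path` (write) or an [affine2d()] (read).
#' @export
write_transform_json <- function(t, path) {
  jsonlite::write_json(
    list(linear = as.vector(t$linear),   # column-major a11 a21 a12 a22
         translation = t$translation,
         model_kind = t$model_kind, fit_rmse = t$fit_rmse),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine2d(matrix(j$linear, 2, 2), j$translation,
           model_kind = j$model_kind,
           fit_rmse = if (is.null(j$fit_rmse)) NA_real_ else j$fit_rmse)
}
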