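## Pixel-wise T2* mapping: fit each in-mask pixel's decay independently and
## assemble a parametric map, mirroring vendor "colour map" pixel-based
## post-processing.

#' Pixel-wise mono-exponential T2* map
#'
#' Fits every in-mask pixel's signal-vs-TE course independently with
#' [fit_monoexp()] (or [truncated_fit()] when a policy is supplied). Pixels
#' whose fit fails (non-decaying course, too few positive signals, optimiser
#' failure) are marked invalid and excluded — their values are never
#' fabricated.
#'
#' @param stack an [echo_stack()].
#' @param mask logical matrix; `NULL` fits every pixel.
#' @param policy optional [truncation_policy()]; `NULL` disables truncation.
#' @return an object of class `t2_map`: list with `values` (matrix of T2* in
#'   ms, `NA` where invalid), `valid` (logical matrix), `tes`, and
#'   `n_failed` (count of in-mask pixels whose fit failed).
#' @export
pixelwise_fit <- function(stack, mask = NULL, policy = NULL) {
  if (!inherits(stack, "echo_stack")) {
    t2_stop("`stack` must be an echo_stack", "t2star_invalid_input")
  }
  d <- dim(stack$data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!is.logical(mask) || !identical(dim(mask), d[1:2])) {
    t2_stop("`mask` must be a logical matrix matching the stack's spatial shape",
            "t2star_invalid_input")
  }
  idx <- which(mask)
  if (length(idx) == 0) {
    t2_stop("ROI mask is empty", "t2star_invalid_input")
  }
  values <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  flat <- matrix(stack$data, d[1] * d[2], d[3])  # pixels x echoes
  n_failed <- 0L
  for (i in idx) {
    fit <- tryCatch({
      s <- echo_series(stack$tes, flat[i, ])
      if (is.null(policy)) fit_monoexp(s) else truncated_fit(s, policy)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
    } else {
      values[i] <- fit$T2star_hat
      valid[i] <- TRUE
    }
  }
  structure(list(values = values, valid = valid, tes = stack$tes,
                 n_failed = n_failed),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  cat(sprintf("<t2_map> %d x %d, %d valid pixels (%d failed fits)\n",
              nrow(x$values), ncol(x$values), sum(x$valid), x$n_failed))
  invisible(x)
}

#' Mean T2* of a map ROI
#'
#' Arithmetic mean of the valid in-mask pixel T2* values — the map-derived
#' ROI statistic reported by pixel-based software. The number of in-mask
#' pixels excluded as invalid is attached as attribute `n_excluded`.
#'
#' @param map a `t2_map` from [pixelwise_fit()].
#' @param mask logical matrix; `NULL` uses the whole map.
#' @return mean T2* (ms) with attribute `n_excluded`.
#' @export
map_roi_mean <- function(map, mask = NULL) {
  if (!inherits(map, "t2_map")) {
    t2_stop("`map` must be a t2_map", "t2star_invalid_input")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map$values), ncol(map$values))
  if (!is.logical(mask) || !identical(dim(mask), dim(map$values))) {
    t2_stop("`mask` must be a logical matrix matching the map", "t2star_invalid_input")
  }
  use <- mask & map$valid
  if (!any(use)) {
    t2_stop("no valid in-mask pixels", "t2star_empty_roi")
  }
  structure(mean(map$values[use]), n_excluded = sum(mask & !map$valid))
}

## Fixed value -> colour ramp for T2* maps (dark blue = short T2* / heavy
## iron through red = long T2*), linearly interpolated in sRGB.
t2_map_palette <- function() {
  grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#7FFF7F",
                         "#FFFF00", "#FF0000"), space = "rgb")
}

#' Render a T2* map as an RGB image
#'
#' Maps T2* values linearly onto a fixed blue-to-red ramp over
#' `color_scale = c(lo, hi)` (ms), clipping at the ends: `lo` renders as
#' dark blue (`#00007F`), `hi` as red (`#FF0000`). Invalid pixels are drawn
#' in a reserved mid-grey (`#404040`). Rendering is deterministic: the same
#' map yields byte-identical PNG output.
#'
#' @param map a `t2_map`.
#' @param color_scale numeric `c(lo, hi)` in ms with `hi > lo`. Typical
#'   scales: `c(0, 20)` for liver and pancreas, `c(0, 50)` for heart.
#' @param file optional PNG path; when given the image is written there.
#' @return invisibly, the RGB array (`nrow x ncol x 3`, values in 0..1).
#' @export
render_map <- function(map, color_scale = c(0, 20), file = NULL) {
  if (!inherits(map, "t2_map")) {
    t2_stop("`map` must be a t2_map", "t2star_invalid_input")
  }
  if (length(color_scale) != 2 || !all(is.finite(color_scale)) ||
      diff(color_scale) <= 0) {
    t2_stop("`color_scale` must be c(lo, hi) with hi > lo", "t2star_invalid_input")
  }
  nr <- nrow(map$values); nc <- ncol(map$values)
  frac <- (map$values - color_scale[1]) / diff(color_scale)
  frac[frac < 0] <- 0
  frac[frac > 1] <- 1
  rgbm <- matrix(64 / 255, nr * nc, 3)  # reserved invalid colour #404040
  ok <- which(map$valid)
  if (length(ok)) rgbm[ok, ] <- t2_map_palette()(frac[ok]) / 255
  img <- array(rgbm, dim = c(nr, nc, 3))
  if (!is.null(file)) png::writePNG(img, target = file)
  invisible(img)
}
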