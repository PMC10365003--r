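## Two-dimensional multi-echo phantoms: images with organ-like regions of
## prescribed T2*, used to exercise ROI- and pixel-based fitting with known
## ground truth.

#' Specify a 2-D multi-echo phantom
#'
#' A phantom is a 2-D image simulated at each echo time. Each region (a
#' logical mask) decays according to its own [decay_params()]; background
#' pixels carry pure Rician noise magnitude (decay amplitude zero) with
#' per-channel SD `background_sigma`.
#'
#' @param image_shape integer vector `c(nrow, ncol)`.
#' @param regions named list; each element is `list(mask =, params =)` where
#'   `mask` is a logical matrix of dimension `image_shape` and `params` a
#'   [decay_params()] object. Regions must be pairwise disjoint.
#' @param tes echo times (ms).
#' @param background_sigma per-channel noise SD of background pixels (a.u.).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape, regions, tes, background_sigma = 0) {
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    t2_stop("`image_shape` must be c(nrow, ncol)", "t2star_invalid_input")
  }
  image_shape <- as.integer(image_shape)
  tes <- check_echo_train(tes)
  if (length(regions) == 0) {
    t2_stop("at least one region is required", "t2star_invalid_spec")
  }
  if (is.null(names(regions)) || any(names(regions) == "")) {
    t2_stop("`regions` must be a named list", "t2star_invalid_spec")
  }
  occupancy <- matrix(0L, image_shape[1], image_shape[2])
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    if (!is.logical(rg$mask) || !identical(dim(rg$mask), image_shape)) {
      t2_stop(sprintf("region '%s': mask must be a logical matrix of dim image_shape", nm),
              "t2star_invalid_spec")
    }
    if (!inherits(rg$params, "decay_params")) {
      t2_stop(sprintf("region '%s': params must be decay_params()", nm),
              "t2star_invalid_spec")
    }
    occupancy <- occupancy + rg$mask
  }
  if (any(occupancy > 1L)) {
    t2_stop("phantom regions overlap", "t2star_invalid_spec")
  }
  if (background_sigma < 0) {
    t2_stop("`background_sigma` must be >= 0", "t2star_invalid_input")
  }
  structure(list(image_shape = image_shape, regions = regions, tes = tes,
                 background_sigma = background_sigma),
            class = "phantom_spec")
}

#' Circular region mask helper
#'
#' @param image_shape `c(nrow, ncol)`.
#' @param center `c(row, col)` of the disk centre.
#' @param radius radius in pixels.
#' @return logical matrix.
#' @export
disk_mask <- function(image_shape, center, radius) {
  rows <- matrix(seq_len(image_shape[1]), image_shape[1], image_shape[2])
  cols <- matrix(seq_len(image_shape[2]), image_shape[1], image_shape[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Rectangular region mask helper
#'
#' @param image_shape `c(nrow, ncol)`.
#' @param rows,cols integer index ranges of the rectangle.
#' @return logical matrix.
#' @export
rect_mask <- function(image_shape, rows, cols) {
  m <- matrix(FALSE, image_shape[1], image_shape[2])
  m[rows, cols] <- TRUE
  m
}

#' Simulate a multi-echo phantom image stack
#'
#' Produces one image per echo time. Every in-region pixel decays with its
#' region's parameters under independent per-pixel Rician noise; background
#' pixels are pure noise magnitude (Rayleigh when `background_sigma > 0`,
#' zero otherwise).
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer seed for exact reproducibility.
#' @return an `echo_stack`: list with `data` (array `nrow x ncol x n_echo`)
#'   and `tes` (echo times, ms).
#' @export
simulate_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) {
    t2_stop("`spec` must be created with phantom_spec()", "t2star_invalid_input")
  }
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ne <- length(spec$tes)
  with_seed(seed, {
    data <- array(0, dim = c(nr, nc, ne))
    in_any <- matrix(FALSE, nr, nc)
    for (rg in spec$regions) {
      idx <- which(rg$mask)
      in_any <- in_any | rg$mask
      clean <- rg$params$K * exp(-spec$tes / rg$params$T2star) + rg$params$noise_floor
      for (e in seq_len(ne)) {
        plane <- data[, , e]
        plane[idx] <- rician_sample(rep(clean[e], length(idx)), rg$params$sigma)
        data[, , e] <- plane
      }
    }
    if (spec$background_sigma > 0) {
      bg <- which(!in_any)
      for (e in seq_len(ne)) {
        plane <- data[, , e]
        plane[bg] <- rician_sample(rep(0, length(bg)), spec$background_sigma)
        data[, , e] <- plane
      }
    }
    echo_stack(data, spec$tes)
  })
}

#' Construct a multi-echo image stack
#'
#' @param data numeric array `nrow x ncol x n_echo`.
#' @param tes echo times (ms), one per slice of the third dimension.
#' @return an object of class `echo_stack`.
#' @export
echo_stack <- function(data, tes) {
  tes <- check_echo_train(tes)
  if (!is.array(data) || length(dim(data)) != 3) {
    t2_stop("`data` must be a 3-D array (row, col, echo)", "t2star_invalid_input")
  }
  if (dim(data)[3] != length(tes)) {
    t2_stop("third dimension of `data` must match the number of echo times",
            "t2star_invalid_input")
  }
  structure(list(data = data, tes = tes), class = "echo_stack")
}

#' @export
print.echo_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_stack> %d x %d pixels, %d echoes (TE %.2f-%.2f ms)\n",
              d[1], d[2], d[3], min(x$tes), max(x$tes)))
  invisible(x)
}
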