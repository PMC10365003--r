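## On-disk formats. Image stacks travel as 4-D NIfTI (x, y, 1, echo) with a
## JSON sidecar listing echo times in ms; tabular outputs are CSV with
## provenance comment headers (lines starting with '#').

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a multi-echo stack as NIfTI plus JSON sidecar
#'
#' The image is stored as a 4-D volume (x, y, 1, echo); the sidecar JSON
#' holds `EchoTimes` in milliseconds.
#'
#' @param stack an [echo_stack()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "echo_stack")) {
    t2_stop("`stack` must be an echo_stack", "t2star_invalid_input")
  }
  d <- dim(stack$data)
  vol <- array(stack$data, dim = c(d[1], d[2], 1, d[3]))
  RNifti::writeNifti(vol, path)
  jsonlite::write_json(list(EchoTimes = stack$tes), sidecar_path(path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a multi-echo stack (NIfTI + JSON sidecar)
#'
#' Reads the volume and its echo-time sidecar and returns the stack with
#' echoes sorted ascending by TE regardless of the stored order. Missing or
#' duplicated echo times are reported as format errors naming the offending
#' echo.
#'
#' @param path path to the `.nii` / `.nii.gz` file; the sidecar is expected
#'   alongside with extension `.json`.
#' @return an [echo_stack()].
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    t2_stop(sprintf("echo-time sidecar not found: %s", sc), "t2star_format_error")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tes <- as.numeric(meta$EchoTimes)
  vol <- as.array(RNifti::readNifti(path))
  dv <- dim(vol)
  if (length(dv) == 4 && dv[3] == 1) {
    vol <- array(vol, dim = dv[c(1, 2, 4)])
  } else if (length(dv) != 3) {
    t2_stop("expected a 4-D (x, y, 1, echo) or 3-D (x, y, echo) volume",
            "t2star_format_error")
  }
  ne <- dim(vol)[3]
  if (length(tes) != ne || anyNA(tes)) {
    bad <- if (anyNA(tes)) which(is.na(tes))[1] else length(tes)
    t2_stop(sprintf("sidecar lists %d echo time(s) for %d echoes (first problem at echo %d)",
                    length(tes), ne, bad), "t2star_format_error")
  }
  if (anyDuplicated(tes)) {
    t2_stop(sprintf("duplicate echo time at echo %d", anyDuplicated(tes)),
            "t2star_format_error")
  }
  ord <- order(tes)
  echo_stack(vol[, , ord, drop = FALSE], tes[ord])
}

#' Read an ROI mask (NIfTI or PNG)
#'
#' Nonzero pixels are in-mask. PNG masks use the first channel.
#'
#' @param path path to a `.nii`/`.nii.gz` or `.png` file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img != 0)
  }
  m <- as.array(RNifti::readNifti(path))
  dm <- dim(m)
  if (length(dm) > 2) m <- array(m, dim = dm[1:2])
  matrix(m != 0, nrow(m), ncol(m))
}

#' Write an ROI mask as NIfTI
#'
#' @param mask logical matrix.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(array(as.numeric(mask), dim = dim(mask)), path)
  invisible(path)
}

#' Write a T2* map as NIfTI
#'
#' Invalid pixels are stored as `NaN`.
#'
#' @param map a `t2_map`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @export
write_map <- function(map, path) {
  if (!inherits(map, "t2_map")) {
    t2_stop("`map` must be a t2_map", "t2star_invalid_input")
  }
  vals <- map$values
  vals[!map$valid] <- NaN
  RNifti::writeNifti(vals, path)
  invisible(path)
}

#' Write / read a decay-curve CSV
#'
#' Two columns, `te_ms` and `signal`, with optional provenance comment
#' header lines starting with `#`.
#'
#' @param series an [echo_series()].
#' @param path file path.
#' @param meta optional named list written as `# key=value` header lines.
#' @export
write_series_csv <- function(series, path, meta = NULL) {
  dat <- as_series_df(series)
  write_csv_with_header(dat, path, meta)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  dat <- utils::read.csv(path, comment.char = "#")
  echo_series(dat$te_ms, dat$signal)
}

#' Write / read a cohort CSV
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @param meta optional named list of provenance header fields.
#' @export
write_cohort_csv <- function(cohort, path, meta = NULL) {
  write_csv_with_header(cohort, path, meta)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

## CSV writer with '# key=value' provenance header lines.
write_csv_with_header <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s=%s", names(meta), vapply(meta, as.character, "")), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Deterministic hash of a configuration object
#'
#' MD5 of the canonical JSON serialisation; used to stamp outputs so a run
#' can be matched to its configuration.
#'
#' @param config any JSON-serialisable list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
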