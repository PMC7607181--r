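# Writers/readers for the generator artifacts: CSV tables, 8-bit PNG
# images, single-channel PNG masks (0/255) and JSON sidecars.

#' Write a synthetic cohort to disk
#'
#' Writes `cohort.csv` (one row per patient-marker-core), `survival.csv`,
#' and `truth.json` (generating parameters and realized values) into
#' `dir`.
#'
#' @param x an `ihc_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  if (!inherits(x, "ihc_cohort"))
    abort("`x` must be an ihc_cohort", "ihcmet_param_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("cohort.csv", "survival.csv", "truth.json"))
  write.csv(x$cohort, paths[1], row.names = FALSE)
  write.csv(x$survival, paths[2], row.names = FALSE)
  truth <- x$truth
  truth$phenotype <- as.character(truth$phenotype)
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor", force = TRUE)
  invisible(paths)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param path path to `cohort.csv`.
#' @return data.frame in the layout [score_cohort()] expects.
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a synthetic slide to disk
#'
#' Writes `<name>.png` (8-bit RGB), one single-channel PNG mask sidecar
#' per truth mask (`<name>_mask_<which>.png`, 0/255), and
#' `<name>.json` with microns_per_pixel and the truth parameters.
#'
#' @param slide an `ihc_slide` from [generate_slide()].
#' @param dir output directory.
#' @param name file stem (default "slide").
#' @return invisibly, the paths written.
#' @export
write_slide <- function(slide, dir, name = "slide") {
  if (!inherits(slide, "ihc_slide"))
    abort("`slide` must be an ihc_slide", "ihcmet_param_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  png::writePNG(slide$image / 255, img_path)
  mask_names <- c("tumor", "margin", "center", "macrophages", "artefacts",
                  "dab_cells", "nuclei")
  mask_paths <- vapply(mask_names, function(m) {
    pth <- file.path(dir, paste0(name, "_mask_", m, ".png"))
    write_mask(slide$truth[[m]], pth)
    pth
  }, "")
  meta <- list(microns_per_pixel = slide$params$microns_per_pixel,
               margin_width_um = slide$params$margin_width_um,
               true_normalized_ratio = slide$truth$true_normalized_ratio,
               dab_fraction_center = slide$truth$dab_fraction_center,
               margin_effect = slide$params$margin_effect,
               seed = slide$params$seed)
  json_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, mask_paths, json_path))
}

#' Read an RGB PNG image as an 8-bit array
#' @param path PNG path.
#' @return integer H x W x 3 array in \[0, 255\].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' Write / read a binary mask as single-channel PNG (0/255)
#' @param mask logical matrix.
#' @param path PNG path.
#' @return `write_mask`: invisibly the path; `read_mask`: logical matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write a synthetic qPCR plate
#' @param x result of [generate_qpcr()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_qpcr <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("qpcr.csv", "qpcr_truth.json"))
  write.csv(x$records, paths[1], row.names = FALSE)
  jsonlite::write_json(list(true_fold_changes = x$truth), paths[2],
                       digits = NA, matrix = "rowmajor")
  invisible(paths)
}
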