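# Optical-density color model and stain deconvolution (Ruifrok-Johnston).
#
# Images are numeric arrays H x W x 3 with values in [0, 255] (8-bit RGB).
# Stain matrices have one column per stain (RGB rows), each column a unit
# optical-density vector.

#' Standard H-DAB stain matrix
#'
#' The Ruifrok--Johnston optical-density unit vectors for hematoxylin and
#' DAB, plus a residual third vector (normalized cross product) completing
#' the basis so the matrix is invertible. Columns: `hematoxylin`, `dab`,
#' `residual`; rows: R, G, B.
#'
#' @return 3 x 3 numeric matrix with unit-norm columns.
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  h <- h / sqrt(sum(h^2))
  d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, dab = d, residual = r)
  rownames(m) <- c("R", "G", "B")
  m
}

validate_stain_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 3L || ncol(m) != 3L || anyNA(m))
    abort("stain matrix must be a 3x3 numeric matrix", "ihcmet_param_error")
  nrm <- sqrt(colSums(m^2))
  if (any(abs(nrm - 1) > 1e-6))
    abort("stain matrix columns must have unit norm", "ihcmet_param_error")
  if (!is.finite(rcond <- 1 / kappa(m)) || rcond < 1e-8)
    abort("stain matrix is singular or near-singular", "ihcmet_stain_error")
  invisible(m)
}

#' RGB to optical density
#'
#' Beer--Lambert conversion `OD = -log10((I + eps) / I0)` per channel.
#' White background maps to ~0 OD; stain amounts add linearly in OD space.
#'
#' @param img numeric array H x W x 3 (or matrix/vector of intensities) in
#'   \[0, I0\].
#' @param I0 incident (background) intensity, default 255.
#' @param eps small offset preventing log of zero.
#' @return array of the same shape, OD >= 0.
#' @export
rgb_to_od <- function(img, I0 = 255, eps = 1e-6) {
  if (!is.numeric(img))
    abort("image must be numeric RGB", "ihcmet_format_error")
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3] != 3L)
    abort("image must have 3 channels", "ihcmet_format_error")
  od <- -log10((img + eps) / I0)
  od[od < 0] <- 0
  od
}

#' Optical density back to RGB
#'
#' Inverse of [rgb_to_od()]; returns continuous intensities (quantize to
#' integers only when writing 8-bit files).
#'
#' @param od numeric array of optical densities.
#' @param I0 incident intensity, default 255.
#' @return numeric array in \[0, I0\].
#' @export
od_to_rgb <- function(od, I0 = 255) {
  I0 * 10^(-od)
}

#' Color deconvolution into stain concentration channels
#'
#' Inverts the stain mixing model per pixel: given pixel OD vector
#' `od = M %*% c`, recovers concentrations `c = M^{-1} od`. Negative
#' concentrations (noise outside the stain simplex) are clipped to 0.
#'
#' @param od numeric array H x W x 3 of optical densities
#'   (see [rgb_to_od()]).
#' @param stain_matrix 3 x 3 matrix, columns = stain OD unit vectors
#'   (default [hdab_stain_matrix()]).
#' @return named list of H x W matrices, one per stain column.
#' @export
deconvolve_stains <- function(od, stain_matrix = hdab_stain_matrix()) {
  validate_stain_matrix(stain_matrix)
  dm <- dim(od)
  if (length(dm) != 3L || dm[3] != 3L)
    abort("`od` must be an H x W x 3 array", "ihcmet_format_error")
  flat <- matrix(od, ncol = 3L)          # N x 3
  conc <- flat %*% t(solve(stain_matrix))  # N x 3, c = M^-1 od per pixel
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3L), function(k) matrix(conc[, k], dm[1], dm[2]))
  names(out) <- colnames(stain_matrix)
  out
}

#' Tissue segmentation from total optical density
#'
#' Tissue pixels absorb light; background is near-white. Pixels whose
#' summed OD over channels exceeds `od_threshold` are tissue; connected
#' specks below `min_area_px` are removed and interior holes filled.
#'
#' @param img numeric H x W x 3 RGB array.
#' @param od_threshold total-OD background threshold (default 0.1).
#' @param min_area_px minimum component area kept, in pixels (default 9).
#' @param fill_holes fill enclosed background holes (default TRUE).
#' @return logical H x W tissue mask.
#' @export
segment_tissue <- function(img, od_threshold = 0.1, min_area_px = 9,
                           fill_holes = TRUE) {
  od <- rgb_to_od(img)
  tot <- od[, , 1] + od[, , 2] + od[, , 3]
  mask <- tot > od_threshold
  if (any(mask) && min_area_px > 1) {
    lab <- label_components(mask, 8L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (fill_holes && any(mask)) {
    bg <- label_components(!mask, 4L)
    border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border_labs <- border_labs[border_labs > 0L]
    hole <- !mask & !(bg %in% border_labs)
    mask <- mask | matrix(hole, nrow(mask), ncol(mask))
  }
  mask
}
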