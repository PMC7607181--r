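# Invasive-margin / tumor-center geometry on the pixel grid.

#' Build margin and center compartments from a tumor mask
#'
#' The invasive margin is the band of tumor tissue within `margin_width_um`
#' (default 1 mm) of the tumor/non-tumor interface, measured by Euclidean
#' distance transform on the pixel grid and scaled by `microns_per_pixel`
#' (square pixels assumed). The center is the remaining tumor. Interface
#' segments touching the image border are technical (cut) edges, not
#' biology: the 1-mm band adjacent to them is added to the exclusion mask,
#' mirroring the manual exclusion of cut margins. A tumor without any
#' center pixel after exclusions raises a `no center compartment` error and
#' the slide is excluded from analysis.
#'
#' @param tumor_mask logical H x W matrix, TRUE = tumor.
#' @param microns_per_pixel pixel pitch in micrometers (> 0).
#' @param margin_width_um margin band thickness in micrometers
#'   (default 1000).
#' @param exclusion_mask optional logical H x W matrix of user-supplied
#'   exclusions (vessels, bronchi, artefacts); merged with technical-edge
#'   exclusions.
#' @return object of class `compartment_masks`: list with logical matrices
#'   `tumor`, `margin`, `center`, `exclusion`, plus `microns_per_pixel`
#'   and `margin_width_um`.
#' @export
build_compartments <- function(tumor_mask, microns_per_pixel,
                               margin_width_um = 1000,
                               exclusion_mask = NULL) {
  if (!is.matrix(tumor_mask) || !is.logical(tumor_mask))
    abort("`tumor_mask` must be a logical matrix", "ihcmet_format_error")
  if (!any(tumor_mask))
    abort("`tumor_mask` is empty", "ihcmet_param_error")
  check_pos(microns_per_pixel, "microns_per_pixel")
  check_pos(margin_width_um, "margin_width_um", strict = FALSE)
  nr <- nrow(tumor_mask); nc <- ncol(tumor_mask)
  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(FALSE, nr, nc)
  } else if (!is.matrix(exclusion_mask) || !is.logical(exclusion_mask) ||
             !all(dim(exclusion_mask) == c(nr, nc))) {
    abort("`exclusion_mask` must be a logical matrix matching the image",
          "ihcmet_format_error")
  }

  d_out_um <- sqrt(edt_sq(!tumor_mask)) * microns_per_pixel
  margin <- tumor_mask & d_out_um <= margin_width_um

  # technical (cut) edges: tumor pixels on the image border
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- TRUE; border[nr, ] <- TRUE
  border[, 1] <- TRUE; border[, nc] <- TRUE
  tech <- tumor_mask & border
  if (any(tech)) {
    d_tech_um <- sqrt(edt_sq(tech)) * microns_per_pixel
    exclusion_mask <- exclusion_mask |
      (tumor_mask & d_tech_um <= margin_width_um)
  }

  center <- tumor_mask & !margin
  if (!any(center & !exclusion_mask))
    abort("no center compartment: tumor lies entirely within the margin band",
          "ihcmet_no_center_error")
  structure(list(tumor = tumor_mask, margin = margin, center = center,
                 exclusion = exclusion_mask,
                 microns_per_pixel = microns_per_pixel,
                 margin_width_um = margin_width_um),
            class = "compartment_masks")
}

#' Detect macrophages by saturated DAB staining
#'
#' Intratumoral and alveolar macrophages take up DAB far more strongly than
#' tumor cells; they are isolated as connected components of the DAB
#' concentration channel at or above `od_cutoff` whose physical area falls
#' in `size_range_um2`. The returned mask is meant to be added to the
#' exclusion mask before quantification.
#'
#' @param dab_channel numeric H x W matrix of DAB concentrations (from
#'   [deconvolve_stains()]).
#' @param microns_per_pixel pixel pitch in micrometers.
#' @param od_cutoff saturation cutoff in OD units (default 1.2; tumor-cell
#'   DAB is typically < 1).
#' @param size_range_um2 numeric length-2, plausible macrophage area in
#'   square micrometers (default c(10, 600), generous enough for touching
#'   pairs).
#' @return logical H x W macrophage mask.
#' @export
detect_macrophages <- function(dab_channel, microns_per_pixel,
                               od_cutoff = 1.2,
                               size_range_um2 = c(10, 600)) {
  if (!is.matrix(dab_channel))
    abort("`dab_channel` must be a matrix", "ihcmet_format_error")
  check_pos(microns_per_pixel, "microns_per_pixel")
  cand <- dab_channel >= od_cutoff
  out <- matrix(FALSE, nrow(cand), ncol(cand))
  if (!any(cand)) return(out)
  lab <- label_components(cand, 8L)
  area_px <- tabulate(lab[lab > 0L])
  area_um2 <- area_px * microns_per_pixel^2
  keep <- which(area_um2 >= size_range_um2[1] & area_um2 <= size_range_um2[2])
  if (length(keep))
    out <- matrix(lab %in% keep, nrow(cand), ncol(cand))
  out
}

#' @export
print.compartment_masks <- function(x, ...) {
  px <- x$microns_per_pixel
  cat("compartment_masks:",
      sprintf("%d x %d px at %.3g um/px", nrow(x$tumor), ncol(x$tumor), px),
      sprintf("| tumor %d px, margin %d px, center %d px, excluded %d px\n",
              sum(x$tumor), sum(x$margin), sum(x$center), sum(x$exclusion)))
  invisible(x)
}

#' Disc mask on a pixel grid
#'
#' Convenience constructor for circular tumor masks (geometry checks,
#' examples).
#'
#' @param nr,nc mask dimensions in pixels.
#' @param center_rc numeric c(row, col) of the disc center.
#' @param radius_px disc radius in pixels.
#' @return logical nr x nc matrix.
#' @export
disc_mask <- function(nr, nc, center_rc, radius_px) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - center_rc[1])^2 + (cc - center_rc[2])^2 <= radius_px^2
}
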