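# Synthetic H-DAB slide generator with pixel-level ground truth.
#
# The image model is Beer-Lambert mixing: each pixel's OD vector is
# hema_conc * H + dab_conc * DAB for the configured stain vectors, plus
# small Gaussian OD noise; RGB = 255 * 10^-OD. Tumor tissue is a field of
# small "cell" blobs carrying hematoxylin; a controllable fraction of cells
# additionally carries DAB, with different fractions in the margin band and
# the center, which is the gradient the margin/center pipeline must
# recover. Macrophages are small saturated-DAB blobs; artefacts are flat
# gray rectangles.

#' Parameters for the synthetic slide generator
#'
#' @param image_size integer c(H, W) in pixels.
#' @param microns_per_pixel pixel pitch, um/px (> 0). Default 4 (coarser
#'   than real scanners so desk-scale slides stay small; blob radii are
#'   chosen to span >= 1 px at this grid).
#' @param tumor_geometry list: `type` "disc" or "blob", `radius_um`, and
#'   for blobs an `irregularity` fraction (radial harmonic amplitude).
#' @param margin_width_um invasive-margin band thickness (default 1000).
#' @param dab_fraction_center fraction of tumor cells DAB-positive in the
#'   center, in \[0,1\].
#' @param margin_effect multiplicative enrichment of the DAB-positive
#'   fraction in the margin band (> 0);
#'   `dab_fraction_center * margin_effect` must be <= 1.
#' @param macrophage_density saturated-DAB speckles per mm^2 of tumor.
#' @param artefact_spec list of integer vectors c(r0, c0, r1, c1) (pixel
#'   rectangles) rendered as flat gray and recorded as artefact truth.
#' @param stain_matrix 3x3 stain matrix (default [hdab_stain_matrix()]);
#'   hematoxylin and DAB columns must be nonnegative unit vectors.
#' @param cell_density_per_mm2 tumor cell (nucleus blob) density.
#' @param cell_radius_um nucleus blob radius, um.
#' @param dab_od mean DAB concentration of positive tumor cells (OD units).
#' @param hema_od mean hematoxylin concentration of cells.
#' @param macrophage_od_range DAB concentration range for macrophages;
#'   minimum must be >= 1.5 so a saturation cutoff can isolate them.
#' @param macrophage_radius_um_range macrophage blob radius range, um.
#' @param od_noise_sd sd of additive Gaussian OD noise per channel.
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `slide_params`.
#' @export
slide_params <- function(image_size = c(720L, 720L),
                         microns_per_pixel = 4,
                         tumor_geometry = list(type = "disc",
                                               radius_um = 1400),
                         margin_width_um = 1000,
                         dab_fraction_center = 0.15,
                         margin_effect = 2,
                         macrophage_density = 20,
                         artefact_spec = list(),
                         stain_matrix = hdab_stain_matrix(),
                         cell_density_per_mm2 = 900,
                         cell_radius_um = 7,
                         dab_od = 0.8,
                         hema_od = 0.55,
                         macrophage_od_range = c(1.6, 2.2),
                         macrophage_radius_um_range = c(3, 8),
                         od_noise_sd = 0.01,
                         seed = 1L) {
  check_pos(microns_per_pixel, "microns_per_pixel")
  check_prob(dab_fraction_center, "dab_fraction_center")
  check_pos(margin_effect, "margin_effect")
  if (dab_fraction_center * margin_effect > 1 + 1e-12)
    abort("dab_fraction_center * margin_effect must be <= 1",
          "ihcmet_param_error")
  check_pos(macrophage_density, "macrophage_density", strict = FALSE)
  check_pos(margin_width_um, "margin_width_um", strict = FALSE)
  validate_stain_matrix(stain_matrix)
  if (any(stain_matrix[, 1:2] < 0))
    abort("hematoxylin/DAB stain vectors must be nonnegative",
          "ihcmet_param_error")
  if (macrophage_od_range[1] < 1.5)
    abort("macrophage DAB OD must be >= 1.5 (saturated)",
          "ihcmet_param_error")
  structure(list(image_size = as.integer(image_size),
                 microns_per_pixel = microns_per_pixel,
                 tumor_geometry = tumor_geometry,
                 margin_width_um = margin_width_um,
                 dab_fraction_center = dab_fraction_center,
                 margin_effect = margin_effect,
                 macrophage_density = macrophage_density,
                 artefact_spec = artefact_spec,
                 stain_matrix = stain_matrix,
                 cell_density_per_mm2 = cell_density_per_mm2,
                 cell_radius_um = cell_radius_um,
                 dab_od = dab_od, hema_od = hema_od,
                 macrophage_od_range = macrophage_od_range,
                 macrophage_radius_um_range = macrophage_radius_um_range,
                 od_noise_sd = od_noise_sd,
                 seed = as.integer(seed)),
            class = "slide_params")
}

# stamp discs of per-blob radius (px) onto conc matrices via pmax
stamp_discs <- function(conc, rows, cols, radii_px, values) {
  nr <- nrow(conc); nc <- ncol(conc)
  rmax <- max(0, ceiling(max(radii_px)))
  for (dy in -rmax:rmax) {
    for (dx in -rmax:rmax) {
      sel <- which(dy * dy + dx * dx <= radii_px^2)
      if (!length(sel)) next
      rr <- rows[sel] + dy; cc <- cols[sel] + dx
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      if (!any(ok)) next
      idx <- cbind(rr[ok], cc[ok])
      conc[idx] <- pmax(conc[idx], values[sel][ok])
    }
  }
  conc
}

#' Generate a synthetic H-DAB slide with ground truth
#'
#' See [slide_params()] for the image model. By construction the true
#' normalized margin ratio (DAB area / nuclei area in the margin,
#' normalized to the center) equals `margin_effect`.
#'
#' @param params a [slide_params()] object.
#' @return object of class `ihc_slide`: list with `image` (H x W x 3
#'   integer array, 8-bit RGB), `truth` (masks `tumor`, `margin`, `center`,
#'   `macrophages`, `artefacts`, `dab_cells`, `nuclei`; scalars
#'   `true_normalized_ratio`, realized DAB fractions) and `params`.
#' @export
generate_slide <- function(params) {
  if (!inherits(params, "slide_params"))
    abort("`params` must come from slide_params()", "ihcmet_param_error")
  p <- params
  nr <- p$image_size[1]; nc <- p$image_size[2]
  mpp <- p$microns_per_pixel
  radius_px <- p$tumor_geometry$radius_um / mpp
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  if (2 * radius_px + 4 > min(nr, nc) || p$margin_width_um < mpp)
    abort("image too small to contain the tumor and margin band at this resolution",
          "ihcmet_geometry_error")

  with_seed(p$seed, {
    # tumor mask: disc, optionally radially perturbed ("blob")
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dy <- rr - ctr[1]; dx <- cc - ctr[2]
    if (identical(p$tumor_geometry$type, "blob")) {
      irr <- p$tumor_geometry$irregularity %||% 0.08
      ph <- runif(2, 0, 2 * pi)
      theta <- atan2(dy, dx)
      rmod <- radius_px * (1 + irr * sin(2 * theta + ph[1]) +
                             0.5 * irr * sin(3 * theta + ph[2]))
      tumor <- (dy^2 + dx^2) <= rmod^2
    } else {
      tumor <- (dy^2 + dx^2) <= radius_px^2
    }

    # truth compartments (no exclusions yet): EDT to non-tumor
    d_out_um <- sqrt(edt_sq(!tumor)) * mpp
    margin <- tumor & d_out_um <= p$margin_width_um
    center <- tumor & !margin

    area_mm2 <- sum(tumor) * (mpp / 1000)^2
    n_cells <- max(1L, round(p$cell_density_per_mm2 * area_mm2))

    # rejection-sample cell centers inside the tumor
    tumor_idx <- which(tumor)
    pick <- sample(tumor_idx, n_cells, replace = TRUE)
    crow <- ((pick - 1L) %% nr) + 1L
    ccol <- ((pick - 1L) %/% nr) + 1L
    in_margin <- margin[cbind(crow, ccol)]

    # exactly round(fraction * n) positive cells per compartment: the
    # stated DAB fraction is realized exactly (no binomial noise), which
    # is what "a fraction of tumor cells carry DAB" promises
    is_dab <- logical(n_cells)
    for (compartment in list(which(in_margin), which(!in_margin))) {
      frac <- if (length(compartment) && in_margin[compartment[1]])
        p$dab_fraction_center * p$margin_effect else p$dab_fraction_center
      n_pos <- round(frac * length(compartment))
      if (n_pos > 0)
        is_dab[sample(compartment, n_pos)] <- TRUE
    }

    cell_r_px <- pmax(0.5, rnorm(n_cells, p$cell_radius_um / mpp,
                                 0.15 * p$cell_radius_um / mpp))
    hema_c <- pmax(0.2, rnorm(n_cells, p$hema_od, 0.12 * p$hema_od))
    dab_c <- pmax(0.3, rnorm(n_cells, p$dab_od, 0.12 * p$dab_od))

    hema <- matrix(0, nr, nc)
    dab <- matrix(0, nr, nc)
    hema <- stamp_discs(hema, crow, ccol, cell_r_px, hema_c)
    nuclei_mask <- hema > 0
    if (any(is_dab)) {
      dab <- stamp_discs(dab, crow[is_dab], ccol[is_dab],
                         cell_r_px[is_dab], dab_c[is_dab])
    }
    dab_cells_mask <- dab > 0

    # macrophages: saturated-DAB speckles anywhere in the tumor
    mac_mask <- matrix(FALSE, nr, nc)
    n_mac <- round(p$macrophage_density * area_mm2)
    if (n_mac > 0) {
      mpick <- sample(tumor_idx, n_mac, replace = TRUE)
      mrow <- ((mpick - 1L) %% nr) + 1L
      mcol <- ((mpick - 1L) %/% nr) + 1L
      mr_px <- runif(n_mac, p$macrophage_radius_um_range[1],
                     p$macrophage_radius_um_range[2]) / mpp
      mod <- runif(n_mac, p$macrophage_od_range[1], p$macrophage_od_range[2])
      dab <- stamp_discs(dab, mrow, mcol, pmax(0.5, mr_px), mod)
      mm <- matrix(0, nr, nc)
      mm <- stamp_discs(mm, mrow, mcol, pmax(0.5, mr_px), rep(1, n_mac))
      mac_mask <- mm > 0
    }

    od <- array(0, dim = c(nr, nc, 3))
    hvec <- p$stain_matrix[, 1]; dvec <- p$stain_matrix[, 2]
    for (k in 1:3)
      od[, , k] <- hema * hvec[k] + dab * dvec[k]

    # artefacts: flat gray smudges overriding tissue
    art_mask <- matrix(FALSE, nr, nc)
    for (rect in p$artefact_spec) {
      r0 <- max(1L, rect[1]); c0 <- max(1L, rect[2])
      r1 <- min(nr, rect[3]); c1 <- min(nc, rect[4])
      art_mask[r0:r1, c0:c1] <- TRUE
      for (k in 1:3) od[r0:r1, c0:c1, k] <- 0.45
    }

    if (p$od_noise_sd > 0) {
      od <- od + array(rnorm(length(od), 0, p$od_noise_sd), dim = dim(od))
      od[od < 0] <- 0
    }

    img <- od_to_rgb(od)
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = dim(img))

    realized_center <- if (any(!in_margin)) mean(is_dab[!in_margin]) else NA
    realized_margin <- if (any(in_margin)) mean(is_dab[in_margin]) else NA

    structure(list(
      image = img,
      truth = list(tumor = tumor, margin = margin, center = center,
                   macrophages = mac_mask, artefacts = art_mask,
                   dab_cells = dab_cells_mask, nuclei = nuclei_mask,
                   true_normalized_ratio = p$margin_effect,
                   dab_fraction_center = p$dab_fraction_center,
                   realized_dab_fraction_center = realized_center,
                   realized_dab_fraction_margin = realized_margin),
      params = p), class = "ihc_slide")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
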