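# Stain-area quantification per compartment and the margin-vs-center test.

#' Quantify marker and nuclei staining per compartment
#'
#' After color deconvolution, marker (DAB) area is the count of pixels with
#' DAB concentration at or above `dab_threshold`, and nuclei (hematoxylin)
#' area the count at or above `hema_threshold`, within each compartment
#' after removing exclusions. The marker area is normalized to the nuclei
#' area (`ratio = marker_area / nuclei_area`), and the margin ratio is
#' further normalized to the tumor center
#' (`normalized_margin_ratio = ratio_margin / ratio_center`, so the center
#' is identically 1). Total integrated concentration per stain is also
#' reported. A compartment with zero nuclei area makes the slide
#' non-evaluable.
#'
#' @param image numeric/integer H x W x 3 RGB array (8-bit scale).
#' @param masks a [build_compartments()] object. Macrophage exclusions
#'   should already be merged into `masks$exclusion` (see
#'   [analyze_slide()]).
#' @param stain_matrix 3x3 stain matrix (default [hdab_stain_matrix()]).
#' @param dab_threshold DAB concentration threshold, OD units
#'   (default 0.15).
#' @param hema_threshold hematoxylin concentration threshold, OD units
#'   (default 0.15).
#' @return object of class `slide_quant`: list with `table` (one row per
#'   compartment: areas in px and um^2, integrated OD, ratio),
#'   `normalized_margin_ratio`, and `evaluable` flag.
#' @export
quantify_slide <- function(image, masks,
                           stain_matrix = hdab_stain_matrix(),
                           dab_threshold = 0.15, hema_threshold = 0.15) {
  if (!inherits(masks, "compartment_masks"))
    abort("`masks` must come from build_compartments()",
          "ihcmet_param_error")
  od <- rgb_to_od(image)
  conc <- deconvolve_stains(od, stain_matrix)
  dab <- conc$dab; hema <- conc$hematoxylin
  mpp2 <- masks$microns_per_pixel^2
  comp <- list(margin = masks$margin & !masks$exclusion,
               center = masks$center & !masks$exclusion)
  rows <- lapply(names(comp), function(nm) {
    m <- comp[[nm]]
    marker_px <- sum(dab[m] >= dab_threshold)
    nuclei_px <- sum(hema[m] >= hema_threshold)
    data.frame(compartment = nm,
               area_px = sum(m),
               marker_area_px = marker_px,
               nuclei_area_px = nuclei_px,
               marker_area_um2 = marker_px * mpp2,
               nuclei_area_um2 = nuclei_px * mpp2,
               integrated_dab_od = sum(dab[m]),
               integrated_hema_od = sum(hema[m]),
               ratio = if (nuclei_px > 0) marker_px / nuclei_px else NA_real_)
  })
  tab <- do.call(rbind, rows)
  evaluable <- all(tab$nuclei_area_px > 0)
  nmr <- if (evaluable && tab$ratio[tab$compartment == "center"] > 0) {
    tab$ratio[tab$compartment == "margin"] /
      tab$ratio[tab$compartment == "center"]
  } else NA_real_
  structure(list(table = tab, normalized_margin_ratio = nmr,
                 evaluable = evaluable,
                 dab_threshold = dab_threshold,
                 hema_threshold = hema_threshold),
            class = "slide_quant")
}

#' @export
print.slide_quant <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("normalized margin ratio: %.4g (evaluable: %s)\n",
              x$normalized_margin_ratio, x$evaluable))
  invisible(x)
}

#' Full margin-versus-center pipeline for one slide
#'
#' Wires the deterministic re-implementation of the whole-slide procedure:
#' color deconvolution, macrophage detection on the DAB channel,
#' compartment construction (margin band of `margin_width_um` via distance
#' transform, technical-edge exclusion), and stain-area quantification.
#'
#' @param image H x W x 3 RGB array.
#' @param tumor_mask logical H x W tumor mask (from [segment_tissue()], a
#'   mask file, or generator truth).
#' @param microns_per_pixel pixel pitch, um/px.
#' @param margin_width_um margin band width (default 1000 = 1 mm).
#' @param exclusion_mask optional manual exclusion mask (vessels, bronchi,
#'   artefacts).
#' @param exclude_macrophages run [detect_macrophages()] and exclude the
#'   result (default TRUE).
#' @param stain_matrix,dab_threshold,hema_threshold passed to
#'   [quantify_slide()].
#' @param macrophage_od_cutoff,macrophage_size_range_um2 passed to
#'   [detect_macrophages()].
#' @return a `slide_quant` object (see [quantify_slide()]) with the
#'   compartment masks attached as attribute `masks`.
#' @export
analyze_slide <- function(image, tumor_mask, microns_per_pixel,
                          margin_width_um = 1000,
                          exclusion_mask = NULL,
                          exclude_macrophages = TRUE,
                          stain_matrix = hdab_stain_matrix(),
                          dab_threshold = 0.15, hema_threshold = 0.15,
                          macrophage_od_cutoff = 1.2,
                          macrophage_size_range_um2 = c(10, 600)) {
  excl <- exclusion_mask
  if (exclude_macrophages) {
    conc <- deconvolve_stains(rgb_to_od(image), stain_matrix)
    mac <- detect_macrophages(conc$dab, microns_per_pixel,
                              od_cutoff = macrophage_od_cutoff,
                              size_range_um2 = macrophage_size_range_um2)
    excl <- if (is.null(excl)) mac else (excl | mac)
  }
  masks <- build_compartments(tumor_mask, microns_per_pixel,
                              margin_width_um, excl)
  out <- quantify_slide(image, masks, stain_matrix,
                        dab_threshold, hema_threshold)
  attr(out, "masks") <- masks
  out
}

#' One-sample test of margin enrichment across slides
#'
#' Tests whether the normalized margin ratio differs from 1 across slides:
#' a one-sample Student t-test of log2(normalized_margin_ratio) against 0,
#' two-sided. Degenerate zero-variance input is handled by contract: all
#' ratios exactly 1 gives t = 0, p = 1; zero variance with nonzero mean
#' reports p at the machine floor with `degenerate = TRUE` (the t statistic
#' is undefined).
#'
#' @param normalized_ratios numeric vector of per-slide normalized margin
#'   ratios (> 0), `NA` dropped.
#' @return list: `mean_log2`, `statistic` (t), `df`, `p.value`, `n`,
#'   `degenerate`.
#' @export
margin_center_test <- function(normalized_ratios) {
  x <- log2(normalized_ratios[!is.na(normalized_ratios)])
  n <- length(x)
  if (n < 3)
    abort("need at least 3 evaluable slides", "ihcmet_insufficient_data")
  m <- mean(x); s <- sd(x)
  if (s == 0) {
    if (m == 0)
      return(list(mean_log2 = 0, statistic = 0, df = n - 1, p.value = 1,
                  n = n, degenerate = TRUE))
    return(list(mean_log2 = m, statistic = Inf, df = n - 1,
                p.value = .Machine$double.xmin, n = n, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(mean_log2 = m, statistic = t, df = n - 1,
       p.value = 2 * pt(-abs(t), n - 1), n = n, degenerate = FALSE)
}
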