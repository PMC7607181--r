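# Shared fixtures: all built in code at test time.

iou <- function(a, b) sum(a & b) / sum(a | b)

# a small, fast slide: 1 mm tumor disc, 0.3 mm margin band
small_slide_params <- function(...) {
  slide_params(image_size = c(280L, 280L),
               microns_per_pixel = 4,
               tumor_geometry = list(type = "disc", radius_um = 500),
               margin_width_um = 300,
               ...)
}

# long-format cohort rows for one patient
core_rows <- function(patient_id, marker, intensity, density,
                      histology = "LUAD", site = "primary") {
  data.frame(patient_id = patient_id, histology = histology, site = site,
             t_stage = 1, grade = 2, gender = "female", age = 60,
             marker = marker, core_index = seq_along(intensity),
             intensity = intensity, density = density,
             stringsAsFactors = FALSE)
}

# exponential survival sample with uniform censoring
sim_surv <- function(n, hazard = 0.05, hr = 1, x = NULL, cens_max = 40) {
  if (is.null(x)) x <- rbinom(n, 1, 0.5)
  tm <- rexp(n, hazard * hr^x)
  cn <- runif(n, 0, cens_max)
  data.frame(time = pmin(tm, cn), event = tm <= cn, x = x)
}
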