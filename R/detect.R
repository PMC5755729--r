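#' Nucleus detection parameters
#'
#' Bundles the tunable parameters of the segmentation and
#' classification stage. Physical sizes are given in microns so the
#' same settings transfer across scanner resolutions; they are
#' converted to pixels using the slide's `mpp`.
#'
#' @param smoothing_sigma Gaussian smoothing scale for the nuclear-stain
#'   map, in pixels.
#' @param nuclear_threshold Concentration threshold on the smoothed
#'   combined (hematoxylin + DAB) map above which a pixel is nuclear.
#' @param min_area_um2 Minimum nucleus area in square microns;
#'   components smaller than the pixel-equivalent are discarded.
#' @param split_touching Apply distance-transform watershed to split
#'   touching nuclei?
#' @param dab_threshold Mean-DAB concentration above which (strictly) a
#'   nucleus is called Ki67-positive; ties fall to negative.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(smoothing_sigma = 1,
                             nuclear_threshold = 0.15,
                             min_area_um2 = 10,
                             split_touching = TRUE,
                             dab_threshold = 0.2) {
  stopifnot(smoothing_sigma > 0, nuclear_threshold > 0, min_area_um2 >= 0)
  if (dab_threshold < 0) {
    stop("`dab_threshold` must be non-negative", call. = FALSE)
  }
  structure(list(smoothing_sigma = smoothing_sigma,
                 nuclear_threshold = nuclear_threshold,
                 min_area_um2 = min_area_um2,
                 split_touching = split_touching,
                 dab_threshold = dab_threshold),
            class = "detection_params")
}

#' Detect nuclei in deconvolved stain maps
#'
#' Segments the combined nuclear-stain map (hematoxylin + DAB
#' concentration): Gaussian smoothing, fixed threshold, connected
#' components, optional distance-transform watershed to split touching
#' nuclei, then removal of components below the minimum area. Per-stain
#' mean concentrations are measured over each component mask on the
#' unsmoothed maps.
#'
#' @param conc Stain concentration maps from [deconvolve_stains()].
#' @param params A [detection_params()] bundle.
#' @param mpp Microns per pixel; taken from `conc` when available.
#' @return A tibble with one row per detection: `x_px`, `y_px`
#'   (centroid, 0-based, continuous), `area_px2`, `mean_dab_od`,
#'   `mean_hema_od`, `label` (`NA` until [classify_detections()]).
#' @export
detect_nuclei <- function(conc, params = detection_params(),
                          mpp = attr(conc, "mpp")) {
  stopifnot(inherits(params, "detection_params"))
  if (is.null(mpp)) {
    stop("`mpp` is required (not found on `conc`)", call. = FALSE)
  }
  nuclear <- conc$hema + conc$dab
  empty <- tibble::tibble(
    x_px = numeric(), y_px = numeric(), area_px2 = numeric(),
    mean_dab_od = numeric(), mean_hema_od = numeric(),
    label = character()
  )
  if (max(nuclear) <= params$nuclear_threshold) {
    return(empty)
  }
  smoothed <- EBImage::gblur(nuclear, sigma = params$smoothing_sigma)
  mask <- smoothed > params$nuclear_threshold
  if (!any(mask)) return(empty)
  storage.mode(mask) <- "integer"
  if (params$split_touching) {
    lab <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1)
  } else {
    lab <- EBImage::bwlabel(mask)
  }
  lab <- as.integer(lab)
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(empty)
  comp <- lab[idx]
  nr <- nrow(mask)
  # 0-based image coordinates from matrix linear index
  row0 <- (idx - 1L) %% nr          # y
  col0 <- (idx - 1L) %/% nr         # x
  area <- tabulate(comp)
  keep_ids <- which(area >= params$min_area_um2 / mpp^2)
  if (length(keep_ids) == 0L) return(empty)
  keep <- comp %in% keep_ids
  comp <- comp[keep]; row0 <- row0[keep]; col0 <- col0[keep]
  pix <- idx[keep]
  f <- factor(comp, levels = keep_ids)
  out <- tibble::tibble(
    x_px = as.numeric(tapply(col0, f, mean)),
    y_px = as.numeric(tapply(row0, f, mean)),
    area_px2 = as.numeric(tabulate(comp)[keep_ids]),
    mean_dab_od = as.numeric(tapply(conc$dab[pix], f, mean)),
    mean_hema_od = as.numeric(tapply(conc$hema[pix], f, mean)),
    label = NA_character_
  )
  out[order(out$y_px, out$x_px), , drop = FALSE]
}

#' Classify detections as Ki67-positive or -negative
#'
#' A nucleus is Ki67-positive (brown, DAB) when its mean DAB
#' concentration strictly exceeds the positivity threshold, otherwise
#' Ki67-negative (blue, hematoxylin only). The strict inequality makes
#' ties fall to negative, a conservative and deterministic rule.
#' Only the `label` column changes; detections are never added or
#' dropped here.
#'
#' @param detections Tibble from [detect_nuclei()].
#' @param dab_threshold Positivity threshold on mean DAB concentration;
#'   must be non-negative.
#' @return The same tibble with `label` filled with `"positive"` /
#'   `"negative"`.
#' @export
classify_detections <- function(detections, dab_threshold = 0.2) {
  if (length(dab_threshold) != 1L || !is.finite(dab_threshold) ||
      dab_threshold < 0) {
    stop("`dab_threshold` must be a single non-negative number",
         call. = FALSE)
  }
  dplyr::mutate(
    detections,
    label = dplyr::if_else(.data$mean_dab_od > dab_threshold,
                           "positive", "negative")
  )
}

#' Detect and classify nuclei in one step
#'
#' Convenience composition of [rgb_to_od()], [deconvolve_stains()],
#' [detect_nuclei()] and [classify_detections()].
#'
#' @param image A [slide_image()].
#' @param params A [detection_params()] bundle.
#' @param basis A [stain_basis()] matrix.
#' @return Labeled detection tibble.
#' @export
find_nuclei <- function(image, params = detection_params(),
                        basis = stain_basis()) {
  conc <- deconvolve_stains(rgb_to_od(image), basis)
  det <- detect_nuclei(conc, params, mpp = image$mpp)
  classify_detections(det, params$dab_threshold)
}
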