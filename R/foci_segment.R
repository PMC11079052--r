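#' Nucleus segmentation configuration
#'
#' @param method `"threshold_otsu"` (global Otsu on the projected DNA
#'   channel) or `"external_mask"` (validate and relabel a supplied mask, so
#'   masks from external segmenters can be reused).
#' @param min_nucleus_area_um2 objects below this area are removed.
#' @param fill_holes fill holes inside nuclei before labeling.
#' @param split_touching split touching nuclei by distance-transform
#'   watershed.
#' @param projection reduction applied to a 3D stack before segmentation:
#'   `"max"` (maximum intensity projection) or `"none"` (input must be 2D).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(method = c("threshold_otsu", "external_mask"),
                                min_nucleus_area_um2 = 20,
                                fill_holes = TRUE,
                                split_touching = FALSE,
                                projection = c("max", "none")) {
  method <- match.arg(method)
  projection <- match.arg(projection)
  stop_if_not(is_number(min_nucleus_area_um2) && min_nucleus_area_um2 > 0,
              "min_nucleus_area_um2 must be positive")
  structure(list(method = method, min_nucleus_area_um2 = min_nucleus_area_um2,
                 fill_holes = isTRUE(fill_holes),
                 split_touching = isTRUE(split_touching),
                 projection = projection),
            class = "segmentation_config")
}

#' Foci detection configuration
#'
#' Thresholds are computed independently inside each nucleus, which makes
#' detection invariant to per-cell absolute brightness.
#'
#' @param threshold_rule `"otsu_within_nucleus"` (Otsu on the nucleus's own
#'   pixels) or `"mean_plus_k_sd"`.
#' @param k multiplier for `mean_plus_k_sd`.
#' @param min_focus_area_um2 connected components below this area are
#'   discarded.
#' @param smoothing_sigma_px Gaussian blur applied to the DNA channel before
#'   thresholding (0 disables).
#' @return an object of class `foci_config`.
#' @export
foci_config <- function(threshold_rule = c("otsu_within_nucleus", "mean_plus_k_sd"),
                        k = 2,
                        min_focus_area_um2 = 0.25,
                        smoothing_sigma_px = 0) {
  threshold_rule <- match.arg(threshold_rule)
  stop_if_not(is_number(k) && k > 0, "k must be positive")
  stop_if_not(is_number(min_focus_area_um2, 0),
              "min_focus_area_um2 must be >= 0")
  stop_if_not(is_number(smoothing_sigma_px, 0),
              "smoothing_sigma_px must be >= 0")
  structure(list(threshold_rule = threshold_rule, k = k,
                 min_focus_area_um2 = min_focus_area_um2,
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "foci_config")
}

project_stack <- function(raster, projection) {
  if (length(dim(raster)) == 3L) {
    stop_if_not(projection == "max",
                "input is a stack but projection = 'none'")
    apply(raster, c(1, 2), max)
  } else raster
}

#' Segment nuclei on a DNA channel
#'
#' Global Otsu threshold on the (optionally max-projected) DNA channel,
#' optional hole filling and watershed splitting, connected-component
#' labeling, and a minimum-area filter. With `method = "external_mask"` the
#' supplied mask is validated and relabeled, not recomputed.
#'
#' @param dna_channel numeric matrix (or 3D stack) of DNA-stain intensities.
#' @param config a [segmentation_config()].
#' @param pixel_size_um pixel size (micrometers per pixel), used to convert the
#'   minimum area.
#' @param mask external label mask (required when `method = "external_mask"`).
#' @return an integer label matrix with labels contiguous from 1 and
#'   attribute `n_nuclei`. When no nuclei survive, `n_nuclei` is 0 and the
#'   mask is all zeros (an explicit empty result, not an error).
#' @examples
#' sc <- simulate_scene(scene_params(nucleus_count = 3, seed = 2))
#' m <- segment_nuclei(sc$channels$dna, segmentation_config(), 0.1)
#' attr(m, "n_nuclei")
#' @export
segment_nuclei <- function(dna_channel, config = segmentation_config(),
                           pixel_size_um = 0.1, mask = NULL) {
  stop_if_not(inherits(config, "segmentation_config"),
              "config must be segmentation_config()")
  stop_if_not(is_number(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be positive")
  min_px <- config$min_nucleus_area_um2 / pixel_size_um^2

  if (config$method == "external_mask") {
    stop_if_not(!is.null(mask), "method 'external_mask' requires a mask")
    stop_if_not(all(mask >= 0) && all(mask == round(mask)),
                "external mask must contain non-negative integer labels")
    lab <- mask
    storage.mode(lab) <- "integer"
  } else {
    img <- project_stack(dna_channel, config$projection)
    stop_if_not(length(img) > 0 && all(is.finite(img)),
                "empty or non-finite image")
    # Otsu on log-intensities: bright foci make the raw histogram trimodal,
    # where the background/nucleus split is not reliably the Otsu optimum;
    # the log compresses the foci mode onto the nucleoplasm mode
    limg <- log1p(pmax(img, 0))
    thr <- otsu_threshold(as.vector(limg))
    if (is.na(thr)) {
      out <- matrix(0L, nrow(img), ncol(img))
      attr(out, "n_nuclei") <- 0L
      return(out)
    }
    bin <- limg > thr
    if (config$fill_holes)
      bin <- EBImage::fillHull(bin) > 0
    if (config$split_touching) {
      dm <- EBImage::distmap(EBImage::Image(bin * 1))
      lab <- EBImage::watershed(dm)
      lab <- EBImage::imageData(lab) * bin
    } else {
      lab <- EBImage::bwlabel(bin * 1)
    }
    lab <- matrix(as.integer(round(lab)), nrow(img), ncol(img))
  }

  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_px)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  out <- relabel_mask(lab)
  attr(out, "n_nuclei") <- attr(out, "n_objects")
  attr(out, "n_objects") <- NULL
  out
}

#' Detect DNA-dense foci within each nucleus
#'
#' For every nucleus the threshold is computed from that nucleus's own
#' pixels (per-nucleus Otsu by default), so detection does not depend on
#' absolute brightness. Nuclei with constant intensity yield no foci (the
#' threshold is undefined there); such nuclei are reported in the
#' `"skipped_nuclei"` attribute.
#'
#' @param dna_channel numeric matrix of DNA-stain intensities.
#' @param nucleus_mask integer label mask from [segment_nuclei()].
#' @param config a [foci_config()].
#' @param pixel_size_um pixel size (micrometers per pixel).
#' @return a logical matrix marking foci pixels (always a subset of the
#'   nuclei), with attribute `skipped_nuclei`.
#' @export
detect_foci <- function(dna_channel, nucleus_mask, config = foci_config(),
                        pixel_size_um = 0.1) {
  stop_if_not(inherits(config, "foci_config"), "config must be foci_config()")
  stop_if_not(all(dim(dna_channel) == dim(nucleus_mask)),
              "raster and mask must share dimensions")
  img <- dna_channel
  if (config$smoothing_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = config$smoothing_sigma_px))
  min_px <- max(1, config$min_focus_area_um2 / pixel_size_um^2)
  foci <- matrix(FALSE, nrow(img), ncol(img))
  skipped <- integer(0)
  ids <- setdiff(sort(unique(as.vector(nucleus_mask))), 0L)
  for (id in ids) {
    inside <- nucleus_mask == id
    vals <- img[inside]
    thr <- switch(config$threshold_rule,
      otsu_within_nucleus = otsu_threshold(vals),
      mean_plus_k_sd = if (sd(vals) == 0) NA_real_
                       else mean(vals) + config$k * sd(vals))
    if (is.na(thr)) {
      skipped <- c(skipped, id)
      next
    }
    cand <- inside & img > thr
    comp <- EBImage::bwlabel(cand * 1)
    sizes <- tabulate(comp[comp > 0])
    keep <- which(sizes >= min_px)
    foci[cand] <- comp[cand] %in% keep
  }
  attr(foci, "skipped_nuclei") <- skipped
  foci
}
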