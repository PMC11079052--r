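#' Parameters for a synthetic two-channel nuclear scene
#'
#' Describes a field of view containing disc-shaped nuclei whose DNA channel
#' carries bright DNA-dense foci (chromocenters) over a dimmer nucleoplasm,
#' plus a reporter channel that either co-enriches at the foci
#' (`reporter_mode = "colocalized"`) or stays diffuse across the nucleus
#' (`reporter_mode = "diffuse"`).
#'
#' Intensities are in arbitrary units: the nucleoplasm sits at
#' `nucleoplasm_level`, foci at `dna_foci_to_nucleoplasm_contrast *
#' nucleoplasm_level` in the DNA channel and at `reporter_foci_ratio *
#' nucleoplasm_level` in a colocalized reporter. Foci are rendered as
#' hard-edged discs so that ground-truth means, areas and ratios are exact by
#' construction; additive Gaussian noise (`noise_sd`, a.u.) is applied last
#' and clamped at zero.
#'
#' @param nucleus_count number of nuclei to place.
#' @param nucleus_radius_px nucleus radius in pixels.
#' @param foci_per_nucleus mean of the per-nucleus Poisson focus count.
#' @param focus_radius_px focus radius in pixels (must be `< nucleus_radius_px`).
#' @param dna_foci_to_nucleoplasm_contrast DNA-channel foci/nucleoplasm mean
#'   ratio (>= 1).
#' @param reporter_mode `"colocalized"` or `"diffuse"`.
#' @param reporter_foci_ratio reporter foci/nucleoplasm ratio when colocalized.
#' @param noise_sd additive Gaussian noise SD (a.u.).
#' @param pixel_size_um pixel size in micrometers per pixel.
#' @param seed integer seed; the same parameters and seed give bit-identical
#'   rasters.
#' @param width,height optional raster size in pixels; by default sized to
#'   hold `nucleus_count` nuclei comfortably.
#' @param nucleoplasm_level nucleoplasm intensity (a.u.).
#' @param background_level intensity outside nuclei (a.u.).
#' @return an object of class `scene_params`.
#' @seealso [simulate_scene()]
#' @export
scene_params <- function(nucleus_count = 5L,
                         nucleus_radius_px = 40,
                         foci_per_nucleus = 4,
                         focus_radius_px = 6,
                         dna_foci_to_nucleoplasm_contrast = 3,
                         reporter_mode = c("colocalized", "diffuse"),
                         reporter_foci_ratio = 3,
                         noise_sd = 0,
                         pixel_size_um = 0.1,
                         seed = 1L,
                         width = NULL, height = NULL,
                         nucleoplasm_level = 100,
                         background_level = 0) {
  reporter_mode <- match.arg(reporter_mode)
  stop_if_not(is_count(nucleus_count, 1), "nucleus_count must be a positive integer")
  stop_if_not(is_number(nucleus_radius_px, 2), "nucleus_radius_px must be >= 2")
  stop_if_not(is_number(foci_per_nucleus, 0), "foci_per_nucleus must be >= 0")
  stop_if_not(is_number(focus_radius_px, 1), "focus_radius_px must be >= 1")
  stop_if_not(focus_radius_px < nucleus_radius_px,
              "focus_radius_px must be smaller than nucleus_radius_px")
  stop_if_not(is_number(dna_foci_to_nucleoplasm_contrast, 1),
              "dna_foci_to_nucleoplasm_contrast must be >= 1")
  stop_if_not(is_number(reporter_foci_ratio, 0), "reporter_foci_ratio must be >= 0")
  stop_if_not(is_number(noise_sd, 0), "noise_sd must be >= 0")
  stop_if_not(is_number(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be positive")
  stop_if_not(is_number(nucleoplasm_level) && nucleoplasm_level > 0,
              "nucleoplasm_level must be positive")
  stop_if_not(is_number(background_level, 0), "background_level must be >= 0")
  if (is.null(width) || is.null(height)) {
    ncol_grid <- ceiling(sqrt(nucleus_count))
    nrow_grid <- ceiling(nucleus_count / ncol_grid)
    cell <- ceiling(2 * nucleus_radius_px + 12)
    width <- width %||% (ncol_grid * cell)
    height <- height %||% (nrow_grid * cell)
  }
  stop_if_not(is_count(width, 8) && is_count(height, 8),
              "width/height must be integers >= 8")
  structure(list(
    nucleus_count = as.integer(nucleus_count),
    nucleus_radius_px = nucleus_radius_px,
    foci_per_nucleus = foci_per_nucleus,
    focus_radius_px = focus_radius_px,
    dna_foci_to_nucleoplasm_contrast = dna_foci_to_nucleoplasm_contrast,
    reporter_mode = reporter_mode,
    reporter_foci_ratio = reporter_foci_ratio,
    noise_sd = noise_sd,
    pixel_size_um = pixel_size_um,
    seed = as.integer(seed),
    width = as.integer(width), height = as.integer(height),
    nucleoplasm_level = nucleoplasm_level,
    background_level = background_level
  ), class = "scene_params")
}

#' Simulate a two-channel nuclear scene with ground truth
#'
#' Renders the scene described by [scene_params()]: disjoint disc nuclei are
#' placed by rejection sampling, each receives a Poisson number of
#' non-overlapping foci fully inside the nucleus, and the DNA/reporter
#' channels are filled at the configured levels before additive noise.
#'
#' @param params a `scene_params` object.
#' @return an object of class `synthetic_scene`: a list with
#'   \describe{
#'     \item{channels}{named list of numeric matrices (`dna`, `reporter`),
#'       row-major, values >= 0 (a.u.).}
#'     \item{ground_truth}{list with `nucleus_label_mask` (integer matrix,
#'       0 = background, ids contiguous from 1), `foci_mask` (logical matrix,
#'       subset of the nuclei), and `per_nucleus` (data frame of true foci
#'       count, foci area in px, and noise-free channel means in foci and
#'       nucleoplasm).}
#'     \item{params}{the generating parameters.}
#'   }
#' @examples
#' sc <- simulate_scene(scene_params(nucleus_count = 2, seed = 7))
#' sc$ground_truth$per_nucleus
#' @export
simulate_scene <- function(params) {
  stop_if_not(inherits(params, "scene_params"), "params must be scene_params()")
  p <- params
  withr::with_seed(p$seed, {
    nr <- p$height; nc <- p$width
    r <- p$nucleus_radius_px
    # disjoint placement: jittered grid when it fits, otherwise rejection
    # sampling with bounded retries (too-crowded fields error out)
    gx <- seq(r + 6, nc - r - 5, by = 2 * r + 11)
    gy <- seq(r + 6, nr - r - 5, by = 2 * r + 11)
    if (length(gx) * length(gy) >= p$nucleus_count) {
      cells <- expand.grid(x = gx, y = gy)
      pick <- sample.int(nrow(cells), p$nucleus_count)
      centers <- cbind(cells$x[pick] + runif(p$nucleus_count, -4, 4),
                       cells$y[pick] + runif(p$nucleus_count, -4, 4))
      centers[, 1] <- pmin(pmax(centers[, 1], r + 2), nc - r - 1)
      centers[, 2] <- pmin(pmax(centers[, 2], r + 2), nr - r - 1)
    } else {
      centers <- matrix(numeric(0), ncol = 2)
      tries <- 0L
      while (nrow(centers) < p$nucleus_count) {
        tries <- tries + 1L
        if (tries > 5000L)
          stop("could not place ", p$nucleus_count,
               " disjoint nuclei: field of view too crowded", call. = FALSE)
        cx <- runif(1, r + 2, nc - r - 1)
        cy <- runif(1, r + 2, nr - r - 1)
        if (nrow(centers) == 0 ||
            all((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 >= (2 * r + 3)^2))
          centers <- rbind(centers, c(cx, cy))
      }
    }

    label <- matrix(0L, nr, nc)
    foci <- matrix(FALSE, nr, nc)
    n_foci <- integer(p$nucleus_count)
    for (i in seq_len(p$nucleus_count)) {
      px <- disc_pixels(centers[i, 1], centers[i, 2], r, nr, nc)
      label[cbind(px$y, px$x)] <- i
      want <- rpois(1L, p$foci_per_nucleus)
      placed <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(want)) {
        for (attempt in 1:100) {
          ang <- runif(1, 0, 2 * pi)
          rad <- sqrt(runif(1)) * (r - p$focus_radius_px - 1)
          fx <- centers[i, 1] + rad * cos(ang)
          fy <- centers[i, 2] + rad * sin(ang)
          if (nrow(placed) == 0 ||
              all((placed[, 1] - fx)^2 + (placed[, 2] - fy)^2 >=
                    (2 * p$focus_radius_px + 1)^2)) {
            placed <- rbind(placed, c(fx, fy))
            fp <- disc_pixels(fx, fy, p$focus_radius_px, nr, nc)
            foci[cbind(fp$y, fp$x)] <- TRUE
            break
          }
        }
      }
      n_foci[i] <- nrow(placed)
    }

    lvl <- p$nucleoplasm_level
    dna <- matrix(p$background_level, nr, nc)
    dna[label > 0] <- lvl
    dna[foci] <- p$dna_foci_to_nucleoplasm_contrast * lvl
    reporter <- matrix(p$background_level, nr, nc)
    reporter[label > 0] <- lvl
    if (p$reporter_mode == "colocalized")
      reporter[foci] <- p$reporter_foci_ratio * lvl

    per_nucleus <- data.frame(
      nucleus_id = seq_len(p$nucleus_count),
      foci_count = n_foci,
      foci_area_px = vapply(seq_len(p$nucleus_count),
                            function(i) sum(foci & label == i), integer(1)),
      dna_foci_mean = ifelse(n_foci > 0,
                             p$dna_foci_to_nucleoplasm_contrast * lvl, NA_real_),
      dna_nucleoplasm_mean = lvl,
      reporter_foci_mean = ifelse(
        n_foci > 0,
        if (p$reporter_mode == "colocalized") p$reporter_foci_ratio * lvl else lvl,
        NA_real_),
      reporter_nucleoplasm_mean = lvl
    )

    if (p$noise_sd > 0) {
      dna <- pmax(dna + rnorm(length(dna), 0, p$noise_sd), 0)
      reporter <- pmax(reporter + rnorm(length(reporter), 0, p$noise_sd), 0)
    }

    structure(list(
      channels = list(dna = dna, reporter = reporter),
      ground_truth = list(nucleus_label_mask = label, foci_mask = foci,
                          per_nucleus = per_nucleus),
      params = p
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_scene: %dx%d px, %d nuclei, reporter %s, noise_sd %.3g\n",
              p$height, p$width, p$nucleus_count, p$reporter_mode, p$noise_sd))
  invisible(x)
}

#' Write a synthetic scene to disk
#'
#' Channels go to a multi-page 32-bit float TIFF (one page per channel, in
#' channel order `dna`, `reporter`), the nucleus label mask and foci mask to
#' 16-bit label TIFFs, and the per-nucleus ground-truth table to CSV.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  stop_if_not(inherits(scene, "synthetic_scene"), "scene must be a synthetic_scene")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    channels = file.path(dir, paste0(prefix, "_channels.tif")),
    nucleus_mask = file.path(dir, paste0(prefix, "_nucleus_mask.tif")),
    foci_mask = file.path(dir, paste0(prefix, "_foci_mask.tif")),
    ground_truth = file.path(dir, paste0(prefix, "_ground_truth.csv"))
  )
  scale <- max(unlist(lapply(scene$channels, max)), 1)
  tiff::writeTIFF(lapply(scene$channels, function(m) m / scale),
                  paths[["channels"]], bits.per.sample = 32L)
  write_label_tiff(scene$ground_truth$nucleus_label_mask, paths[["nucleus_mask"]])
  write_label_tiff(scene$ground_truth$foci_mask * 1L, paths[["foci_mask"]])
  write.csv(scene$ground_truth$per_nucleus, paths[["ground_truth"]],
            row.names = FALSE)
  invisible(paths)
}

write_label_tiff <- function(mask, path) {
  stop_if_not(max(mask) <= 65535, "label mask exceeds 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
}

#' Read a 16-bit label TIFF written by [write_scene()]
#' @param path file path.
#' @return integer matrix of labels.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  m <- round(m * 65535)
  storage.mode(m) <- "integer"
  m
}
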