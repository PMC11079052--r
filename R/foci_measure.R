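#' Measure per-nucleus areas, foci and channel intensities
#'
#' For each nucleus: its area, the number and summed area of its foci, and
#' per channel the mean intensity within foci, the mean in the nucleoplasm
#' (the nucleus minus its foci), the integrated nuclear intensity, and the
#' foci/nucleoplasm ratio. The ratio is absent (`NA`) for nuclei without
#' foci. Areas are reported in micrometers squared
#' (`pixel count * pixel_size_um^2`); intensities stay in acquisition units.
#'
#' @param channels named list of numeric matrices (e.g. `dna`, `reporter`),
#'   all sharing the mask dimensions.
#' @param nucleus_mask integer label mask from [segment_nuclei()].
#' @param foci_mask logical foci mask from [detect_foci()]; every foci pixel
#'   must lie inside a nucleus.
#' @param pixel_size_um pixel size (micrometers per pixel).
#' @return a data frame with one row per nucleus: `nucleus_id`,
#'   `nucleus_area_um2`, `foci_count`, `foci_area_um2`, and per channel `c`
#'   the columns `mean_foci_c`, `mean_nucleoplasm_c`, `total_nuclear_c`,
#'   `ratio_c`.
#' @examples
#' sc <- simulate_scene(scene_params(nucleus_count = 2, seed = 5))
#' gt <- sc$ground_truth
#' measure_nuclei(sc$channels, gt$nucleus_label_mask, gt$foci_mask, 0.1)
#' @export
measure_nuclei <- function(channels, nucleus_mask, foci_mask, pixel_size_um) {
  stop_if_not(is.list(channels) && length(channels) > 0 &&
                !is.null(names(channels)) && all(nzchar(names(channels))),
              "channels must be a named list of matrices")
  stop_if_not(is_number(pixel_size_um) && pixel_size_um > 0,
              "pixel_size_um must be positive")
  for (ch in channels)
    stop_if_not(all(dim(ch) == dim(nucleus_mask)),
                "channel dimensions must match the nucleus mask")
  stop_if_not(all(dim(foci_mask) == dim(nucleus_mask)),
              "foci mask dimensions must match the nucleus mask")
  if (any(foci_mask & nucleus_mask == 0))
    stop("mask inconsistency: foci pixels outside any nucleus", call. = FALSE)

  ids <- setdiff(sort(unique(as.vector(nucleus_mask))), 0L)
  px2 <- pixel_size_um^2
  if (length(ids) == 0L) {
    cols <- c("nucleus_id", "nucleus_area_um2", "foci_count", "foci_area_um2",
              as.vector(outer(c("mean_foci_", "mean_nucleoplasm_",
                                "total_nuclear_", "ratio_"),
                              names(channels), paste0)))
    empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    empty$nucleus_id <- integer(0)
    empty$foci_count <- integer(0)
    return(empty)
  }

  # label foci once; assign each component to the nucleus containing it
  comp <- EBImage::bwlabel(foci_mask * 1)
  comp_ids <- setdiff(sort(unique(as.vector(comp))), 0)
  comp_nucleus <- vapply(comp_ids, function(k) {
    nuc <- unique(nucleus_mask[comp == k])
    nuc[nuc > 0][1]
  }, numeric(1))

  rows <- lapply(ids, function(id) {
    inside <- nucleus_mask == id
    f <- inside & foci_mask
    n_in <- sum(inside)
    n_f <- sum(f)
    count <- sum(comp_nucleus == id)
    row <- list(nucleus_id = id,
                nucleus_area_um2 = n_in * px2,
                foci_count = as.integer(count),
                foci_area_um2 = n_f * px2)
    for (nm in names(channels)) {
      v <- channels[[nm]]
      mf <- if (n_f > 0) mean(v[f]) else NA_real_
      mn <- if (n_in > n_f) mean(v[inside & !foci_mask]) else NA_real_
      row[[paste0("mean_foci_", nm)]] <- mf
      row[[paste0("mean_nucleoplasm_", nm)]] <- mn
      row[[paste0("total_nuclear_", nm)]] <- sum(v[inside])
      row[[paste0("ratio_", nm)]] <- if (count > 0) mf / mn else NA_real_
    }
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Classify nuclear reporter distribution as spotty / mixed / diffuse
#'
#' Applies the three-category rule to the foci/nucleoplasm ratio of a
#' channel: `diffuse` when the nucleus has no foci or the ratio is at most
#' `t_diffuse`; `spotty` when the ratio is at least `t_spotty`; `mixed`
#' otherwise. Thresholds are echoed in the output so every call is
#' reproducible from it.
#'
#' @param measurements data frame from [measure_nuclei()].
#' @param channel channel name whose ratio is classified.
#' @param t_spotty,t_diffuse thresholds with `t_spotty > t_diffuse >= 1`.
#' @return a data frame with `nucleus_id`, `label` (factor
#'   spotty/mixed/diffuse), `ratio_used`, `t_spotty`, `t_diffuse`.
#' @export
classify_distribution <- function(measurements, channel = "reporter",
                                  t_spotty = 1.5, t_diffuse = 1.1) {
  stop_if_not(t_spotty > t_diffuse && t_diffuse >= 1,
              "thresholds must satisfy t_spotty > t_diffuse >= 1")
  rcol <- paste0("ratio_", channel)
  stop_if_not(rcol %in% names(measurements),
              "channel '%s' not present in measurements", channel)
  ratio <- measurements[[rcol]]
  count <- measurements$foci_count
  label <- ifelse(count == 0 | is.na(ratio) | ratio <= t_diffuse, "diffuse",
                  ifelse(ratio >= t_spotty, "spotty", "mixed"))
  data.frame(nucleus_id = measurements$nucleus_id,
             label = factor(label, levels = c("spotty", "mixed", "diffuse")),
             ratio_used = ratio, t_spotty = t_spotty, t_diffuse = t_diffuse)
}

#' Summarize classification calls across replicates
#'
#' Per group, the fraction of cells in each category is computed within each
#' replicate, then averaged across replicates with an SD (the mean +/- SD
#' convention used for species-panel distribution plots). With a single
#' replicate the SD is reported `NA` and flagged.
#'
#' @param calls data frame with columns `label`, `group`, `replicate`.
#' @return a data frame with one row per group x category: `group`, `label`,
#'   `mean_fraction`, `sd_fraction`, `n_replicates`, `single_replicate`.
#'   Within each group and replicate the fractions sum to 1.
#' @export
summarize_calls <- function(calls) {
  stop_if_not(all(c("label", "group", "replicate") %in% names(calls)),
              "calls needs columns label, group, replicate")
  stop_if_not(nrow(calls) > 0, "empty calls table")
  lev <- c("spotty", "mixed", "diffuse")
  calls$label <- factor(as.character(calls$label), levels = lev)
  out <- list()
  for (g in unique(calls$group)) {
    cg <- calls[calls$group == g, , drop = FALSE]
    stop_if_not(nrow(cg) > 0, "empty group '%s'", g)
    reps <- unique(cg$replicate)
    fr <- sapply(reps, function(r) {
      cr <- cg[cg$replicate == r, , drop = FALSE]
      as.vector(table(cr$label)) / nrow(cr)
    })
    fr <- matrix(fr, nrow = length(lev))
    out[[length(out) + 1L]] <- data.frame(
      group = g, label = lev,
      mean_fraction = rowMeans(fr),
      sd_fraction = if (length(reps) > 1) apply(fr, 1, sd) else NA_real_,
      n_replicates = length(reps),
      single_replicate = length(reps) == 1L)
  }
  do.call(rbind, out)
}
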