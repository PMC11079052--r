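# End-to-end runs: foci quantification over a directory of images, FRAP
# batch processing over a manifest of traces. Both write CSV outputs plus a
# JSON run manifest (config hash, per-file status, checksums) so identical
# inputs and config reproduce identical outputs.

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

run_manifest <- function(config, files) {
  list(tool = "chromofoci",
       version = as.character(utils::packageVersion("chromofoci")),
       config = config,
       config_hash = config_hash(config),
       files = files,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the foci quantification pipeline over a set of images
#'
#' For each multi-page TIFF: read the channels, segment nuclei on the DNA
#' channel, detect foci per nucleus, measure, and classify the reporter
#' distribution. Per-image failures are recorded in the manifest and the run
#' continues; the call errors only when there are no inputs or every image
#' fails.
#'
#' @param images character vector of TIFF paths, or a data frame with
#'   columns `path`, `group`, `replicate`.
#' @param output_dir directory for `measurements.csv`, `calls.csv`,
#'   `summary.csv` (when groups are given) and `manifest.json`; `NULL`
#'   writes nothing.
#' @param channels named integer vector mapping channel names to TIFF pages.
#' @param pixel_size_um pixel size (micrometers per pixel).
#' @param seg_config a [segmentation_config()].
#' @param foci_cfg a [foci_config()].
#' @param classify_channel channel whose distribution is classified.
#' @param t_spotty,t_diffuse classification thresholds.
#' @param seed seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed documents the provenance of simulated inputs).
#' @return invisibly, a list with `measurements`, `calls`, `summary`
#'   (or `NULL`), and `manifest`.
#' @export
run_foci_pipeline <- function(images, output_dir = NULL,
                              channels = c(dna = 1L, reporter = 2L),
                              pixel_size_um = 0.1,
                              seg_config = segmentation_config(),
                              foci_cfg = foci_config(),
                              classify_channel = "reporter",
                              t_spotty = 1.5, t_diffuse = 1.1,
                              seed = NA_integer_) {
  if (is.character(images)) {
    stop_if_not(length(images) > 0, "no inputs")
    images <- data.frame(path = images, group = "all", replicate = 1L)
  }
  stop_if_not(is.data.frame(images) && "path" %in% names(images),
              "images must be paths or a data frame with a path column")
  stop_if_not(nrow(images) > 0, "no inputs")
  if (is.null(images$group)) images$group <- "all"
  if (is.null(images$replicate)) images$replicate <- 1L
  stop_if_not("dna" %in% names(channels), "channels must map 'dna' to a page")

  config <- list(channels = as.list(channels), pixel_size_um = pixel_size_um,
                 segmentation = unclass(seg_config), foci = unclass(foci_cfg),
                 classify_channel = classify_channel,
                 t_spotty = t_spotty, t_diffuse = t_diffuse, seed = seed)

  measurements <- list(); calls <- list(); files <- list()
  for (i in seq_len(nrow(images))) {
    path <- images$path[i]
    res <- tryCatch({
      stop_if_not(file.exists(path), "file not found: %s", path)
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      chs <- lapply(channels, function(k) {
        stop_if_not(k <= length(pages), "page %d missing in %s", k, path)
        m <- pages[[k]]
        if (length(dim(m)) == 3L) m <- m[, , 1L]  # collapse RGB reads
        m
      })
      mask <- segment_nuclei(chs$dna, seg_config, pixel_size_um)
      foci <- detect_foci(chs$dna, mask, foci_cfg, pixel_size_um)
      meas <- measure_nuclei(chs, mask, foci, pixel_size_um)
      cl <- classify_distribution(meas, classify_channel, t_spotty, t_diffuse)
      meas$image <- path; meas$group <- images$group[i]
      meas$replicate <- images$replicate[i]
      cl$image <- path; cl$group <- images$group[i]
      cl$replicate <- images$replicate[i]
      list(meas = meas, calls = cl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      files[[i]] <- list(path = path, status = "failed",
                         message = conditionMessage(res))
    } else {
      files[[i]] <- list(path = path, status = "ok",
                         md5 = unname(tools::md5sum(path)))
      measurements[[length(measurements) + 1L]] <- res$meas
      calls[[length(calls) + 1L]] <- res$calls
    }
  }
  n_ok <- sum(vapply(files, function(f) f$status == "ok", logical(1)))
  if (n_ok == 0) stop("all inputs failed", call. = FALSE)

  measurements <- do.call(rbind, measurements)
  calls <- do.call(rbind, calls)
  summary_tab <- tryCatch(summarize_calls(calls), error = function(e) NULL)
  manifest <- run_manifest(config, files)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(measurements, file.path(output_dir, "measurements.csv"),
              row.names = FALSE)
    write.csv(calls, file.path(output_dir, "calls.csv"), row.names = FALSE)
    if (!is.null(summary_tab))
      write.csv(summary_tab, file.path(output_dir, "summary.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  invisible(list(measurements = measurements, calls = calls,
                 summary = summary_tab, manifest = manifest))
}

#' Run the FRAP batch pipeline over a manifest of traces
#'
#' Normalizes every trace, fits the two-phase association model, summarizes
#' mobile/immobile fractions and T50, and aggregates per group into a
#' summary table (group, n, mobile/immobile/T50 with SD and SEM).
#' Non-converged fits and unreadable files are excluded from the group
#' summary and counted.
#'
#' @param manifest data frame with columns `file` and `group`, or the path
#'   of such a CSV.
#' @param output_dir directory for `fits.csv`, `group_summary.csv` and
#'   `manifest.json`; `NULL` writes nothing.
#' @param prebleach passed to [normalize_frap()].
#' @param restarts passed to [fit_two_phase()].
#' @return invisibly, a list with `fits` (per-trace rows), `group_summary`,
#'   and `manifest`.
#' @export
run_frap_pipeline <- function(manifest, output_dir = NULL,
                              prebleach = "mean", restarts = 5L) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read.csv(manifest)
  stop_if_not(is.data.frame(manifest) &&
                all(c("file", "group") %in% names(manifest)),
              "manifest needs columns file and group")
  stop_if_not(nrow(manifest) > 0, "no inputs")

  config <- list(prebleach = prebleach, restarts = restarts)
  rows <- list(); files <- list()
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$file[i]
    res <- tryCatch({
      stop_if_not(file.exists(path), "file not found: %s", path)
      tr <- read_frap_trace(path)
      nt <- normalize_frap(tr, prebleach)
      fit <- fit_two_phase(nt, restarts)
      if (!fit$converged) stop("fit did not converge", call. = FALSE)
      sm <- summarize_fit(fit)
      data.frame(file = path, group = manifest$group[i],
                 mobile_pct = sm$mobile_pct, immobile_pct = sm$immobile_pct,
                 t50_s = sm$t50_s, t50_defined = sm$t50_defined,
                 rss = fit$rss)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      files[[i]] <- list(path = path, status = "failed",
                         message = conditionMessage(res))
    } else {
      files[[i]] <- list(path = path, status = "ok",
                         md5 = unname(tools::md5sum(path)))
      rows[[length(rows) + 1L]] <- res
    }
  }
  stop_if_not(length(rows) > 0, "all traces failed")
  fits <- do.call(rbind, rows)

  group_summary <- do.call(rbind, lapply(split(fits, fits$group), function(d) {
    n <- nrow(d)
    sdv <- function(x) if (n > 1) sd(x) else NA_real_
    data.frame(group = d$group[1L], n = n,
               mobile_pct_mean = mean(d$mobile_pct),
               mobile_pct_sd = sdv(d$mobile_pct),
               mobile_pct_sem = sdv(d$mobile_pct) / sqrt(n),
               immobile_pct_mean = mean(d$immobile_pct),
               immobile_pct_sd = sdv(d$immobile_pct),
               t50_s_mean = mean(d$t50_s[d$t50_defined]),
               t50_s_sd = sdv(d$t50_s[d$t50_defined]),
               n_t50_undefined = sum(!d$t50_defined))
  }))
  rownames(group_summary) <- NULL
  n_failed <- nrow(manifest) - nrow(fits)
  manifest_out <- run_manifest(config, files)
  manifest_out$n_excluded <- n_failed

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(fits, file.path(output_dir, "fits.csv"), row.names = FALSE)
    write.csv(group_summary, file.path(output_dir, "group_summary.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest_out, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
  }
  invisible(list(fits = fits, group_summary = group_summary,
                 manifest = manifest_out))
}
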