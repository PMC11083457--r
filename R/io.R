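#' Write a FLIM stack to disk
#'
#' Two layouts are supported. `"tiff"`: a multi-page TIFF in the
#' time-as-pages dialect — one 16-bit page per time bin, page k holding the
#' photon-count image of bin k — plus a sidecar JSON (`<path>.json`)
#' carrying the time-axis metadata (`bin_width`, `n_bins`, `period`,
#' `rise_bin`, schema version). Counts round-trip exactly as long as no bin
#' exceeds 65535 counts. `"rds"`: a single R serialisation holding the
#' counts array and axis (native container for intermediate results).
#'
#' @param stack A [flim_stack()].
#' @param path Output file path.
#' @param layout `"tiff"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, layout = c("tiff", "rds")) {
  layout <- match.arg(layout)
  stopifnot(inherits(stack, "flim_stack"))
  if (layout == "rds") {
    saveRDS(list(schema = "tifret-stack/1", counts = stack$counts,
                 bin_width = stack$axis$bin_width, n_bins = stack$axis$n_bins,
                 period = stack$axis$period, rise_bin = stack$axis$rise_bin),
            path)
    return(invisible(path))
  }
  if (max(stack$counts) > 65535)
    stop("counts exceed 65535; the 16-bit TIFF layout cannot store them ",
         "losslessly (use layout = 'rds')")
  pages <- lapply(seq_len(stack$axis$n_bins),
                  function(k) stack$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(schema = "tifret-stack/1", bin_width = stack$axis$bin_width,
         n_bins = stack$axis$n_bins, period = stack$axis$period,
         rise_bin = stack$axis$rise_bin),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a FLIM stack from disk
#'
#' Inverse of [write_stack()]. For the TIFF layout the sidecar JSON written
#' next to the stack is required; a missing sidecar, a page count different
#' from the declared `n_bins`, or negative values are descriptive errors.
#' Unknown sidecar keys are ignored with a warning (the schema is
#' versioned).
#'
#' @param path Stack file path.
#' @param layout `"tiff"` or `"rds"`.
#' @return A [flim_stack()].
#' @export
read_stack <- function(path, layout = c("tiff", "rds")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("stack file not found: ", path)
  if (layout == "rds") {
    obj <- readRDS(path)
    ax <- time_axis(obj$bin_width, obj$n_bins, obj$period, obj$rise_bin,
                    allow_wrap = TRUE)
    return(flim_stack(obj$counts, ax))
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing time-axis sidecar: expected ", sc, " next to ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  known <- c("schema", "bin_width", "n_bins", "period", "rise_bin")
  extra <- setdiff(names(meta), known)
  if (length(extra))
    warning("ignoring unknown sidecar keys: ", paste(extra, collapse = ", "))
  need <- setdiff(c("bin_width", "n_bins", "period", "rise_bin"), names(meta))
  if (length(need))
    stop("sidecar ", sc, " lacks required keys: ", paste(need, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins)
    stop("page count (", length(pages), ") does not match sidecar n_bins (",
         meta$n_bins, ")")
  counts <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- pages[[k]]
  if (any(counts < 0)) stop("negative counts in stack")
  ax <- time_axis(meta$bin_width, meta$n_bins, meta$period, meta$rise_bin,
                  allow_wrap = TRUE)
  flim_stack(counts, ax)
}

#' Read a binary ROI mask image
#'
#' Single-channel TIFF or PNG; any nonzero pixel is inside the ROI. For
#' multi-channel images the first channel is used.
#'
#' @param path Mask image path (`.tif`, `.tiff` or `.png`).
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0
}

#' Write a per-pixel map as 16-bit TIFF plus sidecar
#'
#' Real-valued maps (FRET efficiency, lifetime) are stored as a 16-bit TIFF
#' with an affine code recorded in the sidecar JSON
#' (`value = offset + scale * code / 65535`; quantisation error is
#' `range/65535`, about 2e-5 for an efficiency map), alongside an 8-bit
#' validity TIFF (`<path>_valid.tif`, 255 = valid).
#'
#' @param map A `"fret_map"` or `"lifetime_map"`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  values <- if (!is.null(map$E)) map$E else map$tau
  v <- values
  v[!map$valid] <- NA
  rng <- range(v, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  if (diff(rng) == 0) rng[2] <- rng[1] + 1
  code <- (v - rng[1]) / diff(rng)
  code[is.na(code)] <- 0
  tiff::writeTIFF(code, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  tiff::writeTIFF((map$valid * 1), valid_path(path), bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(schema = "tifret-map/1", offset = rng[1], scale = diff(rng),
         kind = if (!is.null(map$E)) "fret" else "lifetime",
         method_tag = if (!is.null(map$method_tag)) map$method_tag else NULL,
         tau_D = map$tau_D),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

valid_path <- function(path) sub("(\\.tiff?)?$", "_valid.tif", path)

#' Read a map written by [write_map()]
#'
#' @param path Map TIFF path (sidecar and validity TIFF expected alongside).
#' @return A `"fret_map"` or `"lifetime_map"` according to the sidecar.
#' @export
read_map <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing map sidecar: expected ", sc, " next to ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  code <- tiff::readTIFF(path, as.is = TRUE)
  values <- meta$offset + meta$scale * code / 65535
  vp <- valid_path(path)
  valid <- if (file.exists(vp)) tiff::readTIFF(vp) > 0 else
    matrix(TRUE, nrow(values), ncol(values))
  values[!valid] <- NA
  if (identical(meta$kind, "lifetime"))
    structure(list(tau = values, valid = valid), class = "lifetime_map")
  else
    new_fret_map(values, valid,
                 if (!is.null(meta$method_tag)) meta$method_tag else "unknown",
                 list(tau_D = meta$tau_D))
}

#' Write analysis results with provenance
#'
#' Writes whichever result objects are supplied under a common path prefix:
#' maps as TIFF + sidecar (`<prefix>_<tag>.tif`), per-segment peaks as CSV
#' (`<prefix>_peaks.csv` with columns `roi_label`, `segment_index`, `peak`),
#' and Gaussian-fit / combined results as JSON (`<prefix>_results.json`).
#' Every JSON carries a provenance block: package version, seed, and an MD5
#' hash of the supplied configuration.
#'
#' @param path_prefix Common prefix for all output files.
#' @param maps Named list of maps (names become file tags), or `NULL`.
#' @param spectrogram A `"fret_spectrogram"` (peaks CSV + fit JSON), or `NULL`.
#' @param combined A `"combined_efficiency"`, or `NULL`.
#' @param config List describing the run configuration (hashed into
#'   provenance).
#' @param seed Seed recorded in provenance.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(path_prefix, maps = NULL, spectrogram = NULL,
                          combined = NULL, config = list(), seed = NULL) {
  written <- character()
  for (nm in names(maps)) {
    f <- paste0(path_prefix, "_", nm, ".tif")
    write_map(maps[[nm]], f)
    written <- c(written, f, sidecar_path(f), valid_path(f))
  }
  results <- list(provenance = provenance_block(config, seed))
  if (!is.null(spectrogram)) {
    f <- paste0(path_prefix, "_peaks.csv")
    utils::write.csv(spectrogram$peaks, f, row.names = FALSE)
    written <- c(written, f)
    results$gaussian_fit <- list(
      mean = spectrogram$fit$mean, sd = spectrogram$fit$sd,
      amplitude = spectrogram$fit$amplitude,
      r_squared = spectrogram$fit$r_squared,
      degenerate = isTRUE(spectrogram$fit$degenerate),
      n_segments = spectrogram$n_segments)
  }
  if (!is.null(combined))
    results$combined <- list(E = combined$E, sem = combined$sem,
                             k = combined$k)
  if (!is.null(spectrogram) || !is.null(combined) || length(config)) {
    f <- paste0(path_prefix, "_results.json")
    jsonlite::write_json(results, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}

provenance_block <- function(config, seed) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  list(package = "tifret",
       version = as.character(utils::packageVersion("tifret")),
       config_md5 = unname(tools::md5sum(tf)),
       seed = seed,
       schema = "tifret-results/1")
}
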