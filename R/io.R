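#' Write traces as a flat delimited table
#'
#' One row per sample with header `neuron_id,trial,intensity,time_s,f`.
#' Values are written with full double precision so a read-back is
#' lossless.
#'
#' @param dataset An `ins_dataset`.
#' @param path Output file (CSV).
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(dataset, path) {
  tb <- tibble::as_tibble(dataset)
  tb$time_s <- sprintf("%.17g", tb$time_s)
  tb$f <- sprintf("%.17g", tb$f)
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat delimited trace table
#'
#' Inverse of [write_trace_table()]. The paradigm is not stored in the flat
#' format and must be supplied (or defaulted) to interpret trial timing.
#'
#' @param path CSV file with header `neuron_id,trial,intensity,time_s,f`.
#' @param paradigm A `stim_paradigm` for the recordings (default
#'   multi-train).
#' @param neurons Optional neuron table; a minimal one (ids only) is built
#'   otherwise.
#' @return An `ins_dataset`.
#' @export
read_trace_table <- function(path, paradigm = make_paradigm("multi_train"),
                             neurons = NULL) {
  tb <- utils::read.csv(path)
  need <- c("neuron_id", "trial", "intensity", "time_s", "f")
  if (!all(need %in% names(tb)))
    stop("trace table header must contain: ", paste(need, collapse = ", "),
      call. = FALSE)
  if (nrow(tb) == 0) {
    return(structure(list(f = matrix(numeric(), 0, 0),
      trials = tibble::tibble(trace_id = integer(), trial = integer(),
        neuron_id = integer(), intensity = double()),
      neurons = neurons %||% tibble::tibble(neuron_id = integer()),
      paradigm = paradigm, sampling_rate = NA_real_,
      config = NULL, seed = NA_integer_), class = "ins_dataset"))
  }
  key <- paste(tb$neuron_id, tb$trial, sep = "\r")
  ukey <- unique(key)
  counts <- table(key)
  if (length(unique(counts)) != 1)
    stop("ragged trace table: traces differ in sample count", call. = FALSE)
  n_samples <- unname(counts[1])
  ord <- order(match(key, ukey), tb$time_s)
  tb <- tb[ord, ]
  f <- matrix(tb$f, nrow = n_samples)
  first <- tb[seq(1, nrow(tb), by = n_samples), ]
  trials <- tibble::tibble(trace_id = seq_along(ukey),
    trial = first$trial, neuron_id = first$neuron_id,
    intensity = first$intensity)
  fs <- 1 / stats::median(diff(tb$time_s[seq_len(n_samples)]))
  if (is.null(neurons))
    neurons <- tibble::tibble(neuron_id = sort(unique(trials$neuron_id)),
      cell_class = NA_character_)
  structure(list(f = f, trials = trials, neurons = neurons,
    paradigm = paradigm, sampling_rate = fs, config = NULL,
    seed = NA_integer_), class = "ins_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset as a hierarchical run directory
#'
#' Plain-text container: `traces.csv` (flat trace table), `neurons.csv`
#' (ground-truth neuron table), `paradigm.yaml` and `meta.yaml` (sampling
#' rate, seed).
#'
#' @param dataset An `ins_dataset`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trace_table(dataset, file.path(dir, "traces.csv"))
  utils::write.csv(dataset$neurons, file.path(dir, "neurons.csv"),
    row.names = FALSE)
  yaml::write_yaml(unclass(dataset$paradigm), file.path(dir, "paradigm.yaml"))
  yaml::write_yaml(list(sampling_rate = dataset$sampling_rate,
    seed = dataset$seed), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a dataset run directory written by [write_dataset()]
#'
#' @param dir Directory containing `traces.csv`, `neurons.csv`,
#'   `paradigm.yaml`, `meta.yaml`.
#' @return An `ins_dataset`.
#' @export
read_dataset <- function(dir) {
  par <- yaml::read_yaml(file.path(dir, "paradigm.yaml"))
  class(par) <- "stim_paradigm"
  neurons <- tibble::as_tibble(utils::read.csv(file.path(dir, "neurons.csv")))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  ds <- read_trace_table(file.path(dir, "traces.csv"), paradigm = par,
    neurons = neurons)
  ds$sampling_rate <- meta$sampling_rate
  ds$seed <- meta$seed
  ds
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return Numeric array `rows x cols x frames`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Read an integer ROI label mask
#'
#' Label semantics: value `n > 0` marks ROI `n`, 0 is background.
#'
#' @param path Single-page TIFF whose pixel values are integer labels
#'   (stored either as integers or as integers scaled to `[0, 1]` by the
#'   TIFF bit depth).
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (max(abs(m - round(m))) > 1e-6)
    stop("ROI mask contains non-integer labels", call. = FALSE)
  storage.mode(m) <- "integer"
  m
}

#' Extract per-ROI mean fluorescence traces from a stack
#'
#' Fluorescence of ROI n in each frame is the mean of the pixel values under
#' mask label n.
#'
#' @param stack Array `rows x cols x frames` (see [read_stack()]).
#' @param mask Integer label matrix matching the stack's spatial dimensions.
#' @return Matrix `frames x n_rois`; column j is ROI j's trace.
#' @export
extract_roi_traces <- function(stack, mask) {
  if (!all(dim(mask) == dim(stack)[1:2]))
    stop("mask and stack spatial dimensions differ", call. = FALSE)
  if (is.double(mask) && max(abs(mask - round(mask))) > 1e-6)
    stop("ROI mask contains non-integer labels", call. = FALSE)
  labels <- sort(setdiff(unique(as.vector(mask)), 0))
  n_frames <- dim(stack)[3]
  out <- matrix(NA_real_, n_frames, length(labels))
  colnames(out) <- as.character(labels)
  for (j in seq_along(labels)) {
    sel <- mask == labels[j]
    out[, j] <- apply(stack, 3, function(fr) mean(fr[sel]))
  }
  out
}

#' Write a fluence map as a multi-page 32-bit TIFF plus metadata sidecar
#'
#' One page per z slice. Samples are stored normalised to the volume maximum
#' (TIFF convention); the sidecar (`<path>.meta.yaml`) records the `scale`
#' needed to restore physical values along with the seed, photon count,
#' totals and a hash of the tissue/fiber configuration.
#'
#' @param fluence A `fluence_map`.
#' @param path Output TIFF path.
#' @param what `"fluence"` or `"absorbed"`.
#' @return `path`, invisibly.
#' @export
write_fluence_tiff <- function(fluence, path, what = c("fluence", "absorbed")) {
  what <- match.arg(what)
  a <- fluence[[what]]
  scale <- max(a)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(seed = fluence$seed, n_photons = fluence$n_photons,
    what = what, scale = scale, totals = fluence$totals,
    config_hash = rlang::hash(list(fluence$tissue, fluence$fiber)))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write an illuminated-region mask as a single-page TIFF
#'
#' @param mask An `illum_mask`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask$mask), nrow(mask$mask)), path)
  invisible(path)
}
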