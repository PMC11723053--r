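# Bundle format: a directory holding `data.bin.gz` (the trial x channel x
# sample array as little-endian doubles, gzip-compressed) and `meta.json`
# (labels, channel names/modalities, class names, sampling rate, subject).
# The round trip is bit-exact.

#' Write an epoched dataset as a portable bundle
#'
#' @param ds an `epoched_dataset`.
#' @param path directory to create (or overwrite with `force = TRUE`).
#' @param force overwrite an existing bundle?
#' @return `path`, invisibly.
#' @export
write_bundle <- function(ds, path, force = FALSE) {
  validate_dataset(ds)
  if (dir.exists(path) && !force)
    stop2("bundle '", path, "' exists; use force = TRUE to overwrite")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- gzfile(file.path(path, "data.bin.gz"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(ds$data), con, size = 8L, endian = "little")
  meta <- list(format = "mieog-bundle", version = 1L,
               dim = dim(ds$data), labels = ds$labels,
               class_names = ds$class_names,
               channel_names = ds$channels$name,
               channel_modalities = ds$channels$modality,
               sampling_rate = ds$sampling_rate,
               subject_id = ds$subject_id)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an epoched dataset bundle
#'
#' Validates the bundle and reports every schema violation at once. A
#' bundle without modality tags loads with a warning, all channels
#' defaulting to EEG.
#'
#' @param path bundle directory written by [write_bundle()].
#' @return an `epoched_dataset`.
#' @export
read_bundle <- function(path) {
  meta_path <- file.path(path, "meta.json")
  data_path <- file.path(path, "data.bin.gz")
  if (!file.exists(meta_path) || !file.exists(data_path))
    stop2("'", path, "' is not a bundle (meta.json / data.bin.gz missing)")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  problems <- character()
  d <- as.integer(meta$dim)
  if (length(d) != 3L) problems <- c(problems, "dim must have 3 entries")
  if (length(meta$labels) != d[1L])
    problems <- c(problems, "labels length != number of trials")
  if (length(meta$channel_names) != d[2L])
    problems <- c(problems, "channel_names length != number of channels")
  if (is.null(meta$sampling_rate) || meta$sampling_rate <= 0)
    problems <- c(problems, "sampling_rate missing or non-positive")
  if (length(problems))
    stop2("invalid bundle '", path, "':\n  - ",
          paste(problems, collapse = "\n  - "))
  con <- gzfile(data_path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "double", n = prod(d), size = 8L, endian = "little")
  if (length(x) != prod(d))
    stop2("invalid bundle '", path, "': data length ", length(x),
          " != prod(dim) = ", prod(d))
  modality <- meta$channel_modalities
  if (is.null(modality) || !length(modality)) {
    warning("bundle has no channel modality tags; defaulting all to EEG")
    modality <- rep("EEG", d[2L])
  }
  epoched_dataset(array(x, d), meta$labels, meta$channel_names, modality,
                  meta$sampling_rate, class_names = meta$class_names,
                  subject_id = meta$subject_id)
}

#' Load a public motor-imagery benchmark recording
#'
#' Reads a locally cached, pre-converted bundle of one subject of a public
#' benchmark: `"bci_iv_2a"` (22 EEG + 3 EOG, 250 Hz, 4 classes; epoch
#' window seconds 2-6 of each trial, 1000 samples) or `"weibo_2014"`
#' (60 EEG + 2 EOG, 200 Hz, 7 classes; window seconds 3-7, 800 samples).
#' Conversion from the public distribution requires the Python
#' mne + moabb stack and network access; the helper script
#' `system.file("python", "fetch_public_dataset.py", package = "mieog")`
#' downloads, epochs, tags the trailing EOG channels and writes the bundle.
#' Without a cached bundle this function fails cleanly (no partial cache).
#'
#' @param name `"bci_iv_2a"` or `"weibo_2014"`.
#' @param subject subject number (1-9 / 1-10).
#' @param cache_dir directory holding converted bundles.
#' @return an `epoched_dataset`.
#' @export
import_public_dataset <- function(name = c("bci_iv_2a", "weibo_2014"),
                                  subject, cache_dir) {
  name <- match.arg(name)
  n_sub <- if (name == "bci_iv_2a") 9L else 10L
  if (!is_count(subject) || subject > n_sub)
    stop2("unknown subject ", subject, " for ", name, " (1..", n_sub, ")")
  bundle <- file.path(cache_dir, sprintf("%s_subject%02d", name, subject))
  if (!dir.exists(bundle))
    stop2("no cached bundle at '", bundle, "'.\n",
          "Convert the public recording first (needs Python with mne and ",
          "moabb, and network access):\n  python ",
          system.file("python", "fetch_public_dataset.py", package = "mieog"),
          " --dataset ", name, " --subject ", subject,
          " --out ", cache_dir)
  ds <- read_bundle(bundle)
  expected <- if (name == "bci_iv_2a") c(25L, 250) else c(62L, 200)
  if (n_channels(ds) != expected[1L] || ds$sampling_rate != expected[2L])
    stop2("cached bundle does not match ", name, ": expected ",
          expected[1L], " channels @ ", expected[2L], " Hz")
  ds
}
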