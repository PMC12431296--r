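#' Write a continuous EEG recording as CSV + JSON sidecar
#'
#' The CSV holds one column per channel (samples as rows); the sidecar
#' `<path>.json` records channel names, sampling rate and events.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV output path.
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_names
  write.csv(df, path, row.names = FALSE)
  side <- list(channel_names = rec$channel_names, fs = rec$fs)
  if (!is.null(rec$events))
    side$events <- lapply(seq_len(nrow(rec$events)), function(i)
      list(onset = rec$events$onset[i], label = rec$events$label[i]))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EEG recording from CSV + JSON sidecar
#'
#' @param path CSV path written by [write_eeg_csv()] (sidecar at
#'   `<path>.json`).
#' @return an [eeg_recording()].
#' @export
read_eeg_csv <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar JSON: ", side_path)
  side <- jsonlite::fromJSON(side_path, simplifyVector = FALSE)
  df <- read.csv(path, check.names = FALSE)
  ch <- vapply(side$channel_names, identity, "")
  if (!all(ch %in% names(df)))
    stop("sidecar channel names not found in CSV columns")
  events <- NULL
  if (!is.null(side$events) && length(side$events) > 0)
    events <- data.frame(
      onset = vapply(side$events, function(e) as.integer(e$onset), 0L),
      label = vapply(side$events, function(e) as.integer(e$label), 0L))
  eeg_recording(t(as.matrix(df[, ch, drop = FALSE])), ch,
                fs = as.numeric(side$fs), events = events)
}

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a plain EDF recording
#'
#' Minimal reader for the European Data Format: parses the fixed-width
#' ASCII header, reads the 16-bit data records and rescales them to
#' physical units. All signals must share one sampling rate; annotation
#' channels ("EDF Annotations") are dropped, so events should be supplied
#' through `events` or attached later.
#'
#' @param path EDF file.
#' @param events optional data.frame (`onset`, `label`), as in
#'   [eeg_recording()].
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                       # version
  read_ascii(con, 80); read_ascii(con, 80) # patient, recording ids
  read_ascii(con, 8); read_ascii(con, 8)   # start date, time
  header_len <- as.integer(read_ascii(con, 8))
  read_ascii(con, 44)                      # reserved
  n_rec <- as.integer(read_ascii(con, 8))
  rec_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: bad signal count")
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  field(80); field(8)                      # transducer, dimension
  pmin_ <- as.numeric(field(8)); pmax_ <- as.numeric(field(8))
  dmin_ <- as.numeric(field(8)); dmax_ <- as.numeric(field(8))
  field(80)                                # prefiltering
  spr <- as.integer(field(8))              # samples per record
  field(32)                                # reserved
  seek(con, header_len)
  keep <- labels != "EDF Annotations"
  if (length(unique(spr[keep])) != 1)
    stop("signals with mixed sampling rates are not supported")
  fs <- spr[keep][1] / rec_dur
  sig <- vector("list", ns)
  for (s in which(keep)) sig[[s]] <- numeric(n_rec * spr[s])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[s])
        stop("truncated EDF file at record ", r)
      if (keep[s]) {
        scale <- (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
        sig[[s]][((r - 1) * spr[s] + 1):(r * spr[s])] <-
          (raw - dmin_[s]) * scale + pmin_[s]
      }
    }
  }
  eeg_recording(do.call(rbind, sig[keep]), labels[keep], fs, events)
}

#' Map recording electrode indices to 10-10 labels
#'
#' Recordings often number electrodes 1..22 instead of naming them; the
#' bundled lookup maps those indices onto the standard 10-10 motor-cortex
#' montage.
#'
#' @param indices integer electrode indices (1-based).
#' @return character vector of 10-10 labels.
#' @export
map_electrode_labels <- function(indices = 1:22) {
  path <- system.file("extdata", "montage_22.json", package = "neurointent")
  labels <- unlist(jsonlite::fromJSON(path)$labels)
  if (any(indices < 1 | indices > length(labels)))
    stop("electrode index outside the bundled ", length(labels),
         "-channel montage")
  labels[indices]
}

#' Save / load labelled epochs
#'
#' Epochs round-trip through a serialized container with an integrity
#' check on load (a truncated file errors rather than returning a partial
#' read).
#'
#' @param epochs an [eeg_epochs()].
#' @param path output path (conventionally `.rds`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt epochs container: ",
                                           conditionMessage(e)))
  if (!inherits(obj, "eeg_epochs"))
    stop("file does not contain an eeg_epochs object")
  obj
}

#' Save / load trained models
#'
#' @param model a `csff_model` or `scene_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt model archive: ",
                                           conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$format_version))
    stop("file is not a neurointent model archive")
  obj$model
}

#' Assemble the end-to-end pipeline configuration
#'
#' A plain nested list (JSON-serializable) holding every stage's
#' parameters; [read_config()]/[write_config()] round-trip it.
#'
#' @param seed master seed driving all randomness in [run_pipeline()].
#' @param eeg,scene,fusion stage parameter lists; defaults reproduce the
#'   package defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            eeg = list(band = c(8, 32), order = 4,
                                       baseline = c(-0.2, 0),
                                       win_s = 2, stride_s = 0.04,
                                       t_start_s = 1, t_end_s = 4,
                                       k_total = 15, alpha = 0.5,
                                       epsilon = 1e-10, pca_var = 0.95,
                                       cost = 1, svr_epsilon = 0.1,
                                       n_trials = 96),
                            scene = list(n_grid = 3, min_score = 0.25,
                                         pca_dim = 50, n_trees = 100,
                                         n_per_scene = 80),
                            fusion = list(tau = 0),
                            task_map_path = NULL) {
  structure(list(seed = seed, eeg = eeg, scene = scene, fusion = fusion,
                 task_map_path = task_map_path),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(obj, class = "pipeline_config")
}

csff_config_from <- function(cfg) {
  e <- cfg$eeg
  csff_config(band = e$band, order = e$order, baseline = e$baseline,
              wp = window_par(e$win_s, e$stride_s, e$t_start_s, e$t_end_s),
              selection = selection_config(e$k_total, e$alpha, e$epsilon),
              pca_var = e$pca_var,
              svr = list(cost = e$cost, epsilon = e$svr_epsilon,
                         gamma = NULL, kernel = "radial"))
}
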