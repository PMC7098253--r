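#' Raw multichannel voltage recording
#'
#' Container for a multielectrode-array recording: voltage in microvolts
#' with one column per channel (`n_samples x n_channels`) plus the sampling
#' rate. All channels share the same length and rate.
#'
#' @param samples Numeric matrix, `n_samples x n_channels`, in microvolts
#'   (one column per channel).
#' @param fs Sampling rate in Hz (default 30000).
#' @param channel_ids Ordered channel identifiers; defaults to `ch001`, ...
#' @param t0 Recording start time in seconds (default 0).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs = 30000, channel_ids = NULL, t0 = 0) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1 || ncol(samples) < 1)
    stop("recording must have at least one channel and one sample")
  if (fs <= 0) stop("sampling rate must be positive")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%03d", seq_len(ncol(samples)))
  if (length(channel_ids) != ncol(samples))
    stop("channel_ids length must equal the number of channels")
  colnames(samples) <- channel_ids
  structure(list(samples = samples, fs = fs,
                 channel_ids = as.character(channel_ids), t0 = t0),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs, recording_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [raw_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$fs
}

#' Write a recording to a flat-binary container with JSON sidecar
#'
#' Samples are quantised to little-endian int16 counts (interleaved by frame,
#' i.e. all channels per timestamp) at `uv_per_count` microvolts per count; a
#' `<name>.json` sidecar records `n_channels`, `fs_hz`, `dtype`,
#' `uv_per_count`, `channel_ids` and `t0_s`. Recordings whose voltages are
#' exact multiples of `uv_per_count` round-trip bit-exactly.
#'
#' @param recording A [raw_recording()].
#' @param path Output path; the `.bin`/`.json` pair is derived by stripping
#'   any extension.
#' @param uv_per_count Quantisation step in microvolts per count
#'   (default 0.25, the conventional acquisition-system resolution).
#' @return `path` (the `.bin` file), invisibly.
#' @export
write_recording <- function(recording, path, uv_per_count = 0.25) {
  stopifnot(inherits(recording, "raw_recording"))
  base <- sub("\\.(bin|json)$", "", path)
  counts <- round(recording$samples / uv_per_count)
  if (any(abs(counts) > 32767))
    stop("voltage exceeds int16 range at this uv_per_count")
  meta <- list(n_channels = ncol(recording$samples),
               fs_hz = recording$fs, dtype = "int16",
               uv_per_count = uv_per_count,
               channel_ids = recording$channel_ids, t0_s = recording$t0)
  jsonlite::write_json(meta, paste0(base, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(paste0(base, ".bin"), "wb")
  on.exit(close(con))
  # transpose so all channels of one timestamp are adjacent on disk
  writeBin(as.integer(t(counts)), con, size = 2L, endian = "little")
  invisible(paste0(base, ".bin"))
}

#' Read a recording from a flat-binary container
#'
#' @param path Path to the `.bin` file (or its basename); the `.json`
#'   sidecar must sit alongside it.
#' @return A [raw_recording()] with samples in microvolts.
#' @export
read_recording <- function(path) {
  base <- sub("\\.(bin|json)$", "", path)
  sidecar <- paste0(base, ".json")
  binfile <- paste0(base, ".bin")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$dtype, "int16"))
    stop("unsupported sample dtype: ", meta$dtype)
  n_bytes <- file.size(binfile)
  frame_bytes <- 2L * meta$n_channels
  if (n_bytes %% frame_bytes != 0)
    stop("corrupt container: ", binfile, " is truncated mid-frame")
  con <- file(binfile, "rb")
  on.exit(close(con))
  counts <- readBin(con, "integer", n = n_bytes / 2, size = 2L,
                    signed = TRUE, endian = "little")
  samples <- t(matrix(counts * meta$uv_per_count, nrow = meta$n_channels))
  raw_recording(samples, fs = meta$fs_hz,
                channel_ids = meta$channel_ids,
                t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

.task_movements <- list(
  Task1 = c("hand_open", "hand_close"),
  Task2 = c("wrist_flexion", "wrist_extension",
            "index_flexion", "index_extension"))

#' Cue schedule for one task block
#'
#' Ordered movement cues for one block of a cued-movement task. Task1 blocks
#' cue hand open/close; Task2 blocks cue wrist flexion/extension and index
#' finger flexion/extension. Every cue lasts 2.5 s and cues may not overlap.
#'
#' @param task_id `"Task1"` or `"Task2"`.
#' @param block_index Integer block index within a session.
#' @param events Data frame with columns `movement`, `onset_s`, `duration_s`,
#'   sorted by onset. May have zero rows (a pure-rest block).
#' @param initial_rest Rest before the first cue (s).
#' @param inter_cue_rest Rest after each cue (s).
#' @param block_duration Total block length (s); computed from the events and
#'   rests when omitted.
#' @return An object of class `cue_schedule`.
#' @export
cue_schedule <- function(task_id, block_index = 0, events,
                         initial_rest = NULL, inter_cue_rest = NULL,
                         block_duration = NULL) {
  task_id <- match.arg(task_id, names(.task_movements))
  events <- as.data.frame(events)
  need <- c("movement", "onset_s", "duration_s")
  if (!all(need %in% names(events)))
    stop("events must have columns movement, onset_s, duration_s")
  events <- events[, need]
  if (nrow(events) > 0) {
    bad <- setdiff(unique(events$movement), .task_movements[[task_id]])
    if (length(bad))
      stop("unknown movement label(s) for ", task_id, ": ",
           paste(bad, collapse = ", "))
    if (is.unsorted(events$onset_s, strictly = TRUE))
      stop("cue onsets must be strictly increasing")
    ends <- events$onset_s + events$duration_s
    if (any(ends[-nrow(events)] > events$onset_s[-1] + 1e-9))
      stop("cues overlap")
  }
  if (is.null(block_duration)) {
    block_duration <- if (nrow(events) == 0) {
      if (is.null(initial_rest)) 0 else initial_rest
    } else {
      max(events$onset_s + events$duration_s) +
        if (is.null(inter_cue_rest)) 0 else inter_cue_rest
    }
  }
  structure(list(task_id = task_id, block_index = block_index,
                 events = events, initial_rest = initial_rest,
                 inter_cue_rest = inter_cue_rest,
                 block_duration = block_duration),
            class = "cue_schedule")
}

#' @export
print.cue_schedule <- function(x, ...) {
  cat(sprintf("<cue_schedule> %s block %d: %d cues, %.1f s\n",
              x$task_id, x$block_index, nrow(x$events), x$block_duration))
  if (nrow(x$events)) print(table(x$events$movement))
  invisible(x)
}

#' Write a cue schedule as CSV
#'
#' Metadata (task, block, rests, duration) is stored in leading `#`-comment
#' lines, followed by a `movement,onset_s,duration_s` table.
#'
#' @param schedule A [cue_schedule()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cue_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "cue_schedule"))
  hdr <- c(sprintf("# task_id,%s", schedule$task_id),
           sprintf("# block_index,%d", schedule$block_index),
           sprintf("# initial_rest_s,%s", schedule$initial_rest),
           sprintf("# inter_cue_rest_s,%s", schedule$inter_cue_rest),
           sprintf("# block_duration_s,%s", schedule$block_duration))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(schedule$events, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cue schedule CSV
#'
#' @param path Path written by [write_cue_schedule()] (or hand-authored in
#'   the same layout).
#' @return A validated [cue_schedule()].
#' @export
read_cue_schedule <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ",")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  events <- read.csv(text = paste(body, collapse = "\n"),
                     stringsAsFactors = FALSE)
  num_or_null <- function(x) if (is.null(x) || x == "NULL") NULL else as.numeric(x)
  cue_schedule(task_id = meta$task_id,
               block_index = as.integer(meta$block_index),
               events = events,
               initial_rest = num_or_null(meta$initial_rest_s),
               inter_cue_rest = num_or_null(meta$inter_cue_rest_s),
               block_duration = num_or_null(meta$block_duration_s))
}

#' Electrode-array geometry
#'
#' Positions of recording channels on the array in millimetres. Only
#' relative positions matter downstream (inter-electrode distances).
#'
#' @param positions Numeric matrix `n_channels x 2` of (x, y) in mm, with
#'   row names giving channel ids (assigned `ch001`, ... if absent).
#' @param pitch Nominal inter-electrode pitch in mm (default 0.4).
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(positions, pitch = 0.4) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2)
  if (is.null(rownames(positions)))
    rownames(positions) <- sprintf("ch%03d", seq_len(nrow(positions)))
  colnames(positions) <- c("x_mm", "y_mm")
  structure(list(positions = positions, pitch = pitch),
            class = "array_geometry")
}

#' Regular grid geometry
#'
#' Builds the geometry of a rectangular microelectrode grid: channel `k` sits
#' at `(col * pitch, row * pitch)` in row-major order with 0-based rows and
#' columns. The default is the 10 x 10, 0.4 mm pitch layout of a 96-channel
#' array mapped onto the first 96 grid sites.
#'
#' @param n_channels Number of channels (default 96).
#' @param n_cols Grid columns (default 10).
#' @param pitch Electrode pitch in mm (default 0.4).
#' @param channel_ids Optional channel identifiers.
#' @return An [array_geometry()].
#' @export
grid_geometry <- function(n_channels = 96, n_cols = 10, pitch = 0.4,
                          channel_ids = NULL) {
  k <- seq_len(n_channels) - 1
  pos <- cbind(x_mm = (k %% n_cols) * pitch,
               y_mm = (k %/% n_cols) * pitch)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%03d", seq_len(n_channels))
  rownames(pos) <- channel_ids
  array_geometry(pos, pitch = pitch)
}

#' Write / read array geometry as JSON
#'
#' The JSON maps each channel id to its `[x_mm, y_mm]` position, plus a
#' `pitch_mm` field.
#'
#' @param geometry An [array_geometry()].
#' @param path JSON path.
#' @return `path` (write) or an [array_geometry()] (read).
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "array_geometry"))
  pos <- lapply(seq_len(nrow(geometry$positions)),
                function(i) unname(geometry$positions[i, ]))
  names(pos) <- rownames(geometry$positions)
  jsonlite::write_json(list(pitch_mm = geometry$pitch, positions = pos),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, j$positions)
  array_geometry(pos, pitch = j$pitch_mm)
}

#' Pairwise inter-electrode distances
#'
#' @param geometry An [array_geometry()].
#' @param channel_ids Channels to include (default: all in the geometry);
#'   an error is raised for channels without a position.
#' @return Symmetric matrix of Euclidean distances in mm with zero diagonal.
#' @examples
#' d <- pairwise_distances(grid_geometry())
#' d["ch001", "ch002"]   # adjacent channels: 0.4 mm
#' @export
pairwise_distances <- function(geometry, channel_ids = NULL) {
  stopifnot(inherits(geometry, "array_geometry"))
  pos <- geometry$positions
  if (!is.null(channel_ids)) {
    missing <- setdiff(channel_ids, rownames(pos))
    if (length(missing))
      stop("no position for channel(s): ", paste(missing, collapse = ", "))
    pos <- pos[channel_ids, , drop = FALSE]
  }
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- list(rownames(pos), rownames(pos))
  d
}
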