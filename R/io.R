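# Plain-file interchange: PCM-16 mono WAV read/write (the RIFF subset the
# field recorders produce), recording-set concatenation, and table export.

#' Write samples as a 16-bit PCM mono WAV file
#'
#' Samples are clipped to [-1, 1) and quantised to 16 bits at export only;
#' all internal processing stays in double precision.
#'
#' @param samples numeric vector in [-1, 1).
#' @param path output file path.
#' @param sample_rate Hz.
#' @export
write_wav <- function(samples, path, sample_rate = 500000) {
  pcm <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file path.
#' @return list with `samples` (doubles in [-1, 1)) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4)
      stop("truncated WAV file: ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM supported: ", path)
      if (fmt[2] != 1) stop("only mono supported: ", path)
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16) stop("only 16-bit PCM supported: ", path)
    } else if (id == "data") {
      n <- size %/% 2
      pcm <- readBin(con, "integer", n, size = 2, endian = "little")
      if (length(pcm) < n) stop("truncated WAV data: ", path)
      return(list(samples = pcm / 32768, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", size)
    }
  }
}

#' Read a set of WAV segments as one contiguous stream
#'
#' Segments are concatenated in the given (filename) order; all files must
#' share the sample rate, and the timeline is continuous across segment
#' boundaries.
#'
#' @param paths character vector of WAV paths, in timeline order.
#' @return list with `samples`, `sample_rate`, `segment_starts_s`.
#' @export
read_recording_set <- function(paths) {
  stopifnot(length(paths) >= 1)
  parts <- lapply(paths, read_wav)
  srs <- vapply(parts, `[[`, numeric(1), "sample_rate")
  if (length(unique(srs)) != 1)
    stop("mixed sample rates across segments: ",
         paste(unique(srs), collapse = ", "))
  lens <- vapply(parts, function(p) length(p$samples), numeric(1))
  list(samples = unlist(lapply(parts, `[[`, "samples"), use.names = FALSE),
       sample_rate = srs[1],
       segment_starts_s = cumsum(c(0, lens[-length(lens)])) / srs[1])
}

#' Export a synthetic encounter as WAV segments with ground truth
#'
#' Writes one 16-bit PCM WAV per rendered segment
#' (`<encounter>_seg<k>.wav`), a sidecar CSV of ground-truth click times
#' and labels, and the configuration as JSON.
#'
#' @param dataset a `click_dataset`.
#' @param encounter encounter id.
#' @param dir output directory (created if needed).
#' @param segments segment indices to render; `NULL` = all (mind memory).
#' @param scale linear scale applied before quantisation so clicks fit in
#'   [-1, 1).
#' @return invisibly, the written WAV paths.
#' @export
export_encounter_wav <- function(dataset, encounter, dir, segments = NULL,
                                 scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- render_recording(dataset, encounter, segments = segments)
  if (is.null(scale)) {
    peak <- max(vapply(rec$blocks, function(b) max(abs(b)), numeric(1)))
    scale <- if (peak > 0) 0.95 / peak else 1
  }
  paths <- character(length(rec$blocks))
  for (i in seq_along(rec$blocks)) {
    paths[i] <- file.path(dir, sprintf("%s_seg%04d.wav", encounter,
                                       i - 1L))
    write_wav(rec$blocks[[i]] * scale, paths[i], rec$sample_rate)
  }
  truth <- dataset$clicks[dataset$clicks$encounter == encounter,
                          c("event_id", "species", "encounter", "time_s",
                            "offset_khz", "snr_db", "variant")]
  write.csv(truth, file.path(dir, paste0(encounter, "_truth.csv")),
            row.names = FALSE)
  cfg <- dataset$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, paste0(encounter, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
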