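# Session serialization: raw little-endian float32 LFP with a YAML sidecar
# header, plus TSVs for the hypnogram, spike times and ground-truth events.

#' Write a session to disk
#'
#' Emits `lfp.bin` (float32 little-endian, channel-interleaved by column) +
#' `lfp.yaml` sidecar (fs, units, channel metadata), `hypnogram.tsv`
#' (`epoch_start_s`, `stage`), `spikes.tsv` (`contact_id`, `wire_id`,
#' `spike_time_s`) and, when ground truth is given, `events_truth.tsv`.
#'
#' @param recording a [SleepRecording-class].
#' @param spikes a [SpikeTrains-class] or NULL.
#' @param truth the `truth` element of [simulateSession()] or NULL.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
writeFixture <- function(recording, spikes = NULL, truth = NULL, path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", path)
  sig <- signalMatrix(recording)
  con <- file(file.path(path, "lfp.bin"), "wb")
  writeBin(as.vector(sig), con, size = 4L, endian = "little")
  close(con)
  hdr <- list(
    fs = samplingRate(recording),
    n_samples = nrow(sig),
    n_channels = ncol(sig),
    units = "uV",
    byte_order = "little",
    dtype = "float32",
    channels = lapply(seq_len(ncol(sig)), function(i) {
      as.list(channelInfo(recording)[i, c("contact_id", "region",
                                          "hemisphere")])
    }),
    preprocessed = recording@preprocessed
  )
  yaml::write_yaml(hdr, file.path(path, "lfp.yaml"))
  utils::write.table(hypnogram(recording),
                     file.path(path, "hypnogram.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(spikes)) {
    w <- wireInfo(spikes)
    df <- do.call(rbind, lapply(seq_len(length(spikes)), function(i) {
      tt <- spikeTimes(spikes)[[i]]
      if (!length(tt)) return(NULL)
      data.frame(contact_id = w$contact_id[i], wire_id = w$wire_id[i],
                 spike_time_s = tt)
    }))
    if (is.null(df)) {
      df <- data.frame(contact_id = integer(), wire_id = integer(),
                       spike_time_s = numeric())
    }
    utils::write.table(df, file.path(path, "spikes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth)) {
    utils::write.table(
      truth$events[, c("type", "contact_id", "onset_s", "center_s",
                       "max_s", "offset_s")],
      file.path(path, "events_truth.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a session from disk
#'
#' Counterpart of [writeFixture()]. Spike times that arrive unsorted are
#' sorted with a warning; unknown hypnogram stage labels raise an error
#' listing the admissible labels.
#'
#' @param path directory holding `lfp.bin`, `lfp.yaml`, `hypnogram.tsv`
#'   and optionally `spikes.tsv`.
#' @return list with `recording` ([SleepRecording-class]) and `spikes`
#'   ([SpikeTrains-class] or NULL).
#' @export
readSession <- function(path) {
  hdrPath <- file.path(path, "lfp.yaml")
  if (!file.exists(hdrPath)) stop("missing sidecar header: ", hdrPath)
  hdr <- yaml::read_yaml(hdrPath)
  need <- c("fs", "n_samples", "n_channels", "channels")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("sidecar header ", hdrPath, " lacks field(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.null(hdr$units) && hdr$units != "uV") {
    stop("lfp.bin units must be uV (microvolts), got: ", hdr$units)
  }
  con <- file(file.path(path, "lfp.bin"), "rb")
  raw <- readBin(con, "numeric", n = hdr$n_samples * hdr$n_channels,
                 size = 4L, endian = "little")
  close(con)
  if (length(raw) != hdr$n_samples * hdr$n_channels) {
    stop("lfp.bin size does not match the sidecar header of ", path)
  }
  sig <- matrix(raw, hdr$n_samples, hdr$n_channels)
  chan <- do.call(rbind, lapply(hdr$channels, as.data.frame))
  hypPath <- file.path(path, "hypnogram.tsv")
  if (!file.exists(hypPath)) stop("missing hypnogram file: ", hypPath)
  hyp <- utils::read.delim(hypPath)
  bad <- setdiff(unique(hyp$stage), .STAGES)
  if (length(bad)) {
    stop("unknown stage label(s) in ", hypPath, ": ",
         paste(bad, collapse = ", "), " (admissible: ",
         paste(.STAGES, collapse = ", "), ")")
  }
  rec <- SleepRecording(sig, hdr$fs, chan, hyp)
  if (isTRUE(hdr$preprocessed)) rec@preprocessed <- TRUE
  spikes <- NULL
  spkPath <- file.path(path, "spikes.tsv")
  if (file.exists(spkPath)) {
    df <- utils::read.delim(spkPath)
    if (any(df$spike_time_s < 0)) {
      stop("negative spike times in ", spkPath)
    }
    key <- interaction(df$contact_id, df$wire_id, drop = TRUE)
    groups <- split(df, key)
    wires <- do.call(rbind, lapply(groups, function(g) {
      g[1, c("contact_id", "wire_id")]
    }))
    ord <- order(wires$contact_id, wires$wire_id)
    spikes <- SpikeTrains(lapply(groups, function(g) g$spike_time_s)[ord],
                          wires[ord, ])
  }
  list(recording = rec, spikes = spikes)
}

#' Export detected events or artifact intervals as TSV
#'
#' @param x data.frame (events or intervals).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEventsTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
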