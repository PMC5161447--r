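# Minimal mono PCM-16 WAV I/O, sufficient for rendered click stimuli and
# simulated extracellular traces. Amplitudes are mapped to [-1, 1].

#' Render a click sequence as an audio pulse train
#'
#' Each click becomes a rectangular unit-amplitude pulse of `pulse_width_us`
#' microseconds (canonical 100 us), the waveform used for stimulus playback.
#'
#' @param seq A `click_sequence`.
#' @param sample_rate Sampling rate in Hz (>= 10 kHz).
#' @param pulse_width_us Pulse width in microseconds.
#' @return An `audio_render`: list with `samples`, `sample_rate`,
#'   `pulse_width_us`.
#' @export
render_audio <- function(seq, sample_rate = 44100, pulse_width_us = 100) {
  stopifnot(inherits(seq, "click_sequence"))
  if (sample_rate < 10000) stop("sample_rate must be >= 10 kHz")
  iv <- sequence_intervals(seq)
  if (length(iv) && min(iv) < pulse_width_us / 1000)
    stop("click spacing shorter than pulse width: pulses would overlap")
  n <- ceiling(seq$total_duration / 1000 * sample_rate)
  pulse_n <- max(1L, ceiling(pulse_width_us * 1e-6 * sample_rate))
  samples <- numeric(n)
  for (t in seq$click_times) {
    i0 <- round(t / 1000 * sample_rate) + 1L
    samples[i0:min(n, i0 + pulse_n - 1L)] <- 1
  }
  structure(list(samples = samples, sample_rate = sample_rate,
                 pulse_width_us = pulse_width_us),
            class = "audio_render")
}

#' Recover click onset times from a rendered pulse train
#' @param samples Amplitude vector (or an `audio_render`).
#' @param sample_rate Sampling rate in Hz (ignored for `audio_render`).
#' @param threshold Amplitude threshold for a rising edge.
#' @return Onset times in ms.
#' @export
audio_onsets <- function(samples, sample_rate = NULL, threshold = 0.5) {
  if (inherits(samples, "audio_render")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  above <- samples > threshold
  rising <- which(above & !c(FALSE, above[-length(above)]))
  (rising - 1) / sample_rate * 1000
}

#' Write a mono 16-bit PCM WAV file
#' @param samples Amplitudes in [-1, 1] (clipped otherwise).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  if (inherits(samples, "audio_render")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(x)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#' @param path File path.
#' @return List with `samples` (in [-1, 1]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop("only mono PCM WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      x <- readBin(con, integer(), n = sz / 2L, size = 2,
                   signed = TRUE, endian = "little")
      return(list(samples = x / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
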