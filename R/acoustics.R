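# Headphone and stimulus acoustics: RMS equalization of word recordings,
# calibration coefficients, and the effective presentation level under
# ambient noise with passive isolation.

#' Construct a waveform
#'
#' A minimal mono waveform container: a numeric sample vector plus a sample
#' rate. Amplitudes are unitless (full scale = 1 when written to 16-bit WAV).
#'
#' @param samples Non-empty numeric vector of sample amplitudes.
#' @param rate Sample rate in samples/second.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate = 44100) {
  if (!is.numeric(samples) || length(samples) == 0L || any(!is.finite(samples))) {
    stop("`samples` must be a non-empty finite numeric vector", call. = FALSE)
  }
  stop_if_not_scalar_number(rate, "rate")
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate), class = "waveform")
}

#' Root-mean-square amplitude
#'
#' @param w A [waveform()] or numeric sample vector.
#' @return `sqrt(mean(samples^2))`.
#' @examples
#' rms_amplitude(c(3, 4))  # sqrt(12.5)
#' @export
rms_amplitude <- function(w) {
  s <- if (inherits(w, "waveform")) w$samples else w
  if (length(s) == 0L) stop("empty waveform", call. = FALSE)
  sqrt(mean(s^2))
}

#' Scale a waveform to a target RMS
#'
#' Word stimuli are equalized to a common root-mean-square amplitude before
#' per-word calibration, so that every word carries the same nominal energy.
#' The waveform is scaled by a single gain; its shape is unchanged.
#'
#' @param w A [waveform()] (or numeric vector; returned as the same type).
#' @param target Target RMS amplitude, > 0.
#' @return The rescaled waveform with `rms_amplitude(.) == target`.
#' @export
equalize_rms <- function(w, target) {
  stop_if_not_scalar_number(target, "target")
  if (target <= 0) stop("`target` must be positive", call. = FALSE)
  r <- rms_amplitude(w)
  if (r == 0) stop("cannot equalize a silent waveform (RMS 0)", call. = FALSE)
  g <- target / r
  if (inherits(w, "waveform")) waveform(w$samples * g, w$rate) else w * g
}

#' Calibration coefficient from paired level-meter readings
#'
#' The additional gain (dB) the playback device needs so that a word peaks at
#' the same A-weighted level as the reference audiometer output, both measured
#' through a coupler with a sound level meter.
#'
#' @param reference_dBA Reference (audiometer) reading, dBA.
#' @param device_dBA Device (tablet + headphone) reading, dBA.
#' @return `reference_dBA - device_dBA` in dB (positive = device too quiet).
#' @examples
#' calibration_coefficient(65, 62.5)  # +2.5 dB
#' @export
calibration_coefficient <- function(reference_dBA, device_dBA) {
  stop_if_not_scalar_number(reference_dBA, "reference_dBA")
  stop_if_not_scalar_number(device_dBA, "device_dBA")
  reference_dBA - device_dBA
}

#' Headphone specification
#'
#' @param name Preset/display name.
#' @param impedance Ohms, > 0.
#' @param sensitivity Output sensitivity, dB SPL (at 1 mW, 1 kHz where the
#'   manufacturer states it that way).
#' @param ambient_isolation Passive ambient-noise isolation, dB, >= 0.
#' @param distortion Total harmonic distortion as a fraction.
#' @param frequency_response Free-text note on the usable frequency range.
#' @return Object of class `headphone_spec`.
#' @seealso [headphone_preset()] for the three study headphones.
#' @export
headphone_spec <- function(name, impedance, sensitivity, ambient_isolation,
                           distortion = 0, frequency_response = "") {
  stop_if_not_scalar_number(impedance, "impedance")
  stop_if_not_scalar_number(ambient_isolation, "ambient_isolation")
  if (impedance <= 0) stop("`impedance` must be > 0", call. = FALSE)
  if (ambient_isolation < 0) stop("`ambient_isolation` must be >= 0", call. = FALSE)
  structure(list(name = name, impedance = impedance, sensitivity = sensitivity,
                 ambient_isolation = ambient_isolation, distortion = distortion,
                 frequency_response = frequency_response),
            class = "headphone_spec")
}

#' Built-in headphone presets
#'
#' Three transducers spanning the audiometric-to-consumer range: the TDH39
#' supra-aural audiometric reference with earmuffs, a closed studio headphone
#' (DT 770 PRO class), and a generic low-cost headphone with earmuffs.
#' Passive ambient-noise isolation is 30, 20 and 30 dB respectively.
#'
#' @param name `"tdh39"`, `"dt770"` or `"generic"`.
#' @return A [headphone_spec()].
#' @examples
#' headphone_preset("dt770")$ambient_isolation  # 20
#' @export
headphone_preset <- function(name = c("tdh39", "dt770", "generic")) {
  name <- match.arg(name)
  switch(name,
    tdh39 = headphone_spec("tdh39", impedance = 10, sensitivity = 108,
                           ambient_isolation = 30, distortion = 0.01,
                           frequency_response = "100-8000 Hz"),
    dt770 = headphone_spec("dt770", impedance = 32, sensitivity = 96,
                           ambient_isolation = 20, distortion = 0.002,
                           frequency_response = "5-350,000 Hz"),
    generic = headphone_spec("generic", impedance = 32, sensitivity = 90,
                             ambient_isolation = 30, distortion = 0.10,
                             frequency_response =
                               "up to 4 kHz, ~10 dB below maximum output")
  )
}

#' @export
print.headphone_spec <- function(x, ...) {
  cat("<headphone_spec>", x$name,
      sprintf("| %g Ohm | %g dB SPL | isolation %g dB\n",
              x$impedance, x$sensitivity, x$ambient_isolation))
  invisible(x)
}

#' Effective presentation level under ambient noise
#'
#' Models the sensation level actually delivered in a non-soundproof room:
#' the nominal protocol level shifted by any residual calibration error, minus
#' a threshold-elevation term for ambient noise that penetrates the
#' headphone's passive isolation. Residual noise only degrades the signal
#' once it exceeds `masking_offset` dB below the effective masked threshold:
#' `nominal + cal_error - max(0, ambient_dBA - isolation - masking_offset)`.
#'
#' @param nominal Nominal presentation level, dB HL.
#' @param spec A [headphone_spec()] supplying `ambient_isolation`.
#' @param cal_error Residual calibration error, dB (0 after perfect
#'   calibration).
#' @param ambient_dBA Ambient room noise, dBA.
#' @param masking_offset Margin (dB) by which residual noise must exceed the
#'   isolated floor before it masks; a transparency-over-fidelity knob.
#' @return Effective level, dB HL. Never exceeds `nominal + cal_error`.
#' @examples
#' effective_level(40, headphone_preset("tdh39"), ambient_dBA = 35)  # 40
#' effective_level(20, headphone_preset("tdh39"), ambient_dBA = 65)  # -5
#' @export
effective_level <- function(nominal, spec, cal_error = 0, ambient_dBA = 35,
                            masking_offset = 10) {
  if (!is.numeric(nominal) || any(!is.finite(nominal))) {
    stop("`nominal` must be finite numeric (dB HL)", call. = FALSE)
  }
  if (!inherits(spec, "headphone_spec")) stop("`spec` must be a headphone_spec",
                                              call. = FALSE)
  loss <- pmax(0, ambient_dBA - spec$ambient_isolation - masking_offset)
  nominal + cal_error - loss
}

#' Calibration tables
#'
#' Per-word, per-level gain corrections: a data frame with columns `word`,
#' `level_dB_HL` and `coefficient_dB`. [calibration_table()] validates that
#' every word has an entry at every protocol level and that coefficients are
#' finite.
#'
#' @param word Character vector of word identifiers.
#' @param level_dB_HL Nominal levels (one of 20, 30, 40) matching `word`.
#' @param coefficient_dB Gains in dB.
#' @param levels The full protocol level set each word must cover.
#' @return A validated `data.frame` of class `calibration_table`.
#' @export
calibration_table <- function(word, level_dB_HL, coefficient_dB,
                              levels = c(20, 30, 40)) {
  df <- data.frame(word = as.character(word),
                   level_dB_HL = as.numeric(level_dB_HL),
                   coefficient_dB = as.numeric(coefficient_dB),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$coefficient_dB))) {
    stop("calibration coefficients must be finite", call. = FALSE)
  }
  if (!all(df$level_dB_HL %in% levels)) {
    stop("levels must be among ", paste(levels, collapse = ", "), call. = FALSE)
  }
  for (w in unique(df$word)) {
    have <- sort(df$level_dB_HL[df$word == w])
    if (!identical(have, sort(as.numeric(levels)))) {
      stop("word '", w, "' missing a calibration entry at some protocol level",
           call. = FALSE)
    }
  }
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' @rdname calibration_table
#' @param path CSV path (`word, level_dB_HL, coefficient_dB`).
#' @export
read_calibration <- function(path, levels = c(20, 30, 40)) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  calibration_table(df$word, df$level_dB_HL, df$coefficient_dB, levels = levels)
}

#' @rdname calibration_table
#' @param x A `calibration_table`.
#' @export
write_calibration <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## --- Minimal RIFF/WAVE I/O ------------------------------------------------
## Mono PCM reader/writer written against the RIFF spec: chunks are walked
## until "fmt " and "data" are found. Supports integer PCM (8/16/24/32 bit)
## and 32-bit IEEE float on read; writes 16-bit PCM.

#' Read and write mono WAV files
#'
#' Lightweight WAV support for word-stimulus bookkeeping: `read_wav()` parses
#' a mono RIFF/WAVE file (integer PCM at 8, 16, 24 or 32 bits, or 32-bit
#' float) into a [waveform()] with samples scaled to \[-1, 1\];
#' `write_wav()` emits 16-bit PCM. Multichannel files are rejected — word
#' stimuli are mono by construction.
#'
#' @param path File path.
#' @return `read_wav()`: a [waveform()]. `write_wav()`: `path`, invisibly.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate     = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits     = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in ", path, call. = FALSE)
  }
  if (fmt$channels != 1L) stop("only mono WAV is supported", call. = FALSE)

  s <- if (fmt$format == 1L) {
    switch(as.character(fmt$bits),
      "8"  = (as.integer(data_raw) - 128) / 128,
      "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                     signed = TRUE, endian = "little") / 32768,
      "24" = {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
        ifelse(v >= 8388608, v - 16777216, v) / 8388608
      },
      "32" = readBin(data_raw, "integer", length(data_raw) / 4, 4,
                     endian = "little") / 2147483648,
      stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE))
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV format code ", fmt$format, call. = FALSE)
  }
  waveform(s, fmt$rate)
}

#' @rdname read_wav
#' @param w A [waveform()]; samples outside \[-1, 1\] are clipped.
#' @export
write_wav <- function(w, path) {
  if (!inherits(w, "waveform")) stop("`w` must be a waveform", call. = FALSE)
  s <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(s * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, size = 2, endian = "little")   # PCM, mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2), con, size = 4, endian = "little") # byte rate
  writeBin(as.integer(c(2, 16)), con, size = 2, endian = "little")  # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
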