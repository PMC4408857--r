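#' Construct an EEG block
#'
#' A block is one fixed-rate scalar time series: 40 s at 125 Hz in the
#' recording protocol emulated here, band-limited to 1--60 Hz by the
#' acquisition hardware. Condition (`"EC"`/`"EO"`) and group
#' (`"CTL"`/`"AD"`) labels are optional metadata carried through the
#' pipeline.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param condition optional condition label, e.g. `"EC"` or `"EO"`.
#' @param group optional group label, e.g. `"CTL"` or `"AD"`.
#' @param meta optional named list of extra metadata (seeds, generating
#'   parameters, ...), kept for provenance.
#' @return An object of class `"eeg_block"`: the numeric samples with
#'   attributes `fs`, `condition`, `group` and `meta`.
#' @examples
#' b <- eeg_block(sin(2 * pi * 10 * seq(0, 2, by = 1 / 125)), fs = 125)
#' b
#' @export
eeg_block <- function(values, fs = 125, condition = NA_character_,
                      group = NA_character_, meta = list()) {
  values <- as.numeric(values)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0, length(values) >= 1L)
  structure(values,
            fs = fs,
            condition = as.character(condition),
            group = as.character(group),
            meta = meta,
            class = "eeg_block")
}

#' @export
print.eeg_block <- function(x, ...) {
  fs <- attr(x, "fs")
  cat(sprintf("<eeg_block> %d samples @ %g Hz (%.1f s)", length(x), fs,
              length(x) / fs))
  lab <- c(attr(x, "condition"), attr(x, "group"))
  lab <- lab[!is.na(lab)]
  if (length(lab)) cat(" [", paste(lab, collapse = "-"), "]", sep = "")
  cat("\n  sd =", format(stats::sd(unclass(x)), digits = 4), "\n")
  invisible(x)
}

#' Sampling rate of an EEG block
#' @param block an [eeg_block()].
#' @return Sampling rate in Hz.
#' @export
block_fs <- function(block) attr(block, "fs")

# Keep attributes when arithmetic/replacement would drop them.
block_like <- function(values, template, meta = NULL) {
  eeg_block(values, fs = attr(template, "fs"),
            condition = attr(template, "condition"),
            group = attr(template, "group"),
            meta = if (is.null(meta)) attr(template, "meta") else meta)
}

#' Write / read an EEG block as two-column CSV with a JSON sidecar
#'
#' The CSV holds `time_s` and `value` columns; the sidecar (same path with
#' `.json` appended) records sampling rate, labels and any metadata so a
#' block round-trips losslessly up to numeric printing precision.
#'
#' @param block an [eeg_block()].
#' @param path CSV file path.
#' @return `write_eeg_block()` returns `path` invisibly; `read_eeg_block()`
#'   returns an [eeg_block()].
#' @export
write_eeg_block <- function(block, path) {
  fs <- attr(block, "fs")
  df <- data.frame(time_s = (seq_along(block) - 1) / fs,
                   value = as.numeric(block))
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(fs = fs,
                  condition = attr(block, "condition"),
                  group = attr(block, "group"),
                  n = length(block),
                  meta = attr(block, "meta"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_eeg_block
#' @export
read_eeg_block <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    info <- jsonlite::read_json(side, simplifyVector = TRUE)
    eeg_block(df$value, fs = info$fs,
              condition = if (is.null(info$condition)) NA else info$condition,
              group = if (is.null(info$group)) NA else info$group,
              meta = if (is.null(info$meta)) list() else info$meta)
  } else {
    fs <- 1 / stats::median(diff(df$time_s))
    eeg_block(df$value, fs = round(fs, 6))
  }
}
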