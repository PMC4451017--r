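# Structured conditions. Every user-facing failure carries a subclass so the
# CLI can map it onto an exit code and tests can assert the failure mode
# rather than matching message text.

po_error <- function(class, msg, ...) {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "po_error")))
}

po_format_error <- function(msg, ...) po_error("po_format_error", msg, ...)
po_input_error <- function(msg, ...) po_error("po_input_error", msg, ...)
po_config_error <- function(msg, ...) po_error("po_config_error", msg, ...)
po_io_error <- function(msg, ...) po_error("po_io_error", msg, ...)

# Read a text file as UTF-8 lines, tolerating a leading byte-order mark.
read_text_lines <- function(path) {
  if (!file.exists(path)) po_io_error("cannot read '%s': no such file", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) > 0L) lines[1L] <- sub("^﻿", "", lines[1L])
  lines
}

# Write through a temporary file in the destination directory and rename,
# so a failure mid-write never leaves a partial output behind.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) po_io_error("output directory '%s' does not exist", dir)
  tmp <- tempfile(pattern = ".pathoverlay-", tmpdir = dir)
  done <- FALSE
  on.exit(if (!done && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!suppressWarnings(file.rename(tmp, path))) {
    if (!file.copy(tmp, path, overwrite = TRUE)) {
      po_io_error("cannot write '%s'", path)
    }
    unlink(tmp)
  }
  done <- TRUE
  invisible(path)
}
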