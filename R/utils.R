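# Internal condition system.
#
# Two error families drive the CLI exit-code contract:
#   cvc_config_error -> exit 1 (usage / configuration problems)
#   cvc_data_error   -> exit 2 (malformed or inconsistent input data)

cvc_condition <- function(msg, class, ...) {
  structure(
    class = c(class, "cvc_error", "error", "condition"),
    list(message = msg, call = sys.call(-2L), ...)
  )
}

stop_config <- function(msg, ...) {
  stop(cvc_condition(msg, "cvc_config_error", ...))
}

stop_data <- function(msg, subclass = character(), ...) {
  stop(cvc_condition(msg, c(subclass, "cvc_data_error"), ...))
}

stop_invalid_variant <- function(msg, line = NA_integer_) {
  stop_data(msg, "cvc_invalid_variant", line = line)
}

stop_format <- function(msg, ...) stop_data(msg, "cvc_format_error", ...)

stop_reference_mismatch <- function(msg) {
  stop_data(msg, "cvc_reference_mismatch")
}

stop_context <- function(msg) stop_data(msg, "cvc_context_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_string1 <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Write through a temp file in the destination directory, then rename, so a
# failure mid-write never leaves a partial output file behind.
write_atomically <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = ".cvc", tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!suppressWarnings(file.rename(tmp, path))) {
    stop_data(sprintf("cannot write output file '%s'", path))
  }
  invisible(path)
}

cvc_log <- function(..., quiet = getOption("consensusvc.quiet", FALSE)) {
  if (!isTRUE(quiet)) message(paste0(...))
}
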