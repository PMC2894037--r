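# Internal helpers: error constructors and logging.

stop_bafnorm <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bafnorm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
log_msg <- function(level = c("info", "debug", "warn", "error"), ...) {
  level <- match.arg(level)
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  min_level <- getOption("bafnorm.log_level", "info")
  if (ranks[[level]] >= ranks[[min_level]]) {
    message(sprintf("[bafnorm %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Strictly increasing positions within each chromosome?
check_sorted_positions <- function(chromosome, position) {
  for (chr in unique(chromosome)) {
    p <- position[chromosome == chr]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      return(FALSE)
    }
  }
  TRUE
}
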