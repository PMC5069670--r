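#' Read and validate a run configuration
#'
#' YAML (or JSON, which YAML subsumes) configuration with one block per
#' pipeline stage. Unknown top-level keys are rejected so typos fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path YAML config path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("optics", "geometry", "shear", "recon", "stitch", "segment",
             "phantom", "paths", "seed", "log_level")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", toString(bad))
  if (!is.null(cfg$paths)) {
    cfg$paths <- lapply(cfg$paths, normalizePath, mustWork = FALSE)
  }
  structure(cfg, class = "run_config")
}

.log_level <- new.env(parent = emptyenv())
.log_level$value <- "INFO"

#' Minimal structured logging
#'
#' Per-stage messages with timestamps; level `"DEBUG"` additionally prints
#' array statistics from the pipeline stages.
#'
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`.
#' @param ... message parts passed to [paste0()].
#' @return Invisibly `NULL`.
#' @export
slot_log <- function(level = "INFO", ...) {
  ranks <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (ranks[[level]] >= ranks[[.log_level$value]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(...)))
  invisible(NULL)
}

#' @rdname slot_log
#' @param value new minimum level.
#' @export
set_log_level <- function(value = c("INFO", "DEBUG", "WARN")) {
  .log_level$value <- match.arg(value)
  invisible(value)
}
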