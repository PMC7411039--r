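# Shared helpers: coordinate conventions, seed derivation, validation.
#
# Conventions used throughout the package:
#  - images are matrices indexed [row, col] = [y + 1, x + 1];
#  - pixel coordinates are 0-based and pixel-centered: pixel i spans
#    (i - 0.5, i + 0.5], so a coordinate is mapped to its pixel by
#    rounding half-down;
#  - frames are 1-based integers; physical time of frame f is
#    (f - 1) * frame_interval_s seconds.

#' Round half-down to the containing pixel index
#' @param v numeric vector of 0-based pixel coordinates
#' @return integer vector of pixel indices
#' @keywords internal
px_index <- function(v) as.integer(ceiling(v - 0.5))

#' Derive a per-stream seed from a master seed
#'
#' Counter-based derivation so that stream `k` is stable when the number of
#' streams changes (adding embryos never reshuffles earlier embryos).
#'
#' @param master integer master seed
#' @param k integer stream index (>= 1)
#' @return integer seed in \[0, 2^31)
#' @export
derive_seed <- function(master, k) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(k) * 69621) %% m
  x <- (x * 16807) %% m
  as.integer(x)
}

stop_config <- function(...) {
  stop(structure(class = c("xenotrack_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Euclidean distance between consecutive rows of a 2-column matrix
step_lengths <- function(xy) {
  if (nrow(xy) < 2L) return(numeric(0))
  sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
}
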