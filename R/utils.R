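# Internal helpers shared across modules.

#' Millimetres per pixel for a given scan resolution
#'
#' @param dpi Dots per inch of the raster.
#' @return Calibration in mm per pixel (25.4 / dpi).
#' @examples
#' mm_per_pixel(300)
#' @export
mm_per_pixel <- function(dpi) {
  stopifnot(is.numeric(dpi), length(dpi) == 1, dpi > 0)
  25.4 / dpi
}

# Stable derived seed: keeps every stream reproducible from one user seed
# while giving each sheet/fold its own substream. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }))
  x <- (as.numeric(seed) %% 2147483647)
  for (p in parts) x <- (x * 69069 + p * 101 + 1) %% 2147483647
  as.integer(x)
}

# run fn with a local RNG state so callers' streams are not disturbed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

stop_config <- function(msg) abort(msg, class = "micrographr_config_error")
stop_generation <- function(msg) abort(msg, class = "micrographr_generation_error")
stop_segmentation <- function(msg) abort(msg, class = "micrographr_segmentation_error")
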