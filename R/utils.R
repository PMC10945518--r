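#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map_dbl list_rbind
NULL

# round half away from zero (base round() is banker's)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# midpoint of a 0-based half-open interval: start + floor(len/2)
interval_midpoint <- function(start, end) start + (end - start) %/% 2L

`%-na%` <- function(x, y) ifelse(is.na(x), y, x)

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(min)))
  }
  invisible(x)
}
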