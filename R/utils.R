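#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; report tables here follow the
#' round-half-up convention common in epidemiological tables, so 0.775
#' rounds to 0.78 at two decimals.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.775, 2) # 0.78
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_muac <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "muacscreen_error")))
}

# deterministic substream seed: one master seed, independent streams per
# purpose so adding a sampled variable never perturbs the others
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647L)
}
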