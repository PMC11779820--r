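#' Round half away from zero
#'
#' Base R `round()` rounds half to even; report tables in this field are
#' conventionally rounded half-up (0.0465 -> 0.047 at three decimals), so all
#' display-level rounding in the package goes through this helper. Internal
#' metrics are kept at full precision; rounding happens only at formatting.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny absolute nudge guards against binary representations like 2.3499999…
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# "100%" for exactly 1, otherwise one decimal place ("80.0%", "23.8%").
format_percent <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  exact <- ok & x == 1
  out[exact] <- "100%"
  rest <- ok & !exact
  out[rest] <- sprintf("%.1f%%", round_half_up(100 * x[rest], 1))
  out[!ok] <- "NA"
  out
}

format_f1 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.3f", round_half_up(x, 3)))
}

stop_input <- function(...) {
  stop(structure(class = c("sangerbin_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
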