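# Internal helpers shared across modules.

# microlitre/min -> litre/h
ul_min_to_l_h <- function(x) x * 60 / 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("dabepbpk_invalid", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_invalid(name, " must be a positive finite number")
  invisible(x)
}

assert_fraction <- function(x, name, open_lower = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x <= 1) &&
    all(if (open_lower) x > 0 else x >= 0)
  if (!ok) stop_invalid(name, " must lie in ", if (open_lower) "(0, 1]" else "[0, 1]")
  invisible(x)
}

# log-normal sdlog from a percent coefficient of variation
cv_to_sdlog <- function(cv_percent) sqrt(log(1 + (cv_percent / 100)^2))
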