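#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rbinom rnorm rgamma setNames
NULL

abort_invalid <- function(msg, ...) {
  abort(msg, class = "hccea_invalid_parameter", ...)
}

abort_format <- function(msg, ...) {
  abort(msg, class = "hccea_format_error", ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "hccea_config_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_positive_scalar <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
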