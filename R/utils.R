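#' Trapezoid integral of y over x
#'
#' @param x numeric vector, strictly increasing.
#' @param y numeric vector, same length as `x`.
#' @return The trapezoid-rule integral as a single number.
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("trapz needs at least two points")
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Check for a strictly increasing numeric vector
#' @noRd
is_strictly_increasing <- function(x) {
  length(x) >= 2L && all(diff(x) > 0)
}

# stop() with a class so callers can test for specific failure modes
st_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "shelltherm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

st_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "shelltherm_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
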