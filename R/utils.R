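# Internal helpers shared across modules.

#' @importFrom stats sd var optim rgamma rlnorm runif rbinom rmultinom pgamma
#'   qgamma uniroot lm coef setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# Geometric mean computed in log space; underflow-safe for long sequences.
geomean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# Squared coefficient of variation. Population (n) denominator by default;
# the sorter literature does not distinguish, so it is switchable.
cv2 <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  m <- mean(x)
  if (m == 0) stop("cv2 undefined: mean is zero")
  v <- if (denominator == "population") mean((x - m)^2) else stats::var(x)
  v / m^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)
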