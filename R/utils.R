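#' @importFrom stats cor pt p.adjust quantile rnorm rbinom sd var hclust
#'   cutree as.dist prcomp runif predict lm coef setNames
#' @importFrom utils combn write.table read.delim head
NULL

# Run expr with a locally-seeded RNG, leaving the caller's RNG untouched.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ichwmi <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ichwmi_error")))
}

assert_that <- function(ok, msg, class = "ichwmi_validation_error") {
  if (!isTRUE(ok)) stop_ichwmi(msg, class)
  invisible(TRUE)
}
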