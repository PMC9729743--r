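#' @useDynLib fontanflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif setNames
#' @importFrom utils write.csv read.csv packageVersion modifyList
NULL

# Pa per mmHg
MMHG_PA <- 133.322

PORT_NAMES <- c("SVC", "IVC", "LPA", "RPA")

ff_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "fontanflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) ff_stop(msg, "fontanflow_validation_error")
geometry_error   <- function(msg) ff_stop(msg, "fontanflow_geometry_error")
resolution_error <- function(msg) ff_stop(msg, "fontanflow_resolution_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a pressure in pascal to millimetres of mercury
#'
#' Fixed conversion constant 1 mmHg = 133.322 Pa.
#'
#' @param pa pressure in Pa.
#' @return pressure in mmHg.
#' @export
pa_to_mmhg <- function(pa) pa / MMHG_PA
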