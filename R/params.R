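#' Model parameters for the hospital flow model
#'
#' Constructs and validates the 14 scalar parameters of the four-compartment
#' hospital patient-flow model. Unspecified parameters take the canonical
#' default values (admission and transfer rates calibrated to a mid-size UK
#' hospital; where the source tabulates a range, the documented endpoint is
#' fixed as default and can be overridden).
#'
#' The parameters are:
#' \describe{
#'   \item{r}{admission rate into the emergency department (per day).}
#'   \item{K}{hospital resource capacity (beds); logistic ceiling of the ED.}
#'   \item{a}{ED-to-ward processing rate (the "time to admit" channel).}
#'   \item{b1, b2}{bed-time handling constants; saturation denominators of the
#'     Holling type II transfer terms (days).}
#'   \item{beta}{ward/ICU flow rate.}
#'   \item{zeta}{ICU transfer modulation rate (per day).}
#'   \item{epsilon}{model-reduction switch for the ICU saturation factor
#'     \eqn{1 + \zeta I/(1+\epsilon I)}; canonical values 0 or 1.}
#'   \item{gamma1, gamma2}{inter-department flow multipliers.}
#'   \item{m1, m2, m3}{per-compartment death rates (Covid ward, general ward,
#'     ICU).}
#'   \item{omega}{discharge rate from the ED (per day).}
#' }
#'
#' All parameters must be finite and non-negative; `K` must be positive and
#' `m1`, `m2`, `m3` strictly positive (the resource--ICU equilibrium divides
#' by `m3`).
#'
#' @param ... named scalar overrides of the defaults, e.g. `zeta = 2.3`.
#' @return An object of class `ward_params`: a named list of the 14 validated
#'   parameters.
#' @examples
#' p <- ward_params()            # canonical defaults
#' p2 <- ward_params(zeta = 2.3, K = 20)
#' @seealso [validate_params()] for construction from a raw named mapping.
#' @export
ward_params <- function(...) {
  validate_params(list(...))
}

#' Canonical default parameter values
#'
#' @return Named list of the 14 default parameter values.
#' @export
param_defaults <- function() {
  list(r = 5, K = 100, a = 4, b1 = 1.5, b2 = 2, beta = 5, zeta = 0.2,
       epsilon = 1, gamma1 = 4, gamma2 = 5, m1 = 1.5, m2 = 1.5, m3 = 1.5,
       omega = 3.5)
}

#' Validate a raw parameter mapping
#'
#' Fills unspecified entries with the canonical defaults, rejects unknown
#' names, and enforces the parameter invariants (finite, non-negative,
#' `K > 0`, `m1, m2, m3 > 0`).
#'
#' @param raw named list (possibly empty) of parameter values.
#' @return A validated `ward_params` object.
#' @examples
#' validate_params(list())               # full defaults
#' validate_params(list(zeta = 2.3))
#' @export
validate_params <- function(raw = list()) {
  if (inherits(raw, "ward_params")) return(raw)
  defaults <- param_defaults()
  if (length(raw)) {
    nm <- names(raw)
    if (is.null(nm) || any(nm == ""))
      stop("parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           "; valid names are: ", paste(names(defaults), collapse = ", "),
           call. = FALSE)
  }
  p <- utils::modifyList(defaults, as.list(raw))
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
  }
  if (p$K <= 0) stop("parameter 'K' must be positive", call. = FALSE)
  for (nm in c("m1", "m2", "m3"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive ",
           "(the resource-ICU equilibrium divides by m3)", call. = FALSE)
  structure(p, class = "ward_params")
}

#' @export
print.ward_params <- function(x, ...) {
  cat("Hospital flow model parameters:\n")
  v <- unlist(x)
  print(v, ...)
  invisible(x)
}

#' Coerce a state vector
#'
#' Accepts a numeric vector of length 4, optionally named, holding the four
#' compartment censuses (E: emergency department, C: Covid ward, G: general
#' medical ward, I: intensive care unit) and returns it named and validated.
#'
#' @param state numeric length-4 vector, optionally named with E, C, G, I.
#' @param allow_negative if `FALSE` (default), negative components are an
#'   error. Equilibrium candidates may carry negative components and use
#'   `TRUE`.
#' @return Named numeric vector `c(E=, C=, G=, I=)`.
#' @export
as_ward_state <- function(state, allow_negative = FALSE) {
  comp <- c("E", "C", "G", "I")
  if (!is.numeric(state) || length(state) != 4L)
    stop("state must be a numeric vector of length 4 (E, C, G, I)",
         call. = FALSE)
  if (!is.null(names(state)) && all(comp %in% names(state)))
    state <- state[comp]
  if (any(!is.finite(state)))
    stop("state components must be finite", call. = FALSE)
  if (!allow_negative && any(state < 0))
    stop("state components must be non-negative", call. = FALSE)
  stats::setNames(as.numeric(state), comp)
}

## internal: check a model variant tag
check_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% c("as_printed", "balanced"))
    stop("variant must be one of 'as_printed', 'balanced'", call. = FALSE)
  variant
}
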