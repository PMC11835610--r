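#' Right-hand side of the hospital flow model
#'
#' Evaluates the vector field of the four-compartment model
#' \deqn{dE/dt = rE(1-E/K) - aEC/(1+b_1E)}
#' \deqn{dC/dt = \Gamma_1 aEC/(1+b_1E) - m_1C - \beta GC/(1+b_2C)\,\sigma(I)}
#' \deqn{dG/dt = \Gamma_2 \beta LC/(1+b_2C)\,\sigma(I) - m_2G}
#' \deqn{dI/dt = \beta aEC/(1+b_1E) - m_3I + \omega E}
#' with ICU saturation factor \eqn{\sigma(I) = 1 + \zeta I/(1+\epsilon I)}.
#'
#' The two variants differ in the leading state \eqn{L} of the general-ward
#' gain term. `as_printed` uses \eqn{L = I}, an exact transcription of the
#' published system; under it the patients removed from the Covid ward are
#' not those arriving on the general ward, and the published closed-form
#' equilibria do not annul \eqn{dG/dt}. `balanced` uses \eqn{L = G}, so the
#' general-ward gain mirrors the Covid-ward loss term; this mass-balanced
#' form reproduces the published closed-form equilibria exactly and is the
#' default for equilibrium work throughout the package.
#'
#' No clipping is performed: the algebra is evaluated exactly as given, and
#' non-negativity is asserted downstream, never silently enforced.
#'
#' @param state numeric length-4 state (E, C, G, I); components must be
#'   non-negative so that the denominators \eqn{1+b_1E}, \eqn{1+b_2C},
#'   \eqn{1+\epsilon I} are strictly positive.
#' @param params a [ward_params()] object (or a named list coercible to one).
#' @param variant `"balanced"` (default) or `"as_printed"`.
#' @return Named numeric vector of the four derivatives `c(dE=, dC=, dG=, dI=)`.
#' @examples
#' p <- ward_params()
#' ward_rhs(c(1, 1, 1, 1), p, variant = "as_printed")
#' ward_rhs(c(0, 0, 0, 0), p)  # the origin is always a fixed point
#' @export
ward_rhs <- function(state, params, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  s <- as_ward_state(state, allow_negative = TRUE)
  E <- s[["E"]]; C <- s[["C"]]; G <- s[["G"]]; I <- s[["I"]]
  dE1 <- 1 + p$b1 * E; dC1 <- 1 + p$b2 * C; dI1 <- 1 + p$epsilon * I
  if (dE1 <= 0 || dC1 <= 0 || dI1 <= 0)
    stop("state outside the model domain: a saturation denominator is <= 0",
         call. = FALSE)
  holl <- p$a * E * C / dE1            # ED -> Covid-ward Holling II flux
  sat  <- 1 + p$zeta * I / dI1         # ICU saturation factor
  lead <- if (variant == "balanced") G else I
  c(dE = p$r * E * (1 - E / p$K) - holl,
    dC = p$gamma1 * holl - p$m1 * C - p$beta * G * C / dC1 * sat,
    dG = p$gamma2 * p$beta * lead * C / dC1 * sat - p$m2 * G,
    dI = p$beta * holl - p$m3 * I + p$omega * E)
}

#' Analytic Jacobian of the hospital flow model
#'
#' Partial derivatives of [ward_rhs()] with respect to the state, derived
#' symbolically from the implemented right-hand side (not transcribed from
#' published matrix entries, several of which are typographically corrupted).
#' Under the `as_printed` variant the matrix has the structural zeros
#' J\[1,3\] = J\[1,4\] = J\[3,1\] = J\[4,3\] = 0 at every admissible state.
#'
#' @inheritParams ward_rhs
#' @return A 4x4 numeric matrix with rows/columns ordered E, C, G, I.
#' @examples
#' ward_jacobian(c(0, 0, 0, 0), ward_params())  # diag(r, -m1, -m2, -m3) + omega in [4,1]
#' @export
ward_jacobian <- function(state, params, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  s <- as_ward_state(state, allow_negative = TRUE)
  E <- s[["E"]]; C <- s[["C"]]; G <- s[["G"]]; I <- s[["I"]]
  dE1 <- 1 + p$b1 * E; dC1 <- 1 + p$b2 * C; dI1 <- 1 + p$epsilon * I
  if (dE1 <= 0 || dC1 <= 0 || dI1 <= 0)
    stop("state outside the model domain: a saturation denominator is <= 0",
         call. = FALSE)
  phi  <- p$a * E / dE1                # per-C Holling flux
  dphi <- p$a / dE1^2                  # d phi / dE
  psi  <- C / dC1                      # saturating C factor
  dpsi <- 1 / dC1^2                    # d psi / dC
  sat  <- 1 + p$zeta * I / dI1
  dsat <- p$zeta / dI1^2               # d sat / dI
  J <- matrix(0, 4, 4, dimnames = list(c("E", "C", "G", "I"),
                                       c("E", "C", "G", "I")))
  J[1, 1] <- p$r * (1 - 2 * E / p$K) - dphi * C
  J[1, 2] <- -phi
  J[2, 1] <- p$gamma1 * dphi * C
  J[2, 2] <- p$gamma1 * phi - p$m1 - p$beta * G * dpsi * sat
  J[2, 3] <- -p$beta * psi * sat
  J[2, 4] <- -p$beta * G * psi * dsat
  if (variant == "as_printed") {
    J[3, 2] <- p$gamma2 * p$beta * I * dpsi * sat
    J[3, 3] <- -p$m2
    J[3, 4] <- p$gamma2 * p$beta * (psi * sat + I * psi * dsat)
  } else {
    J[3, 2] <- p$gamma2 * p$beta * G * dpsi * sat
    J[3, 3] <- p$gamma2 * p$beta * psi * sat - p$m2
    J[3, 4] <- p$gamma2 * p$beta * G * psi * dsat
  }
  J[4, 1] <- p$beta * dphi * C + p$omega
  J[4, 2] <- p$beta * phi
  J[4, 4] <- -p$m3
  J
}

#' Finite-difference Jacobian (verification oracle)
#'
#' Central finite-difference approximation of the partial derivatives of
#' [ward_rhs()]; second-order accurate in `step`. Used to cross-check the
#' analytic [ward_jacobian()].
#'
#' @inheritParams ward_rhs
#' @param step base step size; the per-component step is
#'   `step * (1 + |state_j|)`.
#' @return A 4x4 numeric matrix.
#' @export
ward_jacobian_fd <- function(state, params, variant = "balanced",
                             step = 1e-6) {
  p <- validate_params(params)
  check_variant(variant)
  s <- as_ward_state(state, allow_negative = TRUE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a positive number", call. = FALSE)
  J <- matrix(0, 4, 4, dimnames = list(c("E", "C", "G", "I"),
                                       c("E", "C", "G", "I")))
  for (j in 1:4) {
    h <- step * (1 + abs(s[j]))
    sp <- s; sp[j] <- s[j] + h
    sm <- s; sm[j] <- s[j] - h
    J[, j] <- (ward_rhs(sp, p, variant) - ward_rhs(sm, p, variant)) / (2 * h)
  }
  J
}
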