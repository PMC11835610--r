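#' Equilibrium objects
#'
#' An equilibrium candidate is a labelled state together with the max-norm
#' residual of the vector field at that state (under a stated model variant)
#' and a clinical-feasibility flag (all components non-negative). Published
#' closed forms are emitted exactly as printed -- even where their residual
#' under a variant is non-zero -- so that the reported residual, not a silent
#' "correction", carries the information.
#'
#' @param label character label (`"E1"`, `"E2"`, `"E3"`, `"E4"`, `"E5"` or
#'   `"numeric"`).
#' @param state numeric length-4 state; may carry negative components.
#' @param params a [ward_params()] object.
#' @param variant model variant under which the residual is evaluated.
#' @return An object of class `ward_equilibrium` with fields `label`,
#'   `state`, `residual_norm`, `feasible`, `variant`.
#' @keywords internal
new_equilibrium <- function(label, state, params, variant) {
  s <- as_ward_state(state, allow_negative = TRUE)
  res <- ward_residual(s, params, variant)
  structure(list(label = label, state = s, residual_norm = res,
                 feasible = min(s) >= -1e-12, variant = variant),
            class = "ward_equilibrium")
}

#' @export
print.ward_equilibrium <- function(x, ...) {
  cat(sprintf("<%s equilibrium (%s)>  E=%.7g C=%.7g G=%.7g I=%.7g\n",
              x$label, x$variant, x$state[["E"]], x$state[["C"]],
              x$state[["G"]], x$state[["I"]]))
  cat(sprintf("  residual (max-norm): %.3g   clinically feasible: %s\n",
              x$residual_norm, x$feasible))
  invisible(x)
}

#' @export
as.data.frame.ward_equilibrium <- function(x, ...) {
  data.frame(label = x$label, E = x$state[["E"]], C = x$state[["C"]],
             G = x$state[["G"]], I = x$state[["I"]],
             residual = x$residual_norm, feasible = x$feasible,
             variant = x$variant, stringsAsFactors = FALSE)
}

#' @export
as.data.frame.ward_equilibria <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}

#' @export
print.ward_equilibria <- function(x, ...) {
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Max-norm residual of the vector field at a point
#'
#' @param state numeric length-4 state (negative components allowed).
#' @inheritParams ward_rhs
#' @return Non-negative number; 0 iff the point is a fixed point.
#' @examples
#' ward_residual(c(0, 0, 0, 0), ward_params())  # 0
#' @export
ward_residual <- function(state, params, variant = "balanced") {
  max(abs(ward_rhs(state, params, variant)))
}

#' Clinical feasibility of an equilibrium
#'
#' An equilibrium is clinically feasible when every compartment census is
#' non-negative (within round-off, -1e-12).
#'
#' @param eq a `ward_equilibrium` object.
#' @return Logical.
#' @export
is_clinically_feasible <- function(eq) {
  stopifnot(inherits(eq, "ward_equilibrium"))
  min(eq$state) >= -1e-12
}

#' Trivial (empty-hospital) equilibrium
#'
#' The origin (0, 0, 0, 0): every term of the vector field carries a state
#' factor, so the empty hospital is a fixed point for every parameter set.
#'
#' @inheritParams ward_rhs
#' @return A `ward_equilibrium` labelled `E1` with exact zero residual.
#' @export
equilibrium_trivial <- function(params, variant = "balanced") {
  params <- validate_params(params)
  check_variant(variant)
  new_equilibrium("E1", c(0, 0, 0, 0), params, variant)
}

#' Resource--ICU equilibrium
#'
#' The boundary equilibrium \eqn{(K, 0, 0, K\omega/m_3)}: the ED saturates at
#' the resource capacity, the wards are empty, and the ICU balances the
#' discharge inflow \eqn{\omega E} against its death rate. Exact under both
#' variants.
#'
#' @inheritParams ward_rhs
#' @return A `ward_equilibrium` labelled `E2`.
#' @examples
#' equilibrium_resource_icu(ward_params())  # (100, 0, 0, 233.3333333)
#' @export
equilibrium_resource_icu <- function(params, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  new_equilibrium("E2", c(p$K, 0, 0, p$K * p$omega / p$m3), p, variant)
}

#' ED-free equilibrium (clinically irrelevant point)
#'
#' The published closed form
#' \eqn{(0,\; m_2/(\beta\Gamma_2 - b_2 m_2),\; -m_1\Gamma_1/(\beta\Gamma_2 -
#' b_2 m_2),\; 0)}, emitted exactly as printed. Its general-ward component is
#' negative whenever \eqn{\beta\Gamma_2 > b_2 m_2}, making the point
#' clinically infeasible. The residual is generally non-zero even under the
#' balanced variant, because the printed G-component carries \eqn{\Gamma_1}
#' where the ward-balance derivation yields \eqn{\Gamma_2}; the residual is
#' recorded, never "corrected". The C-component does annul the general-ward
#' balance bracket exactly.
#'
#' @inheritParams ward_rhs
#' @return A `ward_equilibrium` labelled `E3`.
#' @export
equilibrium_no_ed <- function(params, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  den <- p$beta * p$gamma2 - p$b2 * p$m2
  if (abs(den) < .Machine$double.eps * max(1, p$beta * p$gamma2))
    stop("degenerate parameters: beta*gamma2 == b2*m2, the ED-free ",
         "equilibrium is undefined", call. = FALSE)
  new_equilibrium("E3", c(0, p$m2 / den, -p$m1 * p$gamma1 / den, 0),
                  p, variant)
}

#' General-ward-free equilibrium
#'
#' The closed-form equilibrium with an empty general medical ward:
#' \deqn{E = m_1/(a\Gamma_1 - b_1 m_1), \quad
#'       C = r\Gamma_1(aK\Gamma_1 - Kb_1m_1 - m_1)/(K(a\Gamma_1 - b_1m_1)^2),}
#' \eqn{G = 0}, and \eqn{I = (\beta a E C/(1+b_1E) + \omega E)/m_3}. The E
#' component is the unique value at which the Covid ward's per-capita gain
#' \eqn{\Gamma_1 aE/(1+b_1E)} balances its death rate \eqn{m_1}; the I
#' expression is algebraically identical to the published closed form. The
#' point is an exact fixed point of the balanced variant; under `as_printed`
#' the general-ward equation has a positive residual, which is recorded.
#'
#' @inheritParams ward_rhs
#' @return A `ward_equilibrium` labelled `E4`.
#' @examples
#' equilibrium_ward_free(ward_params())
#' @export
equilibrium_ward_free <- function(params, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  den <- p$a * p$gamma1 - p$b1 * p$m1
  if (den <= 0)
    stop("no general-ward-free equilibrium: requires a*gamma1 > b1*m1",
         call. = FALSE)
  E <- p$m1 / den
  C <- p$r * p$gamma1 * (p$a * p$K * p$gamma1 - p$K * p$b1 * p$m1 - p$m1) /
    (p$K * den^2)
  I <- (p$beta * p$a * E * C / (1 + p$b1 * E) + p$omega * E) / p$m3
  new_equilibrium("E4", c(E, C, 0, I), p, variant)
}

## ---- numeric equilibrium location ------------------------------------------

## internal: rhs that returns NULL instead of erroring outside the domain
rhs_or_null <- function(state, p, variant) {
  tryCatch(ward_rhs(state, p, variant), error = function(e) NULL)
}

## internal: damped Newton on the full 4-D system with analytic Jacobian
newton_full <- function(s0, p, variant, tol = 1e-12, maxit = 60) {
  s <- as.numeric(s0)
  f <- rhs_or_null(s, p, variant)
  if (is.null(f) || any(!is.finite(f))) return(NULL)
  fn <- max(abs(f))
  for (it in seq_len(maxit)) {
    if (fn < tol) break
    J <- tryCatch(ward_jacobian(s, p, variant), error = function(e) NULL)
    if (is.null(J)) return(NULL)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      s_new <- s - lambda * step
      f_new <- rhs_or_null(s_new, p, variant)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          max(abs(f_new)) < fn) break
      lambda <- lambda / 2
      if (lambda < 1 / 1024) return(NULL)
    }
    s <- s_new; f <- f_new; fn <- max(abs(f))
  }
  if (fn < tol * 1e4 || fn < 1e-9) s else NULL
}

## internal: damped Newton on a 2-D reduced system (numeric 2x2 Jacobian)
newton_reduced <- function(x0, fun, tol = 1e-10, maxit = 80) {
  x <- as.numeric(x0)
  f <- fun(x)
  if (is.null(f) || any(!is.finite(f))) return(NULL)
  fn <- max(abs(f))
  for (it in seq_len(maxit)) {
    if (fn < tol) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-7 * (1 + abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      fp <- fun(xp); fm <- fun(xm)
      if (is.null(fp) || is.null(fm)) return(NULL)
      J[, j] <- (fp - fm) / (2 * h)
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      f_new <- fun(x_new)
      if (!is.null(f_new) && all(is.finite(f_new)) &&
          max(abs(f_new)) < fn) break
      lambda <- lambda / 2
      if (lambda < 1 / 1024) return(NULL)
    }
    x <- x_new; f <- f_new; fn <- max(abs(f))
  }
  if (fn < tol) x else NULL
}

## internal: lift a reduced (E, C) point to the full state.
## The ICU balance dI/dt = 0 gives I in closed form for any (E, C); the
## general-ward component then follows from dG/dt = 0 (as_printed) or from
## the Covid-ward balance dC/dt = 0 (balanced, C > 0).
lift_state <- function(E, C, p, variant, family = c("gain", "ward_free")) {
  family <- match.arg(family)
  if (1 + p$b1 * E <= 0) return(NULL)
  phi <- p$a * E / (1 + p$b1 * E)
  I <- (p$beta * phi * C + p$omega * E) / p$m3
  if (1 + p$epsilon * I <= 0 || 1 + p$b2 * C <= 0) return(NULL)
  sat <- 1 + p$zeta * I / (1 + p$epsilon * I)
  G <- if (variant == "as_printed") {
    p$gamma2 * p$beta * I * C / (1 + p$b2 * C) * sat / p$m2
  } else if (family == "ward_free") {
    0
  } else {
    ## from dC/dt = 0: beta*G*psi(C)*sat = C*(gamma1*phi - m1)
    if (abs(C) < 1e-300) 0 else
      (p$gamma1 * phi - p$m1) * (1 + p$b2 * C) / (p$beta * sat)
  }
  if (!is.finite(G)) return(NULL)
  c(E, C, G, I)
}

#' Locate equilibria numerically
#'
#' Finds fixed points of the model by reducing the four equations to a
#' two-dimensional system in (E, C) -- the ICU balance gives I in closed form
#' and the remaining ward equation gives G -- then root-finding from a grid
#' of starting points, polishing every candidate in the full 4-D system with
#' a damped Newton iteration, verifying the full residual, and de-duplicating
#' converged roots. The closed forms [equilibrium_trivial()] and
#' [equilibrium_resource_icu()] are always seeded (and therefore always
#' recovered); [equilibrium_ward_free()] and [equilibrium_no_ed()] are
#' included whenever their residual under `variant` passes the tolerance.
#'
#' A root is labelled `E5` when all four components are strictly positive
#' and it coincides with no closed form; other unmatched roots are labelled
#' `"numeric"`.
#'
#' @inheritParams ward_rhs
#' @param search_grid optional list with numeric vectors `E` and `C` of
#'   starting values; default is logarithmically spaced over
#'   (1e-3, 2K) (9 x 7 points).
#' @param extra_starts optional list of full length-4 states used as
#'   additional warm starts (continuation).
#' @param tol_residual maximum allowed full-system residual (max-norm) of a
#'   returned root.
#' @param tol_dedupe pairwise max-norm below which two roots are considered
#'   identical.
#' @return An object of class `ward_equilibria`: a list of
#'   `ward_equilibrium` objects. Empty (with a warning) if nothing converges.
#' @examples
#' eqs <- find_equilibria(ward_params())
#' as.data.frame(eqs)
#' @export
find_equilibria <- function(params, variant = "balanced", search_grid = NULL,
                            extra_starts = NULL, tol_residual = 1e-8,
                            tol_dedupe = 1e-6) {
  p <- validate_params(params)
  check_variant(variant)
  if (is.null(search_grid)) {
    search_grid <- list(E = 10^seq(-3, log10(2 * p$K), length.out = 9),
                        C = 10^seq(-3, log10(2 * p$K), length.out = 7))
  }
  stopifnot(is.list(search_grid), length(search_grid$E) > 0,
            length(search_grid$C) > 0)

  roots <- list()       # numeric states
  add_root <- function(s) {
    if (is.null(s) || any(!is.finite(s))) return(invisible(NULL))
    res <- tryCatch(ward_residual(s, p, variant), error = function(e) Inf)
    if (!is.finite(res) || res >= tol_residual) return(invisible(NULL))
    for (r0 in roots) if (max(abs(r0 - s)) < tol_dedupe) return(invisible(NULL))
    roots[[length(roots) + 1L]] <<- as.numeric(s)
    invisible(NULL)
  }

  ## exact closed forms first (E1, E2 exact under both variants)
  add_root(c(0, 0, 0, 0))
  add_root(c(p$K, 0, 0, p$K * p$omega / p$m3))
  cf_e4 <- tryCatch(equilibrium_ward_free(p, variant), error = function(e) NULL)
  if (!is.null(cf_e4)) add_root(cf_e4$state)
  cf_e3 <- tryCatch(equilibrium_no_ed(p, variant), error = function(e) NULL)
  if (!is.null(cf_e3)) add_root(cf_e3$state)

  ## reduced-system solves from the grid
  families <- if (variant == "balanced") c("gain", "ward_free") else "gain"
  reduced_fun <- function(family) function(x) {
    s <- lift_state(x[1], x[2], p, variant, family)
    if (is.null(s)) return(NULL)
    f <- rhs_or_null(s, p, variant)
    if (is.null(f)) return(NULL)
    if (variant == "as_printed") {
      f[c(1, 2)]                       # dE, dC (G, I eliminated)
    } else if (family == "ward_free") {
      f[c(1, 2)]                       # dE, dC with G = 0
    } else {
      f[c(1, 3)]                       # dE, dG (G from Covid-ward balance)
    }
  }
  for (family in families) {
    fn <- reduced_fun(family)
    for (E0 in search_grid$E) for (C0 in search_grid$C) {
      x <- newton_reduced(c(E0, C0), fn)
      if (is.null(x)) next
      s <- lift_state(x[1], x[2], p, variant, family)
      if (is.null(s)) next
      add_root(newton_full(s, p, variant) %||% s)
    }
  }

  ## continuation warm starts polished in the full system
  for (s0 in extra_starts %||% list()) add_root(newton_full(s0, p, variant))

  if (!length(roots)) {
    warning("no equilibrium converged from any starting point")
    return(structure(list(), class = "ward_equilibria"))
  }

  ## label each root against the closed forms
  closed <- list(E1 = c(0, 0, 0, 0),
                 E2 = c(p$K, 0, 0, p$K * p$omega / p$m3))
  if (!is.null(cf_e3)) closed$E3 <- as.numeric(cf_e3$state)
  if (!is.null(cf_e4)) closed$E4 <- as.numeric(cf_e4$state)
  out <- lapply(roots, function(s) {
    label <- "numeric"
    for (nm in names(closed))
      if (max(abs(closed[[nm]] - s)) < tol_dedupe) { label <- nm; break }
    if (label == "numeric" && all(s > 0)) label <- "E5"
    new_equilibrium(label, s, p, variant)
  })
  structure(out, class = "ward_equilibria")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
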