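#' Characteristic-polynomial coefficients of a 4x4 matrix
#'
#' Coefficients A1..A4 of \eqn{\lambda^4 + A_1\lambda^3 + A_2\lambda^2 +
#' A_3\lambda + A_4} (with \eqn{A_0 = 1}) computed from the invariants of the
#' matrix: \eqn{A_1 = -\mathrm{tr}\,J}, \eqn{A_2} the sum of 2x2 principal
#' minors, \eqn{A_3} minus the sum of 3x3 principal minors, and
#' \eqn{A_4 = \det J}. On matrices with the model's structural zero pattern
#' these expressions reduce exactly to the published coefficient formulas,
#' which omit only products that vanish under that pattern.
#'
#' @param J finite 4x4 numeric matrix.
#' @return An object of class `char_poly`: named numeric vector
#'   `c(A1=, A2=, A3=, A4=)`.
#' @examples
#' char_poly_coeffs(diag(4))          # (lambda - 1)^4: -4, 6, -4, 1
#' char_poly_coeffs(diag(c(1, 2, 3, 4)))
#' @export
char_poly_coeffs <- function(J) {
  stopifnot(is.matrix(J), all(dim(J) == c(4, 4)))
  if (any(!is.finite(J))) stop("J must be finite", call. = FALSE)
  idx <- utils::combn(4, 2, simplify = FALSE)
  m2 <- sum(vapply(idx, function(ij) det(J[ij, ij]), numeric(1)))
  idx3 <- utils::combn(4, 3, simplify = FALSE)
  m3 <- sum(vapply(idx3, function(ijk) det(J[ijk, ijk]), numeric(1)))
  structure(c(A1 = -sum(diag(J)), A2 = m2, A3 = -m3, A4 = det(J)),
            class = "char_poly")
}

#' Routh-Hurwitz conditions for a quartic
#'
#' Evaluates the four published stability conditions
#' \eqn{A_1 > 0}, \eqn{A_3 > 0}, \eqn{A_1A_2 > A_3},
#' \eqn{A_1A_2A_3 > A_3^2 + A_1^2A_4},
#' plus \eqn{A_4 > 0}. The published set of four alone is not sufficient for
#' a quartic (it admits polynomials with \eqn{A_4 < 0}, which always carry a
#' positive real root); `rh_stable` is therefore the full Hurwitz verdict --
#' the conjunction of all five -- which is necessary and sufficient for every
#' root to have negative real part.
#'
#' @param cp a `char_poly` object (or numeric vector A1..A4).
#' @return List with `conditions` (named logical vector of the four published
#'   conditions), `a4_positive` (logical), and `rh_stable` (logical).
#' @examples
#' routh_hurwitz(char_poly_coeffs(diag(c(-1, -2, -3, -4))))
#' @export
routh_hurwitz <- function(cp) {
  a <- as.numeric(cp)
  stopifnot(length(a) == 4, all(is.finite(a)))
  A1 <- a[1]; A2 <- a[2]; A3 <- a[3]; A4 <- a[4]
  conditions <- c(A1_pos = A1 > 0,
                  A3_pos = A3 > 0,
                  A1A2_gt_A3 = A1 * A2 > A3,
                  A1A2A3_gt_A3sq_plus_A1sqA4 =
                    A1 * A2 * A3 > A3^2 + A1^2 * A4)
  a4_positive <- A4 > 0
  list(conditions = conditions, a4_positive = a4_positive,
       rh_stable = all(conditions) && a4_positive)
}

#' Classify an equilibrium from the Jacobian spectrum
#'
#' Computes the eigenvalues of `J` and classifies the local phase portrait:
#' `nonhyperbolic` when any eigenvalue's real part falls within `zero_tol` of
#' zero; otherwise `stable_node`/`stable_focus` when all real parts are
#' negative (focus when a complex pair is present), `unstable_node`/
#' `unstable_focus` when all are positive, and `saddle`/`saddle_focus` for
#' mixed signs.
#'
#' @param J finite 4x4 numeric matrix.
#' @param zero_tol threshold on |Re(lambda)| below which the equilibrium is
#'   declared non-hyperbolic; default `1e-9 * (1 + spectral radius)`
#'   (scale-aware).
#' @return An object of class `stability_report` with fields `eigenvalues`
#'   (complex, sorted by decreasing real part), `classification`, `charpoly`,
#'   `rh` (from [routh_hurwitz()]), `rh_stable`, `zero_tol`.
#' @examples
#' eigen_classify(diag(c(-1, -2, -3, -4)))   # stable_node
#' @export
eigen_classify <- function(J, zero_tol = NULL) {
  stopifnot(is.matrix(J), all(dim(J) == c(4, 4)))
  if (any(!is.finite(J))) stop("J must be finite", call. = FALSE)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  rho <- max(Mod(ev))
  if (is.null(zero_tol)) zero_tol <- 1e-9 * (1 + rho)
  stopifnot(zero_tol > 0)
  im_tol <- 1e-9 * (1 + rho)
  re <- Re(ev)
  has_complex <- any(abs(Im(ev)) > im_tol)
  classification <- if (any(abs(re) <= zero_tol)) {
    "nonhyperbolic"
  } else if (all(re < 0)) {
    if (has_complex) "stable_focus" else "stable_node"
  } else if (all(re > 0)) {
    if (has_complex) "unstable_focus" else "unstable_node"
  } else {
    if (has_complex) "saddle_focus" else "saddle"
  }
  cp <- char_poly_coeffs(J)
  rh <- routh_hurwitz(cp)
  structure(list(eigenvalues = ev, classification = classification,
                 charpoly = cp, rh = rh, rh_stable = rh$rh_stable,
                 zero_tol = zero_tol),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability report> ", x$classification, "\n")
  cat("  eigenvalues:\n")
  for (ev in x$eigenvalues)
    cat(sprintf("    %+.6g %+.6gi\n", Re(ev), Im(ev)))
  cat("  Routh-Hurwitz stable:", x$rh_stable, "\n")
  invisible(x)
}

#' @export
as.data.frame.stability_report <- function(x, ...) {
  ev <- x$eigenvalues
  d <- data.frame(classification = x$classification,
                  rh_stable = x$rh_stable, stringsAsFactors = FALSE)
  for (i in 1:4) {
    d[[paste0("re_lambda", i)]] <- Re(ev[i])
    d[[paste0("im_lambda", i)]] <- Im(ev[i])
  }
  for (nm in names(x$rh$conditions)) d[[nm]] <- unname(x$rh$conditions[nm])
  d$A4_pos <- x$rh$a4_positive
  d
}

#' Full stability analysis of an equilibrium
#'
#' Combines the analytic Jacobian at the equilibrium with both stability
#' routes: eigenvalue classification and the Routh-Hurwitz criterion on the
#' characteristic polynomial. The two routes must agree outside the
#' non-hyperbolic tolerance; a disagreement indicates an internal
#' inconsistency and raises an error rather than returning a report.
#'
#' @param eq a `ward_equilibrium` (warns when its residual exceeds 1e-6:
#'   classifying a point that is not actually a fixed point is flagged, not
#'   hidden).
#' @inheritParams ward_rhs
#' @param zero_tol passed to [eigen_classify()].
#' @return A `stability_report` (with the equilibrium label attached as
#'   attribute `label`).
#' @examples
#' p <- ward_params()
#' analyze_equilibrium(equilibrium_resource_icu(p), p)   # saddle
#' @export
analyze_equilibrium <- function(eq, params, variant = eq$variant,
                                zero_tol = NULL) {
  stopifnot(inherits(eq, "ward_equilibrium"))
  p <- validate_params(params)
  check_variant(variant)
  res <- ward_residual(eq$state, p, variant)
  if (res >= 1e-6)
    warning(sprintf("point '%s' has residual %.3g under variant '%s'; %s",
                    eq$label, res, variant,
                    "classifying a non-equilibrium"), call. = FALSE)
  J <- ward_jacobian(eq$state, p, variant)
  rep <- eigen_classify(J, zero_tol = zero_tol)
  hyperbolic <- !any(abs(Re(rep$eigenvalues)) <= rep$zero_tol)
  if (hyperbolic) {
    eig_stable <- all(Re(rep$eigenvalues) < 0)
    if (xor(eig_stable, rep$rh_stable))
      stop("internal inconsistency: Routh-Hurwitz and eigenvalue verdicts ",
           "disagree at a hyperbolic point (label ", eq$label, ")",
           call. = FALSE)
  }
  attr(rep, "label") <- eq$label
  rep
}
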