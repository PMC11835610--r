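## internal: leading complex-conjugate pair of a spectrum (NA when none)
lead_complex_pair <- function(ev) {
  tol <- 1e-9 * (1 + max(Mod(ev)))
  cplx <- ev[abs(Im(ev)) > tol]
  if (!length(cplx)) return(c(re = NA_real_, im = NA_real_))
  lead <- cplx[which.max(Re(cplx))]
  c(re = Re(lead), im = abs(Im(lead)))
}

## internal: analysis row for one equilibrium
equilibrium_row <- function(eq, p, variant) {
  rep <- suppressWarnings(analyze_equilibrium(eq, p, variant))
  pair <- lead_complex_pair(rep$eigenvalues)
  data.frame(label = eq$label, E = eq$state[["E"]], C = eq$state[["C"]],
             G = eq$state[["G"]], I = eq$state[["I"]],
             residual = eq$residual_norm, feasible = eq$feasible,
             class = rep$classification,
             re_lambda_max = max(Re(rep$eigenvalues)),
             lead_pair_re = pair[["re"]], lead_pair_im = pair[["im"]],
             stringsAsFactors = FALSE)
}

#' One-parameter equilibrium sweep
#'
#' Tracks the equilibria of the model across a grid of values of a single
#' parameter. At each grid point the equilibria are located numerically
#' (warm-started from the previous point's roots -- continuation) and each
#' root is classified by [analyze_equilibrium()]. Branch identity is
#' maintained by nearest-neighbour matching between consecutive grid points
#' with matching radius `max(0.1 * ||state||, 1e-3)`; a branch with no root
#' within the radius is marked terminated and the sweep continues.
#'
#' @inheritParams ward_rhs
#' @param name parameter to sweep (a [ward_params()] field).
#' @param values numeric grid, non-empty and strictly increasing.
#' @return An object of class `ward_sweep`: list with `param`, `values`,
#'   `table` (long data frame: `param_value`, `branch_id`, `label`, state
#'   columns, `residual`, `feasible`, `class`, `re_lambda_max`,
#'   `lead_pair_re`, `lead_pair_im`), `params`, `variant`.
#' @examples
#' \donttest{
#' sw <- sweep_parameter(ward_params(), "zeta", c(0.1, 0.2, 0.3))
#' subset(sw$table, label == "E2")   # E2 is zeta-free
#' }
#' @export
sweep_parameter <- function(params, name, values, variant = "balanced") {
  p <- validate_params(params)
  check_variant(variant)
  if (!name %in% names(param_defaults()))
    stop("'", name, "' is not a model parameter", call. = FALSE)
  stopifnot(is.numeric(values), length(values) > 0)
  if (is.unsorted(values, strictly = TRUE))
    stop("values must be strictly increasing", call. = FALSE)

  branches <- list()   # per id: list(state, alive)
  next_id <- 1L
  rows <- list()
  for (v in values) {
    pv <- p; pv[[name]] <- v
    pv <- validate_params(unclass(pv))
    warm <- lapply(Filter(function(b) b$alive, branches), `[[`, "state")
    eqs <- find_equilibria(pv, variant, extra_starts = warm)
    states <- lapply(eqs, function(e) as.numeric(e$state))
    taken <- rep(FALSE, length(states))
    ## match alive branches to nearest root within the radius
    for (id in seq_along(branches)) {
      b <- branches[[id]]
      if (!b$alive) next
      radius <- max(0.1 * sqrt(sum(b$state^2)), 1e-3)
      d <- vapply(seq_along(states), function(k) {
        if (taken[k]) Inf else max(abs(states[[k]] - b$state))
      }, numeric(1))
      if (length(d) && min(d) <= radius) {
        k <- which.min(d)
        taken[k] <- TRUE
        branches[[id]]$state <- states[[k]]
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(param_value = v, branch_id = id),
          equilibrium_row(eqs[[k]], pv, variant))
      } else {
        branches[[id]]$alive <- FALSE
      }
    }
    ## unmatched roots spawn new branches
    for (k in which(!taken)) {
      id <- next_id; next_id <- next_id + 1L
      branches[[id]] <- list(state = states[[k]], alive = TRUE)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(param_value = v, branch_id = id),
        equilibrium_row(eqs[[k]], pv, variant))
    }
  }
  structure(list(param = name, values = values,
                 table = do.call(rbind, rows), params = p, variant = variant),
            class = "ward_sweep")
}

#' @export
print.ward_sweep <- function(x, ...) {
  cat(sprintf("<parameter sweep> %s over [%g, %g] (%d points, %d branches)\n",
              x$param, min(x$values), max(x$values), length(x$values),
              length(unique(x$table$branch_id))))
  invisible(x)
}

## internal: re-solve an equilibrium at a parameter value from a warm start
## and return its leading complex pair
branch_point_pair <- function(p, name, value, warm_state, variant) {
  pv <- p; pv[[name]] <- value
  pv <- validate_params(unclass(pv))
  s <- newton_full(warm_state, pv, variant)
  if (is.null(s)) return(NULL)
  ev <- eigen(ward_jacobian(s, pv, variant), only.values = TRUE)$values
  list(state = s, pair = lead_complex_pair(ev))
}

#' Detect Hopf crossings along a sweep
#'
#' Scans each branch of a [sweep_parameter()] result for sign changes of the
#' leading complex-conjugate eigenvalue pair's real part (with non-zero
#' imaginary part on both sides of the change) and refines each bracketed
#' crossing by bisection, re-solving the equilibrium from a warm start at
#' every midpoint, until `|Re(lambda)| < refine_tol`.
#'
#' A plain data frame with columns `param_value`, `branch_id`,
#' `lead_pair_re`, `lead_pair_im` is also accepted (e.g. a synthetic branch);
#' without model backing the crossing is located by linear interpolation.
#'
#' @param sweep a `ward_sweep` object, or a data frame as described above.
#' @param refine_tol bisection target on |Re(lambda)|.
#' @return Data frame with one row per crossing: `param_value`, `branch_id`,
#'   `frequency` (|Im(lambda)| at the crossing, radians per hour), `refined`
#'   (logical). Zero rows when no crossing exists.
#' @export
detect_hopf <- function(sweep, refine_tol = 1e-6) {
  tab <- if (inherits(sweep, "ward_sweep")) sweep$table else sweep
  stopifnot(is.data.frame(tab),
            all(c("param_value", "branch_id", "lead_pair_re",
                  "lead_pair_im") %in% names(tab)))
  model_backed <- inherits(sweep, "ward_sweep") &&
    all(c("E", "C", "G", "I") %in% names(tab))
  out <- list()
  for (id in unique(tab$branch_id)) {
    b <- tab[tab$branch_id == id, , drop = FALSE]
    b <- b[order(b$param_value), , drop = FALSE]
    re <- b$lead_pair_re; im <- b$lead_pair_im
    for (i in seq_len(nrow(b) - 1)) {
      pair_ok <- !is.na(re[i]) && !is.na(re[i + 1]) &&
        !is.na(im[i]) && !is.na(im[i + 1]) &&
        im[i] > refine_tol && im[i + 1] > refine_tol
      if (!pair_ok) next
      ## a grid point sitting exactly on the axis is itself the crossing
      if (abs(re[i]) < refine_tol) {
        if (i == 1 || is.na(re[i - 1]) || abs(re[i - 1]) >= refine_tol)
          out[[length(out) + 1L]] <- data.frame(
            param_value = b$param_value[i], branch_id = id,
            frequency = im[i], refined = TRUE)
        next
      }
      if (abs(re[i + 1]) < refine_tol) next  # handled at the next step
      if (sign(re[i]) * sign(re[i + 1]) > 0) next
      lo <- b$param_value[i]; hi <- b$param_value[i + 1]
      re_lo <- re[i]
      if (model_backed) {
        warm <- as.numeric(b[i, c("E", "C", "G", "I")])
        cross_re <- NA_real_; cross_im <- im[i]; refined <- FALSE
        for (it in 1:100) {
          mid <- (lo + hi) / 2
          bp <- branch_point_pair(sweep$params, sweep$param, mid, warm,
                                  sweep$variant)
          if (is.null(bp) || is.na(bp$pair[["re"]])) break
          warm <- bp$state
          cross_re <- bp$pair[["re"]]; cross_im <- bp$pair[["im"]]
          if (abs(cross_re) < refine_tol) { refined <- TRUE; break }
          if (sign(cross_re) == sign(re_lo)) { lo <- mid; re_lo <- cross_re }
          else hi <- mid
        }
        out[[length(out) + 1L]] <- data.frame(
          param_value = (lo + hi) / 2, branch_id = id,
          frequency = cross_im, refined = refined)
      } else {
        pv <- lo + (hi - lo) * re[i] / (re[i] - re[i + 1])
        frq <- im[i] + (im[i + 1] - im[i]) * (pv - lo) / (hi - lo)
        out[[length(out) + 1L]] <- data.frame(
          param_value = pv, branch_id = id, frequency = frq, refined = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(param_value = numeric(), branch_id = integer(),
                      frequency = numeric(), refined = logical()))
  do.call(rbind, out)
}

## internal: pick one equilibrium from a list according to a branch selector
select_branch <- function(eqs, selector) {
  labels <- vapply(eqs, `[[`, character(1), "label")
  pick_label <- function(l) { k <- which(labels == l); if (length(k)) k[1] else 0L }
  k <- switch(selector,
    coexistence = {
      k5 <- pick_label("E5")
      if (k5 == 0L) {
        k4 <- pick_label("E4")
        if (k4 > 0L && eqs[[k4]]$feasible) k4 else 0L
      } else k5
    },
    ward_free = pick_label("E4"),
    resource_icu = pick_label("E2"),
    trivial = pick_label("E1"),
    stop("unknown branch selector '", selector, "'", call. = FALSE))
  if (k == 0L) NULL else eqs[[k]]
}

#' Two-parameter stability heat map
#'
#' Evaluates the equilibria of the model on a rectangular grid of hospital
#' capacity `K` and ICU transfer modulation `zeta`, storing for each cell the
#' selected branch's state, its stability class, and its feasibility. Cells
#' are computed independently from cold starts, so the result does not
#' depend on evaluation order; a cell where the selected branch does not
#' exist (or the solver fails) is flagged missing and the grid completes.
#'
#' @inheritParams ward_rhs
#' @param K_values,zeta_values numeric grids (non-empty; `K_values > 0`).
#'   The published analysis scans capacities up to 1000 beds.
#' @param branch_selector which equilibrium branch to store per cell:
#'   `"coexistence"` (default; the strictly positive interior root, falling
#'   back to the feasible general-ward-free root), `"ward_free"`,
#'   `"resource_icu"`, or `"trivial"`.
#' @return An object of class `ward_heatmap`: list with `K_values`,
#'   `zeta_values`, `grid` (long data frame: `K`, `zeta`, `label`, state
#'   columns, `class`, `feasible`, `missing`), `params`, `variant`,
#'   `branch_selector`.
#' @export
stability_heatmap <- function(params, K_values, zeta_values,
                              variant = "balanced",
                              branch_selector = "coexistence") {
  p <- validate_params(params)
  check_variant(variant)
  stopifnot(is.numeric(K_values), length(K_values) > 0, all(K_values > 0),
            is.numeric(zeta_values), length(zeta_values) > 0,
            all(zeta_values >= 0))
  rows <- list()
  for (K in K_values) for (z in zeta_values) {
    pv <- p; pv$K <- K; pv$zeta <- z
    pv <- validate_params(unclass(pv))
    cell <- tryCatch({
      eqs <- find_equilibria(pv, variant)
      eq <- select_branch(eqs, branch_selector)
      if (is.null(eq)) NULL else {
        rep <- suppressWarnings(analyze_equilibrium(eq, pv, variant))
        data.frame(K = K, zeta = z, label = eq$label,
                   E = eq$state[["E"]], C = eq$state[["C"]],
                   G = eq$state[["G"]], I = eq$state[["I"]],
                   class = rep$classification, feasible = eq$feasible,
                   missing = FALSE, stringsAsFactors = FALSE)
      }
    }, error = function(e) NULL)
    if (is.null(cell))
      cell <- data.frame(K = K, zeta = z, label = NA_character_,
                         E = NA_real_, C = NA_real_, G = NA_real_,
                         I = NA_real_, class = NA_character_,
                         feasible = NA, missing = TRUE,
                         stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- cell
  }
  grid <- do.call(rbind, rows)
  structure(list(K_values = K_values, zeta_values = zeta_values,
                 grid = grid, params = p, variant = variant,
                 branch_selector = branch_selector),
            class = "ward_heatmap")
}

#' @export
print.ward_heatmap <- function(x, ...) {
  cat(sprintf(
    "<stability heat map> %d x %d cells (K x zeta), branch '%s', %d missing\n",
    length(x$K_values), length(x$zeta_values), x$branch_selector,
    sum(x$grid$missing)))
  invisible(x)
}
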