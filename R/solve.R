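# Inner optimization: flux balance analysis (LP) and the confidence-weighted
# uniform-flux-distribution program (convex QP), both solved with the
# Goldfarb-Idnani dual active-set method from quadprog.
#
# The LP is solved as a Tikhonov-regularized QP: for a small enough ridge the
# regularized minimizer is exactly the least-norm LP solution, so the optimal
# objective value is exact, not approximate. Because the active-set method is
# sensitive to the heavy degeneracy of LPs, a deterministic ladder of ridge
# values is tried and two independent successes must agree before a value is
# accepted. The LP runs in net-flux space (half the variables, far fewer
# degenerate vertices); the QP runs in split forward/backward space where the
# penalty is defined.

RIDGE_LADDER <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3)

# min x' diag(w) x - d'x  s.t.  Aeq x = beq, Ain x >= bin, lo <= x <= hi
# Returns list(x, status) with status "optimal" or "infeasible".
qp_box <- function(w, d, Aeq, beq, lo, hi, Ain = NULL, bin = NULL) {
  n <- length(lo)
  fixed <- which(hi - lo < 1e-12)
  free <- setdiff(seq_len(n), fixed)
  xf <- lo[fixed]
  if (length(fixed) && any(abs(hi[fixed] - lo[fixed]) > 0)) {
    xf <- (lo[fixed] + hi[fixed]) / 2
  }
  adj <- function(b, A) {
    if (length(fixed) == 0L || is.null(A)) return(b)
    as.numeric(b - A[, fixed, drop = FALSE] %*% xf)
  }
  beq2 <- adj(beq, Aeq)
  bin2 <- if (!is.null(Ain)) adj(bin, Ain) else NULL
  if (length(free) == 0L) {
    ok <- max(abs(beq2)) <= 1e-9 && (is.null(bin2) || all(bin2 <= 1e-9))
    x <- numeric(n); x[fixed] <- xf
    return(list(x = x, status = if (ok) "optimal" else "infeasible"))
  }
  Aeq2 <- as.matrix(Aeq[, free, drop = FALSE])
  qrA <- qr(t(Aeq2))
  keep <- sort(qrA$pivot[seq_len(qrA$rank)])
  # consistency of the dropped (dependent) rows is re-checked on the solution
  bndA <- rbind(diag(length(free)), -diag(length(free)))
  bndb <- c(lo[free], -hi[free])
  finite <- is.finite(bndb)
  Amat <- t(rbind(Aeq2[keep, , drop = FALSE],
                  if (!is.null(Ain)) as.matrix(Ain[, free, drop = FALSE]),
                  bndA[finite, , drop = FALSE]))
  bvec <- c(beq2[keep], bin2, bndb[finite])
  # scale variables so the feasible box is O(1): the active-set method is
  # far more reliable when bound magnitudes do not dwarf the ridge
  scale <- max(1, abs(bvec[is.finite(bvec)]))
  sol <- tryCatch(
    quadprog::solve.QP(diag(2 * w[free], nrow = length(free)), d[free],
                       Amat, bvec / scale, meq = length(keep)),
    error = function(e) e
  )
  if (inherits(sol, "error")) {
    return(list(x = rep(NA_real_, n),
                status = if (grepl("inconsisten", conditionMessage(sol)))
                  "infeasible" else "solver_error"))
  }
  x <- numeric(n)
  x[fixed] <- xf
  x[free] <- sol$solution * scale
  resid <- max(abs(as.numeric(Aeq %*% x - beq)))
  if (resid > 1e-7) return(list(x = x, status = "solver_error"))
  list(x = x, status = "optimal")
}

# Distinguish genuine infeasibility from active-set failure: minimize the
# squared constraint violation over the box with L-BFGS-B.
box_feasible <- function(Aeq, beq, lo, hi, Ain = NULL, bin = NULL) {
  lo2 <- pmax(lo, -1e6); hi2 <- pmin(hi, 1e6)
  if (any(lo2 > hi2)) return(FALSE)
  x0 <- pmin(pmax(0, lo2), hi2)  # projection of the origin onto the box
  Aeq <- as.matrix(Aeq)
  fn <- function(x) {
    r <- as.numeric(Aeq %*% x - beq)
    v <- if (!is.null(Ain)) pmax(bin - as.numeric(Ain %*% x), 0) else 0
    sum(r^2) + sum(v^2)
  }
  gr <- function(x) {
    r <- as.numeric(Aeq %*% x - beq)
    g <- 2 * as.numeric(crossprod(Aeq, r))
    if (!is.null(Ain)) {
      v <- pmax(bin - as.numeric(Ain %*% x), 0)
      g <- g - 2 * as.numeric(crossprod(as.matrix(Ain), v))
    }
    g
  }
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B", lower = lo2, upper = hi2,
                      control = list(maxit = 2000, factr = 10))
  opt$value < 1e-10 * max(1, fn(x0))
}

# Maximize c'v over { S v = 0, lo <= v <= hi } in net-flux space.
solve_lp_net <- function(S, lo, hi, cvec) {
  beq <- rep(0, nrow(S))
  vals <- c()
  xs <- list()
  n_inf <- 0L
  for (rho in RIDGE_LADDER) {
    r <- qp_box(rep(rho, length(lo)), cvec, S, beq, lo, hi)
    if (r$status == "optimal") {
      if (max(abs(r$x)) > 1e7) {
        abort("FBA objective appears unbounded; check exchange caps",
              class = "actd_model_error")
      }
      obj <- sum(cvec * r$x)
      vals <- c(vals, obj)
      xs <- c(xs, list(r$x))
      agree <- which(abs(vals - obj) <= 1e-7 * max(1, abs(obj)))
      if (length(agree) >= 2L) {
        return(list(x = xs[[agree[[1]]]], objective = vals[[agree[[1]]]],
                    status = "optimal"))
      }
    } else if (r$status == "infeasible") {
      n_inf <- n_inf + 1L
    }
  }
  if (length(vals) >= 1L) {
    # a single clean success (others degenerate-failed): accept it
    return(list(x = xs[[1]], objective = vals[[1]], status = "optimal"))
  }
  if (n_inf > 0L && !box_feasible(S, beq, lo, hi)) {
    return(list(x = NULL, objective = NA_real_, status = "infeasible"))
  }
  abort("LP solver failed on a feasible problem across the full ridge ladder",
        class = "actd_solver_error")
}

#' Construct a flux state
#'
#' Internal assembler used by the solvers: checks steady state and bounds,
#' records the biomass and ATP net fluxes and the compartment-pooled
#' metabolite flow rates.
#'
#' @param split A [split_reversible()] model (possibly with regulated bounds).
#' @param vf,vb Nonnegative flux vectors named by reaction id.
#' @param status `"optimal"` or `"infeasible"`.
#' @param objective_value Optimum of the stage that produced the state.
#' @return Object of class `actd_flux`.
#' @export
flux_state <- function(split, vf, vb, status = "optimal",
                       objective_value = NA_real_) {
  model <- split$base
  if (status != "optimal") {
    zero <- setNames(rep(0, nrow(model$reactions)), model$reactions$id)
    return(structure(
      list(vf = zero, vb = zero, v_biomass = 0, v_atp = 0,
           flow_rates = setNames(rep(0, length(unique(model$metabolites$base_id))),
                                 sort(unique(model$metabolites$base_id))),
           status = status, objective_value = NA_real_),
      class = "actd_flux"
    ))
  }
  vf <- pmax(vf, 0); vb <- pmax(vb, 0)
  v <- vf - vb
  resid <- max(abs(as.numeric(model$stoich %*% v)))
  if (resid > 1e-8) {
    abort(sprintf("flux state violates steady state (residual %.2e)", resid),
          class = "actd_solver_error")
  }
  st <- structure(
    list(vf = vf, vb = vb,
         v_biomass = unname(v[model$biomass_rxn_id]),
         v_atp = unname(v[model$atp_rxn_id]),
         flow_rates = NULL, status = status,
         objective_value = objective_value),
    class = "actd_flux"
  )
  st$flow_rates <- flow_rates(st, model)
  st
}

#' @export
print.actd_flux <- function(x, ...) {
  cat("<actd_flux> status: ", x$status,
      sprintf("  v_biomass: %.4g  v_atp: %.4g\n", x$v_biomass, x$v_atp), sep = "")
  invisible(x)
}

#' Tidy a flux state into a per-reaction tibble
#' @param x An `actd_flux` object.
#' @param ... Unused.
#' @return Tibble with `id`, `vf`, `vb`, `net`.
#' @export
tidy.actd_flux <- function(x, ...) {
  tibble(id = names(x$vf), vf = unname(x$vf), vb = unname(x$vb),
         net = unname(x$vf - x$vb))
}

#' Flux balance analysis on a (possibly regulated) split model
#'
#' Maximizes the biomass or ATP net flux subject to steady state and the
#' split-model bounds. Infeasibility is a valid outcome (a lethal or
#' conflicting perturbation) and is reported in the state's `status`.
#'
#' @param split A [split_reversible()] model.
#' @param objective `"biomass"` or `"atp"`.
#' @return An [flux_state()] with `objective_value` set to the LP optimum.
#' @export
solve_fba <- function(split, objective = c("biomass", "atp")) {
  objective <- match.arg(objective)
  model <- split$base
  nb <- net_bounds(split)
  obj_id <- if (objective == "biomass") model$biomass_rxn_id else model$atp_rxn_id
  cvec <- as.numeric(nb$id == obj_id)
  r <- solve_lp_net(model$stoich, nb$lb, nb$ub, cvec)
  if (r$status != "optimal") {
    return(flux_state(split, NULL, NULL, status = r$status))
  }
  v <- setNames(r$x, nb$id)
  vb <- pmax(split$vb_lb, pmax(-v, 0))
  vf <- v + vb
  flux_state(split, vf, vb, "optimal", objective_value = r$objective)
}

#' Uniform flux distribution: confidence-weighted quadratic program
#'
#' Minimizes `sum_k c_k (v_f,k^2 + v_b,k^2)` over internal reactions subject
#' to steady state, the split bounds, and an objective floor (the FBA optimum
#' of the same bounded model). Exchange reactions carry no penalty beyond a
#' negligible ridge that keeps the program strictly convex.
#'
#' @param split A [split_reversible()] model.
#' @param weights Named vector reaction id -> confidence weight `c_k` (from
#'   [weight_reactions()] / [build_gpr_model()]); missing ids default to 1.
#' @param floor List `list(objective = "biomass"|"atp", value = <num>)`, or
#'   `NULL` for an unfloored minimum-flux state.
#' @param ridge Strict-convexity ridge for unpenalized variables.
#' @return An [flux_state()]; `objective_value` is the quadratic optimum.
#' @export
solve_ufd <- function(split, weights = NULL, floor = NULL, ridge = 1e-9) {
  model <- split$base
  ids <- model$reactions$id
  n <- length(ids)
  w <- setNames(rep(1, n), ids)
  if (!is.null(weights)) w[names(weights)] <- weights
  w[!ids %in% split$internal] <- 0
  wx <- pmax(c(w, w), ridge)
  S <- model$stoich
  Aeq <- cbind(S, -S)
  lo <- c(split$vf_lb, split$vb_lb)
  hi <- c(split$vf_ub, split$vb_ub)
  Ain <- NULL; bin <- NULL
  if (!is.null(floor)) {
    obj_id <- if (floor$objective == "biomass") model$biomass_rxn_id else model$atp_rxn_id
    row <- numeric(2 * n)
    row[match(obj_id, ids)] <- 1
    row[n + match(obj_id, ids)] <- -1
    Ain <- matrix(row, nrow = 1)
    bin <- floor$value - (1e-9 + 1e-10 * abs(floor$value))
  }
  r <- qp_box(wx, rep(0, 2 * n), Aeq, rep(0, nrow(S)), lo, hi, Ain, bin)
  if (r$status == "solver_error") {
    if (!box_feasible(Aeq, rep(0, nrow(S)), lo, hi, Ain, bin)) {
      r$status <- "infeasible"
    } else {
      abort("UFD quadratic program failed on a feasible problem",
            class = "actd_solver_error")
    }
  }
  if (r$status != "optimal") {
    return(flux_state(split, NULL, NULL, status = "infeasible"))
  }
  vf <- setNames(r$x[seq_len(n)], ids)
  vb <- setNames(r$x[n + seq_len(n)], ids)
  obj <- sum(w * (vf^2 + vb^2))
  flux_state(split, vf, vb, "optimal", objective_value = obj)
}

#' Basal template of an unperturbed model
#'
#' Runs the unregulated FBA (biomass for the cancer model, ATP for the
#' healthy model), floors the objective at its optimum, and extracts the
#' uniform-flux-distribution state. The template supplies basal fluxes for
#' regulation bounds, standard levels for the two-sided memberships, and the
#' objective floors; both FBA optima (max biomass and max ATP) are recorded
#' because they bound the mortality/viability membership ramps.
#'
#' @param model A [metnet_model()].
#' @param gpr Optional [build_gpr_model()] supplying confidence weights.
#' @param objective `"biomass"` (cancer template) or `"atp"` (healthy).
#' @param fraction Floor fraction of the FBA optimum (1 keeps the exact
#'   optimum).
#' @return Object of class `actd_template`.
#' @export
compute_template <- function(model, gpr = NULL,
                             objective = c("biomass", "atp"), fraction = 1) {
  objective <- match.arg(objective)
  split <- split_reversible(model)
  weights <- if (!is.null(gpr)) gpr$weights else NULL
  fba_main <- solve_fba(split, objective)
  other <- if (objective == "biomass") "atp" else "biomass"
  fba_other <- solve_fba(split, other)
  if (fba_main$status != "optimal" || fba_other$status != "optimal") {
    abort("unperturbed model is infeasible; fix bounds before computing templates",
          class = "actd_config_error")
  }
  opt <- fba_main$objective_value
  state <- solve_ufd(split, weights,
                     floor = list(objective = objective, value = fraction * opt))
  if (state$status != "optimal") {
    abort("template UFD stage failed at the FBA floor", class = "actd_config_error")
  }
  structure(
    list(objective = objective, split = split, state = state,
         opt_value = opt, floor = fraction * opt,
         biomass_max = if (objective == "biomass") opt else fba_other$objective_value,
         atp_max = if (objective == "atp") opt else fba_other$objective_value,
         weights = weights),
    class = "actd_template"
  )
}

#' @export
print.actd_template <- function(x, ...) {
  cat("<actd_template> objective: ", x$objective,
      sprintf("  biomass_max: %.4g  atp_max: %.4g\n", x$biomass_max, x$atp_max),
      sep = "")
  invisible(x)
}

#' @export
tidy.actd_template <- function(x, ...) tidy(x$state)

#' One-line template summary
#' @param x An `actd_template`.
#' @param ... Unused.
#' @return One-row tibble with the objective, its optimum, both FBA maxima and
#'   the template's realized biomass/ATP fluxes.
#' @export
glance.actd_template <- function(x, ...) {
  tibble(objective = x$objective, opt_value = x$opt_value,
         biomass_max = x$biomass_max, atp_max = x$atp_max,
         v_biomass = x$state$v_biomass, v_atp = x$state$v_atp)
}
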