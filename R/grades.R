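# Fuzzy membership grades and their aggregation.
#
# Linear one-sided memberships score minimization ("flux near zero") and
# maximization ("flux near its ceiling") goals; a two-sided membership scores
# closeness to a standard level taken from a template, and its complement is
# the dissimilarity grade. Grade vectors are pooled by the mean-min operator
# (mean + min)/2, which discriminates grade vectors with identical means. The
# hierarchical decision objective puts the cancer-cell mortality grade first
# and the worst of {mortality, viability, metabolic deviation} second.

#' One-sided minimization membership
#'
#' 1 at or below `lb`, 0 at or above `ub`, linear in between:
#' `(ub - fv) / (ub - lb)`.
#'
#' @param fv Flux value(s).
#' @param lb,ub Ramp bounds, `lb < ub` (equal bounds degrade to a step at the
#'   shared point).
#' @return Grade(s) in `[0, 1]`.
#' @export
grade_min <- function(fv, lb, ub) {
  check_ramp(lb, ub)
  if (any(ub == lb)) {
    g <- ifelse(fv <= lb, 1, 0)
    ok <- ub > lb
    g[ok] <- pmin(1, pmax(0, (ub[ok] - fv[ok]) / (ub[ok] - lb[ok])))
    return(g)
  }
  pmin(1, pmax(0, (ub - fv) / (ub - lb)))
}

#' One-sided maximization membership
#'
#' Mirror of [grade_min()]: 0 at or below `lb`, 1 at or above `ub`; the two
#' grades are complementary on `[lb, ub]`.
#'
#' @inheritParams grade_min
#' @return Grade(s) in `[0, 1]`.
#' @export
grade_max <- function(fv, lb, ub) {
  check_ramp(lb, ub)
  if (any(ub == lb)) {
    g <- ifelse(fv >= ub, 1, 0)
    ok <- ub > lb
    g[ok] <- pmin(1, pmax(0, (fv[ok] - lb[ok]) / (ub[ok] - lb[ok])))
    return(g)
  }
  pmin(1, pmax(0, (fv - lb) / (ub - lb)))
}

check_ramp <- function(lb, ub) {
  if (any(lb > ub)) {
    abort("membership spec requires lb <= ub", class = "actd_spec_error")
  }
}

#' Two-sided similarity membership around a standard level
#'
#' 1 at `pb == st`, ramping linearly to 0 at `lb` (left) and `ub` (right),
#' clamped to `[0, 1]` outside; the dissimilarity grade is its complement.
#' Degenerate ramps (`lb == st` or `st == ub`) become steps.
#'
#' @param pb Perturbed value(s).
#' @param lb,ub Outer ramp bounds.
#' @param st Standard level, `lb <= st <= ub` (typically a template value).
#' @return Grade(s) in `[0, 1]`.
#' @export
grade_two_sided <- function(pb, lb, st, ub) {
  if (any(st < lb | st > ub)) {
    abort("two-sided spec requires lb <= st <= ub", class = "actd_spec_error")
  }
  left <- ifelse(st > lb, (pb - lb) / (st - lb), ifelse(pb >= st, 1, 0))
  right <- ifelse(ub > st, (ub - pb) / (ub - st), ifelse(pb <= st, 1, 0))
  pmax(pmin(pmin(left, right), 1), 0)
}

#' Mean-min aggregation of membership grades
#'
#' `(mean(g) + min(g)) / 2`. Unlike the plain mean it separates grade vectors
#' with equal means but different spreads; it equals the mean exactly when
#' all grades are equal.
#'
#' @param grades Numeric vector of grades in `[0, 1]`.
#' @return Scalar grade in `[0, 1]`.
#' @export
mean_min <- function(grades) {
  if (length(grades) == 0L || anyNA(grades)) {
    abort("mean_min needs at least one non-missing grade",
          class = "actd_domain_error")
  }
  (mean(grades) + min(grades)) / 2
}

#' Compartment-pooled metabolite flow rates
#'
#' For each metabolite instance, production is the sum of positive
#' stoichiometric coefficients times forward fluxes minus the sum of negative
#' coefficients times backward fluxes (reverse-direction flux through a
#' consumer produces the metabolite, so the negative coefficient contributes
#' `|N| * v_b`). Instances of the same base metabolite in different
#' compartments are summed.
#'
#' @param state An [flux_state()].
#' @param model The [metnet_model()] the state was solved on.
#' @return Named numeric vector base-metabolite -> flow rate (nonnegative).
#' @export
flow_rates <- function(state, model) {
  S <- model$stoich
  vf <- state$vf[colnames(S)]
  vb <- state$vb[colnames(S)]
  per_instance <- as.numeric(pmax(S, 0) %*% vf) - as.numeric(pmin(S, 0) %*% vb)
  pooled <- tapply(per_instance, model$metabolites$base_id, sum)
  setNames(as.numeric(pooled), names(pooled))[sort(unique(model$metabolites$base_id))]
}

#' Default two-sided membership specs for a template vector
#'
#' Standard level = template value; ramp half-width
#' `w = max(alpha * |st|, w_min)` with `w_min` a fraction of the median
#' nonzero template magnitude, so the ramps stay scale-aware and never
#' degenerate. The left bound is clamped at zero for quantities that cannot
#' go negative.
#'
#' @param st Numeric vector of standard levels (template values).
#' @param nonneg Logical (recycled): clamp `lb` at 0.
#' @param alpha Relative half-width (default 1).
#' @param w_min_frac Minimum half-width as a fraction of the median nonzero
#'   `|st|` (default 0.1).
#' @return Tibble with `st`, `lb`, `ub`.
#' @export
two_sided_specs <- function(st, nonneg = TRUE, alpha = 1, w_min_frac = 0.1) {
  nz <- abs(st)[abs(st) > 1e-9]
  w_min <- if (length(nz)) w_min_frac * median(nz) else w_min_frac
  w <- pmax(alpha * abs(st), w_min)
  lb <- st - w
  lb[rep_len(nonneg, length(st)) & lb < 0] <- 0
  tibble(st = st, lb = pmin(lb, st), ub = st + w)
}

#' Cancer-cell mortality grade
#'
#' Minimization memberships of the treated cancer state's biomass and ATP
#' fluxes (ramps from 0 up to the unperturbed FBA maxima), pooled by
#' [mean_min()]. An infeasible treated state counts as a complete kill (both
#' fluxes 0, grade 1).
#'
#' @param state Treated cancer [flux_state()].
#' @param template Cancer [compute_template()].
#' @return List with `eta_biomass`, `eta_atp`, `eta_tr`.
#' @export
mortality_grade <- function(state, template) {
  eb <- grade_min(state$v_biomass, 0, template$biomass_max)
  ea <- grade_min(state$v_atp, 0, template$atp_max)
  list(eta_biomass = eb, eta_atp = ea, eta_tr = mean_min(c(eb, ea)))
}

#' Healthy-cell viability grade
#'
#' The healthy cell should not proliferate but must keep producing ATP:
#' minimization membership on the perturbed biomass flux and maximization
#' membership on the perturbed ATP flux (ceiling = unperturbed ATP maximum),
#' pooled by [mean_min()]. An infeasible perturbed state scores ATP 0.
#'
#' @param state Perturbed healthy [flux_state()].
#' @param template Healthy [compute_template()].
#' @return List with `eta_biomass`, `eta_atp`, `eta_cv`.
#' @export
viability_grade <- function(state, template) {
  eb <- grade_min(state$v_biomass, 0, template$biomass_max)
  ea <- grade_max(state$v_atp, 0, template$atp_max)
  list(eta_biomass = eb, eta_atp = ea, eta_cv = mean_min(c(eb, ea)))
}

#' Metabolic deviation grade of the perturbed healthy state
#'
#' Compares the perturbed healthy flux pattern with both templates over a
#' shared comparison universe: internal reactions present in both models
#' (net fluxes) and base metabolites present in both models (flow rates),
#' keeping only elements whose template value is nonzero in at least one
#' template. Similarity to the healthy template uses the two-sided
#' membership with the healthy standard level; dissimilarity from the cancer
#' template is the complement of the two-sided membership with the cancer
#' standard level. The four per-class means are pooled by [mean_min()].
#'
#' @param state Perturbed healthy [flux_state()].
#' @param ca_template,ht_template Templates from [compute_template()].
#' @param alpha,w_min_frac Ramp parameters, see [two_sided_specs()].
#' @return List with `eta_f_ca`, `eta_m_ca`, `eta_f_bl`, `eta_m_bl`,
#'   `eta_md`.
#' @export
deviation_grade <- function(state, ca_template, ht_template,
                            alpha = 1, w_min_frac = 0.1) {
  ca_model <- ca_template$split$base
  ht_model <- ht_template$split$base
  rxns <- intersect(intersect(ca_template$split$internal, ht_template$split$internal),
                    names(state$vf))
  ca_v <- (ca_template$state$vf - ca_template$state$vb)[rxns]
  ht_v <- (ht_template$state$vf - ht_template$state$vb)[rxns]
  keep <- abs(ca_v) > 1e-9 | abs(ht_v) > 1e-9
  rxns <- rxns[keep]
  mets <- intersect(names(ca_template$state$flow_rates),
                    names(ht_template$state$flow_rates))
  ca_r <- ca_template$state$flow_rates[mets]
  ht_r <- ht_template$state$flow_rates[mets]
  keep_m <- abs(ca_r) > 1e-9 | abs(ht_r) > 1e-9
  mets <- mets[keep_m]
  if (length(rxns) == 0L && length(mets) == 0L) {
    abort("empty comparison universe between the two models",
          class = "actd_domain_error")
  }
  pb_v <- (state$vf - state$vb)[rxns]
  pb_r <- state$flow_rates[mets]
  rev_rxns <- !ca_model$reactions$reversible[match(rxns, ca_model$reactions$id)] &
    !ht_model$reactions$reversible[match(rxns, ht_model$reactions$id)]
  sim_vs <- function(pb, st, nonneg) {
    spec <- two_sided_specs(st, nonneg = nonneg, alpha = alpha,
                            w_min_frac = w_min_frac)
    grade_two_sided(pb, spec$lb, spec$st, spec$ub)
  }
  mean_or_1 <- function(g) if (length(g)) mean(g) else 1
  eta_f_bl <- mean_or_1(sim_vs(pb_v, ht_v[rxns], rev_rxns))
  eta_m_bl <- mean_or_1(sim_vs(pb_r, ht_r[mets], TRUE))
  eta_f_ca <- mean_or_1(1 - sim_vs(pb_v, ca_v[rxns], rev_rxns))
  eta_m_ca <- mean_or_1(1 - sim_vs(pb_r, ca_r[mets], TRUE))
  list(eta_f_ca = eta_f_ca, eta_m_ca = eta_m_ca,
       eta_f_bl = eta_f_bl, eta_m_bl = eta_m_bl,
       eta_md = mean_min(c(eta_f_ca, eta_m_ca, eta_f_bl, eta_m_bl)))
}

#' Hierarchical decision objective
#'
#' `(eta_tr + min(eta_tr, eta_cv, eta_md)) / 2`: cancer-cell mortality is the
#' first priority; the worst of the three grades is the second. Always
#' bounded above by `eta_tr`.
#'
#' @param eta_tr,eta_cv,eta_md Grades in `[0, 1]`.
#' @return Scalar decision grade.
#' @export
decision_grade <- function(eta_tr, eta_cv, eta_md) {
  (eta_tr + pmin(eta_tr, pmin(eta_cv, eta_md))) / 2
}
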