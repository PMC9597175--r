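# Evaluation context: pairs the cancer (CA) and healthy (HT) models with
# their GPR models and basal templates, and turns one candidate intervention
# into the full grade set by solving the treated-CA and perturbed-HT inner
# problems.

#' Build an evaluation context for a cancer/healthy model pair
#'
#' Precomputes everything a candidate evaluation needs: parsed GPR models
#' (with expression-derived confidence weights when expression tables are
#' given), the split models, and the basal templates (biomass-maximizing for
#' the cancer model, ATP-maximizing for the healthy model).
#'
#' @param ca,ht [metnet_model()] objects for the cancer and healthy cell.
#' @param ca_expr,ht_expr Optional expression tibbles (`gene`, `mean`) for
#'   [classify_genes()]; without them, reaction confidence classes stored in
#'   the models drive the weights.
#' @param epsilon Isozyme flux ratio for buffered reactions (default 0.03).
#' @param floor_fraction Objective floor as a fraction of the FBA optimum in
#'   the inner problems (default 1: the exact optimum).
#' @param alpha,w_min_frac Two-sided membership ramp parameters, see
#'   [two_sided_specs()].
#' @return Object of class `actd_context`.
#' @export
actd_context <- function(ca, ht, ca_expr = NULL, ht_expr = NULL,
                         epsilon = 0.03, floor_fraction = 1,
                         alpha = 1, w_min_frac = 0.1) {
  ca_gpr <- build_gpr_model(ca, ca_expr)
  ht_gpr <- build_gpr_model(ht, ht_expr)
  structure(
    list(
      ca = ca, ht = ht, ca_gpr = ca_gpr, ht_gpr = ht_gpr,
      ca_split = split_reversible(ca), ht_split = split_reversible(ht),
      ca_template = compute_template(ca, ca_gpr, "biomass"),
      ht_template = compute_template(ht, ht_gpr, "atp"),
      epsilon = epsilon, floor_fraction = floor_fraction,
      alpha = alpha, w_min_frac = w_min_frac
    ),
    class = "actd_context"
  )
}

#' @export
print.actd_context <- function(x, ...) {
  cat("<actd_context>\n  CA: ", nrow(x$ca$reactions), " reactions, ",
      nrow(x$ca_gpr$feasible), " feasible enzymes\n  HT: ",
      nrow(x$ht$reactions), " reactions, ", nrow(x$ht_gpr$feasible),
      " feasible enzymes\n", sep = "")
  invisible(x)
}

# Regulate one model's split according to centric mode; targets absent from
# the model are silently inert (a no-op perturbation there).
regulate_model <- function(ctx, which = c("ca", "ht"), targets,
                           centric = c("gene", "metabolite")) {
  which <- match.arg(which)
  centric <- match.arg(centric)
  split <- ctx[[paste0(which, "_split")]]
  gpr <- ctx[[paste0(which, "_gpr")]]
  template <- ctx[[paste0(which, "_template")]]
  if (centric == "gene") {
    present <- targets[targets$target %in% gpr$feasible$enzyme, ]
    apply_gene_regulation(split, gpr, template, present, epsilon = ctx$epsilon)
  } else {
    present <- targets[targets$target %in% split$base$metabolites$id, ]
    apply_metabolite_regulation(split, template, present)
  }
}

inner_pipeline <- function(ctx, which, regulated) {
  template <- ctx[[paste0(which, "_template")]]
  objective <- if (which == "ca") "biomass" else "atp"
  if (scheme_conflicted(regulated)) {
    return(list(state = flux_state(regulated, NULL, NULL, "infeasible"),
                feasible = FALSE))
  }
  fba <- solve_fba(regulated, objective)
  if (fba$status != "optimal") {
    return(list(state = flux_state(regulated, NULL, NULL, "infeasible"),
                feasible = FALSE))
  }
  weights <- ctx[[paste0(which, "_gpr")]]$weights
  ufd <- solve_ufd(regulated, weights,
                   floor = list(objective = objective,
                                value = ctx$floor_fraction * fba$objective_value))
  if (ufd$status != "optimal") {
    return(list(state = flux_state(regulated, NULL, NULL, "infeasible"),
                feasible = FALSE))
  }
  list(state = ufd, feasible = TRUE)
}

#' Evaluate one candidate intervention
#'
#' Applies the targets to both models, solves the treated-CA (FBA then UFD
#' with the biomass floor) and perturbed-HT (FBA then UFD with the ATP floor)
#' inner problems, and assembles all membership grades. Conflicting or
#' infeasible perturbations are mapped to the all-zero flux pattern
#' (mortality reading) with the status recorded, so the outer search can rank
#' lethal candidates.
#'
#' @param ctx An [actd_context()].
#' @param targets A [regulation_targets()] tibble.
#' @param centric `"gene"` (targets are feasible-enzyme ids) or
#'   `"metabolite"` (compartmented metabolite ids).
#' @return One-row tibble: target descriptor columns, all grades
#'   (`eta_biomass_tr` ... `eta_d`), inner statuses and the flux states as
#'   list-columns.
#' @export
evaluate_targets <- function(ctx, targets, centric = c("gene", "metabolite")) {
  centric <- match.arg(centric)
  ca_reg <- regulate_model(ctx, "ca", targets, centric)
  ht_reg <- regulate_model(ctx, "ht", targets, centric)
  ca <- inner_pipeline(ctx, "ca", ca_reg)
  ht <- inner_pipeline(ctx, "ht", ht_reg)
  tr <- mortality_grade(ca$state, ctx$ca_template)
  cv <- viability_grade(ht$state, ctx$ht_template)
  md <- deviation_grade(ht$state, ctx$ca_template, ctx$ht_template,
                        alpha = ctx$alpha, w_min_frac = ctx$w_min_frac)
  tibble(
    target = paste(targets$target, collapse = " + "),
    mode = paste(targets$mode, collapse = " + "),
    delta = paste(signif(targets$delta, 4), collapse = " + "),
    centric = centric,
    eta_biomass_tr = tr$eta_biomass, eta_atp_tr = tr$eta_atp,
    eta_tr = tr$eta_tr,
    eta_biomass_pb = cv$eta_biomass, eta_atp_pb = cv$eta_atp,
    eta_cv = cv$eta_cv,
    eta_f_ca = md$eta_f_ca, eta_m_ca = md$eta_m_ca,
    eta_f_bl = md$eta_f_bl, eta_m_bl = md$eta_m_bl,
    eta_md = md$eta_md,
    eta_d = decision_grade(tr$eta_tr, cv$eta_cv, md$eta_md),
    ca_status = ca$state$status, ht_status = ht$state$status,
    feasible = ca$feasible || ht$feasible,
    ca_state = list(ca$state), ht_state = list(ht$state)
  )
}
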