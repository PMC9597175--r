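# Target regulation: translating a chosen intervention (enzyme knockout /
# up- / down-modulation, or antimetabolite inhibition of a metabolite's
# synthesis) into forward/backward flux-bound intervals on the split model.
#
# delta in [0,1] interpolates between the basal template flux (delta = 0) and
# the hard bound (delta = 1). Reactions still covered by another isozyme after
# the target is removed are not silenced: their flux is pinned to within
# +/- epsilon of basal (default epsilon = 0.03). Conflicting intervals (for
# example a knockout on a reaction with a forced minimum flux, or overlapping
# targets with incompatible windows) mark the scheme infeasible rather than
# raising: the outer search must be able to rank lethal or incoherent
# candidates.

#' Build a regulation target table
#'
#' @param target Character vector of target ids (feasible-enzyme ids for
#'   gene-centric regulation, compartmented metabolite ids such as
#'   `"orot[c]"` for metabolite-centric regulation).
#' @param mode `"knockout"`, `"down"` or `"up"` (recycled).
#' @param delta Modulation strength in `[0, 1]` (recycled; ignored for
#'   knockouts).
#' @return Tibble with columns `target`, `mode`, `delta`.
#' @export
regulation_targets <- function(target, mode = "knockout", delta = 1) {
  mode <- match.arg(mode, c("knockout", "down", "up"), several.ok = TRUE)
  out <- tibble(target = target,
                mode = rep_len(mode, length(target)),
                delta = rep_len(delta, length(target)))
  if (any(out$delta < 0 | out$delta > 1)) {
    abort("delta must lie in [0, 1]", class = "actd_domain_error")
  }
  out
}

# Intersect an induced interval with the current bounds of one direction.
# Returns the updated (lo, hi) or marks a conflict.
tighten <- function(bnd, rxn, dir, lo, hi) {
  cur_lo <- bnd[[paste0(dir, "_lb")]][[rxn]]
  cur_hi <- bnd[[paste0(dir, "_ub")]][[rxn]]
  new_lo <- max(cur_lo, lo)
  new_hi <- min(cur_hi, hi)
  if (new_lo > new_hi + 1e-9) {
    bnd$conflicts <- bind_rows(bnd$conflicts,
                               tibble(reaction = rxn, direction = dir,
                                      lo = new_lo, hi = new_hi))
  } else {
    bnd[[paste0(dir, "_lb")]][[rxn]] <- new_lo
    bnd[[paste0(dir, "_ub")]][[rxn]] <- max(new_hi, new_lo)
  }
  bnd
}

regulated_interval <- function(mode, delta, basal, lb0, ub0, direction_role) {
  # direction_role: "fwd" or "bwd" relative to the regulated reaction, per the
  # gene/enzyme scheme: up-regulation raises the forward floor and caps the
  # backward range at basal; down-regulation mirrors it.
  if (mode == "up") {
    if (direction_role == "fwd") c((1 - delta) * basal + delta * ub0, ub0)
    else c(lb0, (1 - delta) * basal + delta * lb0)
  } else { # down
    if (direction_role == "fwd") c(lb0, (1 - delta) * basal + delta * lb0)
    else c((1 - delta) * basal + delta * ub0, ub0)
  }
}

#' Apply gene/enzyme-centric regulation to a split model
#'
#' For every reaction catalyzed by a targeted enzyme: a knockout forces both
#' directions to zero unless another isozyme still covers the reaction, in
#' which case (as for buffered down-regulation) the flux is held within
#' `(1 - epsilon) * basal` and `(1 + epsilon) * basal` in both directions.
#' Unbuffered down-regulation caps the forward flux at the `delta`-convex
#' combination of basal and lower bound (and symmetrically opens the backward
#' direction); up-regulation mirrors this. Intervals from multiple targets
#' compose by intersection.
#'
#' @param split A [split_reversible()] model.
#' @param gpr The model's [build_gpr_model()].
#' @param template The model's [compute_template()] (basal fluxes).
#' @param targets A [regulation_targets()] tibble of feasible-enzyme ids.
#' @param epsilon Isozyme flux ratio (basal window half-width, default 0.03).
#' @return A `split_model` with regulated bounds plus fields `conflicts`
#'   (tibble; non-empty marks the scheme infeasible) and `regulated`
#'   (ids of touched reactions).
#' @export
apply_gene_regulation <- function(split, gpr, template, targets,
                                  epsilon = 0.03) {
  stopifnot(inherits(split, "split_model"))
  out <- split
  out$conflicts <- tibble(reaction = character(), direction = character(),
                          lo = numeric(), hi = numeric())
  out$regulated <- character()
  unknown <- setdiff(targets$target, gpr$feasible$enzyme)
  if (length(unknown)) {
    abort(paste0("unknown enzyme target(s): ", paste(unknown, collapse = ", ")),
          class = "actd_lookup_error")
  }
  basal_f <- template$state$vf
  basal_b <- template$state$vb
  model_rxns <- split$base$reactions$id
  for (k in seq_len(nrow(targets))) {
    enz <- targets$target[[k]]
    mode <- targets$mode[[k]]
    delta <- targets$delta[[k]]
    rxns <- intersect(gpr$feasible$reactions[[match(enz, gpr$feasible$enzyme)]],
                      model_rxns)
    for (rxn in rxns) {
      out$regulated <- union(out$regulated, rxn)
      buffered <- isozyme_buffered(rxn, targets$target, gpr)
      bf <- basal_f[[rxn]]; bb <- basal_b[[rxn]]
      if (mode %in% c("knockout", "down") && buffered) {
        out <- tighten(out, rxn, "vf", (1 - epsilon) * bf, (1 + epsilon) * bf)
        out <- tighten(out, rxn, "vb", (1 - epsilon) * bb, (1 + epsilon) * bb)
      } else if (mode == "knockout") {
        out <- tighten(out, rxn, "vf", 0, 0)
        out <- tighten(out, rxn, "vb", 0, 0)
      } else {
        iv_f <- regulated_interval(mode, delta, bf,
                                   split$vf_lb[[rxn]], split$vf_ub[[rxn]], "fwd")
        iv_b <- regulated_interval(mode, delta, bb,
                                   split$vb_lb[[rxn]], split$vb_ub[[rxn]], "bwd")
        out <- tighten(out, rxn, "vf", iv_f[[1]], iv_f[[2]])
        out <- tighten(out, rxn, "vb", iv_b[[1]], iv_b[[2]])
      }
    }
  }
  out
}

#' Apply metabolite-centric regulation (antimetabolite model) to a split model
#'
#' Modulates every producing direction of the targeted metabolite: forward
#' directions of reactions with a positive stoichiometric coefficient and
#' backward directions of reversible reactions with a negative coefficient.
#' A knockout zeroes those directions (antimetabolite inhibition of
#' synthesis); `"down"`/`"up"` scale them by the `delta` convex combination
#' with the respective hard bound.
#'
#' @param split A [split_reversible()] model.
#' @param template The model's [compute_template()].
#' @param targets A [regulation_targets()] tibble of compartmented metabolite
#'   ids.
#' @return As [apply_gene_regulation()].
#' @export
apply_metabolite_regulation <- function(split, template, targets) {
  stopifnot(inherits(split, "split_model"))
  model <- split$base
  out <- split
  out$conflicts <- tibble(reaction = character(), direction = character(),
                          lo = numeric(), hi = numeric())
  out$regulated <- character()
  unknown <- setdiff(targets$target, model$metabolites$id)
  if (length(unknown)) {
    abort(paste0("unknown metabolite target(s): ", paste(unknown, collapse = ", ")),
          class = "actd_lookup_error")
  }
  basal_f <- template$state$vf
  basal_b <- template$state$vb
  for (k in seq_len(nrow(targets))) {
    met <- targets$target[[k]]
    mode <- targets$mode[[k]]
    delta <- targets$delta[[k]]
    coefs <- model$stoich[met, ]
    fwd <- names(coefs)[coefs > 0]
    bwd <- names(coefs)[coefs < 0 & split$vb_ub[names(coefs)] > 0]
    if (length(fwd) + length(bwd) == 0L) {
      warn(paste0("metabolite ", met, " has no producing reaction; no-op"))
      next
    }
    set_dir <- function(out, rxn, dir, basal, lb0, ub0) {
      if (mode == "knockout") return(tighten(out, rxn, dir, 0, 0))
      if (mode == "down") tighten(out, rxn, dir, lb0, (1 - delta) * basal + delta * lb0)
      else tighten(out, rxn, dir, (1 - delta) * basal + delta * ub0, ub0)
    }
    for (rxn in fwd) {
      out$regulated <- union(out$regulated, rxn)
      out <- set_dir(out, rxn, "vf", basal_f[[rxn]],
                     split$vf_lb[[rxn]], split$vf_ub[[rxn]])
    }
    for (rxn in bwd) {
      out$regulated <- union(out$regulated, rxn)
      out <- set_dir(out, rxn, "vb", basal_b[[rxn]],
                     split$vb_lb[[rxn]], split$vb_ub[[rxn]])
    }
  }
  out
}

scheme_conflicted <- function(split) {
  !is.null(split$conflicts) && nrow(split$conflicts) > 0L
}
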