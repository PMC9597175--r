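# Stoichiometric model container and validation.
#
# A model couples a metabolite table, a reaction table and a sparse
# stoichiometric matrix (metabolites x reactions). Metabolite ids carry their
# compartment as a bracketed suffix ("orot[c]"); reaction bounds are in
# mmol/gDW/h. Two reactions are singled out: the biomass (growth) reaction and
# the ATP demand/maintenance reaction whose flux is read as the ATP production
# rate.

CONFIDENCE_CLASSES <- c("high", "medium", "negative", "other")

#' Construct a stoichiometric model
#'
#' Builds and validates the model container used throughout the package.
#' Reaction reversibility is derived from the lower bound (`lb < 0`) and
#' exchange status from single-metabolite stoichiometry; both are recomputed
#' here, not trusted from the caller.
#'
#' @param metabolites Tibble with columns `id` (compartment-suffixed, e.g.
#'   `"glc[e]"`); `base_id` and `compartment` are derived if absent.
#' @param reactions Tibble with columns `id`, `lb`, `ub` and optionally `gpr`
#'   (Boolean gene rule string) and `confidence_class` (one of `"high"`,
#'   `"medium"`, `"negative"`, `"other"`; defaults to `"other"`).
#' @param stoich Either a sparse/dense matrix (metabolites x reactions) or a
#'   tibble with columns `reaction`, `metabolite`, `coefficient`.
#' @param biomass_rxn_id,atp_rxn_id Reaction ids of the growth objective and
#'   the ATP demand reaction. Both must exist.
#' @return An object of class `metnet_model`.
#' @export
metnet_model <- function(metabolites, reactions, stoich,
                         biomass_rxn_id, atp_rxn_id) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (nrow(reactions) == 0L) {
    abort("model has no reactions", class = "actd_validation_error")
  }
  if (nrow(metabolites) == 0L) {
    abort("model has no metabolites", class = "actd_validation_error")
  }
  if (anyDuplicated(metabolites$id)) {
    abort("duplicated metabolite ids", class = "actd_validation_error")
  }
  if (anyDuplicated(reactions$id)) {
    abort("duplicated reaction ids", class = "actd_validation_error")
  }
  if (!all(c("base_id", "compartment") %in% names(metabolites))) {
    parts <- split_compartment(metabolites$id)
    metabolites$base_id <- parts$base_id
    metabolites$compartment <- parts$compartment
  }
  if (any(!nzchar(metabolites$compartment))) {
    abort("every metabolite needs a non-empty compartment suffix, e.g. \"glc[c]\"",
          class = "actd_validation_error")
  }
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (!"confidence_class" %in% names(reactions)) reactions$confidence_class <- "other"
  reactions$confidence_class[is.na(reactions$confidence_class)] <- "other"
  bad_cc <- setdiff(unique(reactions$confidence_class), CONFIDENCE_CLASSES)
  if (length(bad_cc)) {
    abort(paste0("unknown confidence class: ", paste(bad_cc, collapse = ", ")),
          class = "actd_validation_error")
  }
  if (!is.matrix(stoich) && !inherits(stoich, "Matrix")) {
    stoich <- stoich_from_table(stoich, metabolites$id, reactions$id)
  }
  stoich <- Matrix::Matrix(stoich, sparse = TRUE)
  if (is.null(dimnames(stoich)) ||
      !identical(rownames(stoich), metabolites$id) ||
      !identical(colnames(stoich), reactions$id)) {
    abort("stoich dimnames must match metabolite/reaction ids",
          class = "actd_validation_error")
  }
  if (any(is.na(reactions$lb)) || any(is.na(reactions$ub)) ||
      any(reactions$lb > reactions$ub)) {
    abort("reaction bounds must satisfy lb <= ub", class = "actd_validation_error")
  }
  reactions$reversible <- reactions$lb < 0
  nnz <- Matrix::colSums(stoich != 0)
  reactions$is_exchange <- nnz == 1L
  if (any(nnz == 0L)) {
    abort(paste0("reactions with empty stoichiometry: ",
                 paste(reactions$id[nnz == 0L], collapse = ", ")),
          class = "actd_validation_error")
  }
  for (rid in c(biomass = biomass_rxn_id, atp = atp_rxn_id)) {
    if (!rid %in% reactions$id) {
      abort(paste0("objective reaction not in model: ", rid),
            class = "actd_config_error")
    }
  }
  structure(
    list(
      metabolites = metabolites[, c("id", "base_id", "compartment")],
      reactions = reactions[, c("id", "lb", "ub", "reversible", "is_exchange",
                                "gpr", "confidence_class")],
      stoich = stoich,
      biomass_rxn_id = biomass_rxn_id,
      atp_rxn_id = atp_rxn_id,
      compartments = sort(unique(metabolites$compartment))
    ),
    class = "metnet_model"
  )
}

split_compartment <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)\\[([^][]+)\\]$", ids))
  base <- map_chr(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][2] else ids[[i]]
  })
  comp <- map_chr(seq_along(ids), function(i) {
    if (length(m[[i]]) == 3L) m[[i]][3] else ""
  })
  list(base_id = base, compartment = comp)
}

stoich_from_table <- function(tab, met_ids, rxn_ids) {
  tab <- as_tibble(tab)
  i <- match(tab$metabolite, met_ids)
  j <- match(tab$reaction, rxn_ids)
  if (anyNA(i)) {
    abort(paste0("stoichiometry references unknown metabolite: ",
                 paste(unique(tab$metabolite[is.na(i)]), collapse = ", ")),
          class = "actd_validation_error")
  }
  if (anyNA(j)) {
    abort("stoichiometry references unknown reaction",
          class = "actd_validation_error")
  }
  Matrix::sparseMatrix(i = i, j = j, x = tab$coefficient,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' @export
print.metnet_model <- function(x, ...) {
  cat("<metnet_model> ", nrow(x$metabolites), " metabolites x ",
      nrow(x$reactions), " reactions\n", sep = "")
  cat("  biomass: ", x$biomass_rxn_id, "   atp: ", x$atp_rxn_id, "\n", sep = "")
  cat("  reversible: ", sum(x$reactions$reversible),
      "   exchange: ", sum(x$reactions$is_exchange),
      "   compartments: ", paste(x$compartments, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Split reversible reactions into forward/backward flux variables
#'
#' Every reaction `j` with net flux bounds `[lb, ub]` becomes a pair of
#' nonnegative variables `v_f`, `v_b` with `v = v_f - v_b`. Bounds are mapped
#' so the net-flux feasible interval is preserved exactly:
#' `v_f in [max(0, lb), max(0, ub)]`, `v_b in [max(0, -ub), max(0, -lb)]`.
#' Irreversible reactions get `v_b` fixed at 0.
#'
#' @param model A [metnet_model()].
#' @return An object of class `split_model`: the base model plus four named
#'   nonnegative bound vectors (`vf_lb`, `vf_ub`, `vb_lb`, `vb_ub`) and the
#'   set of internal (non-exchange) reaction ids over which the
#'   uniform-flux-distribution penalty runs.
#' @export
split_reversible <- function(model) {
  stopifnot(inherits(model, "metnet_model"))
  rx <- model$reactions
  structure(
    list(
      base = model,
      vf_lb = setNames(pmax(0, rx$lb), rx$id),
      vf_ub = setNames(pmax(0, rx$ub), rx$id),
      vb_lb = setNames(pmax(0, -rx$ub), rx$id),
      vb_ub = setNames(pmax(0, -rx$lb), rx$id),
      internal = rx$id[!rx$is_exchange]
    ),
    class = "split_model"
  )
}

#' @export
print.split_model <- function(x, ...) {
  cat("<split_model> on ", nrow(x$base$reactions), " reactions (",
      length(x$internal), " internal)\n", sep = "")
  invisible(x)
}

#' Net-flux bounds of a split model
#'
#' Collapses forward/backward bounds back to the net-flux interval
#' `[vf_lb - vb_ub, vf_ub - vb_lb]` per reaction. Used by the LP stage and by
#' round-trip invariant checks.
#'
#' @param split A [split_reversible()] result.
#' @return Tibble with `id`, `lb`, `ub`.
#' @export
net_bounds <- function(split) {
  stopifnot(inherits(split, "split_model"))
  tibble(id = names(split$vf_lb),
         lb = unname(split$vf_lb - split$vb_ub),
         ub = unname(split$vf_ub - split$vb_lb))
}
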