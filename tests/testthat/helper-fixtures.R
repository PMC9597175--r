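# Shared fixtures, all built in code.

# Linear chain: uptake (cap 10) -> A -> B -> demand. FBA bottleneck value 10.
chain_model <- function(cap = 10, gpr_r1 = "", orphan_consumer = FALSE) {
  rows <- tibble::tibble(
    id = c("upt", "r1", "r2", if (orphan_consumer) "r3"),
    equation = c("-> A[c]", "A[c] -> B[c]", "B[c] ->",
                 if (orphan_consumer) "C[c] -> A[c]"),
    lb = 0, ub = c(cap, 100, 100, if (orphan_consumer) 100),
    gpr = c("", gpr_r1, "", if (orphan_consumer) "")
  )
  stoich <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    dplyr::mutate(actd::parse_equation(rows$equation[[i]]), reaction = rows$id[[i]])
  }))
  actd::metnet_model(tibble::tibble(id = sort(unique(stoich$metabolite))),
                     dplyr::select(rows, -"equation"), stoich,
                     biomass_rxn_id = "r2", atp_rxn_id = "r2")
}

# Two parallel unit-yield paths A -> B with confidence classes controlling the
# flux-distribution weights; demand forces total flux `demand`.
parallel_model <- function(class1 = "other", class2 = "other", demand = 10) {
  rows <- tibble::tibble(
    id = c("upt", "p1", "p2", "dm"),
    equation = c("-> A[c]", "A[c] -> B[c]", "A[c] -> B[c]", "B[c] ->"),
    lb = c(demand, 0, 0, demand), ub = c(demand, 100, 100, demand),
    gpr = "", confidence_class = c("other", class1, class2, "other")
  )
  stoich <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    dplyr::mutate(actd::parse_equation(rows$equation[[i]]), reaction = rows$id[[i]])
  }))
  actd::metnet_model(tibble::tibble(id = c("A[c]", "B[c]")),
                     dplyr::select(rows, -"equation"), stoich,
                     biomass_rxn_id = "dm", atp_rxn_id = "dm")
}

# Micro model with a unit-capacity isozyme-buffered step whose basal flux is
# exactly 1.0: Giz1 is knockable, Giz2 also covers the side drain so the two
# isozymes survive redundancy reduction.
buffered_model <- function() {
  rows <- tibble::tibble(
    id = c("upt", "riz", "side", "dm"),
    equation = c("-> A[c]", "A[c] -> B[c]", "B[c] -> C[c]", "B[c] ->"),
    lb = 0, ub = c(1, 100, 0, 100),
    gpr = c("", "Giz1 or Giz2", "Giz2", "")
  )
  stoich <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(i) {
    dplyr::mutate(actd::parse_equation(rows$equation[[i]]), reaction = rows$id[[i]])
  }))
  actd::metnet_model(tibble::tibble(id = c("A[c]", "B[c]", "C[c]")),
                     dplyr::select(rows, -"equation"), stoich,
                     biomass_rxn_id = "dm", atp_rxn_id = "dm")
}

# One toy context, built once per test run and reused read-only.
toy_ctx_cache <- new.env(parent = emptyenv())
shared_toy <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(toy_ctx_cache[[key]])) {
    toy <- actd::make_toy_pair(actd::toy_spec(seed = seed))
    toy_ctx_cache[[key]] <- list(
      toy = toy,
      ctx = actd::actd_context(toy$ca, toy$ht, toy$ca_expr, toy$ht_expr))
  }
  toy_ctx_cache[[key]]
}

# Independent LP oracle via pracma, in shifted nonnegative variables (the
# direct lb/ub interface of pracma::linprog is avoided deliberately).
oracle_lp_max <- function(S, lo, hi, cvec) {
  S <- as.matrix(S)
  shift <- lo
  n <- length(lo)
  r <- pracma::linprog(cc = cvec, A = diag(n), b = hi - shift,
                       Aeq = S, beq = as.numeric(-S %*% shift),
                       maximize = TRUE, maxiter = 1000)
  sum(cvec * (r$x + shift))
}

# Second independent LP oracle (HiGHS via scipy), for models too degenerate
# for pracma's simplex.
oracle_lp_scipy <- function(S, lo, hi, cvec) {
  payload <- jsonlite::toJSON(list(S = as.matrix(S), lo = lo, hi = hi,
                                   c = cvec), digits = NA)
  script <- "
import sys, json
import numpy as np
from scipy.optimize import linprog
d = json.load(sys.stdin)
S = np.array(d['S']); c = -np.array(d['c'])
r = linprog(c, A_eq=S, b_eq=np.zeros(S.shape[0]),
            bounds=list(zip(d['lo'], d['hi'])), method='highs')
print(json.dumps({'ok': bool(r.success), 'obj': float(-r.fun) if r.success else None}))
"
  out <- system2("python", c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  stopifnot(isTRUE(res$ok))
  res$obj
}

# Dense-grid minimizer of the weighted quadratic objective over the feasible
# set of a <= 4-free-dimension network (brute-force oracle).
grid_ufd_oracle <- function(model, weights, floor_value, n_grid = 61) {
  split <- actd::split_reversible(model)
  nb <- actd::net_bounds(split)
  S <- as.matrix(model$stoich)
  free <- which(nb$ub - nb$lb > 1e-12)
  stopifnot(length(free) <= 4)
  grids <- lapply(free, function(j) seq(nb$lb[j], nb$ub[j], length.out = n_grid))
  pts <- as.matrix(expand.grid(grids))
  best <- Inf
  obj_id <- model$biomass_rxn_id
  for (i in seq_len(nrow(pts))) {
    v <- nb$lb
    v[free] <- pts[i, ]
    if (max(abs(S %*% v)) > 1e-9) next
    if (v[match(obj_id, nb$id)] < floor_value - 1e-9) next
    w <- weights[nb$id]
    w[model$reactions$is_exchange] <- 0
    val <- sum(w * v^2, na.rm = TRUE)  # one-sided fluxes: v^2 = vf^2 + vb^2
    if (val < best) best <- val
  }
  best
}
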