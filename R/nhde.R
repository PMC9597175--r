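# Nested hybrid differential evolution: the outer mixed-integer search over
# target identities (integer slots) and modulation strengths delta
# (continuous), whose fitness evaluation nests the FBA/UFD inner problems.
# Operators: DE/rand/1 mutation with rounding for the integer part, binomial
# crossover, greedy one-to-one selection on the lexicographic key
# (eta_D, eta_TR, eta_MD), and a migration phase that re-seeds the population
# around the incumbent when diversity collapses. Every distinct evaluated
# target set is archived, so the result is a ranked candidate table rather
# than a single winner.

#' Differential-evolution parameters
#'
#' @param population_size Number of individuals (>= 4).
#' @param F Mutation scale factor in (0, 2].
#' @param CR Crossover rate in `[0, 1]`.
#' @param max_generations Generations to run.
#' @param migration_tolerance Population-diversity fraction below which
#'   migration re-seeds the population.
#' @param migration_fraction Fraction of individuals re-randomized at
#'   migration.
#' @param delta_quantum Quantization step of delta for memoization.
#' @param seed Integer RNG seed.
#' @return List of class `nhde_params`.
#' @export
nhde_params <- function(population_size = 20, F = 0.5, CR = 0.8,
                        max_generations = 200, migration_tolerance = 1e-3,
                        migration_fraction = 0.8, delta_quantum = 1e-3,
                        seed = 1) {
  stopifnot(population_size >= 4, F > 0, F <= 2, CR >= 0, CR <= 1,
            max_generations >= 1)
  structure(as.list(environment()), class = "nhde_params")
}

ind_key <- function(targets) {
  paste(paste(sort(paste(targets$target, targets$mode)), collapse = "|"),
        paste(signif(targets$delta[order(targets$target)], 6), collapse = ","),
        sep = "@")
}

#' Nested hybrid differential evolution over candidate targets
#'
#' Maximizes the hierarchical decision grade over `n_slots` target choices
#' (one index per slot group) and, optionally, per-slot modulation strengths.
#' With `optimize_delta = FALSE` (the default) every slot is a hard
#' intervention of the given mode and delta is irrelevant.
#'
#' @param ctx An [actd_context()].
#' @param candidates Character vector of candidate ids (feasible enzymes or
#'   metabolites), used for every slot when `groups` is absent; duplicate
#'   picks within an individual are repaired by resampling.
#' @param n_slots Number of simultaneous targets (1 or 2 in practice).
#' @param groups Optional list of length `n_slots` giving each slot its own
#'   candidate vector (the two-group pair-search strategy).
#' @param centric `"gene"` or `"metabolite"`.
#' @param mode Regulation mode applied to every slot.
#' @param optimize_delta Search delta in `[0, 1]` per slot (for `"up"` /
#'   `"down"` modes).
#' @param params An [nhde_params()].
#' @return List of class `nhde_result`: `archive` (ranked tibble of all
#'   distinct evaluated target sets with their grades), `best` (top row),
#'   `history` (per-generation best grade and diversity), `n_evaluations`.
#' @export
nhde_optimize <- function(ctx, candidates = NULL, n_slots = 1, groups = NULL,
                          centric = c("gene", "metabolite"),
                          mode = "knockout", optimize_delta = FALSE,
                          params = nhde_params()) {
  centric <- match.arg(centric)
  if (is.null(groups)) {
    if (is.null(candidates) || length(candidates) == 0L) {
      abort("empty candidate list", class = "actd_domain_error")
    }
    groups <- rep(list(candidates), n_slots)
  }
  stopifnot(length(groups) == n_slots)
  if (any(lengths(groups) == 0L)) {
    abort("every slot group needs at least one candidate",
          class = "actd_domain_error")
  }
  shared_pool <- n_slots > 1 && length(unique(map_chr(groups, paste, collapse = "\r"))) == 1L

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  archive <- new.env(parent = emptyenv())
  evaluate_ind <- function(z, delta) {
    delta_q <- round(delta / params$delta_quantum) * params$delta_quantum
    if (!optimize_delta) delta_q <- rep(1, n_slots)
    targets <- regulation_targets(
      map_chr(seq_len(n_slots), function(s) groups[[s]][[z[[s]]]]),
      mode = mode, delta = delta_q)
    key <- ind_key(targets)
    if (!is.null(cache[[key]])) return(cache[[key]])
    row <- evaluate_targets(ctx, targets, centric = centric)
    n_eval <<- n_eval + 1L
    cache[[key]] <- row
    akey <- paste(sort(targets$target), collapse = "|")
    prev <- archive[[akey]]
    if (is.null(prev) || lex_better(row, prev)) archive[[akey]] <- row
    row
  }
  lex_better <- function(a, b) {
    ka <- c(a$eta_d, a$eta_tr, a$eta_md)
    kb <- c(b$eta_d, b$eta_tr, b$eta_md)
    d <- ka - kb
    i <- which(abs(d) > 1e-12)
    length(i) > 0L && d[[i[[1]]]] > 0
  }

  repair <- function(z) {
    if (!shared_pool) return(z)
    while (anyDuplicated(z)) {
      dup <- which(duplicated(z))
      for (s in dup) z[[s]] <- sample.int(length(groups[[s]]), 1L)
    }
    z
  }
  random_ind <- function() {
    z <- repair(map_dbl(groups, function(g) sample.int(length(g), 1L)))
    list(z = z, delta = runif(n_slots))
  }

  with_local_seed(params$seed, {
    NP <- params$population_size
    pop <- map(seq_len(NP), function(i) random_ind())
    fit <- map(pop, function(p) evaluate_ind(p$z, p$delta))
    history <- vector("list", params$max_generations)
    for (gen in seq_len(params$max_generations)) {
      for (i in seq_len(NP)) {
        r <- sample(setdiff(seq_len(NP), i), 3L)
        mz <- pop[[r[[1]]]]$z + params$F * (pop[[r[[2]]]]$z - pop[[r[[3]]]]$z)
        md <- pop[[r[[1]]]]$delta + params$F *
          (pop[[r[[2]]]]$delta - pop[[r[[3]]]]$delta)
        mz <- map_dbl(seq_len(n_slots), function(s) {
          v <- round(mz[[s]])
          ng <- length(groups[[s]])
          if (v < 1 || v > ng) sample.int(ng, 1L) else v
        })
        md <- pmin(1, pmax(0, md))
        cross <- runif(n_slots) < params$CR
        cross[sample.int(n_slots, 1L)] <- TRUE
        tz <- ifelse(cross, mz, pop[[i]]$z)
        td <- ifelse(cross, md, pop[[i]]$delta)
        tz <- repair(tz)
        trial_fit <- evaluate_ind(tz, td)
        if (lex_better(trial_fit, fit[[i]])) {
          pop[[i]] <- list(z = tz, delta = td)
          fit[[i]] <- trial_fit
        }
      }
      keys <- map_chr(pop, function(p) {
        paste(paste(p$z, collapse = ","),
              if (optimize_delta)
                paste(round(p$delta / params$delta_quantum), collapse = ",")
              else "", sep = "@")
      })
      diversity <- (length(unique(keys)) - 1) / max(1, NP - 1)
      best_i <- which.max(map_dbl(seq_len(NP), function(i) {
        fit[[i]]$eta_d + 1e-9 * fit[[i]]$eta_tr
      }))
      history[[gen]] <- tibble(generation = gen,
                               best_eta_d = fit[[best_i]]$eta_d,
                               diversity = diversity)
      if (diversity < params$migration_tolerance && gen < params$max_generations) {
        n_mig <- floor(params$migration_fraction * NP)
        victims <- setdiff(seq_len(NP), best_i)
        victims <- sample(victims, min(n_mig, length(victims)))
        for (i in victims) {
          pop[[i]] <- random_ind()
          fit[[i]] <- evaluate_ind(pop[[i]]$z, pop[[i]]$delta)
        }
      }
    }
    arch <- bind_rows(as.list(archive)) |>
      arrange(desc(.data$eta_d), desc(.data$eta_tr), desc(.data$eta_md),
              .data$target)
    structure(
      list(archive = arch, best = head(arch, 1L),
           history = bind_rows(history), n_evaluations = n_eval,
           params = params),
      class = "nhde_result"
    )
  })
}

#' @export
print.nhde_result <- function(x, ...) {
  cat("<nhde_result> ", nrow(x$archive), " distinct target sets, ",
      x$n_evaluations, " inner evaluations\n", sep = "")
  if (nrow(x$archive)) {
    b <- x$best
    cat(sprintf("  best: %s  eta_d = %.3f (tr %.3f, cv %.3f, md %.3f)\n",
                b$target, b$eta_d, b$eta_tr, b$eta_cv, b$eta_md))
  }
  invisible(x)
}
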