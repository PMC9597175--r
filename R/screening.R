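# Study drivers: one-target enumeration, the two-group two-target search,
# and antimetabolite screening, with ranked report tables (TSV round-trip)
# and plotting/summary methods.

new_screen <- function(rows, ranking = c("eta_d", "eta_md"), provenance = list()) {
  rows <- as_tibble(rows)
  if (nrow(rows)) {
    rows <- arrange(rows, desc(.data$eta_d), desc(.data$eta_md), .data$target)
    rows$rank <- seq_len(nrow(rows))
  } else {
    rows$rank <- integer()
  }
  structure(rows, class = c("actd_screen", class(tibble())),
            ranking = ranking, provenance = provenance)
}

screen_columns <- c("rank", "target", "mode", "delta", "centric",
                    "eta_tr", "eta_cv", "eta_md", "eta_d",
                    "eta_biomass_tr", "eta_atp_tr", "eta_biomass_pb",
                    "eta_atp_pb", "eta_f_ca", "eta_m_ca", "eta_f_bl",
                    "eta_m_bl", "ca_status", "ht_status", "feasible")

#' Size of a target search space
#'
#' Unordered `k`-subsets of `n` candidates, or the cross-pair count
#' `n1 * n2` when two groups are given.
#'
#' @param n_candidates Candidate count, or a length-2 vector of group sizes
#'   for the two-group strategy.
#' @param k Targets per combination (ignored for two groups).
#' @return Number of combinations.
#' @export
count_search_space <- function(n_candidates, k = 1) {
  if (length(n_candidates) == 2L) {
    return(prod(n_candidates))
  }
  if (k > n_candidates || k < 1) {
    abort("k must satisfy 1 <= k <= n_candidates", class = "actd_domain_error")
  }
  choose(n_candidates, k)
}

#' Exhaustive one-target screen
#'
#' Evaluates every candidate once (knockout by default; delta is then
#' irrelevant) and ranks by decision grade, then metabolic deviation grade,
#' then target id. Deterministic and order-independent.
#'
#' @param ctx An [actd_context()].
#' @param candidates Candidate ids; defaults to the cancer model's feasible
#'   enzymes (gene-centric) or to all internal metabolites with at least one
#'   producing reaction (metabolite-centric).
#' @param centric `"gene"` or `"metabolite"`.
#' @param mode,delta Regulation applied to each candidate.
#' @return An `actd_screen` tibble (one row per candidate).
#' @export
enumerate_one_target <- function(ctx, candidates = NULL,
                                 centric = c("gene", "metabolite"),
                                 mode = "knockout", delta = 1) {
  centric <- match.arg(centric)
  if (is.null(candidates)) {
    candidates <- default_candidates(ctx, centric)
  }
  if (length(candidates) == 0L) {
    warn("no candidates to screen; returning an empty result")
    return(new_screen(empty_screen_rows()))
  }
  rows <- bind_rows(map(sort(candidates), function(cand) {
    evaluate_targets(ctx, regulation_targets(cand, mode, delta), centric)
  }))
  new_screen(select(rows, -"ca_state", -"ht_state"),
             provenance = screen_provenance(ctx, "one_target", centric))
}

#' Default candidate list for a context
#' @param ctx An [actd_context()].
#' @param centric `"gene"` (cancer-model feasible enzymes) or `"metabolite"`
#'   (internal cancer-model metabolites with a producing reaction).
#' @return Character vector.
#' @export
default_candidates <- function(ctx, centric = c("gene", "metabolite")) {
  centric <- match.arg(centric)
  if (centric == "gene") return(sort(ctx$ca_gpr$feasible$enzyme))
  S <- ctx$ca$stoich
  internal <- !ctx$ca$reactions$is_exchange
  has_producer <- map_lgl(seq_len(nrow(S)), function(i) {
    coefs <- S[i, ]
    any(coefs > 0 & internal) ||
      any(coefs < 0 & internal & ctx$ca_split$vb_ub[colnames(S)] > 0)
  })
  sort(ctx$ca$metabolites$id[has_producer])
}

#' Two-group two-target search
#'
#' Searches cross-group pairs only (`|G1| * |G2|` combinations, the strategy
#' that tames the quadratic pair space). Small spaces are enumerated
#' exhaustively; larger ones are searched with [nhde_optimize()] using one
#' slot per group.
#'
#' @param ctx An [actd_context()].
#' @param group1,group2 Candidate id vectors; overlap is removed from
#'   `group2`.
#' @param centric,mode As in [enumerate_one_target()].
#' @param exhaustive_cap Pair-space size up to which exhaustive enumeration
#'   is used.
#' @param params [nhde_params()] for the evolutionary path.
#' @return An `actd_screen` of evaluated pairs (all pairs when exhaustive,
#'   the archive otherwise).
#' @export
pair_search <- function(ctx, group1, group2, centric = c("gene", "metabolite"),
                        mode = "knockout", exhaustive_cap = 2000,
                        params = nhde_params()) {
  centric <- match.arg(centric)
  group2 <- setdiff(group2, group1)
  if (length(group1) == 0L || length(group2) == 0L) {
    abort("both candidate groups must be non-empty", class = "actd_domain_error")
  }
  space <- count_search_space(c(length(group1), length(group2)))
  if (space <= exhaustive_cap) {
    rows <- bind_rows(map(group1, function(a) {
      bind_rows(map(group2, function(b) {
        evaluate_targets(ctx, regulation_targets(c(a, b), mode), centric)
      }))
    }))
    return(new_screen(select(rows, -"ca_state", -"ht_state"),
                      provenance = screen_provenance(ctx, "pair_exhaustive",
                                                     centric, space = space)))
  }
  res <- nhde_optimize(ctx, n_slots = 2, groups = list(group1, group2),
                       centric = centric, mode = mode, params = params)
  new_screen(select(res$archive, -"ca_state", -"ht_state"),
             provenance = screen_provenance(ctx, "pair_nhde", centric,
                                            space = space,
                                            n_evaluations = res$n_evaluations))
}

#' Antimetabolite screen
#'
#' Metabolite-centric screening: inhibition of a metabolite's synthesis
#' (knockout of all producing reaction directions) or its modulation. One
#' target enumerates all candidates; two targets run the pair strategy over
#' the same list.
#'
#' @param ctx An [actd_context()].
#' @param metabolites Candidate metabolite ids; default
#'   [default_candidates()] for the metabolite mode.
#' @param n_targets 1 (enumeration) or 2 (pairs).
#' @param mode Regulation mode (default knockout = full synthesis
#'   inhibition).
#' @param exhaustive_cap,params As in [pair_search()].
#' @return An `actd_screen`.
#' @export
screen_antimetabolites <- function(ctx, metabolites = NULL, n_targets = 1,
                                   mode = "knockout", exhaustive_cap = 2000,
                                   params = nhde_params()) {
  if (is.null(metabolites)) metabolites <- default_candidates(ctx, "metabolite")
  if (n_targets == 1) {
    enumerate_one_target(ctx, metabolites, centric = "metabolite", mode = mode)
  } else if (n_targets == 2) {
    half <- ceiling(length(metabolites) / 2)
    pair_search(ctx, metabolites[seq_len(half)],
                metabolites[-seq_len(half)], centric = "metabolite",
                mode = mode, exhaustive_cap = exhaustive_cap, params = params)
  } else {
    abort("n_targets must be 1 or 2", class = "actd_domain_error")
  }
}

empty_screen_rows <- function() {
  tibble(target = character(), mode = character(), delta = character(),
         centric = character(), eta_biomass_tr = numeric(),
         eta_atp_tr = numeric(), eta_tr = numeric(),
         eta_biomass_pb = numeric(), eta_atp_pb = numeric(),
         eta_cv = numeric(), eta_f_ca = numeric(), eta_m_ca = numeric(),
         eta_f_bl = numeric(), eta_m_bl = numeric(), eta_md = numeric(),
         eta_d = numeric(), ca_status = character(), ht_status = character(),
         feasible = logical())
}

screen_provenance <- function(ctx, design, centric, ...) {
  c(list(design = design, centric = centric,
         context_hash = rlang::hash(list(ctx$ca, ctx$ht, ctx$epsilon,
                                         ctx$floor_fraction)),
         timestamp = format(Sys.time(), tz = "UTC")),
    list(...))
}

#' Write a screening result to TSV
#' @param screen An `actd_screen`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  cols <- intersect(screen_columns, names(screen))
  readr::write_tsv(as_tibble(screen)[, cols], path)
  invisible(path)
}

#' Read a screening result written by [write_screen()]
#' @param path TSV file.
#' @return An `actd_screen`.
#' @export
read_screen <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    target = readr::col_character(), mode = readr::col_character(),
    delta = readr::col_character(), centric = readr::col_character(),
    ca_status = readr::col_character(), ht_status = readr::col_character(),
    feasible = readr::col_logical(), rank = readr::col_integer(),
    .default = readr::col_double()))
  new_screen(select(tab, -"rank"))
}

#' @export
tidy.actd_screen <- function(x, ...) {
  as_tibble(x)[, intersect(screen_columns, names(x))]
}

#' @export
glance.actd_screen <- function(x, ...) {
  tibble(n_candidates = nrow(x),
         n_feasible = sum(x$feasible),
         best_target = if (nrow(x)) x$target[[1]] else NA_character_,
         best_eta_d = if (nrow(x)) x$eta_d[[1]] else NA_real_,
         best_eta_md = if (nrow(x)) x$eta_md[[1]] else NA_real_)
}

#' Grade landscape of a screening result
#'
#' Scatter of viability vs metabolic deviation grades, colored by the
#' mortality grade: ideal targets sit in the top-right with a high mortality
#' grade.
#'
#' @param object An `actd_screen`.
#' @param top_n Label the top-ranked targets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.actd_screen <- function(object, top_n = 5, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$eta_cv, y = .data$eta_md,
                      colour = .data$eta_tr)) +
    geom_point(size = 2) +
    labs(x = "cell viability grade", y = "metabolic deviation grade",
         colour = "mortality") +
    theme_minimal()
  if (top_n > 0 && nrow(df)) {
    lab <- head(df, top_n)
    p <- p + ggplot2::geom_text(data = lab,
                                aes(label = .data$target),
                                vjust = -0.7, size = 3, show.legend = FALSE)
  }
  p
}
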