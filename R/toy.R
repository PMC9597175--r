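# Self-contained fixture generators: a four-reaction network illustrating
# GPR reduction, and seeded cancer/healthy toy model pairs with planted
# target structure (a cancer-essential/healthy-dispensable enzyme, a shared
# essential transporter, an isozyme-buffered essential step, a synthetic-
# lethal reaction pair, redundant enzymes and an enzyme complex).

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

toy_reaction_tbl <- function(...) {
  rows <- compact(list(...))
  bind_rows(map(rows, function(r) {
    tibble(id = r[[1]], equation = r[[2]], lb = as.numeric(r[[3]]),
           ub = as.numeric(r[[4]]), gpr = r[[5]])
  }))
}

build_toy_model <- function(rx, biomass_rxn_id, atp_rxn_id) {
  stoich <- bind_rows(map(seq_len(nrow(rx)), function(i) {
    mutate(parse_equation(rx$equation[[i]]), reaction = rx$id[[i]])
  }))
  mets <- tibble(id = sort(unique(stoich$metabolite)))
  metnet_model(mets, select(rx, -"equation"), stoich,
               biomass_rxn_id, atp_rxn_id)
}

#' Four-reaction GPR demonstration network
#'
#' A linear chain (uptake, two conversions, demand) whose rules exhibit the
#' canonical GPR situations: a single-gene enzyme, two single-gene isozymes
#' that both catalyze the same two reactions (hence are mutually redundant),
#' and a two-gene complex that makes the last conversion isozyme-buffered.
#'
#' @return List with `model` (a [metnet_model()]) and `gpr`
#'   (its [build_gpr_model()]).
#' @export
make_fig1_network <- function() {
  rx <- toy_reaction_tbl(
    list("r1", "-> A[c]", 0, 10, "G1"),
    list("r2", "A[c] -> B[c]", 0, 100, "G2 or G3"),
    list("r3", "B[c] -> C[c]", 0, 100, "G2 or G3 or (G4 and G5)"),
    list("r4", "C[c] ->", 0, 100, "")
  )
  model <- build_toy_model(rx, biomass_rxn_id = "r4", atp_rxn_id = "r4")
  list(model = model, gpr = build_gpr_model(model))
}

#' Specification for a toy cancer/healthy model pair
#'
#' @param seed Integer seed driving expression synthesis and decoration.
#' @param n_isozyme_pairs,n_redundant_enzymes,n_complexes Counts of extra
#'   decorative pathway branches carrying each GPR motif (beyond the planted
#'   core, which always contains one of each).
#' @param glc_uptake_ca,glc_uptake_ht Glucose uptake capacities
#'   (mmol/gDW/h).
#' @param atp_maintenance Lower bound of the ATP demand reaction; keeps
#'   treated cells from trivially reporting zero ATP turnover.
#' @param oxp_cap_ca Cap on the respiration-like high-yield ATP branch in the
#'   cancer model (aerobic-glycolysis phenotype); the healthy model is
#'   uncapped.
#' @return List of class `toy_spec`.
#' @export
toy_spec <- function(seed = 1, n_isozyme_pairs = 1, n_redundant_enzymes = 1,
                     n_complexes = 1, glc_uptake_ca = 10, glc_uptake_ht = 8,
                     atp_maintenance = 1, oxp_cap_ca = 2) {
  stopifnot(n_isozyme_pairs >= 0, n_redundant_enzymes >= 0, n_complexes >= 0,
            glc_uptake_ca > 0, glc_uptake_ht > 0, atp_maintenance >= 0)
  structure(as.list(environment()), class = "toy_spec")
}

#' Generate a paired cancer/healthy toy model bundle
#'
#' Both models share a core of glucose/glutamine uptake, an isozyme-buffered
#' hexokinase-like step, glycolysis (an enzyme complex) feeding a
#' respiration-like ATP branch, a nucleotide-precursor pathway required for
#' growth, and two parallel lipid routes. The cancer model adds a high-flux
#' glycolytic bypass and caps respiration (aerobic-glycolysis phenotype);
#' the healthy model is uncapped and should maximize ATP. Planted structure
#' (returned in `truth`): the precursor-synthesis enzyme is cancer-lethal
#' and leaves healthy ATP untouched (an ideal target); the sole glucose
#' transporter is essential to both (a high-side-effect target); each lipid
#' route alone is dispensable but the pair is synthetically lethal for
#' growth only.
#'
#' @param spec A [toy_spec()].
#' @return List with `ca`, `ht` (models), `ca_expr`, `ht_expr` (expression
#'   tibbles) and `truth` (planted target ids).
#' @export
make_toy_pair <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  core <- function(glc_uptake, oxp_cap, with_bypass) {
    toy_reaction_tbl(
      list("EX_glc", "glc[e] ->", -glc_uptake, 0, ""),
      list("EX_gln", "gln[e] ->", -5, 0, ""),
      list("EX_lac", "lac[e] ->", 0, 1000, ""),
      list("T_glc", "glc[e] -> glc[c]", 0, 1000, "Gtglc"),
      list("T_gln", "gln[e] -> gln[c]", 0, 1000, "Gtgln"),
      list("HK", "glc[c] -> g6p[c]", 0, 1000, "Ghk1 or Ghk2"),
      list("GLY", "g6p[c] -> 2 pyr[c] + 2 atp[c]", 0, 1000, "Ggly1 and Ggly2"),
      if (with_bypass) list("ED", "glc[c] -> 2 pyr[c]", 0, 1000, "Ged"),
      list("OXP", "pyr[c] -> 14 atp[c]", 0, oxp_cap, "Goxp"),
      # Ghk2 is promiscuous (also covers LDH) so the two hexokinase isozymes
      # have distinct reaction sets and survive redundancy reduction
      list("LDH", "pyr[c] <-> lac[c]", -1000, 1000, "Gldh or Ghk2"),
      list("T_lac", "lac[c] -> lac[e]", 0, 1000, ""),
      list("PRE", "g6p[c] + gln[c] -> prec[c]", 0, 1000, "Gpre"),
      list("NUC1", "prec[c] -> nuci[c]", 0, 1000, "(Gn1 and Gn2) or Gn3"),
      list("NUC2", "nuci[c] -> nuc[c]", 0, 1000, "(Gn1 and Gn2) or Gn3"),
      list("LIP1", "pyr[c] + atp[c] -> lip[c]", 0, 1000, "Glip1"),
      list("LIP2", "g6p[c] -> lip[c]", 0, 1000, "Glip2"),
      list("BIOMASS", "nuc[c] + lip[c] + 2 pyr[c] + 6 atp[c] ->", 0, 1000, ""),
      list("ATPM", "atp[c] ->", spec$atp_maintenance, 1000, "")
    )
  }
  decorations <- function() {
    rows <- list()
    k <- 0
    add <- function(rows, gpr_in, gpr_out) {
      k <<- k + 1
      c(rows,
        list(list(sprintf("DEC%d_in", k), sprintf("pyr[c] -> dm%d[c]", k),
                  0, 1000, gpr_in),
             list(sprintf("DEC%d_out", k), sprintf("dm%d[c] -> lac[c]", k),
                  0, 1000, gpr_out)))
    }
    for (i in seq_len(spec$n_isozyme_pairs)) {
      # second isozyme also covers the outflow so the pair is not redundant
      rows <- add(rows, sprintf("Giza%d or Gizb%d", i, i), sprintf("Gizb%d", i))
    }
    for (i in seq_len(spec$n_complexes)) {
      rows <- add(rows, "", sprintf("Gcxa%d and Gcxb%d", i, i))
    }
    for (i in seq_len(spec$n_redundant_enzymes)) {
      g <- sprintf("Grda%d or Grdb%d", i, i)
      rows <- add(rows, g, g)
    }
    if (length(rows)) do.call(toy_reaction_tbl, rows) else NULL
  }
  dec <- decorations()
  ca_rx <- bind_rows(core(spec$glc_uptake_ca, spec$oxp_cap_ca, TRUE), dec)
  ht_rx <- bind_rows(core(spec$glc_uptake_ht, 1000, FALSE), dec)
  ca <- build_toy_model(ca_rx, "BIOMASS", "ATPM")
  ht <- build_toy_model(ht_rx, "BIOMASS", "ATPM")
  expr_for <- function(model, seed) {
    genes <- sort(unique(unlist(map(model$reactions$gpr, function(g) {
      gpr_genes(parse_gpr(g))
    }))))
    with_local_seed(seed, {
      m <- rlnorm(length(genes), meanlog = 2, sdlog = 1.2)
      m[runif(length(genes)) < 0.1] <- 0
      tibble(gene = genes, mean = m,
             dispersion = runif(length(genes), 0.1, 0.6))
    })
  }
  list(
    ca = ca, ht = ht,
    ca_expr = expr_for(ca, spec$seed),
    ht_expr = expr_for(ht, spec$seed + 1L),
    truth = list(
      ideal_target = "Gpre",
      shared_essential = "Gtglc",
      isozyme_enzymes = c("Ghk1", "Ghk2"),
      isozyme_reaction = "HK",
      synthetic_lethal = c("Glip1", "Glip2"),
      complex_enzyme = "Ggly1+Ggly2",
      redundant_pair_reactions = c("NUC1", "NUC2")
    )
  )
}
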