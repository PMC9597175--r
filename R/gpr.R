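# Gene-protein-reaction (GPR) Boolean rules: parsing, enzyme enumeration,
# redundant-enzyme reduction, isozyme detection, expression-based gene
# grouping, and reaction confidence weights for the flux-distribution penalty.
#
# An enzyme is an AND-complex of genes (one OR-branch of a rule); its identity
# is its gene set. Enzymes whose catalyzed reaction sets coincide are
# redundant: regulating any member of such a group is equivalent, so one
# representative is kept and the group's branches are treated as one unit when
# deciding whether a reaction stays isozyme-buffered.

#' Parse a GPR rule string
#'
#' Grammar: `expr := term ('or' term)*`, `term := factor ('and' factor)*`,
#' `factor := gene | '(' expr ')'`. Operators are case-insensitive; gene ids
#' may contain letters, digits, `_ . : -`. Nested same-operator nodes are
#' flattened so reparsing a deparsed rule yields the identical tree.
#'
#' @param rule Rule string; `""`/`NA` mean "no gene association" and return
#'   `NULL`.
#' @return A tree of nested lists: `list(op = "gene", gene = id)` or
#'   `list(op = "and"/"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- regmatches(rule, gregexpr("[()]|[A-Za-z0-9_.:-]+", rule))[[1]]
  residue <- gsub("[()]|[A-Za-z0-9_.:-]+|\\s+", "", rule)
  if (nzchar(residue)) {
    abort(paste0("malformed GPR rule (unexpected character '",
                 substr(residue, 1, 1), "'): ", rule),
          class = "actd_parse_error")
  }
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(what) {
    abort(sprintf("malformed GPR rule (%s at token %d): %s", what, pos, rule),
          class = "actd_parse_error")
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) fail("unexpected end")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) fail("missing ')'")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) fail("expected gene id")
    list(op = "gene", gene = t)
  }
  parse_chain <- function(parse_sub, op_name) {
    args <- list(parse_sub())
    while (!is.na(peek()) && tolower(peek()) == op_name) {
      take()
      args <- c(args, list(parse_sub()))
    }
    if (length(args) == 1L) return(args[[1]])
    # flatten nested same-op nodes
    flat <- list()
    for (a in args) {
      flat <- if (identical(a$op, op_name)) c(flat, a$args) else c(flat, list(a))
    }
    list(op = op_name, args = flat)
  }
  parse_expr <- function() parse_chain(function() parse_chain(parse_factor, "and"), "or")
  out <- parse_expr()
  if (!is.na(peek())) fail("trailing input")
  out
}

#' Serialize a GPR tree back to a rule string
#' @param tree A [parse_gpr()] tree (or `NULL`).
#' @return Rule string (`""` for `NULL`).
#' @export
deparse_gpr <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(node, parent_op) {
    if (node$op == "gene") return(node$gene)
    s <- paste(map_chr(node$args, rec, parent_op = node$op),
               collapse = paste0(" ", node$op, " "))
    # parentheses only where precedence requires them: an OR under an AND
    if (identical(parent_op, NA_character_) ||
        (node$op == "and" && identical(parent_op, "or"))) s
    else paste0("(", s, ")")
  }
  rec(tree, NA_character_)
}

#' All gene ids appearing in a GPR tree
#' @param tree A [parse_gpr()] tree (or `NULL`).
#' @return Character vector (unique, in order of appearance).
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(map(tree$args, gpr_genes)))
}

#' OR-branches of a GPR tree as gene complexes
#'
#' Expands the rule to disjunctive normal form: each branch is one gene set
#' (an AND-complex) sufficient to catalyze the reaction. `(G1 or G2) and G3`
#' yields `{G1,G3}` and `{G2,G3}`.
#'
#' @param tree A [parse_gpr()] tree (or `NULL`).
#' @return List of character vectors (sorted gene sets, deduplicated).
#' @export
gpr_branches <- function(tree) {
  if (is.null(tree)) return(list())
  rec <- function(node) {
    switch(node$op,
      gene = list(node$gene),
      or = do.call(c, map(node$args, rec)),
      and = {
        parts <- map(node$args, rec)
        Reduce(function(acc, nxt) {
          do.call(c, map(acc, function(a) map(nxt, function(b) union(a, b))))
        }, parts)
      }
    )
  }
  br <- map(rec(tree), function(g) sort(unique(g)))
  br[!duplicated(map_chr(br, paste, collapse = "\r"))]
}

enzyme_id <- function(genes) paste(sort(genes), collapse = "+")

#' Enumerate candidate enzymes from parsed GPR rules
#'
#' Each distinct OR-branch (gene complex) across all reactions becomes one
#' candidate enzyme, associated with every reaction whose rule contains that
#' branch. Promiscuous enzymes therefore carry multi-reaction sets.
#'
#' @param rules Named list of [parse_gpr()] trees (reaction id -> tree);
#'   `NULL` entries are skipped.
#' @return Tibble with `enzyme` (id derived from the sorted gene set),
#'   `genes` (list of character vectors), `reactions` (list of character
#'   vectors), `n_genes`.
#' @export
enumerate_enzymes <- function(rules) {
  hits <- list()
  for (rid in names(rules)) {
    for (branch in gpr_branches(rules[[rid]])) {
      key <- enzyme_id(branch)
      hits[[key]] <- list(genes = branch,
                          reactions = union(hits[[key]]$reactions, rid))
    }
  }
  if (length(hits) == 0L) {
    return(tibble(enzyme = character(), genes = list(), reactions = list(),
                  n_genes = integer()))
  }
  keys <- sort(names(hits))
  tibble(
    enzyme = keys,
    genes = map(hits[keys], "genes"),
    reactions = map(hits[keys], function(h) sort(h$reactions)),
    n_genes = map_dbl(hits[keys], function(h) length(h$genes))
  )
}

#' Collapse redundant enzymes
#'
#' Enzymes catalyzing exactly the same reaction set are interchangeable as
#' regulation targets; one representative (first by enzyme id) is kept. The
#' representative records all member gene sets so downstream isozyme-buffering
#' checks remove the whole group's branches when it is targeted.
#'
#' @param enzymes Output of [enumerate_enzymes()].
#' @return List with `feasible` (tibble like `enzymes` plus a `members`
#'   list-column of grouped gene sets) and `removed` (tibble mapping each
#'   removed enzyme to its representative).
#' @export
reduce_redundant <- function(enzymes) {
  if (nrow(enzymes) == 0L) {
    return(list(feasible = mutate(enzymes, members = list()),
                removed = tibble(enzyme = character(), representative = character())))
  }
  enzymes <- arrange(enzymes, .data$enzyme)  # deterministic representative
  key <- map_chr(enzymes$reactions, paste, collapse = "\r")
  groups <- split(seq_len(nrow(enzymes)), key)
  keep <- sort(map_dbl(groups, 1L))
  feasible <- enzymes[keep, ]
  feasible$members <- map(keep, function(i) {
    enzymes$genes[groups[[key[[i]]]]]
  })
  removed <- bind_rows(map(groups, function(ix) {
    if (length(ix) == 1L) return(NULL)
    tibble(enzyme = enzymes$enzyme[ix[-1]],
           representative = enzymes$enzyme[ix[[1]]])
  }))
  if (is.null(removed) || nrow(removed) == 0L) {
    removed <- tibble(enzyme = character(), representative = character())
  }
  list(feasible = feasible, removed = arrange(removed, .data$enzyme))
}

#' Reactions buffered by isozymes
#'
#' A reaction belongs to the isozyme set when at least two distinct feasible
#' enzymes (branch groups) can catalyze it, so removing one leaves another.
#'
#' @param rules Named list of parsed rules.
#' @param feasible Feasible-enzyme tibble from [reduce_redundant()]; computed
#'   from `rules` when missing.
#' @return Character vector of reaction ids.
#' @export
isozyme_reactions <- function(rules, feasible = NULL) {
  if (is.null(feasible)) feasible <- reduce_redundant(enumerate_enzymes(rules))$feasible
  counts <- table(unlist(feasible$reactions))
  names(counts)[counts >= 2L]
}

#' Is a reaction still catalyzable after removing target enzymes?
#'
#' Evaluates the reaction's rule with every branch belonging to a targeted
#' enzyme group removed; `TRUE` means another isozyme still covers the
#' reaction, so regulation pins it near its basal flux instead of silencing
#' it.
#'
#' @param reaction Reaction id.
#' @param target_enzymes Character vector of feasible-enzyme ids (empty set
#'   allowed).
#' @param gpr A [build_gpr_model()] object.
#' @return Logical scalar.
#' @export
isozyme_buffered <- function(reaction, target_enzymes, gpr) {
  if (!reaction %in% names(gpr$rules) || is.null(gpr$rules[[reaction]])) {
    abort(paste0("no GPR rule for reaction: ", reaction),
          class = "actd_lookup_error")
  }
  branches <- gpr_branches(gpr$rules[[reaction]])
  if (length(branches) == 0L) return(FALSE)
  removed_keys <- unlist(map(target_enzymes, function(e) {
    row <- match(e, gpr$feasible$enzyme)
    if (is.na(row)) {
      abort(paste0("unknown enzyme target: ", e), class = "actd_lookup_error")
    }
    map_chr(gpr$feasible$members[[row]], enzyme_id)
  }))
  keys <- map_chr(branches, enzyme_id)
  any(!keys %in% removed_keys)
}

GENE_GROUPS <- c("not_detected", "low", "medium", "high")

#' Classify genes into expression groups
#'
#' Quantile-threshold assignment of per-gene expression summaries into four
#' groups. The thresholds (defaults: 25/50/75th percentiles of detected
#' expression) split detected genes into low/medium/high; genes at or below
#' the detection limit, or below the lowest quantile, are `not_detected`.
#'
#' @param expr Tibble with columns `gene` and `mean` (nonnegative expression
#'   summary); a `dispersion` column is accepted and ignored by the default
#'   rule.
#' @param thresholds Three increasing probabilities for [stats::quantile()].
#' @param detect_limit Expression at or below this is `not_detected`
#'   regardless of quantiles.
#' @return Named character vector gene -> group.
#' @export
classify_genes <- function(expr, thresholds = c(0.25, 0.5, 0.75),
                           detect_limit = 0) {
  expr <- as_tibble(expr)
  if (any(expr$mean < 0)) {
    abort("negative expression values", class = "actd_domain_error")
  }
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds))
  detected <- expr$mean > detect_limit
  qs <- if (any(detected)) quantile(expr$mean[detected], thresholds, names = FALSE)
        else c(Inf, Inf, Inf)
  # quantiles may coincide on small or tied samples; count crossed thresholds
  idx <- 1L + rowSums(outer(expr$mean, qs, ">="))
  grp <- GENE_GROUPS[idx]
  grp[!detected] <- "not_detected"
  setNames(grp, expr$gene)
}

#' Reaction confidence weights for the flux-distribution penalty
#'
#' Propagates gene groups through each rule (a complex is as confident as its
#' least-confident gene; a reaction as its most-confident branch), maps the
#' resulting group to the reaction confidence class (high -> high, medium ->
#' medium, low -> negative, not_detected -> other) and assigns the penalty
#' weight: high 1/4, medium 1/2, negative 3/4, other or no gene association 1.
#'
#' @param rules Named list of parsed rules (reaction id -> tree or `NULL`).
#' @param gene_groups Named vector from [classify_genes()]; genes missing from
#'   it count as `not_detected`.
#' @return Named numeric vector reaction id -> weight in {1/4, 1/2, 3/4, 1}.
#' @export
weight_reactions <- function(rules, gene_groups) {
  rank_of <- setNames(seq_along(GENE_GROUPS), GENE_GROUPS)
  class_for <- c(not_detected = "other", low = "negative",
                 medium = "medium", high = "high")
  weight_for <- c(high = 1 / 4, medium = 1 / 2, negative = 3 / 4, other = 1)
  out <- map_dbl(rules, function(tree) {
    if (is.null(tree)) return(1)
    branch_rank <- map_dbl(gpr_branches(tree), function(genes) {
      gg <- gene_groups[genes]
      gg[is.na(gg)] <- "not_detected"
      min(rank_of[gg])
    })
    grp <- GENE_GROUPS[[max(branch_rank)]]
    weight_for[[class_for[[grp]]]]
  })
  setNames(out, names(rules))
}

#' Assemble the GPR model for a stoichiometric model
#'
#' Parses all rules, enumerates and reduces enzymes, finds isozyme-buffered
#' reactions, and (when expression data are supplied) classifies genes and
#' derives reaction confidence weights; without expression data, weights fall
#' back to the model's stored `confidence_class` column.
#'
#' @param model A [metnet_model()].
#' @param expr Optional expression tibble for [classify_genes()].
#' @param thresholds Passed to [classify_genes()].
#' @return Object of class `actd_gpr`: rules, enzyme tables (`enzymes` raw,
#'   `feasible` reduced, `removed`), `isozyme_rxns`, `gene_groups`, `weights`.
#' @export
build_gpr_model <- function(model, expr = NULL, thresholds = c(0.25, 0.5, 0.75)) {
  rx <- model$reactions
  rules <- setNames(map(rx$gpr, parse_gpr), rx$id)
  enzymes <- enumerate_enzymes(rules)
  red <- reduce_redundant(enzymes)
  iz <- isozyme_reactions(rules, red$feasible)
  if (!is.null(expr)) {
    gene_groups <- classify_genes(expr, thresholds)
    weights <- weight_reactions(rules, gene_groups)
  } else {
    gene_groups <- NULL
    weight_for <- c(high = 1 / 4, medium = 1 / 2, negative = 3 / 4, other = 1)
    weights <- setNames(unname(weight_for[rx$confidence_class]), rx$id)
    weights[!nzchar(rx$gpr) & rx$confidence_class == "other"] <- 1
  }
  structure(
    list(rules = rules, enzymes = enzymes, feasible = red$feasible,
         removed = red$removed, isozyme_rxns = iz,
         gene_groups = gene_groups, weights = weights),
    class = "actd_gpr"
  )
}

#' @export
print.actd_gpr <- function(x, ...) {
  cat("<actd_gpr> ", nrow(x$enzymes), " enzymes -> ", nrow(x$feasible),
      " feasible after reduction; ", length(x$isozyme_rxns),
      " isozyme-buffered reactions\n", sep = "")
  invisible(x)
}

#' Resolve a gene symbol to the feasible enzymes containing it
#' @param gene Gene id.
#' @param gpr A [build_gpr_model()] object.
#' @return Character vector of feasible-enzyme ids (possibly empty).
#' @export
enzymes_for_gene <- function(gene, gpr) {
  hit <- map_lgl(gpr$feasible$members, function(member_sets) {
    any(map_lgl(member_sets, function(gs) gene %in% gs))
  })
  gpr$feasible$enzyme[hit]
}
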