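test_that("GPR parsing handles leaves, precedence, absence and malformed input", {
  expect_equal(parse_gpr("G2"), list(op = "gene", gene = "G2"))
  tree <- parse_gpr("G2 or (G4 and G5)")
  expect_equal(tree$op, "or")
  expect_equal(tree$args[[1]], list(op = "gene", gene = "G2"))
  expect_equal(tree$args[[2]]$op, "and")
  expect_equal(sort(gpr_genes(tree$args[[2]])), c("G4", "G5"))
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NA))
  expect_error(parse_gpr("G1 or"), class = "actd_parse_error")
  expect_error(parse_gpr("(G1 and G2"), class = "actd_parse_error")
  expect_error(parse_gpr("G1 ! G2"), class = "actd_parse_error")
  expect_error(parse_gpr("and G1"), class = "actd_parse_error")
})

test_that("deparse/parse is idempotent on representative rules", {
  rules <- c("G1", "Ga and Gb", "G2 or G3 or (G4 and G5)",
             "(G1 or G2) and (G3 or (G4 and G5))",
             "A1 and B2 and C3", "x or y or z")
  for (r in rules) {
    t1 <- parse_gpr(r)
    expect_identical(parse_gpr(deparse_gpr(t1)), t1, label = r)
  }
})

test_that("branch expansion distributes AND over OR", {
  br <- gpr_branches(parse_gpr("(G1 or G2) and G3"))
  expect_setequal(lapply(br, paste, collapse = "+"), list("G1+G3", "G2+G3"))
})

test_that("enzyme enumeration on the demo network matches the published association table", {
  fig <- make_fig1_network()
  enz <- fig$gpr$enzymes
  expect_equal(nrow(enz), 4L)
  got <- setNames(enz$reactions, enz$enzyme)
  expect_equal(got[["G1"]], "r1")
  expect_equal(got[["G2"]], c("r2", "r3"))
  expect_equal(got[["G3"]], c("r2", "r3"))
  expect_equal(got[["G4+G5"]], "r3")
})

test_that("a complex branch shared by two reactions yields one promiscuous enzyme", {
  rules <- list(ra = parse_gpr("Gx and Gy"), rb = parse_gpr("(Gx and Gy) or Gz"))
  enz <- enumerate_enzymes(rules)
  # independent incidence oracle: branch key -> reactions containing it
  oracle <- list()
  for (rid in names(rules)) {
    for (b in gpr_branches(rules[[rid]])) {
      k <- paste(sort(b), collapse = "+")
      oracle[[k]] <- sort(union(oracle[[k]], rid))
    }
  }
  expect_equal(nrow(enz), length(oracle))
  for (i in seq_len(nrow(enz))) {
    expect_equal(enz$reactions[[i]], oracle[[enz$enzyme[[i]]]])
  }
  expect_equal(enz$reactions[[match("Gx+Gy", enz$enzyme)]], c("ra", "rb"))
})

test_that("redundancy reduction keeps one representative per identical reaction set", {
  fig <- make_fig1_network()
  red <- reduce_redundant(fig$gpr$enzymes)
  expect_equal(red$removed$enzyme, "G3")
  expect_equal(red$removed$representative, "G2")
  expect_equal(nrow(red$feasible), 3L)  # 4 enumerated -> 3 feasible

  # k identical copies -> one survivor (oracle: group by frozen reaction-set key)
  k <- 5
  rules <- setNames(lapply(seq_len(k), function(i) parse_gpr(paste0("Gc", i))),
                    rep("rx", k))
  enz <- enumerate_enzymes(list(rx = parse_gpr(paste(paste0("Gc", 1:k),
                                                     collapse = " or "))))
  red2 <- reduce_redundant(enz)
  expect_equal(nrow(red2$feasible), 1L)
  expect_equal(nrow(red2$removed), k - 1L)

  # idempotence and coverage preservation
  red3 <- reduce_redundant(red$feasible[, c("enzyme", "genes", "reactions",
                                            "n_genes")])
  expect_equal(red3$feasible$enzyme, red$feasible$enzyme)
  expect_equal(nrow(red3$removed), 0L)
  expect_setequal(unique(unlist(red$feasible$reactions)),
                  unique(unlist(fig$gpr$enzymes$reactions)))

  # all-distinct reaction sets -> nothing removed
  rules4 <- list(r1 = parse_gpr("Ga"), r2 = parse_gpr("Gb"))
  expect_equal(nrow(reduce_redundant(enumerate_enzymes(rules4))$removed), 0L)
})

test_that("isozyme buffering follows the reduced association groups", {
  gpr <- make_fig1_network()$gpr
  expect_equal(gpr$isozyme_rxns, "r3")
  expect_true(isozyme_buffered("r3", "G2", gpr))
  expect_false(isozyme_buffered("r2", "G2", gpr))   # G3 is in G2's group
  expect_false(isozyme_buffered("r1", "G1", gpr))
  expect_false(isozyme_buffered("r3", c("G2", "G4+G5"), gpr))
  # empty target set leaves any ruled reaction satisfiable
  for (r in c("r1", "r2", "r3")) {
    expect_true(isozyme_buffered(r, character(), gpr))
  }
  expect_error(isozyme_buffered("nope", "G2", gpr), class = "actd_lookup_error")
})

test_that("expression classification assigns quantile groups with a detection floor", {
  expect_error(classify_genes(tibble::tibble(gene = "g", mean = -1)),
               class = "actd_domain_error")
  expr <- tibble::tibble(gene = c("z", "h"), mean = c(0, 100))
  gg <- classify_genes(expr)
  expect_equal(unname(gg["z"]), "not_detected")
  expect_equal(unname(gg["h"]), "high")
  # uniform synthetic expression: about a quarter of genes per group
  withr::with_seed(42, {
    expr2 <- tibble::tibble(gene = sprintf("g%03d", 1:400),
                            mean = runif(400, 1, 100))
  })
  tab <- table(classify_genes(expr2))
  expect_true(all(abs(tab - 100) <= 2))
})

test_that("confidence weights propagate OR-best / AND-worst and map to the four levels", {
  groups <- c(A = "high", B = "medium", C = "low", D = "not_detected")
  w_of <- function(rule) unname(weight_reactions(list(r = parse_gpr(rule)), groups))
  expect_equal(w_of("A"), 0.25)
  expect_equal(w_of("B"), 0.5)
  expect_equal(w_of("C"), 0.75)
  expect_equal(w_of("D"), 1)
  expect_equal(unname(weight_reactions(list(r = NULL), groups)), 1)
  # truth table over all pairs against an independent rank oracle
  lv <- c("not_detected", "low", "medium", "high")
  wmap <- c(not_detected = 1, low = 0.75, medium = 0.5, high = 0.25)
  for (a in names(groups)) for (b in names(groups)) {
    and_expect <- wmap[[lv[min(match(groups[[a]], lv), match(groups[[b]], lv))]]]
    or_expect <- wmap[[lv[max(match(groups[[a]], lv), match(groups[[b]], lv))]]]
    expect_equal(w_of(paste(a, "and", b)), and_expect,
                 label = paste(a, "and", b))
    expect_equal(w_of(paste(a, "or", b)), or_expect,
                 label = paste(a, "or", b))
  }
  # a complex with one silent gene can never beat the negative level
  expect_true(w_of("A and D") %in% c(0.75, 1))
})

test_that("gene symbols resolve to the feasible enzymes containing them", {
  gpr <- make_fig1_network()$gpr
  expect_equal(enzymes_for_gene("G4", gpr), "G4+G5")
  expect_equal(enzymes_for_gene("G3", gpr), "G2")  # via the redundancy group
  expect_equal(enzymes_for_gene("nope", gpr), character())
})
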