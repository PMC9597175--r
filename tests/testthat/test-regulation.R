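test_that("delta interpolates between basal-anchored and hard bounds exactly", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  sp <- ctx$ca_split
  basal <- ctx$ca_template$state$vf[["PRE"]]
  expect_gt(basal, 0)
  # delta = 0: upper bound is exactly the basal flux
  r0 <- apply_gene_regulation(sp, ctx$ca_gpr, ctx$ca_template,
                              regulation_targets("Gpre", "down", 0))
  expect_identical(r0$vf_ub[["PRE"]], basal)
  expect_identical(r0$vf_lb[["PRE"]], sp$vf_lb[["PRE"]])
  # delta = 1: pinned to the lower bound
  r1 <- apply_gene_regulation(sp, ctx$ca_gpr, ctx$ca_template,
                              regulation_targets("Gpre", "down", 1))
  expect_identical(r1$vf_ub[["PRE"]], sp$vf_lb[["PRE"]])
  # up-regulation mirrors: delta = 1 pins the floor at the upper bound
  r2 <- apply_gene_regulation(sp, ctx$ca_gpr, ctx$ca_template,
                              regulation_targets("Gpre", "up", 1))
  expect_identical(r2$vf_lb[["PRE"]], sp$vf_ub[["PRE"]])
  # delta = 0.5 sits at the midpoint of basal and bound
  r3 <- apply_gene_regulation(sp, ctx$ca_gpr, ctx$ca_template,
                              regulation_targets("Gpre", "down", 0.5))
  expect_equal(r3$vf_ub[["PRE"]], 0.5 * basal + 0.5 * sp$vf_lb[["PRE"]])
})

test_that("knockout of a non-buffered reaction fixes both directions at zero", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  r <- apply_gene_regulation(ctx$ca_split, ctx$ca_gpr, ctx$ca_template,
                             regulation_targets("Gpre"))
  expect_identical(unname(c(r$vf_lb[["PRE"]], r$vf_ub[["PRE"]],
                            r$vb_lb[["PRE"]], r$vb_ub[["PRE"]])),
                   c(0, 0, 0, 0))
  expect_equal(nrow(r$conflicts), 0L)
})

test_that("isozyme-buffered knockout pins flux to the 3% basal window", {
  m <- buffered_model()
  gpr <- build_gpr_model(m)
  expect_true("riz" %in% gpr$isozyme_rxns)
  tpl <- compute_template(m, gpr, "biomass")
  basal <- tpl$state$vf[["riz"]]
  expect_equal(basal, 1, tolerance = 1e-6)
  reg <- apply_gene_regulation(split_reversible(m), gpr, tpl,
                               regulation_targets("Giz1"))
  # exact relative to the basal template flux, and 0.97/1.03 nominally
  expect_identical(reg$vf_lb[["riz"]], 0.97 * basal)
  expect_identical(reg$vf_ub[["riz"]], 1.03 * basal)
  expect_equal(reg$vf_lb[["riz"]], 0.97, tolerance = 1e-6)
  expect_equal(reg$vf_ub[["riz"]], 1.03, tolerance = 1e-6)
  # a custom flux ratio widens the window accordingly
  reg2 <- apply_gene_regulation(split_reversible(m), gpr, tpl,
                                regulation_targets("Giz1"), epsilon = 0.1)
  expect_equal(unname(c(reg2$vf_lb[["riz"]], reg2$vf_ub[["riz"]])),
               c(0.9, 1.1), tolerance = 1e-6)
  # targeting both isozymes removes the buffer: hard knockout
  reg3 <- apply_gene_regulation(split_reversible(m), gpr, tpl,
                                regulation_targets(c("Giz1", "Giz2")))
  expect_identical(unname(c(reg3$vf_lb[["riz"]], reg3$vf_ub[["riz"]])), c(0, 0))
})

test_that("metabolite knockout zeroes exactly the producing directions", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  S <- ctx$ca$stoich
  # lip[c] is produced by the two lipid routes
  producers <- colnames(S)[S["lip[c]", ] > 0]
  expect_setequal(producers, c("LIP1", "LIP2"))
  r <- apply_metabolite_regulation(ctx$ca_split, ctx$ca_template,
                                   regulation_targets("lip[c]"))
  expect_equal(unname(r$vf_ub[producers]), c(0, 0))
  expect_setequal(r$regulated, producers)
  # non-producing directions untouched
  expect_identical(r$vf_ub[["GLY"]], ctx$ca_split$vf_ub[["GLY"]])
})

test_that("metabolite up-regulation with delta = 1 pins producers at their ceiling", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  r <- apply_metabolite_regulation(ctx$ca_split, ctx$ca_template,
                                   regulation_targets("lip[c]", "up", 1))
  expect_identical(r$vf_lb[["LIP1"]], ctx$ca_split$vf_ub[["LIP1"]])
  expect_identical(r$vf_lb[["LIP2"]], ctx$ca_split$vf_ub[["LIP2"]])
})

test_that("a metabolite without producers warns and leaves bounds untouched", {
  m <- chain_model(orphan_consumer = TRUE)
  gpr <- build_gpr_model(m)
  tpl <- compute_template(m, gpr, "biomass")
  sp <- split_reversible(m)
  expect_warning(
    r <- apply_metabolite_regulation(sp, tpl, regulation_targets("C[c]")),
    "no producing reaction")
  expect_identical(r$vf_ub, sp$vf_ub)
  expect_error(apply_metabolite_regulation(sp, tpl,
                                           regulation_targets("nope[c]")),
               class = "actd_lookup_error")
})

test_that("contradictory targets mark the scheme infeasible instead of crashing", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  # up-regulating the backward direction floor vs a forward pin cannot clash
  # here, so force a clash: knockout plus full up-regulation of one reaction
  tg <- dplyr::bind_rows(regulation_targets("Gpre", "up", 1),
                         regulation_targets("Gpre", "knockout"))
  r <- apply_gene_regulation(ctx$ca_split, ctx$ca_gpr, ctx$ca_template, tg)
  expect_gt(nrow(r$conflicts), 0L)
  row <- evaluate_targets(ctx, tg)
  expect_equal(row$ca_status, "infeasible")
  expect_equal(row$eta_tr, 1)  # mortality reading of an incoherent CA scheme
  expect_error(apply_gene_regulation(ctx$ca_split, ctx$ca_gpr,
                                     ctx$ca_template,
                                     regulation_targets("NOPE")),
               class = "actd_lookup_error")
})
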