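test_that("FBA recovers the hand-computed bottleneck of a linear chain", {
  m <- chain_model(cap = 10)
  sp <- split_reversible(m)
  st <- solve_fba(sp, "biomass")
  expect_equal(st$status, "optimal")
  expect_equal(st$objective_value, 10, tolerance = 1e-9)
  expect_equal(unname(st$vf[c("upt", "r1", "r2")]), c(10, 10, 10),
               tolerance = 1e-8)
  # objective flux always within its own bounds
  expect_gte(st$v_biomass, m$reactions$lb[m$reactions$id == "r2"] - 1e-9)
  expect_lte(st$v_biomass, m$reactions$ub[m$reactions$id == "r2"] + 1e-9)
})

test_that("FBA agrees with an independent simplex oracle", {
  m <- chain_model(cap = 7.5)
  sp <- split_reversible(m)
  nb <- net_bounds(sp)
  ours <- solve_fba(sp, "biomass")$objective_value
  theirs <- oracle_lp_max(m$stoich, nb$lb, nb$ub,
                          as.numeric(nb$id == "r2"))
  expect_equal(ours, theirs, tolerance = 1e-7)

  # the larger fixture model is too degenerate for the pure-R simplex, so the
  # second opinion comes from an interior-point/HiGHS solver instead
  toy <- shared_toy(1)
  spc <- split_reversible(toy$toy$ca)
  nbc <- net_bounds(spc)
  ours2 <- solve_fba(spc, "biomass")$objective_value
  theirs2 <- oracle_lp_scipy(toy$toy$ca$stoich, nbc$lb, nbc$ub,
                             as.numeric(nbc$id == "BIOMASS"))
  expect_equal(ours2, theirs2, tolerance = 1e-6)
})

test_that("silencing the only path drives the chain objective to zero; a cut maintenance demand is infeasible", {
  m <- chain_model(cap = 10)
  sp <- split_reversible(m)
  sp$vf_ub[["r1"]] <- 0
  st <- solve_fba(sp, "biomass")
  expect_true(st$status == "infeasible" || abs(st$v_biomass) < 1e-9)
  m2 <- parallel_model(demand = 10)  # demand floor forced at 10
  sp2 <- split_reversible(m2)
  sp2$vf_ub[["p1"]] <- 0
  sp2$vf_ub[["p2"]] <- 0
  expect_equal(solve_fba(sp2, "biomass")$status, "infeasible")
})

test_that("the flux-distribution program splits parallel paths by inverse weights", {
  # equal weights: symmetric 5/5 split (KKT of min c(x^2+y^2) s.t. x+y=10)
  m <- parallel_model("other", "other", demand = 10)
  gpr <- build_gpr_model(m)
  st <- solve_ufd(split_reversible(m), gpr$weights,
                  floor = list(objective = "biomass", value = 10))
  expect_equal(unname(st$vf[c("p1", "p2")]), c(5, 5), tolerance = 1e-6)
  # weights 1/4 vs 1: x = 10 * (1/cx) / (1/cx + 1/cy) = 8
  m2 <- parallel_model("high", "other", demand = 10)
  gpr2 <- build_gpr_model(m2)
  expect_equal(unname(gpr2$weights[c("p1", "p2")]), c(0.25, 1))
  st2 <- solve_ufd(split_reversible(m2), gpr2$weights,
                   floor = list(objective = "biomass", value = 10))
  expect_equal(unname(st2$vf[c("p1", "p2")]), c(8, 2), tolerance = 1e-6)
})

test_that("the quadratic optimum matches a dense-grid brute-force oracle", {
  cases <- list(list("other", "other", c(5, 5)),
                list("high", "other", c(8, 2)),
                list("medium", "negative", NULL))
  for (cs in cases) {
    m <- parallel_model(cs[[1]], cs[[2]], demand = 10)
    gpr <- build_gpr_model(m)
    st <- solve_ufd(split_reversible(m), gpr$weights,
                    floor = list(objective = "biomass", value = 10))
    oracle <- grid_ufd_oracle(m, gpr$weights, 10, n_grid = 201)
    expect_lte(st$objective_value, oracle + 1e-6)
    # grid step 0.5 contains the analytic optimum for the first two cases
    if (!is.null(cs[[3]])) {
      expect_equal(st$objective_value, oracle, tolerance = 1e-6)
      expect_equal(unname(st$vf[c("p1", "p2")]), cs[[3]], tolerance = 1e-6)
    }
  }
})

test_that("with equal weights the floored flux state is the minimum-norm optimum", {
  m <- parallel_model("other", "other", demand = 10)
  gpr <- build_gpr_model(m)
  st <- solve_ufd(split_reversible(m), gpr$weights,
                  floor = list(objective = "biomass", value = 10))
  oracle <- grid_ufd_oracle(m, gpr$weights, 10, n_grid = 201)
  expect_equal(st$objective_value, oracle, tolerance = 1e-6)
})

test_that("optimal states satisfy steady state and bounds within 1e-8", {
  toy <- shared_toy(1)
  for (which in c("ca", "ht")) {
    tpl <- toy$ctx[[paste0(which, "_template")]]
    st <- tpl$state
    model <- tpl$split$base
    expect_lt(max(abs(as.numeric(model$stoich %*% (st$vf - st$vb)))), 1e-8)
    expect_true(all(st$vf >= tpl$split$vf_lb - 1e-8))
    expect_true(all(st$vf <= tpl$split$vf_ub + 1e-8))
    expect_true(all(st$vb >= tpl$split$vb_lb - 1e-8))
    expect_true(all(st$vb <= tpl$split$vb_ub + 1e-8))
    expect_gte(st$v_biomass * (which == "ca") + st$v_atp * (which == "ht"),
               tpl$floor - 1e-7 * max(1, abs(tpl$floor)))
  }
})

test_that("templates are deterministic across recomputation", {
  toy <- shared_toy(1)
  t1 <- compute_template(toy$toy$ca, toy$ctx$ca_gpr, "biomass")
  t2 <- compute_template(toy$toy$ca, toy$ctx$ca_gpr, "biomass")
  expect_identical(t1$state$vf, t2$state$vf)
  expect_identical(t1$state$vb, t2$state$vb)
  expect_identical(t1$opt_value, t2$opt_value)
})

test_that("tightening down-regulation never increases the achievable optimum", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  prev <- Inf
  for (delta in c(0, 0.25, 0.5, 0.75, 1)) {
    reg <- apply_gene_regulation(ctx$ca_split, ctx$ca_gpr, ctx$ca_template,
                                 regulation_targets("Gpre", "down", delta))
    st <- solve_fba(reg, "biomass")
    val <- if (st$status == "optimal") st$objective_value else 0
    expect_lte(val, prev + 1e-8)
    prev <- val
  }
})

test_that("knocking out a non-buffered essential enzyme kills growth", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  reg <- apply_gene_regulation(ctx$ca_split, ctx$ca_gpr, ctx$ca_template,
                               regulation_targets(toy$toy$truth$ideal_target))
  st <- solve_fba(reg, "biomass")
  expect_true(st$status == "infeasible" || st$objective_value < 1e-8)
})
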