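test_that("one-sided memberships hit their endpoints and ramp linearly", {
  expect_equal(grade_min(2, 2, 6), 1)
  expect_equal(grade_min(6, 2, 6), 0)
  expect_equal(grade_min(0.5, 0, 1), 0.5)
  expect_equal(grade_min(5, 2, 6), 0.25)   # (6 - 5) / (6 - 2)
  expect_equal(grade_max(10, 0, 10), 1)
  expect_equal(grade_max(2.5, 0, 10), 0.25)
  expect_error(grade_min(1, 5, 2), class = "actd_spec_error")
})

test_that("two-sided membership peaks at the standard level and dies at the ramps", {
  expect_equal(grade_two_sided(4, 0, 4, 10), 1)
  expect_equal(grade_two_sided(0, 0, 4, 10), 0)
  expect_equal(grade_two_sided(10, 0, 4, 10), 0)
  expect_equal(grade_two_sided(7, 0, 4, 10), 0.5)  # (10 - 7) / (10 - 4)
  expect_equal(grade_two_sided(-3, 0, 4, 10), 0)
  expect_equal(grade_two_sided(40, 0, 4, 10), 0)
  expect_error(grade_two_sided(1, 0, 11, 10), class = "actd_spec_error")
})

test_that("the mean-min operator reproduces the published worked example", {
  expect_equal(mean_min(c(1, 0)), 0.25)
  expect_equal(mean_min(c(0.5, 0.5)), 0.5)
  expect_equal(mean_min(c(0.4, 0.6)), 0.45)
  expect_equal(mean_min(c(0.8, 0.6, 1.0, 0.6)), 0.675)
  expect_error(mean_min(numeric()), class = "actd_domain_error")
})

test_that("membership algebra holds under randomized specs", {
  withr::with_seed(99, {
    for (i in 1:500) {
      b <- sort(runif(3, -10, 10))
      fv <- runif(1, -20, 20)
      gmin <- grade_min(fv, b[1], b[3])
      gmax <- grade_max(fv, b[1], b[3])
      g2 <- grade_two_sided(fv, b[1], b[2], b[3])
      expect_true(all(c(gmin, gmax, g2) >= 0 & c(gmin, gmax, g2) <= 1))
      if (fv >= b[1] && fv <= b[3]) {
        expect_equal(gmin + gmax, 1)  # complement identity on the ramp
      }
      # similarity and dissimilarity of one element always sum to 1
      expect_equal(g2 + (1 - g2), 1)
      g <- runif(sample(1:6, 1))
      expect_lte(mean_min(g), mean(g) + 1e-12)
      if (stats::sd(c(g, g[1])) > 1e-12) {
        expect_lt(mean_min(g), mean(g))
      } else {
        expect_equal(mean_min(g), mean(g))
      }
      # hierarchical objective: bounded by the mortality grade, monotone in
      # the other two
      tr <- runif(1); cv <- runif(1); md <- runif(1)
      d <- decision_grade(tr, cv, md)
      expect_lte(d, tr + 1e-12)
      expect_lte(decision_grade(tr, cv * 0.5, md), d + 1e-12)
      expect_lte(decision_grade(tr, cv, md * 0.5), d + 1e-12)
    }
  })
})

test_that("the decision grade reproduces hand-computed hierarchies", {
  expect_equal(decision_grade(0.668, 0.751, 0.682), 0.668)
  expect_equal(decision_grade(0.9, 0.3, 0.8), 0.6)
  for (g in c(0, 0.31, 1)) expect_equal(decision_grade(g, g, g), g)
})

test_that("flow rates pool compartment production with the literal backward-term sign", {
  # one producer with coefficient 1 and forward flux 2
  m1 <- chain_model()
  st <- list(vf = c(upt = 2, r1 = 2, r2 = 2), vb = c(upt = 0, r1 = 0, r2 = 0))
  r <- flow_rates(st, m1)
  expect_equal(unname(r["B"]), 2)
  # producer N = +2 at vf = 3 plus reversible consumer N = -1 run backward at
  # vb = 1: r = 2*3 - (-1)*1 = 7
  rows <- tibble::tibble(id = c("make", "use"), lb = c(0, -10), ub = c(10, 10),
                         gpr = "")
  stoich <- tibble::tibble(reaction = c("make", "use"),
                           metabolite = c("X[c]", "X[c]"),
                           coefficient = c(2, -1))
  m2 <- metnet_model(tibble::tibble(id = "X[c]"), rows, stoich, "make", "make")
  st2 <- list(vf = c(make = 3, use = 0), vb = c(make = 0, use = 1))
  expect_equal(unname(flow_rates(st2, m2)["X"]), 7)
  # the same base metabolite in two compartments pools: 1.5 + 0.5 = 2
  rows3 <- tibble::tibble(id = c("pc", "pm"), lb = 0, ub = 10, gpr = "")
  stoich3 <- tibble::tibble(reaction = c("pc", "pm"),
                            metabolite = c("X[c]", "X[m]"),
                            coefficient = c(1, 1))
  m3 <- metnet_model(tibble::tibble(id = c("X[c]", "X[m]")), rows3, stoich3,
                     "pc", "pc")
  st3 <- list(vf = c(pc = 1.5, pm = 0.5), vb = c(pc = 0, pm = 0))
  expect_equal(unname(flow_rates(st3, m3)["X"]), 2)
})

test_that("deviation grading scores the unperturbed healthy state as fully similar", {
  toy <- shared_toy(1)
  ctx <- toy$ctx
  md <- deviation_grade(ctx$ht_template$state, ctx$ca_template,
                        ctx$ht_template)
  expect_equal(md$eta_f_bl, 1)
  expect_equal(md$eta_m_bl, 1)
  expect_true(md$eta_md >= 0 && md$eta_md <= 1)
  # a state equal to the cancer template carries zero dissimilarity reward on
  # every matched element, capping the deviation grade at half its mean term
  md2 <- deviation_grade(ctx$ca_template$state, ctx$ca_template,
                         ctx$ht_template)
  expect_equal(md2$eta_f_ca, 0)
  expect_equal(md2$eta_m_ca, 0)
  expect_equal(md2$eta_md,
               mean(c(md2$eta_f_ca, md2$eta_m_ca, md2$eta_f_bl, md2$eta_m_bl)) / 2)
  expect_lt(md2$eta_md, md$eta_md)
})

test_that("grade assembly respects the mortality-first hierarchy on real evaluations", {
  toy <- shared_toy(1)
  sc <- evaluate_targets(toy$ctx, regulation_targets(toy$toy$truth$ideal_target))
  expect_equal(sc$eta_tr, mean_min(c(sc$eta_biomass_tr, sc$eta_atp_tr)))
  expect_equal(sc$eta_cv, mean_min(c(sc$eta_biomass_pb, sc$eta_atp_pb)))
  expect_equal(sc$eta_md, mean_min(c(sc$eta_f_ca, sc$eta_m_ca,
                                     sc$eta_f_bl, sc$eta_m_bl)))
  expect_equal(sc$eta_d, decision_grade(sc$eta_tr, sc$eta_cv, sc$eta_md))
  expect_lte(sc$eta_d, sc$eta_tr)
  grades <- unlist(sc[, grep("^eta_", names(sc))])
  expect_true(all(grades >= 0 & grades <= 1))
})
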