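test_that("pure synthesis drives empty state at the synthesis rates", {
  p <- mmi_parameters(2, s_r = 0.7)
  expect_equal(unname(reduced_rhs(c(0, 0), p)), c(1, 0.7))
  n <- p$n_sites
  d <- full_rhs(rep(0, n + 2), p, kon = 100)
  expect_equal(unname(d), c(1, 0.7, rep(0, n)))
})

test_that("reduced derivatives vanish at computed fixed points", {
  p <- fixture("rep_coop_mrna")
  bd <- bifurcation_diagram(p, c(0, 1))
  s_mid <- mean(bd$bistable_interval)
  st <- steady_states_at(p, s_mid)
  for (k in seq_len(nrow(st))) {
    d <- reduced_rhs(c(st$R_T[k], st$r_T[k]), p, s_r = s_mid)
    expect_true(all(abs(d) < 1e-8))
  }
})

test_that("balanced kinetics reduce exactly to linear sequestration dynamics", {
  # with all degradation multipliers 1 the totals obey dR_T = s_R - k_R R_T
  # and dr_T = s_r - k_r r_T regardless of the binding state
  p <- mmi_parameters(2, a = c(1, 1), b = c(1, 1), s_r = 0.8)
  set.seed(11)
  for (k in 1:25) {
    RT <- runif(1, 0, 3); rT <- runif(1, 0, 3)
    d <- reduced_rhs(c(RT, rT), p)
    expect_rel_equal(d[1], 1 - RT, tol = 1e-8)
    expect_rel_equal(d[2], 0.8 - rT, tol = 1e-8)
  }
})

test_that("binding alone conserves both totals in the full model", {
  p <- mmi_parameters(2, a = c(1, 1), b = c(1, 1))
  p$s_R <- 0; p$s_r <- 0; p$k_R <- 1e-300; p$k_r <- 1e-300
  y0 <- c(0.5, 0.8, 0.1, 0.05)
  out <- deSolve::ode(y = y0, times = c(0, 10),
                      func = function(t, y, q) list(full_rhs(y, p, kon = 10)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  fin <- out[nrow(out), -1]
  expect_rel_equal(fin[1] + fin[3] + fin[4], 0.65, tol = 1e-7)
  expect_rel_equal(fin[2] + fin[3] + 2 * fin[4], 1.0, tol = 1e-7)
})

test_that("full and reduced models agree at fast binding", {
  p <- fixture("rep_coop_mrna")
  bd <- bifurcation_diagram(p, c(0, 1))
  s_mid <- mean(bd$bistable_interval)
  p$s_r <- s_mid
  st <- steady_states_at(p, s_mid)
  st <- st[st$stability == "stable_node_or_focus", ]
  for (k in seq_len(nrow(st))) {
    y0 <- c(st$R[k], st$r[k], st$C1[k], st$C2[k])
    out <- deSolve::ode(y = y0, times = seq(0, 50, 10),
                        func = function(t, y, q) list(full_rhs(y, p, kon = 1e8)),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-16)
    fin <- out[nrow(out), -1]
    RT <- fin[1] + fin[3] + fin[4]
    rT <- fin[2] + fin[3] + 2 * fin[4]
    expect_rel_equal(RT, st$R_T[k], tol = 0.01)
    expect_rel_equal(rT, st$r_T[k], tol = 0.01)
  }
})

test_that("null competitor collapses exactly to the base circuit", {
  p <- fixture("rep_coop_mrna")
  m <- build_competitor_model(p, competitor_parameters(s_R2 = 0))
  for (st in list(c(1, 0, 0.5), c(0.2, 0, 1.2), c(2, 0, 0.05))) {
    d3 <- m$rhs(st, s_r = 0.27)
    d2 <- reduced_rhs(st[c(1, 3)], p, s_r = 0.27)
    expect_rel_equal(d3[c(1, 3)], d2, tol = 1e-6)
  }
})

test_that("a weak competitor preserves bistability of the base circuit", {
  p <- fixture("rep_coop_mrna")
  m <- build_competitor_model(p, competitor_parameters(s_R2 = 0.1 * p$s_R,
                                                       n_sites2 = 1L))
  expect_true(competitor_bistable(m))
})

test_that("a very strong competitor suppresses free miRNA monotonically", {
  p <- fixture("rep_coop_mrna")
  m <- build_competitor_model(p, competitor_parameters(s_R2 = 100, n_sites2 = 1L))
  # free miRNA at equilibrium decreases as competitor totals grow
  r_vals <- vapply(c(1, 10, 100), function(RT2)
    m$equilibrium(c(0.5, RT2, 1))$r, numeric(1))
  expect_true(all(diff(r_vals) < 0))
})
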