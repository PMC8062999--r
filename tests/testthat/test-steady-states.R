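test_that("the three representative parameter sets are bistable switches", {
  # cooperative mRNA degradation, cooperative miRNA degradation, and
  # target-directed miRNA degradation all give an S-shaped response with two
  # nodes and a saddle inside the fold interval
  for (nm in c("rep_coop_mrna", "rep_coop_mirna", "rep_tdmd")) {
    p <- fixture(nm)
    bd <- bifurcation_diagram(p, c(0, 4))
    expect_false(is.null(bd$bistable_interval), label = nm)
    st <- steady_states_at(p, mean(bd$bistable_interval))
    expect_identical(nrow(st), 3L)
    expect_identical(sum(st$stability == "stable_node_or_focus"), 2L)
    expect_identical(sum(st$stability == "saddle"), 1L)
  }
})

test_that("balanced kinetics give a single stable state at any control value", {
  p <- mmi_parameters(2, a = c(1, 1), b = c(1, 1))
  for (s in c(0.1, 0.5, 1, 2, 4)) {
    st <- steady_states_at(p, s)
    expect_identical(nrow(st), 1L)
    expect_identical(st$stability, "stable_node_or_focus")
  }
})

test_that("control inversion is consistent with root extraction", {
  p <- fixture("rep_coop_mrna")
  for (r in c(1e-6, 1e-5, 1e-3, 0.05)) {
    s <- control_at_steady_state(r, p)
    st <- steady_states_at(p, s)
    expect_true(any(abs(st$r - r) < 1e-6 * max(r, 1e-12)))
  }
  # r -> 0 implies vanishing miRNA synthesis
  expect_lt(control_at_steady_state(1e-12, p), 1e-5)
})

test_that("the bistable control curve has exactly two interior extrema", {
  p <- fixture("rep_coop_mrna")
  xs <- mmiswitch:::.curve_extrema(p)
  expect_identical(length(xs), 2L)
  # numeric derivative changes sign at each extremum
  K <- p$K_scaled
  for (x in xs) {
    h <- function(z) control_at_steady_state(K * z, p)
    d1 <- h(x * 1.001) - h(x)
    d0 <- h(x) - h(x * 0.999)
    expect_lt(d0 * d1, 0)
  }
})

test_that("polynomial fixed points match the integration oracle", {
  set.seed(99)
  n_checked <- 0
  for (k in 1:25) {
    p <- mmi_parameters(2, a = runif(2, 0.125, 16), b = runif(2, 0.125, 16))
    bd <- bifurcation_diagram(p, c(0, 10), resolution = 50)
    s_probe <- if (is.null(bd$bistable_interval)) 1 else
      mean(bd$bistable_interval)
    st <- steady_states_at(p, s_probe)
    stable <- st[st$stability == "stable_node_or_focus", ]
    inits <- rbind(c(1.5, 1e-3), c(1e-3, 1.5 * max(s_probe, 0.2)),
                   c(0.5, 0.5))
    n_att <- census_attractors(p, s_probe, inits)
    expect_identical(n_att, nrow(stable),
                     label = sprintf("set %d (a=%.3g,%.3g b=%.3g,%.3g)", k,
                                     p$a[1], p$a[2], p$b[1], p$b[2]))
    n_checked <- n_checked + 1
  }
  expect_identical(n_checked, 25)
})

test_that("folds are stationary points with a vanishing leading eigenvalue", {
  p <- fixture("rep_coop_mrna")
  bd <- bifurcation_diagram(p, c(0, 4))
  expect_identical(nrow(bd$folds), 2L)
  for (k in 1:2) {
    r_f <- bd$folds$r[k]
    h <- function(z) control_at_steady_state(z, p)
    num_d <- (h(r_f * (1 + 1e-5)) - h(r_f * (1 - 1e-5))) / (2e-5 * r_f)
    expect_lt(abs(num_d) / max(abs(h(r_f)), 1e-12), 1e-3)
    st <- steady_states_at(p, bd$folds$control_value[k], degenerate_tol = 1e-4)
    expect_true(any(st$degenerate) ||
                  min(abs(st$leading_eigenvalue_real_part)) < 1e-2)
  }
})

test_that("positive fixed point count never exceeds n_sites + 1", {
  set.seed(123)
  for (k in 1:40) {
    n <- sample(2:3, 1)
    p <- mmi_parameters(n, a = runif(n, 0.125, 16), b = runif(n, 0.125, 16))
    st <- steady_states_at(p, runif(1, 0.05, 5))
    expect_lte(nrow(st), n + 1)
  }
})

test_that("mRNA-synthesis control traces the mirrored switch", {
  p <- fixture("rep_coop_mrna")
  p$s_r <- 0.27
  bd <- bifurcation_diagram(p, c(0, 3), control = "s_R")
  expect_false(is.null(bd$bistable_interval))
  st <- steady_states_at(p, mean(bd$bistable_interval), control = "s_R")
  expect_identical(sum(st$stability == "stable_node_or_focus"), 2L)
})
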