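test_that("parameter sampling is reproducible and respects its bounds", {
  m1 <- sample_parameters(500, 0.125, 16, 2, seed = 5)
  m2 <- sample_parameters(500, 0.125, 16, 2, seed = 5)
  expect_identical(m1, m2)
  expect_identical(dim(m1), c(500L, 4L))
  expect_true(all(m1 > 0.125 & m1 < 16))
  m3 <- sample_parameters(500, 0.125, 16, 2, seed = 6)
  expect_false(identical(m1, m3))
  # near-degenerate interval
  m4 <- sample_parameters(1, 1 - 1e-9, 1, 2, seed = 1)
  expect_true(all(abs(m4 - 1) < 1e-8))
  expect_error(sample_parameters(10, 2, 1), "low")
})

test_that("the analytic two-site condition matches its definition", {
  expect_true(analytic_condition(fixture("rep_coop_mrna")))
  expect_false(analytic_condition(mmi_parameters(2, a = c(1, 1), b = c(1, 1))))
  expect_error(analytic_condition(mmi_parameters(1)), "2-site")
})

test_that("every bistable two-site record satisfies the analytic condition", {
  sc <- run_screen(n_sites = 2, n = 2000, seed = 77, metrics = TRUE)
  rec <- sc$records
  cond <- rec$a1 / rec$b1 < rec$a2 / (2 * rec$b2)
  expect_true(all(cond[rec$bistable]))
  # the converse need not hold: some condition-satisfying sets stay
  # monostable in the observable window at finite K
  expect_true(any(cond & !rec$bistable))
})

test_that("closed-form classification agrees with the attractor census", {
  set.seed(31)
  for (k in 1:12) {
    a <- runif(2, 0.125, 16); b <- runif(2, 0.125, 16)
    p <- mmi_parameters(2, a = a, b = b)
    rec <- classify_bistable(p)
    if (rec$bistable) {
      iv <- mmiswitch:::.multistable_intervals(p)
      s_probe <- mean(iv[1, ])
      inits <- rbind(c(1.5, 1e-3), c(1e-3, 1.5 * max(s_probe, 0.2)))
      expect_gte(census_attractors(p, s_probe, inits), 2)
    } else {
      for (s_probe in c(0.3, 1, 3)) {
        inits <- rbind(c(1.5, 1e-3), c(1e-3, 1.5 * max(s_probe, 0.2)))
        expect_identical(census_attractors(p, s_probe, inits), 1L)
      }
    }
  }
})

test_that("bistable records report wide free-mRNA but small total-mRNA switches", {
  sc <- run_screen(n_sites = 2, n = 2000, seed = 78, metrics = TRUE)
  b <- sc$records[sc$records$bistable, ]
  expect_gt(nrow(b), 400)
  expect_gt(mean(b$free_mrna_drop_log10 > 3, na.rm = TRUE), 0.5)
  expect_gt(mean(abs(b$total_mrna_change_log10) < 1, na.rm = TRUE), 0.5)
  expect_lt(sc$n_failed / sc$n_total, 0.001)
})

test_that("bistability imposes no additional constraint on single multipliers", {
  sc <- run_screen(n_sites = 2, n = 4000, seed = 79, metrics = FALSE)
  b <- sc$records[sc$records$bistable, ]
  for (col in c("a1", "a2", "b1", "b2")) {
    span <- diff(range(b[[col]])) / (16 - 0.125)
    expect_gt(span, 0.9)
  }
})

test_that("the one-site circuit is never bistable", {
  sc <- run_screen(n_sites = 1, n = 1000, seed = 80,
                   low = 0.01, high = 100, log_uniform = TRUE,
                   metrics = FALSE)
  expect_identical(sc$n_bistable, 0L)
  # spot-check: a single positive steady state at several control values
  set.seed(81)
  for (k in 1:10) {
    p <- mmi_parameters(1, a = 10^runif(1, -2, 2), b = 10^runif(1, -2, 2))
    for (s in c(0.2, 1, 5)) expect_identical(nrow(steady_states_at(p, s)), 1L)
  }
})

test_that("the bisected degradation-ratio threshold matches theory", {
  expect_rel_equal(critical_ratio(1, 1), 2, tol = 0.01)
  expect_rel_equal(critical_ratio(2, 1), 4, tol = 0.01)
  expect_rel_equal(critical_ratio(1, 2), 1, tol = 0.01)
})
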