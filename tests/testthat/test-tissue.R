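# Tissue-level simulations. Runs use dt = 0.05 and the default 60-unit
# horizon; the methods vignette records these as the package's standard
# problem sizes.

wt_field <- function(seed = 3L, sigma = 0.1)
  make_morphogen_field(noise_sigma = sigma, seed = seed)

majority_fate <- function(ts) {
  lab <- fate_calls(ts)
  apply(matrix(lab, nrow = ts$n_cols), 2,
        function(v) names(which.max(table(v))))
}

test_that("wild-type patterning: exclusive protein fates over overlapping mRNAs", {
  ts <- simulate_tissue(cell_model_spec("mmi_S"), wt_field(), t_end = 60,
                        dt = 0.05, seed = 3)
  lab <- fate_calls(ts)
  expect_identical(sum(lab == "double_on"), 0L)
  pf <- majority_fate(ts)
  # rostral block of Hoxa5-only fates, caudal block of Hoxc8-only fates
  expect_true(all(pf[1:8] == "A5on_C8off"))
  expect_true(all(pf[15:40] == "A5off_C8on"))
  # total mRNAs co-expressed in a contiguous band spanning the boundary
  mA <- tissue_profile(ts, "mrna", "Hoxa5")
  mC <- tissue_profile(ts, "mrna", "Hoxc8")
  both <- mA > 0.1 * max(mA) & mC > 0.1 * max(mC)
  expect_true(all(both[5:25]))
  # protein boundary sharper than the mRNA boundary
  expect_gt(segregation_index(ts), 1)
})

test_that("the cross-repression benchmark keeps protein and mRNA congruent", {
  ts <- simulate_tissue(cell_model_spec("T_CR"), wt_field(), t_end = 60,
                        dt = 0.05, seed = 3)
  expect_lt(abs(segregation_index(ts) - 1), 0.2)
})

test_that("miR-27 knockout de-represses Hoxa5 caudally into double-positives", {
  ko <- knockout(cell_model_spec("mmi_S"), "miR-27")
  ts <- simulate_tissue(ko, wt_field(), t_end = 60, dt = 0.05, seed = 3)
  lab <- fate_calls(ts)
  caudal <- ts$position >= 25
  expect_gt(mean(lab[caudal] == "double_on"), 0.5)
})

test_that("miR-196 knockout shifts the protein boundary rostrally", {
  first_c8 <- function(ts) {
    pf <- majority_fate(ts)
    match("A5off_C8on", pf)
  }
  wt <- simulate_tissue(cell_model_spec("mmi_S"), wt_field(), 60, 0.05, seed = 3)
  ko <- simulate_tissue(knockout(cell_model_spec("mmi_S"), "miR-196"),
                        wt_field(), 60, 0.05, seed = 3)
  expect_lt(first_c8(ko), first_c8(wt))
})

test_that("knockouts are idempotent and rejected for miRNA-free variants", {
  ko1 <- knockout(cell_model_spec("mmi_S"), "miR-27")
  ko2 <- knockout(ko1, "miR-27")
  expect_identical(ko1$params, ko2$params)
  expect_error(knockout(cell_model_spec("T_CR"), "miR-27"), "no miRNA")
  expect_error(knockout(cell_model_spec("mmi_S"), "miR-999"), "unknown")
})

test_that("without morphogen drive all cells stay double-negative", {
  f <- make_morphogen_field(noise_sigma = 0,
                            amplitude = list(A_max = 0, A_low = 0))
  ts <- simulate_tissue(cell_model_spec("mmi_S"), f, t_end = 40, dt = 0.05)
  expect_true(all(fate_calls(ts) == "double_off"))
})

test_that("deterministic runs are bitwise reproducible", {
  f <- make_morphogen_field(noise_sigma = 0, seed = 2)
  t1 <- simulate_tissue(cell_model_spec("T_UR"), f, 30, 0.05, seed = 2)
  t2 <- simulate_tissue(cell_model_spec("T_UR"), f, 30, 0.05, seed = 2)
  expect_identical(t1$final, t2$final)
  fn <- make_morphogen_field(noise_sigma = 0.1, seed = 2)
  t3 <- simulate_tissue(cell_model_spec("T_UR"), fn, 30, 0.05, seed = 2)
  t4 <- simulate_tissue(cell_model_spec("T_UR"), fn, 30, 0.05, seed = 2)
  expect_identical(t3$final, t4$final)
})

test_that("feedback sharpens boundaries on matched noise fields", {
  # paired comparison on identical field and seed
  f <- wt_field(seed = 4)
  w <- function(v) transition_width(
    simulate_tissue(cell_model_spec(v), f, 60, 0.05, seed = 4))
  expect_lt(w("T_CR"), w("T_UR"))
  expect_lt(w("mmi_S"), w("mmi_S_nofeedback"))
})

test_that("model ranking holds in the median over seeds", {
  variants <- c("T_CR", "T_UR", "Tmi_UR", "Tmi_FB", "mmi_S")
  W <- sapply(variants, function(v) {
    vapply(1:5, function(s) {
      f <- wt_field(seed = s)
      transition_width(simulate_tissue(cell_model_spec(v), f, 60, 0.05,
                                       seed = s))
    }, numeric(1))
  })
  med <- apply(W, 2, median)
  for (good in c("T_CR", "Tmi_FB", "mmi_S")) for (bad in c("T_UR", "Tmi_UR"))
    expect_lt(med[good], med[bad])
})

test_that("only the mmi circuit keeps caudal miR-196 high at steady state", {
  f <- wt_field(seed = 2)
  caudal_frac <- function(v) {
    ts <- simulate_tissue(cell_model_spec(v), f, 60, 0.05, seed = 2)
    prof <- as.numeric(tapply(ts$final[, "miR196_total"], ts$position, mean))
    prof[ts$n_pos] / max(prof)
  }
  frac_mmi <- caudal_frac("mmi_S")
  frac_fb <- caudal_frac("Tmi_FB")
  expect_gt(frac_mmi, 0.25)
  expect_lt(frac_fb, 0.1)
  expect_gt(frac_mmi, 5 * frac_fb)
})

test_that("fate flicker under noise is confined to no-feedback models", {
  f <- wt_field(seed = 6)
  ts_fb <- simulate_tissue(cell_model_spec("mmi_S"), f, 60, 0.05, seed = 6)
  ts_nf <- simulate_tissue(cell_model_spec("mmi_S_nofeedback"), f, 60, 0.05,
                           seed = 6)
  expect_gt(transition_width(ts_nf), 3 * transition_width(ts_fb))
})
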