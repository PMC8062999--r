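test_that("the wild-type circuit is tristable over a contiguous mid-domain window", {
  pb <- positional_bifurcation(cell_model_spec("mmi_S"), make_morphogen_field())
  tp <- tristable_positions(pb)
  expect_gte(length(tp), 3)
  expect_true(all(diff(tp) == 1))
  expect_true(all(tp > 5 & tp < 35))
  # the three coexisting stable states are the two exclusive fates plus the
  # undifferentiated state
  mid <- tp[ceiling(length(tp) / 2)]
  fates <- sort(pb$fate[pb$position == mid &
                          pb$stability == "stable_node_or_focus"])
  expect_setequal(fates, c("A5off_C8on", "A5on_C8off", "double_off"))
})

test_that("miR-27 knockout replaces the caudal exclusive state with double-on", {
  ko <- knockout(cell_model_spec("mmi_S"), "miR-27")
  pb <- positional_bifurcation(ko, make_morphogen_field(), positions = 30:39)
  stable <- pb[pb$stability == "stable_node_or_focus", ]
  expect_false(any(stable$fate == "A5off_C8on"))
  expect_true(any(stable$fate == "double_on"))
})

test_that("the unilateral-repression model is monostable at every position", {
  pb <- positional_bifurcation(cell_model_spec("T_UR"), make_morphogen_field())
  ns <- tapply(pb$stability == "stable_node_or_focus", pb$position, sum)
  expect_true(all(ns == 1))
})

test_that("cross-repression yields positional bistability near the boundary", {
  pb <- positional_bifurcation(cell_model_spec("T_CR"), make_morphogen_field())
  ns <- tapply(pb$stability == "stable_node_or_focus", pb$position, sum)
  expect_gte(max(ns), 2)
})

test_that("RA pulse leaves Hoxa5 induced only when miR-27 is active", {
  wt <- ra_pulse_experiment(mir27_active = TRUE)
  expect_true(wt$hoxa5_on[["pulsed"]])
  expect_false(wt$hoxa5_on[["low_only"]])
  expect_false(is.null(wt$bistable_ra_range))
  expect_gt(log10(wt$pulsed[["free_mrna"]] / wt$low_only[["free_mrna"]]), 2)
  ko <- ra_pulse_experiment(mir27_active = FALSE)
  expect_null(ko$bistable_ra_range)
  expect_lt(abs(ko$pulsed[["free_mrna"]] - ko$low_only[["free_mrna"]]) /
              ko$low_only[["free_mrna"]], 0.01)
  # the knockout response is monotone in RA
  expect_true(all(diff(ko$bifurcation$R[order(ko$bifurcation$RA)]) >= -1e-9))
})

test_that("a below-window drive leaves the cell off or low either way", {
  rp <- ra_pulse_experiment(ra_high = 0.05, ra_low = 0.02,
                            mir27_active = TRUE)
  expect_false(rp$hoxa5_on[["low_only"]])
  expect_false(rp$hoxa5_on[["pulsed"]])
  ko <- ra_pulse_experiment(ra_high = 0.05, ra_low = 0.02,
                            mir27_active = FALSE)
  expect_lt(ko$low_only[["free_mrna"]], 0.03)
  expect_lt(ko$pulsed[["free_mrna"]], 0.03)
})
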