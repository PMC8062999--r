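test_that("textbook networks have the expected indices", {
  # single irreversible reaction A -> B
  net <- reaction_network(c("A", "B"), list(c(A = 1L), c(B = 1L)),
                          cbind(1L, 2L))
  rep <- deficiency(net)
  expect_identical(rep$n_complexes, 2L)
  expect_identical(rep$n_linkage_classes, 1L)
  expect_identical(rep$stoich_rank, 1L)
  expect_identical(rep$deficiency, 0L)
  expect_false(rep$weakly_reversible)
  # reversible binding A + B <-> C
  net2 <- reaction_network(c("A", "B", "C"),
                           list(c(A = 1L, B = 1L), c(C = 1L)),
                           rbind(c(1L, 2L), c(2L, 1L)))
  rep2 <- deficiency(net2)
  expect_identical(rep2$deficiency, 0L)
  expect_true(rep2$weakly_reversible)
})

test_that("weak reversibility distinguishes cycles from one-way arrows", {
  ab <- list(c(A = 1L), c(B = 1L))
  expect_true(weak_reversibility(
    reaction_network(c("A", "B"), ab, rbind(c(1L, 2L), c(2L, 1L)))))
  expect_false(weak_reversibility(
    reaction_network(c("A", "B"), ab, cbind(1L, 2L))))
})

test_that("the canonical one-site circuit network has the documented structure", {
  net <- build_network(mmi_parameters(1))
  expect_setequal(net$species, c("R", "r", "C1"))
  expect_setequal(net$keys, c("0", "R", "r", "R+r", "C1"))
  expect_identical(nrow(net$reactions), 4L + 2L + 2L)
  rep <- deficiency(net)
  expect_identical(rep$n_complexes, 5L)
  expect_identical(rep$n_linkage_classes, 1L)
  expect_identical(rep$stoich_rank, 3L)
  expect_identical(rep$deficiency, 1L)
  expect_false(rep$weakly_reversible)
})

test_that("reaction counts scale as 4 + 4 n across site numbers", {
  for (n in 1:3) {
    net <- build_network(mmi_parameters(n))
    expect_identical(nrow(net$reactions), 4L + 4L * n)
    expect_gte(deficiency(net)$deficiency, 0L)
  }
})

test_that("deficiency is invariant under species and reaction reordering", {
  net <- build_network(mmi_parameters(2))
  rep <- deficiency(net)
  perm <- rev(seq_along(net$species))
  net2 <- reaction_network(net$species[perm], net$complexes,
                           net$reactions[rev(seq_len(nrow(net$reactions))), ])
  rep2 <- deficiency(net2)
  expect_identical(rep2$deficiency, rep$deficiency)
  expect_identical(rep2$stoich_rank, rep$stoich_rank)
})

test_that("malformed networks are rejected", {
  expect_error(reaction_network("A", list(c(A = 1L)), cbind(1L, 1L)),
               "self-loop")
  expect_error(reaction_network("A", list(c(B = 1L)), cbind(1L, 1L)),
               "registered")
})
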