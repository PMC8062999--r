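make_cat <- function(df) mmiswitch:::.as_site_catalog(df)

site_rows <- function(gene, fam, n, conserved, start0 = 100) {
  data.frame(gene_id = gene, transcript_id = paste0(gene, ".1"),
             mirna_family = fam,
             site_start = start0 + 10 * seq_len(n),
             site_end = start0 + 10 * seq_len(n) + 6,
             site_type = "7mer-m8", conserved = conserved,
             stringsAsFactors = FALSE)
}

test_that("motif counting follows the lower/upper bound definitions", {
  # two conserved sites: both bounds 1
  mc <- count_motifs(make_cat(site_rows("G1", "miR-x", 2, c(TRUE, TRUE))), 2)
  expect_identical(mc$pair_count_lower, 1L)
  expect_identical(mc$tuple_count_upper, 1)
  # four sites, two conserved: lower 1, upper choose(4, 2) = 6
  mc2 <- count_motifs(make_cat(site_rows("G1", "miR-x", 4,
                                         c(TRUE, TRUE, FALSE, FALSE))), 2)
  expect_identical(mc2$pair_count_lower, 1L)
  expect_identical(mc2$tuple_count_upper, 6)
  # empty catalog
  mc3 <- count_motifs(make_cat(site_rows("G1", "m", 1, TRUE)[0, ]), 2)
  expect_identical(mc3$pair_count_lower, 0L)
  expect_identical(mc3$tuple_count_upper, 0)
  # single sites everywhere: zero for k = 2
  df <- rbind(site_rows("G1", "m1", 1, TRUE), site_rows("G2", "m1", 1, TRUE))
  mc4 <- count_motifs(make_cat(df), 2)
  expect_identical(mc4$pair_count_lower, 0L)
  expect_identical(mc4$tuple_count_upper, 0)
})

test_that("counting is invariant to row order and duplicated rows", {
  gc <- generate_catalog(n_genes = 150, n_families = 4, site_lambda = 0.4,
                         seed = 9)
  cat1 <- gc$catalog
  shuffled <- make_cat(as.data.frame(cat1)[sample(nrow(cat1)), ])
  duplicated_rows <- make_cat(rbind(as.data.frame(cat1), as.data.frame(cat1)))
  for (k in 2:3) {
    ref <- count_motifs(cat1, k)
    expect_identical(count_motifs(shuffled, k)$tuple_count_upper,
                     ref$tuple_count_upper)
    expect_identical(count_motifs(duplicated_rows, k)$pair_count_lower,
                     ref$pair_count_lower)
    expect_identical(count_motifs(duplicated_rows, k)$tuple_count_upper,
                     ref$tuple_count_upper)
  }
})

test_that("synthetic catalogs round-trip through TSV losslessly", {
  gc <- generate_catalog(n_genes = 100, n_families = 3, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_site_catalog(gc$catalog, path)
  back <- read_site_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(gc$catalog))
})

test_that("counts match generation-time ground truth exactly", {
  for (seed in c(1, 2)) {
    gc <- generate_catalog(n_genes = 400, n_families = 6, site_lambda = 0.5,
                           conserved_fraction = 0.4, seed = seed)
    for (k in 2:3) {
      mc <- count_motifs(gc$catalog, k)
      expect_identical(mc$pair_count_lower,
                       unname(gc$truth$lower[as.character(k)]))
      expect_identical(mc$tuple_count_upper,
                       unname(gc$truth$upper[as.character(k)]))
    }
  }
})

test_that("generated counts match the closed-form Poisson expectation", {
  lam <- 0.2; q <- 0.5; G <- 4000L; Fam <- 10L
  gc <- generate_catalog(n_genes = G, n_families = Fam, site_lambda = lam,
                         conserved_fraction = q, seed = 12)
  # E[lower, k=2] per group: P(#conserved >= 2), conserved ~ Poisson(lam*q)
  p_lower <- 1 - ppois(1, lam * q)
  # E[upper, k=2] per group: E[choose(m, 2)] = lam^2 / 2 for m ~ Poisson(lam)
  e_upper <- lam^2 / 2
  n_grp <- as.numeric(G) * Fam
  sd_lower <- sqrt(n_grp * p_lower * (1 - p_lower))
  expect_lt(abs(gc$truth$lower[["2"]] - n_grp * p_lower), 3 * sd_lower + 1)
  # variance of choose(m,2): E[C(m,2)^2] - E^2; bound loosely via simulation-
  # free Chebyshev-style slack of 4 relative standard errors
  m2 <- replicate(0, 0)
  var_c2 <- (lam^2 / 2 + lam^3 + lam^4 / 4 + lam^3 / 2 + lam^2 / 4) -
    (lam^2 / 2)^2
  expect_lt(abs(gc$truth$upper[["2"]] - n_grp * e_upper),
            4 * sqrt(n_grp * var_c2) + 1)
})

test_that("malformed rows are rejected and logged while the rest load", {
  df <- rbind(site_rows("G1", "m1", 2, TRUE),
              site_rows("G2", "m1", 1, TRUE))
  df$site_start[3] <- -5
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat_ <- read_site_catalog(path)
  expect_identical(nrow(cat_), 2L)
  expect_identical(attr(cat_, "n_rejected"), 1L)
})

test_that("column dialects are remapped and missing columns are an error", {
  df <- site_rows("G1", "m1", 2, TRUE)
  names(df)[names(df) == "gene_id"] <- "Gene.Symbol"
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_site_catalog(path), "gene_id")
  cat_ <- read_site_catalog(path, dialect = c(gene_id = "Gene.Symbol"))
  expect_identical(nrow(cat_), 2L)
  expect_error(read_site_catalog(path, dialect = c(gene_id = "nope")), "nope")
})
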