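# Multi-site target motif enumeration from miRNA target-site catalogs.
#
# A site catalog follows the layout of TargetScan "predicted targets" site
# tables: one row per predicted binding site with a gene identifier, a miRNA
# family, site coordinates and a conservation flag. The k-site circuit motif
# is counted two ways: a lower bound (gene-family pairs with >= k conserved
# sites) and an upper bound (distinct k-subsets of all sites sharing gene and
# family).

.catalog_required <- c("gene_id", "transcript_id", "mirna_family",
                       "site_start", "site_end", "site_type", "conserved")

.as_site_catalog <- function(df) {
  df$site_start <- as.numeric(df$site_start)
  df$site_end <- as.numeric(df$site_end)
  if (is.character(df$conserved))
    df$conserved <- toupper(df$conserved) %in% c("TRUE", "T", "1", "YES")
  df$conserved <- as.logical(df$conserved)
  bad <- !is.finite(df$site_start) | !is.finite(df$site_end) |
    df$site_start <= 0 | df$site_end <= 0 | df$site_start >= df$site_end |
    is.na(df$conserved)
  rejected <- df[bad, , drop = FALSE]
  df <- df[!bad, , drop = FALSE]
  dup <- duplicated(df[, .catalog_required])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_rejected") <- nrow(rejected)
  attr(df, "rejected") <- rejected
  class(df) <- c("site_catalog", "data.frame")
  df
}

#' Read a miRNA target-site catalog
#'
#' Reads a tab-separated site table with a header. Column names can be
#' remapped through `dialect` to accommodate different catalog releases.
#' Rows with unparseable or inconsistent coordinates are rejected and logged;
#' duplicated rows are removed.
#'
#' @param path Path to a TSV file.
#' @param dialect Named character vector mapping required column names
#'   (`gene_id`, `transcript_id`, `mirna_family`, `site_start`, `site_end`,
#'   `site_type`, `conserved`) to the column names used in the file.
#' @return A `site_catalog` data frame; attributes `n_rejected` and
#'   `rejected` carry the rejected-row log.
#' @export
read_site_catalog <- function(path, dialect = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (!dialect[[std]] %in% names(df))
        stop(sprintf("dialect column '%s' not found in file", dialect[[std]]))
      names(df)[names(df) == dialect[[std]]] <- std
    }
  }
  miss <- setdiff(.catalog_required, names(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  .as_site_catalog(df[, .catalog_required])
}

#' Write a site catalog to TSV
#'
#' @param cat A `site_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_catalog <- function(cat, path) {
  utils::write.table(as.data.frame(cat)[, .catalog_required], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count k-site circuit motifs in a site catalog
#'
#' The lower bound counts gene-family pairs whose target carries at least `k`
#' conserved sites for the same miRNA family. The upper bound counts all
#' distinct `k`-subsets of sites (conserved and nonconserved) sharing gene
#' and family, i.e. `sum(choose(m, k))` over group sizes `m >= k`.
#' Overlapping sites are not merged.
#'
#' @param cat A `site_catalog`.
#' @param k Motif size, 2 or 3.
#' @return A list of class `motif_counts`: `k`, `pair_count_lower`,
#'   `tuple_count_upper`, and `per_gene` (data frame of qualifying
#'   gene-family groups).
#' @examples
#' gc <- generate_catalog(n_genes = 50, n_families = 3, seed = 1)
#' count_motifs(gc$catalog, k = 2)
#' @export
count_motifs <- function(cat, k = 2L) {
  stopifnot(inherits(cat, "site_catalog"))
  k <- as.integer(k)
  if (!k %in% 2:3) stop("k must be 2 or 3")
  if (nrow(cat) == 0L) {
    return(structure(list(k = k, pair_count_lower = 0L, tuple_count_upper = 0,
                          per_gene = data.frame()), class = "motif_counts"))
  }
  key <- paste(cat$gene_id, cat$mirna_family, sep = "\r")
  m_all <- table(key)
  m_cons <- table(key[cat$conserved])
  lower <- sum(m_cons >= k)
  upper <- sum(choose(as.numeric(m_all[m_all >= k]), k))
  per <- data.frame(do.call(rbind, strsplit(names(m_all), "\r", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(per) <- c("gene_id", "mirna_family")
  per$n_sites_all <- as.integer(m_all)
  per$n_sites_conserved <- as.integer(m_cons[names(m_all)])
  per$n_sites_conserved[is.na(per$n_sites_conserved)] <- 0L
  per$k_tuples <- choose(per$n_sites_all, k)
  structure(list(k = k, pair_count_lower = as.integer(lower),
                 tuple_count_upper = upper, per_gene = per),
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat(sprintf("k = %d motifs: lower bound %d gene-family pairs, upper bound %g site %d-tuples\n",
              x$k, x$pair_count_lower, x$tuple_count_upper, x$k))
  invisible(x)
}

#' Generate a synthetic site catalog with known ground-truth counts
#'
#' Draws per gene-family site counts from a Poisson distribution, marks each
#' site conserved with probability `conserved_fraction`, and records the
#' exact motif counts at generation time by direct bookkeeping, so downstream
#' counting can be asserted against construction.
#'
#' @param n_genes,n_families Catalog dimensions.
#' @param site_lambda Poisson mean of the per gene-family site count.
#' @param conserved_fraction Probability a site is flagged conserved.
#' @param seed Integer seed.
#' @return A list with `catalog` (a `site_catalog`) and `truth` (list with
#'   `lower` and `upper` counts for `k = 2` and `k = 3`).
#' @export
generate_catalog <- function(n_genes = 1000L, n_families = 10L,
                             site_lambda = 0.2, conserved_fraction = 0.5,
                             seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  fams <- sprintf("miR-f%02d", seq_len(n_families))
  counts <- matrix(stats::rpois(n_genes * n_families, site_lambda),
                   nrow = n_genes)
  rows <- vector("list", sum(counts > 0))
  truth <- list(lower = c(`2` = 0L, `3` = 0L), upper = c(`2` = 0, `3` = 0))
  ri <- 0L
  for (g in seq_len(n_genes)) for (f in seq_len(n_families)) {
    m <- counts[g, f]
    if (m == 0L) next
    cons <- stats::runif(m) < conserved_fraction
    starts <- sort(sample.int(5000L, m)) * 3L
    ri <- ri + 1L
    rows[[ri]] <- data.frame(
      gene_id = genes[g], transcript_id = paste0(genes[g], ".1"),
      mirna_family = fams[f],
      site_start = starts, site_end = starts + 6L,
      site_type = sample(c("7mer-m8", "8mer", "7mer-A1"), m, replace = TRUE),
      conserved = cons, stringsAsFactors = FALSE)
    for (k in 2:3) {
      if (sum(cons) >= k) truth$lower[as.character(k)] <-
          truth$lower[as.character(k)] + 1L
      if (m >= k) truth$upper[as.character(k)] <-
          truth$upper[as.character(k)] + choose(m, k)
    }
  }
  df <- if (ri > 0L) do.call(rbind, rows[seq_len(ri)]) else
    data.frame(gene_id = character(0), transcript_id = character(0),
               mirna_family = character(0), site_start = numeric(0),
               site_end = numeric(0), site_type = character(0),
               conserved = logical(0))
  list(catalog = .as_site_catalog(df), truth = truth)
}
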