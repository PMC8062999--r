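# Cell-level gene-regulatory models for rostrocaudal Hoxa5/Hoxc8 patterning.
#
# Six variants are provided:
#   T_CR    transcriptional cross-repression (Hoxa5 and Hoxc8 repress each
#           other); the canonical positive-feedback benchmark
#   T_UR    transcriptional unilateral repression (only Hoxc8 represses
#           Hoxa5); no feedback loop, high Hill cooperativity
#   Tmi_UR  T_UR plus morphogen-driven miRNAs forming coherent feed-forward
#           loops (FGF -> miR-27 -| Hoxa5; RA -> miR-196 -| Hoxc8), with
#           balanced complex degradation (titration without feedback)
#   Tmi_FB  T_UR plus miRNAs under transcriptional repression by their own
#           targets (Hoxa5 -| miR-27, Hoxc8 -| miR-196), a canonical
#           TF-miRNA double-negative loop
#   mmi_S   T_UR plus the noncanonical mRNA-miRNA feedback: each Hox mRNA
#           binds its miRNA at two sites with occupancy-dependent complex
#           degradation (cooperative miRNA protection, b2 < b1), making each
#           pair a bistable titration switch; miR-27 constitutive and
#           uniform, miR-196 FGF-activated (broad caudal expression)
#   mmi_S_nofeedback  mmi_S with balanced complex degradation (the altered
#           model): titration thresholds remain but the switches lose their
#           feedback and hence their memory
#
# All transcriptional edges use Hill functions with per-edge threshold and
# coefficient; every edge is declared in the spec's regulation table.

.hillp <- function(x, theta, n) {
  xn <- pmax(x, 0)^n
  xn / (xn + theta^n)
}
.hillm <- function(x, theta, n) {
  tn <- theta^n
  tn / (pmax(x, 0)^n + tn)
}

.tissue_variants <- c("T_CR", "T_UR", "Tmi_UR", "Tmi_FB", "mmi_S",
                      "mmi_S_nofeedback")

.tissue_defaults <- function(variant) {
  base <- list(theta_RA = 0.2, theta_FGF = 0.2, n_morph = 2,
               theta_rep = 0.05, n_rep = 2,
               k_m = 1, k_mi = 1, k_p = 0.5,
               ratio_fold = 10, thr_frac = 0.1)
  mmi_pair <- function(b2) list(n_sites = 2L, a = c(1, 1), b = c(1, b2),
                                K = 1e-4)
  switch(variant,
    T_CR = utils::modifyList(base, list(
      n_rep = 4,
      bas_A = 0.02, beta_A = 1.0, bas_C = 0.02, beta_C = 1.0)),
    T_UR = utils::modifyList(base, list(
      bas_A = 0.02, beta_A = 1.0, bas_C = 0.02, beta_C = 1.0,
      n_morph = 4, n_rep = 4)),
    Tmi_UR = utils::modifyList(base, list(
      bas_A = 0.02, beta_A = 1.0, bas_C = 0.02, beta_C = 1.0,
      n_morph = 4, n_rep = 4,
      s27_bas = 0.02, s27_beta = 0.08, s27_theta = 0.2, s27_n = 2,
      s196_bas = 0.02, s196_beta = 0.08, s196_theta = 0.2, s196_n = 2,
      pair_A = mmi_pair(1), pair_C = mmi_pair(1))),
    Tmi_FB = utils::modifyList(base, list(
      bas_A = 0.02, beta_A = 1.0, bas_C = 0.02, beta_C = 1.0,
      s27_bas = 0, s27_beta = 0.12, s27_theta = 0.15, s27_n = 2,
      s196_bas = 0, s196_beta = 0.12, s196_theta = 0.15, s196_n = 2,
      pair_A = mmi_pair(1), pair_C = mmi_pair(1))),
    mmi_S = utils::modifyList(base, list(
      theta_rep = 0.1, n_rep = 4, theta_FGF = 0.15,
      bas_A = 0.15, beta_A = 1.2, bas_C = 0.15, beta_C = 0.9,
      s27_bas = 0.17, s27_beta = 0, s27_theta = 0.2, s27_n = 2,
      s196_bas = 0.10, s196_beta = 0.06, s196_theta = 0.2, s196_n = 2,
      pair_A = mmi_pair(0.1), pair_C = mmi_pair(0.1))),
    mmi_S_nofeedback = utils::modifyList(base, list(
      theta_rep = 0.1, n_rep = 4, theta_FGF = 0.15,
      bas_A = 0.15, beta_A = 1.2, bas_C = 0.15, beta_C = 0.9,
      s27_bas = 0.17, s27_beta = 0, s27_theta = 0.2, s27_n = 2,
      s196_bas = 0.10, s196_beta = 0.06, s196_theta = 0.2, s196_n = 2,
      pair_A = mmi_pair(1), pair_C = mmi_pair(1))),
    stop("unknown variant: ", variant))
}

.tissue_regulation <- function(variant) {
  e <- function(target, source, type) data.frame(target = target,
                                                 source = source, type = type)
  tab <- rbind(e("Hoxa5_mRNA", "RA", "activator"),
               e("Hoxc8_mRNA", "FGF", "activator"),
               e("Hoxa5_mRNA", "Hoxc8_protein", "repressor"))
  if (variant == "T_CR")
    tab <- rbind(tab, e("Hoxc8_mRNA", "Hoxa5_protein", "repressor"))
  if (variant == "Tmi_UR")
    tab <- rbind(tab, e("miR27", "FGF", "activator"),
                 e("miR196", "RA", "activator"))
  if (variant == "Tmi_FB")
    tab <- rbind(tab, e("miR27", "Hoxa5_protein", "repressor"),
                 e("miR196", "Hoxc8_protein", "repressor"))
  if (variant %in% c("mmi_S", "mmi_S_nofeedback"))
    tab <- rbind(tab, e("miR196", "FGF", "activator"))
  if (variant %in% c("Tmi_UR", "Tmi_FB", "mmi_S", "mmi_S_nofeedback"))
    tab <- rbind(tab, e("Hoxa5_mRNA", "miR27", "binding"),
                 e("Hoxc8_mRNA", "miR196", "binding"))
  tab
}

#' Cell-level model specification for tissue simulations
#'
#' @param variant One of `"T_CR"`, `"T_UR"`, `"Tmi_UR"`, `"Tmi_FB"`,
#'   `"mmi_S"`, `"mmi_S_nofeedback"`.
#' @param params Named list of parameter overrides merged into the variant
#'   defaults (see the package vignette for the full table).
#' @param pair_sites Optional number of binding sites (1-3) for both
#'   mRNA-miRNA pairs in miRNA-bearing variants; default 2.
#' @return An object of class `cell_model_spec` with `variant`, `species`,
#'   `params` and `regulation` (the declared edge table).
#' @examples
#' spec <- cell_model_spec("mmi_S")
#' spec$species
#' @export
cell_model_spec <- function(variant = "mmi_S", params = list(),
                            pair_sites = NULL) {
  variant <- match.arg(variant, .tissue_variants)
  p <- utils::modifyList(.tissue_defaults(variant), params)
  has_mirna <- variant %in% c("Tmi_UR", "Tmi_FB", "mmi_S", "mmi_S_nofeedback")
  if (!is.null(pair_sites) && has_mirna) {
    pair_sites <- as.integer(pair_sites)
    if (!pair_sites %in% 1:3) stop("pair_sites must be 1, 2 or 3")
    extend <- function(pair) {
      pair$n_sites <- pair_sites
      pair$a <- rep(pair$a[1], pair_sites)
      # keep the terminal-occupancy multiplier on the fully loaded complex
      pair$b <- c(rep(pair$b[1], pair_sites - 1L), pair$b[length(pair$b)])
      pair
    }
    p$pair_A <- extend(p$pair_A)
    p$pair_C <- extend(p$pair_C)
  }
  species <- if (has_mirna) {
    c("Hoxa5_mRNA_total", "miR27_total", "Hoxc8_mRNA_total", "miR196_total",
      "Hoxa5_protein", "Hoxc8_protein")
  } else {
    c("Hoxa5_mRNA", "Hoxc8_mRNA", "Hoxa5_protein", "Hoxc8_protein")
  }
  structure(list(variant = variant, species = species, params = p,
                 has_mirna = has_mirna,
                 regulation = .tissue_regulation(variant)),
            class = "cell_model_spec")
}

#' @export
print.cell_model_spec <- function(x, ...) {
  cat(sprintf("cell model '%s' (%d species)\n", x$variant, length(x$species)))
  cat("  regulation:\n")
  for (k in seq_len(nrow(x$regulation)))
    cat(sprintf("    %s %s %s\n", x$regulation$source[k],
                ifelse(x$regulation$type[k] == "activator", "->",
                       ifelse(x$regulation$type[k] == "repressor", "-|", "::")),
                x$regulation$target[k]))
  invisible(x)
}

#' Knock out a miRNA in a cell model
#'
#' Sets the synthesis rate of the named miRNA to zero in all cells,
#' leaving everything else unchanged. Idempotent.
#'
#' @param spec A `cell_model_spec` containing the miRNA.
#' @param mirna `"miR-27"` or `"miR-196"` (also accepted without dash).
#' @return The modified `cell_model_spec`.
#' @examples
#' ko <- knockout(cell_model_spec("mmi_S"), "miR-27")
#' ko$params$s27_bas
#' @export
knockout <- function(spec, mirna) {
  stopifnot(inherits(spec, "cell_model_spec"))
  key <- gsub("[-_ ]", "", tolower(mirna))
  if (!spec$has_mirna)
    stop(sprintf("variant '%s' contains no miRNA species", spec$variant))
  if (key == "mir27") {
    spec$params$s27_bas <- 0; spec$params$s27_beta <- 0
  } else if (key == "mir196") {
    spec$params$s196_bas <- 0; spec$params$s196_beta <- 0
  } else {
    stop("unknown miRNA: ", mirna)
  }
  ko <- union(attr(spec, "knockouts"), key)
  attr(spec, "knockouts") <- ko
  spec
}

# transcription rates given sensed morphogen levels and current proteins;
# vectors over cells. Returns list(s_A, s_C, s_27, s_196) (miRNA entries NULL
# for T models).
.transcription_rates <- function(spec, RA, FGF, PA, PC) {
  p <- spec$params
  hRA <- .hillp(RA, p$theta_RA, p$n_morph)
  hFGF <- .hillp(FGF, p$theta_FGF, p$n_morph)
  repA <- .hillm(PC, p$theta_rep, p$n_rep)
  mmi <- spec$variant %in% c("mmi_S", "mmi_S_nofeedback")
  # In the transcriptional models the repressor shuts the whole promoter;
  # in the mmi architecture basal Hox transcription persists under
  # repression and its silencing is delegated to the miRNA.
  s_A <- if (mmi) p$bas_A + p$beta_A * hRA * repA
    else (p$bas_A + p$beta_A * hRA) * repA
  s_C <- if (spec$variant == "T_CR") {
    (p$bas_C + p$beta_C * hFGF) * .hillm(PA, p$theta_rep, p$n_rep)
  } else {
    p$bas_C + p$beta_C * hFGF
  }
  s27 <- s196 <- NULL
  if (spec$has_mirna) {
    s27 <- switch(spec$variant,
      Tmi_UR = p$s27_bas + p$s27_beta * .hillp(FGF, p$s27_theta, p$s27_n),
      Tmi_FB = p$s27_bas + p$s27_beta * .hillm(PA, p$s27_theta, p$s27_n),
      p$s27_bas + p$s27_beta)                      # constitutive, uniform
    s196 <- switch(spec$variant,
      Tmi_UR = p$s196_bas + p$s196_beta * .hillp(RA, p$s196_theta, p$s196_n),
      Tmi_FB = p$s196_bas + p$s196_beta * .hillm(PC, p$s196_theta, p$s196_n),
      p$s196_bas + p$s196_beta * .hillp(FGF, p$s196_theta, p$s196_n))
    if (length(s27) == 1L) s27 <- rep(s27, length(RA))
    if (length(s196) == 1L) s196 <- rep(s196, length(RA))
  }
  list(s_A = s_A, s_C = s_C, s27 = s27, s196 = s196)
}

# protein "on" thresholds: thr_frac of the maximal attainable protein level.
# For transcription-only variants that is basal plus fully activated
# transcription; for miRNA-bearing variants it is the free mRNA of the pair
# at full transcriptional drive against the miRNA pool (the transcription
# ceiling is never attainable while the miRNA is expressed). A structural
# constant of the spec, so paired comparisons use matching thresholds.
.protein_thresholds <- function(spec) {
  p <- spec$params
  sA_max <- p$bas_A + p$beta_A
  sC_max <- p$bas_C + p$beta_C
  if (!spec$has_mirna)
    return(c(A = p$thr_frac * sA_max, C = p$thr_frac * sC_max))
  free_max <- function(s, sigma, pair) {
    if (sigma <= 0) return(s)
    st <- .pair_steady_states(s, sigma, pair, p$k_m, p$k_mi)
    max(st$R)
  }
  c(A = p$thr_frac * free_max(sA_max, p$s27_bas + p$s27_beta, p$pair_A),
    C = p$thr_frac * free_max(sC_max, p$s196_bas + p$s196_beta, p$pair_C))
}

# binding polynomials of a tissue pair (statistical-factors convention)
.pair_polys <- function(pair) {
  n <- pair$n_sites
  i <- seq_len(n)
  w <- choose(n, i)
  list(phi = c(1, w), psi = c(0, i * w),
       phi_a = c(1, w * pair$a), psi_b = c(0, i * w * pair$b),
       K = pair$K)
}
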