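# Vectorized tissue simulation: cells are autonomous, share the gradient
# backbone, and receive independent multiplicative white noise on the sensed
# morphogen levels (Euler-Maruyama). For miRNA-bearing variants the fast
# binding equilibrium of each mRNA-miRNA pair is solved per cell at every
# step by a warm-started vectorized Newton iteration.

#' Simulate a tissue model on the cell grid
#'
#' @param spec A [cell_model_spec()].
#' @param field A [make_morphogen_field()] result; its `seed` (mixed with
#'   `seed`) drives the noise realizations.
#' @param t_end Simulation horizon (nondimensional time).
#' @param dt Euler-Maruyama step.
#' @param seed Integer seed for the noise stream.
#' @param snapshot_times Times at which full states are stored (final state
#'   is always stored).
#' @return An object of class `mmi_tissue`: list with `final` (cells x
#'   species matrix), `snapshots` (named list of matrices), `spec`, `field`,
#'   `free` (free mRNA levels at final time for miRNA variants), and the
#'   grid layout (`n_cols`, `n_pos`, `position` per cell).
#' @examples
#' f <- make_morphogen_field(noise_sigma = 0)
#' ts <- simulate_tissue(cell_model_spec("T_UR"), f, t_end = 30)
#' table(fate_calls(ts))
#' @export
simulate_tissue <- function(spec, field, t_end = 60, dt = 0.02, seed = 1L,
                            snapshot_times = NULL) {
  stopifnot(inherits(spec, "cell_model_spec"), inherits(field, "morphogen_field"))
  n_cells <- field$n_cols * field$n_pos
  pos <- rep(field$positions, each = field$n_cols)
  nsp <- length(spec$species)
  X <- matrix(0, n_cells, nsp, dimnames = list(NULL, spec$species))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((field$seed * 7919 + seed * 104729) %% 2147483647)
  p <- spec$params
  has_mi <- spec$has_mirna
  if (has_mi) {
    polA <- .pair_polys(p$pair_A)
    polC <- .pair_polys(p$pair_C)
    warmA <- rep(0, n_cells); warmC <- rep(0, n_cells)
  }
  steps <- ceiling(t_end / dt)
  snap_steps <- if (is.null(snapshot_times)) integer(0) else
    pmin(pmax(round(snapshot_times / dt), 1L), steps)
  snapshots <- list()
  # protein checkpoints over the final stretch, used to detect fate flicker
  hist_steps <- unique(pmax(round(seq(t_end - 10, t_end, by = 0.5) / dt), 1L))
  protein_history <- list()
  freeA <- freeC <- NULL
  for (k in seq_len(steps)) {
    t <- (k - 1L) * dt
    bb <- morphogen_backbone(field, t)
    RA <- .noisy_signal(bb$RA[pos + 1L], field$noise_sigma, dt)
    FGF <- .noisy_signal(bb$FGF[pos + 1L], field$noise_sigma, dt)
    if (has_mi) {
      eqA <- .solve_complexes_vec(X[, 1], X[, 2], polA, polA$K, x0 = warmA)
      eqC <- .solve_complexes_vec(X[, 3], X[, 4], polC, polC$K, x0 = warmC)
      warmA <- eqA$x; warmC <- eqC$x
      freeA <- eqA$R; freeC <- eqC$R
      tr <- .transcription_rates(spec, RA, FGF, X[, 5], X[, 6])
      dX <- cbind(
        tr$s_A - p$k_m * freeA * .polyval(polA$phi_a, eqA$x),
        tr$s27 - p$k_mi * (eqA$r + freeA * .polyval(polA$psi_b, eqA$x)),
        tr$s_C - p$k_m * freeC * .polyval(polC$phi_a, eqC$x),
        tr$s196 - p$k_mi * (eqC$r + freeC * .polyval(polC$psi_b, eqC$x)),
        p$k_p * (freeA - X[, 5]),
        p$k_p * (freeC - X[, 6]))
    } else {
      tr <- .transcription_rates(spec, RA, FGF, X[, 3], X[, 4])
      dX <- cbind(tr$s_A - p$k_m * X[, 1],
                  tr$s_C - p$k_m * X[, 2],
                  p$k_p * (X[, 1] - X[, 3]),
                  p$k_p * (X[, 2] - X[, 4]))
    }
    X <- pmax(X + dt * dX, 0)
    if (any(!is.finite(X)))
      stop(sprintf("numerical instability at t = %.3f (cell %d)",
                   t, which(!is.finite(rowSums(X)))[1]))
    if (k %in% snap_steps)
      snapshots[[sprintf("t%g", k * dt)]] <- X
    if (k %in% hist_steps)
      protein_history[[length(protein_history) + 1L]] <-
        X[, c(nsp - 1L, nsp), drop = FALSE]
  }
  if (has_mi) {
    eqA <- .solve_complexes_vec(X[, 1], X[, 2], polA, polA$K, x0 = warmA)
    eqC <- .solve_complexes_vec(X[, 3], X[, 4], polC, polC$K, x0 = warmC)
    freeA <- eqA$R; freeC <- eqC$R
  } else {
    freeA <- X[, 1]; freeC <- X[, 2]
  }
  structure(list(final = X, snapshots = snapshots, spec = spec, field = field,
                 protein_history = protein_history,
                 free = cbind(Hoxa5 = freeA, Hoxc8 = freeC),
                 n_cols = field$n_cols, n_pos = field$n_pos, position = pos,
                 t_end = t_end, dt = dt, seed = seed),
            class = "mmi_tissue")
}

#' @export
print.mmi_tissue <- function(x, ...) {
  cat(sprintf("tissue simulation '%s': %d x %d cells, t_end = %g\n",
              x$spec$variant, x$n_cols, x$n_pos, x$t_end))
  print(table(fate_calls(x)))
  invisible(x)
}

#' Per-cell fate calls from protein levels
#'
#' Each cell is labeled by comparing its Hoxa5 and Hoxc8 protein levels to
#' the "on" thresholds (a fixed fraction, default 10%, of the maximal
#' attainable level of each protein): `A5on_C8off`, `A5off_C8on`,
#' `double_on`, or `double_off`.
#'
#' @param tissue An `mmi_tissue`, or a state matrix with protein columns.
#' @param spec Required if `tissue` is a bare matrix.
#' @return Character vector of per-cell labels with attribute `thresholds`.
#' @export
fate_calls <- function(tissue, spec = NULL) {
  if (inherits(tissue, "mmi_tissue")) {
    spec <- tissue$spec
    X <- tissue$final
  } else X <- tissue
  thr <- .protein_thresholds(spec)
  PA <- X[, "Hoxa5_protein"]; PC <- X[, "Hoxc8_protein"]
  lab <- ifelse(PA >= thr["A"] & PC >= thr["C"], "double_on",
                ifelse(PA >= thr["A"], "A5on_C8off",
                       ifelse(PC >= thr["C"], "A5off_C8on", "double_off")))
  attr(lab, "thresholds") <- thr
  lab
}

#' Transition width of the tissue boundary
#'
#' The number of rostrocaudal positions containing at least one cell with an
#' equivocal lineage decision: a double-positive or double-negative fate
#' call, a Hoxa5/Hoxc8 protein ratio within `ratio_fold` (default 10-fold)
#' of unity, or a fate call that flips between the protein checkpoints
#' recorded over the final stretch of the simulation (temporal fluctuation
#' of the lineage decision).
#'
#' @param tissue An `mmi_tissue`.
#' @param ratio_fold Ambiguity fold-threshold on the protein ratio.
#' @return Integer in `[0, n_pos]`.
#' @export
transition_width <- function(tissue, ratio_fold = tissue$spec$params$ratio_fold) {
  stopifnot(inherits(tissue, "mmi_tissue"))
  thr <- .protein_thresholds(tissue$spec)
  eps <- 1e-12
  states <- tissue$protein_history
  if (length(states) == 0L)
    states <- list(tissue$final[, c("Hoxa5_protein", "Hoxc8_protein")])
  equivocal <- rep(FALSE, nrow(tissue$final))
  prev_lab <- NULL
  for (S in states) {
    PA <- S[, 1]; PC <- S[, 2]
    onA <- PA >= thr["A"]; onC <- PC >= thr["C"]
    ratio <- abs(log10((PA + eps) / (PC + eps)))
    equivocal <- equivocal | (onA & onC) | (!onA & !onC) |
      ratio < log10(ratio_fold)
    lab <- onA - onC
    if (!is.null(prev_lab)) equivocal <- equivocal | (lab != prev_lab)
    prev_lab <- lab
  }
  sum(tapply(equivocal, tissue$position, any))
}

#' Column-averaged rostrocaudal profile of a species
#'
#' @param tissue An `mmi_tissue`.
#' @param what `"protein"`, `"mrna"` (total mRNA for miRNA variants) or
#'   `"free_mrna"`; `gene` selects Hoxa5 or Hoxc8.
#' @param gene `"Hoxa5"` or `"Hoxc8"`.
#' @return Numeric vector over positions.
#' @export
tissue_profile <- function(tissue, what = c("protein", "mrna", "free_mrna"),
                           gene = c("Hoxa5", "Hoxc8")) {
  what <- match.arg(what); gene <- match.arg(gene)
  v <- switch(what,
    protein = tissue$final[, paste0(gene, "_protein")],
    mrna = if (tissue$spec$has_mirna)
      tissue$final[, paste0(gene, "_mRNA_total")] else
        tissue$final[, paste0(gene, "_mRNA")],
    free_mrna = tissue$free[, gene])
  as.numeric(tapply(v, tissue$position, mean))
}

#' Segregation index: protein versus mRNA boundary steepness
#'
#' The ratio of the maximum absolute discrete spatial derivative of the
#' column-averaged, max-normalized Hoxa5 protein profile to that of the
#' corresponding total-mRNA profile. Values above 1 indicate a protein
#' boundary sharper than the mRNA boundary.
#'
#' @param tissue An `mmi_tissue`.
#' @param gene Profile gene, default Hoxa5.
#' @return Positive scalar.
#' @export
segregation_index <- function(tissue, gene = "Hoxa5") {
  pr <- tissue_profile(tissue, "protein", gene)
  mr <- tissue_profile(tissue, "mrna", gene)
  if (max(pr) <= 0 || max(mr) <= 0)
    stop("flat profile: segregation index undefined")
  steep <- function(v) max(abs(diff(v / max(v))))
  s_m <- steep(mr)
  if (s_m == 0) stop("flat mRNA profile: segregation index undefined")
  steep(pr) / s_m
}

#' Idealized reference expression profiles
#'
#' Step-like target protein profiles with broad overlapping mRNA profiles,
#' used as qualitative comparators for the segregation index.
#'
#' @param n_pos Number of positions.
#' @param boundary Step position of the protein reference.
#' @param mrna_width Length scale of the graded mRNA reference.
#' @return A list with `protein` and `mrna` profiles (Hoxa5 orientation,
#'   rostral high) and the implied `segregation_index`.
#' @export
expression_profile_reference <- function(n_pos = 40L, boundary = 20L,
                                         mrna_width = 12) {
  x <- seq_len(n_pos) - 1L
  protein <- as.numeric(x < boundary)
  mrna <- 0.25 + 0.75 / (1 + exp((x - boundary) / mrna_width))
  steep <- function(v) max(abs(diff(v / max(v))))
  list(protein = protein, mrna = mrna,
       segregation_index = steep(protein) / steep(mrna))
}

#' Long-format per-cell species table
#'
#' @param tissue An `mmi_tissue`.
#' @return Data frame with `column`, `position`, `species`, `value`.
#' @export
tissue_table <- function(tissue) {
  X <- tissue$final
  n <- nrow(X)
  data.frame(
    column = rep(rep(seq_len(tissue$n_cols), tissue$n_pos), ncol(X)),
    position = rep(tissue$position, ncol(X)),
    species = rep(colnames(X), each = n),
    value = as.numeric(X))
}
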