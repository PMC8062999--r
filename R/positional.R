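# Per-position steady-state structure of the tissue models with the
# morphogens frozen at their final (low-plateau) levels, and the single-cell
# RA-pulse hysteresis protocol.

# steady states of one mRNA-miRNA pair at given synthesis rates; returns a
# data frame with free mRNA R, free miRNA r and stability labels
.pair_steady_states <- function(s_R, s_r, pair, k_m = 1, k_mi = 1) {
  if (s_r <= 0) {
    return(data.frame(R = s_R / k_m, r = 0,
                      stability = "stable_node_or_focus"))
  }
  p <- mmi_parameters(n_sites = pair$n_sites, a = pair$a, b = pair$b,
                      s_R = max(s_R, 1e-12), s_r = s_r,
                      k_R = k_m, k_r = k_mi, K_scaled = pair$K)
  st <- steady_states_at(p, s_r, control = "s_r")
  st[, c("R", "r", "stability")]
}

#' Per-position bifurcation structure of a tissue model
#'
#' Computes the steady states of the single-cell model at every rostrocaudal
#' position with the morphogens frozen at their final low-plateau levels
#' (position is the control parameter). For the unilateral-repression
#' architectures the cell decomposes into a Hoxc8 arm feeding forward into a
#' Hoxa5 arm, so the full fixed-point set is the product of the per-arm
#' branches; for the cross-repressive model the two-protein fixed points are
#' found by a one-dimensional composition scan.
#'
#' @param spec A [cell_model_spec()] (`T_CR`, `T_UR`, `Tmi_UR`, or the
#'   `mmi_S` family; the transcription-fedback `Tmi_FB` variant is not
#'   supported).
#' @param field A [make_morphogen_field()] (for the gradient geometry and
#'   final amplitude).
#' @param positions Positions to evaluate (default all).
#' @return A data frame of class `positional_bifurcation` with one row per
#'   steady state: `position`, `Hoxa5_protein`, `Hoxc8_protein`,
#'   `stability`, `fate` (threshold label of stable states).
#' @examples
#' pb <- positional_bifurcation(cell_model_spec("T_UR"), make_morphogen_field())
#' @export
positional_bifurcation <- function(spec, field = make_morphogen_field(),
                                   positions = NULL) {
  stopifnot(inherits(spec, "cell_model_spec"))
  if (spec$variant == "Tmi_FB")
    stop("positional bifurcation is not implemented for the Tmi_FB variant")
  if (is.null(positions)) positions <- field$positions
  p <- spec$params
  A_low <- field$amplitude$A_low
  lam <- field$lambda_decay
  thr <- .protein_thresholds(spec)
  rows <- list()
  for (x in positions) {
    RA <- A_low * exp(-x / lam)
    FGF <- A_low * exp(-(field$n_pos - 1L - x) / lam)
    if (spec$variant == "T_CR") {
      # composition scan in PA: PC = F_C(PA), PA = F_A(PC)
      F_C <- function(PA) p$bas_C + p$beta_C * .hillp(FGF, p$theta_FGF, p$n_morph) *
        .hillm(PA, p$theta_rep, p$n_rep)
      F_A <- function(PC) p$bas_A + p$beta_A * .hillp(RA, p$theta_RA, p$n_morph) *
        .hillm(PC, p$theta_rep, p$n_rep)
      g <- function(PA) F_A(F_C(PA)) - PA
      grid <- seq(0, p$bas_A + p$beta_A, length.out = 400)
      gv <- vapply(grid, g, numeric(1))
      sgn <- which(diff(sign(gv)) != 0)
      for (k in sgn) {
        root <- stats::uniroot(g, grid[c(k, k + 1L)], tol = 1e-12)$root
        eps <- 1e-6
        slope <- (g(root + eps) - g(root - eps)) / (2 * eps)
        stab <- if (slope < 0) "stable_node_or_focus" else "saddle"
        rows[[length(rows) + 1L]] <- data.frame(
          position = x, Hoxa5_protein = root, Hoxc8_protein = F_C(root),
          stability = stab)
      }
      next
    }
    tr0 <- .transcription_rates(spec, RA, FGF, PA = 0, PC = 0)
    # Hoxc8 arm (independent of Hoxa5)
    c_states <- if (spec$has_mirna) {
      .pair_steady_states(tr0$s_C, tr0$s196, p$pair_C, p$k_m, p$k_mi)
    } else {
      data.frame(R = tr0$s_C / p$k_m, r = NA_real_,
                 stability = "stable_node_or_focus")
    }
    for (ci in seq_len(nrow(c_states))) {
      PC <- c_states$R[ci]
      trc <- .transcription_rates(spec, RA, FGF, PA = 0, PC = PC)
      a_states <- if (spec$has_mirna) {
        .pair_steady_states(trc$s_A, trc$s27, p$pair_A, p$k_m, p$k_mi)
      } else {
        data.frame(R = trc$s_A / p$k_m, r = NA_real_,
                   stability = "stable_node_or_focus")
      }
      for (ai in seq_len(nrow(a_states))) {
        sA <- a_states$stability[ai]; sC <- c_states$stability[ci]
        stab <- if (sA == "stable_node_or_focus" && sC == "stable_node_or_focus")
          "stable_node_or_focus"
        else if (sA == "saddle" || sC == "saddle") "saddle" else "unstable"
        rows[[length(rows) + 1L]] <- data.frame(
          position = x, Hoxa5_protein = a_states$R[ai],
          Hoxc8_protein = PC, stability = stab)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$fate <- ifelse(out$stability != "stable_node_or_focus", NA_character_,
    ifelse(out$Hoxa5_protein >= thr["A"] & out$Hoxc8_protein >= thr["C"],
           "double_on",
           ifelse(out$Hoxa5_protein >= thr["A"], "A5on_C8off",
                  ifelse(out$Hoxc8_protein >= thr["C"], "A5off_C8on",
                         "double_off"))))
  class(out) <- c("positional_bifurcation", "data.frame")
  out
}

#' Positions whose single-cell model is tristable
#'
#' @param pb A [positional_bifurcation()] result.
#' @return Integer vector of positions with three or more stable states.
#' @export
tristable_positions <- function(pb) {
  ns <- tapply(pb$stability == "stable_node_or_focus", pb$position, sum)
  as.integer(names(ns)[ns >= 3])
}

#' Single-cell RA-pulse hysteresis experiment
#'
#' Drives a single cell carrying the three-site Hoxa5/miR-27 circuit with a
#' high-then-low retinoic-acid schedule and compares the outcome against a
#' cell held at the low level throughout. With miR-27 active the circuit is
#' bistable over an RA window covering the low level, so a transient high
#' pulse leaves Hoxa5 in the induced state; with miR-27 synthesis off the
#' free mRNA tracks the transcription rate monotonically and the pulse
#' leaves no memory.
#'
#' @param ra_high,ra_low RA levels of the pulse protocol.
#' @param t_switch Time of the high-to-low switch; the run lasts
#'   `3 * t_switch` to let the cell settle.
#' @param mir27_active Logical; `FALSE` silences miR-27 synthesis.
#' @param params Optional overrides: `bas`, `beta`, `theta_RA`, `n_RA`,
#'   `s27`, `pair` (list with `n_sites`, `a`, `b`, `K`).
#' @param dt Euler step.
#' @return A list of class `ra_pulse_result`: `pulsed` and `low_only`
#'   (final free Hoxa5 mRNA and protein), `hoxa5_on` flags (threshold = 10%
#'   of the level attainable at `ra_low` without miRNA, separating the
#'   bimodal branches), `bifurcation` (steady states vs RA on
#'   a grid: data frame `RA`, `R`, `stability`), and `bistable_ra_range`
#'   (range of RA values with >= 2 stable states, or `NULL`).
#' @examples
#' rp <- ra_pulse_experiment(mir27_active = TRUE)
#' rp$hoxa5_on
#' @export
ra_pulse_experiment <- function(ra_high = 1, ra_low = 0.08, t_switch = 40,
                                mir27_active = TRUE, params = list(), dt = 0.01) {
  if (!(ra_high > ra_low && ra_low >= 0)) stop("need ra_high > ra_low >= 0")
  p <- utils::modifyList(list(
    bas = 0.02, beta = 1.0, theta_RA = 0.3, n_RA = 2, s27 = 0.04, k_p = 0.5,
    tau_ra = 8,
    pair = list(n_sites = 3L, a = c(1, 1, 1), b = c(1, 0.3, 0.05), K = 1e-4)),
    params)
  s27 <- if (mir27_active) p$s27 else 0
  pol <- .pair_polys(p$pair)
  s_of <- function(ra) p$bas + p$beta * .hillp(ra, p$theta_RA, p$n_RA)
  # the sensed RA level relaxes toward the protocol target (wash-in /
  # washout kinetics), so window passages are adiabatic
  run <- function(ra_fun, t_end) {
    y <- c(RT = 0, rT = 0, P = 0)
    ra_sensed <- 0
    x_warm <- 0
    steps <- ceiling(t_end / dt)
    for (k in seq_len(steps)) {
      ra_sensed <- ra_sensed +
        dt * (ra_fun((k - 1) * dt) - ra_sensed) / p$tau_ra
      eq <- .solve_complexes_vec(y[1], y[2], pol, pol$K, x0 = x_warm)
      x_warm <- eq$x
      dRT <- s_of(ra_sensed) - eq$R * .polyval(pol$phi_a, eq$x)
      drT <- s27 - (eq$r + eq$R * .polyval(pol$psi_b, eq$x))
      dP <- p$k_p * (eq$R - y[3])
      y <- pmax(y + dt * c(dRT, drT, dP), 0)
    }
    eq <- .solve_complexes_vec(y[1], y[2], pol, pol$K, x0 = x_warm)
    c(free_mrna = unname(eq$R), protein = unname(y[3]))
  }
  # burn-in at RA = 0: progenitors accumulate the miRNA pool before exposure
  t_burn <- t_switch
  t_end <- t_burn + 3 * t_switch
  pulsed <- run(function(t) {
    if (t < t_burn) 0 else if (t < t_burn + t_switch) ra_high else ra_low
  }, t_end)
  low_only <- run(function(t) if (t < t_burn) 0 else ra_low, t_end)
  # bifurcation diagram vs RA through the transcription mapping
  ra_grid <- exp(seq(log(max(ra_low / 10, 1e-3)), log(ra_high * 1.5),
                     length.out = 80))
  bif <- do.call(rbind, lapply(ra_grid, function(ra) {
    st <- .pair_steady_states(s_of(ra), s27, p$pair)
    data.frame(RA = ra, R = st$R, stability = st$stability)
  }))
  stable_counts <- tapply(bif$stability == "stable_node_or_focus", bif$RA, sum)
  bi_ra <- as.numeric(names(stable_counts)[stable_counts >= 2])
  # "on" gate for the bimodal readout at the low condition: 10% of the free
  # mRNA attainable at ra_low in the absence of miRNA
  thr <- 0.1 * s_of(ra_low)
  structure(list(
    pulsed = pulsed, low_only = low_only,
    hoxa5_on = c(pulsed = unname(pulsed["free_mrna"] >= thr),
                 low_only = unname(low_only["free_mrna"] >= thr)),
    threshold = thr, mir27_active = mir27_active,
    bifurcation = bif,
    bistable_ra_range = if (length(bi_ra)) range(bi_ra) else NULL),
    class = "ra_pulse_result")
}

#' @export
print.ra_pulse_result <- function(x, ...) {
  cat(sprintf("RA pulse (miR-27 %s): pulsed free mRNA %.4g, low-only %.4g\n",
              ifelse(x$mir27_active, "active", "off"),
              x$pulsed["free_mrna"], x$low_only["free_mrna"]))
  if (is.null(x$bistable_ra_range)) cat("  no bistable RA window\n") else
    cat(sprintf("  bistable RA window [%.3g, %.3g]\n",
                x$bistable_ra_range[1], x$bistable_ra_range[2]))
  invisible(x)
}
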