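#' Right-hand side of the reduced (tQSSA) circuit
#'
#' Time derivatives of the totals `(R_T, r_T)` with the fast binding
#' equilibrium eliminated algebraically:
#' `dR_T/dt = s_R - k_R (R + sum a_i C_i)` and
#' `dr_T/dt = s_r - k_r (r + sum lambda_i b_i C_i)`, where `lambda_i = i`
#' under the per-molecule miRNA loss convention. Degradation of one partner
#' releases the other intact (multiple turnover), so mRNA decay inside a
#' complex does not consume miRNA and vice versa.
#'
#' @param state Numeric vector `c(R_T, r_T)` or a list with those names.
#' @param p An [mmi_parameters] record.
#' @param s_r Optional override of the miRNA synthesis rate (the usual
#'   control parameter); defaults to `p$s_r`.
#' @return Numeric vector `c(dR_T, dr_T)`.
#' @export
reduced_rhs <- function(state, p, s_r = p$s_r) {
  if (is.list(state)) state <- c(state$R_T, state$r_T)
  fs <- solve_complexes(state[1], state[2], p)
  pol <- .mmi_polys(p)
  x <- fs$r / p$K_scaled
  dRT <- p$s_R - p$k_R * fs$R * .polyval(pol$phi_a, x)
  drT <- s_r - p$k_r * (fs$r + fs$R * .polyval(pol$psi_b, x))
  c(dR_T = dRT, dr_T = unname(drT))
}

#' Right-hand side of the full mass-action circuit
#'
#' Derivatives of all species `(R, r, C_1, ..., C_n)` without the
#' quasi-steady-state reduction. Binding is stepwise with association rate
#' `kon` per free site and dissociation rate `koff = kon * K` per bound
#' miRNA (under the statistical-factors convention the 1:i complex binds a
#' further miRNA at `(n - i) kon` and releases one at `i * koff`, so the
#' equilibrium matches `C_i = choose(n, i) R (r/K)^i`). Complex-resolved
#' degradation releases the surviving partner: mRNA decay of the 1:i complex
#' (rate `a_i k_R`) frees its i miRNAs, and each bound miRNA decays at
#' `b_i k_r`, stepping the complex down to `C_{i-1}`.
#'
#' @param state Numeric vector `c(R, r, C_1, ..., C_n)`.
#' @param p An [mmi_parameters] record.
#' @param kon Association rate constant (nondimensional); binding is fast
#'   relative to turnover when `kon >= 1e4`.
#' @return Numeric vector of derivatives in the same order.
#' @export
full_rhs <- function(state, p, kon = 1e6) {
  if (kon <= 0) stop("kon must be positive")
  n <- p$n_sites
  if (length(state) != n + 2L) stop("state must have length n_sites + 2")
  R <- state[1]; r <- state[2]; C <- state[3:(n + 2L)]
  koff <- kon * p$K_scaled
  stat <- p$binding_convention == "statistical_factors"
  i <- seq_len(n)
  kon_i  <- if (stat) (n - i + 1) * kon else rep(kon, n)   # C_{i-1} + r -> C_i
  koff_i <- if (stat) i * koff else rep(koff, n)           # C_i -> C_{i-1} + r
  lam <- if (p$mirna_loss_convention == "per_molecule") i else rep(1, n)
  Cm1 <- c(R, C[-n])                                  # C_0 = R
  bind <- kon_i * Cm1 * r
  unbind <- koff_i * C
  mdeg <- p$a * p$k_R * C                             # mRNA decays in C_i
  rdeg <- lam * p$b * p$k_r * C                       # one miRNA decays in C_i
  dR <- p$s_R - p$k_R * R - bind[1] + unbind[1] + rdeg[1]
  dr <- p$s_r - p$k_r * r - sum(bind) + sum(unbind) + sum(i * mdeg)
  dC <- bind - unbind - mdeg - rdeg
  if (n > 1L) {
    up <- 2:n
    dC[up - 1L] <- dC[up - 1L] - bind[up] + unbind[up] + rdeg[up]
  }
  c(dR = dR, dr = unname(dr), dC)
}

#' Reduced model with a competitor mRNA sharing the miRNA pool
#'
#' Builds the three-total reduced system `(R_T, R2_T, r_T)` in which a second
#' target mRNA competes for the same free miRNA. The binding equilibria of
#' both targets are coupled only through the free miRNA concentration, which
#' is found by a one-dimensional root solve on the joint miRNA conservation.
#' With `s_R2 = 0` the competitor vanishes and the system collapses exactly
#' to the base circuit.
#'
#' @param p An [mmi_parameters] record for the primary target.
#' @param q A [competitor_parameters] record.
#' @return A list of class `mmi_competitor_model` with elements `rhs(state,
#'   s_r)` (derivatives of `c(R_T, R2_T, r_T)`), `equilibrium(state)` (free
#'   species split) and the parameter records.
#' @export
build_competitor_model <- function(p, q) {
  stopifnot(inherits(p, "mmi_parameters"), inherits(q, "competitor_parameters"))
  p2 <- mmi_parameters(n_sites = q$n_sites2, a = q$a2_vec, b = q$b2_vec,
                       s_R = max(q$s_R2, 1e-300), k_R = q$k_R2,
                       K_scaled = q$K2_scaled,
                       binding_convention = p$binding_convention,
                       mirna_loss_convention = p$mirna_loss_convention)
  pol1 <- .mmi_polys(p); pol2 <- .mmi_polys(p2)
  K1 <- p$K_scaled; K2 <- p2$K_scaled
  equilibrium <- function(state) {
    RT <- state[1]; RT2 <- state[2]; rT <- state[3]
    bound <- function(r) {
      x1 <- r / K1; x2 <- r / K2
      RT * .polyval(pol1$psi, x1) / .polyval(pol1$phi, x1) +
        RT2 * .polyval(pol2$psi, x2) / .polyval(pol2$phi, x2)
    }
    if (rT <= 0) {
      r <- 0
    } else {
      fr <- function(r) r + bound(r) - rT
      r <- stats::uniroot(fr, c(0, rT), tol = .Machine$double.eps^0.75)$root
    }
    x1 <- r / K1; x2 <- r / K2
    list(r = r,
         R1 = RT / .polyval(pol1$phi, x1), x1 = x1,
         R2 = if (RT2 > 0) RT2 / .polyval(pol2$phi, x2) else 0, x2 = x2)
  }
  rhs <- function(state, s_r = p$s_r) {
    eq <- equilibrium(state)
    dRT <- p$s_R - p$k_R * eq$R1 * .polyval(pol1$phi_a, eq$x1)
    dRT2 <- q$s_R2 - q$k_R2 * eq$R2 * .polyval(pol2$phi_a, eq$x2)
    drT <- s_r - p$k_r * (eq$r + eq$R1 * .polyval(pol1$psi_b, eq$x1) +
                            eq$R2 * .polyval(pol2$psi_b, eq$x2))
    c(dR_T = unname(dRT), dR2_T = unname(dRT2), dr_T = unname(drT))
  }
  structure(list(rhs = rhs, equilibrium = equilibrium, p = p, q = q),
            class = "mmi_competitor_model")
}

#' Classify bistability of the competitor-extended system by attractor census
#'
#' Integrates the three-total competitor system from a grid of initial
#' conditions at each of several control values and counts distinct stable
#' attractors, mirroring the brute-force census used to audit the closed-form
#' classifier of the base circuit.
#'
#' @param model Result of [build_competitor_model()].
#' @param s_r_values Control values to probe.
#' @param t_end Integration horizon.
#' @param n_init Number of initial conditions per control value.
#' @return Logical: `TRUE` if any control value supports >= 2 attractors.
#' @export
competitor_bistable <- function(model, s_r_values = seq(0.1, 0.6, by = 0.05),
                                t_end = 400) {
  stopifnot(inherits(model, "mmi_competitor_model"))
  p <- model$p
  fn <- function(t, y, parms) list(model$rhs(y, s_r = parms))
  for (s in s_r_values) {
    inits <- rbind(c(1.5 * p$s_R / p$k_R, 0.1, 0.01),
                   c(0.01, 0.1, 1.5 * max(s, 0.1)))
    keyR <- apply(inits, 1, function(y0) {
      out <- deSolve::ode(y = y0, times = c(0, t_end / 2, t_end),
                          func = fn, parms = s, method = "lsoda",
                          rtol = 1e-8, atol = 1e-10)
      fin <- out[nrow(out), -1]
      if (any(!is.finite(fin))) return(NA_real_)
      model$equilibrium(fin)$R1
    })
    if (all(is.finite(keyR)) &&
        abs(diff(log10(pmax(keyR, 1e-30)))) > 2) return(TRUE)
  }
  FALSE
}
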