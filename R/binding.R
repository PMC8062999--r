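#' Solve the fast binding equilibrium for given totals
#'
#' Under the total quasi-steady-state assumption the binding and unbinding
#' steps are equilibrated, so for given total mRNA `R_T = R + sum(C_i)` and
#' total miRNA `r_T = r + sum(i * C_i)` the free species and complexes are
#' determined by the algebra `C_i = w_i R (r/K)^i` (with `w_i` the
#' site-multiplicity weights of the binding convention). Eliminating `R`
#' through the mRNA conservation leaves a single polynomial in the free miRNA
#' `r` of degree `n_sites + 1`, whose unique root in `[0, r_T]` is the
#' physical branch.
#'
#' @param R_T Total mRNA concentration (scalar, >= 0).
#' @param r_T Total miRNA concentration (scalar, >= 0).
#' @param p An [mmi_parameters] record.
#' @param rel_tol Relative residual tolerance for the conservation audit.
#' @return A list of class `mmi_full_state` with components `R`, `r` (free
#'   species) and `C` (complex concentrations `C_1 .. C_n`).
#' @examples
#' p <- mmi_parameters(2)
#' solve_complexes(1, 1, p)
#' @export
solve_complexes <- function(R_T, r_T, p, rel_tol = 1e-12) {
  stopifnot(inherits(p, "mmi_parameters"))
  if (!is.finite(R_T) || !is.finite(r_T) || R_T < 0 || r_T < 0)
    stop("totals must be finite and nonnegative")
  K <- p$K_scaled
  pol <- .mmi_polys(p)
  if (r_T == 0 || R_T == 0) {
    st <- list(R = R_T, r = r_T, C = rep(0, p$n_sites))
    class(st) <- "mmi_full_state"
    return(st)
  }
  # g(x) = K x phi(x) + R_T psi(x) - r_T phi(x), x = r / K
  g_coef <- .polymul(c(0, K), pol$phi) + c(R_T * pol$psi, 0) - c(r_T * pol$phi, 0)
  x_hi <- r_T / K
  roots <- .real_positive_roots(g_coef)
  roots <- roots[roots <= x_hi * (1 + 1e-9)]
  gfun <- function(x) K * x * .polyval(pol$phi, x) +
    R_T * .polyval(pol$psi, x) - r_T * .polyval(pol$phi, x)
  if (length(roots) >= 1L) {
    x <- roots[which.min(abs(gfun(roots)))]
  } else {
    # bisection fallback; g(0) = -r_T < 0, g(x_hi) = R_T psi(x_hi) > 0
    x <- tryCatch(
      stats::uniroot(gfun, c(0, x_hi), tol = .Machine$double.eps^0.75)$root,
      error = function(e)
        stop(sprintf("binding equilibrium did not converge for R_T=%g, r_T=%g", R_T, r_T)))
  }
  # one Newton polish against round-off in the polynomial root
  dg <- .polyder(g_coef)
  for (k in 1:3) {
    d <- .polyval(dg, x)
    if (abs(d) > 0) {
      step <- gfun(x) / d
      x_new <- x - step
      if (is.finite(x_new) && x_new >= 0 && x_new <= x_hi) x <- x_new
    }
  }
  R <- R_T / .polyval(pol$phi, x)
  ww <- .mmi_weights(p)
  C <- ww$w * R * x^ww$i
  r <- K * x
  res1 <- abs(R + sum(C) - R_T) / max(R_T, 1)
  res2 <- abs(r + sum(ww$i * C) - r_T) / max(r_T, 1)
  if (res1 > rel_tol * 1e3 || res2 > rel_tol * 1e3)
    stop(sprintf("binding equilibrium residual too large for R_T=%g, r_T=%g", R_T, r_T))
  st <- list(R = R, r = r, C = C)
  class(st) <- "mmi_full_state"
  st
}

# Vectorized Newton solver for the binding equilibrium over many cells.
# RT, rT vectors; returns list(x = r/K, R, r). Used by the tissue simulator,
# where warm starts from the previous time step give 2-4 iterations.
.solve_complexes_vec <- function(RT, rT, pol, K, x0 = NULL,
                                 tol = 1e-10, max_iter = 50L) {
  n <- length(RT)
  x_hi <- pmax(rT / K, 0)
  x <- if (is.null(x0)) 0.5 * x_hi else pmin(pmax(x0, 0), x_hi)
  cphi <- pol$phi; cpsi <- pol$psi
  cdphi <- .polyder(cphi); cdpsi <- .polyder(cpsi)
  lo <- numeric(n); hi <- x_hi
  for (it in seq_len(max_iter)) {
    phi <- rep(cphi[length(cphi)], n)
    for (k in seq(length(cphi) - 1L, 1L)) phi <- phi * x + cphi[k]
    psi <- rep(cpsi[length(cpsi)], n)
    for (k in seq(length(cpsi) - 1L, 1L)) psi <- psi * x + cpsi[k]
    g <- (K * x - rT) * phi + RT * psi
    done <- abs(g) <= tol * pmax(1, rT)
    if (all(done)) break
    dphi <- rep(cdphi[length(cdphi)], n)
    if (length(cdphi) > 1L)
      for (k in seq(length(cdphi) - 1L, 1L)) dphi <- dphi * x + cdphi[k]
    dpsi <- rep(cdpsi[length(cdpsi)], n)
    if (length(cdpsi) > 1L)
      for (k in seq(length(cdpsi) - 1L, 1L)) dpsi <- dpsi * x + cdpsi[k]
    pos <- g > 0
    hi[pos] <- pmin(hi[pos], x[pos])
    lo[!pos] <- pmax(lo[!pos], x[!pos])
    x_new <- x - g / (K * phi + (K * x - rT) * dphi + RT * dpsi)
    bad <- !is.finite(x_new) | x_new < lo | x_new > hi
    x_new[bad] <- 0.5 * (lo[bad] + hi[bad])
    x[!done] <- x_new[!done]
  }
  R <- RT / .polyval(pol$phi, x)
  list(x = x, R = R, r = K * x)
}
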