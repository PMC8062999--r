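#' Phase-plane structure of the reduced circuit
#'
#' Computes the two nullclines of the reduced system in the `(R_T, r_T)`
#' plane, a sample of the vector field, the fixed points, and (for bistable
#' parameter sets) the separatrix, obtained by integrating backward in time
#' from the saddle along its stable eigendirections.
#'
#' Both nullclines are parametric curves in the free miRNA level: on the
#' total-mRNA nullcline `R = (s_R/k_R)/phi_a`, and on the total-miRNA
#' nullcline `R = (s_r/k_r - r)/psi_b`; mapping through the binding algebra
#' gives the totals.
#'
#' @param p An [mmi_parameters] record (its `s_r` is the control value used).
#' @param r_max Upper end of the free-miRNA sweep; defaults to covering all
#'   fixed points with margin.
#' @param n_curve Points per nullcline.
#' @param n_field Vector-field sample points per axis.
#' @param t_separatrix Backward-integration horizon for the separatrix.
#' @return A list of class `mmi_phase_plane` with `nullcline_RT`,
#'   `nullcline_rT` (data frames `R_T`, `r_T`), `fixed_points` (from
#'   [steady_states_at()]), `field` (data frame with `R_T`, `r_T`, `dR_T`,
#'   `dr_T`) and `separatrix` (data frame, possibly empty, with a `status`
#'   attribute `"ok"` or `"no_saddle"`).
#' @export
phase_plane <- function(p, r_max = NULL, n_curve = 300L, n_field = 8L,
                        t_separatrix = 50) {
  stopifnot(inherits(p, "mmi_parameters"))
  fps <- steady_states_at(p, p$s_r)
  K <- p$K_scaled
  if (is.null(r_max)) {
    r_max <- max(c(fps$r, p$s_r / p$k_r), na.rm = TRUE) * 1.5 + 10 * K
  }
  pol <- .mmi_polys(p)
  rg <- exp(seq(log(K * 1e-4), log(r_max), length.out = n_curve))
  xg <- rg / K
  curve_from <- function(Rfree, rg, xg) {
    ok <- is.finite(Rfree) & Rfree >= 0
    data.frame(R_T = (Rfree * .polyval(pol$phi, xg))[ok],
               r_T = (rg + Rfree * .polyval(pol$psi, xg))[ok],
               R = Rfree[ok], r = rg[ok])
  }
  nc1 <- curve_from((p$s_R / p$k_R) / .polyval(pol$phi_a, xg), rg, xg)
  R2 <- (p$s_r / p$k_r - rg) / .polyval(pol$psi_b, xg)
  R2[rg >= p$s_r / p$k_r] <- NA
  nc2 <- curve_from(R2, rg, xg)
  # vector-field sample
  RT_max <- max(c(nc1$R_T, fps$R_T), na.rm = TRUE) * 1.2
  rT_max <- max(c(nc2$r_T, fps$r_T, p$s_r / p$k_r), na.rm = TRUE) * 1.2
  grid <- expand.grid(R_T = seq(RT_max / n_field, RT_max, length.out = n_field),
                      r_T = seq(rT_max / n_field, rT_max, length.out = n_field))
  d <- t(apply(grid, 1, function(z) reduced_rhs(c(z[1], z[2]), p)))
  field <- cbind(grid, dR_T = d[, 1], dr_T = d[, 2])
  # separatrix: backward trajectories from the saddle's stable directions
  sep <- data.frame(R_T = numeric(0), r_T = numeric(0))
  status <- "no_saddle"
  sad <- fps[fps$stability == "saddle", , drop = FALSE]
  if (nrow(sad) >= 1L) {
    status <- "ok"
    s0 <- c(sad$R_T[1], sad$r_T[1])
    fs <- solve_complexes(s0[1], s0[2], p)
    J <- .reduced_jacobian(fs, p)
    eg <- eigen(J)
    stable_dir <- Re(eg$vectors[, which.min(Re(eg$values))])
    stable_dir <- stable_dir / sqrt(sum(stable_dir^2))
    back <- function(sign_) {
      y0 <- s0 + sign_ * 1e-6 * max(1, max(abs(s0))) * stable_dir
      fn <- function(t, y, parms) {
        if (any(y < 0) || any(y > 10 * c(RT_max, rT_max))) return(list(c(0, 0)))
        list(-reduced_rhs(y, p))
      }
      out <- deSolve::ode(y = y0, times = seq(0, t_separatrix, length.out = 200),
                          func = fn, parms = NULL, method = "lsoda",
                          rtol = 1e-8, atol = 1e-12)
      data.frame(R_T = out[, 2], r_T = out[, 3])
    }
    up <- back(1)
    dn <- back(-1)
    sep <- rbind(dn[rev(seq_len(nrow(dn))), ], up)
  } else {
    warning("no saddle at this control value; separatrix empty")
  }
  attr(sep, "status") <- status
  structure(list(nullcline_RT = nc1, nullcline_rT = nc2, fixed_points = fps,
                 field = field, separatrix = sep, parameters = p),
            class = "mmi_phase_plane")
}

#' @export
print.mmi_phase_plane <- function(x, ...) {
  cat(sprintf("phase plane at s_r = %g: %d fixed points (%s); separatrix: %s\n",
              x$parameters$s_r, nrow(x$fixed_points),
              paste(x$fixed_points$stability, collapse = ", "),
              attr(x$separatrix, "status")))
  invisible(x)
}

#' @export
plot.mmi_phase_plane <- function(x, log = "xy", ...) {
  nc1 <- x$nullcline_RT; nc2 <- x$nullcline_rT
  graphics::plot(range(c(nc1$R_T, nc2$R_T)), range(c(nc1$r_T, nc2$r_T)),
                 type = "n", log = log, xlab = "total mRNA", ylab = "total miRNA", ...)
  graphics::lines(nc1$R_T, nc1$r_T, col = "blue")
  graphics::lines(nc2$R_T, nc2$r_T, col = "orange")
  if (nrow(x$separatrix)) graphics::lines(x$separatrix$R_T, x$separatrix$r_T,
                                          col = "gray")
  fp <- x$fixed_points
  graphics::points(fp$R_T, fp$r_T,
                   pch = ifelse(fp$stability == "stable_node_or_focus", 16, 1))
  invisible(x)
}
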