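# Steady-state location, stability, and fold structure of the reduced circuit.
#
# At a fixed point, the mRNA balance gives R = (s_R/k_R) / phi_a(x) with
# x = r / K, and substituting into the miRNA balance yields the closed-form
# control curve
#   s_r(r) = k_r * ( r + (s_R/k_R) * psi_b(x) / phi_a(x) ),
# so every steady state is a root of a polynomial in x of degree n_sites + 1,
# and folds (saddle-node points) are roots of the numerator polynomial of
# d s_r / d r. When s_R is the control (morphogen-driven transcription), the
# mirror inversion s_R(r) = (s_r/k_r - r) * k_R * phi_a / psi_b is used.

#' Control value at which a given free-miRNA level is a steady state
#'
#' Inverts the steady-state relation in closed form: for `control = "s_r"`
#' returns the unique miRNA synthesis rate making `r` a steady-state free
#' miRNA level; for `control = "s_R"` returns the mRNA synthesis rate
#' (defined for `r < s_r / k_r`).
#'
#' @param r Free miRNA concentration(s), > 0 (vectorized).
#' @param p An [mmi_parameters] record.
#' @param control `"s_r"` (default) or `"s_R"`.
#' @return Control value(s), same length as `r`.
#' @export
control_at_steady_state <- function(r, p, control = c("s_r", "s_R")) {
  control <- match.arg(control)
  pol <- .mmi_polys(p)
  x <- r / p$K_scaled
  S <- p$s_R / p$k_R
  if (control == "s_r") {
    p$k_r * (r + S * .polyval(pol$psi_b, x) / .polyval(pol$phi_a, x))
  } else {
    sig <- p$s_r / p$k_r
    ifelse(r < sig,
           (sig - r) * p$k_R * .polyval(pol$phi_a, x) / .polyval(pol$psi_b, x),
           NA_real_)
  }
}

# fold polynomial in x: roots are interior extrema of the control curve
.fold_poly <- function(p, control = "s_r") {
  pol <- .mmi_polys(p)
  S <- p$s_R / p$k_R
  K <- p$K_scaled
  if (control == "s_r") {
    # d s_r/dr numerator: phi_a^2 + (S/K) (psi_b' phi_a - psi_b phi_a')
    num <- .polymul(pol$phi_a, pol$phi_a)
    cross <- .polymul(.polyder(pol$psi_b), pol$phi_a) -
      .polymul(pol$psi_b, .polyder(pol$phi_a))
    cross <- c(cross, numeric(max(0L, length(num) - length(cross))))
    num + (S / K) * cross[seq_along(num)]
  } else {
    # d s_R/dx numerator: -K phi_a psi_b + (sigma - K x)(phi_a' psi_b - phi_a psi_b')
    sig <- p$s_r / p$k_r
    t1 <- -K * .polymul(pol$phi_a, pol$psi_b)
    cross <- .polymul(.polyder(pol$phi_a), pol$psi_b) -
      .polymul(pol$phi_a, .polyder(pol$psi_b))
    t2 <- .polymul(c(sig, -K), cross)
    nl <- max(length(t1), length(t2))
    c(t1, numeric(nl - length(t1))) + c(t2, numeric(nl - length(t2)))
  }
}

# interior extrema (fold candidates) of the control curve, as x = r/K
.curve_extrema <- function(p, control = "s_r") {
  xs <- .real_positive_roots(.fold_poly(p, control))
  if (control == "s_R") xs <- xs[xs < p$s_r / (p$k_r * p$K_scaled)]
  xs
}

# analytic Jacobian of the reduced system in (R_T, r_T) at a full state
.reduced_jacobian <- function(fs, p) {
  pol <- .mmi_polys(p)
  K <- p$K_scaled
  x <- fs$r / K
  R <- fs$R
  dphi <- .polyval(.polyder(pol$phi), x) / K
  dpsi <- .polyval(.polyder(pol$psi), x) / K
  dphia <- .polyval(.polyder(pol$phi_a), x) / K
  dpsib <- .polyval(.polyder(pol$psi_b), x) / K
  M <- matrix(c(.polyval(pol$phi, x), R * dphi,
                .polyval(pol$psi, x), 1 + R * dpsi),
              2, 2, byrow = TRUE)          # d(R_T, r_T)/d(R, r)
  Fm <- matrix(c(-p$k_R * .polyval(pol$phi_a, x), -p$k_R * R * dphia,
                 -p$k_r * .polyval(pol$psi_b, x), -p$k_r * (1 + R * dpsib)),
               2, 2, byrow = TRUE)         # dF/d(R, r)
  Fm %*% solve(M)
}

.stability_label <- function(J) {
  ev <- eigen(J, only.values = TRUE)$values
  lead <- max(Re(ev))
  lab <- if (is.complex(ev[1]) && any(abs(Im(ev)) > 1e-12)) {
    if (lead < 0) "stable_node_or_focus" else "unstable"
  } else {
    if (all(Re(ev) < 0)) "stable_node_or_focus"
    else if (prod(Re(ev)) < 0) "saddle" else "unstable"
  }
  list(label = lab, leading = lead)
}

# stability of the reduced system without explicitly inverting the totals
# Jacobian M (which is badly conditioned at extreme occupancies): with
# J = F M^-1, tr(J) = tr(F adj(M)) / det(M) and det(J) = det(F) / det(M)
.stability_at <- function(fs, p) {
  pol <- .mmi_polys(p)
  K <- p$K_scaled
  x <- fs$r / K
  R <- fs$R
  dphi <- .polyval(.polyder(pol$phi), x) / K
  dpsi <- .polyval(.polyder(pol$psi), x) / K
  dphia <- .polyval(.polyder(pol$phi_a), x) / K
  dpsib <- .polyval(.polyder(pol$psi_b), x) / K
  M11 <- .polyval(pol$phi, x);  M12 <- R * dphi
  M21 <- .polyval(pol$psi, x);  M22 <- 1 + R * dpsi
  F11 <- -p$k_R * .polyval(pol$phi_a, x); F12 <- -p$k_R * R * dphia
  F21 <- -p$k_r * .polyval(pol$psi_b, x); F22 <- -p$k_r * (1 + R * dpsib)
  detM <- M11 * M22 - M12 * M21
  trJ <- (F11 * M22 - F12 * M21 - F21 * M12 + F22 * M11) / detM
  detJ <- (F11 * F22 - F12 * F21) / detM
  disc <- trJ^2 - 4 * detJ
  lead <- if (is.finite(disc) && disc >= 0) (trJ + sqrt(disc)) / 2 else trJ / 2
  lab <- if (!is.finite(detJ) || !is.finite(trJ)) "unstable"
    else if (detJ < 0) "saddle"
    else if (trJ < 0) "stable_node_or_focus" else "unstable"
  list(label = lab, leading = lead)
}

#' Steady states of the reduced circuit at one control value
#'
#' Finds all positive fixed points by exhaustive real-root extraction of the
#' one-variable steady-state polynomial in the free miRNA, then labels each
#' by the eigenvalues of the reduced two-variable Jacobian (computed through
#' the binding algebra by implicit differentiation).
#'
#' @param p An [mmi_parameters] record.
#' @param control_value Value of the control parameter.
#' @param control `"s_r"` (miRNA synthesis, default) or `"s_R"`.
#' @param degenerate_tol Roots closer than this (relative, on x) are merged
#'   and flagged as degenerate fold points.
#' @return A data frame with one row per fixed point: `control_value`, `R_T`,
#'   `r_T`, `R`, `r`, complex columns `C1..`, `stability`,
#'   `leading_eigenvalue_real_part`, `degenerate`.
#' @examples
#' p <- mmi_parameters(2, a = c(1, 10), b = c(1, 1))
#' steady_states_at(p, control_value = 0.27)
#' @export
steady_states_at <- function(p, control_value, control = c("s_r", "s_R"),
                             degenerate_tol = 1e-8) {
  control <- match.arg(control)
  stopifnot(inherits(p, "mmi_parameters"))
  if (!is.finite(control_value) || control_value < 0)
    stop("control_value must be finite and nonnegative")
  pol <- .mmi_polys(p)
  K <- p$K_scaled
  S <- p$s_R / p$k_R
  if (control == "s_r") {
    # control * phi_a = k_r (K x phi_a + S psi_b)
    coef <- c(control_value * pol$phi_a, 0) -
      p$k_r * (.polymul(c(0, K), pol$phi_a) + c(S * pol$psi_b, 0))
  } else {
    # control * psi_b = k_R (sigma - K x) phi_a,  sigma = s_r/k_r
    sig <- p$s_r / p$k_r
    t2 <- p$k_R * .polymul(c(sig, -K), pol$phi_a)
    coef <- c(control_value * pol$psi_b, numeric(max(0L, length(t2) - length(pol$psi_b)))) -
      c(t2, numeric(max(0L, length(pol$psi_b) - length(t2))))
  }
  xs <- .real_positive_roots(coef)
  if (control == "s_r" && control_value == 0) xs <- numeric(0)
  if (control == "s_R") xs <- xs[K * xs < p$s_r / p$k_r]
  # merge near-coincident roots (fold degeneracy)
  degen <- rep(FALSE, length(xs))
  if (length(xs) > 1L) {
    keep <- rep(TRUE, length(xs))
    for (k in 2:length(xs)) {
      if ((xs[k] - xs[k - 1L]) <= degenerate_tol * max(1, xs[k])) {
        keep[k] <- FALSE
        degen[k - 1L] <- TRUE
      }
    }
    degen <- degen[keep]
    xs <- xs[keep]
  }
  ww <- .mmi_weights(p)
  rows <- lapply(seq_along(xs), function(k) {
    x <- xs[k]
    if (control == "s_r") {
      R <- S / .polyval(pol$phi_a, x)
    } else {
      R <- (control_value / p$k_R) / .polyval(pol$phi_a, x)
    }
    r <- K * x
    C <- ww$w * R * x^ww$i
    fs <- list(R = R, r = r, C = C)
    st <- .stability_at(fs, p)
    out <- data.frame(control_value = control_value,
                      R_T = R + sum(C), r_T = r + sum(ww$i * C),
                      R = R, r = r,
                      stability = st$label,
                      leading_eigenvalue_real_part = st$leading,
                      degenerate = degen[k])
    for (j in ww$i) out[[paste0("C", j)]] <- C[j]
    out
  })
  if (length(rows) == 0L)
    return(data.frame(control_value = numeric(0), R_T = numeric(0),
                      r_T = numeric(0), R = numeric(0), r = numeric(0),
                      stability = character(0),
                      leading_eigenvalue_real_part = numeric(0),
                      degenerate = logical(0)))
  do.call(rbind, rows)
}

# union of control intervals with >= 3 coexisting states, from curve extrema.
# Returns matrix with columns lo, hi (possibly 0 rows).
.multistable_intervals <- function(p, control = "s_r") {
  xs <- .curve_extrema(p, control)
  if (length(xs) < 2L) return(matrix(numeric(0), 0, 2))
  vals <- control_at_steady_state(p$K_scaled * xs, p, control)
  # extrema alternate; each adjacent pair with a descent contributes the
  # value interval it spans
  iv <- NULL
  for (k in seq_len(length(xs) - 1L)) {
    lo <- min(vals[k], vals[k + 1L]); hi <- max(vals[k], vals[k + 1L])
    if (hi > lo) iv <- rbind(iv, c(lo, hi))
  }
  if (is.null(iv)) return(matrix(numeric(0), 0, 2))
  # merge overlaps
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
    if (iv[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, ])
  }
  out
}

#' One-parameter bifurcation diagram of the reduced circuit
#'
#' Traces the steady-state curve by sweeping the free miRNA level (the
#' natural parameter along the S-shaped curve), so saddle-node folds are
#' resolved exactly as interior extrema of the closed-form control curve
#' rather than by continuation stepping.
#'
#' @param p An [mmi_parameters] record.
#' @param control_range Numeric length-2 interval of control values.
#' @param resolution Number of sample points along the curve.
#' @param control `"s_r"` (default) or `"s_R"`.
#' @return An object of class `mmi_bifurcation`: list with `control_name`,
#'   `branches` (data frame: `control_value`, `R_T`, `r_T`, `R`, `r`,
#'   `stability`, `branch`), `folds` (data frame of saddle-node points) and
#'   `bistable_interval` (length-2 numeric or `NULL`).
#' @examples
#' p <- mmi_parameters(2, a = c(1, 10), b = c(1, 1))
#' bd <- bifurcation_diagram(p, c(0, 1))
#' bd$bistable_interval
#' @export
bifurcation_diagram <- function(p, control_range = c(0, 4), resolution = 400L,
                                control = c("s_r", "s_R")) {
  control <- match.arg(control)
  if (length(control_range) != 2L || diff(control_range) <= 0)
    stop("control_range must be an increasing length-2 interval")
  K <- p$K_scaled
  xs_fold <- .curve_extrema(p, control)
  # r-range covering the requested control window
  if (control == "s_r") {
    r_hi <- max(control_range[2] / p$k_r, K)
  } else {
    r_hi <- p$s_r / p$k_r * (1 - 1e-9)
  }
  xg <- exp(seq(log(1e-6), log(r_hi / K), length.out = resolution))
  xg <- sort(unique(c(xg, xs_fold[xs_fold <= r_hi / K])))
  vals <- control_at_steady_state(K * xg, p, control)
  keep <- is.finite(vals) & vals >= control_range[1] & vals <= control_range[2]
  xg <- xg[keep]; vals <- vals[keep]
  pol <- .mmi_polys(p)
  ww <- .mmi_weights(p)
  Rfree <- if (control == "s_r") {
    (p$s_R / p$k_R) / .polyval(pol$phi_a, xg)
  } else {
    (vals / p$k_R) / .polyval(pol$phi_a, xg)
  }
  RT <- Rfree * .polyval(pol$phi, xg)
  rT <- K * xg + Rfree * .polyval(pol$psi, xg)
  branch <- findInterval(xg, xs_fold) + 1L
  stab <- vapply(seq_along(xg), function(k) {
    .stability_at(list(R = Rfree[k], r = K * xg[k]), p)$label
  }, character(1))
  branches <- data.frame(control_value = vals, R_T = RT, r_T = rT,
                         R = Rfree, r = K * xg,
                         stability = stab, branch = branch)
  fold_vals <- control_at_steady_state(K * xs_fold, p, control)
  fold_keep <- is.finite(fold_vals) & fold_vals >= control_range[1] &
    fold_vals <= control_range[2]
  folds <- data.frame(control_value = fold_vals[fold_keep],
                      r = K * xs_fold[fold_keep],
                      R = if (control == "s_r") {
                        (p$s_R / p$k_R) / .polyval(pol$phi_a, xs_fold[fold_keep])
                      } else {
                        (fold_vals[fold_keep] / p$k_R) /
                          .polyval(pol$phi_a, xs_fold[fold_keep])
                      })
  iv <- .multistable_intervals(p, control)
  bi <- NULL
  if (nrow(iv) > 0L) {
    lo <- pmax(iv[, 1], control_range[1]); hi <- pmin(iv[, 2], control_range[2])
    ok <- hi > lo
    if (any(ok)) bi <- c(min(lo[ok]), max(hi[ok]))
  }
  structure(list(control_name = control, branches = branches, folds = folds,
                 bistable_interval = bi, parameters = p),
            class = "mmi_bifurcation")
}

#' @export
print.mmi_bifurcation <- function(x, ...) {
  cat(sprintf("bifurcation diagram in %s: %d branch points, %d folds\n",
              x$control_name, nrow(x$branches), nrow(x$folds)))
  if (is.null(x$bistable_interval)) {
    cat("  monostable over the sampled window\n")
  } else {
    cat(sprintf("  bistable for %s in [%.5g, %.5g]\n", x$control_name,
                x$bistable_interval[1], x$bistable_interval[2]))
  }
  invisible(x)
}

#' @export
plot.mmi_bifurcation <- function(x, y_var = "R", log = "y", ...) {
  b <- x$branches
  yv <- pmax(b[[y_var]], 1e-300)
  graphics::plot(b$control_value, yv, type = "n", log = log,
                 xlab = x$control_name, ylab = paste("free", y_var), ...)
  for (br in unique(b$branch)) {
    sel <- b$branch == br
    graphics::lines(b$control_value[sel], yv[sel],
                    lty = ifelse(any(b$stability[sel] == "saddle"), 2, 1))
  }
  if (nrow(x$folds)) graphics::points(x$folds$control_value,
                                      pmax(x$folds$R, 1e-300), pch = 1)
  invisible(x)
}

#' Export a bifurcation diagram as a tidy table
#'
#' @param x An `mmi_bifurcation` object.
#' @param path Optional CSV path; when given the table is also written there.
#' @return The branch table (one row per branch point), invisibly if written.
#' @export
bifurcation_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "mmi_bifurcation"))
  tab <- x$branches
  tab$control_name <- x$control_name
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
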