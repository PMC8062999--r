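# Random-parameter bistability screen for the mmi-2 / mmi-3 circuits.
#
# Classification uses the closed-form control curve s_r(r): the circuit is
# bistable iff the curve is non-monotonic in the free miRNA, i.e. iff the
# fold polynomial has >= 2 positive roots, with the lower fold value inside
# the observable control window. This is exact up to polynomial root finding
# and runs four orders of magnitude faster than continuation, which makes
# 10^4-set screens a matter of seconds.

# lean classifier core; a, b numeric vectors of equal length
.classify_core <- function(a, b, K = 1e-5, control_range = c(0, 10),
                           stat = TRUE, per_molecule = TRUE,
                           want_metrics = FALSE) {
  n <- length(a)
  i <- seq_len(n)
  w <- if (stat) choose(n, i) else rep(1, n)
  lam <- if (per_molecule) i else rep(1, n)
  phi_a <- c(1, w * a)
  psi_b <- c(0, lam * w * b)
  num <- .polymul(phi_a, phi_a)
  cross <- .polymul(.polyder(psi_b), phi_a) - .polymul(psi_b, .polyder(phi_a))
  cross <- c(cross, numeric(max(0L, length(num) - length(cross))))
  N <- num + cross[seq_along(num)] / K
  xs <- .real_positive_roots(N)
  out <- list(bistable = FALSE, bistable_width = 0,
              free_mrna_drop_log10 = NA_real_,
              total_mrna_change_log10 = NA_real_, failed = FALSE)
  if (length(xs) < 2L) return(out)
  h <- function(x) K * x + .polyval(psi_b, x) / .polyval(phi_a, x)
  vals <- h(xs)
  # union of control intervals spanned by monotone-descent segments
  iv <- NULL
  for (k in seq_len(length(xs) - 1L)) {
    lo <- min(vals[k], vals[k + 1L]); hi <- max(vals[k], vals[k + 1L])
    if (hi > lo * (1 + 1e-12)) iv <- rbind(iv, c(lo, hi))
  }
  if (is.null(iv)) return(out)
  lo <- pmax(iv[, 1], control_range[1]); hi <- pmin(iv[, 2], control_range[2])
  ok <- hi > lo
  if (!any(ok)) return(out)
  # merged width of observable multistable control intervals
  ivo <- cbind(lo[ok], hi[ok])
  ivo <- ivo[order(ivo[, 1]), , drop = FALSE]
  width <- 0; cur <- ivo[1, ]
  if (nrow(ivo) > 1L) for (k in 2:nrow(ivo)) {
    if (ivo[k, 1] <= cur[2]) cur[2] <- max(cur[2], ivo[k, 2]) else {
      width <- width + diff(cur); cur <- ivo[k, ]
    }
  }
  width <- width + diff(cur)
  out$bistable <- TRUE
  out$bistable_width <- unname(width)
  if (want_metrics) {
    # switch magnitude at the up-switch fold: from the upper-branch fold
    # state (first extremum x1) to the lower branch at the same control
    x1 <- xs[1]
    s1 <- h(x1)
    coef <- c(s1 * phi_a, 0) - (.polymul(c(0, K), phi_a) + c(psi_b, 0))
    roots <- .real_positive_roots(coef)
    # at the fold the root at x1 is double and may be reported as a complex
    # pair; the jump target is the far simple root beyond the last extremum
    roots <- roots[roots > max(xs) * (1 + 1e-9)]
    if (length(roots) >= 1L) {
      x2 <- max(roots)
      phi <- c(1, w)
      Rf <- function(x) 1 / .polyval(phi_a, x)
      RT <- function(x) Rf(x) * .polyval(phi, x)
      out$free_mrna_drop_log10 <- log10(Rf(x1) / Rf(x2))
      out$total_mrna_change_log10 <- log10(RT(x1) / RT(x2))
    } else {
      out$failed <- TRUE
    }
  }
  out
}

#' Sample random kinetic parameter sets
#'
#' Draws the relative degradation multipliers `a_i`, `b_i` independently from
#' a uniform distribution on `(low, high)`; all other rates are 1 and the
#' scaled dissociation constant is `K_scaled`. The draw is reproducible under
#' `seed` and independent of evaluation order.
#'
#' @param n Number of parameter sets.
#' @param low,high Bounds of the uniform sampling interval.
#' @param n_sites Number of binding sites (1, 2 or 3).
#' @param seed Integer seed.
#' @param K_scaled Scaled dissociation constant (default `1e-5`).
#' @param log_uniform Draw log-uniformly instead (used for the broad one-site
#'   audit).
#' @return A numeric matrix with `2 * n_sites` columns (`a1.., b1..`), one
#'   row per set, with attributes recording the sampling window.
#' @export
sample_parameters <- function(n, low = 0.125, high = 16, n_sites = 2L,
                              seed = 1L, K_scaled = 1e-5, log_uniform = FALSE) {
  if (n <= 0) stop("n must be positive")
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  n_sites <- as.integer(n_sites)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  m <- if (log_uniform) {
    exp(matrix(stats::runif(2L * n_sites * n, log(low), log(high)),
               ncol = 2L * n_sites, byrow = TRUE))
  } else {
    matrix(stats::runif(2L * n_sites * n, low, high),
           ncol = 2L * n_sites, byrow = TRUE)
  }
  colnames(m) <- c(paste0("a", seq_len(n_sites)), paste0("b", seq_len(n_sites)))
  attr(m, "n_sites") <- n_sites
  attr(m, "K_scaled") <- K_scaled
  attr(m, "bounds") <- c(low, high)
  m
}

#' Classify one parameter set as monostable or bistable
#'
#' A set is bistable iff the closed-form steady-state control curve is
#' non-monotonic in the free miRNA with the implied fold interval overlapping
#' the observable control window. For bistable sets the switch magnitudes are
#' evaluated at the up-switch fold: the log10 ratio of free mRNA (and of
#' total mRNA) between the upper-branch fold state and the lower branch at
#' the same control value.
#'
#' @param p An [mmi_parameters] record.
#' @param control_range Observable window for the miRNA synthesis rate.
#' @return A list of class `mmi_screen_record`: `params`, `bistable`,
#'   `bistable_width`, `free_mrna_drop_log10`, `total_mrna_change_log10`,
#'   `failed`.
#' @examples
#' classify_bistable(mmi_parameters(2, a = c(1, 10), b = c(1, 1)))
#' @export
classify_bistable <- function(p, control_range = c(0, 10)) {
  stopifnot(inherits(p, "mmi_parameters"))
  res <- .classify_core(p$a, p$b, K = p$K_scaled, control_range = control_range,
                        stat = p$binding_convention == "statistical_factors",
                        per_molecule = p$mirna_loss_convention == "per_molecule",
                        want_metrics = TRUE)
  res$params <- p
  class(res) <- "mmi_screen_record"
  res
}

#' Run a random-parameter bistability screen
#'
#' Applies the closed-form classifier to `n` parameter sets sampled by
#' [sample_parameters()] and summarizes the bistable fraction with its
#' binomial standard error.
#'
#' @param n_sites Number of binding sites.
#' @param n Number of sampled sets (>= 100).
#' @param seed Integer seed.
#' @param low,high Sampling interval for the degradation multipliers.
#' @param control_range Observable control window.
#' @param K_scaled Scaled dissociation constant.
#' @param metrics Also compute switch magnitudes per bistable record
#'   (slightly slower).
#' @param log_uniform Passed to [sample_parameters()].
#' @return A list of class `mmi_screen_summary`: `n_total`, `n_bistable`,
#'   `fraction_bistable`, `se_binomial`, `n_failed`, and `records` (a data
#'   frame with the sampled multipliers and per-record results).
#' @examples
#' run_screen(n_sites = 2, n = 200, seed = 1)
#' @export
run_screen <- function(n_sites = 2L, n = 10000L, seed = 1L,
                       low = 0.125, high = 16, control_range = c(0, 10),
                       K_scaled = 1e-5, metrics = TRUE, log_uniform = FALSE) {
  if (n < 100) stop("n must be at least 100")
  m <- sample_parameters(n, low, high, n_sites, seed, K_scaled, log_uniform)
  ns <- as.integer(n_sites)
  res <- matrix(NA_real_, nrow = n, ncol = 4L)
  for (k in seq_len(n)) {
    r <- .classify_core(m[k, seq_len(ns)], m[k, ns + seq_len(ns)],
                        K = K_scaled, control_range = control_range,
                        want_metrics = metrics)
    res[k, ] <- c(r$bistable, r$bistable_width,
                  if (metrics) r$free_mrna_drop_log10 else NA_real_,
                  if (metrics) r$total_mrna_change_log10 else NA_real_)
  }
  records <- data.frame(m, bistable = res[, 1] == 1,
                        bistable_width = res[, 2],
                        free_mrna_drop_log10 = res[, 3],
                        total_mrna_change_log10 = res[, 4])
  n_b <- sum(records$bistable)
  frac <- n_b / n
  structure(list(n_total = n, n_bistable = n_b, fraction_bistable = frac,
                 se_binomial = sqrt(frac * (1 - frac) / n),
                 n_failed = sum(records$bistable &
                                  !is.finite(records$free_mrna_drop_log10) &
                                  metrics),
                 n_sites = ns, seed = seed, records = records),
            class = "mmi_screen_summary")
}

#' @export
print.mmi_screen_summary <- function(x, ...) {
  cat(sprintf("bistability screen, mmi-%d: %d / %d bistable (%.2f%% +- %.2f%%)\n",
              x$n_sites, x$n_bistable, x$n_total,
              100 * x$fraction_bistable, 100 * x$se_binomial))
  invisible(x)
}

#' Analytic bistability condition for the two-site circuit
#'
#' The two-site circuit admits three positive steady states only if
#' `a1 / b1 < a2 / (2 * b2)`: the per-mRNA degradation gain of the doubly
#' occupied complex must exceed twice the singly occupied ratio, breaking the
#' symmetry of mutual stoichiometric inhibition into a net double-negative
#' feedback loop.
#'
#' @param p An [mmi_parameters] record with `n_sites = 2`.
#' @return Logical.
#' @export
analytic_condition <- function(p) {
  stopifnot(inherits(p, "mmi_parameters"))
  if (p$n_sites != 2L) stop("the analytic condition applies to the 2-site circuit")
  p$a[1] / p$b[1] < p$a[2] / (2 * p$b[2])
}

#' Critical degradation-ratio threshold for onset of bistability
#'
#' Numerically locates, by bisection on `a2` (with `b2` fixed at 1), the
#' smallest ratio `a2/b2` at which some miRNA synthesis rate admits two
#' stable positive steady states. In the strong-binding limit this threshold
#' approaches `2 * a1 / b1`.
#'
#' @param a1,b1 Degradation multipliers of the singly occupied complex.
#' @param K_scaled Scaled dissociation constant.
#' @param tol Relative bisection tolerance.
#' @return The critical `a2/b2` ratio.
#' @examples
#' critical_ratio(1, 1)  # ~ 2
#' @export
critical_ratio <- function(a1, b1, K_scaled = 1e-9, tol = 1e-5) {
  if (a1 <= 0 || b1 <= 0) stop("a1 and b1 must be positive")
  is_bi <- function(a2) {
    .classify_core(c(a1, a2), c(b1, 1), K = K_scaled,
                   control_range = c(0, Inf))$bistable
  }
  lo <- 1e-3 * a1 / b1; hi <- 2 * a1 / b1
  # expand upward until bistable
  for (k in 1:60) {
    if (is_bi(hi)) break
    lo <- hi; hi <- hi * 1.5
  }
  if (!is_bi(hi)) stop("failed to bracket the bistability threshold")
  while ((hi - lo) > tol * hi) {
    mid <- 0.5 * (lo + hi)
    if (is_bi(mid)) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}
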