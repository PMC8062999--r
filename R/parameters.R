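#' Kinetic parameters of an n-site mRNA-miRNA circuit
#'
#' Constructs the parameter record for a mass-action circuit in which one mRNA
#' species carries `n_sites` binding sites for a cognate miRNA. The model is
#' nondimensionalized so that concentrations are measured in units of
#' `s_R / k_R` and time in units of `1 / k_R`; with the defaults
#' `s_R = k_R = k_r = 1` the only remaining scales are the miRNA synthesis
#' rate `s_r` (the usual control parameter), the scaled dissociation constant
#' `K_scaled = K * k_R / s_R`, and the relative degradation multipliers.
#'
#' @param n_sites Number of miRNA binding sites on the mRNA (1, 2 or 3).
#' @param a Numeric vector of length `n_sites`: degradation rate multiplier of
#'   the mRNA while bound in the 1:i complex, relative to its basal rate
#'   `k_R` (`a[i]` applies to the complex carrying i miRNAs).
#' @param b Numeric vector of length `n_sites`: degradation rate multiplier of
#'   each bound miRNA in the 1:i complex, relative to its basal rate `k_r`.
#' @param s_R,s_r mRNA and miRNA synthesis rates (nondimensional).
#' @param k_R,k_r Basal degradation rate constants of free mRNA and free miRNA.
#' @param K_scaled Scaled dissociation constant `K * k_R / s_R` of one binding
#'   step. Strong binding corresponds to small values; the reference screens
#'   use `1e-5`.
#' @param binding_convention `"statistical_factors"` (default) counts the
#'   multiplicity of ways i miRNAs can occupy `n_sites` equivalent sites, so
#'   the equilibrium complex abundances are `C_i = choose(n, i) R (r/K)^i`;
#'   `"plain"` drops the combinatorial factors (`C_i = R (r/K)^i`).
#' @param mirna_loss_convention `"per_molecule"` (default): each bound miRNA
#'   decays independently at `b[i] * k_r`, so the 1:i complex loses miRNA at
#'   total rate `i * b[i] * k_r`. `"per_complex"`: the complex loses one miRNA
#'   at rate `b[i] * k_r` regardless of occupancy.
#'
#' @return An object of class `mmi_parameters`.
#' @examples
#' p <- mmi_parameters(n_sites = 2, a = c(1, 10), b = c(1, 1))
#' p
#' @export
mmi_parameters <- function(n_sites = 2L,
                           a = rep(1, n_sites),
                           b = rep(1, n_sites),
                           s_R = 1, s_r = 1, k_R = 1, k_r = 1,
                           K_scaled = 1e-5,
                           binding_convention = c("statistical_factors", "plain"),
                           mirna_loss_convention = c("per_molecule", "per_complex")) {
  n_sites <- as.integer(n_sites)
  if (!n_sites %in% 1:3) stop("n_sites must be 1, 2 or 3")
  if (length(a) != n_sites || length(b) != n_sites)
    stop("a and b must each have length n_sites")
  rates <- c(a, b, s_R, k_R, k_r, K_scaled)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rate constants and multipliers must be finite and strictly positive")
  if (!is.finite(s_r) || s_r < 0) stop("s_r must be nonnegative")
  structure(
    list(n_sites = n_sites, a = as.numeric(a), b = as.numeric(b),
         s_R = s_R, s_r = s_r, k_R = k_R, k_r = k_r, K_scaled = K_scaled,
         binding_convention = match.arg(binding_convention),
         mirna_loss_convention = match.arg(mirna_loss_convention)),
    class = "mmi_parameters")
}

#' @export
print.mmi_parameters <- function(x, ...) {
  cat(sprintf("mmi-%d circuit parameters (%s binding, %s miRNA loss)\n",
              x$n_sites, x$binding_convention, x$mirna_loss_convention))
  cat(sprintf("  a = (%s)   b = (%s)\n",
              paste(signif(x$a, 4), collapse = ", "),
              paste(signif(x$b, 4), collapse = ", ")))
  cat(sprintf("  s_R = %g  s_r = %g  k_R = %g  k_r = %g  K_scaled = %g\n",
              x$s_R, x$s_r, x$k_R, x$k_r, x$K_scaled))
  invisible(x)
}

#' Competitor mRNA parameters
#'
#' Parameters for an additional target mRNA that shares the free miRNA pool
#' with the primary circuit (a competing endogenous RNA).
#'
#' @param n_sites2 Number of miRNA binding sites on the competitor.
#' @param s_R2 Competitor mRNA synthesis rate; `0` removes the competitor.
#' @param k_R2 Competitor basal degradation rate constant.
#' @param a2_vec Relative mRNA degradation multipliers of the competitor in
#'   its 1:i complexes.
#' @param b2_vec Relative miRNA degradation multipliers in the competitor's
#'   complexes.
#' @param K2_scaled Scaled dissociation constant of competitor binding steps.
#' @return An object of class `competitor_parameters`.
#' @export
competitor_parameters <- function(n_sites2 = 1L, s_R2 = 0.1, k_R2 = 1,
                                  a2_vec = rep(1, n_sites2),
                                  b2_vec = rep(1, n_sites2),
                                  K2_scaled = 1e-5) {
  n_sites2 <- as.integer(n_sites2)
  if (!n_sites2 %in% 1:3) stop("n_sites2 must be 1, 2 or 3")
  if (length(a2_vec) != n_sites2 || length(b2_vec) != n_sites2)
    stop("a2_vec and b2_vec must have length n_sites2")
  if (s_R2 < 0) stop("s_R2 must be nonnegative")
  if (any(c(k_R2, a2_vec, b2_vec, K2_scaled) <= 0))
    stop("competitor rates must be strictly positive")
  structure(list(n_sites2 = n_sites2, s_R2 = s_R2, k_R2 = k_R2,
                 a2_vec = as.numeric(a2_vec), b2_vec = as.numeric(b2_vec),
                 K2_scaled = K2_scaled),
            class = "competitor_parameters")
}

# site-multiplicity weights w_i and per-molecule miRNA loss factors lambda_i
.mmi_weights <- function(p) {
  i <- seq_len(p$n_sites)
  w <- if (p$binding_convention == "statistical_factors") choose(p$n_sites, i) else rep(1, p$n_sites)
  lambda <- if (p$mirna_loss_convention == "per_molecule") i else rep(1, p$n_sites)
  list(i = i, w = w, lambda = lambda)
}

# ascending-power coefficients of the binding polynomials in x = r/K:
#   phi(x)   = 1 + sum w_i x^i            (total mRNA partition)
#   psi(x)   =     sum i w_i x^i          (bound miRNA count)
#   phi_a(x) = 1 + sum w_i a_i x^i        (mRNA consumption)
#   psi_b(x) =     sum lambda_i w_i b_i x^i  (miRNA consumption in complexes)
.mmi_polys <- function(p) {
  ww <- .mmi_weights(p)
  list(phi   = c(1, ww$w),
       psi   = c(0, ww$i * ww$w),
       phi_a = c(1, ww$w * p$a),
       psi_b = c(0, ww$lambda * ww$w * p$b))
}

.polyval <- function(coef, x) {
  # Horner evaluation, vectorized over x
  y <- rep(coef[length(coef)], length(x))
  for (k in rev(seq_len(length(coef) - 1L))) y <- y * x + coef[k]
  y
}

.polyder <- function(coef) {
  if (length(coef) < 2L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

.polymul <- function(p, q) {
  r <- numeric(length(p) + length(q) - 1L)
  for (k in seq_along(p)) {
    idx <- k:(k + length(q) - 1L)
    r[idx] <- r[idx] + p[k] * q
  }
  r
}

# real nonnegative roots of a polynomial given ascending coefficients
.real_positive_roots <- function(coef, rel_im_tol = 1e-7) {
  nz <- which(abs(coef) > 0)
  if (length(nz) == 0L) return(numeric(0))
  coef <- coef[seq_len(max(nz))]
  if (length(coef) < 2L) return(numeric(0))
  rt <- polyroot(coef)
  re <- Re(rt)[abs(Im(rt)) <= rel_im_tol * pmax(1, Mod(rt))]
  sort(re[re > 0])
}

#' Write and read circuit parameters as a flat config file
#'
#' Serializes an [mmi_parameters] record to a flat key-value YAML file
#' (vectors `a`, `b` as sequences) and reads it back.
#'
#' @param p An `mmi_parameters` object.
#' @param path File path.
#' @return `write_mmi_config` returns `path` invisibly; `read_mmi_config`
#'   returns an `mmi_parameters` object.
#' @export
write_mmi_config <- function(p, path) {
  stopifnot(inherits(p, "mmi_parameters"))
  yaml::write_yaml(unclass(p), path)
  invisible(path)
}

#' @rdname write_mmi_config
#' @export
read_mmi_config <- function(path) {
  v <- yaml::read_yaml(path)
  mmi_parameters(n_sites = v$n_sites, a = v$a, b = v$b,
                 s_R = v$s_R, s_r = v$s_r, k_R = v$k_R, k_r = v$k_r,
                 K_scaled = v$K_scaled,
                 binding_convention = v$binding_convention,
                 mirna_loss_convention = v$mirna_loss_convention)
}
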