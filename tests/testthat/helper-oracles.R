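# Shared oracles and utilities, independent of the implementation paths they
# check.

expect_rel_equal <- function(actual, expected, tol = 1e-8) {
  expect_true(all(abs(actual - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("relative difference %.3g exceeds %.3g",
                              max(abs(actual - expected) /
                                    pmax(abs(expected), .Machine$double.eps)),
                              tol))
}

# binding-equilibrium oracle: exhaustive bracketing of the miRNA conservation
# residual on a dense grid, followed by bisection; never touches polyroot
oracle_solve_complexes <- function(R_T, r_T, p) {
  K <- p$K_scaled
  i <- seq_len(p$n_sites)
  w <- if (p$binding_convention == "statistical_factors")
    choose(p$n_sites, i) else rep(1, p$n_sites)
  gfun <- function(r) {
    x <- r / K
    phi <- 1 + sum(w * x^i)
    R <- R_T / phi
    r + R * sum(i * w * x^i) - r_T
  }
  if (r_T == 0) return(list(R = R_T, r = 0, C = rep(0, p$n_sites)))
  grid <- seq(0, r_T, length.out = 2000)
  gv <- vapply(grid, gfun, numeric(1))
  k <- which(diff(sign(gv)) != 0)[1]
  r <- uniroot(gfun, grid[c(k, k + 1)], tol = 1e-15)$root
  x <- r / K
  R <- R_T / (1 + sum(w * x^i))
  list(R = R, r = r, C = w * R * x^i)
}

# attractor census of the reduced system by forward integration from a set
# of initial conditions; returns the number of distinct stable attractors
census_attractors <- function(p, s_r, inits, t_end = 300) {
  fin <- apply(inits, 1, function(y0) {
    out <- deSolve::ode(y = y0, times = c(0, t_end / 2, t_end),
                        func = function(t, y, q) list(reduced_rhs(y, p, s_r = s_r)),
                        parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-12)
    st <- out[nrow(out), -1]
    solve_complexes(st[1], st[2], p)$R
  })
  fin <- sort(log10(pmax(fin, 1e-30)))
  sum(diff(fin) > 1) + 1L  # attractors separated by >= 1 decade of free mRNA
}

quick_field <- function(sigma = 0, seed = 1L)
  make_morphogen_field(noise_sigma = sigma, seed = seed)
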