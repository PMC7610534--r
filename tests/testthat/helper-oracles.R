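# Independent oracles, kept deliberately naive: direct formula evaluation
# and brute-force scans, sharing no code with the package internals.

# trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# required areal strain for n engulfed particles (high-precision direct
# evaluation of the isoperimetric bound; mirrors nothing in the package)
oracle_strain <- function(D, d, n, margin = 2, permeable = FALSE) {
  A0 <- pi * D^2
  V0 <- pi * D^3 / 6
  a <- d / 2 + margin
  dA <- 4 * pi * a^2
  dV <- if (permeable) 0 else 4 / 3 * pi * a^3
  area_left <- A0 - n * dA
  if (area_left <= 0) return(Inf)
  (36 * pi)^(1 / 3) * (V0 + n * dV)^(2 / 3) / area_left - 1
}

# brute-force capacity: argmax over a strain table for n <= n_max
oracle_capacity <- function(D, d, eps, margin = 2, permeable = FALSE,
                            n_max = 1000) {
  strains <- vapply(1:n_max, function(n)
    oracle_strain(D, d, n, margin, permeable), numeric(1))
  feasible <- strains <= eps
  if (!any(feasible)) 0L else max(which(feasible))
}

# brute-force sign scan of the contact energy w(a) = -kw + m/a - 2 ks/a^2
# on a fine wrap-radius grid; returns the adhesion critical (wrap) diameter
# in nm: twice the largest radius with w >= 0, or 0 if w < 0 everywhere
oracle_adhesion_dc <- function(kw, m, ks, a_nm = seq(0.1, 500, by = 0.01)) {
  a <- a_nm * 1e-9
  w <- -kw + m / a - 2 * ks / a^2
  if (all(w < 0)) return(0)
  2 * max(a_nm[w >= 0])
}
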