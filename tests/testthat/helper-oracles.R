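# Independent oracles used across the suite. Each re-derives the expected
# quantity by a different route than the implementation under test.

# Exhaustive permutation enumeration of the two-sided Mann-Whitney p value
# (tie-free inputs only): every relabelling of the pooled values, U counted
# by direct pairwise comparison, two-sided tail by symmetry around mn/2.
mw_enumeration_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  n <- length(y)
  u_of <- function(idx) sum(outer(pooled[idx], pooled[-idx], ">"))
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  centre <- m * n / 2
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# Grantham's distance recomputed from the side-chain composition, polarity
# and volume properties: D = rho * sqrt(a*dc^2 + b*dp^2 + g*dv^2), with
# a = 1.833, b = 0.1018, g = 0.000399 and rho = 50.723, rounded to integer.
grantham_formula <- local({
  comp <- c(S = 1.42, R = 0.65, L = 0, P = 0.39, T = 0.71, A = 0, V = 0,
            G = 0.74, I = 0, F = 0, Y = 0.20, C = 2.75, H = 0.58, Q = 0.89,
            N = 1.33, K = 0.33, D = 1.38, E = 0.92, M = 0, W = 0.13)
  pol <- c(S = 9.2, R = 10.5, L = 4.9, P = 8.0, T = 8.6, A = 8.1, V = 5.9,
           G = 9.0, I = 5.2, F = 5.2, Y = 6.2, C = 5.5, H = 10.4, Q = 10.5,
           N = 11.6, K = 11.3, D = 13.0, E = 12.3, M = 5.7, W = 5.4)
  vol <- c(S = 32, R = 124, L = 111, P = 32.5, T = 61, A = 31, V = 84,
           G = 3, I = 111, F = 132, Y = 136, C = 55, H = 96, Q = 85,
           N = 56, K = 119, D = 54, E = 83, M = 105, W = 170)
  function(a, b) {
    round(50.723 * sqrt(
      1.833 * (comp[a] - comp[b])^2 +
        0.1018 * (pol[a] - pol[b])^2 +
        0.000399 * (vol[a] - vol[b])^2
    ))
  }
})

# Numeric three-species competitive binding equilibrium, written
# independently of the package's closed-form IC50 correction: free protein
# solved by bisection from the mass balance, then the displacement
# midpoint located as the competitor total halving the probe complex.
equilibrium_ic50 <- function(p_tot, l_tot, kd_probe, kd_comp) {
  complex_probe <- function(i_tot) {
    f <- function(p_free) {
      l_free <- l_tot / (1 + p_free / kd_probe)
      i_free <- i_tot / (1 + p_free / kd_comp)
      p_free * (1 + l_free / kd_probe + i_free / kd_comp) - p_tot
    }
    p_free <- uniroot(f, c(0, p_tot), tol = 1e-18)$root
    p_free * (l_tot / (1 + p_free / kd_probe)) / kd_probe
  }
  pl0 <- complex_probe(0)
  uniroot(
    function(i) complex_probe(i) - pl0 / 2,
    c(kd_comp * 1e-6, kd_comp * 1e8), tol = kd_comp * 1e-10
  )$root
}
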