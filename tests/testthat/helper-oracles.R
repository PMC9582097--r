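# Independent oracles and small fixture builders shared across tests.

# Literal periodogram double sum: W(u_n, v_k) = dx*dy/(M*n*n) *
# sum_m |sum_i sum_j ROI_m(i,j) exp(-2 pi i (n*i + k*j)/n)|^2,
# evaluated frequency pair by frequency pair without any fast transform.
nps_2d_bruteforce <- function(regions, dx, dy, n) {
  if (is.matrix(regions)) regions <- list(regions)
  acc <- matrix(0, n, n)
  m_total <- 0L
  ii <- 0:(n - 1L)
  for (reg in regions) {
    tiling <- tile_rois(reg, n)
    for (m in seq_len(tiling$m)) {
      r0 <- tiling$origins[m, 1L]; c0 <- tiling$origins[m, 2L]
      roi <- reg[r0 + 1:n, c0 + 1:n]
      for (a in ii) for (b in ii) {
        phase_r <- exp(-2i * pi * a * ii / n)
        phase_c <- exp(-2i * pi * b * ii / n)
        s <- sum(outer(phase_r, phase_c) * roi)
        acc[a + 1L, b + 1L] <- acc[a + 1L, b + 1L] + Mod(s)^2
      }
      m_total <- m_total + 1L
    }
  }
  dx * dy / (m_total * n * n) * acc
}

# A compact synthetic study (few flats, small region) for pipeline/report
# tests where runtime matters more than spectral statistics.
small_study <- function(dir, seed = 7L, ...) {
  gen_dqe_study(dir,
                model = detector_model(seed = seed),
                n_flat = 3L, region_mm = 25,
                flat_shape = c(320L, 320L),
                edge_shape = c(460L, 240L),
                ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}

# flat fields below NPS size warn by design; fine for non-NPS fixtures
gen_flat_small <- function(...) suppressWarnings(gen_flat_field(...))
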