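# Independent closed-form oracles used by the test suite. These never call
# the package's solvers.

# Layered thick-walled cylinder (plane strain), internal pressure P at the
# inner boundary, elastic-foundation traction sigma_rr = -k u at the outer
# boundary. Per-layer displacement u = A r + B / r with interface continuity
# of u and sigma_rr. `layers` is a list of lists with fields t (thickness),
# E (Young's modulus) and nu (Poisson ratio), inner to outer.
lame_layered <- function(r_in, layers, pressure, k) {
  nl <- length(layers)
  radii <- r_in + cumsum(c(0, vapply(layers, `[[`, numeric(1), "t")))
  lam <- vapply(layers, function(l) {
    l$E * l$nu / ((1 + l$nu) * (1 - 2 * l$nu))
  }, numeric(1))
  g <- vapply(layers, function(l) l$E / (2 * (1 + l$nu)), numeric(1))
  # unknowns (A_1, B_1, ..., A_nl, B_nl)
  # sigma_rr = 2 (lam + g) A - 2 g B / r^2 ; u = A r + B / r
  M <- matrix(0, 2 * nl, 2 * nl)
  rhs <- numeric(2 * nl)
  srr <- function(j, r) c(2 * (lam[j] + g[j]), -2 * g[j] / r^2)
  disp <- function(r) c(r, 1 / r)
  row <- 1
  M[row, 1:2] <- srr(1, radii[1]); rhs[row] <- -pressure; row <- row + 1
  for (j in seq_len(nl - 1)) {
    cj <- 2 * j - 1
    M[row, cj:(cj + 1)] <- disp(radii[j + 1])
    M[row, (cj + 2):(cj + 3)] <- -disp(radii[j + 1])
    row <- row + 1
    M[row, cj:(cj + 1)] <- srr(j, radii[j + 1])
    M[row, (cj + 2):(cj + 3)] <- -srr(j + 1, radii[j + 1])
    row <- row + 1
  }
  cn <- 2 * nl - 1
  r_out <- radii[nl + 1]
  M[row, cn:(cn + 1)] <- srr(nl, r_out) + k * disp(r_out)
  ab <- solve(M, rhs)
  A <- ab[seq(1, 2 * nl, by = 2)]
  B <- ab[seq(2, 2 * nl, by = 2)]
  u_at <- function(r) {
    j <- findInterval(r, radii, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1), nl)
    A[j] * r + B[j] / r
  }
  # mean hoop strain of layer 1: (1/t) int (A + B/r^2) dr
  t1 <- layers[[1]]$t
  eps_t_epi <- A[1] + B[1] * (1 / radii[1] - 1 / radii[2]) / t1
  list(A = A, B = B, radii = radii, u_at = u_at,
       u_in = u_at(radii[1]), u_out = u_at(r_out),
       mean_epi_hoop_strain = eps_t_epi)
}

# Materials of the default wall linearized for the Lame comparison.
lame_layers_default <- function(thicknesses) {
  mats <- lapply(ventilam::default_materials(), ventilam::linearize_material)
  list(list(t = thicknesses[1], E = mats$epithelium$E, nu = mats$epithelium$nu),
       list(t = thicknesses[2], E = mats$connective$E, nu = mats$connective$nu),
       list(t = thicknesses[3], E = mats$asm$E, nu = mats$asm$nu))
}

# Analytic 2D Gaussian diffusion-decay reference on lattice coordinates.
gaussian_heat_ref <- function(n, ctr, s0sq, D, K, t) {
  x <- matrix(rep(seq_len(n), n), n)
  y <- t(x)
  r2 <- (x - ctr)^2 + (y - ctr)^2
  ssq <- s0sq + 2 * D * t
  (s0sq / ssq) * exp(-r2 / (2 * ssq)) * exp(-K * t)
}

# Default pipeline strains used by the CA acceptance runs; recomputed from
# scratch by the pipeline itself inside the tests that need provenance.
default_airway_strains <- function() {
  tree <- ventilam::build_airway_tree(max_gn = 7)
  prof <- ventilam::pressure_profile(tree, ventilam::ventilator_waveform())
  ventilam::strain_for_airways(tree, prof, ventilam::default_wall_sections())
}
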