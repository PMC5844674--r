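test_that("Neo-Hookean energy density follows its defining formula", {
  m <- neo_hookean(2, 1)
  expect_equal(neo_hookean_energy(3, 1, m), 0)        # undeformed
  expect_equal(neo_hookean_energy(4, 1, m), 1)        # (2/2)(4-3) + 0
  expect_error(neo_hookean_energy(3, 0, m), "J")
  expect_error(neo_hookean_energy(3, -1, m), "J")
  # default epithelial stiffness
  expect_equal(default_materials()$epithelium$mu, 5e6)
})

test_that("material constructors validate their parameter ranges", {
  expect_error(neo_hookean(-1), "mu")
  expect_error(linear_elastic(1e6, 0.5))
  expect_error(linear_elastic(-2, 0.3))
  # linearization recovers consistent small-strain moduli
  m <- neo_hookean(5e6)
  lin <- linearize_material(m)
  expect_equal(lin$E / (2 * (1 + lin$nu)), 5e6, tolerance = 1e-12)
  expect_equal(lin$nu, 0.49, tolerance = 1e-12)
})

test_that("stiffening scales mu by (1 + alpha f) and reduces strain", {
  m <- neo_hookean(5e6)
  expect_equal(stiffen(m, 0, 1)$mu, m$mu)
  expect_equal(stiffen(m, 1, 1)$mu, 2 * m$mu)
  expect_equal(stiffen(m, 0.5, 2)$mu, 2 * m$mu)
  expect_equal(stiffen(m, 0.3)$d, m$d)
  expect_error(stiffen(m, 1.5), "fibrosis_fraction")
  expect_error(stiffen(m, -0.1), "fibrosis_fraction")
  # a stiffened wall strains strictly less under the same pressure
  morph <- default_morphology()[5, ]      # generation 4
  mats <- default_materials()
  sec <- wall_section_for_generation(morph, mats)
  base <- solve_wall(sec, 8)$epithelial_hoop_strain
  mats$epithelium <- stiffen(mats$epithelium, 0.5, 2)
  mats$connective <- stiffen(mats$connective, 0.5, 2)
  stiff <- solve_wall(wall_section_for_generation(morph, mats),
                      8)$epithelial_hoop_strain
  expect_lt(stiff, base)
})

test_that("unloaded wall returns the exact zero solution", {
  sec <- wall_section(0.00225, c(1.1e-4, 2.2e-4, 3.4e-4))
  sol <- solve_wall(sec, 0)
  expect_identical(sol$u, numeric(length(sol$r)))
  expect_identical(sol$epithelial_hoop_strain, 0)
  expect_true(all(sol$eps_r == 0) && all(sol$eps_t == 0))
})

test_that("linearized solver matches the layered Lame closed form", {
  th <- c(1.125e-4, 2.25e-4, 3.375e-4)
  r_in <- 0.00225
  ora <- lame_layered(r_in, lame_layers_default(th), 8, 600)
  mats_lin <- lapply(default_materials(), linearize_material)
  sol <- solve_wall(wall_section(r_in, th, mats_lin, 600), 8)
  expect_equal(sol$u[1], ora$u_in, tolerance = 1e-2)
  expect_equal(sol$epithelial_hoop_strain, ora$mean_epi_hoop_strain,
               tolerance = 1e-2)
  # the Neo-Hookean path agrees at these micro-strains too
  sol_nh <- solve_wall(wall_section(r_in, th, default_materials(), 600), 8)
  expect_equal(sol_nh$u[1], ora$u_in, tolerance = 1e-3)
})

test_that("strain responds monotonically to pressure, tethering and mu", {
  sec <- wall_section(0.00225, c(1.1e-4, 2.2e-4, 3.4e-4))
  strains <- vapply(c(2, 4, 8, 16), function(p) {
    solve_wall(sec, p)$epithelial_hoop_strain
  }, numeric(1))
  expect_true(all(diff(strains) > 0))
  # stiffer foundation: outer displacement strictly decreases
  u_out <- vapply(c(0, 600, 6e4, 6e6), function(k) {
    sec_k <- wall_section(0.00225, c(1.1e-4, 2.2e-4, 3.4e-4),
                          foundation_k = k)
    sol <- solve_wall(sec_k, 8)
    sol$u[length(sol$u)]
  }, numeric(1))
  expect_true(all(diff(u_out) < 0))
  # stiffer layers: strain decreases
  mats2 <- default_materials()
  mats2$epithelium <- neo_hookean(1e7)
  s1 <- solve_wall(sec, 8)$epithelial_hoop_strain
  s2 <- solve_wall(wall_section(0.00225, c(1.1e-4, 2.2e-4, 3.4e-4), mats2),
                   8)$epithelial_hoop_strain
  expect_lt(s2, s1)
})

test_that("internal energy balances external boundary work on a load ramp", {
  # soft thick wall at appreciable strain to engage the nonlinearity
  mats <- list(epithelium = neo_hookean(3e5), connective = neo_hookean(1e5),
               asm = linear_elastic(5e5, 0.4))
  sec <- wall_section(0.001, c(5e-4, 5e-4, 5e-4), mats, 600)
  n_ramp <- 40
  p_max <- 2e4
  ps <- seq(0, p_max, length.out = n_ramp + 1)
  u_in <- vapply(ps, function(p) solve_wall(sec, p, n_nodes = 120)$u[1],
                 numeric(1))
  # external work of the (dead) pressure load along the equilibrium path
  w_ext <- sum((ps[-1] + ps[-length(ps)]) / 2 * diff(u_in)) * 2 * pi * 0.001
  sol <- solve_wall(sec, p_max, n_nodes = 120)
  w_int <- wall_internal_energy(sec, sol)
  expect_equal(w_int, w_ext, tolerance = 1e-2)
})

test_that("per-airway strains follow the pressure ordering", {
  tree <- build_airway_tree(max_gn = 7)
  prof <- pressure_profile(tree, ventilator_waveform())
  secs <- default_wall_sections()
  st <- strain_for_airways(tree, prof, secs[c("G4", "G6", "G7")])
  expect_gt(st[["G4"]], st[["G6"]])
  expect_gt(st[["G6"]], st[["G7"]])
  expect_true(all(st > 0))
  # identical sections under ordered pressures give ordered strains
  sec4 <- secs$G4
  s_by_p <- vapply(c(prof$peak_pressure[["G4"]], prof$peak_pressure[["G6"]]),
                   function(p) solve_wall(sec4, p)$epithelial_hoop_strain,
                   numeric(1))
  expect_gt(s_by_p[1], s_by_p[2])
  # single airway equals solve_wall directly
  direct <- solve_wall(secs$G6, prof$peak_pressure[["G6"]])
  expect_equal(st[["G6"]], direct$epithelial_hoop_strain)
  # missing generation errors
  expect_error(strain_for_airways(tree, prof, list(G9 = secs$G7)), "G9")
})
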