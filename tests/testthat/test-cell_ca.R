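test_that("diffusion-decay obeys the exact geometric mass decay", {
  # null field stays null
  f0 <- cytokine_field(20, 20, 0.1, 0.01)
  expect_true(all(diffuse_decay(f0)$C == 0))
  # uniform field with K = 0 is a fixed point (Laplacian of constant = 0)
  fu <- cytokine_field(15, 12, 0.2, 0, init = 3.5)
  expect_equal(diffuse_decay(fu)$C, matrix(3.5, 15, 12))
  # uniform field with K > 0 decays exactly as (1 - K dt)^n
  f <- cytokine_field(10, 10, 0.1, 0.05, init = 2)
  for (i in 1:7) f <- diffuse_decay(f, 1)
  expect_equal(f$C, matrix(2 * (1 - 0.05)^7, 10, 10), tolerance = 1e-12)
  # total mass decays geometrically for an arbitrary field (zero flux)
  set.seed(7)
  g <- cytokine_field(13, 9, 0.2, 0.03,
                      init = matrix(runif(13 * 9), 13, 9))
  tot0 <- sum(g$C)
  g <- diffuse_decay(g, 1)
  expect_equal(sum(g$C), (1 - 0.03) * tot0, tolerance = 1e-12)
  # stability guard names the offending number
  expect_error(diffuse_decay(cytokine_field(5, 5, 0.3, 0), dt = 1), "0.300")
})

test_that("activation gate is thresholded, saturating and monotone", {
  p <- ca_params()
  expect_equal(activation_gate(0, p), 0)
  expect_equal(activation_gate(p$eps_act, p), 0)
  expect_equal(activation_gate(10 * p$eps_sat, p), 1)
  s <- seq(0, 2 * p$eps_sat, length.out = 400)
  g <- activation_gate(s, p)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))
  expect_error(activation_gate(-0.1, p), "strain")
})

test_that("release probabilities follow the saturating interaction forms", {
  p <- ca_params()
  # macrophage: suppressed to 0 by saturating TGF; half at TGF = c_half
  expect_lt(release_probability("macrophage", 0, 1e9, p, gate = 1), 1e-6)
  expect_equal(release_probability("macrophage", 0, p$c_half_supp, p,
                                   gate = 1), p$p_tnf_max / 2)
  expect_equal(release_probability("macrophage", 0, 0, p, gate = 0), 0)
  # fibroblast: no TNF, no release; saturates to p_tgf_max
  expect_equal(release_probability("fibroblast", 0, 0, p), 0)
  expect_equal(release_probability("fibroblast", p$c_half_drive, 0, p),
               p$p_tgf_max / 2)
  expect_lt(release_probability("fibroblast", 1e9, 0, p), p$p_tgf_max + 1e-12)
})

test_that("chemotaxis sampling matches the exponential-weight law", {
  p <- ca_params(width = 21, height = 21)
  n_trial <- 1e5
  # uniform attractant: empirical move frequencies uniform over 5 candidates
  C <- matrix(1, 21, 21)
  set.seed(11)
  mv <- ventilam:::.move_agents(rep(11L, n_trial), rep(11L, n_trial), C,
                                beta = 1, 21, 21)
  key <- paste(mv$x, mv$y)
  counts <- table(key)
  expect_equal(length(counts), 5L)
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.01)
  # beta = 0 ignores any field
  set.seed(12)
  Cg <- matrix(rep(seq_len(21), each = 21) * 0.5, 21, 21)  # gradient in y
  mv0 <- ventilam:::.move_agents(rep(11L, n_trial), rep(11L, n_trial), Cg,
                                 beta = 0, 21, 21)
  chi0 <- stats::chisq.test(as.vector(table(paste(mv0$x, mv0$y))))
  expect_gt(chi0$p.value, 0.01)
  # linear gradient, beta > 0: frequencies match normalized exp weights
  beta <- 0.8
  set.seed(13)
  mvg <- ventilam:::.move_agents(rep(11L, n_trial), rep(11L, n_trial), Cg,
                                 beta = beta, 21, 21)
  # candidates: stay, x-1, x+1, y-1, y+1 at (11, 11)
  w <- exp(beta * c(Cg[11, 11], Cg[10, 11], Cg[12, 11], Cg[11, 10],
                    Cg[11, 12]))
  prob <- w / sum(w)
  obs <- c(sum(mvg$x == 11 & mvg$y == 11), sum(mvg$x == 10),
           sum(mvg$x == 12), sum(mvg$y == 10), sum(mvg$y == 12))
  for (i in 1:5) {
    sigma <- sqrt(n_trial * prob[i] * (1 - prob[i]))
    expect_lt(abs(obs[i] - n_trial * prob[i]), 3 * sigma + 1)
  }
  # boundary agent never leaves the lattice
  set.seed(14)
  mvb <- ventilam:::.move_agents(rep(1L, 1000L), rep(1L, 1000L), C, 1, 21, 21)
  expect_true(all(mvb$x >= 1 & mvb$y >= 1))
})

test_that("epithelial transitions obey their binomial laws", {
  p <- ca_params()
  # alive with no TNF never dies; dead with no TGF never heals
  set.seed(2)
  cell <- list(state = "alive", dead_steps = 0L)
  for (i in 1:50) cell <- epithelial_update(cell, 0, 0, p)
  expect_equal(cell$state, "alive")
  cell <- list(state = "dead", dead_steps = 0L)
  for (i in 1:50) cell <- epithelial_update(cell, 0, 0, p)
  expect_equal(cell$state, "dead")
  # fibrosis is absorbing
  cell <- list(state = "fibrosis", dead_steps = 0L)
  for (i in 1:20) cell <- epithelial_update(cell, 5, 5, p)
  expect_equal(cell$state, "fibrosis")
  # alive at TNF = c_half: damaged fraction = p_damage_max / 2 within 3 sigma
  n_trial <- 1e5
  set.seed(3)
  dead <- sum(vapply(seq_len(n_trial), function(i) {
    epithelial_update(list(state = "alive", dead_steps = 0L),
                      p$c_half_damage, 0, p)$state == "dead"
  }, logical(1)))
  pr <- p$p_damage_max / 2
  expect_lt(abs(dead - n_trial * pr), 3 * sqrt(n_trial * pr * (1 - pr)))
})

test_that("a CA step conserves the epithelial population", {
  p <- ca_params(width = 30, height = 30, n_macrophages = 10,
                 n_fibroblasts = 10)
  set.seed(5)
  st <- init_ca_state(p, p$eps_sat * 2)
  st$tnf[15, 15] <- 50   # seed an injury signal
  for (i in 1:30) {
    st <- ca_step(st, p)
    counts <- table(factor(st$state, levels = 1:3))
    expect_equal(sum(counts), 900L)
  }
  expect_true(all(st$tnf >= 0) && all(st$tgf >= 0))
})

test_that("zero strain with zero cytokines is absorbing quiescence", {
  p <- ca_params(width = 40, height = 40, n_macrophages = 20,
                 n_fibroblasts = 20)
  tr <- run_inflammation(0, p, 400, seed = 9)
  expect_true(all(tr$dead == 0))
  expect_true(all(tr$fibrosis == 0))
  expect_true(all(tr$tnf_total == 0) && all(tr$tgf_total == 0))
  # agents still wander: state unchanged except positions
  fin <- attr(tr, "final_state")
  expect_true(all(fin$state == 1L))
})

test_that("equal seeds give bit-identical runs, different seeds differ", {
  p <- ca_params(width = 40, height = 40)
  s <- default_airway_strains()[["G4"]]
  t1 <- run_inflammation(s, p, 300, seed = 21)
  t2 <- run_inflammation(s, p, 300, seed = 21)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- run_inflammation(s, p, 300, seed = 22)
  expect_false(identical(t1$dead, t3$dead))
})

test_that("mean peak response is non-decreasing in uniform strain", {
  # dose-response sweep at reduced scale (smaller lattice, shorter runs)
  p <- ca_params(width = 40, height = 40, n_macrophages = 15,
                 n_fibroblasts = 15)
  levels <- c(0, p$eps_act * 1.4, p$eps_sat * 1.2)
  mean_peak <- vapply(seq_along(levels), function(i) {
    peaks <- vapply(1:20, function(r) {
      max(run_inflammation(levels[i], p, 600,
                           seed = 1000 * i + r)$dead)
    }, numeric(1))
    mean(peaks)
  }, numeric(1))
  expect_true(all(diff(mean_peak) >= 0))
  expect_equal(mean_peak[1], 0)
  expect_gt(mean_peak[3], mean_peak[2])
})

test_that("ensembles quantify replicate variability", {
  p <- ca_params(width = 40, height = 40, n_macrophages = 15,
                 n_fibroblasts = 15)
  s <- p$eps_sat * 1.2
  ens <- run_ensemble(s, p, n_steps = 500, n_reps = 8, seed = 3)
  expect_equal(dim(ens$dead), c(501L, 8L))
  expect_equal(nrow(ens$peaks), 8L)
  expect_gt(mean(ens$peaks$peak), 0)
  # the ensemble mean is smoother than any single replicate
  tv <- function(x) sum(abs(diff(x)))
  expect_true(all(apply(ens$dead, 2, tv) > tv(ens$mean_trace$dead_mean)))
})
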