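#' Cellular-scale model parameters
#'
#' Parameter set for the stochastic cellular-automata model of the
#' stretch-activated innate immune response. Epithelial cells occupy every
#' site of a bounded 2-D lattice (states alive / dead / fibrosis); wandering
#' macrophages and fibroblasts perform chemotaxis-biased random walks; TNF
#' (pro-inflammatory) and TGF (pro-healing) concentration fields obey an
#' explicit diffusion-decay update.
#'
#' The defaults are calibrated against the default three-airway case study:
#' the activation threshold \code{eps_act} lies above the strain the deepest
#' selected airway (G7) experiences and below the G6 strain, and
#' \code{eps_sat} lies below the G4-1 strain, so the G7 tissue is quiescent
#' while G4-1 is fully activated. See the package vignette for the
#' calibration rationale.
#'
#' @param width,height Lattice dimensions in sites (>= 3).
#' @param n_macrophages,n_fibroblasts Numbers of wandering agents.
#' @param diff_tnf,diff_tgf Cytokine diffusivities (sites^2/step); the
#'   explicit scheme requires \code{D dt/dx^2 <= 0.25}.
#' @param decay_tnf,decay_tgf Cytokine disintegration rates (1/step).
#' @param p_tnf_max,p_tgf_max Maximum per-step cytokine release
#'   probabilities.
#' @param p_damage_max,p_heal_max Maximum per-step epithelial transition
#'   probabilities (alive->dead driven by TNF; dead->alive driven by TGF).
#' @param c_half_damage,c_half_heal,c_half_supp,c_half_drive Half-saturation
#'   concentrations of the four Michaelis-Menten interactions (TNF->damage,
#'   TGF->heal, TGF suppression of macrophage TNF release, TNF drive of
#'   fibroblast TGF release).
#' @param beta Chemotaxis sensitivity (both agent kinds ascend TNF).
#' @param eps_act Strain activation threshold: below it the macrophage
#'   strain gate is 0.
#' @param eps_sat Strain at which the gate saturates at 1 (smoothstep ramp
#'   between \code{eps_act} and \code{eps_sat}).
#' @param gate_floor Minimum gate value just above the activation threshold:
#'   cell activation is all-or-nothing at \code{eps_act} (the gate jumps from
#'   0 to \code{gate_floor}), then ramps smoothly to 1 at \code{eps_sat}.
#' @param relief_gain Gain of the fibrosis strain-relief closure: the strain
#'   felt by immune cells is the input strain scaled by
#'   \code{max(0, 1 - relief_gain * fibrosis_fraction)} (stiff scar carries
#'   the load), and fibrotic sites shield their occupants entirely. This is
#'   the cell-scale reflection of inflammation-driven tissue stiffening and
#'   is what lets a high-strain response resolve completely.
#' @param tau_fib Steps a cell must be continuously dead (under sufficient
#'   TGF) before it may turn fibrotic.
#' @param p_fib Per-step fibrosis probability once eligible.
#' @param tgf_fib_threshold Minimum local TGF for fibrosis entry.
#' @param release_amount Cytokine bolus deposited per release event.
#' @param dt,dx Step and site size (kept at 1; the CA clock is abstract
#'   "simulation time").
#' @return Object of class \code{ca_params}.
#' @export
ca_params <- function(width = 100, height = 100,
                      n_macrophages = 50, n_fibroblasts = 50,
                      diff_tnf = 0.1, diff_tgf = 0.1,
                      decay_tnf = 0.01, decay_tgf = 5e-4,
                      p_tnf_max = 0.3, p_tgf_max = 0.5,
                      p_damage_max = 0.025, p_heal_max = 0.02,
                      c_half_damage = 10, c_half_heal = 0.01,
                      c_half_supp = 5, c_half_drive = 0.5,
                      beta = 0.5, relief_gain = 3,
                      eps_act = 3.35e-7, eps_sat = 6.5e-7, gate_floor = 0.06,
                      tau_fib = 50, p_fib = 0.1,
                      tgf_fib_threshold = 0.01,
                      release_amount = 1, dt = 1, dx = 1) {
  p <- list(width = as.integer(width), height = as.integer(height),
            n_macrophages = as.integer(n_macrophages),
            n_fibroblasts = as.integer(n_fibroblasts),
            diff_tnf = diff_tnf, diff_tgf = diff_tgf,
            decay_tnf = decay_tnf, decay_tgf = decay_tgf,
            p_tnf_max = p_tnf_max, p_tgf_max = p_tgf_max,
            p_damage_max = p_damage_max, p_heal_max = p_heal_max,
            c_half_damage = c_half_damage, c_half_heal = c_half_heal,
            c_half_supp = c_half_supp, c_half_drive = c_half_drive,
            beta = beta, relief_gain = relief_gain,
            eps_act = eps_act, eps_sat = eps_sat, gate_floor = gate_floor,
            tau_fib = as.integer(tau_fib), p_fib = p_fib,
            tgf_fib_threshold = tgf_fib_threshold,
            release_amount = release_amount, dt = dt, dx = dx)
  validate_ca_params(p)
  structure(p, class = "ca_params")
}

validate_ca_params <- function(p) {
  if (p$width < 3 || p$height < 3) stop("lattice must be at least 3 x 3")
  probs <- c(p$p_tnf_max, p$p_tgf_max, p$p_damage_max, p$p_heal_max, p$p_fib)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  ch <- c(p$c_half_damage, p$c_half_heal, p$c_half_supp, p$c_half_drive)
  if (any(ch <= 0)) stop("half-saturation concentrations must be > 0")
  for (D in c(p$diff_tnf, p$diff_tgf)) {
    s <- D * p$dt / p$dx^2
    if (s > 0.25) {
      stop(sprintf("explicit diffusion unstable: D*dt/dx^2 = %.3f > 0.25", s))
    }
  }
  if (p$decay_tnf * p$dt >= 1 || p$decay_tgf * p$dt >= 1) {
    stop("decay per step K*dt must be < 1")
  }
  if (p$eps_sat <= p$eps_act) stop("eps_sat must exceed eps_act")
  if (p$eps_act < 0) stop("eps_act must be >= 0")
  if (p$relief_gain < 0) stop("relief_gain must be >= 0")
  if (p$gate_floor < 0 || p$gate_floor > 1) stop("gate_floor must lie in [0, 1]")
  invisible(p)
}

#' Cytokine concentration field
#'
#' @param width,height Lattice dimensions.
#' @param D Diffusivity (sites^2/step).
#' @param K Decay rate (1/step).
#' @param init Initial concentration: scalar or width x height matrix
#'   (rows = x, columns = y).
#' @return Object of class \code{cytokine_field}.
#' @export
cytokine_field <- function(width, height, D = 0.1, K = 0.01, init = 0) {
  C <- if (is.matrix(init)) init else matrix(init, width, height)
  stopifnot(nrow(C) == width, ncol(C) == height, all(C >= 0), D >= 0, K >= 0)
  structure(list(C = C, D = D, K = K, dx = 1), class = "cytokine_field")
}

# 5-point Laplacian with zero-flux (mirror) boundaries; conserves total mass.
.lap5 <- function(C) {
  n <- nrow(C); m <- ncol(C)
  C[c(1L, seq_len(n - 1L)), ] + C[c(seq_len(n - 1L) + 1L, n), ] +
    C[, c(1L, seq_len(m - 1L))] + C[, c(seq_len(m - 1L) + 1L, m)] - 4 * C
}

.diffuse_mat <- function(C, D, K, dt) {
  Cn <- C + dt * (D * .lap5(C) - K * C)
  if (any(Cn < 0)) Cn[Cn < 0] <- 0   # round-off guard; scheme is positive
  Cn
}

#' One explicit diffusion-decay step
#'
#' Forward-Euler update of dC/dt = D lap(C) - K C with the 5-point Laplacian
#' and zero-flux boundaries. The scheme conserves total mass exactly up to
#' the decay factor: total(t+dt) = (1 - K dt) total(t).
#'
#' @param field A \code{\link{cytokine_field}}.
#' @param dt Time step (default 1).
#' @return The updated field.
#' @export
diffuse_decay <- function(field, dt = 1) {
  stopifnot(inherits(field, "cytokine_field"))
  s <- field$D * dt / field$dx^2
  if (s > 0.25) {
    stop(sprintf("explicit diffusion unstable: D*dt/dx^2 = %.3f > 0.25", s))
  }
  field$C <- .diffuse_mat(field$C, field$D / field$dx^2, field$K, dt)
  field
}

#' Strain activation gate for immune cells
#'
#' Mechanical activation of the innate immune response: exactly 0 at or
#' below the strain threshold \code{eps_act}; immediately above it the gate
#' takes the all-or-nothing activation floor \code{gate_floor} and ramps
#' smoothly (smoothstep) up to 1 at \code{eps_sat}. Monotone non-decreasing
#' in strain throughout.
#'
#' @param strain Non-negative strain value(s).
#' @param p A \code{\link{ca_params}}.
#' @return Gate factor(s) in [0, 1].
#' @export
activation_gate <- function(strain, p) {
  if (any(strain < 0)) stop("strain must be >= 0")
  s <- (strain - p$eps_act) / (p$eps_sat - p$eps_act)
  s <- pmin(pmax(s, 0), 1)
  ramp <- p$gate_floor + (1 - p$gate_floor) * s * s * (3 - 2 * s)
  ifelse(strain > p$eps_act, ramp, 0)
}

#' Cytokine release probability of a wandering cell
#'
#' Macrophages release TNF with probability
#' \code{p_tnf_max * gate * c_half_supp / (c_half_supp + TGF)} -- stretch
#' activated and suppressed by local TGF. Fibroblasts release TGF with
#' probability \code{p_tgf_max * TNF / (c_half_drive + TNF)} -- driven by
#' local TNF.
#'
#' @param kind \code{"macrophage"} or \code{"fibroblast"}.
#' @param local_tnf,local_tgf Local concentrations (>= 0).
#' @param p A \code{\link{ca_params}}.
#' @param gate Strain activation factor in [0, 1] (macrophages only); see
#'   \code{\link{activation_gate}}.
#' @return Release probability in [0, 1].
#' @export
release_probability <- function(kind, local_tnf, local_tgf, p, gate = 1) {
  stopifnot(all(local_tnf >= 0), all(local_tgf >= 0))
  switch(match.arg(kind, c("macrophage", "fibroblast")),
    macrophage = p$p_tnf_max * gate *
      p$c_half_supp / (p$c_half_supp + local_tgf),
    fibroblast = p$p_tgf_max * local_tnf / (p$c_half_drive + local_tnf))
}

# Move a vector of agents one chemotaxis-biased step. Candidates are the
# current site plus its 4-neighbours; weights exp(beta * C), off-lattice
# candidates excluded. Returns new (x, y).
.move_agents <- function(x, y, C, beta, width, height) {
  k <- length(x)
  if (k == 0L) return(list(x = x, y = y))
  cx <- cbind(x, x - 1L, x + 1L, x, x)
  cy <- cbind(y, y, y, y - 1L, y + 1L)
  valid <- cx >= 1L & cx <= width & cy >= 1L & cy <= height
  lx <- pmin.int(pmax.int(cx, 1L), width)
  ly <- pmin.int(pmax.int(cy, 1L), height)
  e <- beta * C[cbind(as.vector(lx), as.vector(ly))]
  dim(e) <- c(k, 5L)
  e <- e - pmax(pmax(e[, 1], e[, 2]), pmax(pmax(e[, 3], e[, 4]), e[, 5]))
  w <- exp(e)
  w[!valid] <- 0
  c2 <- w[, 1] + w[, 2]
  c3 <- c2 + w[, 3]
  c4 <- c3 + w[, 4]
  c5 <- c4 + w[, 5]
  u <- stats::runif(k) * c5
  choice <- 1L + (u > w[, 1]) + (u > c2) + (u > c3) + (u > c4)
  sel <- cbind(seq_len(k), choice)
  list(x = cx[sel], y = cy[sel])
}

#' One chemotaxis step for a single wandering agent
#'
#' Samples the agent's next position among \{stay, 4 neighbours\} with
#' weights proportional to exp(beta * C) at each admissible candidate site.
#'
#' @param agent List with integer fields \code{x}, \code{y} (and optionally
#'   \code{kind}).
#' @param attractant A \code{\link{cytokine_field}}.
#' @param beta Chemotaxis sensitivity; 0 gives an unbiased walk.
#' @return The agent with updated position.
#' @export
chemotaxis_step <- function(agent, attractant, beta = 1) {
  stopifnot(inherits(attractant, "cytokine_field"))
  C <- attractant$C
  stopifnot(agent$x >= 1, agent$x <= nrow(C), agent$y >= 1, agent$y <= ncol(C))
  mv <- .move_agents(as.integer(agent$x), as.integer(agent$y), C, beta,
                     nrow(C), ncol(C))
  agent$x <- mv$x
  agent$y <- mv$y
  agent
}

#' One stochastic update of a single epithelial cell
#'
#' alive -> dead with probability \code{p_damage_max TNF/(c_half + TNF)};
#' dead -> alive with probability \code{p_heal_max TGF/(c_half + TGF)};
#' dead -> fibrosis with probability \code{p_fib} once continuously dead for
#' \code{tau_fib} steps under TGF above \code{tgf_fib_threshold}. Fibrosis is
#' absorbing.
#'
#' @param cell List with \code{state} (\code{"alive"}, \code{"dead"} or
#'   \code{"fibrosis"}) and \code{dead_steps} (steps continuously dead).
#' @param local_tnf,local_tgf Local concentrations.
#' @param p A \code{\link{ca_params}}.
#' @return The updated cell.
#' @export
epithelial_update <- function(cell, local_tnf, local_tgf, p) {
  stopifnot(cell$state %in% c("alive", "dead", "fibrosis"))
  if (cell$state == "alive") {
    pd <- p$p_damage_max * local_tnf / (p$c_half_damage + local_tnf)
    if (stats::runif(1) < pd) {
      cell$state <- "dead"
      cell$dead_steps <- 0L
    }
  } else if (cell$state == "dead") {
    eligible <- cell$dead_steps >= p$tau_fib &&
      local_tgf > p$tgf_fib_threshold
    if (eligible && stats::runif(1) < p$p_fib) {
      cell$state <- "fibrosis"
    } else {
      ph <- p$p_heal_max * local_tgf / (p$c_half_heal + local_tgf)
      if (stats::runif(1) < ph) {
        cell$state <- "alive"
        cell$dead_steps <- 0L
      } else {
        cell$dead_steps <- cell$dead_steps + 1L
      }
    }
  }
  cell
}

#' Initialise the cellular-automata state
#'
#' All epithelial cells start alive, cytokine fields at zero, and wandering
#' agents at uniformly random lattice sites (drawn from the current RNG
#' stream).
#'
#' @param p A \code{\link{ca_params}}.
#' @param strain Per-site strain: scalar (uniform field) or width x height
#'   matrix; must be >= 0.
#' @return Object of class \code{ca_state}: matrices \code{state} (1 alive,
#'   2 dead, 3 fibrosis), \code{dead_clock}, \code{tnf}, \code{tgf},
#'   \code{strain}, agent coordinate vectors \code{mx, my, fx, fy}, and the
#'   step counter.
#' @export
init_ca_state <- function(p, strain) {
  stopifnot(inherits(p, "ca_params"))
  S <- if (is.matrix(strain)) strain else matrix(strain, p$width, p$height)
  if (nrow(S) != p$width || ncol(S) != p$height) {
    stop("strain field must match the lattice dimensions")
  }
  if (any(S < 0)) stop("strain must be >= 0")
  n <- p$width * p$height
  structure(list(
    state = matrix(1L, p$width, p$height),
    dead_clock = matrix(0L, p$width, p$height),
    tnf = matrix(0, p$width, p$height),
    tgf = matrix(0, p$width, p$height),
    strain = S,
    mx = sample.int(p$width, p$n_macrophages, replace = TRUE),
    my = sample.int(p$height, p$n_macrophages, replace = TRUE),
    fx = sample.int(p$width, p$n_fibroblasts, replace = TRUE),
    fy = sample.int(p$height, p$n_fibroblasts, replace = TRUE),
    step = 0L
  ), class = "ca_state")
}

# Core synchronous sweep, operating on unpacked state components inside an
# environment for speed. Sub-step order is fixed for reproducibility:
# (1) agent movement, (2) cytokine release, (3) diffusion-decay,
# (4) epithelial transitions.
.ca_step_env <- function(e, p) {
  n_sites <- p$width * p$height
  # fibrosis-relief closure: scar tissue carries load, so the strain felt by
  # resident immune cells is the input strain scaled down by the global
  # fibrosis fraction, and fibrotic sites shield their occupants entirely.
  relief <- max(0, 1 - p$relief_gain * e$n_fib / n_sites)
  # (1) movement: both kinds ascend the TNF (injury) field
  mv <- .move_agents(e$mx, e$my, e$tnf, p$beta, p$width, p$height)
  e$mx <- mv$x; e$my <- mv$y
  mv <- .move_agents(e$fx, e$fy, e$tnf, p$beta, p$width, p$height)
  e$fx <- mv$x; e$fy <- mv$y
  # (2) release
  midx <- (e$my - 1L) * p$width + e$mx
  gate <- activation_gate(e$strain[midx] * relief, p)
  gate[e$state[midx] == 3L] <- 0
  if (any(gate > 0)) {
    prel <- p$p_tnf_max * gate * p$c_half_supp / (p$c_half_supp + e$tgf[midx])
    rel <- stats::runif(length(prel)) < prel
    if (any(rel)) {
      e$tnf <- e$tnf +
        p$release_amount * tabulate(midx[rel], nbins = n_sites)
      e$tnf_active <- TRUE
    }
  }
  if (e$tnf_active) {
    fidx <- (e$fy - 1L) * p$width + e$fx
    prel <- p$p_tgf_max * e$tnf[fidx] / (p$c_half_drive + e$tnf[fidx])
    rel <- stats::runif(length(prel)) < prel
    if (any(rel)) {
      e$tgf <- e$tgf +
        p$release_amount * tabulate(fidx[rel], nbins = n_sites)
      e$tgf_active <- TRUE
    }
  }
  # (3) diffusion-decay (skipped while a field is identically zero)
  if (e$tnf_active) e$tnf <- .diffuse_mat(e$tnf, p$diff_tnf, p$decay_tnf, p$dt)
  if (e$tgf_active) e$tgf <- .diffuse_mat(e$tgf, p$diff_tgf, p$decay_tgf, p$dt)
  # (4) synchronous epithelial transitions
  if (e$tnf_active || e$n_dead > 0L) {
    state <- e$state
    alive <- state == 1L
    dead <- state == 2L
    dam <- alive & (stats::runif(n_sites) <
                      p$p_damage_max * e$tnf / (p$c_half_damage + e$tnf))
    fib <- dead & e$dead_clock >= p$tau_fib & e$tgf > p$tgf_fib_threshold &
      (stats::runif(n_sites) < p$p_fib)
    heal <- dead & !fib & (stats::runif(n_sites) <
                             p$p_heal_max * e$tgf / (p$c_half_heal + e$tgf))
    state[dam] <- 2L
    state[fib] <- 3L
    state[heal] <- 1L
    e$dead_clock <- (e$dead_clock + 1L) * (state == 2L)
    e$dead_clock[dam] <- 0L
    e$state <- state
    e$n_dead <- sum(state == 2L)
    e$n_fib <- e$n_fib + sum(fib)
  }
  e$step <- e$step + 1L
  invisible(e)
}

.state_to_env <- function(state) {
  e <- new.env(parent = emptyenv())
  for (nm in names(state)) assign(nm, state[[nm]], envir = e)
  e$tnf_active <- any(state$tnf > 0)
  e$tgf_active <- any(state$tgf > 0)
  e$n_dead <- sum(state$state == 2L)
  e$n_fib <- sum(state$state == 3L)
  e
}

.env_to_state <- function(e) {
  structure(list(state = e$state, dead_clock = e$dead_clock, tnf = e$tnf,
                 tgf = e$tgf, strain = e$strain, mx = e$mx, my = e$my,
                 fx = e$fx, fy = e$fy, step = e$step), class = "ca_state")
}

#' One synchronous cellular-automata step
#'
#' Fixed sub-step order: agent movement (chemotaxis up the TNF field), then
#' cytokine release (unit bolus at the agent's site), then diffusion-decay of
#' both fields, then the synchronous epithelial transition sweep. The
#' epithelial population (alive + dead + fibrosis) is conserved.
#'
#' @param state A \code{\link{init_ca_state}} result.
#' @param p A \code{\link{ca_params}}.
#' @return The updated \code{ca_state}.
#' @export
ca_step <- function(state, p) {
  stopifnot(inherits(state, "ca_state"), inherits(p, "ca_params"))
  e <- .state_to_env(state)
  .ca_step_env(e, p)
  .env_to_state(e)
}

#' Run an inflammation time course
#'
#' Iterates the cellular automata from an all-alive tissue and records the
#' per-step epithelial state counts and cytokine totals. The count of dead
#' epithelial cells is the model's inflammation-severity readout.
#'
#' @param strain Per-site strain (scalar or matrix), the tissue-stage output.
#' @param p A \code{\link{ca_params}}.
#' @param n_steps Number of CA steps (>= 1).
#' @param seed Optional integer seed; when given the run is reproducible
#'   byte-for-byte.
#' @return Object of class \code{inflammation_trace}: a data.frame with
#'   columns \code{step} (0 = initial state), \code{alive}, \code{dead},
#'   \code{fibrosis}, \code{tnf_total}, \code{tgf_total}; the final lattice
#'   state is attached as attribute \code{"final_state"}.
#' @export
run_inflammation <- function(strain, p, n_steps = 10000, seed = NULL) {
  stopifnot(inherits(p, "ca_params"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  e <- .state_to_env(init_ca_state(p, strain))
  n_sites <- p$width * p$height
  alive <- integer(n_steps + 1L)
  dead <- integer(n_steps + 1L)
  fib <- integer(n_steps + 1L)
  tnf_tot <- numeric(n_steps + 1L)
  tgf_tot <- numeric(n_steps + 1L)
  alive[1L] <- n_sites
  for (i in seq_len(n_steps)) {
    .ca_step_env(e, p)
    dead[i + 1L] <- e$n_dead
    fib[i + 1L] <- e$n_fib
    alive[i + 1L] <- n_sites - e$n_dead - e$n_fib
    tnf_tot[i + 1L] <- if (e$tnf_active) sum(e$tnf) else 0
    tgf_tot[i + 1L] <- if (e$tgf_active) sum(e$tgf) else 0
  }
  trace <- data.frame(step = 0:n_steps, alive = alive, dead = dead,
                      fibrosis = fib, tnf_total = tnf_tot,
                      tgf_total = tgf_tot)
  attr(trace, "final_state") <- .env_to_state(e)
  class(trace) <- c("inflammation_trace", "data.frame")
  trace
}

#' Seeded replicate ensemble of inflammation runs
#'
#' Runs independent replicates with per-replicate seeds derived from the
#' master seed (seed + replicate index) and summarises the dead-cell traces.
#'
#' @param strain,p,n_steps As in \code{\link{run_inflammation}}.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Master seed.
#' @return List with \code{mean_trace} (data.frame \code{step},
#'   \code{dead_mean}, \code{dead_sd}, \code{fibrosis_mean}), \code{peaks}
#'   (per-replicate peak height and step), \code{cv_peak} (coefficient of
#'   variation of the peak height), and the matrix of per-replicate dead
#'   traces.
#' @export
run_ensemble <- function(strain, p, n_steps = 10000, n_reps = 20, seed = 1) {
  stopifnot(n_reps >= 2)
  dead <- matrix(0L, n_steps + 1L, n_reps)
  fibm <- matrix(0L, n_steps + 1L, n_reps)
  peaks <- data.frame(rep = seq_len(n_reps), peak = 0L, peak_step = 0L)
  for (r in seq_len(n_reps)) {
    tr <- run_inflammation(strain, p, n_steps,
                           seed = (seed + r) %% 2147483647L)
    dead[, r] <- tr$dead
    fibm[, r] <- tr$fibrosis
    peaks$peak[r] <- max(tr$dead)
    peaks$peak_step[r] <- tr$step[which.max(tr$dead)]
  }
  dead_mean <- rowMeans(dead)
  mean_trace <- data.frame(step = 0:n_steps, dead_mean = dead_mean,
                           dead_sd = apply(dead, 1, stats::sd),
                           fibrosis_mean = rowMeans(fibm))
  cv <- if (mean(peaks$peak) > 0) {
    stats::sd(peaks$peak) / mean(peaks$peak)
  } else 0
  list(mean_trace = mean_trace, peaks = peaks, cv_peak = cv, dead = dead)
}
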