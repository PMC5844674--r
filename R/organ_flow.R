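#' Build a symmetric lumped-parameter airway tree
#'
#' Constructs the organ-scale model: an ordered set of airway generations,
#' each a set of \code{2^gn} identical parallel branches characterised by
#' lumen radius, segment length and cross-sectional area. The tree carries the
#' air viscosity used by the Poiseuille resistance model.
#'
#' @param morphology Morphology table as returned by
#'   \code{\link{default_morphology}} or \code{\link{read_morphology}}.
#' @param max_gn Deepest generation to keep (default 7).
#' @param air_viscosity Dynamic viscosity of air in kg/(m s); default
#'   1.79e-5.
#' @return An object of class \code{airway_tree}: a list with elements
#'   \code{generations} (data.frame with \code{gn, radius, length, count, S}
#'   and the wall-layer thicknesses) and \code{air_viscosity}.
#' @export
#' @examples
#' tree <- build_airway_tree(max_gn = 7)
#' tree
build_airway_tree <- function(morphology = default_morphology(max_gn),
                              max_gn = 7, air_viscosity = 1.79e-5) {
  stopifnot(max_gn >= 0, air_viscosity > 0)
  validate_morphology(morphology)
  morph <- morphology[morphology$gn <= max_gn, , drop = FALSE]
  if (max(morph$gn) < max_gn) {
    stop("morphology table stops at generation ", max(morph$gn),
         "; requested max_gn = ", max_gn)
  }
  gen <- data.frame(
    gn = as.integer(morph$gn),
    radius = morph$radius_m,
    length = morph$length_m,
    count = as.integer(2^morph$gn),
    S = pi * morph$radius_m^2,
    t_epi = morph$t_epi_m,
    t_conn = morph$t_conn_m,
    t_asm = morph$t_asm_m
  )
  structure(list(generations = gen, air_viscosity = air_viscosity),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  g <- x$generations
  cat("Symmetric airway tree: generations 0-", max(g$gn),
      " (", sum(g$count), " branches total)\n", sep = "")
  cat("Air viscosity:", format(x$air_viscosity), "kg/(m s)\n")
  print(g[, c("gn", "radius", "length", "count", "S")], row.names = FALSE)
  invisible(x)
}

#' Ventilator inflow waveform
#'
#' Defines the mechanical-ventilation inlet boundary condition: a
#' rising-exponential inspiratory flow followed by a decaying-exponential
#' expiratory flow. The inspiratory amplitude is fixed so the inspired volume
#' equals the tidal volume exactly; the expiratory profile is continuous with
#' the inspiratory flow at the transition and returns exactly the same volume
#' over the expiratory window, so the breath cycle conserves volume in closed
#' form.
#'
#' Inspiration (0 <= t <= T_in): Q(t) = A (1 - exp(-t/tau)).
#' Expiration (s = t - T_in): Q(s) = (Q_e + B s/tau_ex) exp(-s/tau_ex), with
#' Q_e the end-inspiratory flow and B solved so the expired volume equals the
#' tidal volume.
#'
#' @param tidal_volume_ml Tidal volume in millilitres (default 420).
#' @param t_in Inspiration time in seconds (default 0.4).
#' @param t_ex Expiration time in seconds (default 2.0).
#' @param shape_tau Inspiratory exponential time constant (s); default
#'   \code{t_in/5}.
#' @param shape_tau_ex Expiratory time constant (s); default \code{t_ex/5}.
#' @return Object of class \code{ventilator_waveform}.
#' @export
#' @examples
#' w <- ventilator_waveform()
#' inlet_flow(c(0, 0.2, 0.4, 1.0), w)
ventilator_waveform <- function(tidal_volume_ml = 420, t_in = 0.4, t_ex = 2.0,
                                shape_tau = t_in / 5,
                                shape_tau_ex = t_ex / 5) {
  stopifnot(tidal_volume_ml >= 0, t_in > 0, t_ex > 0,
            shape_tau > 0, shape_tau_ex > 0)
  v_t <- tidal_volume_ml * 1e-6             # m^3
  # inspiratory amplitude: integral of A(1 - e^(-t/tau)) over [0, T_in] = V_T
  denom <- t_in - shape_tau * (1 - exp(-t_in / shape_tau))
  amp <- v_t / denom
  q_end <- amp * (1 - exp(-t_in / shape_tau))  # flow at the transition
  # expiratory shape (Q_e + B s/tau) e^(-s/tau): solve B so expired volume = V_T
  ee <- exp(-t_ex / shape_tau_ex)
  int_qe <- shape_tau_ex * (1 - ee)
  int_b <- shape_tau_ex * (1 - (1 + t_ex / shape_tau_ex) * ee)
  b <- (-v_t - q_end * int_qe) / int_b
  structure(list(tidal_volume = v_t, t_in = t_in, t_ex = t_ex,
                 shape_tau = shape_tau, shape_tau_ex = shape_tau_ex,
                 amplitude = amp, q_end = q_end, b = b),
            class = "ventilator_waveform")
}

#' @export
print.ventilator_waveform <- function(x, ...) {
  cat("Ventilator waveform: V_T =", x$tidal_volume * 1e6, "ml, T_in =",
      x$t_in, "s, T_ex =", x$t_ex, "s\n")
  cat("Peak inspiratory flow:", format(x$q_end * 1e6, digits = 4), "ml/s\n")
  invisible(x)
}

#' Inlet flow rate of the ventilator waveform
#'
#' @param t Time(s) in seconds, within one breath cycle
#'   \code{[0, t_in + t_ex]} unless \code{periodic = TRUE}.
#' @param w A \code{\link{ventilator_waveform}}.
#' @param periodic If TRUE, times are wrapped periodically into the cycle.
#' @return Flow rate(s) in m^3/s; positive into the lung during inspiration,
#'   negative during expiration.
#' @export
inlet_flow <- function(t, w, periodic = FALSE) {
  stopifnot(inherits(w, "ventilator_waveform"))
  cycle <- w$t_in + w$t_ex
  if (periodic) {
    t <- t %% cycle
  } else if (any(t < 0 | t > cycle)) {
    stop("t outside the breath cycle [0, ", cycle,
         "]; set periodic = TRUE for periodic extension")
  }
  q <- numeric(length(t))
  insp <- t <= w$t_in
  q[insp] <- w$amplitude * (1 - exp(-t[insp] / w$shape_tau))
  s <- t[!insp] - w$t_in
  q[!insp] <- (w$q_end + w$b * s / w$shape_tau_ex) * exp(-s / w$shape_tau_ex)
  q
}

#' Distribute inlet flow over the symmetric tree
#'
#' Mass conservation on a symmetric bifurcating tree: every generation carries
#' the full inlet flow, split equally over its \code{2^gn} parallel branches.
#'
#' @param tree An \code{\link{build_airway_tree}} result.
#' @param q_inlet Inlet flow rate (m^3/s).
#' @return data.frame with \code{gn}, \code{count}, \code{q_branch} (m^3/s).
#' @export
distribute_flow <- function(tree, q_inlet) {
  stopifnot(inherits(tree, "airway_tree"), is.finite(q_inlet))
  g <- tree$generations
  data.frame(gn = g$gn, count = g$count, q_branch = q_inlet / g$count)
}

#' Poiseuille pressure drop along one branch
#'
#' Fully developed laminar flow in a rigid cylindrical segment:
#' \code{dP = 8 mu L q / (pi r^4)}.
#'
#' @param g A single-generation row: list or one-row data.frame with
#'   \code{radius} and \code{length} (m).
#' @param q_branch Per-branch flow rate (m^3/s).
#' @param mu_air Air dynamic viscosity, kg/(m s).
#' @return Pressure drop in Pa (same sign as \code{q_branch}).
#' @export
#' @examples
#' branch_pressure_drop(list(radius = 0.001, length = 0.01), 1e-5, 1.79e-5)
branch_pressure_drop <- function(g, q_branch, mu_air = 1.79e-5) {
  r <- g$radius
  l <- g$length
  if (any(!is.finite(r)) || any(r <= 0)) stop("branch radius must be positive")
  if (any(!is.finite(l)) || any(l <= 0)) stop("branch length must be positive")
  8 * mu_air * l * q_branch / (pi * r^4)
}

#' Lumen pressure over one breath cycle for every generation
#'
#' Evaluates the quasi-static Poiseuille resistance network per time sample:
#' the inlet waveform flow is split symmetrically, the per-branch viscous drop
#' of each generation is accumulated from the outlet boundary upward, and the
#' lumen pressure of generation g is the outlet pressure plus the drops of all
#' generations at or below g. Pressure therefore decreases monotonically with
#' generation whenever flow is inspiratory, reproducing the generation-wise
#' pressure drop seen along the airway tree.
#'
#' @param tree An \code{airway_tree}.
#' @param w A \code{ventilator_waveform}.
#' @param p_outlet Outlet (gauge) boundary pressure in Pa, default 0.
#' @param n_samples Number of time samples across the cycle (>= 2).
#' @return Object of class \code{pressure_profile}: list with \code{time},
#'   \code{inlet_flow}, \code{pressure} (matrix time x generation, Pa),
#'   \code{branch_flow} (matrix time x generation, m^3/s),
#'   \code{peak_pressure} (named vector, Pa, at peak inspiratory flow) and
#'   \code{p_outlet}.
#' @export
pressure_profile <- function(tree, w, p_outlet = 0, n_samples = 201) {
  stopifnot(inherits(tree, "airway_tree"), inherits(w, "ventilator_waveform"))
  if (n_samples < 2) stop("n_samples must be >= 2")
  g <- tree$generations
  times <- seq(0, w$t_in + w$t_ex, length.out = n_samples)
  q_in <- inlet_flow(times, w)
  # per unit inlet flow: branch drop of generation g
  dp_unit <- vapply(seq_len(nrow(g)), function(i) {
    branch_pressure_drop(g[i, ], 1 / g$count[i], tree$air_viscosity)
  }, numeric(1))
  drops <- outer(q_in, dp_unit)                     # time x generation
  # pressure at generation j = p_outlet + sum of drops for generations >= j
  ngen <- nrow(g)
  if (ngen == 1L) {
    cum <- matrix(drops, ncol = 1L)
  } else {
    cum <- t(apply(drops, 1, function(d) rev(cumsum(rev(d)))))
  }
  pressure <- p_outlet + cum
  colnames(pressure) <- paste0("G", g$gn)
  branch_flow <- outer(q_in, 1 / g$count)
  colnames(branch_flow) <- paste0("G", g$gn)
  i_peak <- which.max(q_in)
  peak <- pressure[i_peak, ]
  structure(list(time = times, inlet_flow = q_in, pressure = pressure,
                 branch_flow = branch_flow, peak_pressure = peak,
                 p_outlet = p_outlet, gn = g$gn),
            class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat("Pressure profile over one breath cycle (", length(x$time),
      " samples)\n", sep = "")
  cat("Peak-of-cycle lumen pressure (Pa):\n")
  print(round(x$peak_pressure, 4))
  invisible(x)
}

#' Tidy per-generation pressure/flow table
#'
#' @param x A \code{pressure_profile}.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return data.frame with \code{time_s, gn, pressure_Pa, flow_m3s}
#'   (per-branch flow), the CSV layout of the organ-stage output.
#' @export
as.data.frame.pressure_profile <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  ngen <- length(x$gn)
  data.frame(
    time_s = rep(x$time, times = ngen),
    gn = rep(x$gn, each = length(x$time)),
    pressure_Pa = as.vector(x$pressure),
    flow_m3s = as.vector(x$branch_flow)
  )
}
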