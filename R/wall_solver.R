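#' Three-layer airway wall section
#'
#' Axisymmetric annulus of three concentric layers (epithelium, connective
#' tissue, airway smooth muscle) around a lumen of radius
#' \code{inner_radius}. The inner boundary carries the lumen pressure as a
#' normal traction; the outer boundary is tethered to the surrounding
#' alveolar sacs by a linear elastic foundation (traction -k u).
#'
#' @param inner_radius Lumen radius (m).
#' @param thicknesses Numeric vector of length 3: layer thicknesses (m) in
#'   inner-to-outer order (epithelium, connective, ASM).
#' @param materials Named list with elements \code{epithelium},
#'   \code{connective}, \code{asm}; see \code{\link{default_materials}}.
#' @param foundation_k Elastic-support stiffness (default 600, the value used
#'   to model airway tethering).
#' @return Object of class \code{wall_section}.
#' @export
wall_section <- function(inner_radius, thicknesses,
                         materials = default_materials(),
                         foundation_k = 600) {
  stopifnot(is.finite(inner_radius), inner_radius > 0,
            length(thicknesses) == 3, all(is.finite(thicknesses)),
            all(thicknesses > 0), foundation_k >= 0)
  stopifnot(all(c("epithelium", "connective", "asm") %in% names(materials)))
  layers <- list(
    list(name = "epithelium", thickness = thicknesses[[1L]],
         material = materials$epithelium),
    list(name = "connective", thickness = thicknesses[[2L]],
         material = materials$connective),
    list(name = "asm", thickness = thicknesses[[3L]],
         material = materials$asm)
  )
  structure(list(inner_radius = inner_radius, layers = layers,
                 foundation_k = foundation_k),
            class = "wall_section")
}

#' Wall section for one airway generation
#'
#' @param morph_row One row of a morphology table.
#' @param materials,foundation_k See \code{\link{wall_section}}.
#' @return A \code{wall_section}.
#' @export
wall_section_for_generation <- function(morph_row,
                                        materials = default_materials(),
                                        foundation_k = 600) {
  wall_section(morph_row$radius_m,
               c(morph_row$t_epi_m, morph_row$t_conn_m, morph_row$t_asm_m),
               materials, foundation_k)
}

# ---- element-level constitutive response -----------------------------------

# Gradient of the energy density wrt the radial/hoop stretches, written in
# the strain variables er = lambda_r - 1, et = lambda_t - 1 (axial stretch 1,
# plane strain). The strain form avoids the catastrophic cancellation of
# J - 1 and 2a^2 - b^2 - 1 at the micro-strains typical of airway pressures,
# which would otherwise cap the attainable Newton residual. Vectorized over
# elements.
.wall_grad <- function(er, et, mat) {
  if (inherits(mat, "material_neo_hookean")) {
    mu <- mat$mu; d <- mat$d
    a <- 1 + er; b <- 1 + et
    J <- a * b
    if (any(J <= 0)) stop("inverted element: J <= 0 during wall solve")
    jm1 <- er + et + er * et                 # J - 1, cancellation-free
    Jm53 <- J^(-5 / 3)
    vol <- (2 / d) * jm1
    # 2a^2 - b^2 - 1 = 4 er - 2 et + 2 er^2 - et^2 (and symmetrically)
    qa <- 4 * er - 2 * et + 2 * er^2 - et^2
    qb <- 4 * et - 2 * er + 2 * et^2 - er^2
    list(ga = mu * Jm53 * b * qa / 3 + vol * b,
         gb = mu * Jm53 * a * qb / 3 + vol * a)
  } else {
    E <- mat$E; nu <- mat$nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    g <- E / (2 * (1 + nu))
    tr <- lam * (er + et)
    list(ga = tr + 2 * g * er, gb = tr + 2 * g * et)
  }
}

.wall_energy <- function(er, et, mat) {
  if (inherits(mat, "material_neo_hookean")) {
    a <- 1 + er; b <- 1 + et
    J <- a * b
    I1 <- (a^2 + b^2 + 1) * J^(-2 / 3)
    neo_hookean_energy(I1, J, mat)
  } else {
    E <- mat$E; nu <- mat$nu
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    g <- E / (2 * (1 + nu))
    0.5 * lam * (er + et)^2 + g * (er^2 + et^2)
  }
}

.wall_stress <- function(er, et, mat) {
  gr <- .wall_grad(er, et, mat)
  if (inherits(mat, "material_neo_hookean")) {
    a <- 1 + er; b <- 1 + et
    J <- a * b
    list(sr = a / J * gr$ga, st = b / J * gr$gb)
  } else {
    list(sr = gr$ga, st = gr$gb)
  }
}

# ---- mesh ------------------------------------------------------------------

.wall_mesh <- function(section, n_nodes) {
  th <- vapply(section$layers, `[[`, numeric(1), "thickness")
  n_el_total <- max(n_nodes - 1L, 12L)
  n_el <- pmax(4L, round(n_el_total * th / sum(th)))
  edges <- section$inner_radius
  layer_id <- integer(0)
  for (j in seq_along(th)) {
    r0 <- edges[length(edges)]
    edges <- c(edges, r0 + seq_len(n_el[j]) * th[j] / n_el[j])
    layer_id <- c(layer_id, rep(j, n_el[j]))
  }
  r <- edges
  list(r = r, rm = (r[-1] + r[-length(r)]) / 2, h = diff(r),
       layer = layer_id, n = length(r))
}

# Thomas algorithm for a tridiagonal system (diag, lower, upper).
.tridiag_solve <- function(dg, lo, up, rhs) {
  n <- length(dg)
  cp <- numeric(n - 1)
  dp <- numeric(n)
  cp[1] <- up[1] / dg[1]
  dp[1] <- rhs[1] / dg[1]
  for (i in 2:n) {
    m <- dg[i] - lo[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- up[i] / m
    dp[i] <- (rhs[i] - lo[i - 1] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# ---- solver ----------------------------------------------------------------

#' Solve the quasi-static layered airway-wall problem
#'
#' Solves radial equilibrium of the three-layer annulus under lumen pressure:
#' a one-dimensional axisymmetric plane-strain discretization (linear finite
#' elements, midpoint quadrature) of the elastic balance with the inertial
#' term dropped. The inner boundary carries the pressure load, the outer
#' boundary the foundation traction -k u. Neo-Hookean layers are handled by
#' Newton iteration on the nonlinear residual; a fully linear section
#' converges in one step.
#'
#' @param section A \code{\link{wall_section}}.
#' @param lumen_pressure Lumen gauge pressure in Pa (>= 0).
#' @param n_nodes Number of radial nodes (default 200).
#' @param tol Relative residual tolerance for Newton (default 1e-10).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return Object of class \code{wall_solution}: radial grid \code{r}, nodal
#'   displacement \code{u}, element-midpoint radial/hoop strains
#'   \code{eps_r}, \code{eps_t}, Cauchy stresses \code{sigma_r},
#'   \code{sigma_t}, per-element \code{layer} ids, the scalar
#'   \code{epithelial_hoop_strain} passed to the cellular stage, and Newton
#'   diagnostics.
#' @export
#' @examples
#' sec <- wall_section(0.00225, c(1.1e-4, 2.2e-4, 3.4e-4))
#' sol <- solve_wall(sec, 10)
#' sol$epithelial_hoop_strain
solve_wall <- function(section, lumen_pressure, n_nodes = 200,
                       tol = 1e-10, max_iter = 50) {
  stopifnot(inherits(section, "wall_section"))
  if (!is.finite(lumen_pressure) || lumen_pressure < 0) {
    stop("lumen_pressure must be >= 0 (inflation case)")
  }
  mesh <- .wall_mesh(section, n_nodes)
  n <- mesh$n
  mats <- lapply(section$layers, `[[`, "material")
  el_mat <- mesh$layer

  if (lumen_pressure == 0) {
    zero_el <- numeric(n - 1)
    return(structure(list(
      r = mesh$r, u = numeric(n), eps_r = zero_el, eps_t = zero_el,
      sigma_r = zero_el, sigma_t = zero_el, layer = mesh$layer,
      epithelial_hoop_strain = 0, converged = TRUE, iterations = 0L,
      residual = 0), class = "wall_solution"))
  }

  r_in <- mesh$r[1]
  r_out <- mesh$r[n]
  k <- section$foundation_k
  w_el <- 2 * pi * mesh$rm * mesh$h   # element quadrature weight

  strains <- function(u) {
    list(er = diff(u) / mesh$h,
         et = (u[-n] + u[-1]) / (2 * mesh$rm))
  }

  grad_by_layer <- function(er, et) {
    ga <- numeric(length(er)); gb <- numeric(length(er))
    for (j in seq_along(mats)) {
      sel <- el_mat == j
      gr <- .wall_grad(er[sel], et[sel], mats[[j]])
      ga[sel] <- gr$ga; gb[sel] <- gr$gb
    }
    list(ga = ga, gb = gb)
  }

  residual <- function(u) {
    st <- strains(u)
    gr <- grad_by_layer(st$er, st$et)
    fa <- w_el * gr$ga      # conjugate to d(lambda_r)
    fb <- w_el * gr$gb      # conjugate to d(lambda_t)
    R <- numeric(n)
    contrib_i <- -fa / mesh$h + fb / (2 * mesh$rm)
    contrib_ip1 <- fa / mesh$h + fb / (2 * mesh$rm)
    R[-n] <- R[-n] + contrib_i
    R[-1] <- R[-1] + contrib_ip1
    R[n] <- R[n] + 2 * pi * r_out * k * u[n]
    R[1] <- R[1] - 2 * pi * r_in * lumen_pressure
    R
  }

  tangent <- function(u) {
    st <- strains(u)
    delta <- 1e-6
    gpa <- grad_by_layer(st$er + delta, st$et)
    gma <- grad_by_layer(st$er - delta, st$et)
    gpb <- grad_by_layer(st$er, st$et + delta)
    gmb <- grad_by_layer(st$er, st$et - delta)
    Waa <- (gpa$ga - gma$ga) / (2 * delta)
    Wab <- (gpb$ga - gmb$ga) / (2 * delta)
    Wbb <- (gpb$gb - gmb$gb) / (2 * delta)
    ca <- 1 / mesh$h          # d(lambda_r)/du_{i+1} = -d/du_i
    cb <- 1 / (2 * mesh$rm)   # d(lambda_t)/du_i = d/du_{i+1}
    k11 <- w_el * (Waa * ca^2 - 2 * Wab * ca * cb + Wbb * cb^2)
    k12 <- w_el * (-Waa * ca^2 + Wbb * cb^2)
    k22 <- w_el * (Waa * ca^2 + 2 * Wab * ca * cb + Wbb * cb^2)
    dg <- numeric(n); lo <- numeric(n - 1); up <- numeric(n - 1)
    dg[-n] <- dg[-n] + k11
    dg[-1] <- dg[-1] + k22
    lo <- lo + k12
    up <- up + k12
    dg[n] <- dg[n] + 2 * pi * r_out * k
    list(dg = dg, lo = lo, up = up)
  }

  u <- numeric(n)
  ref <- 2 * pi * r_in * lumen_pressure
  converged <- FALSE
  res_norm <- NA_real_
  for (it in seq_len(max_iter)) {
    R <- residual(u)
    res_norm <- max(abs(R)) / ref
    if (res_norm <= tol) { converged <- TRUE; break }
    Kt <- tangent(u)
    du <- .tridiag_solve(Kt$dg, Kt$lo, Kt$up, -R)
    u <- u + du
  }
  if (!converged) {
    R <- residual(u)
    res_norm <- max(abs(R)) / ref
    if (res_norm <= tol) converged <- TRUE
  }
  if (!converged) {
    stop(sprintf(
      "Newton failed to converge in %d iterations (relative residual %.3e)",
      max_iter, res_norm))
  }

  st <- strains(u)
  eps_r <- st$er
  eps_t <- st$et
  sr <- numeric(n - 1); stt <- numeric(n - 1)
  for (j in seq_along(mats)) {
    sel <- el_mat == j
    s <- .wall_stress(st$er[sel], st$et[sel], mats[[j]])
    sr[sel] <- s$sr; stt[sel] <- s$st
  }
  epi <- el_mat == 1L
  epi_strain <- sum(eps_t[epi] * mesh$h[epi]) / sum(mesh$h[epi])
  structure(list(r = mesh$r, u = u, eps_r = eps_r, eps_t = eps_t,
                 sigma_r = sr, sigma_t = stt, layer = mesh$layer,
                 epithelial_hoop_strain = epi_strain,
                 converged = converged, iterations = it,
                 residual = res_norm),
            class = "wall_solution")
}

#' @export
print.wall_solution <- function(x, ...) {
  cat("Wall solution:", length(x$r), "nodes,",
      x$iterations, "Newton iteration(s)\n")
  cat("Inner displacement:", format(x$u[1], digits = 6), "m\n")
  cat("Mean epithelial hoop strain:",
      format(x$epithelial_hoop_strain, digits = 6), "\n")
  invisible(x)
}

#' Internal strain energy of a wall solution
#'
#' Total stored energy (per unit axial length) of the deformed section,
#' including the elastic-foundation term. Used to check energy consistency
#' against the external work of the boundary pressure.
#'
#' @param section The \code{wall_section} that was solved.
#' @param sol The corresponding \code{wall_solution}.
#' @return Energy in J/m.
#' @export
wall_internal_energy <- function(section, sol) {
  mesh <- list(rm = (sol$r[-1] + sol$r[-length(sol$r)]) / 2, h = diff(sol$r))
  mats <- lapply(section$layers, `[[`, "material")
  w <- numeric(length(sol$eps_r))
  for (j in seq_along(mats)) {
    sel <- sol$layer == j
    w[sel] <- .wall_energy(sol$eps_r[sel], sol$eps_t[sel], mats[[j]])
  }
  u_out <- sol$u[length(sol$u)]
  sum(w * 2 * pi * mesh$rm * mesh$h) +
    0.5 * section$foundation_k * u_out^2 * 2 * pi * sol$r[length(sol$r)]
}

#' Peak-pressure epithelial strain for each airway generation
#'
#' Applies each generation's peak-of-cycle lumen pressure to its wall section
#' and returns the mean epithelial hoop strain, the scalar handed to the
#' cellular stage.
#'
#' @param tree An \code{airway_tree} (used for generation bookkeeping).
#' @param profile A \code{\link{pressure_profile}} for that tree.
#' @param sections Named list of \code{wall_section}s, names \code{"G<gn>"}
#'   (e.g. as built by \code{\link{default_wall_sections}}).
#' @param ... Passed to \code{\link{solve_wall}}.
#' @return Named numeric vector of epithelial hoop strains, one per section.
#' @export
strain_for_airways <- function(tree, profile, sections, ...) {
  stopifnot(inherits(profile, "pressure_profile"))
  out <- numeric(length(sections))
  names(out) <- names(sections)
  for (nm in names(sections)) {
    if (!nm %in% names(profile$peak_pressure)) {
      stop("no pressure available for generation ", nm)
    }
    sol <- solve_wall(sections[[nm]], profile$peak_pressure[[nm]], ...)
    out[[nm]] <- sol$epithelial_hoop_strain
  }
  out
}

#' Default wall sections for every generation of a morphology table
#'
#' @param morphology Morphology data.frame.
#' @param materials,foundation_k See \code{\link{wall_section}}.
#' @return Named list of \code{wall_section}s, names \code{"G<gn>"}.
#' @export
default_wall_sections <- function(morphology = default_morphology(),
                                  materials = default_materials(),
                                  foundation_k = 600) {
  validate_morphology(morphology)
  secs <- lapply(seq_len(nrow(morphology)), function(i) {
    wall_section_for_generation(morphology[i, ], materials, foundation_k)
  })
  names(secs) <- paste0("G", morphology$gn)
  secs
}
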