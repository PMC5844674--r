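#' Default simulation configuration
#'
#' Nested list with one block per stage (organ, tissue, cellular) plus the
#' coupling options: selected airways, fibrosis->stiffening feedback gain,
#' replicate count and master seed. All values can be overridden via
#' \code{\link{read_config}} or by editing the returned list.
#'
#' @param seed Master RNG seed.
#' @return A list of class \code{simulation_config}.
#' @export
default_config <- function(seed = 42) {
  structure(list(
    organ = list(tidal_volume_ml = 420, t_in_s = 0.4, t_ex_s = 2.0,
                 max_generation = 7, air_viscosity = 1.79e-5,
                 outlet_pressure_pa = 0, n_samples = 201),
    tissue = list(foundation_k = 600, n_nodes = 200,
                  epithelium_mu_pa = 5e6, connective_mu_pa = 5e5,
                  asm_e_pa = 99e6, asm_nu = 0.45),
    cellular = unclass(ca_params()),
    airways = c("G4-1", "G6", "G7"),
    n_steps = 10000,
    feedback_alpha = 1,
    n_reps = 1,
    seed = seed,
    morphology_file = NULL,
    out_dir = NULL
  ), class = "simulation_config")
}

#' Read a simulation configuration from JSON
#'
#' Keys present in the file override the defaults; everything else keeps its
#' default value.
#'
#' @param path Path to a JSON config file.
#' @return A \code{simulation_config} list.
#' @export
read_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_config()), user)
  class(cfg) <- "simulation_config"
  cfg
}

config_materials <- function(cfg) {
  list(epithelium = neo_hookean(cfg$tissue$epithelium_mu_pa),
       connective = neo_hookean(cfg$tissue$connective_mu_pa),
       asm = linear_elastic(cfg$tissue$asm_e_pa, cfg$tissue$asm_nu))
}

config_ca_params <- function(cfg) {
  do.call(ca_params, cfg$cellular[names(cfg$cellular) %in%
                                    names(formals(ca_params))])
}

#' Generation number of an airway label
#'
#' Labels address branches as \code{"G<generation>"} or
#' \code{"G<generation>-<index>"} (e.g. \code{"G4-1"} is a branch at
#' generation 4; in the symmetric tree all branches of a generation are
#' identical).
#'
#' @param label Character vector of airway labels.
#' @return Integer generation numbers.
#' @export
airway_generation <- function(label) {
  m <- regmatches(label, regexec("^G([0-9]+)(-[0-9]+)?$", label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("unrecognised airway label: ", label[bad][1L])
  vapply(m, function(x) as.integer(x[2L]), integer(1))
}

#' Summarise an inflammation trace
#'
#' @param trace An \code{\link{run_inflammation}} trace, or any data.frame
#'   with \code{step} and \code{dead} columns.
#' @return List with \code{peak} (maximum dead count), \code{peak_step}
#'   (first step attaining it), \code{resolution_step} (first step after the
#'   peak with dead count 0, or \code{NA} if unresolved; 0 for an all-zero
#'   trace) and \code{auc} (sum of the dead counts).
#' @export
#' @examples
#' tr <- data.frame(step = 0:4, dead = c(0, 1, 3, 2, 0))
#' summarize_response(tr)
summarize_response <- function(trace) {
  if (nrow(trace) == 0L) stop("empty trace")
  dead <- trace$dead
  peak <- max(dead)
  i_peak <- which.max(dead)
  if (peak == 0) {
    return(list(peak = 0L, peak_step = trace$step[1L],
                resolution_step = trace$step[1L], auc = 0))
  }
  after <- which(dead == 0 & seq_along(dead) > i_peak)
  res <- if (length(after)) trace$step[after[1L]] else NA_integer_
  list(peak = peak, peak_step = trace$step[i_peak],
       resolution_step = res, auc = sum(dead))
}

#' Run the multi-scale case study
#'
#' Executes the full pipeline for the selected airways: ventilator-driven
#' airway-tree pressures, per-generation wall strain, cellular-automata
#' inflammation, and one fibrosis-driven stiffening feedback pass (the
#' end-of-run fibrosis fraction stiffens the Neo-Hookean wall layers, and the
#' tissue stage is re-solved). The report compares the fold-change in immune
#' response across airways with the fold-change in strain after feedback.
#'
#' @param cfg A \code{\link{default_config}}-style configuration.
#' @return Object of class \code{case_study_report}: per-airway pressures,
#'   pre- and post-feedback strains, inflammation traces and summaries,
#'   fibrosis fractions, stiffened material constants and fold-change
#'   comparison. When \code{cfg$out_dir} is set, CSV tables and PNG figures
#'   are written there as a side effect.
#' @export
run_case_study <- function(cfg = default_config()) {
  morph <- tryCatch({
    if (is.null(cfg$morphology_file)) {
      default_morphology(cfg$organ$max_generation)
    } else {
      read_morphology(cfg$morphology_file)
    }
  }, error = function(e) stop("organ stage: ", conditionMessage(e)))

  gens <- airway_generation(cfg$airways)
  if (any(gens > cfg$organ$max_generation)) {
    stop("organ stage: selected airway beyond max_generation")
  }
  if (cfg$feedback_alpha < 0) stop("feedback_alpha must be >= 0")

  tree <- build_airway_tree(morph, cfg$organ$max_generation,
                            cfg$organ$air_viscosity)
  w <- ventilator_waveform(cfg$organ$tidal_volume_ml, cfg$organ$t_in_s,
                           cfg$organ$t_ex_s)
  profile <- pressure_profile(tree, w, cfg$organ$outlet_pressure_pa,
                              cfg$organ$n_samples)

  mats <- config_materials(cfg)
  sections <- default_wall_sections(morph, mats, cfg$tissue$foundation_k)
  sel <- paste0("G", gens)
  strains <- tryCatch(
    strain_for_airways(tree, profile, sections[sel],
                       n_nodes = cfg$tissue$n_nodes),
    error = function(e) stop("tissue stage: ", conditionMessage(e)))
  names(strains) <- cfg$airways

  p <- config_ca_params(cfg)
  traces <- list()
  summaries <- list()
  fib_frac <- numeric(length(cfg$airways))
  names(fib_frac) <- cfg$airways
  for (i in seq_along(cfg$airways)) {
    aw <- cfg$airways[i]
    tr <- tryCatch(
      run_inflammation(strains[[aw]], p, cfg$n_steps,
                       seed = (cfg$seed + i) %% 2147483647L),
      error = function(e) stop("cellular stage (", aw, "): ",
                               conditionMessage(e)))
    traces[[aw]] <- tr
    summaries[[aw]] <- summarize_response(tr)
    fib_frac[aw] <- tr$fibrosis[nrow(tr)] / (p$width * p$height)
  }

  # feedback: fibrosis stiffens the Neo-Hookean layers, tissue re-solved
  post_strains <- strains
  stiffened <- list()
  for (i in seq_along(cfg$airways)) {
    aw <- cfg$airways[i]
    mats_i <- mats
    mats_i$epithelium <- stiffen(mats$epithelium, fib_frac[aw],
                                 cfg$feedback_alpha)
    mats_i$connective <- stiffen(mats$connective, fib_frac[aw],
                                 cfg$feedback_alpha)
    stiffened[[aw]] <- mats_i
    sec <- default_wall_sections(morph, mats_i,
                                 cfg$tissue$foundation_k)[[paste0("G", gens[i])]]
    sol <- solve_wall(sec, profile$peak_pressure[[paste0("G", gens[i])]],
                      n_nodes = cfg$tissue$n_nodes)
    post_strains[aw] <- sol$epithelial_hoop_strain
  }

  peaks <- vapply(summaries, `[[`, numeric(1), "peak")
  # fold change of the inflammation readout: highest peak over the lowest
  # active peak, with a floor of one count for quiescent airways
  active <- peaks[peaks > 0]
  response_fold <- if (length(active)) {
    lower <- active[active < max(active)]
    max(active) / if (length(lower)) max(min(lower), 1) else 1
  } else 1
  strain_fold <- strains / post_strains

  report <- structure(list(
    config = cfg,
    pressure = profile$peak_pressure[sel],
    strain_pre = strains,
    strain_post = post_strains,
    traces = traces,
    summaries = summaries,
    fibrosis_fraction = fib_frac,
    stiffened_materials = stiffened,
    response_fold_change = response_fold,
    strain_fold_change = strain_fold,
    profile = profile
  ), class = "case_study_report")

  if (!is.null(cfg$out_dir)) write_case_study(report, cfg$out_dir)
  report
}

#' @export
print.case_study_report <- function(x, ...) {
  cat("Multi-scale case study:", paste(x$config$airways, collapse = ", "),
      "\n\n")
  tab <- data.frame(
    airway = x$config$airways,
    pressure_Pa = as.numeric(x$pressure),
    strain_pre = as.numeric(x$strain_pre),
    strain_post = as.numeric(x$strain_post),
    peak_dead = vapply(x$summaries, `[[`, numeric(1), "peak"),
    peak_step = vapply(x$summaries, `[[`, numeric(1), "peak_step"),
    fibrosis_fraction = as.numeric(x$fibrosis_fraction)
  )
  print(tab, row.names = FALSE, digits = 4)
  cat("\nImmune-response fold change across airways:",
      format(x$response_fold_change, digits = 4), "\n")
  cat("Strain fold change after feedback (pre/post):",
      paste(format(x$strain_fold_change, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

write_case_study <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# seed: %d", report$config$seed)
  organ <- as.data.frame(report$profile)
  path <- file.path(out_dir, "organ_pressure.csv")
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(organ, path, sep = ",", append = TRUE,
                                      row.names = FALSE, col.names = TRUE))
  tissue <- data.frame(gn = airway_generation(report$config$airways),
                       pressure_Pa = as.numeric(report$pressure),
                       epithelial_hoop_strain = as.numeric(report$strain_pre))
  utils::write.csv(tissue, file.path(out_dir, "tissue_strain.csv"),
                   row.names = FALSE)
  for (aw in names(report$traces)) {
    utils::write.csv(report$traces[[aw]],
                     file.path(out_dir, paste0("trace_", aw, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = report$config$seed,
         pressure_Pa = as.list(report$pressure),
         strain_pre = as.list(report$strain_pre),
         strain_post = as.list(report$strain_post),
         fibrosis_fraction = as.list(report$fibrosis_fraction),
         response_fold_change = report$response_fold_change,
         strain_fold_change = as.list(report$strain_fold_change)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  grDevices::png(file.path(out_dir, "pressure.png"), 800, 600)
  print(plot_pressure(report$profile))
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "inflammation.png"), 800, 600)
  print(plot_traces(report$traces))
  grDevices::dev.off()
  invisible(out_dir)
}

#' Plot lumen pressure over the breath cycle per generation
#'
#' @param profile A \code{\link{pressure_profile}}.
#' @return A ggplot object.
#' @export
plot_pressure <- function(profile) {
  df <- as.data.frame(profile)
  df$generation <- factor(paste0("G", df$gn), levels = paste0("G", profile$gn))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$pressure_Pa,
                                   colour = .data$generation)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "lumen pressure (Pa)",
                  title = "Pressure along the airway tree over one breath")
}

#' Plot inflammation traces (dead-cell counts)
#'
#' @param traces Named list of \code{inflammation_trace}s.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces) {
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    data.frame(airway = nm, step = traces[[nm]]$step,
               dead = traces[[nm]]$dead)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$dead,
                                   colour = .data$airway)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "simulation step", y = "dead epithelial cells",
                  title = "Inflammatory response per airway")
}

#' Write deterministic default fixture files
#'
#' @param kind One of \code{"morphology"} (CSV morphology table),
#'   \code{"strain_field"} (CSV lattice of per-site strain) or
#'   \code{"ca_params"} (JSON parameter block).
#' @param seed Seed recorded in the fixture header (fixtures are
#'   deterministic).
#' @param out_dir Output directory.
#' @param level Uniform strain level for \code{"strain_field"}.
#' @param width,height Lattice size for \code{"strain_field"}.
#' @return The path of the written file, invisibly.
#' @export
generate_fixtures <- function(kind, seed = 1, out_dir = ".",
                              level = 0, width = 100, height = 100) {
  kinds <- c("morphology", "strain_field", "ca_params")
  if (!kind %in% kinds) {
    stop("unknown fixture kind '", kind, "'; available: ",
         paste(kinds, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- switch(kind,
    morphology = {
      f <- file.path(out_dir, "morphology.csv")
      utils::write.csv(default_morphology(), f, row.names = FALSE)
      f
    },
    strain_field = {
      f <- file.path(out_dir, "strain_field.csv")
      utils::write.table(matrix(level, width, height), f, sep = ",",
                         row.names = FALSE, col.names = FALSE)
      f
    },
    ca_params = {
      f <- file.path(out_dir, "ca_params.json")
      jsonlite::write_json(unclass(ca_params()), f, auto_unbox = TRUE,
                           digits = NA)
      f
    })
  invisible(path)
}
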