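#' Default airway morphology (symmetric Weibel-type tree)
#'
#' Returns the packaged per-branch morphology table for generations 0 to
#' \code{max_gn} of a symmetric bifurcating airway tree: lumen radius, segment
#' length, and the thicknesses of the three wall layers (epithelium,
#' connective tissue, airway smooth muscle). Lumen dimensions follow the
#' classic Weibel "model A" morphometry; the wall-layer thicknesses are set
#' proportional to the lumen radius (5\%, 10\% and 15\% respectively), giving
#' a wall-to-lumen ratio typical of conducting bronchioles.
#'
#' @param max_gn Largest generation number to include (0 = trachea). The
#'   packaged table covers generations 0-7.
#' @return A data.frame with columns \code{gn}, \code{radius_m},
#'   \code{length_m}, \code{t_epi_m}, \code{t_conn_m}, \code{t_asm_m}.
#' @export
#' @examples
#' default_morphology(max_gn = 3)
default_morphology <- function(max_gn = 7) {
  path <- system.file("extdata", "weibel_morphology.csv",
                      package = "ventilam", mustWork = TRUE)
  morph <- utils::read.csv(path)
  if (max_gn > max(morph$gn)) {
    stop("packaged morphology covers generations 0-", max(morph$gn),
         "; requested max_gn = ", max_gn)
  }
  morph[morph$gn <= max_gn, , drop = FALSE]
}

#' Read a morphology table from CSV
#'
#' The file must have columns \code{gn, radius_m, length_m, t_epi_m,
#' t_conn_m, t_asm_m} (one row per generation, generations contiguous from 0).
#'
#' @param path Path to a delimited text file.
#' @return A validated morphology data.frame.
#' @export
read_morphology <- function(path) {
  morph <- utils::read.csv(path)
  validate_morphology(morph)
  morph
}

validate_morphology <- function(morph) {
  needed <- c("gn", "radius_m", "length_m", "t_epi_m", "t_conn_m", "t_asm_m")
  missing <- setdiff(needed, names(morph))
  if (length(missing)) {
    stop("morphology table is missing columns: ", paste(missing, collapse = ", "))
  }
  morph <- morph[order(morph$gn), , drop = FALSE]
  if (!identical(as.integer(morph$gn), seq(0L, nrow(morph) - 1L))) {
    stop("morphology generations must be contiguous from 0")
  }
  for (col in setdiff(needed, "gn")) {
    bad <- which(!is.finite(morph[[col]]) | morph[[col]] <= 0)
    if (length(bad)) {
      stop("non-positive ", col, " at generation ", morph$gn[bad[1L]])
    }
  }
  invisible(morph)
}
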