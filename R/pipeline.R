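#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the delineation pipeline. Defaults
#' follow the per-stage defaults: Gaussian scale `sigma = 1` px, search
#' half-width `d = 2` px, search spacing `delta_d = 0.1` px, curve sampling
#' step `delta_s = 0.1`.
#'
#' @param sigma Gaussian scale for the gradient field (pixels).
#' @param d refinement search half-width (pixels, 1--5).
#' @param delta_d refinement candidate spacing (pixels).
#' @param delta_s Hermite curve sampling step.
#' @param n_control optional override for the number of control points
#'   (default `NULL`: allocated from the boundary length).
#' @param tie_policy see [refinement_params()].
#' @param seed RNG seed used by any stochastic stage.
#' @return a `run_config` object.
#' @export
run_config <- function(sigma = 1, d = 2, delta_d = 0.1, delta_s = 0.1,
                       n_control = NULL,
                       tie_policy = "nearest_to_original", seed = 1L) {
  cfg <- list(sigma = sigma,
              refine = refinement_params(d, delta_d, tie_policy),
              sampling = curve_sampling_params(delta_s),
              n_control = if (!is.null(n_control)) as.integer(n_control),
              seed = as.integer(seed))
  if (cfg$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys match the [run_config()] arguments
#' (`sigma`, `d`, `delta_d`, `delta_s`, `n_control`, `tie_policy`,
#' `seed`); missing keys take the defaults, `overrides` (e.g. parsed
#' command-line flags) win over the file.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list of values that override the file.
#' @return a [run_config()].
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  allowed <- c("sigma", "d", "delta_d", "delta_s", "n_control",
               "tie_policy", "seed")
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' Full delineation pipeline
#'
#' Runs the complete semiautomatic workflow on one image and one initial
#' closed boundary (standing in for the hand-drawn contour):
#' boundary length -> control-point allocation -> uniform subsampling ->
#' closed Hermite curve fitting -> Gaussian-derivative gradient field ->
#' subpixel normal-search refinement.
#'
#' @param image numeric intensity matrix, or path to an image file
#'   ([read_image()]).
#' @param init a [contour()] or path to a contour file ([read_contour()]).
#' @param config a [run_config()].
#' @param out_contour optional path: the refined contour is written there
#'   (JSON or CSV by extension).
#' @param out_report optional path: a JSON log of per-stage point counts
#'   and parameters.
#' @param verbose print the per-stage log to the console.
#' @return (invisibly when writing files) a list with `refined`
#'   (the final [contour()]), `fitted` (the Hermite curve before
#'   refinement), `control_points`, `field` and `report`.
#' @export
delineate <- function(image, init, config = run_config(),
                      out_contour = NULL, out_report = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(image)) image <- read_image(image)
  if (is.character(init)) init <- read_contour(init)
  stopifnot(is.matrix(image), inherits(init, "contour"))
  L <- arc_length(init)
  n_cp <- if (is.null(config$n_control)) allocate_control_points(L)
          else config$n_control
  cps <- subsample_control_points(init, n_cp)
  fitted <- evaluate_curve(cps, config$sampling)
  field <- compute_gradient(image, config$sigma)
  refined <- refine_curve(fitted, field, config$refine)
  report <- list(
    boundary_length_px = L,
    n_input_points = nrow(init$points),
    n_control_points = n_cp,
    n_curve_points = nrow(fitted$points),
    n_refined_points = nrow(refined$points),
    sigma = config$sigma,
    d = config$refine$d,
    delta_d = config$refine$delta_d,
    delta_s = config$sampling$delta_s,
    max_displacement_px = max(sqrt(rowSums((refined$points - fitted$points)^2)))
  )
  if (verbose) {
    for (nm in names(report))
      cat(sprintf("  %-22s %s\n", nm, format(report[[nm]], digits = 6)))
  }
  if (!is.null(out_contour)) write_contour(refined, out_contour)
  if (!is.null(out_report))
    jsonlite::write_json(report, out_report, auto_unbox = TRUE, digits = NA)
  res <- list(refined = refined, fitted = fitted, control_points = cps,
              field = field, report = report)
  if (is.null(out_contour)) res else invisible(res)
}

#' Programmatic control-point revision
#'
#' The scripted equivalent of dragging one control point with the mouse:
#' moves control point `index` of the set derived from `init` to
#' `(new_x, new_y)` and re-fits the closed Hermite curve. Only the four
#' segments adjacent to the moved point change.
#'
#' @param init a [contour()] or contour file path; treated as the boundary
#'   from which control points are subsampled, unless `is_control_points`
#'   is `TRUE`, in which case its vertices are used as control points
#'   directly.
#' @param index 1-based control-point index.
#' @param new_x,new_y destination coordinates.
#' @param config a [run_config()].
#' @param is_control_points interpret `init`'s vertices as the control
#'   points themselves.
#' @param out_contour,out_control optional output paths for the re-fitted
#'   curve and the updated control points.
#' @return list with `control_points` (updated set) and `curve`
#'   (re-fitted [contour()]).
#' @export
revise <- function(init, index, new_x, new_y, config = run_config(),
                   is_control_points = FALSE,
                   out_contour = NULL, out_control = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(init)) init <- read_contour(init)
  cps <- if (is_control_points) control_point_set(init$points)
         else subsample_control_points(init, if (is.null(config$n_control))
             allocate_control_points(arc_length(init)) else config$n_control)
  cps2 <- move_control_point(cps, index, c(new_x, new_y))
  curve <- evaluate_curve(cps2, config$sampling)
  if (!is.null(out_contour)) write_contour(curve, out_contour)
  if (!is.null(out_control)) write_contour(contour(cps2$points), out_control)
  list(control_points = cps2, curve = curve)
}

#' Generate and write a synthetic scene
#'
#' Wraps [make_noisy_disc()] for the command line: writes the image (PNG),
#' the analytic ground-truth contour (JSON) and the generation parameters
#' (YAML).
#'
#' @param out_image,out_truth,out_params output paths (`NULL` to skip).
#' @inheritParams make_noisy_disc
#' @return the `synthetic_scene`, invisibly.
#' @export
simulate_scene <- function(out_image = NULL, out_truth = NULL,
                           out_params = NULL, size = c(256, 256),
                           radius = 85, fg = 0, bg = 255,
                           noise_sigma = 10, seed = 1L) {
  sc <- make_noisy_disc(size = size, radius = radius, fg = fg, bg = bg,
                        noise_sigma = noise_sigma, seed = seed)
  if (!is.null(out_image)) write_image(sc$image, out_image)
  if (!is.null(out_truth)) write_contour(sc$truth_contour, out_truth)
  if (!is.null(out_params))
    yaml::write_yaml(c(sc$truth_params,
                       list(size = dim(sc$image), noise_sigma = sc$noise_sigma,
                            seed = sc$seed)), out_params)
  invisible(sc)
}

#' Compare two contour files
#'
#' Computes the [contour_error_report()] between a test and a reference
#' contour and optionally writes it as JSON.
#'
#' @param test,truth [contour()] objects or file paths.
#' @param shape `(rows, cols)` raster size for the Dice overlap (`NULL`
#'   skips Dice).
#' @param out_report optional JSON output path.
#' @return the `contour_error_report`.
#' @export
contour_metrics <- function(test, truth, shape = NULL, out_report = NULL) {
  if (is.character(test)) test <- read_contour(test)
  if (is.character(truth)) truth <- read_contour(truth)
  rep <- contour_error_report(test, truth, shape)
  if (!is.null(out_report))
    jsonlite::write_json(unclass(rep), out_report, auto_unbox = TRUE, digits = NA)
  rep
}
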