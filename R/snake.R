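#' Active contour (snake) baseline
#'
#' A minimal Kass--Witkin snake used as the comparison baseline for the
#' single-pass normal-search refinement. The closed contour
#' `x` evolves by the standard semi-implicit update
#' \deqn{x_{t+1} = (A + \gamma I)^{-1} (\gamma x_t + F_{ext}(x_t)),}
#' where `A` is the circulant pentadiagonal internal-energy matrix built
#' from the tension weight `alpha` (second difference) and rigidity weight
#' `beta` (fourth difference), and the external force is
#' `F_ext = -grad E_ext` with `E_ext = -|grad(G_sigma * I)|^2`, i.e. the
#' contour is attracted to strong edges of the Gaussian-smoothed image.
#' Image intensities are normalized to `[0, 1]` before the external energy
#' is computed so the default weights behave consistently across 8- and
#' 16-bit inputs.
#'
#' @param alpha tension (elasticity) weight, `> 0`; default 0.1.
#' @param beta rigidity (bending) weight, `> 0`; default 0.1.
#' @param gamma step-size (viscosity) parameter, `> 0`; default 1.
#' @param iterations number of update steps, `>= 1`; default 400 (the
#'   update has no natural stopping rule; fixed iteration count keeps runs
#'   deterministic).
#' @param sigma Gaussian scale for the external edge map; default 1.
#' @return `snake_params` returns a parameter object; `run_snake` the
#'   final [contour()] (same point count and ordering as `init`).
#' @export
snake_params <- function(alpha = 0.1, beta = 0.1, gamma = 1,
                         iterations = 400L, sigma = 1) {
  for (nm in c("alpha", "beta", "gamma", "sigma"))
    stop_if_not_scalar(get(nm), nm)
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta and gamma must be positive", call. = FALSE)
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 iterations = iterations, sigma = sigma),
            class = "snake_params")
}

# Circulant pentadiagonal internal-energy matrix for n points:
# row stencil (beta, -alpha - 4 beta, 2 alpha + 6 beta, -alpha - 4 beta, beta)
snake_internal_matrix <- function(n, alpha, beta) {
  stopifnot(n >= 5)
  A <- matrix(0, n, n)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    A[i, idx(i - 2L)] <- A[i, idx(i + 2L)] <- beta
    A[i, idx(i - 1L)] <- A[i, idx(i + 1L)] <- -alpha - 4 * beta
    A[i, i] <- 2 * alpha + 6 * beta
  }
  A
}

#' @rdname snake_params
#' @param image numeric intensity matrix.
#' @param init initial closed [contour()], inside the image and reasonably
#'   close to the target boundary.
#' @param params a [snake_params()].
#' @export
run_snake <- function(image, init, params = snake_params()) {
  stopifnot(is.matrix(image), inherits(init, "contour"),
            inherits(params, "snake_params"))
  nr <- nrow(image); nc <- ncol(image)
  rng <- range(image)
  norm_img <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  g <- compute_gradient(norm_img, params$sigma)
  edge <- g$magnitude^2                      # -E_ext
  # external force = gradient of edge strength (central differences)
  fx <- matrix(0, nr, nc); fy <- matrix(0, nr, nc)
  fx[, 2:(nc - 1)] <- (edge[, 3:nc] - edge[, 1:(nc - 2)]) / 2
  fy[2:(nr - 1), ] <- (edge[3:nr, ] - edge[1:(nr - 2), ]) / 2
  n <- nrow(init$points)
  A <- snake_internal_matrix(n, params$alpha, params$beta)
  M <- A + params$gamma * diag(n)
  Minv <- tryCatch(solve(M), error = function(e)
    stop("singular snake system; check alpha/beta/gamma", call. = FALSE))
  x <- init$points[, 1]; y <- init$points[, 2]
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1))
    stop("initial contour outside image bounds", call. = FALSE)
  for (it in seq_len(params$iterations)) {
    Fx <- bilinear_sample(fx, x, y)
    Fy <- bilinear_sample(fy, x, y)
    x <- clamp(Minv %*% (params$gamma * x + Fx), 0, nc - 1)
    y <- clamp(Minv %*% (params$gamma * y + Fy), 0, nr - 1)
  }
  contour(cbind(as.numeric(x), as.numeric(y)))
}
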