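# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

# Coerce an n x 2 representation (matrix, data.frame, list of pairs) to matrix.
as_points_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.list(points) && !is.matrix(points))
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L) stop("points must have two columns (x, y)", call. = FALSE)
  if (any(!is.finite(points))) stop("points must be finite", call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  points
}
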