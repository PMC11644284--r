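#' Evaluate an expression with a private random seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' `.Random.seed`, so package functions never leak random state. All
#' stochastic functions in the package take an explicit `seed` argument and
#' route it through here.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

## internal argument checks -------------------------------------------------

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && is.logical(mask)
}

assert_mask <- function(mask, nonempty = TRUE) {
  if (!is_binary_mask(mask)) {
    stop("`mask` must be a logical matrix (rows = image rows, cols = image columns)",
         call. = FALSE)
  }
  if (nonempty && !any(mask)) stop("no plant: mask is empty", call. = FALSE)
  invisible(mask)
}

assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must be a height x width x 3 array", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("`image` channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(image)
}
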