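#' Temperature grid for a melt ramp
#'
#' Defines the acquisition grid of an HRM ramp. The default mirrors the
#' common instrument program of 0.1 degC increments between 55 and 95 degC.
#'
#' @param start Ramp start, degC.
#' @param stop Ramp end, degC; must exceed `start`.
#' @param step Increment, degC; must divide `stop - start` evenly.
#'
#' @return An object of class `temp_grid` with fields `start`, `stop`,
#'   `step` and the expanded `temps` vector.
#' @examples
#' g <- temp_grid()
#' length(g$temps)  # 401 points
#' @export
temp_grid <- function(start = 55, stop = 95, step = 0.1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (step <= 0) stop("grid step must be positive")
  if (start >= stop) stop("grid start must be below stop")
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-8) {
    stop("(stop - start) must be an integer multiple of step")
  }
  temps <- start + step * seq(0, round(n))
  structure(
    list(start = start, stop = stop, step = step, temps = temps),
    class = "temp_grid"
  )
}

#' @export
print.temp_grid <- function(x, ...) {
  cat(sprintf(
    "<temp_grid> %.1f..%.1f degC by %.2f (%d points)\n",
    x$start, x$stop, x$step, length(x$temps)
  ))
  invisible(x)
}

# Stable 31-bit string hash for sub-seed derivation; independent of R's RNG.
stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  h
}

# Derive a reproducible sub-seed from a master seed and string tokens, so
# that adding a species/primer does not perturb other cells' draws.
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), unlist(list(...))), collapse = "\x1f")
  (stable_hash(key) + as.integer(master %% 1000003L)) %% 2147483647
}

# Evaluate `expr` under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
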