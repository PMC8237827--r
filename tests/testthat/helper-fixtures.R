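# Shared fixtures and independent oracles for the test suite.

# Small, well-separated 3-species x 2-primer panel for fast pipeline tests.
toy_panel <- function(tm_jitter_sd = 0, noise_sd = 0, seed = 42L) {
  cells <- list(
    "A|P1" = c(76, 80, 84), "A|P2" = c(78, 85),
    "B|P1" = c(77.5, 82), "B|P2" = c(79.5, 83, 87),
    "C|P1" = c(79, 86, 89), "C|P2" = c(76.5, 81.5)
  )
  transitions <- lapply(cells, function(tms) {
    lapply(tms, transition, amplitude = 95 / length(tms))
  })
  panel_spec(species = c("A", "B", "C"), primers = c("P1", "P2"),
             transitions = transitions, tm_jitter_sd = tm_jitter_sd,
             noise_sd = noise_sd, seed = seed)
}

noiseless_curve <- function(tms, grid = temp_grid(), width = 0.2) {
  trs <- lapply(tms, transition, amplitude = 95 / length(tms),
                width = width)
  simulate_melt_curve(trs, grid, baseline_post = 5, baseline_slope = -0.05)
}

# Brute-force oracle for peak-list alignment: enumerate every monotone
# one-to-one matching (equal-size ordered subsets paired in order), keep
# the feasible ones, maximize matched count then minimize total |dTm|.
brute_force_align <- function(ta, tb, tolerance) {
  m <- length(ta)
  n <- length(tb)
  best_k <- 0
  best_cost <- 0
  for (k in seq(min(m, n), 1)) {
    sub_a <- utils::combn(m, k, simplify = FALSE)
    sub_b <- utils::combn(n, k, simplify = FALSE)
    best_here <- Inf
    for (ia in sub_a) {
      for (ib in sub_b) {
        d <- abs(ta[ia] - tb[ib])
        if (all(d <= tolerance + 1e-12)) {
          best_here <- min(best_here, sum(d))
        }
      }
    }
    if (is.finite(best_here)) {
      best_k <- k
      best_cost <- best_here
      break
    }
  }
  list(matches = best_k, cost = best_cost)
}

random_tm_list <- function(max_peaks = 6) {
  k <- sample(0:max_peaks, 1)
  if (k == 0) return(numeric(0))
  sort(stats::runif(k, 75, 90))
}
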