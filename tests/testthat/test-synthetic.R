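test_that("default panel embeds the known fingerprint cells exactly", {
  panel <- make_default_panel(seed = 1)
  expect_length(panel$species, 16)
  expect_length(panel$primers, 8)
  expect_equal(
    transition_tms(panel_cell(panel, "Indo-Pacific bottlenose dolphin",
                              "UBC812")),
    c(80.0, 81.9, 86.1, 88.0))
  expect_equal(
    transition_tms(panel_cell(panel, "Striped dolphin", "UBC812")),
    c(79.9, 82.1, 86.1, 88.0))
  expect_equal(
    transition_tms(panel_cell(panel, "Dugong", "UBC848",
                              population = "AND")),
    c(79.9, 82.6, 87.7))
  expect_equal(
    transition_tms(panel_cell(panel, "Dugong", "UBC848",
                              population = "GOT")),
    c(80.5, 82.6))
  # Kogia cells: reported 2nd/3rd (and pygmy 4th) peaks
  expect_equal(
    transition_tms(panel_cell(panel, "Dwarf sperm whale", "UBC826"))[2:3],
    c(80.6, 82.6))
  expect_equal(
    transition_tms(panel_cell(panel, "Pygmy sperm whale", "UBC826"))[2:4],
    c(80.3, 82.4, 87.2))
})

test_that("panel generation is deterministic in the seed and respects separations", {
  p1 <- make_default_panel(seed = 7)
  p2 <- make_default_panel(seed = 7)
  expect_identical(p1, p2)
  p3 <- make_default_panel(seed = 8)
  expect_false(identical(p1$transitions, p3$transitions))
  for (key in names(p1$transitions)) {
    tms <- sort(transition_tms(p1$transitions[[key]]))
    expect_true(length(tms) >= 1 && length(tms) <= 8)
    if (length(tms) > 1) expect_gte(min(diff(tms)), 0.8 - 1e-9)
    expect_true(all(tms > 55 & tms < 95))
  }
})

test_that("panel_spec rejects invalid cells and noise parameters", {
  g <- temp_grid()
  good <- list("X|P" = list(transition(80), transition(81)))
  expect_s3_class(panel_spec("X", "P", good), "panel_spec")
  expect_error(
    panel_spec("X", "P", list("X|P" = list(transition(80),
                                           transition(80.5)))),
    "separations")
  expect_error(
    panel_spec("X", "P", list("X|P" = list(transition(50)))),
    "outside")
  expect_error(panel_spec("X", "P", good, tm_jitter_sd = -1),
               "non-negative")
  expect_error(panel_spec("X", "P", list()), "missing")
})

test_that("simulated curve follows the logistic-staircase closed form", {
  grid <- temp_grid()
  # no transitions, flat baseline -> constant
  flat <- simulate_melt_curve(list(), grid, baseline_post = 10,
                              baseline_slope = 0)
  expect_true(all(flat$fluorescence == 10))
  # single transition: exact model values, non-increasing
  tr <- transition(80, amplitude = 1, width = 0.4)
  mc <- simulate_melt_curve(list(tr), grid, baseline_post = 0,
                            baseline_slope = 0)
  expect_equal(mc$fluorescence,
               stats::plogis((80 - grid$temps) / 0.4), tolerance = 1e-12)
  expect_true(all(diff(mc$fluorescence) <= 1e-12))
  # derivative peak height closed form amplitude/(4*width) = 0.625
  dc <- derivative_curve(normalize_curve(mc))
  expect_equal(dc$temperatures[which.max(dc$values)], 80, tolerance = 0.05)
  expect_equal(max(dc$values), 1 / (4 * 0.4), tolerance = 0.01 * 0.625)
  # transition outside the grid is rejected
  expect_error(simulate_melt_curve(list(transition(200)), grid),
               "outside")
})

test_that("noise draws are reproducible from the seed", {
  grid <- temp_grid()
  trs <- list(transition(80, 95))
  a <- simulate_melt_curve(trs, grid, noise_sd = 0.2, seed = 11)
  b <- simulate_melt_curve(trs, grid, noise_sd = 0.2, seed = 11)
  c <- simulate_melt_curve(trs, grid, noise_sd = 0.2, seed = 12)
  expect_identical(a$fluorescence, b$fluorescence)
  expect_false(identical(a$fluorescence, c$fluorescence))
})

test_that("reference curve generation counts cells and preserves labels", {
  panel <- make_default_panel(seed = 1)
  panel$amplitude_jitter_cv <- 0 # silence every stochastic component
  refs <- generate_reference_curves(panel, replicates_per_cell = 3,
                                    tm_jitter_sd = 0, noise_sd = 0)
  expect_equal(length(refs), 3 * 16 * 8)
  expect_setequal(unique(refs$meta$species), panel$species)
  # with all noise sources silenced, replicates of one cell are identical
  idx <- which(refs$meta$species == "Dugong" & refs$meta$primer == "UBC848")
  expect_equal(refs$curves[[idx[1]]]$fluorescence,
               refs$curves[[idx[2]]]$fluorescence)
})

test_that("query design defaults to the 140-individual study layout", {
  panel <- make_default_panel(seed = 1)
  qs <- generate_query_set(panel, tm_jitter_sd = 0, noise_sd = 0)
  expect_equal(length(unique(qs$meta$id)), 140)
  expect_equal(length(qs), 140 * 8)
  tab <- table(qs$meta$species[qs$meta$primer == "UBC812"])
  expect_equal(as.integer(tab[names(default_query_counts())]),
               unname(default_query_counts()))
  expect_error(generate_query_set(panel, counts = c("Dugong" = -1)),
               "negative")
  expect_error(generate_query_set(panel, counts = c("Unicorn" = 2)),
               "absent")
  one <- generate_query_set(panel, counts = c("Dugong" = 1))
  expect_equal(length(unique(one$meta$id)), 1)
  # determinism
  q1 <- generate_query_set(panel, counts = c("Dugong" = 2), seed = 5)
  q2 <- generate_query_set(panel, counts = c("Dugong" = 2), seed = 5)
  q3 <- generate_query_set(panel, counts = c("Dugong" = 2), seed = 6)
  expect_identical(q1$curves, q2$curves)
  expect_false(identical(q1$curves, q3$curves))
})

test_that("replicate Tm jitter propagates to recovered peaks at the nominal SD", {
  # one-peak cell, 200 jittered replicates; sample SD of the recovered Tm
  # must track the planted jitter SD (direct Normal sampling oracle)
  grid <- temp_grid()
  sd_true <- 0.1
  panel <- panel_spec("S", "P",
                      list("S|P" = list(transition(82, 95))),
                      tm_jitter_sd = sd_true, noise_sd = 0, seed = 3L)
  refs <- generate_reference_curves(panel, replicates_per_cell = 200)
  tms <- vapply(refs$curves, function(cv) {
    extract_fingerprint(cv)$peaks$tm[1]
  }, numeric(1))
  # Monte-Carlo error of an SD estimate at n = 200 is ~ sd/sqrt(2*199)
  expect_equal(sd(tms), sd_true, tolerance = 0.25)
  expect_equal(mean(tms), 82, tolerance = 0.03)
})

test_that("population offsets shift recovered peaks by the offset", {
  # Fig.-2-style emulation: +0.1 degC on every peak of one population
  base <- c(78, 82, 86)
  cells <- list("D-X|P" = lapply(base, transition, amplitude = 95 / 3),
                "D-Y|P" = lapply(base + 0.1, transition,
                                 amplitude = 95 / 3))
  panel <- panel_spec("D", "P", cells,
                      populations = list(D = c("X", "Y")),
                      tm_jitter_sd = 0, noise_sd = 0, seed = 1L)
  fx <- extract_fingerprint(simulate_melt_curve(
    panel_cell(panel, "D", "P", "X"), panel$grid, baseline_post = 5,
    baseline_slope = -0.05))
  fy <- extract_fingerprint(simulate_melt_curve(
    panel_cell(panel, "D", "P", "Y"), panel$grid, baseline_post = 5,
    baseline_slope = -0.05))
  expect_lt(max(abs((fy$peaks$tm - fx$peaks$tm) - 0.1)), 0.1)
})

test_that("zero-noise round trip recovers every planted Tm with no spurious peaks", {
  panel <- make_default_panel(seed = 2)
  for (key in sample(names(panel$transitions), 25)) {
    trs <- panel$transitions[[key]]
    mc <- simulate_melt_curve(trs, panel$grid,
                              baseline_post = panel$baseline_post_level,
                              baseline_slope = panel$baseline_slope)
    fp <- extract_fingerprint(mc)
    tms <- sort(transition_tms(trs))
    expect_equal(nrow(fp$peaks), length(tms), info = key)
    expect_lt(max(abs(fp$peaks$tm - tms)), 0.05)
  }
})
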