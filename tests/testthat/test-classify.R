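test_that("an exact library match classifies at distance zero", {
  panel <- toy_panel()
  lib <- library_from_panel(panel)
  q <- melt_fingerprint(c(77.5, 82), primer = "P1", id = "q1")
  res <- classify_single_primer(q, lib, "P1")
  expect_equal(res$label, "B")
  expect_equal(res$distance, 0)
  expect_gt(res$margin, 0)
})

test_that("queries far from every reference are rejected as UNCLASSIFIED", {
  panel <- toy_panel()
  lib <- library_from_panel(panel)
  far <- melt_fingerprint(c(60, 65), primer = "P1", id = "q_far")
  res <- classify_single_primer(far, lib, "P1")
  expect_equal(res$label, "UNCLASSIFIED")
  expect_gt(res$distance, 0.5)
  # invalid (0-peak) query
  none <- structure(list(primer = "P1", id = "q0",
                         peaks = data.frame(tm = numeric(0),
                                            height = numeric(0),
                                            prominence = numeric(0),
                                            width = numeric(0)),
                         valid = FALSE), class = "melt_fingerprint")
  res0 <- classify_single_primer(none, lib, "P1")
  expect_equal(res0$label, "UNCLASSIFIED")
  expect_match(res0$reason, "invalid")
})

test_that("distance ties break lexicographically and are flagged", {
  cells <- list("A|P" = list(transition(80)), "B|P" = list(transition(84)))
  panel <- panel_spec(c("B", "A"), "P", cells, seed = 1L)
  lib <- library_from_panel(panel)
  q <- melt_fingerprint(82, primer = "P", id = "mid") # 2 deg from both
  res <- classify_single_primer(q, lib, "P", tolerance = 0.3,
                                reject_threshold = 1)
  expect_true(res$tie)
  expect_equal(res$label, "A")
})

test_that("queries jittered within 0.1 degC classify correctly on the default panel", {
  # bounded +-0.1 degC per-peak jitter on the noiseless panel: every
  # species must be recovered, except that the striped/bottlenose twin
  # cluster (reference Tm sets 0.1-0.2 degC apart under UBC812) may
  # resolve to either of its two members
  panel <- make_default_panel(seed = 1)
  lib <- library_from_panel(panel)
  twins <- c("Striped dolphin", "Indo-Pacific bottlenose dolphin")
  set.seed(88)
  for (sp in panel$species) {
    for (pr in panel$primers) {
      tms <- transition_tms(panel_cell(panel, sp, pr))
      q <- melt_fingerprint(tms + stats::runif(length(tms), -0.1, 0.1),
                            primer = pr, id = sp)
      res <- classify_single_primer(q, lib, pr)
      if (sp %in% twins && pr == "UBC812") {
        expect_true(res$label %in% twins)
      } else {
        expect_equal(res$label, sp)
      }
    }
  }
})

test_that("study-level jitter keeps single-primer accuracy high but imperfect", {
  # at the study conditions (sd 0.1 degC jitter, instrument noise) the
  # classifier is good but no longer perfect, mirroring the reported
  # per-primer accuracy range
  panel <- make_default_panel(seed = 1)
  lib <- library_from_panel(panel)
  qs <- generate_query_set(panel,
                           counts = c("Dugong" = 3, "Spinner dolphin" = 3,
                                      "Striped dolphin" = 3),
                           tm_jitter_sd = 0.1, noise_sd = 0.2, seed = 77)
  fps <- extract_fingerprints(qs)
  ok <- vapply(seq_along(fps), function(k) {
    classify_single_primer(fps[[k]], lib, qs$meta$primer[k])$label ==
      qs$meta$species[k]
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("combining primers resolves single-primer ambiguity", {
  # primer P1 cannot separate A from B; P2 can — hand-computed distances
  cells <- list(
    "A|P1" = list(transition(80)), "B|P1" = list(transition(80)),
    "A|P2" = list(transition(84)), "B|P2" = list(transition(88)))
  panel <- panel_spec(c("A", "B"), c("P1", "P2"), cells, seed = 1L)
  lib <- library_from_panel(panel)
  queries <- list(P1 = melt_fingerprint(80, "P1", "q"),
                  P2 = melt_fingerprint(88, "P2", "q"))
  single <- classify_single_primer(queries$P1, lib, "P1")
  expect_true(single$tie)
  combined <- classify_combined(queries, lib, c("P1", "P2"))
  expect_equal(combined$label, "B")
  # hand-computed: B = mean(0, 0) = 0; A = mean(0, 1) = 0.5
  expect_equal(combined$distance, 0)
  expect_equal(unname(combined$distances["A"]), 0.5)
  expect_error(classify_combined(queries, lib, c("P1", "P3")), "P3")
})

test_that("combined classification beats or matches the best single primer", {
  panel <- toy_panel(tm_jitter_sd = 0.15, noise_sd = 0.2)
  lib <- library_from_panel(panel)
  n_correct <- c(P1 = 0, P2 = 0, both = 0)
  n_total <- 0
  for (s in 1:30) {
    qs <- generate_query_set(panel, counts = c(A = 4, B = 4, C = 4),
                             seed = 1000 + s)
    fps <- extract_fingerprints(qs)
    ids <- unique(qs$meta$id)
    for (qid in ids) {
      sel <- which(qs$meta$id == qid)
      by_primer <- stats::setNames(fps[sel], qs$meta$primer[sel])
      truth <- qs$meta$species[sel[1]]
      n_total <- n_total + 1
      for (p in c("P1", "P2")) {
        r <- classify_single_primer(by_primer[[p]], lib, p)
        if (r$label == truth) n_correct[p] <- n_correct[p] + 1
      }
      rc <- classify_combined(by_primer, lib, c("P1", "P2"))
      if (rc$label == truth) n_correct["both"] <- n_correct["both"] + 1
    }
  }
  expect_gte(n_correct[["both"]], max(n_correct[["P1"]],
                                      n_correct[["P2"]]))
})

test_that("discrimination matrices count pairs and species correctly", {
  panel <- toy_panel()
  lib <- library_from_panel(panel)
  mats <- discrimination_matrix(lib, list("P1", "P2", c("P1", "P2")))
  for (m in mats) {
    d <- m$distinguishable
    expect_true(all(d == t(d), na.rm = TRUE)) # symmetric off-diagonal
    expect_true(all(is.na(diag(d))))
    expect_equal(m$success_rate, 100) # toy species are well separated
  }
  # identical references for every species -> 0% success
  same <- list("A|P" = list(transition(80)), "B|P" = list(transition(80)))
  panel0 <- panel_spec(c("A", "B"), "P", same, seed = 1L)
  m0 <- discrimination_matrix(library_from_panel(panel0), list("P"))[[1]]
  expect_equal(m0$success_rate, 0)
  expect_equal(m0$pair_rate, 0)
})

test_that("adding primers never loses discrimination (set monotonicity)", {
  panel <- make_default_panel(seed = 3)
  lib <- library_from_panel(panel)
  singles <- discrimination_matrix(lib, as.list(panel$primers))
  pairs <- all_primer_pairs(panel$primers)
  pair_mats <- discrimination_matrix(lib, pairs)
  single_rate <- stats::setNames(
    vapply(singles, function(m) m$success_rate, numeric(1)),
    panel$primers)
  for (k in seq_along(pairs)) {
    expect_gte(pair_mats[[k]]$success_rate,
               max(single_rate[pairs[[k]]]))
  }
  expect_length(pairs, choose(8, 2))
})

test_that("the two dugong population references are distinguishable", {
  panel <- make_default_panel(seed = 1)
  lib <- library_from_panel(panel, include_populations = TRUE)
  d <- fingerprint_distance(
    lib_fingerprint(lib, "Dugong-AND", "UBC848"),
    lib_fingerprint(lib, "Dugong-GOT", "UBC848"), tolerance = 0.3)
  expect_gt(d, 0.25) # above the default uniqueness threshold
})
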