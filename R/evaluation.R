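#' Round half away from zero
#'
#' Presentation rounding for metric tables: 75.925 rounds to 75.93 at two
#' decimals (base `round()` uses round-half-even and would give 75.92).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' One-vs-rest confusion counts for a target species
#'
#' Queries assigned to the target count as positive predictions; any other
#' assignment, including `UNCLASSIFIED`, counts as negative. TP/FP/FN/TN
#' always partition the evaluated queries.
#'
#' @param assigned Character vector of assigned labels (may contain
#'   `"UNCLASSIFIED"`).
#' @param truth Character vector of true labels, aligned with `assigned`.
#' @param target Target species.
#' @return A `confusion_counts` object with fields `TP`, `FP`, `FN`, `TN`.
#' @export
one_vs_rest_confusion <- function(assigned, truth, target) {
  if (length(assigned) == 0) stop("no classification results to score")
  if (length(assigned) != length(truth)) {
    stop("assigned and truth must be aligned")
  }
  pos_pred <- assigned == target
  pos_true <- truth == target
  structure(list(TP = sum(pos_pred & pos_true),
                 FP = sum(pos_pred & !pos_true),
                 FN = sum(!pos_pred & pos_true),
                 TN = sum(!pos_pred & !pos_true)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d FP=%d FN=%d TN=%d\n",
              x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' Accuracy, precision, sensitivity and specificity from 2x2 counts
#'
#' accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP). A metric whose
#' denominator is zero is returned as `NA` (undefined), never coerced to 0.
#'
#' @param cc A `confusion_counts` (or list with TP/FP/FN/TN).
#' @return Named list of the four metrics as fractions in `[0, 1]`.
#' @export
compute_metrics <- function(cc) {
  n <- cc$TP + cc$FP + cc$FN + cc$TN
  if (n == 0) stop("empty confusion counts")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (cc$TP + cc$TN) / n,
       precision = frac(cc$TP, cc$TP + cc$FP),
       sensitivity = frac(cc$TP, cc$TP + cc$FN),
       specificity = frac(cc$TN, cc$TN + cc$FP))
}

METRIC_NAMES <- c("accuracy", "precision", "sensitivity", "specificity")

#' Per-primer / per-species metric tables with mean margins
#'
#' Takes a long data frame of metric values (percent scale) with columns
#' `primer`, `metric`, `species`, `value` and assembles the two standard
#' summary layouts: a per-primer table (rows primer x metric, one column
#' per species plus their arithmetic `Mean`) and a per-species table (the
#' mean of each metric over all primers). Means are computed on the
#' unrounded values; rounding is presentation-only (see
#' [format.metrics_table()]). `NA` cells are excluded from means and
#' flagged.
#'
#' @param values Long-format data frame (`primer`, `metric`, `species`,
#'   `value`).
#' @return A `metrics_table` with elements `per_primer`, `per_species`,
#'   `incomplete` (logical).
#' @export
metrics_table <- function(values) {
  stopifnot(all(c("primer", "metric", "species", "value") %in%
                  names(values)))
  primers <- unique(values$primer)
  species <- unique(values$species)
  metrics <- intersect(METRIC_NAMES, unique(values$metric))
  grid_n <- nrow(unique(values[c("primer", "metric", "species")]))
  incomplete <- grid_n < length(primers) * length(species) *
    length(metrics) || anyNA(values$value)
  lookup <- function(p, m, s) {
    v <- values$value[values$primer == p & values$metric == m &
                        values$species == s]
    if (length(v) == 0) NA_real_ else v[[1]]
  }
  per_primer <- do.call(rbind, lapply(primers, function(p) {
    do.call(rbind, lapply(metrics, function(m) {
      row <- vapply(species, function(s) lookup(p, m, s), numeric(1))
      out <- data.frame(primer = p, metric = m, t(row),
                        Mean = mean(row, na.rm = TRUE),
                        check.names = FALSE)
      names(out)[3:(2 + length(species))] <- species
      out
    }))
  }))
  per_species <- do.call(rbind, lapply(species, function(s) {
    row <- vapply(metrics, function(m) {
      cells <- vapply(primers, function(p) lookup(p, m, s), numeric(1))
      mean(cells, na.rm = TRUE)
    }, numeric(1))
    out <- data.frame(species = s, t(row), check.names = FALSE)
    names(out)[-1] <- metrics
    out
  }))
  rownames(per_primer) <- NULL
  rownames(per_species) <- NULL
  structure(list(per_primer = per_primer, per_species = per_species,
                 incomplete = incomplete),
            class = "metrics_table")
}

#' @export
format.metrics_table <- function(x, digits = 2, ...) {
  pp <- x$per_primer
  ps <- x$per_species
  num_pp <- vapply(pp, is.numeric, logical(1))
  pp[num_pp] <- lapply(pp[num_pp], round_half_up, digits = digits)
  num_ps <- vapply(ps, is.numeric, logical(1))
  ps[num_ps] <- lapply(ps[num_ps], round_half_up, digits = digits)
  list(per_primer = pp, per_species = ps)
}

#' @export
print.metrics_table <- function(x, ...) {
  f <- format(x)
  cat("Per-primer metrics (%):\n")
  print(f$per_primer, row.names = FALSE)
  cat("\nPer-species means over primers (%):\n")
  print(f$per_species, row.names = FALSE)
  if (x$incomplete) cat("\n(note: means over available cells only)\n")
  invisible(x)
}

#' Trial configuration for the end-to-end evaluation harness
#'
#' @param panel_seed Seed for [make_default_panel()] (or the panel itself
#'   via `panel`).
#' @param panel Optional pre-built [panel_spec()]; overrides `panel_seed`.
#' @param counts Query design, species -> individuals.
#' @param replicates_per_cell Reference replicates per cell.
#' @param tm_jitter_sd,noise_sd Noise model overrides (NULL = panel
#'   defaults).
#' @param primers Primers to evaluate (NULL = all panel primers).
#' @param config An [hrm_config()] used for extraction and matching.
#' @param query_seed Seed for the query draw.
#' @param primer_pairs Evaluate all pairwise primer combinations in the
#'   discrimination analysis as well.
#' @return A `trial_config`.
#' @export
trial_config <- function(panel_seed = 1L, panel = NULL,
                         counts = default_query_counts(),
                         replicates_per_cell = 3,
                         tm_jitter_sd = NULL, noise_sd = NULL,
                         primers = NULL, config = hrm_config(),
                         query_seed = panel_seed + 1000L,
                         primer_pairs = FALSE) {
  structure(list(panel_seed = as.integer(panel_seed), panel = panel,
                 counts = counts,
                 replicates_per_cell = replicates_per_cell,
                 tm_jitter_sd = tm_jitter_sd, noise_sd = noise_sd,
                 primers = primers, config = config,
                 query_seed = as.integer(query_seed),
                 primer_pairs = primer_pairs),
            class = "trial_config")
}

#' Run a blind classification trial end to end
#'
#' Simulates the full study: build the ground-truth panel, synthesize
#' jittered reference curves and consensus library, draw the labelled
#' query set, extract every fingerprint, classify each query with each
#' primer, and score one-vs-rest confusion metrics per (primer, species).
#' The classifier plays the role of the blinded human judges; truth labels
#' are only consulted at scoring time. Fully reproducible from the seeds
#' in the config.
#'
#' @param cfg A [trial_config()].
#' @return A `blind_trial` list: `results` (per query x primer assignment
#'   data frame), `metrics` (long data frame, percent scale), `table` (a
#'   [metrics_table()]), `per_primer_accuracy` (overall fraction of
#'   correct assignments per primer), `discrimination` (single primers,
#'   plus pairs if requested), `library`, and the config.
#' @export
run_blind_trial <- function(cfg = trial_config()) {
  panel <- if (is.null(cfg$panel)) make_default_panel(cfg$panel_seed) else
    cfg$panel
  primers <- if (is.null(cfg$primers)) panel$primers else cfg$primers
  conf <- cfg$config

  refs <- generate_reference_curves(
    panel, replicates_per_cell = cfg$replicates_per_cell,
    tm_jitter_sd = cfg$tm_jitter_sd, noise_sd = cfg$noise_sd,
    seed = panel$seed)
  ref_keep <- refs$meta$primer %in% primers
  ref_fps <- extract_fingerprints(
    new_curve_set(refs$curves[ref_keep], refs$meta[ref_keep, ],
                  refs$grid), conf)
  lib <- build_reference_library(ref_fps, refs$meta$species[ref_keep],
                                 tolerance = conf$tolerance)

  queries <- generate_query_set(panel, counts = cfg$counts,
                                tm_jitter_sd = cfg$tm_jitter_sd,
                                noise_sd = cfg$noise_sd,
                                seed = cfg$query_seed)
  q_keep <- queries$meta$primer %in% primers
  q_meta <- queries$meta[q_keep, ]
  q_fps <- extract_fingerprints(
    new_curve_set(queries$curves[q_keep], q_meta, queries$grid), conf)

  results <- do.call(rbind, lapply(seq_along(q_fps), function(k) {
    res <- classify_single_primer(q_fps[[k]], lib, q_meta$primer[k],
                                  tolerance = conf$tolerance,
                                  lambda = conf$lambda,
                                  reject_threshold = conf$reject_threshold)
    data.frame(id = q_meta$id[k], primer = q_meta$primer[k],
               truth = q_meta$species[k], assigned = res$label,
               distance = res$distance, margin = res$margin,
               stringsAsFactors = FALSE)
  }))

  target_species <- unique(q_meta$species)
  metrics_long <- do.call(rbind, lapply(primers, function(p) {
    sub <- results[results$primer == p, ]
    do.call(rbind, lapply(target_species, function(s) {
      cc <- one_vs_rest_confusion(sub$assigned, sub$truth, s)
      m <- compute_metrics(cc)
      data.frame(primer = p, metric = METRIC_NAMES, species = s,
                 value = 100 * unlist(m, use.names = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }))

  per_primer_accuracy <- vapply(primers, function(p) {
    sub <- results[results$primer == p, ]
    mean(sub$assigned == sub$truth)
  }, numeric(1))

  sets <- lapply(primers, identity)
  if (isTRUE(cfg$primer_pairs) && length(primers) >= 2) {
    sets <- c(sets, all_primer_pairs(primers))
  }
  disc <- discrimination_matrix(lib, sets,
                                uniqueness_threshold =
                                  conf$uniqueness_threshold,
                                tolerance = conf$tolerance,
                                lambda = conf$lambda)

  structure(list(config = cfg, library = lib, results = results,
                 metrics = metrics_long, table = metrics_table(metrics_long),
                 per_primer_accuracy = per_primer_accuracy,
                 discrimination = disc),
            class = "blind_trial")
}

#' @export
print.blind_trial <- function(x, ...) {
  cat(sprintf("<blind_trial> %d queries x %d primers\n",
              length(unique(x$results$id)),
              length(unique(x$results$primer))))
  cat("Per-primer assignment accuracy (%):\n")
  acc <- round_half_up(100 * x$per_primer_accuracy)
  for (p in names(acc)) cat(sprintf("  %s: %.2f\n", p, acc[[p]]))
  invisible(x)
}
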