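#' Build a consensus reference library from labelled fingerprints
#'
#' Replicate fingerprints of one (species, primer) cell are pooled and
#' their peaks grouped by tolerance linkage (sorted Tm values are split
#' wherever consecutive values are more than `tolerance` apart). Each group
#' present in at least `min_replicate_support` of the replicates
#' contributes one consensus peak at the median Tm; a replicate
#' contributing two peaks to one group counts once, assigned to the
#' nearest.
#'
#' @param fingerprints List of `melt_fingerprint` objects.
#' @param species Character vector of labels, one per fingerprint.
#' @param min_replicate_support Minimum fraction of replicates in which a
#'   peak group must occur (default 0.5).
#' @param tolerance Linkage tolerance, degC.
#' @return A `reference_library`.
#' @export
build_reference_library <- function(fingerprints, species,
                                    min_replicate_support = 0.5,
                                    tolerance = 0.3) {
  stopifnot(length(fingerprints) == length(species))
  primers <- vapply(fingerprints, function(f) f$primer, character(1))
  if (anyNA(primers)) stop("every fingerprint needs a primer label")
  consensus <- list()
  cells <- unique(data.frame(species = species, primer = primers,
                             stringsAsFactors = FALSE))
  for (r in seq_len(nrow(cells))) {
    sp <- cells$species[r]
    pr <- cells$primer[r]
    idx <- which(species == sp & primers == pr)
    reps <- fingerprints[idx]
    n_rep <- length(reps)
    tm <- unlist(lapply(reps, function(f) f$peaks$tm))
    rep_id <- rep(seq_len(n_rep),
                  vapply(reps, function(f) nrow(f$peaks), integer(1)))
    ht <- unlist(lapply(reps, function(f) f$peaks$height))
    if (length(tm) == 0) {
      stop(sprintf("no peaks observed for (%s, %s)", sp, pr))
    }
    o <- order(tm)
    tm <- tm[o]; rep_id <- rep_id[o]; ht <- ht[o]
    grp <- cumsum(c(1, as.integer(diff(tm) > tolerance)))
    peaks <- do.call(rbind, lapply(split(seq_along(tm), grp), function(ix) {
      support <- length(unique(rep_id[ix])) / n_rep
      data.frame(tm = stats::median(tm[ix]),
                 height = stats::median(ht[ix]),
                 support = support)
    }))
    peaks <- peaks[peaks$support >= min_replicate_support - 1e-9, ,
                   drop = FALSE]
    if (nrow(peaks) == 0) {
      stop(sprintf("all peaks of (%s, %s) fall below replicate support",
                   sp, pr))
    }
    fp <- melt_fingerprint_new(
      data.frame(tm = peaks$tm, height = peaks$height,
                 prominence = peaks$height, width = NA_real_),
      pr, sprintf("%s|%s", sp, pr))
    consensus[[sprintf("%s|%s", sp, pr)]] <- fp
  }
  structure(
    list(species = unique(cells$species), primers = unique(cells$primer),
         fingerprints = consensus,
         meta = list(tolerance = tolerance,
                     min_replicate_support = min_replicate_support,
                     built = format(Sys.time(), "%Y-%m-%d"))),
    class = "reference_library"
  )
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("<reference_library> %d species x %d primers (%d entries)\n",
              length(x$species), length(x$primers),
              length(x$fingerprints)))
  invisible(x)
}

#' Look up one consensus fingerprint
#' @param lib A `reference_library`.
#' @param species,primer Cell to fetch.
#' @return A `melt_fingerprint`, or error if absent.
#' @export
lib_fingerprint <- function(lib, species, primer) {
  fp <- lib$fingerprints[[paste(species, primer, sep = "|")]]
  if (is.null(fp)) {
    stop(sprintf("library has no entry for (%s, %s)", species, primer))
  }
  fp
}

#' Build a reference library directly from a panel's true transitions
#'
#' Shortcut for tests and simulations: the consensus fingerprint of every
#' cell is the panel's planted Tm list (reference population for species
#' with population variants, unless `include_populations`).
#'
#' @param panel A [panel_spec()].
#' @param include_populations Label population variants separately.
#' @return A `reference_library`.
#' @export
library_from_panel <- function(panel, include_populations = FALSE) {
  fps <- list()
  labels <- character(0)
  for (sp in panel$species) {
    pops <- panel$populations[[sp]]
    pop_list <- if (is.null(pops)) list(NULL) else
      if (include_populations) as.list(pops) else list(pops[[1]])
    for (pop in pop_list) {
      label <- if (is.null(pop) || !include_populations) sp else
        paste(sp, pop, sep = "-")
      for (pr in panel$primers) {
        trs <- panel_cell(panel, sp, pr, population = pop)
        fps[[length(fps) + 1]] <- melt_fingerprint(
          transition_tms(trs), primer = pr, id = label)
        labels <- c(labels, label)
      }
    }
  }
  build_reference_library(fps, labels, min_replicate_support = 0,
                          tolerance = 0.3)
}

#' Align two peak lists under a Tm tolerance
#'
#' Finds, among all monotone one-to-one matchings whose every pair lies
#' within `tolerance` degC, one that maximizes the number of matched pairs
#' and, among those, minimizes the total absolute Tm discrepancy. Solved by
#' dynamic programming over the two sorted lists; matches never cross,
#' respecting the temperature ordering of melt peaks.
#'
#' @param a,b `melt_fingerprint` objects or numeric Tm vectors (sorted).
#' @param tolerance Maximum |Tm difference| of a matched pair, degC.
#' @return A `peak_matching`: `pairs` (two-column index matrix into a and
#'   b), `unmatched_a`, `unmatched_b`, and `cost` (sum of |dTm| over
#'   matched pairs).
#' @export
align_peak_lists <- function(a, b, tolerance = 0.3) {
  ta <- fingerprint_tms(a)
  tb <- fingerprint_tms(b)
  m <- length(ta)
  n <- length(tb)
  # dp value: matches * BIG - cost, maximized
  BIG <- 1e6
  score <- matrix(0, m + 1, n + 1)
  move <- matrix(0L, m + 1, n + 1) # 1 = skip a, 2 = skip b, 3 = match
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      best <- score[i, j + 1]
      mv <- 1L
      if (score[i + 1, j] > best) {
        best <- score[i + 1, j]
        mv <- 2L
      }
      d <- abs(ta[i] - tb[j])
      if (d <= tolerance + 1e-12) {
        cand <- score[i, j] + BIG - d
        if (cand > best) {
          best <- cand
          mv <- 3L
        }
      }
      score[i + 1, j + 1] <- best
      move[i + 1, j + 1] <- mv
    }
  }
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  i <- m; j <- n
  while (i > 0 && j > 0) {
    mv <- move[i + 1, j + 1]
    if (mv == 3L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (mv == 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  cost <- if (nrow(pairs) > 0) sum(abs(ta[pairs[, 1]] - tb[pairs[, 2]])) else 0
  structure(list(pairs = pairs,
                 unmatched_a = setdiff(seq_len(m), pairs[, 1]),
                 unmatched_b = setdiff(seq_len(n), pairs[, 2]),
                 cost = cost, tolerance = tolerance),
            class = "peak_matching")
}

#' Distance between two melting fingerprints
#'
#' With matching `M` from [align_peak_lists()] and `u` total unmatched
#' peaks on both sides,
#' `d = (sum_M |dTm| / tolerance + lambda * u) / (|M| + u)`.
#' The distance is symmetric, lies in `[0, max(1, lambda)]` (each matched
#' pair contributes at most 1 after tolerance scaling, each unmatched peak
#' exactly `lambda`; with the default `lambda = 1` the range is `[0, 1]`),
#' and is 0 exactly when the two peak sets coincide.
#'
#' @param a,b `melt_fingerprint` objects or numeric Tm vectors.
#' @param tolerance Matching tolerance, degC.
#' @param lambda Penalty per unmatched peak.
#' @return Scalar distance.
#' @export
fingerprint_distance <- function(a, b, tolerance = 0.3, lambda = 1) {
  ta <- fingerprint_tms(a)
  tb <- fingerprint_tms(b)
  if (length(ta) == 0 && length(tb) == 0) stop("invalid fingerprints")
  al <- align_peak_lists(ta, tb, tolerance)
  n_match <- nrow(al$pairs)
  u <- length(al$unmatched_a) + length(al$unmatched_b)
  (al$cost / tolerance + lambda * u) / (n_match + u)
}

classification_result <- function(query_id, primer_set, label, distance,
                                  margin, distances, tie = FALSE,
                                  reason = NA_character_) {
  structure(list(query_id = query_id, primer_set = primer_set,
                 label = label, distance = distance, margin = margin,
                 distances = distances, tie = tie, reason = reason),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s [%s] -> %s (d=%.3f, margin=%.3f)%s\n",
              x$query_id, paste(x$primer_set, collapse = "+"), x$label,
              x$distance, x$margin, if (x$tie) " TIE" else ""))
  invisible(x)
}

assign_from_distances <- function(query_id, primer_set, d, reject_threshold) {
  o <- order(d, names(d)) # lexicographic species order breaks ties
  best <- unname(d[o[1]])
  margin <- if (length(d) > 1) unname(d[o[2]]) - best else Inf
  tie <- length(d) > 1 && abs(d[o[2]] - best) < 1e-12
  if (best > reject_threshold) {
    classification_result(query_id, primer_set, "UNCLASSIFIED", best,
                          margin, d, tie,
                          reason = "best distance above reject threshold")
  } else {
    classification_result(query_id, primer_set, names(d)[o[1]], best,
                          margin, d, tie)
  }
}

#' Classify a query fingerprint with a single primer
#'
#' Assigns the species whose reference fingerprint minimizes
#' [fingerprint_distance()]; queries whose best distance exceeds
#' `reject_threshold`, or whose fingerprint is invalid (no peaks), are
#' returned as `UNCLASSIFIED`. Distance ties are broken by lexicographic
#' species order and flagged.
#'
#' @param query A `melt_fingerprint`.
#' @param lib A `reference_library`.
#' @param primer Primer to use (must be in the library).
#' @param tolerance,lambda Distance parameters.
#' @param reject_threshold Rejection cut-off on the distance.
#' @return A `classification_result`.
#' @export
classify_single_primer <- function(query, lib, primer, tolerance = 0.3,
                                   lambda = 1, reject_threshold = 0.5) {
  if (!primer %in% lib$primers) stop("primer not in library: ", primer)
  if (!query$valid || nrow(query$peaks) == 0) {
    return(classification_result(query$id, primer, "UNCLASSIFIED", NA_real_,
                                 NA_real_, numeric(0),
                                 reason = "invalid query fingerprint"))
  }
  sp_avail <- lib$species[vapply(lib$species, function(s) {
    !is.null(lib$fingerprints[[paste(s, primer, sep = "|")]])
  }, logical(1))]
  d <- vapply(sp_avail, function(s) {
    fingerprint_distance(query, lib_fingerprint(lib, s, primer),
                         tolerance, lambda)
  }, numeric(1))
  assign_from_distances(query$id, primer, d, reject_threshold)
}

#' Classify a query with a primer combination
#'
#' The combined score of a candidate species is the mean of its per-primer
#' fingerprint distances (mean, not sum, so the rejection threshold is
#' scale-free in the number of primers); assignment and rejection then
#' follow the single-primer rule.
#'
#' @param queries Named list, primer -> `melt_fingerprint`, covering every
#'   primer in `primer_set`.
#' @param lib A `reference_library`.
#' @param primer_set Character vector of primers to combine.
#' @param tolerance,lambda,reject_threshold As in
#'   [classify_single_primer()].
#' @return A `classification_result` with per-primer distances attached.
#' @export
classify_combined <- function(queries, lib, primer_set, tolerance = 0.3,
                              lambda = 1, reject_threshold = 0.5) {
  missing <- setdiff(primer_set, names(queries))
  if (length(missing) > 0) {
    stop("no query fingerprint for primer(s): ",
         paste(missing, collapse = ", "))
  }
  valid <- vapply(primer_set, function(p) {
    q <- queries[[p]]
    q$valid && nrow(q$peaks) > 0
  }, logical(1))
  qid <- queries[[primer_set[[1]]]]$id
  if (!any(valid)) {
    return(classification_result(qid, primer_set, "UNCLASSIFIED", NA_real_,
                                 NA_real_, numeric(0),
                                 reason = "invalid query fingerprint"))
  }
  used <- primer_set[valid]
  per_primer <- lapply(used, function(p) {
    sp_avail <- lib$species[vapply(lib$species, function(s) {
      !is.null(lib$fingerprints[[paste(s, p, sep = "|")]])
    }, logical(1))]
    vapply(sp_avail, function(s) {
      fingerprint_distance(queries[[p]], lib_fingerprint(lib, s, p),
                           tolerance, lambda)
    }, numeric(1))
  })
  common <- Reduce(intersect, lapply(per_primer, names))
  d <- colMeans(do.call(rbind, lapply(per_primer, function(v) v[common])))
  res <- assign_from_distances(qid, used, d, reject_threshold)
  res$per_primer <- stats::setNames(per_primer, used)
  res
}

#' All pairwise combinations of a primer set
#' @param primers Character vector.
#' @return List of length `choose(n, 2)` of primer pairs.
#' @export
all_primer_pairs <- function(primers = default_primers()) {
  cmb <- utils::combn(primers, 2)
  lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
}

#' Species discrimination matrices for primer sets
#'
#' A species pair (s, t) is distinguishable under a primer set P when at
#' least one primer in P separates their reference fingerprints by more
#' than `uniqueness_threshold` in [fingerprint_distance()]. Two summary
#' rates are reported per set: the per-species success rate (percentage of
#' species distinguishable from every other species) and the per-pair rate
#' (percentage of distinguishable pairs).
#'
#' @param lib A `reference_library`, complete for the primers used.
#' @param primer_sets List of character vectors (single primers and/or
#'   combinations).
#' @param uniqueness_threshold Distance above which two references are
#'   considered distinct.
#' @param tolerance,lambda Distance parameters.
#' @return List of `discrimination_matrix` objects (fields `primer_set`,
#'   `distinguishable` logical matrix, `success_rate`, `pair_rate`).
#' @export
discrimination_matrix <- function(lib, primer_sets,
                                  uniqueness_threshold = 0.25,
                                  tolerance = 0.3, lambda = 1) {
  if (!is.list(primer_sets)) primer_sets <- list(primer_sets)
  sp <- lib$species
  k <- length(sp)
  lapply(primer_sets, function(pset) {
    missing <- setdiff(pset, lib$primers)
    if (length(missing) > 0) {
      stop("library lacks primer(s): ", paste(missing, collapse = ", "))
    }
    dist_ok <- matrix(FALSE, k, k, dimnames = list(sp, sp))
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        sep <- any(vapply(pset, function(p) {
          fingerprint_distance(lib_fingerprint(lib, sp[i], p),
                               lib_fingerprint(lib, sp[j], p),
                               tolerance, lambda) >
            uniqueness_threshold
        }, logical(1)))
        dist_ok[i, j] <- sep
        dist_ok[j, i] <- sep
      }
    }
    diag(dist_ok) <- NA
    full <- vapply(seq_len(k), function(i) all(dist_ok[i, -i]), logical(1))
    structure(
      list(primer_set = pset, distinguishable = dist_ok,
           success_rate = 100 * mean(full),
           pair_rate = 100 * mean(dist_ok[upper.tri(dist_ok)])),
      class = "discrimination_matrix")
  })
}

#' @export
print.discrimination_matrix <- function(x, ...) {
  cat(sprintf("<discrimination> [%s] species success %.1f%%, pairs %.1f%%\n",
              paste(x$primer_set, collapse = "+"), x$success_rate,
              x$pair_rate))
  invisible(x)
}
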