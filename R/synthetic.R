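#' Melt transition specification
#'
#' One duplex population melting at `tm`. The fluorescence drop across the
#' transition is modelled as a logistic sigmoid of the given amplitude and
#' width (the standard two-state melt approximation), which gives the
#' derivative curve a peak of height `amplitude / (4 * width)` at `tm`.
#'
#' @param tm Melting temperature, degC.
#' @param amplitude Fluorescence drop across the transition, a.u. (> 0).
#' @param width Transition width parameter, degC (> 0).
#' @return A `transition` object.
#' @export
transition <- function(tm, amplitude = 1, width = 0.2) {
  stopifnot(is.numeric(tm), length(tm) == 1)
  if (amplitude <= 0) stop("transition amplitude must be positive")
  if (width <= 0) stop("transition width must be positive")
  structure(list(tm = tm, amplitude = amplitude, width = width),
            class = "transition")
}

transition_tms <- function(transitions) {
  vapply(transitions, function(tr) tr$tm, numeric(1))
}

# Minimum pairwise Tm separation within one fingerprint cell, degC.
MIN_CELL_SEPARATION <- 0.8

validate_cell <- function(transitions, grid, label = "cell") {
  if (length(transitions) < 1 || length(transitions) > 8) {
    stop(sprintf("%s must contain 1-8 transitions", label))
  }
  tms <- sort(transition_tms(transitions))
  if (any(tms <= grid$start | tms >= grid$stop)) {
    stop(sprintf("%s has a tm outside the temperature grid", label))
  }
  if (length(tms) > 1 && min(diff(tms)) < MIN_CELL_SEPARATION - 1e-9) {
    stop(sprintf("%s has tm separations below %.1f degC",
                 label, MIN_CELL_SEPARATION))
  }
  widths <- vapply(transitions, function(tr) tr$width, numeric(1))
  if (any(widths < grid$step)) {
    stop(sprintf("%s has a transition width below the grid step", label))
  }
  invisible(TRUE)
}

cell_key <- function(species, primer, population = NULL) {
  label <- if (is.null(population)) species else paste(species, population,
                                                       sep = "-")
  paste(label, primer, sep = "|")
}

#' Ground-truth melt panel specification
#'
#' A panel holds, for every (species, primer) cell, the list of true melt
#' transitions plus the noise model used when synthesizing curves. Species
#' with several geographic populations (e.g. the two dugong stocks) may
#' carry population-specific cells; the first listed population is the
#' reference variant used by default.
#'
#' @param species Character vector of species labels.
#' @param primers Character vector of primer labels.
#' @param transitions Named list keyed `"<species>|<primer>"` (or
#'   `"<species>-<population>|<primer>"`), each element a list of
#'   [transition()] objects.
#' @param populations Named list mapping a species to its population tags.
#' @param population_offsets Named list keyed like `transitions`, recording
#'   per-peak degC shifts of a population cell relative to the reference
#'   population (metadata; the shifted transitions are stored explicitly).
#' @param tm_jitter_sd Between-replicate Tm jitter SD, degC.
#' @param amplitude_jitter_cv Coefficient of variation of peak amplitudes
#'   between replicates.
#' @param noise_sd Additive instrument noise SD, a.u.
#' @param baseline_pre_level Pre-melt plateau, a.u.
#' @param baseline_post_level Post-melt plateau, a.u.
#' @param baseline_slope Linear drift, a.u. per degC.
#' @param grid A [temp_grid()].
#' @param seed Master seed recorded with the panel.
#' @return A `panel_spec` object.
#' @seealso [make_default_panel()] for the bundled 16-species marine-mammal
#'   panel.
#' @export
panel_spec <- function(species, primers, transitions,
                       populations = list(),
                       population_offsets = list(),
                       tm_jitter_sd = 0.1,
                       amplitude_jitter_cv = 0.05,
                       noise_sd = 0.2,
                       baseline_pre_level = 100,
                       baseline_post_level = 5,
                       baseline_slope = -0.05,
                       grid = temp_grid(),
                       seed = 1L) {
  stopifnot(is.character(species), is.character(primers))
  if (anyDuplicated(species)) stop("duplicate species labels")
  if (anyDuplicated(primers)) stop("duplicate primer labels")
  if (tm_jitter_sd < 0 || amplitude_jitter_cv < 0 || noise_sd < 0) {
    stop("jitter and noise parameters must be non-negative")
  }
  expected <- unlist(lapply(species, function(sp) {
    pops <- populations[[sp]]
    labels <- if (is.null(pops)) sp else paste(sp, pops, sep = "-")
    as.vector(outer(labels, primers, paste, sep = "|"))
  }))
  missing <- setdiff(expected, names(transitions))
  if (length(missing) > 0) {
    stop("transitions missing for cells: ", paste(missing, collapse = ", "))
  }
  for (key in names(transitions)) {
    validate_cell(transitions[[key]], grid, label = key)
  }
  structure(
    list(species = species, primers = primers, transitions = transitions,
         populations = populations, population_offsets = population_offsets,
         tm_jitter_sd = tm_jitter_sd,
         amplitude_jitter_cv = amplitude_jitter_cv, noise_sd = noise_sd,
         baseline_pre_level = baseline_pre_level,
         baseline_post_level = baseline_post_level,
         baseline_slope = baseline_slope, grid = grid,
         seed = as.integer(seed)),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> %d species x %d primers, seed %d\n",
              length(x$species), length(x$primers), x$seed))
  invisible(x)
}

#' Look up the true transitions of one panel cell
#'
#' @param panel A [panel_spec()].
#' @param species Species label.
#' @param primer Primer label.
#' @param population Population tag; defaults to the species' first listed
#'   population (or none).
#' @return List of [transition()] objects.
#' @export
panel_cell <- function(panel, species, primer, population = NULL) {
  if (!species %in% panel$species) stop("unknown species: ", species)
  if (!primer %in% panel$primers) stop("unknown primer: ", primer)
  pops <- panel$populations[[species]]
  if (is.null(population) && !is.null(pops)) population <- pops[[1]]
  if (!is.null(population) && is.null(pops)) {
    stop(species, " has no population variants")
  }
  panel$transitions[[cell_key(species, primer, population)]]
}

#' Default species labels of the marine-mammal study panel
#' @return Character vector of 16 species labels.
#' @export
default_species <- function() {
  c("Spinner dolphin", "Striped dolphin", "Pantropical spotted dolphin",
    "Indo-Pacific bottlenose dolphin", "Dugong", "False killer whale",
    "Rough-toothed dolphin", "Fraser's dolphin", "Risso's dolphin",
    "Dwarf sperm whale", "Indo-Pacific finless porpoise",
    "Long-beaked common dolphin", "Indo-Pacific humpback dolphin",
    "Pygmy sperm whale", "Cuvier's beaked whale", "Short-finned pilot whale")
}

#' Default ISSR primer labels
#' @return Character vector of 8 UBC primer names (used as labels only).
#' @export
default_primers <- function() {
  c("UBC812", "UBC817", "UBC818", "UBC826", "UBC827",
    "UBC847", "UBC848", "UBC880")
}

#' Default query design: individuals per reference species
#'
#' The five species with deep sampling serve as query material: 31 spinner,
#' 30 striped, 28 pantropical spotted, 27 bottlenose and 24 dugong
#' individuals, 140 in total.
#'
#' @return Named integer vector of counts.
#' @export
default_query_counts <- function() {
  c("Spinner dolphin" = 31L, "Striped dolphin" = 30L,
    "Pantropical spotted dolphin" = 28L,
    "Indo-Pacific bottlenose dolphin" = 27L, "Dugong" = 24L)
}

# Equal-amplitude transition list summing to the panel's melt range.
make_cell <- function(tms, total_amplitude = 95, width = 0.2) {
  lapply(tms, transition, amplitude = total_amplitude / length(tms),
         width = width)
}

# Rejection-sample k peak temperatures in [75, 90]. The default spacing
# floor of 1.0 degC keeps every planted pair resolvable by the default
# extraction settings; 0.8 degC is only the hard validity floor.
random_cell_tms <- function(k, min_sep = 1.0) {
  repeat {
    tms <- sort(stats::runif(k, 75, 90))
    if (k == 1 || min(diff(tms)) >= min_sep) return(tms)
  }
}

#' Build the default 16-species x 8-primer ground-truth panel
#'
#' Cells whose melting-peak temperatures are known for the marine-mammal
#' panel are fixed: bottlenose and striped dolphin under UBC812
#' (80.0/81.9/86.1/88.0 and 79.9/82.1/86.1/88.0 degC), the two Kogia
#' species under UBC826 (second/third peaks 80.6/82.6 vs 80.3/82.4 plus a
#' fourth pygmy peak at 87.2; the unreported first peak is a synthetic
#' shared 78.0), and the two dugong populations under UBC848 (Andaman Sea:
#' 79.9/82.6/87.7; Gulf of Thailand: 80.5/82.6). Every other cell is filled
#' with 2-5 random transitions in [75, 90] degC at >= 0.8 degC spacing,
#' deterministically from `seed` via per-cell sub-seeds. Dugong cells for
#' the remaining primers carry small synthetic population offsets for the
#' Gulf-of-Thailand stock (+0.1 degC on all peaks for UBC812/818/827,
#' +0.3 degC on the first two peaks for UBC817/826).
#'
#' @param seed Master seed.
#' @return A [panel_spec()].
#' @examples
#' panel <- make_default_panel(seed = 1)
#' transition_tms(panel_cell(panel, "Indo-Pacific bottlenose dolphin", "UBC812"))
#' @export
make_default_panel <- function(seed = 1L) {
  species <- default_species()
  primers <- default_primers()
  populations <- list("Dugong" = c("AND", "GOT"))
  fixed <- list(
    "Indo-Pacific bottlenose dolphin|UBC812" = c(80.0, 81.9, 86.1, 88.0),
    "Striped dolphin|UBC812"                 = c(79.9, 82.1, 86.1, 88.0),
    "Dwarf sperm whale|UBC826"               = c(78.0, 80.6, 82.6),
    "Pygmy sperm whale|UBC826"               = c(78.0, 80.3, 82.4, 87.2),
    "Dugong-AND|UBC848"                      = c(79.9, 82.6, 87.7),
    "Dugong-GOT|UBC848"                      = c(80.5, 82.6)
  )
  # Gulf-of-Thailand offsets relative to the Andaman reference cells.
  got_offsets <- list(
    UBC812 = function(k) rep(0.1, k),
    UBC818 = function(k) rep(0.1, k),
    UBC827 = function(k) rep(0.1, k),
    UBC817 = function(k) c(rep(0.3, min(2, k)), rep(0, max(0, k - 2))),
    UBC826 = function(k) c(rep(0.3, min(2, k)), rep(0, max(0, k - 2)))
  )
  transitions <- list()
  offsets_meta <- list()
  for (sp in species) {
    pops <- populations[[sp]]
    for (pr in primers) {
      base_key <- cell_key(sp, pr, if (is.null(pops)) NULL else pops[[1]])
      plain_key <- cell_key(sp, pr)
      if (!is.null(fixed[[base_key]])) {
        tms <- fixed[[base_key]]
      } else if (!is.null(fixed[[plain_key]])) {
        tms <- fixed[[plain_key]]
      } else {
        # population-offset cells get extra headroom so a +0.3 degC shift
        # of the first peaks cannot squeeze a separation below the floor
        min_sep <- if (is.null(pops)) 1.0 else 1.3
        tms <- with_seed(derive_seed(seed, sp, pr), {
          k <- sample(2:5, 1)
          random_cell_tms(k, min_sep)
        })
      }
      transitions[[base_key]] <- make_cell(tms)
      if (!is.null(pops)) {
        for (pop in pops[-1]) {
          key <- cell_key(sp, pr, pop)
          if (!is.null(fixed[[key]])) {
            transitions[[key]] <- make_cell(fixed[[key]])
          } else {
            off_fn <- got_offsets[[pr]]
            off <- if (is.null(off_fn)) rep(0, length(tms)) else
              off_fn(length(tms))
            transitions[[key]] <- make_cell(tms + off)
            offsets_meta[[key]] <- off
          }
        }
      }
    }
  }
  panel_spec(species = species, primers = primers, transitions = transitions,
             populations = populations, population_offsets = offsets_meta,
             seed = seed)
}

#' Synthesize one raw melt curve
#'
#' Fluorescence is a descending staircase of logistic transitions on a
#' linear baseline:
#' `F(T) = post + slope * (T - start) + sum_i a_i * plogis((tm_i - T) / w_i)`
#' plus optional i.i.d. Gaussian noise. With zero noise the curve is
#' non-increasing up to the baseline drift and fully reproducible from its
#' parameters.
#'
#' @param transitions List of [transition()] objects (may be empty).
#' @param grid A [temp_grid()].
#' @param noise_sd Additive Gaussian noise SD, a.u.
#' @param baseline_post Post-melt plateau, a.u.
#' @param baseline_slope Baseline drift, a.u. per degC.
#' @param seed Seed for the noise draw; required when `noise_sd > 0` for
#'   reproducibility, ignored otherwise.
#' @param id Curve identifier.
#' @param primer Primer label carried with the curve.
#' @return A `melt_curve` object.
#' @examples
#' mc <- simulate_melt_curve(list(transition(80, 95, 0.4)), temp_grid())
#' @export
simulate_melt_curve <- function(transitions, grid = temp_grid(),
                                noise_sd = 0, baseline_post = 5,
                                baseline_slope = -0.05, seed = NULL,
                                id = "curve", primer = NA_character_) {
  if (length(transitions) > 0) {
    tms <- transition_tms(transitions)
    if (any(tms <= grid$start | tms >= grid$stop)) {
      stop("transition tm outside the temperature grid")
    }
  }
  temps <- grid$temps
  f <- baseline_post + baseline_slope * (temps - grid$start)
  for (tr in transitions) {
    f <- f + tr$amplitude * stats::plogis((tr$tm - temps) / tr$width)
  }
  if (noise_sd > 0) {
    eps <- if (is.null(seed)) stats::rnorm(length(temps), 0, noise_sd) else
      with_seed(seed, stats::rnorm(length(temps), 0, noise_sd))
    f <- f + eps
  }
  melt_curve(id = id, primer = primer, temperatures = temps,
             fluorescence = f)
}

# Jitter a cell's transitions for one synthetic replicate: independent
# Normal(0, tm_jitter_sd) per peak plus multiplicative amplitude noise.
jitter_transitions <- function(transitions, tm_jitter_sd, amplitude_cv) {
  lapply(transitions, function(tr) {
    tm <- tr$tm + stats::rnorm(1, 0, tm_jitter_sd)
    amp <- tr$amplitude * max(0.05, 1 + stats::rnorm(1, 0, amplitude_cv))
    transition(tm, amp, tr$width)
  })
}

new_curve_set <- function(curves, meta, grid) {
  rownames(meta) <- NULL
  structure(list(curves = curves, meta = meta, grid = grid),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %d curves, %d species, %d primers\n",
              length(x$curves), length(unique(x$meta$species)),
              length(unique(x$meta$primer))))
  invisible(x)
}

#' @export
length.curve_set <- function(x) length(x$curves)

#' Simulate reference curves for every panel cell
#'
#' Generates `replicates_per_cell` melt curves per (species, primer) cell,
#' each with independent per-peak Tm jitter and instrument noise, to play
#' the role of the archived reference runs of each species.
#'
#' @param panel A [panel_spec()].
#' @param replicates_per_cell Replicates per cell (>= 1).
#' @param tm_jitter_sd,noise_sd Override the panel's noise model.
#' @param include_populations If `TRUE`, species with population variants
#'   contribute one labelled curve set per population
#'   (`"<species>-<pop>"`); otherwise only the reference population is used
#'   and curves carry the plain species label.
#' @param seed Seed; defaults to the panel seed.
#' @return A `curve_set`: list of curves plus a metadata data frame with
#'   columns `id`, `species`, `population`, `primer`, `replicate`.
#' @export
generate_reference_curves <- function(panel, replicates_per_cell = 3,
                                      tm_jitter_sd = NULL, noise_sd = NULL,
                                      include_populations = FALSE,
                                      seed = panel$seed) {
  if (replicates_per_cell < 1) stop("replicates_per_cell must be >= 1")
  if (is.null(tm_jitter_sd)) tm_jitter_sd <- panel$tm_jitter_sd
  if (is.null(noise_sd)) noise_sd <- panel$noise_sd
  curves <- list()
  meta <- list()
  for (sp in panel$species) {
    pops <- panel$populations[[sp]]
    pop_list <- if (is.null(pops)) list(NULL) else
      if (include_populations) as.list(pops) else list(pops[[1]])
    for (pop in pop_list) {
      label <- if (is.null(pop) || !include_populations) sp else
        paste(sp, pop, sep = "-")
      for (pr in panel$primers) {
        trs <- panel_cell(panel, sp, pr, population = pop)
        for (rep_i in seq_len(replicates_per_cell)) {
          sub <- derive_seed(seed, "ref", label, pr, rep_i)
          jit <- with_seed(sub, jitter_transitions(
            trs, tm_jitter_sd, panel$amplitude_jitter_cv))
          cid <- sprintf("REF_%s_%s_r%d", gsub("[ |]", "_", label), pr, rep_i)
          curves[[length(curves) + 1]] <- simulate_melt_curve(
            jit, panel$grid, noise_sd = noise_sd,
            baseline_post = panel$baseline_post_level,
            baseline_slope = panel$baseline_slope,
            seed = sub + 1, id = cid, primer = pr)
          meta[[length(meta) + 1]] <- data.frame(
            id = cid, species = label,
            population = if (is.null(pop)) NA_character_ else pop,
            primer = pr, replicate = rep_i, stringsAsFactors = FALSE)
        }
      }
    }
  }
  new_curve_set(curves, do.call(rbind, meta), panel$grid)
}

#' Simulate a labelled query set
#'
#' Draws `counts[s]` individuals per species and synthesizes one melt curve
#' per individual per primer, with independent per-reaction Tm jitter and
#' noise. The default design is the 140-individual study layout returned by
#' [default_query_counts()].
#'
#' @param panel A [panel_spec()].
#' @param counts Named integer vector, species -> number of individuals;
#'   names must be panel species.
#' @param tm_jitter_sd,noise_sd Override the panel's noise model.
#' @param seed Seed for all jitter/noise draws.
#' @return A `curve_set`; `meta$id` identifies the individual so that the
#'   8 per-primer curves of one individual share an id.
#' @export
generate_query_set <- function(panel, counts = default_query_counts(),
                               tm_jitter_sd = NULL, noise_sd = NULL,
                               seed = panel$seed + 1L) {
  if (any(counts < 0)) stop("negative query count")
  unknown <- setdiff(names(counts), panel$species)
  if (length(unknown) > 0) {
    stop("counts name species absent from the panel: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(tm_jitter_sd)) tm_jitter_sd <- panel$tm_jitter_sd
  if (is.null(noise_sd)) noise_sd <- panel$noise_sd
  curves <- list()
  meta <- list()
  q <- 0
  for (sp in names(counts)) {
    pops <- panel$populations[[sp]]
    pop <- if (is.null(pops)) NULL else pops[[1]]
    for (i in seq_len(counts[[sp]])) {
      q <- q + 1
      qid <- sprintf("Q%03d", q)
      for (pr in panel$primers) {
        trs <- panel_cell(panel, sp, pr, population = pop)
        sub <- derive_seed(seed, "query", sp, i, pr)
        jit <- with_seed(sub, jitter_transitions(
          trs, tm_jitter_sd, panel$amplitude_jitter_cv))
        curves[[length(curves) + 1]] <- simulate_melt_curve(
          jit, panel$grid, noise_sd = noise_sd,
          baseline_post = panel$baseline_post_level,
          baseline_slope = panel$baseline_slope,
          seed = sub + 1, id = qid, primer = pr)
        meta[[length(meta) + 1]] <- data.frame(
          id = qid, species = sp,
          population = if (is.null(pop)) NA_character_ else pop,
          primer = pr, replicate = 1L, stringsAsFactors = FALSE)
      }
    }
  }
  new_curve_set(curves, do.call(rbind, meta), panel$grid)
}
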