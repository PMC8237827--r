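#' Write melt curves to a plate-export CSV
#'
#' Two dialects are supported. `long`: columns `well`, `primer`,
#' `temperature_C`, `fluorescence`. `wide`: first column `temperature_C`,
#' then one column per well named `"<well>|<primer>"`. Temperatures are
#' serialized with up to 4 decimals; all wells share one grid.
#'
#' @param cs A `curve_set`.
#' @param path Output file.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_melt_curves <- function(cs, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  wells <- vapply(seq_along(cs$curves), function(k) {
    sprintf("%s.%s", cs$curves[[k]]$id, cs$curves[[k]]$primer)
  }, character(1))
  if (anyDuplicated(wells)) stop("duplicate (id, primer) wells")
  temps <- round(cs$curves[[1]]$temperatures, 4)
  if (dialect == "long") {
    df <- do.call(rbind, lapply(seq_along(cs$curves), function(k) {
      cv <- cs$curves[[k]]
      data.frame(well = wells[k], primer = cv$primer,
                 temperature_C = round(cv$temperatures, 4),
                 fluorescence = cv$fluorescence)
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    df <- data.frame(temperature_C = temps, check.names = FALSE)
    for (k in seq_along(cs$curves)) {
      df[[paste(wells[k], cs$curves[[k]]$primer, sep = "|")]] <-
        cs$curves[[k]]$fluorescence
    }
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

parse_num <- function(x, what, rows) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v) & !is.na(x))
  if (length(bad) > 0 || anyNA(x)) {
    row <- if (length(bad) > 0) rows[bad[1]] else rows[which(is.na(x))[1]]
    stop(sprintf("non-numeric %s at data row %d", what, row))
  }
  v
}

#' Read melt curves from a plate-export CSV
#'
#' @param path CSV file in one of the dialects of [write_melt_curves()].
#' @param dialect `"auto"` (sniff from the header), `"long"` or `"wide"`.
#' @return A `curve_set`. All wells must share one temperature grid; a
#'   ragged grid is rejected naming the offending well.
#' @export
read_melt_curves <- function(path, dialect = c("auto", "long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (dialect == "auto") {
    dialect <- if (all(c("well", "primer", "temperature_C",
                         "fluorescence") %in% names(df))) "long" else
                           if (names(df)[1] == "temperature_C") "wide" else
                             stop("cannot sniff CSV dialect from header: ",
                                  paste(names(df), collapse = ", "))
  }
  curves <- list()
  if (dialect == "long") {
    need <- c("well", "primer", "temperature_C", "fluorescence")
    missing <- setdiff(need, names(df))
    if (length(missing) > 0) {
      stop("long dialect lacks column(s): ",
           paste(missing, collapse = ", "))
    }
    temps_all <- parse_num(df$temperature_C, "temperature_C",
                           seq_len(nrow(df)))
    fluo_all <- parse_num(df$fluorescence, "fluorescence",
                          seq_len(nrow(df)))
    grids <- list()
    for (w in unique(df$well)) {
      idx <- which(df$well == w)
      tt <- temps_all[idx]
      if (anyDuplicated(tt)) stop("duplicate (well, temperature) in ", w)
      o <- order(tt)
      grids[[w]] <- tt[o]
      pr <- unique(df$primer[idx])
      if (length(pr) != 1) stop("well ", w, " has multiple primer labels")
      curves[[w]] <- melt_curve(id = sub("\\.[^.]*$", "", w), primer = pr,
                                temperatures = tt[o],
                                fluorescence = fluo_all[idx][o])
    }
    ref <- grids[[1]]
    for (w in names(grids)) {
      if (length(grids[[w]]) != length(ref) ||
            any(abs(grids[[w]] - ref) > 1e-6)) {
        stop(sprintf(
          "ragged temperature grids: well %s (%d pts, %.4f..%.4f) vs %s (%d pts, %.4f..%.4f)",
          w, length(grids[[w]]), min(grids[[w]]), max(grids[[w]]),
          names(grids)[1], length(ref), min(ref), max(ref)))
      }
    }
  } else {
    temps <- parse_num(df[[1]], "temperature_C", seq_len(nrow(df)))
    for (col in names(df)[-1]) {
      parts <- strsplit(col, "|", fixed = TRUE)[[1]]
      if (length(parts) != 2) {
        stop("wide header must encode 'well|primer': ", col)
      }
      curves[[col]] <- melt_curve(
        id = sub("\\.[^.]*$", "", parts[1]), primer = parts[2],
        temperatures = temps,
        fluorescence = parse_num(df[[col]], col, seq_len(nrow(df))))
    }
  }
  meta <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(id = cv$id, species = NA_character_,
               population = NA_character_, primer = cv$primer,
               replicate = 1L, stringsAsFactors = FALSE)
  }))
  step <- curves[[1]]$temperatures[2] - curves[[1]]$temperatures[1]
  grid <- temp_grid(min(curves[[1]]$temperatures),
                    max(curves[[1]]$temperatures), step)
  new_curve_set(unname(curves), meta, grid)
}

#' Write a reference library to JSON
#'
#' Schema: `{"species": {"<sp>": {"<primer>": {"peaks": [{"tm":, "height":}
#' ]}}}, "meta": {...}}`. Tm values survive the round trip exactly at
#' 0.1 degC precision.
#'
#' @param lib A `reference_library`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  species <- list()
  for (key in names(lib$fingerprints)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    fp <- lib$fingerprints[[key]]
    peaks <- lapply(seq_len(nrow(fp$peaks)), function(i) {
      list(tm = fp$peaks$tm[i], height = fp$peaks$height[i])
    })
    species[[parts[1]]][[parts[2]]] <- list(peaks = peaks)
  }
  jsonlite::write_json(list(species = species, meta = lib$meta), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a reference library from JSON
#'
#' @param path JSON file written by [write_library()].
#' @return A `reference_library`. Schema violations are rejected with the
#'   JSON path of the offending node.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  if (is.null(doc$species)) stop("schema error at /species: missing")
  fps <- list()
  species <- character(0)
  primers <- character(0)
  for (sp in names(doc$species)) {
    if (sp %in% species) stop("duplicate species: ", sp)
    species <- c(species, sp)
    for (pr in names(doc$species[[sp]])) {
      node <- doc$species[[sp]][[pr]]
      ptr <- sprintf("/species/%s/%s", sp, pr)
      if (is.null(node$peaks)) {
        stop("schema error at ", ptr, ": missing 'peaks'")
      }
      if (length(node$peaks) == 0) {
        stop("schema error at ", ptr, "/peaks: empty")
      }
      tm <- vapply(node$peaks, function(p) {
        if (is.null(p$tm) || !is.numeric(p$tm)) {
          stop("schema error at ", ptr, "/peaks: missing numeric 'tm'")
        }
        p$tm
      }, numeric(1))
      ht <- vapply(node$peaks, function(p) {
        if (is.null(p$height)) NA_real_ else as.numeric(p$height)
      }, numeric(1))
      key <- paste(sp, pr, sep = "|")
      if (!is.null(fps[[key]])) stop("duplicate (species, primer): ", key)
      o <- order(tm)
      fps[[key]] <- melt_fingerprint_new(
        data.frame(tm = tm[o], height = ht[o], prominence = ht[o],
                   width = NA_real_), pr, key)
      primers <- union(primers, pr)
    }
  }
  structure(list(species = species, primers = primers, fingerprints = fps,
                 meta = doc$meta),
            class = "reference_library")
}

#' Serialize a panel specification to JSON
#' @param panel A [panel_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cells <- lapply(panel$transitions, function(trs) {
    lapply(trs, function(tr) {
      list(tm = tr$tm, amplitude = tr$amplitude, width = tr$width)
    })
  })
  doc <- list(
    species = panel$species, primers = panel$primers,
    populations = panel$populations,
    population_offsets = panel$population_offsets,
    transitions = cells,
    noise = list(tm_jitter_sd = panel$tm_jitter_sd,
                 amplitude_jitter_cv = panel$amplitude_jitter_cv,
                 noise_sd = panel$noise_sd),
    baseline = list(pre_level = panel$baseline_pre_level,
                    post_level = panel$baseline_post_level,
                    slope = panel$baseline_slope),
    grid = list(start = panel$grid$start, stop = panel$grid$stop,
                step = panel$grid$step),
    seed = panel$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a panel specification from JSON
#' @param path File written by [write_panel()].
#' @return A [panel_spec()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  for (f in c("species", "primers", "transitions", "grid", "seed")) {
    if (is.null(doc[[f]])) stop("schema error at /", f, ": missing")
  }
  transitions <- lapply(doc$transitions, function(cell) {
    lapply(cell, function(tr) {
      transition(tr$tm, tr$amplitude, tr$width)
    })
  })
  panel_spec(
    species = unlist(doc$species), primers = unlist(doc$primers),
    transitions = transitions,
    populations = lapply(doc$populations, unlist),
    population_offsets = lapply(doc$population_offsets, unlist),
    tm_jitter_sd = doc$noise$tm_jitter_sd,
    amplitude_jitter_cv = doc$noise$amplitude_jitter_cv,
    noise_sd = doc$noise$noise_sd,
    baseline_pre_level = doc$baseline$pre_level,
    baseline_post_level = doc$baseline$post_level,
    baseline_slope = doc$baseline$slope,
    grid = temp_grid(doc$grid$start, doc$grid$stop, doc$grid$step),
    seed = doc$seed)
}

#' Write extracted fingerprints to JSON
#' @param fps List of `melt_fingerprint` objects.
#' @param path Output file.
#' @param meta Optional metadata data frame aligned with `fps` (columns
#'   `id`, `species`, ... are carried through).
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path, meta = NULL) {
  doc <- lapply(seq_along(fps), function(k) {
    fp <- fps[[k]]
    entry <- list(
      id = fp$id, primer = fp$primer, valid = fp$valid,
      peaks = lapply(seq_len(nrow(fp$peaks)), function(i) {
        list(tm = fp$peaks$tm[i], height = fp$peaks$height[i])
      }))
    if (!is.null(meta)) entry$species <- meta$species[k]
    entry
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#' @param path JSON file.
#' @return List with elements `fingerprints` and `species` (labels or NA).
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  fps <- lapply(doc, function(entry) {
    tm <- vapply(entry$peaks, function(p) p$tm, numeric(1))
    ht <- vapply(entry$peaks, function(p) {
      if (is.null(p$height)) NA_real_ else as.numeric(p$height)
    }, numeric(1))
    melt_fingerprint_new(
      data.frame(tm = tm, height = ht, prominence = ht, width = NA_real_),
      entry$primer, entry$id,
      valid = isTRUE(entry$valid) || length(tm) > 0)
  })
  species <- vapply(doc, function(entry) {
    if (is.null(entry$species)) NA_character_ else entry$species
  }, character(1))
  list(fingerprints = fps, species = species)
}

RUN_CONFIG_KEYS <- c(
  "grid_start", "grid_stop", "grid_step", "pre_region", "post_region",
  "smooth_window", "sg_order", "min_prominence", "min_height",
  "min_separation", "tolerance", "lambda", "reject_threshold",
  "uniqueness_threshold", "seed", "panel_seed", "query_seed",
  "replicates_per_cell", "tm_jitter_sd", "noise_sd", "primers",
  "out_dir", "version")

#' Read a flat YAML run configuration
#'
#' Known keys map onto [hrm_config()] and [trial_config()] fields; unknown
#' keys are rejected rather than silently ignored.
#'
#' @param path YAML file of flat key-value pairs.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

hrm_config_from_run <- function(cfg) {
  take <- function(key, default) if (is.null(cfg[[key]])) default else
    cfg[[key]]
  hrm_config(
    pre_region = cfg$pre_region, post_region = cfg$post_region,
    smooth_window = take("smooth_window", 1.1),
    sg_order = take("sg_order", 5),
    min_prominence = take("min_prominence", 0.05),
    min_height = take("min_height", 0.08),
    min_separation = take("min_separation", 0.8),
    tolerance = take("tolerance", 0.3),
    lambda = take("lambda", 1),
    reject_threshold = take("reject_threshold", 0.5),
    uniqueness_threshold = take("uniqueness_threshold", 0.25))
}

#' Reported identification metrics bundled with the package
#'
#' A fixture dataset of per-primer, per-species identification performance
#' (accuracy, precision, sensitivity, specificity, percent scale) for the
#' five deeply sampled marine mammal species of an ISSR-HRM double-blind
#' accuracy assessment, together with the reported per-primer and
#' per-species mean values. Used to exercise the aggregation routines:
#' every reported mean is the arithmetic mean of its constituent cells to
#' two-decimal presentation rounding.
#'
#' @return List with data frames `cells` (long format: primer, metric,
#'   species, value), `primer_means` (primer, metric, mean) and
#'   `species_means` (species, one column per metric).
#' @export
reported_metrics <- function() {
  dir <- system.file("extdata", package = "meltprint", mustWork = TRUE)
  cells <- utils::read.delim(file.path(dir, "reported_primer_metrics.tsv"),
                             check.names = FALSE)
  long <- stats::reshape(
    cells, direction = "long",
    varying = setdiff(names(cells), c("primer", "metric")),
    v.names = "value", timevar = "species",
    times = setdiff(names(cells), c("primer", "metric")))
  long <- long[order(long$primer, long$metric), c("primer", "metric",
                                                  "species", "value")]
  rownames(long) <- NULL
  list(
    cells = long,
    primer_means = utils::read.delim(
      file.path(dir, "reported_primer_means.tsv"), check.names = FALSE),
    species_means = utils::read.delim(
      file.path(dir, "reported_species_means.tsv"), check.names = FALSE))
}
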