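# Configuration-driven orchestration: families + Ks table + anchors +
# ortholog tables + topology in, weighted distributions, peaks with CIs,
# rate table, placements and event table out, with per-stage status logging.

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, fills defaults (subfamily cutoff 5, bin width
#' 0.01, 100 bootstrap replicates, analysis range `[0.05, 5]`), and checks
#' required fields and referenced paths.
#'
#' Required fields: `focal_species`, `outgroup`, `seed`, and under `inputs`:
#' `families`, `ks_table`, `topology`; optional: `anchors`,
#' `ortholog_tables` (a map species-pair key -> path; keys as in
#' [pair_key()]), `output_dir`.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (a named list, defaults filled).
#' @export
validate_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("focal_species", "outgroup", "seed")
  for (f in req) if (is.null(cfg[[f]])) stop("config missing required field: ", f)
  if (is.null(cfg$inputs)) stop("config missing required field: inputs")
  for (f in c("families", "ks_table", "topology"))
    if (is.null(cfg$inputs[[f]])) stop("config missing required field: inputs.", f)
  defaults <- list(cutoff = 5, bin_width = 0.01, n_boot = 100,
                   ks_range = c(0.05, 5), output_dir = "results")
  for (d in names(defaults)) if (is.null(cfg[[d]])) cfg[[d]] <- defaults[[d]]
  cfg$ks_range <- as.numeric(unlist(cfg$ks_range))
  if (cfg$n_boot < 2) stop("n_boot must be >= 2")
  paths <- c(cfg$inputs$families, cfg$inputs$ks_table, cfg$inputs$topology,
             cfg$inputs$anchors, unlist(cfg$inputs$ortholog_tables))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("config references missing file(s): ", paste(missing, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

.stage <- function(log, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  log$rows[[length(log$rows) + 1L]] <- data.frame(
    stage = name, status = if (res$ok) "ok" else "failed",
    message = if (res$ok) "" else res$value)
  res
}

#' Run the full WGD inference pipeline
#'
#' Stages, in order: weighted paranome/anchor distribution construction,
#' density fitting and peak detection, bootstrap CIs, rate profile from
#' ortholog tables, Ks branch-length estimation, half-Ks placement of each
#' peak, shared/independent classification against corrected divergence
#' peaks, and event synthesis. A failed stage records its error and
#' downstream dependents are skipped with explicit status.
#'
#' @param config A [validate_config()] result, or a path to a YAML config.
#' @return Object of class `result_bundle`: list with `distribution`,
#'   `curve`, `peaks` (list of `peak_estimate`), `rate_table`, `ks_tree`,
#'   `placements`, `calls`, `events`, `log` (stage status data frame),
#'   `config` (echo), `status` (`"ok"` or `"failed"`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- new.env(parent = emptyenv()); log$rows <- list()
  bundle <- list(config = unclass(config), status = "ok")

  inputs <- .stage(log, "read_inputs", {
    fams <- utils::read.delim(config$inputs$families, stringsAsFactors = FALSE)
    kst <- read_ks_table(config$inputs$ks_table)
    anch <- if (!is.null(config$inputs$anchors))
      utils::read.delim(config$inputs$anchors, stringsAsFactors = FALSE) else NULL
    topo <- ape::read.tree(config$inputs$topology)
    ortho <- lapply(config$inputs$ortholog_tables, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE))
    list(fams = fams, kst = kst, anch = anch, topo = topo, ortho = ortho)
  })
  if (!inputs$ok) {
    bundle$status <- "failed"; bundle$log <- do.call(rbind, log$rows)
    return(structure(bundle, class = "result_bundle"))
  }
  inp <- inputs$value

  dist <- .stage(log, "build_distribution",
                 build_distribution(inp$fams, inp$kst, anchors = inp$anch,
                                    cutoff = config$cutoff,
                                    ks_range = config$ks_range))
  peaks <- NULL
  if (dist$ok) {
    bundle$distribution <- dist$value
    pk <- .stage(log, "peak_detection", {
      curve <- fit_density(dist$value, range = config$ks_range,
                           bin_width = config$bin_width)
      found <- find_peaks(curve)
      ests <- lapply(found$location, function(p)
        bootstrap_peak_ci(dist$value, p, n_boot = config$n_boot,
                          seed = config$seed, bin_width = config$bin_width,
                          range = config$ks_range, curve = curve))
      list(curve = curve, peaks = ests)
    })
    if (pk$ok) {
      bundle$curve <- pk$value$curve
      bundle$peaks <- peaks <- pk$value$peaks
    }
  } else {
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(stage = "peak_detection", status = "skipped",
                 message = "distribution unavailable")
  }

  profile <- NULL
  if (length(inp$ortho)) {
    others <- setdiff(unique(unlist(strsplit(names(inp$ortho), "|", fixed = TRUE))),
                      c(config$focal_species, config$outgroup))
    rp <- .stage(log, "rate_profile",
                 rate_profile(config$focal_species, others, config$outgroup, inp$ortho))
    if (rp$ok) bundle$rate_table <- profile <- rp$value
  } else {
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(stage = "rate_profile", status = "skipped",
                 message = "no ortholog tables configured")
  }

  tree <- NULL
  if (!is.null(profile)) {
    tr <- .stage(log, "ks_branch_lengths", {
      # species pairwise Ks matrix from ortholog modes
      sp <- inp$topo$tip.label
      m <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
      diag(m) <- 0
      for (key in names(inp$ortho)) {
        ab <- strsplit(key, "|", fixed = TRUE)[[1]]
        if (all(ab %in% sp))
          m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- kde_mode(inp$ortho[[key]]$ks)
      }
      estimate_ks_branch_lengths(inp$topo, m)
    })
    if (tr$ok) bundle$ks_tree <- tree <- tr$value
  } else {
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(stage = "ks_branch_lengths", status = "skipped",
                 message = "rate profile unavailable")
  }

  if (!is.null(tree) && !is.null(peaks) && length(peaks)) {
    pl <- .stage(log, "placement", {
      placements <- lapply(peaks, function(p)
        map_peak_to_branch(tree, config$focal_species, p))
      calls <- list()
      if (!is.null(profile)) {
        for (p in peaks) for (r in seq_len(nrow(profile))) {
          calls[[length(calls) + 1L]] <- classify_shared(
            p$ci95, 2 * profile$d_focal[r],
            focal_tip = config$focal_species,
            other_lineage = profile$species[r])
        }
      }
      events <- multi_lineage_synthesis(placements, calls)
      list(placements = placements, calls = calls, events = events)
    })
    if (pl$ok) {
      bundle$placements <- pl$value$placements
      bundle$calls <- pl$value$calls
      bundle$events <- pl$value$events
    }
  } else {
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(stage = "placement", status = "skipped",
                 message = "tree or peaks unavailable")
  }

  bundle$log <- do.call(rbind, log$rows)
  if (any(bundle$log$status == "failed")) bundle$status <- "failed"
  structure(bundle, class = "result_bundle")
}

#' Write a result bundle's tables to a directory
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$distribution))
    write_distribution(bundle$distribution, file.path(dir, "weighted_ks.tsv"))
  if (!is.null(bundle$peaks)) {
    pk <- do.call(rbind, lapply(seq_along(bundle$peaks), function(i) {
      p <- bundle$peaks[[i]]
      data.frame(distribution_id = "paranome", peak_ks = p$location,
                 ci_lo = p$ci95[1], ci_hi = p$ci95[2], n_boot = p$n_boot,
                 window_lo = p$window[1], window_hi = p$window[2])
    }))
    utils::write.table(pk, file.path(dir, "peaks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(pk, file.path(dir, "peaks.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(bundle$rate_table))
    write_rate_table(bundle$rate_table, file.path(dir, "rate_table.tsv"))
  if (!is.null(bundle$placements))
    write_placements(bundle$placements, file.path(dir, "placements.tsv"))
  if (!is.null(bundle$events)) {
    write_event_table(bundle$events, file.path(dir, "events.json"))
    if (!is.null(bundle$ks_tree))
      write_annotated_tree(bundle$ks_tree, bundle$events,
                           file.path(dir, "ks_tree_annotated.nwk"))
  }
  utils::write.table(bundle$log, file.path(dir, "stage_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$config, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
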