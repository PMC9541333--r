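#' Run one benchmark scenario end to end
#'
#' Simulates the scenario's tissue sets with glare, distance and noise
#' corruption, applies each requested preprocessing algorithm (the
#' unprocessed baseline `"none"` is always included), computes the pairwise
#' mean-overlap matrix per algorithm, and summarizes mean overlap and
#' improvement relative to the unprocessed baseline of the same run.
#'
#' @param scenario One of `"bvf"`, `"absorbers"`, `"amplitude"`, `"slope"`
#'   (five-set single-contrast scenarios, 25 bins) or `"mixed"` (the
#'   healthy-versus-tumor simulation, 50 bins).
#' @param algorithms Character vector of algorithms (default: all eight).
#' @param config An [acquisition_config()]; defaults to the standard grid
#'   with 100 spectra per set (1000 per class for `"mixed"`).
#' @param n_bins Histogram bins for the overlap (default 25; 50 for
#'   `"mixed"`).
#' @param seed Integer seed for all nuisance draws.
#' @param output_dir Optional directory; when given, overlap matrices
#'   (CSV + JSON), the summary table, heatmaps (PNG) and a run manifest are
#'   written there.
#' @param sg_window,sg_polyorder,reference_wavelength,segments Passed to
#'   [preprocess_spectra()].
#' @return An object of class `scenario_run`: list with `scenario`, `seed`,
#'   `n_bins`, `overlaps` (tibble `algorithm`, `label_1`, `label_2`,
#'   `mean_overlap`), `summary` (tibble `algorithm`, `family`,
#'   `mean_overlap`, `improvement_pct`), `manifest`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' cfg <- acquisition_config(grid = seq(500, 900, by = 10), n_spectra = 15)
#' run <- run_scenario("bvf", algorithms = c("snv", "auc"),
#'                     config = cfg, seed = 1)
#' tidy(run)
#' @export
run_scenario <- function(scenario = c("bvf", "absorbers", "amplitude",
                                      "slope", "mixed"),
                         algorithms = setdiff(preprocessing_algorithms(), "none"),
                         config = NULL, n_bins = NULL, seed = 1L,
                         output_dir = NULL,
                         sg_window = 199, sg_polyorder = 2,
                         reference_wavelength = 730, segments = NULL) {
  scenario <- match.arg(scenario)
  algorithms <- unique(c("none", algorithms))
  bad <- setdiff(algorithms, preprocessing_algorithms())
  if (length(bad) > 0) {
    abort(paste0("Unknown algorithm(s): ", paste(bad, collapse = ", "), "."))
  }
  if (is.null(n_bins)) n_bins <- if (scenario == "mixed") 50 else 25
  if (is.null(config)) {
    config <- if (scenario == "mixed") {
      acquisition_config(n_spectra = 1000)
    } else {
      acquisition_config()
    }
  }

  manifest <- list(
    scenario = scenario, seed = seed, n_bins = n_bins,
    algorithms = algorithms,
    package_version = as.character(packageVersion("specprep")),
    config = unclass(config)[c("k", "n_incident", "n_surface", "d_max",
                               "glare", "distance", "noise", "n_spectra")],
    grid = c(min = min(config$grid), max = max(config$grid),
             n = length(config$grid)),
    started = format(Sys.time(), tz = "UTC"), timings_s = list(),
    files = character(0), status = "running"
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(manifest, output_dir)
  }

  t0 <- proc.time()[["elapsed"]]
  spectra <- if (scenario == "mixed") {
    simulate_mixed(config, seed = seed)
  } else {
    simulate_spectra(scenario_table1(scenario), config, seed = seed)
  }
  manifest$timings_s$simulate <- round(proc.time()[["elapsed"]] - t0, 2)
  manifest$nuisance <- nuisance_summary(spectra)

  overlaps <- vector("list", length(algorithms))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_along(algorithms)) {
    alg <- algorithms[i]
    processed <- preprocess_spectra(
      spectra, alg, reference_wavelength = reference_wavelength,
      sg_window = sg_window, sg_polyorder = sg_polyorder, segments = segments
    )
    pr <- pairwise_overlap(processed, n_bins = n_bins)
    overlaps[[i]] <- mutate(as_tibble(pr), algorithm = alg, .before = 1)
  }
  manifest$timings_s$preprocess_overlap <-
    round(proc.time()[["elapsed"]] - t0, 2)
  overlaps <- bind_rows(overlaps)

  base <- overlaps |>
    filter(.data$algorithm == "none") |>
    select("label_1", "label_2", baseline = "mean_overlap")
  summary <- overlaps |>
    left_join(base, by = c("label_1", "label_2")) |>
    group_by(.data$algorithm) |>
    summarise(
      improvement_pct = mean(overlap_improvement(.data$baseline,
                                                 .data$mean_overlap)),
      mean_overlap = mean(.data$mean_overlap),
      .groups = "drop"
    ) |>
    select("algorithm", "mean_overlap", "improvement_pct") |>
    mutate(family = algorithm_family(.data$algorithm),
           .after = "algorithm") |>
    arrange(match(.data$algorithm, algorithms))

  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  run <- structure(
    list(scenario = scenario, seed = seed, n_bins = n_bins,
         labels = attr_labels(overlaps), algorithms = algorithms,
         overlaps = overlaps, summary = summary, manifest = manifest),
    class = "scenario_run"
  )
  if (!is.null(output_dir)) {
    run$manifest$files <- write_run_artifacts(run, output_dir)
    write_manifest(run$manifest, output_dir)
  }
  run
}

attr_labels <- function(overlaps) unique(c(overlaps$label_1, overlaps$label_2))

nuisance_summary <- function(spectra) {
  if (!all(c("glare", "distance") %in% names(spectra))) return(NULL)
  spectra |>
    distinct(.data$label, .data$spectrum, .data$glare, .data$distance) |>
    group_by(.data$label) |>
    summarise(n_spectra = dplyr::n(),
              mean_glare = mean(.data$glare),
              mean_distance = mean(.data$distance), .groups = "drop")
}

write_manifest <- function(manifest, output_dir) {
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(NULL)
}

write_run_artifacts <- function(run, output_dir) {
  files <- character(0)
  for (alg in run$algorithms) {
    pr <- filter(run$overlaps, .data$algorithm == alg)
    attr(pr, "labels") <- run$labels
    m <- overlap_matrix(pr)
    f_csv <- file.path(output_dir, paste0("overlap_", alg, ".csv"))
    write.csv(as.data.frame(m), f_csv, row.names = TRUE)
    f_json <- file.path(output_dir, paste0("overlap_", alg, ".json"))
    jsonlite::write_json(
      list(algorithm = alg, labels = run$labels, matrix = m,
           n_bins = run$n_bins, seed = run$seed),
      f_json, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
    )
    f_png <- file.path(output_dir, paste0("overlap_", alg, ".png"))
    class(pr) <- c("overlap_pairs", class(pr))
    png_ok <- tryCatch({
      ggsave(f_png, autoplot(pr) + ggtitle(alg), width = 5, height = 4,
             dpi = 120)
      TRUE
    }, error = function(e) FALSE)
    files <- c(files, f_csv, f_json, if (png_ok) f_png)
  }
  f_sum <- file.path(output_dir, "summary.csv")
  write.csv(run$summary, f_sum, row.names = FALSE)
  basename(c(files, f_sum))
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("<scenario_run> scenario '", x$scenario, "', seed ", x$seed,
      ", ", x$n_bins, " bins\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `scenario_run`.
#' @param pairs If `TRUE`, return the per-pair overlaps instead of the
#'   per-algorithm summary.
#' @param ... Unused.
#' @method tidy scenario_run
#' @export
tidy.scenario_run <- function(x, pairs = FALSE, ...) {
  if (pairs) x$overlaps else x$summary
}

#' @rdname run_scenario
#' @method glance scenario_run
#' @export
glance.scenario_run <- function(x, ...) {
  proc <- filter(x$summary, .data$algorithm != "none")
  tibble(
    scenario = x$scenario, seed = x$seed, n_bins = x$n_bins,
    n_sets = length(x$labels), n_algorithms = nrow(proc),
    unprocessed_overlap =
      x$summary$mean_overlap[x$summary$algorithm == "none"],
    best_algorithm = proc$algorithm[which.min(proc$mean_overlap)],
    best_overlap = min(proc$mean_overlap)
  )
}

#' @rdname run_scenario
#' @param object A `scenario_run`.
#' @method autoplot scenario_run
#' @export
autoplot.scenario_run <- function(object, ...) {
  df <- object$overlaps
  full <- bind_rows(
    df,
    rename(df, label_1 = "label_2", label_2 = "label_1"),
    tibble(algorithm = rep(object$algorithms, each = length(object$labels)),
           label_1 = rep(object$labels, times = length(object$algorithms)),
           label_2 = rep(object$labels, times = length(object$algorithms)),
           mean_overlap = 1)
  )
  full$label_1 <- factor(full$label_1, levels = object$labels)
  full$label_2 <- factor(full$label_2, levels = rev(object$labels))
  full$algorithm <- factor(full$algorithm, levels = object$algorithms)
  ggplot(full, aes(x = .data$label_1, y = .data$label_2,
                   fill = .data$mean_overlap)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$mean_overlap)), size = 2.4) +
    scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    facet_wrap(~algorithm) +
    labs(x = NULL, y = NULL, fill = "overlap",
         title = paste0("Scenario '", object$scenario, "'")) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Cross-scenario improvement summary
#'
#' Combines several [run_scenario()] results into one table of mean
#' improvement (percent, relative to each run's own unprocessed baseline)
#' per algorithm and scenario, with the algorithm family annotation.
#'
#' @param runs A list of `scenario_run` objects (named or not; scenario
#'   names are taken from the runs themselves).
#' @return A tibble with columns `algorithm`, `family`, then one column of
#'   improvement percentages per scenario, rows ordered as in the first
#'   run's algorithm list.
#' @export
report_summary <- function(runs) {
  if (inherits(runs, "scenario_run")) runs <- list(runs)
  if (length(runs) < 1) abort("Need at least one completed run.")
  stopifnot(all(vapply(runs, inherits, logical(1), "scenario_run")))
  grids <- unique(vapply(runs, function(r) {
    paste(r$manifest$grid, collapse = "/")
  }, character(1)))
  if (length(grids) > 1) {
    abort("Runs were computed on different wavelength grids; refusing to pool.")
  }
  long <- bind_rows(lapply(runs, function(r) {
    mutate(filter(r$summary, .data$algorithm != "none"),
           scenario = r$scenario, .before = 1)
  }))
  wide <- tidyr::pivot_wider(
    long |> select("scenario", "algorithm", "family", "improvement_pct"),
    names_from = "scenario", values_from = "improvement_pct"
  )
  arrange(wide, match(.data$algorithm, runs[[1]]$algorithms))
}

#' Bar chart of cross-scenario improvements
#'
#' @param summary A table from [report_summary()].
#' @return A ggplot object.
#' @export
plot_report <- function(summary) {
  long <- tidyr::pivot_longer(summary, cols = -c("algorithm", "family"),
                              names_to = "scenario",
                              values_to = "improvement_pct")
  long$algorithm <- factor(long$algorithm, levels = unique(summary$algorithm))
  ggplot(long, aes(x = .data$algorithm, y = .data$improvement_pct,
                   fill = .data$family)) +
    geom_col() +
    facet_wrap(~scenario) +
    labs(x = NULL, y = "improvement in mean overlap (%)", fill = "family") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
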