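default_timepoints <- function(protocol_name) {
  switch(protocol_name,
    step10 = c(10, 20, 30, 40, 50),
    restriction = c(5, 10, 15, 20),
    iaa = c(10, 20, 30),
    sixan = c(10, 20, 30),
    combined = c(10, 20, 30),
    c(10, 20)
  )
}

#' Configuration of a simulated imaging experiment
#'
#' Bundles everything [run_experiment()] needs: the protocol, group sizes,
#' corruption levels of the renderer, analysis windows, and the single seed
#' driving all randomness.
#'
#' @param protocol Name of a standard protocol (see
#'   [make_paper_protocols()]) or a [protocol()] object.
#' @param n_cells Cells per genotype (>= 2 for group summaries).
#' @param genotypes Character vector of genotypes to simulate.
#' @param seed Integer seed; every stochastic draw derives from it.
#' @param baseline_min Baseline length in minutes before the event.
#' @param slope_window Post-event window `c(start, end)` in minutes for the
#'   elimination-rate slope.
#' @param timepoints_min Post-event times (minutes) at which relative-ratio
#'   values are read; defaults depend on the protocol.
#' @param filter Read timepoint values from the median-filtered trace
#'   (default `TRUE`).
#' @param slope_on_filtered Estimate slopes on the median-filtered trace
#'   instead of the raw relative trace (default `FALSE`: the filter exists to
#'   remove display artifacts, and OLS slopes should see the raw samples).
#'   Enable it when artifact injection is turned on.
#' @param cell_cv Between-cell coefficient of variation applied to the
#'   transport and consumption rates (lognormal).
#' @param noise_sd,bleach,drift_px_per_min,artifact_prob Corruption levels
#'   passed to the renderer; see [scene_params()]. `drift_px_per_min` builds
#'   a linear x-y stage-drift path.
#' @param out_dir Optional output directory for the report files.
#' @return A `run_config` list.
#' @export
run_config <- function(protocol = "restriction", n_cells = 4,
                       genotypes = c("nonTg", "3xTgAD"), seed = 1L,
                       baseline_min = 10, slope_window = c(2, 7),
                       timepoints_min = NULL, filter = TRUE,
                       slope_on_filtered = FALSE, cell_cv = 0.10,
                       noise_sd = c(1, 1), bleach = c(0.0015, 0.0005),
                       drift_px_per_min = 0.05, artifact_prob = 0,
                       out_dir = NULL) {
  protocol_name <- if (is.character(protocol)) protocol else "custom"
  if (is.character(protocol)) {
    all_p <- make_paper_protocols()
    if (!protocol %in% names(all_p)) {
      abort(paste0("unknown protocol name: ", protocol))
    }
    protocol <- all_p[[protocol]]
  }
  stopifnot(inherits(protocol, "fret_protocol"))
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (is.null(timepoints_min)) timepoints_min <- default_timepoints(protocol_name)
  structure(
    list(
      protocol = protocol, protocol_name = protocol_name,
      n_cells = as.integer(n_cells), genotypes = genotypes,
      seed = as.integer(seed), baseline_min = baseline_min,
      slope_window = slope_window, timepoints_min = timepoints_min,
      filter = isTRUE(filter), slope_on_filtered = isTRUE(slope_on_filtered),
      cell_cv = cell_cv,
      noise_sd = noise_sd, bleach = bleach,
      drift_px_per_min = drift_px_per_min, artifact_prob = artifact_prob,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage: ", name, "] ", conditionMessage(e)))
  })
}

simulate_group <- function(config, genotype) {
  protocol <- config$protocol
  base_params <- kinetic_params(genotype)
  factors <- with_substream(
    config$seed, paste0("cell_params_", genotype),
    matrix(exp(rnorm(3 * config$n_cells, sd = config$cell_cv)), ncol = 3)
  )
  traces <- purrr::map_dfr(seq_len(config$n_cells), function(i) {
    p <- kinetic_params(genotype,
      v_transport = base_params$v_transport * factors[i, 1],
      v_glycolysis = base_params$v_glycolysis * factors[i, 2],
      v_ppp = base_params$v_ppp * factors[i, 3]
    )
    simulate_ratio_trace(p, protocol, cell_id = paste0("cell_", i))
  })
  n_fr <- length(protocol_times(protocol))
  t_min <- protocol_times(protocol)
  drift <- tibble(
    dx = config$drift_px_per_min * t_min,
    dy = 0.7 * config$drift_px_per_min * t_min
  )
  scene <- make_grid_scene(
    config$n_cells,
    seed = substream_seed(config$seed, paste0("scene_", genotype)),
    noise_sd = config$noise_sd, bleach = config$bleach,
    drift = drift, artifact_prob = config$artifact_prob
  )
  movie <- render_movie(scene, traces)
  list(movie = movie, truth_traces = traces)
}

analyze_movie <- function(config, movie) {
  protocol <- config$protocol
  reg <- stage("register", register_stack(movie$stack))
  rs <- stage("ratio", ratio_stack(reg$stack))
  raw <- stage("extract", extract_traces(rs, movie$truth$rois))
  bl <- c(
    max(0, protocol_event_time(protocol) - config$baseline_min),
    protocol_event_time(protocol)
  )
  corrected <- stage("drift_correct", correct_drift(raw, bl))
  rel <- stage("relative", relative_ratio(corrected, bl))
  filtered <- median_filter5(rel)
  list(raw = raw, rel = rel, filtered = filtered, shifts = reg$shifts)
}

#' Run a complete simulated imaging experiment
#'
#' Chains simulation, rendering, registration, ratio imaging, trace
#' extraction, drift correction, relative-ratio statistics and genotype
#' comparisons into one reproducible report. Given the same configuration
#' and seed the report is identical byte for byte.
#'
#' @param config A [run_config()].
#' @return A list of class `fret_report`:
#' \describe{
#'   \item{config_summary}{protocol name, group size, seed, config hash.}
#'   \item{summaries}{per-genotype group mean +/- SEM tibble.}
#'   \item{cell_metrics}{per-cell timepoint values and slopes.}
#'   \item{comparisons}{Mann-Whitney genotype comparisons per metric.}
#'   \item{traces}{the relative (filtered) traces.}
#'   \item{provenance}{seed, config hash, package version.}
#' }
#' If `config$out_dir` is set, writes `report.json`, per-genotype summary
#' CSVs and a cell-metrics CSV there, each carrying the provenance fields.
#' @export
#' @examples
#' \donttest{
#' rep <- run_experiment(run_config(n_cells = 2, seed = 7))
#' rep$comparisons
#' }
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  protocol <- config$protocol
  ev <- protocol_event_time(protocol)

  per_geno <- lapply(config$genotypes, function(gt) {
    sim <- stage("simulate", simulate_group(config, gt))
    res <- analyze_movie(config, sim$movie)
    tp_trace <- if (config$filter) res$filtered else res$rel
    tps <- purrr::map_dfr(config$timepoints_min, function(tt) {
      timepoint_value(tp_trace, tt, ev) %>%
        mutate(metric = sprintf("t%g", tt), .before = 1)
    })
    slope_trace <- if (isTRUE(config$slope_on_filtered)) res$filtered else res$rel
    slopes <- estimate_slope(slope_trace, config$slope_window, ev) %>%
      mutate(metric = "slope", value = .data$slope, .before = 1)
    metrics <- bind_rows(
      tps[, c("metric", "cell_id", "value")],
      slopes[, c("metric", "cell_id", "value")]
    ) %>% mutate(genotype = gt, .before = 1)
    summary_tbl <- if (config$n_cells >= 2) {
      group_summary(res$filtered) %>% mutate(genotype = gt, .before = 1)
    } else {
      NULL
    }
    list(metrics = metrics, summary = summary_tbl, traces = res$filtered %>%
      mutate(genotype = gt, .before = 1))
  })
  names(per_geno) <- config$genotypes

  cell_metrics <- bind_rows(lapply(per_geno, `[[`, "metrics"))
  summaries <- bind_rows(lapply(per_geno, `[[`, "summary"))
  traces <- bind_rows(lapply(per_geno, `[[`, "traces"))

  comparisons <- NULL
  if (length(config$genotypes) == 2) {
    g1 <- config$genotypes[1]
    g2 <- config$genotypes[2]
    comparisons <- purrr::map_dfr(unique(cell_metrics$metric), function(m) {
      x <- cell_metrics$value[cell_metrics$metric == m & cell_metrics$genotype == g1]
      y <- cell_metrics$value[cell_metrics$metric == m & cell_metrics$genotype == g2]
      mw <- mann_whitney_u(x, y)
      tibble(
        metric = m,
        mean_1 = mean(x), sem_1 = sd(x) / sqrt(length(x)),
        mean_2 = mean(y), sem_2 = sd(y) / sqrt(length(y)),
        U = mw$U, p = mw$p, n1 = mw$n1, n2 = mw$n2, method = mw$method
      )
    })
  }

  cfg_fields <- config[setdiff(names(config), c("protocol", "out_dir"))]
  provenance <- list(
    seed = config$seed,
    config_hash = rlang::hash(cfg_fields),
    package_version = as.character(utils::packageVersion("glucofret"))
  )
  report <- structure(
    list(
      config_summary = list(
        protocol = config$protocol_name, n_cells = config$n_cells,
        genotypes = config$genotypes, seed = config$seed
      ),
      summaries = summaries, cell_metrics = cell_metrics,
      comparisons = comparisons, traces = traces, provenance = provenance
    ),
    class = "fret_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        provenance = provenance, config = report$config_summary,
        summaries = summaries, cell_metrics = cell_metrics,
        comparisons = comparisons
      ),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    prov_header <- sprintf(
      "# seed=%d config_hash=%s version=%s",
      provenance$seed, provenance$config_hash, provenance$package_version
    )
    write_with_header <- function(df, path) {
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(prov_header, con)
      utils::write.csv(as.data.frame(df), con, row.names = FALSE)
    }
    write_with_header(summaries, file.path(config$out_dir, "group_summaries.csv"))
    write_with_header(cell_metrics, file.path(config$out_dir, "cell_metrics.csv"))
  }
  report
}

#' @export
print.fret_report <- function(x, ...) {
  cat(sprintf(
    "<fret_report> protocol %s, %d cells/genotype, seed %d\n",
    x$config_summary$protocol, x$config_summary$n_cells, x$provenance$seed
  ))
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}
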