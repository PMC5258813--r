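#' Segment and measure one field
#'
#' Convenience wrapper running [segment_nuclei()] then [measure_cells()].
#'
#' @param field An `image_field`.
#' @param seg A [seg_params()].
#' @return List with `labels` (integer matrix) and `cells` (tibble).
#' @export
analyze_field <- function(field, seg = seg_params()) {
  labels <- segment_nuclei(field, seg)
  list(labels = labels, cells = measure_cells(labels, field))
}

## seeds for the study design, derived deterministically from a base seed
## and kept well below 2^31
study_seed <- function(base, line_i, rep_i, marker_i = 0L) {
  (as.integer(base) %% 100000L) * 10000L +
    line_i * 1000L + rep_i * 20L + marker_i
}

#' Simulate and analyze the four-line imaging-vs-flow study
#'
#' Runs the full study design: for each cell line and replicate, a
#' negative-control field plus one double-stained field per surface marker
#' (nuclear pluripotency marker on channel x, the surface marker on channel
#' y) are generated, segmented, measured and gated against the control; in
#' parallel, the same populations are dissociated in silico and measured by
#' the flow simulator with gates from a flow-measured control. The result
#' is one percent-positive profile per modality per replicate over the
#' five-marker panel (the nuclear marker's percent is averaged over the
#' four double-stain fields where it is co-measured), ready for
#' [concordance_summary()].
#'
#' @param lines Panel definition as from [line_marker_profiles()].
#' @param n_replicates Independent replicates per line.
#' @param base_config Base [sim_config()] shared by all fields.
#' @param seg Segmentation parameters.
#' @param q Negative-control quantile for gating.
#' @param seed Base seed; every field derives its own seed from it.
#' @return Tibble with `line`, `replicate`, `marker`, `imaging`, `flow`
#'   percent-positive columns; the total number of segmented cells across
#'   all sample fields is attached as attribute `n_cells_imaging`.
#' @export
simulate_study <- function(lines = line_marker_profiles(),
                           n_replicates = 3,
                           base_config = sim_config(),
                           seg = seg_params(),
                           q = 0.995,
                           seed = 1L) {
  line_names <- unique(lines$line)
  out <- list()
  n_cells_total <- 0L
  for (li in seq_along(line_names)) {
    ln <- line_names[li]
    panel <- lines[lines$line == ln, ]
    for (rep_i in seq_len(n_replicates)) {
      ## negative control: imaging gates and flow gates
      ctl_cfg <- control_config(base_config,
                                seed = study_seed(seed, li, rep_i, 19L))
      ctl <- generate_colony_field(ctl_cfg)
      ctl_cells <- analyze_field(ctl$field, seg)$cells
      gate_x <- fit_threshold(ctl_cells, "x", q)
      gate_y <- fit_threshold(ctl_cells, "y", q)
      ctl_flow <- simulate_flow_readings(ctl$truth, ctl_cfg,
                                         seed = study_seed(seed, li, rep_i, 18L))
      fgate_x <- fit_threshold(ctl_flow, "x", q)
      fgate_y <- fit_threshold(ctl_flow, "y", q)

      img_oct4 <- numeric(0); flow_oct4 <- numeric(0)
      rows <- list()
      for (mi in seq_len(nrow(panel))) {
        cfg <- base_config
        cfg$phenotype_fractions <- quadrant_fractions(
          panel$oct4_frac[mi], panel$marker_frac[mi], panel$association[mi])
        cfg$seed <- study_seed(seed, li, rep_i, mi)
        sim <- generate_colony_field(cfg)
        cells <- analyze_field(sim$field, seg)$cells
        n_cells_total <- n_cells_total + nrow(cells)
        flow <- simulate_flow_readings(sim$truth, cfg,
                                       seed = cfg$seed + 7L)
        img_oct4 <- c(img_oct4, percent_positive(cells, gate_x))
        flow_oct4 <- c(flow_oct4, percent_positive(flow, fgate_x))
        rows[[mi]] <- tibble(line = ln, replicate = rep_i,
                             marker = panel$marker[mi],
                             imaging = percent_positive(cells, gate_y),
                             flow = percent_positive(flow, fgate_y))
      }
      rows[[nrow(panel) + 1]] <- tibble(line = ln, replicate = rep_i,
                                        marker = "OCT-3/4",
                                        imaging = mean(img_oct4),
                                        flow = mean(flow_oct4))
      out[[length(out) + 1]] <- dplyr::bind_rows(rows)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_cells_imaging") <- n_cells_total
  res
}

#' Run the single-field pipeline end to end, writing all artifacts
#'
#' Generates (or loads) a field, segments it, measures cells, fits gates
#' from a matched negative control, classifies quadrants, scores colony
#' edge distances, tests edge enrichment of the differentiated
#' single-positive class, and writes every intermediate artifact plus a
#' JSON manifest (configuration hash, seeds, per-file MD5 checksums,
#' headline numbers, machine-readable warnings). Rerunning with the same
#' configuration reproduces identical images, CSVs and checksums.
#'
#' @param config A [sim_config()] for the sample field.
#' @param out_dir Output directory (created if missing).
#' @param seg Segmentation parameters.
#' @param q Negative-control gating quantile.
#' @param enrichment_phenotype Quadrant class tested for edge enrichment.
#' @param n_permutations Permutations for the enrichment test.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seg = seg_params(), q = 0.995,
                         enrichment_phenotype = "y_single_pos",
                         n_permutations = 1999) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  warnings_log <- character(0)
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sim <- stage("simulate", generate_colony_field(config))
  write_field_tiff(sim$field, p("field.tif"))
  readr::write_csv(sim$truth, p("ground_truth.csv"))
  write_sim_config(config, p("sim_config.yaml"))

  ctl_cfg <- control_config(config)
  ctl <- stage("simulate_control", generate_colony_field(ctl_cfg))
  ctl_an <- stage("segment_control", analyze_field(ctl$field, seg))

  an <- stage("segment", analyze_field(sim$field, seg))
  write_labels_tiff(an$labels, p("labels.tif"))
  readr::write_csv(an$cells, p("cells.csv"))

  if (nrow(an$cells) == 0) {
    manifest <- pipeline_manifest(config, out_dir,
                                  summary = list(n_cells = 0,
                                                 note = "no cells"),
                                  warnings = warnings_log)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    return(invisible(manifest))
  }

  gate_x <- stage("gate", fit_threshold(ctl_an$cells, "x", q))
  gate_y <- stage("gate", fit_threshold(ctl_an$cells, "y", q))
  jsonlite::write_json(list(x = unclass(gate_x), y = unclass(gate_y)),
                       p("gates.json"), auto_unbox = TRUE, digits = NA)
  qr <- stage("gate", classify_quadrants(an$cells, gate_x, gate_y))
  readr::write_csv(tidy(qr), p("quadrants.csv"))

  flow <- stage("flow", simulate_flow_readings(sim$truth, config,
                                               seed = config$seed + 7L))
  readr::write_csv(flow, p("flow_sample.csv"))

  asn <- stage("spatial", assign_colonies(qr$cells,
                                          field_shape = config$field_shape))
  scored <- stage("spatial", edge_scores(asn))
  readr::write_csv(scored, p("cells_spatial.csv"))
  readr::write_csv(asn$colonies, p("colonies.csv"))
  enr <- if (any(scored$quadrant == enrichment_phenotype &
                   scored$colony_id > 0))
    stage("spatial",
          phenotype_edge_enrichment(scored, enrichment_phenotype,
                                    n_permutations = n_permutations,
                                    seed = config$seed + 13L))
  else NULL

  summary <- list(
    n_cells = nrow(an$cells),
    n_colonies = nrow(asn$colonies),
    pct_x_positive = percent_positive(an$cells, gate_x),
    pct_y_positive = percent_positive(an$cells, gate_y),
    quadrant_percentages = as.list(qr$percentages),
    edge_enrichment = if (!is.null(enr))
      list(phenotype = enr$phenotype, statistic = enr$statistic,
           p_value = enr$p_value) else NULL)
  manifest <- pipeline_manifest(config, out_dir, summary = summary,
                                warnings = warnings_log)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

pipeline_manifest <- function(config, out_dir, summary, warnings) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  cfg_yaml <- file.path(out_dir, "sim_config.yaml")
  list(package_version = as.character(utils::packageVersion("colonycyto")),
       seed = config$seed,
       config_md5 = unname(tools::md5sum(cfg_yaml)),
       checksums = as.list(sums),
       summary = summary,
       warnings = as.list(warnings))
}
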