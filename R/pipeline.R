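# End-to-end orchestration: normalization -> control fit -> LOD scoring
# -> hit calling -> QC and replicate concordance, with all result tables
# written to an output directory alongside a machine-readable manifest.

#' Score an arrayed viability screen end to end
#'
#' Runs per-plate normalization, fits the control model from the pooled
#' positive-control and scrambled wells, scores each gene's mean
#' normalized viability, calls hits, checks screen QC, and computes
#' replicate concordance when at least two replicates exist. If
#' `out_dir` is given, writes `normalized.csv`, `hits.csv`,
#' `concordance.csv`, `qc.json` and `manifest.json`.
#'
#' @param plate_map plate-map data.frame or CSV path.
#' @param readouts readout data.frame or CSV path.
#' @param cell_line label for the result tables.
#' @param reference normalization reference, "scrambled" or "mock".
#' @param lod_method "density" or "cdf_tail" (see [lod_score()]).
#' @param lod_threshold hit threshold (default 3).
#' @param qc_min_separation,qc_alpha see [screen_qc()].
#' @param background optional background override.
#' @param out_dir optional output directory.
#' @return list with `normalized`, `control_model`, `qc`, `hits`,
#'   `guide_summary`, `concordance` (NULL for single-replicate screens).
#' @export
run_score <- function(plate_map, readouts, cell_line = "screen",
                      reference = c("scrambled", "mock"),
                      lod_method = c("density", "cdf_tail"),
                      lod_threshold = 3, qc_min_separation = 3,
                      qc_alpha = 0.01, background = NULL, out_dir = NULL) {
  reference <- match.arg(reference)
  lod_method <- match.arg(lod_method)
  if (is.character(plate_map)) plate_map <- read_plate_map(plate_map)
  if (is.character(readouts)) readouts <- read_readouts(readouts)

  normalized <- normalize_plate(readouts, plate_map, reference = reference,
                                background = background)
  value_col <- paste0("viability_vs_", reference)
  v <- normalized[[value_col]]
  model <- fit_control_model(
    v[normalized$content_type == "positive_control" & !is.na(v)],
    v[normalized$content_type == "scrambled" & !is.na(v)])
  qc <- screen_qc(model, min_separation = qc_min_separation,
                  alpha = qc_alpha)

  gene_rows <- normalized[normalized$content_type == "gene", , drop = FALSE]
  guide_summary <- summarize_replicates(gene_rows, value = value_col)
  hits <- call_hits(guide_summary, model, threshold = lod_threshold,
                    method = lod_method, cell_line = cell_line)

  concordance <- NULL
  reps <- sort(unique(gene_rows$replicate))
  if (length(reps) >= 2L) {
    per_rep <- lapply(reps[1:2], function(r) {
      summarize_replicates(gene_rows[gene_rows$replicate == r, ,
                                     drop = FALSE], value = value_col)
    })
    concordance <- replicate_concordance(per_rep[[1L]], per_rep[[2L]])
  }

  result <- list(normalized = normalized, control_model = model, qc = qc,
                 hits = hits, guide_summary = guide_summary,
                 concordance = concordance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(normalized, file.path(out_dir, "normalized.csv"),
                     row.names = FALSE)
    write_result_table(hits, file.path(out_dir, "hits.csv"))
    if (!is.null(concordance)) {
      utils::write.csv(concordance$paired,
                       file.path(out_dir, "concordance.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      c(qc[c("pass", "reasons", "separation", "ks_p_pos", "ks_p_neg")],
        list(mu_pos = model$mu_pos, sigma_pos = model$sigma_pos,
             mu_neg = model$mu_neg, sigma_neg = model$sigma_neg)),
      file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, command = "score",
                   config = list(cell_line = cell_line,
                                 reference = reference,
                                 lod_method = lod_method,
                                 lod_threshold = lod_threshold,
                                 qc_min_separation = qc_min_separation,
                                 qc_alpha = qc_alpha),
                   outputs = c("normalized.csv", "hits.csv", "qc.json"))
  }
  result
}

#' Quantify image phenotypes for a set of fields
#'
#' Segments nuclei in every field, measures per-object areas and
#' intensities (and per-cell Golgi totals in `"golgi"` mode), pools the
#' measurements by condition, and tests each target condition against
#' the scrambled condition.
#'
#' @param fields named list of [image_field()] objects; names are
#'   condition labels, the scrambled/control condition named by
#'   `scrambled_label`. Several fields may share a condition by using
#'   names like `"scrambled.1"`, `"scrambled.2"` (suffix after the last
#'   dot is ignored).
#' @param measure phenotype to extract: per-object `"intensity"`
#'   (marker channel mean), `"area"`, or per-cell `"golgi"` totals.
#' @param test group test, "mann_whitney" or "ks".
#' @param scrambled_label control condition name.
#' @param out_dir optional output directory for per-object CSVs and the
#'   comparison report.
#' @param ... segmentation parameters passed to [segment_nuclei()].
#' @return list with `measurements` (data.frame condition/field_id/value)
#'   and `comparisons` (one row per non-control condition).
#' @export
run_phenotype <- function(fields, measure = c("intensity", "area", "golgi"),
                          test = c("mann_whitney", "ks"),
                          scrambled_label = "scrambled", out_dir = NULL,
                          ...) {
  measure <- match.arg(measure)
  test <- match.arg(test)
  if (is.null(names(fields)) || any(names(fields) == "")) {
    stop("fields must be a named list (names = condition labels)")
  }
  condition <- sub("\\.[^.]*$", "", names(fields))
  rows <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    seg <- segment_nuclei(f, ...)
    vals <- switch(measure,
      intensity = unname(measure_nuclear_intensity(seg, "signal")),
      area = measure_nuclear_area(seg)$area_px,
      golgi = segment_golgi(f, seg)$total_intensity)
    if (length(vals)) {
      rows[[i]] <- data.frame(condition = condition[i],
                              field_id = f$field_id, value = vals)
    }
  }
  measurements <- do.call(rbind, rows)
  if (!scrambled_label %in% measurements$condition) {
    stop("no fields for the control condition '", scrambled_label, "'")
  }
  ctrl <- measurements$value[measurements$condition == scrambled_label]
  targets <- setdiff(unique(measurements$condition), scrambled_label)
  comparisons <- do.call(rbind, lapply(targets, function(tg) {
    cmp <- compare_groups(
      measurements$value[measurements$condition == tg], ctrl, test = test)
    data.frame(condition = tg, test = cmp$test, p_value = cmp$p_value,
               normalized_effect = cmp$normalized_effect,
               n_target = cmp$n_target, n_scrambled = cmp$n_scrambled)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements,
                     file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    if (!is.null(comparisons)) {
      utils::write.csv(comparisons,
                       file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    write_manifest(out_dir, command = "phenotype",
                   config = list(measure = measure, test = test),
                   outputs = c("measurements.csv", "comparisons.csv"))
  }
  list(measurements = measurements, comparisons = comparisons)
}

#' Targetability analysis of a turnover table
#'
#' @param turnover turnover data.frame or CSV path (see
#'   [read_turnover_table()]).
#' @param threshold_h half-life threshold in hours (default 120).
#' @param out_dir optional output directory (`half_lives.csv`,
#'   `targetability.json`).
#' @return the [proteome_targetability_summary()] list, plus `n_skipped`.
#' @export
run_targetability <- function(turnover, threshold_h = 120, out_dir = NULL) {
  n_skipped <- 0L
  if (is.character(turnover)) {
    turnover <- read_turnover_table(turnover)
    n_skipped <- attr(turnover, "n_skipped")
  }
  summ <- proteome_targetability_summary(turnover, threshold_h = threshold_h)
  summ$n_skipped <- n_skipped
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summ$per_protein,
                     file.path(out_dir, "half_lives.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(fraction_hard = summ$fraction_hard, n = summ$n,
           threshold_h = threshold_h, n_skipped = n_skipped),
      file.path(out_dir, "targetability.json"),
      auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, command = "targetability",
                   config = list(threshold_h = threshold_h),
                   outputs = c("half_lives.csv", "targetability.json"))
  }
  summ
}

# Machine-readable run manifest (command, config, output files with md5
# checksums, package version) so a run can be reproduced and verified.
write_manifest <- function(out_dir, command, config, outputs) {
  files <- file.path(out_dir, outputs)
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    config = config,
    package = "arrayscreen",
    version = as.character(utils::packageVersion("arrayscreen")),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Replicate-concordance scatter plot
#'
#' Courtesy plot of the paired per-guide table from
#' [replicate_concordance()]; the table itself is the tested artifact.
#'
#' @param concordance output of [replicate_concordance()].
#' @return a ggplot object.
#' @export
plot_concordance <- function(concordance) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(concordance$paired,
                  ggplot2::aes(x = .data$value_1, y = .data$value_2)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "replicate 1 viability", y = "replicate 2 viability",
                  subtitle = sprintf("Pearson r = %.3f",
                                     concordance$pearson))
}
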