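# Background subtraction and control normalization of raw luminescence.
#
# Relative viability is computed per plate: raw values are background
# subtracted (background = mean of designated blank wells, unless
# overridden) and divided by the mean background-subtracted signal of the
# reference wells (no-transfection mocks or non-targeting scrambled
# guides) on the same plate.

#' Estimate per-plate background from blank wells
#'
#' Background is the mean raw luminescence over the plate's blank wells.
#' If a plate has no blanks and no override is supplied, the background
#' falls back to 0 with a warning.
#'
#' @param readouts readout data.frame (see [read_readouts()]).
#' @param plate_map plate-map data.frame (see [read_plate_map()]).
#' @param override optional named numeric vector `plate_id -> background`,
#'   or a single number applied to all plates; takes precedence over blanks.
#' @return named numeric vector of background levels, one per plate.
#' @export
estimate_background <- function(readouts, plate_map, override = NULL) {
  plates <- unique(readouts$plate_id)
  bg <- stats::setNames(numeric(length(plates)), plates)
  for (p in plates) {
    if (!is.null(override)) {
      ov <- if (is.null(names(override))) override[[1L]] else override[[p]]
      if (!is.null(ov) && !is.na(ov)) {
        bg[[p]] <- as.numeric(ov)
        next
      }
    }
    blanks <- plate_map$well[plate_map$plate_id == p &
                               plate_map$content_type == "blank"]
    vals <- readouts$raw_luminescence[readouts$plate_id == p &
                                        readouts$well %in% blanks]
    if (length(vals)) {
      bg[[p]] <- mean(vals)
    } else {
      warning("plate ", p, ": no blank wells and no override; background = 0")
      bg[[p]] <- 0
    }
  }
  bg
}

#' Normalize raw luminescence to relative viability
#'
#' For each well, viability is `max(0, raw - background)` divided by the
#' plate mean of `raw - background` over the reference wells. Both the
#' mock-referenced and scrambled-referenced columns are populated whenever
#' the respective reference wells exist on the plate; the `reference`
#' argument selects which one must exist (its absence is an error, the
#' other's a missing-reference flag). Wells whose background-subtracted
#' signal is negative are clamped to 0 and flagged `clamped_negative`.
#' Wells present in the plate map but absent from the readouts are kept
#' with NA viability and flagged `missing_readout`.
#'
#' @param readouts readout data.frame.
#' @param plate_map plate-map data.frame.
#' @param reference required reference control type, "mock" or "scrambled".
#' @param background optional background override (see
#'   [estimate_background()]).
#' @return data.frame with per-well `viability_vs_mock`,
#'   `viability_vs_scrambled` and a `qc_flags` character column
#'   (`;`-separated flags, empty when clean).
#' @export
normalize_plate <- function(readouts, plate_map,
                            reference = c("mock", "scrambled"),
                            background = NULL) {
  reference <- match.arg(reference)
  ref_ct <- c(mock = "mock", scrambled = "scrambled")[[reference]]
  plate_map <- validate_plate_map(plate_map)
  readouts <- validate_readouts(readouts)
  bg <- estimate_background(readouts, plate_map, override = background)

  tab <- merge(plate_map, readouts, by = c("plate_id", "well"),
               all.x = TRUE, sort = FALSE)
  tab <- tab[order(tab$plate_id, tab$row, tab$col), ]
  tab$viability_vs_mock <- NA_real_
  tab$viability_vs_scrambled <- NA_real_
  flags <- vector("list", nrow(tab))

  for (p in unique(tab$plate_id)) {
    idx <- which(tab$plate_id == p)
    raw <- tab$raw_luminescence[idx]
    sub <- raw - bg[[p]]
    clamped <- !is.na(sub) & sub < 0
    v <- pmax(sub, 0)
    for (ref in c("mock", "scrambled")) {
      rsel <- tab$content_type[idx] == ref & !is.na(sub)
      n_ref <- sum(rsel)
      if (ref == ref_ct && n_ref < 2L) {
        stop("plate ", p, ": fewer than 2 usable ", ref,
             " reference wells (missing_reference)")
      }
      if (n_ref == 0L) next
      denom <- mean(sub[rsel])
      if (denom <= 0) {
        stop("plate ", p, ": non-positive mean signal in ", ref,
             " reference wells")
      }
      col <- paste0("viability_vs_", ref)
      tab[[col]][idx] <- v / denom
    }
    for (k in seq_along(idx)) {
      f <- character(0)
      if (is.na(raw[k])) f <- c(f, "missing_readout")
      if (clamped[k]) f <- c(f, "clamped_negative")
      if (is.na(tab$viability_vs_mock[idx[k]]) && !is.na(raw[k])) {
        f <- c(f, "missing_reference")
      }
      flags[[idx[k]]] <- f
    }
  }
  tab$qc_flags <- vapply(flags, paste, character(1), collapse = ";")
  rownames(tab) <- NULL
  tab[c("plate_id", "well", "row", "col", "content_type", "gene_symbol",
        "guide_id", "replicate", "raw_luminescence",
        "viability_vs_mock", "viability_vs_scrambled", "qc_flags")]
}

#' Summarize normalized viability across replicate wells
#'
#' Mean and sample (n - 1) standard deviation per guide across replicate
#' wells; sd is NA for single-replicate guides.
#'
#' @param normalized output of [normalize_plate()], possibly row-bound
#'   across plates; must contain the viability column selected by `value`.
#' @param value which normalized column to summarize.
#' @param by grouping columns; defaults to guide identity.
#' @return data.frame with `mean`, `sd`, `n` per group.
#' @export
summarize_replicates <- function(normalized,
                                 value = c("viability_vs_scrambled",
                                           "viability_vs_mock"),
                                 by = c("content_type", "gene_symbol",
                                        "guide_id")) {
  value <- match.arg(value)
  keep <- !is.na(normalized[[value]])
  d <- normalized[keep, , drop = FALSE]
  key <- do.call(paste, c(d[by], sep = "\r"))
  out <- d[!duplicated(key), by, drop = FALSE]
  groups <- split(d[[value]], key)[unique(key)]
  out$mean <- vapply(groups, mean, numeric(1))
  out$sd <- vapply(groups, function(x) {
    if (length(x) > 1L) stats::sd(x) else NA_real_
  }, numeric(1))
  out$n <- vapply(groups, length, integer(1))
  rownames(out) <- NULL
  out
}
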