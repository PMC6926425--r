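# Image-based phenotype quantification.
#
# Nuclei are segmented from the nuclear-stain channel (median filter ->
# Otsu threshold -> hole filling -> distance-transform watershed to split
# touching nuclei); per-nucleus mean intensities and areas feed the
# marker-level and nuclear-size phenotypes. Punctate Golgi signal is
# segmented with a white top-hat filter and summed per cell region
# (nearest-nucleus assignment bounded by a dilation radius), corrected
# for background estimated outside all cell regions.

#' Construct a two-channel image field
#'
#' @param nuclear numeric matrix of nuclear-stain intensities (>= 0).
#' @param signal numeric matrix of marker-channel intensities, same shape;
#'   defaults to the nuclear channel when the experiment has no second
#'   channel.
#' @param pixel_size physical pixel size in microns/pixel (NA if unknown).
#' @param field_id identifier carried into measurement tables.
#' @return object of class `image_field`.
#' @export
image_field <- function(nuclear, signal = NULL, pixel_size = NA_real_,
                        field_id = "field") {
  nuclear <- as.matrix(nuclear)
  if (is.null(signal)) signal <- nuclear
  signal <- as.matrix(signal)
  if (!all(dim(nuclear) == dim(signal))) {
    stop("nuclear and signal channels must have the same shape")
  }
  if (any(!is.finite(nuclear)) || any(!is.finite(signal)) ||
      any(nuclear < 0) || any(signal < 0)) {
    stop("channel intensities must be finite and >= 0")
  }
  structure(list(nuclear = nuclear, signal = signal,
                 pixel_size = pixel_size, field_id = field_id),
            class = "image_field")
}

#' Read an image field from TIFF file(s)
#'
#' @param nuclear_path TIFF with the nuclear stain. A two-frame TIFF is
#'   read as (nuclear, signal) when `signal_path` is NULL.
#' @param signal_path optional TIFF with the marker channel.
#' @param pixel_size,field_id metadata, see [image_field()].
#' @return an `image_field`.
#' @export
read_image_field <- function(nuclear_path, signal_path = NULL,
                             pixel_size = NA_real_,
                             field_id = basename(nuclear_path)) {
  img <- EBImage::imageData(EBImage::readImage(nuclear_path))
  if (length(dim(img)) == 3L && is.null(signal_path)) {
    return(image_field(img[, , 1L], img[, , 2L], pixel_size, field_id))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  sig <- NULL
  if (!is.null(signal_path)) {
    sig <- EBImage::imageData(EBImage::readImage(signal_path))
    if (length(dim(sig)) == 3L) sig <- sig[, , 1L]
  }
  image_field(img, sig, pixel_size, field_id)
}

#' Write / read a label map as 16-bit TIFF
#'
#' Labels up to 65535 round-trip exactly.
#'
#' @param label_map integer matrix (0 = background).
#' @param path TIFF path.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(max(label_map) <= 65535L)
  EBImage::writeImage(EBImage::Image(label_map / 65535), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 65535)), nrow = nrow(img))
}

# Rescale a channel to [0, 1] for the threshold/filter steps (EBImage
# expects normalized grayscale); measurements always use raw intensities.
.norm01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) stop("no foreground: channel is constant")
  (x - rng[1L]) / diff(rng)
}

# Per-object measurement table from a label map and the two raw channels.
.object_table <- function(label_map, nuclear, signal) {
  labs <- sort(unique(as.integer(label_map[label_map > 0])))
  if (!length(labs)) {
    return(data.frame(label = integer(0), area_px = integer(0),
                      centroid_r = numeric(0), centroid_c = numeric(0),
                      mean_nuc = numeric(0), total_nuc = numeric(0),
                      mean_signal = numeric(0), total_signal = numeric(0)))
  }
  idx <- which(label_map > 0)
  lab <- as.integer(label_map[idx])
  rr <- (idx - 1L) %% nrow(label_map) + 1L
  cc <- (idx - 1L) %/% nrow(label_map) + 1L
  f <- factor(lab, levels = labs)
  sums <- function(v) as.numeric(rowsum(v, f))
  area <- as.integer(rowsum(rep(1L, length(lab)), f))
  tot_n <- sums(nuclear[idx]); tot_s <- sums(signal[idx])
  data.frame(label = labs, area_px = area,
             centroid_r = sums(rr) / area, centroid_c = sums(cc) / area,
             mean_nuc = tot_n / area, total_nuc = tot_n,
             mean_signal = tot_s / area, total_signal = tot_s)
}

# Relabel a label map so labels are contiguous 1..K.
.relabel <- function(label_map) {
  labs <- sort(unique(as.integer(label_map[label_map > 0])))
  if (!length(labs)) return(label_map)
  lut <- integer(max(labs)); lut[labs] <- seq_along(labs)
  out <- label_map
  out[out > 0] <- lut[out[out > 0]]
  out
}

#' Segment nuclei from the nuclear channel
#'
#' Median filter -> Otsu global threshold -> hole filling -> watershed on
#' the distance transform to split touching nuclei -> discard objects
#' outside the area bounds or touching the image border. Thresholding
#' operates on the min-max rescaled channel, so segmentation is invariant
#' to affine intensity rescaling; measurements use the raw channels.
#'
#' @param field an [image_field()].
#' @param smooth_radius median filter radius in px.
#' @param min_area_px,max_area_px object area bounds in px.
#' @param watershed_tolerance minimum distance-transform height (px)
#'   separating two watershed seeds; ties in the underlying sort are
#'   broken by pixel order, so splitting is deterministic.
#' @return list of class `segmentation` with `label_map` (integer matrix,
#'   labels contiguous 1..K) and `objects` (per-object measurement
#'   data.frame).
#' @export
segment_nuclei <- function(field, smooth_radius = 2L, min_area_px = 50L,
                           max_area_px = Inf, watershed_tolerance = 1) {
  stopifnot(inherits(field, "image_field"))
  x <- .norm01(field$nuclear)
  img <- EBImage::Image(x)
  if (smooth_radius > 0) img <- EBImage::medianFilter(img, smooth_radius)
  thr <- EBImage::otsu(img)
  mask <- EBImage::fillHull(img > thr)
  if (sum(mask) == 0) stop("no foreground: empty mask after thresholding")
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1L)
  lab <- EBImage::imageData(lab)
  lab <- matrix(as.integer(lab), nrow = nrow(lab))

  border <- unique(as.integer(c(lab[1L, ], lab[nrow(lab), ],
                                lab[, 1L], lab[, ncol(lab)])))
  areas <- table(lab[lab > 0])
  bad_area <- as.integer(names(areas))[areas < min_area_px |
                                         areas > max_area_px]
  drop <- union(setdiff(border, 0L), bad_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- .relabel(lab)
  structure(list(label_map = lab,
                 objects = .object_table(lab, field$nuclear, field$signal),
                 field_id = field$field_id,
                 pixel_size = field$pixel_size),
            class = "segmentation")
}

#' Mean per-nucleus intensity of a channel
#'
#' @param seg a [segment_nuclei()] result.
#' @param channel "signal" (marker, default) or "nuclear".
#' @return numeric vector of per-object mean intensities, in label order.
#' @export
measure_nuclear_intensity <- function(seg, channel = c("signal", "nuclear")) {
  channel <- match.arg(channel)
  col <- if (channel == "signal") "mean_signal" else "mean_nuc"
  stats::setNames(seg$objects[[col]], seg$objects$label)
}

#' Per-nucleus areas
#'
#' @param seg a [segment_nuclei()] result.
#' @return data.frame with `label`, `area_px` and, when the field carried
#'   a pixel size, `area_um2 = area_px * pixel_size^2`.
#' @export
measure_nuclear_area <- function(seg) {
  out <- seg$objects[c("label", "area_px")]
  if (!is.na(seg$pixel_size)) {
    out$area_um2 <- out$area_px * seg$pixel_size^2
  }
  out
}

#' Per-cell total punctate (Golgi) intensity
#'
#' Cell regions are built by assigning every pixel within
#' `cell_dilation_px` of a nucleus to its nearest nucleus. Puncta are
#' segmented in the signal channel by a white top-hat filter (disc radius
#' `tophat_radius_px`) followed by Otsu thresholding; the fragment mask is
#' grown by `halo_px` so the faint rim of each punctum is captured. The
#' per-cell value is the raw-signal sum over its fragment pixels minus
#' (fragment pixel count x median signal outside all cell regions).
#'
#' @param field an [image_field()] whose signal channel holds the
#'   punctate marker.
#' @param nuclei a [segment_nuclei()] result for the same field.
#' @param cell_dilation_px maximum distance (px) a cell region extends
#'   from its nucleus.
#' @param tophat_radius_px top-hat structuring-element radius in px;
#'   structures larger than this are treated as local background.
#' @param halo_px dilation of the fragment mask before intensity
#'   summation.
#' @return data.frame with `label`, `n_fragment_px`, `total_intensity`
#'   (background-corrected).
#' @export
segment_golgi <- function(field, nuclei, cell_dilation_px = 25L,
                          tophat_radius_px = 5L, halo_px = 2L) {
  stopifnot(inherits(field, "image_field"), inherits(nuclei, "segmentation"))
  lab <- nuclei$label_map
  if (max(lab) == 0L) stop("no foreground: segmentation has no nuclei")

  disc <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")
  nuc_mask <- EBImage::Image(lab > 0)
  reach <- EBImage::dilate(nuc_mask, disc(cell_dilation_px))
  cells <- EBImage::propagate(EBImage::Image(array(0, dim(lab))),
                              seeds = EBImage::Image(lab),
                              mask = reach, lambda = 1e4)
  cells <- matrix(as.integer(EBImage::imageData(cells)), nrow = nrow(lab))

  sig_raw <- field$signal
  rng <- range(sig_raw)
  frag <- matrix(FALSE, nrow(sig_raw), ncol(sig_raw))
  if (diff(rng) > 0) {
    th <- EBImage::whiteTopHat(EBImage::Image(.norm01(sig_raw)),
                               disc(tophat_radius_px))
    th_max <- max(th)
    if (th_max > 0) {
      thr <- EBImage::otsu(th / th_max) * th_max
      fm <- th > thr
      if (halo_px > 0) fm <- EBImage::dilate(fm, disc(halo_px))
      frag <- EBImage::imageData(fm) > 0
    }
  }

  outside <- cells == 0L
  bg <- if (any(outside)) stats::median(sig_raw[outside]) else 0
  labs <- sort(unique(as.integer(lab[lab > 0])))
  out <- data.frame(label = labs, n_fragment_px = 0L, total_intensity = 0)
  sel <- frag & cells > 0L
  if (any(sel)) {
    f <- factor(cells[sel], levels = labs)
    cnt <- as.integer(rowsum(rep(1L, sum(sel)), f))
    cnt[is.na(cnt)] <- 0L
    tot <- as.numeric(rowsum(sig_raw[sel], f))
    tot[is.na(tot)] <- 0
    out$n_fragment_px <- cnt
    out$total_intensity <- tot - cnt * bg
  }
  out
}

#' Compare a target condition against scrambled controls
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) or Kolmogorov-Smirnov
#' test on per-object (or per-cell) measurements, with the effect size
#' reported as the target median normalized to the scrambled median.
#'
#' @param target,scrambled numeric vectors of measurements, each n >= 3.
#' @param test "mann_whitney" or "ks".
#' @return list with `test`, `p_value`, `median_target`,
#'   `median_scrambled`, `normalized_effect`, `n_target`, `n_scrambled`.
#' @export
compare_groups <- function(target, scrambled,
                           test = c("mann_whitney", "ks")) {
  test <- match.arg(test)
  if (length(target) < 3L || length(scrambled) < 3L) {
    stop("insufficient data: each group needs >= 3 values")
  }
  p <- if (test == "mann_whitney") {
    stats::wilcox.test(target, scrambled)$p.value
  } else {
    suppressWarnings(stats::ks.test(target, scrambled)$p.value)
  }
  m_t <- stats::median(target); m_s <- stats::median(scrambled)
  list(test = test, p_value = p, median_target = m_t,
       median_scrambled = m_s,
       normalized_effect = m_t / m_s,
       n_target = length(target), n_scrambled = length(scrambled))
}

#' Rule-based object exclusion
#'
#' Deterministic surrogate for the manual curation step of high-content
#' screens: excludes border-touching objects, low-solidity objects
#' (debris/merged shapes), and abnormally bright objects (mitotic or
#' stain-artifact cells) whose mean nuclear intensity exceeds a pixel
#' percentile of the nuclear channel. All rules default to off; with no
#' rules the filter is the identity.
#'
#' @param seg a [segment_nuclei()] result.
#' @param field the originating [image_field()]; required for the
#'   intensity-percentile rule.
#' @param max_intensity_percentile exclude objects whose mean nuclear
#'   intensity exceeds this percentile (0-1) of nuclear-channel pixels.
#' @param solidity_min exclude objects whose area / convex hull area
#'   falls below this value.
#' @param border_exclusion exclude objects touching the image border.
#' @return list with `seg` (filtered segmentation, labels recompacted)
#'   and `excluded` (data.frame of label + reason).
#' @export
object_qc_filter <- function(seg, field = NULL,
                             max_intensity_percentile = NULL,
                             solidity_min = NULL,
                             border_exclusion = FALSE) {
  stopifnot(inherits(seg, "segmentation"))
  obj <- seg$objects
  lab <- seg$label_map
  excluded <- data.frame(label = integer(0), reason = character(0))
  note <- function(labels, why) {
    if (length(labels)) {
      excluded <<- rbind(excluded,
                         data.frame(label = labels, reason = why))
    }
  }
  if (border_exclusion && nrow(obj)) {
    border <- setdiff(unique(as.integer(c(lab[1L, ], lab[nrow(lab), ],
                                          lab[, 1L], lab[, ncol(lab)]))), 0L)
    note(border, "border")
  }
  if (!is.null(max_intensity_percentile) && nrow(obj)) {
    if (is.null(field)) stop("intensity rule requires the image field")
    cut <- stats::quantile(field$nuclear, max_intensity_percentile)
    note(obj$label[obj$mean_nuc > cut], "bright")
  }
  if (!is.null(solidity_min) && nrow(obj)) {
    sol <- vapply(obj$label, function(l) .solidity(lab == l), numeric(1))
    note(obj$label[sol < solidity_min], "low_solidity")
  }
  excluded <- excluded[!duplicated(excluded$label), , drop = FALSE]
  if (nrow(excluded)) {
    lab[lab %in% excluded$label] <- 0L
    lab <- .relabel(lab)
  }
  out <- seg
  out$label_map <- lab
  out$objects <- if (nrow(excluded)) {
    kept <- !(seg$objects$label %in% excluded$label)
    o <- seg$objects[kept, , drop = FALSE]
    o$label <- seq_len(nrow(o))
    rownames(o) <- NULL
    o
  } else {
    seg$objects
  }
  list(seg = out, excluded = excluded)
}

# Solidity = object area / convex hull area (shoelace on the hull of
# pixel centers, padded by ~0.5 px of pixel extent).
.solidity <- function(mask) {
  idx <- which(mask)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  if (length(idx) < 4L) return(1)
  pts <- cbind(r, c)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  j <- c(2:n, 1L)
  hull_area <- abs(sum(hp[, 1L] * hp[j, 2L] - hp[j, 1L] * hp[, 2L])) / 2
  # hull of pixel centers misses the half-pixel rim; add perimeter/2 + 1
  per <- sum(sqrt(rowSums((hp - hp[j, , drop = FALSE])^2)))
  min(1, length(idx) / (hull_area + per / 2 + 1))
}
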