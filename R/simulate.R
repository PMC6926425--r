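# Seeded synthetic-data generators.
#
# Every generator is a pure function of its parameters and seed: the
# caller's RNG state is saved and restored, and the same seed reproduces
# the output bit for bit. Generators emit the ground truth needed to
# score every downstream stage (true per-well effects, true object masks
# and intensities, intended half-lives).

# Run code under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Multiplicative log-normal noise with unit mean and coefficient of
# variation cv (luminescence is positive and noise scales with signal).
.lognorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Default arrayed-screen plate layout
#'
#' Builds a 96- or 384-well layout with mock (no-transfection) wells in
#' column 1, scrambled negative controls in column 2, essential-gene
#' positive controls in column 3, blank wells at the top of the last
#' column, and one well per gene filling the remainder row-major.
#'
#' @param genes character vector of gene symbols (one well each).
#' @param format 96 or 384.
#' @param plate_id,replicate plate annotation.
#' @param n_blank number of blank wells.
#' @param positive_gene symbol used for the positive-control guides.
#' @return plate-map data.frame (see [read_plate_map()] for the schema).
#' @export
default_plate_layout <- function(genes, format = 96, plate_id = "plate1",
                                 replicate = 1L, n_blank = 4L,
                                 positive_gene = "POLR2A") {
  format <- as.integer(as.character(format))
  nr <- if (format == 96L) 8L else 16L
  nc <- if (format == 96L) 12L else 24L
  grid <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  grid$well <- rc_to_well(grid$row, grid$col)
  ct <- rep("gene", nrow(grid))
  ct[grid$col == 0L] <- "mock"
  ct[grid$col == 1L] <- "scrambled"
  ct[grid$col == 2L] <- "positive_control"
  ct[grid$col == nc - 1L & grid$row < n_blank] <- "blank"
  gene_slots <- which(ct == "gene")
  if (length(genes) > length(gene_slots)) {
    stop("too many genes for a ", format, "-well layout (",
         length(gene_slots), " gene wells)")
  }
  gene_sym <- rep("", nrow(grid))
  guide <- rep("", nrow(grid))
  use <- gene_slots[seq_along(genes)]
  ct[setdiff(gene_slots, use)] <- "blank"  # unused wells left empty
  gene_sym[use] <- genes
  guide[use] <- paste0(genes, "_g1")
  scr <- which(ct == "scrambled")
  guide[scr] <- sprintf("scr_%02d", seq_along(scr))
  pos <- which(ct == "positive_control")
  gene_sym[pos] <- positive_gene
  guide[pos] <- sprintf("%s_g%d", positive_gene, seq_along(pos))
  validate_plate_map(data.frame(
    plate_id = plate_id, well = grid$well, content_type = ct,
    gene_symbol = gene_sym, guide_id = guide, replicate = replicate,
    stringsAsFactors = FALSE))
}

#' Simulate raw luminescence readouts for one plate
#'
#' The raw value of a well is
#' `blank_mean + (mock_mean - blank_mean) * effect * noise`, with
#' log-normal multiplicative noise of the given coefficient of
#' variation. Blank wells have effect 0, mocks 1, scrambled wells
#' `scrambled_effect`, positive controls `positive_effect` (default 0.15,
#' i.e. an 85% viability loss typical of an essential-gene control), and
#' gene wells the value in `gene_effects` (default 1, neutral).
#'
#' @param plate_map plate-map data.frame for one or more plates.
#' @param mock_mean,blank_mean raw luminescence of untreated and empty
#'   wells.
#' @param scrambled_effect,positive_effect relative viability of the
#'   control wells.
#' @param gene_effects named numeric vector, gene symbol -> relative
#'   viability.
#' @param noise_cv multiplicative noise CV (default 0.05).
#' @param seed RNG seed.
#' @return list with `plate_map`, `readouts`, and `truth` (per-well true
#'   effect).
#' @export
simulate_plate <- function(plate_map, mock_mean = 1.1e6, blank_mean = 1e5,
                           scrambled_effect = 1.0, positive_effect = 0.15,
                           gene_effects = NULL, noise_cv = 0.05,
                           seed = 1L) {
  pm <- validate_plate_map(plate_map)
  effect <- numeric(nrow(pm))
  effect[pm$content_type == "mock"] <- 1
  effect[pm$content_type == "blank"] <- 0
  effect[pm$content_type == "scrambled"] <- scrambled_effect
  effect[pm$content_type == "positive_control"] <- positive_effect
  gi <- pm$content_type == "gene"
  effect[gi] <- 1
  if (!is.null(gene_effects)) {
    hit <- gi & pm$gene_symbol %in% names(gene_effects)
    effect[hit] <- gene_effects[pm$gene_symbol[hit]]
  }
  stopifnot(all(effect >= 0), noise_cv >= 0)
  raw <- with_seed(seed, {
    noise <- .lognorm_noise(nrow(pm), noise_cv)
    blank_mean + (mock_mean - blank_mean) * effect * noise
  })
  readouts <- data.frame(plate_id = pm$plate_id, well = pm$well,
                         raw_luminescence = raw, stringsAsFactors = FALSE)
  truth <- cbind(pm[c("plate_id", "well", "content_type", "gene_symbol",
                      "guide_id")],
                 true_effect = effect)
  list(plate_map = pm, readouts = readouts, truth = truth)
}

#' Simulate a two-cell-line arrayed screen with planted lethal genes
#'
#' Each cell line gets `n_replicates` replicate plates of the same
#' layout. `shared_lethal` genes are lethal in both lines;
#' `specific_lethal` maps a cell line to genes lethal only there; all
#' other genes are neutral (effect 1).
#'
#' @param cell_lines character vector of cell line names.
#' @param n_genes total number of gene wells per plate.
#' @param shared_lethal number of shared lethal genes, or a character
#'   vector of gene symbols.
#' @param specific_lethal named list, cell line -> gene symbols lethal in
#'   that line only; defaults to one line-specific gene per line.
#' @param lethal_effect relative viability of lethal knockouts
#'   (default 0.2).
#' @param n_replicates replicate plates per line.
#' @param seed RNG seed; each plate derives its own sub-seed.
#' @param ... further parameters passed to [simulate_plate()].
#' @return list keyed by cell line, each with `plate_map`, `readouts`,
#'   `truth`; gene panels attached as attributes `genes`,
#'   `shared_lethal`, `specific_lethal`.
#' @export
simulate_screen <- function(cell_lines = c("line_A", "line_B"),
                            n_genes = 45L, shared_lethal = 5L,
                            specific_lethal = NULL, lethal_effect = 0.2,
                            n_replicates = 2L, seed = 1L, ...) {
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  if (is.numeric(shared_lethal)) {
    shared_lethal <- genes[seq_len(shared_lethal)]
  }
  if (is.null(specific_lethal)) {
    pool <- setdiff(genes, shared_lethal)
    specific_lethal <- stats::setNames(
      as.list(pool[seq_along(cell_lines)]), cell_lines)
  }
  out <- list()
  for (i in seq_along(cell_lines)) {
    cl <- cell_lines[i]
    lethal <- union(shared_lethal, unlist(specific_lethal[[cl]]))
    eff <- stats::setNames(rep(lethal_effect, length(lethal)), lethal)
    maps <- list(); reads <- list(); truths <- list()
    for (r in seq_len(n_replicates)) {
      pm <- default_plate_layout(genes,
                                 plate_id = sprintf("%s_rep%d", cl, r),
                                 replicate = r)
      sim <- simulate_plate(pm, gene_effects = eff,
                            seed = seed + 1000L * i + r, ...)
      maps[[r]] <- sim$plate_map
      reads[[r]] <- sim$readouts
      truths[[r]] <- sim$truth
    }
    out[[cl]] <- list(plate_map = do.call(rbind, maps),
                      readouts = do.call(rbind, reads),
                      truth = do.call(rbind, truths))
  }
  attr(out, "genes") <- genes
  attr(out, "shared_lethal") <- shared_lethal
  attr(out, "specific_lethal") <- specific_lethal
  attr(out, "lethal_effect") <- lethal_effect
  out
}

# Render an anti-aliased disk into `img` (value added = level * pixel
# coverage, coverage = clamp(r + 0.5 - d, 0, 1)).
.add_disk <- function(img, cr, cc, r, level) {
  n <- nrow(img); m <- ncol(img)
  r0 <- max(1L, floor(cr - r - 1)); r1 <- min(n, ceiling(cr + r + 1))
  c0 <- max(1L, floor(cc - r - 1)); c1 <- min(m, ceiling(cc + r + 1))
  rr <- r0:r1; cc2 <- c0:c1
  d <- sqrt(outer((rr - cr)^2, (cc2 - cc)^2, `+`))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  img[rr, cc2] <- img[rr, cc2] + level * cov
  img
}

# Render a 2-D Gaussian spot truncated at 3 sigma; returns the image and
# the actually deposited (rendered) integrated intensity.
.add_gaussian <- function(img, cr, cc, sigma, total) {
  n <- nrow(img); m <- ncol(img)
  ext <- ceiling(3 * sigma)
  r0 <- max(1L, floor(cr - ext)); r1 <- min(n, ceiling(cr + ext))
  c0 <- max(1L, floor(cc - ext)); c1 <- min(m, ceiling(cc + ext))
  rr <- r0:r1; cc2 <- c0:c1
  d2 <- outer((rr - cr)^2, (cc2 - cc)^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  g[d2 > (3 * sigma)^2] <- 0
  g <- g * (total / (2 * pi * sigma^2))
  img[rr, cc2] <- img[rr, cc2] + g
  list(img = img, rendered = sum(g))
}

#' Simulate a fluorescence microscopy field with ground truth
#'
#' Nuclei are anti-aliased disks; a `touching_fraction` of them is placed
#' in pairs at a center distance of 0.8 x the summed radii so the
#' watershed split step is exercised. The signal channel either repeats
#' the nuclear footprint at `signal_level` (`"nuclear_marker"`, for
#' Ki67/POLR2A-style readouts) or scatters `n_puncta` Gaussian spots of
#' integrated intensity `punctum_total` just outside each nucleus
#' (`"golgi_puncta"`). Background is added to both channels, then
#' Gaussian and optional Poisson noise.
#'
#' @param size field side length in px.
#' @param n_nuclei number of nuclei.
#' @param radius_mean,radius_sd nuclear radius distribution (px).
#' @param radius_scale multiplier on sampled radii (e.g. 1.5 for an
#'   enlarged-nuclei condition).
#' @param touching_fraction fraction of nuclei placed in touching pairs.
#' @param nuclear_level nuclear-stain intensity per pixel.
#' @param signal_mode "nuclear_marker" or "golgi_puncta".
#' @param signal_level marker intensity (nuclear_marker mode).
#' @param n_puncta,punctum_sigma,punctum_total puncta per cell, Gaussian
#'   sigma (px) and integrated intensity per punctum (golgi mode).
#' @param background additive background level.
#' @param noise_sd additive Gaussian noise sd.
#' @param poisson apply Poisson resampling of pixel values.
#' @param seed RNG seed.
#' @param field_id field identifier.
#' @return list with `field` ([image_field()]), `truth_labels` (integer
#'   matrix, pixel-to-nucleus assignment), and `truth` (per-object
#'   centers, radii, touching flag, and rendered signal totals).
#' @export
simulate_image <- function(size = 256L, n_nuclei = 12L, radius_mean = 12,
                           radius_sd = 1.5, radius_scale = 1,
                           touching_fraction = 0, nuclear_level = 500,
                           signal_mode = c("nuclear_marker", "golgi_puncta"),
                           signal_level = 300, n_puncta = 5L,
                           punctum_sigma = 1.5, punctum_total = 2000,
                           background = 0, noise_sd = 0, poisson = FALSE,
                           seed = 1L, field_id = "synthetic") {
  signal_mode <- match.arg(signal_mode)
  stopifnot(n_nuclei >= 0, touching_fraction >= 0, touching_fraction <= 1)
  with_seed(seed, {
    radii <- pmax(3, stats::rnorm(n_nuclei, radius_mean, radius_sd)) *
      radius_scale
    n_pairs <- floor(n_nuclei * touching_fraction / 2)
    centers <- matrix(NA_real_, n_nuclei, 2)
    partner <- rep(NA_integer_, n_nuclei)
    min_gap <- 6
    ok_sep <- function(k, cr, cc, allow = integer(0)) {
      placed <- setdiff(which(!is.na(centers[, 1L])), allow)
      if (!length(placed)) return(TRUE)
      d <- sqrt((centers[placed, 1L] - cr)^2 + (centers[placed, 2L] - cc)^2)
      all(d >= radii[placed] + radii[k] + min_gap)
    }
    place <- function(k, allow = integer(0)) {
      margin <- radii[k] + 4
      for (try in seq_len(1000L)) {
        cr <- stats::runif(1, margin, size - margin)
        cc <- stats::runif(1, margin, size - margin)
        if (ok_sep(k, cr, cc, allow)) return(c(cr, cc))
      }
      stop("placement error: could not place nucleus ", k,
           " after 1000 attempts")
    }
    i <- 1L
    for (p in seq_len(n_pairs)) {
      a <- i; b <- i + 1L; i <- i + 2L
      for (try in seq_len(1000L)) {
        ca <- place(a)
        ang <- stats::runif(1, 0, 2 * pi)
        dist <- 0.8 * (radii[a] + radii[b])
        cb <- ca + dist * c(cos(ang), sin(ang))
        margin_b <- radii[b] + 4
        inb <- all(cb >= margin_b) && all(cb <= size - margin_b)
        centers[a, ] <- ca
        if (inb && ok_sep(b, cb[1L], cb[2L], allow = a)) {
          centers[b, ] <- cb
          partner[a] <- b; partner[b] <- a
          break
        }
        centers[a, ] <- NA_real_
        if (try == 1000L) stop("placement error: touching pair ", p)
      }
    }
    while (i <= n_nuclei) {
      centers[i, ] <- place(i)
      i <- i + 1L
    }

    nuc <- matrix(0, size, size)
    for (k in seq_len(n_nuclei)) {
      nuc <- .add_disk(nuc, centers[k, 1L], centers[k, 2L], radii[k],
                       nuclear_level)
    }
    # truth labels: nearest center among disks covering the pixel
    labels <- matrix(0L, size, size)
    bestd <- matrix(Inf, size, size)
    rr <- matrix(seq_len(size), size, size)
    cc <- t(rr)
    for (k in seq_len(n_nuclei)) {
      d <- sqrt((rr - centers[k, 1L])^2 + (cc - centers[k, 2L])^2)
      inside <- d <= radii[k] & d < bestd
      labels[inside] <- k
      bestd[inside] <- d[inside]
    }

    sig <- matrix(0, size, size)
    truth_signal <- rep(0, n_nuclei)
    if (signal_mode == "nuclear_marker") {
      for (k in seq_len(n_nuclei)) {
        sig <- .add_disk(sig, centers[k, 1L], centers[k, 2L], radii[k],
                         signal_level)
      }
      for (k in seq_len(n_nuclei)) {
        truth_signal[k] <- sum(sig[labels == k])
      }
    } else if (n_puncta > 0L && punctum_total > 0) {
      for (k in seq_len(n_nuclei)) {
        for (q in seq_len(n_puncta)) {
          for (try in seq_len(1000L)) {
            ang <- stats::runif(1, 0, 2 * pi)
            rad <- radii[k] + stats::runif(1, 3, 8)
            pr <- centers[k, 1L] + rad * cos(ang)
            pc <- centers[k, 2L] + rad * sin(ang)
            ext <- 3 * punctum_sigma + 1
            if (pr > ext && pr < size - ext && pc > ext && pc < size - ext &&
                bestd[round(pr), round(pc)] == Inf) {
              break
            }
          }
          res <- .add_gaussian(sig, pr, pc, punctum_sigma, punctum_total)
          sig <- res$img
          truth_signal[k] <- truth_signal[k] + res$rendered
        }
      }
    }

    nuc <- nuc + background
    sig <- sig + background
    if (noise_sd > 0) {
      nuc <- nuc + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
      sig <- sig + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
    }
    if (poisson) {
      nuc <- matrix(stats::rpois(size^2, pmax(nuc, 0)), size, size)
      sig <- matrix(stats::rpois(size^2, pmax(sig, 0)), size, size)
    }
    nuc <- pmax(nuc, 0); sig <- pmax(sig, 0)

    truth <- data.frame(
      object = seq_len(n_nuclei),
      center_r = centers[, 1L], center_c = centers[, 2L],
      radius = radii,
      touching = !is.na(partner),
      nuclear_level = nuclear_level,
      signal_total = truth_signal
    )
    list(field = image_field(nuc, sig, field_id = field_id),
         truth_labels = labels, truth = truth)
  })
}

#' Simulate a protein turnover table with known half-lives
#'
#' Intended half-lives are drawn log-normally. ED proteins get
#' `k = log(2) / t_half`; NED proteins get a fast/slow two-pool
#' parameterization (fast-pool fraction uniform in \[0.3, 0.7\], rate
#' ratio `k_fast / k_slow = 8`) rescaled so the mixture's half-life
#' equals the intended one.
#'
#' @param n number of proteins.
#' @param ed_fraction fraction of exponentially degraded proteins.
#' @param meanlog,sdlog log-normal parameters of the intended half-life
#'   distribution in hours (defaults: median 30 h, sdlog 1).
#' @param seed RNG seed.
#' @param path optional CSV output path (turnover-table schema, unused
#'   fields empty).
#' @return data.frame with the turnover-table columns plus
#'   `true_half_life_h`.
#' @export
simulate_turnover_table <- function(n, ed_fraction = 0.5,
                                    meanlog = log(30), sdlog = 1,
                                    seed = 1L, path = NULL) {
  stopifnot(n >= 1)
  tt <- with_seed(seed, {
    t_half <- stats::rlnorm(n, meanlog, sdlog)
    is_ed <- stats::runif(n) < ed_fraction
    alpha <- stats::runif(n, 0.3, 0.7)
    ratio <- 8
    k <- ifelse(is_ed, log(2) / t_half, NA_real_)
    k_fast <- rep(NA_real_, n); k_slow <- rep(NA_real_, n)
    for (j in which(!is_ed)) {
      h_unit <- half_life_2state(alpha[j], ratio, 1)  # k_slow = 1 reference
      k_slow[j] <- h_unit / t_half[j]
      k_fast[j] <- ratio * k_slow[j]
    }
    data.frame(
      protein_id = sprintf("P%05d", seq_len(n)),
      deg_class = ifelse(is_ed, "ED", "NED"),
      k = k,
      alpha = ifelse(is_ed, NA_real_, alpha),
      k_fast = k_fast, k_slow = k_slow,
      true_half_life_h = t_half,
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(path)) {
    out <- tt[c("protein_id", "deg_class", "k", "alpha", "k_fast", "k_slow")]
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  tt
}
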