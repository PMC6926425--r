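# Likelihood-ratio LOD scoring of guide effects on viability.
#
# The LOD score of a guide is log10 of the ratio of the probability that
# its normalized viability arose from the positive-control (lethal)
# distribution over the probability that it arose from the negative-
# control (scrambled, no-effect) distribution, both modelled as normals
# fitted to the control wells. LOD >= 3 (odds 1,000:1) is the
# significance threshold.

#' Fit normal models to positive and negative control viabilities
#'
#' Estimates mean and sample standard deviation for each control set,
#' tests each set for normality with a one-sample Kolmogorov-Smirnov test
#' against the fitted normal (diagnostic only; parameters are estimated
#' from the same data, so the p-values are conservative), and computes
#' the control separation `(mu_neg - mu_pos) / pooled sd`.
#'
#' @param pos_values normalized viabilities of positive-control wells
#'   (essential-gene guides, e.g. POLR2A).
#' @param neg_values normalized viabilities of negative-control wells
#'   (scrambled guides).
#' @return object of class `control_model` with elements `mu_pos`,
#'   `sigma_pos`, `mu_neg`, `sigma_neg`, `n_pos`, `n_neg`, `ks_p_pos`,
#'   `ks_p_neg`, `separation`.
#' @export
fit_control_model <- function(pos_values, neg_values) {
  pos_values <- as.numeric(pos_values)
  neg_values <- as.numeric(neg_values)
  if (sum(is.finite(pos_values)) < 3L || sum(is.finite(neg_values)) < 3L) {
    stop("insufficient controls: need >= 3 finite values per control set")
  }
  pos_values <- pos_values[is.finite(pos_values)]
  neg_values <- neg_values[is.finite(neg_values)]
  mu_pos <- mean(pos_values); sigma_pos <- stats::sd(pos_values)
  mu_neg <- mean(neg_values); sigma_neg <- stats::sd(neg_values)
  if (sigma_pos == 0 || sigma_neg == 0) {
    stop("degenerate controls: zero standard deviation in a control set")
  }
  ks <- function(x, mu, s) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean = mu, sd = s)$p.value)
  }
  n_pos <- length(pos_values); n_neg <- length(neg_values)
  pooled <- sqrt(((n_pos - 1) * sigma_pos^2 + (n_neg - 1) * sigma_neg^2) /
                   (n_pos + n_neg - 2))
  structure(list(
    mu_pos = mu_pos, sigma_pos = sigma_pos,
    mu_neg = mu_neg, sigma_neg = sigma_neg,
    n_pos = n_pos, n_neg = n_neg,
    ks_p_pos = ks(pos_values, mu_pos, sigma_pos),
    ks_p_neg = ks(neg_values, mu_neg, sigma_neg),
    separation = (mu_neg - mu_pos) / pooled
  ), class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat("Control model (normal fits to screen controls)\n")
  cat(sprintf("  positive: mu = %.4f, sigma = %.4f (n = %d, KS p = %.3g)\n",
              x$mu_pos, x$sigma_pos, x$n_pos, x$ks_p_pos))
  cat(sprintf("  negative: mu = %.4f, sigma = %.4f (n = %d, KS p = %.3g)\n",
              x$mu_neg, x$sigma_neg, x$n_neg, x$ks_p_neg))
  cat(sprintf("  separation: %.2f pooled sd\n", x$separation))
  invisible(x)
}

#' LOD score of a normalized viability value
#'
#' Default `method = "density"` is the classical likelihood-ratio form,
#' `log10( dnorm(x; mu_pos, sigma_pos) / dnorm(x; mu_neg, sigma_neg) )`.
#' `method = "cdf_tail"` replaces the densities with lower-tail cumulative
#' probabilities, scoring how far into the lethal tail a value lies. Both
#' probabilities are floored at `eps` before taking the ratio so the
#' score stays finite for extreme values.
#'
#' @param x normalized viability value(s).
#' @param model a [fit_control_model()] fit.
#' @param method "density" (default) or "cdf_tail".
#' @param eps probability floor (default 1e-300).
#' @return numeric vector of LOD scores.
#' @export
lod_score <- function(x, model, method = c("density", "cdf_tail"),
                      eps = 1e-300) {
  method <- match.arg(method)
  stopifnot(inherits(model, "control_model"), all(is.finite(x)))
  prob <- switch(method,
    density = function(mu, s) stats::dnorm(x, mu, s),
    cdf_tail = function(mu, s) stats::pnorm(x, mu, s)
  )
  p_pos <- pmax(prob(model$mu_pos, model$sigma_pos), eps)
  p_neg <- pmax(prob(model$mu_neg, model$sigma_neg), eps)
  log10(p_pos) - log10(p_neg)
}

#' Score per-guide viabilities and call hits
#'
#' Scores each guide's mean normalized viability with [lod_score()] and
#' calls a hit when LOD is at or above the threshold (inclusive, so a
#' likelihood ratio of exactly 1,000 is significant at the default 3).
#'
#' @param guide_summary data.frame with one row per guide, carrying at
#'   least `gene_symbol`, `guide_id` and `mean` (mean normalized
#'   viability); [summarize_replicates()] output fits directly.
#' @param model a [fit_control_model()] fit.
#' @param threshold LOD hit threshold (default 3).
#' @param method passed to [lod_score()].
#' @param cell_line optional label attached to the result rows.
#' @return data.frame sorted by descending LOD with columns `cell_line`,
#'   `gene_symbol`, `guide_id`, `n_replicates`,
#'   `mean_normalized_viability`, `lod`, `hit`.
#' @export
call_hits <- function(guide_summary, model, threshold = 3,
                      method = c("density", "cdf_tail"),
                      cell_line = NA_character_) {
  method <- match.arg(method)
  res <- data.frame(
    cell_line = cell_line,
    gene_symbol = guide_summary$gene_symbol,
    guide_id = guide_summary$guide_id,
    n_replicates = if ("n" %in% names(guide_summary)) guide_summary$n else NA,
    mean_normalized_viability = guide_summary$mean,
    stringsAsFactors = FALSE
  )
  res$lod <- lod_score(res$mean_normalized_viability, model, method = method)
  res$hit <- res$lod >= threshold
  res <- res[order(-res$lod), ]
  rownames(res) <- NULL
  res
}

#' Screen quality control from the fitted control model
#'
#' High LOD scores require narrow, well-separated control distributions;
#' the screen fails QC if the controls are closer than `min_separation`
#' pooled standard deviations or if either control set deviates from
#' normality at level `alpha` (KS diagnostic).
#'
#' @param model a [fit_control_model()] fit.
#' @param min_separation minimum control separation in pooled sd
#'   (default 3).
#' @param alpha normality-test significance level (default 0.01).
#' @return list with `pass` (logical), `reasons` (character vector, empty
#'   on pass), and the metrics checked.
#' @export
screen_qc <- function(model, min_separation = 3, alpha = 0.01) {
  stopifnot(inherits(model, "control_model"))
  reasons <- character(0)
  if (!is.finite(model$separation) || model$separation < min_separation) {
    reasons <- c(reasons, "controls not separated")
  }
  if (model$ks_p_pos < alpha) {
    reasons <- c(reasons, "positive controls non-normal")
  }
  if (model$ks_p_neg < alpha) {
    reasons <- c(reasons, "negative controls non-normal")
  }
  list(pass = length(reasons) == 0L, reasons = reasons,
       separation = model$separation,
       ks_p_pos = model$ks_p_pos, ks_p_neg = model$ks_p_neg)
}

#' Replicate concordance of per-guide normalized viabilities
#'
#' Pairs per-guide means from two replicate experiments on their shared
#' guide ids and reports Pearson and Spearman correlations, for the
#' replicate-vs-replicate scatter diagnostic.
#'
#' @param rep1,rep2 data.frames with `guide_id` and `mean` columns (as
#'   from [summarize_replicates()]), or named numeric vectors keyed by
#'   guide id.
#' @return list with `paired` (data.frame guide_id/value_1/value_2),
#'   `pearson`, `spearman`, `n_shared`.
#' @export
replicate_concordance <- function(rep1, rep2) {
  as_named <- function(r) {
    if (is.data.frame(r)) stats::setNames(r$mean, r$guide_id) else r
  }
  v1 <- as_named(rep1); v2 <- as_named(rep2)
  shared <- intersect(names(v1), names(v2))
  if (length(shared) < 3L) {
    stop("insufficient overlap: fewer than 3 shared guides")
  }
  paired <- data.frame(guide_id = shared,
                       value_1 = as.numeric(v1[shared]),
                       value_2 = as.numeric(v2[shared]),
                       stringsAsFactors = FALSE)
  list(paired = paired,
       pearson = stats::cor(paired$value_1, paired$value_2),
       spearman = stats::cor(paired$value_1, paired$value_2,
                             method = "spearman"),
       n_shared = length(shared))
}
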