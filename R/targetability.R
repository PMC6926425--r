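# Protein-turnover targetability for arrayed CRISPR screens.
#
# Arrayed knockout screens read phenotypes within ~3-5 days of
# transfection, so pre-existing protein must decay before a phenotype can
# appear. Proteins are classed by degradation kinetics: exponentially
# degraded (ED) proteins follow a 1-state model R(t) = exp(-k t);
# non-exponentially degraded (NED) proteins follow a 2-state fast/slow
# pool mixture R(t) = alpha exp(-k_fast t) + (1 - alpha) exp(-k_slow t).
# Proteins whose half-life exceeds 120 h are classed hard_to_target.

#' Half-life of a 1-state (exponential) degradation model
#'
#' @param k degradation rate, per hour; must be > 0.
#' @return half-life in hours, `log(2) / k`.
#' @examples
#' half_life_1state(log(2) / 40)  # 40 h
#' @export
half_life_1state <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("rate k must be > 0")
  log(2) / k
}

#' Half-life of a 2-state (fast/slow pool) degradation model
#'
#' The remaining fraction is
#' `R(t) = alpha * exp(-k_fast * t) + (1 - alpha) * exp(-k_slow * t)`,
#' strictly decreasing from 1 to 0, so `R(t) = 1/2` has a unique root.
#' The root is bracketed between the half-lives of the pure fast and pure
#' slow pools and found by bisection to `tol` hours.
#'
#' @param alpha fast-pool fraction in \[0, 1\].
#' @param k_fast,k_slow pool degradation rates per hour, `k_fast >= k_slow`
#'   > 0.
#' @param tol absolute tolerance on the root, hours (default 1e-6).
#' @return half-life in hours.
#' @export
half_life_2state <- function(alpha, k_fast, k_slow, tol = 1e-6) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0, 1]")
  }
  if (!is.finite(k_fast) || !is.finite(k_slow) || k_fast <= 0 || k_slow <= 0) {
    stop("rates must be > 0")
  }
  if (k_fast < k_slow) stop("k_fast must be >= k_slow")
  if (alpha == 1) return(half_life_1state(k_fast))
  if (alpha == 0 || k_fast == k_slow) return(half_life_1state(k_slow))
  R <- function(t) alpha * exp(-k_fast * t) + (1 - alpha) * exp(-k_slow * t)
  lo <- log(2) / k_fast   # R(lo) >= 1/2
  hi <- log(2) / k_slow   # R(hi) <= 1/2
  while ((hi - lo) > tol) {
    mid <- (lo + hi) / 2
    if (R(mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify a half-life as targetable or hard to target
#'
#' Strictly greater than the threshold means hard to target; a protein at
#' exactly 120 h is still called targetable.
#'
#' @param half_life_h half-life in hours (> 0).
#' @param threshold_h classification threshold, hours (default 120).
#' @return character vector, "targetable" or "hard_to_target".
#' @export
classify_targetable <- function(half_life_h, threshold_h = 120) {
  if (any(!is.finite(half_life_h)) || any(half_life_h <= 0)) {
    stop("half_life_h must be > 0")
  }
  ifelse(half_life_h > threshold_h, "hard_to_target", "targetable")
}

#' Read a protein turnover table
#'
#' Schema: `protein_id,deg_class,k,alpha,k_fast,k_slow`; `deg_class` is
#' "ED" (uses `k`) or "NED" (uses `alpha`, `k_fast`, `k_slow`); unused
#' fields are empty. Malformed rows are dropped with a warning and
#' counted in the `n_skipped` attribute.
#'
#' @param path CSV path.
#' @return data.frame of valid turnover records.
#' @export
read_turnover_table <- function(path) {
  if (!file.exists(path)) stop("turnover table not found: ", path)
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "deg_class", "k", "alpha", "k_fast", "k_slow")
  miss <- setdiff(need, names(tt))
  if (length(miss)) stop("turnover table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(tt) == 0L) stop("turnover table is empty")
  for (nm in c("k", "alpha", "k_fast", "k_slow")) {
    tt[[nm]] <- suppressWarnings(as.numeric(tt[[nm]]))
  }
  ok_ed <- tt$deg_class == "ED" & is.finite(tt$k) & tt$k > 0
  ok_ned <- tt$deg_class == "NED" & is.finite(tt$alpha) &
    tt$alpha >= 0 & tt$alpha <= 1 &
    is.finite(tt$k_fast) & tt$k_fast > 0 &
    is.finite(tt$k_slow) & tt$k_slow > 0 & tt$k_fast >= tt$k_slow
  ok <- ok_ed | ok_ned
  if (any(!ok)) {
    warning(sum(!ok), " malformed turnover row(s) skipped")
  }
  out <- tt[ok, need]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Per-protein half-lives and targetability of a proteome
#'
#' Solves the degradation model of each record for its half-life,
#' classifies it at the threshold, and summarizes the hard-to-target
#' fraction along with kernel density estimates of log10 half-life per
#' degradation class (for the half-life density plot).
#'
#' @param records turnover data.frame (see [read_turnover_table()]).
#' @param threshold_h classification threshold, hours (default 120).
#' @return list with `per_protein` (protein_id, deg_class, half_life_h,
#'   targetable), `fraction_hard`, `n`, and `density_curves` (data.frame
#'   of deg_class, log10_half_life_h, density).
#' @export
proteome_targetability_summary <- function(records, threshold_h = 120) {
  if (is.null(records) || nrow(records) == 0L) stop("no turnover records")
  hl <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    hl[i] <- if (records$deg_class[i] == "ED") {
      half_life_1state(records$k[i])
    } else {
      half_life_2state(records$alpha[i], records$k_fast[i],
                       records$k_slow[i])
    }
  }
  per_protein <- data.frame(
    protein_id = records$protein_id,
    deg_class = records$deg_class,
    half_life_h = hl,
    targetable = classify_targetable(hl, threshold_h),
    stringsAsFactors = FALSE
  )
  curves <- do.call(rbind, lapply(split(per_protein, per_protein$deg_class),
    function(d) {
      if (nrow(d) < 2L) return(NULL)
      dn <- stats::density(log10(d$half_life_h))
      data.frame(deg_class = d$deg_class[1L], log10_half_life_h = dn$x,
                 density = dn$y, stringsAsFactors = FALSE)
    }))
  rownames(curves) <- NULL
  list(per_protein = per_protein,
       fraction_hard = mean(per_protein$targetable == "hard_to_target"),
       n = nrow(per_protein),
       density_curves = curves)
}
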