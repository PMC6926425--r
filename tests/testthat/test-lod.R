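model_of <- function(mu_pos, sigma_pos, mu_neg, sigma_neg) {
  # deterministic control model with exact moments, built from a scaled
  # fixed-shape sample so the fit is fully determined
  base <- c(-1.2816, -0.5244, 0, 0.5244, 1.2816)  # symmetric, mean 0
  scale_to <- function(mu, s) mu + base * (s / sd(base))
  fit_control_model(scale_to(mu_pos, sigma_pos), scale_to(mu_neg, sigma_neg))
}

test_that("control fitting recovers parameters and rejects degenerate input", {
  expect_error(fit_control_model(c(0.1, 0.1), c(1, 1.1, 0.9)),
               "insufficient")
  expect_error(fit_control_model(c(0.1, 0.1, 0.1), c(1, 1.1, 0.9)),
               "degenerate")

  set.seed(101)
  neg <- rnorm(200, 1.0, 0.05)
  pos <- rnorm(200, 0.15, 0.05)
  m <- fit_control_model(pos, neg)
  # tolerances ~3 standard errors at n = 200
  expect_lt(abs(m$mu_neg - 1.0), 0.02)
  expect_lt(abs(m$sigma_neg - 0.05), 0.015)
  expect_lt(abs(m$mu_pos - 0.15), 0.02)
  expect_equal(m$n_pos, 200)
  expect_true(m$separation > 10)
})

test_that("KS diagnostic rarely flags genuinely normal controls", {
  reject <- vapply(1:100, function(s) {
    set.seed(s)
    m <- fit_control_model(rnorm(16, 0.15, 0.05), rnorm(16, 1, 0.05))
    m$ks_p_neg < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.10)
})

test_that("density LOD matches direct density evaluation and the closed form", {
  m <- model_of(0.1, 0.1, 1.0, 0.1)
  # equal variances: closed form (mu_neg - mu_pos)^2 / (2 sigma^2 ln 10)
  # at x = mu_pos
  expect_equal(lod_score(0.1, m), (1.0 - 0.1)^2 / (2 * 0.1^2 * log(10)),
               tolerance = 1e-9)
  expect_equal(lod_score(0.1, m), 17.5887, tolerance = 1e-4)
  # independent oracle: direct normal density ratio
  xs <- seq(-0.5, 1.5, length.out = 41)
  expect_equal(lod_score(xs, m),
               log10(dnorm(xs, 0.1, 0.1) / dnorm(xs, 1, 0.1)),
               tolerance = 1e-12)
  # symmetry: midpoint between equal-variance controls scores 0
  expect_equal(lod_score(0.55, m), 0, tolerance = 1e-12)
})

test_that("equal-variance LOD is linear in x, antisymmetric and monotone", {
  m <- model_of(0.15, 0.05, 1.0, 0.05)
  # range kept inside ~35 sd of both means, where neither density
  # underflows to the probability floor
  xs <- seq(-0.5, 1.65, length.out = 1000)
  closed <- ((xs - m$mu_neg)^2 - (xs - m$mu_pos)^2) /
    (2 * m$sigma_pos^2 * log(10))
  expect_equal(lod_score(xs, m), closed, tolerance = 1e-9)

  swapped <- model_of(1.0, 0.05, 0.15, 0.05)
  expect_equal(lod_score(xs, swapped), -lod_score(xs, m), tolerance = 1e-9)

  expect_true(all(diff(lod_score(xs, m)) < 0))  # mu_pos < mu_neg
})

test_that("cdf_tail variant is monotone decreasing and floors extreme values", {
  m <- model_of(0.15, 0.05, 1.0, 0.05)
  xs <- seq(0, 1.2, length.out = 100)
  lods <- lod_score(xs, m, method = "cdf_tail")
  expect_true(all(is.finite(lods)))
  expect_true(all(diff(lods) < 0))
  # far below both means the tail probabilities hit the floor together
  expect_true(is.finite(lod_score(-50, m, method = "cdf_tail")))
  expect_true(is.finite(lod_score(50, m)))
})

test_that("hit calling is inclusive at the threshold and sorted by LOD", {
  m <- model_of(0.15, 0.05, 1.0, 0.05)
  # place one guide exactly at the threshold by making the threshold its
  # own computed LOD; a guide scoring 0.001 lower must not be called
  x3 <- uniroot(function(x) lod_score(x, m) - 3, c(0, 1), tol = 1e-12)$root
  thr <- lod_score(x3, m)
  x299 <- uniroot(function(x) lod_score(x, m) - (thr - 0.001), c(0, 1),
                  tol = 1e-12)$root
  gs <- data.frame(gene_symbol = c("AT3", "BELOW", "LETHAL"),
                   guide_id = c("a", "b", "c"),
                   mean = c(x3, x299, 0.2), n = 2)
  res <- call_hits(gs, m, threshold = thr)
  expect_identical(res$gene_symbol[1], "LETHAL")  # sorted descending
  expect_true(res$hit[res$gene_symbol == "AT3"])
  expect_false(res$hit[res$gene_symbol == "BELOW"])
})

test_that("screen QC fails on poor separation or non-normal controls", {
  good <- model_of(0.15, 0.05, 1.0, 0.05)
  expect_true(screen_qc(good)$pass)

  close <- model_of(0.9, 0.2, 1.0, 0.2)  # separation 0.5 sd
  qc <- screen_qc(close)
  expect_false(qc$pass)
  expect_true("controls not separated" %in% qc$reasons)

  skewed <- good
  skewed$ks_p_neg <- 0.001
  qc2 <- screen_qc(skewed)
  expect_false(qc2$pass)
  expect_true("negative controls non-normal" %in% qc2$reasons)
})

test_that("replicate concordance pairs shared guides and bounds correlations", {
  r1 <- data.frame(guide_id = paste0("g", 1:10), mean = seq(0.1, 1, 0.1))
  expect_equal(replicate_concordance(r1, r1)$pearson, 1)
  r2 <- r1; r2$mean <- 1 - r1$mean
  expect_equal(replicate_concordance(r1, r2)$pearson, -1)
  expect_error(replicate_concordance(r1, r1[1:2, ]), "insufficient overlap")

  set.seed(5)
  noisy <- r1; noisy$mean <- r1$mean + rnorm(10, 0, 0.02)
  cc <- replicate_concordance(r1, noisy)
  expect_equal(nrow(cc$paired), 10)
  expect_gt(cc$spearman, 0.8)
})
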