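make_readouts <- function(pm, raw) {
  data.frame(plate_id = pm$plate_id, well = pm$well,
             raw_luminescence = raw, stringsAsFactors = FALSE)
}

test_that("background is the blank mean, with override precedence and 0 fallback", {
  pm <- tiny_plate_map()
  raw <- rep(1000, nrow(pm))
  raw[pm$content_type == "blank"] <- c(100, 110)
  ro <- make_readouts(pm, raw)
  expect_equal(unname(estimate_background(ro, pm)), 105)
  expect_equal(unname(estimate_background(ro, pm, override = 250)), 250)

  noblank <- pm[pm$content_type != "blank", ]
  ro2 <- ro[ro$well %in% noblank$well, ]
  expect_warning(bg <- estimate_background(ro2, noblank), "background = 0")
  expect_equal(unname(bg), 0)
})

test_that("normalization follows (raw - bg) / mean reference signal with clamping", {
  pm <- tiny_plate_map(n_genes = 2L)
  raw <- rep(NA_real_, nrow(pm))
  raw[pm$content_type == "blank"] <- 100
  raw[pm$content_type == "mock"] <- 1000 + 100   # signal 1000 each
  raw[pm$content_type == "scrambled"] <- c(900, 1100) + 100
  raw[pm$content_type == "positive_control"] <- 150 + 100
  raw[pm$content_type == "gene"] <- c(550, 80)   # 0.45 signal; below bg
  nt <- normalize_plate(make_readouts(pm, raw), pm, reference = "mock")

  gene <- nt[nt$content_type == "gene", ]
  expect_equal(gene$viability_vs_mock[1], 450 / 1000)
  expect_equal(gene$viability_vs_mock[2], 0)           # clamped
  expect_match(gene$qc_flags[2], "clamped_negative")
  expect_false(grepl("clamped", gene$qc_flags[1]))

  # a well equal to the mock mean normalizes to exactly 1
  mock <- nt[nt$content_type == "mock", ]
  expect_equal(mock$viability_vs_mock, c(1, 1))
  # both reference columns populated when both control types exist
  expect_true(all(!is.na(gene$viability_vs_scrambled)))
  expect_equal(gene$viability_vs_scrambled[1], 450 / 1000)
})

test_that("reference wells self-normalize to mean 1 and absence errors", {
  sim <- simulate_plate(default_plate_layout(sprintf("G%02d", 1:10)),
                        seed = 3)
  nt <- normalize_plate(sim$readouts, sim$plate_map, reference = "mock")
  expect_equal(mean(nt$viability_vs_mock[nt$content_type == "mock"]), 1,
               tolerance = 1e-12)
  expect_equal(
    mean(nt$viability_vs_scrambled[nt$content_type == "scrambled"]), 1,
    tolerance = 1e-12)
  expect_true(all(nt$viability_vs_mock >= 0, na.rm = TRUE))

  nomock <- sim$plate_map
  nomock$content_type[nomock$content_type == "mock"] <- "blank"
  nomock$gene_symbol[nomock$content_type == "blank"] <- ""
  nomock$guide_id[nomock$content_type == "blank"] <- ""
  expect_error(normalize_plate(sim$readouts, nomock, reference = "mock"),
               "missing_reference")
})

test_that("normalized viability is invariant to a global intensity rescale", {
  sim <- simulate_plate(default_plate_layout(sprintf("G%02d", 1:10)),
                        seed = 9, noise_cv = 0.08)
  nt1 <- normalize_plate(sim$readouts, sim$plate_map)
  ro2 <- sim$readouts
  ro2$raw_luminescence <- ro2$raw_luminescence * 7.3
  nt2 <- normalize_plate(ro2, sim$plate_map)
  expect_equal(nt2$viability_vs_scrambled, nt1$viability_vs_scrambled,
               tolerance = 1e-12)
  expect_equal(nt2$viability_vs_mock, nt1$viability_vs_mock,
               tolerance = 1e-12)
})

test_that("missing readout wells are flagged, not fatal", {
  pm <- tiny_plate_map()
  raw <- rep(1000, nrow(pm)); raw[pm$content_type == "blank"] <- 100
  ro <- make_readouts(pm, raw)
  ro <- ro[ro$well != pm$well[pm$content_type == "gene"][1], ]
  nt <- normalize_plate(ro, pm, reference = "mock")
  dropped <- nt[nt$qc_flags == "missing_readout", ]
  expect_equal(nrow(dropped), 1)
  expect_true(is.na(dropped$viability_vs_mock))
})

test_that("replicate summaries use sample sd with NA for singletons", {
  nt <- data.frame(content_type = "gene",
                   gene_symbol = c("A", "A", "B", "C", "C", "C"),
                   guide_id = c("A_g1", "A_g1", "B_g1", "C_g1", "C_g1",
                                "C_g1"),
                   viability_vs_scrambled = c(0.4, 0.6, 0.7, 0.5, 0.5, 0.5))
  s <- summarize_replicates(nt)
  expect_equal(s$mean[s$gene_symbol == "A"], 0.5)
  expect_equal(s$sd[s$gene_symbol == "A"], sd(c(0.4, 0.6)))
  expect_true(is.na(s$sd[s$gene_symbol == "B"]))
  expect_equal(s$mean[s$gene_symbol == "B"], 0.7)
  expect_equal(s$sd[s$gene_symbol == "C"], 0)
  expect_equal(s$n, c(2L, 1L, 3L))
})
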