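# Shared fixtures and small utilities for the test suite.

# Distance from each ground-truth nucleus center to its nearest segmented
# centroid (one value per truth object).
truth_centroid_errors <- function(seg, truth) {
  vapply(seq_len(nrow(truth)), function(k) {
    min(sqrt((seg$objects$centroid_r - truth$center_r[k])^2 +
               (seg$objects$centroid_c - truth$center_c[k])^2))
  }, numeric(1))
}

# Index of the segmented object nearest to each truth center.
match_truth_objects <- function(seg, truth) {
  vapply(seq_len(nrow(truth)), function(k) {
    which.min(sqrt((seg$objects$centroid_r - truth$center_r[k])^2 +
                     (seg$objects$centroid_c - truth$center_c[k])^2))
  }, integer(1))
}

# Minimal 2-plate-free single plate map used by the I/O tests: 2 mocks,
# 2 blanks, 2 scrambled, 2 positive controls, the rest gene wells.
tiny_plate_map <- function(plate_id = "p1", n_genes = 4L) {
  wells <- plate_wells(96)[seq_len(8L + n_genes)]
  ct <- c("mock", "mock", "blank", "blank", "scrambled", "scrambled",
          "positive_control", "positive_control", rep("gene", n_genes))
  genes <- sprintf("G%02d", seq_len(n_genes))
  data.frame(
    plate_id = plate_id, well = wells, content_type = ct,
    gene_symbol = c(rep("", 6), "POLR2A", "POLR2A", genes),
    guide_id = c(rep("", 4), "scr_01", "scr_02", "POLR2A_g1", "POLR2A_g2",
                 paste0(genes, "_g1")),
    replicate = 1L, stringsAsFactors = FALSE)
}

# Normalized-scale screen draw used by the LOD recovery tests: control
# wells and per-gene replicate values drawn from the stated normal
# distributions, returned ready for fit_control_model / call_hits.
draw_normalized_screen <- function(genes_lethal, genes_neutral,
                                   n_ctrl = 16L, n_rep = 2L,
                                   mu_neg = 1, mu_pos = 0.15,
                                   lethal_mean = 0.2, sd = 0.05) {
  genes <- c(genes_lethal, genes_neutral)
  means <- c(rep(lethal_mean, length(genes_lethal)),
             rep(mu_neg, length(genes_neutral)))
  per_gene <- vapply(means, function(m) mean(rnorm(n_rep, m, sd)),
                     numeric(1))
  list(
    pos = rnorm(n_ctrl, mu_pos, sd),
    neg = rnorm(n_ctrl, mu_neg, sd),
    summary = data.frame(gene_symbol = genes,
                         guide_id = paste0(genes, "_g1"),
                         mean = per_gene, n = n_rep,
                         stringsAsFactors = FALSE)
  )
}
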