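# The synthetic-data generator: planted truth, determinism, round-trips.

test_that("expression generator plants the configured class counts", {
  cfg <- synthetic_config(n_genes = 500,
                          planted_counts = list(gsr_up = 50, unique_up = 2,
                                                background = 10),
                          noise_sd = 0, seed = 1)
  sim <- simulate_expression(cfg)
  expect_equal(sum(sim$truth$class == "GSR_up"), 50)
  expect_equal(sum(sim$truth$class == "unique_up"), 2 * 8)
  expect_equal(sum(sim$truth$class == "background"), 10)
  expect_equal(nrow(sim$truth), 500)
  expect_equal(ncol(sim$dataset$intensities), 8 * 2 * 2 * 3)

  # planted counts exceeding the universe are a configuration error
  expect_error(synthetic_config(n_genes = 10,
                                planted_counts = list(gsr_up = 50)),
               "exceed")
})

test_that("noise-free planted classes satisfy their FC inequalities exactly", {
  cfg <- synthetic_config(n_genes = 300,
                          planted_counts = list(gsr_up = 20, generally_down = 10,
                                                unique_up = 2, unique_down = 2,
                                                background = 20, low_regulated = 10),
                          noise_sd = 0, seed = 4)
  sim <- simulate_expression(cfg)
  ds <- sim$dataset
  fc <- fold_change_table(ds)
  m <- rhizotox:::fc_matrices(fc)$fc
  tr <- sim$truth
  expect_true(all(m[tr$gene[tr$class == "GSR_up"], ] >= 2))
  expect_true(all(m[tr$gene[tr$class == "generally_down"], ] <= -2))
  expect_true(all(abs(m[tr$gene[tr$class == "background"], ]) <= 1.2))
  low <- m[tr$gene[tr$class == "low_regulated"], ]
  expect_true(all(low > 1.2 & low < 2))
  for (i in which(tr$class == "unique_up")) {
    row <- m[tr$gene[i], ]
    expect_gte(row[tr$stress[i]], 2)
    expect_true(all(abs(row[setdiff(names(row), tr$stress[i])]) <= 1.4))
  }
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- synthetic_config(n_genes = 100, planted_counts = list(gsr_up = 5),
                          noise_sd = 0.05, seed = 77)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$dataset$intensities, b$dataset$intensities)
  expect_identical(a$truth, b$truth)
  p1 <- simulate_promoters(5, 5, motif_pattern("TTGACY"), 0.4, 0.4, 200, seed = 3)
  p2 <- simulate_promoters(5, 5, motif_pattern("TTGACY"), 0.4, 0.4, 200, seed = 3)
  expect_identical(p1, p2)
})

test_that("promoter generator plants exact per-group fractions", {
  pat <- motif_pattern("TTGACY", "W-box")
  pr <- simulate_promoters(10, 10, pat, 1.0, 0.0, 1000, seed = 3)
  expect_equal(motif_gene_fraction(pr$gsr, pat), 100)
  expect_equal(motif_gene_fraction(pr$background, pat), 0)

  pr2 <- simulate_promoters(50, 50, motif_pattern("SCGCGCS"), 0.52, 0.31, 1000, seed = 11)
  # exhaustive window scan of the emitted sequences
  frac <- function(seqs) 100 * mean(vapply(seqs, function(s) {
    nrow(naive_scan(s, "SCGCGCS", "both")) > 0
  }, TRUE))
  expect_equal(frac(pr2$gsr), 52)
  expect_equal(frac(pr2$background), 32)  # round(0.31 * 50) = 16 of 50

  expect_error(simulate_promoters(5, 5, pat, 1, 1, length = 3), "shorter than")
})

test_that("gene model generator round-trips through the GFF3 parser", {
  gm <- simulate_gene_models(
    groups = list(
      none = list(n = 10, intron_count = function(n) rep(0L, n),
                  intron_length = function(k) integer(0)),
      some = list(n = 15, intron_count = function(n) sample(1:4, n, replace = TRUE),
                  intron_length = function(k) sample(50:500, k, replace = TRUE))),
    seed = 5)
  models <- read_gene_models(gm$gff3)
  expect_equal(nrow(models), 25)
  m <- merge(models, gm$truth, by = "gene")
  expect_equal(m$intron_count.x, m$intron_count.y)
  expect_equal(m$total_intron_length.x, m$total_intron_length.y)
  expect_equal(mean(models$intron_count[match(gm$truth$gene[gm$truth$group == "none"],
                                              models$gene)] == 0), 1)
})

test_that("ortholog generator respects omega and produces clean pairs", {
  # omega = 0: no amino-acid differences, Ka = 0 exactly
  op0 <- simulate_ortholog_pairs(5, 80, omega = 0, branch_mutations = 0.5, seed = 2)
  expect_identical(op0$protein_a, setNames(op0$protein_b, names(op0$protein_a)))
  kt0 <- kaks_table(op0$protein_a, op0$protein_b, op0$cds_a, op0$cds_b)
  expect_equal(kt0$Ka, rep(0, 5))
  # no internal stops anywhere
  for (s in c(op0$cds_a, op0$cds_b)) {
    aa <- rhizotox:::translate_codons(rhizotox:::split_codons(s))
    expect_false("*" %in% aa)
  }
  # zero divergence: Ka = Ks = 0
  opid <- simulate_ortholog_pairs(3, 60, omega = 1, branch_mutations = 0, seed = 3)
  ktid <- kaks_table(opid$protein_a, opid$protein_b, opid$cds_a, opid$cds_b)
  expect_equal(ktid$Ka, rep(0, 3))
  expect_equal(ktid$Ks, rep(0, 3))
  expect_true(all(ktid$undefined))  # 0/0 ratio flagged
})

test_that("network generator emits a simple graph with recoverable hubs", {
  net <- simulate_network(400, planted_hubs = 10, hub_degree = 30,
                          background_degree_mean = 3, seed = 2)
  expect_true(all(net$edges$node_a != net$edges$node_b))
  expect_false(any(duplicated(paste(net$edges$node_a, net$edges$node_b))))
  g <- read_edge_list(net$edges)
  hubs <- top_hubs(g, 10)
  expect_setequal(hubs$node, net$truth$node[net$truth$is_hub])
  expect_error(simulate_network(10, 1, 2, 5), "exceed")
})

test_that("Ct generator encodes planted folds exactly", {
  panels <- list(single_Cd = "Cd")
  prof <- list(g1 = c(single_Cd = 8), g2 = c(single_Cd = 1.0))
  ct <- simulate_ct_table(panels, prof, seed = 1)
  # planted 8-fold: target Ct 3 cycles below control; reference constant
  target_treated <- mean(ct$ct$ct[ct$ct$gene_id == "g1" &
                                    ct$ct$sample_id == "single_Cd_treated"])
  target_control <- mean(ct$ct$ct[ct$ct$gene_id == "g1" &
                                    ct$ct$sample_id == "water_control"])
  expect_equal(target_control - target_treated, 3)
  fm <- panel_fold_matrix(ct)
  expect_equal(fm["g1", "single_Cd"], 8)
  expect_equal(fm["g2", "single_Cd"], 1)  # planted fold 1 -> ddCt = 0
  expect_error(simulate_ct_table(panels, list(g1 = c(single_Cd = -1))), "> 0")
})
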