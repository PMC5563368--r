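# GFF3 parsing and the gene-compactness comparisons.

gff_of <- function(exons, gene = "gA") {
  g_start <- exons[[1]][1]; g_end <- exons[[length(exons)]][2]
  c("##gff-version 3",
    sprintf("chr1\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s", g_start, g_end, gene),
    sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.1;Parent=%s", g_start, g_end, gene, gene),
    vapply(seq_along(exons), function(i) {
      sprintf("chr1\ttest\texon\t%d\t%d\t.\t+\t.\tID=%s.1.e%d;Parent=%s.1",
              exons[[i]][1], exons[[i]][2], gene, i, gene)
    }, ""))
}

test_that("parser derives introns from exon coordinate gaps", {
  m <- read_gene_models(gff_of(list(c(1, 100), c(201, 300))))
  expect_equal(m$intron_count, 1)
  expect_equal(m$total_intron_length, 100)

  single <- read_gene_models(gff_of(list(c(10, 500))))
  expect_equal(single$intron_count, 0)
  expect_equal(single$total_intron_length, 0)

  multi <- read_gene_models(gff_of(list(c(1, 10), c(12, 20), c(100, 120))))
  expect_equal(multi$intron_count, 2)
  expect_equal(multi$intron_lengths[[1]], c(1L, 79L))
  expect_equal(multi$total_intron_length, 80)
})

test_that("parser rejects overlapping exons and uses the first mRNA", {
  bad <- gff_of(list(c(1, 100), c(50, 200)))
  expect_warning(m <- read_gene_models(bad), "overlapping")
  expect_equal(nrow(m), 0)
  # two transcripts: first in file order is representative
  two <- c("##gff-version 3",
           "chr1\tt\tgene\t1\t300\t.\t+\t.\tID=gB",
           "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=gB.1;Parent=gB",
           "chr1\tt\texon\t1\t300\t.\t+\t.\tID=e1;Parent=gB.1",
           "chr1\tt\tmRNA\t1\t300\t.\t+\t.\tID=gB.2;Parent=gB",
           "chr1\tt\texon\t1\t100\t.\t+\t.\tID=e2;Parent=gB.2",
           "chr1\tt\texon\t201\t300\t.\t+\t.\tID=e3;Parent=gB.2")
  m2 <- read_gene_models(two)
  expect_equal(m2$intron_count, 0)  # gB.1 is single-exon
})

test_that("intronless-fraction z-test matches the pooled-proportion formula", {
  mk <- function(n_intronless, n_total) {
    data.frame(gene = sprintf("g%03d", seq_len(n_total)),
               intron_count = rep(c(0L, 2L), c(n_intronless, n_total - n_intronless)),
               total_intron_length = rep(c(0L, 200L), c(n_intronless, n_total - n_intronless)))
  }
  r <- intronless_fraction_test(mk(60, 100), mk(40, 100))
  expect_equal(r$z, 2.828, tolerance = 1e-3)
  expect_equal(r$p.value, 2 * pnorm(-r$z))

  eq <- intronless_fraction_test(mk(30, 100), mk(30, 100))
  expect_equal(eq$z, 0)
  expect_equal(eq$p.value, 1)

  degen <- intronless_fraction_test(mk(0, 50), mk(0, 50))
  expect_true(degen$degenerate)
})

test_that("intron metric comparison excludes intronless genes and detects shifts", {
  mk <- function(lens) {
    data.frame(gene = sprintf("g%03d", seq_along(lens)),
               intron_count = ifelse(lens == 0, 0L, 2L),
               total_intron_length = lens)
  }
  ident <- list(a = mk(c(100, 110, 120)), b = mk(c(100, 110, 120)),
                c = mk(c(100, 110, 120)))
  r <- compare_intron_metrics(ident)
  expect_equal(r$kruskal$statistic, 0)
  expect_equal(r$kruskal$p.value, 1)

  # intronless genes are excluded before testing
  with0 <- list(a = mk(c(0, 0, 100, 110, 120)), b = mk(c(1000, 1100, 1200)))
  r2 <- compare_intron_metrics(with0)
  expect_equal(unname(r2$group_sizes), c(3L, 3L))
  # clear separation: Dunn flags the pair
  expect_lt(r2$dunn$p[1], 0.05)

  # generated groups with mean total intron length 400 vs 1200 reject at p < 0.01
  gm <- simulate_gene_models(
    groups = list(
      short = list(n = 200, intron_count = function(n) rep(2L, n),
                   intron_length = function(k) pmax(1L, as.integer(rnorm(k, 200, 40)))),
      long = list(n = 200, intron_count = function(n) rep(2L, n),
                  intron_length = function(k) pmax(1L, as.integer(rnorm(k, 600, 80))))),
    seed = 5)
  models <- read_gene_models(gm$gff3)
  models$group <- gm$truth$group[match(models$gene, gm$truth$gene)]
  r3 <- compare_intron_metrics(split(models, models$group))
  expect_lt(r3$kruskal$p.value, 0.01)

  expect_warning(compare_intron_metrics(list(a = mk(c(0, 0)), b = mk(c(10, 20)),
                                             c = mk(c(30, 40)))),
                 "emptied")
})

test_that("Dunn pairwise ordering follows the mean-rank gaps", {
  set.seed(11)
  groups <- list(a = rnorm(20, 0), b = rnorm(20, 1), c = rnorm(20, 5))
  d <- dunn_posthoc(groups)
  widest <- d[which.max(abs(d$z)), ]
  expect_setequal(c(widest$group1, widest$group2), c("a", "c"))
  expect_equal(which.min(d$p_adjusted), which.max(abs(d$z)))
  expect_true(all(d$p_adjusted >= d$p))
})

test_that("top-vs-bottom FC split compares intron lengths exactly at small n", {
  mk <- function(lens) {
    data.frame(gene = sprintf("g%03d", seq_along(lens)),
               intron_count = ifelse(lens == 0, 0L, 1L),
               total_intron_length = lens)
  }
  # bottom half lengths (1,2), top half (3,4): U = 0, exact p = 0.333
  r <- intron_length_by_fc_test(mk(c(1, 2, 3, 4)), fc_value = c(1, 2, 3, 4))
  expect_true(r$exact)
  expect_equal(min(r$U, r$n_top * r$n_bottom - r$U), 0)  # complete separation
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-9)

  # identical halves: p = 1
  r2 <- intron_length_by_fc_test(mk(c(7, 9, 7, 9)), fc_value = c(1, 2, 3, 4))
  expect_equal(r2$p.value, 1)

  # odd count: median gene assigned to neither half
  r3 <- intron_length_by_fc_test(mk(c(5, 6, 7, 8, 9)), fc_value = 1:5)
  expect_equal(r3$n_top + r3$n_bottom, 4)

  expect_warning(expect_null(intron_length_by_fc_test(mk(c(0, 0, 5, 6)), 1:4)),
                 "fewer than 4")

  # planted: top-FC half systematically shorter introns rejects at n = 200
  set.seed(12)
  lens <- c(round(runif(100, 500, 1500)), round(runif(100, 100, 300)))
  r4 <- intron_length_by_fc_test(mk(lens), fc_value = seq_len(200))
  expect_lt(r4$p.value, 0.01)
  expect_lt(r4$mean_top, r4$mean_bottom)
})

test_that("architecture tests are calibrated under a shared distribution", {
  set.seed(13)
  n_sim <- 1000
  rej_z <- 0; rej_kw <- 0
  for (i in seq_len(n_sim)) {
    intronless <- matrix(runif(200) < 0.3, 100)
    z <- two_proportion_z(sum(intronless[, 1]), 100, sum(intronless[, 2]), 100)
    if (!z$degenerate && z$p.value < 0.05) rej_z <- rej_z + 1
    if (kruskal_wallis(list(rnorm(50), rnorm(50)))$p.value < 0.05) rej_kw <- rej_kw + 1
  }
  expect_gte(rej_z / n_sim, 0.03); expect_lte(rej_z / n_sim, 0.07)
  expect_gte(rej_kw / n_sim, 0.03); expect_lte(rej_kw / n_sim, 0.07)
})
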