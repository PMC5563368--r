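# Normalization, filtering, fold change, rank testing, FDR and the
# four-class taxonomy.

test_that("joint quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  meta <- data.frame(sample_id = c("s1", "s2"), stress = "Cu", timepoint = "1h",
                     replicate = 1:2, condition = "control")
  qn <- quantile_normalize_joint(stress_expression(m, meta))
  # rank-wise row means, hand-computed
  expect_equal(unname(qn$intensities[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$intensities[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are unchanged
  m2 <- matrix(c(5, 1, 9, 5, 1, 9), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  qn2 <- quantile_normalize_joint(stress_expression(m2, meta))
  expect_equal(qn2$intensities, m2)

  # sorted columns all equal after normalization (random case)
  set.seed(1)
  m3 <- matrix(rexp(60) + 0.1, 10, 6,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  meta3 <- data.frame(sample_id = colnames(m3), stress = "Cu", timepoint = "1h",
                      replicate = 1:6, condition = "control")
  qn3 <- quantile_normalize_joint(stress_expression(m3, meta3))
  sorted <- apply(qn3$intensities, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # mismatched gene universes are an alignment error naming the ids
  m4 <- m3; rownames(m4)[1] <- "other_gene"
  expect_error(quantile_normalize_joint(list(stress_expression(m3, meta3),
                                             stress_expression(m4, meta3))),
               "gene universe")
})

test_that("low-intensity filter keeps genes detected in any sample", {
  ds <- tiny_dataset(matrix(c(50, 20, 500), 3, 3), matrix(c(50, 150, 800), 3, 3))
  expect_message(f <- filter_low_intensity(ds, 100), "dropped 1")
  expect_false("g001" %in% rownames(f$intensities))  # all intensities 50
  expect_true("g002" %in% rownames(f$intensities))   # one sample at 150
  f0 <- filter_low_intensity(ds, 0)
  expect_equal(dim(f0$intensities), dim(ds$intensities))
  expect_warning(filter_low_intensity(ds, 1e9), "every gene")
})

test_that("signed fold change maps ratios symmetrically", {
  expect_equal(signed_fold_change(200, 100), 2)
  expect_equal(signed_fold_change(50, 100), -2)
  expect_equal(signed_fold_change(100, 100), 1)
  expect_error(signed_fold_change(0, 100), "positive")
  # |FC| >= 1 for random positive inputs
  set.seed(2)
  fc <- signed_fold_change(rexp(100) + 0.01, rexp(100) + 0.01)
  expect_true(all(abs(fc) >= 1))
})

test_that("Kruskal-Wallis matches the hand-computed rank-sum formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  ident <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  degen <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(degen$p.value, 1)
})

test_that("row-wise KW agrees with stats::kruskal.test including ties", {
  set.seed(3)
  for (sizes in list(c(3, 3), c(6, 6), c(4, 5, 6))) {
    x <- matrix(sample(1:6, 40 * sum(sizes), replace = TRUE), 40)  # heavy ties
    got <- kw_rows(x, sizes)
    grp <- rep(seq_along(sizes), sizes)
    for (i in seq_len(nrow(x))) {
      if (length(unique(x[i, ])) == 1) {
        expect_equal(got$statistic[i], 0)
        expect_equal(got$p.value[i], 1)
      } else {
        kt <- stats::kruskal.test(x[i, ], grp)
        expect_equal(got$statistic[i], unname(kt$statistic), tolerance = 1e-8)
        expect_equal(got$p.value[i], kt$p.value, tolerance = 1e-8)
      }
    }
  }
})

test_that("two small groups agree with the exact Mann-Whitney ordering oracle", {
  # for 3v3 without ties, KW p is a monotone function of |U - 4.5|; check
  # that KW ranks all distinct configurations exactly as exhaustive MW does
  combos <- combn(6, 3)
  stats_kw <- apply(combos, 2, function(ix) {
    kruskal_wallis(list(ix, setdiff(1:6, ix)))$statistic
  })
  u <- apply(combos, 2, function(ix) {
    sum(outer(ix, setdiff(1:6, ix), ">"))
  })
  expect_equal(order(stats_kw), order(abs(u - 4.5)))
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted-p order
  }
})

test_that("fold change table applies the max-|FC| timepoint rule", {
  # one gene: 1h FC +1.1, 3h FC +2.6
  ids <- c(paste0("c1_", 1:3), paste0("t1_", 1:3), paste0("c3_", 1:3), paste0("t3_", 1:3))
  mat <- matrix(c(100, 100, 100, 110, 110, 110, 100, 100, 100, 260, 260, 260),
                1, 12, dimnames = list("g1", ids))
  meta <- data.frame(sample_id = ids, stress = "Cd",
                     timepoint = rep(c("1h", "1h", "3h", "3h"), each = 3),
                     replicate = rep(1:3, 4),
                     condition = rep(c("control", "treated"), each = 3, times = 2))
  ds <- stress_expression(mat, meta)
  fc <- fold_change_table(ds)
  expect_equal(fc$fc, 2.6)
  expect_equal(fc$timepoint, "3h")

  # permuting sample order leaves the table unchanged
  perm <- sample(ncol(mat))
  ds2 <- stress_expression(mat[, perm, drop = FALSE], meta[perm, ])
  fc2 <- fold_change_table(ds2)
  expect_equal(fc2$fc, fc$fc)
  expect_equal(fc2$p, fc$p)

  # missing control group is a configuration error
  meta_bad <- meta; meta_bad$condition[meta_bad$timepoint == "3h"] <- "treated"
  expect_error(stress_expression(mat, meta_bad) |> fold_change_table(), "no control")
})

make_fc_table <- function(fc, q = NULL) {
  stressors <- colnames(fc)
  genes <- rownames(fc)
  if (is.null(q)) q <- matrix(0.001, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  df <- data.frame(gene = rep(genes, times = ncol(fc)),
                   stress = rep(stressors, each = nrow(fc)),
                   fc = as.vector(fc), p = as.vector(q), q = as.vector(q))
  attr(df, "stressors") <- stressors
  class(df) <- c("fc_table", "data.frame")
  df
}

test_that("classifier applies the four-class taxonomy with FDR gating", {
  st <- default_stressors()
  fc <- rbind(gsr = rep(2.5, 8),
              gsr_failq = rep(2.5, 8),
              uniq_cd = c(1.1, 1.2, 3, 1.3, 1.0, -1.2, 1.1, 1.4),
              not_uniq = c(1.5, 1.0, 3, 1.0, 1.0, 1.0, 1.0, 1.0),
              bg = c(1.1, -1.15, 1.2, 1.0, -1.2, 1.05, 1.0, 1.1),
              low = rep(1.5, 8),
              down = rep(-2.2, 8),
              mid = c(1.5, rep(1.0, 7)))
  colnames(fc) <- st
  q <- matrix(0.001, nrow(fc), 8, dimnames = dimnames(fc))
  q["gsr_failq", 3] <- 0.2
  cl <- classify_genes(make_fc_table(fc, q))
  got <- setNames(cl$class, cl$gene)
  expect_equal(got[["gsr"]], "GSR_up")
  expect_equal(got[["gsr_failq"]], "unclassified")  # one stress fails FDR
  expect_equal(got[["uniq_cd"]], "unique_up")
  expect_equal(cl$stress[cl$gene == "uniq_cd"], "Cd")
  expect_equal(got[["not_uniq"]], "unclassified")   # 1.5 elsewhere breaks the 1.4 bound
  expect_equal(got[["bg"]], "background")
  expect_equal(got[["low"]], "low_regulated")
  expect_equal(got[["down"]], "generally_down")
  expect_equal(got[["mid"]], "unclassified")
})

test_that("class predicates partition random FC tables deterministically", {
  set.seed(5)
  st <- default_stressors()
  for (rep_i in 1:5) {
    fc <- matrix(sample(c(-3, -2, -1.4, -1.1, 1, 1.1, 1.3, 1.5, 2, 2.5, 4),
                        200 * 8, replace = TRUE), 200, 8,
                 dimnames = list(sprintf("g%03d", 1:200), st))
    q <- matrix(sample(c(0.001, 0.2), 200 * 8, replace = TRUE, prob = c(.8, .2)),
                200, 8, dimnames = dimnames(fc))
    tab <- make_fc_table(fc, q)
    cl <- classify_genes(tab)          # mutual exclusivity asserted internally
    expect_equal(nrow(cl), 200)
    expect_true(all(!is.na(cl$class)))
    # permutation invariance: shuffling table rows changes nothing
    tab2 <- tab[sample(nrow(tab)), ]
    attr(tab2, "stressors") <- attr(tab, "stressors")
    class(tab2) <- class(tab)
    cl2 <- classify_genes(tab2)
    expect_equal(cl2[order(cl2$gene), ], cl[order(cl$gene), ], ignore_attr = TRUE)
  }
})

test_that("summary table satisfies its internal arithmetic identities", {
  sim <- simulate_expression(synthetic_config(
    n_genes = 400,
    planted_counts = list(gsr_up = 20, generally_down = 5, unique_up = 3,
                          unique_down = 2, background = 30, low_regulated = 10),
    noise_sd = 0, seed = 9))
  r <- suppressMessages(classifier_recovery(sim))
  tab <- summarize_classes(r$classification)
  ns <- 8
  expect_equal(tab$degs[1:ns], tab$up[1:ns] + tab$down[1:ns])
  expect_equal(tab$uniquely_regulated, tab$uniquely_up + tab$uniquely_down)
  expect_equal(tab$uniquely_up[ns + 1], sum(tab$uniquely_up[1:ns]))
  expect_equal(tab$generally_regulated, tab$generally_up + tab$generally_down)
  expect_equal(tab$generally_up[1], 20)
  expect_equal(tab$uniquely_up[ns + 1], 3 * ns)
})

test_that("published count table reproduces its non-redundant totals", {
  counts <- published_deg_counts()
  tot <- class_count_totals(counts)
  expect_identical(tot$uniquely_up_total, 219L)
  expect_identical(tot$uniquely_down_total, 370L)
  expect_identical(tot$uniquely_regulated_total, 591L)
  expect_identical(tot$generally_regulated, 577L)
  # the printed Cr row violates DEGs = up + down (2498 vs 2489); every other
  # row satisfies the identity, and the transcription keeps the printed values
  expect_identical(counts$stress[!tot$degs_consistent], "Cr")
})

test_that("basal expression comparison ranks planted classes and stays calibrated", {
  sim <- simulate_expression(synthetic_config(
    n_genes = 600,
    planted_counts = list(gsr_up = 50, background = 50, low_regulated = 50),
    noise_sd = 0.05, background_basal_boost = 10, seed = 21))
  r <- suppressMessages(classifier_recovery(sim))
  cb <- compare_basal_expression(sim$dataset, r$classification)
  expect_equal(names(which.max(cb$medians)), "background")
  expect_lt(cb$kruskal$p.value, 0.01)

  # single usable class: descriptive output only
  one <- r$classification[r$classification$class %in% c("GSR_up", "background"), ]
  one$class[one$class == "background"] <- "GSR_up"
  class(one) <- class(r$classification)
  cb1 <- suppressWarnings(compare_basal_expression(sim$dataset, one,
                                                   classes = c("GSR_up", "low")))
  expect_null(cb1$kruskal)

  # null calibration: classes drawn from one distribution
  set.seed(6)
  rej <- 0
  n_sim <- 500
  for (i in seq_len(n_sim)) {
    groups <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    if (kruskal_wallis(groups)$p.value < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.03)
  expect_lte(rej / n_sim, 0.07)
})
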