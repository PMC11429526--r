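test_that("per-sample frequencies are simplex-valued", {
  a <- toy_atlas()
  fr <- suppressWarnings(frequency_table(a, "subset"))
  expect_equal(fr["s1", c("tip", "vein")], c(tip = 2 / 3, vein = 1 / 3))
  expect_equal(unname(rowSums(fr)), c(1, 1))

  g <- generate_atlas(synthetic_config(
    atlas = list(n_genes = 120, n_cancer_types = 1, n_samples_per_type = 2,
                 n_cells_per_sample = 250)))
  fr2 <- frequency_table(g$atlas, "subset")
  expect_equal(unname(rowSums(fr2)), rep(1, nrow(fr2)))
  fr3 <- frequency_table(g$atlas, "compartment")
  expect_equal(unname(rowSums(fr3)), rep(1, nrow(fr3)))
  expect_error(frequency_table(a, "cluster"), "arg")
})

test_that("Pearson residuals match the chi-square independence model", {
  # exact independence: all residuals 0
  e0 <- enrichment_table(matrix(10, 2, 2))
  expect_equal(unname(e0$residuals), matrix(0, 2, 2))

  # hand-computed 2x2 residuals
  et <- enrichment_table(matrix(c(20, 10, 10, 20), 2, 2, byrow = TRUE))
  r11 <- (20 - 15) / sqrt(15)
  expect_equal(unname(et$residuals),
               matrix(c(r11, -r11, -r11, r11), 2, 2), tolerance = 1e-12)

  # structural invariants + cross-check against stats::chisq.test
  set.seed(8)
  obs <- matrix(rpois(12, 40), 3, 4)
  et2 <- enrichment_table(obs)
  expect_equal(rowSums(et2$expected), rowSums(obs))
  expect_equal(colSums(et2$expected), colSums(obs))
  expect_equal(sum(obs), sum(et2$expected))
  expect_equal(unname(rowSums(et2$residuals * sqrt(et2$expected))),
               rep(0, 3), tolerance = 1e-10)
  ct <- suppressWarnings(chisq.test(obs, correct = FALSE))
  expect_equal(unname(et2$expected), unname(ct$expected))
  expect_equal(unname(et2$residuals), unname(ct$residuals))
  expect_equal(et2$statistic, unname(ct$statistic))
  expect_equal(et2$p.value, ct$p.value)

  expect_warning(enrichment_table(matrix(c(2, 3, 4, 1), 2, 2)), "expected")
})

test_that("tissue enrichment recovers a planted tumor-enriched subset", {
  cfg <- synthetic_config(
    seed = 5,
    atlas = list(n_genes = 100, n_cancer_types = 1, n_samples_per_type = 3,
                 n_cells_per_sample = 300))
  g <- generate_atlas(cfg)
  et <- roe_enrichment(g$atlas, "tissue")
  top <- rownames(et$residuals)[which.max(et$residuals[, "tumor"])]
  expect_equal(top, "tip_CXCR4")  # the most tumor-enriched planted subset
  expect_lt(et$residuals["vein_SELE", "tumor"], 0)

  # residual signs for planted subsets survive 50% down-sampling
  set.seed(9)
  keep <- sample(nrow(g$atlas$counts), nrow(g$atlas$counts) / 2)
  et_half <- roe_enrichment(subset_cells(g$atlas, keep), "tissue")
  planted <- c("tip_CXCR4", "vein_SELE")
  expect_equal(sign(et_half$residuals[planted, "tumor"]),
               sign(et$residuals[planted, "tumor"]))

  # stratified mode agrees on planted signs and averages per-sample residuals
  et_s <- roe_enrichment(g$atlas, "tissue", mode = "stratified")
  expect_equal(sign(et_s$residuals[planted, "tumor"]),
               sign(et$residuals[planted, "tumor"]))
  expect_error(roe_enrichment(g$atlas, "cancer_type"), "fewer than 2 levels")
})

test_that("abundance comparison gives exact rank-sum p for separated groups", {
  freqs <- matrix(c(0.9, 0.8, 0.85, 0.7, 0.75,   # condition A, subset s1
                    0.1, 0.2, 0.15, 0.3, 0.25),  # condition B
                  ncol = 1, dimnames = list(NULL, "s1"))
  freqs <- cbind(freqs, s2 = 1 - freqs[, 1])
  cond <- rep(c("A", "B"), each = 5)
  res <- abundance_compare(freqs, cond)
  # complete separation at n = 5 vs 5: exact two-sided p = 2 / choose(10, 5)
  expect_equal(res$p[res$subset == "s1"], 2 / choose(10, 5))
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))

  # identical frequency vectors in both conditions carry no evidence
  f2 <- matrix(rep(c(0.4, 0.6), 6), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  res2 <- abundance_compare(f2, rep(c("A", "B"), 3))
  expect_true(all(res2$p == 1))

  expect_warning(abundance_compare(freqs[1:4, ], cond[c(1, 2, 3, 6)]),
                 "fewer than 3")
})

test_that("abundance comparison detects a planted compartment shift", {
  # planted shift in one of 4 compartments, 20 samples/arm
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    base <- matrix(rbeta(40 * 4, 2, 6), 40, 4)
    base[21:40, 2] <- rbeta(20, 4, 4)  # shifted compartment in arm B
    freqs <- base / rowSums(base)
    colnames(freqs) <- paste0("comp", 1:4)
    res <- abundance_compare(freqs, rep(c("A", "B"), each = 20))
    if (res$p[res$subset == "comp2"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("focal-frequency median split recovers planted companion coupling", {
  # companion equal to the focal frequency itself separates maximally
  focal <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.7, 0.8, 0.9)
  res <- frequency_association(focal, cbind(self = focal))
  expect_equal(res$p, 2 / choose(8, 4))
  expect_equal(res$direction, 1)

  expect_error(frequency_association(rep(0.5, 8), cbind(x = focal)),
               "split error")

  # planted coupling R = 0.6 at n = 40: direction recovered in >= 95/100 seeds
  ok <- 0
  for (s in 1:100) {
    set.seed(s)
    f <- rnorm(40)
    comp <- 0.6 * f + sqrt(1 - 0.36) * rnorm(40)
    res <- frequency_association(f, cbind(c1 = comp))
    if (res$direction == 1) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("composition clustering equals the brute-force agglomeration oracle", {
  comp <- rbind(A = c(0.5, 0.5), B = c(0.5, 0.5), C = c(0.1, 0.9))
  cl <- composition_clustering(comp)
  expect_equal(cl$hclust$height[1], 0)  # identical pair merges first
  first_pair <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first_pair, c("A", "B"))

  set.seed(13)
  comp5 <- matrix(rbeta(5 * 6, 2, 2), 5, 6,
                  dimnames = list(paste0("can", 1:5), paste0("s", 1:6)))
  comp5 <- comp5 / rowSums(comp5)
  cl5 <- composition_clustering(comp5)
  expect_equal(cl5$hclust$height, average_linkage_heights(dist(comp5)))
  expect_error(composition_clustering(comp5[1, , drop = FALSE]), "at least 2")

  # Aitchison mode runs and keeps all leaves
  cl_a <- composition_clustering(comp5, distance = "aitchison")
  expect_setequal(cl_a$order, rownames(comp5))
})

test_that("compartment similarity ranks a divergent compartment lowest", {
  # identical profiles across cancers -> similarity 1
  set.seed(21)
  base <- rpois(80, 6)
  counts <- do.call(rbind, replicate(40, base, simplify = FALSE))
  a <- matrix_atlas(counts,
                    subset = rep(c("tip", "cap"), 20),
                    compartment = rep(c("tip", "cap"), 20),
                    cancer = rep(c("C01", "C02"), each = 20),
                    sample = rep(c("s1", "s2"), each = 20))
  sim <- compartment_similarity(a, n_hvg = 80, min_cells = 5)
  expect_equal(sim$mean_similarity, c(1, 1))

  # planted cancer-specific programs in capillaries only
  set.seed(22)
  n_per <- 30
  cancers <- c("C01", "C02", "C03")
  blocks <- list()
  labels <- list()
  for (ci in seq_along(cancers)) {
    for (cp in c("tip", "capillary")) {
      mu <- rep(5, 60)
      if (cp == "capillary") mu[((ci - 1) * 10) + 1:10] <- 40  # cancer-unique block
      blocks[[length(blocks) + 1]] <- matrix(rpois(n_per * 60, rep(mu, each = n_per)),
                                             n_per, 60)
      labels[[length(labels) + 1]] <- data.frame(cp = cp, can = cancers[ci])
    }
  }
  lab <- do.call(rbind, labels)
  a2 <- matrix_atlas(do.call(rbind, blocks),
                     subset = rep(lab$cp, each = n_per),
                     compartment = rep(lab$cp, each = n_per),
                     cancer = rep(lab$can, each = n_per),
                     sample = rep(paste0(lab$can, "_", lab$cp), each = n_per))
  sim2 <- compartment_similarity(a2, n_hvg = 60, min_cells = 5)
  expect_lt(sim2$mean_similarity[sim2$compartment == "capillary"],
            sim2$mean_similarity[sim2$compartment == "tip"])
})
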