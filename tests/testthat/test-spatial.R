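test_that("region sampling tallies points with half-open boundaries", {
  empty <- spatial_slice("e", data.frame(x = numeric(0), y = numeric(0),
                                         cell_type = character(0)),
                         window = c(0, 2000, 0, 2000))
  cat_e <- sample_regions(empty, side = 1000, n_regions = 5, seed = 1,
                          cell_types = c("A", "B"))
  expect_true(all(cat_e$counts == 0))

  one <- spatial_slice("o", data.frame(x = 3, y = 4, cell_type = "A"),
                       window = c(0, 10, 0, 10))
  cat_o <- sample_regions(one, side = 10, n_regions = 3, seed = 1)
  expect_true(all(cat_o$counts[, "A"] == 1))

  tiny <- spatial_slice("t", data.frame(x = 1:3, y = 1:3, cell_type = "A"))
  expect_error(sample_regions(tiny, side = 1000), "smaller side")
})

test_that("region counts equal the brute-force point-in-rectangle oracle", {
  set.seed(41)
  pts <- data.frame(x = runif(500, 0, 5000), y = runif(500, 0, 5000),
                    cell_type = sample(c("A", "B", "C"), 500, replace = TRUE))
  sl <- spatial_slice("s", pts, window = c(0, 5000, 0, 5000))
  cat1 <- sample_regions(sl, side = 1000, n_regions = 200, seed = 42)
  for (i in seq_len(200)) {
    x0 <- cat1$regions$x0[i]; y0 <- cat1$regions$y0[i]
    inside <- pts$x >= x0 & pts$x < x0 + 1000 & pts$y >= y0 & pts$y < y0 + 1000
    oracle <- table(factor(pts$cell_type[inside], levels = c("A", "B", "C")))
    expect_equal(unname(cat1$counts[i, ]), as.integer(oracle))
  }

  # translation equivariance: shifting points and window leaves counts unchanged
  sl2 <- spatial_slice("s2", transform(pts, x = x + 137, y = y - 59),
                       window = c(137, 5137, -59, 4941))
  cat2 <- sample_regions(sl2, side = 1000, n_regions = 200, seed = 42)
  expect_equal(cat2$counts, cat1$counts)
})

test_that("region grouping separates planted co-localization", {
  expect_error(
    region_group_compare(
      sample_regions(spatial_slice("s", data.frame(x = runif(20, 0, 2000),
                                                   y = runif(20, 0, 2000),
                                                   cell_type = "A"),
                                   window = c(0, 2000, 0, 2000)),
                     side = 500, n_regions = 10, seed = 2,
                     cell_types = c("A", "B")),
      "A", high_threshold = 999),
    "empty region group")

  # planted niches: epithelial excess in tip-rich regions, 25 seeds
  ok <- 0
  for (s in 1:25) {
    sp <- generate_spatial(synthetic_config(seed = s))$slices
    catal <- bind_regions(lapply(sp, sample_regions, side = 1000,
                                 n_regions = 60, seed = s))
    res <- region_group_compare(catal, "tip_like", high_threshold = 5)
    epi <- res[res$companion == "epithelial", ]
    if (epi$median_high > epi$median_low) ok <- ok + 1
  }
  expect_gte(ok, 23)
})

test_that("neighborhood counts equal the all-pairs distance oracle", {
  # one focal cell, one neighbor: positive residual iff type under-represented
  sl <- spatial_slice("s", data.frame(
    x = c(0, 10, 500, 600), y = c(0, 10, 500, 600),
    cell_type = c("F", "T", "T", "U")), window = c(0, 1000, 0, 1000))
  np <- neighborhood_residuals(sl, "F", radius = 50)
  expect_equal(unname(np$observed[c("T", "U")]), c(1, 0))
  expect_gt(np$residuals[["T"]], 0)  # T slice frequency 2/3 < 1
  expect_lt(np$residuals[["U"]], 0)

  set.seed(43)
  pts <- data.frame(x = runif(300, 0, 1000), y = runif(300, 0, 1000),
                    cell_type = sample(c("F", "T", "E"), 300, replace = TRUE))
  sl2 <- spatial_slice("s2", pts, window = c(0, 1000, 0, 1000))
  for (r in c(30, 80)) {
    np2 <- neighborhood_residuals(sl2, "F", radius = r)
    d <- as.matrix(dist(pts[, c("x", "y")]))
    fo <- pts$cell_type == "F"
    oracle_mult <- colSums(d[fo, !fo, drop = FALSE] <= r)
    oracle <- tapply(oracle_mult, pts$cell_type[!fo], sum)
    expect_equal(unname(np2$observed[names(oracle)]), as.vector(oracle))
    # dedup variant counts each neighbor once
    npd <- neighborhood_residuals(sl2, "F", radius = r, dedup = TRUE)
    oracle_d <- tapply(oracle_mult > 0, pts$cell_type[!fo], sum)
    expect_equal(unname(npd$observed[names(oracle_d)]), as.vector(oracle_d))
  }
  expect_error(neighborhood_residuals(sl2, "Z", 50), "no focal cells")
})

test_that("label permutation centers neighborhood residuals on zero", {
  set.seed(44)
  pts <- data.frame(x = runif(250, 0, 1500), y = runif(250, 0, 1500),
                    cell_type = rep(c("F", "T", "E", "U"), c(30, 70, 80, 70)))
  res <- replicate(100, {
    p2 <- pts
    p2$cell_type <- sample(p2$cell_type)
    sl <- spatial_slice("s", p2, window = c(0, 1500, 0, 1500))
    neighborhood_residuals(sl, "F", radius = 120)$residuals[["T"]]
  })
  expect_lt(abs(mean(res)), 2 * sd(res) / sqrt(100))
})

test_that("paired residual test handles degenerate and planted cases", {
  mk_prof <- function(id, r_t) {
    structure(list(slice_id = id, focal_type = "F",
                   observed = c(T1 = 1), expected = c(T1 = 1),
                   residuals = c(T1 = r_t), n_focal = 1, radius = 50),
              class = "NeighborhoodProfile")
  }
  pa <- lapply(1:4, function(i) mk_prof(paste0("s", i), i / 2))
  expect_equal(paired_residual_test(pa, pa, "T1"),
               list(t = 0, p = 1, mean_difference = 0, n_slices = 4,
                    exact_separation = FALSE))
  pb <- lapply(1:4, function(i) mk_prof(paste0("s", i), i / 2 - 1))
  deg <- paired_residual_test(pa, pb, "T1")
  expect_true(deg$exact_separation)
  expect_equal(deg$mean_difference, 1)
  expect_true(is.na(deg$p))
  expect_error(paired_residual_test(pa[1:3], pb[2:4], "T1"), "pairing error")

  # planted niches: tip-like neighborhoods enriched for epithelial cells
  # relative to vein-like neighborhoods (and depleted for T cells), 20 seeds
  ok <- 0
  for (s in 1:20) {
    sp <- generate_spatial(synthetic_config(seed = s))$slices
    prof_a <- lapply(sp, neighborhood_residuals, focal_type = "tip_like",
                     radius = 50)
    prof_b <- lapply(sp, neighborhood_residuals, focal_type = "vein_like",
                     radius = 50)
    d_epi <- paired_residual_test(prof_a, prof_b, "epithelial")$mean_difference
    d_t <- paired_residual_test(prof_a, prof_b, "T_cell")$mean_difference
    if (d_epi > 0 && d_t < 0) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("Thomas generator matches the analytic neighbor expectation", {
  # E[neighbors within r of a typical point] =
  #   lambda*pi*r^2 + mu*(1 - exp(-r^2 / (4 sigma^2)))
  kappa <- 20 / 1e6; mu <- 20; sigma <- 30; r <- 50; W <- 1000
  analytic <- kappa * mu * pi * r^2 + mu * (1 - exp(-r^2 / (4 * sigma^2)))
  set.seed(99)
  est <- replicate(200, {
    pts <- rthomas_points(kappa, mu, sigma, c(-100, W + 100, -100, W + 100),
                          clip = FALSE)
    inner <- pts$x >= 0 & pts$x <= W & pts$y >= 0 & pts$y <= W
    if (!sum(inner)) return(NA)
    tot <- 0
    for (i in which(inner)) {
      tot <- tot + sum((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2 <= r^2) - 1
    }
    tot / sum(inner)
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - analytic) / analytic, 0.05)
})
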