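# Small fixtures built in code; all randomness goes through explicit seeds.

# Deterministic 6-cell, 8-gene atlas spanning 2 subsets, 2 tissues, 2 samples.
toy_atlas <- function() {
  counts <- rbind(
    c(5, 3, 0, 0, 1, 2, 0, 4),
    c(4, 2, 1, 0, 0, 3, 0, 5),
    c(0, 0, 6, 4, 2, 0, 1, 0),
    c(1, 0, 5, 5, 3, 0, 0, 1),
    c(2, 1, 1, 1, 1, 1, 1, 1),
    c(0, 2, 0, 3, 0, 4, 0, 5)
  )
  genes <- paste0("g", 1:8)
  meta <- data.frame(
    cell_id = paste0("c", 1:6),
    subset_label = c("tip", "tip", "vein", "vein", "tip", "vein"),
    compartment_label = c("tip", "tip", "vein", "vein", "tip", "vein"),
    cancer_type = "C01",
    tissue = c("tumor", "tumor", "tumor", "normal", "normal", "normal"),
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    patient_id = c("p1", "p1", "p1", "p1", "p1", "p1")
  )
  CellAtlas(counts, genes, meta)
}

# Build an atlas directly from a counts matrix with minimal metadata.
matrix_atlas <- function(counts, subset = "s1", tissue = "tumor",
                         cancer = "C01", sample = NULL, compartment = subset) {
  n <- nrow(counts)
  rec <- function(x) rep_len(x, n)
  if (is.null(sample)) sample <- paste0(rec(cancer), "_", rec(tissue))
  meta <- data.frame(
    cell_id = paste0("c", seq_len(n)),
    subset_label = rec(subset), compartment_label = rec(compartment),
    cancer_type = rec(cancer), tissue = rec(tissue),
    sample_id = rec(sample), patient_id = rec(sample)
  )
  CellAtlas(counts, paste0("g", seq_len(ncol(counts))), meta)
}

# Independent recovery-curve AUC oracle: literal step-curve accumulation.
aucell_oracle <- function(set_ranks, n_genes, n_set, top_fraction = 0.05) {
  k <- ceiling(top_fraction * n_genes)
  hits <- vapply(seq_len(k), function(i) sum(set_ranks <= i), numeric(1))
  max_hits <- vapply(seq_len(k), function(i) min(i, n_set), numeric(1))
  sum(hits) / sum(max_hits)
}

# Exact two-sided rank-sum p-value by full enumeration (tie-free data).
exact_ranksum_p <- function(a, b) {
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ws <- apply(utils::combn(N, na), 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Average-linkage agglomeration oracle: returns merge heights in order.
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}
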