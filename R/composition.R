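#' Per-sample cell-type frequency table
#'
#' @param atlas a [CellAtlas()].
#' @param level `"compartment"` or `"subset"`: which annotation level the
#'   frequencies are computed over.
#' @param min_cells samples with fewer cells are kept but flagged (the
#'   `flagged` attribute lists them).
#' @return samples x levels matrix of frequencies; each row sums to 1.
#' @export
frequency_table <- function(atlas, level = c("subset", "compartment"),
                            min_cells = 10) {
  level <- match.arg(level)
  key <- if (level == "subset") "subset_label" else "compartment_label"
  tab <- table(atlas$cell_meta$sample_id, atlas$cell_meta[[key]])
  n <- rowSums(tab)
  freqs <- as.matrix(tab / n)
  flagged <- rownames(freqs)[n < min_cells]
  if (length(flagged)) {
    warning(length(flagged), " sample(s) below min_cells = ", min_cells, ": ",
            paste(flagged, collapse = ", "))
  }
  attr(freqs, "n_cells") <- as.integer(n)
  attr(freqs, "flagged") <- flagged
  freqs
}

#' Observed/expected enrichment of a contingency table
#'
#' Core of the Ro/e-style enrichment analysis: expected counts under the
#' chi-square independence model, \eqn{E_{ij} = r_i c_j / N}, and Pearson
#' residuals \eqn{(O_{ij} - E_{ij}) / \sqrt{E_{ij}}}. A positive residual
#' for (subset, condition) means the subset is over-represented in that
#' condition.
#'
#' @param observed non-negative count matrix (rows = subsets, columns =
#'   conditions).
#' @param min_expected expected counts below this trigger a warning (the
#'   chi-square approximation degrades), never a failure.
#' @return an `EnrichmentTable`: list with `observed`, `expected`,
#'   `residuals`, `statistic` (chi-square), `df` and `p.value`.
#' @export
enrichment_table <- function(observed, min_expected = 5) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stop("negative counts", call. = FALSE)
  if (nrow(observed) < 1 || ncol(observed) < 2) {
    stop("need a matrix with at least 2 condition columns", call. = FALSE)
  }
  N <- sum(observed)
  expected <- outer(rowSums(observed), colSums(observed)) / N
  if (any(expected < min_expected)) {
    warning(sum(expected < min_expected), " cell(s) have expected count < ",
            min_expected, "; chi-square approximation may be poor")
  }
  residuals <- (observed - expected) / sqrt(expected)
  residuals[expected == 0] <- 0
  stat <- sum(residuals^2)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  structure(list(observed = observed, expected = expected,
                 residuals = residuals, statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "EnrichmentTable")
}

#' @export
print.EnrichmentTable <- function(x, ...) {
  cat("EnrichmentTable:", nrow(x$observed), "subsets x",
      ncol(x$observed), "conditions; chi-square =",
      format(x$statistic, digits = 4), "on", x$df, "df\n")
  print(round(x$residuals, 3))
  invisible(x)
}

#' Tissue/condition enrichment of cell subsets (Ro/e)
#'
#' Cross-tabulates cells by subset and condition and summarizes over- or
#' under-representation with Pearson residuals. The default pools cells
#' across samples; `mode = "stratified"` instead averages per-sample
#' residuals, which guards against a few large samples dominating the
#' pooled table.
#'
#' @param atlas a [CellAtlas()].
#' @param condition_key `cell_meta` column defining the conditions (e.g.
#'   `"tissue"`); must have at least 2 observed levels.
#' @param level annotation level for the rows, `"subset"` or
#'   `"compartment"`.
#' @param mode `"pooled"` (default) or `"stratified"`.
#' @param min_expected see [enrichment_table()].
#' @return an `EnrichmentTable`; in stratified mode `residuals` holds the
#'   mean of per-sample residual matrices and `n_samples` their count.
#' @export
roe_enrichment <- function(atlas, condition_key,
                           level = c("subset", "compartment"),
                           mode = c("pooled", "stratified"),
                           min_expected = 5) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  key <- if (level == "subset") "subset_label" else "compartment_label"
  meta <- atlas$cell_meta
  if (!condition_key %in% names(meta)) {
    stop("parameter error: unknown condition_key '", condition_key, "'",
         call. = FALSE)
  }
  cond <- meta[[condition_key]]
  if (length(unique(cond)) < 2) {
    stop("condition '", condition_key, "' has fewer than 2 levels",
         call. = FALSE)
  }
  if (anyNA(cond) || anyNA(meta[[key]])) {
    stop("validation error: unlabeled cells present", call. = FALSE)
  }
  pooled <- enrichment_table(table(meta[[key]], cond), min_expected)
  if (mode == "pooled") return(pooled)
  # stratified: each sample's subset counts are compared with what the
  # atlas-wide subset frequencies predict for a sample of its size, and the
  # per-sample residuals are averaged within each condition, so every
  # sample carries equal weight regardless of its cell count
  subsets <- rownames(pooled$observed)
  p_overall <- rowSums(pooled$observed) / sum(pooled$observed)
  samp <- split(seq_len(nrow(meta)), meta$sample_id)
  res_samp <- vapply(samp, function(i) {
    o <- table(factor(meta[[key]][i], levels = subsets))
    e <- length(i) * p_overall
    r <- (as.numeric(o) - e) / sqrt(e)
    r[e == 0] <- 0
    r
  }, numeric(length(subsets)))
  if (any(vapply(samp, function(i) length(unique(cond[i])), integer(1)) > 1)) {
    stop("stratified mode needs a sample-level condition", call. = FALSE)
  }
  samp_cond <- vapply(samp, function(i) as.character(cond[i][1]), character(1))
  pooled$residuals <- vapply(colnames(pooled$observed), function(cc) {
    rowMeans(res_samp[, samp_cond == cc, drop = FALSE])
  }, numeric(length(subsets)))
  rownames(pooled$residuals) <- subsets
  pooled$n_samples <- length(samp)
  pooled
}

#' Compare per-sample frequencies between two conditions
#'
#' Two-sided unpaired Wilcoxon rank-sum test per subset, with
#' Benjamini-Hochberg adjustment across subsets.
#'
#' @param freqs samples x subsets frequency matrix ([frequency_table()]).
#' @param condition factor/character of length `nrow(freqs)` with exactly
#'   two levels (e.g. tumor/normal per sample).
#' @param min_samples subsets are only tested when both conditions have at
#'   least this many samples (whole-matrix property, checked once).
#' @return data frame with `subset`, `median_a`, `median_b`, `p`, `p_adj`;
#'   the condition labels backing `median_a`/`median_b` are recorded in the
#'   `conditions` attribute.
#' @export
abundance_compare <- function(freqs, condition, min_samples = 3) {
  condition <- as.factor(condition)
  if (nlevels(droplevels(condition)) != 2) {
    stop("condition must have exactly 2 levels", call. = FALSE)
  }
  condition <- droplevels(condition)
  lv <- levels(condition)
  n_per <- table(condition)
  if (any(n_per < min_samples)) {
    warning("condition(s) with fewer than ", min_samples,
            " samples: results skipped")
    return(structure(data.frame(subset = character(0), median_a = numeric(0),
                                median_b = numeric(0), p = numeric(0),
                                p_adj = numeric(0)),
                     conditions = lv))
  }
  res <- lapply(colnames(freqs), function(s) {
    a <- freqs[condition == lv[1], s]
    b <- freqs[condition == lv[2], s]
    p <- tryCatch(suppressWarnings(stats::wilcox.test(a, b)$p.value),
                  error = function(e) NA_real_)
    data.frame(subset = s, median_a = stats::median(a),
               median_b = stats::median(b), p = p)
  })
  out <- do.call(rbind, res)
  out$p[is.na(out$p)] <- 1  # constant, all-tied columns carry no evidence
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  attr(out, "conditions") <- lv
  out
}

#' Association between a focal subset's frequency and companion abundances
#'
#' Samples are split at the median focal frequency into high/low groups;
#' each companion cell type's abundance is compared between the groups with
#' a two-sided rank-sum test, and the direction is the sign of
#' (median high - median low).
#'
#' @param focal_freq per-sample frequency of the focal subset (named
#'   vector).
#' @param companions samples x companion-types abundance matrix, rows
#'   aligned with `focal_freq`.
#' @return data frame with `companion`, `p`, `p_adj`, `direction` (+1, -1
#'   or 0) and group medians.
#' @export
frequency_association <- function(focal_freq, companions) {
  companions <- as.matrix(companions)
  if (nrow(companions) != length(focal_freq)) {
    stop("companion rows must align with focal_freq", call. = FALSE)
  }
  med <- stats::median(focal_freq)
  high <- focal_freq > med
  if (all(high) || !any(high)) {
    # fall back to >=: a strict split fails when > half the values tie at the median
    high <- focal_freq >= med
  }
  if (all(high) || !any(high)) {
    stop("split error: all focal frequencies identical", call. = FALSE)
  }
  res <- lapply(colnames(companions), function(ct) {
    hi <- companions[high, ct]; lo <- companions[!high, ct]
    p <- tryCatch(suppressWarnings(stats::wilcox.test(hi, lo)$p.value),
                  error = function(e) 1)
    d <- stats::median(hi) - stats::median(lo)
    data.frame(companion = ct, median_high = stats::median(hi),
               median_low = stats::median(lo), p = p, direction = sign(d))
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("companion", "median_high", "median_low", "p", "p_adj", "direction")]
}

#' Hierarchical clustering of cancers by cellular composition
#'
#' Average-linkage clustering on distances between per-cancer mean
#' composition vectors. Rows are sorted by label first so that the result
#' is invariant to input order; ties in the agglomeration are then resolved
#' deterministically by `stats::hclust`.
#'
#' @param composition cancers x subsets matrix of mean frequencies (rows
#'   should each sum to 1).
#' @param distance `"euclidean"` (default) or `"aitchison"` (Euclidean on
#'   centered log-ratios with a pseudo-frequency of half the smallest
#'   nonzero value).
#' @return list with `hclust` (the tree) and `order` (leaf labels, left to
#'   right).
#' @export
composition_clustering <- function(composition,
                                   distance = c("euclidean", "aitchison")) {
  distance <- match.arg(distance)
  composition <- as.matrix(composition)
  if (nrow(composition) < 2) {
    stop("need at least 2 cancers to cluster", call. = FALSE)
  }
  composition <- composition[order(rownames(composition)), , drop = FALSE]
  if (distance == "aitchison") {
    eps <- min(composition[composition > 0]) / 2
    lg <- log(composition + eps)
    composition <- lg - rowMeans(lg)
  }
  hc <- stats::hclust(stats::dist(composition), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}

#' Cross-cancer transcriptome similarity of each compartment
#'
#' For every compartment present in at least two cancers, pseudobulk
#' profiles per (cancer, compartment) are correlated (Pearson, over the
#' most variable genes) for every cancer pair, and the mean pairwise
#' correlation is reported. Low values flag compartments whose
#' transcriptome diverges most across cancers.
#'
#' @param atlas a [CellAtlas()].
#' @param n_hvg number of top-variance genes used (default 2000; capped at
#'   the number of genes available).
#' @param min_cells minimum cells per (cancer, compartment) pseudobulk.
#' @return data frame with `compartment`, `mean_similarity`, `n_cancers`.
#' @export
compartment_similarity <- function(atlas, n_hvg = 2000, min_cells = 20) {
  prof <- pseudobulk(atlas, c("cancer_type", "compartment_label"),
                     min_cells = min_cells)
  parts <- strsplit(rownames(prof), ".", fixed = TRUE)
  cancer <- vapply(parts, `[`, character(1), 1)
  compartment <- vapply(parts, function(p) paste(p[-1], collapse = "."),
                        character(1))
  v <- apply(prof, 2, stats::var)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, ncol(prof)))]
  prof <- prof[, hvg, drop = FALSE]
  res <- lapply(unique(compartment), function(cp) {
    rows <- which(compartment == cp)
    if (length(rows) < 2) {
      warning("compartment '", cp, "' present in < 2 cancers; skipped")
      return(NULL)
    }
    cors <- stats::cor(t(prof[rows, , drop = FALSE]))
    data.frame(compartment = cp,
               mean_similarity = mean(cors[upper.tri(cors)]),
               n_cancers = length(rows))
  })
  do.call(rbind, Filter(Negate(is.null), res))
}
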