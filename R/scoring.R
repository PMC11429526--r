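#' Rank genes within each cell
#'
#' Rank-based gene-set activity scoring depends only on the within-cell
#' ordering of genes by raw count: rank 1 is the highest-expressed gene.
#' Ties receive the average rank by default, which makes the score
#' deterministic; a seeded random tie-break mode is provided for parity
#' with implementations that randomize ties.
#'
#' @param atlas a [CellAtlas()] or a cells x genes count matrix.
#' @param ties `"average"` (default) or `"random"`.
#' @param seed RNG seed used only when `ties = "random"`.
#' @return cells x genes matrix of ranks (descending in expression).
#' @export
rank_genes_per_cell <- function(atlas, ties = c("average", "random"),
                                seed = 1L) {
  ties <- match.arg(ties)
  m <- if (inherits(atlas, "CellAtlas")) as.matrix(atlas$counts) else as.matrix(atlas)
  rk <- if (ties == "random") {
    withr_seed(seed, t(apply(m, 1, function(x) rank(-x, ties.method = "random"))))
  } else {
    t(apply(m, 1, function(x) rank(-x, ties.method = "average")))
  }
  dimnames(rk) <- dimnames(m)
  rk
}

# run expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Per-cell gene-set activity as the area under the recovery curve
#'
#' For each cell, genes are ordered by expression rank and the recovery
#' curve counts, at each of the top `k = ceiling(top_fraction * G)` rank
#' positions, how many gene-set members have already been recovered. The
#' score is the area under this step curve divided by the maximum
#' achievable area (all set genes at the very top), so it lies in
#' \eqn{[0, 1]}. It is invariant to any monotone transform of the counts.
#'
#' @param ranks cells x genes rank matrix from [rank_genes_per_cell()].
#' @param gene_set character vector of gene symbols ([read_gene_sets()]
#'   entry), or a list of such vectors to score several sets at once.
#' @param top_fraction fraction of top-ranked genes forming the curve
#'   support; default 0.05.
#' @return numeric vector of per-cell scores (or a cells x sets matrix when
#'   `gene_set` is a list), named by cell.
#' @export
aucell_score <- function(ranks, gene_set, top_fraction = 0.05) {
  if (is.list(gene_set)) {
    out <- vapply(gene_set, function(s) aucell_score(ranks, s, top_fraction),
                  numeric(nrow(ranks)))
    rownames(out) <- rownames(ranks)
    return(out)
  }
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      top_fraction <= 0 || top_fraction > 1) {
    stop("parameter error: top_fraction must lie in (0, 1]", call. = FALSE)
  }
  G <- ncol(ranks)
  k <- ceiling(top_fraction * G)
  idx <- which(colnames(ranks) %in% gene_set)
  if (!length(idx)) {
    stop("no gene of set ", deparse(substitute(gene_set)),
         " is present in the atlas", call. = FALSE)
  }
  S <- length(idx)
  # a set gene at (possibly fractional) rank r contributes to the curve at
  # integer positions ceiling(r)..k, i.e. max(0, k - ceiling(r) + 1) area units
  contrib <- pmax(k - ceiling(ranks[, idx, drop = FALSE]) + 1, 0)
  auc <- rowSums(contrib)
  i <- seq_len(k)
  max_auc <- sum(pmin(i, S))
  out <- auc / max_auc
  names(out) <- rownames(ranks)
  out
}

#' Bulk signature score: mean of per-gene z-scores
#'
#' Each set gene is z-scored across samples and the score is the mean over
#' set genes, so scores average approximately zero across samples.
#' Zero-variance genes are excluded with a warning.
#'
#' @param bulk genes x samples numeric matrix (e.g. log expression).
#' @param gene_set character vector of gene symbols.
#' @return per-sample numeric vector of scores.
#' @export
bulk_signature_score <- function(bulk, gene_set) {
  idx <- which(rownames(bulk) %in% gene_set)
  if (!length(idx)) {
    stop("no gene of the set is present in the bulk matrix", call. = FALSE)
  }
  sub <- bulk[idx, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance gene(s): ",
            paste(rownames(sub)[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(sub)) stop("all set genes have zero variance", call. = FALSE)
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Relative score of one signature against another
#'
#' The balance between two signatures (e.g. the proinflammatory vein
#' signature relative to the angiogenic tip signature) is summarized per
#' sample. The default `"zdiff"` mode is the difference of the z-scored
#' signatures, which is location/scale invariant and stable when scores
#' cross zero; `"ratio"` computes a literal quotient after shifting both
#' scores to be positive (min + 1).
#'
#' @param score_a,score_b equal-length numeric vectors on the same samples.
#' @param mode `"zdiff"` (default) or `"ratio"`.
#' @return per-sample numeric vector.
#' @export
relative_score <- function(score_a, score_b, mode = c("zdiff", "ratio")) {
  mode <- match.arg(mode)
  if (length(score_a) != length(score_b)) {
    stop("score vectors differ in length (", length(score_a), " vs ",
         length(score_b), ")", call. = FALSE)
  }
  zs <- function(x) if (stats::sd(x) == 0) x * 0 else (x - mean(x)) / stats::sd(x)
  if (mode == "zdiff") {
    zs(score_a) - zs(score_b)
  } else {
    (score_a - min(score_a) + 1) / (score_b - min(score_b) + 1)
  }
}

#' Pearson correlation between two score vectors
#'
#' @param scores_x,scores_y paired numeric vectors, `n >= 3`.
#' @return list with `R` (Pearson correlation) and `p` (two-sided t-based
#'   p-value), plus `n`.
#' @export
score_correlation <- function(scores_x, scores_y) {
  if (length(scores_x) != length(scores_y)) {
    stop("score vectors differ in length", call. = FALSE)
  }
  keep <- is.finite(scores_x) & is.finite(scores_y)
  x <- scores_x[keep]; y <- scores_y[keep]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}
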