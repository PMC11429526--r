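#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided unpaired Wilcoxon test on log-normalized expression,
#' with Benjamini-Hochberg adjustment across genes and log2 fold change of
#' the group means (pseudocount 1e-9 on the normalized means). Small groups
#' without ties use the exact null distribution (delegated to
#' [stats::wilcox.test()]); larger groups use the tie-corrected normal
#' approximation with continuity correction, computed in a single
#' vectorized pass over genes, which matches `wilcox.test(exact = FALSE)`
#' to floating-point accuracy.
#'
#' @param atlas a [CellAtlas()].
#' @param group_a,group_b logical, integer or character (cell id) indices
#'   of the two cell groups; at least 3 cells each.
#' @param scale_factor passed to [normalize_counts()].
#' @return `DEResult` data frame: `gene`, `mean_a`, `mean_b`, `log2fc`,
#'   `p`, `p_adj`.
#' @export
wilcoxon_de <- function(atlas, group_a, group_b, scale_factor = 1e4) {
  ia <- resolve_cells(atlas, group_a)
  ib <- resolve_cells(atlas, group_b)
  if (length(ia) == 0 || length(ib) == 0) stop("empty cell group", call. = FALSE)
  if (length(ia) < 3 || length(ib) < 3) {
    stop("need at least 3 cells per group", call. = FALSE)
  }
  if (length(intersect(ia, ib))) stop("groups overlap", call. = FALSE)
  expr <- normalize_counts(atlas, scale_factor)
  xa <- expr[ia, , drop = FALSE]
  xb <- expr[ib, , drop = FALSE]
  p <- rank_sum_p(xa, xb)
  mean_a <- colMeans(xa)
  mean_b <- colMeans(xb)
  out <- data.frame(gene = atlas$gene_ids,
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_a + 1e-9) / (mean_b + 1e-9)),
                    p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  class(out) <- c("DEResult", "data.frame")
  out
}

resolve_cells <- function(atlas, sel) {
  n <- nrow(atlas$counts)
  if (is.logical(sel)) {
    stopifnot(length(sel) == n)
    which(sel)
  } else if (is.character(sel)) {
    i <- match(sel, atlas$cell_meta$cell_id)
    if (anyNA(i)) stop("unknown cell id(s)", call. = FALSE)
    i
  } else {
    stopifnot(all(sel >= 1 & sel <= n))
    as.integer(sel)
  }
}

# columnwise two-sided rank-sum p-values; exact for small tie-free columns,
# otherwise the tie-corrected normal approximation with continuity correction
rank_sum_p <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb); N <- na + nb
  x <- rbind(xa, xb)
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    r <- rank(v)
    has_ties <- anyDuplicated(v) > 0
    if (N < 50 && !has_ties) {
      return(stats::wilcox.test(v[seq_len(na)], v[na + seq_len(nb)],
                                exact = TRUE)$p.value)
    }
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    mu <- na * nb / 2
    nties <- table(r)
    sigma2 <- (na * nb / 12) *
      ((N + 1) - sum(nties^3 - nties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)  # fully tied column
    z <- W - mu
    z <- z - sign(z) * 0.5  # continuity correction
    p <- 2 * stats::pnorm(-abs(z) / sqrt(sigma2))
    min(p, 1)
  }, numeric(1))
}

#' Top tumor-upregulated genes with rank scores
#'
#' Filters a [wilcoxon_de()] result to significantly upregulated genes and
#' assigns each a linear rank score: the top gene of the list scores 1 and
#' the score decreases by `1/n_top` per rank, so a gene at rank r gets
#' `(n_top - r + 1) / n_top`. Ordering is by adjusted p-value, then larger
#' absolute fold change, then gene symbol.
#'
#' @param de a `DEResult`.
#' @param n_top maximum list length (default 100).
#' @param lfc_min minimum log2 fold change (default 0.25).
#' @param padj_max maximum BH-adjusted p (default 0.05).
#' @param score `"linear"` (default) or `"reciprocal"` (1/rank).
#' @return data frame `gene`, `rank`, `rank_score`, plus the DE columns;
#'   empty (with a warning) when no gene passes.
#' @export
top_upregulated <- function(de, n_top = 100, lfc_min = 0.25, padj_max = 0.05,
                            score = c("linear", "reciprocal")) {
  score <- match.arg(score)
  pass <- de$log2fc >= lfc_min & de$p_adj <= padj_max
  if (!any(pass)) {
    warning("no gene passes the upregulation filters")
    out <- de[0, ]
    out$rank <- integer(0); out$rank_score <- numeric(0)
    return(out)
  }
  sub <- de[pass, , drop = FALSE]
  ord <- order(sub$p_adj, -abs(sub$log2fc), sub$gene)
  sub <- sub[utils::head(ord, n_top), , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  sub$rank_score <- if (score == "linear") {
    (n_top - sub$rank + 1) / n_top
  } else {
    1 / sub$rank
  }
  rownames(sub) <- NULL
  sub
}

#' Distinct-mode set intersections
#'
#' Assigns every gene in the union of the input lists to exactly one
#' membership pattern -- the exact subset of categories that contain it --
#' and reports the size of each pattern (the "distinct" mode of an UpSet
#' plot). Pattern sizes therefore sum to the union cardinality.
#'
#' @param lists named list (>= 2 entries) of character vectors.
#' @return data frame with one row per non-empty category combination:
#'   logical membership columns, `pattern` (categories joined with `&`),
#'   `size`, and a `genes` list-column of the member genes.
#' @export
distinct_intersection <- function(lists) {
  k <- length(lists)
  if (k < 2) stop("need at least 2 categories", call. = FALSE)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop("lists must be named", call. = FALSE)
  }
  universe <- unique(unlist(lists, use.names = FALSE))
  member <- vapply(lists, function(l) universe %in% l, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(lists)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(lists)
  key <- apply(member, 1, paste, collapse = "")
  combo_key <- apply(combos, 1, paste, collapse = "")
  genes <- lapply(combo_key, function(ck) universe[key == ck])
  combos$pattern <- apply(combos[, names(lists), drop = FALSE], 1, function(b) {
    paste(names(lists)[as.logical(b)], collapse = "&")
  })
  combos$size <- lengths(genes)
  combos$genes <- genes
  rownames(combos) <- NULL
  combos
}

#' Cross-cancer conservation of upregulated genes
#'
#' Summarizes per-cancer [top_upregulated()] lists: for every gene that is
#' upregulated in at least one cancer, the number of cancers in which it
#' appears and its mean rank score. Cancers where a gene is not upregulated
#' contribute a rank score of 0 (not missing), so the mean is always over
#' all analyzed cancers.
#'
#' @param top_lists named list (one element per cancer) of
#'   [top_upregulated()] data frames.
#' @return `ConservationSummary` data frame: `gene`, `n_cancers_up`,
#'   `mean_rank_score`, sorted by `mean_rank_score` then `n_cancers_up`
#'   descending.
#' @export
cross_cancer_conservation <- function(top_lists) {
  if (length(top_lists) < 2) stop("need at least 2 cancers", call. = FALSE)
  n_cancers <- length(top_lists)
  genes <- unique(unlist(lapply(top_lists, `[[`, "gene")))
  score_sum <- stats::setNames(numeric(length(genes)), genes)
  n_up <- stats::setNames(integer(length(genes)), genes)
  for (tl in top_lists) {
    hit <- tl$gene
    score_sum[hit] <- score_sum[hit] + tl$rank_score
    n_up[hit] <- n_up[hit] + 1L
  }
  out <- data.frame(gene = genes, n_cancers_up = unname(n_up),
                    mean_rank_score = unname(score_sum) / n_cancers)
  out <- out[order(-out$mean_rank_score, -out$n_cancers_up, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("ConservationSummary", "data.frame")
  out
}

#' Derive the conserved TEC signature
#'
#' Intersects the genes upregulated in all compartments (the
#' all-categories pattern of [distinct_intersection()]) with the genes
#' upregulated in at least `n_cancers_min` cancers, ordering the result by
#' mean rank score (then symbol) descending.
#'
#' @param shared_all_compartments character vector of genes upregulated in
#'   every compartment.
#' @param conservation a [cross_cancer_conservation()] summary.
#' @param n_cancers_min minimum number of cancers a gene must be
#'   upregulated in; default is a majority of the analyzed cancers.
#' @param n_cancers_total total cancers analyzed (needed for the majority
#'   default when `n_cancers_min` is missing).
#' @return character vector of signature genes (possibly empty, with a
#'   warning).
#' @export
derive_conserved_signature <- function(shared_all_compartments, conservation,
                                       n_cancers_min = NULL,
                                       n_cancers_total = NULL) {
  if (is.null(n_cancers_min)) {
    if (is.null(n_cancers_total)) {
      n_cancers_total <- max(conservation$n_cancers_up)
    }
    n_cancers_min <- floor(n_cancers_total / 2) + 1
  }
  specific <- conservation[conservation$n_cancers_up >= n_cancers_min, ,
                           drop = FALSE]
  hits <- specific[specific$gene %in% shared_all_compartments, , drop = FALSE]
  if (!nrow(hits)) {
    warning("empty conserved signature")
    return(character(0))
  }
  hits$gene[order(-hits$mean_rank_score, hits$gene)]
}

#' Rank-based AUC of a score as a binary discriminator
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with ties counting 1/2. Invariant
#' to monotone transforms of the scores.
#'
#' @param scores numeric vector (e.g. mean signature expression per cell).
#' @param labels logical or 0/1 vector; `TRUE`/1 marks the positive class
#'   (e.g. tumor ECs).
#' @return AUC in \eqn{[0, 1]}.
#' @export
signature_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
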