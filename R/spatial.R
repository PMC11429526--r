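#' Randomly sample square regions from a slice
#'
#' Region origins are drawn uniformly from the admissible origin rectangle
#' (the slice window shrunk by `side` on the right/top), and each region's
#' cells are tallied per type over the half-open square
#' `[x0, x0+side) x [y0, y0+side)`.
#'
#' @param slice a [spatial_slice()].
#' @param side region side length in slice units (default 1000).
#' @param n_regions number of regions to draw.
#' @param seed RNG seed for the origins.
#' @param cell_types types to tally; defaults to the types present in the
#'   slice.
#' @return a `RegionCatalog`: list with `regions` (data frame `slice_id`,
#'   `x0`, `y0`), `counts` (regions x types integer matrix), `side`,
#'   `seed`.
#' @export
sample_regions <- function(slice, side = 1000, n_regions = 100, seed = 1L,
                           cell_types = NULL) {
  w <- slice$window
  if (w[2] - w[1] < side || w[4] - w[3] < side) {
    stop("slice ", slice$slice_id, " bounding box (",
         round(w[2] - w[1]), " x ", round(w[4] - w[3]),
         ") is smaller than side = ", side,
         "; use a smaller side", call. = FALSE)
  }
  if (is.null(cell_types)) cell_types <- sort(unique(slice$points$cell_type))
  origins <- withr_seed(seed, {
    data.frame(x0 = stats::runif(n_regions, w[1], w[2] - side),
               y0 = stats::runif(n_regions, w[3], w[4] - side))
  })
  counts <- region_counts(slice$points, origins, side, cell_types)
  structure(list(regions = cbind(slice_id = slice$slice_id, origins),
                 counts = counts, side = side, seed = seed),
            class = "RegionCatalog")
}

region_counts <- function(points, origins, side, cell_types) {
  counts <- matrix(0L, nrow(origins), length(cell_types),
                   dimnames = list(NULL, cell_types))
  if (!nrow(points)) return(counts)
  type <- factor(points$cell_type, levels = cell_types)
  for (i in seq_len(nrow(origins))) {
    inside <- points$x >= origins$x0[i] & points$x < origins$x0[i] + side &
      points$y >= origins$y0[i] & points$y < origins$y0[i] + side
    counts[i, ] <- as.integer(table(type[inside]))
  }
  counts
}

#' Combine region catalogs from several slices
#' @param catalogs list of `RegionCatalog` objects with equal `side`.
#' @return one pooled `RegionCatalog`.
#' @export
bind_regions <- function(catalogs) {
  stopifnot(length(catalogs) >= 1)
  side <- unique(vapply(catalogs, `[[`, numeric(1), "side"))
  if (length(side) != 1) stop("catalogs use different region sides", call. = FALSE)
  types <- sort(unique(unlist(lapply(catalogs, function(ct) colnames(ct$counts)))))
  counts <- do.call(rbind, lapply(catalogs, function(ct) {
    m <- matrix(0L, nrow(ct$counts), length(types),
                dimnames = list(NULL, types))
    m[, colnames(ct$counts)] <- ct$counts
    m
  }))
  structure(list(regions = do.call(rbind, lapply(catalogs, `[[`, "regions")),
                 counts = counts, side = side,
                 seed = catalogs[[1]]$seed),
            class = "RegionCatalog")
}

#' Compare companion-cell abundance between focal-rich and focal-free regions
#'
#' Regions are grouped by their focal-type count: "high" regions have at
#' least `high_threshold` focal cells, "low" regions at most
#' `low_threshold` (default: none). Each companion type's counts are then
#' compared between the groups with a two-sided rank-sum test.
#'
#' @param catalog a `RegionCatalog` (possibly pooled via [bind_regions()]).
#' @param focal_type type defining the grouping.
#' @param companion_types types to test (default: all other types).
#' @param high_threshold,low_threshold group cutoffs (defaults 5 and 0).
#' @return data frame `companion`, `median_high`, `median_low`, `p`,
#'   `p_adj`, `n_high`, `n_low`.
#' @export
region_group_compare <- function(catalog, focal_type, companion_types = NULL,
                                 high_threshold = 5, low_threshold = 0) {
  counts <- catalog$counts
  if (!focal_type %in% colnames(counts)) {
    stop("focal type '", focal_type, "' absent from catalog", call. = FALSE)
  }
  if (is.null(companion_types)) {
    companion_types <- setdiff(colnames(counts), focal_type)
  }
  f <- counts[, focal_type]
  high <- f >= high_threshold
  low <- f <= low_threshold
  if (!any(high) || !any(low)) {
    stop("empty region group (high: ", sum(high), ", low: ", sum(low),
         ") at thresholds [", low_threshold, ", ", high_threshold, "]",
         call. = FALSE)
  }
  res <- lapply(companion_types, function(ct) {
    hi <- counts[high, ct]; lo <- counts[low, ct]
    p <- tryCatch(suppressWarnings(stats::wilcox.test(hi, lo)$p.value),
                  error = function(e) 1)
    data.frame(companion = ct, median_high = stats::median(hi),
               median_low = stats::median(lo), p = p,
               n_high = sum(high), n_low = sum(low))
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("companion", "median_high", "median_low", "p", "p_adj",
          "n_high", "n_low")]
}

#' Neighborhood composition around a focal cell type
#'
#' Pools every non-focal cell lying within Euclidean distance `radius` of
#' a focal cell. By default each neighbor is counted once per focal cell it
#' neighbors (multiplicity reflects neighborhood exposure); `dedup = TRUE`
#' counts each neighbor once. Expected counts allocate the pooled total by
#' the slice-wide non-focal type frequencies, and enrichment is summarized
#' with Pearson residuals \eqn{(O - E)/\sqrt{E}}.
#'
#' @param slice a [spatial_slice()].
#' @param focal_type the focal cell type; at least one focal cell required.
#' @param radius neighborhood radius in slice units (default 50).
#' @param dedup count each neighbor cell once instead of once per focal
#'   cell.
#' @return a `NeighborhoodProfile`: list with `slice_id`, `focal_type`,
#'   `observed`, `expected`, `residuals` (named by type), `n_focal`,
#'   `radius`.
#' @export
neighborhood_residuals <- function(slice, focal_type, radius = 50,
                                   dedup = FALSE) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  pts <- slice$points
  is_focal <- pts$cell_type == focal_type
  if (!any(is_focal)) {
    stop("no focal cells of type '", focal_type, "' in slice ",
         slice$slice_id, call. = FALSE)
  }
  fx <- pts$x[is_focal]; fy <- pts$y[is_focal]
  ox <- pts$x[!is_focal]; oy <- pts$y[!is_focal]
  otype <- pts$cell_type[!is_focal]
  types <- sort(unique(otype))
  slice_freq <- as.numeric(table(factor(otype, levels = types))) / length(otype)
  r2 <- radius^2
  # multiplicity per non-focal cell: number of focal cells within radius
  mult <- integer(length(ox))
  for (i in seq_along(fx)) {
    d2 <- (ox - fx[i])^2 + (oy - fy[i])^2
    mult <- mult + (d2 <= r2)
  }
  w <- if (dedup) as.integer(mult > 0) else mult
  observed <- vapply(types, function(tp) sum(w[otype == tp]), numeric(1))
  total <- sum(observed)
  expected <- total * slice_freq
  names(expected) <- types
  residuals <- (observed - expected) / sqrt(expected)
  residuals[expected == 0] <- 0
  structure(list(slice_id = slice$slice_id, focal_type = focal_type,
                 observed = observed, expected = expected,
                 residuals = residuals, n_focal = sum(is_focal),
                 radius = radius),
            class = "NeighborhoodProfile")
}

#' Paired comparison of neighborhood residuals between two focal types
#'
#' Across slices, compares the Pearson residual of `target_type` in the
#' neighborhoods of focal type A versus focal type B with a paired
#' two-sided t-test. Degenerate cases are flagged rather than tested: all
#' differences zero gives `t = 0, p = 1`; a constant nonzero difference
#' (zero variance) is reported with `exact_separation = TRUE` and `p = NA`.
#'
#' @param profiles_a,profiles_b lists of [neighborhood_residuals()]
#'   profiles for the two focal types, covering the same slices (>= 3).
#' @param target_type the neighbor type whose residual is compared.
#' @return list with `t`, `p`, `mean_difference` (A minus B), `n_slices`,
#'   `exact_separation`.
#' @export
paired_residual_test <- function(profiles_a, profiles_b, target_type) {
  ids_a <- vapply(profiles_a, `[[`, character(1), "slice_id")
  ids_b <- vapply(profiles_b, `[[`, character(1), "slice_id")
  if (!setequal(ids_a, ids_b) || anyDuplicated(ids_a) || anyDuplicated(ids_b)) {
    stop("pairing error: profile slice sets differ", call. = FALSE)
  }
  if (length(ids_a) < 3) stop("need profiles on at least 3 slices", call. = FALSE)
  profiles_b <- profiles_b[match(ids_a, ids_b)]
  get_res <- function(p) {
    if (!target_type %in% names(p$residuals)) {
      stop("target type '", target_type, "' absent from slice ", p$slice_id,
           call. = FALSE)
    }
    p$residuals[[target_type]]
  }
  d <- vapply(profiles_a, get_res, numeric(1)) -
    vapply(profiles_b, get_res, numeric(1))
  if (all(d == 0)) {
    return(list(t = 0, p = 1, mean_difference = 0, n_slices = length(d),
                exact_separation = FALSE))
  }
  if (stats::sd(d) == 0) {
    return(list(t = sign(mean(d)) * Inf, p = NA_real_,
                mean_difference = mean(d), n_slices = length(d),
                exact_separation = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, mean_difference = mean(d),
       n_slices = length(d), exact_separation = FALSE)
}
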