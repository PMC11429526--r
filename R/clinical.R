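#' Per-cancer Cox association of a signature score with survival
#'
#' Fits, for every cancer with enough samples and events, a proportional
#' hazards model of overall survival on the z-scored signature with age,
#' gender and stage corrected, then adjusts the per-cancer p-values with
#' Benjamini-Hochberg. A pooled pan-cancer fit with a cancer-stratified
#' baseline hazard is reported alongside. Stage enters as an ordered
#' numeric covariate by default (`stage_numeric = FALSE` keeps it
#' categorical).
#'
#' @param clinical a [clinical_table()].
#' @param score_name column of `clinical` holding the signature score.
#' @param covariates adjustment covariates, default
#'   `c("age", "gender", "stage")`.
#' @param min_samples,min_events per-cancer inclusion thresholds (defaults
#'   30 and 10).
#' @param stage_numeric encode stage as 1--4 (default) or categorical.
#' @return list with `per_cancer` (data frame `cancer_type`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p`, `p_adj`, `n`, `n_events`,
#'   `converged`), `pooled` (same fields for the stratified fit) and
#'   `provenance` (score name, covariates, BH family scope).
#' @export
cox_signature <- function(clinical, score_name,
                          covariates = c("age", "gender", "stage"),
                          min_samples = 30, min_events = 10,
                          stage_numeric = TRUE) {
  stopifnot(score_name %in% names(clinical))
  missing_cov <- setdiff(covariates, names(clinical))
  if (length(missing_cov)) {
    stop("covariate(s) absent: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(clinical)
  if (stats::sd(dat[[score_name]]) == 0) {
    stop("degenerate covariate: score '", score_name,
         "' is constant across samples", call. = FALSE)
  }
  dat$.z <- as.numeric(scale(dat[[score_name]]))
  if ("stage" %in% covariates && stage_numeric) {
    dat$stage <- as.integer(dat$stage)
  }
  rhs <- paste(c(".z", covariates), collapse = " + ")
  fit_one <- function(d, strat = FALSE) {
    fml <- stats::as.formula(paste(
      "survival::Surv(os_time, os_event) ~", rhs,
      if (strat) "+ survival::strata(cancer_type)" else ""))
    fit <- tryCatch(
      suppressWarnings(survival::coxph(fml, data = d)),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[".z"])) {
      return(data.frame(hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        n = nrow(d), n_events = sum(d$os_event),
                        converged = FALSE))
    }
    sm <- summary(fit)
    ci <- sm$conf.int[".z", , drop = TRUE]
    data.frame(hazard_ratio = unname(ci["exp(coef)"]),
               ci_low = unname(ci["lower .95"]),
               ci_high = unname(ci["upper .95"]),
               p = sm$coefficients[".z", "Pr(>|z|)"],
               n = nrow(d), n_events = sum(d$os_event), converged = TRUE)
  }
  per <- lapply(split(dat, dat$cancer_type), function(d) {
    if (nrow(d) < min_samples || sum(d$os_event) < min_events) return(NULL)
    cbind(cancer_type = d$cancer_type[1], fit_one(d))
  })
  per <- do.call(rbind, Filter(Negate(is.null), per))
  if (is.null(per)) {
    stop("no cancer meets the sample/event thresholds", call. = FALSE)
  }
  rownames(per) <- NULL
  if (any(!per$converged)) {
    warning(sum(!per$converged), " cancer fit(s) did not converge; ",
            "excluded from the BH family")
  }
  per$p_adj <- NA_real_
  per$p_adj[per$converged] <- stats::p.adjust(per$p[per$converged],
                                              method = "BH")
  pooled <- cbind(cancer_type = "pan-cancer", fit_one(dat, strat = TRUE))
  list(per_cancer = per, pooled = pooled,
       provenance = list(score = score_name, covariates = covariates,
                         stage_numeric = stage_numeric,
                         bh_family = "per-cancer Cox fits (converged only)"))
}

#' Kaplan-Meier comparison of high- vs low-score groups
#'
#' Splits samples at the median score (ties go to the low group) and
#' compares survival between the groups with the log-rank test.
#'
#' @param clinical a [clinical_table()].
#' @param score_name score column used for the split.
#' @param min_group minimum samples per group (default 5).
#' @return list with `groups` (factor `"low"`/`"high"` per sample), `n`
#'   per group, `chi2`, `df` and `p`.
#' @export
km_logrank <- function(clinical, score_name, min_group = 5) {
  stopifnot(score_name %in% names(clinical))
  x <- clinical[[score_name]]
  if (stats::sd(x) == 0) {
    stop("split error: all scores equal", call. = FALSE)
  }
  grp <- factor(ifelse(x > stats::median(x), "high", "low"),
                levels = c("low", "high"))
  if (min(table(grp)) < min_group) {
    stop("split error: group below ", min_group, " samples", call. = FALSE)
  }
  sd <- survival::survdiff(
    survival::Surv(os_time, os_event) ~ grp,
    data = data.frame(os_time = clinical$os_time,
                      os_event = clinical$os_event, grp = grp))
  df <- length(sd$n) - 1
  list(groups = grp, n = as.vector(sd$n), chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Correlate a subset proportion with therapy response rates across cancers
#'
#' @param orr an [orr_table()] with at least 4 cancers.
#' @return list with `R` (Pearson), `p` (two-sided), `n`.
#' @export
orr_correlation <- function(orr) {
  keep <- stats::complete.cases(orr[, c("orr", "proportion")])
  tab <- orr[keep, , drop = FALSE]
  if (nrow(tab) < 4) {
    stop("need at least 4 cancers with both ORR and proportion", call. = FALSE)
  }
  score_correlation(tab$proportion, tab$orr)
}

#' Score trend across tumor stages
#'
#' Per-stage mean and standard error of a signature score, rank-sum tests
#' for each adjacent stage pair, and a pooled early (I-II) vs late (III-IV)
#' comparison. Stages below the sample threshold are merged into their
#' lower neighbor (stage I merges upward) with a warning.
#'
#' @param clinical a [clinical_table()].
#' @param score_name score column.
#' @param min_per_stage minimum samples per stage (default 5).
#' @return list with `per_stage` (data frame `stage`, `n`, `mean`, `sem`),
#'   `adjacent` (data frame `pair`, `p`, `direction`), and `early_late`
#'   (`mean_late_minus_early`, `p`).
#' @export
stage_trend <- function(clinical, score_name, min_per_stage = 5) {
  stopifnot(score_name %in% names(clinical))
  x <- clinical[[score_name]]
  stage <- as.character(clinical$stage)
  repeat {
    groups <- unique(stage)
    # order groups by their first roman stage
    groups <- groups[order(match(vapply(strsplit(groups, "/"), `[`,
                                        character(1), 1),
                                 c("I", "II", "III", "IV")))]
    n <- table(factor(stage, levels = groups))
    small <- names(n)[n < min_per_stage]
    if (!length(small) || length(groups) <= 2) break
    s <- small[1]
    i <- match(s, groups)
    nb <- if (i > 1) groups[i - 1] else groups[i + 1]
    warning("stage group '", s, "' below ", min_per_stage,
            " samples; merged into '", nb, "'")
    merged <- paste(sort(unique(unlist(strsplit(c(s, nb), "/")))),
                    collapse = "/")
    stage[stage %in% c(s, nb)] <- merged
  }
  groups <- unique(stage)
  groups <- groups[order(match(vapply(strsplit(groups, "/"), `[`,
                                      character(1), 1),
                               c("I", "II", "III", "IV")))]
  if (length(groups) < 2) {
    stop("need at least 2 stages with ", min_per_stage, "+ samples",
         call. = FALSE)
  }
  per_stage <- do.call(rbind, lapply(groups, function(g) {
    v <- x[stage == g]
    data.frame(stage = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  adjacent <- do.call(rbind, lapply(seq_len(length(groups) - 1), function(i) {
    a <- x[stage == groups[i]]; b <- x[stage == groups[i + 1]]
    p <- tryCatch(suppressWarnings(stats::wilcox.test(a, b)$p.value),
                  error = function(e) 1)
    data.frame(pair = paste(groups[i], groups[i + 1], sep = " vs "),
               p = p, direction = sign(stats::median(b) - stats::median(a)))
  }))
  is_early <- vapply(strsplit(stage, "/"), function(p) {
    all(p %in% c("I", "II"))
  }, logical(1))
  early <- x[is_early]; late <- x[!is_early]
  early_late <- if (length(early) >= 2 && length(late) >= 2) {
    list(mean_late_minus_early = mean(late) - mean(early),
         p = suppressWarnings(stats::wilcox.test(late, early)$p.value))
  } else {
    list(mean_late_minus_early = NA_real_, p = NA_real_)
  }
  list(per_stage = per_stage, adjacent = adjacent, early_late = early_late)
}

#' Compare scores or frequencies between responders and non-responders
#'
#' @param values per-sample relative scores ([relative_score()]) or
#'   frequencies.
#' @param response_labels character/factor with levels `"R"` (responder)
#'   and `"NR"`; at least 3 samples of each.
#' @return list with `median_r`, `median_nr`, `p` (two-sided rank-sum) and
#'   group sizes.
#' @export
responder_compare <- function(values, response_labels) {
  lab <- as.character(response_labels)
  if (length(values) != length(lab)) stop("length mismatch", call. = FALSE)
  bad <- setdiff(unique(lab), c("R", "NR"))
  if (length(bad)) {
    stop("response labels must be 'R'/'NR'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- values[lab == "R"]; nr <- values[lab == "NR"]
  if (length(r) < 3 || length(nr) < 3) {
    stop("need at least 3 samples per response class", call. = FALSE)
  }
  p <- tryCatch(suppressWarnings(stats::wilcox.test(r, nr)$p.value),
                error = function(e) 1)
  list(median_r = stats::median(r), median_nr = stats::median(nr),
       p = p, n_r = length(r), n_nr = length(nr))
}
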