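#' Configuration for the synthetic-data generators
#'
#' Builds the fully-specified parameter list consumed by
#' [generate_atlas()], [generate_spatial()] and [generate_clinical()].
#' Defaults describe a small pan-cancer atlas with the compositional
#' structure the analysis modules are designed for: an angiogenic tip-cell
#' subset enriched in tumors, a proinflammatory vein subset depleted in
#' tumors, negative-binomial counts with subset marker programs, a pair of
#' coupled activity programs ("angio", "collagen"), spatially clustered
#' niches (tip-like cells with epithelial clusters, vein-like cells near
#' T-cell zones), survival with score-dependent hazard, and a therapy
#' response-rate table linear in a subset proportion.
#'
#' @param ... named overrides of any top-level default; list-valued entries
#'   (`atlas`, `spatial`, `clinical`, `orr`) are merged element-wise.
#' @return a validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    seed = 1L,
    atlas = list(
      n_genes = 500,
      n_cancer_types = 3,
      n_samples_per_type = 4,      # per (cancer, tissue)
      n_cells_per_sample = 200,
      subsets = data.frame(
        name = c("tip_CXCR4", "tip_KDR", "vein_SELE", "vein_COL4A1",
                 "capillary", "artery", "lymphatic"),
        compartment = c("tip", "tip", "vein", "vein",
                        "capillary", "artery", "lymphatic"),
        freq_tumor = c(0.30, 0.10, 0.10, 0.15, 0.15, 0.10, 0.10),
        freq_normal = c(0.10, 0.10, 0.30, 0.15, 0.20, 0.10, 0.05)
      ),
      n_marker_genes = 10,
      marker_log2_effect = 2,
      n_program_genes = 15,
      program_tau = 0.5,
      rho_prog = 0.6,
      tumor_programs = list(),
      dispersion = 0.5,            # NB size = 1/dispersion
      libsize_meanlog = log(2000),
      libsize_sdlog = 0.3
    ),
    spatial = list(
      n_slices = 8,
      window = 3000,
      n_niches = 8,                # mean parent count per niche system
      niche_sigma = 150,
      offspring_mu_epithelial = 40,
      offspring_mu_t = 30,
      n_tip = 60,
      n_vein = 50,
      n_other = 150,
      coloc_strength = 4
    ),
    clinical = list(
      n_samples = 300,
      n_cancers = 5,
      baseline_hazard = 0.002,     # events per day
      log_hr = log(1.5),           # per score SD
      age_loghr = 0.01,
      gender_loghr = 0.2,
      stage_loghr = 0.15,
      censoring_rate = 0.3,
      stage_trend = 0.5            # latent-scale shift per score SD
    ),
    orr = list(
      n_cancers = 11,
      intercept = 10,
      slope = 80,
      noise_sd = 10.5,
      proportion_range = c(0.05, 0.5)
    )
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && !is.data.frame(overrides[[nm]]) &&
        is.list(cfg[[nm]])) {
      for (sub in names(overrides[[nm]])) cfg[[nm]][[sub]] <- overrides[[nm]][[sub]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validate_config <- function(cfg) {
  a <- cfg$atlas
  if (abs(sum(a$subsets$freq_tumor) - 1) > 1e-8 ||
      abs(sum(a$subsets$freq_normal) - 1) > 1e-8) {
    stop("config error: subset frequencies must sum to 1 per tissue",
         call. = FALSE)
  }
  if (any(a$subsets$freq_tumor < 0) || any(a$subsets$freq_normal < 0)) {
    stop("config error: negative subset frequency", call. = FALSE)
  }
  if (a$dispersion <= 0) stop("config error: dispersion must be > 0",
                              call. = FALSE)
  s <- cfg$spatial
  if (any(c(s$offspring_mu_epithelial, s$offspring_mu_t, s$n_tip, s$n_vein,
            s$n_other) <= 0)) {
    stop("config error: zero or negative spatial densities", call. = FALSE)
  }
  if (s$coloc_strength < 0) stop("config error: negative co-localization strength",
                                 call. = FALSE)
  cl <- cfg$clinical
  if (cl$baseline_hazard <= 0) {
    stop("config error: baseline hazard must be positive", call. = FALSE)
  }
  if (cl$censoring_rate < 0 || cl$censoring_rate >= 1) {
    stop("config error: censoring_rate must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a synthetic cell atlas with planted structure
#'
#' Draws negative-binomial counts whose per-cell mean is
#' `library_size * softmax(base log-expression + planted effects)`.
#' Planted effects comprise (i) subset marker programs (each subset
#' over-expresses its marker block by `marker_log2_effect`), (ii) two
#' designated activity programs, "angio" and "collagen", whose per-cell
#' log-scale multipliers are bivariate normal with correlation `rho_prog`,
#' and (iii) optional tumor programs: gene blocks up-regulated only in
#' tumor cells of chosen compartments and cancers (see Details). Subset
#' composition per cell follows the tissue-specific frequency catalog, so
#' tumor/normal enrichment is planted at known log-ratios.
#'
#' @details A tumor program is a list with elements `n_genes`,
#'   `log2_effect`, and optionally `compartments` and `cancers` (character
#'   vectors, or `"all"`); each program receives its own block of genes
#'   named after the program.
#'
#' @param config a [synthetic_config()].
#' @return list with `atlas` (a [CellAtlas()]) and `truth`: the planted
#'   per-subset tissue log-enrichment, marker/program/tumor-program gene
#'   names with their effects, and `rho_prog`.
#' @export
generate_atlas <- function(config) {
  validate_config(config)
  a <- config$atlas
  withr_seed(config$seed, {
    subsets <- a$subsets
    n_sub <- nrow(subsets)
    # --- gene bookkeeping: marker blocks, program blocks, tumor programs, nulls
    n_marker <- n_sub * a$n_marker_genes
    n_prog <- 2 * a$n_program_genes
    tp <- lapply(seq_along(a$tumor_programs), function(i) {
      p <- a$tumor_programs[[i]]
      p$name <- if (!is.null(p$name)) p$name else paste0("TP", i)
      p$compartments <- if (is.null(p$compartments)) "all" else p$compartments
      p$cancers <- if (is.null(p$cancers)) "all" else p$cancers
      p
    })
    n_tp <- sum(vapply(tp, `[[`, numeric(1), "n_genes"))
    if (n_marker + n_prog + n_tp > a$n_genes) {
      stop("config error: n_genes too small for the planted gene blocks",
           call. = FALSE)
    }
    gene_ids <- sprintf("G%04d", seq_len(a$n_genes))
    nxt <- 0
    take <- function(n) {
      idx <- nxt + seq_len(n); nxt <<- nxt + n; idx
    }
    marker_idx <- lapply(seq_len(n_sub), function(i) take(a$n_marker_genes))
    names(marker_idx) <- subsets$name
    for (i in seq_len(n_sub)) {
      gene_ids[marker_idx[[i]]] <- sprintf("MK_%s_%02d", subsets$name[i],
                                           seq_len(a$n_marker_genes))
    }
    prog_idx <- list(angio = take(a$n_program_genes),
                     collagen = take(a$n_program_genes))
    gene_ids[prog_idx$angio] <- sprintf("ANGIO_%02d", seq_len(a$n_program_genes))
    gene_ids[prog_idx$collagen] <- sprintf("COLL_%02d", seq_len(a$n_program_genes))
    for (i in seq_along(tp)) {
      tp[[i]]$idx <- take(tp[[i]]$n_genes)
      gene_ids[tp[[i]]$idx] <- sprintf("%s_%02d", tp[[i]]$name,
                                       seq_len(tp[[i]]$n_genes))
    }
    base <- stats::rnorm(a$n_genes, 0, 1)

    # --- cell metadata
    cancers <- sprintf("C%02d", seq_len(a$n_cancer_types))
    meta <- do.call(rbind, lapply(cancers, function(cc) {
      do.call(rbind, lapply(seq_len(a$n_samples_per_type), function(k) {
        do.call(rbind, lapply(c("tumor", "normal"), function(ts) {
          data.frame(cancer_type = cc, tissue = ts,
                     sample_id = sprintf("%s_P%02d_%s", cc, k, ts),
                     patient_id = sprintf("%s_P%02d", cc, k),
                     n = a$n_cells_per_sample)
        }))
      }))
    }))
    cell_rows <- rep(seq_len(nrow(meta)), meta$n)
    n_cells <- length(cell_rows)
    freq <- as.matrix(subsets[, c("freq_tumor", "freq_normal")])
    cell_tissue <- meta$tissue[cell_rows]
    sub_i <- integer(n_cells)
    for (ts in c("tumor", "normal")) {
      rows <- which(cell_tissue == ts)
      f <- if (ts == "tumor") freq[, 1] else freq[, 2]
      sub_i[rows] <- sample.int(n_sub, length(rows), replace = TRUE, prob = f)
    }
    cell_meta <- data.frame(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      subset_label = subsets$name[sub_i],
      compartment_label = subsets$compartment[sub_i],
      cancer_type = meta$cancer_type[cell_rows],
      tissue = meta$tissue[cell_rows],
      sample_id = meta$sample_id[cell_rows],
      patient_id = meta$patient_id[cell_rows]
    )

    # --- per-cell log-scale gene effects
    logit <- matrix(base, n_cells, a$n_genes, byrow = TRUE)
    ln2 <- log(2)
    if (a$marker_log2_effect != 0) {
      for (i in seq_len(n_sub)) {
        rows <- sub_i == i
        if (any(rows)) {
          logit[rows, marker_idx[[i]]] <-
            logit[rows, marker_idx[[i]]] + a$marker_log2_effect * ln2
        }
      }
    }
    z1 <- stats::rnorm(n_cells)
    z2 <- a$rho_prog * z1 + sqrt(1 - a$rho_prog^2) * stats::rnorm(n_cells)
    logit[, prog_idx$angio] <- logit[, prog_idx$angio] + a$program_tau * z1
    logit[, prog_idx$collagen] <- logit[, prog_idx$collagen] + a$program_tau * z2
    for (p in tp) {
      rows <- cell_meta$tissue == "tumor"
      if (!identical(p$compartments, "all")) {
        rows <- rows & cell_meta$compartment_label %in% p$compartments
      }
      if (!identical(p$cancers, "all")) {
        rows <- rows & cell_meta$cancer_type %in% p$cancers
      }
      if (any(rows)) {
        logit[rows, p$idx] <- logit[rows, p$idx] + p$log2_effect * ln2
      }
    }

    # --- NB sampling: mean = libsize * softmax(logit)
    libsize <- stats::rlnorm(n_cells, a$libsize_meanlog, a$libsize_sdlog)
    e <- exp(logit - apply(logit, 1, max))
    mu <- e / rowSums(e) * libsize
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / a$dispersion),
                     n_cells, a$n_genes)
    atlas <- CellAtlas(counts, gene_ids, cell_meta)
    truth <- list(
      subset_tissue_log_enrichment = stats::setNames(
        log(subsets$freq_tumor / subsets$freq_normal), subsets$name),
      marker_genes = lapply(marker_idx, function(i) gene_ids[i]),
      marker_log2_effect = a$marker_log2_effect,
      program_genes = lapply(prog_idx, function(i) gene_ids[i]),
      program_activity = cbind(angio = z1, collagen = z2),
      rho_prog = a$rho_prog,
      tumor_programs = lapply(tp, function(p) {
        list(name = p$name, genes = gene_ids[p$idx],
             log2_effect = p$log2_effect,
             compartments = p$compartments, cancers = p$cancers)
      })
    )
    list(atlas = atlas, truth = truth)
  })
}

#' Simulate a Thomas cluster process on a rectangular window
#'
#' Parents form a homogeneous Poisson process of intensity `kappa`; each
#' parent produces `Poisson(mu)` offspring displaced by isotropic Gaussian
#' noise with standard deviation `sigma`. Offspring falling outside the
#' window are dropped unless `clip = FALSE`. Uses the current RNG stream.
#'
#' @param kappa parent intensity (points per unit area).
#' @param mu mean offspring per parent.
#' @param sigma offspring displacement SD.
#' @param window `c(xmin, xmax, ymin, ymax)`.
#' @param clip drop offspring outside the window (default `TRUE`).
#' @return data frame `x`, `y`, `parent` (parent index per offspring); the
#'   parent coordinates are attached as attribute `parents`.
#' @export
rthomas_points <- function(kappa, mu, sigma, window, clip = TRUE) {
  area <- (window[2] - window[1]) * (window[4] - window[3])
  n_par <- stats::rpois(1, kappa * area)
  px <- stats::runif(n_par, window[1], window[2])
  py <- stats::runif(n_par, window[3], window[4])
  n_off <- if (n_par) stats::rpois(n_par, mu) else integer(0)
  parent <- rep(seq_len(n_par), n_off)
  x <- stats::rnorm(sum(n_off), px[parent], sigma)
  y <- stats::rnorm(sum(n_off), py[parent], sigma)
  pts <- data.frame(x = x, y = y, parent = parent)
  if (clip && nrow(pts)) {
    pts <- pts[pts$x >= window[1] & pts$x <= window[2] &
                 pts$y >= window[3] & pts$y <= window[4], , drop = FALSE]
    rownames(pts) <- NULL
  }
  attr(pts, "parents") <- data.frame(x = px, y = py)
  pts
}

#' Generate synthetic spatial slices with planted co-localization
#'
#' Each slice carries five cell types on a square window: `epithelial`
#' cells clustered in Thomas-process niches, `T_cell` cells clustered in a
#' second, independent niche system, a uniform `other` background, and two
#' focal types. `tip_like` cells are placed inside epithelial niches with
#' probability `strength / (1 + strength)` (uniformly otherwise) and
#' `vein_like` cells likewise inside T-cell niches, so `coloc_strength = 0`
#' gives independent uniform placement and `Inf` confines focal cells to
#' their niches.
#'
#' @param config a [synthetic_config()].
#' @return list with `slices` (list of [spatial_slice()]) and `truth`:
#'   per-slice niche centers and, per focal cell, the assigned niche index
#'   (0 for background placement).
#' @export
generate_spatial <- function(config) {
  validate_config(config)
  s <- config$spatial
  withr_seed(config$seed + 1L, {
    W <- s$window
    win <- c(0, W, 0, W)
    kappa <- s$n_niches / W^2
    p_in <- if (is.infinite(s$coloc_strength)) 1 else {
      s$coloc_strength / (1 + s$coloc_strength)
    }
    place_focal <- function(n_mean, niches) {
      n <- stats::rpois(1, n_mean)
      niche <- integer(n)
      x <- stats::runif(n, 0, W)
      y <- stats::runif(n, 0, W)
      if (nrow(niches) && p_in > 0) {
        in_niche <- stats::runif(n) < p_in
        ni <- sample.int(nrow(niches), sum(in_niche), replace = TRUE)
        niche[in_niche] <- ni
        x[in_niche] <- stats::rnorm(sum(in_niche), niches$x[ni], s$niche_sigma)
        y[in_niche] <- stats::rnorm(sum(in_niche), niches$y[ni], s$niche_sigma)
        x <- pmin(pmax(x, 0), W)
        y <- pmin(pmax(y, 0), W)
      }
      data.frame(x = x, y = y, niche = niche)
    }
    out <- lapply(seq_len(s$n_slices), function(si) {
      epi <- rthomas_points(kappa, s$offspring_mu_epithelial, s$niche_sigma, win)
      tc <- rthomas_points(kappa, s$offspring_mu_t, s$niche_sigma, win)
      epi_niches <- attr(epi, "parents")
      tc_niches <- attr(tc, "parents")
      n_oth <- stats::rpois(1, s$n_other)
      tip <- place_focal(s$n_tip, epi_niches)
      vein <- place_focal(s$n_vein, tc_niches)
      pts <- rbind(
        data.frame(x = epi$x, y = epi$y, cell_type = "epithelial"),
        data.frame(x = tc$x, y = tc$y, cell_type = "T_cell"),
        data.frame(x = stats::runif(n_oth, 0, W),
                   y = stats::runif(n_oth, 0, W), cell_type = "other"),
        data.frame(x = tip$x, y = tip$y, cell_type = "tip_like"),
        data.frame(x = vein$x, y = vein$y, cell_type = "vein_like")
      )
      id <- sprintf("slice%02d", si)
      list(slice = spatial_slice(id, pts, window = win),
           truth = list(slice_id = id, epithelial_niches = epi_niches,
                        t_cell_niches = tc_niches,
                        tip_niche = tip$niche, vein_niche = vein$niche))
    })
    list(slices = lapply(out, `[[`, "slice"),
         truth = list(p_in_niche = p_in,
                      slices = lapply(out, `[[`, "truth")))
  })
}

#' Generate synthetic clinical and therapy-response tables
#'
#' Survival times are exponential with hazard
#' `h0 * exp(log_hr * score + covariate effects)`; censoring is by an
#' independent exponential clock calibrated to the configured censoring
#' rate (no censoring when the rate is 0). Tumor stage is drawn from a
#' latent Gaussian shifted by `stage_trend * score`, giving a monotone
#' score-stage trend. The ORR table draws one proportion per cancer
#' uniformly from `proportion_range` and sets
#' `orr = intercept + slope * proportion + noise`, clipped to `[0, 100]`.
#'
#' @param config a [synthetic_config()].
#' @param scores optional per-sample signature scores (length
#'   `clinical$n_samples`); standard-normal draws when omitted.
#' @return list with `clinical` (a [clinical_table()], score in column
#'   `score`), `orr` (an [orr_table()]) and `truth` (planted log hazard
#'   ratio, covariate effects, the population ORR correlation implied by
#'   the config, and the realized censoring fraction).
#' @export
generate_clinical <- function(config, scores = NULL) {
  validate_config(config)
  cl <- config$clinical
  orr_cfg <- config$orr
  withr_seed(config$seed + 2L, {
    n <- cl$n_samples
    if (is.null(scores)) scores <- stats::rnorm(n)
    if (length(scores) != n) {
      stop("config error: need ", n, " scores", call. = FALSE)
    }
    age <- round(stats::rnorm(n, 60, 10))
    gender <- sample(c("female", "male"), n, replace = TRUE)
    latent <- stats::rnorm(n, cl$stage_trend * scores, 1)
    stage <- cut(latent, c(-Inf, stats::quantile(latent, c(0.3, 0.6, 0.85)), Inf),
                 labels = c("I", "II", "III", "IV"))
    stage_num <- as.integer(stage)
    loghaz <- log(cl$baseline_hazard) + cl$log_hr * scores +
      cl$age_loghr * (age - 60) + cl$gender_loghr * (gender == "male") +
      cl$stage_loghr * (stage_num - mean(stage_num))
    t_event <- stats::rexp(n, rate = exp(loghaz))
    if (cl$censoring_rate == 0) {
      os_time <- t_event
      os_event <- rep(1L, n)
    } else {
      c_rate <- cl$censoring_rate / (1 - cl$censoring_rate) * cl$baseline_hazard
      t_cens <- stats::rexp(n, rate = c_rate)
      os_time <- pmin(t_event, t_cens)
      os_event <- as.integer(t_event <= t_cens)
    }
    cancer <- sprintf("C%02d", rep_len(seq_len(cl$n_cancers), n))
    clin <- clinical_table(data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      cancer_type = cancer,
      os_time = pmax(os_time, 1e-3),
      os_event = os_event,
      age = age, gender = gender, stage = as.character(stage),
      score = scores
    ))
    prop <- stats::runif(orr_cfg$n_cancers, orr_cfg$proportion_range[1],
                         orr_cfg$proportion_range[2])
    orr_val <- orr_cfg$intercept + orr_cfg$slope * prop +
      stats::rnorm(orr_cfg$n_cancers, 0, orr_cfg$noise_sd)
    orr <- orr_table(data.frame(
      cancer_type = sprintf("C%02d", seq_len(orr_cfg$n_cancers)),
      orr = pmin(pmax(orr_val, 0), 100),
      proportion = prop
    ))
    sd_prop <- diff(orr_cfg$proportion_range) / sqrt(12)
    signal <- orr_cfg$slope * sd_prop
    truth <- list(
      log_hr = cl$log_hr,
      covariate_loghr = c(age = cl$age_loghr, gender = cl$gender_loghr,
                          stage = cl$stage_loghr),
      stage_trend = cl$stage_trend,
      orr_true_r = sign(orr_cfg$slope) * signal /
        sqrt(signal^2 + orr_cfg$noise_sd^2),
      censoring_fraction = mean(os_event == 0)
    )
    list(clinical = clin, orr = orr, truth = truth)
  })
}
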