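#' Read typed spatial point tables
#'
#' Reads a CSV with columns `x`, `y`, `cell_type`, `slice_id` and returns
#' one [spatial_slice()] per distinct slice, preserving row order within
#' each slice.
#'
#' @param csv_path path to the CSV file.
#' @return a named list of `SpatialSlice` objects (possibly empty).
#' @export
load_spatial <- function(csv_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("x", "y", "cell_type", "slice_id")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("format error: spatial CSV lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0) return(structure(list(), names = character(0)))
  if (!is.numeric(tab$x) || !is.numeric(tab$y)) {
    stop("format error: non-numeric coordinates in spatial CSV", call. = FALSE)
  }
  ids <- unique(tab$slice_id)
  out <- lapply(ids, function(id) {
    spatial_slice(id, tab[tab$slice_id == id, c("x", "y", "cell_type")])
  })
  names(out) <- ids
  out
}

#' Construct a spatial slice
#'
#' A 2-D point pattern of typed cells from one tissue section. Coordinates
#' are unitless floats in the slice's native units.
#'
#' @param slice_id identifier of the section.
#' @param points data frame with numeric `x`, `y` and character `cell_type`.
#' @param window optional observation window `c(xmin, xmax, ymin, ymax)`;
#'   defaults to the bounding box of the points. Required for empty slices.
#' @return an object of class `SpatialSlice`.
#' @export
spatial_slice <- function(slice_id, points, window = NULL) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "cell_type") %in% names(points)))
  points <- points[, c("x", "y", "cell_type")]
  if (nrow(points) && (!all(is.finite(points$x)) || !all(is.finite(points$y)))) {
    stop("validation error: non-finite coordinates in slice ", slice_id,
         call. = FALSE)
  }
  if (is.null(window)) {
    if (!nrow(points)) {
      stop("validation error: empty slice ", slice_id,
           " needs an explicit window", call. = FALSE)
    }
    window <- c(min(points$x), max(points$x), min(points$y), max(points$y))
  }
  rownames(points) <- NULL
  structure(list(slice_id = as.character(slice_id), points = points,
                 window = as.numeric(window)),
            class = "SpatialSlice")
}

#' @export
print.SpatialSlice <- function(x, ...) {
  cat("SpatialSlice", x$slice_id, ":", nrow(x$points), "cells of",
      length(unique(x$points$cell_type)), "types\n")
  invisible(x)
}

#' Write spatial slices to a CSV
#'
#' @param slices list of [spatial_slice()] objects.
#' @param csv_path output path.
#' @return the path, invisibly.
#' @export
write_spatial <- function(slices, csv_path) {
  tabs <- lapply(slices, function(s) {
    if (!nrow(s$points)) return(NULL)
    cbind(s$points, slice_id = s$slice_id)
  })
  tab <- do.call(rbind, tabs)
  if (is.null(tab)) {
    tab <- data.frame(x = numeric(0), y = numeric(0),
                      cell_type = character(0), slice_id = character(0))
  }
  utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read gene sets from a GMT or plain one-set-per-line file
#'
#' GMT lines are `name<TAB>description<TAB>gene1<TAB>gene2...`; the plain
#' format omits the description column. The two are distinguished per file:
#' a file is treated as GMT when every line has at least three fields, in
#' which case the second field is dropped as the description.
#'
#' @param path gene-set file.
#' @param gmt logical; `TRUE` forces GMT parsing, `FALSE` the plain format,
#'   `NA` (default) auto-detects as above.
#' @return named list of character vectors (unique gene symbols, input
#'   order preserved).
#' @export
read_gene_sets <- function(path, gmt = NA) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t")
  if (is.na(gmt)) gmt <- all(lengths(fields) >= 3)
  sets <- lapply(fields, function(f) {
    genes <- if (gmt) f[-(1:2)] else f[-1]
    unique(genes[nzchar(genes)])
  })
  names(sets) <- vapply(fields, `[`, character(1), 1)
  empty <- !lengths(sets)
  if (any(empty)) {
    stop("format error: empty gene set(s): ",
         paste(names(sets)[empty], collapse = ", "), call. = FALSE)
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Expects columns `sample_id`, `cancer_type`, `os_time` (days), `os_event`
#' (0/1), `age` (years), `gender`, `stage` (I--IV); any further numeric
#' columns are treated as signature scores. Stage is returned as an ordered
#' factor.
#'
#' @param csv_path path to the CSV.
#' @return data frame of class `ClinicalTable`.
#' @export
read_clinical <- function(csv_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  clinical_table(tab)
}

#' Assemble and validate a clinical table
#' @param tab data frame; see [read_clinical()] for the required columns.
#' @return the validated table with `stage` as an ordered factor and class
#'   `ClinicalTable` prepended.
#' @export
clinical_table <- function(tab) {
  need <- c("sample_id", "cancer_type", "os_time", "os_event",
            "age", "gender", "stage")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("format error: clinical table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$os_time <= 0)) {
    stop("validation error: os_time must be positive", call. = FALSE)
  }
  if (!all(tab$os_event %in% c(0, 1))) {
    stop("validation error: os_event must be 0/1", call. = FALSE)
  }
  stages <- c("I", "II", "III", "IV")
  if (!all(tab$stage %in% stages)) {
    stop("validation error: stage must be one of ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  tab$stage <- factor(tab$stage, levels = stages, ordered = TRUE)
  class(tab) <- c("ClinicalTable", "data.frame")
  tab
}

#' Read a per-cancer therapy response-rate table
#'
#' @param csv_path CSV with columns `cancer_type`, `orr` (percent of
#'   patients responding, 0--100) and `proportion` (fraction of the focal
#'   subset among ECs, 0--1).
#' @return validated data frame of class `ORRTable`.
#' @export
read_orr <- function(csv_path) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  orr_table(tab)
}

#' Assemble and validate an ORR table
#' @param tab data frame with `cancer_type`, `orr`, `proportion`.
#' @return the table with class `ORRTable` prepended.
#' @export
orr_table <- function(tab) {
  need <- c("cancer_type", "orr", "proportion")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("format error: ORR table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$orr < 0 | tab$orr > 100)) {
    stop("validation error: orr must lie in [0, 100]", call. = FALSE)
  }
  if (any(tab$proportion < 0 | tab$proportion > 1)) {
    stop("validation error: proportion must lie in [0, 1]", call. = FALSE)
  }
  class(tab) <- c("ORRTable", "data.frame")
  tab
}
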