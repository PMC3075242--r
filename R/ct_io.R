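#' Construct a censored Ct matrix
#'
#' The universal input container of the pipeline: a detectors x samples matrix
#' of qPCR cycle-threshold (Ct) values together with a censoring mask.
#' Reactions in which the target never crossed the fluorescence threshold
#' ("undetectable") carry the detection limit as their Ct value and are marked
#' censored, so the matrix has no missing cells.
#'
#' @param ct numeric matrix (detectors x samples) with unique row and column
#'   names. Values above `detection_limit` are clamped to the limit and marked
#'   censored.
#' @param censored logical matrix of the same shape, `TRUE` where the reaction
#'   was undetectable. Defaults to `ct >= detection_limit`.
#' @param detection_limit Ct (cycles) assigned to undetectable reactions.
#'   Default 40, the usual 40-cycle run convention.
#' @return An object of class `ct_matrix`: a list with elements `ct`,
#'   `censored` and `detection_limit`. Detector and sample identifiers are the
#'   dimnames of `ct`.
#' @export
ct_matrix <- function(ct, censored = NULL, detection_limit = 40) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("`ct` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("`ct` must have detector (row) and sample (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(ct))) {
    stop("duplicate detector ids: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(ct))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(ct)) stop("`ct` contains missing values", call. = FALSE)
  # clamp-at-limit: instruments occasionally emit Ct > limit
  over <- ct >= detection_limit
  ct[over] <- detection_limit
  if (is.null(censored)) {
    censored <- over
  } else {
    if (!is.logical(censored) || !identical(dim(censored), dim(ct))) {
      stop("`censored` must be a logical matrix matching `ct`", call. = FALSE)
    }
    censored <- censored | over
    ct[censored] <- detection_limit
  }
  dimnames(censored) <- dimnames(ct)
  if (any(ct[!censored] <= 0)) {
    stop("uncensored Ct values must be positive", call. = FALSE)
  }
  structure(
    list(ct = ct, censored = censored, detection_limit = detection_limit),
    class = "ct_matrix"
  )
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d detectors x %d samples (detection limit %g, %.1f%% censored)\n",
              nrow(x$ct), ncol(x$ct), x$detection_limit, 100 * mean(x$censored)))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' Detector and sample identifiers of a Ct matrix
#' @param x a `ct_matrix` or `norm_ct_matrix`
#' @return character vector of identifiers
#' @export
detector_ids <- function(x) rownames(x$ct)

#' @rdname detector_ids
#' @export
sample_ids <- function(x) colnames(x$ct)

#' Construct a study design
#'
#' Maps samples to (two) contrast groups and optionally records candidate
#' endogenous-control detectors for normalization.
#'
#' @param groups named character vector: names are sample ids, values group
#'   labels. Each group must hold at least two samples.
#' @param control_candidates detector ids proposed as endogenous controls
#'   (e.g. small nucleolar RNAs or invariant miRNAs).
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups, control_candidates = character()) {
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("`groups` must be named by unique sample ids", call. = FALSE)
  }
  groups <- vapply(groups, as.character, character(1))
  tab <- table(groups)
  if (any(tab < 2)) {
    stop("each group needs >= 2 samples; offending group(s): ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  structure(
    list(groups = groups, control_candidates = as.character(control_candidates)),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$groups)
  cat("study_design:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = " vs "), "\n")
  if (length(x$control_candidates)) {
    cat("  control candidates:", paste(x$control_candidates, collapse = ", "), "\n")
  }
  invisible(x)
}

# split a two-group design into reference / case sample-id vectors
split_contrast <- function(design, reference_group) {
  labs <- unique(design$groups)
  if (length(labs) != 2) {
    stop("a contrast needs exactly two groups, found: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (!reference_group %in% labs) {
    stop("reference group '", reference_group, "' not in design", call. = FALSE)
  }
  case_label <- setdiff(labs, reference_group)
  list(
    ref = names(design$groups)[design$groups == reference_group],
    case = names(design$groups)[design$groups == case_label],
    ref_label = reference_group,
    case_label = case_label
  )
}

#' Construct an amplification-curve set
#'
#' Per-reaction fluorescence trajectories used by the kinetics QC. Stored
#' long: one row per measured cycle.
#'
#' @param df data.frame with columns `detector`, `sample`, `cycle`,
#'   `fluorescence`. Cycles are sorted ascending within each reaction; every
#'   reaction needs at least 10 cycles and finite non-negative fluorescence.
#' @return data.frame of class `curve_set`.
#' @export
curve_set <- function(df) {
  need <- c("detector", "sample", "cycle", "fluorescence")
  if (!all(need %in% names(df))) {
    stop("curve data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$detector <- as.character(df$detector)
  df$sample <- as.character(df$sample)
  if (any(!is.finite(df$fluorescence))) {
    stop("fluorescence values must be finite", call. = FALSE)
  }
  if (any(df$fluorescence < 0)) stop("negative fluorescence", call. = FALSE)
  key <- paste(df$detector, df$sample, sep = "\r")
  if (anyDuplicated(paste(key, df$cycle))) {
    d <- df[duplicated(paste(key, df$cycle)), ]
    stop(sprintf("duplicated cycle %s for reaction (%s, %s)",
                 d$cycle[1], d$detector[1], d$sample[1]), call. = FALSE)
  }
  df <- df[order(key, df$cycle), ]
  rownames(df) <- NULL
  n_per <- table(key)
  if (any(n_per < 10)) {
    stop("every reaction needs >= 10 cycles", call. = FALSE)
  }
  for (k in unique(key)) {
    cyc <- df$cycle[key == k]
    if (any(diff(sort(cyc)) <= 0)) stop("cycles must be strictly increasing", call. = FALSE)
  }
  class(df) <- c("curve_set", "data.frame")
  df
}

# delimiter from file extension: .csv -> comma, anything else -> tab
.delim_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

# text sentinels (case-insensitive) meaning "undetectable"
.undetectable_sentinels <- c("undetermined", "undetected", "", "na")

# parse a character vector of Ct cells: list(ct=numeric, censored=logical)
# errors with `where` labels for non-numeric non-sentinel cells
.parse_ct_cells <- function(cells, detection_limit, where) {
  low <- tolower(trimws(cells))
  censored <- low %in% .undetectable_sentinels
  ct <- rep(NA_real_, length(cells))
  ct[censored] <- detection_limit
  num <- suppressWarnings(as.numeric(cells[!censored]))
  bad <- is.na(num)
  if (any(bad)) {
    stop("non-numeric Ct value '", cells[!censored][bad][1], "' at ",
         where[!censored][bad][1], call. = FALSE)
  }
  ct[!censored] <- num
  over <- !censored & ct >= detection_limit
  censored <- censored | over
  ct[over] <- detection_limit
  list(ct = ct, censored = censored)
}

#' Read a Ct matrix from a delimited text file
#'
#' Supports the two common export dialects: `wide` (detectors in rows, first
#' column the detector id, remaining columns one per sample) and `long`
#' (columns `detector`, `sample`, `ct`). Delimiter is taken from the
#' extension (`.csv` comma, otherwise tab). Cells reading "Undetermined",
#' "undetected", "NA" or blank (case-insensitive), and numeric cells at or
#' above the detection limit, are treated as undetectable: they receive the
#' limit as Ct and are flagged censored.
#'
#' @param path file to read.
#' @param format `"wide"` or `"long"`.
#' @param detection_limit Ct assigned to undetectable reactions (default 40).
#' @return a [ct_matrix]. Row/column order follows first appearance in the
#'   file.
#' @export
read_ct_matrix <- function(path, format = c("wide", "long"), detection_limit = 40) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = .delim_for(path), colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "wide") {
    det <- trimws(raw[[1]])
    if (anyDuplicated(det)) {
      stop("duplicate detector '", det[duplicated(det)][1], "' in ", path, call. = FALSE)
    }
    samples <- colnames(raw)[-1]
    if (anyDuplicated(samples)) {
      stop("duplicate sample column '", samples[duplicated(samples)][1], "'", call. = FALSE)
    }
    cells <- as.matrix(raw[, -1, drop = FALSE])
    where <- outer(det, samples, function(d, s) paste0("(", d, ", ", s, ")"))
    parsed <- .parse_ct_cells(as.vector(cells), detection_limit, as.vector(where))
    ct <- matrix(parsed$ct, nrow = length(det), dimnames = list(det, samples))
    cen <- matrix(parsed$censored, nrow = length(det), dimnames = list(det, samples))
  } else {
    need <- c("detector", "sample", "ct")
    if (!all(need %in% names(raw))) {
      stop("long format needs columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
    det_all <- trimws(raw$detector)
    smp_all <- trimws(raw$sample)
    key <- paste(det_all, smp_all, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop(sprintf("duplicate (detector, sample) pair (%s, %s)",
                   det_all[d], smp_all[d]), call. = FALSE)
    }
    det <- unique(det_all)
    samples <- unique(smp_all)
    parsed <- .parse_ct_cells(raw$ct, detection_limit,
                              paste0("(", det_all, ", ", smp_all, ")"))
    ct <- matrix(NA_real_, length(det), length(samples), dimnames = list(det, samples))
    cen <- matrix(FALSE, length(det), length(samples), dimnames = list(det, samples))
    ct[cbind(det_all, smp_all)] <- parsed$ct
    cen[cbind(det_all, smp_all)] <- parsed$censored
    if (anyNA(ct)) {
      miss <- which(is.na(ct), arr.ind = TRUE)[1, ]
      stop(sprintf("missing cell for (%s, %s): long input must be complete",
                   det[miss[1]], samples[miss[2]]), call. = FALSE)
    }
  }
  ct_matrix(ct, cen, detection_limit)
}

#' Write a Ct matrix to a wide delimited file
#'
#' Censored cells are written as the detection limit; a round trip through
#' [read_ct_matrix()] restores both values and censor flags.
#'
#' @param x a [ct_matrix]
#' @param path destination; extension picks the delimiter
#' @export
write_ct_matrix <- function(x, path) {
  df <- data.frame(detector = detector_ids(x), x$ct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group design table
#'
#' Expects columns `sample` and `group`; delimiter from the extension.
#'
#' @param path design file
#' @param control_candidates optional endogenous-control detector ids to
#'   attach to the design
#' @return a [study_design]
#' @export
read_design <- function(path, control_candidates = character()) {
  raw <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(raw))) {
    stop("design needs columns `sample` and `group`", call. = FALSE)
  }
  groups <- stats::setNames(as.character(raw$group), as.character(raw$sample))
  study_design(groups, control_candidates)
}

#' Read amplification curves from a long table
#'
#' Columns `detector`, `sample`, `cycle`, `fluorescence`; rows may appear in
#' any order, cycles are sorted on load.
#'
#' @param path curves file
#' @return a [curve_set]
#' @export
read_amplification_curves <- function(path) {
  raw <- utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE)
  curve_set(raw)
}

#' Write a differential-expression result table
#'
#' Tab- or comma-separated (by extension) with one row per detector and a
#' fixed column order; `NA` statistics (e.g. curation-failed detectors) are
#' written as the literal token `NA`. [read_results()] round-trips the file.
#'
#' @param table data.frame of per-detector results
#' @param path destination
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("result table must be a nonempty data.frame", call. = FALSE)
  }
  utils::write.table(table, path, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @return `read_results()`: the result data.frame
#' @export
read_results <- function(path) {
  utils::read.delim(path, sep = .delim_for(path), stringsAsFactors = FALSE,
                    check.names = FALSE)
}
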