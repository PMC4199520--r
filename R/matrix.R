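#' Ion-current matrix from a FAIMS scan
#'
#' One full FAIMS scan for a single ion polarity: a grid of ion current
#' (arbitrary units) indexed by dispersion field (percentage of the maximum
#' field, rows) and compensation voltage (volts, columns). The instrument
#' sweeps the dispersion field and, at each setting, records the ion current
#' transmitted at each compensation voltage, so a chemical signature appears
#' as localized structure in this plane.
#'
#' @param current numeric matrix of ion current, `length(df_axis)` rows by
#'   `length(cv_axis)` columns; all values must be finite.
#' @param df_axis strictly increasing numeric vector of dispersion-field
#'   settings (percent of maximum field).
#' @param cv_axis strictly increasing numeric vector of compensation voltages
#'   (V).
#' @param polarity `"positive"` or `"negative"` ion mode.
#'
#' @return An object of class `faims_matrix`: a list with elements
#'   `current`, `df_axis`, `cv_axis`, `polarity`.
#' @examples
#' m <- faims_matrix(matrix(rnorm(12), 3, 4), df_axis = c(10, 20, 30),
#'                   cv_axis = c(-2, -1, 0, 1))
#' dim(m$current)
#' @export
faims_matrix <- function(current, df_axis, cv_axis,
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  current <- as.matrix(current)
  storage.mode(current) <- "double"
  df_axis <- as.numeric(df_axis)
  cv_axis <- as.numeric(cv_axis)
  obj <- structure(
    list(current = current, df_axis = df_axis, cv_axis = cv_axis,
         polarity = polarity),
    class = "faims_matrix")
  validate_faims_matrix(obj)
}

validate_faims_matrix <- function(m) {
  if (length(m$df_axis) == 0L || length(m$cv_axis) == 0L) {
    stop("faims_matrix axes must be non-empty", call. = FALSE)
  }
  if (anyNA(m$current) || !all(is.finite(m$current))) {
    stop("faims_matrix current values must all be finite", call. = FALSE)
  }
  if (!all(diff(m$df_axis) > 0)) {
    stop("df_axis must be strictly increasing", call. = FALSE)
  }
  if (!all(diff(m$cv_axis) > 0)) {
    stop("cv_axis must be strictly increasing", call. = FALSE)
  }
  if (!identical(dim(m$current),
                 c(length(m$df_axis), length(m$cv_axis)))) {
    stop("current must have dim |df_axis| x |cv_axis|; got ",
         paste(dim(m$current), collapse = " x "), call. = FALSE)
  }
  m
}

#' @export
print.faims_matrix <- function(x, ...) {
  cat(sprintf("<faims_matrix> %s polarity, %d DF lines x %d CV points\n",
              x$polarity, length(x$df_axis), length(x$cv_axis)))
  cat(sprintf("  DF %.4g..%.4g %%, CV %.4g..%.4g V, current range [%.4g, %.4g]\n",
              min(x$df_axis), max(x$df_axis), min(x$cv_axis), max(x$cv_axis),
              min(x$current), max(x$current)))
  invisible(x)
}

#' A patient sample: replicate FAIMS matrix pairs plus clinical covariates
#'
#' Each patient contributes one or more replicate scans; a replicate is a
#' pair of `faims_matrix` objects, one per ion polarity. Optional clinical
#' covariates are the anti-tissue-transglutaminase titre (kU/L) and the
#' Marsh histology grade.
#'
#' @param patient_id character scalar, unique within a cohort.
#' @param label class label, `"CD"` or `"D-IBS"`.
#' @param replicates list of replicates; each replicate is a list with
#'   elements `positive` and `negative`, both `faims_matrix` objects.
#' @param ttg optional TTG titre in kU/L (non-negative) or `NA`.
#' @param marsh optional Marsh score, one of `"I"`, `"II"`, `"IIIa"`,
#'   `"IIIb"`, `"IIIc"`, or `NA`.
#'
#' @return An object of class `faims_sample`.
#' @export
faims_sample <- function(patient_id, label, replicates, ttg = NA_real_,
                         marsh = NA_character_) {
  fd_check_label(label)
  if (length(replicates) < 1L) {
    stop("faims_sample needs at least one replicate", call. = FALSE)
  }
  marsh_levels <- c("I", "II", "IIIa", "IIIb", "IIIc")
  if (!is.na(marsh) && !marsh %in% marsh_levels) {
    stop("marsh must be one of ", paste(marsh_levels, collapse = ", "),
         call. = FALSE)
  }
  if (!is.na(ttg) && ttg < 0) stop("ttg must be >= 0", call. = FALSE)
  ref <- replicates[[1L]]
  for (rep in replicates) {
    for (pol in c("positive", "negative")) {
      if (!inherits(rep[[pol]], "faims_matrix")) {
        stop("each replicate must carry a ", pol, " faims_matrix",
             call. = FALSE)
      }
      if (!isTRUE(all.equal(rep[[pol]]$df_axis, ref[[pol]]$df_axis)) ||
          !isTRUE(all.equal(rep[[pol]]$cv_axis, ref[[pol]]$cv_axis))) {
        stop("all replicates of a sample must share axes", call. = FALSE)
      }
    }
  }
  structure(
    list(patient_id = as.character(patient_id), label = label,
         replicates = replicates, ttg = as.numeric(ttg),
         marsh = as.character(marsh)),
    class = "faims_sample")
}

#' @export
print.faims_sample <- function(x, ...) {
  cat(sprintf("<faims_sample> %s (%s), %d replicate(s)\n",
              x$patient_id, x$label, length(x$replicates)))
  invisible(x)
}

cohort_labels <- function(cohort) vapply(cohort, `[[`, "", "label")
cohort_ids <- function(cohort) vapply(cohort, `[[`, "", "patient_id")
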