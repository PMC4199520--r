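#' Write a FAIMS ion-current matrix to a text file
#'
#' Serializes to a plain-text, diff-able tab-separated dialect
#' (conventionally `.faims.tsv`): `#`-prefixed comment lines carry the
#' polarity and axis units, the first data row is the compensation-voltage
#' axis, and each following row starts with its dispersion-field value
#' followed by the ion currents. Values are written with 6 significant
#' digits, which exceeds instrument precision; output bytes are
#' deterministic for identical input.
#'
#' @param m a valid [faims_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_faims_matrix()]
#' @export
write_faims_matrix <- function(m, path) {
  validate_faims_matrix(m)
  fmt <- function(x) formatC(x, digits = 6L, format = "g")
  lines <- c(
    sprintf("# faimsdx matrix v1"),
    sprintf("# polarity: %s", m$polarity),
    "# df_axis: dispersion field (% of max)",
    "# cv_axis: compensation voltage (V)",
    paste(c("df\\cv", fmt(m$cv_axis)), collapse = "\t"))
  body <- vapply(seq_along(m$df_axis), function(i) {
    paste(c(fmt(m$df_axis[i]), fmt(m$current[i, ])), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(lines, body), con = con, sep = "\n")
  fd_log("wrote %s (%d x %d, %s)", path, length(m$df_axis),
         length(m$cv_axis), m$polarity)
  invisible(path)
}

#' Read a FAIMS ion-current matrix from a text file
#'
#' Parses the dialect written by [write_faims_matrix()]. Malformed headers,
#' non-numeric cells and ragged rows raise errors naming the offending line.
#'
#' @param path file path.
#' @param polarity optional expected polarity; an error is raised if the
#'   file header disagrees.
#' @return A [faims_matrix()].
#' @export
read_faims_matrix <- function(path, polarity = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  pol_line <- grep("^# polarity:", lines, value = TRUE)
  if (length(pol_line) != 1L) {
    stop("parse error in ", path, ": expected exactly one '# polarity:' header",
         call. = FALSE)
  }
  file_pol <- trimws(sub("^# polarity:", "", pol_line))
  if (!file_pol %in% c("positive", "negative")) {
    stop("parse error in ", path, ": unknown polarity '", file_pol, "'",
         call. = FALSE)
  }
  if (!is.null(polarity) && !identical(polarity, file_pol)) {
    stop("polarity mismatch in ", path, ": file says ", file_pol,
         ", caller expected ", polarity, call. = FALSE)
  }
  data_idx <- which(!is_comment & nzchar(lines))
  if (length(data_idx) < 2L) {
    stop("parse error in ", path, ": no data rows", call. = FALSE)
  }
  parse_row <- function(idx, drop_first_cell = FALSE) {
    cells <- strsplit(lines[idx], "\t", fixed = TRUE)[[1L]]
    if (drop_first_cell) cells <- cells[-1L]
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      stop("parse error at line ", idx, " of ", path,
           ": non-numeric cell", call. = FALSE)
    }
    vals
  }
  cv_axis <- parse_row(data_idx[1L], drop_first_cell = TRUE)
  rows <- lapply(data_idx[-1L], parse_row)
  ncell <- lengths(rows)
  if (any(ncell != length(cv_axis) + 1L)) {
    bad <- data_idx[-1L][which(ncell != length(cv_axis) + 1L)[1L]]
    stop("parse error at line ", bad, " of ", path,
         ": ragged row (expected ", length(cv_axis) + 1L, " cells)",
         call. = FALSE)
  }
  df_axis <- vapply(rows, `[[`, 0, 1L)
  current <- do.call(rbind, lapply(rows, `[`, -1L))
  if (!all(diff(cv_axis) > 0)) {
    stop("parse error in ", path, ": cv axis not strictly increasing",
         call. = FALSE)
  }
  if (!all(diff(df_axis) > 0)) {
    stop("parse error in ", path, ": df axis not strictly increasing",
         call. = FALSE)
  }
  fd_log("read %s (%d x %d, %s)", path, length(df_axis), length(cv_axis),
         file_pol)
  faims_matrix(current, df_axis, cv_axis, polarity = file_pol)
}

#' Read a cohort manifest and its referenced matrix files
#'
#' The manifest is a CSV with header
#' `patient_id,label,ttg_kU_L,marsh,replicate_paths`. The
#' `replicate_paths` field holds one `positive|negative` file-path pair per
#' replicate, pairs separated by `;`. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A list of [faims_sample()] objects, in manifest order.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("no such manifest: ", manifest_path, call. = FALSE)
  }
  tab <- read.csv(manifest_path, stringsAsFactors = FALSE,
                  colClasses = "character")
  required <- c("patient_id", "label", "ttg_kU_L", "marsh", "replicate_paths")
  if (!all(required %in% names(tab))) {
    stop("manifest must have columns ", paste(required, collapse = ","),
         call. = FALSE)
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in manifest: ",
         paste(unique(tab$patient_id[duplicated(tab$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  cohort <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    pairs <- strsplit(row$replicate_paths, ";", fixed = TRUE)[[1L]]
    reps <- lapply(pairs, function(pair) {
      pp <- strsplit(pair, "|", fixed = TRUE)[[1L]]
      if (length(pp) != 2L) {
        stop("patient ", row$patient_id,
             ": replicate entry must be 'pos_path|neg_path', got '",
             pair, "'", call. = FALSE)
      }
      pp <- resolve(pp)
      missing <- pp[!file.exists(pp)]
      if (length(missing)) {
        stop("patient ", row$patient_id, ": missing matrix file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      list(positive = read_faims_matrix(pp[1L], "positive"),
           negative = read_faims_matrix(pp[2L], "negative"))
    })
    faims_sample(
      patient_id = row$patient_id, label = row$label, replicates = reps,
      ttg = if (nzchar(row$ttg_kU_L)) as.numeric(row$ttg_kU_L) else NA_real_,
      marsh = if (nzchar(row$marsh)) row$marsh else NA_character_)
  })
  fd_log("read cohort of %d samples from %s", length(cohort), manifest_path)
  cohort
}

#' Write a cohort to a directory as matrix files plus a manifest
#'
#' Inverse of [read_cohort()]: one `.faims.tsv` file per replicate per
#' polarity, and a `manifest.csv` indexing them.
#'
#' @param cohort list of [faims_sample()] objects.
#' @param dir output directory (created if absent).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    pairs <- vapply(seq_along(s$replicates), function(r) {
      fp <- sprintf("%s_rep%d_pos.faims.tsv", s$patient_id, r)
      fn <- sprintf("%s_rep%d_neg.faims.tsv", s$patient_id, r)
      write_faims_matrix(s$replicates[[r]]$positive, file.path(dir, fp))
      write_faims_matrix(s$replicates[[r]]$negative, file.path(dir, fn))
      paste(fp, fn, sep = "|")
    }, "")
    data.frame(patient_id = s$patient_id, label = s$label,
               ttg_kU_L = ifelse(is.na(s$ttg), "", format(s$ttg)),
               marsh = ifelse(is.na(s$marsh), "", s$marsh),
               replicate_paths = paste(pairs, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  fd_log("wrote cohort of %d samples under %s", length(cohort), dir)
  invisible(path)
}

#' Write held-out predictions as CSV
#'
#' Columns `patient_id,label,prob_cd`: one row per patient with the true
#' label and the cross-validated probability of coeliac disease.
#'
#' @param predictions data frame as returned by [run_loo_cv()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("patient_id", "label", "prob_cd") %in% names(predictions)))
  write.csv(predictions[, c("patient_id", "label", "prob_cd")], path,
            row.names = FALSE, quote = FALSE)
  fd_log("wrote %d predictions to %s", nrow(predictions), path)
  invisible(path)
}
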