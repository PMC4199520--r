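#' GC-MS chromatogram
#'
#' A single-sample gas-chromatography trace: total ion intensity (MCps,
#' treated as an opaque detector unit) against retention time (minutes,
#' strictly increasing).
#'
#' @param sample_id character scalar.
#' @param label class label, `"CD"` or `"D-IBS"`.
#' @param rt strictly increasing, non-negative retention times (minutes).
#' @param intensity finite intensities (MCps), same length as `rt`.
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(sample_id, label, rt, intensity) {
  fd_check_label(label)
  rt <- as.numeric(rt); intensity <- as.numeric(intensity)
  if (length(rt) != length(intensity)) {
    stop("rt and intensity must have the same length", call. = FALSE)
  }
  if (!all(is.finite(rt)) || !all(is.finite(intensity))) {
    stop("chromatogram values must be finite", call. = FALSE)
  }
  if (any(rt < 0)) stop("retention times must be non-negative", call. = FALSE)
  if (is.unsorted(rt, strictly = TRUE)) {
    stop("retention times must be strictly increasing", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id), label = label,
                 rt = rt, intensity = intensity),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %s (%s), %d points, rt %.2f-%.2f min\n",
              x$sample_id, x$label, length(x$rt), min(x$rt), max(x$rt)))
  invisible(x)
}

#' Write / read a chromatogram as CSV
#'
#' Two-column CSV `rt_min,intensity_mcps`; sample id and label travel in
#' the file name and caller arguments, not the file.
#'
#' @param chrom a [chromatogram()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a [chromatogram()] (reader).
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  write.csv(data.frame(rt_min = chrom$rt, intensity_mcps = chrom$intensity),
            path, row.names = FALSE, quote = FALSE)
  fd_log("wrote chromatogram %s (%d points) to %s", chrom$sample_id,
         length(chrom$rt), path)
  invisible(path)
}

#' @rdname write_chromatogram
#' @param sample_id,label identity to attach to the read trace.
#' @export
read_chromatogram <- function(path, sample_id, label) {
  tab <- read.csv(path)
  if (!all(c("rt_min", "intensity_mcps") %in% names(tab))) {
    stop("chromatogram CSV needs columns rt_min,intensity_mcps", call. = FALSE)
  }
  fd_log("read chromatogram from %s (%d points)", path, nrow(tab))
  chromatogram(sample_id, label, tab$rt_min, tab$intensity_mcps)
}

#' Detect chromatogram peaks above an intensity threshold
#'
#' Subtracts a rolling-median baseline (window 0.5 min), then reports local
#' maxima whose baseline-corrected height exceeds the threshold — by
#' default 1.8 MCps, keeping only peaks clearly above the instrument noise
#' floor. A candidate apex must be the maximum within +/- `min_separation`
#' minutes, so one chemical peak yields one apex. Peak bounds are the
#' half-height crossings around the apex.
#'
#' @param chrom a [chromatogram()] (>= 3 points).
#' @param threshold minimum baseline-corrected height (MCps), default 1.8.
#' @param baseline_window rolling-median window (minutes), default 0.5.
#' @param min_separation minimum apex separation (minutes), default 0.05.
#' @return Data frame of class `peak_list`, ordered by retention time, with
#'   columns `rt_apex`, `height` (baseline-corrected), `left`, `right`.
#' @export
detect_peaks <- function(chrom, threshold = 1.8, baseline_window = 0.5,
                         min_separation = 0.05) {
  stopifnot(inherits(chrom, "chromatogram"))
  n <- length(chrom$rt)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  step <- median(diff(chrom$rt))
  k <- max(3L, round(baseline_window / step))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  baseline <- stats::runmed(chrom$intensity, k, endrule = "median")
  y <- chrom$intensity - baseline
  w <- max(1L, round(min_separation / step))
  cand <- which(y > threshold)
  cand <- cand[cand > 1L & cand < n]
  apexes <- cand[vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    y[i] >= max(y[lo:hi]) && y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, TRUE)]
  if (length(apexes) == 0L) {
    out <- data.frame(rt_apex = numeric(0), height = numeric(0),
                      left = numeric(0), right = numeric(0))
    class(out) <- c("peak_list", "data.frame")
    return(out)
  }
  bounds <- vapply(apexes, function(i) {
    half <- y[i] / 2
    l <- i; while (l > 1L && y[l] > half) l <- l - 1L
    r <- i; while (r < n && y[r] > half) r <- r + 1L
    c(chrom$rt[l], chrom$rt[r])
  }, numeric(2))
  out <- data.frame(rt_apex = chrom$rt[apexes], height = y[apexes],
                    left = bounds[1L, ], right = bounds[2L, ])
  out <- out[order(out$rt_apex), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Bin detected peaks across samples by retention time
#'
#' Greedy agglomeration in retention-time order: a peak joins the current
#' bin while it is within `tolerance` of the previous peak and the bin span
#' stays at most `2 * tolerance`; otherwise it starts a new bin. Every peak
#' lands in exactly one bin; the bin center is the midpoint of its span, so
#' every member apex is within `tolerance` of the center.
#'
#' @param peaks data frame with columns `rt_apex`, `sample_id`, `label`
#'   (peaks pooled over all samples; see [screen_chromatograms()]).
#' @param tolerance maximum apex distance (minutes), default 0.05.
#' @return Data frame of class `peak_bins`: one row per bin with `center`,
#'   `n_peaks`, per-class distinct-sample counts `n_cd`, `n_ibs`, and a
#'   list-column `members` of member row indices into `peaks`.
#' @export
bin_retention_times <- function(peaks, tolerance = 0.05) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  need <- c("rt_apex", "sample_id", "label")
  stopifnot(all(need %in% names(peaks)))
  if (nrow(peaks) == 0L) {
    out <- data.frame(center = numeric(0), n_peaks = integer(0),
                      n_cd = integer(0), n_ibs = integer(0))
    out$members <- list()
    class(out) <- c("peak_bins", "data.frame")
    return(out)
  }
  ord <- order(peaks$rt_apex)
  rts <- peaks$rt_apex[ord]
  bin_id <- integer(length(rts))
  bin_id[1L] <- 1L
  bin_start <- rts[1L]
  for (i in seq_along(rts)[-1L]) {
    if (rts[i] - rts[i - 1L] <= tolerance &&
        rts[i] - bin_start <= 2 * tolerance) {
      bin_id[i] <- bin_id[i - 1L]
    } else {
      bin_id[i] <- bin_id[i - 1L] + 1L
      bin_start <- rts[i]
    }
  }
  out <- do.call(rbind, lapply(split(seq_along(rts), bin_id), function(ii) {
    rows <- ord[ii]
    data.frame(center = (min(rts[ii]) + max(rts[ii])) / 2,
               n_peaks = length(rows),
               n_cd = length(unique(peaks$sample_id[rows][
                 peaks$label[rows] == "CD"])),
               n_ibs = length(unique(peaks$sample_id[rows][
                 peaks$label[rows] == "D-IBS"])))
  }))
  out$members <- lapply(split(seq_along(rts), bin_id), function(ii) ord[ii])
  rownames(out) <- NULL
  class(out) <- c("peak_bins", "data.frame")
  out
}

#' Find peaks present in one class and absent in the other
#'
#' A bin is class-unique when its prevalence (fraction of that class's
#' samples contributing a peak to the bin) is at least `min_prevalence` in
#' one class and exactly zero in the other. Absence is strict: a peak seen
#' in even one sample of the other class disqualifies the bin.
#'
#' @param bins a [bin_retention_times()] result.
#' @param n_cd,n_ibs total number of samples per class (the denominator of
#'   prevalence).
#' @param min_prevalence minimum prevalence in the enriched class,
#'   default 0.9.
#' @return Subset of `bins` with added columns `prev_cd`, `prev_ibs`,
#'   `unique_class`.
#' @export
find_class_unique_peaks <- function(bins, n_cd, n_ibs, min_prevalence = 0.9) {
  stopifnot(inherits(bins, "peak_bins"), n_cd >= 1, n_ibs >= 1)
  prev_cd <- bins$n_cd / n_cd
  prev_ibs <- bins$n_ibs / n_ibs
  cd_unique <- prev_cd >= min_prevalence & bins$n_ibs == 0L
  ibs_unique <- prev_ibs >= min_prevalence & bins$n_cd == 0L
  out <- bins[cd_unique | ibs_unique, , drop = FALSE]
  out$prev_cd <- prev_cd[cd_unique | ibs_unique]
  out$prev_ibs <- prev_ibs[cd_unique | ibs_unique]
  out$unique_class <- ifelse(cd_unique[cd_unique | ibs_unique], "CD", "D-IBS")
  rownames(out) <- NULL
  out
}

#' End-to-end chromatogram screen
#'
#' Detects peaks in every chromatogram, pools and bins them by retention
#' time, and flags class-unique bins.
#'
#' @param chroms list of [chromatogram()] objects (both classes).
#' @param threshold peak height threshold (MCps), default 1.8.
#' @param tolerance retention-time binning tolerance (minutes), default 0.05.
#' @param min_prevalence see [find_class_unique_peaks()].
#' @return List with `peaks` (pooled peak table), `bins`, and `unique_bins`.
#' @export
screen_chromatograms <- function(chroms, threshold = 1.8, tolerance = 0.05,
                                 min_prevalence = 0.9) {
  stopifnot(length(chroms) > 0L)
  pooled <- do.call(rbind, lapply(chroms, function(ch) {
    pk <- detect_peaks(ch, threshold = threshold)
    if (nrow(pk) == 0L) return(NULL)
    cbind(pk, sample_id = ch$sample_id, label = ch$label,
          stringsAsFactors = FALSE)
  }))
  if (is.null(pooled)) {
    pooled <- data.frame(rt_apex = numeric(0), height = numeric(0),
                         left = numeric(0), right = numeric(0),
                         sample_id = character(0), label = character(0))
  }
  labels <- vapply(chroms, `[[`, "", "label")
  bins <- bin_retention_times(pooled, tolerance = tolerance)
  unique_bins <- find_class_unique_peaks(
    bins, n_cd = max(1L, sum(labels == "CD")),
    n_ibs = max(1L, sum(labels == "D-IBS")),
    min_prevalence = min_prevalence)
  list(peaks = pooled, bins = bins, unique_bins = unique_bins)
}
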