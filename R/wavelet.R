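# Standard Daubechies scaling (low-pass) filter coefficients, orders 1-10
# (order = number of vanishing moments; filter length = 2 * order).
# db1 is the Haar filter. These are the published extremal-phase values.
DAUBECHIES_FILTERS <- list(
  db1 = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(0.48296291314453416, 0.83651630373780794, 0.22414386804201339,
          -0.12940952255126037),
  db3 = c(0.33267055295008263, 0.80689150931109255, 0.45987750211849154,
          -0.13501102001025458, -0.085441273882026658, 0.035226291885709533),
  db4 = c(0.23037781330889651, 0.71484657055291567, 0.63088076792985892,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.032883011666885197, -0.010597401785069032),
  db5 = c(0.16010239797419293, 0.60382926979718965, 0.72430852843777294,
          0.13842814590132074, -0.24229488706638203, -0.032244869584638375,
          0.077571493840045719, -0.0062414902127982744, -0.012580751999081999,
          0.0033357252854737712),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
          0.00055384220116149613, 0.0047772575109455108,
          -0.0010773010853084796),
  db7 = c(0.077852054085009184, 0.39653931948191729, 0.72913209084623509,
          0.46978228740519312, -0.14390600392856498, -0.22403618499387498,
          0.071309219266830259, 0.080612609151083078, -0.038029936935014413,
          -0.016574541630666881, 0.01255099855609984, 0.00042957797292136651,
          -0.0018016407040474908, 0.00035371379997452024),
  db8 = c(0.054415842243104008, 0.31287159091429995, 0.67563073629728976,
          0.58535468365420673, -0.015829105256349306, -0.28401554296154691,
          0.00047248457391328279, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.0087460940474057766,
          -0.0048703529934515741, -0.00039174037337694705,
          0.00067544940645056933, -0.00011747678412476953),
  db9 = c(0.038077947363878345, 0.24383467461259034, 0.60482312369011115,
          0.65728807805130052, 0.13319738582500756, -0.29327378327917492,
          -0.096840783222976456, 0.14854074933810638, 0.03072568147933338,
          -0.067632829061329974, 0.00025094711483145197, 0.022361662123679096,
          -0.0047232047577513972, -0.0042815036824634303,
          0.0018476468830562265, 0.00023038576352319597,
          -0.00025196318894271012, 3.9347320316271603e-05),
  db10 = c(0.026670057900555554, 0.1881768000776915, 0.52720118893172563,
           0.68845903945360354, 0.28117234366057747, -0.24984642432731538,
           -0.19594627437737705, 0.12736934033579325, 0.093057364603572348,
           -0.071394147166397082, -0.029457536821875813, 0.033212674059341002,
           0.0036065535669561697, -0.010733175483330575, 0.0013953517470529011,
           0.0019924052951850561, -0.00068585669495971162,
           -0.00011646685512928545, 9.3588670320069592e-05,
           -1.3264202894521244e-05))

daubechies_filter <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("Daubechies order must be a positive integer", call. = FALSE)
  }
  key <- paste0("db", order)
  h <- DAUBECHIES_FILTERS[[key]]
  if (is.null(h)) {
    stop("Daubechies order ", order, " not available (orders 1-10 supported)",
         call. = FALSE)
  }
  # quadrature-mirror high-pass: g[l] = (-1)^l h[L-1-l]
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  list(h = h, g = g)
}

#' Wavelet transform configuration
#'
#' @param order Daubechies order (vanishing moments), 1-10; order 1 is the
#'   Haar wavelet. Default 4 ("db4").
#' @param levels decomposition depth: `"max"` (default) decomposes down to a
#'   single approximation coefficient, or an integer number of levels.
#' @param boundary boundary handling; the transform zero-pads the input to
#'   the next power of two and then applies a periodized orthonormal filter
#'   bank, so `"periodic"` is the only supported value.
#' @return An object of class `wavelet_config`.
#' @export
wavelet_config <- function(order = 4, levels = "max", boundary = "periodic") {
  if (!identical(boundary, "periodic")) {
    stop("only the periodic (periodized orthonormal) boundary is supported",
         call. = FALSE)
  }
  daubechies_filter(order)  # validates order
  if (!identical(levels, "max")) {
    if (!is.numeric(levels) || levels < 1 || levels != round(levels)) {
      stop("levels must be 'max' or a positive integer", call. = FALSE)
    }
    levels <- as.integer(levels)
  }
  structure(list(order = as.integer(order), levels = levels,
                 boundary = boundary),
            class = "wavelet_config")
}

#' Feature vector with provenance
#'
#' A flat numeric vector tagged as raw (flattened ion currents) or wavelet
#' (transform coefficients). Wavelet vectors carry an `index_map` data frame
#' mapping each coefficient index to its decomposition level, band
#' (`approx`/`detail`) and within-band position, plus the original
#' (pre-padding) length, so padded positions are identifiable and never leak
#' signal.
#'
#' @param values finite numeric vector.
#' @param provenance `"raw"` or `"wavelet"`.
#' @param index_map required for wavelet provenance; see description.
#' @param n_orig original vector length before zero-padding.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(values, provenance = c("raw", "wavelet"),
                           index_map = NULL, n_orig = length(values)) {
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty feature vector", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("feature vector values must be finite", call. = FALSE)
  }
  if (provenance == "wavelet") {
    if (is.null(index_map) || nrow(index_map) != length(values)) {
      stop("wavelet feature vectors need an index_map covering all indices",
           call. = FALSE)
    }
  }
  structure(list(values = values, provenance = provenance,
                 index_map = index_map, n_orig = as.integer(n_orig)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s, length %d (original %d)\n",
              x$provenance, length(x$values), x$n_orig))
  invisible(x)
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# one analysis step of the periodized orthonormal filter bank:
# a has even length m; returns list(approx, detail) of length m/2
dwt_step <- function(a, h, g) {
  m <- length(a)
  half <- m %/% 2L
  approx <- numeric(half)
  detail <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (l in seq_along(h)) {
    idx <- (base + (l - 1L)) %% m + 1L
    approx <- approx + h[l] * a[idx]
    detail <- detail + g[l] * a[idx]
  }
  list(approx = approx, detail = detail)
}

idwt_step <- function(approx, detail, h, g) {
  half <- length(approx)
  m <- 2L * half
  y <- numeric(m)
  base <- 2L * (seq_len(half) - 1L)
  for (l in seq_along(h)) {
    idx <- (base + (l - 1L)) %% m + 1L
    y[idx] <- y[idx] + h[l] * approx + g[l] * detail
  }
  y
}

#' Forward 1-D Daubechies wavelet transform
#'
#' Zero-pads the input to the next power of two, then applies a periodized
#' orthonormal Daubechies filter bank for the requested number of levels.
#' The transform is linear and energy-preserving (the padded analysis
#' operator is orthonormal), and is exactly inverted by [dwt_inverse()].
#' Coefficients are ordered coarsest-first: the deepest-level approximation
#' band, then detail bands from deepest to finest.
#'
#' @param x a raw [feature_vector()] or plain numeric vector.
#' @param config a [wavelet_config()].
#' @return A wavelet [feature_vector()] with populated `index_map`.
#' @examples
#' w <- dwt_forward(c(1, 3), wavelet_config(order = 1))
#' w$values  # 2*sqrt(2), -sqrt(2)
#' @export
dwt_forward <- function(x, config = wavelet_config()) {
  if (inherits(x, "feature_vector")) {
    if (x$provenance != "raw") {
      stop("dwt_forward expects a raw vector", call. = FALSE)
    }
    x <- x$values
  }
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty input vector", call. = FALSE)
  filt <- daubechies_filter(config$order)
  n_orig <- length(x)
  n_pad <- next_pow2(n_orig)
  a <- c(x, numeric(n_pad - n_orig))
  max_levels <- as.integer(log2(n_pad))
  n_levels <- if (identical(config$levels, "max")) max_levels
              else min(config$levels, max_levels)
  details <- vector("list", n_levels)
  for (j in seq_len(n_levels)) {
    step <- dwt_step(a, filt$h, filt$g)
    a <- step$approx
    details[[j]] <- step$detail
  }
  values <- c(a, unlist(rev(details)))
  bands <- c(list(data.frame(level = n_levels, kind = "approx",
                             position = seq_along(a))),
             lapply(rev(seq_len(n_levels)), function(j) {
               data.frame(level = j, kind = "detail",
                          position = seq_along(details[[j]]))
             }))
  index_map <- do.call(rbind, bands)
  index_map <- cbind(index = seq_len(n_pad), index_map)
  out <- feature_vector(values, "wavelet", index_map = index_map,
                        n_orig = n_orig)
  out$config <- config
  out
}

#' Inverse 1-D Daubechies wavelet transform
#'
#' Reconstructs the original vector from a wavelet [feature_vector()]
#' produced by [dwt_forward()], truncating the zero-padding back to the
#' original length.
#'
#' @param w a wavelet [feature_vector()] with `index_map`.
#' @param config a [wavelet_config()]; defaults to the one stored on `w`.
#' @return A raw [feature_vector()].
#' @export
dwt_inverse <- function(w, config = NULL) {
  if (!inherits(w, "feature_vector") || w$provenance != "wavelet" ||
      is.null(w$index_map)) {
    stop("dwt_inverse needs a wavelet feature_vector with an index_map",
         call. = FALSE)
  }
  if (is.null(config)) config <- w$config
  if (is.null(config)) {
    stop("no wavelet config stored on the vector; pass one explicitly",
         call. = FALSE)
  }
  filt <- daubechies_filter(config$order)
  map <- w$index_map
  n_levels <- max(map$level)
  a <- w$values[map$kind == "approx"]
  for (j in rev(seq_len(n_levels))) {
    d <- w$values[map$kind == "detail" & map$level == j]
    a <- idwt_step(a, d, filt$h, filt$g)
  }
  feature_vector(a[seq_len(w$n_orig)], "raw", n_orig = w$n_orig)
}
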