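#' Synthetic cohort configuration
#'
#' The generator emulates the pilot-study design: 27 coeliac patients
#' versus 20 diarrhoea-predominant IBS controls, three replicate FAIMS
#' matrix pairs per patient, a sparse class-discriminative signal expressed
#' as amplitude shifts of a few localized 2-D Gaussian blobs in the
#' (dispersion field, compensation voltage) plane, and larger
#' patient-to-patient amplitude variation in the IBS class (IBS is a
#' heterogeneous diagnosis of exclusion, so its volatile profile is modelled
#' as twice as variable between patients as the coeliac one).
#'
#' @param n_cd,n_ibs patients per class (defaults 27 and 20).
#' @param replicates_per_sample replicate scans per patient (default 3).
#' @param n_df,n_cv grid dimensions: dispersion-field lines and
#'   compensation-voltage points per polarity (defaults 51 and 512).
#' @param n_signal_regions number of class-discriminative blobs (default 3).
#' @param effect_size standardized between-class shift of each
#'   discriminative blob amplitude, on Cohen's d scale relative to the
#'   pooled between-patient SD (default 2: a strong, clearly separable
#'   signature; 0 gives an exchangeable null cohort).
#' @param patient_sd_cd,patient_sd_ibs between-patient SD of blob amplitudes
#'   in each class (defaults 1 and 2).
#' @param patient_field_sd per-pixel SD of a smooth patient-specific random
#'   field added to every replicate of a patient (default 1). This models
#'   the diffuse inter-individual variation of a volatile profile (diet,
#'   metabolism) that real cohorts show across the whole measurement plane,
#'   not just at the discriminative locations; it is class-independent and
#'   shared across a patient's replicates.
#' @param noise_sd within-replicate per-pixel measurement noise SD
#'   (default 0.5).
#' @param seed integer RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cd = 27, n_ibs = 20,
                             replicates_per_sample = 3,
                             n_df = 51, n_cv = 512,
                             n_signal_regions = 3,
                             effect_size = 2,
                             patient_sd_cd = 1, patient_sd_ibs = 2,
                             patient_field_sd = 1,
                             noise_sd = 0.5, seed = 1L) {
  stopifnot(n_cd >= 0, n_ibs >= 0, replicates_per_sample >= 1,
            n_signal_regions >= 0, patient_sd_cd >= 0, patient_sd_ibs >= 0,
            patient_field_sd >= 0, noise_sd >= 0, effect_size >= 0)
  if (n_df < 1 || n_cv < 1) stop("grid must be non-empty", call. = FALSE)
  structure(list(n_cd = as.integer(n_cd), n_ibs = as.integer(n_ibs),
                 replicates_per_sample = as.integer(replicates_per_sample),
                 n_df = as.integer(n_df), n_cv = as.integer(n_cv),
                 n_signal_regions = as.integer(n_signal_regions),
                 effect_size = effect_size,
                 patient_sd_cd = patient_sd_cd,
                 patient_sd_ibs = patient_sd_ibs,
                 patient_field_sd = patient_field_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

# smooth instrument background shared by all samples: a curved ridge in the
# (DF, CV) plane mimicking the reactant-ion peak trace
faims_background <- function(df_axis, cv_axis, amplitude = 10) {
  ridge_cv <- -1 + 2.5 * (df_axis / max(df_axis))^2  # V, drifts with field
  outer(seq_along(df_axis), seq_along(cv_axis), function(i, j) {
    amplitude * exp(-(cv_axis[j] - ridge_cv[i])^2 / (2 * 0.8^2))
  })
}

gaussian_blob <- function(df_axis, cv_axis, df0, cv0, sd_df, sd_cv) {
  outer(exp(-(df_axis - df0)^2 / (2 * sd_df^2)),
        exp(-(cv_axis - cv0)^2 / (2 * sd_cv^2)))
}

# row-normalized Gaussian smoothing matrix over an axis in physical units;
# rows have unit L2 norm so a smoothed iid-normal draw keeps unit pixel
# variance. sigma is in the axis units, so field smoothness does not depend
# on grid resolution.
smoothing_matrix <- function(axis, sigma) {
  K <- outer(axis, axis, function(a, b) exp(-(a - b)^2 / (2 * sigma^2)))
  K / sqrt(rowSums(K^2))
}

# smooth patient-specific random field with per-pixel SD `sd`
# (correlation length ~sigma_df grid lines by ~sigma_cv points)
patient_field <- function(Kdf, Kcv, sd) {
  if (sd == 0) return(0)
  Z <- matrix(rnorm(nrow(Kdf) * nrow(Kcv)), nrow(Kdf))
  sd * (Kdf %*% Z %*% t(Kcv))
}

#' Generate a synthetic FAIMS cohort with a planted class signal
#'
#' Draws blob locations once per cohort, then per patient (a) a latent
#' amplitude for each blob (class mean plus a patient effect with the
#' class's between-patient SD) and (b) a smooth patient-specific random
#' field spanning both polarity planes, modelling diffuse inter-individual
#' profile variation. Replicates of one patient share those latent
#' components exactly and differ only by per-pixel measurement noise.
#' Discriminative blobs have their class mean shifted by
#' `effect_size * pooled_sd` in the coeliac class; the random field,
#' non-discriminative common blobs and the instrument background are
#' identical in distribution between classes. Identical seeds give
#' identical cohorts, and per-patient RNG substreams make each patient's
#' draw independent of generation order.
#'
#' @param config a [synthetic_config()].
#' @return List of [faims_sample()] objects (coeliac patients first), with
#'   attribute `"signal"`: the blob locations, polarities and class means
#'   used (for diagnostics).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cd + config$n_ibs
  if (n == 0L) return(list())
  df_axis <- seq(0, 100, length.out = config$n_df)
  cv_axis <- seq(-6, 6, length.out = max(config$n_cv, 2L))[seq_len(config$n_cv)]
  bg <- faims_background(df_axis, cv_axis)

  set.seed(config$seed)
  n_common <- 3L
  n_blob <- config$n_signal_regions + n_common
  blobs <- data.frame(
    df0 = runif(n_blob, 15, 90),
    cv0 = runif(n_blob, -4, 4),
    sd_df = runif(n_blob, 4, 8),
    sd_cv = runif(n_blob, 0.25, 0.5),
    polarity = rep_len(c("positive", "negative"), n_blob),
    discriminative = rep(c(TRUE, FALSE),
                         c(config$n_signal_regions, n_common)))
  sd_pool <- sqrt((config$patient_sd_cd^2 + config$patient_sd_ibs^2) / 2)
  mu_base <- 4
  blobs$mu_ibs <- mu_base
  blobs$mu_cd <- mu_base + ifelse(blobs$discriminative,
                                  config$effect_size * sd_pool, 0)
  shapes <- lapply(seq_len(n_blob), function(b) {
    gaussian_blob(df_axis, cv_axis, blobs$df0[b], blobs$cv0[b],
                  blobs$sd_df[b], blobs$sd_cv[b])
  })

  # field correlation lengths match typical chemical peak widths
  # (~3 %DF by ~0.4 V), so the nuisance structure is resolution-invariant
  Kdf <- smoothing_matrix(df_axis, sigma = 3)
  Kcv <- smoothing_matrix(cv_axis, sigma = 0.4)

  labels <- rep(c("CD", "D-IBS"), c(config$n_cd, config$n_ibs))
  cohort <- lapply(seq_len(n), function(i) {
    set.seed(fd_subseed(config$seed, i))
    lab <- labels[i]
    sd_pat <- if (lab == "CD") config$patient_sd_cd else config$patient_sd_ibs
    mu <- if (lab == "CD") blobs$mu_cd else blobs$mu_ibs
    amp <- mu + rnorm(n_blob, 0, sd_pat)  # latent, shared across replicates
    clean <- list(
      positive = bg + patient_field(Kdf, Kcv, config$patient_field_sd),
      negative = bg + patient_field(Kdf, Kcv, config$patient_field_sd))
    for (b in seq_len(n_blob)) {
      pol <- blobs$polarity[b]
      clean[[pol]] <- clean[[pol]] + amp[b] * shapes[[b]]
    }
    reps <- lapply(seq_len(config$replicates_per_sample), function(r) {
      lapply(setNames(c("positive", "negative"), c("positive", "negative")),
             function(pol) {
               cur <- clean[[pol]] +
                 matrix(rnorm(length(bg), 0, config$noise_sd), nrow(bg))
               faims_matrix(cur, df_axis, cv_axis, polarity = pol)
             })
    })
    ttg <- if (lab == "CD") round(exp(rnorm(1, 1.0, 1.2)), 1) else
      round(runif(1, 0, 0.9), 1)
    marsh <- if (lab == "CD") {
      sample(c("I", "II", "IIIa", "IIIb", "IIIc"), 1,
             prob = c(1, 1, 9, 6, 10))
    } else NA_character_
    faims_sample(sprintf("P%03d", i), lab, reps, ttg = ttg, marsh = marsh)
  })
  attr(cohort, "signal") <- blobs
  cohort
}

#' Permute class labels of a cohort
#'
#' Shuffles the label assignment over patients while leaving every matrix,
#' replicate and covariate untouched; the label multiset is preserved.
#' This is the null-hypothesis generator for permutation checks: any
#' genuine class signal is destroyed, so a fair pipeline should score an
#' AUC near 0.5 on the permuted cohort.
#'
#' @param cohort list of [faims_sample()] objects.
#' @param seed integer RNG seed (permutations are deterministic per seed).
#' @return The cohort with permuted labels.
#' @export
permute_labels <- function(cohort, seed = 1L) {
  if (length(cohort) == 0L) stop("empty cohort", call. = FALSE)
  set.seed(seed)
  perm <- sample(cohort_labels(cohort))
  Map(function(s, lab) { s$label <- lab; s }, cohort, perm)
}

#' Generate synthetic GC-MS chromatograms with a class-unique peak
#'
#' Both classes share a set of common peaks (by default at the retention
#' times 5.30, 7.63, 7.95 and 9.76 minutes typical of urinary headspace
#' volatiles) plus a deliberately sub-threshold peak, while only the
#' coeliac class carries an additional peak near `unique_peak_rt`
#' (default 4.67 min) with height safely above the 1.8 MCps detection
#' threshold. Peaks are Gaussian (SD 0.02 min) on a flat baseline with
#' additive noise of SD 0.05 MCps; per-sample retention times jitter
#' uniformly by at most 0.03 min, within the default binning tolerance.
#'
#' @param n_cd,n_ibs chromatograms per class (>= 1).
#' @param unique_peak_rt retention time (minutes) of the coeliac-only peak.
#' @param seed integer RNG seed.
#' @return List with elements `CD` and `D-IBS`, each a list of
#'   [chromatogram()] objects.
#' @export
generate_chromatograms <- function(n_cd = 27, n_ibs = 20,
                                   unique_peak_rt = 4.67, seed = 1L) {
  stopifnot(n_cd >= 1, n_ibs >= 1)
  rt <- seq(2, 11, by = 0.005)
  common_rt <- c(5.30, 7.63, 7.95, 9.76)
  common_h <- c(4.0, 3.0, 5.0, 2.5)
  sub_rt <- 6.40          # always below the 1.8 MCps reporting threshold
  sub_h <- 1.0
  one <- function(sample_id, label, counter) {
    set.seed(fd_subseed(seed, counter))
    peaks_rt <- common_rt
    peaks_h <- common_h * runif(length(common_h), 0.8, 1.2)
    peaks_rt <- c(peaks_rt, sub_rt)
    peaks_h <- c(peaks_h, sub_h * runif(1, 0.8, 1.2))
    if (label == "CD") {
      peaks_rt <- c(peaks_rt, unique_peak_rt)
      peaks_h <- c(peaks_h, 3.0 * runif(1, 0.8, 1.2))
    }
    peaks_rt <- peaks_rt + runif(length(peaks_rt), -0.03, 0.03)
    y <- 0.2 + rnorm(length(rt), 0, 0.05)
    for (p in seq_along(peaks_rt)) {
      y <- y + peaks_h[p] * exp(-(rt - peaks_rt[p])^2 / (2 * 0.02^2))
    }
    chromatogram(sample_id, label, rt, pmax(y, 0))
  }
  cd <- lapply(seq_len(n_cd), function(i)
    one(sprintf("CD%03d", i), "CD", i))
  ibs <- lapply(seq_len(n_ibs), function(i)
    one(sprintf("IBS%03d", i), "D-IBS", n_cd + i))
  list("CD" = cd, "D-IBS" = ibs)
}
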