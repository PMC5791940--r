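# Synthetic data: textured lesion phantoms and survival cohorts with known
# hazard structure. These generators define the package's test conditions.

#' Specification of a lesion phantom
#'
#' Describes an ellipsoidal lesion on a low-uptake background. Heterogeneity
#' inside the lesion is a random texture field scaled by `mixing_amplitude`
#' (its standard deviation in SUV units). The field blends a spatially
#' coherent component (seeded white noise smoothed to
#' `correlation_length_mm`) with an unsmoothed voxel-scale component; the
#' voxel-scale weight grows with the amplitude as `a / (a + 1)`, so weak
#' heterogeneity forms coherent subregions while strong heterogeneity mixes
#' gray levels ever more finely. This coupling is what makes the amplitude a
#' genuine heterogeneity dial under min-max relative quantization, which
#' discards any purely affine rescaling of the lesion values.
#' `mixing_amplitude = 0` yields a perfectly uniform lesion.
#'
#' @param grid_size integer length-3 voxel counts (default 48 x 48 x 32).
#' @param spacing_mm voxel size in mm (default 4.07 x 4.07 x 3, the native
#'   grid of a 200 x 200 PET matrix).
#' @param center_mm lesion center in mm; default grid center.
#' @param semi_axes_mm ellipsoid semi-axes in mm (default 30, 24, 20).
#' @param background_suv background uptake, must be below 3.5 (default 0.8).
#' @param lesion_suv lesion base uptake, must be at least 3.5 (default 8).
#' @param correlation_length_mm spatial correlation length of the
#'   heterogeneity field (default 8 mm).
#' @param mixing_amplitude SUV standard deviation of the heterogeneity field
#'   (default 1.5).
#' @param noise_sd white-noise standard deviation added everywhere
#'   (default 0.05).
#' @param seed integer seed; fixes the output exactly.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(48L, 48L, 32L),
                         spacing_mm = c(4.07, 4.07, 3.0),
                         center_mm = NULL,
                         semi_axes_mm = c(30, 24, 20),
                         background_suv = 0.8,
                         lesion_suv = 8,
                         correlation_length_mm = 8,
                         mixing_amplitude = 1.5,
                         noise_sd = 0.05,
                         seed = 1L) {
  grid_size <- as.integer(grid_size)
  stopifnot(length(grid_size) == 3L, all(grid_size >= 4L),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            length(semi_axes_mm) == 3L, all(semi_axes_mm > 0),
            mixing_amplitude >= 0, noise_sd >= 0,
            correlation_length_mm > 0)
  if (background_suv >= 3.5)
    stop("background SUV must be below the 3.5 segmentation threshold",
         call. = FALSE)
  if (lesion_suv < 3.5)
    stop("lesion base SUV must be at least 3.5", call. = FALSE)
  if (is.null(center_mm)) center_mm <- (grid_size - 1) / 2 * spacing_mm
  structure(list(grid_size = grid_size, spacing_mm = spacing_mm,
                 center_mm = center_mm, semi_axes_mm = semi_axes_mm,
                 background_suv = background_suv, lesion_suv = lesion_suv,
                 correlation_length_mm = correlation_length_mm,
                 mixing_amplitude = mixing_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing along each axis; sigma in voxel units
smooth_gaussian_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    n <- dim(a)[axis]
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = s)
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    b <- aperm(a, perm)
    dmb <- dim(b)
    b <- K %*% matrix(b, nrow = dmb[1])
    dim(b) <- dmb
    a <- aperm(b, order(perm))
  }
  a
}

#' Generate a textured lesion phantom
#'
#' @param spec a [phantom_spec()].
#' @return List with `volume` (a [pet_volume()]) and `truth_mask` (logical
#'   array: the analytic ellipsoid).
#' @examples
#' ph <- make_phantom(phantom_spec(mixing_amplitude = 0, seed = 7))
#' sum(ph$truth_mask)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_size
  sp <- spec$spacing_mm
  # physical coordinate grids
  cx <- (seq_len(dm[1]) - 1) * sp[1]
  cy <- (seq_len(dm[2]) - 1) * sp[2]
  cz <- (seq_len(dm[3]) - 1) * sp[3]
  u2 <- outer(outer(((cx - spec$center_mm[1]) / spec$semi_axes_mm[1])^2,
                    ((cy - spec$center_mm[2]) / spec$semi_axes_mm[2])^2, "+"),
              ((cz - spec$center_mm[3]) / spec$semi_axes_mm[3])^2, "+")
  truth <- u2 <= 1
  if (!any(truth)) stop("lesion contains no voxel", call. = FALSE)
  lo <- spec$center_mm - spec$semi_axes_mm
  hi <- spec$center_mm + spec$semi_axes_mm
  if (any(lo < 0) || any(hi > (dm - 1) * sp))
    stop("lesion exceeds the grid", call. = FALSE)

  set.seed(spec$seed)
  vals <- array(spec$background_suv, dim = dm)
  vals[truth] <- spec$lesion_suv
  if (spec$mixing_amplitude > 0) {
    a <- spec$mixing_amplitude
    smooth <- array(stats::rnorm(prod(dm)), dim = dm)
    smooth <- smooth_gaussian_3d(smooth, spec$correlation_length_mm / sp)
    smooth <- (smooth - mean(smooth)) / stats::sd(smooth)
    white <- array(stats::rnorm(prod(dm)), dim = dm)
    w <- a / (a + 1)                      # voxel-scale mixing weight
    field <- (1 - w) * smooth + w * white
    field <- (field - mean(field)) / stats::sd(field)
    vals[truth] <- vals[truth] + a * field[truth]
  }
  if (spec$noise_sd > 0)
    vals <- vals + stats::rnorm(prod(dm), sd = spec$noise_sd)
  vals[vals < 0] <- 0
  list(volume = pet_volume(vals, spacing = sp), truth_mask = truth)
}

default_feature_marginals <- function() {
  data.frame(
    feature = c("co_entropy", "co_homogeneity", "va_intensity_variability",
                "va_short_run_emphasis", "nid_busyness", "nid_contrast",
                "isz_intensity_variability", "isz_high_intensity_zone_emphasis",
                "suv_max", "suv_average", "metabolic_volume"),
    mean = c(8, 0.5, 400, 0.6, 1.2, 0.05, 300, 450, 12, 6, 30),
    sd = c(1.5, 0.1, 150, 0.1, 0.4, 0.02, 120, 150, 5, 2, NA),
    loading = c(0.9, -0.85, -0.8, 0.8, -0.75, 0.75, -0.7, 0.7,
                0.4, 0.3, 0.5),
    lognormal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic survival cohort
#'
#' Emulates a per-subject table of texture and conventional PET parameters
#' with right-censored progression-free survival. Feature dependence is a
#' Gaussian copula driven by a single latent heterogeneity factor: feature f
#' has latent value `loading_f * g + sqrt(1 - loading_f^2) * eps`, so
#' features with positive loadings are mutually rank-correlated and
#' anti-correlated with negative-loading features — the structure a Spearman
#' screen against co-occurrence entropy expects. Event times follow a
#' Weibull proportional-hazards model with linear predictor
#' `sum(beta_f * z_f) + sum(beta_c * covariate_c)`, where `z_f` is the
#' latent standard-normal score of feature f (betas on features are
#' per-standard-deviation log hazard ratios). Censoring is independent
#' exponential, with its rate calibrated so the expected censored fraction
#' equals `censoring_rate`.
#'
#' @param n cohort size (default 161, the exploratory dataset size; use 21
#'   for a validation-sized cohort).
#' @param betas named log-hazard coefficients; names may be feature names
#'   (per latent SD) or the binary covariates `ecog_group`,
#'   `disease_status`, `mv_category`.
#' @param weibull_shape,weibull_scale baseline Weibull parameters (months;
#'   defaults 1.2 and 15, putting the baseline median near 11 months).
#' @param censoring_rate target censored fraction in \[0, 1) (default 0.2).
#' @param ecog_prob probability of poor performance status (ECOG 2-4;
#'   default 0.13).
#' @param metastatic_prob probability of initially metastatic (vs recurred)
#'   disease (default 0.85).
#' @param marginals data frame of feature marginals (columns `feature`,
#'   `mean`, `sd`, `loading`, `lognormal`); default
#'   `default_feature_marginals()` covers the eight texture parameters,
#'   SUVmax, SUVaverage and metabolic volume.
#' @param seed integer seed; fixes the output exactly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 161L,
                        betas = c(co_entropy = 0.5, ecog_group = 0.6,
                                  disease_status = 0.3),
                        weibull_shape = 1.2, weibull_scale = 15,
                        censoring_rate = 0.2,
                        ecog_prob = 0.13, metastatic_prob = 0.85,
                        marginals = default_feature_marginals(),
                        seed = 1L) {
  stopifnot(n >= 2L, weibull_shape > 0, weibull_scale > 0,
            ecog_prob >= 0, ecog_prob <= 1,
            metastatic_prob >= 0, metastatic_prob <= 1)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring rate must be in [0, 1)", call. = FALSE)
  stopifnot(all(abs(marginals$loading) <= 1))
  known <- c(marginals$feature, "ecog_group", "disease_status", "mv_category")
  if (length(betas) && !all(names(betas) %in% known))
    stop("betas name unknown terms: ",
         paste(setdiff(names(betas), known), collapse = ", "), call. = FALSE)
  structure(list(n = as.integer(n), betas = betas,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 censoring_rate = censoring_rate, ecog_prob = ecog_prob,
                 metastatic_prob = metastatic_prob, marginals = marginals,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic survival cohort
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with one row per subject: `id`, `pfs_time` (months),
#'   `event` (0/1), `ecog_group`, `disease_status`, `mv_category` (0/1 at
#'   45 cm^3), and one column per feature in the spec's marginals.
#' @examples
#' coh <- make_cohort(cohort_spec(n = 50, seed = 3))
#' mean(coh$event)
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  mg <- spec$marginals
  k <- nrow(mg)
  g <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * k), n, k)
  z <- sweep(eps, 2L, sqrt(1 - mg$loading^2), "*") +
    outer(g, mg$loading)
  feats <- matrix(NA_real_, n, k, dimnames = list(NULL, mg$feature))
  for (j in seq_len(k)) {
    if (mg$lognormal[j]) {
      # mean column holds the median on the natural scale; sdlog fixed 0.9
      feats[, j] <- exp(log(mg$mean[j]) + 0.9 * z[, j])
    } else {
      feats[, j] <- mg$mean[j] + mg$sd[j] * z[, j]
    }
  }
  ecog_group <- stats::rbinom(n, 1L, spec$ecog_prob)
  disease_status <- stats::rbinom(n, 1L, spec$metastatic_prob)
  mv_category <- as.integer(feats[, "metabolic_volume"] > 45)

  lp <- rep(0, n)
  for (nm in names(spec$betas)) {
    x <- if (nm %in% mg$feature) z[, match(nm, mg$feature)]
         else switch(nm, ecog_group = ecog_group,
                     disease_status = disease_status,
                     mv_category = mv_category)
    lp <- lp + spec$betas[[nm]] * x
  }
  u <- stats::runif(n)
  t_event <- spec$weibull_scale * (-log(u) / exp(lp))^(1 / spec$weibull_shape)

  if (spec$censoring_rate > 0) {
    target <- spec$censoring_rate
    frac <- function(r) mean(1 - exp(-r * t_event)) - target
    hi <- 1
    while (frac(hi) < 0) hi <- hi * 2
    rate <- stats::uniroot(frac, c(1e-12, hi), tol = 1e-10)$root
    cens <- stats::rexp(n, rate)
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  time <- pmax(time, 1e-6)
  out <- data.frame(id = seq_len(n), pfs_time = time, event = event,
                    ecog_group = ecog_group, disease_status = disease_status,
                    mv_category = mv_category)
  cbind(out, as.data.frame(feats))
}
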