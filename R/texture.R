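# Texture-matrix families on the quantized tumor.
#
# All four families aggregate the 13 unique 3D directions (and, for the
# co-occurrence matrix, both orientations of each) into a single matrix per
# lesion before any statistic is computed.

#' Build the gray-level co-occurrence matrix (GLCM)
#'
#' Counts ordered pairs of in-mask gray levels separated by `distance` voxel
#' steps along each of the 13 unique 3D directions and both orientations,
#' summed into one symmetric L x L matrix. The offset is in grid steps; no
#' mm correction is applied for anisotropic voxels.
#'
#' @param q a `quantized_volume` from [quantize()].
#' @param distance offset length in voxel steps (default 1).
#' @return An object of class `cooccurrence_matrix`: list with `counts`
#'   (L x L), `normalized` (probabilities summing to 1), `distance`,
#'   `n_directions` (13).
#' @export
build_cooccurrence <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_volume"), distance >= 1L)
  lev <- q$levels
  L <- q$L
  counts <- matrix(0, L, L)
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    nb <- shift_array(lev, dirs[k, ] * as.integer(distance), fill = 0L)
    ok <- lev > 0L & nb > 0L
    if (any(ok)) {
      tab <- matrix(table(factor(lev[ok], levels = 1:L),
                          factor(nb[ok], levels = 1:L)), L, L)
      counts <- counts + tab + t(tab)   # both orientations
    }
  }
  tot <- sum(counts)
  if (tot == 0)
    stop("NoPairs: mask has no voxel pair at the requested offset",
         call. = FALSE)
  structure(list(counts = counts, normalized = counts / tot,
                 distance = as.integer(distance), n_directions = 13L),
            class = "cooccurrence_matrix")
}

#' Co-occurrence entropy
#'
#' Randomness of the voxel-intensity pair distribution:
#' `-sum p(i,j) log2 p(i,j)` over nonzero entries. Higher values mean a more
#' heterogeneous local gray-level structure; a uniform lesion scores 0.
#'
#' @param M a `cooccurrence_matrix`.
#' @param base logarithm base (default 2).
#' @return Non-negative scalar.
#' @export
co_entropy <- function(M, base = 2) {
  stopifnot(inherits(M, "cooccurrence_matrix"))
  p <- M$normalized[M$normalized > 0]
  -sum(p * log(p, base = base))
}

#' Co-occurrence homogeneity
#'
#' `sum p(i,j) / (1 + |i - j|)`; equals 1 when all pair mass lies on the
#' diagonal (a locally uniform lesion) and decreases with local contrast.
#'
#' @param M a `cooccurrence_matrix`.
#' @return Scalar in (0, 1].
#' @export
co_homogeneity <- function(M) {
  stopifnot(inherits(M, "cooccurrence_matrix"))
  L <- nrow(M$normalized)
  w <- 1 / (1 + abs(outer(1:L, 1:L, "-")))
  sum(M$normalized * w)
}

#' Build the neighborhood intensity difference (NGTDM) table
#'
#' For each voxel with at least one in-mask 26-neighbor, the absolute
#' difference between its gray level and the mean level of its in-mask
#' neighbors is accumulated per level (`s_i`); `p_i` is the fraction of
#' contributing voxels at level i. Voxels with no in-mask neighbor are
#' skipped.
#'
#' @param q a `quantized_volume`.
#' @return An object of class `nid_matrix`: list with `p` (length L), `s`
#'   (length L), `n_voxels` (contributing voxels).
#' @export
build_nid <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  lev <- q$levels
  L <- q$L
  inmask <- lev > 0L
  nb_sum <- array(0, dim = dim(lev))
  nb_cnt <- array(0L, dim = dim(lev))
  dirs <- unique_directions_3d()
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      sh <- shift_array(lev, dirs[k, ] * sgn, fill = 0L)
      nb_sum <- nb_sum + sh
      nb_cnt <- nb_cnt + (sh > 0L)
    }
  }
  if (!any(inmask)) stop("empty mask", call. = FALSE)
  contrib <- inmask & nb_cnt > 0L
  if (!any(contrib)) {
    # isolated voxels only: no neighborhood differences exist
    li <- factor(lev[inmask], levels = 1:L)
    n_i <- as.numeric(table(li))
    return(structure(list(p = n_i / sum(n_i), s = numeric(L),
                          n_voxels = sum(n_i)),
                     class = "nid_matrix"))
  }
  diff <- abs(lev[contrib] - nb_sum[contrib] / nb_cnt[contrib])
  li <- factor(lev[contrib], levels = 1:L)
  s <- as.numeric(tapply(diff, li, sum, default = 0))
  n_i <- as.numeric(table(li))
  n <- sum(n_i)
  structure(list(p = n_i / n, s = s, n_voxels = n), class = "nid_matrix")
}

#' NGTDM busyness and contrast
#'
#' Busyness measures rapid level changes between a voxel and its
#' neighborhood relative to the spread of level magnitudes:
#' `(sum_i p_i s_i) / (sum_{i != j} |i p_i - j p_j|)` over present levels.
#' Contrast combines the dynamic range of present levels with the mean
#' neighborhood difference:
#' `[sum_ij p_i p_j (i-j)^2 / (Ngp (Ngp - 1))] * [sum_i s_i / N]`.
#' Both are defined as 0 when their denominator vanishes (a uniform lesion).
#'
#' @param q a `quantized_volume`.
#' @return Named list with `busyness` and `contrast` (both >= 0).
#' @export
nid_features <- function(q) {
  nm <- build_nid(q)
  present <- which(nm$p > 0)
  p <- nm$p
  s <- nm$s
  ngp <- length(present)
  ip <- present * p[present]
  denom_b <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (denom_b > 0) sum(p[present] * s[present]) / denom_b else 0
  contrast <- if (ngp > 1) {
    rng <- sum(outer(p[present], p[present]) *
                 outer(present, present, "-")^2) / (ngp * (ngp - 1))
    rng * sum(s) / nm$n_voxels
  } else 0
  list(busyness = busyness, contrast = contrast)
}

#' Build the gray-level run-length (voxel alignment) matrix
#'
#' For each of the 13 unique 3D directions, maximal runs of consecutive
#' in-mask voxels sharing a gray level are counted into `R[level, length]`;
#' the 13 per-direction matrices are summed. A single isolated voxel thus
#' contributes 13 runs of length 1.
#'
#' @param q a `quantized_volume`.
#' @return An object of class `run_length_matrix`: list with `counts`
#'   (L x max run length), `n_runs`.
#' @export
build_runlength <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  lev <- q$levels
  L <- q$L
  dm <- dim(lev)
  dirs <- unique_directions_3d()
  maxlen <- sum(dm)  # upper bound on any run length
  counts <- matrix(0, L, maxlen)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nxt <- shift_array(lev, d, fill = 0L)
    prv <- shift_array(lev, -d, fill = 0L)
    cont <- lev > 0L & nxt == lev            # run continues at v -> v + d
    start <- which(lev > 0L & prv != lev)    # run starts (predecessor differs)
    dlin <- linear_offset(d, dm)
    pos <- start
    len <- rep(1L, length(start))
    alive <- cont[pos]
    while (any(alive)) {
      pos[alive] <- pos[alive] + dlin
      len[alive] <- len[alive] + 1L
      alive[alive] <- cont[pos[alive]]
    }
    tab <- matrix(table(factor(lev[start], levels = 1:L),
                        factor(len, levels = seq_len(maxlen))), L, maxlen)
    counts <- counts + tab
  }
  used <- max(which(colSums(counts) > 0))
  counts <- counts[, seq_len(used), drop = FALSE]
  structure(list(counts = counts, n_runs = sum(counts)),
            class = "run_length_matrix")
}

#' Run-length intensity variability and short-run emphasis
#'
#' Intensity variability (gray-level nonuniformity):
#' `sum_g (sum_r R(g,r))^2 / n_runs`. Short-run emphasis:
#' `sum_{g,r} R(g,r) / r^2 / n_runs`, in (0, 1], equal to 1 when every run
#' has length 1.
#'
#' @param R a `run_length_matrix`.
#' @return Named list with `intensity_variability` and `short_run_emphasis`.
#' @export
va_features <- function(R) {
  stopifnot(inherits(R, "run_length_matrix"))
  if (R$n_runs <= 0) stop("zero runs", call. = FALSE)
  cnt <- R$counts
  r <- seq_len(ncol(cnt))
  list(
    intensity_variability = sum(rowSums(cnt)^2) / R$n_runs,
    short_run_emphasis = sum(sweep(cnt, 2L, r^2, "/")) / R$n_runs
  )
}

#' Build the intensity size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' `Z[level, size]` counts zones by level and voxel count.
#'
#' @param q a `quantized_volume`.
#' @return An object of class `size_zone_matrix`: list with `zones` (data
#'   frame with columns `level`, `size`, `count`), `n_zones`.
#' @export
build_sizezone <- function(q) {
  stopifnot(inherits(q, "quantized_volume"))
  lev <- q$levels
  comp <- connected_components_3d(lev > 0L, labels = lev)
  ids <- comp[comp > 0L]
  sizes <- as.integer(table(ids))
  zone_level <- as.integer(tapply(lev[comp > 0L], ids, function(v) v[1]))
  agg <- stats::aggregate(count ~ level + size,
                          data = data.frame(level = zone_level, size = sizes,
                                            count = 1L),
                          FUN = sum)
  structure(list(zones = agg[order(agg$level, agg$size), ],
                 n_zones = sum(agg$count)),
            class = "size_zone_matrix")
}

#' Size-zone intensity variability and high-intensity-zone emphasis
#'
#' Intensity variability (gray-level nonuniformity of zones):
#' `sum_g (sum_s Z(g,s))^2 / n_zones`. High-intensity-zone emphasis:
#' `sum_{g,s} Z(g,s) g^2 / n_zones`, weighting zones by the square of their
#' gray level.
#'
#' @param Z a `size_zone_matrix`.
#' @return Named list with `intensity_variability` and
#'   `high_intensity_zone_emphasis`.
#' @export
isz_features <- function(Z) {
  stopifnot(inherits(Z, "size_zone_matrix"))
  if (Z$n_zones <= 0) stop("zero zones", call. = FALSE)
  z <- Z$zones
  per_level <- tapply(z$count, z$level, sum)
  list(
    intensity_variability = sum(per_level^2) / Z$n_zones,
    high_intensity_zone_emphasis = sum(z$count * z$level^2) / Z$n_zones
  )
}

#' Parent family of each feature
#'
#' @return Named character vector mapping feature names to their parent
#'   family (`Co`, `VA`, `NID`, `ISZ`, `global`, `conventional`).
#' @export
feature_parents <- function() {
  c(co_entropy = "Co", co_homogeneity = "Co",
    va_intensity_variability = "VA", va_short_run_emphasis = "VA",
    nid_busyness = "NID", nid_contrast = "NID",
    isz_intensity_variability = "ISZ",
    isz_high_intensity_zone_emphasis = "ISZ",
    hist_mean = "global", hist_variance = "global", hist_entropy = "global",
    suv_max = "conventional", suv_average = "conventional",
    metabolic_volume = "conventional")
}

#' Extract the full heterogeneity feature vector of a lesion
#'
#' Quantizes the segmented tumor to `levels` gray levels, builds all four
#' texture-matrix families, and returns the eight heterogeneity parameters
#' together with conventional SUV statistics and global histogram features
#' (mean and variance of the in-mask SUV, Shannon entropy of the gray-level
#' histogram). For a single-voxel mask the co-occurrence features are
#' undefined (no voxel pairs): they are returned as `NA` and the result
#' carries a `no_pairs` attribute.
#'
#' @param volume a [pet_volume()].
#' @param mask a `tumor_mask` or logical array.
#' @param levels gray levels for quantization (default 64).
#' @param glcm_distance co-occurrence offset in voxel steps (default 1).
#' @return A named numeric vector of class `feature_vector`, with attributes
#'   `parents` (family tags) and `no_pairs`.
#' @export
extract_features <- function(volume, mask, levels = 64L, glcm_distance = 1L) {
  q <- quantize(volume, mask, levels = levels)
  conv <- conventional_params(volume, mask)
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  suv <- volume$values[m]
  inlev <- q$levels[q$levels > 0L]
  ph <- tabulate(inlev, nbins = q$L) / length(inlev)
  ph <- ph[ph > 0]

  no_pairs <- FALSE
  co <- tryCatch(build_cooccurrence(q, distance = glcm_distance),
                 error = function(e) {
                   if (grepl("NoPairs", conditionMessage(e))) NULL else stop(e)
                 })
  if (is.null(co)) no_pairs <- TRUE
  nid <- nid_features(q)
  va <- va_features(build_runlength(q))
  isz <- isz_features(build_sizezone(q))

  out <- c(
    co_entropy = if (no_pairs) NA_real_ else co_entropy(co),
    co_homogeneity = if (no_pairs) NA_real_ else co_homogeneity(co),
    va_intensity_variability = va$intensity_variability,
    va_short_run_emphasis = va$short_run_emphasis,
    nid_busyness = nid$busyness,
    nid_contrast = nid$contrast,
    isz_intensity_variability = isz$intensity_variability,
    isz_high_intensity_zone_emphasis = isz$high_intensity_zone_emphasis,
    hist_mean = mean(suv),
    hist_variance = if (length(suv) > 1) stats::var(suv) else 0,
    hist_entropy = -sum(ph * log2(ph)),
    suv_max = conv$suv_max,
    suv_average = conv$suv_average,
    metabolic_volume = conv$metabolic_volume
  )
  structure(out, parents = feature_parents()[names(out)],
            no_pairs = no_pairs, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  df <- data.frame(feature = names(x), parent = attr(x, "parents"),
                   value = as.numeric(x), row.names = NULL)
  print(df, ...)
  invisible(x)
}
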