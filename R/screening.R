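#' Spearman screening of texture parameters against a reference
#'
#' Rank-correlates every feature column against the reference feature
#' (co-occurrence entropy by default, the package's working measure of
#' intratumoral heterogeneity). Ties receive average ranks; P-values use the
#' asymptotic t approximation. Significance is flagged after Bonferroni
#' adjustment over the non-reference features at the stated threshold.
#'
#' @param features data frame of per-subject feature values (rows =
#'   subjects); non-numeric columns are ignored.
#' @param reference name of the reference column (default `"co_entropy"`).
#' @param alpha adjusted significance threshold (default 0.001).
#' @param parents optional named character vector of parent tags per feature;
#'   defaults to [feature_parents()] for known names, `NA` otherwise.
#' @return A data frame of class `correlation_table` with columns `feature`,
#'   `parent`, `rho`, `p`, `p_adjusted`, `significant`, `sign`. Constant
#'   columns get `NA` rho with a warning.
#' @export
spearman_screen <- function(features, reference = "co_entropy",
                            alpha = 0.001, parents = NULL) {
  stopifnot(is.data.frame(features))
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  if (!reference %in% names(features))
    stop("reference column '", reference, "' not found", call. = FALSE)
  n <- nrow(features)
  if (n < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (is.null(parents)) parents <- feature_parents()
  ref <- features[[reference]]

  res <- lapply(names(features), function(nm) {
    x <- features[[nm]]
    ok <- stats::complete.cases(x, ref)
    if (length(unique(x[ok])) < 2L || length(unique(ref[ok])) < 2L) {
      warning("feature '", nm, "' is constant; rho undefined", call. = FALSE)
      return(data.frame(feature = nm, rho = NA_real_, p = NA_real_))
    }
    rho <- stats::cor(x[ok], ref[ok], method = "spearman")
    m <- sum(ok)
    p <- if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((m - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), df = m - 2)
    }
    data.frame(feature = nm, rho = rho, p = p)
  })
  out <- do.call(rbind, res)
  out$parent <- unname(parents[out$feature])
  is_ref <- out$feature == reference
  out$p_adjusted <- NA_real_
  out$p_adjusted[!is_ref] <- stats::p.adjust(out$p[!is_ref],
                                             method = "bonferroni")
  out$p_adjusted[is_ref] <- 0
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  out$sign <- ifelse(is.na(out$rho), NA_character_,
                     ifelse(out$rho >= 0, "positive", "negative"))
  out <- out[c("feature", "parent", "rho", "p", "p_adjusted",
               "significant", "sign")]
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  attr(out, "reference") <- reference
  attr(out, "family_size") <- sum(!is_ref)
  out
}

#' Select the eight-parameter heterogeneity panel
#'
#' From a screening table, selects four significantly positively correlated
#' and four significantly negatively correlated features, each sign group
#' drawing from distinct parent families. Within a parent the feature with
#' the largest absolute rho wins; parents are then ranked by that winner's
#' absolute rho, ties broken lexicographically by feature name. The
#' reference feature itself (rho = 1) is eligible on the positive side.
#'
#' @param corr a `correlation_table` from [spearman_screen()].
#' @param n_per_sign panel size per correlation sign (default 4).
#' @return Character vector of 2 * `n_per_sign` feature names (positive
#'   group first).
#' @export
select_panel <- function(corr, n_per_sign = 4L) {
  stopifnot(inherits(corr, "correlation_table"))
  cand <- corr[corr$significant & !is.na(corr$rho) & !is.na(corr$parent), ]
  pick_side <- function(side) {
    sub <- cand[cand$sign == side, ]
    if (nrow(sub) == 0L) return(character(0))
    sub <- sub[order(-abs(sub$rho), sub$feature), ]
    sub <- sub[!duplicated(sub$parent), ]   # per-parent winner
    utils::head(sub$feature, n_per_sign)
  }
  pos <- pick_side("positive")
  neg <- pick_side("negative")
  if (length(pos) < n_per_sign || length(neg) < n_per_sign)
    stop("PanelInfeasible: need ", n_per_sign, " significant features from ",
         "distinct parents on each sign; found ", length(pos),
         " positive and ", length(neg), " negative", call. = FALSE)
  c(pos, neg)
}
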