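#' Per-probe delta-beta between two gestational groups
#'
#' Delta-beta is the difference of pairwise-complete group-mean
#' beta-values, later group minus earlier group (`g2 - g1`).
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param g1,g2 Group labels; `g2` is the later group.
#' @return Named numeric vector of delta-beta per probe; `NA` where a
#'   group has no non-missing values.
#' @export
delta_beta <- function(beta, metadata, g1, g2) {
  grp <- metadata$group[match(colnames(beta), metadata$sample_id)]
  if (!any(grp == g1) || !any(grp == g2)) stop("both groups must be present")
  m1 <- rowMeans(beta[, grp == g1, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(beta[, grp == g2, drop = FALSE], na.rm = TRUE)
  d <- m2 - m1
  d[is.nan(m1) | is.nan(m2)] <- NA_real_
  d
}

# Vectorized row-wise two-sample t-test. Zero variance in both groups:
# equal means -> t = 0, p = 1; unequal means -> p collapses to the
# smallest representable positive number.
row_t_test <- function(x1, x2, method = c("pooled_t", "welch_t")) {
  method <- match.arg(method)
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  if (method == "pooled_t") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0 & !is.na(se)
  t[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- .Machine$double.xmin
  t[degenerate & m1 != m2] <- sign(m2 - m1)[degenerate & m1 != m2] * Inf
  bad <- n1 < 2 | n2 < 2
  t[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  list(t = t, df = df, p = p, mean1 = m1, mean2 = m2)
}

#' Per-probe two-sample t-tests between groups
#'
#' Two-sided two-sample t-test per probe row, pooled-variance by default.
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param g1,g2 Group labels.
#' @param method `"pooled_t"` (default) or `"welch_t"`.
#' @return Data frame with probe_id, t, df, p.
#' @export
probe_test <- function(beta, metadata, g1, g2,
                       method = c("pooled_t", "welch_t")) {
  method <- match.arg(method)
  grp <- metadata$group[match(colnames(beta), metadata$sample_id)]
  res <- row_t_test(beta[, grp == g1, drop = FALSE],
                    beta[, grp == g2, drop = FALSE], method)
  data.frame(probe_id = rownames(beta), t = res$t, df = res$df, p = res$p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `adj_p(i) = min over j >= rank(i) of (m / j) * p(j)`, capped at 1.
#' Missing entries are excluded from `m` and propagated as missing.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Full differential-methylation comparison between two groups
#'
#' Combines [delta_beta()], [probe_test()] and [adjust_bh()] into a
#' per-probe result table with direction relative to the later group.
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param g1,g2 Group labels; delta-beta and direction refer to `g2`.
#' @param method Per-probe test, see [probe_test()].
#' @return `DifferentialResult` data frame: probe_id, mean1, mean2,
#'   delta_beta, t, df, p, adj_p.
#' @export
differential_comparison <- function(beta, metadata, g1, g2,
                                    method = c("pooled_t", "welch_t")) {
  method <- match.arg(method)
  grp <- metadata$group[match(colnames(beta), metadata$sample_id)]
  res <- row_t_test(beta[, grp == g1, drop = FALSE],
                    beta[, grp == g2, drop = FALSE], method)
  data.frame(probe_id = rownames(beta),
             mean1 = res$mean1, mean2 = res$mean2,
             delta_beta = res$mean2 - res$mean1,
             t = res$t, df = res$df, p = res$p,
             adj_p = adjust_bh(res$p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify differentially methylated probes
#'
#' A probe is hypermethylated (in the later group) when
#' `delta_beta >= delta_threshold` and `adj_p < p_threshold`;
#' hypomethylated when `delta_beta <= -delta_threshold` with the same
#' significance condition. The sets are disjoint by construction.
#'
#' @param result A `DifferentialResult` from [differential_comparison()].
#' @param delta_threshold Absolute delta-beta threshold (default 0.2;
#'   the inclusive `>=` convention is used).
#' @param p_threshold Adjusted-p threshold (default 0.05).
#' @return List with `hyper`/`hypo` probe-id vectors and `n_hyper`,
#'   `n_hypo` counts.
#' @export
classify_differential <- function(result, delta_threshold = 0.2,
                                  p_threshold = 0.05) {
  stopifnot(delta_threshold > 0, delta_threshold < 1,
            p_threshold > 0, p_threshold < 1)
  sig <- !is.na(result$adj_p) & result$adj_p < p_threshold &
    !is.na(result$delta_beta)
  hyper <- result$probe_id[sig & result$delta_beta >= delta_threshold]
  hypo <- result$probe_id[sig & result$delta_beta <= -delta_threshold]
  list(hyper = hyper, hypo = hypo,
       n_hyper = length(hyper), n_hypo = length(hypo))
}

#' Screen for fluctuating methylation patterns
#'
#' Flags probes with similar methylation in first and third trimesters
#' but deviating methylation in second trimester:
#' `|first - third| < similarity` and both `|second - first|` and
#' `|second - third|` at or above `threshold`.
#'
#' @param means_first,means_second,means_third Aligned per-probe group
#'   mean vectors (named by probe id).
#' @param threshold Deviation threshold for the second trimester
#'   (default 0.2).
#' @param similarity First-vs-third similarity bound (default =
#'   `threshold`).
#' @return Character vector of flagged probe ids.
#' @export
detect_fluctuating <- function(means_first, means_second, means_third,
                               threshold = 0.2, similarity = threshold) {
  stopifnot(length(means_first) == length(means_second),
            length(means_second) == length(means_third))
  flag <- abs(means_first - means_third) < similarity &
    abs(means_second - means_first) >= threshold &
    abs(means_second - means_third) >= threshold
  flag[is.na(flag)] <- FALSE
  ids <- names(means_first)
  if (is.null(ids)) ids <- as.character(seq_along(means_first))
  ids[flag]
}

#' Early-gestation transition comparison (week 8 vs week 12)
#'
#' Applies the pairwise differential machinery to the week-8 and week-12
#' subsets of the first trimester; delta-beta and direction are reported
#' relative to week 12 (positive = hypermethylated at 12 weeks).
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata with `gestational_week`.
#' @param weeks Two gestational weeks to compare; default `c(8, 12)`.
#' @param method Per-probe test, see [probe_test()].
#' @return `DifferentialResult` data frame (delta relative to the later
#'   week).
#' @export
transition_comparison <- function(beta, metadata, weeks = c(8, 12),
                                  method = c("pooled_t", "welch_t")) {
  if (!"gestational_week" %in% names(metadata) ||
      all(is.na(metadata$gestational_week))) {
    stop("gestational week labels are required for the transition comparison")
  }
  weeks <- sort(weeks)
  md <- metadata[metadata$gestational_week %in% weeks, , drop = FALSE]
  if (!all(weeks %in% md$gestational_week)) {
    stop("samples missing for week ", paste(setdiff(weeks,
         md$gestational_week), collapse = ", "))
  }
  md$group <- ifelse(md$gestational_week == weeks[1], "first", "third")
  sub <- beta[, colnames(beta) %in% md$sample_id, drop = FALSE]
  res <- differential_comparison(sub, md, "first", "third", method)
  attr(res, "weeks") <- weeks
  res
}
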