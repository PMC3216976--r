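#' Per-sample Methylation Index
#'
#' The Methylation Index (MI) of a sample is the mean of all analysable
#' (non-missing) beta-values in that sample's column: a global summary of
#' promoter methylation level.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @return Named numeric vector of MI per sample; `NA` (with a warning)
#'   for an all-missing column.
#' @export
methylation_index <- function(beta) {
  if (nrow(beta) < 1L) stop("beta matrix has no probes")
  mi <- colMeans(beta, na.rm = TRUE)
  empty <- colSums(!is.na(beta)) == 0L
  if (any(empty)) {
    warning("all-missing columns: ",
            paste(colnames(beta)[empty], collapse = ", "))
    mi[empty] <- NA_real_
  }
  mi
}

#' Pairwise group comparisons of the Methylation Index
#'
#' Two-sample Student's t-test (pooled variance by default, Welch by
#' flag), two-sided, for every pair of gestational groups.
#'
#' @param mi Named per-sample MI vector (names are sample ids).
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param var_equal Pooled-variance t-test if `TRUE` (default); Welch
#'   otherwise.
#' @return Data frame with one row per group pair: group means/medians,
#'   t, df, p.
#' @export
compare_mi <- function(mi, metadata, var_equal = TRUE) {
  grp <- metadata$group[match(names(mi), metadata$sample_id)]
  lv <- intersect(c("first", "second", "third"), unique(grp))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- mi[grp == pr[1] & !is.na(mi)]
    y <- mi[grp == pr[2] & !is.na(mi)]
    if (length(x) < 2L || length(y) < 2L) {
      warning("group pair ", pr[1], "/", pr[2],
              " skipped: fewer than 2 samples")
      return(NULL)
    }
    tt <- row_t_test(matrix(x, nrow = 1), matrix(y, nrow = 1),
                     if (var_equal) "pooled_t" else "welch_t")
    data.frame(group1 = pr[1], group2 = pr[2],
               mean1 = mean(x), mean2 = mean(y),
               median1 = stats::median(x), median2 = stats::median(y),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Beta-band composition per gestational group
#'
#' Classifies each probe by its per-group mean beta into low
#' `[0, c1)`, intermediate `[c1, c2]` and high `(c2, 1]` bands and
#' reports the fraction of probes per band per group. Band boundaries
#' belong to the intermediate band.
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param cuts Two increasing thresholds in (0, 1); default `c(0.2, 0.6)`.
#' @return Matrix of band fractions (groups x low/intermediate/high),
#'   rows summing to 1.
#' @export
band_proportions <- function(beta, metadata, cuts = c(0.2, 0.6)) {
  stopifnot(length(cuts) == 2L, cuts[1] < cuts[2],
            cuts[1] > 0, cuts[2] < 1)
  gm <- group_mean_beta(beta, metadata)
  t(apply(gm, 2, function(m) {
    m <- m[!is.na(m)]
    c(low = mean(m < cuts[1]),
      intermediate = mean(m >= cuts[1] & m <= cuts[2]),
      high = mean(m > cuts[2]))
  }))
}

#' Per-probe group-mean beta
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @return Probes x groups matrix of pairwise-complete group means.
#' @export
group_mean_beta <- function(beta, metadata) {
  grp <- metadata$group[match(colnames(beta), metadata$sample_id)]
  lv <- intersect(c("first", "second", "third"), unique(grp))
  out <- vapply(lv, function(g) {
    rowMeans(beta[, grp == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(beta)))
  matrix(out, nrow = nrow(beta),
         dimnames = list(rownames(beta), lv))
}
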