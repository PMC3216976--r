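#' Per-probe, per-group sample variance
#'
#' Unbiased sample variance (divisor n - 1) of beta-values within each
#' gestational group, pairwise-complete; probes with fewer than two
#' non-missing values in a group get a missing variance.
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @return Probes x groups matrix of variances.
#' @export
probe_variance <- function(beta, metadata) {
  grp <- metadata$group[match(colnames(beta), metadata$sample_id)]
  lv <- intersect(c("first", "second", "third"), unique(grp))
  out <- vapply(lv, function(g) {
    x <- beta[, grp == g, drop = FALSE]
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
    v[n < 2] <- NA_real_
    v
  }, numeric(nrow(beta)))
  matrix(out, nrow = nrow(beta),
         dimnames = list(rownames(beta), lv))
}

#' Classify probes by variability level
#'
#' Three-way classification of per-probe variances: low (`< low_cut`),
#' intermediate, high (`> high_cut`). Defaults follow the operational
#' cutoffs s2 > 0.02 for "highly variable" and s2 < 0.009 for "very
#' little variation".
#'
#' @param s2 Numeric vector or probes x groups matrix of variances.
#' @param high_cut High-variability threshold (default 0.02).
#' @param low_cut Low-variability threshold (default 0.009).
#' @return For a vector: list with `class` (character vector) and
#'   `counts`; for a matrix: list with `class` matrix and per-group
#'   `counts` matrix.
#' @export
classify_variability <- function(s2, high_cut = 0.02, low_cut = 0.009) {
  stopifnot(low_cut > 0, high_cut > low_cut)
  classify <- function(v) {
    cl <- ifelse(v > high_cut, "high",
                 ifelse(v < low_cut, "low", "intermediate"))
    cl
  }
  lev <- c("low", "intermediate", "high")
  if (is.matrix(s2)) {
    cls <- apply(s2, 2, classify)
    dimnames(cls) <- dimnames(s2)
    counts <- apply(cls, 2, function(x) table(factor(x, levels = lev)))
    list(class = cls, counts = counts)
  } else {
    cls <- classify(s2)
    tab <- table(factor(cls, levels = lev))
    list(class = cls, counts = stats::setNames(as.integer(tab), lev))
  }
}

#' Chi-square comparison of highly-variable probe counts
#'
#' Pearson chi-square (no continuity correction, df = 1) on the 2x2
#' table `[[k1, n - k1], [k2, n - k2]]` comparing the proportions of
#' highly variable probes between two groups over the same probe
#' universe.
#'
#' @param k1,k2 Highly-variable probe counts in the two groups.
#' @param n Total analysable probes per group.
#' @return List with `chisq`, `df`, `p`.
#' @export
compare_variable_counts <- function(k1, k2, n) {
  if (n <= 0) stop("probe universe size must be positive")
  stopifnot(k1 >= 0, k2 >= 0, k1 <= n, k2 <= n)
  tab <- matrix(c(k1, n - k1, k2, n - k2), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - e)^2 / e)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Quadrant partition of first- vs third-trimester variability
#'
#' Partitions probes by whether their variance exceeds `cut` in first
#' and/or third trimester: A = both, B = first only, C = third only,
#' neither otherwise. Probes with a missing variance in either group are
#' assigned to neither (with a warning flag in the output).
#'
#' @param s2_first,s2_third Aligned per-probe variance vectors (named by
#'   probe id).
#' @param cut Variability threshold (default 0.02).
#' @return List with `counts` (A/B/C/neither) and `sets` of probe ids,
#'   plus `n_missing`.
#' @export
quadrant_partition <- function(s2_first, s2_third, cut = 0.02) {
  stopifnot(length(s2_first) == length(s2_third))
  ids <- names(s2_first)
  if (is.null(ids)) ids <- as.character(seq_along(s2_first))
  miss <- is.na(s2_first) | is.na(s2_third)
  if (any(miss)) warning(sum(miss), " probes with missing variance ",
                         "assigned to 'neither'")
  hi1 <- !miss & s2_first > cut
  hi3 <- !miss & s2_third > cut
  sets <- list(A = ids[hi1 & hi3], B = ids[hi1 & !hi3],
               C = ids[!hi1 & hi3], neither = ids[!hi1 & !hi3])
  list(counts = vapply(sets, length, integer(1)), sets = sets,
       n_missing = sum(miss))
}

#' Three-set Venn partition of highly-variable probe sets
#'
#' Standard 7-region inclusion-exclusion partition of the high-variance
#' probe sets from the three gestational groups.
#'
#' @param first,second,third Character vectors of probe ids.
#' @return Named integer vector over the 7 regions
#'   (`first_only`, ..., `all_three`); region counts sum to the size of
#'   the union.
#' @export
venn_partition <- function(first, second, third) {
  u <- union(union(first, second), third)
  in1 <- u %in% first; in2 <- u %in% second; in3 <- u %in% third
  c(first_only = sum(in1 & !in2 & !in3),
    second_only = sum(!in1 & in2 & !in3),
    third_only = sum(!in1 & !in2 & in3),
    first_second = sum(in1 & in2 & !in3),
    first_third = sum(in1 & !in2 & in3),
    second_third = sum(!in1 & in2 & in3),
    all_three = sum(in1 & in2 & in3))
}

#' Cross-tabulate methylation band against variability class
#'
#' Per gestational group, counts probes in each (methylation band x
#' variability class) cell, with band membership from the per-group mean
#' beta and variability class from [classify_variability()]. Marginals
#' match the per-group variability counts.
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata.
#' @param s2 Probes x groups variance matrix from [probe_variance()].
#' @param bands Band cuts, default `c(0.2, 0.6)`.
#' @param high_cut,low_cut Variability cuts, see [classify_variability()].
#' @return Named list (per group) of 3x3 contingency tables
#'   (band x class).
#' @export
variance_by_level <- function(beta, metadata, s2, bands = c(0.2, 0.6),
                              high_cut = 0.02, low_cut = 0.009) {
  gm <- group_mean_beta(beta, metadata)
  cls <- classify_variability(s2, high_cut, low_cut)$class
  out <- list()
  for (g in colnames(s2)) {
    m <- gm[, g]
    band <- ifelse(m < bands[1], "low",
                   ifelse(m <= bands[2], "intermediate", "high"))
    out[[g]] <- table(
      band = factor(band, levels = c("low", "intermediate", "high")),
      class = factor(cls[, g], levels = c("low", "intermediate", "high")))
  }
  out
}
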