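#' Clean an EpiTYPER validation table by three ordered rules
#'
#' Failed measurements are `NA` cells. The rules are applied strictly in
#' order, each on the table as left by the previous rule:
#' \enumerate{
#'   \item remove samples that failed across 100% of CpG sites;
#'   \item remove CpG sites that failed across more than 40% of the
#'     remaining samples;
#'   \item remove samples that failed on more than 70% of the remaining
#'     CpG sites.
#' }
#' Both percentage bounds are strict (exactly 40% / 70% is retained).
#'
#' @param table Numeric sites x samples matrix of methylated fractions
#'   with `NA` marking failures.
#' @param site_fail_cut Rule-2 failure fraction bound (default 0.4).
#' @param sample_fail_cut Rule-3 failure fraction bound (default 0.7).
#' @return List with `cleaned` (possibly empty matrix) and `report`
#'   (removed ids per rule).
#' @export
clean_validation <- function(table, site_fail_cut = 0.4,
                             sample_fail_cut = 0.7) {
  if (!length(table)) stop("empty validation table")
  tab <- as.matrix(table)
  report <- list(rule1_samples = character(0), rule2_sites = character(0),
                 rule3_samples = character(0))

  # rule 1: all-fail samples
  allfail <- colMeans(is.na(tab)) == 1
  report$rule1_samples <- colnames(tab)[allfail]
  tab <- tab[, !allfail, drop = FALSE]

  # rule 2: sites failing in > 40% of remaining samples
  if (ncol(tab) > 0) {
    bad_site <- rowMeans(is.na(tab)) > site_fail_cut
    report$rule2_sites <- rownames(tab)[bad_site]
    tab <- tab[!bad_site, , drop = FALSE]
  }

  # rule 3: samples failing on > 70% of remaining sites
  if (nrow(tab) > 0 && ncol(tab) > 0) {
    bad_sample <- colMeans(is.na(tab)) > sample_fail_cut
    report$rule3_samples <- colnames(tab)[bad_sample]
    tab <- tab[, !bad_sample, drop = FALSE]
  }

  if (!nrow(tab) || !ncol(tab)) {
    warning("cleaning removed the entire table")
  }
  list(cleaned = tab, report = report)
}

#' Cross-platform agreement (squared Pearson correlation)
#'
#' r2 between matched array beta-values and validation methylated
#' fractions over the (site, sample) pairs present in both,
#' pairwise-complete.
#'
#' @param array_beta Numeric vector or sites x samples matrix of array
#'   beta-values.
#' @param validation Cleaned validation matrix (or vector) aligned with
#'   `array_beta`.
#' @return List with `r2`, `n` (matched pairs); `r2` is `NA` with a
#'   reason when either vector is constant.
#' @export
cross_platform_r2 <- function(array_beta, validation) {
  x <- as.numeric(array_beta)
  y <- as.numeric(validation)
  if (length(x) != length(y)) stop("inputs must be aligned")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("need at least 3 matched (site, sample) pairs")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r2 = NA_real_, n = sum(ok),
                reason = "constant vector; correlation undefined"))
  }
  list(r2 = stats::cor(x, y)^2, n = sum(ok))
}
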