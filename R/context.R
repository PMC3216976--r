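#' CGI / non-CGI background proportions of a probe universe
#'
#' @param annotation Probe annotation with `probe_id` and `cgi`
#'   (`"CGI"`/`"non-CGI"`).
#' @param universe Character vector of probe ids defining the analysable
#'   background.
#' @return Named numeric vector `c(cgi = ..., noncgi = ...)`, summing
#'   to 1.
#' @export
background_proportions <- function(annotation, universe) {
  if (!length(universe)) stop("empty probe universe")
  cg <- annotation$cgi[match(universe, annotation$probe_id)]
  if (anyNA(cg)) stop("unannotated probes in universe")
  p <- mean(cg == "CGI")
  c(cgi = p, noncgi = 1 - p)
}

#' CpG-island context enrichment of a probe subset
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the observed
#' (CGI, non-CGI) counts in a subset against the expected counts under
#' the array background proportions; direction is the sign of
#' observed - expected for the CGI cell.
#'
#' @param subset Character vector of probe ids (within the annotated
#'   universe).
#' @param annotation Probe annotation.
#' @param background Background proportions from
#'   [background_proportions()].
#' @return List with `size`, `observed_cgi`, `expected_cgi`, `chisq`,
#'   `df`, `p`, `direction` (`"CGI-enriched"`, `"non-CGI-enriched"` or
#'   `"neither"`), and `low_count` flag (any expected cell < 5).
#' @export
cgi_enrichment <- function(subset, annotation, background) {
  cg <- annotation$cgi[match(subset, annotation$probe_id)]
  if (anyNA(cg)) stop("subset contains unannotated probes")
  n <- length(subset)
  obs <- c(cgi = sum(cg == "CGI"), noncgi = sum(cg == "non-CGI"))
  exp <- background * n
  chisq <- sum((obs - exp)^2 / exp)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  direction <- if (obs[["cgi"]] > exp[["cgi"]]) "CGI-enriched"
    else if (obs[["cgi"]] < exp[["cgi"]]) "non-CGI-enriched"
    else "neither"
  list(size = n, observed_cgi = unname(obs[["cgi"]]),
       expected_cgi = unname(exp[["cgi"]]), chisq = chisq, df = 1L, p = p,
       direction = direction, low_count = any(exp < 5))
}

#' Association between TSS distance and a per-probe statistic
#'
#' Spearman rank correlation between the absolute TSS distance and a
#' supplied per-probe statistic (for example |delta-beta| or s2), with a
#' seeded permutation p-value.
#'
#' @param subset Character vector of probe ids.
#' @param annotation Probe annotation with `tss_distance`.
#' @param statistic_values Named numeric vector of the statistic
#'   (names = probe ids) or a vector aligned with `subset`.
#' @param n_perm Number of permutations for the p-value (default 10000).
#' @param seed RNG seed for the permutations.
#' @return List with `rho`, `p`, `n`; `rho` is `NA` (with reason) when
#'   either input is constant.
#' @export
tss_distance_association <- function(subset, annotation, statistic_values,
                                     n_perm = 10000L, seed = 1L) {
  d <- abs(annotation$tss_distance[match(subset, annotation$probe_id)])
  s <- if (!is.null(names(statistic_values))) {
    statistic_values[subset]
  } else statistic_values
  ok <- !is.na(d) & !is.na(s)
  d <- d[ok]; s <- s[ok]
  if (length(unique(d)) < 2L || length(unique(s)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = length(d),
                reason = "constant input; correlation undefined"))
  }
  rho <- stats::cor(d, s, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm, stats::cor(d, sample(s), method = "spearman"))
  p <- (sum(abs(perm) >= abs(rho)) + 1) / (n_perm + 1)
  list(rho = rho, p = p, n = length(d))
}
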