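#' Construct a signal-pair table
#'
#' Container for Infinium-style two-channel intensities: `A` holds the
#' unmethylated-allele intensities, `B` the methylated-allele intensities,
#' and `detection_p` the per-(probe, sample) detection p-values. All three
#' are probes x samples matrices sharing dimnames.
#'
#' @param A Numeric matrix of unmethylated intensities (probes x samples).
#' @param B Numeric matrix of methylated intensities, same dimensions.
#' @param detection_p Numeric matrix of detection p-values in \[0, 1\],
#'   same dimensions. Defaults to all-zero (every call detected).
#' @return An object of class `signal_pair`.
#' @export
signal_pair <- function(A, B, detection_p = NULL) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) {
    stop("signal matrices A and B must have identical dimensions")
  }
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("signal matrices need probe rownames and sample colnames")
  }
  if (anyNA(A) || anyNA(B) || any(!is.finite(A)) || any(!is.finite(B))) {
    stop("signal intensities must be finite and non-missing")
  }
  if (is.null(detection_p)) {
    detection_p <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  }
  detection_p <- as.matrix(detection_p)
  if (!identical(dim(detection_p), dim(A))) {
    stop("detection_p must match the signal matrix dimensions")
  }
  if (any(detection_p < 0 | detection_p > 1, na.rm = TRUE)) {
    stop("detection p-values must lie in [0, 1]")
  }
  dimnames(B) <- dimnames(A)
  dimnames(detection_p) <- dimnames(A)
  structure(list(A = A, B = B, detection_p = detection_p),
            class = "signal_pair")
}

#' @export
print.signal_pair <- function(x, ...) {
  cat("signal_pair:", nrow(x$A), "probes x", ncol(x$A), "samples\n")
  invisible(x)
}

#' Compute beta-values from a signal-pair table
#'
#' beta = max(B, 0) / (max(A, 0) + max(B, 0)), where B is the methylated
#' and A the unmethylated channel. Negative intensities are clamped to zero
#' before the ratio; a zero denominator yields a missing beta.
#'
#' @param signals A [signal_pair()] object.
#' @return Numeric probes x samples matrix of beta-values in \[0, 1\],
#'   `NA` where both clamped channels are zero.
#' @export
compute_beta <- function(signals) {
  stopifnot(inherits(signals, "signal_pair"))
  if (nrow(signals$A) == 0L) stop("empty signal table")
  A <- pmax(signals$A, 0)
  B <- pmax(signals$B, 0)
  denom <- A + B
  beta <- B / denom
  beta[denom == 0] <- NA_real_
  beta
}

#' Mask or drop probes by detection p-value
#'
#' Cells whose detection p-value is at or above `alpha` are treated as
#' failed measurements. Under `policy = "drop_any"` (default) a probe with
#' any failing cell is removed entirely, which yields a single shared
#' analysable probe set across all samples; `"mask"` sets failing cells to
#' `NA`; `"drop_frac"` removes probes failing in more than `frac` of
#' samples (and masks the remaining failing cells).
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param detection_p Matrix of detection p-values aligned with `beta`.
#' @param alpha Failure threshold; cells with p >= alpha fail. Default 0.05.
#' @param policy One of `"drop_any"`, `"mask"`, `"drop_frac"`.
#' @param frac Failure fraction for `"drop_frac"`.
#' @return Filtered beta matrix.
#' @export
filter_detection <- function(beta, detection_p, alpha = 0.05,
                             policy = c("drop_any", "mask", "drop_frac"),
                             frac = 0.05) {
  policy <- match.arg(policy)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must lie in (0, 1]")
  if (!identical(dim(beta), dim(detection_p)) ||
      !identical(rownames(beta), rownames(detection_p)) ||
      !identical(colnames(beta), colnames(detection_p))) {
    stop("beta and detection_p matrices are not aligned")
  }
  fail <- detection_p >= alpha
  fail[is.na(fail)] <- TRUE
  if (policy == "drop_any") {
    keep <- rowSums(fail) == 0L
    beta[keep, , drop = FALSE]
  } else if (policy == "mask") {
    beta[fail] <- NA_real_
    beta
  } else {
    keep <- rowMeans(fail) <= frac
    beta <- beta[keep, , drop = FALSE]
    beta[fail[keep, , drop = FALSE]] <- NA_real_
    beta
  }
}

#' Remove sex-chromosome probes
#'
#' Drops probes annotated to chromosome X or Y to eliminate sex-specific
#' methylation differences; autosomal row order is preserved.
#'
#' @param beta Beta-value matrix.
#' @param annotation Probe annotation data frame with columns `probe_id`
#'   and `chromosome` (autosome names, `"X"` or `"Y"`).
#' @return Beta matrix restricted to autosomal probes.
#' @export
drop_sex_chromosomes <- function(beta, annotation) {
  chr <- annotation$chromosome[match(rownames(beta), annotation$probe_id)]
  if (anyNA(chr)) {
    stop("unannotated probes: ",
         paste(utils::head(rownames(beta)[is.na(chr)], 5), collapse = ", "))
  }
  keep <- !(chr %in% c("X", "Y", "chrX", "chrY"))
  if (!any(keep)) warning("all probes are sex-linked; returning empty matrix")
  beta[keep, , drop = FALSE]
}

#' Shift-and-scale normalization of signal channels
#'
#' Per sample and channel, applies the order-preserving affine map that
#' sends the channel's 5th percentile (background) to the reference
#' channel's 5th percentile and the channel mean to the reference channel
#' mean. The reference is either a named sample or the pooled average of
#' the per-sample background and level across samples. After
#' normalization all samples share each channel's mean.
#'
#' @param signals A [signal_pair()] object with at least two samples.
#' @param reference `"pooled"` (default) or a sample id.
#' @return A normalized [signal_pair()]; detection p-values pass through.
#' @export
normalize_ssn <- function(signals, reference = "pooled") {
  stopifnot(inherits(signals, "signal_pair"))
  if (ncol(signals$A) < 2L) stop("normalization needs at least two samples")
  norm_channel <- function(X) {
    q05 <- apply(X, 2, stats::quantile, probs = 0.05, names = FALSE)
    lev <- colMeans(X) - q05
    if (identical(reference, "pooled")) {
      ref_q <- mean(q05); ref_lev <- mean(lev)
    } else {
      j <- match(reference, colnames(X))
      if (is.na(j)) stop("reference sample not found: ", reference)
      ref_q <- q05[j]; ref_lev <- lev[j]
    }
    out <- X
    for (j in seq_len(ncol(X))) {
      if (lev[j] <= 0) {
        warning("constant signal channel in sample ", colnames(X)[j],
                "; scaling skipped")
        out[, j] <- X[, j] - q05[j] + ref_q
      } else {
        out[, j] <- (X[, j] - q05[j]) * (ref_lev / lev[j]) + ref_q
      }
    }
    out
  }
  signal_pair(norm_channel(signals$A), norm_channel(signals$B),
              signals$detection_p)
}

#' Group-protected batch correction on the logit scale
#'
#' Per probe, beta-values are clipped to \[eps, 1 - eps\], logit
#' transformed, and batch offsets are estimated as batch means of the
#' residuals left after removing gestational-group means; the offsets are
#' subtracted and the values back-transformed. Because group means are
#' removed first, trimester contrasts are preserved when batches are
#' balanced across groups. Refuses to run when batch is perfectly
#' confounded with group (the correction would erase the biology).
#'
#' @param beta Beta-value matrix.
#' @param metadata Sample metadata with columns `sample_id`, `group`,
#'   `batch`.
#' @param eps Clipping bound for the logit transform. Default 1e-6.
#' @return Batch-corrected beta matrix.
#' @export
correct_batch <- function(beta, metadata, eps = 1e-6) {
  md <- metadata[match(colnames(beta), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata missing for some samples")
  batch <- as.character(md$batch)
  group <- as.character(md$group)
  if (length(unique(batch)) < 2L) return(beta)
  tab <- table(group, batch)
  if (all(colSums(tab > 0) == 1L)) {
    stop("batch is perfectly confounded with gestational group; ",
         "refusing to correct (it would erase group differences)")
  }
  L <- stats::qlogis(pmin(pmax(beta, eps), 1 - eps))
  resid <- L
  for (g in unique(group)) {
    cols <- which(group == g)
    gm <- rowMeans(L[, cols, drop = FALSE], na.rm = TRUE)
    resid[, cols] <- L[, cols, drop = FALSE] - gm
  }
  for (b in unique(batch)) {
    cols <- which(batch == b)
    off <- rowMeans(resid[, cols, drop = FALSE], na.rm = TRUE)
    off[is.na(off)] <- 0
    L[, cols] <- L[, cols, drop = FALSE] - off
  }
  stats::plogis(L)
}

#' Read a beta-value (or detection-p) matrix from TSV/CSV
#'
#' First column is the probe id; remaining columns are samples; missing
#' values are encoded as `NA`. The delimiter is inferred from the file
#' extension (`.csv` comma, otherwise tab) unless given.
#'
#' @param path File path.
#' @param sep Field delimiter; default inferred from extension.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a matrix with an id first column
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_name Header for the id column.
#' @export
write_id_matrix <- function(m, path, id_name = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Expects columns `probe_id`, `gene_symbol`, `chromosome`, `cgi`
#' (`"CGI"`/`"non-CGI"`), `tss_distance` (signed bp; negative = upstream).
#'
#' @param path TSV path.
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `group` (first/second/third),
#' `gestational_week`, `batch`. Checks week/group consistency where both
#' are present (first 8-12, second 17-24, third 34-41 weeks).
#'
#' @param path TSV path.
#' @return Metadata data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  stopifnot(all(c("sample_id", "group") %in% names(md)))
  if (!all(md$group %in% c("first", "second", "third"))) {
    stop("group must be one of first/second/third")
  }
  if ("gestational_week" %in% names(md)) {
    rng <- list(first = c(8, 12), second = c(17, 24), third = c(34, 41))
    for (i in seq_len(nrow(md))) {
      w <- md$gestational_week[i]
      if (is.na(w)) next
      r <- rng[[md$group[i]]]
      if (w < r[1] || w > r[2]) {
        stop("gestational week ", w, " inconsistent with group ",
             md$group[i], " for sample ", md$sample_id[i])
      }
    }
  }
  invisible(md)
}
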