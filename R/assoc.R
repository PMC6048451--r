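#' Do external factors explain the clustering?
#'
#' Logistic regression of cluster membership on binary predictors
#' (mutation or alteration flags): either one joint model with all
#' predictors (`joint = TRUE`, e.g. BRAF and KRAS status together) or one
#' single-predictor model per flag. Fitting is iteratively reweighted
#' least squares (via `stats::glm`) with up to 100 iterations at tolerance
#' 1e-10; complete separation is detected as a diverging coefficient
#' (|estimate| > 15) and flagged rather than crashed on.
#'
#' @param cluster_labels vector with exactly 2 cluster levels, each with
#'   >= 2 samples; the second level is modelled as the outcome.
#' @param predictors data.frame (or vector) of binary predictors, one row
#'   per sample.
#' @param joint fit all predictors jointly (default) or one at a time.
#' @return data.frame with predictor, estimate (log-odds), std_error,
#'   z_value, p_value, fdr_adjusted_p, separation (logical).
#' @export
cluster_association <- function(cluster_labels, predictors, joint = TRUE) {
  f <- factor(cluster_labels)
  if (nlevels(f) != 2L) stop("exactly 2 cluster levels required")
  if (any(table(f) < 2L)) stop("each cluster needs >= 2 samples")
  y <- as.integer(f) - 1L
  if (!is.data.frame(predictors)) {
    predictors <- data.frame(predictor = predictors)
  }
  stopifnot(nrow(predictors) == length(y))
  ctrl <- stats::glm.control(maxit = 100, epsilon = 1e-10)
  fit_one <- function(df) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                       family = stats::binomial(),
                                       control = ctrl))
    s <- summary(fit)$coefficients
    s[rownames(s) != "(Intercept)", , drop = FALSE]
  }
  rows <- if (joint) list(fit_one(predictors)) else
    lapply(names(predictors), function(nm) fit_one(predictors[, nm, drop = FALSE]))
  cf <- do.call(rbind, rows)
  out <- data.frame(predictor = rownames(cf), estimate = cf[, 1L],
                    std_error = cf[, 2L], z_value = cf[, 3L],
                    p_value = cf[, 4L], stringsAsFactors = FALSE,
                    row.names = NULL)
  out$separation <- abs(out$estimate) > 15
  out$fdr_adjusted_p <- bh_fdr(out$p_value)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values ranked ascending, adjusted_(i) =
#' min over j >= i of min(1, m p_(j) / j); order-preserving.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  ord <- order(p_values)
  adj <- pmin(1, p_values[ord] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' QQ-plot data for a set of p-values
#'
#' Pairs expected -log10 quantiles, expected_i = -log10((i - 0.5)/m), with
#' the observed -log10 p-values sorted descending (most significant
#' first). Zero p-values are clamped to the machine floor with a warning.
#'
#' @param p_values numeric vector in [0, 1].
#' @return data.frame with columns `expected` and `observed`.
#' @export
qq_data <- function(p_values) {
  stopifnot(length(p_values) >= 1L)
  if (any(p_values == 0)) {
    warning("p-value(s) of 0 clamped to the machine floor")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  m <- length(p_values)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = sort(-log10(p_values), decreasing = TRUE))
}
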