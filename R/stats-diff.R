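# Significance error model and differential phosphopeptide calling.
#
# The error model is a robust-normal null on log2 peptide ratios:
# location = median, spread = 1.4826 x median absolute deviation.  A
# peptide quantified over several MS/MS scans has a proportionally more
# precise ratio, so the model optionally takes precision weights (the scan
# count): standardized residuals are (x - mu) * sqrt(w) and the spread is
# estimated on that common scale.  Under the null of no change the
# standardized log-ratio is treated as standard normal and converted to a
# two-sided tail probability.  Peptides with at least a 1.5-fold change
# and p < 0.05 are called differential.

#' Fit the robust-normal error model to log2 ratios
#'
#' With `weights` (e.g. the number of MS/MS scans summed into each ratio),
#' the model is a scale family `x_i ~ N(mu, sigma^2 / w_i)`: residuals are
#' put on a common scale by `sqrt(w_i)` before the robust spread estimate,
#' which keeps tail probabilities calibrated when ratios differ in
#' precision.  Without weights it is the plain global robust-normal fit.
#'
#' @param log2_ratios numeric vector of finite log2 peptide ratios; at
#'   least 10 values are required for a stable spread estimate.
#' @param weights optional positive precision weights, same length as
#'   `log2_ratios` (variance of ratio i taken as `sigma^2 / weights[i]`).
#' @param sigma_floor smallest admissible spread; a degenerate sample
#'   (e.g. all values identical) is floored here with a warning.
#' @return object of class `"error_model"` with components `mu`, `sigma`,
#'   `method = "robust_normal"`, `n_fit`, `floored`, `weighted`.
#' @examples
#' m <- fit_error_model(rnorm(100, 0, 0.3))
#' coef(m)
#' predict(m, newdata = c(0, 1))
#' @export
fit_error_model <- function(log2_ratios, weights = NULL,
                            sigma_floor = 1e-6) {
  ok <- is.finite(log2_ratios)
  x <- log2_ratios[ok]
  if (length(x) < 10L) {
    stop("need at least 10 finite log2 ratios to fit the error model; got ",
         length(x), " - provide a larger input")
  }
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(log2_ratios))
    w <- weights[ok]
    if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  } else {
    w <- rep(1, length(x))
  }
  mu <- stats::median(x)
  sigma <- stats::mad((x - mu) * sqrt(w), center = 0)   # 1.4826 * MAD
  floored <- FALSE
  if (sigma < sigma_floor) {
    warning("spread estimate below floor (", sigma_floor,
            "); flooring - p-values will be degenerate")
    sigma <- sigma_floor
    floored <- TRUE
  }
  structure(list(mu = mu, sigma = sigma, method = "robust_normal",
                 n_fit = length(x), floored = floored,
                 weighted = !is.null(weights),
                 data = x, weights = w),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "Robust-normal error model (n = %d)\n  mu = %.5f  sigma = %.5f%s\n",
    x$n_fit, x$mu, x$sigma, if (x$floored) "  [floored]" else ""))
  invisible(x)
}

#' @export
coef.error_model <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' @export
summary.error_model <- function(object, ...) {
  structure(list(model = object,
                 quartiles = stats::quantile(object$data,
                                             c(0.25, 0.5, 0.75)),
                 range = range(object$data)),
            class = "summary.error_model")
}

#' @export
print.summary.error_model <- function(x, ...) {
  print(x$model)
  cat("  fitted log2-ratio quartiles:",
      paste(sprintf("%.4f", x$quartiles), collapse = " / "), "\n")
  cat("  range:", sprintf("%.4f .. %.4f", x$range[1], x$range[2]), "\n")
  invisible(x)
}

#' Two-sided p-values from the error model
#'
#' `predict(model, newdata)` standardizes each log2 ratio as
#' `z = (x - mu) * sqrt(w) / sigma` and returns the two-sided normal tail
#' probability `2 * pnorm(-|z|)`.
#'
#' @param object fitted [fit_error_model()] object.
#' @param newdata numeric vector of log2 ratios (defaults to the fitted
#'   data).
#' @param weights optional precision weights for `newdata` (default 1).
#' @param ... unused.
#' @return numeric vector of p-values in (0, 1].
#' @export
predict.error_model <- function(object, newdata = object$data,
                                weights = NULL, ...) {
  if (any(!is.finite(newdata))) stop("non-finite log2 ratio")
  if (is.null(weights)) weights <- rep(1, length(newdata))
  z <- (newdata - object$mu) * sqrt(weights) / object$sigma
  2 * stats::pnorm(-abs(z))
}

#' @export
residuals.error_model <- function(object, ...) {
  (object$data - object$mu) * sqrt(object$weights) / object$sigma
}

#' @export
simulate.error_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(object$n_fit * nsim, object$mu,
                      object$sigma / sqrt(object$weights)),
         ncol = nsim)
}

#' @export
plot.error_model <- function(x, breaks = 40, ...) {
  graphics::hist(x$data, breaks = breaks, freq = FALSE,
                 main = "Error model fit", xlab = "log2 ratio", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 256)
  graphics::lines(xs, stats::dnorm(xs, x$mu, x$sigma), lwd = 2)
  graphics::abline(v = x$mu, lty = 2)
  invisible(x)
}

#' P-value of a single log2 ratio under the error model
#'
#' Convenience scalar/vector wrapper around [predict.error_model()].
#'
#' @param log2_ratio numeric log2 ratio(s), finite.
#' @param model fitted error model.
#' @param weights optional precision weights (see [fit_error_model()]).
#' @return p-value(s).
#' @export
ratio_pvalue <- function(log2_ratio, model, weights = NULL) {
  predict(model, newdata = log2_ratio, weights = weights)
}

#' Call differential phosphopeptides
#'
#' Status is `"up"` when fold >= `fold_threshold` and p < `alpha`,
#' `"down"` when fold <= 1/`fold_threshold` and p < `alpha`, otherwise
#' `"not_significant"`.  The fold threshold is applied symmetrically on
#' the linear scale.
#'
#' @param fold_change linear fold change(s), > 0 (NA allowed; yields
#'   `not_significant`).
#' @param p_value p-value(s) matching `fold_change`.
#' @param fold_threshold minimal fold change (default 1.5).
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method passed to
#'   [stats::p.adjust()]; `"none"` (default) mirrors raw-p calling, use
#'   `"BH"` for Benjamini-Hochberg.
#' @return character vector of statuses.
#' @export
call_differential <- function(fold_change, p_value, fold_threshold = 1.5,
                              alpha = 0.05, adjust = "none") {
  stopifnot(length(fold_change) == length(p_value), fold_threshold > 0)
  if (any(fold_change <= 0, na.rm = TRUE)) stop("fold changes must be > 0")
  p <- stats::p.adjust(p_value, method = adjust)
  status <- rep("not_significant", length(fold_change))
  sig <- !is.na(p) & p < alpha & !is.na(fold_change)
  status[sig & fold_change >= fold_threshold] <- "up"
  status[sig & fold_change <= 1 / fold_threshold] <- "down"
  status
}

#' Differential result table for one comparison
#'
#' @param quant peptide quant data.frame with `key` and ratio/log2 columns
#'   for the comparison (see [peptide_quant_table()]).
#' @param comparison `c(numerator_group, denominator_group)`.
#' @param model error model fitted on this comparison's log2 ratios; when
#'   NULL it is fitted here.
#' @param weights optional precision weights per peptide (e.g. the
#'   `n_scans` column); used both in fitting and in p-value computation.
#' @param fold_threshold,alpha,adjust see [call_differential()].
#' @return data.frame: `key`, `comparison`, `fold_change`, `log2_ratio`,
#'   `p_value`, `status`, with the thresholds as attributes.
#' @export
differential_table <- function(quant, comparison, model = NULL,
                               weights = NULL, fold_threshold = 1.5,
                               alpha = 0.05, adjust = "none") {
  cn <- paste(comparison, collapse = "_")
  rcol <- paste0("ratio_", cn); lcol <- paste0("log2_", cn)
  if (!all(c(rcol, lcol) %in% names(quant))) {
    stop("quant table lacks columns for comparison ", cn)
  }
  ok <- is.finite(quant[[lcol]])
  if (is.null(model)) {
    model <- fit_error_model(quant[[lcol]][ok],
                             weights = if (is.null(weights)) NULL
                                       else weights[ok])
  }
  p <- rep(NA_real_, nrow(quant))
  p[ok] <- predict(model, newdata = quant[[lcol]][ok],
                   weights = if (is.null(weights)) NULL else weights[ok])
  status <- rep("not_significant", nrow(quant))
  status[ok] <- call_differential(quant[[rcol]][ok], p[ok],
                                  fold_threshold, alpha, adjust)
  out <- data.frame(key = quant$key,
                    comparison = paste0(comparison[1], "/", comparison[2]),
                    fold_change = quant[[rcol]],
                    log2_ratio = quant[[lcol]],
                    p_value = p, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "alpha") <- alpha
  attr(out, "model") <- model
  out
}

#' Summarize differential calls
#'
#' Counts up-, down-regulated and total significant records, per
#' comparison, at the peptide level and (when a protein map is supplied)
#' at the protein level.
#'
#' @param results data.frame with columns `status` and optionally
#'   `comparison`; a `direction` column is accepted as an alias of
#'   `status` for externally tagged tables.
#' @param protein_map optional named vector peptide key -> accession for
#'   protein-level tallies (requires a `key` column).
#' @return data.frame with `comparison`, `n_up`, `n_down`,
#'   `n_significant` (and `n_proteins_up`/`n_proteins_down` when mapped).
#' @export
summarize_differentials <- function(results, protein_map = NULL) {
  if (!nrow(results)) {
    return(data.frame(comparison = character(), n_up = integer(),
                      n_down = integer(), n_significant = integer()))
  }
  st <- if ("status" %in% names(results)) results$status
        else if ("direction" %in% names(results)) results$direction
        else stop("results need a 'status' or 'direction' column")
  cmp <- if ("comparison" %in% names(results)) results$comparison
         else rep("all", nrow(results))
  out <- do.call(rbind, lapply(unique(cmp), function(cc) {
    sel <- cmp == cc
    n_up <- sum(st[sel] == "up"); n_down <- sum(st[sel] == "down")
    row <- data.frame(comparison = cc, n_up = n_up, n_down = n_down,
                      n_significant = n_up + n_down,
                      stringsAsFactors = FALSE)
    if (!is.null(protein_map) && "key" %in% names(results)) {
      acc <- unname(protein_map[results$key[sel]])
      row$n_proteins_up <- length(unique(acc[st[sel] == "up"]))
      row$n_proteins_down <- length(unique(acc[st[sel] == "down"]))
      row$n_proteins_significant <-
        length(unique(acc[st[sel] %in% c("up", "down")]))
    }
    row
  }))
  rownames(out) <- NULL
  out
}
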