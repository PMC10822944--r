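# Columns of a trait table that are traits (everything numeric except
# reserved identifier columns).
trait_columns <- function(t) {
  reserved <- c("sample_id", "genotype")
  nm <- setdiff(names(t), reserved)
  nm[vapply(t[nm], is.numeric, logical(1))]
}

#' Variance inflation factors of a trait table
#'
#' For each trait j, regresses it on all other traits (with intercept) and
#' returns `VIF_j = 1 / (1 - R_j^2)`. Exact collinearity gives `Inf`.
#'
#' @param t data.frame; columns `sample_id` / `genotype` are ignored, all
#'   other numeric columns are traits.
#' @return Named numeric vector of VIFs (>= 1).
#' @export
vif_values <- function(t) {
  cols <- trait_columns(t)
  if (length(cols) < 2) stop("need at least 2 traits")
  X <- as.matrix(t[cols])
  if (nrow(X) <= ncol(X))
    stop("need more samples than traits for exact OLS; ",
         "reduce the trait set first")
  const <- apply(X, 2, stats::var) == 0
  if (any(const))
    stop("constant trait column(s): ", paste(cols[const], collapse = ", "),
         " (VIF undefined)")
  vif <- vapply(seq_along(cols), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    # exact collinearity triggers an "essentially perfect fit" warning from
    # summary.lm; the R^2 >= 1 branch below already handles that case
    r2 <- suppressWarnings(summary(fit))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- cols
  vif
}

#' Iteratively prune collinear traits by VIF
#'
#' Removes the single trait with the largest VIF (ties broken toward the
#' later column), recomputes, and repeats until every VIF is at most
#' `threshold`. The removal history is attached as attribute `removal_log`.
#'
#' @param t trait table (see [vif_values()]).
#' @param threshold VIF threshold (> 1).
#' @return The pruned trait table.
#' @export
vif_prune <- function(t, threshold) {
  stopifnot(threshold > 1)
  log <- data.frame(step = integer(0), trait = character(0), vif = numeric(0))
  step <- 0L
  repeat {
    cols <- trait_columns(t)
    if (length(cols) < 2) break
    v <- vif_values(t)
    if (max(v) <= threshold) break
    worst <- max(which(v == max(v)))  # later column on ties
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, trait = names(v)[worst],
                                 vif = v[worst], row.names = NULL))
    t[[names(v)[worst]]] <- NULL
  }
  attr(t, "removal_log") <- log
  t
}

#' Remaining trait counts over a sweep of VIF thresholds
#'
#' @param t trait table.
#' @param thresholds increasing vector of at least 4 thresholds (> 1).
#' @return data.frame with columns `threshold` and `n_traits`; `n_traits` is
#'   non-decreasing in `threshold`.
#' @export
vif_threshold_sweep <- function(t, thresholds) {
  if (length(thresholds) < 4) stop("need at least 4 thresholds")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  n <- vapply(thresholds,
              function(th) length(trait_columns(vif_prune(t, th))),
              numeric(1))
  data.frame(threshold = thresholds, n_traits = n)
}

#' Fit the log curve y = a * ln(x - b) + c
#'
#' Models the remaining-trait count as a function of the VIF threshold.
#' Levenberg-Marquardt nonlinear least squares with initial values
#' `a0 = (max y - min y) / ln(max x / min x)`, `b0 = 0.9 * min x`,
#' `c0 = mean y`, and the box constraint `b < min(x)`.
#'
#' @param x,y numeric vectors (>= 4 points; all `x > b` at the optimum).
#' @return A `log_fit` object: list with `a`, `b`, `c`, `residuals`.
#' @export
fit_log_curve <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 points")
  if (any(x <= 0)) stop("x values must be positive")
  if (stats::var(y) == 0) {
    warning("constant y: log-curve fit is degenerate (a = 0)")
    return(structure(list(a = 0, b = 0.9 * min(x), c = y[1],
                          residuals = rep(0, length(x))),
                     class = "log_fit"))
  }
  start <- list(a = (max(y) - min(y)) / log(max(x) / min(x)),
                b = 0.9 * min(x), c = mean(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * log(x - b) + c, start = start,
                      upper = c(a = Inf, b = min(x) - 1e-8, c = Inf),
                      lower = c(a = -Inf, b = -Inf, c = -Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("log-curve fit failed to converge: ",
                             conditionMessage(e)))
  p <- as.list(stats::coef(fit))
  structure(list(a = p$a, b = p$b, c = p$c,
                 residuals = as.numeric(stats::resid(fit))),
            class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit> y = %.6g * ln(x - %.6g) + %.6g (RMS resid %.3g)\n",
              x$a, x$b, x$c, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' The "high" VIF threshold from a fitted log curve
#'
#' The x value where the fitted curve `y = a ln(x - b) + c` has slope 1,
#' i.e. where the threshold would start growing faster than the number of
#' retained traits: `a / (x - b) = 1`, so `x = a + b`.
#'
#' @param p a `log_fit` (or list with `a`, `b`); requires `a > 0`.
#' @return The threshold `a + b`.
#' @export
high_vif_threshold <- function(p) {
  if (p$a <= 0) stop("slope-1 point requires a > 0")
  p$a + p$b
}

#' The "median" VIF threshold: half of the high threshold
#'
#' Returned exactly (no rounding); the conventional rounded value is attached
#' as attribute `rounded`.
#'
#' @param high the high VIF threshold (> 2).
#' @return `high / 2`, with attribute `rounded = round(high / 2)`.
#' @export
median_vif_threshold <- function(high) {
  if (high <= 2) stop("high threshold must exceed 2")
  structure(high / 2, rounded = round(high / 2))
}

#' Multivariate principal component traits (mPCs)
#'
#' Standardized PCA on a VIF-pruned trait table; keeps the smallest number
#' of components reaching `cumulative_threshold` of variance and names them
#' `mPC1..mPCk`.
#'
#' @param t pruned trait table.
#' @param cumulative_threshold cumulative variance retention (default 0.90).
#' @return data.frame with `sample_id` (and `genotype` if present) plus mPC
#'   columns; attribute `variance_fractions`.
#' @export
multivariate_pcs <- function(t, cumulative_threshold = 0.90) {
  cols <- trait_columns(t)
  if (length(cols) < 2) stop("need at least 2 traits")
  p <- pca(as.matrix(t[cols]), standardize = TRUE)
  k <- select_num_pcs(p$variance_fractions, cumulative_threshold)
  sc <- p$scores[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("mPC", seq_len(k))
  keep <- intersect(c("sample_id", "genotype"), names(t))
  out <- data.frame(t[keep], sc, check.names = FALSE, row.names = NULL)
  attr(out, "variance_fractions") <- p$variance_fractions
  out
}
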