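#' Empirical p-value with add-one correction
#'
#' p = (1 + #\{b : d_null\[b\] >= d_obs\}) / (B + 1). Ties count as at least
#' as extreme, and the add-one convention guarantees p > 0; both choices
#' are conservative.
#'
#' @param d_obs observed statistic.
#' @param d_null numeric vector of null-resampled statistics.
#' @return A p-value in (0, 1\].
#' @examples
#' empirical_pvalue(2.5, c(1, 2, 3, 4))  # (1 + 2) / 5 = 0.6
#' @export
empirical_pvalue <- function(d_obs, d_null) {
  if (length(d_null) == 0L) stop("empty null vector", call. = FALSE)
  if (anyNA(d_null) || any(!is.finite(d_null)) || !is.finite(d_obs)) {
    stop("statistics must be finite", call. = FALSE)
  }
  (1 + sum(d_null >= d_obs)) / (length(d_null) + 1)
}

.new_test <- function(d_observed, d_null, method, config, B, seed,
                      retries = 0L) {
  structure(list(statistic = d_observed,
                 p.value = empirical_pvalue(d_observed, d_null),
                 null = d_null, B = B, seed = seed, method = method,
                 config = config, retries = retries,
                 direction = "greater"),
            class = "netdiss_test")
}

#' @export
print.netdiss_test <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("D =", format(x$statistic, digits = digits),
      ", resamples =", x$B,
      ", p-value =", format(x$p.value, digits = digits), "\n")
  cat("alternative: observed network farther from target than under",
      "the null\n")
  if (x$retries > 0L) {
    cat("note:", x$retries, "resamples redrawn after estimation",
        "failures\n")
  }
  invisible(x)
}

#' @export
summary.netdiss_test <- function(object, ...) {
  out <- list(method = object$method, statistic = object$statistic,
              p.value = object$p.value, B = object$B, seed = object$seed,
              null_summary = stats::quantile(object$null,
                                             c(0, .25, .5, .75, 1)),
              retries = object$retries)
  class(out) <- "summary.netdiss_test"
  out
}

#' @export
print.summary.netdiss_test <- function(x, digits = 4, ...) {
  cat(x$method, "\n")
  cat("D =", format(x$statistic, digits = digits),
      " p =", format(x$p.value, digits = digits),
      " B =", x$B, "\n")
  cat("null distribution quantiles:\n")
  print(signif(x$null_summary, digits))
  invisible(x)
}

#' Histogram of the resampled null distribution
#' @param x a `netdiss_test`.
#' @param ... passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.netdiss_test <- function(x, ...) {
  graphics::hist(x$null, main = x$method, xlab = "null D", ...)
  graphics::abline(v = x$statistic, lwd = 2)
  invisible(x)
}

#' One-sample test against a null network model
#'
#' Tests whether an observed network is farther from a target network than
#' draws from a null network model. The observed statistic is
#' D(observed, target); the null distribution is D(g_b, target) for B
#' independent draws g_b from `null_sampler`, all against the same fixed
#' target realization. Rejection is one-sided for large D.
#'
#' @param observed observed `labeled_network`.
#' @param target target (gold-standard) `labeled_network`.
#' @param null_sampler a function of no arguments returning a
#'   `labeled_network` draw from the null model.
#' @param config a [dissim_config()].
#' @param B number of null resamples.
#' @param seed optional integer seed (set before the null draws).
#' @return A `netdiss_test`.
#' @examples
#' tgt <- sample_er(25, 0.2, seed = 1)
#' obs <- sample_er(25, 0.3, seed = 2)
#' one_sample_test_model(obs, tgt, function() sample_er(25, 0.2),
#'                       B = 99, seed = 3)
#' @export
one_sample_test_model <- function(observed, target, null_sampler,
                                  config = dissim_config(), B = 1000L,
                                  seed = NULL) {
  stopifnot(is.function(null_sampler), inherits(config, "dissim_config"))
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(B)
  d_obs <- net_dissim(observed, target, config)
  d_null <- vapply(seq_len(B), function(b) {
    net_dissim(null_sampler(), target, config)
  }, numeric(1))
  .new_test(d_obs, d_null, "One-sample network test (null-model resampling)",
            config, B, seed)
}

#' One-sample test with a bootstrapped null from a-priori samples
#'
#' When the null model is represented by a set of historical (a-priori)
#' sampling units rather than a generative model, each null replicate
#' draws `n_resample` rows with replacement from the a-priori data,
#' re-estimates the network, and computes its D against the target.
#' Estimation failures trigger a redraw (up to `max_retries` per
#' replicate).
#'
#' @param apriori samples-by-variables data matrix representing the null.
#' @param estimator a function mapping a data matrix to a
#'   `labeled_network` (e.g. `\(x) correlation_network(x, 0.2)`).
#' @param observed observed `labeled_network`.
#' @param target target network; defaults to `estimator(apriori)`.
#' @param config a [dissim_config()].
#' @param B number of bootstrap resamples.
#' @param n_resample rows per resample (defaults to `nrow(apriori)`).
#' @param seed optional integer seed.
#' @param max_retries redraw cap per replicate on estimation failure.
#' @return A `netdiss_test`.
#' @export
one_sample_test_bootstrap <- function(apriori, estimator, observed,
                                      target = NULL,
                                      config = dissim_config(),
                                      B = 1000L,
                                      n_resample = nrow(apriori),
                                      seed = NULL, max_retries = 100L) {
  stopifnot(is.function(estimator), inherits(config, "dissim_config"))
  apriori <- as.matrix(apriori)
  if (nrow(apriori) < 2L) {
    stop("a-priori sample needs at least 2 rows", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target)) target <- estimator(apriori)
  B <- as.integer(B)
  d_obs <- net_dissim(observed, target, config)
  retries <- 0L
  d_null <- vapply(seq_len(B), function(b) {
    for (try in seq_len(max_retries + 1L)) {
      idx <- sample.int(nrow(apriori), n_resample, replace = TRUE)
      net <- tryCatch(estimator(apriori[idx, , drop = FALSE]),
                      netdiss_estimation_error = function(e) NULL)
      if (!is.null(net)) {
        if (try > 1L) retries <<- retries + (try - 1L)
        return(net_dissim(net, target, config))
      }
    }
    stop("estimation failed ", max_retries, " times in one bootstrap ",
         "replicate", call. = FALSE)
  }, numeric(1))
  .new_test(d_obs, d_null, "One-sample network test (bootstrap null)",
            config, B, seed, retries)
}

# Shared permutation engine: evaluates D under one or more dissimilarity
# configurations on the same permutation stream, so that configurations
# are compared on identical random splits. Group 1 always plays the
# "observed" role of the asymmetric statistic.
.permutation_engine <- function(X1, X2, estimator, configs, B,
                                max_retries = 100L) {
  n1 <- nrow(X1)
  pool <- rbind(X1, X2)
  n <- nrow(pool)
  net1 <- estimator(X1)
  net2 <- estimator(X2)
  d_obs <- vapply(configs, function(cf) net_dissim(net1, net2, cf),
                  numeric(1))
  nc <- length(configs)
  d_null <- matrix(NA_real_, B, nc)
  retries <- 0L
  for (b in seq_len(B)) {
    for (try in seq_len(max_retries + 1L)) {
      idx <- sample.int(n, n1)
      nets <- tryCatch(
        list(estimator(pool[idx, , drop = FALSE]),
             estimator(pool[-idx, , drop = FALSE])),
        netdiss_estimation_error = function(e) NULL)
      if (!is.null(nets)) {
        if (try > 1L) retries <- retries + (try - 1L)
        d_null[b, ] <- vapply(configs, function(cf) {
          net_dissim(nets[[1]], nets[[2]], cf)
        }, numeric(1))
        break
      }
      if (try == max_retries + 1L) {
        stop("estimation failed ", max_retries, " times in one ",
             "permutation replicate", call. = FALSE)
      }
    }
  }
  list(d_obs = d_obs, d_null = d_null, retries = retries)
}

#' Two-sample permutation test for network equality
#'
#' Tests H0: both groups of sampling units generate the same network.
#' The observed statistic is D(estimator(X1), estimator(X2)) with group 1
#' as the observed argument of the asymmetric statistic. Each of the B
#' permutation replicates randomly partitions the pooled rows into groups
#' of the original sizes (every row used exactly once) and recomputes D
#' with the same orientation. Rows must be exchangeable under the null.
#'
#' @param X1,X2 samples-by-variables data matrices with identical column
#'   labels.
#' @param estimator function mapping a data matrix to a
#'   `labeled_network`.
#' @param config a [dissim_config()].
#' @param B number of permutations.
#' @param seed optional integer seed.
#' @param max_retries redraw cap per replicate on estimation failure.
#' @return A `netdiss_test`.
#' @examples
#' pop <- sample_block_correlation(seed = 1)
#' X1 <- sample_mvn(pop, 60, seed = 2)
#' X2 <- sample_mvn(pop, 60, seed = 3)
#' two_sample_permutation_test(X1, X2, function(x) correlation_network(x),
#'                             dissim_config(edge = FALSE), B = 49, seed = 4)
#' @export
two_sample_permutation_test <- function(X1, X2, estimator,
                                        config = dissim_config(),
                                        B = 1000L, seed = NULL,
                                        max_retries = 100L) {
  stopifnot(is.function(estimator), inherits(config, "dissim_config"))
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  if (!identical(colnames(X1), colnames(X2))) {
    stop("'X1' and 'X2' must have identical column labels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(B)
  res <- .permutation_engine(X1, X2, estimator, list(config), B,
                             max_retries)
  .new_test(res$d_obs[[1]], res$d_null[, 1],
            "Two-sample network permutation test", config, B, seed,
            res$retries)
}
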