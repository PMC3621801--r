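#' Rejection rate of a p-value vector
#'
#' @param p numeric vector of p-values (or a `netdiss_experiment`).
#' @param alpha nominal level in (0, 1).
#' @return Exact fraction of p-values strictly below `alpha` (a named
#'   vector with one entry per setting for multi-setting experiments).
#' @examples
#' rejection_rate(c(0.01, 0.2, 0.04, 0.8), 0.05)  # 0.5
#' @export
rejection_rate <- function(p, alpha = 0.05) {
  if (inherits(p, "netdiss_experiment")) p <- p$p_values
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  if (is.matrix(p)) return(colMeans(p < alpha))
  mean(p < alpha)
}

.new_experiment <- function(p_values, config, seed, method,
                            alphas = c(0.01, 0.05, 0.10), extra = list()) {
  rr <- lapply(alphas, function(a) rejection_rate_raw(p_values, a))
  names(rr) <- paste0("alpha_", alphas)
  structure(c(list(p_values = p_values, rejection_rate_at = rr,
                   config = config, seed = seed, method = method),
              extra),
            class = "netdiss_experiment")
}

rejection_rate_raw <- function(p, alpha) {
  if (is.matrix(p)) colMeans(p < alpha) else mean(p < alpha)
}

#' @export
print.netdiss_experiment <- function(x, digits = 3, ...) {
  nexp <- if (is.matrix(x$p_values)) nrow(x$p_values) else
    length(x$p_values)
  cat(x$method, "\n")
  cat("experiments:", nexp, " resamples per test:", x$config$B, "\n")
  cat("rejection rate at alpha = 0.05:\n")
  print(signif(x$rejection_rate_at$alpha_0.05, digits))
  invisible(x)
}

#' @export
summary.netdiss_experiment <- function(object, ...) {
  print(object, ...)
  cat("p-value quartiles:\n")
  p <- object$p_values
  if (is.matrix(p)) print(apply(p, 2, stats::quantile)) else
    print(stats::quantile(p))
  invisible(object)
}

#' Uniform QQ data and plot for experiment p-values
#'
#' Compares the empirical p-value distribution over experiments to the
#' uniform distribution expected under a true null.
#'
#' @param x a `netdiss_experiment`.
#' @param setting column to plot when the experiment tracked several
#'   dissimilarity settings.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, a data frame with `expected` and `observed`
#'   quantiles.
#' @export
plot.netdiss_experiment <- function(x, setting = 1L, ...) {
  p <- x$p_values
  if (is.matrix(p)) p <- p[, setting]
  qq <- qq_table(p)
  graphics::plot(qq$expected, qq$observed, xlab = "expected p",
                 ylab = "observed p", main = x$method, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(qq)
}

#' Expected-vs-observed uniform quantile table
#' @param p numeric vector of p-values.
#' @return Data frame with columns `expected` and `observed`.
#' @export
qq_table <- function(p) {
  n <- length(p)
  data.frame(expected = (seq_len(n) - 0.5) / n, observed = sort(p))
}

#' One-sample Erdős–Rényi simulation study
#'
#' Repeats the one-sample null-model test: per experiment a fixed target
#' realization is drawn from G(n, p0), the observed graph from
#' G(n, p_true), and the null distribution of D is formed from B fresh
#' G(n, p0) draws compared to the same target. The neighbour term uses a
#' constant weight (`c_constant = 0` disables it). With `p_true = p0` the
#' run measures the type-I error rate; with `p_true > p0`, power.
#'
#' @param n_experiments number of independent tests.
#' @param n graph order.
#' @param p_true edge probability generating the observed graphs.
#' @param p0 null edge probability.
#' @param c_constant constant neighbour weight c.
#' @param B null resamples per test.
#' @param seed integer seed for the whole run. Because the neighbour
#'   weight does not influence the random stream, runs that differ only
#'   in `c_constant` see identical graphs, so settings can be compared
#'   experiment by experiment.
#' @return A `netdiss_experiment` whose `p_values` is a vector of length
#'   `n_experiments`.
#' @examples
#' ex <- run_er_experiment(10, p_true = 0.25, B = 99, seed = 1)
#' rejection_rate(ex)
#' @export
run_er_experiment <- function(n_experiments = 100L, n = 25L,
                              p_true = 0.20, p0 = 0.20, c_constant = 0,
                              B = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- if (c_constant > 0) {
    dissim_config(neighbour = "constant", c = c_constant)
  } else {
    dissim_config()
  }
  p_values <- vapply(seq_len(n_experiments), function(e) {
    target <- sample_er(n, p0)
    observed <- sample_er(n, p_true)
    one_sample_test_model(observed, target,
                          function() sample_er(n, p0),
                          config = cfg, B = B)$p.value
  }, numeric(1))
  .new_experiment(p_values,
                  list(n = n, p_true = p_true, p0 = p0,
                       c_constant = c_constant, B = B),
                  seed, "Erdos-Renyi one-sample simulation")
}

#' One-sample correlation-network simulation study
#'
#' Per experiment, an a-priori sample (representing historical null data)
#' and an observed sample are drawn from a block-diagonal correlation
#' population; under the alternative the observed sample comes from a
#' block-perturbed population. The target is the thresholded correlation
#' network of the a-priori sample, the observed network that of the
#' observed sample, and the null distribution is bootstrapped from the
#' a-priori rows. D uses only the weight component, since edge presence
#' in a correlation network is defined through the weight itself.
#'
#' @param n_experiments number of independent tests.
#' @param n_blocks,block_size,min_abs population parameters, see
#'   [sample_block_correlation()].
#' @param n_obs observed sample size.
#' @param apriori_multiplier a-priori sample size as a multiple of
#'   `n_obs` (the test attains its nominal size only when the a-priori
#'   sample is substantially larger than the observed one; 10 is the
#'   recommended factor at `n_obs = 200`).
#' @param rho correlation threshold defining the networks.
#' @param neighbour `"none"` (c_ij = 0) or `"weighted"` (c_ij equal to
#'   the thresholded observed correlation when the target has the edge).
#' @param B bootstrap resamples per test.
#' @param seed integer seed.
#' @param alternative draw the observed sample from a block-perturbed
#'   population (power study) instead of the null population.
#' @param min_fraction fraction of blocks perturbed under the
#'   alternative.
#' @return A `netdiss_experiment`.
#' @export
run_onesample_corr_experiment <- function(n_experiments = 100L,
                                          n_blocks = 6L, block_size = 5L,
                                          min_abs = 0.2, n_obs = 200L,
                                          apriori_multiplier = 10,
                                          rho = 0.2,
                                          neighbour = c("none", "weighted"),
                                          B = 1000L, seed = NULL,
                                          alternative = FALSE,
                                          min_fraction = 0.1) {
  neighbour <- match.arg(neighbour)
  if (apriori_multiplier < 1) {
    stop("'apriori_multiplier' must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cfg <- dissim_config(edge = FALSE, neighbour = neighbour)
  est <- function(x) correlation_network(x, rho)
  p_values <- vapply(seq_len(n_experiments), function(e) {
    pop <- sample_block_correlation(n_blocks, block_size, min_abs)
    apriori <- sample_mvn(pop, round(apriori_multiplier * n_obs))
    obs_pop <- if (alternative) perturb_blocks(pop, min_fraction) else pop
    observed <- est(sample_mvn(obs_pop, n_obs))
    one_sample_test_bootstrap(apriori, est, observed, config = cfg,
                              B = B, n_resample = n_obs)$p.value
  }, numeric(1))
  .new_experiment(p_values,
                  list(n_blocks = n_blocks, block_size = block_size,
                       min_abs = min_abs, n_obs = n_obs,
                       apriori_multiplier = apriori_multiplier, rho = rho,
                       neighbour = neighbour, B = B,
                       alternative = alternative),
                  seed, "One-sample correlation-network simulation")
}

#' Two-sample GGM permutation simulation study
#'
#' Per experiment, a fresh block-diagonal correlation population is
#' drawn; group 1 samples from it and group 2 from the same population
#' (null) or from a block-perturbed copy (alternative). Shrinkage
#' partial-correlation networks are estimated for both groups and
#' compared with the weight-only D in a permutation test. Both neighbour
#' settings (c_ij equal to the observed thresholded partial correlation,
#' and c_ij = 0) are evaluated on the same data and the same permutation
#' stream, so their p-values are comparable experiment by experiment.
#'
#' @param n_experiments number of independent tests.
#' @param n_blocks,block_size,min_abs population parameters.
#' @param n1,n2 group sample sizes.
#' @param cutoff GGM partial-correlation magnitude cutoff.
#' @param B permutations per test.
#' @param seed integer seed.
#' @param alternative perturb group 2's population (power study).
#' @param min_fraction fraction of blocks perturbed under the
#'   alternative.
#' @return A `netdiss_experiment` whose `p_values` is an
#'   `n_experiments` x 2 matrix with columns `"weighted"` (neighbour
#'   term included) and `"none"` (excluded); `retries` records
#'   estimation-failure redraw counts per experiment.
#' @export
run_twosample_ggm_experiment <- function(n_experiments = 100L,
                                         n_blocks = 6L, block_size = 5L,
                                         min_abs = 0.2, n1 = 200L,
                                         n2 = 200L, cutoff = 0.5,
                                         B = 1000L, seed = NULL,
                                         alternative = FALSE,
                                         min_fraction = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  configs <- list(weighted = dissim_config(edge = FALSE,
                                           neighbour = "weighted"),
                  none = dissim_config(edge = FALSE))
  est <- function(x) ggm_network(x, ggm_config(cutoff = cutoff))
  p_values <- matrix(NA_real_, n_experiments, 2L,
                     dimnames = list(NULL, names(configs)))
  retries <- integer(n_experiments)
  for (e in seq_len(n_experiments)) {
    pop <- sample_block_correlation(n_blocks, block_size, min_abs)
    X1 <- sample_mvn(pop, n1)
    pop2 <- if (alternative) perturb_blocks(pop, min_fraction) else pop
    X2 <- sample_mvn(pop2, n2)
    res <- .permutation_engine(X1, X2, est, configs, as.integer(B))
    p_values[e, ] <- vapply(seq_along(configs), function(j) {
      empirical_pvalue(res$d_obs[[j]], res$d_null[, j])
    }, numeric(1))
    retries[e] <- res$retries
  }
  .new_experiment(p_values,
                  list(n_blocks = n_blocks, block_size = block_size,
                       min_abs = min_abs, n1 = n1, n2 = n2,
                       cutoff = cutoff, B = B, alternative = alternative,
                       min_fraction = min_fraction),
                  seed, "Two-sample GGM permutation simulation",
                  extra = list(retries = retries))
}
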