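#' Per-trial baseline-relative power difference and trial-order bins
#'
#' For every post-stimulation trial n,
#' \deqn{pd(n) = (p_{trial}(n) - \bar p_{base}) / \bar p_{base}}
#' where \eqn{\bar p_{base}} is baseline power averaged over trials (and
#' over the cluster units), and \eqn{p_{trial}(n)} is the trial's power
#' averaged over the cluster units.  Trials are then grouped, in recording
#' order, into `n_bins` equal-sized bins (20 trials yield bins
#' (1-4)(5-8)(9-12)(13-16)(17-20)).  Flagged trials contribute `NA` and
#' keep their position so bin membership never shifts.
#'
#' @param post numeric matrix `[unit, trial]` of post-stimulation power at
#'   the ISF (e.g. from [trial_power()]).
#' @param baseline numeric matrix `[unit, trial]` of baseline power at the
#'   ISF.
#' @param units integer cluster-unit indices over which power is averaged.
#' @param rejected_post,rejected_base optional logical flags per trial.
#' @param n_bins number of bins.
#' @return Object of class `bin_series`: `values` (one power difference
#'   per trial), `bins` (bin index per trial), `bin_means`.
#' @export
compute_bin_series <- function(post, baseline, units = NULL,
                               rejected_post = NULL, rejected_base = NULL,
                               n_bins = 5L) {
  post <- as.matrix(post); baseline <- as.matrix(baseline)
  if (!is.null(units)) {
    post <- post[units, , drop = FALSE]
    baseline <- baseline[units, , drop = FALSE]
  }
  n_trial <- ncol(post)
  if (n_trial %% n_bins != 0)
    stop("trial count (", n_trial, ") is not divisible into ", n_bins,
         " equal bins")
  keep_base <- if (is.null(rejected_base)) seq_len(ncol(baseline))
               else which(!rejected_base)
  base_avg <- mean(baseline[, keep_base])
  if (base_avg <= 0) stop("non-positive baseline power")
  values <- colMeans(post) / base_avg - 1
  if (!is.null(rejected_post)) values[rejected_post] <- NA_real_
  per_bin <- n_trial / n_bins
  bins <- rep(seq_len(n_bins), each = per_bin)
  bin_means <- vapply(seq_len(n_bins), function(b) {
    v <- values[bins == b]
    if (sum(!is.na(v)) < 2)
      stop("fewer than 2 usable trials in bin ", b)
    mean(v, na.rm = TRUE)
  }, 0)
  structure(list(values = values, bins = bins, bin_means = bin_means),
            class = "bin_series")
}

#' Friedman test over trial-order bins with Conover post hoc
#'
#' Omnibus Friedman rank test of a bin effect across participants
#' (participants are blocks, bins are treatments; mid-ranks for ties),
#' followed -- only when the omnibus p is below `posthoc_alpha` -- by the
#' pairwise Conover rank test with Bonferroni correction over all bin
#' pairs.
#'
#' The Conover comparison for bins i, j uses the within-participant rank
#' sums \eqn{R_i}, with
#' \deqn{t_{ij} = (R_i - R_j) / \sqrt{ \frac{2 n (A_1 - C_1)}{(n-1)(k-1)}
#'   \left(1 - \frac{T_1}{n (k-1)}\right) }}
#' where \eqn{A_1} is the sum of squared ranks, \eqn{C_1 = n k (k+1)^2/4}
#' and \eqn{T_1} the (tie-corrected) Friedman statistic, referred to a t
#' distribution with \eqn{(n-1)(k-1)} degrees of freedom.
#'
#' @param bin_matrix numeric matrix `[participant, bin]` of per-bin mean
#'   power differences.
#' @param posthoc_alpha omnibus threshold gating the post hoc.
#' @return Object of class `friedman_result`: `chi2`, `df`, `p`,
#'   `posthoc` (Bonferroni-adjusted symmetric p matrix, or `NULL`).
#' @export
friedman_bins <- function(bin_matrix, posthoc_alpha = 0.05) {
  bin_matrix <- as.matrix(bin_matrix)
  n <- nrow(bin_matrix); k <- ncol(bin_matrix)
  if (n < 3) stop("need at least 3 participants")
  if (any(is.na(bin_matrix))) stop("bin matrix contains missing values")
  if (all(apply(bin_matrix, 1, function(z) length(unique(z)) == 1))) {
    return(structure(list(chi2 = 0, df = k - 1, p = 1, posthoc = NULL),
                     class = "friedman_result"))
  }
  ft <- friedman.test(bin_matrix)
  chi2 <- unname(ft$statistic); p <- ft$p.value
  posthoc <- NULL
  if (is.finite(p) && p < posthoc_alpha)
    posthoc <- conover_posthoc(bin_matrix)$p_adjusted
  structure(list(chi2 = chi2, df = unname(ft$parameter), p = p,
                 posthoc = posthoc), class = "friedman_result")
}

#' @rdname friedman_bins
#' @return `conover_posthoc()` returns a list with the pairwise statistic
#'   matrix `t`, raw `p` and Bonferroni-adjusted `p_adjusted` matrices.
#' @export
conover_posthoc <- function(bin_matrix) {
  bin_matrix <- as.matrix(bin_matrix)
  n <- nrow(bin_matrix); k <- ncol(bin_matrix)
  r <- t(apply(bin_matrix, 1, rank))
  R <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  T1 <- (k - 1) * sum((R - n * (k + 1) / 2)^2) / (A1 - C1)
  df <- (n - 1) * (k - 1)
  se2 <- 2 * n * (A1 - C1) / df * (1 - T1 / (n * (k - 1)))
  se <- sqrt(max(se2, 0))
  tmat <- outer(R, R, "-") / ifelse(se > 0, se, NA)
  if (se == 0) {
    # perfectly consistent ranking: distinct rank sums separate with
    # vanishing residual variance
    tmat <- outer(R, R, "-")
    praw <- ifelse(tmat == 0, 1, 0)
  } else {
    praw <- 2 * pt(-abs(tmat), df)
  }
  diag(praw) <- 1
  m <- k * (k - 1) / 2
  padj <- pmin(praw * m, 1)
  diag(padj) <- 1
  dimnames(praw) <- dimnames(padj) <-
    list(paste0("bin", 1:k), paste0("bin", 1:k))
  list(t = tmat, p = praw, p_adjusted = padj, df = df)
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("<friedman_result> chi2(%d) = %.3f, p = %.4g%s\n", x$df,
              x$chi2, x$p,
              if (is.null(x$posthoc)) "" else "; Conover post hoc attached"))
  invisible(x)
}
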