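#' IoU-balanced sampler configuration
#'
#' @param n_samples Total RoIs drawn per step.
#' @param pos_fraction Target fraction of positives.
#' @param k_bins Number of equal-width IoU bins for negatives (3).
#' @param max_neg_iou Upper edge of the negative binning range (0.3);
#'   negatives at or above it fall in the top bin.
#' @return List of class `sampler_config`.
#' @export
sampler_config <- function(n_samples = 32L, pos_fraction = 0.5,
                           k_bins = 3L, max_neg_iou = 0.3) {
  assert_that(is_count(k_bins, 1L), "k_bins must be >= 1")
  assert_that(is_prob(pos_fraction), "pos_fraction must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 pos_fraction = pos_fraction, k_bins = as.integer(k_bins),
                 max_neg_iou = max_neg_iou),
            class = "sampler_config")
}

sample_n_of <- function(pool, n) {
  if (length(pool) <= n) return(pool)
  pool[sample.int(length(pool), n)]
}

#' IoU-balanced sampling of training RoIs
#'
#' Positives are drawn uniformly. Negatives are partitioned into `k_bins`
#' equal-width IoU bins over `[0, max_neg_iou)` and the requested negative
#' count is split evenly across bins; a bin holding fewer candidates than
#' its quota contributes everything it has and the shortfall is
#' redistributed across the remaining bins. This flattens the usual
#' easy-negative skew (most negatives have IoU near 0). With `k_bins = 1`
#' the scheme reduces to plain random sampling. Deterministic per seed.
#'
#' @param iou Max-IoU-to-ground-truth per candidate.
#' @param positive Logical: candidate is a positive.
#' @param config A [sampler_config()].
#' @param seed Integer seed.
#' @return List with `pos` and `neg` integer index vectors (possibly
#'   empty; requesting more than available returns everything available).
#' @export
iou_balanced_sample <- function(iou, positive, config = sampler_config(),
                                seed = 1L) {
  assert_that(length(iou) == length(positive),
              "iou and positive must have equal length")
  if (length(iou) == 0L) return(list(pos = integer(), neg = integer()))
  pos_pool <- which(positive)
  neg_pool <- which(!positive)
  n_pos_req <- round(config$n_samples * config$pos_fraction)
  with_seed(seed, {
    pos <- sample_n_of(pos_pool, n_pos_req)
    n_neg_req <- min(config$n_samples - length(pos), length(neg_pool))
    if (n_neg_req <= 0L || config$k_bins == 1L) {
      neg <- sample_n_of(neg_pool, max(0L, n_neg_req))
    } else {
      k <- config$k_bins
      edges <- seq(0, config$max_neg_iou, length.out = k + 1L)
      bin <- findInterval(iou[neg_pool], edges, rightmost.closed = FALSE)
      bin <- pmin(pmax(bin, 1L), k)   # >= max_neg_iou joins the top bin
      bins <- lapply(seq_len(k), function(b) neg_pool[bin == b])
      quota <- rep(n_neg_req %/% k, k)
      extra <- n_neg_req - sum(quota)
      if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
      neg <- integer()
      remaining <- seq_len(k)
      repeat {
        short <- 0L
        for (b in remaining) {
          take <- min(quota[b], length(bins[[b]]))
          picked <- sample_n_of(bins[[b]], take)
          neg <- c(neg, picked)
          bins[[b]] <- setdiff(bins[[b]], picked)
          short <- short + quota[b] - take
          quota[b] <- 0L
        }
        if (short == 0L) break
        remaining <- which(vapply(bins, length, integer(1)) > 0L)
        if (length(remaining) == 0L) break
        q2 <- rep(short %/% length(remaining), length(remaining))
        r <- short - sum(q2)
        if (r > 0L) q2[seq_len(r)] <- q2[seq_len(r)] + 1L
        quota[remaining] <- q2
      }
    }
    list(pos = sort(pos), neg = sort(neg))
  })
}

#' Balanced L1 loss
#'
#' A smooth-L1 variant that promotes the gradient contribution of inliers
#' (small residuals) relative to outliers:
#' for `|x| < 1`, `L = (alpha/b) (b|x| + 1) ln(b|x| + 1) - alpha |x|`;
#' for `|x| >= 1`, `L = gamma |x| + C`, with `b = exp(gamma/alpha) - 1`
#' (so that `alpha ln(b + 1) = gamma`) and `C = gamma/b - alpha` fixed by
#' continuity at `|x| = 1`. Even, nonnegative, zero only at zero, and
#' asymptotically linear with slope `gamma`.
#'
#' @param x Regression residual(s).
#' @param alpha Inlier scaling (0.5).
#' @param gamma Outlier slope (1.5).
#' @return Loss value(s), same shape as `x`.
#' @export
balanced_l1_loss <- function(x, alpha = 0.5, gamma = 1.5) {
  assert_that(alpha > 0 && gamma > 0, "alpha and gamma must be positive")
  b <- exp(gamma / alpha) - 1
  ax <- abs(x)
  inner <- (alpha / b) * (b * ax + 1) * log(b * ax + 1) - alpha * ax
  outer_ <- gamma * ax + (gamma / b - alpha)
  ifelse(ax < 1, inner, outer_)
}

# dL/dx of the balanced L1 loss (continuous across |x| = 1).
balanced_l1_grad <- function(x, alpha = 0.5, gamma = 1.5) {
  b <- exp(gamma / alpha) - 1
  ax <- abs(x)
  sign(x) * ifelse(ax < 1, alpha * log(b * ax + 1), gamma)
}
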