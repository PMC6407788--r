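#' Poisson log-likelihood over spatial bins
#'
#' For one window of spike counts `K = (k_1, ..., k_N)` observed over `T`
#' seconds, the probability of `K` at position `x` under independent Poisson
#' firing at the ratemap rates `alpha_i(x)` is
#' `prod_i (T alpha_i(x))^{k_i} / k_i! * exp(-T alpha_i(x))`. This function
#' returns its logarithm, `sum_i [k_i log(T alpha_i(x)) - T alpha_i(x) -
#' log k_i!]`, over the visited bins. All math is in the log domain (log
#' factorials via `lgamma`) so long windows and high-rate units cannot
#' overflow.
#'
#' @param counts_K integer vector, one count per unit.
#' @param maps a [compute_ratemaps()] result (rates floored, so finite logs).
#' @param T_s window length in seconds.
#' @return numeric vector of log-likelihoods, one per visited bin.
#' @export
log_likelihood_map <- function(counts_K, maps, T_s) {
  if (any(counts_K < 0)) stop("negative spike counts")
  if (length(counts_K) != nrow(maps$rate_hz))
    stop("counts length must equal the number of units in the ratemap set")
  stopifnot(T_s > 0)
  rate <- maps$rate_hz[, maps$visited, drop = FALSE]  # units x visited bins
  drop(crossprod(log(T_s * rate), counts_K)) - T_s * colSums(rate) -
    sum(lgamma(counts_K + 1))
}

# visited-bin log-likelihoods for every window at once (windows x bins)
ll_matrix <- function(wc, maps) {
  rate <- maps$rate_hz[, maps$visited, drop = FALSE]
  lograte <- log(wc$window_len_s * rate)
  t(wc$counts) %*% lograte -
    matrix(wc$window_len_s * colSums(rate), ncol(wc$counts), ncol(rate),
           byrow = TRUE) -
    colSums(lgamma(wc$counts + 1))
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

decoded_path <- function(wc, maps, post, method) {
  centers <- maps$grid$centers[maps$visited, , drop = FALSE]
  best <- max.col(post, ties.method = "first")
  structure(list(window_centers = wc$window_centers,
                 positions = centers[best, , drop = FALSE],
                 bin = best, posterior = post,
                 bin_centers = centers, method = method),
            class = "decoded_path")
}

#' @export
print.decoded_path <- function(x, ...) {
  cat(sprintf("<decoded_path> %d windows, %s decoder, %d candidate bins\n",
              length(x$bin), x$method, ncol(x$posterior)))
  invisible(x)
}

#' Flat-prior (maximum-likelihood) Bayesian decoder
#'
#' Per window, the posterior over visited bins is the normalised Poisson
#' likelihood of the observed spike-count vector (flat position prior); the
#' decoded position is the centre of the highest-probability bin, ties broken
#' to the lowest bin index. Windows are decoded independently.
#'
#' @param wc a [count_in_windows()] result; unit order must match `maps`.
#' @param maps a [compute_ratemaps()] result.
#' @return object of class `decoded_path` with per-window positions, argmax
#'   bin indices, and the posterior matrix (rows sum to 1).
#' @export
decode_flat <- function(wc, maps) {
  if (!identical(wc$unit_ids, maps$unit_ids))
    stop("unit ids of counts and ratemaps do not match")
  post <- softmax_rows(ll_matrix(wc, maps))
  decoded_path(wc, maps, post, "flat")
}

#' Memory parameters for the continuity-constrained decoder
#'
#' @param history_len number of previous decoded steps whose mean displacement
#'   sets the continuity sigma (15).
#' @param scale multiplier on that mean displacement (1 for open-field
#'   decoding, 5 for a linear track).
#' @param min_sigma_cm floor on sigma so a stationary decoded history cannot
#'   collapse the constraint to a delta (default one 2 cm bin).
#' @return list of class `memory_params`.
#' @export
memory_params <- function(history_len = 15, scale = 1, min_sigma_cm = 2) {
  stopifnot(history_len >= 1, scale > 0, min_sigma_cm > 0)
  structure(list(history_len = as.integer(history_len), scale = scale,
                 min_sigma_cm = min_sigma_cm), class = "memory_params")
}

#' Bayesian decoder with occupancy prior and continuity constraint
#'
#' Sequential decoding: per window the Poisson likelihood is multiplied by
#' the behavioural occupancy prior `p(x)` and, from the second window on, by
#' an isotropic Gaussian of the distance from each bin centre to the
#' previously decoded position, `P(x_t | K_t, x_{t-1}) = C P(x|K)
#' normDist(x_{t-1}, sigma)`. Sigma is the mean displacement per step of the
#' decoded path over the last `history_len` steps, times `scale`, floored at
#' `min_sigma_cm`; with fewer previous steps all available ones are used, and
#' the first window uses the occupancy prior alone. The posterior is
#' renormalised each step and read out by argmax (lowest-index tie-break).
#'
#' @param wc a [count_in_windows()] result.
#' @param maps a [compute_ratemaps()] result.
#' @param prior an [occupancy_prior()], or `NULL` for a uniform prior over
#'   visited bins.
#' @param mp a [memory_params()]; ignored when `continuity = FALSE`.
#' @param continuity set `FALSE` to disable the continuity term (then with a
#'   uniform prior the result equals [decode_flat()]).
#' @return a `decoded_path`.
#' @export
decode_with_memory <- function(wc, maps, prior = NULL, mp = memory_params(),
                               continuity = TRUE) {
  if (!identical(wc$unit_ids, maps$unit_ids))
    stop("unit ids of counts and ratemaps do not match")
  nb <- sum(maps$visited)
  centers <- maps$grid$centers[maps$visited, , drop = FALSE]
  logprior <- if (is.null(prior)) rep(0, nb) else {
    p <- prior$prob[maps$visited]
    if (any(p <= 0)) p <- pmax(p, .Machine$double.xmin)
    log(p / sum(p))
  }
  ll <- ll_matrix(wc, maps)
  nw <- nrow(ll)
  post <- matrix(0, nw, nb)
  pos <- matrix(NA_real_, nw, ncol(centers),
                dimnames = list(NULL, colnames(centers)))
  best <- integer(nw)
  for (t in seq_len(nw)) {
    lp <- ll[t, ] + logprior
    if (continuity && t > 1L) {
      h <- min(t - 1L, mp$history_len)
      steps <- if (t - 1L >= 2L) {
        idx <- (t - h):(t - 1L)
        d <- pos[idx[-1], , drop = FALSE] - pos[idx[-length(idx)], , drop = FALSE]
        sqrt(rowSums(d^2))
      } else numeric(0)
      sigma <- max(if (length(steps)) mp$scale * mean(steps) else 0,
                   mp$min_sigma_cm)
      d2 <- rowSums((centers - matrix(pos[t - 1L, ], nb, ncol(centers),
                                      byrow = TRUE))^2)
      lp <- lp - d2 / (2 * sigma^2)
    }
    lp <- lp - max(lp)
    w <- exp(lp)
    post[t, ] <- w / sum(w)
    best[t] <- which.max(post[t, ])
    pos[t, ] <- centers[best[t], ]
  }
  out <- decoded_path(wc, maps, post, "memory")
  out$bin <- best
  out$positions <- pos
  out
}
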