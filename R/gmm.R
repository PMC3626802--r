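#' Diagonal Gaussian-mixture EM (non-robust baseline)
#'
#' Plain maximum-likelihood EM for a K-component Gaussian mixture with
#' diagonal covariances on per-gene condition-mean profiles. It ignores
#' measurement error, replicate variability and heavy tails, and serves as
#' the control against which the robustness and error-propagation benefits
#' of [fit_tmixture()] are measured. Uses the same seeded k-means++
#' initialisation so comparisons can share a seed.
#'
#' @param x genes x dimensions matrix (e.g. per-condition replicate means).
#' @param K number of components.
#' @param seed integer seed for initialisation.
#' @param n_starts multistarts; best log-likelihood kept.
#' @param tol,maxit convergence control.
#' @return List with `centers`, `covariances` (diagonal), `weights`,
#'   `responsibilities`, `membership`, `loglik`.
#' @export
fit_gaussian_mixture <- function(x, K, seed = 1, n_starts = 3,
                                 tol = 1e-10, maxit = 1000) {
  stopifnot(is.matrix(x), K >= 1, K <= nrow(x))
  G <- nrow(x); J <- ncol(x)
  run <- function() {
    muk <- kmeanspp_centers(winsorize_cols(x), K)
    Sk <- matrix(stats::var(as.vector(x)) / K, K, J)
    Pi <- rep(1 / K, K)
    ll_old <- -Inf
    r <- matrix(0, G, K)
    for (it in seq_len(maxit)) {
      lr <- vapply(seq_len(K), function(k)
        log(Pi[k]) - 0.5 * sum(log(2 * pi * Sk[k, ])) -
          0.5 * rowSums(sweep(sweep(x, 2L, muk[k, ])^2, 2L, Sk[k, ], `/`)),
        numeric(G))
      m <- apply(lr, 1L, max)
      ll <- sum(m + log(rowSums(exp(lr - m))))
      r <- exp(lr - m)
      r <- r / rowSums(r)
      Nk <- colSums(r)
      Pi <- Nk / G
      muk <- (t(r) %*% x) / Nk
      for (k in seq_len(K))
        Sk[k, ] <- pmax(colSums(r[, k] * sweep(x, 2L, muk[k, ])^2) / Nk[k],
                        1e-8)
      if (abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
      ll_old <- ll
    }
    list(centers = muk, covariances = Sk, weights = Pi,
         responsibilities = r,
         membership = max.col(r, ties.method = "first"), loglik = ll)
  }
  fits <- with_seed(seed, lapply(seq_len(n_starts), function(s) run()))
  fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
}
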