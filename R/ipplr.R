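#' Combine replicate expression measurements (hierarchical variational EM)
#'
#' Per gene, the measured log2 expression of replicate i under condition j
#' is modelled as xhat_ij ~ N(x_ij, s_ij^2) with known measurement variance
#' s_ij^2, latent true expression x_ij ~ N(mu_j, 1/lambda), condition mean
#' mu_j ~ N(mu0, 1/eta0), and between-replicate precision lambda ~
#' Gamma(alpha, beta), shared across conditions within a gene but not
#' across genes. The explicit latent layer x_ij makes every E-step update
#' analytic: the factorised posterior q(x) q(mu) q(lambda) has Gaussian
#' q(x_ij), Gaussian q(mu_j) and Gamma q(lambda) coordinate updates in
#' closed form, so no sampling is needed anywhere.
#'
#' Hyperparameters are shared across genes; with `hyper = "estimate"` they
#' are fitted by maximum likelihood inside the same EM (empirical Bayes),
#' each M-step maximising the total evidence lower bound, which therefore
#' increases monotonically every iteration.
#'
#' @param er an [expression_result] (means + sds per gene and array).
#' @param hyper "estimate", or a list with numeric `mu0`, `eta0`, `alpha`,
#'   `beta`.
#' @param tol relative ELBO change declaring convergence.
#' @param maxit iteration cap.
#' @return An object of class `combined_condition`: posterior mean/var of
#'   mu_j per gene (`mu`, `var`), Gamma parameters of q(lambda)
#'   (`lambda_shape`, `lambda_rate`), per-replicate posterior moments of the
#'   latent x (`x_mean`, `x_var`), fitted `hyper`, `elbo` trace, `converged`.
#' @export
combine_replicates_ipplr <- function(er, hyper = "estimate",
                                     tol = 1e-6, maxit = 500) {
  stopifnot(inherits(er, "expression_result"))
  xh <- er$mean
  s2 <- er$sd^2
  if (any(!is.finite(xh)) || any(!is.finite(s2)) || any(s2 <= 0))
    stop_value("expression means/variances must be finite, variances > 0")
  cond <- er$design$condition
  conds <- unique(cond)
  J <- length(conds)
  G <- nrow(xh)
  ci <- match(cond, conds)                  # array -> condition index
  Rj <- tabulate(ci, J)
  N <- ncol(xh)

  estimate <- identical(hyper, "estimate")
  if (!estimate) {
    if (!all(c("mu0", "eta0", "alpha", "beta") %in% names(hyper)))
      stop_usage("hyper must be \"estimate\" or a list with mu0, eta0, alpha, beta")
    hy <- hyper
  } else {
    hy <- list(mu0 = mean(xh), eta0 = 1, alpha = 1, beta = 1)
  }

  # per-condition aggregation helper: genes x arrays -> genes x J
  aggJ <- function(m) {
    out <- matrix(0, G, J)
    for (j in seq_len(J))
      out[, j] <- rowSums(m[, ci == j, drop = FALSE])
    out
  }

  # initial variational state
  mx <- xh; vx <- s2
  w <- 1 / s2
  mu <- aggJ(xh * w) / aggJ(w)
  vu <- 1 / aggJ(w)
  resid2 <- (xh - mu[, ci, drop = FALSE])^2
  al <- rep(hy$alpha + N / 2, G)
  bl <- hy$beta + 0.5 * rowSums(resid2) + 1e-8

  gamma_entropy <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)

  elbo <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    El <- al / bl
    Ell <- digamma(al) - log(bl)

    # q(x_ij): Gaussian, precision 1/s2 + E[lambda]
    px <- 1 / s2 + El
    mx <- (xh / s2 + El * mu[, ci, drop = FALSE]) / px
    vx <- 1 / px

    # q(mu_j): Gaussian, precision eta0 + R_j E[lambda]
    pu <- matrix(hy$eta0, G, J) + outer(El, Rj)
    mu <- (hy$eta0 * hy$mu0 + El * aggJ(mx)) / pu
    vu <- 1 / pu

    # q(lambda): Gamma
    dev2 <- (mx - mu[, ci, drop = FALSE])^2 + vx + vu[, ci, drop = FALSE]
    al <- rep(hy$alpha + N / 2, G)
    bl <- hy$beta + 0.5 * rowSums(dev2)
    El <- al / bl
    Ell <- digamma(al) - log(bl)

    # M-step for shared hyperparameters (empirical Bayes)
    if (estimate) {
      hy$mu0 <- mean(mu)
      hy$eta0 <- 1 / max(mean((mu - hy$mu0)^2 + vu), 1e-12)
      S1 <- mean(Ell); S2 <- mean(El)
      f <- function(la) {
        a <- exp(la)
        a * log(a / S2) - lgamma(a) + (a - 1) * S1 - a
      }
      opt <- stats::optimize(f, c(-12, 12), maximum = TRUE, tol = 1e-10)
      hy$alpha <- exp(opt$maximum)
      hy$beta <- hy$alpha / S2
    }

    # ELBO
    dev2 <- (mx - mu[, ci, drop = FALSE])^2 + vx + vu[, ci, drop = FALSE]
    t1 <- -0.5 * sum(log(2 * pi * s2) + ((xh - mx)^2 + vx) / s2)
    t2 <- 0.5 * sum(Ell * N) - 0.5 * G * N * log(2 * pi) -
      0.5 * sum(El * rowSums(dev2))
    t3 <- 0.5 * sum(log(hy$eta0) - log(2 * pi) -
                      hy$eta0 * ((mu - hy$mu0)^2 + vu))
    t4 <- sum(hy$alpha * log(hy$beta) - lgamma(hy$alpha) +
                (hy$alpha - 1) * Ell - hy$beta * El)
    h <- 0.5 * sum(log(2 * pi * exp(1) * vx)) +
      0.5 * sum(log(2 * pi * exp(1) * vu)) +
      sum(gamma_entropy(al, bl))
    elbo <- c(elbo, t1 + t2 + t3 + t4 + h)
    if (it > 1L &&
        abs(elbo[it] - elbo[it - 1L]) < tol * (abs(elbo[it - 1L]) + 1e-3)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("variational EM did not reach tolerance within ", maxit,
            " iterations; returning last iterate")

  dimnames(mu) <- dimnames(vu) <- list(rownames(xh), conds)
  structure(list(mu = mu, var = vu,
                 lambda_shape = al, lambda_rate = bl,
                 x_mean = mx, x_var = vx,
                 hyper = hy, conditions = conds, design = er$design,
                 elbo = elbo, converged = converged,
                 target_ids = rownames(xh)),
            class = "combined_condition")
}

#' Probability of positive log-ratio
#'
#' PPLR = P(mu_treatment - mu_control > 0) under the (independent) Gaussian
#' variational posteriors of the two condition means:
#' Phi((m_t - m_c) / sqrt(v_t + v_c)). Values near 1 indicate up-regulation
#' in the treatment, near 0 down-regulation, 0.5 no evidence.
#'
#' @param comb a `combined_condition` from [combine_replicates_ipplr()].
#' @param treatment,control condition labels.
#' @return Named numeric vector of PPLR values per gene, in `[0, 1]`.
#' @export
pplr_score <- function(comb, treatment, control) {
  stopifnot(inherits(comb, "combined_condition"))
  for (lab in c(treatment, control))
    if (!lab %in% comb$conditions)
      stop_usage("unknown condition label '%s'", lab)
  z <- (comb$mu[, treatment] - comb$mu[, control]) /
    sqrt(comb$var[, treatment] + comb$var[, control])
  stats::setNames(stats::pnorm(z), comb$target_ids)
}

#' Rank genes by evidence of differential expression
#'
#' Direction is "+" when PPLR > 0.5 (up-regulated in the treatment) and "-"
#' when PPLR < 0.5; the probability of differential expression is
#' max(PPLR, 1 - PPLR). Genes are ranked by that probability, descending,
#' with ties broken lexicographically by gene id. No multiplicity
#' adjustment is applied: the PPLR ranking itself is the result.
#'
#' @param pplr named numeric vector of PPLR values in `[0, 1]`.
#' @return An object of class `de_result`: data.frame with columns `gene`,
#'   `pplr`, `direction`, `prob_de`, `rank`, sorted by rank.
#' @export
rank_de <- function(pplr) {
  if (any(!is.finite(pplr) | pplr < 0 | pplr > 1))
    stop_value("PPLR values must lie in [0, 1]")
  genes <- names(pplr) %||% as.character(seq_along(pplr))
  prob_de <- pmax(pplr, 1 - pplr)
  direction <- ifelse(pplr > 0.5, "+", ifelse(pplr < 0.5, "-", "0"))
  ord <- order(-prob_de, genes)
  out <- data.frame(gene = genes[ord], pplr = unname(pplr[ord]),
                    direction = direction[ord], prob_de = unname(prob_de[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}
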