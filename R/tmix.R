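#' Replicated expression profiles with measurement error, for clustering
#'
#' Holds, for every gene n, condition j and replicate i, the measured log2
#' expression x_nji and its measurement-error variance s_nji (the square of
#' the sd that the summarisation models report). All genes share one design.
#'
#' @param mean genes x columns matrix of log2 expression, target ids as
#'   rownames.
#' @param var matrix of the same shape with strictly positive measurement
#'   variances.
#' @param design an [array_design] matching the columns.
#' @return An object of class `cluster_input`.
#' @export
cluster_input <- function(mean, var, design) {
  if (!is.matrix(mean) || !is.matrix(var) || !all(dim(mean) == dim(var)))
    stop_schema("mean and var must be matrices of identical shape")
  if (any(!is.finite(var) | var <= 0))
    stop_value("measurement variances must be finite and > 0")
  if (!inherits(design, "array_design") || ncol(mean) != nrow(design))
    stop_schema("design must be an array_design matching the columns")
  if (is.null(rownames(mean))) rownames(mean) <- paste0("g", seq_len(nrow(mean)))
  structure(list(mean = mean, var = var, design = design),
            class = "cluster_input")
}

#' @rdname cluster_input
#' @param er an [expression_result]; its sds are squared into variances.
#' @export
as_cluster_input <- function(er) {
  stopifnot(inherits(er, "expression_result"))
  cluster_input(er$mean, er$sd^2, er$design)
}

#' Options for the t-mixture variational EM
#'
#' @param tol relative free-energy change declaring convergence.
#' @param maxit iteration cap.
#' @param n_starts k-means++ multistarts; the best free energy is kept.
#' @param seed integer seed for initialisation.
#' @param fix_nu if non-NULL, all degrees of freedom are held at this value
#'   instead of being estimated (large values give the Gaussian limit).
#' @param fix_eta if non-NULL, the per-gene replicate precision eta_n is
#'   held at this constant (its Gamma prior and update are switched off).
#' @param nu_init,nu_range initial value and search bracket for the degrees
#'   of freedom.
#' @param min_var absolute floor on component variances.
#' @param min_var_frac relative floor: component variances are kept above
#'   this fraction of the per-dimension variance of the condition-mean
#'   profiles, which prevents the likelihood singularities that arise when
#'   a component collapses onto a handful of near-identical genes.
#' @export
tmix_options <- function(tol = 1e-6, maxit = 1000, n_starts = 3, seed = 1,
                         fix_nu = NULL, fix_eta = NULL, nu_init = 20,
                         nu_range = c(0.1, 200), min_var = 1e-8,
                         min_var_frac = 0.05) {
  list(tol = tol, maxit = maxit, n_starts = n_starts, seed = seed,
       fix_nu = fix_nu, fix_eta = fix_eta, nu_init = nu_init,
       nu_range = nu_range, min_var = min_var, min_var_frac = min_var_frac)
}

gamma_entropy <- function(a, b) a - log(b) + lgamma(a) + (1 - a) * digamma(a)

# clamp each column to its central quantile range so that k-means++ seeding
# (which favours far points) is not captured by outlying genes
winsorize_cols <- function(x, p = 0.02) {
  for (j in seq_len(ncol(x))) {
    q <- stats::quantile(x[, j], c(p, 1 - p), names = FALSE)
    x[, j] <- pmin(pmax(x[, j], q[1]), q[2])
  }
  x
}

# seeded k-means++ centre selection on the per-condition mean profiles
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(0, K, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  if (K > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (k in 2:K) {
      p <- d2 / sum(d2)
      i <- sample.int(n, 1L, prob = p)
      centers[k, ] <- x[i, ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
    }
  }
  centers
}

# One EM run of the variational t-mixture from a given initialisation.
# weight_rule "ml" keeps all K components; "mml" applies the
# minimum-message-length support threshold and annihilates components whose
# (penalised) weight drops to zero.
tmix_em <- function(x, s2, ci, Rj, init, opts, weight_rule = "ml", kmin = 1L) {
  G <- nrow(x); J <- length(Rj); Nn <- ncol(x)
  Np <- 2L * J + 3L
  vfloor <- pmax(opts$min_var, init$vfloor %||% 0)
  aggJ <- function(m) {
    out <- matrix(0, G, J)
    for (j in seq_len(J)) out[, j] <- rowSums(m[, ci == j, drop = FALSE])
    out
  }

  muk <- init$muk; Sk <- init$Sk; Pi <- init$Pi
  K <- nrow(muk)
  nu <- rep(opts$fix_nu %||% opts$nu_init, K)
  r <- init$r
  fix_eta <- !is.null(opts$fix_eta)
  if (fix_eta) {
    Eeta <- rep(opts$fix_eta, G); Elogeta <- rep(log(opts$fix_eta), G)
    alpha_k <- beta_k <- rep(NA_real_, K)
  } else {
    Eeta <- rep(init$Eeta0, G); Elogeta <- rep(log(init$Eeta0), G)
    alpha_k <- rep(2, K); beta_k <- rep(2 / init$Eeta0, K)
  }
  mw <- init$mw; vw <- init$vw
  mt <- x; vt <- s2
  Eu <- matrix(1, G, K); Elogu <- matrix(0, G, K)
  au <- (nu + J) / 2; bu <- matrix(1, G, K)

  free_energy <- numeric(0)
  converged <- FALSE

  delta_mat <- function(mw, vw) {
    D <- matrix(0, G, K)
    for (k in seq_len(K))
      D[, k] <- rowSums(sweep(sweep(mw, 2L, muk[k, ])^2 + vw, 2L, Sk[k, ], `/`))
    D
  }

  for (it in seq_len(opts$maxit)) {
    ## E-step ------------------------------------------------------------
    # q(t): Gaussian, combines the measurement and replicate layers
    pt <- 1 / s2 + Eeta
    mt <- (x / s2 + Eeta * mw[, ci, drop = FALSE]) / pt
    vt <- 1 / pt

    # q(w): Gaussian over condition-mean profiles
    W <- r * Eu
    pw <- outer(Eeta, Rj) + W %*% (1 / Sk)
    mw <- (Eeta * aggJ(mt) + W %*% (muk / Sk)) / pw
    vw <- 1 / pw

    # q(eta): Gamma (replicate precision, shared across conditions per gene)
    SSt <- rowSums((mt - mw[, ci, drop = FALSE])^2 + vt + vw[, ci, drop = FALSE])
    if (!fix_eta) {
      ae <- as.vector(r %*% alpha_k) + Nn / 2
      be <- as.vector(r %*% beta_k) + 0.5 * SSt
      Eeta <- ae / be
      Elogeta <- digamma(ae) - log(be)
    }

    # q(u | z = k): Gamma (t-distribution scale latents)
    Delta <- delta_mat(mw, vw)
    au <- (nu + J) / 2
    bu <- sweep(Delta, 2L, nu, `+`) / 2
    Eu <- sweep(1 / bu, 2L, au, `*`)
    Elogu <- sweep(-log(bu), 2L, digamma(au), `+`)

    # q(z): responsibilities
    lq_u <- matrix(0, G, K)                   # E[log q(u | z = k)]
    for (k in seq_len(K))
      lq_u[, k] <- au[k] * log(bu[, k]) - lgamma(au[k]) +
        (au[k] - 1) * Elogu[, k] - au[k]
    lrho <- matrix(log(Pi), G, K, byrow = TRUE) +
      0.5 * J * Elogu -
      0.5 * matrix(rowSums(log(Sk)), G, K, byrow = TRUE) -
      0.5 * J * log(2 * pi) - 0.5 * Eu * Delta +
      matrix(nu / 2 * log(nu / 2) - lgamma(nu / 2), G, K, byrow = TRUE) +
      sweep(Elogu, 2L, nu / 2 - 1, `*`) - sweep(Eu, 2L, nu / 2, `*`) -
      lq_u
    if (!fix_eta)
      lrho <- lrho + outer(Elogeta, alpha_k - 1) +
        matrix(alpha_k * log(beta_k) - lgamma(alpha_k), G, K, byrow = TRUE) -
        outer(Eeta, beta_k)
    lrho <- lrho - apply(lrho, 1L, max)
    r <- exp(lrho)
    r <- r / rowSums(r)

    ## M-step ------------------------------------------------------------
    Nk <- colSums(r)
    if (weight_rule == "mml") {
      w_raw <- pmax(0, Nk - Np / 2)
      # never annihilate below the requested minimum number of components
      if (sum(w_raw > 0) < kmin || sum(w_raw) <= 0) w_raw <- Nk
      Pi <- w_raw / sum(w_raw)
    } else {
      Pi <- Nk / G
    }
    # annihilate dead components
    alive <- Pi > 0 & Nk > 1e-10
    if (sum(alive) < kmin) alive <- alive | rank(-Nk) <= kmin
    if (!all(alive)) {
      keep <- which(alive)
      muk <- muk[keep, , drop = FALSE]; Sk <- Sk[keep, , drop = FALSE]
      Pi <- Pi[keep] / sum(Pi[keep]); nu <- nu[keep]
      alpha_k <- alpha_k[keep]; beta_k <- beta_k[keep]
      r <- r[, keep, drop = FALSE]; r <- r / rowSums(r)
      Eu <- Eu[, keep, drop = FALSE]; Elogu <- Elogu[, keep, drop = FALSE]
      au <- au[keep]; bu <- bu[, keep, drop = FALSE]
      K <- length(keep); Nk <- colSums(r)
      Delta <- delta_mat(mw, vw)
    }

    W <- r * Eu
    sw <- colSums(W)
    muk <- (t(W) %*% mw) / sw
    for (k in seq_len(K))
      Sk[k, ] <- pmax(colSums(W[, k] * (sweep(mw, 2L, muk[k, ])^2 + vw)) / Nk[k],
                      vfloor)
    if (is.null(opts$fix_nu)) {
      stat <- colSums(r * (Elogu - Eu))
      for (k in seq_len(K)) {
        h <- function(lnu) {
          v <- exp(lnu)
          Nk[k] * (v / 2 * log(v / 2) - lgamma(v / 2)) + v / 2 * stat[k]
        }
        nu[k] <- exp(stats::optimize(h, log(opts$nu_range), maximum = TRUE,
                                     tol = 1e-8)$maximum)
      }
    }
    if (!fix_eta) {
      S1 <- as.vector(crossprod(r, Elogeta)) / Nk
      S2 <- as.vector(crossprod(r, Eeta)) / Nk
      for (k in seq_len(K)) {
        f <- function(la) {
          a <- exp(la)
          a * log(a / S2[k]) - lgamma(a) + (a - 1) * S1[k] - a
        }
        alpha_k[k] <- exp(stats::optimize(f, c(-6, 8), maximum = TRUE,
                                          tol = 1e-8)$maximum)
        beta_k[k] <- alpha_k[k] / S2[k]
      }
    }

    ## free energy --------------------------------------------------------
    Delta <- delta_mat(mw, vw)
    A <- -0.5 * sum(log(2 * pi * s2) + ((x - mt)^2 + vt) / s2)
    B <- 0.5 * Nn * sum(Elogeta) - 0.5 * G * Nn * log(2 * pi) -
      0.5 * sum(Eeta * SSt)
    Cc <- sum(r * (0.5 * J * Elogu -
                     0.5 * matrix(rowSums(log(Sk)), G, K, byrow = TRUE) -
                     0.5 * J * log(2 * pi) - 0.5 * Eu * Delta))
    Dd <- sum(r * (sweep(Elogu, 2L, nu / 2 - 1, `*`) -
                     sweep(Eu, 2L, nu / 2, `*`) +
                     matrix(nu / 2 * log(nu / 2) - lgamma(nu / 2),
                            G, K, byrow = TRUE)))
    Ee <- if (fix_eta) 0 else
      sum(r * (outer(Elogeta, alpha_k - 1) - outer(Eeta, beta_k) +
                 matrix(alpha_k * log(beta_k) - lgamma(alpha_k),
                        G, K, byrow = TRUE)))
    lPi <- ifelse(Pi > 0, log(Pi), 0)
    Fz <- sum(sweep(r, 2L, lPi, `*`))
    Hq <- 0.5 * sum(log(2 * pi * exp(1) * vt)) +
      0.5 * sum(log(2 * pi * exp(1) * vw)) +
      (if (fix_eta) 0 else sum(gamma_entropy(ae, be))) +
      sum(ifelse(r > 0, -r * log(r), 0))
    for (k in seq_len(K))
      Hq <- Hq + sum(r[, k] * gamma_entropy(au[k], bu[, k]))
    fe <- A + B + Cc + Dd + Ee + Fz + Hq
    free_energy <- c(free_energy, fe)
    nfe <- length(free_energy)
    if (nfe > 1L &&
        abs(free_energy[nfe] - free_energy[nfe - 1L]) <
          opts$tol * (abs(free_energy[nfe - 1L]) + 1e-3)) {
      converged <- TRUE
      break
    }
  }

  dimnames(r) <- list(rownames(x), NULL)
  structure(list(K = K, weights = Pi, centers = muk, covariances = Sk,
                 dof = nu, eta_shape = alpha_k, eta_rate = beta_k,
                 responsibilities = r,
                 w_mean = mw, w_var = vw,
                 free_energy = free_energy,
                 elbo = free_energy[length(free_energy)],
                 converged = converged, n_genes = G, n_conditions = J,
                 opts = opts),
            class = "cluster_fit")
}

tmix_prepare <- function(data) {
  cond <- data$design$condition
  conds <- unique(cond)
  ci <- match(cond, conds)
  Rj <- tabulate(ci, length(conds))
  xbar <- matrix(0, nrow(data$mean), length(conds))
  for (j in seq_along(conds))
    xbar[, j] <- rowMeans(data$mean[, ci == j, drop = FALSE])
  # pooled within-condition replicate variance (for the eta initialisation)
  vrep <- 0; nv <- 0
  for (j in seq_along(conds)) {
    if (Rj[j] > 1L) {
      vrep <- vrep + sum(apply(data$mean[, ci == j, drop = FALSE], 1L, stats::var))
      nv <- nv + nrow(data$mean)
    }
  }
  vrep <- if (nv > 0) vrep / nv else 1
  list(ci = ci, Rj = Rj, conds = conds, xbar = xbar,
       dimvar = apply(xbar, 2L, stats::var),
       Eeta0 = 1 / max(vrep, 1e-6))
}

tmix_init <- function(prep, K, opts, start_id) {
  xbar <- winsorize_cols(prep$xbar)
  G <- nrow(xbar)
  # k-means++ seeding followed by a few Lloyd passes (robust to empty clusters)
  muk <- kmeanspp_centers(xbar, K)
  assign <- integer(G)
  for (pass in 1:10) {
    d2 <- vapply(seq_len(K),
                 function(k) rowSums(sweep(xbar, 2L, muk[k, ])^2),
                 numeric(G))
    assign_new <- max.col(-matrix(d2, G, K), ties.method = "first")
    if (identical(assign_new, assign)) break
    assign <- assign_new
    for (k in seq_len(K))
      if (any(assign == k))
        muk[k, ] <- colMeans(xbar[assign == k, , drop = FALSE])
  }
  Sk <- matrix(0, K, ncol(xbar))
  for (k in seq_len(K)) {
    xi <- xbar[assign == k, , drop = FALSE]
    v <- if (nrow(xi) > 1L) apply(xi, 2L, stats::var) else rep(1, ncol(xbar))
    Sk[k, ] <- pmax(v, 1e-3)
  }
  sizes <- tabulate(assign, K)
  r <- matrix(0.1 / K, G, K)
  r[cbind(seq_len(G), assign)] <- r[cbind(seq_len(G), assign)] + 0.9
  list(muk = muk, Sk = Sk, Pi = pmax(sizes, 1) / sum(pmax(sizes, 1)),
       r = r, mw = prep$xbar,
       vw = matrix(1 / (prep$Eeta0 * mean(prep$Rj)), G, ncol(prep$xbar)),
       Eeta0 = prep$Eeta0, vfloor = opts$min_var_frac * prep$dimvar)
}

#' Fit a robust Student's-t mixture to replicated expression profiles
#'
#' Clusters genes by their condition-mean profiles w_n while propagating two
#' layers of noise: the known per-value measurement variance s_nji
#' (x_nji ~ N(t_nji, s_nji)) and the gene-specific technical/biological
#' replicate variability (t_nji ~ N(w_nj, 1/eta_n), with eta_n shared
#' across conditions and given a per-component Gamma prior). The profile
#' w_n follows a K-component mixture of Student's-t distributions,
#' written as Gaussians whose precisions are scaled by a Gamma latent u_n,
#' which gives the heavy tails that make the clustering robust to outlying
#' genes. Inference is a variational EM with closed-form E-step updates
#' (Gaussian for t and w, Gamma for eta and u, multinomial for z) and
#' closed-form M-step except the degrees of freedom, found by 1-D search.
#' Component covariances are diagonal.
#'
#' @param data a [cluster_input].
#' @param K number of components (1 <= K <= number of genes).
#' @param opts see [tmix_options()].
#' @return An object of class `cluster_fit` with elements `K`, `weights`,
#'   `centers` (K x conditions), `covariances` (diagonal, K x conditions),
#'   `dof`, `eta_shape`/`eta_rate`, `responsibilities`, `free_energy`
#'   trace and `converged`.
#' @export
fit_tmixture <- function(data, K, opts = tmix_options()) {
  stopifnot(inherits(data, "cluster_input"))
  if (K < 1L) stop_usage("K must be >= 1")
  if (K > nrow(data$mean)) stop_usage("K exceeds the number of genes")
  prep <- tmix_prepare(data)
  fits <- with_seed(opts$seed, {
    lapply(seq_len(opts$n_starts), function(s) {
      init <- tmix_init(prep, K, opts, s)
      tmix_em(data$mean, data$var, prep$ci, prep$Rj, init, opts, "ml")
    })
  })
  best <- fits[[which.max(vapply(fits, `[[`, 0, "elbo"))]]
  colnames(best$centers) <- colnames(best$covariances) <- prep$conds
  best
}

#' Minimum-message-length score of a mixture fit
#'
#' Two-part message length in the Figueiredo-Jain form:
#' -loglik + (Np/2) * sum over nonzero-weight components of
#' log(n Pi_k / 12) + (Knz/2) log(n/12) + Knz (Np + 1)/2, where Np is the
#' number of free parameters per component (centre + diagonal covariance +
#' dof + the two Gamma parameters of the replicate-precision prior) and Knz
#' the number of surviving components. The variational free energy stands
#' in for the (intractable) log-likelihood. Smaller is better; components
#' with zero weight contribute nothing.
#'
#' @param fit a `cluster_fit`.
#' @param n_genes number of clustered genes.
#' @return scalar message length.
#' @export
message_length <- function(fit, n_genes = fit$n_genes) {
  Np <- 2L * fit$n_conditions + 3L
  nz <- fit$weights > 0
  Knz <- sum(nz)
  -fit$elbo + Np / 2 * sum(log(n_genes * fit$weights[nz] / 12)) +
    Knz / 2 * log(n_genes / 12) + Knz * (Np + 1) / 2
}

#' Cluster with automatic selection of the number of components
#'
#' Starts from `maxcls` components and runs the variational EM with the
#' minimum-message-length weight rule, under which components whose support
#' falls below Np/2 observations are annihilated during fitting. After
#' convergence the weakest surviving component is removed and fitting
#' resumes, down to `mincls`; the model with the smallest message length
#' over all visited K is returned.
#'
#' @param data a [cluster_input].
#' @param mincls,maxcls smallest / largest number of components considered.
#' @param opts see [tmix_options()].
#' @return An object of class `cluster_result`: `K` (selected), `membership`
#'   (hard assignments), `fit` (the selected `cluster_fit`), and `trace`
#'   (data.frame of visited K and message length).
#' @export
select_k_mml <- function(data, mincls = 1, maxcls = 8, opts = tmix_options()) {
  stopifnot(inherits(data, "cluster_input"))
  if (mincls < 1 || mincls > maxcls || maxcls > nrow(data$mean))
    stop_usage("need 1 <= mincls <= maxcls <= number of genes")
  prep <- tmix_prepare(data)
  trace_K <- integer(0); trace_ml <- numeric(0)
  best_fit <- NULL; best_ml <- Inf
  with_seed(opts$seed, {
    init <- tmix_init(prep, maxcls, opts, 1L)
    fit <- tmix_em(data$mean, data$var, prep$ci, prep$Rj, init, opts, "mml",
                   kmin = mincls)
    repeat {
      ml <- message_length(fit)
      trace_K <- c(trace_K, fit$K); trace_ml <- c(trace_ml, ml)
      if (fit$K >= mincls && ml < best_ml) {
        best_ml <- ml; best_fit <- fit
      }
      if (fit$K <= mincls) break
      # force-kill the weakest component and continue
      drop <- which.min(fit$weights)
      keep <- setdiff(seq_len(fit$K), drop)
      r <- fit$responsibilities[, keep, drop = FALSE]
      r <- r / pmax(rowSums(r), 1e-12)
      init2 <- list(muk = fit$centers[keep, , drop = FALSE],
                    Sk = fit$covariances[keep, , drop = FALSE],
                    Pi = fit$weights[keep] / sum(fit$weights[keep]),
                    r = r, mw = fit$w_mean, vw = fit$w_var,
                    Eeta0 = prep$Eeta0,
                    vfloor = opts$min_var_frac * prep$dimvar)
      fit <- tmix_em(data$mean, data$var, prep$ci, prep$Rj, init2, opts, "mml",
                     kmin = mincls)
    }
  })
  colnames(best_fit$centers) <- colnames(best_fit$covariances) <- prep$conds
  structure(list(K = best_fit$K,
                 membership = apply(best_fit$responsibilities, 1L, which.max),
                 fit = best_fit,
                 trace = data.frame(K = trace_K, message_length = trace_ml)),
            class = "cluster_result")
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("cluster_fit: K=%d, %d genes, %d conditions, converged=%s\n",
              x$K, x$n_genes, x$n_conditions, x$converged))
  invisible(x)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: selected K=%d (visited: %s)\n",
              x$K, paste(x$trace$K, collapse = ", ")))
  invisible(x)
}
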