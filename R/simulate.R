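#' Simulate probe intensities from the multi-mapping gamma model
#'
#' Draws one dataset from the generative model behind [fit_gme_gene()]:
#' per gene, a probe effect beta_j ~ Gamma(c_g, rate d_g) shared by all
#' isoforms, isoform contributions s_jkc ~ Gamma(alpha_kc, rate beta_j),
#' and observed intensity y_jc = sum over mapped isoforms of s_jkc. Each
#' probe maps to one isoform, plus (with probability `mapping_overlap`) a
#' second isoform of the same gene, emulating probes falling in shared
#' exons. Parameter defaults emulate raw microarray intensity scales.
#'
#' @param n_genes,isoforms_per_gene,probes_per_gene,n_arrays scenario size.
#' @param mapping_overlap fraction of probes mapped to more than one
#'   isoform, in `[0, 1]`.
#' @param param_ranges list with `alpha` (range of alpha_kc), `c` (range of
#'   c_g) and `d` (range of d_g); each parameter is drawn log-uniformly.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @return List with `panel` (a [probe_panel]), `mapping`
#'   (a [mapping_table]) and `truth` (a `sim_truth` carrying the drawn
#'   alpha, c, d per gene).
#' @export
simulate_gme <- function(n_genes = 1, isoforms_per_gene = 2,
                         probes_per_gene = 8, n_arrays = 4,
                         mapping_overlap = 0.5,
                         param_ranges = list(alpha = c(2, 30),
                                             c = c(2, 8), d = c(0.05, 1)),
                         seed = 1) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 1, probes_per_gene >= 1,
            n_arrays >= 1, mapping_overlap >= 0, mapping_overlap <= 1)
  runiflog <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  with_seed(seed, {
    links <- list(); truth <- list(); rows <- list()
    for (g in seq_len(n_genes)) {
      gid <- sprintf("g%03d", g)
      tids <- sprintf("%s_t%d", gid, seq_len(isoforms_per_gene))
      alpha <- matrix(runiflog(isoforms_per_gene * n_arrays, param_ranges$alpha),
                      isoforms_per_gene, n_arrays,
                      dimnames = list(tids, NULL))
      cg <- runiflog(1, param_ranges$c)
      dg <- runiflog(1, param_ranges$d)
      beta <- stats::rgamma(probes_per_gene, cg, rate = dg)
      pm <- matrix(0, probes_per_gene, isoforms_per_gene)
      for (j in seq_len(probes_per_gene)) {
        k1 <- 1 + (j - 1) %% isoforms_per_gene
        pm[j, k1] <- 1
        if (isoforms_per_gene > 1 && stats::runif(1) < mapping_overlap)
          pm[j, sample(setdiff(seq_len(isoforms_per_gene), k1), 1L)] <- 1
      }
      y <- matrix(0, probes_per_gene, n_arrays)
      for (j in seq_len(probes_per_gene))
        for (k in which(pm[j, ] == 1))
          y[j, ] <- y[j, ] + stats::rgamma(n_arrays, alpha[k, ], rate = beta[j])
      pids <- sprintf("%s_p%02d", gid, seq_len(probes_per_gene))
      rownames(y) <- pids
      rows[[g]] <- y
      links[[g]] <- do.call(rbind, lapply(seq_len(probes_per_gene), function(j)
        data.frame(probe_id = pids[j], transcript_id = tids[pm[j, ] == 1],
                   gene_id = gid, stringsAsFactors = FALSE)))
      truth[[gid]] <- list(alpha = alpha, c = cg, d = dg, beta = beta,
                           incidence = pm)
    }
    y <- do.call(rbind, rows)
    design <- array_design(sprintf("a%d", seq_len(n_arrays)),
                           sprintf("cond%d", seq_len(n_arrays)),
                           rep(1L, n_arrays))
    colnames(y) <- design$array_id
    list(panel = probe_panel(y, design),
         mapping = mapping_table(do.call(rbind, links)),
         truth = structure(list(generator = "gme", seed = seed,
                                params = truth), class = "sim_truth"))
  })
}

#' Simulate replicated expression with measurement error and planted DE
#'
#' Draws from the hierarchical model behind [combine_replicates_ipplr()]:
#' per gene, lambda ~ Gamma(alpha, beta) and a baseline expression level
#' mu ~ N(mu0, 1/eta0) shared by all conditions; genes planted as
#' differentially expressed have their condition-2 mean shifted by
#' +/- `effect_size` (sign drawn at random), so non-DE genes are exact
#' nulls. Latent replicate values x_ij ~ N(mu_j, 1/lambda) are observed as
#' xhat_ij ~ N(x_ij, s_ij^2) with measurement variances drawn uniformly
#' from `noise_range`. Defaults emulate log2 microarray expression
#' (means around 7, measurement sd up to ~1).
#'
#' @param n_genes,n_conditions,replicates scenario size (`replicates` may
#'   be a scalar or per-condition vector).
#' @param hyper list with `mu0`, `eta0`, `alpha`, `beta`.
#' @param de_fraction fraction of genes planted as DE in condition 2.
#' @param effect_size absolute shift (log2) of DE genes.
#' @param noise_range range of measurement variances s_ij^2.
#' @param seed integer seed.
#' @return List with `er` (an [expression_result]) and `truth`
#'   (a `sim_truth` with per-gene DE sign in `de_sign`, 0 for non-DE).
#' @export
simulate_ipplr <- function(n_genes = 200, n_conditions = 2, replicates = 3,
                           hyper = list(mu0 = 7, eta0 = 1, alpha = 2, beta = 1),
                           de_fraction = 0.2, effect_size = 1,
                           noise_range = c(0.02, 1), seed = 1) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, n_conditions >= 2)
  reps <- if (length(replicates) == 1L) rep(replicates, n_conditions) else replicates
  stopifnot(length(reps) == n_conditions)
  with_seed(seed, {
    conds <- sprintf("cond%d", seq_len(n_conditions))
    design <- array_design(
      unlist(lapply(seq_len(n_conditions), function(j)
        sprintf("%s_r%d", conds[j], seq_len(reps[j])))),
      rep(conds, reps),
      unlist(lapply(reps, seq_len)))
    ci <- match(design$condition, conds)
    N <- nrow(design)
    genes <- sprintf("g%04d", seq_len(n_genes))
    n_de <- round(de_fraction * n_genes)
    de_sign <- integer(n_genes)
    if (n_de > 0)
      de_sign[seq_len(n_de)] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    lambda <- stats::rgamma(n_genes, hyper$alpha, rate = hyper$beta)
    mu <- matrix(stats::rnorm(n_genes, hyper$mu0, 1 / sqrt(hyper$eta0)),
                 n_genes, n_conditions)
    mu[, 2] <- mu[, 2] + de_sign * effect_size
    s2 <- matrix(stats::runif(n_genes * N, noise_range[1], noise_range[2]),
                 n_genes, N)
    x <- mu[, ci, drop = FALSE] +
      matrix(stats::rnorm(n_genes * N), n_genes, N) / sqrt(lambda)
    xhat <- x + matrix(stats::rnorm(n_genes * N), n_genes, N) * sqrt(s2)
    rownames(xhat) <- rownames(s2) <- genes
    er <- expression_result(xhat, sqrt(s2), design, "gene")
    truth <- structure(list(generator = "ipplr", seed = seed,
                            params = list(hyper = hyper,
                                          effect_size = effect_size,
                                          noise_range = noise_range),
                            de_sign = stats::setNames(de_sign, genes),
                            mu = mu, lambda = lambda, x = x),
                       class = "sim_truth")
    list(er = er, truth = truth)
  })
}

#' Simulate replicated expression profiles with planted t-mixture clusters
#'
#' Draws from the generative model behind [fit_tmixture()]: component
#' z_n ~ Pi, scale u_n ~ Gamma(nu_k/2, nu_k/2), profile w_n ~
#' N(mu_k, Sigma_k / u_n), replicate precision eta_n ~ Gamma(alpha_k,
#' beta_k), replicate truth t_nji ~ N(w_nj, 1/eta_n) and observed value
#' x_nji ~ N(t_nji, s_nji) with measurement sds drawn uniformly from
#' `measurement_sd_range` and squared into the variances s_nji. Defaults
#' emulate log2 expression profiles with per-value measurement sds in the
#' range typical of probe-level summarisation output.
#'
#' @param n_genes number of genes.
#' @param centers K x conditions matrix of component centres.
#' @param scales per-component diagonal variance (scalar or K-vector).
#' @param weights component weights (default uniform).
#' @param nu degrees of freedom (scalar or K-vector).
#' @param eta_params list with `alpha`, `beta` for the replicate precision.
#' @param replicates replicates per condition (scalar or vector).
#' @param measurement_sd_range range of the measurement sds (log2 scale).
#' @param seed integer seed.
#' @return List with `data` (a [cluster_input]) and `truth` (a `sim_truth`
#'   with planted memberships in `membership`).
#' @export
simulate_clusters <- function(n_genes = 200,
                              centers = rbind(c(4, 8), c(8, 4)),
                              scales = 1, weights = NULL, nu = 30,
                              eta_params = list(alpha = 4, beta = 1),
                              replicates = 3,
                              measurement_sd_range = c(0.1, 0.45),
                              seed = 1) {
  K <- nrow(centers); J <- ncol(centers)
  scales <- rep(scales, length.out = K)
  nu <- rep(nu, length.out = K)
  weights <- weights %||% rep(1 / K, K)
  reps <- rep(replicates, length.out = J)
  with_seed(seed, {
    conds <- sprintf("cond%d", seq_len(J))
    design <- array_design(
      unlist(lapply(seq_len(J), function(j)
        sprintf("%s_r%d", conds[j], seq_len(reps[j])))),
      rep(conds, reps), unlist(lapply(reps, seq_len)))
    ci <- match(design$condition, conds)
    N <- nrow(design)
    z <- sample.int(K, n_genes, replace = TRUE, prob = weights)
    u <- stats::rgamma(n_genes, nu[z] / 2, rate = nu[z] / 2)
    w <- centers[z, , drop = FALSE] +
      matrix(stats::rnorm(n_genes * J), n_genes, J) *
        sqrt(scales[z] / u)
    eta <- stats::rgamma(n_genes, eta_params$alpha, rate = eta_params$beta)
    tmat <- w[, ci, drop = FALSE] +
      matrix(stats::rnorm(n_genes * N), n_genes, N) / sqrt(eta)
    s2 <- matrix(stats::runif(n_genes * N, measurement_sd_range[1],
                              measurement_sd_range[2])^2, n_genes, N)
    x <- tmat + matrix(stats::rnorm(n_genes * N), n_genes, N) * sqrt(s2)
    rownames(x) <- sprintf("g%04d", seq_len(n_genes))
    list(data = cluster_input(x, s2, design),
         truth = structure(list(generator = "clusters", seed = seed,
                                params = list(centers = centers,
                                              scales = scales, nu = nu,
                                              weights = weights,
                                              eta_params = eta_params),
                                membership = z, w = w, u = u, eta = eta),
                           class = "sim_truth"))
  })
}
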