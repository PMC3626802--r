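test_that("gene marginal log-likelihood sums per-(probe, array) compound terms", {
  sim <- simulate_gme(n_genes = 1, isoforms_per_gene = 2, probes_per_gene = 3,
                      n_arrays = 2, mapping_overlap = 1, seed = 4)
  fit <- fit_gme_gene(sim$panel, sim$mapping, "g001", gme_options(seed = 1))
  ll <- gme_marginal_loglik(sim$panel, sim$mapping, fit)
  # recompute by direct quadrature of each probe-effect integral
  dat <- uexpress:::gme_gene_data(sim$panel, sim$mapping, "g001")
  shapes <- dat$Pmat %*% fit$alpha[dat$transcripts, , drop = FALSE]
  manual <- 0
  for (j in seq_len(nrow(dat$y)))
    for (cc in seq_len(ncol(dat$y)))
      manual <- manual + quad_logpdf(dat$y[j, cc], shapes[j, cc], fit$c, fit$d)
  pen <- -sum(c(log(fit$alpha[dat$transcripts, ]), log(fit$c), log(fit$d))^2) / 18
  expect_equal(ll, manual + pen, tolerance = 1e-8)
})

test_that("a single probe/isoform/array reduces to the compound density", {
  m <- matrix(5.5, 1, 1, dimnames = list("p1", NULL))
  panel <- probe_panel(m, tiny_design(1))
  mt <- mapping_table(data.frame(probe_id = "p1", transcript_id = "t1",
                                 gene_id = "g1"))
  fit <- fit_gme_gene(panel, mt, "g1", gme_options(seed = 1))
  ll <- gme_marginal_loglik(panel, mt, fit)
  direct <- compound_gamma_logpdf(5.5, fit$alpha[1, 1], fit$c, fit$d) -
    sum(c(log(fit$alpha[1, 1]), log(fit$c), log(fit$d))^2) / 18
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("shared probes enter the likelihood through the summed shape only", {
  # one probe mapping to two isoforms: swapping the isoform shapes leaves
  # the objective unchanged, so only the sum is identified
  m <- matrix(c(4, 6), 1, 2, dimnames = list("p1", NULL))
  panel <- probe_panel(m, tiny_design(2))
  mt <- mapping_table(data.frame(probe_id = "p1",
                                 transcript_id = c("t1", "t2"),
                                 gene_id = "g1"))
  dat <- uexpress:::gme_gene_data(panel, mt, "g1")
  th1 <- c(log(c(1.2, 0.4, 2.0, 0.8)), log(3), log(1))
  th2 <- c(log(c(0.4, 1.2, 0.8, 2.0)), log(3), log(1))  # isoforms swapped
  expect_equal(uexpress:::gme_objective(th1, dat$y, dat$Pmat, 3),
               uexpress:::gme_objective(th2, dat$y, dat$Pmat, 3),
               tolerance = 1e-12)
  fit <- fit_gme_gene(panel, mt, "g1", gme_options(seed = 2))
  expect_false(fit$diagnostics$identifiable)
})

test_that("analytic gradient matches finite differences", {
  sim <- simulate_gme(n_genes = 1, isoforms_per_gene = 2, probes_per_gene = 5,
                      n_arrays = 3, seed = 9)
  dat <- uexpress:::gme_gene_data(sim$panel, sim$mapping, "g001")
  set.seed(2)
  th <- rnorm(ncol(dat$Pmat) * ncol(dat$y) + 2, 0, 0.5)
  g <- uexpress:::gme_gradient(th, dat$y, dat$Pmat, 3)
  eps <- 1e-6
  for (i in seq_along(th)) {
    tp <- tm <- th; tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
    fd <- (uexpress:::gme_objective(tp, dat$y, dat$Pmat, 3) -
             uexpress:::gme_objective(tm, dat$y, dat$Pmat, 3)) / (2 * eps)
    expect_equal(g[i], fd, tolerance = 1e-5)
  }
})

test_that("constant intensities still yield a finite, terminating fit", {
  m <- matrix(7, 6, 3, dimnames = list(paste0("p", 1:6), NULL))
  panel <- probe_panel(m, tiny_design(3))
  mt <- mapping_table(data.frame(probe_id = paste0("p", 1:6),
                                 transcript_id = "t1", gene_id = "g1"))
  fit <- fit_gme_gene(panel, mt, "g1", gme_options(seed = 1))
  expect_true(is.finite(fit$loglik))
  expect_true(is.finite(fit$c) && fit$c > 0)
})

test_that("parameter recovery is reasonable and improves with more data", {
  err_at <- function(probes, arrays, seeds) {
    sapply(seeds, function(s) {
      sim <- simulate_gme(n_genes = 1, isoforms_per_gene = 2,
                          probes_per_gene = probes, n_arrays = arrays, seed = s)
      tr <- sim$truth$params$g001
      fit <- fit_gme_gene(sim$panel, sim$mapping, "g001", gme_options(seed = s))
      est <- rowSums(fit$alpha[rownames(tr$alpha), , drop = FALSE])
      median(abs(est - rowSums(tr$alpha)) / rowSums(tr$alpha))
    })
  }
  e_small <- median(err_at(8, 4, 1:12))
  e_large <- median(err_at(16, 8, 1:12))
  expect_lt(e_large, e_small)   # error decreases with probes x arrays
  expect_lt(e_small, 0.6)       # sanity scale for the small design
})

test_that("isoform summaries implement the digamma/trigamma moments on log2", {
  des <- tiny_design(1)
  fit <- structure(list(gene_id = "g", alpha = matrix(2, 1, 1,
                          dimnames = list("t1", "a1")),
                        c = 3, d = 1, design = des), class = "gamma_fit")
  er <- summarize_isoform_expression(fit)
  expect_equal(unname(er$mean[1, 1]), -0.5 / log(2), tolerance = 1e-12)
  expect_equal(unname(er$sd[1, 1]), sqrt(trigamma(2) + trigamma(3)) / log(2),
               tolerance = 1e-12)
  expect_equal(er$level, "transcript")
})

test_that("gene summary uses the summed isoform shape", {
  des <- tiny_design(1)
  fit <- structure(list(gene_id = "g",
                        alpha = matrix(c(1, 3), 2, 1,
                                       dimnames = list(c("t1", "t2"), "a1")),
                        c = 2, d = 0.5, design = des), class = "gamma_fit")
  gene <- summarize_gene_expression(fit)
  expect_equal(unname(gene$mean[1, 1]),
               (digamma(4) - digamma(2) + log(0.5)) / log(2), tolerance = 1e-12)
  # single-isoform gene: gene row equals the isoform row exactly
  fit1 <- structure(list(gene_id = "g", alpha = matrix(2.7, 1, 1,
                           dimnames = list("t1", "a1")),
                         c = 2, d = 0.5, design = des), class = "gamma_fit")
  expect_equal(unname(summarize_gene_expression(fit1)$mean),
               unname(summarize_isoform_expression(fit1)$mean))
  # gene log-mean dominates each isoform log-mean (digamma is increasing)
  iso <- summarize_isoform_expression(fit)
  expect_true(all(gene$mean[1, 1] >= iso$mean[, 1]))
})

test_that("whole-panel summarisation returns one row per target", {
  sim <- simulate_gme(n_genes = 3, isoforms_per_gene = 2, probes_per_gene = 6,
                      n_arrays = 2, seed = 6)
  erg <- gme_summarize(sim$panel, sim$mapping, "gene", opts = gme_options(seed = 1))
  expect_equal(nrow(erg$mean), 3L)
  ert <- gme_summarize(sim$panel, sim$mapping, "transcript",
                       opts = gme_options(seed = 1))
  expect_equal(nrow(ert$mean), 6L)
  expect_true(all(ert$sd > 0))
})
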