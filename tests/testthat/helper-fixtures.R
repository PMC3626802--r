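# Small fixture builders shared across test files. Everything is generated
# in code; no data files ship with the tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_design <- function(n = 2, conds = NULL) {
  conds <- conds %||% sprintf("c%d", seq_len(n))
  reps <- stats::ave(seq_len(n), conds, FUN = seq_along)
  uexpress::array_design(sprintf("a%d", seq_len(n)), conds, reps)
}

tiny_panel <- function(values = NULL, n_probes = 4, n_arrays = 2) {
  m <- values %||% matrix(seq_len(n_probes * n_arrays) + 0.5,
                          n_probes, n_arrays)
  rownames(m) <- sprintf("p%d", seq_len(nrow(m)))
  uexpress::probe_panel(m, tiny_design(ncol(m)))
}

tiny_er <- function(mean, sd = NULL, design = NULL, level = "gene") {
  sd <- sd %||% (mean * 0 + 0.3)
  rownames(mean) <- rownames(sd) <- sprintf("g%d", seq_len(nrow(mean)))
  uexpress::expression_result(mean, sd, design %||% tiny_design(ncol(mean)),
                              level)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# numerical quadrature of the probe-effect integral: the independent oracle
# for the compound-gamma closed form
quad_logpdf <- function(y, a, cc, d) {
  f <- function(b) stats::dgamma(y, a, rate = b) * stats::dgamma(b, cc, rate = d)
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
}
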