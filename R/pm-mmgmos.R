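#' Fit the PM-only gamma model for one probe-set
#'
#' PM probe intensities within a probe-set are modelled as
#' y_jc ~ Gamma(alpha_c, rate b_j) with probe effect b_j ~ Gamma(c, rate d);
#' integrating b_j out gives the same compound-gamma marginal as the
#' multi-mapping model restricted to a single isoform that every probe maps
#' to. The fit is therefore delegated to the same MAP optimiser, which makes
#' the structural equivalence exact at the parameter level. Using PM probes
#' only avoids the instability that PM-MM differencing causes for weakly
#' expressed genes, where background exceeds signal.
#'
#' @param panel a [probe_panel] whose probes all belong to the probe-set.
#' @param probeset_id identifier for the probe-set.
#' @param opts see [gme_options()].
#' @return An object of class `pm_gamma_fit`: list with `probeset_id`,
#'   `alpha` (per-array vector), `c`, `d`, `converged`, `loglik`,
#'   `diagnostics`, `design`, `opts`.
#' @export
fit_pm_mmgmos <- function(panel, probeset_id = "probeset", opts = gme_options()) {
  if (nrow(panel$intensities) < 2L)
    warning("probe-set '", probeset_id, "' has a single probe; ",
            "probe effect and signal are weakly separated")
  mapping <- mapping_table(data.frame(
    probe_id = panel$probe_ids,
    transcript_id = probeset_id,
    gene_id = probeset_id, stringsAsFactors = FALSE))
  fit <- fit_gme_gene(panel, mapping, probeset_id, opts)
  structure(list(probeset_id = probeset_id,
                 alpha = fit$alpha[1L, ],
                 c = fit$c, d = fit$d,
                 converged = fit$converged, loglik = fit$loglik,
                 diagnostics = fit$diagnostics,
                 design = fit$design, opts = opts),
            class = "pm_gamma_fit")
}

#' Probe-set expression summary from a PM-only fit
#'
#' Same exact log-moment formulas as the isoform summary, applied to the
#' probe-set shapes: on array c the log2 expression is Gaussian with
#' mean (digamma(alpha_c) - digamma(c) + log d)/log 2 and sd
#' sqrt(trigamma(alpha_c) + trigamma(c))/log 2. Because trigamma is
#' decreasing, weak signal (small alpha) yields large sd: low expression is
#' reported with large, high expression with small, measurement error.
#'
#' @param fit a `pm_gamma_fit`.
#' @return An [expression_result] at level "probeset" with one row.
#' @export
summarize_pm_expression <- function(fit) {
  s <- log2_summary(fit$alpha, fit$c, fit$d)
  m <- matrix(s$mean, 1L, dimnames = list(fit$probeset_id, names(fit$alpha)))
  sd <- matrix(s$sd, 1L, dimnames = list(fit$probeset_id, names(fit$alpha)))
  expression_result(m, sd, fit$design, "probeset")
}

#' Summarise a panel of probe-sets with PM-only multi-mgMOS
#'
#' @param panel a [probe_panel].
#' @param probesets data.frame with columns `probe_id`, `probeset_id`
#'   assigning each probe to one probe-set.
#' @param gsnorm normalisation mode, see [global_scaling_normalize()].
#' @param opts see [gme_options()].
#' @return An [expression_result] at level "probeset", fits attached as
#'   attribute "fits".
#' @export
pm_mmgmos_summarize <- function(panel, probesets, gsnorm = "none",
                                opts = gme_options()) {
  need <- c("probe_id", "probeset_id")
  if (!all(need %in% names(probesets)))
    stop_schema("probesets must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(probesets$probe_id))
    stop_consistency("a probe may belong to only one probe-set")
  panel <- global_scaling_normalize(panel, gsnorm)
  keep <- intersect(panel$probe_ids, probesets$probe_id)
  if (length(keep) == 0L) stop_consistency("no probes of any probe-set in the panel")
  sets <- split(probesets$probe_id, probesets$probeset_id)
  fits <- lapply(names(sets), function(ps) {
    probes <- intersect(panel$probe_ids, sets[[ps]])
    if (length(probes) == 0L) return(NULL)
    sub <- probe_panel(panel$intensities[probes, , drop = FALSE], panel$design)
    fit_pm_mmgmos(sub, ps, opts)
  })
  fits <- Filter(Negate(is.null), fits)
  parts <- lapply(fits, summarize_pm_expression)
  out <- expression_result(do.call(rbind, lapply(parts, `[[`, "mean")),
                           do.call(rbind, lapply(parts, `[[`, "sd")),
                           panel$design, "probeset")
  attr(out, "fits") <- fits
  out
}
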