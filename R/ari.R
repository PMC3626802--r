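#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a clustering and a reference
#' partition, computed from the contingency table:
#' ARI = (sum_ij C(n_ij,2) - E) / (max - E) with
#' E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2). Equals 1 for identical
#' partitions and is 0 in expectation for independent ones.
#'
#' @param memberships,truth vectors of cluster labels, equal length.
#' @return ARI in `[-1, 1]`.
#' @export
evaluate_partition <- function(memberships, truth) {
  if (length(memberships) != length(truth))
    stop_usage("partitions must have equal length")
  n <- length(truth)
  tab <- table(memberships, truth)
  choose2 <- function(x) x * (x - 1) / 2
  sij <- sum(choose2(tab))
  sa <- sum(choose2(rowSums(tab)))
  sb <- sum(choose2(colSums(tab)))
  e <- sa * sb / choose2(n)
  mx <- (sa + sb) / 2
  if (mx == e) return(if (sij == e) 1 else 0)
  (sij - e) / (mx - e)
}
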