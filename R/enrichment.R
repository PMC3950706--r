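# Gene-set enrichment of bound-gene lists: one-sided Fisher's exact test
# (upper-tail hypergeometric) against a gene universe, with
# Benjamini-Hochberg correction across the tested sets.

#' Fisher's exact gene-set enrichment
#'
#' For each gene set, tests whether the bound genes overlap the set more
#' than expected under hypergeometric sampling from the universe:
#' `p = P(X >= k)` with `k = |bound & set|`, `K = |set & universe|`,
#' `n = |bound|`, `N = |universe|`. Set members outside the universe are
#' ignored. Results carry BH-adjusted q-values and are sorted by p, then
#' set name.
#'
#' @param bound Bound gene ids (must be a subset of `universe`).
#' @param universe Universe gene ids.
#' @param sets Named list of gene-id vectors (e.g. from
#'   [read_gene_sets()]).
#' @param alternative Only `"greater"` (enrichment) is offered.
#' @return Data frame `set_name, k_overlap, n_bound, K_set, N_universe,
#'   p_value, q_value`.
#' @export
fisher_enrichment <- function(bound, universe, sets,
                              alternative = c("greater")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  bound <- unique(as.character(bound))
  .chk(length(universe) > 0, "universe must not be empty")
  .chk(all(bound %in% universe), "bound genes must be a subset of the universe")
  .chk(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  N <- length(universe)
  n <- length(bound)
  K <- vapply(sets, function(s) length(intersect(s, universe)), integer(1))
  k <- vapply(sets, function(s) length(intersect(bound, s)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set_name = names(sets), k_overlap = k, n_bound = n,
                    K_set = K, N_universe = N, p_value = p,
                    stringsAsFactors = FALSE)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$set_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: on sorted p-values,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order and
#' clipped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order; every `q >= p`.
#' @export
bh_adjust <- function(p_values) {
  .chk(is.numeric(p_values), "p_values must be numeric")
  .chk(!anyNA(p_values) && all(p_values >= 0 & p_values <= 1),
       "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Build a gene universe for enrichment testing
#'
#' @param sets Named list of gene sets.
#' @param mode `"annotated"` restricts the universe to genes carrying at
#'   least one gene-set annotation (the default); `"all"` uses the
#'   supplied `all_genes`.
#' @param all_genes Character vector of all annotated genes (required for
#'   `mode = "all"`).
#' @return Character vector of universe gene ids.
#' @export
gene_universe <- function(sets, mode = c("annotated", "all"),
                          all_genes = NULL) {
  mode <- match.arg(mode)
  annotated <- unique(unlist(sets, use.names = FALSE))
  if (mode == "annotated") return(annotated)
  .chk(!is.null(all_genes), "all_genes is required for mode = 'all'")
  unique(as.character(all_genes))
}
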