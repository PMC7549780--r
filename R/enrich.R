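#' One-sided Fisher overrepresentation test of a gene set
#'
#' For every term with at least one annotated population gene, tests whether
#' the study set contains more term members than expected under random
#' sampling from the population. The p-value is the hypergeometric upper
#' tail `P(X >= k)` with `k` study genes annotated, `n` study genes, `K`
#' annotated population genes and `N` population genes; BH adjustment is
#' applied over all tested terms.
#'
#' @param study Character vector of study genes (must be a subset of
#'   `population`).
#' @param population Character vector of background genes (the analyzed-gene
#'   universe, not the full annotation).
#' @param annotations Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; rows outside the population are ignored.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"` (doubled one-sided tail, capped at 1).
#' @return Data frame of class `enrichment_result`, one row per tested
#'   term: `term_id`, `term_name`, `k`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `fdr`, `significant` (FDR < 0.05).
#' @export
fisher_overrep <- function(study, population, annotations,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  study <- unique(study)
  population <- unique(population)
  missing <- setdiff(study, population)
  if (length(missing))
    stop("study genes absent from population: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  ann <- annotations[annotations$gene_id %in% population, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id", "term_name"),
                                names(ann)), drop = FALSE])
  if (!nrow(ann))
    return(structure(data.frame(), class = c("enrichment_result",
                                             "data.frame")))
  terms <- split(ann$gene_id, ann$term_id)
  names_by_term <- if ("term_name" %in% names(ann))
    tapply(ann$term_name, ann$term_id, `[`, 1L)
  else stats::setNames(rep(NA_character_, length(terms)), names(terms))
  n <- length(study)
  N <- length(population)
  rows <- lapply(names(terms), function(tid) {
    members <- unique(terms[[tid]])
    K <- length(members)
    k <- length(intersect(study, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    if (alternative == "two.sided") p <- min(1, 2 * min(p, 1 - p +
      stats::dhyper(k, K, N - K, n)))
    data.frame(term_id = tid, term_name = unname(names_by_term[tid]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_bh(out$p_value)
  out$significant <- out$fdr < 0.05
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Report significant terms
#'
#' Filters an enrichment result to terms with FDR strictly below the cutoff
#' and sorts by p-value ascending, breaking ties by term identifier.
#'
#' @param results An `enrichment_result`.
#' @param alpha_fdr FDR cutoff (default 0.05; a term at exactly the cutoff
#'   is excluded).
#' @return The filtered, sorted data frame.
#' @export
term_report <- function(results, alpha_fdr = 0.05) {
  if (!nrow(results)) stop("results must be non-empty")
  keep <- results[results$fdr < alpha_fdr, , drop = FALSE]
  keep[order(keep$p_value, keep$term_id), , drop = FALSE]
}
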