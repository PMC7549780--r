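#' Count accepted read pairs per gene
#'
#' Converts origin calls into per-gene counts. Each accepted pair increments
#' exactly one gene in exactly one matrix: in hybrid mode `A_specific` pairs
#' feed the chicken-derived-allele (HG) side and `B_specific` pairs the
#' quail-derived-allele (HQ) side, while `common` pairs (concordant in both
#' genomes) and discarded pairs increment nothing; in parental mode the
#' accepted calls of the conspecific genome are counted.
#'
#' @param calls An `origin_calls` data frame from [classify_pairs()].
#' @param genes Character vector declaring the gene universe of the counts.
#' @param mode `"hybrid"` or `"parental"`.
#' @return For hybrid mode a list with integer vectors `HG` and `HQ` (named
#'   by gene); for parental mode a single named integer vector.
#' @export
count_pairs <- function(calls, genes, mode = c("hybrid", "parental")) {
  mode <- match.arg(mode)
  accepted <- calls$call %in% c("A_specific", "B_specific")
  if (mode == "hybrid") accepted <- accepted & calls$call != "common"
  if (any(accepted & is.na(calls$gene_id)))
    stop("internal consistency error: accepted call without a gene")
  tab <- function(sub) {
    v <- integer(length(genes))
    names(v) <- genes
    if (nrow(sub)) {
      t0 <- table(factor(sub$gene_id, levels = genes))
      v[] <- as.integer(t0)
    }
    v
  }
  if (mode == "hybrid") {
    list(HG = tab(calls[calls$call == "A_specific", , drop = FALSE]),
         HQ = tab(calls[calls$call == "B_specific", , drop = FALSE]))
  } else {
    tab(calls[accepted, , drop = FALSE])
  }
}

#' Exclude genes with low counts in any sample
#'
#' Retains exactly the genes whose count is at or above `threshold` in
#' every sample of the matrix (the default threshold of 1 excludes any gene
#' with a zero count somewhere). The retained gene list is attached as an
#' attribute; the operation is idempotent.
#'
#' @param counts Integer matrix, genes x samples.
#' @param threshold Minimum count required in every sample (>= 0).
#' @return The filtered matrix with `attr(, "retained")` listing kept genes
#'   and `attr(, "filter_threshold")` recording the rule.
#' @export
filter_low_counts <- function(counts, threshold = 1L) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- apply(counts >= threshold, 1L, all)
  out <- counts[keep, , drop = FALSE]
  attr(out, "retained") <- rownames(out)
  attr(out, "filter_threshold") <- as.integer(threshold)
  out
}
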