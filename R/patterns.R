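#' Common analyzed-gene universe
#'
#' Intersection of the retained-gene lists of the series being compared;
#' downstream comparisons and pattern calls are made only on genes that
#' survived the low-count filter in every series involved.
#'
#' @param ... Two or more character vectors of retained genes (or a single
#'   list of them).
#' @return Character vector of genes present in every list.
#' @export
common_universe <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]])) lists <- lists[[1]]
  if (length(lists) < 2L) stop("need >= 2 retained-gene lists")
  out <- Reduce(intersect, lists)
  if (!length(out)) warning("empty common gene universe")
  out
}

direction_levels <- c("up", "unaltered", "down")

#' Direction concordance between two expression series
#'
#' Cross-tabulates the three-way direction calls of two series over a common
#' gene universe (a 3x3 table), reports per-cell percentages, the percent of
#' genes with the same direction in both series (the diagonal), and the
#' Pearson correlation of the paired log2 fold changes.
#'
#' @param de_x,de_y `de_result` data frames (must cover the universe).
#' @param universe Character vector of genes to compare.
#' @param labels Length-2 labels for the two series (for printing).
#' @return Object of class `concordance`: list with `table` (counts,
#'   direction of X in rows), `percent` (same shape, percent of universe),
#'   `percent_same_direction`, `pearson_r`, `universe_size`, `labels`.
#' @export
concordance <- function(de_x, de_y, universe, labels = c("X", "Y")) {
  ix <- match(universe, de_x$gene_id)
  iy <- match(universe, de_y$gene_id)
  if (any(is.na(ix)) || any(is.na(iy)))
    stop("both inputs must cover the gene universe")
  dx <- factor(de_x$direction[ix], levels = direction_levels)
  dy <- factor(de_y$direction[iy], levels = direction_levels)
  tab <- table(dx, dy, dnn = labels)
  n <- length(universe)
  lx <- de_x$log2fc[ix]
  ly <- de_y$log2fc[iy]
  r <- if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    warning("zero-variance log2fc vector; pearson_r undefined")
    NA_real_
  } else stats::cor(lx, ly)
  structure(list(table = tab, percent = 100 * tab / n,
                 percent_same_direction = 100 * sum(diag(tab)) / n,
                 pearson_r = r, universe_size = n, labels = labels),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance %s vs %s over %d genes\n", x$labels[1],
              x$labels[2], x$universe_size))
  print(x$table)
  cat(sprintf("same direction: %.1f%%  pearson r(log2FC): %s\n",
              x$percent_same_direction,
              ifelse(is.na(x$pearson_r), "NA",
                     sprintf("%.3f", x$pearson_r))))
  invisible(x)
}

code_digit <- c(up = "1", down = "2", unaltered = "0")

#' Classify the four-series direction profile of a gene
#'
#' Eligibility requires upregulation in both parental species (Q and G).
#' Among eligible genes the pattern records which hybrid alleles are also
#' upregulated: A = both, B = chicken-derived only, C = quail-derived only,
#' D = neither (misregulated: down or unaltered both count as "no
#' upregulation"). The four-digit code renders the (Q, G, HQ, HG) calls with
#' 1 = up, 2 = down, 0 = unaltered.
#'
#' @param dir_q,dir_g,dir_hq,dir_hg Direction calls (vectors recycled to a
#'   common length), each `up`, `down` or `unaltered`.
#' @return Data frame with `pattern` (`A`, `B`, `C`, `D`, `not_eligible`)
#'   and `code`.
#' @export
classify_pattern <- function(dir_q, dir_g, dir_hq, dir_hg) {
  n <- max(length(dir_q), length(dir_g), length(dir_hq), length(dir_hg))
  dir_q <- rep_len(dir_q, n); dir_g <- rep_len(dir_g, n)
  dir_hq <- rep_len(dir_hq, n); dir_hg <- rep_len(dir_hg, n)
  all_dirs <- c(dir_q, dir_g, dir_hq, dir_hg)
  if (!all(all_dirs %in% direction_levels))
    stop("directions must be 'up', 'down' or 'unaltered'")
  eligible <- dir_q == "up" & dir_g == "up"
  hq_up <- dir_hq == "up"
  hg_up <- dir_hg == "up"
  pattern <- ifelse(!eligible, "not_eligible",
             ifelse(hq_up & hg_up, "A",
             ifelse(!hq_up & hg_up, "B",
             ifelse(hq_up & !hg_up, "C", "D"))))
  code <- paste0(code_digit[dir_q], code_digit[dir_g],
                 code_digit[dir_hq], code_digit[dir_hg])
  data.frame(pattern = pattern, code = code, stringsAsFactors = FALSE)
}

#' Per-gene pattern profiles for one sex
#'
#' Joins the four per-series direction calls over the sex's analyzed-gene
#' universe and classifies each gene's regulatory pattern.
#'
#' @param de_q,de_g,de_hq,de_hg `de_result` data frames for the four series.
#' @param universe Gene universe (typically the intersection of the four
#'   retained-gene lists for this sex).
#' @param sex Label stored with the profiles (`"M"` or `"F"`).
#' @return Data frame of class `pattern_profiles`: `gene_id`, `sex`,
#'   `dir_Q`, `dir_G`, `dir_HQ`, `dir_HG`, `code`, `pattern`.
#' @export
pattern_profiles <- function(de_q, de_g, de_hq, de_hg, universe, sex) {
  pick <- function(de) {
    i <- match(universe, de$gene_id)
    if (any(is.na(i))) stop("a series does not cover the gene universe")
    de$direction[i]
  }
  d <- data.frame(gene_id = universe, sex = sex,
                  dir_Q = pick(de_q), dir_G = pick(de_g),
                  dir_HQ = pick(de_hq), dir_HG = pick(de_hg),
                  stringsAsFactors = FALSE)
  cls <- classify_pattern(d$dir_Q, d$dir_G, d$dir_HQ, d$dir_HG)
  d$code <- cls$code
  d$pattern <- cls$pattern
  class(d) <- c("pattern_profiles", "data.frame")
  d
}

#' Misregulated (pattern D) gene sets across sexes
#'
#' Combines per-sex pattern profiles with the union/intersection logic of
#' the study design: a gene is eligible if upregulated in both parents in at
#' least one sex, misregulated if it shows pattern D in at least one sex,
#' and consistently misregulated if it shows pattern D in both sexes.
#'
#' @param profiles_m,profiles_f `pattern_profiles` for males and females
#'   (each computed on its own per-sex universe).
#' @return List with character vectors `eligible_union`, `patternD_per_sex`
#'   (named list `M`/`F`), `patternD_union`, `patternD_intersection`, and a
#'   per-gene `provenance` data frame.
#' @export
misregulated_sets <- function(profiles_m, profiles_f) {
  elig <- function(p) p$gene_id[p$pattern != "not_eligible"]
  dset <- function(p) p$gene_id[p$pattern == "D"]
  eligible_union <- union(elig(profiles_m), elig(profiles_f))
  d_m <- dset(profiles_m)
  d_f <- dset(profiles_f)
  d_union <- intersect(union(d_m, d_f), eligible_union)
  genes <- sort(union(profiles_m$gene_id, profiles_f$gene_id))
  look <- function(p) {
    i <- match(genes, p$gene_id)
    ifelse(is.na(i), NA_character_, p$pattern[i])
  }
  prov <- data.frame(gene_id = genes, pattern_M = look(profiles_m),
                     pattern_F = look(profiles_f),
                     stringsAsFactors = FALSE)
  prov$eligible <- genes %in% eligible_union
  prov$patternD_union <- genes %in% d_union
  prov$patternD_intersection <- genes %in% intersect(d_m, d_f)
  list(eligible_union = eligible_union,
       patternD_per_sex = list(M = d_m, F = d_f),
       patternD_union = d_union,
       patternD_intersection = intersect(d_m, d_f),
       provenance = prov)
}
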