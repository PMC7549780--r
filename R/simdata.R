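#' Simulate a pair of substitution-diverged parental transcriptomes
#'
#' Generates one transcript per gene for parental species A and derives the
#' orthologous species-B transcript by independent per-site substitution.
#' Divergence is substitution-only, so orthologs have identical length and
#' shared coordinates, which keeps the two genomes directly comparable for
#' competitive read mapping.
#'
#' @param n_genes Number of genes (>= 1).
#' @param lengths Transcript lengths: a single integer recycled to all genes,
#'   a vector of per-gene lengths, or a function of `n` returning lengths.
#' @param divergence_rate Per-site substitution probability in \[0, 0.75\].
#'   The default 0.07 emulates a chicken--quail level of coding divergence.
#' @param seed Integer seed; output is bit-identical for identical inputs.
#' @param min_length Minimum admissible transcript length (the configured
#'   fragment-length ceiling); any shorter sampled gene is an error.
#' @return An object of class `parental_refs`: a list with `gene_id`,
#'   named character vectors `seq_A` and `seq_B`, `divergence_rate`, `seed`.
#' @examples
#' refs <- simulate_references(5, lengths = 500, divergence_rate = 0.07, seed = 1)
#' nchar(refs$seq_A[[1]])
#' @export
simulate_references <- function(n_genes, lengths = 1000L,
                                divergence_rate = 0.07, seed = 1L,
                                min_length = 350L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (!is.numeric(divergence_rate) || divergence_rate < 0 ||
      divergence_rate > 0.75)
    stop("divergence_rate must be in [0, 0.75]")
  set.seed(as.integer(seed))
  if (is.function(lengths)) lengths <- lengths(n_genes)
  lengths <- as.integer(rep_len(lengths, n_genes))
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  bad <- which(lengths < min_length)
  if (length(bad))
    stop("transcript length below fragment length for gene(s): ",
         paste(gene_id[bad], collapse = ", "))
  bases <- c("A", "C", "G", "T")
  seq_a <- character(n_genes)
  seq_b <- character(n_genes)
  for (i in seq_len(n_genes)) {
    a_codes <- sample.int(4L, lengths[i], replace = TRUE)
    hit <- stats::runif(lengths[i]) < divergence_rate
    b_codes <- a_codes
    if (any(hit)) {
      # substituted base uniform over the three alternatives
      shift <- sample.int(3L, sum(hit), replace = TRUE)
      b_codes[hit] <- ((a_codes[hit] - 1L + shift) %% 4L) + 1L
    }
    seq_a[i] <- paste(bases[a_codes], collapse = "")
    seq_b[i] <- paste(bases[b_codes], collapse = "")
  }
  names(seq_a) <- gene_id
  names(seq_b) <- gene_id
  structure(list(gene_id = gene_id, seq_A = seq_a, seq_B = seq_b,
                 divergence_rate = divergence_rate, seed = as.integer(seed)),
            class = "parental_refs")
}

#' @export
print.parental_refs <- function(x, ...) {
  cat("parental_refs:", length(x$gene_id), "genes, divergence",
      x$divergence_rate, "\n")
  invisible(x)
}

#' Plant a per-gene regulatory program for the stage contrast
#'
#' Assigns every gene a true stage log2 fold change (stage XIII/XIV vs stage
#' X) in each of the four expression series: quail (Q), chicken (G), and the
#' quail- and chicken-derived alleles of the hybrid (HQ, HG). A fraction
#' `up_in_both` of genes is upregulated in both parents; of those, a fraction
#' `misregulation_fraction` is planted as hybrid-misregulated ("pattern D":
#' neither hybrid allele is upregulated), the remainder as fully concordant
#' pattern A. All other genes draw their parental directions independently
#' from `direction_mix` (conditioned on not being up in both), and their
#' hybrid alleles track the conspecific parent.
#'
#' @param n_genes Number of genes.
#' @param direction_mix Named proportions over `up`, `down`, `unaltered`
#'   used for genes outside the up-in-both class; must sum to 1.
#' @param up_in_both Prevalence of the up-in-both-parents class.
#' @param misregulation_fraction Fraction of up-in-both genes planted as
#'   pattern D (in \[0, 1\]).
#' @param effect_size_log2 Absolute log2 fold change of planted up/down
#'   genes (>= 1 so that the planted direction matches the fold-change rule).
#' @param baseline_mean Expected normalized count at stage X: scalar,
#'   per-gene vector, or a function of `n`.
#' @param seed Integer seed.
#' @return A data frame of class `expression_program` with one row per gene:
#'   `gene_id`, `baseline_mean`, `lfc_Q`, `lfc_G`, `lfc_HQ`, `lfc_HG`,
#'   `dir_Q`, `dir_G`, `dir_HQ`, `dir_HG`, `true_pattern`
#'   (one of `"A"`, `"D"`, `"none"`). Class counts are attached as
#'   `attr(, "class_counts")`.
#' @export
simulate_program <- function(n_genes,
                             direction_mix = c(up = 0.15, down = 0.15,
                                               unaltered = 0.70),
                             up_in_both = 0.10,
                             misregulation_fraction = 0.5,
                             effect_size_log2 = 2,
                             baseline_mean = 200,
                             seed = 1L) {
  if (abs(sum(direction_mix) - 1) > 1e-9)
    stop("direction_mix proportions must sum to 1")
  if (is.null(names(direction_mix)))
    names(direction_mix) <- c("up", "down", "unaltered")
  if (!setequal(names(direction_mix), c("up", "down", "unaltered")))
    stop("direction_mix must be named over up/down/unaltered")
  if (misregulation_fraction < 0 || misregulation_fraction > 1)
    stop("misregulation_fraction must be in [0, 1]")
  if (effect_size_log2 < 1)
    stop("effect_size_log2 must be >= 1")
  set.seed(as.integer(seed))
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  if (is.function(baseline_mean)) baseline_mean <- baseline_mean(n_genes)
  baseline_mean <- rep_len(baseline_mean, n_genes)
  if (any(baseline_mean <= 0)) stop("baseline_mean must be > 0")

  both_up <- stats::runif(n_genes) < up_in_both
  is_d <- both_up & (stats::runif(n_genes) < misregulation_fraction)

  dirs <- c("up", "down", "unaltered")
  p <- direction_mix[dirs]
  dir_q <- dir_g <- rep("unaltered", n_genes)
  free <- which(!both_up)
  if (length(free)) {
    dq <- sample(dirs, length(free), replace = TRUE, prob = p)
    dg <- sample(dirs, length(free), replace = TRUE, prob = p)
    redo <- which(dq == "up" & dg == "up")
    while (length(redo)) { # condition on NOT both-up outside the planted class
      dq[redo] <- sample(dirs, length(redo), replace = TRUE, prob = p)
      dg[redo] <- sample(dirs, length(redo), replace = TRUE, prob = p)
      redo <- redo[dq[redo] == "up" & dg[redo] == "up"]
    }
    dir_q[free] <- dq
    dir_g[free] <- dg
  }
  dir_q[both_up] <- "up"
  dir_g[both_up] <- "up"

  to_lfc <- function(d) ifelse(d == "up", effect_size_log2,
                               ifelse(d == "down", -effect_size_log2, 0))
  lfc_q <- to_lfc(dir_q)
  lfc_g <- to_lfc(dir_g)
  # hybrid alleles track their conspecific parent, except planted pattern D
  lfc_hq <- lfc_q
  lfc_hg <- lfc_g
  lfc_hq[is_d] <- 0
  lfc_hg[is_d] <- 0

  to_dir <- function(l) ifelse(l > 0, "up", ifelse(l < 0, "down", "unaltered"))
  pattern <- rep("none", n_genes)
  pattern[both_up & !is_d] <- "A"
  pattern[is_d] <- "D"

  out <- data.frame(gene_id = gene_id, baseline_mean = baseline_mean,
                    lfc_Q = lfc_q, lfc_G = lfc_g,
                    lfc_HQ = lfc_hq, lfc_HG = lfc_hg,
                    dir_Q = to_dir(lfc_q), dir_G = to_dir(lfc_g),
                    dir_HQ = to_dir(lfc_hq), dir_HG = to_dir(lfc_hg),
                    true_pattern = pattern, stringsAsFactors = FALSE)
  attr(out, "class_counts") <- c(up_in_both = sum(both_up),
                                 pattern_A = sum(pattern == "A"),
                                 pattern_D = sum(pattern == "D"),
                                 none = sum(pattern == "none"))
  class(out) <- c("expression_program", "data.frame")
  out
}

#' Build the default embryo sample design
#'
#' Three series (Q = quail, G = chicken, H = hybrid) sampled at two
#' blastoderm stages (X and XIII/XIV) in both sexes with a fixed number of
#' replicates per cell, plus per-sample library-size factors.
#'
#' @param replicates Replicates per (series, stage, sex) cell (default 3).
#' @param lib_size_sdlog Log-normal sd of the library-size factors.
#' @param seed Integer seed for the library-size factors.
#' @return Data frame: `sample_id`, `series`, `stage`, `sex`, `replicate`,
#'   `library_size_factor`.
#' @export
simulate_design <- function(replicates = 3L, lib_size_sdlog = 0.15,
                            seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  grid <- expand.grid(replicate = seq_len(replicates),
                      sex = c("M", "F"),
                      stage = c("X", "XIII_XIV"),
                      series = c("Q", "G", "H"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("series", "stage", "sex", "replicate")]
  set.seed(as.integer(seed))
  grid$library_size_factor <- stats::rlnorm(nrow(grid), 0, lib_size_sdlog)
  grid$sample_id <- sprintf("%s_%s_%s_r%d", grid$series, grid$stage,
                            grid$sex, grid$replicate)
  grid[, c("sample_id", "series", "stage", "sex", "replicate",
           "library_size_factor")]
}

series_lfc_col <- function(tag) {
  switch(tag, Q = "lfc_Q", G = "lfc_G", HQ = "lfc_HQ", HG = "lfc_HG",
         stop("unknown series tag: ", tag))
}

#' Simulate negative-binomial count matrices under a planted program
#'
#' Draws gene-by-sample counts with mean
#' `library_size_factor * baseline_mean * 2^lfc` (the fold change applied at
#' stage XIII/XIV only) and variance `mean + dispersion * mean^2`. Hybrid
#' samples yield two allele-level matrices (HQ and HG), each with half the
#' sample's per-gene mean, reflecting the symmetric allele usage of an F1.
#'
#' @param program An `expression_program`.
#' @param design A design data frame as from [simulate_design()].
#' @param dispersion NB dispersion alpha (> 0), scalar or per-gene.
#' @param seed Integer seed.
#' @return A list of class `hybrid_counts` with one element per series tag
#'   (`Q`, `G`, `HQ`, `HG`), each a list with integer `counts`
#'   (genes x samples) and `coldata`; the program is attached as `$truth`.
#' @export
simulate_counts <- function(program, design, dispersion = 0.05, seed = 1L) {
  if (any(dispersion <= 0)) stop("dispersion must be > 0")
  if (nrow(design) == 0) stop("design must be non-empty")
  set.seed(as.integer(seed))
  n_genes <- nrow(program)
  disp <- rep_len(dispersion, n_genes)
  size <- 1 / disp
  tags <- c("Q", "G", "HQ", "HG")
  out <- stats::setNames(vector("list", length(tags)), tags)
  for (tag in tags) {
    parent_series <- if (tag %in% c("Q", "G")) tag else "H"
    cols <- design[design$series == parent_series, , drop = FALSE]
    if (nrow(cols) == 0) { out[[tag]] <- NULL; next }
    lfc <- program[[series_lfc_col(tag)]]
    halve <- if (parent_series == "H") 0.5 else 1
    mat <- matrix(0L, n_genes, nrow(cols),
                  dimnames = list(program$gene_id, cols$sample_id))
    for (j in seq_len(nrow(cols))) {
      mu <- cols$library_size_factor[j] * program$baseline_mean * halve *
        2^(if (cols$stage[j] == "XIII_XIV") lfc else 0)
      mat[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
    out[[tag]] <- list(counts = mat, coldata = cols, series_tag = tag)
  }
  out$truth <- program
  class(out) <- "hybrid_counts"
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

mutate_bases <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  L <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), L, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(L[i], n_err[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      alt <- sample(setdiff(bases, cur), 1L)
      substr(seqs[i], p, p) <- alt
    }
  }
  seqs
}

#' Simulate paired-end reads for one sample
#'
#' Draws fragments per (gene, allele) proportionally to expression weight
#' times transcript length, with uniform start positions, normal fragment
#' lengths, FR mate orientation (mate 1 forward, mate 2 reverse complement of
#' the fragment end), 100 bp mates by default, and independent per-base
#' sequencing errors. The returned truth table records the source gene,
#' species and 0-based fragment start of every pair.
#'
#' @param refs A `parental_refs` object.
#' @param weights_A,weights_B Per-gene expression weights for the A
#'   (chicken-like) and B (quail-like) haplotype. A pure species-A sample
#'   uses `weights_B = 0` everywhere, and vice versa; hybrid samples supply
#'   both halves.
#' @param n_read_pairs Number of read pairs to draw.
#' @param read_length Mate length (default 100).
#' @param fragment_mean,fragment_sd Normal fragment-length model (250 +/- 25
#'   by default); lengths are clamped to `[read_length, transcript length]`.
#' @param error_rate Per-base substitution error probability in \[0, 0.1).
#' @param seed Integer seed.
#' @param sample_id Prefix for read identifiers.
#' @return List with data frames `r1`, `r2` (`read_id`, `seq`) and `truth`
#'   (`read_id`, `gene_id`, `species`, `position`, `fragment_length`).
#' @export
simulate_reads <- function(refs, weights_A, weights_B, n_read_pairs,
                           read_length = 100L, fragment_mean = 250,
                           fragment_sd = 25, error_rate = 0.001,
                           seed = 1L, sample_id = "sample") {
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must be in [0, 0.1)")
  glen <- nchar(refs$seq_A)
  if (any(glen < fragment_mean))
    stop("transcript shorter than mean fragment length: ",
         paste(refs$gene_id[glen < fragment_mean], collapse = ", "))
  if (read_length > min(glen)) stop("read_length exceeds a transcript length")
  set.seed(as.integer(seed))
  n_genes <- length(refs$gene_id)
  weights_A <- rep_len(weights_A, n_genes)
  weights_B <- rep_len(weights_B, n_genes)
  w <- c(weights_A * glen, weights_B * glen) # fragment mass ~ expression x length
  if (sum(w) <= 0) stop("all expression weights are zero")
  pick <- sample.int(2L * n_genes, n_read_pairs, replace = TRUE, prob = w)
  species <- ifelse(pick > n_genes, "B", "A")
  gidx <- ifelse(pick > n_genes, pick - n_genes, pick)
  L <- glen[gidx]
  flen <- as.integer(round(stats::rnorm(n_read_pairs, fragment_mean,
                                        fragment_sd)))
  flen <- pmax(read_length, pmin(flen, L))
  start <- as.integer(floor(stats::runif(n_read_pairs) * (L - flen + 1)))
  src <- ifelse(species == "A", refs$seq_A[gidx], refs$seq_B[gidx])
  frag_1 <- substr(src, start + 1L, start + read_length)
  frag_2 <- revcomp_chr(substr(src, start + flen - read_length + 1L,
                               start + flen))
  r1 <- mutate_bases(frag_1, error_rate)
  r2 <- mutate_bases(frag_2, error_rate)
  read_id <- sprintf("%s_%06d", sample_id, seq_len(n_read_pairs))
  list(r1 = data.frame(read_id = read_id, seq = r1,
                       stringsAsFactors = FALSE),
       r2 = data.frame(read_id = read_id, seq = r2,
                       stringsAsFactors = FALSE),
       truth = data.frame(read_id = read_id, gene_id = refs$gene_id[gidx],
                          species = species, position = start,
                          fragment_length = flen, stringsAsFactors = FALSE))
}

#' Expression weights of one designed sample
#'
#' Converts the planted program into per-gene, per-haplotype expression
#' weights for [simulate_reads()]: parental samples place all mass on the
#' conspecific haplotype; hybrid samples split mass equally between alleles,
#' each following its own planted log2 fold change.
#'
#' @param program An `expression_program`.
#' @param series One of `"Q"`, `"G"`, `"H"`.
#' @param stage `"X"` or `"XIII_XIV"`.
#' @return List with numeric vectors `weights_A` and `weights_B`.
#' @export
sample_weights <- function(program, series, stage) {
  at_stage <- function(lfc) program$baseline_mean *
    2^(if (stage == "XIII_XIV") lfc else 0)
  switch(series,
    G = list(weights_A = at_stage(program$lfc_G),
             weights_B = numeric(nrow(program))),
    Q = list(weights_A = numeric(nrow(program)),
             weights_B = at_stage(program$lfc_Q)),
    H = list(weights_A = at_stage(program$lfc_HG) / 2,
             weights_B = at_stage(program$lfc_HQ) / 2),
    stop("series must be Q, G or H"))
}

#' Simulate a gene-to-term annotation table
#'
#' Random background terms plus one synthetic term concentrated on the
#' planted pattern-D genes and one on the up-in-both class, so that
#' overrepresentation analysis of a recovered misregulated set has a planted
#' positive control.
#'
#' @param program An `expression_program`.
#' @param n_terms Number of random background terms.
#' @param mean_term_size Mean number of genes per background term.
#' @param seed Integer seed.
#' @return Data frame `gene_id`, `term_id`, `term_name`.
#' @export
simulate_annotations <- function(program, n_terms = 40L,
                                 mean_term_size = 30, seed = 1L) {
  set.seed(as.integer(seed))
  genes <- program$gene_id
  rows <- list()
  for (t in seq_len(n_terms)) {
    size <- max(2L, stats::rpois(1L, mean_term_size))
    size <- min(size, length(genes))
    rows[[t]] <- data.frame(gene_id = sample(genes, size),
                            term_id = sprintf("TERM:%04d", t),
                            term_name = sprintf("background process %d", t),
                            stringsAsFactors = FALSE)
  }
  d_genes <- genes[program$true_pattern == "D"]
  up_genes <- genes[program$true_pattern %in% c("A", "D")]
  if (length(d_genes))
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = d_genes, term_id = "TERM:MISREG",
                 term_name = "synthetic misregulation module",
                 stringsAsFactors = FALSE)
  if (length(up_genes))
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = up_genes, term_id = "TERM:STAGEUP",
                 term_name = "synthetic stage-upregulated module",
                 stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  unique(out)
}
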