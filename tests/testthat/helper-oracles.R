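# Independent oracles and small fixture builders shared across tests.

# Naive two-pass Benjamini-Hochberg reference: sort, step-up minimum, cap.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Hypergeometric upper tail by direct enumeration of the table.
enum_hyper_tail <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Full-scan mapping oracle: every window of every transcript on both
# strands, at most max_mm mismatches, via Biostrings' naive matcher.
brute_map <- function(read, refs, genome, max_mm) {
  seqs <- if (genome == "A") refs$seq_A else refs$seq_B
  subject <- Biostrings::DNAStringSet(seqs)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
    hits <- Biostrings::vmatchPattern(q, subject, max.mismatch = max_mm)
    for (i in seq_along(hits)) {
      st <- BiocGenerics::start(hits[[i]])
      st <- st[st >= 1 & st + nchar(q) - 1 <= nchar(seqs[[i]])]
      if (length(st))
        out[[length(out) + 1L]] <- data.frame(
          gene_id = names(seqs)[i], pos = st - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

hamming_chr <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Reference classifier over brute-force hits, written directly from the
# decision rules (independent of the seeded C++ path).
brute_classify_pair <- function(r1, r2, refs, mode, max_mm, fmin, fmax) {
  genomes <- if (mode == "hybrid") c("A", "B") else
    if (mode == "parental_A") "A" else "B"
  res <- list()
  any1 <- FALSE
  any2 <- FALSE
  for (g in genomes) {
    h1 <- brute_map(r1, refs, g, max_mm)
    h2 <- brute_map(r2, refs, g, max_mm)
    any1 <- any1 || nrow(h1) > 0
    any2 <- any2 || nrow(h2) > 0
    seqs <- if (g == "A") refs$seq_A else refs$seq_B
    mmof <- function(h, read) {
      q <- if (h$strand == "+") read else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(read)))
      hamming_chr(substr(seqs[[h$gene_id]], h$pos + 1,
                         h$pos + nchar(q)), q)
    }
    best <- Inf
    locs <- character()
    for (i in seq_len(nrow(h1))) for (j in seq_len(nrow(h2))) {
      a <- h1[i, ]; b <- h2[j, ]
      if (a$gene_id != b$gene_id || a$strand == b$strand) next
      fwd <- if (a$strand == "+") a else b
      rev <- if (a$strand == "+") b else a
      rev_len <- if (a$strand == "+") nchar(r2) else nchar(r1)
      if (rev$pos < fwd$pos) next
      span <- rev$pos + rev_len - fwd$pos
      if (span < fmin || span > fmax) next
      tot <- mmof(a, r1) + mmof(b, r2)
      loc <- paste(a$gene_id, fwd$pos, rev$pos)
      if (tot < best) { best <- tot; locs <- loc }
      else if (tot == best) locs <- union(locs, loc)
    }
    res[[g]] <- if (!length(locs)) "none"
                else if (length(locs) > 1) "multi" else "unique"
  }
  if (any(unlist(res) == "multi")) return(c("discarded", "multimapped"))
  uA <- identical(res[["A"]], "unique")
  uB <- identical(res[["B"]], "unique")
  if (uA && uB) return(c("common", NA))
  if (uA) return(c("A_specific", NA))
  if (uB) return(c("B_specific", NA))
  if (!any1 && !any2) return(c("discarded", "unmapped"))
  if (any1 != any2) return(c("discarded", "orphan"))
  c("discarded", "discordant")
}

# NB likelihood tools for the signed-root LR oracle.
nb_ll <- function(k, mu, alpha) {
  sum(stats::dnbinom(k, mu = mu, size = 1 / alpha, log = TRUE))
}
nb_mle_q <- function(k, s, alpha) {
  exp(stats::optimize(function(th)
    -nb_ll(k, s * exp(th), alpha), c(-10, 15))$minimum)
}

# Small hybrid counts fixture: program + design + counts + per-sex DE.
fixture_de_all <- function(n_genes = 400, seed = 3, replicates = 3,
                           dispersion = 0.05, ...) {
  prog <- simulate_program(n_genes, seed = seed, ...)
  des <- simulate_design(replicates, seed = seed + 1)
  cts <- simulate_counts(prog, des, dispersion, seed = seed + 2)
  de <- list()
  ret <- list()
  for (tag in c("Q", "G", "HQ", "HG")) for (sx in c("M", "F")) {
    cd <- cts[[tag]]$coldata
    sub <- cd$sex == sx
    f <- filter_low_counts(cts[[tag]]$counts[, sub, drop = FALSE], 1)
    key <- paste(tag, sx, sep = "_")
    de[[key]] <- run_de(f, cd$stage[sub])
    ret[[key]] <- attr(f, "retained")
  }
  list(program = prog, design = des, counts = cts, de = de, retained = ret)
}

profiles_for_sex <- function(fx, sx) {
  uni <- common_universe(lapply(paste(c("Q", "G", "HQ", "HG"), sx,
                                      sep = "_"),
                                function(k) fx$retained[[k]]))
  pattern_profiles(fx$de[[paste0("Q_", sx)]], fx$de[[paste0("G_", sx)]],
                   fx$de[[paste0("HQ_", sx)]], fx$de[[paste0("HG_", sx)]],
                   uni, sx)
}
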