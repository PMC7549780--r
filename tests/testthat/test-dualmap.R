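make_refs <- function(n = 20, len = 400, div = 0.07, seed = 21) {
  simulate_references(n, lengths = len, divergence_rate = div, seed = seed,
                      min_length = len)
}

test_that("index records L - k + 1 forward k-mers per N-free gene", {
  refs <- simulate_references(3, lengths = 350, divergence_rate = 0.05,
                              seed = 1)
  # append one 300 nt gene manually
  refs$gene_id <- c(refs$gene_id, "gene_extra")
  extra <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  refs$seq_A <- c(refs$seq_A, gene_extra = extra)
  refs$seq_B <- c(refs$seq_B, gene_extra = extra)
  idx <- build_index(refs, k = 31)
  st <- index_stats(idx)
  expect_identical(st$n_kmers, st$length - 31L + 1L)
  expect_identical(st$n_kmers[st$gene_id == "gene_extra"][1], 270L)
  # zero divergence: identical k-mer coordinates in both genomes
  r0 <- simulate_references(4, lengths = 350, divergence_rate = 0, seed = 2)
  idx0 <- build_index(r0, k = 31)
  rd <- substr(r0$seq_A[[2]], 51, 150)
  hA <- map_read(rd, idx0, "A", 0)
  hB <- map_read(rd, idx0, "B", 0)
  expect_identical(hA[c("gene_id", "pos", "strand")],
                   hB[c("gene_id", "pos", "strand")])
})

test_that("map_read finds exact and near matches and respects the budget", {
  refs <- make_refs(seed = 3)
  idx <- build_index(refs, k = 31)
  rd <- substr(refs$seq_A[[5]], 18, 117) # offset 17, 0-based
  h <- map_read(rd, idx, "A", 2)
  h0 <- h[h$mismatches == 0, ]
  expect_true(any(h0$gene_id == "gene0005" & h0$pos == 17 &
                    h0$strand == "+"))

  # window differing at 3 sites with budget 2: rejected
  rd3 <- rd
  for (p in c(5, 50, 95)) {
    cur <- substr(rd3, p, p)
    substr(rd3, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  h3 <- map_read(rd3, idx, "A", 2)
  expect_false(any(h3$gene_id == "gene0005" & h3$pos == 17))

  # reverse-complement reads are found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  hrc <- map_read(rc, idx, "A", 0)
  expect_true(any(hrc$gene_id == "gene0005" & hrc$pos == 17 &
                    hrc$strand == "-"))

  # N counts as a mismatch everywhere and never seeds
  rdn <- rd
  substr(rdn, 40, 40) <- "N"
  hn <- map_read(rdn, idx, "A", 2)
  expect_true(any(hn$gene_id == "gene0005" & hn$pos == 17 &
                    hn$mismatches == 1))

  expect_error(map_read("ACGTX", idx, "A"), "outside")
})

test_that("seed-and-verify equals the full-window scan oracle", {
  set.seed(31)
  refs <- make_refs(n = 15, len = 300, div = 0.07, seed = 31)
  for (k in c(31L, 15L)) {
    idx <- build_index(refs, k = k)
    for (trial in 1:50) {
      genome <- sample(c("A", "B"), 1)
      src <- if (genome == "A") refs$seq_A else refs$seq_B
      g <- sample(15, 1)
      pos <- sample(300 - 100 + 1, 1)
      rd <- substr(src[[g]], pos, pos + 99)
      n_mm <- sample(0:2, 1)
      if (n_mm > 0) {
        # k = 31: confine planted mismatches so an intact seed survives;
        # k = 15: two mismatches always leave an intact window
        posns <- if (k == 31) sample(60:100, n_mm) else sample(100, n_mm)
        for (p in posns) {
          cur <- substr(rd, p, p)
          substr(rd, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
        }
      }
      if (sample(c(TRUE, FALSE), 1))
        rd <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(rd)))
      for (target in c("A", "B")) {
        mine <- map_read(rd, idx, target, 2)
        oracle <- brute_map(rd, refs, target, 2)
        key <- function(d) sort(paste(d$gene_id, d$pos, d$strand))
        expect_identical(key(mine), key(oracle))
      }
    }
  }
})

test_that("pair classification follows the filtering decision rules", {
  refs <- make_refs(n = 10, len = 400, div = 0.2, seed = 41)
  idx <- build_index(refs, k = 15)
  frag <- function(seqs, g, start, flen) {
    f <- substr(seqs[[g]], start + 1, start + flen)
    list(r1 = substr(f, 1, 100),
         r2 = as.character(Biostrings::reverseComplement(
           Biostrings::DNAString(substr(f, flen - 99, flen)))))
  }
  # A-only fragment at divergence 0.2 is A-specific
  p <- frag(refs$seq_A, 3, 50, 250)
  calls <- classify_pairs(p$r1, p$r2, idx, "hybrid")
  expect_identical(calls$call, "A_specific")
  expect_identical(calls$gene_id, "gene0003")
  expect_identical(calls$fwd_pos, 50L)

  # identical genomes at a gene: concordant in both -> common
  refs2 <- refs
  refs2$seq_B[[3]] <- refs2$seq_A[[3]]
  idx2 <- build_index(refs2, k = 15)
  calls2 <- classify_pairs(p$r1, p$r2, idx2, "hybrid")
  expect_identical(calls2$call, "common")

  # orphan: mate2 unmappable
  calls3 <- classify_pairs(p$r1, paste(rep("A", 100), collapse = ""),
                           idx, "hybrid")
  expect_identical(calls3$call, "discarded")
  expect_identical(calls3$reason, "orphan")

  # unmapped: neither mate maps
  junk <- paste(rep(c("A", "C"), 50), collapse = "")
  calls4 <- classify_pairs(junk, junk, idx, "hybrid")
  expect_identical(calls4$reason, "unmapped")

  # discordant: both mates map but pairing violates FR geometry
  calls5 <- classify_pairs(p$r1, p$r1, idx, "hybrid")
  expect_identical(calls5$reason, "discordant")

  # multimapped: duplicated gene inside genome A
  refs3 <- refs
  refs3$seq_A[[7]] <- refs3$seq_A[[3]]
  idx3 <- build_index(refs3, k = 15)
  calls6 <- classify_pairs(p$r1, p$r2, idx3, "hybrid")
  expect_identical(calls6$reason, "multimapped")

  # parental mode consults only the conspecific genome
  calls7 <- classify_pairs(p$r1, p$r2, idx2, "parental_A")
  expect_identical(calls7$call, "A_specific")

  expect_error(classify_pairs(p$r1, c(p$r2, p$r2), idx, "hybrid"),
               "equal length")
})

test_that("classification over seeded hits equals brute-force classification", {
  refs <- make_refs(n = 12, len = 300, div = 0.07, seed = 51)
  prog <- simulate_program(12, seed = 52)
  w <- sample_weights(prog, "H", "X")
  rd <- simulate_reads(refs, w$weights_A, w$weights_B, 120,
                       error_rate = 0.01, seed = 53)
  idx <- build_index(refs, k = 15)
  mine <- classify_pairs(rd$r1$seq, rd$r2$seq, idx, "hybrid",
                         max_mismatches = 2)
  for (i in seq_len(nrow(mine))) {
    oracle <- brute_classify_pair(rd$r1$seq[i], rd$r2$seq[i], refs,
                                  "hybrid", 2, 150, 350)
    expect_identical(mine$call[i], oracle[1])
    if (mine$call[i] == "discarded")
      expect_identical(mine$reason[i], oracle[2])
  }
})

test_that("origin calls partition the input and swap under relabeling", {
  refs <- make_refs(n = 20, len = 400, div = 0.07, seed = 61)
  prog <- simulate_program(20, seed = 62)
  w <- sample_weights(prog, "H", "XIII_XIV")
  rd <- simulate_reads(refs, w$weights_A, w$weights_B, 1500, seed = 63)
  idx <- build_index(refs, k = 31)
  calls <- classify_pairs(rd$r1$seq, rd$r2$seq, idx, "hybrid")
  tab <- table(factor(calls$call, levels = c("A_specific", "B_specific",
                                             "common", "discarded")))
  expect_identical(sum(tab), 1500L)

  # label swap symmetry
  refs_sw <- refs
  refs_sw$seq_A <- refs$seq_B
  refs_sw$seq_B <- refs$seq_A
  idx_sw <- build_index(refs_sw, k = 31)
  calls_sw <- classify_pairs(rd$r1$seq, rd$r2$seq, idx_sw, "hybrid")
  expect_identical(sum(calls$call == "A_specific"),
                   sum(calls_sw$call == "B_specific"))
  expect_identical(sum(calls$call == "B_specific"),
                   sum(calls_sw$call == "A_specific"))
  expect_identical(sum(calls$call == "common"),
                   sum(calls_sw$call == "common"))

  # specific calls recover the true source species
  spec <- calls$call %in% c("A_specific", "B_specific")
  acc <- mean(ifelse(calls$call[spec] == "A_specific", "A", "B") ==
                rd$truth$species[spec])
  expect_gte(acc, 0.99)
})

test_that("mismatch sweep fractions partition and common never decreases", {
  refs <- make_refs(n = 15, len = 400, div = 0.07, seed = 71)
  prog <- simulate_program(15, seed = 72)
  w <- sample_weights(prog, "H", "X")
  rd <- simulate_reads(refs, w$weights_A, w$weights_B, 800, seed = 73)
  idx <- build_index(refs, k = 31)
  sw <- mismatch_sweep(rd$r1$seq, rd$r2$seq, idx, c(0, 1, 2, 5, 10))
  sums <- rowSums(sw[, c("A_specific", "B_specific", "common", "discarded")])
  expect_equal(sums, rep(1, 5), tolerance = 1e-12)
  expect_true(all(diff(sw$common) >= 0))

  # indistinguishable genomes: specific fractions are zero at every setting
  refs0 <- simulate_references(8, lengths = 400, divergence_rate = 0,
                               seed = 74)
  rd0 <- simulate_reads(refs0, rep(1, 8), rep(0, 8), 300, seed = 75)
  idx0 <- build_index(refs0, k = 31)
  sw0 <- mismatch_sweep(rd0$r1$seq, rd0$r2$seq, idx0, c(0, 2, 5))
  expect_true(all(sw0$A_specific == 0))
  expect_true(all(sw0$B_specific == 0))
})
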