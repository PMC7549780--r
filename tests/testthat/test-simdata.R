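test_that("reference simulation respects divergence, determinism, validation", {
  # zero divergence: B identical to A
  r0 <- simulate_references(5, lengths = 350, divergence_rate = 0, seed = 1)
  expect_identical(unname(r0$seq_A), unname(r0$seq_B))

  # mean per-gene mismatch fraction near the divergence rate
  r <- simulate_references(200, lengths = 1000, divergence_rate = 0.07,
                           seed = 7)
  mism <- mapply(hamming_chr, r$seq_A, r$seq_B) / 1000
  se <- sqrt(0.07 * 0.93 / (200 * 1000))
  expect_lt(abs(mean(mism) - 0.07), 3 * se)

  # seeded determinism down to FASTA bytes
  r2 <- simulate_references(200, lengths = 1000, divergence_rate = 0.07,
                            seed = 7)
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile(); f4 <- tempfile()
  write_ref_fasta(r, f1, f2)
  write_ref_fasta(r2, f3, f4)
  expect_identical(readLines(f1), readLines(f3))
  expect_identical(readLines(f2), readLines(f4))
  unlink(c(f1, f2, f3, f4))

  expect_error(simulate_references(3, lengths = 100, seed = 1), "gene0001")
  expect_error(simulate_references(3, divergence_rate = 0.9, seed = 1),
               "divergence_rate")
})

test_that("planted programs have correct class structure and bookkeeping", {
  # boundary: no misregulation planted
  p0 <- simulate_program(300, misregulation_fraction = 0, seed = 2)
  expect_false(any(p0$true_pattern == "D"))

  # binomial count of planted pattern D genes
  p <- simulate_program(1000, up_in_both = 0.1, misregulation_fraction = 0.5,
                        seed = 3)
  n_d <- sum(p$true_pattern == "D")
  se <- sqrt(1000 * 0.05 * 0.95)
  expect_lt(abs(n_d - 50), 3 * se)

  # pattern D forces the (up, up, unaltered, unaltered) direction tuple
  d <- p[p$true_pattern == "D", ]
  expect_true(all(d$dir_Q == "up" & d$dir_G == "up" &
                    d$dir_HQ == "unaltered" & d$dir_HG == "unaltered"))

  # class counts recorded match a scan of the labels
  cc <- attr(p, "class_counts")
  expect_identical(unname(cc["pattern_D"]), sum(p$true_pattern == "D"))
  expect_identical(unname(cc["pattern_A"]), sum(p$true_pattern == "A"))

  # outside the planted class no gene is up in both parents
  free <- p$true_pattern == "none"
  expect_false(any(p$dir_Q[free] == "up" & p$dir_G[free] == "up"))

  expect_error(simulate_program(10, direction_mix = c(up = .5, down = .5,
                                                      unaltered = .5)),
               "sum to 1")
})

test_that("simulated counts match negative-binomial moments", {
  prog <- simulate_program(200, up_in_both = 0, baseline_mean = 100,
                           seed = 4)
  des <- simulate_design(13, lib_size_sdlog = 0, seed = 4)
  # Poisson limit: variance ~= mean
  cts <- simulate_counts(prog, des, dispersion = 1e-8, seed = 5)
  x <- as.vector(cts$Q$counts) # 200 genes x 52 samples, all means 100*2^0 or lfc
  null_genes <- prog$dir_Q == "unaltered"
  x <- as.vector(cts$Q$counts[null_genes, ])
  expect_gt(length(x), 5000)
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)

  # NB moments: mean 200, alpha 0.05 -> variance 200 + 0.05*200^2 = 2200
  prog2 <- simulate_program(200, up_in_both = 0, baseline_mean = 200,
                            direction_mix = c(up = 0, down = 0,
                                              unaltered = 1), seed = 6)
  cts2 <- simulate_counts(prog2, des, dispersion = 0.05, seed = 7)
  y <- as.vector(cts2$Q$counts)
  expect_lt(abs(var(y) - 2200) / 2200, 0.1)

  # null gene: stage means agree within 3 SE
  g <- which(null_genes)[1]
  m_x <- cts2$Q$counts[g, cts2$Q$coldata$stage == "X"]
  m_s <- cts2$Q$counts[g, cts2$Q$coldata$stage == "XIII_XIV"]
  pooled_se <- sqrt(var(m_x) / length(m_x) + var(m_s) / length(m_s))
  expect_lt(abs(mean(m_x) - mean(m_s)), 3 * pooled_se)

  # hybrid allele matrices carry half the series mean
  expect_lt(abs(mean(cts2$HQ$counts) - 100) / 100, 0.1)

  expect_error(simulate_counts(prog, des, dispersion = 0), "dispersion")
})

test_that("read simulation matches its fragment and error model", {
  refs <- simulate_references(10, lengths = 600, divergence_rate = 0,
                              seed = 8)
  # no divergence, no error: every mate is an exact substring of both refs
  rd <- simulate_reads(refs, rep(1, 10), rep(1, 10), 200, error_rate = 0,
                       seed = 9)
  src_a <- refs$seq_A[rd$truth$gene_id]
  m1 <- substr(src_a, rd$truth$position + 1, rd$truth$position + 100)
  expect_identical(rd$r1$seq, unname(m1))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rd$r2$seq)))
  m2 <- substr(src_a, rd$truth$position + rd$truth$fragment_length - 99,
               rd$truth$position + rd$truth$fragment_length)
  expect_identical(unname(rc), unname(m2))

  # truth-table completeness: one record per pair, ids aligned
  expect_identical(rd$truth$read_id, rd$r1$read_id)
  expect_identical(rd$truth$read_id, rd$r2$read_id)

  # expression ratio: gene at 10x weight gets ~10x the reads
  refs2 <- simulate_references(2, lengths = 600, divergence_rate = 0,
                               seed = 10)
  w <- c(10, 1)
  rd2 <- simulate_reads(refs2, w, c(0, 0), 100000, error_rate = 0,
                        seed = 11)
  n1 <- sum(rd2$truth$gene_id == "gene0001")
  p1 <- 10 / 11
  se <- sqrt(100000 * p1 * (1 - p1))
  expect_lt(abs(n1 - 100000 * p1), 3 * se)

  # error model: mean mismatches vs source ~ error_rate * read_length
  rd3 <- simulate_reads(refs, rep(1, 10), rep(0, 10), 5000,
                        error_rate = 0.001, seed = 12)
  src <- substr(refs$seq_A[rd3$truth$gene_id], rd3$truth$position + 1,
                rd3$truth$position + 100)
  mm <- mapply(hamming_chr, rd3$r1$seq, src)
  se_mm <- sqrt(0.001 * 0.999 * 100 / 5000)
  expect_lt(abs(mean(mm) - 0.1), 3 * se_mm)

  # determinism
  rd4 <- simulate_reads(refs, rep(1, 10), rep(0, 10), 500, seed = 13)
  rd5 <- simulate_reads(refs, rep(1, 10), rep(0, 10), 500, seed = 13)
  expect_identical(rd4, rd5)

  expect_error(simulate_reads(refs, rep(1, 10), rep(1, 10), 10,
                              error_rate = 0.5), "error_rate")
})
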