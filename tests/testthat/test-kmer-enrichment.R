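test_that("overlapping windows are counted and N-windows excluded", {
  kt <- count_kmers(tag_set("AAAA"), k = 3)
  expect_equal(unname(kmer_count(kt, "AAA")), 2L)
  expect_equal(kt$total_windows, 2L)

  kt2 <- count_kmers(tag_set("AUAU"), k = 2)
  expect_equal(unname(kmer_count(kt2, c("AU", "UA"))), c(2L, 1L))
  expect_equal(kt2$total_windows, 3L)

  ktn <- count_kmers(tag_set("ANAA"), k = 2)
  expect_equal(unname(kmer_count(ktn, "AA")), 1L)
  expect_equal(ktn$total_windows, 1L)  # AN and NA windows skipped

  expect_warning(kt0 <- count_kmers(tag_set("ACG"), k = 5), "exceeds")
  expect_equal(kt0$total_windows, 0L)
})

test_that("printed Nrxn2 oligo 4-mer counts match the brute-force scan", {
  kt <- count_kmers(tag_set(NRXN2), k = 4)
  oracle <- naive_count_kmers(NRXN2, 4)
  expect_equal(kt$total_windows, 26L)
  expect_equal(kt$total_windows, oracle$total_windows)
  expect_equal(unname(kmer_count(kt, "UAAC")), unname(oracle$counts["UAAC"]))
  expect_equal(unname(kmer_count(kt, "UAAC")), 4L)  # overlapping UUAAC at 6
  expect_equal(unname(kmer_count(kt, "UAAA")), 1L)
})

test_that("k-mer counting matches the naive oracle on random sequences", {
  seqs <- random_rna(300, 50, seed = 17)
  # sprinkle Ns to exercise window exclusion
  seqs[1:30] <- vapply(seqs[1:30], function(s) {
    substr(s, 10, 10) <- "N"; s
  }, character(1), USE.NAMES = FALSE)
  kt <- count_kmers(tag_set(seqs), k = 6)
  oracle <- naive_count_kmers(seqs, 6)
  expect_equal(kt$total_windows, oracle$total_windows)
  expect_identical(kt$counts[order(names(kt$counts))], oracle$counts)
  # second independent route for the N-free subset
  bs <- Biostrings::oligonucleotideFrequency(
    Biostrings::RNAStringSet(seqs[31:300]), width = 6, simplify.as = "collapsed")
  kt2 <- count_kmers(tag_set(seqs[31:300]), k = 6)
  bs <- bs[bs > 0]
  expect_equal(kt2$counts[order(names(kt2$counts))],
               bs[order(names(bs))])
})

test_that("counts over all k-mers sum to total windows for N-free sets", {
  tags <- tag_set(random_rna(200, 40, seed = 23))
  kt <- count_kmers(tags, k = 6)
  expect_equal(sum(kt$counts), kt$total_windows)
  expect_equal(kt$total_windows, sum(pmax(0L, nchar(tags$seq) - 5L)))
})

test_that("2x2 chi-squared matches closed form, oracle and stats::chisq.test", {
  r <- chi2_two_by_two(10, 100, 10, 100)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  r2 <- chi2_two_by_two(30, 100, 10, 100)
  expect_equal(r2$chi2, 12.5)

  set.seed(4)
  for (i in 1:50) {
    ot <- sample(50:500, 1); bt <- sample(50:500, 1)
    a <- sample.int(ot - 1, 1); c_ <- sample.int(bt - 1, 1)
    mine <- chi2_two_by_two(a, ot, c_, bt)
    expect_equal(mine$chi2, chi2_oracle(a, ot, c_, bt), tolerance = 1e-9)
    ref <- stats::chisq.test(matrix(c(a, ot - a, c_, bt - c_), 2,
                                    byrow = TRUE), correct = FALSE)
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    # symmetric under swapping the two sets
    sw <- chi2_two_by_two(c_, bt, a, ot)
    expect_equal(sw$chi2, mine$chi2)
    expect_equal(sw$p_value, mine$p_value)
  }
})

test_that("degenerate 2x2 tables are flagged with chi2 0, p 1", {
  r <- chi2_two_by_two(0, 100, 0, 100)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
})

test_that("self-comparison yields unit ratios and no significant k-mers", {
  tags <- tag_set(random_rna(100, 40, seed = 31))
  enr <- enrich_kmers(tags, tags, k = 6)
  expect_true(all(abs(enr$ratio - 1) < 1e-12))
  expect_equal(nrow(significant_kmers(enr)), 0L)
})

test_that("an embedded hexamer is recovered as the top-ranked 6-mer", {
  unif <- c(A = .25, C = .25, G = .25, U = .25)
  tags <- generate_tags(tag_generator_spec(
    2000, base_frequencies = unif, embed_fraction = 0.5,
    embed_motif = "AAAAAA", spacing_range = c(10, 20), seed = 42))
  ctrl <- generate_control(nchar(tags$seq), unif, seed = 43)
  enr <- enrich_kmers(tags, ctrl, k = 6)
  expect_equal(enr$kmer[1], "AAAAAA")
  expect_lt(enr$p_value[1], 0.05)
  expect_true(enr$significant[1])
  top <- select_top_kmers(enr, n = 15)
  expect_equal(top$kmer[1], "AAAAAA")
  expect_true(all(top$p_value < 0.05))  # filtered view honours alpha
})

test_that("embedded-motif enrichment ratio is monotone in embed fraction", {
  unif <- c(A = .25, C = .25, G = .25, U = .25)
  ctrl <- generate_control(rep(40L, 1500), unif, seed = 77)
  ratios <- vapply(c(0.1, 0.3, 0.5), function(f) {
    tags <- generate_tags(tag_generator_spec(
      1500, base_frequencies = unif, embed_fraction = f,
      embed_motif = "AAAAAA", spacing_range = c(10, 20), seed = 76))
    enr <- enrich_kmers(tags, ctrl, k = 6)
    enr$ratio[enr$kmer == "AAAAAA"]
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("top-k selection ranks by ratio, then p, then k-mer, and warns", {
  fake <- structure(
    data.frame(kmer = c("AAAAAA", "CCCCCC", "GGGGGG"),
               obs_count = c(30L, 40L, 40L), obs_total = 1000L,
               bg_count = c(10L, 20L, 20L), bg_total = 1000L,
               ratio = c(3, 2, 2), chi2 = c(10, 9, 8),
               p_value = c(1e-3, 1e-3, 2e-3),
               significant = TRUE),
    k = 6L, alpha = 0.05, correction = "none",
    class = c("kmer_enrichment", "data.frame"))
  expect_warning(top <- select_top_kmers(fake, n = 15), "only 3")
  expect_equal(top$kmer, c("AAAAAA", "CCCCCC", "GGGGGG"))
  # equal ratios: smaller p first
  expect_lt(top$p_value[2], top$p_value[3])
})

test_that("logo counts anchor at the first top k-mer occurrence", {
  lc <- build_logo_counts(tag_set("AAAA"), "AAA", flank = 0)
  expect_equal(dim(lc$counts), c(4L, 3L))
  expect_equal(unname(lc$counts["A", ]), c(1L, 1L, 1L))
  expect_equal(sum(lc$counts[c("C", "G", "U"), ]), 0L)
  expect_equal(lc$n_sequences, 1L)

  expect_warning(empty <- build_logo_counts(tag_set("CCCC"), "AAA"),
                 "no tag")
  expect_equal(empty$n_sequences, 0L)
  expect_true(all(empty$counts == 0L))
})

test_that("logo columns from an embedded-motif simulation are motif-dominated", {
  unif <- c(A = .25, C = .25, G = .25, U = .25)
  tags <- generate_tags(tag_generator_spec(
    1000, base_frequencies = unif, embed_fraction = 1,
    embed_motif = "AAAAAA", spacing_range = c(10, 20), seed = 55))
  lc <- build_logo_counts(tags, "AAAAAA", flank = 3)
  core <- as.character(0:5)
  expect_equal(lc$n_sequences, 1000L)
  # fully covered core columns sum to n_sequences, flanks to at most that
  expect_true(all(colSums(lc$counts[, core]) == 1000L))
  expect_true(all(colSums(lc$counts) <= 1000L))
  expect_true(all(lc$counts["A", core] / 1000 > 0.9))
})
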