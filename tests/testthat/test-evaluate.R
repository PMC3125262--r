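probes_for_genes <- function(gene_ids, probes_per_gene) {
  n <- length(gene_ids) * probes_per_gene
  data.frame(
    probe_id = paste0("p", seq_len(n)),
    category = "target",
    gene_id = rep(gene_ids, each = probes_per_gene),
    region = "exon",
    stringsAsFactors = FALSE
  )
}

test_that("gene t statistic matches the textbook one-sample formula", {
  probes <- probes_for_genes("g1", 5)
  ai <- data.frame(probe_id = probes$probe_id, ai = c(2.1, 1.9, 2.0, 2.2, 1.8))
  res <- conserved_gene_test(ai, probes)
  expect_equal(res$t_stat, 2.0 / (sd(ai$ai) / sqrt(5)), tolerance = 1e-9)
  expect_equal(res$t_stat, 28.2843, tolerance = 1e-4)
  expect_true(res$significant)
  # independent route: stats::t.test
  tt <- t.test(ai$ai, alternative = "greater")
  expect_equal(res$t_stat, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p_raw, tt$p.value, tolerance = 1e-12)
})

test_that("all-zero adjusted intensities call no gene conserved", {
  probes <- probes_for_genes(c("g1", "g2"), 4)
  ai <- data.frame(probe_id = probes$probe_id, ai = 0)
  res <- conserved_gene_test(ai, probes)
  expect_false(any(res$significant))
})

test_that("genes with planted shifts are called; nulls and small genes are not", {
  set.seed(88)
  genes <- sprintf("g%03d", 1:100)
  probes <- probes_for_genes(genes, 8)
  shifted <- genes[1:10]
  mu <- ifelse(probes$gene_id %in% shifted, 1.5, 0)
  ai <- data.frame(probe_id = probes$probe_id,
                   ai = rnorm(nrow(probes), mu, 0.5))
  res <- conserved_gene_test(ai, probes)
  expect_setequal(res$gene_id[res$significant], shifted)

  # a 1-probe gene is excluded, not an error
  probes2 <- rbind(probes,
                   data.frame(probe_id = "solo", category = "target",
                              gene_id = "gtiny", region = "exon"))
  ai2 <- rbind(ai, data.frame(probe_id = "solo", ai = 5))
  expect_message(res2 <- conserved_gene_test(ai2, probes2), "excluded")
  expect_identical(attr(res2, "excluded"), "gtiny")
  expect_false("gtiny" %in% res2$gene_id)
})

test_that("ratio track back-transforms AI differences and orders probes", {
  probes <- data.frame(
    probe_id = paste0("p", 1:4), chromosome = "chr1",
    start = c(300, 100, 200, 400), stringsAsFactors = FALSE)
  test <- data.frame(probe_id = probes$probe_id, ai = c(1, 1, 1 + log(2), 9))
  ref <- data.frame(probe_id = c(probes$probe_id[1:3], "only_ref"),
                    ai = c(1, 1, 1, 0))
  expect_message(tr <- ratio_track(test, ref, probes), "excluded")
  expect_equal(tr$position, c(100, 200, 300))
  expect_equal(tr$ratio, c(1, 2, 1), tolerance = 1e-12)

  set.seed(6)
  big <- data.frame(probe_id = paste0("q", 1:500), chromosome = "chr2",
                    start = seq(0, by = 35, length.out = 500))
  t2 <- data.frame(probe_id = big$probe_id, ai = rnorm(500))
  r2 <- data.frame(probe_id = big$probe_id, ai = rnorm(500))
  tr2 <- ratio_track(t2, r2, big)
  want <- exp(t2$ai - r2$ai)[match(tr2$probe_id, t2$probe_id)]
  expect_equal(tr2$ratio, want)
})

test_that("deletion scan finds exactly the planted run and nothing on flat tracks", {
  flat <- data.frame(probe_id = paste0("p", 1:200), chromosome = "chr1",
                     position = seq(0, by = 35, length.out = 200),
                     ratio = 1.0)
  expect_identical(nrow(deletion_scan(flat)), 0L)
  expect_identical(nrow(deletion_scan(flat[0, ])), 0L)

  dipped <- flat
  dipped$ratio[80:119] <- 0.3
  res <- deletion_scan(dipped, window_probes = 5, ratio_threshold = 0.5,
                       min_run = 10)
  expect_identical(nrow(res), 1L)
  oracle <- naive_deletion_runs(dipped$ratio, dipped$position, 5, 0.5, 10)
  expect_length(oracle, 1)
  expect_equal(res$start, unname(oracle[[1]]["start"]))
  expect_equal(res$end, unname(oracle[[1]]["end"]))
  # the called interval covers the planted probes
  expect_lte(res$start, dipped$position[80])
  expect_gte(res$end, dipped$position[119])

  set.seed(14)
  noisy <- flat
  noisy$ratio <- exp(rnorm(200, 0, 0.4))
  noisy$ratio[50:90] <- noisy$ratio[50:90] * 0.2
  res2 <- deletion_scan(noisy)
  oracle2 <- naive_deletion_runs(noisy$ratio, noisy$position, 5, 0.5, 10)
  expect_identical(nrow(res2), length(oracle2))
})

test_that("probe identity counts alignment columns, gaps as mismatch", {
  ident <- list(ref = strrep("ACGTT", 10), alt = strrep("ACGTT", 10))
  res <- probe_identity(ident, c(0, 10, 25))
  expect_equal(res$matches, c(25, 25, 25))
  expect_equal(res$class, rep("true", 3))

  # two substitutions inside the probe span
  ref <- strrep("A", 30)
  alt <- paste0(strrep("A", 5), "C", strrep("A", 10), "G", strrep("A", 13))
  res2 <- probe_identity(list(ref = ref, alt = alt), 0)
  expect_equal(res2$matches, 23)
  expect_equal(res2$class, "semi-true")

  expect_error(probe_identity(ident, 30), "spans beyond")
  expect_equal(identity_class(c(25, 24, 23, 22, 21, 0)),
               c("true", "semi-true", "semi-true", "false", "false", "false"))
})

test_that("probe identity equals the naive column counter on mutated pairs", {
  for (seed in 1:25) {
    pair <- generate_ortholog_pair(120, divergence_per_site = 0.08,
                                   indel_rate = 0.01, seed = seed)
    starts <- seq(0, 120 - 25, by = 7)
    got <- probe_identity(pair$alignment, starts)$matches
    want <- vapply(starts, function(s) {
      naive_probe_matches(pair$alignment, s, 25)
    }, numeric(1))
    expect_identical(got, as.integer(want))
  }
})

test_that("global alignment reproduces hand scores and exhaustive optima", {
  aln <- align_orthologs("ACGT", "ACGT")
  expect_equal(aln$score, 4)
  expect_identical(aln$ref, "ACGT")
  expect_identical(aln$alt, "ACGT")

  # one gap column: 3 matches + gap open (-5), no extensions
  expect_equal(align_orthologs("ACGT", "ACT")$score, -2)

  set.seed(19)
  for (i in 1:30) {
    a <- rand_seqs(1, sample(2:6, 1))
    b <- rand_seqs(1, sample(2:6, 1))
    got <- align_orthologs(a, b)
    expect_equal(got$score, enum_align_score(a, b), info = paste(a, b))
    expect_equal(align_orthologs(b, a)$score, got$score)
  }
  expect_error(align_orthologs("", "ACGT"), "nonempty")
})

test_that("threshold accumulation matches brute-force enumeration", {
  ratios <- data.frame(probe_id = paste0("p", 1:5),
                       ratio = c(1.2, 1.0, 0.9, 1.1, 0.5))
  ids <- data.frame(probe_id = paste0("p", 1:5),
                    matches = c(25, 25, 24, 20, 19),
                    class = identity_class(c(25, 25, 24, 20, 19)))
  curve <- threshold_accumulation(ratios, ids, c(0.4, 1.0, 1.3))
  at1 <- curve[curve$threshold == 1.0, ]
  expect_equal(at1$n_true, 2)
  expect_equal(at1$n_semi_true, 0)
  expect_equal(at1$n_false, 1)
  expect_equal(at1$mismatch_to_perfect, 0.5)
  # nothing at-or-above the top threshold: zero counts, undefined ratio
  top <- curve[curve$threshold == 1.3, ]
  expect_equal(top$n_true + top$n_semi_true + top$n_false, 0)
  expect_true(is.na(top$mismatch_to_perfect))

  set.seed(23)
  r2 <- data.frame(probe_id = paste0("q", 1:300), ratio = exp(rnorm(300)))
  m2 <- sample(0:25, 300, replace = TRUE)
  i2 <- data.frame(probe_id = r2$probe_id, matches = m2,
                   class = identity_class(m2))
  c2 <- threshold_accumulation(r2, i2, seq(0.2, 3, by = 0.2))
  for (col in c("n_true", "n_semi_true", "n_false")) {
    expect_true(all(diff(c2[[col]]) <= 0))
  }
})

test_that("k-mer frequency counts both strands, overlaps included", {
  expect_equal(kmer_frequency("CCCC", c(p = "AA"))$count_in_genome, 0L)
  expect_equal(kmer_frequency("AAAA", c(p = "AA"))$count_in_genome, 3L)
  # palindrome-free double counting: ACG occurs once, CGT (its RC) once
  expect_equal(kmer_frequency("ACGT", c(p = "ACG"))$count_in_genome, 2L)
  expect_equal(kmer_frequency("ACGT", c(p = "ACG"),
                              both_strands = FALSE)$count_in_genome, 1L)

  set.seed(29)
  chrom1 <- rand_seqs(1, 4000)
  dup <- substr(chrom1, 101, 125)
  chrom2 <- paste0(rand_seqs(1, 1000), dup, rand_seqs(1, 500), dup,
                   rand_seqs(1, 200))
  genome <- c(chr1 = chrom1, chr2 = chrom2)
  probes <- c(dup = dup, absent = rand_seqs(1, 25),
              edge = substr(chrom2, 1, 25))
  got <- kmer_frequency(genome, probes)
  want <- vapply(probes, function(p) {
    naive_kmer_count(genome, p) + naive_kmer_count(genome, revcomp(p))
  }, numeric(1))
  expect_identical(got$count_in_genome, as.integer(want))
  expect_gte(got$count_in_genome[got$probe_id == "dup"], 3L)
})
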