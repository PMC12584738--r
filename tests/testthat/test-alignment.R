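test_that("six-frame translation follows the standard code and N policy", {
  tf <- translate_six_frames("ATGAAATAG")
  expect_equal(tf$protein[tf$frame == 1], "MK*")
  # frame -1 equals frame +1 of the reverse complement
  tf_rc <- translate_six_frames(revcomp("ATGAAATAG"))
  expect_equal(tf$protein[tf$frame == -1], tf_rc$protein[tf_rc$frame == 1])
  expect_equal(translate_six_frames("ATGNAA")$protein[1], "MX")
  expect_error(translate_six_frames("AT"), "codon")
})

test_that("protein positions map back to exact nucleotide ranges", {
  set.seed(20)
  nt <- random_dna_str(120)
  tf <- translate_six_frames(nt)
  for (i in seq_len(nrow(tf))) {
    fr <- tf$frame[i]; off <- tf$offset[i]
    n_aa <- nchar(tf$protein[i])
    a <- sample(seq_len(n_aa), 1)
    b <- min(n_aa, a + sample(0:5, 1))
    r <- aa_to_nt_range(fr, off, a, b, nchar(nt))
    sub <- substr(if (fr > 0) nt else revcomp(nt),
                  off + 3 * (a - 1) + 1, off + 3 * b)
    got <- extract_locus(contig_set(c(x = nt)),
                         locus("x", as.integer(r[["start"]]),
                               as.integer(r[["end"]]), r[["strand"]]))$seq
    expect_equal(got, sub)
  }
})

test_that("local alignment handles identical, disjoint and scored cases", {
  al <- local_align("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(al$score, 20)
  expect_equal(al$identity, 1)
  expect_equal(c(al$a_start, al$a_end), c(0L, 10L))
  # disjoint alphabets: empty alignment, score 0
  al0 <- local_align("AAAA", "GGGG")
  expect_equal(al0$score, 0)
  expect_equal(al0$aln_cols, 0L)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local alignment score equals exhaustive enumeration on random 8-mers", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_dna_str(8)
    b <- random_dna_str(8)
    mine <- local_align(a, b, mode = "nucleotide")$score
    orc <- oracle_local_score(a, b)
    expect_equal(mine, orc, info = paste(a, b))
  }
})

test_that("local alignment score is symmetric in its arguments", {
  set.seed(22)
  for (i in 1:10) {
    a <- random_dna_str(30); b <- random_dna_str(30)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(estimate_evalue(10, 1, 1, lambda = log(2), K = 1), 2^-10)
  # linear in search space
  e1 <- estimate_evalue(30, 100, 1e6, mode = "nucleotide")
  e2 <- estimate_evalue(30, 100, 2e6, mode = "nucleotide")
  expect_equal(e2, 2 * e1)
  # monotone decreasing in score
  s <- seq(0, 100, by = 5)
  ev <- estimate_evalue(s, 100, 1e6, mode = "nucleotide")
  expect_true(all(diff(ev) < 0))
  expect_error(estimate_evalue(-1, 10, 10), ">= 0")
})

test_that("seeded search finds a verbatim planted query exactly once", {
  set.seed(23)
  bg <- random_dna_str(20000)
  q <- random_dna_str(300)
  genome <- contig_set(c(chr = paste0(substr(bg, 1, 9000), q,
                                      substr(bg, 9001, 20000))))
  hits <- seeded_search(q, genome, mode = "nucleotide")
  hits <- hits[hits$evalue <= 1e-5, ]
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1)
  expect_equal(hits$coverage, 1)
  expect_equal(hits$s_start, 9000L)
  expect_equal(hits$s_end, 9300L)
  expect_equal(hits$strand, "+")
})

test_that("seeded search is quiet on genomes without the query", {
  set.seed(24)
  q <- random_dna_str(300)
  misses <- 0L
  for (i in 1:10) {
    genome <- contig_set(c(chr = random_dna_str(20000)))
    hits <- seeded_search(q, genome, mode = "nucleotide")
    if (nrow(hits[hits$evalue <= 1e-5, ]) == 0) misses <- misses + 1L
  }
  expect_gte(misses, 9L)
})

test_that("protein search reports negative frames with correct loci", {
  set.seed(25)
  prot <- paste0("M", random_protein(120, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  cds <- paste0("ATG", reverse_translate(substr(prot, 2, nchar(prot))), "TAA")
  bg <- random_dna_str(8000)
  genome <- contig_set(c(chr = paste0(substr(bg, 1, 4000), revcomp(cds),
                                      substr(bg, 4001, 8000))))
  hits <- seeded_search(prot, genome, mode = "protein-vs-translated")
  best <- hits[1, ]
  expect_lt(best$evalue, 1e-5)
  expect_true(best$frame < 0)
  expect_equal(best$strand, "-")
  # reported locus re-extracts a sequence that translates back to the query
  got <- extract_locus(genome, locus(best$contig, best$s_start, best$s_end,
                                     best$strand))$seq
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(got))),
               substr(prot, best$q_start + 1, best$q_end))
})

test_that("hit identities are reproduced by re-aligning the reported ranges", {
  set.seed(26)
  bg <- random_dna_str(30000)
  q0 <- random_dna_str(500)
  q <- mutate_to_identity(q0, 0.9)
  genome <- contig_set(c(chr = paste0(substr(bg, 1, 15000), q0,
                                      substr(bg, 15001, 30000))))
  hits <- seeded_search(q, genome, mode = "nucleotide")
  h <- hits[1, ]
  sub <- substr(genome$contigs[["chr"]], h$s_start + 1, h$s_end)
  qq <- substr(q, h$q_start + 1, h$q_end)
  re <- local_align(qq, sub, mode = "nucleotide")
  expect_equal(re$identity, h$identity, tolerance = 1e-9)
  expect_gte(re$score, h$score - 1e-9)
})

test_that("seeded search recalls 85%-identity planted queries", {
  set.seed(27)
  found <- 0L
  for (i in 1:10) {
    bg <- random_dna_str(20000)
    q0 <- random_dna_str(300)
    genome <- contig_set(c(chr = paste0(substr(bg, 1, 10000), q0,
                                        substr(bg, 10001, 20000))))
    q <- mutate_to_identity(q0, 0.85)
    hits <- seeded_search(q, genome, mode = "nucleotide")
    hits <- hits[hits$evalue <= 1e-5 &
                   hits$s_start < 10300 & hits$s_end > 10000, ]
    if (nrow(hits) > 0) found <- found + 1L
  }
  expect_gte(found / 10, 0.9)
})

test_that("discontiguous mode finds diverged matches and rejects short queries", {
  set.seed(28)
  bg <- random_dna_str(10000)
  q0 <- random_dna_str(600)
  genome <- contig_set(c(chr = paste0(substr(bg, 1, 5000), q0,
                                      substr(bg, 5001, 10000))))
  q <- mutate_to_identity(q0, 0.9)
  hits <- seeded_search(q, genome, mode = "discontiguous-nucleotide")
  expect_gt(nrow(hits), 0)
  expect_gt(hits$identity[1], 0.85)
  expect_error(seeded_search("ACGTACGT", genome,
                             mode = "discontiguous-nucleotide"), "template")
  expect_error(seeded_search(strrep("A", 5), genome, mode = "nucleotide"),
               "word size")
})

test_that("genome_index reproduces direct search results", {
  set.seed(29)
  bg <- random_dna_str(15000)
  q <- random_dna_str(400)
  genome <- contig_set(c(chr = paste0(substr(bg, 1, 7000), q,
                                      substr(bg, 7001, 15000))))
  idx <- genome_index(genome, "nucleotide")
  h1 <- seeded_search(q, genome, mode = "nucleotide")
  h2 <- seeded_search(q, genome, mode = "nucleotide", index = idx)
  expect_equal(h1, h2)
  expect_error(seeded_search(q, genome, mode = "discontiguous-nucleotide",
                             index = idx), "does not match")
})
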