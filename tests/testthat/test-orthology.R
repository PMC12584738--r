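pair_fixture <- function(speciation = 8, seed = 70) {
  set.seed(seed)
  tpl <- default_templates()
  anc_plan <- data.frame(lineage = c("GammaA", "BetaA"), age_myr = c(1, 1.5),
                         state = "intact", strand = "+",
                         stringsAsFactors = FALSE)
  anc <- simulate_genome(anc_plan, tpl)
  simulate_species_pair(anc, speciation_myr = speciation,
                        private_a = data.frame(
                          lineage = "GammaB", age_myr = min(3, speciation / 2 + 1),
                          state = "intact", strand = "+",
                          stringsAsFactors = FALSE),
                        templates = tpl)
}

test_that("flank extraction clips at contig ends and records achieved lengths", {
  g <- contig_set(c(c1 = random_dna_str(5000)), species = "a")
  pr <- extract_flank_pair(g, locus("c1", 100, 600), g, locus("c1", 2000, 2500),
                           flank = 1000)
  expect_equal(nchar(pr$insertion_a), 500L)
  expect_equal(unname(pr$flank_a["left"]), 100)   # clipped at contig start
  expect_equal(unname(pr$flank_a["right"]), 1000)
  expect_equal(unname(pr$flank_b["left"]), 1000)
  # flank 0: insertion regions only
  pr0 <- extract_flank_pair(g, locus("c1", 100, 600), g, locus("c1", 2000, 2500),
                            flank = 0)
  expect_equal(pr0$left_a, "")
  expect_equal(sum(pr0$flank_a), 0)
})

test_that("shared ancestral insertions are called orthologous", {
  pr <- pair_fixture(speciation = 8)
  truth <- pr$truth
  shared_a <- truth[truth$species_tag == "SpA" & !is.na(truth$ortholog_group), ]
  shared_b <- truth[truth$species_tag == "SpB" & !is.na(truth$ortholog_group), ]
  for (g in shared_a$ortholog_group) {
    ra <- shared_a[shared_a$ortholog_group == g, ]
    rb <- shared_b[shared_b$ortholog_group == g, ]
    pairx <- extract_flank_pair(pr$genome_a, locus(ra$contig, ra$start, ra$end),
                                pr$genome_b, locus(rb$contig, rb$start, rb$end))
    call <- call_ortholog(pairx)
    expect_equal(call$verdict, "ortholog")
    expect_gte(call$insertion_identity, 0.85)
    expect_gte(call$flank_coverage, 0.50)
    # retained alignments re-verified against the length and E filters
    for (tab in call$flank_alignments) {
      if (nrow(tab)) expect_true(all(tab$aln_len >= 500))
    }
  }
})

test_that("a private insertion against a random locus is rejected", {
  pr <- pair_fixture(speciation = 8)
  truth <- pr$truth
  priv <- truth[truth$species_tag == "SpA" & is.na(truth$ortholog_group), ][1, ]
  glen <- nchar(pr$genome_b$contigs[["chr1"]])
  w <- priv$end - priv$start
  rnd_start <- glen - w - 2000L   # background tail, clear of planted spans
  rnd <- locus("chr1", rnd_start, rnd_start + w)
  pairx <- extract_flank_pair(pr$genome_a,
                              locus(priv$contig, priv$start, priv$end),
                              pr$genome_b, rnd)
  call <- call_ortholog(pairx)
  expect_equal(call$verdict, "not_ortholog")
})

test_that("matching insertions with unrelated flanks fail the coverage rule", {
  set.seed(71)
  elem <- random_dna_str(6000)
  ga <- contig_set(c(c1 = paste0(random_dna_str(35000), elem,
                                 random_dna_str(35000))), species = "a")
  gb <- contig_set(c(c1 = paste0(random_dna_str(35000), elem,
                                 random_dna_str(35000))), species = "b")
  pairx <- extract_flank_pair(ga, locus("c1", 35000, 41000),
                              gb, locus("c1", 35000, 41000))
  call <- call_ortholog(pairx)
  expect_gte(call$insertion_identity, 0.85)   # insertion matches...
  expect_lt(call$flank_coverage, 0.5)         # ...but flanks do not
  expect_equal(call$verdict, "not_ortholog")
})

test_that("the survey reports one best partner per element", {
  pr <- pair_fixture(speciation = 8)
  truth <- pr$truth
  ta <- truth[truth$species_tag == "SpA", ]
  tb <- truth[truth$species_tag == "SpB", ]
  cat_a <- data.frame(id = ta$element_id, contig = ta$contig, start = ta$start,
                      end = ta$end, strand = ta$strand, stringsAsFactors = FALSE)
  part_b <- data.frame(contig = tb$contig, start = tb$start, end = tb$end,
                       strand = tb$strand, stringsAsFactors = FALSE)
  calls <- survey_orthologs(cat_a, pr$genome_a, pr$genome_b, part_b)
  expect_equal(nrow(calls), nrow(cat_a))
  n_shared <- sum(!is.na(ta$ortholog_group))
  expect_equal(sum(calls$verdict == "ortholog"), n_shared)
  # the private element gets no ortholog verdict
  priv_ids <- ta$element_id[is.na(ta$ortholog_group)]
  expect_true(all(calls$verdict[calls$id %in% priv_ids] == "not_ortholog"))
})

test_that("verdicts are invariant under genome swap", {
  pr <- pair_fixture(speciation = 4, seed = 72)
  truth <- pr$truth
  shared_a <- truth[truth$species_tag == "SpA" & !is.na(truth$ortholog_group), ][1, ]
  shared_b <- truth[truth$species_tag == "SpB" &
                      truth$ortholog_group == shared_a$ortholog_group, ]
  p1 <- extract_flank_pair(pr$genome_a,
                           locus(shared_a$contig, shared_a$start, shared_a$end),
                           pr$genome_b,
                           locus(shared_b$contig, shared_b$start, shared_b$end))
  p2 <- extract_flank_pair(pr$genome_b,
                           locus(shared_b$contig, shared_b$start, shared_b$end),
                           pr$genome_a,
                           locus(shared_a$contig, shared_a$start, shared_a$end))
  expect_equal(call_ortholog(p1)$verdict, call_ortholog(p2)$verdict)
})
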