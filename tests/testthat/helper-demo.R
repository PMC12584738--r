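# Shared fixtures built once per test run.  The demo bundle (simulated
# genome + screen + structural annotation) backs the structural, solo-LTR
# and summary tests; smaller fixtures are built inline where cheap.

.fixture_env <- new.env(parent = emptyenv())

demo_bundle <- function() {
  if (!is.null(.fixture_env$demo)) return(.fixture_env$demo)
  set.seed(20240601)
  templates <- default_templates()
  sim <- simulate_genome(demo_plan(), templates)
  probes <- vapply(templates, function(t) t$proteins$POL, character(1))
  cands <- screen_genome(probes, sim$genome)
  catalog <- annotate_candidates(sim$genome, cands)
  .fixture_env$demo <- list(templates = templates, sim = sim,
                            probes = probes, cands = cands,
                            catalog = catalog)
  .fixture_env$demo
}

small_sim <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  set.seed(11)
  templates <- default_templates()
  plan <- data.frame(
    lineage = c("GammaA", "GammaA", "BetaA", "GammaB"),
    age_myr = c(0, 5, 3, 8),
    state = c("intact", "intact", "solo", "intact"),
    strand = c("+", "-", "+", "+"), stringsAsFactors = FALSE)
  sim <- simulate_genome(plan, templates)
  probes <- vapply(templates, function(t) t$proteins$POL, character(1))
  cands <- screen_genome(probes, sim$genome)
  catalog <- annotate_candidates(sim$genome, cands)
  .fixture_env$small <- list(templates = templates, sim = sim,
                             probes = probes, cands = cands,
                             catalog = catalog)
  .fixture_env$small
}

# match an annotated provirus back to its truth row by span proximity
truth_row_for <- function(truth, pv, slack = 60L) {
  i <- which(truth$contig == pv$contig & abs(truth$start - pv$span$start) < slack)
  if (length(i) != 1) return(NULL)
  truth[i, ]
}
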