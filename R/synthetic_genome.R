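#' Random background DNA
#'
#' I.i.d. sequence with a target GC fraction, used as the neutral host
#' genome into which proviruses are planted.
#'
#' @param length Length in bp (> 0).
#' @param gc Target GC fraction in (0, 1); 0 and 1 are allowed edge cases.
#' @param seed Optional RNG seed (set once; omit to use the current RNG
#'   stream, as the pipeline does).
#' @param contig_id Contig name.
#' @param species Species tag.
#' @return A `ContigSet` with one contig.
#' @export
make_background <- function(length, gc = 0.42, seed = NULL,
                            contig_id = "chr1", species = "sim") {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- random_dna(length, gc)
  contig_set(stats::setNames(s, contig_id), species = species)
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Forward-simulate substitutions under the Kimura two-parameter model
#'
#' Exact continuous-time simulation: the number of substitution events at
#' each site is Poisson with mean `rate * time`, and each event is a
#' transition with probability `kappa / (kappa + 1)` (transitions carry
#' weight kappa against the two transversion channels at 1/2 each, so the
#' observed transition/transversion count ratio converges to kappa).
#' Multiple hits at one site occur naturally, which is what the
#' downstream distance correction must be able to undo.
#'
#' @param seq DNA string.
#' @param time_myr Elapsed time in million years (>= 0).
#' @param rate Substitution rate per site per year (total rate, all
#'   channels); default the average mammalian neutral rate 2.2e-9.
#' @param kappa Transition/transversion ratio: rate of transitions
#'   relative to the total transversion rate.
#' @return Mutated DNA string of the same length.
#' @export
mutate_k2p <- function(seq, time_myr, rate = 2.2e-9, kappa = 2) {
  stopifnot(time_myr >= 0, rate > 0, kappa > 0)
  if (time_myr == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  mu <- rate * time_myr * 1e6
  nev <- stats::rpois(n, mu)
  idx <- which(nev > 0 & v %in% c("A", "C", "G", "T"))
  if (length(idx) == 0) return(seq)
  p_ts <- kappa / (kappa + 1)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (i in idx) {
    b <- v[i]
    for (e in seq_len(nev[i])) {
      if (stats::runif(1) < p_ts) {
        b <- transition[[b]]
      } else {
        b <- transversions[[b]][1L + (stats::runif(1) < 0.5)]
      }
    }
    v[i] <- b
  }
  paste(v, collapse = "")
}

# ---- motif-bearing synthetic proteins -------------------------------------

# residues used for random protein backbone; C excluded so cysteine motifs
# occur only where planted, and the patterns' literal anchors stay unique
# enough for recall bookkeeping.
protein_backbone <- function(n) {
  paste(sample(setdiff(c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                         "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), "H"),
               n, replace = TRUE), collapse = "")
}

splice_in <- function(protein, at, insert) {
  # overwrite (not insert) so planned coordinates stay fixed; `at` 1-based
  paste0(substr(protein, 1, at - 1), insert,
         substr(protein, at + nchar(insert), nchar(protein)))
}

#' Synthetic GAG/POL/ENV proteins carrying the canonical retroviral motifs
#'
#' Random protein backbones with the motif instances the characterization
#' stage screens for, planted at recorded positions: GAG carries the PPPY
#' late domain, the major homology region and the Cys-His box; ENV carries
#' the receptor-binding motif, a furin cleavage site, the CX6CC motif of
#' gamma-type envelopes and the YXXL cytoplasmic-tail motif.  POL is a
#' plain backbone (its characterization in this package is length- and
#' homology-based).
#'
#' @param gag_len,pol_len,env_len Protein lengths (aa).
#' @return List with elements `GAG`, `POL`, `ENV` (strings) and
#'   `motif_truth` (data.frame gene/motif_id/position 0-based/instance).
#' @export
synth_orf_proteins <- function(gag_len = 540, pol_len = 720, env_len = 460) {
  gag <- protein_backbone(gag_len)
  gag_motifs <- data.frame(
    gene = "GAG",
    motif_id = c("PPPY", "MHR", "CysHis"),
    position = c(120L, 260L, gag_len - 40L),
    instance = c("PPPY", "QGAMENLKRFAV", "CKLCNGAGHFAREC"),
    stringsAsFactors = FALSE)  # CysHis instance satisfies CX2CX4HX4C
  for (i in seq_len(nrow(gag_motifs)))
    gag <- splice_in(gag, gag_motifs$position[i] + 1L, gag_motifs$instance[i])

  pol <- protein_backbone(pol_len)

  env <- protein_backbone(env_len)
  env_motifs <- data.frame(
    gene = "ENV",
    motif_id = c("RBM", "Furin", "CX6CC", "YXXL"),
    position = c(90L, 230L, 330L, env_len - 20L),
    instance = c("SDGGGWSDTMR", "RNKR", "CLDTSSACC", "YQAL"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(env_motifs)))
    env <- splice_in(env, env_motifs$position[i] + 1L, env_motifs$instance[i])

  list(GAG = gag, POL = pol, ENV = env,
       motif_truth = rbind(gag_motifs, env_motifs))
}

#' Reverse-translate a protein to DNA
#'
#' Codons are drawn uniformly among synonymous codons; `*` becomes TAA.
#'
#' @param protein Protein string (20-letter alphabet plus `*`).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  tab <- codon_table()
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    ch <- tab[[a]]
    if (is.null(ch)) stop("cannot reverse-translate residue: ", a)
    ch[sample.int(length(ch), 1)]
  }, character(1))
  paste(codons, collapse = "")
}

codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      tab <- split(names(gc), unname(gc))
      cache <<- tab
    }
    cache
  }
})

# ---- provirus templates ---------------------------------------------------

#' Shipped synthetic tRNA 3'-end library for PBS annotation
#'
#' Labeled synthetic 18-mers standing in for tRNA 3' ends (the provirus PBS
#' is the reverse complement of one of these); includes decoys.  Real tRNA
#' sets can be supplied to [find_pbs()] in the same format.
#'
#' @return Data frame with columns `label` and `trna18`.
#' @export
trna_library <- function() {
  data.frame(
    label = c("Pro", "Phe", "Lys", "decoy1", "decoy2"),
    trna18 = c("TGGCGCAGGGTTCGAATC",
               "TGGTGCGAATTCTGTGGA",
               "TGGCGCCCGAACAGGGAC",
               "ACCTAGGACCTTTAGGCA",
               "GATTACACATGGTCCTAA"),
    stringsAsFactors = FALSE)
}

#' Build a provirus template
#'
#' A template is the ancestral (age-0) element: LTR + PBS + GAG/POL/ENV
#' ORF cassette + PPT + LTR, with both LTRs identical.  The PBS is the
#' reverse complement of the chosen tRNA 3' 18-mer; the PPT is a
#' purine-rich tract abutting the 3' LTR.
#'
#' @param name Lineage label for the template (e.g. `"GammaA"`).
#' @param genus `"Gamma"`, `"Beta"`, `"Alpha"` or `"unassigned"`.
#' @param ltr_len LTR length in bp (100..7000).
#' @param trna tRNA label for the PBS (row of [trna_library()]).
#' @param tsd_len Target-site duplication length (4..6).
#' @param proteins Optional protein list from [synth_orf_proteins()].
#' @return A `ProvirusTemplate` list with the assembled `element`, feature
#'   offsets (0-based, element-relative), ORF DNA/proteins and motif truth.
#' @export
provirus_template <- function(name, genus = "Gamma", ltr_len = 600,
                              trna = "Pro", tsd_len = 5L, proteins = NULL) {
  stopifnot(ltr_len >= 100, ltr_len <= 7000, tsd_len >= 4, tsd_len <= 6)
  lib <- trna_library()
  if (!trna %in% lib$label) stop("unknown tRNA label: ", trna)
  if (is.null(proteins)) proteins <- synth_orf_proteins()
  ltr <- random_dna(ltr_len, gc = 0.45)
  pbs <- revcomp(lib$trna18[lib$label == trna])
  orf_dna <- lapply(proteins[c("GAG", "POL", "ENV")], function(p) {
    paste0("ATG", reverse_translate(p), "TAA")
  })
  spacer <- function(n) random_dna(n, gc = 0.42)
  sp1 <- spacer(24); sp2 <- spacer(18); sp3 <- spacer(18); sp4 <- spacer(24)
  ppt <- "AGGAAGGGGAAG"  # 12 bp, all purine

  parts <- list(ltr5 = ltr, pbs = pbs, sp1 = sp1,
                GAG = orf_dna$GAG, sp2 = sp2, POL = orf_dna$POL,
                sp3 = sp3, ENV = orf_dna$ENV, sp4 = sp4,
                ppt = ppt, ltr3 = ltr)
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens
  offsets <- data.frame(feature = names(parts), start = unname(starts),
                        end = unname(ends), stringsAsFactors = FALSE)
  element <- paste(unlist(parts), collapse = "")
  total <- nchar(element)
  if (total > 15000 + ltr_len)
    stop("template longer than the detection window allows")
  structure(list(
    name = name, genus = genus, ltr = ltr, ltr_len = ltr_len,
    pbs = pbs, trna_label = trna, ppt = ppt, tsd_len = as.integer(tsd_len),
    orf_dna = orf_dna, proteins = proteins[c("GAG", "POL", "ENV")],
    motif_truth = proteins$motif_truth, offsets = offsets,
    element = element, length = total), class = "ProvirusTemplate")
}

#' Default template panel for the bundled demo
#'
#' Three lineages: two gammaretrovirus-like templates with distinct LTRs
#' and internal genes, and one betaretrovirus-like template with a PBS-Lys.
#'
#' @param seed Optional seed.
#' @return Named list of `ProvirusTemplate`s.
#' @export
default_templates <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    GammaA = provirus_template("GammaA", genus = "Gamma", ltr_len = 600, trna = "Pro"),
    GammaB = provirus_template("GammaB", genus = "Gamma", ltr_len = 520, trna = "Phe"),
    BetaA = provirus_template("BetaA", genus = "Beta", ltr_len = 420, trna = "Lys")
  )
}

# ---- planting -------------------------------------------------------------

empty_truth <- function() {
  data.frame(element_id = character(), species_tag = character(),
             contig = character(), start = integer(), end = integer(),
             strand = character(), state = character(),
             true_age_myr = numeric(), tsd = character(),
             lineage_id = character(), ltr_len = integer(),
             ortholog_group = character(), stringsAsFactors = FALSE)
}

# LINE-1-like cassette: a non-LTR interruption (ORF2-ish random sequence
# ending in a poly-A tail), used for the nested state.
line1_cassette <- function(len = 2000) {
  paste0(random_dna(len - 30, gc = 0.38), strrep("A", 30))
}

#' Plant one element into a genome
#'
#' Inserts a template-derived element at `point` with a TSD (the
#' `tsd_len` bases at the point duplicated on both sides).  Each LTR is
#' mutated independently for `age_myr` (so the expected LTR-LTR divergence
#' is about `2 * rate * age`); the internal region is mutated once.
#' `state = "degraded"` additionally injects a premature stop into every
#' ORF; `"solo"` leaves a single mutated LTR plus TSD; `"nested"` inserts a
#' LINE-1-like cassette between ENV and the 3' LTR.
#'
#' @param genome `ContigSet` (planting metadata is carried in attributes).
#' @param template A `ProvirusTemplate`.
#' @param contig Target contig id.
#' @param point 0-based insertion point.
#' @param age_myr True age in million years.
#' @param state One of `"intact"`, `"degraded"`, `"solo"`, `"nested"`.
#' @param strand Strand the element is inserted on.
#' @param rate,kappa Substitution-process parameters (see [mutate_k2p()]).
#' @param element_id Identifier for the truth table (auto-numbered if NULL).
#' @return List with the updated `genome` and the accumulated `truth`
#'   table (also attached to the genome as attribute `"truth"`).
#' @export
plant <- function(genome, template, contig, point, age_myr,
                  state = c("intact", "degraded", "solo", "nested"),
                  strand = "+", rate = 2.2e-9, kappa = 2, element_id = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(genome, "ContigSet"), inherits(template, "ProvirusTemplate"))
  gseq <- genome$contigs[[contig]]
  if (is.null(gseq)) stop("unknown contig: ", contig)
  tsd_len <- template$tsd_len
  if (point < tsd_len || point + tsd_len > nchar(gseq))
    stop("insertion point too close to contig end")
  truth <- attr(genome, "truth")
  if (is.null(truth)) truth <- empty_truth()
  prior <- truth[truth$contig == contig, , drop = FALSE]
  if (nrow(prior) > 0 && any(point > prior$start & point < prior$end))
    stop("insertion point overlaps an existing planted element")

  elem <- build_aged_element(template, age_myr, state, rate, kappa)
  if (strand == "-") elem$seq <- revcomp(elem$seq)
  # unambiguous-truth guard: the planted TSD must be the unique maximal
  # flanking duplication in a small neighborhood of the true boundaries,
  # or downstream structure calling faces a genuinely undecidable site.
  # Reject points where (a) the duplication would read longer than the
  # planted TSD at the true boundaries, or (b) a competing duplication of
  # length >= tsd_len exists at any jointly shifted boundary pair within
  # the screened shift range; slide the point a few bases rather than plant an ambiguous
  # site.
  first_b <- substr(elem$seq, 1L, 1L)
  last_b <- substr(elem$seq, nchar(elem$seq), nchar(elem$seq))
  el <- nchar(elem$seq)
  ok_point <- function(p) {
    if (p < tsd_len + 20L || p + tsd_len + 20L > nchar(gseq)) return(FALSE)
    if (substr(gseq, p, p) == last_b) return(FALSE)
    if (substr(gseq, p + tsd_len + 1L, p + tsd_len + 1L) == first_b) return(FALSE)
    if (nrow(prior) > 0 && any(p > prior$start & p < prior$end)) return(FALSE)
    site0 <- substr(gseq, p + 1L, p + tsd_len)
    asm <- paste0(substr(gseq, p - 19L, p), site0, substr(elem$seq, 1L, 20L),
                  substr(elem$seq, el - 19L, el), site0,
                  substr(gseq, p + tsd_len + 1L, p + tsd_len + 20L))
    s0 <- 20L + tsd_len
    e0 <- s0 + 40L
    # the refinement searches +/-6 bp around *detected* boundaries, which
    # can themselves drift a few bases from truth, so screen +/-10.
    # Combos whose candidate copies both lie fully inside the element are
    # excluded: they do not depend on the insertion point, so sliding
    # cannot avoid them; the residual chance of such a duplication both
    # existing and winning the refinement is negligible.
    for (ds in -10:10) {
      for (de in -10:10) {
        if (ds == 0 && de == 0) next
        if (ds >= 6 && de <= -6) next
        t <- find_tsd(asm, s0 + ds, e0 + de, tsd_min = tsd_len, tsd_max = 6L)
        if (is.null(t)) next
        # a longer duplication would outrank the true TSD anywhere in the
        # refinement range; an equal-length one only if it sits closer to
        # the detected boundaries, so only near-zero shifts are fatal
        if (nchar(t$sequence) > tsd_len) return(FALSE)
        if (abs(ds) <= 3 && abs(de) <= 3) return(FALSE)
      }
    }
    TRUE
  }
  if (!ok_point(point)) {
    for (off in as.integer(rbind(1:60, -(1:60)))) {
      if (ok_point(point + off)) { point <- point + off; break }
    }
    if (!ok_point(point)) stop("no unambiguous insertion point near ", point)
  }
  site <- substr(gseq, point + 1L, point + tsd_len)
  new_seq <- paste0(substr(gseq, 1, point + tsd_len), elem$seq,
                    substr(gseq, point + 1L, nchar(gseq)))
  genome$contigs[[contig]] <- new_seq

  shift <- tsd_len + nchar(elem$seq)
  adjust <- truth$contig == contig & truth$start >= point
  truth$start[adjust] <- truth$start[adjust] + shift
  truth$end[adjust] <- truth$end[adjust] + shift

  if (is.null(element_id)) element_id <- sprintf("elem%03d", nrow(truth) + 1L)
  row <- data.frame(
    element_id = element_id, species_tag = genome$species, contig = contig,
    start = point + tsd_len, end = point + tsd_len + nchar(elem$seq),
    strand = strand, state = state, true_age_myr = age_myr, tsd = site,
    lineage_id = template$name, ltr_len = template$ltr_len,
    ortholog_group = NA_character_, stringsAsFactors = FALSE)
  truth <- rbind(truth, row)
  attr(genome, "truth") <- truth
  list(genome = genome, truth = truth)
}

build_aged_element <- function(template, age_myr, state, rate, kappa) {
  if (state == "solo") {
    return(list(seq = mutate_k2p(template$ltr, age_myr, rate, kappa)))
  }
  ltr5 <- mutate_k2p(template$ltr, age_myr, rate, kappa)
  ltr3 <- mutate_k2p(template$ltr, age_myr, rate, kappa)
  off <- template$offsets
  internal_start <- off$end[off$feature == "ltr5"]
  internal_end <- off$start[off$feature == "ltr3"]
  internal <- substr(template$element, internal_start + 1L, internal_end)
  internal <- mutate_k2p(internal, age_myr, rate, kappa)
  if (state == "degraded") {
    # premature stop in each ORF: overwrite a mid-ORF codon with TAA
    for (g in c("GAG", "POL", "ENV")) {
      os <- off$start[off$feature == g] - internal_start
      ol <- nchar(template$orf_dna[[g]])
      codon_i <- floor(ol / 6) * 3L  # in-frame, ~1/3 into the ORF
      at <- os + codon_i
      internal <- paste0(substr(internal, 1, at), "TAA",
                         substr(internal, at + 4L, nchar(internal)))
    }
  }
  if (state == "nested") {
    env_end <- off$end[off$feature == "ENV"] - internal_start
    cassette <- mutate_k2p(line1_cassette(), age_myr, rate, kappa)
    internal <- paste0(substr(internal, 1, env_end), cassette,
                       substr(internal, env_end + 1L, nchar(internal)))
  }
  list(seq = paste0(ltr5, internal, ltr3))
}

#' Simulate a genome with planted elements and a truth table
#'
#' Builds background DNA and plants elements according to a plan.  Elements
#' are laid out left to right with at least `min_spacing` background
#' between consecutive insertions so structural and solo-LTR calls have
#' unambiguous truth.
#'
#' @param plan Data frame with columns `lineage`, `age_myr`, `state` and
#'   optionally `strand`.
#' @param templates Named list of templates (default [default_templates()]).
#' @param background_length Background length in bp before insertions.
#' @param gc Background GC fraction.
#' @param min_spacing Minimum background between consecutive elements (bp).
#' @param seed Optional seed.
#' @param species Species tag.
#' @param rate,kappa Substitution-process parameters.
#' @return List with `genome`, `truth`, `templates`.
#' @export
simulate_genome <- function(plan, templates = NULL,
                            background_length = NULL, gc = 0.42,
                            min_spacing = 20000L, seed = NULL,
                            species = "sim", rate = 2.2e-9, kappa = 2) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(templates)) templates <- default_templates()
  if (is.null(plan$strand)) plan$strand <- "+"
  n <- nrow(plan)
  # spacing is between element BOUNDARIES, so budget for the longest element
  max_elem <- if (length(templates)) {
    max(vapply(templates, function(t) t$length, numeric(1))) + 2200L
  } else 9000L
  if (is.null(background_length))
    background_length <- (n + 1L) * (min_spacing + max_elem)
  genome <- make_background(background_length, gc = gc, species = species)
  # insertion points in the ORIGINAL background, ascending with small jitter
  gap <- background_length / (n + 1L)
  pts0 <- round(gap * seq_len(n) + stats::runif(n, -gap / 16, gap / 16))
  # plant right-to-left so earlier points need no shifting
  ord <- order(pts0, decreasing = TRUE)
  for (i in ord) {
    tpl <- templates[[plan$lineage[i]]]
    if (is.null(tpl)) stop("plan references unknown template: ", plan$lineage[i])
    res <- plant(genome, tpl, names(genome$contigs)[1], pts0[i],
                 age_myr = plan$age_myr[i], state = plan$state[i],
                 strand = plan$strand[i], rate = rate, kappa = kappa,
                 element_id = sprintf("elem%03d", i))
    genome <- res$genome
  }
  truth <- attr(genome, "truth")
  truth <- truth[order(truth$start), ]
  rownames(truth) <- NULL
  attr(genome, "truth") <- truth
  list(genome = genome, truth = truth, templates = templates)
}

#' Derive a descendant species pair from an ancestral genome
#'
#' Each descendant accumulates `speciation_myr` of independent neutral
#' substitution over the whole genome (ancestral elements therefore age by
#' `speciation_myr` in both species and share an ortholog group); optional
#' private elements are then planted post-split in one descendant each.
#'
#' @param ancestor Result of [simulate_genome()] (or a `ContigSet` carrying
#'   a truth attribute).
#' @param speciation_myr Time since the split, Myr.
#' @param private_a,private_b Optional plan data frames (as in
#'   [simulate_genome()]) of elements private to each descendant; ages
#'   should be below `speciation_myr`.
#' @param templates Template list (defaults to the ancestor's).
#' @param species_a,species_b Species tags.
#' @param rate,kappa Substitution-process parameters.
#' @param seed Optional seed.
#' @return List with `genome_a`, `genome_b`, `truth` (both coordinate
#'   systems: columns species_tag/contig/start/end per row) and
#'   `ortholog_groups` (shared group ids).
#' @export
simulate_species_pair <- function(ancestor, speciation_myr,
                                  private_a = NULL, private_b = NULL,
                                  templates = NULL,
                                  species_a = "SpA", species_b = "SpB",
                                  rate = 2.2e-9, kappa = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.list(ancestor) && !inherits(ancestor, "ContigSet")) {
    if (is.null(templates)) templates <- ancestor$templates
    ancestor <- ancestor$genome
  }
  anc_truth <- attr(ancestor, "truth")
  if (is.null(anc_truth)) anc_truth <- empty_truth()

  derive <- function(tag) {
    g <- ancestor
    g$species <- tag
    g$contigs <- vapply(g$contigs, mutate_k2p, character(1),
                        time_myr = speciation_myr, rate = rate, kappa = kappa)
    t <- anc_truth
    if (nrow(t) > 0) {
      t$species_tag <- tag
      t$true_age_myr <- t$true_age_myr + speciation_myr
      t$ortholog_group <- sprintf("og%03d", seq_len(nrow(t)))
    }
    attr(g, "truth") <- t
    g
  }
  ga <- derive(species_a)
  gb <- derive(species_b)

  plant_private <- function(g, plan) {
    if (is.null(plan) || nrow(plan) == 0) return(g)
    if (is.null(plan$strand)) plan$strand <- "+"
    t <- attr(g, "truth")
    len <- nchar(g$contigs[[1]])
    cid <- names(g$contigs)[1]
    for (i in seq_len(nrow(plan))) {
      # place in a gap well clear of existing elements; relax the margin
      # progressively if the genome is too crowded for the preferred 16 kb
      t <- attr(g, "truth")
      occupied <- t[t$contig == cid, , drop = FALSE]
      p <- NA_integer_
      for (margin in c(16000L, 8000L, 4000L, 1000L)) {
        for (try in 1:2000) {
          cand <- floor(stats::runif(1, margin, nchar(g$contigs[[cid]]) - margin))
          if (nrow(occupied) == 0 ||
              all(cand < occupied$start - margin | cand > occupied$end + margin)) {
            p <- cand; break
          }
        }
        if (!is.na(p)) break
      }
      if (is.na(p)) stop("no room to place a private element on ", cid)
      res <- plant(g, templates[[plan$lineage[i]]], cid, p,
                   age_myr = plan$age_myr[i], state = plan$state[i],
                   strand = plan$strand[i], rate = rate, kappa = kappa,
                   element_id = sprintf("%s_priv%02d", g$species, i))
      g <- res$genome
    }
    g
  }
  ga <- plant_private(ga, private_a)
  gb <- plant_private(gb, private_b)

  truth <- rbind(attr(ga, "truth"), attr(gb, "truth"))
  rownames(truth) <- NULL
  shared <- unique(stats::na.omit(truth$ortholog_group))
  list(genome_a = ga, genome_b = gb, truth = truth, ortholog_groups = shared)
}

#' Write a truth table as BED (plus full TSV)
#' @param truth Truth table.
#' @param bed_path BED output path (0-based, name = element_id, score =
#'   age, strand column).
#' @return Invisibly, `bed_path`.
#' @export
write_truth_bed <- function(truth, bed_path) {
  bed <- data.frame(truth$contig, truth$start, truth$end, truth$element_id,
                    truth$true_age_myr, truth$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}
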