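#' Default thresholds for orthologous-insertion calling
#' @return Named list: insertion-region identity >= 0.85, flank alignment
#'   coverage >= 0.50, retained flank alignments >= 500 bp at E <= 1e-5,
#'   flank length 30,000 bp.
#' @export
ortho_params <- function() {
  list(min_insertion_identity = 0.85, min_flank_coverage = 0.50,
       min_aln_len = 500L, evalue_max = 1e-5, flank = 30000L)
}

#' Extract insertion regions and flanks for an ortholog test
#'
#' @param genome_a,genome_b `ContigSet`s.
#' @param locus_a,locus_b Element loci (one-row data.frames).
#' @param flank Flank length (bp), clipped at contig ends with achieved
#'   lengths recorded.
#' @return List with `insertion_a`/`insertion_b`, `left_a`/`right_a`/
#'   `left_b`/`right_b` (flank sequences, contig orientation) and the
#'   achieved flank lengths.
#' @export
extract_flank_pair <- function(genome_a, locus_a, genome_b, locus_b,
                               flank = 30000L) {
  one <- function(genome, loc) {
    len <- check_locus(genome, loc)
    a <- max(0L, loc$start - flank)
    b <- min(len, loc$end + flank)
    s <- genome$contigs[[loc$contig]]
    list(insertion = substr(s, loc$start + 1L, loc$end),
         left = if (loc$start > a) substr(s, a + 1L, loc$start) else "",
         right = if (b > loc$end) substr(s, loc$end + 1L, b) else "",
         left_len = loc$start - a, right_len = b - loc$end)
  }
  ea <- one(genome_a, locus_a)
  eb <- one(genome_b, locus_b)
  list(insertion_a = ea$insertion, insertion_b = eb$insertion,
       left_a = ea$left, right_a = ea$right,
       left_b = eb$left, right_b = eb$right,
       flank_a = c(left = ea$left_len, right = ea$right_len),
       flank_b = c(left = eb$left_len, right = eb$right_len))
}

# discontiguous-seed search of one flank pair; returns retained alignments
# as (a_start, a_end, b_start, b_end, identity, aln_len) in flank-local
# 0-based coordinates.
flank_alignments <- function(fa, fb, params) {
  if (!nzchar(fa) || !nzchar(fb) || nchar(fb) < 28) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      identity = numeric(), aln_len = integer(),
                      stringsAsFactors = FALSE))
  }
  subj <- contig_set(c(flank = fb), species = "")
  hits <- seeded_search(fa, subj, mode = "discontiguous-nucleotide",
                        query_id = "flank")
  hits <- hits[hits$aln_cols >= params$min_aln_len &
                 hits$evalue <= params$evalue_max &
                 hits$strand == "+", , drop = FALSE]
  data.frame(a_start = hits$q_start, a_end = hits$q_end,
             b_start = hits$s_start, b_end = hits$s_end,
             identity = hits$identity, aln_len = hits$aln_cols,
             stringsAsFactors = FALSE)
}

# Identity of the best chained alignment between two insertion regions.
# Short chance matches between unrelated sequences reach high identity
# over a handful of columns, so the alignment must cover a meaningful
# fraction of the insertion (>= `min_aln_len`, capped at half the shorter
# region) to count at all.
insertion_region_identity <- function(a, b, min_aln_len = 500L) {
  need <- min(min_aln_len, floor(min(nchar(a), nchar(b)) / 2))
  if (nchar(a) > 2000 && nchar(b) > 2000) {
    hits <- seeded_search(a, contig_set(c(x = b)), mode = "nucleotide")
    hits <- hits[hits$strand == "+" & hits$aln_cols >= need, , drop = FALSE]
    if (nrow(hits) > 0) return(hits$identity[1])
    return(0)
  }
  al <- local_align(a, b, mode = "nucleotide")
  if (is.na(al$identity) || al$aln_cols < need) 0 else al$identity
}

#' Decide whether two insertions are orthologous
#'
#' Applies the flank-homology decision rule: the insertion regions must
#' align at >= 85% identity, and retained flank alignments (each >= 500
#' bp, E <= 1e-5, discontiguous-seed search) must cover >= 50% of genome
#' A's achieved flanks (union over left and right flanks, computed on A's
#' coordinate system).
#'
#' @param pair Output of [extract_flank_pair()].
#' @param params Thresholds from [ortho_params()].
#' @return `OrthologCall` list: `insertion_identity`, `flank_coverage`,
#'   `flank_alignments` (left/right tables), `verdict`.
#' @export
call_ortholog <- function(pair, params = ortho_params()) {
  insertion_identity <- insertion_region_identity(pair$insertion_a,
                                                  pair$insertion_b,
                                                  params$min_aln_len)
  left <- flank_alignments(pair$left_a, pair$left_b, params)
  right <- flank_alignments(pair$right_a, pair$right_b, params)
  covered <- 0L
  for (tab in list(left, right)) {
    if (nrow(tab) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(start = tab$a_start + 1L,
                                           end = tab$a_end))
    covered <- covered + sum(IRanges::width(ir))
  }
  total_flank <- sum(pair$flank_a)
  flank_coverage <- if (total_flank > 0) covered / total_flank else 0
  verdict <- if (insertion_identity >= params$min_insertion_identity &&
                 flank_coverage >= params$min_flank_coverage)
    "ortholog" else "not_ortholog"
  structure(list(insertion_identity = insertion_identity,
                 flank_coverage = flank_coverage,
                 flank_alignments = list(left = left, right = right),
                 verdict = verdict), class = "OrthologCall")
}

#' Survey orthologous insertions between two genomes
#'
#' Pairs every catalog element of genome A with every candidate partner
#' locus of genome B (a fast shared-k-mer prescreen skips hopeless pairs),
#' runs [call_ortholog()], and reports the best partner per A element
#' (highest flank coverage, then insertion identity).
#'
#' @param catalog_a Data frame of A-element loci (contig/start/end/strand,
#'   plus an `id` column).
#' @param genome_a,genome_b `ContigSet`s.
#' @param partners_b Data frame of candidate partner loci in B (e.g. from
#'   [rt_cross_species_search()] extended to element spans).
#' @param params Thresholds from [ortho_params()].
#' @param prescreen Minimum shared-11-mer fraction between insertion
#'   regions before a full call is attempted.
#' @return Data frame of best calls per A element: partner coordinates,
#'   `insertion_identity`, `flank_coverage`, `verdict`.
#' @export
survey_orthologs <- function(catalog_a, genome_a, genome_b, partners_b,
                             params = ortho_params(), prescreen = 0.05) {
  empty <- data.frame(id = character(), contig_a = character(),
                      start_a = integer(), end_a = integer(),
                      contig_b = character(), start_b = integer(),
                      end_b = integer(), insertion_identity = numeric(),
                      flank_coverage = numeric(), verdict = character(),
                      stringsAsFactors = FALSE)
  if (nrow(catalog_a) == 0) return(empty)
  ins_seq <- function(g, row) {
    extract_locus(g, locus(row$contig, row$start, row$end, "+"))$seq
  }
  ka <- lapply(seq_len(nrow(catalog_a)), function(i)
    unique(seq_kmers(ins_seq(genome_a, catalog_a[i, ]), 11L)))
  kb <- lapply(seq_len(nrow(partners_b)), function(i)
    unique(seq_kmers(ins_seq(genome_b, partners_b[i, ]), 11L)))
  out <- list()
  for (i in seq_len(nrow(catalog_a))) {
    best <- NULL
    for (j in seq_len(nrow(partners_b))) {
      shared <- length(intersect(ka[[i]], kb[[j]])) /
        max(1L, min(length(ka[[i]]), length(kb[[j]])))
      if (shared < prescreen) next
      pair <- extract_flank_pair(
        genome_a, locus(catalog_a$contig[i], catalog_a$start[i],
                        catalog_a$end[i], "+"),
        genome_b, locus(partners_b$contig[j], partners_b$start[j],
                        partners_b$end[j], "+"),
        flank = params$flank)
      call <- call_ortholog(pair, params)
      if (is.null(best) ||
          call$flank_coverage > best$call$flank_coverage ||
          (call$flank_coverage == best$call$flank_coverage &&
           call$insertion_identity > best$call$insertion_identity)) {
        best <- list(j = j, call = call)
      }
    }
    row <- data.frame(
      id = if (!is.null(catalog_a$id)) catalog_a$id[i] else as.character(i),
      contig_a = catalog_a$contig[i], start_a = catalog_a$start[i],
      end_a = catalog_a$end[i],
      contig_b = NA_character_, start_b = NA_integer_, end_b = NA_integer_,
      insertion_identity = NA_real_, flank_coverage = NA_real_,
      verdict = "not_ortholog", stringsAsFactors = FALSE)
    if (!is.null(best)) {
      row$contig_b <- partners_b$contig[best$j]
      row$start_b <- partners_b$start[best$j]
      row$end_b <- partners_b$end[best$j]
      row$insertion_identity <- best$call$insertion_identity
      row$flank_coverage <- best$call$flank_coverage
      row$verdict <- best$call$verdict
    }
    out[[length(out) + 1L]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
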