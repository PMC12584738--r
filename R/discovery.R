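#' Default thresholds for the candidate screens
#' @return Named list: POL-probe screen retains hits with identity >= 0.30,
#'   query coverage >= 0.40 and E <= 1e-5, merged within 1000 bp; the
#'   cross-species RT screen retains identity >= 0.80 over >= 80% of the
#'   query.
#' @export
screen_params <- function() {
  list(min_identity = 0.30, min_coverage = 0.40, evalue_max = 1e-5,
       merge_gap = 1000L,
       rt_min_identity = 0.80, rt_min_coverage = 0.80, rt_evalue_max = 1e-5)
}

#' Screen a genome with retroviral POL protein probes
#'
#' Translated homology search (protein probes against the six-frame
#' translation of the genome), filtered at the screen thresholds, with
#' same-strand hits within `merge_gap` merged into one candidate locus and
#' overlapping candidates deduplicated keeping the best E-value.
#'
#' @param pol_queries Named character vector of protein probes.
#' @param genome A `ContigSet`.
#' @param params Thresholds from [screen_params()].
#' @param search_params Optional overrides for [seeded_search_params()].
#' @param index Optional precomputed [genome_index()] (protein mode).
#' @return Data frame of candidate loci (`id`, `contig`, `start`, `end`,
#'   `strand`, `stage`, `best_query`, `best_evalue`, `n_hits`) with the
#'   retained hits in attribute `"hits"`.
#' @export
screen_genome <- function(pol_queries, genome, params = screen_params(),
                          search_params = NULL, index = NULL) {
  if (length(pol_queries) == 0) stop("at least one protein probe is required")
  if (is.null(names(pol_queries))) names(pol_queries) <- paste0("probe", seq_along(pol_queries))
  if (is.null(index)) index <- genome_index(genome, "protein-vs-translated")
  hits <- lapply(names(pol_queries), function(qid) {
    seeded_search(pol_queries[[qid]], genome, mode = "protein-vs-translated",
                  params = search_params, query_id = qid, index = index)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$identity >= params$min_identity &
                 hits$coverage >= params$min_coverage &
                 hits$evalue <= params$evalue_max, , drop = FALSE]
  cands <- merge_hits_to_candidates(hits, params$merge_gap, stage = "pol_screen")
  attr(cands, "hits") <- hits
  cands
}

#' Cross-species nucleotide search with an RT consensus
#'
#' Finds candidate orthologous ERV loci in a second genome using a
#' reverse-transcriptase consensus sequence, retaining hits with identity
#' >= 80% covering >= 80% of the query.
#'
#' @param rt_consensus RT consensus DNA (>= 200 bp).
#' @param other_genome A `ContigSet`.
#' @param params Thresholds from [screen_params()].
#' @param query_id Label for the hit table.
#' @return Candidate-locus data frame as in [screen_genome()], with
#'   `stage = "rt_cross_species"`.
#' @export
rt_cross_species_search <- function(rt_consensus, other_genome,
                                    params = screen_params(),
                                    query_id = "RT") {
  if (nchar(rt_consensus) < 200) stop("RT consensus shorter than 200 bp")
  hits <- seeded_search(rt_consensus, other_genome, mode = "nucleotide",
                        query_id = query_id)
  hits <- hits[hits$identity >= params$rt_min_identity &
                 hits$coverage >= params$rt_min_coverage &
                 hits$evalue <= params$rt_evalue_max, , drop = FALSE]
  cands <- merge_hits_to_candidates(hits, params$merge_gap,
                                    stage = "rt_cross_species")
  attr(cands, "hits") <- hits
  cands
}

# Merge retained hits into candidate loci: same contig and strand, gap <=
# merge_gap; the candidate locus is the union span of its hits.
merge_hits_to_candidates <- function(hits, merge_gap, stage) {
  empty <- data.frame(id = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      stage = character(), best_query = character(),
                      best_evalue = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) return(empty)
  hits <- hits[order(hits$contig, hits$strand, hits$s_start), ]
  key <- paste(hits$contig, hits$strand)
  out <- list()
  for (grp in split(hits, key)) {
    grp <- grp[order(grp$s_start), ]
    cluster <- cumsum(c(TRUE, grp$s_start[-1] > cummax(grp$s_end[-nrow(grp)]) + merge_gap))
    for (cl in split(grp, cluster)) {
      best <- which.min(cl$evalue)
      out[[length(out) + 1L]] <- data.frame(
        contig = cl$contig[1], start = min(cl$s_start), end = max(cl$s_end),
        strand = cl$strand[1], stage = stage,
        best_query = cl$query_id[best], best_evalue = cl$evalue[best],
        n_hits = nrow(cl), stringsAsFactors = FALSE)
    }
  }
  cands <- do.call(rbind, out)
  # overlapping candidates across strands/queries: keep best E-value
  cands <- cands[order(cands$best_evalue), ]
  keep <- rep(TRUE, nrow(cands))
  for (i in seq_len(nrow(cands))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (cands$contig[i] == cands$contig[j] &&
          cands$start[i] < cands$end[j] && cands$start[j] < cands$end[i]) {
        keep[i] <- FALSE; break
      }
    }
  }
  cands <- cands[keep, , drop = FALSE]
  cands <- cands[order(cands$contig, cands$start), , drop = FALSE]
  cands$id <- sprintf("cand%03d", seq_len(nrow(cands)))
  rownames(cands) <- NULL
  cands[, names(empty)]
}
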