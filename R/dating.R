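#' Kimura two-parameter distance between two aligned sequences
#'
#' Columns containing a gap (`-`) or N in either sequence are removed
#' (complete deletion), then the transition proportion P (A<->G, C<->T)
#' and transversion proportion Q are counted and the K2P distance
#' `D = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` is evaluated.
#'
#' When a log argument is non-positive the divergence is saturated and the
#' distance undefined; the estimate is returned with `saturated = TRUE`
#' and `D = NA` so callers can flag and exclude the element.
#'
#' @param a,b Aligned sequences (equal length after column removal).
#' @return List of class `K2PEstimate`: `P`, `Q`, `D`, `sites`,
#'   `saturated`.
#' @export
k2p_distance <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("aligned sequences must have equal length")
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  n <- length(av)
  if (n == 0) stop("no comparable sites after removing gap/N columns")
  diff <- av != bv
  purine <- c("A", "G")
  a_pur <- av %in% purine
  b_pur <- bv %in% purine
  ts <- sum(diff & (a_pur == b_pur))   # transition: purine<->purine or pyr<->pyr
  tv <- sum(diff & (a_pur != b_pur))
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  D <- if (saturated) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  structure(list(P = P, Q = Q, D = D, sites = n, saturated = saturated),
            class = "K2PEstimate")
}

#' Insertion time from paired-LTR divergence
#'
#' Applies the paired-LTR molecular clock `T = (D / R) / 2`: the two LTRs
#' are identical at integration and diverge independently, so their
#' distance accumulates at twice the neutral rate.
#'
#' @param D K2P distance between the paired LTRs (substitutions/site).
#' @param R Neutral substitution rate per site per year; default the
#'   average mammalian rate 2.2e-9.
#' @return Insertion time in million years (Mya).
#' @export
insertion_time <- function(D, R = 2.2e-9) {
  if (any(R <= 0)) stop("rate R must be positive")
  if (any(D < 0, na.rm = TRUE)) stop("distance D must be non-negative")
  (D / R) / 2 / 1e6
}

#' Date a provirus from its two LTR sequences
#'
#' Globally aligns the 5' and 3' LTR sequences (both boundaries are
#' structurally defined, so end gaps are penalized), strips gap and N
#' columns, and chains [k2p_distance()] with [insertion_time()].
#'
#' @param ltr5,ltr3 LTR sequences (element orientation).
#' @param R Neutral substitution rate per site per year.
#' @return List of class `DatingResult`: `estimate` (K2PEstimate), `R`,
#'   `T_mya` (NA when saturated), `saturated`.
#' @export
date_ltr_pair <- function(ltr5, ltr3, R = 2.2e-9) {
  al <- local_align(ltr5, ltr3, mode = "nucleotide", type = "global")
  est <- k2p_distance(al$a_aln, al$b_aln)
  T_mya <- if (est$saturated) NA_real_ else insertion_time(est$D, R)
  structure(list(estimate = est, R = R, T_mya = T_mya,
                 saturated = est$saturated), class = "DatingResult")
}

#' Date a catalog of provirus candidates
#'
#' Only full-length elements (paired LTRs plus internal region) are dated;
#' others are skipped with a logged reason, mirroring the intact-genome
#' gate of LTR-divergence dating.
#'
#' @param catalog List of `ProvirusCandidate` records (see
#'   [assemble_provirus()]).
#' @param genome The `ContigSet` the catalog coordinates refer to.
#' @param R Neutral substitution rate per site per year.
#' @return Data frame: element per row with `sites`, `P`, `Q`, `D`, `R`,
#'   `T_mya` (2-dp reporting is left to the caller) and `flag`
#'   (`"ok"`, `"saturated"`, `"not_full_length"`).
#' @export
date_catalog <- function(catalog, genome, R = 2.2e-9) {
  rows <- lapply(catalog, function(pv) {
    base <- data.frame(element_id = pv$id, lineage = pv$lineage %||% NA_character_,
                       sites = NA_integer_, P = NA_real_, Q = NA_real_,
                       D = NA_real_, R = R, T_mya = NA_real_,
                       flag = "not_full_length", stringsAsFactors = FALSE)
    if (!isTRUE(pv$full_length)) return(base)
    # ltr5/ltr3 loci carry the element strand, so extraction returns each
    # repeat in element orientation
    ltr5 <- extract_locus(genome, pv$ltr5, 0L)$seq
    ltr3 <- extract_locus(genome, pv$ltr3, 0L)$seq
    dr <- date_ltr_pair(ltr5, ltr3, R)
    base$sites <- dr$estimate$sites
    base$P <- dr$estimate$P
    base$Q <- dr$estimate$Q
    base$D <- dr$estimate$D
    base$T_mya <- dr$T_mya
    base$flag <- if (dr$saturated) "saturated" else "ok"
    base
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
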