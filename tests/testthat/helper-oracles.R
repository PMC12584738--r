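# Independent oracles used by the test suite.  These are deliberately
# naive re-implementations (per-site counting, exhaustive enumeration,
# sliding-window matching) kept separate from the package code paths they
# check.

# -- affine-gap global alignment score by plain dynamic programming (Gotoh),
#    used to enumerate the best local alignment as the max over all
#    substring pairs (empty alignment scores 0).
oracle_global_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = 5, gap_ext = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  gap_cost <- function(L) gap_open + gap_ext * L
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_cost(i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_cost(j - 1)
  if (n >= 1 && m >= 1) {
    for (i in 2:(n + 1)) {
      for (j in 2:(m + 1)) {
        s <- if (av[i - 1] == bv[j - 1]) match else mismatch
        M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
        X[i, j] <- max(M[i - 1, j] - gap_cost(1), X[i - 1, j] - gap_ext)
        Y[i, j] <- max(M[i, j - 1] - gap_cost(1), Y[i, j - 1] - gap_ext)
      }
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_local_score <- function(a, b, ...) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    s <- oracle_global_score(substr(a, i1, i2), substr(b, j1, j2), ...)
    if (s > best) best <- s
  }
  best
}

# -- per-site K2P counting oracle: explicit per-position loop, classifying
#    each differing site as transition or transversion, then the closed
#    form evaluated with plain arithmetic.
oracle_k2p <- function(a, b) {
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  n <- length(av)
  pair <- paste0(pmin(av, bv), pmax(av, bv))
  diff <- av != bv
  ts <- sum(diff & pair %in% c("AG", "CT"))
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    return(list(P = P, Q = Q, D = NA_real_, sites = n, saturated = TRUE))
  }
  list(P = P, Q = Q, D = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       sites = n, saturated = FALSE)
}

# -- sliding-window motif oracle: character-by-character check of the
#    degenerate patterns ('.'-style positions match anything but '*').
oracle_motif_scan <- function(protein, specs = oracle_motif_specs()) {
  pv <- strsplit(protein, "", fixed = TRUE)[[1]]
  out <- list()
  for (id in names(specs)) {
    spec <- specs[[id]]
    L <- length(spec)
    if (length(pv) < L) next
    for (s in 1:(length(pv) - L + 1)) {
      okay <- TRUE
      for (k in 1:L) {
        ch <- pv[s + k - 1]
        allowed <- spec[[k]]
        if (identical(allowed, "ANY")) {
          if (ch == "*") { okay <- FALSE; break }
        } else if (!ch %in% allowed) { okay <- FALSE; break }
      }
      if (okay) out[[length(out) + 1L]] <-
          data.frame(motif_id = id, position = s - 1L,
                     match = substr(protein, s, s + L - 1L),
                     stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(motif_id = character(), position = integer(),
               match = character(), stringsAsFactors = FALSE)
  # same CX6C-vs-CX6CC anchoring rule as the scanner
  if (any(hits$motif_id == "CX6C")) {
    cc <- hits$position[hits$motif_id == "CX6CC"]
    hits <- hits[!(hits$motif_id == "CX6C" & hits$position %in% cc), ,
                 drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

oracle_motif_specs <- function() {
  A <- "ANY"
  list(
    CysHis = c(list("C"), rep(list(A), 2), list("C"), rep(list(A), 4),
               list("H"), rep(list(A), 4), list("C")),
    PPPY = list("P", "P", "P", "Y"),
    MHR = c(list("Q"), list("G"), rep(list(A), 2), list("E"),
            rep(list(A), 4), list("F"), rep(list(A), 2)),
    Furin = list(c("K", "R"), A, c("K", "R"), "R"),
    CX6CC = c(list("C"), rep(list(A), 6), list("C"), list("C")),
    CX6C = c(list("C"), rep(list(A), 6), list("C")),
    YXXL = list("Y", A, A, "L"),
    RBM = c(list("S"), list("D"), list("G"), list("G"), list("G"),
            rep(list(A), 2), list("D"), rep(list(A), 2), list("R"))
  )
}

random_protein <- function(n, alphabet = c(LETTERS[!LETTERS %in%
                                                     c("B", "J", "O", "U", "X", "Z")], "*")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c(rep(1, length(alphabet) - 1), 0.5)), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only mutation to a target identity (no indels)
mutate_to_identity <- function(seq, identity) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(v))
  if (k > 0) {
    idx <- sample(length(v), k)
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  }
  paste(v, collapse = "")
}
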