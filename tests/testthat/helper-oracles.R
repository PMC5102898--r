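# Independent oracles used across the suite.

# Brute-force optimal alignment score by exhaustive enumeration of monotone
# matchings. A (global or local) alignment is determined by its set of
# aligned residue pairs; the unmatched residues between consecutive pairs
# form one gap run per sequence, so the affine gap cost of a matching is
# closed-form. Enumerating all matchings therefore enumerates all
# alignments. Completely independent of the dynamic-programming path.
bf_align_score <- function(a, b, scheme = scoring_scheme(),
                           mode = c("global", "local")) {
  mode <- match.arg(mode)
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  m <- length(ac); n <- length(bc)
  S <- scheme$matrix
  go <- scheme$gap_open; ge <- scheme$gap_extend
  gapcost <- function(k) if (k == 0) 0 else go + ge * k
  env <- new.env()
  env$best <- if (mode == "local") 0 else -Inf
  rec <- function(pi, pj, score) {
    if (mode == "global") {
      tot <- score + gapcost(m - pi) + gapcost(n - pj)
      if (tot > env$best) env$best <- tot
    } else if (score > env$best) {
      env$best <- score
    }
    if (pi < m && pj < n) {
      head_free <- mode == "local" && pi == 0 && pj == 0
      for (ii in (pi + 1):m) {
        for (jj in (pj + 1):n) {
          seg <- if (head_free) 0 else
            gapcost(ii - pi - 1) + gapcost(jj - pj - 1)
          rec(ii, jj, score + seg + S[ac[ii], bc[jj]])
        }
      }
    }
  }
  rec(0L, 0L, 0)
  env$best
}

# Sliding-window motif oracle: checks every window with an explicit loop.
oracle_motif_hits <- function(seq, pattern) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(pattern$positions)
  hits <- integer()
  if (L > length(chars)) return(hits)
  for (off in 0:(length(chars) - L)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(chars[off + j] %in% pattern$positions[[j]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

random_seq <- function(n, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Pure-R patristic (tip-to-tip path length) distances, by breadth-first
# traversal of the edge list. Used instead of ape's compiled cophenetic
# path so the oracle stays independent of the code it checks.
patristic <- function(tree) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)   # robust to non-standard internal-node numbering
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn); dist[s] <- 0; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (k in seq_len(NROW(nb))) {
        u <- nb[k, 1]
        if (is.na(dist[u])) { dist[u] <- dist[v] + nb[k, 2]; queue <- c(queue, u) }
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# Unrooted-topology fingerprint: the set of non-trivial bipartitions, each
# encoded as a canonical string. Two trees have the same unrooted topology
# iff their fingerprints are equal.
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  splits <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    side <- sort(desc_tips(child))
    if (length(side) <= 1 || length(side) >= n - 1) next  # trivial split
    other <- sort(setdiff(tree$tip.label, side))
    splits <- c(splits, paste(sort(c(paste(side, collapse = ","),
                                     paste(other, collapse = ","))),
                              collapse = "|"))
  }
  sort(unique(splits))
}

same_topology <- function(t1, t2) identical(tree_splits(t1), tree_splits(t2))
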