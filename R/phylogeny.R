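## Distance-based relaxase phylogeny. The distance between two relaxase
## calls is 1 - global-alignment identity of their extracted N-terminal
## domains (no multiple-hit correction by default; a Poisson correction is
## available but off by default, since monophyly rather than branch-length
## inference is the deliverable).

#' Pairwise distance matrix of relaxase domains
#'
#' @param calls List of `relaxase_call` objects (>= 3), or a named character
#'   vector of domain sequences. Leaf ids default to plasmid ids (falling
#'   back to protein ids when duplicated).
#' @param scheme A [scoring_scheme()].
#' @param correction `"none"` (default) or `"poisson"`
#'   (`d = -log(identity)` capped at 1).
#' @return Symmetric numeric matrix with zero diagonal and leaf-id dimnames.
#' @export
distance_matrix <- function(calls, scheme = scoring_scheme(),
                            correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (is.character(calls)) {
    domains <- calls
  } else {
    if (length(calls) < 3) stop("need at least 3 relaxase calls for a tree")
    ids <- vapply(calls, `[[`, "", "plasmid_id")
    if (anyDuplicated(ids)) {
      ids <- paste(ids, vapply(calls, `[[`, "", "protein_id"), sep = "/")
    }
    domains <- setNames(vapply(calls, `[[`, "", "domain"), ids)
  }
  if (length(domains) < 3) stop("need at least 3 leaves for a tree")
  if (is.null(names(domains)) || anyDuplicated(names(domains))) {
    stop("leaf ids must be unique and named")
  }
  n <- length(domains)
  D <- matrix(0, n, n, dimnames = list(names(domains), names(domains)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      id <- global_identity(domains[[i]], domains[[j]], scheme)
      d <- if (correction == "poisson") {
        if (id <= 0) 1 else min(1, -log(id))
      } else 1 - id
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]). Negative
#' branch-length estimates, which NJ can produce on non-additive input, are
#' clamped to zero with a logged note.
#'
#' @param D Symmetric non-negative distance matrix with dimnames, n >= 3.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3) stop("need at least 3 leaves")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  tree <- ape::nj(as.dist(D))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    fp_log(sum(neg), " negative NJ branch length(s) clamped to zero")
    tree$edge.length[neg] <- 0
  }
  tree
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf_id Tip label of the outgroup.
#' @return Rooted [ape::phylo] tree with attribute `outgroup`.
#' @export
root_with_outgroup <- function(tree, leaf_id) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(leaf_id, tree$tip.label)
  if (is.na(tip)) stop("outgroup leaf not in tree: ", leaf_id)
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- ape::root(tree, outgroup = leaf_id, resolve.root = TRUE)
  # split the pendant edge evenly between the outgroup and the rest: the
  # total length across the root is conserved however ape distributed it
  root_node <- ape::Ntip(rooted) + 1L
  out_tip <- match(leaf_id, rooted$tip.label)
  root_edges <- which(rooted$edge[, 1] == root_node)
  if (length(root_edges) == 2) {
    total <- sum(rooted$edge.length[root_edges])
    for (e in root_edges) {
      rooted$edge.length[e] <- if (rooted$edge[e, 2] == out_tip) half else
        total - half
    }
  }
  attr(rooted, "outgroup") <- leaf_id
  rooted
}

#' Test whether a set of leaves is monophyletic
#'
#' True when some clade of the rooted tree contains exactly `leaf_set`.
#' Also reports the smallest clade containing the whole set.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param leaf_set Non-empty character vector of tip labels.
#' @return List: `monophyletic` (logical), `clade_size` (number of leaves in
#'   the smallest containing clade), `clade_leaves`.
#' @export
is_monophyletic <- function(tree, leaf_set) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(leaf_set)) stop("leaf_set is empty")
  missing <- setdiff(leaf_set, tree$tip.label)
  if (length(missing)) stop("leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(leaf_set) == 1) {
    return(list(monophyletic = TRUE, clade_size = 1L,
                clade_leaves = leaf_set))
  }
  if (length(leaf_set) == length(tree$tip.label)) {
    return(list(monophyletic = TRUE, clade_size = length(leaf_set),
                clade_leaves = tree$tip.label))
  }
  mrca <- ape::getMRCA(tree, leaf_set)
  clade <- ape::extract.clade(tree, mrca)$tip.label
  list(monophyletic = setequal(clade, leaf_set),
       clade_size = length(clade),
       clade_leaves = clade)
}

#' Monophyly report for a set of groups
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param groups Named list of leaf-id vectors (one per group); leaves not
#'   present in the tree are dropped, empty groups skipped.
#' @return Data frame: group, n_leaves, monophyletic, clade_size.
#' @export
monophyly_report <- function(tree, groups) {
  rows <- lapply(names(groups), function(g) {
    leaves <- intersect(groups[[g]], tree$tip.label)
    if (!length(leaves)) return(NULL)
    res <- is_monophyletic(tree, leaves)
    data.frame(group = g, n_leaves = length(leaves),
               monophyletic = res$monophyletic,
               clade_size = res$clade_size, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(group = character(), n_leaves = integer(),
                      monophyletic = logical(), clade_size = integer()))
  }
  do.call(rbind, rows)
}
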