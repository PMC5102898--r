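## Conjugation-region profiling: presence/absence of the 36 reference tra
## genes per plasmid (best local hit at E <= 1e-3), per-gene conservation
## percentages, and the Hamming co-occurrence statistic
## C(i, j) = N - Hamming(col_i, col_j).

#' Names of the 36 reference conjugation genes
#'
#' The query set used for presence/absence profiling: the conjugation-region
#' proteins of the two classical F-like prototypes (F and R100), with the
#' relaxase TraI represented by its N-terminal 300-residue domain.
#'
#' @return Character vector of length 36.
#' @export
panel_gene_names <- function() {
  c("TraJ", "TraA", "TraL", "TraE", "TraK", "TraB", "TraP", "TrbD", "TrbG",
    "TraV", "TraR", "TraC", "TrbI", "TraW", "TraU", "TrbC", "TraN", "TrbE",
    "TraF", "TrbA", "ArtA", "TraQ", "TrbB", "TrbJ", "TrbF", "TraH", "TraG",
    "TraS", "TraT", "TraD", "TrbH", "TraI", "TraX", "TraM", "TraY", "FinO")
}

#' Names of the three group-marker regulators
#'
#' Group-specific putative regulators: TraJ_V (group C, an IncFV-type
#' activator with no homology to classical TraJ), EntFR (group D, a double
#' ribbon-helix-helix protein at the traJ locus) and SphTR (group E, a small
#' RHH protein immediately upstream of traD).
#'
#' @return Character vector of length 3.
#' @export
marker_gene_names <- function() c("TraJ_V", "EntFR", "SphTR")

#' Load a reference protein panel from FASTA
#'
#' @param path FASTA of reference proteins; ids must be unique gene names.
#' @param expect Optional character vector of names that must all be present.
#' @return Named character vector (a reference panel), in file order.
#' @export
read_panel <- function(path, expect = NULL) {
  panel <- read_fasta(path)
  if (!is.null(expect)) {
    missing <- setdiff(gene_key(expect), gene_key(names(panel)))
    if (length(missing)) {
      stop("panel is missing reference genes: ", paste(missing, collapse = ", "))
    }
  }
  panel
}

#' Presence call for one reference gene in one plasmid
#'
#' A gene is present when the best local alignment of the reference protein
#' against any protein of the record has E-value at or below `e_threshold`.
#' Identity and the best-hit protein are recorded as provenance only; the
#' call itself is by E-value.
#'
#' @param panel_entry Reference protein sequence (character scalar).
#' @param record A [plasmid_record()].
#' @param e_threshold Positive-hit E-value threshold (default `1e-3`).
#' @param scheme A [scoring_scheme()].
#' @return List: `present` (0/1), `evalue`, `identity`, `protein_id`,
#'   `feature_index`.
#' @export
detect_presence <- function(panel_entry, record, e_threshold = 1e-3,
                            scheme = scoring_scheme()) {
  if (!length(record$features)) {
    return(list(present = 0L, evalue = NA_real_, identity = NA_real_,
                protein_id = NA_character_, feature_index = NA_integer_,
                note = "no proteins"))
  }
  m <- nchar(panel_entry)
  best_e <- Inf; best_k <- NA_integer_
  for (k in seq_along(record$features)) {
    p <- record$features[[k]]$protein
    s <- local_score(panel_entry, p, scheme)
    e <- evalue_of(s, m, nchar(p), scheme)
    if (e < best_e) { best_e <- e; best_k <- k }
  }
  present <- as.integer(best_e <= e_threshold)
  identity <- NA_real_
  if (present == 1L) {
    aln <- local_align(panel_entry, record$features[[best_k]]$protein, scheme)
    identity <- aln$identity
  }
  f <- record$features[[best_k]]
  list(present = present, evalue = best_e, identity = identity,
       protein_id = if (nzchar(f$label)) f$label else
         sprintf("cds_%03d", best_k),
       feature_index = best_k)
}

#' Build the plasmids x genes presence/absence matrix
#'
#' Rows follow the input record order, columns the panel order; each cell is
#' the [detect_presence()] call for that (plasmid, gene) pair. Provenance
#' (best E-value, identity, hit protein and its feature index) is kept per
#' cell for downstream architecture inference.
#'
#' @param records List of [plasmid_record()] objects with unique ids.
#' @param panel Named character vector of reference proteins.
#' @inheritParams detect_presence
#' @return A `presence_matrix` object: `matrix` (0/1 with dimnames),
#'   `provenance` (data frame), `e_threshold`.
#' @export
build_matrix <- function(records, panel, e_threshold = 1e-3,
                         scheme = scoring_scheme()) {
  if (!length(records)) stop("no records supplied")
  if (!length(panel)) stop("empty reference panel")
  ids <- vapply(records, `[[`, "", "plasmid_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate plasmid ids: ", paste(dup, collapse = ", "))
  m <- matrix(0L, length(records), length(panel),
              dimnames = list(ids, names(panel)))
  prov <- vector("list", length(records) * length(panel))
  z <- 0L
  for (i in seq_along(records)) {
    for (j in seq_along(panel)) {
      call <- detect_presence(panel[[j]], records[[i]], e_threshold, scheme)
      m[i, j] <- call$present
      z <- z + 1L
      prov[[z]] <- data.frame(
        plasmid_id = ids[i], gene = names(panel)[j],
        present = call$present, evalue = call$evalue,
        identity = call$identity, protein_id = call$protein_id,
        feature_index = call$feature_index, stringsAsFactors = FALSE)
    }
  }
  structure(list(matrix = m, provenance = do.call(rbind, prov),
                 e_threshold = e_threshold),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d plasmids x %d genes (E <= %g)\n",
              nrow(x$matrix), ncol(x$matrix), x$e_threshold))
  invisible(x)
}

as_binary_matrix <- function(x) {
  if (inherits(x, "presence_matrix")) x <- x$matrix
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)))
  x
}

#' Per-gene conservation percentages
#'
#' The percentage of plasmids in which each reference gene is detected
#' (column means of the presence/absence matrix), reported in decreasing
#' order of conservation.
#'
#' @param matrix A `presence_matrix` or binary matrix with dimnames.
#' @return Data frame with columns `gene` and `percent`, sorted descending
#'   (ties keep panel order).
#' @export
conservation <- function(matrix) {
  m <- as_binary_matrix(matrix)
  if (!nrow(m)) stop("empty matrix")
  pct <- 100 * colMeans(m)
  out <- data.frame(gene = colnames(m), percent = unname(pct),
                    stringsAsFactors = FALSE)
  out[order(-out$percent), , drop = FALSE]
}

#' Gene-gene co-occurrence matrix
#'
#' For each pair of gene columns, the co-occurrence statistic is the maximum
#' possible Hamming distance (the number of plasmids, N) minus the observed
#' Hamming distance between the two presence/absence profiles:
#' `C(i, j) = N - Hamming(col_i, col_j)`. A profile against itself gives N;
#' complementary profiles give 0.
#'
#' @param matrix A `presence_matrix` or binary matrix.
#' @return A `cooccurrence_matrix` object: integer `matrix` (genes x genes),
#'   `n_plasmids`, and `normalized` (`matrix / N`).
#' @export
cooccurrence <- function(matrix) {
  m <- as_binary_matrix(matrix)
  if (!nrow(m)) stop("empty matrix")
  n <- nrow(m)
  # Hamming(col_i, col_j) counted via cross products of the 0/1 columns
  ones <- crossprod(m)                # both 1
  zeros <- crossprod(1 - m)           # both 0
  C <- ones + zeros                   # agreements = N - Hamming
  storage.mode(C) <- "integer"
  structure(list(matrix = C, n_plasmids = n, normalized = C / n),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf("cooccurrence_matrix: %d genes, N = %d plasmids\n",
              nrow(x$matrix), x$n_plasmids))
  invisible(x)
}
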