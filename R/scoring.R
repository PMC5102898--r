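#' Scoring scheme for protein alignment
#'
#' Bundles a substitution matrix, affine gap penalties and Karlin-Altschul
#' E-value parameters. The default is BLOSUM62 with gap open -11 and gap
#' extend -1 (a gap of length k scores `gap_open + k * gap_extend`), the
#' standard parameterisation for gapped protein database searches, with the
#' published gapped-BLOSUM62 E-value constants lambda = 0.267 and K = 0.041.
#'
#' @param matrix_name Name of the substitution matrix (informational).
#' @param matrix Square numeric matrix with identical row/column residue
#'   names; must include an `X` column for unknown residues.
#' @param gap_open,gap_extend Negative gap scores, `gap_open <= gap_extend < 0`.
#' @param lambda,K Positive Karlin-Altschul parameters for [evalue_of()].
#' @return An object of class `scoring_scheme`.
#' @examples
#' sch <- scoring_scheme()
#' sch$gap_open
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62",
                           matrix = NULL,
                           gap_open = -11, gap_extend = -1,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            identical(rownames(matrix), colnames(matrix)),
            "X" %in% colnames(matrix))
  if (!(gap_open <= gap_extend && gap_extend < 0)) {
    stop("gap penalties must satisfy gap_open <= gap_extend < 0")
  }
  if (!(lambda > 0 && K > 0)) stop("lambda and K must be positive")
  structure(list(matrix_name = matrix_name, matrix = matrix,
                 alphabet = colnames(matrix),
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring_scheme: %s, gap %g/%g, lambda %g, K %g\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

blosum62_cache <- new.env(parent = emptyenv())

blosum62_matrix <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix files distributed with BLAST
#' (comment lines starting with `#`, a header row of residues, then one row
#' per residue).
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- matrix(NA_real_, length(rows), length(header),
              dimnames = list(vapply(rows, `[[`, "", 1), header))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(rows[[i]][-1]))
    if (length(vals) != length(header) || anyNA(vals)) {
      stop("malformed matrix row for residue ", rows[[i]][1])
    }
    m[i, ] <- vals
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix rows and columns disagree")
  }
  m
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a query of length `m` and a search
#' space of length `n`. Monotone decreasing in the score and linear in both
#' lengths.
#'
#' @param score Alignment raw score.
#' @param m Query length (>= 1).
#' @param n Subject/search-space length (>= 1).
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return Non-negative number.
#' @examples
#' evalue_of(50, 300, 300)
#' @export
evalue_of <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(is.finite(score))
  if (!(m >= 1 && n >= 1)) stop("sequence lengths must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * score)
}
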