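## Pairwise protein alignment: R-facing wrappers over the compiled
## Gotoh kernels. Sequences are plain uppercase character scalars; residues
## not present in the substitution matrix are scored through its X column.

encode_seq <- function(s, alphabet) {
  if (!is.character(s) || length(s) != 1 || !nzchar(s)) {
    stop("sequence must be a non-empty character scalar")
  }
  chars <- strsplit(toupper(s), "")[[1]]
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  idx
}

gap_char <- "-"

build_alignment <- function(a, b, raw, scheme, mode) {
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  ops <- raw$ops
  ai <- raw$a_start; bi <- raw$b_start
  na <- character(length(ops)); nb <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {            # diagonal: consume both
      na[k] <- ac[ai]; nb[k] <- bc[bi]; ai <- ai + 1L; bi <- bi + 1L
    } else if (ops[k] == 1L) {     # up: gap in b
      na[k] <- ac[ai]; nb[k] <- gap_char; ai <- ai + 1L
    } else {                       # left: gap in a
      na[k] <- gap_char; nb[k] <- bc[bi]; bi <- bi + 1L
    }
  }
  ncol_aln <- length(ops)
  matches <- if (ncol_aln) sum(na == nb & na != gap_char) else 0L
  structure(list(
    aligned_a = paste(na, collapse = ""),
    aligned_b = paste(nb, collapse = ""),
    score = raw$score,
    identity = if (ncol_aln) matches / ncol_aln else 0,
    evalue = NA_real_,
    span_a = c(raw$a_start, raw$a_end),
    span_b = c(raw$b_start, raw$b_end),
    mode = mode
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s alignment: score %.1f, identity %.3f%s\n", x$mode, x$score,
              x$identity,
              if (!is.na(x$evalue)) sprintf(", E = %.3g", x$evalue) else ""))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Global (Needleman-Wunsch) protein alignment with affine gaps
#'
#' Computes the optimal global alignment under the scheme's substitution
#' matrix and affine gap penalties. Percent identity is the number of
#' identical columns divided by the total number of alignment columns, so
#' gap columns count against identity. The traceback is deterministic:
#' at every tie, diagonal is preferred over up (gap in `b`) over left.
#'
#' @param a,b Non-empty protein sequences (character scalars).
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result` with fields `aligned_a`, `aligned_b`,
#'   `score`, `identity`, `evalue` (`NA` in global mode), `span_a`, `span_b`.
#' @examples
#' global_align("AAAA", "AAAT")$identity  # 0.75
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  ea <- encode_seq(a, scheme$alphabet)
  eb <- encode_seq(b, scheme$alphabet)
  raw <- .gotoh_align(ea, eb, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend, FALSE)
  build_alignment(a, b, raw, scheme, "global")
}

#' Local (Smith-Waterman) protein alignment with affine gaps
#'
#' Optimal local alignment; identity is computed over the aligned local
#' region only. A Karlin-Altschul E-value ([evalue_of()]) is attached using
#' the full input lengths as the search space.
#'
#' @inheritParams global_align
#' @return An `alignment_result`; `evalue` is set.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  ea <- encode_seq(a, scheme$alphabet)
  eb <- encode_seq(b, scheme$alphabet)
  raw <- .gotoh_align(ea, eb, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend, TRUE)
  res <- build_alignment(a, b, raw, scheme, "local")
  res$evalue <- evalue_of(res$score, length(ea), length(eb), scheme)
  res
}

#' Local alignment score only
#'
#' Fast path used for presence screening: returns the optimal
#' Smith-Waterman score without performing a traceback.
#'
#' @inheritParams global_align
#' @return Numeric score.
#' @export
local_score <- function(a, b, scheme = scoring_scheme()) {
  .gotoh_score(encode_seq(a, scheme$alphabet), encode_seq(b, scheme$alphabet),
               scheme$matrix, scheme$gap_open, scheme$gap_extend, TRUE)
}

#' Global alignment score only
#' @inheritParams global_align
#' @return Numeric score.
#' @export
global_score <- function(a, b, scheme = scoring_scheme()) {
  .gotoh_score(encode_seq(a, scheme$alphabet), encode_seq(b, scheme$alphabet),
               scheme$matrix, scheme$gap_open, scheme$gap_extend, FALSE)
}

#' Percent identity from a full-length global alignment
#'
#' Convenience wrapper returning only the identity fraction of
#' [global_align()].
#'
#' @inheritParams global_align
#' @return Fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b, scheme = scoring_scheme()) {
  global_align(a, b, scheme)$identity
}
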