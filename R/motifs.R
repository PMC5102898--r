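#' Degenerate amino-acid motif pattern
#'
#' An ordered list of residue classes: position `i` of a hit must be one of
#' the residues in `positions[[i]]`.
#'
#' @param name Motif name.
#' @param positions List of non-empty character vectors of allowed residues.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(name, positions) {
  stopifnot(is.character(name), length(positions) >= 1,
            all(vapply(positions, length, 0L) >= 1))
  positions <- lapply(positions, toupper)
  structure(list(name = name, positions = positions), class = "motif_pattern")
}

#' Diagnostic MOB_F12 relaxase motifs
#'
#' The two motifs that define the MOB_F12 relaxase family in the N-terminal
#' relaxase domain: `(D/E)NYY` and `D(L/F)TF`.
#'
#' @return Named list of two [motif_pattern()] objects.
#' @export
default_motifs <- function() {
  list(
    DENYY = motif_pattern("(D/E)NYY",
                          list(c("D", "E"), "N", "Y", "Y")),
    DLFTF = motif_pattern("D(L/F)TF",
                          list("D", c("L", "F"), "T", "F"))
  )
}

#' Scan a protein domain for degenerate motifs
#'
#' Reports every offset (0-based) at which each motif matches; overlapping
#' hits are all reported.
#'
#' @param domain Non-empty protein sequence.
#' @param patterns List of [motif_pattern()] objects
#'   (default [default_motifs()]).
#' @return Data frame with columns `motif` and `offset` (0-based); zero rows
#'   when nothing matches.
#' @examples
#' scan_motifs("MAENYYQ")  # (D/E)NYY at offset 2
#' @export
scan_motifs <- function(domain, patterns = default_motifs()) {
  if (!is.character(domain) || length(domain) != 1 || !nzchar(domain)) {
    stop("domain must be a non-empty sequence")
  }
  chars <- strsplit(toupper(domain), "")[[1]]
  n <- length(chars)
  out <- list()
  for (p in patterns) {
    L <- length(p$positions)
    if (L > n) next
    ok <- rep(TRUE, n - L + 1L)
    for (j in seq_len(L)) {
      ok <- ok & chars[j:(n - L + j)] %in% p$positions[[j]]
    }
    hits <- which(ok) - 1L
    if (length(hits)) {
      out[[length(out) + 1L]] <- data.frame(motif = p$name, offset = hits,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
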