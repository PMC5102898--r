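## MOB_F12 relaxase typing. A protein is called a MOB_F12 relaxase when its
## N-terminal relaxase domain (first 300 residues) carries both diagnostic
## motifs, (D/E)NYY and D(L/F)TF, and shows at least 40% global-alignment
## identity to its closest reference in a relaxase panel.

#' Extract the N-terminal relaxase domain
#'
#' Returns the first `domain_len` residues of a protein (the whole protein,
#' flagged as truncated, when it is shorter).
#'
#' @param protein Non-empty protein sequence.
#' @param domain_len Domain length in residues (default 300).
#' @return Character scalar with attribute `truncated` (logical).
#' @export
extract_domain <- function(protein, domain_len = 300) {
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein)) {
    stop("protein must be a non-empty sequence")
  }
  truncated <- nchar(protein) < domain_len
  structure(substr(protein, 1, min(domain_len, nchar(protein))),
            truncated = truncated)
}

#' Type one protein against a relaxase reference panel
#'
#' Applies the two-part MOB_F12 membership rule to a candidate protein:
#' both diagnostic motifs must occur in the extracted N-terminal domain, and
#' the best full-domain global-alignment identity against the panel must
#' reach `id_threshold`.
#'
#' @param protein Candidate protein sequence.
#' @param panel Named character vector of reference relaxase sequences
#'   (domains or full-length; only their N-terminal domains are compared).
#' @param id_threshold Identity gate in `[0, 1]` (default 0.40).
#' @param domain_len Domain length (default 300).
#' @param scheme A [scoring_scheme()].
#' @param plasmid_id,protein_id Identifiers carried into the call.
#' @param motifs Motif patterns (default [default_motifs()]).
#' @return A `relaxase_call` list: `plasmid_id`, `protein_id`, `is_mobf12`,
#'   `motif_hits` (data frame), `best_reference`, `best_identity`, `domain`,
#'   `truncated`.
#' @export
call_relaxase <- function(protein, panel, id_threshold = 0.40,
                          domain_len = 300, scheme = scoring_scheme(),
                          plasmid_id = NA_character_,
                          protein_id = NA_character_,
                          motifs = default_motifs()) {
  if (!length(panel)) stop("relaxase panel is empty")
  domain <- extract_domain(protein, domain_len)
  hits <- scan_motifs(domain, motifs)
  motif_names <- vapply(motifs, `[[`, "", "name")
  has_all_motifs <- all(motif_names %in% hits$motif)

  ids <- vapply(names(panel), function(nm) {
    global_identity(as.character(domain),
                    as.character(extract_domain(panel[[nm]], domain_len)),
                    scheme)
  }, 0)
  best <- which.max(ids)
  structure(list(
    plasmid_id = plasmid_id,
    protein_id = protein_id,
    is_mobf12 = has_all_motifs && ids[best] >= id_threshold,
    motif_hits = hits,
    best_reference = names(panel)[best],
    best_identity = unname(ids[best]),
    domain = as.character(domain),
    truncated = attr(domain, "truncated")
  ), class = "relaxase_call")
}

#' @export
print.relaxase_call <- function(x, ...) {
  cat(sprintf("relaxase_call %s/%s: %s (best %s at %.1f%% id, %d motif hits)\n",
              x$plasmid_id, x$protein_id,
              if (x$is_mobf12) "MOB_F12" else "not MOB_F12",
              x$best_reference, 100 * x$best_identity, nrow(x$motif_hits)))
  invisible(x)
}

#' Find candidate relaxases in a plasmid record
#'
#' Screens every CDS of a record against the relaxase panel with a
#' permissive local-alignment prefilter (the E-value threshold used for
#' bait retrieval in database sweeps), then types each candidate with
#' [call_relaxase()]. Proteins shorter than 50 aa are never considered.
#' All calls are returned; the best (highest identity, ties broken by
#' protein id) carries `best = TRUE`.
#'
#' @param record A [plasmid_record()].
#' @param panel Named character vector of reference relaxases.
#' @param prefilter_evalue Local-search E-value gate for candidate retrieval
#'   (default `1e-25`).
#' @param min_len Minimum candidate length in residues (default 50).
#' @inheritParams call_relaxase
#' @return List of `relaxase_call` objects (possibly empty), each with a
#'   `best` flag and a `feature_index` back-reference.
#' @export
find_relaxases <- function(record, panel, prefilter_evalue = 1e-25,
                           id_threshold = 0.40, domain_len = 300,
                           min_len = 50, scheme = scoring_scheme()) {
  if (!length(panel)) stop("relaxase panel is empty")
  calls <- list()
  for (k in seq_along(record$features)) {
    f <- record$features[[k]]
    if (nchar(f$protein) < min_len) next
    # permissive prefilter: best local E-value against any panel member
    best_e <- Inf
    for (ref in panel) {
      s <- local_score(f$protein, ref, scheme)
      e <- evalue_of(s, nchar(f$protein), nchar(ref), scheme)
      if (e < best_e) best_e <- e
    }
    if (best_e > prefilter_evalue) next
    call <- call_relaxase(f$protein, panel, id_threshold, domain_len, scheme,
                          plasmid_id = record$plasmid_id,
                          protein_id = if (nzchar(f$label)) f$label else
                            sprintf("cds_%03d", k))
    call$feature_index <- k
    call$prefilter_evalue <- best_e
    calls[[length(calls) + 1L]] <- call
  }
  if (length(calls)) {
    idents <- vapply(calls, `[[`, 0, "best_identity")
    pids <- vapply(calls, `[[`, "", "protein_id")
    best_idx <- order(-idents, pids)[1]
    for (k in seq_along(calls)) calls[[k]]$best <- (k == best_idx)
  }
  calls
}

#' Tabulate relaxase calls
#'
#' @param calls List of `relaxase_call` objects (possibly nested per record).
#' @return Data frame, one row per call.
#' @export
relaxase_calls_table <- function(calls) {
  if (length(calls) && inherits(calls[[1]], "relaxase_call")) calls <- list(calls)
  rows <- lapply(unlist(calls, recursive = FALSE), function(x) {
    data.frame(plasmid_id = x$plasmid_id, protein_id = x$protein_id,
               is_mobf12 = x$is_mobf12,
               n_motif_hits = nrow(x$motif_hits),
               best_reference = x$best_reference,
               best_identity = x$best_identity,
               truncated = x$truncated,
               best = isTRUE(x$best),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(plasmid_id = character(), protein_id = character(),
                      is_mobf12 = logical(), n_motif_hits = integer(),
                      best_reference = character(), best_identity = numeric(),
                      truncated = logical(), best = logical()))
  }
  do.call(rbind, rows)
}
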