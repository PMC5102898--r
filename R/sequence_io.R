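## Record containers and standard-format I/O. Internal coordinates are
## 0-based half-open; GenBank's 1-based inclusive convention is converted
## at the file boundary only, so for every feature
## genbank_start = start + 1 and genbank_end = end.

#' Construct a gene feature
#'
#' One CDS on a plasmid, in the internal 0-based half-open coordinate
#' convention, with its strand and protein translation.
#'
#' @param label Gene or product name (free text, may be empty).
#' @param start,end Integer coordinates, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @param protein Uppercase amino-acid sequence (may contain `X`).
#' @return A `gene_feature` object.
#' @export
gene_feature <- function(label, start, end, strand, protein) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1, length(end) == 1,
            start >= 0, start < end,
            strand %in% c("+", "-"),
            is.character(protein), length(protein) == 1)
  structure(list(label = as.character(label), start = start, end = end,
                 strand = strand, protein = toupper(protein)),
            class = "gene_feature")
}

#' Construct a plasmid record
#'
#' An annotated plasmid: identifier, optional host taxon, sequence length and
#' an ordered list of CDS features (sorted by start coordinate).
#'
#' @param plasmid_id Unique identifier string.
#' @param features List of [gene_feature()] objects.
#' @param length_bp Plasmid length in bp (`>= 0`); defaults to just past the
#'   last feature.
#' @param host_taxon Free-text host label, optional.
#' @return A `plasmid_record` object.
#' @export
plasmid_record <- function(plasmid_id, features = list(), length_bp = NULL,
                           host_taxon = NA_character_) {
  stopifnot(is.character(plasmid_id), length(plasmid_id) == 1,
            nzchar(plasmid_id))
  stopifnot(all(vapply(features, inherits, TRUE, "gene_feature")))
  if (length(features)) {
    features <- features[order(vapply(features, `[[`, 0L, "start"))]
  }
  if (is.null(length_bp)) {
    length_bp <- if (length(features)) {
      max(vapply(features, `[[`, 0L, "end")) + 100L
    } else 0L
  }
  length_bp <- as.integer(length_bp)
  bad <- vapply(features, function(f) f$end > length_bp, TRUE)
  if (any(bad)) stop("feature coordinates exceed plasmid length")
  structure(list(plasmid_id = plasmid_id, host_taxon = host_taxon,
                 length_bp = length_bp, features = features),
            class = "plasmid_record")
}

#' @export
print.plasmid_record <- function(x, ...) {
  cat(sprintf("plasmid_record %s (%s): %d bp, %d CDS\n", x$plasmid_id,
              if (is.na(x$host_taxon)) "host unknown" else x$host_taxon,
              x$length_bp, length(x$features)))
  invisible(x)
}

record_proteins <- function(record) {
  setNames(vapply(record$features, `[[`, "", "protein"),
           vapply(record$features, `[[`, "", "label"))
}

# canonical gene-name key: case and non-alphanumerics are annotation noise
# ("TraD", "traD", "traD_1" all mean traD)
gene_key <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]", "", x))
  sub("[0-9]+$", "", x)
}

#' Read a protein FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order;
#'   names are the full record ids (first token of the header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write a protein FASTA file
#'
#' @param entries Non-empty named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path, width = 70) {
  if (!length(entries)) stop("no entries to write")
  if (is.null(names(entries)) || any(!nzchar(names(entries)))) {
    stop("all FASTA entries must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(entries)) {
    writeLines(paste0(">", names(entries)[i]), con)
    s <- entries[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a matrix as TSV with row and column headers
#'
#' @param matrix Matrix (or object with a matrix in `$matrix`) with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(matrix, path) {
  if (is.list(matrix) && !is.null(matrix$matrix)) matrix <- matrix$matrix
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#' @param path Path to the TSV file.
#' @return Matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}
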