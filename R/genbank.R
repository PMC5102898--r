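## Minimal GenBank flat-file reader/writer for annotated plasmid records.
## Covers the subset of the format the pipeline needs: LOCUS, DEFINITION,
## source /organism, and CDS features with /gene and /translation
## qualifiers, on either strand. Coordinates convert between GenBank's
## 1-based inclusive convention and the internal 0-based half-open one at
## this boundary only.

#' Read plasmid records from a GenBank flat file
#'
#' Parses a (possibly multi-record) GenBank flat file into
#' [plasmid_record()] objects. CDS features carrying a `/translation`
#' become [gene_feature()]s; CDS features without a translation are skipped
#' with a warning so fragmentary annotations still flow through.
#' `complement(a..b)` locations become strand `-`.
#'
#' @param path Path to the GenBank file.
#' @return List of `plasmid_record` objects, one per LOCUS.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    stop("not a GenBank flat file (no LOCUS line): ", path)
  }
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^LOCUS", lines[i])) {
      if (nzchar(trimws(lines[i]))) {
        stop("malformed GenBank file at line ", i, ": expected LOCUS, got: ",
             trimws(lines[i]))
      }
      i <- i + 1L
      next
    }
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) < 3 || is.na(suppressWarnings(as.integer(toks[3])))) {
      stop("malformed LOCUS line at line ", i)
    }
    locus_name <- toks[2]
    length_bp <- as.integer(toks[3])
    host <- NA_character_
    feats <- list()
    i <- i + 1L
    # scan to end-of-record marker
    in_features <- FALSE
    while (i <= n && !grepl("^//", lines[i])) {
      line <- lines[i]
      if (grepl("^FEATURES", line)) {
        in_features <- TRUE
        i <- i + 1L
        next
      }
      if (in_features && grepl("^ {5}\\S", line)) {
        key <- trimws(substr(line, 1, 20))
        loc <- trimws(substr(line, 21, nchar(line)))
        qualifiers <- character()
        i <- i + 1L
        # gather continuation/qualifier lines (21 leading spaces)
        while (i <= n && grepl("^ {21}", lines[i])) {
          qualifiers <- c(qualifiers, trimws(lines[i]))
          i <- i + 1L
        }
        if (key == "source") {
          org <- grep('^/organism="', qualifiers, value = TRUE)
          if (length(org)) host <- sub('^/organism="(.*)"$', "\\1", org[1])
        } else if (key == "CDS") {
          feat <- parse_cds(loc, qualifiers, line_no = i)
          if (is.null(feat)) {
            fp_warn("CDS without /translation skipped in ", locus_name,
                    " at ", loc)
          } else {
            feats[[length(feats) + 1L]] <- feat
          }
        }
        next
      }
      i <- i + 1L
    }
    if (i > n) stop("record ", locus_name, " not terminated by //")
    i <- i + 1L
    records[[length(records) + 1L]] <-
      plasmid_record(locus_name, feats, length_bp = length_bp,
                     host_taxon = host)
  }
  ids <- vapply(records, `[[`, "", "plasmid_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate plasmid ids: ", paste(dup, collapse = ", "))
  records
}

parse_cds <- function(loc, qualifiers, line_no) {
  strand <- "+"
  body <- loc
  if (grepl("^complement\\(", body)) {
    strand <- "-"
    body <- sub("^complement\\((.*)\\)$", "\\1", body)
  }
  m <- regmatches(body, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", body))[[1]]
  if (length(m) != 3) {
    stop("unsupported CDS location near line ", line_no, ": ", loc)
  }
  gb_start <- as.integer(m[2]); gb_end <- as.integer(m[3])
  # qualifiers may wrap over several physical lines; re-join on '/'
  qjoin <- character()
  for (q in qualifiers) {
    if (grepl("^/", q) || !length(qjoin)) {
      qjoin <- c(qjoin, q)
    } else {
      qjoin[length(qjoin)] <- paste0(qjoin[length(qjoin)], q)
    }
  }
  getq <- function(name) {
    hit <- grep(paste0("^/", name, '="'), qjoin, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0('^/', name, '="(.*)"$'), "\\1", hit[1])
  }
  translation <- getq("translation")
  if (is.na(translation) || !nzchar(translation)) return(NULL)
  label <- getq("gene")
  if (is.na(label)) label <- getq("product")
  if (is.na(label)) label <- ""
  gene_feature(label, gb_start - 1L, gb_end, strand, translation)
}

#' Write plasmid records as a GenBank flat file
#'
#' Deterministic inverse of [read_genbank()]: identical input always
#' produces byte-identical output (the LOCUS date field is fixed). Each
#' feature gets a synthetic in-frame nucleotide backing via a fixed
#' reverse-translation codon table, so the ORIGIN block is a valid DNA
#' sequence of the declared length.
#'
#' @param records List of [plasmid_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(records, path) {
  if (inherits(records, "plasmid_record")) records <- list(records)
  if (!length(records)) stop("no records to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf("LOCUS       %-16s %11d bp    DNA     circular BCT 01-JAN-2016",
                       rec$plasmid_id, rec$length_bp), con)
    writeLines(sprintf("DEFINITION  synthetic F-like plasmid %s.",
                       rec$plasmid_id), con)
    writeLines(sprintf("ACCESSION   %s", rec$plasmid_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rec$length_bp), con)
    if (!is.na(rec$host_taxon)) {
      writeLines(sprintf('                     /organism="%s"', rec$host_taxon),
                 con)
    }
    for (f in rec$features) {
      loc <- sprintf("%d..%d", f$start + 1L, f$end)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      if (nzchar(f$label)) {
        writeLines(sprintf('                     /gene="%s"', f$label), con)
      }
      writeLines(wrap_qualifier("translation", f$protein), con)
    }
    writeLines("ORIGIN", con)
    writeLines(format_origin(backing_sequence(rec)), con)
    writeLines("//", con)
  }
  invisible(path)
}

wrap_qualifier <- function(name, value, width = 58) {
  text <- sprintf('/%s="%s"', name, value)
  starts <- seq(1, nchar(text), by = width)
  paste0(strrep(" ", 21),
         substring(text, starts, pmin(starts + width - 1, nchar(text))))
}

# one fixed codon per amino acid (plus stop); enough to give every CDS an
# in-frame nucleotide backing — only the protein level is ever analysed
codon_table <- c(A = "gct", R = "cgt", N = "aat", D = "gat", C = "tgt",
                 Q = "caa", E = "gaa", G = "ggt", H = "cat", I = "att",
                 L = "ctg", K = "aaa", M = "atg", F = "ttt", P = "cct",
                 S = "tct", T = "act", W = "tgg", Y = "tat", V = "gtt",
                 X = "nnn", "*" = "taa")

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- codon_table[aa]
  codons[is.na(codons)] <- "nnn"
  paste0(paste(codons, collapse = ""), "taa")
}

revcomp <- function(s) {
  chartr("acgtn", "tgcan", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

backing_sequence <- function(rec) {
  seq <- rep("a", rec$length_bp)
  for (f in rec$features) {
    nt <- reverse_translate(f$protein)
    nt <- substr(nt, 1, f$end - f$start)   # clip if frame doesn't fit exactly
    if (f$strand == "-") nt <- revcomp(nt)
    chars <- strsplit(nt, "")[[1]]
    seq[(f$start + 1L):(f$start + length(chars))] <- chars
  }
  paste(seq, collapse = "")
}

format_origin <- function(seq) {
  n <- nchar(seq)
  out <- character()
  for (pos in seq(1, n, by = 60)) {
    chunk_ends <- pmin(seq(pos + 9, pos + 59, by = 10), n)
    chunk_starts <- seq(pos, pos + 50, by = 10)
    keep <- chunk_starts <= n
    blocks <- substring(seq, chunk_starts[keep], chunk_ends[keep])
    out <- c(out, sprintf("%9d %s", pos, paste(blocks, collapse = " ")))
  }
  out
}
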