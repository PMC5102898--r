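## Operon-architecture inference and group A-E assignment.
##
## Architecture is read off the genomic layout of the detected tra genes:
## genes are clustered by distance (gap <= max_gap), then
##   - one co-oriented cluster                      -> single_operon
##   - relaxosome cluster (traD/traI) transcribed
##     divergently from the pilus cluster          -> bipartite_divergent
##   - two clusters on opposite strands pointing
##     toward each other                            -> split_convergent
##   - fewer than min_genes located genes           -> fragmentary
##   - anything else                                -> unknown

pilus_core_genes <- c("traA", "traL", "traE", "traK", "traB", "traV", "traC",
                      "traW", "traU", "trbC", "traN", "traF", "traH")
relaxosome_genes <- c("traD", "traI")

#' Default essential-gene set for F conjugation
#'
#' The 13 pilus genes established as essential for F-plasmid conjugation by
#' transposon-insertion genetics (traA, traL, traE, traK, traB, traV, traC,
#' traW, traU, trbC, traN, traF, traH), plus traG (mating-pair
#' stabilisation), the coupling protein traD and the relaxase traI for
#' transfer completeness. Configurable in all downstream calls.
#'
#' @return Character vector of 16 gene names.
#' @export
essential_genes <- function() {
  c("TraA", "TraL", "TraE", "TraK", "TraB", "TraV", "TraC", "TraW", "TraU",
    "TrbC", "TraN", "TraF", "TraH", "TraG", "TraD", "TraI")
}

#' Infer conjugation-region operon architecture
#'
#' Locates the detected tra genes on the record via the profiler's hit
#' provenance, clusters them by genomic gap, and classifies the layout.
#'
#' @param record A [plasmid_record()].
#' @param matrix_row Named 0/1 vector for this plasmid (panel + markers).
#' @param provenance Provenance data frame from [build_matrix()] restricted
#'   to this plasmid (used for feature coordinates of the best hits).
#' @param max_gap Maximum intergenic gap (bp) within one operon cluster
#'   (default 5000).
#' @param min_genes Minimum located tra genes for a non-fragmentary call
#'   (default 4).
#' @return An `architecture_class` object: `class` string and `clusters`
#'   (list of data frames with gene, start, end, strand).
#' @export
infer_architecture <- function(record, matrix_row, provenance,
                               max_gap = 5000, min_genes = 4) {
  prov <- provenance[provenance$present == 1L &
                       provenance$plasmid_id == record$plasmid_id, ,
                     drop = FALSE]
  loc <- NULL
  if (nrow(prov)) {
    feats <- record$features[prov$feature_index]
    loc <- data.frame(
      gene = prov$gene,
      start = vapply(feats, `[[`, 0L, "start"),
      end = vapply(feats, `[[`, 0L, "end"),
      strand = vapply(feats, `[[`, "", "strand"),
      stringsAsFactors = FALSE)
    # two panel entries may hit the same CDS (e.g. TraI domain vs full);
    # one location per distinct feature is enough for layout purposes
    loc <- loc[!duplicated(prov$feature_index), , drop = FALSE]
    loc <- loc[order(loc$start), , drop = FALSE]
  }
  if (is.null(loc) || nrow(loc) < min_genes) {
    return(structure(list(class = "fragmentary",
                          clusters = if (is.null(loc)) list() else list(loc)),
                     class = "architecture_class"))
  }
  gaps <- loc$start[-1] - loc$end[-nrow(loc)]
  cluster_id <- cumsum(c(1L, as.integer(gaps > max_gap)))
  clusters <- split(loc, cluster_id)

  cls <- "unknown"
  strands <- vapply(clusters, function(cl) {
    if (length(unique(cl$strand)) == 1L) cl$strand[1] else NA_character_
  }, "")
  if (length(clusters) == 1L && !is.na(strands[1])) {
    cls <- "single_operon"
  } else if (length(clusters) == 2L && !anyNA(strands) &&
             strands[1] != strands[2]) {
    keys <- lapply(clusters, function(cl) gene_key(cl$gene))
    has_relax <- vapply(keys, function(k) any(k %in% gene_key(relaxosome_genes)), TRUE)
    has_pilus <- vapply(keys, function(k) any(k %in% gene_key(pilus_core_genes)), TRUE)
    divergent <- strands[1] == "-" && strands[2] == "+"
    convergent <- strands[1] == "+" && strands[2] == "-"
    split_ok <- xor(has_relax[1], has_relax[2]) &&
      any(has_pilus[!has_relax])
    if (divergent && split_ok) cls <- "bipartite_divergent"
    else if (convergent) cls <- "split_convergent"
  }
  structure(list(class = cls, clusters = unname(clusters)),
            class = "architecture_class")
}

#' @export
print.architecture_class <- function(x, ...) {
  cat(sprintf("architecture: %s (%d cluster%s)\n", x$class,
              length(x$clusters), if (length(x$clusters) == 1) "" else "s"))
  invisible(x)
}

#' Regulator presence profile of one plasmid
#'
#' Extracts the booleans the group rules consume from a presence/absence
#' row: the classical regulators traM, traJ, traY, finO, the MPF marker
#' traC, and the three group-specific markers TraJ_V, EntFR, SphTR.
#' Markers absent from the panel are reported as `NA` (unknown), not FALSE.
#'
#' @param matrix_row Named 0/1 vector (one row of the presence matrix built
#'   with the 36-gene panel plus the marker regulators).
#' @return A `regulator_profile` (named logical vector).
#' @export
regulator_profile <- function(matrix_row) {
  keys <- gene_key(names(matrix_row))
  get <- function(gene) {
    i <- match(gene_key(gene), keys)
    if (is.na(i)) NA else matrix_row[[i]] == 1L
  }
  structure(c(traM = get("TraM"), traJ = get("TraJ"), traY = get("TraY"),
              finO = get("FinO"), traC = get("TraC"),
              traJ_V = get("TraJ_V"), entFR = get("EntFR"),
              sphTR = get("SphTR")),
            class = "regulator_profile")
}

isTRUE_na <- function(x) !is.na(x) && x
isFALSE_na <- function(x) !is.na(x) && !x

#' Assign a plasmid to one of the five F-like groups
#'
#' Applies the regulatory-gene rules in fixed order A -> B -> C -> D -> E;
#' the first matching rule wins and the evidence trace records every rule
#' evaluated:
#' \describe{
#'   \item{A}{traM and traJ present (classical fertility-inhibition layout);
#'     flagged `derepressed_finO_minus` when finO is absent, the F-plasmid
#'     exception.}
#'   \item{B}{finO present, traM and traJ absent, traC present, and a
#'     bipartite divergent operon layout.}
#'   \item{C}{TraJ_V present, finO absent, traC present, single operon.}
#'   \item{D}{EntFR present, traJ and finO absent, traC present.}
#'   \item{E}{SphTR present with a split convergent layout.}
#' }
#' Anything else is `unassigned` (a valid outcome). traY is deliberately not
#' used by any rule: it is too small to be reliably annotated.
#'
#' @param profile A [regulator_profile()].
#' @param architecture An `architecture_class` from [infer_architecture()].
#' @param completeness Optional completeness report from [completeness()];
#'   contributes the `deletion_derivative` and `incomplete_mpf` flags.
#' @param truncated_relaxase Logical; flags a truncated relaxase domain.
#' @return A `group_assignment`: `group`, `flags`, `evidence` (rule trace).
#' @export
classify_group <- function(profile, architecture, completeness = NULL,
                           truncated_relaxase = FALSE) {
  arch <- architecture$class
  rules <- list(
    A = isTRUE_na(profile[["traM"]]) && isTRUE_na(profile[["traJ"]]),
    B = isTRUE_na(profile[["finO"]]) && isFALSE_na(profile[["traM"]]) &&
      isFALSE_na(profile[["traJ"]]) && isTRUE_na(profile[["traC"]]) &&
      arch == "bipartite_divergent",
    C = isTRUE_na(profile[["traJ_V"]]) && isFALSE_na(profile[["finO"]]) &&
      isTRUE_na(profile[["traC"]]) && arch == "single_operon",
    D = isTRUE_na(profile[["entFR"]]) && isFALSE_na(profile[["traJ"]]) &&
      isFALSE_na(profile[["finO"]]) && isTRUE_na(profile[["traC"]]),
    E = isTRUE_na(profile[["sphTR"]]) && arch == "split_convergent"
  )
  group <- "unassigned"
  for (g in names(rules)) {
    if (rules[[g]]) { group <- g; break }
  }
  flags <- character()
  if (group == "A" && isFALSE_na(profile[["finO"]])) {
    flags <- c(flags, "derepressed_finO_minus")
  }
  if (!is.null(completeness)) {
    if (isTRUE(completeness$deletion_derivative)) {
      flags <- c(flags, "deletion_derivative")
    }
    if (!completeness$complete) flags <- c(flags, "incomplete_mpf")
  }
  if (isTRUE(truncated_relaxase)) flags <- c(flags, "truncated_relaxase")
  structure(list(group = group, flags = flags,
                 evidence = list(rules = rules, profile = unclass(profile),
                                 architecture = arch)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group %s%s\n", x$group,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "),
                                          "]") else ""))
  invisible(x)
}

#' Essential-gene completeness of one plasmid
#'
#' Reports whether every essential transfer gene is present, the sorted list
#' of missing ones, and whether the plasmid looks like a deletion derivative
#' (the reduction seen in *Shigella*-type plasmids: only traI, traX and finO
#' left, with the MPF marker traC gone).
#'
#' @param matrix_row Named 0/1 vector over the reference panel.
#' @param essential_set Character vector of essential gene names
#'   (default [essential_genes()]); must be a subset of the panel.
#' @return List: `complete`, `missing`, `deletion_derivative`.
#' @export
completeness <- function(matrix_row, essential_set = essential_genes()) {
  keys <- gene_key(names(matrix_row))
  ess <- gene_key(essential_set)
  if (!all(ess %in% keys)) {
    stop("essential set contains genes absent from the panel: ",
         paste(essential_set[!ess %in% keys], collapse = ", "))
  }
  present <- names(matrix_row)[matrix_row == 1L]
  missing <- essential_set[!ess %in% gene_key(present)]
  shigella_sig <- gene_key(c("TraI", "TraX", "FinO"))
  # only genes of the core 36-entry panel count toward the deletion signature
  core <- matrix_row[gene_key(names(matrix_row)) %in% gene_key(panel_gene_names())]
  core_present <- gene_key(names(core)[core == 1L])
  deletion <- length(core_present) > 0 &&
    all(core_present %in% shigella_sig) &&
    !("trac" %in% core_present)
  list(complete = length(missing) == 0,
       missing = sort(missing),
       deletion_derivative = deletion)
}
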