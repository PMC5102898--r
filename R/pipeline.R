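## End-to-end pipeline and reporting: relaxase typing -> tra profiling ->
## architecture -> group assignment -> NJ tree -> monophyly, plus the
## simulate/classify/report front ends driven by a YAML run configuration.

#' Build a run configuration
#'
#' All thresholds of the pipeline in one validated object: the relaxase
#' identity gate (0.40), the presence-call E-value (1e-3), the N-terminal
#' domain length (300 aa), the permissive relaxase prefilter E-value
#' (1e-25), and the operon clustering constants. Round-trips losslessly
#' through YAML.
#'
#' @param input GenBank file of plasmids to classify (classify/report).
#' @param panel_path FASTA of the 36 + 3 profiling references.
#' @param typing_panel_path FASTA of relaxase references for MOB typing.
#' @param out_dir Output/run directory.
#' @param id_threshold,e_threshold,domain_len,prefilter_evalue,max_gap,min_genes
#'   Pipeline thresholds (see Details).
#' @param seed Integer seed for the simulate step.
#' @param n_per_group,identity_range,between_identity,n_decoys Generator
#'   parameters for the simulate step.
#' @param outgroup Leaf id of the outgroup relaxase (optional).
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, panel_path = NULL,
                       typing_panel_path = NULL, out_dir = "run",
                       id_threshold = 0.40, e_threshold = 1e-3,
                       domain_len = 300, prefilter_evalue = 1e-25,
                       max_gap = 5000, min_genes = 4, seed = 1,
                       n_per_group = 10, identity_range = c(0.6, 0.9),
                       between_identity = 0.5, n_decoys = 0,
                       outgroup = "TrwC_out") {
  cfg <- list(input = input, panel_path = panel_path,
              typing_panel_path = typing_panel_path, out_dir = out_dir,
              id_threshold = id_threshold, e_threshold = e_threshold,
              domain_len = domain_len, prefilter_evalue = prefilter_evalue,
              max_gap = max_gap, min_genes = min_genes, seed = seed,
              n_per_group = n_per_group,
              identity_range = identity_range,
              between_identity = between_identity, n_decoys = n_decoys,
              outgroup = outgroup)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (!(cfg$id_threshold >= 0 && cfg$id_threshold <= 1)) {
    stop("id_threshold must lie in [0, 1]")
  }
  if (!(cfg$e_threshold > 0)) stop("e_threshold must be positive")
  if (!(cfg$domain_len >= 1)) stop("domain_len must be >= 1")
  if (!(cfg$max_gap > 0 && cfg$min_genes >= 1)) {
    stop("max_gap must be positive and min_genes >= 1")
  }
  if (length(cfg$identity_range) != 2 ||
      any(cfg$identity_range <= 0) || any(cfg$identity_range > 1) ||
      cfg$identity_range[1] > cfg$identity_range[2]) {
    stop("identity_range must be an increasing pair in (0, 1]")
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a ground-truth dataset onto disk
#'
#' Wraps [make_dataset()]: writes the GenBank dataset, the profiling and
#' typing panel FASTAs (typing panel includes the outgroup relaxase), the
#' truth table TSV and a manifest echoing every parameter.
#'
#' @param config A `run_config`.
#' @return Invisibly, the [make_dataset()] result with a `paths` element.
#' @export
cmd_simulate <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- make_dataset(n_per_group = config$n_per_group,
                     identity_range = config$identity_range,
                     seed = config$seed,
                     between_identity = config$between_identity,
                     n_decoys = config$n_decoys)
  paths <- list(
    genbank = file.path(config$out_dir, "plasmids.gbk"),
    panel = file.path(config$out_dir, "panel.faa"),
    typing_panel = file.path(config$out_dir, "typing_panel.faa"),
    truth = file.path(config$out_dir, "truth.tsv"),
    manifest = file.path(config$out_dir, "manifest.yaml"))
  write_genbank(ds$records, paths$genbank)
  write_fasta(ds$panel_obj$profile_panel, paths$panel)
  write_fasta(c(ds$typing_panel, ds$panel_obj$outgroup), paths$typing_panel)
  write.table(ds$truths, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  yaml::write_yaml(ds$manifest, paths$manifest)
  fp_log("simulated ", length(ds$records), " plasmids into ", config$out_dir)
  ds$paths <- paths
  invisible(ds)
}

#' Classify a set of plasmid records in memory
#'
#' The core pipeline: MOB_F12 relaxase typing, 36-gene + marker profiling,
#' architecture inference, completeness, group assignment, and (for three
#' or more typed relaxases) the NJ tree with outgroup rooting and a
#' monophyly report over the predicted groups.
#'
#' @param records List of [plasmid_record()] objects.
#' @param panel Named vector: profiling references (36 genes + markers).
#' @param typing_panel Named vector of relaxase references.
#' @param config A `run_config` (thresholds; paths ignored).
#' @param outgroup_seq Optional named length-1 vector with an outgroup
#'   relaxase; enables rooting.
#' @return A `classification` list: `calls`, `matrix`, `conservation`,
#'   `cooccurrence`, `assignments` (data frame), `per_plasmid` (list),
#'   `tree` (rooted phylo or NULL), `monophyly`.
#' @export
classify_records <- function(records, panel, typing_panel,
                             config = run_config(), outgroup_seq = NULL) {
  scheme <- scoring_scheme()
  validate_config(config)
  fp_log("profiling ", length(records), " records against ",
         length(panel), " references")
  pam <- build_matrix(records, panel, e_threshold = config$e_threshold,
                      scheme = scheme)
  cons <- conservation(pam)
  cooc <- cooccurrence(pam)

  per_plasmid <- list()
  rows <- list()
  best_calls <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    calls <- find_relaxases(rec, typing_panel,
                            prefilter_evalue = config$prefilter_evalue,
                            id_threshold = config$id_threshold,
                            domain_len = config$domain_len, scheme = scheme)
    best <- if (length(calls)) calls[[which(vapply(calls, function(x)
      isTRUE(x$best), TRUE))[1]]] else NULL
    row <- pam$matrix[rec$plasmid_id, ]
    prof <- regulator_profile(row)
    arch <- infer_architecture(rec, row, pam$provenance,
                               max_gap = config$max_gap,
                               min_genes = config$min_genes)
    comp <- completeness(row)
    assign <- classify_group(prof, arch, comp,
                             truncated_relaxase =
                               !is.null(best) && isTRUE(best$truncated))
    is_mobf12 <- !is.null(best) && best$is_mobf12
    if (!is.null(best) && best$is_mobf12) best_calls[[length(best_calls) + 1L]] <- best
    per_plasmid[[rec$plasmid_id]] <- list(
      plasmid_id = rec$plasmid_id, host_taxon = rec$host_taxon,
      is_mobf12 = is_mobf12,
      relaxase = if (is.null(best)) NULL else
        best[c("protein_id", "best_reference", "best_identity", "truncated")],
      group = assign$group, flags = assign$flags,
      regulator_profile = as.list(unclass(prof)),
      architecture = arch$class,
      missing_essentials = comp$missing)
    rows[[i]] <- data.frame(
      plasmid_id = rec$plasmid_id, host = rec$host_taxon,
      is_mobf12 = is_mobf12, group = assign$group,
      flags = paste(assign$flags, collapse = ";"),
      architecture = arch$class,
      n_missing_essentials = length(comp$missing),
      stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)

  tree <- NULL
  mono <- NULL
  if (length(best_calls) >= 3) {
    domains <- setNames(vapply(best_calls, `[[`, "", "domain"),
                        vapply(best_calls, `[[`, "", "plasmid_id"))
    if (!is.null(outgroup_seq)) {
      og <- setNames(as.character(extract_domain(outgroup_seq[[1]],
                                                 config$domain_len)),
                     names(outgroup_seq)[1])
      domains <- c(domains, og)
    }
    D <- distance_matrix(domains, scheme)
    tree <- neighbor_joining(D)
    if (!is.null(outgroup_seq)) {
      tree <- root_with_outgroup(tree, names(outgroup_seq)[1])
    }
    groups <- split(assignments$plasmid_id, assignments$group)
    mono <- monophyly_report(tree, groups)
  } else {
    fp_log("fewer than 3 typed relaxases: no tree built")
  }
  structure(list(calls = best_calls, matrix = pam, conservation = cons,
                 cooccurrence = cooc, assignments = assignments,
                 per_plasmid = per_plasmid, tree = tree, monophyly = mono),
            class = "classification")
}

#' Classify plasmids from disk and write all reports
#'
#' Reads the GenBank input and panels named in the configuration, runs
#' [classify_records()], and writes: per-plasmid JSON, the presence/absence
#' matrix TSV, co-occurrence TSVs (integer statistic and normalized C/N),
#' the conservation table, the relaxase-call table, the Newick tree (when
#' built), the monophyly report and a dataset-level summary TSV with group
#' counts and whole-number percentages.
#'
#' @param config A `run_config` with `input`, `panel_path`,
#'   `typing_panel_path` and `out_dir` set.
#' @return Invisibly, the `classification` object.
#' @export
cmd_classify <- function(config) {
  validate_config(config)
  for (p in c(config$input, config$panel_path, config$typing_panel_path)) {
    if (is.null(p) || !file.exists(p)) stop("input file not found: ",
                                            if (is.null(p)) "(unset)" else p)
  }
  records <- read_genbank(config$input)
  panel <- read_panel(config$panel_path)
  typing <- read_panel(config$typing_panel_path)
  outgroup_seq <- NULL
  if (!is.null(config$outgroup) && config$outgroup %in% names(typing)) {
    outgroup_seq <- typing[config$outgroup]
    typing <- typing[setdiff(names(typing), config$outgroup)]
  }
  cls <- classify_records(records, panel, typing, config, outgroup_seq)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cls$per_plasmid,
                       file.path(out, "classification.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_matrix_tsv(cls$matrix$matrix, file.path(out, "presence_absence.tsv"))
  write_matrix_tsv(cls$cooccurrence$matrix, file.path(out, "cooccurrence.tsv"))
  write_matrix_tsv(cls$cooccurrence$normalized,
                   file.path(out, "cooccurrence_normalized.tsv"))
  write.table(cls$conservation, file.path(out, "conservation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(relaxase_calls_table(list(cls$calls)),
              file.path(out, "relaxase_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cls$tree)) {
    write_newick(cls$tree, file.path(out, "relaxase_tree.nwk"))
    write.table(cls$monophyly, file.path(out, "monophyly.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(group_summary(cls$assignments),
              file.path(out, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  fp_log("classification written to ", out)
  invisible(cls)
}

#' Group counts with whole-number percentages
#'
#' @param assignments Data frame with a `group` column.
#' @return Data frame: group, count, percent (nearest integer, ties away
#'   from zero), one row per group A-E plus unassigned.
#' @export
group_summary <- function(assignments) {
  lv <- c("A", "B", "C", "D", "E", "unassigned")
  counts <- table(factor(assignments$group, levels = lv))
  data.frame(group = lv, count = as.integer(counts),
             percent = vapply(as.integer(counts), percent_round,
                              0L, total = nrow(assignments)),
             stringsAsFactors = FALSE)
}

#' Print a human-readable summary of a finished classification run
#'
#' Reads the classify outputs back from the run directory and prints the
#' conservation table (sorted descending), the group table with recomputed
#' percentages, and flag counts.
#'
#' @param config A `run_config` whose `out_dir` holds classify outputs.
#' @return Invisibly, a list with the three tables.
#' @export
cmd_report <- function(config) {
  out <- config$out_dir
  need <- file.path(out, c("summary.tsv", "conservation.tsv",
                           "classification.json"))
  for (p in need) if (!file.exists(p)) stop("missing classify output: ", p)
  summary_tbl <- read.delim(need[1], stringsAsFactors = FALSE)
  cons <- read.delim(need[2], stringsAsFactors = FALSE)
  per <- jsonlite::read_json(need[3])
  flags <- table(unlist(lapply(per, function(x) unlist(x$flags))))
  flag_tbl <- data.frame(flag = names(flags), count = as.integer(flags),
                         stringsAsFactors = FALSE)
  cons$percent <- round(cons$percent, 1)
  cat("== Gene conservation (% of plasmids) ==\n")
  print(cons[order(-cons$percent), ], row.names = FALSE)
  cat("\n== Groups ==\n")
  print(summary_tbl, row.names = FALSE)
  cat("\n== Flags ==\n")
  if (nrow(flag_tbl)) print(flag_tbl, row.names = FALSE) else cat("none\n")
  invisible(list(conservation = cons, groups = summary_tbl,
                 flags = flag_tbl))
}
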