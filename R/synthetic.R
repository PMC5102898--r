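## Ground-truth synthetic plasmids. The generator emulates the statistical
## structure the classifier assumes: per-group gene complements and operon
## layouts, and protein sequences diverged to controlled percent identity
## from a synthetic reference panel (including a relaxase carrying the
## (D/E)NYY and D(L/F)TF motifs). Everything is a pure function of the seed.

amino_acids <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Robinson-Robinson style background frequencies (approximate)
aa_freqs <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
              Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
              L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
              S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.065)

# realistic length spread (aa) for the 36 reference proteins + markers +
# outgroup; TraI is represented by its N-terminal 300-residue domain
panel_lengths <- c(
  TraJ = 229, TraA = 121, TraL = 91, TraE = 188, TraK = 242, TraB = 475,
  TraP = 196, TrbD = 64, TrbG = 80, TraV = 171, TraR = 73, TraC = 875,
  TrbI = 128, TraW = 210, TraU = 330, TrbC = 212, TraN = 602, TrbE = 86,
  TraF = 247, TrbA = 115, ArtA = 104, TraQ = 94, TrbB = 179, TrbJ = 93,
  TrbF = 127, TraH = 458, TraG = 938, TraS = 149, TraT = 244, TraD = 717,
  TrbH = 139, TraI = 300, TraX = 248, TraM = 127, TraY = 131, FinO = 186,
  TraJ_V = 210, EntFR = 95, SphTR = 72, TrwC_out = 300)

# 1-based positions of the diagnostic motifs placed in the synthetic TraI
# domain; kept invariant ("protected") by every evolution step
relaxase_motif_positions <- function() {
  list(DENYY = 96:99, DLFTF = 151:154)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

sub_seed <- function(seed, k) {
  ((as.numeric(seed) %% 1e6) * 1009 + k * 97 + 11) %% 2147483629
}

random_protein <- function(len) {
  paste(sample(amino_acids, len, replace = TRUE, prob = aa_freqs),
        collapse = "")
}

#' Generate the synthetic reference protein panel
#'
#' Builds the 36-gene profiling panel plus the three group-marker regulators
#' (TraJ_V, EntFR, SphTR) and a MOB_F11-like outgroup relaxase, all as
#' synthetic stand-in sequences with a realistic length spread (60-1200 aa).
#' The relaxase entry (TraI, N-terminal domain) carries both diagnostic
#' motifs, (D/E)NYY and D(L/F)TF, within its first 300 residues. The marker
#' regulators are verified mutually dissimilar (< 25% pairwise identity, by
#' the package's own aligner) and dissimilar to the classical regulators
#' they might be confused with; generation is resampled until that holds.
#'
#' @param seed Integer seed; identical seeds give byte-identical panels.
#' @param scheme A [scoring_scheme()] used for the dissimilarity check.
#' @return List: `profile_panel` (named vector, 36 + 3 markers),
#'   `panel` (the 36), `markers` (3), `outgroup` (length-1 named vector),
#'   `motif_positions`, `seed`.
#' @export
make_reference_panel <- function(seed = 1, scheme = scoring_scheme()) {
  for (attempt in 0:19) {
    seqs <- with_seed(sub_seed(seed, 1000 + attempt), {
      s <- vapply(panel_lengths, random_protein, "")
      # stamp the diagnostic motifs into the relaxase domain
      pos <- relaxase_motif_positions()
      tra_i <- strsplit(s[["TraI"]], "")[[1]]
      tra_i[pos$DENYY] <- c("D", "N", "Y", "Y")
      tra_i[pos$DLFTF] <- c("D", "L", "T", "F")
      s[["TraI"]] <- paste(tra_i, collapse = "")
      s
    })
    # markers must not be mistaken for each other or for the classical
    # regulators; the outgroup must not look like the MOB_F12 relaxase
    check <- list(c("TraJ_V", "EntFR"), c("TraJ_V", "SphTR"),
                  c("EntFR", "SphTR"), c("TraJ_V", "TraJ"),
                  c("EntFR", "TraY"), c("EntFR", "TraM"),
                  c("SphTR", "TraM"), c("TrwC_out", "TraI"))
    ok <- all(vapply(check, function(p) {
      global_identity(seqs[[p[1]]], seqs[[p[2]]], scheme) < 0.25
    }, TRUE))
    if (ok) break
  }
  if (!ok) stop("could not generate a dissimilar marker set")
  core <- setdiff(names(panel_lengths), c(marker_gene_names(), "TrwC_out"))
  list(profile_panel = seqs[c(core, marker_gene_names())],
       panel = seqs[core],
       markers = seqs[marker_gene_names()],
       outgroup = seqs["TrwC_out"],
       motif_positions = relaxase_motif_positions(),
       seed = seed)
}

#' Evolve a protein to a target percent identity
#'
#' Substitution-only divergence: a deterministic number of positions
#' (`round((1 - target) * length)`) outside the protected intervals is
#' replaced by different residues, and the realized identity is measured
#' with the package's global aligner; the draw is repeated (up to
#' `max_attempts` times with derived seeds) until the realized identity is
#' within `tol` of the target.
#'
#' @param seq Protein sequence.
#' @param target_identity Target in `(0, 1]`; 1 returns the input unchanged.
#' @param seed Integer seed.
#' @param protected Integer vector of 1-based positions never mutated
#'   (e.g. motif positions).
#' @param tol Acceptance tolerance on realized identity (default 0.03).
#' @param max_attempts Resampling budget (default 20).
#' @param scheme A [scoring_scheme()].
#' @return Evolved sequence with attribute `realized_identity`.
#' @export
evolve <- function(seq, target_identity, seed, protected = integer(),
                   tol = 0.03, max_attempts = 20,
                   scheme = scoring_scheme()) {
  stopifnot(target_identity > 0, target_identity <= 1)
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  k <- round((1 - target_identity) * L)
  if (k == 0) return(structure(seq, realized_identity = 1))
  eligible <- setdiff(seq_len(L), protected)
  if (k > length(eligible)) {
    stop("target identity unattainable: protected intervals too large")
  }
  for (attempt in seq_len(max_attempts)) {
    mutated <- with_seed(sub_seed(seed, attempt), {
      out <- chars
      at <- sample(eligible, k)
      for (i in at) {
        out[i] <- sample(setdiff(amino_acids, out[i]), 1)
      }
      paste(out, collapse = "")
    })
    realized <- global_identity(seq, mutated, scheme)
    if (abs(realized - target_identity) <= tol) {
      return(structure(mutated, realized_identity = realized))
    }
  }
  stop(sprintf("could not reach target identity %.2f within %d attempts",
               target_identity, max_attempts))
}

#' Group archetypes: gene complement, order, strand and layout per group
#'
#' Encodes the five conjugation-region configurations the classifier is
#' built to recognise: the classical single-operon layout with full
#' regulators (A), the bipartite divergent layout without traM/traJ (B),
#' the single operon with TraJ_V instead of traJ/finO (C), the single
#' operon with EntFR (D), and the two convergent operons with SphTR
#' immediately upstream of traD (E). Each archetype lists clusters in
#' genome order; genes within a minus-strand cluster are listed in genome
#' order too (transcription runs right to left).
#'
#' @return Named list of archetype objects (`group`, `host`, `architecture`,
#'   `clusters` = list of data frames with `gene` and `strand`).
#' @export
group_archetypes <- function() {
  cl <- function(genes, strand) data.frame(gene = genes, strand = strand,
                                           stringsAsFactors = FALSE)
  a_order <- c("TraM", "TraJ", "TraY", "TraA", "TraL", "TraE", "TraK",
               "TraB", "TraP", "TrbD", "TrbG", "TraV", "TraR", "TraC",
               "TrbI", "TraW", "TraU", "TrbC", "TraN", "TrbE", "TraF",
               "TrbA", "ArtA", "TraQ", "TrbB", "TrbJ", "TrbF", "TraH",
               "TraG", "TraS", "TraT", "TraD", "TrbH", "TraI", "TraX",
               "FinO")
  pilus_b <- c("TraA", "TraL", "TraE", "TraK", "TraB", "TraP", "TraR",
               "TraV", "TraC", "TrbI", "TraW", "TraU", "TrbC", "TraN",
               "TraF", "TraQ", "TrbB", "TraH", "TraG")
  c_order <- c("TraJ_V", setdiff(a_order, c("TraM", "TraJ", "TraY", "FinO")))
  d_order <- c("EntFR", "TraA", "TraL", "TraE", "TraK", "TraB", "TraV",
               "TraC", "TrbI", "TraW", "TraU", "TrbC", "TraN", "TraF",
               "TrbB", "TraH", "TraG", "TraD", "TraI", "TraX")
  pilus_e <- c("TraA", "TraL", "TraE", "TraK", "TraB", "TraV", "TraC",
               "TrbI", "TraW", "TraU", "TrbC", "TraN", "TraF", "TraH",
               "TraG")
  list(
    A = list(group = "A", host = "Escherichia coli",
             architecture = "single_operon",
             clusters = list(cl(a_order, "+"))),
    B = list(group = "B", host = "Yersinia pestis",
             architecture = "bipartite_divergent",
             # relaxosome cluster on minus strand, then pilus cluster on plus:
             # the two operons are transcribed away from each other
             clusters = list(cl(c("FinO", "TraX", "TraI", "TraD"), "-"),
                             cl(pilus_b, "+"))),
    C = list(group = "C", host = "Escherichia coli",
             architecture = "single_operon",
             clusters = list(cl(c_order, "+"))),
    D = list(group = "D", host = "Enterobacter sp.",
             architecture = "single_operon",
             clusters = list(cl(d_order, "+"))),
    E = list(group = "E", host = "Sphingomonas sp.",
             architecture = "split_convergent",
             # pilus operon on plus strand, relaxosome operon on minus
             # strand to its right: convergent transcription; on the minus
             # strand SphTR sits immediately upstream of traD
             clusters = list(cl(pilus_e, "+"),
                             cl(c("TraI", "TraD", "SphTR"), "-")))
  )
}

archetype_genes <- function(archetype) {
  unlist(lapply(archetype$clusters, `[[`, "gene"), use.names = FALSE)
}

#' Build one synthetic plasmid from an archetype
#'
#' Lays the archetype's gene clusters onto a genome with intergenic spacers
#' of 50-500 bp (clusters separated by gaps well beyond the operon-
#' clustering distance), using the supplied per-gene protein sequences.
#' Supported ablations: `drop` (remove genes), `shigella` (reduce to
#' traI/traX/finO, the deletion-derivative signature), `ablate_motifs`
#' (destroy the relaxase motifs), `truncate_relaxase` (cut the relaxase to
#' 120 aa).
#'
#' @param archetype One element of [group_archetypes()].
#' @param sequences Named character vector supplying a protein per gene of
#'   the archetype.
#' @param plasmid_id Record identifier.
#' @param seed Integer seed (spacer layout).
#' @param ablations List with optional elements `drop` (character),
#'   `shigella`, `ablate_motifs`, `truncate_relaxase` (logicals).
#' @return List: `record` ([plasmid_record()]) and `truth` (row-compatible
#'   list: expected group, flags, ablations applied).
#' @export
make_plasmid <- function(archetype, sequences, plasmid_id, seed,
                         ablations = list()) {
  genes <- archetype_genes(archetype)
  missing <- setdiff(genes, names(sequences))
  if (length(missing)) {
    stop("sequences missing for genes: ", paste(missing, collapse = ", "))
  }
  drop <- ablations$drop %||% character()
  bad_drop <- setdiff(drop, genes)
  if (length(bad_drop)) {
    stop("cannot drop genes absent from the archetype: ",
         paste(bad_drop, collapse = ", "))
  }
  expected_group <- archetype$group
  expected_flags <- character()

  if (isTRUE(ablations$shigella)) {
    sig <- c("TraI", "TraX", "FinO")
    if (!all(sig %in% genes)) {
      stop("shigella ablation requires an archetype carrying traI/traX/finO")
    }
    keep <- intersect(genes, sig)
    drop <- setdiff(genes, keep)
    expected_group <- "unassigned"
    expected_flags <- c(expected_flags, "deletion_derivative", "incomplete_mpf")
  }
  if ("FinO" %in% drop && archetype$group == "A" &&
      !isTRUE(ablations$shigella)) {
    expected_flags <- c(expected_flags, "derepressed_finO_minus")
  }
  if (isTRUE(ablations$ablate_motifs)) {
    sequences[["TraI"]] <- ablate_motifs(sequences[["TraI"]])
  }
  if (isTRUE(ablations$truncate_relaxase)) {
    sequences[["TraI"]] <- substr(sequences[["TraI"]], 1, 120)
    expected_flags <- c(expected_flags, "truncated_relaxase")
  }

  feats <- list()
  pos <- 200L
  with_seed(sub_seed(seed, 7), {
    for (ci in seq_along(archetype$clusters)) {
      cluster <- archetype$clusters[[ci]]
      if (ci > 1) pos <- pos + sample(6000:9000, 1)
      for (gi in seq_len(nrow(cluster))) {
        g <- cluster$gene[gi]
        if (g %in% drop) next
        aa <- sequences[[g]]
        ntlen <- 3L * nchar(aa) + 3L
        feats[[length(feats) + 1L]] <-
          gene_feature(tolower_gene(g), pos, pos + ntlen, cluster$strand[gi],
                       aa)
        pos <- pos + ntlen + sample(50:500, 1)
      }
    }
  })
  if (!length(feats)) stop("ablations removed every gene of the archetype")
  record <- plasmid_record(plasmid_id, feats, length_bp = pos + 200L,
                           host_taxon = archetype$host)
  truth <- list(plasmid_id = plasmid_id, group = archetype$group,
                expected_group = expected_group,
                expected_flags = expected_flags,
                ablations = ablations, seed = seed)
  list(record = record, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation-style labels: traM, trbC, finO, artA, but TraJ_V-style markers
# keep their capitalisation quirk
tolower_gene <- function(g) {
  if (g %in% marker_gene_names()) return(g)
  paste0(tolower(substr(g, 1, 1)), substr(g, 2, nchar(g)))
}

#' Destroy the diagnostic relaxase motifs in a sequence
#'
#' Replaces the first residue of every (D/E)NYY and D(L/F)TF occurrence with
#' glycine until no hit remains; the replacement residue cannot take part in
#' either motif, so no new hit can be created.
#'
#' @param seq Protein sequence.
#' @param patterns Motif patterns (default [default_motifs()]).
#' @return Sequence without motif hits.
#' @export
ablate_motifs <- function(seq, patterns = default_motifs()) {
  repeat {
    hits <- scan_motifs(seq, patterns)
    if (!nrow(hits)) return(seq)
    at <- hits$offset[1] + 1L
    substr(seq, at, at) <- "G"
  }
}

#' Generate a full ground-truth dataset
#'
#' Emits `5 * n_per_group` synthetic plasmids (plus optional unrelated
#' decoys) with two-tier relaxase divergence: each group descends from its
#' own relaxase ancestor (evolved from the reference relaxase at
#' `between_identity`, motifs protected), and each plasmid's relaxase
#' diverges from that ancestor at a within-group identity drawn from
#' `identity_range`. All other genes diverge directly from their reference
#' panel entry at the same per-plasmid identity, which is therefore the
#' identity the profiler measures. By default one group-A plasmid loses
#' finO (the derepressed, F-like exception) and one is reduced to the
#' traI/traX/finO deletion signature.
#'
#' @param n_per_group Plasmids per group (>= 1).
#' @param identity_range Within-group identity range, drawn uniformly per
#'   plasmid (default `c(0.6, 0.9)`).
#' @param seed Integer master seed; all output is a pure function of it.
#' @param between_identity Identity of each group's relaxase ancestor to the
#'   reference relaxase (default 0.5, the between-group tier).
#' @param n_derepressed,n_deletion Number of group-A plasmids given the
#'   finO-loss / deletion-derivative ablation (defaults 1 and 1; capped so
#'   at least one intact group-A plasmid remains when `n_per_group >= 3`).
#' @param n_decoys Unrelated decoy plasmids with random proteins
#'   (default 0).
#' @param scheme A [scoring_scheme()].
#' @return List: `records`, `truths` (data frame), `panel_obj`
#'   (from [make_reference_panel()]), `typing_panel` (group relaxase
#'   ancestors + reference), `manifest` (all parameters).
#' @export
make_dataset <- function(n_per_group = 10, identity_range = c(0.6, 0.9),
                         seed = 1, between_identity = 0.5,
                         n_derepressed = 1, n_deletion = 1, n_decoys = 0,
                         scheme = scoring_scheme()) {
  stopifnot(n_per_group >= 1, length(identity_range) == 2,
            identity_range[1] > 0, identity_range[2] <= 1,
            identity_range[1] <= identity_range[2])
  panel_obj <- make_reference_panel(seed, scheme)
  motifs_protected <- unlist(panel_obj$motif_positions)
  archetypes <- group_archetypes()

  # per-group relaxase ancestors: the between-group divergence tier
  ancestors <- lapply(seq_along(archetypes), function(gi) {
    evolve(panel_obj$panel[["TraI"]], between_identity,
           sub_seed(seed, 100 + gi), protected = motifs_protected,
           scheme = scheme)
  })
  names(ancestors) <- names(archetypes)
  typing_panel <- c(TraI_ref = unname(panel_obj$panel[["TraI"]]),
                    setNames(vapply(ancestors, as.character, ""),
                             paste0("TraI_anc", names(archetypes))))

  all_refs <- panel_obj$profile_panel
  records <- list()
  truths <- list()
  pidx <- 0L
  for (gi in seq_along(archetypes)) {
    arch <- archetypes[[gi]]
    g <- arch$group
    for (i in seq_len(n_per_group)) {
      pidx <- pidx + 1L
      pseed <- sub_seed(seed, 10000 + 200 * gi + i)
      w <- with_seed(pseed, runif(1, identity_range[1], identity_range[2]))
      genes <- archetype_genes(arch)
      seqs <- character()
      for (k in seq_along(genes)) {
        gname <- genes[k]
        src <- if (gname == "TraI") ancestors[[g]] else all_refs[[gname]]
        prot <- if (gname == "TraI") motifs_protected else integer()
        seqs[gname] <- evolve(as.character(src), w,
                              sub_seed(pseed, 20 + k), protected = prot,
                              scheme = scheme)
      }
      ablations <- list()
      if (g == "A" && i <= n_derepressed) {
        ablations <- list(drop = "FinO")
      } else if (g == "A" && i <= n_derepressed + n_deletion) {
        ablations <- list(shigella = TRUE)
      }
      built <- make_plasmid(arch, seqs, sprintf("p%s%03d", g, i),
                            sub_seed(pseed, 3), ablations)
      records[[pidx]] <- built$record
      truths[[pidx]] <- data.frame(
        plasmid_id = built$truth$plasmid_id, group = g,
        expected_group = built$truth$expected_group,
        expected_flags = paste(built$truth$expected_flags, collapse = ";"),
        target_identity = w, host = arch$host,
        ablations = paste(names(ablations), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (n_decoys > 0) {
    for (i in seq_len(n_decoys)) {
      pidx <- pidx + 1L
      feats <- with_seed(sub_seed(seed, 90000 + i), {
        lens <- sample(80:400, 8, replace = TRUE)
        pos <- 200L
        fs <- list()
        for (k in seq_along(lens)) {
          aa <- random_protein(lens[k])
          ntlen <- 3L * nchar(aa) + 3L
          fs[[k]] <- gene_feature(sprintf("orf%02d", k), pos, pos + ntlen,
                                  "+", aa)
          pos <- pos + ntlen + sample(50:500, 1)
        }
        fs
      })
      rec <- plasmid_record(sprintf("pX%03d", i), feats,
                            host_taxon = "Vibrio sp.")
      records[[pidx]] <- rec
      truths[[pidx]] <- data.frame(
        plasmid_id = rec$plasmid_id, group = "decoy",
        expected_group = "unassigned", expected_flags = "",
        target_identity = NA_real_, host = "Vibrio sp.", ablations = "",
        stringsAsFactors = FALSE)
    }
  }
  list(records = records,
       truths = do.call(rbind, truths),
       panel_obj = panel_obj,
       typing_panel = typing_panel,
       manifest = list(n_per_group = n_per_group,
                       identity_range = identity_range,
                       between_identity = between_identity,
                       n_derepressed = n_derepressed,
                       n_deletion = n_deletion,
                       n_decoys = n_decoys, seed = seed))
}
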