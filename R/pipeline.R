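# End-to-end orchestration: parse -> find operons -> detect arrays ->
# extract junctions -> classify -> per-group profiles -> protein/repeat
# trees -> clade cutting -> concordance -> dataset statistics, with
# per-locus drop accounting.

#' Pipeline configuration
#'
#' Collects the tunables of all stages with their defaults.
#'
#' @param window_nt Leader/array search window downstream of csn2 (nt).
#'   The first repeat must start inside this window.
#' @param refine_nt Extent (nt, >= `window_nt`) of the wider window used
#'   to refine array boundaries against the full genomic array, mirroring
#'   manual validation of repeat length against the whole array. Set equal
#'   to `window_nt` to disable refinement.
#' @param array [array_params()] for the repeat detector.
#' @param synonyms Cas synonym table, see [cas_synonyms()].
#' @param max_operon_span Operon clustering span limit (nt).
#' @param scheme [scoring_scheme()] for junction DNA alignment.
#' @param kmer_protein,kmer_dna K-mer sizes for protein and repeat
#'   distance matrices.
#' @param classify_tolerance Mismatch tolerance for motif classification.
#' @param classify_mode `"motif"` (parameter-free, per-locus motif match)
#'   or `"clade"` (group = majority motif group of the locus's Cas1 tree
#'   clade, the procedure used to derive the original groups).
#' @param clade_k Clades to cut per tree.
#' @param consensus_threshold IUPAC consensus threshold.
#' @param pseudocount Profile pseudocount.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_nt = 400, refine_nt = 1200,
                            array = array_params(),
                            synonyms = cas_synonyms(),
                            max_operon_span = 15000,
                            scheme = scoring_scheme(),
                            kmer_protein = 4, kmer_dna = 6,
                            classify_tolerance = 0,
                            classify_mode = c("motif", "clade"),
                            clade_k = 4,
                            consensus_threshold = 0.9,
                            pseudocount = 0) {
  classify_mode <- match.arg(classify_mode)
  if (refine_nt < window_nt) stop("refine_nt must be >= window_nt")
  structure(list(window_nt = window_nt, refine_nt = refine_nt,
                 array = array, synonyms = synonyms,
                 max_operon_span = max_operon_span, scheme = scheme,
                 kmer_protein = kmer_protein, kmer_dna = kmer_dna,
                 classify_tolerance = classify_tolerance,
                 classify_mode = classify_mode, clade_k = clade_k,
                 consensus_threshold = consensus_threshold,
                 pseudocount = pseudocount),
            class = "pipeline_config")
}

as_records <- function(inputs) {
  if (inherits(inputs, "genome_record")) return(list(inputs))
  if (is.character(inputs))
    return(unlist(lapply(inputs, parse_genome_record), recursive = FALSE))
  if (is.list(inputs) && all(vapply(inputs, inherits, TRUE, "genome_record")))
    return(inputs)
  stop("inputs must be genome records or file paths")
}

#' Run the full type II-A locus analysis pipeline
#'
#' @param inputs Genome records (list of [genome_record()]) or paths to
#'   GenBank files.
#' @param config A [pipeline_config()].
#' @param genus_map Optional named vector locus_id -> genus for the
#'   genera-per-group statistics (pass the truth table's mapping for
#'   synthetic data).
#' @return An object of class `crispr_report`: tables `loci`, `junctions`,
#'   `assignments`, `drops`, `cluster_drops`; per-group `profiles`
#'   (profile, information content, IUPAC consensus); `trees`, `clades`
#'   and `concordance` per Cas protein and for the first repeat; `stats`
#'   (a [dataset_statistics()] result); and the `config` used.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         genus_map = NULL) {
  records <- as_records(inputs)

  loci <- list(); junctions <- list(); drops <- list()
  cluster_drops <- list(); proteins <- list()
  n_candidate_operons <- 0L

  for (rec in records) {
    hits <- find_cas_genes(rec, config$synonyms)
    operons <- assemble_type_iia_operons(hits, record_id = rec$record_id,
                                         max_operon_span = config$max_operon_span,
                                         on_duplicate = "drop")
    cd <- attr(operons, "drops")
    if (nrow(cd)) cluster_drops[[length(cluster_drops) + 1L]] <- cd
    for (op in operons) {
      n_candidate_operons <- n_candidate_operons + 1L
      drop <- function(reason) {
        drops[[length(drops) + 1L]] <<- data.frame(
          locus_id = op$locus_id, record_id = rec$record_id,
          reason = reason, stringsAsFactors = FALSE)
      }
      win <- tryCatch(leader_search_window(op, rec, config$window_nt),
                      error = function(e) NULL)
      if (is.null(win)) { drop("degenerate_window"); next }
      # refinement window: same anchor, extended in transcription
      # direction so the whole genomic array can vote on boundaries
      rwin <- tryCatch(leader_search_window(op, rec, config$refine_nt),
                       error = function(e) win)
      rseq <- oriented_subsequence(rec, rwin)
      arrays <- detect_crispr_array(rseq, config$array)
      # the first repeat must start inside the csn2-proximal search window
      arrays <- Filter(function(a) a$repeat_starts[1] < config$window_nt,
                       arrays)
      if (!length(arrays)) { drop("no_array"); next }
      array <- arrays[[1]]  # nearest the csn2-proximal window edge
      jn <- tryCatch(extract_leader_junction(rseq, array, op$locus_id),
                     error = function(e) NULL)
      if (is.null(jn)) { drop("empty_leader"); next }

      hit_tab <- op$hits
      gene_cols <- unlist(lapply(CAS_ROLES, function(role) {
        row <- hit_tab[hit_tab$role == role, , drop = FALSE]
        setNames(c(row$start, row$end), paste0(role, c("_start", "_end")))
      }))
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = op$locus_id, record_id = rec$record_id,
        operon_start = op$span[["start"]], operon_end = op$span[["end"]],
        orientation = op$orientation,
        window_start = win$start, window_end = win$end,
        t(gene_cols),
        array_copies = array$copies,
        repeat_length = array$repeat_unit_length,
        stringsAsFactors = FALSE)
      junctions[[length(junctions) + 1L]] <- data.frame(
        locus_id = op$locus_id, leader20 = jn$leader20,
        leader_end7 = jn$leader_end7,
        junction_leader3 = jn$junction_leader3,
        first_repeat = jn$first_repeat,
        junction_repeat4 = jn$junction_repeat4,
        repeat_length = jn$repeat_length,
        truncated = jn$truncated, stringsAsFactors = FALSE)
      prot <- setNames(hit_tab$protein[match(CAS_ROLES, hit_tab$role)],
                       CAS_ROLES)
      proteins[[op$locus_id]] <- prot
    }
  }

  bind_or_empty <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  loci <- bind_or_empty(loci, data.frame(locus_id = character(0)))
  junctions <- bind_or_empty(junctions, data.frame(locus_id = character(0)))
  drops <- bind_or_empty(drops, data.frame(locus_id = character(0),
                                           record_id = character(0),
                                           reason = character(0)))
  cluster_drops <- bind_or_empty(cluster_drops,
                                 data.frame(record_id = character(0),
                                            start = integer(0),
                                            end = integer(0),
                                            reason = character(0)))
  rownames(loci) <- rownames(junctions) <- NULL

  report <- list(loci = loci, junctions = junctions, drops = drops,
                 cluster_drops = cluster_drops,
                 n_candidate_operons = n_candidate_operons,
                 config = config)
  class(report) <- "crispr_report"
  if (!nrow(junctions)) {
    report$assignments <- data.frame(locus_id = character(0),
                                     group = character(0))
    report$stats <- NULL
    return(report)
  }

  # motif-mode classification
  assignments <- do.call(rbind, lapply(seq_len(nrow(junctions)), function(i)
    classify_leader_end(junctions$leader_end7[i],
                        tolerance = config$classify_tolerance,
                        locus_id = junctions$locus_id[i])))

  # per-group alignment, profile, consensus
  group_profiles <- list()
  for (g in unique(assignments$group)) {
    ids <- assignments$locus_id[assignments$group == g]
    idx <- match(ids, junctions$locus_id)
    seqs <- setNames(paste0(junctions$leader20[idx],
                            junctions$first_repeat[idx]), ids)
    msa <- progressive_msa(seqs, config$scheme)
    prof <- build_profile(msa, pseudocount = config$pseudocount)
    group_profiles[[g]] <- list(
      msa = msa, profile = prof,
      info_bits = information_content(prof, small_sample_correction = FALSE),
      consensus = iupac_consensus(prof, config$consensus_threshold))
  }

  # trees: one per Cas protein (k-mer distances) plus the first repeat
  prot_mat <- do.call(rbind, proteins)
  trees <- list(); clades <- list(); concordance <- list()
  groups_vec <- setNames(assignments$group, assignments$locus_id)
  build_tree <- function(seqs, k) {
    seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
    if (length(seqs) < 2) return(NULL)
    neighbor_joining(kmer_distance_matrix(seqs, k))
  }
  for (role in CAS_ROLES) {
    tr <- build_tree(setNames(prot_mat[, role], rownames(prot_mat)),
                     config$kmer_protein)
    if (is.null(tr)) next
    trees[[role]] <- tr
    kk <- min(config$clade_k, length(tr$tip.label))
    clades[[role]] <- cut_tree_clades(tr, kk)
    concordance[[role]] <- clade_concordance(clades[[role]],
                                             groups_vec[names(clades[[role]])])
  }
  tr <- build_tree(setNames(junctions$first_repeat, junctions$locus_id),
                   config$kmer_dna)
  if (!is.null(tr)) {
    trees[["repeat"]] <- tr
    kk <- min(config$clade_k, length(tr$tip.label))
    clades[["repeat"]] <- cut_tree_clades(tr, kk)
    concordance[["repeat"]] <- clade_concordance(clades[["repeat"]],
                                                 groups_vec[names(clades[["repeat"]])])
  }

  # clade-mode assignment: majority motif group within each Cas1 clade
  clade_assignments <- assignments
  if (!is.null(clades[["cas1"]])) {
    cl <- clades[["cas1"]]
    for (ci in unique(cl)) {
      ids <- names(cl)[cl == ci]
      tab <- sort(table(groups_vec[ids]), decreasing = TRUE)
      maj <- sort(names(tab)[tab == tab[1]])[1]
      clade_assignments$group[clade_assignments$locus_id %in% ids] <- maj
    }
  }
  assignments$clade_group <- clade_assignments$group[
    match(assignments$locus_id, clade_assignments$locus_id)]

  used <- if (config$classify_mode == "clade") clade_assignments else assignments
  csn2_lengths <- setNames(nchar(prot_mat[, "csn2"]), rownames(prot_mat))
  stats <- dataset_statistics(junctions, used[, c("locus_id", "group",
                                                  "matched_motif",
                                                  "mismatches")],
                              genus_of = genus_map,
                              csn2_lengths = csn2_lengths,
                              clades = clades[["csn2"]])

  report$assignments <- assignments
  report$profiles <- group_profiles
  report$trees <- trees
  report$clades <- clades
  report$concordance <- concordance
  report$proteins <- prot_mat
  report$stats <- stats
  report
}

#' @export
print.crispr_report <- function(x, ...) {
  cat("<crispr_report>\n")
  cat(sprintf("  candidate operons: %d; loci reported: %d; dropped: %d\n",
              x$n_candidate_operons, nrow(x$junctions), nrow(x$drops)))
  if (nrow(x$drops))
    cat("  drop reasons:",
        paste(names(table(x$drops$reason)), table(x$drops$reason),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$stats)) print(x$stats)
  if (!is.null(x$concordance$cas1))
    cat(sprintf("  Cas1 clade/motif concordance: purity %.3f, ARI %.3f\n",
                x$concordance$cas1$purity, x$concordance$cas1$adjusted_rand))
  invisible(x)
}

stats_to_list <- function(stats) {
  if (is.null(stats)) return(NULL)
  list(n_loci = stats$n_loci,
       group_counts = as.list(stats$group_counts),
       genera_per_group = if (is.null(stats$genera_per_group)) NULL else
         as.list(stats$genera_per_group),
       n_genera = stats$n_genera,
       junction_gag_gttt_count = stats$junction_gag_gttt_count,
       repeat_length_mode = stats$repeat_length_mode,
       repeat_length_exceptions = stats$repeat_length_exceptions,
       count_missing_5prime_GTTT = stats$count_missing_5prime_GTTT,
       count_missing_3prime_C = stats$count_missing_3prime_C,
       csn2_mean_length_per_clade =
         if (is.null(stats$csn2_mean_length_per_clade)) NULL else
           as.list(stats$csn2_mean_length_per_clade))
}

#' Write a report bundle to a directory
#'
#' Emits the loci, junction, assignment and drop tables (TSV), per-locus
#' leader and repeat FASTA, per-role protein FASTA, Newick trees, PHYLIP
#' distance matrices, per-group profile matrices, and a JSON summary.
#' Deterministic: identical reports produce byte-identical bundles.
#'
#' @param report A `crispr_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) write.table(df, file.path(dir, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(report$loci, "loci.tsv")
  wt(report$junctions, "junctions.tsv")
  if (!is.null(report$assignments)) wt(report$assignments, "assignments.tsv")
  wt(report$drops, "drops.tsv")
  wt(report$cluster_drops, "cluster_drops.tsv")

  if (nrow(report$junctions)) {
    write_fasta(setNames(report$junctions$leader20,
                         report$junctions$locus_id),
                file.path(dir, "leader20.fasta"))
    write_fasta(setNames(report$junctions$first_repeat,
                         report$junctions$locus_id),
                file.path(dir, "first_repeat.fasta"))
  }
  if (!is.null(report$proteins)) {
    for (role in colnames(report$proteins)) {
      seqs <- setNames(report$proteins[, role], rownames(report$proteins))
      seqs <- seqs[!is.na(seqs)]
      if (length(seqs))
        write_fasta(seqs, file.path(dir, paste0(role, ".fasta")),
                    type = "protein")
    }
  }
  for (nm in names(report$trees))
    write_newick(report$trees[[nm]], file.path(dir, paste0(nm, ".nwk")))
  for (nm in names(report$profiles))
    write_profile_table(report$profiles[[nm]]$profile,
                        file.path(dir, paste0("profile_", nm, ".tsv")))

  summary <- list(
    n_candidate_operons = report$n_candidate_operons,
    n_loci = nrow(report$junctions),
    n_dropped = nrow(report$drops),
    stats = stats_to_list(report$stats),
    consensus = lapply(report$profiles, function(p)
      paste(p$consensus, collapse = "")),
    concordance = lapply(report$concordance, function(cc)
      list(purity = cc$purity, adjusted_rand = cc$adjusted_rand)))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
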