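# Seeded synthetic genomes with planted type II-A loci: a four-gene cas
# operon, an A/T-rich leader ending in a group-specific motif, and a
# repeat-spacer array, on either strand, with configurable mutation rates
# and decoy tandem repeats. Every pipeline stage is testable against the
# emitted truth table without any download.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults emulate the structure of a curated type II-A locus collection:
#' group proportions follow the 87/55/25 split over 167 loci, repeats are
#' 36 nt starting `GTTT` and ending `AAAC` (first base G, last base C),
#' spacers 30 nt, leaders 150 nt at 70% A/T, arrays of 12 repeat copies,
#' and Csn2 comes in a long (320 aa, ancestral) and short (224 aa) form.
#'
#' @param n_loci Number of planted loci (one contig each).
#' @param group_proportions Proportions of Groups 1, 2, 3 (sum to 1);
#'   allocated deterministically by largest remainder.
#' @param motif_mutation_rate Per-base substitution rate on the planted
#'   leader-end motif.
#' @param repeat_length Planted repeat unit length (nt).
#' @param repeat_mutation_rate Per-base substitution rate applied to each
#'   repeat copy independently.
#' @param n_repeat_copies Repeat copies per array (>= 2).
#' @param spacer_length Spacer length (nt).
#' @param leader_length Leader length (nt).
#' @param at_richness Fraction of A/T in leader sequence.
#' @param reverse_strand_fraction Probability a locus is planted on the
#'   reverse strand of its contig.
#' @param decoy_repeat_rate Probability a contig carries a decoy tandem
#'   repeat whose period lies outside CRISPR bounds.
#' @param csn2_long_fraction Fraction of Group 1 loci given the long
#'   (ancestral, ~320 aa) Csn2; the rest get the short form.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 30,
                       group_proportions = c(87, 55, 25) / 167,
                       motif_mutation_rate = 0,
                       repeat_length = 36,
                       repeat_mutation_rate = 0,
                       n_repeat_copies = 12,
                       spacer_length = 30,
                       leader_length = 150,
                       at_richness = 0.7,
                       reverse_strand_fraction = 0.5,
                       decoy_repeat_rate = 0.3,
                       csn2_long_fraction = 0.5,
                       seed = 1) {
  rates <- c(motif_mutation_rate, repeat_mutation_rate,
             reverse_strand_fraction, decoy_repeat_rate, csn2_long_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (abs(sum(group_proportions) - 1) > 1e-9)
    stop("group_proportions must sum to 1")
  if (length(group_proportions) != 3) stop("need proportions for 3 groups")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (leader_length < 7) stop("leader shorter than the 7-nt motif")
  if (repeat_length < 9) stop("repeat too short for GTTT...AAAC ends")
  if (n_repeat_copies < 2) stop("need at least 2 repeat copies")
  structure(as.list(environment())[c(
    "n_loci", "group_proportions", "motif_mutation_rate", "repeat_length",
    "repeat_mutation_rate", "n_repeat_copies", "spacer_length",
    "leader_length", "at_richness", "reverse_strand_fraction",
    "decoy_repeat_rate", "csn2_long_fraction", "seed")],
    class = "sim_config")
}

#' Substitute positions of a sequence at a fixed rate
#'
#' Each position is independently replaced by a uniformly chosen
#' *different* symbol with probability `rate`. Uses the current RNG
#' stream.
#'
#' @param seq Character scalar.
#' @param rate Substitution probability per position, in `[0, 1]`.
#' @param alphabet Symbol set (default DNA).
#' @return Mutated sequence.
#' @export
plant_mutations <- function(seq, rate, alphabet = DNA_ALPHABET) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (rate == 0 || !nzchar(seq)) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(ch) {
      others <- setdiff(alphabet, ch)
      others[sample.int(length(others), 1L)]
    }, "")
  }
  paste(v, collapse = "")
}

rand_dna <- function(n, at = 0.5) {
  if (n <= 0) return("")
  p <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), seq_along(props))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# protein = signature head + locus-specific middle + signature tail; the
# signatures (40% of length) are shared within a subgroup so k-mer
# distances cluster loci by subgroup.
make_signature_protein <- function(len, sig) {
  half <- nchar(sig) %/% 2
  mid <- len - nchar(sig)
  paste0(substr(sig, 1, half), rand_protein(mid),
         substr(sig, half + 1, nchar(sig)))
}

PROTEIN_LENGTHS <- c(cas9 = 1100L, cas1 = 290L, cas2 = 100L)
CSN2_LONG <- 320L
CSN2_SHORT <- 224L

#' Generate a seeded synthetic dataset of planted type II-A loci
#'
#' Each locus occupies its own contig: flanking sequence (optionally with
#' a decoy tandem repeat of non-CRISPR period), the cas9-cas1-cas2-csn2
#' operon with group-signature protein translations, an A/T-rich leader
#' ending in the group motif (Group 1 `ATTTGAG`; Group 2 `CTRCGAG` with R
#' drawn from A/G; Group 3 an A-rich tail ending `CG`), and the
#' repeat-spacer array. Loci land on the reverse strand with probability
#' `reverse_strand_fraction`. Group 1 splits into an ancestral subgroup
#' (long Csn2) and a derived one; all four proteins carry
#' subgroup-specific signature segments.
#'
#' @param config A [sim_config()].
#' @return List with `records` (list of [genome_record()]), `truth`
#'   (data frame: one row per planted locus with group, subgroup, genus,
#'   strand, planted junction strings, coordinates and protein lengths)
#'   and `config`.
#' @export
generate_synthetic_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  counts <- largest_remainder(config$n_loci, config$group_proportions)
  groups <- rep(c("Group1", "Group2", "Group3"), counts)

  n1 <- counts[1]
  n_long <- round(config$csn2_long_fraction * n1)
  subgroups <- character(config$n_loci)
  subgroups[groups == "Group1"] <- rep(c("1a", "1b"),
                                       c(n_long, n1 - n_long))
  subgroups[groups == "Group2"] <- "2"
  subgroups[groups == "Group3"] <- "3"

  # subgroup-level fixed material: protein signatures and repeat interiors
  sgs <- c("1a", "1b", "2", "3")
  sig_of <- list()
  for (sg in sgs) {
    csn2_len <- if (sg == "1a") CSN2_LONG else CSN2_SHORT
    lens <- c(PROTEIN_LENGTHS, csn2 = csn2_len)
    sig_of[[sg]] <- lapply(lens, function(L) rand_protein(round(0.4 * L)))
  }
  repeat_interior <- setNames(lapply(c("Group1", "Group2", "Group3"),
                                     function(g)
                                       rand_dna(config$repeat_length - 8L)),
                              c("Group1", "Group2", "Group3"))
  genus_pool <- list(Group1 = sprintf("GenusA%02d", 1:42),
                     Group2 = sprintf("GenusB%02d", 1:5),
                     Group3 = sprintf("GenusC%02d", 1:7))
  genus_counter <- c(Group1 = 0L, Group2 = 0L, Group3 = 0L)

  records <- vector("list", config$n_loci)
  truth <- vector("list", config$n_loci)
  for (i in seq_len(config$n_loci)) {
    g <- groups[i]
    sg <- subgroups[i]
    locus_id <- sprintf("locus_%03d", i)
    genus_counter[g] <- genus_counter[g] + 1L
    pool <- genus_pool[[g]]
    genus <- pool[(genus_counter[g] - 1L) %% length(pool) + 1L]

    csn2_len <- if (sg == "1a") CSN2_LONG else CSN2_SHORT
    prot_lens <- c(PROTEIN_LENGTHS, csn2 = csn2_len)
    proteins <- setNames(lapply(names(prot_lens), function(role)
      make_signature_protein(prot_lens[[role]], sig_of[[sg]][[role]])),
      names(prot_lens))

    # leader with planted 3' motif
    tail7 <- switch(g,
      Group1 = "ATTTGAG",
      Group2 = paste0("CT", sample(c("A", "G"), 1L), "CGAG"),
      Group3 = paste0(rand_dna(5L, at = 0.8), "CG"))
    tail7 <- plant_mutations(tail7, config$motif_mutation_rate)
    leader <- paste0(rand_dna(config$leader_length - 7L,
                              config$at_richness), tail7)

    base_repeat <- paste0("GTTT", repeat_interior[[g]], "AAAC")
    copies <- vapply(seq_len(config$n_repeat_copies), function(j)
      plant_mutations(base_repeat, config$repeat_mutation_rate), "")
    spacers <- vapply(seq_len(config$n_repeat_copies - 1L), function(j)
      rand_dna(config$spacer_length), "")
    array_seq <- paste0(paste0(copies[-length(copies)], spacers,
                               collapse = ""), copies[length(copies)])

    flank1 <- rand_dna(300L)
    if (runif(1) < config$decoy_repeat_rate) {
      unit <- rand_dna(12L)
      decoy <- strrep(unit, 6L)  # period 12, far below CRISPR bounds
      substr(flank1, 100L, 100L + nchar(decoy) - 1L) <- decoy
    }
    flank2 <- rand_dna(300L)

    gene_names <- c(
      cas9 = "type II-A CRISPR-associated endonuclease Cas9 (Csn1)",
      cas1 = "CRISPR-associated protein Cas1",
      cas2 = "CRISPR-associated protein Cas2",
      csn2 = "type II-A CRISPR-associated protein Csn2")

    pieces <- character(0)
    cursor <- 0L
    ann <- list()
    push <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      cursor <<- cursor + nchar(s)
    }
    push(flank1)
    # a non-cas gene so the annotation scan has something to ignore
    ann[[1]] <- data.frame(name = "hypothetical protein",
                           start = 30L, end = 90L, strand = "+",
                           protein = rand_protein(19L))
    for (role in names(prot_lens)) {
      gene_len <- 3L * prot_lens[[role]] + 3L
      ann[[length(ann) + 1L]] <- data.frame(
        name = gene_names[[role]], start = cursor, end = cursor + gene_len,
        strand = "+", protein = proteins[[role]])
      push(rand_dna(gene_len))
      if (role != "csn2") push(rand_dna(20L))
    }
    push(rand_dna(30L))          # csn2-leader intergenic gap
    leader_start <- cursor
    push(leader)
    array_start <- cursor
    push(array_seq)
    array_end <- cursor
    push(flank2)
    seqfwd <- paste(pieces, collapse = "")

    rec <- genome_record(locus_id, seqfwd, do.call(rbind, ann),
                         source = "synthetic")
    strand <- if (runif(1) < config$reverse_strand_fraction) "-" else "+"
    coords <- c(leader_start = leader_start, leader_end = array_start,
                array_start = array_start, array_end = array_end)
    if (strand == "-") {
      L <- nchar(seqfwd)
      rec <- revcomp_record(rec)
      coords <- c(leader_start = L - array_start,
                  leader_end = L - leader_start,
                  array_start = L - array_end,
                  array_end = L - array_start)
    }
    records[[i]] <- rec
    truth[[i]] <- data.frame(
      locus_id = locus_id, group = g, subgroup = sg, genus = genus,
      strand = strand,
      leader_end7 = tail7, first_repeat = copies[1],
      repeat_length = nchar(copies[1]),
      n_repeat_copies = config$n_repeat_copies,
      leader_start = coords["leader_start"],
      leader_end = coords["leader_end"],
      array_start = coords["array_start"],
      array_end = coords["array_end"],
      cas9_len = prot_lens[["cas9"]], cas1_len = prot_lens[["cas1"]],
      cas2_len = prot_lens[["cas2"]], csn2_len = prot_lens[["csn2"]],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(records = records, truth = truth, config = config)
}
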