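# Positional conservation profiles (the logo-matrix replacement), IUPAC
# consensus calling, leader-end motif group classification, and the
# whole-dataset summary statistics.

DNA_ALPHABET <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Build a positional conservation profile from an alignment
#'
#' Per-column symbol counts over non-gap symbols (plus an optional
#' pseudocount per symbol), normalized frequencies, and the per-column gap
#' fraction. Symbols outside the alphabet (e.g. `N` in DNA) are excluded
#' from counts and tracked in the `other_fraction`.
#'
#' @param msa An `msa` object from [progressive_msa()], or a character
#'   vector of equal-length (gapped) strings.
#' @param pseudocount Non-negative real added to every symbol count.
#' @param alphabet Symbol set; defaults to DNA `A/C/G/T`.
#' @return An object of class `conservation_profile` with matrices
#'   `counts` and `frequencies` (symbols x columns), vectors
#'   `gap_fraction`, `other_fraction`, and `n_rows`. Columns consisting
#'   only of gaps have `NA` frequencies and are flagged in `all_gap`.
#' @export
build_profile <- function(msa, pseudocount = 0, alphabet = DNA_ALPHABET) {
  rows <- if (inherits(msa, "msa")) unname(msa$rows) else as.character(msa)
  if (!length(rows)) stop("empty alignment")
  if (length(unique(nchar(rows))) != 1) stop("rows must have equal length")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  L <- ncol(mat)
  counts <- matrix(0, length(alphabet), L,
                   dimnames = list(alphabet, NULL))
  for (s in alphabet) counts[s, ] <- colSums(mat == s)
  gap_fraction <- colSums(mat == "-") / nrow(mat)
  other_fraction <- 1 - gap_fraction - colSums(counts) / nrow(mat)
  all_gap <- colSums(counts) == 0
  ccounts <- counts + pseudocount
  tot <- colSums(ccounts)
  freqs <- sweep(ccounts, 2, tot, "/")
  freqs[, all_gap & pseudocount == 0] <- NA_real_
  structure(list(alphabet = alphabet, counts = counts, frequencies = freqs,
                 gap_fraction = gap_fraction,
                 other_fraction = pmax(other_fraction, 0),
                 all_gap = all_gap, n_rows = nrow(mat)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns x alphabet {%s}, %d rows\n",
              ncol(x$counts), paste(x$alphabet, collapse = ""), x$n_rows))
  invisible(x)
}

#' Per-column information content of a profile
#'
#' `R = log2(|alphabet|) - H - e(n)` in bits, where `H` is the Shannon
#' entropy of the column frequencies and `e(n) = (|alphabet| - 1) /
#' (2 ln(2) n)` is the small-sample correction (applied per column over
#' its non-gap rows when enabled). Values are clamped at 0; all-gap
#' columns yield `NA`.
#'
#' @param profile A [build_profile()] result.
#' @param small_sample_correction Apply the correction term? Default off,
#'   giving the analytic 0/1/2-bit values for uniform, two-symbol-even and
#'   single-symbol DNA columns.
#' @return Numeric vector of bits per column, in `[0, log2(|alphabet|)]`.
#' @export
information_content <- function(profile, small_sample_correction = FALSE) {
  f <- profile$frequencies
  H <- apply(f, 2, function(p) {
    p <- p[!is.na(p) & p > 0]
    -sum(p * log2(p))
  })
  H[profile$all_gap] <- NA_real_
  e <- 0
  if (small_sample_correction) {
    ncol_rows <- round((1 - profile$gap_fraction - profile$other_fraction) *
                         profile$n_rows)
    e <- ifelse(ncol_rows > 0,
                (length(profile$alphabet) - 1) / (2 * log(2) * ncol_rows), 0)
  }
  pmax(log2(length(profile$alphabet)) - H - e, 0)
}

#' IUPAC degenerate consensus of a DNA profile
#'
#' Per column, bases are added in descending frequency (ties by
#' alphabetical order) until their cumulative frequency reaches
#' `threshold`; the smallest IUPAC symbol covering that base set is
#' emitted. All-gap columns emit `-`.
#'
#' @param profile A DNA [build_profile()] result.
#' @param threshold Cumulative frequency threshold in `(0, 1]`.
#' @return Degenerate DNA string, one symbol per column.
#' @export
iupac_consensus <- function(profile, threshold = 0.9) {
  if (!identical(profile$alphabet, DNA_ALPHABET))
    stop("IUPAC consensus requires a DNA profile")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sizes <- vapply(IUPAC_SETS, length, 0L)
  vapply(seq_len(ncol(profile$frequencies)), function(j) {
    if (profile$all_gap[j]) return("-")
    f <- profile$frequencies[, j]
    ord <- order(-f, names(f))
    cum <- cumsum(f[ord])
    need <- which(cum >= threshold - 1e-12)[1]
    if (is.na(need)) need <- length(f)
    bases <- sort(names(f)[ord][seq_len(need)])
    hit <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
      length(s) >= length(bases) && all(bases %in% s), TRUE)]
    hit[which.min(sizes[hit])]
  }, "")
}

GROUP_MOTIFS <- list(Group1 = "ATTTGAG", Group2 = "CTRCGAG")

motif_mismatches <- function(x, motif) {
  # mismatch count of string x against an IUPAC motif of the same length;
  # Inf when x is shorter than the motif
  if (nchar(x) < nchar(motif)) return(Inf)
  x <- substr(x, nchar(x) - nchar(motif) + 1, nchar(x))
  xs <- strsplit(x, "")[[1]]
  ms <- strsplit(motif, "")[[1]]
  sum(vapply(seq_along(ms), function(i)
    !(xs[i] %in% IUPAC_SETS[[ms[i]]]), TRUE))
}

#' Classify a locus by its 3' leader-end motif
#'
#' Precedence order: (1) the last 7 leader nucleotides match `ATTTGAG`
#' within `tolerance` mismatches (Group 1); (2) they match `CTRCGAG`
#' (`R` = A or G, not counted as a mismatch) within `tolerance` (Group 2);
#' (3) the last 2 nucleotides are `CG` (Group 3); otherwise unclassified.
#'
#' @param junction A `leader_junction` from [extract_leader_junction()],
#'   or a character scalar giving the leader 3' end (>= last 7 nt, or
#'   shorter for truncated leaders).
#' @param tolerance Maximum mismatches against the 7-nt motifs (default 0).
#' @param locus_id Used when `junction` is a bare string.
#' @return One-row data frame: `locus_id`, `group`, `matched_motif`,
#'   `mismatches`.
#' @export
classify_leader_end <- function(junction, tolerance = 0, locus_id = "locus") {
  if (inherits(junction, "leader_junction")) {
    leader_end <- junction$leader_end7
    locus_id <- junction$locus_id
  } else {
    leader_end <- toupper(as.character(junction))
  }
  res <- data.frame(locus_id = locus_id, group = "unclassified",
                    matched_motif = NA_character_, mismatches = NA_integer_,
                    stringsAsFactors = FALSE)
  if (is.na(leader_end) || !nzchar(leader_end)) return(res)
  for (g in names(GROUP_MOTIFS)) {
    mm <- motif_mismatches(leader_end, GROUP_MOTIFS[[g]])
    if (mm <= tolerance) {
      res$group <- g
      res$matched_motif <- GROUP_MOTIFS[[g]]
      res$mismatches <- as.integer(mm)
      return(res)
    }
  }
  if (nchar(leader_end) >= 2 &&
      substr(leader_end, nchar(leader_end) - 1, nchar(leader_end)) == "CG") {
    res$group <- "Group3"
    res$matched_motif <- "CG"
    res$mismatches <- 0L
  }
  res
}

mode_int <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Dataset-level summary statistics
#'
#' Aggregates, purely from its inputs: loci per motif group; distinct
#' genera per group; the count of Group 1 and Group 2 loci whose junction
#' reads `GAG`/`GTTT` (leader 3' trimer / repeat 5' tetramer); the modal
#' first-repeat length with its exceptions; how many first repeats lack
#' the 5' `GTTT` or the 3' `C`; and the mean Csn2 length per tree clade.
#'
#' @param junctions Data frame of junctions (one row per locus, as built
#'   by [run_pipeline()] or from [extract_leader_junction()] rows).
#' @param assignments Data frame from [classify_leader_end()] rows.
#' @param genus_of Optional named vector, locus_id -> genus.
#' @param csn2_lengths Optional named vector, locus_id -> Csn2 length (aa).
#' @param clades Optional named vector, locus_id -> clade index.
#' @return An object of class `dataset_stats`.
#' @export
dataset_statistics <- function(junctions, assignments, genus_of = NULL,
                               csn2_lengths = NULL, clades = NULL) {
  ids <- junctions$locus_id
  if (!setequal(ids, assignments$locus_id))
    stop("locus id sets of junctions and assignments differ: ",
         paste(union(setdiff(ids, assignments$locus_id),
                     setdiff(assignments$locus_id, ids)), collapse = ", "))
  check_ids <- function(v, what) {
    if (!is.null(v) && length(setdiff(ids, names(v))))
      stop("loci missing from ", what, ": ",
           paste(setdiff(ids, names(v)), collapse = ", "))
  }
  check_ids(genus_of, "genus_of"); check_ids(csn2_lengths, "csn2_lengths")
  check_ids(clades, "clades")
  assignments <- assignments[match(ids, assignments$locus_id), , drop = FALSE]

  grp <- assignments$group
  group_levels <- c("Group1", "Group2", "Group3", "unclassified")
  group_counts <- vapply(group_levels, function(g) sum(grp == g), 0L)

  genera_per_group <- NULL
  if (!is.null(genus_of))
    genera_per_group <- vapply(group_levels, function(g)
      length(unique(genus_of[ids[grp == g]])), 0L)

  g12 <- grp %in% c("Group1", "Group2")
  junction_gag_gttt_count <- sum(g12 &
                                   junctions$junction_leader3 == "GAG" &
                                   junctions$junction_repeat4 == "GTTT")

  rep_len <- nchar(junctions$first_repeat)
  repeat_length_mode <- mode_int(rep_len)
  exc <- rep_len != repeat_length_mode
  repeat_length_exceptions <- data.frame(locus_id = ids[exc],
                                         length = rep_len[exc],
                                         stringsAsFactors = FALSE)
  count_missing_5prime_GTTT <- sum(substr(junctions$first_repeat, 1, 4) != "GTTT")
  count_missing_3prime_C <- sum(substring(junctions$first_repeat,
                                          nchar(junctions$first_repeat)) != "C")

  csn2_mean_length_per_clade <- NULL
  if (!is.null(csn2_lengths) && !is.null(clades)) {
    cl <- clades[ids]
    m <- tapply(as.numeric(csn2_lengths[ids]), cl, mean)
    csn2_mean_length_per_clade <- setNames(as.numeric(m), names(m))
  }

  structure(list(n_loci = length(ids),
                 group_counts = group_counts,
                 genera_per_group = genera_per_group,
                 n_genera = if (is.null(genus_of)) NULL else
                   length(unique(genus_of[ids])),
                 junction_gag_gttt_count = junction_gag_gttt_count,
                 repeat_length_mode = repeat_length_mode,
                 repeat_length_exceptions = repeat_length_exceptions,
                 count_missing_5prime_GTTT = count_missing_5prime_GTTT,
                 count_missing_3prime_C = count_missing_3prime_C,
                 csn2_mean_length_per_clade = csn2_mean_length_per_clade),
            class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat("<dataset_stats>\n")
  cat("  loci:", x$n_loci, "\n")
  cat("  group counts:",
      paste(names(x$group_counts), x$group_counts, sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$genera_per_group))
    cat("  genera per group:",
        paste(names(x$genera_per_group), x$genera_per_group, sep = "=",
              collapse = ", "), "\n")
  cat("  GAG/GTTT junctions (Groups 1+2):", x$junction_gag_gttt_count, "\n")
  cat("  modal repeat length:", x$repeat_length_mode, "with",
      nrow(x$repeat_length_exceptions), "exception(s)\n")
  cat("  first repeats lacking 5' GTTT:", x$count_missing_5prime_GTTT,
      "; lacking 3' C:", x$count_missing_3prime_C, "\n")
  if (!is.null(x$csn2_mean_length_per_clade)) {
    cat("  mean Csn2 length per clade:",
        paste(names(x$csn2_mean_length_per_clade),
              round(x$csn2_mean_length_per_clade, 1), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a conservation profile as a tab-separated logo matrix
#'
#' Emits position, per-symbol counts and frequencies, gap fraction and
#' information content, consumable by standard logo-plotting tools.
#'
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @param small_sample_correction Passed to [information_content()]
#'   (default on for reports).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path, small_sample_correction = TRUE) {
  ic <- information_content(profile, small_sample_correction)
  tab <- data.frame(position = seq_len(ncol(profile$counts)))
  for (s in profile$alphabet) tab[[paste0("count_", s)]] <- profile$counts[s, ]
  for (s in profile$alphabet)
    tab[[paste0("freq_", s)]] <- round(profile$frequencies[s, ], 6)
  tab$gap_fraction <- round(profile$gap_fraction, 6)
  tab$info_bits <- round(ic, 6)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
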