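# Seed-and-extend CRISPR repeat-spacer array detection inside the leader
# search window, and extraction of the leader-repeat junction. All window
# coordinates are 0-based half-open in the window's own (transcription)
# orientation.

#' Detector settings for CRISPR array detection
#'
#' Repeat and spacer length bounds follow the canonical CRISPR unit range
#' (repeats ~24-50 nt, spacers of comparable size). `boundary_consensus`
#' is the minimum per-column majority-base frequency across repeat copies
#' for a column to be absorbed into the repeat during boundary extension;
#' at 1.0 extension requires unanimity and the detector reduces to exact
#' periodic substring matching.
#'
#' @param k Seed k-mer length.
#' @param min_repeat,max_repeat Repeat unit length bounds (nt).
#' @param min_spacer,max_spacer Spacer length bounds (nt).
#' @param min_copies Minimum repeat copies for a reportable array.
#' @param boundary_consensus Column majority threshold in (0, 1] used when
#'   extending repeat boundaries.
#' @param bridge_columns Number of consecutive below-threshold columns the
#'   extension may step across when the following column passes again
#'   (default 1). Bridging keeps a repeat from being split by one heavily
#'   mutated column; set 0 for strict extension, where a single failing
#'   column terminates the repeat (the natural companion of
#'   `boundary_consensus = 1`, under which a bridged column could never
#'   satisfy the unanimity the mode asserts). Bridging needs at least 3
#'   repeat copies: with 2 copies a disagreeing column carries no majority
#'   evidence, and bridging would let low-complexity sequence (e.g. the
#'   A/T-rich leader) masquerade as a two-copy repeat.
#' @param max_seed_occurrences Low-complexity guard: k-mers occurring more
#'   often than this in a window are not used as seeds.
#' @return A list of class `array_params`.
#' @export
array_params <- function(k = 8, min_repeat = 24, max_repeat = 50,
                         min_spacer = 20, max_spacer = 60, min_copies = 2,
                         boundary_consensus = 0.8, bridge_columns = 1,
                         max_seed_occurrences = 25) {
  stopifnot(k >= 4, min_repeat >= k, max_repeat >= min_repeat,
            min_spacer >= 1, max_spacer >= min_spacer, min_copies >= 2,
            boundary_consensus > 0, boundary_consensus <= 1,
            bridge_columns >= 0)
  k <- as.integer(k)
  min_repeat <- as.integer(min_repeat); max_repeat <- as.integer(max_repeat)
  min_spacer <- as.integer(min_spacer); max_spacer <- as.integer(max_spacer)
  min_copies <- as.integer(min_copies)
  structure(list(k = k, min_repeat = min_repeat, max_repeat = max_repeat,
                 min_spacer = min_spacer, max_spacer = max_spacer,
                 min_copies = min_copies,
                 boundary_consensus = boundary_consensus,
                 bridge_columns = as.integer(bridge_columns),
                 max_seed_occurrences = max_seed_occurrences),
            class = "array_params")
}

majority_frac <- function(bases) {
  tab <- table(bases)
  max(tab) / length(bases)
}

majority_base <- function(bases) {
  tab <- sort(table(bases), decreasing = TRUE)
  # alphabetical tie-break
  top <- names(tab)[tab == tab[1]]
  sort(top)[1]
}

#' Detect CRISPR repeat-spacer arrays in a sequence window
#'
#' Seed-and-extend tandem-repeat detection: (1) index all k-mers of the
#' window; (2) k-mers recurring at a period compatible with
#' repeat-plus-spacer bounds nucleate a candidate copy chain; (3) repeat
#' boundaries are extended left and right column-by-column while the
#' column's majority base frequency across copies stays at or above
#' `boundary_consensus` and the repeat stays within length bounds;
#' (4) overlapping candidates are merged keeping the one with more copies
#' (ties: longer repeat, then smaller start coordinate); (5) surviving
#' arrays must satisfy the copy-number and spacer-length bounds. Candidate
#' repeats containing `N` are rejected and counted in the `n_rejected`
#' attribute of the result.
#'
#' @param window_seq DNA string (the oriented search window).
#' @param params An [array_params()] list.
#' @return List of `crispr_array` objects sorted by start coordinate
#'   (possibly empty). Each has fields `repeat_unit_length`, `copies`,
#'   `period`, `repeat_starts` (0-based), `repeat_intervals`,
#'   `spacer_intervals`, `span`, `consensus_repeat`, `first_repeat`.
#' @export
detect_crispr_array <- function(window_seq, params = array_params()) {
  window_seq <- toupper(window_seq)
  chars <- strsplit(window_seq, "")[[1]]
  n <- length(chars)
  empty <- structure(list(), n_rejected = 0L)
  if (n < 2 * params$min_repeat + params$min_spacer) return(empty)
  k <- params$k
  p_min <- params$min_repeat + params$min_spacer
  p_max <- params$max_repeat + params$max_spacer

  starts <- 1:(n - k + 1)
  kmers <- substring(window_seq, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)
  pos_by_kmer <- pos_by_kmer[vapply(pos_by_kmer, length, 0L) >= 2]

  cands <- list()
  n_rejected <- 0L
  for (P in pos_by_kmer) {
    if (length(P) > params$max_seed_occurrences) next
    Pset <- P
    for (o in P) {
      periods <- unique(Pset[Pset > o] - o)
      periods <- periods[periods >= p_min & periods <= p_max]
      for (p in periods) {
        if ((o - p) %in% Pset) next  # not a chain start for this period
        anchors <- o
        while ((anchors[length(anchors)] + p) %in% Pset)
          anchors <- c(anchors, anchors[length(anchors)] + p)
        if (length(anchors) < 2) next
        cand <- extend_candidate(chars, n, anchors, p, k, params)
        if (!is.null(cand)) {
          if (cand$has_n) n_rejected <- n_rejected + 1L else
            cands[[length(cands) + 1L]] <- cand
        }
      }
    }
  }
  if (!length(cands)) return(structure(list(), n_rejected = n_rejected))

  # dedupe identical extended candidates
  keys <- vapply(cands, function(cc)
    paste(cc$start, cc$L, cc$copies, cc$period, sep = "_"), "")
  cands <- cands[!duplicated(keys)]

  # merge overlapping candidates: more copies > longer repeat > smaller start
  ord <- order(-vapply(cands, `[[`, 0L, "copies"),
               -vapply(cands, `[[`, 0L, "L"),
               vapply(cands, `[[`, 0L, "start"))
  cands <- cands[ord]
  kept <- list()
  for (cc in cands) {
    overlaps <- any(vapply(kept, function(kk)
      cc$start < kk$end && kk$start < cc$end, TRUE))
    if (!overlaps) kept[[length(kept) + 1L]] <- cc
  }
  kept <- kept[vapply(kept, `[[`, 0L, "copies") >= params$min_copies]
  kept <- kept[order(vapply(kept, `[[`, 0L, "start"))]

  out <- lapply(kept, function(cc) {
    rep_starts0 <- cc$rep_starts - 1L  # to 0-based
    rep_iv <- data.frame(start = rep_starts0, end = rep_starts0 + cc$L)
    sp_iv <- if (cc$copies > 1)
      data.frame(start = rep_iv$end[-cc$copies],
                 end = rep_iv$start[-1]) else
      data.frame(start = integer(0), end = integer(0))
    copy_seqs <- substring(window_seq, cc$rep_starts, cc$rep_starts + cc$L - 1L)
    cons <- paste(vapply(seq_len(cc$L), function(j)
      majority_base(substring(copy_seqs, j, j)), ""), collapse = "")
    structure(list(repeat_unit_length = cc$L,
                   copies = cc$copies,
                   period = cc$period,
                   repeat_starts = rep_starts0,
                   repeat_intervals = rep_iv,
                   spacer_intervals = sp_iv,
                   spacer_lengths = sp_iv$end - sp_iv$start,
                   span = c(start = rep_iv$start[1],
                            end = rep_iv$end[cc$copies]),
                   consensus_repeat = cons,
                   first_repeat = copy_seqs[1]),
              class = "crispr_array")
  })
  structure(out, n_rejected = n_rejected)
}

# Extend a seeded copy chain to full repeat boundaries. `anchors` are
# 1-based k-mer start positions; returns NULL for candidates that violate
# the length/spacer bounds.
extend_candidate <- function(chars, n, anchors, p, k, params) {
  c_n <- length(anchors)
  max_L <- min(params$max_repeat, p - params$min_spacer)
  if (max_L < params$min_repeat) return(NULL)
  ext_l <- 0L
  ext_r <- 0L
  passes <- function(offsets) {
    majority_frac(chars[offsets]) >= params$boundary_consensus
  }
  # leftwards; a failing column may be bridged when the column beyond it
  # passes again, so one mutated column does not split the repeat
  while (k + ext_l + ext_r < max_L && anchors[1] - ext_l - 1L >= 1L) {
    if (passes(anchors - ext_l - 1L)) { ext_l <- ext_l + 1L; next }
    bridged <- FALSE
    if (params$bridge_columns >= 1L && c_n >= 3L &&
        k + ext_l + ext_r + 2L <= max_L && anchors[1] - ext_l - 2L >= 1L &&
        passes(anchors - ext_l - 2L)) {
      ext_l <- ext_l + 2L
      bridged <- TRUE
    }
    if (!bridged) break
  }
  # rightwards
  while (k + ext_l + ext_r < max_L && anchors[c_n] + k + ext_r <= n) {
    if (passes(anchors + k + ext_r)) { ext_r <- ext_r + 1L; next }
    bridged <- FALSE
    if (params$bridge_columns >= 1L && c_n >= 3L &&
        k + ext_l + ext_r + 2L <= max_L && anchors[c_n] + k + ext_r + 1L <= n &&
        passes(anchors + k + ext_r + 1L)) {
      ext_r <- ext_r + 2L
      bridged <- TRUE
    }
    if (!bridged) break
  }
  L <- k + ext_l + ext_r
  if (L < params$min_repeat || L > params$max_repeat) return(NULL)
  spacer <- p - L
  if (spacer < params$min_spacer || spacer > params$max_spacer) return(NULL)
  rep_starts <- anchors - ext_l
  if (rep_starts[1] < 1L || rep_starts[c_n] + L - 1L > n) return(NULL)
  copy_idx <- unlist(lapply(rep_starts, function(s) s:(s + L - 1L)))
  list(rep_starts = rep_starts, L = L, copies = c_n, period = p,
       start = rep_starts[1], end = rep_starts[c_n] + L,
       has_n = any(chars[copy_idx] == "N"))
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf(
    "<crispr_array> %d copies x %d nt repeat (period %d), span [%d, %d)\n",
    x$copies, x$repeat_unit_length, x$period, x$span["start"], x$span["end"]))
  cat("  consensus:", x$consensus_repeat, "\n")
  invisible(x)
}

#' Extract the leader-repeat junction of a detected array
#'
#' The leader is the window sequence from the window start (the
#' csn2-proximal end, in transcription orientation) to the start of the
#' first repeat copy. The first repeat is taken verbatim from the genome
#' (not the array consensus), since genomic first repeats can differ from
#' database consensus repeats.
#'
#' @param window_seq The oriented window string the array was detected in.
#' @param array A `crispr_array` from [detect_crispr_array()].
#' @param locus_id Locus identifier carried into the result.
#' @return An object of class `leader_junction` with fields `locus_id`,
#'   `leader20` (last <= 20 nt of leader), `first_repeat`, `leader_end7`,
#'   `junction_leader3`, `junction_repeat4`, `repeat_length`, `truncated`.
#' @export
extract_leader_junction <- function(window_seq, array, locus_id = "locus") {
  window_seq <- toupper(window_seq)
  lead_len <- array$repeat_starts[1]
  if (lead_len <= 0)
    stop("locus '", locus_id, "': array abuts the window start, empty leader")
  leader <- substr(window_seq, 1L, lead_len)
  truncated <- lead_len < 20L
  leader20 <- substr(leader, max(1L, lead_len - 19L), lead_len)
  leader_end7 <- substr(leader, max(1L, lead_len - 6L), lead_len)
  first_repeat <- array$first_repeat
  structure(list(locus_id = locus_id,
                 leader20 = leader20,
                 first_repeat = first_repeat,
                 leader_end7 = leader_end7,
                 junction_leader3 = substr(leader, max(1L, lead_len - 2L),
                                           lead_len),
                 junction_repeat4 = substr(first_repeat, 1L, 4L),
                 repeat_length = nchar(first_repeat),
                 truncated = truncated),
            class = "leader_junction")
}

#' @export
print.leader_junction <- function(x, ...) {
  cat(sprintf("<leader_junction> %s: ...%s / %s...%s\n", x$locus_id,
              x$leader_end7, x$junction_repeat4,
              if (x$truncated) " (leader truncated)" else ""))
  invisible(x)
}
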