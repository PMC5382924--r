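# Mining of complete type II-A cas operons (cas9, cas1, cas2, csn2) from
# annotated genome records, locus orientation, and the leader/array search
# window downstream of csn2.

CAS_ROLES <- c("cas9", "cas1", "cas2", "csn2")

#' Default cas gene synonym table
#'
#' Maps each type II-A role to regular expressions matched
#' case-insensitively against annotation names. `Csn1` is a synonym of
#' Cas9. Patterns use word boundaries so e.g. `cas1` does not match
#' `cas13`. User-extensible: pass a modified copy to [find_cas_genes()].
#'
#' @return Named list of regex character vectors, one per role, in the
#'   fixed matching order cas9, cas1, cas2, csn2.
#' @export
cas_synonyms <- function() {
  list(cas9 = c("\\bcas9\\b", "\\bcsn1\\b"),
       cas1 = "\\bcas1\\b",
       cas2 = "\\bcas2\\b",
       csn2 = "\\bcsn2\\b")
}

#' Find cas gene annotations in a genome record
#'
#' Case-insensitive pattern match of annotation names against the synonym
#' table. Each annotation yields at most one hit: roles are tried in the
#' fixed order cas9, cas1, cas2, csn2 and the first match wins.
#'
#' @param record A [genome_record()].
#' @param synonyms Synonym table as from [cas_synonyms()].
#' @return Data frame of hits: `role`, `name`, `matched_synonym`, `start`,
#'   `end`, `strand`, `protein` (possibly zero rows).
#' @export
find_cas_genes <- function(record, synonyms = cas_synonyms()) {
  if (!length(synonyms)) stop("synonym table must be non-empty")
  ann <- record$annotations
  out <- data.frame(role = character(0), name = character(0),
                    matched_synonym = character(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    protein = character(0), stringsAsFactors = FALSE)
  if (!nrow(ann)) return(out)
  for (i in seq_len(nrow(ann))) {
    nm <- tolower(ann$name[i])
    for (role in intersect(CAS_ROLES, names(synonyms))) {
      pats <- synonyms[[role]]
      hit <- pats[vapply(pats, function(p) grepl(p, nm, perl = TRUE), TRUE)]
      if (length(hit)) {
        out <- rbind(out, data.frame(
          role = role, name = ann$name[i], matched_synonym = hit[1],
          start = ann$start[i], end = ann$end[i], strand = ann$strand[i],
          protein = ann$protein[i], stringsAsFactors = FALSE))
        break
      }
    }
  }
  out[order(out$start), , drop = FALSE]
}

new_operon <- function(locus_id, record_id, hits, orientation) {
  structure(list(locus_id = locus_id, record_id = record_id,
                 hits = hits,
                 span = c(start = min(hits$start), end = max(hits$end)),
                 orientation = orientation),
            class = "cas_operon")
}

#' @export
print.cas_operon <- function(x, ...) {
  cat(sprintf("<cas_operon> %s on %s: [%d, %d) orientation %s\n",
              x$locus_id, x$record_id, x$span["start"], x$span["end"],
              x$orientation))
  invisible(x)
}

#' Assemble complete type II-A operons from cas gene hits
#'
#' Hits are clustered greedily by genomic proximity (gap between
#' consecutive cas genes at most `max_operon_span / 4`). A cluster becomes
#' an operon only when it carries all four roles exactly once; its
#' orientation is the majority strand of the four genes. Clusters missing
#' a role, exceeding the span limit, or with a 2-2 strand tie are dropped
#' and reported in the `drops` attribute of the result; several complete
#' clusters on one record become independent loci.
#'
#' @param hits Data frame from [find_cas_genes()] (one genome record).
#' @param record_id Record the hits came from (used in locus ids).
#' @param max_operon_span Maximum operon span in nt (type II-A operons are
#'   compact; default 15000).
#' @param on_duplicate `"error"` (strict: a cluster with a duplicated role
#'   aborts with the duplicate coordinates) or `"drop"` (cluster is
#'   dropped with reason `"duplicate_role"`).
#' @return List of `cas_operon` objects with a `drops` attribute (data
#'   frame: cluster span, reason).
#' @export
assemble_type_iia_operons <- function(hits, record_id = "record",
                                      max_operon_span = 15000,
                                      on_duplicate = c("error", "drop")) {
  on_duplicate <- match.arg(on_duplicate)
  drops <- data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), reason = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hits))
    return(structure(list(), drops = drops))
  hits <- hits[order(hits$start), , drop = FALSE]
  gap_limit <- max_operon_span / 4
  cluster_id <- cumsum(c(1, (hits$start[-1] - hits$end[-nrow(hits)]) > gap_limit))
  operons <- list()
  for (cl in unique(cluster_id)) {
    sub <- hits[cluster_id == cl, , drop = FALSE]
    span <- c(min(sub$start), max(sub$end))
    drop_with <- function(reason) {
      drops <<- rbind(drops, data.frame(record_id = record_id,
                                        start = span[1], end = span[2],
                                        reason = reason,
                                        stringsAsFactors = FALSE))
    }
    counts <- table(factor(sub$role, levels = CAS_ROLES))
    if (any(counts > 1)) {
      dup <- names(counts)[counts > 1]
      msg <- paste0("ambiguous cluster on ", record_id, ": duplicated role(s) ",
                    paste(dup, collapse = ", "), " at ",
                    paste(sprintf("%s[%d,%d)", sub$role, sub$start, sub$end),
                          collapse = " "))
      if (on_duplicate == "error") stop(msg)
      drop_with("duplicate_role")
      next
    }
    if (any(counts == 0)) { drop_with("missing_role"); next }
    if (span[2] - span[1] > max_operon_span) { drop_with("span_exceeded"); next }
    n_plus <- sum(sub$strand == "+")
    if (n_plus == 2) {
      warning("orientation tie (2 vs 2 strands) on ", record_id,
              "; locus rejected")
      drop_with("orientation_tie")
      next
    }
    orientation <- if (n_plus > 2) "+" else "-"
    operons[[length(operons) + 1L]] <- new_operon(record_id, record_id, sub,
                                                  orientation)
  }
  # a record with a single complete operon keeps its own id as locus id;
  # multiple independent loci get a numbered suffix
  if (length(operons) > 1) {
    for (i in seq_along(operons))
      operons[[i]]$locus_id <- sprintf("%s_locus%02d",
                                       operons[[i]]$record_id, i)
  }
  structure(operons, drops = drops)
}

#' Leader/array search window downstream of csn2
#'
#' For a `+` locus: `[csn2_end, csn2_end + window_nt)` on `+`; for a `-`
#' locus: `[csn2_start - window_nt, csn2_start)` on `-`. The window is
#' clipped at the contig ends, in which case the result carries a
#' `truncated` attribute; a zero-length window (csn2 at the contig edge)
#' is an error.
#'
#' @param operon A `cas_operon`.
#' @param record The [genome_record()] the operon lives on.
#' @param window_nt Window length in nt (default 400, approximately one
#'   leader plus the first array repeats).
#' @return A [genomic_interval()] read in locus transcription direction,
#'   with attribute `truncated`.
#' @export
leader_search_window <- function(operon, record, window_nt = 400) {
  csn2 <- operon$hits[operon$hits$role == "csn2", , drop = FALSE]
  if (nrow(csn2) != 1) stop("operon ", operon$locus_id, " lacks a csn2 hit")
  n <- nchar(record$sequence)
  if (operon$orientation == "+") {
    start <- csn2$end
    end <- min(csn2$end + window_nt, n)
  } else {
    start <- max(0L, csn2$start - window_nt)
    end <- csn2$start
  }
  if (end <= start)
    stop("degenerate (zero-length) leader window for locus ",
         operon$locus_id, ": csn2 at contig edge")
  iv <- genomic_interval(start, end, operon$orientation)
  attr(iv, "truncated") <- (end - start) < window_nt
  iv
}
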