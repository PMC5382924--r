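#' @importFrom stats as.dist cophenetic hclust runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Internal coordinate convention, used everywhere in this package:
# 0-based, half-open [start, end) on the forward strand of a contig.
# GenBank / tabular annotation coordinates (1-based inclusive) are converted
# at the I/O boundary and nowhere else.

#' Construct a genomic interval
#'
#' A strand-aware, 0-based half-open interval on a single contig.
#'
#' @param start Integer >= 0, 0-based start (inclusive).
#' @param end Integer > `start`, 0-based end (exclusive).
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval(0, 36, "+")
#' @export
genomic_interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0 || end <= start)
    stop("invalid interval [", start, ", ", end, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("[%d, %d) strand %s (length %d)\n",
              x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

empty_annotations <- function() {
  data.frame(name = character(0), start = integer(0), end = integer(0),
             strand = character(0), protein = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' One contig's sequence plus its gene annotations. Annotations are kept
#' sorted by start coordinate and validated against the contig bounds.
#'
#' @param record_id Contig identifier.
#' @param sequence DNA string over `A`, `C`, `G`, `T`, `N` (upper-cased).
#' @param annotations Data frame with columns `name`, `start`, `end`,
#'   `strand`, `protein` (0-based half-open coordinates; `protein` is the
#'   translated product or `NA`).
#' @param source Free-text provenance (e.g. a file path).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(record_id, sequence, annotations = NULL,
                          source = NA_character_) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of '", record_id, "' contains non-ACGTN characters")
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- empty_annotations()
  } else {
    need <- c("name", "start", "end", "strand")
    if (!all(need %in% names(annotations)))
      stop("annotations need columns: ", paste(need, collapse = ", "))
    if (!"protein" %in% names(annotations))
      annotations$protein <- NA_character_
    annotations$start <- as.integer(annotations$start)
    annotations$end <- as.integer(annotations$end)
    bad <- annotations$start < 0 | annotations$end > nchar(sequence) |
      annotations$start >= annotations$end
    if (any(bad))
      stop("annotation out of bounds in '", record_id, "': ",
           paste(annotations$name[bad], collapse = ", "))
    if (!all(annotations$strand %in% c("+", "-")))
      stop("annotation strand must be '+' or '-'")
    annotations <- annotations[order(annotations$start, annotations$end), ,
                               drop = FALSE]
    rownames(annotations) <- NULL
  }
  structure(list(record_id = record_id, sequence = sequence,
                 annotations = annotations, source = source),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d annotations\n",
              x$record_id, nchar(x$sequence), nrow(x$annotations)))
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (may contain `N`).
#' @return Character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract a subsequence in transcription orientation
#'
#' Returns `sequence[start:end)` for a `+` interval and its reverse
#' complement for a `-` interval, so the result always reads 5' to 3' in
#' the orientation the interval declares.
#'
#' @param record A [genome_record()].
#' @param interval A [genomic_interval()].
#' @return DNA string.
#' @export
oriented_subsequence <- function(record, interval) {
  n <- nchar(record$sequence)
  if (interval$start < 0 || interval$end > n)
    stop("interval [", interval$start, ", ", interval$end,
         ") out of bounds for '", record$record_id, "' (", n, " bp)")
  s <- substr(record$sequence, interval$start + 1L, interval$end)
  if (interval$strand == "-") s <- dna_revcomp(s)
  s
}

#' Reverse-complement a whole genome record
#'
#' Mirrors the sequence and all annotation coordinates/strands; used to
#' check that locus calls are invariant to the strand a contig was
#' deposited on.
#'
#' @param record A [genome_record()].
#' @return A [genome_record()] on the opposite strand.
#' @export
revcomp_record <- function(record) {
  n <- nchar(record$sequence)
  ann <- record$annotations
  if (nrow(ann)) {
    new_start <- n - ann$end
    new_end <- n - ann$start
    ann$start <- new_start
    ann$end <- new_end
    ann$strand <- ifelse(ann$strand == "+", "-", "+")
  }
  genome_record(record$record_id, dna_revcomp(record$sequence), ann,
                source = record$source)
}

## ---- GenBank flat-file I/O (minimal: LOCUS / FEATURES CDS / ORIGIN) ----

parse_gb_location <- function(loc, feature_key) {
  loc <- gsub("[<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc))
    stop("malformed location '", loc, "' in feature ", feature_key)
  parts <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  # GenBank is 1-based inclusive; internal is 0-based half-open
  list(start = parts[1] - 1L, end = parts[2], strand = strand)
}

parse_gb_record <- function(lines, source) {
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus_line)) stop("GenBank record without LOCUS line in ", source)
  record_id <- strsplit(trimws(sub("^LOCUS", "", locus_line[1])), "\\s+")[[1]][1]

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank record '", record_id, "' has no ORIGIN")
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  ann <- empty_annotations()
  if (length(fstart)) {
    feat_lines <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # feature keys start at column 6; qualifiers/continuations at column 22
    key_idx <- grep("^ {5}\\S", feat_lines)
    for (i in seq_along(key_idx)) {
      from <- key_idx[i]
      to <- if (i < length(key_idx)) key_idx[i + 1] - 1L else length(feat_lines)
      block <- feat_lines[from:to]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (key != "CDS") next
      # location may wrap; collect until first qualifier line
      qual_at <- grep("^ +/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(trimws(sub("^ {5}\\S+", "", block[1])),
                   paste(trimws(block[seq_len(loc_end)[-1]]), collapse = ""),
                   sep = "")
      loc <- gsub("\\s", "", loc)
      pl <- parse_gb_location(loc, paste0("CDS #", i, " in ", record_id))
      quals <- parse_gb_qualifiers(block[seq.int(loc_end + 1L,
                                                 length.out = max(0L, length(block) - loc_end))])
      nm <- quals[["product"]]
      if (is.null(nm)) nm <- quals[["gene"]]
      if (is.null(nm)) nm <- "unnamed CDS"
      ann <- rbind(ann, data.frame(
        name = nm, start = pl$start, end = pl$end, strand = pl$strand,
        protein = if (is.null(quals[["translation"]])) NA_character_ else
          quals[["translation"]],
        stringsAsFactors = FALSE))
    }
  }
  genome_record(record_id, sequence, ann, source = source)
}

parse_gb_qualifiers <- function(lines) {
  quals <- list()
  cur_key <- NULL
  cur_val <- NULL
  flush <- function() {
    if (!is.null(cur_key)) quals[[cur_key]] <<- cur_val
  }
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (startsWith(t, "/")) {
      flush()
      if (grepl("=", t, fixed = TRUE)) {
        cur_key <- sub("^/([^=]+)=.*$", "\\1", t)
        cur_val <- sub("^/[^=]+=", "", t)
      } else {
        cur_key <- sub("^/", "", t)
        cur_val <- ""
      }
    } else if (!is.null(cur_key)) {
      # continuation line: translations concatenate without separator,
      # free-text qualifiers rejoin with a space
      sep <- if (identical(cur_key, "translation")) "" else " "
      cur_val <- paste(cur_val, t, sep = sep)
    }
  }
  flush()
  lapply(quals, function(v) gsub("\"", "", v))
}

#' Read genome records
#'
#' Parses annotated genomes either from a GenBank flat file (CDS features
#' with `/gene`, `/product` and `/translation` qualifiers) or from a plain
#' FASTA plus a 5-column tab-separated annotation table
#' (`record_id`, `start`, `end`, `strand`, `name`; 1-based inclusive
#' coordinates as in GFF). All coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path Path to the GenBank or FASTA file.
#' @param format `"genbank"` or `"fasta"`.
#' @param annotations_path For `format = "fasta"`: optional path to the
#'   annotation table; omit for records without annotations.
#' @return List of [genome_record()] objects, one per contig.
#' @export
parse_genome_record <- function(path, format = c("genbank", "fasta"),
                                annotations_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "genbank") {
    lines <- readLines(path, warn = FALSE)
    ends <- grep("^//\\s*$", lines)
    if (!length(ends)) ends <- length(lines)
    starts <- c(1L, head(ends, -1L) + 1L)
    recs <- list()
    for (i in seq_along(ends)) {
      chunk <- lines[starts[i]:ends[i]]
      if (!any(grepl("^LOCUS", chunk))) next
      recs[[length(recs) + 1L]] <- parse_gb_record(chunk, source = path)
    }
    if (!length(recs)) stop("no GenBank records found in ", path)
    recs
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    tab <- NULL
    if (!is.null(annotations_path)) {
      tab <- read.delim(annotations_path, header = TRUE,
                        stringsAsFactors = FALSE)
      need <- c("record_id", "start", "end", "strand", "name")
      if (!all(need %in% names(tab)))
        stop("annotation table needs columns: ", paste(need, collapse = ", "))
    }
    lapply(seq_along(seqs), function(i) {
      ann <- NULL
      if (!is.null(tab)) {
        sel <- tab[tab$record_id == ids[i], , drop = FALSE]
        if (nrow(sel)) {
          ann <- data.frame(name = sel$name,
                            start = as.integer(sel$start) - 1L,  # 1-based -> 0-based
                            end = as.integer(sel$end),
                            strand = sel$strand,
                            protein = if ("protein" %in% names(sel))
                              sel$protein else NA_character_,
                            stringsAsFactors = FALSE)
        }
      }
      genome_record(ids[i], as.character(seqs[[i]]), ann, source = path)
    })
  }
}

wrap_string <- function(x, width) {
  if (!nzchar(x)) return(character(0))
  starts <- seq(1L, nchar(x), by = width)
  substring(x, starts, pmin(starts + width - 1L, nchar(x)))
}

format_gb_record <- function(record) {
  out <- character(0)
  n <- nchar(record$sequence)
  out <- c(out, sprintf("LOCUS       %-17s %d bp    DNA     linear   UNK",
                        record$record_id, n))
  out <- c(out, sprintf("DEFINITION  %s.", record$record_id))
  out <- c(out, "FEATURES             Location/Qualifiers")
  out <- c(out, sprintf("     source          1..%d", n))
  ann <- record$annotations
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      loc <- sprintf("%d..%d", ann$start[i] + 1L, ann$end[i])  # back to 1-based
      if (ann$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out, sprintf("     CDS             %s", loc))
      out <- c(out, sprintf("                     /product=\"%s\"", ann$name[i]))
      if (!is.na(ann$protein[i]) && nzchar(ann$protein[i])) {
        tr <- wrap_string(paste0("/translation=\"", ann$protein[i], "\""), 58)
        out <- c(out, paste0(strrep(" ", 21), tr))
      }
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, n))
    blocks <- wrap_string(tolower(chunk), 10L)
    out <- c(out, sprintf("%9d %s", p, paste(blocks, collapse = " ")))
  }
  c(out, "//")
}

#' Write genome records
#'
#' Inverse of [parse_genome_record()]: emits either a GenBank-style flat
#' file or a FASTA plus the 5-column annotation table (1-based inclusive
#' coordinates). Round-tripping preserves sequences, coordinates, strands
#' and protein translations.
#'
#' @param records List of [genome_record()] objects (or a single one).
#' @param path Output file path (for `format = "fasta"` the annotation
#'   table is written next to it with extension `.annotations.tsv`).
#' @param format `"genbank"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_genome_record <- function(records, path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  if (inherits(records, "genome_record")) records <- list(records)
  if (format == "genbank") {
    lines <- unlist(lapply(records, format_gb_record))
    writeLines(lines, path)
  } else {
    seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "sequence"))
    names(seqs) <- vapply(records, `[[`, "", "record_id")
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    tabs <- lapply(records, function(r) {
      if (!nrow(r$annotations)) return(NULL)
      data.frame(record_id = r$record_id,
                 start = r$annotations$start + 1L,
                 end = r$annotations$end,
                 strand = r$annotations$strand,
                 name = r$annotations$name,
                 protein = r$annotations$protein,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab)) tab <- data.frame(record_id = character(0),
                                        start = integer(0), end = integer(0),
                                        strand = character(0),
                                        name = character(0),
                                        protein = character(0))
    write.table(tab, paste0(path, ".annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs Named character vector of DNA or protein sequences.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
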