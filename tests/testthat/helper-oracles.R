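# Independent oracles used by the unit and acceptance tests. These are
# deliberately written against different formulations than the package
# implementations they check.

# Brute-force periodic exact-substring oracle: enumerates (offset, period,
# copies) triples, takes the leading run of columns on which all copies
# agree exactly, applies the repeat/spacer bounds, and merges overlapping
# candidates by (more copies, longer repeat, smaller start). Matches the
# detector's semantics when boundary extension demands unanimity
# (boundary_consensus = 1).
oracle_periodic_arrays <- function(window, min_repeat = 24, max_repeat = 50,
                                   min_spacer = 20, max_spacer = 60,
                                   min_copies = 2) {
  ch <- strsplit(toupper(window), "")[[1]]
  n <- length(ch)
  cands <- list()
  for (p in (min_repeat + min_spacer):(max_repeat + max_spacer)) {
    if (p + min_repeat > n) break
    cap <- min(max_repeat, p - min_spacer)
    if (cap < min_repeat) next
    for (s in 1:(n - p)) {
      run_all <- Inf  # leading unanimous columns over copies seen so far
      cc <- 2
      repeat {
        last <- s + (cc - 1) * p
        if (last + min_repeat - 1 > n) break
        # leading equal run between copy cc-1 and copy cc
        a <- s + (cc - 2) * p
        r <- 0
        while (last + r <= n && ch[a + r] == ch[last + r]) r <- r + 1
        run_all <- min(run_all, r)
        L <- min(run_all, cap)
        spacer <- p - L
        if (L >= min_repeat && spacer >= min_spacer && spacer <= max_spacer &&
            cc >= min_copies) {
          cands[[length(cands) + 1L]] <- list(
            start = s - 1L, L = as.integer(L), copies = cc, period = p,
            end = s - 1L + (cc - 1L) * p + as.integer(L))
        }
        if (run_all < min_repeat) break
        cc <- cc + 1
      }
    }
  }
  if (!length(cands)) return(list())
  ord <- order(-vapply(cands, `[[`, 0, "copies"),
               -vapply(cands, `[[`, 0, "L"),
               vapply(cands, `[[`, 0, "start"))
  cands <- cands[ord]
  kept <- list()
  for (cc in cands) {
    if (!any(vapply(kept, function(k)
      cc$start < k$end && k$start < cc$end, TRUE)))
      kept[[length(kept) + 1L]] <- cc
  }
  kept[order(vapply(kept, `[[`, 0, "start"))]
}

# Exhaustive recursive alignment-score oracle with affine gaps (memoized
# recursion over consumed prefixes and the last move; convention: a gap
# run of length L costs gap_open + (L-1) * gap_extend).
oracle_align_score <- function(a, b, scheme) {
  av <- if (nzchar(a)) strsplit(a, "")[[1]] else character(0)
  bv <- if (nzchar(b)) strsplit(b, "")[[1]] else character(0)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    if (i == length(av) && j == length(bv)) return(0)
    key <- paste(i, j, last)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i < length(av) && j < length(bv)) {
      s <- if (av[i + 1] == bv[j + 1]) scheme$match else scheme$mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i < length(av))
      best <- max(best, (if (last == "X") ge else go) + rec(i + 1, j, "X"))
    if (j < length(bv))
      best <- max(best, (if (last == "Y") ge else go) + rec(i, j + 1, "Y"))
    memo[[key]] <- best
    best
  }
  rec(0, 0, "S")
}

# Sum-of-pairs score of a set of equal-length gapped rows under a scheme,
# scoring each gap run in each induced pairwise alignment affinely and
# ignoring gap-gap columns.
sum_of_pairs <- function(rows, scheme) {
  n <- length(rows)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(rows[[i]], "")[[1]]
    b <- strsplit(rows[[j]], "")[[1]]
    keep <- !(a == "-" & b == "-")
    a <- a[keep]; b <- b[keep]
    ingap_a <- FALSE; ingap_b <- FALSE
    for (k in seq_along(a)) {
      if (a[k] == "-") {
        total <- total + if (ingap_a) scheme$gap_extend else scheme$gap_open
        ingap_a <- TRUE; ingap_b <- FALSE
      } else if (b[k] == "-") {
        total <- total + if (ingap_b) scheme$gap_extend else scheme$gap_open
        ingap_b <- TRUE; ingap_a <- FALSE
      } else {
        total <- total + if (a[k] == b[k]) scheme$match else scheme$mismatch
        ingap_a <- FALSE; ingap_b <- FALSE
      }
    }
  }
  total
}

# Star alignment onto a chosen center: every other sequence is aligned
# pairwise to the (ungapped) center, and the centers' gap patterns are
# merged with "once a gap, always a gap" (max gap count per center slot).
star_alignment <- function(seqs, center, scheme) {
  m <- nchar(seqs[[center]])
  others <- setdiff(seq_along(seqs), center)
  parsed <- lapply(others, function(o) {
    al <- crisprleader::global_align(seqs[[center]], seqs[[o]], scheme)
    cc <- strsplit(al$a, "")[[1]]; oo <- strsplit(al$b, "")[[1]]
    slots <- vector("list", m + 1)  # other-row chars falling in center gaps
    main <- character(m)            # other-row char aligned to center pos
    pos <- 0L
    for (k in seq_along(cc)) {
      if (cc[k] == "-") slots[[pos + 1L]] <- c(slots[[pos + 1L]], oo[k])
      else { pos <- pos + 1L; main[pos] <- oo[k] }
    }
    list(slots = slots, main = main)
  })
  counts <- vapply(parsed, function(p) vapply(p$slots, length, 0L),
                   integer(m + 1))
  merged <- if (is.matrix(counts)) apply(counts, 1, max) else counts
  build <- function(main, slots) {
    out <- character(0)
    for (pos in 0:m) {
      sl <- slots[[pos + 1L]]
      out <- c(out, sl, rep("-", merged[pos + 1L] - length(sl)))
      if (pos < m) out <- c(out, main[pos + 1L])
    }
    paste(out, collapse = "")
  }
  center_row <- build(strsplit(seqs[[center]], "")[[1]],
                      vector("list", m + 1))
  rows <- c(list(center_row),
            lapply(parsed, function(p) build(p$main, p$slots)))
  unlist(rows)
}

# random DNA string helper for tests
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
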