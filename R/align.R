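# In-repo alignment machinery for short junction DNA: affine-gap global
# pairwise alignment (Gotoh) and a guide-tree progressive MSA. Cas proteins
# are deliberately compared alignment-free (k-mer set distances) instead of
# via large-scale protein MSA; the downstream claims depend on clustering,
# not on particular alignment columns.

#' Affine-gap scoring scheme
#'
#' Gap convention: a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend` (the opening column carries the open
#' penalty, each further column the extension penalty).
#'
#' @param match Score for an identical residue pair (must exceed `mismatch`).
#' @param mismatch Score for a non-identical pair. `N` matches only `N`.
#' @param gap_open Score of the first column of a gap run (<= 0).
#' @param gap_extend Score of each subsequent gap column (<= 0).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -4,
                           gap_extend = -1) {
  if (match <= mismatch) stop("match score must exceed mismatch score")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

#' Optimal global pairwise alignment (Needleman-Wunsch/Gotoh)
#'
#' Affine gap penalties, deterministic traceback with tie-break
#' diagonal > up (gap in `b`) > left (gap in `a`).
#'
#' @param a,b Sequences (character scalars) over a shared alphabet.
#' @param scheme A [scoring_scheme()].
#' @return List with elements `a`, `b` (gapped strings) and `score`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  av <- if (nzchar(a)) strsplit(a, "")[[1]] else character(0)
  bv <- if (nzchar(b)) strsplit(b, "")[[1]] else character(0)
  n <- length(av); m <- length(bv)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -1e18

  # M: ends in residue pair; X: ends with gap in b (consumes a);
  # Y: ends with gap in a (consumes b)
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- go + (0:(n - 1)) * ge
  if (m > 0) Y[1, 2:(m + 1)] <- go + (0:(m - 1)) * ge

  sub_score <- function(x, y) if (x == y) scheme$match else scheme$mismatch

  for (i in seq_len(n + 1)) {
    for (j in seq_len(m + 1)) {
      if (i == 1 && j == 1) next
      if (i > 1 && j > 1) {
        M[i, j] <- sub_score(av[i - 1], bv[j - 1]) +
          max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      }
      if (i > 1) {
        X[i, j] <- max(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      }
      if (j > 1) {
        Y[i, j] <- max(M[i, j - 1] + go, X[i, j - 1] + go, Y[i, j - 1] + ge)
      }
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  if (n == 0 && m == 0) score <- 0

  # traceback, tie-break diagonal > up > left (and M > X > Y within a cell)
  ra <- character(0); rb <- character(0)
  i <- n + 1; j <- m + 1
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  if (n == 0 && m == 0) state <- "M"
  tol <- 1e-9
  while (i > 1 || j > 1) {
    if (state == "M") {
      s <- sub_score(av[i - 1], bv[j - 1])
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- c("M", "X", "Y")[which(prev >= max(prev) - tol)[1]]
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cand <- c(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      state <- c("M", "X", "Y")[which(cand >= max(cand) - tol)[1]]
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      i <- i - 1
    } else {
      cand <- c(M[i, j - 1] + go, X[i, j - 1] + go, Y[i, j - 1] + ge)
      state <- c("M", "X", "Y")[which(cand >= max(cand) - tol)[1]]
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- "Y"
    if (j == 1 && i > 1) state <- "X"
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = score)
}

msa_object <- function(labels, rows) {
  stopifnot(length(labels) == length(rows))
  if (length(rows) && length(unique(nchar(rows))) != 1)
    stop("alignment rows must have equal length")
  structure(list(labels = labels, rows = setNames(rows, labels)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$rows),
              if (length(x$rows)) nchar(x$rows[[1]]) else 0L))
  for (i in seq_len(min(8L, length(x$rows))))
    cat(sprintf("  %-20s %s\n", x$labels[i], x$rows[[i]]))
  if (length(x$rows) > 8) cat("  ...\n")
  invisible(x)
}

# Profile-profile affine global alignment; a profile is a character matrix
# (rows = sequences, columns = alignment columns, '-' for gaps). The column
# pair score is the mean residue-pair score over all row pairs.
profile_align <- function(pa, pb, scheme) {
  n <- ncol(pa); m <- ncol(pb)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -1e18

  col_score <- function(ca, cb) {
    tot <- 0; cnt <- 0L
    for (x in ca) for (y in cb) {
      cnt <- cnt + 1L
      if (x == "-" && y == "-") next
      tot <- tot + if (x == "-" || y == "-") ge else
        if (x == y) scheme$match else scheme$mismatch
    }
    tot / cnt
  }
  S <- matrix(0, n, m)
  if (n && m) for (i in 1:n) for (j in 1:m) S[i, j] <- col_score(pa[, i], pb[, j])

  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n > 0) X[2:(n + 1), 1] <- go + (0:(n - 1)) * ge
  if (m > 0) Y[1, 2:(m + 1)] <- go + (0:(m - 1)) * ge
  for (i in seq_len(n + 1)) for (j in seq_len(m + 1)) {
    if (i == 1 && j == 1) next
    if (i > 1 && j > 1)
      M[i, j] <- S[i - 1, j - 1] + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                       Y[i - 1, j - 1])
    if (i > 1) X[i, j] <- max(M[i - 1, j] + go, X[i - 1, j] + ge,
                              Y[i - 1, j] + go)
    if (j > 1) Y[i, j] <- max(M[i, j - 1] + go, X[i, j - 1] + go,
                              Y[i, j - 1] + ge)
  }
  i <- n + 1; j <- m + 1
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  ops <- character(0)
  tol <- 1e-9
  while (i > 1 || j > 1) {
    if (state == "M") {
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- c("M", "X", "Y")[which(prev >= max(prev) - tol)[1]]
      ops <- c("D", ops); i <- i - 1; j <- j - 1
    } else if (state == "X") {
      cand <- c(M[i - 1, j] + go, X[i - 1, j] + ge, Y[i - 1, j] + go)
      state <- c("M", "X", "Y")[which(cand >= max(cand) - tol)[1]]
      ops <- c("U", ops); i <- i - 1
    } else {
      cand <- c(M[i, j - 1] + go, X[i, j - 1] + go, Y[i, j - 1] + ge)
      state <- c("M", "X", "Y")[which(cand >= max(cand) - tol)[1]]
      ops <- c("L", ops); j <- j - 1
    }
    if (i == 1 && j > 1) state <- "Y"
    if (j == 1 && i > 1) state <- "X"
  }
  # build merged profile
  ai <- 0L; bj <- 0L
  out <- matrix("", nrow = nrow(pa) + nrow(pb), ncol = length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "D") {
      ai <- ai + 1L; bj <- bj + 1L
      out[, k] <- c(pa[, ai], pb[, bj])
    } else if (ops[k] == "U") {
      ai <- ai + 1L
      out[, k] <- c(pa[, ai], rep("-", nrow(pb)))
    } else {
      bj <- bj + 1L
      out[, k] <- c(rep("-", nrow(pa)), pb[, bj])
    }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Short-sequence progressive aligner: pairwise identity distances from
#' [global_align()], a UPGMA guide tree, and profile-profile affine
#' alignment along the guide tree. Deterministic given input order. Rows
#' of the result ungap exactly to the input sequences.
#'
#' @param seqs Named character vector (>= 1 sequence).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `msa` (fields `labels`, `rows`).
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  if (!length(seqs)) stop("no sequences given")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  labels <- names(seqs)
  if (length(seqs) == 1) return(msa_object(labels, unname(seqs)))

  n <- length(seqs)
  if (n == 2) {
    al <- global_align(seqs[[1]], seqs[[2]], scheme)
    return(msa_object(labels, c(al$a, al$b)))
  }

  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    al <- global_align(seqs[[i]], seqs[[j]], scheme)
    ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
    ident <- sum(ca == cb & ca != "-") / length(ca)
    D[i, j] <- D[j, i] <- 1 - ident
  }
  hc <- hclust(as.dist(D), method = "average")

  profiles <- lapply(seqs, function(s)
    matrix(strsplit(s, "")[[1]], nrow = 1))
  members <- as.list(seq_len(n))
  merged_profiles <- vector("list", n - 1)
  merged_members <- vector("list", n - 1)
  getp <- function(id) if (id < 0) profiles[[-id]] else merged_profiles[[id]]
  getm <- function(id) if (id < 0) members[[-id]] else merged_members[[id]]
  for (k in seq_len(n - 1)) {
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    merged_profiles[[k]] <- profile_align(getp(a), getp(b), scheme)
    merged_members[[k]] <- c(getm(a), getm(b))
  }
  final <- merged_profiles[[n - 1]]
  ord <- merged_members[[n - 1]]
  rows <- apply(final, 1, paste, collapse = "")
  rows <- rows[order(ord)]  # restore input order
  msa_object(labels, rows)
}

#' Alignment-free k-mer set distance matrix
#'
#' `d(i, j) = 1 - |K_i` \eqn{\cap}{\intersect} `K_j| / min(|K_i|, |K_j|)` where
#' `K_s` is the set of distinct k-mers of sequence `s`. Symmetric, zero
#' diagonal, values in `[0, 1]`.
#'
#' @param seqs Named character vector; every sequence must be at least
#'   `k` long.
#' @param k K-mer length (default 4, suited to proteins; use ~6 for DNA).
#' @return Symmetric numeric matrix with `labels` as dimnames.
#' @export
kmer_distance_matrix <- function(seqs, k = 4) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  short <- nchar(seqs) < k
  if (any(short))
    stop("sequence(s) shorter than k=", k, ": ",
         paste(names(seqs)[short], collapse = ", "))
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 1 - length(intersect(sets[[i]], sets[[j]])) /
      min(length(sets[[i]]), length(sets[[j]]))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param D Symmetric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  labs <- rownames(D)
  lines <- c(sprintf("%5d", nrow(D)),
             vapply(seq_len(nrow(D)), function(i)
               paste0(sprintf("%-10s", substr(labs[i], 1, 10)),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), ""))
  writeLines(lines, path)
  invisible(path)
}
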