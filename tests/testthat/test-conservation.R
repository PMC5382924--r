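test_that("profile counts, frequencies and gap handling are column-wise", {
  prof <- build_profile(c("AAGA", "AAG-", "GAGA", "GAGA"))
  expect_equal(unname(prof$frequencies["A", 2]), 1.0)
  expect_equal(unname(prof$frequencies["A", 1]), 0.5)
  expect_equal(unname(prof$frequencies["G", 1]), 0.5)
  expect_equal(prof$gap_fraction[4], 0.25)
  expect_equal(sum(prof$frequencies[, 4]), 1)  # over non-gap rows

  all_gap <- build_profile(c("A-", "G-"))
  expect_true(all_gap$all_gap[2])
  expect_true(all(is.na(all_gap$frequencies[, 2])))
})

test_that("information content hits the analytic 0/1/2-bit values", {
  uniform <- build_profile(c("A", "C", "G", "T"))
  even2 <- build_profile(c("A", "A", "T", "T"))
  single <- build_profile(c("A", "A", "A", "A"))
  expect_equal(unname(information_content(uniform)), 0)
  expect_equal(unname(information_content(even2)), 1)
  expect_equal(unname(information_content(single)), 2)
})

test_that("information content stays in [0, 2] and correction only lowers it", {
  set.seed(44)
  for (trial in 1:10) {
    rows <- vapply(1:6, function(i) rand_seq(12), "")
    prof <- build_profile(rows)
    ic <- information_content(prof)
    expect_true(all(ic >= 0 & ic <= 2))
    icc <- information_content(prof, small_sample_correction = TRUE)
    expect_true(all(icc <= ic + 1e-12))
    # 2 bits iff single-symbol column
    mat <- do.call(rbind, strsplit(rows, ""))
    mono <- apply(mat, 2, function(col) length(unique(col)) == 1)
    expect_equal(unname(ic == 2), unname(mono))
  }
})

test_that("IUPAC consensus picks minimal degenerate symbols", {
  half <- build_profile(c("A", "A", "G", "G"))
  expect_equal(iupac_consensus(half, 0.9), "R")
  expect_equal(iupac_consensus(build_profile(c("A", "A")), 0.9), "A")
  expect_equal(iupac_consensus(build_profile(c("A", "C", "G", "T")), 0.9), "N")
  # threshold 1.0 over a single gap-free sequence returns the sequence
  one <- build_profile("GTTTCAGA")
  expect_equal(paste(iupac_consensus(one, 1.0), collapse = ""), "GTTTCAGA")
  gapcol <- build_profile(c("A-", "A-"))
  expect_equal(iupac_consensus(gapcol, 0.9)[2], "-")
})

test_that("leader ends classify into the three motif groups with precedence", {
  expect_equal(classify_leader_end("ATTTGAG")$group, "Group1")
  expect_equal(classify_leader_end("CTACGAG")$group, "Group2")
  expect_equal(classify_leader_end("CTGCGAG")$group, "Group2")
  expect_equal(classify_leader_end("TTAAAACG")$group, "Group3")
  expect_equal(classify_leader_end("TTTTTTT")$group, "unclassified")
  expect_equal(classify_leader_end("")$group, "unclassified")
  # classification is a pure function of the last 7 nt
  expect_equal(classify_leader_end("CCCCCCCCCCATTTGAG")$group, "Group1")
  # tolerance admits near-misses in precedence order
  expect_equal(classify_leader_end("ATTTGAT", tolerance = 1)$group, "Group1")
  expect_equal(classify_leader_end("ATTTGAT", tolerance = 0)$group,
               "unclassified")
  # the degenerate R position never counts as a mismatch
  expect_equal(classify_leader_end("CTGCGAG", tolerance = 0)$mismatches, 0)
  # truncated leaders shorter than 7 nt can still be Group 3
  expect_equal(classify_leader_end("ACG")$group, "Group3")
})

mk_junctions <- function(n_grp = c(5, 3, 2)) {
  ends <- c(rep("ATTTGAG", n_grp[1]), rep("CTACGAG", n_grp[2]),
            rep("AAAAACG", n_grp[3]))
  n <- sum(n_grp)
  reps <- rep(paste0("GTTT", strrep("A", 28), "AAAC"), n)
  data.frame(locus_id = sprintf("L%02d", 1:n),
             leader20 = paste0(strrep("T", 13), ends),
             leader_end7 = ends,
             junction_leader3 = substr(ends, 5, 7),
             first_repeat = reps,
             junction_repeat4 = "GTTT",
             repeat_length = nchar(reps),
             truncated = FALSE, stringsAsFactors = FALSE)
}

test_that("dataset statistics recover planted counts and exceptions", {
  jn <- mk_junctions()
  asg <- do.call(rbind, lapply(seq_len(nrow(jn)), function(i)
    classify_leader_end(jn$leader_end7[i], locus_id = jn$locus_id[i])))
  # plant one 35-nt repeat and one missing-GTTT repeat
  jn$first_repeat[3] <- substr(jn$first_repeat[3], 1, 35)
  jn$first_repeat[7] <- paste0("CTTT", substr(jn$first_repeat[7], 5, 36))
  jn$junction_repeat4[7] <- "CTTT"
  genus <- setNames(rep(c("gA", "gB"), length.out = nrow(jn)), jn$locus_id)
  csn2 <- setNames(rep(c(320, 224), length.out = nrow(jn)), jn$locus_id)
  clades <- setNames(rep(c(1L, 2L), length.out = nrow(jn)), jn$locus_id)
  st <- dataset_statistics(jn, asg, genus, csn2, clades)
  expect_equal(unname(st$group_counts[c("Group1", "Group2", "Group3")]),
               c(5L, 3L, 2L))
  expect_equal(st$repeat_length_mode, 36)
  expect_equal(st$repeat_length_exceptions$locus_id, "L03")
  expect_equal(st$repeat_length_exceptions$length, 35)
  expect_equal(st$count_missing_5prime_GTTT, 1)
  expect_equal(st$count_missing_3prime_C, 1)  # the 35-nt truncation removed the 3-prime C
  # GAG/GTTT over Groups 1+2: 8 minus the GTTT-broken locus L07
  expect_equal(st$junction_gag_gttt_count, 7)
  expect_equal(unname(st$csn2_mean_length_per_clade), c(320, 224))

  # permutation invariance
  perm <- sample(nrow(jn))
  st2 <- dataset_statistics(jn[perm, ], asg[perm, ], genus, csn2, clades)
  expect_equal(st2$group_counts, st$group_counts)
  expect_equal(st2$junction_gag_gttt_count, st$junction_gag_gttt_count)
  expect_equal(st2$count_missing_5prime_GTTT, st$count_missing_5prime_GTTT)

  expect_error(dataset_statistics(jn[-1, ], asg), "differ")
})
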