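strict_params <- array_params(boundary_consensus = 1.0, bridge_columns = 0)

plant_window <- function(lead_len, repeat_seq, n_copies, spacer_len,
                         tail_len = 0) {
  spacers <- replicate(n_copies - 1, rand_seq(spacer_len))
  paste0(rand_seq(lead_len),
         paste0(rep(repeat_seq, n_copies),
                c(spacers, ""), collapse = ""),
         rand_seq(tail_len))
}

test_that("a planted exact array is found and matches the brute-force oracle", {
  set.seed(101)
  R <- rand_seq(36)
  win <- plant_window(120, R, 3, 30)
  arrays <- detect_crispr_array(win, strict_params)
  expect_length(arrays, 1)
  a <- arrays[[1]]
  expect_equal(a$repeat_unit_length, 36)
  expect_equal(a$copies, 3)
  expect_equal(a$repeat_starts[1], 120)
  expect_equal(a$first_repeat, R)
  expect_equal(a$spacer_lengths, c(30, 30))

  orc <- oracle_periodic_arrays(win)
  expect_length(orc, 1)
  expect_equal(orc[[1]]$start, a$repeat_starts[1])
  expect_equal(orc[[1]]$L, a$repeat_unit_length)
  expect_equal(orc[[1]]$copies, a$copies)
})

test_that("random windows without periodic structure yield no arrays", {
  set.seed(55)
  for (i in 1:10) {
    win <- rand_seq(400)
    expect_length(detect_crispr_array(win, strict_params), 0)
    expect_length(oracle_periodic_arrays(win), 0)
  }
})

test_that("a minimal two-copy array is detected", {
  set.seed(9)
  R <- rand_seq(30)
  win <- plant_window(60, R, 2, 25, tail_len = 40)
  arrays <- detect_crispr_array(win, strict_params)
  expect_length(arrays, 1)
  expect_equal(arrays[[1]]$copies, 2)
  expect_equal(arrays[[1]]$repeat_unit_length, 30)
})

test_that("detector at unanimity equals the oracle on seeded exact windows", {
  set.seed(2024)
  for (trial in 1:25) {
    if (trial %% 2 == 0) {
      win <- rand_seq(sample(150:300, 1))
    } else {
      R <- rand_seq(sample(24:40, 1))
      win <- plant_window(sample(30:80, 1), R, sample(2:3, 1),
                          sample(20:35, 1), tail_len = sample(0:40, 1))
      win <- substr(win, 1, 300)
    }
    det <- detect_crispr_array(win, strict_params)
    orc <- oracle_periodic_arrays(win)
    expect_equal(length(det), length(orc))
    for (i in seq_along(det)) {
      expect_equal(det[[i]]$repeat_starts[1], orc[[i]]$start)
      expect_equal(det[[i]]$repeat_unit_length, orc[[i]]$L)
      expect_equal(det[[i]]$copies, orc[[i]]$copies)
    }
  }
})

test_that("planted repeat length is recovered under 2% copy mutation", {
  set.seed(77)
  hits <- 0L
  n_trials <- 200L
  for (trial in seq_len(n_trials)) {
    R <- rand_seq(36)
    copies <- vapply(1:12, function(i) plant_mutations(R, 0.02), "")
    spacers <- replicate(11, rand_seq(30))
    win <- paste0(rand_seq(60),
                  paste0(copies, c(spacers, ""), collapse = ""),
                  rand_seq(30))
    arrays <- detect_crispr_array(win)  # default boundary_consensus
    if (length(arrays) && arrays[[1]]$repeat_unit_length == 36)
      hits <- hits + 1L
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("candidate repeats containing N are rejected and counted", {
  set.seed(13)
  R <- paste0(rand_seq(17), "N", rand_seq(18))
  win <- plant_window(100, R, 3, 30)
  arrays <- detect_crispr_array(win, strict_params)
  expect_length(arrays, 0)
  expect_gte(attr(arrays, "n_rejected"), 1)
})

test_that("junction extraction slices the leader end and repeat start", {
  set.seed(21)
  leader <- paste0(rand_seq(100), "CAAAATTTGAG")
  R <- paste0("GTTTTTGTAC", rand_seq(26))
  win <- paste0(leader, R, rand_seq(30), R, rand_seq(30), R)
  arrays <- detect_crispr_array(win, strict_params)
  jn <- extract_leader_junction(win, arrays[[1]], "locusX")
  expect_equal(jn$leader_end7, "ATTTGAG")
  expect_equal(jn$junction_leader3, "GAG")
  expect_equal(jn$junction_repeat4, "GTTT")
  expect_equal(jn$first_repeat, R)
  expect_equal(nchar(jn$leader20), 20)
  expect_false(jn$truncated)
})

test_that("short leaders set the truncated flag; empty leaders error", {
  set.seed(31)
  R <- rand_seq(36)
  win12 <- plant_window(12, R, 3, 30)
  arrays <- detect_crispr_array(win12, strict_params)
  jn <- extract_leader_junction(win12, arrays[[1]], "short")
  expect_equal(nchar(jn$leader20), 12)
  expect_true(jn$truncated)
  expect_equal(nchar(jn$leader_end7), 7)

  win0 <- plant_window(0, R, 3, 30)
  arrays0 <- detect_crispr_array(win0, strict_params)
  if (length(arrays0) && arrays0[[1]]$repeat_starts[1] == 0)
    expect_error(extract_leader_junction(win0, arrays0[[1]], "empty"),
                 "empty leader")
})

test_that("junction strings are identical when the locus sits on the minus strand", {
  set.seed(41)
  R <- rand_seq(36)
  win <- plant_window(100, R, 3, 30)
  ctx <- paste0(rand_seq(50), win, rand_seq(50))
  fwd <- genome_record("f", ctx)
  rev <- revcomp_record(fwd)
  iv_f <- genomic_interval(50, 50 + nchar(win), "+")
  iv_r <- genomic_interval(nchar(ctx) - 50 - nchar(win),
                           nchar(ctx) - 50, "-")
  w1 <- oriented_subsequence(fwd, iv_f)
  w2 <- oriented_subsequence(rev, iv_r)
  expect_identical(w1, w2)
  a1 <- detect_crispr_array(w1, strict_params)[[1]]
  a2 <- detect_crispr_array(w2, strict_params)[[1]]
  expect_identical(extract_leader_junction(w1, a1, "x"),
                   extract_leader_junction(w2, a2, "x"))
})

test_that("leader plus first repeat plus remainder reconstructs the window", {
  set.seed(61)
  R <- rand_seq(36)
  win <- plant_window(90, R, 4, 28, tail_len = 20)
  a <- detect_crispr_array(win, strict_params)[[1]]
  s0 <- a$repeat_starts[1]
  leader <- substr(win, 1, s0)
  rest <- substr(win, s0 + a$repeat_unit_length + 1, nchar(win))
  jn <- extract_leader_junction(win, a, "concat")
  expect_identical(paste0(leader, jn$first_repeat, rest), win)
})
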