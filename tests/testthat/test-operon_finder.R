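mk_record <- function(genes, len = 20000) {
  # genes: data.frame(name, start, end, strand)
  genes$protein <- NA_character_
  genome_record("rec1", strrep("ACGT", len / 4), genes)
}

four_genes <- data.frame(
  name = c("cas9", "cas1", "cas2", "csn2"),
  start = c(1000, 5200, 6200, 6700),
  end = c(5100, 6100, 6500, 7400),
  strand = "+", stringsAsFactors = FALSE)

test_that("synonym matching maps Csn1 to cas9 and ignores other cas genes", {
  r <- mk_record(data.frame(name = c("Csn1 protein", "cas3", "CRISPR Cas13a"),
                            start = c(100, 300, 500),
                            end = c(200, 400, 600), strand = "+"))
  hits <- find_cas_genes(r)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$role, "cas9")
  expect_equal(hits$matched_synonym, "\\bcsn1\\b")
})

test_that("each annotation yields at most one hit, in fixed role order", {
  r <- mk_record(four_genes)
  hits <- find_cas_genes(r)
  expect_equal(sort(hits$role), sort(c("cas9", "cas1", "cas2", "csn2")))
  expect_equal(nrow(hits), 4)
})

test_that("complete clusters become operons; incomplete ones are dropped", {
  r <- mk_record(four_genes)
  ops <- assemble_type_iia_operons(find_cas_genes(r), "rec1")
  expect_length(ops, 1)
  expect_equal(ops[[1]]$orientation, "+")
  expect_equal(unname(ops[[1]]$span), c(1000, 7400))

  r2 <- mk_record(four_genes[1:3, ])  # cas9+cas1+cas2 only
  ops2 <- assemble_type_iia_operons(find_cas_genes(r2), "rec1")
  expect_length(ops2, 0)
  expect_equal(attr(ops2, "drops")$reason, "missing_role")
})

test_that("two distant complete clusters are independent loci", {
  far <- four_genes
  far$start <- far$start + 200000
  far$end <- far$end + 200000
  r <- mk_record(rbind(four_genes, far), len = 300000)
  ops <- assemble_type_iia_operons(find_cas_genes(r), "rec1")
  expect_length(ops, 2)
  expect_equal(vapply(ops, `[[`, "", "locus_id"),
               c("rec1_locus01", "rec1_locus02"))
})

test_that("duplicated roles error in strict mode and drop otherwise", {
  dup <- rbind(four_genes,
               data.frame(name = "cas2", start = 7600, end = 7900,
                          strand = "+", stringsAsFactors = FALSE))
  hits <- find_cas_genes(mk_record(dup))
  expect_error(assemble_type_iia_operons(hits, "rec1"), "duplicated role")
  ops <- assemble_type_iia_operons(hits, "rec1", on_duplicate = "drop")
  expect_length(ops, 0)
  expect_equal(attr(ops, "drops")$reason, "duplicate_role")
})

test_that("orientation is the majority strand; 2-2 ties reject the locus", {
  mixed <- four_genes
  mixed$strand <- c("-", "-", "-", "+")
  ops <- assemble_type_iia_operons(find_cas_genes(mk_record(mixed)), "rec1")
  expect_equal(ops[[1]]$orientation, "-")

  tied <- four_genes
  tied$strand <- c("-", "-", "+", "+")
  expect_warning(
    ops2 <- assemble_type_iia_operons(find_cas_genes(mk_record(tied)), "rec1"),
    "orientation tie")
  expect_length(ops2, 0)
})

test_that("leader window sits downstream of csn2 in transcription direction", {
  genes <- data.frame(name = c("cas9", "cas1", "cas2", "csn2"),
                      start = c(100, 4300, 4600, 4800),
                      end = c(4200, 4500, 4700, 5000),
                      strand = "+", stringsAsFactors = FALSE)
  r <- mk_record(genes, len = 10000)
  op <- assemble_type_iia_operons(find_cas_genes(r), "rec1")[[1]]
  w <- leader_search_window(op, r, 400)
  expect_equal(w$start, 5000L)
  expect_equal(w$end, 5400L)
  expect_equal(w$strand, "+")
  expect_false(attr(w, "truncated"))

  genes$strand <- "-"
  genes2 <- data.frame(name = rev(genes$name),
                       start = c(2000, 2400, 2600, 2900),
                       end = c(2300, 2500, 2800, 7000),
                       strand = "-", stringsAsFactors = FALSE)
  r2 <- mk_record(genes2, len = 10000)
  op2 <- assemble_type_iia_operons(find_cas_genes(r2), "rec1")[[1]]
  w2 <- leader_search_window(op2, r2, 400)
  expect_equal(w2$start, 1600L)
  expect_equal(w2$end, 2000L)
  expect_equal(w2$strand, "-")
})

test_that("windows clipped at the contig edge are flagged; empty ones error", {
  genes <- four_genes
  r <- mk_record(genes, len = 7700)  # 300 nt downstream of csn2 end
  op <- assemble_type_iia_operons(find_cas_genes(r), "rec1")[[1]]
  w <- leader_search_window(op, r, 400)
  expect_equal(w$end - w$start, 300)
  expect_true(attr(w, "truncated"))

  r2 <- mk_record(genes, len = 7400)  # csn2 ends exactly at the contig end
  op2 <- assemble_type_iia_operons(find_cas_genes(r2), "rec1")[[1]]
  expect_error(leader_search_window(op2, r2, 400), "degenerate")
})

test_that("operon calls are invariant to annotation order and strand flip", {
  ds <- generate_synthetic_dataset(sim_config(n_loci = 3, seed = 5))
  for (r in ds$records) {
    ops <- assemble_type_iia_operons(find_cas_genes(r), r$record_id)
    # shuffle annotation rows before reconstruction
    set.seed(1)
    shuf <- r$annotations[sample(nrow(r$annotations)), ]
    r_shuf <- genome_record(r$record_id, r$sequence, shuf)
    ops_shuf <- assemble_type_iia_operons(find_cas_genes(r_shuf), r$record_id)
    expect_length(ops_shuf, length(ops))

    rc <- revcomp_record(r)
    ops_rc <- assemble_type_iia_operons(find_cas_genes(rc), r$record_id)
    expect_length(ops_rc, length(ops))
    # mirrored coordinates, flipped orientation, identical window sequence
    n <- nchar(r$sequence)
    expect_equal(unname(ops_rc[[1]]$span),
                 unname(n - rev(ops[[1]]$span)))
    expect_equal(ops_rc[[1]]$orientation,
                 if (ops[[1]]$orientation == "+") "-" else "+")
    w <- leader_search_window(ops[[1]], r, 400)
    w_rc <- leader_search_window(ops_rc[[1]], rc, 400)
    expect_equal(oriented_subsequence(rc, w_rc), oriented_subsequence(r, w))
  }
})
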