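# Alignment scoring, identity, trimming, ortholog pairing, synteny.

test_that("identity and single-substitution alignments score as expected", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$score, 4 * 2)
  expect_equal(percent_identity(al), 100)
  al2 <- global_align("ACGT", "ACGA")
  expect_equal(percent_identity(al2), 75)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("alignment score equals exhaustive enumeration on short sequences", {
  seqs <- unlist(lapply(1:4, function(n) {
    apply(expand.grid(rep(list(c("A", "C")), n)), 1, paste, collapse = "")
  }))
  for (a in seqs) {
    for (b in seqs) {
      got <- global_align(a, b)$score
      want <- oracle_align_score(a, b)
      expect_equal(got, want, info = sprintf("%s vs %s", a, b))
    }
  }
  # longer random pairs over the full alphabet, including length 5-6
  set.seed(99)
  for (rep in 1:40) {
    a <- rand_dna(sample(4:6, 1))
    b <- rand_dna(sample(4:6, 1))
    expect_equal(global_align(a, b)$score, oracle_align_score(a, b),
                 info = sprintf("%s vs %s", a, b))
  }
})

test_that("percent identity handles gap columns per mode and is symmetric", {
  aln <- structure(list(aligned_a = "AC-GT", aligned_b = "ACTGT"),
                   class = "pairwise_alignment")
  expect_equal(percent_identity(aln, "ungapped_columns"), 100)
  expect_equal(percent_identity(aln, "all_columns"), 80)
  swapped <- structure(list(aligned_a = "ACTGT", aligned_b = "AC-GT"),
                       class = "pairwise_alignment")
  expect_equal(percent_identity(swapped, "all_columns"), 80)
  # constructed truth: k substitutions, no gaps
  set.seed(5)
  a <- rand_dna(60)
  ch <- strsplit(a, "")[[1]]
  pos <- sample(60, 9)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  aln2 <- structure(list(aligned_a = a, aligned_b = paste(ch, collapse = "")),
                    class = "pairwise_alignment")
  expect_equal(percent_identity(aln2), (60 - 9) / 60 * 100)
  empty <- structure(list(aligned_a = "---", aligned_b = "AAA"),
                     class = "pairwise_alignment")
  expect_error(percent_identity(empty), "undefined")
})

test_that("trimming removes a gappy island and respects block length", {
  a <- paste0(strrep("A", 20), "-----", strrep("G", 20))
  b <- paste0(strrep("A", 20), "CCCCC", strrep("G", 20))
  aln <- structure(list(aligned_a = a, aligned_b = b),
                   class = "pairwise_alignment")
  tr <- trim_conserved_blocks(aln)
  expect_equal(nchar(tr$aligned_a), 40)
  expect_equal(tr$n_columns_trimmed, 5)
  expect_false(grepl("-", tr$aligned_a))
  # gapless identical alignment is unchanged
  ident <- structure(list(aligned_a = strrep("ACGT", 5), aligned_b = strrep("ACGT", 5)),
                     class = "pairwise_alignment")
  expect_equal(trim_conserved_blocks(ident)$aligned_a, strrep("ACGT", 5))
  # min_block_len longer than the alignment empties it with a warning
  short <- structure(list(aligned_a = "ACGT", aligned_b = "ACGT"),
                     class = "pairwise_alignment")
  expect_warning(tr2 <- trim_conserved_blocks(short, min_block_len = 10), "trimmed")
  expect_equal(nchar(tr2$aligned_a), 0)
})

test_that("reciprocal-best-hit pairing recovers a known ortholog map", {
  set.seed(31)
  anc <- vapply(1:10, function(i) random_cds(80), character(1))
  ga <- tibble::tibble(feature_id = sprintf("a%02d", 1:10), cds = anc)
  gb <- tibble::tibble(
    feature_id = sprintf("b%02d", 1:10),
    cds = vapply(anc, evolve_cds, character(1), target_ds = 0.1)
  )[sample(10), ] # permute to make pairing non-trivial
  pairs <- pair_orthologs(ga, gb)
  expect_equal(nrow(pairs), 10)
  expect_equal(sub("a", "", pairs$gene_a), sub("b", "", pairs$gene_b))
  expect_true(all(pairs$percent_identity > 85))
})

test_that("identical gene sets pair perfectly and deletions leave genes unpaired", {
  set.seed(8)
  g <- tibble::tibble(feature_id = sprintf("g%d", 1:5),
                      cds = vapply(1:5, function(i) random_cds(60), character(1)))
  self <- pair_orthologs(g, g)
  expect_equal(self$percent_identity, rep(100, 5))
  gb <- g[-3, ]
  gb$feature_id <- sub("g", "h", gb$feature_id)
  pairs <- pair_orthologs(g, gb)
  expect_equal(attr(pairs, "unpaired_a"), "g3")
  expect_equal(length(attr(pairs, "unpaired_b")), 0)
})

test_that("synteny partitions genes into blocks and discrepant regions", {
  # identical ordered pairings: one block, no discrepant regions
  pairs <- tibble::tibble(gene_a = sprintf("a%d", 1:6), gene_b = sprintf("b%d", 1:6))
  rep1 <- find_synteny(pairs, sprintf("a%d", 1:6), sprintf("b%d", 1:6))
  expect_equal(length(unique(rep1$blocks$block_id)), 1)
  expect_equal(nrow(rep1$discrepant), 0)
  expect_equal(rep1$blocks$orientation, rep("+", 6))

  # internal 5-gene deletion on side b: one discrepant region of 5 on side a
  order_a <- sprintf("a%d", 1:15)
  keep <- setdiff(1:15, 6:10)
  pairs2 <- tibble::tibble(gene_a = sprintf("a%d", keep), gene_b = sprintf("b%d", keep))
  rep2 <- find_synteny(pairs2, order_a, sprintf("b%d", keep))
  expect_equal(nrow(rep2$discrepant), 5)
  expect_equal(unique(rep2$discrepant$side), "a")
  expect_equal(length(unique(rep2$discrepant$region_id)), 1)

  # inverted 3-gene run: a block of opposite orientation appears
  order_b3 <- c("b1", "b2", "b5", "b4", "b3", "b6")
  pairs3 <- tibble::tibble(gene_a = sprintf("a%d", 1:6), gene_b = sprintf("b%d", 1:6))
  rep3 <- find_synteny(pairs3, sprintf("a%d", 1:6), order_b3)
  oris <- unique(rep3$blocks$orientation[rep3$blocks$gene_a %in% c("a3", "a4", "a5")])
  expect_equal(oris, "-")

  # coverage and disjointness: every gene in exactly one block or region
  for (rep_ in list(rep1, rep2, rep3)) {
    in_blocks_a <- rep_$blocks$gene_a
    in_disc_a <- rep_$discrepant$gene[rep_$discrepant$side == "a"]
    expect_equal(length(intersect(in_blocks_a, in_disc_a)), 0)
  }
  all_a <- c(rep2$blocks$gene_a, rep2$discrepant$gene[rep2$discrepant$side == "a"])
  expect_setequal(all_a, order_a)
})
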