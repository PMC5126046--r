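# Data model, format readers/writers, coordinate conventions.

toy_genbank <- function(path) {
  seq <- "atgaaatttggctaacccatggggtgctag" # 30 bp, two CDS
  lines <- c(
    "LOCUS       toyctg                 30 bp    DNA     linear   BCT",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..30",
    "     CDS             1..15",
    '                     /locus_tag="toy_001"',
    '                     /product="protein one"',
    "     CDS             complement(16..30)",
    '                     /locus_tag="toy_002"',
    '                     /product="protein two"',
    "ORIGIN",
    "        1 atgaaatttg gctaacccat ggggtgctag",
    "//"
  )
  writeLines(lines, path)
  toupper(seq)
}

test_that("a toy GenBank record parses with both strands handled", {
  path <- withr::local_tempfile(fileext = ".gb")
  seq <- toy_genbank(path)
  g <- read_genome(path, format = "genbank")
  expect_equal(nrow(g$features), 2)
  expect_equal(unname(g$contigs[["toyctg"]]), seq)
  expect_equal(g$features$cds[1], substr(seq, 1, 15))
  # minus-strand CDS is the reverse complement of the contig slice
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 16, 30))
  ))
  expect_equal(g$features$cds[2], rc)
  expect_equal(g$features$strand, c("+", "-"))
})

test_that("malformed GenBank input fails with an informative error", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file"), path)
  expect_error(read_genome(path, format = "genbank"), "LOCUS")
})

test_that("FASTA+GFF3 round-trips through write_genome and read_genome", {
  sim <- simulate_study(sim_config(seed = 2, host = list(n_genes = 3),
                                   phage = list(n_genes = 3, resident_ds = 0.27),
                                   alien = list(length = 700, n_cargo_genes = 1)))
  g <- sim$genome_a
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, format = "fasta+gff3", gff = gff, genome_id = g$genome_id)
  expect_equal(g2$contigs, g$contigs)
  expect_setequal(g2$features$feature_id, g$features$feature_id)
  m <- match(g$features$feature_id, g2$features$feature_id)
  expect_equal(g2$features$start[m], g$features$start)
  expect_equal(g2$features$end[m], g$features$end)
  expect_equal(g2$features$cds[m], g$features$cds)
})

test_that("minus-strand GFF3 CDS is reverse complemented on read", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">c1", "TTAACGTGGG"), fa)
  writeLines(c("##gff-version 3",
               "c1\ttest\tCDS\t3\t8\t.\t-\t0\tID=m1"), gff)
  g <- read_genome(fa, format = "fasta+gff3", gff = gff)
  expect_equal(g$features$cds, "CACGTT") # revcomp of the slice AACGTG
})

test_that("features outside their contig are rejected", {
  expect_error(
    genome_record("g", c(c1 = "ACGT"),
                  tibble::tibble(feature_id = "f1", genome_id = "g",
                                 contig_id = "c1", start = 2L, end = 9L,
                                 strand = "+", product = "", cds = "X",
                                 is_pseudo = FALSE)),
    "beyond"
  )
  expect_error(
    genome_record("g", c(c1 = "ACGT"),
                  tibble::tibble(feature_id = c("f", "f"), genome_id = "g",
                                 contig_id = "c1", start = 1L, end = 2L,
                                 strand = "+", product = "", cds = "AC",
                                 is_pseudo = FALSE)),
    "unique"
  )
})

test_that("extract_region follows 1-based inclusive coordinates", {
  g <- genome_record("g", c(c1 = "ACGTACGTA"))
  expect_equal(extract_region(g, "c1", 5, 7), "ACG")
  expect_equal(extract_region(g, "c1", 1, 9), "ACGTACGTA")
  expect_error(extract_region(g, "c1", 0, 3), "out of range")
  expect_error(extract_region(g, "c2", 1, 2), "unknown contig")
  # round-trip: a feature's recorded cds equals the strand-aware slice
  sim <- simulate_study(sim_config(seed = 3, host = list(n_genes = 2),
                                   phage = list(n_genes = 2, resident_ds = 0.2),
                                   alien = list(length = 700, n_cargo_genes = 1)))
  f <- sim$genome_a$features[1, ]
  expect_equal(extract_region(sim$genome_a, f$contig_id, f$start, f$end), f$cds)
})

test_that("codon admissibility excludes short, pseudo, and stop-bearing features", {
  feats <- tibble::tibble(
    feature_id = c("ok", "len10", "pseudo", "stopper"),
    genome_id = "g", contig_id = "c", start = 1L, end = 1L, strand = "+",
    product = "",
    cds = c("ATGAAATAA", "ACGTACGTAC", "ATGAAATAA", "ATGTAAAAATAA"),
    is_pseudo = c(FALSE, FALSE, TRUE, FALSE)
  )
  expect_message(kept <- codon_admissible(feats), "len10")
  expect_equal(kept$feature_id, "ok")
  exc <- attr(kept, "excluded")
  expect_setequal(exc$reason,
                  c("length not divisible by 3", "pseudogene", "internal stop codon"))
  # pseudogenes can be retained by configuration
  kept2 <- suppressMessages(codon_admissible(feats, include_pseudo = TRUE))
  expect_true("pseudo" %in% kept2$feature_id)
})

test_that("ortholog tables round-trip losslessly and are header-keyed", {
  tb <- tibble::tibble(gene_a = c("x1", "x2", "x3"),
                       gene_b = c("y1", "y2", "y3"),
                       percent_identity = c(99.1, 88.2, 75.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tb, path)
  expect_equal(read_ortholog_table(path), tb)
  # permuted column order parses to the same content
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(tb[, c(3, 2, 1)], path2)
  back <- read_ortholog_table(path2)
  expect_equal(back[, names(tb)], tb)
  # empty table reads back as zero rows without error
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_table(tb[0, ], path3)
  expect_equal(nrow(read_ortholog_table(path3)), 0)
  # missing required columns is a schema error
  path4 <- withr::local_tempfile(fileext = ".tsv")
  write_table(tibble::tibble(foo = 1), path4)
  expect_error(read_ortholog_table(path4), "gene_a")
})
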