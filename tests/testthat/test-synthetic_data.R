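# Generators: determinism, validity, and parameter recovery.

test_that("generators are byte-identical under the same seed", {
  expect_identical(simulate_gene_pair(300, 0.1, seed = 4),
                   simulate_gene_pair(300, 0.1, seed = 4))
  expect_identical(random_cds(50, seed = 9), random_cds(50, seed = 9))
  s1 <- simulate_study(sim_config(seed = 6, host = list(n_genes = 3),
                                  phage = list(n_genes = 3, resident_ds = 0.27),
                                  alien = list(length = 700, n_cargo_genes = 1)))
  s2 <- simulate_study(sim_config(seed = 6, host = list(n_genes = 3),
                                  phage = list(n_genes = 3, resident_ds = 0.27),
                                  alien = list(length = 700, n_cargo_genes = 1)))
  expect_identical(s1$genome_a$contigs, s2$genome_a$contigs)
  expect_identical(s1$genome_b$features, s2$genome_b$features)
})

test_that("generated CDSs carry no internal stops and pass admissibility", {
  set.seed(1)
  for (rep in 1:10) {
    cds <- random_cds(60)
    ev <- evolve_cds(cds, 0.3)
    codons <- substring(ev, seq(1, 178, 3), seq(3, 180, 3))
    expect_false(any(Biostrings::GENETIC_CODE[codons] == "*"))
  }
  sim <- simulate_study(sim_config(seed = 11, host = list(n_genes = 4),
                                   phage = list(n_genes = 3, resident_ds = 0.2),
                                   alien = list(length = 700, n_cargo_genes = 1)))
  kept <- suppressMessages(codon_admissible(sim$genome_a$features))
  expect_equal(nrow(kept), nrow(sim$genome_a$features))
})

test_that("a zero-divergence target yields an identical pair and bookkeeping holds", {
  gp <- simulate_gene_pair(300, 0, seed = 2)
  expect_identical(gp$cds_a, gp$cds_b)
  expect_equal(gp$realized_ps, 0)
  # realized pS equals a direct recount on the emitted pair
  gp2 <- simulate_gene_pair(600, 0.2, seed = 12)
  recount <- ng86(gp2$cds_a, gp2$cds_b)
  expect_equal(gp2$realized_ps, recount$pS, tolerance = 1e-12)
  expect_error(simulate_gene_pair(100, 0.1), "multiple of 3")
  expect_error(simulate_gene_pair(300, 1.2), "below 1")
})

test_that("estimated dS recovers the generating value on average", {
  est <- vapply(1:15, function(s) {
    gp <- simulate_gene_pair(999, 0.10, seed = 3000 + s)
    ng86(gp$cds_a, gp$cds_b)$dS
  }, numeric(1))
  expect_gt(mean(est), 0.07)
  expect_lt(mean(est), 0.13)
})

test_that("composition-targeted CDS generation hits the GC target", {
  hot <- random_cds(400, gc = 0.62, seed = 8)
  cold <- random_cds(400, gc = 0.33, seed = 8)
  expect_gt(gc_fraction(hot), 0.55)
  expect_lt(gc_fraction(cold), 0.40)
})

test_that("the simulated study carries a consistent ground-truth record", {
  sim <- simulate_study(sim_config(seed = 21, host = list(n_genes = 4),
                                   phage = list(n_genes = 3, resident_ds = 0.3),
                                   alien = list(length = 900, n_cargo_genes = 1)))
  truth <- sim$truth
  # every truth ortholog id exists in the corresponding genome
  expect_true(all(truth$host_orthologs$gene_a %in% sim$genome_a$features$feature_id))
  expect_true(all(truth$host_orthologs$gene_b %in% sim$genome_b$features$feature_id))
  # the recorded alien span is GC-shifted relative to the backbone
  span <- truth$alien_span_a
  alien_seq <- extract_region(sim$genome_a, "chr", span[1], span[2])
  expect_gt(gc_fraction(alien_seq), 0.5)
  # the candidate prophage span covers all its genes
  reg <- sim$regions$candidate_a
  f <- sim$genome_a$features
  g <- f[f$feature_id %in% reg$gene_ids, ]
  expect_true(all(g$start >= as.integer(reg$span[2]) &
                    g$end <= as.integer(reg$span[3])))
  # att truth: the four derived junctions contain the planted core
  left <- extract_region(sim$genome_a, "chr", 1, as.integer(reg$span[2]) - 1)
  proph <- extract_region(sim$genome_a, "chr", as.integer(reg$span[2]),
                          as.integer(reg$span[3]))
  right <- extract_region(sim$genome_a, "chr", as.integer(reg$span[3]) + 1,
                          nchar(sim$genome_a$contigs[["chr"]]))
  ctx <- att_context(proph, left, right, window = 80)
  expect_equal(find_core(ctx)$core, truth$att$core)
})

test_that("qPCR generator respects the efficiency guard", {
  expect_error(simulate_qpcr(sim_config(qpcr = list(efficiency = 0.3))),
               "efficiency")
})
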