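# attP construction, core detection, inverted-repeat arms.

test_that("attP joins the prophage 3' end to its 5' start", {
  p <- build_attP("AAAACCCC", window = 2)
  expect_equal(p$seq, "CCAA")
  expect_equal(p$offset, 2)
  expect_warning(p2 <- build_attP("ACGTAC", window = 10), "shorter")
  expect_equal(p2$offset, 3)
})

test_that("att context derives the four junctions consistently", {
  s <- simulate_att_set(core = "ATGA", seed = 1)
  ctx <- s$ctx
  expect_named(ctx, c("attL", "attR", "attB", "attP"))
  w <- ctx$attP$offset
  # attP is the circular junction of the prophage
  expect_equal(ctx$attP$seq,
               paste0(substr(s$prophage, nchar(s$prophage) - w + 1, nchar(s$prophage)),
                      substr(s$prophage, 1, w)))
  # attB joins the two host flanks
  expect_equal(ctx$attB$seq,
               paste0(substr(s$left_flank, nchar(s$left_flank) - w + 1, nchar(s$left_flank)),
                      substr(s$right_flank, 1, w)))
})

test_that("the planted core is recovered, including ATGA and length-1 cores", {
  s <- simulate_att_set(core = "ATGA", seed = 10)
  core <- find_core(s$ctx)
  expect_equal(core$core, "ATGA")
  # the returned occurrences span every junction
  for (i in seq_len(nrow(core$positions))) {
    site <- core$positions$site[i]
    off <- s$ctx[[site]]$offset
    expect_true(core$positions$start[i] <= off + 1 && core$positions$end[i] >= off)
    expect_equal(substr(s$ctx[[site]]$seq, core$positions$start[i],
                        core$positions$end[i]), "ATGA")
  }
  # single-nucleotide cores are admissible
  s1 <- simulate_att_set(core = "T", arm = "GGCAC", seed = 3)
  expect_equal(find_core(s1$ctx)$core, "T")
})

test_that("identical sequences give the maximal admissible core and mismatches give none", {
  seq <- strrep("ACGT", 30)
  ctx <- structure(
    lapply(1:4, function(i) list(seq = seq, offset = 60)),
    names = c("attL", "attR", "attB", "attP"), class = "att_context"
  )
  core <- find_core(ctx, max_core = 20)
  expect_equal(core$length, 20)
  # four junctions with nothing in common: explicit no-core result
  ctx2 <- structure(
    list(attL = list(seq = "AAAA", offset = 2), attR = list(seq = "CCCC", offset = 2),
         attB = list(seq = "GGGG", offset = 2), attP = list(seq = "TTTT", offset = 2)),
    class = "att_context"
  )
  expect_true(is.na(find_core(ctx2)$core))
})

test_that("find_core agrees with the exhaustive substring oracle on small toys", {
  set.seed(17)
  for (rep in 1:20) {
    s <- simulate_att_set(core = paste(sample(c("A", "C", "G", "T"),
                                              sample(3:6, 1), replace = TRUE),
                                       collapse = ""),
                          arm = rand_dna(5), flank_len = 60, phage_len = 120,
                          window = 30, seed = 500 + rep)
    got <- find_core(s$ctx)
    want <- oracle_core_set(s$ctx)
    expect_equal(got$length, want$length)
    expect_true(got$core %in% want$cores)
  }
})

test_that("planted core recovery holds across seeded fixtures", {
  ok <- 0L
  for (s in 1:30) {
    core_len <- 3 + (s %% 5)
    planted <- paste(sample(c("A", "C", "G", "T"), core_len, replace = TRUE),
                     collapse = "")
    fx <- simulate_att_set(core = planted, flank_len = 80, window = 60,
                           seed = 7000 + s)
    if (identical(find_core(fx$ctx)$core, planted)) ok <- ok + 1L
  }
  expect_equal(ok, 30L)
})

test_that("core detection is invariant to padding beyond the junction windows", {
  s <- simulate_att_set(core = "ATGA", seed = 21, window = 50)
  padded <- structure(
    lapply(s$ctx, function(site) {
      list(seq = paste0(rand_dna(40), site$seq, rand_dna(40)),
           offset = site$offset + 40)
    }),
    names = names(s$ctx), class = "att_context"
  )
  expect_equal(find_core(padded)$core, find_core(s$ctx)$core)
})

test_that("planted inverted-repeat arms are detected exactly on a tight toy", {
  seq <- paste0("GATTC", "ATGA", "GAATC") # arms are reverse complements
  ir <- find_inverted_repeats(seq, c(6, 9))
  expect_equal(ir$arm_length, 5)
  expect_equal(ir$mismatches, 0)
  expect_equal(ir$left_arm, "GATTC")
  expect_equal(ir$right_arm, "GAATC")
})

test_that("random flanks rarely produce arms at min_arm 8", {
  found <- 0L
  for (s in 1:30) {
    set.seed(8000 + s)
    seq <- paste0(rand_dna(200), "ATGA", rand_dna(200))
    ir <- find_inverted_repeats(seq, c(201, 204), min_arm = 8)
    if (!is.null(ir)) found <- found + 1L
  }
  expect_lte(found, 1L)
})

test_that("inverted-repeat search matches the brute-force oracle on 80 bp toys", {
  set.seed(5150)
  for (rep in 1:25) {
    core_start <- 38
    seq <- rand_dna(80)
    got <- find_inverted_repeats(seq, c(core_start, core_start + 3),
                                 min_arm = 4, max_mismatch = 1, max_gap = 2)
    want <- oracle_inverted_repeats(seq, c(core_start, core_start + 3),
                                    min_arm = 4, max_mismatch = 1, max_gap = 2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$arm_length, want$arm_length)
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$left_span, want$left_span)
      expect_equal(got$right_span, want$right_span)
    }
  }
})
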