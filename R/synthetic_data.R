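# Seeded generators for genomes, prophages, att sites, and qPCR data with
# the statistical structure the analysis assumes, plus ground-truth records.

#' Simulation configuration
#'
#' Defaults encode the study regime the pipeline is designed to detect: a
#' transferred phage pair at low synonymous divergence (dS 0.07), resident
#' phages in the recipient genome at high divergence (dS 0.27), host
#' orthologs in between (dS 0.10), a compositionally alien insert (GC 0.60
#' on a GC 0.35 background) at the phage 3' end, att sites with a planted
#' core (ATGA) and inverted-repeat arms, and qPCR copy ratios of 2.90
#' (phage : host), 3.21 / 2.45 (flanking region : host) and 1.01
#' (host : host control).
#'
#' @param seed Integer seed recorded in all outputs.
#' @param host List: `n_genes`, `gene_len_mean`, `gene_len_sd` (nt, rounded
#'   to codons), `ds` (target host-ortholog dS).
#' @param phage List: `n_genes`, `gene_len_mean`, `gene_len_sd`,
#'   `candidate_ds`, `resident_ds` (vector, one per resident phage).
#' @param alien List: `length`, `gc`, `n_cargo_genes`, `cargo_len`.
#' @param att List: `core`, `arm`, `arm_mismatches`, `flank_len`, `window`.
#' @param background List: `gc` (intergenic/backbone GC), `spacer_len`.
#' @param qpcr List: `ratios` (named, relative to the calibrator),
#'   `calibrator`, `efficiency`, `ct_sd`, `n_replicates` (samples),
#'   `standard_replicates` (per dilution point; triplicate by default),
#'   `plates`, `plate_offset_sd`, `base_copies`, `intercept`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       host = list(),
                       phage = list(),
                       alien = list(),
                       att = list(),
                       background = list(),
                       qpcr = list()) {
  cfg <- list(
    seed = seed,
    host = utils::modifyList(
      list(n_genes = 12, gene_len_mean = 300, gene_len_sd = 60, ds = 0.10),
      host
    ),
    phage = utils::modifyList(
      list(n_genes = 8, gene_len_mean = 300, gene_len_sd = 60,
           candidate_ds = 0.07, resident_ds = c(0.27, 0.27)),
      phage
    ),
    alien = utils::modifyList(
      list(length = 2000, gc = 0.60, n_cargo_genes = 2, cargo_len = 300),
      alien
    ),
    att = utils::modifyList(
      list(core = "ATGA", arm = "GCGATTC", arm_mismatches = 0,
           flank_len = 300, window = 100),
      att
    ),
    background = utils::modifyList(
      list(gc = 0.35, spacer_len = 30),
      background
    ),
    qpcr = utils::modifyList(
      list(
        ratios = c(phage_ank = 2.90, flank_regulator = 3.21,
                   flank_hsp20 = 2.45, ftsZ = 1.01),
        calibrator = "groEL", efficiency = 1.0, ct_sd = 0.15,
        n_replicates = 9, standard_replicates = 3, plates = 1,
        plate_offset_sd = 0,
        base_copies = 1e5, intercept = 38
      ),
      qpcr
    )
  )
  all_ds <- c(cfg$host$ds, cfg$phage$candidate_ds, cfg$phage$resident_ds)
  if (any(all_ds >= 1)) {
    abort("target dS values must be below the Jukes-Cantor feasibility bound of 1")
  }
  structure(cfg, class = "sim_config")
}

#' Random nucleotide sequence at a target GC fraction
#'
#' @param length Sequence length.
#' @param gc Target GC fraction.
#' @param seed Optional seed.
#' @return Nucleotide string.
#' @export
random_sequence <- function(length, gc = 0.5, seed = NULL) {
  with_seed(seed, paste(
    sample(DNA_BASES, length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""
  ))
}

#' Random sense-codon coding sequence
#'
#' Codons are drawn uniformly over the sense codons, or, when `gc` is set,
#' with probabilities proportional to a base-frequency model at that GC
#' fraction restricted to sense codons (so composition targets are met
#' without internal stops).
#'
#' @param n_codons Number of codons.
#' @param gc Optional target GC fraction.
#' @param seed Optional seed.
#' @inheritParams sense_codons
#' @return CDS string with no internal stop codons.
#' @export
random_cds <- function(n_codons, gc = NULL, seed = NULL,
                       code = Biostrings::GENETIC_CODE) {
  codons <- sense_codons(code)
  prob <- if (is.null(gc)) {
    rep(1 / length(codons), length(codons))
  } else {
    base_p <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES)
    w <- vapply(codons, function(cod) {
      prod(base_p[strsplit(cod, "")[[1]]])
    }, numeric(1))
    w / sum(w)
  }
  with_seed(seed, paste(
    sample(codons, n_codons, replace = TRUE, prob = prob),
    collapse = ""
  ))
}

# apply `n_events` random synonymous single-base substitutions; codons are
# chosen with probability proportional to their number of synonymous
# single-base options, then an option uniformly
.apply_synonymous_events <- function(codons, n_events, tabs) {
  n_opt <- vapply(tabs$syn_options[codons], length, integer(1))
  for (i in seq_len(n_events)) {
    if (all(n_opt == 0L)) break
    idx <- sample.int(length(codons), 1, prob = n_opt)
    opts <- tabs$syn_options[[codons[idx]]]
    pick <- opts[[sample.int(length(opts), 1)]]
    codons[idx] <- .mutate_codon(codons[idx], as.integer(pick[["pos"]]), pick[["base"]])
    n_opt[idx] <- length(tabs$syn_options[[codons[idx]]])
  }
  codons
}

#' Evolve a coding sequence by synonymous substitutions to a target dS
#'
#' Applies a Poisson number of synonymous single-base substitutions with
#' expectation `S * pS_target`, where
#' `pS_target = 3/4 * (1 - exp(-4/3 * target_ds))` inverts the Jukes-Cantor
#' correction and S is the sequence's synonymous site count. No
#' nonsynonymous changes are made, so dS is the only divergence axis.
#'
#' @param cds Sense-codon CDS string.
#' @param target_ds Target synonymous divergence (must be below 1).
#' @param seed Optional seed.
#' @inheritParams sense_codons
#' @return Evolved CDS string of the same length.
#' @export
evolve_cds <- function(cds, target_ds, seed = NULL,
                       code = Biostrings::GENETIC_CODE) {
  if (target_ds >= 1) abort("target_ds must be below 1 (Jukes-Cantor feasibility)")
  tabs <- codon_tables(code)
  n <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(toupper(cds), starts, starts + 2L)
  stopifnot(all(codons %in% tabs$codons))
  S <- sum(tabs$s[codons])
  ps_target <- 0.75 * (1 - exp(-4 / 3 * target_ds))
  with_seed(seed, {
    m <- rpois(1, S * ps_target)
    paste(.apply_synonymous_events(codons, m, tabs), collapse = "")
  })
}

#' Simulate a gene pair at a controlled synonymous divergence
#'
#' Draws a random sense-codon ancestor and evolves one copy with
#' [evolve_cds()]; the realized proportion of synonymous differences is
#' recounted directly and recorded.
#'
#' @param length CDS length in nucleotides (multiple of 3).
#' @param target_ds Target dS.
#' @param seed Seed (recorded).
#' @inheritParams sense_codons
#' @return List with `cds_a`, `cds_b`, `realized_ps`, `realized_ds`,
#'   `target_ds`, `seed`.
#' @export
simulate_gene_pair <- function(length, target_ds, seed = NULL,
                               code = Biostrings::GENETIC_CODE) {
  if (length %% 3L != 0L) abort("`length` must be a multiple of 3")
  with_seed(seed, {
    a <- random_cds(length %/% 3L, code = code)
    b <- evolve_cds(a, target_ds, code = code)
    tabs <- codon_tables(code)
    cols <- codon_columns(a, b, code)
    cs <- .ng_columns(cols, tabs)
    pt <- .ng_point(cs, cols$n_retained)
    list(cds_a = a, cds_b = b, realized_ps = pt$pS,
         realized_ds = pt$dS, target_ds = target_ds, seed = seed)
  })
}

#' Simulate a sequence with a compositionally alien insert
#'
#' @param length Total length.
#' @param gc_background Background GC fraction.
#' @param insert_start 1-based start of the insert.
#' @param insert_length Insert length.
#' @param gc_insert Insert GC fraction.
#' @param seed Seed.
#' @return List with `seq` and `insert_span = c(start, end)`.
#' @export
simulate_genome_with_insert <- function(length = 10000, gc_background = 0.35,
                                        insert_start = 4001,
                                        insert_length = 2000, gc_insert = 0.60,
                                        seed = NULL) {
  stopifnot(insert_start > 1, insert_start + insert_length - 1 < length)
  with_seed(seed, {
    left <- random_sequence(insert_start - 1, gc_background)
    ins <- random_sequence(insert_length, gc_insert)
    right <- random_sequence(length - insert_length - insert_start + 1, gc_background)
    list(seq = paste0(left, ins, right),
         insert_span = c(insert_start, insert_start + insert_length - 1))
  })
}

# mutate `n` random positions of a string to a different base
.mutate_positions <- function(seq, n) {
  if (n == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate an attachment-site fixture with a planted core and arms
#'
#' Builds host flanks and a prophage whose ends carry inverted-repeat arms
#' abutting a planted core, then derives the four att junction sequences.
#' The bases adjacent to the core in the host flanks are constrained to
#' differ from the arm bases at the same offsets, so the longest common
#' junction-spanning string is exactly the planted core.
#'
#' @param core Planted core sequence.
#' @param arm Planted left-arm sequence (the right arm is its reverse
#'   complement, with `arm_mismatches` substitutions applied).
#' @param flank_len Host flank length on each side.
#' @param phage_len Total prophage length (core + arms + filler).
#' @param arm_mismatches Hamming mismatches planted into the right arm.
#' @param gc Background GC for flanks and filler.
#' @param window Junction window passed to [att_context()].
#' @param seed Seed.
#' @return List with `ctx` (an [att_context()]), the parent sequences, and
#'   `truth` (planted core, arms, spans).
#' @export
simulate_att_set <- function(core = "ATGA", arm = "GCGATTC", flank_len = 300,
                             phage_len = 2000, arm_mismatches = 0, gc = 0.35,
                             window = 100, seed = NULL) {
  core <- toupper(core)
  arm <- toupper(arm)
  with_seed(seed, {
    arm_rc <- .mutate_positions(revcomp(arm), arm_mismatches)
    filler_len <- phage_len - nchar(core) - 2 * nchar(arm)
    stopifnot(filler_len > 0)
    body <- paste0(arm_rc, random_sequence(filler_len, gc), arm)
    prophage <- paste0(core, body)
    arm_last <- substr(arm, nchar(arm), nchar(arm))
    arm_rc_first <- substr(arm_rc, 1, 1)
    # flanks are resampled until the planted core is the unique maximal
    # junction-spanning common string, so "planted core" is well defined
    for (attempt in 1:25) {
      hl <- random_sequence(flank_len, gc)
      hr <- random_sequence(flank_len, gc)
      # prevent extension of the core across the junctions
      if (substr(hl, flank_len, flank_len) == arm_last) {
        substr(hl, flank_len, flank_len) <- sample(setdiff(DNA_BASES, arm_last), 1)
      }
      if (substr(hr, 1, 1) == arm_rc_first) {
        substr(hr, 1, 1) <- sample(setdiff(DNA_BASES, arm_rc_first), 1)
      }
      right_flank <- paste0(core, hr)
      ctx <- att_context(prophage, hl, right_flank, window = window)
      cj <- .common_junction_strings(ctx)
      if (cj$length == nchar(core) && identical(cj$strings, core)) break
    }
    list(
      ctx = ctx, prophage = prophage, left_flank = hl,
      right_flank = right_flank,
      truth = list(core = core, left_arm = arm, right_arm = arm_rc,
                   arm_mismatches = arm_mismatches, seed = seed)
    )
  })
}

# maximal-length strings common to all four att sequences with a
# junction-overlapping occurrence in each (direct enumeration; used by the
# generator to certify that a planted core is unambiguous)
.common_junction_strings <- function(ctx, max_len = 50) {
  occ_overlaps <- function(pat, seq, offset) {
    hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(FALSE)
    any(hits <= offset + 1L & hits + nchar(pat) - 1L >= offset)
  }
  ap <- ctx$attP
  for (len in rev(seq_len(min(max_len, nchar(ap$seq))))) {
    found <- character(0)
    for (s in seq_len(nchar(ap$seq) - len + 1L)) {
      e <- s + len - 1L
      if (!(s <= ap$offset + 1L && e >= ap$offset)) next
      cand <- substr(ap$seq, s, e)
      if (all(vapply(ctx, function(site) {
        occ_overlaps(cand, site$seq, site$offset)
      }, logical(1)))) {
        found <- union(found, cand)
      }
    }
    if (length(found)) return(list(length = len, strings = sort(found)))
  }
  list(length = 0L, strings = character(0))
}

# assembler used by simulate_study: appends sequence chunks and records
# gene features as it goes
.new_assembly <- function(contig_id, genome_id) {
  env <- new.env(parent = emptyenv())
  env$chunks <- character(0)
  env$pos <- 0L
  env$features <- list()
  env$contig_id <- contig_id
  env$genome_id <- genome_id
  env
}

.asm_add_seq <- function(env, seq) {
  env$chunks <- c(env$chunks, seq)
  start <- env$pos + 1L
  env$pos <- env$pos + nchar(seq)
  c(start, env$pos)
}

.asm_add_gene <- function(env, id, cds, product = "") {
  span <- .asm_add_seq(env, cds)
  env$features[[length(env$features) + 1L]] <- tibble(
    feature_id = id, genome_id = env$genome_id, contig_id = env$contig_id,
    start = span[1], end = span[2], strand = "+", product = product,
    cds = cds, is_pseudo = FALSE
  )
  span
}

.asm_finish <- function(env) {
  list(seq = paste(env$chunks, collapse = ""), features = bind_rows(env$features))
}

#' Simulate a two-genome study with a planted phage transfer
#'
#' Builds a donor-like genome A and a recipient-like genome B realizing the
#' three divergence groups the pipeline compares: host orthologs at
#' `host$ds`, a candidate prophage pair at `phage$candidate_ds`
#' (transferred), and resident prophages in B at `phage$resident_ds`
#' relative to the candidate. The candidate prophage carries a
#' compositionally alien 3'-end insert with cargo genes and is delimited by
#' att cores with inverted-repeat arms. A toy host phylogeny in which the
#' two carrier strains are distant relatives is attached, together with a
#' complete ground-truth record.
#'
#' @param config A [sim_config()].
#' @return List with `genome_a`, `genome_b` ([genome_record()]s), `regions`
#'   (list of `prophage_region`s), `tree` (`phylo`), `carriers`, `truth`,
#'   and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  with_seed(config$seed, {
    tabs <- codon_tables()
    bg <- config$background
    gene_len <- function(mean, sd) {
      n <- max(30, round(rnorm(1, mean, sd)))
      3L * max(10L, round(n / 3))
    }
    spacer <- function() random_sequence(bg$spacer_len, bg$gc)
    modules <- c("recombination", "replication", "head", "baseplate", "tail")

    # ancestral gene sets
    host_anc <- purrr::map_chr(seq_len(config$host$n_genes), function(i) {
      random_cds(gene_len(config$host$gene_len_mean, config$host$gene_len_sd) %/% 3L)
    })
    phage_anc <- purrr::map_chr(seq_len(config$phage$n_genes), function(i) {
      random_cds(gene_len(config$phage$gene_len_mean, config$phage$gene_len_sd) %/% 3L)
    })
    cargo_anc <- purrr::map_chr(seq_len(config$alien$n_cargo_genes), function(i) {
      random_cds(config$alien$cargo_len %/% 3L, gc = config$alien$gc)
    })

    host_a <- host_anc
    host_b <- purrr::map_chr(host_anc, evolve_cds, target_ds = config$host$ds)
    phage_a <- phage_anc
    phage_b <- purrr::map_chr(phage_anc, evolve_cds,
                              target_ds = config$phage$candidate_ds)
    cargo_a <- cargo_anc
    cargo_b <- purrr::map_chr(cargo_anc, evolve_cds,
                              target_ds = config$phage$candidate_ds)
    residents <- purrr::map(config$phage$resident_ds, function(ds) {
      purrr::map_chr(phage_anc, evolve_cds, target_ds = ds)
    })

    att <- config$att
    core <- toupper(att$core)
    arm <- toupper(att$arm)
    arm_rc <- .mutate_positions(revcomp(arm), att$arm_mismatches)
    alien_filler_len <- max(
      0L,
      config$alien$length - config$alien$n_cargo_genes * config$alien$cargo_len
    )

    build_genome <- function(genome_id, host_genes, phage_genes, cargo_genes,
                             resident_sets) {
      asm <- .new_assembly("chr", genome_id)
      .asm_add_seq(asm, spacer())
      for (i in seq_along(host_genes)) {
        .asm_add_gene(asm, sprintf("%s_host%02d", genome_id, i), host_genes[i],
                      product = "conserved host protein")
        .asm_add_seq(asm, spacer())
      }
      resident_regions <- list()
      for (r in seq_along(resident_sets)) {
        ids <- character(0)
        span_start <- asm$pos + 1L
        for (i in seq_along(resident_sets[[r]])) {
          id <- sprintf("%s_res%d_%02d", genome_id, r, i)
          .asm_add_gene(asm, id, resident_sets[[r]][i],
                        product = sprintf("resident phage %d protein", r))
          ids <- c(ids, id)
          .asm_add_seq(asm, spacer())
        }
        resident_regions[[r]] <- list(
          phage_id = sprintf("%s_resident%d", genome_id, r),
          genome_id = genome_id, gene_ids = ids,
          span = c("chr", span_start, asm$pos),
          gene_module = setNames(rep(modules, length.out = length(ids)), ids)
        )
      }
      # junction-adjacent flank bases are constrained so the common
      # junction-spanning string is exactly the planted core
      hl <- random_sequence(att$flank_len, bg$gc)
      arm_last <- substr(arm, nchar(arm), nchar(arm))
      if (substr(hl, att$flank_len, att$flank_len) == arm_last) {
        substr(hl, att$flank_len, att$flank_len) <-
          sample(setdiff(DNA_BASES, arm_last), 1)
      }
      .asm_add_seq(asm, hl)
      phage_start <- asm$pos + 1L
      .asm_add_seq(asm, core)
      .asm_add_seq(asm, arm_rc)
      ids <- character(0)
      for (i in seq_along(phage_genes)) {
        id <- sprintf("%s_phg%02d", genome_id, i)
        .asm_add_gene(asm, id, phage_genes[i], product = "phage structural protein")
        ids <- c(ids, id)
        .asm_add_seq(asm, spacer())
      }
      alien_start <- asm$pos + 1L
      .asm_add_seq(asm, random_sequence(alien_filler_len %/% 2L, config$alien$gc))
      cargo_ids <- character(0)
      for (i in seq_along(cargo_genes)) {
        id <- sprintf("%s_cargo%02d", genome_id, i)
        .asm_add_gene(asm, id, cargo_genes[i], product = "ankyrin-repeat cargo protein")
        cargo_ids <- c(cargo_ids, id)
      }
      .asm_add_seq(asm, random_sequence(alien_filler_len - alien_filler_len %/% 2L,
                                        config$alien$gc))
      alien_end <- asm$pos
      .asm_add_seq(asm, arm)
      phage_end <- asm$pos
      .asm_add_seq(asm, core)
      hr <- random_sequence(att$flank_len, bg$gc)
      arm_rc_first <- substr(arm_rc, 1, 1)
      if (substr(hr, 1, 1) == arm_rc_first) {
        substr(hr, 1, 1) <- sample(setdiff(DNA_BASES, arm_rc_first), 1)
      }
      .asm_add_seq(asm, hr)
      .asm_add_seq(asm, spacer())
      out <- .asm_finish(asm)
      all_ids <- c(ids, cargo_ids)
      candidate_region <- list(
        phage_id = paste0(genome_id, "_candidate"), genome_id = genome_id,
        gene_ids = all_ids, span = c("chr", phage_start, phage_end),
        gene_module = setNames(
          c(rep(modules, length.out = length(ids)),
            rep("ank", length(cargo_ids))),
          all_ids
        )
      )
      genome <- genome_record(
        genome_id = genome_id,
        contigs = c(chr = out$seq),
        features = out$features,
        metadata = list(host_species = "synthetic", supergroup = NA,
                        assembly_status = "simulated")
      )
      list(genome = genome, candidate = candidate_region,
           residents = resident_regions,
           alien_span = c(alien_start, alien_end))
    }

    A <- build_genome("wA", host_a, phage_a, cargo_a, list())
    B <- build_genome("wB", host_b, phage_b, cargo_b, residents)

    tree <- ape::read.tree(text = "((wA,(o1,o2)),(o3,(wB,(o4,o5))));")
    carriers <- c("wA", "wB")

    truth <- list(
      host_orthologs = tibble(
        gene_a = sprintf("wA_host%02d", seq_along(host_a)),
        gene_b = sprintf("wB_host%02d", seq_along(host_b)),
        target_ds = config$host$ds
      ),
      candidate_orthologs = tibble(
        gene_a = c(sprintf("wA_phg%02d", seq_along(phage_a)),
                   sprintf("wA_cargo%02d", seq_along(cargo_a))),
        gene_b = c(sprintf("wB_phg%02d", seq_along(phage_b)),
                   sprintf("wB_cargo%02d", seq_along(cargo_b))),
        target_ds = config$phage$candidate_ds
      ),
      resident_ds = config$phage$resident_ds,
      alien_span_a = A$alien_span, alien_span_b = B$alien_span,
      att = list(core = core, left_arm = arm, right_arm = arm_rc),
      expected_label = "recent_transfer",
      seed = config$seed
    )
    list(
      genome_a = A$genome, genome_b = B$genome,
      regions = list(candidate_a = A$candidate, candidate_b = B$candidate,
                     residents_b = B$residents),
      tree = tree, carriers = carriers, truth = truth, config = config
    )
  })
}

#' Simulate qPCR runs from known copy ratios
#'
#' Generates per-plate standard dilution series (10-fold, 10^3 to 10^7
#' copies) from the Ct curve implied by the configured amplification
#' efficiency, and per-replicate sample Cts for each gene from its true
#' copy number (calibrator copies times the configured ratio) with Gaussian
#' Ct noise and optional additive plate offsets.
#'
#' @param config A [sim_config()] (its `qpcr` block is used).
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with columns `plate`, `gene`, `role`
#'   (`"standard"`/`"sample"`), `log10_copies` (standards only), `ct`,
#'   `replicate`.
#' @export
simulate_qpcr <- function(config = sim_config(), seed = NULL) {
  q <- config$qpcr
  if (q$efficiency <= 0.5 || q$efficiency >= 1.5) {
    abort("efficiency must lie in (0.5, 1.5)")
  }
  slope <- -1 / log10(1 + q$efficiency)
  genes <- c(setNames(1, q$calibrator), q$ratios)
  with_seed(seed %||% config$seed, {
    rows <- list()
    for (plate in seq_len(q$plates)) {
      offset <- if (q$plate_offset_sd > 0) rnorm(1, 0, q$plate_offset_sd) else 0
      for (lg in 3:7) {
        rows[[length(rows) + 1L]] <- tibble(
          plate = plate, gene = "standard_template", role = "standard",
          log10_copies = lg,
          ct = q$intercept + slope * lg + rnorm(q$standard_replicates, 0, q$ct_sd),
          replicate = seq_len(q$standard_replicates)
        )
      }
      for (g in names(genes)) {
        true_copies <- q$base_copies * genes[[g]]
        rows[[length(rows) + 1L]] <- tibble(
          plate = plate, gene = g, role = "sample",
          log10_copies = NA_real_,
          ct = q$intercept + slope * log10(true_copies) + offset +
            rnorm(q$n_replicates, 0, q$ct_sd),
          replicate = seq_len(q$n_replicates)
        )
      }
    }
    bind_rows(rows)
  })
}
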