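# End-to-end evidence assembly: ortholog pairing per gene group, identity
# and dS per pair, and the final verdict.

.genes_of <- function(genome, ids) {
  f <- filter(genome$features, .data$feature_id %in% ids)
  tibble(feature_id = f$feature_id, cds = f$cds)
}

#' Assemble per-gene transfer evidence for a candidate phage pair
#'
#' Pairs the candidate prophage's genes against every prophage gene set of
#' the other genome by reciprocal best hit; the set with the highest mean
#' identity is taken as the transferred counterpart (the candidate group)
#' and the remaining sets as resident phages. Host orthologs are paired the
#' same way. Each ortholog pair contributes its trimmed percent identity
#' and Nei-Gojobori dS.
#'
#' @param candidate_genes Gene table (`feature_id`, `cds`) of the candidate
#'   prophage in genome A.
#' @param phage_sets_b Named list of gene tables, one per prophage in
#'   genome B (counterpart plus residents; which is which is inferred).
#' @param host_genes_a,host_genes_b Host (non-phage) gene tables of the two
#'   genomes.
#' @param min_identity Minimum RBH identity, see [pair_orthologs()].
#' @param params Alignment scoring, see [align_params()].
#' @return Tibble with `group` (`candidate`/`resident`/`host`), `gene_a`,
#'   `gene_b`, `phage_set`, `percent_identity`, `dS`; the inferred
#'   counterpart set name is attached as `attr(x, "counterpart")`.
#' @export
transfer_evidence <- function(candidate_genes, phage_sets_b,
                              host_genes_a, host_genes_b,
                              min_identity = 50, params = align_params()) {
  stopifnot(length(names(phage_sets_b)) == length(phage_sets_b))
  phage_pairs <- purrr::map(phage_sets_b, function(gb) {
    pair_orthologs(candidate_genes, gb, min_identity = min_identity,
                   params = params)
  })
  mean_id <- vapply(phage_pairs, function(p) {
    if (nrow(p)) mean(p$percent_identity) else -Inf
  }, numeric(1))
  counterpart <- names(phage_sets_b)[which.max(mean_id)]
  host_pairs <- pair_orthologs(host_genes_a, host_genes_b,
                               min_identity = min_identity, params = params)
  ds_of <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(i) {
      ng86(pairs$aligned_a[i], pairs$aligned_b[i])$dS
    }, numeric(1))
  }
  rows <- purrr::map(names(phage_sets_b), function(nm) {
    p <- phage_pairs[[nm]]
    if (!nrow(p)) return(NULL)
    tibble(
      group = if (nm == counterpart) "candidate" else "resident",
      gene_a = p$gene_a, gene_b = p$gene_b, phage_set = nm,
      percent_identity = p$percent_identity, dS = ds_of(p)
    )
  })
  host_rows <- if (nrow(host_pairs)) {
    tibble(group = "host", gene_a = host_pairs$gene_a,
           gene_b = host_pairs$gene_b, phage_set = NA_character_,
           percent_identity = host_pairs$percent_identity,
           dS = ds_of(host_pairs))
  } else NULL
  out <- bind_rows(c(rows, list(host_rows)))
  attr(out, "counterpart") <- counterpart
  out
}

#' Run the full transfer pipeline on a simulated study
#'
#' Extracts the candidate prophage, the recipient genome's prophages, and
#' the host gene sets from a [simulate_study()] result, assembles the
#' evidence with [transfer_evidence()], counts Dollo losses on the attached
#' host tree, and classifies the candidate with [classify_transfer()].
#'
#' @param sim A [simulate_study()] result.
#' @param config A [verdict_config()].
#' @param min_identity Minimum RBH identity.
#' @return A `transfer_verdict` (see [classify_transfer()]).
#' @export
run_transfer_pipeline <- function(sim, config = verdict_config(),
                                  min_identity = 50) {
  ga <- sim$genome_a
  gb <- sim$genome_b
  cand <- .genes_of(ga, sim$regions$candidate_a$gene_ids)
  sets_b <- c(
    list(candidate_b = .genes_of(gb, sim$regions$candidate_b$gene_ids)),
    setNames(
      purrr::map(sim$regions$residents_b, function(r) .genes_of(gb, r$gene_ids)),
      purrr::map_chr(sim$regions$residents_b, "phage_id")
    )
  )
  phage_ids <- unlist(c(sim$regions$candidate_a$gene_ids,
                        purrr::map(sim$regions$residents_b, "gene_ids"),
                        sim$regions$candidate_b$gene_ids))
  host_a <- filter(ga$features, !.data$feature_id %in% phage_ids)
  host_b <- filter(gb$features, !.data$feature_id %in% phage_ids)
  ev <- transfer_evidence(
    cand, sets_b,
    tibble(feature_id = host_a$feature_id, cds = host_a$cds),
    tibble(feature_id = host_b$feature_id, cds = host_b$cds),
    min_identity = min_identity
  )
  losses <- dollo_losses(sim$tree, sim$carriers)
  classify_transfer(ev, loss_count = losses, config = config)
}

#' Fit standard curves and copy-ratio tests from qPCR run tables
#'
#' Fits one standard curve per plate from the `role == "standard"` rows,
#' converts sample Cts to absolute copies, removes plate effects by
#' calibrator scaling, and tests each gene's per-replicate copy ratio to
#' the calibrator against the expected value.
#'
#' @param runs Run tibble as produced by [simulate_qpcr()] (columns `plate`,
#'   `gene`, `role`, `log10_copies`, `ct`, `replicate`).
#' @param calibrator Denominator/calibrator gene.
#' @param expected Expected ratio under the null.
#' @return List with `curves` (per-plate `std_curve`s), `copies` (adjusted
#'   tibble), and `ratios` (tidy tibble, one row per gene).
#' @export
qpcr_copy_ratios <- function(runs, calibrator = "groEL", expected = 1) {
  runs <- as_tibble(runs)
  plates <- unique(runs$plate)
  curves <- lapply(setNames(plates, paste0("plate", plates)), function(p) {
    std <- filter(runs, .data$plate == p, .data$role == "standard")
    fit_standard_curve(std)
  })
  samples <- filter(runs, .data$role == "sample")
  samples$copies <- NA_real_
  for (p in plates) {
    idx <- samples$plate == p
    samples$copies[idx] <- copies_from_ct(samples$ct[idx],
                                          curves[[paste0("plate", p)]])
  }
  adjusted <- normalize_plate_effects(
    select(samples, "plate", "gene", "replicate", "copies"), calibrator
  )
  cal <- filter(adjusted, .data$gene == calibrator) |>
    arrange(.data$plate, .data$replicate)
  ratios <- purrr::map(setdiff(unique(adjusted$gene), calibrator), function(g) {
    num <- filter(adjusted, .data$gene == g) |>
      arrange(.data$plate, .data$replicate)
    tidy(copy_ratio_test(num$copies, cal$copies, expected = expected,
                         numerator = g, denominator = calibrator))
  })
  list(curves = curves, copies = adjusted, ratios = bind_rows(ratios))
}
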