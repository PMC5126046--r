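# Pairwise alignment, identity, trimming, ortholog pairing, and synteny.

align_params <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.as_cds_table <- function(x, id_col = "feature_id", seq_col = "cds") {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(tibble(feature_id = names(x), cds = unname(toupper(x))))
  }
  x <- as_tibble(x)
  stopifnot(id_col %in% names(x), seq_col %in% names(x))
  tibble(feature_id = x[[id_col]], cds = toupper(x[[seq_col]]))
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global alignment (via Biostrings) under match/mismatch
#' scoring with affine gaps: a gap run of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param a,b Nucleotide strings (A/C/G/T), non-empty.
#' @param params Scoring parameters from [align_params()]
#'   (defaults match +2, mismatch -3, gap open 5, gap extend 2).
#' @param id_a,id_b Optional sequence identifiers carried into the result.
#' @return A `pairwise_alignment`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and `params`.
#' @examples
#' global_align("ACGT", "ACGA")$score
#' @export
global_align <- function(a, b, params = align_params(), id_a = "a", id_b = "b") {
  a <- toupper(a)
  b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  structure(
    list(
      id_a = id_a, id_b = id_b,
      aligned_a = as.character(Biostrings::alignedPattern(aln)),
      aligned_b = as.character(Biostrings::alignedSubject(aln)),
      score = Biostrings::score(aln), params = params
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s (score %.1f, %d columns)\n",
              x$id_a, x$id_b, x$score, nchar(x$aligned_a)))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

.aln_chars <- function(aln) {
  list(a = strsplit(aln$aligned_a, "")[[1]], b = strsplit(aln$aligned_b, "")[[1]])
}

.make_alignment <- function(ch_a, ch_b, template, n_trimmed = 0) {
  out <- template
  out$aligned_a <- paste(ch_a, collapse = "")
  out$aligned_b <- paste(ch_b, collapse = "")
  out$n_columns_trimmed <- n_trimmed
  out
}

#' Percent identity of a pairwise alignment
#'
#' @param aln A `pairwise_alignment`.
#' @param mode `"ungapped_columns"` (default) counts only columns without a
#'   gap; `"all_columns"` divides matches by the full alignment length.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(aln, mode = c("ungapped_columns", "all_columns")) {
  mode <- match.arg(mode)
  ch <- .aln_chars(aln)
  gap <- ch$a == "-" | ch$b == "-"
  matches <- sum(ch$a == ch$b & !gap)
  denom <- if (mode == "ungapped_columns") sum(!gap) else length(ch$a)
  if (denom == 0L) abort("no counted columns; percent identity undefined")
  100 * matches / denom
}

#' Remove poorly aligned columns and short blocks
#'
#' A simplified conserved-block filter: columns whose gap fraction reaches
#' `max_gap_fraction` are removed; the surviving columns are grouped into
#' maximal runs, and runs shorter than `min_block_len` or with mean identity
#' below `min_conservation` are dropped.
#'
#' @inheritParams percent_identity
#' @param max_gap_fraction Columns with a gap fraction at or above this are
#'   removed (for a pairwise alignment any gapped column).
#' @param min_block_len Minimum retained run length, in columns.
#' @param min_conservation Minimum fraction of identical columns in a
#'   retained run.
#' @return A trimmed `pairwise_alignment` with `n_columns_trimmed` recorded;
#'   if everything is trimmed an empty alignment is returned with a warning.
#' @export
trim_conserved_blocks <- function(aln, max_gap_fraction = 0.5,
                                  min_block_len = 10, min_conservation = 0.5) {
  ch <- .aln_chars(aln)
  ncol_in <- length(ch$a)
  gap_frac <- ((ch$a == "-") + (ch$b == "-")) / 2
  pass <- gap_frac < max_gap_fraction
  keep <- logical(ncol_in)
  if (any(pass)) {
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$values)) {
      if (!r$values[i] || r$lengths[i] < min_block_len) next
      idx <- starts[i]:ends[i]
      if (mean(ch$a[idx] == ch$b[idx]) >= min_conservation) keep[idx] <- TRUE
    }
  }
  if (!any(keep)) {
    warn("all columns trimmed; identity is undefined downstream")
  }
  .make_alignment(ch$a[keep], ch$b[keep], aln, n_trimmed = ncol_in - sum(keep))
}

#' Reciprocal-best-hit ortholog pairing between two gene sets
#'
#' Every gene of `genes_a` is globally aligned to every gene of `genes_b`;
#' identity is computed on trimmed columns; pairs that are each other's best
#' hit and reach `min_identity` become one-to-one orthologs. Ties are broken
#' by longer aligned length, then lexicographic gene id.
#'
#' @param genes_a,genes_b Data frames with `feature_id` and `cds` columns, or
#'   named character vectors of coding sequences.
#' @param min_identity Minimum trimmed percent identity for a pair.
#' @param params Alignment scoring, see [align_params()].
#' @param trim Trim alignments with [trim_conserved_blocks()] before
#'   computing identity.
#' @return Tibble with `gene_a`, `gene_b`, `percent_identity`,
#'   `n_columns_compared`, `n_columns_trimmed`, `aligned_a`, `aligned_b`.
#'   Unpaired gene ids are attached as `attr(x, "unpaired_a")` and
#'   `attr(x, "unpaired_b")`.
#' @export
pair_orthologs <- function(genes_a, genes_b, min_identity = 50,
                           params = align_params(), trim = TRUE) {
  ga <- .as_cds_table(genes_a)
  gb <- .as_cds_table(genes_b)
  na_ <- nrow(ga)
  nb <- nrow(gb)
  pid <- matrix(NA_real_, na_, nb)
  alen <- matrix(0L, na_, nb)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = TRUE
  )
  patterns <- Biostrings::DNAStringSet(ga$cds)
  alnsets <- vector("list", nb)
  for (j in seq_len(nb)) {
    alnset <- Biostrings::pairwiseAlignment(
      pattern = patterns, subject = gb$cds[j], type = "global",
      substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend
    )
    alnsets[[j]] <- alnset
    nm <- Biostrings::nmatch(alnset)
    nmm <- Biostrings::nmismatch(alnset)
    ungapped <- nm + nmm
    pid[, j] <- ifelse(ungapped > 0, 100 * nm / ungapped, NA_real_)
    alen[, j] <- Biostrings::nchar(alnset)
  }
  best_of <- function(scores, lens, ids) {
    # best identity; ties by longer aligned length, then lexicographic id
    ok <- which(!is.na(scores))
    if (!length(ok)) return(NA_integer_)
    ord <- ok[order(-scores[ok], -lens[ok], ids[ok])]
    ord[1]
  }
  best_b_for_a <- vapply(seq_len(na_), function(i) {
    best_of(pid[i, ], alen[i, ], gb$feature_id)
  }, integer(1))
  best_a_for_b <- vapply(seq_len(nb), function(j) {
    best_of(pid[, j], alen[, j], ga$feature_id)
  }, integer(1))
  rows <- list()
  for (i in seq_len(na_)) {
    j <- best_b_for_a[i]
    if (is.na(j)) next
    if (!(!is.na(best_a_for_b[j]) && best_a_for_b[j] == i)) next
    # reciprocal best: extract the aligned strings for this pair only,
    # trim, and recompute identity on the trimmed columns
    aln <- structure(
      list(id_a = ga$feature_id[i], id_b = gb$feature_id[j],
           aligned_a = as.character(Biostrings::alignedPattern(alnsets[[j]][i])),
           aligned_b = as.character(Biostrings::alignedSubject(alnsets[[j]][i])),
           score = Biostrings::score(alnsets[[j]])[i], params = params),
      class = "pairwise_alignment"
    )
    n_full <- nchar(aln$aligned_a)
    if (trim) aln <- suppressWarnings(trim_conserved_blocks(aln))
    len <- nchar(aln$aligned_a)
    if (len == 0L) next
    id_final <- percent_identity(aln)
    if (id_final < min_identity) next
    rows[[length(rows) + 1L]] <- tibble(
      gene_a = ga$feature_id[i], gene_b = gb$feature_id[j],
      percent_identity = id_final,
      n_columns_compared = len, n_columns_trimmed = n_full - len,
      aligned_a = aln$aligned_a, aligned_b = aln$aligned_b
    )
  }
  out <- if (length(rows)) bind_rows(rows) else tibble(
    gene_a = character(), gene_b = character(), percent_identity = numeric(),
    n_columns_compared = integer(), n_columns_trimmed = integer(),
    aligned_a = character(), aligned_b = character()
  )
  attr(out, "unpaired_a") <- setdiff(ga$feature_id, out$gene_a)
  attr(out, "unpaired_b") <- setdiff(gb$feature_id, out$gene_b)
  ph_log("pair_orthologs", sprintf(
    "%d/%d + %d/%d genes paired", nrow(out), na_, nrow(out), nb
  ))
  out
}

#' Synteny blocks and discrepant regions between two gene orders
#'
#' Paired genes are grouped into maximal collinear runs (consecutive in both
#' orders, consistent orientation); genes private to one side are grouped
#' into maximal discrepant regions.
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (e.g. from
#'   [pair_orthologs()]).
#' @param order_a,order_b Character vectors giving the gene order of each
#'   region (all genes, paired or not).
#' @return A `synteny_report`: list with `blocks` (tibble: `block_id`,
#'   `gene_a`, `gene_b`, `orientation`) and `discrepant` (tibble:
#'   `region_id`, `side`, `gene`).
#' @export
find_synteny <- function(pairs, order_a, order_b) {
  stopifnot(all(pairs$gene_a %in% order_a), all(pairs$gene_b %in% order_b))
  partner <- setNames(pairs$gene_b, pairs$gene_a)
  paired_a <- order_a[order_a %in% pairs$gene_a]
  paired_b <- order_b[order_b %in% pairs$gene_b]
  rank_b <- setNames(seq_along(paired_b), paired_b)
  rb <- unname(rank_b[partner[paired_a]])
  block_id <- integer(length(paired_a))
  orientation <- character(0)
  cur <- 0L
  dir <- 0L
  for (i in seq_along(paired_a)) {
    if (i == 1L) {
      cur <- 1L
      dir <- 0L
    } else {
      step <- rb[i] - rb[i - 1L]
      if (dir == 0L && abs(step) == 1L) {
        dir <- step
      } else if (step != dir || dir == 0L) {
        cur <- cur + 1L
        dir <- 0L
      }
    }
    block_id[i] <- cur
  }
  blocks <- tibble(
    block_id = block_id, gene_a = paired_a,
    gene_b = unname(partner[paired_a])
  )
  ori <- blocks |>
    group_by(.data$block_id) |>
    summarise(orientation = {
      r <- rank_b[.data$gene_b]
      if (length(r) > 1 && r[2] < r[1]) "-" else "+"
    }, .groups = "drop")
  blocks <- left_join(blocks, ori, by = "block_id")
  runs_of_private <- function(ord, paired, side) {
    private <- !(ord %in% paired)
    if (!any(private)) {
      return(tibble(region_id = integer(), side = character(), gene = character()))
    }
    r <- rle(private)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out <- list()
    rid <- 0L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      rid <- rid + 1L
      out[[rid]] <- tibble(region_id = rid, side = side,
                           gene = ord[starts[k]:ends[k]])
    }
    bind_rows(out)
  }
  disc_a <- runs_of_private(order_a, pairs$gene_a, "a")
  disc_b <- runs_of_private(order_b, pairs$gene_b, "b")
  if (nrow(disc_b)) disc_b$region_id <- disc_b$region_id + max(0L, disc_a$region_id)
  structure(
    list(blocks = blocks, discrepant = bind_rows(disc_a, disc_b)),
    class = "synteny_report"
  )
}

#' @export
print.synteny_report <- function(x, ...) {
  n_blocks <- length(unique(x$blocks$block_id))
  n_disc <- length(unique(x$discrepant$region_id))
  cat(sprintf("Synteny report: %d collinear block(s), %d discrepant region(s)\n",
              n_blocks, n_disc))
  invisible(x)
}
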