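# Seeded homology search with Karlin-Altschul style E-values, and the
# presence/absence screening matrix built on it.

# Solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for lambda under uniform base
# frequencies and match/mismatch scoring.
ka_lambda <- function(match = 2, mismatch = -3, p = rep(0.25, 4)) {
  f <- function(l) {
    sum(outer(p, p) * exp(l * ifelse(diag(4) == 1, match, mismatch))) - 1
  }
  uniroot(f, c(1e-8, 10), tol = 1e-10)$root
}

# E-value calibration constant; only the ranking and a broad cutoff are used
# downstream, so K is fixed rather than estimated iteratively.
KA_K <- 0.1

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.kmer_index <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  split(starts, kmers)
}

# ungapped X-drop extension of a seed; returns best-scoring segment
.extend_seed <- function(qc, sc, qpos, spos, k, match, mismatch, xdrop) {
  score <- k * match
  # extend right
  best <- score
  bq_r <- qpos + k - 1L
  bs_r <- spos + k - 1L
  i <- qpos + k
  j <- spos + k
  cur <- score
  while (i <= length(qc) && j <= length(sc)) {
    cur <- cur + if (qc[i] == sc[j]) match else mismatch
    if (cur > best) {
      best <- cur
      bq_r <- i
      bs_r <- j
    }
    if (best - cur > xdrop) break
    i <- i + 1L
    j <- j + 1L
  }
  # extend left
  score <- best
  bq_l <- qpos
  bs_l <- spos
  i <- qpos - 1L
  j <- spos - 1L
  cur <- score
  while (i >= 1L && j >= 1L) {
    cur <- cur + if (qc[i] == sc[j]) match else mismatch
    if (cur > score) {
      score <- cur
      bq_l <- i
      bs_l <- j
    }
    if (score - cur > xdrop) break
    i <- i - 1L
    j <- j - 1L
  }
  ident <- mean(qc[bq_l:bq_r] == sc[bs_l:bs_r])
  list(score = score, q_start = bq_l, q_end = bq_r,
       s_start = bs_l, s_end = bs_r, identity = 100 * ident)
}

#' Homology search of query features against a sequence database
#'
#' Seeded local search: exact k-mer seeds, one ungapped X-drop extension per
#' diagonal, and a Karlin-Altschul style expect value
#' `E = K * m * n * exp(-lambda * S)` with lambda solved from the scoring
#' scheme. Both query strands are searched. Only hits with
#' `expect < evalue_cutoff` are returned, sorted by ascending expect.
#'
#' @param queries Named character vector of query sequences, or a data frame
#'   with `feature_id` and `cds` columns.
#' @param database Named character vector of subject sequences, or a
#'   `genome_record` (its contigs are searched), or a list of either.
#' @param evalue_cutoff Maximum reported expect value (default `1e-5`).
#' @param word_size Seed k-mer length.
#' @param match,mismatch Scoring used for seeds/extension and the E-value.
#' @param xdrop Extension stops when the running score falls this far below
#'   the best score.
#' @return Tibble of hits: `query_id`, `subject_id`, `score`, `expect`,
#'   `identity`, `strand`, and segment coordinates.
#' @export
search_homologs <- function(queries, database, evalue_cutoff = 1e-5,
                            word_size = 11, match = 2, mismatch = -3,
                            xdrop = 20) {
  q <- .as_cds_table(queries)
  db <- .as_subject_seqs(database)
  empty <- tibble(
    query_id = character(), subject_id = character(), score = numeric(),
    expect = numeric(), identity = numeric(), strand = character(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer()
  )
  if (!length(db)) {
    warn("empty database; no hits")
    return(empty)
  }
  lambda <- ka_lambda(match, mismatch)
  m_total <- sum(nchar(db))
  idx <- lapply(db, .kmer_index, k = word_size)
  db_chars <- lapply(db, function(s) strsplit(s, "")[[1]])
  rows <- list()
  for (qi in seq_len(nrow(q))) {
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q$cds[qi] else revcomp(q$cds[qi])
      nq <- nchar(qs)
      if (nq < word_size) next
      qc <- strsplit(qs, "")[[1]]
      qstarts <- seq_len(nq - word_size + 1L)
      qkmers <- substring(qs, qstarts, qstarts + word_size - 1L)
      for (sj in seq_along(db)) {
        hits_idx <- idx[[sj]]
        seen_diag <- new.env(parent = emptyenv())
        best <- NULL
        for (t in seq_along(qkmers)) {
          spos_all <- hits_idx[[qkmers[t]]]
          if (is.null(spos_all)) next
          for (spos in spos_all) {
            dkey <- as.character(qstarts[t] - spos)
            if (!is.null(seen_diag[[dkey]])) next
            assign(dkey, TRUE, envir = seen_diag)
            ext <- .extend_seed(qc, db_chars[[sj]], qstarts[t], spos,
                                word_size, match, mismatch, xdrop)
            if (is.null(best) || ext$score > best$score) best <- ext
          }
        }
        if (is.null(best)) next
        expect <- KA_K * m_total * nq * exp(-lambda * best$score)
        if (expect >= evalue_cutoff) next
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q$feature_id[qi], subject_id = names(db)[sj],
          score = best$score, expect = expect, identity = best$identity,
          strand = strand,
          q_start = best$q_start, q_end = best$q_end,
          s_start = best$s_start, s_end = best$s_end
        )
      }
    }
  }
  out <- if (length(rows)) bind_rows(rows) else empty
  arrange(out, .data$expect)
}

.as_subject_seqs <- function(database) {
  if (length(database) == 0L) return(character(0))
  if (inherits(database, "genome_record")) {
    return(database$contigs)
  }
  if (is.list(database) && !is.data.frame(database)) {
    seqs <- character(0)
    for (nm in names(database)) {
      el <- database[[nm]]
      if (inherits(el, "genome_record")) {
        s <- el$contigs
        names(s) <- paste(nm, names(s), sep = ":")
        seqs <- c(seqs, s)
      } else {
        seqs <- c(seqs, setNames(as.character(el), nm))
      }
    }
    return(seqs)
  }
  if (is.data.frame(database)) {
    tb <- .as_cds_table(database)
    return(setNames(tb$cds, tb$feature_id))
  }
  stopifnot(is.character(database))
  if (is.null(names(database))) names(database) <- paste0("subject", seq_along(database))
  toupper(database)
}

#' Presence/absence screening of queries across a genome set
#'
#' Runs [search_homologs()] for each genome; a query is present in a genome
#' when at least one hit falls below the E-value cutoff. Raising the cutoff
#' never removes a presence call.
#'
#' @param queries As in [search_homologs()].
#' @param genome_set Named list of `genome_record` objects or named character
#'   sequences.
#' @inheritParams search_homologs
#' @return Long tibble `genome_id`, `query_id`, `present` (logical), with
#'   per-genome and per-query totals as attributes `genome_totals` and
#'   `query_totals`.
#' @export
presence_matrix <- function(queries, genome_set, evalue_cutoff = 1e-5, ...) {
  q <- .as_cds_table(queries)
  stopifnot(length(names(genome_set)) == length(genome_set))
  rows <- purrr::map(names(genome_set), function(g) {
    hits <- search_homologs(q, genome_set[[g]], evalue_cutoff = evalue_cutoff, ...)
    tibble(genome_id = g, query_id = q$feature_id,
           present = q$feature_id %in% hits$query_id)
  })
  out <- bind_rows(rows)
  attr(out, "genome_totals") <- out |>
    group_by(.data$genome_id) |>
    summarise(n_present = sum(.data$present), .groups = "drop")
  attr(out, "query_totals") <- out |>
    group_by(.data$query_id) |>
    summarise(n_present = sum(.data$present), .groups = "drop")
  out
}
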