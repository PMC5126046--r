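# Nei-Gojobori (1986) synonymous/nonsynonymous divergence.
#
# The method counts, for each codon, the fraction of single-base changes that
# are synonymous (site counting), averages synonymous/nonsynonymous step
# counts over all mutational pathways between two codons (difference
# counting), and applies the Jukes-Cantor multiple-hit correction to the
# per-site proportions. Changes to and pathways through stop codons are
# excluded, matching the behaviour of mainstream implementations.

.ph_env <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

#' Sense codons of a genetic code
#'
#' @param code Named character vector mapping codons to amino acids, with
#'   `"*"` for stops. Defaults to the standard genetic code.
#' @return Character vector of the 61 (for the standard code) sense codons.
#' @export
sense_codons <- function(code = Biostrings::GENETIC_CODE) {
  names(code)[code != "*"]
}

.permutations <- function(x) {
  n <- length(x)
  if (n <= 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

.mutate_codon <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

.site_fractions_one <- function(codon, code) {
  aa <- unname(code[[codon]])
  s <- 0
  for (pos in 1:3) {
    syn <- 0L
    admissible <- 0L
    for (b in setdiff(DNA_BASES, substr(codon, pos, pos))) {
      maa <- unname(code[[.mutate_codon(codon, pos, b)]])
      if (maa == "*") next # changes to stops excluded from both counts
      admissible <- admissible + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (admissible > 0L) s <- s + syn / admissible
  }
  c(s = s, n = 3 - s)
}

.pathway_one <- function(codon_a, codon_b, code) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L) {
    return(c(sd = 0, nd = 0, no_legal_path = 0))
  }
  legal <- matrix(numeric(0), ncol = 2)
  all_paths <- matrix(numeric(0), ncol = 2)
  for (ord in .permutations(diff_pos)) {
    cur <- codon_a
    sd <- 0L
    nd <- 0L
    through_stop <- FALSE
    for (pos in ord) {
      nxt <- .mutate_codon(cur, pos, substr(codon_b, pos, pos))
      if (unname(code[[nxt]]) == "*") through_stop <- TRUE
      if (unname(code[[nxt]]) == unname(code[[cur]])) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    all_paths <- rbind(all_paths, c(sd, nd))
    if (!through_stop) legal <- rbind(legal, c(sd, nd))
  }
  if (nrow(legal) > 0L) {
    c(sd = mean(legal[, 1]), nd = mean(legal[, 2]), no_legal_path = 0)
  } else {
    # all orderings pass through a stop: fall back to the unrestricted
    # average and flag it (logged by callers)
    c(sd = mean(all_paths[, 1]), nd = mean(all_paths[, 2]), no_legal_path = 1)
  }
}

# Cached lookup tables for the (injectable) genetic code: per-codon site
# fractions, 61x61 pathway-difference matrices, and the synonymous
# single-base substitution options used by the simulator.
codon_tables <- function(code = Biostrings::GENETIC_CODE) {
  key <- paste(code, collapse = "")
  cached <- .ph_env$tables
  if (!is.null(cached) && identical(cached$key, key)) {
    return(cached)
  }
  codons <- sense_codons(code)
  nc <- length(codons)
  sf <- vapply(codons, .site_fractions_one, numeric(2), code = code)
  sd_mat <- matrix(0, nc, nc, dimnames = list(codons, codons))
  nd_mat <- sd_mat
  stopflag <- matrix(FALSE, nc, nc, dimnames = list(codons, codons))
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (j < i) {
        sd_mat[i, j] <- sd_mat[j, i]
        nd_mat[i, j] <- nd_mat[j, i]
        stopflag[i, j] <- stopflag[j, i]
      } else if (j > i) {
        pw <- .pathway_one(codons[i], codons[j], code)
        sd_mat[i, j] <- pw[["sd"]]
        nd_mat[i, j] <- pw[["nd"]]
        stopflag[i, j] <- pw[["no_legal_path"]] > 0
      }
    }
  }
  syn_options <- lapply(codons, function(cod) {
    aa <- unname(code[[cod]])
    out <- list()
    for (pos in 1:3) {
      for (b in setdiff(DNA_BASES, substr(cod, pos, pos))) {
        mut <- .mutate_codon(cod, pos, b)
        if (unname(code[[mut]]) == aa) out[[length(out) + 1L]] <- c(pos = pos, base = b)
      }
    }
    out
  })
  names(syn_options) <- codons
  tabs <- list(
    key = key, code = code, codons = codons,
    s = sf["s", ], n = sf["n", ],
    sd = sd_mat, nd = nd_mat, no_legal_path = stopflag,
    syn_options = syn_options
  )
  .ph_env$tables <- tabs
  tabs
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the three positions, the fraction of admissible single-base
#' changes (changes producing stop codons are excluded from numerator and
#' denominator) that leave the encoded amino acid unchanged. The fractions
#' sum with the nonsynonymous complement to 3.
#'
#' @param codon A single sense codon (3 characters, A/C/G/T).
#' @param code Genetic code, as in [sense_codons()].
#' @return Named numeric vector `c(s = , n = )` with `s + n == 3`.
#' @examples
#' synonymous_site_fractions("GGG") # fourfold-degenerate third position: s = 1
#' @export
synonymous_site_fractions <- function(codon, code = Biostrings::GENETIC_CODE) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || !all(strsplit(codon, "")[[1]] %in% DNA_BASES)) {
    abort(sprintf("`codon` must be 3 unambiguous bases, got \"%s\"", codon))
  }
  if (unname(code[[codon]]) == "*") {
    abort(sprintf("\"%s\" is a stop codon; site fractions are undefined", codon))
  }
  tabs <- codon_tables(code)
  c(s = unname(tabs$s[[codon]]), n = unname(tabs$n[[codon]]))
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' When the codons differ at k positions, the k! orderings of single-base
#' changes are averaged; orderings passing through a stop codon are excluded.
#' If every ordering passes through a stop, the unrestricted average is used
#' and the event is logged.
#'
#' @param codon_a,codon_b Sense codons.
#' @inheritParams synonymous_site_fractions
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions.
#' @examples
#' pathway_differences("GGG", "GGA") # synonymous single step
#' @export
pathway_differences <- function(codon_a, codon_b, code = Biostrings::GENETIC_CODE) {
  for (cod in c(codon_a, codon_b)) {
    if (nchar(cod) != 3L || !all(strsplit(toupper(cod), "")[[1]] %in% DNA_BASES)) {
      abort(sprintf("codons must be 3 unambiguous bases, got \"%s\"", cod))
    }
    if (unname(code[[toupper(cod)]]) == "*") {
      abort(sprintf("\"%s\" is a stop codon", cod))
    }
  }
  tabs <- codon_tables(code)
  a <- toupper(codon_a)
  b <- toupper(codon_b)
  if (tabs$no_legal_path[a, b]) {
    ph_log("codon_evolution",
      sprintf("all pathways between %s and %s pass through stops; stop-exclusion relaxed", a, b),
      force = TRUE
    )
  }
  c(sd = tabs$sd[a, b], nd = tabs$nd[a, b])
}

# Split two aligned, equal-length sequences into retained codon columns.
# Columns holding a gap, an ambiguity code, or a stop codon in either
# sequence are dropped and counted.
codon_columns <- function(seq_a, seq_b, code = Biostrings::GENETIC_CODE) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("sequences must be aligned (equal length); align them first")
  }
  len <- nchar(seq_a)
  n_cod <- len %/% 3L
  if (len %% 3L != 0L) {
    warn(sprintf("alignment length %d is not a multiple of 3; trailing %d column(s) ignored", len, len %% 3L))
  }
  if (n_cod == 0L) abort("no complete codon columns in input")
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  cod_a <- substring(seq_a, starts, starts + 2L)
  cod_b <- substring(seq_b, starts, starts + 2L)
  clean <- function(x) grepl("^[ACGT]{3}$", x)
  ok <- clean(cod_a) & clean(cod_b)
  n_gap_amb <- sum(!ok)
  is_stop <- function(x) unname(code[x]) == "*"
  stop_col <- ok & (is_stop(cod_a) | is_stop(cod_b))
  n_stop <- sum(stop_col)
  keep <- ok & !stop_col
  list(
    codon_a = cod_a[keep], codon_b = cod_b[keep],
    n_retained = sum(keep), n_dropped_gap_ambiguous = n_gap_amb,
    n_dropped_stop = n_stop
  )
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 / 3 * p), NA_real_)
}

# per-column statistics used by ng86 and the codon bootstrap
.ng_columns <- function(cols, tabs) {
  ia <- match(cols$codon_a, tabs$codons)
  ib <- match(cols$codon_b, tabs$codons)
  list(
    s_bar = (tabs$s[ia] + tabs$s[ib]) / 2,
    sd = tabs$sd[cbind(ia, ib)],
    nd = tabs$nd[cbind(ia, ib)],
    no_legal = tabs$no_legal_path[cbind(ia, ib)]
  )
}

.ng_point <- function(colstats, n_codons) {
  S <- sum(colstats$s_bar)
  N <- 3 * n_codons - S
  Sd <- sum(colstats$sd)
  Nd <- sum(colstats$nd)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc_correct(pS), dN = jc_correct(pN))
}

#' Nei-Gojobori divergence between two aligned coding sequences
#'
#' Computes synonymous (S) and nonsynonymous (N) site counts (averaged over
#' the two sequences), pathway-averaged difference counts (Sd, Nd), the
#' proportions pS/pN, and Jukes-Cantor-corrected rates dS/dN. Codon columns
#' containing gaps, ambiguity codes, or stop codons are dropped pairwise.
#' When `pS >= 3/4` (or `pN`) the corrected rate is undefined and flagged.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length (gaps as
#'   `-`), or a [global_align()] result passed as `seq_a`.
#' @param n_boot Number of codon-bootstrap replicates for standard errors
#'   (0 disables the bootstrap).
#' @param seed Optional integer seed controlling the bootstrap resampling.
#' @inheritParams synonymous_site_fractions
#' @return An object of class `ng_result`; see [tidy.ng_result()].
#' @examples
#' fit <- ng86("TTTGGGAAA", "TTTGGAAAA")
#' fit$dS # about 1.207
#' @export
ng86 <- function(seq_a, seq_b = NULL, n_boot = 0, seed = NULL,
                 code = Biostrings::GENETIC_CODE) {
  if (inherits(seq_a, "pairwise_alignment")) {
    seq_b <- seq_a$aligned_b
    seq_a <- seq_a$aligned_a
  }
  cols <- codon_columns(seq_a, seq_b, code)
  if (cols$n_retained == 0L) {
    abort("no codon columns retained after filtering gaps/ambiguity/stops")
  }
  tabs <- codon_tables(code)
  cs <- .ng_columns(cols, tabs)
  pt <- .ng_point(cs, cols$n_retained)
  flags <- character(0)
  if (any(cs$no_legal)) {
    flags <- c(flags, "stop_exclusion_relaxed")
    ph_log("codon_evolution",
      sprintf("%d codon column(s) had no stop-free pathway; unrestricted average used", sum(cs$no_legal)),
      force = TRUE
    )
  }
  if (is.na(pt$dS) && !is.na(pt$pS)) flags <- c(flags, "dS_saturated")
  if (is.na(pt$dN) && !is.na(pt$pN)) flags <- c(flags, "dN_saturated")
  se <- list(dS = NA_real_, dN = NA_real_)
  if (n_boot > 0) {
    for (stat in c("dS", "dN")) {
      bs <- .codon_bootstrap(cs, cols$n_retained, stat, n_boot, seed)
      se[[stat]] <- bs$se
      if (bs$flagged) flags <- c(flags, paste0("bootstrap_unstable_", stat))
    }
  }
  structure(
    list(
      S = pt$S, N = pt$N, Sd = pt$Sd, Nd = pt$Nd,
      pS = pt$pS, pN = pt$pN, dS = pt$dS, dN = pt$dN,
      se_dS = se$dS, se_dN = se$dN,
      n_codons = cols$n_retained,
      n_dropped_gap_ambiguous = cols$n_dropped_gap_ambiguous,
      n_dropped_stop = cols$n_dropped_stop,
      n_reps = n_boot, seed = seed, flags = flags
    ),
    class = "ng_result"
  )
}

.codon_bootstrap <- function(colstats, n_codons, statistic, n_reps, seed) {
  draw <- function() {
    # multinomial column weights are equivalent to resampling columns with
    # replacement and keep the whole bootstrap as matrix products
    w <- stats::rmultinom(n_reps, n_codons, rep(1 / n_codons, n_codons))
    S_rep <- as.numeric(crossprod(w, colstats$s_bar))
    N_rep <- 3 * n_codons - S_rep
    Sd_rep <- as.numeric(crossprod(w, colstats$sd))
    Nd_rep <- as.numeric(crossprod(w, colstats$nd))
    if (statistic == "dS") jc_correct(ifelse(S_rep > 0, Sd_rep / S_rep, NA_real_))
    else jc_correct(ifelse(N_rep > 0, Nd_rep / N_rep, NA_real_))
  }
  reps <- with_seed(seed, draw())
  n_undef <- sum(is.na(reps))
  flagged <- FALSE
  if (n_undef > n_reps / 2) {
    warn(sprintf("%d of %d bootstrap replicates undefined; SE flagged", n_undef, n_reps))
    flagged <- TRUE
  }
  ok <- reps[!is.na(reps)]
  list(se = if (length(ok) >= 2) sd(ok) else NA_real_,
       n_defined = length(ok), flagged = flagged)
}

#' Codon-bootstrap standard error of a divergence statistic
#'
#' Resamples codon columns with replacement and reports the standard
#' deviation of the replicate statistics. Replicates where the statistic is
#' undefined (Jukes-Cantor saturation) are dropped and counted.
#'
#' @inheritParams ng86
#' @param statistic `"dS"` or `"dN"`.
#' @param n_reps Number of bootstrap replicates.
#' @return List with `se`, `n_defined`, `n_reps`, `flagged`.
#' @export
bootstrap_se <- function(seq_a, seq_b = NULL, statistic = c("dS", "dN"),
                         n_reps = 1000, seed = NULL,
                         code = Biostrings::GENETIC_CODE) {
  statistic <- match.arg(statistic)
  if (inherits(seq_a, "pairwise_alignment")) {
    seq_b <- seq_a$aligned_b
    seq_a <- seq_a$aligned_a
  }
  cols <- codon_columns(seq_a, seq_b, code)
  if (cols$n_retained < 2L) abort("need at least 2 codon columns to bootstrap")
  tabs <- codon_tables(code)
  cs <- .ng_columns(cols, tabs)
  out <- .codon_bootstrap(cs, cols$n_retained, statistic, n_reps, seed)
  out$n_reps <- n_reps
  out
}

#' Nei-Gojobori divergence for a table of sequence pairs
#'
#' Tidy wrapper applying [ng86()] to every row of a pair table.
#'
#' @param pairs Data frame with columns `cds_a` and `cds_b` (aligned or
#'   equal-length coding sequences); extra columns are carried through.
#' @inheritParams ng86
#' @return A tibble with one row per pair and the `ng_result` fields.
#' @export
ng86_pairs <- function(pairs, n_boot = 0, seed = NULL,
                       code = Biostrings::GENETIC_CODE) {
  stopifnot(all(c("cds_a", "cds_b") %in% names(pairs)))
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    s <- if (is.null(seed)) NULL else seed + i
    tidy(ng86(pairs$cds_a[i], pairs$cds_b[i], n_boot = n_boot, seed = s, code = code))
  })
  dplyr::bind_cols(
    dplyr::select(as_tibble(pairs), -dplyr::any_of(c("cds_a", "cds_b"))),
    dplyr::bind_rows(res)
  )
}

#' @export
print.ng_result <- function(x, ...) {
  cat("Nei-Gojobori divergence\n")
  cat(sprintf("  codons retained: %d (dropped %d gap/ambiguous, %d stop)\n",
              x$n_codons, x$n_dropped_gap_ambiguous, x$n_dropped_stop))
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n", x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  pS = %.4f  dS = %s%s\n", x$pS,
              ifelse(is.na(x$dS), "undefined (saturated)", sprintf("%.4f", x$dS)),
              ifelse(is.na(x$se_dS), "", sprintf(" (SE %.4f)", x$se_dS))))
  cat(sprintf("  pN = %.4f  dN = %s%s\n", x$pN,
              ifelse(is.na(x$dN), "undefined (saturated)", sprintf("%.4f", x$dN)),
              ifelse(is.na(x$se_dN), "", sprintf(" (SE %.4f)", x$se_dN))))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a Nei-Gojobori result
#'
#' @param x An `ng_result` from [ng86()].
#' @param ... Unused.
#' @return One-row tibble of site counts, differences, proportions,
#'   corrected rates, bootstrap SEs, and flags.
#' @export
tidy.ng_result <- function(x, ...) {
  tibble(
    S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
    dS = x$dS, dN = x$dN, se_dS = x$se_dS, se_dN = x$se_dN,
    n_codons = x$n_codons, flags = paste(x$flags, collapse = ";")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# evaluate `code` with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}
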