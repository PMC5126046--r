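# Independent brute-force oracles used to check the package's
# implementations on small inputs.

# Exhaustive enumeration of all global alignments under affine gaps
# (a gap run of length k costs gap_open + k * gap_extend).
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  na <- nchar(a)
  nb <- nchar(b)
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > na && j > nb) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= na && j <= nb) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      rec(i + 1L, j + 1L, "M", score + s)
    }
    if (i <= na) {
      pen <- gap_extend + if (state == "A") 0 else gap_open
      rec(i + 1L, j, "A", score - pen)
    }
    if (j <= nb) {
      pen <- gap_extend + if (state == "B") 0 else gap_open
      rec(i, j + 1L, "B", score - pen)
    }
  }
  rec(1L, 1L, "M", 0)
  best
}

# Direct enumeration of codon mutational pathways (orderings hard-coded),
# with the stop-exclusion rule and its unrestricted fallback.
oracle_pathway <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  orders <- switch(as.character(k),
    "1" = list(1L),
    "2" = list(c(1L, 2L), c(2L, 1L)),
    "3" = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  legal <- list()
  unrestricted <- list()
  for (o in orders) {
    cur <- a
    sd <- 0L
    nd <- 0L
    ok <- TRUE
    for (q in pos[o]) {
      nxt <- cur
      substr(nxt, q, q) <- substr(b, q, q)
      if (code[[nxt]] == "*") ok <- FALSE
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    unrestricted[[length(unrestricted) + 1L]] <- c(sd, nd)
    if (ok) legal[[length(legal) + 1L]] <- c(sd, nd)
  }
  use <- if (length(legal)) legal else unrestricted
  m <- colMeans(do.call(rbind, use))
  c(sd = m[1], nd = m[2])
}

# Direct enumeration of single-base changes for site fractions.
oracle_site_fractions <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    syn <- 0
    adm <- 0
    for (bb in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- bb
      if (code[[mut]] == "*") next
      adm <- adm + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (adm > 0) s <- s + syn / adm
  }
  s
}

# Exact two-tailed Mann-Whitney p-value by enumeration of all
# choose(n1+n2, n1) labelings (symmetric-tail definition).
oracle_mwu_p <- function(g1, g2) {
  n1 <- length(g1)
  vals <- c(g1, g2)
  n <- length(vals)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-9)
}

# Brute-force minimum Dollo losses: enumerate loss-edge subsets within the
# carriers' MRCA clade and take the smallest subset reproducing the
# presence pattern (a tip carries the character iff no loss edge lies on
# its path from the MRCA).
oracle_dollo <- function(tree, carriers) {
  ntip <- length(tree$tip.label)
  carrier_tip <- which(tree$tip.label %in% carriers)
  if (length(carrier_tip) == 1L) return(0L)
  mrca <- ape::getMRCA(tree, carrier_tip)
  parent <- integer(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) parent[tree$edge[e, 2]] <- tree$edge[e, 1]
  in_clade <- function(v) {
    while (v != mrca && v != 0L) v <- parent[v]
    v == mrca
  }
  clade_children <- which(vapply(seq_along(parent), function(v) {
    v != mrca && in_clade(v)
  }, logical(1)))
  edges <- clade_children # identify each edge by its child node
  path_edges <- lapply(seq_len(ntip), function(t) {
    if (!in_clade(t) && t != mrca) return(integer(0))
    p <- integer(0)
    v <- t
    while (v != mrca) {
      p <- c(p, v)
      v <- parent[v]
    }
    p
  })
  clade_tips <- which(vapply(seq_len(ntip), function(t) t == mrca || in_clade(t), logical(1)))
  target <- clade_tips %in% carrier_tip
  best <- Inf
  for (mask in 0:(2^length(edges) - 1)) {
    losses <- edges[bitwAnd(bitwShiftR(mask, seq_along(edges) - 1L), 1L) == 1L]
    if (length(losses) >= best) next
    present <- vapply(clade_tips, function(t) {
      !any(path_edges[[t]] %in% losses)
    }, logical(1))
    if (all(present == target)) best <- length(losses)
  }
  as.integer(best)
}

# Exhaustive substring search for the att core: all substrings of attP
# that occur in all four sequences overlapping each junction; returns the
# maximal length and the set of strings achieving it.
oracle_core_set <- function(ctx, max_core = 50) {
  occ_overlaps <- function(pat, seq, offset) {
    len <- nchar(pat)
    hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(FALSE)
    any(hits <= offset + 1L & hits + len - 1L >= offset)
  }
  ap <- ctx$attP
  for (len in rev(seq_len(min(max_core, nchar(ap$seq))))) {
    found <- character(0)
    for (s in seq_len(nchar(ap$seq) - len + 1L)) {
      cand <- substr(ap$seq, s, s + len - 1L)
      if (all(vapply(ctx, function(site) {
        occ_overlaps(cand, site$seq, site$offset)
      }, logical(1)))) {
        found <- union(found, cand)
      }
    }
    if (length(found)) return(list(length = len, cores = found))
  }
  list(length = 0L, cores = character(0))
}

# Exhaustive inverted-repeat search mirroring the anchored-arm model.
oracle_inverted_repeats <- function(seq, core_span, search_window = 200,
                                    min_arm = 5, max_mismatch = 1, max_gap = 0) {
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  hamming <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  cs <- core_span[1]
  ce <- core_span[2]
  L <- nchar(seq)
  best <- NULL
  for (len in seq_len(min(search_window, cs - 1L, L - ce))) {
    if (len < min_arm) next
    for (gl in 0:max_gap) {
      le <- cs - 1L - gl
      ls <- le - len + 1L
      if (ls < 1L) next
      for (gr in 0:max_gap) {
        rs <- ce + 1L + gr
        re <- rs + len - 1L
        if (re > L) next
        mm <- hamming(rc(substr(seq, ls, le)), substr(seq, rs, re))
        if (mm > max_mismatch) next
        cand <- list(arm_length = len, mismatches = mm, gap = gl + gr,
                     left_span = c(ls, le), right_span = c(rs, re))
        if (is.null(best) ||
            cand$arm_length > best$arm_length ||
            (cand$arm_length == best$arm_length && cand$mismatches < best$mismatches) ||
            (cand$arm_length == best$arm_length && cand$mismatches == best$mismatches &&
             cand$gap < best$gap)) {
          best <- cand
        }
      }
    }
  }
  best
}

# random DNA helpers for property tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
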