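# Attachment-site analysis: build the circularized-phage attP junction,
# find the core sequence shared by attL/attR/attB/attP across each junction,
# and detect inverted-repeat arms flanking the core.

.take_head <- function(seq, n) substr(seq, 1L, n)
.take_tail <- function(seq, n) substr(seq, nchar(seq) - n + 1L, nchar(seq))

#' Build the attP junction of a circularized phage
#'
#' A temperate phage excises as a circle, joining its 3' end to its 5'
#' start; attP is that junction: the last `window` bases of the prophage
#' concatenated with its first `window` bases, with the junction offset at
#' `window`.
#'
#' @param prophage_seq Prophage nucleotide sequence.
#' @param window Bases taken from each end (default 300). If the prophage is
#'   shorter than `window`, full halves are used with a warning.
#' @return List with `seq` and `offset` (bases before the junction).
#' @examples
#' build_attP("AAAACCCC", window = 2) # "CCAA", offset 2
#' @export
build_attP <- function(prophage_seq, window = 300) {
  L <- nchar(prophage_seq)
  w <- window
  if (L < window) {
    w <- L %/% 2L
    warn(sprintf("prophage (%d bp) shorter than window (%d); using %d bp halves", L, window, w))
  }
  list(seq = paste0(.take_tail(prophage_seq, w), .take_head(prophage_seq, w)),
       offset = w)
}

#' Build the four attachment-site junction sequences
#'
#' Given a prophage and its host flanks, constructs attL (host left +
#' prophage start), attR (prophage end + host right), attB (host left +
#' host right, i.e. the un-integrated site), and attP (the circularized
#' phage junction), each with the junction offset at `window`.
#'
#' @param prophage_seq Prophage sequence (starting at its attL core).
#' @param left_flank,right_flank Host sequence to the left/right of the
#'   prophage (the right flank beginning at the attR core).
#' @param window Bases taken from each side of every junction.
#' @return An `att_context`: named list of `list(seq, offset)` for
#'   `attL`, `attR`, `attB`, `attP`.
#' @export
att_context <- function(prophage_seq, left_flank, right_flank, window = 300) {
  w <- min(window, nchar(prophage_seq) %/% 2L, nchar(left_flank), nchar(right_flank))
  if (w < window) {
    warn(sprintf("window reduced to %d to fit the shortest input", w))
  }
  junction <- function(left, right) list(seq = paste0(left, right), offset = w)
  structure(
    list(
      attL = junction(.take_tail(left_flank, w), .take_head(prophage_seq, w)),
      attR = junction(.take_tail(prophage_seq, w), .take_head(right_flank, w)),
      attB = junction(.take_tail(left_flank, w), .take_head(right_flank, w)),
      attP = junction(.take_tail(prophage_seq, w), .take_head(prophage_seq, w))
    ),
    class = "att_context"
  )
}

# does an occurrence [s, e] overlap the junction between offset and offset+1
# (touching either junction-adjacent base counts, so length-1 cores work)
.overlaps_junction <- function(s, e, offset) s <= offset + 1L & e >= offset

# occurrences of `pat` in `seq` that overlap the junction; returns start
# positions
.junction_occurrences <- function(pat, seq, offset) {
  if (!nzchar(pat)) return(integer(0))
  starts <- c()
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(seq, from, nchar(seq)), fixed = TRUE)
    if (hit == -1L) break
    s <- from + as.integer(hit) - 1L
    starts <- c(starts, s)
    from <- s + 1L
    if (from > nchar(seq)) break
  }
  len <- nchar(pat)
  starts[.overlaps_junction(starts, starts + len - 1L, offset)]
}

#' Find the attachment-site core sequence
#'
#' The core is the longest string occurring in all four att sequences with
#' an occurrence overlapping each sequence's junction offset (the
#' recombination-crossover semantics: the core spans each junction). Ties
#' are broken by the attP occurrence closest to the junction, then
#' lexicographically. Cores can be as short as a single base.
#'
#' @param ctx An [att_context()].
#' @param max_core Maximum core length considered.
#' @return An `att_core`: list with `core`, `length`, and the per-site
#'   occurrence `positions`; or a `core = NA` result if no common
#'   junction-spanning string exists.
#' @export
find_core <- function(ctx, max_core = 50) {
  sites <- names(ctx)
  ap <- ctx$attP
  max_len <- min(max_core, nchar(ap$seq))
  for (len in rev(seq_len(max_len))) {
    s_min <- max(1L, ap$offset - len + 1L)
    s_max <- min(ap$offset + 1L, nchar(ap$seq) - len + 1L)
    if (s_max < s_min) next
    cand <- unique(substring(ap$seq, s_min:s_max, (s_min:s_max) + len - 1L))
    cand <- cand[grepl("^[ACGTacgt]+$", cand)]
    found <- list()
    for (core in cand) {
      positions <- list()
      ok <- TRUE
      for (site in sites) {
        occ <- .junction_occurrences(core, ctx[[site]]$seq, ctx[[site]]$offset)
        if (!length(occ)) {
          ok <- FALSE
          break
        }
        # occurrence closest to the junction centre
        centre <- ctx[[site]]$offset + 0.5
        occ <- occ[order(abs(occ + (len - 1) / 2 - centre))]
        positions[[site]] <- occ[1]
      }
      if (ok) found[[core]] <- positions
    }
    if (length(found)) {
      cores <- names(found)
      centre <- ap$offset + 0.5
      dist <- vapply(cores, function(cc) {
        abs(found[[cc]]$attP + (len - 1) / 2 - centre)
      }, numeric(1))
      pick <- cores[order(dist, cores)][1]
      return(structure(
        list(core = pick, length = len,
             positions = tibble(
               site = sites,
               start = vapply(sites, function(s) found[[pick]][[s]], numeric(1)),
               end = vapply(sites, function(s) found[[pick]][[s]], numeric(1)) + len - 1
             )),
        class = "att_core"
      ))
    }
  }
  structure(list(core = NA_character_, length = 0L, positions = NULL),
            class = "att_core")
}

#' @export
print.att_core <- function(x, ...) {
  if (is.na(x$core)) {
    cat("No common junction-spanning core found\n")
  } else {
    cat(sprintf("att core \"%s\" (%d bp), spanning all four junctions\n",
                x$core, x$length))
  }
  invisible(x)
}

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Detect inverted-repeat arms flanking an att core
#'
#' Searches for a pair of arms abutting the core (left arm ending at the
#' core start, right arm beginning after the core end, with up to `max_gap`
#' intervening bases on each side) such that the right arm is within
#' `max_mismatch` Hamming mismatches of the reverse complement of the left
#' arm. The highest-scoring pair wins: longest arm, then fewest mismatches,
#' then smallest total gap.
#'
#' @param seq Sequence containing the core (e.g. the attP junction).
#' @param core_span Integer vector `c(start, end)` of the core in `seq`.
#' @param search_window Maximum distance from the core an arm may extend.
#' @param min_arm Minimum arm length.
#' @param max_mismatch Maximum Hamming mismatches between the right arm and
#'   the reverse complement of the left arm.
#' @param max_gap Maximum bases between core and arm on each side.
#' @return List with `left_arm`, `right_arm`, `arm_length`, `mismatches`,
#'   `left_span`, `right_span`; or `NULL` when no admissible pair exists.
#' @export
find_inverted_repeats <- function(seq, core_span, search_window = 200,
                                  min_arm = 5, max_mismatch = 1, max_gap = 0) {
  cs <- core_span[1]
  ce <- core_span[2]
  L <- nchar(seq)
  best <- NULL
  max_len <- min(search_window, cs - 1L, L - ce)
  if (max_len < min_arm) return(NULL)
  for (len in seq(max_len, min_arm)) {
    for (gl in 0:max_gap) {
      le <- cs - 1L - gl
      ls <- le - len + 1L
      if (ls < 1L || le < 1L) next
      left <- substr(seq, ls, le)
      left_rc <- revcomp(left)
      for (gr in 0:max_gap) {
        rs <- ce + 1L + gr
        re <- rs + len - 1L
        if (re > L) next
        right <- substr(seq, rs, re)
        mm <- .hamming(left_rc, right)
        if (mm > max_mismatch) next
        cand <- list(left_arm = left, right_arm = right, arm_length = len,
                     mismatches = mm, left_span = c(ls, le),
                     right_span = c(rs, re), gap = gl + gr)
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
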