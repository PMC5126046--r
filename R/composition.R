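# Cumulative GC profile and recursive compositional segmentation for
# flagging alien (genomic-island / HGT candidate) segments.

#' Segmentation configuration
#'
#' @param halting_threshold Split statistic threshold below which recursion
#'   stops (unitless; default 7).
#' @param min_segment_length Minimum segment length in bases (default 100).
#' @param alien_delta Minimum absolute GC-fraction difference from the
#'   genome background for a segment to be flagged alien (default 0.05).
#' @return A `gc_profile_config` list.
#' @export
gc_profile_config <- function(halting_threshold = 7, min_segment_length = 100,
                              alien_delta = 0.05) {
  stopifnot(halting_threshold > 0, min_segment_length >= 2)
  structure(
    list(halting_threshold = halting_threshold,
         min_segment_length = min_segment_length,
         alien_delta = alien_delta),
    class = "gc_profile_config"
  )
}

# +1 for A/T, -1 for G/C, 0 for anything else (ambiguity codes)
.at_gc_steps <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  u <- integer(length(ch))
  u[ch %in% c("A", "T")] <- 1L
  u[ch %in% c("G", "C")] <- -1L
  u
}

#' Cumulative GC (AT-GC excess) profile of a sequence
#'
#' Walks the sequence scoring +1 for A/T and -1 for G/C (0 for ambiguous
#' bases); returns the running sum and the linearly detrended profile
#' `d_n - (n/L) d_L`, whose interior extrema mark compositional boundaries.
#'
#' @param seq Nucleotide string, non-empty.
#' @return A `gc_profile`: list with `length`, `d` (cumulative excess) and
#'   `detrended`.
#' @export
cumulative_gc_profile <- function(seq) {
  if (!nzchar(seq)) abort("sequence must be non-empty")
  u <- .at_gc_steps(seq)
  d <- cumsum(u)
  L <- length(u)
  detr <- d - (seq_len(L) / L) * d[L]
  structure(list(length = L, d = d, detrended = detr), class = "gc_profile")
}

# two-proportion z statistic for a split of the GC indicator counts
.split_statistic <- function(n_l, gc_l, n_r, gc_r) {
  p_l <- gc_l / n_l
  p_r <- gc_r / n_r
  p <- (gc_l + gc_r) / (n_l + n_r)
  denom <- sqrt(p * (1 - p) * (1 / n_l + 1 / n_r))
  ifelse(denom > 0, abs(p_l - p_r) / denom, 0)
}

#' Recursive compositional segmentation of a sequence
#'
#' Recursive binary segmentation on GC content: at each step the interior
#' split maximising a two-proportion z statistic between left and right GC
#' fractions is taken (leftmost argmax on ties, candidates restricted so
#' both sides keep at least `min_segment_length` bases) and accepted iff the
#' statistic reaches `halting_threshold`; accepted sides are recursed.
#' A final refinement pass re-localises each boundary using only the two
#' adjacent segments (early global cuts are noisy when several change
#' points are present). Ambiguous bases count as neither AT nor GC.
#'
#' @param seq Nucleotide string of length at least
#'   `2 * min_segment_length`.
#' @param config A [gc_profile_config()].
#' @return Tibble of segments tiling the sequence: `start`, `end` (1-based
#'   inclusive), `gc_fraction`, `split_statistic` (of the cut that created
#'   the segment, `NA` for an unsplit root), `alien_flag` (`NA` until
#'   [call_alien_segments()]).
#' @export
segment_genome <- function(seq, config = gc_profile_config()) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  if (L < 2 * config$min_segment_length) {
    abort(sprintf("sequence length %d is below 2 * min_segment_length", L))
  }
  is_gc <- as.integer(ch %in% c("G", "C"))
  is_valid <- as.integer(ch %in% c("A", "C", "G", "T"))
  cum_gc <- c(0L, cumsum(is_gc))
  cum_valid <- c(0L, cumsum(is_valid))
  min_len <- config$min_segment_length
  segs <- list()
  emit <- function(a, b, stat) {
    n_valid <- cum_valid[b + 1L] - cum_valid[a]
    gc <- cum_gc[b + 1L] - cum_gc[a]
    segs[[length(segs) + 1L]] <<- tibble(
      start = a, end = b,
      gc_fraction = if (n_valid > 0) gc / n_valid else NA_real_,
      split_statistic = stat, alien_flag = NA
    )
  }
  recurse <- function(a, b, stat) {
    len <- b - a + 1L
    n_all <- cum_valid[b + 1L] - cum_valid[a]
    gc_all <- cum_gc[b + 1L] - cum_gc[a]
    if (len < 2L * min_len || n_all == 0L ||
        gc_all == 0L || gc_all == n_all) {
      emit(a, b, stat)
      return(invisible(NULL))
    }
    # candidate cut after position n, both sides >= min_len bases
    cuts <- (a + min_len - 1L):(b - min_len)
    n_l <- cum_valid[cuts + 1L] - cum_valid[a]
    gc_l <- cum_gc[cuts + 1L] - cum_gc[a]
    n_r <- n_all - n_l
    gc_r <- gc_all - gc_l
    ok <- n_l > 0L & n_r > 0L
    if (!any(ok)) {
      emit(a, b, stat)
      return(invisible(NULL))
    }
    t_vals <- rep(-Inf, length(cuts))
    t_vals[ok] <- .split_statistic(n_l[ok], gc_l[ok], n_r[ok], gc_r[ok])
    best <- which.max(t_vals) # leftmost argmax
    if (t_vals[best] >= config$halting_threshold) {
      cut <- cuts[best]
      recurse(a, cut, t_vals[best])
      recurse(cut + 1L, b, t_vals[best])
    } else {
      emit(a, b, stat)
    }
  }
  recurse(1L, L, NA_real_)
  out <- arrange(bind_rows(segs), .data$start)
  if (nrow(out) > 1L) out <- .refine_boundaries(out, cum_gc, cum_valid, min_len)
  out
}

# re-localise every internal boundary within its two flanking segments;
# iterate until stable (boundary count is preserved)
.refine_boundaries <- function(segs, cum_gc, cum_valid, min_len) {
  bounds <- segs$end[-nrow(segs)]
  stats <- rep(NA_real_, length(bounds))
  for (iter in 1:10) {
    changed <- FALSE
    for (j in seq_along(bounds)) {
      edges <- c(0L, bounds, segs$end[nrow(segs)])
      a <- edges[j] + 1L
      b <- edges[j + 2L]
      cuts <- (a + min_len - 1L):(b - min_len)
      n_all <- cum_valid[b + 1L] - cum_valid[a]
      gc_all <- cum_gc[b + 1L] - cum_gc[a]
      n_l <- cum_valid[cuts + 1L] - cum_valid[a]
      gc_l <- cum_gc[cuts + 1L] - cum_gc[a]
      ok <- n_l > 0L & (n_all - n_l) > 0L
      if (!any(ok)) next
      t_vals <- rep(-Inf, length(cuts))
      t_vals[ok] <- .split_statistic(n_l[ok], gc_l[ok],
                                     n_all - n_l[ok], gc_all - gc_l[ok])
      best <- which.max(t_vals)
      stats[j] <- t_vals[best]
      if (cuts[best] != bounds[j]) {
        bounds[j] <- cuts[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, segs$end[nrow(segs)])
  tibble(
    start = starts, end = ends,
    gc_fraction = vapply(seq_along(starts), function(k) {
      nv <- cum_valid[ends[k] + 1L] - cum_valid[starts[k]]
      if (nv > 0) (cum_gc[ends[k] + 1L] - cum_gc[starts[k]]) / nv else NA_real_
    }, numeric(1)),
    split_statistic = c(NA_real_, stats), alien_flag = NA
  )
}

#' Flag compositionally alien segments
#'
#' @param segments Segment tibble from [segment_genome()].
#' @param genome_gc Background GC fraction of the genome.
#' @param alien_delta Minimum `|gc_fraction - genome_gc|` to flag.
#' @return The segment tibble with `alien_flag` filled in.
#' @export
call_alien_segments <- function(segments, genome_gc, alien_delta = 0.05) {
  mutate(segments,
         alien_flag = abs(.data$gc_fraction - genome_gc) >= alien_delta)
}

#' GC fraction of a sequence (ambiguous bases excluded)
#'
#' @param seq Nucleotide string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n_valid <- sum(ch %in% c("A", "C", "G", "T"))
  if (n_valid == 0L) return(NA_real_)
  sum(ch %in% c("G", "C")) / n_valid
}

#' Plot a cumulative GC profile with segment boundaries
#'
#' @param profile A `gc_profile` from [cumulative_gc_profile()].
#' @param segments Optional segment tibble from [segment_genome()];
#'   boundaries are drawn as dashed lines and alien segments shaded.
#' @return A ggplot object.
#' @export
plot_gc_profile <- function(profile, segments = NULL) {
  df <- tibble(position = seq_len(profile$length), detrended = profile$detrended)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$detrended)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Position (bp)", y = "Detrended cumulative AT-GC excess") +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments) > 1) {
    p <- p + ggplot2::geom_vline(
      xintercept = segments$end[-nrow(segments)],
      linetype = "dashed", colour = "grey40"
    )
    alien <- filter(segments, isTRUE(.data$alien_flag) | .data$alien_flag %in% TRUE)
    if (nrow(alien)) {
      p <- p + ggplot2::geom_rect(
        data = alien, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$start, xmax = .data$end,
                     ymin = -Inf, ymax = Inf),
        fill = "firebrick", alpha = 0.12
      )
    }
  }
  p
}
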