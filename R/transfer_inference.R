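# The statistical spine: Mann-Whitney group comparisons, Dollo loss
# counting on a host phylogeny, and the transfer-verdict classifier that
# combines the divergence evidence.

#' Mann-Whitney U test between two groups
#'
#' U is computed from rank sums (midranks for ties). In `auto` mode the
#' exact two-tailed p-value is obtained by enumeration of labelings when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param g1,g2 Numeric vectors, both non-empty.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`
#'   (alternative about group 1 relative to group 2).
#' @return A `group_comparison`: list with `U` (statistic of group 1),
#'   `p_value`, `method`, `ties`, group sizes, and the inputs.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value # exact 1/3
#' @export
mann_whitney_u <- function(g1, g2, mode = c("auto", "exact", "normal"),
                           alternative = "two.sided") {
  mode <- match.arg(mode)
  if (!length(g1) || !length(g2)) abort("both groups must be non-empty")
  n1 <- length(g1)
  n2 <- length(g2)
  r <- rank(c(g1, g2))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(g1, g2)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal = FALSE,
    auto = (n1 + n2) <= 20 && !has_ties
  )
  if (use_exact && has_ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  ht <- suppressWarnings(wilcox.test(
    g1, g2, alternative = alternative,
    exact = use_exact, correct = TRUE
  ))
  p_value <- ht$p.value
  if (is.nan(p_value)) p_value <- 1 # all observations tied: no evidence
  structure(
    list(
      U = unname(U), p_value = p_value,
      method = if (use_exact) "exact" else "normal_approx",
      ties = has_ties, alternative = alternative,
      n1 = n1, n2 = n2, values_1 = g1, values_2 = g2
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n1 = %d, n2 = %d), %s %s p = %.4g%s\n",
              x$U, x$n1, x$n2, x$method, x$alternative, x$p_value,
              if (x$ties) " [ties: midranks]" else ""))
  invisible(x)
}

#' Tidy a Mann-Whitney comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(U = x$U, p_value = x$p_value, method = x$method,
         alternative = x$alternative, ties = x$ties, n1 = x$n1, n2 = x$n2)
}

#' Minimum loss count under Dollo parsimony
#'
#' Assuming a single gain of the character (phage/gene presence) on the
#' branch above the most recent common ancestor of all carriers, counts the
#' maximal carrier-free subtrees inside the MRCA clade: the minimum number
#' of independent losses required by vertical descent.
#'
#' @param tree A rooted `phylo` tree (or a newick string / file path).
#' @param carriers Character vector of tip labels bearing the character;
#'   must be non-empty and a subset of the tip labels.
#' @return Integer loss count.
#' @examples
#' dollo_losses("((A,B),(C,(D,E)));", c("A", "E")) # 3
#' @export
dollo_losses <- function(tree, carriers) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!length(carriers)) abort("at least one carrier is required")
  if (!all(carriers %in% tree$tip.label)) {
    abort("carriers must be a subset of the tree's tip labels")
  }
  ntip <- length(tree$tip.label)
  carrier_tip <- which(tree$tip.label %in% carriers)
  if (length(carrier_tip) == 1L) return(0L) # MRCA is the tip itself
  mrca <- ape::getMRCA(tree, carrier_tip)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  has_carrier <- rep(NA, nnode)
  fill <- function(v) {
    if (v <= ntip) {
      has_carrier[v] <<- v %in% carrier_tip
    } else {
      for (k in kids[[v]]) fill(k)
      has_carrier[v] <<- any(has_carrier[kids[[v]]])
    }
  }
  fill(mrca)
  losses <- 0L
  count <- function(v) {
    for (k in kids[[v]]) {
      if (!has_carrier[k]) {
        losses <<- losses + 1L # maximal empty subtree: one loss on this branch
      } else if (k > ntip) {
        count(k)
      }
    }
  }
  count(mrca)
  losses
}

#' Thresholds for the transfer verdict
#'
#' @param p_separation Significance level for the candidate-vs-resident
#'   identity separation (default 0.01, two-tailed MWU).
#' @param p_not_lower Level for the one-sided "candidate identity lower than
#'   host identity" test; the verdict requires `p >= p_not_lower` or a
#'   candidate mean dS at or below the host mean (default 0.05).
#' @param min_losses Minimum Dollo loss count (when a tree is supplied) for
#'   vertical descent to be considered less parsimonious (default 2).
#' @return A `verdict_config` list.
#' @export
verdict_config <- function(p_separation = 0.01, p_not_lower = 0.05,
                           min_losses = 2) {
  structure(list(p_separation = p_separation, p_not_lower = p_not_lower,
                 min_losses = min_losses),
            class = "verdict_config")
}

#' Classify a candidate phage pair as recently transferred or not
#'
#' Combines the three gene-group summaries into a verdict. The label is
#' `recent_transfer` iff (i) candidate-pair identity significantly exceeds
#' the candidate-vs-resident-phage identity (two-tailed MWU below
#' `p_separation` with the candidate median higher), (ii) candidate-pair
#' identity is not significantly lower than host-ortholog identity
#' (one-sided MWU at `p_not_lower`) or the candidate mean dS does not
#' exceed the host mean dS, and (iii) the Dollo loss count reaches
#' `min_losses` when a tree is supplied. `vertical_or_ancient` iff (i)
#' fails; otherwise `indeterminate`. A full evidence record is always
#' emitted.
#'
#' @param evidence Data frame with one row per gene pair and columns
#'   `group` (`"candidate"`, `"resident"`, `"host"`), `percent_identity`,
#'   and `dS`.
#' @param loss_count Optional Dollo loss count from [dollo_losses()].
#' @param config A [verdict_config()].
#' @return A `transfer_verdict`: list with `label`, `group_summary`,
#'   `tests`, `loss_count`, `config`, `evidence`, and `reason` when
#'   indeterminate.
#' @export
classify_transfer <- function(evidence, loss_count = NULL,
                              config = verdict_config()) {
  evidence <- as_tibble(evidence)
  needed <- c("candidate", "resident", "host")
  have <- intersect(needed, unique(evidence$group))
  base <- list(config = config, loss_count = loss_count, evidence = evidence)
  if (length(setdiff(needed, have))) {
    return(structure(c(base, list(
      label = "indeterminate",
      reason = paste("missing gene group(s):",
                     paste(setdiff(needed, have), collapse = ", ")),
      group_summary = NULL, tests = NULL
    )), class = "transfer_verdict"))
  }
  grp <- function(g, col) evidence[[col]][evidence$group == g]
  summary_tbl <- evidence |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      mean_identity = mean(.data$percent_identity, na.rm = TRUE),
      sd_identity = sd(.data$percent_identity, na.rm = TRUE),
      mean_dS = mean(.data$dS, na.rm = TRUE),
      sd_dS = sd(.data$dS, na.rm = TRUE),
      .groups = "drop"
    )
  mwu_cand_res <- mann_whitney_u(grp("candidate", "percent_identity"),
                                 grp("resident", "percent_identity"))
  mwu_cand_host_lower <- mann_whitney_u(grp("candidate", "percent_identity"),
                                        grp("host", "percent_identity"),
                                        alternative = "less")
  mean_of <- function(g, col) mean(grp(g, col), na.rm = TRUE)
  sep_ok <- mwu_cand_res$p_value < config$p_separation &&
    mean_of("candidate", "percent_identity") > mean_of("resident", "percent_identity")
  not_lower_ok <- mwu_cand_host_lower$p_value >= config$p_not_lower ||
    isTRUE(mean_of("candidate", "dS") <= mean_of("host", "dS"))
  losses_ok <- is.null(loss_count) || loss_count >= config$min_losses
  label <- if (!sep_ok) {
    "vertical_or_ancient"
  } else if (not_lower_ok && losses_ok) {
    "recent_transfer"
  } else {
    "indeterminate"
  }
  tests <- tibble(
    test = c("candidate_vs_resident_identity", "candidate_lower_than_host_identity"),
    U = c(mwu_cand_res$U, mwu_cand_host_lower$U),
    p_value = c(mwu_cand_res$p_value, mwu_cand_host_lower$p_value),
    method = c(mwu_cand_res$method, mwu_cand_host_lower$method),
    alternative = c(mwu_cand_res$alternative, mwu_cand_host_lower$alternative)
  )
  # gene-level values are pseudo-replicated within a genome pair; flag it
  structure(c(base, list(
    label = label, group_summary = summary_tbl, tests = tests,
    reason = NULL,
    notes = "gene-level observations within a genome pair are not independent"
  )), class = "transfer_verdict")
}

#' @export
print.transfer_verdict <- function(x, ...) {
  cat("Transfer verdict:", x$label, "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.null(x$group_summary)) {
    s <- x$group_summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-9s n = %2d  identity %6.2f%%  dS %.3f\n",
                  s$group[i], s$n[i], s$mean_identity[i], s$mean_dS[i]))
    }
  }
  if (!is.null(x$tests)) {
    for (i in seq_len(nrow(x$tests))) {
      cat(sprintf("  %s: p = %.3g (%s)\n", x$tests$test[i],
                  x$tests$p_value[i], x$tests$method[i]))
    }
  }
  if (!is.null(x$loss_count)) {
    cat(sprintf("  Dollo losses under vertical null: %d\n", x$loss_count))
  }
  invisible(x)
}

#' Tidy a transfer verdict (the underlying tests)
#'
#' @param x A `transfer_verdict`.
#' @param ... Unused.
#' @export
tidy.transfer_verdict <- function(x, ...) {
  if (is.null(x$tests)) return(tibble())
  x$tests
}

#' One-row summary of a transfer verdict
#'
#' @param x A `transfer_verdict`.
#' @param ... Unused.
#' @export
glance.transfer_verdict <- function(x, ...) {
  out <- tibble(label = x$label,
                loss_count = x$loss_count %||% NA_integer_)
  if (!is.null(x$group_summary)) {
    s <- x$group_summary
    for (g in s$group) {
      out[[paste0("mean_identity_", g)]] <- s$mean_identity[s$group == g]
      out[[paste0("mean_dS_", g)]] <- s$mean_dS[s$group == g]
    }
  }
  out
}

#' Identity-by-group plot for transfer evidence
#'
#' Jittered per-gene percent identities by gene group with group means, the
#' display that motivates the divergence-ratio test.
#'
#' @param evidence Evidence tibble as in [classify_transfer()], or a
#'   `transfer_verdict`.
#' @return A ggplot object.
#' @export
plot_identity_groups <- function(evidence) {
  if (inherits(evidence, "transfer_verdict")) evidence <- evidence$evidence
  ggplot2::ggplot(evidence,
                  ggplot2::aes(x = .data$group, y = .data$percent_identity)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Percent nucleotide identity") +
    ggplot2::theme_minimal()
}
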