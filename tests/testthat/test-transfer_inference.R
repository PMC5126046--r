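# Mann-Whitney U, Dollo loss counting, verdict classification.

test_that("exact MWU matches enumeration on canonical and random small groups", {
  cmp <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(cmp$method, "exact")
  set.seed(61)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      g1 <- rnorm(n1)
      g2 <- rnorm(n2)
      got <- mann_whitney_u(g1, g2)
      expect_equal(got$p_value, oracle_mwu_p(g1, g2), tolerance = 1e-10,
                   info = sprintf("n1=%d n2=%d", n1, n2))
      expect_true(got$U >= 0 && got$U <= n1 * n2)
    }
  }
})

test_that("tied identical groups give p = 1 under the normal approximation", {
  cmp <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$method, "normal_approx")
  expect_true(cmp$ties)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("MWU type-I error is calibrated at alpha 0.05", {
  set.seed(314)
  rejections <- 0L
  n_sims <- 400
  for (i in seq_len(n_sims)) {
    p <- mann_whitney_u(rnorm(30), rnorm(30))$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_sims, 0.02)
  expect_lte(rejections / n_sims, 0.08)
})

test_that("Dollo loss counting handles the toy tree and edge cases", {
  expect_equal(dollo_losses("((A,B),(C,(D,E)));", c("A", "E")), 3)
  expect_equal(dollo_losses("((A,B),(C,(D,E)));", c("A", "B", "C", "D", "E")), 0)
  expect_equal(dollo_losses("((A,B),(C,(D,E)));", "C"), 0)
  expect_error(dollo_losses("((A,B),(C,D));", character(0)), "carrier")
  expect_error(dollo_losses("((A,B),(C,D));", "Z"), "subset")
})

test_that("Dollo equals the brute-force minimum on random trees", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    tr <- ape::rtree(n, tip.label = LETTERS[1:n])
    k <- sample(seq_len(n), 1)
    carriers <- sample(LETTERS[1:n], k)
    expect_equal(dollo_losses(tr, carriers), oracle_dollo(tr, carriers),
                 info = paste(n, paste(sort(carriers), collapse = ",")))
  }
})

make_evidence <- function(cand_id, res_id, host_id, cand_ds, res_ds, host_ds) {
  tibble::tibble(
    group = rep(c("candidate", "resident", "host"),
                times = c(length(cand_id), length(res_id), length(host_id))),
    gene_a = paste0("g", seq_len(length(cand_id) + length(res_id) + length(host_id))),
    gene_b = paste0("h", seq_len(length(cand_id) + length(res_id) + length(host_id))),
    percent_identity = c(cand_id, res_id, host_id),
    dS = c(cand_ds, res_ds, host_ds)
  )
}

test_that("the paper-regime evidence pattern is classified as recent transfer", {
  set.seed(5)
  ev <- make_evidence(
    cand_id = rnorm(10, 94.4, 1), res_id = rnorm(16, 85, 3), host_id = rnorm(12, 95.7, 1.5),
    cand_ds = rnorm(10, 0.07, 0.02), res_ds = rnorm(16, 0.27, 0.05),
    host_ds = rnorm(12, 0.10, 0.03)
  )
  v <- classify_transfer(ev, loss_count = 3)
  expect_equal(v$label, "recent_transfer")
  expect_true(all(c("candidate", "resident", "host") %in% v$group_summary$group))
  g <- glance(v)
  expect_equal(g$label, "recent_transfer")
})

test_that("undifferentiated groups are never classified as recent transfer", {
  set.seed(8)
  labels <- vapply(1:50, function(i) {
    ev <- make_evidence(rnorm(8, 90, 2), rnorm(16, 90, 2), rnorm(12, 90, 2),
                        rnorm(8, 0.1, 0.03), rnorm(16, 0.1, 0.03), rnorm(12, 0.1, 0.03))
    classify_transfer(ev, loss_count = 3)$label
  }, character(1))
  expect_lte(sum(labels == "recent_transfer"), 2)
})

test_that("missing groups give an indeterminate verdict with a reason", {
  ev <- make_evidence(rnorm(5, 95, 1), rnorm(5, 85, 1), numeric(0),
                      rnorm(5, 0.05, 0.01), rnorm(5, 0.3, 0.05), numeric(0))
  v <- classify_transfer(ev)
  expect_equal(v$label, "indeterminate")
  expect_match(v$reason, "host")
})

test_that("decreasing candidate dS never flips recent_transfer to vertical", {
  set.seed(33)
  cand_id <- rnorm(10, 96, 1)
  res_id <- rnorm(16, 85, 2)
  host_id <- rnorm(12, 95, 1)
  res_ds <- rnorm(16, 0.27, 0.05)
  host_ds <- rnorm(12, 0.10, 0.02)
  labels <- vapply(c(0.15, 0.10, 0.07, 0.03, 0.0), function(ds) {
    ev <- make_evidence(cand_id, res_id, host_id,
                        rep(ds, 10), res_ds, host_ds)
    classify_transfer(ev, loss_count = 3)$label
  }, character(1))
  # once recent_transfer, lowering candidate dS keeps it
  first_rt <- match("recent_transfer", labels)
  if (!is.na(first_rt)) {
    expect_true(all(labels[first_rt:length(labels)] == "recent_transfer"))
  }
  # a low loss count blocks the transfer call when a tree is supplied
  ev <- make_evidence(cand_id, res_id, host_id, rep(0.05, 10), res_ds, host_ds)
  expect_equal(classify_transfer(ev, loss_count = 1)$label, "indeterminate")
  expect_equal(classify_transfer(ev, loss_count = NULL)$label, "recent_transfer")
})
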