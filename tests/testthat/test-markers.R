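# Exact two-sided Wilcoxon oracle by enumeration of all C(n, n_a) group
# assignments of the pooled sample (probability of a rank sum as or more
# extreme, doubling the smaller tail).
wilcox_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  sums <- combn(length(pooled), na, function(i) sum(r[i]))
  obs <- sum(r[seq_len(na)])
  lo <- mean(sums <= obs)
  hi <- mean(sums >= obs)
  min(1, 2 * min(lo, hi))
}

test_that("rank-sum p-values agree with exact enumeration on small samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3) * 1e-9 + 5), 0.1)
  expect_equal(rank_sum_test(c(3, 1, 4, 2), c(3, 1, 4, 2)), 1)
  expect_equal(rank_sum_test(rep(2, 5), rep(2, 4)), 1)  # all tied
  withr::with_seed(2, {
    for (i in 1:40) {
      na <- sample(2:6, 1)
      nb <- sample(2:6, 1)
      a <- rnorm(na)
      b <- rnorm(nb)
      expect_equal(rank_sum_test(a, b), wilcox_enum_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("approximate and exact rank-sum branches agree near the cutoff", {
  withr::with_seed(3, {
    devs <- replicate(100, {
      a <- rnorm(6)
      b <- rnorm(6)
      exact <- rank_sum_test(a, b)                   # n = 12: exact branch
      approx <- relapseScope:::.rank_sum_approx(rank(c(a, b)), 1:6, 6, 6)
      abs(exact - approx)
    })
    expect_lt(max(devs), 0.02)
  })
  # invariance under strictly monotone transforms of the pooled values
  withr::with_seed(6, {
    x <- rpois(30, 3)
    y <- rpois(25, 4)
    expect_equal(rank_sum_test(x, y), rank_sum_test(exp(x), exp(y)))
    expect_equal(rank_sum_test(x, y), rank_sum_test(rank(c(x, y))[1:30],
                                                    rank(c(x, y))[31:55]))
  })
})

test_that("marker detection recovers planted cluster markers with correct sign", {
  cfg <- small_config(n_cells_dx = 80, n_cells_re = 80, seed = 19)
  sce <- normalize_counts(simulate_counts(cfg))
  truth <- metadata(sce)$ground_truth$markers
  res <- find_markers(sce, labels = sce$cluster)
  for (k in unique(truth$cluster)) {
    planted <- truth$gene[truth$cluster == k]
    found <- res$gene[res$group == k & res$significant & res$log2fc > 0]
    expect_gte(mean(planted %in% found), 0.9)
  }
  # swapping the two group labels flips the fold change, not the p-value
  two <- as.character(sce$cluster)
  a <- find_markers(sce, two, group = "1", reference = "2")
  b <- find_markers(sce, two, group = "2", reference = "1")
  shared <- intersect(a$gene, b$gene)
  ia <- match(shared, a$gene)
  ib <- match(shared, b$gene)
  expect_equal(a$log2fc[ia], -b$log2fc[ib])
  expect_equal(a$p[ia], b$p[ib])
  # BH over tested genes matches the shared adjustment routine
  expect_equal(a$q, bh_adjust(a$p))
})

test_that("degenerate marker inputs are handled without false output", {
  m <- matrix(5, 20, 12, dimnames = list(sprintf("g%02d", 1:20),
                                         sprintf("c%02d", 1:12)))
  labs <- rep(c("x", "y"), each = 6)
  expect_equal(nrow(find_markers(log1p(m), labs)), 0L)  # nothing passes filters
  # both one-vs-rest contrasts are degenerate, so each one warns
  expect_warning(
    expect_warning(res <- find_markers(log1p(m), c(rep("x", 10), "y", "y")),
                   "fewer than 3"),
    "fewer than 3")
  expect_equal(nrow(res), 0L)
})

test_that("gene-set contrasts report per-gene fold changes and misses", {
  cfg <- small_config(n_cells_dx = 70, n_cells_re = 70, seed = 23)
  sce <- normalize_counts(simulate_counts(cfg))
  set <- metadata(sce)$ground_truth$markers
  set1 <- set$gene[set$cluster == 1]
  in_cells <- colnames(sce)[sce$cluster == 1]
  out_cells <- colnames(sce)[sce$cluster != 1]
  res <- signature_contrast(sce, c(set1, "NOT_A_GENE"), in_cells, out_cells)
  expect_equal(res$missing, "NOT_A_GENE")
  expect_equal(res$summary$n_tested, length(set1))
  expect_gte(res$summary$n_pass / res$summary$n_tested, 0.9)
  # identical groups: FC = 1 and p = 1 throughout
  null <- signature_contrast(sce, set1, in_cells, in_cells)
  expect_true(all(abs(null$genes$fc - 1) < 1e-12))
  expect_true(all(null$genes$p == 1))
})

test_that("DEG set comparison equals brute-force set algebra", {
  expect_equal(compare_deg_sets(list(a = c("x", "y"), b = c("x", "y")))$count,
               c(0L, 0L, 2L))
  expect_equal(compare_deg_sets(list(a = "x", b = "y"))$count, c(1L, 1L, 0L))
  withr::with_seed(10, {
    for (i in 1:20) {
      sets <- lapply(1:3, function(j) {
        sample(sprintf("g%02d", 1:30), sample(0:15, 1))
      })
      names(sets) <- c("p1", "p2", "p3")
      res <- compare_deg_sets(sets)
      u <- unique(unlist(sets))
      for (r in seq_len(nrow(res))) {
        members <- strsplit(res$subset[r], "&", fixed = TRUE)[[1]]
        expected <- sum(vapply(u, function(g) {
          setequal(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
                   members)
        }, logical(1)))
        expect_equal(res$count[r], expected)
      }
    }
  })
})
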