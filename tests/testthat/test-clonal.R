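# Independent enumeration oracle for the two-sided Fisher test: walks every
# table with the observed margins using log-binomial coefficients.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  ks <- max(0, k - n2):min(k, m)
  lp <- lchoose(m, ks) + lchoose(n2, k - ks) - lchoose(m + n2, k)
  p <- exp(lp)
  sum(p[p <= p[ks == a] * (1 + 1e-7)])
}

test_that("VAF arithmetic treats zero depth as missing, never as zero", {
  expect_equal(compute_vaf(5, 15), 0.25)
  expect_equal(compute_vaf(0, 50), 0)
  expect_true(is.na(compute_vaf(0, 0)))
  expect_equal(compute_vaf(c(5, 0), c(15, 0)), c(0.25, NA))
  expect_error(compute_vaf(-1, 5), "non-negative")
})

test_that("the detection rule uses inclusive ALT and VAF thresholds", {
  expect_true(detect_variant(5, 95))          # VAF exactly 0.05
  expect_false(detect_variant(4, 0))          # below the ALT floor
  expect_false(detect_variant(10, 400))       # VAF ~ 0.024
  expect_false(detect_variant(0, 0))
  expect_true(detect_variant(4, 0, min_alt = 4))
})

test_that("two-sided Fisher p matches enumeration and the reference test", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 9, 9), 2)), 1)
  # two extreme tables among choose(20, 10) = 184,756 arrangements
  expect_equal(fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_equal(p0, 1)

  withr::with_seed(5, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, 8), 2)
      if (sum(tab) == 0) next
      p <- fisher_exact_2x2(tab)
      expect_lt(abs(p - fisher_enum_oracle(tab[1, 1], tab[1, 2],
                                           tab[2, 1], tab[2, 2])), 1e-10)
      # independent cross-check against the reference implementation
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
      # symmetric under row and column swap
      expect_equal(p, fisher_exact_2x2(tab[2:1, ]))
      expect_equal(p, fisher_exact_2x2(tab[, 2:1]))
    }
  })
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("BH adjustment matches the step-up definition on oracle inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.3)), "\\[0, 1\\]")

  bh_naive <- function(p) {           # literal step-up: q_(i) = min_{j>=i} p_(j) m/j
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    qs <- vapply(seq_len(m), function(i) min(1, min(m / (i:m) * ps[i:m])),
                 numeric(1))
    q <- numeric(m)
    q[o] <- qs
    q
  }
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_naive(p))
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
})

test_that("VAF-shift testing flags planted clonal changes and only those", {
  v <- data.frame(variant_id = c("stable", "lost", "faint"),
                  ref_dx = c(60, 60, 100), alt_dx = c(40, 40, 2),
                  ref_re = c(60, 100, 100), alt_re = c(40, 0, 1))
  res <- test_vaf_shifts(v)
  expect_equal(res$p[1], 1)
  expect_false(res$reportable[1])
  expect_equal(res$direction[1], "none")
  expect_true(res$reportable[2])
  expect_equal(res$direction[2], "Dx-enriched")
  expect_true(res$q[2] < 0.05)
  # undetected at both timepoints: excluded from testing, kept in output
  expect_false(res$tested[3])
  expect_true(is.na(res$p[3]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))

  expect_error(test_vaf_shifts(v[c(1, 1), ]), "duplicate")
  expect_error(test_vaf_shifts(v[0, ]), "at least one")
})

test_that("shift-test power grows with sequencing depth", {
  power_at <- function(depth, reps = 100) {
    withr::with_seed(depth, {
      hits <- 0
      for (i in seq_len(reps)) {
        alt_dx <- rbinom(1, depth, 0.35)
        alt_re <- rbinom(1, depth, 0.15)
        v <- data.frame(variant_id = "v", ref_dx = depth - alt_dx,
                        alt_dx = alt_dx, ref_re = depth - alt_re,
                        alt_re = alt_re)
        hits <- hits + test_vaf_shifts(v)$reportable
      }
      hits / reps
    })
  }
  p30 <- power_at(30)
  p100 <- power_at(100)
  p300 <- power_at(300)
  expect_lte(p30, p100 + 0.1)      # allow Monte-Carlo slack
  expect_lte(p100, p300 + 0.05)
  expect_gt(p300, 0.95)
})
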