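test_that("GMT files round-trip and reject malformed lines", {
  sets <- list(setA = c("g1", "g2", "g3"), setB = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  ernalink:::write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  writeLines("lonely\tdesc", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("hypergeometric p equals exhaustive enumeration for N <= 12", {
  for (N in c(4L, 7L, 10L, 12L)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in 0:N) {
      term <- universe[seq_len(K)]
      for (n in 0:N) {
        if (n == 0L) next  # empty query is not a meaningful test call
        ks <- max(0L, n - (N - K)):min(n, K)
        for (k in ks) {
          query <- c(universe[seq_len(k)],
                     if (n - k > 0) universe[K + seq_len(n - k)])
          got <- hypergeom_test(query, list(t = term), universe)
          expect_equal(got$p, oracle_hyper_tail(N, K, n, k),
                       tolerance = 1e-12)
          expect_equal(got$k_overlap, k)
        }
      }
    }
  }
})

test_that("hypergeometric worked examples and error guards", {
  u <- sprintf("g%02d", 1:10)
  res <- hypergeom_test(u[1:5], list(t = u[1:5]), u)
  expect_equal(res$p, 1 / choose(10, 5))   # 1/252
  res0 <- hypergeom_test(u[6:10], list(t = u[1:5]), u)
  expect_equal(res0$p, 1)                   # k = 0, upper tail from 0
  expect_error(hypergeom_test(u, list(t = u[1:2]), u[1:3]),
               "universe smaller")
  # BH across the collection
  many <- hypergeom_test(u[1:5], list(a = u[1:5], b = u[6:10]), u)
  expect_equal(many$q, bh_fdr(many$p))
})

test_that("summit overlap fraction uses half-open region semantics", {
  regions <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                        end = c(50L, 150L, 250L, 350L),
                        stringsAsFactors = FALSE)
  summits <- data.frame(chrom = "chr1", pos = c(0L, 150L),
                        stringsAsFactors = FALSE)
  # summit at region start counts; summit at end coordinate does not
  expect_equal(tfbs_overlap_stat(regions, summits), 0.25)
  summits2 <- data.frame(chrom = "chr1", pos = c(10L, 110L),
                         stringsAsFactors = FALSE)
  expect_equal(tfbs_overlap_stat(regions, summits2), 0.5)
  expect_error(tfbs_overlap_stat(regions[0, ], summits), "empty query")
})

test_that("background sampler respects TADs, exclusions and the seed", {
  tads <- data.frame(chrom = "chr1", start = 0L, end = 1000L, id = "t1")
  r1 <- sample_background_regions(200L, 40L, tads, NULL, seed = 5L)
  expect_true(all(r1$start >= 0L & r1$end <= 1000L))
  r2 <- sample_background_regions(200L, 40L, tads, NULL, seed = 5L)
  expect_identical(r1, r2)
  r3 <- sample_background_regions(200L, 40L, tads, NULL, seed = 6L)
  expect_false(identical(r1, r3))

  # exclusion covering all but one legal slot of the right width
  excl <- data.frame(chrom = "chr1", start = c(0L, 140L),
                     end = c(100L, 1000L), stringsAsFactors = FALSE)
  only <- sample_background_regions(5L, 40L, tads, excl, seed = 1L)
  expect_true(all(only$start == 100L & only$end == 140L))
  expect_error(
    sample_background_regions(1L, 500L, tads, excl, seed = 1L),
    "width 500")
})

test_that("Monte-Carlo p uses the plus-one estimator and its bounds", {
  tads <- data.frame(chrom = "chr1", start = 0L, end = 10000L, id = "t1")
  query <- data.frame(chrom = "chr1", start = c(100L, 300L, 500L),
                      end = c(140L, 340L, 540L), stringsAsFactors = FALSE)
  summits <- data.frame(chrom = "chr1", pos = c(110L, 310L, 510L),
                        stringsAsFactors = FALSE)
  pool_bad <- data.frame(chrom = "chr1",
                         start = seq(1000L, 2800L, by = 200L),
                         end = seq(1040L, 2840L, by = 200L),
                         stringsAsFactors = FALSE)
  res <- monte_carlo_p(query, summits, pool_bad, trials = 200L, seed = 2L)
  expect_equal(res$observed_frac, 1)
  expect_equal(res$p_value, 1 / 201)        # observed beats every trial
  res2 <- monte_carlo_p(pool_bad[1:3, ], summits, query, trials = 100L,
                        seed = 2L)
  expect_equal(res2$p_value, 1)             # observed below every trial
  expect_error(monte_carlo_p(query, summits, pool_bad[1:2, ], trials = 10L),
               "pool smaller")
})

test_that("empirical p sits within 3 MC standard errors of enumeration", {
  # pool of 5 regions, draws of 3: all C(5,3) = 10 subsets enumerable
  pool <- data.frame(chrom = "chr1",
                     start = c(0L, 100L, 200L, 300L, 400L),
                     end = c(50L, 150L, 250L, 350L, 450L),
                     stringsAsFactors = FALSE)
  summits <- data.frame(chrom = "chr1", pos = c(10L, 110L),
                        stringsAsFactors = FALSE)
  query <- pool[c(1, 2, 5), ]               # observed 2/3 regions hit
  obs <- tfbs_overlap_stat(query, summits)
  subsets <- combn(5, 3)
  stat <- apply(subsets, 2, function(ix)
    tfbs_overlap_stat(pool[ix, ], summits))
  p_exact <- mean(stat >= obs)
  trials <- 2000L
  res <- monte_carlo_p(query, summits, pool, trials = trials, seed = 11L)
  se <- sqrt(p_exact * (1 - p_exact) / trials)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / (trials + 1))
})

test_that("TF retention needs all backgrounds significant plus expression", {
  tab <- data.frame(tf = c("a", "b", "c"),
                    p1 = c(0.001, 0.001, 0.002),
                    p2 = c(0.002, 0.02, 0.003),
                    p3 = c(0.009, 0.001, 0.004),
                    stringsAsFactors = FALSE)
  expr <- c(a = 5, b = 10, c = 0)
  expect_equal(significant_tfbs(tab, expr), "a")  # b fails p2, c unexpressed
  expect_error(significant_tfbs(tab["tf"], expr), "background")
  tab_na <- tab; tab_na$p2[1] <- NA
  expect_error(significant_tfbs(tab_na, expr), "missing")
})
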