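zmat <- function(x, bg_mean, bg_sd, n_bg = 10L) {
  # build a matrix whose background columns realize the given mean/sd
  bg <- stats::qnorm(stats::ppoints(n_bg), bg_mean, bg_sd)
  bg <- (bg - mean(bg)) / sd(bg) * bg_sd + bg_mean
  m <- matrix(c(x, bg), nrow = 1,
              dimnames = list("f", c("t1", sprintf("b%02d", seq_len(n_bg)))))
  m
}

test_that("z-scores subtract the background mean and divide by its sd", {
  m <- zmat(10, 4, 2)
  z <- zscores(m, "t1", sprintf("b%02d", 1:10))
  expect_equal(z["f", "t1"], 3, tolerance = 1e-12)
  m2 <- zmat(4, 4, 2)
  expect_equal(zscores(m2, "t1", sprintf("b%02d", 1:10))["f", "t1"], 0,
               tolerance = 1e-12)
})

test_that("constant backgrounds follow the declared Inf/0 convention", {
  m <- matrix(c(5, 2, 2, 2), nrow = 1,
              dimnames = list("f", c("t1", "b1", "b2", "b3")))
  z <- zscores(m, "t1", c("b1", "b2", "b3"))
  expect_identical(z["f", "t1"], Inf)
  m[1, 1] <- 1  # below the constant background mean
  expect_identical(zscores(m, "t1", c("b1", "b2", "b3"))["f", "t1"], 0)
  expect_true("f" %in% macrophage_specific(
    zscores(matrix(c(5, 5, 2, 2, 2), 1,
                   dimnames = list("f", c("t1", "t2", "b1", "b2", "b3"))),
            c("t1", "t2"), c("b1", "b2", "b3"))))
  expect_error(zscores(m, "t1", character(0)))
})

test_that("tissue specificity uses at-least-ceiling, strictly above z", {
  ids <- sprintf("t%02d", 1:20)
  mk <- function(zv) {
    z <- matrix(rep(zv, each = 1), nrow = 1,
                dimnames = list("f", ids))
    z
  }
  # ceiling(0.1 * 20) = 2 target samples required
  expect_equal(macrophage_specific(mk(c(rep(4, 2), rep(0, 18)))), "f")
  expect_equal(macrophage_specific(mk(c(4, rep(0, 19)))), character(0))
  # z exactly at the threshold does not count
  expect_equal(macrophage_specific(mk(c(rep(3, 20)))), character(0))
})

test_that("stimulus response needs strictly more than a quarter of samples", {
  stim <- sprintf("s%02d", 1:16)
  untx <- sprintf("u%02d", 1:10)
  mk <- function(k) {
    m <- matrix(rnorm(26, 100, 1), nrow = 1,
                dimnames = list("f", c(stim, untx)))
    m[1, untx] <- seq(99, 101, length.out = 10)  # sd ~ 0.67
    if (k > 0) m[1, stim[seq_len(k)]] <- 200     # huge z
    m[1, stim[-seq_len(max(k, 0))]] <- 100
    m
  }
  expect_equal(stimuli_responsive(mk(5L), stim, untx), "f")   # 5 > 4
  expect_equal(stimuli_responsive(mk(4L), stim, untx), character(0))
  expect_equal(stimuli_responsive(mk(0L), stim, untx), character(0))
  expect_error(stimuli_responsive(mk(5L), stim, c(untx, stim[1])),
               "disjoint")
})

test_that("null calibration: no responsive calls under a pure null", {
  # large background so z is effectively standard normal and the binomial
  # tail (p ~ 0.00135, need >= 5 of 16) puts the per-feature rate below 1e-6
  set.seed(1)
  n <- 10000L; nbg <- 1000L
  stim <- sprintf("s%02d", 1:16)
  bg <- sprintf("u%04d", seq_len(nbg))
  m <- matrix(rnorm(n * (nbg + 16L), 100, 10), nrow = n,
              dimnames = list(sprintf("f%05d", seq_len(n)), c(bg, stim)))
  expect_length(stimuli_responsive(m, stim, bg), 0L)
})

test_that("a +5 background-SD shift is detected in >= 99% of features", {
  set.seed(7)
  n <- 1000L
  stim <- sprintf("s%02d", 1:16)
  untx <- sprintf("u%02d", 1:10)
  mu <- stats::rlnorm(n, log(30), 0.5)
  sdv <- sqrt(mu + mu^2 / 10)   # generator's NB sd
  m <- cbind(
    matrix(stats::rnbinom(n * 10L, 10, mu = rep(mu, 10L)), nrow = n),
    matrix(stats::rnbinom(n * 16L, 10, mu = rep(mu + 5 * sdv, 16L)),
           nrow = n))
  dimnames(m) <- list(sprintf("f%04d", seq_len(n)), c(untx, stim))
  called <- stimuli_responsive(m, stim, untx)
  expect_gte(length(called), 990L)
})

test_that("state-restricted links keep only positive in-state correlation", {
  set.seed(21)
  ss <- sprintf("s%02d", 1:16)
  em <- rbind(e_up = 1:16, e_down = 16:1, e_flat = rep(2, 16))
  colnames(em) <- ss
  pm <- rbind(p1 = (1:16) + rnorm(16, 0, 0.1))
  colnames(pm) <- ss
  links <- data.frame(enhancer_id = c("e_up", "e_down", "e_flat"),
                      promoter_id = "p1", stringsAsFactors = FALSE)
  expect_message(out <- condition_links(links, em, pm, ss), "constant")
  expect_equal(out$enhancer_id, "e_up")
  expect_gt(out$rho_state, 0)
})

test_that("marker enhancers require exclusivity, marker link and z rule", {
  ifng <- sprintf("i%02d", 1:16)
  il4 <- sprintf("l%02d", 1:16)
  em <- matrix(10, nrow = 3, ncol = 32,
               dimnames = list(c("eA", "eB", "eC"), c(ifng, il4)))
  em["eA", ifng] <- 100 + rnorm(16)   # strongly up versus il4 background
  em["eA", il4] <- 10 + rnorm(16)
  em["eB", ifng] <- 100 + rnorm(16)
  em["eB", il4] <- 10 + rnorm(16)
  em["eC", ifng] <- 100 + rnorm(16)
  em["eC", il4] <- 10 + rnorm(16)
  responsive <- list(ifng = c("eA", "eB", "eC"), il4il13 = c("eC"))
  state_links <- list(
    ifng = data.frame(enhancer_id = c("eA", "eB", "eC"),
                      gene_id = c("mk1", "other", "mk1"),
                      stringsAsFactors = FALSE),
    il4il13 = data.frame(enhancer_id = character(),
                         gene_id = character(), stringsAsFactors = FALSE))
  markers <- data.frame(gene_id = c("mk1", "mk2"),
                        state = c("ifng", "il4il13"),
                        stringsAsFactors = FALSE)
  calls <- marker_enhancers(responsive, state_links, markers, em,
                            list(ifng = ifng, il4il13 = il4))
  # eA passes; eB is linked to no marker gene; eC is responsive in both
  expect_equal(calls$enhancer_id, "eA")
  expect_equal(calls$state, "ifng")
  expect_equal(calls$marker_gene_ids, "mk1")
  # marker sets of the two states are disjoint by construction
  expect_length(intersect(calls$enhancer_id[calls$state == "ifng"],
                          calls$enhancer_id[calls$state == "il4il13"]), 0L)
})
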