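test_that("strand-break probability is a linear ramp between 5 and 37.5 eV", {
  expect_equal(strandBreakProbability(5.0), 0.0)
  expect_equal(strandBreakProbability(37.5), 1.0)
  expect_equal(strandBreakProbability(21.25), 0.5)
  expect_equal(strandBreakProbability(c(0, 2, 5)), c(0, 0, 0))
  expect_equal(strandBreakProbability(c(40, 1000)), c(1, 1))
  e <- seq(5, 37.5, length.out = 11)
  expect_equal(strandBreakProbability(e), (e - 5) / 32.5)
  expect_error(strandBreakProbability(-1), "energy")
})

test_that("opposite-strand breaks cluster within 10 bp, others stay isolated", {
  cl <- clusterStrandBreaks(data.frame(genomic_pos = c(100, 105),
                                       strand = c(1, 2)))
  expect_equal(nrow(cl$sites), 1L)
  expect_equal(nrow(cl$isolated), 0L)

  cl <- clusterStrandBreaks(data.frame(genomic_pos = c(100, 111),
                                       strand = c(1, 2)))
  expect_equal(nrow(cl$sites), 0L)
  expect_equal(nrow(cl$isolated), 2L)

  # exactly at the threshold: still one site
  cl <- clusterStrandBreaks(data.frame(genomic_pos = c(100, 110),
                                       strand = c(1, 2)))
  expect_equal(nrow(cl$sites), 1L)

  # same strand never forms a DSB
  cl <- clusterStrandBreaks(data.frame(genomic_pos = c(100, 102),
                                       strand = c(1, 1)))
  expect_equal(nrow(cl$sites), 0L)
  expect_equal(nrow(cl$isolated), 2L)

  # empty input
  cl <- clusterStrandBreaks(data.frame(genomic_pos = integer(0),
                                       strand = integer(0)))
  expect_equal(nrow(cl$sites), 0L)
})

test_that("clustering matches the brute-force oracle on random small inputs", {
  set.seed(42)
  for (trial in 1:200) {
    n <- sample(0:12, 1)
    b <- data.frame(genomic_pos = sample(0:40, n, replace = TRUE),
                    strand = sample(1:2, n, replace = TRUE))
    got <- clusterStrandBreaks(b)
    want <- oracleCluster(b)
    expect_equal(nrow(got$sites), want$nSites)
    expect_equal(nrow(got$isolated), want$nIsolated)
    if (want$nSites > 0) {
      gotPairs <- lapply(seq_len(nrow(got$sites)), function(i) {
        sort(c(got$sites$bp_a[i], got$sites$bp_b[i]))
      })
      expect_setequal(gotPairs, want$pairs)
    }
    # every reported site is a genuine opposite-strand pair within 10 bp
    if (nrow(got$sites) > 0) {
      expect_true(all(abs(got$sites$bp_a - got$sites$bp_b) <= 10))
    }
  }
})

test_that("photon damage yield is Poisson with the configured mean", {
  expect_equal(nSites(generatePhotonDamage(0, seed = 1)), 0L)
  counts <- vapply(1:4000, function(s) {
    nSites(generatePhotonDamage(1, seed = s))
  }, numeric(1))
  # mean 25 within 3 standard errors; variance equal to the mean (Poisson)
  se <- sqrt(25 / length(counts))
  expect_lt(abs(mean(counts) - 25), 3 * se)
  expect_lt(abs(var(counts) - mean(counts)) / mean(counts), 0.1)
  # Poisson linearity in dose
  counts4 <- vapply(1:2000, function(s) {
    nSites(generatePhotonDamage(4, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(counts4) - 100), 3 * sqrt(100 / length(counts4)))
  expect_lt(abs(var(counts4) - 100) / 100, 0.15)
  expect_error(generatePhotonDamage(-1), "dose")
})

test_that("generated positions lie strictly inside the nucleus", {
  d <- generatePhotonDamage(40, seed = 3)
  r <- sqrt(sites(d)$x^2 + sites(d)$y^2 + sites(d)$z^2)
  expect_true(all(r < 5000))
  dt <- generateTrackDamage(20, nPrimaries = 50, seed = 3)
  rt <- sqrt(sites(dt)$x^2 + sites(dt)$y^2 + sites(dt)$z^2)
  expect_true(all(rt < 5000))
})

test_that("identical seeds reproduce the damage set byte for byte", {
  d1 <- generatePhotonDamage(2, seed = 11)
  d2 <- generatePhotonDamage(2, seed = 11)
  expect_identical(sites(d1), sites(d2))
  f1 <- tempfile(); f2 <- tempfile()
  writeSDD(d1, f1); writeSDD(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("track damage yield rises with LET and vanishes without primaries", {
  expect_equal(nSites(generateTrackDamage(10, nPrimaries = 0, seed = 1)), 0L)
  perTrack <- function(let) {
    mean(vapply(1:300, function(s) {
      nSites(generateTrackDamage(let, nPrimaries = 3, seed = s)) / 3
    }, numeric(1)))
  }
  low <- perTrack(2); high <- perTrack(20)
  expect_gt(high, low)
  expect_error(generateTrackDamage(0, nPrimaries = 1), "let")
})

test_that("chromatin assignment is Bernoulli at the requested fraction", {
  d <- generatePhotonDamage(3, seed = 5)
  expect_true(all(sites(assignChromatin(d, 0, seed = 1))$chromatin ==
                  "euchromatin"))
  expect_true(all(sites(assignChromatin(d, 1, seed = 1))$chromatin ==
                  "heterochromatin"))
  big <- fixedDamage(matrix(0, nrow = 100000, ncol = 3))
  frac <- mean(sites(assignChromatin(big, 0.48, seed = 2))$chromatin ==
               "heterochromatin")
  expect_lt(abs(frac - 0.48), 0.01)
  expect_error(assignChromatin(d, 1.2), "[Ff]raction")
})
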