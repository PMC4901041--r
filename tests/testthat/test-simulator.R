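test_that("break_positions_uniform honours range, count and uniformity", {
  expect_identical(break_positions_uniform(0, 850), numeric(0))
  set.seed(3)
  p3 <- break_positions_uniform(3, 850)
  expect_length(p3, 3)
  expect_true(all(p3 >= 0 & p3 < 850))
  expect_error(break_positions_uniform(-1, 850), "non-negative")
  expect_error(break_positions_uniform(2, 0), "positive")

  # goodness of fit over 17 equal cells at alpha = 0.01
  set.seed(11)
  pos <- break_positions_uniform(1000, 850)
  counts <- tabulate(findInterval(pos, seq(0, 850, by = 50),
                                  rightmost.closed = TRUE), nbins = 17)
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("fragments_from_breaks returns circular spacings that conserve length", {
  expect_equal(fragments_from_breaks(c(0, 425), 850)$lengths, c(425, 425))
  expect_equal(sort(fragments_from_breaks(c(0, 100, 300), 850)$lengths),
               c(100, 200, 550))
  # a single break linearises the plasmid at full length
  one <- fragments_from_breaks(212.5, 850)
  expect_equal(one$lengths, 850)
  expect_identical(one$topology, "linear")
  # no breaks: intact circle
  zero <- fragments_from_breaks(numeric(0), 850)
  expect_identical(zero$topology, "circular")
  expect_equal(zero$lengths, 850)

  expect_error(fragments_from_breaks(c(0, 850), 850), "\\[0, L\\)")
  expect_error(fragments_from_breaks(-0.1, 850), "\\[0, L\\)")

  # property: k breaks -> k fragments, summing to L bit-exactly
  set.seed(21)
  for (rep in 1:50) {
    k <- sample(1:40, 1)
    fr <- fragments_from_breaks(runif(k, 0, 850), 850)
    expect_length(fr$lengths, k)
    expect_true(all(fr$lengths > 0))
    expect_identical(sum(fr$lengths), 850)
  }
})

test_that("simulate_sample: no radiation means intact circles only", {
  s <- simulate_sample(uniform_break_model(0), pUC19(), 100, seed = 1)
  expect_equal(nrow(s$records), 100)
  expect_true(all(s$records$topology == "circular"))
  expect_true(all(s$records$length_nm == 850))
})

test_that("simulate_sample is reproducible and extensible in n_plasmids", {
  m <- uniform_break_model(4)
  a <- simulate_sample(m, pUC19(), 300, seed = 7)
  b <- simulate_sample(m, pUC19(), 300, seed = 7)
  expect_identical(a$records, b$records)
  # per-plasmid sub-streams: a larger sample extends, never reshuffles
  big <- simulate_sample(m, pUC19(), 500, seed = 7)
  expect_identical(big$records$length_nm[big$records$plasmid <= 300],
                   a$records$length_nm)
  # different seed, different sample
  expect_false(identical(
    simulate_sample(m, pUC19(), 300, seed = 8)$records$length_nm,
    a$records$length_nm))
  # the caller's RNG state is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_sample(m, pUC19(), 10, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("per-plasmid conservation and fragment count = break count", {
  for (model in list(uniform_break_model(5.83),
                     clustered_break_model(2, cluster_size_geometric(3), 50))) {
    s <- simulate_sample(model, pUC19(), 2000, seed = 13)
    sums <- tapply(s$records$length_nm, s$records$plasmid, sum)
    expect_true(all(sums == 850))
    # every plasmid appears exactly once as a group (no dropped molecules)
    expect_equal(length(sums), 2000)
    # circular records only for unbroken plasmids, exactly one each
    circ <- s$records[s$records$topology == "circular", ]
    expect_true(all(table(circ$plasmid) == 1))
    expect_true(all(circ$length_nm == 850))
  }
})

test_that("uniform simulation recovers its Poisson mean", {
  n <- 20000
  s <- simulate_sample(uniform_break_model(5.83), pUC19(), n, seed = 31)
  est <- dsb_per_dna(s, 850)
  expect_lt(abs(est - 5.83), 3 * sqrt(5.83 / n))
})

test_that("detection model: floor drops short fragments, noise keeps positivity", {
  det <- detection_model(min_detectable_nm = 30)
  s <- simulate_sample(uniform_break_model(8), pUC19(), 3000, det, seed = 17)
  expect_true(all(s$records$length_nm[s$records$topology == "linear"] >= 30))
  # same seed without the floor produces short fragments that the floor removes
  s0 <- simulate_sample(uniform_break_model(8), pUC19(), 3000, seed = 17)
  expect_gt(sum(s0$records$length_nm < 30), 0)
  expect_lt(nrow(s$records), nrow(s0$records))

  det2 <- detection_model(length_noise_sd_nm = 5)
  s2 <- simulate_sample(uniform_break_model(8), pUC19(), 1000, det2, seed = 19)
  expect_true(all(s2$records$length_nm > 0))
  circ <- s2$records$length_nm[s2$records$topology == "circular"]
  expect_true(all(abs(circ - 850) < 5 * 6))  # within 6 sd of the intact length
})

test_that("single-break clusters reduce the clustered model to the uniform one", {
  mu <- 4
  u <- simulate_sample(uniform_break_model(mu), pUC19(), 4000, seed = 23)
  c1 <- simulate_sample(clustered_break_model(mu, cluster_size_fixed(1), 50),
                        pUC19(), 4000, seed = 24)
  lu <- u$records$length_nm[u$records$topology == "linear"]
  lc <- c1$records$length_nm[c1$records$topology == "linear"]
  ks <- suppressWarnings(stats::ks.test(lu, lc))
  expect_gt(ks$p.value, 0.01)
  # break counts agree too
  expect_lt(abs(length(lu) - length(lc)) / length(lu), 3 * sqrt(2 / (mu * 4000)))
})

test_that("conditional fragment-length law matches the brute-force spacings oracle", {
  # condition on exactly k = 3 breaks and compare with directly simulated
  # spacings of 3 uniform cuts
  s <- simulate_sample(uniform_break_model(3), pUC19(), 8000, seed = 29)
  rec <- s$records[s$records$topology == "linear", ]
  k_per <- table(rec$plasmid)
  keep <- names(k_per)[k_per == 3]
  obs <- rec$length_nm[rec$plasmid %in% as.integer(keep)]
  expect_gte(length(obs), 5000)
  orc <- oracle_conditional_spacings(3, 850, 2000, seed = 31)
  ks <- suppressWarnings(stats::ks.test(obs, orc))
  expect_gt(ks$p.value, 0.01)
})

test_that("short-fragment fraction is monotone in cluster size and span", {
  mu_tot <- 6; n <- 20000
  means <- c(2, 4, 8); spans <- c(30, 120, 480)
  frac <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- clustered_break_model(mu_tot / means[i], cluster_size_geometric(means[i]),
                               spans[j])
    s <- simulate_sample(m, pUC19(), n, seed = 99)
    d <- bin_fragments(s, 850)
    frac[i, j] <- d$counts[1] / d$n_fragments
  }
  # non-decreasing in mean cluster size at every span
  expect_true(all(apply(frac, 2, function(x) all(diff(x) >= 0))))
  # non-increasing in cluster span at every mean size
  expect_true(all(apply(frac, 1, function(x) all(diff(x) <= 0))))
})

test_that("simulate_sample rejects invalid configuration", {
  expect_error(simulate_sample(uniform_break_model(2), pUC19(), 0, seed = 1),
               "n_plasmids")
  expect_error(simulate_sample(uniform_break_model(2), pUC19(), 10),
               "seed")
  expect_error(simulate_sample(list(mu = 2), pUC19(), 10, seed = 1),
               "break model")
  expect_error(
    simulate_sample(clustered_break_model(1, cluster_size_fixed(2), 900),
                    pUC19(), 10, seed = 1),
    "cluster_span_nm")
})
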