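test_that("the mismatch-rate ECDF equals direct counting", {
  e <- build_delta_ecdf(c(0, 0, 0.1, 0.5))
  expect_equal(q_delta(e, 0.5), 1)
  expect_equal(q_delta(e, 0.1), 0.75)
  expect_equal(q_delta(e, 0), 0.5)
  # between observed values: inclusive "<=" convention
  expect_equal(q_delta(e, 0.3), 0.75)
  # below every observed value: floored, never zero
  expect_equal(q_delta(e, -0.01), 1 / 5)
  # excluding delta = 0 sites
  e0 <- build_delta_ecdf(c(0, 0, 0.1, 0.5), include_zero = FALSE)
  expect_equal(q_delta(e0, 0.1), 0.5)
  expect_equal(q_delta(e0, 0.5), 1)
  expect_error(build_delta_ecdf(numeric()), "no sites")
})

test_that("q(delta) is monotone and in (0, 1] on random inputs", {
  set.seed(31)
  for (rep in 1:5) {
    delta <- sample(0:20, 200, replace = TRUE) / sample(20:60, 200,
                                                        replace = TRUE)
    e <- build_delta_ecdf(delta)
    grid <- sort(c(delta, runif(50)))
    q <- q_delta(e, grid)
    expect_true(all(diff(q) >= 0))
    expect_true(all(q > 0 & q <= 1))
    expect_equal(q_delta(e, max(delta)), 1)
    # direct counting oracle on the observed support
    expect_equal(q_delta(e, delta),
                 vapply(delta, function(d) mean(delta <= d), numeric(1)))
  }
})

test_that("background sampling honours the qualifying window 0 < delta < 0.5", {
  # 3 qualifying sites among invariant, high-delta and fully variant ones
  pb <- rbind(
    make_cs(rep("A", 10), pos = 1L),                      # delta = 0
    make_cs(rep(c("C", "A"), c(1, 9)), pos = 2L),         # 0.1
    make_cs(rep(c("C", "A"), c(2, 8)), pos = 3L),         # 0.2
    make_cs(rep(c("C", "A"), c(4, 6)), pos = 4L),         # 0.4
    make_cs(rep(c("C", "A"), c(5, 5)), pos = 5L),         # 0.5: excluded
    make_cs(rep(c("C", "A"), c(6, 4)), pos = 6L),         # 0.6: excluded
    make_cs(rep("C", 10), pos = 7L)                       # 1.0: excluded
  )
  expect_warning(bg <- sample_background_sites(pb, n = 100000L, seed = 1L),
                 "qualify")
  sites <- attr(bg, "sites")
  expect_setequal(sites$pos, 2:4)
  expect_equal(nrow(bg), 30L)

  sub <- sample_background_sites(pb, n = 2L, seed = 7L)
  expect_equal(nrow(attr(sub, "sites")), 2L)
  expect_true(all(attr(sub, "sites")$pos %in% 2:4))

  # reproducible given the seed; no leakage into the caller's RNG
  s1 <- attr(sample_background_sites(pb, n = 2L, seed = 7L), "sites")
  expect_identical(s1, attr(sub, "sites"))

  only_bad <- rbind(make_cs(rep("A", 4), pos = 1L),
                    make_cs(rep("C", 4), pos = 2L))
  expect_error(sample_background_sites(only_bad, n = 5L),
               "no background estimable")
})

test_that("conditional tables apply additive smoothing as specified", {
  # one read position bin with 99 matches and 1 mismatch
  pb <- make_cs(rep(c("C", "A"), c(1, 99)), read_pos = 10L,
                read_len = 100L)
  tabs <- estimate_conditional_tables(pb, p_bins = 50L, pseudocount = 0.5)
  b <- ceiling((10 / 100) * 50)
  expect_equal(tabs$P$prob[b], 99.5 / 101)
  # unobserved bin: uninformative prior
  expect_equal(tabs$P$prob[40], 0.5)
  expect_true(all(tabs$P$prob > 0 & tabs$P$prob < 1))
  # every base contributes exactly one count per table
  for (k in c("P", "R", "H")) {
    expect_equal(sum(tabs[[k]]$match) + sum(tabs[[k]]$mismatch), 100L)
  }
  # maxima over occupied bins only
  expect_equal(tabs$P$p_M, 99.5 / 101)
  expect_equal(tabs$P$p_Mbar, 1 - 99.5 / 101)
})

test_that("R and H values beyond the last bin pool into the overflow bin", {
  pb <- rbind(
    make_cs("C", read_errors = 25L, read_hits = 60L, pos = 1L),
    make_cs("C", read_errors = 99L, read_hits = 99L, pos = 2L),
    make_cs("A", read_errors = 3L, read_hits = 1L, pos = 3L)
  )
  tabs <- estimate_conditional_tables(pb, r_max = 20L, h_max = 50L)
  expect_equal(tabs$R$mismatch[22], 2L)   # both overflow R values
  expect_equal(tabs$H$mismatch[51], 2L)
  expect_equal(ct_lookup(tabs$R, 25L), ct_lookup(tabs$R, 99L))
  expect_equal(ct_lookup(tabs$H, 60L), ct_lookup(tabs$H, 99L))
})

test_that("a position-independent error process gives a flat Pr(M|P)", {
  cfg <- sim_config(genome_length = 20000L, coverage = 40,
                    n_variants = 0L, error_rate = 0.02,
                    error_profile = "flat", error_sdlog = 0,
                    seed = 77L)
  ds <- simulate_dataset(cfg, dir = tempfile("flat"))
  pb <- read_pileup(ds$bam, ds$fasta)
  bg <- suppressWarnings(sample_background_sites(pb, n = 100000L, seed = 2L))
  tabs <- estimate_conditional_tables(bg)
  occ <- (tabs$P$match + tabs$P$mismatch) > 0
  p <- tabs$P$prob[occ]
  tot <- (tabs$P$match + tabs$P$mismatch)[occ]
  # flat within binomial sampling error: 4 sigma around the pooled mean
  pool <- sum(tabs$P$match[occ]) / sum(tot)
  se <- sqrt(pool * (1 - pool) / tot)
  expect_true(all(abs(p - pool) < 4 * se + 2 / tot))
  # the rescaling constant log(P_Mbar / P_M) is stable across datasets
  # drawn from the same flat error process
  cfg2 <- sim_config(genome_length = 20000L, coverage = 40,
                     n_variants = 0L, error_rate = 0.02,
                     error_profile = "flat", error_sdlog = 0,
                     seed = 79L)
  ds2 <- simulate_dataset(cfg2, dir = tempfile("flat2"))
  pb2 <- read_pileup(ds2$bam, ds2$fasta)
  bg2 <- suppressWarnings(sample_background_sites(pb2, n = 100000L,
                                                  seed = 2L))
  tabs2 <- estimate_conditional_tables(bg2)
  expect_lt(abs(log(tabs$P$p_Mbar / tabs$P$p_M) -
                  log(tabs2$P$p_Mbar / tabs2$P$p_M)), 0.4)
})

test_that("errors rising toward read ends depress Pr(M|P) there", {
  cfg <- sim_config(genome_length = 20000L, coverage = 40,
                    n_variants = 0L, error_rate = 0.03,
                    error_profile = "linear", ramp_factor = 6,
                    error_sdlog = 0, seed = 78L)
  ds <- simulate_dataset(cfg, dir = tempfile("ramp"))
  pb <- read_pileup(ds$bam, ds$fasta)
  bg <- suppressWarnings(sample_background_sites(pb, n = 100000L, seed = 2L))
  tabs <- estimate_conditional_tables(bg)
  occ <- which((tabs$P$match + tabs$P$mismatch) > 0)
  p <- tabs$P$prob[occ]
  # monotone trend: later read positions have lower match probability
  expect_lt(cor(tabs$P$values[occ], p, method = "spearman"), -0.8)
  expect_lt(mean(p[tail(seq_along(p), 5)]), mean(p[1:5]))
})

test_that("background models serialize and reload bit-identically", {
  fix <- small_sim_fixture()
  model <- fix$model
  path <- tempfile(fileext = ".json")
  write_background_model(model, path)
  m2 <- read_background_model(path)
  grid <- c(0, 0.013, 1 / 7, 0.2499999, 0.5, 1)
  expect_identical(q_delta(model$ecdf, grid), q_delta(m2$ecdf, grid))
  for (k in c("P", "R", "H")) {
    expect_identical(model$tables[[k]]$prob, m2$tables[[k]]$prob)
    expect_identical(model$tables[[k]]$match, m2$tables[[k]]$match)
  }
  expect_identical(model$tables$P$p_M, m2$tables$P$p_M)
  expect_identical(model$tables$P$p_Mbar, m2$tables$P$p_Mbar)
  # unknown versions are rejected
  bad <- jsonlite::read_json(path)
  bad$version <- 99
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE)
  expect_error(read_background_model(path2), "version")
})

test_that("sampling with different seeds stays within binomial error", {
  fix <- small_sim_fixture()
  pb <- fix$pb
  b1 <- sample_background_sites(pb, n = 3000L, seed = 1L)
  b2 <- sample_background_sites(pb, n = 3000L, seed = 2L)
  t1 <- estimate_conditional_tables(b1)
  t2 <- estimate_conditional_tables(b2)
  tot1 <- t1$P$match + t1$P$mismatch
  tot2 <- t2$P$match + t2$P$mismatch
  occ <- tot1 > 50 & tot2 > 50
  se <- sqrt(t1$P$prob * (1 - t1$P$prob) * (1 / tot1 + 1 / tot2))
  expect_true(all(abs(t1$P$prob[occ] - t2$P$prob[occ]) <
                    6 * se[occ] + 0.02))
})
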