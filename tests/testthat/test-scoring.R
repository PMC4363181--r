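# hand-made conditional tables with known probabilities
fake_P_table <- function(prob_all, p_M, p_Mbar, p_bins = 50L) {
  structure(list(kind = "P", values = seq_len(p_bins) / p_bins,
                 match = rep(1L, p_bins), mismatch = rep(1L, p_bins),
                 prob = rep(prob_all, p_bins), p_bins = p_bins,
                 r_max = 20L, h_max = 50L, pseudocount = 0.5,
                 p_M = p_M, p_Mbar = p_Mbar),
            class = "conditional_table")
}

fake_int_table <- function(kind, prob_all, r_max = 20L, h_max = 50L) {
  n <- if (kind == "R") r_max + 2L else h_max + 1L
  structure(list(kind = kind, values = seq_len(n),
                 match = rep(1L, n), mismatch = rep(1L, n),
                 prob = rep(prob_all, n), p_bins = 50L,
                 r_max = r_max, h_max = h_max, pseudocount = 0.5),
            class = "conditional_table")
}

test_that("the base-quality component is the mean mismatch log-odds", {
  expect_equal(delta_Q(make_cs("C", qual = 0.5)), 0)
  cs <- make_cs(rep(c("C", "A"), c(1, 9)), qual = 0.99)
  expect_equal(delta_Q(cs), log(99) / 10)
  cs2 <- make_cs(rep(c("C", "A"), c(2, 2)), qual = 0.9)
  expect_equal(delta_Q(cs2), 2 * log(9) / 4)
  # qualities are clamped, so extreme values stay finite
  expect_true(is.finite(delta_Q(make_cs("C", qual = 1))))
  expect_true(is.finite(delta_Q(make_cs("C", qual = 0))))
})

test_that("the read-position component applies the maximum rescaling", {
  t0 <- fake_P_table(0.5, p_M = 0.6, p_Mbar = 0.6)
  expect_equal(delta_P(make_cs("C"), t0), 0)
  t1 <- fake_P_table(0.99, p_M = 0.99, p_Mbar = 0.05)
  expect_equal(delta_P(make_cs("C"), t1), log(99) + log(0.05 / 0.99))
  # linearity: per-base terms sum
  cs3 <- make_cs(rep(c("C", "A"), c(3, 7)), read_pos = 10L)
  expect_equal(delta_P(cs3, t1),
               3 * (log(99) + log(0.05 / 0.99)) / 10)
})

test_that("read-error and multiplicity components match brute-force sums", {
  fix <- small_sim_fixture()
  tabs <- fix$model$tables
  cs <- make_cs(c("C", "G", "A"), qual = c(0.9, 0.8, 0.99),
                read_pos = c(3L, 97L, 50L), read_len = 100L,
                read_errors = c(0L, 2L, 1L), read_hits = c(1L, 4L, 1L))
  brute_R <- sum(vapply(which(cs$is_mismatch), function(i) {
    p <- tabs$R$prob[min(cs$read_errors[i], 20L) + 1L]
    log(p / (1 - p))
  }, numeric(1))) / nrow(cs)
  expect_equal(delta_R(cs, tabs$R), brute_R)
  brute_H <- sum(vapply(which(cs$is_mismatch), function(i) {
    p <- tabs$H$prob[min(cs$read_hits[i], 51L)]
    log(p / (1 - p))
  }, numeric(1))) / nrow(cs)
  expect_equal(delta_H(cs, tabs$H), brute_H)
  # Pr(M|x) = 0.5 contributes nothing
  half <- fake_int_table("R", 0.5)
  expect_equal(delta_R(cs, half), 0)
  # overflow values use the overflow bin log-odds
  cs_of <- make_cs("C", read_errors = 500L)
  expect_equal(delta_R(cs_of, tabs$R),
               log(tabs$R$prob[22] / (1 - tabs$R$prob[22])))
})

test_that("all-match cross-sections are excluded from the model", {
  fix <- small_sim_fixture()
  expect_null(score_site(make_cs(rep("A", 5)), fix$model))
  sc <- score_pileup(rbind(make_cs(rep("A", 5), pos = 1L),
                           make_cs(c("C", rep("A", 4)), pos = 2L)),
                     fix$model)
  expect_equal(sc$pos, 2L)
})

test_that("the total score is the sum of its components", {
  fix <- small_sim_fixture()
  pb <- fix$pb
  sc <- score_pileup(pb, fix$model)
  expect_true(all(abs(sc$score -
                        (sc$d_Q + sc$d_P + sc$d_R + sc$d_H + sc$log_q)) <
                    1e-12))
  expect_true(all(sc$log_q <= 0))
  expect_true(all(sc$n_mismatch >= 1L))
  # score_site agrees with the vectorized path
  cs <- pb[chrom == sc$chrom[1] & pos == sc$pos[1]]
  one <- score_site(cs, fix$model)
  expect_equal(one$score, sc$score[1])
  expect_equal(one$alt, sc$alt[1])
})

test_that("raising a mismatch quality never decreases the score", {
  fix <- small_sim_fixture()
  quals <- c(0.2, 0.5, 0.9, 0.99, 0.999)
  scores <- vapply(quals, function(q) {
    cs <- make_cs(rep(c("C", "A"), c(2, 8)), qual = q)
    score_site(cs, fix$model)$score
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("a higher mismatch-rate quantile never decreases the score", {
  fix <- small_sim_fixture()
  # same evidence per mismatch, increasing delta -> increasing q(delta)
  cs_lo <- make_cs(rep(c("C", "A"), c(1, 19)))
  cs_hi <- make_cs(rep(c("C", "A"), c(10, 10)))
  q_lo <- q_delta(fix$model$ecdf, mismatch_rate(cs_lo))
  q_hi <- q_delta(fix$model$ecdf, mismatch_rate(cs_hi))
  expect_gte(q_hi, q_lo)
  # isolate the quantile term: identical components, different log_q
  s_lo <- score_site(cs_lo, fix$model)
  s_hi <- score_site(cs_hi, fix$model)
  expect_gte(s_hi$log_q, s_lo$log_q)
})

test_that("duplicating every read leaves delta and all components unchanged", {
  fix <- small_sim_fixture()
  set.seed(99)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    cs <- make_cs(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                         prob = c(0.6, 0.2, 0.1, 0.1)),
                  qual = runif(n, 0.3, 0.999),
                  read_pos = sample(100L, n, replace = TRUE),
                  read_errors = sample(0:4, n, replace = TRUE),
                  read_hits = sample(c(1L, 1L, 2L, 5L), n, replace = TRUE))
    if (!any(cs$is_mismatch)) next
    s1 <- score_site(cs, fix$model)
    s2 <- score_site(rbind(cs, cs), fix$model)
    expect_equal(s2$delta, s1$delta)
    for (f in c("d_Q", "d_P", "d_R", "d_H", "log_q", "score")) {
      expect_equal(s2[[f]], s1[[f]])
    }
  }
})

test_that("the reported alt is the modal mismatch base, ties alphabetical", {
  fix <- small_sim_fixture()
  s <- score_site(make_cs(c("T", "T", "C", "A", "A")), fix$model)
  expect_equal(s$alt, "T")
  expect_equal(s$other_alts, "C")
  tie <- score_site(make_cs(c("T", "C", "A", "A")), fix$model)
  expect_equal(tie$alt, "C")
  expect_equal(tie$other_alts, "T")
})

test_that("variant sites score above noise sites on simulated data", {
  fix <- small_sim_fixture()
  sc <- score_pileup(fix$pb, fix$model)
  truth <- fix$ds$truth
  on_truth <- sc[truth[, .(chrom, pos)], on = c("chrom", "pos"),
                 nomatch = NULL]
  noise <- sc[!truth[, .(chrom, pos)], on = c("chrom", "pos")]
  expect_gt(mean(on_truth$score), mean(noise$score) + 2)
  expect_lt(t.test(noise$score, on_truth$score,
                   alternative = "less")$p.value, 1e-6)
})
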