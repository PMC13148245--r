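test_that("Kruskal-Wallis reproduces the textbook two-group case", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p, 0.0495, tolerance = 1e-3)
  expect_equal(kw$p_exact, 0.1)            # 2 of the 20 splits reach this H

  same <- kruskal_wallis(list(rep(2, 4), rep(2, 4)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
})

test_that("the exact small-sample p matches an independent enumeration", {
  set.seed(61)
  for (i in 1:5) {
    g1 <- rnorm(4); g2 <- rnorm(4)
    kw <- kruskal_wallis(list(g1, g2))
    pooled <- c(g1, g2)
    combs <- combn(8, 4)
    Hs <- apply(combs, 2, function(idx)
      brute_kw_H(pooled[idx], pooled[-idx]))
    expect_equal(kw$H, brute_kw_H(g1, g2), tolerance = 1e-9)
    expect_equal(kw$p_exact, mean(Hs >= kw$H - 1e-12), tolerance = 1e-12)
  }
})

test_that("Bonferroni multiplies and clips", {
  expect_equal(bonferroni(0.01, 12), 0.12)
  expect_equal(bonferroni(0.2, 10), 1)
  expect_equal(bonferroni(c(0.3, 0.04), 1), c(0.3, 0.04))
  p <- runif(20)
  expect_true(all(bonferroni(p, 7) >= p))
  expect_true(all(bonferroni(p, 7) <= 1))
})

test_that("the emotion chi-square matches its closed forms", {
  cs <- chi_square_emotion(5, 25)
  expect_equal(cs$chisq, 40 / 3, tolerance = 1e-9)
  expect_lt(cs$p, 0.001)

  expect_equal(chi_square_emotion(17, 17)$p, 1)

  small <- chi_square_emotion(6, 0)
  expect_equal(small$chisq, 6)
  expect_equal(small$p, pchisq(6, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(small$p_exact, 2 / 64)

  expect_true(is.na(chi_square_emotion(0, 0)$p))
})

test_that("the Pearson t-test follows the closed form", {
  x <- 1:20
  perfect <- pearson_test(x, 2 * x + 1)
  expect_equal(perfect$r, 1)
  expect_lt(perfect$p, 1e-12)

  # exactly orthogonal pair: r = 0, p = 1
  r0 <- pearson_test(rep(c(-1, 1), 3), c(1, 1, -1, -1, 0, 0))
  expect_equal(r0$r, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-9)

  set.seed(62)
  mt <- pearson_test(rnorm(100), rnorm(100))
  expect_equal(mt$df, 98)
  expect_true(is.na(pearson_test(rep(1, 10), rnorm(10))$r))
})

test_that("contrast tables keep the quantile definition and directed classes", {
  features <- data.frame(
    segment_id = rep(1:6, each = 2),
    participant_id = rep(c("p1", "p2"), 6),
    feature = "f",
    value = c(10, 1, 11, 2, 12, 3, 1.5, 10.5, 2.5, 11.5, 3.5, 12.5))
  coupling <- data.frame(segment_id = 1:6,
                         lag_class = rep(c("POS", "NEG"), each = 3),
                         corr_class = "POS")
  tab <- build_contrast_table(features, coupling, "lag", c("p1", "p2"))
  # POS-directed observations: p1 of segments 1-3 and p2 of segments 4-6
  pos_vals <- c(10, 11, 12, 10.5, 11.5, 12.5)
  expect_equal(tab$pos_median, median(pos_vals))
  expect_equal(tab$pos_q25, quantile(pos_vals, 0.25, names = FALSE))
  expect_equal(tab$n_pos, 6)
  expect_equal(tab$n_neg, 6)
  expect_lt(tab$p_adj, 0.05)
})

test_that("null simulations keep the contrast false-positive rate in check", {
  set.seed(63)
  n_sig <- 0; n_tests <- 0
  for (i in 1:40) {
    features <- data.frame(segment_id = rep(1:20, each = 2),
                           participant_id = rep(c("p1", "p2"), 20),
                           feature = rep(c("a", "b"), each = 40)[1:40],
                           value = rnorm(40))
    coupling <- data.frame(segment_id = 1:20,
                           lag_class = sample(c("POS", "NEG"), 20, TRUE),
                           corr_class = "POS")
    tab <- build_contrast_table(features, coupling, "lag", c("p1", "p2"))
    n_sig <- n_sig + sum(tab$p_adj < 0.05, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(tab$p_adj))
  }
  expect_lte(n_sig / n_tests, 0.05)
})

test_that("an injected one-SD class shift is detected with high power", {
  set.seed(64)
  hits <- 0
  for (i in 1:20) {
    cls <- rep(c("POS", "NEG"), each = 30)
    vals <- rnorm(60) + (cls == "POS") * 1
    features <- data.frame(segment_id = 1:60, participant_id = "p1",
                           feature = "f", value = vals)
    features <- rbind(features,
                      data.frame(segment_id = 1:60, participant_id = "p2",
                                 feature = "f", value = NA_real_))
    coupling <- data.frame(segment_id = 1:60, lag_class = cls,
                           corr_class = "POS")
    tab <- build_contrast_table(features, coupling, "lag", c("p1", "p2"))
    if (!is.na(tab$p_adj) && tab$p_adj < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("emotion tables conserve counts and give flat tables p near 1", {
  sim <- quick_sim(seed = 65, duration = 300)
  tracks <- lapply(sim$truth$beats, interpolate_rr, fs = 64, n = 300 * 64)
  seg <- segment_phases(sim$bundle$speak_mask$p1, sim$bundle$speak_mask$p2)
  seg <- attach_emotions(seg, sim$bundle$emotion)
  cp <- couple_session(tracks, seg)
  tab <- build_emotion_table(seg, cp, "lag")

  classified <- sum(cp$lag_class %in% c("POS", "NEG") &
                      cp$segment_id %in% seg$segment_id[seg$kept])
  sa <- tab[tab$perspective == "self" & tab$dimension == "arousal", ]
  expect_equal(sum(sa$pos_count + sa$neg_count), classified)
  tot <- tab[tab$perspective == "total" & tab$dimension == "arousal", ]
  expect_equal(sum(tot$pos_count + tot$neg_count), 3 * classified)
  ok <- !is.na(sa$pos_pct)
  expect_equal(sa$pos_pct[ok] + sa$neg_pct[ok], rep(100, sum(ok)))

  # equal-count construction: every defined cell p equals 1
  flat <- data.frame(segment_id = 1:8, self_arousal = rep(1:2, each = 4))
  cpf <- data.frame(segment_id = 1:8, lag_class = rep(c("POS", "NEG"), 4),
                    corr_class = "POS")
  tf <- build_emotion_table(flat, cpf, "lag")
  expect_true(all(tf$p[!is.na(tf$p)] == 1))
})

test_that("the omnibus association test flags only biased emotion structure", {
  sim <- quick_sim(seed = 66, duration = 600)   # bias ties 4-5 to POS
  tracks <- lapply(sim$truth$beats, interpolate_rr, fs = 64, n = 600 * 64)
  seg <- segment_phases(sim$bundle$speak_mask$p1, sim$bundle$speak_mask$p2)
  seg <- attach_emotions(seg, sim$bundle$emotion)
  cp <- couple_session(tracks, seg)
  tab <- build_emotion_table(seg, cp, "lag")
  at <- emotion_association_test(tab, "arousal", "self")
  expect_lt(at$p, 0.05)

  simn <- quick_sim(seed = 67, duration = 600,
                    emotion_bias = emotion_bias_null())
  tracksn <- lapply(simn$truth$beats, interpolate_rr, fs = 64, n = 600 * 64)
  segn <- segment_phases(simn$bundle$speak_mask$p1, simn$bundle$speak_mask$p2)
  segn <- attach_emotions(segn, simn$bundle$emotion)
  cpn <- couple_session(tracksn, segn)
  tabn <- build_emotion_table(segn, cpn, "lag")
  atn <- emotion_association_test(tabn, "arousal", "self")
  expect_gt(atn$p, 0.05)
})
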