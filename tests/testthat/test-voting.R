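test_that("SCAV hand examples: both branches and unanimity", {
  # 3 models, sample probs (0.6, 0.7, 0.2), t = 2: two mutant votes
  m <- matrix(c(0.6, 0.7, 0.2, 0.4, 0.3, 0.6), nrow = 3)
  r <- scav_vote(m, t = 2)
  expect_equal(r$score[1], 0.65)
  expect_equal(as.character(r$label[1]), "mutant")
  # second sample: one vote < t -> wildtype branch average
  expect_equal(r$score[2], 0.35)
  expect_equal(as.character(r$label[2]), "wildtype")

  uni <- scav_vote(matrix(0.9, 4, 1), t = 1)
  expect_equal(uni$score, 0.9)
  expect_equal(as.character(uni$label), "mutant")

  expect_error(scav_vote(m, t = 0), "'t'")
  expect_error(scav_vote(m, t = 4), "'t'")
})

test_that("SCAV agrees exactly with the naive per-sample oracle", {
  set.seed(23)
  for (rep in 1:1000) {
    m <- sample(1:10, 1)
    n <- sample(1:50, 1)
    sc <- random_score_matrix(m, n)
    t <- sample(m, 1)
    got <- scav_vote(sc, t)
    want <- naive_scav(sc, t)
    expect_equal(got$score, want$score)
    expect_identical(as.character(got$label), want$label)
  }
})

test_that("t = 1 is the any-vote rule and t = m requires unanimity", {
  set.seed(31)
  for (rep in 1:200) {
    sc <- random_score_matrix(5, 20)
    any_rule <- scav_vote(sc, 1)
    expect_identical(any_rule$label == "mutant",
                     apply(sc >= 0.5, 2, any))
    unan <- scav_vote(sc, 5)
    expect_identical(unan$label == "mutant", apply(sc >= 0.5, 2, all))
  }
})

test_that("minority-labelled set shrinks as t grows: sensitivity down, specificity up", {
  set.seed(37)
  for (rep in 1:50) {
    sc <- random_score_matrix(8, 40)
    y <- rep(c("mutant", "wildtype"), c(10, 30))[sample(40)]
    prev <- NULL
    sens <- spec <- numeric(8)
    for (t in 1:8) {
      r <- scav_vote(sc, t)
      mut <- which(r$label == "mutant")
      if (!is.null(prev)) expect_true(all(mut %in% prev))
      prev <- mut
      cm <- confusion_metrics(y, as.character(r$label))
      sens[t] <- cm$sensitivity
      spec[t] <- cm$specificity
    }
    expect_true(all(diff(sens) <= 1e-12))
    expect_true(all(diff(spec) >= -1e-12))
  }
})

test_that("label always equals score >= 0.5 across all three schemes", {
  set.seed(41)
  for (rep in 1:100) {
    sc <- random_score_matrix(sample(1:7, 1), sample(2:30, 1))
    for (r in list(scav_vote(sc, sample(nrow(sc), 1)), average_vote(sc),
                   maximum_vote(sc))) {
      expect_identical(r$label == "mutant", r$score >= 0.5)
    }
  }
})

test_that("average voting averages, and reduces to the single model", {
  r <- average_vote(matrix(c(0.6, 0.2), nrow = 2))
  expect_equal(r$score, 0.4)
  expect_equal(as.character(r$label), "wildtype")

  one <- matrix(stats::runif(10), 1)
  expect_equal(average_vote(one)$score, drop(one))
})

test_that("maximum voting picks the most confident model, ties to lowest index", {
  r <- maximum_vote(matrix(c(0.6, 0.1), nrow = 2))
  expect_equal(r$score, 0.1)                 # model 2: confidence 0.9
  expect_equal(as.character(r$label), "wildtype")

  sure <- maximum_vote(rbind(c(0.7, 0.6), c(1.0, 1.0)))
  expect_equal(sure$score, c(1, 1))

  tie <- maximum_vote(rbind(c(0.3), c(0.7)))  # equal confidence -> model 1
  expect_equal(tie$score, 0.3)

  same <- matrix(rep(c(0.8, 0.3), each = 3), nrow = 3, byrow = TRUE)
  same <- rbind(c(0.8, 0.3), c(0.8, 0.3), c(0.8, 0.3))
  expect_equal(maximum_vote(same)$score, average_vote(same)$score)
})

test_that("threshold selection maximizes training AUC with smallest-t ties", {
  # two informative models, one anti-informative: t = 2 separates perfectly
  y <- rep(c("mutant", "wildtype"), each = 4)
  good <- c(0.9, 0.8, 0.9, 0.7, 0.2, 0.3, 0.1, 0.2)
  sc <- rbind(good, good, 1 - good)
  sel <- select_threshold(sc, y)
  expect_equal(max(sel$auc_by_t), 1)
  expect_identical(sel$t, match(1, sel$auc_by_t))

  single <- select_threshold(matrix(stats::runif(6), 1),
                             rep(c("mutant", "wildtype"), 3))
  expect_identical(single$t, 1L)

  # duplicating rows doubles the vote counts: tuned t preserves the same
  # vote fraction (smallest-t tie rule)
  set.seed(5)
  sc2 <- random_score_matrix(4, 30)
  y2 <- rep(c("mutant", "wildtype"), c(8, 22))[sample(30)]
  t1 <- select_threshold(sc2, y2)
  t2 <- select_threshold(rbind(sc2, sc2), y2)
  expect_equal(t2$auc_by_t[2 * t1$t], t1$auc_by_t[t1$t])
  expect_lte(t2$t, 2 * t1$t)
  expect_error(select_threshold(sc2, rep("mutant", 30)), "both classes")
})

test_that("member ranking takes the k largest training AUCs, stable under ties", {
  expect_identical(rank_members(c(0.7, 0.6, 0.8), 2), c(3L, 1L))
  expect_identical(rank_members(c(0.7, 0.6, 0.8), 3), c(3L, 1L, 2L))
  expect_identical(rank_members(c(0.7, 0.7, 0.5), 1), 1L)
  expect_error(rank_members(c(0.7, 0.6), 3), "exceeds")
})

test_that("scav_ensemble fits members + threshold on training data and predicts", {
  lab <- rep(c(1, 0), c(28, 172))[sample(200)]
  sc <- simulate_score_matrix(lab, n_models = 10, discrimination = 0.5,
                              model_noise_sd = 1, seed = 17)
  fit <- scav_ensemble(sc, lab, n_members = 5)
  expect_s3_class(fit, "scav_ensemble")
  expect_length(fit$members, 5)
  expect_identical(fit$members, rank_members(fit$member_aucs, 5))
  expect_true(fit$t >= 1 && fit$t <= 5)
  # predictions on the training matrix reproduce the fitted voting rule
  pred <- predict(fit, sc)
  direct <- scav_vote(sc[fit$members, ], fit$t)
  expect_equal(pred$score, direct$score)
  # row-name matching: shuffled rows give the same prediction
  shuffled <- sc[rev(seq_len(nrow(sc))), ]
  expect_equal(predict(fit, shuffled)$score, pred$score)
  # average/maximum fits carry no threshold
  fa <- scav_ensemble(sc, lab, voting = "average", n_members = 5)
  expect_true(is.na(fa$t))
  expect_equal(predict(fa, sc)$score,
               average_vote(sc[fa$members, ])$score)
})

test_that("ensemble fit errors on degenerate inputs", {
  sc <- random_score_matrix(3, 10)
  expect_error(scav_ensemble(sc, rep(1, 10)), "both classes")
  expect_error(scav_ensemble(sc, rep(c(1, 0), 5), n_members = 7), "exceeds")
  expect_error(score_matrix(matrix(c(0.2, 1.4), 1)), "pseudo-probabilities")
})
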