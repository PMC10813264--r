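test_that("the bank has 18 templates over a partition of the 90 frames", {
  syn <- synthetic_features()
  bank <- fit_templates(syn$features, syn$directions)
  expect_length(bank$templates, 18L)
  dirs <- vapply(bank$templates, `[[`, "", "direction")
  wins <- vapply(bank$templates, `[[`, 1, "window")
  expect_equal(sum(dirs == "right"), 9L)
  expect_equal(sum(dirs == "left"), 9L)
  expect_equal(sort(unique(wins)), 1:9)
  # frame pairs 2..90 partition into windows: 9 pairs in window 1, 10 in 2..9
  expect_equal(as.vector(table(bank$pair_window)), c(9L, rep(10L, 8L)))
  expect_true(all(unlist(lapply(bank$templates, `[[`, "sigma2")) > 0))
})

test_that("training is permutation invariant and validates its inputs", {
  syn <- synthetic_features(n_per_class = 3)
  bank <- fit_templates(syn$features, syn$directions)
  perm <- c(4, 1, 6, 2, 5, 3)
  bank_p <- fit_templates(syn$features[perm], syn$directions[perm])
  expect_equal(bank_p$templates, bank$templates)
  expect_equal(bank_p$scale, bank$scale)
  expect_error(fit_templates(syn$features[1:2], c("right", "right")),
               "per direction")
  bad <- syn$features; bad[[1]] <- bad[[1]][1:10, ]
  expect_error(fit_templates(bad, syn$directions), "frame count"
  )
})

test_that("identical training sequences hit the dispersion floor", {
  f <- matrix(rep(seq(0.1, 1, length.out = 20), 89), 89, 20, byrow = TRUE)
  bank <- fit_templates(list(f, f, f, f), c("right", "right", "left", "left"),
                        var_floor = 1e-4)
  for (tp in bank$templates) {
    expect_equal(tp$mu, f[1, ], ignore_attr = TRUE)
    expect_true(all(tp$sigma2 == 1e-4))
  }
})

test_that("feature dimension follows the detector configuration", {
  g <- motion_grid()
  seqs <- list(generate_kick("right", 7), generate_kick("right", 12),
               generate_kick("left", 7), generate_kick("left", 12))
  dirs <- c("right", "right", "left", "left")
  f_on <- lapply(seqs, sequence_features, layout = opponent_layout(g))
  f_off <- lapply(seqs, sequence_features,
                  layout = opponent_layout(g, rotation = FALSE))
  expect_equal(fit_templates(f_on, dirs)$D, 100L)
  expect_equal(fit_templates(f_off, dirs)$D, 80L)
  expect_error(template_evidence(numeric(7), fit_templates(f_on, dirs)),
               "dimension")
})

test_that("an at-mean feature maximises evidence within its window", {
  syn <- synthetic_features(sep = 4, noise = 0.05)
  bank <- fit_templates(syn$features, syn$directions)
  for (i in c(2, 7, 11, 16)) {
    tp <- bank$templates[[i]]
    g <- template_evidence(tp$mu, bank)
    rival <- which(vapply(bank$templates, `[[`, 1, "window") == tp$window)
    expect_equal(which.max(g[rival]), which(rival == i))
  }
})

test_that("lambda = 0 reduces to pure Gaussian log-likelihood ranking", {
  syn <- synthetic_features(n_per_class = 3)
  bank <- fit_templates(syn$features, syn$directions, lambda = 0)
  x <- syn$features[[1]][15, ]
  raw <- kinemotion:::raw_evidence(x, bank)[1, ]
  oracle <- vapply(bank$templates, function(tp)
    sum(stats::dnorm(x, tp$mu, sqrt(tp$sigma2), log = TRUE)) / bank$D, 1)
  expect_equal(order(raw), order(oracle))
  expect_equal(raw, oracle, tolerance = 1e-12)
})

test_that("risk aversion penalises dispersion for an at-mean feature", {
  mk_bank <- function(inflate) {
    syn <- synthetic_features(n_per_class = 3, seed = 11)
    bank <- fit_templates(syn$features, syn$directions, lambda = 0.5)
    bank$templates[[4]]$sigma2 <- bank$templates[[4]]$sigma2 * inflate
    bank
  }
  b1 <- mk_bank(1); b2 <- mk_bank(2)
  mu <- b1$templates[[4]]$mu
  g1 <- kinemotion:::raw_evidence(mu, b1)[1, 4]
  g2 <- kinemotion:::raw_evidence(mu, b2)[1, 4]
  expect_lt(g2, g1)
})

test_that("mirror-symmetric training yields mirrored template banks", {
  g <- motion_grid()
  lay <- opponent_layout(g)
  p <- mirror_permutation(lay)
  angles <- c(7, 10, 14, 18)
  feats <- c(lapply(angles, function(a) sequence_features(generate_kick("right", a), lay)),
             lapply(angles, function(a) sequence_features(generate_kick("left", a), lay)))
  dirs <- rep(c("right", "left"), each = length(angles))
  bank <- fit_templates(feats, dirs)
  for (w in c(1, 5, 9)) {
    tr <- bank$templates[[w]]        # right, window w
    tl <- bank$templates[[9 + w]]    # left, window w
    expect_equal(tl$mu, tr$mu[p], tolerance = 1e-12)
    expect_equal(tl$sigma2, tr$sigma2[p], tolerance = 1e-12)
  }
  # evidence for a stimulus equals the direction-swapped evidence of its mirror
  fx <- sequence_features(generate_kick("right", 9), lay)
  fm <- sequence_features(generate_kick("left", 9), lay)
  ev <- evidence_stream(fx, bank)
  evm <- evidence_stream(fm, bank)
  expect_equal(evm[, c(10:18, 1:9)], ev, tolerance = 1e-10)
})

test_that("cross-validation separates separable classes and rejects bad folds", {
  syn <- synthetic_features(n_per_class = 10, sep = 5, noise = 0.05)
  cv <- crossvalidate_templates(syn$features, syn$directions, k = 5, seed = 2)
  expect_length(cv$fold_accuracy, 5L)
  expect_equal(cv$mean, 1)
  expect_equal(as.vector(table(cv$fold)), rep(4L, 5))
  # label-randomised data classifies at chance
  set.seed(30)
  shuf <- sample(syn$directions)
  cv0 <- crossvalidate_templates(syn$features, shuf, k = 5, seed = 2)
  expect_gt(cv0$mean, 0.5 - 1.96 * sqrt(0.25 / 20))
  expect_lt(cv0$mean, 0.5 + 1.96 * sqrt(0.25 / 20))
  expect_error(crossvalidate_templates(syn$features[c(1, 3, 5, 2)],
                                       c("right", "right", "right", "left"),
                                       k = 2, seed = 1),
               "single class|per direction")
})
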