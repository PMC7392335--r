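# Optimization machinery.

test_that("poisson_loss closed forms and minimum at pred == target", {
  expect_equal(poisson_loss(matrix(1), matrix(0)), 1)      # 1 - 0*ln 1
  y <- matrix(c(2, 3, 0.5, 4), 2)
  expect_equal(poisson_loss(y, y), mean(y - y * log(y)))
  expect_error(poisson_loss(matrix(-1), matrix(0)), "positive")
  expect_error(poisson_loss(matrix(1), matrix(0, 2, 2)), "shape")
  # finite-difference minimality at pred = target
  base <- poisson_loss(y, y)
  for (eps in c(1e-3, -1e-3)) {
    pert <- y
    pert[1, 1] <- pert[1, 1] + eps
    expect_gt(poisson_loss(pert, y), base)
  }
})

test_that("crop_center slices symmetrically and validates parity", {
  m <- matrix(seq_len(1024 * 2), 1024)
  c1 <- crop_center(m, 896)
  expect_equal(nrow(c1), 896)
  expect_equal(c1, m[65:960, ])                # 64 dropped per side
  expect_identical(crop_center(m, 1024), m)
  expect_error(crop_center(m, 895), "even")
  # slicing oracle on a random small case
  r <- matrix(rnorm(40), 10)
  expect_equal(crop_center(r, 6), r[3:8, ])
  # the 7/8 rule reproduces 1024 -> 896
  expect_equal(crossreg:::default_crop_keep(1024), 896L)
})

test_that("augmentation: rc involution, identity, shift semantics", {
  cfg <- tiny_config()
  ex <- random_examples(1, cfg)[[1]]
  expect_equal(augment_example(ex, rc = FALSE, shift = 0L), ex)
  rc2 <- augment_example(augment_example(ex, rc = TRUE), rc = TRUE)
  expect_equal(rc2, ex)
  # rc target order equals an explicit reversal oracle
  rc1 <- augment_example(ex, rc = TRUE)
  expect_equal(rc1$y, ex$y[nrow(ex$y):1, , drop = FALSE])
  expect_equal(rc1$x, revcomp_onehot(ex$x))
  # shift re-extracts the window; targets unchanged
  genome <- list(chr1 = random_seq(2048, 77))
  ex$x <- encode_sequence(substr(genome$chr1, 101, 100 + 1024))
  ex$chrom <- "chr1"; ex$start <- 100L; ex$end <- 1124L
  sh <- augment_example(ex, shift = 3L, genome = genome)
  expect_equal(sh$x, encode_sequence(substr(genome$chr1, 104, 103 + 1024)))
  expect_equal(sh$y, ex$y)
  expect_error(augment_example(ex, shift = 5000L, genome = genome),
               "off the contig")
  expect_error(augment_example(ex, shift = 1L), "genome")
})

test_that("genome-proportional batching matches binomial expectation", {
  # printed counts: 38.2k human vs 33.5k mouse -> P(A) = 0.533
  counts <- c(A = 38200, B = 33500)
  sched <- sample_genome_batches(counts, 1e5, seed = 1)
  p <- unname(counts[1] / sum(counts))
  expect_equal(p, 0.53277, tolerance = 1e-4)
  # empirical frequency within 3 sigma of the binomial expectation
  phat <- mean(sched == "A")
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 1e5))
  # degenerate cases
  expect_true(all(sample_genome_batches(c(A = 10, B = 0), 50) == "A"))
  expect_error(sample_genome_batches(c(A = 0, B = 0), 5), "positive")
  expect_identical(sample_genome_batches(counts, 100, seed = 9),
                   sample_genome_batches(counts, 100, seed = 9))
})

test_that("training drives predictions toward a constant target", {
  # closed-form Poisson optimum for a constant target y* is pred = y*;
  # a short run on one constant-target dataset must move predictions
  # toward it
  cfg <- tiny_config(heads = c(A = 1), seq_len = 512, dropout = 0)
  set.seed(11)
  target <- 3
  exs <- lapply(1:4, function(i) {
    structure(list(x = encode_sequence(random_seq(512, 20 + i)),
                   y = matrix(target, cfg$n_bins, 1), genome_id = "A",
                   chrom = "chr1", start = 0L, end = 512L,
                   split = "train"), class = "training_example")
  })
  m <- build_model(cfg, seed = 5)
  p0 <- mean(forward(m, exs[[1]]$x, "A"))
  tc <- train_config(batch_size = 4, lr = 0.05, momentum = 0.9,
                     max_epochs = 15, shift_max = 0, rc_augment = FALSE,
                     seed = 3)
  res <- train_model(m, list(A = exs), list(A = exs), tc, patience = 15)
  p1 <- mean(forward(res$model, exs[[1]]$x, "A"))
  expect_lt(abs(p1 - target), abs(p0 - target))
  expect_lt(abs(p1 - target), 1)
  # identical seeds give identical training histories
  res2 <- train_model(build_model(cfg, seed = 5), list(A = exs),
                      list(A = exs), tc, patience = 15)
  expect_equal(res$history, res2$history)
})

test_that("early stopping honors patience and returns best weights", {
  cfg <- tiny_config(heads = c(A = 2), seq_len = 512, dropout = 0)
  exs <- random_examples(4, cfg, seed = 31)
  m <- build_model(cfg, seed = 8)
  # patience 0: stop after the first non-improving epoch
  tc <- train_config(batch_size = 2, lr = 1e-4, momentum = 0,
                     max_epochs = 50, shift_max = 0, rc_augment = FALSE,
                     seed = 2)
  res <- train_model(m, list(A = exs), list(A = exs), tc, patience = 0)
  h <- res$history
  wv <- h$weighted_valid[h$genome == "A"]
  stopped_at <- max(h$epoch)
  expect_lt(stopped_at, 50)                      # stopped early
  expect_equal(res$best_epoch, which.min(wv))
  expect_equal(res$best_valid, min(wv))
  # no more than patience+1 epochs after the best
  expect_lte(stopped_at - res$best_epoch, 1)
})

test_that("fine_tune updates only the target genome's head", {
  cfg <- tiny_config(seq_len = 512, dropout = 0)
  m <- build_model(cfg, seed = 4)
  exA <- random_examples(4, cfg, "A", seed = 1)
  tc <- train_config(batch_size = 2, lr = 0.01, momentum = 0.5,
                     max_epochs = 4, shift_max = 0, rc_augment = FALSE,
                     seed = 6)
  res <- fine_tune(m, "A", exA, exA, tc)
  expect_identical(res$model$heads[["B"]], m$heads[["B"]])
  # best-weights contract: validation loss no worse than at entry
  entry <- crossreg:::valid_loss(m, exA, "A",
                                 crossreg:::default_crop_keep(cfg$n_bins))
  expect_lte(res$best_valid, entry)
  expect_error(fine_tune(m, "Z", exA, exA, tc), "unknown genome")
})

test_that("evaluate_model equals a two-pass Pearson oracle", {
  cfg <- tiny_config(heads = c(A = 3), seq_len = 512)
  exs <- random_examples(3, cfg, seed = 41)
  m <- tiny_model(seed = 1, heads = c(A = 3), seq_len = 512)
  ev <- evaluate_model(m, exs, "A", crop_keep = cfg$n_bins)
  # oracle: textbook two-pass correlation over pooled bins
  P <- do.call(rbind, lapply(exs, function(e) forward(m, e$x, "A")))
  Y <- do.call(rbind, lapply(exs, function(e) e$y))
  for (j in 1:3) {
    num <- sum((P[, j] - mean(P[, j])) * (Y[, j] - mean(Y[, j])))
    den <- sqrt(sum((P[, j] - mean(P[, j]))^2) *
                  sum((Y[, j] - mean(Y[, j]))^2))
    expect_equal(ev$r[j], num / den, tolerance = 1e-12)
  }
  # degenerate targets
  exs1 <- exs
  for (i in seq_along(exs1)) exs1[[i]]$y[, 2] <- 5
  ev1 <- evaluate_model(m, exs1, "A", crop_keep = cfg$n_bins)
  expect_true(is.na(ev1$r[2]))
  # perfect predictions give r = 1
  exs2 <- lapply(exs, function(e) { e$y <- forward(m, e$x, "A"); e })
  ev2 <- evaluate_model(m, exs2, "A", crop_keep = cfg$n_bins)
  expect_equal(ev2$r, rep(1, 3), tolerance = 1e-12)
})
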