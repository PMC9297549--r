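test_that("cosine annealing follows the closed form with restarts", {
  a <- function(t) cosine_annealing_lr(t, a0 = 0.1, total_epochs = 100,
                                       n_cycles = 10)
  expect_equal(a(1), 0.1)
  expect_equal(a(6), 0.05)
  expect_equal(a(10), (0.1 / 2) * (cos(0.9 * pi) + 1))
  expect_equal(a(10), 0.0024472, tolerance = 1e-4)
  expect_equal(a(11), a(1))
  # periodicity over the whole run
  t <- 1:90
  expect_equal(a(t), a(t + 10))
  # non-increasing within each cycle, maximal at cycle starts
  within <- a(1:10)
  expect_true(all(diff(within) < 0))
  expect_equal(max(a(1:100)), a(1))
  expect_error(a(0), "out of range")
  expect_error(a(101), "out of range")
  expect_error(cosine_annealing_lr(1, total_epochs = 100, n_cycles = 7),
               "multiple")
  expect_error(schedule_params(0.1, 100, 7), "multiple")
})

test_that("splitting yields round(fraction*N) with stratification", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("SMAD3", "SMAD2"), c(80, 20))
  sp <- split_dataset(ids, labels, seed = 4)
  expect_length(sp$train_ids, 75)
  expect_length(sp$test_ids, 25)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  tr_lab <- labels[sp$train_idx]
  expect_equal(sum(tr_lab == "SMAD3"), 60)
  expect_equal(sum(tr_lab == "SMAD2"), 15)
  # determinism
  sp2 <- split_dataset(ids, labels, seed = 4)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_error(split_dataset(ids, rep(c("SMAD3", "SMAD2"), c(99, 1)),
                             seed = 1), "at least 2")
})

test_that("snapshots are taken at every cycle end", {
  fix <- tiny_ensemble()
  ens <- fix$ens
  expect_length(ens$snapshots, 2)
  expect_length(ens$manifest$loss, 4)
  expect_true(all(is.finite(ens$manifest$loss)))
  # recorded learning rates equal the closed-form schedule
  expect_equal(ens$manifest$lr,
               cosine_annealing_lr(1:4, a0 = 0.05, total_epochs = 4,
                                   n_cycles = 2))
  expect_error(
    train_snapshot_ensemble(ens$spec, fix$enc,
                            labels = rep("SMAD3", length(fix$enc$ids)),
                            schedule = schedule_params(0.05, 4, 2)),
    "single class")
})

test_that("ensemble predictions are snapshot means, order-invariant", {
  fix <- tiny_ensemble()
  P <- predict_snapshots(fix$ens, fix$enc)
  expect_equal(ncol(P), 2)
  full <- predict_ensemble(fix$ens, fix$enc)
  expect_equal(full, rowMeans(P), tolerance = 1e-12)
  expect_equal(predict_ensemble(fix$ens, fix$enc, subset = 2), P[, 2])
  expect_equal(predict_ensemble(fix$ens, fix$enc, subset = c(2, 1)), full)
  expect_error(predict_ensemble(fix$ens, fix$enc, subset = integer(0)),
               "empty")
  expect_error(predict_ensemble(fix$ens, fix$enc, subset = 9), "range")
})

test_that("a single-cycle run learns separable toy data to accuracy 1", {
  set.seed(21)
  width <- 20
  n <- 40
  # trivially separable: SMAD3 sequences are G-rich, SMAD2 A-rich
  seqs <- c(vapply(1:(n / 2), function(i) random_seq(width, gc = 0.95), ""),
            vapply(1:(n / 2), function(i) random_seq(width, gc = 0.05), ""))
  labels <- rep(c("SMAD3", "SMAD2"), each = n / 2)
  enc <- one_hot_encode(seqs, labels, width = width)
  spec <- model_spec("cnn_lstm", input_width = width, conv1_filters = 4,
                     lstm_units = 4)
  ens <- train_snapshot_ensemble(spec, enc,
                                 schedule = schedule_params(0.05, 15, 1),
                                 seed = 6)
  expect_length(ens$snapshots, 1)
  p <- predict_ensemble(ens, enc)
  acc <- mean((p >= 0.5) == (encode_labels(labels) == 1))
  expect_equal(acc, 1.0)
})

test_that("training is reproducible given a seed", {
  set.seed(31)
  enc <- one_hot_encode(random_seq_n(24, 20, c("A", "C", "G", "T")),
                        rep(c("SMAD2", "SMAD3"), 12), width = 20)
  spec <- model_spec("cnn_lstm", input_width = 20, conv1_filters = 3,
                     lstm_units = 4)
  e1 <- train_snapshot_ensemble(spec, enc,
                                schedule = schedule_params(0.05, 2, 1),
                                seed = 9)
  e2 <- train_snapshot_ensemble(spec, enc,
                                schedule = schedule_params(0.05, 2, 1),
                                seed = 9)
  expect_identical(e1$snapshots, e2$snapshots)
  expect_identical(e1$manifest$loss, e2$manifest$loss)
})
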