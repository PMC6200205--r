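# helper: metadata of a session without rendering any pixels
fake_meta <- function(n_flies, days, frames) {
  expand.grid(frame = seq_len(frames), day = days,
              identity = seq_len(n_flies))[, c("identity", "day", "frame")]
}

test_that("day splits take the leading train fraction and trailing validation fraction", {
  meta <- fake_meta(2L, 1:3, 1000L)
  idx <- split_indices(meta, split_spec())
  expect_equal(length(idx$train), 2 * 2 * 850)   # 0.85 x 1000 per fly per day
  expect_equal(length(idx$val), 2 * 2 * 150)
  expect_equal(length(idx$test), 2 * 1000)
  # contiguity: per fly-day all training frames precede all validation frames
  for (id in 1:2) for (d in 1:2) {
    tr <- meta$frame[intersect(idx$train,
                               which(meta$identity == id & meta$day == d))]
    va <- meta$frame[intersect(idx$val,
                               which(meta$identity == id & meta$day == d))]
    expect_equal(sort(tr), 1:850)
    expect_equal(sort(va), 851:1000)
  }
  # no frame lands in two splits
  expect_length(intersect(idx$train, idx$val), 0)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_length(intersect(idx$val, idx$test), 0)
})

test_that("split edge cases: empty validation, missing day, fraction bound", {
  meta <- fake_meta(1L, 1:3, 100L)
  idx <- split_indices(meta, split_spec(val_frac = 0))
  expect_length(idx$val, 0)
  expect_error(split_indices(fake_meta(1L, 1:2, 10L), split_spec()),
               "missing day")
  expect_error(split_spec(train_frac = 0.9, val_frac = 0.2), "exceed 1")
  expect_error(split_spec(train_days = c(1, 3), test_day = 3),
               "must not be a training day")
})

test_that("perfect predictions score macro F1 1 with an identity confusion matrix", {
  truth <- rep(1:20, each = 5)
  rep <- eval_report(truth, truth)
  expect_equal(rep$macro_f1, 1)
  expect_equal(unname(rep$confusion), diag(20))
  expect_equal(rep$per_class$precision, rep(1, 20))
})

test_that("degenerate and random predictors match analytic expectations", {
  truth <- rep(1:20, each = 50)
  # always predict class 1: oracle from first principles
  pred1 <- rep(1L, length(truth))
  orc <- oracle_metrics(truth, pred1, 1:20)
  expect_equal(macro_f1(truth, pred1, levels = 1:20), orc$macro_f1)
  # uniform random guessing sits at the 0.05 chance line
  withr::with_seed(1, {
    truth_big <- rep(1:20, each = 2000)
    pred_big <- sample(1:20, length(truth_big), replace = TRUE)
  })
  expect_lt(abs(macro_f1(truth_big, pred_big, levels = 1:20) - 0.05), 0.01)
  expect_error(eval_report(integer(0), integer(0)), "empty")
})

test_that("sex collapsing scores discrimination of male vs female", {
  sex_map <- c(`1` = "M", `2` = "M", `3` = "F", `4` = "F")
  truth <- rep(1:4, each = 10)
  expect_equal(collapse_by_sex(truth, truth, sex_map), 1)
  # all mass on the within-sex wrong class: ids all wrong, sexes all right
  swap <- c(2L, 1L, 4L, 3L)
  pred <- swap[truth]
  expect_equal(collapse_by_sex(truth, pred, sex_map), 1)
  expect_equal(macro_f1(truth, pred, levels = 1:4), 0)
  expect_error(collapse_by_sex(truth, pred, sex_map[-1]), "no sex mapping")
})

test_that("confusion rows are ordered by sex then ascending size and sum to one", {
  truth <- rep(1:4, each = 5)
  withr::with_seed(2, pred <- sample(1:4, 20, TRUE))
  sex <- c(`1` = "F", `2` = "M", `3` = "F", `4` = "M")
  size <- c(`1` = 120, `2` = 100, `3` = 110, `4` = 90)
  rep <- eval_report(truth, pred, sex = sex, size = size)
  expect_equal(rownames(rep$confusion), c("4", "2", "3", "1"))  # M by size, F by size
  expect_equal(unname(rowSums(rep$confusion)), rep(1, 4))
  expect_true(!is.null(rep$sex_f1))
})

# a small two-fly training problem rendered at 61 px and bottlenecked to 29x29
toy_parts <- function() {
  memo("toy_parts", {
    spec <- session_spec(n_flies = 2L, n_days = 3L, frames_per_day = 50L,
                         chip_size = 61L)
    ds <- make_dataset(spec, seed = 21L, transform = bottleneck_29)
    split_dataset(ds, split_spec())
  })
}

test_that("training reduces the loss on a separable two-fly problem and is seed-deterministic", {
  parts <- toy_parts()
  net <- build_network(load_connectome(default_connectome_path()),
                       c(29L, 29L), n_classes = 2L, seed = 1L)
  fit <- train_reid(net, parts$train, parts$val, epochs = 3L,
                    batch_size = 32L, seed = 1L)
  h <- fit$history
  expect_gt(nrow(h), 1)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  rep <- evaluate_model(fit, parts$test)
  expect_gt(rep$macro_f1, 0.5)
  # determinism: same seeds reproduce the trained weights exactly
  fit2 <- train_reid(net, parts$train, parts$val, epochs = 3L,
                     batch_size = 32L, seed = 1L)
  expect_identical(fit$model$params$head$W, fit2$model$params$head$W)
  expect_identical(fit$history, fit2$history)
})

test_that("leakage and label-coverage guards refuse bad training setups", {
  parts <- toy_parts()
  net <- build_network(load_connectome(default_connectome_path()),
                       c(29L, 29L), n_classes = 2L, seed = 1L)
  # validation drawn from the held-out test day is refused
  expect_error(train_reid(net, parts$train, parts$test),
               "leakage")
  # a class missing from training is refused
  tr1 <- subset_stack(parts$train, parts$train$meta$identity == 1L)
  expect_error(train_reid(net, tr1, parts$val), "absent from the training set")
  expect_error(evaluate_model(structure(list(), class = "flyeye_fit"),
                              subset_stack(parts$test, integer(0))),
               "empty test set")
})

test_that("run_experiment aggregates replicates and reports no sd for a single one", {
  cfg <- list(
    generator = list(n_flies = 2L, n_days = 3L, frames_per_day = 20L,
                     chip_size = 61L),
    train = list(epochs = 2L, batch_size = 16L, seed = 1L),
    seeds = 31L)
  out <- run_experiment(cfg)
  expect_length(out$reports, 1L)
  expect_true(is.na(out$summary$macro_f1_sd))
  expect_true(out$summary$macro_f1_mean >= 0 &&
                out$summary$macro_f1_mean <= 1)
  expect_s3_class(out$reports[[1]], "eval_report")
  # the fly-eye model refuses non-bottleneck paths
  expect_error(run_experiment(c(cfg, list(mode = "highres"))),
               "bottleneck")
})

test_that("multi-replicate experiments aggregate mean and sd across dataset seeds", {
  cfg <- list(
    generator = list(n_flies = 4L, n_days = 3L, frames_per_day = 15L,
                     chip_size = 61L),
    model = "ridge", zoom = TRUE,
    seeds = c(41L, 42L))
  out <- run_experiment(cfg)
  expect_length(out$reports, 2L)
  f1s <- vapply(out$reports, function(r) r$macro_f1, 0)
  expect_equal(out$summary$macro_f1_mean, mean(f1s))
  expect_equal(out$summary$macro_f1_sd, sd(f1s))
  expect_true(out$summary$zoom)
})
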