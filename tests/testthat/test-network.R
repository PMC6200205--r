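tab_default <- load_connectome(default_connectome_path())

test_that("the default network at 29x29 holds about 25,000 units (30 maps x 841 columns)", {
  net <- build_network(tab_default, c(29L, 29L), n_classes = 20L, seed = 3L)
  expect_identical(net$unit_count, 30L * 29L * 29L)
  expect_equal(round(net$unit_count / 1000) * 1000, 25000)
})

test_that("unit count and edge round-trip hold over random tables", {
  for (seed in 1:12) {
    tab <- random_table(seed)
    H <- sample(5:9, 1)
    net <- build_network(tab, c(H, H), n_classes = 2L, seed = seed)
    expect_identical(net$unit_count, nrow(tab$cell_types) * H * H)
    rep <- connection_report(net)
    expect_equal(rep[, c("pre", "post", "rf_columns")],
                 tab$connections[, c("pre", "post", "rf_columns")])
    expect_equal(rep$n_weights, H * H * tab$connections$rf_columns^2)
  }
})

test_that("the minimal two-type model has 50 units and 25 weights on its edge at 5x5", {
  net <- build_network(minimal_table(), c(5L, 5L), n_classes = 2L, seed = 1L)
  expect_identical(net$unit_count, 50L)
  rep <- connection_report(net)
  expect_equal(rep$n_weights, 25L)
  expect_equal(rep$n_bias_post, 25L)
})

test_that("a 3x3 locally connected edge on a 29x29 grid holds 7,569 weights", {
  tab <- connectome_table(
    data.frame(name = c("P", "LCx"), stage = c("photoreceptor", "lobula"),
               rank = c(0L, 1L)),
    data.frame(pre = "P", post = "LCx", rf_columns = 3L))
  net <- build_network(tab, c(29L, 29L), n_classes = 2L, seed = 1L)
  expect_equal(connection_report(net)$n_weights, 841L * 9L)
  expect_equal(length(net$params$edges[["P->LCx"]]), 7569L)
})

test_that("identical seeds give bit-identical initial parameters, different seeds do not", {
  a <- build_network(tab_default, c(29L, 29L), 20L, seed = 42L)
  b <- build_network(tab_default, c(29L, 29L), 20L, seed = 42L)
  expect_identical(a$params, b$params)
  c <- build_network(tab_default, c(29L, 29L), 20L, seed = 43L)
  expect_false(identical(a$params$head$W, c$params$head$W))
})

test_that("softmax outputs are finite and normalized for untrained models", {
  net <- build_network(tab_default, c(29L, 29L), 20L, seed = 5L)
  withr::with_seed(1, x <- matrix(runif(3 * 841), 3, 841))
  probs <- forward_network(net, x)$probs
  expect_true(all(is.finite(probs)))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-12)
  expect_equal(predict_network(net, x, batch_size = 2L), probs)
})

test_that("the photoreceptor front-end respects the hexagonal mask", {
  net <- build_network(tab_default, c(29L, 29L), 20L, seed = 5L)
  ph <- net$params$photo[["R1-6"]]
  expect_identical(ph$mask, hex_mask())
  expect_equal(sum(hex_mask()), 6L)
  expect_true(all(ph$w[!ph$mask] == 0))
  expect_true(all(ph$w[ph$mask] != 0))
  # R7/R8 are 1x1
  expect_equal(length(net$params$photo[["R7"]]$w), 1L)
})

test_that("a single-pixel perturbation stays within the composed receptive field", {
  # P (1x1 front-end) -> A (rf 3): composed radius around the pixel is 1
  tab <- connectome_table(
    data.frame(name = c("P", "A"), stage = c("photoreceptor", "lobula"),
               rank = c(0L, 1L)),
    data.frame(pre = "P", post = "A", rf_columns = 3L))
  net <- build_network(tab, c(9L, 9L), n_classes = 2L, seed = 2L)
  withr::with_seed(7, x <- matrix(runif(81), 1, 81))
  base <- forward_network(net, x, return_acts = TRUE)$acts[["A"]]
  px_row <- 5L; px_col <- 5L
  changed <- rep(FALSE, 81)
  for (delta in c(10, -10)) {
    x2 <- x
    x2[1, (px_col - 1) * 9 + px_row] <- x2[1, (px_col - 1) * 9 + px_row] + delta
    pert <- forward_network(net, x2, return_acts = TRUE)$acts[["A"]]
    changed <- changed | (abs(pert - base)[1, ] > 1e-12)
  }
  grid <- expand.grid(r = 1:9, c = 1:9)
  inside <- abs(grid$r - px_row) <= 1 & abs(grid$c - px_col) <= 1
  expect_true(all(!changed[!inside]))
  expect_true(any(changed[inside]))
})

test_that("analytic gradients match finite differences", {
  tab <- connectome_table(
    data.frame(name = c("P", "A", "B"),
               stage = c("photoreceptor", "medulla", "lobula"),
               rank = c(0L, 1L, 2L)),
    data.frame(pre = c("P", "P", "A"), post = c("A", "B", "B"),
               rf_columns = c(3L, 1L, 3L)))
  net <- build_network(tab, c(5L, 5L), n_classes = 3L, seed = 2L)
  withr::with_seed(3, {
    x <- matrix(rnorm(4 * 25), 4, 25)
    y <- c(1L, 2L, 3L, 1L)
  })
  g <- flyeye:::network_grads(net, x, y)
  eps <- 1e-6
  probes <- list(list("edges", "P->A", 7L), list("edges", "A->B", 30L),
                 list("bias", "A", 11L), list("head", "W", 14L))
  for (pr in probes) {
    net2 <- net
    net2$params[[pr[[1]]]][[pr[[2]]]][pr[[3]]] <-
      net2$params[[pr[[1]]]][[pr[[2]]]][pr[[3]]] + eps
    num <- (flyeye:::network_grads(net2, x, y)$loss - g$loss) / eps
    expect_equal(g$grads[[pr[[1]]]][[pr[[2]]]][pr[[3]]], num,
                 tolerance = 1e-4)
  }
  net2 <- net
  net2$params$photo$P$w <- net2$params$photo$P$w + eps
  num <- (flyeye:::network_grads(net2, x, y)$loss - g$loss) / eps
  expect_equal(g$grads$photo$P$w, num, tolerance = 1e-4)
})

test_that("input-size and class-count preconditions are enforced", {
  expect_error(build_network(tab_default, c(4L, 4L), 20L, seed = 1L),
               "smaller than the largest filter")
  expect_error(build_network(tab_default, c(29L, 29L), 1L, seed = 1L),
               "at least 2")
})

test_that("save/load round-trips architecture and weights exactly", {
  tab <- random_table(5)
  net <- build_network(tab, c(7L, 7L), n_classes = 4L, seed = 9L)
  dir <- withr::local_tempdir()
  save_network(net, dir)
  expect_true(file.exists(file.path(dir, "architecture.yaml")))
  expect_true(file.exists(file.path(dir, "weights.h5")))
  back <- load_network(dir)
  expect_equal(back$params, net$params)
  expect_identical(back$unit_count, net$unit_count)
  withr::with_seed(2, x <- matrix(runif(2 * 49), 2, 49))
  expect_identical(forward_network(back, x)$probs,
                   forward_network(net, x)$probs)
})
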