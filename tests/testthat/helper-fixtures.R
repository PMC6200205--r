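# Shared fixtures. Everything is generated in code; heavyweight datasets are
# memoized so several test files can reuse one generation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# minimal valid table: one photoreceptor, one lobula output
minimal_table <- function(rf = 1L) {
  connectome_table(
    data.frame(name = c("P", "LCx"),
               stage = c("photoreceptor", "lobula"),
               rank = c(0L, 1L)),
    data.frame(pre = "P", post = "LCx", rf_columns = rf))
}

# random valid connectome: a guaranteed photoreceptor->lamina->medulla->lobula
# spine plus random extra rank-increasing edges
random_table <- function(seed) {
  withr::with_seed(seed, {
    n_ph <- sample(1:2, 1); n_la <- sample(1:3, 1)
    n_me <- sample(1:3, 1); n_lo <- sample(1:3, 1)
    types <- data.frame(
      name = c(paste0("Ph", seq_len(n_ph)), paste0("La", seq_len(n_la)),
               paste0("Me", seq_len(n_me)), paste0("Lo", seq_len(n_lo))),
      stage = rep(c("photoreceptor", "lamina", "medulla", "lobula"),
                  c(n_ph, n_la, n_me, n_lo)),
      rank = c(rep(0L, n_ph), rep(1L, n_la), rep(2L, n_me),
               3L + seq_len(n_lo)),
      stringsAsFactors = FALSE)
    rfs <- c(1L, 3L, 5L)
    edges <- data.frame(pre = character(0), post = character(0),
                        rf_columns = integer(0))
    add <- function(e, pre, post)
      rbind(e, data.frame(pre = pre, post = post, rf_columns = sample(rfs, 1)))
    # spine: photoreceptors feed every lamina type; lamina -> Me1; medulla ->
    # every lobula, so all types have afferents and all sources reach outputs
    for (p in paste0("Ph", seq_len(n_ph))) edges <- add(edges, p, "La1")
    for (l in paste0("La", seq_len(n_la))) {
      if (l != "La1") edges <- add(edges, "Ph1", l)
      edges <- add(edges, l, "Me1")
    }
    for (m in paste0("Me", seq_len(n_me)))
      if (m != "Me1") edges <- add(edges, "La1", m)
    for (lo in paste0("Lo", seq_len(n_lo))) edges <- add(edges, "Me1", lo)
    # random extras (rank-increasing, no duplicates)
    for (i in seq_len(sample(0:4, 1))) {
      a <- sample(types$name, 1); b <- sample(types$name, 1)
      ra <- types$rank[types$name == a]; rb <- types$rank[types$name == b]
      if (ra < rb && !any(edges$pre == a & edges$post == b))
        edges <- add(edges, a, b)
    }
    connectome_table(types, edges)
  })
}

# brute-force metric oracle: per-class precision/recall/F1 from raw counts,
# written with explicit loops, independent of eval_report()
oracle_metrics <- function(truth, pred, levels) {
  f1 <- prec <- rec <- numeric(length(levels))
  for (i in seq_along(levels)) {
    cl <- levels[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0)
      2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  list(precision = prec, recall = rec, f1 = f1, macro_f1 = mean(f1))
}

# ---- shared heavyweight fixtures -------------------------------------------

# study-condition dataset, scaled down: 10 flies, 3 days, 200 frames/day.
# One generation yields both preprocessing variants: the plain 29x29
# bottleneck and the bottleneck of the randomly zoomed frame (the ablation
# applies the zoom to training and test frames alike). The two 29x29 chips
# are stacked vertically during generation and split afterwards.
headline_stacks <- function() {
  memo("headline", {
    spec <- session_spec(n_flies = 10L, n_days = 3L, frames_per_day = 200L)
    both <- function(ch)
      rbind(bottleneck_29(ch), bottleneck_29(random_zoom(ch)))
    ds <- make_dataset(spec, seed = 101L, transform = both)
    split2 <- function(rows) {
      out <- ds
      out$images <- ds$images[rows, , , drop = FALSE]
      out
    }
    list(plain = split2(1:29), zoom = split2(30:58))
  })
}

# small-chip datasets for generator property tests (geometry scales with size)
drift_dataset <- function(drift, seed, frames = 40L) {
  make_dataset(session_spec(n_flies = 10L, n_days = 3L,
                            frames_per_day = frames, chip_size = 61L,
                            day_drift_sd = drift),
               seed = seed)
}

centroid_f1 <- function(stack, spec = split_spec()) {
  parts <- split_dataset(stack, spec)
  pred <- nearest_centroid_predict(parts$train, parts$test)
  macro_f1(parts$test$meta$identity, pred)
}
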