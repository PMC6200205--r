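# Mini-batch Adam training of a fly-eye network. Kept separate from the
# reid-level wrapper so the optimizer can be tested on raw matrices.

# one Adam step over the nested parameter list; m/v grow lazily to mirror the
# gradient structure. Leaves with no gradient this step are left untouched.
adam_step <- function(p, g, m, v, lr, b1, b2, eps, t) {
  if (is.numeric(g)) {
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    return(list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v))
  }
  if (is.list(g)) {
    if (is.null(m)) { m <- list(); v <- list() }
    for (nm in names(g)) {
      r <- adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, b1, b2, eps, t)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
  }
  list(p = p, m = m, v = v)
}

#' Fit a fly-eye network with Adam and early stopping
#'
#' Low-level trainer on flattened image matrices; [train_reid()] is the
#' user-facing wrapper that adds standardization and leakage guards.
#'
#' @param model a [build_network()] model.
#' @param x,y training images (n x H*W matrix, standardized) and 1-based
#'   integer class labels.
#' @param x_val,y_val validation data; early stopping monitors validation
#'   macro F1.
#' @param epochs,batch_size,lr,patience,seed see [train_reid()].
#' @param verbose print one line per epoch.
#' @return list with the best \code{model}, \code{history} data.frame
#'   (epoch, train_loss, val_f1) and \code{best_epoch}.
#' @export
fit_network <- function(model, x, y, x_val, y_val, epochs = 30L,
                        batch_size = 64L, lr = 1e-3, patience = 5L,
                        seed = 1L, verbose = FALSE) {
  stopifnot(max(y) <= model$n_classes, min(y) >= 1L)
  n <- nrow(x)
  params <- model$params
  m <- NULL; v <- NULL; t_step <- 0L
  best_f1 <- -Inf; best_params <- params; best_epoch <- 0L; stale <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_f1 = numeric(0))

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        model$params <- params
        gr <- network_grads(model, x[idx, , drop = FALSE], y[idx])
        losses <- c(losses, gr$loss)
        t_step <- t_step + 1L
        upd <- adam_step(params, gr$grads, m, v, lr, 0.9, 0.999, 1e-8, t_step)
        params <- upd$p; m <- upd$m; v <- upd$v
      }
      model$params <- params
      val_pred <- max.col(predict_network(model, x_val), ties.method = "first")
      f1 <- macro_f1(y_val, val_pred, levels = seq_len(model$n_classes))
      history[ep, ] <- list(ep, mean(losses), f1)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val macro F1 %.4f",
                        ep, mean(losses), f1))
      if (f1 > best_f1 + 1e-9) {
        best_f1 <- f1; best_params <- params; best_epoch <- ep; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= patience) break
      }
    }
  })
  model$params <- best_params
  list(model = model, history = history, best_epoch = best_epoch)
}
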