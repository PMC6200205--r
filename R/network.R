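#' Compile a connectome table into a retinotopic network
#'
#' Every cell type in the table becomes one feature map of exactly the input
#' resolution: there is no pooling and no striding anywhere, mirroring the
#' columnar organisation of the optic lobe in which modular neurons occur once
#' per retinotopic column. The photoreceptor front-end consists of one
#' weight-shared 3x3 convolution with a fixed 6-tap hexagonal mask (the pooled
#' R1-6 channel: the centre and two opposite corner taps are frozen at zero,
#' leaving the 6 hexagonal neighbours free) plus an independent weight-shared
#' 1x1 convolution per remaining photoreceptor type (R7, R8). Every downstream
#' connection is compiled into a locally connected filter — weights are NOT
#' shared across grid positions — of side \code{rf_columns} with same-padding,
#' and each non-photoreceptor map sums its afferent filters, adds a
#' per-position bias and applies a ReLU. The classifier head flattens the
#' lobula-stage maps into a dense softmax layer.
#'
#' @param table a [connectome_table()].
#' @param input_size integer length-2 (height, width) or a single side length.
#' @param n_classes number of identities to classify (at least 2).
#' @param seed integer; the same seed always yields bit-identical initial
#'   weights.
#' @param photoreceptor_mask logical length-9 (column-major 3x3 tap order),
#'   \code{TRUE} where a tap is free. Default: the hexagonal 6-tap mask.
#' @return An object of class \code{flyeye_network}. \code{$unit_count} is
#'   the number of artificial neurons: cell types x height x width.
#' @examples
#' tab <- load_connectome(default_connectome_path())
#' net <- build_network(tab, c(29, 29), n_classes = 20, seed = 1)
#' net$unit_count                       # 30 * 29 * 29 = 25230
#' round(net$unit_count / 1000) * 1000  # reported as approximately 25,000
#' @export
build_network <- function(table, input_size, n_classes, seed = 1L,
                          photoreceptor_mask = hex_mask()) {
  stopifnot(inherits(table, "connectome_table"))
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  H <- as.integer(input_size[1]); W <- as.integer(input_size[2])
  if (n_classes < 2) stop("n_classes must be at least 2")
  ct <- table$cell_types; cn <- table$connections
  stage_of <- setNames(ct$stage, ct$name)
  max_rf <- max(c(cn$rf_columns, 3L))
  if (min(H, W) < max_rf)
    stop("input size ", H, "x", W, " is smaller than the largest filter (",
         max_rf, " columns)")
  stopifnot(length(photoreceptor_mask) == 9L, is.logical(photoreceptor_mask))

  ord <- topo_order(table)
  P <- H * W
  rfs <- sort(unique(c(cn$rf_columns, if ("R1-6" %in% ct$name) 3L else 1L)))
  nbr <- lapply(setNames(rfs, rfs), function(k) build_nbr(H, W, k))

  incoming <- lapply(setNames(ord, ord), function(ty) {
    cn[cn$post == ty, , drop = FALSE]
  })

  params <- with_seed(seed, {
    photo <- list(); edges <- list(); bias <- list()
    for (ty in ord) {
      if (stage_of[ty] == "photoreceptor") {
        if (ty == "R1-6") {
          w <- rnorm(9L, 0, sqrt(2 / sum(photoreceptor_mask)))
          w[!photoreceptor_mask] <- 0
          photo[[ty]] <- list(rf = 3L, w = w, mask = photoreceptor_mask,
                              bias = 0)
        } else {
          photo[[ty]] <- list(rf = 1L, w = rnorm(1L, 0, sqrt(2)),
                              mask = TRUE, bias = 0)
        }
      } else {
        inc <- incoming[[ty]]
        fan_in <- sum(inc$rf_columns^2)
        for (i in seq_len(nrow(inc))) {
          k2 <- inc$rf_columns[i]^2
          edges[[paste0(inc$pre[i], "->", ty)]] <-
            matrix(rnorm(P * k2, 0, sqrt(2 / fan_in)), P, k2)
        }
        bias[[ty]] <- numeric(P)
      }
    }
    lob <- ord[stage_of[ord] == "lobula"]
    D <- length(lob) * P
    head <- list(W = matrix(rnorm(D * n_classes, 0, sqrt(1 / D)),
                            D, n_classes),
                 b = numeric(n_classes))
    list(photo = photo, edges = edges, bias = bias, head = head)
  })

  structure(list(
    table = table,
    input_height = H, input_width = W,
    n_classes = as.integer(n_classes),
    seed = as.integer(seed),
    order = ord,
    stage = stage_of,
    incoming = incoming,
    lobula = ord[stage_of[ord] == "lobula"],
    nbr = nbr,
    params = params,
    unit_count = length(ord) * P
  ), class = "flyeye_network")
}

#' The hexagonal 6-tap photoreceptor mask
#'
#' A square-grid surrogate for the hexagonal R1-R6 ommatidial neighbourhood:
#' of the 9 taps of a 3x3 kernel (column-major order), the 4 edge neighbours
#' and the NE/SW corner pair are free; the centre and the NW/SE corners are
#' frozen at zero, leaving exactly 6 free taps.
#'
#' @return logical vector of length 9.
#' @export
hex_mask <- function() {
  m <- rep(TRUE, 9L)
  m[c(1L, 5L, 9L)] <- FALSE   # NW corner, centre, SE corner
  m
}

# P x k^2 neighbour index table for a k x k same-padded window on an
# H x W grid; 0 marks out-of-grid taps (zero padding). Column-major
# pixel order: p = (col-1)*H + row. Tap order: column-major over (dr, dc).
build_nbr <- function(H, W, k) {
  r <- (k - 1L) %/% 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  nbr <- matrix(0L, H * W, nrow(offs))
  for (t in seq_len(nrow(offs))) {
    ii <- i + offs$dr[t]; jj <- j + offs$dc[t]
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    nbr[ok, t] <- (jj[ok] - 1L) * H + ii[ok]
  }
  nbr
}

relu <- function(x) { x[x < 0] <- 0; x }

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of a fly-eye network
#'
#' @param model a [build_network()] model.
#' @param x numeric matrix, one flattened image per row (n x H*W,
#'   column-major pixel order).
#' @param return_acts keep per-type activations (used by training/backprop).
#' @return list with \code{probs} (n x n_classes softmax output) and, when
#'   requested, \code{acts} and pre-activation sign masks.
#' @export
forward_network <- function(model, x, return_acts = FALSE) {
  stopifnot(is.matrix(x), ncol(x) == model$input_height * model$input_width)
  p <- model$params
  acts <- list(); pos <- list()
  for (ty in model$order) {
    if (model$stage[ty] == "photoreceptor") {
      ph <- p$photo[[ty]]
      z <- sc_forward(x, ph$w, model$nbr[[as.character(ph$rf)]]) + ph$bias
    } else {
      inc <- model$incoming[[ty]]
      z <- NULL
      for (i in seq_len(nrow(inc))) {
        e <- lc_forward(acts[[inc$pre[i]]],
                        p$edges[[paste0(inc$pre[i], "->", ty)]],
                        model$nbr[[as.character(inc$rf_columns[i])]])
        z <- if (is.null(z)) e else z + e
      }
      z <- sweep(z, 2L, p$bias[[ty]], "+")
    }
    pos[[ty]] <- z > 0
    acts[[ty]] <- relu(z)
  }
  a_lob <- do.call(cbind, acts[model$lobula])
  logits <- a_lob %*% p$head$W
  logits <- sweep(logits, 2L, p$head$b, "+")
  probs <- softmax_rows(logits)
  if (return_acts) list(probs = probs, acts = acts, pos = pos, a_lob = a_lob)
  else list(probs = probs)
}

#' Predict class probabilities in batches
#'
#' @inheritParams forward_network
#' @param batch_size mini-batch size used to bound memory.
#' @return n x n_classes matrix of class probabilities (rows sum to 1).
#' @export
predict_network <- function(model, x, batch_size = 512L) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, model$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx, ] <- forward_network(model, x[idx, , drop = FALSE])$probs
  }
  out
}

# loss + gradients for one mini-batch; y is an integer class vector (1-based).
# Returns mean cross-entropy and a gradient list parallel to model$params.
network_grads <- function(model, x, y) {
  fw <- forward_network(model, x, return_acts = TRUE)
  n <- nrow(x); C <- model$n_classes; P <- model$input_height * model$input_width
  probs <- fw$probs
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y)], 1e-12)))

  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits / n

  p <- model$params
  g <- list(photo = list(), edges = list(), bias = list(),
            head = list(W = crossprod(fw$a_lob, dlogits),
                        b = colSums(dlogits)))
  d_lob <- tcrossprod(dlogits, p$head$W)
  dA <- list()
  for (i in seq_along(model$lobula))
    dA[[model$lobula[i]]] <- d_lob[, ((i - 1) * P + 1):(i * P), drop = FALSE]

  for (ty in rev(model$order)) {
    if (is.null(dA[[ty]])) next   # type feeds nothing that was reached
    dz <- dA[[ty]] * fw$pos[[ty]]
    if (model$stage[ty] == "photoreceptor") {
      ph <- p$photo[[ty]]
      nb <- model$nbr[[as.character(ph$rf)]]
      dw <- sc_backward_weight(dz, x, nb)
      dw[!ph$mask] <- 0
      g$photo[[ty]] <- list(w = dw, bias = sum(dz))
    } else {
      inc <- model$incoming[[ty]]
      g$bias[[ty]] <- colSums(dz)
      for (i in seq_len(nrow(inc))) {
        pre <- inc$pre[i]
        key <- paste0(pre, "->", ty)
        nb <- model$nbr[[as.character(inc$rf_columns[i])]]
        g$edges[[key]] <- lc_backward_weight(dz, fw$acts[[pre]], nb)
        dx <- lc_backward_input(dz, p$edges[[key]], nb)
        dA[[pre]] <- if (is.null(dA[[pre]])) dx else dA[[pre]] + dx
      }
    }
  }
  list(loss = loss, grads = g, probs = probs)
}

#' Per-connection parameter counts of a compiled network
#'
#' One row per connection of the underlying table. A locally connected edge
#' on an H x W grid with an rf x rf window over a single afferent map holds
#' \code{H*W*rf^2} weights (per-position biases belong to the postsynaptic
#' type, not to individual edges, and are listed in the \code{n_bias_post}
#' column).
#'
#' @param model a [build_network()] model.
#' @return data.frame with columns \code{pre}, \code{post}, \code{rf_columns},
#'   \code{n_weights}, \code{n_bias_post}.
#' @export
connection_report <- function(model) {
  stopifnot(inherits(model, "flyeye_network"))
  cn <- model$table$connections
  P <- model$input_height * model$input_width
  data.frame(pre = cn$pre, post = cn$post, rf_columns = cn$rf_columns,
             n_weights = P * cn$rf_columns^2,
             n_bias_post = P,
             stringsAsFactors = FALSE)
}

#' @export
print.flyeye_network <- function(x, ...) {
  cat("<flyeye_network> ", length(x$order), " feature maps of ",
      x$input_height, "x", x$input_width, " (", x$unit_count,
      " units), head over ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' Save / load a compiled network (YAML architecture + HDF5 weights)
#'
#' The architecture (connectome table, input size, classes, seed) goes to
#' \code{architecture.yaml}; all weights go to \code{weights.h5}. The
#' round-trip is exact: doubles are stored losslessly.
#'
#' @param model a [build_network()] model.
#' @param dir directory to create/use.
#' @return \code{dir} (save) or the restored model (load).
#' @export
save_network <- function(model, dir) {
  stopifnot(inherits(model, "flyeye_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask <- model$params$photo[["R1-6"]]$mask
  if (is.null(mask) || length(mask) != 9L) mask <- hex_mask()
  arch <- list(
    input_height = model$input_height, input_width = model$input_width,
    n_classes = model$n_classes, seed = model$seed,
    photoreceptor_mask = as.logical(mask),
    cell_types = model$table$cell_types,
    connections = model$table$connections,
    edge_names = names(model$params$edges)
  )
  yaml::write_yaml(arch, file.path(dir, "architecture.yaml"))
  h5 <- file.path(dir, "weights.h5")
  if (file.exists(h5)) unlink(h5)
  rhdf5::h5createFile(h5)
  rhdf5::h5createGroup(h5, "edges")
  for (i in seq_along(model$params$edges))
    rhdf5::h5write(model$params$edges[[i]], h5, sprintf("edges/e%04d", i))
  rhdf5::h5createGroup(h5, "bias")
  for (i in seq_along(model$params$bias))
    rhdf5::h5write(model$params$bias[[i]], h5, sprintf("bias/b%04d", i))
  rhdf5::h5createGroup(h5, "photo")
  for (i in seq_along(model$params$photo)) {
    ph <- model$params$photo[[i]]
    rhdf5::h5write(c(ph$w, ph$bias), h5, sprintf("photo/p%04d", i))
  }
  rhdf5::h5write(model$params$head$W, h5, "head_W")
  rhdf5::h5write(model$params$head$b, h5, "head_b")
  rhdf5::h5closeAll()
  invisible(dir)
}

#' @rdname save_network
#' @export
load_network <- function(dir) {
  arch <- yaml::read_yaml(file.path(dir, "architecture.yaml"))
  tab <- connectome_table(as.data.frame(arch$cell_types),
                          as.data.frame(arch$connections))
  model <- build_network(tab, c(arch$input_height, arch$input_width),
                         arch$n_classes, seed = arch$seed,
                         photoreceptor_mask = arch$photoreceptor_mask)
  h5 <- file.path(dir, "weights.h5")
  stopifnot(identical(names(model$params$edges), unlist(arch$edge_names)))
  for (i in seq_along(model$params$edges)) {
    w <- rhdf5::h5read(h5, sprintf("edges/e%04d", i))
    dim(w) <- dim(model$params$edges[[i]])
    model$params$edges[[i]] <- w
  }
  for (i in seq_along(model$params$bias))
    model$params$bias[[i]] <- as.numeric(rhdf5::h5read(h5, sprintf("bias/b%04d", i)))
  for (i in seq_along(model$params$photo)) {
    v <- as.numeric(rhdf5::h5read(h5, sprintf("photo/p%04d", i)))
    k <- length(model$params$photo[[i]]$w)
    model$params$photo[[i]]$w <- v[seq_len(k)]
    model$params$photo[[i]]$bias <- v[k + 1]
  }
  W <- rhdf5::h5read(h5, "head_W")
  dim(W) <- dim(model$params$head$W)
  model$params$head$W <- W
  model$params$head$b <- as.numeric(rhdf5::h5read(h5, "head_b"))
  rhdf5::h5closeAll()
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
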