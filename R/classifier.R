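#' Backbone specification for the tile classifier
#'
#' The classifier is weakly supervised: every tile carries the protein-based
#' subtype of its parent slide as label, and the backbone maps a batch of
#' tiles to per-class probabilities summing to one.  The backbone is an
#' abstraction; the package ships \code{"tiny"}, a small pooled-pixel
#' multilayer perceptron designed to separate class-distinctive tissue
#' textures on a single CPU in seconds: tiles are average-pooled to
#' \code{input_edge}, pooled again to \code{pool_edge}, flattened to an RGB
#' feature vector and passed through one hidden layer with softmax output.
#'
#' @param name Backbone name; currently \code{"tiny"}.
#' @param input_edge Edge length tiles are pooled to before featurization.
#' @param pool_edge Edge of the final pooled feature grid.
#' @param hidden Hidden layer width.
#' @param pretrained Unused by \code{"tiny"} (no pretrained weights ship with
#'   the package); kept so externally trained backbones can declare it.
#' @param n_outputs Number of classes (2: luminal, basal).
#' @return A \code{"backbone_spec"}.
#' @export
backbone_spec <- function(name = "tiny", input_edge = 64, pool_edge = 16,
                          hidden = 32, pretrained = FALSE, n_outputs = 2) {
  if (!identical(name, "tiny"))
    stop("unknown backbone '", name, "'; available: tiny")
  stopifnot(input_edge >= pool_edge, n_outputs == 2)
  structure(list(name = name, input_edge = input_edge, pool_edge = pool_edge,
                 hidden = hidden, pretrained = pretrained,
                 n_outputs = n_outputs),
            class = "backbone_spec")
}

#' Training configuration for the tile classifier
#'
#' @param epochs Number of passes over the balanced training set (default 4;
#'   0 leaves the model at its random initialization).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate SGD learning rate (default 0.05 for the tiny
#'   backbone).
#' @param seed Seed fixing initialization and data order.
#' @param augment Dihedral augmentation: when \code{TRUE} the training
#'   features are expanded with the 8 rotations/flips of the pooled grid
#'   (histology has no canonical orientation).  Off by default.
#' @return A \code{"train_config"}.
#' @export
train_config <- function(epochs = 4, batch_size = 32, learning_rate = 0.05,
                         seed = 1, augment = FALSE) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed,
                 augment = isTRUE(augment)),
            class = "train_config")
}

# Average-pool an image array to edge x edge by index binning.
pool_image <- function(px, edge) {
  d <- dim(px)
  ri <- floor((seq_len(d[1]) - 1) * edge / d[1]) + 1
  ci <- floor((seq_len(d[2]) - 1) * edge / d[2]) + 1
  out <- array(0, c(edge, edge, 3))
  for (ch in 1:3) {
    s <- rowsum(px[, , ch], ri)                 # pool rows
    s <- t(rowsum(t(s), ci))                    # pool cols
    cnt <- tabulate(ri, edge) %o% tabulate(ci, edge)
    out[, , ch] <- s / cnt
  }
  out
}

#' Featurize tiles for a backbone
#'
#' @param tiles List of \code{T x T x 3} arrays (values in \[0, 1\] or
#'   \[0, 255\]) or a character vector of PNG paths.
#' @param backbone A \code{\link{backbone_spec}}.
#' @return Numeric matrix, one row per tile, \code{3 * pool_edge^2} columns.
#' @export
featurize_tiles <- function(tiles, backbone = backbone_spec()) {
  if (is.character(tiles)) tiles <- lapply(tiles, read_tile_png)
  if (is.array(tiles)) tiles <- list(tiles)
  t(vapply(tiles, function(px) {
    px <- tile_unit_scale(px)
    if (dim(px)[1] != backbone$input_edge)
      px <- pool_image(px, backbone$input_edge)
    as.vector(pool_image(px, backbone$pool_edge))
  }, numeric(3 * backbone$pool_edge^2)))
}

# The 8 dihedral transforms of a pooled feature vector.
dihedral_features <- function(feat, edge) {
  a <- array(feat, c(edge, edge, 3))
  rot <- function(x) aperm(x[, rev(seq_len(edge)), , drop = FALSE], c(2, 1, 3))
  out <- vector("list", 8)
  cur <- a
  for (i in 1:4) {
    out[[i]] <- as.vector(cur)
    out[[i + 4]] <- as.vector(cur[rev(seq_len(edge)), , , drop = FALSE])
    cur <- rot(cur)
  }
  do.call(rbind, out)
}

classifier_classes <- function() c("luminal", "basal")

#' Fit the weakly supervised tile classifier
#'
#' Trains the backbone's classification head by seeded minibatch stochastic
#' gradient descent on softmax cross-entropy.  Inputs are the balanced
#' training rows of a tile manifest (see
#' \code{\link{balance_training_tiles}}) plus the tiles themselves, given as
#' a list of pixel arrays, PNG paths (a \code{tile_path} column), or a
#' precomputed feature matrix from \code{\link{featurize_tiles}}.  All
#' randomness (weight initialization, minibatch order) is fixed by
#' \code{config$seed}: identical inputs give identical models.
#'
#' @param train_rows Manifest rows with a \code{label} column
#'   (\code{"luminal"} / \code{"basal"}).
#' @param tiles List of tile arrays or character vector of PNG paths,
#'   aligned with \code{train_rows}; ignored when \code{features} is given.
#' @param backbone A \code{\link{backbone_spec}}.
#' @param config A \code{\link{train_config}}.
#' @param features Optional precomputed feature matrix (rows aligned with
#'   \code{train_rows}).
#' @return A \code{"tile_classifier"} with the fitted weights, feature
#'   scaling, training \code{log} (epoch, loss, accuracy) and metadata.
#' @examples
#' sl <- gen_pseudo_slide(pseudo_slide_params(width = 512, height = 512,
#'                                            layout = "luminal",
#'                                            tile_edge = 128, seed = 1))
#' f <- featurize_tiles(list(sl$image), backbone_spec())
#' @export
tile_classifier <- function(train_rows, tiles = NULL,
                            backbone = backbone_spec(),
                            config = train_config(), features = NULL) {
  labels <- as.character(train_rows$label)
  bad <- setdiff(unique(labels), classifier_classes())
  if (length(bad))
    stop("labels outside {luminal, basal}: ", paste(bad, collapse = ", "))
  if (is.null(features)) {
    if (is.null(tiles)) {
      if (is.null(train_rows$tile_path))
        stop("provide tiles, features, or a tile_path manifest column")
      tiles <- train_rows$tile_path
      missing <- if (is.character(tiles)) tiles[!file.exists(tiles)] else character()
      if (length(missing)) stop("unreadable tile: ", missing[1])
    }
    features <- featurize_tiles(tiles, backbone)
  }
  stopifnot(nrow(features) == length(labels))
  y <- match(labels, classifier_classes())
  if (config$augment) {
    features <- do.call(rbind, lapply(seq_len(nrow(features)), function(i)
      dihedral_features(features[i, ], backbone$pool_edge)))
    y <- rep(y, each = 8)
  }
  mu <- colMeans(features)
  sg <- pmax(apply(features, 2, stats::sd), 1e-8)
  x <- sweep(sweep(features, 2, mu), 2, sg, `/`)
  d <- ncol(x); h <- backbone$hidden; k <- backbone$n_outputs
  with_seed(derive_seed(config$seed, 271828L), {
    w1 <- matrix(stats::rnorm(d * h, sd = 0.01), d, h)
    b1 <- numeric(h)
    w2 <- matrix(stats::rnorm(h * k, sd = 0.01), h, k)
    b2 <- numeric(k)
    trainlog <- data.frame(epoch = integer(), loss = numeric(),
                      accuracy = numeric())
    n <- nrow(x)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        hid <- tanh(sweep(xb %*% w1, 2, b1, `+`))
        logits <- sweep(hid %*% w2, 2, b2, `+`)
        p <- softmax_rows(logits)
        grad <- p
        grad[cbind(seq_along(idx), y[idx])] <-
          grad[cbind(seq_along(idx), y[idx])] - 1
        grad <- grad / length(idx)
        gw2 <- t(hid) %*% grad
        gb2 <- colSums(grad)
        ghid <- (grad %*% t(w2)) * (1 - hid^2)
        gw1 <- t(xb) %*% ghid
        gb1 <- colSums(ghid)
        lr <- config$learning_rate
        w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
        w1 <- w1 - lr * gw1; b1 <- b1 - lr * gb1
      }
      p_all <- mlp_forward(x, w1, b1, w2, b2)
      trainlog <- rbind(trainlog, data.frame(
        epoch = ep,
        loss = -mean(log(pmax(p_all[cbind(seq_len(n), y)], 1e-12))),
        accuracy = mean(max.col(p_all) == y)))
    }
    structure(list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, mu = mu, sigma = sg,
                   backbone = backbone, config = config, log = trainlog,
                   classes = classifier_classes(), n_train = n),
              class = "tile_classifier")
  })
}

#' @rdname tile_classifier
#' @export
train_model <- tile_classifier

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

mlp_forward <- function(x, w1, b1, w2, b2) {
  hid <- tanh(sweep(x %*% w1, 2, b1, `+`))
  softmax_rows(sweep(hid %*% w2, 2, b2, `+`))
}

#' Predict tile-level class probabilities
#'
#' Deterministic in evaluation mode: the same tile always receives the same
#' \code{(p_luminal, p_basal)}, and the two probabilities sum to one.
#'
#' @param model A fitted \code{\link{tile_classifier}}.
#' @param tiles Tile arrays, PNG paths, or a feature matrix (when
#'   \code{features = TRUE} it is taken as features directly).
#' @param features Logical; treat \code{tiles} as a precomputed feature
#'   matrix.
#' @return Data frame with columns \code{p_luminal}, \code{p_basal}.
#' @export
predict_tiles <- function(model, tiles, features = FALSE) {
  stopifnot(inherits(model, "tile_classifier"))
  f <- if (isTRUE(features)) tiles else featurize_tiles(tiles, model$backbone)
  if (ncol(f) != length(model$mu))
    stop("tile/feature shape does not match the backbone input spec")
  x <- sweep(sweep(f, 2, model$mu), 2, model$sigma, `/`)
  p <- mlp_forward(x, model$w1, model$b1, model$w2, model$b2)
  stats::setNames(as.data.frame(p), paste0("p_", model$classes))
}

#' @export
predict.tile_classifier <- function(object, newdata, ...) {
  predict_tiles(object, newdata, ...)
}

#' @export
print.tile_classifier <- function(x, ...) {
  cat("Weakly supervised tile classifier (backbone: ", x$backbone$name,
      ", ", length(x$mu), " features, hidden ", x$backbone$hidden, ")\n",
      sep = "")
  cat("  trained on", x$n_train, "tiles,", x$config$epochs, "epoch(s)\n")
  if (nrow(x$log))
    cat("  final loss ", round(utils::tail(x$log$loss, 1), 4),
        ", training accuracy ",
        round(utils::tail(x$log$accuracy, 1), 3), "\n", sep = "")
  invisible(x)
}
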