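# Training loop: binary cross-entropy minimised by SGD with momentum,
# gradient accumulation over the batch, early stopping on validation loss,
# best-checkpoint restoration. Entirely seeded: data order, augmentation and
# dropout all draw from one RNG stream, so a run is bit-reproducible on CPU.

#' Training configuration
#'
#' Defaults are the tuned recipe used throughout: binary cross-entropy
#' minimised by SGD with momentum 0.99 and no decay, learning rate 0.002,
#' batch size 6, up to 360 epochs with early-stopping patience of 100 epochs
#' monitoring the validation loss, keeping the best-validation weights.
#'
#' @param learning_rate,momentum SGD parameters (constant learning rate).
#' @param batch_size Patches per gradient step (gradient accumulation).
#' @param max_epochs Epoch budget; an epoch visits every training patch once.
#' @param patience Stop after this many epochs without validation-loss
#'   improvement. Must not exceed `max_epochs`.
#' @param augment Apply random right-angle rotations and flips on the fly.
#' @param elastic Add elastic deformations (used for 3D training).
#' @param seed Seed for data order, augmentation and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.002, momentum = 0.99, batch_size = 6L,
                         max_epochs = 360L, patience = 100L,
                         augment = TRUE, elastic = FALSE, seed = 42L) {
  if (patience > max_epochs && max_epochs > 0L) {
    stop("patience must not exceed max_epochs")
  }
  structure(
    list(
      loss = "bce", learning_rate = learning_rate, momentum = momentum,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), augment = isTRUE(augment),
      elastic = isTRUE(elastic), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(as.vector(p), eps), 1 - eps)
  y <- as.vector(y)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.strip_channel <- function(x) {
  d <- dim(x)
  if (d[length(d)] == 1L) dim(x) <- d[-length(d)]
  x
}

#' Train a network
#'
#' @param model An `em_network` from [build_network()].
#' @param train_data,val_data Lists of `list(image, labels)` patch pairs
#'   (e.g. from [random_patches()]); images in `[0, 1]`, labels binary, train
#'   and validation disjoint.
#' @param cfg A [train_config()].
#' @return List with `model` (weights of the best validation epoch),
#'   `history` (data frame: epoch, train_loss, val_loss) and `best_epoch`.
#'   `max_epochs = 0` returns the initial weights and an empty history.
#' @export
train_model <- function(model, train_data, val_data, cfg = train_config()) {
  stopifnot(inherits(model, "em_network"))
  if (length(train_data) == 0L) stop("empty training set")
  if (cfg$max_epochs == 0L) {
    return(list(
      model = model,
      history = data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric()),
      best_epoch = 0L
    ))
  }

  val_loss_of <- function(m) {
    if (length(val_data) == 0L) {
      return(NA_real_)
    }
    mean(vapply(val_data, function(s) {
      p <- predict_patch(m, .strip_channel(s$image))
      bce_loss(p, .strip_channel(s$labels))
    }, 0))
  }

  velocity <- lapply(model$params, function(p) array(0, dim(p) %||% length(p)))
  best <- list(params = model$params, val = Inf, epoch = 0L)
  hist_rows <- vector("list", cfg$max_epochs)
  n <- length(train_data)

  withr::with_seed(cfg$seed, {
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      n_seen <- 0L
      for (bstart in seq.int(1L, n, by = cfg$batch_size)) {
        bidx <- ord[seq.int(bstart, min(n, bstart + cfg$batch_size - 1L))]
        grads <- NULL
        for (i in bidx) {
          s <- train_data[[i]]
          img <- .strip_channel(s$image)
          lab <- .strip_channel(s$labels)
          if (cfg$augment) {
            a <- augment(img, lab, elastic = cfg$elastic)
            img <- a$image
            lab <- a$labels
          }
          fw <- forward_network(model, img, train = TRUE)
          p <- fw$out
          epoch_loss <- epoch_loss + bce_loss(p, lab)
          n_seen <- n_seen + 1L
          # fused sigmoid + BCE gradient on the logits
          dlogit <- array((as.vector(p) - as.vector(lab)) / (length(p) * length(bidx)), dim(p))
          g <- backward_network(fw, dlogit)
          grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        }
        for (nm in names(model$params)) {
          velocity[[nm]] <- cfg$momentum * velocity[[nm]] - cfg$learning_rate * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + velocity[[nm]]
        }
      }
      vl <- val_loss_of(model)
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epoch_loss / n_seen, val_loss = vl
      )
      monitor <- if (is.na(vl)) epoch_loss / n_seen else vl
      if (monitor < best$val) {
        best <- list(params = model$params, val = monitor, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  list(
    model = model,
    history = do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)]),
    best_epoch = best$epoch
  )
}
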