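# U-net training harness: a compact encoder-decoder CNN trained with the
# negative soft-Dice loss and Adam, on image/mask pairs. Convolution kernels
# live in src/; this file owns architecture, autodiff bookkeeping, the
# optimizer and the data plumbing.

#' Training configuration
#'
#' Defaults are the desk-scale protocol (64 x 64 inputs, a 2-down U-net,
#' 50 epochs, learning rate 1e-3, test set of 20) which trains in minutes on
#' one CPU; \code{\link{paperTrainConfig}} gives the full-scale protocol
#' (256 x 256, 4-down, 600 epochs, Adam step 1e-5, test set of 50).
#'
#' @slot inputSize square input side in pixels.
#' @slot depth number of pooling levels.
#' @slot baseFilters filters in the first encoder block (doubled per level).
#' @slot epochs training epochs.
#' @slot lr Adam step length.
#' @slot batchSize minibatch size.
#' @slot testCount images held out as the test set.
#' @slot trainFrac fraction of the remainder used for training (rest is
#'   validation).
#' @slot seed RNG seed for weight init, splitting and shuffling.
#' @slot diceEps smoothing constant of the Dice loss.
#' @export
setClass("TrainConfig",
  representation(inputSize = "integer", depth = "integer",
                 baseFilters = "integer", epochs = "integer", lr = "numeric",
                 batchSize = "integer", testCount = "integer",
                 trainFrac = "numeric", seed = "integer", diceEps = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@trainFrac <= 0 || object@trainFrac >= 1)
    return("trainFrac must be in (0,1)")
  if (object@epochs < 1) return("epochs must be >= 1")
  if (object@inputSize %% 2^object@depth != 0)
    return("inputSize must be divisible by 2^depth")
  if (object@lr <= 0 || object@diceEps <= 0)
    return("lr and diceEps must be positive")
  TRUE
})

#' Construct a TrainConfig
#'
#' @param inputSize square input side (default 64).
#' @param depth pooling levels (default 2).
#' @param baseFilters first-block filter count (default 8).
#' @param epochs training epochs (default 50).
#' @param lr Adam step length (default 1e-3).
#' @param batchSize minibatch size (default 8).
#' @param testCount held-out test images (default 20).
#' @param trainFrac training fraction of the remainder (default 0.8).
#' @param seed RNG seed (default 1).
#' @param diceEps Dice-loss smoothing (default 1).
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(inputSize = 64L, depth = 2L, baseFilters = 8L,
                        epochs = 50L, lr = 1e-3, batchSize = 8L,
                        testCount = 20L, trainFrac = 0.8, seed = 1L,
                        diceEps = 1) {
  new("TrainConfig", inputSize = as.integer(inputSize),
      depth = as.integer(depth), baseFilters = as.integer(baseFilters),
      epochs = as.integer(epochs), lr = lr, batchSize = as.integer(batchSize),
      testCount = as.integer(testCount), trainFrac = trainFrac,
      seed = as.integer(seed), diceEps = diceEps)
}

#' Full-scale training configuration
#'
#' The published-scale protocol: 256 x 256 inputs, a 4-down U-net (19
#' convolutional layers counting the 1 x 1 output), negative-Dice loss,
#' Adam with step length 1e-5, 600 epochs, 50 test images. Expect hours of
#' CPU time at this scale.
#'
#' @param ... overrides passed to \code{\link{trainConfig}}.
#' @return a \linkS4class{TrainConfig}.
#' @export
paperTrainConfig <- function(...) {
  args <- list(inputSize = 256L, depth = 4L, baseFilters = 16L,
               epochs = 600L, lr = 1e-5, batchSize = 8L, testCount = 50L)
  over <- list(...)
  args[names(over)] <- over
  do.call(trainConfig, args)
}

#' Trained U-net model
#'
#' @slot layers named list of convolution weights.
#' @slot config the \linkS4class{TrainConfig} used.
#' @slot history data.frame with per-epoch loss and validation Dice.
#' @slot maskKind which mask source the model was trained on ("et", "ha",
#'   or "truth").
#' @export
setClass("UnetModel",
  representation(layers = "list", config = "TrainConfig",
                 history = "data.frame", maskKind = "character"))

setMethod("show", "UnetModel", function(object) {
  h <- object@history
  cat(sprintf("UnetModel (%s masks): depth %d, %d base filters, %d epochs\n",
              object@maskKind, object@config@depth, object@config@baseFilters,
              nrow(h)))
  if (nrow(h))
    cat(sprintf("  final loss %.4f, validation Dice %.4f\n",
                h$loss[nrow(h)], h$valDice[nrow(h)]))
})

#' Normalize an image to zero mean and unit standard deviation
#'
#' Per-image standardization applied before network input; invariant to
#' affine intensity rescaling of the input.
#'
#' @param img numeric matrix with more than one distinct value.
#' @return matrix with mean 0 and sd 1.
#' @export
normalizeImage <- function(img) {
  s <- sd(img)
  if (!is.finite(s) || s < 1e-12)
    stop("constant image cannot be normalized (sd is 0)")
  (img - mean(img)) / s
}

#' Split a dataset manifest into train/validation/test index sets
#'
#' The test set is drawn at random from the lesion images only (normals are
#' kept for training, where they teach the network specificity); the
#' remainder is split train/validation by \code{trainFrac}. Disjoint and
#' exhaustive, reproducible given the config seed. With 356 lesion images,
#' a test count of 50 and the default 0.8 fraction this yields the classic
#' 245/61/50 split.
#'
#' @param manifest data.frame with one row per image (a \code{label} column,
#'   if present, marks "lesion"/"normal").
#' @param cfg a \linkS4class{TrainConfig}.
#' @return list of integer row indices: \code{train}, \code{val}, \code{test}.
#' @export
splitDataset <- function(manifest, cfg) {
  n <- nrow(manifest)
  if (n < cfg@testCount + 5)
    stop("manifest too small: need at least testCount + 5 images")
  pool <- if ("label" %in% names(manifest))
    which(manifest$label == "lesion") else seq_len(n)
  if (length(pool) < cfg@testCount)
    stop("not enough lesion images for the requested test count")
  with_seed(cfg@seed, {
    test <- sort(sample(pool, cfg@testCount))
    rest <- setdiff(seq_len(n), test)
    ntr <- round(cfg@trainFrac * length(rest))
    train <- sort(sample(rest, ntr))
    val <- setdiff(rest, train)
    list(train = train, val = val, test = test)
  })
}

# ---- architecture ----------------------------------------------------------

enc_channels <- function(cfg, i) cfg@baseFilters * 2^(i - 1)

glorot <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin + 9 * cout))
  array(rnorm(9 * cin * cout, 0, sd), c(3, 3, cin, cout))
}

unet_init <- function(cfg) {
  d <- cfg@depth; f <- cfg@baseFilters
  with_seed(cfg@seed, {
    net <- list()
    cin <- 1L
    for (i in seq_len(d)) {
      co <- enc_channels(cfg, i)
      net[[paste0("enc", i, "a")]] <- list(W = glorot(cin, co), b = numeric(co))
      net[[paste0("enc", i, "b")]] <- list(W = glorot(co, co), b = numeric(co))
      cin <- co
    }
    cb <- f * 2^d
    net[["bota"]] <- list(W = glorot(cin, cb), b = numeric(cb))
    net[["botb"]] <- list(W = glorot(cb, cb), b = numeric(cb))
    for (i in rev(seq_len(d))) {
      below <- if (i == d) cb else enc_channels(cfg, i + 1)
      ci <- below + enc_channels(cfg, i)
      co <- enc_channels(cfg, i)
      net[[paste0("dec", i, "a")]] <- list(W = glorot(ci, co), b = numeric(co))
      net[[paste0("dec", i, "b")]] <- list(W = glorot(co, co), b = numeric(co))
    }
    sdo <- sqrt(2 / (f + 1))
    net[["out"]] <- list(W = rnorm(f, 0, sdo), b = 0)
    net
  })
}

bind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

unet_forward <- function(net, x, cfg, want_cache = TRUE) {
  d <- cfg@depth
  cache <- list(convs = list(), pools = list(), updims = list())
  cr <- function(name, a) {
    z <- cpp_conv3_fwd(a, net[[name]]$W, net[[name]]$b)
    if (want_cache) cache$convs[[name]] <<- list(x = a, pos = z > 0)
    pmax(z, 0)
  }
  a <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    a <- cr(paste0("enc", i, "a"), a)
    a <- cr(paste0("enc", i, "b"), a)
    skips[[i]] <- a
    pl <- cpp_maxpool2_fwd(a)
    if (want_cache) cache$pools[[i]] <- list(idx = pl$idx, xdim = dim(a))
    a <- pl$y
  }
  a <- cr("bota", a)
  a <- cr("botb", a)
  for (i in rev(seq_len(d))) {
    u <- cpp_upsample2_fwd(a)
    if (want_cache) cache$updims[[i]] <- dim(a)[3] # channels below
    a <- cr(paste0("dec", i, "a"), bind_channels(u, skips[[i]]))
    a <- cr(paste0("dec", i, "b"), a)
  }
  # 1x1 output convolution (linear), then sigmoid
  da <- dim(a)
  logits <- array(net$out$b, c(da[1], da[2], 1, da[4]))
  for (c in seq_len(da[3]))
    logits[, , 1, ] <- logits[, , 1, ] + a[, , c, ] * net$out$W[c]
  if (want_cache) cache$outx <- a
  list(probs = sigmoid(logits), logits = logits, cache = cache)
}

unet_backward <- function(net, cfg, cache, probs, dlogits) {
  d <- cfg@depth
  grads <- list()
  crb <- function(name, dout) {
    cc <- cache$convs[[name]]
    dz <- dout * cc$pos
    g <- cpp_conv3_bwd(cc$x, net[[name]]$W, dz)
    grads[[name]] <<- list(W = g$dw, b = g$db)
    g$dx
  }
  # output 1x1 conv
  a <- cache$outx
  da <- dim(a)
  dW <- numeric(da[3]); dA <- array(0, da)
  dl <- dlogits[, , 1, , drop = FALSE]
  for (c in seq_len(da[3])) {
    dW[c] <- sum(a[, , c, ] * dl[, , 1, ])
    dA[, , c, ] <- dl[, , 1, ] * net$out$W[c]
  }
  grads[["out"]] <- list(W = dW, b = sum(dl))
  dskips <- vector("list", d)
  dv <- dA
  for (i in seq_len(d)) { # reverse of the decoder loop (which ran d..1)
    dv <- crb(paste0("dec", i, "b"), dv)
    dcat <- crb(paste0("dec", i, "a"), dv)
    cu <- cache$updims[[i]]
    du <- dcat[, , seq_len(cu), , drop = FALSE]
    dskips[[i]] <- dcat[, , cu + seq_len(dim(dcat)[3] - cu), , drop = FALSE]
    dv <- cpp_upsample2_bwd(du)
  }
  dv <- crb("botb", dv)
  dv <- crb("bota", dv)
  for (i in rev(seq_len(d))) {
    pl <- cache$pools[[i]]
    dv <- cpp_maxpool2_bwd(dv, pl$idx, pl$xdim) + dskips[[i]]
    dv <- crb(paste0("enc", i, "b"), dv)
    dv <- crb(paste0("enc", i, "a"), dv)
  }
  grads
}

#' Soft Dice loss of probability maps against binary masks
#'
#' Per-image smoothed Dice, averaged, negated: a perfect prediction scores
#' about -1 (within the smoothing tolerance) and a fully wrong prediction
#' approaches 0.
#'
#' @param probs array (H, W, 1, N) or a single matrix of probabilities.
#' @param masks matching array or matrix of 0/1 labels.
#' @param eps smoothing constant added to numerator and denominator.
#' @return list with \code{loss} (scalar) and \code{dprobs} (gradient).
#' @export
diceLoss <- function(probs, masks, eps = 1) {
  if (is.matrix(probs)) probs <- array(probs, c(dim(probs), 1, 1))
  if (is.matrix(masks)) masks <- array(masks, c(dim(masks), 1, 1))
  N <- dim(probs)[4]
  pm <- matrix(probs, ncol = N)
  ym <- matrix(masks, ncol = N)
  Sp <- colSums(pm); Sy <- colSums(ym); Spy <- colSums(pm * ym)
  den <- Sp + Sy + eps
  num <- 2 * Spy + eps
  dice <- num / den
  dl <- -sweep(sweep(2 * ym, 2, den, "*") - sweep(matrix(1, nrow(pm), N),
                                                  2, num, "*"),
               2, den^2, "/") / N
  list(loss = -mean(dice),
       dprobs = array(dl, dim(probs)),
       dice = dice)
}

adam_init <- function(net) {
  lapply(net, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(net)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    net[[nm]]$W <- net[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    net[[nm]]$b <- net[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(net = net, state = state)
}

# Core fitting routine on in-memory arrays (H, W, 1, N).
fit_unet <- function(x, y, cfg, xval = NULL, yval = NULL, maskKind = "truth",
                     verbose = FALSE) {
  stopifnot(length(dim(x)) == 4, identical(dim(x), dim(y)))
  net <- unet_init(cfg)
  state <- adam_init(net)
  N <- dim(x)[4]
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     valDice = numeric(0))
  tstep <- 0
  shuffle_seeds <- derive_seeds(cfg@seed, cfg@epochs)
  for (ep in seq_len(cfg@epochs)) {
    ord <- with_seed(shuffle_seeds[ep], sample.int(N))
    losses <- numeric(0)
    for (b0 in seq(1, N, by = cfg@batchSize)) {
      idx <- ord[b0:min(b0 + cfg@batchSize - 1, N)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[, , , idx, drop = FALSE]
      fw <- unet_forward(net, xb, cfg)
      ls <- diceLoss(fw$probs, yb, cfg@diceEps)
      dlogits <- ls$dprobs * fw$probs * (1 - fw$probs)
      grads <- unet_backward(net, cfg, fw$cache, fw$probs, dlogits)
      tstep <- tstep + 1
      up <- adam_step(net, grads, state, cfg@lr, tstep)
      net <- up$net; state <- up$state
      losses <- c(losses, ls$loss)
    }
    vd <- NA_real_
    if (!is.null(xval) && dim(xval)[4] > 0) {
      pv <- unet_forward(net, xval, cfg, want_cache = FALSE)$probs
      vd <- mean(vapply(seq_len(dim(xval)[4]), function(i)
        diceCoef((pv[, , 1, i] >= 0.5) + 0, yval[, , 1, i]), 0))
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   valDice = vd))
    if (verbose && (ep %% 10 == 0 || ep == 1))
      message(sprintf("epoch %3d  loss %.4f  val Dice %s", ep, mean(losses),
                      ifelse(is.na(vd), "-", sprintf("%.4f", vd))))
  }
  new("UnetModel", layers = net, config = cfg, history = hist,
      maskKind = maskKind)
}

# Load manifest rows into (H, W, 1, n) arrays of normalized images and masks.
load_tensor <- function(manifest, dir, idx, maskCol, cfg) {
  s <- cfg@inputSize
  n <- length(idx)
  x <- array(0, c(s, s, 1, n))
  y <- array(0, c(s, s, 1, n))
  for (k in seq_len(n)) {
    i <- idx[k]
    img <- readImagePNG(file.path(dir, manifest$image[i]))
    msk <- readMaskPNG(file.path(dir, manifest[[maskCol]][i]))
    rp <- resizePair(img, msk, c(s, s))
    x[, , 1, k] <- normalizeImage(rp$image)
    y[, , 1, k] <- maskMatrix(rp$mask)
  }
  list(x = x, y = y)
}

#' Train a U-net on a dataset manifest
#'
#' Reads images and the chosen mask kind from disk, resizes to the
#' configured input size, normalizes each image to zero mean and unit sd,
#' and fits the U-net with negative-Dice loss and Adam. Weight
#' initialization, data splitting and shuffling all derive from the config
#' seed, so two runs with the same seed produce the same model.
#'
#' @param manifest manifest data.frame or path to manifest.csv.
#' @param maskKind which masks to train on: "et", "ha" or "truth".
#' @param cfg a \linkS4class{TrainConfig}.
#' @param dir directory the manifest paths are relative to (defaults to the
#'   manifest's directory when a path is given).
#' @param split optional list with \code{train} and \code{val} indices (as
#'   from \code{\link{splitDataset}}); computed from cfg when omitted.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{UnetModel}.
#' @export
trainUnet <- function(manifest, maskKind = c("et", "ha", "truth"),
                      cfg = trainConfig(), dir = NULL, split = NULL,
                      verbose = FALSE) {
  maskKind <- match.arg(maskKind)
  if (is.character(manifest)) {
    if (is.null(dir)) dir <- dirname(manifest)
    manifest <- read.csv(manifest, check.names = FALSE)
  }
  if (is.null(dir)) dir <- "."
  if (is.null(split)) split <- splitDataset(manifest, cfg)
  maskCol <- paste0(maskKind, "_mask")
  if (identical(maskKind, "truth")) maskCol <- "truth_mask"
  if (!maskCol %in% names(manifest))
    stop("manifest has no column ", maskCol)
  tr <- load_tensor(manifest, dir, split$train, maskCol, cfg)
  va <- if (length(split$val))
    load_tensor(manifest, dir, split$val, maskCol, cfg) else NULL
  fit_unet(tr$x, tr$y, cfg,
           xval = if (is.null(va)) NULL else va$x,
           yval = if (is.null(va)) NULL else va$y,
           maskKind = maskKind, verbose = verbose)
}

#' Predict probability maps for a set of images
#'
#' Images are resized to the model's input size and normalized exactly as
#' during training; the raw probability maps are returned with no size
#' thresholding (cluster filtering belongs to the evaluation stage).
#'
#' @param model a \linkS4class{UnetModel}.
#' @param images list of grayscale matrices in [0,1] (or a single matrix).
#' @return list of probability matrices in [0,1].
#' @export
predictUnet <- function(model, images) {
  if (is.matrix(images)) images <- list(images)
  cfg <- model@config
  s <- cfg@inputSize
  n <- length(images)
  x <- array(0, c(s, s, 1, n))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!identical(dim(img), c(s, s)))
      img <- as.matrix(EBImage::resize(img, w = s, h = s))
    x[, , 1, i] <- normalizeImage(img)
  }
  out <- vector("list", n)
  for (b0 in seq(1, n, by = 8)) {
    idx <- b0:min(b0 + 7, n)
    p <- unet_forward(model@layers, x[, , , idx, drop = FALSE], cfg,
                      want_cache = FALSE)$probs
    for (k in seq_along(idx)) out[[idx[k]]] <- p[, , 1, k]
  }
  out
}
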