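# Model adapters: the contract between the synthesis/analysis code and any
# convolutional network. Built-ins: a toy identity/negation adapter for exact
# arithmetic tests and a seeded random CNN (valid convolutions, stride 2,
# leaky-ReLU) whose forward and backward passes are implemented here so the
# whole pipeline runs offline on CPU. Further backends (e.g. a pretrained
# Inception-V1 exposed from an external runtime) plug in through
# registerAdapter() with the same contract.

.adapterRegistry <- new.env(parent = emptyenv())

#' Register a model adapter factory
#'
#' @param name registry key.
#' @param factory `function(...)` returning a [ModelAdapter-class].
#' @return Invisibly, `name`.
#' @export
registerAdapter <- function(name, factory) {
  stopifnot(is.character(name), is.function(factory))
  assign(name, factory, envir = .adapterRegistry)
  invisible(name)
}

#' Instantiate a registered adapter
#'
#' @param name registry key (see [listAdapters()]).
#' @param ... passed to the registered factory.
#' @return A [ModelAdapter-class].
#' @export
getAdapter <- function(name, ...) {
  if (!exists(name, envir = .adapterRegistry))
    stop("unknown adapter '", name, "'; registered: ",
         paste(listAdapters(), collapse = ", "))
  get(name, envir = .adapterRegistry)(...)
}

#' List registered adapter names
#' @return character vector.
#' @export
listAdapters <- function() sort(ls(.adapterRegistry))

#' Toy adapter: identity and negation layers
#'
#' A two-layer "network" whose first layer returns the flattened pixels and
#' whose second returns their negation. Gradients are exact; used for
#' arithmetic tests of the activation/gradient contract.
#'
#' @param inputDim input dimensions `c(h, w, 3)`.
#' @return A [ModelAdapter-class].
#' @export
toyAdapter <- function(inputDim = c(4L, 4L, 3L)) {
  inputDim <- as.integer(inputDim)
  nUnits <- prod(inputDim)
  flat <- function(px) {
    n <- dim(px)[1]
    matrix(px, nrow = n)   # row i = image i flattened (h,w,c column-major)
  }
  modelAdapter(
    layerIds = c("identity", "negation"),
    activationFn = function(px) {
      f <- flat(px)
      list(identity = f, negation = -f)
    },
    gradientFn = function(px, gradActs) {
      n <- dim(px)[1]
      g <- matrix(0, n, nUnits)
      if (!is.null(gradActs[["identity"]])) g <- g + gradActs[["identity"]]
      if (!is.null(gradActs[["negation"]])) g <- g - gradActs[["negation"]]
      array(g, dim = dim(px))
    },
    inputDim = inputDim,
    channels = list(identity = list(), negation = list()))
}

# im2col index table for one valid-convolution layer: rows are output
# positions (column-major over the output grid), columns are patch elements
# ordered column-major over (k, k, c_in); entries are linear indices into the
# input array (h, w, c_in), column-major.
.convIndex <- function(h, w, cin, k, stride) {
  if (h < k || w < k)
    stop("input (", h, "x", w, ") smaller than the ", k, "x", k,
         " kernel; use fewer stages or a larger input")
  oh <- (h - k) %/% stride + 1L
  ow <- (w - k) %/% stride + 1L
  pos <- expand.grid(xx = seq_len(oh), yy = seq_len(ow))
  pat <- expand.grid(dx = seq_len(k), dy = seq_len(k), ci = seq_len(cin))
  rowIdx <- outer((pos$xx - 1L) * stride, pat$dx, `+`)          # npos x q
  colIdx <- outer((pos$yy - 1L) * stride, pat$dy, `+`)
  ciIdx <- matrix(pat$ci, nrow(rowIdx), ncol(rowIdx), byrow = TRUE)
  idx <- rowIdx + (colIdx - 1L) * h + (ciIdx - 1L) * (h * w)
  list(idx = idx, oh = oh, ow = ow)
}

#' Seeded random CNN adapter
#'
#' A small convolutional network with randomly initialized (He-scaled,
#' seed-reproducible) weights: valid 3x3 convolutions with stride 2 and
#' leaky-ReLU nonlinearities. Exposes one layer per convolution stage, with
#' activations flattened channel-major (each channel's spatial map
#' contiguous). The leaky slope keeps gradients alive everywhere so pixel
#' optimization never stalls on dead units. Both the activation pass and the
#' vector-Jacobian backward pass run in plain R on CPU.
#'
#' @param inputSize spatial input size `c(h, w)` (RGB assumed), default 64x64.
#' @param channels output channels per stage, default `c(8, 16, 16)`.
#' @param kernel kernel size (default 3).
#' @param stride stride (default 2).
#' @param seed weight seed.
#' @param leak leaky-ReLU negative slope (default 0.1).
#' @return A [ModelAdapter-class] with layers `conv1, conv2, ...` and
#'   per-layer channel unit-index metadata.
#' @export
randomCNNAdapter <- function(inputSize = c(64L, 64L), channels = c(8L, 16L, 16L),
                             kernel = 3L, stride = 2L, seed = 1L, leak = 0.1) {
  h <- as.integer(inputSize[1]); w <- as.integer(inputSize[2])
  L <- length(channels)
  layerIds <- paste0("conv", seq_len(L))
  dims <- vector("list", L)  # geometry per layer
  W <- vector("list", L)
  cin <- 3L; hh <- h; ww <- w
  withSeed(seed, {
    for (l in seq_len(L)) {
      geo <- .convIndex(hh, ww, cin, kernel, stride)
      q <- kernel * kernel * cin
      W[[l]] <- matrix(stats::rnorm(q * channels[l], sd = sqrt(2 / q)),
                       q, channels[l])
      dims[[l]] <- list(idx = geo$idx, npos = geo$oh * geo$ow,
                        inLen = hh * ww * cin, cout = channels[l])
      hh <- geo$oh; ww <- geo$ow; cin <- as.integer(channels[l])
    }
  })
  lrelu <- function(z) ifelse(z > 0, z, leak * z)
  lreluGrad <- function(z) ifelse(z > 0, 1, leak)

  forwardOne <- function(x) {   # x: flat input vector; returns acts + caches
    acts <- vector("list", L); zs <- vector("list", L)
    for (l in seq_len(L)) {
      P <- matrix(x[dims[[l]]$idx], nrow = dims[[l]]$npos)
      Z <- P %*% W[[l]]
      A <- lrelu(Z)
      zs[[l]] <- Z
      acts[[l]] <- as.vector(A)   # npos x cout column-major = channel-major
      x <- acts[[l]]
    }
    list(acts = acts, zs = zs)
  }

  backwardOne <- function(fw, gradActs) {  # gradActs: list of unit-grad vectors
    gUp <- NULL   # gradient flowing into layer l's activations from above
    for (l in rev(seq_len(L))) {
      g <- gradActs[[l]] %||% 0
      if (!is.null(gUp)) g <- g + gUp
      if (all(g == 0) && l > 1L) { gUp <- 0; next }
      dZ <- matrix(g, nrow = dims[[l]]$npos) * lreluGrad(fw$zs[[l]])
      dP <- dZ %*% t(W[[l]])
      gin <- numeric(dims[[l]]$inLen)
      rs <- rowsum(as.vector(dP), group = as.vector(dims[[l]]$idx))
      gin[as.integer(rownames(rs))] <- rs[, 1]
      gUp <- gin
    }
    gUp
  }

  activationFn <- function(px) {
    n <- dim(px)[1]
    out <- lapply(seq_len(L), function(l)
      matrix(0, n, dims[[l]]$npos * dims[[l]]$cout))
    names(out) <- layerIds
    for (i in seq_len(n)) {
      fw <- forwardOne(as.vector(px[i, , , ]))
      for (l in seq_len(L)) out[[l]][i, ] <- fw$acts[[l]]
    }
    out
  }

  gradientFn <- function(px, gradActs) {
    n <- dim(px)[1]
    g <- array(0, dim = dim(px))
    for (i in seq_len(n)) {
      fw <- forwardOne(as.vector(px[i, , , ]))
      gi <- lapply(seq_len(L), function(l) {
        ga <- gradActs[[layerIds[l]]]
        if (is.null(ga)) NULL else ga[i, ]
      })
      g[i, , , ] <- array(backwardOne(fw, gi), dim = dim(px)[2:4])
    }
    g
  }

  chans <- lapply(seq_len(L), function(l) {
    npos <- dims[[l]]$npos
    lapply(seq_len(dims[[l]]$cout), function(ch)
      seq.int((ch - 1L) * npos + 1L, ch * npos))
  })
  names(chans) <- layerIds

  modelAdapter(layerIds, activationFn, gradientFn,
               inputDim = c(h, w, 3L), channels = chans)
}

registerAdapter("toy", toyAdapter)
registerAdapter("random_cnn", randomCNNAdapter)
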