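layerDesc <- function(type, ...) c(list(type = type), list(...))

#' Build the dense (fully connected) global classifier
#'
#' Flatten(edge^3) -> dense 1000 (ReLU) -> dense 100 (ReLU) -> dense 3
#' (softmax over high/medium/low). The published widths are the defaults;
#' \code{hidden} allows desk-scale variants without changing the topology.
#'
#' @param inputEdge cubic input edge in voxels (default 64; >= 2).
#' @param hidden widths of the two hidden layers.
#' @return A \linkS4class{NetworkSpec}.
#' @examples
#' countParams(buildDNN(64))  # 262,245,403
#' @export
buildDNN <- function(inputEdge = 64, hidden = c(1000, 100)) {
  if (inputEdge < 2) stop("input edge must be >= 2")
  layers <- list(
    layerDesc("flatten"),
    layerDesc("dense", units = hidden[1], activation = "relu"),
    layerDesc("dense", units = hidden[2], activation = "relu"),
    layerDesc("dense", units = 3L, activation = "softmax"))
  new("NetworkSpec", architecture = "dnn", inputEdge = as.integer(inputEdge),
      inputChannels = 1L, layers = layers, nClasses = 3L)
}

#' Build the 3D convolutional global classifier
#'
#' conv(32 filters, 7^3, ELU) -> maxpool/2 -> conv(64, 5^3, ELU) ->
#' maxpool/2 -> conv(128, 5^3, ReLU) -> maxpool/2 -> dense 1024 (tanh,
#' dropout 0.4) -> dense 3 (softmax). Convolutions use zero ("same")
#' padding, so spatial dimensions are preserved through each conv and
#' halved only by the three pools; the input edge must be divisible by 8.
#'
#' @param inputEdge cubic input edge in voxels (default 64).
#' @param filters filter counts for the three convolutional layers.
#' @param denseUnits width of the dense layer (default 1024).
#' @return A \linkS4class{NetworkSpec}.
#' @export
buildCNN3D <- function(inputEdge = 64, filters = c(32, 64, 128),
                       denseUnits = 1024) {
  if (inputEdge %% 8 != 0)
    stop("input edge must be divisible by 8 (three 2x poolings)")
  layers <- list(
    layerDesc("conv3", filters = filters[1], kernel = 7L,
              activation = "elu"),
    layerDesc("pool3"),
    layerDesc("conv3", filters = filters[2], kernel = 5L,
              activation = "elu"),
    layerDesc("pool3"),
    layerDesc("conv3", filters = filters[3], kernel = 5L,
              activation = "relu"),
    layerDesc("pool3"),
    layerDesc("flatten"),
    layerDesc("dense", units = denseUnits, activation = "tanh",
              dropout = 0.4),
    layerDesc("dense", units = 3L, activation = "softmax"))
  new("NetworkSpec", architecture = "cnn3d",
      inputEdge = as.integer(inputEdge), inputChannels = 1L,
      layers = layers, nClasses = 3L)
}

#' Build the 3D U-Net voxel-wise classifier
#'
#' Four encoder levels (two 3^3 ReLU convolutions, channel-wise spatial
#' dropout 0.5, 2x max-pool; filters 64/128/256/512 by default), a root
#' with 1024 filters plus dropout, and four decoder levels (nearest
#' neighbour 2x upsampling, a 2^3 convolution, concatenation with the
#' matching encoder level's dropout output, two 3^3 convolutions). A final
#' 1^3 convolution maps to ten channels with a per-voxel softmax. All
#' convolutions use "same" padding and He initialization.
#'
#' @param inputEdge cubic patch edge; a power of two >= 16 (default 16, at
#'   which the root spatial size is 1^3).
#' @param baseFilters filters at the first level (default 64); deeper
#'   levels double it.
#' @return A \linkS4class{NetworkSpec}.
#' @export
buildUNet3D <- function(inputEdge = 16, baseFilters = 64) {
  if (inputEdge < 16 || bitwAnd(inputEdge, inputEdge - 1L) != 0)
    stop("input edge must be a power of two >= 16 (four 2x poolings)")
  b <- baseFilters
  layers <- list()
  for (l in 0:3) {
    f <- b * 2^l
    layers <- c(layers, list(
      layerDesc("conv3", filters = f, kernel = 3L, activation = "relu"),
      layerDesc("conv3", filters = f, kernel = 3L, activation = "relu"),
      layerDesc("sdrop", rate = 0.5, tag = paste0("enc", l)),
      layerDesc("pool3")))
  }
  layers <- c(layers, list(
    layerDesc("conv3", filters = b * 16, kernel = 3L, activation = "relu"),
    layerDesc("conv3", filters = b * 16, kernel = 3L, activation = "relu"),
    layerDesc("sdrop", rate = 0.5)))
  for (l in 3:0) {
    f <- b * 2^l
    layers <- c(layers, list(
      layerDesc("upsample3"),
      layerDesc("conv3", filters = f, kernel = 2L, activation = "relu"),
      layerDesc("concat", skip = paste0("enc", l)),
      layerDesc("conv3", filters = f, kernel = 3L, activation = "relu"),
      layerDesc("conv3", filters = f, kernel = 3L, activation = "relu")))
  }
  layers <- c(layers, list(
    layerDesc("conv3", filters = 10L, kernel = 1L, activation = "softmax")))
  new("NetworkSpec", architecture = "unet3d",
      inputEdge = as.integer(inputEdge), inputChannels = 1L,
      layers = layers, nClasses = 10L)
}

#' Per-layer output shapes of a network
#'
#' Derives every layer's output shape from the architecture description
#' alone (no weights allocated). Volumetric shapes are
#' \code{c(channels, edge)}; flattened shapes are \code{c(units)}.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return list with one shape per layer (plus attribute \code{input}).
#' @export
inferShapes <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  shapes <- vector("list", length(spec@layers))
  cur <- list(kind = "vol", channels = spec@inputChannels,
              edge = spec@inputEdge)
  tags <- list()
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    cur <- switch(ly$type,
      flatten = list(kind = "vec",
                     units = cur$channels * cur$edge^3),
      dense = list(kind = "vec", units = ly$units,
                   fanIn = cur$units),
      conv3 = list(kind = "vol", channels = ly$filters, edge = cur$edge,
                   fanIn = cur$channels * ly$kernel^3),
      pool3 = {
        if (cur$edge < 2) stop("volume too small to pool at layer ", i)
        list(kind = "vol", channels = cur$channels, edge = cur$edge %/% 2L)
      },
      upsample3 = list(kind = "vol", channels = cur$channels,
                       edge = cur$edge * 2L),
      sdrop = cur,
      concat = {
        skip <- tags[[ly$skip]]
        if (skip$edge != cur$edge)
          stop("concat spatial mismatch at layer ", i)
        list(kind = "vol", channels = cur$channels + skip$channels,
             edge = cur$edge)
      },
      stop("unknown layer type: ", ly$type))
    if (!is.null(ly$tag)) tags[[ly$tag]] <- cur
    shapes[[i]] <- cur
  }
  shapes
}

#' Trainable-parameter count of a network
#'
#' Closed-form count from the architecture description: each dense layer
#' contributes \code{units * fanIn + units}, each convolution
#' \code{filters * (channelsIn * kernel^3) + filters}.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return total number of trainable parameters (numeric, to stay exact
#'   beyond 32-bit range).
#' @export
countParams <- function(spec) {
  shapes <- inferShapes(spec)
  tot <- 0
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    if (ly$type %in% c("dense", "conv3")) {
      sh <- shapes[[i]]
      n <- if (ly$type == "dense") sh$units else ly$filters
      tot <- tot + n * sh$fanIn + n
    }
  }
  tot
}
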