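# The two classifiers.
#
# Skeleton branch: a spatiotemporal graph convolutional network (ST-GCN)
# alternating graph convolutions over the 25-joint skeletal edges with
# temporal convolutions over the frame axis, optional learned per-joint
# attention, and a softmax head. Pressure branch: a residual CNN of the
# ResNet-18 family (4 stages x 2 blocks by default) on 1-channel images.

#' Normalized adjacency matrices for the skeletal graph
#'
#' Builds `D^(-1/2) (A_s + I_s) D^(-1/2)` per partition subset `s`:
#' \describe{
#'   \item{uniform}{one subset containing all edges plus self-loops;}
#'   \item{distance}{self-loops and neighbors as two subsets;}
#'   \item{spatial}{spatial-configuration partitioning: self, centripetal
#'     (neighbor closer to the sacrum root), centrifugal (farther).}
#' }
#' Rows/columns with no connections in a subset normalize to zero.
#'
#' @param graph A connected [joint_graph()].
#' @param strategy Partitioning strategy.
#' @return List of V x V matrices (one per subset).
#' @export
build_adjacency <- function(graph, strategy = c("spatial", "uniform", "distance")) {
  strategy <- match.arg(strategy)
  if (!graph_is_connected_tree(graph)) {
    # allow general connected graphs too, but reject disconnected ones
    n <- graph$node_count
    A <- matrix(0, n, n)
    A[graph$edges + 1L] <- 1; A[graph$edges[, 2:1, drop = FALSE] + 1L] <- 1
    reach <- (diag(n) + A)
    for (k in seq_len(ceiling(log2(n)) + 1)) reach <- sign(reach %*% reach)
    if (any(reach[1, ] == 0)) {
      sg_abort("graph is disconnected", "sarcogait_invalid_input")
    }
  }
  n <- graph$node_count
  A <- matrix(0, n, n)
  A[graph$edges + 1L] <- 1
  A[graph$edges[, 2:1, drop = FALSE] + 1L] <- 1
  norm_sub <- function(M) {
    # D^(-1/2) M D^(-1/2); for asymmetric subsets (centripetal/centrifugal)
    # the left factor uses row degrees and the right column degrees so no
    # existing edge is annihilated by a zero-degree counterpart row
    dr <- rowSums(M); dc <- colSums(M)
    ir <- ifelse(dr > 0, 1 / sqrt(dr), 0)
    ic <- ifelse(dc > 0, 1 / sqrt(dc), 0)
    M * outer(ir, ic)
  }
  subsets <- switch(strategy,
    uniform = list(A + diag(n)),
    distance = list(diag(n), A),
    spatial = {
      d <- hop_distance_from(graph, 0L)
      centri <- matrix(0, n, n)
      centrifu <- matrix(0, n, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (A[i, j] == 1) {
          if (d[j] < d[i]) centri[i, j] <- 1 else centrifu[i, j] <- 1
        }
      }
      list(diag(n), centri, centrifu)
    })
  lapply(subsets, norm_sub)
}

# ---- ST-GCN -----------------------------------------------------------------

#' ST-GCN configuration
#'
#' @param block_channels Output widths of the graph blocks. Default is the
#'   full profile (64, 128, 256); `stgcn_config_desk()` gives the reduced
#'   2-block profile (32, 64) used for desk-scale experiments at T = 60.
#' @param temporal_kernel Odd temporal kernel size (frames).
#' @param temporal_strides Per-block temporal strides; default 1 for the
#'   first block, 2 afterwards.
#' @param input_branches Any of `"position"`, `"velocity"`, `"bone"`;
#'   branches are concatenated channel-wise (3 channels each) at the input.
#' @param attention_enabled Learned per-joint softmax attention mask.
#' @param partition_strategy See [build_adjacency()].
#' @param num_classes Number of output classes (2).
#' @param residual,input_bn Architecture toggles (residual shortcuts from
#'   the second block on; batch norm on the raw input features).
#' @return A config list.
#' @export
stgcn_config <- function(block_channels = c(64, 128, 256),
                         temporal_kernel = 9,
                         temporal_strides = NULL,
                         input_branches = "position",
                         attention_enabled = TRUE,
                         partition_strategy = "spatial",
                         num_classes = 2,
                         residual = TRUE,
                         input_bn = TRUE) {
  sg_assert(length(input_branches) >= 1 &&
              all(input_branches %in% c("position", "velocity", "bone")),
            "input_branches must be a non-empty subset of position/velocity/bone")
  sg_assert(temporal_kernel %% 2 == 1, "temporal kernel must be odd")
  if (is.null(temporal_strides)) {
    temporal_strides <- c(1, rep(2, length(block_channels) - 1))
  }
  sg_assert(length(temporal_strides) == length(block_channels),
            "one temporal stride per block")
  list(kind = "stgcn", block_channels = block_channels,
       temporal_kernel = temporal_kernel, temporal_strides = temporal_strides,
       input_branches = input_branches, attention_enabled = attention_enabled,
       partition_strategy = partition_strategy, num_classes = num_classes,
       residual = residual, input_bn = input_bn)
}

#' @rdname stgcn_config
#' @export
stgcn_config_desk <- function(...) {
  stgcn_config(block_channels = c(32, 64), ...)
}

#' Build an ST-GCN model
#'
#' @param config From [stgcn_config()].
#' @param graph A [joint_graph()] (or `adjacency` to override directly).
#' @param adjacency Optional list of V x V matrices replacing
#'   [build_adjacency()] output (used e.g. for identity-adjacency checks).
#' @param seed Integer seed controlling weight initialization.
#' @return A `sarcogait_model` object.
#' @export
build_stgcn <- function(config = stgcn_config(), graph = joint_graph(),
                        adjacency = NULL, seed = 0) {
  A_list <- adjacency %||% build_adjacency(graph, config$partition_strategy)
  V <- nrow(A_list[[1]])
  c_in <- 3 * length(config$input_branches)
  with_seed(derive_seed(seed, "stgcn-init"), {
    layers <- list()
    if (config$input_bn) layers <- c(layers, list(bn_layer(c_in)))
    prev <- c_in
    for (i in seq_along(config$block_channels)) {
      w <- config$block_channels[i]
      s <- config$temporal_strides[i]
      main <- sequential_layer(list(
        gconv_layer(prev, w, A_list),
        bn_layer(w),
        relu_layer(),
        tconv_layer(w, w, k = config$temporal_kernel, stride = s),
        bn_layer(w)
      ))
      use_res <- config$residual && i > 1
      blk <- if (use_res) {
        shortcut <- if (prev == w && s == 1) NULL else {
          sequential_layer(list(
            tconv_layer(prev, w, k = 1, stride = s),
            bn_layer(w)
          ))
        }
        residual_layer(main, shortcut)
      } else {
        sequential_layer(list(main, relu_layer()))
      }
      layers <- c(layers, list(blk))
      prev <- w
    }
    attn <- NULL
    if (config$attention_enabled) {
      attn <- attention_layer(V)
      layers <- c(layers, list(attn))
    }
    layers <- c(layers, list(gap_tv_layer(), dense_layer(prev, config$num_classes)))
    root <- sequential_layer(layers)
    structure(list(root = root, config = config, attn = attn,
                   # datasets carry (C, T, V, N); the network runs (C, T, N, V)
                   # so the joint mix is a single GEMM
                   to_internal = function(x) aperm(x, c(1, 2, 4, 3)),
                   c_in = c_in),
              class = "sarcogait_model")
  })
}

#' Forward pass of the ST-GCN
#'
#' @param model From [build_stgcn()].
#' @param batch N x C x T x V array (C = 3 x number of enabled branches,
#'   T at least the temporal kernel size).
#' @return N x 2 matrix of class probabilities (rows sum to 1), columns
#'   `normal`, `sarcopenia`.
#' @export
stgcn_forward <- function(model, batch) {
  sg_assert(inherits(model, "sarcogait_model") && model$config$kind == "stgcn",
            "model must be a built ST-GCN")
  d <- dim(batch)
  if (length(d) != 4 || d[2] != model$c_in) {
    sg_abort(sprintf("expected N x %d x T x V input, got %s",
                     model$c_in, paste(d, collapse = " x ")),
             "sarcogait_shape_error")
  }
  sg_assert(d[3] >= model$config$temporal_kernel,
            "T must be at least the temporal kernel size")
  x <- aperm(batch, c(2, 3, 1, 4))        # (N,C,T,V) -> (C,T,N,V)
  logits <- model$root$forward(x, train = FALSE)
  t(softmax_cols(logits))
}

#' Attention weights over the joints
#'
#' Softmax-normalized (non-negative, sum to 1 over the V joints); `NULL`
#' when the model was built without attention.
#'
#' @param model A `sarcogait_model` from [build_stgcn()].
#' @export
attention_weights <- function(model) {
  if (is.null(model$attn)) return(NULL)
  attention_weights_of(model$attn)
}

# ---- residual CNN -----------------------------------------------------------

#' Residual CNN configuration
#'
#' Defaults give the ResNet-18 shape: a 7x7/2 stem with 3x3/2 max pooling,
#' then 4 stages of 2 residual blocks with widths (64, 128, 256, 512), global
#' average pooling and a 2-way softmax head. The first convolution accepts
#' the single pressure channel directly. `cnn_config_desk()` is the reduced
#' profile (2 stages, widths 8/16, 3x3/2 stem, no pool) for 64 x 64 inputs.
#'
#' @param stage_widths Channel widths per stage.
#' @param blocks_per_stage Residual blocks per stage.
#' @param stem_kernel,stem_stride,stem_pool Stem convolution geometry.
#' @param in_channels Input channels (1 for pressure images).
#' @param num_classes Output classes (2).
#' @param skip_connections Disable to ablate the residual shortcuts.
#' @return A config list.
#' @export
cnn_config <- function(stage_widths = c(64, 128, 256, 512),
                       blocks_per_stage = rep(2, length(stage_widths)),
                       stem_kernel = 7, stem_stride = 2, stem_pool = TRUE,
                       in_channels = 1, num_classes = 2,
                       skip_connections = TRUE) {
  sg_assert(length(blocks_per_stage) == length(stage_widths),
            "one block count per stage")
  list(kind = "cnn", stage_widths = stage_widths,
       blocks_per_stage = blocks_per_stage, stem_kernel = stem_kernel,
       stem_stride = stem_stride, stem_pool = stem_pool,
       in_channels = in_channels, num_classes = num_classes,
       skip_connections = skip_connections)
}

#' @rdname cnn_config
#' @param ... Overrides passed to [cnn_config()].
#' @export
cnn_config_desk <- function(...) {
  cnn_config(stage_widths = c(8, 16), blocks_per_stage = c(2, 2),
             stem_kernel = 3, stem_stride = 2, stem_pool = FALSE, ...)
}

#' Build the residual CNN
#'
#' @param config From [cnn_config()].
#' @param seed Integer seed controlling weight initialization.
#' @return A `sarcogait_model` object.
#' @export
build_cnn <- function(config = cnn_config(), seed = 0) {
  with_seed(derive_seed(seed, "cnn-init"), {
    k <- config$stem_kernel
    layers <- list(
      conv2d_layer(config$in_channels, config$stage_widths[1], kh = k,
                   sh = config$stem_stride, bias = FALSE),
      bn_layer(config$stage_widths[1]),
      relu_layer()
    )
    if (config$stem_pool) layers <- c(layers, list(maxpool_layer(3, sh = 2)))
    prev <- config$stage_widths[1]
    for (s in seq_along(config$stage_widths)) {
      w <- config$stage_widths[s]
      for (b in seq_len(config$blocks_per_stage[s])) {
        stride <- if (s > 1 && b == 1) 2 else 1
        main <- sequential_layer(list(
          conv2d_layer(prev, w, kh = 3, sh = stride, bias = FALSE),
          bn_layer(w),
          relu_layer(),
          conv2d_layer(w, w, kh = 3, sh = 1, bias = FALSE),
          bn_layer(w)
        ))
        blk <- if (config$skip_connections) {
          shortcut <- if (prev == w && stride == 1) NULL else {
            sequential_layer(list(
              conv2d_layer(prev, w, kh = 1, sh = stride, bias = FALSE),
              bn_layer(w)
            ))
          }
          residual_layer(main, shortcut)
        } else {
          sequential_layer(list(main, relu_layer()))
        }
        layers <- c(layers, list(blk))
        prev <- w
      }
    }
    layers <- c(layers, list(gap_layer(), dense_layer(prev, config$num_classes)))
    root <- sequential_layer(layers)
    structure(list(root = root, config = config, attn = NULL,
                   to_internal = NULL, c_in = config$in_channels),
              class = "sarcogait_model")
  })
}

#' Forward pass of the residual CNN
#'
#' @param model From [build_cnn()].
#' @param batch N x C x H x W array (C must match the configured input
#'   channels; 1 for pressure images).
#' @return N x 2 matrix of class probabilities, columns `normal`,
#'   `sarcopenia`.
#' @export
cnn_forward <- function(model, batch) {
  sg_assert(inherits(model, "sarcogait_model") && model$config$kind == "cnn",
            "model must be a built CNN")
  d <- dim(batch)
  if (length(d) != 4 || d[2] != model$c_in) {
    sg_abort(sprintf("expected N x %d x H x W input, got %s",
                     model$c_in, paste(d, collapse = " x ")),
             "sarcogait_shape_error")
  }
  x <- aperm(batch, c(2, 3, 4, 1))
  logits <- model$root$forward(x, train = FALSE)
  t(softmax_cols(logits))
}

#' Save / load a trained model checkpoint
#'
#' Weights, batch-norm statistics and the builder config are stored in a
#' single RDS file; `load_checkpoint` rebuilds the architecture and
#' restores the parameters.
#'
#' @param model A `sarcogait_model`.
#' @param path Checkpoint file path.
#' @param graph Graph used for rebuilding ST-GCN models.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = snapshot_params(model$root)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, graph = joint_graph()) {
  ck <- readRDS(path)
  model <- if (ck$config$kind == "stgcn") {
    build_stgcn(ck$config, graph = graph)
  } else {
    build_cnn(ck$config)
  }
  restore_params(model$root, ck$params)
  model
}
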