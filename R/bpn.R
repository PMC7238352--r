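# Four-class neural-network classifier. One hidden layer whose width follows
# the sizing rule H = floor(O + 0.75 I) capped strictly below 2 I, with O = 4
# output classes; logistic hidden units, softmax outputs, cross-entropy
# fitting. The network's validation accuracy is the GA's fitness.

#' Hidden-layer size rule
#'
#' `H = floor(O + 0.75 I)`, constrained to `H < 2 I`, hence
#' `H = min(floor(O + 0.75 I), 2 I - 1)`. For four output classes this gives
#' `H = 101` at `I = 130`, `H = 38` at `I = 46` and `H = 1` at `I = 1`
#' (where the upper bound binds).
#'
#' @param I input feature count, `>= 1`.
#' @param O output class count (default 4).
#' @return integer hidden-unit count, always `>= 1`.
#' @examples
#' hiddenSize(130)  # 101
#' hiddenSize(46)   # 38
#' hiddenSize(1)    # 1
#' @export
hiddenSize <- function(I, O = 4L) {
  I <- as.integer(I)
  if (any(I < 1L)) stop("I must be >= 1")
  pmax(1L, pmin(as.integer(floor(O + 0.75 * I)), 2L * I - 1L))
}

#' BPN training configuration
#'
#' The fitting hyperparameters: `maxit` optimization iterations and `decay`
#' weight-decay regularization (the optimizer is nnet's quasi-Newton fit of
#' the cross-entropy objective), plus the RNG seed controlling the random
#' weight initialization.
#'
#' @param maxit maximum fitting iterations (default 200).
#' @param decay weight decay (default 1e-3).
#' @param seed RNG seed (default 1).
#' @return list of class `BPNConfig`.
#' @export
bpnConfig <- function(maxit = 200L, decay = 1e-3, seed = 1L) {
  structure(list(maxit = as.integer(maxit), decay = decay,
                 seed = as.integer(seed)), class = "BPNConfig")
}

#' Stratified train/test split
#'
#' Splits a labeled feature table 60/40 (by default) per class, preserving
#' class proportions to within one case; deterministic under `seed`. With
#' 125 cases per class this yields 75 training and 50 test cases per class.
#'
#' @param table data.frame with a `label` column.
#' @param trainFraction fraction allocated to training (default 0.6).
#' @param seed RNG seed.
#' @param classes expected class labels (default `B2 B3 B4 B5`; every class
#'   must be present).
#' @return list with integer row indices `train` and `test`.
#' @export
stratifiedSplit <- function(table, trainFraction = 0.6, seed = 1L,
                            classes = .BIRADS_CLASSES) {
  lab <- as.character(table$label)
  if (!all(classes %in% lab)) stop("every class must be present in the table")
  .withSeed(seed, {
    train <- integer(0)
    for (cl in classes) {
      idx <- which(lab == cl)
      nTrain <- round(length(idx) * trainFraction)
      train <- c(train, sample(idx, nTrain))
    }
    list(train = sort(train), test = sort(setdiff(seq_len(nrow(table)), train)))
  })
}

#' Train the four-class network
#'
#' Fits a single-hidden-layer network (logistic hidden units, softmax
#' output, cross-entropy loss) on normalized features, with the hidden
#' width set by [hiddenSize()] from the input dimension. Deterministic under
#' `cfg$seed`. Inputs are expected in `[0, 1]` (a warning is raised
#' otherwise, since unscaled features dominate the fit).
#'
#' @param x numeric feature matrix (rows = cases) or feature table whose
#'   `f###` columns are used.
#' @param labels factor or character vector of class labels.
#' @param cfg a [bpnConfig()].
#' @param classes class level order.
#' @return list of class `BPNModel` with the fitted net, feature names and
#'   class levels.
#' @export
trainBPN <- function(x, labels, cfg = bpnConfig(), classes = .BIRADS_CLASSES) {
  x <- .asFeatureMatrix(x)
  if (min(x) < -0.01 || max(x) > 1.01)
    warning("features outside [0, 1]: did you forget min-max normalization?")
  y <- factor(as.character(labels), levels = classes)
  if (anyNA(y)) stop("unknown class label")
  H <- hiddenSize(ncol(x), length(classes))
  fit <- .withSeed(cfg$seed,
    nnet::nnet(x, nnet::class.ind(y), size = H, softmax = TRUE,
               maxit = cfg$maxit, decay = cfg$decay, trace = FALSE,
               MaxNWts = 100000L))
  structure(list(net = fit, features = colnames(x), classes = classes,
                 hidden = H), class = "BPNModel")
}

#' @rdname trainBPN
#' @param model a fitted `BPNModel`.
#' @param newdata feature matrix or table to classify.
#' @return `predictBPN()` returns a factor of predicted classes.
#' @export
predictBPN <- function(model, newdata) {
  stopifnot(inherits(model, "BPNModel"))
  x <- .asFeatureMatrix(newdata)
  if (!is.null(model$features) && !is.null(colnames(x)))
    x <- x[, model$features, drop = FALSE]
  p <- predict(model$net, x)
  factor(model$classes[max.col(p, ties.method = "first")], levels = model$classes)
}

.asFeatureMatrix <- function(x) {
  if (is.data.frame(x)) x <- .featureColumns(x)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' GA fitness: validation accuracy of the network on a feature subset
#'
#' Carves an inner stratified 75/25 validation split out of the training
#' table (the held-out test set never informs selection), trains the network
#' on the subset's columns with the hidden width recomputed from the subset
#' size, and returns the validation accuracy in `[0, 1]`. Deterministic per
#' subset: the weight-initialization seed is derived from `cfg$seed` and the
#' subset ids.
#'
#' @param subsetIds integer feature ids (columns `f###` of the table).
#' @param table normalized training feature table with `label` column.
#' @param cfg a [bpnConfig()].
#' @param innerFraction inner training fraction (default 0.75).
#' @param featureCols optional column-name vector; id `i` then refers to
#'   `featureCols[i]` instead of `f00i` (used when feature families are
#'   toggled off and ids are positions among the remaining columns).
#' @return accuracy in `[0, 1]`.
#' @export
gaFitness <- function(subsetIds, table, cfg = bpnConfig(), innerFraction = 0.75,
                      featureCols = NULL) {
  if (length(subsetIds) == 0L) stop("empty feature subset")
  cols <- if (is.null(featureCols)) .featureIds(sort(as.integer(subsetIds)))
          else featureCols[sort(as.integer(subsetIds))]
  sp <- stratifiedSplit(table, trainFraction = innerFraction, seed = cfg$seed)
  if (length(sp$test) == 0L)
    stop("inner validation split is empty; the training table is too small")
  sub <- table[, c("label", cols)]
  subsetSeed <- (cfg$seed + sum(as.integer(subsetIds) * 131L)) %% 2147483647L
  model <- trainBPN(as.matrix(sub[sp$train, cols, drop = FALSE]),
                    sub$label[sp$train],
                    bpnConfig(maxit = cfg$maxit, decay = cfg$decay,
                              seed = as.integer(subsetSeed)))
  pred <- predictBPN(model, as.matrix(sub[sp$test, cols, drop = FALSE]))
  mean(pred == sub$label[sp$test])
}
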