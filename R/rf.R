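#' Random forest classifier (internal engine)
#'
#' A bagged ensemble of CART classification trees with Gini splits and
#' per-node feature subsampling, exposing out-of-bag error (for
#' hyperparameter tuning), vote-share class probabilities (prediction
#' confidence) and total-Gini-decrease variable importance. Categorical
#' predictors (e.g. the sediment class) are one-hot encoded internally and
#' their importance is aggregated back to the parent variable.
#'
#' @param x data.frame of predictors (numeric and factor/character columns).
#' @param y factor response.
#' @param ntree number of trees.
#' @param mtry predictors sampled at each split (on the encoded matrix).
#' @param minnode minimal node size to attempt a split.
#' @param balanced stratify each bootstrap sample to the minority class size
#'   (balanced random forest).
#' @param seed integer seed; forests are deterministic given the seed.
#' @return an object of class `bs_forest` with elements `trees`, `classes`,
#'   `importance` (aggregated, named), `oob_error`, `encoding`.
#' @export
bs_forest <- function(x, y, ntree = 500, mtry = NULL, minnode = 1,
                      balanced = FALSE, seed = 1) {
  stopifnot(is.data.frame(x), nrow(x) == length(y))
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  enc <- .rf_encoding(x)
  X <- .rf_encode(x, enc)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- .rf_fit_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(ntree),
                     as.integer(mtry), as.integer(minnode), balanced,
                     as.double(seed))
  imp <- fit$importance
  agg <- tapply(imp, enc$parent, sum)
  structure(list(trees = fit$trees, classes = levels(y),
                 importance = agg[order(-agg)],
                 oob_error = fit$oob_error,
                 ntree = ntree, mtry = mtry, balanced = balanced,
                 seed = seed, encoding = enc),
            class = "bs_forest")
}

# column encoding plan: numeric columns pass through, factors expand to
# one 0/1 column per level; `parent` maps encoded columns back to inputs
.rf_encoding <- function(x) {
  cols <- list()
  parent <- character(0)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- list(type = "numeric")
      parent <- c(parent, nm)
    } else {
      lev <- sort(unique(as.character(v)))
      cols[[nm]] <- list(type = "factor", levels = lev)
      parent <- c(parent, rep(nm, length(lev)))
    }
  }
  list(cols = cols, parent = parent)
}

.rf_encode <- function(x, enc) {
  mats <- lapply(names(enc$cols), function(nm) {
    spec <- enc$cols[[nm]]
    v <- x[[nm]]
    if (spec$type == "numeric") {
      matrix(as.double(v), ncol = 1)
    } else {
      v <- as.character(v)
      hits <- outer(v, spec$levels, "==")
      hits[is.na(hits)] <- FALSE
      matrix(as.double(hits), length(v), length(spec$levels))
    }
  })
  m <- do.call(cbind, mats)
  storage.mode(m) <- "double"
  m
}

#' Predict from a bs_forest
#'
#' @param object a [bs_forest()] fit.
#' @param newdata data.frame with the training predictor columns.
#' @param type `"class"` for the majority-vote label, `"prob"` for the full
#'   vote-share matrix.
#' @param ... unused.
#' @return factor of predicted classes with attribute `prob` (winning vote
#'   share), or a vote-share matrix.
#' @export
predict.bs_forest <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- .rf_encode(newdata, object$encoding)
  votes <- .rf_predict_cpp(object$trees, X, length(object$classes))
  colnames(votes) <- object$classes
  if (type == "prob") return(votes)
  idx <- max.col(votes, ties.method = "first")
  cls <- factor(object$classes[idx], levels = object$classes)
  attr(cls, "prob") <- votes[cbind(seq_len(nrow(votes)), idx)]
  cls
}

#' @export
print.bs_forest <- function(x, ...) {
  cat(sprintf("<bs_forest> %d trees, mtry %d, %d classes, OOB error %.4f\n",
              x$ntree, x$mtry, length(x$classes), x$oob_error))
  invisible(x)
}
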