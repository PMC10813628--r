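#' Predictive biotope modelling
#'
#' Per-realm (endobenthos/epibenthos) multiclass random-forest models
#' predicting HUB level 4-6 community tokens from per-cell predictors.
#' Stations are attributed to grid cells, predictors sampled at the cell
#' centre and sediment entered as a categorical predictor; slope, PAR and
#' the photic flag enter the epibenthos model only, and the epibenthos model
#' is restricted to hard-substrate-dominant cells. The labelled set is
#' randomly split 70/30 into training and test data; tree count and
#' predictors-per-split are tuned to the lowest out-of-bag error; imbalance
#' corrections touch the training data only; all reported metrics come from
#' the untouched test split.
#'
#' @name biotope-model
NULL

#' Model configuration
#'
#' @param realm `"endo"` or `"epi"`.
#' @param train_fraction training share of the labelled stations.
#' @param ntree_grid,mtry_grid hyperparameter candidate sets; a NULL
#'   `mtry_grid` defaults to `floor(sqrt(p)) + (-1, 0, 1)` for p encoded
#'   predictors.
#' @param imbalance one of `"none"`, `"downsample"`, `"upsample"`,
#'   `"balanced"`, `"smote"`.
#' @param seed integer seed controlling split, tuning and forests.
#' @return list of class `model_config`.
#' @export
model_config <- function(realm = c("endo", "epi"), train_fraction = 0.70,
                         ntree_grid = c(250, 500, 1000), mtry_grid = NULL,
                         imbalance = c("none", "downsample", "upsample",
                                       "balanced", "smote"),
                         seed = 1) {
  realm <- match.arg(realm)
  imbalance <- match.arg(imbalance)
  stopifnot(train_fraction > 0, train_fraction < 1, length(ntree_grid) >= 1)
  structure(list(realm = realm, train_fraction = train_fraction,
                 ntree_grid = ntree_grid, mtry_grid = mtry_grid,
                 imbalance = imbalance, seed = seed),
            class = "model_config")
}

# predictor layers per realm: slope/PAR/photic are epibenthos-only
.realm_layers <- function(realm, layer_names) {
  epi_only <- c("slope", "par")
  if (realm == "endo") setdiff(layer_names, epi_only) else layer_names
}

#' Build the per-station feature matrix for one realm
#'
#' One row per labelled station; predictor values are taken from the cell
#' containing the station (values being per-cell, this equals centre-point
#' sampling); sediment enters as a categorical column. For the epibenthos
#' realm only stations on hard-substrate-dominant cells are retained, and
#' the photic flag is added. Stations outside the grid or excluded by the
#' conventions are dropped (counts in attribute `n_dropped`).
#'
#' @param stations data.frame with `station_id`, `row`, `col` (or `x`, `y`),
#'   and a label column.
#' @param labels character vector of harmonised labels (parallel to
#'   `stations`), or the name of a label column.
#' @param env environment stack from [generate_environment()] (or any list
#'   with `geom`, `layers`, `photic`).
#' @param sediment character matrix of sediment classes.
#' @param realm `"endo"` or `"epi"`.
#' @param hard optional logical matrix of hard-substrate dominance (required
#'   for the epi realm).
#' @return list with `x` (data.frame), `y` (factor), `cells` (row/col per
#'   retained station).
#' @export
build_feature_matrix <- function(stations, labels, env, sediment,
                                 realm = c("endo", "epi"), hard = NULL) {
  realm <- match.arg(realm)
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% names(stations)) {
    labels <- stations[[labels]]
  }
  stopifnot(length(labels) == nrow(stations))
  if (!all(c("row", "col") %in% names(stations))) {
    loc <- locate_cells(env$geom, stations$x, stations$y)
    stations$row <- loc$row
    stations$col <- loc$col
  }
  keep <- !is.na(stations$row) & !is.na(labels)
  n_outside <- sum(is.na(stations$row))
  if (realm == "epi") {
    if (is.null(hard)) stop("epi realm requires a hard-substrate matrix",
                            call. = FALSE)
    on_hard <- !is.na(stations$row) &
      hard[cbind(stations$row, stations$col)]
    keep <- keep & on_hard
  }
  st <- stations[keep, , drop = FALSE]
  ij <- cbind(st$row, st$col)
  lay <- .realm_layers(realm, names(env$layers))
  x <- as.data.frame(lapply(env$layers[lay], function(m) m[ij]))
  x$sediment <- as.character(sediment[ij])
  if (realm == "epi") x$photic <- as.numeric(env$photic[ij])
  if (nrow(st) == 0) {
    y <- factor(character(0))
  } else {
    y <- factor(labels[keep])
  }
  structure(list(x = x, y = y, cells = data.frame(row = st$row,
                                                  col = st$col)),
            n_dropped = sum(!keep), n_outside = n_outside)
}

# ---- imbalance corrections (training data only) -------------------------

.resample_train <- function(x, y, how, seed) {
  set.seed(seed)
  if (how %in% c("none", "balanced")) return(list(x = x, y = y))
  tab <- table(y)
  target <- switch(how, downsample = min(tab), upsample = max(tab),
                   smote = max(tab))
  idx <- integer(0)
  extra_x <- NULL
  extra_y <- character(0)
  for (cls in names(tab)) {
    rows <- which(y == cls)
    if (how == "downsample") {
      idx <- c(idx, sample(rows, target))
    } else if (how == "upsample") {
      idx <- c(idx, rows, sample(rows, target - length(rows),
                                 replace = TRUE))
    } else {  # smote
      idx <- c(idx, rows)
      need <- target - length(rows)
      if (need > 0) {
        syn <- .smote_synthesise(x[rows, , drop = FALSE], need, k = 5)
        extra_x <- rbind(extra_x, syn)
        extra_y <- c(extra_y, rep(cls, need))
      }
    }
  }
  x2 <- x[idx, , drop = FALSE]
  y2 <- as.character(y)[idx]
  if (!is.null(extra_x)) {
    x2 <- rbind(x2, extra_x)
    y2 <- c(y2, extra_y)
  }
  list(x = x2, y = factor(y2, levels = levels(y)))
}

# SMOTE with k nearest neighbours: continuous columns are interpolated,
# categorical columns take the majority value among the neighbours
.smote_synthesise <- function(x, n_new, k = 5) {
  num_cols <- vapply(x, is.numeric, logical(1))
  xm <- as.matrix(x[, num_cols, drop = FALSE])
  sds <- apply(xm, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  xs <- sweep(xm, 2, sds, "/")
  n <- nrow(x)
  k <- min(k, n - 1)
  out <- x[rep(1L, n_new), , drop = FALSE]
  for (s in seq_len(n_new)) {
    i <- sample.int(n, 1)
    if (k < 1) {
      out[s, ] <- x[i, ]
      next
    }
    d <- rowSums(sweep(xs, 2, xs[i, ])^2)
    nb <- order(d)[2:(k + 1)]
    j <- nb[sample.int(length(nb), 1)]
    gap <- stats::runif(1)
    row <- x[i, , drop = FALSE]
    row[num_cols] <- x[i, num_cols] + gap * (x[j, num_cols] - x[i, num_cols])
    for (cc in names(x)[!num_cols]) {
      vals <- as.character(x[nb, cc])
      row[[cc]] <- names(sort(table(vals), decreasing = TRUE))[1]
    }
    out[s, ] <- row
  }
  rownames(out) <- NULL
  out
}

#' Fit a biotope model
#'
#' Splits the labelled data 70/30, tunes `(ntree, mtry)` on out-of-bag error
#' over the configured grids, applies the imbalance strategy to the training
#' split only, refits with the winning pair and evaluates on the untouched
#' test split.
#'
#' @param features list from [build_feature_matrix()] (elements `x`, `y`).
#' @param config a [model_config()].
#' @return object of class `biotope_fit`: `forest`, `confusion`, `accuracy`,
#'   `ci` (95 % Clopper-Pearson), `auc` (Hand-Till), `kappa`, `oob_error`,
#'   `importance`, `hyperparameters`, `split` (train/test indices).
#' @export
fit_biotope_model <- function(features, config = model_config()) {
  x <- features$x
  y <- droplevels(factor(features$y))
  n <- length(y)
  if (nlevels(y) < 2 || any(table(y) < 2)) {
    stop("need at least 2 classes with at least 2 rows each", call. = FALSE)
  }
  set.seed(config$seed)
  n_train <- round(config$train_fraction * n)
  train <- sort(sample.int(n, n_train))
  if (!all(levels(y) %in% unique(y[train]))) {
    # stratified re-split: guarantee every class in the training data
    train <- sort(unlist(lapply(split(seq_len(n), y), function(rows) {
      k <- max(1L, round(config$train_fraction * length(rows)))
      sample(rows, k)
    })))
  }
  test <- setdiff(seq_len(n), train)

  xt <- x[train, , drop = FALSE]
  yt <- droplevels(y[train])
  res <- .resample_train(xt, yt, config$imbalance, config$seed + 7L)

  p_enc <- ncol(.rf_encode(res$x[1, , drop = FALSE],
                           .rf_encoding(res$x)))
  mtry_grid <- config$mtry_grid
  if (is.null(mtry_grid)) {
    m0 <- floor(sqrt(p_enc))
    mtry_grid <- unique(pmax(1L, c(m0 - 1L, m0, m0 + 1L)))
  }
  balanced <- config$imbalance == "balanced"

  grid <- expand.grid(ntree = config$ntree_grid, mtry = mtry_grid)
  oob <- vapply(seq_len(nrow(grid)), function(i) {
    bs_forest(res$x, res$y, ntree = grid$ntree[i], mtry = grid$mtry[i],
              balanced = balanced, seed = config$seed + 13L)$oob_error
  }, numeric(1))
  best <- which.min(oob)
  forest <- bs_forest(res$x, res$y, ntree = grid$ntree[best],
                      mtry = grid$mtry[best], balanced = balanced,
                      seed = config$seed + 13L)

  xe <- x[test, , drop = FALSE]
  ye <- y[test]
  prob <- predict(forest, xe, type = "prob")
  pred <- factor(forest$classes[max.col(prob, ties.method = "first")],
                 levels = levels(y))
  confusion <- table(truth = ye, predicted = pred)
  ev <- evaluate_confusion(confusion)
  auc <- hand_till_auc(prob, ye)

  structure(list(forest = forest, confusion = confusion,
                 accuracy = ev$accuracy, ci = ev$ci, kappa = ev$kappa,
                 auc = auc, oob_error = forest$oob_error,
                 importance = forest$importance,
                 hyperparameters = list(ntree = grid$ntree[best],
                                        mtry = grid$mtry[best],
                                        imbalance = config$imbalance),
                 tuning = cbind(grid, oob = oob),
                 split = list(train = train, test = test),
                 config = config),
            class = "biotope_fit")
}

#' @export
print.biotope_fit <- function(x, ...) {
  cat(sprintf(paste0("<biotope_fit> accuracy %.3f (95%% CI %.3f-%.3f), ",
                     "kappa %.3f, AUC %.3f\n  ntree %d, mtry %d, OOB %.3f\n"),
              x$accuracy, x$ci[1], x$ci[2], x$kappa, x$auc,
              x$hyperparameters$ntree, x$hyperparameters$mtry, x$oob_error))
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Overall accuracy (trace over total), exact binomial 95 % confidence
#' interval (Clopper-Pearson on the correct count), and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with expected agreement from the marginal
#' products. Kappa is NA (with a warning) when chance agreement is 1.
#'
#' @param confusion square confusion matrix (truth in rows).
#' @return list with `accuracy`, `ci` (length 2), `kappa`, `n`.
#' @examples
#' evaluate_confusion(matrix(c(40, 5, 10, 45), 2))  # accuracy 0.85
#' @export
evaluate_confusion <- function(confusion) {
  m <- as.matrix(confusion)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square",
                               call. = FALSE)
  if (any(m < 0)) stop("confusion matrix must be non-negative",
                       call. = FALSE)
  n <- sum(m)
  correct <- sum(diag(m))
  accuracy <- correct / n
  ci <- as.numeric(stats::binom.test(correct, n)$conf.int)
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (1 - p_e < .Machine$double.eps) {
    warning("chance agreement is 1; kappa undefined", call. = FALSE)
    NA_real_
  } else {
    (accuracy - p_e) / (1 - p_e)
  }
  list(accuracy = accuracy, ci = ci, kappa = kappa, n = n)
}

#' Multiclass AUC (Hand-Till mean pairwise AUC)
#'
#' The average over all unordered class pairs (i, j) of
#' `(A(i|j) + A(j|i)) / 2`, where `A(i|j)` is the probability that a random
#' class-i case receives a higher class-i score than a random class-j case
#' (ties count 1/2), computed from the held-out class-probability matrix.
#'
#' @param prob numeric matrix (rows = cases, columns = classes, named).
#' @param truth factor/character of true classes.
#' @return scalar AUC in \[0, 1\]; NA if fewer than 2 classes are present.
#' @export
hand_till_auc <- function(prob, truth) {
  truth <- as.character(truth)
  classes <- intersect(colnames(prob), unique(truth))
  if (length(classes) < 2) return(NA_real_)
  pair_auc <- function(ci, cj) {
    si <- prob[truth == ci, ci]
    sj <- prob[truth == cj, ci]
    r <- rank(c(si, sj))
    ni <- length(si)
    nj <- length(sj)
    (sum(r[seq_len(ni)]) - ni * (ni + 1) / 2) / (ni * nj)
  }
  total <- 0
  npair <- 0
  for (a in seq_along(classes)) {
    for (b in seq_along(classes)) {
      if (a < b) {
        total <- total +
          (pair_auc(classes[a], classes[b]) +
             pair_auc(classes[b], classes[a])) / 2
        npair <- npair + 1
      }
    }
  }
  total / npair
}

#' Predict community tokens over the grid
#'
#' Every cell with complete predictors receives the majority-vote community
#' token and its vote share (prediction probability); cells with any missing
#' predictor, and epi-realm cells outside the hard-substrate mask, are NA.
#'
#' @param fit a [fit_biotope_model()] result (or a bare [bs_forest()]).
#' @param env environment stack.
#' @param sediment sediment class matrix.
#' @param realm `"endo"` or `"epi"`.
#' @param hard logical hard-substrate matrix (epi realm only).
#' @return list with `token` (character matrix) and `probability` (numeric
#'   matrix); a token is present wherever a probability is, and vice versa.
#' @export
predict_grid <- function(fit, env, sediment, realm = c("endo", "epi"),
                         hard = NULL) {
  realm <- match.arg(realm)
  forest <- if (inherits(fit, "biotope_fit")) fit$forest else fit
  g <- env$geom
  nr <- g$nrow
  nc <- g$ncol
  lay <- .realm_layers(realm, names(env$layers))
  x <- as.data.frame(lapply(env$layers[lay], as.vector))
  x$sediment <- as.character(as.vector(sediment))
  if (realm == "epi") x$photic <- as.numeric(as.vector(env$photic))
  complete <- stats::complete.cases(x)
  if (realm == "epi") {
    if (is.null(hard)) stop("epi realm requires a hard-substrate matrix",
                            call. = FALSE)
    complete <- complete & as.vector(hard)
  }
  token <- rep(NA_character_, nr * nc)
  probability <- rep(NA_real_, nr * nc)
  if (any(complete)) {
    cls <- predict(forest, x[complete, , drop = FALSE], type = "class")
    token[complete] <- as.character(cls)
    probability[complete] <- attr(cls, "prob")
  }
  list(token = matrix(token, nr, nc),
       probability = matrix(probability, nr, nc))
}
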