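#' Z-score a color-index feature table
#'
#' Centers and scales each column using the population (n-denominator)
#' standard deviation. Zero-variance columns are dropped with a warning
#' (they carry no correlation information for PCA).
#'
#' @param x numeric matrix or data frame of features (rows = samples).
#' @return list: `z` (matrix), `center`, `scale` (named), `dropped`
#'   (character, possibly empty).
#' @export
ci_standardize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  ctr <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, ctr)^2))  # population sd
  dropped <- colnames(x)[sdp == 0]
  if (length(dropped))
    warning("zero-variance column(s) dropped: ",
            paste(dropped, collapse = ", "))
  keep <- sdp > 0
  z <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, sdp[keep], "/")
  list(z = z, center = ctr[keep], scale = sdp[keep], dropped = dropped)
}

#' Correlation-matrix principal component analysis
#'
#' Eigendecomposition of the feature correlation matrix. Eigenvalues sum to
#' the number of variables; loading signs are fixed so each component's
#' largest-magnitude loading is positive.
#'
#' @param z standardized feature matrix (see [ci_standardize()]).
#' @return list: `eigenvalues` (descending), `loadings` (variables x
#'   components), `proportion`, `cumulative`.
#' @export
ci_pca <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) < 2) {
    return(list(eigenvalues = 1, proportion = 1, cumulative = 1,
                loadings = matrix(1, 1, 1,
                                  dimnames = list(colnames(z), "Comp.1"))))
  }
  C <- stats::cor(z)
  e <- eigen(C, symmetric = TRUE)
  ev <- e$values
  L <- e$vectors
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(z), paste0("Comp.", seq_len(ncol(L))))
  list(eigenvalues = ev, loadings = L,
       proportion = ev / length(ev), cumulative = cumsum(ev) / length(ev))
}

#' Retain components by the Kaiser rule with a cumulative-variance fallback
#'
#' Keeps components with eigenvalue above `kaiser` (default 1), extending
#' the set until the cumulative explained proportion reaches `cum_cut`
#' (default 0.90) if the Kaiser set falls short.
#'
#' @param eigenvalues numeric, descending.
#' @param kaiser eigenvalue threshold.
#' @param cum_cut cumulative-proportion target in (0, 1\].
#' @return integer indices of the retained components.
#' @export
retain_components <- function(eigenvalues, kaiser = 1.0, cum_cut = 0.90) {
  p <- length(eigenvalues)
  cum <- cumsum(eigenvalues) / sum(eigenvalues)
  k <- sum(eigenvalues > kaiser)
  if (k < 1) k <- 1
  while (cum[k] < cum_cut && k < p) k <- k + 1
  seq_len(k)
}

#' Default redundancy groups for color-index selection
#'
#' Three groups of indices that are deterministic functions of indices
#' already in the feature set: `H2` duplicates `H1` exactly; the ratio
#' family `NDI`/`GI`/`RGRI` is determined by R and G (represented by `H1`
#' on the red-green axis); `Y`/`Cr`/`Cb` are affine in (R, G, B). A group
#' member is dropped when one of its representatives is selected on the
#' same component.
#'
#' @return list of groups, each `list(members, reps)`.
#' @export
default_redundancy_groups <- function() {
  list(list(members = "H2", reps = "H1"),
       list(members = c("NDI", "GI", "RGRI"), reps = "H1"),
       list(members = c("Y", "Cr", "Cb"), reps = c("R", "G", "B")))
}

#' Select color indices from retained-component loadings
#'
#' For each retained component, indices with `|loading| >= threshold` are
#' candidates; redundancy-group members are dropped when a representative
#' is itself a candidate on that component; the union across components is
#' returned. An empty selection lowers the threshold by 20% steps with a
#' warning.
#'
#' @param loadings variables x components matrix (see [ci_pca()]).
#' @param retained integer component indices ([retain_components()]).
#' @param threshold absolute-loading cut, default 0.32.
#' @param redundancy_groups see [default_redundancy_groups()].
#' @return character vector of selected index names.
#' @export
select_cis <- function(loadings, retained, threshold = 0.32,
                       redundancy_groups = default_redundancy_groups()) {
  vars <- rownames(loadings)
  sel <- character(0)
  for (j in retained) {
    cand <- vars[abs(loadings[, j]) >= threshold]
    for (grp in redundancy_groups) {
      if (any(grp$reps %in% cand)) cand <- setdiff(cand, grp$members)
    }
    sel <- union(sel, cand)
  }
  if (!length(sel)) {
    if (threshold < 0.05) stop("empty selection at minimal threshold")
    warning(sprintf(
      "empty selection at threshold %.3f; lowering to %.3f",
      threshold, threshold * 0.8))
    return(select_cis(loadings, retained, threshold * 0.8,
                      redundancy_groups))
  }
  sel[order(match(sel, vars))]
}

#' Reproducible train/test split with K folds
#'
#' Held-out test fraction (default 20%) stratified by response decile
#' (`stratify = FALSE` restores a plain random split), plus a K-fold
#' assignment (default K = 5) over the training rows.
#'
#' @param y numeric response (defines n and the strata).
#' @param test_fraction fraction held out.
#' @param k number of folds.
#' @param seed integer seed; the split is reproducible under it.
#' @param stratify stratify the test split by response decile.
#' @return list: `train`, `test` (row indices), `folds` (fold id per
#'   training row), `seed`.
#' @export
split_and_fold <- function(y, test_fraction = 0.2, k = 5, seed = 1,
                           stratify = TRUE) {
  n <- length(y)
  if (n < 2 * k) stop("too few rows for ", k, "-fold evaluation")
  set.seed(seed)
  n_test <- round(n * test_fraction)
  if (stratify) {
    dec <- cut(rank(y, ties.method = "first"),
               breaks = 10, labels = FALSE)
    ord <- sample(n)                       # shuffle, then take per-stratum
    test <- unlist(lapply(split(ord, dec[ord]), function(ix)
      ix[seq_len(round(length(ix) * test_fraction))]), use.names = FALSE)
    # round-off can leave a deficit; top up at random
    short <- n_test - length(test)
    if (short > 0) test <- c(test, sample(setdiff(ord, test), short))
    test <- sort(test[seq_len(min(length(test), n_test))])
  } else {
    test <- sort(sample(n, n_test))
  }
  train <- setdiff(seq_len(n), test)
  folds <- sample(rep(seq_len(k), length.out = length(train)))
  list(train = train, test = test, folds = folds, seed = seed)
}

#' Regressor specification
#'
#' Hyperparameters follow the field-calibration defaults: RF with 1000 trees; MLP with
#' two 30-neuron sigmoid hidden layers trained by RMSProp at learning rate
#' 0.001; SVR with an RBF kernel (cost 10, epsilon 0.1, bandwidth
#' `1/(p * mean feature variance)`); MLR by ordinary least squares.
#'
#' @param kind one of "SVR", "RF", "MLP", "MLR".
#' @param seed integer training seed, recorded in the model.
#' @param ... overrides: `ntree`; `hidden`, `lr`, `epochs`, `patience`;
#'   `cost`, `epsilon`, `gamma`.
#' @return A `regressor_spec` list.
#' @export
regressor_spec <- function(kind = c("SVR", "RF", "MLP", "MLR"), seed = 1,
                           ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    RF = list(ntree = 1000),
    MLP = list(hidden = c(30, 30), lr = 0.001, epochs = 500, patience = 50,
               val_fraction = 0.1),
    SVR = list(cost = 10, epsilon = 0.1, gamma = NULL),
    MLR = list())
  spec <- modifyList(base, list(...))
  structure(c(list(kind = kind, seed = seed), spec),
            class = "regressor_spec")
}

#' Train a GMC regressor
#'
#' @param x numeric feature matrix (rows = samples, selected indices).
#' @param y numeric GMC response, percent wet basis.
#' @param spec a [regressor_spec()].
#' @return A `gmc_model` with a [predict()] method.
#' @export
gmc_train <- function(x, y, spec = regressor_spec("SVR")) {
  x <- as.matrix(x)
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    MLR = {
      df <- data.frame(x, y = y, check.names = FALSE)
      lm(y ~ ., data = df)
    },
    RF = randomForest::randomForest(x, y, ntree = spec$ntree),
    SVR = {
      gam <- spec$gamma
      if (is.null(gam)) gam <- 1 / (ncol(x) * mean(apply(x, 2, var)))
      e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                 cost = spec$cost, epsilon = spec$epsilon, gamma = gam)
    },
    MLP = mlp_fit(x, y, hidden = spec$hidden, lr = spec$lr,
                  epochs = spec$epochs, patience = spec$patience,
                  val_fraction = spec$val_fraction, seed = spec$seed))
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 features = colnames(x)),
            class = "gmc_model")
}

#' @export
predict.gmc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x)))
    x <- x[, object$features, drop = FALSE]
  switch(object$kind,
    MLR = as.numeric(predict(object$fit,
                             data.frame(x, check.names = FALSE))),
    RF = as.numeric(predict(object$fit, x)),
    SVR = as.numeric(predict(object$fit, x)),
    MLP = mlp_predict(object$fit, x))
}

## ---- multilayer perceptron (sigmoid hidden layers, RMSProp) -------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# mini-batch RMSProp on squared error; inputs min-max scaled to [0, 1]
# (sigmoid layers saturate on raw z-scores), linear output on scaled y
mlp_fit <- function(x, y, hidden = c(30, 30), lr = 0.001, epochs = 500,
                    patience = 50, val_fraction = 0.1, seed = 1,
                    batch_size = 32) {
  set.seed(seed)
  rngx <- apply(x, 2, range)
  spanx <- pmax(rngx[2, ] - rngx[1, ], 1e-12)
  xs <- sweep(sweep(x, 2, rngx[1, ]), 2, spanx, "/")
  rngy <- range(y); spany <- max(rngy[2] - rngy[1], 1e-12)
  ys <- (y - rngy[1]) / spany
  n <- nrow(xs)
  n_val <- max(1L, round(n * val_fraction))
  val <- sample(n, n_val)
  tr <- setdiff(seq_len(n), val)
  sizes <- c(ncol(xs), hidden, 1L)
  L <- length(sizes) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(runif(sizes[l] * sizes[l + 1], -0.5, 0.5) / sqrt(sizes[l]),
           sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  cW <- lapply(W, function(w) w * 0); cb <- lapply(b, function(v) v * 0)
  rho <- 0.9; eps <- 1e-8
  fwd <- function(X) {
    acts <- vector("list", L + 1L); acts[[1]] <- X
    for (l in seq_len(L)) {
      z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
      acts[[l + 1]] <- if (l < L) sigmoid(z) else z
    }
    acts
  }
  best <- list(W = W, b = b, rmse = Inf, epoch = 0L)
  trace <- numeric(epochs)
  Xt <- xs[tr, , drop = FALSE]; yt <- ys[tr]
  Xv <- xs[val, , drop = FALSE]; yv <- ys[val]
  nt <- length(yt)
  for (ep in seq_len(epochs)) {
    ord <- sample(nt)
    starts <- seq(1, nt, by = batch_size)
    for (s0 in starts) {
      bi <- ord[s0:min(s0 + batch_size - 1, nt)]
      acts <- fwd(Xt[bi, , drop = FALSE])
      delta <- (acts[[L + 1]] - yt[bi]) * (2 / length(bi))
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          a <- acts[[l]]
          delta <- (delta %*% t(W[[l]])) * a * (1 - a)
        }
        cW[[l]] <- rho * cW[[l]] + (1 - rho) * gW^2
        cb[[l]] <- rho * cb[[l]] + (1 - rho) * gb^2
        W[[l]] <- W[[l]] - lr * gW / (sqrt(cW[[l]]) + eps)
        b[[l]] <- b[[l]] - lr * gb / (sqrt(cb[[l]]) + eps)
      }
    }
    pv <- fwd(Xv)[[L + 1]]
    vr <- sqrt(mean((pv - yv)^2))
    trace[ep] <- vr
    if (vr < best$rmse) best <- list(W = W, b = b, rmse = vr, epoch = ep)
    if (ep - best$epoch >= patience) { trace <- trace[seq_len(ep)]; break }
  }
  list(W = best$W, b = best$b, sizes = sizes,
       x_min = rngx[1, ], x_span = spanx, y_min = rngy[1], y_span = spany,
       val_rmse = best$rmse * spany, loss_trace = trace * spany,
       converged = is.finite(best$rmse))
}

mlp_predict <- function(fit, x) {
  xs <- sweep(sweep(as.matrix(x), 2, fit$x_min), 2, fit$x_span, "/")
  a <- xs
  L <- length(fit$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    a <- if (l < L) sigmoid(z) else z
  }
  as.numeric(a) * fit$y_span + fit$y_min
}

## ---- evaluation ---------------------------------------------------------

#' Regression error metrics
#'
#' `RMSE = sqrt(mean((yhat - y)^2))`, `MAE = mean(|yhat - y|)`,
#' `MAPE = 100 mean(|yhat - y| / |y|)` percent. Elements with `y = 0` are
#' excluded from MAPE with a warning.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return named numeric `c(RMSE, MAE, MAPE)`.
#' @export
gmc_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  err <- yhat - y
  ok <- y != 0
  if (!all(ok)) warning(sum(!ok), " zero observation(s) excluded from MAPE")
  c(RMSE = sqrt(mean(err^2)), MAE = mean(abs(err)),
    MAPE = 100 * mean(abs(err[ok] / y[ok])))
}

#' Coefficient of determination
#' @inheritParams gmc_metrics
#' @return `1 - SSE/SST`.
#' @export
r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

#' Interval-stratified evaluation report
#'
#' Metrics on the full test set and on the subsets with true GMC below each
#' cut (default 40 and 32 percent), the intervals used when judging
#' harvest-range accuracy.
#'
#' @inheritParams gmc_metrics
#' @param cuts descending GMC cuts, percent.
#' @return data.frame rows (`all`, `below_40`, `below_32`): n, RMSE, MAE,
#'   MAPE; attribute `r_squared` for the full set.
#' @export
interval_report <- function(y, yhat, cuts = c(40, 32)) {
  subsets <- c(list(all = rep(TRUE, length(y))),
               setNames(lapply(cuts, function(ct) y < ct),
                        paste0("below_", cuts)))
  rows <- lapply(names(subsets), function(nm) {
    keep <- subsets[[nm]]
    if (!any(keep))
      return(data.frame(interval = nm, n = 0L, RMSE = NA_real_,
                        MAE = NA_real_, MAPE = NA_real_))
    m <- gmc_metrics(y[keep], yhat[keep])
    data.frame(interval = nm, n = sum(keep), RMSE = m["RMSE"],
               MAE = m["MAE"], MAPE = m["MAPE"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "r_squared") <- r_squared(y, yhat)
  out
}
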