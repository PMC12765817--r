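#' @include synthetic.R
NULL

driverFeatures <- c("Pre", "Tem", "Srad", "Slope", "Ele", "Asp", "Ha",
                    "forest_type", "forest_age")

#' Assemble the per-pixel driver/response table
#'
#' Multi-year means over the study period: monthly-mean climate (Pre mm,
#' Tem deg C, Srad W m-2), static topography (Slope deg, Ele m, Asp deg),
#' human-activity index Ha, forest type (planted/natural) and forest age,
#' with mean annual NPP (gC m-2 a-1) as the response. Rows are the pixels
#' of \code{mask}; when more than \code{sampleCap} pixels are masked a
#' seeded uniform spatial subsample is drawn. Rows with any missing layer
#' are dropped (count reported via a message).
#'
#' @param npp \linkS4class{AnnualCube} of annual NPP.
#' @param climate list with \code{pre}, \code{tem}, \code{srad}
#'   \linkS4class{MonthlyCube}s.
#' @param terrain list with \code{elevation}, \code{slope}, \code{aspect}
#'   \linkS4class{RasterGrid}s.
#' @param anthro list with \code{ha}, \code{age}, \code{ftype}
#'   \linkS4class{RasterGrid}s.
#' @param mask logical matrix of pixels to tabulate (e.g. a SF or CF mask).
#' @param subregions optional label matrix/\linkS4class{RasterGrid}.
#' @param stratum optional single label attached to every row (e.g. "SF").
#' @param sampleCap maximum number of rows (default 10000).
#' @param seed integer seed for the spatial subsample.
#' @return data.frame with \code{row}, \code{col}, the nine driver columns,
#'   \code{npp}, and \code{subregion}/\code{stratum} labels.
#' @export
buildDriverTable <- function(npp, climate, terrain, anthro, mask,
                             subregions = NULL, stratum = NA_character_,
                             sampleCap = 10000, seed = 1) {
  if (!any(mask)) stop("mask selects no pixels")
  idx <- which(mask)
  if (length(idx) > sampleCap) {
    set.seed(seed)
    idx <- sort(sample(idx, sampleCap))
  }
  rc <- arrayInd(idx, dim(mask))
  grab <- function(m) m[cbind(rc[, 1], rc[, 2])]
  meanOver <- function(cube) grab(apply(gridValues(cube), c(1, 2), mean))
  if (is(subregions, "RasterGrid")) subregions <- gridValues(subregions)
  tab <- data.frame(
    row = rc[, 1], col = rc[, 2],
    Pre = meanOver(climate$pre),
    Tem = meanOver(climate$tem),
    Srad = meanOver(climate$srad),
    Slope = grab(gridValues(terrain$slope)),
    Ele = grab(gridValues(terrain$elevation)),
    Asp = grab(gridValues(terrain$aspect)),
    Ha = grab(gridValues(anthro$ha)),
    forest_type = factor(ifelse(grab(gridValues(anthro$ftype)) > 0,
                                "planted", "natural"),
                         levels = c("natural", "planted")),
    forest_age = grab(gridValues(anthro$age)),
    npp = meanOver(npp),
    subregion = if (is.null(subregions)) NA_character_
                else as.character(grab(subregions)),
    stratum = stratum,
    stringsAsFactors = FALSE
  )
  keep <- stats::complete.cases(tab[, c(driverFeatures, "npp")])
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped for missing layers")
  }
  tab[keep, , drop = FALSE]
}

# numeric encoding actually passed to the forest: planted = 1, natural = 0
encodeFeatures <- function(table, features = driverFeatures) {
  X <- table[, features, drop = FALSE]
  if ("forest_type" %in% features) {
    X$forest_type <- as.numeric(X$forest_type == "planted")
  }
  X
}

# ---- Gaussian-process expected-improvement tuner ------------------------

tunerSpace <- list(
  num.trees = c(100L, 400L),
  max.depth = c(4L, 9L),
  mtry = c(2L, 9L),
  min.node.size = c(2L, 20L)
)

denormParams <- function(u, space) {
  p <- lapply(seq_along(space), function(j) {
    r <- space[[j]]
    as.integer(round(r[1] + u[j] * (r[2] - r[1])))
  })
  names(p) <- names(space)
  p
}

gpEI <- function(U, y, cand, noise = 1e-6) {
  # squared-exponential GP on the unit cube; EI for maximization
  sqd <- function(A, B) {
    outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  }
  ell <- 0.3
  K <- exp(-sqd(U, U) / (2 * ell^2)) + diag(noise + 1e-8, nrow(U))
  mu0 <- mean(y)
  alpha <- solve(K, y - mu0)
  Ks <- exp(-sqd(cand, U) / (2 * ell^2))
  mu <- mu0 + Ks %*% alpha
  v <- pmax(1 - rowSums((Ks %*% solve(K)) * Ks), 1e-12)
  s <- sqrt(v)
  best <- max(y)
  z <- (mu - best) / s
  (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
}

cvR2 <- function(X, y, params, folds, seed) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  press <- 0; tss <- sum((y - mean(y))^2)
  for (f in seq_len(folds)) {
    tr <- fold != f
    rf <- ranger::ranger(
      x = X[tr, , drop = FALSE], y = y[tr],
      num.trees = params$num.trees, max.depth = params$max.depth,
      mtry = min(params$mtry, ncol(X)), min.node.size = params$min.node.size,
      seed = seed + f, num.threads = 1
    )
    pred <- stats::predict(rf, data = X[!tr, , drop = FALSE],
                           num.threads = 1)$predictions
    press <- press + sum((y[!tr] - pred)^2)
  }
  1 - press / tss
}

#' Fit a tuned random-forest regression of NPP on its drivers
#'
#' Stratified (by \code{stratum}/\code{subregion} when present) random 70/30
#' train/test split, Bayesian hyperparameter optimization of the forest
#' (number of trees, maximum depth, features per split, minimum leaf size)
#' maximizing k-fold cross-validated R2 on the training split, final fit at
#' the best configuration, and holdout R2/RMSE. The tuner is a Gaussian
#' process with expected improvement over a Latin-hypercube initial design;
#' \code{budget} counts total objective evaluations (\code{budget = 0}
#' skips tuning and fits documented defaults: 200 trees, depth 7, mtry 3,
#' min node 5). The seed fixes split, search and forest.
#'
#' @param table driver table from \code{\link{buildDriverTable}}.
#' @param split training fraction (default 0.7).
#' @param budget tuner evaluations (default 30; 0 = defaults, no search).
#' @param folds cross-validation folds inside the tuner (default 5).
#' @param seed integer seed.
#' @param response response column name.
#' @param features driver columns to use (default all nine).
#' @param params optional named list of fixed hyperparameters
#'   (\code{num.trees}, \code{max.depth}, \code{mtry},
#'   \code{min.node.size}); bypasses the search entirely.
#' @return An \linkS4class{AttributionModel}.
#' @export
fitRf <- function(table, split = 0.7, budget = 30, folds = 5, seed = 1,
                  response = "npp", features = driverFeatures,
                  params = NULL) {
  if (nrow(table) < 200) stop("need at least 200 rows")
  y <- table[[response]]
  if (stats::var(y) == 0) stop("response has zero variance")
  X <- encodeFeatures(table, features)
  set.seed(seed)
  strat <- paste(table$stratum, table$subregion)
  trainIdx <- sort(unlist(lapply(split(seq_len(nrow(table)), strat),
                                 function(ix) {
    sample(ix, round(split * length(ix)))
  }), use.names = FALSE))
  testIdx <- setdiff(seq_len(nrow(table)), trainIdx)
  Xtr <- X[trainIdx, , drop = FALSE]; ytr <- y[trainIdx]

  tuning <- data.frame()
  if (!is.null(params)) {
    best <- utils::modifyList(list(num.trees = 200L, max.depth = 7L,
                                   mtry = 3L, min.node.size = 5L), params)
    budget <- 0
  } else if (budget > 0) {
    nInit <- max(4L, min(budget, ceiling(budget / 3)))
    set.seed(seed + 17L)
    U <- lhs::randomLHS(nInit, length(tunerSpace))
    scores <- apply(U, 1, function(u) {
      cvR2(Xtr, ytr, denormParams(u, tunerSpace), folds, seed)
    })
    while (nrow(U) < budget) {
      cand <- matrix(stats::runif(400 * length(tunerSpace)), ncol =
                       length(tunerSpace))
      ei <- gpEI(U, scores, cand)
      u <- cand[which.max(ei), ]
      U <- rbind(U, u)
      scores <- c(scores, cvR2(Xtr, ytr, denormParams(u, tunerSpace),
                               folds, seed))
    }
    best <- denormParams(U[which.max(scores), ], tunerSpace)
    tuning <- as.data.frame(t(apply(U, 1, function(u) {
      unlist(denormParams(u, tunerSpace))
    })))
    tuning$cv_r2 <- scores
  } else {
    best <- list(num.trees = 200L, max.depth = 7L, mtry = 3L,
                 min.node.size = 5L)
  }
  best$mtry <- min(best$mtry, ncol(X))
  rf <- ranger::ranger(
    x = Xtr, y = ytr,
    num.trees = best$num.trees, max.depth = best$max.depth,
    mtry = best$mtry, min.node.size = best$min.node.size,
    seed = seed, num.threads = 1
  )
  pred <- stats::predict(rf, data = X[testIdx, , drop = FALSE],
                         num.threads = 1)$predictions
  yte <- y[testIdx]
  metrics <- c(
    r2 = 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2),
    rmse = sqrt(mean((yte - pred)^2)),
    n_train = length(trainIdx), n_test = length(testIdx)
  )
  new("AttributionModel", forest = rf, table = table,
      features = features, response = response,
      trainIdx = as.integer(trainIdx), testIdx = as.integer(testIdx),
      metrics = metrics, hyperparams = best, tuning = tuning,
      seed = as.integer(seed))
}

# flatten a ranger forest into the arrays the C++ subset-value code reads
flattenForest <- function(model) {
  rf <- model@forest
  lapply(seq_len(rf$num.trees), function(t) {
    ti <- ranger::treeInfo(rf, t)
    left <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
    right <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
    list(
      left = as.integer(left), right = as.integer(right),
      var = as.integer(ifelse(is.na(ti$splitvarID), 0L, ti$splitvarID)),
      val = as.numeric(ifelse(is.na(ti$splitval), 0, ti$splitval)),
      pred = as.numeric(ifelse(is.na(ti$prediction), 0, ti$prediction))
    )
  })
}

shapleyWeights <- function(M) {
  s <- 0:(M - 1)
  exp(lfactorial(s) + lfactorial(M - s - 1) - lfactorial(M))
}

#' Exact SHAP decomposition of a fitted attribution model
#'
#' Computes tree-Shapley values and pairwise Shapley interaction values
#' exactly under interventional conditioning: conditional expectations
#' \eqn{v(S) = E_b f(x_S, b_{\bar S})} are enumerated over all feature
#' subsets against a seeded background sample (C++ backend), on a seeded
#' evaluation subsample of the driver table. This is the functional-ANOVA
#' decomposition of the fitted ensemble, so an additive fit has exactly
#' zero pairwise terms. Reports per-sample SHAP values, the symmetric
#' interaction array, and the normalized summaries: total importance
#' (mean |SHAP|, normalized to sum 1), main importance (mean |diagonal
#' interaction|) and the mean |off-diagonal| interaction matrix. By
#' construction each sample satisfies \eqn{f(x) = base + \sum_i \phi_i}
#' and \eqn{\phi_i = \phi_{ii} + \sum_{j \ne i} \phi_{ij}}.
#'
#' @param model an \linkS4class{AttributionModel} from \code{\link{fitRf}}.
#' @param evalCap maximum evaluation rows (default 2000).
#' @param bgCap maximum background rows, drawn from the training split
#'   (default 200).
#' @param seed integer seed for the evaluation/background subsamples.
#' @return An \linkS4class{AttributionResult}.
#' @export
shapEffects <- function(model, evalCap = 2000, bgCap = 200, seed = 1) {
  if (!inherits(model, "AttributionModel") ||
      !inherits(model@forest, "ranger")) {
    stop("shapEffects requires a tree-ensemble AttributionModel")
  }
  X <- encodeFeatures(model@table, model@features)
  M <- ncol(X)
  idx <- seq_len(nrow(X))
  if (length(idx) > evalCap) {
    set.seed(seed)
    idx <- sort(sample(idx, evalCap))
  }
  bgIdx <- model@trainIdx
  if (length(bgIdx) > bgCap) {
    set.seed(seed + 1L)
    bgIdx <- sort(sample(bgIdx, bgCap))
  }
  Xe <- as.matrix(X[idx, , drop = FALSE])
  Bg <- as.matrix(X[bgIdx, , drop = FALSE])
  V <- .treeSubsetValues(flattenForest(model), Xe, Bg)
  n <- nrow(Xe)
  masks <- 0:(2^M - 1)
  popcount <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(M - 1))) > 0),
                     numeric(1))
  w1 <- shapleyWeights(M)
  phi <- matrix(0, n, M, dimnames = list(NULL, colnames(X)))
  for (i in seq_len(M)) {
    bit <- 2^(i - 1)
    without <- masks[bitwAnd(masks, bit) == 0]
    wv <- w1[popcount[without + 1] + 1]
    phi[, i] <- (V[, without + bit + 1, drop = FALSE] -
                   V[, without + 1, drop = FALSE]) %*% wv
  }
  # pairwise Shapley interaction values (each pair's total split evenly)
  s2 <- 0:(M - 2)
  w2 <- exp(lfactorial(s2) + lfactorial(M - s2 - 2) - lfactorial(M - 1)) / 2
  inter <- array(0, c(n, M, M),
                 dimnames = list(NULL, colnames(X), colnames(X)))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      bi <- 2^(i - 1); bj <- 2^(j - 1)
      base <- masks[bitwAnd(masks, bi) == 0 & bitwAnd(masks, bj) == 0]
      wv <- w2[popcount[base + 1] + 1]
      d <- (V[, base + bi + bj + 1, drop = FALSE] -
              V[, base + bi + 1, drop = FALSE] -
              V[, base + bj + 1, drop = FALSE] +
              V[, base + 1, drop = FALSE]) %*% wv
      inter[, i, j] <- d
      inter[, j, i] <- d
    }
  }
  for (i in seq_len(M)) {
    # main effect as the remainder of the interaction-row identity
    inter[, i, i] <- phi[, i] - rowSums(matrix(inter[, i, ], n, M))
  }
  total <- colMeans(abs(phi))
  main <- vapply(seq_len(M), function(i) mean(abs(inter[, i, i])),
                 numeric(1))
  names(main) <- colnames(X)
  im <- matrix(0, M, M, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      im[i, j] <- mean(abs(inter[, i, j]))
    }
  }
  new("AttributionResult",
      shap = phi, interactions = inter,
      baseValue = V[1, 1],  # v(empty set) does not depend on the sample
      predictions = as.numeric(V[, 2^M]),
      totalImportance = total / sum(total),
      mainImportance = main / sum(main),
      interactionMatrix = im,
      evalIdx = as.integer(idx))
}

#' Rank drivers by normalized total SHAP importance
#'
#' Descending mean |SHAP| order; exact ties are broken alphabetically and
#' flagged. The ranking is invariant to feature column order.
#'
#' @param result an \linkS4class{AttributionResult}.
#' @param which \code{"total"} or \code{"main"} importance.
#' @return data.frame with \code{feature}, \code{importance}, \code{rank},
#'   \code{tied}.
#' @export
rankDrivers <- function(result, which = c("total", "main")) {
  which <- match.arg(which)
  imp <- if (which == "total") totalImportance(result)
         else mainImportance(result)
  ord <- order(-imp, names(imp))
  imp <- imp[ord]
  tied <- duplicated(imp) | duplicated(imp, fromLast = TRUE)
  data.frame(feature = names(imp), importance = as.numeric(imp),
             rank = seq_along(imp), tied = tied, row.names = NULL)
}
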