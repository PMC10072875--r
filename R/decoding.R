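#' Drop extreme-outlier trials by trace variability
#'
#' Removes trials whose trace standard deviation is strictly greater than
#' `factor` (default 10) times the group-average trace SD; a trial at exactly
#' the factor is retained.
#'
#' @param aligned A `trial_aligned` object (or a trial x time matrix).
#' @param factor Multiplier on the group-mean SD.
#' @return The filtered object of the same type, with the dropped (1-based)
#'   trial indices in attribute `dropped`.
#' @export
remove_outliers <- function(aligned, factor = 10) {
  mat <- if (inherits(aligned, "trial_aligned")) aligned$traces else as.matrix(aligned)
  if (nrow(mat) < 3) stop("need at least 3 trials to define the group SD")
  sds <- apply(mat, 1, stats::sd)
  drop <- which(sds > factor * mean(sds))
  if (length(drop) == 0) {
    attr(aligned, "dropped") <- integer(0)
    return(aligned)
  }
  if (inherits(aligned, "trial_aligned")) {
    aligned$traces <- aligned$traces[-drop, , drop = FALSE]
    aligned$labels <- aligned$labels[-drop, , drop = FALSE]
    out <- aligned
  } else {
    out <- mat[-drop, , drop = FALSE]
  }
  attr(out, "dropped") <- drop
  out
}

#' Min/max feature normalization
#'
#' Maps every feature column to \[0, 1\] by `(x - min) / (max - min)`, except
#' the raw trace extremes (`f_base_min`, `f_base_max`, `f_cue_min`,
#' `f_cue_max`), which pass through unchanged. Constant columns are dropped
#' with a warning.
#'
#' @param features A tibble of per-trial features (non-numeric columns such
#'   as labels pass through untouched).
#' @param exclude Column names exempt from normalization.
#' @return The normalized tibble.
#' @export
normalize_features <- function(features,
                               exclude = c("f_base_min", "f_base_max",
                                           "f_cue_min", "f_cue_max")) {
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  norm_cols <- setdiff(grep("^f_", num, value = TRUE), exclude)
  dropped <- character(0)
  for (col in norm_cols) {
    rng <- range(features[[col]])
    if (diff(rng) == 0) {
      dropped <- c(dropped, col)
    } else {
      features[[col]] <- (features[[col]] - rng[1]) / diff(rng)
    }
  }
  if (length(dropped) > 0) {
    warning("dropping constant feature column(s): ", paste(dropped, collapse = ", "))
    features <- features[setdiff(names(features), dropped)]
  }
  features
}

feature_cols <- function(data) grep("^f_", names(data), value = TRUE)

# Euclidean k-nearest neighbours among `pool` rows for each `query` row
knn_index <- function(query, pool, k, exclude_self = FALSE) {
  d <- as.matrix(stats::dist(rbind(query, pool)))
  nq <- nrow(query)
  d <- d[seq_len(nq), nq + seq_len(nrow(pool)), drop = FALSE]
  t(apply(d, 1, function(row) order(row)[seq_len(k + exclude_self)]))
}

#' Class rebalancing: SMOTE oversampling + Tomek-link cleaning
#'
#' Brings an imbalanced binary feature set to a near 50:50 class balance.
#' SMOTE: for each synthetic minority sample needed, a random minority point
#' is paired with one of its `k_neighbors` nearest minority neighbours
#' (Euclidean distance on the feature columns) and a new point is
#' interpolated at a uniform random fraction along the segment. Tomek
#' cleaning then removes the majority member of every cross-class
#' mutual-nearest-neighbour pair.
#'
#' @param data A tibble containing `f_*` feature columns and a binary label
#'   column.
#' @param label_col Name of the label column (default "label").
#' @param k_neighbors SMOTE neighbourhood size (reduced, with a warning, if
#'   the minority class is too small).
#' @param seed Integer RNG seed.
#' @return The rebalanced tibble (synthetic rows appended, Tomek-removed rows
#'   dropped), with attributes `minority_fraction`, `n_synthetic`,
#'   `n_tomek_removed`.
#' @export
rebalance <- function(data, label_col = "label", k_neighbors = 5, seed = 1) {
  y <- data[[label_col]]
  if (is.null(y)) stop("no label column '", label_col, "'")
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("rebalance needs exactly two classes")
  cols <- feature_cols(data)
  if (length(cols) == 0) stop("no f_* feature columns found")
  n_by <- table(y)
  minority <- names(n_by)[which.min(n_by)]
  majority <- setdiff(names(table(y)), minority)
  n_min <- sum(y == minority)
  n_maj <- sum(y == majority)
  if (n_min < 2) stop("minority class needs at least 2 samples")
  if (n_min <= k_neighbors) {
    warning("minority class smaller than k_neighbors + 1; reducing k to ",
            n_min - 1)
    k_neighbors <- n_min - 1
  }
  withr::with_seed(seed, {
    x_min <- as.matrix(data[y == minority, cols])
    n_new <- n_maj - n_min
    synth <- NULL
    if (n_new > 0) {
      nn <- knn_index(x_min, x_min, k_neighbors, exclude_self = TRUE)
      nn <- nn[, -1, drop = FALSE] # drop self-match
      base_idx <- sample.int(n_min, n_new, replace = TRUE)
      nb_pick <- vapply(base_idx, function(i) {
        nn[i, sample.int(ncol(nn), 1)]
      }, numeric(1))
      u <- stats::runif(n_new)
      synth <- x_min[base_idx, , drop = FALSE] +
        u * (x_min[nb_pick, , drop = FALSE] - x_min[base_idx, , drop = FALSE])
    }
    aug <- data
    if (!is.null(synth)) {
      new_rows <- data[rep(which(y == minority)[1], n_new), ]
      new_rows[cols] <- as.data.frame(synth)
      new_rows[[label_col]] <- minority
      aug <- dplyr::bind_rows(data, new_rows)
    }
    # Tomek links: mutual 1-NN pairs of opposite class; drop the majority member
    xa <- as.matrix(aug[cols])
    ya <- aug[[label_col]]
    d <- as.matrix(stats::dist(xa))
    diag(d) <- Inf
    nn1 <- apply(d, 1, which.min)
    is_tomek_maj <- vapply(seq_len(nrow(xa)), function(i) {
      j <- nn1[i]
      ya[i] == majority && ya[j] != ya[i] && nn1[j] == i
    }, logical(1))
    synthetic_flag <- c(rep(FALSE, nrow(data)),
                        rep(TRUE, if (is.null(synth)) 0 else n_new))
    out <- aug[!is_tomek_maj, , drop = FALSE]
    attr(out, "minority_fraction") <- mean(out[[label_col]] == minority)
    attr(out, "n_synthetic") <- if (is.null(synth)) 0L else as.integer(n_new)
    attr(out, "n_tomek_removed") <- sum(is_tomek_maj)
    attr(out, "is_synthetic") <- synthetic_flag[!is_tomek_maj]
    out
  })
}

#' @rdname rebalance
#' @param balanced Output of `rebalance()`.
#' @return `minority_fraction()`: the minority-class fraction after
#'   rebalancing.
#' @export
minority_fraction <- function(balanced) attr(balanced, "minority_fraction")

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict_xgb <- function(x_tr, y_tr, x_te, params) {
  d_tr <- xgboost::xgb.DMatrix(x_tr, label = y_tr)
  booster <- xgboost::xgb.train(
    params = list(
      objective = "binary:logistic", max_depth = params$max_depth,
      eta = params$eta, subsample = params$row_subsample,
      colsample_bytree = params$col_subsample, nthread = 1,
      eval_metric = "logloss"
    ),
    data = d_tr, nrounds = params$nrounds, verbose = 0
  )
  stats::predict(booster, xgboost::xgb.DMatrix(x_te))
}

auc_score <- function(y_true, score) {
  as.numeric(pROC::auc(pROC::roc(response = y_true, predictor = score,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
}

#' Cross-validated trial-outcome decoding
#'
#' Gradient-boosted decision trees (binary logistic objective; depth 3,
#' 200 rounds, learning rate 0.1 by default) with rows and features randomly
#' subsampled at 80% and 30% per boosting iteration, evaluated by repeated
#' (k = 10, n = 3) stratified k-fold cross-validation on held-out ROC-AUC.
#' Class rebalancing ([rebalance()]) is applied inside each training fold
#' only — never to held-out data — so chance-level data stays at chance.
#' A resample-before-CV mode mirroring the source ordering is available via
#' `rebalance_mode = "before_cv"` for comparison.
#'
#' @param data Tibble with `f_*` feature columns and a binary label column.
#' @param label_col Label column name; the positive class is the
#'   alphabetically later level.
#' @param k,repeats Folds and repeats (defaults 10 and 3).
#' @param row_subsample,col_subsample Per-iteration subsampling fractions.
#' @param max_depth,nrounds,eta Boosted-tree hyperparameters.
#' @param k_neighbors SMOTE neighbourhood size for in-fold rebalancing.
#' @param rebalance_mode "in_fold" (leakage-safe, default), "before_cv", or
#'   "none".
#' @param seed Integer RNG seed; fixes fold assignment, rebalancing and tree
#'   fitting.
#' @return A `decoding_report`: list with `fold_aucs` (tibble: `rep`, `fold`,
#'   `auc`), `mean_auc`, `params`, `seed`.
#' @export
crossval_auc <- function(data, label_col = "label", k = 10, repeats = 3,
                         row_subsample = 0.8, col_subsample = 0.3,
                         max_depth = 3, nrounds = 200, eta = 0.1,
                         k_neighbors = 5,
                         rebalance_mode = c("in_fold", "before_cv", "none"),
                         seed = 1) {
  rebalance_mode <- match.arg(rebalance_mode)
  params <- list(max_depth = max_depth, nrounds = nrounds, eta = eta,
                 row_subsample = row_subsample, col_subsample = col_subsample,
                 k = k, repeats = repeats, rebalance_mode = rebalance_mode)
  res <- run_cv(data, label_col, params, k_neighbors, seed, shuffle_fn = NULL)
  structure(list(fold_aucs = res, mean_auc = mean(res$auc), params = params,
                 seed = seed, null = NULL),
            class = "decoding_report")
}

run_cv <- function(data, label_col, params, k_neighbors, seed, shuffle_fn) {
  cols <- feature_cols(data)
  if (length(cols) == 0) stop("no f_* feature columns found")
  lv <- sort(unique(data[[label_col]]))
  if (length(lv) != 2) stop("decoding needs exactly two classes")
  y_all <- as.integer(data[[label_col]] == lv[2])
  k <- params$k
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(params$repeats), function(r) {
      dat <- data
      y <- y_all
      if (!is.null(shuffle_fn)) {
        perm <- shuffle_fn(length(y))
        y <- y[perm]
        dat[[label_col]] <- dat[[label_col]][perm]
      }
      if (params$rebalance_mode == "before_cv") {
        dat <- rebalance(dat, label_col, k_neighbors,
                         seed = child_seed(seed, 1000 + r))
        y <- as.integer(dat[[label_col]] == lv[2])
      }
      if (min(table(y)) < k) stop("stratification failure: a class has fewer ",
                                  "samples than folds")
      fold <- stratified_folds(y, k)
      purrr::map_dfr(seq_len(k), function(f) {
        tr <- dat[fold != f, , drop = FALSE]
        te <- dat[fold == f, , drop = FALSE]
        y_te <- y[fold == f]
        if (length(unique(y_te)) < 2) stop("stratification failure: held-out ",
                                           "fold lacks a class")
        if (params$rebalance_mode == "in_fold") {
          tr <- rebalance(tr, label_col, k_neighbors,
                          seed = child_seed(seed, r * 100 + f))
        }
        y_tr <- as.integer(tr[[label_col]] == lv[2])
        score <- fit_predict_xgb(as.matrix(tr[cols]), y_tr,
                                 as.matrix(te[cols]), params)
        tibble::tibble(rep = r, fold = f, auc = auc_score(y_te, score))
      })
    })
  })
}

#' Shuffled-label null model
#'
#' Repeats the full cross-validation pipeline with labels permuted once per
#' repeat before training, and compares real vs null per-fold AUCs with a
#' rank-sum (Wilcoxon) test.
#'
#' @param data,label_col,k_neighbors,seed As in [crossval_auc()].
#' @param real A `decoding_report` from [crossval_auc()]; its CV parameters
#'   are reused.
#' @param shuffle_fn Permutation generator `function(n) -> indices`;
#'   `sample.int` by default (the identity is a useful test hook).
#' @return The `real` report with `null` filled in: `null_fold_aucs`,
#'   `null_mean_auc`, and `p_value` (one-sided rank-sum, real > null).
#' @export
null_model <- function(data, real, label_col = "label", k_neighbors = 5,
                       seed = 1, shuffle_fn = sample.int) {
  stopifnot(inherits(real, "decoding_report"))
  res <- run_cv(data, label_col, real$params, k_neighbors, seed,
                shuffle_fn = shuffle_fn)
  real$null <- list(
    null_fold_aucs = res,
    null_mean_auc = mean(res$auc),
    p_value = stats::wilcox.test(real$fold_aucs$auc, res$auc,
      alternative = "greater", exact = FALSE)$p.value
  )
  real
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("<decoding_report> mean AUC = %.3f over %d folds (k = %d x %d repeats)\n",
    x$mean_auc, nrow(x$fold_aucs), x$params$k, x$params$repeats))
  if (!is.null(x$null)) {
    cat(sprintf("  null mean AUC = %.3f; rank-sum p = %.2g\n",
      x$null$null_mean_auc, x$null$p_value))
  }
  invisible(x)
}
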