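# Classifier stack: Matthews correlation coefficient, mRMR feature
# ranking, forward stepwise selection, standardized RBF-SVM with
# grid-search cross-validation, prediction and quality scoring.

#' Model configuration
#'
#' @param C_grid,gamma_grid RBF-SVM grid-search values; defaults are the
#'   eight-point grid \{1e-4, 1e-3, 0.01, 0.1, 1, 10, 100, 1000\}.
#' @param cv_folds folds for the grid-search cross-validation
#'   (default 10).
#' @param split_ratio training fraction of the train/validation split
#'   (default 0.8, i.e. 4:1).
#' @param split_replicates number of random split replicates in forward
#'   selection (default 10).
#' @param selection_epsilon MCC slack when choosing the smallest feature
#'   count (default 0.005).
#' @param seed integer seed governing splits and folds.
#' @return a `ModelConfig` list.
#' @export
model_config <- function(C_grid = c(1e-4, 1e-3, 0.01, 0.1, 1, 10, 100, 1000),
                         gamma_grid = c(1e-4, 1e-3, 0.01, 0.1, 1, 10, 100,
                                        1000),
                         cv_folds = 10L, split_ratio = 0.8,
                         split_replicates = 10L,
                         selection_epsilon = 0.005, seed = 1L) {
  stopifnot(length(C_grid) > 0, length(gamma_grid) > 0, cv_folds >= 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds),
                 split_ratio = split_ratio,
                 split_replicates = as.integer(split_replicates),
                 selection_epsilon = selection_epsilon,
                 seed = as.integer(seed)),
            class = "ModelConfig")
}

#' Matthews correlation coefficient
#'
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)); 0 by convention
#' when any denominator factor is zero.  Counts are taken as doubles to
#' avoid integer overflow.
#'
#' @param tp,fp,tn,fn confusion-matrix counts (non-negative).
#' @return value in \[-1, 1\].
#' @export
mcc <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("mcc: counts must be non-negative")
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

mcc_from_labels <- function(pred, truth) {
  mcc(sum(pred & truth), sum(pred & !truth),
      sum(!pred & !truth), sum(!pred & truth))
}

# equal-frequency discretization into at most n_bins bins
discretize_ef <- function(x, n_bins = 10L) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               type = 7, names = FALSE))
  if (length(qs) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' mRMR feature ranking
#'
#' Minimum-redundancy maximum-relevance, MID (difference) variant:
#' features are discretized into equal-frequency bins, relevance is the
#' mutual information with the class label, redundancy the mean mutual
#' information with already-ranked features, and features are greedily
#' ranked by relevance - redundancy.  Deterministic: ties break by
#' feature name.
#'
#' @param x numeric feature matrix (columns named).
#' @param y class labels (logical or two-level).
#' @param n_bins discretization bins (default 10).
#' @return data frame `feature`, `score` in rank order.
#' @export
mrmr_rank <- function(x, y, n_bins = 10L) {
  stopifnot(ncol(x) >= 2L)
  feats <- colnames(x)
  disc <- lapply(seq_len(ncol(x)), function(j) discretize_ef(x[, j], n_bins))
  names(disc) <- feats
  rel <- vapply(disc, mutual_information, numeric(1), b = y)

  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  mi_cache <- list()
  while (length(remaining)) {
    if (!length(selected)) {
      sc <- rel[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        mean(vapply(selected, function(s) {
          key <- paste(sort(c(f, s)), collapse = "\r")
          v <- mi_cache[[key]]
          if (is.null(v)) {
            v <- mutual_information(disc[[f]], disc[[s]])
            mi_cache[[key]] <<- v
          }
          v
        }, numeric(1)))
      }, numeric(1))
      sc <- rel[remaining] - red
    }
    ord <- order(-sc, remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, sc[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  data.frame(feature = selected, score = scores, stringsAsFactors = FALSE)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0 | is.na(sdev)] <- 1
  list(mean = mu, scale = sdev)
}

standardize_apply <- function(x, sc) {
  scale(x, center = sc$mean, scale = sc$scale)[, , drop = FALSE]
}

fit_svm <- function(x, y01, C, gamma) {
  yv <- ifelse(y01, 1, -1)
  svm_smo_train_cpp(as.matrix(x), yv, C, gamma)
}

decision_svm <- function(model, x) {
  svm_decision_cpp(model$sv, model$coef, model$b, model$gamma,
                   as.matrix(x))
}

cv_fold_ids <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# 10-fold CV grid search maximizing MCC; returns best C, gamma, cv_mcc
grid_search_cv <- function(x, y01, config) {
  n <- nrow(x)
  k <- config$cv_folds
  if (n < k) {
    warning("n < cv_folds; reducing folds to ", n)
    k <- max(2L, n)
  }
  folds <- cv_fold_ids(n, k, config$seed)
  best <- list(mcc = -Inf, C = config$C_grid[1],
               gamma = config$gamma_grid[1])
  for (C in config$C_grid) {
    for (g in config$gamma_grid) {
      preds <- logical(n)
      ok <- TRUE
      for (f in seq_len(k)) {
        tr <- folds != f
        if (length(unique(y01[tr])) < 2L) { ok <- FALSE; break }
        sc <- standardize_fit(x[tr, , drop = FALSE])
        m <- fit_svm(standardize_apply(x[tr, , drop = FALSE], sc),
                     y01[tr], C, g)
        preds[!tr] <- decision_svm(
          m, standardize_apply(x[!tr, , drop = FALSE], sc)) > 0
      }
      if (!ok) next
      v <- mcc_from_labels(preds, y01)
      if (v > best$mcc) best <- list(mcc = v, C = C, gamma = g)
    }
  }
  best
}

#' Forward stepwise feature selection
#'
#' For k = 1..K (top-k features of the mRMR ranking), trains an RBF-SVM
#' with default parameters (C = 1, gamma = 1/k) on `split_replicates`
#' random 4:1 train/validation splits and records the mean validation
#' MCC; the chosen feature count is the smallest k whose mean MCC is
#' within `selection_epsilon` of the maximum.
#'
#' @param x feature matrix.
#' @param y logical labels (TRUE = miRNA).
#' @param ranked ranking from [mrmr_rank()] (data frame or character
#'   vector).
#' @param config a [model_config()].
#' @param max_k cap on the number of candidate features (default all).
#' @return list: `k`, `features`, `mcc_by_k` (data frame k / mean / sd).
#' @export
forward_select <- function(x, y, ranked, config = model_config(),
                           max_k = ncol(x)) {
  feats <- if (is.data.frame(ranked)) ranked$feature else ranked
  feats <- feats[seq_len(min(max_k, length(feats)))]
  K <- length(feats)
  n <- nrow(x)
  means <- numeric(K)
  sds <- numeric(K)
  for (k in seq_len(K)) {
    cols <- feats[seq_len(k)]
    vals <- numeric(0)
    for (r in seq_len(config$split_replicates)) {
      set.seed(config$seed * 1000L + r)
      tr <- sample(n) <= round(config$split_ratio * n)
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        warning("degenerate single-class split skipped (k=", k,
                ", replicate ", r, ")")
        next
      }
      sc <- standardize_fit(x[tr, cols, drop = FALSE])
      m <- fit_svm(standardize_apply(x[tr, cols, drop = FALSE], sc),
                   y[tr], C = 1, gamma = 1 / k)
      pred <- decision_svm(
        m, standardize_apply(x[!tr, cols, drop = FALSE], sc)) > 0
      vals <- c(vals, mcc_from_labels(pred, y[!tr]))
    }
    means[k] <- if (length(vals)) mean(vals) else NA_real_
    sds[k] <- if (length(vals) > 1L) stats::sd(vals) else NA_real_
  }
  if (all(is.na(means))) {
    stop("forward_select: every split replicate was degenerate")
  }
  target <- max(means, na.rm = TRUE) - config$selection_epsilon
  k_sel <- which(means >= target)[1]
  list(k = k_sel, features = feats[seq_len(k_sel)],
       mcc_by_k = data.frame(k = seq_len(K), mean_mcc = means,
                             sd_mcc = sds))
}

#' Train the RBF-SVM on selected features
#'
#' Standardization is fitted on the training data only; C and gamma are
#' chosen by `cv_folds`-fold cross-validated grid search maximizing MCC,
#' and the final machine is refitted on all training data with the best
#' parameters.
#'
#' @param x feature matrix.
#' @param y logical labels (TRUE = positive / miRNA).
#' @param features selected feature names.
#' @param config a [model_config()].
#' @return a `TrainedModel`: feature names, scaler, best C / gamma,
#'   support data, cross-validated MCC and seed.
#' @export
train_model <- function(x, y, features = colnames(x),
                        config = model_config()) {
  if (length(unique(y)) < 2L) stop("training needs both classes")
  xs <- as.matrix(x[, features, drop = FALSE])
  best <- grid_search_cv(xs, y, config)
  sc <- standardize_fit(xs)
  m <- fit_svm(standardize_apply(xs, sc), y, best$C, best$gamma)
  structure(list(features = features, scaler = sc, C = best$C,
                 gamma = best$gamma, sv = m$sv, coef = as.numeric(m$coef),
                 b = m$b, cv_mcc = best$mcc, seed = config$seed),
            class = "TrainedModel")
}

#' @export
print.TrainedModel <- function(x, ...) {
  cat(sprintf(
    "<TrainedModel: %d features, C=%g, gamma=%g, CV MCC=%.3f, %d SVs>\n",
    length(x$features), x$C, x$gamma, x$cv_mcc, nrow(x$sv)))
  invisible(x)
}

#' Predict cluster labels with a trained model
#'
#' @param object a `TrainedModel`.
#' @param newdata feature matrix (must contain the model's features;
#'   unknown requested features raise an error).
#' @param ... unused.
#' @return data frame: `decision` (SVM decision value), `label`
#'   (logical, decision > 0).
#' @export
predict.TrainedModel <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) {
    stop("missing features: ", paste(missing, collapse = ", "))
  }
  xs <- as.matrix(newdata[, object$features, drop = FALSE])
  xs[is.na(xs)] <- 0                      # imputation rule: absent -> 0
  dec <- svm_decision_cpp(object$sv, as.numeric(object$coef), object$b,
                          object$gamma,
                          standardize_apply(xs, object$scaler))
  data.frame(decision = dec, label = dec > 0)
}

#' Quality scores from decision values
#'
#' Predictions are ranked by decision value descending; the score is
#' 1 - rank/N, so the best of N scores (N-1)/N and the worst scores 0.
#' Ties share the mean of their ranks.
#'
#' @param decision numeric decision values.
#' @return scores in \[0, 1\].
#' @export
quality_score <- function(decision) {
  n <- length(decision)
  if (!n) return(numeric(0))
  r <- rank(-decision, ties.method = "average")
  1 - r / n
}

#' Serialize / restore a trained model as JSON
#'
#' Versioned plain-text container: feature names, scaler, kernel
#' parameters and support data; no binary serialization.
#'
#' @param model a `TrainedModel`.
#' @param path output path.
#' @export
write_model <- function(model, path) {
  obj <- list(format = "srnakit-svm", version = 1L,
              features = model$features,
              scaler_mean = as.numeric(model$scaler$mean),
              scaler_scale = as.numeric(model$scaler$scale),
              C = model$C, gamma = model$gamma,
              sv = unname(as.matrix(model$sv)),
              coef = model$coef, b = model$b, cv_mcc = model$cv_mcc,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "srnakit-svm")) {
    stop("not an srnakit model file: ", path)
  }
  sv <- if (is.matrix(obj$sv)) obj$sv else
    do.call(rbind, lapply(obj$sv, as.numeric))
  structure(list(features = obj$features,
                 scaler = list(mean = stats::setNames(obj$scaler_mean,
                                                      obj$features),
                               scale = stats::setNames(obj$scaler_scale,
                                                       obj$features)),
                 C = obj$C, gamma = obj$gamma, sv = sv,
                 coef = as.numeric(obj$coef), b = obj$b,
                 cv_mcc = obj$cv_mcc, seed = obj$seed),
            class = "TrainedModel")
}
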