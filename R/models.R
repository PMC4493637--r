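#' Train a phosphorylation-site predictor
#'
#' Fits the full pipeline on labeled training fragments: encode under the
#' chosen scheme, fit a per-feature min-max scaler on the training features,
#' reduce combined encodings with relief-F, and fit the classifier. Every
#' fitted component (scaler ranges, retained feature identifiers, KNN
#' reference fragments) is stored in the returned model so that prediction
#' uses training-time state only.
#'
#' SVM (radial-basis kernel) and the k-nearest-neighbour classifier consume
#' features scaled to `[0, 1]` by the training ranges; the tree-based
#' classifiers consume raw features, which are invariant to monotone
#' per-feature rescaling anyway.
#'
#' @param fragments Labeled training fragment tibble (both classes present).
#' @param scheme Encoding scheme (see [encode_fragments()]).
#' @param classifier `"svm"` (RBF kernel, the default), `"rf"` (random
#'   forest), `"dt"` (decision tree, Gini splits) or `"knnc"` (k-nearest
#'   neighbours).
#' @param target_dim Retained dimension after relief-F for combined schemes;
#'   `NULL` uses the scheme default (AF-KNN 27, AF-CKSAAP 952, CKSAAP-KNN
#'   939). Sole schemes are never reduced.
#' @param relieff_neighbors,relieff_sample Relief-F neighbours and instance
#'   sample size (see [relieff_weights()]).
#' @param cost,gamma SVM cost and RBF width. `gamma = NULL` (default) uses
#'   the variance-scaled heuristic `1 / (d * Var(X))`, with `d` the retained
#'   dimension and `Var(X)` the mean per-feature variance of the scaled
#'   training matrix; pass `"1/d"` for the plain dimension-reciprocal, or a
#'   number.
#' @param tune Run an inner 3-fold grid search for the SVM over
#'   `cost` in 0.1/1/10/100 and `gamma` in `{g * 4^j, j = -2..2}` (with `g`
#'   the default width), selecting the pair with the best inner
#'   cross-validated MCC. Ignored for the other families.
#' @param n_trees Random-forest size (default 100).
#' @param mtry Features tried per random-forest split; `NULL` =
#'   `floor(sqrt(d))`.
#' @param knn_k Neighbourhood size of the KNN classifier (odd, default 5).
#' @param k_max,knn_fractions Encoding parameters (see
#'   [encode_fragments()]).
#' @param seed Integer seed; the whole fit is deterministic given it.
#' @param threshold Decision threshold on the classifier score; `NULL` uses
#'   0 for the SVM decision value and 0.5 for the vote/proportion scores of
#'   the other families.
#' @return A `phossite_model` object.
#' @seealso [predict.phossite_model()], [cross_validate()],
#'   [evaluate_predictor()]
#' @export
phossite <- function(fragments, scheme = "AF-CKSAAP",
                     classifier = c("svm", "rf", "dt", "knnc"),
                     target_dim = NULL, relieff_neighbors = 10L,
                     relieff_sample = NULL, cost = 1, gamma = NULL,
                     tune = FALSE, n_trees = 100L, mtry = NULL, knn_k = 5L,
                     k_max = 5L, knn_fractions = DEFAULT_KNN_FRACTIONS,
                     seed = 1L, threshold = NULL) {
  classifier <- match.arg(classifier)
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  check_fragments(fragments, require_label = TRUE)
  if (!all(CLASS_LEVELS %in% fragments$label)) {
    abort("Training data must contain both classes",
      class = "phossite_data_error"
    )
  }

  uses_knn <- grepl("KNN", scheme)
  sim <- if (uses_knn) normalized_blosum62() else NULL
  x <- encode_fragments(
    fragments,
    scheme = scheme, refs = if (uses_knn) fragments else NULL,
    k_max = k_max, knn_fractions = knn_fractions, sim = sim,
    exclude_self = TRUE
  )
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    abort(
      paste0(
        "Non-finite feature value at fragment ", rownames(x)[bad[1]],
        ", feature ", colnames(x)[bad[2]]
      ),
      class = "phossite_data_error"
    )
  }

  y <- factor(fragments$label, levels = CLASS_LEVELS)

  # relief-F reduction for combined encodings, fit on training data only
  td <- target_dim %||% default_target_dim(scheme, ncol(x))
  weights <- NULL
  if (td < ncol(x)) {
    weights <- relieff_weights(x, fragments$label,
      neighbors = relieff_neighbors,
      sample_size = relieff_sample, seed = seed
    )
    sel <- select_top(x, weights, td)
    x <- sel$x
  }
  retained <- colnames(x)

  scaler <- list(
    min = apply(x, 2L, min),
    max = apply(x, 2L, max)
  )
  d <- ncol(x)
  xs <- apply_scaler(x, scaler)
  fit_gamma <- default_gamma(xs, gamma)
  set.seed(seed)
  if (tune && classifier == "svm") {
    tuned <- tune_svm_grid(xs, y, fit_gamma, seed)
    cost <- tuned$cost
    fit_gamma <- tuned$gamma
    set.seed(seed)
  }
  fit <- switch(classifier,
    svm = e1071::svm(
      x = xs, y = y, kernel = "radial", cost = cost, gamma = fit_gamma,
      scale = FALSE
    ),
    rf = randomForest::randomForest(
      x = x, y = y, ntree = n_trees,
      mtry = mtry %||% max(1L, floor(sqrt(d)))
    ),
    dt = {
      df <- as.data.frame(x)
      names(df) <- make.names(colnames(x))
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
        parms = list(split = "gini")
      )
    },
    knnc = list(train = xs, y = y, k = knn_k)
  )

  structure(
    list(
      fit = fit,
      classifier = classifier,
      scheme = scheme,
      params = list(
        k_max = k_max, knn_fractions = knn_fractions, target_dim = td,
        cost = cost, gamma = fit_gamma, n_trees = n_trees,
        mtry = mtry %||% max(1L, floor(sqrt(d))), knn_k = knn_k,
        relieff_neighbors = relieff_neighbors, seed = seed
      ),
      retained = retained,
      weights = weights,
      scaler = scaler,
      refs = if (uses_knn) {
        fragments[c("protein_id", "position", "residue", "label", "sequence")]
      } else {
        NULL
      },
      training_keys = fragment_keys(fragments),
      n_train = nrow(fragments),
      threshold = threshold %||% if (classifier == "svm") 0 else 0.5,
      schema_version = 1L
    ),
    class = "phossite_model"
  )
}

# RBF kernel width. The plain 1/d reciprocal is a poor width for min-max
# scaled sparse pair features (the kernel goes flat), so the default follows
# the variance-scaled heuristic 1 / (d * mean per-feature variance).
default_gamma <- function(xs, gamma) {
  if (is.numeric(gamma)) {
    return(gamma)
  }
  d <- ncol(xs)
  if (identical(gamma, "1/d")) {
    return(1 / d)
  }
  v <- mean(apply(xs, 2L, stats::var))
  if (!is.finite(v) || v <= 0) 1 / d else 1 / (d * v)
}

# Inner stratified 3-fold grid search over (cost, gamma), scored by MCC;
# ties resolved toward the first grid point (smaller cost, then gamma).
tune_svm_grid <- function(xs, y, base_gamma, seed) {
  grid <- expand.grid(
    cost = c(0.1, 1, 10, 100),
    gamma = base_gamma * 4^(-2:2)
  )
  folds <- assign_folds(as.character(y), 3L, seed = seed)
  best <- list(mcc = -Inf, cost = grid$cost[1], gamma = grid$gamma[1])
  for (g in seq_len(nrow(grid))) {
    preds <- character(length(y))
    for (f in 1:3) {
      set.seed(seed)
      fit <- e1071::svm(
        x = xs[folds != f, , drop = FALSE], y = y[folds != f],
        kernel = "radial", cost = grid$cost[g], gamma = grid$gamma[g],
        scale = FALSE
      )
      preds[folds == f] <- as.character(
        predict(fit, xs[folds == f, , drop = FALSE])
      )
    }
    mcc <- suppressMessages(
      metrics_from_labels(as.character(y), preds)$mcc
    )
    if (mcc > best$mcc) {
      best <- list(mcc = mcc, cost = grid$cost[g], gamma = grid$gamma[g])
    }
  }
  best
}

apply_scaler <- function(x, scaler) {
  rng <- scaler$max - scaler$min
  rng[rng <= 0] <- 1
  xs <- sweep(x, 2L, scaler$min, "-")
  sweep(xs, 2L, rng, "/")
}

# Encode new fragments exactly as the model was trained, restricted to the
# retained features.
model_features <- function(object, fragments, exclude_self = FALSE) {
  uses_knn <- grepl("KNN", object$scheme)
  x <- encode_fragments(
    fragments,
    scheme = object$scheme, refs = object$refs,
    k_max = object$params$k_max,
    knn_fractions = object$params$knn_fractions,
    sim = if (uses_knn) normalized_blosum62() else NULL,
    exclude_self = exclude_self
  )
  x[, object$retained, drop = FALSE]
}

#' Continuous decision scores for fragments
#'
#' Larger scores indicate a more phosphosite-like fragment. For the SVM the
#' score is the signed distance to the separating hyperplane (positive side
#' = positive class); for the random forest the fraction of trees voting
#' positive; for the decision tree the positive proportion of the assigned
#' leaf; for the KNN classifier the fraction of positive neighbours.
#'
#' @param object A `phossite_model`.
#' @param fragments Fragment tibble to score.
#' @param exclude_self Exclude each query from the KNN-encoding reference
#'   pool when it is part of the training references (cross-validation use).
#' @return Numeric vector of scores, one per fragment.
#' @export
decision_scores <- function(object, fragments, exclude_self = FALSE) {
  stopifnot(inherits(object, "phossite_model"))
  check_fragments(fragments)
  x <- model_features(object, fragments, exclude_self = exclude_self)
  switch(object$classifier,
    svm = {
      xs <- apply_scaler(x, object$scaler)
      pred <- predict(object$fit, xs, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      # e1071 orients the decision value toward the first named class
      if (grepl("^positive/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    },
    rf = unname(predict(object$fit, x, type = "prob")[, "positive"]),
    dt = {
      df <- as.data.frame(x)
      names(df) <- make.names(colnames(x))
      unname(predict(object$fit, df, type = "prob")[, "positive"])
    },
    knnc = {
      xs <- apply_scaler(x, object$scaler)
      pred <- class::knn(
        train = object$fit$train, test = xs, cl = object$fit$y,
        k = object$fit$k, prob = TRUE
      )
      p <- attr(pred, "prob")
      ifelse(pred == "positive", p, 1 - p)
    }
  )
}

#' Predict phosphorylation labels and scores
#'
#' @param object A `phossite_model`.
#' @param fragments Fragment tibble to score.
#' @param threshold Decision threshold; scores greater than or equal to it
#'   are called positive. `NULL` uses the model default (0 for SVM decision
#'   values, 0.5 for the other families).
#' @param exclude_self See [decision_scores()].
#' @param ... Unused.
#' @return The fragment tibble with added columns `score` and `label_pred`.
#' @export
predict.phossite_model <- function(object, fragments, threshold = NULL,
                                   exclude_self = FALSE, ...) {
  thr <- threshold %||% object$threshold
  scores <- decision_scores(object, fragments, exclude_self = exclude_self)
  out <- as_tibble(fragments)
  out$score <- as.numeric(scores)
  out$label_pred <- ifelse(out$score >= thr, "positive", "negative")
  out
}

#' Scan whole proteins for candidate phosphorylation sites
#'
#' Extracts the 25-mer window around every S, T and Y residue of every
#' input protein and scores it with the model.
#'
#' @param object A `phossite_model`.
#' @param sequences Tibble from [read_fasta()].
#' @param threshold Decision threshold (`NULL` = model default).
#' @return A tibble with columns `protein_id`, `position`, `residue`,
#'   `score`, `label` (1-based positions), one row per S/T/Y.
#' @export
scan_proteins <- function(object, sequences, threshold = NULL) {
  sites <- sty_candidates(sequences)
  if (nrow(sites) == 0L) {
    return(tibble(
      protein_id = character(), position = integer(),
      residue = character(), score = numeric(), label = character()
    ))
  }
  seq_lookup <- setNames(sequences$sequence, sequences$protein_id)
  sites$sequence <- vapply(
    seq_len(nrow(sites)),
    function(i) extract_fragment(seq_lookup[[sites$protein_id[i]]], sites$position[i]),
    character(1)
  )
  pred <- predict(object, sites, threshold = threshold)
  tibble(
    protein_id = pred$protein_id, position = pred$position,
    residue = pred$residue, score = pred$score, label = pred$label_pred
  )
}

#' Save / load a trained predictor
#'
#' The archive holds the classifier state, encoding scheme and parameters,
#' retained feature identifiers, training scaler ranges, the KNN reference
#' fragments when the scheme needs them, and a schema version checked at
#' load time.
#'
#' @param object A `phossite_model`.
#' @param path Archive path.
#' @return `path` (save) or the restored `phossite_model` (load).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "phossite_model"))
  saveRDS(object, path, version = 2L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Model archive not found: ", path), class = "phossite_io_error")
  }
  object <- readRDS(path)
  if (!inherits(object, "phossite_model")) {
    abort("File is not a phossite model archive", class = "phossite_io_error")
  }
  if (!identical(object$schema_version, 1L)) {
    abort(
      paste0(
        "Model schema version ", object$schema_version,
        " is not supported by this package version (expects 1)"
      ),
      class = "phossite_io_error"
    )
  }
  object
}

#' @export
print.phossite_model <- function(x, ...) {
  cat("<phossite_model>\n")
  cat("  classifier:", x$classifier, "  scheme:", x$scheme, "\n")
  cat(
    "  features retained:", length(x$retained), "  training fragments:",
    x$n_train, "\n"
  )
  cat("  decision threshold:", x$threshold, "  seed:", x$params$seed, "\n")
  invisible(x)
}

#' Tidy a trained predictor
#'
#' Returns one row per retained feature with its relief-F weight and rank
#' when feature selection was applied, or just the retained layout
#' otherwise.
#'
#' @param x A `phossite_model`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `weight`, `rank`.
#' @export
tidy.phossite_model <- function(x, ...) {
  if (is.null(x$weights)) {
    return(tibble(
      feature = x$retained, weight = NA_real_,
      rank = seq_along(x$retained)
    ))
  }
  out <- x$weights[x$weights$feature %in% x$retained, ]
  as_tibble(out)
}

#' Summarise a trained predictor in one row
#'
#' @param x A `phossite_model`.
#' @param ... Unused.
#' @return A one-row tibble with the model configuration.
#' @export
glance.phossite_model <- function(x, ...) {
  tibble(
    classifier = x$classifier, scheme = x$scheme,
    n_features = length(x$retained), n_train = x$n_train,
    threshold = x$threshold, seed = x$params$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
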