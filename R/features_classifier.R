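# Per-cluster feature vectors (SASA burial + mediated-triplet probabilities)
# and a one-vs-one multiclass linear SVM over them.

#' @include interaction_analysis.R
NULL

#' Feature column names of the cluster feature vector
#'
#' Four per-kind SASA burial ratios (peptide, drug, Zn2+, NO3-) followed by
#' the twelve canonical triplet probabilities, 16 features in total.
#'
#' @export
FEATURE_NAMES <- c("sasa_peptide", "sasa_drug", "sasa_zn", "sasa_no3",
                   paste0("trip_", TRIPLET_PATTERNS))

#' Assemble per-cluster feature vectors
#'
#' Combines the SASA columns of [cluster_stats()] rows with per-cluster
#' triplet probabilities from [mediated_triplets()]. A kind absent from a
#' cluster has no SASA ratio and is imputed as 0, as are unobserved triplet
#' patterns.
#'
#' @param stats data.frame of per-cluster statistics, one row per cluster.
#' @param profiles list of [mediated_triplets()] results aligned with
#'   `stats` rows.
#' @param labels optional class label per cluster (factor or character).
#' @return data.frame with the 16 [FEATURE_NAMES] columns and, when given,
#'   a `label` column.
#' @export
assemble_features <- function(stats, profiles, labels = NULL) {
  if (length(profiles) != nrow(stats))
    stop("stats rows and profiles are misaligned")
  if (!is.null(labels) && length(labels) != nrow(stats))
    stop("labels are misaligned with stats rows")
  sasa <- as.matrix(stats[, c("sasa_peptide", "sasa_drug", "sasa_zn",
                              "sasa_no3")])
  sasa[is.na(sasa)] <- 0
  trip <- do.call(rbind, lapply(profiles, function(p) p$probability))
  trip[is.na(trip)] <- 0
  out <- as.data.frame(cbind(sasa, trip))
  names(out) <- FEATURE_NAMES
  if (!all(is.finite(as.matrix(out)))) stop("non-finite feature values")
  if (!is.null(labels)) out$label <- as.character(labels)
  out
}

feature_matrix <- function(features) {
  miss <- setdiff(FEATURE_NAMES, names(features))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  as.matrix(features[, FEATURE_NAMES])
}

#' Train a one-vs-one multiclass linear SVM
#'
#' Standardizes every feature to training-set mean 0 / sd 1 (constant
#' features are left unscaled), fits one linear-kernel binary support-vector
#' learner per unordered class pair, and predicts by majority vote with ties
#' broken toward the lowest class index.
#'
#' @param features data.frame with the [FEATURE_NAMES] columns.
#' @param labels class label per row; at least two classes with >= 5 rows
#'   each.
#' @param seed integer seed recorded with the model.
#' @param cost soft-margin cost of the binary learners.
#' @return an object of class `coassembly_svm`.
#' @export
train_multiclass_svm <- function(features, labels, seed = 1L, cost = 1.0) {
  x <- feature_matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels are misaligned with features")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  if (any(table(labels) < 5L)) stop("need at least 5 rows per class")
  set.seed(as.integer(seed))
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  xs <- scale(x, center = mu, scale = sdev)
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  learners <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    e1071::svm(xs[sel, , drop = FALSE],
               factor(labels[sel], levels = pr),
               kernel = "linear", cost = cost, scale = FALSE)
  })
  names(learners) <- vapply(pairs, paste, "", collapse = "|")
  structure(list(learners = learners, pairs = pairs, classes = classes,
                 center = mu, scale = sdev, cost = cost,
                 seed = as.integer(seed)),
            class = "coassembly_svm")
}

#' @export
print.coassembly_svm <- function(x, ...) {
  cat(sprintf("one-vs-one linear SVM: %d classes (%s), %d binary learners, cost %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$learners), x$cost))
  invisible(x)
}

#' @export
predict.coassembly_svm <- function(object, newdata, ...) {
  classify_clusters(object, newdata)$labels
}

#' Classify feature vectors and expose per-pair decision values
#'
#' @param model a `coassembly_svm`.
#' @param features data.frame with the [FEATURE_NAMES] columns.
#' @return list with `labels` (character), `votes` (matrix rows x classes)
#'   and `decision_values` (matrix rows x class pairs; positive favors the
#'   first class of the pair).
#' @export
classify_clusters <- function(model, features) {
  x <- feature_matrix(features)
  if (ncol(x) != length(model$center)) stop("feature dimension mismatch")
  xs <- scale(x, center = model$center, scale = model$scale)
  votes <- matrix(0L, nrow(x), length(model$classes),
                  dimnames = list(NULL, model$classes))
  dv <- matrix(NA_real_, nrow(x), length(model$learners),
               dimnames = list(NULL, names(model$learners)))
  for (k in seq_along(model$learners)) {
    pr <- model$pairs[[k]]
    p <- predict(model$learners[[k]], xs, decision.values = TRUE)
    dvk <- attr(p, "decision.values")
    # orient so positive favors the first class of the pair
    sgn <- if (colnames(dvk)[1] == paste(pr[1], pr[2], sep = "/")) 1 else -1
    dv[, k] <- sgn * dvk[, 1]
    win <- as.character(p)
    for (cls in pr) votes[, cls] <- votes[, cls] + (win == cls)
  }
  labels <- model$classes[apply(votes, 1, which.max)]  # ties: lowest index
  list(labels = labels, votes = votes, decision_values = dv)
}

#' Linear feature weights of each binary learner
#'
#' For linear kernels the decision function is `w . x + b` in standardized
#' feature space; the weight magnitudes indicate which features drive each
#' class pair's separation.
#'
#' @param model a `coassembly_svm`.
#' @return matrix, one row per class pair, columns = [FEATURE_NAMES].
#' @export
svm_feature_weights <- function(model) {
  w <- t(vapply(model$learners, function(m)
    as.numeric(crossprod(m$coefs, m$SV)), numeric(length(FEATURE_NAMES))))
  colnames(w) <- FEATURE_NAMES
  rownames(w) <- names(model$learners)
  w
}

#' Cross-validated accuracy of the one-vs-one SVM
#'
#' Stratified k-fold cross-validation; standardization is refit inside every
#' training fold so no test-fold information leaks into it.
#'
#' @param features data.frame with the [FEATURE_NAMES] columns.
#' @param labels class label per row.
#' @param k number of folds.
#' @param seed integer seed (fold assignment).
#' @param cost learner cost.
#' @return mean held-out accuracy.
#' @export
svm_cv_accuracy <- function(features, labels, k = 5L, seed = 1L, cost = 1.0) {
  labels <- as.character(labels)
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_multiclass_svm(features[tr, , drop = FALSE], labels[tr],
                                  seed = seed, cost = cost)
    mean(classify_clusters(model, features[!tr, , drop = FALSE])$labels ==
           labels[!tr])
  }, 0)
  mean(acc)
}
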