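#' Select common, well-called autosomal variants for ancestry inference
#'
#' Population structure is read from common variation; rare variants add
#' noise and sex chromosomes add sex structure, so PCA input is restricted
#' to autosomal variants with cohort minor allele frequency and call rate
#' above thresholds.
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param annotation Variant annotation with `variant_key` and `chrom`.
#' @param maf_min Minimum cohort minor allele frequency (default 0.05).
#' @param call_rate_min Minimum fraction of non-missing calls (default
#'   0.95).
#' @return Character vector of retained variant keys.
#' @export
select_common_variants <- function(genotypes, annotation,
                                   maf_min = 0.05, call_rate_min = 0.95) {
  if (nrow(genotypes) == 0L || ncol(genotypes) == 0L) {
    stop("empty genotype matrix")
  }
  autosomal <- annotation$variant_key[annotation$chrom %in% as.character(1:22)]
  keys <- intersect(colnames(genotypes), autosomal)
  sub <- genotypes[, keys, drop = FALSE]
  call_rate <- colMeans(!is.na(sub))
  af <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- keys[!is.na(maf) & maf >= maf_min & call_rate >= call_rate_min]
  if (length(keep) == 0L) {
    stop("no variant passes MAF >= ", maf_min, " and call rate >= ",
         call_rate_min, "; PCA impossible")
  }
  keep
}

#' Fit the PCA stage of an ancestry model
#'
#' Centered, variance-scaled principal component analysis of the dosage
#' matrix restricted to a common-variant subset. Missing dosages are
#' mean-imputed per variant (the imputed value is the column mean, i.e.
#' zero after centering, so missing calls are neutral). Components are
#' ordered by decreasing explained variance and each loading column's sign
#' is fixed so that its largest-magnitude entry is positive, making fits
#' reproducible across platforms.
#'
#' @param genotypes Dosage matrix.
#' @param variant_subset Keys from [select_common_variants()].
#' @param n_components Number of retained components (default 10).
#' @return An object of class `"ancestry_model"` holding the variant
#'   subset, per-variant centers/scales, the loading matrix, per-component
#'   explained variance fractions, and sample scores of the fitting data.
#' @export
fit_pca <- function(genotypes, variant_subset, n_components = 10L) {
  x <- genotypes[, variant_subset, drop = FALSE]
  if (nrow(x) <= n_components) {
    stop("need more than ", n_components, " samples to fit ",
         n_components, " components; got ", nrow(x))
  }
  storage.mode(x) <- "double"
  centers <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- centers[j]
  }
  scales <- apply(x, 2, stats::sd)
  scales[scales == 0] <- 1
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")
  sv <- svd(xs, nu = 0, nv = n_components)
  loadings <- sv$v
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(loadings))) {
    peak <- which.max(abs(loadings[, j]))
    if (loadings[peak, j] < 0) loadings[, j] <- -loadings[, j]
  }
  dimnames(loadings) <- list(variant_subset,
                             paste0("PC", seq_len(n_components)))
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- xs %*% loadings
  rownames(scores) <- rownames(genotypes)
  structure(list(
    variant_subset = variant_subset,
    centers = centers,
    scales = scales,
    loadings = loadings,
    explained_variance = ev[seq_len(n_components)],
    scores = scores,
    classifier = NULL,
    label_set = NULL,
    confidence_threshold = 0.8
  ), class = "ancestry_model")
}

#' Project samples onto a fitted PCA
#'
#' Uses the stored centering, scaling and loadings; never refits. Missing
#' dosages are imputed with the stored per-variant means.
#'
#' @param model An `"ancestry_model"`.
#' @param genotypes Dosage matrix containing the model's variant subset.
#' @return Scores matrix (samples x components).
#' @export
project_scores <- function(model, genotypes) {
  missing_keys <- setdiff(model$variant_subset, colnames(genotypes))
  if (length(missing_keys)) {
    stop("genotype matrix lacks ", length(missing_keys),
         " model variants, e.g.: ",
         paste(utils::head(missing_keys, 5), collapse = ", "))
  }
  x <- genotypes[, model$variant_subset, drop = FALSE]
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- model$centers[j]
  }
  xs <- sweep(sweep(x, 2, model$centers), 2, model$scales, "/")
  scores <- xs %*% model$loadings
  rownames(scores) <- rownames(genotypes)
  scores
}

#' Remove self-report outliers from the training set
#'
#' Self-reported ethnicity is error-prone; a sample whose PC-space position
#' does not cluster with its reported label would poison classifier
#' training. Each sample's squared Mahalanobis distance to its reported
#' label's centroid is compared against the chi-square quantile with as
#' many degrees of freedom as components; samples beyond it are dropped.
#'
#' Two estimation choices make the rule work at realistic training-group
#' sizes (a few dozen samples per label):
#' \itemize{
#'   \item The metric defaults to the \emph{pooled} within-label covariance
#'     (ridge-regularized), estimated from all filterable labels after
#'     centering each on its own centroid. A label-specific 10x10
#'     covariance from ~30 samples is so noisy that true outliers both
#'     inflate it and bump against the hard upper bound on sample
#'     Mahalanobis distances, masking themselves; the pooled estimate
#'     sidesteps both problems. `covariance = "label"` restores the
#'     per-label metric for large groups.
#'   \item Trimming is iterative: after outliers are removed, centroids and
#'     covariance are re-estimated from the inliers and all samples
#'     re-scored, until stable. A single pass lets clustered mislabels
#'     stretch the metric along exactly the directions that separate
#'     populations.
#' }
#'
#' Labels with fewer than `min_group` samples pass through unfiltered with
#' a warning, since their centroid/covariance cannot be estimated.
#'
#' @param scores Samples x components score matrix.
#' @param reported_labels Character vector aligned with `scores` rows.
#' @param distance_quantile Chi-square quantile beyond which a sample is an
#'   outlier (default 0.99, i.e. about 1 percent of well-labelled samples
#'   are sacrificed).
#' @param min_group Minimum label size for filtering (default 11).
#' @param ridge Relative ridge added to the covariance diagonal.
#' @param max_iter Maximum trimming iterations (default 10; usually 2-3
#'   suffice).
#' @param covariance "pooled" (default) or "label".
#' @return Logical vector: `TRUE` for retained training samples.
#' @export
remove_label_outliers <- function(scores, reported_labels,
                                  distance_quantile = 0.99,
                                  min_group = 11L, ridge = 1e-3,
                                  max_iter = 10L,
                                  covariance = c("pooled", "label")) {
  covariance <- match.arg(covariance)
  stopifnot(nrow(scores) == length(reported_labels))
  d <- ncol(scores)
  cutoff <- stats::qchisq(distance_quantile, df = d)
  labs <- unique(reported_labels)
  sizes <- table(reported_labels)
  small <- names(sizes)[sizes < min_group]
  for (lab in small) {
    warning("label '", lab, "' has only ", sizes[lab],
            " samples; outlier filtering skipped for it")
  }
  filterable <- reported_labels %in% setdiff(labs, small)

  keep <- rep(TRUE, nrow(scores))
  if (covariance == "pooled") {
    for (it in seq_len(max_iter)) {
      mus <- list()
      centered <- scores
      for (lab in setdiff(labs, small)) {
        in_lab <- reported_labels == lab
        mus[[lab]] <- colMeans(scores[in_lab & keep, , drop = FALSE])
        centered[in_lab, ] <- sweep(scores[in_lab, , drop = FALSE], 2,
                                    mus[[lab]])
      }
      sigma <- stats::cov(centered[filterable & keep, , drop = FALSE])
      sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-12, d)
      new_keep <- rep(TRUE, nrow(scores))
      for (lab in setdiff(labs, small)) {
        idx <- which(reported_labels == lab)
        d2 <- stats::mahalanobis(scores[idx, , drop = FALSE],
                                 mus[[lab]], sigma)
        out <- d2 > cutoff
        if (sum(!out) < min_group) next   # refuse to trim a label away
        new_keep[idx[out]] <- FALSE
      }
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
    return(keep)
  }
  for (lab in setdiff(labs, small)) {
    idx <- which(reported_labels == lab)
    inlier <- rep(TRUE, length(idx))
    for (it in seq_len(max_iter)) {
      s <- scores[idx[inlier], , drop = FALSE]
      mu <- colMeans(s)
      sigma <- stats::cov(s)
      sigma <- sigma + diag(ridge * mean(diag(sigma)) + 1e-12, d)
      d2 <- stats::mahalanobis(scores[idx, , drop = FALSE], mu, sigma)
      new_inlier <- d2 <= cutoff
      if (sum(new_inlier) < min_group) break
      done <- identical(new_inlier, inlier)
      inlier <- new_inlier
      if (done) break
    }
    keep[idx[!inlier]] <- FALSE
  }
  keep
}

#' Train the ancestry classifier on PC scores
#'
#' Multinomial logistic regression (softmax) with a small L2 weight decay
#' on the retained training scores. The fit is deterministic: initial
#' weights come from a fixed internal seed and the optimizer settings are
#' fixed.
#'
#' @param model A fitted `"ancestry_model"` (PCA part).
#' @param scores Training score matrix.
#' @param labels Training labels (character), one per score row.
#' @param decay L2 weight decay passed to the optimizer.
#' @param confidence_threshold Minimum winning-class probability for a
#'   sample to be assigned (default 0.8); below it the sample is reported
#'   as "unassigned" and excluded from per-ancestry denominators downstream.
#' @return The model with `classifier`, `label_set` and
#'   `confidence_threshold` filled in.
#' @export
train_classifier <- function(model, scores, labels, decay = 1e-4,
                             confidence_threshold = 0.8) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    stop("classifier training needs at least 2 distinct labels")
  }
  df <- as.data.frame(scores)
  df$.label <- factor(labels, levels = sort(unique(labels)))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  set.seed(20230328L)   # fixed: nnet draws its initial weights from the RNG
  fit <- nnet::multinom(.label ~ ., data = df, decay = decay,
                        maxit = 500L, trace = FALSE, MaxNWts = 5000L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  model$classifier <- fit
  model$label_set <- levels(df$.label)
  model$confidence_threshold <- confidence_threshold
  model
}

#' Predict ancestry for a cohort
#'
#' Projects samples with the stored PCA and applies the trained softmax
#' classifier. The assigned label is the most probable class; its
#' probability is the confidence. Samples whose confidence falls below the
#' model threshold are labelled "unassigned" so that they never enter
#' ancestry-specific carrier-frequency denominators.
#'
#' @param model Trained `"ancestry_model"`.
#' @param genotypes Dosage matrix.
#' @return data.frame: `sample_id`, `ancestry` (may be "unassigned"),
#'   `best_label`, `confidence`, plus one probability column per label.
#' @export
predict_ancestry <- function(model, genotypes) {
  if (is.null(model$classifier)) stop("model has no trained classifier")
  scores <- project_scores(model, genotypes)
  probs <- stats::predict(model$classifier, newdata = as.data.frame(scores),
                          type = "probs")
  if (is.null(dim(probs))) {   # two-class fits return P(second level)
    probs <- cbind(1 - probs, probs)
    colnames(probs) <- model$label_set
  }
  probs <- probs[, model$label_set, drop = FALSE]
  best <- max.col(probs, ties.method = "first")
  confidence <- probs[cbind(seq_len(nrow(probs)), best)]
  best_label <- model$label_set[best]
  ancestry <- ifelse(confidence >= model$confidence_threshold,
                     best_label, "unassigned")
  out <- data.frame(sample_id = rownames(scores),
                    ancestry = ancestry,
                    best_label = best_label,
                    confidence = confidence,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(probs))
}

#' Fit the full ancestry model from a labelled training subset
#'
#' Convenience wrapper chaining [select_common_variants()], [fit_pca()],
#' [remove_label_outliers()] and [train_classifier()]: the PCA is fitted on
#' the whole cohort (structure estimation needs no labels), the outlier
#' rule and classifier use only the labelled training samples.
#'
#' @param genotypes Cohort dosage matrix.
#' @param annotation Variant annotation.
#' @param training_ids Sample ids with trusted self-reported labels.
#' @param training_labels Their reported ancestries.
#' @param maf_min,call_rate_min Passed to [select_common_variants()].
#' @param n_components Number of principal components (default 10).
#' @param distance_quantile Passed to [remove_label_outliers()].
#' @param confidence_threshold Passed to [train_classifier()].
#' @return Trained `"ancestry_model"` with an extra `training` element
#'   recording which training samples survived the outlier filter.
#' @export
fit_ancestry_model <- function(genotypes, annotation, training_ids,
                               training_labels,
                               maf_min = 0.05, call_rate_min = 0.95,
                               n_components = 10L,
                               distance_quantile = 0.99,
                               confidence_threshold = 0.8) {
  subset <- select_common_variants(genotypes, annotation,
                                   maf_min = maf_min,
                                   call_rate_min = call_rate_min)
  model <- fit_pca(genotypes, subset, n_components = n_components)
  tr_scores <- model$scores[training_ids, , drop = FALSE]
  keep <- remove_label_outliers(tr_scores, training_labels,
                                distance_quantile = distance_quantile)
  model <- train_classifier(model, tr_scores[keep, , drop = FALSE],
                            training_labels[keep],
                            confidence_threshold = confidence_threshold)
  model$training <- data.frame(sample_id = training_ids,
                               reported = training_labels,
                               retained = keep, stringsAsFactors = FALSE)
  model
}
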