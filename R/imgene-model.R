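#' Top-k feature selection by coefficient magnitude
#'
#' Keeps the `k` names with the largest absolute coefficients; ties break
#' lexicographically. Fewer than `k` available means all are retained.
#'
#' @param coefficients named numeric vector.
#' @param k number of features to keep (default 10).
#' @return character vector of selected names.
#' @export
select_features <- function(coefficients, k = 10) {
  if (length(coefficients) == 0) stop("no coefficients", call. = FALSE)
  ord <- order(-abs(coefficients), names(coefficients))
  names(coefficients)[ord][seq_len(min(k, length(coefficients)))]
}

#' Fit one feature-block SVM with leave-one-out tuning
#'
#' Grid-searches C, kernel and gamma by leave-one-out cross-validated
#' accuracy on the training set; decision scores are calibrated to \[0, 1\]
#' by min-max on the training scores; the classification cutoff is the
#' calibrated score maximizing accuracy on the validation scores (ties take
#' the lower cutoff). Zero-variance features are dropped with a warning.
#'
#' @param x training feature matrix (patients x features).
#' @param y binary 0/1 labels.
#' @param x_valid,y_valid validation block used only for cutoff selection
#'   (defaults to the training block).
#' @param grid data.frame of candidate hyperparameters with columns
#'   `cost`, `kernel`, `gamma` (default: C in 0.01..100, linear + rbf,
#'   gamma in 0.001..1).
#' @return list of class `block_svm`: `model`, `params`, `cutoff`,
#'   `loocv_accuracy`, `calibration` (min/max), `features`.
#' @export
fit_block_svm <- function(x, y, x_valid = NULL, y_valid = NULL,
                          grid = svm_grid()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  if (nrow(x) < 10) stop("need at least 10 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance features: ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  yf <- factor(y, c(0, 1))
  best <- NULL; best_acc <- -1
  for (g in seq_len(nrow(grid))) {
    acc <- loocv_accuracy(x, yf, cost = grid$cost[g],
                          kernel = grid$kernel[g], gamma = grid$gamma[g])
    if (acc > best_acc) { best_acc <- acc; best <- grid[g, ] }
  }
  model <- suppressWarnings(
    e1071::svm(x, yf, type = "C-classification", kernel = best$kernel,
               cost = best$cost, gamma = best$gamma, scale = TRUE))
  tr_scores <- svm_decision(model, x)
  lo <- min(tr_scores); hi <- max(tr_scores)
  if (hi <= lo) hi <- lo + 1
  calib <- function(s) pmin(pmax((s - lo) / (hi - lo), 0), 1)
  if (is.null(x_valid)) { x_valid <- x; y_valid <- y }
  va_scores <- calib(svm_decision(model, as.matrix(x_valid)))
  cutoff <- pick_cutoff(va_scores, y_valid)
  structure(list(model = model, params = best, cutoff = cutoff,
                 loocv_accuracy = best_acc,
                 calibration = c(lo = lo, hi = hi),
                 features = colnames(x)),
            class = "block_svm")
}

svm_grid <- function() {
  rbind(
    data.frame(cost = c(0.01, 0.1, 1, 10, 100), kernel = "linear", gamma = 0.1),
    expand.grid(cost = c(0.01, 0.1, 1, 10, 100), kernel = "radial",
                gamma = c(0.001, 0.01, 0.1, 1), stringsAsFactors = FALSE))
}

# decision values oriented so larger = class "1"
svm_decision <- function(model, x) {
  dvm <- attr(suppressWarnings(
    stats::predict(model, x, decision.values = TRUE)), "decision.values")
  dv <- dvm[, 1]
  if (grepl("^1", colnames(dvm)[1])) dv else -dv
}

loocv_accuracy <- function(x, yf, cost, kernel, gamma) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    yi <- yf[-i]
    if (length(unique(yi)) < 2) { pred[i] <- NA; next }
    m <- suppressWarnings(
      e1071::svm(x[-i, , drop = FALSE], yi, type = "C-classification",
                 kernel = kernel, cost = cost, gamma = gamma, scale = TRUE))
    pred[i] <- as.character(suppressWarnings(
      stats::predict(m, x[i, , drop = FALSE])))
  }
  mean(pred == as.character(yf), na.rm = TRUE)
}

# cutoff maximizing accuracy; ties -> lower cutoff
pick_cutoff <- function(scores, y) {
  cand <- sort(unique(c(0, scores, 1)))
  acc <- vapply(cand, function(ct) mean((scores >= ct) == (y == 1)),
                numeric(1))
  cand[which.max(acc)]  # which.max takes the first (lowest) maximizer
}

#' Score a fitted block SVM
#'
#' @param block a `block_svm`.
#' @param x feature matrix.
#' @return calibrated scores in \[0, 1\].
#' @export
score_block_svm <- function(block, x) {
  s <- svm_decision(block$model, as.matrix(x)[, block$features, drop = FALSE])
  lo <- block$calibration["lo"]; hi <- block$calibration["hi"]
  unname(pmin(pmax((s - lo) / (hi - lo), 0), 1))
}

#' ImGene integration formula
#'
#' Pr = exp(Z) / (1 + exp(Z)) with
#' Z = intercept + beta_im * im_score + beta_gene * gene_score. The default
#' intercept is the published 3.51.
#'
#' @param im_score,gene_score calibrated sub-model scores.
#' @param beta_im,beta_gene integration coefficients.
#' @param intercept integration intercept (default 3.51).
#' @return probability in (0, 1).
#' @export
integrate_scores <- function(im_score, gene_score, beta_im, beta_gene,
                             intercept = 3.51) {
  if (any(!is.finite(c(im_score, gene_score, beta_im, beta_gene, intercept))))
    stop("non-finite input to integration", call. = FALSE)
  stats::plogis(intercept + beta_im * im_score + beta_gene * gene_score)
}

#' Classification metrics at a cutoff
#'
#' Rank-based ROC AUC plus F1 and accuracy at the given cutoff. AUC is
#' reported NA when only one class is present.
#'
#' @param prob predicted probabilities/scores.
#' @param labels binary 0/1 truth.
#' @param cutoff classification threshold.
#' @return list of class `eval_report`: `auc`, `f1`, `accuracy`, `cutoff`.
#' @export
evaluate_predictions <- function(prob, labels, cutoff = 0.5) {
  labels <- as.numeric(labels)
  auc <- if (length(unique(labels)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(labels, prob, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  pred <- as.numeric(prob >= cutoff)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  structure(list(auc = auc, f1 = f1, accuracy = mean(pred == labels),
                 cutoff = cutoff), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f | F1 %.3f | accuracy %.3f (cutoff %.3f)\n",
              x$auc, x$f1, x$accuracy, x$cutoff))
  invisible(x)
}

#' Train the integrated ImGene nodal-stage predictor
#'
#' Fits the two monomodal sub-models - an image-feature (mIHC) SVM and a
#' genomic-feature SVM, each on its top-10 features ranked by standardized
#' univariable logistic coefficient magnitude, tuned by leave-one-out
#' cross-validation - then fits the integration logistic regression on the
#' calibrated sub-model scores (discovery + validation pooled), picks the
#' max-accuracy cutoff on validation scores, and evaluates ImGene against
#' both monomodal baselines on the validation split. Patients missing
#' either block are dropped with a count.
#'
#' @param im_features patients x image-features matrix (rownames = ids).
#' @param gene_features patients x genomic-features matrix.
#' @param labels named 0/1 vector (1 = pN positive).
#' @param k_features per-block feature count (default 10).
#' @param validation_fraction held-out fraction for cutoff selection and
#'   evaluation (stratified).
#' @param seed RNG seed.
#' @return object of class `imgene_fit`.
#' @export
imgene_fit <- function(im_features, gene_features, labels, k_features = 10,
                       validation_fraction = 1 / 3, seed = 1) {
  set.seed(seed)
  ids <- intersect(intersect(rownames(im_features), rownames(gene_features)),
                   names(labels))
  n_dropped <- length(labels) - length(ids)
  im <- as.matrix(im_features[ids, , drop = FALSE])
  ge <- as.matrix(gene_features[ids, , drop = FALSE])
  y <- labels[ids]

  # stratified discovery/validation split
  val <- unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1, round(length(idx) * validation_fraction)))))
  tr <- setdiff(seq_along(y), val)

  rank_block <- function(x) {
    cf <- vapply(seq_len(ncol(x)), function(j) {
      xs <- x[tr, j]
      if (stats::sd(xs) == 0) return(0)
      fit <- suppressWarnings(stats::glm(y[tr] ~ scale(xs),
                                         family = stats::binomial()))
      stats::coef(fit)[2]
    }, numeric(1))
    names(cf) <- colnames(x)
    cf[is.na(cf)] <- 0
    cf
  }
  im_sel <- select_features(rank_block(im), k_features)
  ge_sel <- select_features(rank_block(ge), k_features)

  im_svm <- fit_block_svm(im[tr, im_sel, drop = FALSE], y[tr],
                          im[val, im_sel, drop = FALSE], y[val])
  ge_svm <- fit_block_svm(ge[tr, ge_sel, drop = FALSE], y[tr],
                          ge[val, ge_sel, drop = FALSE], y[val])

  im_score <- score_block_svm(im_svm, im)
  ge_score <- score_block_svm(ge_svm, ge)

  # integration logistic on pooled discovery + validation scores
  integ <- fit_logistic(y, data.frame(im = im_score, gene = ge_score))
  beta_im <- unname(integ$coefficients["im"])
  beta_gene <- unname(integ$coefficients["gene"])
  prob <- score_logistic(integ, data.frame(im = im_score, gene = ge_score))
  cutoff <- pick_cutoff(prob[val], y[val])

  report <- list(
    imgene = evaluate_predictions(prob[val], y[val], cutoff),
    im_only = evaluate_predictions(im_score[val], y[val], im_svm$cutoff),
    gene_only = evaluate_predictions(ge_score[val], y[val], ge_svm$cutoff))

  structure(list(
    im_svm = im_svm, gene_svm = ge_svm, integration = integ,
    beta_im = beta_im, beta_gene = beta_gene, cutoff = cutoff,
    selected = list(im = im_sel, gene = ge_sel),
    split = list(train = ids[tr], validation = ids[val]),
    n_dropped = n_dropped, report = report, labels = y,
    scores = data.frame(patient_id = ids, im = im_score, gene = ge_score,
                        prob = prob)),
    class = "imgene_fit")
}

#' @export
print.imgene_fit <- function(x, ...) {
  cat(sprintf(
    "ImGene model: %d patients (%d train / %d validation), %d dropped\n",
    nrow(x$scores), length(x$split$train), length(x$split$validation),
    x$n_dropped))
  cat(sprintf("  integration: Z = %.2f + (%.2f x ImFeatures) + (%.2f x GeneFeatures)\n",
              x$integration$intercept, x$beta_im, x$beta_gene))
  cat("  validation: ImGene ");     print(x$report$imgene)
  cat("              ImFeatures "); print(x$report$im_only)
  cat("              GeneFeatures "); print(x$report$gene_only)
  invisible(x)
}

#' @export
summary.imgene_fit <- function(object, ...) {
  print(object)
  cat("selected image features:   ",
      paste(object$selected$im, collapse = ", "), "\n")
  cat("selected genomic features: ",
      paste(object$selected$gene, collapse = ", "), "\n")
  invisible(object)
}

#' Predict nodal-metastasis probability for new patients
#'
#' @param object an `imgene_fit`.
#' @param im_features,gene_features feature matrices with the model's
#'   selected columns (rownames = patient ids).
#' @param ... unused.
#' @return data.frame: patient_id, im_score, gene_score, prob, predicted.
#' @export
predict.imgene_fit <- function(object, im_features, gene_features, ...) {
  ids <- intersect(rownames(im_features), rownames(gene_features))
  im_score <- score_block_svm(object$im_svm,
                              as.matrix(im_features[ids, , drop = FALSE]))
  ge_score <- score_block_svm(object$gene_svm,
                              as.matrix(gene_features[ids, , drop = FALSE]))
  prob <- score_logistic(object$integration,
                         data.frame(im = im_score, gene = ge_score))
  data.frame(patient_id = ids, im_score = im_score, gene_score = ge_score,
             prob = prob, predicted = as.integer(prob >= object$cutoff))
}
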