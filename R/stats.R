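#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. For small samples (both
#' groups of size 8 or less) the exact two-sided p-value is obtained by full
#' enumeration of all rank arrangements (valid under ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact Force exact enumeration (`TRUE`), the approximation
#'   (`FALSE`), or choose by sample size (`NULL`, default).
#' @return List with `U` (statistic for `x`, counting pairs where x exceeds y,
#'   ties counted 1/2), `p_value`, `method`, and `degenerate` (TRUE when all
#'   values are identical, in which case p = 1 by convention).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be nonempty")
  pooled <- c(x, y)
  if (diff(range(pooled)) == 0)
    return(list(U = n1 * n2 / 2, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  u <- u_stat(seq_len(n1))
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8
  if (exact) {
    combos <- utils::combn(n1 + n2, n1)
    r <- rank(pooled)
    us <- apply(combos, 2, function(idx)
      sum(r[idx]) - n1 * (n1 + 1) / 2)
    dev <- abs(us - n1 * n2 / 2)
    p <- mean(dev >= abs(u - n1 * n2 / 2) - 1e-9)
    return(list(U = u, p_value = p, method = "exact enumeration",
                degenerate = FALSE))
  }
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  nn <- n1 + n2
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1))))
  mu <- n1 * n2 / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sigma
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u, p_value = p,
       method = "normal approximation (tie + continuity corrected)",
       degenerate = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`; e.g. 0.05 over the 8 hemodynamic comparisons gives
#'   0.00625.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 8) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  alpha / m
}

#' Spearman rank correlation
#'
#' Midrank-tie rank correlation with a t-approximation p-value.
#'
#' @param x,y Equal-length samples (n >= 3).
#' @return List with `rho`, `p_value`, `n`; `rho` is `NA` (flagged via
#'   `degenerate`) when either rank vector has zero variance.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length samples of size >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, degenerate = FALSE)
}

# covariate set used by every adjusted model
MLR_COVARIATES <- c("age", "dm_duration", "htn_duration", "sex", "bmi",
                    "smoking")
MEDICATION_COVARIATES <- c("statin", "antiplatelet", "antihypertensive")

#' Covariate-adjusted logistic model for one hemodynamic parameter
#'
#' Maximum-likelihood binary logistic regression of PAD status on a single
#' hemodynamic parameter plus clinical covariates (one model per parameter),
#' with Wald 95% confidence intervals on the odds-ratio scale. Complete or
#' quasi-complete separation is detected and flagged; coefficient results are
#' withheld (`NA`) for flagged fits.
#'
#' @param data Data frame holding the feature, covariates, and label.
#' @param feature Name of the hemodynamic parameter column.
#' @param covariates Character vector of adjustment columns (default: age,
#'   diabetes duration, hypertension duration, sex, BMI, smoking status).
#' @param label Name of the outcome column (logical or "PAD"/"nonPAD"; PAD is
#'   the positive class).
#' @return List of class `mlr_result`: `terms` (data frame of coefficient,
#'   odds_ratio, ci_low, ci_high, p_value per term), `converged`, `separation`,
#'   `model` (the glm fit), `covariates`.
#' @export
fit_mlr <- function(data, feature, covariates = MLR_COVARIATES,
                    label = "group") {
  cols <- c(feature, covariates, label)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[cols])) stop("missing values are not supported")
  y <- data[[label]]
  if (!is.logical(y)) y <- y == "PAD"
  if (length(unique(y)) < 2) stop("need at least one subject per class")
  df <- data[, c(feature, covariates), drop = FALSE]
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(c(feature, covariates),
                                               collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df, control = list(maxit = 100)))
  co <- summary(fit)$coefficients
  probs <- stats::fitted(fit)
  # scale-free separation check: standardise coefficients by their
  # predictor's SD so small-unit covariates are not falsely flagged
  mm <- stats::model.matrix(fit)
  sds <- apply(mm, 2, stats::sd)[rownames(co)]
  std_coef <- co[-1, "Estimate"] * sds[-1]
  separation <- !fit$converged ||
    (length(std_coef) && max(abs(std_coef), na.rm = TRUE) > 15) ||
    all(pmin(probs, 1 - probs) < 1e-8)
  terms <- data.frame(
    term = rownames(co),
    coefficient = co[, "Estimate"],
    odds_ratio = exp(co[, "Estimate"]),
    ci_low = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
    ci_high = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"],
    row.names = NULL
  )
  if (separation) {
    bad <- which.max(abs(co[-1, "Estimate"])) + 1L
    terms[, -1] <- NA_real_
    attr(terms, "offending_term") <- rownames(co)[bad]
  }
  structure(list(terms = terms, converged = fit$converged,
                 separation = separation, covariates = covariates,
                 feature = feature, model = fit),
            class = "mlr_result")
}

#' Stratified k-fold assignment
#'
#' Partitions subjects into k folds preserving class proportions: per-class
#' per-fold counts differ by at most one, with leftover subjects spread across
#' folds in rotation so overall fold sizes are as even as possible.
#' Deterministic given the seed.
#'
#' @param labels Class labels (any type; coerced to factor).
#' @param k Number of folds (default 5); every class must have >= k members.
#' @param seed Integer seed for the within-class shuffle.
#' @return Integer vector of fold ids (1..k) aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1) {
  f <- as.factor(labels)
  if (any(table(f) < k))
    stop("every class must have at least k = ", k, " members")
  set.seed(as.integer(seed %% .Machine$integer.max))
  fold <- integer(length(f))
  offset <- 0L
  for (lv in levels(f)) {
    idx <- sample(which(f == lv))
    assign <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    fold[idx] <- assign
    offset <- (offset + length(idx)) %% k
  }
  fold
}

#' Trapezoidal ROC curve and AUC
#'
#' ROC over all unique probability thresholds with simultaneous steps for
#' tied scores; the trapezoidal area equals the Mann-Whitney U statistic of
#' the positive-class scores divided by `n_pos * n_neg`.
#'
#' @param probabilities Predicted probabilities (or any scores).
#' @param labels Positive-class indicator (logical, or "PAD"/"nonPAD").
#' @return For [roc_curve()], a data frame `(threshold, fpr, tpr)`; for
#'   [roc_auc()], the area under that curve.
#' @export
roc_curve <- function(probabilities, labels) {
  y <- if (is.logical(labels)) labels else labels == "PAD"
  if (length(unique(y)) < 2) stop("both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  p <- probabilities[ord]; y <- y[ord]
  steps <- !duplicated(p, fromLast = TRUE) # last index of each tied block
  tp <- cumsum(y)[steps]; fp <- cumsum(!y)[steps]
  data.frame(threshold = c(Inf, p[steps]),
             fpr = c(0, fp / sum(!y)),
             tpr = c(0, tp / sum(y)))
}

#' @rdname roc_curve
#' @export
roc_auc <- function(probabilities, labels) {
  rc <- roc_curve(probabilities, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

threshold_metrics <- function(prob, y, threshold = 0.5) {
  pred <- prob >= threshold   # probability exactly at threshold -> PAD
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  sens <- tp / (tp + fn)
  f1 <- if (is.na(prec) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  c(accuracy = (tp + tn) / length(y), sensitivity = sens,
    specificity = tn / (tn + fp), precision = prec, f1 = f1,
    tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Stratified cross-validated classification for one parameter
#'
#' Fits the covariate-adjusted logistic model on k-1 folds and predicts the
#' held-out fold, for each of k stratified folds. Out-of-fold probabilities
#' are pooled to form the pooled ROC curve, AUC, and confusion matrix at the
#' fixed probability threshold (0.50; a probability exactly at the threshold
#' is classified PAD). Threshold metrics and fold-local AUCs are also
#' summarised as mean +/- SD across folds.
#'
#' @inheritParams fit_mlr
#' @param k Number of folds (default 5).
#' @param threshold Classification threshold on the predicted probability.
#' @param seed Seed for the fold assignment.
#' @return List of class `cv_report`: `fold_metrics`, `summary` (mean/sd per
#'   metric), `pooled` (auc, metrics, confusion matrix), `oof` (out-of-fold
#'   probabilities with labels and fold ids), `incomplete` (fold ids whose
#'   model did not converge), `seed`.
#' @export
cross_validated_classification <- function(data, feature,
                                           covariates = MLR_COVARIATES,
                                           label = "group", k = 5,
                                           threshold = 0.5, seed = 1) {
  y <- data[[label]]
  if (!is.logical(y)) y <- y == "PAD"
  fold <- stratified_kfold(y, k = k, seed = seed)
  prob <- rep(NA_real_, length(y))
  incomplete <- integer()
  for (fd in seq_len(k)) {
    train <- data[fold != fd, , drop = FALSE]
    fit <- fit_mlr(train, feature, covariates, label)
    if (fit$separation) incomplete <- c(incomplete, fd)
    # rank-deficiency in tiny training splits is already surfaced through the
    # separation/convergence flags; predict's warning adds no information
    prob[fold == fd] <- suppressWarnings(
      stats::predict(fit$model,
                     newdata = data[fold == fd, , drop = FALSE],
                     type = "response"))
  }
  fold_metrics <- do.call(rbind, lapply(seq_len(k), function(fd) {
    sel <- fold == fd
    data.frame(fold = fd, auc = roc_auc(prob[sel], y[sel]),
               t(threshold_metrics(prob[sel], y[sel], threshold)[1:5]))
  }))
  msum <- data.frame(
    metric = names(fold_metrics)[-1],
    mean = colMeans(fold_metrics[-1]),
    sd = apply(fold_metrics[-1], 2, stats::sd),
    row.names = NULL)
  pooled_tm <- threshold_metrics(prob, y, threshold)
  confusion <- matrix(pooled_tm[c("tn", "fp", "fn", "tp")], 2, 2,
                      dimnames = list(truth = c("nonPAD", "PAD"),
                                      predicted = c("nonPAD", "PAD")))
  structure(list(
    feature = feature, fold_metrics = fold_metrics, summary = msum,
    pooled = list(auc = roc_auc(prob, y),
                  metrics = pooled_tm[1:5],
                  confusion = confusion,
                  roc = roc_curve(prob, y)),
    oof = data.frame(probability = prob, pad = y, fold = fold),
    incomplete = incomplete, threshold = threshold, seed = seed,
    k = k), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$feature, ": pooled AUC ",
      round(x$pooled$auc, 4), ", pooled accuracy ",
      round(x$pooled$metrics["accuracy"], 4), " (", x$k, " folds)\n",
      sep = "")
  invisible(x)
}

#' Medication sensitivity analysis
#'
#' Re-runs the cross-validated classification with binary indicators of
#' statin, antiplatelet, and antihypertensive use added to the covariate set.
#' Fold assignments depend only on the labels and seed, so they are identical
#' to the base model's, and the report carries the AUC/accuracy deltas
#' against the base run.
#'
#' @inheritParams cross_validated_classification
#' @return A `cv_report` with an extra `comparison` element (base vs extended
#'   pooled AUC and accuracy).
#' @export
medication_sensitivity <- function(data, feature,
                                   covariates = MLR_COVARIATES,
                                   label = "group", k = 5, threshold = 0.5,
                                   seed = 1) {
  base <- cross_validated_classification(data, feature, covariates, label,
                                         k, threshold, seed)
  ext <- cross_validated_classification(
    data, feature, c(covariates, MEDICATION_COVARIATES), label, k,
    threshold, seed)
  ext$comparison <- data.frame(
    model = c("base", "with_medications"),
    auc = c(base$pooled$auc, ext$pooled$auc),
    accuracy = c(base$pooled$metrics["accuracy"],
                 ext$pooled$metrics["accuracy"]))
  ext
}
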