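# Class-weighted elastic nets, performance metrics and Platt calibration.

#' Balanced class weights
#'
#' Per-observation weights `n_total / (2 * n_class)`, so each class
#' contributes equally to the loss regardless of imbalance.
#'
#' @param y binary 0/1 labels.
#' @return Numeric weight per observation.
#' @export
classWeights <- function(y) {
    n <- length(y)
    n1 <- sum(y == 1); n0 <- n - n1
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

#' Class-weighted logarithmic loss
#'
#' `-sum(w_i * (y_i log p_i + (1 - y_i) log(1 - p_i))) / sum(w_i)`.
#' Probabilities at 0 or 1 are clipped to `1e-15` with a warning.
#'
#' @param labels binary 0/1 labels.
#' @param probabilities predicted probabilities in (0, 1).
#' @param weights per-observation weights, or `"balanced"` (default) for
#'   [classWeights()].
#' @return Non-negative loss.
#' @examples
#' weightedLogLoss(c(1, 0), c(0.5, 0.5))  # log(2)
#' @export
weightedLogLoss <- function(labels, probabilities, weights = "balanced") {
    if (length(labels) != length(probabilities))
        stop("labels and probabilities must have equal length")
    p <- probabilities
    if (any(p <= 0 | p >= 1)) {
        warning("probabilities clipped away from 0/1")
        p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    }
    w <- if (identical(weights, "balanced")) classWeights(labels) else weights
    -sum(w * (labels * log(p) + (1 - labels) * log(1 - p))) / sum(w)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_case > score_control) + 0.5 P(equal)`, computed from midranks.
#'
#' @param labels binary 0/1 labels (both classes required).
#' @param scores numeric scores.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))  # 0.75
#' @export
auroc <- function(labels, scores) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 == 0 || n0 == 0) stop("both classes must be present")
    r <- rank(scores)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a class-weighted elastic net at fixed hyperparameters
#'
#' Penalised logistic regression minimising the class-weighted log-loss plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha) * ||b||_2^2 / 2)`, via glmnet's
#' coordinate descent. Predictors are used as given (standardise upstream).
#'
#' @param X numeric matrix (samples x features), complete.
#' @param y binary 0/1 labels.
#' @param alpha L1/L2 mixing in `[0, 1]`.
#' @param lambda penalty strength (>= 0).
#' @param weights per-observation weights or `"balanced"`.
#' @param lambda_path optional decreasing lambda sequence containing `lambda`
#'   (a path stabilises glmnet's warm starts; defaults to a short path down
#'   to the requested value).
#' @return An `ElasticNetModel` list: `a0`, `beta` (named), `alpha`, `lambda`,
#'   `features`.
#' @seealso [predictRisk()], [tuneElasticNet()]
#' @export
fitWeightedElasticNet <- function(X, y, alpha, lambda, weights = "balanced",
                                  lambda_path = NULL) {
    X <- as.matrix(X)
    if (anyNA(X)) stop("X must be complete")
    w <- if (identical(weights, "balanced")) classWeights(y) else weights
    if (is.null(lambda_path))
        lambda_path <- sort(unique(c(lambda, lambda * c(32, 16, 8, 4, 2))),
                            decreasing = TRUE)
    lambda_path <- sort(unique(pmax(lambda_path, 0)), decreasing = TRUE)
    if (!any(abs(lambda_path - lambda) < 1e-12))
        lambda_path <- sort(c(lambda_path, lambda), decreasing = TRUE)
    if (ncol(X) == 1L)  # glmnet needs >= 2 columns
        X <- cbind(X, `.const.` = 0)
    fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                          family = "binomial", alpha = alpha,
                          lambda = lambda_path, weights = w,
                          standardize = FALSE, thresh = 1e-9,
                          maxit = 1e6)
    if (!fit$jerr == 0 && is.null(fit$lambda))
        stop("glmnet failed to converge: jerr = ", fit$jerr)
    i <- which.min(abs(fit$lambda - lambda))
    beta <- as.numeric(fit$beta[, i])
    names(beta) <- rownames(fit$beta)
    beta <- beta[names(beta) != ".const."]
    model <- list(a0 = as.numeric(fit$a0[i]), beta = beta, alpha = alpha,
                  lambda = lambda, features = names(beta))
    class(model) <- "ElasticNetModel"
    model
}

#' Predicted case probabilities from an ElasticNetModel
#'
#' @param model an `ElasticNetModel` from [fitWeightedElasticNet()].
#' @param X matrix with (at least) the model's feature columns.
#' @return Probabilities in (0, 1).
#' @export
predictRisk <- function(model, X) {
    X <- as.matrix(X)[, model$features, drop = FALSE]
    as.numeric(stats::plogis(model$a0 + X %*% model$beta))
}

#' @method print ElasticNetModel
#' @export
print.ElasticNetModel <- function(x, ...) {
    cat(sprintf(
        "ElasticNetModel: alpha = %.3f, lambda = %.3f, %d/%d non-zero coefficients\n",
        x$alpha, x$lambda, sum(x$beta != 0), length(x$beta)))
    invisible(x)
}

#' Tune elastic-net hyperparameters on a fold plan
#'
#' Evaluates `grid_size` alphas by `grid_size` lambdas, both evenly spaced in
#' `[0, 1]`, by class-weighted log-loss of out-of-fold predictions, and
#' returns the pair with the best mean loss across folds. Ties break toward
#' larger lambda, then larger alpha (stronger regularisation preferred). The
#' per-fold out-of-fold predictions at the chosen pair are returned for
#' calibration and inner-CV scoring. A log-spaced lambda path is available
#' via `lambda_grid = "log"`.
#'
#' @param X complete numeric matrix (samples x features).
#' @param y binary 0/1 labels.
#' @param folds integer fold id per sample (stratified; every fold must
#'   contain both classes).
#' @param grid_size grid resolution per axis (default 20: 400 pairs).
#' @param weights observation weights or `"balanced"`.
#' @param lambda_grid `"linear"` (default) or `"log"`.
#' @return list: `alpha`, `lambda`, `cv_logloss`, `cv_auroc` (mean per-fold
#'   AUROC at the chosen pair), `oof` (out-of-fold probabilities, sample
#'   order), `n_evaluated` (number of grid pairs assessed).
#' @export
tuneElasticNet <- function(X, y, folds, grid_size = 20L,
                           weights = "balanced", lambda_grid = "linear") {
    X <- as.matrix(X)
    grid_size <- as.integer(grid_size)
    alphas <- if (grid_size == 1L) 0 else seq(0, 1, length.out = grid_size)
    lambdas <- if (grid_size == 1L) 0
               else if (lambda_grid == "log") exp(seq(log(1), log(1e-4),
                                                      length.out = grid_size))
               else seq(0, 1, length.out = grid_size)
    lam_desc <- sort(lambdas, decreasing = TRUE)
    fold_ids <- sort(unique(folds))
    for (f in fold_ids)
        if (length(unique(y[folds != f])) < 2 ||
            length(unique(y[folds == f])) < 2)
            stop("fold ", f, " lacks a class")
    w_all <- if (identical(weights, "balanced")) classWeights(y) else weights

    # loss[alpha, lambda] accumulated over folds; out-of-fold probabilities
    # kept for every combo, AUROC computed at the winner only.
    A <- length(alphas); L <- length(lam_desc)
    loss <- matrix(0, A, L)
    preds <- vector("list", length(fold_ids))
    for (fi in seq_along(fold_ids)) {
        f <- fold_ids[fi]
        tr <- folds != f; te <- !tr
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[te, , drop = FALSE]
        if (ncol(Xtr) == 1L) {
            Xtr <- cbind(Xtr, `.const.` = 0)
            Xte <- cbind(Xte, `.const.` = 0)
        }
        pmat <- matrix(NA_real_, sum(te), A * L)
        for (ai in seq_len(A)) {
            # maxit is capped: near-zero lambda on separable folds diverges
            # (coefficients unbounded); such combos lose on held-out loss
            # regardless, so burning passes on them is pointless
            fit <- suppressWarnings(
                glmnet::glmnet(Xtr, factor(y[tr], levels = c(0, 1)),
                               family = "binomial", alpha = alphas[ai],
                               lambda = lam_desc, weights = w_all[tr],
                               standardize = FALSE, thresh = 1e-8,
                               maxit = 1e4))
            # probabilities at every path lambda straight from the
            # coefficient matrix (predict()'s dispatch is the hot path here)
            B <- as.matrix(fit$beta)[colnames(Xte), , drop = FALSE]
            lin <- sweep(Xte %*% B, 2, as.numeric(fit$a0), "+")
            idx <- match(round(lam_desc, 10), round(fit$lambda, 10))
            idx[is.na(idx)] <- ncol(lin)  # truncated path: reuse last fit
            pmat[, (ai - 1L) * L + seq_len(L)] <-
                stats::plogis(lin[, idx, drop = FALSE])
        }
        pp <- pmin(pmax(pmat, 1e-15), 1 - 1e-15)
        wte <- w_all[te]
        ll <- -(crossprod(log(pp), wte * y[te]) +
                crossprod(log1p(-pp), wte * (1 - y[te]))) / sum(wte)
        loss <- loss + matrix(ll, A, L, byrow = TRUE)
        preds[[fi]] <- pmat
    }
    loss <- loss / length(fold_ids)
    # ties toward larger lambda then larger alpha
    best <- which(loss <= min(loss) + 1e-12, arr.ind = TRUE)
    best <- best[order(-lam_desc[best[, 2]], -alphas[best[, 1]]), , drop = FALSE]
    ai <- best[1, 1]; li <- best[1, 2]
    col <- (ai - 1L) * L + li
    oof <- numeric(length(y))
    auc <- 0
    for (fi in seq_along(fold_ids)) {
        te <- folds == fold_ids[fi]
        oof[te] <- preds[[fi]][, col]
        auc <- auc + (if (length(unique(y[te])) == 2)
                          auroc(y[te], oof[te]) else 0.5)
    }
    list(alpha = alphas[ai], lambda = lam_desc[li],
         cv_logloss = loss[ai, li], cv_auroc = auc / length(fold_ids),
         oof = oof, n_evaluated = A * L)
}

#' Platt scaling: fit and apply
#'
#' `plattFit` fits a one-dimensional logistic regression of the labels on raw
#' classifier scores; `plattApply` maps scores through the fitted logistic.
#' The map is strictly monotone, so ranking metrics such as AUROC are
#' unchanged (for a positive slope).
#'
#' @param raw_scores finite numeric classifier scores.
#' @param labels binary 0/1 labels (both classes required).
#' @return `plattFit`: a `CalibrationModel` list (`intercept`, `slope`);
#'   `plattApply`: calibrated probabilities in (0, 1).
#' @name platt
#' @export
plattFit <- function(raw_scores, labels) {
    if (any(!is.finite(raw_scores))) stop("scores must be finite")
    if (length(unique(labels)) < 2) stop("both classes must be present")
    if (stats::sd(raw_scores) == 0)
        stop("constant scores: no slope identifiable")
    fit <- suppressWarnings(
        stats::glm(labels ~ raw_scores, family = stats::binomial()))
    model <- list(intercept = unname(stats::coef(fit)[1]),
                  slope = unname(stats::coef(fit)[2]))
    class(model) <- "CalibrationModel"
    model
}

#' @rdname platt
#' @param model a `CalibrationModel` from `plattFit`.
#' @export
plattApply <- function(model, raw_scores) {
    as.numeric(stats::plogis(model$intercept + model$slope * raw_scores))
}
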