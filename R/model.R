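# L2-regularised logistic classifier over assembled E-G pair features.
#
# Features are z-scored with training means/scales; the intercept is not
# penalised. Fitting is damped Newton (IRLS) on the penalised log-loss
#   (1/n) * sum_i log(1 + exp(-y_i * eta_i)) + (lambda/2) * ||beta||^2
# with lambda = 1 / (C * n): C is the inverse penalty strength, so C -> Inf
# approaches the unpenalised MLE.

.logistic <- function(eta) plogis(eta)

.ridge_logistic_fit <- function(Z, y, lambda, tol = 1e-8, max_iter = 10000L) {
  n <- nrow(Z); p <- ncol(Z)
  beta <- numeric(p)
  b0 <- qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  # numerically stable penalised mean log-loss
  obj <- function(b0, beta) {
    eta <- drop(Z %*% beta) + b0
    ll <- mean((1 - y) * eta + ifelse(eta > 0, log1p(exp(-eta)), -eta + log1p(exp(eta))))
    ll + lambda / 2 * sum(beta^2)
  }
  prev <- obj(b0, beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta) + b0
    mu <- .logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g_beta <- drop(crossprod(Z, mu - y)) / n + lambda * beta
    g_b0 <- mean(mu - y)
    H <- crossprod(Z, Z * w) / n + diag(lambda, p)
    h_cross <- colSums(Z * w) / n
    h_b0 <- mean(w)
    Hfull <- rbind(cbind(h_b0, matrix(h_cross, nrow = 1)),
                   cbind(matrix(h_cross, ncol = 1), H))
    step <- as.numeric(tryCatch(solve(Hfull, c(g_b0, g_beta)),
                                error = function(e) c(g_b0, g_beta))) # gradient fallback
    t_ <- 1
    repeat {
      nb0 <- b0 - t_ * step[1]
      nbeta <- beta - t_ * step[-1]
      val <- obj(nb0, nbeta)
      if (is.finite(val) && val <= prev + 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-12) { nb0 <- b0; nbeta <- beta; val <- prev; break }
    }
    conv <- max(abs(c(nb0 - b0, nbeta - beta)))
    b0 <- nb0; beta <- nbeta
    if (abs(prev - val) < tol && conv < sqrt(tol)) {
      prev <- val
      return(list(intercept = b0, coefficients = beta, iterations = it,
                  objective = val, converged = TRUE))
    }
    prev <- val
  }
  warning("ridge logistic fit did not converge in ", max_iter, " iterations")
  list(intercept = b0, coefficients = beta, iterations = max_iter,
       objective = prev, converged = FALSE)
}

#' Train the E-G interaction classifier
#'
#' Logistic regression with an L2 penalty over the assembled pair features,
#' labelled by CRISPRi outcome (1 = perturbation significantly reduced the
#' target gene's expression; 0 = no such evidence). Features are
#' standardised to zero mean / unit scale on the training rows; the penalty
#' applies to standardised coefficients and not the intercept.
#'
#' @param features an `eg_features` object, or a data.frame with `cre_id`,
#'   `gene_id` plus numeric feature columns.
#' @param labels data.frame `cre_id`, `gene_id`, `label` (0/1). Rows are
#'   matched to `features` by key; features without a label are dropped.
#' @param C inverse penalty strength (larger = weaker penalty). Default 1.
#' @param cv_C optional numeric grid; when supplied, `C` is chosen by
#'   `n_folds`-fold cross-validated log-loss over the grid.
#' @param n_folds folds for `cv_C` selection.
#' @param class_weight `"none"` (default) or `"balanced"` (inverse
#'   prevalence weights).
#' @param tol,max_iter Newton convergence controls.
#' @param seed integer seed (used only for CV fold assignment).
#' @return object of class `eg_model`: feature names, coefficients (on the
#'   standardised scale), intercept, standardisation means/scales, `C`, and
#'   training metadata.
#' @export
train_eg_model <- function(features, labels, C = 1.0, cv_C = NULL, n_folds = 5L,
                           class_weight = c("none", "balanced"),
                           tol = 1e-8, max_iter = 10000L, seed = 1L) {
  class_weight <- match.arg(class_weight)
  X <- if (inherits(features, "eg_features")) features$matrix else features
  stopifnot(all(c("cre_id", "gene_id") %in% names(X)))
  key <- paste(X$cre_id, X$gene_id, sep = "\r")
  lkey <- paste(labels$cre_id, labels$gene_id, sep = "\r")
  y <- labels$label[match(key, lkey)]
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  feat_names <- setdiff(names(X), c("cre_id", "gene_id"))
  M <- as.matrix(X[keep, feat_names, drop = FALSE])
  if (any(!is.finite(M))) stop("non-finite feature values")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (class_weight == "balanced") {
    # implemented by duplicating the minority weighting into the loss via
    # observation replication is avoided; weights enter IRLS directly
    w_pos <- length(y) / (2 * sum(y == 1))
    w_neg <- length(y) / (2 * sum(y == 0))
  }
  mu <- colMeans(M)
  sc <- apply(M, 2, sd)
  sc[sc == 0 | !is.finite(sc)] <- 1
  Z <- sweep(sweep(M, 2, mu), 2, sc, "/")
  if (!is.null(cv_C)) {
    C <- .select_C_cv(Z, y, cv_C, n_folds, tol, max_iter, seed)
  }
  lambda <- 1 / (C * nrow(Z))
  if (class_weight == "balanced") {
    # weighted fit: replicate via weights in a modified IRLS
    fit <- .ridge_logistic_fit_w(Z, y, lambda, ifelse(y == 1, w_pos, w_neg),
                                 tol, max_iter)
  } else {
    fit <- .ridge_logistic_fit(Z, y, lambda, tol, max_iter)
  }
  structure(list(
    feature_names = feat_names,
    coefficients = setNames(fit$coefficients, feat_names),
    intercept = fit$intercept,
    C = C,
    standardization = list(mean = setNames(mu, feat_names),
                           scale = setNames(sc, feat_names)),
    class_weight = class_weight,
    converged = fit$converged,
    iterations = fit$iterations,
    n_train = nrow(Z), n_pos = sum(y == 1), n_neg = sum(y == 0),
    seed = seed
  ), class = "eg_model")
}

.ridge_logistic_fit_w <- function(Z, y, lambda, w, tol, max_iter) {
  # weighted variant: weights rescale each observation's loss contribution
  n <- nrow(Z); p <- ncol(Z)
  wsum <- sum(w)
  beta <- numeric(p); b0 <- 0
  obj <- function(b0, beta) {
    eta <- drop(Z %*% beta) + b0
    ll <- sum(w * ((1 - y) * eta + ifelse(eta > 0, log1p(exp(-eta)),
                                          -eta + log1p(exp(eta))))) / wsum
    ll + lambda / 2 * sum(beta^2)
  }
  prev <- obj(b0, beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta) + b0
    mu <- .logistic(eta)
    ww <- pmax(mu * (1 - mu), 1e-10) * w / wsum
    g_beta <- drop(crossprod(Z, w * (mu - y))) / wsum + lambda * beta
    g_b0 <- sum(w * (mu - y)) / wsum
    H <- crossprod(Z, Z * ww) + diag(lambda, p)
    h_cross <- colSums(Z * ww)
    h_b0 <- sum(ww)
    Hfull <- rbind(cbind(h_b0, matrix(h_cross, nrow = 1)),
                   cbind(matrix(h_cross, ncol = 1), H))
    step <- as.numeric(tryCatch(solve(Hfull, c(g_b0, g_beta)),
                                error = function(e) c(g_b0, g_beta)))
    t_ <- 1
    repeat {
      nb0 <- b0 - t_ * step[1]; nbeta <- beta - t_ * step[-1]
      val <- obj(nb0, nbeta)
      if (is.finite(val) && val <= prev + 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-12) { nb0 <- b0; nbeta <- beta; val <- prev; break }
    }
    conv <- max(abs(c(nb0 - b0, nbeta - beta)))
    b0 <- nb0; beta <- nbeta
    if (abs(prev - val) < tol && conv < sqrt(tol)) {
      return(list(intercept = b0, coefficients = beta, iterations = it,
                  objective = val, converged = TRUE))
    }
    prev <- val
  }
  warning("weighted ridge logistic fit did not converge")
  list(intercept = b0, coefficients = beta, iterations = max_iter,
       objective = prev, converged = FALSE)
}

.select_C_cv <- function(Z, y, grid, n_folds, tol, max_iter, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), nrow(Z)))
  losses <- vapply(grid, function(C) {
    fold_loss <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      f <- .ridge_logistic_fit(Z[tr, , drop = FALSE], y[tr], 1 / (C * sum(tr)),
                               tol = 1e-7, max_iter = max_iter)
      eta <- drop(Z[!tr, , drop = FALSE] %*% f$coefficients) + f$intercept
      yk <- y[!tr]
      mean((1 - yk) * eta + ifelse(eta > 0, log1p(exp(-eta)),
                                   -eta + log1p(exp(eta))))
    }, numeric(1))
    mean(fold_loss)
  }, numeric(1))
  grid[which.min(losses)]
}

#' Model coefficients on the original feature scale
#' @param object an `eg_model`.
#' @param ... unused.
#' @return named numeric vector of per-unit (unstandardised) coefficients.
#' @export
coef.eg_model <- function(object, ...) {
  object$coefficients / object$standardization$scale
}

#' Score E-G pairs with a trained model
#'
#' Applies the inverse-logit of the standardised linear predictor; all model
#' features must be present (by name) in the new feature table.
#'
#' @param object an `eg_model`.
#' @param features an `eg_features` or data.frame with the model's feature
#'   columns.
#' @param ... unused.
#' @return numeric vector of scores in (0, 1), aligned with the feature rows.
#' @export
predict.eg_model <- function(object, features, ...) {
  X <- if (inherits(features, "eg_features")) features$matrix else features
  miss <- setdiff(object$feature_names, names(X))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  M <- as.matrix(X[, object$feature_names, drop = FALSE])
  Z <- sweep(sweep(M, 2, object$standardization$mean), 2,
             object$standardization$scale, "/")
  .logistic(drop(Z %*% object$coefficients) + object$intercept)
}

#' @export
print.eg_model <- function(x, ...) {
  cat("E-G ridge-logistic model:", length(x$feature_names), "features, C =", x$C,
      "\n  trained on", x$n_train, "pairs (", x$n_pos, "positive /", x$n_neg,
      "negative )\n")
  invisible(x)
}

#' Serialise / load a trained model as JSON
#' @param model an `eg_model`.
#' @param path file path.
#' @return `write_model`: the path invisibly; `read_model`: an `eg_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$standardization$mean <- unlist(x$standardization$mean)
  x$standardization$scale <- unlist(x$standardization$scale)
  structure(x, class = "eg_model")
}

# RNG state helpers: run seeded code without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
.with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code
}
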