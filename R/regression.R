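# ---- core fitters on plain matrices (X already standardized) ----

ols_core <- function(X, y) {
  Xa <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xa)
  if (qr_x$rank < ncol(Xa)) {
    warn("rank-deficient design: using minimum-norm pseudo-inverse solution")
    sv <- svd(Xa)
    pos <- sv$d > max(dim(Xa)) * .Machine$double.eps * sv$d[1]
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    coefs <- as.numeric(coefs)
  } else {
    coefs <- qr.coef(qr_x, y)
  }
  coefs <- unname(coefs)
  list(weights = coefs[-1], intercept = coefs[1])
}

# univariate-response PLS by NIPALS with deflation (equals SIMPLS for a
# single response); returns regression weights in the input X space.
pls_core <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  rk <- qr(X)$rank
  if (ncomp > rk) abort(paste0("ncomp (", ncomp, ") exceeds rank of X (", rk, ")"))
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); fres <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    wv <- crossprod(E, fres)
    wv <- wv / sqrt(sum(wv^2))
    tv <- E %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(E, tv) / tt
    qa <- sum(fres * tv) / tt
    E <- E - tv %*% t(pv)
    fres <- fres - qa * tv
    W[, a] <- wv; P[, a] <- pv; q[a] <- qa; Tm[, a] <- tv
  }
  B <- W %*% solve(t(P) %*% W, q)
  list(weights = as.numeric(B), intercept = ym - sum(xm * B), scores = Tm)
}

svr_core <- function(X, y, kernel, C, gamma, epsilon, tol = 1e-4, max_iter = 1e6) {
  ktype <- if (kernel == "rbf") 1L else 0L
  fit <- svr_smo_cpp(X, y, C, epsilon, ktype, gamma %||% 0, tol, max_iter)
  if (!fit$converged) {
    warn(paste0("SVR solver hit the iteration cap (", format(max_iter),
                ") before reaching tolerance ", tol))
  }
  fit
}

# ---- shared plumbing ----

# Resolve a feature_matrix (or data frame) into scaled X, y, scaler, columns.
prepare_training <- function(fm, y = NULL) {
  if (is.null(y)) {
    if (!"target_ha_rmsd" %in% names(fm)) {
      abort("no target: supply y or a target_ha_rmsd column")
    }
    y <- fm$target_ha_rmsd
  }
  cols <- feature_cols(fm)
  scaler <- attr(fm, "scaling")
  if (is.null(scaler)) {
    scaler <- fit_scaler(fm)
    fm <- apply_scaler(fm, scaler)
  }
  list(X = as.matrix(fm[, cols]), y = y, scaler = scaler, columns = cols)
}

new_decoy_model <- function(kind, prep, fit, extra = list()) {
  structure(
    c(list(kind = kind, columns = prep$columns, scaler = prep$scaler), fit, extra),
    class = "decoy_model"
  )
}

#' Fit RMSD-prediction regression functions
#'
#' Fits a function predicting each decoy's peptide heavy-atom RMSD from its
#' per-residue structural/energetic features. Four kinds are available:
#' ordinary least squares (`fit_ols`), partial least squares with a chosen
#' number of latent components (`fit_pls`, NIPALS), and epsilon-insensitive
#' support vector regression with either no kernel (`linSVR`) or a Gaussian
#' radial basis function kernel (`radSVR`) via `fit_svr`.
#'
#' Features are standardized internally (mean 0, sample sd 1) and the scaler
#' is stored in the model, so [predict.decoy_model()] takes unscaled feature
#' rows. If `fm` already carries a scaling attribute (from [apply_scaler()]),
#' that scaler is reused unchanged.
#'
#' @param fm a `feature_matrix` with a `target_ha_rmsd` column (or pass `y`).
#' @param y optional response vector (Å), overriding the target column.
#' @return a `decoy_model`.
#' @export
fit_ols <- function(fm, y = NULL) {
  prep <- prepare_training(fm, y)
  fit <- ols_core(prep$X, prep$y)
  names(fit$weights) <- prep$columns
  new_decoy_model("ols", prep, fit,
                  list(training_meta = list(n = nrow(prep$X))))
}

#' @rdname fit_ols
#' @param ncomp number of PLS components (default 10, the count beyond which
#'   cross-validated error stops improving on peptide/MHC decoy features).
#' @export
fit_pls <- function(fm, y = NULL, ncomp = 10) {
  prep <- prepare_training(fm, y)
  fit <- pls_core(prep$X, prep$y, ncomp)
  fit$scores <- NULL
  names(fit$weights) <- prep$columns
  new_decoy_model("pls", prep, fit,
                  list(ncomp = as.integer(ncomp),
                       training_meta = list(n = nrow(prep$X))))
}

#' @rdname fit_ols
#' @param kernel `"linear"` (linSVR) or `"rbf"` (radSVR).
#' @param C regularization parameter: the balance between training error and
#'   function complexity.
#' @param gamma RBF width; larger values make each support vector's influence
#'   more local (ignored for the linear kernel; default `1/n_features`).
#' @param epsilon half-width of the insensitive tube, Å: residuals smaller
#'   than `epsilon` carry no loss. Default 0.1 (the conventional default of
#'   standard SVR implementations; not stated by the training protocol).
#' @param tol SMO stopping tolerance on the maximal KKT violation.
#' @param max_iter iteration cap for the solver.
#' @export
fit_svr <- function(fm, y = NULL, kernel = c("linear", "rbf"), C = 1,
                    gamma = NULL, epsilon = 0.1, tol = 1e-4, max_iter = 1e6) {
  kernel <- match.arg(kernel)
  if (C <= 0) abort("C must be positive")
  if (epsilon < 0) abort("epsilon must be non-negative")
  prep <- prepare_training(fm, y)
  if (kernel == "rbf") {
    gamma <- gamma %||% (1 / ncol(prep$X))
    if (gamma <= 0) abort("gamma must be positive for the rbf kernel")
  }
  fit <- svr_core(prep$X, prep$y, kernel, C, gamma, epsilon, tol, max_iter)
  kind <- if (kernel == "rbf") "radsvr" else "linsvr"
  sv <- which(abs(fit$beta) > 1e-12)
  model <- if (kernel == "rbf") {
    new_decoy_model(kind, prep, list(
      support = prep$X[sv, , drop = FALSE],
      dual_coef = fit$beta[sv],
      intercept = fit$bias
    ), list(
      hyperparams = list(C = C, gamma = gamma, epsilon = epsilon),
      training_meta = list(n = nrow(prep$X), n_support = length(sv),
                           iterations = fit$iterations,
                           converged = fit$converged)
    ))
  } else {
    w <- as.numeric(fit$w); names(w) <- prep$columns
    new_decoy_model(kind, prep, list(weights = w, intercept = fit$bias),
                    list(
                      hyperparams = list(C = C, gamma = gamma, epsilon = epsilon),
                      training_meta = list(n = nrow(prep$X), n_support = length(sv),
                                           iterations = fit$iterations,
                                           converged = fit$converged)
                    ))
  }
  check_prediction_collapse(model, prep, kind)
  model
}

# Guard against the degenerate-prediction pathology seen with overfit RBF
# models: a large share of predictions piling onto one value while the
# actual RMSDs span a wide range.
check_prediction_collapse <- function(model, prep, kind) {
  if (kind != "radsvr") return(invisible())
  pred <- predict_scaled(model, prep$X)
  if (diff(range(prep$y)) <= 1) return(invisible())
  cand <- unique(round(pred, 2))
  if (length(cand) > 500) cand <- sample(cand, 500)
  frac <- max(vapply(cand, function(v) mean(abs(pred - v) <= 0.05), numeric(1)))
  if (frac > 0.2) {
    warn(sprintf(paste0(
      "radSVR prediction collapse: %.0f%% of predictions lie within 0.05 ",
      "Å of one value while actual RMSDs span %.2f Å; the model may be ",
      "overfit (consider smaller gamma)"), 100 * frac, diff(range(prep$y))))
  }
  invisible()
}

# prediction from an already-scaled design matrix with model columns
predict_scaled <- function(object, Xs) {
  switch(object$kind,
    ols = ,
    pls = ,
    linsvr = as.numeric(Xs %*% object$weights + object$intercept),
    radsvr = as.numeric(
      rbf_kernel_cpp(Xs, object$support, object$hyperparams$gamma) %*%
        object$dual_coef + object$intercept
    ),
    abort(paste0("unsupported model kind: ", object$kind))
  )
}

#' Predict heavy-atom RMSD for new decoys
#'
#' Applies the model's stored scaler and then the fitted function. Columns
#' are matched by name, so column order in `newdata` is irrelevant;
#' prediction is pure and deterministic.
#'
#' @param object a `decoy_model`.
#' @param newdata unscaled feature rows (feature matrix, tibble or data
#'   frame) containing all model columns.
#' @param ... unused.
#' @return numeric vector of predicted HA RMSDs (Å).
#' @export
predict.decoy_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$columns, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata is missing model column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  Xs <- as.matrix(as.data.frame(newdata)[, object$columns, drop = FALSE])
  already_scaled <- !is.null(attr(newdata, "scaling"))
  if (!already_scaled) {
    sc <- object$scaler[match(object$columns, object$scaler$column), ]
    Xs <- sweep(sweep(Xs, 2, sc$mean), 2, sc$sd, "/")
  }
  predict_scaled(object, Xs)
}

#' @export
print.decoy_model <- function(x, ...) {
  cat("<decoy_model> kind:", x$kind)
  if (!is.null(x$ncomp)) cat(", ncomp:", x$ncomp)
  if (!is.null(x$hyperparams)) {
    hp <- x$hyperparams
    cat(", C:", format(hp$C), if (!is.null(hp$gamma)) paste0(", gamma: ", format(hp$gamma)),
        ", epsilon:", format(hp$epsilon))
  }
  cat("\n  ", length(x$columns), " features, trained on ",
      x$training_meta$n %||% NA, " decoys\n", sep = "")
  invisible(x)
}

#' Tidy a fitted decoy model
#'
#' Returns per-feature coefficients for the linear kinds (OLS, PLS, linSVR).
#' By default coefficients are reported on the original (unscaled) feature
#' scale with the intercept adjusted accordingly; `scale = "standardized"`
#' reports the fitted weights on standardized features.
#'
#' @param x a `decoy_model`.
#' @param scale `"original"` or `"standardized"`.
#' @param ... unused.
#' @return tibble with `term` and `estimate`.
#' @export
tidy.decoy_model <- function(x, scale = c("original", "standardized"), ...) {
  scale <- match.arg(scale)
  if (x$kind == "radsvr") {
    abort("radSVR has no explicit feature weights; see glance() for hyperparameters")
  }
  if (scale == "standardized") {
    return(tibble(term = c("(Intercept)", names(x$weights)),
                  estimate = c(x$intercept, unname(x$weights))))
  }
  sc <- x$scaler[match(names(x$weights), x$scaler$column), ]
  w_raw <- unname(x$weights) / sc$sd
  b_raw <- x$intercept - sum(unname(x$weights) * sc$mean / sc$sd)
  tibble(term = c("(Intercept)", names(x$weights)),
         estimate = c(b_raw, w_raw))
}

#' @rdname tidy.decoy_model
#' @export
glance.decoy_model <- function(x, ...) {
  hp <- x$hyperparams
  tibble(
    kind = x$kind,
    n_train = x$training_meta$n %||% NA_integer_,
    n_features = length(x$columns),
    ncomp = x$ncomp %||% NA_integer_,
    C = hp$C %||% NA_real_,
    gamma = hp$gamma %||% NA_real_,
    epsilon = hp$epsilon %||% NA_real_,
    cv_rmse = x$training_meta$cv_rmse %||% NA_real_,
    converged = x$training_meta$converged %||% TRUE
  )
}

# ---- serialization ----

MODEL_SCHEMA_VERSION <- "1"

#' Save / load a fitted model as JSON
#'
#' The JSON schema is versioned and all numerics are written at full
#' precision, so a reloaded model reproduces predictions to better than
#' 1e-12.
#'
#' @param model a `decoy_model`.
#' @param path JSON file path.
#' @return `save_model`: `path` invisibly. `load_model`: a `decoy_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    kind = model$kind,
    columns = model$columns,
    scaler = list(column = model$scaler$column, mean = model$scaler$mean,
                  sd = model$scaler$sd),
    weights = if (!is.null(model$weights)) unname(model$weights),
    intercept = model$intercept,
    ncomp = model$ncomp,
    hyperparams = model$hyperparams,
    support = if (!is.null(model$support)) unname(model$support),
    dual_coef = model$dual_coef,
    training_meta = model$training_meta
  )
  payload <- payload[!vapply(payload, is.null, logical(1))]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort(paste0("cannot parse model JSON: ", conditionMessage(e)))
  )
  if (!identical(as.character(payload$schema_version), MODEL_SCHEMA_VERSION)) {
    abort(paste0("model schema version mismatch: got '",
                 payload$schema_version %||% "<none>", "', expected '",
                 MODEL_SCHEMA_VERSION, "'"))
  }
  if (!payload$kind %in% c("ols", "pls", "linsvr", "radsvr")) {
    abort(paste0("unsupported model kind: ", payload$kind))
  }
  model <- list(
    kind = payload$kind,
    columns = payload$columns,
    scaler = tibble(column = payload$scaler$column,
                    mean = payload$scaler$mean, sd = payload$scaler$sd),
    intercept = payload$intercept,
    training_meta = as.list(payload$training_meta)
  )
  if (!is.null(payload$weights)) {
    model$weights <- setNames(payload$weights, payload$columns)
  }
  if (!is.null(payload$ncomp)) model$ncomp <- as.integer(payload$ncomp)
  if (!is.null(payload$hyperparams)) model$hyperparams <- as.list(payload$hyperparams)
  if (!is.null(payload$support)) {
    sup <- payload$support
    if (!is.matrix(sup)) sup <- do.call(rbind, lapply(sup, as.numeric))
    model$support <- sup
    model$dual_coef <- payload$dual_coef
  }
  structure(model, class = "decoy_model")
}
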