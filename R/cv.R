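#' Seeded k-fold assignment
#'
#' Shuffles row indices under the given seed and assigns them to folds
#' modulo `k`. The same `(n, k, seed)` always gives the same folds, and the
#' assignment is shared across grid points and model kinds so their
#' cross-validation errors are paired.
#'
#' @param n number of rows.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold labels 1..k, length `n`.
#' @export
make_folds <- function(n, k = 10, seed = 1) {
  if (k < 2) abort("k must be >= 2")
  if (n < 2 * k) abort("every fold needs at least 2 rows")
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- (seq_len(n) - 1L) %% k + 1L
  folds
}

fit_kind <- function(kind, fm, hp = list()) {
  switch(kind,
    ols = fit_ols(fm),
    pls = fit_pls(fm, ncomp = hp$ncomp %||% 10),
    linsvr = fit_svr(fm, kernel = "linear", C = hp$C %||% 1,
                     epsilon = hp$epsilon %||% 0.1,
                     tol = hp$tol %||% 1e-4, max_iter = hp$max_iter %||% 1e6),
    radsvr = fit_svr(fm, kernel = "rbf", C = hp$C %||% 1, gamma = hp$gamma,
                     epsilon = hp$epsilon %||% 0.1,
                     tol = hp$tol %||% 1e-4, max_iter = hp$max_iter %||% 1e6),
    abort(paste0("unknown model kind: ", kind))
  )
}

#' k-fold cross-validated RMSE for one model configuration
#'
#' Mean over folds of the root-mean-square held-out prediction error.
#' Features are standardized once on `fm` before folding (the protocol
#' scales before partitioning); folds are seeded and reproducible.
#'
#' @param fm a `feature_matrix` with `target_ha_rmsd`.
#' @param kind one of `"ols"`, `"pls"`, `"linsvr"`, `"radsvr"`.
#' @param hp named list of hyperparameters (`C`, `gamma`, `epsilon`,
#'   `ncomp`, ...).
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param folds optional precomputed fold labels (overrides `k`/`seed`).
#' @return mean CV RMSE (Å).
#' @export
cross_validate <- function(fm, kind, hp = list(), k = 10, seed = 1, folds = NULL) {
  if (is.null(attr(fm, "scaling"))) fm <- apply_scaler(fm, fit_scaler(fm))
  folds <- folds %||% make_folds(nrow(fm), k, seed)
  rmse <- vapply(sort(unique(folds)), function(fd) {
    tr <- fm[folds != fd, ]
    te <- fm[folds == fd, ]
    model <- fit_kind(kind, new_feature_matrix(tr, attr(fm, "scaling")), hp)
    pred <- predict(model, new_feature_matrix(te, attr(fm, "scaling")))
    sqrt(mean((te$target_ha_rmsd - pred)^2))
  }, numeric(1))
  mean(rmse)
}

#' Default hyperparameter grids
#'
#' linSVR: regularization C from 1e-8 to 1e8 in decade steps (17 points).
#' radSVR: C from 1e-4 to 1e10 crossed with RBF width gamma from 1e-11 to
#' 1e2 in decade steps. The gamma grid is deliberately capped at 1e2 even
#' though CV error can still be decreasing there: very large gamma shrinks
#' each support vector's influence and overfits.
#'
#' @param kind `"linsvr"`, `"radsvr"` or `"pls"` (grid over `ncomp` 1..30).
#' @return tibble of grid points.
#' @export
default_grid <- function(kind = c("linsvr", "radsvr", "pls")) {
  kind <- match.arg(kind)
  switch(kind,
    linsvr = tibble(C = 10^seq(-8, 8)),
    radsvr = tidyr::expand_grid(C = 10^seq(-4, 10), gamma = 10^seq(-11, 2)),
    pls = tibble(ncomp = 1:30)
  )
}

#' Cross-validated hyperparameter grid search
#'
#' Evaluates every grid point with identical seeded folds and returns the
#' point with the lowest mean CV RMSE. Ties (within 1e-12) are broken toward
#' the smallest `C`, then smallest `gamma` — preferring the simpler, less
#' overfit model. Solver non-convergence at extreme hyperparameters is
#' recorded as a missing (`NA`) grid cell rather than an error.
#'
#' @param fm a `feature_matrix` with `target_ha_rmsd`.
#' @param kind model kind (see [cross_validate()]).
#' @param grid tibble of hyperparameter combinations (see [default_grid()]).
#' @param k,seed fold count and seed.
#' @param epsilon SVR tube half-width applied to every grid point.
#' @param max_iter solver iteration cap per fit.
#' @return a `cv_result`: list with `best` (named list of hyperparameters),
#'   `cv` (the full grid with an `rmse` column), `k`, `seed`.
#' @export
grid_search <- function(fm, kind, grid = default_grid(kind), k = 10, seed = 1,
                        epsilon = 0.1, max_iter = 1e6) {
  if (nrow(grid) == 0) abort("empty hyperparameter grid")
  if (is.null(attr(fm, "scaling"))) fm <- apply_scaler(fm, fit_scaler(fm))
  folds <- make_folds(nrow(fm), k, seed)
  # Iteration-cap warnings are muffled here: a capped fit is still a valid
  # model (its CV error speaks for itself), which mirrors how the reference
  # SMO implementations behave. Hard solver failures become missing cells.
  rmse <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- as.list(grid[i, ])
    hp$epsilon <- hp$epsilon %||% epsilon
    hp$max_iter <- max_iter
    tryCatch(
      withCallingHandlers(
        cross_validate(fm, kind, hp, folds = folds),
        warning = function(w) {
          if (grepl("iteration cap", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        }
      ),
      error = function(e) NA_real_
    )
  }, numeric(1))
  cv <- grid
  cv$rmse <- rmse
  if (all(is.na(rmse))) abort("no grid point converged")
  best_rmse <- min(rmse, na.rm = TRUE)
  cand <- cv[!is.na(cv$rmse) & cv$rmse <= best_rmse + 1e-12, , drop = FALSE]
  ord <- do.call(order, unname(as.list(cand[, intersect(c("C", "gamma", "ncomp"),
                                                        names(cand)), drop = FALSE])))
  best <- as.list(cand[ord[1], setdiff(names(cand), "rmse"), drop = FALSE])
  best$epsilon <- best$epsilon %||% (if (kind %in% c("linsvr", "radsvr")) epsilon)
  structure(list(best = best, cv = cv, k = k, seed = seed, kind = kind),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$kind, ", ", nrow(x$cv), " grid points, ",
      x$k, "-fold CV (seed ", x$seed, ")\n", sep = "")
  cat("  best:", paste(names(x$best), "=", vapply(x$best, format, character(1)),
                       collapse = ", "),
      " (rmse ", format(min(x$cv$rmse, na.rm = TRUE), digits = 4), ")\n")
  invisible(x)
}

#' @rdname grid_search
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
tidy.cv_result <- function(x, ...) as_tibble(x$cv)
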