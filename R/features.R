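META_COLS <- c("target_id", "decoy_id", "target_ha_rmsd", "target_ca_rmsd",
               "total_energy", "peptide_energy")

new_feature_matrix <- function(tbl, scaling = NULL) {
  tbl <- as_tibble(tbl)
  class(tbl) <- c("feature_matrix", class(tbl))
  attr(tbl, "scaling") <- scaling
  tbl
}

#' Names of the feature columns of a feature matrix
#'
#' Feature columns are named `p{position}_{term}` (position-major, term
#' alphabetical within position); identifier, target-RMSD and energy columns
#' are metadata, never predictors.
#'
#' @param fm a feature matrix (tibble).
#' @return character vector of feature column names.
#' @export
feature_cols <- function(fm) {
  setdiff(names(fm), META_COLS)
}

# order feature names position-major, term alphabetical
order_feature_names <- function(nms) {
  pos <- as.integer(sub("^p([1-9])_.*$", "\\1", nms))
  term <- sub("^p[1-9]_", "", nms)
  nms[order(pos, term)]
}

#' Read a per-residue score table for one decoy
#'
#' Two dialects are supported. `"generic_csv"`: a CSV with a `position`
#' column (1-9) and one column per score term. `"rosetta_per_residue"`: a
#' whitespace-separated table in the style of Rosetta per-residue energy
#' breakdowns — lines starting with `SCORE:`, a header naming the terms, and
#' a final `description` column whose residue label ends in `_<position>`;
#' only rows whose position falls in 1-9 (the peptide) are used.
#'
#' @param path file path.
#' @param dialect `"generic_csv"` or `"rosetta_per_residue"`.
#' @param decoy_id identifier recorded for this decoy (default: file name).
#' @return tibble with columns `decoy_id`, `position`, `term`, `value`; all
#'   nine positions present with an identical term set at each.
#' @export
read_score_table <- function(path, dialect = c("generic_csv", "rosetta_per_residue"),
                             decoy_id = NULL) {
  dialect <- match.arg(dialect)
  decoy_id <- decoy_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "generic_csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
    if (!"position" %in% names(df)) abort("generic_csv dialect needs a 'position' column")
    long <- tidyr::pivot_longer(df, -"position", names_to = "term", values_to = "value")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[startsWith(lines, "SCORE:")]
    if (length(lines) < 2) abort("no SCORE: lines found in rosetta_per_residue file")
    fields <- lapply(lines, function(l) strsplit(trimws(sub("^SCORE:", "", l)), "\\s+")[[1]])
    header <- fields[[1]]
    if (utils::tail(header, 1) != "description") {
      abort("rosetta_per_residue header must end in 'description'")
    }
    terms <- header[-length(header)]
    rows <- lapply(fields[-1], function(f) {
      desc <- utils::tail(f, 1)
      pos <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", desc)))
      vals <- suppressWarnings(as.numeric(f[-length(f)]))
      tibble(position = pos, term = terms, value = vals)
    })
    long <- bind_rows(rows)
    long <- long[!is.na(long$position) & long$position >= 1 & long$position <= 9, ]
  }
  long$position <- as.integer(long$position)
  missing_pos <- setdiff(1:9, unique(long$position))
  if (length(missing_pos) > 0) {
    abort(paste0("missing positions: ", paste(missing_pos, collapse = ",")))
  }
  per_pos_terms <- tapply(long$term, long$position, function(t) paste(sort(t), collapse = "|"))
  if (length(unique(per_pos_terms)) != 1) {
    abort("term sets differ across positions within one score table")
  }
  tibble(decoy_id = decoy_id, position = long$position,
         term = long$term, value = long$value)
}

#' Assemble the decoy-by-feature matrix
#'
#' Joins per-residue score tables with (optionally) per-residue SASA/hSASA
#' into one row per decoy with columns `p{position}_{term}` in deterministic
#' position-major, term-alphabetical order. True RMSDs and total/peptide
#' energies, when supplied, are carried as metadata columns — energies are
#' selection baselines, never predictor features.
#'
#' @param tables long score tibble (`decoy_id`, `position`, `term`, `value`)
#'   or a list of such tibbles from [read_score_table()].
#' @param sasa optional tibble `decoy_id`, `position`, `sasa`, `hsasa`
#'   (e.g. `tidy()` of [shrake_rupley()] results), added as terms `sasa` and
#'   `hsasa`.
#' @param rmsd optional tibble `decoy_id`, `target_ha_rmsd` (and
#'   `target_ca_rmsd`).
#' @param energy optional tibble `decoy_id`, `total_energy`,
#'   `peptide_energy`.
#' @return a `feature_matrix` tibble, rows ordered by `decoy_id`.
#' @export
assemble_features <- function(tables, sasa = NULL, rmsd = NULL, energy = NULL) {
  long <- if (is.data.frame(tables)) as_tibble(tables) else bind_rows(tables)
  if (!is.null(sasa)) {
    sl <- tidyr::pivot_longer(as_tibble(sasa), c("sasa", "hsasa"),
                              names_to = "term", values_to = "value")
    long <- bind_rows(long, sl[, c("decoy_id", "position", "term", "value")])
  }
  universe <- tapply(paste0("p", long$position, "_", long$term), long$decoy_id,
                     function(k) paste(sort(unique(k)), collapse = "|"))
  if (length(unique(universe)) != 1) {
    abort("inconsistent term universe across decoys")
  }
  long$column <- paste0("p", long$position, "_", long$term)
  wide <- tidyr::pivot_wider(long[, c("decoy_id", "column", "value")],
                             names_from = "column", values_from = "value")
  feat <- order_feature_names(setdiff(names(wide), "decoy_id"))
  wide <- wide[order(wide$decoy_id), c("decoy_id", feat)]
  if (!is.null(rmsd)) wide <- left_join(wide, as_tibble(rmsd), by = "decoy_id")
  if (!is.null(energy)) wide <- left_join(wide, as_tibble(energy), by = "decoy_id")
  meta <- intersect(META_COLS, names(wide))
  new_feature_matrix(wide[, c(meta, feat)])
}

#' Term filtering policy
#'
#' Reproduces the training-data filter rules: keep only terms with non-zero
#' variance across all decoys and drop terms that are specific to residue
#' identity (e.g. an aromatic ring-planarity term), named on an a priori
#' exclusion list.
#'
#' @param exclusion term names (the `{term}` part of `p{pos}_{term}`)
#'   excluded regardless of variance.
#' @param min_variance columns with variance `<= min_variance` are dropped
#'   (default 0: exact zero-variance test).
#' @return a `term_filter_policy`.
#' @export
term_filter_policy <- function(exclusion = character(), min_variance = 0) {
  if (anyDuplicated(exclusion)) abort("exclusion list entries must be unique")
  structure(list(exclusion = exclusion, min_variance = min_variance),
            class = "term_filter_policy")
}

#' Filter feature columns by policy
#'
#' @param fm an unscaled `feature_matrix`.
#' @param policy a [term_filter_policy()].
#' @param verbose log removed columns.
#' @return filtered `feature_matrix`; idempotent.
#' @export
filter_terms <- function(fm, policy = term_filter_policy(), verbose = TRUE) {
  if (!is.null(attr(fm, "scaling"))) abort("filter_terms expects an unscaled matrix")
  feat <- feature_cols(fm)
  term <- sub("^p[1-9]_", "", feat)
  by_name <- feat[term %in% policy$exclusion]
  vars <- vapply(feat, function(cn) stats::var(fm[[cn]]), numeric(1))
  by_var <- feat[is.na(vars) | vars <= policy$min_variance]
  drop <- union(by_name, by_var)
  keep <- setdiff(feat, drop)
  if (length(keep) == 0) abort("empty feature matrix after filtering")
  if (verbose && length(drop) > 0) {
    inform(paste0("filter_terms removed ", length(drop), " column(s): ",
                  paste(drop, collapse = ", ")))
  }
  new_feature_matrix(fm[, c(intersect(META_COLS, names(fm)), keep)])
}

#' Fit and apply per-column standardization
#'
#' Centers each feature column at its mean and scales by its sample standard
#' deviation (n - 1 denominator). The fitted scaler is serializable (it is
#' stored inside model JSON) and reusable on new decoys, so held-out rows are
#' scaled with training-set statistics — their scaled means need not be zero.
#'
#' @param fm a `feature_matrix` (post-filter, so all sds are positive).
#' @return `fit_scaler`: tibble with `column`, `mean`, `sd`.
#' @export
fit_scaler <- function(fm) {
  feat <- feature_cols(fm)
  sc <- tibble(
    column = feat,
    mean = unname(vapply(feat, function(cn) mean(fm[[cn]]), numeric(1))),
    sd = unname(vapply(feat, function(cn) stats::sd(fm[[cn]]), numeric(1)))
  )
  if (any(!is.finite(sc$sd)) || any(sc$sd <= 0)) {
    abort("zero or non-finite column sd; run filter_terms() first")
  }
  sc
}

#' @rdname fit_scaler
#' @param scaler a scaler tibble from `fit_scaler()`.
#' @return `apply_scaler`: the scaled `feature_matrix` (scaling recorded in
#'   attribute `"scaling"`).
#' @export
apply_scaler <- function(fm, scaler) {
  missing_cols <- setdiff(scaler$column, names(fm))
  if (length(missing_cols) > 0) {
    abort(paste0("feature matrix lacks scaler column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- fm
  for (i in seq_len(nrow(scaler))) {
    cn <- scaler$column[i]
    out[[cn]] <- (out[[cn]] - scaler$mean[i]) / scaler$sd[i]
  }
  new_feature_matrix(out, scaling = scaler)
}

# run expr with a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derived stream seeds, kept below 2^31
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + 104729 * as.double(stream)) %% 2147483647
}

#' Seeded train/test split, optionally stratified on the target
#'
#' Randomly partitions decoys into training (default 80%) and test rows.
#' With `stratify_bins > 1`, rows are binned by target-RMSD quantiles and
#' split within bins, so training and test RMSD distributions are comparable
#' even for skewed or multimodal ensembles.
#'
#' @param fm a `feature_matrix` with a `target_ha_rmsd` column.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed; identical seeds give identical partitions.
#' @param stratify_bins number of target-quantile bins (1 = plain split).
#' @return list with `train` and `test` feature matrices.
#' @export
split_train_test <- function(fm, fraction = 0.8, seed = 1, stratify_bins = 1) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (!"target_ha_rmsd" %in% names(fm)) abort("target_ha_rmsd column required")
  n <- nrow(fm)
  y <- fm$target_ha_rmsd
  idx_train <- with_seed(seed, {
    if (stratify_bins > 1) {
      br <- unique(stats::quantile(y, probs = seq(0, 1, length.out = stratify_bins + 1)))
      bin <- cut(y, breaks = br, include.lowest = TRUE, labels = FALSE)
      unlist(lapply(split(seq_len(n), bin), function(ix) {
        sample(ix, round(length(ix) * fraction))
      }), use.names = FALSE)
    } else {
      sample.int(n, round(n * fraction))
    }
  })
  idx_train <- sort(idx_train)
  list(
    train = new_feature_matrix(fm[idx_train, ], attr(fm, "scaling")),
    test = new_feature_matrix(fm[-idx_train, ], attr(fm, "scaling"))
  )
}

#' Write / read a feature matrix as CSV
#'
#' The CSV carries metadata columns first, then position-major feature
#' columns, preceded by a `#` provenance header line.
#'
#' @param fm a `feature_matrix`.
#' @param path file path.
#' @param provenance optional character vector of extra header lines.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_features <- function(fm, path, provenance = NULL) {
  hdr <- c(paste0("# decoyrank feature matrix v1; generated ",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           if (!is.null(provenance)) paste0("# ", provenance))
  writeLines(hdr, path)
  suppressWarnings(readr::write_csv(as_tibble(as.data.frame(fm)), path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  new_feature_matrix(readr::read_csv(path, comment = "#", show_col_types = FALSE))
}
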