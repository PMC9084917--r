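#' Bundle one target's decoys into an ensemble
#'
#' A `decoy_ensemble` holds the per-decoy feature rows of one target complex
#' together with selection baselines (total and peptide-only energy) and —
#' when the reference crystal structure is known — the true groove-superposed
#' Cα/HA RMSDs.
#'
#' @param target_id label for the target complex.
#' @param features a `feature_matrix` with a `decoy_id` column; optional
#'   metadata columns `target_ha_rmsd`, `target_ca_rmsd`, `total_energy`,
#'   `peptide_energy`.
#' @param sequence optional 9-letter peptide sequence.
#' @return a `decoy_ensemble`.
#' @export
decoy_ensemble <- function(target_id, features, sequence = NULL) {
  if (!"decoy_id" %in% names(features)) abort("features need a decoy_id column")
  if (nrow(features) < 1) abort("empty ensemble")
  if ("target_ha_rmsd" %in% names(features) &&
      any(features$target_ha_rmsd < 0, na.rm = TRUE)) {
    abort("true RMSDs must be non-negative")
  }
  if (!is.null(sequence) && nchar(sequence) != 9) {
    abort("sequence length != 9")
  }
  structure(list(target_id = target_id, features = features, sequence = sequence),
            class = "decoy_ensemble")
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat("<decoy_ensemble> ", x$target_id,
      if (!is.null(x$sequence)) paste0(" (", x$sequence, ")"),
      ": ", nrow(x$features), " decoys\n", sep = "")
  invisible(x)
}

ensemble_criterion <- function(ensemble, criterion, model = NULL) {
  fm <- ensemble$features
  switch(criterion,
    true_ha_rmsd = {
      if (!"target_ha_rmsd" %in% names(fm)) abort("criterion column absent: target_ha_rmsd")
      fm$target_ha_rmsd
    },
    total_energy = {
      if (!"total_energy" %in% names(fm)) abort("criterion column absent: total_energy")
      fm$total_energy
    },
    peptide_energy = {
      if (!"peptide_energy" %in% names(fm)) abort("criterion column absent: peptide_energy")
      fm$peptide_energy
    },
    predicted_rmsd = {
      if (is.null(model)) abort("criterion 'predicted_rmsd' needs a model")
      predict(model, fm)
    },
    abort(paste0("unknown criterion: ", criterion))
  )
}

#' Rank the decoys of an ensemble by a criterion
#'
#' Ascending criterion values get ascending ranks (rank 1 = best = lowest
#' RMSD or energy); ties receive average (mid) ranks. When true HA RMSDs are
#' available the Spearman correlation of the criterion against them is
#' attached — `NA` with a warning when the criterion (or truth) is constant,
#' the degenerate case of an ensemble sampled so tightly there are no good
#' vs. bad decoys to discriminate.
#'
#' @param ensemble a [decoy_ensemble()].
#' @param criterion one of `"true_ha_rmsd"`, `"total_energy"`,
#'   `"peptide_energy"`, `"predicted_rmsd"`.
#' @param model a `decoy_model`, required for `"predicted_rmsd"`.
#' @return a `ranking_result` tibble (`decoy_id`, `value`, `rank`) with
#'   attributes `criterion` and `spearman_vs_true`.
#' @export
rank_decoys <- function(ensemble, criterion = "true_ha_rmsd", model = NULL) {
  values <- ensemble_criterion(ensemble, criterion, model)
  out <- tibble(
    decoy_id = ensemble$features$decoy_id,
    value = values,
    rank = rank(values, ties.method = "average")
  )
  rho <- NA_real_
  if ("target_ha_rmsd" %in% names(ensemble$features)) {
    rho <- spearman_rho(values, ensemble$features$target_ha_rmsd)
  }
  class(out) <- c("ranking_result", class(out))
  attr(out, "criterion") <- criterion
  attr(out, "spearman_vs_true") <- rho
  out
}

#' Select the optimal decoy of an ensemble by a criterion
#'
#' Argmin of the selection criterion; ties are broken deterministically by
#' lexical decoy id. `"best_true"` is the oracle (lowest true HA RMSD);
#' `"model"` selects by predicted RMSD.
#'
#' @param ensemble a [decoy_ensemble()].
#' @param method `"best_true"`, `"lowest_total_energy"`,
#'   `"lowest_peptide_energy"` or `"model"`.
#' @param model a `decoy_model` (for `method = "model"`).
#' @param method_label name recorded in the output row.
#' @return one-row tibble: `target_id`, `method`, `decoy_id`,
#'   `criterion_value`, plus `true_ha_rmsd`/`true_ca_rmsd` when available.
#' @export
select_optimal <- function(ensemble,
                           method = c("best_true", "lowest_total_energy",
                                      "lowest_peptide_energy", "model"),
                           model = NULL, method_label = NULL) {
  method <- match.arg(method)
  criterion <- switch(method,
    best_true = "true_ha_rmsd",
    lowest_total_energy = "total_energy",
    lowest_peptide_energy = "peptide_energy",
    model = "predicted_rmsd"
  )
  values <- ensemble_criterion(ensemble, criterion, model)
  fm <- ensemble$features
  best <- order(values, fm$decoy_id)[1]
  tibble(
    target_id = ensemble$target_id,
    method = method_label %||% method,
    decoy_id = fm$decoy_id[best],
    criterion_value = values[best],
    true_ha_rmsd = if ("target_ha_rmsd" %in% names(fm)) fm$target_ha_rmsd[best] else NA_real_,
    true_ca_rmsd = if ("target_ca_rmsd" %in% names(fm)) fm$target_ca_rmsd[best] else NA_real_
  )
}

#' Compare decoy-selection methods across targets
#'
#' For every target ensemble, selects one decoy per method and summarises
#' the distributions of the selected decoys' true RMSDs; named method pairs
#' are compared with paired significance tests on per-target true HA RMSDs.
#'
#' By construction the oracle `best_true` method has the lowest possible
#' mean; the question the tests answer is whether a trained selector gets
#' significantly closer to it than energy-based selection does.
#'
#' @param ensembles list of [decoy_ensemble()] objects (>= 2).
#' @param methods named list; each element is a method string accepted by
#'   [select_optimal()] or a fitted `decoy_model`.
#' @param tests optional list of test specs, each a list with `pair`
#'   (two method names), `test` (`"wilcoxon"` or `"ttest"`) and
#'   `alternative` (defaults `"less"`: the first method selects decoys with
#'   smaller true RMSD).
#' @return a `selection_comparison`: list with `selections` (tibble, one row
#'   per target x method), `summary` (per-method distribution summaries,
#'   ascending mean HA RMSD), and `tests` (tibble of test results).
#' @export
compare_methods <- function(ensembles, methods, tests = NULL) {
  if (length(ensembles) < 2) abort("need at least 2 targets")
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort("methods must be a fully named list")
  }
  selections <- bind_rows(lapply(ensembles, function(ens) {
    bind_rows(lapply(names(methods), function(nm) {
      m <- methods[[nm]]
      if (inherits(m, "decoy_model")) {
        select_optimal(ens, "model", model = m, method_label = nm)
      } else {
        select_optimal(ens, m, method_label = nm)
      }
    }))
  }))
  summary_tbl <- selections |>
    group_by(method = .data$method) |>
    summarise(
      mean_ha = mean(.data$true_ha_rmsd), median_ha = stats::median(.data$true_ha_rmsd),
      q1_ha = unname(quantile(.data$true_ha_rmsd, 0.25)),
      q3_ha = unname(quantile(.data$true_ha_rmsd, 0.75)),
      mean_ca = mean(.data$true_ca_rmsd), median_ca = stats::median(.data$true_ca_rmsd),
      n_targets = dplyr::n(), .groups = "drop"
    ) |>
    arrange(.data$mean_ha)
  test_rows <- lapply(tests %||% list(), function(ts) {
    ts$alternative <- ts$alternative %||% "less"
    bad <- setdiff(ts$pair, names(methods))
    if (length(bad) > 0) {
      abort(paste0("test on method(s) not evaluated: ", paste(bad, collapse = ", ")))
    }
    a <- selections$true_ha_rmsd[selections$method == ts$pair[1]]
    b <- selections$true_ha_rmsd[selections$method == ts$pair[2]]
    d <- a - b
    if (all(d == 0)) {
      # identical selections: nothing to test, report the degenerate result
      return(tibble(method_a = ts$pair[1], method_b = ts$pair[2], test = ts$test,
                    alternative = ts$alternative, statistic = 0, p_value = 1,
                    note = "identical selections"))
    }
    res <- switch(ts$test,
      wilcoxon = wilcoxon_signed_rank(d, alternative = ts$alternative),
      ttest = paired_t(d, alternative = ts$alternative),
      abort(paste0("unknown test: ", ts$test))
    )
    tibble(method_a = ts$pair[1], method_b = ts$pair[2], test = ts$test,
           alternative = ts$alternative, statistic = res$statistic,
           p_value = res$p_value, note = NA_character_)
  })
  structure(
    list(selections = selections, summary = summary_tbl,
         tests = bind_rows(test_rows)),
    class = "selection_comparison"
  )
}

#' @export
print.selection_comparison <- function(x, ...) {
  cat("<selection_comparison> ", length(unique(x$selections$target_id)),
      " targets x ", nrow(x$summary), " methods\n", sep = "")
  print(x$summary)
  if (nrow(x$tests) > 0) print(x$tests)
  invisible(x)
}

#' @rdname compare_methods
#' @param x a `selection_comparison`.
#' @param ... unused.
#' @export
tidy.selection_comparison <- function(x, ...) x$selections

#' @rdname compare_methods
#' @export
glance.selection_comparison <- function(x, ...) x$summary

#' Stratify selected-decoy error by peptide position and amino acid
#'
#' Averages per-position RMSDs of the selected decoys across targets
#' (backbone and side-chain classes), and heavy-atom RMSD by
#' (position, amino acid). Amino acids represented at a position in fewer
#' than `min_count` peptides are omitted — absent, not zero.
#'
#' @param reports tibble of per-position RMSD rows across targets: columns
#'   `target_id`, `position`, `atom_class`, `rmsd` (e.g. `tidy()` of
#'   [stratified_rmsd()] reports, one selected decoy per target).
#' @param sequences named character vector, target id -> 9-letter peptide
#'   sequence.
#' @param min_count minimum peptides per (position, amino acid) cell.
#' @return a `stratified_error_table`: list with `by_position` (tibble:
#'   `position`, `atom_class`, `mean_rmsd`, `n_targets`) and `by_residue`
#'   (tibble: `position`, `aa`, `mean_ha_rmsd`, `n`).
#' @export
stratify_errors <- function(reports, sequences, min_count = 3) {
  if (any(nchar(sequences) != 9)) abort("sequence length != 9")
  reports <- as_tibble(reports)
  missing_seq <- setdiff(unique(reports$target_id), names(sequences))
  if (length(missing_seq) > 0) {
    abort(paste0("no sequence for target(s): ", paste(missing_seq, collapse = ", ")))
  }
  by_position <- reports |>
    filter(!is.na(.data$rmsd)) |>
    group_by(.data$position, .data$atom_class) |>
    summarise(mean_rmsd = mean(.data$rmsd), n_targets = dplyr::n(), .groups = "drop")
  ha <- reports |>
    filter(.data$atom_class == "heavy", !is.na(.data$rmsd)) |>
    mutate(aa = unname(substr(sequences[.data$target_id], .data$position, .data$position)))
  by_residue <- ha |>
    group_by(.data$position, .data$aa) |>
    summarise(mean_ha_rmsd = mean(.data$rmsd), n = dplyr::n(), .groups = "drop") |>
    filter(.data$n >= min_count)
  structure(list(by_position = by_position, by_residue = by_residue,
                 min_count = min_count),
            class = "stratified_error_table")
}

#' @export
print.stratified_error_table <- function(x, ...) {
  cat("<stratified_error_table> min_count =", x$min_count, "\n")
  print(x$by_position)
  print(x$by_residue)
  invisible(x)
}

#' @rdname stratify_errors
#' @param x a `stratified_error_table`.
#' @param ... unused.
#' @export
tidy.stratified_error_table <- function(x, ...) x$by_residue
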