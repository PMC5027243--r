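# Cohort-level models: mutation-type x group mixed-effects interaction,
# count regression for inversion/deletion enrichment, and the aggregate
# report.

#' Long per-sample mutation count table
#'
#' One row per (sample, mutation type) with types `substitution`, `deletion`
#' and `insertion`; the response shape expected by
#' [mixed_interaction_model()].
#'
#' @param catalogues List of [tumour_catalogue()] objects, or a
#'   [burden_summary()] tibble.
#' @return Tibble: `sample_id`, `group`, `mutation_type`, `count`.
#' @export
long_count_table <- function(catalogues) {
  burdens <- if (is.data.frame(catalogues)) {
    tibble::as_tibble(catalogues)
  } else {
    burden_summary(catalogues)
  }
  burdens |>
    dplyr::transmute(.data$sample_id, .data$group,
                     substitution = .data$n_subs, deletion = .data$n_del,
                     insertion = .data$n_ins) |>
    tidyr::pivot_longer(c("substitution", "deletion", "insertion"),
                        names_to = "mutation_type", values_to = "count")
}

#' Mutation-type x group mixed-effects interaction model
#'
#' Fits `log(count + 1) ~ mutation_type * group + (1 | sample_id)`: the
#' per-sample random intercept absorbs total burden so the type-by-group
#' interaction isolates, for example, a deletion-specific excess in the
#' exposed group. P-values are Satterthwaite-approximate (lmerTest).
#'
#' @param table Long count table from [long_count_table()].
#' @param type_ref,group_ref Reference levels (defaults: `"substitution"`
#'   and the first group in the table).
#' @return Object of class `radsig_mixed` with elements `fit`,
#'   `interactions` (tibble: `term`, `estimate`, `std_error`, `df`,
#'   `p_value`) and `coefficients` (all fixed effects).
#' @export
mixed_interaction_model <- function(table, type_ref = "substitution",
                                    group_ref = NULL) {
  table <- tibble::as_tibble(table)
  groups <- unique(table$group)
  types <- unique(table$mutation_type)
  if (length(groups) < 2L || length(types) < 2L) {
    abort("need at least 2 groups and 2 mutation types")
  }
  cells <- table |>
    dplyr::count(.data$group, .data$mutation_type)
  full <- tidyr::expand_grid(group = groups, mutation_type = types)
  missing_cell <- dplyr::anti_join(full, cells,
                                   by = c("group", "mutation_type"))
  if (nrow(missing_cell) > 0L) {
    abort(paste0("singular design: no counts for group '",
                 missing_cell$group[1L], "' x type '",
                 missing_cell$mutation_type[1L], "'"))
  }
  n_per_group <- table |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$group)
  if (any(n_per_group$n < 2L)) {
    abort("random intercept inestimable: need >= 2 samples per group")
  }
  if (is.null(group_ref)) group_ref <- groups[1L]
  df <- dplyr::mutate(
    table,
    mutation_type = stats::relevel(factor(.data$mutation_type),
                                   ref = type_ref),
    group = stats::relevel(factor(.data$group), ref = group_ref),
    log_count = log(.data$count + 1)
  )
  fit <- lmerTest::lmer(log_count ~ mutation_type * group + (1 | sample_id),
                        data = df)
  sm <- summary(fit)$coefficients
  all_terms <- tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    df = unname(sm[, "df"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  interactions <- all_terms[grepl(":", all_terms$term), , drop = FALSE]
  structure(list(fit = fit, interactions = interactions,
                 coefficients = all_terms),
            class = "radsig_mixed")
}

#' @export
print.radsig_mixed <- function(x, ...) {
  cat("<radsig_mixed> log(count+1) ~ mutation_type * group + (1 | sample)\n")
  print(x$interactions)
  invisible(x)
}

#' Count regression of per-sample burdens on group
#'
#' Log-link Poisson regression of per-sample counts (balanced inversions,
#' deletions, ...) on group, with an automatic overdispersion check: when
#' the Pearson dispersion exceeds `dispersion_limit` the model is refit with
#' a quasi-Poisson variance and that fit's inference is reported. Under a
#' Poisson fit with a two-level factor the group coefficient is exactly the
#' log ratio of group means.
#'
#' @param data Data frame holding the counts and labels.
#' @param count,group Column names (strings) of the response and grouping
#'   factor.
#' @param group_ref Reference group level (default: first level).
#' @param dispersion_limit Pearson-dispersion threshold for the
#'   quasi-Poisson switch (default 2).
#' @return Object of class `radsig_glm`: `fit`, `family` used,
#'   `dispersion`, `overdispersed`, `coefficients` tibble (log rate ratios
#'   with `std_error`, `p_value`).
#' @export
count_glm <- function(data, count = "count", group = "group",
                      group_ref = NULL, dispersion_limit = 2) {
  y <- data[[count]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("need at least 2 groups")
  if (all(y == 0)) abort("all counts are zero")
  if (!is.null(group_ref)) g <- stats::relevel(g, ref = group_ref)
  fit <- glm(y ~ g, family = poisson())
  disp <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  overdispersed <- is.finite(disp) && disp > dispersion_limit
  if (overdispersed) {
    fit <- glm(y ~ g, family = quasipoisson())
  }
  sm <- summary(fit)$coefficients
  terms <- sub("^g", "group", rownames(sm))
  coefs <- tibble::tibble(
    term = terms,
    estimate = unname(sm[, 1L]),
    std_error = unname(sm[, 2L]),
    p_value = unname(sm[, 4L])
  )
  structure(list(fit = fit,
                 family = if (overdispersed) "quasipoisson" else "poisson",
                 dispersion = disp, overdispersed = overdispersed,
                 coefficients = coefs),
            class = "radsig_glm")
}

#' @export
print.radsig_glm <- function(x, ...) {
  cat("<radsig_glm> count ~ group,", x$family,
      sprintf("(dispersion %.2f%s)\n", x$dispersion,
              if (x$overdispersed) ", overdispersed" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Cohort-level aggregate report
#'
#' Per-group medians of substitution, indel and rearrangement-breakpoint
#' burdens; the balanced-inversion survey (with optional pooled rows); the
#' mutation-type x group mixed model; and a count regression of balanced
#' inversion counts on group.
#'
#' @param catalogues List of [tumour_catalogue()] objects.
#' @param config [screen_config()] shared by every sample.
#' @param pooled Optional named list of group-label vectors to pool in the
#'   inversion survey, e.g. `list(naive = c("naive_breast",
#'   "naive_osteosarcoma"))`.
#' @param glm_group_ref Reference level for the inversion count regression.
#' @return Object of class `radsig_report` with elements `burdens`,
#'   `group_medians`, `inversion_summary`, `inversion_per_sample`,
#'   `mixed_model`, `inversion_glm`.
#' @export
cohort_report <- function(catalogues, config = screen_config(),
                          pooled = NULL, glm_group_ref = NULL) {
  burdens <- burden_summary(catalogues)
  breakpoints <- setNames(
    purrr::map_int(catalogues, function(cat) 2L * nrow(cat$rearrangements)),
    purrr::map_chr(catalogues, "sample_id"))
  burdens$n_breakpoints <- unname(breakpoints[burdens$sample_id])
  group_medians <- burdens |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      median_substitutions = median(.data$n_subs),
      median_indels = median(.data$n_del + .data$n_ins + .data$n_complex),
      median_breakpoints = median(.data$n_breakpoints),
      median_indel_sub_ratio = median(.data$indel_sub_ratio, na.rm = TRUE),
      median_del_ins_ratio = median(.data$del_ins_ratio, na.rm = TRUE)
    )
  inv_summary <- inversion_cohort_summary(catalogues, config)
  per_sample_inv <- attr(inv_summary, "per_sample")
  if (!is.null(pooled)) {
    pooled_rows <- purrr::imap_dfr(pooled, function(groups, label) {
      pool_inversion_summary(inv_summary, groups, label)
    })
    inv_summary <- dplyr::bind_rows(inv_summary, pooled_rows)
  }
  mixed <- tryCatch(mixed_interaction_model(long_count_table(burdens)),
                    error = function(e) e)
  inv_glm <- tryCatch(
    count_glm(per_sample_inv, count = "n_inversions", group = "group",
              group_ref = glm_group_ref),
    error = function(e) e
  )
  structure(list(burdens = burdens, group_medians = group_medians,
                 inversion_summary = inv_summary,
                 inversion_per_sample = per_sample_inv,
                 mixed_model = mixed, inversion_glm = inv_glm),
            class = "radsig_report")
}

#' @export
print.radsig_report <- function(x, ...) {
  cat("<radsig_report>\n\nPer-group medians:\n")
  print(x$group_medians)
  cat("\nBalanced-inversion survey:\n")
  print(x$inversion_summary)
  if (inherits(x$mixed_model, "radsig_mixed")) {
    cat("\nMutation-type x group interactions:\n")
    print(x$mixed_model$interactions)
  }
  if (inherits(x$inversion_glm, "radsig_glm")) {
    cat("\nInversion count regression:\n")
    print(x$inversion_glm$coefficients)
  }
  invisible(x)
}

#' Serialize a cohort report to TSV + JSON
#'
#' @param report A `radsig_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$burdens, file.path(dir, "burdens.tsv"))
  readr::write_tsv(report$group_medians, file.path(dir, "group_medians.tsv"))
  readr::write_tsv(report$inversion_summary,
                   file.path(dir, "inversion_summary.tsv"))
  out <- list(
    group_medians = report$group_medians,
    inversion_summary = report$inversion_summary,
    mixed_interactions = if (inherits(report$mixed_model, "radsig_mixed"))
      report$mixed_model$interactions,
    inversion_glm = if (inherits(report$inversion_glm, "radsig_glm"))
      list(family = report$inversion_glm$family,
           dispersion = report$inversion_glm$dispersion,
           coefficients = report$inversion_glm$coefficients)
  )
  jsonlite::write_json(out, file.path(dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
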