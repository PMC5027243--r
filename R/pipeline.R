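# Pipeline orchestration: simulate/load -> inversion screen -> indel
# metrics -> genome distribution -> clonality -> cohort report, with a
# provenance block and per-stage status so partial failures keep earlier
# outputs.

#' Validate a pipeline run configuration
#'
#' A run configuration (YAML file or list) has an `out_dir`, and either a
#' `simulate` block (`seed`, optionally any [sim_params()] override written
#' out by hand) or an `inputs` block with `manifest`, `reference`,
#' `callable`, `tracks` paths. Optional blocks: `screen` (fields of
#' [screen_config()]), `genome_dist` (`n_background`, `window_bp`, `seed`),
#' `clonality` (`clonal_threshold`), `pooled` (named group sets for the
#' survey).
#'
#' @param config Path to a YAML file or an equivalent list.
#' @return The normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    config$.base_dir <- base
  }
  if (is.null(config$out_dir)) abort("config requires out_dir")
  if (is.null(config$simulate) && is.null(config$inputs)) {
    abort("config requires either a simulate block or an inputs block")
  }
  if (!is.null(config$inputs)) {
    base <- config$.base_dir %||% "."
    for (key in c("manifest", "reference", "callable", "tracks")) {
      p <- config$inputs[[key]]
      if (is.null(p)) abort(paste0("inputs block missing ", key))
      if (!file.exists(p) && !file.exists(file.path(base, p))) {
        abort(paste0("input path does not exist (stage: load, ", key, "): ",
                     p))
      }
    }
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes every stage whose inputs are present and writes `report.json`,
#' per-stage TSVs and a provenance block (package version, seeds, config
#' hash) under `out_dir`. A stage failure is recorded in the report without
#' discarding other stages' outputs.
#'
#' @param config See [validate_run_config()].
#' @return The report list, invisibly; its `stages` element maps stage name
#'   to `"completed"` / `"failed: <message>"` / `"skipped"`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  report <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- paste0("failed: ", conditionMessage(res))
      NULL
    } else {
      stages[[name]] <<- "completed"
      res
    }
  }

  # --- load or simulate
  seed <- config$simulate$seed %||% config$genome_dist$seed %||% 1L
  if (!is.null(config$simulate)) {
    sim <- run_stage("load", {
      overrides <- config$simulate[
        intersect(names(config$simulate), names(formals(sim_params)))]
      s <- simulate_cohort(do.call(sim_params, overrides), seed = seed)
      write_cohort(s, file.path(out_dir, "sim"))
      s
    })
    if (is.null(sim)) abort("simulation stage failed")
    catalogues <- sim$catalogues
    reference <- sim$reference
    callable <- sim$callable
    tracks <- sim$tracks
  } else {
    base <- config$.base_dir %||% "."
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    loaded <- run_stage("load", {
      reference <- read_genome_fasta(resolve(config$inputs$reference))
      list(
        reference = reference,
        callable = read_callable_bed(resolve(config$inputs$callable)),
        tracks = read_feature_tracks(resolve(config$inputs$tracks)),
        catalogues = read_cohort(
          read_manifest(resolve(config$inputs$manifest)),
          reference = reference,
          base_dir = dirname(resolve(config$inputs$manifest))
        )
      )
    })
    if (is.null(loaded)) abort(paste0("load stage ", stages$load))
    catalogues <- loaded$catalogues
    reference <- loaded$reference
    callable <- loaded$callable
    tracks <- loaded$tracks
  }

  cfg_screen <- do.call(screen_config, config$screen %||% list())

  # --- inversion screen
  screen_res <- run_stage("screen_inversions", {
    inv <- purrr::map_dfr(catalogues, function(cat) {
      screen_balanced_inversions(cat$rearrangements, cfg_screen)$inversions
    })
    readr::write_tsv(inv, file.path(out_dir, "balanced_inversions.tsv"))
    inv
  })

  # --- indel metrics
  metrics <- run_stage("indel_metrics", {
    catalogues <<- purrr::map(catalogues, function(cat) {
      cat$indels <- compute_microhomology(cat$indels, reference)
      cat
    })
    burdens <- burden_summary(catalogues)
    readr::write_tsv(burdens, file.path(out_dir, "burden_summary.tsv"))
    spectra <- purrr::imap_dfr(
      split(catalogues, purrr::map_chr(catalogues, "group")),
      function(cats, gr) {
        ind <- purrr::map_dfr(cats, "indels")
        dplyr::mutate(deletion_size_spectrum(ind), group = gr)
      }
    )
    readr::write_tsv(spectra[, c("group", "length_bin", "count", "fraction")],
                     file.path(out_dir, "deletion_size_spectrum.tsv"))
    mh <- purrr::map_dfr(catalogues, "indels") |>
      dplyr::filter(.data$indel_class == "deletion") |>
      dplyr::select("sample_id", "chrom", "pos", "length", "mh_len")
    readr::write_tsv(mh, file.path(out_dir, "microhomology.tsv"))
    burdens
  })

  # --- genome distribution
  gd <- config$genome_dist %||% list()
  dist_res <- run_stage("genome_dist", {
    n_bg <- gd$n_background %||% 5000L
    window_bp <- gd$window_bp %||% 100L
    bg <- sample_background(callable, n_bg, seed = gd$seed %||% seed)
    bg_annot <- annotate_positions(bg, reference, tracks, window_bp)
    groups <- unique(purrr::map_chr(catalogues, "group"))
    tests <- purrr::map_dfr(groups, function(gr) {
      cats <- purrr::keep(catalogues, function(cat) cat$group == gr)
      dels <- purrr::map_dfr(cats, "indels") |>
        dplyr::filter(.data$indel_class == "deletion")
      if (nrow(dels) == 0L) return(NULL)
      annot <- annotate_positions(dels[, c("chrom", "pos")], reference,
                                  tracks, window_bp)
      dplyr::mutate(
        test_feature_associations(annot, bg_annot, tracks = tracks),
        group = gr, .before = 1L
      )
    })
    readr::write_tsv(dplyr::select(tests, -"tables"),
                     file.path(out_dir, "feature_tests.tsv"))
    tests
  })

  # --- clonality
  clon <- run_stage("clonality", {
    thr <- config$clonality$clonal_threshold %||% 0.75
    catalogues <<- purrr::map(catalogues, assign_clonality,
                              clonal_threshold = thr)
    contrasts <- purrr::map(catalogues, clonal_deletion_contrast)
    out <- purrr::imap_dfr(contrasts, function(ct, sid) {
      tibble::tibble(sample_id = sid, p_value = ct$p_value,
                     odds_ratio = ct$odds_ratio, computable = ct$computable)
    })
    readr::write_tsv(out, file.path(out_dir, "clonality_contrasts.tsv"))
    out
  })

  # --- cohort report
  rep_res <- run_stage("cohort_report", {
    rep <- cohort_report(catalogues, cfg_screen, pooled = config$pooled,
                         glm_group_ref = config$glm_group_ref)
    write_cohort_report(rep, out_dir)
    rep
  })

  provenance <- list(
    package = "radsig",
    version = as.character(utils::packageVersion("radsig")),
    seed = seed,
    config_hash = rlang::hash(
      config[setdiff(names(config), c(".base_dir", "out_dir"))])
  )
  report <- list(
    stages = stages, provenance = provenance,
    feature_tests = if (!is.null(dist_res))
      dplyr::select(dist_res, -"tables"),
    clonality = clon,
    group_medians = if (!is.null(rep_res)) rep_res$group_medians,
    inversion_summary = if (!is.null(rep_res)) rep_res$inversion_summary,
    mixed_interactions = if (!is.null(rep_res) &&
                               inherits(rep_res$mixed_model, "radsig_mixed"))
      rep_res$mixed_model$interactions,
    inversion_glm = if (!is.null(rep_res) &&
                          inherits(rep_res$inversion_glm, "radsig_glm"))
      rep_res$inversion_glm$coefficients
  )
  jsonlite::write_json(report[!purrr::map_lgl(report, is.null)],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}
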