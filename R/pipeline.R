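#' Validate a run manifest
#'
#' Checks a YAML run manifest for the full analysis pipeline. Content
#' problems are returned as human-readable messages, never raised;
#' only an unparseable file is an error.
#'
#' A manifest has the shape:
#' ```yaml
#' output_dir: out/
#' options: {alpha: 0.05, vip_threshold: 0.75, permutations: 0,
#'           n_orthogonal: 0, seed: 1}
#' experiments:
#'   - peak_table: pgp_zosuquidar.csv
#'     compound: zosuquidar
#'     transporter: pgp
#'     kind: inhibitor
#'     main: true
#' ```
#'
#' @param path manifest file, or an already-parsed manifest list.
#' @return Character vector of problems (empty when valid).
#' @export
validate_manifest <- function(path) {
  manifest <- if (is.character(path)) yaml::read_yaml(path) else path
  base_dir <- if (is.character(path)) dirname(path) else "."
  problems <- character(0)
  exps <- manifest$experiments
  if (is.null(exps) || length(exps) == 0) {
    problems <- c(problems, "manifest lists no experiments")
  }
  for (i in seq_along(exps)) {
    e <- exps[[i]]
    lab <- e$compound %||% sprintf("experiment %d", i)
    if (is.null(e$peak_table)) {
      problems <- c(problems, sprintf("%s: missing peak_table path", lab))
    } else if (!file.exists(e$peak_table) &&
               !file.exists(file.path(base_dir, e$peak_table))) {
      problems <- c(problems, sprintf("%s: peak_table file not found (%s)",
                                      lab, e$peak_table))
    }
    if (!is.null(e$design) && !file.exists(e$design) &&
        !file.exists(file.path(base_dir, e$design))) {
      problems <- c(problems, sprintf("%s: design file not found (%s)",
                                      lab, e$design))
    }
    if (!is.null(e$kind) && !e$kind %in% c("inhibitor", "knockout", "substrate", "vehicle")) {
      problems <- c(problems, sprintf("%s: unknown kind '%s'", lab, e$kind))
    }
    if (!is.null(e$transporter) && !e$transporter %in% c("pgp", "bcrp", "mrp2", "none")) {
      problems <- c(problems, sprintf("%s: unknown transporter '%s'", lab, e$transporter))
    }
  }
  opt <- manifest$options
  if (!is.null(opt$vip_threshold) && opt$vip_threshold < 0) {
    problems <- c(problems, "options: vip_threshold must be >= 0")
  }
  if (!is.null(opt$alpha) && (opt$alpha <= 0 || opt$alpha >= 1)) {
    problems <- c(problems, "options: alpha must be in (0, 1)")
  }
  if (!is.null(opt$permutations) && opt$permutations != 0 && opt$permutations < 19) {
    problems <- c(problems, "options: permutations must be 0 or >= 19")
  }
  if (is.null(manifest$output_dir)) {
    problems <- c(problems, "manifest has no output_dir")
  }
  problems
}

#' Run the full analysis pipeline from a manifest
#'
#' Executes, for every experiment in the manifest: read, instrument QC,
#' total-sum normalization, OPLS-DA fit with VIP scores, percent-change
#' table — then derives a consensus signature for any transporter with
#' at least one inhibitor and one knockout experiment, scores every
#' experiment against the packaged reference signatures, and classifies
#' the scores. All intermediates are written under `output_dir`
#' (normalized tables, model summaries as JSON, VIP and percent-change
#' CSVs, signature JSONs, score report CSV) together with a provenance
#' record; rerunning the same manifest reproduces identical outputs.
#'
#' @param manifest path to a YAML manifest, or a manifest list (see
#'   [validate_manifest()]).
#' @return Run summary list (invisibly): `experiments` (per-experiment
#'   stage records), `signatures`, `report`, `output_dir`, `provenance`.
#' @export
run_pipeline <- function(manifest) {
  path <- NULL
  if (is.character(manifest)) {
    path <- manifest
    manifest <- yaml::read_yaml(manifest)
  }
  problems <- validate_manifest(manifest %||% list())
  if (length(problems)) {
    stop("manifest validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  base_dir <- if (is.null(path)) "." else dirname(path)
  out_dir <- manifest$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  opt <- manifest$options %||% list()
  alpha <- opt$alpha %||% 0.05
  vip_threshold <- opt$vip_threshold %||% 0.75
  n_perm <- opt$permutations %||% 0
  n_orth <- opt$n_orthogonal  # NULL means select by cross-validation
  seed <- opt$seed %||% 1

  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)

  experiments <- list()
  for (i in seq_along(manifest$experiments)) {
    e <- manifest$experiments[[i]]
    lab <- e$compound %||% sprintf("experiment_%d", i)
    stage <- "read"
    rec <- tryCatch({
      tab <- read_peak_table(resolve(e$peak_table),
                             dialect = e$dialect %||% "wide_csv",
                             control_analyte = e$control_analyte)
      qc <- if (!is.null(tab$control_analyte)) qc_instrument_control(tab) else NULL
      stage <- "analyze"
      ana <- analyze_experiment(tab, n_orthogonal = n_orth, cv_folds = 7,
                                cv_seed = seed)
      perm <- if (n_perm >= 19) {
        stage <- "permutation"
        permutation_test(ana$table, ana$table$groups, n_permutations = n_perm,
                         seed = seed, n_orthogonal = n_orth %||% 0)
      }
      stage <- "write"
      slug <- gsub("[^A-Za-z0-9_.-]", "_", lab)
      write_peak_table(ana$table, file.path(out_dir, paste0(slug, "_normalized.csv")))
      utils::write.csv(data.frame(metabolite = names(ana$vip$vip),
                                  vip = unname(ana$vip$vip))[
                         order(-unname(ana$vip$vip)), ],
                       file.path(out_dir, paste0(slug, "_vip.csv")),
                       row.names = FALSE)
      utils::write.csv(ana$changes,
                       file.path(out_dir, paste0(slug, "_percent_change.csv")),
                       row.names = FALSE)
      jsonlite::write_json(
        list(compound = lab, r2x = ana$model$r2x, r2y = ana$model$r2y,
             q2 = ana$model$q2, n_orthogonal = ncol(ana$model$ortho_scores),
             qc = if (!is.null(qc)) list(control_cv = qc$control_cv, pass = qc$pass),
             permutation_p = if (!is.null(perm)) perm$p_value_q2),
        file.path(out_dir, paste0(slug, "_model.json")),
        auto_unbox = TRUE, digits = NA, null = "null")
      list(compound = lab, kind = e$kind %||% "inhibitor",
           transporter = e$transporter %||% "none",
           main = isTRUE(e$main), changes = ana$changes, vip = ana$vip,
           model = ana$model, qc = qc, ok = TRUE)
    }, error = function(err) {
      stop(sprintf("pipeline aborted at stage '%s' for %s: %s",
                   stage, lab, conditionMessage(err)), call. = FALSE)
    })
    experiments[[lab]] <- rec
  }

  signatures <- list()
  for (tr in c("pgp", "bcrp", "mrp2")) {
    sub <- Filter(function(e) identical(e$transporter, tr), experiments)
    kinds <- vapply(sub, function(e) e$kind, character(1))
    if (any(kinds == "inhibitor") && any(kinds == "knockout")) {
      sig <- derive_signature(sub, vip_threshold = vip_threshold,
                              transporter = tr)
      signatures[[tr]] <- sig
      jsonlite::write_json(
        list(transporter = tr, vip_threshold = vip_threshold,
             members = sig$members),
        file.path(out_dir, paste0("signature_", tr, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  report <- score_report(unname(experiments))
  utils::write.csv(report, file.path(out_dir, "score_report.csv"),
                   row.names = FALSE)
  provenance <- list(
    package = "effluxsig",
    version = as.character(utils::packageVersion("effluxsig")),
    seed = seed, alpha = alpha, vip_threshold = vip_threshold,
    permutations = n_perm,
    thresholds = unclass(score_thresholds()),
    n_experiments = length(experiments))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(experiments = experiments, signatures = signatures,
                 report = report, output_dir = out_dir,
                 provenance = provenance))
}
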