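#' Validate and normalize a run configuration
#'
#' Checks all tunable thresholds against their legal ranges (window widths
#' within \[2, 20\], significance levels in (0, 1), the RISSc threshold
#' schedule is fixed and not configurable) and fills documented defaults.
#' Unknown keys are rejected. Errors are aggregated into one message.
#'
#' @param config named list of settings; see Details.
#' @details Recognized keys and defaults: `widths` (2:20), `alpha` (0.05),
#'   `genomewide_alpha` (5e-8), `mark_alpha` (0.01), `min_copies` (5),
#'   `theta` (0.8), `phase_threshold` (0.9), `study_covariate` (TRUE),
#'   `bootstrap_B` (200), `seed` (1).
#' @return normalized config list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(widths = 2:20, alpha = 0.05, genomewide_alpha = 5e-8,
                   mark_alpha = 0.01, min_copies = 5, phase_threshold = 0.9,
                   theta = 0.8, study_covariate = TRUE, bootstrap_B = 200,
                   seed = 1)
  errs <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  if (any(cfg$widths < 2 | cfg$widths > 20))
    errs <- c(errs, "widths must lie within [2, 20]")
  for (k in c("alpha", "mark_alpha", "genomewide_alpha", "theta",
              "phase_threshold"))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0 || cfg[[k]] >= 1)
      errs <- c(errs, paste0(k, " must lie in (0, 1)"))
  if (cfg$min_copies < 1) errs <- c(errs, "min_copies must be >= 1")
  if (cfg$bootstrap_B < 1) errs <- c(errs, "bootstrap_B must be >= 1")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  cfg
}

#' Run the full analysis chain end to end
#'
#' Executes the stage order: per-study single-variant scans; two-study
#' concordance filter; combined scan with genome-wide flags; sliding-window
#' haplotype reconstruction over the concordant variants (assembly, peak
#' windows, marking alleles); RISSc sentinel selection among the
#' genome-wide-significant variants; bootstrap optimism-corrected AUC; and
#' modifier tests (age at diagnosis, dichotomized severity) over the
#' concordant variants. Per-stage TSVs and a run manifest are written to
#' `out_dir`.
#'
#' @param collection a [study_collection] (e.g. from
#'   [simulate_replicated_studies()]).
#' @param config run configuration, passed through [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return list with all stage objects plus `manifest` (data.frame).
#' @export
run_end_to_end <- function(collection, config = list(), out_dir = tempfile()) {
  cfg <- validate_config(config)
  stopifnot(inherits(collection, "study_collection"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labs <- names(collection$studies)
  manifest <- list()
  emit <- function(stage, obj, file) {
    path <- file.path(out_dir, file)
    write_results_table(obj, path)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, output = file, rows = nrow(obj))
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # 1. per-study scans
  scans <- stage("scan", lapply(labs, function(lab) {
    s <- collection$studies[[lab]]
    scan_variants(s$geno, s$pheno, scope = lab)
  }))
  names(scans) <- labs
  for (lab in labs) emit("scan", scans[[lab]],
                         paste0("scan_", lab, ".tsv"))

  # 2. concordance replication
  conc <- stage("replicate",
                concordance_filter(scans[[1]], scans[[2]], cfg$alpha))
  emit("replicate", conc, "concordant.tsv")

  # 3. combined scan over concordant variants
  comb <- stage("combine", combined_scan(
    collection, variants = conc$variant,
    genomewide_alpha = cfg$genomewide_alpha,
    study_covariate = cfg$study_covariate))
  emit("combine", comb, "combined.tsv")
  gw <- comb$variant[comb$genomewide %in% TRUE]

  # 4. haplotype reconstruction over concordant variants
  vidx <- sort(match(conc$variant, collection$variants$id))
  swin <- stage("hapscan", sliding_window_scan(
    collection, widths = cfg$widths, alpha = cfg$alpha,
    min_copies = cfg$min_copies, phase_threshold = cfg$phase_threshold,
    variants = vidx))
  emit("hapscan", swin, "window_haplotypes.tsv")
  models <- stage("hapscan", assemble_ancestral_haplotypes(swin, collection))
  marking <- stage("hapscan", assign_marking_alleles(
    collection, models, comb, theta = cfg$theta,
    phase_threshold = cfg$phase_threshold))
  emit("hapscan", marking, "marking_alleles.tsv")

  # 5. RISSc sentinels among genome-wide-significant variants
  pooledX <- t(do.call(cbind, lapply(collection$studies,
                                     function(s) s$geno$dosage)))
  colnames(pooledX) <- collection$variants$id
  status <- unlist(lapply(collection$studies, function(s)
    case_indicator(s$geno, s$pheno)), use.names = FALSE)
  sentinel <- NULL
  if (length(gw)) {
    sentinel <- stage("sentinels", run_rissc(
      pooledX[, gw, drop = FALSE], status, mark_alpha = cfg$mark_alpha,
      trace = TRUE))
    if (!is.null(sentinel$results))
      emit("sentinels", sentinel$results, "sentinels.tsv")
    emit("sentinels", sentinel$audit, "sentinel_audit.tsv")
  }

  # 6. optimism-corrected AUC
  optimism <- NULL
  if (length(gw)) {
    optimism <- stage("predict", bootstrap_optimism(
      pooledX[, gw, drop = FALSE], status, B = cfg$bootstrap_B,
      seed = cfg$seed, mark_alpha = cfg$mark_alpha))
    emit("predict", data.frame(apparent_auc = optimism$apparent,
                               bagged_optimism = optimism$bagged_optimism,
                               shrunken_auc = optimism$shrunken,
                               B = optimism$B,
                               n_failed = optimism$n_failed),
         "auc_optimism.tsv")
    emit("predict", optimism$replicates, "auc_replicates.tsv")
  }

  # 7. modifier tests over concordant variants
  pheno_all <- do.call(rbind, lapply(collection$studies, function(s)
    s$pheno[, intersect(names(s$pheno),
                        c("subject", "status", "study", "age", "stage",
                          "gleason_sum", "psa_dx", "prostatectomy",
                          "died_of_disease")), drop = FALSE]))
  cases <- pheno_all$status == "case"
  sev <- classify_severity_table(pheno_all)
  modifier_rows <- list()
  for (v in conc$variant) {
    dv <- pooledX[cases, v]
    at <- tryCatch(age_at_diagnosis_test(dv, pheno_all$age[cases]),
                   error = function(e) NULL)
    if (!is.null(at))
      modifier_rows[[length(modifier_rows) + 1L]] <-
        data.frame(variant = v, comparison = "age", p = at$p,
                   effect = at$effect, stringsAsFactors = FALSE)
    for (pair in list(c("aggressive", "insignificant"),
                      c("moderate", "insignificant"),
                      c("aggressive", "moderate"))) {
      sc <- tryCatch(severity_comparison(dv, sev[cases], pair),
                     error = function(e) NULL)
      if (!is.null(sc))
        modifier_rows[[length(modifier_rows) + 1L]] <-
          data.frame(variant = v, comparison = sc$comparison, p = sc$p,
                     effect = sc$effect, stringsAsFactors = FALSE)
    }
  }
  modifiers <- if (length(modifier_rows)) do.call(rbind, modifier_rows)
    else data.frame(variant = character(), comparison = character(),
                    p = numeric(), effect = numeric())
  emit("modifiers", modifiers, "modifiers.tsv")

  manifest <- do.call(rbind, manifest)
  manifest$seed <- cfg$seed
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_snapshot <- data.frame(key = names(cfg),
                             value = vapply(cfg, function(v)
                               paste(format(v), collapse = ","), ""))
  utils::write.table(cfg_snapshot, file.path(out_dir, "config.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(scans = scans, concordant = conc, combined = comb,
       genomewide = gw, windows = swin, models = models,
       marking = marking, sentinel = sentinel, optimism = optimism,
       modifiers = modifiers, manifest = manifest, config = cfg,
       out_dir = out_dir)
}
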