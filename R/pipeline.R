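#' Run the full breathing pipeline on a FASTA of promoters
#'
#' Chains the stages FASTA -> Langevin ensemble -> breathing profile
#' (JSON + TSV) -> pairwise TSS contrast (when exactly two sequences are
#' given), writing every artifact plus a run manifest into `out_dir`.
#' All inputs are validated before any simulation starts (fail-fast), and
#' the run is a deterministic function of the manifest: rerunning with
#' the same inputs and seed reproduces every text artifact byte for byte.
#'
#' @param fasta Path to a FASTA file with `tss=` header tokens (see
#'   [read_promoter_fasta()]).
#' @param out_dir Output directory (created if needed).
#' @param params An [epbd_parameters] object.
#' @param config A [langevin_config]; its `seed` is the master seed.
#' @param thresholds,L_max,margin Passed to [lifetime_profile()].
#' @param window,compare_threshold Passed to [compare_profiles()] when
#'   two sequences are present.
#' @param save_ensembles Also save each `trajectory_ensemble` as RDS.
#' @param quiet Suppress stage messages.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_breathing_pipeline <- function(fasta, out_dir,
                                   params = epbd_parameters(),
                                   config = test_scale_config(),
                                   thresholds = c(0.5, 1.0, 1.5, 2.1),
                                   L_max = 20L, margin = 5L,
                                   window = c(-10, 10),
                                   compare_threshold = 1.0,
                                   save_ensembles = FALSE,
                                   quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  # fail-fast validation of every input before any simulation
  seqs <- read_promoter_fasta(fasta)
  if (length(seqs) == 0L) stop("stage 'sequences': FASTA contains no records")
  stopifnot(inherits(params, "epbd_parameters"), inherits(config, "langevin_config"))
  check_stability(config, params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(
    tool = "dnabreathe", version = as.character(utils::packageVersion("dnabreathe")),
    pipeline = "breathing",
    input = list(fasta = normalizePath(fasta), md5 = unname(tools::md5sum(fasta))),
    master_seed = config$seed,
    config = unclass(config),
    params = list(D = as.list(params$D), a = as.list(params$a), k = params$k,
                  k_stack = if (is.null(params$k_stack)) NULL else as.list(params$k_stack),
                  rho = params$rho, beta = params$beta, mass = params$mass),
    analysis = list(thresholds = thresholds, L_max = L_max, margin = margin,
                    window = window, compare_threshold = compare_threshold),
    outputs = list(), timings_s = list()
  )

  profiles <- list()
  for (s in seqs) {
    say("stage 'simulate': '%s' (%d bp, %d replicas x %d steps, seed %d)",
        s$name, nchar(s$bases), config$n_replicas, config$n_prod_steps, config$seed)
    t0 <- proc.time()[["elapsed"]]
    ens <- tryCatch(simulate_ensemble(s, params, config),
                    error = function(e) stop("stage 'simulate' failed for '", s$name, "': ",
                                             conditionMessage(e)))
    manifest$timings_s[[paste0("simulate_", s$name)]] <- proc.time()[["elapsed"]] - t0
    if (save_ensembles) {
      ens_path <- file.path(out_dir, paste0(s$name, "_ensemble.rds"))
      saveRDS(ens, ens_path)
      manifest$outputs[[paste0(s$name, "_ensemble")]] <- basename(ens_path)
    }
    say("stage 'profile': '%s'", s$name)
    t0 <- proc.time()[["elapsed"]]
    prof <- lifetime_profile(ens, thresholds = thresholds, L_max = L_max, margin = margin)
    manifest$timings_s[[paste0("profile_", s$name)]] <- proc.time()[["elapsed"]] - t0
    cens_rate <- sum(prof$n_censored, na.rm = TRUE) /
      max(1L, sum(prof$n_censored, na.rm = TRUE) + sum(prof$event_count, na.rm = TRUE))
    if (cens_rate > 0.2) {
      warning(sprintf("'%s': %.0f%% of bubble events are censored; lifetime means are based on short runs",
                      s$name, 100 * cens_rate))
    }
    json_path <- file.path(out_dir, paste0(s$name, "_profile.json"))
    tsv_path <- file.path(out_dir, paste0(s$name, "_profile.tsv"))
    write_profile(prof, json_path)
    export_profile_tsv(prof, tsv_path)
    manifest$outputs[[paste0(s$name, "_profile_json")]] <- basename(json_path)
    manifest$outputs[[paste0(s$name, "_profile_tsv")]] <- basename(tsv_path)
    profiles[[s$name]] <- prof
  }

  if (length(profiles) == 2L) {
    say("stage 'compare': '%s' vs '%s'", names(profiles)[1L], names(profiles)[2L])
    contrast <- compare_profiles(profiles[[1L]], profiles[[2L]],
                                 window = window, threshold = compare_threshold)
    report_path <- file.path(out_dir, "contrast_report.txt")
    write_contrast_report(contrast, report_path)
    manifest$outputs$contrast_report <- basename(report_path)
    manifest$outputs$contrast_json <- "contrast_report.json"
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  say("wrote %s", manifest_path)
  invisible(manifest)
}

#' Run the expression (comparative-CT) pipeline on a Ct table
#'
#' Reads a delimited Ct table, computes delta-delta-Ct fold changes for
#' every non-reference gene, classifies them by the two-fold rule, and
#' writes the fold-change report, class fractions and a manifest.
#'
#' @param ct_path Path to a TSV with columns `gene`, `condition`,
#'   `replicate`, `ct` (or a [ct_table] object).
#' @param out_dir Output directory.
#' @param reference_gene Reference gene label.
#' @param threshold Fold threshold for regulation classes.
#' @param quiet Suppress stage messages.
#' @return The manifest, invisibly.
#' @export
run_expression_pipeline <- function(ct_path, out_dir, reference_gene = "TBP",
                                    threshold = 2.0, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  table <- if (inherits(ct_path, "ct_table")) ct_path else {
    read_ct_table(ct_path, reference_gene = reference_gene)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say("stage 'qpcr': %d genes, reference '%s'",
      length(unique(table$data$gene)), table$reference_gene)
  fc <- fold_change_table(table, threshold = threshold)
  fractions <- summarize_fractions(fc)
  fc_path <- file.path(out_dir, "fold_changes.tsv")
  utils::write.table(fc, fc_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = "dnabreathe", version = as.character(utils::packageVersion("dnabreathe")),
    pipeline = "expression",
    reference_gene = table$reference_gene, fold_threshold = threshold,
    fractions = as.list(fractions),
    outputs = list(fold_changes = basename(fc_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  say("wrote %s", file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
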