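#' Construct a qPCR Ct table
#'
#' Long-format cycle-threshold measurements for the comparative-CT
#' (delta-delta-Ct) method: one row per (gene, condition, replicate),
#' with a designated reference gene (default `"TBP"`) used for
#' normalization. The reference must be measured in every
#' (condition, replicate) pair present.
#'
#' @param data `data.frame` with columns `gene`, `condition`
#'   (`"treated"`/`"control"`), `replicate`, `ct` (cycles).
#' @param reference_gene Reference (housekeeping) gene label.
#' @return A `ct_table` object.
#' @export
ct_table <- function(data, reference_gene = "TBP") {
  req <- c("gene", "condition", "replicate", "ct")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("data must be a data.frame with columns ", paste(req, collapse = ", "))
  }
  if (nrow(data) == 0L) stop("Ct table is empty")
  data$gene <- as.character(data$gene)
  data$condition <- as.character(data$condition)
  bad_cond <- setdiff(unique(data$condition), c("treated", "control"))
  if (length(bad_cond) > 0L) {
    stop("condition must be 'treated' or 'control'; found: ", paste(bad_cond, collapse = ", "))
  }
  if (any(!is.finite(data$ct))) stop("all Ct values must be finite")
  if (any(data$ct < 5 | data$ct > 40)) {
    warning("Ct values outside the typical 5-40 cycle range")
  }
  if (!reference_gene %in% data$gene) {
    stop("reference gene '", reference_gene, "' absent from the table")
  }
  pairs <- unique(data[, c("condition", "replicate")])
  ref <- data[data$gene == reference_gene, ]
  for (i in seq_len(nrow(pairs))) {
    hit <- ref$condition == pairs$condition[i] & ref$replicate == pairs$replicate[i]
    if (!any(hit)) {
      stop(sprintf("reference gene '%s' missing for condition '%s', replicate '%s'",
                   reference_gene, pairs$condition[i], pairs$replicate[i]))
    }
  }
  structure(list(data = data, reference_gene = reference_gene), class = "ct_table")
}

#' Read a Ct table from delimited text
#'
#' @param path TSV/CSV path with columns `gene`, `condition`,
#'   `replicate`, `ct`.
#' @param reference_gene Reference gene label.
#' @param sep Field separator (default tab).
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path, reference_gene = "TBP", sep = "\t") {
  ct_table(utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE),
           reference_gene = reference_gene)
}

#' Comparative-CT (delta-delta-Ct) fold change for one gene
#'
#' `dCt_cond = mean Ct(gene, cond) - mean Ct(reference, cond)` per
#' condition (arithmetic means on the cycle scale), `ddCt = dCt_treated -
#' dCt_control`, `fold = 2^(-ddCt)`. Assumes ideal doubling per cycle
#' (amplification efficiency 2), as the comparative-CT method does.
#'
#' @param table A [ct_table].
#' @param gene Gene label present in both conditions.
#' @param threshold Fold threshold forwarded to [classify_regulation()].
#' @return A `fold_change_record`: list with `gene`, `ddct`, `fold`,
#'   `regulation_class`.
#' @export
ddct_fold_change <- function(table, gene, threshold = 2.0) {
  stopifnot(inherits(table, "ct_table"))
  d <- table$data
  mean_ct <- function(g, cond) {
    x <- d$ct[d$gene == g & d$condition == cond]
    if (length(x) == 0L) {
      stop(sprintf("no Ct measurements for gene '%s' in condition '%s'", g, cond))
    }
    mean(x)
  }
  dct_treated <- mean_ct(gene, "treated") - mean_ct(table$reference_gene, "treated")
  dct_control <- mean_ct(gene, "control") - mean_ct(table$reference_gene, "control")
  ddct <- dct_treated - dct_control
  fold <- 2^(-ddct)
  structure(list(gene = gene, ddct = ddct, fold = fold,
                 regulation_class = classify_regulation(fold, threshold)),
            class = "fold_change_record")
}

#' @export
print.fold_change_record <- function(x, ...) {
  cat(sprintf("%s: ddCt = %.4g cycles, fold = %.4g (%s)\n",
              x$gene, x$ddct, x$fold, x$regulation_class))
  invisible(x)
}

#' Two-fold regulation class of a fold change
#'
#' "Up" means strictly more than `threshold`-fold increase, "down"
#' strictly more than `threshold`-fold decrease (fold < 1/threshold);
#' anything else — including exactly two-fold at the default — is
#' "unchanged" (a strict reading of "more than two times").
#'
#' @param fold Fold change (> 0), or a `fold_change_record`.
#' @param threshold Fold threshold (> 1), default 2.
#' @return `"up"`, `"down"` or `"unchanged"`.
#' @export
classify_regulation <- function(fold, threshold = 2.0) {
  if (inherits(fold, "fold_change_record")) fold <- fold$fold
  if (!is.finite(threshold) || threshold <= 1) stop("threshold must be > 1")
  if (!is.finite(fold) || fold <= 0) stop("fold must be > 0")
  if (fold > threshold) "up" else if (fold < 1 / threshold) "down" else "unchanged"
}

#' Fold changes for every non-reference gene in a table
#'
#' @param table A [ct_table].
#' @param threshold Fold threshold for classification.
#' @return `data.frame` with columns `gene`, `ddct`, `fold`,
#'   `regulation_class`.
#' @export
fold_change_table <- function(table, threshold = 2.0) {
  stopifnot(inherits(table, "ct_table"))
  genes <- setdiff(unique(table$data$gene), table$reference_gene)
  recs <- lapply(genes, function(g) {
    r <- ddct_fold_change(table, g, threshold)
    data.frame(gene = r$gene, ddct = r$ddct, fold = r$fold,
               regulation_class = r$regulation_class)
  })
  do.call(rbind, recs)
}

#' Fractions of up/down/unchanged genes
#'
#' @param records A `data.frame` from [fold_change_table()] (or any with
#'   a `regulation_class` column), or a list of `fold_change_record`s.
#' @return Named numeric `c(up =, down =, unchanged =)` summing to 1.
#' @export
summarize_fractions <- function(records) {
  cls <- if (is.data.frame(records)) {
    records$regulation_class
  } else {
    vapply(records, `[[`, character(1L), "regulation_class")
  }
  if (length(cls) == 0L) stop("no fold-change records to summarize")
  counts <- table(factor(cls, levels = c("up", "down", "unchanged")))
  fr <- as.numeric(counts) / length(cls)
  names(fr) <- c("up", "down", "unchanged")
  fr
}

#' Terahertz pulse source metadata
#'
#' Declared characteristics of a pulsed THz source, validated to be
#' strictly positive. SI units throughout.
#'
#' @param pulse_energy Energy per pulse, J.
#' @param pulse_width Pulse duration, s.
#' @param repetition_rate Pulses per second, Hz.
#' @param avg_power_density Time-averaged power density at the sample,
#'   W/cm^2.
#' @param center_frequency Center frequency, Hz.
#' @return An `irradiation_metadata` object.
#' @export
irradiation_metadata <- function(pulse_energy = 1e-6,
                                 pulse_width = 35e-15,
                                 repetition_rate = 1e3,
                                 avg_power_density = 1e-3,
                                 center_frequency = 10e12) {
  vals <- c(pulse_energy = pulse_energy, pulse_width = pulse_width,
            repetition_rate = repetition_rate,
            avg_power_density = avg_power_density,
            center_frequency = center_frequency)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all irradiation metadata fields must be strictly positive; got ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  }
  structure(as.list(vals), class = "irradiation_metadata")
}

#' Peak power of a THz pulse
#'
#' `pulse_energy / pulse_width`, plus the duty-cycle-consistent average
#' power `pulse_energy x repetition_rate` for cross-checking a stated
#' average power density (the spot size is not part of the metadata, so
#' the check is a consistency note, not a hard constraint).
#'
#' @param meta An [irradiation_metadata].
#' @return List with `peak_power_w`, `average_power_w`, and
#'   `implied_spot_cm2` (average power / declared density).
#' @export
pulse_peak_power <- function(meta = irradiation_metadata()) {
  stopifnot(inherits(meta, "irradiation_metadata"))
  if (meta$pulse_width <= 0) stop("pulse width must be positive")
  avg <- meta$pulse_energy * meta$repetition_rate
  list(peak_power_w = meta$pulse_energy / meta$pulse_width,
       average_power_w = avg,
       implied_spot_cm2 = avg / meta$avg_power_density)
}
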