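#' Construct a promoter sequence with a TSS anchor
#'
#' A `promoter_sequence` couples a strict A/C/G/T base string with the
#' 1-based index of the base annotated as the transcription start site
#' (TSS). The TSS defines the "+1" origin of the promoter coordinate
#' system used by every downstream breathing profile; promoter numbering
#' skips 0, so the base immediately upstream of +1 is -1.
#'
#' The sequence is given 5'->3' for one strand only: the model's state
#' variable is the stretch of a base *pair*, so no reverse-complement
#' handling is needed.
#'
#' @param bases Character scalar over the alphabet A/C/G/T (lowercase is
#'   accepted and uppercased). Length must be at least 2 because the
#'   stacking term needs one dinucleotide step.
#' @param tss_index 1-based index of the TSS base within `bases`.
#' @param name Text label for the record.
#' @return An object of class `promoter_sequence` with fields `name`,
#'   `bases`, `tss_index`.
#' @examples
#' p <- promoter_sequence("ATGCA", tss_index = 3, name = "p")
#' tss_coordinate(p, 3)  # +1
#' @export
promoter_sequence <- function(bases, tss_index, name = "promoter") {
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  n <- nchar(bases)
  if (n < 2L) {
    stop("promoter sequence must have at least 2 bases (one dinucleotide step), got ", n)
  }
  bad <- gregexpr("[^ACGT]", bases)[[1L]]
  if (bad[1L] != -1L) {
    ch <- substr(bases, bad[1L], bad[1L])
    stop(sprintf("invalid base '%s' at position %d: only A/C/G/T are allowed (ambiguity codes such as N are rejected, not imputed)",
                 ch, bad[1L]))
  }
  tss_index <- as.integer(tss_index)
  if (length(tss_index) != 1L || is.na(tss_index) || tss_index < 1L || tss_index > n) {
    stop(sprintf("tss_index must lie in [1, %d], got %s", n, deparse(tss_index)))
  }
  structure(
    list(name = as.character(name), bases = bases, tss_index = tss_index),
    class = "promoter_sequence"
  )
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat(sprintf("promoter_sequence '%s': %d bp, TSS at base %d (position +1)\n",
              x$name, nchar(x$bases), x$tss_index))
  cat(" ", x$bases, "\n")
  invisible(x)
}

#' @export
length.promoter_sequence <- function(x) nchar(x$bases)

#' Base-pair classes (AT vs GC) of a promoter sequence
#'
#' The EPBD on-site potential distinguishes only the hydrogen-bond class of
#' a pair: A:T (two bonds) versus G:C (three bonds).
#'
#' @param seq A [promoter_sequence].
#' @return Character vector of `"AT"`/`"GC"`, one per base pair.
#' @export
base_classes <- function(seq) {
  stopifnot(inherits(seq, "promoter_sequence"))
  b <- strsplit(seq$bases, "", fixed = TRUE)[[1L]]
  ifelse(b %in% c("A", "T"), "AT", "GC")
}

#' Dinucleotide steps of a promoter sequence
#'
#' @param seq A [promoter_sequence].
#' @return Character vector of length N-1 with steps such as `"AT"`,
#'   `"CG"`, read 5'->3'.
#' @export
dinucleotide_steps <- function(seq) {
  stopifnot(inherits(seq, "promoter_sequence"))
  b <- strsplit(seq$bases, "", fixed = TRUE)[[1L]]
  n <- length(b)
  paste0(b[-n], b[-1L])
}

#' TSS-relative promoter coordinate of an internal index
#'
#' Maps the 1-based internal index of a base to the biological promoter
#' coordinate in which the TSS is "+1" and there is no position 0: the
#' base at `tss_index` maps to +1, the base immediately upstream to -1.
#'
#' @param seq A [promoter_sequence].
#' @param internal_index 1-based index (vectorized) into the sequence.
#' @return Integer vector of signed positions (never 0).
#' @export
tss_coordinate <- function(seq, internal_index) {
  stopifnot(inherits(seq, "promoter_sequence"))
  i <- as.integer(internal_index)
  n <- nchar(seq$bases)
  if (any(is.na(i)) || any(i < 1L) || any(i > n)) {
    stop(sprintf("internal_index out of range [1, %d]", n))
  }
  ifelse(i >= seq$tss_index, i - seq$tss_index + 1L, i - seq$tss_index)
}

#' Internal index of a TSS-relative promoter coordinate
#'
#' Inverse of [tss_coordinate()]. Position 0 does not exist and is
#' rejected.
#'
#' @param seq A [promoter_sequence].
#' @param position Signed TSS-relative coordinate(s); 0 is invalid.
#' @return 1-based internal indices.
#' @export
internal_index <- function(seq, position) {
  stopifnot(inherits(seq, "promoter_sequence"))
  p <- as.integer(position)
  if (any(is.na(p)) || any(p == 0L)) stop("promoter coordinates skip 0; position 0 is invalid")
  i <- ifelse(p > 0L, p + seq$tss_index - 1L, p + seq$tss_index)
  n <- nchar(seq$bases)
  if (any(i < 1L) || any(i > n)) stop("position maps outside the sequence")
  i
}

#' GC fraction of a promoter sequence or window
#'
#' Composition diagnostic used when interpreting breathing profiles: the
#' softer A:T Morse wells open far more readily than G:C, so local GC
#' content largely shapes the profile.
#'
#' @param seq A [promoter_sequence].
#' @param window Optional integer vector `c(from, to)` of 1-based internal
#'   indices (inclusive). Default: the whole sequence.
#' @return Fraction of G or C bases in the window, in `[0, 1]`.
#' @export
gc_fraction <- function(seq, window = NULL) {
  stopifnot(inherits(seq, "promoter_sequence"))
  n <- nchar(seq$bases)
  if (is.null(window)) window <- c(1L, n)
  window <- as.integer(window)
  if (length(window) != 2L || any(is.na(window)) ||
      window[1L] < 1L || window[2L] > n || window[1L] > window[2L]) {
    stop("window must be c(from, to) with 1 <= from <= to <= ", n)
  }
  b <- strsplit(substr(seq$bases, window[1L], window[2L]), "", fixed = TRUE)[[1L]]
  mean(b %in% c("G", "C"))
}

#' Read promoter sequences from a FASTA file
#'
#' Parses FASTA through Biostrings and attaches the TSS from a
#' `tss=<1-based offset>` token in each record header, e.g.
#' `>PPARG tss=181`. Records without the token fall back to the sequence
#' midpoint, with a warning, unless a sidecar override is supplied.
#'
#' @param path FASTA file path.
#' @param tss_override Optional named integer vector/list mapping record
#'   names to 1-based TSS offsets; takes precedence over header tokens
#'   (the "sidecar config" channel).
#' @return List of [promoter_sequence] objects (empty list for an empty
#'   file).
#' @examples
#' fa <- system.file("extdata", "synthetic_promoters.fa", package = "dnabreathe")
#' seqs <- read_promoter_fasta(fa)
#' vapply(seqs, `[[`, character(1), "name")
#' @export
read_promoter_fasta <- function(path, tss_override = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0L) return(list())
  headers <- names(set)
  out <- vector("list", length(set))
  for (k in seq_along(set)) {
    header <- headers[[k]]
    name <- sub("\\s.*$", "", header)
    bases <- as.character(set[[k]])
    tss <- NULL
    if (!is.null(tss_override) && !is.null(tss_override[[name]])) {
      tss <- as.integer(tss_override[[name]])
    } else {
      m <- regmatches(header, regexec("\\btss=(\\d+)\\b", header))[[1L]]
      if (length(m) == 2L) tss <- as.integer(m[[2L]])
    }
    if (is.null(tss)) {
      tss <- as.integer(ceiling(nchar(bases) / 2))
      warning(sprintf("record '%s' has no tss= header token or override; defaulting TSS to midpoint (base %d)",
                      name, tss))
    }
    out[[k]] <- promoter_sequence(bases, tss_index = tss, name = name)
  }
  out
}

#' Write promoter sequences to FASTA
#'
#' Headers carry the TSS as a `tss=` token so that
#' [read_promoter_fasta()] round-trips `bases` and `tss_index` exactly.
#'
#' @param seqs A [promoter_sequence] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(seqs, path) {
  if (inherits(seqs, "promoter_sequence")) seqs <- list(seqs)
  stopifnot(all(vapply(seqs, inherits, logical(1L), "promoter_sequence")))
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1L), "bases"))
  names(set) <- vapply(seqs, function(s) sprintf("%s tss=%d", s$name, s$tss_index), character(1L))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
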