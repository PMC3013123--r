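#' Design for a synthetic promoter sequence
#'
#' Describes a random promoter stand-in: an i.i.d. background with a set
#' GC fraction, plus optional composition blocks (AT-only, GC-only, or a
#' given GC fraction) overriding the background in fixed windows. The
#' canonical use is an AT-rich block embedded at the TSS of a GC-richer
#' background, mimicking the composition contrast that concentrates
#' breathing at real promoters' start sites.
#'
#' @param length Sequence length, bp (>= 2).
#' @param background_gc Background GC fraction in `[0, 1]`.
#' @param blocks List of blocks, each `list(start =, length =,
#'   composition =)` with `composition` either `"AT"`, `"GC"`, or a
#'   numeric GC fraction; `start` is 1-based. Blocks must lie within the
#'   sequence and not overlap.
#' @param tss_index 1-based TSS position.
#' @param seed Integer seed making the draw deterministic.
#' @param name Record label.
#' @return A `sequence_design` object.
#' @export
sequence_design <- function(length = 60L, background_gc = 0.8, blocks = list(),
                            tss_index = NULL, seed = 1L, name = "synthetic") {
  length <- as.integer(length)
  if (length < 2L) stop("sequence length must be >= 2")
  if (!is.finite(background_gc) || background_gc < 0 || background_gc > 1) {
    stop("background_gc must lie in [0, 1]")
  }
  if (is.null(tss_index)) tss_index <- as.integer(ceiling(length / 2))
  tss_index <- as.integer(tss_index)
  if (tss_index < 1L || tss_index > length) stop("tss_index out of range")
  covered <- integer(0)
  for (b in blocks) {
    stopifnot(all(c("start", "length", "composition") %in% names(b)))
    span <- seq.int(b$start, b$start + b$length - 1L)
    if (b$start < 1L || max(span) > length) stop("block extends outside the sequence")
    if (any(span %in% covered)) stop("blocks overlap")
    if (is.numeric(b$composition)) {
      if (b$composition < 0 || b$composition > 1) stop("block gc fraction must lie in [0, 1]")
    } else if (!b$composition %in% c("AT", "GC")) {
      stop("block composition must be 'AT', 'GC', or a GC fraction")
    }
    covered <- c(covered, span)
  }
  structure(list(length = length, background_gc = background_gc,
                 blocks = blocks, tss_index = tss_index,
                 seed = as.integer(seed), name = name),
            class = "sequence_design")
}

#' Generate a promoter sequence from a design
#'
#' Deterministic for a given design (the design's seed is applied
#' locally, without disturbing the caller's RNG stream).
#'
#' @param design A [sequence_design].
#' @return A [promoter_sequence].
#' @export
make_sequence <- function(design) {
  stopifnot(inherits(design, "sequence_design"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(design$seed)
  draw <- function(n, gc) {
    is_gc <- stats::runif(n) < gc
    b <- character(n)
    b[is_gc] <- sample(c("G", "C"), sum(is_gc), replace = TRUE)
    b[!is_gc] <- sample(c("A", "T"), sum(!is_gc), replace = TRUE)
    b
  }
  bases <- draw(design$length, design$background_gc)
  for (blk in design$blocks) {
    span <- seq.int(blk$start, blk$start + blk$length - 1L)
    gc <- if (identical(blk$composition, "AT")) 0 else if (identical(blk$composition, "GC")) 1 else blk$composition
    bases[span] <- draw(length(span), gc)
  }
  promoter_sequence(paste(bases, collapse = ""),
                    tss_index = design$tss_index, name = design$name)
}

#' Canonical TSS-focused and flat synthetic designs
#'
#' The shipped stand-in pair for a TSS-focused promoter versus a
#' dynamically flat one: both are 60 bp with a GC fraction of 0.8 in the
#' background and the TSS at the midpoint; the focused design carries a
#' 10-bp AT-only block centered on the TSS, the flat design has no
#' blocks. A chain whose TSS sits in the soft AT block breathes strongly
#' and locally there; the flat chain's activity is weak and evenly
#' spread.
#'
#' @param seed Seed for the background draw.
#' @return A [sequence_design].
#' @export
focused_design <- function(seed = 1L) {
  sequence_design(length = 60L, background_gc = 0.8,
                  blocks = list(list(start = 26L, length = 10L, composition = "AT")),
                  tss_index = 30L, seed = seed, name = "focused")
}

#' @rdname focused_design
#' @export
flat_design <- function(seed = 1L) {
  sequence_design(length = 60L, background_gc = 0.8, blocks = list(),
                  tss_index = 30L, seed = seed, name = "flat")
}

#' Build a trajectory with planted bubble events
#'
#' Ground-truth fixture generator for the bubble detector: a baseline of
#' small Gaussian noise, clipped below the detection thresholds so it can
#' never create or destroy an event, with rectangular plateaus of a given
#' amplitude planted on chosen cells during half-open frame intervals
#' `[birth, death)`. With `noise_sd = 0` the planted events are the exact
#' and only events any threshold below the amplitude will detect.
#'
#' @param n_sites Chain length, bp.
#' @param n_frames Stored frames.
#' @param events `data.frame` with columns `start`, `length`, `birth`,
#'   `death` (1-based frames, half-open), `amplitude` (Angstrom).
#' @param noise_sd Baseline noise standard deviation, Angstrom.
#' @param noise_clip Baseline values are clipped to `[-noise_clip,
#'   noise_clip]`; keep this below the smallest detection threshold.
#' @param seed Integer seed.
#' @return frames x n_sites numeric matrix.
#' @export
make_planted_trajectory <- function(n_sites, n_frames, events = NULL,
                                    noise_sd = 0, noise_clip = 0.4,
                                    seed = 1L) {
  n_sites <- as.integer(n_sites); n_frames <- as.integer(n_frames)
  stopifnot(n_sites >= 1L, n_frames >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  traj <- if (noise_sd > 0) {
    m <- matrix(stats::rnorm(n_frames * n_sites, sd = noise_sd), n_frames, n_sites)
    pmin(pmax(m, -noise_clip), noise_clip)
  } else {
    matrix(0, n_frames, n_sites)
  }
  if (!is.null(events) && nrow(events) > 0L) {
    req <- c("start", "length", "birth", "death", "amplitude")
    stopifnot(all(req %in% names(events)))
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      if (e$start < 1L || e$start + e$length - 1L > n_sites) stop("event sites out of bounds")
      if (e$birth < 1L || e$death > n_frames + 1L || e$death <= e$birth) {
        stop("event frames must satisfy 1 <= birth < death <= n_frames + 1")
      }
      if (e$amplitude <= noise_clip) stop("event amplitude must exceed the noise clip")
      traj[e$birth:(e$death - 1L), e$start:(e$start + e$length - 1L)] <- e$amplitude
    }
  }
  traj
}

#' Build a synthetic Ct table with known fold changes
#'
#' Inverts the comparative-CT formula: control Ct sits at `ct_base`,
#' treated Ct at `ct_base - log2(true_fold)`, both plus optional Gaussian
#' cycle noise; the reference gene is constructed with fold 1. With zero
#' noise, [ddct_fold_change()] recovers every `true_fold` exactly.
#'
#' @param genes Named numeric vector of true fold changes (> 0), e.g.
#'   `c(PPARG = 3.5, PPARA = 1.0)`.
#' @param reference_gene Reference gene label (fold fixed at 1).
#' @param n_replicates Replicates per (gene, condition).
#' @param ct_base Baseline Ct, cycles.
#' @param noise_sd Gaussian Ct noise standard deviation, cycles.
#' @param seed Integer seed.
#' @return A [ct_table].
#' @export
make_ct_table <- function(genes, reference_gene = "TBP", n_replicates = 3L,
                          ct_base = 22, noise_sd = 0, seed = 1L) {
  stopifnot(is.numeric(genes), !is.null(names(genes)), all(nzchar(names(genes))))
  if (any(!is.finite(genes)) || any(genes <= 0)) stop("true folds must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  all_genes <- c(stats::setNames(1.0, reference_gene), genes)
  rows <- list()
  for (g in names(all_genes)) {
    for (cond in c("control", "treated")) {
      mu <- ct_base - if (cond == "treated") log2(all_genes[[g]]) else 0
      ctv <- mu + if (noise_sd > 0) stats::rnorm(n_replicates, sd = noise_sd) else rep(0, n_replicates)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, condition = cond, replicate = seq_len(n_replicates), ct = ctv)
    }
  }
  ct_table(do.call(rbind, rows), reference_gene = reference_gene)
}
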