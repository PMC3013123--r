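#' Is a bubble open in one frame?
#'
#' The amplitude-threshold opening criterion: a bubble of a given length
#' is open at a start position iff every base pair in
#' `[position, position + length - 1]` has stretch `y >= threshold`.
#'
#' @param frame Numeric vector of pair stretches for one stored frame.
#' @param position 1-based start (5'-most base pair of the bubble).
#' @param length Bubble length, bp.
#' @param threshold Opening threshold, Angstrom.
#' @return Logical scalar.
#' @export
opening_indicator <- function(frame, position, length, threshold) {
  position <- as.integer(position); length <- as.integer(length)
  if (length < 1L || position < 1L || position + length - 1L > base::length(frame)) {
    stop("bubble window out of bounds")
  }
  all(frame[position:(position + length - 1L)] >= threshold)
}

# frames x (N - L + 1) logical matrix: bubble of length L open at each start
run_indicator_matrix <- function(open_matrix, len) {
  n <- ncol(open_matrix)
  ind <- open_matrix[, 1:(n - len + 1L), drop = FALSE]
  if (len > 1L) {
    for (j in 2:len) {
      ind <- ind & open_matrix[, j:(n - len + j), drop = FALSE]
    }
  }
  ind
}

# Maximal runs of TRUE in a logical vector -> matrix with columns
# birth (1-based first frame) and death (exclusive).
true_runs <- function(ind) {
  d <- diff(c(FALSE, ind, FALSE))
  cbind(birth = which(d == 1L), death = which(d == -1L))
}

#' Detect bubble events in one replica trajectory
#'
#' Scans the opening indicator for every admissible start position and
#' emits each maximal run of consecutive open frames as one event
#' (half-open frame interval `[birth, death)`). Events touching the first
#' or last stored frame are flagged censored: their true lifetime is only
#' bounded below.
#'
#' @param trajectory frames x N numeric matrix of pair stretches.
#' @param threshold Opening threshold, Angstrom.
#' @param length Bubble length, bp.
#' @param sample_dt Time between stored frames, ps.
#' @param replica_id Identifier copied into the result.
#' @return `data.frame` with columns `start` (1-based 5'-most base pair),
#'   `length`, `threshold`, `birth_frame`, `death_frame` (half-open,
#'   1-based), `lifetime` (ps), `replica`, `censored`.
#' @export
detect_bubbles <- function(trajectory, threshold, length, sample_dt = 1,
                           replica_id = 1L) {
  stopifnot(is.matrix(trajectory), length >= 1L)
  n <- ncol(trajectory)
  if (length > n) stop("bubble length exceeds chain length")
  n_frames <- nrow(trajectory)
  ind <- run_indicator_matrix(trajectory >= threshold, as.integer(length))
  out <- vector("list", ncol(ind))
  for (p in seq_len(ncol(ind))) {
    runs <- true_runs(ind[, p])
    if (nrow(runs) == 0L) next
    out[[p]] <- data.frame(
      start = p, length = as.integer(length), threshold = threshold,
      birth_frame = runs[, "birth"], death_frame = runs[, "death"],
      lifetime = (runs[, "death"] - runs[, "birth"]) * sample_dt,
      replica = replica_id,
      censored = runs[, "birth"] == 1L | runs[, "death"] == n_frames + 1L
    )
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (base::length(out) == 0L) {
    return(data.frame(start = integer(0), length = integer(0),
                      threshold = numeric(0), birth_frame = integer(0),
                      death_frame = integer(0), lifetime = numeric(0),
                      replica = integer(0), censored = logical(0)))
  }
  do.call(rbind, out)
}

#' Aggregate an ensemble into a breathing profile
#'
#' Pools bubble events across replicas into the average-lifetime and
#' occupancy maps over (threshold x bubble length x TSS-relative
#' position). Positions index the bubble's 5'-most base pair; a margin at
#' each chain end is excluded from the reported positions so the
#' open-boundary choice cannot colour the profile. Censored events
#' (touching a trajectory boundary) are dropped from lifetime means by
#' default — they only lower-bound the lifetime — and never affect
#' occupancy.
#'
#' @param ensemble A `trajectory_ensemble` from [simulate_ensemble()].
#' @param thresholds Strictly increasing opening thresholds, Angstrom.
#' @param L_max Largest bubble length, bp.
#' @param censoring `"drop"` (default) or `"keep"` (treat censored
#'   lifetimes as observed).
#' @param margin Base pairs excluded at each chain end (default 5).
#' @return A `breathing_profile`: arrays `occupancy`, `mean_lifetime`
#'   (ps; `NA` where no event was observed), `event_count` and
#'   `n_censored` indexed `[threshold, length, position]`, plus axes and
#'   provenance. Cells whose bubble would run past the 3' chain end are
#'   `NA` throughout.
#' @export
lifetime_profile <- function(ensemble, thresholds = c(0.5, 1.0, 1.5, 2.1),
                             L_max = 20L, censoring = c("drop", "keep"),
                             margin = 5L) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  censoring <- match.arg(censoring)
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L || is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be non-empty and strictly increasing")
  }
  L_max <- as.integer(L_max)
  if (L_max < 1L) stop("L_max must be >= 1")
  if (length(ensemble$replicas) == 0L) stop("empty ensemble")
  n <- ncol(ensemble$replicas[[1L]])
  margin <- as.integer(margin)
  starts <- seq.int(margin + 1L, n - margin)
  if (length(starts) == 0L) stop("margins leave no interior positions")
  n_frames <- nrow(ensemble$replicas[[1L]])
  n_rep <- length(ensemble$replicas)

  dims <- c(length(thresholds), L_max, length(starts))
  open_frames <- array(0, dims)       # frames with the criterion satisfied
  life_sum <- array(0, dims)          # summed lifetimes entering the mean
  n_event <- array(0L, dims)          # events entering the mean
  n_cens <- array(0L, dims)           # censored events seen

  for (r in seq_len(n_rep)) {
    traj <- ensemble$replicas[[r]]
    for (ti in seq_along(thresholds)) {
      open_matrix <- traj >= thresholds[ti]
      for (len in seq_len(min(L_max, n))) {
        ind <- run_indicator_matrix(open_matrix, len)
        valid <- starts[starts <= n - len + 1L]
        if (length(valid) == 0L) break
        pos_idx <- seq_along(valid)
        open_frames[ti, len, pos_idx] <- open_frames[ti, len, pos_idx] +
          colSums(ind[, valid, drop = FALSE])
        for (pi in pos_idx) {
          runs <- true_runs(ind[, valid[pi]])
          if (nrow(runs) == 0L) next
          cens <- runs[, "birth"] == 1L | runs[, "death"] == n_frames + 1L
          n_cens[ti, len, pi] <- n_cens[ti, len, pi] + sum(cens)
          keep <- if (censoring == "drop") !cens else rep(TRUE, nrow(runs))
          if (any(keep)) {
            life_sum[ti, len, pi] <- life_sum[ti, len, pi] +
              sum(runs[keep, "death"] - runs[keep, "birth"]) * ensemble$sample_dt
            n_event[ti, len, pi] <- n_event[ti, len, pi] + sum(keep)
          }
        }
      }
    }
  }

  occupancy <- open_frames / (n_frames * n_rep)
  mean_lifetime <- ifelse(n_event > 0L, life_sum / pmax(n_event, 1L), NA_real_)
  # cells whose bubble would overrun the 3' end are undefined
  for (len in seq_len(L_max)) {
    bad <- which(starts > n - len + 1L)
    if (length(bad) > 0L) {
      occupancy[, len, bad] <- NA_real_
      mean_lifetime[, len, bad] <- NA_real_
      n_event[, len, bad] <- NA_integer_
      n_cens[, len, bad] <- NA_integer_
    }
  }

  axes <- list(threshold = thresholds, length = seq_len(L_max),
               position = tss_coordinate(ensemble$seq, starts))
  dimnames(occupancy) <- dimnames(mean_lifetime) <-
    dimnames(n_event) <- dimnames(n_cens) <- lapply(axes, as.character)

  structure(
    list(thresholds = thresholds, lengths = seq_len(L_max),
         positions = axes$position, starts = starts,
         occupancy = occupancy, mean_lifetime = mean_lifetime,
         event_count = n_event, n_censored = n_cens,
         sample_dt = ensemble$sample_dt,
         n_frames_pooled = n_frames * n_rep,
         margin = margin, censoring = censoring,
         provenance = list(
           sequence_name = ensemble$seq$name, bases = ensemble$seq$bases,
           tss_index = ensemble$seq$tss_index,
           config = unclass(ensemble$config),
           params = list(D = as.list(ensemble$params$D),
                         a = as.list(ensemble$params$a),
                         k = ensemble$params$k,
                         k_stack = if (is.null(ensemble$params$k_stack)) NULL
                                   else as.list(ensemble$params$k_stack),
                         rho = ensemble$params$rho, beta = ensemble$params$beta,
                         mass = ensemble$params$mass),
           replica_seeds = ensemble$replica_seeds)),
    class = "breathing_profile"
  )
}

#' @export
print.breathing_profile <- function(x, ...) {
  cat(sprintf("breathing_profile: '%s', positions %s..%s (TSS-relative), lengths 1..%d bp, thresholds {%s} A\n",
              x$provenance$sequence_name, min(x$positions), max(x$positions),
              max(x$lengths), paste(x$thresholds, collapse = ", ")))
  cat(sprintf("  %d pooled frames, sample_dt = %g ps, censoring = '%s'\n",
              x$n_frames_pooled, x$sample_dt, x$censoring))
  invisible(x)
}

#' Flatten a breathing profile to a table
#'
#' One row per (threshold, length, position) cell; undefined lifetimes
#' are `NA` (exported as an empty field by [export_profile_tsv()]).
#'
#' @param profile A `breathing_profile`.
#' @return `data.frame` with columns `threshold`, `length`,
#'   `tss_position`, `mean_lifetime_ps`, `occupancy`, `n_events`.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "breathing_profile"))
  grid <- expand.grid(threshold = profile$thresholds,
                      length = profile$lengths,
                      tss_position = profile$positions,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_lifetime_ps <- as.vector(profile$mean_lifetime)
  occ <- as.vector(profile$occupancy)
  occ[is.na(occ)] <- 0
  grid$occupancy <- occ
  nev <- as.vector(profile$event_count)
  nev[is.na(nev)] <- 0L
  grid$n_events <- nev
  grid
}

#' Export a breathing profile as TSV
#'
#' @param profile A `breathing_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_profile_tsv <- function(profile, path) {
  tab <- profile_table(profile)
  tab$mean_lifetime_ps <- ifelse(is.na(tab$mean_lifetime_ps), "",
                                 formatC(tab$mean_lifetime_ps, format = "g", digits = 15))
  tab$occupancy <- formatC(tab$occupancy, format = "g", digits = 15)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PROFILE_FORMAT_VERSION <- "1.0"

#' Write / read a breathing profile (lossless)
#'
#' Versioned JSON container preserving every array, axis, mask and the
#' provenance block at full double precision. A TSV flat export for
#' spreadsheets sits alongside via [export_profile_tsv()].
#'
#' @param profile A `breathing_profile`.
#' @param path Output `.json` path.
#' @return `write_profile`: `path` invisibly; `read_profile`: the
#'   reconstructed `breathing_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "breathing_profile"))
  payload <- list(
    format = "dnabreathe/breathing_profile",
    format_version = PROFILE_FORMAT_VERSION,
    thresholds = profile$thresholds, lengths = profile$lengths,
    positions = profile$positions, starts = profile$starts,
    dims = dim(profile$occupancy),
    occupancy = as.vector(profile$occupancy),
    mean_lifetime = as.vector(profile$mean_lifetime),
    event_count = as.vector(profile$event_count),
    n_censored = as.vector(profile$n_censored),
    sample_dt = profile$sample_dt, n_frames_pooled = profile$n_frames_pooled,
    margin = profile$margin, censoring = profile$censoring,
    provenance = profile$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "dnabreathe/breathing_profile") ||
      !identical(p$format_version, PROFILE_FORMAT_VERSION)) {
    stop("not a breathing_profile container of version ", PROFILE_FORMAT_VERSION,
         " (found format '", p$format, "' version '", p$format_version, "')")
  }
  dims <- as.integer(p$dims)
  axes <- list(threshold = as.character(p$thresholds),
               length = as.character(p$lengths),
               position = as.character(p$positions))
  arr <- function(x, mode = "double") {
    a <- array(as.vector(x, mode = mode), dims)
    dimnames(a) <- axes
    a
  }
  prov <- p$provenance
  prov$config <- as.list(prov$config)
  structure(
    list(thresholds = as.numeric(p$thresholds), lengths = as.integer(p$lengths),
         positions = as.integer(p$positions), starts = as.integer(p$starts),
         occupancy = arr(p$occupancy), mean_lifetime = arr(p$mean_lifetime),
         event_count = arr(p$event_count, "integer"),
         n_censored = arr(p$n_censored, "integer"),
         sample_dt = p$sample_dt, n_frames_pooled = p$n_frames_pooled,
         margin = as.integer(p$margin), censoring = p$censoring,
         provenance = prov),
    class = "breathing_profile"
  )
}
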