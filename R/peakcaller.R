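#' Median-filter a structural profile
#'
#' Replaces each bin by the median of the unmasked bins in a centred window,
#' removing narrow low-intensity noise spikes that survive the moving-average
#' smoothing. The window is the smallest odd number of bins covering
#' `median_window_bp` (11 bins at the default 100 bp window and 10 bp step).
#' Windows are truncated at chromosome ends; a window with no unmasked bins
#' yields a masked bin.
#'
#' @param profile Profile tibble (`chrom`, `feature`, `pos`, `value`).
#' @param median_window_bp Filter window in bp (default 100, matching the
#'   smoothing window).
#' @return The filtered profile (same shape).
#' @export
median_filter <- function(profile, median_window_bp = 100) {
  step <- infer_step(profile)
  w <- ceiling(median_window_bp / step)
  if (w %% 2 == 0) w <- w + 1L
  out <- profile |>
    group_by(.data$chrom, .data$feature) |>
    arrange(.data$pos, .by_group = TRUE) |>
    mutate(value = running_median(.data$value, w)) |>
    ungroup()
  keep_profile_attrs(out, profile)
}

# Sliding median with truncated end windows and NA tolerance.
running_median <- function(x, w) {
  n <- length(x)
  if (n == 0 || w <= 1) return(x)
  h <- (w - 1L) %/% 2L
  if (!anyNA(x) && n >= w) {
    out <- stats::runmed(x, w, endrule = "keep")
    for (j in c(seq_len(h), (n - h + 1L):n)) {
      out[j] <- median(x[max(1L, j - h):min(n, j + h)])
    }
    return(as.numeric(out))
  }
  vapply(seq_len(n), function(j) {
    win <- x[max(1L, j - h):min(n, j + h)]
    if (all(is.na(win))) NA_real_ else median(win, na.rm = TRUE)
  }, numeric(1))
}

#' Adaptive peak-intensity threshold of a profile
#'
#' Partitions each (chromosome, feature) profile into non-overlapping scan
#' windows, takes each window's peak intensity `Pi = max - min`, and averages
#' them into `APi`. The detection threshold is `Ps * APi`, so it adapts to
#' the dynamic range of every chromosome and feature; `Ps` in `(0, 1]` sets
#' the stringency (the method performs best for `Ps` in 0.3-0.6; the default
#' is the midpoint 0.45).
#'
#' @param profile Median-filtered, oriented profile tibble.
#' @param ps Peak significance in `(0, 1]`.
#' @param scan_window_bp Scan window width in bp (default 165, the typical
#'   centre-to-centre spacing of adjacent yeast nucleosomes).
#' @return A tibble with one row per (`chrom`, `feature`): columns `ap_i`,
#'   `threshold`, `n_windows`.
#' @export
peak_threshold <- function(profile, ps = 0.45, scan_window_bp = 165) {
  stopifnot(ps > 0, ps <= 1)
  step <- infer_step(profile)
  w <- max(1L, as.integer(floor(scan_window_bp / step + 0.5)))
  profile |>
    group_by(.data$chrom, .data$feature) |>
    arrange(.data$pos, .by_group = TRUE) |>
    summarise(ap_i = window_mean_intensity(.data$value, w),
              n_windows = length(.data$value) %/% w,
              .groups = "drop") |>
    mutate(threshold = ps * .data$ap_i)
}

window_mean_intensity <- function(v, w) {
  nwin <- length(v) %/% w
  if (nwin < 1) {
    abort("Profile shorter than one scan window; cannot set a threshold")
  }
  pis <- vapply(seq_len(nwin), function(i) {
    win <- v[((i - 1L) * w + 1L):(i * w)]
    if (all(is.na(win))) NA_real_ else diff(range(win, na.rm = TRUE))
  }, numeric(1))
  mean(pis, na.rm = TRUE)
}

#' Call non-overlapping 147-bp nucleosomes from an oriented profile
#'
#' Scans the median-filtered profile left to right with a sliding window
#' (bin-by-bin advance). A window whose peak intensity `Pi = max - min`
#' reaches the adaptive threshold contains a peak: the leftmost bin with the
#' maximal filtered value becomes the centre `Pc`, and the implied call is
#' the 147 bp interval `[Pc - 73, Pc + 74)`. Steric exclusion is enforced -
#' candidate centres whose call would overlap the previous call or run off
#' the covered sequence are not eligible - and after an accepted call the
#' scan resumes immediately right of the called core. A flat profile yields
#' no calls even at threshold zero (`Pi` must be positive).
#'
#' @param profile Oriented, median-filtered profile tibble (see
#'   [oriented_profile()], [median_filter()]).
#' @param ps Peak significance in `(0, 1]` (ignored when `thresholds` given).
#' @param scan_window_bp Scan window width in bp (default 165).
#' @param window_bp Smoothing window used to build the profile; sets the
#'   covered-sequence bounds for boundary clipping. Taken from the profile's
#'   attributes when present.
#' @param thresholds Optional precomputed [peak_threshold()] table.
#' @return A calls tibble: `chrom`, `start`, `end`, `center`, `score`
#'   (peak intensity), `source` (feature name). Coordinates are 0-based
#'   half-open; `end - start == 147`.
#' @export
call_nucleosomes <- function(profile, ps = 0.45, scan_window_bp = 165,
                             window_bp = NULL, thresholds = NULL) {
  step <- infer_step(profile)
  window_bp <- window_bp %||% attr(profile, "window_bp") %||% 100
  w <- max(1L, as.integer(floor(scan_window_bp / step + 0.5)))
  if (is.null(thresholds)) {
    thresholds <- peak_threshold(profile, ps = ps,
                                 scan_window_bp = scan_window_bp)
  }
  groups <- distinct(profile[, c("chrom", "feature")])
  out <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    ch <- groups$chrom[gi]; f <- groups$feature[gi]
    sub <- profile[profile$chrom == ch & profile$feature == f, ]
    sub <- sub[order(sub$pos), ]
    thr <- thresholds$threshold[thresholds$chrom == ch &
                                  thresholds$feature == f]
    if (length(thr) != 1 || is.na(thr)) next
    calls <- scan_profile(sub$pos, sub$value, w, thr, window_bp)
    if (nrow(calls) > 0) {
      calls$chrom <- ch
      calls$source <- f
      out[[gi]] <- calls
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  center = numeric(0), score = numeric(0),
                  source = character(0)))
  }
  res[, c("chrom", "start", "end", "center", "score", "source")]
}

# Core scanner over one (chrom, feature) profile, in bin space.
scan_profile <- function(pos, v, w, thr, window_bp) {
  n <- length(v)
  empty <- tibble(start = numeric(0), end = numeric(0),
                  center = numeric(0), score = numeric(0))
  if (n < w) return(empty)
  # rolling max/min of windows of w bins starting at each bin
  nw <- n - w + 1L
  rmax <- v[seq_len(nw)]; rmin <- v[seq_len(nw)]
  if (w > 1) {
    for (j in 2:w) {
      s <- v[seq_len(nw) + j - 1L]
      rmax <- pmax(rmax, s, na.rm = TRUE)
      rmin <- pmin(rmin, s, na.rm = TRUE)
    }
  }
  covered_lo <- max(0, pos[1] - window_bp / 2)
  covered_hi <- pos[n] + window_bp / 2
  # a callable centre must be the summit of its own scan window: bin j is a
  # peak iff it attains the maximum over the centred w-bin neighbourhood
  # (ties allowed; NA never a peak). This stops the left-to-right scan from
  # calling rising-flank bins before a summit has entered the window.
  h <- (w - 1L) %/% 2L
  vneg <- ifelse(is.na(v), -Inf, v)
  nbh_max <- vneg
  for (d in seq_len(h)) {
    nbh_max <- pmax(nbh_max,
                    c(rep(-Inf, d), vneg[seq_len(n - d)]),
                    c(vneg[(d + 1):n], rep(-Inf, d)))
  }
  is_peak <- !is.na(v) & vneg >= nbh_max
  starts <- numeric(0); centers <- numeric(0); scores <- numeric(0)
  prev_end <- covered_lo
  i <- 1L
  while (i <= nw) {
    pi_w <- rmax[i] - rmin[i]
    accepted <- FALSE
    if (!is.na(pi_w) && pi_w >= thr && pi_w > 0) {
      idx <- i:(i + w - 1L)
      # Pc must attain the window maximum AND be an eligible summit: a
      # centred local maximum whose implied call neither overlaps the
      # previous call nor runs off the covered span. If the window maximum
      # sits on an ineligible bin (e.g. a rising flank), the window yields
      # no call and the scan slides on.
      at_max <- !is.na(v[idx]) & v[idx] == rmax[i]
      ok <- at_max & is_peak[idx] &
        (pos[idx] - 73) >= prev_end &
        (pos[idx] + 74) <= covered_hi
      cand <- idx[ok]
      if (length(cand) > 0) {
        # median filtering produces exact-tie plateaus; take the middle of
        # the first tied run so the call sits on the plateau centre rather
        # than its left edge
        gap <- which(diff(cand) != 1L)
        run <- cand[seq_len(if (length(gap) == 0) length(cand) else gap[1])]
        pc <- pos[run[floor((length(run) + 1) / 2)]]
        starts <- c(starts, pc - 73)
        centers <- c(centers, pc)
        scores <- c(scores, pi_w)
        prev_end <- pc + 74
        # resume right of the called core
        nxt <- which(pos >= prev_end)
        i <- if (length(nxt) == 0) n + 1L else nxt[1]
        accepted <- TRUE
      }
    }
    if (!accepted) i <- i + 1L
  }
  tibble(start = starts, end = starts + 147, center = centers, score = scores)
}

#' Locate nucleosomes from structural profiles (single-feature peak calls)
#'
#' Convenience pipeline: orient each feature's profile by its sign class,
#' median-filter it, compute per-chromosome adaptive thresholds and call
#' non-overlapping 147 bp nucleosomes. Equivalent to
#' `oriented_profile() |> median_filter() |> call_nucleosomes()`.
#'
#' @inheritParams call_nucleosomes
#' @param profile Profile tibble from [structural_profile()] (unoriented).
#' @param scales Scale tibble supplying sign classes.
#' @param median_window_bp Median-filter window in bp.
#' @return Calls tibble with one `source` per feature present in `profile`.
#' @examples
#' g <- simulate_genome(chrom_lengths = c(chrI = 8000), seed = 1)
#' sc <- structural_scales()
#' p <- structural_profile(g$genome, sc, features = "DNA denaturation")
#' dlane(p, sc)
#' @export
dlane <- function(profile, scales, ps = 0.45, scan_window_bp = 165,
                  median_window_bp = 100) {
  profile |>
    oriented_profile(scales) |>
    median_filter(median_window_bp = median_window_bp) |>
    call_nucleosomes(ps = ps, scan_window_bp = scan_window_bp)
}
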