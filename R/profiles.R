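#' Raw per-position structural values of a DNA sequence
#'
#' Replaces each k-mer of `seq` with its value from one structural scale.
#' Position `i` of the result is the value of the k-mer starting at base `i`.
#' K-mers containing non-ACGT symbols (e.g. `N`) are masked as `NA`; masked
#' entries are later excluded from window means rather than raising an error,
#' since real FASTA routinely contains `N` runs.
#'
#' @param seq A single DNA string (case-insensitive).
#' @param scales Scale tibble from [structural_scales()].
#' @param feature Name of the feature to apply.
#' @return Numeric vector of length `nchar(seq) - k + 1`.
#' @examples
#' structural_vector("ACGTACGT", structural_scales(), "Propeller twist")
#' @export
structural_vector <- function(seq, scales, feature) {
  k <- scale_k(scales, feature)
  lut <- scale_lookup(scales, feature)
  codes <- dna_codes(seq)
  n <- length(codes) - k + 1L
  if (n < 1) abort("Sequence shorter than the k-mer order of the scale")
  idx <- codes[seq_len(n)]
  if (k >= 2) for (j in 2:k) idx <- idx * 4L + codes[seq_len(n) + (j - 1L)]
  # idx is NA wherever any constituent base is non-ACGT; lexicographic
  # order of all_kmers() matches base-4 order, so idx + 1 indexes lut.
  unname(lut[idx + 1L])
}

# Integer codes 0..3 for A,C,G,T; NA otherwise.
dna_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[chars])
}

#' Smooth a raw structural vector into fixed-step bins
#'
#' Moving average with a `window_bp` window advanced by `step_bp`, the
#' smoothing the structural-profile method uses genome-wide (defaults 100 bp
#' and 10 bp). Only full windows are emitted, left-aligned from the start of
#' the raw vector; masked (`NA`) entries are excluded from each window mean
#' and a fully masked window yields a masked bin. The representative
#' coordinate of bin `j` (0-based) is `origin_bp + j * step_bp +
#' window_bp / 2`, i.e. the window centre.
#'
#' @param raw Numeric vector of per-position values (may contain `NA`).
#' @param window_bp,step_bp Smoothing window and bin step in bp.
#' @param origin_bp 0-based coordinate of `raw[1]`.
#' @return A tibble with columns `pos` and `value`; zero rows when `raw` is
#'   shorter than `window_bp`.
#' @export
smooth_vector <- function(raw, window_bp = 100, step_bp = 10, origin_bp = 0) {
  stopifnot(step_bp >= 1, window_bp >= step_bp)
  n <- length(raw)
  if (n < window_bp) {
    return(tibble(pos = numeric(0), value = numeric(0)))
  }
  nbins <- (n - window_bp) %/% step_bp + 1L
  ok <- !is.na(raw)
  x <- ifelse(ok, raw, 0)
  cs <- c(0, cumsum(x))
  cn <- c(0, cumsum(ok))
  starts <- (seq_len(nbins) - 1L) * step_bp
  sums <- cs[starts + window_bp + 1L] - cs[starts + 1L]
  counts <- cn[starts + window_bp + 1L] - cn[starts + 1L]
  vals <- ifelse(counts > 0, sums / counts, NA_real_)
  tibble(pos = origin_bp + starts + window_bp / 2, value = vals)
}

#' Smoothed structural profiles of a genome
#'
#' Converts every chromosome into per-feature structural profiles: raw k-mer
#' substitution ([structural_vector()]) followed by moving-average smoothing
#' ([smooth_vector()]). With the defaults the result is a structural value
#' every 10 bp, each summarising a 100 bp window.
#'
#' @param genome A genome as returned by [read_genome()] or
#'   [simulate_genome()]: a tibble with columns `chrom` and `seq`, or a named
#'   character vector of sequences.
#' @param scales Scale tibble from [structural_scales()].
#' @param features Features to profile; default all features in `scales`.
#' @inheritParams smooth_vector
#' @return A profile tibble with columns `chrom`, `feature`, `pos`, `value`.
#'   The smoothing parameters are recorded in attributes `window_bp` and
#'   `step_bp`.
#' @examples
#' g <- simulate_genome(chrom_lengths = c(chrI = 3000), seed = 1)
#' p <- structural_profile(g$genome, structural_scales(),
#'                         features = "DNA denaturation")
#' head(p)
#' @export
structural_profile <- function(genome, scales, features = NULL,
                               window_bp = 100, step_bp = 10) {
  genome <- as_genome(genome)
  features <- features %||% unique(scales$feature)
  out <- vector("list", nrow(genome) * length(features))
  i <- 0L
  for (ci in seq_len(nrow(genome))) {
    for (f in features) {
      raw <- structural_vector(genome$seq[ci], scales, f)
      sm <- smooth_vector(raw, window_bp = window_bp, step_bp = step_bp)
      i <- i + 1L
      out[[i]] <- tibble(chrom = genome$chrom[ci], feature = f,
                         pos = sm$pos, value = sm$value)
    }
  }
  res <- bind_rows(out)
  attr(res, "window_bp") <- window_bp
  attr(res, "step_bp") <- step_bp
  res
}

#' Orient profiles so nucleosomes always appear as peaks
#'
#' Values of negative-class features (those negatively correlated with
#' nucleosome occupancy) are negated, so that downstream peak detection
#' handles both classes uniformly: peak detection on an oriented profile is
#' valley detection on the original.
#'
#' @param profile Profile tibble (`chrom`, `feature`, `pos`, `value`).
#' @param scales Scale tibble supplying each feature's `sign_class`.
#' @return The profile with negative-class values negated.
#' @export
oriented_profile <- function(profile, scales) {
  signs <- distinct(scales[, c("feature", "sign_class")])
  missing <- setdiff(unique(profile$feature), signs$feature)
  if (length(missing) > 0) {
    abort(paste0("No sign class for feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- left_join(profile, signs, by = "feature")
  out$value <- ifelse(out$sign_class == "negative", -out$value, out$value)
  out$sign_class <- NULL
  keep_profile_attrs(out, profile)
}

keep_profile_attrs <- function(new, old) {
  attr(new, "window_bp") <- attr(old, "window_bp")
  attr(new, "step_bp") <- attr(old, "step_bp")
  new
}

# Infer the bin step of a profile/track tibble (attribute first, then the
# smallest positive spacing observed).
infer_step <- function(track) {
  st <- attr(track, "step_bp")
  if (!is.null(st)) return(st)
  d <- diff(sort(unique(track$pos[track$chrom == track$chrom[1]])))
  d <- d[d > 0]
  if (length(d) == 0) abort("Cannot infer bin step from a single-bin track")
  min(d)
}

#' Average a track around anchor coordinates
#'
#' Computes the mean profile (or occupancy) in a window of `flank_bp` on
#' either side of a set of anchor positions - the aggregation used for
#' centromere and TSS metaprofiles. Minus-strand anchors are reversed so
#' that positive offsets always point downstream. Anchors whose flank is
#' truncated by a chromosome end (or absent from the track) are dropped.
#'
#' @param track Tibble with columns `chrom`, `pos`, `value` (a single
#'   feature's profile or an occupancy track).
#' @param anchors Tibble with columns `chrom`, `pos` and optionally `strand`
#'   (`"+"`/`"-"`) and `class` (anchors are aggregated per class when
#'   present).
#' @param flank_bp Flank width in bp; must be a multiple of the track's bin
#'   step.
#' @return A tibble with columns `offset`, `value`, `n_anchors` (plus
#'   `class` when the anchors carry one).
#' @export
aggregate_around_anchors <- function(track, anchors, flank_bp) {
  step <- infer_step(track)
  if (flank_bp %% step != 0) {
    abort("flank_bp must be a multiple of the track's bin step")
  }
  if (!"strand" %in% names(anchors)) anchors$strand <- "+"
  classes <- if ("class" %in% names(anchors)) unique(anchors$class) else NA
  fl <- flank_bp %/% step
  res <- list()
  for (cl in classes) {
    anc <- if (is.na(cl[1])) anchors else anchors[anchors$class == cl, ]
    res[[length(res) + 1]] <- aggregate_one(track, anc, fl, step, cl)
  }
  bind_rows(res)
}

# Mean per offset over anchors, NA-tolerant; internal worker.
aggregate_one <- function(track, anchors, fl, step, cl) {
  mat <- list()
  for (ch in unique(anchors$chrom)) {
    tr <- track[track$chrom == ch, ]
    if (nrow(tr) == 0) next
    tr <- tr[order(tr$pos), ]
    pos0 <- tr$pos[1]
    nb <- nrow(tr)
    for (ai in which(anchors$chrom == ch)) {
      j <- round((anchors$pos[ai] - pos0) / step) + 1
      if (j - fl < 1 || j + fl > nb) next
      v <- tr$value[(j - fl):(j + fl)]
      if (anchors$strand[ai] == "-") v <- rev(v)
      mat[[length(mat) + 1]] <- v
    }
  }
  if (length(mat) == 0) abort("No usable anchors (all flanks truncated)")
  m <- do.call(rbind, mat)
  out <- tibble(
    offset = seq(-fl * step, fl * step, by = step),
    value = colMeans(m, na.rm = TRUE),
    n_anchors = nrow(m)
  )
  if (!is.na(cl[1])) out$class <- cl
  out
}

# Normalise the accepted genome representations to tibble(chrom, seq).
as_genome <- function(genome) {
  if (is.character(genome)) {
    nm <- names(genome) %||% paste0("seq", seq_along(genome))
    return(tibble(chrom = nm, seq = unname(genome)))
  }
  if (is.data.frame(genome) && all(c("chrom", "seq") %in% names(genome))) {
    return(as_tibble(genome[, c("chrom", "seq")]))
  }
  abort("genome must be a tibble with columns chrom/seq or a named character vector")
}
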