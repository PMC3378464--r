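#' Match predicted nucleosome centres to a reference map
#'
#' One-to-one greedy matching in increasing distance order: predicted and
#' reference centres on the same chromosome are paired from the closest pair
#' outwards, each centre used at most once, keeping only pairs within
#' `cutoff_bp`. A prediction is a true positive iff it is matched. One-to-one
#' matching means redundant predictions of the same reference nucleosome
#' penalise specificity instead of inflating it.
#'
#' @param calls Calls tibble with columns `chrom`, `center` (e.g. from
#'   [dlane()], [predict_meta()], [hmm_calls()] or [random_calls()]).
#' @param reference Reference tibble with columns `chrom`, `center`.
#' @param cutoff_bp Maximum centre-to-centre distance `L` for a correct
#'   prediction (must be positive).
#' @return A tibble of matches: `chrom`, `pred_center`, `ref_center`,
#'   `distance`.
#' @export
match_calls <- function(calls, reference, cutoff_bp = 35) {
  stopifnot(cutoff_bp > 0)
  out <- list()
  for (ch in unique(reference$chrom)) {
    p <- sort(calls$center[calls$chrom == ch])
    r <- sort(reference$center[reference$chrom == ch])
    if (length(p) == 0 || length(r) == 0) next
    # candidate pairs within the cutoff, via interval overlap on sorted vecs
    pairs <- candidate_pairs(p, r, cutoff_bp)
    if (nrow(pairs) == 0) next
    pairs <- pairs[order(pairs$distance, pairs$pred, pairs$ref), ]
    used_p <- logical(length(p)); used_r <- logical(length(r))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      pi <- pairs$pi[i]; ri <- pairs$ri[i]
      if (!used_p[pi] && !used_r[ri]) {
        used_p[pi] <- TRUE; used_r[ri] <- TRUE; keep[i] <- TRUE
      }
    }
    m <- pairs[keep, ]
    if (nrow(m) > 0) {
      out[[ch]] <- tibble(chrom = ch, pred_center = m$pred,
                          ref_center = m$ref, distance = m$distance)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(0), pred_center = numeric(0),
                  ref_center = numeric(0), distance = numeric(0))
  }
  res
}

candidate_pairs <- function(p, r, cutoff) {
  lo <- findInterval(p - cutoff - 1e-9, r) + 1L
  hi <- findInterval(p + cutoff + 1e-9, r)
  n <- pmax(0L, hi - lo + 1L)
  pi <- rep(seq_along(p), n)
  ri <- unlist(lapply(seq_along(p), function(i) {
    if (n[i] <= 0) integer(0) else lo[i]:hi[i]
  }))
  if (length(pi) == 0) {
    return(tibble(pi = integer(0), ri = integer(0), pred = numeric(0),
                  ref = numeric(0), distance = numeric(0)))
  }
  d <- abs(p[pi] - r[ri])
  ok <- d <= cutoff
  tibble(pi = pi[ok], ri = ri[ok], pred = p[pi][ok], ref = r[ri][ok],
         distance = d[ok])
}

#' Sensitivity, specificity and F-measure of nucleosome calls
#'
#' `Se` is the fraction of reference nucleosomes that are correctly
#' predicted, `Sp` the fraction of predictions that are correct, and the
#' F-measure their harmonic mean `2 * Se * Sp / (Se + Sp)` (0 when both are
#' 0). `evaluate_calls()` sweeps one or more distance cutoffs, and scores
#' each call `source` separately when several are present.
#'
#' @inheritParams match_calls
#' @param cutoffs Distance cutoffs `L` in bp to evaluate (default the single
#'   operating point 35; use e.g. `seq(10, 60, 10)` for a sweep).
#' @return A tibble with columns `source`, `cutoff_bp`, `tp`, `n_reference`,
#'   `n_predicted`, `se`, `sp`, `f_measure`.
#' @examples
#' f_measure(0.703, 0.412)
#' @export
evaluate_calls <- function(calls, reference, cutoffs = 35) {
  if (!"source" %in% names(calls)) calls$source <- "calls"
  grid <- expand.grid(source = unique(calls$source), cutoff_bp = cutoffs,
                      stringsAsFactors = FALSE)
  n_ref <- nrow(reference)
  purrr::pmap_dfr(grid, function(source, cutoff_bp) {
    sub <- calls[calls$source == source, ]
    tp <- nrow(match_calls(sub, reference, cutoff_bp))
    se <- if (n_ref > 0) tp / n_ref else NA_real_
    sp <- if (nrow(sub) > 0) tp / nrow(sub) else 0
    tibble(source = source, cutoff_bp = cutoff_bp, tp = tp,
           n_reference = n_ref, n_predicted = nrow(sub),
           se = se, sp = sp, f_measure = f_measure(se, sp))
  })
}

#' @rdname evaluate_calls
#' @param se,sp Sensitivity and specificity values.
#' @export
f_measure <- function(se, sp) {
  ifelse(se + sp == 0, 0, 2 * se * sp / (se + sp))
}

#' Random non-overlapping nucleosome baseline
#'
#' Samples, for each chromosome, the same number of non-overlapping 147 bp
#' nucleosomes as in the reference map, exactly uniformly among all legal
#' placements (combinatorial construction, so dense chromosomes pose no
#' problem). This is the chance-level baseline against which structural
#' predictions are compared.
#'
#' @param reference Reference tibble (`chrom`, `center`).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param seed Integer seed; the same seed reproduces the same calls.
#' @return Calls tibble with `source = "random"`.
#' @export
random_calls <- function(reference, chrom_lengths, seed = 1) {
  out <- list()
  counts <- table(reference$chrom)
  for (ch in names(counts)) {
    n <- as.integer(counts[[ch]])
    if (!ch %in% names(chrom_lengths)) {
      abort(paste0("No length provided for chromosome '", ch, "'"))
    }
    len <- chrom_lengths[[ch]]
    if (n * 147 > len) {
      abort(paste0("Chromosome '", ch, "' too short for ", n,
                   " non-overlapping nucleosomes"))
    }
    starts <- with_seed_stream(seed, ch, sample_nonoverlapping(n, len))
    out[[ch]] <- tibble(chrom = ch, start = starts, end = starts + 147,
                        center = starts + 73, score = 0, source = "random")
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# Uniform sample of n non-overlapping 147-bp placements on [0, len): via the
# stars-and-bars bijection, n sorted distinct draws from 0..(len - 147 n + n
# - 1) map one-to-one onto legal start configurations, so every legal
# configuration is equally likely even at high packing density.
sample_nonoverlapping <- function(n, len) {
  slack <- len - 147 * n
  x <- sort(sample.int(slack + n, n)) - 1L
  t <- x - (seq_len(n) - 1L)
  t + 147 * (seq_len(n) - 1L)
}

#' Pearson correlation of two tracks on their shared bins
#'
#' Aligns two profile/occupancy tibbles on (`chrom`, `pos`), drops masked
#' bins, and returns the Pearson correlation coefficient. Used to relate
#' structural profiles to experimental occupancy and to compare features
#' with each other.
#'
#' @param a,b Tibbles with columns `chrom`, `pos`, `value`.
#' @return A single correlation coefficient.
#' @export
track_correlation <- function(a, b) {
  m <- inner_join(a[, c("chrom", "pos", "value")],
                  b[, c("chrom", "pos", "value")],
                  by = c("chrom", "pos"), suffix = c("_a", "_b"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3) abort("Fewer than 3 shared unmasked bins")
  cor(m$value_a, m$value_b)
}
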