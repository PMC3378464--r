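#' Default feature set for the meta-predictor and the HMM
#'
#' The six top-performing structural features for nucleosome positioning:
#' DNA denaturation, propeller twist, DNA-bending stiffness, Z-DNA, stacking
#' energy and duplex free energy. Both the Random-Forest meta-predictor and
#' the chromatin HMM use these channels by default; all twelve features can
#' be supplied instead.
#'
#' @return Character vector of six feature names.
#' @export
top_features <- function() {
  c("DNA denaturation", "Propeller twist", "DNA-bending stiffness",
    "Z-DNA", "Stacking energy", "Duplex free energy")
}

#' Pool per-feature call sets into meta-predictor candidates
#'
#' Every individual call becomes a candidate, described by: `support_count`,
#' the number of distinct features with a call centre within `neighbor_bp`
#' of the candidate (its own source included); `nearest_neighbor_bp`, the
#' distance to the closest other candidate in the pooled set (Inf when a
#' candidate is alone on its chromosome); and one binary `flag_*` indicator
#' per feature.
#'
#' @param calls Calls tibble pooling at least two `source` features (e.g.
#'   several [dlane()] outputs row-bound together).
#' @param neighbor_bp Support radius in bp (default 73, half a nucleosome).
#' @return The candidate tibble: the call columns plus `support_count`,
#'   `nearest_neighbor_bp` and the per-feature flags.
#' @export
build_candidates <- function(calls, neighbor_bp = 73) {
  feats <- unique(calls$source)
  if (length(feats) < 2) {
    abort("Need call sets from at least 2 features to build candidates")
  }
  if (nrow(calls) == 0) return(calls)
  out <- list()
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, ]
    sub <- sub[order(sub$center), ]
    ctr <- sub$center
    n <- nrow(sub)
    # per-feature flags: does feature f call within neighbor_bp?
    flags <- matrix(0L, n, length(feats),
                    dimnames = list(NULL, paste0("flag_", feats)))
    for (fi in seq_along(feats)) {
      fc <- sort(ctr[sub$source == feats[fi]])
      if (length(fc) == 0) next
      lo <- findInterval(ctr - neighbor_bp - 1e-9, fc) + 1L
      hi <- findInterval(ctr + neighbor_bp + 1e-9, fc)
      flags[, fi] <- as.integer(hi >= lo)
    }
    support <- rowSums(flags)
    nn <- if (n > 1) {
      gaps_l <- c(Inf, diff(ctr))
      gaps_r <- c(diff(ctr), Inf)
      pmin(gaps_l, gaps_r)
    } else Inf
    res <- sub
    res$support_count <- as.integer(support)
    res$nearest_neighbor_bp <- nn
    out[[ch]] <- bind_cols(res, as_tibble(flags))
  }
  bind_rows(out)
}

#' Train the Random-Forest meta-predictor
#'
#' Labels each candidate positive iff its centre lies within
#' `label_cutoff_bp` of a reference nucleosome centre, then fits a Random
#' Forest classifier (default 100 trees) on the candidate features
#' (`support_count`, `nearest_neighbor_bp` and the per-feature flags). The
#' seed is stored so predictions are reproducible.
#'
#' @param candidates Candidate tibble from [build_candidates()].
#' @param reference Reference tibble (`chrom`, `center`) covering the
#'   training chromosome(s).
#' @param label_cutoff_bp Labelling cutoff in bp (default 35, the standard
#'   evaluation operating point).
#' @param ntree Number of trees.
#' @param seed Integer seed.
#' @return An object of class `nuc_meta`.
#' @export
train_meta <- function(candidates, reference, label_cutoff_bp = 35,
                       ntree = 100, seed = 1) {
  x <- candidate_design(candidates)
  lab <- label_candidates(candidates, reference, label_cutoff_bp)
  if (length(unique(lab)) < 2) {
    abort(c("Training labels are single-class",
            i = paste0("Adjust the synthetic data or the label cutoff so ",
                       "both accepted and rejected candidates occur")))
  }
  rf <- with_seed_stream(seed, "meta-train", {
    randomForest::randomForest(x, factor(lab, c(FALSE, TRUE)), ntree = ntree)
  })
  structure(list(forest = rf, feature_cols = colnames(x),
                 sources = sub("^flag_", "", grep("^flag_", colnames(x),
                                                  value = TRUE)),
                 label_cutoff_bp = label_cutoff_bp, ntree = ntree,
                 seed = seed,
                 train_chroms = unique(candidates$chrom)),
            class = "nuc_meta")
}

label_candidates <- function(candidates, reference, cutoff) {
  vapply(seq_len(nrow(candidates)), function(i) {
    r <- reference$center[reference$chrom == candidates$chrom[i]]
    length(r) > 0 && min(abs(r - candidates$center[i])) <= cutoff
  }, logical(1))
}

candidate_design <- function(candidates) {
  cols <- c("support_count", "nearest_neighbor_bp",
            grep("^flag_", names(candidates), value = TRUE))
  x <- as.data.frame(candidates[, cols])
  names(x) <- make.names(names(x))
  # Random Forests cannot split on Inf; cap the isolated-candidate sentinel
  x$nearest_neighbor_bp <- pmin(x$nearest_neighbor_bp, 1e6)
  x
}

#' @export
print.nuc_meta <- function(x, ...) {
  cat("Random-Forest meta-predictor:", x$ntree, "trees,",
      length(x$sources), "source features, label cutoff",
      x$label_cutoff_bp, "bp, seed", x$seed, "\n")
  invisible(x)
}

#' @method tidy nuc_meta
#' @export
tidy.nuc_meta <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(term = rownames(imp), importance = unname(imp[, 1]))
}

#' @method glance nuc_meta
#' @export
glance.nuc_meta <- function(x, ...) {
  err <- x$forest$err.rate[x$forest$ntree, "OOB"]
  tibble(ntree = x$ntree, n_train = length(x$forest$y),
         oob_error = unname(err), seed = x$seed)
}

#' Consensus nucleosome calls from the meta-predictor
#'
#' Applies the trained classifier to the candidates, single-linkage clusters
#' the accepted centres at `cluster_bp` (chains of centres each within
#' `cluster_bp` of the next form one cluster), and emits the middle
#' candidate of each cluster (lower median for even cluster sizes) as the
#' meta prediction. Clusters whose surviving calls would still overlap are
#' resolved greedily by descending `support_count`.
#'
#' @param model A `nuc_meta` from [train_meta()].
#' @param candidates Candidate tibble from [build_candidates()].
#' @param cluster_bp Clustering radius in bp (default 73).
#' @return Calls tibble with `source = "meta"`.
#' @export
predict_meta <- function(model, candidates, cluster_bp = 73) {
  stopifnot(inherits(model, "nuc_meta"))
  empty <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  center = numeric(0), score = numeric(0),
                  source = character(0))
  if (nrow(candidates) == 0) return(empty)
  x <- candidate_design(candidates)
  x <- x[, model$feature_cols, drop = FALSE]
  acc <- stats::predict(model$forest, x) == "TRUE"
  if (!any(acc)) return(empty)
  kept <- candidates[acc, ]
  out <- list()
  for (ch in unique(kept$chrom)) {
    sub <- kept[kept$chrom == ch, ]
    sub <- sub[order(sub$center), ]
    cl <- cumsum(c(1, diff(sub$center) > cluster_bp))
    reps <- vapply(split(seq_len(nrow(sub)), cl), function(idx) {
      idx[floor((length(idx) + 1) / 2)]       # lower median
    }, integer(1))
    r <- sub[reps, ]
    out[[ch]] <- tibble(chrom = ch, start = r$center - 73,
                        end = r$center + 74, center = r$center,
                        score = r$support_count, source = "meta")
  }
  res <- bind_rows(out)
  resolve_overlaps(res)
}

# Greedy non-overlap resolution by descending score (support count).
resolve_overlaps <- function(calls) {
  if (nrow(calls) < 2) return(calls)
  out <- list()
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, ]
    sub <- sub[order(-sub$score, sub$center), ]
    kept <- sub[0, ]
    for (i in seq_len(nrow(sub))) {
      if (nrow(kept) == 0 ||
          all(sub$end[i] <= kept$start | sub$start[i] >= kept$end)) {
        kept <- bind_rows(kept, sub[i, ])
      }
    }
    out[[ch]] <- kept
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}
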