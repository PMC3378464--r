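#' Simulate a genome with planted nucleosomes
#'
#' Builds chromosomes as alternating 147 bp nucleosome cores and short
#' linkers (optionally interrupted by longer nucleosome-free regions), with
#' core and linker sequence drawn from different first-order Markov chains.
#' The bundled synthetic composition (chosen once; see the package vignette)
#' makes every positive-class structural scale higher on average inside
#' cores than in linkers and every negative-class scale lower, emulating the
#' structural contrast between nucleosome-enriched and nucleosome-depleted
#' DNA. `contrast` interpolates the chains between uniform-random sequence
#' (0, no contrast) and the full bundled composition (1).
#'
#' Layout: each chromosome starts with a core at position 0, and cores are
#' separated by linkers drawn uniformly from `linker_range` (10-20 bp, the
#' typical yeast linker). With `free_fraction > 0`, nucleosome-free gaps of
#' `free_length` bp are interspersed so that approximately that fraction of
#' the chromosome is nucleosome-free. All randomness flows from `seed`
#' through a per-chromosome stream.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param core_bp Nucleosome core length (147 bp).
#' @param linker_range Two integers, min and max linker length in bp.
#' @param contrast Composition contrast in `[0, Inf)`; 0 removes the
#'   core/linker difference entirely.
#' @param free_fraction Approximate fraction of each chromosome left
#'   nucleosome-free (default 0.1).
#' @param free_length Two numbers, min and max free-gap length in bp.
#' @param composition Optional composition table (as read from the bundled
#'   `synthetic_composition.tsv`): columns `segment` (`core`/`linker`),
#'   `from`, `to`, `prob`.
#' @param dyad_taper Concentrate the core composition bias at the dyad with
#'   a squared-cosine taper towards the core edges (default TRUE), mimicking
#'   the dyad-centred positioning signal of real nucleosomal DNA; FALSE
#'   plants a uniform bias across the core.
#' @param seed Integer seed.
#' @return An object of class `nuc_sim`: a list with tibbles `genome`
#'   (`chrom`, `seq`), `nucleosomes` (`chrom`, `start`, `end`, `center` -
#'   the truth map), `free_regions` (`chrom`, `start`, `end`) and a `config`
#'   list echoing all parameters.
#' @examples
#' sim <- simulate_genome(chrom_lengths = c(chrI = 10000),
#'                        linker_range = c(15, 15), free_fraction = 0,
#'                        seed = 1)
#' nrow(sim$nucleosomes)  # 61 planted nucleosomes
#' @export
simulate_genome <- function(chrom_lengths = c(chrI = 50000, chrII = 50000),
                            core_bp = 147, linker_range = c(10, 20),
                            contrast = 1, free_fraction = 0.1,
                            free_length = c(300, 800),
                            composition = NULL, dyad_taper = TRUE,
                            seed = 1) {
  stopifnot(all(chrom_lengths > 0), core_bp > 0,
            linker_range[1] <= linker_range[2], contrast >= 0,
            free_fraction >= 0, free_fraction < 1)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  comp <- composition %||% default_composition()
  chains <- build_chains(comp, contrast, core_bp, dyad_taper)
  if (any(chrom_lengths < core_bp)) {
    abort("Every chromosome must be at least one core long")
  }
  # probability of inserting a free gap before a nucleosome unit, chosen so
  # the expected nucleosome-free fraction matches free_fraction
  mean_gap <- mean(free_length)
  mean_unit <- core_bp + mean(linker_range)
  q <- if (free_fraction > 0) {
    free_fraction * mean_unit / ((1 - free_fraction) * mean_gap)
  } else 0
  genomes <- list(); nucs <- list(); frees <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    res <- with_seed_stream(seed, ch, {
      plant_chromosome(len, core_bp, linker_range, q, free_length, chains)
    })
    genomes[[ch]] <- tibble(chrom = ch, seq = res$seq)
    if (nrow(res$nucs) > 0) res$nucs$chrom <- ch
    if (nrow(res$free) > 0) res$free$chrom <- ch
    nucs[[ch]] <- res$nucs
    frees[[ch]] <- res$free
  }
  structure(list(
    genome = bind_rows(genomes),
    nucleosomes = relocate_chrom(bind_rows(nucs)),
    free_regions = relocate_chrom(bind_rows(frees)),
    config = list(chrom_lengths = chrom_lengths, core_bp = core_bp,
                  linker_range = linker_range, contrast = contrast,
                  free_fraction = free_fraction, free_length = free_length,
                  dyad_taper = dyad_taper, seed = seed)
  ), class = "nuc_sim")
}

relocate_chrom <- function(x) {
  if (nrow(x) == 0) return(x)
  x[, c("chrom", setdiff(names(x), "chrom"))]
}

#' @export
print.nuc_sim <- function(x, ...) {
  cat("Synthetic genome:", nrow(x$genome), "chromosome(s),",
      sum(nchar(x$genome$seq)), "bp,",
      nrow(x$nucleosomes), "planted nucleosomes,",
      nrow(x$free_regions), "free regions (seed",
      x$config$seed, ")\n")
  invisible(x)
}

plant_chromosome <- function(len, core_bp, linker_range, q, free_length,
                             chains) {
  segs <- character(0)       # "core" / "linker" per segment
  seg_len <- integer(0)
  pos <- 0
  first <- TRUE
  repeat {
    if (!first) {
      lk <- linker_range[1] + sample.int(linker_range[2] - linker_range[1] + 1L, 1) - 1L
      if (pos + lk + core_bp > len) break
      segs <- c(segs, "linker"); seg_len <- c(seg_len, lk)
      pos <- pos + lk
    }
    if (q > 0 && runif(1) < q) {
      gap <- round(runif(1, free_length[1], free_length[2]))
      if (pos + gap + core_bp > len) break
      segs <- c(segs, "free"); seg_len <- c(seg_len, gap)
      pos <- pos + gap
    }
    if (pos + core_bp > len) break
    segs <- c(segs, "core"); seg_len <- c(seg_len, core_bp)
    pos <- pos + core_bp
    first <- FALSE
  }
  if (pos < len) {  # trailing tail is linker-like sequence
    segs <- c(segs, "tail"); seg_len <- c(seg_len, len - pos)
  }
  if (!any(segs == "core")) abort("Infeasible packing: no core fits")
  starts <- cumsum(c(0, head(seg_len, -1)))
  is_core <- segs == "core"
  seq <- markov_sequence(seg_len, is_core, chains)
  free_idx <- which(segs == "free")
  list(
    seq = seq,
    nucs = tibble(start = starts[is_core], end = starts[is_core] + core_bp,
                  center = starts[is_core] + (core_bp - 1) / 2),
    free = tibble(start = starts[free_idx],
                  end = starts[free_idx] + seg_len[free_idx])
  )
}

# Sample the concatenated segments position by position; each position has
# a composition level (linker, or a dyad-tapered core level).
markov_sequence <- function(seg_len, is_core, chains) {
  bases <- c("A", "C", "G", "T")
  total <- sum(seg_len)
  lab <- integer(total)                  # 0 = linker level
  pos <- cumsum(c(0, head(seg_len, -1)))
  for (si in which(is_core)) {
    lab[(pos[si] + 1):(pos[si] + seg_len[si])] <- chains$core_level
  }
  cums <- chains$cum                     # list: [[1]] linker, [[l+1]] core lvl l
  u <- runif(total)
  out <- integer(total)
  out[1] <- sample(4, 1)
  for (i in 2:total) {
    row <- cums[[lab[i] + 1L]][out[i - 1], ]
    out[i] <- findInterval(u[i], row) + 1L
  }
  paste(bases[out], collapse = "")
}

# Precompute cumulative transition matrices for the linker chain and the
# (optionally dyad-tapered) core chain levels. Weight u in [0, 1] scales the
# core logits: T(u) = row-softmax(contrast * u * log T_core); linkers use
# T = row-softmax(contrast * log T_linker). With no taper every core
# position uses u = 1.
build_chains <- function(comp, contrast, core_bp, dyad_taper) {
  t_core <- chain_matrix(comp, "core")
  t_link <- chain_matrix(comp, "linker")
  if (dyad_taper) {
    off <- seq_len(core_bp) - (core_bp + 1) / 2
    w <- cos(pi * off / core_bp)^2
  } else {
    w <- rep(1, core_bp)
  }
  lvl <- pmax(1L, as.integer(round(w * 20)))   # 20 quantized taper levels
  cum <- vector("list", 21L)
  cum[[1]] <- t(apply(soften(t_link, contrast), 1, cumsum))
  for (l in sort(unique(lvl))) {
    cum[[l + 1L]] <- t(apply(soften(t_core, contrast * l / 20), 1, cumsum))
  }
  list(cum = cum, core_level = lvl)
}

soften <- function(m, g) {
  lg <- g * log(m)
  e <- exp(lg - apply(lg, 1, max))
  e / rowSums(e)
}

chain_matrix <- function(comp, segment) {
  bases <- c("A", "C", "G", "T")
  sub <- comp[comp$segment == segment, ]
  m <- matrix(0.25, 4, 4, dimnames = list(bases, bases))
  m[cbind(match(sub$from, bases), match(sub$to, bases))] <- sub$prob
  m
}

# Read the bundled synthetic core/linker composition.
default_composition <- function() {
  path <- system.file("extdata", "synthetic_composition.tsv",
                      package = "nucstruct", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    segment = readr::col_character(), from = readr::col_character(),
    to = readr::col_character(), prob = readr::col_double()
  ))
}

#' Simulate a noisy nucleosome occupancy track
#'
#' Emulates an MNase-style continuous occupancy signal for a synthetic
#' genome: every planted nucleosome contributes a triangular footprint of
#' width `footprint_bp` peaking at its dyad (the shape of a midpoint-density
#' signal, so each core is a ~150 bp peak flanked by lower linker values and
#' track maxima sit on the planted centres by construction), binned exactly
#' like a structural profile, with Gaussian noise of standard deviation
#' `noise_sd` added per bin.
#'
#' @param sim A `nuc_sim` object from [simulate_genome()].
#' @param noise_sd Standard deviation of per-bin Gaussian noise (signal is
#'   on a 0-1 occupancy scale; default 0.5 emulates a noisy in vivo
#'   log-ratio signal, 0 gives the clean construction).
#' @param footprint_bp Footprint width in bp (default 147).
#' @param window_bp,step_bp Binning, matching [structural_profile()].
#' @param seed Integer seed for the noise.
#' @return An occupancy tibble: `chrom`, `pos`, `value`.
#' @export
simulate_occupancy <- function(sim, noise_sd = 0.5, footprint_bp = 147,
                               window_bp = 100, step_bp = 10, seed = 1) {
  stopifnot(inherits(sim, "nuc_sim"), noise_sd >= 0)
  out <- list()
  for (ch in sim$genome$chrom) {
    len <- nchar(sim$genome$seq[sim$genome$chrom == ch])
    occ <- numeric(len)
    nc <- sim$nucleosomes[sim$nucleosomes$chrom == ch, ]
    half <- (footprint_bp + 1) / 2
    for (i in seq_len(nrow(nc))) {
      span <- max(1, ceiling(nc$center[i] - half + 1)):
        min(len, floor(nc$center[i] + half + 1))
      kern <- pmax(0, 1 - abs(span - 1 - nc$center[i]) / half)
      occ[span] <- occ[span] + kern
    }
    sm <- smooth_vector(occ, window_bp = window_bp, step_bp = step_bp)
    if (noise_sd > 0) {
      sm$value <- sm$value +
        with_seed_stream(seed, paste0("occ:", ch), rnorm(nrow(sm), 0, noise_sd))
    }
    out[[ch]] <- tibble(chrom = ch, pos = sm$pos, value = sm$value)
  }
  res <- bind_rows(out)
  attr(res, "step_bp") <- step_bp
  attr(res, "window_bp") <- window_bp
  res
}


#' Simulate expression-class anchors for metaprofile tests
#'
#' Emits two classes of anchor coordinates on a synthetic genome: class
#' `"depleted"` anchors at the centres of nucleosome-free regions and class
#' `"occupied"` anchors at planted core centres. Aggregating occupancy
#' around them ([aggregate_around_anchors()]) must show the antagonistic
#' pattern expected of, e.g., active-promoter versus genic anchors.
#'
#' @param sim A `nuc_sim` object with at least one free region.
#' @param n_per_class Maximum anchors per class (default all available).
#' @param seed Integer seed for subsampling.
#' @return Anchor tibble: `chrom`, `pos`, `strand`, `class`.
#' @export
simulate_anchors <- function(sim, n_per_class = NULL, seed = 1) {
  stopifnot(inherits(sim, "nuc_sim"))
  dep <- sim$free_regions
  occ <- sim$nucleosomes
  if (nrow(dep) == 0) {
    abort("No nucleosome-free regions; simulate with free_fraction > 0")
  }
  if (nrow(occ) == 0) abort("No planted nucleosomes")
  a1 <- tibble(chrom = dep$chrom, pos = (dep$start + dep$end) / 2,
               strand = "+", class = "depleted")
  a2 <- tibble(chrom = occ$chrom, pos = occ$center, strand = "+",
               class = "occupied")
  if (!is.null(n_per_class)) {
    a1 <- with_seed_stream(seed, "anchors1",
                           a1[sample(nrow(a1), min(n_per_class, nrow(a1))), ])
    a2 <- with_seed_stream(seed, "anchors2",
                           a2[sample(nrow(a2), min(n_per_class, nrow(a2))), ])
  }
  bind_rows(a1, a2)
}
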