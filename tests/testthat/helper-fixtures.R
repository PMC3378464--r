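# Shared fixture builders. All synthetic inputs are built in code at test
# time; nothing is read from disk except the package's bundled assets.

# Profile tibble from a bare value vector (bins every step_bp, representative
# coordinate = window centre convention).
make_profile <- function(values, step_bp = 10, window_bp = 100,
                         chrom = "chrT", feature = "toy") {
  p <- tibble::tibble(
    chrom = chrom, feature = feature,
    pos = window_bp / 2 + (seq_along(values) - 1) * step_bp,
    value = as.numeric(values)
  )
  attr(p, "step_bp") <- step_bp
  attr(p, "window_bp") <- window_bp
  p
}

# A minimal two-feature scale tibble (one positive, one negative class).
toy_scales <- function() {
  kmers <- nucstruct:::all_kmers(2)
  tibble::tibble(
    feature = rep(c("posfeat", "negfeat"), each = 16),
    k = 2L,
    sign_class = rep(c("positive", "negative"), each = 16),
    units = "arbitrary",
    kmer = rep(kmers, 2),
    value = c(seq_along(kmers), rev(seq_along(kmers)))
  )
}

# A smooth profile with bumps at the requested bin indices.
bumpy_profile <- function(n_bins, bump_bins, bump_height = 10,
                          bump_halfwidth = 5, ...) {
  v <- numeric(n_bins)
  for (b in bump_bins) {
    idx <- max(1, b - bump_halfwidth):min(n_bins, b + bump_halfwidth)
    v[idx] <- v[idx] + bump_height * (1 - abs(idx - b) / (bump_halfwidth + 1))
  }
  make_profile(v, ...)
}

# Default-conditions synthetic benchmark used by several suites.
bench_sim <- function(seed, total_bp = 20000, n_chroms = 2) {
  lens <- setNames(rep(total_bp %/% n_chroms, n_chroms),
                   c("chrI", "chrII", "chrIII")[seq_len(n_chroms)])
  simulate_genome(chrom_lengths = lens, seed = seed)
}
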