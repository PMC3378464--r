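#' The twelve bundled DNA structural property scales
#'
#' Loads the physicochemical property tables that map every dinucleotide (or
#' trinucleotide, for bendability) to an experimentally derived structural
#' value: propeller twist, DNA denaturation (duplex melting stability),
#' DNA-bending stiffness, trinucleotide bendability, duplex disrupt energy
#' (melting enthalpy), base-stacking energy, B-to-Z-DNA transition energy,
#' duplex free energy, A-philicity, protein-DNA twist, B-DNA twist and
#' protein-induced deformability. Each scale carries a sign class recording
#' whether it is positively or negatively correlated with nucleosome
#' occupancy: peaks of positive-class profiles and valleys of negative-class
#' profiles mark nucleosome-favouring DNA.
#'
#' The scale values are shipped as a versioned TSV asset
#' (`inst/extdata/structural_scales.tsv` plus `scale_metadata.tsv`), sourced
#' from the published structural models; the TSV, not code, is the ground
#' truth. A custom table in the same format can be supplied via `path`.
#'
#' @param path Optional path to a scale TSV with columns `feature`, `kmer`,
#'   `value`. Defaults to the bundled table.
#' @param metadata Optional path to the companion metadata TSV with columns
#'   `feature`, `k`, `sign_class`, `units`. Defaults to the bundled table.
#' @param features Optional character vector restricting the result to a
#'   subset of features. Unknown names are an error.
#'
#' @return A tibble with one row per (feature, k-mer): columns `feature`,
#'   `k`, `sign_class`, `units`, `kmer`, `value`. Every feature has exactly
#'   `4^k` k-mer rows over the DNA alphabet.
#'
#' @examples
#' scales <- structural_scales()
#' dplyr::count(scales, feature, sign_class)
#' @export
structural_scales <- function(path = NULL, metadata = NULL, features = NULL) {
  path <- path %||% system.file("extdata", "structural_scales.tsv",
                                package = "nucstruct", mustWork = TRUE)
  metadata <- metadata %||% system.file("extdata", "scale_metadata.tsv",
                                        package = "nucstruct", mustWork = TRUE)
  values <- readr::read_tsv(path, col_types = readr::cols(
    feature = readr::col_character(),
    kmer = readr::col_character(),
    value = readr::col_double()
  ))
  meta <- readr::read_tsv(metadata, col_types = readr::cols(
    feature = readr::col_character(),
    k = readr::col_integer(),
    sign_class = readr::col_character(),
    units = readr::col_character()
  ))
  if (!is.null(features)) {
    unknown <- setdiff(features, meta$feature)
    if (length(unknown) > 0) {
      abort(c(
        paste0("Unknown structural feature(s): ",
               paste(unknown, collapse = ", ")),
        i = paste0("Valid names: ", paste(meta$feature, collapse = ", "))
      ))
    }
    meta <- meta[meta$feature %in% features, ]
    values <- values[values$feature %in% features, ]
  }
  scales <- inner_join(meta, values, by = "feature")
  validate_scales(scales)
  scales
}

#' @rdname structural_scales
#' @param scales A scale tibble as returned by [structural_scales()].
#' @export
validate_scales <- function(scales) {
  stopifnot(all(c("feature", "k", "sign_class", "kmer", "value") %in%
                  names(scales)))
  if (!all(scales$sign_class %in% c("positive", "negative"))) {
    abort("sign_class must be 'positive' or 'negative'")
  }
  for (f in unique(scales$feature)) {
    sub <- scales[scales$feature == f, ]
    k <- unique(sub$k)
    if (length(k) != 1) abort(paste0("Feature '", f, "' has inconsistent k"))
    expected <- all_kmers(k)
    missing <- setdiff(expected, sub$kmer)
    if (length(missing) > 0) {
      abort(paste0("Feature '", f, "' is missing k-mer entry '",
                   missing[1], "'"))
    }
    extra <- setdiff(sub$kmer, expected)
    if (length(extra) > 0 || nrow(sub) != length(expected)) {
      abort(paste0("Feature '", f, "' must have exactly 4^", k,
                   " unique ACGT k-mers"))
    }
    if (anyNA(sub$value)) abort(paste0("Feature '", f, "' has NA values"))
  }
  invisible(scales)
}

all_kmers <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), k),
                      stringsAsFactors = FALSE)[, k:1, drop = FALSE]
  sort(do.call(paste0, grid))
}

# Named value vector of one feature's scale, in lexicographic k-mer order.
scale_lookup <- function(scales, feature) {
  sub <- scales[scales$feature == feature, ]
  if (nrow(sub) == 0) {
    abort(paste0("Feature '", feature, "' not present in the scale table"))
  }
  setNames(sub$value, sub$kmer)[all_kmers(sub$k[1])]
}

scale_sign <- function(scales, feature) {
  s <- unique(scales$sign_class[scales$feature == feature])
  if (length(s) != 1) abort(paste0("No unique sign class for '", feature, "'"))
  s
}

scale_k <- function(scales, feature) {
  k <- unique(scales$k[scales$feature == feature])
  if (length(k) != 1) abort(paste0("No unique k for '", feature, "'"))
  as.integer(k)
}
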