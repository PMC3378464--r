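# Readers and writers for the plain-text genomics formats the toolkit
# exchanges: FASTA (via Biostrings), BED6 call sets, bedGraph tracks and the
# scale TSVs. All coordinates are 0-based half-open (BED convention); bin
# tracks are written as intervals of one bin step centred on the bin's
# representative coordinate.

#' Read and write genomes as FASTA
#'
#' Thin wrappers around \pkg{Biostrings} handling multi-record, wrapped,
#' mixed-case FASTA.
#'
#' @param path File path.
#' @return `read_genome()`: a tibble with columns `chrom`, `seq`.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(chrom = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' @rdname read_genome
#' @param genome Genome tibble (`chrom`, `seq`) or named character vector.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  x <- Biostrings::DNAStringSet(setNames(genome$seq, genome$chrom))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

provenance_line <- function(extra = "") {
  ver <- tryCatch(as.character(utils::packageVersion("nucstruct")),
                  error = function(e) "dev")
  paste0("# nucstruct ", ver, if (nzchar(extra)) paste0(" ", extra) else "")
}

#' Read and write nucleosome call sets as BED6
#'
#' BED columns: chrom, start, end, name (the call's `source` feature), score
#' (peak intensity rescaled to 0-1000 on write), strand (`.`). Coordinates
#' are 0-based half-open; `--one-based` style input can be shifted with
#' `one_based = TRUE`. Lines starting with `#` or `track` are skipped.
#'
#' @param path File path.
#' @param one_based Input uses 1-based inclusive starts; shift down on read.
#' @return `read_bed()`: a calls tibble (`chrom`, `start`, `end`, `center`,
#'   `score`, `source`).
#' @export
read_bed <- function(path, one_based = FALSE) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  if (!any(keep)) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  center = numeric(0), score = numeric(0),
                  source = character(0)))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(keep)[which(nf < 3)[1]]
    abort(paste0(path, ":", bad, ": BED line has fewer than 3 fields"))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(keep)[which(is.na(start) | is.na(end))[1]]
    abort(paste0(path, ":", bad, ": malformed BED coordinates"))
  }
  if (one_based) start <- start - 1
  if (any(end <= start)) {
    bad <- which(keep)[which(end <= start)[1]]
    abort(paste0(path, ":", bad, ": BED end must exceed start"))
  }
  src <- if (all(nf >= 4)) vapply(fields, `[`, "", 4) else "calls"
  score <- if (all(nf >= 5)) {
    suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  } else 0
  tibble(chrom = chrom, start = start, end = end,
         center = (start + end - 1) / 2,
         score = ifelse(is.na(score), 0, score), source = src)
}

#' @rdname read_bed
#' @param calls Calls tibble.
#' @param header Write a provenance comment line first.
#' @export
write_bed <- function(calls, path, header = TRUE) {
  score <- calls$score %||% 0
  mx <- suppressWarnings(max(score, na.rm = TRUE))
  scaled <- if (is.finite(mx) && mx > 0) round(1000 * score / mx) else 0L
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   calls$chrom, as.integer(calls$start),
                   as.integer(calls$end),
                   calls$source %||% "calls", as.integer(scaled))
  if (header) lines <- c(provenance_line("BED6 nucleosome calls"), lines)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a reference nucleosome map from BED
#'
#' Like [read_bed()] but returns the reference representation (sorted
#' centres per chromosome) used by the evaluation and training functions.
#'
#' @inheritParams read_bed
#' @return Tibble `chrom`, `center`, `start`, `end`, sorted by centre.
#' @export
read_reference <- function(path, one_based = FALSE) {
  b <- read_bed(path, one_based = one_based)
  arrange(b[, c("chrom", "center", "start", "end")],
          .data$chrom, .data$center)
}

#' Read and write binned tracks as bedGraph
#'
#' Four tab-separated columns (chrom, start, end, value). On write, each
#' unmasked bin becomes an interval of one bin step centred on the bin's
#' representative coordinate; masked bins are omitted. On read, the bin
#' coordinate is the interval midpoint. Overlapping intervals are rejected.
#'
#' @param path File path.
#' @return `read_bedgraph()`: a track tibble (`chrom`, `pos`, `value`).
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) != 4)) {
    bad <- which(keep)[which(lengths(fields) != 4)[1]]
    abort(paste0(path, ":", bad, ": bedGraph line must have 4 fields"))
  }
  chrom <- vapply(fields, `[`, "", 1)
  start <- as.numeric(vapply(fields, `[`, "", 2))
  end <- as.numeric(vapply(fields, `[`, "", 3))
  value <- as.numeric(vapply(fields, `[`, "", 4))
  if (anyNA(start) || anyNA(end) || any(end <= start)) {
    abort(paste0(path, ": malformed bedGraph intervals"))
  }
  d <- tibble(chrom = chrom, start = start, end = end, value = value)
  d <- arrange(d, .data$chrom, .data$start)
  overl <- d |>
    group_by(.data$chrom) |>
    summarise(bad = any(.data$start[-1] < .data$end[-length(.data$end)]),
              .groups = "drop")
  if (any(overl$bad)) abort(paste0(path, ": overlapping bedGraph intervals"))
  tibble(chrom = d$chrom, pos = (d$start + d$end) / 2, value = d$value)
}

#' @rdname read_bedgraph
#' @param track Track tibble (`chrom`, `pos`, `value`); a profile tibble
#'   with a `feature` column must be filtered to one feature first.
#' @param step_bp Bin step; inferred from the track when omitted.
#' @param header Write a provenance comment line first.
#' @export
write_bedgraph <- function(track, path, step_bp = NULL, header = TRUE) {
  if ("feature" %in% names(track) && length(unique(track$feature)) > 1) {
    abort("Track has multiple features; write one file per feature")
  }
  step <- step_bp %||% infer_step(track)
  t2 <- track[!is.na(track$value), ]
  lines <- sprintf("%s\t%d\t%d\t%s", t2$chrom,
                   as.integer(t2$pos - step / 2),
                   as.integer(t2$pos + step / 2),
                   format(t2$value, trim = TRUE, digits = 8))
  if (header) lines <- c(provenance_line("bedGraph binned track"), lines)
  readr::write_lines(lines, path)
  invisible(path)
}
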