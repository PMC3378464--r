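# 16-state chromatin HMM: one linker state L0 and fifteen ordered
# nucleosome states N1..N15 (a 147-bp core spans ~15 bins at 10-bp
# resolution). Legal transitions: L0->L0, L0->N1, Nk->Nk+1, N15->L0 and
# (optionally) N15->N1 for zero-linker abutment. Emissions are independent
# Gaussians per feature channel per state; training is supervised.

hmm_states <- function() c("L0", paste0("N", 1:15))

# predecessor table under the legal transition set
hmm_predecessors <- function(allow_wrap = TRUE) {
  preds <- list(L0 = c("L0", "N15"), N1 = if (allow_wrap) c("L0", "N15") else "L0")
  for (k in 2:15) preds[[paste0("N", k)]] <- paste0("N", k - 1)
  preds[hmm_states()]
}

#' Convert a reference nucleosome map to a per-bin HMM state path
#'
#' Each reference nucleosome claims the 15 consecutive profile bins whose
#' centres best cover it (the bin nearest the nucleosome centre, plus seven
#' bins on each side) and is labelled `N1..N15` left to right; all remaining
#' bins are the linker state `L0`. Nucleosomes whose 15-bin footprint is
#' truncated by the profile edge are skipped; footprints overlapping in bin
#' space are an illegal reference and raise an error.
#'
#' @param reference Reference tibble (`chrom`, `center`).
#' @param bins Tibble of profile bins (`chrom`, `pos`), e.g. one feature's
#'   profile.
#' @return A tibble `chrom`, `pos`, `state`.
#' @export
reference_state_path <- function(reference, bins) {
  bins <- distinct(bins[, c("chrom", "pos")])
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- sort(bins$pos[bins$chrom == ch])
    n <- length(b)
    state <- rep("L0", n)
    refs <- sort(reference$center[reference$chrom == ch])
    claimed <- integer(0)
    for (rc in refs) {
      jc <- which.min(abs(b - rc))
      j0 <- jc - 7L
      if (j0 < 1 || j0 + 14L > n) next
      idx <- j0:(j0 + 14L)
      if (any(idx %in% claimed)) {
        abort(paste0("Reference nucleosomes overlap in bin space on ", ch))
      }
      state[idx] <- paste0("N", 1:15)
      claimed <- c(claimed, idx)
    }
    out[[ch]] <- tibble(chrom = ch, pos = b, state = state)
  }
  bind_rows(out)
}

#' Train the chromatin HMM supervised
#'
#' Estimates transition probabilities as empirical counts with add-one
#' smoothing restricted to the legal transition set, and per-state emission
#' means and variances per feature channel, from a labelled state path (see
#' [reference_state_path()]).
#'
#' @param profile Profile tibble covering the training bins for the feature
#'   channels in `features`.
#' @param path State-path tibble (`chrom`, `pos`, `state`).
#' @param features Feature channels to use (default: all in `profile`).
#' @param allow_wrap Allow the direct `N15 -> N1` transition (zero-linker
#'   abutment).
#' @return An object of class `nuc_hmm`.
#' @export
train_hmm <- function(profile, path, features = NULL, allow_wrap = TRUE) {
  features <- features %||% unique(profile$feature)
  obs <- observation_matrix(profile, features)
  dat <- inner_join(path, obs, by = c("chrom", "pos"))
  if (nrow(dat) == 0) abort("Path and profile share no bins")
  states <- hmm_states()
  if (!all(dat$state %in% states)) abort("Unknown state labels in path")
  # transitions: consecutive bins within each chromosome
  counts <- matrix(0, 16, 16, dimnames = list(states, states))
  for (ch in unique(dat$chrom)) {
    s <- dat$state[dat$chrom == ch][order(dat$pos[dat$chrom == ch])]
    if (length(s) > 1) {
      tt <- table(factor(head(s, -1), states), factor(tail(s, -1), states))
      counts <- counts + as.matrix(tt)
    }
  }
  allowed <- matrix(FALSE, 16, 16, dimnames = list(states, states))
  preds <- hmm_predecessors(allow_wrap)
  for (to in states) allowed[preds[[to]], to] <- TRUE
  if (any(counts[!allowed] > 0)) {
    abort("Training path contains illegal state transitions")
  }
  trans <- matrix(0, 16, 16, dimnames = list(states, states))
  trans[allowed] <- counts[allowed] + 1       # add-one smoothing
  trans <- trans / rowSums(trans)
  # emissions
  mu <- sig2 <- matrix(NA_real_, 16, length(features),
                       dimnames = list(states, features))
  for (st in states) {
    rows <- dat[dat$state == st, features, drop = FALSE]
    ok <- rowSums(!is.na(rows)) > 0
    if (sum(ok) < 2) {
      abort(paste0("State ", st, " has fewer than 2 training bins; ",
                   "use a longer or denser training chromosome"))
    }
    mu[st, ] <- colMeans(rows, na.rm = TRUE)
    v <- apply(rows, 2, var, na.rm = TRUE)
    floorv <- 1e-8 * max(1, max(v, na.rm = TRUE))
    sig2[st, ] <- pmax(v, floorv)
  }
  init <- as.numeric(table(factor(dat$state, states))) + 1
  init <- init / sum(init)
  structure(list(transition = trans, init = setNames(init, states),
                 mean = mu, var = sig2, features = features,
                 allow_wrap = allow_wrap,
                 trained_on = unique(dat$chrom), n_bins = nrow(dat)),
            class = "nuc_hmm")
}

# bins x features wide tibble from a long profile
observation_matrix <- function(profile, features) {
  miss <- setdiff(features, unique(profile$feature))
  if (length(miss) > 0) {
    abort(paste0("Profile lacks feature channel(s): ",
                 paste(miss, collapse = ", ")))
  }
  profile |>
    filter(.data$feature %in% features) |>
    select("chrom", "pos", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}

#' @export
print.nuc_hmm <- function(x, ...) {
  cat("Chromatin HMM: 16 states (L0 + N1..N15),",
      length(x$features), "feature channel(s), trained on",
      paste(x$trained_on, collapse = ", "),
      paste0("(", x$n_bins, " bins)\n"))
  invisible(x)
}

#' @method tidy nuc_hmm
#' @export
tidy.nuc_hmm <- function(x, ...) {
  em <- as_tibble(x$mean, rownames = "state") |>
    tidyr::pivot_longer(-"state", names_to = "feature", values_to = "mean")
  ev <- as_tibble(x$var, rownames = "state") |>
    tidyr::pivot_longer(-"state", names_to = "feature", values_to = "variance")
  left_join(em, ev, by = c("state", "feature"))
}

#' @method glance nuc_hmm
#' @export
glance.nuc_hmm <- function(x, ...) {
  tibble(n_states = 16L, n_features = length(x$features),
         n_train_bins = x$n_bins,
         linker_self_transition = x$transition["L0", "L0"])
}

#' Viterbi decoding of the chromatin HMM
#'
#' Computes the most probable legal state path for each chromosome in log
#' domain. Ties are broken towards the lower-indexed (leftmost) predecessor
#' state, so decoding is deterministic. Masked feature channels contribute
#' no emission term for that bin; a fully masked bin is uninformative and
#' the path through it is decided by the transitions alone.
#'
#' @param model A `nuc_hmm` from [train_hmm()].
#' @param profile Profile tibble containing the model's feature channels.
#' @return A tibble `chrom`, `pos`, `state`.
#' @export
viterbi_decode <- function(model, profile) {
  stopifnot(inherits(model, "nuc_hmm"))
  obs <- observation_matrix(profile, model$features)
  states <- hmm_states()
  logt <- log(model$transition)
  logt[model$transition == 0] <- -Inf
  out <- list()
  for (ch in unique(obs$chrom)) {
    sub <- obs[obs$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    x <- as.matrix(sub[, model$features, drop = FALSE])
    logb <- emission_loglik(model, x)          # n x 16
    n <- nrow(x)
    delta <- matrix(-Inf, n, 16)
    back <- matrix(0L, n, 16)
    delta[1, ] <- log(model$init) + logb[1, ]
    for (t in 2:n) {
      for (s in 1:16) {
        cand <- delta[t - 1, ] + logt[, s]
        b <- which.max(cand)                   # first max = leftmost
        delta[t, s] <- cand[b] + logb[t, s]
        back[t, s] <- b
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
    out[[ch]] <- tibble(chrom = ch, pos = sub$pos, state = states[path])
  }
  bind_rows(out)
}

# log emission density per bin (rows) and state (cols); NA channels skipped
emission_loglik <- function(model, x) {
  n <- nrow(x); p <- ncol(x)
  logb <- matrix(0, n, 16)
  for (j in seq_len(p)) {
    ok <- !is.na(x[, j])
    if (!any(ok)) next
    for (s in 1:16) {
      logb[ok, s] <- logb[ok, s] +
        stats::dnorm(x[ok, j], model$mean[s, j], sqrt(model$var[s, j]),
                     log = TRUE)
    }
  }
  logb
}

#' Nucleosome calls from a decoded state path
#'
#' Every maximal complete `N1..N15` run becomes one 147 bp call centred on
#' the run's midpoint; incomplete runs truncated at sequence ends are
#' discarded. Calls are non-overlapping by construction of the legal
#' transition set.
#'
#' @param path State-path tibble (`chrom`, `pos`, `state`) from
#'   [viterbi_decode()].
#' @return Calls tibble with `source = "hmm"`.
#' @export
hmm_calls <- function(path) {
  out <- list()
  for (ch in unique(path$chrom)) {
    sub <- path[path$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    st <- sub$state
    starts_idx <- which(st == "N1")
    centers <- numeric(0); scores <- numeric(0)
    for (i in starts_idx) {
      if (i + 14 > length(st)) next
      if (all(st[i:(i + 14)] == paste0("N", 1:15))) {
        centers <- c(centers, (sub$pos[i] + sub$pos[i + 14]) / 2)
      }
    }
    if (length(centers) > 0) {
      out[[ch]] <- tibble(chrom = ch, start = centers - 73,
                          end = centers + 74, center = centers,
                          score = 1, source = "hmm")
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  center = numeric(0), score = numeric(0), source = character(0))
  }
  res
}

#' Train-and-decode convenience wrapper for the chromatin HMM
#'
#' Trains on the reference map of `train_chroms` and decodes `decode_chroms`
#' (default: all other chromosomes in the profile).
#'
#' @inheritParams train_hmm
#' @param reference Reference tibble (`chrom`, `center`).
#' @param train_chroms Chromosomes used for supervised training.
#' @param decode_chroms Chromosomes to decode.
#' @return List with elements `model` (`nuc_hmm`), `path` and `calls`.
#' @export
hmm_locate <- function(profile, reference, train_chroms,
                       decode_chroms = NULL, features = NULL,
                       allow_wrap = TRUE) {
  decode_chroms <- decode_chroms %||%
    setdiff(unique(profile$chrom), train_chroms)
  ptrain <- profile[profile$chrom %in% train_chroms, ]
  path0 <- reference_state_path(reference[reference$chrom %in% train_chroms, ],
                                ptrain)
  model <- train_hmm(ptrain, path0, features = features,
                     allow_wrap = allow_wrap)
  pdec <- profile[profile$chrom %in% decode_chroms, ]
  path <- viterbi_decode(model, pdec)
  list(model = model, path = path, calls = hmm_calls(path))
}
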