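#' Align structural profiles and an occupancy track on shared bins
#'
#' Joins the per-feature profiles (and optionally an occupancy track) into
#' one wide table on (`chrom`, `pos`), keeping only bins present and
#' unmasked in every input. Feature columns follow a fixed canonical
#' (alphabetical) order, so the design matrix is invariant to input order.
#'
#' @param profiles Profile tibble (`chrom`, `feature`, `pos`, `value`).
#' @param occupancy Optional occupancy tibble (`chrom`, `pos`, `value`).
#' @return A wide tibble: `chrom`, `pos`, one column per feature, and
#'   `occupancy` when supplied.
#' @export
align_tracks <- function(profiles, occupancy = NULL) {
  feats <- sort(unique(profiles$feature))
  wide <- observation_matrix(profiles, feats)
  wide <- wide[, c("chrom", "pos", feats)]
  if (!is.null(occupancy)) {
    occ <- rename(occupancy[, c("chrom", "pos", "value")],
                  occupancy = "value")
    wide <- inner_join(wide, occ, by = c("chrom", "pos"))
  }
  out <- wide[complete.cases(wide), ]
  if (nrow(out) == 0) abort("No shared unmasked bins between the inputs")
  arrange(out, .data$chrom, .data$pos)
}

#' Least angle regression of occupancy on structural profiles
#'
#' Fits a linear model of nucleosome occupancy on the structural profiles by
#' least angle regression (LARS): features enter the model one at a time in
#' order of their correlation with the residual, coefficients growing along
#' the equiangular direction until the next feature ties. The final model is
#' the point on the path minimising Mallows' Cp (`stop = "cp"`, the
#' conventional choice) or the full-path OLS endpoint (`stop = "full"`).
#' Features are centred and scaled internally; reported coefficients are on
#' the original scale. Chromosome-split training is supported via
#' `train_chroms`; bins of other chromosomes are never seen by the fit.
#'
#' @param profiles Profile tibble with the predictor features.
#' @param occupancy Occupancy tibble (`chrom`, `pos`, `value`).
#' @param train_chroms Chromosomes to train on (default all).
#' @param stop Model-selection rule: `"cp"` or `"full"`.
#' @return An object of class `nuc_lars` with intercept, per-feature
#'   coefficients (zeros allowed), the entry order of features, the
#'   coefficient path and Cp values.
#' @export
fit_occupancy <- function(profiles, occupancy, train_chroms = NULL,
                          stop = c("cp", "full")) {
  stop <- match.arg(stop)
  if (!is.null(train_chroms)) {
    profiles <- profiles[profiles$chrom %in% train_chroms, ]
    occupancy <- occupancy[occupancy$chrom %in% train_chroms, ]
  }
  wide <- align_tracks(profiles, occupancy)
  feats <- setdiff(names(wide), c("chrom", "pos", "occupancy"))
  X <- as.matrix(wide[, feats, drop = FALSE])
  y <- wide$occupancy
  fit <- lars_path(X, y)
  k_sel <- if (stop == "cp") which.min(fit$cp) else length(fit$cp)
  beta_std <- fit$beta[k_sel, ]
  # back-transform to original scale
  beta <- rep(0, length(feats)); names(beta) <- feats
  beta[fit$kept] <- beta_std / fit$scale
  intercept <- fit$ymean - sum(beta[fit$kept] * fit$xmean)
  structure(list(
    intercept = intercept,
    coefficients = beta,
    features = feats,
    entry_order = fit$entry_order,
    stop_rule = stop,
    stop_index = k_sel - 1L,
    cp = fit$cp,
    path = fit$beta,
    scale = fit$scale, xmean = fit$xmean, ymean = fit$ymean,
    kept = fit$kept, dropped = fit$dropped,
    n = nrow(X),
    train_chroms = unique(wide$chrom),
    r_squared = fit$r2[k_sel]
  ), class = "nuc_lars")
}

# LARS path on raw X, y. Standardizes internally; returns the path in
# standardized coordinates plus the info needed to back-transform.
lars_path <- function(X, y) {
  n <- nrow(X); p0 <- ncol(X)
  if (n < p0 + 1) abort("Need at least one more row than features")
  xmean <- colMeans(X)
  Xc <- sweep(X, 2, xmean)
  sds <- apply(Xc, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped) > 0) {
    warn(paste0("Dropping constant feature(s): ",
                paste(dropped, collapse = ", ")))
  }
  kept <- colnames(X)[sds > 0]
  Xs <- sweep(Xc[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  rank <- qr(Xs, tol = 1e-10)$rank
  if (rank == 0) abort("Design matrix has rank 0")
  if (rank < ncol(Xs)) {
    # exact collinearity is the rule rather than the exception for the
    # strand-symmetric dinucleotide scales; collinear entrants are skipped
    # along the path, as the classical LARS implementation does
    warn(paste0("Design matrix is rank deficient (rank ", rank, " < ",
                ncol(Xs), "); collinear features will be skipped"))
  }
  p <- ncol(Xs)
  ymean <- mean(y)
  yc <- y - ymean
  mu <- rep(0, n)
  beta <- matrix(0, p + 1, p, dimnames = list(NULL, kept))
  active <- integer(0)
  excluded <- integer(0)
  entry_order <- character(0)
  rss <- numeric(p + 1); rss[1] <- sum(yc^2)
  realized <- 0L
  for (step in seq_len(p)) {
    cvec <- drop(crossprod(Xs, yc - mu))
    inactive <- setdiff(seq_len(p), c(active, excluded))
    # admit the most correlated inactive feature whose equiangular system
    # is solvable; exclude entrants that are collinear with the active set
    Ginv1 <- NULL
    while (length(inactive) > 0) {
      jnew <- inactive[which.max(abs(cvec[inactive]))]
      active_try <- c(active, jnew)
      s <- sign(cvec[active_try])
      Xa <- Xs[, active_try, drop = FALSE] %*% diag(s, length(active_try))
      G <- crossprod(Xa)
      Ginv1 <- tryCatch(solve(G, rep(1, length(active_try))),
                        error = function(e) NULL)
      if (!is.null(Ginv1) && sum(Ginv1) > 0 && rcond(G) > 1e-12) break
      excluded <- c(excluded, jnew)
      inactive <- setdiff(inactive, jnew)
      Ginv1 <- NULL
    }
    if (is.null(Ginv1)) break
    active <- active_try
    entry_order <- c(entry_order, kept[jnew])
    C <- max(abs(cvec[active]))
    Aa <- 1 / sqrt(sum(Ginv1))
    w <- Aa * Ginv1
    u <- drop(Xa %*% w)
    rest <- setdiff(seq_len(p), c(active, excluded))
    if (length(rest) == 0) {
      gamma <- C / Aa
    } else {
      a <- drop(crossprod(Xs, u))
      g1 <- (C - cvec[rest]) / (Aa - a[rest])
      g2 <- (C + cvec[rest]) / (Aa + a[rest])
      gammas <- c(g1, g2)
      gammas <- gammas[is.finite(gammas) & gammas > 1e-12]
      gamma <- if (length(gammas) == 0) C / Aa else min(gammas, C / Aa)
    }
    mu <- mu + gamma * u
    beta[realized + 2L, ] <- beta[realized + 1L, ]
    beta[realized + 2L, active] <- beta[realized + 2L, active] + gamma * w * s
    rss[realized + 2L] <- sum((yc - mu)^2)
    realized <- realized + 1L
  }
  beta <- beta[seq_len(realized + 1L), , drop = FALSE]
  rss <- rss[seq_len(realized + 1L)]
  sigma2 <- rss[realized + 1L] / (n - realized - 1)
  cp <- rss / sigma2 - n + 2 * (seq_len(realized + 1L) - 1)
  list(beta = beta, entry_order = entry_order, cp = cp,
       rss = rss, r2 = 1 - rss / rss[1],
       kept = kept, dropped = dropped,
       scale = sds[sds > 0], xmean = xmean[sds > 0], ymean = ymean)
}

#' @export
print.nuc_lars <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("LARS occupancy model:", nz, "of", length(x$features),
      "features selected (", x$stop_rule, "rule ) on",
      x$n, "bins\n")
  cat("Entry order:", paste(head(x$entry_order, nz), collapse = " > "), "\n")
  invisible(x)
}

#' @method tidy nuc_lars
#' @export
tidy.nuc_lars <- function(x, ...) {
  ord <- match(x$features, x$entry_order)
  tibble(term = c("(Intercept)", x$features),
         estimate = c(x$intercept, unname(x$coefficients[x$features])),
         entry_step = c(NA_integer_, ord))
}

#' @method glance nuc_lars
#' @export
glance.nuc_lars <- function(x, ...) {
  tibble(n = x$n, n_features = length(x$features),
         n_selected = sum(x$coefficients != 0),
         stop_index = x$stop_index,
         cp = x$cp[x$stop_index + 1L],
         r_squared = x$r_squared)
}

#' Predict continuous occupancy from structural profiles
#'
#' Applies a fitted [fit_occupancy()] model as an affine map of the aligned
#' profiles. Bins masked in any input feature are masked in the output.
#'
#' @param model A `nuc_lars` object.
#' @param profiles Profile tibble containing the model's features.
#' @return An occupancy tibble: `chrom`, `pos`, `value`.
#' @export
predict_occupancy <- function(model, profiles) {
  stopifnot(inherits(model, "nuc_lars"))
  wide <- observation_matrix(profiles, model$features)
  X <- as.matrix(wide[, model$features, drop = FALSE])
  pred <- model$intercept + drop(X %*% model$coefficients[model$features])
  pred[!complete.cases(X)] <- NA_real_
  out <- tibble(chrom = wide$chrom, pos = wide$pos, value = pred)
  attr(out, "step_bp") <- attr(profiles, "step_bp")
  out
}
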