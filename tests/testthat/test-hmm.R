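mk_bins <- function(n, chrom = "chrI") {
  tibble::tibble(chrom = chrom, pos = 50 + (seq_len(n) - 1) * 10)
}

test_that("a reference nucleosome maps to one N1..N15 run flanked by linker", {
  bins <- mk_bins(40)
  ref <- tibble::tibble(chrom = "chrI", center = bins$pos[20])
  path <- reference_state_path(ref, bins)
  expect_equal(path$state[13:27], paste0("N", 1:15))
  expect_true(all(path$state[-(13:27)] == "L0"))
  # empty reference: all linker
  empty <- reference_state_path(tibble::tibble(chrom = "chrI",
                                               center = numeric(0)), bins)
  expect_true(all(empty$state == "L0"))
})

test_that("adjacent nucleosomes with a 20-bp linker leave linker bins between runs", {
  bins <- mk_bins(60)
  c1 <- bins$pos[20]
  ref <- tibble::tibble(chrom = "chrI", center = c(c1, c1 + 167))
  path <- reference_state_path(ref, bins)
  st <- path$state
  i15 <- which(st == "N15")[1]
  next_n1 <- which(st == "N1" & seq_along(st) > i15)[1]
  expect_gte(next_n1 - i15, 2)            # at least one L0 between runs
  expect_true(any(st[(i15 + 1):(next_n1 - 1)] == "L0"))
  # overlapping reference nucleosomes are illegal
  bad <- tibble::tibble(chrom = "chrI", center = c(c1, c1 + 60))
  expect_error(reference_state_path(bad, bins), "overlap")
})

test_that("supervised training recovers transition counts and emission moments", {
  withr::local_seed(10)
  bins <- mk_bins(400)
  ref <- tibble::tibble(chrom = "chrI",
                        center = seq(bins$pos[10], bins$pos[390], by = 200))
  path <- reference_state_path(ref, bins)
  # well-separated synthetic emissions: nucleosome states high, linker low
  mu_true <- ifelse(path$state == "L0", 0, 5)
  prof <- tibble::tibble(chrom = "chrI", feature = "f1", pos = bins$pos,
                         value = rnorm(nrow(bins), mu_true, 0.3))
  model <- train_hmm(prof, path)
  expect_s3_class(model, "nuc_hmm")
  expect_equal(unname(rowSums(model$transition)), rep(1, 16), tolerance = 1e-12)
  # only legal transitions have mass
  legal <- matrix(FALSE, 16, 16, dimnames = dimnames(model$transition))
  legal["L0", c("L0", "N1")] <- TRUE
  for (k in 1:14) legal[paste0("N", k), paste0("N", k + 1)] <- TRUE
  legal["N15", c("L0", "N1")] <- TRUE
  expect_true(all(model$transition[!legal] == 0))
  # emission means recovered within 3 standard errors
  n_l0 <- sum(path$state == "L0")
  expect_lt(abs(model$mean["L0", "f1"] - 0), 3 * 0.3 / sqrt(n_l0))
  expect_lt(abs(model$mean["N8", "f1"] - 5), 3 * 0.3 / sqrt(20))
  # unobserved N15 -> N1 sits at its add-one smoothing floor
  n15_to_l0 <- sum(path$state == "N15")   # every run returns to linker
  expect_equal(model$transition["N15", "N1"], 1 / (n15_to_l0 + 2))
  expect_error(train_hmm(prof[1:20, ], path[1:20, ]), "fewer than 2")
})

test_that("the linker self-transition estimate approaches 1 on linker-only data", {
  withr::local_seed(3)
  est <- sapply(c(60, 600), function(n) {
    bins <- mk_bins(n)
    # one planted nucleosome so every state has two training bins
    ref <- tibble::tibble(chrom = "chrI", center = bins$pos[n %/% 2])
    path <- reference_state_path(ref, bins)
    path2 <- dplyr::bind_rows(path, dplyr::mutate(path, chrom = "chrII"))
    prof <- tibble::tibble(chrom = path2$chrom, feature = "f1",
                           pos = path2$pos, value = rnorm(nrow(path2)))
    train_hmm(prof, path2)$transition["L0", "L0"]
  })
  expect_true(est[2] > est[1])
  expect_gt(est[2], 0.95)
})

test_that("viterbi matches brute-force enumeration on short sequences", {
  withr::local_seed(404)
  for (i in 1:25) {
    model <- random_hmm(n_feat = 2)
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 2, 0, 2), n, 2,
                dimnames = list(NULL, model$features))
    if (runif(1) < 0.2) x[sample(length(x), 1)] <- NA
    prof <- dplyr::bind_rows(lapply(1:2, function(j) {
      tibble::tibble(chrom = "c", feature = model$features[j],
                     pos = 50 + (seq_len(n) - 1) * 10, value = x[, j])
    }))
    got <- viterbi_decode(model, prof)
    want <- oracle_viterbi(model, x)
    expect_equal(got$state, want$path)
  }
})

test_that("observations at the nucleosome-state means decode as complete runs", {
  model <- random_hmm(n_feat = 1)
  # separate the linker mean clearly and tighten variances so the decoded
  # path is determined by the emissions
  model$mean["L0", 1] <- 20
  model$var[] <- 0.5
  # build an observation stream following L0 x5, N1..N15, L0 x5 at the means
  states <- c(rep("L0", 5), paste0("N", 1:15), rep("L0", 5))
  x <- matrix(model$mean[states, 1], ncol = 1,
              dimnames = list(NULL, model$features))
  prof <- tibble::tibble(chrom = "c", feature = model$features,
                         pos = 50 + (seq_along(states) - 1) * 10,
                         value = x[, 1])
  got <- viterbi_decode(model, prof)
  expect_true(any(grepl("^N", got$state)))
  calls <- hmm_calls(got)
  expect_equal(nrow(calls), 1)
})

test_that("uninformative emissions leave the path to the transitions", {
  model <- random_hmm(n_feat = 1)
  model$transition["L0", ] <- 0
  model$transition["L0", "L0"] <- 0.999
  model$transition["L0", "N1"] <- 0.001
  model$init[] <- c(0.99, rep(0.01 / 15, 15))
  prof <- tibble::tibble(chrom = "c", feature = model$features,
                         pos = 50 + (0:19) * 10, value = NA_real_)
  got <- viterbi_decode(model, prof)
  expect_true(all(got$state == "L0"))
})

test_that("state paths convert to non-overlapping 147-bp calls, dropping incomplete runs", {
  pos <- 50 + (0:39) * 10
  st <- rep("L0", 40)
  st[11:25] <- paste0("N", 1:15)
  path <- tibble::tibble(chrom = "c", pos = pos, state = st)
  calls <- hmm_calls(path)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$center, (pos[11] + pos[25]) / 2)
  expect_equal(calls$end - calls$start, 147)
  # all-linker path: no calls
  expect_equal(nrow(hmm_calls(tibble::tibble(chrom = "c", pos = pos,
                                             state = "L0"))), 0)
  # back-to-back runs via N15 -> N1
  st2 <- c(rep("L0", 3), paste0("N", 1:15), paste0("N", 1:15), rep("L0", 7))
  path2 <- tibble::tibble(chrom = "c", pos = pos, state = st2)
  calls2 <- hmm_calls(path2)
  expect_equal(nrow(calls2), 2)
  expect_true(calls2$start[2] >= calls2$end[1])
  # truncated run at the sequence end is discarded
  st3 <- c(rep("L0", 30), paste0("N", 1:10))
  expect_equal(nrow(hmm_calls(tibble::tibble(chrom = "c", pos = pos,
                                             state = st3))), 0)
})

test_that("label-then-call round trip recovers interior reference centres within half a bin", {
  bins <- mk_bins(200)
  ref <- tibble::tibble(chrom = "chrI",
                        center = c(500, 800, 1200, 1650))
  path <- reference_state_path(ref, bins)
  calls <- hmm_calls(path)
  expect_equal(nrow(calls), nrow(ref))
  expect_true(all(abs(sort(calls$center) - sort(ref$center)) <= 5))
})

test_that("the decoded path is at least as probable as the generating path", {
  withr::local_seed(6)
  model <- random_hmm(n_feat = 1)
  # sample a legal path and emissions from the model
  states <- c("L0", paste0("N", 1:15))
  st <- "L0"; pathv <- character(0)
  for (t in 1:30) {
    pathv <- c(pathv, st)
    st <- sample(states, 1, prob = model$transition[st, ])
  }
  x <- matrix(rnorm(30, model$mean[pathv, 1], sqrt(model$var[pathv, 1])),
              ncol = 1, dimnames = list(NULL, model$features))
  prof <- tibble::tibble(chrom = "c", feature = model$features,
                         pos = 50 + (0:29) * 10, value = x[, 1])
  got <- viterbi_decode(model, prof)
  lp <- function(sts) {
    tot <- log(model$init[[sts[1]]]) +
      sum(dnorm(x[, 1], model$mean[sts, 1], sqrt(model$var[sts, 1]),
                log = TRUE))
    for (t in 2:length(sts)) {
      tot <- tot + log(model$transition[sts[t - 1], sts[t]])
    }
    tot
  }
  expect_gte(lp(got$state), lp(pathv) - 1e-9)
})
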